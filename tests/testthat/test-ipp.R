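test_that("quadrature design conserves length and evaluates covariates exactly", {
  net <- single_edge_net(8000, multitrack = TRUE)
  set.seed(41)
  d <- build_design(net, network_points(1, 3000), covs = list(),
                    dummies = network_points(1, 6000))
  expect_equal(sum(d$w), 8000)
  expect_equal(d$y * d$w, c(1, 0))

  w <- small_world()
  set.seed(42)
  cases <- w$cases[1:20, ]
  des <- build_design(w$net, cases, w$covs, n_dummy = 300)
  expect_equal(sum(des$w), total_network_length(w$net), tolerance = 1e-6)
  expect_true(all(abs(des$y * des$w - as.numeric(des$is_data)) < 1e-9))
  mt_col <- des$V[, "multitrack"]
  expect_equal(mt_col, as.numeric(w$net$edges$multitrack[des$pts$edge]))

  # weights agree with the fine-discretization oracle on a Y network
  yn <- y_net()
  pts_c <- network_points(1, 500)
  pts_d <- network_points(c(2, 3), c(500, 800))
  dy <- build_design(yn, pts_c, covs = list(), dummies = pts_d)
  wo <- oracle_tessellation(yn, network_points(c(1, 2, 3), c(500, 500, 800)))
  expect_lt(max(abs(dy$w - wo)) / total_network_length(yn), 0.01)
})

test_that("intercept-only fit recovers the homogeneous closed form log(n/L)", {
  set.seed(43)
  w <- small_world()
  L <- total_network_length(w$net)
  n <- 800
  ints <- replicate(5, {
    cs <- random_network_points(w$net, n)
    d <- build_design(w$net, cs, covs = list(), n_dummy = 2000)
    fit_ipp(d)$coefficients[["intercept"]]
  })
  se <- sd(ints) / sqrt(5)
  expect_lt(abs(mean(ints) - log(n / L)), 3 * max(se, 0.01))
})

test_that("fit recovers known coefficients within 3 standard errors", {
  set.seed(44)
  w <- small_world()
  theta <- c(intercept = -7, psy = 8, multitrack = 0.6, pop = 0.5,
             comp1 = 0.25, comp2 = -0.25)
  cases <- simulate_cases(w$net, w$covs, theta, 3000)
  f <- fit_ipp(build_design(w$net, cases, w$covs, n_dummy = 8000))
  expect_true(f$converged)
  for (nm in names(theta)[-1]) {
    expect_lt(abs(f$coefficients[[nm]] - theta[[nm]]), 3 * f$se[[nm]])
  }
})

test_that("doubling the dummy count moves coefficients less than their SEs", {
  set.seed(45)
  w <- small_world()
  theta <- c(intercept = -7, multitrack = 0.6, pop = 0.5)
  cases <- simulate_cases(w$net, w$covs, theta, 1500)
  f1 <- fit_ipp(build_design(w$net, cases, w$covs[c("multitrack", "pop")],
                             n_dummy = 4000))
  f2 <- fit_ipp(build_design(w$net, cases, w$covs[c("multitrack", "pop")],
                             n_dummy = 8000))
  expect_true(all(abs(f1$coefficients - f2$coefficients) <=
                    pmax(f1$se, 1e-3)))
})

test_that("noise-averaged fit collapses to the plain fit as sigma shrinks", {
  set.seed(46)
  w <- small_world()
  cases <- w$cases[1:120, ]
  covs <- w$covs[c("multitrack", "pop")]
  nf <- fit_with_noise(w$net, cases, covs, n_reps = 5, sigma_m = 1,
                       n_dummy = 1500)
  f0 <- fit_ipp(build_design(w$net, cases, covs, n_dummy = 1500))
  # 1 m noise: replicate spread reflects only dummy regeneration
  expect_lt(max(abs(nf$mean - f0$coefficients) / pmax(abs(f0$coefficients), 0.1)),
            0.25)
  expect_equal(nrow(nf$fits), 5)
})

test_that("simulated patterns reduce to CSR under flat covariates", {
  set.seed(47)
  w <- small_world()
  pats <- simulate_fitted(w$net, c(intercept = -6), covs = list(), N = 8000,
                          n_real = 1)
  cnt <- tabulate(pats[[1]]$edge, nbins = nrow(w$net$edges))
  p <- w$net$edges$length_m / total_network_length(w$net)
  expect_gt(stats::chisq.test(cnt, p = p)$p.value, 0.001)
  expect_equal(nrow(pats[[1]]), 8000)
})

test_that("simulate-refit loop closes: all |Z| below 3", {
  set.seed(48)
  w <- small_world()
  theta <- c(intercept = -7, multitrack = 0.6, pop = 0.5)
  covs <- w$covs[c("multitrack", "pop")]
  cases <- simulate_cases(w$net, covs, theta, 1000)
  f <- fit_ipp(build_design(w$net, cases, covs, n_dummy = 4000))
  pats <- simulate_fitted(w$net, f$coefficients, covs, N = 1000, n_real = 30)
  refits <- t(sapply(pats, function(p) {
    fit_ipp(build_design(w$net, p, covs, n_dummy = 4000))$coefficients
  }))
  zt <- coefficient_z_test(f$coefficients, refits)
  expect_true(all(abs(zt$Z) < 3))
  expect_true(all(zt$p_value >= 0 & zt$p_value <= 1))
  expect_named(zt, c("variable", "mean", "sd", "Z", "p_value"))
})

test_that("Z-test degenerate and error cases", {
  input <- c(a = 1, b = -2)
  refits <- rbind(input, input, input)
  zt <- coefficient_z_test(input, refits)
  expect_equal(zt$Z, c(0, 0))
  expect_equal(zt$p_value, c(1, 1))
  expect_error(coefficient_z_test(input, refits[1, , drop = FALSE]), "2 refits")
  bad <- rbind(c(1.5, -2), c(1.5, -2))
  expect_error(coefficient_z_test(input, bad), "zero simulation")
})

test_that("excess risks multiply back to the fitted intensity", {
  set.seed(49)
  w <- small_world()
  g <- w$model$grid
  segs <- network_pixel_segments(w$net, g)
  cells <- unique(segs$cell)[1:50]
  coefs <- c(intercept = -7, psy = 8, multitrack = 0.6, pop = 0.5,
             comp1 = 0.25, comp2 = -0.25)
  er <- excess_risk(coefs, w$covs, w$net, g, cells)
  # theta_j = 0 gives er = 1 everywhere
  c0 <- coefs; c0["pop"] <- 0
  er0 <- excess_risk(c0, w$covs, w$net, g, cells)
  expect_true(all(er0$er[, "pop"] == 1))
  # reconstruction identity
  U <- log(er$er) %*% diag(1 / coefs[-1])
  lam <- exp(coefs[1]) * apply(er$er, 1, prod)
  expect_equal(lam, er$lambda, tolerance = 1e-10)
  # hotspot means average the pixel ERs
  hs <- list(structure(list(cells = cells[1:5]), class = "hotspot"))
  erh <- excess_risk(coefs, w$covs, w$net, g, cells, hotspots = hs)
  expect_equal(as.numeric(erh$hotspot_er[1, ]),
               as.numeric(colMeans(er$er[1:5, ])))
})

test_that("mean coefficient bias over 50 replicates stays below 10% of truth", {
  set.seed(70)
  cfg <- synth_config(seed = 70)
  w <- synth_world(cfg, n_pca_sample = 5000)
  theta <- w$theta
  ests <- t(replicate(50, {
    cases <- simulate_cases(w$net, w$covs, theta, 1130)
    fit_ipp(build_design(w$net, cases, w$covs, n_dummy = 20000))$coefficients
  }))
  bias <- colMeans(ests)[names(theta)[-1]] - theta[-1]
  se_mean <- apply(ests, 2, sd)[names(theta)[-1]] / sqrt(nrow(ests))
  # bound: 10% of the true magnitude plus Monte Carlo allowance on the mean
  expect_true(all(abs(bias) <= 0.10 * abs(theta[-1]) + 3 * se_mean))
})
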