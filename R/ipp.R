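#' Build the quadrature design for the dummy-point Poisson GLM
#'
#' The Berman-Turner device on a network: data points (the cases) and random
#' dummy points jointly tessellate the network; each point receives its
#' nearest-by-shortest-path share `w_i` of the total arc length, the response
#' is `y_i = 1/w_i` for data points and 0 for dummies, and covariates are
#' evaluated exactly at the point locations. A weighted Poisson GLM with log
#' link on this design maximizes the discretized IPP likelihood.
#'
#' @param net a `rail_network`
#' @param cases `network_points` of case locations (snapped to the network)
#' @param covs named covariate list (see [eval_covariates()])
#' @param n_dummy number of dummy points (default 20000)
#' @param dummies optional fixed dummy `network_points`
#' @return object of class `ipp_design`: `V`, `y`, `w`, `is_data`, `pts`
#' @export
build_design <- function(net, cases, covs, n_dummy = 20000, dummies = NULL) {
  .check_points(net, cases)
  if (is.null(dummies)) dummies <- random_network_points(net, n_dummy)
  pts <- network_points(c(cases$edge, dummies$edge),
                        c(cases$offset_m, dummies$offset_m))
  is_data <- c(rep(TRUE, nrow(cases)), rep(FALSE, nrow(dummies)))
  w <- network_tessellation(net, pts)
  if (any(w <= 0)) {
    # co-located points can produce zero shares; give them a tiny share so
    # 1/w stays finite (their contribution to the likelihood is negligible)
    w[w <= 0] <- 1e-9
  }
  y <- ifelse(is_data, 1 / w, 0)
  V <- eval_covariates(net, covs, pts)
  structure(list(V = V, y = y, w = w, is_data = is_data, pts = pts,
                 total_length = total_network_length(net)),
            class = "ipp_design")
}

#' Fit the inhomogeneous Poisson process by the weighted GLM device
#'
#' Maximizes the quadrature-weighted Poisson log-likelihood with log link
#' (iteratively reweighted least squares via `stats::glm.fit`). Deterministic
#' given the design.
#'
#' @param design an `ipp_design`
#' @return object of class `ipp_fit`: `coefficients` (intercept first),
#'   `se`, `converged`, `deviance`
#' @export
fit_ipp <- function(design) {
  X <- cbind(intercept = 1, design$V)
  # quasipoisson gives the identical IRLS solution to poisson for the
  # Berman-Turner device but skips the dpois-based AIC, which is undefined
  # (and costly) for the non-integer responses y = 1/w
  fit <- suppressWarnings(
    stats::glm.fit(X, design$y, weights = design$w,
                   family = stats::quasipoisson(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  p <- ncol(X)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  se <- rep(NA_real_, p)
  cov_ok <- !inherits(try(ci <- chol2inv(R), silent = TRUE), "try-error")
  if (cov_ok) se <- sqrt(diag(ci))
  names(se) <- names(fit$coefficients)
  structure(list(coefficients = fit$coefficients, se = se,
                 converged = fit$converged, deviance = fit$deviance),
            class = "ipp_fit")
}

#' @export
print.ipp_fit <- function(x, ...) {
  cat("Inhomogeneous Poisson process fit (network quadrature GLM)\n")
  print(data.frame(estimate = x$coefficients, se = x$se))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' Noise-averaged IPP fit
#'
#' Repeats the fit under independent Gaussian location-noise realizations of
#' the cases (displacement along the network), regenerating the dummy set
#' each time, and averages the coefficient estimates.
#'
#' @param net a `rail_network`
#' @param cases `network_points`
#' @param covs covariate list
#' @param n_reps number of noise realizations (default 39)
#' @param sigma_m noise sd (m; default 1000)
#' @param n_dummy dummy points per fit
#' @return list: `mean`, `sd` (per coefficient), `fits` (reps x coef matrix),
#'   `n_dropped`
#' @export
fit_with_noise <- function(net, cases, covs, n_reps = 39, sigma_m = 1000,
                           n_dummy = 20000) {
  stopifnot(n_reps >= 1)
  rows <- list()
  dropped <- 0
  for (r in seq_len(n_reps)) {
    pts <- gaussian_displace(net, cases, sigma_m)
    f <- fit_ipp(build_design(net, pts, covs, n_dummy = n_dummy))
    if (f$converged) rows[[length(rows) + 1]] <- f$coefficients
    else dropped <- dropped + 1
  }
  if (dropped > 0.2 * n_reps) stop("more than 20% of noise-replicate fits failed")
  fits <- do.call(rbind, rows)
  list(mean = colMeans(fits), sd = apply(fits, 2, stats::sd),
       fits = fits, n_dropped = dropped)
}

#' Simulate realizations of a fitted network IPP
#'
#' Builds an intensity mass per pixel-subsegment of the working grid (raster
#' covariates contribute their containing-pixel value, the multitrack flag is
#' exact per edge; mass = exp(linear predictor) x subsegment length) and
#' draws, per realization, `N` cases multinomially over subsegments with
#' uniform placement inside each subsegment.
#'
#' @param net a `rail_network`
#' @param coefs named coefficients, intercept first (as from [fit_ipp()])
#' @param covs covariate list matching `names(coefs)[-1]`
#' @param N cases per realization (default 1130)
#' @param n_real number of realizations (default 199)
#' @param pixel_m working grid pixel (default 250)
#' @param segs optional precomputed [network_pixel_segments()] table
#' @return list of `network_points` patterns
#' @export
simulate_fitted <- function(net, coefs, covs, N = 1130, n_real = 199,
                            pixel_m = 250, segs = NULL) {
  if (any(!is.finite(coefs))) stop("non-finite coefficients")
  if (is.null(segs)) {
    segs <- network_pixel_segments(net, network_grid(net, pixel_m, pad_m = 0))
  }
  mids <- network_points(segs$edge, (segs$o0 + segs$o1) / 2)
  V <- eval_covariates(net, covs[names(coefs)[-1]], mids)
  lp <- coefs[1] + as.vector(V %*% coefs[-1])
  mass <- exp(lp - max(lp)) * segs$len
  if (sum(mass) <= 0) stop("zero total intensity")
  lapply(seq_len(n_real), function(r) {
    k <- sample.int(length(mass), N, replace = TRUE, prob = mass)
    network_points(segs$edge[k],
                   segs$o0[k] + stats::runif(N) * (segs$o1[k] - segs$o0[k]))
  })
}

#' Z-test of simulation input coefficients against refitted coefficients
#'
#' For each coefficient: `Z = (mean(refits) - input) / sd(refits)` with a
#' two-sided standard-normal p-value. Small |Z| for every coefficient
#' indicates negligible discretization error of the simulation grid.
#'
#' @param input_coefs named input coefficient vector
#' @param refits matrix of refitted coefficients (one row per realization)
#' @return data frame: `variable`, `mean`, `sd`, `Z`, `p_value`
#' @export
coefficient_z_test <- function(input_coefs, refits) {
  refits <- as.matrix(refits)
  if (nrow(refits) < 2) stop("need at least 2 refits")
  m <- colMeans(refits)
  s <- apply(refits, 2, stats::sd)
  degen <- s == 0
  if (any(degen & abs(m - input_coefs) > 1e-12)) {
    stop("zero simulation standard deviation")
  }
  Z <- ifelse(degen, 0, (m - input_coefs) / s)
  data.frame(variable = names(input_coefs), mean = m, sd = s, Z = Z,
             p_value = 2 * stats::pnorm(-abs(Z)), row.names = NULL)
}

#' Per-variable excess risk
#'
#' The fitted log-linear intensity factorizes over covariates:
#' `lambda(x) = exp(theta_0) * prod_j er_j(x)` with
#' `er_j(x) = exp(theta_j u_j(x))`, `u_j` being the covariate exactly as it
#' entered the GLM. Returns per-pixel excess risks at the given cells and,
#' if hotspots are supplied, their per-hotspot means.
#'
#' @param coefs named coefficients, intercept first
#' @param covs covariate list matching `names(coefs)[-1]`
#' @param net a `rail_network`
#' @param grid the working `grid_spec`
#' @param cells pixel indices (into the grid, column-major) to evaluate;
#'   multitrack is evaluated via [multitrack_raster()] on this grid
#' @param hotspots optional list from [extract_hotspots()] (whose `cells`
#'   refer to the same grid)
#' @return list: `er` (cells x variables matrix), `baseline`
#'   (`exp(intercept)`), `lambda` (reconstructed intensity per cell),
#'   `hotspot_er` (hotspots x variables means, if requested)
#' @export
excess_risk <- function(coefs, covs, net, grid, cells, hotspots = NULL) {
  vn <- names(coefs)[-1]
  cx <- grid$origin[1] + (((cells - 1L) %% grid$nx) + 0.5) * grid$pixel_m
  cy <- grid$origin[2] + (((cells - 1L) %/% grid$nx) + 0.5) * grid$pixel_m
  U <- matrix(NA_real_, length(cells), length(vn), dimnames = list(NULL, vn))
  mtr <- NULL
  for (j in seq_along(vn)) {
    cj <- covs[[vn[j]]]
    if (inherits(cj, "multitrack_cov")) {
      if (is.null(mtr)) mtr <- multitrack_raster(net, grid)
      U[, j] <- mtr$values[cells]
    } else {
      U[, j] <- raster_lookup(cj, cbind(cx, cy))
    }
  }
  er <- exp(sweep(U, 2, coefs[-1], "*"))
  lambda <- exp(coefs[1]) * apply(er, 1, prod)
  out <- list(er = er, baseline = exp(coefs[1]), lambda = lambda)
  if (!is.null(hotspots)) {
    out$hotspot_er <- t(vapply(hotspots, function(h) {
      colMeans(er[match(h$cells, cells), , drop = FALSE])
    }, numeric(length(vn))))
    colnames(out$hotspot_er) <- vn
  }
  out
}
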