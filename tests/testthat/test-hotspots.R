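test_that("box counting assigns each point to exactly one pixel", {
  expect_true(all(box_count(matrix(numeric(0), 0, 2), c(0, 0), 100) == 0))
  cnt <- box_count(matrix(rep(c(312, 475), 7), 7, 2, byrow = TRUE),
                   c(0, 0), 1000)
  expect_equal(sum(cnt), 7)
  expect_equal(max(cnt), 7)
  set.seed(31)
  xy <- cbind(runif(1000, -3000, 3000), runif(1000, -3000, 3000))
  for (orig in list(c(-3000, -3000), c(-3123, -3457))) {
    expect_equal(sum(box_count(xy, orig, 700)), 1000)
  }
  # half-open boundary: a point exactly on a pixel edge belongs to the upper pixel
  b <- box_count(rbind(c(1000, 0)), c(0, 0), 1000, nx = 2, ny = 1)
  expect_equal(b[2, 1], 1L)
})

test_that("displaced grids subdivide the base pixel symmetrically into 16 origins", {
  o <- displaced_grid_origins(1000, 250)
  expect_equal(nrow(o), 16)
  expect_equal(sort(unique(o$dx)), c(0, 250, 500, 750))
  expect_equal(sort(unique(o$dy)), c(0, 250, 500, 750))
  expect_equal(nrow(unique(o)), 16)
})

test_that("ensemble image has n_real x 16 counts per pixel and ordered quantiles", {
  set.seed(32)
  w <- small_world()
  cases <- w$cases[1:40, ]
  img <- ensemble_quantile_image(w$net, cases, sigma_m = 500, n_real = 5,
                                 q = 0.10)
  expect_equal(img$ensemble_size, 5 * 16)
  expect_equal(dim(img$case_pix), c(40, 5))
  # q = 0 gives the pointwise minimum, q = 1 the maximum, min <= max
  set.seed(32)
  img0 <- ensemble_quantile_image(w$net, cases, sigma_m = 500, n_real = 5, q = 0)
  set.seed(32)
  img1 <- ensemble_quantile_image(w$net, cases, sigma_m = 500, n_real = 5, q = 1)
  expect_true(all(img0$values <= img1$values))
  expect_true(all(img$values >= img0$values - 1e-12))
  expect_true(all(img$values <= img1$values + 1e-12))
  expect_error(ensemble_quantile_image(w$net, cases, sigma_m = -1), "sigma")
})

test_that("a single concentrated case mass produces one local hotspot", {
  set.seed(33)
  net <- single_edge_net(20000)
  cases <- network_points(rep(1, 60), rnorm(60, 10000, 150))
  img <- ensemble_quantile_image(net, cases, sigma_m = 300, n_real = 30)
  hs <- extract_hotspots(img)
  expect_gte(length(hs), 1)
  # the top hotspot brackets most of the mass around offset 10 km
  top <- hotspot_summary(hs[1], img)
  expect_lt(abs(top$x_max - 10000), 2000)
  expect_gte(top$cases_hi, top$cases_lo)
})

# minimal hand-built quantile image for connectivity/merging checks
fake_img <- function(values, n_cases = 0, n_real = 1) {
  g <- grid_spec(c(0, 0), 250, nrow(values), ncol(values))
  structure(list(grid = g, values = values, mean_counts = values,
                 case_pix = matrix(integer(0), 0, n_real),
                 ensemble_size = 16, n_real = n_real, n_grids = 16, q = 0.1),
            class = "quantile_image")
}

test_that("hotspot extraction: connectivity, merging and thresholds", {
  expect_equal(length(extract_hotspots(fake_img(matrix(0, 5, 5)))), 0)

  # diagonal neighbours join under 8-connectivity, not under 4
  v <- matrix(0, 5, 5); v[2, 2] <- 1; v[3, 3] <- 1
  expect_equal(length(extract_hotspots(fake_img(v), merge_dist_px = 0)), 1)
  expect_equal(length(extract_hotspots(fake_img(v), connectivity = 4,
                                       merge_dist_px = -1)), 2)

  # groups 3 pixels apart merge, 4 apart do not
  v3 <- matrix(0, 12, 3); v3[2, 2] <- 1; v3[6, 2] <- 1   # gap of 3 pixels
  expect_equal(length(extract_hotspots(fake_img(v3))), 1)
  v4 <- matrix(0, 12, 3); v4[2, 2] <- 1; v4[7, 2] <- 1   # gap of 4 pixels
  expect_equal(length(extract_hotspots(fake_img(v4))), 2)

  # raising the threshold never increases the above-threshold pixel count
  set.seed(34)
  vr <- matrix(rpois(400, 1), 20, 20)
  n_above <- sapply(0:4, function(th) sum(vr > th))
  expect_true(all(diff(n_above) <= 0))
})

test_that("hotspot summary reports area, case range and hand-checked distance", {
  set.seed(35)
  net <- single_edge_net(4000)
  cases <- network_points(rep(1, 30), runif(30, 1800, 2200))
  img <- ensemble_quantile_image(net, cases, sigma_m = 100, n_real = 20)
  hs <- extract_hotspots(img)
  expect_gte(length(hs), 1)
  tab <- hotspot_summary(hs, img,
                         hospitals = data.frame(x_m = 2125, y_m = 3125,
                                                total_beds = 100,
                                                n_department_types = 2,
                                                has_psychiatry = TRUE))
  expect_equal(tab$area_px[1], length(hs[[1]]$cells))
  # all 30 cases stay near the centre: the range brackets the total count
  expect_gte(tab$cases_hi[1], tab$cases_lo[1])
  expect_gte(tab$cases_hi[1], 20)
  # hand-computed Euclidean distance from the reported maximum-density pixel
  want <- sqrt((2125 - tab$x_max[1])^2 + (3125 - tab$y_max[1])^2) / 1000
  expect_equal(tab$psych_dist_km[1], want)
  # no psychiatric institutions: distance missing
  tab0 <- hotspot_summary(hs, img, hospitals = NULL)
  expect_true(is.na(tab0$psych_dist_km[1]))
})

test_that("hotspot pipeline is reproducible and stable at coarser grids", {
  w <- small_world()
  cases <- w$cases[1:150, ]
  set.seed(36)
  i1 <- ensemble_quantile_image(w$net, cases, n_real = 10)
  set.seed(36)
  i2 <- ensemble_quantile_image(w$net, cases, n_real = 10)
  expect_identical(i1$values, i2$values)
  expect_identical(i1$case_pix, i2$case_pix)

  # with 500 m destination pixels the dominant hotspot carries a similar
  # case mass
  set.seed(37)
  i250 <- ensemble_quantile_image(w$net, cases, n_real = 15)
  set.seed(37)
  i500 <- ensemble_quantile_image(w$net, cases, n_real = 15,
                                  dest_pixel_m = 500, base_pixel_m = 1000)
  h250 <- extract_hotspots(i250)
  h500 <- extract_hotspots(i500)
  if (length(h250) && length(h500)) {
    expect_lt(abs(h250[[1]]$approx_cases - h500[[1]]$approx_cases),
              0.5 * max(h250[[1]]$approx_cases, h500[[1]]$approx_cases) + 5)
  }
})
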