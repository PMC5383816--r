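test_that("shortest-path distances: identity, single edge, and oracle agreement", {
  net1 <- single_edge_net(10000)
  a <- network_points(1, 2000); b <- network_points(1, 7500)
  expect_equal(shortest_path_distance(net1, a, a), 0)
  expect_equal(shortest_path_distance(net1, a, b), 5500)

  tri <- triangle_net()
  m3 <- network_points(1, 1500)   # midpoint of the 3 km edge
  m4 <- network_points(2, 2000)   # midpoint of the 4 km edge
  d <- shortest_path_distance(tri, m3, m4)
  expect_equal(d, oracle_distance(tri, m3, m4, step = 1), tolerance = 1e-6)

  # random pairs on a small synthetic network vs the discretization oracle
  set.seed(101)
  w <- small_world()
  pts <- random_network_points(w$net, 4)
  for (i in 1:3) {
    d <- shortest_path_distance(w$net, pts[i, ], pts[i + 1, ])
    expect_equal(d, oracle_distance(w$net, pts[i, ], pts[i + 1, ], step = 5),
                 tolerance = 5e-3)
  }
})

test_that("shortest-path distance is a metric on random triples", {
  set.seed(102)
  w <- small_world()
  pts <- random_network_points(w$net, 30)
  M <- network_distance_matrix(w$net, pts)
  expect_true(all(M >= 0))
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  for (r in 1:50) {
    ijk <- sample.int(30, 3)
    expect_lte(M[ijk[1], ijk[2]],
               M[ijk[1], ijk[3]] + M[ijk[3], ijk[2]] + 1e-9)
  }
})

test_that("edge lengths equal polyline arc lengths and invalid points error", {
  g <- rbind(c(0, 0), c(300, 400), c(300, 1400))   # arc 500 + 1000
  net <- rail_network(rbind(c(0, 0), c(300, 1400)),
                      data.frame(from = 1, to = 2), geoms = list(g))
  expect_equal(net$edges$length_m, 1500)
  # coordinates at an offset lie on the polyline
  xy <- network_point_coords(net, network_points(1, 250))
  expect_equal(as.numeric(xy), c(150, 200))
  expect_error(shortest_path_distance(net, network_points(1, 2000),
                                      network_points(1, 0)),
               "offset")
  expect_error(shortest_path_distance(net, network_points(9, 0),
                                      network_points(1, 0)),
               "edge")
})

test_that("random network points are uniform with respect to arc length", {
  expect_equal(nrow(random_network_points(triangle_net(), 0)), 0)
  set.seed(103)
  net <- rail_network(rbind(c(0, 0), c(1000, 0), c(1000, 3000)),
                      data.frame(from = c(1, 2), to = c(2, 3)))
  p <- random_network_points(net, 40000)
  frac_long <- mean(p$edge == 2)
  se <- sqrt(0.75 * 0.25 / 40000)
  expect_lt(abs(frac_long - 0.75), 3 * se)

  # 5-edge fixture: per-edge counts consistent with length-proportional
  # multinomial at alpha = 0.001
  net5 <- rail_network(cbind(0:5 * 1000, 0),
                       data.frame(from = 1:5, to = 2:6))
  net5$edges$length_m   # all 1000
  p5 <- random_network_points(net5, 10000)
  cnt <- tabulate(p5$edge, nbins = 5)
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)
})

test_that("gaussian displacement preserves the network and matches the normal law", {
  net <- single_edge_net(1e6)
  p0 <- network_points(rep(1, 10000), rep(5e5, 10000))
  set.seed(104)
  pd <- gaussian_displace(net, p0, sigma_m = 1000)
  expect_true(all(pd$offset_m >= 0 & pd$offset_m <= 1e6))
  delta <- pd$offset_m - 5e5
  expect_lt(abs(sd(delta) / 1000 - 1), 0.03)
  expect_gt(stats::shapiro.test(delta[1:5000])$p.value, 0.001)

  # on a branched network the result is always a valid network point
  set.seed(105)
  w <- small_world()
  pts <- random_network_points(w$net, 200)
  moved <- gaussian_displace(w$net, pts, 2000)
  expect_true(all(moved$edge >= 1 & moved$edge <= nrow(w$net$edges)))
  expect_true(all(moved$offset_m >= 0 &
                    moved$offset_m <= w$net$edges$length_m[moved$edge]))
  expect_error(gaussian_displace(w$net, pts, 0), "sigma")
})

test_that("tessellation: conservation, two-point split, and oracle equivalence", {
  net1k <- single_edge_net(1000)
  expect_equal(network_tessellation(net1k, network_points(1, 333)), 1000)
  expect_equal(network_tessellation(net1k, network_points(c(1, 1), c(200, 800))),
               c(500, 500))
  expect_error(network_tessellation(net1k, network_points(integer(0), numeric(0))),
               "at least one")

  yn <- y_net()
  pts <- network_points(c(1, 2, 3), c(100, 700, 900))
  w <- network_tessellation(yn, pts)
  wo <- oracle_tessellation(yn, pts, step = 1)
  expect_lt(max(abs(w - wo)) / total_network_length(yn), 0.01)
  expect_equal(sum(w), total_network_length(yn), tolerance = 1e-9)

  set.seed(106)
  for (rep in 1:5) {
    cfg <- synth_config(seed = 500 + rep, extent_m = c(6000, 4000),
                        cell_m = 2000, n_hospitals = 0)
    net <- make_network(cfg)
    pts <- random_network_points(net, sample(3:9, 1))
    w <- network_tessellation(net, pts)
    wo <- oracle_tessellation(net, pts, step = 1)
    expect_lt(max(abs(w - wo)) / max(wo), 0.01)
    expect_lt(abs(sum(w) - total_network_length(net)) /
                total_network_length(net), 1e-6)
  }
})

test_that("pixel segments partition every edge exactly", {
  set.seed(107)
  w <- small_world()
  grid <- network_grid(w$net, 250, pad_m = 0)
  segs <- network_pixel_segments(w$net, grid)
  expect_equal(sum(segs$len), total_network_length(w$net), tolerance = 1e-9)
  bylen <- tapply(segs$len, segs$edge, sum)
  expect_equal(as.numeric(bylen), w$net$edges$length_m, tolerance = 1e-9)
  expect_true(all(segs$ix >= 1 & segs$ix <= grid$nx))
})

test_that("GeoJSON round trip preserves the network", {
  net <- triangle_net()
  tf <- tempfile(fileext = ".geojson")
  write_network_geojson(net, tf)
  net2 <- read_network_geojson(tf)
  expect_equal(total_network_length(net2), total_network_length(net))
  expect_equal(sort(net2$edges$length_m), sort(net$edges$length_m))
  expect_equal(sum(net2$edges$multitrack), 1)
  unlink(tf)
})
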