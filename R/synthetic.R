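#' Configuration for the synthetic study system
#'
#' Defaults emulate the study conditions the pipeline is built for: a
#' connected planar railway network of a few hundred kilometres with a
#' contiguous multitrack subnetwork, a spatially autocorrelated log-normal
#' population surface on a 1 km source grid, hospitals placed preferentially
#' in populated areas with skewed bed counts, cases drawn from a known
#' log-linear intensity, and a raw case table of 1170 records of which
#' 4 + 6 + 30 carry the exclusion flags.
#'
#' @param seed integer seed consumed by [synth_world()]
#' @param extent_m network extent (width, height) in metres
#' @param cell_m grid cell size of the generated network (m)
#' @param diag_frac fraction of cells receiving a diagonal edge
#' @param multitrack_frac fraction of total edge length flagged multitrack
#'   (grown as one contiguous subnetwork)
#' @param pop_pixel_m population source grid pixel (m; default 1000)
#' @param dest_pixel_m working/destination grid pixel (m; default 250)
#' @param pop_meanlog,pop_sdlog log-normal parameters of the population field
#' @param pop_corr_m spatial autocorrelation bandwidth of the latent fields (m)
#' @param n_hospitals number of hospitals
#' @param psych_frac probability a hospital has a psychiatric department
#' @param beds_meanlog,beds_sdlog log-normal parameters of total bed counts
#' @param socio_mixing mixing matrix (fields x 2) generating the
#'   socio-economic rasters from the two latent fields
#' @param socio_noise_sd independent noise added to each socio field
#' @param socio_pixel_m socio raster pixel size (m; coarse, default 2000)
#' @param theta named true coefficient vector (intercept, psy, multitrack,
#'   pop, comp1, comp2) of the ground-truth log-linear intensity
#' @param n_cases number of retained cases (default 1130)
#' @param raw_total,n_liechtenstein,n_inside_train,n_off_network raw-table
#'   record counts (defaults 1170, 4, 6, 30)
#' @param study_window character length-2, ISO dates of the study period
#' @return a `synth_config` list
#' @export
synth_config <- function(seed = 1L,
                         extent_m = c(32000, 18000),
                         cell_m = 2000,
                         diag_frac = 0.10,
                         multitrack_frac = 0.25,
                         pop_pixel_m = 1000,
                         dest_pixel_m = 250,
                         pop_meanlog = 3.0,
                         pop_sdlog = 1.1,
                         pop_corr_m = 3000,
                         n_hospitals = 40,
                         psych_frac = 0.5,
                         beds_meanlog = 5.0,
                         beds_sdlog = 0.7,
                         socio_mixing = rbind(c(1.0, 0.2), c(0.8, -0.4),
                                              c(-0.3, 1.0), c(0.2, 0.9)),
                         socio_noise_sd = 0.15,
                         socio_pixel_m = 2000,
                         theta = c(intercept = -9, psy = 10, multitrack = 0.7,
                                   pop = 0.6, comp1 = 0.3, comp2 = -0.3),
                         n_cases = 1130,
                         raw_total = 1170,
                         n_liechtenstein = 4,
                         n_inside_train = 6,
                         n_off_network = 30,
                         study_window = c("1998-01-01", "2009-12-31")) {
  cfg <- as.list(environment())
  stopifnot(all(extent_m > 0), n_cases >= 0,
            n_liechtenstein + n_inside_train + n_off_network <= raw_total)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic rail network
#'
#' Connected grid-with-diagonals network over the configured extent, with a
#' contiguous multitrack subnetwork grown from a random edge.
#'
#' @param cfg a `synth_config`
#' @return a `rail_network`
#' @export
make_network <- function(cfg) {
  nx <- round(cfg$extent_m[1] / cfg$cell_m)
  ny <- round(cfg$extent_m[2] / cfg$cell_m)
  if (nx < 1 || ny < 1) stop("degenerate extent")
  vid <- function(i, j) i + (j - 1) * (nx + 1)           # i in 1..nx+1
  verts <- as.matrix(expand.grid(x = (0:nx) * cfg$cell_m,
                                 y = (0:ny) * cfg$cell_m))
  from <- integer(0); to <- integer(0)
  for (j in 1:(ny + 1)) for (i in 1:nx) {               # horizontal
    from <- c(from, vid(i, j)); to <- c(to, vid(i + 1, j))
  }
  for (j in 1:ny) for (i in 1:(nx + 1)) {               # vertical
    from <- c(from, vid(i, j)); to <- c(to, vid(i, j + 1))
  }
  ncell <- nx * ny
  ndiag <- round(cfg$diag_frac * ncell)
  if (ndiag > 0) {
    cells <- sample.int(ncell, ndiag)
    ci <- (cells - 1) %% nx + 1
    cj <- (cells - 1) %/% nx + 1
    up <- stats::runif(ndiag) < 0.5
    from <- c(from, ifelse(up, vid(ci, cj), vid(ci, cj + 1)))
    to <- c(to, ifelse(up, vid(ci + 1, cj + 1), vid(ci + 1, cj)))
  }
  edges <- data.frame(from = from, to = to, multitrack = FALSE)
  net <- rail_network(verts, edges)
  # grow a contiguous multitrack subnetwork up to the target length share
  target <- cfg$multitrack_frac * total_network_length(net)
  if (target > 0) {
    mt <- logical(nrow(net$edges))
    frontier <- sample.int(nrow(net$edges), 1)
    acc <- 0
    while (acc < target && length(frontier)) {
      e <- frontier[1]; frontier <- frontier[-1]
      if (mt[e]) next
      mt[e] <- TRUE
      acc <- acc + net$edges$length_m[e]
      nb <- unique(c(net$incident[[net$edges$from[e]]],
                     net$incident[[net$edges$to[e]]]))
      frontier <- c(frontier, nb[!mt[nb]])
    }
    net$edges$multitrack <- mt
  }
  net
}

# spatially autocorrelated standard-normal field on a grid
.latent_field <- function(grid, corr_m) {
  z <- cov_raster(grid, matrix(stats::rnorm(grid$nx * grid$ny), grid$nx, grid$ny))
  s <- .smooth_field(z, corr_m, grid)
  (s - mean(s)) / stats::sd(as.vector(s))
}

#' Generate synthetic covariate inputs and a hospital table
#'
#' Produces a strictly positive log-normal population raster with spatial
#' autocorrelation, coarse socio-economic rasters as known linear mixes of
#' two latent fields plus independent noise, and hospitals sampled with
#' probability proportional to population.
#'
#' @param net a `rail_network` from [make_network()]
#' @param cfg a `synth_config`
#' @return list: `pop` (1 km `cov_raster`), `socio` (named raster list),
#'   `hospitals` (data frame), `latents`, `mixing`
#' @export
make_covariates <- function(net, cfg) {
  pad <- 8000
  pgrid <- network_grid(net, cfg$pop_pixel_m, pad_m = pad)
  z1 <- .latent_field(pgrid, cfg$pop_corr_m)
  pop <- cov_raster(pgrid, exp(cfg$pop_meanlog + cfg$pop_sdlog * z1), "pop")
  # socio fields on a coarse grid: linear mixes of (standardized log pop,
  # independent latent) plus noise, so the PCA structure is known
  sgrid <- network_grid(net, cfg$socio_pixel_m, pad_m = pad)
  l1 <- matrix(raster_lookup(cov_raster(pgrid, z1),
                             do.call(expand.grid, grid_centres(sgrid))),
               sgrid$nx, sgrid$ny)
  l2 <- .latent_field(sgrid, cfg$pop_corr_m)
  A <- cfg$socio_mixing
  socio <- list()
  for (k in seq_len(nrow(A))) {
    v <- A[k, 1] * l1 + A[k, 2] * l2 +
      cfg$socio_noise_sd * matrix(stats::rnorm(sgrid$nx * sgrid$ny), sgrid$nx, sgrid$ny)
    socio[[paste0("socio", k)]] <- cov_raster(sgrid, v, paste0("socio", k))
  }
  hospitals <- if (cfg$n_hospitals > 0) {
    mass <- as.vector(pop$values)
    cell <- sample.int(length(mass), cfg$n_hospitals, replace = TRUE, prob = mass)
    ix <- (cell - 1) %% pgrid$nx + 1
    iy <- (cell - 1) %/% pgrid$nx + 1
    data.frame(
      x_m = pgrid$origin[1] + (ix - 1 + stats::runif(cfg$n_hospitals)) * pgrid$pixel_m,
      y_m = pgrid$origin[2] + (iy - 1 + stats::runif(cfg$n_hospitals)) * pgrid$pixel_m,
      total_beds = pmax(1, round(stats::rlnorm(cfg$n_hospitals, cfg$beds_meanlog,
                                               cfg$beds_sdlog))),
      n_department_types = 1 + stats::rpois(cfg$n_hospitals, 5),
      has_psychiatry = stats::runif(cfg$n_hospitals) < cfg$psych_frac)
  } else {
    data.frame(x_m = numeric(0), y_m = numeric(0), total_beds = numeric(0),
               n_department_types = integer(0), has_psychiatry = logical(0))
  }
  list(pop = pop, socio = socio, hospitals = hospitals,
       latents = list(l1 = cov_raster(pgrid, z1, "l1"),
                      l2 = cov_raster(sgrid, l2, "l2")),
       mixing = A)
}

#' Simulate cases from a log-linear network intensity
#'
#' Conditional on the case count N, locations are i.i.d. with density
#' proportional to `exp(theta . v(x))` with respect to arc length. Sampling
#' is exact by inversion on a fine segmentation of the edges.
#'
#' @param net a `rail_network`
#' @param covs named covariate list (see [eval_covariates()]); must match
#'   `names(theta)` after the intercept
#' @param theta named coefficients; first element is the intercept
#' @param N number of cases
#' @param seg_m segmentation resolution (m; default 10)
#' @return `network_points`
#' @export
simulate_cases <- function(net, covs, theta, N, seg_m = 10) {
  if (N == 0) return(network_points(integer(0), numeric(0)))
  stopifnot(all(names(theta)[-1] %in% names(covs)))
  segs <- .fine_segments(net, seg_m)
  mids <- network_points(segs$edge, (segs$o0 + segs$o1) / 2)
  V <- eval_covariates(net, covs[names(theta)[-1]], mids)
  lp <- theta[1] + as.vector(V %*% theta[-1])
  if (any(!is.finite(lp))) stop("non-finite intensity")
  wt <- exp(lp - max(lp)) * segs$len
  k <- sample.int(length(wt), N, replace = TRUE, prob = wt)
  network_points(segs$edge[k], segs$o0[k] + stats::runif(N) * (segs$o1[k] - segs$o0[k]))
}

.fine_segments <- function(net, seg_m) {
  lens <- net$edges$length_m
  nseg <- pmax(1L, ceiling(lens / seg_m))
  edge <- rep(seq_along(lens), nseg)
  idx <- sequence(nseg)
  step <- rep(lens / nseg, nseg)
  data.frame(edge = edge, o0 = (idx - 1) * step, o1 = idx * step, len = step)
}

#' Generate a raw case table with exclusion flags
#'
#' Produces exactly `cfg$raw_total` records: the configured numbers flagged
#' as Liechtenstein cases (coordinates far outside the study extent), cases
#' inside trains (on-network coordinates, flag set) and off-network cases
#' (coordinates displaced well beyond the snapping tolerance); the remainder
#' are clean cases drawn from the ground-truth intensity, with coordinates
#' jittered by at most 30 m so that snapping is exercised. Record order is
#' shuffled; dates are uniform over the study window.
#'
#' @param net a `rail_network`
#' @param covs covariate list for the ground-truth intensity
#' @param cfg a `synth_config`
#' @return data frame: `id`, `date`, `x_m`, `y_m`, `liechtenstein`,
#'   `inside_train`, `off_network`
#' @export
make_raw_case_table <- function(net, covs, cfg) {
  n_excl <- cfg$n_liechtenstein + cfg$n_inside_train + cfg$n_off_network
  if (n_excl > cfg$raw_total) stop("exclusion counts exceed total")
  total <- cfg$raw_total
  if (total == 0) {
    return(data.frame(id = integer(0), date = as.Date(character(0)),
                      x_m = numeric(0), y_m = numeric(0),
                      liechtenstein = integer(0), inside_train = integer(0),
                      off_network = integer(0)))
  }
  n_clean <- total - n_excl
  n_on <- n_clean + cfg$n_inside_train
  pts <- simulate_cases(net, covs, cfg$theta, n_on)
  xy <- network_point_coords(net, pts)
  ang <- stats::runif(n_on) * 2 * pi
  rad <- stats::runif(n_on) * 30
  xy <- xy + cbind(rad * cos(ang), rad * sin(ang))
  flags <- matrix(0L, total, 3,
                  dimnames = list(NULL, c("liechtenstein", "inside_train", "off_network")))
  coords <- matrix(NA_real_, total, 2)
  coords[seq_len(n_on), ] <- xy
  flags[n_clean + seq_len(cfg$n_inside_train), "inside_train"] <- 1L
  i <- n_on
  if (cfg$n_off_network > 0) {
    # rejection sampling guarantees the off-network records really are
    # beyond the snapping tolerance (with margin) of every edge
    got <- matrix(numeric(0), 0, 2)
    while (nrow(got) < cfg$n_off_network) {
      m <- 4 * (cfg$n_off_network - nrow(got))
      base <- random_network_points(net, m)
      bxy <- network_point_coords(net, base)
      ang <- stats::runif(m) * 2 * pi
      rad <- 500 + stats::runif(m) * 1500
      prop <- bxy + cbind(rad * cos(ang), rad * sin(ang))
      dist <- snap_to_network(net, prop, max_dist_m = 1e9)$dist_m
      got <- rbind(got, prop[dist > 200, , drop = FALSE])
    }
    coords[i + seq_len(cfg$n_off_network), ] <- got[seq_len(cfg$n_off_network), ]
    flags[i + seq_len(cfg$n_off_network), "off_network"] <- 1L
    i <- i + cfg$n_off_network
  }
  if (cfg$n_liechtenstein > 0) {
    coords[i + seq_len(cfg$n_liechtenstein), ] <-
      cbind(-1e5 - stats::runif(cfg$n_liechtenstein) * 1e4,
            -1e5 - stats::runif(cfg$n_liechtenstein) * 1e4)
    flags[i + seq_len(cfg$n_liechtenstein), "liechtenstein"] <- 1L
  }
  win <- as.Date(cfg$study_window)
  dates <- win[1] + floor(stats::runif(total) * (as.numeric(win[2] - win[1]) + 1))
  ord <- sample.int(total)
  out <- data.frame(id = seq_len(total), date = dates,
                    x_m = coords[ord, 1], y_m = coords[ord, 2])
  out <- cbind(out, as.data.frame(flags[ord, , drop = FALSE]))
  out
}

#' Generate a complete synthetic study system
#'
#' Seeds the RNG from `cfg$seed` and generates, in order: the network, the
#' covariate inputs and hospital table, the assembled five-covariate model
#' stack, the ground-truth case pattern and the raw case table.
#'
#' @param cfg a `synth_config`
#' @param n_pca_sample sample size for the PCA stage
#' @return list: `cfg`, `net`, `raw` (population/socio/hospitals), `model`
#'   (from [build_model_covariates()]), `covs`, `theta`, `cases`, `raw_table`
#' @export
synth_world <- function(cfg = synth_config(), n_pca_sample = 20000) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  net <- make_network(cfg)
  raw <- make_covariates(net, cfg)
  model <- build_model_covariates(net, raw$pop, raw$socio, raw$hospitals,
                                  dest_pixel_m = cfg$dest_pixel_m,
                                  n_pca_sample = n_pca_sample)
  cases <- simulate_cases(net, model$covs, cfg$theta, cfg$n_cases)
  raw_table <- make_raw_case_table(net, model$covs, cfg)
  list(cfg = cfg, net = net, raw = raw, model = model, covs = model$covs,
       theta = cfg$theta, cases = cases, raw_table = raw_table)
}
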