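#' Approximate psychiatric bed count of a hospital
#'
#' Proxy for psychiatric department size: total beds divided by the number of
#' department types, for institutions with a psychiatric department.
#'
#' @param hospitals data frame with columns `total_beds`,
#'   `n_department_types`, `has_psychiatry`
#' @return numeric vector, one value per row
#' @export
approx_psych_beds <- function(hospitals) {
  if (!all(hospitals$has_psychiatry)) {
    stop("approx_psych_beds is defined only for hospitals with a psychiatric department")
  }
  if (any(hospitals$n_department_types < 1)) stop("n_department_types must be >= 1")
  hospitals$total_beds / hospitals$n_department_types
}

# psychiatric hospitals with their approximate bed mass
.psych_mass <- function(hospitals) {
  h <- hospitals[hospitals$has_psychiatry, , drop = FALSE]
  list(xy = cbind(h$x_m, h$y_m),
       beds = if (nrow(h)) approx_psych_beds(h) else numeric(0))
}

#' Psychiatric bed density at arbitrary locations
#'
#' Gaussian kernel density (beds per square kilometre) of the approximate
#' psychiatric bed masses, evaluated exactly at the given coordinates.
#'
#' @param hospitals hospital table (`x_m`, `y_m`, `total_beds`,
#'   `n_department_types`, `has_psychiatry`)
#' @param xy two-column coordinate matrix
#' @param bandwidth_m kernel bandwidth (m); default 800
#' @export
bed_density_at <- function(hospitals, xy, bandwidth_m = 800) {
  pm <- .psych_mass(hospitals)
  xy <- .as_xy(xy)
  out <- numeric(nrow(xy))
  norm <- 1e6 / (2 * pi * bandwidth_m^2)
  for (k in seq_along(pm$beds)) {
    r2 <- (xy[, 1] - pm$xy[k, 1])^2 + (xy[, 2] - pm$xy[k, 2])^2
    out <- out + pm$beds[k] * norm * exp(-r2 / (2 * bandwidth_m^2))
  }
  out
}

#' Psychiatric-bed GLM covariate raster
#'
#' Rasterizes the approximate psychiatric bed counts, offsets by one (the bed
#' counts are zero almost everywhere), logarithmizes, and finally smooths with
#' a Gaussian kernel of 0.8 km bandwidth.
#'
#' @param hospitals hospital table
#' @param dest_grid destination `grid_spec` (typically the 250 m working grid)
#' @param bandwidth_m kernel bandwidth (m)
#' @export
psych_bed_covariate <- function(hospitals, dest_grid, bandwidth_m = 800) {
  pm <- .psych_mass(hospitals)
  src <- rasterize_mass(dest_grid, pm$xy, pm$beds, name = "psy_beds")
  smoothed_log_field(src, bandwidth_m, dest_grid = dest_grid, offset = 1,
                     name = "psy")
}

#' Binary multitrack raster
#'
#' Pixel value 1 where any multitrack edge intersects the pixel, else 0.
#' (For IPP fitting the multitrack covariate is evaluated exactly from the
#' edge flag at each point, not through this raster.)
#'
#' @param net a `rail_network`
#' @param grid destination `grid_spec`
#' @export
multitrack_raster <- function(net, grid) {
  segs <- network_pixel_segments(net, grid)
  v <- matrix(0, grid$nx, grid$ny)
  mt <- segs$cell[net$edges$multitrack[segs$edge]]
  v[unique(mt)] <- 1
  cov_raster(grid, v, "multitrack")
}

#' Population-weighted centred PCA of socio-economic fields
#'
#' Samples all fields at uniform random points on the network, centres each
#' variable by its population-weighted mean, weights observations by the
#' (unlogged) smoothed population, and eigen-decomposes the weighted
#' covariance. Returns the first two component score rasters on the common
#' grid, the loadings and the explained-variance fractions.
#'
#' @param fields named list of `cov_raster`s sharing one destination grid
#' @param pop_weights `cov_raster` of (unlogged) smoothed population used as
#'   observation weights
#' @param net a `rail_network`
#' @param n_sample number of random network sample points (default 20000)
#' @return list: `comp1`, `comp2` (score `cov_raster`s), `loadings`,
#'   `explained`, `means`, `dropped`
#' @export
socio_pca <- function(fields, pop_weights, net, n_sample = 20000) {
  stopifnot(length(fields) >= 2, n_sample >= length(fields))
  pts <- random_network_points(net, n_sample)
  xy <- network_point_coords(net, pts)
  X <- sapply(fields, raster_lookup, xy = xy)
  colnames(X) <- names(fields)
  if (anyNA(X)) stop("sampled point outside a covariate raster")
  wts <- raster_lookup(pop_weights, xy)
  wts <- pmax(wts, 0)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant field(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    fields <- fields[colnames(X)]
  }
  if (ncol(X) < 2) stop("need at least two non-constant fields")
  mu <- colSums(X * wts) / sum(wts)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc * sqrt(wts / sum(wts)))   # weighted covariance
  eig <- eigen(C, symmetric = TRUE)
  load <- eig$vectors
  # sign convention: largest-magnitude entry of each loading positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(X)
  explained <- pmax(eig$values, 0) / sum(pmax(eig$values, 0))
  # score rasters on the common grid
  grid <- fields[[1]]$grid
  G <- sapply(fields, function(f) as.vector(f$values))
  Sc <- sweep(G, 2, mu) %*% load[, 1:2, drop = FALSE]
  list(comp1 = cov_raster(grid, matrix(Sc[, 1], grid$nx, grid$ny), "comp1"),
       comp2 = cov_raster(grid, matrix(Sc[, 2], grid$nx, grid$ny), "comp2"),
       loadings = load, explained = explained, means = mu, dropped = dropped)
}

#' Marker for the exact multitrack covariate
#'
#' Placed in a covariate list, evaluates at a network point as the multitrack
#' flag of the point's edge (1/0) rather than through a raster.
#' @export
multitrack_cov <- function() structure(list(), class = "multitrack_cov")

#' Evaluate a covariate list at network points
#'
#' Raster covariates use containing-pixel lookup at the point's planar
#' coordinates; `multitrack_cov()` entries use the exact edge flag.
#'
#' @param net a `rail_network`
#' @param covs named list of `cov_raster` / `multitrack_cov` entries
#' @param pts `network_points`
#' @param xy optional precomputed coordinates for `pts`
#' @return numeric matrix, one column per covariate
#' @export
eval_covariates <- function(net, covs, pts, xy = NULL) {
  if (is.null(xy)) xy <- network_point_coords(net, pts)
  V <- matrix(NA_real_, nrow(pts), length(covs),
              dimnames = list(NULL, names(covs)))
  for (j in seq_along(covs)) {
    cj <- covs[[j]]
    if (inherits(cj, "multitrack_cov")) {
      V[, j] <- as.numeric(net$edges$multitrack[pts$edge])
    } else if (inherits(cj, "cov_raster")) {
      V[, j] <- raster_lookup(cj, xy)
    } else {
      stop("unsupported covariate entry: ", names(covs)[j])
    }
  }
  if (anyNA(V)) stop("covariate undefined (NA) at some points; raster too small?")
  V
}

#' Assemble the standard five-covariate stack
#'
#' Builds the explanatory variables of the intensity model on a common 250 m
#' working grid: smoothed log population (bandwidth 1.6 km), smoothed log
#' psychiatric bed counts (offset 1, bandwidth 0.8 km), exact multitrack flag,
#' and the first two population-weighted principal components of the
#' socio-economic fields.
#'
#' @param net a `rail_network`
#' @param pop_raster population source `cov_raster` (typically 1 km pixels)
#' @param socio_fields named list of socio-economic `cov_raster`s
#' @param hospitals hospital table
#' @param dest_pixel_m working grid pixel size (default 250)
#' @param pop_bandwidth_m,psy_bandwidth_m kernel bandwidths (m)
#' @param n_pca_sample network sample size for the PCA
#' @return list: `covs` (named covariate list in model order: psy, multitrack,
#'   pop, comp1, comp2), `pca`, `grid`
#' @export
build_model_covariates <- function(net, pop_raster, socio_fields, hospitals,
                                   dest_pixel_m = 250,
                                   pop_bandwidth_m = 1600,
                                   psy_bandwidth_m = 800,
                                   n_pca_sample = 20000) {
  grid <- network_grid(net, dest_pixel_m, pad_m = 4 * dest_pixel_m)
  pop <- smoothed_log_field(pop_raster, pop_bandwidth_m, dest_grid = grid,
                            offset = if (any(pop_raster$values == 0)) 1 else 0,
                            name = "pop")
  psy <- psych_bed_covariate(hospitals, grid, psy_bandwidth_m)
  pop_w <- smoothed_field(pop_raster, pop_bandwidth_m, dest_grid = grid,
                          name = "pop_weight")
  fields <- lapply(socio_fields, function(f) {
    cov_raster(grid, matrix(raster_lookup(f, do.call(expand.grid, grid_centres(grid))),
                            grid$nx, grid$ny), f$name)
  })
  names(fields) <- names(socio_fields)
  # population joins the PCA on the log scale (same transformation as the
  # model covariate) so its variance is commensurate with the socio fields
  fields$pop <- pop
  pca <- socio_pca(fields, pop_w, net, n_sample = n_pca_sample)
  list(covs = list(psy = psy, multitrack = multitrack_cov(), pop = pop,
                   comp1 = pca$comp1, comp2 = pca$comp2),
       pca = pca, grid = grid)
}
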