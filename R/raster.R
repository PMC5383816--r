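#' Regular grid specification
#'
#' @param origin numeric length-2, lower-left corner (m)
#' @param pixel_m pixel side length (m)
#' @param nx,ny number of pixels in x and y
#' @return a `grid_spec` list
#' @export
grid_spec <- function(origin, pixel_m, nx, ny) {
  stopifnot(pixel_m > 0, nx >= 1, ny >= 1)
  structure(list(origin = as.numeric(origin), pixel_m = pixel_m,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' Grid covering a network bounding box
#'
#' @param net a `rail_network`
#' @param pixel_m pixel size (m)
#' @param pad_m padding added on every side (m)
#' @export
network_grid <- function(net, pixel_m, pad_m = pixel_m) {
  xy <- do.call(rbind, net$geoms)
  x0 <- min(xy[, 1]) - pad_m; y0 <- min(xy[, 2]) - pad_m
  nx <- max(1, ceiling((max(xy[, 1]) + pad_m - x0) / pixel_m))
  ny <- max(1, ceiling((max(xy[, 2]) + pad_m - y0) / pixel_m))
  grid_spec(c(x0, y0), pixel_m, nx, ny)
}

#' Pixel-centre coordinates of a grid
#' @param grid a `grid_spec`
#' @return list with vectors `x`, `y`
#' @export
grid_centres <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$pixel_m,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$pixel_m)
}

#' Covariate raster
#'
#' A named matrix of values on a regular grid; `values[ix, iy]` with `ix`
#' increasing eastwards and `iy` northwards.
#'
#' @param grid a `grid_spec`
#' @param values numeric matrix of dimension `nx` x `ny`
#' @param name variable name
#' @export
cov_raster <- function(grid, values, name = "") {
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$nx, ncol(values) == grid$ny)
  structure(list(grid = grid, values = values, name = name), class = "cov_raster")
}

#' @export
print.cov_raster <- function(x, ...) {
  cat(sprintf("cov_raster '%s': %d x %d pixels of %g m, range [%.4g, %.4g]\n",
              x$name, x$grid$nx, x$grid$ny, x$grid$pixel_m,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Raster value at planar coordinates (containing-pixel lookup)
#'
#' @param r a `cov_raster`
#' @param xy two-column coordinate matrix
#' @return numeric vector; `NA` outside the grid
#' @export
raster_lookup <- function(r, xy) {
  xy <- .as_xy(xy)
  g <- r$grid
  ix <- floor((xy[, 1] - g$origin[1]) / g$pixel_m) + 1
  iy <- floor((xy[, 2] - g$origin[2]) / g$pixel_m) + 1
  ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
  out <- rep(NA_real_, nrow(xy))
  out[ok] <- r$values[cbind(ix[ok], iy[ok])]
  out
}

#' Sum point masses into grid pixels
#'
#' @param grid a `grid_spec`
#' @param xy two-column coordinate matrix
#' @param mass per-point mass (default 1)
#' @return `cov_raster` of per-pixel mass totals; points outside are dropped
#' @export
rasterize_mass <- function(grid, xy, mass = NULL, name = "mass") {
  xy <- .as_xy(xy)
  if (is.null(mass)) mass <- rep(1, nrow(xy))
  ix <- floor((xy[, 1] - grid$origin[1]) / grid$pixel_m) + 1
  iy <- floor((xy[, 2] - grid$origin[2]) / grid$pixel_m) + 1
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  v <- matrix(0, grid$nx, grid$ny)
  if (any(ok)) {
    cell <- ix[ok] + (iy[ok] - 1) * grid$nx
    tot <- tapply(mass[ok], cell, sum)
    v[as.integer(names(tot))] <- tot
  }
  cov_raster(grid, v, name)
}

# 1-D Gaussian weight matrix between destination and source centre vectors,
# truncated (per axis) at `trunc` bandwidths.
.gauss_w <- function(dest, src, h, trunc = 4) {
  d <- outer(dest, src, "-")
  w <- exp(-d^2 / (2 * h^2))
  w[abs(d) > trunc * h] <- 0
  w
}

# Gaussian-kernel-weighted mean of a transformed source raster, evaluated on
# a destination grid. Separable; truncation at 4 bandwidths per axis with
# renormalization through the weight denominator.
.smooth_field <- function(source, bandwidth_m, dest_grid, transform = identity) {
  sc <- grid_centres(source$grid)
  dc <- grid_centres(dest_grid)
  Wx <- .gauss_w(dc$x, sc$x, bandwidth_m)
  Wy <- .gauss_w(dc$y, sc$y, bandwidth_m)
  L <- transform(source$values)
  num <- Wx %*% L %*% t(Wy)
  den <- outer(rowSums(Wx), rowSums(Wy))
  num / pmax(den, .Machine$double.eps)
}

#' Smoothed logarithmic covariate field
#'
#' Computes, at every destination pixel, the Gaussian-kernel-weighted mean of
#' `log(source + offset)` over the source pixels (log first, smooth second).
#' This is the transformation chain used for the population covariate
#' (offset 0, bandwidth 1.6 km) and the psychiatric-bed covariate (offset 1
#' for the zero-inflated bed counts, bandwidth 0.8 km).
#'
#' @param source a `cov_raster` of non-negative values
#' @param bandwidth_m Gaussian kernel bandwidth (m)
#' @param dest_grid destination `grid_spec` (default: source grid resampled to
#'   `dest_pixel_m`)
#' @param dest_pixel_m destination pixel size when `dest_grid` is NULL
#' @param offset 0 or 1, added before the log; 1 is required when zeros occur
#' @param name output variable name
#' @return `cov_raster` on the destination grid
#' @export
smoothed_log_field <- function(source, bandwidth_m, dest_grid = NULL,
                               dest_pixel_m = 250, offset = 0, name = source$name) {
  stopifnot(bandwidth_m > 0)
  if (any(source$values < 0)) stop("source values must be non-negative")
  if (offset == 0 && any(source$values == 0)) {
    stop("zeros present: use offset = 1")
  }
  if (is.null(dest_grid)) {
    g <- source$grid
    dest_grid <- grid_spec(g$origin, dest_pixel_m,
                           ceiling(g$nx * g$pixel_m / dest_pixel_m),
                           ceiling(g$ny * g$pixel_m / dest_pixel_m))
  }
  v <- .smooth_field(source, bandwidth_m, dest_grid,
                     transform = function(z) log(z + offset))
  cov_raster(dest_grid, v, name)
}

#' Gaussian smoothing of a raster (no transformation)
#'
#' @inheritParams smoothed_log_field
#' @export
smoothed_field <- function(source, bandwidth_m, dest_grid = NULL,
                           dest_pixel_m = source$grid$pixel_m, name = source$name) {
  if (is.null(dest_grid)) {
    g <- source$grid
    dest_grid <- grid_spec(g$origin, dest_pixel_m,
                           ceiling(g$nx * g$pixel_m / dest_pixel_m),
                           ceiling(g$ny * g$pixel_m / dest_pixel_m))
  }
  cov_raster(dest_grid, .smooth_field(source, bandwidth_m, dest_grid), name)
}

#' Gaussian kernel density surface of point masses
#'
#' Density in mass units per square kilometre, evaluated at pixel centres.
#'
#' @param grid destination `grid_spec`
#' @param xy point coordinates (m)
#' @param mass per-point mass
#' @param bandwidth_m kernel bandwidth (m)
#' @export
kernel_density_raster <- function(grid, xy, mass, bandwidth_m, name = "density") {
  xy <- .as_xy(xy)
  dc <- grid_centres(grid)
  v <- matrix(0, grid$nx, grid$ny)
  norm <- 1e6 / (2 * pi * bandwidth_m^2)   # per km^2
  for (k in seq_len(nrow(xy))) {
    gx <- exp(-(dc$x - xy[k, 1])^2 / (2 * bandwidth_m^2))
    gy <- exp(-(dc$y - xy[k, 2])^2 / (2 * bandwidth_m^2))
    gx[abs(dc$x - xy[k, 1]) > 4 * bandwidth_m] <- 0
    gy[abs(dc$y - xy[k, 2]) > 4 * bandwidth_m] <- 0
    v <- v + mass[k] * norm * outer(gx, gy)
  }
  cov_raster(grid, v, name)
}

#' Read an ESRI ASCII grid
#' @param path file path
#' @param name variable name for the resulting raster
#' @return a `cov_raster`
#' @export
read_ascii_grid <- function(path, name = "") {
  hdr <- list()
  con <- file(path, "r"); on.exit(close(con))
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  vals <- scan(con, what = double(), quiet = TRUE)
  nx <- as.integer(hdr$ncols); ny <- as.integer(hdr$nrows)
  m <- matrix(vals, nrow = nx, ncol = ny)       # scanned row-major top row first
  m <- m[, ny:1, drop = FALSE]                  # flip to south-up iy
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cov_raster(grid_spec(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, nx, ny), m, name)
}

#' Write an ESRI ASCII grid
#' @param r a `cov_raster`
#' @param path file path
#' @export
write_ascii_grid <- function(r, path) {
  g <- r$grid
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
               sprintf("xllcorner %.10g", g$origin[1]),
               sprintf("yllcorner %.10g", g$origin[2]),
               sprintf("cellsize %.10g", g$pixel_m),
               "NODATA_value -9999"), con)
  v <- r$values
  v[is.na(v)] <- -9999
  for (iy in g$ny:1) {
    writeLines(paste(format(v[, iy], trim = TRUE, digits = 10), collapse = " "), con)
  }
}

# coerce coordinate input (matrix or data frame) to a numeric 2-column matrix
.as_xy <- function(xy) {
  m <- as.matrix(xy)
  storage.mode(m) <- "double"
  stopifnot(ncol(m) == 2)
  m
}
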