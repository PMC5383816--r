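#' Displaced grid origins for MAUP mitigation
#'
#' Symmetric subdivision of the base pixel: origins displaced by all
#' combinations of multiples of the destination pixel, e.g. 16 origins for a
#' 1 km base pixel subdivided into 250 m destination pixels.
#'
#' @param base_pixel_m counting pixel size (m; default 1000)
#' @param dest_pixel_m destination pixel size (m; default 250)
#' @return data frame with columns `dx`, `dy`
#' @export
displaced_grid_origins <- function(base_pixel_m = 1000, dest_pixel_m = 250) {
  stopifnot(base_pixel_m %% dest_pixel_m == 0)
  off <- seq(0, base_pixel_m - dest_pixel_m, by = dest_pixel_m)
  expand.grid(dx = off, dy = off)
}

#' Box counting on a fixed pixel grid
#'
#' Each point is assigned to exactly one pixel under half-open intervals
#' `[x0 + i s, x0 + (i+1) s)`. If `nx`/`ny` are omitted the grid is sized to
#' cover all points, so the matrix total equals the number of points.
#'
#' @param xy two-column coordinate matrix
#' @param origin grid origin (lower-left corner)
#' @param pixel_size_m pixel side (m)
#' @param nx,ny grid dimensions; points outside a fixed grid are dropped
#' @return integer count matrix `nx` x `ny`
#' @export
box_count <- function(xy, origin, pixel_size_m, nx = NULL, ny = NULL) {
  stopifnot(pixel_size_m > 0)
  xy <- .as_xy(xy)
  ix <- floor((xy[, 1] - origin[1]) / pixel_size_m) + 1
  iy <- floor((xy[, 2] - origin[2]) / pixel_size_m) + 1
  if (is.null(nx)) nx <- max(ix, 1L)
  if (is.null(ny)) ny <- max(iy, 1L)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  cnt <- tabulate(ix[ok] + (iy[ok] - 1) * nx, nbins = nx * ny)
  matrix(as.integer(cnt), nx, ny)
}

#' Ensemble quantile image of case counts under location noise
#'
#' For each of `n_real` Gaussian-noise realizations of the case locations
#' (displacement along the network, sd `sigma_m`), box counts are taken on
#' the displaced base grids (origins from [displaced_grid_origins()]); each
#' destination pixel inherits, per grid, the count of the base pixel that
#' contains it, yielding `n_real * n_grids` values per destination pixel.
#' The image stores the lower empirical `q`-quantile (type 1) per pixel,
#' a conservative estimate of the spatial case density.
#'
#' @param net a `rail_network`
#' @param cases `network_points`
#' @param sigma_m location-noise sd (m; default 1000)
#' @param n_real number of noise realizations (default 1000)
#' @param q lower quantile (default 0.10)
#' @param dest_pixel_m destination pixel (default 250)
#' @param base_pixel_m counting pixel (default 1000)
#' @return object of class `quantile_image`: destination `grid`, `values`
#'   (quantile matrix), `mean_counts`, `ensemble_size`, `case_pix` (dest-pixel
#'   index of every displaced case per realization), `tally`
#' @export
ensemble_quantile_image <- function(net, cases, sigma_m = 1000, n_real = 1000,
                                    q = 0.10, dest_pixel_m = 250,
                                    base_pixel_m = 1000) {
  if (sigma_m <= 0) stop("sigma_m must be positive")
  .check_points(net, cases)
  grid <- network_grid(net, dest_pixel_m, pad_m = 0)
  origins <- displaced_grid_origins(base_pixel_m, dest_pixel_m)
  ng <- nrow(origins)
  npix <- grid$nx * grid$ny
  ctr <- grid_centres(grid)
  cx <- rep(ctr$x, times = grid$ny)
  cy <- rep(ctr$y, each = grid$nx)
  # parent-cell index of each destination pixel under each displaced grid
  margin <- base_pixel_m
  pdim <- list()
  pmap <- matrix(0L, npix, ng)
  for (g in seq_len(ng)) {
    ox <- grid$origin[1] + origins$dx[g] - margin
    oy <- grid$origin[2] + origins$dy[g] - margin
    pnx <- ceiling((max(ctr$x) - ox) / base_pixel_m) + 1
    pny <- ceiling((max(ctr$y) - oy) / base_pixel_m) + 1
    pix <- floor((cx - ox) / base_pixel_m) + 1
    piy <- floor((cy - oy) / base_pixel_m) + 1
    pmap[, g] <- pix + (piy - 1L) * pnx
    pdim[[g]] <- c(ox, oy, pnx, pny)
  }
  tally <- matrix(0, npix, 1)       # tally[pix, v+1] = occurrences of count v
  sum_counts <- numeric(npix)
  case_pix <- matrix(NA_integer_, nrow(cases), n_real)
  for (r in seq_len(n_real)) {
    pts <- gaussian_displace(net, cases, sigma_m)
    xy <- network_point_coords(net, pts)
    dix <- pmin(floor((xy[, 1] - grid$origin[1]) / dest_pixel_m) + 1, grid$nx)
    diy <- pmin(floor((xy[, 2] - grid$origin[2]) / dest_pixel_m) + 1, grid$ny)
    inb <- dix >= 1 & diy >= 1
    case_pix[inb, r] <- dix[inb] + (diy[inb] - 1L) * grid$nx
    for (g in seq_len(ng)) {
      pd <- pdim[[g]]
      cnt <- box_count(xy, pd[1:2], base_pixel_m, pd[3], pd[4])
      v <- as.integer(cnt)[pmap[, g]]
      vmax <- max(v)
      if (vmax + 1 > ncol(tally)) {
        tally <- cbind(tally, matrix(0, npix, vmax + 1 - ncol(tally)))
      }
      inc <- tabulate(seq_len(npix) + npix * v, nbins = npix * (vmax + 1))
      tally[, seq_len(vmax + 1)] <- tally[, seq_len(vmax + 1)] +
        matrix(inc, npix, vmax + 1)
      sum_counts <- sum_counts + v
    }
  }
  m <- n_real * ng
  rank_needed <- max(1, ceiling(q * m))
  cum <- tally
  for (j in seq_len(ncol(cum))[-1]) cum[, j] <- cum[, j] + cum[, j - 1]
  qv <- max.col(cum >= rank_needed, ties.method = "first") - 1L
  structure(list(grid = grid, q = q, n_real = n_real, n_grids = ng,
                 ensemble_size = m,
                 values = matrix(as.numeric(qv), grid$nx, grid$ny),
                 mean_counts = matrix(sum_counts / m, grid$nx, grid$ny),
                 case_pix = case_pix, sigma_m = sigma_m,
                 base_pixel_m = base_pixel_m, tally = tally),
            class = "quantile_image")
}

#' @export
print.quantile_image <- function(x, ...) {
  cat(sprintf("quantile_image: %d x %d pixels of %g m, q = %.2f, %d counts/pixel (%d realizations x %d grids)\n",
              x$grid$nx, x$grid$ny, x$grid$pixel_m, x$q, x$ensemble_size,
              x$n_real, x$n_grids))
  cat(sprintf("  pixels with quantile > 0: %d\n", sum(x$values > 0)))
  invisible(x)
}

# label 4/8-connected components of a logical matrix; 0 = background
.label_components <- function(mask, connectivity = 8) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 0, 1, -1, 1, -1, 0, 1), c(-1, -1, -1, 0, 0, 1, 1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      pi <- (p - 1L) %% nx + 1L; pj <- (p - 1L) %/% nx + 1L
      for (k in seq_len(nrow(nb))) {
        qi <- pi + nb[k, 1]; qj <- pj + nb[k, 2]
        if (qi >= 1 && qi <= nx && qj >= 1 && qj <= ny) {
          qq <- qi + (qj - 1L) * nx
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- cur
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  lab
}

#' Extract hotspots from a quantile image
#'
#' Pixels whose lower-quantile count exceeds `count_threshold` are grouped by
#' 8-connectivity; groups whose border-to-border gap (Chebyshev pixel units,
#' number of empty pixels between nearest member pixels) is at most
#' `merge_dist_px` are merged transitively. Output is sorted by descending
#' approximate case count.
#'
#' @param img a `quantile_image`
#' @param count_threshold inclusion threshold on the quantile value (default
#'   0: a pixel participates only if at least a fraction `1 - q` of the
#'   ensemble places one or more cases in it)
#' @param connectivity 8 (default) or 4
#' @param merge_dist_px merge distance in pixels (default 3)
#' @return list of `hotspot` objects: `pixels` (ix, iy matrix), `cells`,
#'   `approx_cases` (mean over realizations of cases inside the pixel set)
#' @export
extract_hotspots <- function(img, count_threshold = 0, connectivity = 8,
                             merge_dist_px = 3) {
  stopifnot(count_threshold >= 0)
  mask <- img$values > count_threshold
  if (!any(mask)) return(list())
  lab <- .label_components(mask, connectivity)
  k <- max(lab)
  groups <- lapply(seq_len(k), function(i) which(lab == i))
  # transitive merge by union-find on border-to-border Chebyshev gaps
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  coords <- lapply(groups, function(cells) {
    cbind((cells - 1L) %% img$grid$nx + 1L, (cells - 1L) %/% img$grid$nx + 1L)
  })
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- coords[[i]]; b <- coords[[j]]
      cheb <- Inf
      for (r in seq_len(nrow(a))) {
        cheb <- min(cheb, min(pmax(abs(a[r, 1] - b[, 1]),
                                   abs(a[r, 2] - b[, 2]))))
      }
      if (cheb - 1 <= merge_dist_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    sort(unlist(groups[roots == r]))
  })
  hs <- lapply(merged, function(cells) {
    inside <- matrix(img$case_pix %in% cells, nrow(img$case_pix))
    per_real <- colSums(inside)
    structure(list(cells = cells,
                   pixels = cbind(ix = (cells - 1L) %% img$grid$nx + 1L,
                                  iy = (cells - 1L) %/% img$grid$nx + 1L),
                   approx_cases = mean(per_real),
                   case_range = stats::quantile(per_real, c(0.10, 0.90),
                                                type = 1, names = FALSE)),
              class = "hotspot")
  })
  hs[order(-vapply(hs, function(h) h$approx_cases, numeric(1)))]
}

#' Hotspot summary table
#'
#' One row per hotspot: pixel area, approximate case range (10-90% quantiles
#' over noise realizations of the case count inside the hotspot), coordinates
#' of the maximum mean-count pixel, and air-line distance (km) to the nearest
#' psychiatric institution.
#'
#' @param hotspots list from [extract_hotspots()]
#' @param img the `quantile_image` the hotspots came from
#' @param hospitals hospital table (may be NULL; distance reported as NA)
#' @return data frame sorted as given
#' @export
hotspot_summary <- function(hotspots, img, hospitals = NULL) {
  g <- img$grid
  psych <- if (!is.null(hospitals)) hospitals[hospitals$has_psychiatry, , drop = FALSE]
           else NULL
  rows <- lapply(seq_along(hotspots), function(i) {
    h <- hotspots[[i]]
    mc <- img$mean_counts[h$cells]
    top <- h$cells[which.max(mc)]
    cx <- g$origin[1] + (((top - 1L) %% g$nx) + 0.5) * g$pixel_m
    cy <- g$origin[2] + (((top - 1L) %/% g$nx) + 0.5) * g$pixel_m
    dk <- if (!is.null(psych) && nrow(psych)) {
      min(sqrt((psych$x_m - cx)^2 + (psych$y_m - cy)^2)) / 1000
    } else NA_real_
    data.frame(hotspot = i, area_px = length(h$cells),
               cases_lo = h$case_range[1], cases_hi = h$case_range[2],
               approx_cases = h$approx_cases,
               x_max = cx, y_max = cy, psych_dist_km = dk)
  })
  do.call(rbind, rows)
}

#' @export
plot.quantile_image <- function(x, what = c("quantile", "mean"), ...) {
  what <- match.arg(what)
  v <- if (what == "quantile") x$values else x$mean_counts
  ctr <- grid_centres(x$grid)
  graphics::image(ctr$x / 1000, ctr$y / 1000, v, xlab = "x (km)",
                  ylab = "y (km)", useRaster = TRUE, ...)
  invisible(x)
}
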