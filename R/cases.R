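#' Apply the exclusion filters to a raw case table
#'
#' Removes records with any exclusion flag set (`liechtenstein`,
#' `inside_train`, `off_network`), preserving the order of retained records.
#' Records carrying several flags are excluded once but reported in every
#' matching category; the report totals count unique records.
#'
#' @param records data frame with 0/1 (or logical) flag columns
#' @return list: `retained` (data frame), `report` (list with `total`,
#'   per-category counts, `excluded`, `retained`, `multi_flag`)
#' @export
filter_cases <- function(records) {
  flags <- c("liechtenstein", "inside_train", "off_network")
  present <- intersect(flags, names(records))
  fm <- if (length(present)) {
    sapply(records[present], function(z) as.integer(z) > 0)
  } else {
    matrix(FALSE, nrow(records), 0)
  }
  if (nrow(records) == 0) fm <- matrix(FALSE, 0, length(present))
  any_flag <- if (ncol(fm)) rowSums(fm) > 0 else rep(FALSE, nrow(records))
  per_cat <- if (ncol(fm)) colSums(fm) else stats::setNames(integer(0), character(0))
  report <- list(total = nrow(records),
                 per_category = as.list(per_cat),
                 excluded = sum(any_flag),
                 retained = sum(!any_flag),
                 multi_flag = if (ncol(fm)) sum(rowSums(fm) > 1) else 0L)
  list(retained = records[!any_flag, , drop = FALSE], report = report)
}

#' Snap planar coordinates onto the network
#'
#' Finds for each point the nearest location on any edge polyline
#' (perpendicular foot or segment endpoint). Points farther than `max_dist_m`
#' from every edge receive an off-network verdict.
#'
#' @param net a `rail_network`
#' @param xy two-column coordinate matrix
#' @param max_dist_m snapping tolerance (m; default 100, small relative to
#'   the 1 km location noise)
#' @return list: `points` (`network_points`; NA rows where off-network),
#'   `dist_m`, `off_network` (logical)
#' @export
snap_to_network <- function(net, xy, max_dist_m = 100) {
  stopifnot(max_dist_m > 0)
  if (nrow(net$edges) == 0) stop("empty network")
  xy <- .as_xy(xy)
  n <- nrow(xy)
  best_d2 <- rep(Inf, n)
  best_e <- rep(NA_integer_, n)
  best_o <- rep(NA_real_, n)
  for (e in seq_len(nrow(net$edges))) {
    g <- net$geoms[[e]]; cum <- net$cum[[e]]
    for (j in seq_len(nrow(g) - 1)) {
      p0 <- g[j, ]; p1 <- g[j + 1, ]
      v <- p1 - p0
      vv <- sum(v^2)
      if (vv <= 0) next
      t <- ((xy[, 1] - p0[1]) * v[1] + (xy[, 2] - p0[2]) * v[2]) / vv
      t <- pmin(pmax(t, 0), 1)
      dx <- xy[, 1] - (p0[1] + t * v[1])
      dy <- xy[, 2] - (p0[2] + t * v[2])
      d2 <- dx^2 + dy^2
      upd <- d2 < best_d2
      if (any(upd)) {
        best_d2[upd] <- d2[upd]
        best_e[upd] <- e
        best_o[upd] <- cum[j] + t[upd] * (cum[j + 1] - cum[j])
      }
    }
  }
  d <- sqrt(best_d2)
  off <- d > max_dist_m
  best_e[off] <- NA_integer_
  best_o[off] <- NA_real_
  list(points = network_points(best_e, best_o), dist_m = d, off_network = off)
}
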