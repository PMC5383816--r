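#' Histogram of pairwise shortest-path distances
#'
#' Counts all unordered pairs of a pattern by network distance. Pairs beyond
#' the last bin edge or in different connected components are excluded and
#' reported.
#'
#' @param net a `rail_network`
#' @param pts `network_points`
#' @param bin_edges increasing numeric vector of bin edges (m)
#' @return list: `counts` (per bin), `bin_edges`, `n_pairs`, `n_excluded`
#' @export
pairwise_distance_histogram <- function(net, pts, bin_edges) {
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  n <- nrow(pts)
  if (n < 2) {
    return(list(counts = integer(length(bin_edges) - 1), bin_edges = bin_edges,
                n_pairs = 0L, n_excluded = 0L))
  }
  M <- network_distance_matrix(net, pts)
  d <- M[upper.tri(M)]
  .bin_distances(d, bin_edges)
}

.bin_distances <- function(d, bin_edges) {
  ok <- is.finite(d) & d >= bin_edges[1] & d < bin_edges[length(bin_edges)]
  idx <- findInterval(d[ok], bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1)
  list(counts = counts, bin_edges = bin_edges,
       n_pairs = length(d), n_excluded = sum(!ok))
}

.pcf_from_counts <- function(obs, sims, bin_edges, envelope) {
  mean_sim <- colMeans(sims)
  ok <- mean_sim > 0
  g <- ifelse(ok, obs / mean_sim, NA_real_)
  gs <- sweep(sims, 2, ifelse(ok, mean_sim, NA_real_), "/")
  a <- (1 - envelope) / 2
  lo <- apply(gs, 2, stats::quantile, probs = a, na.rm = TRUE, names = FALSE)
  hi <- apply(gs, 2, stats::quantile, probs = 1 - a, na.rm = TRUE, names = FALSE)
  lo[!ok] <- NA_real_; hi[!ok] <- NA_real_
  structure(list(
    table = data.frame(bin_lo = bin_edges[-length(bin_edges)],
                       bin_hi = bin_edges[-1],
                       mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                       g = g, lo = lo, hi = hi),
    n_sim = nrow(sims), envelope = envelope, sim_g = gs),
    class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  out_band <- with(x$table, sum(g < lo | g > hi, na.rm = TRUE))
  cat(sprintf("pair_correlation: %d bins, %d simulations, %.0f%% envelope; %d bins outside band\n",
              nrow(x$table), x$n_sim, 100 * x$envelope, out_band))
  invisible(x)
}

#' @export
plot.pair_correlation <- function(x, ...) {
  t <- x$table
  graphics::plot(t$mid / 1000, t$g, type = "l", xlab = "distance (km)",
                 ylab = "g(r)", ylim = range(c(t$g, t$lo, t$hi, 1), na.rm = TRUE), ...)
  graphics::lines(t$mid / 1000, t$lo, lty = 3, col = "grey40")
  graphics::lines(t$mid / 1000, t$hi, lty = 3, col = "grey40")
  graphics::abline(h = 1, lty = 2, col = "grey60")
  invisible(x)
}

#' Network pair correlation function with simulation envelope
#'
#' The pair correlation g per bin is the data pair-distance histogram divided
#' by the bin-wise mean histogram of `n_sim` null simulations; the pointwise
#' envelope comes from the empirical quantiles of the simulated g curves.
#' With the CSR generator this normalizes with respect to complete spatial
#' randomness on the network.
#'
#' @param net a `rail_network`
#' @param pattern `network_points` (the data)
#' @param null_generator function(n) returning a null `network_points`
#'   pattern of size n (e.g. [csr_generator()])
#' @param n_sim number of simulations (default 199)
#' @param bin_edges bin edges in metres (default 2 km bins to 150 km)
#' @param envelope pointwise envelope level (default 0.95)
#' @return a `pair_correlation` object
#' @export
pair_correlation <- function(net, pattern, null_generator, n_sim = 199,
                             bin_edges = seq(0, 150000, by = 2000),
                             envelope = 0.95) {
  obs <- pairwise_distance_histogram(net, pattern, bin_edges)
  n <- nrow(pattern)
  sims <- t(vapply(seq_len(n_sim), function(i) {
    pairwise_distance_histogram(net, null_generator(n), bin_edges)$counts
  }, numeric(length(bin_edges) - 1)))
  out <- .pcf_from_counts(obs$counts, sims, bin_edges, envelope)
  out$n_excluded <- obs$n_excluded
  out
}

#' CSR (binomial) null generator on a network
#'
#' Complete spatial randomness conditioned on the observed point count:
#' uniform independent points with respect to arc length.
#'
#' @param net a `rail_network`
#' @return function(n) returning `network_points`
#' @export
csr_generator <- function(net) function(n) random_network_points(net, n)

#' Purely temporal pair correlation function
#'
#' Same estimator in one dimension: histogram of all pairwise day differences
#' normalized by `n_sim` simulations of uniform dates over the study window
#' (homogeneous Poisson in time conditioned on n).
#'
#' @param dates `Date` vector (or numeric days)
#' @param study_window length-2 `Date`/numeric window
#' @param n_sim number of simulations (default 199)
#' @param bin_edges bin edges in days (default 90-day bins over the window)
#' @param envelope pointwise envelope level
#' @return a `pair_correlation` object (bins in days)
#' @export
temporal_pair_correlation <- function(dates, study_window, n_sim = 199,
                                      bin_edges = NULL, envelope = 0.95) {
  t0 <- as.numeric(study_window[1]); t1 <- as.numeric(study_window[2])
  if (t1 <= t0) stop("study window has zero length")
  tt <- as.numeric(dates)
  if (any(tt < t0 | tt > t1)) stop("dates outside study window")
  if (is.null(bin_edges)) bin_edges <- seq(0, t1 - t0, by = 90)
  n <- length(tt)
  pair_d <- function(v) abs(outer(v, v, "-"))[upper.tri(diag(length(v)))]
  obs <- .bin_distances(pair_d(tt), bin_edges)
  sims <- t(vapply(seq_len(n_sim), function(i) {
    .bin_distances(pair_d(stats::runif(n, t0, t1)), bin_edges)$counts
  }, numeric(length(bin_edges) - 1)))
  .pcf_from_counts(obs$counts, sims, bin_edges, envelope)
}
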