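# Shared fixtures and independent oracles, built in code.

# single straight edge of given length
single_edge_net <- function(length_m = 10000, multitrack = FALSE) {
  rail_network(rbind(c(0, 0), c(length_m, 0)),
               data.frame(from = 1, to = 2, multitrack = multitrack))
}

# 3-4-5 km triangle
triangle_net <- function() {
  rail_network(rbind(c(0, 0), c(3000, 0), c(3000, 4000)),
               data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                          multitrack = c(TRUE, FALSE, FALSE)))
}

# Y-shaped network: three edges meeting at one interior node
y_net <- function() {
  rail_network(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(2000, 0)),
               data.frame(from = c(1, 2, 2), to = c(2, 3, 4)))
}

# small synthetic world, memoised per test session
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 421, extent_m = c(12000, 8000),
                          cell_m = 2000, n_cases = 300, n_hospitals = 12)
      cache <<- synth_world(cfg, n_pca_sample = 2000)
    }
    cache
  }
})

# Independent tessellation oracle: discretize every edge into `step`-metre
# pieces, assign each piece to its nearest point(s) by shortest-path distance
# (computed pointwise, not via the tessellation code path); exact ties share
# the piece evenly.
oracle_tessellation <- function(net, pts, step = 1, tol = 1e-6) {
  segs <- railpp:::.fine_segments(net, step)
  mids <- network_points(segs$edge, (segs$o0 + segs$o1) / 2)
  D <- sapply(seq_len(nrow(pts)), function(i) {
    shortest_path_distance(net, mids, pts[i, ])
  })
  best <- apply(D, 1, min)
  share <- (D <= best + tol) / rowSums(D <= best + tol)
  as.numeric(colSums(share * segs$len))
}

# Brute-force shortest path: build a fine chain graph (one node per `step`
# metres along every edge, plus the two query points) and run Dijkstra on it.
# Independent of the package's distance formula.
oracle_distance <- function(net, a, b, step = 1) {
  nv <- nrow(net$vertices)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  nid <- nv
  locate <- list()
  for (e in seq_len(nrow(net$edges))) {
    L <- net$edges$length_m[e]
    brk <- sort(unique(c(seq(0, L, by = step), L,
                         if (a$edge == e) a$offset_m,
                         if (b$edge == e) b$offset_m)))
    ids <- c(net$edges$from[e], nid + seq_len(length(brk) - 2), net$edges$to[e])
    nid <- nid + length(brk) - 2
    from <- c(from, ids[-length(ids)]); to <- c(to, ids[-1])
    wt <- c(wt, diff(brk))
    locate[[e]] <- list(brk = brk, ids = ids)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  node_of <- function(p) {
    l <- locate[[p$edge]]
    l$ids[which.min(abs(l$brk - p$offset_m))]
  }
  igraph::distances(g, v = node_of(a), to = node_of(b), weights = wt)[1, 1]
}
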