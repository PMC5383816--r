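#' Rail network objects
#'
#' A `rail_network` is a planar linear network: vertices in a metric CRS
#' (metres) joined by polyline edges, each carrying its arc length and a
#' single/multitrack flag. All event locations ("network points") are linear
#' references `(edge, offset_m)` with `0 <= offset_m <= length_m`.
#'
#' @param vertices two-column numeric matrix of planar vertex coordinates (m).
#' @param edges data frame with integer columns `from`, `to` (vertex indices)
#'   and logical `multitrack`.
#' @param geoms optional list (one entry per edge) of two-column coordinate
#'   matrices giving the edge polyline; first/last rows must equal the `from`
#'   and `to` vertex coordinates. Defaults to straight segments.
#'
#' @return object of class `rail_network` with components `vertices`, `edges`
#'   (including computed `length_m`), `geoms`, a cached vertex-to-vertex
#'   shortest-path distance matrix and component labels.
#' @export
rail_network <- function(vertices, edges, geoms = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 2, all(is.finite(vertices)))
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$multitrack)) edges$multitrack <- FALSE
  ne <- nrow(edges)
  if (is.null(geoms)) {
    geoms <- lapply(seq_len(ne), function(i) {
      rbind(vertices[edges$from[i], ], vertices[edges$to[i], ])
    })
  }
  stopifnot(length(geoms) == ne)
  cum <- vector("list", ne)
  len <- numeric(ne)
  for (i in seq_len(ne)) {
    g <- as.matrix(geoms[[i]])
    seg <- sqrt(rowSums((g[-1, , drop = FALSE] - g[-nrow(g), , drop = FALSE])^2))
    cum[[i]] <- c(0, cumsum(seg))
    len[i] <- sum(seg)
  }
  if (any(len <= 0)) stop("every edge must have positive length")
  edges$length_m <- len
  g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to), directed = FALSE)
  if (igraph::vcount(g) < nrow(vertices)) {
    g <- igraph::add_vertices(g, nrow(vertices) - igraph::vcount(g))
  }
  D <- igraph::distances(g, weights = edges$length_m)
  comp <- igraph::components(g)$membership
  # incidence list: for each vertex the edges touching it
  inc <- vector("list", nrow(vertices))
  for (i in seq_len(ne)) {
    inc[[edges$from[i]]] <- c(inc[[edges$from[i]]], i)
    inc[[edges$to[i]]] <- c(inc[[edges$to[i]]], i)
  }
  structure(list(vertices = vertices, edges = edges, geoms = geoms, cum = cum,
                 D = D, comp = comp, incident = inc),
            class = "rail_network")
}

#' @export
print.rail_network <- function(x, ...) {
  cat(sprintf("rail_network: %d vertices, %d edges, total length %.1f km (%.0f%% multitrack)\n",
              nrow(x$vertices), nrow(x$edges), total_network_length(x) / 1000,
              100 * sum(x$edges$length_m[x$edges$multitrack]) / total_network_length(x)))
  invisible(x)
}

#' Total arc length of a network (metres)
#' @param net a `rail_network`
#' @export
total_network_length <- function(net) sum(net$edges$length_m)

#' Linear-referenced points on a network
#'
#' @param edge integer edge indices
#' @param offset_m numeric offsets along each edge, in `[0, length_m]`
#' @return data frame of class `network_points`
#' @export
network_points <- function(edge, offset_m) {
  structure(data.frame(edge = as.integer(edge), offset_m = as.numeric(offset_m)),
            class = c("network_points", "data.frame"))
}

.check_points <- function(net, pts) {
  if (nrow(pts) == 0) return(invisible(TRUE))
  if (any(pts$edge < 1 | pts$edge > nrow(net$edges))) stop("invalid edge index")
  len <- net$edges$length_m[pts$edge]
  if (any(pts$offset_m < -1e-9 | pts$offset_m > len + 1e-9)) {
    stop("offset outside [0, edge length]")
  }
  invisible(TRUE)
}

#' Planar coordinates of network points
#' @param net a `rail_network`
#' @param pts a `network_points` data frame
#' @return two-column matrix of coordinates (m)
#' @export
network_point_coords <- function(net, pts) {
  .check_points(net, pts)
  out <- matrix(NA_real_, nrow(pts), 2)
  for (k in seq_len(nrow(pts))) {
    e <- pts$edge[k]
    o <- min(max(pts$offset_m[k], 0), net$edges$length_m[e])
    cum <- net$cum[[e]]
    g <- net$geoms[[e]]
    j <- findInterval(o, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(cum) - 1)
    t <- (o - cum[j]) / max(cum[j + 1] - cum[j], .Machine$double.eps)
    out[k, ] <- g[j, ] + t * (g[j + 1, ] - g[j, ])
  }
  out
}

#' Shortest-path distance between two network points
#'
#' Distances are measured along the network (arc length). Points in different
#' connected components are at distance `Inf`.
#'
#' @param net a `rail_network`
#' @param a,b `network_points` of equal row count (recycled if one has 1 row)
#' @return numeric vector of distances (m)
#' @export
shortest_path_distance <- function(net, a, b) {
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), ]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), ]
  stopifnot(nrow(a) == nrow(b))
  .check_points(net, a); .check_points(net, b)
  ea <- a$edge; eb <- b$edge
  la <- net$edges$length_m[ea]; lb <- net$edges$length_m[eb]
  ua <- net$edges$from[ea]; va <- net$edges$to[ea]
  ub <- net$edges$from[eb]; vb <- net$edges$to[eb]
  dau <- a$offset_m; dav <- la - a$offset_m
  dbu <- b$offset_m; dbv <- lb - b$offset_m
  D <- net$D
  d <- pmin(dau + D[cbind(ua, ub)] + dbu,
            dau + D[cbind(ua, vb)] + dbv,
            dav + D[cbind(va, ub)] + dbu,
            dav + D[cbind(va, vb)] + dbv)
  same <- ea == eb
  d[same] <- pmin(d[same], abs(a$offset_m[same] - b$offset_m[same]))
  d
}

#' All pairwise shortest-path distances among a point pattern
#'
#' @param net a `rail_network`
#' @param pts `network_points`
#' @return symmetric n x n matrix; `Inf` across components
#' @export
network_distance_matrix <- function(net, pts) {
  .check_points(net, pts)
  n <- nrow(pts)
  e <- pts$edge
  u <- net$edges$from[e]; v <- net$edges$to[e]
  da <- pts$offset_m
  db <- net$edges$length_m[e] - pts$offset_m
  D <- net$D
  M <- pmin(outer(da, da, "+") + D[u, u, drop = FALSE],
            outer(da, db, "+") + D[u, v, drop = FALSE],
            outer(db, da, "+") + D[v, u, drop = FALSE],
            outer(db, db, "+") + D[v, v, drop = FALSE])
  same <- outer(e, e, "==")
  direct <- abs(outer(da, da, "-"))
  M[same] <- pmin(M[same], direct[same])
  diag(M) <- 0
  M
}

#' Uniform random points on a network
#'
#' Edge chosen with probability proportional to its length; offset uniform.
#' Uses the R session RNG (`set.seed()` for reproducibility).
#'
#' @param net a `rail_network`
#' @param n number of points
#' @return `network_points`
#' @export
random_network_points <- function(net, n) {
  if (n == 0) return(network_points(integer(0), numeric(0)))
  if (nrow(net$edges) == 0) stop("empty network")
  e <- sample.int(nrow(net$edges), n, replace = TRUE, prob = net$edges$length_m)
  network_points(e, stats::runif(n) * net$edges$length_m[e])
}

#' Gaussian displacement along a network
#'
#' Each point travels a signed distance drawn from Normal(0, `sigma_m`) along
#' the network. At an interior vertex the walk continues onto one of the other
#' incident edges chosen uniformly at random; at a dead end it reflects. The
#' travelled arc length always equals the absolute drawn displacement, so the
#' marginal displacement magnitude is half-normal with scale `sigma_m`.
#'
#' @param net a `rail_network`
#' @param pts `network_points` to displace
#' @param sigma_m displacement standard deviation (m); default 1000 is the
#'   location-uncertainty scale of the case records
#' @return displaced `network_points`
#' @export
gaussian_displace <- function(net, pts, sigma_m = 1000) {
  if (sigma_m <= 0) stop("sigma_m must be positive")
  .check_points(net, pts)
  n <- nrow(pts)
  d <- stats::rnorm(n, 0, sigma_m)
  out_e <- integer(n); out_o <- numeric(n)
  lens <- net$edges$length_m
  from <- net$edges$from; to <- net$edges$to
  for (k in seq_len(n)) {
    e <- pts$edge[k]; o <- pts$offset_m[k]
    rem <- abs(d[k])
    dir <- if (d[k] >= 0) 1L else -1L   # +1 towards `to`, -1 towards `from`
    repeat {
      ahead <- if (dir == 1L) lens[e] - o else o
      if (rem <= ahead) {
        o <- o + dir * rem
        break
      }
      rem <- rem - ahead
      node <- if (dir == 1L) to[e] else from[e]
      inc <- net$incident[[node]]
      nxt <- inc[inc != e]
      if (length(nxt) == 0) {       # dead end: reflect back along same edge
        nxt <- e
      } else if (length(nxt) > 1) {
        nxt <- nxt[sample.int(length(nxt), 1)]
      }
      e <- nxt
      if (from[e] == node) { o <- 0; dir <- 1L } else { o <- lens[e]; dir <- -1L }
    }
    out_e[k] <- e; out_o[k] <- min(max(o, 0), lens[e])
  }
  network_points(out_e, out_o)
}

# Best point-offer per vertex: for vertex w, the smallest along-network
# distance from w to any point entering via one of w's incident edges.
# All points tying (within tolerance) for the minimum are kept, so that
# critical-node overlaps can be split downstream.
.vertex_offers <- function(net, pts, tol = 1e-9) {
  nv <- nrow(net$vertices)
  e <- pts$edge
  cand_node <- c(net$edges$from[e], net$edges$to[e])
  cand_dist <- c(pts$offset_m, net$edges$length_m[e] - pts$offset_m)
  cand_pt <- rep(seq_len(nrow(pts)), 2)
  offer <- rep(Inf, nv)
  best <- tapply(cand_dist, cand_node, min)
  offer[as.integer(names(best))] <- best
  offer_set <- vector("list", nv)
  keep <- cand_dist <= offer[cand_node] + tol * (1 + offer[cand_node])
  by_node <- split(cand_pt[keep], cand_node[keep])
  for (nm in names(by_node)) {
    offer_set[[as.integer(nm)]] <- unique(by_node[[nm]])
  }
  list(dist = offer, set = offer_set)
}

#' Network Voronoi tessellation weights
#'
#' Partitions the network's total arc length among a point set by nearest
#' shortest-path distance: every location on the network contributes its
#' length to its nearest point. Where two or more candidates are exactly
#' equidistant over a segment (critical-node overlaps, co-located points) the
#' segment's length is divided among them proportionally to the inverse
#' shortest-path distance, which at an exact tie is an even split.
#'
#' @param net a `rail_network`
#' @param pts `network_points`; at least one
#' @return numeric vector of weights (m), one per point; sums to the total
#'   network length when every component contains a point
#' @export
network_tessellation <- function(net, pts) {
  if (nrow(pts) == 0) stop("tessellation needs at least one point")
  .check_points(net, pts)
  n <- nrow(pts)
  off <- .vertex_offers(net, pts)
  nv <- nrow(net$vertices)
  # nearest point distance from each vertex, routing through any vertex w
  M <- net$D + off$dist                  # M[w, v] = offer[w] + D[w, v]
  near_d <- rep(Inf, nv); near_set <- vector("list", nv)
  tol <- 1e-9
  for (v in seq_len(nv)) {
    col <- M[, v]
    m <- min(col)
    near_d[v] <- m
    if (is.finite(m)) {
      ws <- which(col <= m + tol * (1 + m))
      near_set[[v]] <- unique(unlist(off$set[ws]))
    }
  }
  w <- numeric(n)
  by_edge <- split(seq_len(n), factor(pts$edge, levels = seq_len(nrow(net$edges))))
  add <- function(ids, d, len) {
    # split `len` among tied generators proportional to inverse distance
    # (an even split at exact ties)
    if (len <= 0 || length(ids) == 0) return()
    if (length(ids) == 1) { w[ids] <<- w[ids] + len; return() }
    inv <- rep_len(1 / pmax(d, 1e-12), length(ids))
    w[ids] <<- w[ids] + len * inv / sum(inv)
  }
  for (e in seq_len(nrow(net$edges))) {
    L <- net$edges$length_m[e]
    A <- net$edges$from[e]; B <- net$edges$to[e]
    dA <- near_d[A]; dB <- near_d[B]
    on_ids <- by_edge[[e]]
    if (length(on_ids) == 0) {
      if (!is.finite(dA) && !is.finite(dB)) next   # unreachable component
      if (!is.finite(dA)) { add(near_set[[B]], dB, L); next }
      if (!is.finite(dB)) { add(near_set[[A]], dA, L); next }
      xs <- min(max((L + dB - dA) / 2, 0), L)
      add(near_set[[A]], dA, xs)
      add(near_set[[B]], dB, L - xs)
      next
    }
    o <- pts$offset_m[on_ids]
    ord <- order(o)
    on_ids <- on_ids[ord]; o <- o[ord]
    # group coincident offsets
    grp <- cumsum(c(TRUE, diff(o) > 1e-9))
    gs <- split(on_ids, grp)
    go <- tapply(o, grp, function(z) z[1])
    k <- length(gs)
    # left boundary: generator set reachable via A vs first on-edge group
    b <- if (is.finite(dA)) min(max((go[1] - dA) / 2, 0), go[1]) else 0
    add(near_set[[A]], dA, b)
    bounds_prev <- b
    for (i in seq_len(k)) {
      right <- if (i < k) (go[i] + go[i + 1]) / 2
               else if (is.finite(dB)) min(max((go[k] + L + dB) / 2, go[k]), L)
               else L
      add(gs[[i]], 0, right - bounds_prev)
      bounds_prev <- right
    }
    add(near_set[[B]], dB, L - bounds_prev)
  }
  w
}

#' Decompose a network into grid-pixel subsegments
#'
#' Clips every edge polyline against a regular pixel grid, returning for each
#' resulting subsegment its edge, offset interval, length and pixel index.
#' Used for network-length-per-pixel computations, the multitrack raster and
#' simulation of fitted intensity images.
#'
#' @param net a `rail_network`
#' @param grid a grid spec from [grid_spec()]
#' @return data frame: `edge`, `o0`, `o1`, `len`, `ix`, `iy`, `cell`
#' @export
network_pixel_segments <- function(net, grid) {
  res <- vector("list", nrow(net$edges))
  px <- grid$pixel_m; x0 <- grid$origin[1]; y0 <- grid$origin[2]
  for (e in seq_len(nrow(net$edges))) {
    g <- net$geoms[[e]]; cum <- net$cum[[e]]
    parts <- list()
    for (j in seq_len(nrow(g) - 1)) {
      p0 <- g[j, ]; p1 <- g[j + 1, ]
      seglen <- cum[j + 1] - cum[j]
      if (seglen <= 0) next
      ts <- c(0, 1)
      for (ax in 1:2) {
        a0 <- p0[ax]; a1 <- p1[ax]; orig <- grid$origin[ax]
        if (abs(a1 - a0) > 1e-12) {
          i1 <- ceiling((min(a0, a1) - orig) / px)
          i2 <- floor((max(a0, a1) - orig) / px)
          if (i2 >= i1) {
            lines_at <- orig + (i1:i2) * px
            ts <- c(ts, (lines_at - a0) / (a1 - a0))
          }
        }
      }
      ts <- sort(unique(pmin(pmax(ts, 0), 1)))
      mids <- (ts[-1] + ts[-length(ts)]) / 2
      lens <- (ts[-1] - ts[-length(ts)]) * seglen
      keep <- lens > 1e-9
      if (!any(keep)) next
      mx <- p0[1] + mids[keep] * (p1[1] - p0[1])
      my <- p0[2] + mids[keep] * (p1[2] - p0[2])
      parts[[length(parts) + 1]] <- data.frame(
        o0 = cum[j] + ts[-length(ts)][keep] * seglen,
        o1 = cum[j] + ts[-1][keep] * seglen,
        len = lens[keep],
        # outermost grid boundary closed from above
        ix = pmin(pmax(floor((mx - x0) / px) + 1L, 1L), grid$nx),
        iy = pmin(pmax(floor((my - y0) / px) + 1L, 1L), grid$ny))
    }
    if (length(parts)) {
      dd <- do.call(rbind, parts)
      dd$edge <- e
      res[[e]] <- dd
    }
  }
  out <- do.call(rbind, res)
  out$cell <- out$ix + (out$iy - 1L) * grid$nx
  rownames(out) <- NULL
  out[, c("edge", "o0", "o1", "len", "ix", "iy", "cell")]
}

#' Read a rail network from GeoJSON
#'
#' Expects a FeatureCollection of LineString features in a planar metric CRS,
#' with an optional boolean property `multitrack`. Shared endpoints (within
#' `tol_m`) are merged into vertices.
#'
#' @param path file path
#' @param tol_m endpoint snapping tolerance (m)
#' @return a `rail_network`
#' @export
read_network_geojson <- function(path, tol_m = 0.01) {
  js <- jsonlite::read_json(path)
  feats <- js$features
  geoms <- list(); mt <- logical(0)
  for (f in feats) {
    if (!identical(f$geometry$type, "LineString")) next
    co <- do.call(rbind, lapply(f$geometry$coordinates, function(p) c(p[[1]], p[[2]])))
    geoms[[length(geoms) + 1]] <- co
    mt <- c(mt, isTRUE(f$properties$multitrack))
  }
  ends <- do.call(rbind, lapply(geoms, function(g) rbind(g[1, ], g[nrow(g), ])))
  key <- paste(round(ends[, 1] / tol_m), round(ends[, 2] / tol_m))
  idx <- match(key, unique(key))
  verts <- ends[!duplicated(key), , drop = FALSE]
  from <- idx[seq(1, length(idx), by = 2)]
  to <- idx[seq(2, length(idx), by = 2)]
  rail_network(verts, data.frame(from = from, to = to, multitrack = mt), geoms)
}

#' Write a rail network to GeoJSON
#' @param net a `rail_network`
#' @param path file path
#' @export
write_network_geojson <- function(net, path) {
  feats <- lapply(seq_len(nrow(net$edges)), function(i) {
    g <- net$geoms[[i]]
    list(type = "Feature",
         properties = list(length_m = net$edges$length_m[i],
                           multitrack = isTRUE(net$edges$multitrack[i])),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(j) c(g[j, 1], g[j, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}
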