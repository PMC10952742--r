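# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use brute force (dense resampling, exhaustive
# pairs, library BFS) and never call the code paths they check.

# Small, fast generator configuration for unit tests.
small_config <- function(seed = 1L, ...) {
  generator_config(roi_extent = c(150, 150, 60),
                   segment_length_range = c(30, 50),
                   branch_prob = 0.5, seed = seed, ...)
}

cells_xyz <- function(cells) {
  as.matrix(cells[, c("x_um", "y_um", "z_um")])
}

# Dense-resampling oracle for point-to-centerline distance: walk every
# polyline piece at `step` resolution, keep sample points whose
# interpolated diameter is below the cap, report the minimum distance.
oracle_vessel_distance <- function(cells, network, d_max = 10,
                                   step = 0.1, two_d = FALSE) {
  pts <- network$points
  samples <- list()
  for (sid in unique(pts$segment_id)) {
    sp <- pts[pts$segment_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(sp) - 1L)) {
      a <- c(sp$x[k], sp$y[k], sp$z[k]); b <- c(sp$x[k + 1L], sp$y[k + 1L],
                                                sp$z[k + 1L])
      len <- sqrt(sum((b - a)^2))
      ts <- seq(0, 1, by = min(1, step / max(len, 1e-9)))
      dm <- sp$diameter[k] + (sp$diameter[k + 1L] - sp$diameter[k]) * ts
      keep <- dm < d_max
      if (!any(keep)) next
      m <- cbind(a[1] + (b[1] - a[1]) * ts, a[2] + (b[2] - a[2]) * ts,
                 a[3] + (b[3] - a[3]) * ts)[keep, , drop = FALSE]
      samples[[length(samples) + 1L]] <- m
    }
  }
  if (length(samples) == 0L) return(rep(NA_real_, nrow(cells)))
  S <- do.call(rbind, samples)
  cc <- cells_xyz(cells)
  if (two_d) { S[, 3] <- 0; cc[, 3] <- 0 }
  cc[is.na(cc)] <- 0
  vapply(seq_len(nrow(cc)), function(i) {
    min(sqrt(colSums((t(S) - cc[i, ])^2)))
  }, numeric(1))
}

# Exhaustive all-pairs PEM oracle over eligible pericytes.
oracle_pem_labels <- function(mic, peri, r = 10, d_max = 10,
                              strict = TRUE) {
  elig <- peri[!is.na(peri$host_diameter) & peri$host_diameter < d_max, ,
               drop = FALSE]
  if (nrow(elig) == 0L || nrow(mic) == 0L) {
    return(rep(FALSE, nrow(mic)))
  }
  mc <- cells_xyz(mic); pc <- cells_xyz(elig)
  mc[is.na(mc)] <- 0; pc[is.na(pc)] <- 0
  vapply(seq_len(nrow(mc)), function(i) {
    d <- sqrt(colSums((t(pc) - mc[i, ])^2))
    if (strict) any(d < r) else any(d <= r)
  }, logical(1))
}

# Branch-order oracle: BFS depth of each segment in the segment-adjacency
# (line) graph, computed by igraph. In a tree this is the number of
# junctions crossed from the root segment.
oracle_branch_orders <- function(network, root_segment) {
  seg <- network$segments
  n <- nrow(seg)
  edges <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (length(intersect(c(seg$from_node[i], seg$to_node[i]),
                           c(seg$from_node[j], seg$to_node[j]))) > 0L) {
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  ri <- match(root_segment, seg$segment_id)
  as.integer(igraph::distances(g, v = ri)[1, ])
}

# Random tree topology with straight 3-point polylines; geometry is
# arbitrary (orders depend on topology alone).
random_tree_network <- function(n_segments, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- data.frame(node_id = 1L, x = 0, y = 0, z = 0)
  segs <- list(); pts <- list()
  for (s in seq_len(n_segments)) {
    from <- sample(nodes$node_id, 1L)
    p0 <- unlist(nodes[nodes$node_id == from, c("x", "y", "z")])
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    p1 <- p0 + dirv * stats::runif(1, 20, 40)
    nid <- nrow(nodes) + 1L
    nodes <- rbind(nodes, data.frame(node_id = nid, x = p1[1], y = p1[2],
                                     z = p1[3]))
    segs[[s]] <- data.frame(segment_id = s, from_node = from, to_node = nid,
                            branch_order = NA_integer_,
                            vessel_class = "capillary")
    mid <- (p0 + p1) / 2
    pts[[s]] <- data.frame(segment_id = s,
                           x = c(p0[1], mid[1], p1[1]),
                           y = c(p0[2], mid[2], p1[2]),
                           z = c(p0[3], mid[3], p1[3]),
                           diameter = stats::runif(3, 3, 6))
  }
  vessel_network(nodes, do.call(rbind, segs), do.call(rbind, pts),
                 validate = FALSE)
}

# Straight horizontal test capillary along x at a given y/z with constant
# (or supplied) diameter profile.
straight_capillary <- function(length_um = 100, diameter = 4,
                               y = 50, z = 0, n_points = 51L,
                               vessel_class = "capillary") {
  x <- seq(0, length_um, length.out = n_points)
  d <- rep(diameter, length.out = n_points)
  nodes <- data.frame(node_id = c(1L, 2L),
                      x = c(0, length_um), y = y, z = z)
  segs <- data.frame(segment_id = 1L, from_node = 1L, to_node = 2L,
                     branch_order = 1L, vessel_class = vessel_class)
  pts <- data.frame(segment_id = 1L, x = x, y = y, z = z, diameter = d)
  vessel_network(nodes, segs, pts, validate = FALSE)
}

# Minimal hand-built cell rows for geometric cases.
test_cell <- function(id, type, x, y, z = 0) {
  df <- data.frame(cell_id = as.integer(id), cell_type = type,
                   x_um = x, y_um = y, z_um = z,
                   soma_x = x, soma_y = y, soma_z = z,
                   day = 0L, has_nucleus = TRUE,
                   truth_class = NA_character_, partner_id = NA_integer_,
                   on_segment = NA_integer_, arclength = NA_real_,
                   host_diameter = NA_real_)
  df
}

# Rigid motion: rotation about z by `theta` plus translation, applied to
# a cell table and a network alike.
rotate_cells <- function(cells, theta, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- as.matrix(cells[, c("x_um", "y_um")]) %*% R
  cells$x_um <- xy[, 1] + shift[1]; cells$y_um <- xy[, 2] + shift[2]
  cells$z_um <- cells$z_um + shift[3]
  cells$soma_x <- cells$x_um; cells$soma_y <- cells$y_um
  cells$soma_z <- cells$z_um
  cells
}

rotate_network <- function(network, theta, shift = c(0, 0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  for (part in c("nodes", "points")) {
    xy <- as.matrix(network[[part]][, c("x", "y")]) %*% R
    network[[part]]$x <- xy[, 1] + shift[1]
    network[[part]]$y <- xy[, 2] + shift[2]
    network[[part]]$z <- network[[part]]$z + shift[3]
  }
  network
}
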