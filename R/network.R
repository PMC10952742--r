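# Vessel centerline networks: junction nodes joined by polyline segments
# carrying a per-point diameter, a branch order and a vessel class.

#' Construct a vessel network
#'
#' A vessel network is a graph of junction/terminal nodes joined by polyline
#' segments. Each segment carries an ordered run of centerline points with a
#' local diameter, a branch order (0 = penetrating arteriole) and a vessel
#' class (`"arteriole"`, `"capillary"` or `"venule"`).
#'
#' @param nodes data.frame with columns `node_id`, `x`, `y`, `z`.
#' @param segments data.frame with columns `segment_id`, `from_node`,
#'   `to_node`, `branch_order` (integer or `NA` for unassigned) and
#'   `vessel_class`.
#' @param points data.frame with columns `segment_id`, `x`, `y`, `z`,
#'   `diameter`; rows are ordered along each segment and segment endpoints
#'   must coincide with node coordinates.
#' @param validate check structural invariants (connectivity, endpoint
#'   agreement, positive diameters).
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, segments, points, validate = TRUE) {
  net <- structure(list(nodes = nodes, segments = segments, points = points),
                   class = "vessel_network")
  if (validate) validate_network(net)
  net
}

#' Validate a vessel network's structural invariants
#'
#' Checks positive diameters, segment endpoints coinciding with node
#' coordinates, and graph connectivity. Problems are reported naming the
#' offending segments or nodes.
#'
#' @param network a `vessel_network`.
#' @param tol coordinate tolerance for endpoint/node agreement, micrometres.
#' @return `network`, invisibly.
#' @export
validate_network <- function(network, tol = 1e-6) {
  pts <- network$points
  seg <- network$segments
  nod <- network$nodes
  if (any(pts$diameter <= 0)) {
    stop("non-positive diameters on segment(s): ",
         paste(unique(pts$segment_id[pts$diameter <= 0]), collapse = ", "),
         call. = FALSE)
  }
  node_xyz <- as.matrix(nod[, c("x", "y", "z")])
  rownames(node_xyz) <- as.character(nod$node_id)
  for (i in seq_len(nrow(seg))) {
    sp <- pts[pts$segment_id == seg$segment_id[i], , drop = FALSE]
    if (nrow(sp) < 2L) {
      stop("segment ", seg$segment_id[i], " has fewer than two points",
           call. = FALSE)
    }
    for (end in c("from_node", "to_node")) {
      nid <- as.character(seg[[end]][i])
      if (!nid %in% rownames(node_xyz)) {
        stop("segment ", seg$segment_id[i], " references unknown node ", nid,
             call. = FALSE)
      }
      ref <- node_xyz[nid, ]
      row <- if (end == "from_node") 1L else nrow(sp)
      if (max(abs(c(sp$x[row], sp$y[row], sp$z[row]) - ref)) > tol) {
        stop("segment ", seg$segment_id[i], " endpoint does not lie on node ",
             nid, call. = FALSE)
      }
    }
  }
  # connectivity over the node graph
  if (nrow(seg) > 0L) {
    adj <- split(c(seg$to_node, seg$from_node),
                 c(seg$from_node, seg$to_node))
    seen <- as.character(seg$from_node[1])
    frontier <- seen
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- setdiff(as.character(nxt), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    all_nodes <- as.character(unique(c(seg$from_node, seg$to_node)))
    orphan <- setdiff(all_nodes, seen)
    if (length(orphan) > 0L) {
      stop("network is disconnected; unreachable node(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  invisible(network)
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network> ", nrow(x$segments), " segments, ",
      nrow(x$nodes), " nodes, ", nrow(x$points), " centerline points\n",
      sep = "")
  if (nrow(x$segments) > 0L) {
    ord <- x$segments$branch_order
    cat("  branch orders: ",
        if (all(is.na(ord))) "unassigned" else
          paste(range(ord, na.rm = TRUE), collapse = ".."),
        "; total length ", round(total_length(x), 1), " um\n", sep = "")
  }
  invisible(x)
}

#' Total centerline length of a network
#'
#' @param network a `vessel_network`.
#' @param segment_ids optional subset of segments.
#' @return length in micrometres.
#' @export
total_length <- function(network, segment_ids = NULL) {
  pts <- network$points
  if (!is.null(segment_ids)) pts <- pts[pts$segment_id %in% segment_ids, ]
  if (nrow(pts) < 2L) return(0)
  sum(vapply(split(pts, pts$segment_id), function(sp) {
    co <- as.matrix(sp[, c("x", "y", "z")])
    sum(sqrt(rowSums((co[-1, , drop = FALSE] - co[-nrow(co), , drop = FALSE])^2)))
  }, numeric(1)))
}

#' Segment arclength table
#'
#' @param network a `vessel_network`.
#' @return data.frame of `segment_id` and `length` (micrometres).
#' @export
segment_lengths <- function(network) {
  pts <- network$points
  sl <- vapply(split(pts, pts$segment_id), function(sp) {
    co <- as.matrix(sp[, c("x", "y", "z")])
    sum(sqrt(rowSums((co[-1, , drop = FALSE] - co[-nrow(co), , drop = FALSE])^2)))
  }, numeric(1))
  data.frame(segment_id = as.integer(names(sl)), length = unname(sl))
}

# Cumulative arclength of the points of one segment.
.segment_arclengths <- function(network, segment_id) {
  sp <- network$points[network$points$segment_id == segment_id, , drop = FALSE]
  co <- as.matrix(sp[, c("x", "y", "z")])
  c(0, cumsum(sqrt(rowSums(
    (co[-1, , drop = FALSE] - co[-nrow(co), , drop = FALSE])^2))))
}

#' Interpolated diameter at an arclength position on a segment
#'
#' @param network a `vessel_network`.
#' @param segment_id segment identifier.
#' @param arclength position along the segment in micrometres from its
#'   `from_node` end.
#' @return diameter in micrometres.
#' @export
diameter_at <- function(network, segment_id, arclength) {
  s <- .segment_arclengths(network, segment_id)
  dm <- network$points$diameter[network$points$segment_id == segment_id]
  stats::approx(s, dm, xout = .clamp(arclength, 0, max(s)), rule = 2)$y
}

# Coordinates of the centerline point at an arclength position.
.point_at <- function(network, segment_id, arclength) {
  s <- .segment_arclengths(network, segment_id)
  sp <- network$points[network$points$segment_id == segment_id, , drop = FALSE]
  arclength <- .clamp(arclength, 0, max(s))
  c(stats::approx(s, sp$x, xout = arclength, rule = 2)$y,
    stats::approx(s, sp$y, xout = arclength, rule = 2)$y,
    stats::approx(s, sp$z, xout = arclength, rule = 2)$y)
}

# Multiply point diameters within an arclength window by a factor; when
# windows overlap the larger resulting factor wins (factors do not stack).
.apply_dilation <- function(network, segment_id, s_center, half_width, factor,
                            base = NULL) {
  sel <- network$points$segment_id == segment_id
  s <- .segment_arclengths(network, segment_id)
  hit <- abs(s - s_center) <= half_width
  idx <- which(sel)[hit]
  ref <- if (is.null(base)) network$points$diameter[idx] else base[idx]
  network$points$diameter[idx] <- pmax(network$points$diameter[idx],
                                       ref * factor)
  network
}

# Multiply point diameters within an arclength window by a factor
# unconditionally (sequential event scaling, unlike .apply_dilation).
.scale_window <- function(network, segment_id, s_center, half_width,
                          factor) {
  sel <- network$points$segment_id == segment_id
  s <- .segment_arclengths(network, segment_id)
  idx <- which(sel)[abs(s - s_center) <= half_width]
  network$points$diameter[idx] <- network$points$diameter[idx] * factor
  network
}

# Arclength distance from a position to the nearest end (node) of its
# segment; used for branchpoint exclusion.
.dist_to_segment_ends <- function(network, segment_id, arclength) {
  s <- .segment_arclengths(network, segment_id)
  min(arclength, max(s) - arclength)
}
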