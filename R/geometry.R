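# Internal computational geometry used across modules. All coordinates are
# continuous micrometres, 0-based at the ROI corner, right-handed, z
# increasing with imaging depth.

# Coordinate matrix (n x 3) from a cell table; 2D tables get z = 0 so the
# Euclidean metric degenerates to the in-plane distance.
.cell_coords <- function(cells, use_nucleus = TRUE) {
  if (nrow(cells) == 0L) return(matrix(numeric(0), ncol = 3L))
  if (use_nucleus || !all(c("soma_x", "soma_y") %in% names(cells))) {
    x <- cells$x_um; y <- cells$y_um
    z <- if (.is_3d(cells)) cells$z_um else rep(0, nrow(cells))
  } else {
    x <- cells$soma_x; y <- cells$soma_y
    z <- if (.is_3d(cells)) cells$soma_z else rep(0, nrow(cells))
  }
  cbind(x, y, z)
}

.is_3d <- function(cells) {
  "z_um" %in% names(cells) && nrow(cells) > 0L && !all(is.na(cells$z_um))
}

.assert_same_dims <- function(cells_a, cells_b) {
  if (nrow(cells_a) == 0L || nrow(cells_b) == 0L) return(invisible(TRUE))
  if (.is_3d(cells_a) != .is_3d(cells_b)) {
    stop("mixed 2D and 3D cell tables: all records must share dimensionality",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Pairwise Euclidean distances between rows of two coordinate matrices.
.cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Toroidal (wrap-around) pairwise distances inside a periodic box.
.cross_dist_torus <- function(a, b, box) {
  nd <- length(box)
  d2 <- matrix(0, nrow(a), ncol = nrow(b))
  for (k in seq_len(nd)) {
    dk <- abs(outer(a[, k], b[, k], "-"))
    dk <- pmin(dk, box[k] - dk)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Distance from each point in P (n x 3) to the piecewise-linear pieces
# defined by consecutive rows A -> B, together with the interpolation
# parameter of the closest point on each piece. Exact for polylines.
# Returns, per point, the minimum over pieces satisfying `keep` (logical
# per piece), plus attributes of the winning piece.
.point_pieces_nearest <- function(p, A, B, dA, dB, keep = NULL) {
  m <- nrow(A)
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1e-12
  AP <- sweep(-A, 2, -p)          # p - A, rowwise
  t <- rowSums(AP * AB) / len2
  t <- pmin(pmax(t, 0), 1)
  proj <- A + AB * t
  d <- sqrt(rowSums(sweep(proj, 2, p)^2))
  diam <- dA + (dB - dA) * t
  if (!is.null(keep)) d[!keep] <- Inf
  i <- which.min(d)
  list(dist = d[i], piece = i, t = t[i], diam = diam[i],
       proj = proj[i, ], all_d = d)
}

# Flatten a vessel network into piece arrays for fast point queries.
.network_pieces <- function(network) {
  pts <- network$points
  if (is.null(pts) || nrow(pts) < 2L) {
    return(NULL)
  }
  sid <- pts$segment_id
  n <- nrow(pts)
  first_of_next <- c(sid[-1] != sid[-n], TRUE)
  ia <- which(!first_of_next)        # rows that start a piece
  ib <- ia + 1L
  co <- as.matrix(pts[, c("x", "y", "z")])
  # cumulative arclength within each segment, at piece start
  dseg <- sqrt(rowSums((co[ib, , drop = FALSE] - co[ia, , drop = FALSE])^2))
  s0 <- numeric(length(ia))
  cs <- 0
  for (k in seq_along(ia)) {
    if (k > 1L && sid[ia[k]] != sid[ia[k - 1L]]) cs <- 0
    s0[k] <- cs
    cs <- cs + dseg[k]
  }
  list(A = co[ia, , drop = FALSE], B = co[ib, , drop = FALSE],
       dA = pts$diameter[ia], dB = pts$diameter[ib],
       segment_id = sid[ia], s0 = s0, piece_len = dseg)
}

# Nearest point on the network for each row of `coords` (n x 3). Pieces can
# be filtered by `piece_keep`. Returns a data.frame with distance, segment,
# arclength and local (interpolated) diameter at the foot point.
.nearest_on_network <- function(coords, pieces, piece_keep = NULL) {
  n <- nrow(coords)
  out <- data.frame(distance = rep(NA_real_, n),
                    segment_id = rep(NA_integer_, n),
                    arclength = rep(NA_real_, n),
                    local_diameter = rep(NA_real_, n))
  if (is.null(pieces) || n == 0L) return(out)
  if (!is.null(piece_keep) && !any(piece_keep)) return(out)
  for (i in seq_len(n)) {
    hit <- .point_pieces_nearest(coords[i, ], pieces$A, pieces$B,
                                 pieces$dA, pieces$dB, keep = piece_keep)
    if (!is.finite(hit$dist)) next
    out$distance[i] <- hit$dist
    out$segment_id[i] <- pieces$segment_id[hit$piece]
    out$arclength[i] <- pieces$s0[hit$piece] + hit$t * pieces$piece_len[hit$piece]
    out$local_diameter[i] <- hit$diam
  }
  out
}

# Even-odd (ray crossing) point-in-polygon test; polygon is a closed ring
# given as an n x 2 matrix without a repeated last vertex.
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Distance from points to the boundary of a polygon ring.
.dist_to_polygon_boundary <- function(px, py, poly) {
  n <- nrow(poly)
  d <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- ((px - ax) * abx + (py - ay) * aby) / max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    d <- pmin(d, sqrt((ax + t * abx - px)^2 + (ay + t * aby - py)^2))
  }
  d
}

# Uniform sample inside a d-ball of radius r (rows of directions).
.runif_ball <- function(n, r, dim = 3L) {
  dirs <- matrix(stats::rnorm(n * dim), ncol = dim)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- r * stats::runif(n)^(1 / dim)
  dirs * rad
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Project points into an axis-aligned box [0, extent]; non-expansive, so a
# clamped point never moves further from any point already inside the box.
.clamp_to_box <- function(coords, extent) {
  for (k in seq_along(extent)) {
    coords[, k] <- .clamp(coords[, k], 0, extent[k])
  }
  coords
}
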