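# CAM/PEM classification by nucleus/soma center distance criteria, plus
# the boxed-ROI and grid counting protocols.

#' Association criteria
#'
#' Distance criteria for capillary-associated (CAM) and
#' pericyte-associated (PEM) microglia. A microglia is a CAM when its
#' reference center lies strictly within `r_assoc` of the centerline of a
#' vessel whose local diameter is below `d_vessel_max`; it is a PEM when
#' its reference center lies strictly within `r_assoc` of the nucleus
#' center of a pericyte residing on such a vessel. The two labels are
#' independent.
#'
#' @param r_assoc association radius in micrometres (default 10).
#' @param d_vessel_max maximum eligible vessel diameter in micrometres
#'   (default 10).
#' @param strict_inequality use `<` at the boundary (default `TRUE`; a
#'   distance of exactly `r_assoc` does not associate).
#' @param use_nucleus_center reference the nucleus center (`TRUE`, fixed
#'   tissue) or the soma center (`FALSE`, in-vivo mode).
#' @return A list of class `association_criteria`.
#' @export
association_criteria <- function(r_assoc = 10, d_vessel_max = 10,
                                 strict_inequality = TRUE,
                                 use_nucleus_center = TRUE) {
  stopifnot(r_assoc > 0, d_vessel_max > 0)
  structure(list(r_assoc = r_assoc, d_vessel_max = d_vessel_max,
                 strict_inequality = strict_inequality,
                 use_nucleus_center = use_nucleus_center),
            class = "association_criteria")
}

.closer <- function(d, r, strict) if (strict) d < r else d <= r

#' Distance from cells to the nearest eligible vessel centerline
#'
#' Exact minimum Euclidean point-to-polyline distance from each cell's
#' reference center to the centerlines of eligible vessel pieces (local
#' diameter below `criteria$d_vessel_max`, interpolated at the foot
#' point). Cells with no eligible vessel anywhere get `NA` distance.
#'
#' @param cells a cell table (any cell type).
#' @param network a [vessel_network()].
#' @param criteria an [association_criteria()].
#' @return data.frame with `distance`, `segment_id`, `arclength`,
#'   `local_diameter` per input row.
#' @export
nearest_vessel_distance <- function(cells, network,
                                    criteria = association_criteria()) {
  pieces <- .network_pieces(network)
  if (is.null(pieces)) {
    stop("network has no centerline pieces", call. = FALSE)
  }
  # a piece is eligible where its diameter can drop below the cap; final
  # eligibility uses the interpolated diameter at the foot point, so keep
  # pieces whose minimum endpoint diameter qualifies and re-check below
  keep <- pmin(pieces$dA, pieces$dB) < criteria$d_vessel_max
  if (!any(keep)) {
    out <- data.frame(distance = rep(NA_real_, nrow(cells)),
                      segment_id = NA_integer_, arclength = NA_real_,
                      local_diameter = NA_real_)
    attr(out, "no_eligible_vessel") <- TRUE
    return(out)
  }
  coords <- .cell_coords(cells, use_nucleus = criteria$use_nucleus_center)
  if (!.is_3d(cells)) {
    # 2D analysis: distances in the section plane
    pieces$A[, 3] <- 0; pieces$B[, 3] <- 0
  }
  res <- .nearest_on_network(coords, pieces, piece_keep = keep)
  # enforce eligibility at the foot point itself
  bad <- !is.na(res$local_diameter) &
    res$local_diameter >= criteria$d_vessel_max
  if (any(bad)) {
    for (i in which(bad)) {
      keep_i <- keep
      hit <- .point_pieces_nearest(coords[i, ], pieces$A, pieces$B,
                                   pieces$dA, pieces$dB, keep = keep_i)
      # walk candidate pieces until the foot-point diameter qualifies
      ord <- order(hit$all_d)
      res$distance[i] <- NA_real_
      res$segment_id[i] <- NA_integer_
      res$arclength[i] <- NA_real_
      res$local_diameter[i] <- NA_real_
      for (j in ord) {
        if (!keep_i[j] || !is.finite(hit$all_d[j])) next
        one <- .point_pieces_nearest(coords[i, ],
                                     pieces$A[j, , drop = FALSE],
                                     pieces$B[j, , drop = FALSE],
                                     pieces$dA[j], pieces$dB[j])
        if (one$diam < criteria$d_vessel_max) {
          res$distance[i] <- one$dist
          res$segment_id[i] <- pieces$segment_id[j]
          res$arclength[i] <- pieces$s0[j] + one$t * pieces$piece_len[j]
          res$local_diameter[i] <- one$diam
          break
        }
      }
    }
  }
  res
}

# Pericytes eligible to anchor a PEM: resident on a vessel with local
# diameter below the cap. Uses the recorded host diameter when the table
# carries one, otherwise projects onto the network.
.eligible_pericytes <- function(peri, network, criteria) {
  if (nrow(peri) == 0L) return(logical(0))
  if ("host_diameter" %in% names(peri) && !all(is.na(peri$host_diameter))) {
    hd <- peri$host_diameter
  } else {
    if (is.null(network)) {
      # no residence information: treat all supplied pericytes as eligible
      return(rep(TRUE, nrow(peri)))
    }
    nv <- nearest_vessel_distance(peri, network, criteria)
    hd <- nv$local_diameter
  }
  !is.na(hd) & hd < criteria$d_vessel_max
}

#' Classify CAM and PEM
#'
#' Runs both distance criteria on a cell table: microglia within
#' `r_assoc` of an eligible vessel centerline are CAM; microglia within
#' `r_assoc` of an eligible pericyte nucleus are PEM, irrespective of
#' their CAM status. Ties between equidistant pericytes break to the
#' lowest `cell_id` for reproducibility.
#'
#' @param cells cell table containing microglia and (optionally) pericytes.
#' @param network a [vessel_network()], or `NULL` to skip CAM labels (all
#'   pericytes supplied are then assumed capillary-resident unless they
#'   carry a `host_diameter` column).
#' @param criteria an [association_criteria()].
#' @return An `association_result`: list with `microglia` (labels and
#'   distances), `pericytes` (with `has_pem`), `criteria` and `summary`
#'   (see [summarize_association()]).
#' @export
classify_cells <- function(cells, network = NULL,
                           criteria = association_criteria()) {
  mic <- cells[cells$cell_type == "microglia", , drop = FALSE]
  peri <- cells[cells$cell_type == "pericyte", , drop = FALSE]
  .assert_same_dims(mic, peri)

  mic$nearest_vessel_distance <- rep(NA_real_, nrow(mic))
  mic$is_cam <- rep(FALSE, nrow(mic))
  if (!is.null(network) && nrow(mic) > 0L && nrow(network$points) > 0L) {
    nv <- nearest_vessel_distance(mic, network, criteria)
    mic$nearest_vessel_distance <- nv$distance
    mic$is_cam <- !is.na(nv$distance) &
      .closer(nv$distance, criteria$r_assoc, criteria$strict_inequality)
  }

  mic$nearest_pericyte_distance <- rep(NA_real_, nrow(mic))
  mic$nearest_pericyte_id <- rep(NA_integer_, nrow(mic))
  mic$is_pem <- rep(FALSE, nrow(mic))
  elig <- .eligible_pericytes(peri, network, criteria)
  peri$has_pem <- rep(FALSE, nrow(peri))
  if (nrow(mic) > 0L && any(elig)) {
    pe <- peri[elig, , drop = FALSE]
    dm <- .cross_dist(.cell_coords(mic, criteria$use_nucleus_center),
                      .cell_coords(pe, criteria$use_nucleus_center))
    # lowest cell_id wins ties: order columns by id, then which.min takes
    # the first minimum
    ord <- order(pe$cell_id)
    dm <- dm[, ord, drop = FALSE]
    pe_ids <- pe$cell_id[ord]
    j <- apply(dm, 1L, which.min)
    dmin <- dm[cbind(seq_len(nrow(dm)), j)]
    mic$nearest_pericyte_distance <- dmin
    mic$nearest_pericyte_id <- pe_ids[j]
    mic$is_pem <- .closer(dmin, criteria$r_assoc, criteria$strict_inequality)
    # pericyte-side flag is symmetric: any microglia within the radius
    col_min <- apply(dm, 2L, min)
    with_pem <- pe_ids[.closer(col_min, criteria$r_assoc,
                               criteria$strict_inequality)]
    peri$has_pem <- peri$cell_id %in% with_pem
  }

  res <- structure(list(microglia = mic, pericytes = peri,
                        criteria = criteria),
                   class = "association_result")
  res$summary <- summarize_association(res)
  res
}

#' @rdname classify_cells
#' @export
classify_cam <- function(cells, network, criteria = association_criteria()) {
  classify_cells(cells, network, criteria)
}

#' @rdname classify_cells
#' @export
classify_pem <- function(cells, criteria = association_criteria(),
                         network = NULL) {
  classify_cells(cells, network, criteria)
}

#' Summary proportions of an association result
#'
#' Percentages of microglia that are CAM, PEM, the percentage of CAM that
#' are also PEM, and the percentage of pericytes carrying a PEM. Zero
#' denominators yield `NA`, never 0.
#'
#' @param result an `association_result` from [classify_cells()].
#' @return list with counts and percentages.
#' @export
summarize_association <- function(result) {
  mic <- result$microglia
  peri <- result$pericytes
  n_mic <- nrow(mic)
  n_cam <- sum(mic$is_cam, na.rm = TRUE)
  n_pem <- sum(mic$is_pem, na.rm = TRUE)
  n_cam_pem <- sum(mic$is_cam & mic$is_pem, na.rm = TRUE)
  n_peri <- nrow(peri)
  n_peri_pem <- sum(peri$has_pem, na.rm = TRUE)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(n_microglia = n_mic, n_pericytes = n_peri,
       n_cam = n_cam, n_pem = n_pem, n_cam_and_pem = n_cam_pem,
       n_pericytes_with_pem = n_peri_pem,
       pct_cam = pct(n_cam, n_mic),
       pct_pem = pct(n_pem, n_mic),
       pct_cam_that_are_pem = pct(n_cam_pem, n_cam),
       pct_pericytes_with_pem = pct(n_peri_pem, n_peri))
}

#' @export
print.association_result <- function(x, ...) {
  s <- x$summary
  cat("<association_result> ", s$n_microglia, " microglia, ",
      s$n_pericytes, " pericytes\n", sep = "")
  cat(sprintf("  CAM %.1f%%  PEM %.1f%%  CAM-that-are-PEM %.1f%%  pericytes with PEM %.1f%%\n",
              s$pct_cam, s$pct_pem, s$pct_cam_that_are_pem,
              s$pct_pericytes_with_pem))
  invisible(x)
}

#' Count cells under the boxed-ROI and grid sampling protocols
#'
#' Three counting protocols over a labeled cell table:
#' * `"A"`: one box (default 800 x 600 um); cells whose nucleus disc
#'   (configurable radius) touches any box edge are excluded.
#' * `"B"`: square tiles (default 400 um) laid over the region; the first
#'   complete tile and every second complete tile thereafter are counted,
#'   up to `max_tiles`; a cell on a tile margin is counted only in the
#'   tile whose top or left margin it touches, so no cell is double
#'   counted.
#' * `"C"`: like `"B"` for a traced region polygon shrunk inward by
#'   `shrink_um` (default 50 um), tiles of 500 um, every fourth complete
#'   tile, up to 20 tiles.
#'
#' @param result an `association_result` (labeled cells), or a plain cell
#'   table (then only raw cell counts are reported).
#' @param protocol `"A"`, `"B"` or `"C"`.
#' @param geometry for `"A"` and `"B"`: numeric `c(x0, y0, width, height)`
#'   box; for `"C"`: an n x 2 matrix tracing the region polygon.
#' @param nucleus_radius radius (um) used for the protocol-A edge-touch
#'   rule; default 3.
#' @param artifact_polygons optional list of n x 2 matrices; tiles
#'   intersecting any are skipped.
#' @param tile_size,every,max_tiles,shrink_um protocol parameters;
#'   defaults follow the protocol letter.
#' @return data.frame of per-sampling-unit counts (microglia, pericytes,
#'   CAM, PEM, pericytes with a PEM) with tile origins; attribute
#'   `"tiles_skipped"` records exclusions.
#' @export
count_protocol <- function(result, protocol = c("A", "B", "C"), geometry,
                           nucleus_radius = 3, artifact_polygons = list(),
                           tile_size = NULL, every = NULL, max_tiles = NULL,
                           shrink_um = 50) {
  protocol <- match.arg(protocol)
  if (inherits(result, "association_result")) {
    mic <- result$microglia; peri <- result$pericytes
  } else {
    mic <- result[result$cell_type == "microglia", , drop = FALSE]
    peri <- result[result$cell_type == "pericyte", , drop = FALSE]
    mic$is_cam <- NA; mic$is_pem <- NA; peri$has_pem <- NA
  }
  count_unit <- function(in_mic, in_peri) {
    data.frame(n_microglia = sum(in_mic),
               n_pericytes = sum(in_peri),
               n_cam = sum(mic$is_cam[in_mic], na.rm = TRUE),
               n_pem = sum(mic$is_pem[in_mic], na.rm = TRUE),
               n_pericytes_with_pem = sum(peri$has_pem[in_peri],
                                          na.rm = TRUE))
  }

  if (protocol == "A") {
    stopifnot(length(geometry) == 4L)
    x0 <- geometry[1]; y0 <- geometry[2]
    x1 <- x0 + geometry[3]; y1 <- y0 + geometry[4]
    inside_clear <- function(cc) {
      cc$x_um > x0 + nucleus_radius & cc$x_um < x1 - nucleus_radius &
        cc$y_um > y0 + nucleus_radius & cc$y_um < y1 - nucleus_radius
    }
    out <- cbind(data.frame(unit = 1L, x0 = x0, y0 = y0),
                 count_unit(inside_clear(mic), inside_clear(peri)))
    attr(out, "tiles_skipped") <- 0L
    return(out)
  }

  if (is.null(tile_size)) tile_size <- if (protocol == "B") 400 else 500
  if (is.null(every)) every <- if (protocol == "B") 2L else 4L
  if (is.null(max_tiles)) max_tiles <- if (protocol == "B") 12L else 20L

  if (protocol == "B") {
    stopifnot(length(geometry) == 4L)
    x0 <- geometry[1]; y0 <- geometry[2]
    nx <- floor(geometry[3] / tile_size)
    ny <- floor(geometry[4] / tile_size)
    tile_ok <- function(tx, ty) TRUE
  } else {
    poly <- as.matrix(geometry)
    x0 <- min(poly[, 1]); y0 <- min(poly[, 2])
    nx <- floor((max(poly[, 1]) - x0) / tile_size)
    ny <- floor((max(poly[, 2]) - y0) / tile_size)
    # a tile is complete when its corners and edge midpoints lie inside
    # the trace with at least `shrink_um` clearance from its boundary
    tile_ok <- function(tx, ty) {
      px <- tx + tile_size * c(0, 0.5, 1, 0, 1, 0, 0.5, 1)
      py <- ty + tile_size * c(0, 0, 0, 0.5, 0.5, 1, 1, 1)
      all(.point_in_polygon(px, py, poly) &
            .dist_to_polygon_boundary(px, py, poly) >= shrink_um)
    }
  }
  if (nx < 1L || ny < 1L) {
    warning("region smaller than one tile: zero sampling units")
    out <- data.frame(unit = integer(0), x0 = numeric(0), y0 = numeric(0),
                      n_microglia = integer(0), n_pericytes = integer(0),
                      n_cam = integer(0), n_pem = integer(0),
                      n_pericytes_with_pem = integer(0))
    attr(out, "tiles_skipped") <- 0L
    return(out)
  }

  hits_artifact <- function(tx, ty) {
    for (ap in artifact_polygons) {
      ap <- as.matrix(ap)
      cx <- tx + tile_size * c(0, 0.5, 1, 0, 0.5, 1, 0, 0.5, 1)
      cy <- ty + tile_size * c(0, 0, 0, 0.5, 0.5, 0.5, 1, 1, 1)
      if (any(.point_in_polygon(cx, cy, ap))) return(TRUE)
      if (any(ap[, 1] >= tx & ap[, 1] <= tx + tile_size &
              ap[, 2] >= ty & ap[, 2] <= ty + tile_size)) return(TRUE)
    }
    FALSE
  }

  skipped <- 0L
  complete <- list()
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      tx <- x0 + (ix - 1L) * tile_size
      ty <- y0 + (iy - 1L) * tile_size
      if (!tile_ok(tx, ty)) next
      if (hits_artifact(tx, ty)) { skipped <- skipped + 1L; next }
      complete[[length(complete) + 1L]] <- c(tx, ty)
    }
  }
  sel <- complete[seq(1L, length(complete), by = every)]
  if (length(sel) > max_tiles) sel <- sel[seq_len(max_tiles)]

  # membership under the top/left rule: half-open [x, x + s) x [y, y + s)
  in_tile <- function(cc, tx, ty) {
    cc$x_um >= tx & cc$x_um < tx + tile_size &
      cc$y_um >= ty & cc$y_um < ty + tile_size
  }
  rows <- lapply(seq_along(sel), function(k) {
    tx <- sel[[k]][1]; ty <- sel[[k]][2]
    cbind(data.frame(unit = k, x0 = tx, y0 = ty),
          count_unit(in_tile(mic, tx, ty), in_tile(peri, tx, ty)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = integer(0), x0 = numeric(0), y0 = numeric(0),
               n_microglia = integer(0), n_pericytes = integer(0),
               n_cam = integer(0), n_pem = integer(0),
               n_pericytes_with_pem = integer(0))
  attr(out, "tiles_skipped") <- skipped
  out
}
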