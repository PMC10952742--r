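# Synthetic cell placement on a vessel network and 2D slab projection.

# Canonical empty cell table shared by generator and readers.
.empty_cells <- function() {
  data.frame(cell_id = integer(0), cell_type = character(0),
             x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             soma_x = numeric(0), soma_y = numeric(0), soma_z = numeric(0),
             day = integer(0), has_nucleus = logical(0),
             truth_class = character(0), partner_id = integer(0),
             on_segment = integer(0), arclength = numeric(0),
             host_diameter = numeric(0))
}

.cells_row <- function(cell_id, cell_type, xyz, day = 0L,
                       truth_class = NA_character_, partner_id = NA_integer_,
                       on_segment = NA_integer_, arclength = NA_real_,
                       host_diameter = NA_real_) {
  data.frame(cell_id = as.integer(cell_id), cell_type = cell_type,
             x_um = xyz[1], y_um = xyz[2], z_um = xyz[3],
             soma_x = xyz[1], soma_y = xyz[2], soma_z = xyz[3],
             day = as.integer(day), has_nucleus = TRUE,
             truth_class = truth_class, partner_id = partner_id,
             on_segment = as.integer(on_segment), arclength = arclength,
             host_diameter = host_diameter)
}

#' Place pericytes and microglia on a synthetic vessel network
#'
#' Pericytes are anchored at random arclengths on capillary segments
#' (local diameter below 10 um) subject to a minimum centerline spacing,
#' with nucleus centers offset radially to the vessel wall. Microglia are
#' placed as the configured mixture of uniform, vessel-attracted and
#' pericyte-attracted cells; attracted cells are offset uniformly within a
#' ball of `config$attraction_radius` around their target so that every
#' pericyte-attracted microglia is a positive PEM case at generation time.
#' Vessel diameters are locally dilated at pericyte, CAM and PEM
#' landmarks according to `config$width_profile`. Ground-truth placement
#' class and intended partner pericyte are recorded per microglia.
#'
#' @param network a [vessel_network()], typically from
#'   [generate_vessel_network()].
#' @param config a [generator_config()].
#' @param seed optional integer seed; defaults to the current RNG stream so
#'   that a single seed set at the top of a pipeline governs everything.
#' @return A `synthetic_scene`: list with elements `network` (diameters
#'   include landmark dilation), `cells` and `config`.
#' @export
place_cells <- function(network, config, seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ext <- config$roi_extent
  wp <- config$width_profile

  seg <- network$segments
  cap_ids <- seg$segment_id[seg$vessel_class == "capillary"]
  sl <- segment_lengths(network)
  sl <- sl[sl$segment_id %in% cap_ids, , drop = FALSE]
  L <- sum(sl$length)

  # ---- pericytes ------------------------------------------------------
  lam_p <- config$pericyte_linear_density * L
  n_peri <- if (config$exact_counts) round(lam_p) else stats::rpois(1, lam_p)
  peri <- .empty_cells()
  placed <- list()  # per segment, accepted arclengths
  if (n_peri > 0L) {
    if (n_peri * config$pericyte_min_spacing > L) {
      stop(structure(class = c("pemscope_infeasible_density", "error",
                               "condition"),
                     list(message = paste0(
                       n_peri, " pericytes at minimum spacing ",
                       config$pericyte_min_spacing,
                       " um cannot fit on ", round(L, 1),
                       " um of capillary centerline"), call = NULL)))
    }
    cum <- cumsum(sl$length)
    rows <- vector("list", n_peri)
    for (i in seq_len(n_peri)) {
      ok <- FALSE
      for (attempt in seq_len(200L)) {
        u <- stats::runif(1, 0, L)
        k <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
        sid <- sl$segment_id[k]
        s <- u - c(0, cum)[k]
        prev <- placed[[as.character(sid)]]
        if (!is.null(prev) &&
            any(abs(prev - s) < config$pericyte_min_spacing)) next
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(structure(class = c("pemscope_infeasible_density", "error",
                                 "condition"),
                       list(message = paste0(
                         "could not place pericyte ", i, " of ", n_peri,
                         " at minimum spacing ",
                         config$pericyte_min_spacing, " um"), call = NULL)))
      }
      placed[[as.character(sid)]] <- c(placed[[as.character(sid)]], s)
      ctr <- .point_at(network, sid, s)
      diam <- diameter_at(network, sid, s)
      # radial offset to the vessel wall, perpendicular to local tangent
      eps <- min(1, max(s, 1e-3))
      tang <- .point_at(network, sid, s + eps) - .point_at(network, sid, s - eps)
      if (sum(tang^2) < 1e-12) tang <- c(1, 0, 0)
      tang <- tang / sqrt(sum(tang^2))
      ref <- if (abs(tang[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u1 <- ref - sum(ref * tang) * tang; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- c(tang[2] * u1[3] - tang[3] * u1[2],
              tang[3] * u1[1] - tang[1] * u1[3],
              tang[1] * u1[2] - tang[2] * u1[1])
      ang <- stats::runif(1, 0, 2 * pi)
      nucleus <- ctr + (diam / 2) * (cos(ang) * u1 + sin(ang) * u2)
      nucleus <- .clamp(nucleus, 0, ext)
      rows[[i]] <- .cells_row(i, "pericyte", nucleus,
                              on_segment = sid, arclength = s,
                              host_diameter = diam)
    }
    peri <- do.call(rbind, rows)
  }

  # ---- microglia ------------------------------------------------------
  area <- ext[1] * ext[2]
  lam_m <- config$microglia_density * area
  n_mic <- if (config$exact_counts) round(lam_m) else stats::rpois(1, lam_m)
  mic <- .empty_cells()
  if (n_mic > 0L) {
    fp <- config$frac_pericyte_attracted
    fv <- config$frac_vessel_attracted
    if (n_peri == 0L) fp <- 0  # nothing to attract to
    if (config$exact_counts) {
      n_p <- round(fp * n_mic); n_v <- round(fv * n_mic)
    } else {
      draw <- stats::rmultinom(1, n_mic, c(fp, fv, max(1 - fp - fv, 0)))
      n_p <- draw[1]; n_v <- draw[2]
    }
    n_u <- n_mic - n_p - n_v
    classes <- c(rep("pericyte-attracted", n_p),
                 rep("vessel-attracted", n_v),
                 rep("uniform", n_u))
    coords <- matrix(NA_real_, n_mic, 3)
    partner <- rep(NA_integer_, n_mic)
    if (n_p > 0L) {
      idx <- if (n_p <= n_peri) sample(seq_len(n_peri), n_p) else
        sample(seq_len(n_peri), n_p, replace = TRUE)
      tgt <- as.matrix(peri[idx, c("x_um", "y_um", "z_um")])
      coords[seq_len(n_p), ] <-
        .clamp_to_box(tgt + .runif_ball(n_p, config$attraction_radius), ext)
      partner[seq_len(n_p)] <- peri$cell_id[idx]
    }
    pieces <- .network_pieces(network)
    if (n_v > 0L) {
      keep <- pieces$segment_id %in% cap_ids
      w <- pieces$piece_len * keep
      # vessel-attracted (CAM-like) targets keep clear of pericyte somata
      # (association radius + attraction radius), so placed cells cannot
      # be PEM by construction and the pericyte-attracted fraction alone
      # controls enrichment over chance
      clearance <- 10 + config$attraction_radius
      pxyz <- if (n_peri > 0L) .cell_coords(peri) else NULL
      for (k in seq_len(n_v)) {
        tgt <- NULL
        for (attempt in seq_len(50L)) {
          pk <- sample(seq_along(w), 1L, prob = w / sum(w))
          t <- stats::runif(1)
          cand <- pieces$A[pk, ] + (pieces$B[pk, ] - pieces$A[pk, ]) * t
          if (is.null(pxyz) ||
              min(.cross_dist(matrix(cand, 1L), pxyz)) >= clearance) {
            tgt <- cand
            break
          }
        }
        if (is.null(tgt)) tgt <- cand  # pericytes everywhere: accept
        coords[n_p + k, ] <-
          .clamp_to_box(matrix(tgt, 1L) +
                          .runif_ball(1L, config$attraction_radius), ext)
      }
    }
    if (n_u > 0L) {
      coords[n_p + n_v + seq_len(n_u), ] <-
        cbind(stats::runif(n_u, 0, ext[1]), stats::runif(n_u, 0, ext[2]),
              stats::runif(n_u, 0, ext[3]))
    }
    mic <- do.call(rbind, lapply(seq_len(n_mic), function(i) {
      .cells_row(n_peri + i, "microglia", coords[i, ],
                 truth_class = classes[i], partner_id = partner[i])
    }))
  }

  cells <- rbind(peri, mic)

  # ---- landmark dilation ---------------------------------------------
  # Dilation reflects the realized geometry, matching how the analysis
  # later classifies landmarks: a pericyte with any microglia nucleus
  # within 10 um is a PEM site (factor PEM), otherwise a P site; any
  # microglia within 10 um of an eligible centerline and at least 10 um
  # from every pericyte marks a CAM site.
  base_diam <- network$points$diameter
  mic_xyz <- if (nrow(mic) > 0L) .cell_coords(mic) else NULL
  peri_xyz <- if (n_peri > 0L) .cell_coords(peri) else NULL
  if (n_peri > 0L) {
    d_mp <- if (!is.null(mic_xyz)) .cross_dist(mic_xyz, peri_xyz) else NULL
    for (i in seq_len(n_peri)) {
      near_mic <- !is.null(d_mp) && any(d_mp[, i] < 10)
      f <- if (near_mic) wp$dilation[["PEM"]] else wp$dilation[["P"]]
      network <- .apply_dilation(network, peri$on_segment[i],
                                 peri$arclength[i], wp$window_um, f,
                                 base = base_diam)
    }
  }
  if (nrow(mic) > 0L) {
    pieces <- .network_pieces(network)
    keep <- pieces$segment_id %in% cap_ids
    near <- .nearest_on_network(mic_xyz, pieces, piece_keep = keep)
    for (i in seq_len(nrow(mic))) {
      if (is.na(near$segment_id[i]) || near$distance[i] >= 10) next
      dmin <- if (!is.null(peri_xyz))
        min(.cross_dist(mic_xyz[i, , drop = FALSE], peri_xyz)) else Inf
      if (dmin >= 10) {  # a CAM landmark clear of pericytes
        network <- .apply_dilation(network, near$segment_id[i],
                                   near$arclength[i], wp$window_um,
                                   wp$dilation[["CAM"]], base = base_diam)
      }
    }
  }

  structure(list(network = network, cells = cells, config = config, dims = 3L),
            class = "synthetic_scene")
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: seeds the RNG once from `config$seed` (or `seed`),
#' grows the network and places the cells.
#'
#' @inheritParams place_cells
#' @return A `synthetic_scene`.
#' @export
generate_scene <- function(config, seed = NULL) {
  .maybe_seed(config, seed)
  net <- generate_vessel_network(config, seed = NULL)
  place_cells(net, config, seed = NULL)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  tab <- table(x$cells$cell_type)
  cat("<synthetic_scene> ", x$dims, "D, ",
      sum(tab[names(tab) == "microglia"]), " microglia, ",
      sum(tab[names(tab) == "pericyte"]), " pericytes, ",
      nrow(x$network$segments), " vessel segments\n", sep = "")
  invisible(x)
}

#' Project a 3D scene onto a thin section
#'
#' Emulates extended-focal 2D analysis of a thin slab: cells whose nucleus
#' center lies inside the slab are retained with their z coordinate
#' dropped, and vessel polylines are clipped to the slab and flattened.
#' An empty slab yields an empty (not erroneous) scene.
#'
#' @param scene a `synthetic_scene`.
#' @param thickness slab thickness in micrometres (> 0).
#' @param z_center slab center depth; the slab must overlap the ROI.
#' @return A 2D `synthetic_scene` (cells carry `NA` z).
#' @export
project_to_section <- function(scene, thickness, z_center) {
  stopifnot(thickness > 0)
  ext <- scene$config$roi_extent
  lo <- z_center - thickness / 2
  hi <- z_center + thickness / 2
  if (hi < 0 || lo > ext[3]) {
    stop("slab [", lo, ", ", hi, "] lies outside the ROI depth 0..", ext[3],
         call. = FALSE)
  }
  cells <- scene$cells
  keep <- !is.na(cells$z_um) & cells$z_um >= lo & cells$z_um <= hi
  cells <- cells[keep, , drop = FALSE]
  cells$z_um <- rep(NA_real_, nrow(cells))
  cells$soma_z <- rep(NA_real_, nrow(cells))

  # clip polylines: consecutive runs of in-slab points become new segments
  pts <- scene$network$points
  seg <- scene$network$segments
  new_pts <- list(); new_seg <- list(); new_nodes <- list()
  sid_new <- 0L; nid_new <- 0L
  for (i in seq_len(nrow(seg))) {
    sp <- pts[pts$segment_id == seg$segment_id[i], , drop = FALSE]
    inside <- sp$z >= lo & sp$z <= hi
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- sp[starts[k]:ends[k], , drop = FALSE]
      if (nrow(run) < 2L) next
      sid_new <- sid_new + 1L
      run$segment_id <- sid_new
      run$z <- 0
      nid_new <- nid_new + 2L
      new_nodes[[nid_new - 1L]] <- data.frame(
        node_id = nid_new - 1L, x = run$x[1], y = run$y[1], z = 0)
      new_nodes[[nid_new]] <- data.frame(
        node_id = nid_new, x = run$x[nrow(run)], y = run$y[nrow(run)], z = 0)
      new_seg[[sid_new]] <- data.frame(
        segment_id = sid_new, from_node = nid_new - 1L, to_node = nid_new,
        branch_order = seg$branch_order[i], vessel_class = seg$vessel_class[i])
      new_pts[[sid_new]] <- run
    }
  }
  net2 <- structure(list(
    nodes = if (length(new_nodes)) do.call(rbind, new_nodes) else
      data.frame(node_id = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0)),
    segments = if (length(new_seg)) do.call(rbind, new_seg) else
      data.frame(segment_id = integer(0), from_node = integer(0),
                 to_node = integer(0), branch_order = integer(0),
                 vessel_class = character(0)),
    points = if (length(new_pts)) do.call(rbind, new_pts) else
      data.frame(segment_id = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), diameter = numeric(0))),
    class = "vessel_network")
  # segment references into the 3D network no longer apply
  cells$on_segment <- rep(NA_integer_, nrow(cells))
  cells$arclength <- rep(NA_real_, nrow(cells))
  structure(list(network = net2, cells = cells, config = scene$config,
                 dims = 2L),
            class = "synthetic_scene")
}
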