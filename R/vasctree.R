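# Branch-order assignment, vascular-tree positioning of cells, and vessel
# width measurement at VO/P/CAM/PEM landmarks.

#' Assign branch orders on a vessel network
#'
#' The root segment (a penetrating arteriole) gets order 0; at every
#' junction each daughter segment's order is its parent's order plus one,
#' so orders equal the breadth-first traversal depth from the root. By
#' default the root is the segment with the largest mean diameter among
#' arteriole-classified segments (falling back to the overall largest).
#'
#' @param network a [vessel_network()].
#' @param root_segment optional explicit root segment id.
#' @param spanning_tree if the graph contains cycles, refuse (`FALSE`,
#'   default) or order along a breadth-first spanning tree (`TRUE`).
#' @return The network with `segments$branch_order` filled in.
#' @export
assign_branch_orders <- function(network, root_segment = NULL,
                                 spanning_tree = FALSE) {
  seg <- network$segments
  if (nrow(seg) == 0L) return(network)
  if (is.null(root_segment)) {
    mean_d <- vapply(seg$segment_id, function(sid) {
      mean(network$points$diameter[network$points$segment_id == sid])
    }, numeric(1))
    cand <- if (any(seg$vessel_class == "arteriole")) {
      which(seg$vessel_class == "arteriole")
    } else seq_len(nrow(seg))
    root_segment <- seg$segment_id[cand[which.max(mean_d[cand])]]
  }
  ri <- match(root_segment, seg$segment_id)
  if (is.na(ri)) stop("unknown root segment ", root_segment, call. = FALSE)

  order_out <- rep(NA_integer_, nrow(seg))
  order_out[ri] <- 0L
  # frontier of (node, order-at-node); order at a node = order of the
  # segment that reached it, daughters get +1. Both root endpoints are
  # depth 0: a capillary branching off either end of the arteriole is
  # first order.
  frontier <- list(list(node = seg$from_node[ri], ord = 0L),
                   list(node = seg$to_node[ri], ord = 0L))
  seen_nodes <- as.character(c(seg$from_node[ri], seg$to_node[ri]))
  seen_seg <- rep(FALSE, nrow(seg)); seen_seg[ri] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- list()
    for (f in frontier) {
      inc <- which(!seen_seg &
                     (seg$from_node == f$node | seg$to_node == f$node))
      for (i in inc) {
        seen_seg[i] <- TRUE
        order_out[i] <- f$ord + 1L
        other <- if (seg$from_node[i] == f$node) seg$to_node[i] else
          seg$from_node[i]
        if (as.character(other) %in% seen_nodes) {
          if (!spanning_tree) {
            stop("network contains a cycle; rerun with spanning_tree = TRUE",
                 call. = FALSE)
          }
        } else {
          seen_nodes <- c(seen_nodes, as.character(other))
          nxt[[length(nxt) + 1L]] <- list(node = other, ord = f$ord + 1L)
        }
      }
    }
    frontier <- nxt
  }
  if (anyNA(order_out)) {
    stop("segments unreachable from the root: ",
         paste(seg$segment_id[is.na(order_out)], collapse = ", "),
         call. = FALSE)
  }
  network$segments$branch_order <- order_out
  network
}

#' Locate cells on the vascular tree
#'
#' Maps each cell to the branch order of the segment holding its nearest
#' centerline point and flags whether it sits at a vessel junction
#' (within `d_junction` of a node). Cells farther than `max_snap` from
#' every centerline are flagged unmapped and excluded from tallies.
#'
#' @param cells cell table (pericytes and/or labeled microglia).
#' @param network a [vessel_network()] with branch orders assigned.
#' @param d_junction junction attribution radius, micrometres (default 10).
#' @param max_snap maximum snap distance to a centerline, micrometres.
#' @return `cells` with added columns `tree_order`, `at_junction`,
#'   `snap_distance`, `mapped`.
#' @export
locate_on_tree <- function(cells, network, d_junction = 10, max_snap = 20) {
  if (anyNA(network$segments$branch_order)) {
    stop("branch orders unassigned; run assign_branch_orders() first",
         call. = FALSE)
  }
  pieces <- .network_pieces(network)
  near <- .nearest_on_network(.cell_coords(cells), pieces)
  ord <- network$segments$branch_order[
    match(near$segment_id, network$segments$segment_id)]
  cells$tree_order <- ord
  cells$snap_distance <- near$distance
  cells$mapped <- !is.na(near$distance) & near$distance <= max_snap
  nod <- as.matrix(network$nodes[, c("x", "y", "z")])
  dn <- .cross_dist(.cell_coords(cells), nod)
  cells$at_junction <- if (ncol(dn) > 0L)
    apply(dn, 1L, min) <= d_junction else FALSE
  cells$tree_order[!cells$mapped] <- NA_integer_
  cells
}

#' Distribution of cells across branch orders
#'
#' Fractions of mapped cells per branch order, per cell class, optionally
#' restricted to cells at junctions.
#'
#' @param located output of [locate_on_tree()] with a `class_label`
#'   column (e.g. `"pericyte"`, `"CAM"`, `"PEM"`).
#' @param junctions_only tally only cells flagged `at_junction`.
#' @return data.frame of `class_label`, `tree_order`, `n`, `fraction`.
#' @export
order_distribution <- function(located, junctions_only = FALSE) {
  d <- located[located$mapped, , drop = FALSE]
  if (junctions_only) d <- d[d$at_junction, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(class_label = character(0), tree_order = integer(0),
                      n = integer(0), fraction = numeric(0)))
  }
  tab <- as.data.frame(table(class_label = d$class_label,
                             tree_order = d$tree_order),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab$tree_order <- as.integer(tab$tree_order)
  tot <- stats::ave(tab$n, tab$class_label, FUN = sum)
  tab$fraction <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab[tab$n > 0 | TRUE, , drop = FALSE]
}

#' Measure vessel width at a location
#'
#' Interpolated vessel diameter at an arclength position on a segment.
#' Two rules: `"center"` (in-vivo style, one line at the cell center) and
#' `"two_line"` (fixed-tissue style for pericytes/PEM: the mean of the
#' diameters sampled at +/- `side_offset` on either side of the soma).
#'
#' @param network a [vessel_network()].
#' @param segment_id,arclength the location.
#' @param rule `"center"` or `"two_line"`.
#' @param side_offset side-line offset for the two-line rule, micrometres.
#' @return width in micrometres.
#' @export
measure_width_at <- function(network, segment_id, arclength,
                             rule = c("center", "two_line"),
                             side_offset = 4) {
  rule <- match.arg(rule)
  if (rule == "center") {
    diameter_at(network, segment_id, arclength)
  } else {
    mean(c(diameter_at(network, segment_id, arclength - side_offset),
           diameter_at(network, segment_id, arclength + side_offset)))
  }
}

#' Width-measurement rules
#'
#' @param mode `"fixed"` uses the two-line average for pericyte/PEM
#'   widths; `"invivo"` uses a single line at the soma center for every
#'   location type.
#' @param side_offset side-line offset (um) for the two-line rule.
#' @param branch_exclusion_um arclength clearance from any junction node
#'   required of every measurement (measurements are made on segments
#'   away from branchpoints).
#' @param vo_clearance_um radius (um) around a vessel-only point that must
#'   contain no pericyte or microglia soma.
#' @param cam_pericyte_min_dist CAM widths are measured only at CAM
#'   farther than this from every pericyte (um), to avoid including PEM.
#' @param d_vessel_max only vessels below this diameter are measured.
#' @return list of class `width_rules`.
#' @export
width_rules <- function(mode = c("invivo", "fixed"), side_offset = 4,
                        branch_exclusion_um = 10, vo_clearance_um = 10,
                        cam_pericyte_min_dist = 10, d_vessel_max = 10) {
  structure(list(mode = match.arg(mode), side_offset = side_offset,
                 branch_exclusion_um = branch_exclusion_um,
                 vo_clearance_um = vo_clearance_um,
                 cam_pericyte_min_dist = cam_pericyte_min_dist,
                 d_vessel_max = d_vessel_max),
            class = "width_rules")
}

#' Measure capillary width at VO, P, CAM and PEM landmarks
#'
#' Builds the width-measurement table for one scene:
#' * `P` - pericytes without a PEM, width at the pericyte soma (two-line
#'   average in fixed mode);
#' * `PEM` - pericytes with a PEM, same rule;
#' * `CAM` - CAM microglia farther than `cam_pericyte_min_dist` from every
#'   pericyte, width at the soma's projection onto its nearest eligible
#'   vessel;
#' * `VO` - points on capillary segments with no pericyte or microglia
#'   soma within `vo_clearance_um`.
#'
#' All measurements respect the branchpoint exclusion zone and the
#' `d_vessel_max` eligibility cap; locations failing a rule are skipped
#' and counted in the `"n_excluded"` attribute.
#'
#' @param result an `association_result` whose cells carry `on_segment` /
#'   `arclength` anchors (as generator scenes do).
#' @param network the scene's [vessel_network()].
#' @param rules a [width_rules()].
#' @param group_id scene/animal identifier stored on every row.
#' @param vo_per_segment maximum VO points sampled per segment.
#' @param vo_step arclength step (um) of the VO candidate grid.
#' @return data.frame of `WidthMeasurement` rows: `group_id`,
#'   `location_type`, `segment_id`, `arclength`, `width`, `cell_id`.
#' @export
measure_widths <- function(result, network, rules = width_rules(),
                           group_id = 1L, vo_per_segment = 2L,
                           vo_step = 2) {
  peri <- result$pericytes
  mic <- result$microglia
  p_rule <- if (rules$mode == "fixed") "two_line" else "center"
  rows <- list()
  excl <- 0L

  ok_location <- function(sid, s) {
    if (is.na(sid)) return(FALSE)
    if (.dist_to_segment_ends(network, sid, s) < rules$branch_exclusion_um) {
      return(FALSE)
    }
    diameter_at(network, sid, s) < rules$d_vessel_max
  }

  # pericyte-anchored measurements (P and PEM)
  for (i in seq_len(nrow(peri))) {
    sid <- peri$on_segment[i]; s <- peri$arclength[i]
    if (!ok_location(sid, s)) { excl <- excl + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = group_id,
      location_type = if (isTRUE(peri$has_pem[i])) "PEM" else "P",
      segment_id = sid, arclength = s,
      width = measure_width_at(network, sid, s, p_rule, rules$side_offset),
      cell_id = peri$cell_id[i])
  }

  # CAM: only those clear of pericytes; width at soma projection
  cam <- mic[isTRUE_vec(mic$is_cam), , drop = FALSE]
  if (nrow(cam) > 0L) {
    pc <- .cell_coords(peri)
    crit <- association_criteria(d_vessel_max = rules$d_vessel_max)
    near <- nearest_vessel_distance(cam, network, crit)
    for (i in seq_len(nrow(cam))) {
      dmin <- if (nrow(peri) > 0L)
        min(.cross_dist(.cell_coords(cam[i, , drop = FALSE]), pc)) else Inf
      if (dmin <= rules$cam_pericyte_min_dist) { excl <- excl + 1L; next }
      sid <- near$segment_id[i]; s <- near$arclength[i]
      if (!ok_location(sid, s)) { excl <- excl + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = group_id, location_type = "CAM",
        segment_id = sid, arclength = s,
        width = measure_width_at(network, sid, s, "center"),
        cell_id = cam$cell_id[i])
    }
  }

  # VO: centerline points with no soma of any type nearby
  soma <- rbind(.cell_coords(peri), .cell_coords(mic))
  cap_ids <- network$segments$segment_id[
    network$segments$vessel_class == "capillary"]
  for (sid in cap_ids) {
    smax <- max(.segment_arclengths(network, sid))
    grid <- seq(rules$branch_exclusion_um, smax - rules$branch_exclusion_um,
                by = vo_step)
    if (length(grid) == 0L) { excl <- excl + 1L; next }
    good <- logical(length(grid))
    for (k in seq_along(grid)) {
      if (!ok_location(sid, grid[k])) next
      pt <- matrix(.point_at(network, sid, grid[k]), 1L)
      clear <- nrow(soma) == 0L ||
        min(.cross_dist(pt, soma)) > rules$vo_clearance_um
      good[k] <- clear
    }
    gk <- which(good)
    if (length(gk) == 0L) { excl <- excl + 1L; next }
    take <- gk[unique(round(seq(1, length(gk),
                                length.out = min(vo_per_segment,
                                                 length(gk)))))]
    for (k in take) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = group_id, location_type = "VO",
        segment_id = sid, arclength = grid[k],
        width = measure_width_at(network, sid, grid[k], "center"),
        cell_id = NA_integer_)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = integer(0), location_type = character(0),
               segment_id = integer(0), arclength = numeric(0),
               width = numeric(0), cell_id = integer(0))
  attr(out, "n_excluded") <- excl
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Width contrasts by location type
#'
#' Per-group (animal/scene) mean widths by location type, computed only
#' for groups meeting the minimum-measurement threshold in every type
#' present, with percent differences versus the vessel-only (VO)
#' baseline. The omnibus matched-samples comparison is delegated to
#' [stats::friedman.test()] when at least three groups have complete
#' VO/P/CAM/PEM rows.
#'
#' @param measurements data.frame from [measure_widths()], possibly
#'   row-bound over scenes.
#' @param min_measurements minimum measurements per group and type
#'   (default 4).
#' @return list with `per_group` (group x type means), `means` (pooled
#'   per-type mean of group means), `pct_diff_vs_vo`, `friedman_p`,
#'   `groups_excluded`.
#' @export
width_contrast_table <- function(measurements, min_measurements = 4L) {
  types <- c("VO", "P", "CAM", "PEM")
  groups <- unique(measurements$group_id)
  per_group <- list()
  excluded <- character(0)
  for (g in groups) {
    mg <- measurements[measurements$group_id == g, , drop = FALSE]
    counts <- table(factor(mg$location_type, levels = types))
    present <- names(counts)[counts > 0]
    if (any(counts[present] < min_measurements)) {
      excluded <- c(excluded, as.character(g))
      next
    }
    means <- tapply(mg$width, factor(mg$location_type, levels = types), mean)
    per_group[[length(per_group) + 1L]] <-
      data.frame(group_id = g, t(as.numeric(means))) |>
      stats::setNames(c("group_id", types))
  }
  per_group <- if (length(per_group)) do.call(rbind, per_group) else
    stats::setNames(data.frame(matrix(numeric(0), ncol = 5L)),
                    c("group_id", types))
  means <- colMeans(per_group[, types, drop = FALSE], na.rm = TRUE)
  pct <- 100 * (means / means[["VO"]] - 1)
  complete <- per_group[stats::complete.cases(per_group[, types]), types,
                        drop = FALSE]
  friedman_p <- if (nrow(complete) >= 3L) {
    stats::friedman.test(as.matrix(complete))$p.value
  } else NA_real_
  list(per_group = per_group, means = means, pct_diff_vs_vo = pct,
       friedman_p = friedman_p, groups_excluded = excluded)
}

#' Paired vessel widths where a pericyte gained or lost a PEM
#'
#' For every pericyte whose PEM status differs between the first and last
#' imaging day of a time series, measures the vessel width at the
#' pericyte on both days (from the day-specific network snapshots) and
#' summarises the percent width change separately for gain and loss
#' events. Pericytes whose width is unmeasurable on either day (e.g.
#' inside the branchpoint exclusion zone) are dropped and counted.
#'
#' @param series a `timeseries_scene` (see [simulate_timepoints()]).
#' @param rules a [width_rules()]; in-vivo single-line rule by default.
#' @param criteria an [association_criteria()] for the per-day PEM labels.
#' @param min_events minimum events per type for a summary mean
#'   (default 2).
#' @return list with `events` (paired widths per pericyte) and `summary`
#'   (per type: n, mean percent change).
#' @export
width_change_on_gain_loss <- function(series, rules = width_rules("invivo"),
                                      criteria = association_criteria(
                                        use_nucleus_center = FALSE),
                                      min_events = 2L) {
  days <- series$days
  d0 <- days[1]; d1 <- days[length(days)]
  lab0 <- classify_cells(series$cells_by_day[[as.character(d0)]],
                         series$networks_by_day[[as.character(d0)]], criteria)
  lab1 <- classify_cells(series$cells_by_day[[as.character(d1)]],
                         series$networks_by_day[[as.character(d1)]], criteria)
  p0 <- lab0$pericytes; p1 <- lab1$pericytes
  common <- intersect(p0$cell_id, p1$cell_id)
  rows <- list(); dropped <- 0L
  for (id in common) {
    a <- p0[p0$cell_id == id, ]; b <- p1[p1$cell_id == id, ]
    if (isTRUE(a$has_pem) == isTRUE(b$has_pem)) next
    type <- if (isTRUE(b$has_pem)) "gain" else "loss"
    sid <- a$on_segment; s <- a$arclength
    if (is.na(sid) ||
        .dist_to_segment_ends(series$networks_by_day[[as.character(d0)]],
                              sid, s) < rules$branch_exclusion_um) {
      dropped <- dropped + 1L
      next
    }
    rule <- if (rules$mode == "fixed") "two_line" else "center"
    w0 <- measure_width_at(series$networks_by_day[[as.character(d0)]],
                           sid, s, rule, rules$side_offset)
    w1 <- measure_width_at(series$networks_by_day[[as.character(d1)]],
                           sid, s, rule, rules$side_offset)
    rows[[length(rows) + 1L]] <- data.frame(
      pericyte_id = id, type = type, day_before = d0, day_after = d1,
      width_before = w0, width_after = w1,
      pct_change = 100 * (w1 / w0 - 1))
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pericyte_id = integer(0), type = character(0),
               day_before = integer(0), day_after = integer(0),
               width_before = numeric(0), width_after = numeric(0),
               pct_change = numeric(0))
  summ <- lapply(c(gain = "gain", loss = "loss"), function(tp) {
    e <- events[events$type == tp, , drop = FALSE]
    list(n = nrow(e),
         mean_pct_change = if (nrow(e) >= min_events)
           mean(e$pct_change) else NA_real_)
  })
  list(events = events, summary = summ, n_dropped = dropped)
}
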