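# Cross-day cell matching and PEM retention / gain / loss analysis.

#' Match cells across two imaging days
#'
#' Greedy mutual-nearest-neighbour matching within `max_displacement`:
#' candidate pairs are pairs of same-type cells that are each other's
#' nearest neighbour, accepted in order of increasing distance (ties
#' break to the lower cell id); each cell links at most once. In the
#' regime where displacements are small relative to inter-cell spacing
#' this equals the globally optimal assignment. Unmatched cells are
#' flagged appeared/disappeared.
#'
#' @param table_a,table_b cell tables for the two days (single cell type,
#'   or pre-filtered identically).
#' @param max_displacement maximum link length, micrometres (default 15).
#' @return data.frame of links (`id_a`, `id_b`, `distance`) with
#'   attributes `"disappeared"` (ids in `table_a` with no link) and
#'   `"appeared"` (ids in `table_b`).
#' @export
match_across_days <- function(table_a, table_b, max_displacement = 15) {
  links <- data.frame(id_a = integer(0), id_b = integer(0),
                      distance = numeric(0))
  for (tp in intersect(unique(table_a$cell_type),
                       unique(table_b$cell_type))) {
    a <- table_a[table_a$cell_type == tp, , drop = FALSE]
    b <- table_b[table_b$cell_type == tp, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    d <- .cross_dist(.cell_coords(a), .cell_coords(b))
    repeat {
      if (all(!is.finite(d)) || min(d) > max_displacement) break
      # mutual nearest neighbours among remaining cells
      ra <- apply(d, 1L, which.min)
      rb <- apply(d, 2L, which.min)
      mutual <- which(rb[ra] == seq_len(nrow(d)) & is.finite(
        d[cbind(seq_len(nrow(d)), ra)]))
      mutual <- mutual[d[cbind(mutual, ra[mutual])] <= max_displacement]
      if (length(mutual) == 0L) break
      ord <- order(d[cbind(mutual, ra[mutual])], a$cell_id[mutual])
      used_a <- logical(nrow(d)); used_b <- logical(ncol(d))
      for (i in mutual[ord]) {
        j <- ra[i]
        if (used_a[i] || used_b[j]) next
        links <- rbind(links, data.frame(id_a = a$cell_id[i],
                                         id_b = b$cell_id[j],
                                         distance = d[i, j]))
        used_a[i] <- TRUE; used_b[j] <- TRUE
      }
      d[used_a, ] <- Inf
      d[, used_b] <- Inf
      if (!any(is.finite(d))) break
    }
  }
  attr(links, "disappeared") <- setdiff(table_a$cell_id, links$id_a)
  attr(links, "appeared") <- setdiff(table_b$cell_id, links$id_b)
  links
}

# Links for every consecutive day pair of a series.
.series_links <- function(series, max_displacement = 15) {
  days <- series$days
  out <- list()
  for (v in seq_len(length(days) - 1L)) {
    out[[paste(days[v], days[v + 1L], sep = "->")]] <-
      match_across_days(series$cells_by_day[[as.character(days[v])]],
                        series$cells_by_day[[as.character(days[v + 1L])]],
                        max_displacement)
  }
  out
}

# Follow one cell id forward through chained links; NA once lost.
.chain_ids <- function(ids, links_list) {
  out <- matrix(NA_integer_, length(ids), length(links_list) + 1L)
  out[, 1L] <- ids
  for (v in seq_along(links_list)) {
    lk <- links_list[[v]]
    out[, v + 1L] <- lk$id_b[match(out[, v], lk$id_a)]
  }
  out
}

#' PEM retention across imaging days
#'
#' Fraction of day-0 PEM whose tracked microglia remains within the
#' association radius of a pericyte on each follow-up day. The default
#' definition accepts adjacency to any pericyte; the strict same-partner
#' variant (adjacency to the tracked day-0 partner) is reported
#' alongside. A day-0 PEM whose microglia cannot be matched on a later
#' day counts as not retained.
#'
#' @param series a `timeseries_scene`.
#' @param criteria an [association_criteria()] (in-vivo soma centers by
#'   default).
#' @param max_displacement matching tolerance across consecutive days,
#'   micrometres.
#' @return data.frame with one row per follow-up day: `day`, `n_day0`,
#'   `n_retained`, `retained_frac`, `n_same_partner`,
#'   `same_partner_frac`.
#' @export
pem_retention <- function(series,
                          criteria = association_criteria(
                            use_nucleus_center = FALSE),
                          max_displacement = 15) {
  days <- series$days
  lab0 <- classify_cells(series$cells_by_day[[as.character(days[1])]],
                         series$networks_by_day[[as.character(days[1])]],
                         criteria)
  m0 <- lab0$microglia
  pem0 <- m0[m0$is_pem, , drop = FALSE]
  n0 <- nrow(pem0)
  links <- .series_links(series, max_displacement)
  mic_chain <- .chain_ids(pem0$cell_id, links)
  peri_chain <- .chain_ids(pem0$nearest_pericyte_id, links)

  rows <- list()
  for (v in seq_len(length(days) - 1L)) {
    day <- days[v + 1L]
    cells_d <- series$cells_by_day[[as.character(day)]]
    lab <- classify_cells(cells_d,
                          series$networks_by_day[[as.character(day)]],
                          criteria)
    micd <- lab$microglia
    tracked <- mic_chain[, v + 1L]
    present <- !is.na(tracked)
    idx <- match(tracked, micd$cell_id)
    retained <- present & !is.na(idx) & micd$is_pem[idx]
    retained[is.na(retained)] <- FALSE
    # same-partner: tracked microglia within r of its tracked partner
    partner_d <- peri_chain[, v + 1L]
    same <- logical(n0)
    perid <- lab$pericytes
    for (k in seq_len(n0)) {
      if (!retained[k] || is.na(partner_d[k])) next
      mrow <- micd[idx[k], , drop = FALSE]
      prow <- perid[perid$cell_id == partner_d[k], , drop = FALSE]
      if (nrow(prow) == 0L) next
      dd <- .cross_dist(.cell_coords(mrow, criteria$use_nucleus_center),
                        .cell_coords(prow, criteria$use_nucleus_center))
      same[k] <- .closer(dd[1, 1], criteria$r_assoc,
                         criteria$strict_inequality)
    }
    rows[[v]] <- data.frame(day = day, n_day0 = n0,
                            n_retained = sum(retained),
                            retained_frac = if (n0 > 0) mean(retained)
                            else NA_real_,
                            n_same_partner = sum(same),
                            same_partner_frac = if (n0 > 0) mean(same)
                            else NA_real_)
  }
  do.call(rbind, rows)
}

#' Percentage of pericytes with a PEM per imaging day
#'
#' @param series a `timeseries_scene`.
#' @param criteria an [association_criteria()].
#' @return data.frame of `day`, `n_pericytes`, `n_with_pem`, `pct`
#'   (missing when a day has no pericytes).
#' @export
pem_proportion_by_day <- function(series,
                                  criteria = association_criteria(
                                    use_nucleus_center = FALSE)) {
  rows <- lapply(series$days, function(day) {
    lab <- classify_cells(series$cells_by_day[[as.character(day)]],
                          series$networks_by_day[[as.character(day)]],
                          criteria)
    s <- lab$summary
    data.frame(day = day, n_pericytes = s$n_pericytes,
               n_with_pem = s$n_pericytes_with_pem,
               pct = s$pct_pericytes_with_pem)
  })
  do.call(rbind, rows)
}

#' Repeated-measures comparison of PEM proportions across days
#'
#' Tests for a day effect on the percentage of pericytes with a PEM over
#' scenes, delegated to a repeated-measures ANOVA
#' (`aov(pct ~ day + Error(scene))`).
#'
#' @param per_scene data.frame with columns `scene`, `day`, `pct`.
#' @return p-value for the day effect.
#' @export
compare_pem_proportions <- function(per_scene) {
  per_scene$day <- factor(per_scene$day)
  per_scene$scene <- factor(per_scene$scene)
  fit <- stats::aov(pct ~ day + Error(scene), data = per_scene)
  summary(fit)[["Error: Within"]][[1]]["day", "Pr(>F)"]
}

#' Per-pericyte PEM gain/loss event table
#'
#' Tracks every pericyte across the series, derives its has-PEM status
#' per day from the association labels, and classifies the transition
#' sequence: `stable` (status never changes), `gained`, `lost`, or
#' `transient` (status changes more than once, e.g. lost then regained;
#' every individual transition is still logged as an event). Pericytes
#' that cannot be matched across all days are excluded and reported.
#'
#' @param series a `timeseries_scene`.
#' @param criteria an [association_criteria()].
#' @param max_displacement matching tolerance, micrometres.
#' @return list with `events` (`pericyte_id`, `day_from`, `day_to`,
#'   `type`), `per_pericyte` (`pericyte_id`, classification, has-PEM
#'   sequence) and `n_unmatched`.
#' @export
gain_loss_events <- function(series,
                             criteria = association_criteria(
                               use_nucleus_center = FALSE),
                             max_displacement = 15) {
  days <- series$days
  links <- .series_links(series, max_displacement)
  p0 <- series$cells_by_day[[as.character(days[1])]]
  p0 <- p0[p0$cell_type == "pericyte", , drop = FALSE]
  chain <- .chain_ids(p0$cell_id, links)
  ok <- stats::complete.cases(chain)

  status <- matrix(NA, nrow(p0), length(days))
  for (d in seq_along(days)) {
    lab <- classify_cells(series$cells_by_day[[as.character(days[d])]],
                          series$networks_by_day[[as.character(days[d])]],
                          criteria)
    perid <- lab$pericytes
    status[, d] <- perid$has_pem[match(chain[, d], perid$cell_id)]
  }

  events <- list(); classif <- character(nrow(p0))
  for (i in seq_len(nrow(p0))) {
    if (!ok[i]) { classif[i] <- "unmatched"; next }
    st <- status[i, ]
    ch <- which(diff(st) != 0)
    for (v in ch) {
      events[[length(events) + 1L]] <- data.frame(
        pericyte_id = p0$cell_id[i], day_from = days[v],
        day_to = days[v + 1L],
        type = if (st[v + 1L]) "gained" else "lost")
    }
    classif[i] <- if (length(ch) == 0L) "stable" else
      if (length(ch) > 1L) "transient" else
        if (st[length(st)]) "gained" else "lost"
  }
  list(events = if (length(events)) do.call(rbind, events) else
    data.frame(pericyte_id = integer(0), day_from = integer(0),
               day_to = integer(0), type = character(0)),
    per_pericyte = data.frame(pericyte_id = p0$cell_id,
                              classification = classif,
                              stats::setNames(as.data.frame(status),
                                              paste0("day", days))),
    n_unmatched = sum(!ok))
}
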