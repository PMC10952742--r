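# Longitudinal simulation: PEM retention, gain and loss over imaging days.

#' Simulate a longitudinal imaging series from a day-0 scene
#'
#' Between consecutive imaging days each existing pericyte-microglia
#' adjacency persists with probability `config$retention_per_visit`
#' (retained microglia re-settle within the attraction radius of their
#' pericyte; lost microglia are displaced by a random walk far enough to
#' be unambiguous at the association criterion). Pericytes currently
#' without a PEM gain one with probability `config$gain_rate`, recruiting
#' a free microglia that was not part of the day-0 PEM population so that
#' gained associations are genuinely new. All other microglia jitter
#' isotropically (SD `config$jitter_sd_stable`). The local vessel
#' diameter at a pericyte is multiplied by `width_profile$gain` when it
#' gains a PEM and by `width_profile$loss` when it loses one, and every
#' event is logged with its day stamp.
#'
#' @param scene a 3D `synthetic_scene` (day 0).
#' @param days strictly increasing integer days including 0
#'   (default `c(0, 4, 7, 28)`).
#' @param config a [generator_config()]; `retention_per_visit` may be a
#'   scalar or one value per visit.
#' @param criteria association criteria defining adjacency (in-vivo soma
#'   centers by default).
#' @param seed optional integer seed.
#' @return A `timeseries_scene`: list with `days`, `cells_by_day`,
#'   `networks_by_day`, `events` (truth log: `day`, `type`,
#'   `pericyte_id`, `microglia_id`) and `day0_pem` (data.frame of day-0
#'   PEM microglia and their partner pericytes).
#' @export
simulate_timepoints <- function(scene, days = c(0L, 4L, 7L, 28L),
                                config = scene$config,
                                criteria = association_criteria(
                                  use_nucleus_center = FALSE),
                                seed = NULL) {
  stopifnot(scene$dims == 3L)
  days <- as.integer(days)
  if (days[1] != 0L || any(diff(days) <= 0)) {
    stop("days must be strictly increasing and include day 0",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  ext <- config$roi_extent
  wp <- config$width_profile
  n_visits <- length(days) - 1L
  retain_p <- rep(config$retention_per_visit, length.out = n_visits)

  cells <- scene$cells
  net <- scene$network
  lab <- classify_cells(cells, net, criteria)
  mic <- lab$microglia
  peri <- lab$pericytes
  # current adjacency state: partner pericyte per PEM microglia
  partner <- stats::setNames(mic$nearest_pericyte_id, mic$cell_id)
  partner[!mic$is_pem] <- NA_integer_
  day0_pem <- data.frame(microglia_id = mic$cell_id[mic$is_pem],
                         pericyte_id = partner[as.character(
                           mic$cell_id[mic$is_pem])])

  cells_by_day <- list(); networks_by_day <- list()
  cells$day <- days[1]
  cells_by_day[[as.character(days[1])]] <- cells
  networks_by_day[[as.character(days[1])]] <- net
  events <- list()

  peri_tab <- cells[cells$cell_type == "pericyte", , drop = FALSE]
  peri_xyz <- .cell_coords(peri_tab)
  mic_ids <- cells$cell_id[cells$cell_type == "microglia"]

  displace_clear <- function(p, min_clear) {
    # push a lost microglia beyond the association radius of every pericyte
    for (attempt in seq_len(50L)) {
      step <- stats::rnorm(3, 0, config$jitter_sd_loss)
      cand <- .clamp(p + step, 0, ext)
      if (nrow(peri_xyz) == 0L ||
          min(.cross_dist(matrix(cand, 1L), peri_xyz)) > min_clear) {
        return(cand)
      }
    }
    # deterministic fallback: walk away from the nearest pericyte
    j <- which.min(.cross_dist(matrix(p, 1L), peri_xyz))
    dirv <- p - peri_xyz[j, ]
    if (sum(dirv^2) < 1e-9) dirv <- c(1, 0, 0)
    .clamp(p + dirv / sqrt(sum(dirv^2)) * (min_clear + 5), 0, ext)
  }

  for (v in seq_len(n_visits)) {
    day <- days[v + 1L]
    mic_rows <- which(cells$cell_type == "microglia")
    is_pem_now <- !is.na(partner[as.character(cells$cell_id[mic_rows])])

    for (k in seq_along(mic_rows)) {
      i <- mic_rows[k]
      id <- as.character(cells$cell_id[i])
      p <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
      if (is_pem_now[k]) {
        if (stats::runif(1) < retain_p[v]) {
          # retained: jitter in place but stay inside the attraction
          # ball of the partner (cells drift, they do not teleport)
          anchor <- peri_xyz[match(partner[id], peri_tab$cell_id), ]
          newp <- NULL
          for (attempt in seq_len(20L)) {
            cand <- .clamp(p + stats::rnorm(3, 0, config$jitter_sd_stable),
                           0, ext)
            if (sqrt(sum((cand - anchor)^2)) < config$attraction_radius) {
              newp <- cand
              break
            }
          }
          if (is.null(newp)) {
            newp <- .clamp(anchor + drop(
              .runif_ball(1, config$attraction_radius)), 0, ext)
          }
        } else {
          # clearance margin beyond the radius keeps losses unambiguous
          # even as the cell keeps jittering on later visits
          newp <- displace_clear(p, criteria$r_assoc +
                                   2 * config$jitter_sd_stable + 2)
          events[[length(events) + 1L]] <- data.frame(
            day = day, type = "loss", pericyte_id = unname(partner[id]),
            microglia_id = as.integer(id))
          pk <- match(partner[id], peri_tab$cell_id)
          net <- .scale_window(net, peri_tab$on_segment[pk],
                               peri_tab$arclength[pk], wp$window_um,
                               wp$loss)
          partner[id] <- NA_integer_
        }
      } else {
        newp <- .clamp(p + stats::rnorm(3, 0, config$jitter_sd_stable),
                       0, ext)
      }
      cells$x_um[i] <- newp[1]; cells$y_um[i] <- newp[2]
      cells$z_um[i] <- newp[3]
      cells$soma_x[i] <- newp[1]; cells$soma_y[i] <- newp[2]
      cells$soma_z[i] <- newp[3]
    }

    # gains at pericytes currently without a PEM
    have_pem <- unique(stats::na.omit(partner))
    free_peri <- peri_tab$cell_id[!(peri_tab$cell_id %in% have_pem)]
    for (pid in free_peri) {
      if (stats::runif(1) >= config$gain_rate) next
      anchor <- peri_xyz[match(pid, peri_tab$cell_id), ]
      candidates <- setdiff(mic_ids[is.na(partner[as.character(mic_ids)])],
                            day0_pem$microglia_id)
      if (length(candidates) == 0L) next
      crow <- match(candidates, cells$cell_id)
      dmat <- .cross_dist(matrix(anchor, 1L),
                          as.matrix(cells[crow, c("x_um", "y_um", "z_um")]))
      mid <- candidates[which.min(dmat)]
      i <- match(mid, cells$cell_id)
      newp <- .clamp(anchor + drop(.runif_ball(1, config$attraction_radius)),
                     0, ext)
      cells$x_um[i] <- newp[1]; cells$y_um[i] <- newp[2]
      cells$z_um[i] <- newp[3]
      cells$soma_x[i] <- newp[1]; cells$soma_y[i] <- newp[2]
      cells$soma_z[i] <- newp[3]
      partner[as.character(mid)] <- pid
      events[[length(events) + 1L]] <- data.frame(
        day = day, type = "gain", pericyte_id = pid, microglia_id = mid)
      pk <- match(pid, peri_tab$cell_id)
      net <- .scale_window(net, peri_tab$on_segment[pk],
                           peri_tab$arclength[pk], wp$window_um, wp$gain)
    }

    cells$day <- day
    cells_by_day[[as.character(day)]] <- cells
    networks_by_day[[as.character(day)]] <- net
  }

  structure(list(days = days, cells_by_day = cells_by_day,
                 networks_by_day = networks_by_day,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(day = integer(0), type = character(0),
                              pericyte_id = integer(0),
                              microglia_id = integer(0)),
                 day0_pem = day0_pem, config = config),
            class = "timeseries_scene")
}

#' @export
print.timeseries_scene <- function(x, ...) {
  cat("<timeseries_scene> days ", paste(x$days, collapse = ", "),
      "; ", nrow(x$day0_pem), " day-0 PEM; ",
      nrow(x$events), " gain/loss events\n", sep = "")
  invisible(x)
}
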