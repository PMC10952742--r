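# Synthetic microvascular tree growth.

#' Generate a synthetic microvascular tree
#'
#' Grows a connected, acyclic vessel network inside the configured ROI by
#' recursive bifurcation: a single order-0 penetrating arteriole feeds a
#' main path of capillaries whose branch order increments at every
#' junction (orders 1-7), terminating on an order-8 ascending venule; side
#' subtrees of capillaries sprout at junctions with probability
#' `config$branch_prob`. Per-point diameters come from the configured
#' baseline per order (capillary orders below 10 um by default) with mild
#' multiplicative noise, and every centerline point lies inside the ROI
#' (growth reflects off the ROI walls).
#'
#' @param config a [generator_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return A [vessel_network()] with branch orders and vessel classes
#'   assigned.
#' @export
generate_vessel_network <- function(config, seed = NULL) {
  validate_generator_config(config)
  .maybe_seed(config, seed)
  ext <- config$roi_extent
  len_rng <- config$segment_length_range
  if (max(ext[1:2]) < len_rng[1] || min(ext[1:2]) < 15) {
    stop(structure(class = c("pemscope_infeasible_geometry", "error",
                             "condition"),
                   list(message = paste0(
                     "ROI (", paste(ext, collapse = " x "),
                     " um) is too small to contain an arteriole-to-venule ",
                     "path with segment lengths >= ", len_rng[1], " um"),
                     call = NULL)))
  }
  wp <- config$width_profile
  spacing <- config$point_spacing
  zscale <- min(1, ext[3] / max(ext[1:2]))

  st <- new.env(parent = emptyenv())
  st$nodes <- list(); st$segments <- list(); st$points <- list()
  st$next_node <- 1L; st$next_seg <- 1L; st$n_seg <- 0L

  add_node <- function(xyz) {
    id <- st$next_node; st$next_node <- id + 1L
    st$nodes[[id]] <- c(node_id = id, x = xyz[1], y = xyz[2], z = xyz[3])
    id
  }
  norm1 <- function(v) v / sqrt(sum(v^2))
  baseline_for <- function(order) wp$baseline[min(order, 8L) + 1L]

  grow_segment <- function(from_node, p0, dir, order, vclass) {
    L <- stats::runif(1, len_rng[1], len_rng[2])
    n_steps <- max(2L, ceiling(L / spacing))
    pts <- matrix(NA_real_, n_steps + 1L, 3L)
    pts[1L, ] <- p0
    p <- p0; d <- dir
    for (k in seq_len(n_steps)) {
      d <- norm1(d + stats::rnorm(3, 0, 0.12) * c(1, 1, zscale))
      cand <- p + d * spacing
      for (ax in 1:3) {
        if (cand[ax] < 0 || cand[ax] > ext[ax]) {
          d[ax] <- -d[ax]
          cand <- p + d * spacing
        }
      }
      cand <- .clamp(cand, 0, ext)
      p <- cand
      pts[k + 1L, ] <- p
    }
    base <- baseline_for(order)
    diam <- base * (1 + stats::rnorm(n_steps + 1L, 0, wp$noise_sd))
    diam <- pmax(diam, 0.5 * base)
    to_node <- add_node(pts[n_steps + 1L, ])
    sid <- st$next_seg; st$next_seg <- sid + 1L
    st$segments[[sid]] <- data.frame(segment_id = sid, from_node = from_node,
                                     to_node = to_node, branch_order = order,
                                     vessel_class = vclass)
    st$points[[sid]] <- data.frame(segment_id = sid, x = pts[, 1],
                                   y = pts[, 2], z = pts[, 3],
                                   diameter = diam)
    st$n_seg <- st$n_seg + 1L
    list(node = to_node, end = pts[n_steps + 1L, ], dir = d)
  }

  # main arteriole -> capillary chain -> venule; side-branch tips open
  # at every main-path junction
  p0 <- c(min(2, ext[1] / 4),
          stats::runif(1, 0.25, 0.75) * ext[2],
          stats::runif(1, 0.3, 0.7) * ext[3])
  root <- add_node(p0)
  dir <- norm1(c(1, stats::runif(1, -0.3, 0.3), 0.1 * zscale))
  node <- root; pos <- p0
  tips <- list()
  for (order in 0:8) {
    vclass <- if (order == 0L) "arteriole" else
      if (order == 8L) "venule" else "capillary"
    tip <- grow_segment(node, pos, dir, order, vclass)
    if (order < 7L) {
      tips[[length(tips) + 1L]] <- list(node = tip$node, end = tip$end,
                                        dir = tip$dir, order = order + 1L)
    }
    node <- tip$node; pos <- tip$end
    dir <- norm1(tip$dir + c(0.4, 0, 0))  # keep drifting across the ROI
  }

  # budgeted bifurcation: open tips sprout daughter capillaries until the
  # segment budget is spent; each daughter tip stays open for further
  # branching with probability branch_prob while below order 7
  while (st$n_seg < config$n_segments && length(tips) > 0L) {
    i <- sample.int(length(tips), 1L)
    tp <- tips[[i]]
    tips[[i]] <- NULL
    for (sgn in c(-1, 1)) {
      if (st$n_seg >= config$n_segments) break
      ddir <- norm1(tp$dir + sgn * stats::rnorm(3, 0.4, 0.2) *
                      c(1, 1, zscale) * sample(c(-1, 1), 3, TRUE))
      new_tip <- grow_segment(tp$node, tp$end, ddir, tp$order, "capillary")
      if (tp$order < 7L && stats::runif(1) < config$branch_prob) {
        tips[[length(tips) + 1L]] <- list(node = new_tip$node,
                                          end = new_tip$end,
                                          dir = new_tip$dir,
                                          order = tp$order + 1L)
      }
    }
  }

  vessel_network(nodes = as.data.frame(do.call(rbind, st$nodes)),
                 segments = do.call(rbind, st$segments),
                 points = do.call(rbind, st$points),
                 validate = FALSE)
}
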