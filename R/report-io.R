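# Readers/writers for cell tables, networks (JSON/SWC) and stacks, a run
# manifest, and the end-to-end pipeline driver.

.cell_column_aliases <- list(
  cell_id = c("cell_id", "id", "Object ID", "object_id"),
  cell_type = c("cell_type", "type", "class", "Class", "Classification"),
  x_um = c("x_um", "x", "X", "Centroid X", "Centroid X um"),
  y_um = c("y_um", "y", "Y", "Centroid Y", "Centroid Y um"),
  z_um = c("z_um", "z", "Z", "Centroid Z", "Centroid Z um"),
  day = c("day", "Day", "timepoint"),
  has_nucleus = c("has_nucleus", "nucleus", "Nucleus"))

#' Read a cell-coordinate table
#'
#' Reads a CSV/TSV export (one row per cell) into the canonical cell
#' table. Column names are resolved through a built-in alias map
#' compatible with common cell-detection exports, extendable via
#' `column_map`. Rows with unparseable coordinates are rejected with
#' row-numbered diagnostics; a coordinate scale that looks implausible
#' for micrometres (all magnitudes below 10, suggesting millimetres)
#' triggers a warning but is never silently converted.
#'
#' @param path file path (`.csv` or `.tsv`; delimiter inferred).
#' @param column_map optional named list mapping canonical names
#'   (`cell_id`, `cell_type`, `x_um`, ...) to the file's column names.
#' @return canonical cell data.frame.
#' @export
read_cells <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  aliases <- .cell_column_aliases
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      aliases[[nm]] <- c(column_map[[nm]], aliases[[nm]])
    }
  }
  resolve <- function(canon) {
    hit <- intersect(aliases[[canon]], names(raw))
    if (length(hit) > 0L) hit[1] else NA_character_
  }
  mandatory <- c("cell_type", "x_um", "y_um")
  for (m in mandatory) {
    if (is.na(resolve(m))) {
      stop("missing mandatory column '", m, "' (accepted names: ",
           paste(aliases[[m]], collapse = ", "), ")", call. = FALSE)
    }
  }
  n <- nrow(raw)
  out <- .empty_cells()[rep(1L, 0L), ]
  get <- function(canon, default) {
    col <- resolve(canon)
    if (is.na(col)) default else raw[[col]]
  }
  out <- data.frame(
    cell_id = as.integer(get("cell_id", seq_len(n))),
    cell_type = tolower(as.character(get("cell_type", NA))),
    x_um = suppressWarnings(as.numeric(get("x_um", NA))),
    y_um = suppressWarnings(as.numeric(get("y_um", NA))),
    z_um = suppressWarnings(as.numeric(get("z_um", rep(NA_real_, n)))),
    day = as.integer(get("day", rep(0L, n))),
    has_nucleus = as.logical(get("has_nucleus", rep(TRUE, n))))
  out$soma_x <- out$x_um; out$soma_y <- out$y_um; out$soma_z <- out$z_um
  out$truth_class <- NA_character_; out$partner_id <- NA_integer_
  out$on_segment <- NA_integer_; out$arclength <- NA_real_
  out$host_diameter <- NA_real_
  bad <- which(!is.finite(out$x_um) | !is.finite(out$y_um))
  if (length(bad) > 0L) {
    warning("dropping ", length(bad), " malformed row(s): ",
            paste(utils::head(bad, 10), collapse = ", "))
    out <- out[-bad, , drop = FALSE]
  }
  if (nrow(out) > 0L &&
      max(abs(c(out$x_um, out$y_um)), na.rm = TRUE) < 10) {
    warning("coordinate magnitudes are all below 10; units may be mm, ",
            "not um - no conversion applied")
  }
  known <- out$cell_type %in% c("microglia", "pericyte")
  if (any(!known)) {
    warning("dropping ", sum(!known), " row(s) with cell_type outside ",
            "{microglia, pericyte}")
    out <- out[known, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a cell table to CSV
#'
#' @param cells canonical cell data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a vessel network as JSON
#'
#' Lossless round-trip of nodes, segments and per-point
#' `[x, y, z, diameter]` lists.
#'
#' @param network a [vessel_network()].
#' @param path file path.
#' @return [read_network_json()] returns a validated `vessel_network`;
#'   the writer returns `path` invisibly.
#' @export
write_network_json <- function(network, path) {
  segs <- lapply(seq_len(nrow(network$segments)), function(i) {
    sid <- network$segments$segment_id[i]
    sp <- network$points[network$points$segment_id == sid, , drop = FALSE]
    list(segment_id = sid,
         from_node = network$segments$from_node[i],
         to_node = network$segments$to_node[i],
         branch_order = network$segments$branch_order[i],
         vessel_class = network$segments$vessel_class[i],
         points = unname(as.matrix(sp[, c("x", "y", "z", "diameter")])))
  })
  jsonlite::write_json(list(nodes = network$nodes, segments = segs),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(j$nodes)
  segs <- j$segments
  if (is.data.frame(segs)) {  # homogeneous records simplify to a frame
    seg_df <- segs[, c("segment_id", "from_node", "to_node",
                       "branch_order", "vessel_class")]
    pts_list <- segs$points
    sids <- segs$segment_id
  } else {
    seg_df <- data.frame(
      segment_id = vapply(segs, `[[`, numeric(1), "segment_id"),
      from_node = vapply(segs, `[[`, numeric(1), "from_node"),
      to_node = vapply(segs, `[[`, numeric(1), "to_node"),
      branch_order = vapply(segs, function(s)
        if (is.null(s$branch_order)) NA_real_ else s$branch_order,
        numeric(1)),
      vessel_class = vapply(segs, `[[`, character(1), "vessel_class"))
    pts_list <- lapply(segs, `[[`, "points")
    sids <- seg_df$segment_id
  }
  pts <- do.call(rbind, lapply(seq_along(pts_list), function(k) {
    m <- pts_list[[k]]
    data.frame(segment_id = sids[k], x = m[, 1], y = m[, 2],
               z = m[, 3], diameter = m[, 4])
  }))
  vessel_network(nodes, seg_df, pts, validate = TRUE)
}

# SWC sample types used to encode the vessel class.
.swc_type <- c(arteriole = 5L, capillary = 6L, venule = 7L)

#' Write / read a vessel network as SWC
#'
#' Maps each segment to a chain of SWC samples (`id type x y z radius
#' parent`); the diameter is halved into the SWC radius column and the
#' custom sample types 5/6/7 encode arteriole/capillary/venule. Segment
#' chains are parented on the sample nearest their `from_node`, so
#' re-import preserves coordinates and radii but merges the polylines
#' into one tree rooted at the first sample; branch orders are not
#' stored in SWC and re-imported networks need [assign_branch_orders()].
#'
#' @param network a [vessel_network()].
#' @param path file path.
#' @return the reader returns a `vessel_network`; the writer `path`,
#'   invisibly.
#' @export
write_network_swc <- function(network, path) {
  lines <- c("# pemscope vessel network export",
             "# columns: id type x y z radius parent",
             "# types: 5 arteriole, 6 capillary, 7 venule")
  idc <- 0L
  node_sample <- list()  # first sample id written at each node
  for (i in seq_len(nrow(network$segments))) {
    sid <- network$segments$segment_id[i]
    sp <- network$points[network$points$segment_id == sid, , drop = FALSE]
    tp <- .swc_type[[network$segments$vessel_class[i]]]
    from <- as.character(network$segments$from_node[i])
    parent <- if (!is.null(node_sample[[from]])) node_sample[[from]] else -1L
    for (k in seq_len(nrow(sp))) {
      idc <- idc + 1L
      lines <- c(lines, sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                                idc, tp, sp$x[k], sp$y[k], sp$z[k],
                                sp$diameter[k] / 2, parent))
      parent <- idc
    }
    if (is.null(node_sample[[from]])) node_sample[[from]] <- idc - nrow(sp) + 1L
    to <- as.character(network$segments$to_node[i])
    if (is.null(node_sample[[to]])) node_sample[[to]] <- idc
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network_swc
#' @export
read_network_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  cls <- names(.swc_type)[match(raw$type, .swc_type)]
  cls[is.na(cls)] <- "capillary"
  # split into chains at parent discontinuities or type changes (new
  # segment when the parent is not the previous sample, or the vessel
  # class switches at a junction)
  n_raw <- nrow(raw)
  new_chain <- c(TRUE, raw$parent[-1] != raw$id[-n_raw] |
                   raw$type[-1] != raw$type[-n_raw])
  chain_id <- cumsum(new_chain)
  nodes <- list(); segs <- list(); pts <- list()
  nid <- 0L
  for (cid in unique(chain_id)) {
    rr <- raw[chain_id == cid, , drop = FALSE]
    first_parent <- rr$parent[1]
    if (first_parent > 0) {
      pr <- raw[raw$id == first_parent, , drop = FALSE]
      # re-attach the junction sample unless the chain already repeats
      # the junction coordinate (as this package's own exports do)
      if (max(abs(c(pr$x - rr$x[1], pr$y - rr$y[1],
                    pr$z - rr$z[1]))) > 1e-9) {
        rr <- rbind(pr, rr)
        rr$type[1] <- rr$type[2]
      }
    }
    if (nrow(rr) < 2L) next
    nid <- nid + 2L
    nodes[[nid - 1L]] <- data.frame(node_id = nid - 1L, x = rr$x[1],
                                    y = rr$y[1], z = rr$z[1])
    nodes[[nid]] <- data.frame(node_id = nid, x = rr$x[nrow(rr)],
                               y = rr$y[nrow(rr)], z = rr$z[nrow(rr)])
    segs[[cid]] <- data.frame(segment_id = cid, from_node = nid - 1L,
                              to_node = nid, branch_order = NA_integer_,
                              vessel_class = names(.swc_type)[
                                match(rr$type[2], .swc_type)])
    pts[[cid]] <- data.frame(segment_id = cid, x = rr$x, y = rr$y,
                             z = rr$z, diameter = 2 * rr$radius)
  }
  # merge coincident chain endpoints into shared nodes
  nod <- do.call(rbind, nodes)
  seg <- do.call(rbind, segs)
  key <- paste(signif(nod$x, 9), signif(nod$y, 9), signif(nod$z, 9))
  canon <- nod$node_id[match(key, key)]
  seg$from_node <- canon[match(seg$from_node, nod$node_id)]
  seg$to_node <- canon[match(seg$to_node, nod$node_id)]
  nod <- nod[nod$node_id %in% canon, , drop = FALSE]
  vessel_network(nod, seg, do.call(rbind, pts), validate = FALSE)
}

#' Write a multi-plane stack as TIFF
#'
#' @param stack an `intensity_stack` or 3D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- if (inherits(stack, "intensity_stack")) stack$stack else stack
  mx <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-plane TIFF into an array
#'
#' @param path TIFF path.
#' @return 3D array (nx x ny x planes) of float intensities.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                          length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  arr
}

#' Build a run manifest
#'
#' Captures the configuration echo, seed, input digests, package version
#' and timestamp so a run can be reproduced and audited.
#'
#' @param config configuration object (echoed verbatim).
#' @param seed integer seed of the run.
#' @param inputs character vector of input file paths (digested with
#'   md5).
#' @param warnings character vector of warnings to record.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character(0),
                         warnings = character(0)) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else list()
  structure(list(package = "pemscope",
                 version = as.character(utils::packageVersion("pemscope")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = seed, config = config, input_digests = digests,
                 warnings = warnings),
            class = "run_manifest")
}

#' Run the end-to-end demonstration pipeline
#'
#' Chains the full analysis on one synthetic scene: generate, classify
#' CAM/PEM, Monte-Carlo chance null, branch orders and tree location,
#' width measurement, longitudinal simulation with retention and
#' gain/loss width change, and ROI intensity quantification. Writes
#' labeled tables, summary JSONs and a manifest into `out_dir`.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing the whole run.
#' @param n_chance_iterations Monte-Carlo iterations for the chance null.
#' @param days imaging days for the longitudinal stage.
#' @return list of in-memory results, invisibly; files in `out_dir`.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         seed = 1L, n_chance_iterations = 200L,
                         days = c(0L, 4L, 7L, 28L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  scene <- generate_scene(config)

  crit <- association_criteria(use_nucleus_center = FALSE)
  labels <- classify_cells(scene$cells, scene$network, crit)
  write_cells(labels$microglia, file.path(out_dir, "microglia_labeled.csv"))
  write_cells(labels$pericytes, file.path(out_dir, "pericytes_labeled.csv"))
  write_network_json(scene$network, file.path(out_dir, "network.json"))

  roi3 <- config$roi_extent
  chance <- simulate_chance_pem(
    scene$cells, roi3,
    chance_config(n_iterations = n_chance_iterations),
    observed_pct = labels$summary$pct_pem)

  net_o <- assign_branch_orders(scene$network)
  peri <- labels$pericytes
  mic <- labels$microglia
  core <- c("cell_id", "cell_type", "tree_order", "at_junction",
            "snap_distance", "mapped")
  locate_as <- function(cells, label) {
    out <- locate_on_tree(cells, net_o)[, core]
    out$class_label <- rep(label, nrow(out))
    out
  }
  located <- rbind(
    locate_as(peri, "pericyte"),
    locate_as(mic[isTRUE_vec(mic$is_cam), , drop = FALSE], "CAM"),
    locate_as(mic[isTRUE_vec(mic$is_pem), , drop = FALSE], "PEM"))
  orders <- order_distribution(located)

  widths <- measure_widths(labels, net_o, width_rules("invivo"))
  contrast <- width_contrast_table(widths, min_measurements = 1L)

  series <- simulate_timepoints(scene, days = days, config = config)
  retention <- pem_retention(series)
  by_day <- pem_proportion_by_day(series)
  events <- gain_loss_events(series)
  wchange <- width_change_on_gain_loss(series)

  stack <- render_intensity_stack(scene)
  rois <- pericyte_roi_polygons(scene)
  roi_means <- roi_intensity_table(stack, rois)
  write_stack_tiff(stack, file.path(out_dir, "stack.tif"))

  summary_json <- list(
    association = labels$summary,
    chance = list(observed_pct = chance$observed_pct,
                  expected_pct = chance$expected_pct,
                  expected_sd = chance$expected_sd,
                  enrichment_ratio = chance$enrichment_ratio),
    width_means = as.list(contrast$means),
    width_pct_diff_vs_vo = as.list(contrast$pct_diff_vs_vo),
    retention = retention,
    pem_proportion_by_day = by_day,
    width_change = wchange$summary)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       na = "null")
  utils::write.csv(orders, file.path(out_dir, "order_distribution.csv"),
                   row.names = FALSE)
  utils::write.csv(widths, file.path(out_dir, "widths.csv"),
                   row.names = FALSE)
  utils::write.csv(events$events, file.path(out_dir, "pem_events.csv"),
                   row.names = FALSE)
  utils::write.csv(roi_means, file.path(out_dir, "roi_intensity.csv"),
                   row.names = FALSE)
  manifest <- run_manifest(config, seed)
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(list(scene = scene, labels = labels, chance = chance,
                 orders = orders, widths = widths, contrast = contrast,
                 series = series, retention = retention,
                 by_day = by_day, events = events, wchange = wchange,
                 roi_means = roi_means, manifest = manifest))
}
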