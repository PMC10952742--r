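# ROI intensity quantification: plane projection, rolling-ball-style
# background subtraction, expanded-polygon ROI means, and the with/without
# PEM group comparison.

#' Project selected planes of a stack
#'
#' Per-pixel sum or maximum over the selected planes. The paper-style
#' workflow traces cell outlines on a max projection and quantifies on a
#' sum projection of the same planes.
#'
#' @param stack 3D array (nx x ny x planes) or an `intensity_stack`.
#' @param plane_indices planes to project (non-empty, within depth).
#' @param mode `"sum"` or `"max"`.
#' @return matrix (nx x ny).
#' @export
project_planes <- function(stack, plane_indices, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (inherits(stack, "intensity_stack")) stack <- stack$stack
  stopifnot(length(dim(stack)) == 3L)
  if (length(plane_indices) == 0L) {
    stop("plane_indices must be non-empty", call. = FALSE)
  }
  if (any(plane_indices < 1L | plane_indices > dim(stack)[3])) {
    stop("plane index outside stack depth", call. = FALSE)
  }
  sub <- stack[, , plane_indices, drop = FALSE]
  if (mode == "sum") {
    apply(sub, c(1, 2), sum)
  } else {
    apply(sub, c(1, 2), max)
  }
}

#' Subtract a rolling-ball-style background
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a disc structuring element of the given radius (a standard
#' approximation of the classic rolling-ball estimator, documented as
#' such) and subtracts it; output is clipped at zero. A constant image
#' maps to (numerically) zero; features smaller than the radius are
#' preserved.
#'
#' @param image numeric matrix.
#' @param radius_px structuring-element radius in pixels (>= 1,
#'   default 50).
#' @return matrix of the same dimensions, >= 0.
#' @export
subtract_background <- function(image, radius_px = 50) {
  stopifnot(radius_px >= 1)
  side <- 2L * as.integer(radius_px) + 1L
  # scale into [0,1] for EBImage, then back
  lo <- min(image); hi <- max(image)
  if (hi - lo < 1e-300) return(matrix(0, nrow(image), ncol(image)))
  img01 <- (image - lo) / (hi - lo)
  brush <- EBImage::makeBrush(side, shape = "disc")
  bg01 <- EBImage::opening(img01, brush)
  bg <- bg01 * (hi - lo) + lo
  pmax(image - bg, 0)
}

#' Mean intensity inside an expanded polygon ROI
#'
#' Offsets the polygon outward by `expansion_um` (Euclidean offset: a
#' pixel belongs to the expanded ROI when its center lies inside the
#' polygon or within `expansion_um` of its boundary) and averages the
#' image over member pixels. Pixel centers sit at
#' `(i - 0.5) * pixel_size`.
#'
#' @param image numeric matrix (x along rows, y along columns).
#' @param polygon n x 2 matrix of vertex coordinates in micrometres.
#' @param expansion_um outward offset (default 0.25).
#' @param pixel_size micrometres per pixel.
#' @return mean gray value over the ROI pixels.
#' @export
roi_mean_intensity <- function(image, polygon, expansion_um = 0.25,
                               pixel_size = 1) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L ||
      max(polygon[, 1]) - min(polygon[, 1]) <= 0 ||
      max(polygon[, 2]) - min(polygon[, 2]) <= 0) {
    stop("degenerate ROI polygon", call. = FALSE)
  }
  nx <- nrow(image); ny <- ncol(image)
  # restrict to the polygon's bounding box for speed
  xr <- range(polygon[, 1]) + c(-1, 1) * (expansion_um + pixel_size)
  yr <- range(polygon[, 2]) + c(-1, 1) * (expansion_um + pixel_size)
  ix <- which((seq_len(nx) - 0.5) * pixel_size >= xr[1] &
                (seq_len(nx) - 0.5) * pixel_size <= xr[2])
  iy <- which((seq_len(ny) - 0.5) * pixel_size >= yr[1] &
                (seq_len(ny) - 0.5) * pixel_size <= yr[2])
  if (length(ix) == 0L || length(iy) == 0L) {
    stop("ROI lies outside the image", call. = FALSE)
  }
  px <- rep((ix - 0.5) * pixel_size, times = length(iy))
  py <- rep((iy - 0.5) * pixel_size, each = length(ix))
  member <- .point_in_polygon(px, py, polygon)
  if (expansion_um > 0) {
    member <- member |
      .dist_to_polygon_boundary(px, py, polygon) <= expansion_um
  }
  if (!any(member)) stop("expanded ROI contains no pixel centers",
                         call. = FALSE)
  vals <- image[ix, iy, drop = FALSE]
  mean(vals[matrix(member, length(ix), length(iy))])
}

#' Per-pericyte ROI means over a stack
#'
#' Convenience wrapper for the paper-style flow: sum-project the chosen
#' planes, subtract the rolling-ball background, and measure the mean
#' intensity in each expanded pericyte ROI.
#'
#' @param stack an `intensity_stack` (or 3D array plus `pixel_size`).
#' @param rois named list of polygons from [pericyte_roi_polygons()].
#' @param plane_indices planes to project (default: all).
#' @param background_radius_px rolling-ball radius in pixels; `NULL`
#'   skips background subtraction.
#' @param expansion_um ROI expansion (default 0.25).
#' @param pixel_size micrometres per pixel (taken from the stack when
#'   available).
#' @return data.frame of `pericyte_id`, `mean_intensity`.
#' @export
roi_intensity_table <- function(stack, rois, plane_indices = NULL,
                                background_radius_px = 50,
                                expansion_um = 0.25, pixel_size = NULL) {
  if (inherits(stack, "intensity_stack")) {
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
    arr <- stack$stack
  } else {
    arr <- stack
    if (is.null(pixel_size)) pixel_size <- 1
  }
  if (is.null(plane_indices)) plane_indices <- seq_len(dim(arr)[3])
  img <- project_planes(arr, plane_indices, "sum")
  if (!is.null(background_radius_px)) {
    img <- subtract_background(img, background_radius_px)
  }
  means <- vapply(rois, function(poly) {
    tryCatch(roi_mean_intensity(img, poly, expansion_um, pixel_size),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(pericyte_id = as.integer(names(rois)),
             mean_intensity = unname(means))
}

#' Compare per-pericyte intensities by PEM status
#'
#' Per-scene means of the with-PEM and without-PEM groups and their
#' paired difference across scenes, with the paired comparison delegated
#' to [stats::t.test()] (paired). Scenes lacking one of the groups are
#' dropped from the paired comparison and reported.
#'
#' @param per_pericyte data.frame with columns `scene`, `mean_intensity`,
#'   `has_pem`.
#' @return list with `per_scene` (scene, with-PEM mean, without-PEM mean,
#'   difference), `mean_difference`, `conf_int`, `p_value`,
#'   `scenes_dropped`.
#' @export
compare_by_pem_status <- function(per_pericyte) {
  scenes <- unique(per_pericyte$scene)
  rows <- list(); dropped <- character(0)
  for (sc in scenes) {
    d <- per_pericyte[per_pericyte$scene == sc &
                        !is.na(per_pericyte$mean_intensity), , drop = FALSE]
    w <- d$mean_intensity[d$has_pem]
    wo <- d$mean_intensity[!d$has_pem]
    if (length(w) == 0L || length(wo) == 0L) {
      dropped <- c(dropped, as.character(sc))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scene = sc, with_pem = mean(w), without_pem = mean(wo),
      difference = mean(w) - mean(wo))
  }
  per_scene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scene = character(0), with_pem = numeric(0),
               without_pem = numeric(0), difference = numeric(0))
  tt <- if (nrow(per_scene) >= 2L) {
    stats::t.test(per_scene$with_pem, per_scene$without_pem, paired = TRUE)
  } else NULL
  list(per_scene = per_scene,
       mean_difference = if (nrow(per_scene) > 0L)
         mean(per_scene$difference) else NA_real_,
       conf_int = if (!is.null(tt)) unname(tt$conf.int) else
         c(NA_real_, NA_real_),
       p_value = if (!is.null(tt)) tt$p.value else NA_real_,
       scenes_dropped = dropped)
}
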