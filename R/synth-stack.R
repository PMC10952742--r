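# Synthetic multi-plane intensity stacks emulating marker labeling
# (e.g. astrocyte-endfoot coverage) around pericyte somata.

#' Marker rendering model
#'
#' @param signal_amplitude peak added intensity of a covered pericyte's
#'   blob (arbitrary units).
#' @param signal_sigma_um Gaussian blob SD in micrometres (roughly the
#'   pericyte soma scale).
#' @param covered_fraction fraction of pericytes rendered with signal.
#' @param pem_extra_amplitude additional amplitude for pericytes with a
#'   PEM (0 = the two groups share one signal model).
#' @param background_level flat background offset.
#' @param background_sigma_um SD of the smooth (low-frequency) background
#'   field.
#' @param background_amplitude amplitude of the smooth background field.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param pixel_size micrometres per pixel.
#' @return list of class `marker_model`.
#' @export
marker_model <- function(signal_amplitude = 100, signal_sigma_um = 3,
                         covered_fraction = 0.5, pem_extra_amplitude = 0,
                         background_level = 10, background_sigma_um = 40,
                         background_amplitude = 5, noise_sd = 1,
                         pixel_size = 1) {
  structure(list(signal_amplitude = signal_amplitude,
                 signal_sigma_um = signal_sigma_um,
                 covered_fraction = covered_fraction,
                 pem_extra_amplitude = pem_extra_amplitude,
                 background_level = background_level,
                 background_sigma_um = background_sigma_um,
                 background_amplitude = background_amplitude,
                 noise_sd = noise_sd, pixel_size = pixel_size),
            class = "marker_model")
}

#' Render a synthetic multi-plane intensity stack
#'
#' Renders `planes` 2D images over the scene's xy footprint: a Gaussian
#' blob of marker signal around a configurable subset of pericytes
#' (emulating marker-covered versus marker-devoid cells), a smooth
#' background field, a flat offset and additive Gaussian noise. The
#' ground-truth per-pericyte mean added intensity (mean of the noiseless
#' per-plane signal over the soma disc, per plane) is recorded.
#'
#' @param scene a `synthetic_scene`.
#' @param model a [marker_model()].
#' @param planes number of planes (>= 1, default 8).
#' @param pem_flags optional logical vector (one per pericyte) marking
#'   pericytes with a PEM; defaults to the generator's truth partners.
#' @param seed optional integer seed.
#' @return list of class `intensity_stack`: `stack` (array
#'   nx x ny x planes), `truth` (per-pericyte data.frame with `covered`,
#'   `has_pem`, `added_mean` per plane), `pixel_size`.
#' @export
render_intensity_stack <- function(scene, model = marker_model(),
                                   planes = 8L, pem_flags = NULL,
                                   seed = NULL) {
  stopifnot(planes >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ext <- scene$config$roi_extent
  ps <- model$pixel_size
  nx <- max(2L, floor(ext[1] / ps))
  ny <- max(2L, floor(ext[2] / ps))
  cx <- (seq_len(nx) - 0.5) * ps
  cy <- (seq_len(ny) - 0.5) * ps

  peri <- scene$cells[scene$cells$cell_type == "pericyte", , drop = FALSE]
  n_p <- nrow(peri)
  covered <- if (n_p > 0L)
    stats::runif(n_p) < model$covered_fraction else logical(0)
  if (is.null(pem_flags)) {
    pem_flags <- peri$cell_id %in%
      scene$cells$partner_id[scene$cells$cell_type == "microglia"]
  }

  base <- matrix(model$background_level, nx, ny)
  if (model$background_amplitude > 0) {
    # one broad Gaussian bump at a random position per stack
    bx <- stats::runif(1, 0, ext[1]); by <- stats::runif(1, 0, ext[2])
    base <- base + model$background_amplitude *
      outer(exp(-(cx - bx)^2 / (2 * model$background_sigma_um^2)),
            exp(-(cy - by)^2 / (2 * model$background_sigma_um^2)))
  }

  signal <- matrix(0, nx, ny)
  amp <- numeric(n_p)
  for (i in seq_len(n_p)) {
    a <- 0
    if (covered[i]) a <- model$signal_amplitude
    if (pem_flags[i]) a <- a + model$pem_extra_amplitude
    amp[i] <- a
    if (a == 0) next
    signal <- signal + a *
      outer(exp(-(cx - peri$x_um[i])^2 / (2 * model$signal_sigma_um^2)),
            exp(-(cy - peri$y_um[i])^2 / (2 * model$signal_sigma_um^2)))
  }

  stack <- array(0, dim = c(nx, ny, planes))
  for (pl in seq_len(planes)) {
    noise <- if (model$noise_sd > 0)
      matrix(stats::rnorm(nx * ny, 0, model$noise_sd), nx, ny) else 0
    stack[, , pl] <- base + signal + noise
  }

  # truth: mean added signal within the soma disc (radius = blob sigma)
  added <- vapply(seq_len(n_p), function(i) {
    if (amp[i] == 0) return(0)
    r <- model$signal_sigma_um
    ix <- which(abs(cx - peri$x_um[i]) <= r)
    iy <- which(abs(cy - peri$y_um[i]) <= r)
    if (length(ix) == 0L || length(iy) == 0L) return(NA_real_)
    mean(signal[ix, iy])
  }, numeric(1))

  structure(list(stack = stack,
                 truth = if (n_p > 0L)
                   data.frame(pericyte_id = peri$cell_id, covered = covered,
                              has_pem = pem_flags, added_mean = added,
                              x_um = peri$x_um, y_um = peri$y_um) else
                     data.frame(pericyte_id = integer(0),
                                covered = logical(0), has_pem = logical(0),
                                added_mean = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)),
                 pixel_size = ps),
            class = "intensity_stack")
}

#' Circle outline polygons around pericyte somata
#'
#' Regular polygons (default 24-gon) approximating the traced pericyte
#' soma outline, in micrometre coordinates, as the intensity module's ROI
#' input.
#'
#' @param scene a `synthetic_scene`.
#' @param radius_um outline radius (default 3, a 5-6 um diameter soma).
#' @param n_vertices polygon resolution.
#' @return named list of n x 2 matrices keyed by pericyte id.
#' @export
pericyte_roi_polygons <- function(scene, radius_um = 3, n_vertices = 24L) {
  peri <- scene$cells[scene$cells$cell_type == "pericyte", , drop = FALSE]
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  out <- lapply(seq_len(nrow(peri)), function(i) {
    cbind(peri$x_um[i] + radius_um * cos(th),
          peri$y_um[i] + radius_um * sin(th))
  })
  names(out) <- peri$cell_id
  out
}
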