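# Configuration for the synthetic microvascular scene generator.

#' Generator configuration
#'
#' Bundles every tunable of the synthetic scene generator. Defaults emulate
#' a cortical two-photon field of view (210 x 210 x 130 um) with a
#' penetrating arteriole (order 0) branching through capillary orders 1-7
#' onto an ascending venule (order 8), pericytes on capillary walls, and a
#' microglia population mixing uniform, vessel-attracted and
#' pericyte-attracted placement.
#'
#' @param roi_extent numeric length-3, ROI dimensions (x, y, z) in
#'   micrometres; strictly positive.
#' @param pericyte_linear_density pericytes per micrometre of capillary
#'   centerline (default 0.0083, one per ~120 um; calibrated so a
#'   uniformly placed microglia has a ~1.5% chance of sitting within the
#'   association radius of a pericyte).
#' @param microglia_density microglia per square micrometre of the ROI's
#'   xy footprint (cells are still placed in 3D). Default 1.4e-3.
#' @param frac_vessel_attracted fraction of microglia drawn toward a
#'   vessel centerline point (within `attraction_radius`); targets are
#'   sampled clear of pericyte somata so this fraction does not feed the
#'   PEM class. The default 0.25, combined with uniformly placed
#'   microglia that land near the capillary bed by chance, puts the
#'   scene-level CAM proportion near 40%.
#' @param frac_pericyte_attracted fraction of microglia drawn to within
#'   `attraction_radius` of a pericyte nucleus. Default 0.064, which
#'   together with the default densities puts the scene-level PEM
#'   proportion near 7% against a chance level near 1.5%.
#' @param attraction_radius radius (um) of the placement ball around the
#'   attraction target; must stay below the 10 um association criterion so
#'   attracted placements are positive cases by construction.
#' @param width_profile list with elements `baseline` (diameter per branch
#'   order 0..8, um), `dilation` (named multiplicative factors `P`, `CAM`,
#'   `PEM` applied at landmarks), `gain` and `loss` (factors applied to the
#'   local diameter when a pericyte gains or loses a PEM), `window_um`
#'   (arclength half-width of the dilated window) and `noise_sd`
#'   (multiplicative per-point diameter noise).
#' @param retention_per_visit probability a PEM remains adjacent at the
#'   next imaging visit; a scalar, or one value per visit. The default
#'   schedule `c(0.810, 0.963, 0.564)` over the three default visits
#'   (days 0-4, 4-7, 7-28) yields cumulative retention of 81%, 78% and
#'   44% at days 4, 7 and 28.
#' @param gain_rate probability per visit that a pericyte currently
#'   without a PEM gains one.
#' @param pericyte_min_spacing minimum centerline spacing between pericyte
#'   anchors on a segment (um).
#' @param segment_length_range uniform range for segment lengths (um).
#' @param branch_prob probability that a freshly grown capillary tip
#'   stays open for further bifurcation (controls bushiness).
#' @param n_segments total segment budget of the tree (default 48);
#'   growth bifurcates open tips until the budget is spent, which keeps
#'   total capillary length - and with it the pericyte count and the
#'   chance association level - stable across seeds.
#' @param point_spacing centerline point spacing (um).
#' @param jitter_sd_stable isotropic per-axis displacement SD (um) of a
#'   stable cell between visits.
#' @param jitter_sd_loss displacement scale (um) of a microglia that loses
#'   its pericyte association; large enough that losses are unambiguous at
#'   the 10 um criterion.
#' @param exact_counts if `TRUE`, cell counts are `round(density * measure)`
#'   and class counts are rounded fractions instead of Poisson/multinomial
#'   draws; used when an analysis needs a fixed number of cells.
#' @param seed integer seed; identical config and seed reproduce the scene
#'   bit for bit.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(roi_extent = c(210, 210, 130),
                             pericyte_linear_density = 0.0083,
                             microglia_density = 1.4e-3,
                             frac_vessel_attracted = 0.25,
                             frac_pericyte_attracted = 0.064,
                             attraction_radius = 8,
                             width_profile = NULL,
                             retention_per_visit = c(0.810, 0.963, 0.564),
                             gain_rate = 0.12,
                             pericyte_min_spacing = 25,
                             segment_length_range = c(40, 80),
                             branch_prob = 0.7,
                             n_segments = 48L,
                             point_spacing = 2,
                             jitter_sd_stable = 3,
                             jitter_sd_loss = 15,
                             exact_counts = FALSE,
                             seed = NULL) {
  default_profile <- list(
    baseline = c(15, rep(4.21, 7), 12),  # orders 0..8
    dilation = c(P = 1.16, CAM = 1.15, PEM = 1.21),
    gain = 1.20, loss = 0.91,
    window_um = 5, noise_sd = 0.02)
  if (is.null(width_profile)) {
    width_profile <- default_profile
  } else {
    width_profile <- utils::modifyList(default_profile, width_profile)
  }
  cfg <- list(roi_extent = as.numeric(roi_extent),
              pericyte_linear_density = pericyte_linear_density,
              microglia_density = microglia_density,
              frac_vessel_attracted = frac_vessel_attracted,
              frac_pericyte_attracted = frac_pericyte_attracted,
              attraction_radius = attraction_radius,
              width_profile = width_profile,
              retention_per_visit = retention_per_visit,
              gain_rate = gain_rate,
              pericyte_min_spacing = pericyte_min_spacing,
              segment_length_range = as.numeric(segment_length_range),
              branch_prob = branch_prob,
              n_segments = as.integer(n_segments),
              point_spacing = point_spacing,
              jitter_sd_stable = jitter_sd_stable,
              jitter_sd_loss = jitter_sd_loss,
              exact_counts = isTRUE(exact_counts),
              seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' @param config a `generator_config`.
#' @return `config`, invisibly.
#' @export
validate_generator_config <- function(config) {
  stopifnot(length(config$roi_extent) == 3L)
  if (any(config$roi_extent <= 0)) {
    stop("roi_extent must be strictly positive", call. = FALSE)
  }
  dens <- c(config$pericyte_linear_density, config$microglia_density)
  if (any(dens < 0)) stop("densities must be >= 0", call. = FALSE)
  f <- c(config$frac_vessel_attracted, config$frac_pericyte_attracted)
  if (any(f < 0) || any(f > 1) || sum(f) > 1 + 1e-12) {
    stop("attraction fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (config$attraction_radius <= 0) {
    stop("attraction_radius must be positive", call. = FALSE)
  }
  rp <- config$retention_per_visit
  if (any(rp < 0 | rp > 1)) {
    stop("retention_per_visit must lie in [0, 1]", call. = FALSE)
  }
  if (any(config$width_profile$baseline <= 0)) {
    stop("width_profile baselines must be positive", call. = FALSE)
  }
  invisible(config)
}

# Seed the session RNG from a config if it carries a seed. All generator
# randomness flows through R's single RNG stream.
.maybe_seed <- function(config, seed = NULL) {
  s <- if (!is.null(seed)) seed else config$seed
  if (!is.null(s)) set.seed(as.integer(s))
  invisible(NULL)
}
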