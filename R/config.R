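#' Imaging-field configuration for the synthetic generator
#'
#' Describes one square viewfield: its physical size, pixel and frame
#' calibration, cell packing, and the noise model of the ratiometric
#' (FRET/CFP) readout. Defaults emulate a 0.213 mm^2 two-photon viewfield
#' imaged at 90-s intervals with nuclear-localised biosensor.
#'
#' @param field_size_um Side length of the square field (micrometres).
#' @param pixel_size_um Physical size of one pixel (micrometres).
#' @param frame_interval_min Time between frames (minutes).
#' @param n_frames Number of frames.
#' @param n_cells Number of nuclei placed in the field.
#' @param nucleus_radius_um Nucleus radius (micrometres).
#' @param baseline_ratio_mean Mean per-cell baseline FRET/CFP ratio.
#' @param baseline_ratio_sd Between-cell s.d. of the baseline ratio.
#' @param noise_sd Per-frame additive Gaussian noise on the ratio.
#' @param cfp_level CFP (donor) intensity of a nucleus, arbitrary units.
#' @param seed Integer seed making every derived artefact reproducible.
#' @return An object of class `field_config` (a validated list).
#' @export
field_config <- function(field_size_um = 462,
                         pixel_size_um = 462 / 512,
                         frame_interval_min = 1.5,
                         n_frames = 80,
                         n_cells = 350,
                         nucleus_radius_um = 3,
                         baseline_ratio_mean = 1.2,
                         baseline_ratio_sd = 0.03,
                         noise_sd = 0.02,
                         cfp_level = 400,
                         seed = 1L) {
  cfg <- list(field_size_um = field_size_um,
              pixel_size_um = pixel_size_um,
              frame_interval_min = frame_interval_min,
              n_frames = as.integer(n_frames),
              n_cells = as.integer(n_cells),
              nucleus_radius_um = nucleus_radius_um,
              baseline_ratio_mean = baseline_ratio_mean,
              baseline_ratio_sd = baseline_ratio_sd,
              noise_sd = noise_sd,
              cfp_level = cfp_level,
              seed = as.integer(seed))
  stopifnot(field_size_um > 0, pixel_size_um > 0, frame_interval_min > 0,
            cfg$n_frames >= 1, cfg$n_cells >= 1, nucleus_radius_um > 0,
            baseline_ratio_mean > 0, baseline_ratio_sd >= 0, noise_sd >= 0,
            cfp_level > 0)
  class(cfg) <- "field_config"
  cfg
}

#' Ground truth of one simulated SPREAD
#'
#' A SPREAD is modelled as a radially propagating half-sine pulse of ERK
#' activity: a cell at distance `d` from the origin becomes a responder
#' with logistic probability `1 / (1 + exp((d - radius_um) /
#' responder_steepness_um))`, and a responder pulses at time
#' `onset_min + d / velocity_um_per_min` with amplitude `amp0` reduced by
#' the configured decay law.
#'
#' @param origin_xy_um Numeric length-2; origin coordinates (micrometres).
#' @param onset_min SPREAD onset time (minutes).
#' @param velocity_um_per_min Radial propagation velocity (um/min).
#' @param amp0 Ratio elevation at the origin (dimensionless).
#' @param amp_decay_per_um Fractional amplitude loss per micrometre
#'   (linear law) or exponential rate (exponential law).
#' @param radius_um Distance at which the responder probability is 0.5.
#' @param responder_steepness_um Logistic scale of the responder
#'   probability (micrometres).
#' @param pulse_width_min Half-sine pulse width tau (minutes); the true
#'   single-cell duration above half-maximum is (2/3) tau.
#' @param decay_law `"linear"` (clipped at zero) or `"exponential"`.
#' @return An object of class `spread_truth`.
#' @export
spread_truth <- function(origin_xy_um = c(231, 231),
                         onset_min = 10,
                         velocity_um_per_min = 1.5,
                         amp0 = 0.3,
                         amp_decay_per_um = 0.005,
                         radius_um = 47.7,
                         responder_steepness_um = 6,
                         pulse_width_min = 70.5,
                         decay_law = c("linear", "exponential")) {
  decay_law <- match.arg(decay_law)
  stopifnot(length(origin_xy_um) == 2, velocity_um_per_min > 0, amp0 > 0,
            amp_decay_per_um >= 0, radius_um > 0, responder_steepness_um > 0,
            pulse_width_min > 0)
  out <- list(origin_xy_um = as.numeric(origin_xy_um), onset_min = onset_min,
              velocity_um_per_min = velocity_um_per_min, amp0 = amp0,
              amp_decay_per_um = amp_decay_per_um, radius_um = radius_um,
              responder_steepness_um = responder_steepness_um,
              pulse_width_min = pulse_width_min, decay_law = decay_law)
  class(out) <- "spread_truth"
  out
}

#' Ground truth of simulated wound-edge ERK activation waves
#'
#' Planar waves start at the wound edge and travel into the tissue with
#' constant velocity and non-decaying amplitude (a trigger wave), reaching
#' cells up to `max_reach_um` from the edge.
#'
#' @param edge_polyline_um Two-column matrix of polyline vertices (um).
#' @param wave_onsets_min Numeric vector of wave start times (minutes).
#' @param velocity_um_per_min Propagation velocity (um/min).
#' @param max_reach_um Maximal distance from the edge reached by a wave.
#' @param amp0 Ratio elevation of the pulse, independent of distance.
#' @param responder_prob Probability that a cell within reach responds.
#' @param pulse_width_min Half-sine pulse width tau (minutes).
#' @return An object of class `wound_truth`.
#' @export
wound_truth <- function(edge_polyline_um,
                        wave_onsets_min = 10,
                        velocity_um_per_min = 1.4,
                        max_reach_um = 100,
                        amp0 = 0.3,
                        responder_prob = 0.9,
                        pulse_width_min = 70.5) {
  edge_polyline_um <- as.matrix(edge_polyline_um)
  stopifnot(ncol(edge_polyline_um) == 2, nrow(edge_polyline_um) >= 2,
            velocity_um_per_min > 0, max_reach_um > 0, amp0 > 0,
            responder_prob >= 0, responder_prob <= 1, pulse_width_min > 0)
  out <- list(edge_polyline_um = edge_polyline_um,
              wave_onsets_min = as.numeric(wave_onsets_min),
              velocity_um_per_min = velocity_um_per_min,
              max_reach_um = max_reach_um, amp0 = amp0,
              responder_prob = responder_prob,
              pulse_width_min = pulse_width_min)
  class(out) <- "wound_truth"
  out
}

#' Pulse-fitting configuration
#'
#' @param smooth_window_min Width of the pre-fit moving average (minutes).
#' @param residual_threshold Residual cutoff separating flat-line fits
#'   (non-responders) from sine fits (responders), in squared-ratio units
#'   for the default `"mse"` metric.
#' @param max_sine_components Maximum number of summed sine components.
#' @param multistart_count Number of period grid points used to seed the
#'   nonlinear fits.
#' @param metric Residual functional compared against the threshold:
#'   mean squared error (default) or its square root.
#' @param fit_on Whether the threshold applies to residuals of the
#'   smoothed (default) or raw trace.
#' @param seed Seed for any randomised start (fits are deterministic;
#'   kept for interface stability).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(smooth_window_min = 15,
                       residual_threshold = 0.003,
                       max_sine_components = 3,
                       multistart_count = 12,
                       metric = c("mse", "rmse"),
                       fit_on = c("smoothed", "raw"),
                       seed = 1L) {
  metric <- match.arg(metric)
  fit_on <- match.arg(fit_on)
  stopifnot(smooth_window_min > 0, residual_threshold > 0,
            max_sine_components >= 1, multistart_count >= 2)
  out <- list(smooth_window_min = smooth_window_min,
              residual_threshold = residual_threshold,
              max_sine_components = as.integer(max_sine_components),
              multistart_count = as.integer(multistart_count),
              metric = metric, fit_on = fit_on, seed = as.integer(seed))
  class(out) <- "fit_config"
  out
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf("Synthetic viewfield: %.0f x %.0f um (%.3f mm^2), %.3f um/px\n",
              x$field_size_um, x$field_size_um,
              (x$field_size_um / 1000)^2, x$pixel_size_um))
  cat(sprintf("  %d frames every %.2f min, %d cells, nucleus radius %.1f um\n",
              x$n_frames, x$frame_interval_min, x$n_cells,
              x$nucleus_radius_um))
  cat(sprintf("  baseline ratio %.2f +/- %.3f, noise sd %.3f, seed %d\n",
              x$baseline_ratio_mean, x$baseline_ratio_sd, x$noise_sd, x$seed))
  invisible(x)
}

# Scoped RNG: run code under a given seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
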