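# Validation presets: fully specified synthetic scenarios whose ground
# truths are pinned to the published in vivo estimates, used to check
# that each estimator recovers what it should. Each returns the config,
# the truth, and the generated data.

spread_scenario <- function(config, truth,
                            responder_mode = "bernoulli") {
  cells <- place_cells(config)
  sim <- simulate_spread_traces(cells, truth, config,
                                responder_mode = responder_mode)
  list(config = config, truth = truth, cells = cells,
       traces = sim$traces, cell_truth = sim$cells,
       baselines = sim$baselines)
}

#' Synthetic single SPREAD with the published single-SPREAD velocity
#'
#' A 150-um analysis crop (90-s frames, 350 cells, ratio noise 0.02)
#' containing one SPREAD whose true velocity is 1.93 um/min, radius
#' 47.7 um and pulse width 70.5 min.
#'
#' @param seed Integer seed.
#' @return List `config`, `truth`, `cells`, `traces`, `cell_truth`,
#'   `baselines`.
#' @export
synthetic_spread6 <- function(seed = 42L) {
  cfg <- field_config(field_size_um = 150, n_frames = 85, n_cells = 350,
                      frame_interval_min = 1.5, seed = seed)
  tr <- spread_truth(origin_xy_um = c(75, 75), onset_min = 10,
                     velocity_um_per_min = 1.93)
  spread_scenario(cfg, tr)
}

#' Ensemble of eight synthetic SPREADs with mean velocity 1.5 um/min
#'
#' Eight independent single-SPREAD crops whose fixed true velocities are
#' equally spaced from 1.05 to 1.95 um/min (mean 1.5, s.d. ~0.3).
#'
#' @param seeds Integer vector of eight seeds, one per SPREAD.
#' @return List of eight scenarios (as in [synthetic_spread6()]); the
#'   true velocities are in `attr(, "velocities")`.
#' @export
synthetic_spread_ensemble <- function(seeds = 1:8) {
  stopifnot(length(seeds) == 8)
  v <- seq(1.05, 1.95, length.out = 8)
  out <- lapply(1:8, function(i) {
    cfg <- field_config(field_size_um = 150, n_frames = 100,
                        n_cells = 250, frame_interval_min = 1.5,
                        seed = seeds[i])
    tr <- spread_truth(origin_xy_um = c(75, 75), onset_min = 10,
                       velocity_um_per_min = v[i])
    spread_scenario(cfg, tr)
  })
  attr(out, "velocities") <- v
  out
}

#' Synthetic SPREAD field for radius recovery
#'
#' A 250-um field with 800 cells and a responder-probability midpoint at
#' the published mean radius (47.7 um, logistic steepness 6 um).
#'
#' @param seed Integer seed.
#' @return A scenario list (see [synthetic_spread6()]).
#' @export
synthetic_radius_field <- function(seed = 7L) {
  cfg <- field_config(field_size_um = 250, n_frames = 85, n_cells = 800,
                      frame_interval_min = 1.5, seed = seed)
  tr <- spread_truth(origin_xy_um = c(125, 125), onset_min = 5,
                     velocity_um_per_min = 1.5, radius_um = 47.7,
                     responder_steepness_um = 6)
  spread_scenario(cfg, tr)
}

# Full width at half maximum of the responder density over distance,
# c(d) = d * p(d) with logistic p; closed-form-free but analytic in the
# sense of being computed from the model, not from data.
responder_distance_fwhm <- function(radius_um, steepness_um,
                                    d_max = 2 * radius_um) {
  d <- seq(0.01, d_max, by = 0.01)
  dens <- d / (1 + exp((d - radius_um) / steepness_um))
  half <- max(dens) / 2
  rng <- range(d[dens >= half])
  diff(rng)
}

#' Synthetic SPREAD whose peak-time histogram width is 30.5 min
#'
#' The half-maximum width of the responder peak-time histogram equals
#' the published mean per-SPREAD duration by construction: the responder
#' distance density `d * p(d)` has an analytic half-maximum width, and
#' the true velocity is set to that width divided by 30.5 min.
#' Responders are assigned by systematic (stratified) thinning rather
#' than independent coin flips: the half-maximum width of a histogram
#' with ~30 counts per bin is dominated by Bernoulli noise otherwise,
#' while the marginal responder fraction at every distance is identical.
#'
#' @param seed Integer seed.
#' @return A scenario list; the implied velocity is in
#'   `truth$velocity_um_per_min`.
#' @export
synthetic_duration_field <- function(seed = 11L) {
  radius <- 47.7; steep <- 6
  fwhm <- responder_distance_fwhm(radius, steep)
  v <- fwhm / 30.5
  cfg <- field_config(field_size_um = 200, n_frames = 110, n_cells = 1000,
                      frame_interval_min = 1.5, seed = seed)
  tr <- spread_truth(origin_xy_um = c(100, 100), onset_min = 5,
                     velocity_um_per_min = v, radius_um = radius,
                     responder_steepness_um = steep)
  spread_scenario(cfg, tr, responder_mode = "systematic")
}

#' Synthetic all-responder field for single-cell duration recovery
#'
#' Every cell responds (logistic midpoint far beyond the field) with an
#' undecayed half-sine of width 70.5 min, whose true above-half-maximum
#' duration is (2/3) x 70.5 = 47 min.
#'
#' @param seed Integer seed.
#' @return A scenario list.
#' @export
synthetic_cellpulse_field <- function(seed = 5L) {
  cfg <- field_config(field_size_um = 150, n_frames = 90, n_cells = 300,
                      frame_interval_min = 1.5, seed = seed)
  tr <- spread_truth(origin_xy_um = c(75, 75), onset_min = 5,
                     velocity_um_per_min = 1.93, amp0 = 0.3,
                     amp_decay_per_um = 0, radius_um = 140,
                     responder_steepness_um = 1, pulse_width_min = 70.5)
  spread_scenario(cfg, tr)
}

#' Synthetic wound-edge trigger wave at the published wave velocity
#'
#' A straight wound edge along the left border of a 250-um field; one
#' wave at 1.4 um/min reaching 100 um with non-decaying amplitude;
#' 2.5-min frames.
#'
#' @param seed Integer seed.
#' @return List `config`, `truth`, `cells`, `traces`, `cell_truth`,
#'   `baselines`, `edge`.
#' @export
synthetic_wound_wave <- function(seed = 3L) {
  # window covers every pulse with >= one smoothing window of margin on
  # both sides (onset 15; last pulse ends 15 + 100/1.4 + 70.5 ~ 157 min)
  cfg <- field_config(field_size_um = 250, n_frames = 70, n_cells = 250,
                      frame_interval_min = 2.5, seed = seed)
  edge <- rbind(c(0, 0), c(0, 250))
  tr <- wound_truth(edge_polyline_um = edge, wave_onsets_min = 15,
                    velocity_um_per_min = 1.4, max_reach_um = 100,
                    amp0 = 0.3, responder_prob = 0.9)
  cells <- place_cells(cfg)
  sim <- simulate_wound_traces(cells, tr, cfg)
  list(config = cfg, truth = tr, cells = cells, traces = sim$traces,
       cell_truth = sim$cells, baselines = sim$baselines, edge = edge)
}

#' Synthetic Fucci viewfield at the published S/G2/M proportion
#'
#' A 0.213 mm^2 viewfield with 723 nuclei, exactly `round(723 * 0.122)`
#' of them S/G2/M (exact-count mode), rendered with default channel
#' noise.
#'
#' @param seed Integer seed.
#' @return List as returned by [simulate_fucci_field()], plus `config`.
#' @export
synthetic_fucci_viewfield <- function(seed = 9L) {
  cfg <- field_config(n_cells = 723, seed = seed)
  out <- simulate_fucci_field(cfg, sgm_fraction = 0.122,
                              exact_count = TRUE)
  out$config <- cfg
  out
}

#' Synthetic clustered SPREAD-origin pattern
#'
#' Thomas-type process: 4 uniform parents with 5 offspring each at
#' Gaussian scale 20 um in the 462-um viewfield.
#'
#' @param seed Integer seed.
#' @return List `points` (20 x 2 matrix) and `region_um`.
#' @export
synthetic_clustered_origins <- function(seed = 21L) {
  region <- c(462, 462)
  pts <- simulate_origin_pattern(region, mode = "clustered",
                                 n_parents = 4, n_offspring = 5,
                                 offspring_scale_um = 20, seed = seed)
  list(points = pts, region_um = region)
}
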