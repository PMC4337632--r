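# Small shared fixtures, generated in code.

tiny_config <- function(...) {
  args <- list(field_size_um = 80, pixel_size_um = 1, n_frames = 6,
               n_cells = 20, noise_sd = 0, baseline_ratio_sd = 0.05,
               seed = 12L)
  args[names(list(...))] <- list(...)
  do.call(field_config, args)
}

# one noiseless half-sine pulse riding on a flat baseline
pulse_trace <- function(t0 = 20, tau = 70.5, amp = 0.3, baseline = 1.2,
                        dt = 1.5, t_end = 120, noise = 0, seed = 99) {
  t <- seq(0, t_end, by = dt)
  set.seed(seed)
  y <- baseline + erkwave:::half_sine_pulse(t, t0, tau, amp) +
    stats::rnorm(length(t), 0, noise)
  list(t = t, y = y)
}

# radial SPREAD scenario small enough for routine tests
small_spread_scenario <- function(seed = 1L, n_cells = 150,
                                  velocity = 1.93) {
  cfg <- field_config(field_size_um = 150, n_frames = 85,
                      n_cells = n_cells, frame_interval_min = 1.5,
                      seed = seed)
  tr <- spread_truth(origin_xy_um = c(75, 75), onset_min = 10,
                     velocity_um_per_min = velocity)
  cells <- place_cells(cfg)
  sim <- simulate_spread_traces(cells, tr, cfg)
  list(config = cfg, truth = tr, cells = cells, traces = sim$traces,
       cell_truth = sim$cells)
}
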