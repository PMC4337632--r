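# minimal synthetic fit table: cells on a disc pulsing radially from a
# known origin at velocity v
radial_fit_table <- function(n = 60, origin = c(50, 50), v = 1.5,
                             onset = 10, seed = 1, jitter = 0) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi); d <- sqrt(runif(n)) * 45
  data.frame(cell_id = seq_len(n),
             x_um = origin[1] + d * cos(th),
             y_um = origin[2] + d * sin(th),
             class = "responder", responder = TRUE,
             peak_time = onset + d / v + rnorm(n, 0, jitter),
             amplitude = 0.3 * (1 - 0.004 * d),
             duration = 47)
}

test_that("origin optimisation maximises the distance/peak-time correlation", {
  fits <- radial_fit_table()
  opt <- optimize_origin(fits, initial_origin_um = c(45, 45),
                         pixel_size_um = 1, search_radius_px = 10)
  expect_equal(opt$origin_um, c(50, 50))
  expect_gt(opt$correlation, 0.999)
  # zero search radius returns the initial origin
  opt0 <- optimize_origin(fits, c(45, 45), 1, search_radius_px = 0)
  expect_equal(opt0$origin_um, c(45, 45))
  # objective at the returned point is never below the initial one
  expect_gte(opt$correlation, opt0$correlation)
  # degenerate inputs surface as errors
  few <- fits[1:2, ]
  expect_error(optimize_origin(few, c(45, 45)), "3 responders")
  const <- fits; const$peak_time <- 30
  expect_error(optimize_origin(const, c(45, 45)), "undefined")
})

test_that("velocity regression reads the slope of distance on peak time", {
  fits <- data.frame(cell_id = 1:3, x_um = c(0, 15, 30), y_um = 0,
                     responder = TRUE, peak_time = c(10, 20, 30))
  v <- estimate_velocity(fits, c(0, 0))
  expect_equal(v$velocity_um_per_min, 1.5)
  expect_equal(v$onset_min, 10)
  expect_equal(v$r2, 1)
  expect_true(v$propagating)
  flat <- data.frame(cell_id = 1:4, x_um = 10, y_um = 0,
                     responder = TRUE, peak_time = c(5, 10, 15, 20))
  vf <- estimate_velocity(flat, c(0, 0))
  expect_equal(vf$velocity_um_per_min, 0)
  expect_false(vf$propagating)
})

test_that("square-root fits recover their own generating law", {
  t <- seq(6, 40, length.out = 30)
  fits <- data.frame(cell_id = seq_along(t), x_um = 3 * sqrt(t - 5),
                     y_um = 0, responder = TRUE, peak_time = t)
  sq <- fit_sqrt_law(fits, c(0, 0))
  expect_lt(abs(sq$a - 3), 0.01)
  expect_lt(abs(sq$t0_min - 5), 0.05)
  expect_gt(sq$r2, 0.999)
})

test_that("linear and square-root fits are near-indistinguishable on a
           30-min propagation window", {
  # the indeterminacy that precludes concluding whether the wave slows
  for (law in c("linear", "sqrt")) {
    t <- seq(10, 40, length.out = 40)
    d <- if (law == "linear") 1.8 * (t - 8) else 11 * sqrt(t - 8)
    set.seed(4)
    fits <- data.frame(cell_id = seq_along(t), x_um = d + rnorm(40, 0, 2),
                       y_um = 0, responder = TRUE, peak_time = t)
    lin <- estimate_velocity(fits, c(0, 0))
    sq <- fit_sqrt_law(fits, c(0, 0))
    expect_lt(abs(lin$r2 - sq$r2), 0.1)
  }
})

test_that("responder profiles bin annuli and gate sparse bins", {
  fits <- radial_fit_table(n = 200, seed = 2)
  fits$responder[sqrt((fits$x_um - 50)^2 + (fits$y_um - 50)^2) > 30] <- FALSE
  prof <- responder_fraction_profile(fits, c(50, 50), bin_width_um = 10,
                                     min_cells_per_bin = 5)
  expect_true(all(prof$fraction >= 0 & prof$fraction <= 1, na.rm = TRUE))
  expect_true(all(diff(prof$center_um) == 10))
  expect_false(any(prof$usable & prof$n_cells < 5))
  all_resp <- radial_fit_table(n = 80, seed = 3)
  pa <- responder_fraction_profile(all_resp, c(50, 50))
  expect_true(all(pa$fraction[pa$n_cells > 0] == 1))
})

test_that("the radius interpolates the 50% crossing between annulus centres", {
  prof <- data.frame(bin_lo = seq(0, 50, 10), bin_hi = seq(10, 60, 10),
                     center_um = seq(5, 55, 10),
                     n_cells = 20, n_responders = 10,
                     fraction = c(1.0, 0.95, 0.85, 0.70, 0.55, 0.35),
                     usable = TRUE)
  est <- estimate_radius(prof)
  expect_equal(est$radius_um, 47.5)
  expect_equal(est$flag, "ok")
  # all above 0.5: unbounded at the outermost usable centre
  prof$fraction <- rep(0.8, 6)
  expect_equal(estimate_radius(prof)$flag, "unbounded")
  expect_equal(estimate_radius(prof)$radius_um, 55)
  # already below 0.5 in the innermost annulus
  prof$fraction <- rep(0.2, 6)
  est0 <- estimate_radius(prof)
  expect_equal(est0$radius_um, 0)
  expect_equal(est0$flag, "all_below")
  expect_error(estimate_radius(prof[1, ]), "usable")
})

test_that("peak-time histograms conserve counts and yield FWHM durations", {
  fits <- radial_fit_table(n = 120, seed = 5)
  h <- peak_time_histogram(fits, bin_min = 5)
  expect_equal(sum(h$count), 120)
  # hand-built histogram: bins >= half max are {10, 14, 12} -> 15 min
  h2 <- data.frame(bin_lo = seq(0, 30, 5), bin_hi = seq(5, 35, 5),
                   mid = seq(2.5, 32.5, 5),
                   count = c(2, 10, 14, 12, 6, 3, 1))
  expect_equal(spread_duration(h2), 15)
  h2$count <- h2$count * 2   # scale invariance
  expect_equal(spread_duration(h2), 15)
  single <- data.frame(bin_lo = 0, bin_hi = 5, mid = 2.5, count = 4)
  expect_equal(spread_duration(single), 5)
})

test_that("cross-SPREAD correlations flag degenerate ensembles", {
  df <- data.frame(radius_um = c(30, 40, 50, 60),
                   velocity_um_per_min = c(1.0, 1.3, 1.6, 1.9),
                   max_amplitude = c(0.2, 0.25, 0.3, 0.35))
  s <- summarize_spreads(df)
  expect_gt(s$radius_velocity$r, 0.9)
  expect_gt(s$radius_amplitude$r, 0.9)
  expect_true(all(abs(c(s$radius_velocity$r, s$radius_amplitude$r)) <= 1))
  same <- df; same$radius_um <- 40
  expect_false(summarize_spreads(same)$radius_velocity$defined)
  expect_error(summarize_spreads(df[1:2, ]), "3 SPREADs")
})

test_that("candidate detection finds well-separated SPREADs", {
  f1 <- radial_fit_table(n = 80, origin = c(60, 60), seed = 6)
  f2 <- radial_fit_table(n = 80, origin = c(260, 240), seed = 7)
  f2$cell_id <- f2$cell_id + 100
  none <- radial_fit_table(n = 40, origin = c(160, 150), seed = 8)
  none$cell_id <- none$cell_id + 300
  none$responder <- FALSE
  none$peak_time <- NA_real_
  fits <- rbind(f1, f2, none)
  cand <- detect_spread_candidates(fits, grid_um = 40, min_count = 5)
  expect_gte(nrow(cand), 2)
  expect_lte(nrow(cand), sum(fits$responder))
  d1 <- min(sqrt((cand$x_um - 60)^2 + (cand$y_um - 60)^2))
  d2 <- min(sqrt((cand$x_um - 260)^2 + (cand$y_um - 240)^2))
  expect_lt(max(d1, d2), 20)
  # no responders, no candidates
  expect_equal(nrow(detect_spread_candidates(none)), 0)
})

test_that("the full SPREAD pipeline recovers generator geometry", {
  sc <- small_spread_scenario(seed = 17L, n_cells = 200)
  fits <- fit_pulses(sc$traces)
  sf <- analyze_spread(fits, sc$truth$origin_xy_um +
                         5 * sc$config$pixel_size_um,
                       pixel_size_um = sc$config$pixel_size_um)
  expect_lt(abs(sf$velocity_um_per_min - 1.93), 0.15)
  expect_lt(abs(sf$radius_um - 47.7), 5)
  expect_lt(sqrt(sum((sf$origin_um - c(75, 75))^2)), 6)
  expect_gt(sf$r2_linear, 0.9)
  expect_lt(abs(sf$sqrt_fit$r2 - sf$r2_linear), 0.1)
  expect_output(print(sf), "velocity")
  expect_named(coef(sf), c("velocity_um_per_min", "onset_min", "radius_um",
                           "duration_min", "max_amplitude"))
})
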