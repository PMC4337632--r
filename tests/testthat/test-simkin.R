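test_that("place_cells packs non-overlapping nuclei deterministically", {
  cfg <- tiny_config(n_cells = 4, field_size_um = 100,
                     nucleus_radius_um = 3)
  p1 <- place_cells(cfg)
  expect_equal(nrow(p1), 4)
  expect_true(all(p1$x_um >= 0 & p1$x_um <= 100))
  expect_gte(min(dist(p1[, c("x_um", "y_um")])), 6)
  expect_identical(p1, place_cells(cfg))
  p2 <- place_cells(cfg, method = "dart")
  expect_gte(min(dist(p2[, c("x_um", "y_um")])), 6)
  expect_identical(p2, place_cells(cfg, method = "dart"))
})

test_that("infeasible packing densities are rejected", {
  # 15 disks of radius 3 in a 20-um square exceeds the hexagonal limit
  expect_error(place_cells(tiny_config(n_cells = 15, field_size_um = 20,
                                       nucleus_radius_um = 3)),
               "packing")
  # below the disk bound but grid spacing under one diameter
  expect_error(place_cells(tiny_config(n_cells = 120, field_size_um = 60,
                                       nucleus_radius_um = 3)),
               "packing")
})

test_that("spread pulses follow onset delay, sigmoid and amplitude decay", {
  cfg <- tiny_config(n_cells = 1, n_frames = 241, frame_interval_min = 0.5,
                     noise_sd = 0, baseline_ratio_sd = 0)
  cells <- data.frame(cell_id = 1L, x_um = 19.3, y_um = 0)
  tr <- spread_truth(origin_xy_um = c(0, 0), onset_min = 10,
                     velocity_um_per_min = 1.93, amp0 = 0.3,
                     amp_decay_per_um = 0.005, radius_um = 60,
                     responder_steepness_um = 1e-3,  # always respond
                     pulse_width_min = 70.5)
  sim <- simulate_spread_traces(cells, tr, cfg)
  y <- sim$traces$ratio
  t <- sim$traces$t_min
  b <- cfg$baseline_ratio_mean
  # d / v = 10 min delay after the 10-min onset
  expect_equal(max(abs(y[t <= 20] - b)), 0)
  expect_gt(y[t == 21] - b, 0)
  # peak at t0 + tau/2 with linearly decayed amplitude
  amp <- 0.3 * (1 - 0.005 * 19.3)
  expect_equal(max(y) - b, amp, tolerance = 1e-3)
  expect_lt(abs(t[which.max(y)] - (20 + 70.5 / 2)), 0.5)
  # generator half-sine spends exactly (2/3) tau above half-maximum
  dur <- sum(y - b >= amp / 2) * 0.5
  expect_lt(abs(dur - 2 / 3 * 70.5), 1)
})

test_that("responder probability is 0.5 at the radius midpoint", {
  n <- 2000
  th <- runif(n, 0, 2 * pi)
  cells <- data.frame(cell_id = seq_len(n),
                      x_um = 200 + 47.7 * cos(th),
                      y_um = 200 + 47.7 * sin(th))
  cfg <- tiny_config(n_cells = n, field_size_um = 400, n_frames = 3,
                     seed = 4L)
  tr <- spread_truth(origin_xy_um = c(200, 200), radius_um = 47.7)
  sim <- simulate_spread_traces(cells, tr, cfg)
  expect_lt(abs(mean(sim$cells$responder) - 0.5), 0.04)
})

test_that("wound waves reach only cells within max_reach and repeat", {
  cfg <- tiny_config(n_cells = 3, n_frames = 200, frame_interval_min = 1,
                     noise_sd = 0, baseline_ratio_sd = 0)
  cells <- data.frame(cell_id = 1:3, x_um = c(14, 50, 150), y_um = 10)
  tr <- wound_truth(edge_polyline_um = rbind(c(0, 0), c(0, 80)),
                    wave_onsets_min = c(5, 95), velocity_um_per_min = 1.4,
                    max_reach_um = 100, amp0 = 0.25, responder_prob = 1,
                    pulse_width_min = 20)
  sim <- simulate_wound_traces(cells, tr, cfg)
  b <- cfg$baseline_ratio_mean
  y1 <- sim$traces$ratio[sim$traces$cell_id == 1]
  t <- sort(unique(sim$traces$t_min))
  # delay d / v = 10 min; two pulses, amplitude undecayed
  expect_equal(max(abs(y1[t <= 15] - b)), 0)
  expect_gt(y1[t == 16] - b, 0)
  peaks <- which(diff(sign(diff(y1))) == -2)
  expect_equal(length(peaks), 2)
  expect_equal(max(y1) - b, 0.25, tolerance = 1e-9)
  # cell beyond reach stays flat
  y3 <- sim$traces$ratio[sim$traces$cell_id == 3]
  expect_equal(max(abs(y3 - b)), 0)
})

test_that("rendered stacks encode ratio * CFP inside nuclei", {
  cfg <- tiny_config(n_cells = 1, n_frames = 1, cfp_level = 400)
  traces <- data.frame(cell_id = 1L, x_um = 40, y_um = 40, t_min = 0,
                       ratio = 1.5)
  st <- render_stack(traces, cfg)
  cfp <- get_channel(st, "CFP")[, , 1]
  fret <- get_channel(st, "FRET")[, , 1]
  expect_setequal(unique(as.vector(cfp)), c(0, 400))
  expect_equal(max(fret), 600)
  expect_equal(fret[cfp > 0] / cfp[cfp > 0], rep(1.5, sum(cfp > 0)))
  expect_error(render_stack(traces, tiny_config(field_size_um = 4,
                                                nucleus_radius_um = 3)),
               "too small")
})

test_that("division events follow the two-rate inhomogeneous model", {
  cfg <- field_config(seed = 31L)
  truths <- list(spread_truth(origin_xy_um = c(150, 150), onset_min = 60),
                 spread_truth(origin_xy_um = c(320, 300), onset_min = 240))
  # rate_out = 0: every event lies in a SPREAD area
  dv0 <- simulate_divisions(cfg, truths, rate_in = 500, rate_out = 0,
                            duration_hr = 8)
  expect_true(all(dv0$in_area))
  # homogeneous case: expected count = rate * volume
  ns <- vapply(1:200, function(i)
    nrow(simulate_divisions(field_config(seed = i), truths, 100, 100, 5)),
    0)
  expected <- 100 * (462 / 1000)^2 * 5
  expect_equal(mean(ns), expected, tolerance = 0.03)
})

test_that("fucci generator honours exact counts and phase encoding", {
  cfg <- tiny_config(n_cells = 50, field_size_um = 200, seed = 8L)
  fu <- simulate_fucci_field(cfg, sgm_fraction = 0.3, exact_count = TRUE,
                             noise_sd = 0)
  expect_equal(sum(fu$cells$phase == "S/G2/M"), round(50 * 0.3))
  g <- fu$cells$phase == "S/G2/M"
  i <- which(g)[1]; j <- which(!g)[1]
  px <- function(m, k) m[round(fu$cells$y_um[k]), round(fu$cells$x_um[k])]
  expect_gt(px(fu$mAG, i), px(fu$mKO2, i))
  expect_lt(px(fu$mAG, j), px(fu$mKO2, j))
  fu0 <- simulate_fucci_field(cfg, sgm_fraction = 0, noise_sd = 0)
  expect_true(all(fu0$cells$phase == "G0/G1"))
})

test_that("origin patterns are reproducible and match CSR geometry", {
  p1 <- simulate_origin_pattern(c(462, 462), n = 20, seed = 5L)
  expect_identical(p1, simulate_origin_pattern(c(462, 462), n = 20,
                                               seed = 5L))
  # offspring scale 0 collapses each cluster onto its parent
  cl <- simulate_origin_pattern(c(462, 462), mode = "clustered",
                                n_parents = 3, n_offspring = 4,
                                offspring_scale_um = 0, seed = 2L)
  expect_equal(nrow(unique(round(cl, 9))), 3)
  # toroidal mean NN distance for uniform points: 1 / (2 sqrt(n / A))
  nn_tor <- function(pts, L) {
    dx <- abs(outer(pts[, 1], pts[, 1], "-")); dx <- pmin(dx, L - dx)
    dy <- abs(outer(pts[, 2], pts[, 2], "-")); dy <- pmin(dy, L - dy)
    dm <- sqrt(dx^2 + dy^2); diag(dm) <- Inf
    mean(apply(dm, 1, min))
  }
  m <- mean(vapply(1:200, function(i)
    nn_tor(simulate_origin_pattern(c(1, 1), n = 400, seed = i), 1), 0))
  expect_equal(m, 1 / (2 * sqrt(400)), tolerance = 0.03)
})

test_that("generation is bit-reproducible under a fixed seed", {
  s1 <- small_spread_scenario(seed = 3L, n_cells = 30)
  s2 <- small_spread_scenario(seed = 3L, n_cells = 30)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$cell_truth, s2$cell_truth)
})
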