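test_that("the nearest-neighbour statistic is exact and homogeneous", {
  pts <- cbind(c(0, 3, 10), c(0, 0, 0))
  expect_equal(nn_statistic(pts), 13 / 3)
  expect_equal(nn_statistic(pts * 2.5), 2.5 * 13 / 3)
  expect_equal(nn_statistic(rbind(c(1, 1), c(1, 1))), 0)
  expect_error(nn_statistic(cbind(1, 1)), "2 points")
})

test_that("division-rate comparison uses exact spatio-temporal volumes", {
  # single SPREAD area fully inside the field: volume = pi r^2 * 1 hr
  tr <- spread_truth(origin_xy_um = c(231, 231), onset_min = 60)
  dv <- data.frame(x_um = c(231, 240, 10, 450), y_um = c(231, 231, 10, 450),
                   t_min = c(90, 90, 90, 400))
  out <- division_rate_ratio(dv, list(tr), field_size_um = 462, span_hr = 10)
  vol_disc <- pi * 0.1^2 * 1
  expect_equal(out$volume_in, vol_disc, tolerance = 0.01)
  expect_equal(out$n_in, 2)
  expect_equal(out$n_out, 2)
  expect_equal(out$rate_in, 2 / out$volume_in)
  expect_equal(out$ratio, (2 / out$volume_in) / (2 / out$volume_out))
  # overlapping cylinders are unioned, not double counted
  tr2 <- spread_truth(origin_xy_um = c(235, 231), onset_min = 60)
  out2 <- division_rate_ratio(dv, list(tr, tr2), 462, 10)
  expect_lt(out2$volume_in, 2 * vol_disc)
  # refining the grid moves the volume by < 0.5%
  fine <- division_rate_ratio(dv, list(tr, tr2), 462, 10, grid_um = 0.5)
  expect_equal(out2$volume_in, fine$volume_in, tolerance = 0.005)
  # and a Monte Carlo oracle agrees within its sampling error
  set.seed(8)
  xs <- runif(2e6, 0, 462); ys <- runif(2e6, 0, 462)
  ts <- runif(2e6, 0, 600)
  frac <- mean(erkwave:::in_spread_area(xs, ys, ts, list(tr, tr2)))
  expect_equal(out2$volume_in, frac * (0.462^2 * 10), tolerance = 0.02)
})

test_that("recovered division-rate ratio matches the generator on average", {
  truths <- list(spread_truth(origin_xy_um = c(120, 150), onset_min = 60),
                 spread_truth(origin_xy_um = c(330, 280), onset_min = 240),
                 spread_truth(origin_xy_um = c(231, 380), onset_min = 420))
  ratios <- vapply(1:15, function(i) {
    dv <- simulate_divisions(field_config(seed = 1000L + i), truths,
                             rate_in = 400, rate_out = 200,
                             duration_hr = 10)
    division_rate_ratio(dv, truths, 462, 10)$ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.35)
  # equal rates give a ratio near one
  r1 <- vapply(1:15, function(i) {
    dv <- simulate_divisions(field_config(seed = 2000L + i), truths,
                             rate_in = 250, rate_out = 250,
                             duration_hr = 10)
    division_rate_ratio(dv, truths, 462, 10)$ratio
  }, 0)
  expect_lt(abs(mean(r1) - 1), 0.2)
})

test_that("Monte Carlo CSR p-values behave at their extremes", {
  pts <- matrix(10, 5, 2)  # all coincident: minimal attainable p
  ct <- mc_csr_test(pts, c(100, 100), n_trials = 999, seed = 2L)
  expect_equal(ct$p_value, 1 / 1000)
  expect_output(print(ct), "one-sided")
  # toroidal null mean matches 1 / (2 sqrt(lambda))
  ct2 <- mc_csr_test(cbind(runif(400), runif(400)), c(1, 1),
                     n_trials = 300, seed = 3L, metric = "toroidal")
  expect_equal(ct2$null_mean, 1 / (2 * sqrt(400)), tolerance = 0.03)
})

test_that("CSR test is calibrated under the null and powerful vs clusters", {
  # type-I calibration at reduced trial count for the routine suite
  pvals <- vapply(1:400, function(i) {
    pts <- simulate_origin_pattern(c(462, 462), n = 20, seed = 5000L + i)
    mc_csr_test(pts, c(462, 462), n_trials = 2000, seed = 6000L + i)$p_value
  }, 0)
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.04)
  expect_lt(abs(mean(pvals <= 0.2) - 0.2), 0.08)
  # power against Thomas clusters at the published-analysis scale
  pclu <- vapply(1:25, function(i) {
    pts <- simulate_origin_pattern(c(462, 462), mode = "clustered",
                                   n_parents = 4, n_offspring = 5,
                                   offspring_scale_um = 20,
                                   seed = 7000L + i)
    mc_csr_test(pts, c(462, 462), n_trials = 2000, seed = 8000L + i)$p_value
  }, 0)
  expect_gte(mean(pclu <= 0.01), 0.9)
})

test_that("follicle-proximity fractions follow exact geometry", {
  # one zone disk centred in the field; origin at its centre
  out <- follicle_proximity(cbind(231, 231), cbind(231, 231),
                            field_size_um = 462, zone_radius_um = 50)
  expect_equal(out$fraction_origins_in_zone, 1)
  expect_equal(out$fraction_area_in_zone, pi * 50^2 / 462^2,
               tolerance = 0.005)
  expect_equal(follicle_proximity(cbind(10, 10), matrix(numeric(0), 0, 2),
                                  462)$fraction_origins_in_zone, 0)
  # zone covering the whole field
  big <- follicle_proximity(cbind(100, 100), cbind(231, 231), 462,
                            zone_radius_um = 400)
  expect_equal(big$fraction_origins_in_zone, 1)
  expect_equal(big$fraction_area_in_zone, 1)
})
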