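make_stack <- function(fret, cfp, px = 1, dt = 1) {
  d <- array(0, c(dim(fret)[1], dim(fret)[2],
                  if (length(dim(fret)) == 3) dim(fret)[3] else 1, 2),
             dimnames = list(NULL, NULL, NULL, c("FRET", "CFP")))
  d[, , , "FRET"] <- fret
  d[, , , "CFP"] <- cfp
  image_stack(d, px, dt)
}

test_that("ratio stacks divide channels and mask low donor signal", {
  fret <- matrix(600, 4, 4); cfp <- matrix(400, 4, 4)
  cfp[1, 1] <- 0
  r <- compute_ratio_stack(make_stack(fret, cfp), cfp_floor = 1)
  expect_equal(r[2, 2, 1], 1.5)
  expect_true(is.na(r[1, 1, 1]))
  # invariance under common rescaling of both channels
  r2 <- compute_ratio_stack(make_stack(fret * 7, cfp * 7), cfp_floor = 1)
  expect_equal(r, r2)
  expect_error(compute_ratio_stack(
    image_stack(array(1, c(2, 2, 1, 1),
                      dimnames = list(NULL, NULL, NULL, "CFP")), 1, 1)),
    "missing channel")
})

test_that("the 3x3 median filter is the identity on constant regions", {
  fret <- matrix(450, 8, 8); cfp <- matrix(300, 8, 8)
  r <- compute_ratio_stack(make_stack(fret, cfp), median_filter = TRUE)
  expect_equal(as.vector(r[, , 1]), rep(1.5, 64))
  # a single-pixel outlier is removed
  fret[4, 4] <- 3000
  rf <- compute_ratio_stack(make_stack(fret, cfp), median_filter = TRUE)
  expect_equal(rf[4, 4, 1], 1.5)
})

test_that("temporal projection averages frames mask-aware", {
  r <- array(rep(c(1.0, 1.1, 1.2, 1.3, 1.4), each = 4), c(2, 2, 5))
  p <- project_mean(r, 5)
  expect_equal(dim(p)[3], 1)
  expect_equal(p[1, 1, 1], 1.2)
  expect_equal(project_mean(r, 1), r)
  r[1, 1, 2] <- NA  # masked frame ignored at that pixel
  p2 <- project_mean(r, 5)
  expect_equal(p2[1, 1, 1], mean(c(1.0, 1.2, 1.3, 1.4)))
  expect_error(project_mean(r, 0), "window")
  expect_error(project_mean(r, 9), "window")
  ps <- project_mean(r, 3, mode = "sliding")
  expect_equal(dim(ps), dim(r))
})

test_that("IMD rendering quantises into 8 hues x 32 grades monotonically", {
  ratio <- matrix(seq(0.8, 2.4, length.out = 64), 8, 8)
  cfp <- matrix(seq(0, 500, length.out = 64), 8, 8)
  out <- render_imd(ratio, cfp, ratio_range = c(1, 2),
                    intensity_range = c(0, 500))
  expect_true(all(out$hue_bin %in% 0:7))
  expect_true(all(out$grade %in% 0:31))
  # clipping at both ends, monotone in ratio
  expect_equal(out$hue_bin[ratio <= 1], rep(0L, sum(ratio <= 1)))
  expect_equal(out$hue_bin[ratio >= 2][-1] * 0 + 7L,
               out$hue_bin[ratio >= 2][-1])
  ord <- order(ratio)
  expect_true(all(diff(out$hue_bin[ord]) >= 0))
  # midpoint of the range falls into bin 4 (half-open bins)
  mid <- render_imd(matrix(1.5, 1, 1), matrix(500, 1, 1),
                    ratio_range = c(1, 2), intensity_range = c(0, 500))
  expect_equal(as.vector(mid$hue_bin), 4L)
  expect_equal(as.vector(mid$grade), 31L)
  gold <- render_imd(ratio, cfp, ratio_range = c(1, 2),
                     intensity_range = c(0, 500), mode = "gold")
  expect_equal(as.vector(gold$rgb[, , 3]), rep(0, 64))  # no blue in gold
  expect_lte(nrow(unique(matrix(out$rgb, ncol = 3))), 8 * 32 + 1)
})

test_that("adaptive-threshold segmentation keeps nuclei in the size gate", {
  img <- matrix(10, 120, 120)
  centers <- expand.grid(x = c(20, 50, 80, 110), y = c(20, 50, 80))
  xg <- col(img) - 0.5
  yg <- row(img) - 0.5
  for (i in seq_len(nrow(centers)))
    img[(xg - centers$x[i])^2 + (yg - centers$y[i])^2 <= 3^2] <- 110
  # one blob below the minimum diameter
  img[(xg - 110)^2 + (yg - 110)^2 <= 1] <- 110
  labs <- segment_nuclei(img, pixel_size_um = 1)
  expect_equal(nrow(labs$table), 12)
  eqd <- 2 * sqrt(labs$table$area_px / pi)
  expect_true(all(eqd >= 4 & eqd <= 10))
  # centroids land on the planted centres
  near <- vapply(seq_len(12), function(i)
    min(sqrt((centers$x - labs$table$x_um[i])^2 +
             (centers$y - labs$table$y_um[i])^2)), 0)
  expect_lt(max(near), 1)
  # uniform image: no objects, not an error
  expect_equal(nrow(segment_nuclei(matrix(5, 40, 40))$table), 0)
})

test_that("trace extraction recovers generator ratios on noiseless renders", {
  cfg <- tiny_config(n_cells = 12, n_frames = 5)
  cells <- place_cells(cfg)
  sim <- simulate_spread_traces(
    cells, spread_truth(origin_xy_um = c(40, 40), radius_um = 30,
                        onset_min = 1, pulse_width_min = 6), cfg)
  st <- render_stack(sim$traces, cfg)
  ratio <- compute_ratio_stack(st)
  labs <- segment_nuclei(apply(get_channel(st, "CFP"), c(1, 2), mean),
                         cfg$pixel_size_um)
  expect_equal(nrow(labs$table), cfg$n_cells)
  tr <- extract_traces(ratio, labs, cfg$frame_interval_min)
  m <- vapply(seq_len(nrow(labs$table)), function(i)
    which.min((cells$x_um - labs$table$x_um[i])^2 +
              (cells$y_um - labs$table$y_um[i])^2), 0L)
  for (i in seq_len(nrow(labs$table))) {
    got <- tr$ratio[tr$cell_id == labs$table$label[i]]
    want <- sim$traces$ratio[sim$traces$cell_id == cells$cell_id[m[i]]]
    expect_lt(max(abs(got - want)), 1e-6)
  }
  # ratio-of-sums agrees on uniform-donor renders
  tr2 <- extract_traces(st, labs, method = "ratio_of_sums")
  expect_equal(tr2$ratio, tr$ratio, tolerance = 1e-9)
})

test_that("field-mean ratio is mask-aware and consistent with traces", {
  r <- array(1.2, c(4, 4, 3))
  expect_equal(mean_field_ratio(r), rep(1.2, 3))
  r[, 1:2, 2] <- 1.0; r[, 3:4, 2] <- 2.0
  expect_equal(mean_field_ratio(r)[2], 1.5)
  r[, , 3] <- NA
  expect_true(is.na(mean_field_ratio(r)[3]))
})
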