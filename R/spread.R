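responders_of <- function(fits) {
  stopifnot(is.data.frame(fits))
  r <- fits[fits$responder & !is.na(fits$peak_time), , drop = FALSE]
  r
}

#' Optimise the SPREAD origin on an integer pixel grid
#'
#' Starting from a visually determined origin, every integer pixel offset
#' within `search_radius_px` in x and y is evaluated and the position
#' maximising the Pearson correlation between responder distance and
#' peak time is returned. Ties are broken by the smallest offset norm,
#' then lexicographically.
#'
#' @param fits A [fit_pulses()] table (needs `x_um`, `y_um`, `responder`,
#'   `peak_time`).
#' @param initial_origin_um Length-2 initial origin guess (micrometres).
#' @param pixel_size_um Micrometres per pixel of the search grid.
#' @param search_radius_px Half-width of the search square in pixels.
#' @return List with `origin_um`, `correlation`, `offset_px`.
#' @export
optimize_origin <- function(fits, initial_origin_um, pixel_size_um = 1,
                            search_radius_px = 10) {
  r <- responders_of(fits)
  if (nrow(r) < 3) stop("origin optimisation needs at least 3 responders")
  if (stats::sd(r$peak_time) == 0)
    stop("all responder peak times are equal; correlation undefined")
  offs <- seq(-search_radius_px, search_radius_px)
  grid <- expand.grid(dx = offs, dy = offs)
  cors <- vapply(seq_len(nrow(grid)), function(i) {
    ox <- initial_origin_um[1] + grid$dx[i] * pixel_size_um
    oy <- initial_origin_um[2] + grid$dy[i] * pixel_size_um
    d <- sqrt((r$x_um - ox)^2 + (r$y_um - oy)^2)
    if (stats::sd(d) == 0) return(-Inf)
    stats::cor(d, r$peak_time)
  }, 0)
  best <- max(cors)
  cand <- which(cors >= best - 1e-12)
  norm2 <- grid$dx[cand]^2 + grid$dy[cand]^2
  cand <- cand[order(norm2, grid$dx[cand], grid$dy[cand])]
  i <- cand[1]
  list(origin_um = c(initial_origin_um[1] + grid$dx[i] * pixel_size_um,
                     initial_origin_um[2] + grid$dy[i] * pixel_size_um),
       correlation = cors[i],
       offset_px = c(grid$dx[i], grid$dy[i]))
}

#' Estimate the propagation velocity of a SPREAD
#'
#' Ordinary least squares of responder distance from the origin
#' (response) on peak time (predictor): the slope is the radial velocity
#' in um/min and the time at which the regression line crosses zero
#' distance is the SPREAD onset.
#'
#' @param fits A [fit_pulses()] table.
#' @param origin_um Length-2 origin (micrometres).
#' @return List `velocity_um_per_min`, `onset_min`, `r2`, `n`, and
#'   `propagating` (`FALSE` when the slope is not positive).
#' @export
estimate_velocity <- function(fits, origin_um) {
  r <- responders_of(fits)
  if (nrow(r) < 3) stop("velocity estimation needs at least 3 responders")
  d <- sqrt((r$x_um - origin_um[1])^2 + (r$y_um - origin_um[2])^2)
  if (stats::sd(r$peak_time) == 0) stop("singular design: constant peak times")
  fit <- stats::lm(d ~ r$peak_time)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d - mean(d))^2)
  list(velocity_um_per_min = slope,
       onset_min = if (slope != 0) -intercept / slope else NA_real_,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_, n = nrow(r),
       propagating = slope > 0)
}

#' Square-root propagation fit
#'
#' Least-squares fit of `d = a * sqrt(t - t0)` to responder
#' distance/peak-time pairs, with `t0` constrained not to exceed the
#' earliest peak time. Its coefficient of determination is compared with
#' the linear fit's to judge whether the wave decelerates.
#'
#' @inheritParams estimate_velocity
#' @return List `a` (um/min^0.5), `t0_min`, `r2`, `converged`.
#' @export
fit_sqrt_law <- function(fits, origin_um) {
  r <- responders_of(fits)
  if (nrow(r) < 3) stop("sqrt-law fit needs at least 3 responders")
  d <- sqrt((r$x_um - origin_um[1])^2 + (r$y_um - origin_um[2])^2)
  t <- r$peak_time
  tmin <- min(t)
  resid_fun <- function(p) {
    dt <- pmax(t - p[2], 0)
    d - p[1] * sqrt(dt)
  }
  span <- max(diff(range(t)), 1)
  best <- NULL
  for (off in c(1e-3, 0.1 * span, 0.5 * span, 2 * span)) {
    a0 <- max(d) / sqrt(max(max(t) - (tmin - off), 1e-6))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, tmin - off), fn = resid_fun,
                         upper = c(Inf, tmin), lower = c(0, -Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(ans)) {
      ss <- sum(resid_fun(ans$par)^2)
      if (is.null(best) || ss < best$ss)
        best <- list(par = ans$par, ss = ss)
    }
  }
  if (is.null(best))
    return(list(a = NA_real_, t0_min = NA_real_, r2 = NA_real_,
                converged = FALSE))
  r2 <- 1 - best$ss / sum((d - mean(d))^2)
  list(a = best$par[1], t0_min = best$par[2], r2 = r2, converged = TRUE)
}

#' Responder fraction in annuli around the origin
#'
#' Bins all classified cells into annuli of `bin_width_um` around the
#' origin and reports the responder fraction per annulus. Annuli with
#' fewer than `min_cells_per_bin` cells are flagged unusable and ignored
#' by the radius estimator (the field convention for sparsely populated
#' central annuli). A cumulative-disk mode is available.
#'
#' @inheritParams estimate_velocity
#' @param bin_width_um Annulus width (micrometres).
#' @param min_cells_per_bin Minimum cells for a usable annulus.
#' @param cumulative Use cumulative disks instead of annuli.
#' @return Data frame of class `responder_profile`: `bin_lo`, `bin_hi`,
#'   `center_um`, `n_cells`, `n_responders`, `fraction`, `usable`.
#' @export
responder_fraction_profile <- function(fits, origin_um, bin_width_um = 10,
                                       min_cells_per_bin = 5,
                                       cumulative = FALSE) {
  d <- sqrt((fits$x_um - origin_um[1])^2 + (fits$y_um - origin_um[2])^2)
  nb <- ceiling(max(d) / bin_width_um)
  lo <- (seq_len(nb) - 1) * bin_width_um
  hi <- lo + bin_width_um
  idx <- pmin(floor(d / bin_width_um) + 1, nb)
  n_cells <- tabulate(idx, nb)
  n_resp <- tabulate(idx[fits$responder], nb)
  if (cumulative) {
    n_cells <- cumsum(n_cells)
    n_resp <- cumsum(n_resp)
  }
  frac <- ifelse(n_cells > 0, n_resp / n_cells, NA_real_)
  out <- data.frame(bin_lo = lo, bin_hi = hi, center_um = (lo + hi) / 2,
                    n_cells = n_cells, n_responders = n_resp,
                    fraction = frac,
                    usable = n_cells >= min_cells_per_bin)
  class(out) <- c("responder_profile", "data.frame")
  out
}

#' SPREAD radius from the responder-fraction profile
#'
#' Moving outward over usable annuli, the radius is the distance at which
#' the responder fraction first drops below 50%, linearly interpolated
#' between the centres of the straddling annuli. If no annulus falls
#' below 0.5 the outermost usable centre is returned with flag
#' `"unbounded"`; if already the innermost usable annulus is below 0.5
#' the radius is 0 with flag `"all_below"`. The inflection-point variant
#' (centre of the steepest decrease) is reported as a secondary estimate.
#'
#' @param profile A [responder_fraction_profile()].
#' @return List `radius_um`, `flag`, `radius_inflection_um`.
#' @export
estimate_radius <- function(profile) {
  p <- profile[profile$usable & !is.na(profile$fraction), , drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 usable annuli")
  # secondary: inflection = centre of steepest drop between usable bins
  slopes <- diff(p$fraction) / diff(p$center_um)
  infl <- if (any(slopes < 0))
    mean(p$center_um[which.min(slopes) + c(0, 1)]) else NA_real_
  below <- which(p$fraction < 0.5)
  if (!length(below)) {
    return(list(radius_um = p$center_um[nrow(p)], flag = "unbounded",
                radius_inflection_um = infl))
  }
  i <- below[1]
  if (i == 1) {
    return(list(radius_um = 0, flag = "all_below",
                radius_inflection_um = infl))
  }
  f1 <- p$fraction[i - 1]; f2 <- p$fraction[i]
  c1 <- p$center_um[i - 1]; c2 <- p$center_um[i]
  radius <- c1 + (c2 - c1) * (f1 - 0.5) / (f1 - f2)
  list(radius_um = radius, flag = "ok", radius_inflection_um = infl)
}

#' Histogram of responder peak times
#'
#' @param fits A [fit_pulses()] table.
#' @param bin_min Bin width in minutes.
#' @return Data frame `bin_lo`, `bin_hi`, `mid`, `count` of class
#'   `peak_time_histogram`.
#' @export
peak_time_histogram <- function(fits, bin_min = 5) {
  r <- responders_of(fits)
  if (!nrow(r)) stop("no responders")
  lo0 <- floor(min(r$peak_time) / bin_min) * bin_min
  hi0 <- ceiling(max(r$peak_time) / bin_min) * bin_min
  if (hi0 == lo0) hi0 <- lo0 + bin_min
  breaks <- seq(lo0, hi0, by = bin_min)
  counts <- graphics::hist(r$peak_time, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                    count = counts)
  class(out) <- c("peak_time_histogram", "data.frame")
  out
}

#' SPREAD-level duration from the peak-time histogram
#'
#' Width at half maximum of the responder peak-time histogram: the span
#' from the first to the last bin whose count reaches half the maximum,
#' inclusive, in minutes. This operationalises the per-SPREAD duration
#' as the period during which responders keep peaking at an appreciable
#' rate.
#'
#' @param histogram A [peak_time_histogram()].
#' @return Duration in minutes.
#' @export
spread_duration <- function(histogram) {
  stopifnot(nrow(histogram) >= 1)
  half <- max(histogram$count) / 2
  idx <- which(histogram$count >= half)
  bw <- histogram$bin_hi[1] - histogram$bin_lo[1]
  (max(idx) - min(idx) + 1) * bw
}

#' Cross-SPREAD correlation report
#'
#' Pearson correlations (with two-sided tests) of SPREAD radius against
#' propagation velocity and against maximal ERK amplitude, over a set of
#' per-SPREAD summaries.
#'
#' @param summaries Data frame with columns `radius_um`,
#'   `velocity_um_per_min`, `max_amplitude` (one row per SPREAD), or a
#'   list of `spread_fit` objects.
#' @return List of two `htest`-like entries (`radius_velocity`,
#'   `radius_amplitude`), each with `r`, `p`, `n`, `defined`.
#' @export
summarize_spreads <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, lapply(summaries, function(s)
      data.frame(radius_um = s$radius_um,
                 velocity_um_per_min = s$velocity_um_per_min,
                 max_amplitude = s$max_amplitude)))
  if (nrow(summaries) < 3) stop("need at least 3 SPREADs")
  pair <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, n = length(x),
                  defined = FALSE))
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         defined = TRUE)
  }
  list(radius_velocity = pair(summaries$radius_um,
                              summaries$velocity_um_per_min),
       radius_amplitude = pair(summaries$radius_um,
                               summaries$max_amplitude))
}

#' Propose SPREAD candidate origins from classified cells
#'
#' Responder positions are binned on a spatial grid; grid cells that are
#' local count maxima with at least `min_count` responders yield a
#' candidate whose origin is the responder centroid over the 3x3
#' neighbourhood and whose onset estimate is the 10th percentile of their
#' peak times. A coarse automated stand-in for visual SPREAD scoring,
#' intended to seed [optimize_origin()].
#'
#' @param fits A [fit_pulses()] table.
#' @param grid_um Spatial bin size (micrometres).
#' @param min_count Minimum responders in the peak cell.
#' @return Data frame `x_um`, `y_um`, `onset_min`, `n_responders`
#'   (possibly empty).
#' @export
detect_spread_candidates <- function(fits, grid_um = 40, min_count = 3) {
  r <- responders_of(fits)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      onset_min = numeric(0), n_responders = integer(0))
  if (!nrow(r)) return(empty)
  gx <- floor(r$x_um / grid_um); gy <- floor(r$y_um / grid_um)
  nxb <- max(gx) + 1L; nyb <- max(gy) + 1L
  counts <- matrix(0L, nyb + 2L, nxb + 2L)   # pad with zero border
  for (i in seq_len(nrow(r)))
    counts[gy[i] + 2L, gx[i] + 2L] <- counts[gy[i] + 2L, gx[i] + 2L] + 1L
  cand <- list()
  for (cy in seq_len(nyb)) for (cx in seq_len(nxb)) {
    v <- counts[cy + 1L, cx + 1L]
    if (v < min_count) next
    nb <- counts[cy:(cy + 2L), cx:(cx + 2L)]
    if (v < max(nb)) next
    if (v == max(nb) && sum(nb == v) > 1) {
      # tie within neighbourhood: keep only the lexicographically first
      pos <- which(nb == v, arr.ind = TRUE)
      if (!(pos[1, 1] == 2 && pos[1, 2] == 2)) next
    }
    sel <- abs(gx - (cx - 1L)) <= 1 & abs(gy - (cy - 1L)) <= 1
    cand[[length(cand) + 1L]] <- data.frame(
      x_um = mean(r$x_um[sel]), y_um = mean(r$y_um[sel]),
      onset_min = unname(stats::quantile(r$peak_time[sel], 0.1)),
      n_responders = sum(sel))
  }
  if (!length(cand)) return(empty)
  do.call(rbind, cand)
}

#' Full single-SPREAD analysis
#'
#' Runs the complete per-SPREAD pipeline on a classified cell table:
#' origin optimisation, distance-versus-peak-time velocity regression,
#' square-root fit, responder-fraction profile with radius estimation,
#' peak-time histogram with the half-maximum SPREAD duration, and the
#' maximal responder amplitude.
#'
#' @param fits A [fit_pulses()] table (or a trace table, which is then
#'   classified with `config`).
#' @param origin_guess_um Length-2 initial origin guess.
#' @param pixel_size_um Pixel size of the origin search grid.
#' @param search_radius_px Origin search half-width in pixels.
#' @param bin_width_um Annulus width for the responder profile.
#' @param peak_bin_min Peak-time histogram bin (minutes).
#' @param config A [fit_config()] (used only when `fits` is a trace
#'   table).
#' @return Object of class `spread_fit`.
#' @export
analyze_spread <- function(fits, origin_guess_um, pixel_size_um = 1,
                           search_radius_px = 10, bin_width_um = 10,
                           peak_bin_min = 5, config = fit_config()) {
  if (!inherits(fits, "pulse_fit_set") && "ratio" %in% names(fits))
    fits <- fit_pulses(fits, config)
  opt <- optimize_origin(fits, origin_guess_um, pixel_size_um,
                         search_radius_px)
  vel <- estimate_velocity(fits, opt$origin_um)
  sq <- fit_sqrt_law(fits, opt$origin_um)
  prof <- responder_fraction_profile(fits, opt$origin_um, bin_width_um)
  rad <- estimate_radius(prof)
  hist <- peak_time_histogram(fits, peak_bin_min)
  r <- responders_of(fits)
  out <- list(origin_um = opt$origin_um,
              origin_correlation = opt$correlation,
              onset_min = vel$onset_min,
              velocity_um_per_min = vel$velocity_um_per_min,
              r2_linear = vel$r2,
              sqrt_fit = sq,
              radius_um = rad$radius_um, radius_flag = rad$flag,
              radius_inflection_um = rad$radius_inflection_um,
              duration_min = spread_duration(hist),
              max_amplitude = max(r$amplitude),
              n_responders = nrow(r), n_cells = nrow(fits),
              profile = prof, histogram = hist, fits = fits)
  class(out) <- "spread_fit"
  out
}

#' @export
print.spread_fit <- function(x, ...) {
  cat("SPREAD analysis\n")
  cat(sprintf("  origin (%.1f, %.1f) um, onset %.1f min (peak-time corr %.3f)\n",
              x$origin_um[1], x$origin_um[2], x$onset_min,
              x$origin_correlation))
  cat(sprintf("  velocity %.2f um/min (R^2 %.3f); sqrt fit a = %.2f, R^2 %.3f\n",
              x$velocity_um_per_min, x$r2_linear, x$sqrt_fit$a,
              x$sqrt_fit$r2))
  cat(sprintf("  radius %.1f um [%s] (inflection %.1f um), duration %.0f min\n",
              x$radius_um, x$radius_flag, x$radius_inflection_um,
              x$duration_min))
  cat(sprintf("  %d responders / %d cells, max amplitude %.3f\n",
              x$n_responders, x$n_cells, x$max_amplitude))
  invisible(x)
}

#' @export
coef.spread_fit <- function(object, ...) {
  c(velocity_um_per_min = object$velocity_um_per_min,
    onset_min = object$onset_min,
    radius_um = object$radius_um,
    duration_min = object$duration_min,
    max_amplitude = object$max_amplitude)
}

#' @export
summary.spread_fit <- function(object, ...) {
  object
}

#' @export
plot.spread_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  r <- responders_of(x$fits)
  d <- sqrt((r$x_um - x$origin_um[1])^2 + (r$y_um - x$origin_um[2])^2)
  plot(r$peak_time, d, pch = 16, cex = 0.7,
       xlab = "peak time (min)", ylab = "distance from origin (um)",
       main = sprintf("v = %.2f um/min", x$velocity_um_per_min))
  graphics::abline(-x$onset_min * x$velocity_um_per_min,
                   x$velocity_um_per_min, col = "firebrick")
  p <- x$profile[x$profile$usable, ]
  plot(p$center_um, p$fraction, type = "b", ylim = c(0, 1),
       xlab = "distance (um)", ylab = "responder fraction",
       main = sprintf("radius %.1f um", x$radius_um))
  graphics::abline(h = 0.5, lty = 2); graphics::abline(v = x$radius_um,
                                                       col = "firebrick")
  graphics::barplot(x$histogram$count, names.arg = x$histogram$mid,
                    xlab = "peak time (min)", ylab = "responders",
                    main = sprintf("duration %.0f min", x$duration_min))
  invisible(x)
}
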