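#' Division rates inside and outside SPREAD areas
#'
#' The SPREAD area is the spatio-temporal union of cylinders: within
#' `radius_um` of each origin and within `window_hr` after its onset,
#' clipped to the field and the observation span. Division rates
#' (events/mm^2/hr) inside and outside the union are compared; the
#' union volume is computed by pixel counting at `grid_um` resolution
#' over the distinct time intervals between onset/offset breakpoints.
#'
#' @param divisions Data frame `x_um`, `y_um`, `t_min`.
#' @param truths List of [spread_truth()] (origins and onsets), or a data
#'   frame with `x_um`, `y_um`, `onset_min`.
#' @param field_size_um Side of the square field (um).
#' @param span_hr Total observation span (hours).
#' @param radius_um,window_hr SPREAD-area definition.
#' @param grid_um Rasterisation step for the union area (um).
#' @return List `rate_in`, `rate_out` (events/mm^2/hr), `ratio`,
#'   `volume_in`, `volume_out` (mm^2 hr), `n_in`, `n_out`, and
#'   `ratio_defined`.
#' @export
division_rate_ratio <- function(divisions, truths, field_size_um, span_hr,
                                radius_um = 100, window_hr = 1,
                                grid_um = 2) {
  stopifnot(nrow(divisions) >= 1, span_hr > 0)
  if (is.data.frame(truths)) {
    truths <- lapply(seq_len(nrow(truths)), function(i)
      list(origin_xy_um = c(truths$x_um[i], truths$y_um[i]),
           onset_min = truths$onset_min[i]))
  }
  if (!is.null(truths$origin_xy_um)) truths <- list(truths)
  L <- field_size_um
  # time breakpoints: interval boundaries where the active disk set changes
  bp <- sort(unique(c(0, span_hr * 60,
                      unlist(lapply(truths, function(tr)
                        c(tr$onset_min, tr$onset_min + window_hr * 60))))))
  bp <- bp[bp >= 0 & bp <= span_hr * 60]
  g <- seq(grid_um / 2, L - grid_um / 2, by = grid_um)
  xs <- rep(g, times = length(g)); ys <- rep(g, each = length(g))
  vol_in <- 0
  for (i in seq_len(length(bp) - 1)) {
    tmid <- (bp[i] + bp[i + 1]) / 2
    active <- Filter(function(tr)
      tmid >= tr$onset_min && tmid <= tr$onset_min + window_hr * 60, truths)
    if (!length(active)) next
    inside <- rep(FALSE, length(xs))
    for (tr in active)
      inside <- inside | ((xs - tr$origin_xy_um[1])^2 +
                          (ys - tr$origin_xy_um[2])^2 <= radius_um^2)
    area_mm2 <- sum(inside) * (grid_um / 1000)^2
    vol_in <- vol_in + area_mm2 * (bp[i + 1] - bp[i]) / 60
  }
  vol_total <- (L / 1000)^2 * span_hr
  vol_out <- vol_total - vol_in
  inside_ev <- in_spread_area(divisions$x_um, divisions$y_um,
                              divisions$t_min, truths, radius_um, window_hr)
  n_in <- sum(inside_ev); n_out <- sum(!inside_ev)
  rate_in <- if (vol_in > 0) n_in / vol_in else NA_real_
  rate_out <- if (vol_out > 0) n_out / vol_out else NA_real_
  ratio_defined <- !is.na(rate_in) && !is.na(rate_out) && rate_out > 0
  list(rate_in = rate_in, rate_out = rate_out,
       ratio = if (ratio_defined) rate_in / rate_out else NA_real_,
       volume_in = vol_in, volume_out = vol_out,
       n_in = n_in, n_out = n_out, ratio_defined = ratio_defined)
}

#' Mean nearest-neighbour distance
#'
#' @param points Two-column matrix of coordinates.
#' @return Mean over points of the distance to the nearest other point.
#' @export
nn_statistic <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2) stop("need at least 2 points")
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

# Mean NN distance for B trials of n uniform points in an Lx x Ly
# rectangle, vectorised over trials (pairwise for small n, per-trial
# dist() otherwise). Toroidal metric wraps both axes.
null_nn_batch <- function(B, n, Lx, Ly, metric = "planar") {
  if (n <= 60) {
    x <- matrix(stats::runif(B * n, 0, Lx), B, n)
    y <- matrix(stats::runif(B * n, 0, Ly), B, n)
    nnd <- matrix(Inf, B, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- abs(x[, i] - x[, j]); dy <- abs(y[, i] - y[, j])
      if (metric == "toroidal") {
        dx <- pmin(dx, Lx - dx); dy <- pmin(dy, Ly - dy)
      }
      d <- sqrt(dx^2 + dy^2)
      nnd[, i] <- pmin(nnd[, i], d)
      nnd[, j] <- pmin(nnd[, j], d)
    }
    rowMeans(nnd)
  } else {
    vapply(seq_len(B), function(b) {
      pts <- cbind(stats::runif(n, 0, Lx), stats::runif(n, 0, Ly))
      if (metric == "toroidal") {
        dx <- abs(outer(pts[, 1], pts[, 1], "-"))
        dy <- abs(outer(pts[, 2], pts[, 2], "-"))
        dx <- pmin(dx, Lx - dx); dy <- pmin(dy, Ly - dy)
        dm <- sqrt(dx^2 + dy^2)
      } else {
        dm <- as.matrix(stats::dist(pts))
      }
      diag(dm) <- Inf
      mean(apply(dm, 1, min))
    }, 0)
  }
}

#' Monte Carlo test of complete spatial randomness
#'
#' One-sided test for clustering of a point pattern: the observed mean
#' nearest-neighbour distance is compared against its null distribution
#' under uniform placement of the same number of points in the region,
#' simulated `n_trials` times. Small statistics indicate clustering;
#' `p = (1 + #{null <= observed}) / (n_trials + 1)`.
#'
#' @param points Two-column matrix of observed coordinates (um).
#' @param region_um Length-2 rectangle `(Lx, Ly)` (um).
#' @param n_trials Number of Monte Carlo trials.
#' @param seed Integer seed.
#' @param metric `"planar"` (default) or `"toroidal"` (edge-effect-free
#'   validation mode).
#' @return Object of class `csr_test`: `statistic`, `null_mean`,
#'   `null_distribution`, `p_value`, `n_points`, `n_trials`, `seed`.
#' @export
mc_csr_test <- function(points, region_um, n_trials = 100000, seed = 1L,
                        metric = c("planar", "toroidal")) {
  metric <- match.arg(metric)
  pts <- as.matrix(points)
  region_um <- rep(as.numeric(region_um), length.out = 2)
  stopifnot(nrow(pts) >= 2, all(region_um > 0), n_trials >= 1)
  obs <- if (metric == "toroidal") {
    dx <- abs(outer(pts[, 1], pts[, 1], "-"))
    dy <- abs(outer(pts[, 2], pts[, 2], "-"))
    dx <- pmin(dx, region_um[1] - dx); dy <- pmin(dy, region_um[2] - dy)
    dm <- sqrt(dx^2 + dy^2); diag(dm) <- Inf
    mean(apply(dm, 1, min))
  } else nn_statistic(pts)
  null <- with_seed(seed,
    null_nn_batch(n_trials, nrow(pts), region_um[1], region_um[2], metric))
  p <- (1 + sum(null <= obs)) / (n_trials + 1)
  out <- list(statistic = obs, null_mean = mean(null),
              null_distribution = null, p_value = p,
              n_points = nrow(pts), n_trials = n_trials, seed = seed,
              metric = metric)
  class(out) <- "csr_test"
  out
}

#' @export
print.csr_test <- function(x, ...) {
  cat("Monte Carlo test of complete spatial randomness\n")
  cat(sprintf("  mean NN distance = %.2f um (null mean %.2f um), n = %d points\n",
              x$statistic, x$null_mean, x$n_points))
  cat(sprintf("  one-sided p = %.4g (%d trials, %s metric)\n",
              x$p_value, x$n_trials, x$metric))
  invisible(x)
}

#' Fraction of SPREAD origins near hair follicles
#'
#' The follicle-proximal zone is the union of disks of `zone_radius_um`
#' around the follicle centres, clipped to the field. Reports both the
#' fraction of origins falling in the zone and the fraction of field
#' area the zone occupies (by pixel counting).
#'
#' @param origins Two-column matrix of SPREAD origins (um).
#' @param follicles Two-column matrix of follicle centres (um).
#' @param field_size_um Side of the square field (um).
#' @param zone_radius_um Zone radius (um).
#' @param grid_um Rasterisation step for the area fraction.
#' @return List `fraction_origins_in_zone`, `fraction_area_in_zone`,
#'   `n_origins`.
#' @export
follicle_proximity <- function(origins, follicles, field_size_um,
                               zone_radius_um = 50, grid_um = 1) {
  origins <- as.matrix(origins)
  stopifnot(nrow(origins) >= 1)
  follicles <- as.matrix(follicles)
  if (!nrow(follicles))
    return(list(fraction_origins_in_zone = 0, fraction_area_in_zone = 0,
                n_origins = nrow(origins)))
  near <- rep(FALSE, nrow(origins))
  for (i in seq_len(nrow(follicles)))
    near <- near | ((origins[, 1] - follicles[i, 1])^2 +
                    (origins[, 2] - follicles[i, 2])^2 <= zone_radius_um^2)
  g <- seq(grid_um / 2, field_size_um - grid_um / 2, by = grid_um)
  xs <- rep(g, times = length(g)); ys <- rep(g, each = length(g))
  inzone <- rep(FALSE, length(xs))
  for (i in seq_len(nrow(follicles)))
    inzone <- inzone | ((xs - follicles[i, 1])^2 +
                        (ys - follicles[i, 2])^2 <= zone_radius_um^2)
  list(fraction_origins_in_zone = mean(near),
       fraction_area_in_zone = mean(inzone),
       n_origins = nrow(origins))
}
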