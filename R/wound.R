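#' Distance from points to a wound-edge polyline
#'
#' Euclidean distance from each point to its nearest point on the
#' polyline, computed by projecting onto each segment.
#'
#' @param points Two-column matrix or data frame of coordinates (um).
#' @param edge_polyline_um Two-column matrix of polyline vertices (um).
#' @return Numeric vector of distances (um).
#' @export
distance_to_edge <- function(points, edge_polyline_um) {
  pts <- as.matrix(points)
  edge <- as.matrix(edge_polyline_um)
  stopifnot(ncol(pts) == 2, ncol(edge) == 2, nrow(edge) >= 2)
  d2 <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(edge) - 1)) {
    a <- edge[s, ]; b <- edge[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2s <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      d2s <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    }
    d2 <- pmin(d2, d2s)
  }
  sqrt(d2)
}

#' Wound-wave velocity from edge distance versus peak time
#'
#' Isolates one wave by a peak-time window and regresses responder
#' distance-to-edge on peak time (OLS); the slope is the wave velocity.
#'
#' @param fits A [fit_pulses()] table.
#' @param distances_um Per-cell distance to the wound edge, aligned with
#'   `fits` rows.
#' @param window_min Length-2 peak-time window selecting the wave; `NULL`
#'   uses all responders.
#' @return List `velocity_um_per_min`, `onset_min`, `r2`, `n`.
#' @export
estimate_wave_velocity <- function(fits, distances_um, window_min = NULL) {
  stopifnot(length(distances_um) == nrow(fits))
  sel <- fits$responder & !is.na(fits$peak_time)
  if (!is.null(window_min))
    sel <- sel & fits$peak_time >= window_min[1] &
      fits$peak_time <= window_min[2]
  if (sum(sel) < 3) stop("fewer than 3 responders in the wave window")
  d <- distances_um[sel]; t <- fits$peak_time[sel]
  if (stats::sd(t) == 0) stop("singular design: constant peak times")
  fit <- stats::lm(d ~ t)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d - mean(d))^2)
  list(velocity_um_per_min = slope,
       onset_min = if (slope != 0) -unname(stats::coef(fit)[1]) / slope
                   else NA_real_,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n = sum(sel))
}

#' Responder amplitude versus distance from the wound edge
#'
#' Linear trend of the baseline-subtracted peak amplitude against edge
#' distance over responders. For trigger waves from a wound the slope is
#' expected to be statistically indistinguishable from zero (activity is
#' maintained), in contrast to the decaying amplitude of a SPREAD.
#'
#' @inheritParams estimate_wave_velocity
#' @return List `slope`, `slope_ci` (95%), `r`, `n`, plus the per-cell
#'   `scatter` data frame.
#' @export
amplitude_vs_distance <- function(fits, distances_um) {
  stopifnot(length(distances_um) == nrow(fits))
  sel <- fits$responder & !is.na(fits$amplitude)
  if (sum(sel) < 3) stop("fewer than 3 responders")
  d <- distances_um[sel]; a <- fits$amplitude[sel]
  fit <- stats::lm(a ~ d)
  ci <- stats::confint(fit)["d", ]
  list(slope = unname(stats::coef(fit)[2]), slope_ci = unname(ci),
       r = stats::cor(d, a), n = sum(sel),
       scatter = data.frame(distance_um = d, amplitude = a))
}

#' Responder fraction versus distance from the wound edge
#'
#' Same binning contract as [responder_fraction_profile()], keyed to the
#' distance from the wound edge instead of a radial origin.
#'
#' @inheritParams estimate_wave_velocity
#' @param bin_width_um Bin width (micrometres).
#' @param min_cells_per_bin Minimum cells for a usable bin.
#' @return A `responder_profile` data frame.
#' @export
responder_fraction_vs_distance <- function(fits, distances_um,
                                           bin_width_um = 10,
                                           min_cells_per_bin = 5) {
  stopifnot(length(distances_um) == nrow(fits))
  nb <- ceiling(max(distances_um) / bin_width_um)
  idx <- pmin(floor(distances_um / bin_width_um) + 1, nb)
  lo <- (seq_len(nb) - 1) * bin_width_um
  n_cells <- tabulate(idx, nb)
  n_resp <- tabulate(idx[fits$responder], nb)
  frac <- ifelse(n_cells > 0, n_resp / n_cells, NA_real_)
  out <- data.frame(bin_lo = lo, bin_hi = lo + bin_width_um,
                    center_um = lo + bin_width_um / 2,
                    n_cells = n_cells, n_responders = n_resp,
                    fraction = frac, usable = n_cells >= min_cells_per_bin)
  class(out) <- c("responder_profile", "data.frame")
  out
}
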