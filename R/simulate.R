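#' Place non-overlapping nuclei in a square field
#'
#' Positions `n_cells` nucleus centres so that the minimum pairwise
#' distance is at least twice the nucleus radius. The default jittered
#' grid guarantees feasibility whenever the grid spacing
#' `field_size_um / ceiling(sqrt(n_cells))` is at least one nucleus
#' diameter; dart throwing (random sequential placement) is available for
#' sparser, less regular fields.
#'
#' @param config A [field_config()].
#' @param method `"jittered_grid"` (default) or `"dart"`.
#' @return A data frame with columns `cell_id`, `x_um`, `y_um`.
#' @export
place_cells <- function(config, method = c("jittered_grid", "dart")) {
  method <- match.arg(method)
  n <- config$n_cells
  L <- config$field_size_um
  rmin <- 2 * config$nucleus_radius_um
  # disk-packing feasibility bound (hexagonal limit ~0.9069)
  if (n * pi * config$nucleus_radius_um^2 / L^2 > 0.9069)
    stop("infeasible packing: requested density exceeds the disk-packing limit")
  with_seed(config$seed, {
    if (method == "jittered_grid") {
      k <- ceiling(sqrt(n))
      s <- L / k
      if (s < rmin)
        stop("infeasible packing: grid spacing below one nucleus diameter")
      jit <- (s - rmin) / 2
      grid <- expand.grid(ix = seq_len(k), iy = seq_len(k))
      grid <- grid[sample.int(nrow(grid), n), , drop = FALSE]
      x <- (grid$ix - 0.5) * s + stats::runif(n, -jit, jit)
      y <- (grid$iy - 0.5) * s + stats::runif(n, -jit, jit)
    } else {
      x <- y <- numeric(0)
      tries <- 0L
      while (length(x) < n) {
        cand <- stats::runif(2, 0, L)
        if (!length(x) ||
            min((x - cand[1])^2 + (y - cand[2])^2) >= rmin^2) {
          x <- c(x, cand[1]); y <- c(y, cand[2])
        }
        tries <- tries + 1L
        if (tries > 2000L * n)
          stop("infeasible packing: dart throwing failed to place all cells")
      }
    }
    data.frame(cell_id = seq_len(n), x_um = x, y_um = y)
  })
}

half_sine_pulse <- function(t, t0, tau, amp) {
  ifelse(t >= t0 & t <= t0 + tau,
         amp * pmax(0, sin(pi * (t - t0) / tau)), 0)
}

pulse_amplitude <- function(truth, d) {
  if (truth$decay_law == "exponential")
    truth$amp0 * exp(-truth$amp_decay_per_um * d)
  else
    truth$amp0 * pmax(0, 1 - truth$amp_decay_per_um * d)
}

#' Simulate per-cell FRET/CFP ratio traces under one or more SPREADs
#'
#' Each cell responds to a SPREAD at distance `d` from its origin with
#' probability `1 / (1 + exp((d - radius_um) / steepness))`. A responder's
#' pulse starts `d / velocity` after the SPREAD onset and follows a
#' half-sine of width tau and distance-decayed amplitude on top of the
#' cell's baseline; i.i.d. Gaussian noise is added per frame.
#'
#' @param cells Data frame from [place_cells()].
#' @param truths A `spread_truth` or list of them.
#' @param config A [field_config()].
#' @param seed Seed; defaults to `config$seed + 1`.
#' @param responder_mode `"bernoulli"` (default) draws each responder
#'   flag independently with probability `p(d)`; `"systematic"` assigns
#'   responders by deterministic thinning along the distance ordering so
#'   that the cumulative responder count tracks the cumulative
#'   probability exactly (stratified variance reduction for presets that
#'   validate count-based estimators; the marginal fraction at every
#'   distance is unchanged).
#' @return List with `traces` (cell_id, x_um, y_um, t_min, ratio),
#'   `cells` (per cell and SPREAD: distance, responder flag, true onset
#'   delay, amplitude), and `baselines`.
#' @export
simulate_spread_traces <- function(cells, truths, config,
                                   seed = config$seed + 1L,
                                   responder_mode = c("bernoulli",
                                                      "systematic")) {
  responder_mode <- match.arg(responder_mode)
  if (inherits(truths, "spread_truth")) truths <- list(truths)
  stopifnot(length(truths) >= 1)
  t_min <- (seq_len(config$n_frames) - 1L) * config$frame_interval_min
  n <- nrow(cells)
  with_seed(seed, {
    baseline <- stats::rnorm(n, config$baseline_ratio_mean,
                             config$baseline_ratio_sd)
    ratio <- matrix(rep(baseline, each = length(t_min)), nrow = length(t_min))
    flags <- vector("list", length(truths))
    for (s in seq_along(truths)) {
      tr <- truths[[s]]
      d <- sqrt((cells$x_um - tr$origin_xy_um[1])^2 +
                (cells$y_um - tr$origin_xy_um[2])^2)
      p <- 1 / (1 + exp((d - tr$radius_um) / tr$responder_steepness_um))
      if (responder_mode == "systematic") {
        resp <- logical(n)
        ord <- order(d)
        cum <- cumsum(p[ord])
        resp[ord] <- floor(cum) > floor(cum - p[ord])
      } else {
        resp <- stats::runif(n) < p
      }
      amp <- pulse_amplitude(tr, d)
      t0 <- tr$onset_min + d / tr$velocity_um_per_min
      for (i in which(resp & amp > 0)) {
        ratio[, i] <- ratio[, i] +
          half_sine_pulse(t_min, t0[i], tr$pulse_width_min, amp[i])
      }
      flags[[s]] <- data.frame(cell_id = cells$cell_id, spread = s,
                               distance_um = d, responder = resp & amp > 0,
                               onset_delay_min = d / tr$velocity_um_per_min,
                               amplitude = amp)
    }
    if (config$noise_sd > 0)
      ratio <- ratio + stats::rnorm(length(ratio), 0, config$noise_sd)
    traces <- data.frame(
      cell_id = rep(cells$cell_id, each = length(t_min)),
      x_um = rep(cells$x_um, each = length(t_min)),
      y_um = rep(cells$y_um, each = length(t_min)),
      t_min = rep(t_min, n),
      ratio = as.vector(ratio))
    list(traces = traces, cells = do.call(rbind, flags),
         baselines = data.frame(cell_id = cells$cell_id, baseline = baseline))
  })
}

#' Simulate wound-edge trigger-wave traces
#'
#' For each wave, every cell within `max_reach_um` of the edge responds
#' with constant probability and pulses `d / velocity` after the wave
#' onset with amplitude `amp0` independent of distance.
#'
#' @inheritParams simulate_spread_traces
#' @param truth A [wound_truth()].
#' @return Same shape as [simulate_spread_traces()]; `cells` has one row
#'   per cell and wave with `distance_um` measured to the wound edge.
#' @export
simulate_wound_traces <- function(cells, truth, config,
                                  seed = config$seed + 1L) {
  stopifnot(inherits(truth, "wound_truth"))
  t_min <- (seq_len(config$n_frames) - 1L) * config$frame_interval_min
  n <- nrow(cells)
  d <- distance_to_edge(cells[, c("x_um", "y_um")], truth$edge_polyline_um)
  with_seed(seed, {
    baseline <- stats::rnorm(n, config$baseline_ratio_mean,
                             config$baseline_ratio_sd)
    ratio <- matrix(rep(baseline, each = length(t_min)), nrow = length(t_min))
    flags <- vector("list", length(truth$wave_onsets_min))
    for (k in seq_along(truth$wave_onsets_min)) {
      within <- d <= truth$max_reach_um
      resp <- within & stats::runif(n) < truth$responder_prob
      t0 <- truth$wave_onsets_min[k] + d / truth$velocity_um_per_min
      for (i in which(resp)) {
        ratio[, i] <- ratio[, i] +
          half_sine_pulse(t_min, t0[i], truth$pulse_width_min, truth$amp0)
      }
      flags[[k]] <- data.frame(cell_id = cells$cell_id, wave = k,
                               distance_um = d, responder = resp)
    }
    if (config$noise_sd > 0)
      ratio <- ratio + stats::rnorm(length(ratio), 0, config$noise_sd)
    traces <- data.frame(
      cell_id = rep(cells$cell_id, each = length(t_min)),
      x_um = rep(cells$x_um, each = length(t_min)),
      y_um = rep(cells$y_um, each = length(t_min)),
      t_min = rep(t_min, n),
      ratio = as.vector(ratio))
    list(traces = traces, cells = do.call(rbind, flags),
         baselines = data.frame(cell_id = cells$cell_id, baseline = baseline))
  })
}

# Pixel indices (single linear index into an ny x nx matrix) covered by a
# disk centred at (x_um, y_um); pixel centres at (index - 0.5) * px.
disk_pixels <- function(x_um, y_um, radius_um, config) {
  px <- config$pixel_size_um
  npix <- ceiling(config$field_size_um / px)
  cmin <- max(1L, floor((x_um - radius_um) / px))
  cmax <- min(npix, ceiling((x_um + radius_um) / px) + 1L)
  rmin <- max(1L, floor((y_um - radius_um) / px))
  rmax <- min(npix, ceiling((y_um + radius_um) / px) + 1L)
  if (cmin > cmax || rmin > rmax) return(integer(0))
  cc <- cmin:cmax; rr <- rmin:rmax
  xc <- (cc - 0.5) * px; yc <- (rr - 0.5) * px
  keep <- outer((yc - y_um)^2, (xc - x_um)^2, "+") <= radius_um^2
  idx <- which(keep)
  r <- rr[(idx - 1L) %% length(rr) + 1L]
  c <- cc[(idx - 1L) %/% length(rr) + 1L]
  (c - 1L) * npix + r
}

#' Render a two-channel image stack from traces
#'
#' The CFP (donor) channel shows nuclei as uniform disks of intensity
#' `cfp_level` on a dark background; the FRET channel equals
#' `ratio * CFP` within each disk, so that pixelwise division recovers the
#' ratio exactly. This is the imaging inverse used by the round-trip
#' validation of the extraction pipeline.
#'
#' @param traces Trace table (`cell_id`, `x_um`, `y_um`, `t_min`, `ratio`).
#' @param config A [field_config()].
#' @return An [image_stack()] with channels `FRET` and `CFP`.
#' @export
render_stack <- function(traces, config) {
  px <- config$pixel_size_um
  npix <- ceiling(config$field_size_um / px)
  if (2 * config$nucleus_radius_um > config$field_size_um)
    stop("field too small to contain a nucleus")
  cells <- unique(traces[, c("cell_id", "x_um", "y_um")])
  t_all <- sort(unique(traces$t_min))
  nT <- length(t_all)
  masks <- lapply(seq_len(nrow(cells)), function(i)
    disk_pixels(cells$x_um[i], cells$y_um[i], config$nucleus_radius_um,
                config))
  ratio_mat <- matrix(NA_real_, nT, nrow(cells))
  key <- paste(traces$cell_id, traces$t_min)
  ord <- match(paste(rep(cells$cell_id, each = nT), rep(t_all, nrow(cells))),
               key)
  ratio_mat[] <- traces$ratio[ord]
  data <- array(0, dim = c(npix, npix, nT, 2),
                dimnames = list(NULL, NULL, NULL, c("FRET", "CFP")))
  for (f in seq_len(nT)) {
    cfp <- matrix(0, npix, npix)
    fret <- matrix(0, npix, npix)
    for (i in seq_len(nrow(cells))) {
      cfp[masks[[i]]] <- config$cfp_level
      fret[masks[[i]]] <- ratio_mat[f, i] * config$cfp_level
    }
    data[, , f, "CFP"] <- cfp
    data[, , f, "FRET"] <- fret
  }
  image_stack(data, pixel_size_um = px,
              frame_interval_min = config$frame_interval_min)
}

#' Simulate cell-division events enriched in SPREAD areas
#'
#' Events follow an inhomogeneous Poisson process whose intensity is
#' `rate_in` (events/mm^2/hr) inside the spatio-temporal SPREAD-area
#' union (disks of `radius_um` around each origin, for `window_hr` after
#' its onset) and `rate_out` elsewhere, simulated by thinning.
#'
#' @param config A [field_config()] (supplies the field polygon).
#' @param truths List of `spread_truth` (origins and onsets).
#' @param rate_in,rate_out Division rates in events/mm^2/hr.
#' @param duration_hr Total observed time span (hours).
#' @param radius_um,window_hr SPREAD-area definition (defaults 100 um, 1 hr).
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return Data frame `x_um`, `y_um`, `t_min`, `in_area`.
#' @export
simulate_divisions <- function(config, truths, rate_in, rate_out,
                               duration_hr, radius_um = 100, window_hr = 1,
                               seed = config$seed + 2L) {
  stopifnot(rate_in >= 0, rate_out >= 0, duration_hr > 0)
  if (inherits(truths, "spread_truth")) truths <- list(truths)
  L <- config$field_size_um
  rmax <- max(rate_in, rate_out)
  vol <- (L / 1000)^2 * duration_hr              # mm^2 * hr
  with_seed(seed, {
    n <- stats::rpois(1, rmax * vol)
    x <- stats::runif(n, 0, L); y <- stats::runif(n, 0, L)
    t <- stats::runif(n, 0, duration_hr * 60)
    inside <- in_spread_area(x, y, t, truths, radius_um, window_hr)
    rate <- ifelse(inside, rate_in, rate_out)
    keep <- stats::runif(n) < rate / rmax
    data.frame(x_um = x[keep], y_um = y[keep], t_min = t[keep],
               in_area = inside[keep])
  })
}

in_spread_area <- function(x, y, t_min, truths, radius_um = 100,
                           window_hr = 1) {
  inside <- rep(FALSE, length(x))
  for (tr in truths) {
    d2 <- (x - tr$origin_xy_um[1])^2 + (y - tr$origin_xy_um[2])^2
    inside <- inside | (d2 <= radius_um^2 &
                        t_min >= tr$onset_min &
                        t_min <= tr$onset_min + window_hr * 60)
  }
  inside
}

#' Simulate a two-channel Fucci viewfield
#'
#' Nuclei are assigned S/G2/M (mAG-bright) or G0/G1 (mKO2-bright) either
#' independently with probability `sgm_fraction` or, in exact-count mode,
#' as exactly `round(n * sgm_fraction)` S/G2/M cells. Each channel shows
#' its phase's nuclei at `bright_level`, the opposite phase at
#' `dim_level`, plus Gaussian intensity noise.
#'
#' @param config A [field_config()].
#' @param sgm_fraction Target S/G2/M proportion in `[0, 1]`.
#' @param exact_count Use exact-count assignment instead of Bernoulli.
#' @param bright_level,dim_level,noise_sd Channel intensity model.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return List with `mAG` and `mKO2` image matrices, `cells` (positions
#'   and true phase), and `sgm_fraction_true`.
#' @export
simulate_fucci_field <- function(config, sgm_fraction, exact_count = TRUE,
                                 bright_level = 500, dim_level = 50,
                                 noise_sd = 10, seed = config$seed + 3L) {
  stopifnot(sgm_fraction >= 0, sgm_fraction <= 1)
  cells <- place_cells(config)
  n <- nrow(cells)
  px <- config$pixel_size_um
  npix <- ceiling(config$field_size_um / px)
  with_seed(seed, {
    if (exact_count) {
      k <- round(n * sgm_fraction)
      sgm <- rep(FALSE, n)
      sgm[sample.int(n, k)] <- TRUE
    } else {
      sgm <- stats::runif(n) < sgm_fraction
    }
    mAG <- matrix(0, npix, npix)
    mKO2 <- matrix(0, npix, npix)
    for (i in seq_len(n)) {
      idx <- disk_pixels(cells$x_um[i], cells$y_um[i],
                         config$nucleus_radius_um, config)
      mAG[idx] <- if (sgm[i]) bright_level else dim_level
      mKO2[idx] <- if (sgm[i]) dim_level else bright_level
    }
    if (noise_sd > 0) {
      mAG <- matrix(pmax(mAG + stats::rnorm(length(mAG), 0, noise_sd), 0),
                    npix, npix)
      mKO2 <- matrix(pmax(mKO2 + stats::rnorm(length(mKO2), 0, noise_sd), 0),
                     npix, npix)
    }
    cells$phase <- ifelse(sgm, "S/G2/M", "G0/G1")
    list(mAG = mAG, mKO2 = mKO2, cells = cells,
         sgm_fraction_true = mean(sgm))
  })
}

#' Simulate SPREAD-origin point patterns
#'
#' Uniform mode draws i.i.d. points in the rectangle (the null of the
#' clustering test); clustered mode draws a Thomas-type parent-offspring
#' process: `n_parents` uniform parents each with `n_offspring` points
#' displaced by isotropic Gaussian offsets of scale `offspring_scale_um`,
#' wrapped toroidally so the intensity stays uniform.
#'
#' @param region_um Length-2 rectangle size `(Lx, Ly)` in micrometres.
#' @param n Number of points (uniform mode).
#' @param mode `"uniform"` or `"clustered"`.
#' @param n_parents,n_offspring,offspring_scale_um Thomas parameters.
#' @param seed Integer seed.
#' @return Two-column matrix of coordinates (um).
#' @export
simulate_origin_pattern <- function(region_um, n = NULL,
                                    mode = c("uniform", "clustered"),
                                    n_parents = 4, n_offspring = 5,
                                    offspring_scale_um = 20, seed = 1L) {
  mode <- match.arg(mode)
  region_um <- rep(as.numeric(region_um), length.out = 2)
  with_seed(seed, {
    if (mode == "uniform") {
      stopifnot(n >= 2)
      cbind(x_um = stats::runif(n, 0, region_um[1]),
            y_um = stats::runif(n, 0, region_um[2]))
    } else {
      px <- stats::runif(n_parents, 0, region_um[1])
      py <- stats::runif(n_parents, 0, region_um[2])
      x <- rep(px, each = n_offspring) +
        stats::rnorm(n_parents * n_offspring, 0, offspring_scale_um)
      y <- rep(py, each = n_offspring) +
        stats::rnorm(n_parents * n_offspring, 0, offspring_scale_um)
      cbind(x_um = x %% region_um[1], y_um = y %% region_um[2])
    }
  })
}
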