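#' Classify nuclei into cell-cycle phases from a Fucci frame
#'
#' S/G2/M nuclei are segmented on the clipped difference image
#' `max(mAG - mKO2, 0)` and G0/G1 nuclei on `max(mKO2 - mAG, 0)`, each
#' with the adaptive-threshold nucleus segmentation. Detections whose
#' masks overlap between the two channels are resolved to the channel
#' with the greater mean intensity, so the final phase masks are
#' disjoint. An optional pre-filter removes small saturated objects
#' (melanin granules) bright in both channels.
#'
#' @param mAG,mKO2 Co-registered single-channel image matrices
#'   (mAG-Geminin marks S/G2/M, mKO2-Cdt1 marks G0/G1).
#' @param pixel_size_um Micrometres per pixel.
#' @param diameter_range_px,local_intensity_above_background Passed to
#'   [segment_nuclei()].
#' @param melanin_filter Apply the melanin pre-filter.
#' @param melanin_max_area_px,melanin_min_intensity Pre-filter: objects
#'   at most this large and at least this bright in both channels are
#'   blanked before classification.
#' @return Object of class `fucci_calls`: data frame `cell_id`, `phase`,
#'   `x_um`, `y_um`, `mean_mAG`, `mean_mKO2` plus attributes
#'   `sgm_fraction` and the two label maps.
#' @export
classify_fucci_frame <- function(mAG, mKO2, pixel_size_um = 1,
                                 diameter_range_px = c(4, 10),
                                 local_intensity_above_background = 30,
                                 melanin_filter = FALSE,
                                 melanin_max_area_px = 6,
                                 melanin_min_intensity = 1000) {
  if (!all(dim(mAG) == dim(mKO2))) stop("channel shape mismatch")
  if (melanin_filter) {
    bright <- mAG >= melanin_min_intensity & mKO2 >= melanin_min_intensity
    if (any(bright)) {
      lab <- EBImage::bwlabel(bright * 1L)
      lab <- matrix(as.integer(round(lab)), nrow(mAG), ncol(mAG))
      areas <- tabulate(lab[lab > 0])
      kill <- which(areas <= melanin_max_area_px)
      if (length(kill)) {
        bad <- lab %in% kill & lab > 0
        mAG[bad] <- 0; mKO2[bad] <- 0
      }
    }
  }
  d_green <- pmax(mAG - mKO2, 0)
  d_red <- pmax(mKO2 - mAG, 0)
  seg_g <- segment_nuclei(d_green, pixel_size_um, diameter_range_px,
                          local_intensity_above_background)
  seg_r <- segment_nuclei(d_red, pixel_size_um, diameter_range_px,
                          local_intensity_above_background)
  mean_in <- function(img, labels, lab) {
    idx <- which(labels == lab)
    mean(img[idx])
  }
  # resolve overlapping detections to the brighter channel
  keep_g <- rep(TRUE, nrow(seg_g$table))
  keep_r <- rep(TRUE, nrow(seg_r$table))
  both <- seg_g$labels > 0 & seg_r$labels > 0
  if (any(both)) {
    pairs <- unique(cbind(seg_g$labels[both], seg_r$labels[both]))
    for (i in seq_len(nrow(pairs))) {
      g <- pairs[i, 1]; r <- pairs[i, 2]
      mg <- mean_in(mAG, seg_g$labels, g)
      mr <- mean_in(mKO2, seg_r$labels, r)
      if (mg >= mr) keep_r[r] <- FALSE else keep_g[g] <- FALSE
    }
  }
  row_of <- function(seg, lab, phase) {
    data.frame(phase = phase,
               x_um = seg$table$x_um[lab], y_um = seg$table$y_um[lab],
               mean_mAG = mean_in(mAG, seg$labels, seg$table$label[lab]),
               mean_mKO2 = mean_in(mKO2, seg$labels, seg$table$label[lab]))
  }
  rows <- c(lapply(which(keep_g), function(l) row_of(seg_g, l, "S/G2/M")),
            lapply(which(keep_r), function(l) row_of(seg_r, l, "G0/G1")))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = character(0), x_um = numeric(0), y_um = numeric(0),
               mean_mAG = numeric(0), mean_mKO2 = numeric(0))
  out <- cbind(cell_id = seq_len(nrow(out)), out)
  attr(out, "sgm_fraction") <- if (nrow(out))
    mean(out$phase == "S/G2/M") else NA_real_
  attr(out, "labels_sgm") <- seg_g
  attr(out, "labels_g0g1") <- seg_r
  class(out) <- c("fucci_calls", "data.frame")
  out
}

#' @export
print.fucci_calls <- function(x, ...) {
  cat(sprintf("fucci_calls: %d cells, %.1f%% S/G2/M\n",
              nrow(x), 100 * attr(x, "sgm_fraction")))
  invisible(x)
}

#' S/G2/M proportion over a time course
#'
#' Classifies each timepoint's two-channel Fucci frame and reports the
#' S/G2/M fraction with its counts.
#'
#' @param frames List of timepoints, each a list with elements `mAG` and
#'   `mKO2`.
#' @param t_hr Optional timepoint labels (hours).
#' @param ... Passed to [classify_fucci_frame()].
#' @return Data frame `t_hr`, `n_cells`, `n_sgm`, `fraction` (`NA`
#'   fraction when no cell was classified).
#' @export
sgm_fraction_timecourse <- function(frames, t_hr = seq_along(frames), ...) {
  stopifnot(length(frames) >= 1)
  rows <- lapply(seq_along(frames), function(i) {
    calls <- classify_fucci_frame(frames[[i]]$mAG, frames[[i]]$mKO2, ...)
    n <- nrow(calls)
    data.frame(t_hr = t_hr[i], n_cells = n,
               n_sgm = sum(calls$phase == "S/G2/M"),
               fraction = if (n > 0) mean(calls$phase == "S/G2/M")
                          else NA_real_)
  })
  do.call(rbind, rows)
}

#' Histogram of S/G2/M percentages across viewfields
#'
#' @param fractions Numeric vector of per-viewfield S/G2/M fractions
#'   (`[0, 1]`).
#' @param bin_percent Bin width in percentage points.
#' @return List `histogram` (bin_lo, bin_hi, count), `mean_percent`,
#'   `tail_mass_above_50` (fraction of viewfields above 50%), `n`.
#' @export
viewfield_histogram <- function(fractions, bin_percent = 5) {
  stopifnot(length(fractions) >= 1)
  pct <- 100 * fractions
  breaks <- seq(0, 100, by = bin_percent)
  counts <- graphics::hist(pmin(pct, 100 - 1e-9), breaks = breaks,
                           plot = FALSE, right = FALSE)$counts
  list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1], count = counts),
       mean_percent = mean(pct),
       tail_mass_above_50 = mean(pct > 50),
       n = length(fractions))
}
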