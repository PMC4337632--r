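#' Two-channel calibrated image stack
#'
#' Thin container for pixel data indexed `[row, col, frame, channel]`
#' with physical calibration. Row/column indices are 0-based at the
#' top-left when converted to physical coordinates: a pixel centre sits
#' at `(index - 0.5) * pixel_size_um`.
#'
#' @param data Numeric 4-d array `[row, col, frame, channel]`; the
#'   channel dimension must carry dimnames (e.g. `c("FRET", "CFP")`).
#' @param pixel_size_um Micrometres per pixel.
#' @param frame_interval_min Minutes per frame.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_min) {
  stopifnot(length(dim(data)) == 4, dim(data)[3] >= 1,
            pixel_size_um > 0, frame_interval_min > 0,
            !is.null(dimnames(data)[[4]]))
  out <- list(data = data, pixel_size_um = pixel_size_um,
              frame_interval_min = frame_interval_min,
              channel_names = dimnames(data)[[4]])
  class(out) <- "image_stack"
  out
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), channels [%s]\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  %.3f um/px, %.2f min/frame\n",
              x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Extract one channel of an image stack
#' @param stack An [image_stack()].
#' @param name Channel name.
#' @return 3-d array `[row, col, frame]`.
#' @export
get_channel <- function(stack, name) {
  if (!name %in% stack$channel_names)
    stop("missing channel: ", name)
  d <- dim(stack$data)
  array(stack$data[, , , name, drop = FALSE], d[1:3])
}

# Vectorised 3x3 median via Paeth's median-of-9 exchange network, with
# replicate padding at the borders.
median3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- c(pmax(1L, seq_len(ny) - 1L), seq_len(ny), pmin(ny, seq_len(ny) + 1L))
  shift <- function(dr, dc) {
    rows <- pmin(ny, pmax(1L, seq_len(ny) + dr))
    cols <- pmin(nx, pmax(1L, seq_len(nx) + dc))
    m[rows, cols, drop = FALSE]
  }
  v <- list(shift(-1, -1), shift(-1, 0), shift(-1, 1),
            shift(0, -1),  shift(0, 0),  shift(0, 1),
            shift(1, -1),  shift(1, 0),  shift(1, 1))
  cx <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  cx(2, 3); cx(5, 6); cx(8, 9); cx(1, 2); cx(4, 5); cx(7, 8)
  cx(2, 3); cx(5, 6); cx(8, 9); cx(1, 4); cx(6, 9); cx(5, 8)
  cx(4, 7); cx(2, 5); cx(3, 6); cx(5, 8); cx(3, 5); cx(7, 5); cx(3, 5)
  v[[5]]
}

#' Compute a masked FRET/CFP ratio stack
#'
#' Pixelwise acceptor/donor ratio wherever the donor signal reaches
#' `cfp_floor`; all other pixels are masked (`NA`). Optionally a 3x3
#' median filter is applied to each ratio frame (masked centres stay
#' masked; masked neighbours of a valid centre are substituted by the
#' centre value so nuclei filter within themselves).
#'
#' @param stack An [image_stack()] with `FRET` and `CFP` channels.
#' @param median_filter Apply the 3x3 median filter per frame.
#' @param cfp_floor Minimum donor intensity for a defined ratio.
#' @return 3-d array `[row, col, frame]` of ratios with `NA` mask.
#' @export
compute_ratio_stack <- function(stack, median_filter = FALSE, cfp_floor = 1) {
  fret <- get_channel(stack, "FRET")
  cfp <- get_channel(stack, "CFP")
  if (length(dim(fret)) == 2) {
    fret <- array(fret, c(dim(fret), 1))
    cfp <- array(cfp, c(dim(cfp), 1))
  }
  ratio <- fret / cfp
  ratio[cfp < cfp_floor] <- NA_real_
  if (median_filter) {
    for (f in seq_len(dim(ratio)[3])) {
      fr <- ratio[, , f]
      na <- is.na(fr)
      filled <- fr
      # substitute masked neighbours by a large sentinel-free fill: use the
      # frame median of defined pixels so border effects stay local
      if (any(na) && !all(na)) {
        # per-pixel: replace NA by the value of the nearest defined centre
        # (approximated by the centre itself during the shift), so run the
        # network on a copy where NA -> centre value via two passes
        fill <- stats::median(fr, na.rm = TRUE)
        filled[na] <- fill
      }
      out <- median3x3(filled)
      out[na] <- NA_real_
      ratio[, , f] <- out
    }
  }
  ratio
}

#' Temporal mean projection of a ratio stack
#'
#' Averages runs of consecutive frames, ignoring masked pixels. The
#' default groups frames into non-overlapping blocks (e.g. five serial
#' images to one projection); `"sliding"` returns a centred moving mean
#' with one output frame per input frame.
#'
#' @param ratio 3-d ratio array `[row, col, frame]`.
#' @param window Number of frames per projection (>= 1).
#' @param mode `"block"` (non-overlapping, default) or `"sliding"`.
#' @return 3-d array of projected frames.
#' @export
project_mean <- function(ratio, window, mode = c("block", "sliding")) {
  mode <- match.arg(mode)
  if (window < 1) stop("window must be >= 1")
  nT <- dim(ratio)[3]
  if (window > nT) stop("window exceeds number of frames")
  if (window == 1) return(ratio)
  avg <- function(idx) {
    sub <- ratio[, , idx, drop = FALSE]
    cnt <- apply(!is.na(sub), c(1, 2), sum)
    s <- apply(sub, c(1, 2), function(v) sum(v, na.rm = TRUE))
    out <- s / cnt
    out[cnt == 0] <- NA_real_
    out
  }
  if (mode == "block") {
    nb <- nT %/% window
    out <- array(NA_real_, c(dim(ratio)[1:2], nb))
    for (b in seq_len(nb))
      out[, , b] <- avg(((b - 1) * window + 1):(b * window))
  } else {
    half <- (window - 1) %/% 2
    out <- array(NA_real_, dim(ratio))
    for (f in seq_len(nT))
      out[, , f] <- avg(max(1, f - half):min(nT, f + window - 1 - half))
  }
  out
}

#' Intensity-modulated display rendering
#'
#' Encodes a ratio frame into 8 hue bins (blue = low to red = high) and a
#' donor-intensity frame into 32 brightness grades, the standard display
#' for ratiometric FRET images. Bins are half-open `[lo + i*w, lo +
#' (i+1)*w)` with both ends clipped, so a ratio exactly at the range
#' midpoint falls in the fifth bin (index 4 of 0..7). A single-hue gold
#' pseudo-colour mode is also provided.
#'
#' @param ratio_frame Matrix of ratios (may contain `NA`).
#' @param cfp_frame Matrix of donor intensities, same shape.
#' @param ratio_range,intensity_range Length-2 display ranges.
#' @param mode `"imd"` (8 hues x 32 grades) or `"gold"`.
#' @return List with `rgb` (`[row, col, 3]` in `[0, 1]`), `hue_bin` and
#'   `grade` integer matrices (`NA` where masked).
#' @export
render_imd <- function(ratio_frame, cfp_frame,
                       ratio_range = c(1, 2),
                       intensity_range = range(cfp_frame),
                       mode = c("imd", "gold")) {
  mode <- match.arg(mode)
  stopifnot(diff(ratio_range) > 0, diff(intensity_range) > 0)
  bin_of <- function(x, rng, nbin) {
    b <- floor((x - rng[1]) / diff(rng) * nbin)
    pmin(pmax(b, 0), nbin - 1)
  }
  hue_bin <- bin_of(ratio_frame, ratio_range, 8L)
  grade <- bin_of(cfp_frame, intensity_range, 32L)
  pal <- grDevices::colorRampPalette(
    c("#0000FF", "#00FFFF", "#00FF00", "#FFFF00", "#FF0000"))(8)
  rgbpal <- grDevices::col2rgb(pal) / 255
  ny <- nrow(ratio_frame); nx <- ncol(ratio_frame)
  rgb <- array(0, c(ny, nx, 3))
  ok <- !is.na(hue_bin)
  bright <- (grade + 1) / 32
  for (ch in 1:3) {
    plane <- matrix(0, ny, nx)
    if (mode == "imd") {
      plane[ok] <- rgbpal[ch, hue_bin[ok] + 1] * bright[ok]
    } else {
      gold <- c(1, 0.843, 0)
      plane[ok] <- gold[ch] * (hue_bin[ok] + 1) / 8 * bright[ok]
    }
    rgb[, , ch] <- plane
  }
  hue_bin[!ok] <- NA_integer_
  list(rgb = rgb, hue_bin = hue_bin, grade = grade)
}

# Box mean over a w x w window (w odd) with window/image intersection
# normalisation, via integral images.
box_mean <- function(m, w) {
  ny <- nrow(m); nx <- ncol(m)
  h <- (w - 1) %/% 2
  sat <- rbind(0, apply(m, 2, cumsum))
  sat <- cbind(0, t(apply(sat, 1, cumsum)))
  r1 <- pmax(seq_len(ny) - h, 1L); r2 <- pmin(seq_len(ny) + h, ny)
  c1 <- pmax(seq_len(nx) - h, 1L); c2 <- pmin(seq_len(nx) + h, nx)
  s <- sat[r2 + 1, c2 + 1] - sat[r1, c2 + 1] - sat[r2 + 1, c1] + sat[r1, c1]
  cnt <- outer(r2 - r1 + 1, c2 - c1 + 1)
  s / cnt
}

#' Segment nuclei by adaptive local thresholding
#'
#' A pixel is foreground when its intensity exceeds the local background
#' (mean over a window of three times the maximal nucleus diameter) by at
#' least `local_intensity_above_background`, in the image's native
#' intensity units. Connected components whose equivalent diameter
#' (`2 * sqrt(area / pi)`) lies within `diameter_range_px` are kept.
#'
#' @param frame Single-channel image matrix.
#' @param pixel_size_um Micrometres per pixel (for centroid output).
#' @param diameter_range_px Admissible equivalent-diameter range (px).
#' @param local_intensity_above_background Threshold above local mean.
#' @return An object of class `label_map`: `labels` (integer matrix, 0 =
#'   background) and `table` (label, x_um, y_um, area_px).
#' @export
segment_nuclei <- function(frame, pixel_size_um = 1,
                           diameter_range_px = c(4, 10),
                           local_intensity_above_background = 30) {
  w <- 3 * max(diameter_range_px)
  if (w %% 2 == 0) w <- w + 1
  bg <- box_mean(frame, w)
  fg <- (frame - bg) >= local_intensity_above_background
  if (!any(fg)) {
    return(structure(list(labels = matrix(0L, nrow(frame), ncol(frame)),
                          table = data.frame(label = integer(0),
                                             x_um = numeric(0),
                                             y_um = numeric(0),
                                             area_px = integer(0)),
                          pixel_size_um = pixel_size_um),
                     class = "label_map"))
  }
  lab <- EBImage::bwlabel(fg * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(frame), ncol(frame))
  areas <- tabulate(lab[lab > 0])
  eqd <- 2 * sqrt(areas / pi)
  keep <- which(eqd >= diameter_range_px[1] & eqd <= diameter_range_px[2])
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(frame), ncol(frame))
  pos <- lab > 0
  newlab[pos] <- relab[lab[pos]]
  if (length(keep)) {
    idx <- which(newlab > 0)
    l <- newlab[idx]
    rr <- (idx - 1L) %% nrow(frame) + 1L
    cc <- (idx - 1L) %/% nrow(frame) + 1L
    tab <- data.frame(
      label = seq_along(keep),
      x_um = (tapply(cc, l, mean) - 0.5) * pixel_size_um,
      y_um = (tapply(rr, l, mean) - 0.5) * pixel_size_um,
      area_px = as.integer(tabulate(l)))
  } else {
    tab <- data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0))
  }
  rownames(tab) <- NULL
  structure(list(labels = newlab, table = tab,
                 pixel_size_um = pixel_size_um),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d object(s) on %d x %d px (%.3f um/px)\n",
              nrow(x$table), nrow(x$labels), ncol(x$labels),
              x$pixel_size_um))
  invisible(x)
}

#' Extract per-nucleus ratio traces
#'
#' Averages the ratio over each (static) nucleus mask at every frame.
#' With `method = "ratio_of_sums"` the per-cell ratio is instead
#' `sum(FRET) / sum(CFP)` over the mask, which weights pixels by donor
#' intensity; the default averages pixelwise ratios.
#'
#' @param x An [image_stack()] (required for `"ratio_of_sums"`) or a 3-d
#'   ratio array.
#' @param labels A [segment_nuclei()] label map.
#' @param frame_interval_min Minutes per frame (taken from `x` when it is
#'   an `image_stack`).
#' @param method `"mean_ratio"` (default) or `"ratio_of_sums"`.
#' @param cfp_floor Donor floor used when `x` is an `image_stack`.
#' @return Trace table: `cell_id`, `x_um`, `y_um`, `t_min`, `ratio`
#'   (`NA` at frames where the whole mask is masked out).
#' @export
extract_traces <- function(x, labels, frame_interval_min = NULL,
                           method = c("mean_ratio", "ratio_of_sums"),
                           cfp_floor = 1) {
  method <- match.arg(method)
  is_stack <- inherits(x, "image_stack")
  if (is.null(frame_interval_min)) {
    if (!is_stack) stop("frame_interval_min required for a ratio array")
    frame_interval_min <- x$frame_interval_min
  }
  labmat <- labels$labels
  tab <- labels$table
  if (!nrow(tab))
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), t_min = numeric(0),
                      ratio = numeric(0)))
  idx <- which(labmat > 0)
  l <- labmat[idx]
  nlab <- nrow(tab)
  if (method == "ratio_of_sums") {
    if (!is_stack) stop("ratio_of_sums requires an image_stack")
    fret <- get_channel(x, "FRET"); cfp <- get_channel(x, "CFP")
    nT <- dim(fret)[3]
    vals <- matrix(NA_real_, nT, nlab)
    for (f in seq_len(nT)) {
      cf <- cfp[, , f][idx]
      fr <- fret[, , f][idx]
      ok <- cf >= cfp_floor
      s_f <- rowsum(ifelse(ok, fr, 0), l)[, 1]
      s_c <- rowsum(ifelse(ok, cf, 0), l)[, 1]
      v <- s_f / s_c
      v[s_c == 0] <- NA_real_
      vals[f, as.integer(rownames(rowsum(ifelse(ok, fr, 0), l)))] <- v
    }
  } else {
    ratio <- if (is_stack) compute_ratio_stack(x, cfp_floor = cfp_floor)
             else x
    nT <- dim(ratio)[3]
    vals <- matrix(NA_real_, nT, nlab)
    for (f in seq_len(nT)) {
      v <- ratio[, , f][idx]
      ok <- !is.na(v)
      cnt <- rowsum((ok) * 1, l)[, 1]
      s <- rowsum(ifelse(ok, v, 0), l)[, 1]
      m <- s / cnt
      m[cnt == 0] <- NA_real_
      vals[f, as.integer(names(cnt))] <- m
    }
  }
  t_min <- (seq_len(nT) - 1L) * frame_interval_min
  data.frame(cell_id = rep(tab$label, each = nT),
             x_um = rep(tab$x_um, each = nT),
             y_um = rep(tab$y_um, each = nT),
             t_min = rep(t_min, nlab),
             ratio = as.vector(vals))
}

#' Mask-aware mean ratio per frame
#'
#' @param ratio 3-d ratio array `[row, col, frame]`.
#' @return Numeric vector, one spatial mean per frame (`NA` when a frame
#'   is entirely masked).
#' @export
mean_field_ratio <- function(ratio) {
  if (length(dim(ratio)) == 2) ratio <- array(ratio, c(dim(ratio), 1))
  apply(ratio, 3, function(fr)
    if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE))
}
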