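#' Write an image stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered channel-major (all frames of the first channel,
#' then the next channel). Intensities are stored as 32-bit floats
#' scaled into `[0, 1]`; the scale factor and the physical calibration
#' (um/px, min/frame, channel names) go into `<path>.yaml`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- list()
  for (ch in seq_len(d[4])) for (f in seq_len(d[3]))
    pages[[length(pages) + 1]] <- stack$data[, , f, ch] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               frame_interval_min = stack$frame_interval_min,
               channel_names = as.list(stack$channel_names),
               n_frames = d[3], intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (with `<path>.yaml` sidecar alongside).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  chn <- unlist(meta$channel_names)
  nT <- meta$n_frames
  stopifnot(length(pages) == nT * length(chn))
  dims <- dim(pages[[1]])
  data <- array(0, c(dims[1], dims[2], nT, length(chn)),
                dimnames = list(NULL, NULL, NULL, chn))
  i <- 1
  for (ch in seq_along(chn)) for (f in seq_len(nT)) {
    data[, , f, ch] <- pages[[i]] * meta$intensity_scale
    i <- i + 1
  }
  image_stack(data, meta$pixel_size_um, meta$frame_interval_min)
}

#' Write or read a trace table as CSV
#' @param traces Trace table.
#' @param path CSV path.
#' @return `path` (write) or the trace table (read).
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path)
}

#' Serialise generator ground truth to JSON
#'
#' @param truth A list of generator artefacts (configs, truths, event
#'   tables); classed objects are flattened to plain lists.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.matrix(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a label map as 16-bit TIFF
#' @param labels A [segment_nuclei()] label map.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a rendered display frame as PNG
#' @param rendered A [render_imd()] result.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_render_png <- function(rendered, path) {
  png::writePNG(rendered$rgb, path)
  invisible(path)
}
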