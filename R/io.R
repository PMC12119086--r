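# Readers and writers for the pipeline's on-disk formats: multi-page TIFF
# stacks, behavior/ground-truth/event/trace CSVs with JSON sidecars.

#' Write / read a frame stack as multi-page 16-bit TIFF
#'
#' Intensities are scaled by `max_intensity` into the 16-bit range on write
#' and rescaled on read, so a round trip recovers values up to 16-bit
#' quantization.
#'
#' @param stack Numeric array (height x width x frames).
#' @param path TIFF file path.
#' @param max_intensity Intensity mapped to the top of the 16-bit range
#'   (default: the stack maximum). Stored in a `<path>.json` sidecar.
#' @return `write_stack()`: `path`, invisibly. `read_stack()`: the array.
#' @export
write_stack <- function(stack, path, max_intensity = max(stack)) {
  frames <- lapply(seq_len(dim(stack)[3]), function(t)
    pmin(pmax(stack[, , t] / max_intensity, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(list(max_intensity = max_intensity,
                            n_frames = dim(stack)[3]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, max_intensity = NULL) {
  if (is.null(max_intensity)) {
    sidecar <- paste0(path, ".json")
    max_intensity <- if (file.exists(sidecar))
      jsonlite::read_json(sidecar)$max_intensity else 1
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]] * max_intensity
  arr
}

#' Write / read a behavior log CSV
#'
#' Columns: `time_s`, `running_speed_cmps`, `visual_flow_cmps`,
#' `grating_on`, `mismatch_on`, `opto_on`.
#' @param log Behavior log tibble.
#' @param path CSV path.
#' @param frame_rate Frame rate attached on read (inferred from `time_s`
#'   when `NULL`).
#' @export
write_behavior_log <- function(log, path) {
  readr::write_csv(as_tibble(log), path)
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path, frame_rate = NULL) {
  log <- readr::read_csv(path, show_col_types = FALSE)
  rate <- frame_rate %||% 1 / median(diff(log$time_s))
  attr(log, "frame_rate") <- rate
  class(log) <- c("behavior_log", class(log))
  log
}

#' Write ground truth as a per-frame CSV plus a JSON geometry sidecar
#'
#' Truth columns are `true_`-prefixed; soma-level series are spread into one
#' column per soma. Scene geometry and the config go into `<path>.json`.
#'
#' @param truth A `ground_truth` from [render_frames()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  att <- truth$attenuation |>
    tidyr::pivot_wider(names_from = "soma_id",
                       values_from = c("true_attenuation",
                                       "true_soma_fluorescence"))
  tab <- truth$area |>
    dplyr::rename(true_area_um2 = "area_um2") |>
    left_join(att, by = "frame") |>
    left_join(dplyr::rename(truth$shifts, true_dx = "dx", true_dy = "dy"),
              by = "frame")
  readr::write_csv(tab, path)
  cfg <- unclass(truth$config)
  cfg$coupling_kernels <- lapply(cfg$coupling_kernels, unclass)
  jsonlite::write_json(
    list(somata = truth$somata, config = cfg),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an event set CSV with a JSON provenance sidecar
#' @param events An `event_set` tibble.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  readr::write_csv(as_tibble(events), path)
  prov <- attr(events, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(kind = "c", frame = "i",
                                                time_s = "d"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(ev, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  class(ev) <- c("event_set", class(ev))
  ev
}

#' Write / read dF/F0 traces as a wide CSV plus a JSON sidecar
#'
#' One column per ROI, a leading `frame` column; `F0` and the frame rate go
#' into `<path>.json`.
#' @param dff Long dF/F0 tibble from [compute_dff_traces()].
#' @param path CSV path.
#' @export
write_traces <- function(dff, path) {
  wide <- tidyr::pivot_wider(dff[, c("roi_id", "frame", "dff")],
                             names_from = "roi_id", values_from = "dff")
  readr::write_csv(wide, path)
  jsonlite::write_json(
    list(frame_rate = attr(dff, "frame_rate"),
         f0 = attr(dff, "f0")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"frame", names_to = "roi_id",
                              values_to = "dff")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(long, "frame_rate") <- meta$frame_rate
    attr(long, "f0") <- as_tibble(meta$f0)
    long$time_s <- frame_time(long$frame, meta$frame_rate)
  }
  long
}

#' Write / read an ROI table CSV (0-based half-open rectangles)
#' @param rois ROI tibble (see [scene_rois()]).
#' @param path CSV path.
#' @export
write_rois <- function(rois, path) {
  readr::write_csv(rois, path)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(roi_id = "c", kind = "c"))
}
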