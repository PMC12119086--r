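# Rigid registration, ROI trace extraction, percentile-baseline drift
# correction, and dF/F0 computation.

roi_rect_mask <- function(h, w, x0, y0, x1, y1) {
  if (x1 <= x0 || y1 <= y0 || x0 < 0 || y0 < 0 || x1 > w || y1 > h)
    abort("ROI rectangle empty or outside frame bounds",
          class = "hemoccl_roi_error")
  m <- matrix(FALSE, h, w)
  m[(y0 + 1):y1, (x0 + 1):x1] <- TRUE
  m
}

as_roi_mask <- function(roi, dim) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dim[1:2]))
      abort("mask dimensions do not match the stack", class = "hemoccl_roi_error")
    return(roi)
  }
  roi <- as.list(roi)
  roi_rect_mask(dim[1], dim[2], roi$x0, roi$y0, roi$x1, roi$y1)
}

#' Register a frame stack by integer rigid translation
#'
#' Each frame's displacement relative to the reference is estimated by
#' exhaustive search over integer shifts within `radius`, maximizing the
#' Pearson correlation between the back-shifted frame and the reference. Ties
#' are broken by the smallest Euclidean shift, then lexicographically. The
#' corrected stack translates every frame by the negative of its estimated
#' shift; exposed pixels are filled with the frame median.
#'
#' @param stack Numeric array (height x width x frames), at least 2 frames.
#' @param reference `"mean"` (default) for the stack mean image, or a frame
#'   index.
#' @param radius Maximum absolute shift searched, pixels.
#' @return A list of class `registered_stack`: `stack` (corrected array) and
#'   `shifts` (tibble `frame`, `dx`, `dy` of estimated frame displacements).
#' @export
register_frames <- function(stack, reference = "mean", radius = 5) {
  if (length(dim(stack)) != 3 || dim(stack)[3] < 2)
    abort("`stack` must be an array with at least 2 frames",
          class = "hemoccl_config_error")
  ref <- if (identical(reference, "mean")) {
    apply(stack, c(1, 2), mean)
  } else {
    stack[, , as.integer(reference)]
  }
  ref_v <- as.numeric(ref)
  n <- dim(stack)[3]
  grid <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  grid <- grid[order(grid$dx^2 + grid$dy^2, grid$dx, grid$dy), ]
  out <- array(0, dim = dim(stack))
  shifts <- tibble(frame = seq_len(n), dx = 0L, dy = 0L)
  for (t in seq_len(n)) {
    fr <- stack[, , t]
    if (sd(fr) == 0) {
      warn(sprintf("frame %d has zero variance; shift set to (0, 0)", t))
      out[, , t] <- fr
      next
    }
    fill <- median(fr)
    best <- c(0L, 0L); best_score <- -Inf
    for (i in seq_len(nrow(grid))) {
      cand <- translate_int(fr, -grid$dx[i], -grid$dy[i], fill)
      score <- suppressWarnings(cor(as.numeric(cand), ref_v))
      if (is.finite(score) && score > best_score + 1e-12) {
        best_score <- score
        best <- c(grid$dx[i], grid$dy[i])
      }
    }
    shifts$dx[t] <- best[1]; shifts$dy[t] <- best[2]
    out[, , t] <- translate_int(fr, -best[1], -best[2], fill)
  }
  structure(list(stack = out, shifts = shifts, reference = ref),
            class = "registered_stack")
}

#' Extract the mean-intensity trace of one ROI
#'
#' Per-frame arithmetic mean over the ROI pixels. No neuropil subtraction is
#' applied.
#'
#' @param stack Numeric array (height x width x frames) or
#'   `registered_stack`.
#' @param roi A logical mask matrix, or anything with fields `x0`, `y0`,
#'   `x1`, `y1` (0-based, half-open rectangle).
#' @return Numeric vector, one value per frame (arbitrary units).
#' @export
extract_roi_trace <- function(stack, roi) {
  if (inherits(stack, "registered_stack")) stack <- stack$stack
  mask <- as_roi_mask(roi, dim(stack))
  if (!any(mask)) abort("ROI mask is empty", class = "hemoccl_roi_error")
  idx <- which(mask)
  npx <- length(idx)
  mat <- matrix(stack, nrow = prod(dim(stack)[1:2]))
  colSums(mat[idx, , drop = FALSE]) / npx
}

#' Extract traces for a table of ROIs
#'
#' @param stack Numeric array or `registered_stack`.
#' @param rois ROI tibble as produced by [scene_rois()] (columns `roi_id`,
#'   `kind`, `x0`, `y0`, `x1`, `y1`, ...).
#' @return A long tibble: `roi_id`, `kind`, `frame`, `value`.
#' @export
extract_traces <- function(stack, rois) {
  if (inherits(stack, "registered_stack")) stack <- stack$stack
  purrr::map(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    tibble(roi_id = roi$roi_id, kind = roi$kind,
           frame = seq_len(dim(stack)[3]),
           value = extract_roi_trace(stack, roi))
  }) |> dplyr::bind_rows()
}

#' Running-percentile baseline of a fluorescence trace
#'
#' For each frame, the given percentile of the trace over a centered window,
#' truncated at the recording edges. The default 8th percentile over 66 s
#' tracks slow drift while ignoring transients.
#'
#' @param trace Numeric vector (raw fluorescence, a.u.).
#' @param frame_rate Frame rate, Hz.
#' @param window_s Window length, seconds (window of
#'   `round(window_s * frame_rate)` frames, at least 3).
#' @param percentile Percentile in `[0, 100]`.
#' @return Numeric baseline vector of the same length.
#' @export
percentile_baseline <- function(trace, frame_rate, window_s = 66,
                                percentile = 8) {
  if (length(trace) < 3)
    abort("trace must have at least 3 frames", class = "hemoccl_config_error")
  win <- max(3L, as.integer(round(window_s * frame_rate)))
  # order-statistic percentile (inverse ECDF), as in percentile filters
  as.numeric(zoo::rollapply(zoo::zoo(trace), width = win,
                            FUN = quantile, probs = percentile / 100,
                            names = FALSE, type = 1,
                            partial = TRUE, align = "center"))
}

#' Drift-corrected, median-normalized dF/F0
#'
#' The baseline is subtracted and its mean re-added, preserving the absolute
#' intensity scale; `F0` is the overall median of the drift-corrected trace
#' and `dF/F0 = (F_c - F0) / F0`.
#'
#' @param trace Raw fluorescence trace (a.u.).
#' @param baseline Baseline from [percentile_baseline()].
#' @param frame_rate Frame rate, Hz (stored on the result).
#' @param roi_id Optional ROI label used in error messages.
#' @return A `dff_trace` list: `roi_id`, `values` (dF/F0 per frame),
#'   `frame_rate`, `f0`.
#' @export
compute_dff <- function(trace, baseline, frame_rate = NA_real_,
                        roi_id = NULL) {
  if (length(trace) != length(baseline))
    abort("trace and baseline lengths differ", class = "hemoccl_config_error")
  fc <- trace - baseline + mean(baseline)
  f0 <- median(fc)
  if (!is.finite(f0) || f0 <= 0)
    abort(sprintf("non-positive F0 for ROI %s", roi_id %||% "<unnamed>"),
          class = "hemoccl_dff_error")
  structure(list(roi_id = roi_id, values = (fc - f0) / f0,
                 frame_rate = frame_rate, f0 = f0),
            class = "dff_trace")
}

#' dF/F0 traces for a long trace table
#'
#' Applies [percentile_baseline()] and [compute_dff()] per ROI.
#'
#' @param traces Long tibble from [extract_traces()] (`roi_id`, `frame`,
#'   `value`).
#' @param frame_rate Frame rate, Hz.
#' @param window_s,percentile Baseline parameters.
#' @return A long tibble `roi_id`, `frame`, `time_s`, `dff`, with a `f0`
#'   attribute tibble (`roi_id`, `f0`).
#' @export
compute_dff_traces <- function(traces, frame_rate, window_s = 66,
                               percentile = 8) {
  parts <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_split()
  res <- purrr::map(parts, function(d) {
    bl <- percentile_baseline(d$value, frame_rate, window_s, percentile)
    dt <- compute_dff(d$value, bl, frame_rate, roi_id = d$roi_id[1])
    list(tbl = tibble(roi_id = d$roi_id[1], frame = d$frame,
                      time_s = frame_time(d$frame, frame_rate),
                      dff = dt$values),
         f0 = tibble(roi_id = d$roi_id[1], f0 = dt$f0))
  })
  out <- dplyr::bind_rows(purrr::map(res, "tbl"))
  attr(out, "f0") <- dplyr::bind_rows(purrr::map(res, "f0"))
  attr(out, "frame_rate") <- frame_rate
  out
}
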