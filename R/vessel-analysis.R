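# Blood-vessel cross-section estimation (binarize + ellipse fit), the lumen
# fluorescence proxy, smoothing, variance explained, and display outliers.

# 8-connected component labeling of a logical matrix (flood fill).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% h + 1L
      c <- (p - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Moment-based ellipse fit to a set of pixels (rows r, cols c): the ellipse
# with the same second central moments as the pixel set. For a solid ellipse
# the variance along a principal axis is (semi-axis)^2 / 4.
fit_ellipse_moments <- function(r, c) {
  n <- length(r)
  cx <- mean(c); cy <- mean(r)
  # population moments with the 1/12 square-pixel sampling correction
  mu20 <- sum((c - cx)^2) / n + 1 / 12
  mu02 <- sum((r - cy)^2) / n + 1 / 12
  mu11 <- sum((c - cx) * (r - cy)) / n
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  a <- 2 * sqrt(l1)
  b <- 2 * sqrt(l2)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  list(cx = cx, cy = cy, a = a, b = b, theta_deg = theta,
       area = pi * a * b)
}

#' Estimate vessel cross-section per frame by binarize + ellipse fit
#'
#' A single intensity threshold -- the 0.5th percentile of all pixel
#' intensities in the (trial-averaged) video -- binarizes every frame; the
#' largest 8-connected below-threshold component is taken as the vessel
#' lumen, and an ellipse with the same second central moments is fitted to
#' it. The ellipse area `pi * a * b` estimates the vessel cross-section.
#'
#' @param stack Trial-averaged video cropped to the vessel box: numeric
#'   array (height x width x frames).
#' @param percentile Binarization percentile of all video intensities.
#' @param pixel_size_um Optional pixel size; adds an `area_um2` column.
#' @return Tibble per frame: `frame`, `area_px2`, ellipse parameters (`cx`,
#'   `cy`, `a`, `b`, `theta_deg`), component pixel count `n_px`, and
#'   `truncated` (component touches the box edge). Frames with no
#'   below-threshold pixels get area 0 with a warning.
#' @export
vessel_area_trace <- function(stack, percentile = 0.5, pixel_size_um = NULL) {
  if (length(dim(stack)) != 3)
    abort("`stack` must be a height x width x frames array",
          class = "hemoccl_config_error")
  thr <- quantile(stack, percentile / 100, names = FALSE)
  n <- dim(stack)[3]
  h <- dim(stack)[1]; w <- dim(stack)[2]
  rows <- vector("list", n)
  n_empty <- 0L
  for (t in seq_len(n)) {
    mask <- stack[, , t] < thr
    if (!any(mask)) {
      n_empty <- n_empty + 1L
      rows[[t]] <- tibble(frame = t, area_px2 = 0, cx = NA_real_,
                          cy = NA_real_, a = NA_real_, b = NA_real_,
                          theta_deg = NA_real_, n_px = 0L, truncated = FALSE)
      next
    }
    lab <- label_components8(mask)
    sizes <- tabulate(lab)
    biggest <- which.max(sizes)
    px <- which(lab == biggest)
    r <- (px - 1L) %% h + 1L
    c <- (px - 1L) %/% h + 1L
    fit <- fit_ellipse_moments(r, c)
    rows[[t]] <- tibble(frame = t, area_px2 = fit$area, cx = fit$cx,
                        cy = fit$cy, a = fit$a, b = fit$b,
                        theta_deg = fit$theta_deg, n_px = length(px),
                        truncated = any(r == 1L | r == h | c == 1L | c == w))
  }
  if (n_empty > 0)
    warn(sprintf("%d frame(s) had no below-threshold pixels; area set to 0",
                 n_empty))
  out <- dplyr::bind_rows(rows)
  if (any(out$truncated))
    inform(sprintf("%d frame(s) flagged: vessel component touches the box edge",
                   sum(out$truncated)))
  if (!is.null(pixel_size_um))
    out$area_um2 <- out$area_px2 * pixel_size_um^2
  out
}

#' Lumen-ROI fluorescence proxy for vessel cross-section
#'
#' The mean fluorescence of a fixed ROI fully contained in the vessel at
#' rest, run through the standard dF/F0 pipeline. Since the lumen itself is
#' dark, any signal comes from surrounding labeled tissue entering the point
#' spread function: the proxy rises as the vessel constricts and falls as it
#' dilates.
#'
#' @param stack Numeric array or `registered_stack`.
#' @param lumen_roi ROI (mask matrix or rectangle fields).
#' @param frame_rate Frame rate, Hz.
#' @param window_s,percentile Baseline parameters (see
#'   [percentile_baseline()]).
#' @return A `dff_trace` for the lumen ROI.
#' @export
vessel_lumen_trace <- function(stack, lumen_roi, frame_rate, window_s = 66,
                               percentile = 8) {
  tr <- extract_roi_trace(stack, lumen_roi)
  bl <- percentile_baseline(tr, frame_rate, window_s, percentile)
  compute_dff(tr, bl, frame_rate, roi_id = "vessel_lumen")
}

#' Centered moving average
#'
#' Boxcar of width `width_s`, rounded to the nearest odd frame count,
#' truncated at the edges (partial windows average the available frames).
#'
#' @param x Numeric series.
#' @param frame_rate Frame rate, Hz.
#' @param width_s Boxcar width, seconds.
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(x, frame_rate, width_s = 0.5) {
  w <- as.integer(round(width_s * frame_rate))
  if (w %% 2L == 0L) w <- w - 1L
  w <- max(1L, w)
  if (w == 1L) return(as.numeric(x))
  as.numeric(zoo::rollapply(zoo::zoo(x), width = w, FUN = mean,
                            partial = TRUE, align = "center"))
}

#' Variance in one signal explained by another
#'
#' `R^2`, the squared Pearson correlation between the two (pre-smoothed)
#' signals -- either over a window relative to an event onset (the default
#' -2 s to +6 s) or, with `onset = NULL`, over the entire series.
#'
#' @param x,y Numeric series of equal length (e.g. vessel area and the mean
#'   neuronal dF/F0), smoothed with [moving_average()] beforehand.
#' @param onset Optional onset frame; when given, `R^2` is computed on the
#'   mapped `window`.
#' @param window Window `c(from, to)` in seconds relative to `onset`.
#' @param frame_rate Frame rate, Hz (required with `onset`).
#' @return `R^2` in `[0, 1]`, or `NA` if either signal has zero variance in
#'   the window.
#' @export
variance_explained <- function(x, y, onset = NULL, window = c(-2, 6),
                               frame_rate = NULL) {
  if (length(x) != length(y))
    abort("series lengths differ", class = "hemoccl_config_error")
  if (!is.null(onset)) {
    if (is.null(frame_rate))
      abort("`frame_rate` required with `onset`", class = "hemoccl_config_error")
    idx <- onset + window_to_offsets(window[1], window[2], frame_rate)
    idx <- idx[idx >= 1 & idx <= length(x)]
    x <- x[idx]; y <- y[idx]
  }
  if (sd(x) == 0 || sd(y) == 0) {
    inform("zero variance in a series; variance explained undefined")
    return(NA_real_)
  }
  cor(x, y)^2
}

#' Tukey-fence outlier mask
#'
#' Flags values above `Q3 + 1.5 * IQR` or below `Q1 - 1.5 * IQR`. Used only
#' to omit points from display; never for statistics.
#'
#' @param values Numeric vector (>= 4 values).
#' @return Logical mask, `TRUE` for outliers.
#' @export
iqr_outlier_mask <- function(values) {
  if (length(values) < 4)
    abort("need at least 4 values", class = "hemoccl_config_error")
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  values > q[2] + 1.5 * iqr | values < q[1] - 1.5 * iqr
}
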