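# Event onset detection and behavioral state masks.
#
# Locomotion onset rule: running speed crosses 0.25 cm/s and stays at or
# above it for at least 1 s, having been strictly below it for the whole
# preceding 1 s. The same rule applied to visual flow speed defines visual
# flow onsets.

#' Detect threshold-crossing onsets in a speed trace
#'
#' A frame `f` is an onset iff `speed[f] >= threshold`, the speed is
#' `>= threshold` at every frame of the following `min_above_s` window
#' (including `f`), and `< threshold` at every frame of the preceding
#' `min_below_s` window. Frames whose windows extend past the recording are
#' never onsets.
#'
#' @param speed Numeric speed trace, cm/s.
#' @param frame_rate Frame rate, Hz.
#' @param threshold Speed threshold, cm/s.
#' @param min_above_s Required time at/above threshold from the onset, s.
#' @param min_below_s Required time below threshold before the onset, s.
#' @return Integer vector of onset frames (1-based).
#' @export
detect_onsets <- function(speed, frame_rate, threshold = 0.25,
                          min_above_s = 1, min_below_s = 1) {
  if (threshold <= 0 || min_above_s <= 0 || min_below_s <= 0)
    abort("threshold and window lengths must be positive",
          class = "hemoccl_config_error")
  n <- length(speed)
  above_f <- as.integer(round(min_above_s * frame_rate))
  below_f <- as.integer(round(min_below_s * frame_rate))
  if (n < above_f + below_f) {
    warn("speed trace shorter than min_above + min_below; no onsets")
    return(integer(0))
  }
  above <- speed >= threshold
  # run of consecutive above-threshold frames starting at f
  run_above <- rev(Reduce(function(acc, x) if (x) acc + 1L else 0L,
                          rev(above), accumulate = TRUE))
  # run of consecutive below-threshold frames ending at f
  run_below <- Reduce(function(acc, x) if (x) acc + 1L else 0L,
                      !above, accumulate = TRUE)
  cand <- which(above &
                  run_above >= above_f &
                  dplyr::lag(run_below, default = 0L) >= below_f)
  cand[cand - below_f >= 1L & cand + above_f - 1L <= n]
}

#' Validate visuomotor mismatch events against sustained locomotion
#'
#' A mismatch onset (first frame of each contiguous flag run) is retained iff
#' the running speed is at or above `threshold` at every frame of the
#' validity window around the onset. Events whose window extends past the
#' recording are dropped with a message.
#'
#' @param mismatch_on Logical per-frame mismatch flag.
#' @param speed Running speed, cm/s, aligned to the flags.
#' @param frame_rate Frame rate, Hz.
#' @param threshold Locomotion threshold, cm/s (0.25 by default; a relaxed
#'   0.12 is used when triggers are scarce).
#' @param window Validity window `c(from, to)` in seconds around the onset.
#' @return Integer vector of valid mismatch onset frames.
#' @export
validate_mismatch_events <- function(mismatch_on, speed, frame_rate,
                                     threshold = 0.25,
                                     window = c(-0.5, 1)) {
  if (length(mismatch_on) != length(speed))
    abort("flags and speed must be aligned", class = "hemoccl_config_error")
  onsets <- flag_rising_edges(mismatch_on)
  keep <- vapply(onsets, function(f) {
    lo <- f + as.integer(round(window[1] * frame_rate))
    hi <- f + as.integer(round(window[2] * frame_rate))
    if (lo < 1L || hi > length(speed)) {
      inform(sprintf("mismatch at frame %d dropped: validity window leaves recording", f))
      return(FALSE)
    }
    all(speed[lo:hi] >= threshold)
  }, logical(1))
  onsets[keep]
}

# Frames eligible as random locomotion triggers: satisfy the mismatch
# validity rule, and (optionally) lie at least `exclude_s` from any true
# mismatch onset.
eligible_trigger_frames <- function(speed, frame_rate, threshold = 0.25,
                                    window = c(-0.5, 1),
                                    mismatch_onsets = integer(0),
                                    exclude_s = 1) {
  n <- length(speed)
  lo_f <- as.integer(round(window[1] * frame_rate))
  hi_f <- as.integer(round(window[2] * frame_rate))
  ok <- vapply(seq_len(n), function(f) {
    lo <- f + lo_f; hi <- f + hi_f
    lo >= 1L && hi <= n && all(speed[lo:hi] >= threshold)
  }, logical(1))
  if (length(mismatch_onsets) > 0) {
    ex <- as.integer(round(exclude_s * frame_rate))
    for (m in mismatch_onsets) {
      lo <- max(1L, m - ex); hi <- min(n, m + ex)
      ok[lo:hi] <- FALSE
    }
  }
  which(ok)
}

#' Sample random locomotion triggers
#'
#' Uniform sample, without replacement, of frames that satisfy the mismatch
#' validity rule (sustained locomotion over the window), excluding frames
#' within `exclude_s` of a true mismatch onset. Used to construct the
#' random-trigger chance distribution of event-triggered responses during
#' locomotion.
#'
#' @param speed Running speed, cm/s.
#' @param frame_rate Frame rate, Hz.
#' @param n_triggers Number of triggers to draw.
#' @param threshold Locomotion threshold, cm/s.
#' @param window Validity window in seconds around each trigger.
#' @param mismatch_onsets True mismatch onset frames to exclude around.
#' @param exclude_s Exclusion half-width around true mismatches, s.
#' @param seed Integer seed; the draw is reproducible.
#' @return Sorted integer vector of trigger frames.
#' @export
sample_random_triggers <- function(speed, frame_rate, n_triggers,
                                   threshold = 0.25, window = c(-0.5, 1),
                                   mismatch_onsets = integer(0),
                                   exclude_s = 1, seed = NULL) {
  elig <- eligible_trigger_frames(speed, frame_rate, threshold, window,
                                  mismatch_onsets, exclude_s)
  if (length(elig) < n_triggers)
    abort(sprintf("only %d eligible frames for %d requested triggers",
                  length(elig), n_triggers),
          class = "hemoccl_trigger_error")
  sort(with_seed(seed, sample(elig, n_triggers)))
}

#' Per-frame locomotion state
#'
#' @param speed Running speed, cm/s.
#' @param threshold Locomotion threshold, cm/s.
#' @return Character vector, `"locomoting"` where `speed >= threshold`, else
#'   `"stationary"`. No hysteresis is applied.
#' @export
locomotion_state_mask <- function(speed, threshold = 0.25) {
  ifelse(speed >= threshold, "locomoting", "stationary")
}

#' Derive a validated event set from a behavior log
#'
#' Locomotion and visual-flow onsets come from the threshold rule
#' ([detect_onsets()]); grating and opto onsets are rising edges of their
#' stimulus flags; mismatch onsets are validated against sustained
#' locomotion.
#'
#' @param log A behavior log tibble.
#' @param frame_rate Frame rate, Hz (default: the log's attribute).
#' @param threshold Locomotion/visual-flow onset threshold, cm/s.
#' @param mismatch_threshold Mismatch validity threshold, cm/s.
#' @return An `event_set` tibble: `kind`, `frame`, `time_s`, with detection
#'   parameters recorded in the `provenance` attribute.
#' @export
detect_events <- function(log, frame_rate = NULL, threshold = 0.25,
                          mismatch_threshold = 0.25) {
  rate <- behavior_frame_rate(log, frame_rate)
  loco <- detect_onsets(log$running_speed_cmps, rate, threshold)
  flow <- detect_onsets(log$visual_flow_cmps, rate, threshold)
  grat <- flag_rising_edges(log$grating_on)
  opto <- flag_rising_edges(log$opto_on)
  mism <- validate_mismatch_events(log$mismatch_on, log$running_speed_cmps,
                                   rate, mismatch_threshold)
  ev <- dplyr::bind_rows(
    tibble(kind = "locomotion_onset", frame = loco),
    tibble(kind = "visual_flow_onset", frame = flow),
    tibble(kind = "grating_onset", frame = grat),
    tibble(kind = "opto", frame = opto),
    tibble(kind = "mismatch", frame = mism)
  ) |>
    mutate(frame = as.integer(.data$frame),
           time_s = frame_time(.data$frame, rate)) |>
    arrange(.data$kind, .data$frame)
  attr(ev, "provenance") <- list(frame_rate = rate, threshold = threshold,
                                 mismatch_threshold = mismatch_threshold,
                                 min_above_s = 1, min_below_s = 1,
                                 mismatch_window_s = c(-0.5, 1))
  class(ev) <- c("event_set", class(ev))
  ev
}
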