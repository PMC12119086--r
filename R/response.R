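# Event-triggered response extraction, responsiveness tests, and the
# random-trigger chance band.

# Analysis-window presets, seconds relative to onset. The "responsiveness"
# profile feeds the per-neuron t-test; the "comparison" profile matches the
# trial-averaged response-amplitude comparisons.
window_profiles <- list(
  responsiveness = list(
    baseline = list(locomotion_onset = c(-1, -0.5), default = c(-0.5, 0)),
    response = list(grating_onset = c(0.5, 2.5), default = c(0.5, 1.5))
  ),
  comparison = list(
    baseline = list(grating_onset = c(-0.5, 0), default = c(-1, -0.5)),
    response = list(grating_onset = c(0.5, 3), default = c(0, 2))
  )
)

profile_window <- function(profile, which, kind) {
  p <- window_profiles[[profile]]
  if (is.null(p)) abort(sprintf("unknown window profile '%s'", profile),
                        class = "hemoccl_config_error")
  p[[which]][[kind]] %||% p[[which]][["default"]]
}

#' Event-triggered trial matrix for one ROI
#'
#' Slices the dF/F0 trace into windows `[-pre_s, +post_s)` around each event
#' onset. Events whose window leaves the recording are dropped with a
#' message; an ROI needs at least three surviving trials to be included.
#'
#' @param values Numeric dF/F0 trace (or a `dff_trace`).
#' @param events Integer event onset frames.
#' @param frame_rate Frame rate, Hz.
#' @param pre_s,post_s Window extent before/after onset, seconds (> 0).
#' @param kind Event kind label (selects default windows downstream).
#' @param roi_id Optional ROI label.
#' @return A `trial_matrix`: trials x time-bin matrix plus the relative time
#'   axis, surviving event frames, and bookkeeping. `included` is `FALSE`
#'   when fewer than 3 trials survive.
#' @export
event_triggered_matrix <- function(values, events, frame_rate,
                                   pre_s = 1, post_s = 1.5,
                                   kind = "event", roi_id = NULL) {
  if (inherits(values, "dff_trace")) {
    roi_id <- roi_id %||% values$roi_id
    values <- values$values
  }
  if (pre_s <= 0 || post_s <= 0)
    abort("`pre_s` and `post_s` must be positive", class = "hemoccl_config_error")
  offsets <- window_to_offsets(-pre_s, post_s, frame_rate)
  n <- length(values)
  ok <- events + min(offsets) >= 1L & events + max(offsets) <= n
  if (any(!ok))
    inform(sprintf("%d %s event(s) dropped: incomplete window", sum(!ok), kind))
  events <- events[ok]
  mat <- if (length(events) > 0) {
    t(vapply(events, function(f) values[f + offsets], numeric(length(offsets))))
  } else {
    matrix(numeric(0), 0, length(offsets))
  }
  structure(list(roi_id = roi_id, kind = kind, mat = mat,
                 offsets = offsets, time_s = offsets / frame_rate,
                 frame_rate = frame_rate, events = events,
                 n_dropped = sum(!ok), included = length(events) >= 3,
                 baseline_window = NULL),
            class = "trial_matrix")
}

offsets_in_window <- function(tm, window) {
  want <- window_to_offsets(window[1], window[2], tm$frame_rate)
  if (!all(want %in% tm$offsets))
    abort("window maps outside the trial matrix time bins",
          class = "hemoccl_window_error")
  tm$offsets %in% want
}

#' Baseline-subtract a trial matrix
#'
#' Subtracts each trial's mean over the baseline window from that trial's
#' row. Defaults: -1 to -0.5 s before locomotion onsets (preparatory
#' activity), -0.5 to 0 s otherwise.
#'
#' @param tm A [event_triggered_matrix()].
#' @param baseline_window `c(from, to)` seconds (inside `[-pre, 0]`), or
#'   `NULL` for the kind's default from `profile`.
#' @param profile Window profile name.
#' @return The trial matrix with baseline-subtracted rows.
#' @export
baseline_subtract <- function(tm, baseline_window = NULL,
                              profile = "responsiveness") {
  bw <- baseline_window %||% profile_window(profile, "baseline", tm$kind)
  if (bw[2] > 1e-9)
    abort("baseline window must lie inside [-pre, 0]",
          class = "hemoccl_window_error")
  idx <- offsets_in_window(tm, bw)
  if (nrow(tm$mat) > 0)
    tm$mat <- tm$mat - rowMeans(tm$mat[, idx, drop = FALSE])
  tm$baseline_window <- bw
  tm
}

#' Per-trial mean responses over the response window
#'
#' @param tm A baseline-subtracted [event_triggered_matrix()].
#' @param response_window `c(from, to)` seconds inside `[0, post]`, or `NULL`
#'   for the kind's default from `profile` (+0.5 to +1.5 s for locomotion and
#'   mismatch, +0.5 to +2.5 s for gratings under `"responsiveness"`).
#' @param profile Window profile name.
#' @return Numeric vector of per-trial window means.
#' @export
trial_mean_response <- function(tm, response_window = NULL,
                                profile = "responsiveness") {
  rw <- response_window %||% profile_window(profile, "response", tm$kind)
  if (rw[1] < -1e-9)
    abort("response window must lie inside [0, post]",
          class = "hemoccl_window_error")
  idx <- offsets_in_window(tm, rw)
  rowMeans(tm$mat[, idx, drop = FALSE])
}

#' One-sample responsiveness t-test
#'
#' Two-sided one-sample t-test of the per-trial window means against zero; a
#' neuron is responsive when `p < alpha` (5% chance threshold by default).
#' Degenerate zero-variance inputs are resolved by the sign of the mean.
#'
#' @param scalars Per-trial mean responses (>= 3 values).
#' @param alpha Significance threshold.
#' @param roi_id,kind Labels carried into the result.
#' @return A one-row tibble: `roi_id`, `kind`, `n_trials`, `mean_response`,
#'   `t`, `p`, `responsive`.
#' @export
test_responsive <- function(scalars, alpha = 0.05, roi_id = NULL,
                            kind = NULL) {
  if (length(scalars) < 3)
    abort("responsiveness test requires at least 3 trials",
          class = "hemoccl_config_error")
  m <- mean(scalars)
  if (sd(scalars) == 0) {
    p <- if (m == 0) 1 else .Machine$double.xmin
    tstat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    ht <- t.test(scalars, mu = 0)
    p <- ht$p.value
    tstat <- unname(ht$statistic)
  }
  tibble(roi_id = roi_id %||% NA_character_, kind = kind %||% NA_character_,
         n_trials = length(scalars), mean_response = m, t = tstat, p = p,
         responsive = p < alpha)
}

#' Per-ROI responsiveness over an event set
#'
#' Runs the event-triggered pipeline (window slicing, baseline subtraction,
#' response-window means, t-test) for every ROI and requested event kind.
#'
#' @param dff Long dF/F0 tibble (`roi_id`, `frame`, `dff`) from
#'   [compute_dff_traces()].
#' @param events An [detect_events()] event set (or tibble `kind`, `frame`).
#' @param frame_rate Frame rate, Hz.
#' @param kinds Event kinds to analyze (default: all present).
#' @param profile Window profile.
#' @param alpha Significance threshold.
#' @return Tibble with one row per (ROI, kind): test results plus `included`
#'   (`FALSE` rows had fewer than 3 complete trials and carry `NA` stats).
#' @export
responsiveness_table <- function(dff, events, frame_rate,
                                 kinds = NULL, profile = "responsiveness",
                                 alpha = 0.05) {
  kinds <- kinds %||% unique(events$kind)
  rois <- split(dff, dff$roi_id)
  out <- list()
  for (kind in kinds) {
    ev <- events$frame[events$kind == kind]
    rw <- profile_window(profile, "response", kind)
    bw <- profile_window(profile, "baseline", kind)
    for (d in rois) {
      tm <- event_triggered_matrix(d$dff, ev, frame_rate,
                                   pre_s = -bw[1], post_s = rw[2],
                                   kind = kind, roi_id = d$roi_id[1])
      if (!tm$included) {
        out[[length(out) + 1]] <- tibble(
          roi_id = d$roi_id[1], kind = kind, n_trials = nrow(tm$mat),
          mean_response = NA_real_, t = NA_real_, p = NA_real_,
          responsive = NA, included = FALSE)
        next
      }
      tm <- baseline_subtract(tm, bw)
      sc <- trial_mean_response(tm, rw)
      out[[length(out) + 1]] <- test_responsive(sc, alpha,
                                                roi_id = d$roi_id[1],
                                                kind = kind) |>
        mutate(included = TRUE)
    }
  }
  dplyr::bind_rows(out)
}

#' Responsive fraction per imaging site, compared to chance
#'
#' The per-site fraction of tested ROIs declared responsive, and a one-sample
#' t-test of the site fractions against the nominal chance level (the 5%
#' dashed line).
#'
#' @param results Tibble from [responsiveness_table()] with a `site_id`
#'   column; rows with `included = FALSE` are ignored, sites with zero tested
#'   ROIs are omitted with a message.
#' @param chance Nominal chance level.
#' @return A `responsive_fraction` list: `fractions` tibble (`site_id`,
#'   `kind`, `n_tested`, `n_responsive`, `fraction`), `chance`, and the
#'   across-site test (`t`, `p`) per kind.
#' @export
responsive_fraction <- function(results, chance = 0.05) {
  if (!"site_id" %in% names(results))
    abort("`results` must carry a site_id column", class = "hemoccl_config_error")
  tested <- results
  if ("included" %in% names(tested))
    tested <- dplyr::filter(tested, .data$included)
  tested <- dplyr::filter(tested, !is.na(.data$responsive))
  if (nrow(tested) == 0) abort("no tested ROIs", class = "hemoccl_config_error")
  fr <- tested |>
    group_by(.data$site_id, .data$kind) |>
    summarise(n_tested = dplyr::n(),
              n_responsive = sum(.data$responsive),
              fraction = mean(.data$responsive), .groups = "drop")
  dropped <- results |>
    dplyr::anti_join(fr, by = c("site_id", "kind")) |>
    dplyr::distinct(.data$site_id, .data$kind)
  if (nrow(dropped) > 0)
    inform(sprintf("%d site/kind group(s) omitted (no tested ROIs)", nrow(dropped)))
  tests <- fr |>
    group_by(.data$kind) |>
    summarise(n_sites = dplyr::n(),
              mean_fraction = mean(.data$fraction),
              t = if (dplyr::n() > 1 && sd(.data$fraction) > 0)
                    unname(t.test(.data$fraction, mu = chance)$statistic)
                  else NA_real_,
              p = if (dplyr::n() > 1 && sd(.data$fraction) > 0)
                    t.test(.data$fraction, mu = chance)$p.value
                  else NA_real_,
              .groups = "drop")
  structure(list(fractions = fr, chance = chance, tests = tests),
            class = "responsive_fraction")
}

#' @export
print.responsive_fraction <- function(x, ...) {
  cat(sprintf("<responsive_fraction> chance level %.3g\n", x$chance))
  print(x$tests)
  invisible(x)
}

# Population event-triggered average: mean over ROIs and trials of
# baseline-subtracted windows. `traces` is a ROIs x frames matrix.
population_eta <- function(traces, triggers, offsets, baseline_idx) {
  acc <- numeric(length(offsets))
  used <- 0L
  n <- ncol(traces)
  for (f in triggers) {
    cols <- f + offsets
    if (cols[1] < 1L || cols[length(cols)] > n) next
    sub <- traces[, cols, drop = FALSE]
    sub <- sub - rowMeans(sub[, baseline_idx, drop = FALSE])
    acc <- acc + colSums(sub)
    used <- used + 1L
  }
  if (used == 0L) abort("no usable triggers", class = "hemoccl_trigger_error")
  acc / (used * nrow(traces))
}

dff_to_matrix <- function(dff) {
  wide <- tidyr::pivot_wider(dff[, c("roi_id", "frame", "dff")],
                             names_from = "frame", values_from = "dff")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$roi_id
  m
}

#' Random-trigger chance band for event-triggered averages
#'
#' Repeatedly draws random trigger sets from locomotion-eligible frames,
#' computes the population event-triggered average for each draw, and
#' returns the per-bin 2.5th-97.5th percentile band -- the 95% interval of
#' response amplitudes expected by chance during locomotion.
#'
#' @param dff Long dF/F0 tibble (`roi_id`, `frame`, `dff`).
#' @param speed Running speed, cm/s, aligned to the frames.
#' @param frame_rate Frame rate, Hz.
#' @param n_triggers Triggers per draw (typically the session's valid
#'   mismatch count).
#' @param n_rep Number of random draws (>= 40 for a usable 95% band).
#' @param pre_s,post_s Window extent, seconds.
#' @param baseline_window Baseline window, seconds.
#' @param threshold,validity_window,mismatch_onsets,exclude_s Trigger
#'   eligibility parameters (see [sample_random_triggers()]).
#' @param seed Integer seed.
#' @return Tibble `time_s`, `lo`, `hi` (per-bin 95% chance band).
#' @export
chance_interval_from_random_triggers <- function(dff, speed, frame_rate,
                                                 n_triggers, n_rep = 100,
                                                 pre_s = 1, post_s = 1.5,
                                                 baseline_window = c(-0.5, 0),
                                                 threshold = 0.25,
                                                 validity_window = c(-0.5, 1),
                                                 mismatch_onsets = integer(0),
                                                 exclude_s = 1,
                                                 seed = NULL) {
  if (n_rep < 40)
    abort("n_rep must be >= 40 for a 95% band", class = "hemoccl_config_error")
  traces <- dff_to_matrix(dff)
  offsets <- window_to_offsets(-pre_s, post_s, frame_rate)
  b_idx <- offsets %in% window_to_offsets(baseline_window[1],
                                          baseline_window[2], frame_rate)
  etas <- matrix(NA_real_, n_rep, length(offsets))
  for (r in seq_len(n_rep)) {
    trig <- sample_random_triggers(speed, frame_rate, n_triggers, threshold,
                                   validity_window, mismatch_onsets,
                                   exclude_s,
                                   seed = if (is.null(seed)) NULL
                                          else derive_seed(seed, r))
    etas[r, ] <- population_eta(traces, trig, offsets, b_idx)
  }
  tibble(time_s = offsets / frame_rate,
         lo = apply(etas, 2, quantile, 0.025, names = FALSE),
         hi = apply(etas, 2, quantile, 0.975, names = FALSE))
}
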