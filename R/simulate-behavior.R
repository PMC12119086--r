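# Behavior generator: locomotion bouts, visual contexts, stimulus schedules.

# Two-state (stationary/locomoting) semi-Markov speed trace with exponential
# dwell times and a boxcar ramp; returns cm/s per frame.
simulate_speed_trace <- function(n, rate, mean_stationary_s, mean_locomotion_s,
                                 run_speed_cmps, speed_ramp_s) {
  speed <- numeric(n)
  if (mean_locomotion_s > 0 && run_speed_cmps > 0) {
    f <- 1L
    state <- "stationary"
    while (f <= n) {
      dwell_s <- if (state == "stationary") rexp(1, 1 / mean_stationary_s)
                 else rexp(1, 1 / mean_locomotion_s)
      dwell <- max(1L, round(dwell_s * rate))
      hi <- min(n, f + dwell - 1L)
      if (state == "locomoting") {
        # slow multiplicative wobble around the bout mean speed
        wob <- stats::filter(rnorm(hi - f + 1L, 0, 1), rep(1 / 5, 5),
                             sides = 2, circular = TRUE)
        speed[f:hi] <- run_speed_cmps * pmax(0.2, 1 + 0.1 * as.numeric(wob))
      }
      f <- hi + 1L
      state <- if (state == "stationary") "locomoting" else "stationary"
    }
  }
  ramp <- max(1L, round(speed_ramp_s * rate))
  if (ramp > 1L) {
    speed <- as.numeric(stats::filter(speed, rep(1 / ramp, ramp), sides = 2))
    speed[is.na(speed)] <- 0
  }
  pmax(speed, 0)
}

# Regularly spaced onsets with uniform jitter, kept inside the session.
schedule_onsets <- function(n, rate, interval_s, duration_s, start_s, kind) {
  if (is.null(interval_s) || interval_s <= 0) return(integer(0))
  dur_f <- max(1L, round(duration_s * rate))
  if (n < dur_f + round(start_s * rate)) {
    abort(sprintf("session too short to place any %s event", kind),
          class = "hemoccl_schedule_error")
  }
  times <- seq(start_s, (n / rate) - duration_s, by = interval_s)
  times <- times + runif(length(times), -0.1 * interval_s, 0.1 * interval_s)
  onsets <- pmax(1L, pmin(n - dur_f, as.integer(floor(times * rate)) + 1L))
  sort(unique(onsets))
}

#' Simulate a behavior log
#'
#' Generates per-frame running speed (two-state semi-Markov bouts), visual
#' flow speed according to the visuomotor context, and stimulus flags.
#' Mismatch events (1 s visual-flow halts) are placed only at frames where the
#' smoothed running speed stays at or above the locomotion threshold over the
#' whole -0.5 s to +1 s validity window, so every generated mismatch is valid
#' by construction. In the open-loop context visual flow is an independently
#' generated bout trace; in the dark it is zero.
#'
#' @param config A [scene_config()].
#' @return A `behavior_log` tibble with columns `time_s`,
#'   `running_speed_cmps`, `visual_flow_cmps`, `grating_on`, `mismatch_on`,
#'   `opto_on`, and a `frame_rate` attribute.
#' @export
simulate_behavior <- function(config) {
  rate <- config$frame_rate
  n <- as.integer(round(config$duration_s * rate))
  with_seed(derive_seed(config$seed, "behavior"), {
    speed <- simulate_speed_trace(n, rate, config$mean_stationary_s,
                                  config$mean_locomotion_s,
                                  config$run_speed_cmps, config$speed_ramp_s)

    grating_on <- mismatch_on <- opto_on <- logical(n)
    if (config$context != "dark" && config$grating_interval_s > 0) {
      g_on <- schedule_onsets(n, rate, config$grating_interval_s,
                              config$grating_duration_s, 8, "grating")
      dur <- max(1L, round(config$grating_duration_s * rate))
      for (f in g_on) grating_on[f:min(n, f + dur - 1L)] <- TRUE
    }
    if (config$opto_interval_s > 0) {
      o_on <- schedule_onsets(n, rate, config$opto_interval_s,
                              config$opto_duration_s, 13, "opto")
      dur <- max(1L, round(config$opto_duration_s * rate))
      for (f in o_on) opto_on[f:min(n, f + dur - 1L)] <- TRUE
    }

    if (config$context == "closed_loop" && config$n_mismatch > 0) {
      thr <- config$speed_threshold
      pre_f <- round(0.5 * rate)
      post_f <- round(1.0 * rate)
      ok <- vapply(seq_len(n), function(f) {
        lo <- f - pre_f; hi <- f + post_f
        lo >= 1L && hi <= n && all(speed[lo:hi] >= thr)
      }, logical(1))
      eligible <- which(ok)
      if (length(eligible) == 0L) {
        warn("no frames satisfy the mismatch validity rule; 0 mismatch events placed")
      } else {
        sep_f <- round(5 * rate)
        placed <- integer(0)
        for (f in sample(eligible)) {
          if (length(placed) >= config$n_mismatch) break
          if (all(abs(f - placed) >= sep_f)) placed <- c(placed, f)
        }
        dur <- max(1L, round(config$mismatch_duration_s * rate))
        for (f in sort(placed)) mismatch_on[f:min(n, f + dur - 1L)] <- TRUE
      }
    }

    flow <- switch(config$context,
      closed_loop = speed,
      open_loop = simulate_speed_trace(n, rate, config$mean_stationary_s,
                                       config$mean_locomotion_s,
                                       config$run_speed_cmps,
                                       config$speed_ramp_s),
      dark = numeric(n))
    flow[mismatch_on] <- 0

    log <- tibble(
      time_s = frame_time(seq_len(n), rate),
      running_speed_cmps = speed,
      visual_flow_cmps = flow,
      grating_on = grating_on,
      mismatch_on = mismatch_on,
      opto_on = opto_on
    )
    attr(log, "frame_rate") <- rate
    class(log) <- c("behavior_log", class(log))
    log
  })
}

behavior_frame_rate <- function(log, frame_rate = NULL) {
  rate <- frame_rate %||% attr(log, "frame_rate")
  if (is.null(rate)) abort("frame rate not given and not stored on the log",
                           class = "hemoccl_config_error")
  rate
}
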