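# Shared fixture builders, generated in code and cached per test run.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.scene_cache[[key]])) assign(key, force(expr), .scene_cache)
  .scene_cache[[key]]
}

# Quiet scene config: no stimuli, no locomotion, no noise -- a blank stage
# for prescribed vessel dynamics.
quiet_config <- function(...) {
  args <- list(grating_interval_s = 0, opto_interval_s = 0, n_mismatch = 0,
               mean_locomotion_s = 0, photon_scale = 0, vessel_noise_sd = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(scene_config, args)
}

# Noise-free scene with a prescribed sinusoidal dilation (+/-15% area).
sin_dilation_scene <- function() cached("sin_dilation", {
  cfg <- quiet_config(duration_s = 40, seed = 11)
  log <- simulate_behavior(cfg)
  n <- nrow(log)
  area <- cfg$baseline_area_um2 * (1 + 0.15 * sin(2 * pi * seq_len(n) / 200))
  scene <- render_frames(log, area, cfg)
  list(cfg = cfg, log = log, area = area, scene = scene,
       rois = scene_rois(scene$truth))
})

# Full noisy default session used by several integration tests.
default_session <- function() cached("default_session", {
  cfg <- scene_config(duration_s = 120, seed = 5)
  log <- simulate_behavior(cfg)
  vessel <- simulate_vessel_dynamics(log, cfg)
  scene <- render_frames(log, vessel, cfg)
  rois <- scene_rois(scene$truth)
  traces <- extract_traces(scene$stack, rois)
  dff <- compute_dff_traces(dplyr::filter(traces, kind == "soma"),
                            cfg$frame_rate)
  events <- detect_events(log)
  list(cfg = cfg, log = log, vessel = vessel, scene = scene, rois = rois,
       traces = traces, dff = dff, events = events)
})

# Bout-structured speed trace: near-zero rest, fast bouts.
bout_speed <- function(n, rate = 15, p_switch = 0.02, speed = 10) {
  state <- FALSE
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (runif(1) < p_switch) state <- !state
    out[i] <- if (state) speed * runif(1, 0.8, 1.2) else abs(rnorm(1, 0, 0.02))
  }
  out
}

# Brute-force transcription of the onset rule, used as the oracle.
oracle_onsets <- function(speed, rate, thr, above_s = 1, below_s = 1) {
  af <- as.integer(round(above_s * rate))
  bf <- as.integer(round(below_s * rate))
  n <- length(speed)
  keep <- integer(0)
  for (f in seq_len(n)) {
    if (f - bf < 1 || f + af - 1 > n) next
    if (all(speed[f:(f + af - 1)] >= thr) &&
        all(speed[(f - bf):(f - 1)] < thr))
      keep <- c(keep, f)
  }
  keep
}

# Long white-noise dF/F0 table for null-calibration tests.
null_dff_site <- function(n_rois, n_frames, sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_rois), function(r)
      tibble::tibble(roi_id = sprintf("roi_%03d", r),
                     frame = seq_len(n_frames),
                     dff = rnorm(n_frames, 0, sd))))
  })
}
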