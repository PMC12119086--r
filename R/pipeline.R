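# End-to-end orchestration: simulate -> preprocess -> events -> responses ->
# bootstrap -> vessels -> correlations, with a machine-readable summary.

#' Trial-averaged video around event onsets
#'
#' Averages the stack over windows `[-pre_s, +post_s)` around each onset
#' (events with incomplete windows dropped), giving one frame per relative
#' time bin.
#'
#' @param stack Numeric array (height x width x frames).
#' @param onsets Event onset frames.
#' @param frame_rate Frame rate, Hz.
#' @param pre_s,post_s Window extent, seconds.
#' @return List: `stack` (height x width x bins array), `time_s` (relative
#'   bin times), `n_trials`.
#' @export
trial_average_stack <- function(stack, onsets, frame_rate, pre_s = 2,
                                post_s = 6) {
  offsets <- window_to_offsets(-pre_s, post_s, frame_rate)
  n <- dim(stack)[3]
  ok <- onsets + min(offsets) >= 1L & onsets + max(offsets) <= n
  onsets <- onsets[ok]
  if (length(onsets) == 0)
    abort("no onsets with complete windows", class = "hemoccl_trigger_error")
  acc <- array(0, dim = c(dim(stack)[1:2], length(offsets)))
  for (f in onsets) acc <- acc + stack[, , f + offsets]
  list(stack = acc / length(onsets), time_s = offsets / frame_rate,
       n_trials = length(onsets))
}

crop_stack <- function(stack, roi) {
  stack[(roi$y0 + 1):roi$y1, (roi$x0 + 1):roi$x1, , drop = FALSE]
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "hemoccl_pipeline_error"))
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Simulates a session from `config`, renders the frame stack, registers it
#' (when jitter is on), extracts dF/F0 traces, detects events, runs the
#' responsiveness tests, computes the hierarchical-bootstrap locomotion-onset
#' band, the vessel cross-section / lumen-proxy analyses with variance
#' explained, and the state-dependent pairwise correlations; optionally
#' writes all outputs plus a JSON summary to `out_dir`.
#'
#' @param config A [scene_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Overrides `config$seed` when given.
#' @param n_boot Bootstrap replicates for the response-curve band.
#' @param site_id Site label attached to all ROIs.
#' @return A `hemoccl_report` list with all intermediate tables and the
#'   `summary` list written to JSON.
#' @export
run_pipeline <- function(config = scene_config(), out_dir = NULL,
                         seed = NULL, n_boot = 1000, site_id = "site_01") {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  rate <- config$frame_rate

  log <- run_stage("simulate", simulate_behavior(config))
  vessel <- run_stage("vessel_dynamics", simulate_vessel_dynamics(log, config))
  scene <- run_stage("render", render_frames(log, vessel, config))

  stack <- scene$stack
  shifts <- NULL
  if (config$jitter_px > 0) {
    reg <- run_stage("register",
                     register_frames(stack, radius = config$jitter_px + 2))
    stack <- reg$stack
    shifts <- reg$shifts
  }

  rois <- run_stage("rois", scene_rois(scene$truth, site_id = site_id))
  traces <- run_stage("extract", extract_traces(stack, rois))
  soma_dff <- run_stage("dff", {
    d <- compute_dff_traces(dplyr::filter(traces, .data$kind == "soma"), rate)
    d$site_id <- site_id
    d
  })
  events <- run_stage("events", detect_events(log))

  resp <- run_stage("respond", {
    kinds <- events |>
      dplyr::count(.data$kind) |>
      dplyr::filter(.data$n >= 3) |>
      dplyr::pull(.data$kind)
    r <- responsiveness_table(soma_dff, events, rate, kinds = kinds)
    r$site_id <- site_id
    r
  })

  loco <- events$frame[events$kind == "locomotion_onset"]
  hb_band <- run_stage("hb_stats", {
    if (length(loco) >= 3) {
      nested <- soma_dff |>
        dplyr::group_by(.data$roi_id) |>
        dplyr::group_split() |>
        purrr::map(function(d) {
          tm <- event_triggered_matrix(d$dff, loco, rate, pre_s = 1,
                                       post_s = 1.5,
                                       kind = "locomotion_onset")
          if (!tm$included) return(NULL)
          tm <- baseline_subtract(tm)
          tibble(site_id = site_id, roi_id = d$roi_id[1],
                 bin_index = seq_along(tm$time_s),
                 time_s = tm$time_s, value = colMeans(tm$mat))
        }) |>
        dplyr::bind_rows()
      if (nrow(nested) > 0) {
        bt <- hierarchical_bootstrap_mean(nested, n_boot,
                                          seed = derive_seed(config$seed, "hb"))
        band <- bootstrap_se_band(bt)
        band$time_s <- sort(unique(nested$time_s))
        band
      } else NULL
    } else NULL
  })

  vessel_res <- run_stage("vessels", {
    box <- dplyr::filter(rois, .data$kind == "vessel_box")
    lum <- dplyr::filter(rois, .data$kind == "vessel_lumen")
    ev_kind <- if (sum(events$kind == "opto") >= 3) "opto" else "locomotion_onset"
    onsets <- events$frame[events$kind == ev_kind]
    avg <- trial_average_stack(crop_stack(stack, box), onsets, rate,
                               pre_s = 2, post_s = 6)
    area <- vessel_area_trace(avg$stack, pixel_size_um = config$pixel_size_um)
    lumen <- vessel_lumen_trace(stack, lum, rate)
    mean_dff <- soma_dff |>
      group_by(.data$frame) |>
      summarise(dff = mean(.data$dff), .groups = "drop")
    sm <- function(x) moving_average(x, rate, 0.5)
    # event-window R^2: trial-averaged neuronal response vs trial-averaged
    # lumen proxy (both smoothed), -2 to +6 s around the event
    eta <- function(x) {
      tm <- event_triggered_matrix(x, onsets, rate, pre_s = 2, post_s = 6,
                                   kind = ev_kind)
      colMeans(tm$mat)
    }
    r2_event <- variance_explained(sm(eta(lumen$values)),
                                   sm(eta(mean_dff$dff)))
    # whole-recording R^2: lumen proxy vs mean neuronal dF/F0
    r2_recording <- variance_explained(sm(lumen$values), sm(mean_dff$dff))
    list(event_kind = ev_kind, area = area, lumen_f0 = lumen$f0,
         lumen_dff = lumen$values,
         r2 = tibble(vessel_id = "vessel_01",
                     mode = c("event_lumen", "recording_lumen"),
                     event_kind = c(ev_kind, NA),
                     r2 = c(r2_event, r2_recording)))
  })

  correlations <- run_stage("correlate", {
    state <- locomotion_state_mask(log$running_speed_cmps,
                                   config$speed_threshold)
    tryCatch(pairwise_state_correlations(soma_dff, state),
             error = function(e) {
               inform(paste("state correlations unavailable:",
                            conditionMessage(e)))
               NULL
             })
  })

  fractions <- tryCatch(responsive_fraction(resp), error = function(e) NULL)
  summary <- list(
    seed = config$seed, frame_rate = rate, duration_s = config$duration_s,
    n_frames = nrow(log), n_rois = length(unique(soma_dff$roi_id)),
    n_events = as.list(table(events$kind)),
    responsive_fraction = if (!is.null(fractions))
      as.list(setNames(fractions$fractions$fraction,
                       fractions$fractions$kind)) else NULL,
    r2 = as.list(setNames(vessel_res$r2$r2, vessel_res$r2$mode)),
    mean_corr_stationary = if (!is.null(correlations))
      mean(correlations$corr_stationary, na.rm = TRUE) else NULL,
    mean_corr_locomoting = if (!is.null(correlations))
      mean(correlations$corr_locomoting, na.rm = TRUE) else NULL
  )

  report <- structure(list(
    config = config, log = log, vessel = vessel, truth = scene$truth,
    rois = rois, dff = soma_dff, events = events, responsiveness = resp,
    fractions = fractions, hb_band = hb_band, vessels = vessel_res,
    correlations = correlations, shifts = shifts, summary = summary
  ), class = "hemoccl_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_behavior_log(log, file.path(out_dir, "behavior.csv"))
    write_events(events, file.path(out_dir, "events.csv"))
    write_traces(soma_dff, file.path(out_dir, "traces.csv"))
    readr::write_csv(resp, file.path(out_dir, "responsiveness.csv"))
    readr::write_csv(vessel_res$r2, file.path(out_dir, "r2.csv"))
    if (!is.null(correlations))
      readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    if (!is.null(hb_band))
      readr::write_csv(hb_band, file.path(out_dir, "locomotion_band.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.hemoccl_report <- function(x, ...) {
  cat("<hemoccl_report>\n")
  cat(sprintf("  %d frames at %g Hz, %d soma ROIs\n", x$summary$n_frames,
              x$summary$frame_rate, x$summary$n_rois))
  cat("  events:", paste(names(x$summary$n_events),
                         unlist(x$summary$n_events), collapse = ", "), "\n")
  if (!is.null(x$fractions)) print(x$fractions)
  invisible(x)
}

#' Generate the small on-disk test fixture bundle
#'
#' A 64 x 64 px, 2 min synthetic closed-loop session with 8 somata, one
#' vessel, and all event types (at least 3 valid mismatches, guaranteed by
#' deterministic re-seeding of the behavior schedule if a draw falls short).
#' Writes the rendered stack (16-bit TIFF), behavior, ground truth, ROI
#' table, and config under `dir`.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param photon_scale Shot-noise photon scale (0 = noise-free fixture).
#' @return List of file paths plus the in-memory `scene`, `log`, `config`.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("hemoccl_fix"),
                          photon_scale = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- NULL; log <- NULL
  for (try in 0:19) {
    cfg <- scene_config(duration_s = 120, seed = derive_seed(seed, try),
                        photon_scale = photon_scale,
                        grating_interval_s = 20, opto_interval_s = 25,
                        mean_stationary_s = 10, mean_locomotion_s = 15,
                        n_mismatch = 6)
    log <- simulate_behavior(cfg)
    n_mm <- length(validate_mismatch_events(log$mismatch_on,
                                            log$running_speed_cmps,
                                            cfg$frame_rate))
    if (n_mm >= 3) break
    log <- NULL
  }
  if (is.null(log))
    abort("could not generate a fixture with >= 3 valid mismatch events",
          class = "hemoccl_schedule_error")
  vessel <- simulate_vessel_dynamics(log, cfg)
  scene <- render_frames(log, vessel, cfg)
  rois <- scene_rois(scene$truth)
  paths <- list(
    stack = file.path(dir, "stack.tif"),
    behavior = file.path(dir, "behavior.csv"),
    truth = file.path(dir, "truth.csv"),
    rois = file.path(dir, "rois.csv"),
    config_yaml = file.path(dir, "config.yaml")
  )
  write_stack(scene$stack, paths$stack)
  write_behavior_log(log, paths$behavior)
  write_ground_truth(scene$truth, paths$truth)
  write_rois(rois, paths$rois)
  write_scene_config(cfg, paths$config_yaml)
  c(paths, list(scene = scene, log = log, config = cfg, rois = rois,
                vessel = vessel, dir = dir))
}
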