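# Scene configuration for the forward occlusion simulator.

#' Vessel coupling kernel
#'
#' A signed double-exponential kernel describing how a vessel's cross-section
#' responds to one event type. The kernel is
#' `a * (1 - exp(-t/rise)) * exp(-t/decay)`, rescaled so its peak equals the
#' signed amplitude `a` (fractional change in cross-section; dilation
#' positive, constriction negative).
#'
#' @param amplitude Peak fractional change in cross-section (e.g. `-0.08` for
#'   an 8% constriction).
#' @param rise_s,decay_s Rise and decay time constants in seconds.
#' @return A `coupling_kernel` list.
#' @export
coupling_kernel <- function(amplitude, rise_s = 0.5, decay_s = 2) {
  stopifnot_scalar_pos(rise_s, "rise_s")
  stopifnot_scalar_pos(decay_s, "decay_s")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude))
    abort("`amplitude` must be a finite scalar", class = "hemoccl_config_error")
  structure(list(amplitude = amplitude, rise_s = rise_s, decay_s = decay_s),
            class = "coupling_kernel")
}

# Discretize a coupling kernel at a given frame rate; peak-normalized so the
# maximum absolute value equals |amplitude|.
kernel_discretize <- function(kernel, rate, support_s = 20) {
  t <- seq(0, support_s, by = 1 / rate)
  shape <- (1 - exp(-t / kernel$rise_s)) * exp(-t / kernel$decay_s)
  peak <- max(shape)
  if (peak <= 0) return(numeric(length(t)))
  kernel$amplitude * shape / peak
}

#' Build a simulated-scene configuration
#'
#' Collects every knob of the forward model: imaging geometry, behavior
#' schedule, vessel coupling kernels, the occlusion gain, and noise. Defaults
#' emulate the study conditions: 15 Hz effective frame rate, locomotion bouts
#' on a spherical treadmill, 2 s drifting gratings, 1 s visuomotor mismatches
#' restricted to sustained locomotion, 1 s optogenetic light pulses, a
#' locomotion-coupled vessel constriction and light-coupled dilations sized so
#' the noise-free population locomotion-onset response is about 1% dF/F0.
#'
#' @param frame_rate Imaging frame rate, Hz.
#' @param duration_s Session duration, seconds.
#' @param context Visuomotor context: `"closed_loop"` (visual flow equals
#'   running speed), `"open_loop"` (flow replayed independently of running),
#'   or `"dark"` (flow zero).
#' @param field_of_view_um Field of view `c(width, height)` in micrometers.
#' @param pixel_size_um Pixel size, micrometers per pixel.
#' @param n_somata Number of soma disks rendered.
#' @param soma_radius_um Soma radius, micrometers.
#' @param soma_level,neuropil_level,lumen_level Rendered intensity (arbitrary
#'   units) of soma disks, background neuropil, and the vessel lumen.
#' @param vessel_center_um Vessel ellipse center `c(x, y)` in micrometers.
#' @param vessel_axes_um Vessel ellipse semi-axes `c(a, b)` in micrometers at
#'   baseline; the baseline cross-section is `A0 = pi * a * b`.
#' @param vessel_orientation_deg In-plane orientation of the vessel ellipse.
#' @param psf_sigma_px Gaussian point-spread proxy width, pixels; `0`
#'   disables blurring.
#' @param coupling_kernels Named list of [coupling_kernel()]s, one per event
#'   kind (`locomotion_onset`, `grating_onset`, `mismatch`, `opto`).
#' @param occlusion_gain Dimensionless gain `k` linking relative cross-section
#'   change to fluorescence attenuation (`>= 0`).
#' @param vessel_noise_sd SD of the smoothed fractional cross-section noise
#'   (default 0.02, emulating spontaneous vasomotion).
#' @param min_area_frac Floor on `A(t)` as a fraction of `A0`.
#' @param photon_scale Photon counts per intensity unit for Poisson shot
#'   noise (default 100); `0` disables noise.
#' @param jitter_px Maximum absolute rigid frame jitter, integer pixels; `0`
#'   disables jitter.
#' @param speed_threshold Locomotion threshold, cm/s (used when placing
#'   mismatch events).
#' @param mean_stationary_s,mean_locomotion_s Mean exponential dwell times of
#'   the stationary/locomoting states, seconds.
#' @param run_speed_cmps Mean running speed during bouts, cm/s.
#' @param speed_ramp_s Boxcar smoothing width applied to the speed trace so
#'   bouts ramp on and off, seconds.
#' @param grating_duration_s,grating_interval_s Grating stimulus duration and
#'   mean inter-onset interval, seconds.
#' @param mismatch_duration_s Visuomotor mismatch duration, seconds.
#' @param n_mismatch Maximum number of mismatch events to place.
#' @param opto_duration_s,opto_interval_s Optogenetic light pulse duration and
#'   mean inter-onset interval, seconds.
#' @param seed Integer seed fixing all randomness of the scene.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(frame_rate = 15,
                         duration_s = 300,
                         context = c("closed_loop", "open_loop", "dark"),
                         field_of_view_um = c(64, 64),
                         pixel_size_um = 1,
                         n_somata = 8,
                         soma_radius_um = 4,
                         soma_level = 100,
                         neuropil_level = 10,
                         lumen_level = 0.5,
                         vessel_center_um = c(32, 14),
                         vessel_axes_um = c(10, 5),
                         vessel_orientation_deg = 0,
                         psf_sigma_px = 1.5,
                         coupling_kernels = list(
                           locomotion_onset = coupling_kernel(-0.08, 0.5, 2),
                           grating_onset    = coupling_kernel(+0.05, 0.5, 2),
                           mismatch         = coupling_kernel(-0.03, 0.5, 1),
                           opto             = coupling_kernel(+0.10, 0.5, 2)
                         ),
                         occlusion_gain = 0.12,
                         vessel_noise_sd = 0.02,
                         min_area_frac = 0.1,
                         photon_scale = 100,
                         jitter_px = 0,
                         speed_threshold = 0.25,
                         mean_stationary_s = 20,
                         mean_locomotion_s = 15,
                         run_speed_cmps = 10,
                         speed_ramp_s = 0.5,
                         grating_duration_s = 2,
                         grating_interval_s = 15,
                         mismatch_duration_s = 1,
                         n_mismatch = 10,
                         opto_duration_s = 1,
                         opto_interval_s = 20,
                         seed = 1L) {
  context <- match.arg(context)
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(soma_radius_um, "soma_radius_um")
  if (length(field_of_view_um) != 2L || any(field_of_view_um <= 0))
    abort("`field_of_view_um` must be two positive numbers",
          class = "hemoccl_config_error")
  if (length(vessel_axes_um) != 2L || any(vessel_axes_um <= 0))
    abort("`vessel_axes_um` must be two positive semi-axes",
          class = "hemoccl_config_error")
  if (occlusion_gain < 0)
    abort("`occlusion_gain` must be >= 0", class = "hemoccl_config_error")
  if (photon_scale < 0)
    abort("`photon_scale` must be >= 0", class = "hemoccl_config_error")
  if (!is.list(coupling_kernels) || is.null(names(coupling_kernels)) ||
      !all(vapply(coupling_kernels, inherits, logical(1), "coupling_kernel")))
    abort("`coupling_kernels` must be a named list of coupling_kernel objects",
          class = "hemoccl_config_error")
  cfg <- list(
    frame_rate = frame_rate, duration_s = duration_s, context = context,
    field_of_view_um = as.numeric(field_of_view_um),
    pixel_size_um = pixel_size_um,
    n_somata = as.integer(n_somata), soma_radius_um = soma_radius_um,
    soma_level = soma_level, neuropil_level = neuropil_level,
    lumen_level = lumen_level,
    vessel_center_um = as.numeric(vessel_center_um),
    vessel_axes_um = as.numeric(vessel_axes_um),
    vessel_orientation_deg = vessel_orientation_deg,
    psf_sigma_px = psf_sigma_px,
    baseline_area_um2 = pi * prod(vessel_axes_um),
    coupling_kernels = coupling_kernels,
    occlusion_gain = occlusion_gain,
    vessel_noise_sd = vessel_noise_sd,
    min_area_frac = min_area_frac,
    photon_scale = photon_scale,
    jitter_px = as.integer(jitter_px),
    speed_threshold = speed_threshold,
    mean_stationary_s = mean_stationary_s,
    mean_locomotion_s = mean_locomotion_s,
    run_speed_cmps = run_speed_cmps,
    speed_ramp_s = speed_ramp_s,
    grating_duration_s = grating_duration_s,
    grating_interval_s = grating_interval_s,
    mismatch_duration_s = mismatch_duration_s,
    n_mismatch = as.integer(n_mismatch),
    opto_duration_s = opto_duration_s,
    opto_interval_s = opto_interval_s,
    seed = as.integer(seed)
  )
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  %g Hz, %g s, context %s, FOV %g x %g um @ %g um/px\n",
              x$frame_rate, x$duration_s, x$context,
              x$field_of_view_um[1], x$field_of_view_um[2], x$pixel_size_um))
  cat(sprintf("  %d somata (r = %g um), vessel A0 = %.1f um^2, k = %g, seed %d\n",
              x$n_somata, x$soma_radius_um, x$baseline_area_um2,
              x$occlusion_gain, x$seed))
  invisible(x)
}

#' Read / write a scene configuration as YAML or JSON
#'
#' Round-trips every field losslessly; kernels are stored as plain lists.
#' @param config A `scene_config`.
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `write_scene_config()` returns `path` invisibly;
#'   `read_scene_config()` returns a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  x$coupling_kernels <- lapply(x$coupling_kernels, unclass)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  kernels <- lapply(x$coupling_kernels, function(k)
    coupling_kernel(k$amplitude, k$rise_s, k$decay_s))
  args <- x[setdiff(names(x), c("coupling_kernels", "baseline_area_um2"))]
  args$coupling_kernels <- kernels
  do.call(scene_config, args)
}
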