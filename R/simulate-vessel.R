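# Vessel cross-section dynamics, the occlusion model, and light-cone
# geometry.

flag_rising_edges <- function(flag) which(flag & !dplyr::lag(flag, default = FALSE))

#' Simulate vessel cross-section dynamics
#'
#' The cross-section is `A(t) = A0 * (1 + sum of kernel-convolved event
#' drives + noise)`, floored at `min_area_frac * A0`. Each event kind present
#' in the log drives the vessel through its signed coupling kernel (dilation
#' positive, constriction negative). Locomotion onsets are taken as rising
#' edges of the thresholded speed trace; stimulus onsets as rising edges of
#' their flags.
#'
#' @param log A [simulate_behavior()] log.
#' @param config The [scene_config()] that produced it.
#' @return A tibble with columns `time_s` and `area_um2`.
#' @export
simulate_vessel_dynamics <- function(log, config) {
  rate <- behavior_frame_rate(log, config$frame_rate)
  n <- nrow(log)
  onsets <- list(
    locomotion_onset = flag_rising_edges(log$running_speed_cmps >= config$speed_threshold),
    grating_onset    = flag_rising_edges(log$grating_on),
    mismatch         = flag_rising_edges(log$mismatch_on),
    opto             = flag_rising_edges(log$opto_on)
  )
  present <- names(onsets)[vapply(onsets, length, integer(1)) > 0]
  missing_k <- setdiff(present, names(config$coupling_kernels))
  if (length(missing_k) > 0)
    abort(paste0("no coupling kernel defined for event kind(s): ",
                 paste(missing_k, collapse = ", ")),
          class = "hemoccl_config_error")

  drive <- numeric(n)
  for (kind in present) {
    k <- kernel_discretize(config$coupling_kernels[[kind]], rate)
    for (f in onsets[[kind]]) {
      idx <- f:min(n, f + length(k) - 1L)
      drive[idx] <- drive[idx] + k[seq_along(idx)]
    }
  }

  if (config$vessel_noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, "vessel_noise"), rnorm(n))
    w <- max(1L, round(0.5 * rate))
    noise <- as.numeric(stats::filter(noise, rep(1 / w, w), sides = 2))
    noise[is.na(noise)] <- 0
    if (sd(noise) > 0) noise <- noise * config$vessel_noise_sd / sd(noise)
  } else {
    noise <- 0
  }

  a0 <- config$baseline_area_um2
  area <- a0 * (1 + drive + noise)
  floor_val <- config$min_area_frac * a0
  n_floored <- sum(area < floor_val)
  if (n_floored > 0)
    warn(sprintf("vessel cross-section floored at %.3g um^2 on %d frame(s)",
                 floor_val, n_floored))
  area <- pmax(area, floor_val)
  tibble(time_s = log$time_s, area_um2 = area)
}

#' Occlusion attenuation factor
#'
#' First-order model of hemodynamic occlusion: the measured fluorescence is
#' the true fluorescence multiplied by
#' `clamp(1 - k * (A - A0) / A0, 0.05, 20)`. Dilation (`A > A0`) darkens the
#' measurement; constriction brightens it.
#'
#' @param area Vessel cross-section(s), same units as `baseline_area`.
#' @param baseline_area Baseline cross-section `A0` (> 0).
#' @param gain Dimensionless occlusion gain `k` (>= 0).
#' @return Attenuation factor(s), clamped to `[0.05, 20]`.
#' @export
occlusion_attenuation <- function(area, baseline_area, gain) {
  stopifnot_scalar_pos(baseline_area, "baseline_area")
  if (gain < 0) abort("`gain` must be >= 0", class = "hemoccl_config_error")
  eps <- 0.05
  pmin(pmax(1 - gain * (area - baseline_area) / baseline_area, eps), 1 / eps)
}

#' Surface footprint of the collection light cone
#'
#' A neuron imaged at depth `d` through an objective whose collection cone has
#' half angle `theta` collects light through a surface circle of diameter
#' `2 * d * tan(theta)`; any surface vessel inside that circle can occlude the
#' neuron. An NA-1 objective has a half angle of about 45 degrees, so a
#' neuron at 500 um depth sees a 1 mm footprint.
#'
#' @param depth_um Imaging depth below the surface, micrometers (>= 0).
#' @param half_angle_deg Collection-cone half angle, degrees (in `[0, 90)`).
#' @return Footprint circle diameter in micrometers.
#' @export
occlusion_footprint <- function(depth_um, half_angle_deg = 45) {
  if (any(depth_um < 0)) abort("`depth_um` must be >= 0",
                               class = "hemoccl_domain_error")
  if (any(half_angle_deg < 0) || any(half_angle_deg >= 90))
    abort("`half_angle_deg` must be in [0, 90)", class = "hemoccl_domain_error")
  2 * depth_um * tan(half_angle_deg * pi / 180)
}

#' Effective per-plane frame rate of multi-plane two-photon acquisition
#'
#' A resonant scanner acquiring full frames at `scanner_rate_hz` while a piezo
#' steps the objective through `n_planes` depths revisits each plane at
#' `scanner_rate_hz / n_planes`. The study configuration (60 Hz, 4 planes)
#' gives 15 Hz.
#'
#' @param scanner_rate_hz Full-frame acquisition rate, Hz.
#' @param n_planes Number of interleaved imaging planes.
#' @return Effective per-plane frame rate, Hz.
#' @export
effective_frame_rate <- function(scanner_rate_hz = 60, n_planes = 4) {
  stopifnot_scalar_pos(scanner_rate_hz, "scanner_rate_hz")
  if (n_planes != as.integer(n_planes) || n_planes < 1)
    abort("`n_planes` must be a positive integer", class = "hemoccl_domain_error")
  scanner_rate_hz / n_planes
}
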