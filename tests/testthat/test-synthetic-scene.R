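# Forward simulator: behavior schedules, vessel dynamics, occlusion model,
# light-cone geometry, and the renderer.

test_that("behavior generator honors its contracts", {
  # no locomotion => flat speed and no mismatch events
  cfg0 <- scene_config(duration_s = 90, seed = 2, mean_locomotion_s = 0)
  expect_warning(log0 <- simulate_behavior(cfg0), "mismatch")
  expect_true(all(log0$running_speed_cmps == 0))
  expect_false(any(log0$mismatch_on))

  cfg <- scene_config(duration_s = 180, seed = 4)
  log <- simulate_behavior(cfg)
  expect_equal(nrow(log), 180 * 15)
  expect_true(all(log$running_speed_cmps >= 0))
  expect_true(all(log$visual_flow_cmps >= 0))

  # every mismatch onset is backed by sustained locomotion over -0.5..+1 s
  onsets <- which(log$mismatch_on & !dplyr::lag(log$mismatch_on, default = FALSE))
  expect_gt(length(onsets), 0)
  for (f in onsets) {
    win <- (f - round(0.5 * 15)):(f + round(1 * 15))
    expect_true(all(log$running_speed_cmps[win] >= cfg$speed_threshold))
  }
  # mismatch frames themselves occur during locomotion
  expect_true(all(log$running_speed_cmps[log$mismatch_on] >= cfg$speed_threshold))

  # closed loop couples flow to speed except during mismatch halts
  ok <- !log$mismatch_on
  expect_equal(log$visual_flow_cmps[ok], log$running_speed_cmps[ok])
  expect_true(all(log$visual_flow_cmps[log$mismatch_on] == 0))

  # determinism: same config => byte-identical logs
  expect_identical(log, simulate_behavior(cfg))

  # open loop flow is independent of running; dark has none
  log_ol <- simulate_behavior(scene_config(duration_s = 120, seed = 4,
                                           context = "open_loop"))
  expect_false(isTRUE(all.equal(log_ol$visual_flow_cmps,
                                log_ol$running_speed_cmps)))
  log_dk <- suppressWarnings(
    simulate_behavior(scene_config(duration_s = 120, seed = 4,
                                   context = "dark")))
  expect_true(all(log_dk$visual_flow_cmps == 0))
  expect_false(any(log_dk$grating_on))

  # scheduling error names the event type when the session cannot hold it
  expect_error(simulate_behavior(scene_config(duration_s = 5, seed = 1)),
               "grating")
})

test_that("vessel dynamics follow the signed kernel model", {
  cfg <- quiet_config(duration_s = 60, seed = 3)
  log <- simulate_behavior(cfg)

  # zero kernels, zero noise => constant baseline area
  v0 <- simulate_vessel_dynamics(log, cfg)
  expect_equal(v0$area_um2, rep(cfg$baseline_area_um2, nrow(log)))

  # a single event with amplitude +0.1 peaks at 1.1 * A0
  log1 <- log
  log1$opto_on[300:314] <- TRUE
  cfg1 <- cfg
  cfg1$coupling_kernels <- list(opto = coupling_kernel(0.1, 0.5, 2))
  v1 <- simulate_vessel_dynamics(log1, cfg1)
  expect_equal(max(v1$area_um2), 1.1 * cfg$baseline_area_um2,
               tolerance = 1e-6)
  expect_equal(v1$area_um2[1], cfg$baseline_area_um2)

  # constriction kernel at locomotion onset dips below baseline
  cfg2 <- quiet_config(duration_s = 120, seed = 3,
                       mean_locomotion_s = 15)
  cfg2$coupling_kernels <- list(locomotion_onset = coupling_kernel(-0.1))
  log2 <- simulate_behavior(cfg2)
  v2 <- simulate_vessel_dynamics(log2, cfg2)
  expect_lt(min(v2$area_um2), cfg2$baseline_area_um2)
  expect_equal(min(v2$area_um2), 0.9 * cfg2$baseline_area_um2,
               tolerance = 0.02)

  # kernel missing for a present event type is an error
  cfg3 <- cfg2
  cfg3$coupling_kernels <- list(opto = coupling_kernel(0.1))
  expect_error(simulate_vessel_dynamics(log2, cfg3), "locomotion_onset")
})

test_that("occlusion attenuation follows the clamped linear model", {
  expect_equal(occlusion_attenuation(100, 100, 0.5), 1)
  expect_equal(occlusion_attenuation(110, 100, 0.5), 0.95)
  expect_equal(occlusion_attenuation(123, 100, 0), 1)
  # dilation darkens, constriction brightens
  expect_lt(occlusion_attenuation(120, 100, 1), 1)
  expect_gt(occlusion_attenuation(80, 100, 1), 1)
  # clamped at [0.05, 20]
  expect_equal(occlusion_attenuation(1e6, 100, 1), 0.05)
  expect_equal(occlusion_attenuation(-1e6, 100, 1), 20)
  expect_error(occlusion_attenuation(1, -1, 1), "baseline_area")
})

test_that("light-cone footprint matches independent trigonometry", {
  # the study's worked example: 500 um deep at 45 degrees -> 1 mm circle
  expect_equal(occlusion_footprint(500, 45), 1000, tolerance = 1e-12)
  expect_equal(occlusion_footprint(0, 45), 0)
  expect_equal(occlusion_footprint(250, 45), 500, tolerance = 1e-12)
  withr::with_seed(99, {
    depth <- runif(20, 0, 800)
    ang <- runif(20, 0, 89)
    # independent evaluation via the sine/cosine ratio
    expect_equal(occlusion_footprint(depth, ang),
                 2 * depth * sin(ang * pi / 180) / cos(ang * pi / 180),
                 tolerance = 1e-9)
  })
  expect_error(occlusion_footprint(100, 90), "half_angle")
  expect_error(occlusion_footprint(-1, 45), "depth")
})

test_that("multi-plane timing gives the per-plane rate", {
  expect_equal(effective_frame_rate(60, 4), 15)
  expect_equal(effective_frame_rate(30, 1), 30)
  expect_error(effective_frame_rate(60, 2.5), "n_planes")
})

test_that("renderer produces the constructed scene", {
  sd <- sin_dilation_scene()
  cfg <- sd$cfg
  n <- nrow(sd$log)

  # static scene, no noise, no jitter => identical frames
  const <- render_frames(sd$log, rep(cfg$baseline_area_um2, n), cfg)
  expect_equal(const$stack[, , 1], const$stack[, , n])

  # determinism
  again <- render_frames(sd$log, sd$area, cfg)
  expect_identical(sd$scene$stack, again$stack)

  # mean lumen intensity rises as the vessel constricts (inverse relation)
  lum <- dplyr::filter(sd$rois, kind == "vessel_lumen")
  lt <- extract_roi_trace(sd$scene$stack, lum)
  expect_lt(cor(lt, sd$area), -0.9)

  # vessel exceeding the frame at max dilation is a configuration error
  cfg_bad <- quiet_config(duration_s = 40, seed = 11,
                          vessel_center_um = c(5, 5))
  expect_error(render_frames(sd$log, sd$area, cfg_bad), "frame bounds")
})

test_that("injected rigid shifts translate frames exactly", {
  cfg <- quiet_config(duration_s = 20, seed = 13, jitter_px = 3)
  log <- simulate_behavior(cfg)
  n <- nrow(log)
  area <- rep(cfg$baseline_area_um2, n)
  sc <- render_frames(log, area, cfg)
  sh <- sc$truth$shifts
  expect_true(any(sh$dx != 0 | sh$dy != 0))
  # the scene is static and noise-free, so a shifted frame must equal an
  # unshifted frame translated by the recorded jitter
  t0 <- which(sh$dx == 0 & sh$dy == 0)[1]
  t <- which(sh$dx != 0 | sh$dy != 0)[1]
  expect_equal(sc$stack[, , t],
               hemoccl:::translate_int(sc$stack[, , t0], sh$dx[t], sh$dy[t]))
})

test_that("ground truth suffices to reconstruct noise-free frames", {
  sd <- sin_dilation_scene()
  truth <- sd$scene$truth
  t <- 137
  att <- dplyr::filter(truth$attenuation, frame == t)
  img <- hemoccl:::render_scene_image(truth$geometry, truth$config,
                                      truth$area$area_um2[t],
                                      att$true_attenuation)
  expect_equal(img, sd$scene$stack[, , t])
})

test_that("occlusion sign drives the rendered soma trace", {
  base_cfg <- function(amp) {
    cfg <- quiet_config(duration_s = 40, seed = 17)
    cfg$coupling_kernels <- list(opto = coupling_kernel(amp, 0.5, 2))
    cfg
  }
  run_one <- function(amp) {
    cfg <- base_cfg(amp)
    log <- simulate_behavior(cfg)
    log$opto_on[200:214] <- TRUE
    v <- simulate_vessel_dynamics(log, cfg)
    sc <- render_frames(log, v, cfg)
    soma <- dplyr::filter(scene_rois(sc$truth), kind == "soma")[1, ]
    tr <- extract_roi_trace(sc$stack, soma)
    mean(tr[215:245]) - mean(tr[150:199])
  }
  expect_gt(run_one(-0.1), 0)  # constriction brightens the soma
  expect_lt(run_one(+0.1), 0)  # dilation darkens it
})
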