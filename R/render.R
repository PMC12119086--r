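# Scene renderer: soma disks + dark vessel lumen + neuropil background,
# Gaussian PSF proxy, Poisson shot noise, optional rigid jitter.

# Logical mask of an ellipse on an H x W pixel grid. Center/axes in pixels
# (x rightwards = columns, y downwards = rows), orientation in degrees.
ellipse_mask <- function(h, w, cx, cy, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  xs <- matrix(seq_len(w) - 0.5, h, w, byrow = TRUE) - cx
  ys <- matrix(seq_len(h) - 0.5, h, w) - cy
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(h, w, cx, cy, r) ellipse_mask(h, w, cx, cy, r, r)

# Half-extent of a rotated ellipse's axis-aligned bounding box.
ellipse_bbox_half <- function(a, b, theta_deg) {
  th <- theta_deg * pi / 180
  c(x = sqrt((a * cos(th))^2 + (b * sin(th))^2),
    y = sqrt((a * sin(th))^2 + (b * cos(th))^2))
}

# Deterministic (pre-noise, pre-jitter) scene image for one frame.
render_scene_image <- function(geom, config, area_um2, attenuation) {
  img <- matrix(config$neuropil_level, geom$h, geom$w)
  for (j in seq_len(nrow(geom$somata))) {
    s <- geom$somata[j, ]
    img[geom$soma_masks[[j]]] <- img[geom$soma_masks[[j]]] +
      s$base_level * attenuation[j]
  }
  scale <- sqrt(area_um2 / config$baseline_area_um2)
  vmask <- ellipse_mask(geom$h, geom$w, geom$vx, geom$vy,
                        geom$va * scale, geom$vb * scale,
                        config$vessel_orientation_deg)
  img[vmask] <- config$lumen_level
  if (config$psf_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = config$psf_sigma_px))
  img
}

# Place scene geometry: vessel in pixel coordinates plus non-overlapping soma
# disks clear of the vessel, the frame edge, and the jitter margin.
place_geometry <- function(config, max_area_um2) {
  px <- config$pixel_size_um
  w <- as.integer(round(config$field_of_view_um[1] / px))
  h <- as.integer(round(config$field_of_view_um[2] / px))
  vx <- config$vessel_center_um[1] / px
  vy <- config$vessel_center_um[2] / px
  va <- config$vessel_axes_um[1] / px
  vb <- config$vessel_axes_um[2] / px
  max_scale <- sqrt(max_area_um2 / config$baseline_area_um2)
  half <- ellipse_bbox_half(va * max_scale, vb * max_scale,
                            config$vessel_orientation_deg)
  if (vx - half["x"] < 0 || vx + half["x"] > w ||
      vy - half["y"] < 0 || vy + half["y"] > h)
    abort("vessel ellipse exceeds frame bounds at its maximal cross-section",
          class = "hemoccl_config_error")

  r <- config$soma_radius_um / px
  margin <- r + config$jitter_px + 1
  somata <- tibble(soma_id = sprintf("soma_%02d", seq_len(config$n_somata)),
                   x_px = NA_real_, y_px = NA_real_, radius_px = r,
                   base_level = config$soma_level *
                     runif(config$n_somata, 0.8, 1.2))
  placed <- 0L
  tries <- 0L
  while (placed < config$n_somata && tries < 5000L) {
    tries <- tries + 1L
    cx <- runif(1, margin, w - margin)
    cy <- runif(1, margin, h - margin)
    # keep the whole soma clear of the vessel at maximal dilation
    u <- (cx - vx) * cos(config$vessel_orientation_deg * pi / 180) +
         (cy - vy) * sin(config$vessel_orientation_deg * pi / 180)
    v <- -(cx - vx) * sin(config$vessel_orientation_deg * pi / 180) +
          (cy - vy) * cos(config$vessel_orientation_deg * pi / 180)
    in_vessel <- (u / (va * max_scale + r))^2 + (v / (vb * max_scale + r))^2 <= 1
    overlaps <- placed > 0 && any(
      (somata$x_px[seq_len(placed)] - cx)^2 +
        (somata$y_px[seq_len(placed)] - cy)^2 < (2 * r)^2)
    if (!in_vessel && !overlaps) {
      placed <- placed + 1L
      somata$x_px[placed] <- cx
      somata$y_px[placed] <- cy
    }
  }
  if (placed < config$n_somata)
    abort("could not place all somata; reduce n_somata or soma_radius_um",
          class = "hemoccl_config_error")
  soma_masks <- lapply(seq_len(config$n_somata), function(j)
    disk_mask(h, w, somata$x_px[j], somata$y_px[j], r))
  list(h = h, w = w, vx = vx, vy = vy, va = va, vb = vb,
       somata = somata, soma_masks = soma_masks)
}

#' Render an imaging frame stack from behavior and vessel dynamics
#'
#' Each frame is background neuropil plus soma disks whose brightness is the
#' per-soma ground-truth fluorescence multiplied by the occlusion attenuation
#' for the instantaneous vessel cross-section, with the vessel drawn as a
#' near-zero-intensity ellipse of area `A(t)`. Frames are blurred by a
#' Gaussian point-spread proxy, subjected to Poisson shot noise on the
#' configured photon scale, and optionally translated by integer rigid
#' jitter. Everything injected is recorded losslessly in the returned ground
#' truth.
#'
#' @param log A [simulate_behavior()] log.
#' @param vessel A [simulate_vessel_dynamics()] tibble (or a numeric vector
#'   of cross-sections in square micrometers, one per frame).
#' @param config The [scene_config()].
#' @return A list of class `rendered_scene` with elements `stack` (numeric
#'   array height x width x frames, arbitrary intensity units) and `truth`
#'   (class `ground_truth`: soma geometry and per-frame fluorescence and
#'   attenuation, vessel area, injected shifts, and the config).
#' @export
render_frames <- function(log, vessel, config) {
  area <- if (is.data.frame(vessel)) vessel$area_um2 else as.numeric(vessel)
  n <- nrow(log)
  if (length(area) != n)
    abort("vessel series and behavior log lengths differ",
          class = "hemoccl_config_error")
  with_seed(derive_seed(config$seed, "render"), {
    geom <- place_geometry(config, max(area))
    atten <- occlusion_attenuation(area, config$baseline_area_um2,
                                   config$occlusion_gain)
    shifts <- if (config$jitter_px > 0) {
      tibble(frame = seq_len(n),
             dx = sample(-config$jitter_px:config$jitter_px, n, replace = TRUE),
             dy = sample(-config$jitter_px:config$jitter_px, n, replace = TRUE))
    } else {
      tibble(frame = seq_len(n), dx = 0L, dy = 0L)
    }
    stack <- array(0, dim = c(geom$h, geom$w, n))
    for (t in seq_len(n)) {
      img <- render_scene_image(geom, config, area[t],
                                rep(atten[t], nrow(geom$somata)))
      if (config$photon_scale > 0) {
        img <- matrix(rpois(length(img), pmax(img, 0) * config$photon_scale),
                      geom$h, geom$w) / config$photon_scale
      }
      if (shifts$dx[t] != 0L || shifts$dy[t] != 0L)
        img <- translate_int(img, shifts$dx[t], shifts$dy[t])
      stack[, , t] <- img
    }
    truth <- structure(list(
      config = config,
      geometry = geom,
      somata = geom$somata,
      area = tibble(frame = seq_len(n), time_s = log$time_s, area_um2 = area),
      attenuation = tibble(frame = rep(seq_len(n), each = nrow(geom$somata)),
                           soma_id = rep(geom$somata$soma_id, n),
                           true_attenuation = rep(atten, each = nrow(geom$somata)),
                           true_soma_fluorescence =
                             rep(geom$somata$base_level, n)),
      shifts = shifts
    ), class = "ground_truth")
    structure(list(stack = stack, truth = truth), class = "rendered_scene")
  })
}

#' Default ROI table for a rendered scene
#'
#' Rectangular ROIs in the 0-based, half-open convention: one square ROI
#' inscribed in each soma disk, a lumen ROI strictly inside the vessel at
#' rest, and a vessel box enclosing the vessel at maximal dilation plus a
#' neuropil margin.
#'
#' @param truth A `ground_truth` from [render_frames()].
#' @param site_id,depth_label Metadata attached to every ROI.
#' @return A tibble with columns `roi_id`, `kind`, `x0`, `y0`, `x1`, `y1`,
#'   `site_id`, `depth_label`.
#' @export
scene_rois <- function(truth, site_id = "site_01", depth_label = "L2/3") {
  geom <- truth$geometry
  cfg <- truth$config
  half_soma <- floor(geom$somata$radius_px / sqrt(2))
  soma <- tibble(
    roi_id = geom$somata$soma_id, kind = "soma",
    x0 = pmax(0L, as.integer(round(geom$somata$x_px - half_soma))),
    y0 = pmax(0L, as.integer(round(geom$somata$y_px - half_soma))),
    x1 = pmin(geom$w, as.integer(round(geom$somata$x_px + half_soma))),
    y1 = pmin(geom$h, as.integer(round(geom$somata$y_px + half_soma)))
  )
  # inscribed rectangle of the baseline ellipse at 0.9 scale: fully inside
  # the vessel at rest, but close enough to the wall that the point-spread
  # tail of the surrounding labeled tissue reaches it
  lum_half_x <- max(1, round(geom$va / sqrt(2) * 0.9))
  lum_half_y <- max(1, round(geom$vb / sqrt(2) * 0.9))
  lumen <- tibble(
    roi_id = "lumen_01", kind = "vessel_lumen",
    x0 = as.integer(floor(geom$vx - lum_half_x)),
    y0 = as.integer(floor(geom$vy - lum_half_y)),
    x1 = as.integer(ceiling(geom$vx + lum_half_x)),
    y1 = as.integer(ceiling(geom$vy + lum_half_y))
  )
  max_scale <- sqrt(max(truth$area$area_um2) / cfg$baseline_area_um2)
  half <- ellipse_bbox_half(geom$va * max_scale, geom$vb * max_scale,
                            cfg$vessel_orientation_deg)
  box <- tibble(
    roi_id = "vessel_01", kind = "vessel_box",
    x0 = max(0L, as.integer(floor(geom$vx - half["x"] - 3))),
    y0 = max(0L, as.integer(floor(geom$vy - half["y"] - 3))),
    x1 = min(geom$w, as.integer(ceiling(geom$vx + half["x"] + 3))),
    y1 = min(geom$h, as.integer(ceiling(geom$vy + half["y"] + 3)))
  )
  dplyr::bind_rows(soma, lumen, box) |>
    mutate(site_id = site_id, depth_label = depth_label)
}
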