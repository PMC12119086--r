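# Vessel cross-section estimation, lumen proxy, smoothing, variance
# explained, display outliers.

# Raw synthetic video: dark ellipse on a bright background, lumen kept below
# 0.5% of pooled pixels so the percentile threshold binarizes the full lumen.
dark_ellipse_video <- function(h, w, frames, a, b, cx = w / 2, cy = h / 2,
                               bg = 100, dark = 0, bg_noise = 0.5,
                               scale = rep(1, frames)) {
  arr <- array(0, dim = c(h, w, frames))
  for (t in seq_len(frames)) {
    img <- matrix(bg + rnorm(h * w, 0, bg_noise), h, w)
    m <- hemoccl:::ellipse_mask(h, w, cx, cy, a * scale[t], b * scale[t])
    img[m] <- dark
    arr[, , t] <- img
  }
  arr
}

test_that("ellipse fit recovers a dark disk within 5% of its true area", {
  withr::with_seed(61, {
    vid <- dark_ellipse_video(256, 256, 5, a = 10, b = 10)
    est <- vessel_area_trace(vid)
    expect_equal(est$area_px2, rep(pi * 100, 5), tolerance = 0.05)
    # oracle: below-threshold pixel count
    expect_equal(est$area_px2, as.numeric(est$n_px), tolerance = 0.05)
    expect_false(any(est$truncated))
  })
})

test_that("ellipse area matches the pixel-count oracle on convex lumens", {
  withr::with_seed(62, {
    shapes <- list(c(8, 8), c(12, 5), c(6, 14), c(12, 8))
    for (s in shapes) {
      vid <- dark_ellipse_video(256, 256, 3, a = s[1], b = s[2])
      est <- vessel_area_trace(vid)
      expect_equal(est$area_px2, as.numeric(est$n_px), tolerance = 0.10)
    }
  })
})

test_that("uniform frames yield zero area and edge contact is flagged", {
  expect_warning(est <- vessel_area_trace(array(5, dim = c(16, 16, 3))),
                 "no below-threshold")
  expect_equal(est$area_px2, rep(0, 3))
  # component touching the box edge is flagged as possibly truncated
  withr::with_seed(63, {
    vid <- dark_ellipse_video(256, 256, 3, a = 10, b = 10, cy = 5)
    est2 <- suppressMessages(vessel_area_trace(vid))
    expect_true(all(est2$truncated))
  })
})

test_that("estimated area tracks a known dilation sequence", {
  withr::with_seed(64, {
    n <- 120
    scale <- sqrt(1 + 0.3 * sin(2 * pi * seq_len(n) / 60))
    vid <- dark_ellipse_video(256, 256, n, a = 10, b = 5, scale = scale)
    est <- vessel_area_trace(vid)
    true_area <- pi * 50 * scale^2
    expect_gt(cor(est$area_px2, true_area), 0.95)
  })
})

test_that("lumen proxy rises on constriction and opposes the fitted area", {
  sd <- sin_dilation_scene()
  lum <- dplyr::filter(sd$rois, kind == "vessel_lumen")
  proxy <- vessel_lumen_trace(sd$scene$stack, lum, 15)
  # noise-free constriction: proxy increases as area falls
  expect_lt(cor(proxy$values, sd$area), -0.9)

  # constant vessel: proxy flat at zero
  cfg <- sd$cfg
  flat <- render_frames(sd$log, rep(cfg$baseline_area_um2, nrow(sd$log)), cfg)
  proxy0 <- vessel_lumen_trace(flat$stack, lum, 15)
  expect_equal(proxy0$values, rep(0, nrow(sd$log)))
})

test_that("moving average is a truncated centered boxcar", {
  expect_equal(moving_average(rep(4, 50), 15, 0.5), rep(4, 50))
  # unit impulse with a 3-frame window spreads to 1/3 over three frames
  x <- rep(0, 11); x[6] <- 1
  sm <- moving_average(x, 6, 0.5)  # 3-frame window
  expect_equal(sm[5:7], rep(1 / 3, 3))
  expect_equal(sum(sm[-c(5:7)]), 0)
  # interior mass is preserved
  withr::with_seed(65, y <- rnorm(500))
  expect_lt(abs(mean(moving_average(y, 15, 0.5)[20:480]) - mean(y[20:480])),
            0.01)
})

test_that("variance explained is the squared correlation with guards", {
  withr::with_seed(66, x <- rnorm(1000))
  expect_equal(variance_explained(x, 2 * x + 3), 1)
  # independent white noise explains almost nothing
  expect_lt(variance_explained(x, rnorm(1000)), 0.02)
  # equal signal and noise variance halves R^2
  withr::with_seed(67, {
    s <- rnorm(5000)
    expect_equal(variance_explained(s, s + rnorm(5000)), 0.5,
                 tolerance = 0.1)
  })
  # symmetry and affine invariance
  withr::with_seed(68, {
    a <- rnorm(300); b <- a + rnorm(300)
    expect_equal(variance_explained(a, b), variance_explained(b, a))
    expect_equal(variance_explained(a, b),
                 variance_explained(5 - 2 * a, b), tolerance = 1e-12)
  })
  # zero variance is reported as missing
  expect_message(r <- variance_explained(rep(1, 10), rnorm(10)), "zero")
  expect_true(is.na(r))
  # onset-windowed mode restricts to -2..+6 s
  n <- 300
  x2 <- rnorm(n); y2 <- x2
  y2[1:100] <- rnorm(100)  # disagreement outside the window
  r2 <- variance_explained(x2, y2, onset = 200, frame_rate = 15)
  expect_equal(r2, 1)
})

test_that("noise-free occlusion is fully explained; noise degrades it", {
  sd <- sin_dilation_scene()
  soma <- dplyr::filter(sd$rois, kind == "soma")
  d <- compute_dff_traces(
    dplyr::filter(extract_traces(sd$scene$stack, soma), kind == "soma"), 15)
  mean_dff <- d |>
    dplyr::group_by(frame) |>
    dplyr::summarise(dff = mean(dff), .groups = "drop")
  sm <- function(x) moving_average(x, 15, 0.5)
  r2_clean <- variance_explained(sm(sd$area), sm(mean_dff$dff))
  expect_gte(r2_clean, 0.95)

  # strictly decreasing across five increasing noise levels
  withr::with_seed(69, {
    r2s <- vapply(c(0.002, 0.005, 0.01, 0.02, 0.05), function(s) {
      noisy <- mean_dff$dff + rnorm(nrow(mean_dff), 0, s)
      variance_explained(sm(sd$area), sm(noisy))
    }, numeric(1))
  })
  expect_true(all(diff(c(r2_clean, r2s)) < 0))
})

test_that("Tukey fences flag only genuine outliers", {
  expect_equal(iqr_outlier_mask(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outlier_mask(rep(2, 10))))
  # symmetric data produce symmetric fences
  v <- c(-5, -2, -1, 0, 1, 2, 5)
  expect_equal(iqr_outlier_mask(v), rev(iqr_outlier_mask(-v)))
  expect_error(iqr_outlier_mask(c(1, 2, 3)), "4 values")
})
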