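# Event-triggered matrices, responsiveness tests, chance bands.

test_that("event-triggered slicing is exact and enforces the 3-trial rule", {
  rate <- 15
  n <- 900
  trace <- numeric(n)
  events <- c(150L, 400L, 700L)
  bump <- hemoccl:::window_to_offsets(0, 1, rate)
  for (f in events) trace[f + bump] <- 1

  tm <- event_triggered_matrix(trace, events, rate, pre_s = 1, post_s = 2,
                               kind = "locomotion_onset")
  expect_true(tm$included)
  expect_equal(nrow(tm$mat), 3)
  # every trial shows the rectangular bump at the same latency
  for (i in 1:3) {
    expect_equal(tm$mat[i, tm$offsets %in% bump], rep(1, length(bump)))
    expect_equal(sum(tm$mat[i, ]), length(bump))
  }

  # event too close to the start is dropped
  expect_message(
    tm2 <- event_triggered_matrix(trace, c(2L, events), rate, 1, 2),
    "dropped")
  expect_equal(nrow(tm2$mat), 3)

  # fewer than three surviving trials excludes the ROI
  tm3 <- event_triggered_matrix(trace, events[1:2], rate, 1, 2)
  expect_false(tm3$included)
})

test_that("baseline subtraction uses the kind-specific windows", {
  rate <- 15
  trace <- rep(0.3, 600)
  events <- c(100L, 300L, 500L)
  tm <- event_triggered_matrix(trace, events, rate, 1, 2,
                               kind = "grating_onset")
  tm <- baseline_subtract(tm)
  expect_equal(tm$baseline_window, c(-0.5, 0))
  expect_true(all(tm$mat == 0))  # constant rows vanish

  tml <- event_triggered_matrix(trace, events, rate, 1.5, 2,
                                kind = "locomotion_onset")
  tml <- baseline_subtract(tml)
  expect_equal(tml$baseline_window, c(-1, -0.5))

  expect_error(baseline_subtract(tm, c(0, 0.5)), "baseline")
})

test_that("response windows follow the named profiles", {
  rate <- 15
  trace <- rnorm(1200)
  ev <- c(200L, 500L, 800L)
  tm <- baseline_subtract(event_triggered_matrix(trace, ev, rate, 1, 2.5,
                                                 kind = "grating_onset"))
  # grating responsiveness window is +0.5..+2.5 s, mapped half-open as
  # frame offsets floor(0.5 * 15) .. floor(2.5 * 15) - 1
  sc <- trial_mean_response(tm)
  direct <- rowMeans(tm$mat[, tm$offsets %in% 7:36])
  expect_equal(sc, direct)

  # comparison profile: gratings use +0.5..+3 s
  tm2 <- baseline_subtract(event_triggered_matrix(trace, ev, rate, 1, 3,
                                                  kind = "grating_onset"),
                           profile = "comparison")
  sc2 <- trial_mean_response(tm2, profile = "comparison")
  expect_equal(sc2, rowMeans(tm2$mat[, tm2$offsets %in% 7:44]))

  # a ramp equal to t over 0..2 s averages to ~1 over that window
  ramp <- rep(0, 600)
  ev3 <- c(150L, 350L)
  for (f in c(ev3, 550L)) {
    off <- hemoccl:::window_to_offsets(0, 2, rate)
    ramp[f + off] <- off / rate
  }
  tm3 <- event_triggered_matrix(ramp, c(ev3, 550L), rate, 1, 2)
  sc3 <- trial_mean_response(tm3, response_window = c(0, 2))
  expect_equal(unname(sc3), rep(1, 3), tolerance = 1 / (2 * rate) * 2)

  # constant rows give constant scalars
  tm4 <- event_triggered_matrix(rep(1, 600), ev3, rate, 1, 2)
  expect_error(trial_mean_response(tm4, c(-0.5, 1)), "response")
})

test_that("responsiveness t-test behaves at the edges", {
  expect_false(test_responsive(rep(0, 5))$responsive)
  r <- test_responsive(c(10, 10.1, 9.9, 10.2))
  expect_true(r$responsive)
  expect_lt(r$p, 1e-6)
  # zero variance, nonzero mean: responsive with a floor p
  r2 <- test_responsive(rep(2, 4))
  expect_true(r2$responsive)
  expect_lte(r2$p, .Machine$double.xmin)
  expect_error(test_responsive(c(1, 2)), "3 trials")
})

test_that("window means are linear in the traces", {
  rate <- 15
  withr::with_seed(31, trace <- rnorm(900))
  ev <- c(200L, 500L, 800L)
  scal <- function(x) {
    tm <- baseline_subtract(event_triggered_matrix(x, ev, rate, 1, 1.5,
                                                   kind = "mismatch"))
    trial_mean_response(tm)
  }
  expect_equal(scal(3 * trace), 3 * scal(trace), tolerance = 1e-12)
})

test_that("an added deterministic response drives the fraction to 1", {
  rate <- 15
  n_frames <- 3000
  sd_noise <- 0.02
  n_tr <- 12
  amp <- 5 * sd_noise / sqrt(n_tr)
  withr::with_seed(12, {
    ev <- sort(sample(seq(50, n_frames - 50), n_tr))
    d <- null_dff_site(20, n_frames, sd = sd_noise, seed = 3)
    off <- hemoccl:::window_to_offsets(0.5, 1.5, rate)
    d <- d |>
      dplyr::group_by(roi_id) |>
      dplyr::mutate(dff = {
        v <- dff
        for (f in ev) v[f + off] <- v[f + off] + amp
        v
      }) |>
      dplyr::ungroup()
    ev_tbl <- tibble::tibble(kind = "locomotion_onset", frame = ev)
    res <- responsiveness_table(d, ev_tbl, rate)
    expect_true(all(res$responsive))
  })
})

test_that("responsive fractions aggregate per site with a chance test", {
  res <- tibble::tibble(
    site_id = rep(c("a", "b"), each = 4),
    kind = "locomotion_onset",
    responsive = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    included = TRUE)
  fr <- responsive_fraction(res)
  expect_equal(sort(fr$fractions$fraction), c(0.75, 1))
  expect_equal(fr$chance, 0.05)
  expect_error(responsive_fraction(dplyr::select(res, -site_id)), "site_id")
})

test_that("random-trigger chance band brackets the null and flags signal", {
  rate <- 15
  n <- 3000
  speed <- rep(1, n)
  withr::with_seed(77, {
    d <- null_dff_site(15, n, sd = 0.05, seed = 8)
    band <- chance_interval_from_random_triggers(
      d, speed, rate, n_triggers = 10, n_rep = 60, seed = 4)
    # pure-noise band straddles zero in every bin
    expect_true(all(band$lo <= 0 & band$hi >= 0))

    # constant traces give a zero-width band at zero
    dc <- dplyr::mutate(d, dff = 0.42)
    band0 <- chance_interval_from_random_triggers(
      dc, speed, rate, n_triggers = 10, n_rep = 60, seed = 4)
    expect_true(all(band0$lo == 0 & band0$hi == 0))

    expect_error(chance_interval_from_random_triggers(
      d, speed, rate, n_triggers = 10, n_rep = 10, seed = 1), "n_rep")

    # a shared event-locked bump pushes the population average above the band
    ev <- c(500L, 1500L, 2500L)
    off <- hemoccl:::window_to_offsets(0, 1, rate)
    db <- d |>
      dplyr::group_by(roi_id) |>
      dplyr::mutate(dff = {
        v <- dff
        for (f in ev) v[f + off] <- v[f + off] + 0.3
        v
      }) |>
      dplyr::ungroup()
    traces <- hemoccl:::dff_to_matrix(db)
    offs <- hemoccl:::window_to_offsets(-1, 1.5, rate)
    bidx <- offs %in% hemoccl:::window_to_offsets(-0.5, 0, rate)
    eta <- hemoccl:::population_eta(traces, ev, offs, bidx)
    in_resp <- offs %in% off
    expect_true(all(eta[in_resp] > band$hi[in_resp]))
  })
})
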