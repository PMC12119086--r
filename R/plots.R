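# ggplot2 displays for the main result types.

#' @export
autoplot.trial_matrix <- function(object, ...) {
  if (nrow(object$mat) == 0) abort("empty trial matrix", class = "hemoccl_config_error")
  trials <- tibble(trial = rep(seq_len(nrow(object$mat)), ncol(object$mat)),
                   time_s = rep(object$time_s, each = nrow(object$mat)),
                   dff = as.numeric(object$mat))
  avg <- trials |>
    group_by(.data$time_s) |>
    summarise(dff = mean(.data$dff), .groups = "drop")
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$trial), alpha = 0.25) +
    ggplot2::geom_line(data = avg, linewidth = 1, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from onset (s)", y = expression(Delta*F/F[0]),
                  title = sprintf("%s, %s (%d trials)",
                                  object$roi_id %||% "ROI", object$kind,
                                  nrow(object$mat))) +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap mean with its SE band
#'
#' @param band Tibble from [bootstrap_se_band()], optionally with a
#'   `time_s` column.
#' @param chance Optional chance-band tibble (`time_s`, `lo`, `hi`) from
#'   [chance_interval_from_random_triggers()].
#' @return A ggplot object.
#' @export
plot_bootstrap_band <- function(band, chance = NULL) {
  x <- if ("time_s" %in% names(band)) "time_s" else "bin"
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data[[x]]))
  if (!is.null(chance))
    p <- p + ggplot2::geom_ribbon(
      data = chance, ggplot2::aes(x = .data$time_s, ymin = .data$lo,
                                  ymax = .data$hi),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.6)
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue4") +
    ggplot2::labs(x = if (x == "time_s") "time from onset (s)" else "bin",
                  y = expression(Delta*F/F[0])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.responsive_fraction <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$kind, y = .data$fraction)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fraction responsive") +
    ggplot2::theme_minimal()
}

#' Plot state-dependent pairwise correlations
#'
#' Each point is one neuron's mean pairwise correlation to its site mates,
#' stationary vs locomoting; the diagonal marks equality.
#' @param corr Tibble from [pairwise_state_correlations()].
#' @return A ggplot object.
#' @export
plot_state_correlations <- function(corr) {
  ggplot2::ggplot(corr, ggplot2::aes(x = .data$corr_stationary,
                                     y = .data$corr_locomoting,
                                     colour = .data$site_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "pairwise correlation, stationary",
                  y = "pairwise correlation, locomoting") +
    ggplot2::theme_minimal()
}

#' Plot an estimated vessel cross-section series
#' @param area Tibble from [vessel_area_trace()], optionally with `time_s`.
#' @return A ggplot object.
#' @export
plot_vessel_area <- function(area) {
  x <- if ("time_s" %in% names(area)) "time_s" else "frame"
  y <- if ("area_um2" %in% names(area)) "area_um2" else "area_px2"
  ggplot2::ggplot(area, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (x == "time_s") "time (s)" else "frame",
                  y = if (y == "area_um2") expression("area ("*mu*m^2*")")
                      else expression("area ("*px^2*")")) +
    ggplot2::theme_minimal()
}
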