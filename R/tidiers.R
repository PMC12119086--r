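# broom-style tidiers for the fitted/result objects.

#' @export
tidy.hb_boot <- function(x, ...) bootstrap_se_band(x)

#' @export
glance.hb_boot <- function(x, ...) {
  tibble(n_boot = x$n_boot, n_bins = ncol(x$draws),
         mean = mean(x$draws), sd = sd(as.numeric(x$draws)))
}

#' @export
tidy.responsive_fraction <- function(x, ...) x$fractions

#' @export
glance.responsive_fraction <- function(x, ...) {
  x$tests |> mutate(chance = x$chance)
}

#' @export
tidy.dff_trace <- function(x, ...) {
  tibble(roi_id = x$roi_id %||% NA_character_,
         frame = seq_along(x$values),
         time_s = if (is.finite(x$frame_rate))
           frame_time(seq_along(x$values), x$frame_rate)
         else NA_real_,
         dff = x$values)
}

#' @export
glance.dff_trace <- function(x, ...) {
  tibble(roi_id = x$roi_id %||% NA_character_, f0 = x$f0,
         frame_rate = x$frame_rate, n_frames = length(x$values))
}

#' @export
tidy.trial_matrix <- function(x, ...) {
  if (nrow(x$mat) == 0)
    return(tibble(trial = integer(0), time_s = numeric(0), dff = numeric(0)))
  tibble(trial = rep(seq_len(nrow(x$mat)), times = ncol(x$mat)),
         time_s = rep(x$time_s, each = nrow(x$mat)),
         dff = as.numeric(x$mat))
}

#' @export
glance.trial_matrix <- function(x, ...) {
  tibble(roi_id = x$roi_id %||% NA_character_, kind = x$kind,
         n_trials = nrow(x$mat), n_bins = ncol(x$mat),
         n_dropped = x$n_dropped, included = x$included)
}
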