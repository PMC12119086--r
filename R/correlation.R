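# Behavioral-state-dependent pairwise correlation structure.

#' Mean pairwise correlations per ROI, split by locomotion state
#'
#' Pearson correlations between the dF/F0 traces of all same-site ROI pairs,
#' computed separately on stationary and locomoting frames (each state's
#' frames concatenated across the session), then averaged per ROI over its
#' pairings. Sites whose frame count in either state falls below
#' `min_frames` are skipped with a message; zero-variance traces within a
#' state yield `NA` pairings.
#'
#' @param dff Long tibble `site_id`, `roi_id`, `frame`, `dff` (>= 2 ROIs per
#'   site).
#' @param state Per-frame state from [locomotion_state_mask()] (aligned to
#'   `frame`).
#' @param min_frames Minimum frames required in each state (default 150,
#'   i.e. 10 s at 15 Hz).
#' @return Tibble `site_id`, `roi_id`, `corr_stationary`, `corr_locomoting`,
#'   `n_frames_stationary`, `n_frames_locomoting`.
#' @export
pairwise_state_correlations <- function(dff, state, min_frames = 150) {
  if (!"site_id" %in% names(dff))
    abort("`dff` must carry a site_id column", class = "hemoccl_config_error")
  out <- list()
  for (site in split(dff, dff$site_id)) {
    m <- dff_to_matrix(site)
    if (nrow(m) < 2) {
      inform(sprintf("site %s skipped: fewer than 2 ROIs", site$site_id[1]))
      next
    }
    if (length(state) != ncol(m))
      abort("state mask and traces are not aligned", class = "hemoccl_config_error")
    n_stat <- sum(state == "stationary")
    n_loco <- sum(state == "locomoting")
    if (n_stat < min_frames || n_loco < min_frames) {
      inform(sprintf("site %s skipped: < %d frames in a state",
                     site$site_id[1], min_frames))
      next
    }
    mean_pair <- function(frames) {
      cc <- suppressWarnings(cor(t(m[, frames, drop = FALSE])))
      # mean over each ROI's pairings; NA from a zero-variance trace
      # propagates to its pairings
      vapply(seq_len(nrow(cc)), function(i) mean(cc[i, -i]), numeric(1))
    }
    cs <- mean_pair(which(state == "stationary"))
    cl <- mean_pair(which(state == "locomoting"))
    out[[length(out) + 1]] <- tibble(
      site_id = site$site_id[1], roi_id = rownames(m),
      corr_stationary = unname(cs), corr_locomoting = unname(cl),
      n_frames_stationary = n_stat, n_frames_locomoting = n_loco)
  }
  if (length(out) == 0)
    abort("no site had enough ROIs and state frames", class = "hemoccl_config_error")
  dplyr::bind_rows(out)
}
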