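# Hierarchical (imaging-site -> neuron) bootstrap statistics.
#
# Each replicate resamples imaging sites with replacement (as many as
# observed), then, within every drawn site, resamples its neurons with
# replacement (as many as that site has), and takes the mean over all drawn
# neurons. The spread of replicate means respects the nested dependence of
# neurons within sites.

# Convert a nested tibble (site_id, roi_id, value[, bin_index]) into a list
# of per-site matrices (neurons x bins).
as_nested_sites <- function(data) {
  req <- c("site_id", "roi_id", "value")
  if (!all(req %in% names(data)))
    abort("nested data needs columns site_id, roi_id, value",
          class = "hemoccl_config_error")
  has_bins <- "bin_index" %in% names(data)
  sites <- split(data, data$site_id)
  bins <- NULL
  mats <- lapply(sites, function(s) {
    if (has_bins) {
      w <- tidyr::pivot_wider(s[, c("roi_id", "bin_index", "value")],
                              names_from = "bin_index",
                              values_from = "value", names_sort = TRUE)
      m <- as.matrix(w[, -1, drop = FALSE])
    } else {
      m <- matrix(s$value, ncol = 1,
                  dimnames = list(s$roi_id, NULL))
    }
    if (nrow(m) < 1) abort("empty site", class = "hemoccl_config_error")
    if (anyNA(m)) abort("sites must share one time axis (NA after widening)",
                        class = "hemoccl_config_error")
    m
  })
  nb <- unique(vapply(mats, ncol, integer(1)))
  if (length(nb) != 1)
    abort("sites must share one time axis", class = "hemoccl_config_error")
  mats
}

#' Hierarchical bootstrap distribution of the mean
#'
#' @param data Nested tibble with columns `site_id`, `roi_id`, `value`, and
#'   optionally `bin_index` for time-binned vectors (all neurons sharing one
#'   axis).
#' @param n_boot Number of bootstrap replicates (>= 100; 10,000 for testing,
#'   1,000 for plotted curves).
#' @param seed Integer seed for reproducible replicate streams.
#' @return An `hb_boot` list: `draws` (n_boot x bins matrix of replicate
#'   means), `n_boot`, `seed`.
#' @export
hierarchical_bootstrap_mean <- function(data, n_boot = 10000, seed = NULL) {
  if (n_boot < 100)
    abort("n_boot must be >= 100", class = "hemoccl_config_error")
  mats <- as_nested_sites(data)
  s <- length(mats)
  nb <- ncol(mats[[1]])
  draws <- with_seed(seed, {
    if (s == 1L && nb == 1L) {
      # flat scalar hierarchy: the single site is drawn every time, so only
      # neuron resampling matters -- vectorized draw
      v <- mats[[1]][, 1]
      n <- length(v)
      idx <- sample.int(n, n * n_boot, replace = TRUE)
      matrix(colMeans(matrix(v[idx], n, n_boot)), ncol = 1)
    } else {
      out <- matrix(NA_real_, n_boot, nb)
      counts <- vapply(mats, nrow, integer(1))
      for (b in seq_len(n_boot)) {
        drawn <- sample.int(s, s, replace = TRUE)
        total <- numeric(nb)
        m <- 0L
        for (si in drawn) {
          ni <- counts[si]
          rows <- sample.int(ni, ni, replace = TRUE)
          total <- total + colSums(mats[[si]][rows, , drop = FALSE])
          m <- m + ni
        }
        out[b, ] <- total / m
      }
      out
    }
  })
  structure(list(draws = draws, n_boot = n_boot, seed = seed),
            class = "hb_boot")
}

#' Bootstrap SE band (68% interval) of a replicate distribution
#'
#' The bootstrap SE band is the 15.8th to 84.2nd percentile interval of the
#' replicate means (a 1-SD, 68% confidence interval), computed per time bin
#' for vector data.
#'
#' @param dist An `hb_boot`, or a numeric vector/matrix of replicate means
#'   (rows = replicates).
#' @return Tibble `bin`, `mean`, `lo`, `hi` (one row for scalar data).
#' @export
bootstrap_se_band <- function(dist) {
  draws <- if (inherits(dist, "hb_boot")) dist$draws else dist
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) == 0) abort("empty distribution", class = "hemoccl_config_error")
  tibble(bin = seq_len(ncol(draws)),
         mean = colMeans(draws),
         lo = apply(draws, 2, quantile, 0.158, names = FALSE),
         hi = apply(draws, 2, quantile, 0.842, names = FALSE))
}

#' Per-bin hierarchical-bootstrap comparison of two conditions
#'
#' Bootstraps each condition independently (site-then-neuron resampling),
#' forms the per-bin distribution of the difference of means, and reports
#' two-sided sign-fraction p values: `p = 2 * min(frac <= 0, frac >= 0)`,
#' floored at `1/n_boot`. No across-bin correction is applied.
#'
#' @param a,b Nested tibbles (see [hierarchical_bootstrap_mean()]) sharing
#'   one time axis.
#' @param n_boot Replicates per condition.
#' @param alpha Per-bin significance threshold (0.01 for response curves).
#' @param seed Integer seed.
#' @return Tibble `bin`, `diff_mean`, `p`, `significant`.
#' @export
compare_conditions <- function(a, b, n_boot = 10000, alpha = 0.01,
                               seed = NULL) {
  ba <- hierarchical_bootstrap_mean(a, n_boot,
                                    seed = if (is.null(seed)) NULL
                                           else derive_seed(seed, "a"))
  bb <- hierarchical_bootstrap_mean(b, n_boot,
                                    seed = if (is.null(seed)) NULL
                                           else derive_seed(seed, "b"))
  if (ncol(ba$draws) != ncol(bb$draws))
    abort("conditions do not share a time axis", class = "hemoccl_config_error")
  d <- ba$draws - bb$draws
  p <- vapply(seq_len(ncol(d)), function(j) {
    lo <- mean(d[, j] <= 0)
    hi <- mean(d[, j] >= 0)
    min(1, max(2 * min(lo, hi), 1 / n_boot))
  }, numeric(1))
  tibble(bin = seq_len(ncol(d)), diff_mean = colMeans(d), p = p,
         significant = p < alpha)
}
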