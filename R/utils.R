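# Shared helpers: frame/time conventions, seeded RNG, integer translation.
#
# Convention used throughout: frames are 1-based in R; frame i covers the
# half-open time interval [(i-1)/rate, i/rate) seconds. A window [t0, t1) in
# seconds relative to an onset maps to the half-open 0-based relative frame
# range [floor(t0*rate), floor(t1*rate)).

#' Map a time window to relative frame offsets
#'
#' @param t0,t1 Window edges in seconds (half-open, `t0 < t1`).
#' @param rate Frame rate in Hz.
#' @return Integer vector of 0-based frame offsets relative to the onset
#'   frame.
#' @keywords internal
window_to_offsets <- function(t0, t1, rate) {
  lo <- floor(t0 * rate)
  hi <- floor(t1 * rate)
  if (hi <= lo) abort("empty window after frame mapping", class = "hemoccl_window_error")
  seq.int(lo, hi - 1L)
}

frame_time <- function(frames, rate) (frames - 1) / rate

#' Derive a child seed from a parent seed and stage label
#'
#' Deterministic fan-out so pipeline stages are independently reproducible.
#' Kept below 2^31 so the result is a valid R integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Translate an image by an integer pixel shift
#'
#' Content moves by `dx` columns (rightwards) and `dy` rows (downwards);
#' exposed pixels are filled with `fill`.
#' @param img Numeric matrix (rows = y, cols = x).
#' @param dx,dy Integer shifts in pixels.
#' @param fill Fill value for exposed pixels (default: image median).
#' @return Shifted matrix of the same dimension.
#' @keywords internal
translate_int <- function(img, dx, dy, fill = median(img)) {
  dx <- as.integer(dx); dy <- as.integer(dy)
  out <- matrix(fill, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dy
  src_c <- seq_len(ncol(img)) - dx
  ok_r <- src_r >= 1L & src_r <= nrow(img)
  ok_c <- src_c >= 1L & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a positive finite scalar", name),
          class = "hemoccl_config_error")
}
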