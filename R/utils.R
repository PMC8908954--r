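# Shared numeric helpers.

#' Centred running mean with shrinking windows at the edges
#'
#' O(n) via cumulative sums. At positions closer than half a window to
#' either end the window shrinks symmetrically-as-possible, so the output
#' has the same length as the input with no NA padding.
#'
#' @param x numeric vector
#' @param k window length in samples (coerced to an odd integer >= 1)
#' @return numeric vector of the same length
#' @export
running_mean <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || n == 1L) return(x)
  if (k > 2L * n) stop("running-mean window longer than the record")
  half <- k %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fold values into [lo, hi] by reflection (triangle wave)
#' @keywords internal
fold_reflect <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) stop("degenerate reflection interval")
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Degrees to radians / radians to degrees
#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) x * 180 / pi

#' Deterministic sub-seed for one animal-night and pipeline stage
#'
#' All randomness in a study descends from one root seed; per-night
#' sub-seeds keep nights independent yet reproducible in isolation.
#' @keywords internal
derive_seed <- function(seed, animal = 0L, night = 0L, stage = 0L) {
  s <- (as.numeric(seed) * 100003 + animal * 10007 + night * 1009 + stage * 101)
  as.integer(s %% 2147483647)
}

#' Last-observation-carried-forward fill for leading/internal NAs
#' @keywords internal
locf <- function(x) {
  ok <- !is.na(x)
  if (all(ok)) return(x)
  if (!any(ok)) stop("no valid values to fill from")
  idx <- cumsum(ok)
  first <- which(ok)[1]
  vals <- x[ok][pmax(1L, idx)]
  vals[seq_len(first - 1L)] <- x[ok][1]
  vals
}
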