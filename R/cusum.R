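#' CUSUM contrast at a candidate split
#'
#' The scaled difference of left and right sample means used throughout binary
#' segmentation. For an interval `[start, end]` of length `n = end - start + 1`
#' and a split `b` (last index of the left part),
#' \deqn{C(b) = \sqrt{\frac{e-b}{n(b-s+1)}} \sum_{t=s}^{b} x_t -
#'       \sqrt{\frac{b-s+1}{n(e-b)}} \sum_{t=b+1}^{e} x_t,}
#' equivalently \eqn{\sqrt{n_L n_R / n}\,(\bar x_L - \bar x_R)}. Its maximiser
#' in absolute value estimates a change-point location, and under a constant
#' mean it is invariant to adding a constant and scales linearly with the data.
#'
#' @param x Numeric series.
#' @param start,end Interval bounds, 1-based inclusive, `start < end`.
#' @param b Split index (or vector of splits), `start <= b <= end - 1`.
#' @return Signed contrast value(s), one per element of `b`.
#' @examples
#' cusum_at(c(0, 0, 1, 1), 1, 4, 2) # -1
#' @export
cusum_at <- function(x, start, end, b) {
  check_series(x)
  iv <- check_interval(length(x), start, end)
  b <- as.integer(b)
  if (any(b < iv[1]) || any(b > iv[2] - 1L)) {
    abort("split `b` must satisfy start <= b <= end - 1.",
          class = "wbs2sdll_input_error")
  }
  n <- iv[2] - iv[1] + 1
  cs <- c(0, cumsum(x))
  n_l <- b - iv[1] + 1
  n_r <- iv[2] - b
  left <- cs[b + 1L] - cs[iv[1]]
  right <- cs[iv[2] + 1L] - cs[b + 1L]
  sqrt(n_r / (n * n_l)) * left - sqrt(n_l / (n * n_r)) * right
}

#' Best split of an interval by absolute CUSUM
#'
#' Evaluates the CUSUM contrast at every admissible split of `[start, end]`
#' and returns the maximiser of its absolute value; ties go to the smallest
#' split. The robust variant applies the contrast to
#' `sign(x - median(x[start:end]))` (see [sign_transform()]), which bounds all
#' magnitudes by `sqrt(n)` regardless of the error distribution.
#'
#' @inheritParams cusum_at
#' @param variant `"standard"` for the plain CUSUM of `x`, `"robust"` for the
#'   sign CUSUM of the median-centred segment.
#' @return A one-row tibble with columns `start`, `end`, `b`, `contrast`,
#'   `magnitude`.
#' @examples
#' max_cusum(c(0, 0, 1, 1), 1, 4) # b = 2, magnitude = 1
#' @export
max_cusum <- function(x, start, end, variant = c("standard", "robust")) {
  variant <- match.arg(variant)
  check_series(x)
  iv <- check_interval(length(x), start, end)
  res <- cusum_best_cpp(as.numeric(x), iv[1], iv[2], variant == "robust")
  tibble::tibble(start = iv[1], end = iv[2], b = as.integer(res[1, 1]),
                 contrast = res[1, 2], magnitude = res[1, 3])
}

#' Sign transform of a median-centred segment
#'
#' Returns `sign(x_t - m)` for `t` in `[start, end]`, where `m` is the median
#' of the segment (mean of the two central order statistics for even length;
#' `sign(0) = 0`). This is the input to the robust sign-CUSUM: the transformed
#' values lie in `{-1, 0, +1}` and are median-balanced on the segment, so the
#' robust variant needs no moment conditions on the noise.
#'
#' @inheritParams cusum_at
#' @return Numeric vector of length `end - start + 1` with values in
#'   `{-1, 0, 1}`.
#' @examples
#' sign_transform(c(3, 1, 2), 1, 3) # +1 -1 0
#' @export
sign_transform <- function(x, start, end) {
  check_series(x)
  iv <- check_interval(length(x), start, end)
  seg <- x[iv[1]:iv[2]]
  sign(seg - median(seg))
}

#' Sharpness of a CUSUM peak
#'
#' Change-points detected from CUSUMs whose absolute value drops off quickly
#' on both sides of the maximiser localise best; a CUSUM computed on a stretch
#' of data containing a single change-point always has this shape. The score
#' compares the decay of the squared contrast at offsets `1..h` on each side
#' of `b` against a triangular reference that reaches zero at offset `h`:
#' \deqn{\mathrm{score} = \mathrm{clip}_{[0,1]}\min_{j,\pm}
#'   \frac{C(b)^2 - C(b \pm j)^2}{j\,C(b)^2 / h}.}
#' Offsets falling outside the admissible split range contribute a zero
#' contrast. A flat profile scores 0; an exact single-step signal scores 1
#' (its squared CUSUM decays at least at the triangular rate). The score is an
#' optional diagnostic/filter and is never applied by default.
#'
#' @inheritParams cusum_at
#' @param b Single split index.
#' @param h Offset window, `1 <= h <= min(b - start + 1, end - b)`.
#' @return A score in `[0, 1]`; 0 whenever `C(b) = 0`.
#' @export
sharpness_score <- function(x, start, end, b, h) {
  check_series(x)
  iv <- check_interval(length(x), start, end)
  b <- as.integer(b)
  if (length(b) != 1L || b < iv[1] || b > iv[2] - 1L) {
    abort("split `b` must satisfy start <= b <= end - 1.",
          class = "wbs2sdll_input_error")
  }
  h <- as.integer(h)
  if (length(h) != 1L || h < 1L || h > min(b - iv[1] + 1L, iv[2] - b)) {
    abort("`h` must satisfy 1 <= h <= min(b - start + 1, end - b).",
          class = "wbs2sdll_input_error")
  }
  c0 <- cusum_at(x, iv[1], iv[2], b)^2
  if (c0 == 0) return(0)
  off_val <- function(bb) {
    if (bb < iv[1] || bb > iv[2] - 1L) return(0)
    cusum_at(x, iv[1], iv[2], bb)^2
  }
  j <- seq_len(h)
  drops <- c(
    (c0 - vapply(b - j, off_val, numeric(1))) / (j * c0 / h),
    (c0 - vapply(b + j, off_val, numeric(1))) / (j * c0 / h)
  )
  min(max(min(drops), 0), 1)
}

#' Best splits for a batch of intervals
#'
#' Vectorised [max_cusum()] over many intervals at once (one C++ pass): the
#' workhorse behind the solution-path recursion, exposed for diagnostics such
#' as checking the no-change bound on the absolute CUSUMs of all sub-intervals
#' of a constant-mean series.
#'
#' @inheritParams max_cusum
#' @param intervals A data frame with integer columns `start`, `end`
#'   (e.g. from [random_intervals()] or [all_intervals()]).
#' @return A tibble with one row per interval: `start`, `end`, `b`,
#'   `contrast`, `magnitude`.
#' @export
max_cusum_batch <- function(x, intervals, variant = c("standard", "robust")) {
  variant <- match.arg(variant)
  check_series(x)
  stopifnot(is.data.frame(intervals),
            all(c("start", "end") %in% names(intervals)))
  s <- as.integer(intervals$start)
  e <- as.integer(intervals$end)
  if (any(s < 1L) || any(e > length(x)) || any(s >= e)) {
    abort("every interval must satisfy 1 <= start < end <= length(x).",
          class = "wbs2sdll_input_error")
  }
  res <- cusum_best_cpp(as.numeric(x), s, e, variant == "robust")
  tibble::tibble(start = s, end = e, b = as.integer(res[, 1]),
                 contrast = res[, 2], magnitude = res[, 3])
}
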