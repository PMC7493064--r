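#' Candidate sub-intervals of a segment
#'
#' Wild binary segmentation searches each current segment over a collection of
#' sub-intervals. Three schemes are provided:
#'
#' * `all_intervals()` — every `[a, b]` with `start <= a < b <= end`
#'   (`n(n-1)/2` intervals for a segment of length `n`);
#' * `random_intervals()` — `m` intervals with start- and end-points drawn
#'   independently and uniformly from the segment, redrawing any degenerate
#'   pair (so every interval admits a split); reproducible under [set.seed()];
#' * `grid_intervals()` — the deterministic analogue: all pairs of points from
#'   the equispaced grid `g_i = start + round(i * delta * (end - start))`,
#'   `i = 0..k-1`, where `k` is the smallest integer with `k(k-1)/2 >= m` and
#'   `delta = 1/(k-1)`. Rounding is half-away-from-zero and collided grid
#'   points are deduplicated, so on short segments the returned count may fall
#'   below `m`.
#'
#' All three return intervals sorted lexicographically (random sampling keeps
#' draw order). [draw_intervals()] dispatches on `mode` and, for every mode,
#' falls back to the exhaustive set whenever `n(n-1)/2 <= m`: on short
#' segments there is nothing to be gained from sampling.
#'
#' @param start,end Segment bounds, 1-based inclusive, `start < end`.
#' @param m Target number of intervals (at least 1).
#' @param mode `"random"`, `"grid"`, or `"exhaustive"`.
#' @return A tibble with integer columns `start`, `end`, one row per interval.
#' @examples
#' grid_intervals(1, 5, 3) # grid {1,3,5}: [1,3], [1,5], [3,5]
#' @name intervals
NULL

#' @rdname intervals
#' @export
all_intervals <- function(start, end) {
  iv <- check_interval(end, start, end)
  as_interval_tibble(all_intervals_mat(iv[1], iv[2]))
}

#' @rdname intervals
#' @export
random_intervals <- function(start, end, m) {
  iv <- check_interval(end, start, end)
  stopifnot(m >= 1)
  as_interval_tibble(random_intervals_mat(iv[1], iv[2], as.integer(m)))
}

#' @rdname intervals
#' @export
grid_intervals <- function(start, end, m) {
  iv <- check_interval(end, start, end)
  stopifnot(m >= 1)
  as_interval_tibble(grid_intervals_mat(iv[1], iv[2], as.integer(m)))
}

#' @rdname intervals
#' @export
draw_intervals <- function(start, end, m,
                           mode = c("random", "grid", "exhaustive")) {
  mode <- match.arg(mode)
  iv <- check_interval(end, start, end)
  stopifnot(m >= 1)
  as_interval_tibble(draw_intervals_mat(iv[1], iv[2], as.integer(m), mode))
}

as_interval_tibble <- function(mat) {
  tibble::tibble(start = as.integer(mat[, 1]), end = as.integer(mat[, 2]))
}

## ---- internal matrix-returning workhorses (hot path of the recursion) ----

all_intervals_mat <- function(s, e) {
  pts <- s:e
  n <- length(pts)
  a <- rep.int(pts[-n], times = (n - 1):1)
  b <- unlist(lapply(seq_len(n - 1), function(i) pts[(i + 1):n]), use.names = FALSE)
  cbind(a, b, deparse.level = 0)
}

random_intervals_mat <- function(s, e, m) {
  n <- e - s + 1
  out_a <- integer(0)
  out_b <- integer(0)
  need <- m
  while (need > 0L) {
    k <- max(2L * need, 8L)
    a <- s - 1L + sample.int(n, k, replace = TRUE)
    b <- s - 1L + sample.int(n, k, replace = TRUE)
    ok <- (b - a) >= 1L
    out_a <- c(out_a, a[ok])
    out_b <- c(out_b, b[ok])
    need <- m - length(out_a)
  }
  cbind(out_a[seq_len(m)], out_b[seq_len(m)], deparse.level = 0)
}

round_half_away <- function(v) sign(v) * floor(abs(v) + 0.5)

grid_intervals_mat <- function(s, e, m) {
  k <- max(2, ceiling((1 + sqrt(1 + 8 * m)) / 2))
  while (k * (k - 1) / 2 < m) k <- k + 1   # guard against fp slop in ceiling
  delta <- 1 / (k - 1)
  g <- unique(as.integer(s + round_half_away((0:(k - 1)) * delta * (e - s))))
  pts <- sort(unique(c(s, g, e)))
  n <- length(pts)
  a <- rep.int(pts[-n], times = (n - 1):1)
  b <- unlist(lapply(seq_len(n - 1), function(i) pts[(i + 1):n]), use.names = FALSE)
  keep <- (b - a) >= 1L
  cbind(a[keep], b[keep], deparse.level = 0)
}

draw_intervals_mat <- function(s, e, m, mode) {
  n <- e - s + 1
  if (mode == "exhaustive" || n * (n - 1) / 2 <= m) {
    all_intervals_mat(s, e)
  } else if (mode == "grid") {
    grid_intervals_mat(s, e, m)
  } else {
    random_intervals_mat(s, e, m)
  }
}
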