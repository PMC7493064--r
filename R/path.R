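#' Complete WBS2 solution path
#'
#' Runs the Wild Binary Segmentation 2 recursion: on each current segment
#' `[s, e]` (starting from the full series) a set of candidate sub-intervals is
#' drawn (see [draw_intervals()]; the exhaustive set is used whenever the
#' segment is short enough that `n(n-1)/2 <= m_intervals`), the CUSUM contrast
#' is maximised over every interval and split, the winning split `b` is
#' recorded, and the recursion continues on `[s, b]` and `[b+1, e]` until
#' segments of length 1 remain. Every series of length `T` therefore yields
#' exactly `T - 1` candidate change-points — a complete solution path whose
#' prefixes, after sorting by magnitude, form the nested model sequence that
#' the SDLL rule selects from.
#'
#' Ties in the winning magnitude are broken to the smallest split, then to the
#' shortest source interval. In the robust variant the CUSUM is applied to
#' `sign(x - median)` with the median recomputed on every candidate interval.
#' With random sampling the path is reproducible given `seed`; with grid
#' sampling (or exhaustive search) it is fully deterministic.
#'
#' @param x Numeric series or data frame (see `column`).
#' @param column For data-frame input, the column holding the series (name or
#'   position; defaults to the first numeric column).
#' @param m_intervals Target number of candidate intervals per segment
#'   (the parameter usually written as M; default 100).
#' @param sampling `"random"`, `"grid"`, or `"exhaustive"`.
#' @param variant `"standard"` (mean changes) or `"robust"` (median changes
#'   via sign CUSUM).
#' @param seed Optional integer; seeds the interval sampling locally without
#'   disturbing the caller's RNG state.
#' @return A tibble of class `"wbs2_path"` with one row per candidate:
#'   `location`, `contrast`, `magnitude`, `start`, `end` (source interval),
#'   `depth`, `order` (detection sequence). Attributes `n_obs`, `variant`,
#'   `sampling`, `m_intervals`.
#' @examples
#' wbs2_path(c(0, 0, 0, 5, 5, 5), sampling = "exhaustive")
#' @export
wbs2_path <- function(x, column = NULL, m_intervals = 100,
                      sampling = c("random", "grid", "exhaustive"),
                      variant = c("standard", "robust"), seed = NULL) {
  sampling <- match.arg(sampling)
  variant <- match.arg(variant)
  x <- as_series(x, column)
  check_series(x)
  if (!is.null(seed)) withr::local_seed(seed)
  n_obs <- length(x)
  robust <- variant == "robust"
  m_intervals <- as.integer(m_intervals)
  stopifnot(m_intervals >= 1L)

  n_out <- n_obs - 1L
  loc <- integer(n_out); ctr <- numeric(n_out); mag <- numeric(n_out)
  iv_s <- integer(n_out); iv_e <- integer(n_out); dep <- integer(n_out)
  stack <- list(c(1L, n_obs, 0L))
  k <- 0L
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    s <- seg[1]; e <- seg[2]; d <- seg[3]
    ivs <- draw_intervals_mat(s, e, m_intervals, sampling)
    res <- cusum_best_cpp(x, ivs[, 1], ivs[, 2], robust)
    win <- order(-res[, 3], res[, 1], ivs[, 2] - ivs[, 1])[1L]
    b <- as.integer(res[win, 1])
    k <- k + 1L
    loc[k] <- b; ctr[k] <- res[win, 2]; mag[k] <- res[win, 3]
    iv_s[k] <- ivs[win, 1]; iv_e[k] <- ivs[win, 2]; dep[k] <- d
    # left child pushed last so it is processed first (detection order
    # follows a depth-first, left-to-right walk)
    if (e - (b + 1L) >= 1L) stack[[length(stack) + 1L]] <- c(b + 1L, e, d + 1L)
    if (b - s >= 1L) stack[[length(stack) + 1L]] <- c(s, b, d + 1L)
  }
  out <- tibble::tibble(location = loc, contrast = ctr, magnitude = mag,
                        start = iv_s, end = iv_e, depth = dep,
                        order = seq_len(n_out))
  structure(out,
            n_obs = n_obs, variant = variant, sampling = sampling,
            m_intervals = m_intervals,
            class = c("wbs2_path", class(out)))
}

#' Sort a solution path by candidate magnitude
#'
#' Orders the path entries by non-increasing CUSUM magnitude, keeping the
#' detection order among exact ties (stable sort). The sorted prefixes define
#' the nested models with `0, 1, ..., T-1` change-points from which the SDLL
#' rule selects; with random sampling a child segment's winning magnitude can
#' exceed its parent's, so the global re-sort is what defines the model
#' sequence, not the recursion order.
#'
#' @param path A `"wbs2_path"` tibble from [wbs2_path()].
#' @return The same tibble, rows sorted by decreasing `magnitude` (stable in
#'   `order`), with a `rank` column prepended.
#' @export
sort_path <- function(path) {
  stopifnot(inherits(path, "wbs2_path"))
  idx <- order(-path$magnitude, path$order)
  out <- tibble::as_tibble(path)[idx, , drop = FALSE]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  for (a in c("n_obs", "variant", "sampling", "m_intervals")) {
    attr(out, a) <- attr(path, a)
  }
  out
}
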