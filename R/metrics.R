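#' Change-point count error
#'
#' Signed difference between estimated and true numbers of change-points,
#' `|est| - |truth|`.
#'
#' @param est,truth Integer vectors of change-point locations (possibly empty).
#' @return Signed integer.
#' @export
count_error <- function(est, truth) {
  length(est) - length(truth)
}

#' Hausdorff distance between change-point sets
#'
#' The larger of the two directed maximum nearest-neighbour distances between
#' the estimated and true location sets — the standard localisation metric in
#' the segmentation literature. Conventions for empty sets (which occur by
#' design when nothing is detected): both empty gives 0, exactly one empty
#' gives `n_obs`.
#'
#' @inheritParams count_error
#' @param n_obs Series length `T`, used as the penalty when exactly one set is
#'   empty.
#' @return Non-negative scalar.
#' @examples
#' hausdorff_dist(10, 12, 100) # 2
#' @export
hausdorff_dist <- function(est, truth, n_obs) {
  if (length(est) == 0 && length(truth) == 0) return(0)
  if (length(est) == 0 || length(truth) == 0) return(as.numeric(n_obs))
  d_et <- max(vapply(est, function(b) min(abs(truth - b)), numeric(1)))
  d_te <- max(vapply(truth, function(b) min(abs(est - b)), numeric(1)))
  max(d_et, d_te)
}

#' Multi-run stability frequencies of detected change-points
#'
#' With random interval sampling the detector is deliberately non-
#' deterministic, and that randomness carries information: running the
#' procedure many times and recording how often each change-point is detected
#' gives an empirical measure of its significance, in the spirit of stability
#' selection. The procedure is run `n_runs` times with seeds
#' `seed + 1, ..., seed + n_runs`; all detected locations are pooled and
#' single-linkage clustered (neighbouring locations at distance `<= tol` join
#' one cluster); each cluster is reported by its median location together with
#' the fraction of runs contributing at least one location to it.
#'
#' Only available with `sampling = "random"`: a fixed grid gives the same
#' answer every run, so there is no distribution to examine.
#'
#' @inheritParams wbs_sdll
#' @param n_runs Number of repeated runs `K` (>= 1).
#' @param tol Matching window in index units; default `max(1, round(0.01 * T))`.
#' @param seed Base seed (run `k` uses `seed + k`).
#' @param ... Further arguments passed to [wbs_sdll()] (variant, threshold
#'   settings, ...).
#' @return A tibble of class `"wbs_stability"` with columns `location`
#'   (cluster median), `frequency` (fraction of runs, in `[0, 1]`), `n_runs`;
#'   attributes `tol` and `n_obs`. Clusters are separated by more than `tol`.
#' @export
stability_frequencies <- function(x, column = NULL, n_runs = 20, tol = NULL,
                                  seed = 1, sampling = "random", ...) {
  if (!identical(sampling, "random")) {
    abort("stability analysis needs `sampling = \"random\"`: a fixed grid is deterministic across runs.",
          class = "wbs2sdll_config_error")
  }
  x <- as_series(x, column)
  check_series(x)
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1L)
  n_obs <- length(x)
  if (is.null(tol)) tol <- max(1, round(0.01 * n_obs))

  runs <- purrr::map(seq_len(n_runs), function(k) {
    wbs_sdll(x, sampling = "random", seed = seed + k, ...)$changepoints
  })
  pooled <- tibble::tibble(
    run = rep.int(seq_len(n_runs), lengths(runs)),
    location = unlist(runs, use.names = FALSE) %||% integer(0)
  )
  if (nrow(pooled) == 0) {
    out <- tibble::tibble(location = numeric(0), frequency = numeric(0),
                          n_runs = integer(0))
  } else {
    pooled <- dplyr::arrange(pooled, .data$location)
    cluster_id <- cumsum(c(1, diff(pooled$location) > tol))
    out <- pooled |>
      dplyr::mutate(cluster = cluster_id) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(location = median(.data$location),
                       frequency = dplyr::n_distinct(.data$run) / n_runs,
                       .groups = "drop") |>
      dplyr::select("location", "frequency") |>
      dplyr::mutate(n_runs = n_runs)
  }
  structure(out, tol = tol, n_obs = n_obs,
            class = c("wbs_stability", class(out)))
}

#' Two-group separation of fitted values
#'
#' Summarises whether the fitted piecewise-constant values concentrate around
#' two distinct levels — the signature of a process oscillating between two
#' signal values (e.g. a two-regime SETAR path), visible as bimodality in the
#' histogram of the fitted values. The values are split into two groups by an
#' exact one-dimensional two-means partition (the within-group sum of squares
#' is minimised over all threshold splits of the sorted values), and the
#' summary reports the two group centres, the pooled within-group spread
#' `sqrt(WSS/n)`, and the separation index `(centre_high - centre_low) /
#' within_spread`. This is a reproducible descriptive proxy, not a formal
#' hypothesis test: a unimodal Gaussian sample already scores about 2.6, so
#' the flag threshold defaults to 3.
#'
#' @param fitted Numeric vector of fitted values (length >= 2).
#' @param cap Value reported for the separation index when the within-group
#'   spread is exactly zero but the centres differ (default 1000).
#' @param flag_threshold Separation index above which `bimodal` is `TRUE`
#'   (default 3).
#' @return One-row tibble: `centre_low`, `centre_high`, `within_spread`,
#'   `separation`, `bimodal`. A constant input gives identical centres and
#'   separation 0.
#' @export
bimodality_summary <- function(fitted, cap = 1000, flag_threshold = 3) {
  check_series(fitted, arg = "fitted")
  v <- sort(fitted)
  n <- length(v)
  if (v[1] == v[n]) {
    return(tibble::tibble(centre_low = v[1], centre_high = v[1],
                          within_spread = 0, separation = 0, bimodal = FALSE))
  }
  cs <- cumsum(v)
  cq <- cumsum(v^2)
  i <- seq_len(n - 1)
  wss <- (cq[i] - cs[i]^2 / i) +
    ((cq[n] - cq[i]) - (cs[n] - cs[i])^2 / (n - i))
  best <- which.min(wss)
  c1 <- cs[best] / best
  c2 <- (cs[n] - cs[best]) / (n - best)
  within <- sqrt(max(wss[best], 0) / n)
  sep <- if (within == 0) cap else (c2 - c1) / within
  tibble::tibble(centre_low = c1, centre_high = c2, within_spread = within,
                 separation = sep, bimodal = sep > flag_threshold)
}
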