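#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a WBS2.SDLL fit
#'
#' @param x A `"wbs_sdll"` object.
#' @param ... Unused.
#' @return A tibble with one row per detected change-point: `changepoint`
#'   (last index of the left segment), `magnitude` (CUSUM magnitude at
#'   selection time), and the fitted levels `level_left`, `level_right` on
#'   either side. Zero detections give a zero-row tibble.
#' @export
tidy.wbs_sdll <- function(x, ...) {
  cp <- x$changepoints
  tibble::tibble(
    changepoint = cp,
    magnitude = x$path$magnitude[match(cp, x$path$location)],
    level_left = x$fitted[cp],
    level_right = x$fitted[pmin(cp + 1L, x$n_obs)]
  )
}

#' One-row summary of a WBS2.SDLL fit
#'
#' @inheritParams tidy.wbs_sdll
#' @return One-row tibble: `n_obs`, `q_hat`, `sigma_hat`, `zeta`, `variant`,
#'   `sampling`, `m_intervals`, `beta`.
#' @export
glance.wbs_sdll <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, q_hat = x$q_hat, sigma_hat = x$sigma_hat, zeta = x$zeta,
    variant = x$config$variant, sampling = x$config$sampling,
    m_intervals = x$config$m_intervals, beta = x$config$beta
  )
}

#' Per-observation view of a WBS2.SDLL fit
#'
#' @inheritParams tidy.wbs_sdll
#' @return Tibble with `t`, `value`, `.fitted`, `.segment` (segment id,
#'   `1..q_hat + 1`).
#' @export
augment.wbs_sdll <- function(x, ...) {
  seg <- cumsum(c(1L, seq_len(x$n_obs - 1L) %in% x$changepoints))
  tibble::tibble(t = seq_len(x$n_obs), value = x$x, .fitted = x$fitted,
                 .segment = seg)
}

#' @export
print.wbs_sdll <- function(x, ...) {
  cat(sprintf("WBS2.SDLL fit (%s variant, %s sampling, M = %d)\n",
              x$config$variant, x$config$sampling, x$config$m_intervals))
  cat(sprintf("  T = %d observations, sigma_hat = %.4g, zeta = %.4g\n",
              x$n_obs, x$sigma_hat, x$zeta))
  cat(sprintf("  q_hat = %d change-point%s\n", x$q_hat,
              if (x$q_hat == 1) "" else "s"))
  if (x$q_hat > 0 && x$q_hat <= 25) {
    cat("  locations:", paste(x$changepoints, collapse = ", "), "\n")
  } else if (x$q_hat > 25) {
    cat("  locations:", paste(x$changepoints[1:25], collapse = ", "), "...\n")
  }
  invisible(x)
}

#' @export
print.wbs_stability <- function(x, ...) {
  cat(sprintf("Change-point stability over %s runs (tol = %s):\n",
              if (nrow(x)) x$n_runs[1] else "?", attr(x, "tol")))
  NextMethod()
}
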