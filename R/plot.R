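#' Plot a WBS2.SDLL fit
#'
#' Data (points) with the piecewise-constant fit (step line) and detected
#' change-points (dashed verticals).
#'
#' @param object A `"wbs_sdll"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wbs_sdll <- function(object, ...) {
  d <- augment(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value),
                        colour = "grey40", size = 0.7, alpha = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$.fitted),
                       colour = "#b5651d", linewidth = 0.8)
  if (object$q_hat > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$changepoints + 0.5,
                                 linetype = "dashed", colour = "steelblue",
                                 alpha = 0.5)
  }
  p + ggplot2::labs(
    x = "t", y = "value",
    title = sprintf("WBS2.SDLL fit: %d change-point%s",
                    object$q_hat, if (object$q_hat == 1) "" else "s"),
    subtitle = sprintf("%s variant, %s sampling, zeta = %.3g",
                       object$config$variant, object$config$sampling,
                       object$zeta)
  )
}

#' Plot the sorted solution-path magnitudes
#'
#' The diagnostic view behind the steepest-drop selection: sorted CUSUM
#' magnitudes on a log scale against model size, with the threshold `zeta`
#' and the selected size marked. A well-separated problem shows a cliff at
#' the true number of change-points.
#'
#' @param fit A `"wbs_sdll"` object.
#' @param max_rank How many leading magnitudes to show (default
#'   `min(T - 1, 3 * q_hat + 30)`).
#' @return A ggplot.
#' @export
plot_solution_path <- function(fit, max_rank = NULL) {
  stopifnot(inherits(fit, "wbs_sdll"))
  mags <- fit$diagnostics$sorted_magnitudes
  if (is.null(max_rank)) max_rank <- min(length(mags), 3 * fit$q_hat + 30)
  d <- tibble::tibble(rank = seq_len(max_rank),
                      magnitude = pmax(mags[seq_len(max_rank)], .Machine$double.eps))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$magnitude)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = max(fit$zeta, .Machine$double.eps),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = fit$q_hat + 0.5, colour = "#b5651d") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "model size (sorted rank)", y = "CUSUM magnitude (log)",
                  title = sprintf("Solution path: steepest drop at q = %d",
                                  fit$q_hat))
}

#' Plot multi-run stability frequencies
#'
#' @param object A `"wbs_stability"` tibble from [stability_frequencies()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wbs_stability <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$location, y = .data$frequency)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$location, yend = 0),
                          colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "location", y = "detection frequency",
                  title = "Change-point stability across randomized runs")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
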