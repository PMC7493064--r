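#' Calibrate the universal threshold constant
#'
#' The universal threshold `zeta = const * sigma_hat * sqrt(2 log T)` governs
#' the no-detection rate on a constant signal, and shipped defaults for such
#' constants are known to deliver less than their advertised nominal rate.
#' This routine calibrates `const` by simulation: for each replicate a pure
#' standard-Gaussian series is generated, the full solution path built, and
#' the ratio `s_1 / (sigma_hat * sqrt(2 log T))` recorded, where `s_1` is the
#' largest path magnitude (the detector reports zero change-points exactly
#' when `s_1 < zeta`). The recommended constant is the `target_rate` empirical
#' quantile of these ratios, so that a fresh constant-signal series is flagged
#' change-point-free with probability close to `target_rate`.
#'
#' @param n_obs Series length the constant is calibrated for.
#' @param n_rep Number of simulation replicates.
#' @param target_rate Desired no-detection probability on a constant signal
#'   (in (0, 1), e.g. 0.90 or 0.95).
#' @param variant,sampling,m_intervals As in [wbs_sdll()].
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @return One-row tibble: `th_const` (recommended constant), `target_rate`,
#'   `n_obs`, `n_rep`, plus the shipped default `th_const_default` for
#'   comparison.
#' @export
calibrate_threshold <- function(n_obs = 500, n_rep = 200, target_rate = 0.95,
                                variant = c("standard", "robust"),
                                sampling = c("random", "grid"),
                                m_intervals = 100, seed = 1) {
  variant <- match.arg(variant)
  sampling <- match.arg(sampling)
  stopifnot(n_rep >= 10, target_rate > 0, target_rate < 1)
  scale_ref <- sqrt(2 * log(n_obs))
  ratios <- vapply(seq_len(n_rep), function(i) {
    withr::with_seed(seed + i, {
      x <- rnorm(n_obs)
      path <- wbs2_path(x, m_intervals = m_intervals, sampling = sampling,
                        variant = variant)
      s1 <- max(path$magnitude)
      sig <- if (variant == "robust") 1 else estimate_sigma(x)
      s1 / (sig * scale_ref)
    })
  }, numeric(1))
  tibble::tibble(th_const = as.numeric(quantile(ratios, target_rate)),
                 target_rate = target_rate, n_obs = as.integer(n_obs),
                 n_rep = as.integer(n_rep), th_const_default = 1.3)
}
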