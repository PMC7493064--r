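#' Piecewise-constant test signals
#'
#' Deterministic mean functions used throughout the simulation study:
#' `"constant"` (no change-points), `"step"` (one change at `floor(T/2)`),
#' `"teeth"` / `"extreme_teeth"` (alternation between 0 and `jump` every
#' `segment_length` points — the frequent-change-point regime; the extreme
#' flavour defaults to `segment_length = 5`), and `"custom"`
#' (explicit `breakpoints` and `levels`). A teeth signal of length `T` with
#' spacing `L` has `floor((T-1)/L)` change-points, at the multiples of `L`.
#'
#' @param signal One of `"constant"`, `"step"`, `"teeth"`, `"extreme_teeth"`,
#'   `"custom"`.
#' @param n_obs Signal length `T`.
#' @param jump Level amplitude for `step`/`teeth` (default 1).
#' @param segment_length Tooth width for the teeth signals (defaults: 50 for
#'   `"teeth"`, 5 for `"extreme_teeth"`).
#' @param level Constant level for `"constant"` (default 0).
#' @param breakpoints,levels For `"custom"`: ascending change-point locations
#'   (each in `1..T-1`) and the `length(breakpoints) + 1` segment levels.
#' @return Numeric vector of length `n_obs`.
#' @examples
#' make_signal("teeth", 10, jump = 1, segment_length = 5)
#' @export
make_signal <- function(signal = c("constant", "step", "teeth",
                                   "extreme_teeth", "custom"),
                        n_obs, jump = 1, segment_length = NULL, level = 0,
                        breakpoints = NULL, levels = NULL) {
  signal <- match.arg(signal)
  n_obs <- as.integer(n_obs)
  stopifnot(n_obs >= 1L)
  switch(signal,
    constant = rep(level, n_obs),
    step = {
      b <- max(1L, n_obs %/% 2L)
      c(rep(0, b), rep(jump, n_obs - b))
    },
    teeth = ,
    extreme_teeth = {
      if (is.null(segment_length)) {
        segment_length <- if (signal == "extreme_teeth") 5L else 50L
      }
      segment_length <- as.integer(segment_length)
      stopifnot(segment_length >= 1L)
      jump * ((((seq_len(n_obs) - 1L) %/% segment_length) %% 2L))
    },
    custom = {
      if (is.null(levels) || length(levels) != length(breakpoints) + 1L) {
        abort("`custom` needs `levels` of length `length(breakpoints) + 1`.",
              class = "wbs2sdll_input_error")
      }
      bp <- as.integer(breakpoints)
      if (length(bp) && (is.unsorted(bp, strictly = TRUE) ||
                         bp[1] < 1L || bp[length(bp)] > n_obs - 1L)) {
        abort("`breakpoints` must be strictly ascending and lie in 1..T-1.",
              class = "wbs2sdll_input_error")
      }
      rep(levels, times = diff(c(0L, bp, n_obs)))
    })
}

#' Ground-truth change-points of a deterministic signal
#'
#' @param f Numeric signal vector.
#' @return Integer locations `b` where `f[b + 1] != f[b]`.
#' @export
true_changepoints <- function(f) {
  which(diff(f) != 0)
}

#' Add noise to a signal
#'
#' Generates `X_t = f_t + e_t` where the noise `e_t` is serially independent
#' with median zero: Gaussian, scaled Student-t (heavy tails for small `df`),
#' Cauchy, or Gaussian with a time-varying scale schedule
#' (`heteroskedastic_gaussian`, `sigma` given as a positive length-`T` vector).
#'
#' @param f Numeric signal.
#' @param family Noise family.
#' @param sigma Scale: a scalar, or a positive length-`T` schedule for the
#'   heteroskedastic family.
#' @param df Degrees of freedom for `student_t` (default 3; `df = 2` has
#'   infinite variance, `df = 1` is Cauchy).
#' @param seed Optional integer seed (local; caller's RNG state untouched).
#' @return Numeric series of the same length as `f`.
#' @export
add_noise <- function(f, family = c("gaussian", "student_t", "cauchy",
                                    "heteroskedastic_gaussian"),
                      sigma = 1, df = 3, seed = NULL) {
  family <- match.arg(family)
  n <- length(f)
  if (family == "heteroskedastic_gaussian") {
    if (length(sigma) != n || any(sigma <= 0)) {
      abort("heteroskedastic `sigma` must be a positive schedule of length T.",
            class = "wbs2sdll_input_error")
    }
  } else {
    stopifnot(length(sigma) == 1L, sigma >= 0)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  eps <- switch(family,
    gaussian = rnorm(n, sd = 1),
    student_t = rt(n, df = df),
    cauchy = rcauchy(n),
    heteroskedastic_gaussian = rnorm(n, sd = 1))
  f + sigma * eps
}

#' Simulate a signal-plus-noise series as a tibble
#'
#' Convenience wrapper pairing [make_signal()] and [add_noise()] for piped
#' workflows and the command-line `simulate` subcommand.
#'
#' @inheritParams make_signal
#' @inheritParams add_noise
#' @param ... Passed on to [make_signal()].
#' @return Tibble with columns `t`, `signal`, `value`.
#' @examples
#' simulate_series("teeth", 100, segment_length = 10, jump = 3, seed = 1)
#' @export
simulate_series <- function(signal, n_obs, ..., family = "gaussian",
                            sigma = 1, df = 3, seed = NULL) {
  f <- make_signal(signal, n_obs, ...)
  x <- add_noise(f, family = family, sigma = sigma, df = df, seed = seed)
  tibble::tibble(t = seq_along(f), signal = f, value = x)
}

#' Simulate a two-regime SETAR path
#'
#' A self-exciting threshold autoregression:
#' `X_t = a1 * X_{t-1} + c1 + e_t` when `X_{t-1} <= r`, and
#' `X_t = a2 * X_{t-1} + c2 + e_t` otherwise, with `X_0 = 0` and Gaussian
#' innovations. With the defaults each regime is stationary with well
#' separated attracting means `c1/(1-a1) = -2` and `c2/(1-a2) = +2`, and the
#' innovation scale is large enough that the path switches regime a handful of
#' times per 500 observations, so it genuinely oscillates between two signal
#' levels rather than settling in one. These defaults are synthetic stand-ins
#' chosen for that qualitative behaviour, not estimates from any dataset.
#'
#' @param n_obs Path length.
#' @param a1,c1 Slope and intercept in the lower regime (`|a1| < 1`).
#' @param a2,c2 Slope and intercept in the upper regime (`|a2| < 1`).
#' @param r Regime threshold on the lagged value.
#' @param noise_sd Innovation standard deviation (default 1).
#' @param seed Optional integer seed (local).
#' @return Numeric path of length `n_obs`.
#' @export
setar_path <- function(n_obs, a1 = 0.5, c1 = -1, a2 = 0.5, c2 = 1, r = 0,
                       noise_sd = 1, seed = NULL) {
  n_obs <- as.integer(n_obs)
  stopifnot(n_obs >= 1L, noise_sd >= 0)
  if (abs(a1) >= 1 || abs(a2) >= 1) {
    abort("both regimes must be stationary: |a1| < 1 and |a2| < 1.",
          class = "wbs2sdll_input_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  eps <- rnorm(n_obs, sd = noise_sd)
  x <- numeric(n_obs)
  prev <- 0
  for (t in seq_len(n_obs)) {
    x[t] <- if (prev <= r) a1 * prev + c1 + eps[t] else a2 * prev + c2 + eps[t]
    prev <- x[t]
  }
  x
}

#' Simulate a Gaussian random walk
#'
#' @param n_obs Path length.
#' @param step_sd Standard deviation of the i.i.d. Gaussian increments.
#' @param seed Optional integer seed (local).
#' @return Numeric path (cumulative sum of the increments).
#' @export
random_walk <- function(n_obs, step_sd = 1, seed = NULL) {
  n_obs <- as.integer(n_obs)
  stopifnot(n_obs >= 1L, step_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  cumsum(rnorm(n_obs, sd = step_sd))
}

#' Synthetic epidemic-shaped daily-count series
#'
#' A seeded generator emulating the shape of a daily epidemic count series:
#' a gamma-shaped trend rising to a peak (default near day 32) followed by a
#' slow decay, multiplied by a period-7 seasonal profile (weekday reporting
#' effect) and by multiplicative log-normal noise, rounded to non-negative
#' counts. Entirely synthetic — no real surveillance data are used.
#'
#' @param n_obs Series length in days.
#' @param peak_time Day of the trend maximum.
#' @param peak_level Trend value at the peak.
#' @param noise_sd Standard deviation of the multiplicative log-normal noise.
#' @param seed Optional integer seed (local).
#' @return Tibble with columns `t`, `trend`, `value`.
#' @export
sim_epidemic_series <- function(n_obs = 150, peak_time = 32, peak_level = 900,
                                noise_sd = 0.08, seed = NULL) {
  stopifnot(n_obs >= 14, peak_time >= 1, peak_level > 0, noise_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  t <- seq_len(n_obs)
  shape <- 4
  trend <- peak_level * (t / peak_time)^shape * exp(shape * (1 - t / peak_time))
  weekly <- c(0.75, 0.85, 1.00, 1.10, 1.20, 1.15, 0.95)
  season <- weekly[((t - 1) %% 7) + 1]
  value <- round(trend * season * exp(rnorm(n_obs, sd = noise_sd)))
  tibble::tibble(t = t, trend = trend, value = pmax(value, 0))
}
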