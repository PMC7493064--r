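# wbs2sdll

Change-point detection for univariate series that works in **both infrequent
and frequent change-point regimes**, built from two decoupled ingredients:

* **WBS2** (Wild Binary Segmentation 2): a recursion that, on each current
  segment, maximises the CUSUM contrast
  `C(b) = sqrt(nL*nR/n) * (mean_left - mean_right)` over many random (or
  deterministically gridded) sub-intervals, records the winning split, and
  recurses on both sides until a **complete solution path** of all `T - 1`
  candidate change-points is built — so the nested models with
  `0, 1, ..., T-1` change-points are all available.
* **SDLL** (Steepest Drop to Low Levels): model selection that picks the
  model size at the steepest drop in the sorted candidate magnitudes
  `s_1 >= s_2 >= ...`, among sizes whose drop starts above `beta * zeta` and
  lands below the threshold `zeta = lambda * sigma_hat * sqrt(2 log T)`.
  Thresholding enters only as a secondary check (`q_hat = 0` iff
  `s_1 < zeta`), not as a penalty — which is why the procedure does not
  break down when change-points are dense.

Also included: a **robust variant** (CUSUMs of `sign(x - median)` per
interval, for heavy-tailed or arbitrarily heteroskedastic median-zero noise),
threshold **calibration** by simulation, **multi-run stability frequencies**
(how often each change-point is re-detected across randomized runs — an
empirical significance measure), a **two-regime separation summary** of the
fitted values, synthetic-data generators (piecewise-constant signals, SETAR
paths, random walks, an epidemic-shaped demo series) and evaluation metrics
(signed count error, Hausdorff distance).

Who this is for: anyone segmenting means/medians of noisy sequences —
epidemic surveillance counts, genomic coverage or copy-number-like profiles,
sensor drift — especially when the number of segments may be large and
unknown.

## Worked example

A "teeth" signal of length 500 alternating between 0 and 4 every 5 points
has 99 change-points — the frequent-change regime where penalty-based
selection fails:

```r
library(wbs2sdll)

d <- simulate_series("teeth", n_obs = 500, segment_length = 5, jump = 4,
                     family = "gaussian", sigma = 1, seed = 42)
fit <- wbs_sdll(d, column = "value", seed = 1)
fit
#> WBS2.SDLL fit (standard variant, random sampling, M = 100)
#>   T = 500 observations, sigma_hat = 1.29, zeta = 5.685
#>   q_hat = 100 change-points
#>   locations: 5, 10, 15, 20, 24, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, ...
```

The detector reports 100 change-points against the true 99 (one spurious
candidate at this seed), each at (or within one index of) a multiple of 5.
`glance()`, `tidy()` and `augment()` expose the fit broom-style, and
`autoplot(fit)` / `plot_solution_path(fit)` draw the fit and the sorted
magnitude profile with the selected drop:

```r
glance(fit)
#> # A tibble: 1 × 8
#>   n_obs q_hat sigma_hat  zeta variant  sampling m_intervals  beta
#>   <int> <int>     <dbl> <dbl> <chr>    <chr>          <int> <dbl>
#> 1   500   100      1.29  5.68 standard random           100   0.5

tidy(fit)
#> # A tibble: 100 × 4
#>   changepoint magnitude level_left level_right
#>         <int>     <dbl>      <dbl>       <dbl>
#> 1           5      6.66      0.441       4.65
#> 2          10      6.39      4.65        0.358
#> 3          15      5.36      0.358       3.31
#> # ℹ 97 more rows

count_error(fit$changepoints, true_changepoints(d$signal))
#> [1] 1
hausdorff_dist(fit$changepoints, true_changepoints(d$signal), 500)
#> [1] 1
```

Here `sigma_hat` is the MAD of first differences (Gaussian-consistent) and
`zeta` the calibrated universal threshold; a change-point at `b` means the
level may differ between `t <= b` and `t >= b + 1` (1-based, `b` is the last
index of the left segment).

Because random interval sampling makes runs differ, re-running the detector
many times turns that randomness into a significance measure — the fraction
of runs in which each change-point is re-detected:

```r
x <- make_signal("custom", 200, breakpoints = c(70, 140), levels = c(0, 5, 0)) +
  withr::with_seed(7, rnorm(200))
stability_frequencies(x, n_runs = 20, seed = 1)
#> Change-point stability over 20 runs (tol = 2):
#> # A tibble: 12 × 3
#>    location frequency n_runs
#>  *    <dbl>     <dbl>  <int>
#>  2        9      1        20
#>  3       15      1        20
#>  4       70      1        20
#>  6      140      1        20
#> 10      183      0.6      20
#> # ... low-frequency clusters omitted
```

The two genuine change-points (70, 140) are found in every run; spurious
locations appear only sporadically. (This seed's noise also contains a
level-like excursion around 9–15 that is consistently detected — stability
separates it from one-off artefacts.) Deterministic alternatives:
`sampling = "grid"` gives bit-identical fits across runs, and
`sampling = "exhaustive"` searches all sub-intervals (used automatically on
short segments).

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wbs2sdll.R", package = "wbs2sdll"))')
Rscript $CLI simulate --kind signal --signal teeth --T 500 --segment-length 5 \
  --jump 4 --seed 42 --output series.csv
Rscript $CLI detect --input series.csv --column value --seed 1 --output fit.json
Rscript $CLI calibrate --T 500 --reps 200 --rate 0.90
Rscript $CLI stability --input series.csv --column value --runs 20
```

Exit codes: 0 success, 2 input error, 3 configuration error.

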