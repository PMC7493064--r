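---
title: "Detecting possibly frequent change-points: methodology and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting possibly frequent change-points: methodology and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 4)
set.seed(1)
```

```{r}
library(wbs2sdll)
```

## The model and the problem

The package estimates change-points in the level of a univariate series
under the signal-plus-noise model

$$X_t = f_t + \varepsilon_t, \qquad t = 1, \dots, T,$$

where $f$ is piecewise constant and the noise is serially independent. The
standard variant assumes the noise has (at least approximately) a common
scale and targets changes in the *mean* of $f$; the robust variant only
assumes the noise has median zero — no moment conditions, arbitrary
heterogeneity — and targets changes in the *median*.

The difficulty the package is built around is the *frequent* change-point
regime: when segments are short, classical binary segmentation and
penalty-based model selection (BIC-type penalties in particular) degrade
badly, because no single penalty works across both infrequent and frequent
regimes. The approach here combines two ingredients that are deliberately
decoupled:

1. **WBS2** (Wild Binary Segmentation 2) produces a *complete solution
   path*: an ordering of all $T-1$ candidate change-points, so that the
   nested models with $0, 1, \dots, T-1$ change-points are all available and
   no model size is ruled out in advance.
2. **SDLL** (Steepest Drop to Low Levels) picks the model size by the shape
   of the sorted candidate magnitudes, using a threshold only as a secondary
   check — not as a penalty.

## The CUSUM contrast

All candidate evaluation uses the CUSUM contrast on an interval
$[s, e]$ of length $n = e - s + 1$ at a split $b$:

$$C(b) = \sqrt{\tfrac{e-b}{n(b-s+1)}}\sum_{t=s}^{b} X_t \;-\;
         \sqrt{\tfrac{b-s+1}{n(e-b)}}\sum_{t=b+1}^{e} X_t
       \;=\; \sqrt{\tfrac{n_L n_R}{n}}\,(\bar X_L - \bar X_R).$$

It is invariant to adding a constant and equivariant to rescaling, and under
a constant mean with unit-variance Gaussian noise each $C(b)$ is standard
normal. Internally the kernel (C++) evaluates the *mean form* on the right:
it is algebraically identical to the sum form, and it returns an exact
floating-point zero on constant segments, which keeps tie-breaking and the
noiseless degenerate path exactly reproducible.

## WBS2: the complete solution path

On each current segment $[s, e]$ (starting from $[1, T]$) the recursion

* draws candidate sub-intervals — `m_intervals` (default $M = 100$) of them,
  either uniformly at random or from a deterministic grid; whenever the
  segment is short enough that $n(n-1)/2 \le M$, *all* sub-intervals are used
  instead, for every sampling mode (nothing is gained by sampling there, and
  it removes needless randomness on short segments);
* maximises $|C(b)|$ over every interval and split, breaking ties to the
  smallest split and then to the shortest source interval;
* records the winner and recurses on $[s, b]$ and $[b+1, e]$ ($b$ belongs to
  the left child) until only singleton segments remain.

Each series of length $T$ yields exactly $T-1$ recorded candidates. $M$ is
re-drawn in full on every segment (subject to the exhaustive fallback); we
found no reason to scale it down with depth, and the exhaustive fallback
already bounds the work on small segments. Random start/end points are drawn
independently with replacement across the $M$ draws, redrawing degenerate
pairs so that every interval admits a split.

The **deterministic grid** takes $k$ equispaced points
$g_i = s + \mathrm{round}(i\,\delta\,(e-s))$, $i = 0, \dots, k-1$, with $k$
the smallest integer such that $k(k-1)/2 \ge M$ and $\delta = 1/(k-1)$, and
uses all pairs of grid points. Rounding is half-away-from-zero (platform
independent) and collided grid points are deduplicated, so on short segments
the interval count can fall below $M$ — the exhaustive fallback usually takes
over before this matters. Grid (and exhaustive) fits are bit-identical across
runs; random-mode fits are bit-identical given a seed.

With random sampling a child's winning magnitude can exceed its parent's, so
the path is re-sorted globally by magnitude (stably, preserving detection
order among exact ties) before model selection; the sorted prefixes are the
nested model sequence.

## SDLL: model selection by the steepest drop

Let $s_1 \ge s_2 \ge \dots$ be the sorted magnitudes with a sentinel $0$
appended, and let $\zeta$ be the threshold. The rule implemented by
`sdll_select()` is:

* if $s_1 < \zeta$: no change-points (this is the *secondary check* — the
  only place thresholding decides anything by itself);
* otherwise, over the candidate set
  $J = \{\, j : s_j \ge \beta\zeta \text{ and } s_{j+1} < \zeta \,\}$
  — drops that *start* at a non-negligible magnitude and *land at low
  levels*, below the significance threshold — return the $j$ with the
  steepest log-drop $\log s_j - \log s_{j+1}$ (a drop onto an exact zero is
  infinite; ties go to the smallest $j$);
* if $J$ is empty (possible only for $\beta > 1$): plain thresholding,
  $\max\{ j : s_j \ge \zeta \}$.

The log-ratio rather than the raw difference measures the drop, so the
selection is invariant to rescaling the data.

**Why the candidate set has two different bars.** A one-bar rule — selectable
sizes must themselves exceed $\zeta$ — collapses to plain thresholding, and
thresholding is exactly what fails in frequent-change regimes: with
$T = 500$, spacing $5$ and jumps of $4\sigma$, a sizeable share of the
*true* change-point magnitudes falls below any $\zeta$ that also controls
false detections (the sorted-magnitude profile crosses $\zeta$ in the middle
of the genuine candidates, while the steepest log-drop sits precisely at the
true model size). Separating the two roles — $\beta\zeta$ as the floor where
a drop may *start*, $\zeta$ as the level it must *land* below — lets the
steepest drop be found below the threshold without ever abandoning the
secondary check. The default $\beta = 0.5$ keeps the candidate range well
clear of the noisy far tail of tiny magnitudes (whose log-ratios are large
but meaningless); $\beta = 1$ recovers pure thresholding. This candidate-set
construction is this package's own operationalization of the
steepest-drop idea, and the `teeth` simulations in the test suite are the
evidence for it.

## The threshold and its calibration

The default threshold is the universal form
$\zeta = \lambda\, \hat\sigma\, \sqrt{2 \log T}$ with
$\hat\sigma = \mathrm{median}(|X_{t+1} - X_t|) / (\sqrt{2}\cdot 0.6744898)$,
the Gaussian-consistent MAD of first differences: differencing removes a
piecewise-constant mean everywhere except at the (sparse) change-points, and
the median ignores those.

Shipped constants of this kind are known to under- or over-deliver their
advertised confidence level, so the constant is *calibrated, not assumed*:
`calibrate_threshold()` simulates constant-signal series, records the ratio
$s_1 / (\hat\sigma\sqrt{2\log T})$ per replicate (the detector reports zero
change-points exactly when $s_1 < \zeta$), and returns the empirical
`target_rate` quantile. The shipped default $\lambda = 1.25$ is the rounded
output of `calibrate_threshold(n_obs = 500, n_rep = 500, target_rate = 0.925,
seed = 10)` (targeting the middle of the 90–95% band); the acceptance test
re-runs the calibration at a 90% target and verifies the achieved
no-detection rate on fresh replicates.

The alternative form `"sqrt3logT-slack"`,
$\zeta = \sigma (1 + \delta) \sqrt{3 \log T}$, implements the asymptotic
bound on the absolute CUSUMs of *all* sub-intervals of a constant-mean
Gaussian series (valid for any slack $\delta > 0$). Being asymptotic, it is
not exact at moderate lengths: at $T = 1000$ with $\delta = 0.1$ the test
suite measures the bound holding in roughly 98–99% of replicates (just short
of a 99% working level), which is worth knowing before using it as a hard
guarantee.

**Degenerate noiseless input.** If $\hat\sigma = 0$ (an exactly
piecewise-constant series), $\zeta = 0$ and the selection switches to
counting the strictly positive magnitudes, which recovers the signal exactly
in exhaustive mode: within constant stretches every contrast is exactly zero
(mean-form kernel), and positive magnitudes occur only at true change-points.

## The robust variant — and its limits

The robust variant replaces, on every candidate interval, the data by
$\mathrm{sign}(X_t - \mathrm{median}(X_{s:e}))$ — the median recomputed per
interval, the even-length median the mean of the two central order
statistics, and $\mathrm{sign}(0) = 0$ — and applies the same CUSUM,
recursion and selection. Sign-transformed data have unit-order scale by
construction, so $\sigma$ is fixed at 1 for thresholding; fitted values are
segment *medians*. This needs no moment conditions: a single-step signal
under Cauchy noise is handled cleanly (see the test suite).

The transform buys robustness at a hard price in resolution: on an interval
spanning one change at spacing $L$, the sign-CUSUM magnitude is at most
$\sqrt{2L}$ (all signs $\pm 1$, balanced split), while the *null* maximum of
the sign-CUSUM over the sampled sub-intervals of a length-$T$ series grows
like $\sqrt{2\log T}$. For $T = 500$ and $L = 5$ the cap is
$\sqrt{10} \approx 3.16$, *below* the typical null maximum (~3.5), so no
threshold can give the robust variant both false-positive control and power:
the secondary check then reports zero change-points. This is a property of
the sign transform itself, not of the implementation, and it is why the
dedicated heavy-tail acceptance experiment (t2 noise on spacing-5 teeth)
shows the robust variant losing to the standard one there. The robust
variant is the right tool for heavy tails and heteroskedasticity when
spacings are comfortably larger than $\log T$; it is the wrong tool for
extreme-frequency regimes.

## Sharpness of a CUSUM peak (optional diagnostic)

Candidates whose $|C|$ falls off steeply on both sides of the maximiser are
the best localisers (a CUSUM computed over a stretch containing a single
change-point always has this shape). `sharpness_score()` compares the decay
of the *squared* contrast at offsets $1..h$ against a triangular reference
reaching zero at offset $h$, clipped to $[0, 1]$. The squared contrast is
used because it, unlike $|C|$ itself, decays at least at the triangular rate
for an exact single step — with $|C|$ the score of a clean step would be
about 0.76 rather than 1, making the scale awkward to interpret. Offsets
beyond the admissible split range count as zero contrast. The score is a
diagnostic only; it is never applied as a filter by default, because
restricting the path to sharp candidates would shrink the very drop that
SDLL relies on.

## Multi-run stability and regime summaries

With random sampling, repeated runs differ — and that is usable information
rather than a defect: `stability_frequencies()` reruns the detector with
seeds `seed + 1..seed + K`, pools all detected locations, single-linkage
clusters them at distance `tol` (default `max(1, round(0.01 T))`, a
scale-free matching window), and reports each cluster's median location and
the fraction of runs contributing to it — an empirical significance measure
for each change-point, in the spirit of stability selection. It refuses
grid/exhaustive sampling, where every run is identical and the frequency
would be vacuously 0 or 1.

`bimodality_summary()` supports the model-misspecification use case: when
the detector is applied to data that actually oscillate between two regimes
(e.g. a two-regime SETAR path), the *fitted* values concentrate around two
levels even though the raw data show no visible bimodality. The summary
splits the fitted values by an exact one-dimensional two-means partition
(minimising within-group sum of squares over all threshold splits of the
sorted values — deterministic, no iterative seeding) and reports the two
centres, the pooled within-group spread $\sqrt{WSS/n}$, and their ratio. A
unimodal Gaussian sample already scores about 2.6 on this index (two-means
always splits *something*), so the `bimodal` flag defaults to a threshold of
3; an exactly two-valued input has zero within-spread and reports the
configured cap (default 1000). This is a reproducible descriptive proxy, not
a hypothesis test.

Hausdorff distance and the signed count error are the evaluation metrics;
with exactly one of the two location sets empty the Hausdorff distance is
defined as $T$ (detections are legitimately empty by design, so the
convention must be explicit), and with both empty it is 0.

## Synthetic data: what is and is not emulated

* `make_signal()` builds the deterministic means: constant, single step,
  and `teeth`/`extreme_teeth` (alternation between 0 and `jump` every
  `segment_length` points — the frequent-change regime; spacing 5 puts
  $\lfloor (T-1)/5 \rfloor = 99$ change-points in a series of length 500).
  Ground truth is exactly recoverable via `true_changepoints()`.
* `add_noise()` supplies Gaussian, Student-t (df 2 = infinite variance),
  Cauchy and schedule-driven heteroskedastic Gaussian noise, all serially
  independent with median zero.
* `setar_path()` simulates a two-regime self-exciting threshold
  autoregression: $X_t = 0.5 X_{t-1} - 1 + \varepsilon_t$ below the
  threshold $r = 0$, $X_t = 0.5 X_{t-1} + 1 + \varepsilon_t$ above, with
  attracting means $\mp 2$. The innovation scale defaults to 1.0: a regime
  switch then requires a $2\sigma$ innovation (probability ≈ 0.023 per
  step, ≈ 11 expected switches per 500 observations), so paths genuinely
  oscillate between the two levels with persistent regimes. A scale of 0.5
  would make a switch a $4\sigma$ event and freeze the path in its first
  regime for the whole sample, defeating the purpose of the generator.
  These parameters are synthetic stand-ins chosen for that qualitative
  behaviour, not estimates from any dataset.
* `random_walk()` provides the second misspecification benchmark, and
  `sim_epidemic_series()` a synthetic epidemic-shaped daily-count series
  (gamma-shaped trend peaking near day 32, period-7 multiplicative
  seasonality, log-normal noise) for demonstrations; no real surveillance
  data are fetched or shipped.

What the generators do **not** emulate: autocorrelated noise beyond the
SETAR/random-walk misspecification cases (thresholds based on long-run
variance are out of scope), trends or smooth signals, multivariate series.
Tests passing on these generators therefore say nothing about, e.g.,
strongly autocorrelated data, where the i.i.d.-calibrated threshold is
anti-conservative.

## Numerical conventions, in one place

* Indices are 1-based; a change-point at $b$ means the level may differ
  between $t \le b$ and $t \ge b+1$ ($b$ is the last index of the left
  segment).
* Ties: smallest split, then shortest source interval (recursion); smallest
  $j$ (SDLL); detection order preserved among exact magnitude ties (sort).
* Grid rounding: half away from zero; grid points deduplicated.
* Strict input handling: non-numeric entries, missing values and embedded
  blank lines are errors, never imputed; series must have $T \ge 2$ and be
  finite throughout.
* Problem sizes in the test suite and acceptance script (chosen to exercise
  the full study designs): specificity at $T = 500$ with 500 replicates,
  teeth recovery and the heavy-tail comparison at $T = 500$ with 100
  replicates each, the no-change bound at $T = 1000$ with 200 replicates and
  $10^4$ sampled intervals, SETAR at $T = 500$ over 50 seeds.

## Known limitations

* WBS2 always records the largest available CUSUMs, which are not the best
  localisers; no localisation-rate guarantee is claimed. The sharpness score
  exists as a refinement hook, not as a default.
* The robust variant cannot resolve spacings at or below the $\log T$ scale
  (see above) — by construction, not by accident.
* The $\sqrt{3\log T}$ bound is asymptotic; do not treat the 99% working
  level as exact at moderate $T$.
* Thresholds assume serially independent noise. For autocorrelated errors
  the calibrated constant is invalid; this is deliberately out of scope.
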