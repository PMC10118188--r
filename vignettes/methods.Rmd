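---
title: "Methods: multi-route BACI inference for paired watershed studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-route BACI inference for paired watershed studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streambaci)
```

# Overview

`streambaci` answers one question three ways: *did a stream response
change from the pre-impact to the post-impact period, and in which
treatment groups or watersheds?* The three routes — a distributional
test (KS2), a mean-comparison by bootstrap CI overlap (BCa), and a
factorial latent-variable regression (PLS) with resampling-based
significance — make different assumptions and fail differently, so
agreement among them is far stronger evidence than any single p-value.
None of the routes assumes normally distributed data or homoscedastic
errors, which matters for small, skewed, spatially structured field
samples.

The analysis unit is the **site-year mean**: replicate measurements
(e.g. four epilithon composites per site-year) are averaged first, so a
site contributes one value per year and composite pseudo-replication is
avoided. Replicate-level analysis is available via
`analysis_config(unit = "replicate")`, but nothing in the package
asserts it as the preferred choice.

# Route 1: two-sample Kolmogorov–Smirnov

For each group, the pre-period and post-period site-year values are
compared through $D = \sup_x |F_{pre}(x) - F_{post}(x)|$. Two p-value
engines are implemented:

* **Exact** (used when $n \cdot m \le 10{,}000$): the permutation null
  conditional on the observed tie pattern, counted by a dynamic program
  over blocks of tied pooled values. All boundary deviations are kept as
  integers ($|i m - j n|$), so there is no floating-point ambiguity in
  "$D^* \ge D_{obs}$", and ties are handled exactly.
* **Asymptotic**: the Kolmogorov series
  $Q(\lambda) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$ with
  $\lambda = \sqrt{nm/(n+m)}\,D$.

The suite checks that the two engines agree within 0.01 at
$n = m = 50$ and that the exact engine reproduces brute-force
enumeration over all $\binom{n+m}{n}$ label assignments on small
fixtures, ties included.

# Route 2: BCa bootstrap and the non-overlap rule

95% BCa intervals for the pre- and post-period group means use the
standard bias correction $z_0 = \Phi^{-1}(\#\{\bar{x}^*_b <
\bar{x}\}/B)$ and the jackknife-skewness acceleration
$a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$, $d_i = \bar\theta_{(\cdot)} -
\theta_{(i)}$. The change code is `increase` iff the post interval lies
strictly above the pre interval, `decrease` iff strictly below, else
`0`; intervals touching at a point count as overlapping. The rule is
deliberately conservative — its simulated type-I error under identical
lognormal distributions is well below 0.05 (tested) — which is the
point: a flagged change survives a conservative filter.

Defaults: $B = 10{,}000$ resamples (the method's source is silent; this
is large enough that interval endpoints are stable to ~1% of interval
width), mandatory seed in the API. A zero-variance sample yields the
degenerate interval $[\bar x, \bar x]$ with a warning rather than an
error, so constant attributes cannot abort a multi-attribute run.

# Route 3: PLS factorial regression

## Design and fit

Categorical factors are dummy-coded with the **last level deleted**; for
the 4-level treatment × 2-level period factorial this gives
$3 + 1 + 3 = 7$ columns, for the 12-watershed design $11 + 1 + 11 = 23$.
Regressors and response are centered and scaled. The fit is univariate
PLS1 (NIPALS; identical to SIMPLS for a single response, and verified at
full rank against least squares to $10^{-8}$). PLS is used instead of
OLS because the factorial columns plus interactions are strongly
correlated and the latent-variable path gives a principled way to stop
short of the noise.

## Model selection

Leave-one-out cross-validation (centering/scaling re-estimated inside
every fold) produces RMSECV and R²CV curves over $k = 1..k_{max}$. The
selection rule operationalizes "a notable change in slope, usually at or
near the minimum": the smallest $k$ whose relative improvement to
$k+1$ drops to $\tau$ (default 0.02) or below, capped at the global
minimum. $\tau$ is exposed in `analysis_config()` and the full curve is
stored in every report so any other rule can be audited. Models with
R²CV at or below the suppression floor (default 0) are never used for
significance reporting; the panel shows `--` and the diagnostics keep
the fit.

## Box-Cox search

A response transform $y^{(\lambda)} = (y^\lambda - 1)/\lambda$ (log at
$\lambda = 0$; non-positive data get an automatic shift
$|\min y| + \varepsilon$) is profiled over a dense grid
$\lambda \in \{-2.0, -1.9, \dots, 3.0\}$, maximizing the R²CV of the
selected-$k$ model. R²CV is unit-free, which is what makes it
comparable across exponents. The identity is retained unless a
candidate beats it by more than 0.01 R²CV — without this margin the
search chases cross-validation noise (directly observable in tests: at
moderate noise a spurious exponent can "win" by ~0.02 through the
interaction with the $k$-selection rule). A real-coded genetic
algorithm over the same range (population 30, 50 generations,
tournament selection) is available as an alternative optimizer; the
grid is the reference. $\lambda$ is selected once on the full data and
frozen inside LOO folds and resampling refits — re-selecting per fold
is statistically defensible but makes the search objective unstable,
and is therefore not done.

Letter comparisons of cell predictions are made **on the Box-Cox
scale**; back-transformed predictions are reported alongside for
interpretation.

## Degrees of freedom

PLS fitted values after $m$ components are the projection of $y$ onto
the Krylov space $\mathrm{span}\{Ay, A^2y, \dots, A^my\}$, $A = XX'$
(centered/scaled data). Because the space itself depends on $y$, each
latent variable costs more than one least-squares degree of freedom.
The package computes $\mathrm{DoF} = 1 + \mathrm{tr}(\partial\hat
y/\partial y)$ by propagating the exact analytic Jacobian through the
Arnoldi recursion that builds the basis — the unbiased trace estimate
of the Krylov formulation — with the response-scaling constant treated
as fixed (the $+1$ accounts for centering). At $k = \mathrm{rank}(X)$
this collapses to $p + 1$, and a finite-difference oracle reproduces it
to $10^{-4}$ on fixtures. The diagonal of the same Jacobian supplies
the linearized leverage $h_i$ used by both resampling procedures; at
full rank it equals the OLS hat diagonal (tested).

## Wu jackknife

"Full cross validation" is interpreted as delete-one refits of the
entire fixed-structure pipeline ($k$ and $\lambda$ frozen at their
full-data selections). The default variance estimator is the
leverage-weighted form
$v_r = \sum_i (1 - h_i)(\hat\beta_{(i)r} - \hat\beta_r)^2$, which for
OLS reduces to a HC-type sandwich; the unweighted delete-one variant is
available (`weighted = FALSE`) and the report records which was used,
since the original label does not pin down the weighting. The t
statistic is referred to Student-t with $n - \mathrm{DoF}$ degrees of
freedom — the df convention is not dictated by any source and is the
natural choice given the DoF estimate above. Re-running $k$/$\lambda$
selection inside each deletion is deliberately not the default: it is
costly and makes the deleted fits non-comparable.

## Wild bootstrap (HC3)

Residuals are rescaled by $(1 - h_i)^{-1}$, multiplied by Rademacher
signs (Mammen's two-point distribution available), added to the fitted
values, and the pipeline is refit per resample (2000 by default).
Percentile 95% intervals are reported for every coefficient (significant
iff the interval excludes zero) and for every factor-cell prediction.
Cell CIs need not be centered on the point prediction — PLS is
nonlinear in $y$, so the resampled predictions can be shifted relative
to the full-data fit; this is a property of the method, not a bug.

## Letter displays

Compact letters are assigned by insert-and-absorb over the pairwise
relation "CIs intersect" (touching counts as intersecting,
conservative). "A" is attached to the cell with the largest prediction
on the Box-Cox scale; the alphabet extends AA, AB, … past 26 groups
(the watershed design has 24 cells). Every generated display is
post-hoc asserted to satisfy *share-a-letter ⇔ CIs intersect*; a
violation is a hard error, never silent.

# The synthetic generator: what it emulates, what it does not

`default_trask_design()` states one world and the tests live in it:

* 12 headwater watersheds in 4 catchments (3 clearcut-variable,
  3 clearcut-uniform, 1 thinned, 5 reference) and 4 downstream sites
  (3 downstream-of-harvest, 1 downstream reference); pre years
  2007–2011, post years 2013–2016 (no sampling in the harvest year);
  9 attributes; replicate counts 1 (chemistry grab, canopy),
  4/6 (epilithon and chlorophyll, headwater/downstream), 3/5 (sediment).
* Values are multiplicative:
  $v = b \cdot e^{\delta_s}\cdot f^{[post]}\cdot\epsilon$, with a
  persistent site effect $\delta_s \sim N(0, 0.4)$ on the log scale
  (emulating pronounced between-watershed baseline differences) and
  mean-one lognormal noise with attribute-specific CV (0.3–0.6). The
  lognormal choice is the minimal positive right-skewed model and is
  consistent with a downstream Box-Cox search. Mean-one noise makes the
  post/pre ratio of expected group means exactly the injected factor —
  the analytic oracle for the recovery tests.
* Canopy closure is simulated on the logit scale (effects act on the
  odds, `noise_cv` is the logit-scale SD) and mapped back to percent,
  so values stay in $[0, 100]$.
* Baselines sit in ranges typical of oligotrophic forested headwaters:
  DIN 0.03, SRP 0.01, DON 0.03 mg/L, DOC 0.5 mg/L, DIN:SRP molar ratio
  ~7, epilithon 8 g AFDM/m², chlorophyll a 7 mg/m², sediment 80 g/m²,
  canopy closure 90%. These were chosen once and are not tuned to any
  test outcome.
* Year effects default to off (an optional common multiplier exists to
  emulate climate years). Replicates are exchangeable draws —
  within-site-year correlation of composites is not modeled, because no
  source states it. There is no hydrological routing: downstream sites
  are independent groups, and no storm or seasonal dynamics exist
  (the design samples one early-summer snapshot per year).

A green effect-recovery test therefore establishes that the pipeline
detects a stated multiplicative signal under lognormal noise at the
study's actual sample sizes — not that it would behave identically on
real field data with serial correlation, detection limits, or
non-multiplicative responses.

# Numerical choices and degenerate inputs

* Zero-variance design columns or responses are errors that name the
  offending column; inside LOO folds a column that loses variance is
  frozen (scale 1, centered to 0) and the fold is flagged.
* Components beyond the rank of the design are rejected in `fit_pls()`;
  LOO folds that lose rank fall back to the deepest available
  component.
* `select_k` compares relative improvements with a $10^{-12}$ tolerance
  so exact-threshold curves (e.g. a literal 2% step) select the smaller
  model.
* Leverage is capped at $1 - 10^{-8}$ with a warning; a numerically
  singular Krylov basis triggers a conditioning warning, not silence.
* Bootstrap/jackknife degeneracy (zero residuals) yields zero-width
  intervals and flagged p = 0, matching the "no resampling
  variability" limit.
* All resampling is explicitly seeded; sub-analyses derive their seeds
  from the master seed with 32-bit-safe arithmetic, so whole reports
  are reproducible bit for bit.

# Scaled-down simulations in the test suite

The acceptance suite reproduces each calibration property at a size
that keeps the full run under a few minutes on one CPU: BCa coverage
uses 400 whole-procedure replicates at $B = 600$ — justified because
the implementation and the independent reference produce *identical*
intervals on shared random streams (asserted to $10^{-10}$), so the
scaled-down coverage comparison is exact rep-for-rep and the remaining
Monte-Carlo error concerns only the coverage level itself; the
effect-recovery criterion runs its full 200 seeds with $B = 2000$.

# Known limitations

* The Wu jackknife's exact historical weighting is ambiguous; both
  variants are implemented and reported, but only the weighted form is
  exercised by default.
* The Box-Cox shift convention for data containing zeros
  ($|\min| + \varepsilon$) is a documented stand-in; sources on the
  original procedure's shift handling were unavailable.
* The GA optimizer is a convenience mirror of the grid search, not a
  performance-tuned implementation.
* No multiple-testing correction is applied across attributes (each
  test uses a fixed 0.05), matching the motivating analysis; a
  Benjamini–Hochberg option would be a clearly-labelled extension, not
  current behavior.
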