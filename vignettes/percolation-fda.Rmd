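---
title: "Density-parameterized percolation analysis of weighted brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-parameterized percolation analysis of weighted brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpercolate)
```

## The problem

How robust is a functional brain network to the loss of its regions, and
how does that robustness change across childhood? `netpercolate`
implements an in silico attack framework for weighted connectomes:
nodes are removed one at a time — at random, or targeted by betweenness
(BC) or eigenvector (EC) centrality — and the sizes of the largest and
second-largest connected components are tracked after every removal. In a
finite graph the largest component only vanishes when everything has been
removed, so the *percolation point* is defined instead as the fraction of
nodes removed at which the **second-largest** component first peaks: the
moment the network dis-integrates into comparably sized fragments.

Any single proportional threshold (keeping the top `d` fraction of
strongest edges) is arbitrary, and graph metrics depend on it. The
package therefore sweeps thresholds across a dense grid of initial
densities and treats the per-subject percolation point **as a function of
density**. Those functions become the response of a penalized
function-on-scalar regression (FoSR) on subject covariates — age, sex,
handedness, and mean Euclidean node distance as a field-spread nuisance —
so covariate effects can vary over density without mass-univariate
multiple-comparison corrections.

## Pipeline stages and their parameters

### Connectivity (optional entry point)

When the input is node-level oscillatory time series rather than
precomputed connectomes, `multitaper_cross_spectra()` computes trial-wise
Fourier coefficients on a 0.5–100 Hz grid in 0.5 Hz steps with ±2 Hz
Slepian multitaper smoothing (time–half-bandwidth `NW = duration ×
half_bandwidth`; with the default 2 s epochs and 2 Hz half-bandwidth,
`NW = 4` and `2·NW − 1 = 7` tapers). Tapers are computed in-package via
the symmetric tridiagonal eigenproblem. Each trial is demeaned per
channel; the FFT is zero-padded so bin centers fall exactly on the grid.

`wpli()` estimates the weighted phase lag index per bin,
`|E[Im S_xy]| / E[|Im S_xy|]`, pooling trials and tapers as i.i.d.
observations of the cross-spectrum (the reference describing wPLI does
not distinguish the two sources of replication; pooling uses all of
them). When the denominator is zero the value is defined as 0 — zero-lag
coupling is exactly what wPLI is designed to discount. `aggregate_l2()`
collapses the 200 narrowband matrices into one connectome edge weight per
pair via the Euclidean norm, bounding entries by `sqrt(n_bins)`.

### Attacks

`proportional_threshold()` keeps the `round(d · N(N−1)/2)` heaviest edges
(rounding half away from zero, ties broken by lexicographic pair order so
edge counts are reproducible across implementations); zero-weight pairs
never become edges. Graphs are binarized after thresholding and
centralities computed on the binary graph — the attack literature's
convention; weighted centralities after a density threshold would mix the
two notions of strength.

`rank_nodes()` ranks once on the intact thresholded graph ("static"
attack; adaptive re-ranking after each removal is available behind
`recompute_centrality`). Betweenness comes from igraph; eigenvector
centrality is the leading eigenvector of the adjacency by power iteration
(run on `A + I`, which has the same leading eigenvector but also
converges on bipartite graphs; tolerance 1e-10, at most 10000
iterations; absolute values, so nodes outside the dominant component get
≈0 and fall to the end). Centralities are rounded to 8 significant digits
before ranking so symmetric nodes tie exactly, and ties are permuted
uniformly at random — the reason targeted attacks are iterated at all.

`run_attacks()` iterates `n_iter = 100` times per density (collapsing to
a single run when a targeted ranking has no ties), records the mean
percolation point, and accumulates per-node counts of removal *strictly
before* the percolation step, the "removed prior to failure" sets behind
the removal-frequency maps. The component traces use a reverse
union-find in C++ (building the graph up in reverse removal order), so
the full grid × iteration sweep stays fast.

`percolation_point()` takes the *first* index of the S2 maximum; an
all-zero S2 trace (a graph that never splits, e.g. complete) degenerates
to `1/N`.

### Functional preprocessing

The functional domain follows the thresholding sweep from dense to
sparse, matching how these curves behave: near full density the
percolation point sits on a static plateau, then falls precipitously as
the thresholded graphs approach their fragmentation regime, ending in a
static sparse range where the estimate is unstable (very few edges
remain). Three quality-control rules:

1. **Terminal spike removal** (`drop_terminal_spike_outliers()`): the last
   value of each curve (sparsest density) is z-scored across subjects
   once; subjects with z > 2 are dropped.
2. **Domain trimming** (`trim_domain()`): the first finite-difference
   derivative (velocity per unit density swept) of the group-mean curve
   locates the onset of the decline; the static dense plateau before it
   is discarded. The stated rule in the source methodology ("the standard
   deviation of the first derivative became negative") cannot be taken
   literally — an SD is nonnegative — so the onset is detected on the
   mean velocity, and the across-subject SD of the velocity is also
   returned for transparency. With `relative = TRUE` the tolerance is a
   fraction of the peak velocity (the pipeline uses 0.02), since
   empirical plateaus are never exactly flat.
3. **SSR screening** (`drop_ssr_outliers()`): each curve is smoothed with
   an order-4 B-spline basis with knots at the grid points (`M + 2` basis
   functions for `M` densities — 402 on the production 400-density grid)
   and a second-derivative roughness penalty whose weight λ is selected
   from `e^k, k = −5..12` by GCV. Subjects whose smoothed fit has an SSR
   z-score above 2 (threshold configurable; the source does not state
   one, so the terminal-spike rule is mirrored) are dropped as
   ill-fitting. λ is selected with densities in **percent** units: the
   roughness matrix scales as the inverse fourth power of the grid
   spacing, so on a fraction-unit domain every candidate in that grid
   would oversmooth.

Smoothing serves *only* outlier detection: the model is fit to the
unsmoothed trimmed curves, since pre-smoothing deletes measurement
variability that the regression's own penalization should handle.

## The model

`fosr()` fits

y_i(d) = β₀(d) + Σ_j x_ij β_j(d) + ε_i(d)

on the stacked subject × density data, each coefficient function expanded
in 5 cubic B-splines with a first-order difference penalty (P-splines),
smoothing weights selected by REML via mgcv — the same engine the
established FoSR implementations wrap. Age is centered at the cohort mean
by the pipeline (stabilizing the intercept function; other coefficients
are unaffected), sex is coded female = 1, handedness enters as two
indicators with right-handed as reference.

Estimation treats grid points as working-independent. Inference handles
the dependence explicitly:

- **Overall tests**: both are computed from **unpenalized** companion
  fits — F tests built on differences of shrunken effective df are
  anticonservative (in our null simulations they rejected at far above
  the nominal rate), whereas with the penalties off the comparisons are
  classical nested linear F tests, exact under i.i.d. Gaussian errors.
  The *model test* (the gate in `significance_summary()`) compares the
  full fit with the functional-intercept-only fit, so it detects
  covariate effects whether or not they vary over density. The
  *constant-vs-functional* comparison constrains the covariate
  coefficients to scalars while retaining the functional intercept
  (constraining the intercept too would make the test reject for any
  curved mean function, destroying calibration under covariate-null
  data) and asks specifically whether effects vary over density.
- **Per-covariate tests** come from the penalized fit's approximate F
  statistics (mgcv).
- **Functional R²** is the edf-adjusted variance explained beyond the
  functional-intercept-only model, overall and per covariate
  (intercept + one regressor); **semi-partial correlations** are the
  square root of the clamped drop in adjusted R² when one regressor is
  removed.
- **Pointwise CIs** (`confint()`): case bootstrap over subjects —
  resampling grid points would break within-curve dependence, and
  resampling subjects is the resampling unit under which curves are
  exchangeable. Smoothing parameters are held at the original REML
  estimates during refits (standard practice; re-estimating per draw
  proved numerically unstable on resampled designs in our checks, besides
  costing ~20× more). Rank-deficient resamples are redrawn and counted.
- **Three-condition significance** (`significance_summary()`): a
  covariate is reported significant over exactly those contiguous density
  ranges where the overall test, its own test (both at a conservative
  α = 0.001, appropriate to the large stacked effective df) and the
  pointwise CI excluding zero all hold.

Residual dependence along the domain still inflates the working-
independence tests when curves deviate smoothly from the mean — the
motivation for the conservative α and the CI gate. The type-I calibration
we verify (and report via `scripts/acceptance.R`) is therefore defined
under an intercept-plus-i.i.d.-noise null at the generator's scale: the
null mean function and noise SD are taken from a real zero-slope cohort
run. Under the full generator null with its correlated curves, the
overall test alone over-rejects; the three-condition rule is the
operative control.

## The synthetic cohort generator

`generate_cohort()` emulates the developmental contrast the analysis is
designed to detect, with a stochastic block model (default 60 nodes, 4
modules). One hub node per module carries a fixed set of bridge edges
(all hub pairs). A concentration level `c(age) = 0.5 +
hub_concentration_slope · (age − midpoint)`, clamped to [0, 1], drives
two opposing changes while preserving the expected total edge weight:
non-bridge inter-module edges (the redundant, distributed wiring of young
subjects) appear with probability `p_inter_max · (1 − c)`, and the weight
freed by their loss is loaded onto the bridges; within modules, weight
tilts toward the hub (`hub_tilt`), so older subjects' modules become
hub-and-spoke. Thresholded sparsely, an old-subject graph is a set of
star-like modules hanging off a few heavy bridges — fragmented early by
centrality-targeted (and random) removal — while a young-subject graph is
a distributed sparse mesh. Edge weights carry lognormal noise
(`edge_noise_sd`, default 0.15). Defaults (slope `1/15` per year over
ages 4–19, `p_within = 0.85`, `p_inter_max = 0.35`) were calibrated once
so that the age–vulnerability rank correlation under BC attack at 5%
density is clearly negative on 60-subject cohorts, and then frozen.

Sex and handedness frequencies follow the shipped example cohort
demographics (55% female; 88% right-handed). Node coordinates are drawn
once per cohort on a 70 mm sphere; per-subject radius grows ~1% per year
around the age midpoint plus a 3% idiosyncratic component (head-size
variation), so mean node distance correlates with age without being
collinear.

What the generator does **not** emulate: spatially structured
connectivity (edges are independent given the block structure), genuine
oscillatory dynamics behind the weights (the connectome is drawn
directly; the oscillator simulator exists separately to validate the
wPLI estimator), volume-conduction artifacts, or measurement noise that
correlates across subjects. Passing tests on this generator show the
pipeline detects hub-concentration shifts encoded this way — not that
real developmental MEG shows them.

## Numerical choices and degenerate inputs

- Edge-count rounding: half away from zero; `m` capped by the number of
  positive weights; `m = 0` is an error ("density too low"), and such
  densities are recorded as missing by `run_attacks()` and dropped before
  gridding.
- Percolation point of a never-fragmenting graph: `1/N` (first index of
  an all-zero S2 trace).
- Zero-variance columns in the z-score rules: no one is dropped.
- `smooth_gcv` solves the penalized normal equations by Cholesky with the
  exact second-derivative Gram matrix (Simpson per knot interval — exact,
  since products of the piecewise-linear second derivatives are
  quadratics).
- Noiseless responses break REML (zero residual variance); `fosr()`
  falls back to the unpenalized fit, which is exact there.
- All randomness is seeded: per-subject seeds derive from the master seed
  by multiplicative splitting (never reused), and every seeded helper
  restores the caller's RNG state.

## Problem sizes used in tests and the acceptance script

Simulations are sized for a single CPU: cohorts of 60–80 subjects on
60-node networks, a 1–30% density grid in 1% steps (the production
default of the attack literature, 0.25–100% in 0.25% steps, is the
documented `attack_config()` default), 100 attack iterations where tie
randomization matters and 20 where it does not, 200 null replicates for
calibration, 30 simulations × 200 draws for bootstrap coverage, and
200-draw bands in the end-to-end run (the `confint()` default remains
1000). These sizes are the package's own reporting choices.

## Known limitations

- Working-independence estimation means the reported per-covariate F
  statistics are approximate; treat the three-condition rule, not any
  single p-value, as the inferential unit.
- The constant-coefficient comparison is computed unpenalized; with very
  small grids (< 10 points) the functional terms are barely
  over-parameterized and the test loses meaning (`fosr()` refuses grids
  shorter than 10).
- EC-targeted attacks on graphs with many symmetric fragments spend their
  iterations almost entirely on tie randomization; percolation points at
  extreme sparsity are dominated by the degenerate conventions above and
  are exactly what the terminal-spike and trimming rules exist to
  contain.
- `removal_frequency_map()` is tabular; rendering onto a brain surface is
  out of scope.
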