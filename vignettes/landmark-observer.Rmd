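---
title: "An ideal-observer account of landmark effects in spatial working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ideal-observer account of landmark effects in spatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmem)
```

## The problem

In continuous-report experiments on visuospatial working memory, an observer
memorizes the angular positions of one or more colored disks on an invisible
circle and later reproduces the position of a probed item. When a
task-irrelevant but stable visual landmark is present, localization becomes
markedly more precise for items near the landmark, while performance far from
it is unchanged. `landmem` implements the generative model that explains this
pattern, the experimental designs that probe it, and the estimation and
model-comparison machinery needed to test it on trial-level data.

## The model

The observer holds two independent estimates of the target's position $x$ on
the circle:

* an **egocentric** estimate with mean $x$ and precision (inverse variance)
  $P_{ego}$, independent of the landmark;
* an **allocentric** estimate, anchored to the landmark, with mean $x$ (or
  $x + s$ if the landmark has been displaced by $s$) and precision that
  decays exponentially with the target–landmark circular distance $d$:
  $$P_{allo}(d) = A_{max}\, e^{-A_{scale}\, d}.$$

The two are fused by precision weighting,
$$\mu_{MLE} = \frac{P_{ego}\,\mu_{ego} + P_{allo}\,\mu_{allo}}
  {P_{ego} + P_{allo}}, \qquad P_{MLE} = P_{ego} + P_{allo},$$
and the response is drawn from a lapse-contaminated von Mises distribution,
$$p(\hat{x}) = (1 - \lambda)\,\phi(\hat{x};\, \mu_{MLE}, P_{MLE})
  + \frac{\lambda}{2\pi},$$
where the lapse rate $\lambda$ absorbs guesses and swap errors (swaps are not
modelled as a separate mixture component). The weighted-mean fusion uses the
Gaussian-style formulas on the circle's local chart (the allocentric mean
expressed as a signed deviation from the egocentric mean before averaging),
not the exact von Mises product rule; at the concentrations relevant for
localization data the two are practically identical, and the simple weighted
mean is what defines the model here.

Two closed consequences drive the qualitative signatures:

* **bias** under a landmark shift $s$:
  $b(d) = s \cdot P_{allo}(d) / (P_{ego} + P_{allo}(d))$, largest at the
  landmark and vanishing far from it;
* **variability**: the median absolute deviation (MAD) of responses shrinks
  near the landmark because $P_{MLE}$ grows, and plateaus at the
  landmark-free level far away.

`predicted_bias()` and `predicted_mad()` compute these; the latter offers a
deterministic quadrature method and a Monte-Carlo method that mirrors how
model predictions are generated for comparison with binned data.

### Units and the precision–concentration mapping

All internal computation is in radians on the response circle; file I/O and
summaries use degrees on the circle (not degrees of visual angle). Precisions
are rad^-2 and map directly onto the von Mises concentration,
$\kappa = P$, justified by the high-precision regime in which the von Mises
and the Gaussian with variance $1/P$ coincide; `dvonmises()` remains exact at
any $\kappa$, so nothing depends on the approximation.

## Which conditions carry an allocentric cue

The allocentric component is active only when the landmark is visible both at
encoding and at test: `LM_PRESENT`, `LM_GAP` and `LM_SHIFT`. In `LM_ABSENT`,
`LM_ENCODE` (landmark at encoding only) and `LM_RETRIEVE` (landmark at
retrieval only) the allocentric precision is fixed at zero in the
best-fitting configuration; `param_tying()` can still attach free allocentric
parameters to any condition for the model comparisons that establish this
configuration. In `LM_SHIFT` the allocentric distance $d$ is computed from
the pre-shift (encoding-time) landmark position by default, on the view that
the allocentric memory was formed before the displacement; because the shift
is small this is nearly indistinguishable from the post-shift convention,
which is available via `shift_reference = "post"`.

## Synthetic experiments

`generate_design()` reproduces the four designs: E1 (set sizes 1/2/4, 216
landmark-present and 36 landmark-absent trials per set size, six blocks of
126), E2 (216 each of present/gap/encode plus 72 absent, six blocks of 120),
E3 (216 each of present/gap/shift plus 36 absent, six blocks of 114) and E2B
(210 each of present/retrieve plus 105 absent, five blocks of 105). Within
each block the targets of landmark conditions are stratified over 12
thirty-degree bins of target–landmark separation — exactly equal counts
where the arithmetic divides (36 per block in E1–E3), as equal as possible
with randomly placed remainders in E2B (42 per block does not divide by 12).
Bin $k$ covers $[k \cdot 30° - 15°, k \cdot 30° + 15°)$ of signed
separation. The landmark is uniform on the circle, non-target items are
placed by rejection sampling under the 15° minimum separation rule (10^4
retries before an error, unreachable in practice at set size 4), the
landmark itself is exempt from the separation rule, and the 6° shift sign is
balanced within block. Responses are sampled by `simulate_responses()`
directly from the generative model.

The generator's default parameters (`default_params()`) define the simulated
observer population: $P_{ego}$ = 100/72/45 rad^-2 at set sizes 1/2/4 (a
roughly linear decline of ~18 rad^-2 per added item), $A_{max}$ =
800/500/180 rad^-2, $A_{scale}$ = 8 rad^-1 shared across set sizes, and
$\lambda$ = 0.01/0.025/0.05. They were chosen once, from the structure the
model itself implies: at set size 4, $A_{max} = 4 P_{ego}$ puts the peak
shift-bias at 80% of the displacement, and $A_{scale} = 8$ confines the
allocentric benefit to within roughly 45° of the landmark (under 5% precision
change beyond that), with precision and lapse trends across set size of the
size typically seen in continuous-report data.

What the synthetic data deliberately do **not** emulate: encoding-stage
biases or attraction/repulsion between items, separate swap responses (they
are folded into the lapse, as in the model), eye movements, display geometry
and color assignment, or between-participant heterogeneity (cohorts are
generated homogeneous unless you pass a per-participant parameter function).
Tests that pass on these data therefore validate the pipeline's internal
consistency — estimation, selection, summaries — not the model's adequacy
for any real dataset.

## Fitting

`fit_observer()` maximizes the trial-wise log-likelihood under a declarative
tying scheme (`param_tying()`) that maps each parameter, per
condition/set-size cell, to a shared free slot or a fixed constant; the slot
count is the variant's $k$. Bounds are $P_{ego}, A_{max} \in [0, 10^6]$ (a
large finite stand-in for an unbounded precision — $10^6$ rad^-2 is a
standard deviation of 0.06°, far beyond any plausible motor precision),
$A_{scale} \in [0, 500]$ rad^-1 (the conventional bound, configurable via
`bounds=` since a rate bound is unit-dependent), $\lambda \in [0, 1]$.
Optimization is bounded quasi-Newton (`nlminb`) from randomized interior
multistarts (default 20): precisions log-uniform over $[1, 10^3]$ rad^-2,
$A_{scale}$ log-uniform over $[0.5, 50]$ rad^-1, lapse uniform over a small
interior range. The decay rate is started log-uniformly rather than
uniformly over its full box because uniform draws almost always land where
allocentric precision is numerically zero at every sampled distance, leaving
the start on a flat plateau. Objective convergence tolerance is $10^{-8}$;
the best of the starts is kept and reproducibility is guaranteed by the
seed. Fitting is strictly per participant; there is no hierarchical pooling.

Model comparison uses AICc with the Hurvich–Tsai small-sample correction,
$-2\ell + 2k + 2k(k+1)/(n-k-1)$, summed over participants in
`compare_fits()` (a mean is available; the sum is the conventional cohort
statistic). The **reduced** variant fixes $A_{max} = 0$ (and with it
$A_{scale}$, which becomes unidentifiable). The **cost** variant replaces
$P_{ego}$ by a landmark-absent precision and a proportional cost $C$ with
$P_{ego}^{LM} = P_{ego}^{NO\text{-}LM}(1 - C)$, $C \in [0, 1]$ by default —
a one-tailed test of whether landmark encoding consumes egocentric resources
— with `allow_negative_cost = TRUE` widening the bound to $[-1, 1]$ for
meta-analytic use. `setsize_trend()` (per-participant OLS slope plus a
one-sample t-test, $df = n - 1$) and `predicted_cost()`
($1 - P_{ego}(2N)/P_{ego}(N)$) provide the secondary analyses of fitted
parameters.

A note on identifiability: $A_{max}$ and $A_{scale}$ trade off along a ridge
of the likelihood (a higher peak with faster decay produces nearly the same
precision profile over the few trials that land close to the landmark), so
at single-experiment sample sizes their individual estimates are
considerably noisier than $P_{ego}$ or $\lambda$, even when the optimizer
demonstrably finds the global optimum. This is a property of the design —
only a twelfth of the landmark trials fall in the bin nearest the landmark —
not of the estimator.

## Summaries

`binned_summary()` computes the median signed deviation (bias) and the
median absolute deviation (variability) of responses versus target–landmark
distance in partially overlapping bins: half-width 15°, spaced every 15°, 24
bins on the signed axis or 13 on the folded $[0°, 180°]$ axis, edge
convention $[c - 15°, c + 15°)$, each trial contributing to the (up to) two
bins that cover it. Landmark-absent cells have no distance axis and are
pooled into a single row. With `shift_align = TRUE` deviations are signed by
the shift direction and the per-bin median bias is subtracted before the
MAD, so the variability curve is not inflated by the systematic bias. Empty
bins yield missing values, never errors. Bootstrap intervals (percentile by
default, seeded, 95%) are provided because plotted intervals need a concrete
method; a normal-approximation method (estimate ± z·bootstrap SE) is
available for extreme coverage levels where percentile endpoints of a few
hundred resamples are unreliable. Bins may pool trials across participants
(default) or average per-participant medians (`pool = "participants"`),
matching the two conventions used for cohort figures.

`model_curves()` overlays the model by forward simulation at uniform target
positions; `predicted_curves()` is its deterministic counterpart, pooling
the response distribution over each bin's distance window on an angular grid
(8192 points, midpoint-corrected CDF — a plain cumulative sum biases grid
quantiles by half a cell) and reading off the pooled median and MAD.

## Numerical choices

* von Mises density via the exponentially scaled Bessel function, stable to
  $\kappa = 10^6$ and beyond; sampling by the Best–Fisher rejection
  algorithm, valid for all $\kappa$ with $\kappa = 0$ handled as uniform.
* `predicted_mad()` quadrature root-finds the folded-distribution median
  with an adaptive integral truncated 30 standard deviations into the tail,
  so sharply peaked densities do not defeat the integrator.
* Degenerate inputs are kept finite: $d = 0$ with huge $A_{max}$ is allowed;
  both cue precisions zero is an error in `integrate_cues()` but yields a
  uniform response distribution in the likelihood (where the lapse and the
  bounds keep the objective finite).
* Ties and seams: all angular arithmetic wraps into $(-\pi, \pi]$, with the
  seam assigned to the upper endpoint.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes chosen to give stable
verdicts on one CPU: oracle comparisons at 3×10^4 simulated trials per
parameter draw, parameter recovery on 20 synthetic observers of 756 trials
each (8 multistarts), model selection on cohorts of 8 observers of 720
trials (5 multistarts), cost-model checks on 2400 balanced trials per
observer, and qualitative-signature checks on a 12-observer cohort. The
acceptance script reruns the same computations at slightly smaller cohort
sizes.

## Known limitations

* The model inherits the weighted-mean integration rule; it is normative
  here and not compared against exact circular fusion.
* No separate swap-error component: datasets dominated by binding errors
  will inflate the fitted lapse rate.
* The cost parameter's maximum-likelihood estimate carries a small positive
  finite-sample bias at typical trial counts (it vanishes in larger
  simulations), so cohort-level summaries of $\hat{C}$ are more reliable
  than individual estimates.
* Bootstrap intervals are percentile-based display aids, not inferential
  replacements for the likelihood machinery.
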