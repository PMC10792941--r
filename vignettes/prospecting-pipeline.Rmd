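---
title: "Prospecting, recess recursion and nest fate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prospecting, recess recursion and nest fate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestprospect)
```

`nestprospect` quantifies whether an incubating female returns to the places
she visited during egg laying, and whether the breadth of those returns
predicts nest fate. This vignette is the package's account of its models,
thresholds, and design choices — what each stage assumes, why each default
is what it is, and what passing the recovery tests does and does not show
about field data.

## The trajectory model

GPS transmitters in this study system record one fix every hour from 05:00
to 20:00 plus a single nightly fix at 23:58:58 (local standard time). The
nightly fix is the linchpin of segmentation: an incubating female sleeps on
the nest, so the first night her 23:58:58 fix sits within the on-nest radius
marks incubation onset.

Three distance thresholds carry the behavioural classification, all taken
from the transmitter and movement-rate characteristics of the system rather
than tuned to any dataset:

| quantity | default | meaning |
|---|---|---|
| on-nest / recess radius | 27.5 m | 90th-percentile positional error of the transmitter; a fix strictly farther is a recess, anything at or inside is on-nest |
| laying visit radius | 20 m (strict `<`) | first hourly fix this close to the nest, within a 20-day lookback before incubation, defines laying onset |
| CLP linkage radius | 150 m (inclusive `≤`) | hourly movement scale during laying; fixes chained within it form one clustered laying patch |
| CLP revisit buffer | 45 m (inclusive `≤`) | half the 90-m daily recess travel scale; a recess within it of a CLP centroid revisits that patch |
| DOP filter | 7 (strict `>` removed) | satellite-geometry quality cutoff |
| minimum incubation | 3 days (strict `<` removed) | shorter attempts cannot be separated from noise |

Boundary conventions matter for reproducibility and are asserted by unit
tests: the removal rules are strict inequalities (`dop > 7`, `< 3 days`,
`> 27.5 m` is a recess, `< 20 m` is a visit), while the spatial buffers are
inclusive (`≤ 150 m` links, `≤ 45 m` counts — "fell within" a buffer).

## Segmentation without field confirmation

In the field, nests are confirmed by visiting them. As a reproducible
surrogate, the package estimates the nest as the geometric median
(Weiszfeld's algorithm) of the largest single-linkage cluster of nightly
fixes at the 27.5-m radius. Chained proximity, rather than an all-pairs
condition, is deliberate: with 10-m GPS noise two genuine on-nest fixes are
more than 27.5 m apart about 15% of the time, so demanding that all pairs be
mutually close would shatter real incubation runs; cluster linkage tolerates
individual noisy nights. A caller who has field-confirmed coordinates passes
them via `nest_xy`/`known_nests` and skips estimation.

Incubation onset is the first nightly fix within the radius of that nest
that begins a run of at least `min_nights` consecutive on-nest nights
(default 1); incubation ends the day after the run's last night. Candidate
nest clusters need at least 3 nightly members so that a chance pair of roost
nights cannot spawn a phantom attempt; when candidate attempts overlap in
time the longer incubation wins. Renests become `attempt_index` 2, 3, ... in
onset order.

Recovery performance under the generator's conditions: at 10-m noise, onset
is exact for ≥ 95% of attempts and the nest estimate lands within 10 m of
truth for ≥ 95% (the residual failures are first-night fixes whose radial
error exceeds 27.5 m, probability ≈ 2% per attempt at that noise level).

## Clustered laying patches and recursion

Laying-period fixes are partitioned by single-linkage clustering: two fixes
share a patch iff a chain of pairwise distances ≤ 150 m connects them
(`stats::hclust(method = "single")` cut at the linkage height; a brute-force
union-find over all pairwise distances serves as the independent oracle in
the test suite). The centroid is the arithmetic mean of member coordinates
(unit-vector mean for geographic inputs); patch ids follow the earliest
member timestamp so they are stable under re-runs.

Recession counting anchors one 45-m buffer at each CLP centroid — not at
every member fix — and a recess fix inside overlapping buffers is attributed
once, to the nearest centroid (ties to the lower id). This guarantees
`proportion_to_clp ≤ 1`. The proportion's denominator counts recess fixes,
not recess bouts, matching how recess totals are reported at fix scale.

Two readings of the clustering radius circulate in the field's descriptions
(150-m radius vs 150-m diameter, i.e. a 75-m threshold, and a buffer-overlap
reading at 300 m); the package defaults to the 150-m radius and exposes
`linkage_radius_m` so either alternative is one argument away.

## The dynamic Brownian bridge movement model

The incubation range is the 95% contour of a dBBMM utilization distribution
with the published settings: location error 20 m, window 7 fixes, margin 3.
Within each sliding window the motion variance maximises the leave-one-out
likelihood of the even-position fixes given their temporal neighbours:

* mean: linear interpolation between the neighbours at the fix's relative
  time `a`;
* variance: `sigma^2 * T * a * (1 - a) + ((1 - a)^2 + a^2 + 1) * err^2`.

The error term carries the telemetry error of *all three* fixes — the two
conditioning neighbours propagate `(1 - a)^2 + a^2` of it into the bridge
mean and the observed fix contributes its own `err^2`. Omitting the observed
fix's term folds observation noise into the motion variance (a ~3x upward
bias at hourly sampling, verified by simulation), which would defeat the
package's recovery tests; with it, simulated Brownian motion with known
variance is recovered within a few percent when the diffusion signal
dominates the error term. A window may split at one interior breakpoint
(honouring the margin) into two variance regimes when BIC improves; window
estimates are averaged over the interior bridges of overlapping windows and
end bridges inherit the nearest estimate.

The UD integrates isotropic bridge densities over each bridge (midpoint
rule, 10 steps, bridges weighted by duration) on a 30-m grid matching the
covariate rasters, and normalises to total mass 1. The 95% contour is the
smallest set of cells whose cumulative density reaches 0.95 (mass lands in
`[0.95, 0.95 + max cell mass]`). With a constant variance the machinery
reduces exactly to the plain Brownian bridge movement model — an internal
cross-check in the tests. Available points are sampled uniformly over the
contour cells (cells equal-area, uniform within a cell), 500 per range.

Two coincident fixes produce a radially symmetric error kernel whose
per-time variance interpolates between `err^2/2` (mid-bridge) and `err^2`
(endpoints) — a mixture close to, but not exactly, a single Gaussian of SD
`err`; the tests bracket its 95% radius accordingly.

## The resource-selection model

Third-order (within-range) selection: recesses that reached a CLP are the
used points (1), the 500 per-range samples are available (0), and a
binomial-logit GLMM with a per-female random intercept is fitted by Laplace
maximum likelihood (`lme4::glmer`). Covariates are distances (m) to each of
the six landcover classes, to secondary roads, and to the nest; distance
surfaces are exact Euclidean distance transforms (separable
parabolic-envelope algorithm) on the 30-m grid, road distances exact
point-to-segment. All fixed effects are rescaled by two standard deviations;
covariates with pairwise Pearson `|r| > 0.60` are removed greedily (largest
mean absolute correlation first) before fitting. Distance to the nest is
computed for available points from the same nest as for used points — the
model needs the covariate on both arms of the design. Because every
covariate is a distance, a negative coefficient means selection for
proximity.

One property of this design worth knowing when interpreting coefficients:
the used:available ratio is fixed per range, so between-range variation in a
covariate carries no selection signal, and shrinkage of the random
intercepts attenuates fitted coefficients toward zero wherever availability
differs strongly between ranges. Distance to nest, whose within-range
distribution is identical across ranges, is immune; landscape covariates
recover their generative sign reliably (the package's recovery tests demand
sign detection in 20/20 replicates and null calibration `|β| < 2 SE` in ≥
18/20) but their magnitudes sit below the generative within-range values.
This is a property of used/available GLMMs generally, not of this
implementation.

## The nest-fate model

Fate (success = hatched, failure otherwise) is Bernoulli with a logit link:

```
fate_i ~ Bernoulli(plogis(alpha + b1 * z1_i + b2 * z2_i + u_{f(i)}))
u_f ~ Normal(0, sigma_b^2)
```

with `z1` = proportion of recesses to CLPs and `z2` = number of CLPs
visited, both standardised by their sample SD, and a random intercept per
female (shared across her attempts). Priors are weakly informative —
Normal(0, 2.5^2) on coefficients, half-Normal(0, 2^2) on `sigma_b` — and
posterior sampling is an adaptive random-walk Metropolis-within-Gibbs
scheme: componentwise fixed-effect updates, a vectorised per-female sweep
for the intercepts, a log-scale update for `sigma_b`, and a joint scaling
move that rescales all intercepts together with `sigma_b` (the move that
traverses the funnel-shaped posterior; without it `sigma_b` mixes an order
of magnitude more slowly). Proposal scales adapt toward 44% acceptance
during burn-in only, so the post-burn-in chains are valid Markov chains.

The default schedule is 4 chains x 8000 iterations with the first 1000 of
each discarded. Summaries per parameter: posterior mean, central 95%
credible interval, probability of direction (`max(P(β > 0), P(β < 0))`, ties
split), and split R-hat; any R-hat ≥ 1.1 flags the fit as unconverged with a
warning rather than an error. Posterior means agree with `lme4::glmer`
maximum-likelihood estimates on well-identified fixtures (a test asserts
this), keeping the dual model-fitting routes mutually checking.

`marginal_effect()` converts the patches-visited coefficient into an average
marginal effect in percentage points per additional patch: the +1-patch step
is divided by the covariate's original-scale SD, and the success-probability
change is averaged over posterior draws and observed rows (each row using
its female's posterior-mean intercept).

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults are the study conditions: the fix schedule above, 12
laying days, 28 incubation days, ~2 recesses per day (Poisson), revisit
probability 0.57, a Poisson-spread patch count (mean 6, clamped to 2–12),
and fate coefficients of 0.19 per SD of patches visited, 0 for the recess
proportion, and a female random-intercept SD of 1.2. Patch centres sit
250–700 m from the nest with ≥ 350-m separation so they resolve into
distinct CLPs at the 150-m linkage radius; non-patch recess targets fall
60–900 m from the nest so the 27.5-m rule separates classes cleanly — these
are generator constraints chosen for identifiability, not claims about
turkeys. Nightly roosts during laying sit 300–600 m out, beyond the linkage
radius of the nest cluster.

Default GPS noise is 5 m. This deserves a sentence: at 10-m noise roughly 2%
of on-nest fixes fall in the 27.5–45 m annulus, where they are classified as
recesses *and* land inside the nest-cluster CLP buffer, inflating the
recovered revisit proportion by a few points. Real analyses absorb that
artifact silently; recovery experiments need the generative probability to
be recoverable, so the default models a high-quality fix series, and the
segmentation robustness tests override the noise to 10 m explicitly.

Landcover is six independent smoothed Gaussian fields compared cellwise,
with offsets iterated so areal shares track the requested mix — independent
fields interleave the classes, keeping distance-to-class covariates only
moderately correlated (max |r| ≈ 0.3, consistent with a screen at 0.60
removing nothing). The generator does **not** emulate: correlated random
walks or habitat-dependent step selection between recess targets, weather or
seasonal effects, missed fixes or transmitter dropout, renesting-specific
behaviour shifts, or fate mechanisms beyond the stated logistic model.
Passing the recovery tests therefore demonstrates that the estimators are
correct under their assumed data-generating process — not that field data
satisfy those assumptions.

## Numerical choices

* Distances: planar Euclidean in projected metres; haversine on a
  6,371,000-m sphere for geographic inputs (ellipsoidal precision is
  irrelevant at ≤ 1-km scales). Raster work is always planar; geographic
  fixes are projected through a fixed local equirectangular mapping first.
* Timestamps are taken as local standard time verbatim; nightly-fix matching
  tolerates ±5 minutes (wrapping midnight) because real receivers drift.
* Sub-hourly duplicate fixes keep the first record; gaps are tolerated.
* Standardisation uses the sample SD (n − 1); the RSF divides by 2 SD.
* The motion-variance search runs `stats::optimize` on
  `[0, 10 x max squared step rate]`; degenerate (stationary) tracks return
  variances indistinguishable from 0.
* Determinism: every stochastic stage draws its seed from the configuration
  seed, and re-running `run_pipeline()` under an identical configuration
  reproduces every summary table byte for byte; outputs embed an MD5 hash of
  the full configuration.
* Problem sizes in the tests and acceptance script (100-attempt recovery
  runs, 20-replicate model calibrations, 4x2000 chains in the replicated
  calibration study, 585 attempts at the full 4x8000 schedule in the
  acceptance script) were chosen as the smallest sizes at which the checked
  properties are statistically decidable.

## Interface notes

The package is driven from R: `run_pipeline()` orchestrates
simulate → segment → prospect → range → rsf → fate → report, and each stage
is an exported function usable on real data (`read_fixes()` ingests
delimited fix tables; rasters travel as Arc/Info ASCII grids with a JSON
legend; roads and CLPs as GeoJSON). `scripts/acceptance.R` reruns the
headline computations from scratch under a caller-supplied seed.

## Known limitations

* Nest-fate determination is an input label; the package does not infer
  hatching from movement data.
* The dBBMM breakpoint search considers a single breakpoint per window —
  adequate at window 7, but not a general changepoint model.
* `detect_incubation_onset()` ends an attempt at the first off-nest night;
  an incubating female with one aberrant nightly fix mid-attempt will have
  her incubation truncated at that night (configurable only through the
  on-nest radius).
* The number of consecutive on-nest nights that constitutes "remaining
  overnight" (`min_nights`) and the candidate-cluster size are exposed
  parameters; their defaults (1 and 3) are operational choices, not field
  calibrations.
* Recess bouts are not modelled — consecutive recess fixes count
  individually, matching fix-scale recess totals.
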