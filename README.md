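# nestprospect

Tools for asking whether a nesting, GPS-tagged female returns during
incubation to the places she explored while laying — and whether that
matters for her nest's fate.

Ground-nesting birds such as wild turkeys are central-place foragers during
incubation: they must leave the nest to feed (incubation *recesses*) and
return before the clutch cools. During the preceding egg-laying period the
female ranges widely, and the patches she visits then may function as
*prospected* foraging sites she can exploit efficiently later. `nestprospect`
implements the full analysis chain that quantifies this behaviour from raw
GPS fix tables:

1. **Cleaning** — drop fixes with dilution of precision > 7.
2. **Segmentation** — incubation onset is the first night (23:58:58 fix) the
   female remains on the nest (within 27.5 m, the transmitter's
   90th-percentile error); laying onset is her first hourly fix < 20 m from
   the nest in the preceding 20 days; attempts incubated < 3 days are
   discarded.
3. **Clustered laying patches (CLPs)** — laying-period fixes are merged by
   single-linkage clustering at a 150-m radius; each cluster's centroid gets
   a 45-m (90-m diameter) revisit buffer.
4. **Recursion analysis** — every incubation fix > 27.5 m from the nest is a
   recess; a recess inside a CLP buffer is a return to a prospected patch.
   Per attempt: the proportion of recesses to CLPs and the number of
   distinct CLPs visited.
5. **Incubation ranges** — dynamic Brownian bridge movement model (dBBMM;
   window 7, margin 3, 20-m error) utilization distributions, 95% contours,
   and 500 uniformly sampled available points per range.
6. **Resource selection** — used (recesses to CLPs) vs available logistic
   GLMM with a per-female random intercept, distance-to-feature covariates
   (six landcover classes, secondary roads, the nest) rescaled by 2 SD, and
   a Pearson r > 0.60 collinearity screen.
7. **Nest fate** — Bayesian random-intercept logistic regression of
   success/failure on the two prospecting covariates (standardised), fitted
   by an adaptive MCMC sampler (4 chains x 8000 iterations, 1000 burn-in)
   with 95% credible intervals, probability of direction, and split R-hat
   diagnostics.

A first-class synthetic-data module generates landscapes (6-class mosaic
rasters with roads), trajectories on the real transmitter schedule (hourly
fixes 05:00–20:00 plus one nightly fix at 23:58:58), and nest fates from a
known hierarchical logistic model — with complete ground truth, so every
stage of the pipeline is validated by recovery experiments.

## Worked example

```r
library(nestprospect)

cfg <- sim_config(n_females = 12, p_revisit = 0.57, seed = 5)
report <- run_pipeline(cfg, pipeline_params(iterations = 2000,
                                            burn_in = 500,
                                            n_available = 100,
                                            max_ranges = 4))
report
```

```
<np_report>
  12 attempts, 669 recesses
  mean proportion of recesses to CLPs: 0.564
  mean CLPs visited: 5.58 (of 11.67 total)
  ...
```

The simulated females were built to send 57% of recesses back to laying
patches; the pipeline — which never sees the truth labels — recovers a mean
proportion of 0.564 across attempts and a mean of 5.6 patches visited.
Individual stages are available as plain functions
(`detect_incubation_onset()`, `cluster_laying_locations()`,
`classify_recesses()`, `count_revisits()`, `dbbmm()`, `fit_rsf()`,
`fit_nest_fate()`, ...), each accepting either synthetic or real fix tables
(`read_fixes()`).

## Vignette

`vignettes/prospecting-pipeline.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations.
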