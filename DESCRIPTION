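Package: nestprospect
Title: Prospecting, Recess Recursion and Nest-Fate Analysis for Nesting GPS-Tagged Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking egg-laying-period prospecting by
    GPS-tagged nesting females to incubation recess movements and nest fate.
    Provides trajectory cleaning and segmentation into laying and incubation
    windows, single-linkage clustering of laying locations into clustered
    laying patches (CLPs), recursion (revisit) counting of incubation
    recesses into CLP buffers, dynamic Brownian bridge movement model (dBBMM)
    incubation ranges with available-point sampling, a used/available
    resource-selection GLMM, and a Bayesian random-intercept logistic model
    of nest fate with probability-of-direction and R-hat diagnostics. A
    synthetic-data module generates landscapes, trajectories and fates with
    known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
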