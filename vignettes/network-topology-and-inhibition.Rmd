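---
title: "Linking functional-network topology to stop-signal inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking functional-network topology to stop-signal inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopnet)
library(dplyr)
```

stopnet implements a complete analysis chain for asking whether the
*topology* of a person's resting-state functional brain network predicts
their ability to cancel a prepared motor response. The chain has four
stages, each usable on its own: a stop-signal task simulator and SSRT
estimator, nodal graph metrics on thresholded connectomes, per-network
regression with cross-validated permutation inference, and a synthetic
cohort generator that makes every stage testable end to end without any
imaging data.

## The stop-signal task and the race model

In a stop-signal session the subject responds to a go stimulus on most
trials; on a minority of trials a stop signal sounds after a delay (the SSD)
and the response must be withheld. Behavior is modelled as a race between an
independent go process and a stop process: the response escapes inhibition
iff the go process finishes before `SSD + SSRT`, where SSRT — the
stop-signal reaction time — is the latent latency of inhibition.

`simulate_sst()` reproduces the standard protocol: five blocks of 100 go and
40 stop trials; two interleaved staircases with starting SSDs of 150 and
350 ms that take stop trials in strict alternation; after each successful
stop the staircase's SSD rises by 50 ms (making stopping harder), after each
failed stop it falls by 50 ms, clamped to \[0, 800\] ms. This one-up
one-down rule drives the probability of responding on a stop trial to 50%.
Go finishing times are ex-Gaussian (`go_mu`, `go_sigma`, `go_tau`, all in
ms), a standard, right-skewed RT model. Go omissions and choice errors occur
with fixed probabilities. All randomness in a session flows from a single
integer seed.

Default simulator parameters are fixed at realistic task values: ex-Gaussian
go RTs with mu 500, sigma 60, tau 100 ms; true SSRT 200 ms; omission
probability 7.5% and choice-error probability 1.5% (typical observed rates
for this task in healthy adults); they are parameters, not tuning knobs.

`estimate_ssrt()` implements the block-wise integration estimator. Within
each block, with `m` usable go RTs sorted ascending and
`p = p(respond|stop)`, the rank is `n = p * m` and the block estimate is

```
SSRT_block = nth go RT - mean SSD
```

with the session SSRT the mean of the block values. Two conventions needed
fixing where the method is usually left vague:

* **Rank rule.** `n` is rarely an integer. The default takes `ceiling(n)`
  clamped to `[1, m]` — a conservative integer rank; `rank_rule =
  "interpolate"` instead linearly interpolates between the bracketing order
  statistics.
* **Go omissions.** Go trials without a response are excluded from the
  go-RT distribution by default. Because an omission would most plausibly
  have been a slow response, exclusion shifts the retained distribution
  fast and the estimator low; `omission_policy = "replace_max"` substitutes
  the block's maximum go RT for each omission, the correction recommended in
  consensus guidance. Both conventions are exposed because published
  descriptions of the integration method usually do not say which was used.

The sign convention is `nth go RT - mean SSD`, the only direction that
produces positive SSRTs.

Simulation at the package's defaults puts the achieved stop-success rate
within a point or two of 50% and recovers a generating SSRT of 200 ms to
within about 3 ms (omission-free race) — the residual reflecting the mild
skew sensitivity of the integration method — while excluded omissions at
7.5% depress the estimate by roughly 15 ms, exactly the bias `replace_max`
compensates. The test suite checks all three behaviors.

`tukey_outliers()` provides the behavioral screening rule: a value is an
outlier iff it lies below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`. Quartiles
use linear interpolation of the empirical CDF (`stats::quantile` type 7);
the convention is configurable since whisker rules are quantile-convention
sensitive near small samples.

## Nodal graph metrics on thresholded connectomes

Subjects contribute an ROI-by-ROI Pearson correlation matrix
(`roi_correlation_matrix()` builds one from time series). Analysis operates
on binarized graphs: `threshold_by_density(C, d)` keeps the
`round(d * N(N-1)/2)` strongest positive correlations as edges. Negative
correlations are never retained — binarizing "above a threshold" has no
meaningful negative counterpart — and ties at the cutoff break
deterministically by weight, then node index, so results are reproducible to
the byte. If fewer positive edges exist than requested, all positives are
kept with a warning.

With a partition of nodes into `N_M` networks (the parcellation; the
full-scale default is 400 nodes in 17 networks), two standard hub metrics
are computed per node:

* **Participation coefficient**, `PC_i = 1 - sum_s (K_is / K_i)^2`, with
  `K_i` the degree of node `i` and `K_is` its edges into network `s`.
  PC is 0 when all edges stay inside the node's own network and approaches
  `1 - 1/N_M` when edges spread evenly — a "connector hub" profile indexing
  between-network integration.
* **Within-module degree z-score**, `WMD_i = (k_i - mean_s(k)) / sd_s(k)`,
  the z-score of the within-network degree relative to the node's own
  network — a "provincial hub" profile indexing within-network connectivity.

Conventions where the definitions are silent: isolated nodes get PC 0; the
WMD sd is the population sd over the network's nodes (configurable to
sample sd, a pure rescaling); a network whose within-degrees have zero sd
gets WMD 0 for all its nodes at that density; both metrics are computed on
the *same* binarized graphs for consistency, with a documented
strength-based PC option (`weighted_pc`) that uses the positive weights
directly.

`nodal_metrics()` computes both metrics at each density of a grid and
averages elementwise. The default grid is 0.10 to 0.15; the step is not part
of the published range, so the package uses 0.01 (six thresholds),
configurable. Threshold averaging damps the arbitrariness of any single
density choice.

## Per-network prediction of SSRT

For each network and each property (PC or WMD), the feature matrix is the
subjects-by-nodes block of that property
(`build_feature_block()`), and the model is ordinary least squares with
intercept:

```
SSRT_i = b0 + b1 x_i1 + ... + bk x_ik + e_i
```

Out-of-sample accuracy uses leave-one-out cross-validation: each subject is
predicted from a model fitted on the other `n - 1`. `loocv_predict()`
computes this exactly through the hat-matrix identity
`yhat(-i) = (yhat_i - h_i y_i)/(1 - h_i)` — algebraically identical to
refitting per fold (the suite verifies this against an explicit refit loop)
and fast enough to sit inside a permutation loop. Accuracy is summarized as
the partial Pearson correlation between predictions and observed SSRT,
controlling the head-motion scalar by residualizing both sides on it
(`partial_pearson()`); motion is the classic nuisance in resting-state
connectivity.

**Rank handling.** The solver contract is strict: a rank-deficient design is
an error, never a silent pseudoinverse. One systematic case needs care: the
WMD z-scores of a network's nodes sum to zero by construction (each column
block carries one exact linear constraint), so the *full* WMD block of any
network is rank-deficient by exactly one column. `run_network_models()`
therefore drops exactly aliased columns by QR pivoting before fitting — the
same aliasing treatment `lm()` applies — which spans the identical column
space and leaves fitted values, leverages and LOOCV predictions unchanged;
the dropped node is recorded per model. This is a reparametrization, not
regularization; `drop_aliased = FALSE` restores the strict per-model error.

**Permutation inference.** Significance comes from rerunning the *entire*
LOOCV under shuffled SSRT: each of `n_iter` iterations (default 10000)
permutes `y`, retrains every fold on the permuted values, and recomputes the
identical partial-correlation statistic; the motion covariate stays attached
to subjects. The p-value uses add-one smoothing,
`p = (1 + #{null >= observed}) / (1 + n_iter)`, avoiding p = 0 and keeping
the test valid at Monte-Carlo resolution. Ties at the observed statistic
count as `>=` with a 1e-12 relative tolerance (degenerate models can tie
exactly up to float jitter). On null synthetic cohorts the rejection rate at
alpha 0.05 sits inside the binomial band around 0.05 — the calibration is
itself part of the acceptance checks. A subtlety worth knowing: because only
`y` is shuffled while motion stays attached, exchangeability is exact only
when motion carries no SSRT signal; at the generator's realistic
motion-effect size the distortion is well below Monte-Carlo resolution.

A model is **retained** when its permutation p is below alpha *and* its
partial r is positive — a one-sided rule matching how prediction accuracy is
read (an anticorrelated predictor is not a successful prediction). Sign and
threshold are configuration keys. No multiple-comparison correction is
applied by default (per-network p-values are reported uncorrected); an
optional Benjamini-Hochberg column is available (`fdr = TRUE`).

**Bayes factors.** `bf10_correlation(r, n)` quantifies evidence for the
presence of a correlation between predicted and observed SSRT: a
Jeffreys-style default Bayes factor obtained by numerically integrating the
exact sampling density of the Pearson correlation (the hypergeometric-form
density) against a uniform prior on the population correlation. The default
is two-sided; `sided = "positive"` restricts the prior to positive
correlations, the variant consistent with the one-sided retention rule.
Conventional reading: BF10 of 1-3 anecdotal, 3-10 moderate evidence. The
implementation agrees with an independent high-resolution quadrature of the
same integrand to four decimals, and the test suite checks the documented
monotonicity and the evidence ordering of reference value pairs.

**Post-hoc power.** `posthoc_power(R2, n, k, alpha)` is the power of the
overall F test at the model's observed effect size, `f2 = R2/(1 - R2)`, via
the noncentral F distribution with df `(k, n - k - 1)`. The noncentrality
convention is `lambda = f2 * n` (the common post-hoc convention); a
df-adjusted `f2 * (n - k - 1)` variant is available because published power
analyses rarely state which was used. At `R2 = 0` the function returns
exactly alpha.

`run_network_models()` assembles everything: with a 17-network parcellation
it produces exactly 34 rows (17 PC + 17 WMD models), each carrying the
partial r, permutation p, BF10, observed power, full-fit R² and the
retention flag; failures (e.g. degenerate feature blocks at toy scales) are
recorded per model without stopping the batch. `tidy()`, `glance()` and
`autoplot()` follow the usual fitted-object conventions.

## The synthetic cohort generator

`generate_cohort()` exists so the pipeline's statistical behavior can be
measured against known ground truth. Per subject it draws a latent standard
normal signal `s` and builds a weighted stochastic-block connectome:
within-network pairs centered at 0.5 (sd 0.12), between-network pairs at
0.15 (sd 0.12), truncated to \[-1, 1\]. Every between-network pair touching
the designated signal network is shifted by `signal_scale * s`
(default 0.05 per sd), so that network's between-network edges survive
density thresholding more often for high-signal subjects and its mean PC
rises monotonically with `s` — the signal is planted in *between*-network
connectivity, the quantity PC measures. Behavior is then

```
SSRT_i = 220 + beta * s_i + 150 * motion_i + noise_i,   noise ~ N(0, 70 ms)
```

with motion log-normal around 0.1 mm. The intercept and noise scale give a
cohort SSRT distribution (mean ~220 ms, sd ~80 ms) matching what healthy
adult cohorts show; `beta` (default 40 ms/sd) controls how much SSRT
variance the network signal explains, and `beta = 0` yields an exactly null
cohort in which shuffling SSRT is a true null — the basis of the
calibration experiments.

The desk-scale default shape is 60 nodes, 6 networks, 40 subjects: large
enough that density thresholding at 0.10-0.15 retains a meaningful mix of
within- and between-network edges, small enough that hundreds of replicate
cohorts run in minutes. The full 400-node/17-network shape is one argument
away. Two caveats on external validity: the generator's edge weights are
independent draws (no spatial autocorrelation, no shared global signal),
and its signal enters a single network linearly — so passing calibration
and recovery tests demonstrates correctness of the *procedure*, not that
real resting-state data carry signal of this form or size.

Problem sizes used by the shipped checks, chosen to make Monte-Carlo error
small relative to the tolerances they are compared against: 50 pooled
sessions for staircase convergence, 200 sessions for SSRT recovery, 400
replicate cohorts (500 permutation iterations each) for the test-suite
calibration and 300 cohorts at 1000 iterations in the acceptance script,
100 random modular graphs for the PC bound.

## Pipeline commands and reproducibility

`cmd_simulate()`, `cmd_metrics()`, `cmd_predict()` and `cmd_report()` wrap
the stages behind a YAML-configurable file interface (one connectivity CSV
per subject, a parcellation table, long-format metrics, a Table-style
results CSV, per-model JSON detail, plain-text report), with a thin Rscript
dispatcher in `inst/cli/stopnet.R`. Every stage writes a manifest embedding
the seed and a hash of the analysis-relevant configuration (file paths
excluded), existing outputs are never overwritten unless asked, and equal
config plus equal seed reproduces byte-identical outputs — all verified in
the suite.

## Known limitations

* The race model is the standard independent-horse-race idealization:
  context independence is assumed, no trigger failures, no go/stop
  dependence. The simulator is a protocol testbed, not a cognitive model fit.
* The integration SSRT estimator inherits its documented small-sample
  sensitivity to go-RT skew and omission handling; both knobs are exposed.
* The exact correlation-BF integrand assumes bivariate normality of the
  correlated pair, and the post-hoc "observed power" is the usual monotone
  transform of the observed R² — reported because it is part of the standard
  output surface, not because it adds evidence beyond p and BF.
* Graph metrics are computed on hard binarized graphs; the density grid and
  the positive-edges-only rule are conventions, and results at very sparse
  densities on small parcellations can degenerate (all-within-module
  edges), which the model layer surfaces as recorded failures rather than
  silently patching.
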