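---
title: "Prognostic connectivity modelling: methods and design notes"
author: "coxfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic connectivity modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxfc)
```

## The problem

Cohorts recovering from substance-use treatment are followed for a fixed
window (here 168 days) and either relapse at an observed day or reach the
end of follow-up abstinent (administrative censoring). The scientific
question is whether resting-state functional connectivity (FC) of a chosen
seed region measured before follow-up predicts each individual's
time to relapse, and which voxels carry that prognosis. Because relapse is
a censored time-to-event outcome, ordinary regression or classification
discards information; the natural model is Cox proportional hazards,

$$ h(X_i, t) = h_0(t)\, e^{\sum_j x_{ij} \beta_j}, $$

with the baseline hazard $h_0(t)$ left unspecified and the coefficients
$\beta_j$ estimated by maximizing the partial likelihood. A hazard ratio
$e^{\beta} < 1$ means stronger connectivity goes with a *longer* time to
relapse (protective); $e^{\beta} > 1$ means earlier relapse (risk).

## The pipeline

`coxfc` implements the full prognostic pipeline:

1. **Motion QC** (`framewise_displacement`, `censor_volumes`,
   `qc_subject`): frame-to-frame displacement is the Euclidean norm of the
   six rigid-body parameter differences, rotations in degrees treated as
   mm-equivalent (the convention of the AFNI motion tooling; a Power-style
   L1 norm with a 50 mm head radius is available by flag). Volumes moving
   more than 0.35 mm are censored; subjects fail QC when mean displacement
   exceeds 0.2 mm or more than 20% of volumes are censored.
2. **Time-series cleaning** (`detrend_poly`, `regress_nuisance`,
   `bandpass`): polynomial detrending up to order 3, projection of
   white-matter/CSF nuisance signals, and a 0.012–0.1 Hz band-pass.
3. **Seed connectivity** (`seed_fc`): Pearson correlation of every
   in-mask voxel with the mean seed series over uncensored frames,
   Fisher-z transformed with `atanh` after clipping at $1 - 10^{-7}$.
4. **Voxel-wise survival screening** (`voxelwise_cox`,
   `threshold_maps`): a univariate Cox fit per voxel; voxels with
   two-sided Wald $p < 0.001$ split by coefficient sign into protective
   and risk circuit masks.
5. **Composite indices and the final model** (`composite_indices`,
   `fit_final_model`): `indexP`/`indexR` are linear sums of Fisher-z
   values over each mask; the final Cox model uses the seven covariates
   `indexP, indexR, age, sex, edu, cpd, hm` in that fixed order.
6. **Nested leave-one-out evaluation** (`loocv`, `roc_at_cutoff`,
   `permutation_test`): screening, thresholding and the final fit are all
   recomputed with each subject held out; the held-out subject is scored
   by the fold's linear predictor, scores are evaluated by a fixed-cutoff
   ROC (relapse by day 30/90/168), and significance comes from an
   empirical null built by permuting the (duration, event) pairs and
   re-running the entire analysis.
7. **Post-hoc subtyping** (`circuit_heatmap`, `group_masks`,
   `posthoc_indices`, `pr_regression`, `elbow_curve`,
   `kmeans_subtypes`): per-fold masks are stacked into inclusion-
   frequency heat maps, thresholded at >85% of folds into group-level
   circuits, averaged into per-subject `idxP_ph`/`idxR_ph`, and clustered
   by k-means in that plane.

## The statistical engine

The Cox engine (`fit_cox`) is self-contained: Newton–Raphson from
$\beta = 0$ with step-halving whenever a step would decrease the log
partial likelihood, convergence on a gradient norm below `tol` (default
$10^{-8}$), at most `max_iter = 100` iterations, and standard errors from
the inverse observed information. The compiled core is shared by the
single-fit, the mass-univariate screen and the cross-validation loop, so
all three are numerically identical paths.

Design choices worth knowing:

* **Ties.** Breslow's approximation is the default; Efron's is available
  via `ties = "efron"`. Breslow is the simplest defensible default, is
  exactly what the brute-force grid oracle in the test suite maximizes,
  and makes the score test at $\beta = 0$ coincide with the classical
  log-rank statistic. Event times from the synthetic generator are
  continuous, so the choice rarely matters there.
* **Monotone likelihoods.** A separable covariate (one that perfectly
  orders the earliest events) sends $\beta$ to infinity. Two detectors
  flag it: a hard cap `|beta| > 50`, and a collapse of the observed
  information below $10^{-6}$ of its value at $\beta = 0$ — the second is
  needed because the gradient of a monotone partial likelihood decays to
  zero on its own, which would otherwise look like convergence. Flagged
  voxels are excluded from circuit masks rather than kept with a capped
  coefficient, because a capped coefficient has a meaningless Wald p.
* **Wald p-values.** The screening threshold is applied to two-sided
  Wald p-values with direction taken from the sign of $\beta$. Score and
  likelihood-ratio alternatives would behave almost identically at these
  sample sizes; Wald is the cheapest inside a mass-univariate loop.
* **No multiplicity correction at screening.** The voxel threshold is
  deliberately a *pre-selection* device, not an inference: generalization
  is guarded by the nested cross-validation, in which selection is redone
  without the held-out subject, not by family-wise error control.

## Cross-validation and its evaluation

Feature selection is the dominant overfitting risk in this design, so it
lives entirely inside the fold: erasing the held-out subject's FC map
must not change the fold's masks or coefficients, and the test suite
asserts exactly that. The out-of-fold score is the fold model's linear
predictor at the held-out subject's covariates (centred at training
means); the baseline hazard is never needed because the ROC is
rank-based.

For the ROC at cut-off $c$, subjects with an observed relapse at or
before $c$ are positive and subjects observed beyond $c$ are negative;
subjects censored at or before $c$ carry no label and are excluded with a
logged count. In the targeted study design that excluded set is empty —
censoring only happens at day 168, because a missed follow-up appointment
counts as relapse — so the rule only matters for general data. The AUC is
computed by the Mann–Whitney rank identity, which equals the trapezoidal
area under the empirical ROC and gives tied scores exactly half a
concordance.

The permutation test shuffles the (duration, event) pairs against the
subjects and re-runs the *entire* nested analysis per permutation,
screening included. The p-value uses the add-one rank estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$,
which can never return zero. A `mode = "reuse"` shortcut keeps the
observed out-of-fold scores and permutes only the ROC labels; it is
anti-conservative (the scores were selected on the unpermuted outcome)
and is intended for exploration only. Whether the original analysis
re-ran screening inside each permutation or reused the observed indices
is ambiguous in prose descriptions of such pipelines; the full re-run is
the defensible reading and is the default here.

## The synthetic cohort generator

Real seed-FC relapse cohorts are restricted-access clinical data, so
every stage is validated on synthetic cohorts with known truth
(`simulate_cohort`). Per subject, latents $(u_P, u_R)$ are bivariate
normal with correlation $\rho$; voxel values are $a\,u_P + \varepsilon$
in a planted protective circuit, $a\,u_R + \varepsilon$ in a disjoint
risk circuit, and $\varepsilon \sim N(0, \sigma^2)$ elsewhere; the hazard
is $h_0 e^{b_P u_P + b_R u_R}$ with exponential raw event times censored
administratively at day 168.

Defaults, chosen once: $h_0 = 0.01$/day — under a null effect this gives
a censored fraction $e^{-0.01 \cdot 168} \approx 0.186$, matching the
roughly 81% relapse-by-day-168 regime the pipeline targets; grid
$20^3$ with a central-ellipsoid brain mask (~3100 voxels); circuits of 50
voxels each; loading $a = 1$ with noise $\sigma = 0.3$; effects
$b_P = -0.7$, $b_R = +0.7$; $\rho = 0$ so that null-calibration checks
(uniform screening p-values, mask fraction $\approx \alpha$) hold
exactly; covariates (age 25–60 y, sex Bernoulli(0.12), education 8–18 y,
0–30 cigarettes/day, mean FD 0.03–0.15 mm) with zero hazard
coefficients. Exponential event times were chosen because Cox is
baseline-agnostic and the exponential gives closed-form checks.

What the generator does *not* emulate: spatial smoothness (off by
default so per-voxel independence holds in calibration tests; a planted
circuit is not spatially contiguous), hemodynamics, physiological noise,
motion artefacts, or any anatomical template. Passing tests therefore
demonstrate statistical correctness of the pipeline, not robustness to
fMRI artefact structure.

One property of the generator matters when reading recovery results: all
voxels of a circuit share a single subject latent, so their screening
statistics rise and fall together. In a single simulated cohort the
sensitivity of the $p < 0.001$ screen is close to all-or-nothing per
circuit, and at $n = 80$, $b = \pm 0.7$ the circuit-level Wald statistic
sits near the threshold ($|z| \approx 3.3$–4), so one cohort draw can
recover one circuit and miss the other. Averaged over many draws the
screen recovers planted circuits in most cohorts; any single fixed-seed
cohort is a coin-flip-weighted snapshot of that.

Similarly, the out-of-fold AUC of a null cohort with about 20 positive
and 20 negative labels has a Mann–Whitney standard deviation near 0.09,
inflated further by correlation between folds, so individual null AUCs
outside $[0.35, 0.65]$ are expected in roughly a fifth of replicates;
the permutation test, which calibrates against exactly this variability,
is the quantity that stays uniform under the null.

## Subtyping conventions

The elbow curve reports $\sum D_{within}/\sum D_{between}$ with
$\sum D_{within}$ the sum over points of the Euclidean distance to their
centroid and $\sum D_{between}$ the sum over unordered centroid pairs of
centroid–centroid distance; squared variants are available by flag. The
choice of unsquared distances is a convention — the symbols alone do not
fix it — and the elbow pick itself is left to visual inspection, with the
largest-second-difference knee reported only as a suggestion.

k-means uses k-means++ seeding with 100 restarts under a fixed RNG seed,
Lloyd iterations from `stats::kmeans`, and best-restart selection by the
within-distance convention above. Cluster labels are canonicalized by
descending centroid `idxP_ph`, so reported labels are stable under point
reordering. Points are clustered unstandardized — both axes are already
mean-Fisher-z values on a common scale.

Outlier handling before subtyping is a single pass: means and SDs of
`idxP_ph` and `idxR_ph` are computed on the full sample and a subject is
excluded when *either* index lies more than 3 SD out. Applying the rule
to either index (rather than requiring both) is the stricter reading and
is the package's choice.

## Numerical conventions

* Fisher-z clipping at $1 - 10^{-7}$ keeps maps finite
  ($\mathrm{atanh}(1 - 10^{-7}) \approx 8.41$ is the maximum attainable
  z); zero-variance voxels map to $z = 0$ with a warning rather than NaN
  so cohort matrices stay dense.
* The band-pass is an ideal frequency-domain filter (bins inside
  the band kept inclusively, DC removed); it is exactly idempotent and
  exactly testable on bin-aligned sinusoids. A zero-phase Butterworth
  (order 4) is available for users who prefer a smooth transition band.
* All covariates are centred at training means before each fit; the
  partial likelihood is shift-invariant, so this changes nothing
  statistically and prevents overflow of $e^{\eta}$.
* Maps are float32 on disk, float64 in computation. Cohort matrices use
  the flattened in-mask voxel order of the reference mask, and fixture
  sidecars carry an MD5 of the mask so misaligned cohorts fail loudly.
* Default problem sizes in the test suite (cohorts of 20–80 subjects,
  grids of $10^3$–$20^3$, 200 permutations) were chosen to make every
  statistical property measurable in a few minutes on one CPU; the same
  code runs unchanged at larger sizes.

## Known limitations

* Registration, slice timing, and spatial normalization are out of
  scope: the pipeline expects already-registered volumes on a common
  grid.
* The ROC is a fixed-cutoff binary ROC, not a time-dependent AUC.
* No cluster-extent or TFCE-style spatial thresholding at screening.
* K-fold and repeated cross-validation variants, frailty or
  time-varying-covariate Cox models, and gap-statistic style cluster
  validation are deliberately not implemented.
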