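# coxfc

Seed-based functional-connectivity survival modelling for individual
relapse prognosis, with nested leave-one-out cross-validation,
permutation-tested ROC evaluation and circuit-based disease subtyping.

## The problem

In longitudinal treatment studies (the motivating setting is substance-use
disorder with a 168-day follow-up), each participant either relapses at an
observed day or reaches the end of follow-up abstinent — a censored
time-to-event outcome. `coxfc` asks whether resting-state functional
connectivity (FC) of a chosen seed region predicts each individual's time
to relapse, and which voxels carry that prognosis. It is aimed at
neuroimaging groups running seed-based prognosis analyses on small-to-
moderate cohorts, where honest out-of-sample evaluation matters most.

## The model

Every stage is built on the Cox proportional-hazards model

```
h(X_i, t) = h0(t) · exp( Σ_j x_ij β_j )
```

estimated by maximizing the partial likelihood (Newton–Raphson,
Breslow or Efron ties; self-contained compiled engine). The pipeline:

1. **QC** — framewise displacement from rigid-body parameters, >0.35 mm
   volume censoring, subject exclusion at mean FD > 0.2 mm or >20%
   censored volumes.
2. **Cleaning + connectivity** — polynomial detrending, nuisance
   regression, 0.012–0.1 Hz band-pass; per-voxel seed correlation,
   Fisher-z (`z = atanh(cc)`).
3. **Screening** — a univariate Cox fit per voxel; two-sided Wald
   p < 0.001 splits voxels by coefficient sign into *protective*
   (HR < 1) and *risk* (HR > 1) circuit masks.
4. **Composite indices + final model** — `indexP`/`indexR` are sums of
   Fisher-z over each mask; the final Cox model adds age, sex, education,
   cigarettes/day and head motion as covariates.
5. **Nested LOOCV + permutation test** — screening and fitting are redone
   with each subject held out; out-of-fold risk scores are evaluated by
   ROC at a follow-up cut-off (30/90/168 days), with significance from an
   empirical null that re-runs the entire analysis on permuted outcomes.
6. **Subtyping** — per-fold masks stack into circuit-frequency heat maps;
   >85%-of-folds group circuits give per-subject mean indices
   (`idxP_ph`, `idxR_ph`), which feed an outlier rule, a
   protective–risk regression, an elbow curve and k-means subtypes.

Real cohorts of this kind are restricted-access clinical data, so the
package ships a synthetic-cohort generator (`simulate_cohort`) with
planted protective/risk circuits, log-linear hazard and administrative
censoring — every stage is testable end to end with known ground truth.

## Worked example

```r
library(coxfc)

cfg    <- sim_config(n_subjects = 60, rng_seed = 7)   # planted circuits
cohort <- simulate_cohort(cfg)
print(cohort)
#> <sim_cohort> n = 60 | events = 44 | 3112 voxels | circuits 50 + 50

stats <- voxelwise_cox(cohort$fc, cohort$outcome)
masks <- threshold_maps(stats, alpha = 0.001)
print(masks)
#> <circuit_masks> alpha = 0.001 | protective: 32 | risk: 53 voxels

cv <- loocv(cohort$fc, cohort$records, cohort$outcome,
            alpha = 0.001, cutoff_days = 90)
print(cv)
#> <cv_result> n = 60 folds | alpha 0.001 | cutoff 90 d | AUC 0.8348
#>   voxels/fold: protective 29.1, risk 52.4 (means)

pt <- permutation_test(cohort$fc, cohort$records, cohort$outcome,
                       alpha = 0.001, cutoff_days = 90,
                       n_perm = 199, rng_seed = 7)
print(pt)
#> <perm_test> AUC 0.8348 | p = 0.01 (199 permutations, full mode)

km <- kaplan_meier(cohort$outcome)
sprintf("relapse by day 90: %.1f%%", 100 * (1 - km_survival_at(km, 90)))
#> "relapse by day 90: 56.7%"
```

Reading the numbers: the screen recovers most of the 50+50 planted
circuit voxels at p < 0.001 while admitting almost no null voxels; the
cross-validated AUC of 0.83 says the out-of-fold risk scores separate
subjects who relapse within 90 days from those who do not; and the
permutation p of 0.01 is the rank of that AUC in a null built by
re-running the whole pipeline on 199 permuted outcomes. The Kaplan–Meier
curve summarizes the cohort's relapse course itself.

A command-line surface over the same functions lives at
`inst/cli/coxfc.R` (subcommands `simulate`, `qc`, `fc`, `screen`,
`loocv`, `permtest`, `subtype`).

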