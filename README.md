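# hdpsbench

Benchmarking automated data-adaptive propensity-score adjustment under
strong confounding by indication, on synthetic linked claims + clinical
registry cohorts.

## The problem

Comparative-effectiveness studies built on routinely collected data are
threatened by *confounding by indication*: when a treatment is indicated
only for a clinically distinct group, crude comparisons largely measure
prognosis, not effect.  The canonical example implemented here is carotid
artery stenting (CAS) vs. carotid endarterectomy (CEA) in the era when
stenting was reimbursed only for patients at *high surgical risk* — a
status recorded carefully in a clinical registry but badly proxied by
billing codes.  Randomized evidence supports a mortality hazard ratio
near 1.0, so any upward drift in an adjusted estimate is residual bias.

`hdpsbench` asks: how much of that bias can each combination of

1. **PS modeling strategy** — investigator-specified variable lists vs.
   the automated high-dimensional propensity score (hdPS) engine,
2. **data source** — claims only, registry only, both, or both with the
   high-surgical-risk dimension deliberately blinded, and
3. **adjustment approach** — 1:1 caliper matching, PS quintiles, and
   quintiles after 5% asymmetric trimming

remove, when the truth is known because the cohort is simulated?

## The methods inside

* **Cohort simulator** — latent binary clinical conditions drive a
  logistic treatment model and a proportional-hazards death model
  (exponential baseline, lognormal hospital frailty, administrative
  censoring).  Conditions surface in a registry (5 dimensions, with
  MCAR/MAR missingness) and as noisy claims codes (6 dimensions,
  per-dimension sensitivity, zero-truncated Poisson counts, plus pure
  noise codes).  The default scenario is calibrated so ~38% receive the
  stenting analog, high surgical risk is ~97% vs ~45% by arm, 3-year
  mortality sits in the 15–26% band per arm, and the crude HR is well
  above 1.3 while the true HR is 1.0.
* **hdPS engine** — per-dimension candidate screening (prevalence floor,
  top codes by deviation from ubiquity `min(p, 1-p)`), recurrence
  expansion into *once / sporadic / frequent* indicators at the median
  and 75th percentile of positive counts, and prioritization by the
  Bross bias multiplier

  `BM = (PC1 (RR - 1) + 1) / (PC0 (RR - 1) + 1)`

  with `PC1`/`PC0` the covariate prevalences by arm and `RR` its crude
  outcome relative risk (clamped to `max(RR, 1/RR)`); covariates are
  ranked by `|log BM|` and the top k = 500 selected.
* **PS estimation** — ridge-penalized logistic regression (IRLS, penalty
  ladder 1e-6 → 1e-3 → 1e-1 under separation), concordance c-statistic.
* **Adjustment** — greedy 1:1 nearest-neighbor matching within a caliper
  of 0.2 SD of the logit PS; quintile stratification with interpolated
  cut points; asymmetric trimming at the 5th percentile of the exposed
  and 95th of the unexposed PS.
* **Estimation** — Kaplan–Meier 3-year cumulative incidence (Greenwood,
  log(-log) CI) and Cox HRs (Efron ties) with a cluster-robust sandwich
  at the hospital level (pair level for matched designs), via the
  survival package; registry missingness handled by conditional-draw
  multiple imputation pooled with Rubin's rules.
* **Evaluation grid** — every (model × adjustment) cell on one cohort,
  and a replication engine reporting per-cell bias, empirical SE, RMSE
  and benchmark coverage.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a
thin driver over exported functions.  `Rscript analysis/01_simulate_cohort.R`
prints the calibration of the shipped cohort:

```
cohort: 5254 patients, 1964 exposed (37.4%)
high surgical risk: 97.1% exposed vs 43.6% unexposed
3-year mortality (exposed): 23.2% (21.4-25.1)
3-year mortality (unexposed): 16.7% (15.5-18.0)
crude HR: 1.45 (1.27-1.65) — confounded upward, truth is 1.0
```

`Rscript analysis/04_design_grid.R` then runs the full grid; the
quintile-adjusted column tells the story:

```
              model_id   hr ci_lo ci_hi c_statistic
 investigator_registry 1.01 0.897  1.14       0.815
         hdps_registry 1.01 0.897  1.14       0.815
             hdps_both 1.02 0.881  1.18       0.873
     investigator_both 1.02 0.903  1.16       0.819
   investigator_claims 1.25 1.093  1.43       0.704
  hdps_both_minus_risk 1.29 1.120  1.48       0.760
           hdps_claims 1.33 1.155  1.53       0.756
```

Claims-only models — automated or not — leave most of the planted bias
in place because the decisive confounder lives in the registry; blinding
the combined-source hdPS to the high-surgical-risk dimension puts the
bias back.  `analysis/05_replicate_grid.R` repeats the key cells over
independent cohorts and reports bias, RMSE and coverage per cell.

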