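---
title: "Benchmarking propensity-score confounding adjustment with a known truth"
author: "hdpsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking propensity-score confounding adjustment with a known truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hdpsbench)
```

## What this package models

Treatment choice between two revascularization procedures is assumed to
be dominated by a clinical composite — *high surgical risk* — that is
recorded faithfully in a procedure registry but only weakly reflected in
billing claims.  Because that composite also predicts death, a crude
comparison of the two procedures is biased upward even when the true
effect is null.  The package simulates this situation end to end and
measures how much of the planted bias each propensity-score (PS) design
removes, with the truth available by construction.

The generative model, per patient $i$:

* latent conditions $C_{ik} \sim \mathrm{Bernoulli}(\pi_k)$, independent
  across conditions and patients;
* treatment $A_i \sim \mathrm{Bernoulli}(\mathrm{expit}(\alpha_0 +
  \sum_k \beta_k C_{ik}))$;
* death time $T_i$ from a proportional-hazards model with hazard
  $\lambda_0 \, t^{\kappa-1}\exp(\theta A_i + \sum_k \gamma_k C_{ik} +
  \mathbf{d}_i'\boldsymbol\delta)\,u_{h(i)}$, where $\mathbf d_i$ are
  demographics (modest age and sex effects, balanced across arms),
  $u_h$ is a lognormal hospital frailty, and $\kappa = 1$ (exponential)
  by default;
* administrative censoring at a fixed horizon; follow-up is
  $\min(T_i, c)$.

Exponential baseline is the default because it is the simplest process
whose marginal-over-time Cox coefficient equals the generating log
hazard ratio; a Weibull shape is available for sensitivity runs.
Conditions surface twice: the registry records each one in its clinical
dimension with capture probability 1 by default, then loses values MCAR
at configured rates (a MAR variant tilted by exposure exists for
sensitivity analyses — rates are reported in the literature, mechanisms
are not, so MCAR is the default); claims emit one code per condition per
data dimension with a per-dimension sensitivity and a zero-truncated
Poisson occurrence count, plus independent noise codes whose prevalences
are drawn log-uniformly on [0.01, 0.3] so the candidate-screening
prevalence filter is non-trivially exercised.

## The default scenario and its calibration

`default_scenario()` ships 11 conditions.  The high-surgical-risk
composite has population prevalence 0.643, a treatment log-odds of 3.70
against an intercept of -3.95, a log hazard ratio of 0.50, registry
capture 1, and claims sensitivity 0.15 — the anatomy-type content of the
composite (lesion level, laterality) is essentially invisible to billing
codes, which is the scientific crux.  A heart-failure condition is the
strongest *claims-capturable* confounder (sensitivity 0.85), and the
remaining conditions (symptomatic status, coronary disease, diabetes,
COPD, cancer, renal failure, contralateral occlusion, antiplatelet use,
hyperlipidemia) carry smaller effects with prevalences taken from the
kind of marginal case-mix published for such cohorts.  The two treatment
knobs were solved from the three targeted marginals — 38% treated, and
composite prevalence 96.7% / 44.5% by arm — via the exact two-point
logistic identity, then verified by simulation at n = 100{,}000; the
baseline hazard (6.4e-5 events/day) centers untreated 3-year mortality
near 17% with the treated arm landing near 23%, inside the intended
15–26% band, and the crude hazard ratio near 1.4 while the true effect
is null.  Default missingness: heart failure 17.6%, hyperlipidemia
33.2%, contralateral occlusion 5.4%.  Clustering: 40 hospitals with 5
physicians each, frailty SD 0.2 — real analyses cluster at both levels
but magnitudes are never published; single-level hospital clustering is
the robust-variance default, with a physician option.  Two-way
clustering is out of scope.

What the generator does **not** emulate: correlated conditions (the
latent indicators are independent, so it cannot reproduce a published
joint case-mix, only marginals), code semantics (tokens are opaque),
calendar structure within the baseline year (counts are pre-collapsed),
informative censoring, and treatment-effect heterogeneity.  Passing
tests therefore show that each estimator removes the *kind* of bias
planted here, not that real claims–registry linkages behave this way.

## The automated covariate engine

Candidate screening keeps, per data dimension, codes with patient-level
prevalence at least 0.01 and then the top 200 by deviation from
ubiquity, $\min(p, 1-p)$, ties broken lexicographically.  The
prevalence floor is the conventional "1% or more"; the deviation
ordering is what makes a per-dimension cap meaningful, since a code
carried by everyone can separate no one.  Both knobs are exposed.

Each surviving code expands into up to three binary recurrence
covariates: count $\ge 1$ (*once*), count $\ge$ median of positive
counts (*sporadic*), and count $\ge$ 75th percentile of positive counts
(*frequent*), quantiles interpolated linearly over patients with at
least one occurrence; a level whose indicator duplicates a lower level
is dropped.  Registry variables enter as their own dimensions with
counts in {0, 1} (recurrence collapses to *once*); a continuous registry
variable would be binarized at its cohort median.

Prioritization uses the Bross bias multiplier
$(PC_1(RR-1)+1)/(PC_0(RR-1)+1)$ on the binary
any-death-during-follow-up outcome, ignoring censoring time — the
ranking literature specifies an outcome association, not a
survival-aware one, and at ~3-year horizons with administrative
censoring the binary proxy orders covariates the same way.  Two
numerical choices, both switchable: when any cell of the covariate ×
outcome table is zero, 0.1 is added to all four cells so $RR$ stays
finite; and $RR$ is clamped to $\max(RR, 1/RR)$ so protective proxies
rank symmetrically with harmful ones.  Covariates are ordered by
$|\log BM|$ (ties lexicographic on dimension, code, level) and the top
k = 500 selected.  Because prioritization is per-covariate, blinding a
dimension and re-selecting (`hdps_exclude()`) is exactly equivalent to
excluding it before ranking; the blinded combined-source model reuses
the assessed set this way.

## Propensity models and adjustment

Seven model variants mirror the study design: investigator-specified
lists on claims, registry, and both, and hdPS selections on claims,
registry, both, and both-minus-risk.  Demographics (age group, sex,
race analog, procedure year) are always forced in.  The investigator's
claims list contains any-occurrence indicators of the clinically named
code groups plus utilization summaries (log total claims, log distinct
codes, any nursing-home code) — the simulator numbers clinical-concept
codes below 1000, which is how "codes an investigator would know to
pre-specify" is represented without leaking the truth record; noise
codes and recurrence structure are available only to the automated
engine, which is precisely its advantage on claims.

PS estimation is logistic regression by IRLS with a ridge penalty of
1e-6 on non-intercept coefficients, escalating through 1e-3 and 1e-1 if
the fit fails to converge: near-deterministic indication makes
quasi-separation an expected condition, not an error.  Scores are
clipped to (1e-12, 1 - 1e-12).  Discrimination is the exposed-vs-
unexposed concordance, computed by a rank statistic with an $O(n_1 n_0)$
enumeration kept as a cross-check.

Adjustment conventions, fixed for determinism:

* *Matching*: greedy 1:1 nearest neighbor on the logit PS without
  replacement, exposed processed in descending PS order, distance ties
  to the smaller unexposed id.  The caliper "0.2 times the logit of the
  propensity score" is read as 0.2 × SD of the logit PS — the standard
  Austin caliper; the literal reading is dimensionally incoherent, and
  an absolute-width flag provides it anyway.  Optimal matching is out
  of scope.
* *Quintiles*: cut points at the 20/40/60/80th interpolated percentiles
  of the analysis sample; a score equal to a cut point falls in the
  lower stratum.  Quintiles enter the Cox model as indicator terms by
  default (a strata flag exists); the phrase "grouping patients into
  quintiles" describes covariate adjustment more naturally than
  baseline-hazard stratification, and indicators keep the estimate
  comparable across cells.
* *Trimming*: exposed below the 5th percentile of the exposed PS and
  unexposed above the 95th of the unexposed PS are removed; quintiles
  are recomputed on the retained sample (recomputation keeps strata
  non-degenerate); the PS is *not* re-estimated by default, with a flag
  for the re-estimation variant.

## Survival estimation, imputation, and the grid

Hazard ratios come from Cox partial likelihood with Efron ties
(simulated times are continuous, so ties are rare and the choice is
cheap insurance) and a cluster-robust sandwich aggregated at the
hospital level — pair level for matched designs.  Kaplan–Meier 3-year
cumulative incidence uses Greenwood variance with log(-log) limits.

Registry missingness is handled by conditional-draw multiple
imputation: each missing value is drawn from the observed distribution
of its variable within exposure × outcome cells (marginal fallback with
a warning when a cell is empty), m = 5 by default.  Chained equations
would add little here because the default missingness is MCAR and the
variables binary; the interface admits a richer engine.  The whole
downstream pipeline — ranking, PS fit, adjustment, Cox — is re-run
inside each completed dataset and the log hazard ratios pooled by
Rubin's rules ("within" MI; averaging the PS across imputations is left
as a flag).  All grid cells share one imputation set so cell contrasts
reflect the PS design alone, and cell failures are recorded per cell
rather than aborting the grid.

## Problem sizes and replication scale

Single-cohort runs use the full defaults: n = 5254, k = 500, m = 5.
Replication runs use a reduced scale chosen a priori: the four cells
the bias-ordering comparison needs (investigator/claims, hdPS/claims,
hdPS/both, hdPS/both-minus-risk), quintile adjustment, m = 2, and
k = 150 — the synthetic code universe holds only ~300 distinct codes
(~750 covariates after recurrence expansion), so k = 150 already
saturates the informative set, and m affects pooled points only through
Monte-Carlo noise.  The shipped replication uses 50 cohorts for the
bias ordering, 20 for discrimination and ranking-recovery rates, and 50
for null-calibration coverage, sizes at which a ±10 percentage-point
statement about a coverage or recovery rate is resolvable.

## Known limitations

Registry-only adjustment is nearly unbiased *in this scenario* because
every confounder is registry-captured at probability 1; real registries
miss claims-visible frailty proxies, a direction the generator can
express (set `registry_capture` < 1) but the default does not.  The
Bross prioritization ignores censoring time; two-way (hospital and
physician) robust variance is not implemented; matching is greedy, not
optimal; and the benchmark logic presumes the randomized-evidence null
transports to the simulated population — trivially true here, famously
arguable with real data.
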