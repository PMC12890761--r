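---
title: "Methods: the nephrarisk risk framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nephrarisk risk framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter,
what the synthetic generator does and does not emulate, and the numerical
conventions used throughout. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The clinical risk engine

The deployed score is a literature-coefficient proportional-hazards
calculator over a 36-month horizon:

$$\mathrm{risk}_{36} = 1 - \exp\{-36 \cdot h_{s} \cdot e^{\eta}\}, \qquad
\eta = \sum_k \beta_k\, t_k(x_k),$$

with a stage-specific monthly base hazard $h_s$ (0.00048, 0.0013, 0.0030,
0.0070, 0.016 for no CKD through stage 4) and published per-covariate log
hazard ratios $\beta_k$ applied to transformed deviations $t_k$ from
clinical reference values (age 60 y, BMI 25, SBP 120 mmHg, HbA1c 7%,
ACR 10 mg/g, full adherence, waist 100 cm, duration 0 y).

Key conventions:

* **Survival form.** "Monthly hazard" is read as a continuous rate, so the
  horizon risk is $1-\exp(-h\,t\,\mathrm{HR})$. The discrete-compounding
  alternative $1-(1-h)^t$ differs by under 0.1% at these magnitudes; the
  transform is isolated in `predict_risk36()` so it could be swapped.
* **eGFR enters twice, deliberately separated.** The stage base hazard
  carries the between-stage gradient; the continuous HR 1.24 per 10 mL/min
  acts on the deviation from a stage-specific reference (95, 75, 52, 37,
  22 — bracket midpoints). This keeps both published constants live
  without double counting. Stage boundaries are assigned to the
  better-function stage (90 → no CKD, 60 → stage 1–2), matching the
  bracket labels.
* **ACR transform.** $\log_2(\mathrm{ACR}/10)$ with a floor at 1 mg/g: a
  "per log₂ unit" effect needs a reference, and 10 mg/g is the
  normal-range anchor.
* **Categories.** Left-closed bins at 5/15/30%: a boundary risk belongs to
  the higher category, consistent with the ">30%" label of the top band.
* **Uncertainty.** Half-width $(0.05 + n \times 0.01)$ as a fraction of
  the risk, where $n$ counts *supplied* (non-missing) predictors — the
  interval widens with model complexity actually used. Missing features
  contribute zero to $\eta$ and are excluded from $n$.
* **Safety bounds.** Inputs outside the validity ranges (eGFR 5–150,
  HbA1c 4–20%, and physiologic ranges for the rest) are refused, never
  silently clipped.

Per-feature attributions are exact for this additive model:
`clinical_gain()` reports mean absolute log-hazard contributions
normalised to percent (a permutation fallback covers black-box learners).
Note a structural consequence of the published constants: retinopathy
grade HRs of 2.9–16.6 with half the population above grade 0 give that
single variable a larger mean absolute contribution than eGFR and ACR
combined, so exact attribution ranks it first on the synthetic cohort.

## 2. The prior registry

`priors.json` encodes each literature-informed variable: kind (binary /
ordinal / quintile), prevalence or category probabilities, hazard
ratio(s), an optional 95% CI, a source label, and an optional conditioning
map. The standard error of a log-HR is taken from the printed CI as
$(\ln\mathrm{hi}-\ln\mathrm{lo})/3.92$, else defaults to 0.10. Scaling for
sensitivity analysis is multiplicative on the log-HR scale — "shrinkage
toward null" means toward HR 1 — so scale 0 reproduces flat priors and
scaling composes multiplicatively.

Two registry values are package choices rather than published numbers:

* The deprivation quintile has published uniform prevalences but no
  printed effect size; we store a weak per-quintile-step gradient of
  ln(1.05) (se 0.05) so the variable is live but minor, consistent with
  its small reported contribution.
* Medication prevalences are not printed; we use field-realistic rates
  (SGLT2i 0.30 — consistent with the published fairness table's treated
  fraction — ACE/ARB 0.55, GLP-1 RA 0.15, finerenone 0.05, statin 0.60).

The combined protective-therapy HR printed in the source literature (0.66)
is not the product of the component HRs; the registry stores components
only and makes no attempt to reproduce the combined figure.

## 3. The synthetic cohort generator

`generate_cohort()` emulates the registry's study conditions: covariate
marginals (age 58.8 ± 11.4, 56.8% female, BMI 32.2 ± 6.6, HbA1c 8.1 ± 1.6,
hypertension 67.2%, CKD-stage mix 55.2/34.6/7.0/2.3/0.9%), log-normal ACR
and FGF-23 matched to printed median/IQR (the printed ACR mean/SD of
92.2 ± 420.2 is incompatible with any log-normal that also matches the
median 17 — both cannot hold, and the median/IQR is the better-identified
pair), observed-lab missingness rates (HbA1c 38%, waist 43.8%, FGF-23 15%,
ACR 9.4%, phosphorus 4%), ground-truth literature-informed variables drawn
from the registry prevalences, and exponential event times with monthly
rate $h_{s}\,m\,e^{\eta}$.

Two scalars are solved numerically (by `uniroot` on the realised draws, so
generation stays reproducible) and logged as attributes:

* a **hazard multiplier** $m$ so that the negative:positive ratio at 36
  months among determinable-status patients is 9.5. A multiplier below 1
  is expected: the published base hazards already absorb typical covariate
  burden, whereas the generator's linear predictor re-applies it.
* a **dropout window** for administrative censoring. The temporal design
  guarantees every patient the opportunity for complete 36-month
  follow-up from the study end (enrolment window + 36 months), so
  truncation before the horizon is modelled as a uniform per-patient
  dropout time whose window width is tuned to make the
  censored-before-36-months fraction exactly 10.1%. Tying censoring
  purely to late index dates would instead make the entire test window
  indeterminable at the horizon, contradicting the split design.

Competing death/transplant events occur at a fixed 0.2%/month and are
recorded as censoring. Follow-up is stored in whole months: event months
are ceilings (which preserves the 36-month status exactly), censoring
months are floors. Adherence scores, for which no distribution is
printed, are drawn from a truncated normal (7.5 ± 2 on 0–10).

What the generator does **not** emulate: longitudinal lab trajectories
(one index visit per patient; the registry's visit-level percentages are
an acknowledged discrepancy), correlation between covariates beyond what
the risk model uses, non-proportional hazards, and any group × risk
interaction — so a passing fairness audit on synthetic data shows the
audit machinery works, not that any real model is fair.

Parameter recovery is the generator's validation: a Cox refit on the true
covariates of a 50,000-patient cohort (stratified by stage, Efron ties)
returns each generating HR within Monte-Carlo error
(`recover_hazard_ratios()`, exercised by the acceptance suite).

## 4. Dual imputation

Observed variables below 40% missingness get median fill plus a
`miss_*` indicator (the missingness pattern itself is informative);
variables at or above the threshold are left to chained imputation and
logged — under the default rates only waist circumference crosses the
threshold.

Fully-missing literature-informed variables are imputed by a chained
Bayesian sampler. Per chain and sweep, each variable's parameters are
drawn from the literature prior — prevalence on the logit scale (se 0.05),
conditioning coefficients from $N(\text{scale}\times\beta, se)$ — and
patient values are sampled conditional on z-scored observed covariates
through a logistic link whose intercept is solved so the marginal
prevalence equals the drawn value. Because these variables have *no
observed data*, imputed values carry no information about their own
parameters; feeding them back would be circular. The sampler therefore
never conditions parameters on imputed values (a cut model): the
parameter conditional is exactly the prior, chains are stationary from
the first sweep, and convergence diagnostics measure mixing of the
monitored summaries.

Defaults are 20 chains and 10 burn-in sweeps, returning one completed
dataset per chain (M = 20). The sampler additionally runs 60 monitored
post-burn-in sweeps solely so the Gelman–Rubin statistic — computed from
the between/within-chain variance of the per-sweep prevalence (binary) or
mean grade (ordinal) — has enough draws to be stable; with fewer than ~30
monitored sweeps the R̂ estimator's own sampling noise exceeds the 1.01
convergence criterion it is compared against. Completed datasets remain
the final sweep of each chain.

The posterior-predictive check simulates replicate dataset sets from the
priors, standardises each summary by its prior-predictive scale
(estimated once by simulation), and reports the tail fraction of the
replicate discrepancy at or above the observed one — calibrated by
construction when imputations truly come from the priors, and near zero
when a prevalence is forced away from its prior.

The shipped registry's conditioning maps are empty: the source material
never states which covariates condition each imputed variable, and
independence is the only assumption-free default. Correlated imputation
is fully supported when a registry supplies coefficients (and scale 0
cuts it, restoring independence — coefficients shrunk exactly to zero
carry no association). One downstream consequence is worth stating
plainly: under independence the imputed draws are distributionally
invariant to the prior scale, so the four-scenario prior-sensitivity
spread of refit-model AUROC is exactly zero under a fixed seed. The
scenario machinery is still exercised end to end; a registry with
conditioning would produce genuine spread.

## 5. Splitting, censoring policy, ensemble, calibration

* **Temporal split** is patient-level, a function of index date only;
  windows default to the 70% and 85% index-date quantiles
  (train/validation/test ≈ 70/15/15). Overlap is
  impossible by construction and verified.
* **Censoring policy.** The binary learner drops patients whose 36-month
  status is administratively indeterminable (censored before 36 months
  without an event); censoring at exactly 36 months is a complete
  observation. Death/transplant before the horizon are retained as
  non-events. The survival learner keeps everyone.
* **Base learners** are pluggable contracts, not contributions: a
  gradient-boosted classifier (xgboost, class-weighted by the training
  split's negative:positive ratio) and a Cox model with a Breslow
  baseline whose 36-month survival converts to an event probability.
  A small random search (default 10 trials) over the published
  hyperparameter space is available but not default.
* **Stacking** uses the published combiner
  $\sigma(0.64\,\mathrm{logit}\,p_b + 0.36\,\mathrm{logit}\,p_s)$ in
  fixed mode; learned mode fits a ridge logistic meta-model
  ($\alpha = 0.01$) on the validation-window base logits. Inputs are
  clipped to $[10^{-6}, 1-10^{-6}]$.
* **Isotonic calibration** is fitted on the *stacked* validation
  predictions (the final-production reading of the development table),
  never on test-window patients; out-of-range inputs clamp to the fitted
  endpoints, and fewer than 10 points yields an identity calibrator with
  a warning.

## 6. Evaluation conventions

* **Censoring weights.** All IPCW metrics use the Kaplan–Meier estimate
  of the censoring survival $G$, evaluated left-continuously at event
  times (ties broken event-before-censor). The time-dependent AUROC is
  cumulative/dynamic at 36 months (case weight $1/G(T-)$, control weight
  $1/G(36)$); Uno's C weights usable pairs by $1/G(T_i-)^2$. Both reduce
  exactly to their uncensored counterparts, and both are verified against
  brute-force pair enumeration and, for Uno's C, against
  `survival::concordance(timewt = "n/G2")`.
* **Calibration** compares decile-mean predictions with
  $1-\mathrm{KM}(36)$ and Greenwood intervals; the slope is the Cox
  coefficient on $\log(-\log(1-\hat p))$ and the intercept the observed
  minus mean-predicted horizon risk on the same complementary log-log
  scale (survival-appropriate; the source method description names the
  Cox regression but not the scale).
* **Decision curves** compute TP/FP at the horizon from the KM event
  probability within the treat-positive group, so censoring is handled;
  net benefit follows $TP/n - FP/n \cdot p_t/(1-p_t)$, and
  events-prevented-per-1000 is $1000\times(NB - NB_{\text{treat-all}})$ —
  the standard decision-curve summary, chosen over a weighted-count
  reading of the verbal definition.
* **Fairness** flags $|\Delta\mathrm{AUROC}| > 0.03$ or slope outside
  0.8–1.2 per subgroup (largest group as reference), by threshold only —
  no p-values. Subgroups without both outcome classes (or under 20
  patients) are marked unassessable, never flagged.
* **Drift** flags an AUROC drop over 0.05 or a slope outside 0.85–1.15.
* **Optimism** refits on patient-level resamples; the BCa interval uses
  bias correction from the bootstrap distribution and acceleration from
  jackknifing the apparent statistic under the full-data model (a
  full refit jackknife at registry scale would be prohibitive).
* **Stability** reports 95% bootstrap prediction-interval widths in
  percentage points, banded <5 / 5–10 / >10, overall and by baseline risk
  category.
* **Threshold curves** interpolate sensitivity and false-positive rate
  across the full 0–1 threshold range with a monotone cubic spline
  (Hyman filtering) through the computed anchors, with the exact limits
  (sens, FPR) = (1, 1) at threshold 0 and (0, 0) at 1.

## 7. Problem sizes and reproducibility

Every stochastic stage takes an explicit seed (default 42) and derives
per-chain or per-replicate streams from it; an end-to-end run is
bit-reproducible for fixed library versions. The package's standard
analysis sizes — also used by the acceptance script — are n = 20,000 for
the default cohort, imputation and sensitivity runs, and n = 50,000 for
parameter-recovery refits; the sensitivity pipeline imputes 5 chains per
scenario and fits on 3 completed datasets, pooling predictions by
averaging (Rubin's rule for a probability point estimate). Unit tests use
smaller cohorts (300–6,000) with Monte-Carlo-error tolerances stated
inline.

## 8. Known limitations

* Independence-conditioned imputation makes imputed variables pure noise
  relative to individual outcomes; they match population margins but add
  no discrimination — visible in the near-identical performance of
  models with and without them, and in the zero prior-sensitivity spread
  discussed above.
* The engine assumes proportional hazards and additive log-hazard
  effects; no interactions or time-varying effects.
* The composite-outcome adjudicator defines "sustained" albuminuria as
  three consecutive monthly measurements at/above threshold (measurement
  cadence is not specified in the source material) and measures eGFR
  decline against the index baseline, not a rolling minimum.
* Fine–Gray competing-risk modelling is out of scope; death and
  transplant are censored (binary models treat them as non-events).
* The published headline metrics (AUROC ≈ 0.85, slope 0.98, +22/1000)
  are registry-data-dependent and are not reproduction targets; the
  synthetic-data analogues here validate self-consistency, not external
  performance.
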