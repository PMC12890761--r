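# nephrarisk

Literature-informed 36-month diabetic kidney disease (DKD/DN) risk
modelling for type 2 diabetes registries: a clinical risk engine built from
published hazard ratios, and the full development pipeline around it —
synthetic cohort generation, dual imputation with literature priors, a
stacked binary + survival ensemble with isotonic calibration, and a
survival-aware evaluation, fairness, stability and drift suite.

## Who this is for

Biostatisticians and clinical-ML engineers building or auditing 3-year
kidney-risk prediction for diabetes cohorts, where several important
predictors (family history of CKD, chronic NSAID use, retinopathy grade,
deprivation, nephroprotective medication) are absent from the registry and
must be imputed from external evidence rather than observed data.

## The model

The deployed clinical score is a proportional-hazards calculator on a
36-month horizon. For patient *i* with CKD stage *s(i)* (from eGFR
brackets 90/60/45/30/15):

    risk_36(i) = 1 − exp(−36 · h_s(i) · exp(η_i)),
    η_i = Σ_k β_k · x_ik

with stage-specific monthly base hazards *h* = 0.00048 / 0.0013 / 0.0030 /
0.0070 / 0.016 (no CKD … stage 4) and per-covariate log hazard ratios
β_k taken from published studies: age HR 1.16/decade, male 1.19, eGFR 1.24
per 10 mL/min decrease (within stage), ACR 1.30 per log₂ unit, HbA1c
1.13/%, diabetes duration 1.10/5 y, BMI 1.09/5 kg/m², SBP 1.07/10 mmHg,
current smoking 1.35, adherence 1.30 per 2-point decrease, waist 1.08/10 cm,
plus the literature-informed variables (family history 2.04, chronic NSAID
1.32, retinopathy grades 2.9/5.8/10.2/16.6, SGLT2i 0.61, ACE/ARB 0.77,
GLP-1 RA 0.79, finerenone 0.82, statin 0.88). Risks are categorised at
<5% / 5–15% / 15–30% / >30%, with an uncertainty half-width of
0.05 + n_features × 0.01 as a fraction of the risk.

Fully-missing covariates are imputed by Bayesian chained sampling from a
machine-readable prior registry (prevalences + scaled log-HR associations),
with Gelman–Rubin R̂ convergence checks and a posterior-predictive fit
p-value. The learned pipeline stacks a gradient-boosted binary classifier
with a Cox survival learner:

    P_ensemble = σ(0.64 · logit(P_binary) + 0.36 · logit(P_survival)),

calibrated isotonically on a patient-level temporal validation window.
Evaluation uses IPCW time-dependent AUROC, Uno's C, time-dependent Brier,
decile calibration (slope/intercept on the complementary log-log scale),
decision-curve net benefit NB = TP/n − FP/n · pt/(1−pt), subgroup fairness
thresholds (|ΔAUROC| > 0.03, slope outside 0.8–1.2), bootstrap optimism,
prediction-interval stability bands, and drift triggers (AUROC drop > 0.05,
slope outside 0.85–1.15).

## Worked example

```r
library(nephrarisk)

# a 62-year-old woman, stage s1_2 (eGFR 72), suboptimal control, on ACE/ARB
patient <- data.frame(
  patient_id = "EX", index_date = "2021-03", age = 62, sex = "female",
  bmi = 33, waist_circumference = 104, sbp = 142, dbp = 82, egfr = 72,
  acr = 40, hba1c = 8.5, diabetes_duration = 12, smoking = "never",
  medication_compliance = 8, lit_family_history_ckd = 1, lit_sglt2i = 0,
  lit_ace_arb = 1, lit_nsaid_chronic = 0, lit_dr_severity = 0,
  lit_imd_quintile = 3, lit_glp1_ra = 0, lit_finerenone = 0,
  lit_statin = 1, followup_months = 36, event = FALSE,
  censor_reason = "none")
predict_risk36(patient, risk_model_spec())
#>   patient_id   risk36 linear_predictor  category uncertainty        lo        hi
#> 1         EX 0.300322         2.032231 very_high        0.25 0.2252415 0.3754025
```

A predicted 36-month risk of 30.0% (interval 22.5–37.5%) puts the patient
in the very-high band (>30%): family history, a 2-log₂-unit ACR elevation,
the within-stage eGFR deficit and HbA1c 1.5 points above target multiply
the stage 1–2 base hazard by exp(2.03) ≈ 7.6.

End-to-end on synthetic data:

```r
cohort <- generate_cohort(generator_config(n_patients = 20000, seed = 42))
cohort <- impute_observed(cohort)
imp    <- mice_literature(cohort, default_registry(), chains = 20,
                          burn_in = 10, seed = 42)
max(imp$gelman_rubin)                         # 1.0026
100 * pooled_prevalence(imp, "family_history_ckd")  # 21.84 (prior: 21.8)
```

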