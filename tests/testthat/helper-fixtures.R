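# Shared fixtures, generated in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fun()
  .fixtures[[name]]
}

# The default study-conditions cohort (used by the acceptance checks).
default_cohort <- function() {
  fixture("default20k", function() {
    generate_cohort(generator_config(n_patients = 20000, seed = 42))
  })
}

# Large cohort for parameter recovery.
recovery_cohort <- function() {
  fixture("recovery50k", function() {
    generate_cohort(generator_config(n_patients = 50000, seed = 42))
  })
}

# Default-settings literature imputation on the default cohort.
default_imputation <- function() {
  fixture("imp_default", function() {
    mice_literature(default_cohort(), default_registry(),
                    chains = 20, burn_in = 10, seed = 42)
  })
}

# A single patient at every effect reference value (zero linear predictor).
reference_record <- function(...) {
  rec <- data.frame(
    patient_id = "ref", index_date = "2019-06",
    age = 60, sex = "female", ethnicity = "saudi",
    bmi = 25, waist_circumference = 100, sbp = 120, dbp = 80,
    egfr = 95, acr = 10, hba1c = 7, phosphorus = 3.8, fgf23 = 55,
    diabetes_duration = 0, smoking = "never",
    hypertension = FALSE, cvd = FALSE, medication_compliance = 10,
    followup_months = 40, event = FALSE, censor_reason = "none",
    true_family_history_ckd = 0, true_nsaid_chronic = 0,
    true_dr_severity = 0, true_imd_quintile = 1, true_sglt2i = 0,
    true_ace_arb = 0, true_glp1_ra = 0, true_finerenone = 0,
    true_statin = 0,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

# A small hand-written censored survival fixture for pairwise oracles.
censored_fixture <- function() {
  data.frame(
    pred = c(0.80, 0.55, 0.70, 0.30, 0.20, 0.40),
    time = c(10, 20, 25, 30, 40, 50),
    event = c(1, 0, 1, 1, 0, 0)
  )
}

# Brute-force IPCW cumulative/dynamic AUC: explicit double loop over
# case-control pairs with Kaplan-Meier censoring weights. Independent of
# the package's vectorised implementation.
brute_auroc_ipcw <- function(pred, time, event, horizon = 36) {
  G <- nephrarisk:::km_censoring(time, event)
  num <- 0
  den <- 0
  for (i in seq_along(pred)) {
    if (!(event[i] == 1 && time[i] <= horizon)) next
    for (j in seq_along(pred)) {
      if (!(time[j] > horizon)) next
      w <- (1 / G(time[i], minus = TRUE)) * (1 / G(horizon))
      conc <- if (pred[i] > pred[j]) 1 else if (pred[i] == pred[j]) 0.5 else 0
      num <- num + w * conc
      den <- den + w
    }
  }
  num / den
}

# Brute-force Uno's C: loop over usable pairs weighted by 1/G(T_i-)^2.
brute_unos_c <- function(pred, time, event, tau = NULL) {
  G <- nephrarisk:::km_censoring(time, event)
  num <- 0
  den <- 0
  for (i in seq_along(pred)) {
    if (event[i] != 1) next
    if (!is.null(tau) && time[i] >= tau) next
    for (j in seq_along(pred)) {
      if (!(time[j] > time[i])) next
      w <- 1 / G(time[i], minus = TRUE)^2
      conc <- if (pred[i] > pred[j]) 1 else if (pred[i] == pred[j]) 0.5 else 0
      num <- num + w * conc
      den <- den + w
    }
  }
  num / den
}
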