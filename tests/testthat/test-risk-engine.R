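spec <- risk_model_spec()

test_that("linear predictor reproduces the published per-feature logs", {
  ref <- linear_predictor(reference_record(), spec)
  expect_equal(ref$lp, 0, tolerance = 1e-12)
  expect_true(all(abs(ref$contributions) < 1e-12))

  smoker <- linear_predictor(reference_record(smoking = "current"), spec)
  expect_equal(smoker$lp, log(1.35), tolerance = 1e-12)
  expect_equal(smoker$lp, 0.3001, tolerance = 1e-4)

  aged <- linear_predictor(reference_record(age = 70), spec)
  expect_equal(aged$lp, log(1.16), tolerance = 1e-12)
  expect_equal(unname(aged$contributions[, "age"]), log(1.16))
  expect_equal(log(1.16), 0.1484, tolerance = 5e-4)
})

test_that("out-of-bounds inputs are refused with the safety bound", {
  expect_error(linear_predictor(reference_record(egfr = 160), spec),
               "safety-bound.*egfr.*150")
  expect_error(predict_risk36(reference_record(hba1c = 3.5), spec),
               "hba1c.*4")
})

test_that("missing features contribute zero and are counted", {
  rec <- reference_record(smoking = "current")
  rec$hba1c <- NA
  rec$acr <- NA
  res <- linear_predictor(rec, spec)
  expect_equal(res$lp, log(1.35), tolerance = 1e-12)
  full <- linear_predictor(reference_record(), spec)
  expect_equal(res$n_supplied, full$n_supplied - 2)
})

test_that("predict_risk36 follows the closed-form survival transform", {
  out <- predict_risk36(reference_record(), spec)
  expect_equal(out$risk36, 1 - exp(-36 * 0.00048), tolerance = 1e-12)
  expect_equal(out$risk36, 0.01713, tolerance = 1e-4)

  smoker <- predict_risk36(reference_record(smoking = "current"), spec)
  expect_equal(smoker$risk36, 1 - exp(-36 * 0.00048 * 1.35),
               tolerance = 1e-12)
  expect_equal(smoker$risk36, 0.02306, tolerance = 1e-4)

  # uncertainty: 0.05 + n_features x 0.01, interval around the risk
  n_feat <- linear_predictor(reference_record(), spec)$n_supplied
  expect_equal(out$uncertainty, 0.05 + n_feat * 0.01)
  expect_true(out$lo <= out$risk36 && out$risk36 <= out$hi)
  expect_equal(out$hi - out$lo, 2 * out$uncertainty * out$risk36,
               tolerance = 1e-12)
})

test_that("risk categories use left-closed published cutpoints", {
  expect_equal(as.character(categorize(0.04)), "low")
  expect_equal(as.character(categorize(0.05)), "moderate")
  expect_equal(as.character(categorize(0.10)), "moderate")
  expect_equal(as.character(categorize(0.15)), "high")
  expect_equal(as.character(categorize(0.30)), "very_high")
  expect_equal(as.character(categorize(0.35)), "very_high")
  expect_equal(as.character(categorize(1)), "very_high")
  expect_equal(as.character(categorize(0)), "low")
})

test_that("contributions decompose the linear predictor exactly", {
  co <- generate_cohort(generator_config(n_patients = 300, seed = 17))
  imp <- mice_literature(co, default_registry(), chains = 2, burn_in = 2,
                         monitor = 3, seed = 1)
  dat <- imp$datasets[[1]]
  dat$egfr[is.na(dat$egfr)] <- dat$true_egfr[is.na(dat$egfr)]
  res <- linear_predictor(dat, spec)
  expect_lt(max(abs(rowSums(res$contributions) - res$lp)), 1e-12)

  risks <- predict_risk36(dat, spec)
  expect_true(all(risks$risk36 >= 0 & risks$risk36 < 1))
  expect_true(all(risks$lo <= risks$risk36 & risks$risk36 <= risks$hi))
})

test_that("risk is monotone in risk-increasing and protective covariates", {
  base <- predict_risk36(reference_record(), spec)$risk36
  worse_hba1c <- vapply(c(8, 9, 11), function(h) {
    predict_risk36(reference_record(hba1c = h), spec)$risk36
  }, 0)
  expect_true(all(diff(c(base, worse_hba1c)) > 0))
  protected <- predict_risk36(reference_record(lit_sglt2i = 1), spec)$risk36
  expect_lt(protected, base)
  expect_gt(predict_risk36(reference_record(lit_family_history_ckd = 1),
                           spec)$risk36, base)
})

test_that("exponentiating the attribution gradient recovers the printed HRs", {
  # linear features: the per-unit contribution gradient is exactly log HR
  lo <- linear_predictor(reference_record(hba1c = 7.5), spec)
  hi <- linear_predictor(reference_record(hba1c = 8.5), spec)
  grad <- (hi$contributions[, "hba1c"] - lo$contributions[, "hba1c"]) / 1
  expect_equal(exp(unname(grad)), 1.13, tolerance = 1e-12)
  lo_b <- linear_predictor(reference_record(bmi = 27.5), spec)
  hi_b <- linear_predictor(reference_record(bmi = 32.5), spec)
  expect_equal(exp(unname(hi_b$contributions[, "bmi"] -
                            lo_b$contributions[, "bmi"])), 1.09,
               tolerance = 1e-12)
})

test_that("clinical gain attributions are exact for the engine", {
  # a single active effect takes 100%
  one <- function(df) (df$age - 60) / 10 * log(1.16)
  cohort <- do.call(rbind, lapply(1:50, function(i) {
    reference_record(age = 40 + i)
  }))
  cohort$patient_id <- sprintf("c%02d", 1:50)
  g1 <- suppressWarnings(
    clinical_gain(one, cohort, features = c("age"), iterations = 10))
  expect_equal(unname(g1["age"]), 100)

  # two features with equal coefficients and matched spread split 50/50
  set.seed(4)
  dat <- data.frame(a = stats::rnorm(4000), b = stats::rnorm(4000))
  lin <- function(df) df$a + df$b
  g2 <- clinical_gain(lin, dat, features = c("a", "b"), iterations = 40,
                      seed = 2)
  expect_equal(unname(g2["a"]), 50, tolerance = 0.1)

  # engine attribution on the synthetic cohort: kidney markers outrank
  # every other observed covariate
  co <- generate_cohort(generator_config(n_patients = 4000, seed = 19))
  dat2 <- as.data.frame(co)
  for (v in c("hba1c", "acr", "waist_circumference", "phosphorus",
              "fgf23")) {
    dat2[[v]] <- dat2[[paste0("true_", v)]]
  }
  for (e in names(default_registry()$entries)) {
    dat2[[paste0("lit_", e)]] <- dat2[[paste0("true_", e)]]
  }
  g3 <- clinical_gain(spec, dat2)
  kidney <- g3[["egfr_per10"]] + g3[["acr_log2"]]
  others <- g3[setdiff(names(g3),
                       c("egfr_per10", "acr_log2",
                         grep("^(family|nsaid|dr_|imd|sglt2i|ace|glp1|finer|statin)",
                              names(g3), value = TRUE)))]
  expect_true(all(kidney > others))
  expect_equal(sum(g3), 100, tolerance = 1e-9)
})

test_that("a constant predictor yields all-zero importances with a warning", {
  dat <- data.frame(a = 1:20, b = 21:40)
  expect_warning(g <- clinical_gain(function(df) rep(0.5, nrow(df)), dat,
                                    features = c("a", "b"),
                                    iterations = 4),
                 "constant predictor")
  expect_true(all(g == 0))
})
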