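test_that("temporal split is a disjoint exhaustive function of index date", {
  df <- do.call(rbind, lapply(1:3, function(i) reference_record()))
  df$patient_id <- c("a", "b", "c")
  df$index_date <- c("2019-05", "2021-01", "2021-10")
  co <- as_cohort(df)
  windows <- list(train = c(0, 23), validation = c(24, 29),
                  test = c(30, 35))
  sp <- temporal_split(co, windows)
  expect_equal(as.character(sp$split), c("train", "validation", "test"))

  dup <- df
  dup$patient_id <- c("a", "a", "c")
  expect_error(temporal_split(dup), "duplicate")

  outside <- df
  outside$index_date[2] <- "2030-01"
  expect_error(temporal_split(as_cohort(outside), windows),
               "outside all windows")
})

test_that("quantile windows give roughly 70/15/15 on the default cohort", {
  sp <- temporal_split(default_cohort())
  fr <- attr(sp, "fractions")
  expect_equal(unname(fr[["train"]]), 0.70, tolerance = 0.05)
  expect_equal(unname(fr[["validation"]]), 0.15, tolerance = 0.25)
  expect_equal(unname(fr[["test"]]), 0.15, tolerance = 0.25)
  expect_equal(nrow(sp), nrow(default_cohort()))
})

test_that("the censoring policy drops only indeterminable binary patients", {
  df <- do.call(rbind, lapply(1:4, function(i) reference_record()))
  df$patient_id <- letters[1:4]
  df$followup_months <- c(30, 12, 36, 20)
  df$event <- c(FALSE, TRUE, FALSE, FALSE)
  df$censor_reason <- c("administrative", "none", "administrative", "death")
  co <- as_cohort(df)

  bin <- censoring_filter(co, "binary")
  expect_setdiff <- setdiff(co$patient_id, bin$patient_id)
  expect_equal(expect_setdiff, "a")      # admin-censored at 30 dropped
  expect_true("b" %in% bin$patient_id)   # event at 12 kept
  expect_true("c" %in% bin$patient_id)   # censored exactly at 36 kept
  expect_true("d" %in% bin$patient_id)   # competing risk kept as non-event

  srv <- censoring_filter(co, "survival")
  expect_equal(nrow(srv), 4)
})

test_that("stack_predict evaluates the published combiner exactly", {
  expect_equal(stack_predict(0.5, 0.5), 0.5, tolerance = 1e-12)
  expect_equal(stack_predict(0.8, 0.2), 0.5958, tolerance = 1e-4)
  manual <- plogis(0.64 * qlogis(0.8) + 0.36 * qlogis(0.2))
  expect_equal(stack_predict(0.8, 0.2), manual, tolerance = 1e-15)
  expect_equal(stack_predict(0.7, 0.3, ensemble_spec(1, 0)), 0.7,
               tolerance = 1e-6)
  # extreme inputs are clipped, never infinite
  expect_true(is.finite(stack_predict(1, 0)))
})

test_that("equal base inputs pass through when weights sum to one", {
  for (p in c(0.05, 0.3, 0.62, 0.9)) {
    expect_equal(stack_predict(p, p), p, tolerance = 1e-6)
    expect_equal(stack_predict(p, p, ensemble_spec(0.25, 0.75)), p,
                 tolerance = 1e-6)
  }
})

test_that("the learned meta-model shrinks an uninformative base learner", {
  set.seed(10)
  n <- 4000
  p_true <- plogis(stats::rnorm(n, -2, 1.2))
  y <- stats::rbinom(n, 1, p_true)
  noise <- rep(0.5, n)
  spec <- fit_meta(p_true, noise, y)
  expect_equal(spec$meta, "learned")
  expect_gt(spec$w_binary, 0.5)
  expect_lt(abs(spec$w_survival), 0.1)

  # duplicated identical learners split the weight symmetrically
  spec2 <- fit_meta(p_true, p_true, y)
  expect_equal(spec2$w_binary, spec2$w_survival, tolerance = 0.05)

  expect_error(fit_meta(p_true, noise, rep(1, n)), "single-class")
})

test_that("fixed published weights are honoured without fitting", {
  ens <- ensemble_spec()
  expect_equal(ens$w_binary, 0.64)
  expect_equal(ens$w_survival, 0.36)
  expect_equal(ens$meta, "fixed")
})

test_that("isotonic calibration matches observed rates and stays monotone", {
  set.seed(6)
  n <- 6000
  p <- stats::runif(n, 0.02, 0.5)
  y <- stats::rbinom(n, 1, p)
  cal <- isotonic_calibrate(p, y)
  grid <- seq(0.02, 0.5, length.out = 50)
  out <- apply_calibrator(cal, grid)
  expect_true(all(diff(out) >= -1e-12))
  expect_lt(mean(abs(out - grid)), 0.03)  # near identity when calibrated

  # predictions that double the risk are pulled back to the observed rate
  doubled <- clip(2 * p, 0, 0.999)
  cal2 <- isotonic_calibrate(doubled, y)
  out2 <- apply_calibrator(cal2, 2 * grid)
  expect_lt(mean(abs(out2 - grid)), 0.035)

  expect_warning(id <- isotonic_calibrate(c(0.1, 0.9), c(0, 1)),
                 "identity")
  expect_equal(apply_calibrator(id, 0.42), 0.42)
  # out-of-range inputs clamp to the fitted endpoints
  expect_equal(apply_calibrator(cal, -1), apply_calibrator(cal, min(p)))
})

test_that("the full stacked ensemble fits, predicts and is deterministic", {
  co <- fixture("ens_cohort", function() {
    cohort <- generate_cohort(generator_config(n_patients = 4000,
                                               seed = 23))
    cohort <- impute_observed(cohort)
    imp <- mice_literature(cohort, default_registry(), chains = 2,
                           burn_in = 2, monitor = 3, seed = 3)
    imp$datasets[[1]]
  })
  sp <- temporal_split(co)
  tr <- as_cohort(co[sp$split == "train", ], "synthetic")
  va <- as_cohort(co[sp$split == "validation", ], "synthetic")
  te <- co[sp$split == "test", ]

  ens <- fit_ensemble(tr, va, nrounds = 60, seed = 42)
  p1 <- predict_ensemble(ens, te)
  expect_true(all(p1 >= 0 & p1 <= 1))

  ens2 <- fit_ensemble(tr, va, nrounds = 60, seed = 42)
  p2 <- predict_ensemble(ens2, te)
  expect_identical(p1, p2)

  # discrimination beats chance on the determinable test patients
  auc <- auroc_ipcw(p1, te$followup_months, te$event)
  expect_gt(auc, 0.55)

  # learned-meta route also runs
  ens3 <- fit_ensemble(tr, va, meta = "learned", nrounds = 60, seed = 42)
  expect_equal(ens3$spec$meta, "learned")
  expect_true(all(is.finite(predict_ensemble(ens3, te))))
})
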