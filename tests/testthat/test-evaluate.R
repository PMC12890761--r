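test_that("IPCW AUROC matches the brute-force weighted-pair oracle", {
  fx <- censored_fixture()
  expect_equal(auroc_ipcw(fx$pred, fx$time, fx$event, horizon = 36),
               brute_auroc_ipcw(fx$pred, fx$time, fx$event, horizon = 36),
               tolerance = 1e-10)
  # a second fixture with ties in the predictions
  fx2 <- data.frame(pred = c(0.5, 0.5, 0.7, 0.2, 0.9, 0.2, 0.4, 0.3),
                    time = c(5, 50, 12, 44, 20, 39, 60, 41),
                    event = c(1, 0, 1, 0, 1, 0, 0, 1))
  expect_equal(auroc_ipcw(fx2$pred, fx2$time, fx2$event, 36),
               brute_auroc_ipcw(fx2$pred, fx2$time, fx2$event, 36),
               tolerance = 1e-10)
})

test_that("IPCW AUROC reduces to the empirical AUC without censoring", {
  set.seed(12)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  p <- plogis(2 * y + rnorm(n))
  time <- ifelse(y == 1, 12, 60)  # events by 36, controls followed past it
  auc_emp <- {
    pos <- p[y == 1]; neg <- p[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auroc_ipcw(p, time, y, 36), auc_emp, tolerance = 1e-12)
  # perfectly separated risks
  expect_equal(auroc_ipcw(ifelse(y == 1, 0.9, 0.1), time, y, 36), 1)
  # uninformative predictor sits near one half
  set.seed(13)
  expect_lt(abs(auroc_ipcw(runif(n), time, y, 36) - 0.5), 0.06)
  expect_error(auroc_ipcw(p, rep(40, n), rep(0, n), 36), "undefined")
})

test_that("Uno's C matches the pairwise oracle and its reductions", {
  fx <- censored_fixture()
  expect_equal(unos_c(fx$pred, fx$time, fx$event),
               brute_unos_c(fx$pred, fx$time, fx$event),
               tolerance = 1e-10)
  # independent cross-check against the survival package's G^2 weighting
  cc <- survival::concordance(survival::Surv(time, event) ~ pred,
                              data = fx, reverse = TRUE,
                              timewt = "n/G2")
  expect_equal(unos_c(fx$pred, fx$time, fx$event),
               unname(cc$concordance), tolerance = 1e-6)

  # without censoring it is Harrell's C
  set.seed(14)
  t2 <- rexp(60); e2 <- rep(1, 60); p2 <- -t2 + rnorm(60, sd = 0.4)
  ch <- survival::concordance(survival::Surv(t2, e2) ~ p2,
                              reverse = TRUE)
  expect_equal(unos_c(p2, t2, e2), unname(ch$concordance),
               tolerance = 1e-10)
  # anti-concordant predictor is the mirror image
  expect_equal(unos_c(-p2, t2, e2), 1 - unos_c(p2, t2, e2),
               tolerance = 1e-10)
})

test_that("Brier and AUPRC behave on closed-form cases", {
  n <- 200
  y <- rep(c(1, 0), each = n / 2)
  time <- ifelse(y == 1, 10, 50)
  expect_equal(brier36(y, time, y, 36), 0, tolerance = 1e-12)
  p <- rep(0.3, n)
  expect_equal(brier36(p, time, y, 36), mean((0.3 - y)^2),
               tolerance = 1e-12)
  # all-positive fixture: AUPRC 1
  expect_equal(auprc36(runif(20), rep(10, 20), rep(1, 20), 36), 1,
               tolerance = 1e-12)
  # perfect ranking: AUPRC 1
  expect_equal(auprc36(y, time, y, 36), 1, tolerance = 1e-12)
})

test_that("calibration recovers slope 1 for self-consistent risks", {
  co <- default_cohort()
  cfg <- attr(co, "config")
  mult <- attr(co, "hazard_multiplier")
  h <- cfg$base_hazards[as.character(ckd_stage(
    ifelse(is.na(co$egfr), co$true_egfr, co$egfr)))]
  true_risk <- 1 - exp(-36 * mult * h * exp(co$true_lp))
  cal <- calibration(true_risk, co$followup_months, co$event)
  expect_equal(cal$slope, 1, tolerance = 0.05)
  expect_lt(abs(cal$intercept), 0.1)
  expect_equal(sum(cal$table$n), nrow(co))
  # decile points sit inside their Greenwood intervals most of the time
  inside <- with(cal$table, observed >= lo & observed <= hi)
  cover <- mean(with(cal$table, pred >= lo & pred <= hi))
  expect_gte(cover, 0.8)
  expect_true(all(inside))

  # a deliberately overdispersed score is detected
  cal2 <- calibration(true_risk^2, co$followup_months, co$event)
  expect_gt(abs(cal2$slope - 1), 0.1)
})

test_that("uncensored deciles reduce to raw event fractions", {
  set.seed(15)
  n <- 600
  p <- runif(n, 0.05, 0.6)
  y <- rbinom(n, 1, p)
  time <- ifelse(y == 1, 18, 48)
  cal <- calibration(p, time, y)
  grp <- cut(p, unique(quantile(p, seq(0, 1, 0.1))),
             include.lowest = TRUE, labels = FALSE)
  raw <- tapply(y, grp, mean)
  expect_equal(unname(cal$table$observed), unname(as.vector(raw)),
               tolerance = 1e-10)
})

test_that("net benefit follows the published formula", {
  expect_equal(net_benefit(87, 190, 1000, 0.1),
               0.087 - 0.190 * (0.1 / 0.9), tolerance = 1e-12)
  expect_equal(net_benefit(87, 190, 1000, 0.1), 0.06589, tolerance = 1e-4)
  expect_error(net_benefit(1, 1, 10, 1), "domain error")

  set.seed(16)
  n <- 800
  p <- runif(n, 0, 0.6)
  y <- rbinom(n, 1, p)
  time <- ifelse(y == 1, 12, 40)
  dca <- decision_curve(p, time, y, thresholds = c(1e-9, 0.05, 0.1, 0.2))
  prev <- attr(dca, "prevalence")
  # treat-model never beats the prevalence; pt -> 0 tends to TP/n
  expect_true(all(dca$nb <= prev + 1e-12))
  expect_equal(dca$nb[1], sum(y) / n, tolerance = 1e-3)
  # uncensored counts match direct classification counts at pt = 0.2
  expect_equal(dca$TP[4], sum(p >= 0.2 & y == 1), tolerance = 1e-8)
  expect_equal(dca$FP[4], sum(p >= 0.2 & y == 0), tolerance = 1e-8)
  expect_equal(dca$events_prevented_per_1000,
               1000 * (dca$nb - dca$nb_all), tolerance = 1e-12)
  expect_error(decision_curve(p, time, y, thresholds = 1.2),
               "domain error")
})

test_that("bootstrap optimism is near zero for a fixed model and positive for overfit", {
  co <- generate_cohort(generator_config(n_patients = 500, seed = 27))
  fixed <- function(cohort) {
    function(newdata) (100 - newdata$true_egfr %||% newdata$egfr) +
      newdata$true_lp
  }
  fixed <- function(cohort) function(newdata) newdata$true_lp
  res <- bootstrap_optimism(fixed, co, B = 20, seed = 1)
  expect_lt(abs(res$optimism), 0.02)
  expect_true(res$ci[1] <= res$corrected + 0.05)

  # memorising learner: perfect in-sample, chance out-of-sample
  memoriser <- function(cohort) {
    key <- sub("_.*", "", cohort$patient_id)
    val <- as.numeric(cohort$event) + 0.001 * seq_len(nrow(cohort))
    function(newdata) {
      k <- sub("_.*", "", newdata$patient_id)
      out <- val[match(k, key)]
      ifelse(is.na(out), 0.5, out)
    }
  }
  res2 <- bootstrap_optimism(memoriser, co, B = 20, seed = 2)
  expect_gt(res2$optimism, 0.05)
  expect_error(bootstrap_optimism(fixed, co, B = 1), "BCa")
})

test_that("fairness flags fire exactly at the published cutpoints", {
  expect_false(fairness_flags(-0.0299, 1.0))
  expect_true(fairness_flags(-0.0301, 1.0))
  expect_true(fairness_flags(0.04, 1.0))
  expect_false(fairness_flags(0.0, 0.801))
  expect_true(fairness_flags(0.0, 0.799))
  expect_true(fairness_flags(0.0, 1.201))
  expect_false(fairness_flags(0.0, 1.199))
  expect_false(fairness_flags(NA, NA))
})

test_that("the fairness audit passes homogeneous groups and catches broken ones", {
  co <- default_cohort()
  mult <- attr(co, "hazard_multiplier")
  cfg <- attr(co, "config")
  h <- cfg$base_hazards[as.character(ckd_stage(
    ifelse(is.na(co$egfr), co$true_egfr, co$egfr)))]
  p <- 1 - exp(-36 * mult * h * exp(co$true_lp))
  groups <- data.frame(sex = co$sex,
                       age_band = ifelse(co$age >= 65, ">=65", "<65"))
  tab <- fairness_audit(p, co$followup_months, co$event, groups)
  expect_false(any(tab$flag))
  expect_true(all(tab$assessable))

  # shuffling one group's predictions destroys its discrimination
  set.seed(20)
  broken <- p
  male <- co$sex == "male"
  broken[male] <- sample(broken[male])
  tab2 <- fairness_audit(broken, co$followup_months, co$event,
                         data.frame(sex = co$sex))
  expect_true(tab2$flag[tab2$level == "male"])

  # single-class subgroups are unassessable, never flagged
  tiny <- data.frame(grp = rep(c("x", "y"), c(nrow(co) - 5, 5)))
  tab3 <- fairness_audit(p, co$followup_months, co$event, tiny)
  expect_false(tab3$assessable[tab3$level == "y"])
  expect_false(tab3$flag[tab3$level == "y"])
})

test_that("drift flags fire exactly at the published thresholds", {
  mk <- function(auc, slope) list(auroc36 = auc, calib = list(slope = slope))
  base <- mk(0.852, 1.0)
  expect_true(drift_check(mk(0.79, 1.0), base)[["auroc_drift"]])
  expect_false(drift_check(mk(0.8021, 1.0), base)[["auroc_drift"]])
  expect_true(drift_check(mk(0.852, 1.16), base)[["slope_drift"]])
  expect_false(drift_check(mk(0.852, 1.149), base)[["slope_drift"]])
  expect_true(drift_check(mk(0.852, 0.849), base)[["slope_drift"]])
  expect_false(drift_check(mk(0.852, 0.851), base)[["slope_drift"]])
  none <- drift_check(base, base)
  expect_false(any(none))
})

test_that("prediction stability bands behave as specified", {
  co <- generate_cohort(generator_config(n_patients = 400, seed = 33))
  newdata <- co[1:50, ]
  # deterministic model: zero-width intervals
  det <- function(cohort) function(nd) plogis(nd$true_lp - 3)
  st <- stability_intervals(det, co, newdata, B = 15, seed = 4)
  expect_true(all(st$width_pp == 0))
  expect_equal(sum(st$bands), 1, tolerance = 1e-12)

  # injected parameter noise of known scale: width tracks the propagation
  noisy <- function(cohort) {
    shift <- stats::rnorm(1, 0, 0.02)
    function(nd) clip(0.2 + shift, 0, 1)
  }
  st2 <- stability_intervals(noisy, co, newdata, B = 400, seed = 5)
  # 95% interval of N(0, 0.02) has width 2 x 1.96 x 0.02 = 0.0784
  expect_equal(st2$median_width, 100 * 2 * 1.96 * 0.02, tolerance = 0.12)
  expect_equal(sum(st2$bands), 1, tolerance = 1e-12)
})

test_that("threshold curves pass through their anchors with correct limits", {
  set.seed(21)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  p <- plogis(qlogis(0.3) + 1.5 * y + rnorm(n, sd = 0.8))
  tm <- threshold_metrics(p, y, pts = c(0.1, 0.15, 0.2))
  a <- tm$anchors
  expect_equal(a$sens[a$pt == 0], 1)
  expect_equal(a$fpr[a$pt == 0], 1)
  expect_equal(a$sens[a$pt == 1], 0)
  expect_equal(a$fpr[a$pt == 1], 0)
  expect_equal(tm$sens_fun(a$pt), a$sens, tolerance = 1e-10)
  expect_equal(tm$fpr_fun(a$pt), a$fpr, tolerance = 1e-10)
  grid <- seq(0, 1, length.out = 101)
  expect_true(all(diff(tm$sens_fun(grid)) <= 1e-9))
})

test_that("evaluate_model assembles a coherent report", {
  co <- fixture("eval_cohort", function() {
    generate_cohort(generator_config(n_patients = 3000, seed = 29))
  })
  mult <- attr(co, "hazard_multiplier")
  cfg <- attr(co, "config")
  h <- cfg$base_hazards[as.character(ckd_stage(
    ifelse(is.na(co$egfr), co$true_egfr, co$egfr)))]
  p <- 1 - exp(-36 * mult * h * exp(co$true_lp))
  rep1 <- evaluate_model(p, co)
  expect_s3_class(rep1, "eval_report")
  expect_true(rep1$auroc36 > 0.5 && rep1$auroc36 <= 1)
  expect_true(rep1$unos_c > 0.5)
  expect_equal(rep1$calib$slope, 1, tolerance = 0.15)
  expect_true(all(rep1$dca$nb <= attr(rep1$dca, "prevalence") + 1e-12))
  flags <- drift_check(rep1, rep1)
  expect_false(any(flags))
})
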