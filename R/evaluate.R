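#' @title Survival-aware evaluation suite
#' @description
#' Time-dependent discrimination (IPCW AUROC, Uno's C, AUPRC, Brier score),
#' decile calibration on the complementary log-log scale, decision-curve
#' net benefit and events-prevented-per-1000, bootstrap optimism with BCa
#' intervals, a subgroup fairness audit, individual prediction-interval
#' stability, and drift flags. Censoring weights use the Kaplan-Meier
#' estimate of the censoring survival function, left-continuous at event
#' times with ties broken event-before-censor.
#' @name evaluate
NULL

#' IPCW time-dependent AUROC at a horizon
#'
#' Cumulative/dynamic AUC at `horizon`: cases are patients with an observed
#' event by the horizon, controls are patients still under observation
#' beyond it. Each case is weighted by 1/G(T-) and each control by
#' 1/G(horizon), with G the censoring survival function. With no censoring
#' this equals the empirical AUC.
#'
#' @param preds risk scores (higher = riskier).
#' @param times follow-up months.
#' @param events event indicators.
#' @param horizon months (default 36).
#' @return AUC in \[0, 1\].
#' @export
auroc_ipcw <- function(preds, times, events, horizon = 36) {
  events <- as.numeric(events)
  G <- km_censoring(times, events)
  case <- events == 1 & times <= horizon
  ctrl <- times > horizon
  if (!any(case) || !any(ctrl)) {
    stop("undefined: no comparable case/control pairs at the horizon",
         call. = FALSE)
  }
  w_case <- 1 / G(times[case], minus = TRUE)
  w_ctrl <- rep(1 / G(horizon), sum(ctrl))
  pc <- preds[case]
  pt <- preds[ctrl]
  # weighted probability that a case outranks a control (ties count 1/2)
  o <- order(pt)
  pt <- pt[o]; w_ctrl <- w_ctrl[o]
  cw <- cumsum(w_ctrl)
  total_w <- sum(w_ctrl)
  lt <- findInterval(pc, pt, left.open = TRUE)   # controls strictly below
  le <- findInterval(pc, pt)                     # controls <= case
  w_below <- c(0, cw)[lt + 1]
  w_tied <- c(0, cw)[le + 1] - w_below
  num <- sum(w_case * (w_below + 0.5 * w_tied))
  num / (sum(w_case) * total_w)
}

#' Uno's censoring-robust concordance
#'
#' Concordance over usable pairs (the earlier time is an observed event)
#' weighted by 1/G(T_i-)^2, optionally truncated at `tau`. With no
#' censoring this reduces to Harrell's C.
#'
#' @param preds risk scores (higher = riskier = expected earlier event).
#' @param times,events follow-up and event indicator.
#' @param tau optional truncation time for the earlier event.
#' @return concordance in \[0, 1\].
#' @export
unos_c <- function(preds, times, events, tau = NULL) {
  events <- as.numeric(events)
  G <- km_censoring(times, events)
  n <- length(preds)
  idx <- which(events == 1 & (if (is.null(tau)) TRUE else times < tau))
  if (!length(idx)) stop("undefined: no usable pairs", call. = FALSE)
  num <- 0
  den <- 0
  for (i in idx) {
    comp <- times > times[i]
    if (!any(comp)) next
    w <- 1 / G(times[i], minus = TRUE)^2
    conc <- sum(preds[i] > preds[comp]) + 0.5 * sum(preds[i] == preds[comp])
    num <- num + w * conc
    den <- den + w * sum(comp)
  }
  if (den == 0) stop("undefined: no usable pairs", call. = FALSE)
  num / den
}

#' IPCW Brier score at a horizon
#'
#' Mean squared error between predicted horizon risk and the observed
#' status, with events before the horizon weighted by 1/G(T-) and
#' horizon survivors by 1/G(horizon); indeterminable patients get weight 0.
#'
#' @inheritParams auroc_ipcw
#' @return Brier score.
#' @export
brier36 <- function(preds, times, events, horizon = 36) {
  events <- as.numeric(events)
  G <- km_censoring(times, events)
  w <- numeric(length(preds))
  y <- numeric(length(preds))
  case <- events == 1 & times <= horizon
  ctrl <- times > horizon
  w[case] <- 1 / G(times[case], minus = TRUE)
  y[case] <- 1
  w[ctrl] <- 1 / G(horizon)
  sum(w * (y - preds)^2) / length(preds)
}

#' IPCW area under the precision-recall curve at a horizon
#'
#' Step-interpolated AUPRC over the IPCW-weighted horizon outcomes.
#'
#' @inheritParams auroc_ipcw
#' @return AUPRC in \[0, 1\].
#' @export
auprc36 <- function(preds, times, events, horizon = 36) {
  events <- as.numeric(events)
  G <- km_censoring(times, events)
  case <- events == 1 & times <= horizon
  ctrl <- times > horizon
  keep <- case | ctrl
  if (!any(case)) stop("undefined: no positives at horizon", call. = FALSE)
  w <- numeric(length(preds))
  w[case] <- 1 / G(times[case], minus = TRUE)
  w[ctrl] <- 1 / G(horizon)
  p <- preds[keep]; y <- as.numeric(case[keep]); w <- w[keep]
  o <- order(p, decreasing = TRUE)
  y <- y[o]; w <- w[o]
  tp <- cumsum(w * y)
  fp <- cumsum(w * (1 - y))
  prec <- tp / (tp + fp)
  rec <- tp / tp[length(tp)]
  # step integration in recall, carrying precision from the left
  sum(diff(c(0, rec)) * prec)
}

#' Decile calibration with slope and intercept
#'
#' Splits the test set into deciles of predicted risk; observed risk per
#' decile is 1 - KM(horizon) with a Greenwood 95% CI. The calibration
#' slope is the coefficient of a Cox regression on the single covariate
#' log(-log(1 - p)); the intercept is the difference between the observed
#' and mean predicted horizon risk on the same complementary log-log
#' scale (ideal slope 1, intercept 0).
#'
#' @inheritParams auroc_ipcw
#' @param n_groups number of risk groups (default 10).
#' @return list(table, slope, intercept).
#' @export
calibration <- function(preds, times, events, horizon = 36,
                        n_groups = 10) {
  if (length(preds) < 100) {
    stop("calibration deciles need n >= 100", call. = FALSE)
  }
  events <- as.numeric(events)
  br <- unique(stats::quantile(preds, seq(0, 1, length.out = n_groups + 1)))
  grp <- cut(preds, br, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1,
                             conf.type = "log-log")
    s <- summary(fit, times = min(horizon, max(times[sel])), extend = TRUE)
    data.frame(decile = g, n = sum(sel), pred = mean(preds[sel]),
               observed = 1 - s$surv,
               lo = 1 - s$upper, hi = 1 - s$lower)
  })
  tab <- do.call(rbind, rows)

  cll <- cloglog(clip(preds, 1e-12, 1 - 1e-12))
  fit <- survival::coxph(survival::Surv(times, events) ~ cll)
  slope <- unname(stats::coef(fit)[1])
  overall <- summary(survival::survfit(
    survival::Surv(times, events) ~ 1), times = horizon, extend = TRUE)
  # calibration-in-the-large: observed vs mean predicted horizon risk,
  # both on the complementary log-log scale
  intercept <- cloglog(clip(1 - overall$surv, 1e-12, 1 - 1e-12)) -
    cloglog(clip(mean(preds), 1e-12, 1 - 1e-12))
  list(table = tab, slope = slope, intercept = intercept)
}

#' Decision curve analysis
#'
#' Per threshold pt: patients with predicted risk >= pt are classified
#' positive; TP and FP at the horizon are estimated from the Kaplan-Meier
#' event probability within the positive group (so censoring is handled);
#' net benefit NB = TP/n - FP/n x pt/(1-pt). Delta is reported against the
#' treat-all strategy NB_all = prevalence - (1-prevalence) x pt/(1-pt),
#' and events-prevented-per-1000 = 1000 x (NB - NB_all). Treat-none has
#' NB 0 everywhere.
#'
#' @inheritParams auroc_ipcw
#' @param thresholds risk thresholds in \[0, 1).
#' @return data frame of threshold points (pt, TP, FP, n, nb, nb_all,
#'   delta, events_prevented_per_1000, sens, spec).
#' @export
decision_curve <- function(preds, times, events, horizon = 36,
                           thresholds = seq(0.05, 0.25, by = 0.05)) {
  if (any(thresholds >= 1 | thresholds < 0)) {
    stop("domain error: thresholds must be in [0, 1)", call. = FALSE)
  }
  events <- as.numeric(events)
  n <- length(preds)
  km_risk <- function(sel) {
    if (!any(sel)) return(0)
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    s <- summary(fit, times = min(horizon, max(times[sel])), extend = TRUE)
    1 - s$surv
  }
  prevalence <- km_risk(rep(TRUE, n))
  total_events <- n * prevalence
  rows <- lapply(thresholds, function(pt) {
    pos <- preds >= pt
    n_pos <- sum(pos)
    risk_pos <- km_risk(pos)
    tp <- n_pos * risk_pos
    fp <- n_pos * (1 - risk_pos)
    nb <- tp / n - fp / n * pt / (1 - pt)
    nb_all <- prevalence - (1 - prevalence) * pt / (1 - pt)
    sens <- if (total_events > 0) tp / total_events else NA_real_
    spec <- if (n - total_events > 0) {
      1 - fp / (n - total_events)
    } else {
      NA_real_
    }
    data.frame(pt = pt, TP = tp, FP = fp, n = n, nb = nb, nb_all = nb_all,
               delta = nb - nb_all,
               events_prevented_per_1000 = 1000 * (nb - nb_all),
               sens = sens, spec = spec)
  })
  out <- do.call(rbind, rows)
  attr(out, "prevalence") <- prevalence
  out
}

#' Net benefit from classification counts
#'
#' NB(pt) = TP/n - FP/n x pt/(1 - pt).
#'
#' @param tp,fp,n counts at the horizon.
#' @param pt risk threshold in \[0, 1).
#' @return net benefit.
#' @export
net_benefit <- function(tp, fp, n, pt) {
  if (any(pt >= 1)) stop("domain error: pt must be < 1", call. = FALSE)
  tp / n - fp / n * pt / (1 - pt)
}

#' Bootstrap optimism of the concordance statistic
#'
#' Refits the model on `B` patient-level resamples; optimism is the mean
#' of (C on the bootstrap sample) - (bootstrap model's C on the original
#' cohort). A BCa interval for the original-cohort C of the refitted
#' models is included (bias-corrected, with acceleration from jackknifing
#' the apparent statistic under the full-data model).
#'
#' @param fit_fun function(cohort) returning function(cohort) -> risk
#'   scores.
#' @param cohort a `nephra_cohort`.
#' @param B bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @return list(apparent, optimism, corrected, ci, n_failed).
#' @export
bootstrap_optimism <- function(fit_fun, cohort, B = 1000, seed = 42) {
  if (B < 2) stop("B >= 2 required for BCa", call. = FALSE)
  n <- nrow(cohort)
  model0 <- fit_fun(cohort)
  p0 <- model0(cohort)
  c_app <- unos_c(p0, cohort$followup_months, cohort$event)
  set.seed(seed)
  opt <- c_orig <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    boot$patient_id <- paste0(boot$patient_id, "_", seq_len(n))
    boot <- as_cohort(boot, provenance = attr(cohort, "provenance") %||%
                        "observed")
    mb <- tryCatch(fit_fun(boot), error = function(e) NULL)
    if (is.null(mb)) next
    c_boot <- unos_c(mb(boot), boot$followup_months, boot$event)
    c_orig[b] <- unos_c(mb(cohort), cohort$followup_months, cohort$event)
    opt[b] <- c_boot - c_orig[b]
  }
  ok <- !is.na(opt)
  optimism <- mean(opt[ok])
  # BCa interval on the refitted-model original-cohort C
  theta <- c_orig[ok]
  z0 <- stats::qnorm(clip(mean(theta < (c_app - optimism)), 1e-6, 1 - 1e-6))
  # jackknife acceleration on the apparent statistic, fixed model
  jk <- vapply(seq_len(min(n, 200)), function(i) {
    keep <- setdiff(seq_len(n), i)
    unos_c(p0[keep], cohort$followup_months[keep], cohort$event[keep])
  }, 0)
  u <- mean(jk) - jk
  a <- sum(u^3) / (6 * sum(u^2)^1.5 + 1e-300)
  alpha <- c(0.025, 0.975)
  zq <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- unname(stats::quantile(theta, adj, na.rm = TRUE))
  list(apparent = c_app, optimism = optimism,
       corrected = c_app - optimism, ci = ci, n_failed = sum(!ok))
}

#' Fairness violation rule
#'
#' A non-reference subgroup violates fairness when |delta-AUROC| exceeds
#' 0.03 or its calibration slope falls outside \[0.8, 1.2\].
#'
#' @param delta_auroc subgroup AUROC minus reference AUROC (NA for the
#'   reference itself).
#' @param slope subgroup calibration slope.
#' @param delta_threshold |delta-AUROC| cutpoint (default 0.03).
#' @param slope_range acceptable slope band (default 0.8-1.2).
#' @return logical flag vector.
#' @export
fairness_flags <- function(delta_auroc, slope, delta_threshold = 0.03,
                           slope_range = c(0.8, 1.2)) {
  d <- !is.na(delta_auroc) & abs(delta_auroc) > delta_threshold
  s <- !is.na(slope) & (slope < slope_range[1] | slope > slope_range[2])
  d | s
}

#' Subgroup fairness audit
#'
#' Per subgroup (and any supplied intersections): IPCW AUROC at the
#' horizon, delta versus the reference (largest) group, and calibration
#' slope. A violation is flagged when |delta-AUROC| > 0.03 or the slope is
#' outside \[0.8, 1.2\]. Subgroups without both outcome classes are flagged
#' unassessable.
#'
#' @inheritParams auroc_ipcw
#' @param groups data frame of grouping factors, one row per patient.
#' @param delta_threshold flag threshold on |delta-AUROC|.
#' @param slope_range acceptable calibration-slope band.
#' @return data frame fairness table.
#' @export
fairness_audit <- function(preds, times, events, groups,
                           horizon = 36, delta_threshold = 0.03,
                           slope_range = c(0.8, 1.2)) {
  events <- as.numeric(events)
  rows <- list()
  for (gv in names(groups)) {
    g <- as.factor(groups[[gv]])
    ref_level <- names(sort(table(g), decreasing = TRUE))[1]
    metrics <- lapply(levels(g), function(lv) {
      sel <- g == lv & !is.na(g)
      assessable <- sum(sel) >= 20 &&
        any(events[sel] == 1 & times[sel] <= horizon) &&
        any(times[sel] > horizon)
      if (!assessable) {
        return(data.frame(variable = gv, level = lv, n = sum(sel),
                          auroc = NA_real_, slope = NA_real_,
                          assessable = FALSE))
      }
      auc <- auroc_ipcw(preds[sel], times[sel], events[sel], horizon)
      slope <- tryCatch({
        cll <- cloglog(clip(preds[sel], 1e-12, 1 - 1e-12))
        unname(stats::coef(survival::coxph(
          survival::Surv(times[sel], events[sel]) ~ cll))[1])
      }, error = function(e) NA_real_)
      data.frame(variable = gv, level = lv, n = sum(sel), auroc = auc,
                 slope = slope, assessable = TRUE)
    })
    tab <- do.call(rbind, metrics)
    ref_auc <- tab$auroc[tab$level == ref_level]
    tab$reference <- tab$level == ref_level
    tab$delta_auroc <- tab$auroc - ref_auc
    tab$flag <- tab$assessable &
      fairness_flags(ifelse(tab$reference, NA, tab$delta_auroc),
                     tab$slope, delta_threshold, slope_range)
    rows[[gv]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual prediction-interval stability
#'
#' Refits the model on `B` bootstrap resamples, generating a distribution
#' of predicted risks per patient; the 95% prediction interval
#' (2.5th-97.5th percentile) width in percentage points summarises
#' individual stability, banded as <5 / 5-10 / >10 pp.
#'
#' @param fit_fun function(cohort) -> function(newdata) -> risks.
#' @param cohort training cohort resampled at patient level.
#' @param newdata patients whose prediction stability is assessed.
#' @param B bootstrap refits.
#' @param seed RNG seed.
#' @param bands band edges in percentage points (default 5, 10).
#' @return list(width_pp, median_width, mad, cv, bands, band_by_category).
#' @export
stability_intervals <- function(fit_fun, cohort, newdata, B = 1000,
                                seed = 42, bands = c(5, 10)) {
  n <- nrow(cohort)
  set.seed(seed)
  preds <- matrix(NA_real_, B, nrow(newdata))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- cohort[idx, , drop = FALSE]
    boot$patient_id <- paste0("b", seq_len(n))
    boot <- as_cohort(boot, provenance = "synthetic")
    preds[b, ] <- fit_fun(boot)(newdata)
  }
  qs <- apply(preds, 2, stats::quantile, probs = c(0.025, 0.975))
  width <- 100 * (qs[2, ] - qs[1, ])
  point <- rep_len(fit_fun(cohort)(newdata), nrow(newdata))
  band <- cut(width, c(-Inf, bands, Inf),
              labels = c(paste0("<", bands[1]),
                         paste0(bands[1], "-", bands[2]),
                         paste0(">", bands[2])))
  cat_base <- categorize(clip(point, 0, 1))
  list(width_pp = width,
       median_width = stats::median(width),
       mad = stats::mad(width),
       cv = stats::sd(width) / max(mean(width), 1e-12),
       bands = prop.table(table(band)),
       band_by_category = table(category = cat_base, band = band))
}

#' Drift flags between two evaluation reports
#'
#' Flags retraining when the AUROC drops by more than `auroc_drop` from
#' the baseline or the calibration slope leaves `slope_range`
#' (0.85-1.15).
#'
#' @param current,baseline `eval_report` objects (or lists with `auroc36`
#'   and `calib$slope`).
#' @param auroc_drop allowed AUROC decrease (default 0.05).
#' @param slope_range acceptable slope band.
#' @return named logical vector (auroc_drift, slope_drift) with details in
#'   attribute `details`.
#' @export
drift_check <- function(current, baseline, auroc_drop = 0.05,
                        slope_range = c(0.85, 1.15)) {
  cur_auc <- current$auroc36
  base_auc <- baseline$auroc36
  cur_slope <- current$calib$slope
  flags <- c(auroc_drift = isTRUE(base_auc - cur_auc > auroc_drop),
             slope_drift = isTRUE(cur_slope < slope_range[1] ||
                                    cur_slope > slope_range[2]))
  attr(flags, "details") <- data.frame(
    metric = c("auroc36", "slope"),
    baseline = c(base_auc, baseline$calib$slope),
    current = c(cur_auc, cur_slope))
  flags
}

#' Sensitivity / false-positive-rate curves across thresholds
#'
#' Computes sensitivity and FPR at the supplied anchor thresholds
#' (classification rule: predicted risk >= pt) and returns monotone cubic
#' spline interpolants over the full \[0, 1\] threshold range, passing
#' through the anchors exactly; pt = 0 gives (sens 1, FPR 1) and pt = 1
#' gives (sens 0, FPR 0).
#'
#' @param preds predicted risks.
#' @param outcomes 0/1 horizon outcomes.
#' @param pts anchor thresholds.
#' @return list(anchors, sens_fun, fpr_fun).
#' @export
threshold_metrics <- function(preds, outcomes,
                              pts = seq(0.05, 0.25, by = 0.05)) {
  outcomes <- as.numeric(outcomes)
  anchor_pts <- sort(unique(c(0, pts, 1)))
  sens <- vapply(anchor_pts, function(pt) {
    if (pt == 0) return(1)
    if (pt == 1) return(0)
    mean(preds[outcomes == 1] >= pt)
  }, 0)
  fpr <- vapply(anchor_pts, function(pt) {
    if (pt == 0) return(1)
    if (pt == 1) return(0)
    mean(preds[outcomes == 0] >= pt)
  }, 0)
  # enforce (weakly) monotone anchors for the monotone interpolant
  sens <- rev(cummax(rev(sens)))
  fpr <- rev(cummax(rev(fpr)))
  mk <- function(y) {
    if (length(unique(y)) == 1) return(function(x) rep(y[1], length(x)))
    stats::splinefun(anchor_pts, y, method = "hyman")
  }
  list(anchors = data.frame(pt = anchor_pts, sens = sens, fpr = fpr),
       sens_fun = mk(sens), fpr_fun = mk(fpr))
}

#' Assemble a full evaluation report
#'
#' Runs the discrimination, calibration, decision-curve, fairness and
#' (optionally) stability components on one prediction set and returns an
#' `eval_report`.
#'
#' @param preds predicted 36-month risks for the cohort.
#' @param cohort the evaluation cohort.
#' @param horizon months.
#' @param groups optional data frame of fairness grouping factors; by
#'   default sex, age band (<65 / >=65), CKD stage, and the sex x age
#'   intersection.
#' @param thresholds decision-curve thresholds.
#' @return an `eval_report` list.
#' @export
evaluate_model <- function(preds, cohort, horizon = 36, groups = NULL,
                           thresholds = seq(0.05, 0.25, by = 0.05)) {
  t <- cohort$followup_months
  e <- as.numeric(cohort$event)
  if (is.null(groups)) {
    age_band <- ifelse(cohort$age >= 65, ">=65", "<65")
    groups <- data.frame(
      sex = cohort$sex,
      age_band = age_band,
      ckd_stage = as.character(ckd_stage(
        if (!is.null(cohort$true_egfr)) cohort$true_egfr else cohort$egfr)),
      sex_x_age = paste(cohort$sex, age_band, sep = ":"))
  }
  calib <- calibration(preds, t, e, horizon)
  status <- status_at_horizon(cohort, horizon)
  det <- !is.na(status)
  structure(list(
    n = nrow(cohort),
    auroc36 = auroc_ipcw(preds, t, e, horizon),
    unos_c = unos_c(preds, t, e),
    auprc36 = auprc36(preds, t, e, horizon),
    brier36 = brier36(preds, t, e, horizon),
    calib = calib,
    dca = decision_curve(preds, t, e, horizon, thresholds),
    fairness = fairness_audit(preds, t, e, groups, horizon),
    threshold_curves = threshold_metrics(preds[det], status[det],
                                         thresholds)$anchors
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  n = %d\n  AUROC(36m, IPCW) = %.3f\n  Uno's C = %.3f\n",
              x$n, x$auroc36, x$unos_c))
  cat(sprintf("  AUPRC = %.3f; Brier = %.4f\n", x$auprc36, x$brier36))
  cat(sprintf("  calibration slope = %.3f, intercept = %.3f\n",
              x$calib$slope, x$calib$intercept))
  cat(sprintf("  fairness violations: %d\n",
              sum(x$fairness$flag, na.rm = TRUE)))
  invisible(x)
}
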