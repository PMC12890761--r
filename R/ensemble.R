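#' @title Stacked binary + survival ensemble
#' @description
#' The model pipeline around the deployed score: patient-level temporal
#' splitting, the censoring policy (administratively censored patients are
#' excluded from the binary learner but retained by the survival learner),
#' pluggable base learners (a gradient-boosted binary classifier and a
#' proportional-hazards survival learner), the stacked combiner
#' P = sigma(w_bin x logit(P_bin) + w_surv x logit(P_surv)) with fixed
#' weights 0.64/0.36 or a ridge-penalised learned meta-model, and isotonic
#' calibration fitted on the validation window.
#' @name ensemble
NULL

month_index <- function(index_date) {
  y <- as.integer(substr(index_date, 1, 4))
  m <- as.integer(substr(index_date, 6, 7))
  (y - 2019L) * 12L + (m - 1L)
}

#' Patient-level temporal split
#'
#' Assigns each patient to train / validation / test by index date alone.
#' With `windows = NULL` the window boundaries are the index-date quantiles
#' at the cumulative `fractions` (default 70/15/15).
#'
#' @param cohort a `nephra_cohort`.
#' @param windows optional list with elements train, validation, test, each
#'   c(first, last) month index (inclusive).
#' @param fractions target fractions when deriving windows from quantiles.
#' @return a `split_assignment`: data frame (patient_id, split) with the
#'   windows and realised fractions as attributes.
#' @export
temporal_split <- function(cohort, windows = NULL,
                           fractions = c(0.70, 0.15, 0.15)) {
  if (anyDuplicated(cohort$patient_id)) {
    stop("integrity error: duplicate patient_id", call. = FALSE)
  }
  mi <- month_index(cohort$index_date)
  if (anyNA(mi)) stop("index_date missing for some patients", call. = FALSE)
  if (is.null(windows)) {
    q <- stats::quantile(mi, cumsum(fractions)[1:2], type = 1)
    windows <- list(train = c(min(mi), q[1]),
                    validation = c(q[1] + 1, q[2]),
                    test = c(q[2] + 1, max(mi)))
  }
  split <- rep(NA_character_, length(mi))
  for (w in names(windows)) {
    split[mi >= windows[[w]][1] & mi <= windows[[w]][2]] <- w
  }
  if (anyNA(split)) {
    stop("assignment error: patients outside all windows: ",
         paste(utils::head(cohort$patient_id[is.na(split)], 5),
               collapse = ", "), call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(cohort$patient_id),
                    split = factor(split,
                                   levels = c("train", "validation", "test")))
  structure(out, class = c("split_assignment", "data.frame"),
            windows = windows, fractions = prop.table(table(out$split)))
}

#' Censoring policy filter
#'
#' Binary mode drops administratively censored patients with follow-up
#' under 36 months and no event (their 36-month status is indeterminable);
#' competing-risk censorings (death, transplant) are retained and treated
#' as non-events. Survival mode keeps everyone.
#'
#' @param cohort a `nephra_cohort`.
#' @param mode "binary" or "survival".
#' @param horizon months (default 36); censoring at exactly the horizon is
#'   a complete observation and is kept.
#' @return the filtered cohort.
#' @export
censoring_filter <- function(cohort, mode = c("binary", "survival"),
                             horizon = 36) {
  mode <- match.arg(mode)
  if (mode == "survival") return(cohort)
  drop <- !cohort$event & cohort$followup_months < horizon &
    cohort$censor_reason == "administrative"
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "provenance") <- attr(cohort, "provenance")
  out
}

#' Ensemble combiner specification
#' @param w_binary,w_survival stacking weights on the logit scale.
#' @param intercept meta-model intercept (0 in fixed mode).
#' @param meta "fixed" (published weights) or "learned".
#' @param l2_alpha ridge penalty for the learned meta-model.
#' @param calibrator optional isotonic calibrator applied to the stack.
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(w_binary = 0.64, w_survival = 0.36,
                          intercept = 0, meta = "fixed", l2_alpha = 0.01,
                          calibrator = NULL) {
  stopifnot(is.finite(w_binary), is.finite(w_survival))
  structure(list(w_binary = w_binary, w_survival = w_survival,
                 intercept = intercept, meta = meta, l2_alpha = l2_alpha,
                 calibrator = calibrator),
            class = "ensemble_spec")
}

#' Stacked prediction
#'
#' P = sigma(w_bin x logit(p_bin) + w_surv x logit(p_surv) + intercept),
#' inputs clipped to \[1e-6, 1 - 1e-6\].
#'
#' @param p_bin,p_surv base-learner probabilities.
#' @param spec an `ensemble_spec`.
#' @return combined probabilities.
#' @export
stack_predict <- function(p_bin, p_surv, spec = ensemble_spec()) {
  p_bin <- clip(p_bin, 1e-6, 1 - 1e-6)
  p_surv <- clip(p_surv, 1e-6, 1 - 1e-6)
  inv_logit(spec$w_binary * logit(p_bin) +
              spec$w_survival * logit(p_surv) + spec$intercept)
}

#' Fit the stacking meta-learner
#'
#' Ridge-penalised logistic regression of the outcome on the two base
#' logits, fitted on validation predictions.
#'
#' @param p_bin,p_surv base probabilities on the validation set.
#' @param outcome 0/1 outcomes.
#' @param l2_alpha ridge penalty (default 0.01).
#' @return an `ensemble_spec` with learned weights and intercept.
#' @export
fit_meta <- function(p_bin, p_surv, outcome, l2_alpha = 0.01) {
  if (length(unique(outcome)) < 2) {
    stop("fit error: validation outcomes are single-class", call. = FALSE)
  }
  x <- cbind(lb = logit(clip(p_bin, 1e-6, 1 - 1e-6)),
             ls = logit(clip(p_surv, 1e-6, 1 - 1e-6)))
  fit <- glmnet::glmnet(x, outcome, family = "binomial", alpha = 0,
                        lambda = l2_alpha, standardize = FALSE)
  co <- as.numeric(stats::coef(fit))
  ensemble_spec(w_binary = co[2], w_survival = co[3], intercept = co[1],
                meta = "learned", l2_alpha = l2_alpha)
}

#' Isotonic probability calibration
#'
#' Fits a monotone non-decreasing map from predicted to observed risk by
#' isotonic regression (pool-adjacent-violators). Inputs outside the fitted
#' range are clamped to the range endpoints. Fewer than 10 points yields an
#' identity calibrator with a warning.
#'
#' @param preds validation predictions.
#' @param outcomes 0/1 outcomes.
#' @return an `isotonic_calibrator`.
#' @export
isotonic_calibrate <- function(preds, outcomes) {
  ok <- !is.na(preds) & !is.na(outcomes)
  preds <- preds[ok]; outcomes <- as.numeric(outcomes[ok])
  if (length(preds) < 10) {
    warning("fewer than 10 calibration points: identity calibrator",
            call. = FALSE)
    return(structure(list(identity = TRUE), class = "isotonic_calibrator"))
  }
  o <- order(preds)
  iso <- stats::isoreg(preds[o], outcomes[o])
  # collapse to unique knots for interpolation
  x <- iso$x; y <- iso$yf
  keep <- !duplicated(x)
  structure(list(identity = FALSE, x = x[keep], y = y[keep]),
            class = "isotonic_calibrator")
}

#' Apply an isotonic calibrator
#' @param cal an `isotonic_calibrator`.
#' @param p probabilities to calibrate.
#' @return calibrated probabilities (monotone non-decreasing in `p`).
#' @export
apply_calibrator <- function(cal, p) {
  stopifnot(inherits(cal, "isotonic_calibrator"))
  if (isTRUE(cal$identity)) return(p)
  if (length(cal$x) == 1) return(rep(cal$y, length(p)))
  stats::approx(cal$x, cal$y, xout = p, rule = 2, ties = "ordered")$y
}

# ---------------------------------------------------------------- learners

# Model matrix for the learners: observed covariates (median-filled with
# missingness flags) plus imputed literature-informed variables.
build_features <- function(cohort) {
  df <- as.data.frame(cohort)
  num <- c("age", "bmi", "waist_circumference", "sbp", "dbp", "egfr",
           "acr", "hba1c", "phosphorus", "fgf23", "diabetes_duration",
           "medication_compliance")
  x <- list()
  for (v in intersect(num, names(df))) {
    col <- as.numeric(df[[v]])
    if (anyNA(col)) {
      x[[paste0("miss_", v)]] <- as.integer(is.na(col))
      col[is.na(col)] <- stats::median(col, na.rm = TRUE)
    }
    x[[v]] <- col
  }
  x$acr <- log2(pmax(x$acr, 1))
  x$sex_male <- as.numeric(df$sex == "male")
  x$smoking_current <- as.numeric(df$smoking == "current")
  x$smoking_former <- as.numeric(df$smoking == "former")
  if (!is.null(df$hypertension)) x$hypertension <- as.numeric(df$hypertension)
  if (!is.null(df$cvd)) x$cvd <- as.numeric(df$cvd)
  for (v in grep("^(lit_|miss_)", names(df), value = TRUE)) {
    x[[v]] <- as.numeric(df[[v]])
  }
  m <- do.call(cbind, x)
  rownames(m) <- NULL
  m
}

# Align a feature matrix with a fitted learner's feature set; columns the
# fit never saw are dropped, absent columns (e.g. a missingness flag not
# triggered in this cohort) are zero-filled.
align_features <- function(x, features) {
  out <- matrix(0, nrow(x), length(features),
                dimnames = list(NULL, features))
  common <- intersect(colnames(x), features)
  out[, common] <- x[, common]
  out
}

# horizon event label for the binary learner (after censoring_filter the
# remaining patients all have determinable status)
label36 <- function(cohort, horizon = 36) {
  as.numeric(cohort$event & cohort$followup_months <= horizon)
}

#' Fit the gradient-boosted binary base learner
#'
#' Thin wrapper over xgboost (binary:logistic) with class weighting set to
#' the training split's negative:positive ratio.
#'
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @param params list overriding the default boosting parameters
#'   (max_depth 4, eta 0.1, min_child_weight 10, subsample 0.8).
#' @param nrounds boosting rounds.
#' @param seed RNG seed.
#' @return a model object usable with `predict_binary_learner()`.
#' @export
fit_binary_learner <- function(x, y, params = list(), nrounds = 150,
                               seed = 42) {
  spw <- sum(y == 0) / max(sum(y == 1), 1)
  p <- utils::modifyList(list(objective = "binary:logistic",
                              max_depth = 4, eta = 0.1,
                              min_child_weight = 10, subsample = 0.8,
                              colsample_bytree = 0.8,
                              scale_pos_weight = spw, nthread = 1), params)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  bst <- xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                            verbose = 0)
  structure(list(model = bst, features = colnames(x)),
            class = "binary_learner")
}

#' @rdname fit_binary_learner
#' @param object a fitted `binary_learner`.
#' @export
predict_binary_learner <- function(object, x) {
  dm <- xgboost::xgb.DMatrix(align_features(x, object$features),
                             nthread = 1)
  stats::predict(object$model, dm)
}

#' Fit the proportional-hazards survival base learner
#'
#' Cox model on the feature matrix with a Breslow baseline; 36-month event
#' probability is 1 - S(36 | x) = 1 - exp(-H0(36) exp(lp)).
#'
#' @param x feature matrix.
#' @param time,event follow-up months and event indicator.
#' @param horizon months for the converted event probability.
#' @return a `survival_learner`.
#' @export
fit_survival_learner <- function(x, time, event, horizon = 36) {
  df <- as.data.frame(x)
  df$.time <- time
  df$.event <- as.numeric(event)
  keep <- colnames(x)[apply(x, 2, function(v) stats::sd(v) > 0)]
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", keep),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron", x = FALSE,
                         y = TRUE)
  bh <- survival::basehaz(fit, centered = TRUE)
  h0 <- stats::approx(bh$time, bh$hazard, xout = horizon, rule = 2)$y
  structure(list(fit = fit, features = keep, h0_horizon = h0,
                 centers = fit$means, horizon = horizon),
            class = "survival_learner")
}

#' @rdname fit_survival_learner
#' @param object a fitted `survival_learner`.
#' @export
predict_survival_learner <- function(object, x) {
  nd <- as.data.frame(align_features(x, object$features))
  lp <- as.vector(stats::predict(object$fit, newdata = nd, type = "lp"))
  1 - exp(-object$h0_horizon * exp(lp))
}

#' Small random hyperparameter search for the binary learner
#'
#' Samples `n_trials` configurations from the boosted-tree search space
#' (num_leaves 7-127 via depth 2-8, learning rate 0.01-0.30, min leaf
#' 10-100) and keeps the one with the best validation AUROC.
#'
#' @param x_train,y_train,x_valid,y_valid split data.
#' @param n_trials search budget (default 10).
#' @param nrounds boosting rounds per trial.
#' @param seed RNG seed.
#' @return list(params, auroc, model).
#' @export
tune_binary_learner <- function(x_train, y_train, x_valid, y_valid,
                                n_trials = 10, nrounds = 150, seed = 42) {
  set.seed(seed)
  best <- list(auroc = -Inf)
  for (i in seq_len(n_trials)) {
    cand <- list(max_depth = sample(2:8, 1),
                 eta = stats::runif(1, 0.01, 0.30),
                 min_child_weight = sample(10:100, 1))
    fit <- fit_binary_learner(x_train, y_train, params = cand,
                              nrounds = nrounds, seed = seed + i)
    p <- predict_binary_learner(fit, x_valid)
    auc <- auroc_ipcw(p, rep(37, length(y_valid)), y_valid)
    if (auc > best$auroc) best <- list(params = cand, auroc = auc,
                                       model = fit)
  }
  best
}

#' Fit the full stacked ensemble
#'
#' Fits the binary learner on the binary-eligible training patients, the
#' survival learner on all training patients, the combiner (fixed
#' published weights or a learned ridge meta-model) on the validation
#' window, and an isotonic calibrator on the stacked validation
#' predictions. Calibration and meta-learning never see test-window
#' patients.
#'
#' @param train,valid training and validation cohorts (with imputed
#'   `lit_*` columns).
#' @param meta "fixed" or "learned".
#' @param weights stacking weights used in fixed mode.
#' @param params,nrounds binary learner settings.
#' @param seed RNG seed.
#' @return a `nephra_ensemble`.
#' @export
fit_ensemble <- function(train, valid, meta = c("fixed", "learned"),
                         weights = c(0.64, 0.36), params = list(),
                         nrounds = 150, seed = 42) {
  meta <- match.arg(meta)
  train_bin <- censoring_filter(train, "binary")
  xb <- build_features(train_bin)
  bin <- fit_binary_learner(xb, label36(train_bin), params = params,
                            nrounds = nrounds, seed = seed)
  xs <- build_features(train)
  srv <- fit_survival_learner(xs, train$followup_months,
                              train$event)

  valid_bin <- censoring_filter(valid, "binary")
  xv <- build_features(valid_bin)
  pb <- predict_binary_learner(bin, xv)
  ps <- predict_survival_learner(srv, xv)
  yv <- label36(valid_bin)
  spec <- if (meta == "learned") {
    fit_meta(pb, ps, yv)
  } else {
    ensemble_spec(w_binary = weights[1], w_survival = weights[2])
  }
  stacked <- stack_predict(pb, ps, spec)
  spec$calibrator <- isotonic_calibrate(stacked, yv)
  structure(list(binary = bin, survival = srv, spec = spec),
            class = "nephra_ensemble")
}

#' Predict calibrated 36-month risk from a fitted ensemble
#' @param object a `nephra_ensemble`.
#' @param cohort patient records.
#' @param calibrated apply the isotonic calibrator (default TRUE).
#' @return probabilities.
#' @export
predict_ensemble <- function(object, cohort, calibrated = TRUE) {
  x <- build_features(cohort)
  pb <- predict_binary_learner(object$binary, x)
  ps <- predict_survival_learner(object$survival, x)
  p <- stack_predict(pb, ps, object$spec)
  if (calibrated && !is.null(object$spec$calibrator)) {
    p <- apply_calibrator(object$spec$calibrator, p)
  }
  p
}
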