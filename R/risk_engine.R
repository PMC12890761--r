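#' @title Literature-coefficient clinical risk engine
#' @description
#' The deployed clinical model: a proportional-hazards score assembled from
#' published per-covariate hazard ratios, stage-specific monthly base
#' hazards, and a 36-month horizon, with KDIGO-aligned risk categories, a
#' complexity-adjusted uncertainty band, and exact additive per-feature
#' attributions.
#' @name risk_engine
NULL

#' Risk model specification
#'
#' Bundles the effect table (observed covariates plus literature-informed
#' variables from a prior registry), the monthly base hazards per CKD
#' stage, the prediction horizon, category cutpoints, validity bounds, and
#' the uncertainty constants 0.05 + n_features x 0.01.
#'
#' @param registry a `prior_registry` for the literature-informed effects.
#' @param base_hazards monthly base hazard per CKD stage (must be strictly
#'   increasing with stage severity).
#' @param horizon prediction horizon in months.
#' @param category_cuts risk category cutpoints, strictly increasing in
#'   (0, 1).
#' @param bounds validity bounds, see [default_bounds()].
#' @param uncertainty_base,uncertainty_per_feature uncertainty half-width
#'   constants.
#' @return a `risk_model_spec`.
#' @export
risk_model_spec <- function(registry = default_registry(),
                            base_hazards = c(none = 0.00048, s1_2 = 0.0013,
                                             s3a = 0.0030, s3b = 0.0070,
                                             s4 = 0.016),
                            horizon = 36,
                            category_cuts = c(0.05, 0.15, 0.30),
                            bounds = default_bounds(),
                            uncertainty_base = 0.05,
                            uncertainty_per_feature = 0.01) {
  if (any(diff(base_hazards) <= 0)) {
    stop("base hazards must be strictly increasing with stage",
         call. = FALSE)
  }
  if (any(diff(category_cuts) <= 0) || any(category_cuts <= 0) ||
      any(category_cuts >= 1)) {
    stop("category cuts must be strictly increasing in (0,1)", call. = FALSE)
  }
  structure(list(
    effects = c(observed_effects(include_egfr = TRUE),
                registry_effects(registry)),
    base_hazards = base_hazards, horizon = horizon,
    category_cuts = category_cuts, bounds = bounds,
    uncertainty_base = uncertainty_base,
    uncertainty_per_feature = uncertainty_per_feature
  ), class = "risk_model_spec")
}

#' Linear predictor and per-feature contributions
#'
#' lp = sum over effects of log-HR x transformed covariate deviation from
#' its reference. Missing features contribute 0 and are counted; an
#' out-of-bounds value is refused with the safety-bound violation.
#'
#' @param records cohort rows (imputed `lit_*` columns are used for
#'   literature-informed variables when present).
#' @param spec a `risk_model_spec`.
#' @return list with `lp`, the `contributions` matrix (rows sum to lp),
#'   and `n_supplied` features per record.
#' @export
linear_predictor <- function(records, spec) {
  records <- as.data.frame(records)
  viol <- validate_record(records, spec)
  if (nrow(viol)) {
    stop("safety-bound violation: ",
         paste(sprintf("%s=%g violates %s bound %g (patient %s)",
                       viol$field, viol$value, viol$side, viol$bound,
                       viol$patient_id),
               collapse = "; "), call. = FALSE)
  }
  cm <- contribution_matrix(records, spec$effects, .get_lit_first)
  n_supplied <- rowSums(!is.na(cm))
  cm[is.na(cm)] <- 0
  list(lp = rowSums(cm), contributions = cm, n_supplied = n_supplied)
}

#' Risk category from cutpoints
#'
#' Left-closed binning: risk in \[0, .05) low, \[.05, .15) moderate,
#' \[.15, .30) high, \[.30, 1\] very_high; a boundary value belongs to the
#' higher category.
#'
#' @param risk probabilities in \[0, 1\].
#' @param cuts strictly increasing cutpoints.
#' @return factor with levels low, moderate, high, very_high.
#' @export
categorize <- function(risk, cuts = c(0.05, 0.15, 0.30)) {
  stopifnot(all(risk >= 0 & risk <= 1, na.rm = TRUE))
  labs <- c("low", "moderate", "high", "very_high")
  factor(labs[findInterval(risk, c(0, cuts))], levels = labs)
}

#' 36-month risk prediction
#'
#' risk = 1 - exp(-horizon x h_stage x exp(lp)) with the stage-specific
#' monthly base hazard; uncertainty half-width = (0.05 + n_supplied x 0.01)
#' as a fraction of the risk, interval clipped to \[0, 1\].
#'
#' @param records cohort rows.
#' @param spec a `risk_model_spec`.
#' @return data frame with patient_id, risk36, linear_predictor, category,
#'   uncertainty, lo, hi; the contribution matrix is in attribute
#'   `contributions`.
#' @export
predict_risk36 <- function(records, spec = risk_model_spec()) {
  records <- as.data.frame(records)
  lpres <- linear_predictor(records, spec)
  stage <- as.character(ckd_stage(records$egfr))
  h <- spec$base_hazards[stage]
  risk <- 1 - exp(-spec$horizon * h * exp(lpres$lp))
  unc <- spec$uncertainty_base +
    lpres$n_supplied * spec$uncertainty_per_feature
  out <- data.frame(
    patient_id = if (!is.null(records$patient_id)) {
      as.character(records$patient_id)
    } else {
      as.character(seq_len(nrow(records)))
    },
    risk36 = unname(risk),
    linear_predictor = lpres$lp,
    category = categorize(unname(risk), spec$category_cuts),
    uncertainty = unname(unc),
    lo = unname(clip(risk * (1 - unc), 0, 1)),
    hi = unname(clip(risk * (1 + unc), 0, 1))
  )
  attr(out, "contributions") <- lpres$contributions
  out
}

#' Clinical-gain feature importance
#'
#' For the linear-hazard engine the attributions are exact: each feature's
#' importance is its mean absolute log-hazard contribution across the
#' cohort, normalised to percent of total. For a black-box predictor a
#' permutation attribution is used: each feature is permuted and the mean
#' absolute change in prediction, averaged over permutations, is
#' normalised the same way.
#'
#' @param model a `risk_model_spec`, or a function(data) -> predictions.
#' @param cohort patient records.
#' @param features for a black-box model, the columns of `cohort` to
#'   attribute over (defaults to all numeric columns).
#' @param iterations total permutation iterations across features.
#' @param seed RNG seed for permutations.
#' @return named numeric vector of percentages summing to 100 (or all zero,
#'   with a warning, for a constant predictor).
#' @export
clinical_gain <- function(model, cohort, features = NULL,
                          iterations = 1000, seed = 42) {
  cohort <- as.data.frame(cohort)
  if (inherits(model, "risk_model_spec")) {
    cm <- contribution_matrix(cohort, model$effects, .get_lit_first)
    cm[is.na(cm)] <- 0
    imp <- colMeans(abs(cm))
  } else {
    stopifnot(is.function(model))
    if (is.null(features)) {
      features <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
    }
    set.seed(seed)
    base <- model(cohort)
    n_perm <- max(1L, ceiling(iterations / length(features)))
    imp <- vapply(features, function(f) {
      deltas <- replicate(n_perm, {
        perm <- cohort
        perm[[f]] <- perm[[f]][sample.int(nrow(perm))]
        mean(abs(model(perm) - base))
      })
      mean(deltas)
    }, 0)
  }
  tot <- sum(imp)
  if (tot < .Machine$double.eps) {
    warning("constant predictor: all importances zero", call. = FALSE)
    return(imp * 0)
  }
  100 * imp / tot
}
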