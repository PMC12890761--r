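# Shared effect definitions: the literature-coefficient table used both by
# the synthetic generator (to build the true log-hazard) and by the risk
# engine (to score patients). Each effect is a per-unit log hazard ratio
# applied to a transformed covariate deviation from its reference value.

# eGFR reference within each CKD stage (bracket midpoints), so that the
# continuous eGFR effect acts within stage while the stage-specific base
# hazard acts between stages.
.stage_egfr_ref <- c(none = 95, s1_2 = 75, s3a = 52, s3b = 37, s4 = 22)

.mk_eff <- function(name, hr, ci, fun, requires) {
  list(name = name, log_hr = log(hr), se = .se_from_ci(ci),
       fun = fun, requires = requires)
}

# Observed-covariate effects. `get` is a column resolver so callers can
# prefer ground-truth (`true_*`) or imputed (`lit_*`) columns.
observed_effects <- function(include_egfr = TRUE) {
  effs <- list(
    .mk_eff("age", 1.16, c(1.13, 1.19),
            function(df, get) (get(df, "age") - 60) / 10, "age"),
    .mk_eff("sex_male", 1.19, c(1.11, 1.27),
            function(df, get) as.numeric(get(df, "sex") == "male"), "sex"),
    .mk_eff("acr_log2", 1.30, c(1.26, 1.34),
            function(df, get) log2(pmax(get(df, "acr"), 1) / 10), "acr"),
    .mk_eff("hba1c", 1.13, c(1.10, 1.16),
            function(df, get) get(df, "hba1c") - 7, "hba1c"),
    .mk_eff("diabetes_duration", 1.10, c(1.07, 1.13),
            function(df, get) get(df, "diabetes_duration") / 5,
            "diabetes_duration"),
    .mk_eff("bmi", 1.09, c(1.06, 1.12),
            function(df, get) (get(df, "bmi") - 25) / 5, "bmi"),
    .mk_eff("sbp", 1.07, c(1.05, 1.09),
            function(df, get) (get(df, "sbp") - 120) / 10, "sbp"),
    .mk_eff("smoking_current", 1.35, c(1.28, 1.42),
            function(df, get) as.numeric(get(df, "smoking") == "current"),
            "smoking"),
    .mk_eff("compliance", 1.30, c(1.24, 1.36),
            function(df, get) (10 - get(df, "medication_compliance")) / 2,
            "medication_compliance"),
    .mk_eff("waist", 1.08, c(1.04, 1.12),
            function(df, get) (get(df, "waist_circumference") - 100) / 10,
            "waist_circumference")
  )
  if (include_egfr) {
    egfr_eff <- .mk_eff(
      "egfr_per10", 1.24, c(1.20, 1.28),
      function(df, get) {
        egfr <- get(df, "egfr")
        ref <- .stage_egfr_ref[as.character(ckd_stage(egfr))]
        (ref - egfr) / 10
      }, "egfr")
    effs <- append(effs, list(egfr_eff), after = 2)
  }
  effs
}

# Literature-informed variable effects derived from a prior registry.
# Binary: indicator * log HR. Ordinal: grade-specific log HR vs grade 0.
# Quintile: per-quintile-step linear gradient from quintile 1.
registry_effects <- function(registry) {
  lapply(registry$entries, function(e) {
    nm <- e$name
    fun <- switch(e$kind,
      binary = function(df, get) as.numeric(get(df, nm)),
      ordinal = function(df, get) get(df, nm),
      quintile = function(df, get) get(df, nm) - 1,
      continuous = function(df, get) get(df, nm))
    list(name = nm, kind = e$kind, log_hr = e$log_hr, se = e$se,
         fun = fun, requires = nm)
  })
}

# Evaluate one effect's log-hazard contribution; ordinal effects map grade
# g > 0 to their grade-specific log HR.
.effect_contribution <- function(eff, df, get) {
  val <- eff$fun(df, get)
  if (!is.null(eff$kind) && eff$kind == "ordinal") {
    g <- as.integer(val)
    contrib <- rep(0, length(g))
    pos <- !is.na(g) & g > 0
    contrib[pos] <- eff$log_hr[pmin(g[pos], length(eff$log_hr))]
    contrib[is.na(g)] <- NA_real_
    contrib
  } else {
    val * eff$log_hr[1]
  }
}

# Column resolvers
.get_plain <- function(df, col) df[[col]]
.get_true_first <- function(df, col) {
  tc <- paste0("true_", col)
  if (!is.null(df[[tc]])) df[[tc]] else df[[col]]
}
.get_lit_first <- function(df, col) {
  lc <- paste0("lit_", col)
  if (!is.null(df[[lc]])) return(df[[lc]])
  if (!is.null(df[[col]])) return(df[[col]])
  tc <- paste0("true_", col)
  if (!is.null(df[[tc]])) df[[tc]] else NULL
}

# Full contribution matrix (n x effects). Missing resolved columns yield NA
# contributions; callers decide the policy (error for the generator, zero
# with a supplied-feature count for the engine).
contribution_matrix <- function(df, effects, get) {
  out <- vapply(effects, function(eff) {
    col <- eff$requires
    resolved <- get(df, col)
    if (is.null(resolved)) return(rep(NA_real_, nrow(df)))
    .effect_contribution(eff, df, get)
  }, numeric(nrow(df)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(df))
  colnames(out) <- vapply(effects, `[[`, "", "name")
  out
}
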