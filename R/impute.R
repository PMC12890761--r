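#' @title Dual imputation strategy
#' @description
#' Partially missing observed variables get median imputation with missing
#' indicator flags; variables that are 100% missing by design (the
#' literature-informed variables) are imputed by Bayesian chained sampling
#' from their literature priors, with Gelman-Rubin convergence diagnostics
#' and a posterior-predictive fidelity check.
#' @name impute
NULL

#' Median imputation with missing-indicator flags
#'
#' Every observed variable with a missingness fraction strictly below
#' `threshold` is filled with the cohort median and gains a binary
#' `miss_<var>` indicator column preserving the information content of the
#' missingness pattern. Variables at or above the threshold are left for
#' chained imputation and listed in the `skipped` attribute; an all-missing
#' observed variable is routed to the literature-informed path with a
#' warning.
#'
#' @param cohort a `nephra_cohort`.
#' @param threshold missingness fraction at/above which a variable is not
#'   median-filled (default 0.40).
#' @param vars observed numeric variables to consider.
#' @return the cohort with filled values and indicator columns; attributes
#'   `missing_indicators` (named fill medians) and `skipped`.
#' @export
impute_observed <- function(cohort, threshold = 0.40,
                            vars = c("bmi", "waist_circumference", "sbp",
                                     "dbp", "egfr", "acr", "hba1c",
                                     "phosphorus", "fgf23",
                                     "diabetes_duration",
                                     "medication_compliance")) {
  filled <- numeric(0)
  skipped <- character(0)
  for (v in intersect(vars, names(cohort))) {
    x <- cohort[[v]]
    rate <- mean(is.na(x))
    if (rate == 0) next
    if (rate >= 1) {
      warning("impute_observed: '", v, "' is entirely missing; ",
              "routed to the literature-informed path", call. = FALSE)
      skipped <- c(skipped, v)
      next
    }
    if (rate >= threshold) {
      message("impute_observed: '", v, "' is ", round(100 * rate, 1),
              "% missing (>= threshold); left for chained imputation")
      skipped <- c(skipped, v)
      next
    }
    med <- stats::median(x, na.rm = TRUE)
    cohort[[paste0("miss_", v)]] <- as.integer(is.na(x))
    cohort[[v]][is.na(x)] <- med
    filled[v] <- med
  }
  attr(cohort, "missing_indicators") <- filled
  attr(cohort, "skipped") <- skipped
  cohort
}

# One chained sweep for one chain: for each registry variable, draw the
# model parameters from their literature prior, then sample patient values
# conditional on observed covariates through the conditioning map. Because
# these variables carry no observed data, imputed draws never feed back
# into the parameter updates (a cut model): the exact conditional for the
# parameters is the prior itself, so each sweep draws them afresh and the
# chains are stationary from the first iteration.
.sweep_chain <- function(n, registry, cond_x, prev_logit_se = 0.05,
                         dirichlet_ess = 200) {
  values <- list()
  monitored <- numeric(0)
  for (e in registry$entries) {
    if (e$kind == "binary") {
      alpha <- stats::rnorm(1, logit(e$prevalence), prev_logit_se)
      # coefficients shrunk exactly to zero (flat priors) carry no
      # association: imputation falls back to independence
      cond <- e$conditioning[e$conditioning != 0]
      if (length(cond)) {
        gamma <- stats::rnorm(length(cond), cond, e$se[1])
        eta <- as.vector(cond_x[, names(cond), drop = FALSE] %*% gamma)
        # keep the marginal prevalence at the drawn value
        a0 <- stats::uniroot(function(a) mean(inv_logit(a + eta)) -
                               inv_logit(alpha),
                             c(-15, 15), tol = 1e-6)$root
        p <- inv_logit(a0 + eta)
      } else {
        p <- inv_logit(alpha)
      }
      v <- stats::rbinom(n, 1, p)
      monitored[e$name] <- mean(v)
    } else if (e$kind %in% c("ordinal", "quintile")) {
      conc <- e$prevalence * dirichlet_ess
      g <- stats::rgamma(length(conc), conc)
      probs <- g / sum(g)
      lev <- if (e$kind == "ordinal") seq_along(probs) - 1L
             else seq_along(probs)
      v <- sample(lev, n, replace = TRUE, prob = probs)
      monitored[e$name] <- mean(v)
    } else {
      v <- stats::rnorm(n, e$prevalence, 1)
      monitored[e$name] <- mean(v)
    }
    values[[paste0("lit_", e$name)]] <- v
  }
  list(values = values, monitored = monitored)
}

#' Literature-informed chained imputation of fully-missing variables
#'
#' Runs `chains` independent chains. Each chain draws, at every sweep, the
#' per-variable model parameters from their literature priors (prevalence
#' logit intercept; conditioning coefficients centred on the registry's
#' scaled log-HR associations) and then cycles through the variables
#' sampling patient values conditional on observed covariates. After
#' `burn_in` sweeps, a further `monitor` sweeps are recorded for the
#' convergence diagnostics; the completed dataset returned for each chain
#' is its final sweep, giving M = `chains` completed cohorts.
#'
#' @param cohort a `nephra_cohort`.
#' @param registry a `prior_registry` covering every variable to impute.
#' @param chains number of chains / completed datasets (default 20).
#' @param burn_in sweeps discarded before monitoring (default 10).
#' @param monitor monitored post-burn-in sweeps (default 60) used for the
#'   Gelman-Rubin statistic.
#' @param seed RNG seed.
#' @return a `nephra_imputation`: `datasets` (list of cohorts),
#'   `trace` (chains x iterations x variables array of monitored
#'   parameters: running prevalence for binary variables, mean grade for
#'   ordinal), `gelman_rubin`, `burn_in`, `registry`.
#' @export
mice_literature <- function(cohort, registry, chains = 20, burn_in = 10,
                            monitor = 60, seed = 42) {
  stopifnot(inherits(registry, "prior_registry"))
  if (chains < 2) {
    stop("config error: at least 2 chains are required for diagnostics",
         call. = FALSE)
  }
  n <- nrow(cohort)
  vars <- names(registry$entries)
  n_iter <- burn_in + monitor

  # z-scored observed covariates available to conditioning maps
  cond_cols <- unique(unlist(lapply(registry$entries,
                                    function(e) names(e$conditioning))))
  cond_x <- NULL
  if (length(cond_cols)) {
    missing_cols <- setdiff(cond_cols, names(cohort))
    if (length(missing_cols)) {
      stop("conditioning covariate(s) absent from cohort: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    cond_x <- scale(vapply(cond_cols, function(cc) {
      x <- cohort[[cc]]
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      as.numeric(x)
    }, numeric(n)))
    colnames(cond_x) <- cond_cols
  }

  chain_seeds <- derive_seeds(seed, chains)
  trace <- array(NA_real_, dim = c(chains, n_iter, length(vars)),
                 dimnames = list(NULL, NULL, vars))
  datasets <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    last <- NULL
    for (it in seq_len(n_iter)) {
      sw <- .sweep_chain(n, registry, cond_x)
      trace[ch, it, ] <- sw$monitored[vars]
      last <- sw$values
    }
    dat <- as.data.frame(cohort)
    for (col in names(last)) dat[[col]] <- last[[col]]
    datasets[[ch]] <- as_cohort(dat, provenance = paste0("imputed:", ch))
  }

  res <- structure(list(datasets = datasets, trace = trace,
                        burn_in = burn_in, chains = chains,
                        registry = registry, seed = seed),
                   class = "nephra_imputation")
  res$gelman_rubin <- gelman_rubin(res)
  res
}

#' Gelman-Rubin potential scale reduction
#'
#' R-hat = sqrt(((N-1)/N * W + B/N) / W), with W the mean within-chain
#' variance and B = N * variance of chain means of the monitored parameter.
#' Zero within-chain variance is reported as R-hat = 1 with a `degenerate`
#' attribute.
#'
#' @param trace a `nephra_imputation` (post-burn-in trace is used), a
#'   chains x iterations matrix, or a chains x iterations x variables array.
#' @return named vector of R-hat values with attribute `degenerate`.
#' @export
gelman_rubin <- function(trace) {
  if (inherits(trace, "nephra_imputation")) {
    keep <- seq(trace$burn_in + 1L, dim(trace$trace)[2])
    trace <- trace$trace[, keep, , drop = FALSE]
  }
  if (length(dim(trace)) == 2) {
    trace <- array(trace, dim = c(dim(trace), 1),
                   dimnames = list(NULL, NULL, "param"))
  }
  m <- dim(trace)[1]
  n <- dim(trace)[2]
  if (m < 2 || n < 2) {
    stop("gelman_rubin needs >= 2 chains and >= 2 iterations", call. = FALSE)
  }
  vars <- dimnames(trace)[[3]]
  rhat <- numeric(length(vars))
  degenerate <- logical(length(vars))
  names(rhat) <- names(degenerate) <- vars
  for (k in seq_along(vars)) {
    x <- trace[, , k]
    w <- mean(apply(x, 1, stats::var))
    b <- n * stats::var(rowMeans(x))
    if (w < .Machine$double.eps) {
      rhat[k] <- 1
      degenerate[k] <- TRUE
    } else {
      rhat[k] <- sqrt(((n - 1) / n * w + b / n) / w)
    }
  }
  attr(rhat, "degenerate") <- degenerate
  rhat
}

#' Pooled prevalence of an imputed variable
#'
#' Mean of the variable across all completed datasets (Rubin pooling of a
#' proportion).
#'
#' @param res a `nephra_imputation`.
#' @param var registry variable name (without the `lit_` prefix).
#' @return pooled mean.
#' @export
pooled_prevalence <- function(res, var) {
  col <- paste0("lit_", var)
  mean(vapply(res$datasets, function(d) mean(d[[col]]), 0))
}

#' Posterior-predictive fidelity check
#'
#' Discrepancy statistic: sum over variables of squared standardised
#' differences between each completed dataset's summary (prevalence for
#' binary variables, mean grade otherwise) and its prior value, averaged
#' over datasets. The p-value is the fraction of prior-replicated dataset
#' sets whose discrepancy is at least the observed one; values near 0
#' indicate imputations inconsistent with the priors.
#'
#' @param res a `nephra_imputation`.
#' @param registry the prior registry (defaults to the one used to impute).
#' @param draws number of prior-predictive replicate sets.
#' @param seed RNG seed.
#' @return list with `p_value`, `observed` discrepancy, and the per-variable
#'   standardisation used.
#' @export
posterior_predictive_check <- function(res, registry = res$registry,
                                       draws = 1000, seed = 1) {
  n <- nrow(res$datasets[[1]])
  m <- length(res$datasets)
  vars <- names(registry$entries)

  prior_mean <- vapply(registry$entries, function(e) {
    switch(e$kind,
           binary = e$prevalence,
           ordinal = sum((seq_along(e$prevalence) - 1) * e$prevalence),
           quintile = sum(seq_along(e$prevalence) * e$prevalence),
           continuous = e$prevalence)
  }, 0)

  sim_summary <- function(e) {
    if (e$kind == "binary") {
      p <- inv_logit(stats::rnorm(1, logit(e$prevalence), 0.05))
      stats::rbinom(1, n, p) / n
    } else if (e$kind %in% c("ordinal", "quintile")) {
      g <- stats::rgamma(length(e$prevalence), e$prevalence * 200)
      probs <- g / sum(g)
      lev <- if (e$kind == "ordinal") seq_along(probs) - 1 else
        seq_along(probs)
      counts <- stats::rmultinom(1, n, probs)
      sum(lev * counts) / n
    } else {
      stats::rnorm(1, e$prevalence, 1 / sqrt(n))
    }
  }

  set.seed(seed)
  # prior-predictive scale of each summary, estimated once by simulation
  calib <- vapply(vars, function(v) {
    stats::sd(replicate(400, sim_summary(registry$entries[[v]])))
  }, 0)
  calib <- pmax(calib, 1e-12)

  obs_summ <- vapply(vars, function(v) {
    e <- registry$entries[[v]]
    col <- paste0("lit_", v)
    mean(vapply(res$datasets, function(d) mean(d[[col]]), 0))
  }, 0)
  # discrepancy of the mean over M datasets, on the scale of a pooled mean
  disc <- function(summ) sum(((summ - prior_mean) / (calib / sqrt(m)))^2)
  observed <- disc(obs_summ)

  reps <- replicate(draws, {
    summ <- vapply(vars, function(v) {
      mean(replicate(m, sim_summary(registry$entries[[v]])))
    }, 0)
    disc(summ)
  })
  list(p_value = mean(reps >= observed), observed = observed,
       scale = calib)
}

#' @export
print.nephra_imputation <- function(x, ...) {
  cat(sprintf("<nephra_imputation> %d chains x %d patients, burn-in %d\n",
              x$chains, nrow(x$datasets[[1]]), x$burn_in))
  cat("  max Gelman-Rubin R-hat:", format(max(x$gelman_rubin), digits = 4),
      "\n")
  invisible(x)
}
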