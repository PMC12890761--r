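# Small numeric helpers shared across modules.

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# complementary log-log of an event probability
cloglog <- function(p) log(-log(1 - p))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated normal via inverse-CDF; bounds may be +-Inf
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Derive a reproducible stream of sub-seeds from one integer seed.
derive_seeds <- function(seed, k) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Kaplan-Meier censoring survival function
#'
#' Estimates the survival function of the censoring process, G(t), by
#' Kaplan-Meier on the censoring indicator. Returned closure evaluates
#' G right-continuously; `minus = TRUE` gives the left limit G(t-), the
#' convention used to weight events (ties broken event-before-censor).
#'
#' @param time follow-up times.
#' @param event 0/1 or logical event indicator (1 = event, 0 = censored).
#' @return function(t, minus = FALSE) returning G evaluated at t.
#' @keywords internal
km_censoring <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - as.numeric(event)) ~ 1)
  kt <- c(0, fit$time)
  ks <- c(1, fit$surv)
  function(t, minus = FALSE) {
    tt <- if (minus) t - 1e-9 else t
    idx <- findInterval(tt, kt)
    ks[pmax(idx, 1L)]
  }
}

# binary outcome status at the horizon:
#  1 = event by horizon, 0 = event-free through horizon (or competing-risk
#  censoring, treated as non-event), NA = administratively indeterminable
status_at_horizon <- function(cohort, horizon = 36) {
  ev <- cohort$event & cohort$followup_months <= horizon
  neg <- (!cohort$event & cohort$followup_months >= horizon) |
    (cohort$event & cohort$followup_months > horizon) |
    (!cohort$event & cohort$censor_reason %in% c("death", "transplant"))
  out <- rep(NA_real_, nrow(cohort))
  out[ev] <- 1
  out[neg & !ev] <- 0
  out
}
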