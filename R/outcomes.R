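#' @title Composite outcome adjudication
#' @description
#' Applies the composite kidney-outcome definition to longitudinal lab
#' series: (1) new eGFR < 60 with a >= 25% decline from the index
#' baseline, (2) ACR >= 30 mg/g sustained for >= 3 consecutive months,
#' (3) ESRD / renal replacement therapy, or (4) biopsy-proven disease.
#' Death or transplant censors at its month. Any criterion alone
#' suffices; the earliest qualifying month wins.
#' @name outcomes
NULL

#' Outcome rule parameters
#'
#' @param egfr_threshold eGFR onset threshold (mL/min, default 60).
#' @param decline_fraction required decline from baseline (default 0.25).
#' @param acr_threshold albuminuria threshold (mg/g, default 30).
#' @param sustained_months consecutive months ACR must stay at/above the
#'   threshold (default 3).
#' @param horizon months (default 36).
#' @return an `outcome_rule`.
#' @export
outcome_rule <- function(egfr_threshold = 60, decline_fraction = 0.25,
                         acr_threshold = 30, sustained_months = 3,
                         horizon = 36) {
  stopifnot(egfr_threshold > 0, decline_fraction > 0, acr_threshold > 0,
            sustained_months > 0, horizon > 0)
  structure(list(egfr_threshold = egfr_threshold,
                 decline_fraction = decline_fraction,
                 acr_threshold = acr_threshold,
                 sustained_months = sustained_months,
                 horizon = horizon), class = "outcome_rule")
}

#' Adjudicate the composite outcome for one patient
#'
#' @param baseline list or one-row data frame with index-visit `egfr` and
#'   `acr`.
#' @param labs long-format follow-up data frame with columns `month` and
#'   any of `egfr`, `acr`, `esrd`, `biopsy`, `death`, `transplant`
#'   (flags default to absent); must be time-ordered.
#' @param rule an `outcome_rule`.
#' @return list(event, event_month, criterion, censor_reason).
#'   `event_month` is NA
#'   when neither an event nor a censoring occurs in the series. The
#'   sustained-albuminuria criterion requires a measurement >= threshold in
#'   each of `sustained_months` consecutive months and dates the event at
#'   the window end; the eGFR criterion requires both sub-conditions
#'   (below threshold AND >= 25% below the index baseline) at the same
#'   visit.
#' @export
adjudicate <- function(baseline, labs, rule = outcome_rule()) {
  baseline <- as.list(as.data.frame(baseline))
  if (is.null(baseline$egfr) || is.na(baseline$egfr)) {
    stop("input error: baseline eGFR required", call. = FALSE)
  }
  labs <- as.data.frame(labs)
  if (is.unsorted(labs$month, strictly = FALSE)) {
    stop("input error: lab series must be time-ordered", call. = FALSE)
  }
  get_flag <- function(nm) {
    if (is.null(labs[[nm]])) rep(FALSE, nrow(labs)) else
      !is.na(labs[[nm]]) & as.logical(labs[[nm]])
  }
  esrd <- get_flag("esrd"); biopsy <- get_flag("biopsy")
  death <- get_flag("death"); transplant <- get_flag("transplant")

  candidates <- data.frame(month = numeric(0), what = character(0))
  add <- function(month, what) {
    rbind(candidates, data.frame(month = month, what = what))
  }
  # composite rule: eGFR below threshold AND decline >= fraction of baseline
  if (!is.null(labs$egfr)) {
    hit <- !is.na(labs$egfr) & labs$egfr < rule$egfr_threshold &
      labs$egfr <= (1 - rule$decline_fraction) * baseline$egfr
    if (any(hit)) candidates <- add(min(labs$month[hit]), "egfr_decline")
  }
  # composite rule: sustained albuminuria over consecutive months
  if (!is.null(labs$acr)) {
    high <- labs$month[!is.na(labs$acr) & labs$acr >= rule$acr_threshold]
    high <- sort(unique(high))
    k <- rule$sustained_months
    if (length(high) >= k) {
      runs <- which(high[seq_len(length(high) - k + 1) + (k - 1)] -
                      high[seq_len(length(high) - k + 1)] == k - 1)
      if (length(runs)) {
        candidates <- add(high[min(runs)] + k - 1, "sustained_acr")
      }
    }
  }
  if (any(esrd)) candidates <- add(min(labs$month[esrd]), "esrd")
  if (any(biopsy)) candidates <- add(min(labs$month[biopsy]), "biopsy")

  censor_month <- Inf
  censor_reason <- "none"
  if (any(death)) {
    censor_month <- min(labs$month[death]); censor_reason <- "death"
  }
  if (any(transplant) && min(labs$month[transplant]) < censor_month) {
    censor_month <- min(labs$month[transplant])
    censor_reason <- "transplant"
  }

  if (nrow(candidates) && min(candidates$month) <= censor_month) {
    m <- min(candidates$month)
    return(list(event = TRUE, event_month = m,
                criterion = candidates$what[which.min(candidates$month)],
                censor_reason = "none"))
  }
  if (is.finite(censor_month)) {
    return(list(event = FALSE, event_month = censor_month,
                criterion = NA_character_, censor_reason = censor_reason))
  }
  list(event = FALSE, event_month = NA_real_, criterion = NA_character_,
       censor_reason = "none")
}
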