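#' @title Patient cohorts
#' @description
#' A cohort is a data frame with one row per patient carrying demographics,
#' labs, comorbidities, follow-up time in whole months, an event indicator
#' and a censoring reason. Literature-informed variables appear as `lit_*`
#' columns once imputed; the synthetic generator additionally retains ground
#' truth in `true_*` columns. Missing values are empty CSV cells, never
#' sentinel numbers.
#' @name cohort
NULL

.required_cols <- c("patient_id", "index_date", "age", "sex", "egfr",
                    "followup_months", "event")

.numeric_cols <- c("age", "bmi", "waist_circumference", "sbp", "dbp", "egfr",
                   "acr", "hba1c", "phosphorus", "fgf23", "diabetes_duration",
                   "medication_compliance", "followup_months")

.censor_levels <- c("none", "administrative", "death", "transplant")

#' Construct a cohort from a data frame
#'
#' Validates the core invariants (unique patient ids, positive follow-up,
#' events carry censor_reason "none") and stamps provenance.
#'
#' @param df data frame of patient records.
#' @param provenance one of "observed", "synthetic", or "imputed:<chain>".
#' @return a `nephra_cohort` (a data frame).
#' @export
as_cohort <- function(df, provenance = "observed") {
  stopifnot(is.data.frame(df))
  miss <- setdiff(.required_cols, names(df))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    stop("integrity error: duplicate patient_id in cohort", call. = FALSE)
  }
  if (is.null(df$censor_reason)) df$censor_reason <- "none"
  df$event <- as.logical(df$event)
  if (any(!is.na(df$followup_months) & df$followup_months <= 0)) {
    stop("invariant violated: followup_months must be > 0", call. = FALSE)
  }
  bad <- df$event & df$censor_reason != "none"
  if (any(bad, na.rm = TRUE)) {
    stop("invariant violated: event implies censor_reason == 'none'",
         call. = FALSE)
  }
  structure(df,
            class = c("nephra_cohort", "data.frame"),
            provenance = provenance)
}

#' Read a patient cohort from CSV
#'
#' Expects a header row; `index_date` is an ISO-8601 month ("YYYY-MM").
#' Unparseable numeric cells become missing, with the count reported via a
#' message. A missing required column is a schema error; a duplicate
#' patient id is an integrity error.
#'
#' @param path CSV file path.
#' @param provenance provenance tag for the cohort.
#' @return a `nephra_cohort`.
#' @export
read_cohort <- function(path, provenance = "observed") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  miss <- setdiff(.required_cols, names(raw))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_bad <- 0L
  for (col in intersect(c(.numeric_cols, grep("^(true_|lit_|miss_)",
                                              names(raw), value = TRUE)),
                        names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- n_bad + sum(is.na(parsed) & !is.na(raw[[col]]))
    raw[[col]] <- parsed
  }
  raw$event <- tolower(raw$event) %in% c("true", "t", "1", "yes")
  for (col in intersect(c("hypertension", "cvd"), names(raw))) {
    raw[[col]] <- tolower(raw[[col]]) %in% c("true", "t", "1", "yes")
  }
  if (n_bad > 0) message("read_cohort: ", n_bad,
                         " unparseable cell(s) set to missing")
  as_cohort(raw, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty cells so that
#' `read_cohort(write_cohort(x))` round-trips all non-missing fields.
#'
#' @param cohort a `nephra_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.nephra_cohort <- function(x, ...) {
  cat(sprintf("<nephra_cohort> %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  if (!is.null(x$event)) {
    cat(sprintf("  events: %d; median follow-up: %s months\n",
                sum(x$event, na.rm = TRUE),
                format(stats::median(x$followup_months, na.rm = TRUE))))
  }
  invisible(x)
}

#' CKD stage from eGFR
#'
#' Maps eGFR (mL/min/1.73m^2) to the stage brackets none (>=90),
#' s1_2 (60-89), s3a (45-59), s3b (30-44), s4 (<30). Boundary values go to
#' the better-function stage (90 -> none, 60 -> s1_2). Total and
#' deterministic on (0, Inf); nonpositive eGFR is a domain error.
#'
#' @param egfr numeric vector of eGFR values.
#' @return factor with levels none, s1_2, s3a, s3b, s4.
#' @export
ckd_stage <- function(egfr) {
  if (any(!is.na(egfr) & egfr <= 0)) {
    stop("domain error: egfr must be positive", call. = FALSE)
  }
  breaks <- c(0, 30, 45, 60, 90, Inf)
  labs <- c("s4", "s3b", "s3a", "s1_2", "none")
  factor(labs[findInterval(egfr, breaks)],
         levels = c("none", "s1_2", "s3a", "s3b", "s4"))
}

#' Default clinical plausibility bounds
#'
#' Safety ranges used for input validation; eGFR 5-150 and HbA1c 4-20 are
#' the deployed model's published bounds, the rest are physiologic ranges.
#'
#' @return named list of c(lower, upper) bounds.
#' @export
default_bounds <- function() {
  list(
    age = c(18, 110),
    bmi = c(10, 80),
    waist_circumference = c(40, 220),
    sbp = c(60, 260),
    dbp = c(30, 160),
    egfr = c(5, 150),
    acr = c(0.1, 15000),
    hba1c = c(4, 20),
    phosphorus = c(0.5, 15),
    fgf23 = c(1, 5000),
    diabetes_duration = c(0, 80),
    medication_compliance = c(0, 10)
  )
}

#' Validate records against model bounds
#'
#' Reports (never mutates) out-of-range values. Missing values are not
#' violations; they are flagged as missing elsewhere.
#'
#' @param records a cohort or data frame of patient records.
#' @param spec a `risk_model_spec` (its `bounds` are used) or a plain list of
#'   bounds as from [default_bounds()].
#' @return data frame of violations with columns patient_id, field, value,
#'   bound, side; zero rows when everything is in range.
#' @export
validate_record <- function(records, spec = NULL) {
  bounds <- if (is.null(spec)) default_bounds()
            else if (inherits(spec, "risk_model_spec")) spec$bounds
            else spec
  records <- as.data.frame(records)
  out <- list()
  for (field in intersect(names(bounds), names(records))) {
    v <- records[[field]]
    b <- bounds[[field]]
    low <- !is.na(v) & v < b[1]
    high <- !is.na(v) & v > b[2]
    if (any(low)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = as.character(records$patient_id[low]),
        field = field, value = v[low], bound = b[1], side = "lower")
    }
    if (any(high)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = as.character(records$patient_id[high]),
        field = field, value = v[high], bound = b[2], side = "upper")
    }
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), field = character(),
                      value = numeric(), bound = numeric(),
                      side = character()))
  }
  do.call(rbind, out)
}
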