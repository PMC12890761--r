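#' @title Literature prior registry
#' @description
#' Machine-readable registry of the published effect sizes and prevalences
#' behind the literature-informed variables: for each variable a
#' distribution kind (binary / ordinal / quintile), its population
#' prevalence or category probabilities, per-level log hazard ratios with
#' standard errors, a source label, and an optional conditioning map of
#' observed-covariate association coefficients. A registry carries a global
#' `scale` applied on the log-HR scale (1 = literature, 0.5 = weakened,
#' 1.5 = strengthened, 0 = flat/non-informative).
#' @name priors
NULL

.validate_prior <- function(name, e) {
  if (is.null(e$kind) ||
      !e$kind %in% c("binary", "ordinal", "quintile", "continuous")) {
    stop("schema error in prior '", name, "': field 'kind' must be one of ",
         "binary/ordinal/quintile/continuous", call. = FALSE)
  }
  if (is.null(e$prevalence)) {
    stop("schema error in prior '", name, "': field 'prevalence' missing",
         call. = FALSE)
  }
  p <- e$prevalence
  if (length(p) > 1 && abs(sum(p) - 1) > 1e-9) {
    stop("schema error in prior '", name,
         "': category probabilities must sum to 1", call. = FALSE)
  }
  if (length(p) == 1 && (p < 0 || p > 1)) {
    stop("schema error in prior '", name,
         "': field 'prevalence' not a probability", call. = FALSE)
  }
  if (!is.null(e$log_hr) && any(!is.finite(e$log_hr))) {
    stop("schema error in prior '", name, "': field 'log_hr' not finite",
         call. = FALSE)
  }
  if (!is.null(e$se) && any(e$se < 0)) {
    stop("schema error in prior '", name, "': field 'se' negative",
         call. = FALSE)
  }
  invisible(TRUE)
}

# standard error of a log-HR from a printed 95% CI
.se_from_ci <- function(ci) (log(ci[2]) - log(ci[1])) / 3.92

#' Load a prior registry from JSON
#'
#' The JSON schema is an object with a `scale` fraction and an `entries`
#' map name -> \{kind, prevalence, hr, ci (optional), se (optional),
#' source, conditioning (optional map covariate -> coefficient)\}. Hazard
#' ratios are converted to log-HRs; when a 95% CI is given the standard
#' error is (ln hi - ln lo)/3.92, otherwise it defaults to 0.10.
#'
#' @param path JSON file; defaults to the registry shipped with the package.
#' @return a `prior_registry`.
#' @export
load_registry <- function(path = system.file("extdata", "priors.json",
                                             package = "nephrarisk")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$entries) || !length(raw$entries)) {
    stop("schema error: registry has no 'entries'", call. = FALSE)
  }
  entries <- lapply(names(raw$entries), function(name) {
    e <- raw$entries[[name]]
    if (!is.null(e$hr)) e$log_hr <- log(e$hr)
    if (is.null(e$se)) {
      e$se <- if (!is.null(e$ci)) {
        ci <- e$ci
        if (is.matrix(ci)) apply(ci, 1, .se_from_ci) else .se_from_ci(ci)
      } else rep(0.10, length(e$log_hr %||% 1))
    }
    if (is.null(e$log_hr)) e$log_hr <- 0
    if (length(e$se) == 1 && length(e$log_hr) > 1) {
      e$se <- rep(e$se, length(e$log_hr))
    }
    e$name <- name
    e$conditioning <- if (length(e$conditioning)) {
      unlist(e$conditioning)
    } else {
      numeric(0)
    }
    .validate_prior(name, e)
    e
  })
  names(entries) <- names(raw$entries)
  structure(list(entries = entries, scale = raw$scale %||% 1.0),
            class = "prior_registry")
}

#' The registry shipped with the package
#' @return a `prior_registry` at scale 1.
#' @export
default_registry <- function() load_registry()

#' Rescale a registry's effect sizes
#'
#' Multiplies every log hazard ratio (and conditioning coefficient) by
#' `factor`, leaving prevalences untouched. Scaling is multiplicative on
#' the log-HR scale, so factor 0 reproduces flat non-informative priors
#' (all HR = 1) and scaling by a then b equals scaling by a*b.
#'
#' @param reg a `prior_registry`.
#' @param factor nonnegative scaling fraction.
#' @return a rescaled `prior_registry`.
#' @export
scale_registry <- function(reg, factor) {
  stopifnot(inherits(reg, "prior_registry"))
  if (factor < 0) stop("domain error: scale factor must be >= 0",
                       call. = FALSE)
  reg$entries <- lapply(reg$entries, function(e) {
    e$log_hr <- e$log_hr * factor
    if (length(e$conditioning)) e$conditioning <- e$conditioning * factor
    e
  })
  reg$scale <- reg$scale * factor
  reg
}

#' @export
print.prior_registry <- function(x, ...) {
  cat(sprintf("<prior_registry> %d entries, scale = %g\n",
              length(x$entries), x$scale))
  for (e in x$entries) {
    cat(sprintf("  %-18s %-8s HR %s\n", e$name, e$kind,
                paste(sprintf("%.2f", exp(e$log_hr)), collapse = "/")))
  }
  invisible(x)
}
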