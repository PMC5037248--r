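#' Relative risk estimate with log-scale standard error
#'
#' Container for a relative risk, its 95\% confidence interval, and the
#' log-scale standard error derived from that interval. The standard error is
#' what the substitution method samples from; it can also be supplied
#' directly when no interval is available.
#'
#' @param rr point estimate of the relative risk, positive.
#' @param ci_lower,ci_upper confidence bounds (optional; both or neither).
#'   Must satisfy `0 < ci_lower <= rr <= ci_upper`.
#' @param log_se standard error of `log(rr)`; derived from the bounds via
#'   [log_se_from_ci()] when omitted.
#' @param factor,outcome,stratum optional labels carried through to results.
#' @param z normal multiplier used to extract `log_se` from the bounds.
#' @return an object of class `"rr_estimate"`.
#' @examples
#' rr_estimate(1.5164, 1.3001, 1.7521, factor = "smoking",
#'             outcome = "CHD", stratum = "men")
#' @export
rr_estimate <- function(rr, ci_lower = NULL, ci_upper = NULL, log_se = NULL,
                        factor = NA_character_, outcome = NA_character_,
                        stratum = NA_character_, z = 1.96) {
  if (!is.numeric(rr) || length(rr) != 1L || is.na(rr) || rr <= 0) {
    stop("'rr' must be a single positive number", call. = FALSE)
  }
  has_ci <- !is.null(ci_lower) || !is.null(ci_upper)
  if (has_ci) {
    if (is.null(ci_lower) || is.null(ci_upper)) {
      stop("supply both 'ci_lower' and 'ci_upper', or neither", call. = FALSE)
    }
    if (ci_lower <= 0 || ci_lower > rr || ci_upper < rr) {
      stop("need 0 < ci_lower <= rr <= ci_upper", call. = FALSE)
    }
    if (is.null(log_se)) log_se <- log_se_from_ci(ci_lower, ci_upper, z = z)
  }
  if (!is.null(log_se) && (!is.numeric(log_se) || is.na(log_se) || log_se < 0)) {
    stop("'log_se' must be nonnegative", call. = FALSE)
  }
  structure(
    list(rr = rr,
         ci_lower = if (has_ci) ci_lower else NA_real_,
         ci_upper = if (has_ci) ci_upper else NA_real_,
         log_se = if (is.null(log_se)) NA_real_ else log_se,
         factor = factor, outcome = outcome, stratum = stratum, z = z),
    class = "rr_estimate"
  )
}

#' @export
print.rr_estimate <- function(x, digits = 4, ...) {
  lab <- paste(Filter(function(s) !is.na(s), c(x$factor, x$outcome, x$stratum)),
               collapse = " / ")
  if (nzchar(lab)) cat(lab, "\n")
  cat(sprintf("RR %s", format(round(x$rr, digits), nsmall = 0)))
  if (!is.na(x$ci_lower)) {
    cat(sprintf(" (95%% CI %s, %s)", round(x$ci_lower, digits), round(x$ci_upper, digits)))
  }
  cat("\n")
  if (!is.na(x$log_se)) cat(sprintf("log-scale SE %s\n", signif(x$log_se, 4)))
  invisible(x)
}

#' Crude risk ratio from an individual-level sample
#'
#' Estimates the unadjusted (crude) risk ratio of the outcome for one binary
#' risk factor from the 2x2 table of a [population_sample], with the
#' large-sample log-scale standard error
#' \deqn{SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}}
#' (`a` exposed cases, `b` exposed non-cases, `c` unexposed cases, `d`
#' unexposed non-cases) and a Wald confidence interval on the log scale.
#'
#' In a population with correlated risk factors the crude risk ratio is
#' confounded by the other exposures, which is exactly what feeding it into
#' Levin's formula inherits; see [attribution()].
#'
#' @param sample a [population_sample].
#' @param factor name of the factor, one of `sample$scenario$factors`.
#' @param z normal multiplier for the interval (default 1.96).
#' @return an [rr_estimate].
#' @examples
#' sc <- scenario(n = 20000, factors = "smoking", prevalence = 0.3,
#'                rr_true = 2, baseline_risk = 0.05)
#' estimate_crude_rr(simulate(sc, seed = 1), "smoking")
#' @export
estimate_crude_rr <- function(sample, factor, z = 1.96) {
  stopifnot(inherits(sample, "population_sample"))
  if (!factor %in% sample$scenario$factors) {
    stop(sprintf("factor '%s' is not in the sample", factor), call. = FALSE)
  }
  x <- sample$exposures[, factor]
  y <- sample$outcome
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  if (a + b == 0L || c_ + d == 0L || a == 0L || c_ == 0L) {
    stop("degenerate 2x2 table: need exposed and unexposed cases", call. = FALSE)
  }
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  rr_estimate(rr,
              ci_lower = rr * exp(-z * se), ci_upper = rr * exp(z * se),
              log_se = se, factor = factor, z = z)
}
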