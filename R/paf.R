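#' Fit a single-factor population attributable fraction with uncertainty
#'
#' The central single-factor estimator: computes the Levin PAR for one
#' exposure and propagates the sampling uncertainty of the relative risk
#' into the PAR by the substitution method. Prevalence is treated as fixed —
#' its sampling variability is assumed negligible relative to that of the
#' RR — so the only random quantity is the RR, modelled as lognormal
#' (normal on `log(RR)`) with standard deviation `log_se`.
#'
#' Two interval methods are provided:
#' \describe{
#'   \item{`"monte-carlo"`}{draws `n_iter` values of `log(RR)` from the
#'     normal sampling distribution, maps each through Levin's formula, and
#'     reports empirical percentiles (default 2.5th and 97.5th) as the
#'     confidence limits. Percentiles use linear interpolation between order
#'     statistics ([stats::quantile()] type 7). Reproducible under `seed`.}
#'   \item{`"substitution"`}{the deterministic closed form: because Levin's
#'     formula is strictly increasing in RR, the exact interval is the
#'     formula evaluated at the lognormal quantiles of RR. This is the
#'     large-`n_iter` limit of the Monte Carlo interval.}
#' }
#'
#' The sampling distribution can be centred at the log of the point RR
#' (`location = "point"`, the default) or at the midpoint of the log-scale
#' confidence bounds (`location = "geometric-mean"`), which differ slightly
#' when a published interval is not log-symmetric around the rounded point
#' estimate. The location used is recorded in the fitted object.
#'
#' @param pe exposure prevalence, a proportion in `[0, 1]`.
#' @param rr an [rr_estimate], or a positive number (then supply bounds or
#'   `log_se`).
#' @param ci_lower,ci_upper optional RR confidence bounds when `rr` is
#'   numeric.
#' @param log_se optional standard error of `log(RR)` when `rr` is numeric
#'   and no bounds are given.
#' @param method interval method: `"monte-carlo"` (default),
#'   `"substitution"`, or `"none"` (point estimate only).
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed integer seed for the Monte Carlo draws (default 1).
#' @param percentiles lower and upper interval probabilities, default
#'   `c(0.025, 0.975)`.
#' @param location `"point"` or `"geometric-mean"`; centre of the `log(RR)`
#'   sampling distribution.
#' @param z normal multiplier used when extracting `log_se` from bounds.
#' @param factor,outcome,stratum optional labels.
#' @return an object of class `"paf"` with components `par` (point estimate,
#'   proportion scale), `ci_lower`, `ci_upper`, and metadata (`method`,
#'   `location`, `n_iter`, `seed`, `percentiles`, `pe`, `rr`).
#' @seealso [levin_par()], [substitution_ci()], [par_to_percent()]
#' @examples
#' smoking <- rr_estimate(1.5164, 1.3001, 1.7521)
#' fit <- paf(0.649, smoking, seed = 7)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
paf <- function(pe, rr, ci_lower = NULL, ci_upper = NULL, log_se = NULL,
                method = c("monte-carlo", "substitution", "none"),
                n_iter = 10000L, seed = 1L,
                percentiles = c(0.025, 0.975),
                location = c("point", "geometric-mean"), z = 1.96,
                factor = NULL, outcome = NULL, stratum = NULL) {
  method <- match.arg(method)
  location <- match.arg(location)
  if (!inherits(rr, "rr_estimate")) {
    rr <- rr_estimate(rr, ci_lower = ci_lower, ci_upper = ci_upper,
                      log_se = log_se, z = z)
  }
  stop_if_not_proportion(pe, "pe")
  if (length(pe) != 1L) stop("'pe' must be a single prevalence", call. = FALSE)

  point <- levin_par(pe, rr$rr)
  loc_log <- switch(location,
    "point" = log(rr$rr),
    "geometric-mean" = {
      if (is.na(rr$ci_lower)) {
        stop("location = 'geometric-mean' needs RR confidence bounds", call. = FALSE)
      }
      (log(rr$ci_lower) + log(rr$ci_upper)) / 2
    })

  ci <- c(NA_real_, NA_real_)
  if (method != "none") {
    if (is.na(rr$log_se)) {
      stop("interval estimation needs 'log_se' or RR confidence bounds", call. = FALSE)
    }
    if (!is.numeric(percentiles) || length(percentiles) != 2L ||
        any(percentiles <= 0) || any(percentiles >= 1) ||
        percentiles[1] >= percentiles[2]) {
      stop("'percentiles' must be an increasing pair in (0, 1)", call. = FALSE)
    }
    if (method == "monte-carlo") {
      if (!is.numeric(n_iter) || n_iter < 2) stop("'n_iter' must be >= 2", call. = FALSE)
      set.seed(as.integer(seed))
      draws <- levin_par(pe, exp(stats::rnorm(n_iter, loc_log, rr$log_se)))
      ci <- unname(stats::quantile(draws, percentiles, type = 7))
    } else {
      ci <- substitution_ci(pe, exp(loc_log), rr$log_se, percentiles = percentiles)
    }
  }

  structure(
    list(par = point, ci_lower = ci[1], ci_upper = ci[2],
         pe = pe, rr = rr, method = method, location = location,
         n_iter = if (method == "monte-carlo") as.integer(n_iter) else NA_integer_,
         seed = if (method == "monte-carlo") as.integer(seed) else NA_integer_,
         percentiles = percentiles,
         factor = if (is.null(factor)) rr$factor else factor,
         outcome = if (is.null(outcome)) rr$outcome else outcome,
         stratum = if (is.null(stratum)) rr$stratum else stratum),
    class = "paf"
  )
}

#' Closed-form substitution interval for a Levin PAR
#'
#' Deterministic counterpart of the Monte Carlo substitution interval:
#' Levin's formula is strictly increasing in RR, so the exact percentile
#' interval of the PAR is the formula evaluated at the lognormal quantiles
#' of the RR, `exp(log(rr) + qnorm(p) * log_se)`. Serves as the analytic
#' oracle that the Monte Carlo interval converges to.
#'
#' @param pe exposure prevalence in `[0, 1]`.
#' @param rr median of the RR sampling distribution.
#' @param log_se standard deviation of `log(RR)`, nonnegative.
#' @param percentiles increasing pair of probabilities, default 2.5/97.5\%.
#' @return numeric length-2 interval on the proportion scale; degenerate at
#'   the point PAR when `log_se = 0`. Always contained in
#'   `(-pe/(1-pe), 1)`.
#' @examples
#' substitution_ci(0.649, 1.5092, 0.07612)  # c(0.163, 0.328) to 3 d.p.
#' @export
substitution_ci <- function(pe, rr, log_se, percentiles = c(0.025, 0.975)) {
  if (!is.numeric(log_se) || anyNA(log_se) || any(log_se < 0)) {
    stop("'log_se' must be nonnegative", call. = FALSE)
  }
  rr_q <- exp(log(rr) + stats::qnorm(percentiles) * log_se)
  par_at_rr_bound(pe, rr_q)
}

#' @export
print.paf <- function(x, ...) {
  lab <- paste(Filter(function(s) !is.null(s) && !is.na(s),
                      c(x$factor, x$outcome, x$stratum)), collapse = " / ")
  cat("Population attributable fraction",
      if (nzchar(lab)) paste0("(", lab, ")") else "", "\n")
  cat(sprintf("  PAR: %.1f%%", par_to_percent(x$par)))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  (%.0f%% interval: %.1f, %.1f)",
                100 * diff(x$percentiles),
                par_to_percent(x$ci_lower), par_to_percent(x$ci_upper)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.paf <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  prevalence %.3f, RR %.4f", x$pe, x$rr$rr))
  if (!is.na(x$rr$log_se)) cat(sprintf(", log-SE %.5f", x$rr$log_se))
  cat("\n")
  if (x$method == "monte-carlo") {
    cat(sprintf("  Monte Carlo substitution interval: %d iterations, seed %d, location '%s'\n",
                x$n_iter, x$seed, x$location))
  } else if (x$method == "substitution") {
    cat(sprintf("  closed-form substitution interval, location '%s'\n", x$location))
  }
  invisible(x)
}

#' @export
coef.paf <- function(object, ...) c(par = object$par)

#' @export
confint.paf <- function(object, parm, level, ...) {
  out <- matrix(c(object$ci_lower, object$ci_upper), nrow = 1,
                dimnames = list("par", paste0(100 * object$percentiles, " %")))
  out
}
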