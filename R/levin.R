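#' Levin population attributable risk for a dichotomous exposure
#'
#' Computes the population attributable risk proportion (PAR, also written
#' PAF) from the prevalence of a binary exposure and the relative risk of
#' disease in the exposed,
#' \deqn{PAR = \frac{P_e (RR - 1)}{P_e (RR - 1) + 1},}
#' where \eqn{P_e} is the exposure prevalence in the whole population and
#' \eqn{RR} the relative risk. The PAR is the proportional reduction in
#' disease burden expected if the exposure were eliminated, assuming the RR
#' is causal and unconfounded.
#'
#' The value is negative when `rr < 1` (a protective exposure) and is never
#' truncated to zero: negative attributable fractions are meaningful and are
#' retained throughout the package. `rr = 1` or `pe = 0` give exactly `0`.
#'
#' @param pe exposure prevalence, a proportion in `[0, 1]`. Vectorised.
#' @param rr relative risk, strictly positive. Vectorised (recycled against
#'   `pe`).
#' @return PAR on the proportion scale, in `(-pe/(1-pe), 1)`.
#' @seealso [invert_rr()] for the algebraic inverse, [par_at_rr_bound()] for
#'   evaluation at a confidence bound, [paf()] for interval estimation.
#' @examples
#' levin_par(0.5, 2)        # 1/3
#' levin_par(0.649, 1.5164) # 0.2510, the male smoking CHD fraction
#' levin_par(0.3, 0.8)      # negative: protective exposure
#' @export
levin_par <- function(pe, rr) {
  stop_if_not_proportion(pe, "pe")
  if (!is.numeric(rr) || anyNA(rr) || any(rr <= 0)) {
    stop("'rr' must be a positive relative risk", call. = FALSE)
  }
  num <- pe * (rr - 1)
  denom <- num + 1
  if (any(denom <= 0)) {
    stop("denominator pe*(rr - 1) + 1 must be positive (violated only at pe = 1, rr = 0)",
         call. = FALSE)
  }
  num / denom
}

#' Relative risk implied by an attributable fraction
#'
#' Algebraic inverse of [levin_par()] in the relative risk: given a PAR and
#' the exposure prevalence, returns the RR that reproduces it,
#' \deqn{RR = 1 + \frac{PAR}{P_e (1 - PAR)}.}
#' Used to back-derive relative-risk fixtures from published PAR tables when
#' the source RRs are not printed.
#'
#' @param par attributable fraction on the proportion scale, `< 1`. Vectorised.
#' @param pe exposure prevalence, strictly positive. Vectorised.
#' @return implied relative risk; `levin_par(pe, invert_rr(par, pe))`
#'   recovers `par` to floating-point accuracy.
#' @examples
#' invert_rr(1 / 3, 0.5)     # 2
#' invert_rr(0.251, 0.649)   # 1.5164 to 4 d.p.
#' @export
invert_rr <- function(par, pe) {
  if (!is.numeric(par) || anyNA(par) || any(par >= 1)) {
    stop("'par' must be numeric and < 1", call. = FALSE)
  }
  stop_if_not_proportion(pe, "pe", allow_zero = FALSE)
  rr <- 1 + par / (pe * (1 - par))
  if (any(rr <= 0)) {
    stop("implied relative risk is non-positive; 'par' is below the attainable minimum -pe/(1-pe)",
         call. = FALSE)
  }
  rr
}

#' Log-scale standard error of a relative risk from its confidence interval
#'
#' Extracts the standard error of `log(RR)` from a reported confidence
#' interval, assuming the interval was built symmetrically on the log scale:
#' \deqn{SE = \frac{\ln(U) - \ln(L)}{2 z}.}
#'
#' @param ci_lower,ci_upper positive confidence bounds, `ci_lower <= ci_upper`.
#' @param z normal multiplier of the interval (default `1.96` for a 95\% CI).
#' @return nonnegative standard error of `log(RR)`; zero iff the bounds are
#'   equal.
#' @examples
#' log_se_from_ci(1.3001, 1.7521)  # 0.07612 to 5 d.p.
#' @export
log_se_from_ci <- function(ci_lower, ci_upper, z = 1.96) {
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) || anyNA(ci_lower) || anyNA(ci_upper) ||
      any(ci_lower <= 0) || any(ci_upper <= 0)) {
    stop("confidence bounds must be positive", call. = FALSE)
  }
  if (any(ci_upper < ci_lower)) stop("'ci_upper' must be >= 'ci_lower'", call. = FALSE)
  if (!is.numeric(z) || length(z) != 1L || is.na(z) || z <= 0) {
    stop("'z' must be a positive scalar", call. = FALSE)
  }
  (log(ci_upper) - log(ci_lower)) / (2 * z)
}

#' PAR evaluated at a relative-risk confidence bound
#'
#' The substitution method propagates RR uncertainty into the PAR by
#' evaluating Levin's formula at the RR confidence bounds; because the
#' formula is strictly increasing in RR, the transformed bounds are the PAR
#' bounds. This is a named alias of [levin_par()] used at interval endpoints.
#'
#' @inheritParams levin_par
#' @param rr_bound a confidence bound of the relative risk, positive.
#' @return PAR at the bound, proportion scale.
#' @examples
#' par_at_rr_bound(0.649, 1.3001)  # 0.1630: lower PAR bound
#' par_at_rr_bound(0.649, 1.7521)  # 0.3280: upper PAR bound
#' @export
par_at_rr_bound <- function(pe, rr_bound) {
  levin_par(pe, rr_bound)
}
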