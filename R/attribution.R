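# Multifactor attributable-fraction estimators computed on individual-level
# samples. All elimination effects are evaluated on model risks
# (expectations), which makes the telescoping and additivity identities
# exact; the sampled outcomes enter only through the crude and case-based
# estimators that mimic what an analyst would compute from observed data.

# Mean counterfactual risk for every subset of factors removed, keyed by
# bitmask over the factor order (element i+1 = mask i). 2^K entries; used by
# the Shapley recursion so the K! ordering average never enumerates
# orderings.
subset_mean_risk <- function(sample) {
  sc <- sample$scenario
  K <- length(sc$factors)
  lr <- log(sc$rr_true)
  contrib <- sweep(sample$exposures, 2, lr, "*")  # n x K log-risk contributions
  total <- if (K > 0) rowSums(contrib) else numeric(length(sample$outcome))
  vapply(0:(2^K - 1), function(mask) {
    removed <- which(bitwAnd(mask, bitwShiftL(1L, 0:(max(K, 1) - 1))) > 0)
    removed <- removed[removed <= K]
    drop <- if (length(removed)) rowSums(contrib[, removed, drop = FALSE]) else 0
    mean(sc$baseline_risk * exp(total - drop))
  }, numeric(1))
}

#' Case-based (Miettinen) attributable fraction
#'
#' The attributable fraction from the exposure prevalence among cases,
#' \deqn{PAF = p_c \frac{RR - 1}{RR},}
#' which stays internally valid under confounding when `rr` is an adjusted
#' relative risk, unlike the crude Levin form. By default `p_c` is the
#' risk-weighted exposure prevalence (exposure prevalence among expected
#' cases, `sum(risk * x) / sum(risk)`), which removes outcome-sampling
#' noise; `cases = "observed"` uses the sampled outcomes instead.
#'
#' @param sample a [population_sample].
#' @param factor factor label.
#' @param rr relative risk to attribute with; defaults to the scenario's
#'   true (adjusted) risk ratio for the factor. Supply
#'   `estimate_crude_rr(sample, factor)$rr` to see the confounded version.
#' @param cases `"model"` (risk-weighted, default) or `"observed"`
#'   (sampled outcomes; errors if the sample contains no cases).
#' @return attributable fraction on the proportion scale.
#' @examples
#' s <- simulate(demo_scenario(n = 20000), seed = 5)
#' case_based_paf(s, "smoking")
#' @export
case_based_paf <- function(sample, factor, rr = NULL,
                           cases = c("model", "observed")) {
  stopifnot(inherits(sample, "population_sample"))
  cases <- match.arg(cases)
  if (!factor %in% sample$scenario$factors) {
    stop(sprintf("factor '%s' is not in the sample", factor), call. = FALSE)
  }
  if (is.null(rr)) rr <- unname(sample$scenario$rr_true[factor])
  if (!is.numeric(rr) || rr <= 0) stop("'rr' must be positive", call. = FALSE)
  x <- sample$exposures[, factor]
  p_c <- if (cases == "model") {
    sum(sample$model_risk * x) / sum(sample$model_risk)
  } else {
    if (sum(sample$outcome) == 0) stop("no cases in sample", call. = FALSE)
    mean(x[sample$outcome == 1])
  }
  p_c * (rr - 1) / rr
}

#' Sequential attributable fractions for an elimination ordering
#'
#' Removes the factors one at a time in the given order and attributes to
#' the k-th factor the share of the original mean risk eliminated at its
#' step:
#' \deqn{SAF_k = \frac{\bar r(F_{1..k-1}) - \bar r(F_{1..k})}{\bar r}.}
#' The fractions telescope: for every ordering they sum exactly to the
#' joint PAF (`true_paf(sample)`); a factor's share depends on its position
#' because earlier removals shrink the remaining attributable pool.
#'
#' @param sample a [population_sample].
#' @param ordering a permutation of the configured factors (default: the
#'   configuration order).
#' @return named vector of per-factor fractions, in elimination order.
#' @seealso [average_paf()] for the order-free summary.
#' @examples
#' s <- simulate(demo_scenario(n = 20000), seed = 5)
#' saf <- sequential_paf(s)
#' sum(saf) - true_paf(s)   # 0 to machine precision
#' @export
sequential_paf <- function(sample, ordering = sample$scenario$factors) {
  stopifnot(inherits(sample, "population_sample"))
  if (!setequal(ordering, sample$scenario$factors) ||
      length(ordering) != length(sample$scenario$factors)) {
    stop("'ordering' must be a permutation of the configured factors", call. = FALSE)
  }
  r0 <- mean(sample$model_risk)
  prev <- r0
  out <- numeric(length(ordering))
  for (k in seq_along(ordering)) {
    cur <- counterfactual_mean_risk(sample, ordering[seq_len(k)])
    out[k] <- (prev - cur) / r0
    prev <- cur
  }
  stats::setNames(out, ordering)
}

#' Average attributable fractions (Shapley decomposition)
#'
#' The per-factor mean of its sequential attributable fraction over all
#' `K!` elimination orderings — the Shapley value of the cooperative game
#' `v(S) = (mean risk - mean risk with S removed) / mean risk`. Computed
#' exactly from the `2^K` subset-risk table with the standard
#' `|S|! (K-|S|-1)! / K!` weights, never by enumerating orderings. Average
#' fractions are order-free and sum exactly to the joint PAF, making them
#' the preferred multifactor decomposition when risk factors are correlated.
#'
#' @param sample a [population_sample].
#' @param limit maximum number of factors for exact enumeration (default
#'   6; `2^K` subset evaluations).
#' @return named vector of per-factor average fractions.
#' @examples
#' s <- simulate(demo_scenario(n = 20000), seed = 5)
#' ap <- average_paf(s)
#' sum(ap) - true_paf(s)    # 0 to machine precision
#' @export
average_paf <- function(sample, limit = 6L) {
  stopifnot(inherits(sample, "population_sample"))
  K <- length(sample$scenario$factors)
  if (K == 0) return(stats::setNames(numeric(0), character(0)))
  if (K > limit) {
    stop(sprintf("exact enumeration limited to %d factors (2^K subsets); average over sampled orderings of sequential_paf() instead",
                 limit), call. = FALSE)
  }
  risks <- subset_mean_risk(sample)       # indexed by removal bitmask + 1
  r0 <- risks[1]
  v <- (r0 - risks) / r0                  # game value per removed subset
  lf <- lgamma(seq_len(K + 1))            # log factorials: lf[m+1] = log(m!)
  phi <- numeric(K)
  for (mask in 0:(2^K - 1)) {
    s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(K - 1))) > 0)
    for (j in 0:(K - 1)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(mask, bit) == 0) {
        w <- exp(lf[s + 1] + lf[K - s] - lf[K + 1])
        phi[j + 1] <- phi[j + 1] + w * (v[mask + bit + 1] - v[mask + 1])
      }
    }
  }
  stats::setNames(phi, sample$scenario$factors)
}

#' Side-by-side attribution report for a simulated population
#'
#' Fits every attributable-fraction estimator the package provides to one
#' sample and assembles them for comparison:
#' \describe{
#'   \item{crude Levin}{[levin_par()] at the empirical prevalence and the
#'     crude (confounded) risk-ratio estimate from the sampled outcomes —
#'     what a summary-statistics analysis computes.}
#'   \item{case-based}{[case_based_paf()] with the true (adjusted) risk
#'     ratio.}
#'   \item{sequential}{[sequential_paf()] in the configuration order.}
#'   \item{average}{[average_paf()], the Shapley decomposition.}
#' }
#' plus the joint counterfactual PAF and the headline diagnostic: the sum
#' of single-factor crude Levin PARs against the joint PAF. With positively
#' correlated factors the crude sum overshoots the joint fraction — summed
#' single-factor PARs double-count burden and are overestimates — which is
#' precisely what the report is designed to exhibit.
#'
#' @param sample a [population_sample].
#' @param limit enumeration limit passed to [average_paf()].
#' @return an object of class `"attribution"`: list with `estimates` (per
#'   factor), `joint`, `sum_crude`, `sum_average`, `scenario`.
#' @examples
#' rep <- attribution(simulate(demo_scenario(n = 20000), seed = 5))
#' rep
#' coef(rep)
#' @export
attribution <- function(sample, limit = 6L) {
  stopifnot(inherits(sample, "population_sample"))
  sc <- sample$scenario
  K <- length(sc$factors)
  if (K == 0) {
    est <- data.frame(factor = character(0), prevalence = numeric(0),
                      rr_crude = numeric(0), levin_crude = numeric(0),
                      case_based = numeric(0), sequential = numeric(0),
                      average = numeric(0))
    return(structure(list(estimates = est, joint = 0, sum_crude = 0,
                          sum_average = 0, scenario = sc),
                     class = "attribution"))
  }
  pe_hat <- colMeans(sample$exposures)
  rr_crude <- vapply(sc$factors, function(f) estimate_crude_rr(sample, f)$rr,
                     numeric(1))
  seq_ref <- sequential_paf(sample)
  est <- data.frame(
    factor = sc$factors,
    prevalence = unname(pe_hat),
    rr_crude = unname(rr_crude),
    levin_crude = unname(levin_par(pe_hat, rr_crude)),
    case_based = vapply(sc$factors, function(f) case_based_paf(sample, f),
                        numeric(1)),
    sequential = unname(seq_ref[sc$factors]),
    average = unname(average_paf(sample, limit = limit)[sc$factors]),
    stringsAsFactors = FALSE
  )
  structure(list(estimates = est,
                 joint = true_paf(sample),
                 sum_crude = sum(est$levin_crude),
                 sum_average = sum(est$average),
                 scenario = sc),
            class = "attribution")
}

#' @export
print.attribution <- function(x, digits = 3, ...) {
  cat("Attributable-fraction report",
      if (!is.null(x$scenario$label)) sprintf("— scenario '%s'", x$scenario$label), "\n")
  est <- x$estimates
  if (nrow(est)) {
    shown <- data.frame(factor = est$factor,
                        prevalence = round(est$prevalence, digits),
                        rr_crude = round(est$rr_crude, digits),
                        levin_crude = round(est$levin_crude, digits),
                        case_based = round(est$case_based, digits),
                        sequential = round(est$sequential, digits),
                        average = round(est$average, digits))
    print(shown, row.names = FALSE)
  }
  cat(sprintf("  joint PAF (all factors removed): %.4f\n", x$joint))
  cat(sprintf("  sum of crude Levin PARs:         %.4f\n", x$sum_crude))
  cat(sprintf("  sum of average PAFs:             %.4f (= joint by construction)\n",
              x$sum_average))
  if (nrow(est) && x$sum_crude > x$joint) {
    cat(sprintf("  crude single-factor PARs overstate the joint burden by %.1f%%\n",
                100 * (x$sum_crude - x$joint) / x$joint))
  }
  invisible(x)
}

#' @export
summary.attribution <- function(object, ...) {
  print(object, ...)
  cat(sprintf("  n = %d, baseline risk %.3f\n",
              object$scenario$n, object$scenario$baseline_risk))
  invisible(object)
}

#' @export
coef.attribution <- function(object, ...) {
  stats::setNames(object$estimates$average, object$estimates$factor)
}

#' @export
plot.attribution <- function(x, ...) {
  est <- x$estimates
  if (!nrow(est)) return(invisible(x))
  m <- rbind(crude = est$levin_crude, average = est$average)
  colnames(m) <- est$factor
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "attributable fraction",
                    main = "Crude Levin vs average (Shapley) PAF", ...)
  graphics::abline(h = x$joint, lty = 2)
  invisible(x)
}

#' Export an attribution report as delimited text
#'
#' Writes the per-factor estimate table as CSV and appends the joint/sum
#' diagnostics as comment lines.
#'
#' @param x an [attribution] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(x, path) {
  stopifnot(inherits(x, "attribution"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(x$estimates, con, row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("# joint_paf,%.10f", x$joint),
               sprintf("# sum_crude_levin,%.10f", x$sum_crude),
               sprintf("# sum_average_paf,%.10f", x$sum_average)), con)
  invisible(path)
}
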