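#' Generate an individual-level population from a scenario
#'
#' Draws `n` individuals with correlated binary exposures by Gaussian-copula
#' dichotomisation (latent `Z ~ N(0, latent_correlation)`, exposure `j`
#' present iff `Z_j < qnorm(prevalence_j)`), assigns each individual the
#' model risk `baseline_risk * prod_j rr_true[j]^x_j`, and samples the
#' binary outcome as Bernoulli(model risk).
#'
#' All randomness derives from `seed` through fixed substreams (one for the
#' latent exposures, one for the outcomes), so the sample is bit-for-bit
#' reproducible and downstream per-factor analyses cannot perturb it.
#'
#' @param scenario a [scenario].
#' @param seed integer seed.
#' @return an object of class `"population_sample"`: list with `exposures`
#'   (n x K 0/1 matrix, factor-named columns), `outcome` (0/1 vector),
#'   `model_risk` (per-individual outcome probability), `scenario`, `seed`.
#' @seealso [simulate.scenario()] (the S3 route to the same generator),
#'   [true_paf()], [attribution()]
#' @examples
#' s <- generate_population(demo_scenario(n = 5000), seed = 1)
#' colMeans(s$exposures)
#' @export
generate_population <- function(scenario, seed) {
  stopifnot(inherits(scenario, "scenario"))
  n <- scenario$n
  K <- length(scenario$factors)
  if (K > 0) {
    set.seed(substream_seed(seed, 1L))
    Z <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = scenario$latent_correlation)
    if (K == 1L) Z <- matrix(Z, ncol = 1L)
    thresholds <- stats::qnorm(scenario$prevalence)
    X <- 1L * (Z < matrix(thresholds, n, K, byrow = TRUE))
  } else {
    X <- matrix(integer(0), nrow = n, ncol = 0)
  }
  colnames(X) <- scenario$factors
  risk <- as.vector(scenario$baseline_risk *
                      exp(X %*% log(scenario$rr_true)))
  if (any(risk > 1)) {
    stop("individual model risk exceeds 1; invalid scenario", call. = FALSE)
  }
  set.seed(substream_seed(seed, 2L))
  y <- 1L * (stats::runif(n) < risk)
  structure(list(exposures = X, outcome = y, model_risk = risk,
                 scenario = scenario, seed = as.integer(seed)),
            class = "population_sample")
}

#' Simulate populations from a scenario
#'
#' S3 [stats::simulate()] method: draws `nsim` independent
#' [population_sample][generate_population]s, each under a deterministic
#' substream of `seed`.
#'
#' @param object a [scenario].
#' @param nsim number of samples (default 1).
#' @param seed integer seed (required for reproducibility; defaults to 1).
#' @param ... unused.
#' @return a single `population_sample` if `nsim = 1`, else a list of them.
#' @examples
#' samples <- simulate(demo_scenario(n = 2000), nsim = 2, seed = 9)
#' @export
simulate.scenario <- function(object, nsim = 1, seed = 1L, ...) {
  out <- lapply(seq_len(nsim), function(i)
    generate_population(object, seed = substream_seed(seed, 100L + i)))
  if (nsim == 1) out[[1]] else out
}

#' @export
print.population_sample <- function(x, ...) {
  K <- ncol(x$exposures)
  cat(sprintf("Population sample: n = %d, %d risk factor%s, seed %d\n",
              length(x$outcome), K, if (K == 1) "" else "s", x$seed))
  if (K > 0) {
    cat("  empirical prevalence:",
        paste(sprintf("%s %.3f", colnames(x$exposures), colMeans(x$exposures)),
              collapse = ", "), "\n")
  }
  cat(sprintf("  outcome rate %.4f (mean model risk %.4f)\n",
              mean(x$outcome), mean(x$model_risk)))
  invisible(x)
}

# Mean population risk after setting the exposures in `remove` to zero.
counterfactual_mean_risk <- function(sample, remove) {
  sc <- sample$scenario
  keep <- setdiff(sc$factors, remove)
  if (length(keep) == 0) return(sc$baseline_risk)
  lr <- log(sc$rr_true[keep])
  mean(sc$baseline_risk * exp(sample$exposures[, keep, drop = FALSE] %*% lr))
}

#' Counterfactual (true) population attributable fraction
#'
#' The attributable fraction actually realised in a generated population:
#' the proportional drop in mean model risk when the listed exposures are
#' set to zero,
#' \deqn{PAF = 1 - \bar r(\mathrm{removed}) / \bar r,}
#' computed on the per-individual model risks rather than the sampled
#' outcomes, so the only noise is the exposure draw itself. With all
#' factors removed this is the joint PAF. For a single factor it equals
#' `levin_par()` at the sample's empirical prevalence exactly.
#'
#' @param sample a [population_sample].
#' @param factors_removed character vector of factors to eliminate
#'   (default: all configured factors, giving the joint PAF).
#' @return attributable fraction on the proportion scale.
#' @seealso [expected_paf()] for the closed-form expectation under
#'   independence, [sequential_paf()], [average_paf()]
#' @examples
#' s <- simulate(demo_scenario(n = 20000), seed = 3)
#' true_paf(s, "smoking")
#' true_paf(s)  # joint: all five factors
#' @export
true_paf <- function(sample, factors_removed = sample$scenario$factors) {
  stopifnot(inherits(sample, "population_sample"))
  bad <- setdiff(factors_removed, sample$scenario$factors)
  if (length(bad)) {
    stop("unknown factors: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(factors_removed) == 0) return(0)
  1 - counterfactual_mean_risk(sample, factors_removed) / mean(sample$model_risk)
}

#' Expected attributable fraction under independent factors
#'
#' Closed-form population expectation of [true_paf()] when the latent
#' correlation is the identity (or there is a single factor): the mean risk
#' factorises as `baseline * prod_j (1 - p_j + p_j rr_j)`, so
#' \deqn{PAF = 1 - \prod_{j \in removed} \frac{1}{1 - p_j + p_j RR_j}.}
#' For one factor this reduces exactly to Levin's formula, which is why the
#' crude single-factor PAR is unbiased under independence. Errors for
#' correlated scenarios, where the expectation has no product form.
#'
#' @param scenario a [scenario] with identity latent correlation.
#' @param factors_removed factors to eliminate (default all).
#' @return attributable fraction on the proportion scale.
#' @examples
#' sc <- scenario(n = 10, factors = "smoking", prevalence = 0.3, rr_true = 2,
#'                baseline_risk = 0.05)
#' expected_paf(sc)            # equals levin_par(0.3, 2)
#' @export
expected_paf <- function(scenario, factors_removed = scenario$factors) {
  stopifnot(inherits(scenario, "scenario"))
  K <- length(scenario$factors)
  if (K > 1) {
    off <- scenario$latent_correlation[upper.tri(scenario$latent_correlation)]
    if (any(off != 0)) {
      stop("expected_paf() has a closed form only for independent factors; use true_paf() on a generated sample",
           call. = FALSE)
    }
  }
  bad <- setdiff(factors_removed, scenario$factors)
  if (length(bad)) stop("unknown factors: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(factors_removed) == 0) return(0)
  p <- scenario$prevalence[factors_removed]
  r <- scenario$rr_true[factors_removed]
  1 - 1 / prod(1 - p + p * r)
}
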