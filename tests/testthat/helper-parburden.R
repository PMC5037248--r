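# Shared helpers: permutation enumeration (oracle for the Shapley average),
# a brute-force ordering average, and a hand-built sample from a 2x2 table.

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Mean sequential PAF per factor over all K! orderings, enumerated directly.
brute_average_paf <- function(sample) {
  factors <- sample$scenario$factors
  acc <- stats::setNames(numeric(length(factors)), factors)
  all_orders <- perms(factors)
  for (ord in all_orders) {
    saf <- sequential_paf(sample, ord)
    acc[names(saf)] <- acc[names(saf)] + saf
  }
  acc / length(all_orders)
}

# population_sample with exposure/outcome counts fixed by a 2x2 table
# (a exposed cases, b exposed non-cases, c unexposed cases, d unexposed
# non-cases); scenario fields are placeholders.
sample_from_2x2 <- function(a, b, c_, d, factor = "x") {
  x <- c(rep(1L, a + b), rep(0L, c_ + d))
  y <- c(rep(1L, a), rep(0L, b), rep(1L, c_), rep(0L, d))
  sc <- scenario(n = length(x), factors = factor, prevalence = mean(x),
                 rr_true = 2, baseline_risk = 0.05)
  structure(list(exposures = matrix(x, ncol = 1, dimnames = list(NULL, factor)),
                 outcome = y, model_risk = rep(0.05, length(x)),
                 scenario = sc, seed = 0L),
            class = "population_sample")
}
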