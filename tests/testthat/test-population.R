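# Gaussian-copula population generator, crude RR estimation, and the
# counterfactual attributable fraction.

test_that("scenario validation rejects bad correlation matrices and risk overflow", {
  expect_error(scenario(n = 10, factors = c("a", "b"), prevalence = c(0.5, 0.5),
                        rr_true = c(2, 2),
                        latent_correlation = matrix(c(1, 0.99, 0.2, 1), 2, 2),
                        baseline_risk = 0.1),
               "symmetric")
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(scenario(n = 10, factors = c("a", "b", "c"),
                        prevalence = rep(0.5, 3), rr_true = rep(2, 3),
                        latent_correlation = bad, baseline_risk = 0.05),
               "eigenvalue")
  expect_error(scenario(n = 10, factors = c("a", "b"), prevalence = c(0.5, 0.5),
                        rr_true = c(4, 4), baseline_risk = 0.1),
               "exceeds 1")
  expect_error(scenario(n = 10, factors = "a", prevalence = 1.2, rr_true = 2,
                        baseline_risk = 0.05), "proportion")
})

test_that("marginal prevalences are calibrated and independence holds at rho = 0", {
  sc <- scenario(n = 1e5, factors = c("a", "b", "c"),
                 prevalence = c(0.5, 0.5, 0.5), rr_true = c(1.5, 1.5, 1.5),
                 baseline_risk = 0.05)
  s <- generate_population(sc, seed = 202)
  tol <- 3 * sqrt(0.25 / 1e5)
  expect_true(all(abs(colMeans(s$exposures) - 0.5) < tol))
  cors <- cor(s$exposures)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 4 / sqrt(1e5)))
})

test_that("binary-scale exposure correlation is monotone in the latent rho", {
  cors <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    sc <- scenario(n = 5e4, factors = c("a", "b"), prevalence = c(0.3, 0.6),
                   rr_true = c(1.5, 1.5), latent_correlation = rho,
                   baseline_risk = 0.05)
    s <- generate_population(sc, seed = 77)
    cor(s$exposures[, 1], s$exposures[, 2])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  # binary correlation is attenuated relative to the latent one
  expect_lt(cors[4], 0.9)
})

test_that("outcome rate matches the closed-form expectation for one factor", {
  sc <- scenario(n = 4e5, factors = "smoking", prevalence = 0.3, rr_true = 2,
                 baseline_risk = 0.05)
  s <- generate_population(sc, seed = 12)
  target <- 0.05 * (0.7 + 0.3 * 2)   # 0.065
  expect_equal(mean(s$outcome), target, tolerance = 4 * sqrt(target / 4e5) / target)
  expect_equal(mean(s$model_risk), target, tolerance = 0.01)
  # model risk invariant: baseline * prod rr^x per individual
  expect_equal(s$model_risk,
               0.05 * 2^s$exposures[, 1], tolerance = 1e-12)
})

test_that("generation is reproducible under seed and order-independent substreams", {
  sc <- demo_scenario(n = 2000)
  a <- generate_population(sc, seed = 5)
  b <- generate_population(sc, seed = 5)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$outcome, b$outcome)
  expect_false(identical(a$outcome, generate_population(sc, seed = 6)$outcome))
})

test_that("crude risk ratio matches hand arithmetic on a fixed 2x2 table", {
  s <- sample_from_2x2(a = 20, b = 80, c_ = 10, d = 90)
  est <- estimate_crude_rr(s, "x")
  expect_equal(est$rr, 2)
  expect_equal(est$log_se, sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100))
  expect_equal(est$ci_lower, 2 * exp(-1.96 * est$log_se))
  expect_error(estimate_crude_rr(sample_from_2x2(0, 100, 10, 90), "x"),
               "degenerate")
})

test_that("a coin-flip exposure independent of outcome gives RR near 1", {
  sc <- scenario(n = 2e5, factors = "noise", prevalence = 0.5, rr_true = 1,
                 baseline_risk = 0.1)
  est <- estimate_crude_rr(generate_population(sc, seed = 40), "noise")
  expect_lt(abs(log(est$rr)), 3 * est$log_se)
})

test_that("crude RR recovery: true RR covered by its 95% CI in most replicates", {
  sc <- scenario(n = 2e5, factors = "f", prevalence = 0.3, rr_true = 1.5,
                 baseline_risk = 0.05)
  covered <- vapply(1:100, function(i) {
    est <- estimate_crude_rr(generate_population(sc, seed = 1000 + i), "f")
    est$ci_lower <= 1.5 && 1.5 <= est$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("true_paf: boundary identities and single-factor Levin exactness", {
  sc <- scenario(n = 5e4, factors = c("a", "b"), prevalence = c(0.3, 0.2),
                 rr_true = c(2, 1.5), latent_correlation = 0.4,
                 baseline_risk = 0.05)
  s <- generate_population(sc, seed = 9)
  expect_identical(true_paf(s, character(0)), 0)
  expect_equal(true_paf(s),
               1 - sc$baseline_risk / mean(s$model_risk), tolerance = 1e-12)
  expect_lte(true_paf(s), 1)
  # monotone under superset removal
  expect_lte(true_paf(s, "a"), true_paf(s, c("a", "b")))
  expect_error(true_paf(s, "zzz"), "unknown")
  # single factor: exactly Levin at the empirical prevalence
  sc1 <- scenario(n = 2e4, factors = "f", prevalence = 0.3, rr_true = 2,
                  baseline_risk = 0.05)
  s1 <- generate_population(sc1, seed = 13)
  expect_equal(true_paf(s1, "f"),
               levin_par(mean(s1$exposures[, 1]), 2), tolerance = 1e-12)
})

test_that("expected_paf equals Levin for one factor and factorises under independence", {
  sc1 <- scenario(n = 10, factors = "f", prevalence = 0.3, rr_true = 2,
                  baseline_risk = 0.05)
  expect_equal(expected_paf(sc1), levin_par(0.3, 2), tolerance = 1e-12)
  sc3 <- scenario(n = 10, factors = c("a", "b"), prevalence = c(0.2, 0.4),
                  rr_true = c(1.5, 2), baseline_risk = 0.02)
  expect_equal(expected_paf(sc3),
               1 - 1 / ((1 - 0.2 + 0.2 * 1.5) * (1 - 0.4 + 0.4 * 2)),
               tolerance = 1e-12)
  sc_corr <- scenario(n = 10, factors = c("a", "b"), prevalence = c(0.2, 0.4),
                      rr_true = c(1.5, 2), latent_correlation = 0.5,
                      baseline_risk = 0.02)
  expect_error(expected_paf(sc_corr), "independent")
})

test_that("scenario YAML round-trips through read/write", {
  sc <- demo_scenario(n = 1234)
  p <- tempfile(fileext = ".yaml")
  write_scenario(sc, p)
  back <- read_scenario(p)
  expect_equal(back$prevalence, sc$prevalence)
  expect_equal(back$rr_true, sc$rr_true)
  expect_equal(back$latent_correlation, sc$latent_correlation)
  expect_identical(back$n, sc$n)
  expect_error(read_scenario({
    q <- tempfile(); writeLines("n: 10", q); q
  }), "missing fields")
})
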