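# Case-based, sequential and average (Shapley) attributable fractions and
# the side-by-side attribution report.

corr3 <- function(n = 3e4, rho = 0.5, seed = 21) {
  sc <- scenario(n = n, factors = c("a", "b", "c"),
                 prevalence = c(0.3, 0.5, 0.2), rr_true = c(2, 1.5, 3),
                 latent_correlation = rho, baseline_risk = 0.03)
  generate_population(sc, seed = seed)
}

test_that("case-based PAF: null RR gives zero; equals Levin without confounding", {
  s <- corr3()
  expect_identical(case_based_paf(s, "a", rr = 1), 0)
  # single factor, risk-weighted case prevalence: Miettinen = Levin exactly
  sc1 <- scenario(n = 2e4, factors = "f", prevalence = 0.5, rr_true = 2,
                  baseline_risk = 0.05)
  s1 <- generate_population(sc1, seed = 17)
  pe_hat <- mean(s1$exposures[, 1])
  expect_equal(case_based_paf(s1, "f"), levin_par(pe_hat, 2), tolerance = 1e-12)
  expect_error(case_based_paf(s, "zzz"), "not in the sample")
})

test_that("under positive correlation the crude Levin PAR exceeds the adjusted case-based PAF", {
  s <- simulate(demo_scenario(n = 5e4), seed = 29)
  for (f in c("diabetes", "excess_body_weight")) {
    crude <- levin_par(mean(s$exposures[, f]), estimate_crude_rr(s, f)$rr)
    adjusted <- case_based_paf(s, f)   # true RR, confounding removed
    expect_gt(crude, adjusted)
  }
})

test_that("sequential PAFs telescope to the joint PAF for every ordering", {
  s <- corr3()
  joint <- true_paf(s)
  for (ord in perms(c("a", "b", "c"))) {
    saf <- sequential_paf(s, ord)
    expect_equal(sum(saf), joint, tolerance = 1e-10)
  }
  # random correlated 4-factor scenarios too
  for (seed in 1:3) {
    set.seed(seed)
    sc <- scenario(n = 5e3, factors = letters[1:4],
                   prevalence = runif(4, 0.1, 0.6),
                   rr_true = runif(4, 1.1, 2.2),
                   latent_correlation = 0.3, baseline_risk = 0.02)
    s4 <- generate_population(sc, seed = seed)
    ord <- sample(letters[1:4])
    expect_equal(sum(sequential_paf(s4, ord)), true_paf(s4), tolerance = 1e-10)
  }
  expect_error(sequential_paf(s, c("a", "b")), "permutation")
  expect_error(sequential_paf(s, c("a", "a", "b")), "permutation")
})

test_that("one-factor population: sequential and average equal the counterfactual PAF", {
  sc1 <- scenario(n = 2e4, factors = "f", prevalence = 0.3, rr_true = 2,
                  baseline_risk = 0.05)
  s1 <- generate_population(sc1, seed = 23)
  tp <- true_paf(s1, "f")
  expect_equal(unname(sequential_paf(s1)), tp, tolerance = 1e-12)
  expect_equal(unname(average_paf(s1)), tp, tolerance = 1e-12)
})

test_that("earlier elimination attributes at least as much: first >= second position", {
  sc <- scenario(n = 5e4, factors = c("a", "b"), prevalence = c(0.4, 0.3),
                 rr_true = c(2, 1.8), baseline_risk = 0.05)
  s <- generate_population(sc, seed = 31)
  first <- sequential_paf(s, c("a", "b"))["a"]
  second <- sequential_paf(s, c("b", "a"))["a"]
  expect_gte(first, second)
})

test_that("Shapley recursion equals the brute-force ordering average for K <= 4", {
  s3 <- corr3(n = 5e3)
  expect_equal(average_paf(s3), brute_average_paf(s3), tolerance = 1e-12)
  sc4 <- scenario(n = 4e3, factors = letters[1:4],
                  prevalence = c(0.2, 0.5, 0.35, 0.1),
                  rr_true = c(1.4, 2.2, 1.8, 3),
                  latent_correlation = 0.25, baseline_risk = 0.02)
  s4 <- generate_population(sc4, seed = 3)
  expect_equal(average_paf(s4), brute_average_paf(s4), tolerance = 1e-12)
})

test_that("average PAFs are symmetric for exchangeable factors and sum to the joint", {
  sc <- scenario(n = 4e4, factors = c("a", "b", "c"),
                 prevalence = rep(0.3, 3), rr_true = rep(2, 3),
                 latent_correlation = 0.4, baseline_risk = 0.02)
  s <- generate_population(sc, seed = 47)
  ap <- average_paf(s)
  expect_equal(sum(ap), true_paf(s), tolerance = 1e-10)
  # exchangeable in distribution: equal up to exposure sampling noise
  expect_lt(max(ap) - min(ap), 0.02)
  # dominance: each average PAF lies within the factor's sequential range
  all_orders <- perms(c("a", "b", "c"))
  seqs <- sapply(all_orders, function(o) sequential_paf(s, o)[c("a", "b", "c")])
  expect_true(all(ap >= apply(seqs, 1, min) - 1e-12))
  expect_true(all(ap <= apply(seqs, 1, max) + 1e-12))
  expect_error(average_paf(s, limit = 2), "enumeration")
})

test_that("attribution report: identities, diagnostics and the empty edge case", {
  s <- simulate(demo_scenario(n = 3e4), seed = 51)
  rep <- attribution(s)
  expect_equal(rep$sum_average, rep$joint, tolerance = 1e-10)
  expect_equal(sum(rep$estimates$sequential), rep$joint, tolerance = 1e-10)
  expect_gt(rep$sum_crude, rep$joint)   # positive correlation: overestimation
  expect_equal(unname(coef(rep)), rep$estimates$average)
  # empty factor list: all-zero report
  sc0 <- scenario(n = 100, factors = character(0), prevalence = numeric(0),
                  rr_true = numeric(0), baseline_risk = 0.05)
  rep0 <- attribution(generate_population(sc0, seed = 1))
  expect_identical(nrow(rep0$estimates), 0L)
  expect_identical(rep0$joint, 0)
  expect_identical(rep0$sum_crude, 0)
})

test_that("with weak independent factors the crude sum approximates the joint PAF", {
  # first-order regime: small pe*(rr-1) makes single-factor PARs near-additive
  sc <- scenario(n = 2e5, factors = c("a", "b", "c"),
                 prevalence = rep(0.2, 3), rr_true = rep(1.1, 3),
                 baseline_risk = 0.01)
  rep <- attribution(generate_population(sc, seed = 61))
  expect_equal(rep$sum_crude, rep$joint, tolerance = 0.15)
  expect_lt(abs(rep$sum_crude - rep$joint), 0.01)
})

test_that("attribution report exports as delimited text with diagnostics", {
  rep <- attribution(simulate(demo_scenario(n = 5e3), seed = 71))
  p <- tempfile(fileext = ".csv")
  write_attribution(rep, p)
  lines <- readLines(p)
  est <- utils::read.csv(p, comment.char = "#")
  expect_identical(nrow(est), 5L)
  expect_true(any(grepl("^# joint_paf", lines)))
})
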