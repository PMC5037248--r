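---
title: "Attributable-fraction methods in parburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable-fraction methods in parburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parburden)
```

## The single-factor model

For a binary exposure with population prevalence $P_e$ and relative risk
$RR$ of disease in the exposed, Levin's population attributable risk is

$$PAR = \frac{P_e (RR - 1)}{P_e (RR - 1) + 1}.$$

It is the proportional reduction in disease burden if the exposure were
removed, under three assumptions: the $RR$ is causal and free of
confounding, the exposure is dichotomous, and the factor acts alone. The
formula is strictly increasing in both arguments (for $RR > 1$), negative
for protective exposures ($RR < 1$) — negative values are meaningful and are
never truncated — and bounded in $(-P_e/(1-P_e),\, 1)$. `levin_par()`
implements it on the proportion scale; percent rendering happens only at
output, via `par_to_percent()`, rounding half away from zero to one decimal.
The half-away-from-zero convention is an assumption: the source tables do
not state their rounding rule, and one-decimal agreement of the
reproduction is insensitive to it because no reproduced value falls at a
rounding boundary.

The algebraic inverse `invert_rr()`, $RR = 1 + PAR / (P_e(1 - PAR))$, exists
because published PAR tables often omit the source relative risks; inverting
the printed PAR point and CI bounds reconstructs the RRs they imply.

## Uncertainty: the substitution method

Prevalence in a very large survey carries negligible sampling error relative
to the cohort-derived $RR$, so the substitution method treats $P_e$ as fixed
and propagates only RR uncertainty. The sampling distribution of $RR$ is
taken as lognormal: $\log RR \sim N(\mu, \sigma^2)$ with
$\sigma = (\log U - \log L) / (2z)$ extracted from the reported
$(L, U)$ interval ($z = 1.96$ by default; the multiplier is configurable
because sources rarely state it). Lognormality is the standard reading of a
CI that is symmetric on the log scale; the choice of sampling scale is
recorded in the fitted object's metadata.

`paf()` implements both routes:

* **Monte Carlo** (default): `n_iter = 10000` draws of $\log RR$, each
  mapped through Levin's formula; the empirical 2.5th/97.5th percentiles
  (linear interpolation between order statistics, `quantile()` type 7 — the
  percentile estimator is fixed and documented because sources do not state
  theirs) are the confidence limits. Fully reproducible under `seed`.
* **Closed form** (`substitution_ci()`): monotonicity makes the exact
  interval the formula evaluated at the lognormal quantiles of $RR$. The
  Monte Carlo interval converges to it as `n_iter` grows; the test suite
  checks agreement to $10^{-3}$ (proportion scale, absolute) at $10^6$
  draws over a grid of prevalences and log-scale SEs.

Two centring options exist because printed point estimates and CI bounds are
independently rounded and hence not exactly log-symmetric: `location =
"point"` centres at $\log RR$ (default), `"geometric-mean"` at the midpoint
of the log bounds. For the packaged male-smoking CHD fixture the two differ
by less than 0.5% in RR.

## Packaged study fixtures and their provenance

The packaged tables come from a national Indonesian analysis of CHD and
stroke burden attributable to smoking, hypertension, diabetes, elevated
total cholesterol and excess body weight, with relative risks sourced from
Asia-Pacific cohort analyses. Three provenance rules govern what is data
here:

1. Only values printed *numerically* are packaged as data: the PAR table
   (80 cells, percent scale, including negative entries) and five
   prevalences (male smoking 0.649, female smoking 0.021, female elevated
   cholesterol 0.396, male diabetes 0.056, female diabetes 0.077).
   Prevalences shown only in bar charts are marked `unavailable` rather than
   read off the figure, so hypertension and excess-body-weight rows — and
   all age-group strata — are excluded from reproduction and listed as such.
2. The source RRs are not published. `implied_rr_table()` back-derives them
   from the printed PAR cells at 4-decimal precision and tags every value
   `derived`; the shipped `extdata/implied_rr.csv` regenerates
   byte-identically from the printed constants (a test asserts this).
3. `reproduce_study_table()` closes the loop: forward Levin on printed
   prevalence × derived RR, rendered at one decimal, must equal every
   printed reportable cell (point and both bounds — 20 cells). A mismatch
   would indicate an arithmetic or rounding defect in the package, not a
   data issue.

```{r fixtures}
reproduce_study_table()
```

## The synthetic population generator

`scenario()` + `simulate()` generate the individual-level data that
summary-statistics analyses lack, so that every multifactor estimator can be
validated. The generative model:

* **Exposures**: Gaussian-copula dichotomisation. A latent
  $Z \sim N(0, \Sigma)$ with correlation matrix $\Sigma$ is thresholded at
  $\Phi^{-1}(p_j)$, giving binary exposures with *exactly* controlled
  marginals and dependence inherited from $\Sigma$. The configured
  correlation is the latent one; the binary-scale correlation is attenuated
  (tests check marginal calibration and monotonicity of the binary
  correlation in the latent $\rho$).
* **Outcome**: multiplicative risk-ratio model on the probability scale,
  $r_i = r_0 \prod_j RR_j^{x_{ij}}$, then $Y_i \sim \text{Bernoulli}(r_i)$.
  A risk-ratio (log) link is used rather than odds because Levin's formula
  consumes risk ratios. Configurations whose all-exposed risk would exceed
  1 are rejected at construction instead of silently truncated.
* **Reproducibility**: one user seed feeds fixed substreams (latent draw,
  outcome draw), so per-factor analyses cannot perturb the sample and are
  order-independent.

What the generator does *not* emulate: survey weighting and multistage
sampling, continuous exposures, age structure beyond labels, and any
measured between-factor correlation for the study population — none is
published, so the shipped `demo_scenario()` uses an illustrative
exchangeable latent $\rho = 0.3$, and its hypertension (0.30) and
excess-body-weight (0.25) prevalences and their RRs (1.9, 1.3) are labelled
placeholders. Passing tests therefore demonstrate correctness of the
estimators under this generative model, not calibration to the real
population.

Default study conditions: $n = 2 \times 10^5$ individuals, baseline risk
0.05, the three printed prevalences and derived CHD RRs where they exist.
Unit tests use smaller $n$ (a few $10^4$) where only identities — which are
exact at any $n$ — are asserted; calibration checks use $n$ large enough
that a $3$–$4\sigma$ binomial band is decisive.

## Multifactor attributable fractions

With correlated factors the single-factor PAR is doubly wrong: the crude RR
is confounded by the other exposures, and summing per-factor PARs
double-counts burden jointly attributable to several factors. On a
generated sample the package computes, all on model risks (expectations), so
the algebraic identities below are exact rather than approximate:

* **Joint PAF** (`true_paf()`): $1 - \bar r(\text{all removed})/\bar r$.
  For one factor it reduces *exactly* to Levin at the sample's empirical
  prevalence; `expected_paf()` gives the closed-form population expectation
  under independence, which reduces to Levin at the configured prevalence.
* **Case-based (Miettinen) PAF** (`case_based_paf()`):
  $p_c (RR - 1)/RR$ with $p_c$ the exposure prevalence among cases. With an
  adjusted (here: true) RR it stays internally valid under confounding. The
  default $p_c$ is risk-weighted (prevalence among *expected* cases); an
  observed-outcome mode quantifies finite-sample noise.
* **Sequential PAFs** (`sequential_paf()`): burden removed by each factor
  in a stated elimination order, normalised by the original mean risk; they
  telescope to the joint PAF for every ordering.
* **Average PAF** (`average_paf()`): the mean sequential fraction over all
  $K!$ orderings — the Shapley value of the elimination game — computed
  exactly from the $2^K$ subset-risk table with weights
  $|S|!(K-|S|-1)!/K!$, never by enumerating orderings. Average fractions
  are order-free and sum exactly to the joint PAF. Exact enumeration is
  capped at $K = 6$ (64 subset evaluations); beyond that, average sampled
  orderings of `sequential_paf()` instead.

`attribution()` assembles all of them side by side with the headline
diagnostic — the sum of crude Levin PARs versus the joint PAF:

```{r attribution}
rep <- attribution(simulate(demo_scenario(n = 50000), seed = 108))
rep
```

Under positive correlation the crude sum exceeds the joint fraction by a
wide margin, which is the package's operational demonstration that summed
single-factor PARs are overestimates. Under independence the crude sum
still exceeds the joint PAF unless the factors are weak: additivity of
single-factor PARs is a first-order approximation in $P_e(RR-1)$, not a
consequence of a rare outcome. The test suite asserts near-additivity only
in the weak-factor independent regime where the approximation is valid.

## Numerical choices and edge cases

* Internal scale is always proportion; percent only at rendering.
* `rr = 1` or `pe = 0` return exactly `0`, with no tolerance fuzz.
* The Levin denominator $P_e(RR-1)+1$ can only vanish at $P_e = 1$,
  $RR \to 0$; since $RR \le 0$ is rejected, the guard is defensive.
* Non-positive-semidefinite latent correlation matrices are rejected with
  the offending eigenvalue reported.
* Typographic minus signs (U+2212) in the packaged printed table are
  normalised to ASCII on ingest.
* Degenerate 2×2 tables (no exposed or no unexposed cases) raise an error
  in `estimate_crude_rr()` rather than returning infinities.

## Known limitations

* No uncertainty on prevalence — deliberate, per the substitution method's
  assumption — and no confidence intervals on sequential/average PAFs.
* The regression-model-standardised PAF family is represented only by the
  case-based estimator with an externally supplied adjusted RR.
* `expected_paf()` has a closed form only for independent factors; under
  correlation use `true_paf()` on a large generated sample.
* The demo scenario's correlation and placeholder parameters are
  illustrative; conclusions about the magnitude of overestimation in the
  real population would require measured joint exposure data.
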