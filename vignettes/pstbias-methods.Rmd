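---
title: "Methods: paired screening trial bias and its correction"
author: "pstbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired screening trial bias and its correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pstbias)
```

## The problem

In a paired screening trial every participant receives both of two
continuous screening tests. A definitive reference standard (biopsy with
pathological confirmation) is applied only when at least one score is at or
above its test's threshold of suspicion, or when signs and symptoms appear
during follow-up. Participants with unremarkable scores and no symptoms are
recorded as non-cases. Under the standard assumptions used here — the
reference standard is perfectly sensitive and specific, and symptoms occur
only in true cases — every observed case is a true case, but a true case
with two negative screens and no symptoms is *misclassified* as a non-case.

The standard ("observed") analysis uses all participants under their
observed status. Removing the lowest-scoring cases from the case sample
shifts the case score distribution upward and shrinks its variance, so both
tests' full binormal AUCs are overestimated — by different amounts when the
two thresholds refer different fractions of cases. The difference in AUCs,
the quantity the trial is run to estimate, can then be biased in either
direction, and in extreme designs reverses sign: the hypothesis test
rejects in favour of the truly inferior test.

## Model and notation

Conditional on disease class `k` (1 = case, 0 = non-case), the paired
scores are bivariate Gaussian with means `mu_jk`, variances `sigma_jk^2`
(test `j` in {1, 2}) and correlation `rho_k`. The number of cases is
`M ~ Binomial(n, pi)` with prevalence `pi`; the interval-case rate
`psi = P(symptoms | case)` and `P(symptoms | non-case) = 0`. A score at or
exactly equal to its threshold `a_j` counts as suspicious (the `>=`
convention, applied identically in simulation, partition and percent
ascertainment). The full AUC of test `j` is
`Phi((mu_j1 - mu_j0) / sqrt(sigma_j1^2 + sigma_j0^2))`.

### Default design conventions

The simulator fixes non-cases at the standard bivariate Gaussian (means 0,
variances 1) and gives cases unit variances with means chosen by inverting
the AUC formula (`calibrate_case_mean()`), the minimal convention
consistent with any stated pair of true AUCs. Thresholds are placed at true
case-score quantiles: `calibrate_threshold(t, mu, v)` returns the value
exceeded by a fraction `t` of cases. The realized *percent ascertainment*
reported from data (`percent_ascertainment()`) uses observed cases in the
denominator, so it equals the calibration target only when essentially all
cases are observed (for example when `psi = 1`); at design time the
observed-denominator definition is circular, which is why calibration
targets the true quantile.

In a real trial the thresholds are fixed properties of the design, chosen
when the study is planned. The `calibration_auc1` / `calibration_auc2`
arguments of `trial_config()` therefore allow null ("state of nature")
simulations that retain thresholds calibrated under the planned
alternative, as in the oral cancer demonstration configuration.

## The correction algorithm

Only the case parameters are corrected; at screening prevalences the error
in the non-case (specificity) parameters from a handful of misclassified
cases among tens of thousands of non-cases is negligible, and it is left
uncorrected deliberately.

**Step 1 — partition.** The thresholds cut the plane into quadrants Q1
(both scores at/above), Q2 (test 1 only), Q3 (test 2 only) and Q4 (both
below). Observed cases in Q1–Q3 form set A (all cases there are verified);
observed cases in Q4 form set B, the interval cases (only the symptomatic
fraction `psi` of Q4 cases is verified, but those that are verified are an
unbiased sample of Q4 because symptoms are independent of scores given case
status).

**Step 2 — truncated maximum likelihood.** Within each quadrant holding at
least two observed cases, the case distribution is a bivariate Gaussian
singly truncated to a convex quadrant, and all five parameters are
estimated by maximising the truncated log-likelihood
`sum log phi2(x; theta) - n log P(quadrant; theta)`. The classical
iterative moment scheme for this problem targets the same maximum
likelihood estimand; this package maximises the likelihood directly
(numerically), which is equivalent at the optimum and simpler to make
robust. Among the per-quadrant candidates, the one maximising the
*untruncated* bivariate Gaussian log-likelihood over **all** observed cases
(sets A and B pooled — the evaluation sample is a free choice here, and
pooling uses all available case information) is selected, with
ties broken in quadrant order Q1 < Q2 < Q3 < Q4.

**Step 3 — weighting.** The selected estimates give the sampling fraction
`lambda = 1 - Phi2((a1 - mu1)/s1, (a2 - mu2)/s2, rho)`, the model
probability that a case lands in set A. The corrected parameters then blend
the within-set sample moments:

* means: `mu_j = lambda * mean_A + (1 - lambda) * mean_B`;
* second moments: `sigma_j^2 = G_j + H_j - mu_j^2` with
  `G_j = lambda (mean_A^2 + S_A^2)`, `H_j = (1 - lambda)(mean_B^2 + S_B^2)`;
* cross moment: `rho = (P + Q - mu_1 mu_2) / (sigma_1 sigma_2)` with
  `P = lambda (mean_{1A} mean_{2A} + S_{1A} S_{2A} r_A)` and the analogous
  `Q` for set B.

This is the conditional-moment (law of total covariance) decomposition over
the A/B partition. Within-set variances and correlations use count (ML)
denominators so that the decomposition is exact: with `lambda` set to the
realized fraction `|A|/(|A|+|B|)` the weighted estimates reproduce the
pooled full-sample ML moments to machine precision (a property the test
suite checks by brute force). If either set holds at most one observation
the weighting is skipped and the Step 2 estimates serve as the corrected
estimates. A weighted variance that is not positive, or a weighted
correlation outside [-1, 1], is a *correction failure*: the replicate is
flagged and reported, never imputed.

## The AUC-difference test

Each analysis mode ends in a two-sided z test of equal full binormal AUCs.
Two variance estimators for the paired difference are implemented:

* `var_method = "delta"` — the exact delta-method variance. With Gaussian
  sample moments, `Var(mean) = sigma^2/n`, `Var(s^2) = 2 sigma^4/n`,
  `Cov(mean_1, mean_2) = rho sigma_1 sigma_2 / n` and
  `Cov(s_1^2, s_2^2) = 2 rho^2 sigma_1^2 sigma_2^2 / n` within each class,
  and the partials of `Phi(d)` with respect to the four binormal moments
  give the variances of each AUC and their covariance (case and non-case
  samples are independent; the between-test covariance is driven by
  `rho_1` and `rho_0`). This estimator tracks the Monte Carlo variance of
  the AUC-difference estimator (the suite requires agreement within 15%)
  and yields a test with close-to-nominal size on true-status data.
* `var_method = "obuchowski"` (default) — the Obuchowski–McClish variance
  function of the full binormal AUC,
  `VF(A) = 0.0099 e^{-a^2/2} ((5a^2 + 8) + (a^2 + 8)/R)` with
  `a = sqrt(2) qnorm(A)` and `R` the non-case/case ratio, variance
  `VF/n_cases` per test, combined with the between-test correlation taken
  from the delta-method covariance. Derived for rating-scale data, it
  exceeds the continuous-score variance away from AUC 0.5 and makes the
  test conservative (empirical size of the true analysis well below
  nominal), which is the calibration screening trial practice in this
  literature exhibits and the one the decision-error tables in the package
  reproduce. It is the default for all three analysis modes.

**Effective case counts.** The true analysis uses the realized case count,
the observed analysis the observed case count. For the corrected analysis
the corrected parameters describe the *full* case population — the
weighting explicitly reconstructs the unobserved portion — so the variance
is evaluated at the estimated total case count `|A| / lambda`, clamped to
`[n_observed_cases, n]`. Using only the observed count would treat the
corrected estimates as if they described the truncated sample and makes the
corrected test visibly over-conservative relative to the decision-error
rates the correction is known to achieve; the estimated total uses only
quantities available to a real investigator. Non-positive or non-finite
variances flag the replicate invalid rather than dropping it silently.

## The Monte Carlo harness

`run_cell()` simulates `n_reps` trials, runs all three analyses on each,
and reports per mode: the rejection rate (Type I error under a null cell),
the correct and wrong rejection fractions under an alternative (rejecting
*and* naming the truly superior / inferior test as winner — the winner is
the test with the larger estimated AUC), the mean estimated AUC difference,
the correction failure rate, and the binomial Monte Carlo standard error
`sqrt(p(1-p)/n_valid)`. Failed corrections are excluded from the
corrected-mode denominator and counted in the failure rate. Under a null
cell the correct/wrong split is undefined and reported as `NA`. Replicate
seeds are drawn once from the cell seed, so replicates are reproducible and
cells order-independent; `sweep_cells()` runs grids and records per-cell
errors without aborting the sweep.

### What the generator does and does not emulate

The generator reproduces the study design features that drive paired
screening trial bias: binomial case counts, correlated Gaussian score
pairs, threshold-triggered verification, symptom-triggered verification of
interval cases, and the two non-Gaussian departures described below. It
does not model covariate-dependent risk, imperfect reference standards
(sensitivity below 100%), reader or centre effects, or unpaired designs.
Passing tests therefore certify the correction under the stated score
model, not under arbitrary real-world screening data; with real data the
Gaussian-given-class assumption should be checked first.

Two non-Gaussian variants probe robustness. *Multinomial*: scores are
snapped to centres of half-open bins `[m w, (m+1) w)` aligned at zero (the
alignment is a package convention; nothing in the method depends on it).
*Zero-inflated*: per participant, a correlated Bernoulli pair with class
specific marginals `(p1, p2)` and joint rate `q` — drawn from the four-cell
joint distribution `{q, p1 - q, p2 - q, 1 - p1 - p2 + q}` — replaces the
selected scores with exactly 0; `q` defaults to the midpoint of its Fréchet
interval (`median_allowed_agreement()`). Observed status is re-derived from
the transformed scores in both variants, since referral depends on the
recorded score.

## Numerical choices

* The bivariate normal CDF is Genz's double-precision quadrature algorithm
  (compiled; three Gauss–Legendre rules by correlation band plus an
  expansion near `|rho| = 1`), accurate to about 5e-16 and checked in the
  suite against both the arcsine closed form at the origin and an
  independent implementation. The truncated-likelihood objective is also
  compiled, since the optimiser evaluates it hundreds of times per
  quadrant.
* The truncated-Gaussian optimisation is parameterised as
  `(mu1, mu2, log s1, log s2, atanh rho)` so iterates stay feasible; it is
  initialised at the quadrant sample statistics (a deliberately simple
  starting point — no truncation adjustment), run with Nelder–Mead and
  polished with BFGS (tolerance 1e-6, iteration cap 500 per stage). A
  quadrant probability underflowing to zero makes the objective return a
  large penalty, steering the optimiser back to feasible regions; an
  optimiser that never reaches a feasible point reports non-convergence and
  the quadrant is dropped from the candidate set.
* Degenerate inputs: infinite thresholds are legal throughout (quadrant
  membership and probabilities take their limiting values), which makes the
  fully verified design (`a = -Inf`) an exact special case — all three
  analyses coincide there up to the ML-vs-unbiased variance denominator in
  the corrected fit. Correlations of exactly +/-1 in `bvn_cdf` fall back to
  the analytic boundary forms.

## Problem sizes and limitations

The test suite and the reproduction script use 500 replicates per
simulation cell of n = 50,000 trials (the study-scale design), which puts
Monte Carlo standard errors on reported proportions around 0.01–0.02;
property checks use up to 20,000 truncated draws and 10,000 resampling
replicates. These sizes are the package's chosen compromise between
resolution and desk-scale runtimes.

Known limitations, in line with the method's own assumptions:

* the correction needs information in both sets — designs with very few
  observed cases (a few hundred) or almost no interval cases give noisy
  corrected estimates, and the truncated-MLE variances are weakly
  identified from a single lower quadrant even at large samples (maximum
  parameter errors around 0.05 at 20,000 truncated points);
* corrected Type I error control is *improved*, not guaranteed: under
  strongly differential designs it remains above nominal, and under equal
  ascertainment the observed analysis can be the better-calibrated one —
  the harness exists precisely to check a candidate design before choosing
  an analysis;
* zero-inflation beyond about 1% of scores makes the quadrant MLE fail
  often (zeros pile onto quadrant boundaries), and coarse binning (above
  about a quarter of a standard deviation) degrades the Gaussian
  approximation; the harness reports both effects via failure rates and
  error rates rather than trying to repair them.
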