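---
title: "Antedependent Poisson models for longitudinal counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antedependent Poisson models for longitudinal counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcount)
```

## The model and its assumptions

`adcount` fits equally spaced longitudinal counts Y_i1, …, Y_in on m
independent subjects under three assumptions:

1. **First-order antedependence** (the Markov property): given its
   immediate predecessor, each count is independent of all earlier ones,
   so the joint pmf factorizes into P(Y_i1) ∏_j P(Y_ij | Y_ij−1).
2. **Constant adjacent correlation** α between consecutive counts.
3. **Linear conditional expectations**: E(Y_ij | Y_ij−1) is linear in
   Y_ij−1.

Together these force an AR(1) correlation structure,
corr(Y_ij, Y_ij+t) = α^t, and pin the conditional mean at

λ*_ij = λ_ij + α (σ_ij/σ_ij−1)(Y_ij−1 − λ_ij−1),  λ_ij = exp(x_ij′β).

Taking Y_i1 ~ Poisson(λ_i1) and Y_ij | Y_ij−1 ~ Poisson(λ*_ij) gives the
full likelihood. A consequence worth emphasising: the marginal variance
at visits j ≥ 2 is λ_ij / (1 − α²), so the serial correlation *induces*
overdispersion — the model cannot represent overdispersion without
correlation, nor strong correlation without overdispersion, and the first
visit is exactly Poisson. Data that are overdispersed at baseline, or
whose correlations do not decay geometrically (e.g. exchangeable), are
outside its scope.

### Validity constraints and the feasible correlation bound

The conditional rate must be positive for every attainable history. The
binding constraints are |α| < 1 and, per adjacent pair,
λ_ij − α (σ_ij/σ_ij−1) λ_ij−1 > 0 (the previous-count-zero worst case;
for α ≥ 0 it covers all larger counts). The sd ratio needs a case split
that recurs throughout the package:

* j = 2: σ_i2/σ_i1 = sqrt(λ_i2 / ((1 − α²) λ_i1)) — the previous visit
  is the Poisson first visit;
* j ≥ 3: σ_ij/σ_ij−1 = sqrt(λ_ij / λ_ij−1) — the 1/(1 − α²) factors
  cancel.

We implement the split explicitly rather than through a generic variance
array because the α-derivative differs between the two cases (the j = 2
ratio depends on α). `alpha_bound()` finds the supremum of feasible
α ≥ 0 by bisection on (0, 1) to 1e-10: the minimal slack is continuous
and strictly decreasing in α there, so bisection is exact for practical
purposes. With equal means at all visits the j = 2 pair requires
α/sqrt(1 − α²) < 1, i.e. α < 1/√2 ≈ 0.7071 — the bound for the default
simulation design. Datasets in which no subject has two visits have no
pairs; the bound is reported as 1.

Negative α is accepted by the likelihood code whenever the constraints
*as stated* hold (they are the y = 0 case); whether validity for α < 0
requires a stronger condition over all attainable previous counts is an
open modelling question we deliberately do not resolve. The simulator,
by contrast, refuses α < 0 outright, because with an unbounded previous
count the conditional rate can go negative.

## Estimation

### Score and information

The score is derived analytically by the chain rule through λ*_ij
(including the α-dependence of the j = 2 sd ratio) and is verified
against central finite differences of the log-likelihood in a
property-style test (relative error < 1e-6 on randomized feasible
instances). ln(y!) uses `lgamma` for stability at large counts.
The observed information is computed by central finite differences *of
the analytic score* (step 1e-5 scaled to parameter magnitude,
symmetrized, steps shrunk if they would cross the feasible boundary):
the gradient is exact, so only one level of differencing error enters,
and a test checks agreement with double differencing of the
log-likelihood itself. Standard errors are the square roots of the
diagonal of the inverse observed information; Wald statistics
(est/SE)² are referred to chi-square(1); confidence intervals are
est ± 1.96 SE.

### Constrained maximization

`fit_ml()` maximizes the log-likelihood with a logarithmic-barrier outer
loop: objective ℓ(θ) + μ [Σ log(slack) + log(1 − α²)], μ_t = μ_0 · 0.1^t
with μ_0 = 1e-4 · |ℓ(start)|, at most 8 outer iterations, BFGS inner
iterations with the analytic barrier gradient. This mirrors the adaptive
barrier behaviour of the standard constrained optimizer without
reimplementing it verbatim. Convergence is declared when successive
outer log-likelihoods differ by < 1e-8 — tighter than any reporting
precision; the max-norm of the score at the solution is returned as
`grad_norm`. Interior solutions are unperturbed by the barrier beyond
tolerance (tested against an unconstrained BFGS run). When the
constrained optimum lies on the feasibility boundary (possible when the
true α is near the design bound), the outer loop keeps creeping toward
the boundary and the fit is flagged not converged; the simulation
harness drops such replicates per method and reports the count. Starting
values come from the GEE comparator, with the α start halved toward 0
until feasible (and kept 2% inside the bound so the barrier has room),
falling back to plain Poisson regression (α = 0).

Degenerate inputs: subjects with a single visit contribute only the
marginal Poisson term and are accepted; if *no* subject has repeated
visits, α is inestimable and `fit_ml()` fixes α = 0, returns the Poisson
MLE, and reports an undefined SE for α rather than failing.

### Model comparison

`information_criteria()` uses aic = −2ℓ + 2k and bic = −2ℓ + k ln(n) with
n = the total observation count Σ n_i, because the likelihood is a
product over observations. This is a documented package choice, not a
claim about any published convention: published BIC values for this
model family are internally inconsistent (back-solving different tables
yields n = subjects in one place and n = observations in another), so
our epilepsy regression test pins AIC (convention-free) and not BIC.
`likelihood_ratio_test()` clips the statistic at 0 and warns when the
"full" fit has the lower likelihood.

## The GEE comparator

The comparator the package is benchmarked against is GEE for Poisson
marginal means with an AR(1) *working* correlation and naive
(model-based) covariance — correct mean and correlation model, but no
accounting for overdispersion beyond a scalar scale. Our implementation
reproduces the conventions of the widely used `geeglm`/`geese` routines,
determined empirically against them on the epilepsy seizure data and
frozen into a regression test:

* scale: φ̂ = Σ z_ij² / N from Pearson residuals z = (y − λ̂)/sqrt(λ̂);
* α̂ solves the all-pairs moment estimating equation
  Σ_pairs (z_j z_k / φ̂ − α^d) d α^(d−1) = 0, d the lag;
* naive covariances: Cov(β̂) = φ̂ (Σ D′V⁻¹D)⁻¹ and
  Var(α̂) = [Σ_pairs (d α̂^(d−1))²]⁻¹.

A simpler lag-1 moment estimator with φ fixed at 1 was considered and
rejected: under the model's overdispersion its expectation at α = 0.6 is
≈ 0.87, which is not the behaviour of the published comparator. The
sandwich covariance is intentionally out of scope (the benchmarked
coverage experiments use naive variances); consequently our GEE
regression tests pin estimates, scale and naive variances, not the
sandwich SEs that appear in published per-dataset tables.
`dispersion_estimate()` implements the separate per-subject diagnostic
φ̂ = (1/m) Σ_i Z_i′Z_i / n_i used to detect overdispersion after a
working-independence fit; note it is *not* the same statistic as the GEE
scale above.

## The simulator and what a green test establishes

`sim_covariates()`/`sim_counts()` generate data from an
epilepsy-trial-calibrated design: two exactly equal arms of m/2
(treatment assignment deterministic by subject index), a Poisson(31.22)
baseline count drawn once per subject and held constant across visits, a
truncated-normal age (mean 28.3, sd 6.261, minimum 18, rejection-sampled
and rounded to whole years), 4 visits, and
β = (0.4467, −0.1659, 0.0232, 0.0258). These defaults are the stated
experimental conditions of the benchmark study, not tuning knobs.
Outcomes are sampled sequentially from the model's own conditional
distributions — Y_i1 ~ Poisson(λ_i1), then Y_ij | Y_ij−1 ~
Poisson(λ*_ij) — which *is* the likelihood's data-generating process, so
moment checks (mean λ_ij at every visit; variance λ_ij at visit 1 and
λ_ij/(1 − α²) later; lag-t correlation α^t) within 4 Monte-Carlo
standard errors at m = 1e5 are the acceptance evidence that simulator
and likelihood describe the same process.

What the simulator does *not* emulate: dropout or unequal series
lengths, time-varying covariates, baseline overdispersion, non-AR(1)
correlation, or model misspecification of any kind. A green
parameter-recovery or coverage test therefore establishes internal
consistency (the estimator recovers the truth of its own model), not
robustness.

`run_study()` replicates the design R times, fits both estimators, and
aggregates MSE = (1/R) Σ (θ − θ̂)², percent bias = 100 · mean((θ − θ̂)/θ)
(positive = underestimation of a positive truth), and 95% coverage of
est ± 1.96 SE (ML: observed-information SEs; GEE: naive). Replicates are
excluded per method only if that method failed or did not converge, and
exclusion counts are reported. Per-replicate seeds are pre-drawn from
the master seed so aggregates are independent of execution order and
bit-reproducible.

## Numerical choices, in one place

* bisection tolerance for the feasible bound: 1e-10;
* barrier schedule μ_0 = 1e-4 |ℓ(start)|, ratio 0.1, ≤ 8 outer rounds;
* outer convergence |Δℓ| < 1e-8; inner BFGS reltol 1e-12, ≤ 200 steps;
* observed-information step 1e-5 · max(1, |θ_k|), shrunk ×¼ near the
  boundary;
* GEE α̂ solved on (−0.99, 0.99) (clipped for stability), alternation
  tolerance 1e-8, ≤ 100 rounds;
* infeasible points probed by the line search return +∞ (BFGS shrinks
  the step), including overflow-large β proposals;
* ties/degeneracies: no adjacent pairs ⇒ α fixed at 0 with SE NA.

## Known limitations

Exchangeable or unstructured correlation cannot be represented (AR(1) is
forced by the assumptions). The first visit is assumed exactly Poisson,
so baseline overdispersion is unmodelled. Overdispersion strength is
tied to α (φ = 1/(1 − α²)), so weak-correlation/strong-overdispersion
data are misspecified. Estimation near the feasibility bound can
terminate on the boundary and is flagged rather than hidden. Unequally
spaced visits are out of scope: the visit index, not time, drives the
model.
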