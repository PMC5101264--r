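# adcount

Maximum likelihood for equally spaced longitudinal count data with
first-order antedependence and overdispersion, with a GEE comparator, an
exact simulator of the assumed process, and a replicated simulation-study
harness.

## Who this is for

Biostatisticians and epidemiologists analysing repeated counts on
subjects — seizure counts over clinic visits, doctor visits across survey
waves — where two features of real serial count data break plain Poisson
regression: intra-subject correlation and overdispersion (variance larger
than the mean). Semi-parametric GEE handles the correlation but ignores
the overdispersion, which distorts inference on the correlation parameter
in particular; this package fits the full likelihood of a model in which
the overdispersion is *induced by* the serial correlation, so both are
modelled at once, and likelihood-based tools (LRT, AIC/BIC) become
available.

## The model

For subject *i* with counts Y_i1, …, Y_in at equally spaced visits and
covariate rows x_ij:

* marginal mean: E(Y_ij) = λ_ij = exp(x_ij′β);
* first-order antedependence (Markov): Y_ij ⊥ past | Y_ij−1;
* constant adjacent correlation: corr(Y_ij, Y_ij−1) = α;
* linear conditional expectations:
  E(Y_ij | Y_ij−1) = λ*_ij = λ_ij + α (σ_ij/σ_ij−1)(Y_ij−1 − λ_ij−1).

Y_i1 is Poisson(λ_i1); each later Y_ij | Y_ij−1 is Poisson(λ*_ij). These
assumptions induce an AR(1) correlation structure, corr(Y_ij, Y_ij+t) =
α^t, and overdispersion at visits j ≥ 2: var(Y_ij) = λ_ij / (1 − α²).
The likelihood is valid only if λ_ij > 0, |α| < 1, and every slack
λ_ij − α (σ_ij/σ_ij−1) λ_ij−1 is positive; for a 4-visit design with
equal means across visits this caps the correlation at α < 1/√2 ≈ 0.707.
The log-likelihood is maximized by a log-barrier BFGS scheme with the
analytic score; standard errors come from the inverse observed
information (negative Hessian).

## Worked example

Simulate a 60-subject, 4-visit trial from the model (two equal arms,
Poisson baseline count and truncated-normal age as covariates) and fit
both estimators:

```r
library(adcount)
set.seed(2026)
cfg <- sim_config(m = 60, alpha = 0.4, seed = 2026)
dat <- sim_counts(sim_covariates(cfg), cfg$beta, cfg$alpha)
alpha_bound(dat, cfg$beta)   # 0.7071068
fit <- fit_ml(dat)
print(fit)
```

```
Antedependent Poisson ML fit
log-likelihood: -533.2056   AIC: 1076.41   BIC: 1093.81
Coefficients:
            Estimate       SE   Wald  Pr(>|W|)
(Intercept)  0.53240 0.286400  3.456 6.304e-02
treatment   -0.21760 0.073710  8.717 3.152e-03
baseline     0.01959 0.006398  9.376 2.198e-03
age          0.02840 0.006926 16.820 4.109e-05
Correlation parameter:
      Estimate      SE
alpha   0.4373 0.07448
```

The treatment coefficient −0.218 (truth −0.1659) is the log-rate
difference between arms; α̂ = 0.437 (truth 0.4) is the adjacent
correlation, with a Wald 95% interval 0.437 ± 1.96·0.0745. The GEE
comparator on the same data gives α̂ = 0.394 with naive SE 0.0611
(`fit_gee_ar1(dat)`); in repeated sampling those naive intervals for α
undercover, which is the point of the likelihood-based fit
(`run_study()` reproduces that experiment).

A command-line surface wraps the same operations
(`fit`, `gee`, `bound`, `simulate`, `study`), e.g.

```sh
Rscript inst/exec/adcount bound --seed 1          # prints 0.7071
Rscript inst/exec/adcount study --m 60 --alpha 0.2 --R 100 --seed 1
```

(installed: `Rscript $(Rscript -e 'cat(system.file("exec","adcount",package="adcount"))') …`).

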