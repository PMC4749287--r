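# twindelta

Classical twin analysis of **longitudinal change scores** in R, for
biostatisticians and genetic epidemiologists working with two-occasion twin
cohort data (for example metabolic phenotypes — lipids, glucose, body-mass
traits, blood pressure — measured at intake and at follow-up in adult MZ/DZ
twin registries).

The quantity analysed throughout is the within-individual change

Δy = y(time 2) − y(time 1),

and the package answers three questions about it:

1. **Did the phenotype change on average?** A mixed-effect kinship model
   `y = β₀ + β₁·age + β₂·sex + β₃·time + random effects` is fitted by
   maximum likelihood with a genetic random effect correlated 1 between MZ
   and 0.5 between DZ co-twins, an individual random intercept across the
   two occasions, and an independent residual; β₃ is tested with a Wald
   statistic.
2. **Do co-twins change alike?** The intra-pair correlation of Δy,
   ρ = σ²ₛ/(σ²ₛ + σ²ₑ) with σ²ₛ the between-pair and σ²ₑ the within-pair
   variance, is estimated per zygosity by exchangeable bivariate-normal ML
   (optionally adjusting the mean for sex, baseline age, and baseline trait
   level), with pair-bootstrap percentile CIs and a bootstrap test of
   ρ_MZ = ρ_DZ.
3. **Why do individuals differ in how they change?** The variance of Δy is
   decomposed into additive-genetic (A), shared-environment (C) or
   dominance (D), and unique-environment (E) proportions under the classical
   twin model: cov(MZ) = (a² + c² + d²)·V, cov(DZ) = (a²/2 + c² + d²/4)·V.
   Both full models (ACE, ADE) are fitted; the one with lower AIC is the
   full model (the heuristic "ADE iff r_MZ > 2·r_DZ" is also reported);
   nested AE/CE/E models are compared by likelihood-ratio tests, with the
   most parsimonious non-rejected model selected (DE is never fitted);
   component CIs come from a zygosity-stratified pair bootstrap.

A seeded synthetic-cohort generator with exact ACE/ADE covariance algebra
for both phenotype *level* and *change* makes every stage testable without
access to confidential cohort data, and a preprocessing module implements
the standard cleaning rules (natural-log transform, single-pass 3-SD
outlier masking pooled over occasions, change-score construction).

## Worked example

Simulate a Danish-registry-sized cohort (226 MZ + 276 DZ pairs, baseline
ages 18–67, 12-year follow-up) with one log-normal total-cholesterol-like
trait whose change is 45% additive-genetic, then run the full analysis:

```r
library(twindelta)

cfg <- sim_config(
  n_mz_pairs = 226, n_dz_pairs = 276,
  traits = list(
    trait_spec("tc", mu_baseline = 1.68, total_sd_level = 0.20,
               total_sd_change = 0.15, beta_time = 0.02, beta_age = 0.002,
               var_change = c(0.45, 0, 0, 0.55), lognormal = TRUE)
  ),
  age_range = c(18, 67), follow_up_years = 12, seed = 2026
)
cohort <- simulate_cohort(cfg)
prep   <- preprocess_trait(cohort, "tc", log_transform = TRUE)

glance(fit_mixed_change(prep$cleaned, "tc"))
#>   trait sigma2_g sigma2_p sigma2_e logLik n_obs n_pairs     p_time
#> 1 tc      0.0215   0.0216   0.0119   568.  2004     502 0.00000176

bootstrap_icc_ci(prep$deltas, "MZ", covariates = TRUE, reps = 1000, seed = 1)
#> Intra-pair correlation (MZ, 225 pairs): 0.467 [0.359, 0.562]
bootstrap_icc_ci(prep$deltas, "DZ", covariates = TRUE, reps = 1000, seed = 2)
#> Intra-pair correlation (DZ, 273 pairs): 0.260 [0.156, 0.356]

sel <- fit_twin_cascade(prep$deltas, covariates = TRUE, boot_reps = 1000, seed = 3)
sel
#> Full model: ACE (AIC rule; ICC heuristic: ACE)
#> Best model: AE
#> AE model (225 MZ / 273 DZ pairs)
#>   a2 = 0.477  c2 = 0.000  d2 = 0.000  e2 = 0.523
#>   total var = 0.02377, logLik = 486.036, k = 6, AIC = -960.07
tidy(sel$best_fit)
#>   component estimate free    low  high
#> 1 a2           0.477 TRUE  0.386 0.556
#> 2 c2           0     FALSE 0     0
#> 3 d2           0     FALSE 0     0
#> 4 e2           0.523 TRUE  0.444 0.614
```

Reading the output: the mean level rose significantly over the follow-up
(p ≈ 2e-6 for the time effect); co-twin changes correlate 0.47 (MZ) versus
0.26 (DZ), so roughly twice as alike in MZ pairs — a genetic signature; and
model selection keeps the AE model with 48% (95% CI 39–56%) of the variance
in change attributed to additive genetics and the remaining 52% to unique
environment, close to the generating 45/55 split.

`run_pipeline()` / `write_report()` orchestrate all stages for a trait list
and emit per-table CSVs plus a JSON bundle; `autoplot()` methods draw the
occasion-1 versus occasion-2 residual scatter of a mixed fit and the
component bars of a selected model. A thin command-line front end with
`simulate` / `preprocess` / `mixedfit` / `icc` / `twinfit` / `report`
subcommands is installed at `inst/cli/twindelta.R`.

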