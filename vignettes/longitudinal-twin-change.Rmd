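---
title: "Decomposing longitudinal change in twin cohorts: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing longitudinal change in twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindelta)
```

## The scientific problem

Levels of metabolic phenotypes (lipids, glucose, body-mass traits, blood
pressure) are known to be moderately to strongly heritable, but the *rate at
which an individual's phenotype changes* over adult life is a different
quantity with a potentially different genetic and environmental
architecture. With two measurement occasions per person, the natural metric
is the change score Δy = y₂ − y₁, and the classical twin design — comparing
monozygotic (MZ) pairs, who share all segregating genetic effects, with
dizygotic (DZ) pairs, who share on average half of the additive and a
quarter of the dominance effects — identifies how much of the variance in
Δy is genetic versus environmental. twindelta implements that analysis end
to end: data cleaning, a mixed-model test of mean change, zygosity-specific
intra-pair correlations, and ACE/ADE variance decomposition with
likelihood-ratio model selection and bootstrap confidence intervals.

## Models

### Mean change: the mixed-effect kinship model

For each trait, the long-format data (one row per individual per occasion)
are modelled as

y = β₀ + β₁·age + β₂·sex + β₃·time + g + p + ε,

where `time` is 0 at baseline and 1 at follow-up, `age` is baseline age and
`sex` is coded 0/1 (male/female). The random part has three components: a
genetic effect *g* constant over a person's two occasions and correlated 1
between MZ and 0.5 between DZ co-twins, an individual random intercept *p*
linking one person's two occasions, and an independent residual ε. Each
pair therefore contributes a block of up to 4 observations with covariance
σ²_g·K + σ²_p·P + σ²_e·I, and pairs with missing measurements contribute
the observed sub-block, so incomplete pairs still inform the fixed effects.
The fit is maximum likelihood (not REML), with fixed effects profiled out
by GLS at each variance evaluation; variances are optimized on the
standard-deviation scale (squared internally) so zero is attainable. The
significance of mean change is the Wald statistic β₃/SE(β₃) against the
standard normal — the default output of the mixed-model software this
analysis style is built on; the data are fully informative about β₃ at the
sample sizes involved, so Wald and LRT versions are practically identical.

Whether the kinship-style model should carry an individual random intercept
across occasions in addition to the genetic effect is genuinely open with
two occasions; it is included by default (it absorbs person-level
environmental stability that is neither genetic nor occasion-specific) and
can be switched off via the `free` argument of `fit_mixed_change()`.

### Intra-pair correlation of change

Co-twin changes (Δy₁, Δy₂) of one zygosity are modelled as exchangeable
bivariate normal: common mean model, common variance, correlation ρ. Then
ρ = σ²ₛ/(σ²ₛ + σ²ₑ), the between-pair share of the variance of Δy. The MLE
is computed by iterated GLS: the sum/difference rotation
z± = (r₁ ± r₂)/√2 diagonalizes the exchangeable covariance, so given the
mean coefficients the variance and covariance have closed-form ML updates,
and given ρ the mean coefficients are GLS; the iteration converges in a
handful of steps (one step exactly when the mean is an intercept). Because
every statistic is symmetric in the co-twins, the estimate is invariant to
within-pair ordering, and ρ may be negative (informative about competition
or measurement artefacts) rather than being truncated at zero. An ANOVA
moment estimator is kept in the test suite as an independent oracle: with
ML (n) divisors the two estimators coincide, which the tests verify to
1e-6.

Confidence intervals are percentile intervals from resampling *pairs* (the
exchangeable sampling unit), never individuals, within zygosity; the MZ=DZ
comparison bootstraps both ICCs independently and reports a two-sided
percentile-of-zero p-value for the difference. Whether the original
analyses used asymptotic or bootstrap intervals is not stated; bootstrap is
the declared default here because it respects the [−1, 1] range and the
pair structure.

Covariate adjustment (sex, baseline age, baseline trait level) enters the
mean model of the likelihood rather than pre-residualizing, keeping one
estimation framework; the two approaches differ only in how estimation
uncertainty in the adjustment propagates, and the unadjusted path remains
available via `covariates = FALSE`.

### Variance decomposition of change

Under the classical twin model the co-twin covariance of Δy is
(a² + c² + d²)·V for MZ and (a²/2 + c² + d²/4)·V for DZ pairs, with V the
total variance and a², c², d², e² the standardized additive-genetic,
shared-environment, dominance and unique-environment proportions. C and D
are not jointly identifiable with twins reared together, so the full models
are ACE and ADE. Both are always fitted; the AIC rule picks the full model
(the classical heuristic — ADE when r_MZ > 2·r_DZ — is computed and
reported alongside, and ties go to ACE). Nested models (AE, CE, E under
ACE; AE, E under ADE) are tested against the full model by likelihood-ratio
tests; among the non-rejected nested models the one with fewest free
parameters is selected (ties by lower AIC), and parsimony by LRT overrides
AIC relative to the full model. DE is never fitted: dominance without
additive effects cannot produce a DZ correlation as low relative to MZ as
the model implies, so it is biologically implausible.

Numerically, the likelihood is a sum of bivariate-normal pair densities.
For fixed standardized components the mean coefficients are GLS and the
total variance has a closed-form ML solution, so these are concentrated
out and the optimizer searches only the 0–2 free component proportions.
Proportions are parameterized as squared path-style coordinates normalized
onto the unit simplex, so every component lies in [0, 1], the four
components sum to one by construction, and boundary values (a² = 0) are
attainable exactly — which matters because published tables print exact
zeros with LRT p = 1.00 at X² = 0. One free component is optimized by
golden-section search with the pure-E boundary evaluated explicitly; two
free components use Nelder–Mead from the Falconer moment start
(a² = 2(r_MZ − r_DZ), c² = 2r_DZ − r_MZ, clipped to the simplex) plus
seeded random restarts (5 starts by default; ADE likelihoods can be
multimodal in small samples). The solutions of the nested models are also
injected as exact candidate points of the full-model search, which
guarantees loglik(full) ≥ loglik(nested) and hence non-negative LRT
statistics.

LRT p-values use the naive χ² reference with df equal to the parameter
difference, not a boundary mixture. At a boundary null (a true component
of zero) the naive reference is conservative — the null distribution of X²
is approximately a half-half mixture of a point mass at zero and χ²₁, so
the realized type-I error at nominal 0.05 is near 2.5–3% — but it is the
convention that reproduces the published bookkeeping (p = 1.00 printed at
X² = 0.00), and it is documented rather than replaced. Component CIs are
percentile intervals from a zygosity-stratified pair bootstrap refitting
the selected model per replicate; non-convergent replicates are dropped and
counted, with a warning beyond 5%.

## The synthetic-cohort generator

Since the original cohort data are confidential, the package ships a
generator that reproduces the *design* of two-occasion twin studies — not
the marginal distributions of any real cohort. Latent A, C, D, E scores are
standard normal, built from pair-level and individual-level draws with
sharing weights √1/√0.5 (additive, MZ/DZ), √1/√0.25 (dominance), 1/1
(shared environment) and 0/0 (unique environment), then scaled by
√(proportion)·total SD; this reproduces the twin covariance algebra
exactly, which the tests verify empirically at 5000 pairs per zygosity
within ±0.03. Level and change have separate architectures; the follow-up
value is the baseline value plus the trait's mean change plus the latent
change draw. Age is uniform over the configured range and shared within a
pair (twins share a birth date); age and sex act on the level and therefore
carry over to both occasions, matching the analysis model's single age and
sex coefficients. MZ pairs are always same-sex; DZ pairs may be
opposite-sex. Log-normal traits exponentiate the normal-scale model so the
log-transform path of the pipeline is exercised end to end.

Default study conditions mirror the adult twin cohorts this design comes
from: 226 MZ + 276 DZ complete pairs (a Danish-registry-sized sample; the
smaller Chinese-registry design, 101 MZ + 80 DZ, is a parameter choice
away), baseline ages 18–67, balanced sexes, complete pairs at both
occasions (the analyzed samples were complete pairs; attrition is not
modelled). What the generator does *not* emulate: real phenotype marginals
and units, assay error structure, age-dependent variance, selection
effects of recruitment, or correlation between baseline level and change.
Passing tests therefore demonstrate correctness of the estimators under
the model's own assumptions, not robustness to every feature of real
registry data.

## Data cleaning rules and their reading

The pipeline order is fixed: natural-log transform (where enabled per
trait), then a single-pass mask setting values more than 3 SD from the
trait mean to missing, then the change score. Two details are
under-determined by the usual one-sentence description of this rule and
are implemented as declared, switchable defaults: masking operates on the
*transformed* scale (the rule is stated after the transform), and the mean
and SD pool both occasions (the rule does not stratify by occasion). The
mask is applied once — the SD is not re-estimated after masking. Pairs in
which a co-twin lacks an observed change score are excluded from the
pairwise stages (ICC, twin models), which need complete pairs, while their
remaining measurements still enter the mixed-model stage.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `k_sd` | `mask_outliers()` | 3 | outlier cut-off, SD multiples on the analysis scale |
| `covariates` | ICC / twin fits | pipeline: TRUE | adjust means for sex, baseline age, baseline level |
| `alpha` | `fit_twin_cascade()` | 0.05 | LRT level for parsimony selection |
| `reps` / `boot_reps` | bootstraps | 1000 | pair-bootstrap replicates (minimum 100) |
| `level` | bootstraps | 0.95 | CI level |
| `n_starts` | `fit_twin_model()` | 5 | optimizer starts for two-component models |
| `seed` | everywhere | — | all randomness derives from explicit seeds |

All pipeline randomness flows from one root seed through fixed per-stage
derived seeds, so re-running a configuration reproduces every number and
output file byte for byte.

## Verification strategy and problem sizes

The test suite validates each stage against independent oracles: hand
arithmetic for the cleaning rules and Falconer starts, a direct
bivariate-normal density for the pair likelihood (1e-10), an ANOVA moment
estimator for the ICC (1e-6), method-of-moments estimates and an
exhaustive 0.005-resolution grid search of the likelihood for the
biometric fits, and Monte Carlo calibration for the inferential claims.
The calibration suites run at the scale where their asymptotic targets
apply and with replicate counts sized for stable pass/fail behaviour:
parameter recovery as mean bias over 10 cohorts of 5000 pairs per
zygosity (±0.04); model-selection recovery over 100 cohorts per generating
architecture at the same size (≥80%, with pure-E data allowed to keep
familial components ≤0.05 under AE/CE); bootstrap coverage of ICC and
component intervals over 200 outer replicates at 500 pairs (90–98%);
mixed-model type-I error over 200 replicates of 500 pairs (2–9%); and the
boundary-LRT type-I error over 1000 replicates at 2000 pairs per zygosity,
where the naive reference's conservative 2.5–3% rate is measured precisely
enough to sit stably inside the 2–9% band. Null-calibration simulations
use architectures under which the fitted model is correctly specified
(e.g. change generated with no familial component when testing mean-change
type-I error), so the measured rates test the estimator rather than model
misspecification.

## Known limitations

- Two occasions identify the variance of change but not growth curves or
  the correlation between baseline level and rate of change; no
  growth-curve or bivariate Cholesky models are provided.
- No sex-limitation models and no special treatment of opposite-sex DZ
  pairs.
- The ICC estimator constrains nothing, but the biometric models constrain
  implied twin correlations to be non-negative (path parameterization), as
  standard twin software does; strongly negative observed correlations
  will fit at a boundary.
- The naive χ² LRT reference is conservative for boundary nulls (documented
  above), so nested models are retained slightly more often than a mixture
  reference would retain them — the parsimony-friendly direction.
- The Wald test for mean change relies on the pair-block covariance being
  correctly specified; with heteroscedastic occasions its model-based SE is
  an approximation, adequate in the balanced complete-pair designs
  simulated here.
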