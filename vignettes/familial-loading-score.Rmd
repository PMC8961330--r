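---
title: "The familial loading score: model, simulator, and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The familial loading score: model, simulator, and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famload)
```

## The measurement problem

Family history of depression and anxiety is an established risk factor,
but it is usually coded as a single yes/no indicator: FH+ if at least
one first-degree relative is affected. Two participants — one with an
affected parent and four unaffected adult siblings, one with both
parents and two siblings affected — receive the same value. The familial
loading score (FLS) replaces the dichotomy with a continuous
likelihood-ratio index that uses the whole family: how many relatives,
how many affected, and how much of the first-onset risk window each
unaffected relative has already traversed without becoming ill.

## The model

For participant $i$, each first-degree relative $j$ observed at age
$x_{ij}$ contributes a likelihood ratio comparing the hypothesis that
$i$ carries familial risk (relatives then have lifetime prevalence $a$)
against the hypothesis that they do not (prevalence $b$). First onsets
are modelled as uniform on the window $[d, c]$, so cumulative onset risk
by age $x$ under prevalence $p$ is $p\,u(x)$ with
$u(x) = \min(\max((x-d)/(c-d), 0), 1)$ (`onset_fraction()`). Then

$$\mathrm{LR}^{\text{aff}}_{ij} = \frac{a\,u(x_{ij})}{b\,u(x_{ij})} = \frac{a}{b},
\qquad
\mathrm{LR}^{\text{unaff}}_{ij} = \frac{1 - a\,u(x_{ij})}{1 - b\,u(x_{ij})},$$

and the score is the common logarithm of the product over the $n_i$
relatives:

$$\mathrm{FLS}_i = \log_{10}\prod_{j=1}^{n_i} \mathrm{LR}_{ij}
 = \sum_{j=1}^{n_i} \log_{10}\mathrm{LR}_{ij}.$$

Under this construction the age term cancels for affected relatives —
all age adjustment acts through the unaffected ones, whose ratio falls
continuously from 1 (no window traversed, no evidence) to
$(1-a)/(1-b)$ at $u = 1$. Because the printed algebra of the original
formulas is not always reproduced in secondary sources, the two ratios
are isolated in `lr_affected()` / `lr_unaffected()`; a different algebra
is a two-function change, and the scoring, simulator and pipeline above
them would be untouched.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `a` | lifetime prevalence of depression/anxiety given FH+ | probability | 0.50 |
| `b` | lifetime prevalence given FH− | probability | 0.134 |
| `c_upper` | upper limit of first-onset window | years | 65 |
| `d_lower` | lower limit of first-onset window | years | 5 |

`b` follows the original algorithm's convention of half the
general-population lifetime prevalence (26.8% in the Dutch population,
hence 0.134; `fh_negative_prevalence()`). When a user supplies a
different population prevalence, `b` is deliberately *not* re-derived
automatically — the choice of convention is left explicit.
`fls_parameters()` enforces $b \le a$ (otherwise the LR directions
invert silently) and $0 \le d < c$. Ages above `c_upper` contribute the
$u = 1$ value; ages above 120 are rejected as data errors.

### Numerical choices

The score is accumulated as a sum of `log10` terms, never as the raw
product, so arbitrarily long pedigrees cannot under- or overflow; the
product-scale `overall_lr` in the result object is reconstructed as
$10^{\mathrm{FLS}}$ for audit only. An empty family is the empty
product: FLS = 0, FH−, with a warning. An affected relative recorded at
or below `d_lower` is a data inconsistency (an onset cannot have
occurred yet); the score still uses $a/b$ — the limiting value for any
$u > 0$ — and a warning is raised. Scores are serialized at 4 decimal
places in CSV outputs; full double precision is kept internally.

## Classifying relatives and the FH indicator

A relative is affected only when both interview criteria hold: at least
one endorsement among episode/core-symptom/restriction questions *and*
at least one among treatment/admission questions (`classify_relative()`).
The data model accepts pre-aggregated flags or per-question columns
(prefixes `symptom_`, `treatment_`), which are OR-reduced per criterion;
only the two aggregate flags matter. For deceased relatives the
observation age is the age at death — the standard censoring choice,
which treats the life actually lived as the exposure window. Missing
ages are a hard error by default; `impute_missing_age = TRUE` switches
to relation-class mean imputation with a warning, mirroring the fact
that the source analyses excluded rather than imputed incomplete family
interviews. Offspring are not modelled: the instrument covers biological
parents and siblings.

## What the synthetic cohort emulates

`generate_cohort()` produces data with the statistical structure the
analysis assumes, not a portrait of any real sample:

* **Familial clustering.** Each family draws a shared factor $F$; member
  liability is $\sqrt{\rho}F + \sqrt{1-\rho}\,\varepsilon$, so
  `familial_effect` $= \rho$ is the within-family liability correlation
  and the marginal liability is standard normal for every $\rho$. The
  affection threshold is the closed-form quantile
  $\Phi^{-1}(1 - \text{prevalence})$ — no bisection needed because the
  marginal is invariant to $\rho$.
* **Onset and observation.** Each lifetime-affected member draws an
  onset age, uniform on $[d, c]$ by default — deliberately the score's
  own assumption, so the score can be tested under its own model; an
  alternative mildly peaked law (`onset_law = "beta"`) is available for
  robustness experiments. A member is *observed* affected only once
  their onset age has passed.
* **Ascertainment.** Probands are rejection-sampled until lifetime
  affected with onset passed, mirroring the inclusion criterion of a
  lifetime-affected clinical sample. Every generated proband is
  affected by construction.
* **Under-reporting.** A truly affected relative is reported affected
  with probability `reporting_sensitivity` (default 0.62). This knob is
  essential for realism: with prevalence 0.268 and mean family size
  near 3.5, perfect reporting would force the FH+ fraction above 60%
  even with *independent* family members, whereas family-interview
  instruments with strict two-criterion rules detect substantially
  fewer affected relatives than the true cumulative risk. Unaffected
  relatives endorse symptom questions without treatment 15% of the
  time, so the two-criterion rule is exercised, not vacuous.
* **Calibration.** The defaults $\rho = 0.45$,
  `reporting_sensitivity` = 0.62 were tuned once so the *emergent* FH+
  fraction lands near 0.598 at the default configuration (0.597 over 25
  seeds); FH+ is never forced directly. At $\rho = 0.5$ the lifetime
  risk of a relative of an affected proband is ≈ 0.50, matching the
  meaning of parameter $a$.
* **Covariates and PRS stand-in.** Gender is Bernoulli(0.666),
  education years are a rounded normal (mean 13, sd 3) truncated to
  [5, 22], proband ages are uniform on [26, 75]. Sibling counts are 0
  with probability 0.08 and otherwise $1 + \mathrm{Poisson}(0.63)$
  (mean ≈ 1.5) — a plain Poisson cannot give both a mean of 1.5 and 8%
  zeros. The polygenic-score stand-in is
  $r\,z(\text{liability}) + \sqrt{1-r^2}\,\text{noise}$ with target
  $r = 0.07$; it carries no genotype structure.
* **Outcomes.** Each outcome is linear in a standardized exposure basis
  plus small covariate effects plus Gaussian noise, with the noise
  scale set from the realized variance of the linear predictor so the
  outcome has unit variance and the planted *standardized* coefficient
  holds in expectation. The default basis is the computed FLS itself:
  the operational exposure the pipeline regresses on, which makes
  parameter-recovery simulations unbiased by construction. Planting on
  the latent liability instead (`basis = "liability"`) attenuates the
  recovered FLS coefficient by the FLS–liability correlation — a useful
  robustness scenario, not the default contract. Default planted
  effects (0.07, 0.07, 0.10, −0.09, 0.07, 0.12, 0.13 across seven named
  vulnerability outcomes) are the standardized familial-loading effect
  sizes the score was designed to detect.

What the simulator does **not** emulate: assortative mating,
multigenerational pedigrees, real genotypes, non-Gaussian liability,
informant-specific reporting biases, or item-level instrument structure.
Passing tests therefore show that the score and pipeline behave
correctly under a liability-threshold world consistent with the score's
own assumptions — not that the score is well calibrated for any
particular real population.

## The analysis pipeline

`run_full_analysis()` reproduces the comparison design: for every
outcome, three ordinary-least-squares models adjusted for age, gender
and years of education — exposure FLS, exposure FH, and exposure
*residualized* FLS (residuals of FLS regressed on FH, exactly orthogonal
to the dichotomy; `residualize()`). Coefficients are reported
unstandardized with 95% CIs and as fully standardized betas (all
variables z-scored, binary ones included, the convention of the major
commercial statistics packages; a partial-standardization option leaves
0/1 exposures unscaled). Complete cases are used per model and `n_used`
is reported per row. The two-sample comparison of FLS by FH group uses
the pooled-variance Student's t (its df equal $N - 2$, the form matching
a printed df of 1423 at $N = 1425$); 2×2 tables use Pearson's chi-square
*without* continuity correction, the form that reproduces published
values from raw counts. Repeated instrument scores are averaged over all
available waves (`aggregate_repeated_measures()`), with all-missing
propagating to missing.

Multiplicity is controlled with Benjamini–Hochberg at a 5% FDR. Because
it is ambiguous whether a single family should span all exposures or one
family per exposure block, both are implemented
(`bh_family = "per_exposure"` is the default, `"global"` the
alternative) and neither is asserted as canonical. Raw p values are
always preserved in outputs; decisions are flags alongside them.

## Problem sizes used in the checks

The test suite exercises the algebraic properties (oracle equivalence of
sum-of-logs against product-then-log, additivity, exact increments,
degenerate parameters) on 1000 random families; orthogonality and BH
agreement with a brute-force step-up on 1000 random p-vectors;
parameter recovery on 200 replicate cohorts of n = 1425 with a planted
standardized effect of 0.13; and global-null FDR behaviour on 500
replicate null cohorts of n = 400 with 20 outcomes — the null property
is invariant to cohort size, so the smaller n simply buys replicates.
`scripts/acceptance.R` reruns the 200-replicate recovery end to end from
a single seed.

## Known limitations

* The uniform-onset window is a coarse onset model; ages far above the
  window contribute no additional information by construction.
* The score treats relatives' statuses as conditionally independent
  given the familial-risk hypothesis; dense multiplex pedigrees violate
  this more strongly than small families.
* `reporting_sensitivity` is a single scalar; real informant accuracy
  varies by relative, disorder and recall distance.
* Parameters $a$ and $b$ are disorder-specific constants taken from the
  depression/anxiety literature; other disorders require explicit
  overrides, and the package does not re-derive $b$ from a supplied
  population prevalence.
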