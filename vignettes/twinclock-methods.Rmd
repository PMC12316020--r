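---
title: "Methods: linking epigenetic and brain age acceleration in twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking epigenetic and brain age acceleration in twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinclock)
```

# The scientific problem

Two families of biological-age markers are in wide use: epigenetic clocks,
which predict age (or pace of ageing) from weighted DNA-methylation beta
values in blood, and brain-age models, which predict age from structural
MRI. Each yields an *age acceleration*: the part of the predicted age not
explained by chronological age. twinclock implements the full analysis path
for asking two questions in a family-based sample:

1. Is blood DNA-methylation age acceleration associated with brain-age
   acceleration across individuals?
2. If so, is the association driven by familial factors (genes, shared
   environment) or by unique-environment factors?

The second question exploits the twin design: monozygotic (MZ) co-twins
share all their segregating genes and their rearing environment, so any
association between *within-pair differences* of two traits can only come
from unique-environment (E) influences, while a *cross-twin cross-trait*
(CTCT) correlation — trait X in one twin against trait Y in the co-twin —
can only come from familial (A and/or C) influences.

# Pipeline stages and their models

## Clock engine

A clock is a linear predictor over CpG beta values,
$\hat{y} = T^{-1}\!\left(\beta_0 + \sum_i w_i \beta_i\right)$,
with $T^{-1}$ either the identity or the piecewise log-linear age transform
used by multi-tissue chronological-age clocks:
$T^{-1}(y) = (A+1)e^{y} - 1$ for $y < 0$ and $y(A+1) + A$ otherwise, with
adult-age knot $A = 20$ years by default (the constant used by the
published calculator; it is configurable because coefficient files do not
always restate it). Coefficients are user-supplied delimited text
(`cpg,weight` with a reserved `(Intercept)` row and `#key=value` metadata
lines), because published clocks are distributed as external software or
supplementary tables rather than a single canonical format.

Age-type clock estimates are residualized on chronological age by OLS
*within the analysis sample*: the acceleration of an individual is defined
relative to the cohort's own age trend, not an external reference. This is
the appropriate choice when the cohort is the inferential universe; it
implies accelerations are not comparable across differently-composed
cohorts. Pace-type clocks already estimate a rate of ageing and enter the
models as-is (standardization happens at the modelling stage).

Missing clock CpGs are an error by default; an opt-in imputation mode
substitutes the hemi-methylated value 0.5 with a warning. The strict
default reflects that silent probe loss changes a clock's meaning.

## Brain-age gap and age-bias correction

The raw brain-age gap is `predicted - chronological`. Brain-age models
over-predict young and under-predict old brains, so the raw gap carries a
spurious negative age trend. The sample-level correction fits
`gap = a*age + b` by OLS over the whole analysis sample and subtracts the
fitted trend; two presentations of this correction exist in the literature
(adjusting the prediction vs. adjusting the gap) and the package adjusts
the gap directly, which is algebraically the residualization the
downstream models need. The correction is fitted **after** the
trained-age-range filter (default 18–92 years, inclusive, matching the
training range of the widely used Gaussian-process brain-age model) and
**before** outlier exclusion, because the bias is a property of the
prediction model and should be estimated on all validly predicted samples.
Age at MRI is the regressor, again because the bias belongs to the MRI
model. The bias regression is pooled over the sample; fitting per
sub-study would also be defensible but uses many fewer points per fit, and
the pooled fit is what the corrected-gap definition requires when the
sample is analysed as one.

## Outlier screening

Sample exclusion has two stages: rows missing any required covariate are
removed (with the offending columns reported), then Rosner's generalized
extreme studentized deviate (ESD) test is applied to each acceleration
measure, removing the union of flags. The ESD test computes, at iteration
$i$ on $n$ points, $R_i = \max_j |x_j - \bar{x}|/s$ on the current set and
compares it to
$\lambda_i = (n-i)\, t_{p,\,n-i-1} \big/ \sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}$
with $p = 1 - \alpha/(2(n-i+1))$; the declared outlier count is the
largest $i$ with $R_i > \lambda_i$. Defaults are $k_{\max} = 10$ per
variable and $\alpha = 0.05$; the variables screened, $k_{\max}$ and
$\alpha$ are explicit configuration because published analyses rarely
state them. Ties at the maximum deviation break toward the lowest index,
making the procedure deterministic.

## Association models

Brain-age acceleration is regressed once on each clock's acceleration with
a Gaussian random intercept per family (REML, via lme4), which absorbs the
non-independence of twins and siblings. Covariate sets:

* **base** — technical only: collapsed bisulphite-plate dummies
  (reference-coded) and methylation array row.
* **full** — base plus sex, BMI, smoking dummies (former and current vs.
  never) and the neutrophil, monocyte and eosinophil percentages.
  Lymphocytes are excluded because a five-part differential makes them
  near-collinear with neutrophils; basophils because they barely vary
  between individuals.
* **full_scanner** — full plus an MRI field-strength dummy (sensitivity
  analysis for multi-scanner samples).

Plates carry a processing order, and consecutive plates share batch
conditions, so the 34 plates are collapsed into 6 contiguous groups of
near-equal size (6,6,6,6,5,5); only contiguity and near-equality are
principled here, and both are enforced. All continuous variables
(response, exposure, array row, BMI, WBC percentages) are Z-scored on the
analysis sample after exclusions, so with no covariates the exposure
coefficient is exactly the Pearson correlation, and with covariates it
reads as a partial correlation. Array row (1–6 on the array) is treated as
a standardized continuous covariate.

Wald p-values use residual degrees of freedom ($n - p$) by default; a
Satterthwaite option (via lmerTest) is provided since the df convention
behind published mixed-model p-values is often unstated. When every family
is a singleton the random intercept is unidentified and the model is the
OLS limit; the package detects this and fits OLS directly, which is exact
rather than approximate in that case.

Multiple testing uses the effective number of independent tests: five
clocks spanning three independent dimensions give a per-test threshold of
$0.05/3 = 0.0167$ (displayed to four decimals, compared unrounded).

## Twin aetiology decomposition

Complete MZ pairs are assembled by family id with twin order fixing the
slots. The CTCT correlation uses double entry by default — each pair
contributes $(x_1, y_2)$ and $(x_2, y_1)$ — making the estimate exactly
invariant to the arbitrary within-pair labelling. Double-entered
observations are not independent, so the default p-value uses the
conservative $n_{\text{pairs}} - 2$ degrees of freedom; a
$n_{\text{obs}} - 2$ option exists for replicating reports that count
double-entered observations. The MZ-difference regression fits
$\Delta y \sim \Delta x$ without intercept by default (differences have
expectation zero under arbitrary pair ordering; an intercept option
exists). On traits standardized in the full analysis sample — differences
are deliberately *not* re-standardized within pairs — the no-intercept
slope estimates the unique-environment cross-trait correlation
$r_E$, since $\mathrm{Cov}(\Delta x, \Delta y) = 2 r_E \sqrt{e^2_x e^2_y}$
and $\mathrm{Var}(\Delta x) = 2 e^2_x$.

The package deliberately does not fit the full bivariate ACE structural
model (Cholesky decomposition with submodel tests): with few or no
complete DZ pairs the A and C components are not separable, and the
CTCT/ΔMZ pair of estimators is exactly the part of the decomposition the
design supports.

# The synthetic cohort generator

Restricted cohort data cannot ship with an analysis package, so the
generator is a first-class module producing cohorts with *known* latent
structure. Two standardized traits per individual follow a bivariate ACE
model: trait $= \sqrt{a^2}A + \sqrt{c^2}C + \sqrt{e^2}E$ with A correlated
1 across MZ and 0.5 across DZ co-twins (no assortative mating or
dominance), C shared within pair, E unique, and cross-trait correlation
imposed on like components only ($r_A$, $r_C$, $r_E$). Closed-form
consequences used throughout validation: within-trait pair correlations
$r_{MZ} = a^2 + c^2$, $r_{DZ} = a^2/2 + c^2$; MZ CTCT
$= r_A\sqrt{a^2_x a^2_y} + r_C\sqrt{c^2_x c^2_y}$; the correlation of MZ
differences $= r_E$.

Around the traits the generator fills: uniform ages over a configurable
range (default 20–84 years, shared within pair); blood drawn a Gaussian
interval before MRI (default mean 2, SD 4 years, giving both signs of the
interval as real cohorts show); sex (shared within MZ pairs); BMI (normal,
mean 24, SD 3.5, truncated to 15–45 kg/m²); smoking status
(never/former/current = 0.60/0.24/0.16, the pooled frequencies of a
typical adult European twin cohort); a five-part WBC differential drawn
around adult means and renormalized to sum to 100; plate (1–34) and array
row (1–6); and a scanner field-strength label. Covariates carry no
dependence on the traits, so they are non-confounding by construction —
confounding scenarios are for the user to build explicitly.

Brain-age predictions are chronological age plus a scaled latent
acceleration (default 5 years per SD), a linear bias
(default intercept 8, slope −0.3 — the regression-to-the-mean pattern of
real brain-age models), and Gaussian noise (default SD 5 years, the
typical RMSE scale of structural brain-age prediction). CpG beta matrices
are built by inverting the clock: all CpGs start at 0.5 and are displaced
together along the normalized coefficient direction by the scalar solving
the linear predictor for the noisy target, then clipped, with a post-clip
residual check that turns infeasibility into an error instead of silent
degradation. One displacement direction is used rather than per-CpG
variation because the object under test downstream is the clock
arithmetic; the generator makes no attempt at genome-wide methylation
covariance, probe artefacts, or realistic per-CpG distributions.
Consequently, passing tests demonstrate the correctness of the estimators
and pipeline plumbing on data satisfying the generative assumptions — they
say nothing about normalization, cell-composition or probe-quality issues
in real methylation data, which are out of scope (measured WBC percentages
are taken as given).

All generation is deterministic given the config seed, invariant to input
row order (stages sort by individual id internally), and leaves the
caller's RNG state untouched.

# Numerical choices and degenerate inputs

* OLS residualizations (acceleration, bias correction) use `lm`; both
  refuse constant regressors and fewer than 3 samples.
* The beta-matrix inversion tolerance is 1e-6 on the achieved target; the
  ESD tie-break is the lowest original index; standardization uses the
  n−1 SD and refuses zero-variance input.
* lme4 convergence diagnostics are captured; boundary-singular fits
  (random-intercept variance estimated at zero) are accepted as valid REML
  solutions, while genuine gradient failures surface as warnings and a
  `converged = FALSE` flag.
* The pipeline skips twin tables (with a logged reason) below 3 complete
  MZ pairs and skips sensitivity subsets below 30 rows rather than fitting
  unstable models.

# Validation scale

The test suite and the acceptance script validate at sizes chosen to keep
Monte-Carlo error well below the effects checked: pair-correlation and
CTCT recovery at 3,000–10,000 pairs (3 Monte-Carlo SEs), bias-slope
recovery at ~2,000 individuals, ESD oracle agreement on 200 datasets of
n = 100 plus a 2,000-replicate null flag-rate check, mixed-model recovery
of a 0.15 exposure effect over 200 replicates of 500 two-member families,
aetiology dissociation over 100 replicates per scenario at 5,000 pairs,
and MZ-difference power at the study-like scale of 120 pairs with
measurement noise that attenuates the latent traits (noise SD 0.4 on
unit-variance traits, matching the default clock/brain noise-to-signal
ratio of the generator).

# Known limitations

* Acceleration is residualized within-sample; estimates are not portable
  across cohorts with different age structures.
* The CTCT p-value treats pairs, not double-entered observations, as the
  unit of information; no additional family-clustering adjustment is
  applied to twin-model p-values.
* The DZ additive-genetic correlation is fixed at 0.5; dominance,
  assortative mating, and sibling-specific shared environment are not
  modelled.
* The generator's covariates are non-confounding by default, so covariate
  adjustment in the association models is exercised structurally, not
  against realistic confounding.
* The command-line entry point (`inst/scripts/twinclock.R`) is a thin
  wrapper over `simulate_twin_cohort()` and `run_pipeline()`; the package
  functions are the primary interface, and the remaining operations are
  exposed as ordinary functions rather than shell subcommands.
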