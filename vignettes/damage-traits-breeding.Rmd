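---
title: "Breeding against ear and tail damage: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breeding against ear and tail damage: models, validation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ear and tail biting in group-housed pigs damage welfare and profit. Because
the behaviour itself is hard to record at scale, breeding programs score the
*damage on the victims* (0 = none to 3 = severe, per body part) and select
against the genetic liability to being bitten. This package implements that
analysis end to end: trait definitions derived from the raw scores, a
pedigree-based linear animal model for variance components and breeding
values, three validation procedures for the EBVs, and the translation of
accuracies and realized selection intensities into expected response to
selection. Since nucleus-herd damage records are proprietary, a simulator
generates populations with the same structure, so every claim the package
makes is testable.

## The animal model

For a scored trait $y$ (one record per animal),

$$ y = Xb + Z_a a + Z_l l + Z_g g + Z_{hys} hys + e $$

with fixed effects $b$ (sex, line, sex×line, scorer, and age at scoring in
days as a linear covariate) and independent random effects: additive genetic
$a \sim N(0, A\sigma^2_a)$ with $A$ the pedigree relationship matrix, litter
$l$, pen group $g$, herd-year-season of scoring $hys$ (all i.i.d.), and
residual $e$. Scores are analysed on their observed scale with a linear
model — the practical convention for routine evaluation — so heritabilities
are observed-scale quantities. The phenotypic variance sums all five
components; `heritability(fit, include_hys = FALSE)` reports the alternative
convention that treats the herd-year-season term as fixed.

Seven trait definitions are derived from the raw ear/tail scores: ED03 and
TD03 (raw 0–3), ED01/TD01 (any damage per part), AD01 (any damage at all),
NBP (number of parts affected, 0–2) and SD06 (summed damage, 0–6). Derived
columns are always recomputed from the raw scores.

## REML estimation

Variance components maximize the restricted likelihood, evaluated through
the sparse mixed-model equations (MME). The default algorithm is
average-information (AI) REML:

* the MME coefficient matrix is assembled on a fixed sparsity pattern
  (precomputed index maps; one fill-reducing permutation) and factorized as
  LDLᵀ by a compiled kernel;
* exact first derivatives use the Takahashi selected inverse of that factor
  — the traces $\mathrm{tr}(K^{-1}C^{kk})$ that EM/AI REML needs are sums of
  inverse-matrix entries on the sparsity pattern of each $K^{-1}$, all of
  which lie inside the factor's pattern;
* updates are Newton steps with the AI matrix, halved until the likelihood
  improves, with a monotone EM step as fallback; variances are floored at
  `floor_frac` (default 1e-8) times the phenotypic variance, and 2×2 blocks
  that leave the PSD cone are projected back by eigenvalue clipping (flagged
  if still active at convergence);
* convergence requires a relative component change below 1e-6 and a
  likelihood change below 1e-8; non-convergence is flagged, not thrown;
* standard errors come from the inverse AI matrix; heritability and genetic
  correlation SEs by the delta method.

A derivative-free quasi-Newton maximization of the same likelihood is kept
as `method = "lbfgs"`; the test suite uses it as a second, independent route
to the optimum, and checks the likelihood itself against a dense-matrix
oracle and the solutions against dense GLS.

Bivariate fits give every random term and the residual an unstructured 2×2
covariance block, parameterized by two log-variances and the correlation.
Starting variances come from the univariate fits and starting correlations
from the phenotypic correlation of the two responses. When two trait
definitions are nearly duplicates (e.g. a score and its own binary version),
the litter correlation can be frozen (`fix = list(term = "litter", value =
0.99)`): that block then updates only its variances, which resolves the
otherwise inestimable direction.

Prediction error variances (PEV) of all breeding values fall out of the
Takahashi inverse at no extra cost; the model-derived accuracy is
$r_i = \sqrt{1 - PEV_i/\hat\sigma^2_a}$ with PEV clamped into
$[0, \hat\sigma^2_a]$ (clamping counted and reported).

## Validation procedures

**Five-fold cross-validation.** Records are allocated to five folds,
re-allocated `replicates` times; besides random allocation, full-sib and
half-sib maskings keep sib groups (connected components of the sib graph,
through either shared parent) in one fold. For each fold, BLUP re-predicts
EBVs from the other four folds at the full-data REML components — components
are not re-estimated per fold, which keeps 100-replicate runs affordable and
matches how the adjusted phenotypes are defined; re-estimating per fold
would mix two sources of noise into the comparison. Validation phenotypes
are adjusted for *all* non-animal effects using the full-data model
(including the animal effect, so the genetic signal is not absorbed), and
accuracy is $\rho(y_{adj}, \hat a)/h$; dispersion is the regression slope of
$y_{adj}$ on $\hat a$ (1 = calibrated). Fixed-effect levels that lose all
records in a fold are pinned to zero (a generalized-inverse convention);
EBV predictions are unaffected.

A scale subtlety deserves emphasis. The published form
$\rho(y_{adj},\hat a)/h$ uses $h$ defined against the *full* phenotypic
variance, but the adjusted phenotype no longer carries the litter, pen and
herd-year-season variance, so its standard deviation is roughly
$\sqrt{\sigma^2_a+\sigma^2_e}$ rather than $\sigma_P$. As an estimator of
$\mathrm{corr}(\hat a, a)$ this form is therefore inflated by about
$\sqrt{\sigma^2_P/(\sigma^2_a+\sigma^2_e)}$ — around 1.3 at this package's
default variance structure — which is one reason k-fold accuracies exceed
forward-validation accuracies in practice. `run_cv()` reports this
conventional accuracy unchanged (it is the right quantity for *comparing*
trait definitions, where the scale factor is common) and additionally
reports `accuracy_cov` $= \mathrm{cov}(y_{adj},\hat a)/(\hat\sigma_a\,
\mathrm{sd}(\hat a))$, a variance-consistent estimator of
$\mathrm{corr}(\hat a, a)$ whose denominator does not depend on how much
variance the adjustment happened to remove; the calibration suite checks
that this version tracks the simulated truth.

**Forward (LR) validation.** The data are split at a birth-date cutoff;
EBVs of the youngest animals are computed with the complete data and with
their phenotypes removed (pedigree links retained). Accuracy
$\sqrt{\mathrm{cov}(EBV_p, EBV_c)/((1-\bar F)\hat\sigma^2_a)}$ uses the mean
inbreeding of the validation animals; bias is reported in genetic-SD units;
dispersion is $\mathrm{cov}(EBV_p, EBV_c)/\mathrm{var}(EBV_p)$. A negative
covariance yields NaN accuracy with a flag rather than an error.

## Selection intensity and response

EBV distributions of few-level traits inherit discreteness, so the realized
intensity of selecting the best 5% — the standardized difference between
the selected group's mean EBV and the population mean — can fall below the
normal-theory value $\phi(z_{0.95})/0.05 = 2.063$, and with heavy ties it
must. EBVs are first detrended by regression on the herd-year-season of
scoring (an ordinary least-squares factor model; the spec of that
adjustment is deliberately minimal). Selection is toward less damage, so
the lower tail is selected and intensities are reported as magnitudes with
the tail recorded. Ties are broken by a stable sort on animal id, making
the selected set deterministic. Responses in genetic-SD units are
$R_{direct} = i \cdot r$ and $R_{correlated} = R_{direct} \cdot r_g$ with
forward-validation accuracies, which represent the prediction task a
breeding program actually faces.

## What the simulator emulates (and what it does not)

`sim_config()` defaults describe a six-line nucleus population scaled to
about 5,000 scored animals: per line and generation, 7 sires and 108 dams
(mirroring the roughly 64 scored offspring per sire and 12.7 dams per sire
of large published damage-scoring datasets), one litter per dam with
truncated-Poisson size (mean 12.5, range 1–30), of which a random ~31%
enter the scored test group; test pens of 6–16 animals interleave litters
within a line-generation cohort; three scoring and four birth
herd-year-season levels per cohort; 23 scorers shared across lines; scoring
ages ~N(153.5, 15) days clamped to 119–221. Generating components per trait
are σ²_a = 0.05, σ²_l = 0.10, σ²_g = 0.20, σ²_hys = 0.10, σ²_e = 0.55
(h² = 0.05, inside the published 0.04–0.06 range) with genetic correlation
0.45 between ear and tail liabilities; environmental correlations (0.20
litter, 0.10 pen and herd-year-season, 0.05 residual) are simulation
choices that give a phenotypic correlation of about 0.10, since component
correlations other than the genetic one are not published. Breeding values
follow the pedigree exactly (founders from $N(0, \Sigma_a)$; offspring as
parent average plus a Mendelian deviation scaled by the parents'
inbreeding), so simulated covariances are consistent with **A**. Ordinal
mode thresholds the liabilities at three cutpoints (defaults at the
75/90/97% quantiles, i.e. score prevalences of roughly 75/15/7/3%).

Not emulated: social (indirect) genetic effects of pen mates on the
victim's damage, selection across the simulated generations, repeated
scoring, across-line relationships, and the biological distinction between
biting and necrosis. Passing calibration tests on these simulations shows
the machinery is correct and the procedures calibrated *under the model's
own assumptions*; it cannot show that real damage scores satisfy those
assumptions (in particular, real EBV accuracy may be overstated if social
genetic variance is present, since the pen-group term absorbs it only as a
nuisance).

## Numerical choices and degenerate inputs

* Unknown parents accept the tokens `0`, empty and `NA`; a single known
  parent contributes half a breeding value with correspondingly larger
  Mendelian variance. Pedigree cycles, duplicate ids and self-parentage are
  rejected with the offending animal named.
* The dense relationship matrix is limited to 5,000 animals; the MME only
  ever use the sparse inverse.
* The fixed design uses treatment contrasts and must be full rank;
  confounded columns are reported by name rather than silently dropped.
* Likelihood invariances (record order, reference level, covariate
  centering) and the MME residual (relative norm < 1e-6) are asserted in the
  test suite on every fitted model.
* Zero-variance responses, empty folds, undefined intensities (zero EBV
  variance) and empty forward-validation sides raise informative errors;
  zero-signal fits return the floor rather than failing.

## Problem sizes used in the checks

The calibration and recovery suites run at the defaults above (about 5,000
phenotyped animals per population): 20 populations for parameter recovery
(univariate σ²_a and bivariate r_g), and three populations for validation
calibration with 20 random-allocation cross-validation replicates plus five
replicates for each sib masking. At these sizes a single population carries
limited information about a heritability of 0.05 — the asymptotic SE of
σ̂²_a is about 0.018 — so recovery is judged on the mean over populations
and on the coverage of ±2 SE intervals, and single-population estimates
(as in the acceptance script's JSON report) should be read with that
sampling noise in mind.

## Known limitations

* Linear models on ordinal scores (the field's routine practice) estimate
  observed-scale parameters; liability-scale heritabilities would need
  threshold models, which are out of scope.
* Multivariate fits are limited to two traits; the full seven-trait response
  table therefore combines bivariate correlation estimates (or published
  ones, as in the worked example).
* The LR method's σ̂²_a comes from the full-data univariate fit; if the
  genetic variance is itself poorly estimated, accuracy inherits that error.
* Dominance, maternal effects, genomic relationships and social genetic
  effects are not modelled.
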