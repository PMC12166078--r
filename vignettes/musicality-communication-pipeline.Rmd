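---
title: "Modelling preschool musicality and school-age communication with polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preschool musicality and school-age communication with polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musicom)
```

## The scientific problem

Longitudinal birth cohorts let us ask whether early, seemingly playful
abilities — singing a few songs, humming a tune, clapping in time with a
beat at age five — are precursors of communication skills measured years
later. Phenotypic correlations alone cannot separate a developmental
pathway from shared upstream causes, so the framework implemented here
triangulates three sources of evidence: (i) covariate-adjusted phenotypic
association and a latent-variable condensation of many noisy parent
reports into a few interpretable factors, (ii) association of those
measures with a polygenic score (PGS) for rhythmicity estimated in a
large independent adult GWAS, and (iii) a mediation-style structural
model in which the PGS acts as a common exogenous cause, splitting each
factor-to-factor association into a genetically shared and a direct part.
Temporal ordering (preschool predictors, school-age outcomes) guards
against reverse causation; a GWAS-by-subtraction step guards against
genetic confounding through educational attainment.

## The covariance-structure engine

Models are specified in reticular-action form: directed paths in a matrix
$A$ over observed-plus-latent variables, symmetric (co)variances in $S$,
implied covariance $\Sigma = F (I-A)^{-1} S (I-A)^{-\top} F^\top$. A pure
confirmatory factor model reduces to
$\Sigma = \Lambda \Psi \Lambda^\top + \Theta$. Estimation minimises the
normal-theory discrepancy

$$F_{ML}(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\,\Sigma(\theta)^{-1}) - \log|S| - p,$$

with $T = (n-1)\,F_{ML}$ as the test statistic. Ordinal 3-category items
are treated as continuous throughout the SEM stages, fitted on
covariate-residualised, unit-scaled scores of the listwise-complete
analysis sample; this mirrors the reporting of a single N per model and
keeps ordinal-threshold (WLSMV-style) estimation out of scope. The cost
is a known, modest attenuation of loadings on 3-category items relative
to their latent-response values; the synthetic experiments quantify it.

Numerical choices:

* **Identification.** Factors are standardised (variance fixed to 1), so
  estimates are directly comparable with reported standardised loadings;
  an explicit check requires every latent variable to carry a fixed
  variance or a fixed marker loading, and degrees of freedom must be
  non-negative before optimisation starts.
* **Optimisation.** `nlminb` with box lower bounds ($10^{-6}$) on
  variance parameters, relative tolerance $10^{-10}$, five restarts (the
  first from the supplied start values, the rest jittered by
  $N(0, 0.2^2)$); ties between restarts break by lowest $F_{ML}$.
  A stationary point with vanishing scaled gradient is accepted as
  converged even when `nlminb` reports its "false convergence" code, a
  common artefact at flat optima. Discrepancies below $10^{-10}$ are
  treated as an exactly saturated fit so that perfect-fit limits
  (CFI = 1, RMSEA = 0) hold exactly.
* **Standard errors.** Inverse-Hessian ML covariance
  ($2/(n-1)\,H^{-1}$), mapped through the standardisation transform by a
  numeric Jacobian (delta method). Defined parameters — arbitrary
  arithmetic expressions in parameter labels, used for $a\,b_k$ and
  $a\,b_k + c_k$ — are evaluated on the standardised solution and
  inherit full delta-method SEs, including cross-parameter covariances.
  The covariance-free Sobel form
  $\sqrt{a^2 SE_b^2 + b^2 SE_a^2}$ is reported alongside for the product
  terms; with an exogenous standardised score the two agree closely.
* **Fit indices.** CFI (capped to $[0,1]$), TLI (uncapped, may exceed 1),
  RMSEA, and SRMR computed on residual correlations over the lower
  triangle including the diagonal, against a closed-form independence
  baseline ($F_0 = \log|\mathrm{diag}(S)| - \log|S|$). With zero degrees
  of freedom TLI and RMSEA are reported as undefined rather than zero.
* **Bootstrap.** Nonparametric case resampling with per-replicate refits
  (single start at the full-sample solution scale); the SE is the SD of
  converged replicate standardised estimates, with replicate failures
  counted and a hard failure above 50%. The package default is
  B = 1000, the convention for final reported models; examples and tests
  use smaller B where only the machinery is being exercised.

## Structure discovery

The data-driven recipe is: estimate factor counts by the Kaiser rule
(eigenvalues strictly greater than 1) on the residualised correlation
matrix; split the sample into halves matched on sex and the per-measure
missingness signature (stratified shuffling with alternate assignment,
strata below 4 members pooled); fit two-block exploratory factor models
(ML extraction per block, varimax or oblimin rotation) on half A; keep
loadings with $|\lambda| > 0.1$ (strictly — a loading of exactly 0.1 is
dropped) to form candidate confirmatory specifications; confirm on half
B, selecting between the rotations' specifications by lowest RMSEA with
ties broken by higher CFI; refit the winner on the full sample.
Standardised loadings and factor correlations above 0.3 (strictly) are
flagged as meaningful in the interpretation table.

Design points that were genuinely open and how they were settled:

* The factor-count rule is applied **per block** (predictor block,
  outcome block), because the two-block exploratory model needs a count
  for each side; the overall Kaiser count on the joint matrix is logged
  for comparison. On the reference structure both routes agree (1 + 2 =
  3 overall).
* Cross-block loadings are fixed to zero; the blocks communicate only
  through factor correlations, matching the predictor/outcome separation
  of the exploratory model. Inter-block factor correlations during EFA
  are estimated from Thomson regression-score coefficients applied to
  the joint correlation matrix — they inform interpretation only, since
  the confirmatory step frees all factor correlations anyway.
* The oblimin (quartimin) rotation is computed by the standard oblique
  gradient-projection algorithm; varimax comes from `stats`.
* Composite measures (e.g. a pragmatic total score built from subscales
  already in the model) are excluded up front via the measure metadata,
  avoiding collinearity; predictors whose best incremental R² across
  outcomes is below 1% are dropped before multivariate modelling
  (boundary inclusive: exactly 1% is retained).

## Association screening and multiple testing

Incremental R² compares nested linear models on the complete cases of
each pair, with the ANOVA F-test for the p-value; ordinal predictors
enter as integer-coded linear terms, consistent with their reverse-coded
ordered semantics. Confounder-score adjustment adds the score to *both*
models. For ordinal outcomes, proportional-odds models (cumulative
logit, `MASS::polr`; the two-category special case falls back to
ordinary logistic regression, to which the model collapses) yield the
incremental Nagelkerke R²

$$R^2_N = \frac{1 - \exp\{(2/n)(LL_0 - LL_1)\}}{1 - \exp\{(2/n) LL_0\}},$$

computed for the covariate-only and covariate-plus-score models against
the shared intercept-only $LL_0$, with the increment tested by a 1-df
likelihood ratio.

Multiplicity is handled two ways, mirroring the two thresholds in use:
plain Bonferroni over the literal test count for the phenotypic screen
(0.05/154 for an 11 × 14 grid), and Bonferroni over the effective number
of independent phenotypes for the PGS stage. `meff_spectral` implements
Li–Ji ($\sum_i [\,\mathbb{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)\,]$) and Nyholt ($1 + (M-1)(1 -
\mathrm{Var}(\lambda)/M)$); eigenvalues are clamped at zero and rounded
at the tenth decimal so that numerically negative zeros cannot corrupt
the floor term. The integer used for thresholding is the ceiling of the
raw value — the conservative direction — with the raw value always
reported. The analytic power of a 1-df score test uses the noncentral
$\chi^2$ with NCP $= n r^2/(1-r^2)$; it describes target-sample power
only and makes no claim about discovery-sample noise.

## Polygenic scoring and GWAS-by-subtraction

Scoring is the standard weighted dosage sum over the harmonised SNP
overlap, with missing dosages imputed to twice the allele frequency and
optional Z-standardisation (a zero-variance raw score is an error, not a
silent constant). Harmonisation intersects on SNP id, sign-flips
effects where the allele pair is swapped, and removes strand-ambiguous
(A/T, C/G) and irreconcilable SNPs, logging every removal. Shrinkage
re-estimation of weights (PRS-CS and kin) is deliberately not
reimplemented: the pipeline consumes pre-shrunk weight files, and the
synthetic generator produces plain Gaussian weights in the same layout.

GWAS-by-subtraction takes the 2×2 genetic covariance of the confounder
and focal traits (an input, normally from LD-score regression, which is
out of scope), Cholesky-factorises it with the confounder first, solves
the per-SNP latent effects, and returns
$\beta_{sub} = \beta_{trait} - (\lambda_{21}/\lambda_{11})\,
\beta_{conf}$ — computed in that algebraically equivalent form so that a
diagonal genetic covariance reproduces the focal betas bit for bit — with
delta-method SEs assuming independent input errors. The effective sample
size of the subtracted statistics uses the standardised-trait estimator
$\tilde N_j = 1/(2 p_j (1-p_j)\, se_j^2)$ averaged over SNPs with MAF
between 10% and 40%, a window where the approximation is stable; the
window is configurable.

## The mediation decomposition

`build_mediation_spec` grafts the standardised score onto a confirmed
factor model: free paths $a$ (score → predictor factor) and $b_k$
(score → outcome factor $k$), directed paths $c_k$ replacing the
predictor–outcome factor correlations, outcome disturbances left freely
correlated, measurement model untouched. Because the score is exogenous
and disturbances are mutually uncorrelated with it, path tracing gives
the exact identity, on the standardised scale,

$$\mathrm{cor}(F_{pred}, F_k) = a\,b_k + c_k,$$

so `total_k` is not an approximation but the model-implied factor
correlation; the tests assert the identity to numerical precision.
Directionality follows the temporal order — preschool factor to
school-age factors, never reverse. After fitting, the measurement part
is compared loading-by-loading with a score-free refit of the same
structure and flagged if any loading moves by more than two standard
errors. A sensitivity rerun with a confounder-subtracted score is a
config switch that swaps the score column and nothing else.

## What the synthetic cohort does and does not emulate

The generator draws factor scores from the configured correlation matrix
(optionally partly driven by a supplied score through per-factor paths,
with the residual factor covariance adjusted to keep unit variances),
builds each measure as loading × factor + covariate effects + scaled
Gaussian residual, thresholds ordinal items at the latent quantiles of
the published category frequencies, and masks values completely at
random to reproduce published per-measure Ns. Defaults are the study
conditions: the three-factor standardised parameterisation (loadings
0.55/0.74/0.54, 0.61/0.64/0.20, 0.55/0.59/0.40; correlations
0.31/0.42/0.56), N = 5873 for the reference model, category counts such
as 403/1003/4562 for clapping at five, score effects calibrated to
incremental R² near 0.008 (inside the reported 0.004–0.011 range), and a
genetic covariance of [[0.12, 0.02], [0.02, 0.05]] for the
summary-statistic pair. Covariate effects default to zero — the analysis
residualises them out, so nonzero values exist only to exercise the
adjustment machinery.

Deliberately not emulated: linkage disequilibrium (genotypes are in
linkage equilibrium; scoring is LD-agnostic given weights), population
structure and relatedness, imputation uncertainty, and the monotone
attrition of real cohorts — missingness is MCAR because no attrition
mechanism is published. Passing tests therefore demonstrate that the
estimators recover what they target under the assumed generating model;
they cannot certify behaviour under informative missingness, LD, or
ordinal-threshold misspecification beyond the attenuation noted above.

## Problem sizes used in the test suite

The simulate-and-refit and mediation experiments run at the reference
N = 5873; end-to-end discovery robustness uses ten seeds at that N; the
null-calibration check uses 1000 replicates at n = 300; pipeline smoke
tests run cohorts of 600–2000 with 500 SNPs and a 5000-SNP
summary-statistic pair. These sizes make every property statistically
meaningful while keeping a full run of the suite in the low minutes on a
single core.

## Known limitations

* Normal-theory ML on integer-coded 3-category items attenuates loadings
  relative to a threshold model; comparisons against generating values in
  the tests therefore use continuous simulations, and ordinal runs are
  exercised for robustness, not parameter equality.
* Listwise completeness per model; full-information ML is not
  implemented.
* The mediation p-values are two-sided normal approximations on
  standardised estimates; for products of coefficients near zero the
  bootstrap option is the safer inferential route.
* `effective_n` implements one defensible estimator of effective GWAS
  sample size; published effective-N figures derived by other recipes
  will not be reproduced exactly.
* The Kaiser rule is the implemented factor-count criterion; parallel
  analysis and scree alternatives are out of scope, though the full
  eigenvalue spectrum is always returned for inspection.
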