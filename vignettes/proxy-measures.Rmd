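---
title: "Building and validating proxy measures of age, fluid intelligence, and neuroticism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating proxy measures of age, fluid intelligence, and neuroticism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainproxy)
```

## The problem

Population studies of mental health rarely have the resources to administer
full psychometric batteries. `brainproxy` implements a pipeline that builds
*proxy measures* — machine-learning approximations of age, fluid intelligence
(a 13-item score, 0–13), and neuroticism (the 12-item EPQ-N score, 0–12) —
from general-purpose inputs: image-derived phenotypes (157 structural and
432 diffusion features), functional-connectivity features derived from
multivariate component time series, and 86 sociodemographic variables
organized in five blocks (mood/sentiment MS, age/sex AS, lifestyle LS,
education EDU, early-life EL). It then validates the proxies out of sample
against health-related habits (a compound weekly drinking score, MET minutes
of physical activity, pack-years of smoking, sleep hours).

Because the cohorts such pipelines are developed on are controlled-access,
the package ships a synthetic-cohort generator with recorded ground truth.
The generator is first-class, tested code: every downstream claim the test
suite makes is a recovery statement about structure the generator is known
to contain.

## Pipeline anatomy

1. **Split first.** Subjects are partitioned once by a randomized split-half
   into a *validation* set (model construction) and a *generalization* set
   (statistical analysis), strictly non-overlapping. The validation set is
   subdivided into Monte-Carlo train/test splits (shuffle-split, 10% test;
   100 splits at full fidelity). The same splits are reused by every model so
   paired comparisons are meaningful.
2. **Features.** Missing sociodemographic values are imputed by column
   medians *fitted on validation rows only*, with binary indicators appended
   for columns that had missing values in the fitting split. Per-subject
   covariance matrices of the component time series are estimated with
   Ledoit-Wolf shrinkage (symmetric positive definite even when the series
   is shorter than the component count, from three time points on) and
   embedded in tangent space at the affine-invariant geometric mean of the
   *validation* covariances; the strictly lower triangle gives
   $p(p-1)/2$ connectivity features (1,485 for 55 components).
3. **Models.** Random-forest regression (mean-squared-error impurity, 250
   trees at full fidelity) with nested 5-fold grid search over maximum depth
   {5, 10, 20, 40, unrestricted} and features-per-split {1, 5, log2, sqrt,
   all}. Out-of-sample predictions for generalization subjects are averaged
   across all split models (*CV-bagging*), giving one prediction per
   subject. For classification, targets are discretized into extreme groups
   at the 33rd/66th percentiles (middle tercile discarded) and ranking
   accuracy is measured by ROC AUC.
4. **Proxies and deconfounding.** The brain age $\Delta$ is predicted minus
   chronological age. Because prediction residuals retain age-related
   variance, each habit is residualized against age through a quadratic OLS
   fit *on validation data*; evaluating that polynomial on generalization
   ages yields a *deconfounder* covariate. The same fit/apply pair serves
   the proxy-specific variants (substituting fluid intelligence or
   neuroticism for age).
5. **Inference.** Habit regressions standardize outcome and predictors on
   the exact complete-case rows and fit OLS. Model forms: the deconfounder
   plus the three proxies (with $\Delta$ or with predicted age), the variant
   with proxy-specific deconfounders, the joint proxy-plus-target model, and
   single-proxy marginals. Uncertainty comes from a parametric bootstrap
   (the Gelman–Hill "sim" procedure: scaled inverse-chi-square draw of the
   residual scale, then multivariate-normal coefficient draws), reported as
   percentile 2.5/97.5 intervals. Model performance is tested by permutation
   baselines, non-parametric bootstrap intervals, and paired swap tests;
   multicollinearity is monitored with variance inflation factors.

## What the generator emulates — and what it does not

Targets are drawn first: age from a truncated normal (mean 55, SD 7.5,
range 40–70), and the two integer scores by quantile-binning latent
Gaussians into 14 and 13 levels — this preserves rank signal while matching
the documented score ranges. Each feature block mixes a shared within-block
latent factor (loading 0.7), per-target signal in standardized units, and
unit Gaussian noise, so within-block correlations exceed between-block ones
as in the real data's block structure. Component-series covariances
interpolate in log-eigenvalue space between a shared base SPD matrix and a
target-modulated direction, which keeps every subject covariance SPD by
construction. Habits are affine transforms of linear combinations of the
*z-scored observed targets* plus noise, so configured effects are directly
comparable to the standardized coefficients estimated downstream; the
drinking habit is decomposed into six alcohol-family columns whose row sum
reproduces it exactly. Missingness can be completely at random or driven by
a logistic function of a lifestyle column (the driver itself is never
masked, and targets are never masked).

The generator does *not* attempt realistic marginal distributions (habits
can take negative values), selection bias, non-linear target-feature links,
or raw-image artifacts. Passing recovery tests therefore demonstrates that
the pipeline's estimators and guards behave correctly under the structural
assumptions the analysis makes — not that any particular real-world effect
size is reproducible.

An important consequence of the block structure: because a feature column
can carry signal from several targets at once, the age prediction partially
loads on fluid intelligence and neuroticism, and the brain-age $\Delta$
inherits part of any habit effect operating through those targets. The
recovery suite therefore asserts generative *signs* on the deconfounder and
the two cognitive/affective proxies, and asserts near-zero coefficients
only in the arm where all habit effects are switched off.

## Numerical choices

* Ledoit-Wolf shrinkage follows the published formula with the $1/T$
  covariance normalization; at $T = 2$ the estimated optimal intensity is
  exactly zero (centering makes the two observations collinear), so the
  SPD-under-$T<p$ guarantee starts at $T = 3$.
* The tangent reference is the affine-invariant geometric mean, computed by
  fixed-point iteration from the arithmetic-mean initialization, tolerance
  $10^{-6}$ on the Frobenius norm of the mean whitened logarithm, at most
  200 iterations. Off-diagonal entries are not $\sqrt{2}$-rescaled and the
  diagonal is discarded: the downstream forest is invariant to per-feature
  monotone scaling, and the connectivity width is then exactly
  $p(p-1)/2$.
* Vectorization order is row-major over the strictly lower triangle:
  (2,1), (3,1), (3,2), (4,1), …
* The grid labels "1" and "5" are absolute feature counts; "all" uses every
  feature. Inner model selection minimizes squared error for regression and
  maximizes AUC for classification. Ties in the grid resolve to the first
  listed setting, deterministically.
* Extreme-group boundaries are inclusive on both sides (≤ P33 low, ≥ P66
  high), so ties at a boundary value fall into the corresponding extreme
  group.
* The quadratic deconfounder includes an intercept (the textbook quadratic
  without one is a biased residualizer) and centers the confounder before
  squaring to decorrelate the linear and quadratic terms; the centering
  constant is stored with the model so either convention is reproducible.
* Monte-Carlo p-values use add-one smoothing, $p = (1 + \#\{s_0 \ge s\}) /
  (B + 1)$, so the attainable minimum is $1/(B+1)$ and calibration under
  the null is within binomial tolerance of nominal. The swap test swaps
  each subject's pair independently with probability ½, matching a
  per-data-point randomization, and its paired bootstrap reuses one index
  stream for both models.
* Standardization uses the $n-1$ denominator, computed on the exact rows
  entering each regression.
* One global seed spawns independent per-stage child seeds, so any stage
  can be replayed in isolation.

## Problem sizes

Two execution profiles are built in. The `paper` profile carries the
full-fidelity settings (100 Monte-Carlo splits, 250 trees, the complete
5×5 grid, 10,000 permutations/bootstrap resamples/coefficient draws). The
`test` profile is the package's desk-scale default used throughout the test
suite and the acceptance script: 20 splits, 100 trees, a reduced grid
(depth 10 vs unrestricted at sqrt features-per-split), 200–1,000 resamples,
and cohorts of 1,000–2,000 subjects with reduced imaging blocks (20 sMRI,
20 dMRI, 10 components → 45 connectivity features). The recovery cohort
uses habit effects (0.3, −0.2, 0.1) on (age, fluid intelligence,
neuroticism) for the drinking score. Learning-curve checks plateau well
below these sizes for the strong-signal synthetic targets, so the reduced
profile loses calibration resolution, not qualitative behavior.

## A worked example

```{r example, eval = FALSE}
cfg <- generative_config(
  n_subjects = 2000, seed = 101,
  block_sizes = c(MS = 10, AS = 3, LS = 10, EDU = 2, EL = 5,
                  sMRI = 20, dMRI = 20),
  n_components = 10, series_length = 60)

pc <- pipeline_config(outdir = "bp-out", generative = cfg, seed = 202,
                      profile = "test")
res <- run_pipeline(pc)
res$state$report$scores
res$state$report$habit_coefficients
```

The report lists, per target, the mean cross-validated $R^2$ on the
validation half and the CV-bagged $R^2$ on the held-out half (these agree
within sampling noise — no cross-validation bias), and one
percentile-interval row per habit and proxy coefficient.

## Known limitations

* The forest backend is `ranger`; the nested tuning loop is the package's
  own, because maximum depth is part of the documented grid.
* Deconfounders are quadratic in the confounder; alternative brain-age bias
  corrections (e.g. slope rescaling) are out of scope.
* No multiple-testing correction is applied across habits; intervals are
  per-model, as reported.
* The Gaussian-copula-like feature marginals are a stand-in, not an
  inference about any real cohort's distributions.
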