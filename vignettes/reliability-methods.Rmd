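---
title: "Methods: reliability and longitudinal inference for dense task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliability and longitudinal inference for dense task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldReliability)
```

This vignette records the statistical methods implemented by
`boldReliability`, the defaults of the synthetic-data generator, and the
approximations the package makes. The reference design throughout is 30
participants measured in 10 roughly monthly sessions.

## 1. The three-level measurement model

For voxel $i$, participant $j$, session $k$, a contrast value is modeled as

$$y_{ijk} = \beta_0 + b_k + \lambda_j + \pi_{jk} + \varepsilon_{ijk},$$

with session fixed effects $b_k$, participant effects
$\lambda_j \sim N(0, \sigma^2_\lambda)$, participant-session effects
$\pi_{jk} \sim N(0, \sigma^2_\pi)$, and voxel noise
$\varepsilon_{ijk} \sim N(0, \sigma^2_\varepsilon)$. Three reliability
quantities follow:

- **Internal consistency** (voxels within one participant-session):
  $\mathrm{ICC}_{\text{within}} = \sigma^2_\pi / (\sigma^2_\lambda +
  \sigma^2_\pi + \sigma^2_\varepsilon)$, estimated by `fitInternalConsistency`
  from the three-level REML or MCMC fit.
- **Test-retest reliability** for a session pair, on parcel means:
  a two-level model with session fixed effects gives
  $\mathrm{ICC}(3,1) = \sigma^2_b / (\sigma^2_b + \sigma^2_w)$
  (`estimatePairICC`). Averaging $V$ voxels shrinks the within term: on
  parcel means the between variance is $\sigma^2_\lambda$ and the residual
  is $\sigma^2_\pi + \sigma^2_\varepsilon / V$, which is why a contrast can
  be internally consistent yet rank participants unstably.
- **Multilevel alpha** for $k$ indicators:
  $\alpha(k) = \sigma^2_\pi / (\sigma^2_\lambda + \sigma^2_\pi +
  \sigma^2_\varepsilon / k)$ (`multilevelAlpha`), monotone in $k$ and equal
  to $\mathrm{ICC}_{\text{within}}$ at $k = 1$. `iccOneway` supplies the
  one-way ANOVA ICC(1,1) with the usual $n_0$ correction for unbalanced
  groups.

## 2. Meta-analytic pooling of pairwise ICCs

Adjacent-session ICC estimates are pooled on the logit scale with a
normal-normal model, $\mathrm{logit}(\rho_s) \sim N(\mu, \sigma^2)$,
sampled with JAGS (`poolICCMeta`). Draws are clamped away from 0/1 by
$10^{-6}$ before the logit. With `fixedSigma = TRUE` the heterogeneity is
pinned at zero and the posterior reproduces the inverse-variance
fixed-effect closed form (verified against `metafor::rma(method = "FE")` in
the test suite). Overlapping adjacent pairs share sessions; the pooled
interval is therefore interpreted descriptively. A disjoint-pair option
removes the overlap.

## 3. Longitudinal within-person inference

Predictors are decomposed exactly into person means (relative to the grand
mean) and person-mean deviations (`centerWithinBetween`); on balanced
panels the two components are orthogonal. The outcome model is a
random-intercept GLS fit,

$$y_{jk} = \beta_0 + \beta_t\,\mathrm{time} + \beta_b x^{(b)}_j +
\beta_w x^{(w)}_{jk} + \lambda_j + e_{jk},$$

with inference by the CR2 small-sample cluster-robust sandwich (clustered
by participant) and Satterthwaite degrees of freedom computed from the
cluster-level covariance of the half-statistics; both are verified to
agree with a dense reference implementation to 8 decimals. Two-sided
$t(\nu)$ p-values are converted to signed Z statistics.

**Freedman-Lane permutation.** The outcome is residualized on the nuisance
design (intercept, time, between-person component) under the same
random-intercept structure; the *fixed-effect* fitted values are kept and
the residuals are permuted only within participants (nested exchangeability
blocks), reconstructed, and refit through the identical CR2/Satterthwaite
pipeline. The identity permutation is always the first row, so the observed
statistic belongs to its own null set and permutation p-values cannot be
zero. Voxel-wise application uses a profiled-REML engine on a fixed grid of
intracluster variance ratios with per-grid-point precomputation; its Z
statistics match the single-outcome fit.

**Cluster familywise error.** $|Z|$ maps are thresholded at the two-sided
cluster-forming level (default $p = .01$), 6-connectivity components are
formed within the mask, and the null distribution of the maximum cluster
extent over permutations calibrates the critical extent (type-1 quantile;
observed clusters survive only when strictly larger). This is a simplified
max-extent stand-in for multi-threshold cluster methods; it preserves the
permutation FWE contract, which the acceptance suite verifies empirically
on a masked $24^3$ grid.

**Sign-error selection.** Given per-parcel posterior probabilities of
correct effect sign $p_s$, parcels are sorted descending (ties broken by
parcel id) and selected while the running product stays at or above
$1 - \text{budget}$. The joint probability of any sign error among the
selected parcels is therefore bounded by the budget, by construction. With
probabilities $(1.0, .99, .98, .97)$ and a 5% budget, exactly three
parcels are selected and the combined error is 2.98%.

**Power.** `estimatePower` simulates standardized outcomes with intercept
variance share $\tau^2 = 0.07$ and a standardized within-person slope,
fitting the full robust pipeline per replicate. At effect 0.17 under the
30 × 10 design the empirical power is approximately 0.80.

## 4. Internal consistency as a function of parcel properties

Parcel-level consistency estimates are modeled with a logit-link beta
regression (maximum likelihood via `mgcv::gam` with the `betar` family).
The *constrained* specification has anatomy-class intercepts and one linear
parcel-size slope; the *unconstrained* specification adds per-class
B-spline terms (fixed df) in parcel size and residual smoothness. Models
are compared by leave-one-out ELPD: exact case-deletion refits for
moderate n, otherwise importance sampling from the Laplace approximation
of the coefficient posterior. Decisions use the two-SE rule: the models are
declared non-equivalent only when $|\Delta \mathrm{ELPD}| > 2\,\mathrm{SE}$,
and the constrained model is retained otherwise. Exact LOO punishes the
heavily parameterized unconstrained model more severely than importance
sampling on small datasets; this is expected estimator behavior, not a
discrepancy. Spline boundary knots are pinned to the full-data range
(widened by a relative $10^{-6}$) so case-deletion refits never rebuild the
basis on a shrunken range.

## 5. Residual smoothness

`estimateFWHM` uses the classical variance-ratio estimator: along each
axis, $\rho_a = \mathrm{Var}(\Delta_a y) / (2 \mathrm{Var}(y))$ and
$\mathrm{FWHM}_a = \Delta_a \sqrt{-2 \ln 2 / \ln(1 - \rho_a)}$, combined
across axes by the geometric mean and scaled by voxel size. `smoothVolume`
applies a separable truncated-Gaussian kernel with edge renormalization.
Recovery is within ±10% at kernel widths of 2, 4, and 6 voxels.

## 6. Generator defaults and their rationale

The synthetic-data defaults *are* the study conditions, not tuning knobs:

- variance components $\sigma^2_\lambda = 0.07$, $\sigma^2_\pi = 0.44$,
  $\sigma^2_\varepsilon = 0.49$ — a regime with low test-retest reliability
  and substantial internal consistency;
- predictor variance split 0.44 between / 0.56 within, standardized scale;
- within-person effect 0.17, time trend −0.05 per session;
- 36 parcels (12 cortical, 12 subcortical, 12 control) with sizes varying
  deterministically around the nominal voxel count so parcel size is an
  identifiable covariate;
- stress severities on the 1–5 half-point grid; sleep aggregated over
  19:00→19:00 windows for the 14 pre-scan days, requiring at least 7
  observed windows.

## 7. Limitations

- The cluster correction is max-extent only; multi-threshold cluster
  enhancement is out of scope.
- Pooling of overlapping adjacent pairs ignores their shared-session
  dependence.
- The permutation pipeline assumes the same CR2/Satterthwaite statistic for
  observed and permuted fits (exchangeability of the full pipeline).
- The beta-regression comparison reports equivalence, not effect absence;
  retaining the constrained model is a parsimony decision.
- MVPA/multivariate reliability is not implemented.
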