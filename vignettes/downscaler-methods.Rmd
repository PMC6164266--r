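---
title: "Methods: regional Bayesian downscaling of satellite AOD to daily PM2.5"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional Bayesian downscaling of satellite AOD to daily PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(downscaler)
```

## The problem

Ground monitors measure PM2.5 (particulate matter with aerodynamic
diameter below 2.5 micrometres, in ug/m3) accurately but sparsely: they
are concentrated in cities and many operate only every third or sixth
day.  Satellite aerosol optical depth (AOD) — a unitless column-integrated
extinction measure — is available on a regular grid (here a 12-km grid)
nearly everywhere, but it is an indirect proxy, its relationship with
ground PM2.5 varies in space and time, and retrievals are missing
wherever cloud or snow blocks the view (observed coverage of daily AOD
is roughly 12–30% of cell-days).  The downscaling problem is to
calibrate the gridded AOD and ancillary covariates (meteorology, land
use, emissions) against the point-referenced monitor data, and then
predict daily concentration surfaces with honest uncertainty on the full
grid.

The `downscaler` package implements a regional hierarchical Bayesian
model of this calibration, predicts posterior surfaces, blends
overlapping regional models into a seamless surface, and evaluates
predictions by random and spatially blocked cross-validation.  A
synthetic-data generator with known ground truth supports all testing.

## The model

Within one region and temporal block, for monitor location $s$ and day
$t$:

$$PM(s,t) = \alpha_0(s,t) + \alpha_1(s,t)\,AOD(s,t) +
  Z(s,t)'\gamma + \varepsilon(s,t), \qquad
  \varepsilon \sim N(0, \sigma^2),$$

with additive space and time decompositions
$\alpha_i(s,t) = \mu_i + \beta_i(s) + \beta_i(t)$, $i = 0, 1$.  The
spatially varying intercept and slope are built from two independent
latent unit-variance Gaussian processes through a linear model of
coregionalization (LMC):

$$\beta_0(s) = c_1 W_1(s), \qquad
  \beta_1(s) = c_2 W_1(s) + c_3 W_2(s),$$

so the intercept and slope surfaces are correlated through the shared
process $W_1$, with amplitudes carried by $c_1, c_2, c_3$.  Each $W_i$
has correlation given by an exponential kernel with range $\phi_i$
multiplied by a compactly supported taper, so correlation is exactly
zero beyond the taper radius and the matrices are sparse-structured.
The daily series $\beta_0(t), \beta_1(t)$ are independent first-order
random walks (RW1): an intrinsic Gaussian prior that penalises squared
day-to-day increments with precision $\tau_i$, smooths across days with
no observations, and is constrained to sum to zero over the block.
$Z(s,t)$ collects the transformed ancillary covariates; an
AOD-by-temperature interaction can be included as one of its columns.

Monitors are points inside grid cells; each record is paired with the
AOD and covariates of the cell containing the monitor (half-open cell
footprints make edge assignment deterministic).  Records whose cell has
no AOD retrieval that day are dropped from the likelihood, not imputed,
and counted.

### Covariate transforms

Count-like covariates (fire, emissions, road length) are
log-transformed with offset 1 to absorb zeros; all covariates except
PM2.5 and AOD are then z-standardised using means and SDs fitted on the
training records and stored, so prediction and held-out data are scaled
identically.  The transforms round trip to floating-point accuracy
(`invert_transforms`).

## Priors and the sampler

The model is fit by a systematic-scan Gibbs sampler (order: fixed
effects, latent processes, coregionalization, daily series, variances,
ranges).  Every block is conjugate:

* $\gamma$ (including $\mu_0$, $\mu_1$) and $c$: multivariate normal
  full conditionals under independent $N(0, 100^2)$ priors;
* $(W_1, W_2)$ at the monitor sites: one joint multivariate normal
  draw whose likelihood loadings per record are $(c_1 + c_2 AOD)$ on
  $W_1$ and $c_3 AOD$ on $W_2$;
* $\beta_i(t)$: Gaussian draws on the sum-to-zero subspace with
  tridiagonal-prior plus diagonal-likelihood precision;
* $\sigma^2$: inverse-gamma (prior IG(0.001, 0.001));
* $\tau_i$: gamma with shape increment $(T-1)/2$, the rank of the
  intrinsic RW1 (prior Gamma(0.5, 5e-4));
* $\phi_i$: a discrete ("griddy") Gibbs draw over a log-spaced
  candidate grid spanning 10–400 km, with each candidate's correlation
  Cholesky, inverse and log-determinant precomputed once per chain.

These prior constants are the package's documented defaults, chosen as
weakly informative standards for downscaler-type models; the grid prior
on the range avoids tuning a Metropolis step and allows factorisation
reuse.

### Identifiability

Two choices here were genuinely open:

* **Sign of the LMC.**  The likelihood is invariant under jointly
  flipping $(W_1, c_1, c_2)$.  The sampler reflects after each $c$ draw
  so that $c_1 \ge 0$; the reflection preserves the (symmetric)
  posterior and leaves all sign-invariant quantities untouched.
* **Levels.**  The global intercept is confounded with the level of
  $c_1 W_1$ and of $\beta_0(t)$.  The daily series are sampled directly
  on the sum-to-zero subspace (an orthonormal basis of the complement
  of the constant vector), which is exact, keeps one code path when a
  block has unobserved days, and makes the intrinsic prior proper on
  its domain.  For the latent processes we deliberately do *not*
  recenter: the proper unit-variance process prior already pins their
  level softly.  An earlier recenter-and-shift variant (moving the
  process mean into $\mu_0, \mu_1$ each iteration) was rejected because
  a Geweke-style successive-conditional simulation showed it is not an
  invariant move under a proper process prior — it visibly inflated the
  marginal variance of the fixed effects.  With the final sampler the
  same Geweke check preserves the prior of $\gamma$ exactly (it runs in
  the test suite at 5,000 iterations on a small instance).

### Numerical choices

A jitter of 1e-8 is added to correlation diagonals before Cholesky
factorisation (near-coincident sites).  The taper family is Wendland-1,
$(1-d/T)^2(1+d/(2T))$ for $d < T$, a valid compactly supported
correlation in the plane whose product with the exponential stays
positive definite; a spherical taper is available by configuration.  The
default taper radius of 400 km is the upper end of the typical mesoscale
variability range of lower-tropospheric aerosol (about 40–400 km).
Marginal process variance is fixed at 1, with scale carried by the $c$
coefficients, for LMC identifiability.  Chain defaults are 5,000
iterations, 2,500 burn-in, thinning 5.

## Prediction, blending, aggregation

For each retained posterior state, the latent processes are kriged from
the monitor sites to cell centroids (simple kriging under that state's
range, with conditional-covariance draws, reusing one factorisation per
unique range), the model mean is composed from the cell's AOD and
covariates, and a residual draw is added.  Intervals are therefore
*predictive* by default; mean-surface intervals are available with
`include_resid = FALSE`.  Cell-days without AOD are not predicted.

Regions are fitted independently on buffered monitor sets (default
buffer 100 km).  Where several buffered regional models claim a cell,
their posterior draws are pooled with equal weight before summarising —
this both averages the overlapping predictions into a seamless surface
and propagates every contributor's uncertainty.  Distance weighting was
considered and rejected: equal-weight draw pooling is the simplest rule
consistent with averaging overlapping predictions, and keeps the pooled
sample a genuine posterior-predictive mixture.

Period aggregates (seasonal or annual means) are computed per posterior
draw over each cell's predicted days, then summarised across draws, so
the period-mean SD correctly reflects within-draw averaging.

## Cross-validation

Random 10-fold CV partitions records uniformly; spatial 10-fold CV
clusters sites by k-means on their coordinates (best of 10 seeded
restarts) and holds out whole monitor locations, measuring
extrapolation to unmonitored places.  Each fold refits the model
(including the covariate scaling — the linear model absorbs that affine
change, so predictions are unaffected by the refit-versus-reuse choice)
and predicts held-out records from the posterior predictive
distribution.  A held-out site beyond the taper range of all training
sites receives a fresh latent draw: prediction from the fixed and
temporal effects with full latent uncertainty, which is the model's
honest answer rather than an error.  Metrics follow the standard CV
calibration convention: least squares of observed on predicted
(intercept, slope, $R^2$), RMSE, mean 90% predictive-interval length and
its empirical coverage.

## The synthetic-data generator

`simulate_dataset` emulates exactly the structure the model assumes:
monitors scattered uniformly over a regular grid (spatial misalignment),
latent fields drawn jointly at sites and centroids from the
tapered-exponential process, sum-to-zero RW1 daily series, log-normal
AOD on the descriptive scale of real retrievals (mean about 0.14, SD
about 0.15), Bernoulli AOD missingness at 20% coverage by default (the
middle of the observed 12–30% range), strictly positive unimodal
covariates, and Gaussian residual noise.  Default effect sizes are on
the scale of a regional PM2.5 model: baseline near 10 ug/m3, AOD slope
15, covariate effects of order one, residual SD 2 ug/m3, spatial
amplitude around 2 ug/m3 for the intercept surface, range 50 km.  The
generator composes the true mean using the same log/z transform
pipeline the fitting path applies (scaling fitted on the records that
carry observed AOD), so fitted fixed effects are directly comparable to
the generating values.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: true retrieval-error structure in AOD,
correlated covariate fields, seasonally varying coverage, non-Gaussian
residuals, and monitor siting bias toward cities.  Recovery and
calibration results on synthetic data demonstrate the implementation is
correct and internally calibrated, not that the model is adequate for
any particular real dataset.

## Study sizes used in the checks

The test suite and acceptance script use desk-scale problem sizes,
chosen once: density-ratio identities on a 10-site, 5-day instance;
conjugate-oracle equivalence at about 200 records and 20,000 draws;
parameter recovery over 20 replicates of 60 sites and 40 days with four
covariates at 5,000 iterations; predictive calibration on about 2,000
held-out records (100 sites, 105 days, 10 folds); and the
random-versus-spatial ordering over 20 replicates of 40 sites and 20
days with strengthened spatial amplitude ($c = (3, 6, 3)$, AOD coverage
0.5 so each replicate has enough records at the small scale).  In the
recovery study the 90% intervals for the fixed effects achieve nominal
coverage; the coregionalization amplitudes ($c_1$ especially) are only
weakly identified at 60 sites and show under-coverage — a known
property of LMC amplitude parameters at small spatial sample sizes, not
a sampler defect (the density-ratio and Geweke checks cover those
blocks exactly).

## Limitations

Single study year, three 4-month blocks, no extrapolation outside a
fitted block; no gap-filling of missing AOD; equirectangular planar
coordinates (adequate to regional extents of ~2,000 km; great-circle
distances are available in `project_lonlat`'s alternative); dense
factorisations internally (fine to a few hundred sites per region);
no multi-chain convergence diagnostics beyond trace extraction.
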