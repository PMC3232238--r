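---
title: "Methods: hierarchical spatial trend models for zone-structured counts"
author: "zonetrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical spatial trend models for zone-structured counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonetrend)
```

## The problem

Monitoring programs for restoration sites often inherit strong spatial
structure from past land use: roads and ditches partition a site into
subpopulations ("zones") with different histories, topography drives
within-zone density gradients, and limited dispersal produces residual
spatial autocorrelation at scales of tens to hundreds of metres. A single
pooled trend estimate over such a site can be misleading, and ignoring
the spatial correlation misstates the uncertainty of whatever trend is
reported.

`zonetrend` estimates temporal trend in quadrat density counts collected
under a stratified design — a fixed number of randomly placed plots per
zone per year — with a ladder of Bayesian hierarchical models of
increasing spatial structure, and ships a synthetic-data generator so the
whole pipeline is testable without field data.

## The model ladder

Let $y_{ki} = \log(c_{ki} + 1)$ be the log-scale response for count
$c_{ki}$ of plot-year $i$ in zone $k$, and
$X_k = [1, \mathrm{year}_c, \mathrm{elev}_s]$ the design matrix with year
centered at its mean and elevation standardized. The four rungs are:

* **Model 1 (no pooling).** Independent per-zone regressions of $y$ on
  centered year, diffuse normal priors, per-zone residual variance. No
  site-level trend exists in this model.
* **Model 2.** Zone-specific intercepts and year slopes drawn from common
  hyperparameters, $\beta_k \sim N(\mu_\beta, \mathrm{diag}(\sigma_\beta^2))$,
  independent residuals. Partial pooling shrinks low-information zones
  toward the site mean $\mu_\beta$.
* **Model 3.** Model 2 plus the standardized elevation covariate.
* **Model 4 (fully spatial).** Model 3 plus a zone-specific exponential
  covariance on the residuals:
  $$y_k \sim \mathrm{MVN}\!\left(X_k\beta_k,\;
    \sigma_k^2\exp(-\phi_k D_k) + \tau_k^2 I\right),$$
  with $D_k$ the Euclidean distance matrix over all plot-years in zone
  $k$, partial sill $\sigma_k^2$, decay $\phi_k$ (1/m) and nugget
  $\tau_k^2$. Zone blocks are independent, so the likelihood is additive
  over zones — the stratified-kriging treatment of zonal anisotropy,
  which also keeps each factorization at $n_k \times n_k$ rather than
  $n \times n$.

The latent spatial process is marginalized into the covariance rather
than sampled as a latent vector: the marginal model is identical, and at
these problem sizes the collapsed sampler mixes far better than a
latent-field one. The effective range $\xi_k = -\log(0.05)/\phi_k$ — the
lag at which residual correlation drops to 5% — is reported alongside
$\phi_k$ because it is the interpretable quantity.

### Zero counts and the log response

Counts are zero-heavy with long positive tails; the lognormal response
handles the tails, and zeros enter through the additive offset
$y = \log(c + 1)$. The offset is configurable (`model_config(offset=)`)
and recorded with the fit, since trend estimates at very low densities
are mildly sensitive to it. Exact inversion is `exp(y) - offset`.

### Priors

* Hyper-SDs $\sigma_\beta$: uniform$(0, 100)$.
* Hyper-means $\mu_\beta$: normal$(0, 1000)$ — the conventional diffuse
  choice; the scale matters only through its finiteness here.
* Variances ($\sigma_k^2$, $\tau_k^2$, residual): inverse-gamma$(0.1, 0.1)$.
* Decay $\phi_k$: uniform with *data-driven* bounds
  $\phi_\min = -\log(0.5)/d_\max$ and $\phi_\max = -\log(0.01)/d_\min$,
  i.e. at most 50% correlation at the largest inter-plot distance and at
  least 1% at the smallest positive distance. Diffuse priors on $\phi$
  are notoriously poorly identified; these bounds confine the sampler to
  the distinguishable part of the parameter space. When a degenerate
  layout makes $\phi_\min \ge \phi_\max$ the fit aborts with an
  explanatory error rather than silently reordering the bounds.

Model 1 runs in the same Bayesian machinery with independent diffuse
priors per zone, so ladder comparisons are apples-to-apples.

## Sampler

`zonetrend()` uses Gibbs-within-Metropolis on the marginalized model:

* $\beta_k$, $\mu_\beta$, and (models 1–3) residual variances have
  conjugate conditional draws.
* $\log\sigma_k^2$, $\log\tau_k^2$, $\mathrm{logit}$-rescaled $\phi_k$,
  and $\log\sigma_\beta$ use adaptive scalar random-walk Metropolis,
  with step sizes adapted in batches of 50 toward 44% acceptance and
  frozen after burn-in (so the post-burn-in chain is a fixed Markov
  kernel).
* The Cholesky factor of each zone covariance is cached and recomputed
  only when a covariance-parameter proposal is evaluated; the contract is
  value-identical to naive recomputation.
* A Metropolis block that accepts nothing during burn-in flags the run as
  failed (`fit$failed_blocks`) with a warning.

The default `chain_config()` is the long-run scheme (3 chains, 1000
burn-in, 40,000 iterations thinned by 10, 12,000 retained draws);
desk-scale analyses and all package tests use shorter chains. Runs are
deterministic given the master seed: per-chain seeds are derived from it,
and every generator in the package routes through a seed argument.

## Diagnostics

* **Split-chain Gelman–Rubin $\hat R$** (each chain halved): more
  conservative than the original two-moment version because it also
  detects within-chain drift. The pass threshold defaults to 1.1 and is
  configurable. An autocorrelation-based effective sample size
  accompanies it.
* **Posterior-predictive P-value** from the sum-of-squared-residuals
  discrepancy: for each sampled parameter set, replicate log responses
  are drawn from the marginal model and $D = \sum(y - X\beta)^2$ compared
  between observed and replicated data. The discrepancy deliberately uses
  the marginal mean $X\beta$ (not a latent field), matching the
  marginalized representation; the tag `ss_residual_marginal` is recorded
  in the report. Values near 0.5 indicate adequacy.

## The synthetic-data generator

`sim_camas()` emulates the monitoring design the models assume:

* **Layout.** Simple random plot locations per zone per year. Defaults:
  5 zones as side-by-side 200 m × 1000 m strips (zero-width boundaries —
  functional disconnection is carried entirely by the independent
  covariance blocks), 70 plots per zone per year over 2005–2010, so 350
  plots annually; `reference_design()` gives the single-zone control at
  150 plots per year. Coordinates are continuous uniform draws, so repeat
  coordinates across years never occur.
* **Elevation.** A smooth superposition of sinusoidal "swales" (dominant
  wavelength 120 m plus shorter low-amplitude components), calibrated so
  the site-wide SD is 1 m — the standardization unit used in reporting —
  while total relief never exceeds 15 m.
* **Counts.** Per zone, a latent log-density vector is drawn from the
  model-4 MVN (built with the same centering rules as fitting),
  exponentiated, and discretized. Default generating parameters reflect
  the target system: site-level trend ≈ 0.09/yr on the log scale,
  elevation effect ≈ −0.8 per SD, zone intercepts from ≈ 0 to 3, partial
  sill 1.0 and nugget 0.5 (log scale), and zone decay parameters spanning
  effective ranges from hundreds of metres down to under a metre (a
  no-autocorrelation zone). Sill and nugget are not reported quantities
  anywhere we could anchor to, so they were chosen once as values that
  reproduce the observed zero-heavy, long-tailed count marginals, and are
  not revisited.
* **Discretization.** The model treats log counts as Gaussian, but counts
  are integers. The default front-end draws counts as Poisson with the
  latent density as mean, which preserves zeros and long tails;
  `discretize = "round"` switches to deterministic rounding for
  noise-free checks. The Poisson layer is deliberate, mild
  misspecification — real counts are not exactly lognormal either — and
  its extra variance loads onto the nugget in fits.

What the generator does **not** emulate: real terrain (no LiDAR rasters,
no polygonal zone geometries), observer error, year-to-year environmental
shocks shared across zones, and any cross-zone spatial correlation.
Passing tests therefore demonstrate internal consistency of estimator and
generator under the stated design, not field validity.

## Numerical choices

* Jitter $10^{-8}(\sigma^2 + \tau^2)$ on the covariance diagonal before
  factorization; factorization failure after jitter is an error, never a
  silent fallback.
* `d_min` is the minimum *positive* distance: pooled plot-years cannot
  collide by construction, but user data might, and a zero distance would
  make $\phi_\max$ infinite.
* Semivariograms default to 15 equal-width bins to half the maximum lag
  (standard variogram practice); the robust Hawkins–Cressie estimator is
  the default, the classical one available for oracle comparisons. The
  weighted least-squares fit uses Cressie weights $N(h)/\gamma(h;\theta)^2$
  and flags flat semivariograms (sill ≈ 0) as range-unidentifiable rather
  than returning a spurious decay.
* Credible intervals are equal-tailed 2.5%/97.5% quantiles pooled over
  chains; the effective range is summarized by transforming $\phi$ draws
  draw-wise and then taking quantiles.
* Percent-change reporting uses $(e^\beta - 1)\cdot 100$ with the sign
  carrying the direction, so a coefficient of 0.15 reads as a 16% annual
  increase and −0.85 as a 57% decrease per SD of elevation.

## Design choices that were genuinely open

* **Correlation across years.** All plot-years in a zone share one
  covariance matrix whose correlation depends only on spatial distance —
  stationarity over time, consistent with pooling years when estimating
  semivariograms. The alternative (independent year blocks within zones)
  is defensible; it would shrink each factorization further but discards
  between-year spatial information. We chose the pooled form and note
  that at the default sizes the cost is acceptable.
* **Elevation in model 1.** The no-pooling baseline regresses on year
  only, mirroring the "separate simple regressions" reading; elevation
  enters the ladder at model 3.
* **Reference-site fits** drop the elevation covariate
  (`model_config(m, include_elevation = FALSE)`); with a single zone the
  hierarchy degenerates gracefully (hyper-means track the zone's
  coefficients, hyper-SDs revert to their priors).

## Problem sizes in tests

The test-suite fits use deliberately scaled runs chosen for statistical
adequacy at package-check scale: parameter-recovery uses 20 replicates of
5 zones × 30 plots × 3 years with single chains of 2,400 iterations;
conjugate-subcase and prior-recovery checks use 2 × 1,500–3,000
iterations; shrinkage and posterior-predictive checks use non-spatial
rungs where iterations are cheap. Recovery of the decay parameter is
judged only for zones where the generating effective range lies inside
the realized prior support and well under the zone's distance span —
outside that region $\phi$ is unidentifiable at these sample sizes and
its posterior is dominated by the uniform prior, which is a property of
the design, not a sampler defect (credible-interval coverage of the
trend remains the primary recovery criterion).

## Known limitations

* The exponential kernel is the only covariance model; the
  $\phi$-bound construction is specific to it and must be re-derived for
  other kernels.
* The log-offset response is a pragmatic zero-handling device, not a
  zero-inflation model; sites dominated by structural zeros deserve an
  explicit mixture.
* Scalar random-walk updates for $(\sigma^2, \tau^2, \phi)$ mix slowly
  when the partial sill and nugget are weakly separated; long chains or
  reparameterization are advisable for final inference at full study
  sizes.
* No kriging prediction surfaces and no directional semivariograms are
  provided; the target estimand is the structural trend parameters.
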