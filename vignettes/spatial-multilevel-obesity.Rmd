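---
title: "Bayesian spatial multilevel logistic models for small-area obesity risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian spatial multilevel logistic models for small-area obesity risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bymlogit` fits multilevel logistic regression for a binary health outcome
(obesity, BMI >= 25 kg/m^2) observed on individuals j = 1, ..., n_i nested
in small areas i = 1, ..., N, with spatially structured and unstructured
area random effects on the logit scale:

$$y_{ij} \sim \mathrm{Bernoulli}(p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \lambda_{ij}$$

Four nested variants of the linear predictor are supported:

| variant | linear predictor |
|---------|------------------|
| M1 | $\alpha + v_i$ |
| M2 | $\alpha + X_{ij}'\beta + v_i$ |
| M3 | $\alpha + X_{ij}'\beta + W_i'\gamma + v_i$ |
| M4 | $\alpha + X_{ij}'\beta + W_i'\gamma + u_i + v_i$ |

$X_{ij}$ collects dummy-coded individual covariates (sociodemographics,
health behaviours, health status), $W_i$ dummy-coded area covariates
(tertiles of built-environment metrics, reference T1 so odds ratios are
oriented against the lowest tertile). $v_i \sim N(0, \sigma_v^2)$ is
independent area heterogeneity; $u_i$ follows the intrinsic conditional
autoregressive (CAR) prior

$$u_i \mid u_{k \ne i} \sim
N\!\left(\frac{\sum_k w_{ik} u_k}{w_{i+}},\; \frac{\sigma_u^2}{w_{i+}}\right),$$

where $w_{ik} = 1$ for adjacent areas and $w_{i+}$ is the neighbour count.
M4 is the Besag–York–Mollié convolution. Priors follow the common
vague choices for this model class: $N(0, 10{,}000)$ on the intercept and
all fixed coefficients, and Gamma(1, 0.0005) on each precision
$1/\sigma^2$ (equivalently a log-gamma prior on the log precision); a
sensitivity setting swaps in Gamma(1, 1) via
`model_spec(prior_logprec_rate = 1)`.

Model comparison uses the deviance information criterion
$\mathrm{DIC} = \bar D + p_D$ with $\bar D$ the posterior mean of
$D(\theta) = -2 \log p(y \mid \theta)$ and
$p_D = \bar D - D(\hat\theta)$ at the componentwise posterior mean
$\hat\theta$. The share of residual area-level variation that is spatially
structured is summarized by the spatial fraction
$\mathrm{SF} = \sigma_u^2 / (\sigma_u^2 + \sigma_v^2)$.

## Design choices where the design was open

**Intrinsic CAR identifiability.** The joint CAR density
$\propto \exp(-u'Qu / 2\sigma_u^2)$, with $Q$ the graph Laplacian, is
improper: constants (per connected component) are unpenalized. We impose
the standard resolution — a sum-to-zero constraint on $u$ alongside a
global intercept. The prior's generalized density uses the exponent
$\mathrm{rank}(Q)/2 = (N - c)/2$ ($c$ components) on $\sigma_u^2$, the
correct scaling for variance updates under the constrained prior. Islands
(areas with no neighbours) have an undefined CAR conditional; their $u_i$
is fixed at 0 with a warning, the usual convolution-model convention.

**Conditional DIC.** The deviance is $-2\times$ the Bernoulli
log-likelihood only, conditioned on the random effects, with the plug-in
at the componentwise posterior mean of *all* parameters including $u$ and
$v$. Integrating random effects out of the deviance is a different (also
defensible) estimand; the conditional version matches the plug-in formula
above and is the one implemented.

**SF uses the raw variance parameters.** $\sigma_u^2$ in the intrinsic CAR
is a *conditional* variance; the marginal variance of $u_i$ is
$\sigma_u^2 [Q^+]_{ii}$, which differs by a graph-dependent factor
(`car_covariance()` exposes it). The spatial fraction is nevertheless
computed from the raw $\sigma_u^2, \sigma_v^2$ exactly as its defining
formula states; users comparing against marginal-variance variants should
note the distinction.

**Screening threshold.** The univariate pre-selection stage uses a joint
Wald test per covariate within each gender x age stratum, with default
threshold 0.05 (configurable); no multiple-testing correction is applied,
mirroring common practice for this screening style.

**Tertile ties and weighting.** Cut points are the 33.3rd/66.7th
percentiles (type-7 interpolation) computed over areas (each area counts
once); values exactly at a cut go to the lower tertile. A person-weighted
mode is available for metrics whose tertiles should balance individuals.

**Land-use mix.** LUM is the 3-class entropy index
$-\sum_k p_k \ln p_k / \ln 3$ over domestic/commercial/business floor-area
proportions, the standard walkability formulation bounded in [0, 1]; a
literal "floor area divided by land area" ratio is neither bounded by 1
nor an entropy and is not implemented.

**Distances.** Mean grid distance averages, over the 100 m cell centres of
an area's urbanized land, the planar Euclidean distance to the nearest
destination of a class *anywhere* in the landscape (facility use does not
stop at administrative boundaries); coordinates are assumed projected, so
no geodesic corrections are applied.

## Posterior computation

The sampler (`fit_bym()`) is Metropolis-within-Gibbs:

* adaptive random-walk Metropolis for $\alpha$ and each $\beta_j,
  \gamma_j$ (scales tuned towards ~0.44 acceptance during burn-in, frozen
  afterwards);
* blocked random-walk updates for all $v_i$ simultaneously (their full
  conditionals are mutually independent) and for $u_i$ one graph colour at
  a time (non-adjacent CAR conditionals are mutually independent given the
  rest — a greedy proper colouring makes the block update exact);
* conjugate Gibbs draws for the precisions, whose full conditionals are
  Gamma;
* two extra moves that cure the convolution model's notoriously slow
  mixing: an exact Gibbs draw of $u$ given the sum $b = u + v$ (the
  conditional is Gaussian with precision $Q/\sigma_u^2 + I/\sigma_v^2$),
  and a marginalized Metropolis move on
  $(\log \sigma_u^2, \log \sigma_v^2)$ targeting the Gaussian marginal of
  $b$ in the eigenbasis of $Q$, so the variance partition moves without
  dragging the current $u/v$ split along;
* an exact Gibbs draw along the likelihood-invariant direction
  ($\alpha$ vs. the mean of $v$), plus re-centring of $u$ with the mean
  absorbed into $\alpha$ (leaving $\lambda$ unchanged).

With several graph components the residual per-component means of $u$ are
removed by projection (the classic WinBUGS-style convention); all shipped
default graphs (rook lattices) are connected, where the centring is exact.

Numerical safeguards: $\log(1 + e^\lambda)$ via the split `log1p`
formulation (stable to $|\lambda| \approx 700$), probabilities clipped at
$|\lambda| = 35$ before exponentiation, eigenvalues below
$10^{-10}\lambda_{max}$ treated as the CAR null space.

Defaults are 4 chains of 10,000 iterations (5,000 burn-in, thin 5);
Gelman–Rubin $\hat R$ is reported for all scalar parameters with a warning
above 1.05, and acceptance rates outside [0.1, 0.6] after adaptation are
flagged. Fits are bit-reproducible given the mandatory seed.

The sampler was validated against an independent JAGS implementation of
the same posterior (intrinsic CAR encoded via the zeros trick) on a
12-area fixture; the test suite ships this cross-check.

## The synthetic generator and what it does (not) emulate

No public microdata exist for the survey setting this package targets, so
`simulate_cohort()` generates nested cohorts with known ground truth by
running the model forward: $u$ from the constrained intrinsic CAR on a
rook lattice (dimensions nearest square), $v$ iid normal, categorical
covariates from declared level probabilities, outcomes from the logistic
model. Defaults emulate the study scale the package is designed around:
546 areas, ~143 individuals per area (negative-binomially dispersed,
`nb_size = 8`, since district sample sizes vary widely; `nb_size = Inf`
gives fixed sizes), marginal prevalence calibrated to 25%
(`alpha = -1.68` with the default gender/age effect sizes, which are set
to the log-odds contrasts implied by the published marginal counts), and
area-effect variances $\sigma_u^2 = \sigma_v^2 = 0.1$ — a moderate,
realistic amount of unexplained area-level variation on the logit scale.
`simulate_landscape()` generates the geometry consumed by the
built-environment metrics: per-area blocks of 100 m cells, destination
point processes with log-normally heterogeneous tile intensities (so
distance distributions span the published district ranges, from dense
urban cores to sparse rural stretches), and Dirichlet floor-area mixtures
spanning the full LUM range.

The generator does **not** emulate: survey weights or multistage sampling,
the real adjacency of any province, spatial covariate confounding
(covariates are sampled independently of $u$), or item missingness.
Passing recovery tests therefore demonstrate correctness of the model and
sampler under the model's own assumptions, not robustness to the
design features of real survey data.

## Problem sizes used by the shipped tests

The test suite exercises recovery at 100 areas x 80 individuals with 20
replicates and single chains of 3,000 iterations (1,500 burn-in, thin 3),
spatial-fraction recovery at 64 areas x 60, and the sampler cross-checks
at 5-12 areas — sizes chosen so the whole suite completes in well under
half an hour on one core while leaving Monte-Carlo error comfortably
inside the asserted tolerances.

## Known limitations

* **The BYM variance partition is weakly identified from binary data.**
  Only the sum $u_i + v_i$ enters the likelihood; the split is informed
  solely by spatial smoothness, and the vague Gamma(1, 0.0005) precision
  prior places substantial mass on very small variances. In repeated
  simulation at the sizes above, converged posteriors frequently place
  $\sigma_v^2$ near zero and inflate $\sigma_u^2$ correspondingly even
  when the generating $\sigma_v^2$ is 0.1: interval coverage for the two
  variance parameters individually falls well below nominal while
  coverage for $\alpha, \beta, \gamma$ is essentially nominal. This is a
  property of the model-plus-prior, reproduced identically by the
  independent JAGS implementation — not a sampler artifact. Posterior SF
  values should be read with this in mind (penalized-complexity priors or
  the scaled reparameterized convolution model are principled remedies,
  out of scope here).
* The intrinsic CAR is the only spatial prior (no proper-CAR
  autocorrelation parameter, no distance weighting).
* Logit link only; no survey weighting; no imputation (records with
  missing covariates are dropped with a warning).
* DIC is the only comparison criterion (no WAIC/LOO).
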