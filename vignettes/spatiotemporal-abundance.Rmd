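---
title: "Modelling spatiotemporal structure in trawl-survey abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatiotemporal structure in trawl-survey abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

trawlGMRF models the spatial structure of groundfish abundance — here
motivated by juvenile Atlantic halibut in the Northwest Atlantic — from
stratified-random research trawl surveys. The quantity of scientific
interest is not a single abundance index but the *structure* of the
latent abundance surface: how far temporal patterns cohere in space
(connectivity), how much the surface varies across the seascape (spatial
variance), and how strongly the spatial pattern persists from one
management regime to the next (persistence). This vignette documents the
model, its numerical implementation, the synthetic-data generator used to
validate it, and the design decisions taken where more than one choice was
defensible.

## The observation model

Each trawl set $i$ contributes a count $y_i$ (individuals of the target
species) at location $s_i$, period $t_i$, with standardized tow effort
$E_i$ and covariates such as bottom temperature. Counts are modelled as

$$y_i \sim \mathrm{Poisson}(\mu_i), \qquad
  \log \mu_i = \xi(s_i, t_i) + \beta_0 + \beta^\top c(s_i,t_i) + \log E_i,$$

where $\xi(s,t)$ is a latent spatiotemporal Gaussian random field.
Negative binomial and Gaussian likelihoods are available for model
comparison (`model_spec(likelihood=)`); in the motivating analysis the
Poisson consistently fit best. Effort enters as a log-link *offset* rather
than by dividing counts: a Poisson likelihood needs integral responses,
and the offset is the statistically coherent way to account for tow
duration/distance differences. The catch-per-standard-tow multiplier
(`standardize_effort(mode = "multiplier")`) is provided for descriptive
plots only.

Years are grouped into three management-regime periods (1978–1989,
1990–2003, 2004–2013; `assign_period()`), so $t \in \{1,2,3\}$.

## The latent field

$\xi$ is a Gaussian Markov random field built from the SPDE representation
of the Matérn covariance. On a triangulated mesh with linear finite
elements ($C$ the lumped mass matrix, $G$ the stiffness matrix), the
spatial precision at SPDE order $\alpha = 2$ is

$$Q_s = \tau^2\left(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\right),$$

whose inverse approximates a Matérn ($\nu = 1$) covariance with range
$\rho = \sqrt{8}/\kappa$ (degrees latitude) and marginal variance
$\sigma^2 = 1/(4\pi \kappa^2 \tau^2)$. The reported range is the distance
at which the correlation $r(d) = \kappa d\, K_1(\kappa d)$ falls to
$\approx 0.13$ (the exact value is 0.1397; we treat the convention as the
*definition* $\rho = \sqrt 8/\kappa$, not as a root-finding target). For
interpretation, degrees latitude convert to kilometres at 111 km/degree
(`range_to_km()`).

Time enters through a stationary AR(1) across periods, standardized to
unit marginal variance per slice so that $\sigma^2$ is carried entirely by
the spatial part and is identified as a single number. The joint precision
is the Kronecker product $Q_t \otimes Q_s$ (`st_precision()`). The AR(1)
coefficient $a \in (-1, 1)$ is the persistence of the spatial pattern
between consecutive regimes; `temporal_mode = "independent"` and
`"shared"` give the no-correlation and time-invariant alternatives used in
model screening.

Several choices here were genuinely open:

* **SPDE order.** $\alpha = 2$ ($\nu = 1$ in 2-D) is fixed; it is the
  default of the standard SPDE implementations in this field and pins down
  the $\rho$ and $\sigma^2$ conventions above.
* **Planar coordinates.** Lon/lat degrees are treated as planar. At
  40–52°N an east–west degree is 0.64–0.77 of a north–south degree, so
  east–west distances are stretched by up to ~1.5x on the degree scale.
  The reported range is therefore read "in degrees latitude" with this
  caveat; no spherical correction is applied.
* **One $\rho$, $\sigma^2$, $a$.** The three periods share a single set of
  field hyperparameters (a grouped model), matching how the motivating
  analysis reports them.

## The mesh

`build_mesh()` implements an incremental (Bowyer–Watson) Delaunay
triangulation refined by circumcenter/edge-midpoint insertion, written
in-package because no triangulation library is available to R here and the
mesh is a core primitive of the method. Nodes are the domain boundary
densified to `max_edge`, the data locations thinned to a minimum spacing
`cutoff`, and refinement points inserted until no interior triangle has an
edge longer than `max_edge` — so triangles are small where sets are dense.
The domain is extended outward by `extension` (fraction of the domain
diameter) beyond the data before meshing: the SPDE's Neumann boundary
inflates the marginal variance near the mesh edge (the test suite measures
roughly a doubling at boundary nodes), and the buffer keeps that inflation
away from the data. Concave boundaries are supported, which is how the
sharp estuary corner is omitted from the model domain; the matching *data*
exclusion (strictly-inside points dropped, boundary points kept) lives in
`exclude_polygon()`.

The default recovery-experiment mesh (`design_mesh()`) lands at ~320 nodes
on the synthetic shelf domain — the few-hundred-node problem size used for
all simulation studies in this package, small enough that a full fit takes
tens of seconds yet fine enough (node spacing ~0.6–1.1°, well under the
2.25° range) to resolve the field.

## Inference

Fitting is an INLA-style empirical-Bayes Laplace approximation, written
against sparse Cholesky factorizations from Matrix:

1. **Inner step.** At fixed hyperparameters
   $\theta = (\log\kappa, \log\tau, \log\frac{1+a}{1-a})$, Newton
   iterations maximize the joint log-posterior of the latent vector
   $[\xi; \beta]$, giving the Gaussian approximation with precision
   $Q_{\text{post}} = Q_{\text{prior}} + A^\top W A$. The sparsity pattern
   of $Q_{\text{post}}$ is fixed across iterations and $\theta$ values, so
   the symbolic factorization is analysed once and only numerically
   updated; the values of $A^\top W A$ are obtained as a single sparse
   matrix–vector product through a precomputed map from observation
   weights to precision entries. Convergence is declared at gradient
   max-norm $< 10^{-8}$, or when successive objectives agree to a relative
   $10^{-9}$ with gradient norm already below $10^{-4}$ — with tens of
   thousands of observations the summed gradient cannot be pushed below
   floating-point accumulation error, and the stagnation rule stops at the
   round-off-limited mode.
2. **Outer step.** The Laplace-approximate log marginal posterior
   $\log p(\theta \mid y)$ is maximized by Nelder–Mead (relative tolerance
   $10^{-6}$, one restart from the incumbent to polish the simplex mode),
   with the inner Newton warm-started across evaluations. A
   finite-difference Hessian at the mode scales the exploration grid.
3. **Hyperparameter posterior.** $\log p(\theta\mid y)$ is evaluated on a
   regular grid in the principal axes of the posterior covariance (default
   5 points per dimension spanning ±2.5 sd), weights are normalized, each
   atom is transformed to $(\rho, \sigma^2, a)$, and the reported mean, sd
   and 0.025/0.5/0.975 quantiles are those of the induced mixture
   (quantiles by interpolating the weighted ECDF). Latent summaries are
   empirical-Bayes at the $\theta$ mode — a deliberate simplification of
   full INLA (no per-marginal nested Laplace corrections), exact in the
   Gaussian-likelihood limit, which the test suite exploits: the whole
   pipeline is checked against closed forms there.

**Priors** (the motivating analysis does not state its settings; these are
weakly informative defaults in the spirit of that software era):
$\mathcal N(0, 10^2)$ on fixed effects; $\mathcal N(\cdot, 3^2)$ on
$\log\kappa$ and $\log\tau$, centred so the prior range is a fifth of the
domain diameter and the prior field variance 1; $\mathcal N(0, 2^2)$ on
the Fisher-z transform of $a$ and on any extra likelihood parameter
(log observation precision, log NB size).

**Zero handling.** The motivating analysis removed true-zero sets from the
likelihood, representing them only through the mesh. `model_spec(zeros =
"exclude")` reproduces that convention and is the default for real survey
data. For synthetic-recovery experiments the package fits with `zeros =
"include"`: the generator's truth is an untruncated Poisson field model,
and fitting an untruncated likelihood to positive-only draws is
generatively inconsistent — at ~6% occupancy the positive counts carry
almost no information about the field amplitude (the signal is attenuated
by roughly a factor $\lambda/2 \approx 0.03$), so no estimator of
$\sigma^2$ could recover the truth from truncated data. Both modes are
exposed so the sensitivity is one flag away.

## Model comparison

`dic()` computes $\mathrm{DIC} = 2\bar D - D(\hat x)$ with $\bar D$
estimated from seeded Monte-Carlo draws of the Gaussian approximation
(default 1,000 draws — a documented approximation in place of the analytic
expectation). `cpo()` computes leave-one-out predictive densities by the
harmonic-mean identity $1/\mathrm{CPO}_i = E[1/p(y_i\mid x)]$ over the
full posterior; draws from the Gaussian approximation are
importance-reweighted to the exact unnormalized posterior (the proposal
density comes free from the sampling normals), so the estimate converges
to the true CPO — verified against literal leave-one-out quadrature in the
tests. Observations whose combined importance weights have effective
sample size below 30 are flagged. `compare_models()` ranks candidates by
ascending DIC with ties broken by larger summed log CPO, and records
failed candidates as flagged rows rather than aborting the table.

## The synthetic survey generator

`survey_design()` and `simulate_sets()` emulate the features of the real
multi-survey series that the model relies on: a shelf-like ~12°x8°
polygon with a triangular estuary notch; a 4x3 block stratification with
areas clipped to the polygon and stratified-random placement proportional
to area; three periods; a smooth north–south temperature gradient plus a
warm middle period and set-level noise, clamped to 2–7 °C (so the
covariate is partially confounded with space, mimicking the weak covariate
significance in the motivating analysis); log-normal(0, 0.1²) effort to
exercise the offset path; an intercept calibrated by root finding so the
expected positive fraction hits the 6% occupancy of the real series
(~1,500 positive sets per 25,000-set period, positive-set means ~1.05);
and 61 records planted inside the estuary ring so the exclusion step is
exercised end to end. True zeros are retained in the output — zero
handling is the fitted model's concern.

What the generator does **not** emulate: the seven real trawl gears and
their catchability differences, season/vintage differences among the 27
surveys (coverage is balanced within periods), depth-dependent
stratification, and any non-Poisson overdispersion. Passing recovery tests
therefore demonstrate that the estimator is consistent for its own model
class at realistic sizes — not that the real surveys satisfy these
assumptions.

`recovery_experiment()` drives the seeded study: simulate at the reference
truth (range 2.25°, variance 0.12, persistence 0.77 — the posterior means
of the fitted survey model), refit, and report bias, 95%-interval coverage
and whether each posterior mean lies within twice the reference posterior
sds (0.44, 0.02, 0.06). The default study is 20 replicates at 25,000 sets
per period on the ~320-node mesh; one replicate fits in well under a
minute.

## Numerical edge cases

* Degenerate (zero-area or mis-oriented) triangles abort FEM assembly
  naming the triangle; collinear point sets abort meshing.
* Points outside the mesh hull are an error in `projector()` (with the
  offending indices) except for map rasters, where they are masked.
* The linear predictor is clamped at ±30 inside likelihood evaluations so
  a wild line-search step cannot overflow `exp()`; the line search itself
  halves the step until the joint posterior is non-decreasing.
* A non-positive-definite precision surfaces as an explicit error from the
  sparse factorization, not as NaNs downstream.
* `ar1_precision(a)` requires |a| < 1; `a = 0` gives an identity and one
  period degenerates to the purely spatial model.
* Ties in `compare_models()` are broken by CPO; equal specifications
  produce byte-equal rows.

## Limitations

Beyond the generator simplifications above: the Laplace approximation is
empirical-Bayes at the hyperparameter mode, so latent credible intervals
ignore hyperparameter uncertainty; the planar-coordinate distortion means
the single reported range mixes slightly different metric distances
east–west vs north–south; the mesh is an unconstrained Delaunay filtered
to the domain (boundary segments are respected only through densification,
not as hard constraints); and the AR(1) with three time slices estimates
persistence from effectively two transitions, so $a$ is the least
precisely identified of the three hyperparameters at small domain sizes.
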