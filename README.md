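# trawlGMRF

Bayesian spatiotemporal modelling of groundfish trawl-survey abundance.

Research trawl surveys record, for every standardized tow ("set"), where
and when it happened and how many fish it caught. For a recovering stock
such as Atlantic halibut in the Northwest Atlantic the management question
is not only *how many* juveniles there are but *where* they persistently
concentrate, and on what spatial scale those concentrations are connected
— areas of persistently high abundance may deserve protection, and a
connectivity scale much smaller than the management unit implies more
population structure than assumed. trawlGMRF is for quantitative fisheries
scientists who want to ask those questions of set-level survey data.

## The model

Counts per set are Poisson on a log link with a tow-effort offset,

    y_i ~ Poisson(mu_i),   log mu_i = xi(s_i, t_i) + beta0 + beta' c_i + log E_i,

where `xi(s,t)` is a latent Gaussian random field over space `s` and
management-regime period `t` (1978–1989, 1990–2003, 2004–2013) and `c_i`
holds covariates such as bottom temperature. The field is the SPDE/Matérn
Gaussian Markov random field of Lindgren–Rue type: on a triangulated mesh
with finite-element matrices `C` (lumped mass) and `G` (stiffness), the
spatial precision at SPDE order alpha = 2 is

    Q_s = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G),

with range `rho = sqrt(8)/kappa` (degrees latitude; the distance at which
the Matérn nu = 1 correlation decays to ~0.13) and marginal variance
`sigma2 = 1/(4 pi kappa^2 tau^2)`. Periods are coupled by a unit-variance
AR(1) with persistence `a`, giving the separable space-time precision
`Q_t (x) Q_s`. The three hyperparameters are the scientific quantities:

* **connectivity** `rho` — how far temporal patterns cohere in space,
* **spatial variance** `sigma2` — amplitude of structure across the
  seascape on the log-abundance scale,
* **persistence** `a` — similarity of the spatial pattern between
  consecutive management regimes.

Inference is an INLA-style Laplace approximation written against sparse
Cholesky factorizations: Newton on the latent field inside, Nelder–Mead
plus a principal-axis grid over the hyperparameter posterior outside.
Candidate models (likelihood family, temporal structure, covariate sets)
are compared by DIC and CPO. Because the underlying surveys are not
redistributable, the package ships a synthetic stratified-random survey
generator that reproduces their statistical structure (three periods, ~6%
occupancy, counts of 1–5 per positive set, bottom temperature within
2–7 °C, log-normal effort, an estuary exclusion), so that every stage —
including full parameter recovery — is testable from a seed.

## Worked example

The `analysis/` scripts run the whole pipeline on the default synthetic
survey (numbered stages; each writes delimited tables under `results/`):

```sh
Rscript analysis/01_simulate_surveys.R    # simulate 75,061 sets on a 319-node mesh
Rscript analysis/02_survey_summaries.R    # occupancy + stratified-mean indices
Rscript analysis/03_fit_final_model.R     # fit Poisson/AR(1)/temperature model
Rscript analysis/04_model_selection.R     # DIC/CPO candidate table
Rscript analysis/05_recovery.R            # 5-replicate recovery check
```

Stage 1 reports the generator hitting the survey conditions
(`simulated 75061 sets over 3 periods; occupancy 6.04%`, positive-set
mean 1.04). Stage 3 prints the posterior-summary table for the data
simulated at generating values rho = 2.25, sigma2 = 0.12, a = 0.77:

```
               parameter             Mean   SD Q0.025 Q0.5 Q0.975
        rho Connectivity 1.98 (220.25 km) 0.39   1.33 1.91   2.89
 sigma2 Spatial variance             0.14 0.02   0.10 0.13   0.19
           a Persistence             0.83 0.07   0.71 0.83   0.94
```

Each row is the posterior of one hyperparameter: connectivity is
recovered at ~2.0 degrees latitude (~220 km; truth 2.25 inside the 95%
interval), the field variance at 0.14 (truth 0.12), and the persistence
at 0.83 (truth 0.77) — all three generating values sit within their
credible intervals. Stage 4 ranks the four covariate candidates on the
same data, lowest DIC first:

```
                         model      dic   cpo_sum failed
         xi(s,t) + temperature 35038.53 -17517.00  FALSE
 xi(s,t) + depth + temperature 35038.81 -17516.92  FALSE
                       xi(s,t) 35047.29 -17520.07  FALSE
               xi(s,t) + depth 35048.25 -17522.03  FALSE
```

The `+ temperature` model wins (the generator's only real covariate
effect is temperature), with depth adding nothing once temperature is in.

The same steps are available programmatically — `simulate_sets()`,
`exclude_polygon()`, `occupancy_summary()`, `stratified_mean()`,
`build_mesh()`, `fit_spde()`, `compare_models()`, `latent_summary()`,
`recovery_experiment()` — and as one call, `run_pipeline(run_config(...))`.
See the methods vignette (`vignettes/spatiotemporal-abundance.Rmd`) for
the model, priors, numerical choices and limitations.

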