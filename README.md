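# waspnest

Multi-scale stochastic dynamics of dominance and caste in paper wasp colonies.

## The problem

Small *Polistes* paper-wasp societies hold two properties in tension. They are
robustly specialized — exactly one queen reproduces, and workers whose
queen-gene expression fluctuates upward are pushed back down — yet they are
rapidly plastic: when the queen is lost, any worker can become the
replacement queen within days. `waspnest` implements a minimal biophysical
model of how a colony achieves both at once, together with the statistics,
estimators and observables needed to confront the model with behavioural,
imaging and expression data, and seeded synthetic-data generators so every
analysis step can be validated as a parameter-recovery problem.

The package is aimed at quantitative biologists studying self-organization in
social insects, and more generally at anyone who wants a worked, tested
example of coupling an individual-based master equation to its mean-field
limit and to data-analysis pipelines.

## The model

Each insect *i* carries a coarse-grained molecular state: the number *nᵢ* of
queen-gene products, produced at rate μ and degraded at per-molecule rate δ.
Time is measured in units of the degradation time (δ = 1) and expression is
scaled by the unrepressed steady state, *rᵢ = nᵢ / n_ss*, so an undisturbed
insect fluctuates around *r* = 1. Insects are coupled by dominance
interactions: insect *i* is subject to a subdominant interaction with *j* at
rate

> α · K(rᵢ, rⱼ),  K(rᵢ, rⱼ) = rᵢ rⱼ σ(rᵢ − rⱼ),  σ(x) = 1 / (1 + e^{λx}),

which removes *m* gene products from the loser. σ decreases on a scale 1/λ,
so λ measures how reliably a small expression difference decides a fight, and
K(rᵢ,rⱼ) + K(rⱼ,rᵢ) = rᵢrⱼ — every encounter has exactly one loser. A full
variant tracks an explicit repression flag *qᵢ* (production off while
repressed, decay back at rate Γ, repression triggered at rate ω·ΣⱼK).

In the mean-field limit the colony composition *f(r, τ)* (normalized to mass
1) obeys the transport equation

> ∂τ f + ∂r [ v(r) f ] = 0,  v(r) = (1 − r) − α̃ ∫ K(r, r′) f(r′) dr′,

whose microscopic attractors are the queen state r₀ = 1 and the worker state
r₂ = 1/(1 + α̃ r̄), with the steady colony mean r̄ = (√(2α̃ + 1) − 1)/α̃. The
colony composition itself acts as the control parameter of a saddle-node
bifurcation: perturbations of one insect's state (intrinsic, e.g. expression
noise) are suppressed, while perturbations of the whole composition
(extrinsic, e.g. queen removal) push the colony through a plastic state from
which a new queen emerges.

Because interactions are stochastic, a queen persists only until a worker's
chance activation; with *N* workers, mean interaction gap T_int and a
stability-to-gap ratio *R*, the expected persistence time is

> T = T_int · ( R + 1 / [ 1 − (1 − e^{−R})^N ] ),

less than three days at the empirically estimated parameters — and the
variant T = T_int·(R + 1/[1 − (1 − e^{−1/σ})^N]) shows that reducing the
expression-noise scale σ (as gene-body DNA methylation does) extends
persistence faster than exponentially.

## Worked example

```r
library(waspnest)

# place the field estimates on the phase diagram:
# 3.7 fights/day, 30 h molecular degradation time
p <- nondimensionalize(interaction_rate = 3.7 / 24, delta = 1 / 30)
p$alpha
#> [1] 4.625

# a colony of 16 under frequent, asymmetric interactions
tr <- simulate_reduced(model_params(N = 16, alpha = 20, lambda_asym = 24),
                       horizon = 50, seed = 1, record_events = FALSE)
snap <- final_snapshot(tr, average_over = 5)
round(sort(snap), 2)
#>  [1] 0.14 0.15 0.15 0.15 0.16 0.16 0.18 0.18 0.18 0.19 0.19 0.21 0.22
#> [14] 0.24 0.25 0.97
classify_social_structure(snap, threshold = 0.6)
#> [1] "single-queen"
```

One insect sits at the queen attractor (r ≈ 1) while the rest are suppressed
near the worker attractor — a single queen emerges without parameter tuning.

```r
# how long does she last against chance activations?
persistence_time_R(R = 4.6, N = 20, T_int = 30 / 4.6) / 24
#> [1] 2.735326   # days: the bare model underpredicts real queen tenure

# recover generator ground truth from a synthetic behavioural log
sc <- nest_scenario(seed = 1, phase_hours = c(control = 24, eggless = 1,
                                              D1 = 1, D4 = 1, D14 = 1))
ev <- generate_events(sc)
est <- estimate_from_log(ev[ev$phase == "control", ],
                         scenario_hours(sc, "control"))
c(rate = est$rate$rate_per_day, sem = est$rate$sem)
#>     rate      sem
#> 3.125000 1.520691   # true rate 3.7/day, within 2 SEM
est$queen
#> [1] "w01"           # the asymmetry exposes the queen
```

The 2.7-day persistence time, far below the weeks-long stability of real
colonies, is the quantitative motivation for the package's noise-suppression
analysis: `persistence_time_sigma()` and
`variable_fraction_by_methylation()` connect gene-body methylation, reduced
expression variability and colony stability.

A thin command-line wrapper over the same functions is installed at
`inst/cli/waspnest` (subcommands `simulate`, `meanfield`, `phase-diagram`,
`persistence`, `estimate`, `observe`, `synth`, `report`).

## Method vignette

`vignettes/multiscale-colony-dynamics.Rmd` documents the model assumptions,
the numerical choices (upwind finite-volume transport, kinetic Monte Carlo
thinning, tracer closures), what the synthetic generators do and do not
emulate, and the package's design decisions and limitations.
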