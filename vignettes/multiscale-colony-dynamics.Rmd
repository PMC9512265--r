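---
title: "Multi-scale colony dynamics: model, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale colony dynamics: model, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(waspnest)
```

## The model and its assumptions

`waspnest` studies how a small paper-wasp colony maintains exactly one
reproductive queen while retaining the capacity to replace her quickly. The
model is deliberately minimal: each insect's molecular state is collapsed
into a single coarse-grained variable, the level of queen-gene products
$r_i$, justified by the observation that different queen-associated molecular
programs (gene expression, hormones) respond to colony perturbations on
similar time scales and are mutually correlated. No nonlinearity is assumed
on the molecular scale: products are produced at a constant rate and degraded
in proportion to their level, so an isolated insect relaxes to the scaled
steady state $r = 1$.

All structure beyond that single molecular attractor comes from the colony
scale. Pairs of insects interact at a rate proportional to both expression
levels, and the loser — determined by the discrimination function
$\sigma(x) = 1/(1 + e^{\lambda x})$ of the expression difference — has
queen-gene production repressed. The interaction kernel
$K(r_i, r_j) = r_i r_j \sigma(r_i - r_j)$ is the rate at which $i$ is
subdominant to $j$; the complement identity
$K(r_i,r_j) + K(r_j,r_i) = r_i r_j$ states that every encounter has exactly
one loser. Two model granularities are implemented:

* **reduced** (`simulate_reduced()`): each subdominant interaction instantly
  removes $m$ products (floored at zero). This is the long-time limit in
  which the repressor dynamics are integrated out.
* **full** (`simulate_full()`): an explicit repression flag $q_i$ switches
  production off; it decays at rate $\Gamma$ and is raised at rate
  $\omega \sum_j K(r_i,r_j)$. When repression episodes are much shorter than
  the time between interactions, each episode removes on average
  $\mu/\Gamma$ products and the full model reduces to the reduced one with
  $m = \mu/\Gamma$, $\alpha = \omega$ — verified by a two-sample test in the
  suite. The repression decay is Markovian by default; a deterministic
  refractory variant (episodes of exactly $1/\Gamma$) is provided for
  sensitivity checks because the decay law is only constrained up to its
  mean.

Both simulators are exact kinetic Monte Carlo (Gillespie) algorithms written
in C++. The pair-interaction channel is sampled by thinning: candidate
ordered pairs are drawn with weight $r_i r_j$ under the envelope rate
$\alpha(S^2 - Q)$, $S = \sum r_i$, $Q = \sum r_i^2$, and accepted with
probability $\sigma(r_i - r_j) \le 1$, which is exact. Simultaneous events
cannot occur in continuous time; the dominance direction within an encounter
is decided by the $\sigma$ acceptance itself. All randomness flows through
R's RNG, so a fixed `(params, seed)` pair reproduces a trajectory exactly on
any platform.

## Parameters

| parameter | meaning | unit | default | rationale |
|---|---|---|---|---|
| `N` | colony size | insects | 16 | typical nest census (~15 ± 7) |
| `delta` | degradation rate | 1/time | 1 | defines the time unit (≈ 30 h) |
| `mu` | production rate | products/time | `n_ss` | sets the scaled steady state r = 1 |
| `n_ss` | steady-state product count | products | 50 | Monte-Carlo granularity knob; demographic noise sd = $1/\sqrt{n_{ss}}$ ≈ 0.14 |
| `alpha` | per-individual interaction rate | dimensionless | 4.6 | 3.7 fights/day × 30 h degradation time ≈ 4.6 |
| `lambda_asym` | dominance discrimination steepness | dimensionless | 24 | lower bound from 0/17 subdominant-queen outcomes |
| `m` | products lost per subdominant interaction | products | 5 | 10% of steady state per fight; sets $\tilde\alpha$ via $m/n_{ss}$ |
| `Gamma`, `omega` | repression decay / onset constants | 1/time | 10, 1 | full model only; `Gamma = mu/m` matches the reduced model |

The mean-field coupling $\tilde\alpha$ deserves care. The transport equation
is written for a composition normalized to mass 1, so its coupling absorbs
both the per-interaction expression loss and the number of partners:
`alpha_tilde_match()` returns $\tilde\alpha = \alpha\,(m/n_{ss})\,(N-1)$, the
value used whenever a finite-$N$ simulation is compared with the mean-field
equation. The per-partner product $\alpha \, m/n_{ss}$ (the default stored in
`model_params()`) is the natural dimensionless strength of a single
relationship; all mean-field functions are parameterized directly by
$\tilde\alpha$ so either convention can be used explicitly.

## Mean-field numerics

The mean-field dynamics are implemented as a conservative
transport equation, $\partial_\tau f + \partial_r[v(r)f] = 0$ with
$v(r) = (1-r) - \tilde\alpha \int K(r,r') f(r')\,dr'$ — the advective form whose fixed points are the attractors $r_0 = 1$ and
$r_2 = 1/(1+\tilde\alpha\bar r)$ exactly. Discretization: first-order upwind
finite volume on $[0, 1.5]$ with 600 cells by default, explicit stepping at
CFL 0.5, zero boundary fluxes (the drift points inward at both ends). This
scheme conserves mass to machine precision and preserves positivity;
delta-like initial conditions are represented as Gaussians two cells wide.

Two exact identities anchor the numerics:

* at any steady state the mass-weighted mean satisfies
  $\bar r = 1 - \tilde\alpha \bar r^2/2$ — a direct consequence of the
  complement identity applied to the mean of the equation — with positive
  root $\bar r = (\sqrt{2\tilde\alpha + 1} - 1)/\tilde\alpha$. The $\alpha
  \to 0$ limit is 1, and the solver reproduces the root to a few $10^{-4}$
  at 600 cells (asserted in the tests at tolerance 0.02, and evaluated with
  a series expansion below $\tilde\alpha = 10^{-6}$ to avoid cancellation);
* the attractors $r_0$ and $r_2$ are *tracer* fixed points under the
  frozen-population closure, in which the composition enters only through
  its mean (a point mass at $\bar r$). This is the closure behind the
  bifurcation diagram, where the colony structure is the control parameter.
  `tracer_fixed_points()` also accepts the full steady density; in that case
  the upper fixed point sits a few percent below 1 because a finite mass
  fraction of queens mutually suppress at $\sigma(0) = 1/2$ — a mean-field
  artifact of representing a single queen as a continuum fraction, which is
  why the closed-form identities are checked under the frozen-$\bar r$
  closure.

One known numerical limitation: with zero diffusion, the upwind steady state
can freeze into several nearby spikes rather than one clean worker mode (the
flow is locally expanding at a delta peak's top edge for large $\lambda$).
The mass-weighted mean and the Wasserstein comparison with stochastic
histograms are insensitive to this; perturbation magnitudes in
`perturb_and_classify()` tests are therefore specified relative to the
*measured* separatrix gap of the tracer field rather than as absolute
displacements.

The mean-field steady composition is validated against the long-run
histogram of `simulate_reduced()` at $N = 200$ and matched $\tilde\alpha$
under a preregistered 1-Wasserstein tolerance of 0.15: the stochastic
histogram smears each atomic mean-field mode by the demographic noise scale
$1/\sqrt{n_{ss}} \approx 0.14$, which alone contributes
$\mathbb{E}|X| \approx 0.11$ to the distance.

## Perturbations: suppressed versus reprogrammed

`perturb_and_classify()` operationalizes the central dichotomy. An
*intrinsic* perturbation displaces one tracer insect's expression while the
composition — a colony-scale object unaffected by any single insect — stays
fixed; displacements below the separatrix gap relax back and are classified
`suppressed`. An *extrinsic* perturbation modifies the composition itself
(removal of a configurable fraction of the queen-mode mass) and co-evolves
tracer and composition; the colony passes through an elevated plastic state
and the tracer converges away from its original worker state
(`reprogrammed`). The stochastic counterpart, `queen_removal_experiment()`,
removes the highest-expressing insect from a burned-in colony and reports
egg-layer counts over time (transiently more than one), the time until a
unique queen is re-established, and two activity proxies discussed next.

## The activity proxy

Queen removal is predicted to raise global nest activity. In the reduced
model the *fight rate* cannot carry that prediction: every subdominant event
consumes $m$ products, so at quasi-steady state the total event rate is
pinned to the production deficit $(n_{ss}/m)\sum_i(1-r_i)$, which *falls* as
the colony collectively upregulates after queen removal (both simulators
reproduce this small decline). The observable actually measured on nests is
per-wasp pixel movement, and dominance-related movement tracks an insect's
queen-gene state; the model analogue is therefore the mean per-wasp scaled
expression. `queen_removal_experiment()` returns both: `activity`
(interaction-rate windows, falls slightly) and `pre_arousal`/`post_arousal`
(mean per-wasp $r$, rises with the collective upregulation). The acceptance
suite tests the prediction on the arousal proxy; both numbers are reported
by `scripts/acceptance.R` so the distinction stays visible.

## Queen persistence times

The closed forms implemented in `persistence_time_R()` and
`persistence_time_sigma()` follow a discrete observation-window
construction: per window of length $T_{int}$ each of $N$ workers escapes
repression independently — with probability $e^{-R}$ (no interaction during
the stability period $R\,T_{int}$) or, in the noise-scale variant, with the
tail probability of its expression exceeding the unit activation threshold
($e^{-1/\sigma}$ for an exponential tail, $\Phi(-1/\sigma)$ upper tail for a
normal one; the normal variant mirrors the exponential template by design). The first escape window is geometric and
one stability time completes the activation, giving
$T = T_{int}(R + 1/[1-(1-p_1)^N])$.

`simulate_replacement()` is the independent Monte-Carlo oracle: it actually
draws per-window Poisson interaction counts (or tail excursions) per worker
and records the first escape. Two caveats are documented rather than hidden:
the closed form is an *estimate*, not the exact continuous-time first-passage
law (for $N = 1$ the exact mean time for a Poisson renewal gap to reach
$R\,T_{int}$ is $T_{int}(e^R - 1)$, about half the windowed value at
$R = 1$); and the noise scale $\sigma$ enters the activation
probability directly as $e^{-1/\sigma}$ — whether it denotes a standard deviation or a
variance is a labeling convention that rescales the axis of the
$\sigma \mapsto T$ curve without changing its shape or monotonicity.

## Estimation conventions

* `estimate_interaction_rate()`: total fighting involvements per census
  individual per day, SEM across individuals; censused insects without
  events enter the denominator.
* `estimate_error_rate()`: observed frequency $k/n$, except at $k = 0$ where
  one pseudo-observation gives $(k+1)/n$ — the rule that keeps a zero count
  usable as a bound (0 of 17 gives 1/17).
* `estimate_lambda_bound()`: exact inversion of the logistic,
  $\lambda = \log((1-\varepsilon)/\varepsilon)/\Delta$. The steady
  queen–worker gap $\Delta$ is genuinely ambiguous — it depends on which
  expression contrast the observed fights probed — so it is an explicit
  argument, defaulting to the mean-field gap $1 - r_2$ at the supplied
  coupling. The bound scales as $1/\Delta$; with a gap of
  $\ln 16/24 \approx 0.116$ the 1/17 error rate gives $\lambda \approx 24$,
  while the full mean-field gap at the empirical coupling gives a weaker
  bound near 4.

## Observables

Behavioural indices follow the annotation-table conventions: interaction
rate (all six types per hour observed), fight index
$(\mathrm{DOM}+\mathrm{SUB})/\mathrm{all}$, dominance index
$\mathrm{DOM}/(\mathrm{DOM}+\mathrm{SUB})$, each undefined (`NA`) when its
denominator is empty. Dyadic fights are stored as paired DOM/SUB rows
(`expand_dominance()` imports single-row dialects). Phase comparisons use
Wilcoxon tests with Benjamini-Hochberg correction — the *rank-sum* test by
default because individuals collected in different phases come from
different (sacrificed) colonies and cannot be paired; the signed-rank mode is
available when pairing identifiers exist.

`global_activity()` is mean absolute per-pixel change between consecutive
frames, normalized by wasp count and squared spatial scale; the calibration
constant is camera-specific, so only relative comparisons are meaningful.
Ovary maturity uses the inclusive 1.5 mm threshold on the largest egg.

`variable_fraction_by_methylation()` stands in for full technical-noise
decompositions with a deliberately simple over-dispersion screen: per-gene
variance against a loess mean–variance trend, scaled statistic
$(n-1)s^2/\mathrm{trend} \sim \chi^2_{n-1}$, BH correction at 0.05, fraction
of variable genes per methylation bin, and a Pearson test on the unbinned
(methylation, log dispersion ratio) pairs. It preserves the contract needed
here — which genes vary more than expected at their expression level, and
whether that excess declines with methylation — but it is not a substitute
for a mean–variance decomposition on real counts, where technical noise,
library size and dropout structure matter.

## Synthetic data: what it does and does not emulate

`nest_scenario()` fixes the study design: a 16-insect colony observed through
control, eggless, D1, D4, D14 phases (45 min of video per phase by default);
3.7 fights per individual per day with dominance concentrated on the queen
(error rate 1/17); a tripled fighting rate in the eggless phase; ~10,000
genes with 200 queen genes; queen-gene upregulation in queens and — at D4 —
in every individual, with a gene-specific signature (a flat shift would be
invisible to profile correlations); per-gene expression noise decreasing
exponentially in gene-body methylation; ovary sizes increasing with
queen-gene score so queens cross 1.5 mm; and disks moving at per-phase speeds
for the imaging module. Each generator exposes its ground truth, and one
scenario seed fans out to independent substreams per generator.

Deliberately *not* emulated: count-level sequencing noise, library-size and
mapping effects, transcriptome covariance beyond the queen-gene block, any
methylation–mean-expression coupling (kept independent so the null of the
over-dispersion screen is exact), spatial structure on the comb, and
relatedness. Passing the recovery tests therefore shows the estimators are
correct *given this generative structure*, not that they are robust to the
full mess of field data.

Problem sizes in the test and acceptance suites are chosen for desk-scale
runs and stated where used: recovery logs use a 24 h control window (the
unit in which the daily fighting rate is defined), expression recovery uses
800–2,000 genes, the mean-field/stochastic comparison uses $N = 200$ at 600
grid cells, phase-diagram cells use 20 seeded replicates at horizon 50, and
the type-I-error simulation uses 200 null seeds checked against the
one-sided binomial 95% bound for a nominal 5% level.

## Known limitations

* The bare model underpredicts queen tenure at the empirical parameters
  (under three days) — that tension is the package's point of departure for
  the noise-suppression analysis, not a bug; correspondingly the
  single-queen state at the *empirical* coupling is contested by transient
  challengers, and robust single-queen statistics are collected deeper in
  the phase diagram.
* Pure advection leaves grid-frozen fine structure in mean-field steady
  states (see above); quantities derived from means, masses and tracer
  analyses are reliable, pointwise peak shapes are not.
* The dominance-direction function σ is only constrained qualitatively
  (monotone decreasing on a scale $1/\lambda$), and $\tilde\alpha$ admits
  more than one normalization; the logistic form and the
  $\alpha m (N-1)/n_{ss}$ mapping are documented package conventions, chosen
  for the clean complement identity and the closed-form inversion used in
  estimation.
* Activity is only meaningful as a relative quantity, and the model-to-pixel
  map is a stated interpretive choice (arousal proxy) rather than a derived
  result.
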