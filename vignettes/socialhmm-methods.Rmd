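---
title: "Inferring social information use from movement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring social information use from movement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialhmm)
```

This vignette is the package's own account of its science: the latent-state
movement model at its core, the agent-based generator used to validate it,
the numerical choices that make the pipeline reproducible, and what the
package's tests do and do not establish about real data.

## 1. The scientific problem

Groups of foragers searching a shared environment face a
producer–scrounger trade-off: search independently, or exploit the
discoveries of others. The decision to use social information is not
directly observable. A forager that turns towards a digging group member
has made a social decision even if it never arrives; a forager that joins
a patch may have discovered it independently. The package therefore
treats social information use as a *latent behavioral state* and infers
it statistically from movement and gaze geometry, in the tradition of
hidden Markov movement models in animal ecology.

## 2. The latent-state model

### States and observation channels

Each forager-second is in one of three states: **individual exploration
(I)**, **social relocation (S)**, or **exploitation (E)**. Exploitation
is directly observed (the forager is immobile on a patch, extracting), so
only I and S are hidden. Three observation channels distinguish them:

* **Turning angle** `θ_t` (wrapped heading change between consecutive
  seconds), modeled as von Mises. Directed relocation has a larger
  concentration κ than meandering search.
* **Smallest change in distance** to the exploiting players currently in
  the field of view (meters per second), modeled as Normal. Relocation
  means approach: a more negative mean.
* **Smallest relative bearing** to visible exploiting players (radians),
  modeled as log-Normal. Relocation aims at its target: a smaller
  median.

The social channels exist only when at least one exploiting player is in
the focal's field of view; otherwise they are *missing* and their factors
are dropped from the likelihood (marginalization, not imputation). A
bearing of exactly zero is floored at `1e-6` rad because the log-normal
has strictly positive support.

### Validity mask and segments

Only seconds at which a forager *could* use social information are
modeled: seconds when the focal was itself exploiting, or when no group
member was exploiting, are omitted, as is the first second of a round
(no turning angle exists). Maximal runs of modeled seconds form
*segments*; the latent chain restarts in state I at the start of every
segment, the state a forager is reset to after every omission. The same
reset is applied at the round start: a round begins with no social
information in play, so exploration is the only defensible initial
state.

### Covariate-dependent switching

The transition I→S at second `t` is

`P(I→S) = logit⁻¹(α_ij + β_V,ij V_t + β_D,ij V_t D_t + β_N,ij V_t N_t + β_T,ij T_t)`

per incentive condition `i` (individual vs. group payoffs) and
environment `j` (concentrated vs. distributed patches). `V` is the
visibility indicator, `D` the z-scored distance to the closest visible
exploiting player, `N` the number of *other* players extracting at that
player's patch (`N = 0` = a single exploiter), `T` the z-scored time
since the focal's own last success. `D` and `N` are multiplied by `V` so
their effects switch on only under visibility. The reverse transition
S→I is a condition intercept `γ_ij`: the model's substance concerns what
*triggers* social relocation; making the abandonment rate
covariate-dependent is left as an extension. The transition into second
`t` uses the predictors observed at `t`, and the generative sampler
(`simulate_from_model()`) uses the identical convention, so the fitted
model is the exact probabilistic twin of the generator.

`N` enters raw (its coding is already interpretable: additional
co-exploiters), `D` and `T` z-scored; `D` is standardized over the valid
seconds where it is defined (V = 1), pooled across the dataset so
condition contrasts stay on one scale (per-condition scoping would make
a unit of `D` mean different meters in different conditions).

### Time-varying effects

Any switching coefficient can vary by minute-of-round through a
monotonic (ordered-categorical) effect: `β(t̃) = β_max · Σ_{m=0}^{t̃-1}
δ_m` with `δ` a 12-simplex. This assumes only that a coefficient drifts
monotonically over the round and lets the data place the steps; at
`t̃ = 12` the full `β_max` is reached. In time-varying mode only the
average effects carry individual/group offsets.

### Hierarchy

In the hierarchical modes, the five switching coefficients receive
additive per-individual and per-group offsets with estimated scales
(non-centered, `offset = scale · z`, `z ~ N(0,1)`). The offsets are
independent across coefficients: a full covariance (Cholesky/LKJ)
structure among decision weights is not reliably estimable by joint-mode
optimization, which is this package's fitting strategy, so correlations
among weights are intentionally out of scope.

## 3. Fitting: penalized likelihood with Laplace draws

The marginal likelihood is computed by the forward algorithm in log
space, vectorized across segments (the recursion advances all segments'
within-position index simultaneously, so its cost is the longest
segment, not the number of steps). Decoding uses the Viterbi algorithm
with ties broken deterministically towards state I.

Fitting maximizes the log likelihood plus weakly informative Gaussian
penalties in an unconstrained parameterization, then draws from the
Gaussian (Laplace) approximation at the mode. Two kinds of prior
knowledge are baked into the *parameterization itself* rather than the
penalty:

* positivity: concentrations, standard deviations and random-effect
  scales live on the log scale;
* label identification: `dd_mu_S = dd_mu_I − exp(·)`,
  `vm_kappa_S = vm_kappa_I + exp(·)`, `lb_mu_S = lb_mu_I − exp(·)`, so in
  *every* draw the S state approaches faster, turns less and aims better
  — the orderings that make S interpretable as social relocation. This
  removes label switching by construction.

Default penalties: `α, γ ~ N(0, 2.5)`, slopes `~ N(0, 1)`, monotonic
simplex (softmax) raws `~ N(0, 1)`, log emission scales `~ N(−0.5, 1)`,
log random-effect scales `~ N(log 0.3, 0.5)`. All are on the logit or
log scale and wide relative to plausible effects; they matter only in
data-poor corners (they make the empty-data fit reproduce the prior,
which the tests exploit).

Draw-based summaries mimic the Bayesian workflow: 90% highest-density
intervals, directed evidence ratios with the `> 100` cap when fewer than
1/101 of draws oppose the direction, split-chain convergence statistics
and effective sample sizes per parameter. Because Laplace draws are
independent, the split statistic fluctuates around 1 with scale
`1/n_draws`; a fit whose optimizer failed, whose Hessian is not positive
definite, or whose diagnostics exceed 1.01 is *flagged* with a warning,
never silently returned.

Limitations of the backend: the Gaussian approximation understates
uncertainty for strongly non-Gaussian posteriors (small data, boundary
parameters), and joint-mode estimation of random-effect scales is biased
low relative to marginal-likelihood estimation. Where those properties
matter, the draws should be treated as a fast approximation, not a
substitute for full MCMC.

## 4. The agent-based generator

`simulate_round()` implements the virtual foraging experiment as a
mechanistic simulation whose one-second discretization *is* the model's
generative process, which makes latent-state and parameter recovery
well-posed tests rather than hopeful analogies.

The arena is a 90 m × 90 m square with non-overlapping circular patches
of radius 3 m; the **concentrated** preset has 5 patches of 48 coins,
the **distributed** preset 15 patches of 16 coins. Avatars move at 2 m/s
with a 108° horizontal field of view; the vertical field of view of the
original 3D setting is ignored because the arena is planar and all
avatars share one height, leaving the horizontal cone as the binding
constraint. Visibility has no distance cutoff (the walled arena is only
90 m across) and no occluders. Extraction yields one coin per two
seconds per extracting avatar (shared depletion); a depleted patch
respawns at a random location overlapping neither surviving patches nor
any avatar, keeping task structure constant. Patch placement also avoids
initial avatar positions. The simulation ticks at 25 Hz; movement is
forward-only with a 90°/s turn-rate cap, mirroring the three-key
(forward / turn left / turn right) control scheme; walls reflect the
heading.

The behavioral policy mirrors the statistical model: exploring avatars
follow a correlated random walk (per-second heading change
`~ von Mises(0, κ = 2)`); while any exploiting player is visible they
switch to relocation with per-second probability
`logit⁻¹(−3 + 1.5 − 0.05·D_m − 0.3·N + 0.2·T_min)` (raw cue scales:
meters, counts, minutes); relocating avatars head for their target at
full speed with a small per-second aiming error (`von Mises(0, κ = 100)`,
≈ 6° s.d. — human tracking is imperfect, and an error-free pursuit would
place all bearings on an atom at zero, outside the log-normal support)
and abandon pursuit with probability 0.15/s or when the target stops
exploiting. These defaults were chosen to produce unhurried, realistic
round dynamics: a 4-avatar concentrated round yields roughly 300–350
coins, ~20% of seconds spent exploiting and ~4–6% in social relocation.
Relocation requires a visible target, so the social state only occurs
while someone is exploiting — one of the simulator's tested invariants,
along with exact coin conservation, the per-tick displacement bound, and
bit-identical output under a fixed seed.

What the generator does *not* emulate: memory-guided systematic search,
occlusion, heterogeneous avatar skill, interference competition, and the
coin-collection mini-game's motor component. Passing recovery tests on
this generator therefore demonstrates that the inference machinery is
correct and well-calibrated *for data generated by its own model class*;
it does not certify the model as a complete description of human
foragers.

## 5. The feature pipeline

`resample_to_1hz()` reduces raw 25 Hz trajectories by sample-and-hold at
the tick nearest each second boundary. `state_series()` then computes,
per forager-second, the three observation channels, the four predictors,
the validity mask, minute-of-round, and segment structure. The pipeline
and the simulator share one implementation of the visibility and
social-channel geometry (`fov_visible()`, `social_channels()`), and a
test asserts that the pipeline reproduces, at every valid second,
exactly the `V`, `D` and `N` values the simulated avatars acted on.

Patch identity for an exploiting player is inferred from position: the
unique active patch whose disc contains the player (patches cannot
overlap, and extraction only happens inside a disc). The time since
success runs from the round start before a forager's first extraction —
"time unsuccessful" is well defined from zero at the start.

## 6. Behavioral metrics

A *scrounging opportunity* is one (focal, patch-lifetime) pair at which
the focal observed at least one exploiting group member while not
exploiting; it is *joined* when the focal's first extraction at that
patch follows the first observation. One opportunity per patch-lifetime
(not per observation second) keeps the denominator interpretable as
"patches where social information was available". Discovering a patch
with no prior observation of diggers there is not scrounging. The
empirical joined/observed ratio is the default estimator; rates are
undefined (NA), not zero, for foragers who never observed anyone.
The minimal join criterion — arrival during the patch lifetime after
first observation, with no minimum observation duration — is adopted
deliberately; any stricter criterion would need a justification the data
cannot supply.

The exploitation time-course uses the same monotonic minute effect as
the switching model, on a Bernoulli second-level indicator aggregated to
condition × minute binomial counts (an identical likelihood at a
fraction of the cost). It carries condition intercepts only: the
estimand of interest is the population curve per condition.

## 7. Time-lagged Gaussian-process regression

To relate a group's past spatial/visual organization to current
collective success, the package fits a distributed-lag binomial model
per condition:

`y_t ~ Binomial(g, logit⁻¹(a + Σ_τ (β̄ + d_τ) x_{t−τ}))`

where `y_t` is the number of players exploiting at second `t`, `g` the
group size, and `x` the z-scored predictor (mean pairwise distance, or
the count of directed visibility edges, 0–12 for four players since
exploiting players see no one). The lag grid is every second up to 30 s
plus every 5 s up to 180 s — 60 distinct lags in one model. The offsets
`d` follow a zero-mean multivariate Gaussian with squared-exponential
covariance `K(τ_x, τ_y) = η · exp(−ρ (τ_y − τ_x)² / τ_max²)`, so nearby
lags shrink together and the per-lag weights `β̄ + d_τ` form a smooth
curve; `η` and `ρ` are estimated.

Each observed second enters the likelihood exactly once. The alternative
of stacking one pseudo-observation per (t, lag) pair duplicates every
outcome across the lag grid and overstates the information roughly
L-fold; in testing it produced confidently nonzero lag effects on null
data, while the joint form's intervals cover zero across the entire lag
grid — this is why the joint form is the implemented one. The offsets
use the non-centered parameterization `d = √η · L(ρ)ᵀ z` (with `L` the
Cholesky factor of the correlation kernel): optimizing the centered form
collapses `η` at the mode (the usual funnel) and undercovers, whereas
transforming draws of `(η, ρ, z)` propagates hyperparameter uncertainty
into the lag-effect intervals.

Two mechanical couplings to keep in mind when interpreting short lags:
exploiting players are invisible to others by design, so visibility
edges drop while many players extract, and the outcome at `t` shares
mechanics with the predictor at small `τ`. Distance and visibility are
fitted in separate models, one predictor per model.

## 8. Numerical choices

* Angles live in `(−π, π]`; the wrapped difference maps `−π` to `+π`.
* Log-space forward recursion with a pairwise log-sum-exp that survives
  `−Inf` (impossible states).
* Viterbi ties prefer state I, at every backpointer and at the final
  state — arbitrary but fixed.
* The von Mises density uses the exponentially scaled Bessel function,
  finite up to very large κ; sampling uses the Best–Fisher rejection
  method.
* HPDI = narrowest sorted-draw window containing ⌈0.9 n⌉ draws.
* z-scores use the sample (denominator n−1) standard deviation; a
  two-point series maps to ±1/√2.
* The Hessian at the mode is symmetrized and, if needed, ridge-jittered
  until a Cholesky factorization exists; a fit needing more than a
  relative `1e-4` ridge is flagged as non-converged.
* Rejection-sampled patch placement fails loudly after a stated retry
  budget (default 10,000) rather than degrading the non-overlap
  guarantee.

## 9. Problem sizes used by the tests

The recovery study fits 40 synthetic players (20 per incentive
condition, each with one concentrated and one distributed round of ~300
valid seconds) — about 24,000 modeled seconds in 700 segments — in the
fixed-effects mode, and checks mean absolute recovery error of the
switching intercept and visibility weight across the four conditions,
relative emission-mean error, draw-level label ordering, and aggregate
interval calibration. State recovery runs the full pipeline on eight
simulated rounds (~35,000 seconds, enough that parameter-estimation
error no longer dominates the decoding error) and requires ≥ 90%
agreement between the decoded and true states on modeled seconds. The lag-GP recovery uses four 720 s
group series on a 27-lag grid, checking null coverage and the recovery
of an injected short-positive/long-negative crossover. These sizes were
chosen as the smallest at which the estimators' asymptotic behavior is
visibly established; all are seeded and deterministic.

## 10. Known limitations

* The Laplace backend is a mode-centered approximation; tail summaries
  (extreme evidence ratios) inherit Gaussian tails.
* Random-effect covariances among decision weights are not modeled.
* The S→I transition carries no covariates.
* Visibility is a planar cone without occlusion; gaze direction is
  equated with heading.
* The generator's exploration is memoryless; real foragers search
  systematically, so decoded state shares on real data should be
  validated against behavioral ground truth where available.
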