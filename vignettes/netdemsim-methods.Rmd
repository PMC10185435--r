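---
title: "Simulating co-capture data and estimating social effects on survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating co-capture data and estimating social effects on survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`netdemsim` generates longitudinal datasets in which capture–recapture
records simultaneously encode social associations ("co-capture" data), with
the true relationships between network position and survival known by
construction. This vignette documents the models behind each stage, the
parameters that matter, the numerical conventions, and the design choices
made where more than one reasonable construction existed.

## The generative model, stage by stage

### Population and space

A population of `n` individuals is assigned to `ng` social groups placed
uniformly at random in the **unit square**; all members of a group share
its location, and with `ng = n` every individual has its own location (no
group structure). The package deliberately does not scale the spatial
extent with `n`: distances are in unit-square units, so population density
— and hence the reach of spatial effects on the network — grows with `n`.
Comparisons across population sizes should keep this in mind.

Survival is realized as independent Bernoulli draws from each
individual's survival probability. Recruitment, when enabled, draws
`Poisson(N_surv · (1/s̄ − 1))` recruits, where `s̄` is the mean survival
probability of the pre-step alive population. The per-survivor rate
`1/s̄ − 1` exactly offsets expected mortality, so the expected population
size is stationary — recruitment is *strongly* density-dependent by
design, a tool for holding the population roughly constant rather than a
demographic model in its own right. We scale the rate by the number of
survivors because that is the only scaling that delivers this
stationarity. Recruits join existing groups (group-structured case) or
reuse locations vacated by deaths before drawing fresh ones (no-group
case). Dead individuals are retained with `alive = FALSE` so that row
indexing of capture histories never shifts; ids are never reused, and
group membership is fixed for life.

### The underlying network

Networks come from an adapted stochastic block model in which *blocks are
the prespecified social groups*. Edge presence and edge weight are sampled
independently per dyad: presence is Bernoulli with the block's baseline
probability, and weight (given presence) is Beta with parameters
moment-matched to the block's target mean and variance
(`α = mν`, `β = (1−m)ν`, `ν = m(1−m)/v − 1`). Between-block baselines
(probability and weight mean) are multiplied by `1/d_eff^distance`;
within-block dyads are co-located so the modifier is vacuous for them.
Covariate effects enter **additively on the probability and weight-mean
scales** (each endpoint contributes, then values are clipped to
`(10⁻⁶, 1 − 10⁻⁶)`); a logit-scale option is available via
`effect_scale = "logit"`. Additive-with-clipping was chosen as the
simplest construction consistent with trait effects acting separately on
within- and between-block edges; the clip is logged by a warning when it
binds.

Network dynamics: after each demographic timestep dead individuals are
dropped, recruits' dyads are drawn fresh from the generative model, each
survivor is independently selected with probability `p_individual`, and
every edge incident to a selected individual is re-drawn with probability
`p_edge` (a dyad re-draws if *either* endpoint triggers it, so the
per-dyad refresh rate between survivors is `1 − (1 − p_ind·p_edge)²`).
Re-drawn edges use the same generative model, so rewiring does not change
the network's statistical character, only its volatility.

"Moderate spatial structure" in the case-study configurations is encoded
as `d_eff = 4` with a between-block baseline probability of 0.2 and weight
mean 0.25 (weight variances 0.02 between, 0.04 within). The decay base is
a free knob: at `d_eff = 4` an average unit-square separation (~0.5)
halves the baseline.

### Grouping events

At each behavioural timestep the alive population is partitioned into
grouping events. Target event sizes are drawn as
`1 + Poisson(mean_group_size − 1)` until they cover the population (the
last event is truncated), which guarantees isolates occur and matches the
target mean. Each event is seeded with a uniformly random unassigned
individual; subsequent members join with probability proportional to
`(∏w + Σw/pm + float)^pow`, where `w` are the candidate's edge weights to
current members. `float > 0` keeps assignment feasible even for socially
isolated individuals — with `float = 0` and an empty neighbourhood the
partition can become impossible, and the generator stops with an error.
Defaults `pm = 1`, `float = 0.05`, `pow = 2` give event compositions that
clearly reflect network structure while leaving isolates common; they are
package conventions (exposed in `grouping_config()`), not estimates of
anything.

Association networks are rebuilt from GBIs with the **simple ratio
index**: co-occurrence count divided by the number of behavioural
timesteps both individuals were available — the standard index for
group-based association data. Because the partition generator places every
individual in exactly one event per timestep, the denominator is simply
`n_ts`.

`check_interaction_network()` quantifies fidelity by per-individual
strength/betweenness correlations and a matrix regression of event-derived
on underlying edge weights with a QAP-style node-label permutation test
(default 1000 permutations; `p = (1 + #{|slope*| ≥ |slope|}) / (n_perm + 1)`).

### Survival from network position

`covariates_survival()` builds
`logit(s_i) = logit(baseline) + Σ_t β_t·trait_{i,t} + β_net·z_i + ε_i`,
with `z` the chosen measure — strength (row sums) or weighted betweenness
(shortest paths with edge length `1/weight`) — **scaled to mean 0 and unit
sample SD (divisor n − 1) within the timestep**. A constant measure scales
to all zeros. Effects are strictly additive on the logit scale;
interactions are intentionally unsupported. Probabilities are clipped to
`(10⁻⁶, 1 − 10⁻⁶)`.

Optional network covariance makes strongly connected individuals' survival
deviations correlated (positive mode) or anti-correlated (negative): the
weight matrix (off-diagonal negated for the negative mode) with unit
diagonal is projected to the nearest positive semi-definite matrix by
eigenvalue clipping at zero, rescaled to unit diagonal, jittered by
`10⁻⁸`, and multiplied by `covariance_scale²` (default scale 0.5 on the
logit SD scale — the magnitude of "positive/negative covariance" is not
quantified by the study designs this emulates, so it is an exposed knob).

### Observation

Sampling is two-stage: events are detected with `pcg` (captures) or `pmg`
(observations), individuals within detected events with `pci`/`pmi`.
Captures mark; observations only register already-marked individuals.
Individuals are marked *immediately*, within the timestep of capture; in
timesteps designated for both processes only captures run, so the
immediate-marking convention never lets a same-timestep observation
depend on it. An individual in an undetected event cannot be detected that
timestep. Detections collapse to behavioural capture histories and then,
by OR-reduction over each demographic step's behavioural timesteps, to
demographic capture histories.

## The CJS model and imputation

Survival between demographic occasions `t` and `t+1` is
`φ_{i,t} = logit⁻¹(β0 + β_sex·sex_i + β_net·x_{i,t})` with a constant
capture probability `p`. The likelihood marginalizes the latent
alive/dead process with a forward recursion (compiled, Rcpp) from each
individual's first occasion. Two conditioning modes:

* **Pre-marked population** (`condition_on_first_capture = FALSE`): every
  individual is known alive at occasion 1; first-occasion detections enter
  the likelihood as Bernoulli(`p`) terms.
* **Conditioned on first capture** (default): standard CJS; individuals
  never detected are excluded.

The covariate `x_{i,t}` is the network measure scaled within each
demographic timestep, computed either from the full interaction network
(all grouping events; defined for every alive individual) or from the
sampled network (detected individuals only). Missing cells — undetected
individuals, or occasions after death where the model still needs a value
— are **latent parameters**, not plug-ins: each gets a
`Normal(mean, SD)` prior from `impute_covariate()` and is sampled within
the MCMC. Cross-sectional imputation takes moments across individuals
observed at the same timestep; longitudinal imputation takes them within
the individual across its observed timesteps, falling back to the overall
moments for individuals observed at most once. Treating imputed values as
latent is what makes the two modes differ in posterior *width* and not
just location; zero-SD cells are held fixed.

Priors are Gaussian for the survival-scale parameters and Uniform(0, 1)
for `p`. The default survival prior is `Normal(0, 10)`: weakly
informative on the logit scale, since a prior centred away from zero
(e.g. at +10) would push survival toward 1 and amount to a strong claim
about the system. The prior mean and SD are both configurable.

The sampler is adaptive random-walk Metropolis-within-Gibbs: scalar
updates for `β0`, `β_sex`, `β_net` (Gaussian proposals, step sizes
adapted toward 0.44 acceptance during burn-in only), a reflected-reject
walk for `p`, and independence proposals from the imputation prior for
the latent covariates, accepted per individual (valid because the
likelihood factorizes over individuals). Default chain: 3000 iterations,
burn-in 500, thinning 5 → 500 retained draws, a budget that the
parameter-recovery tests show is sufficient for these model sizes.

Summaries per parameter: posterior median, SD, `Pr(> 0)`, the **89%
highest density interval** (shortest contiguous interval containing
`⌈0.89·n⌉` sorted draws), and whether it excludes zero. Statistical power
for a parameter cell is the fraction of *converged* replicate fits whose
HDI excludes zero. Convergence is screened by k-means (`k = 6`) on the
standardized (median, SD) pairs of the social-effect posterior across
runs, flagging clusters whose mean posterior SD exceeds twice the global
median SD — a mechanical rule chosen so the screen needs no visual
inspection; with fewer runs than clusters all runs pass (with a
warning). Paired full/partial posteriors are compared by the
1-D Wasserstein-1 (earth mover's) distance of their draws.

## Case-study workflows

`case_study1_config()` encodes: 200 individuals, no group structure,
moderate spatial structure, 10 demographic × 5 behavioural timesteps,
mean event size 2, sex assigned 50/50, female baseline survival 0.8, sex
effect 0.5, no recruitment, the whole population pre-marked, captures in
all 50 behavioural timesteps with individual detection 0.9 and group
capture probability `pcg` ∈ {0.25, 0.5, 0.75}. The grid over measure
(strength/betweenness) × effect (0/0.4/0.8) × survival covariance
(neg/none/pos) × rewiring (0/0.1/0.5) × `pcg` has 162 cells
(`case_study1_grid()`); four model versions (M1–M4: sampled vs full
network measure × cross-sectional vs longitudinal imputation) are fitted
per dataset.

`case_study2_config()` differs in: 20 behavioural timesteps per step,
recruitment on, rewiring 0.1, initially unmarked population, captures
only in the first behavioural timestep of each step (90% of groups, 0.9
within), and observation designs pairing event probability
{0.1, 0.2, 0.4, 1} with {19, 10, 5, 2} sampled timesteps (observed
timesteps spread evenly across 2..20) and within-group observation
probability {0.5, 0.75, 1}; optionally 20 social groups with within-group
edge probability 0.5 and weight mean 0.5. The grid has 144 cells
(`case_study2_grid()`). Fits condition on first capture and use the
sampled-network measure with cross-sectional imputation (the package's
choice; the strong-effect power cells are insensitive to it).

Per demographic timestep the survival covariate is the measure from *that
step's own* interaction network (all of its grouping events), which is
also exactly the full-network covariate handed to M3/M4 — so full-network
fits probe estimation error only, while partial-network fits additionally
probe sampling-induced attenuation.

The replicated example cells in the tests and the acceptance script fix
rewiring at 0 and covariance at "none": the imputation and power
patterns of interest are driven by the sampling process and the measure,
not by these two grid dimensions.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed; `run_case_study()`
derives one seed per replicate (`seed + 7919·r`, with the fit seeded at
`replicate seed + model index`) and records it in the results table, so
any run can be replayed exactly. The bundled test suite exercises the
full pipeline at reduced scale (populations of 40–100, 3–6 timesteps) and
the power/calibration properties at the full study scale of 200
individuals with 10–40 replicates per cell; `scripts/acceptance.R` runs
selected table cells at the study's 20 replicates. These sizes are the
package's own verification choices and can be scaled up freely.

## What passing tests do and do not show

The generator emulates: block/spatially structured weighted networks,
network-driven group formation with isolates, logit-additive trait and
network effects on survival, density-dependent recruitment, and two-stage
imperfect detection with marking. It does **not** emulate: triadic
closure or assortativity beyond what blocks and space induce, interaction
(non-additive) effects, dynamic group membership, age structure,
immigration, trap response, misidentification, tag loss, or higher-order
(hypergraph) interaction processes. Results about imputation and sampling
design obtained on these simulations therefore transfer to real systems
only insofar as those systems resemble this generative world; in
particular, real networks with heavy-tailed degree or strong individual
detection heterogeneity may behave differently.

Known limitations worth restating: simple mean/SD imputation of network
measures is structurally unable to undo sampling-induced attenuation of
network–survival effects (the package reproduces this as downward-biased
`β_net` from partial networks — that is the scientific point, not a
defect); the convergence screen is a heuristic; and `p` is constant
across occasions by design.
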