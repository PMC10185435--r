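# netdemsim

Simulation of integrated social network and capture–recapture
("co-capture") datasets, and Bayesian survival analysis on them.

Many wild-population studies record *who was caught or observed together*:
the same field data yield both a capture–recapture dataset and a social
network. Linking the two — estimating how an individual's network position
affects its survival — is methodologically hard, because undetected
individuals have missing network measures and sampled networks are biased
versions of the true ones. `netdemsim` lets researchers generate
longitudinal co-capture datasets with *known* statistical relationships and
then test how well an analysis pipeline recovers them, supporting power
analyses and sampling-design comparisons for animal social network studies.

## What the package simulates

1. **Population** — `n` individuals in `ng` social groups placed uniformly
   in the unit square; per-individual traits (factors or covariates);
   stochastic survival and strongly density-dependent recruitment
   (`recruits ~ Poisson(N_surv (1/s̄ − 1))`, keeping the expected
   population size stationary).
2. **Underlying social network** — an adapted stochastic block model:
   edge presence `~ Bernoulli(p_block)` and edge weight
   `~ Beta(α, β)` (moment-matched to a block-specific mean/variance),
   independently per dyad; between-block baselines decay with distance as
   `1/d_eff^distance`; trait effects shift probabilities and weight means
   additively; networks can be rewired between timesteps.
3. **Grouping events** — at each behavioural timestep the population is
   partitioned into events (isolates allowed); individuals join an event
   with probability proportional to
   `(∏w + Σw / pm + float)^pow` of their edge weights `w` to current
   members, so events mirror the network. Events are stored as
   group-by-individual (GBI) matrices; `gbi_to_network()` rebuilds an
   association network with the simple ratio index.
4. **Survival from network position** —
   `logit(s_i) = logit(baseline) + Σ β_trait + β_net · z_i + ε`, where
   `z_i` is the individual's strength or weighted betweenness scaled
   within the timestep, and `ε` is optionally multivariate normal with a
   network-derived (nearest-PD) covariance.
5. **Observation** — two-stage sampling of grouping events (event detected
   with `pcg`/`pmg`, individuals within with `pci`/`pmi`); captures mark
   individuals, observations only register marked ones; detections become
   behavioural- and demographic-timestep capture histories.
6. **Inference** — a Bayesian Cormack–Jolly–Seber model
   (`φ_{i,t} = logit⁻¹(β0 + β_sex sex_i + β_net x_{i,t})`, constant `p`)
   with the marginalized likelihood in compiled code, missing covariate
   values treated as latent parameters with cross-sectional or
   longitudinal imputation priors, 89% highest-density-interval summaries,
   earth mover's distances between paired posteriors, and a k-means
   convergence screen.

## Worked example

```r
library(netdemsim)

# one parameter cell of a power analysis: strength effect 0.8 on survival,
# half of all grouping events sampled
cfg <- case_study1_config(measure = "strength", effect = 0.8, pcg = 0.5)
sim <- run_demographic_loop(cfg, seed = 42)
sim$pop_size
#>  [1] 200 162 128 100  80  62  45  37  31  27

fit <- fit_cjs(build_cjs_data(sim, "full"), impute = "cross_sectional",
               seed = 1)
fit
#> Bayesian CJS fit (500 retained draws, cross_sectional imputation)
#>  parameter median      sd pr_gt0 hdi_lower hdi_upper hdi_excludes_zero
#>         b0  1.307 0.14577  1.000    1.0684     1.544              TRUE
#>      b_sex  0.422 0.18485  0.988    0.0934     0.669              TRUE
#>      b_net  0.842 0.11881  1.000    0.6570     1.039              TRUE
#>          p  0.933 0.00911  1.000    0.9181     0.947              TRUE
```

The population declines from 200 to 27 over ten demographic timesteps (no
recruitment in this design). The fit recovers the simulated truth: baseline
female survival 0.8 (`b0` ≈ logit(0.8) = 1.39), sex effect 0.5, network
effect 0.8, and the per-timestep detection probability implied by sampling
half of all events (`p` ≈ 0.95). `b_net`'s 89% HDI excludes zero, so this
run counts as a detection; `run_case_study()` repeats this over replicate
datasets and model versions (full vs sampled network measure,
cross-sectional vs longitudinal imputation) and reports statistical power
per cell.

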