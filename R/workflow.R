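#' Build a simulation configuration
#'
#' Bundles every stage's parameters for [run_demographic_loop()]. The two
#' case-study constructors ([case_study1_config()], [case_study2_config()])
#' fill this in with the conditions of the two bundled case studies.
#'
#' @param n,ng Population size and number of groups.
#' @param n_dem,n_beh Number of demographic timesteps and behavioural
#'   timesteps per demographic timestep.
#' @param traits Trait specification list ([generate_traits()]).
#' @param network A [network_params()] object.
#' @param rewire A [rewire_params()] object.
#' @param grouping A [grouping_config()] object (`n_ts` is overridden by
#'   `n_beh`).
#' @param survival A [survival_spec()] object; its `net_measure` also
#'   selects the covariate recorded for model fitting.
#' @param cap_beh,obs_beh Behavioural timesteps (within each demographic
#'   step, 1-based) at which captures / observations occur.
#' @param pcg,pci,pmg,pmi Detection probabilities, see
#'   [sampling_design()].
#' @param pre_marked Logical; is the whole initial population marked before
#'   the study?
#' @param recruit Logical; simulate recruitment?
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 200, ng = 200, n_dem = 10, n_beh = 5,
                       traits = list(trait_factor("sex", c("F", "M"),
                                                  c(0.5, 0.5))),
                       network = network_params(d_eff = 4),
                       rewire = rewire_params(0, 0.5),
                       grouping = grouping_config(mean_group_size = 2),
                       survival = survival_spec(),
                       cap_beh = seq_len(n_beh), obs_beh = integer(),
                       pcg = 0.5, pci = 0.9, pmg = 1, pmi = 1,
                       pre_marked = TRUE, recruit = FALSE) {
  structure(list(n = n, ng = ng, n_dem = n_dem, n_beh = n_beh,
                 traits = traits, network = network, rewire = rewire,
                 grouping = grouping, survival = survival,
                 cap_beh = as.integer(cap_beh),
                 obs_beh = as.integer(obs_beh),
                 pcg = pcg, pci = pci, pmg = pmg, pmi = pmi,
                 pre_marked = pre_marked, recruit = recruit),
            class = "sim_config")
}

#' Case-study configurations
#'
#' `case_study1_config()`: 200 individuals with no group structure and
#' moderate spatial structure, 10 demographic x 5 behavioural timesteps,
#' mean grouping-event size 2, female baseline survival 0.8, sex effect 0.5
#' (logit scale), no recruitment, the whole population marked in advance,
#' captures in every behavioural timestep with individual detection 0.9.
#'
#' `case_study2_config()`: as above but 20 behavioural timesteps per
#' demographic step, recruitment on (approximately stationary population),
#' rewiring probability 0.1 (per-edge 0.5), the population initially
#' unmarked, captures only in the first behavioural timestep of each
#' demographic step (90% of groups, 0.9 within-group), and an observation
#' design spreading roughly constant effort (`pmg` x number of sampled
#' timesteps) across the rest of the step. With `structure = "groups"` the
#' population is split into 20 groups with within-group edge probability
#' 0.5 and weight mean 0.5 (between-group baselines 0.2 / 0.25 before
#' distance decay).
#'
#' @param measure Network measure driving survival (`"strength"` or
#'   `"betweenness"`).
#' @param effect Logit-scale effect of the scaled measure (0, 0.4, 0.8 in
#'   the study grids).
#' @param pcg Group capture probability (0.25 / 0.5 / 0.75 in the grid).
#' @param rewire_p Per-individual rewiring probability (0 / 0.1 / 0.5).
#' @param covariance Network covariance in survival (`"none"`,
#'   `"positive"`, `"negative"`).
#' @return A `sim_config` object.
#' @export
case_study1_config <- function(measure = "strength", effect = 0.8,
                               pcg = 0.5, rewire_p = 0,
                               covariance = "none") {
  n_beh <- 5L
  sim_config(
    n = 200, ng = 200, n_dem = 10, n_beh = n_beh,
    network = network_params(p_between = 0.2, w_between_mean = 0.25,
                             w_between_var = 0.02, d_eff = 4),
    rewire = rewire_params(rewire_p, 0.5),
    grouping = grouping_config(mean_group_size = 2),
    survival = survival_spec(baseline = 0.8,
                             trait_effects = list(sex = c(M = 0.5)),
                             net_measure = measure, net_effect = effect,
                             covariance_mode = covariance),
    cap_beh = seq_len(n_beh), obs_beh = integer(),
    pcg = pcg, pci = 0.9,
    pre_marked = TRUE, recruit = FALSE
  )
}

#' @rdname case_study1_config
#' @param structure `"none"` (no groups) or `"groups"` (20 groups).
#' @param pmg Probability of observing a grouping event in a sampled
#'   behavioural timestep (0.1 / 0.2 / 0.4 / 1 in the grid).
#' @param n_obs_ts Number of observed behavioural timesteps per demographic
#'   step (19 / 10 / 5 / 2, paired with `pmg` for constant effort).
#' @param pmi Probability of observing an individual in a sampled group
#'   (0.5 / 0.75 / 1).
#' @export
case_study2_config <- function(measure = "strength", effect = 0.8,
                               structure = c("none", "groups"),
                               pmg = 0.2, n_obs_ts = 10, pmi = 1,
                               rewire_p = 0.1) {
  structure <- match.arg(structure)
  n_beh <- 20L
  obs_beh <- round(seq(2, n_beh, length.out = n_obs_ts))
  sim_config(
    n = 200, ng = if (structure == "groups") 20 else 200,
    n_dem = 10, n_beh = n_beh,
    network = network_params(p_within = 0.5, p_between = 0.2,
                             w_within_mean = 0.5, w_within_var = 0.04,
                             w_between_mean = 0.25, w_between_var = 0.02,
                             d_eff = 4),
    rewire = rewire_params(rewire_p, 0.5),
    grouping = grouping_config(mean_group_size = 2),
    survival = survival_spec(baseline = 0.8,
                             trait_effects = list(sex = c(M = 0.5)),
                             net_measure = measure, net_effect = effect),
    cap_beh = 1L, obs_beh = obs_beh,
    pcg = 0.9, pci = 0.9, pmg = pmg, pmi = pmi,
    pre_marked = FALSE, recruit = TRUE
  )
}

#' Enumerate the full case-study parameter grids
#'
#' Returns one row per parameter cell of the full factorial designs: 162
#' cells for case study 1 (2 measures x 3 effects x 3 covariance modes x 3
#' rewiring probabilities x 3 group capture probabilities) and 144 for case
#' study 2 (2 measures x 3 effects x 2 structures x 4 sampling designs x 3
#' within-group observation probabilities). At 20 replicates per cell these
#' correspond to 3240 and 2880 simulated datasets; desk-scale analyses run
#' selected cells via [case_study1_config()] / [case_study2_config()].
#'
#' @return data.frame of parameter combinations.
#' @export
case_study1_grid <- function() {
  expand.grid(measure = c("strength", "betweenness"),
              effect = c(0, 0.4, 0.8),
              covariance = c("negative", "none", "positive"),
              rewire_p = c(0, 0.1, 0.5),
              pcg = c(0.25, 0.5, 0.75),
              stringsAsFactors = FALSE)
}

#' @rdname case_study1_grid
#' @export
case_study2_grid <- function() {
  designs <- data.frame(pmg = c(0.1, 0.2, 0.4, 1),
                        n_obs_ts = c(19, 10, 5, 2))
  g <- expand.grid(measure = c("strength", "betweenness"),
                   effect = c(0, 0.4, 0.8),
                   structure = c("none", "groups"),
                   design = seq_len(nrow(designs)),
                   pmi = c(0.5, 0.75, 1),
                   stringsAsFactors = FALSE)
  g$pmg <- designs$pmg[g$design]
  g$n_obs_ts <- designs$n_obs_ts[g$design]
  g$design <- NULL
  g
}

#' Read a simulation configuration from YAML
#'
#' Maps a YAML file with blocks `population` (size, groups), `timesteps`
#' (demographic, behavioural), `network`, `rewire`, `grouping`, `survival`
#' and `observation` onto [sim_config()]; omitted fields keep their
#' defaults. (Key names avoid bare `n`/`y`, which YAML 1.1 parses as
#' booleans.)
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$population)) {
    args$n <- y$population$size %||% 200
    args$ng <- y$population$groups %||% args$n
  }
  if (!is.null(y$timesteps)) {
    args$n_dem <- y$timesteps$demographic %||% 10
    args$n_beh <- y$timesteps$behavioural %||% 5
  }
  if (!is.null(y$network)) args$network <- do.call(network_params, y$network)
  if (!is.null(y$rewire)) args$rewire <- do.call(rewire_params, y$rewire)
  if (!is.null(y$grouping)) {
    args$grouping <- do.call(grouping_config, y$grouping)
  }
  if (!is.null(y$survival)) {
    sv <- y$survival
    if (!is.null(sv$trait_effects)) {
      sv$trait_effects <- lapply(sv$trait_effects, unlist)
    }
    args$survival <- do.call(survival_spec, sv)
  }
  if (!is.null(y$observation)) {
    for (nm in intersect(names(y$observation),
                         c("cap_beh", "obs_beh", "pcg", "pci", "pmg", "pmi",
                           "pre_marked", "recruit"))) {
      args[[nm]] <- y$observation[[nm]]
    }
  }
  do.call(sim_config, args)
}

#' Simulate one co-capture dataset
#'
#' Runs the full demographic loop: per demographic timestep, grouping
#' events are generated from the current underlying network, the
#' observation process samples them, the timestep's full interaction
#' network is built, the focal network measure is computed and scaled from
#' both the full and the sampled network, survival probabilities are set
#' from traits and the full interaction network, mortality (and optionally
#' recruitment) is realized, and the underlying network is updated for the
#' next step (dead removed, recruits wired in, survivors rewired).
#'
#' @param config A `sim_config` object.
#' @param seed Optional integer seed for the whole run.
#' @return An object of class `sim_dataset`: `capture` (a `capture_data`
#'   over all individuals ever alive), `x_full` / `x_partial` (individuals
#'   x demographic timesteps matrices of the scaled focal measure, `NA`
#'   where the individual was not alive / not detected), `sex` (0 =
#'   reference level), `alive` (logical matrix: alive during step),
#'   `true_surv` (simulated survival probabilities), `pop_size` (alive
#'   count per step), `ids`, `pop`, `traits`, `config`.
#' @export
run_demographic_loop <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gp <- generate_population(config$n, config$ng)
  pop <- gp$pop
  dist <- gp$dist
  traits <- generate_traits(config$traits, pop$id)
  net <- generate_network(pop, traits, dist, config$network)
  measure <- if (config$survival$net_measure == "none") "strength" else
    config$survival$net_measure
  gcfg <- config$grouping
  gcfg$n_ts <- config$n_beh

  grow <- function(m, k) rbind(m, matrix(NA_real_, k, ncol(m)))
  x_full <- matrix(NA_real_, config$n, config$n_dem)
  x_partial <- matrix(NA_real_, config$n, config$n_dem)
  true_surv <- matrix(NA_real_, config$n, config$n_dem)
  alive_mat <- matrix(FALSE, config$n, config$n_dem)
  pop_size <- integer(config$n_dem)
  obs_list <- vector("list", config$n_dem)
  marked <- if (config$pre_marked) pop$id else integer()

  for (t in seq_len(config$n_dem)) {
    alive <- which(pop$alive)
    pop_size[t] <- length(alive)
    alive_mat[alive, t] <- TRUE
    off <- (t - 1L) * config$n_beh
    gbi <- generate_grouping_events(pop, net, gcfg, ts_offset = off)
    des <- sampling_design(cap_ts = off + config$cap_beh,
                           obs_ts = off + config$obs_beh,
                           pcg = config$pcg, pci = config$pci,
                           pmg = config$pmg, pmi = config$pmi,
                           pre_cap = marked)
    o <- cap_and_obs(gbi, des)
    marked <- union(marked, o$marked)
    obs_list[[t]] <- o

    event_net <- gbi_to_network(gbi, n_ts = config$n_beh)
    x_full[alive, t] <-
      scale_within_timestep(network_measure(event_net, measure))

    det_mat <- (o$captured + o$observed) > 0
    det <- which(colSums(det_mat) > 0)
    if (length(det) >= 2L) {
      snet <- gbi_to_network(det_mat * 1L, n_ts = config$n_beh)
      snet <- snet[det, det, drop = FALSE]
      x_partial[alive[det], t] <-
        scale_within_timestep(network_measure(snet, measure))
    }

    pop <- covariates_survival(pop, traits, event_net, config$survival)
    true_surv[alive, t] <- pop$surv_prob[alive]

    step <- demographic_timestep(pop, recruit = config$recruit,
                                 timestep = t)
    pop <- step$pop
    dist <- step$dist
    if (step$n_recruits > 0L) {
      new_ids <- utils::tail(pop$id, step$n_recruits)
      traits <- add_recruit_traits(traits, config$traits, new_ids)
      x_full <- grow(x_full, step$n_recruits)
      x_partial <- grow(x_partial, step$n_recruits)
      true_surv <- grow(true_surv, step$n_recruits)
      alive_mat <- rbind(alive_mat,
                         matrix(FALSE, step$n_recruits, config$n_dem))
    }
    if (t < config$n_dem) {
      net <- rewire_network(net, pop, traits, dist, config$network,
                            config$rewire)
    }
  }
  capture <- cap_dat_gen(obs_list,
                         demographic_map = rep(seq_len(config$n_dem),
                                               each = config$n_beh),
                         ids = pop$id)
  structure(list(capture = capture, x_full = x_full,
                 x_partial = x_partial,
                 sex = as.numeric(traits$sex == "M"),
                 alive = alive_mat, true_surv = true_surv,
                 pop_size = pop_size, ids = pop$id, pop = pop,
                 traits = traits, config = config),
            class = "sim_dataset")
}

#' Assemble CJS model data from a simulated dataset
#'
#' @param sim A `sim_dataset` from [run_demographic_loop()].
#' @param network `"full"` (measure from all grouping events) or
#'   `"partial"` (measure from the sampled network only).
#' @return A [cjs_data()] object. For a pre-marked population every
#'   individual enters at occasion 1 and first-occasion detections inform
#'   `p`; otherwise the model conditions on first capture and
#'   never-detected individuals are dropped.
#' @export
build_cjs_data <- function(sim, network = c("full", "partial")) {
  network <- match.arg(network)
  x <- if (network == "full") sim$x_full else sim$x_partial
  ch <- sim$capture$demographic
  if (sim$config$pre_marked) {
    keep <- which(sim$alive[, 1])
    cjs_data(ch[keep, , drop = FALSE], sim$sex[keep],
             x[keep, , drop = FALSE],
             first = rep(1L, length(keep)),
             condition_on_first_capture = FALSE)
  } else {
    first <- apply(ch, 1, function(r) {
      w <- which(r == 1)
      if (length(w)) w[1] else NA_integer_
    })
    keep <- which(!is.na(first))
    cjs_data(ch[keep, , drop = FALSE], sim$sex[keep],
             x[keep, , drop = FALSE], first = first[keep],
             condition_on_first_capture = TRUE)
  }
}

.model_defs <- list(
  M1 = list(network = "partial", impute = "cross_sectional"),
  M2 = list(network = "partial", impute = "longitudinal"),
  M3 = list(network = "full", impute = "cross_sectional"),
  M4 = list(network = "full", impute = "longitudinal")
)

#' Run a replicated power analysis for one parameter cell
#'
#' Simulates `n_replicates` datasets from `config` and fits the requested
#' model versions to each (M1/M2: measure from the sampled network with
#' cross-sectional / longitudinal imputation; M3/M4: measure from the full
#' network). Each model's runs are screened for convergence with
#' [classify_convergence()], and statistical power is the fraction of
#' converged runs whose 89% HDI for the social effect excludes zero. When
#' both members of a full/partial pair with the same imputation mode are
#' fitted (M1 & M3, or M2 & M4), the earth mover's distance between their
#' social-effect posteriors is recorded per replicate.
#'
#' @param config A `sim_config` object (one cell of the parameter grid).
#' @param n_replicates Number of replicate datasets.
#' @param models Character subset of `c("M1", "M2", "M3", "M4")`.
#' @param seed Base seed; replicate r runs with `seed + 7919 * r`.
#' @param mcmc MCMC settings passed to [fit_cjs()].
#' @return List of class `results_table`: `results` (one row per run:
#'   replicate, model, seed, posterior median/SD, `pr_gt0`, HDI,
#'   `hdi_excludes_zero`, `converged`), `power` and `convergence_rate`
#'   (named by model), `emd` (data.frame, possibly empty).
#' @export
run_case_study <- function(config, n_replicates = 20, models = "M3",
                           seed = 1,
                           mcmc = list(iters = 3000, burnin = 500,
                                       thin = 5)) {
  stopifnot(all(models %in% names(.model_defs)))
  rows <- list()
  emd_rows <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- (seed + 7919L * r) %% .Machine$integer.max
    sim <- run_demographic_loop(config, seed = rseed)
    draws_net <- list()
    for (m in models) {
      def <- .model_defs[[m]]
      cd <- build_cjs_data(sim, def$network)
      fit <- fit_cjs(cd, impute = def$impute, mcmc = mcmc,
                     seed = rseed + match(m, names(.model_defs)))
      s <- fit$summary[fit$summary$parameter == "b_net", ]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, model = m, seed = rseed,
        median = s$median, sd = s$sd, pr_gt0 = s$pr_gt0,
        hdi_lower = s$hdi_lower, hdi_upper = s$hdi_upper,
        hdi_excludes_zero = s$hdi_excludes_zero
      )
      draws_net[[m]] <- fit$draws$b_net
    }
    for (pair in list(c("M1", "M3"), c("M2", "M4"))) {
      if (all(pair %in% models)) {
        emd_rows[[length(emd_rows) + 1L]] <- data.frame(
          replicate = r, imputation = .model_defs[[pair[1]]]$impute,
          emd = emd(draws_net[[pair[1]]], draws_net[[pair[2]]])
        )
      }
    }
  }
  results <- do.call(rbind, rows)
  results$converged <- TRUE
  for (m in models) {
    idx <- results$model == m
    results$converged[idx] <-
      classify_convergence(results[idx, c("median", "sd")])
  }
  power <- vapply(models, function(m) {
    ok <- results$model == m & results$converged
    if (!any(ok)) return(NA_real_)
    mean(results$hdi_excludes_zero[ok])
  }, numeric(1))
  conv <- vapply(models, function(m) {
    mean(results$converged[results$model == m])
  }, numeric(1))
  structure(list(results = results, power = power,
                 convergence_rate = conv,
                 emd = if (length(emd_rows)) do.call(rbind, emd_rows)
                       else data.frame()),
            class = "results_table")
}

#' @export
print.results_table <- function(x, ...) {
  cat("Replicated power analysis\n")
  for (m in names(x$power)) {
    cat(sprintf("  %s: power %.2f (convergence %.2f, %d runs)\n", m,
                x$power[m], x$convergence_rate[m],
                sum(x$results$model == m)))
  }
  invisible(x)
}
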