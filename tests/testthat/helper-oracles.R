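# Independent oracles used across the test files. These deliberately use
# naive exhaustive algorithms, not the package's code paths.

# Exhaustive CJS likelihood: sum over every possible last-alive occasion.
# ch N x T, first 1-based, phi N x (T-1), constant p. When
# condition_first = FALSE the detection at the first occasion also counts
# (pre-marked population known alive at `first`).
cjs_loglik_enum <- function(ch, first, phi, p, condition_first = TRUE) {
  n <- nrow(ch)
  T <- ncol(ch)
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- first[i]
    if (f >= T) {
      out[i] <- if (condition_first) 0 else
        log(ifelse(ch[i, f] == 1, p, 1 - p))
      next
    }
    tot <- 0
    for (d in f:T) { # d = last occasion alive
      pr <- 1
      if (d > f) for (t in f:(d - 1)) pr <- pr * phi[i, t]
      if (d < T) pr <- pr * (1 - phi[i, d])
      occs <- if (condition_first) seq(f + 1, T) else seq(f, T)
      for (t in occs) {
        if (t <= d) {
          pr <- pr * ifelse(ch[i, t] == 1, p, 1 - p)
        } else if (ch[i, t] == 1) {
          pr <- 0
          break
        }
      }
      tot <- tot + pr
    }
    out[i] <- log(tot)
  }
  out
}

# Brute-force weighted betweenness: enumerate all simple paths per pair,
# keep the shortest (edge length = 1 / weight), count interior nodes.
betweenness_brute <- function(net) {
  n <- nrow(net)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (tt in seq(s + 1, n)) {
      best <- Inf
      best_paths <- list()
      visit <- function(path, cost) {
        v <- path[length(path)]
        if (v == tt) {
          if (cost < best - 1e-12) {
            best <<- cost
            best_paths <<- list(path)
          } else if (abs(cost - best) < 1e-12) {
            best_paths[[length(best_paths) + 1]] <<- path
          }
          return(invisible())
        }
        for (w in which(net[v, ] > 0)) {
          if (!(w %in% path) && cost + 1 / net[v, w] < best + 1e-12) {
            visit(c(path, w), cost + 1 / net[v, w])
          }
        }
      }
      visit(s, 0)
      if (is.finite(best) && length(best_paths) > 0) {
        for (pth in best_paths) {
          interior <- setdiff(pth, c(s, tt))
          bt[interior] <- bt[interior] + 1 / length(best_paths)
        }
      }
    }
  }
  bt
}

# Small ready-made population + network fixture.
tiny_world <- function(n = 12, ng = 3, seed = 1) {
  set.seed(seed)
  gp <- generate_population(n, ng)
  traits <- generate_traits(list(trait_factor("sex", c("F", "M"),
                                              c(0.5, 0.5))), gp$pop$id)
  net <- generate_network_basic(gp$pop, gp$dist,
                                network_params(p_within = 0.9,
                                               p_between = 0.3))
  list(pop = gp$pop, dist = gp$dist, traits = traits, net = net)
}

# Cache shared across test files (expensive replicate sweeps are computed
# once per session and reused by several assertions).
.oracle_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .oracle_cache)) {
    assign(key, force(expr), envir = .oracle_cache)
  }
  get(key, envir = .oracle_cache)
}

# Replicated power run for one CS1 cell, cached by its arguments.
cs1_power_runs <- function(measure, effect, models, n_replicates,
                           seed = 2024) {
  key <- paste("cs1", measure, effect, paste(models, collapse = "-"),
               n_replicates, seed, sep = "_")
  cached(key, {
    cfg <- case_study1_config(measure = measure, effect = effect,
                              pcg = 0.5)
    run_case_study(cfg, n_replicates = n_replicates, models = models,
                   seed = seed)
  })
}
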