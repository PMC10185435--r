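test_that("joining weight follows the product + scaled-sum + float rule", {
  expect_equal(joining_weight(c(0.5, 0.4), pm = 1, float = 0, pow = 1), 1.1)
  # float keeps joining possible with no connections
  expect_equal(joining_weight(c(0, 0, 0), pm = 1, float = 0.1, pow = 1),
               0.1)
  # pow = 2 squares the pow = 1 value
  w <- c(0.3, 0.8, 0.1)
  expect_equal(joining_weight(w, pm = 2, float = 0.05, pow = 2),
               joining_weight(w, pm = 2, float = 0.05, pow = 1)^2)
  expect_error(joining_weight(numeric(0)), "empty")
})

test_that("grouping events partition the population every timestep", {
  w <- tiny_world(n = 60, ng = 6, seed = 2)
  cfg <- grouping_config(mean_group_size = 2, n_ts = 5)
  gbi <- generate_grouping_events(w$pop, w$net, cfg, seed = 11)
  expect_s3_class(gbi, "gbi")
  expect_true(all(gbi$matrix %in% c(0L, 1L)))
  expect_true(all(rowSums(gbi$matrix) >= 1))
  # partition invariant: each individual in exactly one event per timestep
  for (t in unique(gbi$timestep)) {
    sub <- gbi$matrix[gbi$timestep == t, , drop = FALSE]
    expect_equal(unname(colSums(sub)), rep(1L, 60))
  }
  # realized mean event size near the target over seeds
  sizes <- unlist(lapply(1:10, function(s) {
    g <- generate_grouping_events(w$pop, w$net, cfg, seed = 100 + s)
    rowSums(g$matrix)
  }))
  expect_lt(abs(mean(sizes) - 2) / 2, 0.1)

  # mean size 1: everything is an isolate
  g1 <- generate_grouping_events(w$pop, w$net,
                                 grouping_config(mean_group_size = 1,
                                                 n_ts = 2), seed = 3)
  expect_true(all(rowSums(g1$matrix) == 1))
  expect_equal(nrow(g1$matrix), 120)
})

test_that("event composition reflects network structure", {
  # strong block network: within-event dyads should be same-group far more
  # often than under the float-only (uniform) null
  gp <- generate_population(60, 6, seed = 5)
  par <- network_params(p_within = 1, p_between = 1e-9,
                        w_within_mean = 0.7, w_within_var = 0.02)
  net <- generate_network_basic(gp$pop, gp$dist, par, seed = 1)
  same <- outer(gp$pop$group_id, gp$pop$group_id, `==`)
  frac_same <- function(g) {
    tot <- 0; sm <- 0
    for (r in seq_len(nrow(g$matrix))) {
      m <- which(g$matrix[r, ] == 1)
      if (length(m) < 2) next
      prs <- utils::combn(m, 2)
      tot <- tot + ncol(prs)
      sm <- sm + sum(same[t(prs)])
    }
    if (tot == 0) NA else sm / tot
  }
  cfg <- grouping_config(mean_group_size = 3, float = 0.01, n_ts = 3)
  g_struct <- generate_grouping_events(gp$pop, net, cfg, seed = 21)
  # float-only null: same generator on an empty network
  g_null <- generate_grouping_events(gp$pop, matrix(0, 60, 60), cfg,
                                     seed = 22)
  expect_gt(frac_same(g_struct), frac_same(g_null) + 0.2)

  # large float washes structure out toward the uniform partition
  cfg_f <- grouping_config(mean_group_size = 3, float = 1e6, n_ts = 3)
  g_flat <- generate_grouping_events(gp$pop, net, cfg_f, seed = 23)
  expect_lt(frac_same(g_flat), frac_same(g_struct))

  # zero float on an empty network cannot assign anyone
  expect_error(
    generate_grouping_events(gp$pop, matrix(0, 60, 60),
                             grouping_config(mean_group_size = 3,
                                             float = 0, n_ts = 1),
                             seed = 1),
    "joining weights"
  )
})

test_that("single-event sampling honours size and network affinity", {
  w <- tiny_world(n = 20, ng = 20, seed = 6)
  ev1 <- generate_single_event(w$pop, w$net, 1, seed = 1)
  expect_length(ev1, 1)
  evN <- generate_single_event(w$pop, w$net, 20, seed = 2)
  expect_setequal(evN, w$pop$id)
  expect_error(generate_single_event(w$pop, w$net, 21), "size")

  # two disjoint cliques, float -> 0: pair events stay within a clique
  net2 <- matrix(0, 10, 10, dimnames = list(1:10, 1:10))
  net2[1:5, 1:5] <- 0.8
  net2[6:10, 6:10] <- 0.8
  diag(net2) <- 0
  popc <- data.frame(id = 1:10, group_id = 1:10, x = 0, y = 0,
                     alive = TRUE, surv_prob = NA, entry_timestep = 0L)
  set.seed(31)
  cfg <- grouping_config(float = 1e-9)
  same_clique <- replicate(200, {
    ev <- generate_single_event(popc, net2, 2, cfg)
    all(ev <= 5) || all(ev > 5)
  })
  expect_gt(mean(same_clique), 0.98)
})

test_that("simple ratio index matches brute-force pair counting", {
  # a,b together in 3 of 5 timesteps -> 0.6; never together -> 0
  m <- matrix(0L, 5, 3, dimnames = list(NULL, 1:3))
  m[1, c(1, 2)] <- 1L; m[1, 3] <- 0L
  m[2, c(1, 2)] <- 1L
  m[3, c(1, 2)] <- 1L
  m[4, 1] <- 1L; m[4, 3] <- 1L
  m[5, 1] <- 1L
  net <- gbi_to_network(m, n_ts = 5)
  expect_equal(net[1, 2], 0.6)
  expect_equal(net[2, 3], 0)
  expect_equal(net[1, 3], 0.2)

  # random GBI vs brute-force co-occurrence counting
  set.seed(13)
  g <- matrix(rbinom(12 * 4, 1, 0.4), 12, 4)
  g[rowSums(g) == 0, 1] <- 1L
  expected <- matrix(0, 4, 4)
  for (a in 1:3) for (b in (a + 1):4) {
    expected[a, b] <- expected[b, a] <- sum(g[, a] == 1 & g[, b] == 1) / 3
  }
  expect_equal(unname(gbi_to_network(g, n_ts = 3)), expected)
  expect_error(gbi_to_network(g, n_ts = 0), "timestep")
})

test_that("fidelity check regression and permutation test behave", {
  w <- tiny_world(n = 40, ng = 4, seed = 8)
  gbi <- generate_grouping_events(w$pop, w$net,
                                  grouping_config(mean_group_size = 3,
                                                  float = 0.01,
                                                  n_ts = 20), seed = 9)
  enet <- gbi_to_network(gbi)
  # network regressed on itself: slope 1, intercept 0, minimal p
  self <- check_interaction_network(enet, enet, n_perm = 99, seed = 1)
  expect_equal(self$regression$slope, 1)
  expect_equal(self$regression$intercept, 0, tolerance = 1e-12)
  expect_equal(self$regression$p_value, 1 / 100)
  expect_equal(unname(self$measure_correlations), c(1, 1))

  # events generated from a structured network associate with it
  chk <- check_interaction_network(gbi, w$net, n_perm = 200, seed = 2)
  expect_gt(chk$regression$slope, 0)
  expect_lt(chk$regression$p_value, 0.05)
  expect_gt(chk$measure_correlations["strength"], 0)

  # independent unstructured network: p roughly uniform (here just:
  # frequently > 0.05). p_within = p_between and d_eff = 1 so the null
  # network shares no block/spatial structure with the event network.
  set.seed(33)
  ps <- replicate(20, {
    other <- generate_network_basic(w$pop, w$dist,
                                    network_params(p_within = 0.4,
                                                   p_between = 0.4,
                                                   w_within_mean = 0.5,
                                                   w_within_var = 0.04,
                                                   w_between_mean = 0.5,
                                                   w_between_var = 0.04))
    check_interaction_network(enet, other, n_perm = 99)$regression$p_value
  })
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(min(ps), 0.005)
})

test_that("GBIs round-trip through CSV", {
  w <- tiny_world(n = 10, ng = 2, seed = 4)
  gbi <- generate_grouping_events(w$pop, w$net,
                                  grouping_config(n_ts = 3), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gbi(gbi, path)
  back <- read_gbi(path)
  expect_equal(unname(back$matrix), unname(gbi$matrix))
  expect_equal(back$timestep, gbi$timestep)
  expect_equal(back$ids, gbi$ids)
})
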