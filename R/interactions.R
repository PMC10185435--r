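#' Configuration of grouping-event generation
#'
#' @param mean_group_size Target mean event size (>= 1). Event sizes are
#'   drawn as `1 + Poisson(mean_group_size - 1)`, so isolates (events of
#'   size 1) occur naturally.
#' @param pm Divisor adjusting the relative importance of the edge-weight
#'   sum versus the product in the joining rule.
#' @param float Additive constant preventing joining probabilities from all
#'   being zero; keep `> 0` or event assignment can fail.
#' @param pow Exponent applied to the final joining weight.
#' @param n_ts Number of behavioural timesteps to generate.
#' @return An object of class `grouping_config`.
#' @export
grouping_config <- function(mean_group_size = 2, pm = 1, float = 0.05,
                            pow = 2, n_ts = 1) {
  stopifnot(mean_group_size >= 1, pm > 0, float >= 0, pow > 0, n_ts >= 1)
  structure(list(mean_group_size = mean_group_size, pm = pm, float = float,
                 pow = pow, n_ts = as.integer(n_ts)),
            class = "grouping_config")
}

#' Joining weight of a candidate to a grouping event
#'
#' The (unnormalized) probability weight with which an unassigned individual
#' joins an event, given its edge weights to the current members:
#' `(prod(w) + sum(w) / pm + float)^pow`. A positive `float` means joining
#' is never impossible even with no social connections to members.
#'
#' @param weights Numeric vector of edge weights in \[0, 1\] to current
#'   members (length >= 1).
#' @param pm,float,pow Joining-rule constants, see [grouping_config()].
#' @return Non-negative scalar.
#' @export
#' @examples
#' joining_weight(c(0.5, 0.4), pm = 1, float = 0, pow = 1) # 1.1
joining_weight <- function(weights, pm = 1, float = 0.05, pow = 2) {
  if (length(weights) == 0L) {
    stop("empty member set: events are seeded separately", call. = FALSE)
  }
  stopifnot(pm > 0, pow > 0)
  (prod(weights) + sum(weights) / pm + float)^pow
}

# Vectorized joining weights: rows of `w` are candidates, columns members.
.joining_weights <- function(w, pm, float, pow) {
  pr <- w[, 1]
  sm <- w[, 1]
  if (ncol(w) > 1) {
    for (k in 2:ncol(w)) {
      pr <- pr * w[, k]
      sm <- sm + w[, k]
    }
  }
  (pr + sm / pm + float)^pow
}

# Build one event of target size from the unassigned pool (indices into net).
.build_event <- function(net, pool, size, cfg) {
  seed <- pool[sample.int(length(pool), 1L)]
  members <- seed
  pool <- setdiff(pool, seed)
  while (length(members) < size && length(pool) > 0L) {
    w <- net[pool, members, drop = FALSE]
    jw <- .joining_weights(w, cfg$pm, cfg$float, cfg$pow)
    if (all(jw <= 0)) {
      stop("all joining weights are zero; set a positive `float`",
           call. = FALSE)
    }
    pick <- if (length(pool) == 1L) 1L else
      sample.int(length(pool), 1L, prob = jw)
    members <- c(members, pool[pick])
    pool <- pool[-pick]
  }
  members
}

#' Generate grouping events from an underlying network
#'
#' For each of `cfg$n_ts` behavioural timesteps, partitions all alive
#' individuals into grouping events (size-1 events are isolates). Target
#' event sizes are drawn as `1 + Poisson(mean_group_size - 1)` until they
#' exhaust the population (the last event is truncated). Events are filled
#' sequentially: a uniformly random unassigned individual seeds the event,
#' then unassigned individuals join one at a time with probability
#' proportional to [joining_weight()] of their edge weights to current
#' members, so event composition reflects the underlying network.
#'
#' @param pop Population data.frame; alive individuals are partitioned.
#' @param net Underlying network over the alive individuals (dimnames =
#'   ids).
#' @param cfg A [grouping_config()] object.
#' @param seed Optional integer seed.
#' @param ts_offset Integer added to the 1..n_ts timestep labels (for
#'   globally numbered behavioural timesteps across demographic steps).
#' @return An object of class `gbi`: list with `matrix` (binary events x
#'   individuals incidence, colnames = ids), `timestep` (per-event
#'   behavioural timestep), `ids`.
#' @export
generate_grouping_events <- function(pop, net, cfg = grouping_config(),
                                     seed = NULL, ts_offset = 0L) {
  if (!is.null(seed)) set.seed(seed)
  ids <- pop$id[pop$alive]
  stopifnot(nrow(net) == length(ids))
  n <- length(ids)
  rows <- list()
  ts <- integer()
  for (t in seq_len(cfg$n_ts)) {
    sizes <- integer()
    while (sum(sizes) < n) {
      sizes <- c(sizes, 1L + stats::rpois(1L, cfg$mean_group_size - 1))
    }
    extra <- sum(sizes) - n
    sizes[length(sizes)] <- sizes[length(sizes)] - extra
    sizes <- sizes[sizes > 0L]
    pool <- seq_len(n)
    for (s in sizes) {
      ev <- .build_event(net, pool, s, cfg)
      pool <- setdiff(pool, ev)
      row <- integer(n)
      row[ev] <- 1L
      rows[[length(rows) + 1L]] <- row
      ts <- c(ts, t + ts_offset)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- ids
  structure(list(matrix = m, timestep = ts, ids = ids), class = "gbi")
}

#' Sample one grouping event of fixed size
#'
#' Builds a single event of exactly `size` members from the alive
#' population, using the same seeding and sequential joining rule as
#' [generate_grouping_events()].
#'
#' @inheritParams generate_grouping_events
#' @param size Event size, `1 <= size <=` number of alive individuals.
#' @return Integer vector of member ids.
#' @export
generate_single_event <- function(pop, net, size, cfg = grouping_config(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- pop$id[pop$alive]
  if (size < 1 || size > length(ids)) {
    stop("`size` must be between 1 and the number of alive individuals",
         call. = FALSE)
  }
  ids[.build_event(net, seq_along(ids), size, cfg)]
}

#' Association network from a group-by-individual matrix
#'
#' Builds a weighted network from grouping events with the simple ratio
#' index: `weight(a, b) = co-occurrences / n_ts`, where `n_ts` is the
#' number of behavioural timesteps covered by the GBI (every individual is
#' in exactly one event per timestep, so the pair was available in all of
#' them).
#'
#' @param gbi A `gbi` object (or a plain binary matrix, in which case
#'   `n_ts` must be given).
#' @param n_ts Optional denominator override.
#' @return Symmetric association matrix with zero diagonal, dimnames = ids.
#' @export
gbi_to_network <- function(gbi, n_ts = NULL) {
  if (inherits(gbi, "gbi")) {
    m <- gbi$matrix
    if (is.null(n_ts)) n_ts <- length(unique(gbi$timestep))
  } else {
    m <- gbi
    if (is.null(n_ts)) stop("`n_ts` required for a plain matrix",
                            call. = FALSE)
  }
  if (n_ts < 1) stop("need at least one behavioural timestep", call. = FALSE)
  cc <- crossprod(m)
  diag(cc) <- 0
  cc / n_ts
}

#' Compare an event-derived network with the underlying network
#'
#' Computes (a) Pearson correlations of per-individual strength and
#' weighted betweenness between the event-derived network and the
#' underlying network, and (b) a matrix regression of event-derived on
#' underlying edge weights with a QAP-style permutation p-value: the node
#' labels of the predictor matrix are permuted `n_perm` times and the
#' absolute regression slope compared with the observed one.
#'
#' @param gbi A `gbi` object or an association matrix already derived from
#'   events.
#' @param net Underlying network (same node set and order).
#' @param n_perm Number of node-label permutations.
#' @param seed Optional integer seed.
#' @return An object of class `network_check`: list with
#'   `measure_correlations` (strength, betweenness), `regression` (slope,
#'   intercept, p_value, n_perm).
#' @export
check_interaction_network <- function(gbi, net, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enet <- if (inherits(gbi, "gbi")) gbi_to_network(gbi) else gbi
  stopifnot(all(dim(enet) == dim(net)))
  cors <- c(
    strength = stats::cor(network_measure(enet, "strength"),
                          network_measure(net, "strength")),
    betweenness = stats::cor(network_measure(enet, "betweenness"),
                             network_measure(net, "betweenness"))
  )
  reg <- .qap_regression(enet, net, n_perm)
  structure(list(measure_correlations = cors, regression = reg),
            class = "network_check")
}

# OLS of upper-triangle y-weights on x-weights + node-label permutation test.
.qap_regression <- function(y, x, n_perm) {
  ut <- upper.tri(y)
  yv <- y[ut]
  xv <- x[ut]
  if (stats::sd(yv) == 0 || stats::sd(xv) == 0) {
    stop("constant edge weights: regression undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, xv), yv)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  n <- nrow(y)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    xp <- x[perm, perm][ut]
    s <- stats::cov(yv, xp) / stats::var(xp)
    if (abs(s) >= abs(slope)) exceed <- exceed + 1L
  }
  list(slope = slope, intercept = intercept,
       p_value = (exceed + 1L) / (n_perm + 1L), n_perm = n_perm)
}

#' @export
print.network_check <- function(x, ...) {
  cat("Event-network fidelity check\n")
  cat(sprintf("  strength correlation:    %.3f\n",
              x$measure_correlations["strength"]))
  cat(sprintf("  betweenness correlation: %.3f\n",
              x$measure_correlations["betweenness"]))
  cat(sprintf("  edge regression: slope %.3f, intercept %.3f, p = %.4g (%d perms)\n",
              x$regression$slope, x$regression$intercept,
              x$regression$p_value, x$regression$n_perm))
  invisible(x)
}

#' Read/write group-by-individual matrices
#'
#' CSV round-trip for `gbi` objects with a leading `timestep` column and one
#' column per individual id.
#'
#' @param gbi A `gbi` object.
#' @param path File path.
#' @export
write_gbi <- function(gbi, path) {
  out <- data.frame(timestep = gbi$timestep)
  m <- as.data.frame(gbi$matrix)
  names(m) <- paste0("id_", gbi$ids)
  utils::write.csv(cbind(out, m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gbi
#' @export
read_gbi <- function(path) {
  x <- utils::read.csv(path)
  ts <- as.integer(x$timestep)
  m <- as.matrix(x[, -1, drop = FALSE])
  ids <- as.integer(sub("^id_", "", colnames(m)))
  colnames(m) <- ids
  structure(list(matrix = m, timestep = ts, ids = ids), class = "gbi")
}
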