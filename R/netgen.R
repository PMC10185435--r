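#' Beta distribution parameters from a mean and variance
#'
#' Moment-matches a Beta(alpha, beta) distribution to a target mean and
#' variance. Requires `var < mean * (1 - mean)`.
#'
#' @param mean Target mean in (0, 1).
#' @param var Target variance, `0 < var < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_params_from_moments(0.5, 1 / 12) # uniform: alpha = beta = 1
beta_params_from_moments <- function(mean, var) {
  if (mean <= 0 || mean >= 1) stop("`mean` must be in (0, 1)", call. = FALSE)
  if (var <= 0 || var >= mean * (1 - mean)) {
    stop("`var` must be in (0, mean * (1 - mean))", call. = FALSE)
  }
  nu <- mean * (1 - mean) / var - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Spatial decay of edge probabilities and weights
#'
#' Multiplies a baseline edge probability or weight mean by
#' `1 / d_eff^distance`, the distance-decay used for between-block dyads.
#' With `d_eff = 1` or `distance = 0` the baseline is unchanged.
#'
#' @param base Baseline value(s) in \[0, 1\].
#' @param d_eff Decay base, `>= 1`.
#' @param distance Non-negative distance(s) (unit-square units).
#' @return `base / d_eff^distance`, clipped to \[0, 1\].
#' @export
spatial_modifier <- function(base, d_eff, distance) {
  if (any(d_eff < 1)) stop("`d_eff` must be >= 1", call. = FALSE)
  if (any(distance < 0)) stop("`distance` must be >= 0", call. = FALSE)
  pmin(pmax(base / d_eff^distance, 0), 1)
}

#' Parameters of the network generative model
#'
#' Collects the parameters of the adapted stochastic block model used to
#' generate underlying social networks: block membership is the prespecified
#' social group, edge presence and edge weight are sampled independently,
#' weights are Beta-distributed with moment-matched parameters, and
#' between-block baselines (probability and weight mean) decay with the
#' spatial distance between groups as `1 / d_eff^distance`.
#'
#' Covariate effects enter additively on the probability scale and on the
#' weight-mean scale (then clipped to `(1e-6, 1 - 1e-6)`), or on the logit
#' scale when `effect_scale = "logit"`. Each element of `covariate_effects`
#' is a list with `trait` (column in the trait table), optionally `level`
#' (for factor traits: the effect applies per endpoint carrying that level;
#' numeric traits use the trait value itself per endpoint), and any of
#' `prob_within`, `prob_between`, `weight_within`, `weight_between` additive
#' coefficients. A dyad receives the sum of its two endpoints'
#' contributions.
#'
#' @param p_within,p_between Baseline edge probabilities in \[0, 1\].
#' @param w_within_mean,w_within_var,w_between_mean,w_between_var Beta
#'   moment targets for edge weights.
#' @param d_eff Spatial decay base, `>= 1` (1 = no spatial structure).
#' @param covariate_effects List of effect specifications (see Details).
#' @param effect_scale `"probability"` (additive with clipping) or
#'   `"logit"`.
#' @return An object of class `network_params`.
#' @export
network_params <- function(p_within = 0.5, p_between = 0.2,
                           w_within_mean = 0.5, w_within_var = 0.04,
                           w_between_mean = 0.25, w_between_var = 0.02,
                           d_eff = 1, covariate_effects = list(),
                           effect_scale = c("probability", "logit")) {
  stopifnot(
    w_within_var < w_within_mean * (1 - w_within_mean),
    w_between_var < w_between_mean * (1 - w_between_mean),
    d_eff >= 1
  )
  structure(
    list(p_within = p_within, p_between = p_between,
         w_within_mean = w_within_mean, w_within_var = w_within_var,
         w_between_mean = w_between_mean, w_between_var = w_between_var,
         d_eff = d_eff, covariate_effects = covariate_effects,
         effect_scale = match.arg(effect_scale)),
    class = "network_params"
  )
}

#' Rewiring parameters for dynamic networks
#'
#' @param p_individual Probability that a surviving individual rewires any of
#'   its relationships after a demographic timestep.
#' @param p_edge Per-edge probability of change, given the individual rewires.
#' @return An object of class `rewire_params`.
#' @export
rewire_params <- function(p_individual = 0, p_edge = 0.5) {
  stopifnot(p_individual >= 0, p_individual <= 1, p_edge >= 0, p_edge <= 1)
  structure(list(p_individual = p_individual, p_edge = p_edge),
            class = "rewire_params")
}

.clip_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# Per-individual covariate contribution vectors for one effect entry.
.effect_contrib <- function(eff, traits, ids) {
  v <- traits[[eff$trait]][match(ids, traits$id)]
  if (is.null(v)) stop("trait not found: ", eff$trait, call. = FALSE)
  if (is.factor(v) || is.character(v)) {
    if (is.null(eff$level)) {
      stop("factor trait effect needs a `level`", call. = FALSE)
    }
    as.numeric(v == eff$level)
  } else {
    as.numeric(v)
  }
}

# Dyadic additive adjustment matrices for probability and weight mean.
.covariate_adjustments <- function(params, traits, ids) {
  n <- length(ids)
  z <- matrix(0, n, n)
  adj <- list(prob_within = z, prob_between = z,
              weight_within = z, weight_between = z)
  for (eff in params$covariate_effects) {
    contrib <- .effect_contrib(eff, traits, ids)
    dy <- outer(contrib, contrib, `+`)
    for (slot in names(adj)) {
      if (!is.null(eff[[slot]])) adj[[slot]] <- adj[[slot]] + eff[[slot]] * dy
    }
  }
  adj
}

# Dyad-level edge probability and weight-mean matrices implied by the model.
.edge_model <- function(pop, traits, dist, params) {
  alive <- which(pop$alive)
  ids <- pop$id[alive]
  n <- length(ids)
  same <- outer(pop$group_id[alive], pop$group_id[alive], `==`)
  d <- dist[alive, alive, drop = FALSE]

  p <- ifelse(same, params$p_within,
              spatial_modifier(params$p_between, params$d_eff, d))
  m <- ifelse(same, params$w_within_mean,
              spatial_modifier(params$w_between_mean, params$d_eff, d))
  if (length(params$covariate_effects) > 0 && !is.null(traits)) {
    adj <- .covariate_adjustments(params, traits, ids)
    if (params$effect_scale == "logit") {
      p <- stats::plogis(stats::qlogis(.clip_unit(p)) +
                           ifelse(same, adj$prob_within, adj$prob_between))
      m <- stats::plogis(stats::qlogis(.clip_unit(m)) +
                           ifelse(same, adj$weight_within, adj$weight_between))
    } else {
      p <- p + ifelse(same, adj$prob_within, adj$prob_between)
      m <- m + ifelse(same, adj$weight_within, adj$weight_between)
      if (any(p < 0 | p > 1) || any(m <= 0 | m >= 1)) {
        warning("covariate-adjusted probabilities/means clipped to (0, 1)")
      }
    }
  }
  list(ids = ids, n = n, same = same,
       p = .clip_unit(p), m = .clip_unit(m),
       v = ifelse(same, params$w_within_var, params$w_between_var))
}

# Sample a full symmetric weighted adjacency from dyad-level p/m/v matrices.
.sample_edges <- function(em) {
  n <- em$n
  net <- matrix(0, n, n, dimnames = list(em$ids, em$ids))
  if (n < 2) return(net)
  ut <- upper.tri(net)
  p <- em$p[ut]
  m <- em$m[ut]
  v <- pmin(em$v[ut], m * (1 - m) * 0.999) # keep beta moments feasible
  present <- stats::runif(length(p)) < p
  w <- numeric(length(p))
  if (any(present)) {
    nu <- m[present] * (1 - m[present]) / v[present] - 1
    w[present] <- stats::rbeta(sum(present), m[present] * nu,
                               (1 - m[present]) * nu)
  }
  net[ut] <- w
  net + t(net)
}

#' Generate an underlying weighted social network
#'
#' Samples a symmetric weighted adjacency matrix over the alive individuals
#' from the adapted stochastic block model described in [network_params()]:
#' within-block dyads use the within-group baselines, between-block dyads the
#' (spatially decayed) between-group baselines, covariates shift
#' probabilities and weight means additively, edge presence is Bernoulli and
#' edge weight (given presence) Beta with the block's moment-matched
#' parameters.
#'
#' @param pop Population data.frame; only alive individuals enter the
#'   network, node order follows their order in `pop`.
#' @param traits Trait data.frame (or NULL if no covariate effects).
#' @param dist Distance matrix aligned with `pop` rows.
#' @param params A [network_params()] object.
#' @param seed Optional integer seed.
#' @return Symmetric matrix of edge weights in \[0, 1\], zero diagonal,
#'   dimnames set to individual ids.
#' @export
generate_network <- function(pop, traits, dist, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .sample_edges(.edge_model(pop, traits, dist, params))
}

#' @rdname generate_network
#' @export
generate_network_basic <- function(pop, dist, params, seed = NULL) {
  params$covariate_effects <- list()
  generate_network(pop, NULL, dist, params, seed = seed)
}

#' Update a network after a demographic timestep
#'
#' Removes dead individuals, draws edges for recruits from the generative
#' model, and optionally rewires surviving individuals' relationships: each
#' survivor is independently selected with probability `p_individual`, and
#' every edge incident to a selected individual is independently re-drawn
#' from the generative model with probability `p_edge` (a dyad is re-drawn
#' if either endpoint triggers it). Unselected survivor-survivor dyads are
#' carried over unchanged.
#'
#' @param old_net Previous network (dimnames = ids).
#' @param new_pop Population after [demographic_timestep()].
#' @param traits Trait data.frame (or NULL).
#' @param dist Distance matrix aligned with `new_pop`.
#' @param params A [network_params()] object.
#' @param rewire A [rewire_params()] object.
#' @param seed Optional integer seed.
#' @return Updated symmetric weighted adjacency over alive individuals of
#'   `new_pop`.
#' @export
rewire_network <- function(old_net, new_pop, traits, dist, params,
                           rewire = rewire_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  em <- .edge_model(new_pop, traits, dist, params)
  fresh <- .sample_edges(em)
  ids <- em$ids
  old_ids <- as.integer(rownames(old_net))
  surv <- ids %in% old_ids
  n <- length(ids)
  net <- fresh
  if (any(surv)) {
    sel <- surv & (stats::runif(n) < rewire$p_individual)
    ut <- which(upper.tri(net), arr.ind = TRUE)
    both_surv <- surv[ut[, 1]] & surv[ut[, 2]]
    # a dyad is re-drawn if either endpoint was selected and its own
    # per-edge Bernoulli(p_edge) fires
    m <- nrow(ut)
    redraw <- (sel[ut[, 1]] & stats::runif(m) < rewire$p_edge) |
      (sel[ut[, 2]] & stats::runif(m) < rewire$p_edge)
    keep <- both_surv & !redraw
    if (any(keep)) {
      old_pos <- match(ids, old_ids)
      ki <- ut[keep, , drop = FALSE]
      old_w <- old_net[cbind(old_pos[ki[, 1]], old_pos[ki[, 2]])]
      net[ki] <- old_w
      net[ki[, c(2, 1), drop = FALSE]] <- old_w
    }
  }
  diag(net) <- 0
  net
}
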