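#' Individual network position measures
#'
#' Computes per-individual centrality from a weighted network. `strength`
#' is the row sum of edge weights (weighted degree). `betweenness` is
#' weighted betweenness with edge length `1 / weight` (stronger ties are
#' shorter paths), computed with igraph.
#'
#' @param net Symmetric weighted adjacency matrix.
#' @param measure `"strength"` or `"betweenness"`.
#' @return Numeric vector, one value per node (network order).
#' @export
network_measure <- function(net, measure = c("strength", "betweenness")) {
  measure <- match.arg(measure)
  if (measure == "strength") return(unname(rowSums(net)))
  if (all(net == 0)) return(numeric(nrow(net)))
  g <- igraph::graph_from_adjacency_matrix(net, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  unname(igraph::betweenness(g, weights = 1 / igraph::E(g)$weight))
}

#' Mean-centre and scale a covariate within a timestep
#'
#' Standardizes a vector to mean 0 and unit sample standard deviation
#' (divisor `n - 1`). A constant (or length-1) vector maps to zeros.
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
scale_within_timestep <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Network-structured covariance for survival
#'
#' Builds a covariance matrix from a social network so that strongly
#' connected individuals have correlated (positive mode) or anti-correlated
#' (negative mode) deviations in survival. The weight matrix (off-diagonal
#' negated for the negative mode) with unit diagonal is projected to the
#' nearest positive semi-definite matrix by eigenvalue clipping at zero
#' (plus `1e-8` jitter), rescaled to unit diagonal, and multiplied by
#' `scale^2`.
#'
#' @param net Symmetric weighted adjacency matrix.
#' @param mode `"none"`, `"positive"` or `"negative"`.
#' @param scale Logit-scale standard deviation of the induced noise.
#' @return Covariance matrix (zero matrix for mode `"none"`).
#' @export
network_covariance <- function(net, mode = c("none", "positive", "negative"),
                               scale = 0.5) {
  mode <- match.arg(mode)
  n <- nrow(net)
  if (mode == "none") return(matrix(0, n, n))
  a <- if (mode == "positive") net else -net
  diag(a) <- 1
  e <- eigen(a, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  p <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(p), 1e-12))
  p <- p / outer(d, d)
  diag(p) <- 1
  scale^2 * (p + diag(1e-8, n))
}

#' Survival-effect specification
#'
#' @param baseline Reference-class survival probability in (0, 1) (e.g.
#'   females with average network position).
#' @param trait_effects Named list: trait name -> logit-scale coefficient.
#'   For a factor trait supply a named vector of per-level effects (the
#'   reference level implicitly 0), e.g. `list(sex = c(M = 0.5))`; for a
#'   numeric trait a single coefficient.
#' @param net_measure `"strength"`, `"betweenness"` or `"none"`.
#' @param net_effect Logit-scale coefficient of the scaled network measure.
#' @param covariance_mode `"none"`, `"positive"` or `"negative"` network
#'   covariance in survival.
#' @param covariance_scale Logit-scale SD of the network-structured noise.
#' @return An object of class `survival_spec`.
#' @export
survival_spec <- function(baseline = 0.8, trait_effects = list(),
                          net_measure = c("strength", "betweenness", "none"),
                          net_effect = 0,
                          covariance_mode = c("none", "positive", "negative"),
                          covariance_scale = 0.5) {
  stopifnot(baseline > 0, baseline < 1)
  structure(
    list(baseline = baseline, trait_effects = trait_effects,
         net_measure = match.arg(net_measure), net_effect = net_effect,
         covariance_mode = match.arg(covariance_mode),
         covariance_scale = covariance_scale),
    class = "survival_spec"
  )
}

#' Simulate survival probabilities from traits and network position
#'
#' Sets `surv_prob` for every alive individual as
#' `logit(s_i) = logit(baseline) + sum(trait effects) + net_effect *
#' scaled_measure_i + eps`, where the network measure is computed from
#' `net`, scaled within the timestep ([scale_within_timestep()]), and `eps`
#' is multivariate normal with [network_covariance()] (zero when
#' `covariance_mode = "none"`). Effects are strictly additive on the logit
#' scale; no interactions. Probabilities are clipped to
#' `(1e-6, 1 - 1e-6)`.
#'
#' @param pop Population data.frame.
#' @param traits Trait data.frame.
#' @param net Network over alive individuals (e.g. the timestep's
#'   interaction network from [gbi_to_network()]).
#' @param spec A [survival_spec()] object.
#' @param seed Optional integer seed.
#' @return `pop` with `surv_prob` filled in for alive individuals.
#' @export
covariates_survival <- function(pop, traits, net, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alive <- which(pop$alive)
  n <- length(alive)
  stopifnot(nrow(net) == n)
  lp <- rep(stats::qlogis(spec$baseline), n)
  ids <- pop$id[alive]
  for (nm in names(spec$trait_effects)) {
    v <- traits[[nm]][match(ids, traits$id)]
    if (is.null(v)) stop("trait not found: ", nm, call. = FALSE)
    eff <- spec$trait_effects[[nm]]
    if (is.factor(v) || is.character(v)) {
      contrib <- rep(0, n)
      for (lev in names(eff)) contrib[v == lev] <- eff[[lev]]
      lp <- lp + contrib
    } else {
      lp <- lp + eff * as.numeric(v)
    }
  }
  if (spec$net_measure != "none" && spec$net_effect != 0) {
    msr <- scale_within_timestep(network_measure(net, spec$net_measure))
    lp <- lp + spec$net_effect * msr
  }
  if (spec$covariance_mode != "none") {
    sig <- network_covariance(net, spec$covariance_mode,
                              spec$covariance_scale)
    lp <- lp + as.numeric(MASS::mvrnorm(1, mu = rep(0, n), Sigma = sig))
  }
  pop$surv_prob[alive] <- pmin(pmax(stats::plogis(lp), 1e-6), 1 - 1e-6)
  pop
}

#' Constant population-level survival probabilities
#'
#' @param n Number of individuals.
#' @param s Survival probability in (0, 1\].
#' @return Numeric vector `rep(s, n)`.
#' @export
basic_survival <- function(n, s) {
  stopifnot(s > 0, s <= 1)
  rep(s, n)
}
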