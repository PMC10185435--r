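#' Generate a group-structured population in 2-D space
#'
#' Creates a population of `n` individuals assigned to `ng` social groups
#' distributed uniformly at random in the unit square. When `n == ng` every
#' individual has its own location (no group structure); when `n > ng` the
#' `ng` group locations are drawn and all members of a group share their
#' group's location. Distances are therefore in unit-square units and the
#' density of the population scales with `n`.
#'
#' @param n Population size.
#' @param ng Number of social groups, `1 <= ng <= n`.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{pop}{data.frame with columns `id`, `group_id`, `x`, `y`,
#'       `alive`, `surv_prob` (NA until set), `entry_timestep` (0 for
#'       founders). Carries an attribute `ng`.}
#'     \item{dist}{`n` x `n` Euclidean distance matrix between individual
#'       locations (zero within groups).}
#'   }
#' @export
#' @examples
#' p <- generate_population(20, 4, seed = 1)
#' table(p$pop$group_id)
generate_population <- function(n, ng, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  ng <- as.integer(ng)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (length(ng) != 1L || is.na(ng) || ng < 1L || ng > n) {
    stop("`ng` must satisfy 1 <= ng <= n", call. = FALSE)
  }
  gx <- stats::runif(ng)
  gy <- stats::runif(ng)
  if (n == ng) {
    group_id <- seq_len(n)
  } else {
    # every group gets at least one member; remainder assigned at random
    group_id <- c(seq_len(ng), sample(ng, n - ng, replace = TRUE))
    group_id <- sample(group_id) # shuffle so group blocks are not contiguous
  }
  pop <- data.frame(
    id = seq_len(n),
    group_id = group_id,
    x = gx[group_id],
    y = gy[group_id],
    alive = TRUE,
    surv_prob = NA_real_,
    entry_timestep = 0L
  )
  attr(pop, "ng") <- ng
  list(pop = pop, dist = distance_matrix(pop))
}

#' Euclidean distance matrix for a population
#'
#' @param pop Population data.frame as returned by [generate_population()].
#' @return Symmetric matrix of pairwise Euclidean distances, rows/columns in
#'   the order of `pop`.
#' @export
distance_matrix <- function(pop) {
  d <- as.matrix(stats::dist(cbind(pop$x, pop$y)))
  dimnames(d) <- list(pop$id, pop$id)
  d
}

#' Generate individual trait data
#'
#' Draws stochastic trait values for a set of individuals. Each trait is
#' specified as either a continuous covariate with a named distribution or a
#' categorical factor with levels and level probabilities.
#'
#' @param spec A list of trait specifications. Each element is a list with
#'   `name`, `kind` (`"covariate"` or `"factor"`) and, for covariates,
#'   `dist` (`"normal"`, `"uniform"` or `"lognormal"`) plus `params`
#'   (arguments passed to the corresponding `r*` function); for factors,
#'   `levels` (character) and `probs` (probabilities summing to 1).
#' @param ids Integer vector of individual ids (one row generated per id).
#' @param seed Optional integer seed.
#'
#' @return data.frame with column `id` plus one column per trait (factors as
#'   factor columns with the declared levels).
#' @export
#' @examples
#' spec <- list(trait_factor("sex", c("F", "M"), c(0.5, 0.5)))
#' generate_traits(spec, 1:5, seed = 1)
generate_traits <- function(spec, ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(spec) == 0L) stop("`spec` must be non-empty", call. = FALSE)
  if (length(ids) == 0L) stop("`ids` must be non-empty", call. = FALSE)
  out <- data.frame(id = ids)
  for (tr in spec) {
    out[[tr$name]] <- draw_trait(tr, length(ids))
  }
  out
}

draw_trait <- function(tr, n) {
  kind <- match.arg(tr$kind, c("covariate", "factor"))
  if (kind == "factor") {
    if (is.null(tr$levels) || is.null(tr$probs) ||
        length(tr$levels) != length(tr$probs)) {
      stop("factor trait needs matching `levels` and `probs`", call. = FALSE)
    }
    factor(sample(tr$levels, n, replace = TRUE, prob = tr$probs),
           levels = tr$levels)
  } else {
    fun <- switch(tr$dist,
      normal = stats::rnorm,
      uniform = stats::runif,
      lognormal = stats::rlnorm,
      stop("unknown covariate distribution: ", tr$dist, call. = FALSE)
    )
    do.call(fun, c(list(n), as.list(tr$params %||% list())))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname generate_traits
#' @param name Trait name.
#' @param levels Factor levels.
#' @param probs Level probabilities.
#' @export
trait_factor <- function(name, levels, probs) {
  list(name = name, kind = "factor", levels = levels, probs = probs)
}

#' @rdname generate_traits
#' @param dist Distribution name for a covariate trait.
#' @param params List of distribution parameters.
#' @export
trait_covariate <- function(name, dist = "normal", params = list()) {
  list(name = name, kind = "covariate", dist = dist, params = params)
}

#' Add trait rows for newly recruited individuals
#'
#' Extends an existing trait table with stochastic draws for recruits, using
#' the same trait specification as the founders. Existing rows are unchanged.
#'
#' @param traits Existing trait data.frame.
#' @param spec Trait specification list (as for [generate_traits()]).
#' @param new_ids Ids of the recruits; must not overlap existing ids.
#' @param seed Optional integer seed.
#' @return The extended trait data.frame.
#' @export
add_recruit_traits <- function(traits, spec, new_ids, seed = NULL) {
  if (length(new_ids) == 0L) return(traits)
  if (any(new_ids %in% traits$id)) {
    stop("`new_ids` overlap existing ids", call. = FALSE)
  }
  rbind(traits, generate_traits(spec, new_ids, seed = seed))
}

#' Simulate one demographic timestep: survival and recruitment
#'
#' Each alive individual survives independently with its `surv_prob`. If
#' `recruit = TRUE`, the number of recruits is Poisson distributed with rate
#' `N_surv * (1 / mean(surv_prob) - 1)`, where the mean is taken over the
#' pre-step alive population — with constant mean survival this keeps the
#' expected population size approximately stationary (strong density
#' dependence). Recruits join existing groups when the population is
#' group-structured; with no group structure they reuse locations vacated by
#' deaths where available and otherwise receive fresh uniform locations.
#' Dead individuals are retained with `alive = FALSE` so that row indexing of
#' downstream capture histories is stable.
#'
#' @param pop Population data.frame (attribute `ng` set), all alive rows with
#'   `surv_prob` in \[0, 1\].
#' @param recruit Logical; simulate recruitment?
#' @param timestep Integer recorded as `entry_timestep` for recruits.
#' @param seed Optional integer seed.
#'
#' @return A list with `pop` (updated, recruits appended), `dist` (updated
#'   distance matrix over all rows), `survivors` (logical over the pre-step
#'   alive individuals, in `pop` order) and `n_recruits`.
#' @export
demographic_timestep <- function(pop, recruit = TRUE, timestep = 1L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alive_idx <- which(pop$alive)
  if (length(alive_idx) == 0L) {
    stop("population is empty: no alive individuals", call. = FALSE)
  }
  sp <- pop$surv_prob[alive_idx]
  if (anyNA(sp) || any(sp < 0 | sp > 1)) {
    stop("all alive individuals need `surv_prob` in [0, 1]", call. = FALSE)
  }
  ng <- attr(pop, "ng")
  grouped <- !is.null(ng) && ng < sum(pop$entry_timestep == 0L)
  survived <- stats::runif(length(alive_idx)) < sp
  dead_now <- alive_idx[!survived]
  pop$alive[dead_now] <- FALSE

  n_recruits <- 0L
  if (recruit) {
    sbar <- mean(sp)
    lambda <- if (sbar > 0) sum(survived) * (1 / sbar - 1) else 0
    n_recruits <- stats::rpois(1L, lambda)
  }
  if (n_recruits > 0L) {
    new_ids <- max(pop$id) + seq_len(n_recruits)
    if (grouped) {
      g <- sample(sort(unique(pop$group_id)), n_recruits, replace = TRUE)
      gx <- pop$x[match(g, pop$group_id)]
      gy <- pop$y[match(g, pop$group_id)]
    } else {
      # reuse vacated (dead individuals') locations first, then fresh draws
      vac <- which(!pop$alive)
      take <- vac[seq_len(min(length(vac), n_recruits))]
      n_new <- n_recruits - length(take)
      g <- max(pop$group_id) + seq_len(n_recruits) # singleton groups
      gx <- c(pop$x[take], stats::runif(n_new))
      gy <- c(pop$y[take], stats::runif(n_new))
    }
    rec <- data.frame(
      id = new_ids, group_id = g, x = gx, y = gy,
      alive = TRUE, surv_prob = NA_real_,
      entry_timestep = as.integer(timestep)
    )
    pop <- rbind(pop, rec)
  }
  attr(pop, "ng") <- ng
  list(pop = pop, dist = distance_matrix(pop),
       survivors = survived, n_recruits = n_recruits)
}

#' Read/write population tables
#'
#' Round-trip a population data.frame to CSV. The `ng` attribute is stored in
#' a comment-free extra column on write and restored on read.
#'
#' @param pop Population data.frame.
#' @param path File path.
#' @export
write_population <- function(pop, path) {
  out <- pop
  out$.ng <- attr(pop, "ng") %||% NA_integer_
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  x <- utils::read.csv(path)
  ng <- x$.ng[1]
  x$.ng <- NULL
  x$entry_timestep <- as.integer(x$entry_timestep)
  attr(x, "ng") <- as.integer(ng)
  x
}
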