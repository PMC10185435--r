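#' Assemble data for the Bayesian CJS model
#'
#' @param ch Binary N x T demographic capture-history matrix.
#' @param sex Numeric vector (0 = reference class, 1 = other) of length N.
#' @param x N x T matrix of the scaled network measure, `NA` where
#'   unobserved (the per-timestep scaling is assumed already applied).
#'   Columns `1..T-1` drive survival from occasion `t` to `t + 1`.
#' @param first Integer vector of first-capture occasions (1-based). For a
#'   fully pre-marked population use `first = 1` for everyone and
#'   `condition_on_first_capture = FALSE`, in which case the occasion-1
#'   detections also inform the capture probability.
#' @param condition_on_first_capture Logical; if TRUE the detection at the
#'   first-capture occasion is conditioned on (standard CJS).
#' @return An object of class `cjs_data`.
#' @export
cjs_data <- function(ch, sex, x, first,
                     condition_on_first_capture = TRUE) {
  ch <- matrix(as.integer(ch > 0), nrow(ch), ncol(ch))
  stopifnot(length(sex) == nrow(ch), all(dim(x) == dim(ch)),
            length(first) == nrow(ch), all(first >= 1))
  structure(list(ch = ch, sex = as.numeric(sex), x = x,
                 first = as.integer(first),
                 condition_on_first_capture =
                   isTRUE(condition_on_first_capture)),
            class = "cjs_data")
}

#' Impute moments for missing network-measure values
#'
#' Produces per-cell prior means and SDs for missing entries of a scaled
#' covariate matrix. Cross-sectional imputation uses the mean and SD of the
#' observed individuals at the same timestep (column); longitudinal
#' imputation uses the individual's own observed timesteps (row), falling
#' back to the overall observed mean/SD for individuals observed at most
#' once. Observed cells get their value with SD 0; a zero imputation SD
#' falls back to the overall SD.
#'
#' @param x Matrix with `NA` for missing cells.
#' @param mode `"cross_sectional"` or `"longitudinal"`.
#' @return List with matrices `mean` and `sd` (same shape as `x`).
#' @export
impute_covariate <- function(x, mode = c("cross_sectional",
                                         "longitudinal")) {
  mode <- match.arg(mode)
  obs <- !is.na(x)
  if (!any(obs)) stop("no observed covariate values", call. = FALSE)
  overall_mean <- mean(x[obs])
  overall_sd <- stats::sd(x[obs])
  if (!is.finite(overall_sd) || overall_sd == 0) overall_sd <- 1
  mu <- x
  sdm <- matrix(0, nrow(x), ncol(x))
  miss <- which(!obs, arr.ind = TRUE)
  if (nrow(miss) > 0) {
    if (mode == "cross_sectional") {
      cm <- apply(x, 2, function(v) mean(v, na.rm = TRUE))
      cs <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE))
      empty <- !is.finite(cm)
      if (any(empty[unique(miss[, 2])])) {
        warning("timestep(s) with no observed individuals: using overall moments")
      }
      cm[!is.finite(cm)] <- overall_mean
      cs[!is.finite(cs) | cs == 0] <- overall_sd
      mu[miss] <- cm[miss[, 2]]
      sdm[miss] <- cs[miss[, 2]]
    } else {
      rn <- rowSums(obs)
      rm_ <- ifelse(rn >= 2, rowMeans(x, na.rm = TRUE), overall_mean)
      rs <- apply(x, 1, function(v) stats::sd(v, na.rm = TRUE))
      rs[rn < 2 | !is.finite(rs) | rs == 0] <- overall_sd
      mu[miss] <- rm_[miss[, 1]]
      sdm[miss] <- rs[miss[, 1]]
    }
  }
  list(mean = mu, sd = sdm)
}

#' Marginalized CJS log-likelihood
#'
#' Per-individual log-likelihood of a CJS capture history, marginalized
#' over the latent alive/dead process by a forward recursion from each
#' individual's first occasion. Survival is
#' `phi[i, t] = plogis(b0 + b_sex * sex_i + b_net * x[i, t])` and the
#' capture probability `p` is constant.
#'
#' @param data A [cjs_data()] object.
#' @param params Named list/vector with `b0`, `b_sex`, `b_net`, `p`.
#' @param x Optional covariate matrix overriding `data$x` (e.g. with
#'   imputed draws filled in); must contain no `NA` in used cells.
#' @param sum Logical, return the total (TRUE) or per-individual vector.
#' @return Log-likelihood (total or per individual). For a pre-marked
#'   population (`condition_on_first_capture = FALSE`) the first-occasion
#'   detections contribute Bernoulli(`p`) terms.
#' @export
cjs_log_likelihood <- function(data, params, x = NULL, sum = TRUE) {
  if (is.null(x)) x <- data$x
  xs <- x
  xs[is.na(xs)] <- 0 # unused cells only; used cells must be filled
  ll <- cjs_loglik_indiv_or_reg(data, params, xs)
  if (!data$condition_on_first_capture) {
    y1 <- data$ch[cbind(seq_len(nrow(data$ch)), data$first)]
    ll <- ll + ifelse(y1 == 1, log(params$p), log1p(-params$p))
  }
  if (sum) base::sum(ll) else ll
}

cjs_loglik_indiv_or_reg <- function(data, params, xs) {
  cjs_loglik_reg(data$ch, data$first, data$sex, xs,
                 params$b0, params$b_sex, params$b_net, params$p)
}

#' Fit the Bayesian CJS model with covariate imputation
#'
#' Metropolis-within-Gibbs sampler for the CJS model with a time-varying
#' individual network covariate. Regression parameters (`b0`, `b_sex`,
#' `b_net`) get Gaussian priors and adaptive random-walk updates; the
#' capture probability `p` gets a Uniform(0, 1) prior; missing covariate
#' cells are latent parameters with Normal(mean, SD) priors from
#' [impute_covariate()], updated by independence proposals from their
#' prior (cells with SD 0 are held fixed).
#'
#' @param data A [cjs_data()] object.
#' @param impute Imputation mode, see [impute_covariate()].
#' @param priors List with `mean` and `sd` of the Gaussian prior on the
#'   survival-scale parameters (default Normal(0, 10)).
#' @param mcmc List with `iters`, `burnin`, `thin`. The defaults (3000,
#'   500, 5) retain 500 draws.
#' @param seed Optional integer seed.
#' @return An object of class `cjs_fit`: `draws` (data.frame of retained
#'   draws of `b0`, `b_sex`, `b_net`, `p`), `summary` (per-parameter
#'   median, SD, `pr_gt0`, 89% HDI bounds, `hdi_excludes_zero`),
#'   `settings`, `acceptance` rates.
#' @export
fit_cjs <- function(data, impute = c("cross_sectional", "longitudinal"),
                    priors = list(mean = 0, sd = 10),
                    mcmc = list(iters = 3000, burnin = 500, thin = 5),
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  impute <- match.arg(impute)
  stopifnot(inherits(data, "cjs_data"))
  pm <- priors$mean %||% 0
  ps <- priors$sd %||% 10
  iters <- mcmc$iters %||% 3000
  burnin <- mcmc$burnin %||% 500
  thin <- mcmc$thin %||% 5

  n <- nrow(data$ch)
  nocc <- ncol(data$ch)
  imp <- impute_covariate(data$x, impute)
  xcur <- data$x
  na_cells <- is.na(xcur)
  xcur[na_cells] <- imp$mean[na_cells]
  # latent cells: missing, positive prior SD, and actually used (columns
  # 1..T-1 at occasions >= the individual's first capture)
  lat <- vector("list", nocc - 1)
  for (t in seq_len(nocc - 1)) {
    lat[[t]] <- which(na_cells[, t] & imp$sd[, t] > 0 & data$first <= t)
  }
  lat_cols <- which(vapply(lat, length, 1L) > 0)

  par <- list(b0 = stats::qlogis(0.7), b_sex = 0, b_net = 0, p = 0.5)
  llv <- cjs_loglik_indiv_or_reg(data, par, xcur)
  first_y <- data$ch[cbind(seq_len(n), data$first)]
  p_extra <- function(p) {
    if (data$condition_on_first_capture) return(0)
    sum(first_y) * log(p) + sum(first_y == 0) * log1p(-p)
  }
  lprior <- function(v) stats::dnorm(v, pm, ps, log = TRUE)

  step <- c(b0 = 0.2, b_sex = 0.2, b_net = 0.2, p = 0.05)
  acc <- tot <- c(b0 = 0, b_sex = 0, b_net = 0, p = 0)
  n_keep <- floor((iters - burnin) / thin)
  draws <- matrix(NA_real_, n_keep, 4,
                  dimnames = list(NULL, c("b0", "b_sex", "b_net", "p")))
  kept <- 0L

  for (it in seq_len(iters)) {
    for (nm in c("b0", "b_sex", "b_net")) {
      prop <- par
      prop[[nm]] <- par[[nm]] + stats::rnorm(1, 0, step[nm])
      llp <- cjs_loglik_indiv_or_reg(data, prop, xcur)
      lr <- sum(llp) - sum(llv) + lprior(prop[[nm]]) - lprior(par[[nm]])
      tot[nm] <- tot[nm] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        par <- prop
        llv <- llp
        acc[nm] <- acc[nm] + 1
      }
    }
    pnew <- par$p + stats::rnorm(1, 0, step["p"])
    tot["p"] <- tot["p"] + 1
    if (pnew > 0 && pnew < 1) {
      prop <- par
      prop$p <- pnew
      llp <- cjs_loglik_indiv_or_reg(data, prop, xcur)
      lr <- sum(llp) + p_extra(pnew) - sum(llv) - p_extra(par$p)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        par <- prop
        llv <- llp
        acc["p"] <- acc["p"] + 1
      }
    }
    for (t in lat_cols) {
      cells <- lat[[t]]
      xnew <- xcur
      xnew[cells, t] <- stats::rnorm(length(cells), imp$mean[cells, t],
                                     imp$sd[cells, t])
      llp <- cjs_loglik_indiv_or_reg(data, par, xnew)
      accept <- log(stats::runif(length(cells))) < (llp[cells] - llv[cells])
      if (any(accept)) {
        ci <- cells[accept]
        xcur[ci, t] <- xnew[ci, t]
        llv[ci] <- llp[ci]
      }
    }
    if (it <= burnin && it %% 50 == 0) {
      rate <- ifelse(tot > 0, acc / tot, 0.44)
      step <- step * exp(0.5 * (rate - 0.44))
      acc[] <- 0
      tot[] <- 0
    }
    if (it > burnin && (it - burnin) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      draws[kept, ] <- c(par$b0, par$b_sex, par$b_net, par$p)
    }
  }

  draws <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  summ <- do.call(rbind, lapply(names(draws), function(nm) {
    d <- draws[[nm]]
    h <- hdi(d, 0.89)
    data.frame(parameter = nm, median = stats::median(d), sd = stats::sd(d),
               pr_gt0 = mean(d > 0), hdi_lower = h[1], hdi_upper = h[2],
               hdi_excludes_zero = h[1] > 0 | h[2] < 0)
  }))
  structure(list(draws = draws, summary = summ,
                 settings = list(impute = impute, iters = iters,
                                 burnin = burnin, thin = thin,
                                 prior_mean = pm, prior_sd = ps),
                 acceptance = ifelse(tot > 0, acc / tot, NA)),
            class = "cjs_fit")
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("Bayesian CJS fit (%d retained draws, %s imputation)\n",
              nrow(x$draws), x$settings$impute))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Highest density interval of posterior draws
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass (default 0.89).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.89) {
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  win <- s[k:n] - s[seq_len(n - k + 1)]
  i <- which.min(win)
  c(s[i], s[i + k - 1])
}

#' Earth mover's distance between two sets of draws
#'
#' The 1-D Wasserstein-1 distance between the empirical distributions of
#' two samples (integral of the absolute difference of their ECDFs).
#'
#' @param draws_a,draws_b Non-empty numeric vectors.
#' @return Non-negative scalar.
#' @export
emd <- function(draws_a, draws_b) {
  stopifnot(length(draws_a) > 0, length(draws_b) > 0)
  grid <- sort(c(draws_a, draws_b))
  if (grid[1] == grid[length(grid)]) return(0)
  fa <- stats::ecdf(draws_a)(grid[-length(grid)])
  fb <- stats::ecdf(draws_b)(grid[-length(grid)])
  sum(abs(fa - fb) * diff(grid))
}

#' Screen simulation runs for likely non-convergence
#'
#' Clusters runs by the (standardized) posterior median and SD of the focal
#' parameter with k-means and flags clusters whose mean posterior SD
#' exceeds `sd_factor` times the global median SD — non-converged runs show
#' up as clusters of inflated posterior spread.
#'
#' @param run_summaries data.frame with columns `median` and `sd`, one row
#'   per run.
#' @param k Number of clusters (default 6).
#' @param sd_factor Flagging threshold multiplier.
#' @return Logical vector: TRUE = converged.
#' @export
classify_convergence <- function(run_summaries, k = 6, sd_factor = 2) {
  m <- run_summaries$median
  s <- run_summaries$sd
  n <- length(m)
  pts <- cbind(scale_within_timestep(m), scale_within_timestep(s))
  n_distinct <- nrow(unique(pts))
  if (n < k || n_distinct < k) {
    if (n < k) warning("fewer runs than clusters: all marked converged")
    return(rep(TRUE, n))
  }
  km <- stats::kmeans(pts, centers = k, nstart = 10)
  thresh <- sd_factor * stats::median(s)
  bad <- vapply(seq_len(k), function(cl) {
    mean(s[km$cluster == cl]) > thresh
  }, logical(1))
  !bad[km$cluster]
}
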