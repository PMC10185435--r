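cjs_toy <- function(ch, first = NULL, sex = NULL, x = NULL,
                    condition = TRUE) {
  n <- nrow(ch)
  T <- ncol(ch)
  if (is.null(first)) {
    first <- apply(ch, 1, function(r) which(r == 1)[1])
    first[is.na(first)] <- 1L
  }
  cjs_data(ch, sex %||% rep(0, n), x %||% matrix(0, n, T), first,
           condition_on_first_capture = condition)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CJS likelihood matches hand-worked single histories", {
  # alive and detected at both occasions, phi = 1, p = 1 -> logL = 0
  d <- cjs_toy(matrix(c(1L, 1L), 1, 2))
  expect_equal(
    cjs_log_likelihood(d, list(b0 = 100, b_sex = 0, b_net = 0, p = 1)), 0)

  # history (1, 0, 1), phi = 0.8, p = 0.5: only one latent path,
  # L = 0.8 * 0.5 * 0.8 * 0.5 = 0.16
  d2 <- cjs_toy(matrix(c(1L, 0L, 1L), 1, 3))
  b0 <- qlogis(0.8)
  expect_equal(
    cjs_log_likelihood(d2, list(b0 = b0, b_sex = 0, b_net = 0, p = 0.5)),
    log(0.16))
})

test_that("CJS likelihood equals exhaustive latent-path enumeration", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(1:3, 1)
    T <- sample(2:4, 1)
    ch <- matrix(rbinom(n * T, 1, 0.5), n, T)
    first <- sapply(1:n, function(i) sample(1:T, 1))
    ch[cbind(1:n, first)] <- 1L
    sex <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * T), n, T)
    b0 <- rnorm(1); bs <- rnorm(1, 0, 0.5); bn <- rnorm(1, 0, 0.5)
    p <- runif(1, 0.05, 0.95)
    phi <- plogis(b0 + bs * sex + bn * x[, -T, drop = FALSE])
    for (cond in c(TRUE, FALSE)) {
      d <- cjs_data(ch, sex, x, first, condition_on_first_capture = cond)
      got <- cjs_log_likelihood(d, list(b0 = b0, b_sex = bs, b_net = bn,
                                        p = p), sum = FALSE)
      want <- cjs_loglik_enum(ch, first, phi, p, condition_first = cond)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("imputation moments follow the cross-sectional and longitudinal rules", {
  x <- matrix(c(-1, 0, 1, NA,
                 2, NA, NA, NA,
                 0.5, 1.5, NA, 4), 4, 3)
  # fully observed: zero SDs everywhere
  full <- impute_covariate(matrix(rnorm(12), 4, 3), "cross_sectional")
  expect_true(all(full$sd == 0))

  cs <- impute_covariate(x, "cross_sectional")
  # column 1 has (-1, 0, 1) observed; missing cell gets mean 0, sd 1
  expect_equal(cs$mean[4, 1], 0)
  expect_equal(cs$sd[4, 1], 1)
  # observed entries are returned verbatim with sd 0
  expect_equal(cs$mean[1, 1], -1)
  expect_equal(cs$sd[1, 1], 0)

  lg <- impute_covariate(x, "longitudinal")
  # row 1 observed at (-1, 2, 0.5): own moments for its missing cells
  expect_equal(lg$mean[1, 3], 0.5)  # x[1,3] observed -> verbatim
  # row 4 observed once (4): falls back to overall moments
  obs_all <- x[!is.na(x)]
  expect_equal(lg$mean[4, 1], mean(obs_all))
  expect_equal(lg$sd[4, 1], sd(obs_all))
  # row 2 observed twice: own moments
  expect_equal(lg$mean[2, 2], mean(c(0, 1.5)))
  expect_equal(lg$sd[2, 2], sd(c(0, 1.5)))

  # a column with no observations falls back with a warning
  x2 <- x
  x2[, 3] <- NA
  expect_warning(cs2 <- impute_covariate(x2, "cross_sectional"),
                 "overall")
  expect_equal(cs2$mean[1, 3], mean(x2[!is.na(x2)]))
})

test_that("HDI is the shortest interval with the requested mass", {
  expect_equal(hdi(rep(3, 100)), c(3, 3))
  set.seed(3)
  z <- rnorm(20000)
  h <- hdi(z, 0.89)
  expect_equal(h[1], -qnorm(0.945), tolerance = 0.05)
  expect_equal(h[2], qnorm(0.945), tolerance = 0.05)
  # always within the data range and ordered
  y <- rexp(500)
  hy <- hdi(y, 0.89)
  expect_gte(hy[1], min(y))
  expect_lte(hy[2], max(y))
  expect_lte(hy[1], hy[2])
  # skewed draws: HDI shorter than the central interval
  expect_lt(diff(hdi(y, 0.89)),
            diff(unname(quantile(y, c(0.055, 0.945)))) + 1e-9)
})

test_that("earth mover's distance matches the sorted-difference formula", {
  a <- c(0.1, 0.5, 0.9, 1.4)
  expect_equal(emd(a, a), 0)
  expect_equal(emd(a, a + 2.5), 2.5)
  set.seed(4)
  b <- rnorm(4)
  # equal sample sizes: mean absolute difference of order statistics
  expect_equal(emd(a, b), mean(abs(sort(a) - sort(b))))
  # unequal sizes still non-negative and symmetric
  cc <- rnorm(7)
  expect_equal(emd(a, cc), emd(cc, a))
  expect_gte(emd(a, cc), 0)
})

test_that("convergence screen flags planted high-SD clusters only", {
  set.seed(6)
  good <- data.frame(median = rnorm(40, 0.5, 0.05),
                     sd = runif(40, 0.09, 0.11))
  expect_true(all(classify_convergence(good)))
  # planted outlier cluster with ~10x the SD
  bad <- data.frame(median = rnorm(6, 2, 0.3), sd = runif(6, 0.9, 1.1))
  lab <- classify_convergence(rbind(good, bad))
  expect_true(all(lab[1:40]))
  expect_false(any(lab[41:46]))
  # fewer runs than clusters: everything passes, with a warning
  expect_warning(ok <- classify_convergence(good[1:4, ]), "fewer")
  expect_true(all(ok))
})

test_that("sampler reproduces the prior when the data are uninformative", {
  # both individuals first captured at the final occasion: zero likelihood
  # contribution, so b_net draws should follow the Normal(0, 10) prior
  ch <- matrix(0L, 2, 3)
  ch[, 3] <- 1L
  d <- cjs_data(ch, c(0, 1), matrix(0, 2, 3), first = c(3L, 3L))
  fit <- fit_cjs(d, mcmc = list(iters = 6000, burnin = 1000, thin = 5),
                 seed = 8)
  expect_equal(nrow(fit$draws), 1000)
  expect_lt(abs(mean(fit$draws$b_net)), 2.5)
  expect_gt(sd(fit$draws$b_net), 5)
  expect_lt(sd(fit$draws$b_net), 16)
  # p prior is Uniform(0, 1)
  expect_gt(sd(fit$draws$p), 0.15)
})

test_that("fit recovers parameters from simulated capture histories", {
  # simulate a plain CJS dataset with known phi-covariate effect
  set.seed(9)
  n <- 300; T <- 8
  sex <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * T), n, T)
  b0 <- 1.2; bs <- 0.5; bn <- 0.6; p_true <- 0.7
  alive <- matrix(0L, n, T)
  alive[, 1] <- 1L
  for (t in 1:(T - 1)) {
    phi <- plogis(b0 + bs * sex + bn * x[, t])
    alive[, t + 1] <- alive[, t] * rbinom(n, 1, phi)
  }
  ch <- alive * matrix(rbinom(n * T, 1, p_true), n, T)
  ch[, 1] <- 1L # all released at occasion 1
  d <- cjs_data(ch, sex, x, first = rep(1L, n))
  fit <- fit_cjs(d, seed = 10)
  s <- fit$summary
  get <- function(nm, col) s[s$parameter == nm, col]
  expect_lt(abs(get("b_net", "median") - bn), 0.25)
  expect_lt(abs(get("p", "median") - p_true), 0.08)
  expect_true(get("b_net", "hdi_lower") < bn + 0.3 &&
              get("b_net", "hdi_upper") > bn - 0.3)
  # default retained draw count: (3000 - 500) / 5
  expect_equal(nrow(fit$draws), 500)
})
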