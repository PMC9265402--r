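test_that("model inputs and MCMC settings are validated", {
  Q <- matrix(rep(0:4, 4), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 5)
  expect_error(fit_bayes_index(Q, y + 1), "binary")
  expect_error(fit_bayes_index(Q, rep(0, 10)), "both classes")
  expect_error(fit_bayes_index(Q + 0.5, y), "integers")
  expect_error(fit_bayes_index(Q, y[1:6]), "rows of Q")
  expect_error(mcmc_settings(n_iter = 0), "positive")
  expect_error(mcmc_settings(thin = 0), "positive")
})

test_that("every retained weight draw lies exactly on the probability simplex", {
  dat <- make_index_model_data(300, c(0.5, 0.3, 0.2), beta0 = 0, beta1 = 0.5,
                               seed = 9)
  fit <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 600, n_burnin = 300,
                                       n_adapt = 100, seed = 2))
  W <- fit$chains[, grep("^w\\.", colnames(fit$chains)), drop = FALSE]
  expect_true(all(W >= 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_equal(nrow(fit$chains), 600)
  expect_equal(colnames(fit$chains),
               c("beta0", "beta1", "sigma1", paste0("w.", c("x1", "x2", "x3")),
                 "lp"))

  thin2 <- fit_bayes_index(dat$qm, dat$y,
                           mcmc_settings(n_iter = 600, n_burnin = 300,
                                         n_adapt = 100, thin = 2, seed = 2))
  expect_equal(nrow(thin2$chains), 300)
})

test_that("sampling is reproducible from the seed", {
  dat <- make_index_model_data(200, c(0.6, 0.4), beta0 = -0.5, beta1 = 0.8,
                               seed = 14)
  st <- mcmc_settings(n_iter = 400, n_burnin = 200, n_adapt = 100, seed = 77)
  f1 <- fit_bayes_index(dat$qm, dat$y, st)
  f2 <- fit_bayes_index(dat$qm, dat$y, st)
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_bayes_index(dat$qm, dat$y,
                        mcmc_settings(n_iter = 400, n_burnin = 200,
                                      n_adapt = 100, seed = 78))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("fixed weights are held constant and never proposed", {
  w0 <- c(0.5, 0.3, 0.2)
  dat <- make_index_model_data(300, w0, beta0 = 0, beta1 = 0.5, seed = 9)
  fit <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 400, n_burnin = 200,
                                       n_adapt = 100, seed = 5),
                         fix_weights = w0)
  W <- fit$chains[, grep("^w\\.", colnames(fit$chains)), drop = FALSE]
  for (j in 1:3) expect_true(all(abs(W[, j] - w0[j]) < 1e-12))
  expect_true(all(fit$acceptance[paste0("w.", c("x1", "x2", "x3"))] == 0))
  expect_error(fit_bayes_index(dat$qm, dat$y, fix_weights = c(0.9, 0.3, 0.2)))
})

test_that("with fixed weights the posterior matches deterministic grid integration", {
  # weights fixed => a two-parameter logistic model (after integrating sigma1
  # out of the beta1 prior numerically), so the exact posterior is computable
  # on a dense (beta0, beta1) grid and the sampler must reproduce its
  # marginal medians
  w0 <- c(0.4, 0.25, 0.15, 0.1, 0.1)
  dat <- make_index_model_data(800, w0, beta0 = -1, beta1 = 0.3, seed = 301)
  fit <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 4000, n_burnin = 1000,
                                       n_adapt = 300, seed = 11),
                         fix_weights = w0)
  s <- dat$score; y <- dat$y
  stable_log1pexp <- function(x) {
    big <- x > 33; x[!big] <- log1p(exp(x[!big])); x
  }
  prior_b1 <- function(b) vapply(b, function(bb)
    stats::integrate(function(sg) dnorm(bb, 0, sg) / 100, 1e-6, 100,
                     rel.tol = 1e-10)$value, numeric(1))
  b0g <- seq(-2.5, 0.5, length.out = 121)
  b1g <- seq(-0.2, 0.8, length.out = 121)
  lp <- matrix(NA_real_, 121, 121)
  for (i in seq_along(b0g)) for (j in seq_along(b1g)) {
    eta <- b0g[i] + b1g[j] * s
    lp[i, j] <- sum(y * eta) - sum(stable_log1pexp(eta)) +
      dnorm(b0g[i], 0, 100, log = TRUE)
  }
  lp <- sweep(lp, 2, log(prior_b1(b1g)), `+`)
  post <- exp(lp - max(lp))
  grid_median <- function(g, marg) {
    cdf <- cumsum(marg / sum(marg))
    g[which.max(cdf >= 0.5)]
  }
  med_b1 <- grid_median(b1g, colSums(post))
  med_b0 <- grid_median(b0g, rowSums(post))
  tab <- fit$summary$table
  expect_lt(abs(tab$median[tab$param == "beta1"] - med_b1), 0.05)
  expect_lt(abs(tab$median[tab$param == "beta0"] - med_b0), 0.05)
})

test_that("the sampler recovers generating weights and the effect odds ratio", {
  w <- c(0.35, 0.25, 0.2, 0.1, 0.05, 0.05, 0, 0)
  dat <- make_index_model_data(1500, w, beta0 = -0.8, beta1 = 1.2, seed = 402)
  fit <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 3000, n_burnin = 1500,
                                       n_adapt = 300, seed = 2))
  wm <- fit$summary$weights
  expect_lt(max(abs(wm - w)), 0.1)
  expect_gt(cor(wm, w), 0.9)
  expect_equal(names(which.max(wm)), "x1")
  expect_true(fit$summary$or_lower <= exp(1.2) &&
              fit$summary$or_upper >= exp(1.2))
  expect_true(fit$summary$significant)
  # post-adaptation acceptance stays in a healthy random-walk range
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.9))
})

test_that("a null effect leaves the odds-ratio interval covering one", {
  covered <- vapply(1:5, function(sd) {
    dat <- make_index_model_data(400, rep(0.25, 4), beta0 = 0.2, beta1 = 0,
                                 seed = 500 + sd)
    f <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 1500, n_burnin = 800,
                                       n_adapt = 200, seed = sd))
    f$summary$or_lower <= 1 && f$summary$or_upper >= 1
  }, logical(1))
  expect_gte(sum(covered), 4)
})

test_that("Geweke z separates stationary from drifting chains", {
  # early and late windows with identical repeating pattern: means match
  # exactly, so z is exactly zero
  pattern <- rep(c(1, 2, 3, 4, 5), 200)
  expect_equal(geweke_z(pattern), 0)

  set.seed(2024)
  z_iid <- replicate(200, geweke_z(rnorm(1000)))
  expect_gt(mean(abs(z_iid) < 2), 0.9)

  set.seed(2025)
  drifting <- seq(0, 5, length.out = 1000) + rnorm(1000, sd = 0.1)
  expect_gt(abs(geweke_z(drifting)), 2)

  expect_error(geweke_z(rnorm(50)), "at least 100")
  expect_error(geweke_z(rep(3, 500)), "constant")
})

test_that("posterior summaries match sort-based quantile oracles", {
  set.seed(61)
  n <- 4000
  chains <- cbind(beta0 = rnorm(n, -1, 0.3),
                  beta1 = rnorm(n, 0.25, 0.04),
                  sigma1 = runif(n, 1, 5),
                  w.a = rep(0.6, n), w.b = rep(0.4, n),
                  lp = rnorm(n))
  sm <- summarize_posterior(chains)
  tab <- sm$table
  for (p in c("beta0", "beta1", "sigma1")) {
    x <- chains[, p]
    expect_equal(tab$median[tab$param == p], type7_quantile(x, 0.5))
    expect_equal(tab$lower[tab$param == p], type7_quantile(x, 0.025))
    expect_equal(tab$upper[tab$param == p], type7_quantile(x, 0.975))
  }
  expect_equal(sm$or_median, type7_quantile(exp(chains[, "beta1"]), 0.5))
  expect_equal(sm$weights, c(a = 0.6, b = 0.4))
  # all beta1 draws are well above zero here, so the interval excludes OR = 1
  expect_true(sm$significant)

  null_chains <- chains
  null_chains[, "beta1"] <- rnorm(n, 0, 0.05)
  expect_false(summarize_posterior(null_chains)$significant)
  expect_error(summarize_posterior(chains[0, , drop = FALSE]), "no retained")
})

test_that("index application reproduces the stored weighted sum", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  V <- rbind(c(2, 0, 5), c(0, 0, 0))
  colnames(V) <- c("a", "b", "c")
  expect_equal(apply_bayes_index(w, V, mode = "raw"), c(2.0, 0.0))

  # equal weights reduce the score to the mean quantile score
  set.seed(3)
  M <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  qm <- quantile_score(M, Q = 10)
  eq <- rep(equal_weight_reference(4), 4)
  names(eq) <- letters[1:4]
  expect_equal(apply_bayes_index(eq, qm), rowMeans(qm$scores))

  colnames(V) <- c("a", "b", "z")
  expect_error(apply_bayes_index(w, V, mode = "raw"), "missing.*c")
  expect_equal(equal_weight_reference(25), 0.04)
})

test_that("chains export to delimited text and read back numerically intact", {
  dat <- make_index_model_data(150, c(0.7, 0.3), beta0 = 0, beta1 = 0.4,
                               seed = 6)
  fit <- fit_bayes_index(dat$qm, dat$y,
                         mcmc_settings(n_iter = 200, n_burnin = 100,
                                       n_adapt = 100, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chains(fit, path)
  back <- as.matrix(read.csv(path))
  expect_equal(unname(back), unname(fit$chains), tolerance = 1e-12)
})
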