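#' MCMC settings for the Bayesian index model
#'
#' The default schedule is 500 adaptation iterations, 5,000 burn-in, and
#' 10,000 retained iterations with no thinning, on 10 quantiles (deciles).
#' Proposal scales are tuned only during the adaptation phase and frozen
#' afterwards so that the post-adaptation chain satisfies detailed balance.
#'
#' @param n_iter Retained iterations after burn-in.
#' @param n_burnin Burn-in iterations (discarded), run after adaptation.
#' @param n_adapt Adaptation iterations (discarded).
#' @param thin Thinning interval.
#' @param n_quantiles Number of quantile bins for the exposure scores.
#' @param seed Integer seed.
#' @param n_chains Number of chains (a single chain is the default).
#' @return An `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 10000, n_burnin = 5000, n_adapt = 500,
                          thin = 1, n_quantiles = 10, seed = 1L,
                          n_chains = 1L) {
  s <- list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
            n_adapt = as.integer(n_adapt), thin = as.integer(thin),
            n_quantiles = as.integer(n_quantiles), seed = as.integer(seed),
            n_chains = as.integer(n_chains))
  if (any(unlist(s[c("n_iter", "n_burnin", "n_adapt", "n_quantiles",
                     "n_chains")]) < 1L) || s$thin < 1L) {
    stop("all MCMC settings must be positive counts (thin >= 1)")
  }
  structure(s, class = "mcmc_settings")
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  big <- x > 33
  x[!big] <- log1p(exp(x[!big]))
  x
}

# Bernoulli-logit log likelihood given the linear predictor
bern_loglik <- function(y, eta) sum(y * eta) - sum(log1pexp(eta))

#' Fit the Bayesian index regression model
#'
#' Logistic regression of a binary outcome on a weighted sum of quantile
#' scores, `logit(p_i) = beta0 + beta1 * sum_j w_j q_ij`, with the weights
#' constrained to the probability simplex. Priors: `w ~ Dirichlet(1,...,1)`
#' (represented as independent Gamma(1,1) components normalized to sum 1, so
#' every draw lies exactly on the simplex), `beta1 ~ N(0, sigma1^2)` with
#' `sigma1 ~ Uniform(0, 100)`, and a vague `beta0 ~ N(0, 100^2)`. Sampling
#' is adaptive Metropolis-within-Gibbs: each unnormalized weight component is
#' updated by a log-scale random walk, `beta0`, `beta1`, and `sigma1` by
#' Gaussian random walks; proposal scales are tuned toward 44% acceptance
#' during the adaptation phase only.
#'
#' @param Q Integer score matrix or [quantile_score()] result (rows =
#'   participants, columns = exposure variables).
#' @param y Binary outcome vector (both classes present).
#' @param settings An [mcmc_settings()].
#' @param fix_weights Optional simplex vector: fixes the weights (no weight
#'   updates), e.g. for likelihood cross-checks.
#' @return A `bayes_index_fit`: list with `chains` (retained draws, columns
#'   `beta0`, `beta1`, `sigma1`, `w.<name>`, `lp`), `summary` (a
#'   [summarize_posterior()] result), `acceptance` rates, and `settings`.
#' @export
fit_bayes_index <- function(Q, y, settings = mcmc_settings(),
                            fix_weights = NULL) {
  if (inherits(Q, "quantile_matrix")) Q <- Q$scores
  Q <- as.matrix(Q)
  if (any(Q != round(Q))) stop("quantile scores must be integers")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (nrow(Q) != length(y)) stop("rows of Q must match length of y")
  n <- nrow(Q); C <- ncol(Q)
  vnames <- colnames(Q)
  if (is.null(vnames)) vnames <- paste0("v", seq_len(C))
  storage.mode(Q) <- "double"

  set.seed(settings$seed)
  fixed_w <- !is.null(fix_weights)
  if (fixed_w) {
    stopifnot(length(fix_weights) == C,
              abs(sum(fix_weights) - 1) < 1e-8, all(fix_weights >= 0))
  }

  # state
  theta <- rep(1, C)
  if (fixed_w) theta <- as.numeric(fix_weights) * C
  Tsum <- sum(theta)
  u <- drop(Q %*% theta)              # n-vector, s = u / Tsum
  beta0 <- qlogis(mean(y))
  beta1 <- 0
  sigma1 <- 10
  b0_prior_sd <- 100
  sigma1_upper <- 100

  eta <- beta0 + beta1 * u / Tsum
  ll <- bern_loglik(y, eta)

  # proposal scales + adaptation bookkeeping
  s_phi <- rep(0.5, C); s_b0 <- 0.2; s_b1 <- 0.2; s_sig <- 5
  acc <- numeric(C + 3L); att <- numeric(C + 3L)
  batch_acc <- numeric(C + 3L); batch_att <- numeric(C + 3L)
  batch_size <- 50L; batch_no <- 0L

  total <- settings$n_adapt + settings$n_burnin +
    settings$n_iter
  keep_from <- settings$n_adapt + settings$n_burnin
  n_keep <- floor(settings$n_iter / settings$thin)
  draws <- matrix(NA_real_, n_keep, C + 4L,
                  dimnames = list(NULL, c("beta0", "beta1", "sigma1",
                                          paste0("w.", vnames), "lp")))
  keep_i <- 0L

  for (iter in seq_len(total)) {
    adapting <- iter <= settings$n_adapt

    if (!fixed_w) {
      for (j in seq_len(C)) {
        phi <- log(theta[j])
        phi_new <- phi + rnorm(1, 0, s_phi[j])
        th_new <- exp(phi_new)
        d <- th_new - theta[j]
        T_new <- Tsum + d
        u_new <- u + d * Q[, j]
        eta_new <- beta0 + beta1 * u_new / T_new
        ll_new <- bern_loglik(y, eta_new)
        # Gamma(1,1) prior on theta plus log-scale Jacobian: -theta + phi
        logr <- (ll_new - ll) + (-th_new + phi_new) - (-theta[j] + phi)
        att[j] <- att[j] + 1; batch_att[j] <- batch_att[j] + 1
        if (is.finite(logr) && log(runif(1)) < logr) {
          theta[j] <- th_new; Tsum <- T_new; u <- u_new
          eta <- eta_new; ll <- ll_new
          acc[j] <- acc[j] + 1; batch_acc[j] <- batch_acc[j] + 1
        }
      }
    }

    ib0 <- C + 1L
    b0_new <- beta0 + rnorm(1, 0, s_b0)
    eta_new <- eta + (b0_new - beta0)
    ll_new <- bern_loglik(y, eta_new)
    logr <- (ll_new - ll) +
      dnorm(b0_new, 0, b0_prior_sd, log = TRUE) -
      dnorm(beta0, 0, b0_prior_sd, log = TRUE)
    att[ib0] <- att[ib0] + 1; batch_att[ib0] <- batch_att[ib0] + 1
    if (log(runif(1)) < logr) {
      beta0 <- b0_new; eta <- eta_new; ll <- ll_new
      acc[ib0] <- acc[ib0] + 1; batch_acc[ib0] <- batch_acc[ib0] + 1
    }

    ib1 <- C + 2L
    s_vec <- u / Tsum
    b1_new <- beta1 + rnorm(1, 0, s_b1)
    eta_new <- beta0 + b1_new * s_vec
    ll_new <- bern_loglik(y, eta_new)
    logr <- (ll_new - ll) +
      dnorm(b1_new, 0, sigma1, log = TRUE) -
      dnorm(beta1, 0, sigma1, log = TRUE)
    att[ib1] <- att[ib1] + 1; batch_att[ib1] <- batch_att[ib1] + 1
    if (log(runif(1)) < logr) {
      beta1 <- b1_new; eta <- eta_new; ll <- ll_new
      acc[ib1] <- acc[ib1] + 1; batch_acc[ib1] <- batch_acc[ib1] + 1
    }

    isg <- C + 3L
    sg_new <- sigma1 + rnorm(1, 0, s_sig)
    att[isg] <- att[isg] + 1; batch_att[isg] <- batch_att[isg] + 1
    if (sg_new > 0 && sg_new < sigma1_upper) {
      logr <- dnorm(beta1, 0, sg_new, log = TRUE) -
        dnorm(beta1, 0, sigma1, log = TRUE)
      if (log(runif(1)) < logr) {
        sigma1 <- sg_new
        acc[isg] <- acc[isg] + 1; batch_acc[isg] <- batch_acc[isg] + 1
      }
    }

    if (adapting && iter %% batch_size == 0L) {
      batch_no <- batch_no + 1L
      delta <- min(0.25, 1 / sqrt(batch_no))
      rate <- ifelse(batch_att > 0, batch_acc / batch_att, 0.44)
      adj <- exp(delta * sign(rate - 0.44))
      s_phi <- s_phi * adj[seq_len(C)]
      s_b0 <- s_b0 * adj[ib0]; s_b1 <- s_b1 * adj[ib1]
      s_sig <- s_sig * adj[isg]
      batch_acc[] <- 0; batch_att[] <- 0
    }

    if (iter > keep_from && (iter - keep_from) %% settings$thin == 0L) {
      keep_i <- keep_i + 1L
      w <- theta / Tsum
      lp <- ll +
        dnorm(beta0, 0, b0_prior_sd, log = TRUE) +
        dnorm(beta1, 0, sigma1, log = TRUE) +
        sum(-theta + log(theta)) - log(sigma1_upper)
      draws[keep_i, ] <- c(beta0, beta1, sigma1, w, lp)
    }
  }

  chains <- draws[seq_len(keep_i), , drop = FALSE]
  fit <- structure(list(
    chains = chains,
    acceptance = setNames(acc / pmax(att, 1),
                          c(paste0("w.", vnames), "beta0", "beta1", "sigma1")),
    settings = settings,
    n_obs = n,
    variable_names = vnames,
    fixed_weights = if (fixed_w) fix_weights else NULL
  ), class = "bayes_index_fit")
  fit$summary <- summarize_posterior(fit, settings)
  fit
}

#' @export
print.bayes_index_fit <- function(x, ...) {
  cat("Bayesian index regression fit:", x$n_obs, "observations,",
      length(x$variable_names), "variables,",
      nrow(x$chains), "retained draws\n")
  print(x$summary)
  invisible(x)
}

#' Geweke convergence z-score
#'
#' Compares the means of an early and a late chain segment (by default the
#' first 10% and last 50%) with a z statistic whose variance uses each
#' segment's spectral density at frequency zero, estimated from an
#' autoregressive fit. `|z| < 2` is read as evidence of convergence.
#'
#' @param chain Numeric vector of MCMC draws (length >= 100, non-constant).
#' @param frac_first Fraction of the chain in the early window.
#' @param frac_last Fraction in the late window.
#' @return The z statistic (scalar).
#' @export
geweke_z <- function(chain, frac_first = 0.10, frac_last = 0.50) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100L) stop("chain must have at least 100 draws")
  if (var(chain) == 0) stop("constant chain: zero variance")
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  a <- chain[seq_len(n1)]
  b <- chain[seq.int(n - n2 + 1L, n)]
  spec0 <- function(x) {
    if (var(x) == 0) return(0)
    fit <- ar(x, aic = TRUE, order.max = min(20L, length(x) - 1L),
              method = "yule-walker")
    if (length(fit$ar) == 0) return(fit$var.pred)
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  (mean(a) - mean(b)) / sqrt(spec0(a) / n1 + spec0(b) / n2)
}

#' Summarize posterior draws
#'
#' Posterior medians and central 95% credible intervals per parameter, the
#' odds ratio `exp(beta1)` summarized on its own scale, a significance flag
#' (odds-ratio interval excludes 1), and per-parameter Geweke z with an
#' overall convergence flag (all `|z| < 2`).
#'
#' @param chains A `bayes_index_fit` or a draws matrix with named columns.
#' @param settings The [mcmc_settings()] used (recorded in the output).
#' @return A `posterior_summary`: list with `table` (param, median, lower,
#'   upper, geweke_z), `or_median`, `or_lower`, `or_upper`, `significant`,
#'   `converged`, `weights` (posterior median weights).
#' @export
summarize_posterior <- function(chains, settings = NULL) {
  if (inherits(chains, "bayes_index_fit")) {
    if (is.null(settings)) settings <- chains$settings
    chains <- chains$chains
  }
  chains <- as.matrix(chains)
  if (nrow(chains) == 0L) stop("no retained draws to summarize")
  params <- setdiff(colnames(chains), "lp")
  qs <- t(apply(chains[, params, drop = FALSE], 2, quantile,
                probs = c(0.5, 0.025, 0.975), type = 7, names = FALSE))
  gz <- vapply(params, function(p) {
    tryCatch(geweke_z(chains[, p]), error = function(e) NA_real_)
  }, numeric(1))
  tab <- data.frame(param = params, median = qs[, 1], lower = qs[, 2],
                    upper = qs[, 3], geweke_z = gz,
                    row.names = NULL, stringsAsFactors = FALSE)
  or_draws <- exp(chains[, "beta1"])
  orq <- quantile(or_draws, c(0.5, 0.025, 0.975), type = 7, names = FALSE)
  wcols <- grep("^w\\.", params, value = TRUE)
  structure(list(
    table = tab,
    or_median = orq[1], or_lower = orq[2], or_upper = orq[3],
    significant = orq[2] > 1 || orq[3] < 1,
    converged = all(is.finite(gz)) && all(abs(gz) < 2),
    weights = setNames(tab$median[match(wcols, tab$param)],
                       sub("^w\\.", "", wcols)),
    settings = settings
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (medians, 95% CrI)\n")
  core <- x$table[x$table$param %in% c("beta0", "beta1", "sigma1"), ]
  print(format(core, digits = 3), row.names = FALSE)
  cat(sprintf("Odds ratio exp(beta1): %.3f (%.3f, %.3f)%s\n",
              x$or_median, x$or_lower, x$or_upper,
              if (x$significant) " *" else ""))
  cat("Geweke convergence:",
      if (x$converged) "all |z| < 2" else "NOT converged", "\n")
  if (length(x$weights)) {
    cat("Median weights range:",
        sprintf("%.4f - %.4f", min(x$weights), max(x$weights)), "\n")
  }
  invisible(x)
}

#' Equal-weight reference value
#'
#' The weight each variable would carry if all `n_vars` variables were
#' weighted equally, `1 / n_vars`; used as the reference line for flagging
#' variables with above-average posterior weights.
#'
#' @param n_vars Number of index variables.
#' @return `1 / n_vars`.
#' @export
equal_weight_reference <- function(n_vars) {
  stopifnot(n_vars >= 1)
  1 / n_vars
}

#' Apply posterior index weights to data
#'
#' Each row's score is the weighted sum of its per-variable values using the
#' posterior median weights: decile scores in `mode = "quantile"` (internally
#' consistent with the fitted model, the default) or the oriented raw values
#' in `mode = "raw"`.
#'
#' @param summary A `posterior_summary`, `bayes_index_fit`, or a named
#'   weight vector.
#' @param data A `quantile_matrix` (quantile mode) or numeric matrix /
#'   `oriented_matrix` whose columns match the model variables.
#' @param mode `"quantile"` or `"raw"`.
#' @return Numeric score vector.
#' @export
apply_bayes_index <- function(summary, data, mode = c("quantile", "raw")) {
  mode <- match.arg(mode)
  w <- if (inherits(summary, "bayes_index_fit")) summary$summary$weights
       else if (inherits(summary, "posterior_summary")) summary$weights
       else summary
  V <- if (inherits(data, "quantile_matrix")) data$scores
       else as_matrix_values(data)
  if (!is.null(names(w)) && !is.null(colnames(V))) {
    missing <- setdiff(names(w), colnames(V))
    if (length(missing)) stop("columns missing for index application: ",
                              paste(missing, collapse = ", "))
    V <- V[, names(w), drop = FALSE]
  } else if (ncol(V) != length(w)) {
    stop("data has ", ncol(V), " columns but the model has ", length(w),
         " variables")
  }
  drop(V %*% w)
}

#' Export retained chains as delimited text
#'
#' @param fit A `bayes_index_fit`.
#' @param path Output CSV path (one column per parameter, one row per
#'   retained draw).
#' @return `path`, invisibly.
#' @export
write_chains <- function(fit, path) {
  stopifnot(inherits(fit, "bayes_index_fit"))
  write.csv(as.data.frame(fit$chains), path, row.names = FALSE)
  invisible(path)
}
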