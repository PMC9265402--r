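#' Simulation configuration
#'
#' Bundles every generating parameter for the synthetic tract/participant
#' data. Defaults emulate the structure of a city-wide ACE survey nested in
#' census tracts: 380 tracts, 1,680 adults, 25 correlated neighborhood
#' variables on mixed percent/rate scales, a binary 4+ ACE outcome generated
#' from a weighted decile-index logistic model calibrated to 32.7%
#' prevalence, and BMI with tract-level random intercepts.
#'
#' @param n_tracts Number of census tracts.
#' @param n_participants Number of participants.
#' @param n_vars Number of neighborhood variables.
#' @param n_factors Number of latent factors driving between-variable
#'   correlation.
#' @param factor_loading_scale SD of the latent-factor loadings; 0 gives
#'   mutually independent variables.
#' @param true_weights Generating index weights on the probability simplex
#'   (length `n_vars`, non-negative, summing to 1).
#' @param beta0 Intercept of the ACE model on the logit scale; ignored (and
#'   solved numerically) when `target_prevalence` is non-`NULL`.
#' @param beta1 Log-odds of 4+ ACEs per unit of the decile index.
#' @param target_prevalence Population-average probability of 4+ ACEs the
#'   intercept is calibrated to, or `NULL` to use `beta0` as given.
#' @param gamma_index BMI change (kg/m^2) per index unit.
#' @param gamma_ace BMI change (kg/m^2) for participants with 4+ ACEs.
#' @param bmi_intercept Baseline BMI (kg/m^2) at index 0, reference
#'   covariates.
#' @param covariate_effects Named list of BMI effects for non-reference
#'   covariate levels (age 18-34, male, White are references).
#' @param sigma_tract SD of the tract-level random intercept for BMI.
#' @param sigma_resid Residual SD for BMI.
#' @param covariate_freqs Named list of category frequency vectors for
#'   `age_group`, `sex`, `race`; each must sum to 1.
#' @param tract_skew Non-negative skew of participants-per-tract allocation;
#'   0 (default) is near-uniform.
#' @param specs Optional variable spec table; defaults to
#'   [default_variable_specs()] when `n_vars` is 25, or a generic generated
#'   set otherwise.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tracts = 380,
                       n_participants = 1680,
                       n_vars = 25,
                       n_factors = 2,
                       factor_loading_scale = 0.8,
                       true_weights = default_true_weights(n_vars),
                       beta0 = 0,
                       beta1 = log(1.24),
                       target_prevalence = 0.327,
                       gamma_index = 0.4,
                       gamma_ace = 0.85,
                       bmi_intercept = 26,
                       covariate_effects = default_covariate_effects(),
                       sigma_tract = 1.5,
                       sigma_resid = 6,
                       covariate_freqs = default_covariate_freqs(),
                       tract_skew = 0,
                       specs = NULL,
                       seed = 1L) {
  cfg <- list(n_tracts = as.integer(n_tracts),
              n_participants = as.integer(n_participants),
              n_vars = as.integer(n_vars),
              n_factors = as.integer(n_factors),
              factor_loading_scale = factor_loading_scale,
              true_weights = true_weights,
              beta0 = beta0, beta1 = beta1,
              target_prevalence = target_prevalence,
              gamma_index = gamma_index, gamma_ace = gamma_ace,
              bmi_intercept = bmi_intercept,
              covariate_effects = covariate_effects,
              sigma_tract = sigma_tract, sigma_resid = sigma_resid,
              covariate_freqs = covariate_freqs,
              tract_skew = tract_skew,
              specs = specs,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_tracts < 1L || n_participants < 1L || n_vars < 1L || n_factors < 0L)
      stop("counts must be positive")
    if (n_factors > n_vars) stop("invalid config: n_factors > n_vars")
    w <- true_weights
    if (length(w) != n_vars) stop("true_weights must have length n_vars")
    if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-10)
      stop("true_weights must lie on the probability simplex")
    if (!is.null(target_prevalence) &&
        (target_prevalence <= 0 || target_prevalence >= 1))
      stop("target_prevalence must be in (0, 1)")
    if (sigma_tract < 0 || sigma_resid <= 0)
      stop("sigma_tract must be >= 0 and sigma_resid > 0")
    if (factor_loading_scale < 0) stop("factor_loading_scale must be >= 0")
    if (tract_skew < 0) stop("tract_skew must be >= 0")
    for (nm in names(covariate_freqs)) {
      f <- covariate_freqs[[nm]]
      if (any(f < 0) || abs(sum(f) - 1) > 1e-10)
        stop("covariate frequencies for '", nm, "' must sum to 1")
    }
  })
  cfg
}

#' Default generating index weights
#'
#' A realistic sparse-ish simplex profile: roughly the top 40% of variables
#' carry declining weights (about 0.11 down to 0.04 for 25 variables) and the
#' remainder share small near-floor weights (about 0.02) — matching the shape
#' typically estimated for neighborhood indexes where a minority of variables
#' dominate.
#'
#' @param n_vars Number of variables.
#' @return Numeric vector on the simplex.
#' @export
default_true_weights <- function(n_vars) {
  n_strong <- max(1L, round(0.4 * n_vars))
  raw <- c(seq(6, 2, length.out = n_strong), rep(1, n_vars - n_strong))
  raw / sum(raw)
}

#' @rdname sim_config
#' @export
default_covariate_freqs <- function() {
  list(
    age_group = c("18-34" = 0.109, "35-64" = 0.607, "65+" = 0.284),
    sex = c(male = 0.275, female = 0.725),
    race = c(White = 0.467, Black = 0.445, Hispanic = 0.021,
             Asian = 0.011, Other = 0.056)
  )
}

#' @rdname sim_config
#' @export
default_covariate_effects <- function() {
  list(age_group = c("35-64" = 1.8, "65+" = 0.5),
       sex = c(female = -0.5),
       race = c(Black = 2.2, Hispanic = -0.2, Asian = -3.0, Other = 1.5))
}

generic_specs <- function(n_vars) {
  do.call(rbind, lapply(seq_len(n_vars), function(j) {
    variable_spec(sprintf("var%02d", j),
                  scale_type = if (j %% 3 == 0) "rate" else "percent",
                  direction = if (j %% 5 == 0) "inverse" else "risk_aligned")
  }))
}

sim_specs <- function(config) {
  if (!is.null(config$specs)) return(validate_specs(config$specs))
  if (config$n_vars == 25L) default_variable_specs() else
    generic_specs(config$n_vars)
}

#' Generate a synthetic tract table
#'
#' Tract variables are built from a latent-factor model: `n_factors`
#' independent standard-normal factors per tract, variable-specific loadings
#' with SD `factor_loading_scale`, plus unit-variance noise. The latent value
#' is then mapped to the variable's scale — a logistic transform onto
#' \[0, 100\] for percent-type columns, an exponential transform onto
#' \[0, Inf) for rate-type columns — and inverse-direction columns are
#' flipped so their raw values run opposite to risk, as real protective
#' measures (greenspace, homeownership) do.
#'
#' @param config A [sim_config()].
#' @return A data frame with `tract_id` plus one column per variable, with
#'   the variable-spec table attached as attribute `"specs"`.
#' @export
generate_tracts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  specs <- sim_specs(config)
  set.seed(config$seed)
  n <- config$n_tracts
  p <- config$n_vars
  k <- config$n_factors
  lambda <- matrix(rnorm(p * k, sd = config$factor_loading_scale), p, k)
  fac <- matrix(rnorm(n * k), n, k)
  latent <- fac %*% t(lambda) + matrix(rnorm(n * p), n, p)
  alpha_pct <- rnorm(p, mean = -1, sd = 0.5)
  alpha_rate <- rnorm(p, mean = 0.5, sd = 0.5)
  X <- matrix(NA_real_, n, p, dimnames = list(NULL, specs$name))
  for (j in seq_len(p)) {
    l <- latent[, j]
    if (specs$direction[j] == "inverse") l <- -l
    X[, j] <- if (specs$scale_type[j] == "percent") {
      100 * plogis(alpha_pct[j] + 0.8 * l)
    } else {
      exp(alpha_rate[j] + 0.6 * l)
    }
  }
  out <- data.frame(tract_id = sprintf("t%05d", seq_len(n)), X,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "specs") <- specs
  out
}

# Solve the ACE-model intercept so the population-average event probability
# equals the target; bisection to 1e-6 on the prevalence scale.
calibrate_beta0 <- function(eta_index, target, tol = 1e-6) {
  f <- function(b0) mean(plogis(b0 + eta_index)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("cannot bracket intercept for target prevalence")
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate synthetic participants nested in tracts
#'
#' Participants are allocated to tracts multinomially (near-uniform by
#' default). Each participant's true index score is the weighted sum of
#' decile scores of the oriented tract variables (weights =
#' `config$true_weights`). The binary 4+ ACE outcome is Bernoulli with
#' `logit(p) = beta0 + beta1 * score`; when `target_prevalence` is set,
#' `beta0` is solved by bisection so the population-average probability
#' matches it. The ACE count is drawn uniformly within the class implied by
#' the binary outcome (0-3 or 4-14). BMI is linear in the index, the ACE
#' indicator, and covariates, plus a tract-level random intercept and
#' residual noise.
#'
#' @param tracts Tract table from [generate_tracts()].
#' @param config A [sim_config()].
#' @return A list with `participants` (data frame) and `truth` (a
#'   `truth_record` holding generating parameters, tract scores, and realized
#'   prevalence).
#' @export
generate_participants <- function(tracts, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tracts) || nrow(tracts) == 0L) stop("empty tract table")
  if (!is.null(config$target_prevalence) &&
      (config$target_prevalence <= 0 || config$target_prevalence >= 1))
    stop("target_prevalence must be in (0, 1)")
  specs <- attr(tracts, "specs")
  if (is.null(specs)) specs <- sim_specs(config)
  set.seed(config$seed + 1L)
  n <- config$n_participants
  nt <- nrow(tracts)

  probs <- rep(1 / nt, nt)
  if (config$tract_skew > 0) {
    probs <- exp(config$tract_skew * rnorm(nt))
    probs <- probs / sum(probs)
  }
  assign <- sample.int(nt, n, replace = TRUE, prob = probs)

  oriented <- orient_variables(tracts[, specs$name, drop = FALSE], specs)
  qm <- quantile_score(oriented, Q = 10)
  tract_scores <- drop(qm$scores %*% config$true_weights)
  score <- tract_scores[assign]

  beta0 <- config$beta0
  if (!is.null(config$target_prevalence)) {
    beta0 <- calibrate_beta0(config$beta1 * score, config$target_prevalence)
  }
  p_ace <- plogis(beta0 + config$beta1 * score)
  ace4 <- rbinom(n, 1L, p_ace)
  ace_count <- integer(n)
  n1 <- sum(ace4 == 1L)
  ace_count[ace4 == 1L] <- sample(4:14, n1, replace = TRUE)
  ace_count[ace4 == 0L] <- sample(0:3, n - n1, replace = TRUE)

  cf <- config$covariate_freqs
  draw_cat <- function(f) {
    factor(sample(names(f), n, replace = TRUE, prob = f), levels = names(f))
  }
  age_group <- draw_cat(cf$age_group)
  sex <- draw_cat(cf$sex)
  race <- draw_cat(cf$race)

  eff <- config$covariate_effects
  lookup <- function(values, effects) {
    out <- rep(0, n)
    for (lv in names(effects)) out[values == lv] <- effects[[lv]]
    out
  }
  b_tract <- rnorm(nt, 0, config$sigma_tract)
  bmi <- config$bmi_intercept +
    config$gamma_index * score +
    config$gamma_ace * ace4 +
    lookup(age_group, eff$age_group) +
    lookup(sex, eff$sex) +
    lookup(race, eff$race) +
    b_tract[assign] +
    rnorm(n, 0, config$sigma_resid)

  participants <- data.frame(
    participant_id = sprintf("p%06d", seq_len(n)),
    tract_id = tracts$tract_id[assign],
    ace_count = ace_count,
    ace4 = ace4,
    bmi = bmi,
    age_group = age_group,
    sex = sex,
    race = race,
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    config = config,
    beta0_used = beta0,
    tract_scores = setNames(tract_scores, tracts$tract_id),
    participant_scores = score,
    realized_prevalence = mean(ace4)
  ), class = "truth_record")

  list(participants = participants, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat("  intercept (logit):", format(x$beta0_used, digits = 4), "\n")
  cat("  index effect beta1:", format(x$config$beta1, digits = 4), "\n")
  cat("  realized 4+ ACE prevalence:",
      format(x$realized_prevalence, digits = 4), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Tract and participant tables are written as comma-separated text with a
#' header row; the ground-truth record is written as a key/value text file
#' including the generating seed.
#'
#' @param tracts,participants Data frames from the generators.
#' @param truth A `truth_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(tracts, participants, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("tracts.csv", "participants.csv", "truth.txt"))
  write.csv(tracts, paths[1], row.names = FALSE)
  write.csv(participants, paths[2], row.names = FALSE)
  cfg <- truth$config
  lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("n_tracts: ", cfg$n_tracts),
    paste0("n_participants: ", cfg$n_participants),
    paste0("beta0_used: ", format(truth$beta0_used, digits = 17)),
    paste0("beta1: ", format(cfg$beta1, digits = 17)),
    paste0("realized_prevalence: ",
           format(truth$realized_prevalence, digits = 17)),
    paste0("true_weights: ",
           paste(format(cfg$true_weights, digits = 17), collapse = ","))
  )
  writeLines(lines, paths[3])
  invisible(paths)
}
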