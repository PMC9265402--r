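# Shared fixture builders; every fixture is generated in code from a seed.

# Standardized matrix with two independent latent blocks of `per_block`
# strongly loading variables plus pure-noise columns: the canonical input on
# which the threshold-based reduction should keep the block variables and
# drop the noise. The blocks carry different signal strengths so the leading
# eigenvectors align with the blocks rather than mixing them.
make_two_block_matrix <- function(n = 2000, per_block = 6, n_noise = 4,
                                  seed = 42) {
  set.seed(seed)
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, strength, noise) {
    sapply(seq_len(per_block), function(j) strength * f + noise * rnorm(n))
  }
  X <- cbind(block(f1, 0.95, 0.30), block(f2, 0.80, 0.60),
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(X) <- c(paste0("a", seq_len(per_block)),
                   paste0("b", seq_len(per_block)),
                   paste0("noise", seq_len(n_noise)))
  standardize_columns(X)
}

# Data drawn from the weighted decile-index logistic model itself.
make_index_model_data <- function(n, weights, beta0, beta1, Q = 10,
                                  seed = 1) {
  set.seed(seed)
  C <- length(weights)
  X <- matrix(rnorm(n * C), n, C, dimnames = list(NULL, paste0("x", 1:C)))
  qm <- quantile_score(X, Q = Q)
  s <- drop(qm$scores %*% weights)
  y <- rbinom(n, 1, plogis(beta0 + beta1 * s))
  list(X = X, qm = qm, score = s, y = y)
}

# Confounding fixture: BMI depends on the neighborhood index only
# (gamma_ace = 0) while 4+ ACE status depends strongly on the index, so the
# marginal ACE-BMI association in model 2 is confounded and should attenuate
# once the index enters in model 3. Covariate categories are balanced so the
# fixture isolates the attenuation phenomenon without indicator collinearity.
make_confounded_suite_data <- function(seed, n_tracts = 100,
                                       n_participants = 1000) {
  cfg <- sim_config(
    n_tracts = n_tracts, n_participants = n_participants,
    n_vars = 10, beta1 = 0.8, target_prevalence = 0.35,
    gamma_index = 0.6, gamma_ace = 0,
    sigma_tract = 1, sigma_resid = 4,
    covariate_freqs = list(
      age_group = c("18-34" = 1/3, "35-64" = 1/3, "65+" = 1/3),
      sex = c(male = 0.5, female = 0.5),
      race = c(White = 0.2, Black = 0.2, Hispanic = 0.2,
               Asian = 0.2, Other = 0.2)),
    covariate_effects = list(age_group = c(), sex = c(), race = c()),
    seed = seed)
  tr <- generate_tracts(cfg)
  gp <- generate_participants(tr, cfg)
  list(participants = gp$participants,
       scores = gp$truth$participant_scores)
}

# Manual type-7 quantile (linear interpolation between order statistics),
# written independently of stats::quantile.
type7_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- pmin(lo + 1, n)
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}
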