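#' Random-intercept linear mixed model
#'
#' Fits `y ~ X + (1 | cluster)` by restricted maximum likelihood. Fixed
#' effects are reported with Wald (large-sample z) 95% confidence intervals
#' and p-values; variance components are the cluster random-intercept
#' variance and the residual variance.
#'
#' @param y Numeric response.
#' @param X Design matrix including an intercept column.
#' @param cluster Cluster id vector (>= 2 clusters).
#' @return An `mlm_fit`: list with `coefficients` (term, estimate, se,
#'   lower, upper, z, p), `cluster_variance`, `residual_variance`, `n_obs`,
#'   `n_clusters`, and the underlying `lme4` fit.
#' @export
fit_mlm <- function(y, X, cluster) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cluster <- factor(cluster)
  if (nlevels(cluster) < 2L) stop("need at least 2 clusters")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  df <- data.frame(.y = as.numeric(y), .cluster = cluster)
  fit <- lme4::lmer(.y ~ 0 + X + (1 | .cluster), data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  names(est) <- sub("^X", "", names(est))
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  crit <- qnorm(0.975)
  vc <- as.data.frame(lme4::VarCorr(fit))
  cl_var <- vc$vcov[vc$grp == ".cluster"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se),
                              lower = unname(est - crit * se),
                              upper = unname(est + crit * se),
                              z = unname(z), p = unname(p),
                              stringsAsFactors = FALSE),
    cluster_variance = cl_var,
    residual_variance = res_var,
    n_obs = nrow(X),
    n_clusters = nlevels(cluster),
    model = fit
  ), class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Random-intercept linear model:", x$n_obs, "obs in", x$n_clusters,
      "clusters\n")
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat(sprintf("Cluster variance: %.4f  Residual variance: %.4f\n",
              x$cluster_variance, x$residual_variance))
  invisible(x)
}

#' Variance inflation factors
#'
#' For each non-intercept column of a design matrix, `VIF_j = 1 / (1 -
#' R^2_j)` where `R^2_j` comes from regressing that column on all other
#' predictors (with an intercept). Categorical predictors must already be
#' expanded to indicator columns; the VIF is reported per column. Perfect
#' collinearity yields an infinite VIF.
#'
#' @param X Design matrix; a constant column is treated as the intercept and
#'   excluded from the report.
#' @return A `vif_report`: data frame `table` (term, vif) and `max_vif`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  is_const <- apply(X, 2, function(col) sd(col) == 0)
  pred <- colnames(X)[!is_const]
  if (length(pred) < 2L) stop("need at least 2 non-intercept predictors")
  vifs <- vapply(pred, function(v) {
    xj <- X[, v]
    others <- cbind(`(Intercept)` = 1, X[, setdiff(pred, v), drop = FALSE])
    fit <- lm.fit(others, xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(list(table = data.frame(term = pred, vif = unname(vifs),
                                    stringsAsFactors = FALSE),
                 max_vif = max(vifs)),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  print(format(x$table, digits = 3), row.names = FALSE)
  cat("Max VIF:", format(x$max_vif, digits = 3), "\n")
  invisible(x)
}

suite_design <- function(dat) {
  dat$age_group <- stats::relevel(factor(dat$age_group), ref = "18-34")
  dat$sex <- stats::relevel(factor(dat$sex), ref = "male")
  dat$race <- stats::relevel(factor(dat$race), ref = "White")
  dat
}

#' Multilevel BMI model suite
#'
#' Fits four random-intercept (census tract) linear models of BMI on the
#' identical complete-case rows:
#' model 1 `BMI ~ index`; model 2 `BMI ~ ACE4`; model 3 `BMI ~ index +
#' ACE4`; model 4 `BMI ~ index + ACE4 + age + sex + race` (references: age
#' 18-34, male, White). VIFs are computed on the exact fixed-effect designs
#' of models 3 and 4, and the attenuation of the ACE coefficient from model
#' 2 to model 3 is summarized.
#'
#' @param participants Data frame with columns `bmi`, `ace4`, `tract_id`,
#'   `age_group`, `sex`, `race`.
#' @param index_scores Numeric index score per participant row.
#' @param alpha Significance threshold (default 0.05).
#' @return A `model_suite`: list with `models` (m1-m4 `mlm_fit`s), `vif`
#'   (reports for models 3-4), `attenuation`, `n_obs`.
#' @export
run_model_suite <- function(participants, index_scores, alpha = 0.05) {
  need <- c("bmi", "ace4", "tract_id", "age_group", "sex", "race")
  missing_cols <- setdiff(need, names(participants))
  if (length(missing_cols)) stop("participants table missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  stopifnot(length(index_scores) == nrow(participants))
  dat <- participants[, need]
  dat$index <- as.numeric(index_scores)
  keep <- complete.cases(dat)
  dat <- suite_design(dat[keep, , drop = FALSE])

  designs <- list(
    model1 = model.matrix(~ index, dat),
    model2 = model.matrix(~ ace4, dat),
    model3 = model.matrix(~ index + ace4, dat),
    model4 = model.matrix(~ index + ace4 + age_group + sex + race, dat)
  )
  models <- list()
  for (nm in names(designs)) {
    models[[nm]] <- tryCatch(
      fit_mlm(dat$bmi, designs[[nm]], dat$tract_id),
      error = function(e) stop(nm, " failed: ", conditionMessage(e)))
  }
  vifs <- list(model3 = vif(designs$model3), model4 = vif(designs$model4))
  ace_m2 <- models$model2$coefficients
  ace_m3 <- models$model3$coefficients
  a2 <- ace_m2$estimate[ace_m2$term == "ace4"]
  a3 <- ace_m3$estimate[ace_m3$term == "ace4"]
  structure(list(
    models = models,
    vif = vifs,
    attenuation = list(ace_model2 = a2, ace_model3 = a3,
                       change = a3 - a2,
                       attenuated_toward_zero = abs(a3) < abs(a2),
                       ace_p_model2 = ace_m2$p[ace_m2$term == "ace4"],
                       ace_p_model3 = ace_m3$p[ace_m3$term == "ace4"]),
    alpha = alpha,
    n_obs = nrow(dat)
  ), class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Multilevel BMI model suite (", x$n_obs, " observations)\n", sep = "")
  for (nm in names(x$models)) {
    cat("--", nm, "--\n")
    print(x$models[[nm]])
  }
  cat(sprintf("ACE coefficient model 2 -> 3: %.3f -> %.3f (change %.3f)\n",
              x$attenuation$ace_model2, x$attenuation$ace_model3,
              x$attenuation$change))
  cat(sprintf("Max VIF: model 3 = %.2f, model 4 = %.2f\n",
              x$vif$model3$max_vif, x$vif$model4$max_vif))
  invisible(x)
}

#' Write a model suite as delimited text
#'
#' One row per model term: model, term, estimate, 95% CI, p.
#'
#' @param suite A `model_suite`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_model_suite <- function(suite, path) {
  stopifnot(inherits(suite, "model_suite"))
  rows <- lapply(names(suite$models), function(nm) {
    cbind(model = nm, suite$models[[nm]]$coefficients)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
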