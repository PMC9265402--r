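#' Akaike information criterion
#'
#' @param logL Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @return `2 * k - 2 * logL`.
#' @export
aic <- function(logL, k) 2 * k - 2 * logL

#' Construct a logistic-fit record
#'
#' Holds the quantities the index comparison needs. Normally produced by
#' [fit_logistic()]; can also be built directly, e.g. to feed externally
#' computed AICs into [compare_indexes()].
#'
#' @param coefficients Named coefficient vector (may be `NULL`).
#' @param log_likelihood Maximized log-likelihood.
#' @param k Parameter count.
#' @param converged Logical convergence flag.
#' @param slope_p Two-sided p-value for the score coefficient (optional).
#' @return A `logistic_fit` list with `aic = 2k - 2 logL`.
#' @export
logistic_fit <- function(coefficients = NULL, log_likelihood, k,
                         converged = TRUE, slope_p = NA_real_) {
  structure(list(coefficients = coefficients,
                 log_likelihood = log_likelihood,
                 k = as.integer(k),
                 aic = aic(log_likelihood, k),
                 converged = converged,
                 slope_p = slope_p),
            class = "logistic_fit")
}

#' Logistic regression of the binary ACE outcome on one index score
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, tolerance 1e-8, up to 100 iterations) with the binary outcome as
#' dependent variable and a single continuous index score as predictor. A
#' constant score column is dropped, leaving an intercept-only model (k = 1).
#' Perfect separation is flagged via `converged = FALSE` and the capped fit
#' is still reported.
#'
#' @param y Binary outcome (both classes present).
#' @param score Numeric index score column.
#' @return A [logistic_fit()].
#' @export
fit_logistic <- function(y, score) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  score <- as.numeric(score)
  stopifnot(length(score) == length(y))
  separated <- FALSE
  ctrl <- glm.control(epsilon = 1e-8, maxit = 100)
  if (sd(score) == 0) {
    fit <- glm(y ~ 1, family = binomial(), control = ctrl)
    slope_p <- NA_real_
  } else {
    fit <- withCallingHandlers(
      glm(y ~ score, family = binomial(), control = ctrl),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    slope_p <- summary(fit)$coefficients["score", 4]
  }
  k <- length(coef(fit))
  logistic_fit(coefficients = coef(fit),
               log_likelihood = as.numeric(logLik(fit)),
               k = k,
               converged = fit$converged && !separated,
               slope_p = slope_p)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: logL = %.3f, k = %d, AIC = %.2f%s\n",
              x$log_likelihood, x$k, x$aic,
              if (!x$converged) " (separation / non-convergence flagged)" else ""))
  invisible(x)
}

#' Compare candidate indexes by AIC
#'
#' Each method contributes one logistic fit per score column (a multi-column
#' threshold index contributes one fit per component). The best method is the
#' one owning the minimum single-fit AIC; a fit is meaningfully worse when
#' its AIC exceeds the best by at least `meaningful_delta` (default 3), and a
#' multi-fit method is collectively worse when *any* of its fits is
#' meaningfully worse. Exact AIC ties for best are broken by a fixed
#' method-priority order.
#'
#' @param fits Named list: each element a [logistic_fit()] or a list of them
#'   (one per component).
#' @param meaningful_delta AIC difference treated as meaningful.
#' @param priority Character vector giving the tie-break order.
#' @return A `comparison_report`: list with `table` (method, component, aic,
#'   delta_aic, meaningfully_worse), `method_worse` (collective per-method
#'   flag), `selected`, `best_aic`.
#' @export
compare_indexes <- function(fits, meaningful_delta = 3,
                            priority = c("bayes", "first_pc", "supervised",
                                         "threshold")) {
  if (length(fits) == 0L) stop("no fits to compare")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("fits must be a named list")
  rows <- list()
  for (m in names(fits)) {
    f <- fits[[m]]
    if (inherits(f, "logistic_fit")) f <- list(f)
    for (i in seq_along(f)) {
      comp <- names(f)[i]
      if (is.null(comp) || !nzchar(comp)) comp <- paste0("PC", i)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, component = if (length(f) > 1L) comp else "index",
        aic = f[[i]]$aic, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  best_aic <- min(tab$aic)
  tab$delta_aic <- tab$aic - best_aic
  tab$meaningfully_worse <- tab$delta_aic >= meaningful_delta
  method_worse <- tapply(tab$meaningfully_worse, tab$method, any)
  candidates <- unique(tab$method[tab$delta_aic == 0])
  ord <- match(candidates, priority)
  ord[is.na(ord)] <- length(priority) + rank(candidates[is.na(ord)])
  selected <- candidates[which.min(ord)]
  structure(list(table = tab,
                 method_worse = method_worse[unique(tab$method)],
                 selected = selected,
                 best_aic = best_aic,
                 meaningful_delta = meaningful_delta,
                 priority = priority),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Index method comparison (lower AIC is better)\n")
  tab <- x$table
  tab$aic <- sprintf("%.2f", tab$aic)
  tab$delta_aic <- sprintf("%+.2f", tab$delta_aic)
  print(tab, row.names = FALSE)
  worse <- names(x$method_worse)[x$method_worse]
  if (length(worse)) {
    cat("Collectively meaningfully worse (delta AIC >=",
        x$meaningful_delta, "):", paste(worse, collapse = ", "), "\n")
  }
  cat("Selected method:", x$selected, "\n")
  invisible(x)
}

#' Write a comparison report as delimited text
#'
#' @param report A `comparison_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  tab <- report$table
  tab$selected_method <- tab$method == report$selected
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
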