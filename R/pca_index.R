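#' High-loading classification rule
#'
#' Thresholds used by the threshold-based PCA method: a variable loads
#' "high" on a component when its absolute loading is at least `loading_min`
#' and exceeds its largest absolute loading on any other retained component
#' by at least `separation_min`; a component is meaningful when at least
#' `min_vars_per_pc` variables load high on it.
#'
#' @param loading_min Minimum absolute loading (default 0.15).
#' @param separation_min Minimum margin over the other components'
#'   absolute loadings (default 0.10).
#' @param min_vars_per_pc Minimum high-loading variables per component
#'   (default 4).
#' @return A `high_loading_rule` list.
#' @export
high_loading_rule <- function(loading_min = 0.15, separation_min = 0.10,
                              min_vars_per_pc = 4) {
  stopifnot(loading_min > 0, separation_min > 0, min_vars_per_pc > 0)
  structure(list(loading_min = loading_min, separation_min = separation_min,
                 min_vars_per_pc = as.integer(min_vars_per_pc)),
            class = "high_loading_rule")
}

# Deterministic eigenvector signs: each loading column is flipped so its sum
# is positive; a zero sum is broken by making the largest-|loading| entry
# positive.
fix_signs <- function(L) {
  for (a in seq_len(ncol(L))) {
    s <- sum(L[, a])
    if (abs(s) < 1e-12) s <- L[which.max(abs(L[, a])), a]
    if (s < 0) L[, a] <- -L[, a]
  }
  L
}

#' Fit a principal components solution
#'
#' Eigendecomposition of the sample covariance of `Z`; with `Z` standardized
#' this is the correlation structure. The top `k` components are retained
#' with a deterministic sign convention (each loading column sums positive).
#'
#' @param Z Standardized numeric matrix (see [standardize_columns()]).
#' @param k Number of components to retain.
#' @return A `pca_solution`: list with `loadings` (variables x components),
#'   `eigenvalues` (all), `prop_variance` (retained components),
#'   `variable_names`, `scores` (row projections), `k`.
#' @export
fit_pca <- function(Z, k) {
  Z <- as_matrix_values(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("v", seq_len(ncol(Z)))
  kmax <- min(nrow(Z) - 1L, ncol(Z))
  if (k < 1 || k > kmax) {
    stop("k must be between 1 and min(rows - 1, cols) = ", kmax)
  }
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  L <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE])
  structure(list(
    loadings = L,
    eigenvalues = eig,
    prop_variance = eig[seq_len(k)] / sum(eig),
    variable_names = colnames(Z),
    scores = Z %*% L,
    k = as.integer(k)
  ), class = "pca_solution")
}

#' @export
print.pca_solution <- function(x, ...) {
  cat("PCA solution:", length(x$variable_names), "variables,", x$k,
      "component(s)\n")
  cat("Proportion of variance:",
      paste(sprintf("%.3f", x$prop_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Classify variables as high-loading per component
#'
#' Applies the [high_loading_rule()]: variable v is high on component a iff
#' `|loading(v,a)| >= loading_min` and its margin over the maximum absolute
#' loading on the other components is at least `separation_min`. With a
#' single component the separation clause passes vacuously.
#'
#' @param solution A `pca_solution`.
#' @param rule A [high_loading_rule()].
#' @return Logical matrix, variables x components.
#' @export
classify_high_loading <- function(solution, rule = high_loading_rule()) {
  A <- abs(solution$loadings)
  k <- ncol(A)
  if (k < 1) stop("solution has no components")
  high <- A >= rule$loading_min
  if (k > 1) {
    for (a in seq_len(k)) {
      other_max <- apply(A[, -a, drop = FALSE], 1, max)
      high[, a] <- high[, a] & (A[, a] - other_max >= rule$separation_min)
    }
  }
  high
}

new_index_definition <- function(method, loadings, variable_names,
                                 preprocessing = list()) {
  structure(list(method = method,
                 loadings = loadings,
                 variable_names = variable_names,
                 preprocessing = preprocessing,
                 n_score_columns = ncol(loadings)),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat("Index definition [", x$method, "]: ", length(x$variable_names),
      " variables, ", x$n_score_columns, " score column(s)\n", sep = "")
  invisible(x)
}

#' Threshold-based PCA index with iterative variable reduction
#'
#' Starting from a two-component solution, the number of components is
#' increased while every component keeps at least `min_vars_per_pc`
#' high-loading variables. When a component first falls short at k
#' components, the last valid solution is used (k - 1 components, or the
#' two-component solution itself if that already fails); variables that load
#' high on none of its components are dropped, and the procedure restarts at
#' two components on the reduced set. It stops when a pass drops no
#' variables; the final solution's components are returned collectively as a
#' (possibly multi-column) index.
#'
#' @param Z Standardized matrix.
#' @param rule A [high_loading_rule()].
#' @param use_failing_solution If `TRUE`, variables are dropped using the
#'   failing k-component solution instead of the last valid one (an
#'   alternative reading of the procedure).
#' @return A list with `index` (an `index_definition`) and `trace` (a
#'   `threshold_trace` recording every fit, the drops, and the stop reason).
#' @export
threshold_pca_index <- function(Z, rule = high_loading_rule(),
                                use_failing_solution = FALSE) {
  Z <- as_matrix_values(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("v", seq_len(ncol(Z)))
  if (ncol(Z) < rule$min_vars_per_pc) {
    stop("need at least ", rule$min_vars_per_pc, " variables")
  }
  vars <- colnames(Z)
  trace <- list()
  warned <- FALSE
  pass <- 0L
  final <- NULL
  repeat {
    pass <- pass + 1L
    Zv <- Z[, vars, drop = FALSE]
    kmax <- min(nrow(Zv) - 1L, ncol(Zv))
    k <- 2L
    last_valid <- NULL
    failing <- NULL
    repeat {
      sol <- fit_pca(Zv, min(k, kmax))
      flags <- classify_high_loading(sol, rule)
      n_high <- colSums(flags)
      valid <- all(n_high >= rule$min_vars_per_pc)
      trace[[length(trace) + 1L]] <- list(
        pass = pass, k = sol$k, n_high = unname(n_high), valid = valid,
        n_vars = length(vars))
      if (valid) {
        last_valid <- sol
        if (k >= kmax) break
        k <- k + 1L
      } else {
        failing <- sol
        break
      }
    }
    drop_sol <- if (use_failing_solution && !is.null(failing)) failing
                else if (!is.null(last_valid)) last_valid
                else failing   # k = 2 itself failed: drop from it anyway
    flags <- classify_high_loading(drop_sol, rule)
    dropped <- vars[rowSums(flags) == 0]
    trace[[length(trace)]]$dropped <- dropped
    if (length(dropped) == 0L) {
      final <- drop_sol
      trace[[length(trace)]]$stop_reason <- "no further variables to drop"
      break
    }
    remaining <- setdiff(vars, dropped)
    if (length(remaining) < rule$min_vars_per_pc) {
      final <- drop_sol
      warned <- TRUE
      trace[[length(trace)]]$stop_reason <-
        "dropping would leave fewer variables than min_vars_per_pc"
      warning("variable reduction stopped: fewer than ", rule$min_vars_per_pc,
              " variables would remain; returning prior solution")
      break
    }
    vars <- remaining
  }
  defn <- new_index_definition(
    "threshold_pca", final$loadings, final$variable_names,
    preprocessing = list(standardized = TRUE,
                         rule = unclass(rule)))
  trace <- structure(list(iterations = trace, warned = warned),
                     class = "threshold_trace")
  list(index = defn, trace = trace)
}

#' @export
print.threshold_trace <- function(x, ...) {
  for (it in x$iterations) {
    cat(sprintf("pass %d: k=%d, vars=%d, high per PC = [%s]%s\n",
                it$pass, it$k, it$n_vars,
                paste(it$n_high, collapse = ","),
                if (!is.null(it$dropped) && length(it$dropped))
                  paste0(" -> drop ", length(it$dropped)) else ""))
    if (!is.null(it$stop_reason)) cat("  stop:", it$stop_reason, "\n")
  }
  invisible(x)
}

#' First principal component as index
#'
#' @param Z Standardized matrix.
#' @return An `index_definition` with a single score column; all variables
#'   retained.
#' @export
first_pc_index <- function(Z) {
  sol <- fit_pca(Z, 1)
  new_index_definition("first_pc", sol$loadings, sol$variable_names,
                       preprocessing = list(standardized = TRUE,
                                            prop_variance = sol$prop_variance))
}

#' Supervised PCA index
#'
#' Finds the single direction of the variable space with the greatest
#' dependence on a binary response. With a linear kernel on the centered
#' response the response-dependence operator `Z' y_c y_c' Z` is rank one, so
#' its leading eigenvector is proportional to the vector of covariances
#' between each column and the centered response; that direction (unit
#' normalized, deterministic sign) defines the index. All variables are
#' retained. A screening variant (univariate filter, then ordinary first PC
#' on the passing columns) is available via `variant = "screen"`.
#'
#' @param Z Standardized matrix.
#' @param y Binary response (both classes present).
#' @param variant `"dependence"` (default) or `"screen"`.
#' @param screen_alpha Univariate p-value threshold for the screening
#'   variant.
#' @return An `index_definition` with one score column.
#' @export
supervised_pca_index <- function(Z, y, variant = c("dependence", "screen"),
                                 screen_alpha = 0.05) {
  variant <- match.arg(variant)
  Z <- as_matrix_values(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("v", seq_len(ncol(Z)))
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("response y is constant")
  if (nrow(Z) != length(y)) stop("Z rows must match length(y)")
  yc <- y - mean(y)
  if (variant == "dependence") {
    v <- drop(crossprod(Z, yc))
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("response has zero covariance with every column")
    L <- fix_signs(matrix(v / nv, ncol = 1,
                          dimnames = list(colnames(Z), "PC1")))
    new_index_definition("supervised_pca", L, colnames(Z),
                         preprocessing = list(standardized = TRUE,
                                              variant = variant))
  } else {
    pvals <- apply(Z, 2, function(x) {
      f <- summary(glm(y ~ x, family = binomial()))$coefficients
      if (nrow(f) < 2) 1 else f[2, 4]
    })
    keep <- colnames(Z)[pvals <= screen_alpha]
    if (length(keep) < 1L) stop("no columns pass the univariate screen")
    sol <- fit_pca(Z[, keep, drop = FALSE], 1)
    new_index_definition("supervised_pca", sol$loadings, keep,
                         preprocessing = list(standardized = TRUE,
                                              variant = variant,
                                              screen_alpha = screen_alpha))
  }
}

#' Apply an index definition to data
#'
#' Projects rows of `Z` onto the stored loading columns. Columns of `Z` must
#' cover exactly the definition's variable set (extra columns are ignored
#' after a match check on the required ones).
#'
#' @param defn An `index_definition`.
#' @param Z Matrix with the definition's variables as columns.
#' @return Numeric matrix of scores, one column per retained component.
#' @export
apply_index <- function(defn, Z) {
  stopifnot(inherits(defn, "index_definition"))
  Z <- as_matrix_values(Z)
  if (is.null(colnames(Z)) && ncol(Z) == length(defn$variable_names)) {
    colnames(Z) <- defn$variable_names
  }
  missing <- setdiff(defn$variable_names, colnames(Z))
  if (length(missing)) {
    stop("columns missing for index application: ",
         paste(missing, collapse = ", "))
  }
  Z[, defn$variable_names, drop = FALSE] %*% defn$loadings
}

#' Serialize / restore an index definition
#'
#' Writes the definition (method, variable names, loadings at full floating
#' point precision, preprocessing provenance) as JSON so it can be re-applied
#' to new data bit-identically.
#'
#' @param defn An `index_definition`.
#' @param path File path.
#' @return `write_index_definition` returns `path` invisibly;
#'   `read_index_definition` returns the restored `index_definition`.
#' @export
write_index_definition <- function(defn, path) {
  stopifnot(inherits(defn, "index_definition"))
  obj <- list(method = defn$method,
              variable_names = defn$variable_names,
              loadings = defn$loadings,
              colnames_loadings = colnames(defn$loadings),
              preprocessing = defn$preprocessing,
              n_score_columns = defn$n_score_columns)
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_index_definition
#' @export
read_index_definition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- matrix(obj$loadings, ncol = obj$n_score_columns,
              dimnames = list(obj$variable_names, obj$colnames_loadings))
  new_index_definition(obj$method, L, obj$variable_names,
                       preprocessing = as.list(obj$preprocessing))
}
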