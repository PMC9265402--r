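#' Orient variables so higher values align with higher adversity risk
#'
#' Index construction assumes every column points in the same direction:
#' higher value, higher expected ACE exposure. Columns whose spec says
#' `direction = "inverse"` are flipped with `max(x) - x_j`, where the maximum
#' is taken over the rows supplied here (the analysis set). Risk-aligned
#' columns pass through unchanged.
#'
#' @param raw Numeric matrix or data frame, one column per variable, column
#'   names matching `specs$name`.
#' @param specs Variable spec table, see [variable_spec()].
#' @return An object of class `oriented_matrix`: a list with `values` (the
#'   oriented numeric matrix), `specs`, and `inverted` (names of flipped
#'   columns).
#' @export
orient_variables <- function(raw, specs) {
  validate_specs(specs)
  X <- as.matrix(raw)
  if (nrow(X) == 0L) stop("cannot orient an empty table (zero rows)")
  if (ncol(X) != nrow(specs)) {
    stop("column count (", ncol(X), ") does not match spec count (",
         nrow(specs), ")")
  }
  if (is.null(colnames(X))) colnames(X) <- specs$name
  if (!identical(colnames(X), specs$name)) {
    missing <- setdiff(specs$name, colnames(X))
    if (length(missing)) stop("columns missing from input: ",
                              paste(missing, collapse = ", "))
    X <- X[, specs$name, drop = FALSE]
  }
  inv <- specs$name[specs$direction == "inverse"]
  for (v in inv) {
    if (anyNA(X[, v])) {
      stop("inverse-direction column '", v,
           "' contains missing values; drop incomplete rows first")
    }
    X[, v] <- max(X[, v]) - X[, v]
  }
  structure(list(values = X, specs = specs, inverted = inv),
            class = "oriented_matrix")
}

#' @export
print.oriented_matrix <- function(x, ...) {
  cat("Oriented variable matrix:", nrow(x$values), "rows x",
      ncol(x$values), "variables\n")
  if (length(x$inverted)) {
    cat("Inverted (max(x) - x):", paste(x$inverted, collapse = ", "), "\n")
  } else cat("No columns inverted\n")
  invisible(x)
}

as_matrix_values <- function(X) {
  if (inherits(X, "oriented_matrix")) X$values else as.matrix(X)
}

#' Drop rows with missing values in required columns
#'
#' Complete-case filtering used before index construction: any row missing a
#' value in one of the required columns is removed, and the number dropped is
#' reported.
#'
#' @param table A data frame.
#' @param required_columns Character vector of column names that must be
#'   non-missing.
#' @return A list with `table` (filtered data frame) and `n_dropped`.
#' @export
drop_incomplete <- function(table, required_columns = names(table)) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(required_columns, names(table))
  if (length(missing_cols)) {
    stop("required columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- complete.cases(table[, required_columns, drop = FALSE])
  n_dropped <- sum(!keep)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all rows dropped: empty analysis set")
  rownames(out) <- NULL
  list(table = out, n_dropped = n_dropped)
}

#' Center and scale columns
#'
#' Each column is centered to mean zero and scaled to unit sample standard
#' deviation (denominator n - 1), so that variables measured on large scales
#' do not dominate a principal components analysis.
#'
#' @param X Numeric matrix or `oriented_matrix`.
#' @return Numeric matrix with standardized columns.
#' @export
standardize_columns <- function(X) {
  M <- as_matrix_values(X)
  sds <- apply(M, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(M)[const], collapse = ", "))
  }
  Z <- scale(M, center = TRUE, scale = sds)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z[, , drop = FALSE]
}

#' Quantile (decile) scoring of variables
#'
#' Converts each column to integer scores 0..Q-1 by equal-frequency binning.
#' Cutpoints are the empirical k/Q quantiles (k = 1..Q-1, linear-interpolation
#' "type 7" convention); a value's score is the number of cutpoints strictly
#' below it. Ties therefore all receive the same score — the lowest bin
#' consistent with the cutpoints — and a constant column scores 0 everywhere.
#'
#' @param X Numeric matrix or `oriented_matrix` (rows = tracts or
#'   participants).
#' @param Q Number of quantile bins (default 10 = deciles).
#' @return An object of class `quantile_matrix`: list with `scores` (integer
#'   matrix), `n_quantiles`, and `cutpoints` ((Q-1) x p matrix).
#' @export
quantile_score <- function(X, Q = 10) {
  stopifnot(is.numeric(Q), length(Q) == 1L, Q >= 2)
  Q <- as.integer(Q)
  M <- as_matrix_values(X)
  if (anyNA(M)) stop("missing values present; drop incomplete rows first")
  probs <- seq_len(Q - 1L) / Q
  cut <- apply(M, 2, quantile, probs = probs, type = 7, names = FALSE)
  cut <- matrix(cut, nrow = Q - 1L, dimnames = list(NULL, colnames(M)))
  scores <- score_with_cutpoints(M, cut)
  structure(list(scores = scores, n_quantiles = Q, cutpoints = cut),
            class = "quantile_matrix")
}

#' Apply learned quantile cutpoints to new rows
#'
#' Scores rows of `M` against previously learned per-column cutpoints (see
#' [quantile_score()]); used to score participants with tract-level cutpoints.
#'
#' @param M Numeric matrix with the same columns as the cutpoint matrix.
#' @param cutpoints (Q-1) x p cutpoint matrix, or a `quantile_matrix`.
#' @return Integer score matrix.
#' @export
score_with_cutpoints <- function(M, cutpoints) {
  if (inherits(cutpoints, "quantile_matrix")) cutpoints <- cutpoints$cutpoints
  M <- as_matrix_values(M)
  if (!identical(colnames(M), colnames(cutpoints))) {
    M <- M[, colnames(cutpoints), drop = FALSE]
  }
  out <- matrix(0L, nrow(M), ncol(M), dimnames = dimnames(M))
  for (j in seq_len(ncol(M))) {
    # count of cutpoints strictly below the value: left-open intervals,
    # ties collapse to the lowest bin
    out[, j] <- findInterval(M[, j], cutpoints[, j], left.open = TRUE)
  }
  storage.mode(out) <- "integer"
  out
}

#' @export
print.quantile_matrix <- function(x, ...) {
  cat("Quantile score matrix:", nrow(x$scores), "rows x", ncol(x$scores),
      "variables, Q =", x$n_quantiles, "\n")
  invisible(x)
}
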