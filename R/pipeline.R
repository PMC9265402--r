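#' Pipeline run configuration
#'
#' Either a simulation config (`simulate`) or file paths to tract and
#' participant tables must be supplied. The configuration carries everything
#' downstream stages need: variable specs, the method list, MCMC settings,
#' the high-loading rule, the comparison tie-break order, and the output
#' directory.
#'
#' @param simulate A [sim_config()], or `NULL` to read files.
#' @param tract_file,participant_file CSV paths (used when `simulate` is
#'   `NULL`).
#' @param specs Variable spec table (default [default_variable_specs()]).
#' @param methods Index methods to run, a subset of
#'   `c("threshold", "first_pc", "supervised", "bayes")`.
#' @param mcmc An [mcmc_settings()].
#' @param rule A [high_loading_rule()].
#' @param priority Tie-break order for [compare_indexes()].
#' @param index_mode `"quantile"` or `"raw"` for applying the Bayesian index
#'   to the outcome models.
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @param seed Integer seed recorded in the manifest (and used for the
#'   simulation / MCMC when those carry no explicit seed).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, tract_file = NULL,
                       participant_file = NULL,
                       specs = default_variable_specs(),
                       methods = c("threshold", "first_pc", "supervised",
                                   "bayes"),
                       mcmc = mcmc_settings(),
                       rule = high_loading_rule(),
                       priority = c("bayes", "first_pc", "supervised",
                                    "threshold"),
                       index_mode = c("quantile", "raw"),
                       output_dir = NULL,
                       seed = 1L) {
  index_mode <- match.arg(index_mode)
  if (is.null(simulate) && (is.null(tract_file) || is.null(participant_file))) {
    stop("either a simulate config or both input file paths are required")
  }
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(simulate = simulate, tract_file = tract_file,
                 participant_file = participant_file, specs = specs,
                 methods = methods, mcmc = mcmc, rule = rule,
                 priority = priority, index_mode = index_mode,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and validate tract and participant tables
#'
#' Reads comma-separated tables with header rows and validates them:
#' percent-type variables must lie in \[0, 100\] and rate-type variables be
#' non-negative, tract ids must be unique, ACE counts in 0-14, BMI positive,
#' and every participant's tract id must exist in the tract table.
#' Violations are reported with row numbers.
#'
#' @param tract_file,participant_file CSV paths.
#' @param specs Variable spec table.
#' @return A list with `tracts` and `participants` data frames (specs
#'   attached to the tract table).
#' @export
read_tables <- function(tract_file, participant_file,
                        specs = default_variable_specs()) {
  validate_specs(specs)
  tracts <- read.csv(tract_file, check.names = FALSE,
                     stringsAsFactors = FALSE)
  participants <- read.csv(participant_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  unknown <- setdiff(specs$name, names(tracts))
  if (length(unknown)) stop("tract table is missing variable column(s): ",
                            paste(unknown, collapse = ", "))
  if (!"tract_id" %in% names(tracts)) stop("tract table needs a tract_id column")
  dup <- duplicated(tracts$tract_id)
  if (any(dup)) stop("duplicate tract id(s): ",
                     paste(unique(tracts$tract_id[dup]), collapse = ", "))
  for (j in seq_len(nrow(specs))) {
    v <- specs$name[j]
    x <- tracts[[v]]
    bad <- if (specs$scale_type[j] == "percent") {
      which(!is.na(x) & (x < 0 | x > 100))
    } else {
      which(!is.na(x) & x < 0)
    }
    if (length(bad)) {
      stop("variable '", v, "' out of range (",
           specs$scale_type[j], ") at tract row(s): ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  need <- c("participant_id", "tract_id", "ace_count", "bmi")
  missing_cols <- setdiff(need, names(participants))
  if (length(missing_cols)) stop("participant table missing column(s): ",
                                 paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(participants$ace_count) &
                 (participants$ace_count < 0 | participants$ace_count > 14))
  if (length(bad)) stop("ace_count out of range 0-14 at participant row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.na(participants$bmi) & participants$bmi <= 0)
  if (length(bad)) stop("non-positive BMI at participant row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  orphan <- which(!participants$tract_id %in% tracts$tract_id)
  if (length(orphan)) {
    stop("participant tract_id not present in tract table at row(s): ",
         paste(head(orphan, 5), collapse = ", "))
  }
  if (!"ace4" %in% names(participants)) {
    participants$ace4 <- as.integer(participants$ace_count >= 4)
  }
  attr(tracts, "specs") <- specs
  list(tracts = tracts, participants = participants)
}

#' Run the full index-construction pipeline
#'
#' Orchestrates the end-to-end workflow: obtain data (simulate or read),
#' complete-case filtering, variable orientation on the analysis set,
#' standardization and decile scoring, the requested index-construction
#' methods, per-index logistic regressions and AIC comparison, and the
#' multilevel BMI model suite using the selected method's index. When
#' `config$output_dir` is set, every intermediate artifact is written
#' (oriented-matrix summary, PCA solutions and threshold trace, MCMC chains,
#' posterior summary, comparison report, model suite, and a manifest with the
#' seed and a config hash).
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: list with `comparison`, `suite`, `indexes`,
#'   `bayes_fit` (if run), `selected`, `data`, and `artifacts` (paths, when
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  dat <- stage("input", {
    if (!is.null(config$simulate)) {
      tracts <- generate_tracts(config$simulate)
      gp <- generate_participants(tracts, config$simulate)
      list(tracts = tracts, participants = gp$participants,
           truth = gp$truth, specs = attr(tracts, "specs"))
    } else {
      rt <- read_tables(config$tract_file, config$participant_file,
                        config$specs)
      list(tracts = rt$tracts, participants = rt$participants,
           truth = NULL, specs = config$specs)
    }
  })
  specs <- dat$specs

  pre <- stage("preprocess", {
    merged <- merge(dat$participants,
                    dat$tracts[, c("tract_id", specs$name)],
                    by = "tract_id", sort = FALSE)
    merged <- merged[order(merged$participant_id), , drop = FALSE]
    dc <- drop_incomplete(merged, c(specs$name, "ace4", "bmi"))
    analysis <- dc$table
    oriented <- orient_variables(analysis[, specs$name], specs)
    Z <- standardize_columns(oriented)
    # decile cutpoints learned on tract-level rows, looked up per participant
    tr_oriented <- orient_variables(dat$tracts[, specs$name], specs)
    qm_tr <- quantile_score(tr_oriented, Q = config$mcmc$n_quantiles)
    q_part <- score_with_cutpoints(oriented$values, qm_tr$cutpoints)
    list(analysis = analysis, oriented = oriented, Z = Z,
         qm_tracts = qm_tr, q_participants = q_part,
         n_dropped = dc$n_dropped)
  })
  y <- pre$analysis$ace4

  indexes <- list(); scores <- list(); fits <- list()
  thr_trace <- NULL; bayes_fit <- NULL

  if ("threshold" %in% config$methods) {
    res <- stage("threshold_pca", threshold_pca_index(pre$Z, config$rule))
    indexes$threshold <- res$index
    thr_trace <- res$trace
    sc <- apply_index(res$index, pre$Z)
    scores$threshold <- sc
    fits$threshold <- lapply(seq_len(ncol(sc)),
                             function(i) fit_logistic(y, sc[, i]))
    names(fits$threshold) <- colnames(sc)
  }
  if ("first_pc" %in% config$methods) {
    indexes$first_pc <- stage("first_pc", first_pc_index(pre$Z))
    scores$first_pc <- apply_index(indexes$first_pc, pre$Z)
    fits$first_pc <- fit_logistic(y, scores$first_pc[, 1])
  }
  if ("supervised" %in% config$methods) {
    indexes$supervised <- stage("supervised_pca",
                                supervised_pca_index(pre$Z, y))
    scores$supervised <- apply_index(indexes$supervised, pre$Z)
    fits$supervised <- fit_logistic(y, scores$supervised[, 1])
  }
  if ("bayes" %in% config$methods) {
    bayes_fit <- stage("bayes_index",
                       fit_bayes_index(pre$q_participants, y, config$mcmc))
    scores$bayes <- matrix(
      apply_bayes_index(bayes_fit, pre$q_participants, mode = "quantile"),
      ncol = 1)
    fits$bayes <- fit_logistic(y, scores$bayes[, 1])
  }

  comparison <- stage("compare",
                      compare_indexes(fits, priority = config$priority))
  selected <- comparison$selected

  suite_scores <- if (selected == "bayes" && config$index_mode == "raw") {
    apply_bayes_index(bayes_fit, pre$oriented, mode = "raw")
  } else {
    scores[[selected]][, 1]
  }
  suite <- stage("outcome_models",
                 run_model_suite(pre$analysis, suite_scores))

  result <- structure(list(
    comparison = comparison, suite = suite, indexes = indexes,
    bayes_fit = bayes_fit, threshold_trace = thr_trace,
    selected = selected,
    data = list(tracts = dat$tracts, participants = pre$analysis,
                truth = dat$truth, n_dropped = pre$n_dropped,
                q_participants = pre$q_participants),
    artifacts = NULL
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    result$artifacts <- stage("write_artifacts",
                              write_pipeline_artifacts(result, pre, config))
  }
  result
}

write_pipeline_artifacts <- function(result, pre, config) {
  dir <- config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  M <- pre$oriented$values
  osum <- data.frame(variable = colnames(M),
                     mean = colMeans(M),
                     sd = apply(M, 2, sd),
                     min = apply(M, 2, min),
                     max = apply(M, 2, max),
                     inverted = colnames(M) %in% pre$oriented$inverted)
  write.csv(osum, add(file.path(dir, "oriented_summary.csv")),
            row.names = FALSE)

  for (m in names(result$indexes)) {
    write_index_definition(result$indexes[[m]],
                           add(file.path(dir, paste0("index_", m, ".json"))))
  }
  if (!is.null(result$threshold_trace)) {
    jsonlite::write_json(result$threshold_trace$iterations,
                         add(file.path(dir, "threshold_trace.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$bayes_fit)) {
    write_chains(result$bayes_fit, add(file.path(dir, "chains.csv")))
    write.csv(result$bayes_fit$summary$table,
              add(file.path(dir, "posterior_summary.csv")),
              row.names = FALSE)
  }
  write_comparison(result$comparison,
                   add(file.path(dir, "comparison.csv")))
  write_model_suite(result$suite, add(file.path(dir, "model_suite.csv")))

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "specs")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   mcmc_seed = config$mcmc$seed,
                   selected = result$selected,
                   n_dropped = result$data$n_dropped,
                   package_version =
                     as.character(utils::packageVersion("aceindex")))
  unlink(tmp)
  jsonlite::write_json(manifest, add(file.path(dir, "manifest.json")),
                       auto_unbox = TRUE)
  unlist(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$comparison)
  cat("\n")
  cat(sprintf("ACE coefficient model 2 -> 3: %.3f -> %.3f\n",
              x$suite$attenuation$ace_model2, x$suite$attenuation$ace_model3))
  invisible(x)
}
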