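#' Read an expression matrix from TSV
#'
#' Expects samples as rows: a header whose first cell names the id column
#' and remaining cells are gene names, then one row per sample. TSV is used
#' for expression because gene annotations may contain commas.
#'
#' @param path TSV file.
#' @return list with `matrix` (samples x genes), `gene_names`, `sample_ids`.
#' @export
read_expression <- function(path) {
  df <- read.csv(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop_input("expression file has no columns")
  sample_ids <- as.character(df[[1]])
  gene_names <- colnames(df)[-1]
  if (anyDuplicated(gene_names))
    stop_input("duplicate gene column(s): ",
               paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_input("duplicate sample id(s): ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop_input("non-numeric values in expression matrix")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop_input("missing values in expression matrix at (sample, gene): ",
               paste(apply(bad, 1, function(r)
                 paste0("(", sample_ids[r[1]], ", ", gene_names[r[2]], ")")),
                 collapse = ", "))
  }
  if (any(!is.finite(mat))) stop_input("non-finite values in expression matrix")
  rownames(mat) <- sample_ids
  list(matrix = mat, gene_names = gene_names, sample_ids = sample_ids)
}

#' Write an expression matrix to TSV
#'
#' @param data a [survival_dataset()] or a numeric matrix with dimnames.
#' @param path output file.
#' @param id_column header of the sample-id column.
#' @export
write_expression <- function(data, path, id_column = "sample_id") {
  mat <- if (inherits(data, "survival_dataset")) data$expression else as.matrix(data)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival table from CSV
#'
#' Expects columns `sample_id,time,event` and optionally `group`.
#'
#' @param path CSV file.
#' @return data frame with `sample_id`, `time`, `event` (and `group`).
#' @export
read_survival <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(df)))
    stop_input("survival table must have columns ",
               paste(need, collapse = ","), " (got: ",
               paste(colnames(df), collapse = ","), ")")
  if (any(!is.finite(df$time) | df$time <= 0))
    stop_input("times must be finite and strictly positive; offending rows: ",
               paste(which(!is.finite(df$time) | df$time <= 0), collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop_input("event must be 0/1; offending rows: ",
               paste(which(!df$event %in% c(0, 1)), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write the survival table of a dataset to CSV
#'
#' @param data a [survival_dataset()].
#' @param path output file.
#' @export
write_survival <- function(data, path) {
  df <- data.frame(sample_id = data$sample_ids, time = data$times,
                   event = data$events, stringsAsFactors = FALSE)
  if (!is.null(data$group)) df$group <- data$group
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and align an expression matrix and survival table into a dataset
#'
#' Samples are matched on id; any id present on one side only is an error
#' (no silent dropping). A complete mismatch usually means the expression
#' file is transposed (genes as rows), which the error message points out.
#'
#' @param expression_path TSV expression file (see [read_expression()]).
#' @param survival_path CSV survival table (see [read_survival()]).
#' @return a [survival_dataset()] in the expression file's sample order.
#' @export
read_cohort <- function(expression_path, survival_path) {
  ex <- read_expression(expression_path)
  sv <- read_survival(survival_path)
  if (length(intersect(ex$sample_ids, sv$sample_id)) == 0)
    stop_input("no sample ids shared between expression and survival ",
               "tables; is the expression file transposed (genes as rows)?")
  missing_sv <- setdiff(ex$sample_ids, sv$sample_id)
  missing_ex <- setdiff(sv$sample_id, ex$sample_ids)
  if (length(missing_sv) > 0)
    stop_input("samples missing from survival table: ",
               paste(missing_sv, collapse = ", "))
  if (length(missing_ex) > 0)
    stop_input("samples missing from expression matrix: ",
               paste(missing_ex, collapse = ", "))
  sv <- sv[match(ex$sample_ids, sv$sample_id), , drop = FALSE]
  survival_dataset(ex$matrix, sv$time, sv$event,
                   sample_ids = ex$sample_ids, gene_names = ex$gene_names,
                   group = sv$group)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Default pipeline configuration
#'
#' @param expression,survival optional input paths; when `NULL` a synthetic
#'   cohort is simulated from `generator`.
#' @param out output directory.
#' @param seed master seed for simulation and fold assignment.
#' @param generator a [generator_config()] (used when simulating).
#' @param penalty a [penalty_config()] template.
#' @param k_folds,n_lambda,lambda_min_ratio cross-validation settings.
#' @param cure_threshold,horizon prediction and evaluation settings.
#' @export
pipeline_config <- function(expression = NULL, survival = NULL, out = "curemix_out",
                            seed = 1L, generator = generator_config(seed = seed),
                            penalty = penalty_config(tolerance = 1e-4,
                                                     max_iterations = 50L),
                            k_folds = 5, n_lambda = 4, lambda_min_ratio = 0.05,
                            cure_threshold = 0.5, horizon = 5) {
  list(expression = expression, survival = survival, out = out,
       seed = as.integer(seed), generator = generator, penalty = penalty,
       k_folds = k_folds, n_lambda = n_lambda,
       lambda_min_ratio = lambda_min_ratio,
       cure_threshold = cure_threshold, horizon = horizon)
}

#' Run the full analysis pipeline
#'
#' Simulate (when no input files are given) -> cross-validate penalties ->
#' fit -> predict/stratify -> Kaplan-Meier by predicted groups -> evaluate.
#' Writes `model.json`, `cure_genes.csv`, `latency_genes.csv`,
#' `predictions.csv` (expression-only rule, as applied to new samples),
#' `training_stratification.csv` (posterior rule for the fitted cohort),
#' `baseline_hazard.csv`, `km/*.csv` (stratified by the posterior labels),
#' `report.json` and `manifest.json` (seed, config hash, package version)
#' under `config$out`.
#' Reruns with an identical config and seed produce byte-identical gene
#' tables and predictions.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the fitted model, predictions, evaluation
#'   report and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$expression)) {
    gen <- config$generator
    gen$seed <- config$seed
    cohort <- simulate_cohort(gen)
    data <- cohort$data
    write_cohort(cohort, file.path(out, "simulated"))
  } else {
    data <- read_cohort(config$expression, config$survival)
  }

  grid <- default_lambda_grid(data, n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio,
                              penalty = config$penalty)
  cv <- mcm_cv(data, grid, k_folds = config$k_folds, seed = config$seed,
               penalty = config$penalty, cure_threshold = config$cure_threshold)
  fit <- suppressWarnings(mcm_fit(data, cv$best_penalty, config$cure_threshold))

  pred <- predict(fit, data$expression, horizon = config$horizon)
  strat <- stratify_training(fit, data, horizon = config$horizon)
  genes <- selected_genes(fit)
  # KM stratification uses the posterior cure labels: for samples with
  # observed follow-up the posterior is the right classifier (events are
  # susceptible with certainty)
  km_all <- km_by_group(data, strat$cure_label)
  susc <- strat$cure_label == "susceptible"
  km_risk <- if (sum(susc) > 0) {
    km_by_group(survival_dataset(data$expression[susc, , drop = FALSE],
                                 data$times[susc], data$events[susc],
                                 sample_ids = data$sample_ids[susc],
                                 gene_names = data$gene_names),
                strat$risk_group[susc])
  } else NULL
  report <- evaluate_fit(fit, data, horizon = config$horizon)

  write_mcm(fit, file.path(out, "model.json"))
  write.csv(genes$cure, file.path(out, "cure_genes.csv"), row.names = FALSE)
  write.csv(genes$latency, file.path(out, "latency_genes.csv"), row.names = FALSE)
  write.csv(pred, file.path(out, "predictions.csv"), row.names = FALSE)
  write.csv(strat, file.path(out, "training_stratification.csv"),
            row.names = FALSE)
  write_baseline(fit$parameters$baseline, file.path(out, "baseline_hazard.csv"))
  write_km(km_all, file.path(out, "km"))
  if (!is.null(km_risk)) write_km(km_risk, file.path(out, "km"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  strip_classes <- function(x) if (is.list(x)) lapply(x, strip_classes) else x
  cfg_serializable <- strip_classes(config)
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(cfg_serializable),
                   config = cfg_serializable,
                   package_version = as.character(utils::packageVersion("curemix")),
                   selected_lambda = list(
                     incidence = cv$best_penalty$lambda_incidence,
                     latency = cv$best_penalty$lambda_latency))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fit = fit, cv = cv, predictions = pred, report = report,
                 out = out))
}
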