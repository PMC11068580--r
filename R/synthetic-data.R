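#' Configuration for the synthetic mixture-cure cohort generator
#'
#' Defaults emulate the scale of an adult CN-AML cohort profiled by RNA-seq:
#' about 300 patients, a few thousand standardized expression covariates in
#' correlated blocks, a cured subpopulation of roughly 40%, relapse times in
#' years with a finite susceptible support so the Kaplan-Meier curve shows a
#' genuine plateau, and an administrative censoring horizon of 10 years.
#'
#' @param n_samples number of patients.
#' @param n_genes number of expression covariates.
#' @param n_blocks number of equicorrelated gene blocks (genes are split as
#'   evenly as possible; `n_blocks = n_genes` gives independent genes).
#' @param within_block_correlation common correlation inside a block, in
#'   `[0, 1)`.
#' @param n_true_incidence,n_true_latency number of genes with nonzero true
#'   effects in each component (overlap allowed and recorded).
#' @param effect_size_incidence true log-odds per unit expression
#'   (alternating signs across the chosen genes).
#' @param effect_size_latency true log-hazard per unit expression
#'   (alternating signs).
#' @param incidence_intercept true log-odds of susceptibility at average
#'   expression; the cure fraction is about `1 - expit(incidence_intercept)`.
#' @param baseline_shape,baseline_scale Weibull shape/scale of the
#'   susceptible event-time law (years).
#' @param susceptible_time_cap upper truncation of susceptible event times
#'   (resampled within `[0, cap]`), enforcing finite support so the plateau
#'   is a true cure phenomenon rather than a censoring artifact.
#' @param censoring_max horizon of the Uniform(0, max) censoring law.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 306, n_genes = 2000, n_blocks = 100,
                             within_block_correlation = 0.3,
                             n_true_incidence = 10, n_true_latency = 10,
                             effect_size_incidence = 1.0,
                             effect_size_latency = 1.0,
                             incidence_intercept = qlogis(0.6),
                             baseline_shape = 1.5, baseline_scale = 2,
                             susceptible_time_cap = 8, censoring_max = 10,
                             seed = 1L) {
  if (within_block_correlation < 0 || within_block_correlation >= 1)
    stop_input("within_block_correlation must lie in [0, 1)")
  if (n_blocks < 1 || n_blocks > n_genes)
    stop_input("n_blocks must lie in [1, n_genes]")
  if (n_true_incidence + n_true_latency > n_genes)
    stop_input("n_true_incidence + n_true_latency must not exceed n_genes")
  if (baseline_shape <= 0 || baseline_scale <= 0)
    stop_input("Weibull shape and scale must be > 0")
  if (susceptible_time_cap <= 0 || censoring_max <= 0)
    stop_input("susceptible_time_cap and censoring_max must be > 0")
  if (censoring_max < susceptible_time_cap)
    warning("censoring_max < susceptible_time_cap: follow-up is too short ",
            "to reveal the cure plateau", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_blocks = as.integer(n_blocks),
                 within_block_correlation = within_block_correlation,
                 n_true_incidence = as.integer(n_true_incidence),
                 n_true_latency = as.integer(n_true_latency),
                 effect_size_incidence = effect_size_incidence,
                 effect_size_latency = effect_size_latency,
                 incidence_intercept = incidence_intercept,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 susceptible_time_cap = susceptible_time_cap,
                 censoring_max = censoring_max,
                 seed = as.integer(seed)),
            class = "generator_config")
}

block_assignment <- function(n_genes, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n_genes))
}

#' Generate a block-correlated expression matrix
#'
#' Genes within a block share a latent factor giving equicorrelation
#' `within_block_correlation`; blocks are independent. Columns are
#' standardized to empirical mean 0 and variance 1, mimicking preprocessed
#' log-scale RNA-seq summaries.
#'
#' @param config a [generator_config()].
#' @return `n_samples x n_genes` matrix with gene names `gene_1 ...` and
#'   sample ids `sample_1 ...`.
#' @export
generate_expression <- function(config) {
  set.seed(config$seed)
  generate_expression_impl(config)
}

generate_expression_impl <- function(config) {
  n <- config$n_samples; p <- config$n_genes
  rho <- config$within_block_correlation
  blocks <- block_assignment(p, config$n_blocks)
  U <- matrix(rnorm(n * config$n_blocks), n, config$n_blocks)
  E <- matrix(rnorm(n * p), n, p)
  X <- sqrt(rho) * U[, blocks, drop = FALSE] + sqrt(1 - rho) * E
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  dimnames(X) <- list(paste0("sample_", seq_len(n)), paste0("gene_", seq_len(p)))
  X
}

sparse_truth <- function(idx, signs, effect, p, names) {
  v <- setNames(numeric(p), names)
  v[idx] <- signs * effect
  v
}

#' Simulate a mixture-cure survival cohort
#'
#' For each sample the latent susceptibility label is Bernoulli with
#' probability \eqn{\pi_i = \mathrm{expit}(b_0 + x_i^\top b)}. Susceptible
#' samples draw an event time from a Weibull proportional-hazards law with
#' log-hazard shift \eqn{z_i^\top \beta} (the same expression row feeds both
#' components), truncated by inverse-CDF resampling at
#' `susceptible_time_cap`; cured samples never relapse. Censoring is
#' Uniform(0, `censoring_max`); the observed time is the minimum and cured
#' samples are always censored.
#'
#' True incidence and latency genes are drawn at random (in distinct
#' correlation blocks when possible) with alternating signs; any overlap
#' between the two sets is recorded in the returned truth.
#'
#' @param config a [generator_config()].
#' @return list with elements `data` (a [survival_dataset()]) and `truth`
#'   (class `synthetic_truth`: true coefficient vectors, latent 0/1
#'   susceptibility labels, overlap, and the config).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  X <- generate_expression_impl(config)
  n <- config$n_samples; p <- config$n_genes
  genes <- colnames(X)

  blocks <- block_assignment(p, config$n_blocks)
  pick_spread <- function(k) {
    # prefer one gene per block so true effects are not confounded within
    # a correlation block
    if (k == 0) return(integer(0))
    reps <- sample(seq_len(p))
    ord <- reps[order(duplicated(blocks[reps]))]
    sort(ord[seq_len(k)])
  }
  idx_inc <- pick_spread(config$n_true_incidence)
  idx_lat <- pick_spread(config$n_true_latency)
  sign_seq <- function(k) if (k == 0) numeric(0) else (-1)^(seq_len(k) + 1)
  b_true <- sparse_truth(idx_inc, sign_seq(length(idx_inc)),
                         config$effect_size_incidence, p, genes)
  beta_true <- sparse_truth(idx_lat, sign_seq(length(idx_lat)),
                            config$effect_size_latency, p, genes)

  pi_i <- expit(config$incidence_intercept + linear_predictor(X, b_true))
  y <- rbinom(n, 1, pi_i)

  eta <- linear_predictor(X, beta_true)
  hr <- exp(pmin(eta, ETA_CAP))
  # Weibull PH: S(t) = exp(-(t/scale)^shape * hr); inverse-CDF draw
  # conditional on T <= susceptible_time_cap (truncation, not censoring)
  Fcap <- 1 - exp(-(config$susceptible_time_cap / config$baseline_scale)^
                    config$baseline_shape * hr)
  V <- runif(n)
  Tlat <- config$baseline_scale *
    (-log(1 - V * Fcap) / hr)^(1 / config$baseline_shape)
  Tlat[y == 0] <- Inf
  Cens <- runif(n, 0, config$censoring_max)
  times <- pmin(Tlat, Cens)
  events <- as.integer(Tlat <= Cens)
  # guard against zero follow-up from numerical underflow
  times <- pmax(times, 1e-8)

  data <- survival_dataset(X, times, events)
  truth <- structure(list(true_incidence_coefficients = b_true,
                          true_latency_coefficients = beta_true,
                          latent_cure_labels = as.integer(y),
                          overlap_genes = intersect(genes[idx_inc], genes[idx_lat]),
                          config = config),
                     class = "synthetic_truth")
  list(data = data, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Expression as TSV (samples in rows, first column `sample_id`), survival
#' table as CSV (`sample_id,time,event[,group]`), truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                survival = file.path(dir, "survival.csv"),
                truth = file.path(dir, "truth.json"))
  write_expression(cohort$data, paths$expression)
  write_survival(cohort$data, paths$survival)
  tr <- cohort$truth
  jsonlite::write_json(
    list(true_incidence_coefficients = as.list(tr$true_incidence_coefficients[tr$true_incidence_coefficients != 0]),
         true_latency_coefficients = as.list(tr$true_latency_coefficients[tr$true_latency_coefficients != 0]),
         latent_cure_labels = tr$latent_cure_labels,
         overlap_genes = tr$overlap_genes,
         config = unclass(tr$config)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
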