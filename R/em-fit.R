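#' Initialize parameters and weights for the EM algorithm
#'
#' Events start at weight 1. A censored sample at time t starts at the
#' Kaplan-Meier plateau-adjusted susceptibility estimate
#' \eqn{w = 1 - c / S_{KM}(t)}, where c is the KM plateau (its final
#' value): the posterior a nonparametric mixture with cure fraction c would
#' assign. Coefficients start at zero; the baseline comes from the weighted
#' Breslow estimator at \eqn{\beta = 0} with these initial weights.
#'
#' @param data a [survival_dataset()] with at least one event.
#' @return list with `parameters` ([mcm_parameters()]) and `weights`.
#' @export
mcm_initialize <- function(data) {
  if (sum(data$events) == 0)
    stop_input("cannot fit a cure model without any events")
  km <- survival::survfit(survival::Surv(data$times, data$events) ~ 1)
  surv_fun <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  plateau <- min(km$surv)
  s_at <- surv_fun(data$times)
  w <- ifelse(s_at > 0, 1 - plateau / s_at, 0)
  w <- pmin(pmax(w, 0), 1)
  w[data$events == 1] <- 1
  p <- ncol(data$expression)
  b <- setNames(numeric(p), data$gene_names)
  baseline <- breslow_baseline(data, w, b)
  wbar <- min(max(mean(w), 1e-12), 1 - 1e-12)
  params <- mcm_parameters(max(min(logit(wbar), INTERCEPT_CAP), -INTERCEPT_CAP),
                           b, b, baseline)
  list(parameters = params, weights = w)
}

# penalty term on the standardization scale actually optimized by the
# M-steps; scales are fixed across EM iterations so ascent of this
# quantity is the EM ascent guarantee
penalty_term <- function(params, penalty, scales) {
  penalty$lambda_incidence * sum(abs(params$incidence_coefficients) * scales) +
    penalty$lambda_latency * sum(abs(params$latency_coefficients) * scales)
}

#' Fit the regularized semi-parametric mixture cure model by EM
#'
#' Alternates the E-step (posterior susceptibility weights) with the two
#' penalized M-steps — fractional-response LASSO logistic for incidence and
#' case-weighted LASSO Cox for latency — followed by a weighted Breslow
#' refresh of the baseline under the zero-tail constraint. The first
#' iteration uses the Kaplan-Meier-initialized weights; thereafter weights
#' are exact posteriors, so the recorded penalized observed-data
#' log-likelihood is non-decreasing (monitored; a violation beyond 1e-8
#' relative slack triggers a warning and is recorded in the trace).
#'
#' @param data a [survival_dataset()].
#' @param penalty a [penalty_config()]; its `tolerance` and
#'   `max_iterations` also govern the EM loop (convergence when the maximum
#'   absolute change of intercept and coefficients falls below `tolerance`).
#' @param cure_threshold samples with fitted susceptibility probability
#'   below this are labelled cured (default 0.5, the symmetric Bayes rule).
#' @param init optional [mcm_parameters()] used as a warm start (e.g. the
#'   solution at a neighbouring penalty); the E-step runs from iteration 1
#'   in that case, so the ascent guarantee is unaffected.
#' @return object of class `mcm_fit`: `parameters`, `penalty`, `trace`
#'   (data frame: iteration, penalized_loglik, max_param_change), `converged`,
#'   `training_risk_score_cutoff` (median latency linear predictor among
#'   predicted-susceptible training samples; the high/low-risk boundary
#'   reused unchanged on new data), `cure_threshold`, `gene_names`.
#' @export
mcm_fit <- function(data, penalty = penalty_config(), cure_threshold = 0.5,
                    init = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (cure_threshold <= 0 || cure_threshold >= 1)
    stop_input("cure_threshold must lie in (0, 1)")
  if (is.null(init)) {
    start <- mcm_initialize(data)
    params <- start$parameters
    w <- start$weights
    warm <- FALSE
  } else {
    stopifnot(inherits(init, "mcm_parameters"))
    if (sum(data$events) == 0)
      stop_input("cannot fit a cure model without any events")
    params <- init
    w <- e_step(params, data)
    warm <- TRUE
  }
  X <- data$expression
  scales <- if (penalty$standardize) column_scales(X) else
    rep(1, ncol(X))

  # generalized EM: each M-step only needs to improve its objective (the
  # step-halving inside the solvers guarantees that), so the solvers run a
  # few warm-started outer iterations per EM pass; joint convergence is
  # still governed by the EM loop's parameter-change criterion
  solver_cfg <- penalty
  solver_cfg$max_iterations <- min(penalty$max_iterations, 8L)

  trace <- data.frame(iteration = integer(0), penalized_loglik = numeric(0),
                      max_param_change = numeric(0))
  converged <- FALSE
  ascent_ok <- TRUE
  pll_prev <- -Inf

  for (iter in seq_len(penalty$max_iterations)) {
    if (iter > 1 || warm) w <- e_step(params, data)
    logi <- suppressWarnings(fit_weighted_lasso_logistic(
      X, w, penalty$lambda_incidence,
      init = params$incidence_coefficients, config = solver_cfg))
    cox <- suppressWarnings(fit_weighted_lasso_cox(
      X, data$times, data$events, w, penalty$lambda_latency,
      init = params$latency_coefficients, config = solver_cfg))
    baseline <- breslow_baseline(data, w, cox$coefficients)
    new_params <- mcm_parameters(logi$intercept, logi$coefficients,
                                 cox$coefficients, baseline)
    max_change <- max(abs(c(
      new_params$incidence_intercept - params$incidence_intercept,
      new_params$incidence_coefficients - params$incidence_coefficients,
      new_params$latency_coefficients - params$latency_coefficients)))
    params <- new_params
    pll <- observed_loglik(params, data) - penalty_term(params, penalty, scales)
    if (iter > 1 && pll < pll_prev - 1e-8 * abs(pll_prev)) {
      ascent_ok <- FALSE
      warning("penalized observed log-likelihood decreased at iteration ",
              iter, " (", signif(pll_prev, 10), " -> ", signif(pll, 10), ")",
              call. = FALSE)
    }
    pll_prev <- pll
    trace <- rbind(trace, data.frame(iteration = iter, penalized_loglik = pll,
                                     max_param_change = max_change))
    if (max_change < penalty$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge in ", penalty$max_iterations, " iterations",
            call. = FALSE)

  pi_hat <- susceptibility_probability(params, X)
  risk <- linear_predictor(X, params$latency_coefficients)
  susceptible <- pi_hat >= cure_threshold
  cutoff <- if (any(susceptible)) median(risk[susceptible]) else NA_real_

  structure(list(parameters = params, penalty = penalty, trace = trace,
                 converged = converged, ascent_ok = ascent_ok,
                 training_risk_score_cutoff = cutoff,
                 cure_threshold = cure_threshold,
                 gene_names = data$gene_names),
            class = "mcm_fit")
}

#' @export
print.mcm_fit <- function(x, ...) {
  cat("Regularized semi-parametric mixture cure model\n")
  cat("  lambda (incidence, latency):", x$penalty$lambda_incidence, ",",
      x$penalty$lambda_latency, "\n")
  cat("  selected genes: incidence", sum(x$parameters$incidence_coefficients != 0),
      "/ latency", sum(x$parameters$latency_coefficients != 0), "\n")
  cat("  EM iterations:", nrow(x$trace),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Stratified cross-validation folds
#'
#' Fold labels 1..k, stratified on the event indicator so every fold keeps
#' events; deterministic given the seed.
#' @keywords internal
cv_folds <- function(events, k_folds, seed) {
  set.seed(seed)
  fold <- integer(length(events))
  for (lvl in unique(events)) {
    idx <- sample(which(events == lvl))
    fold[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Default two-dimensional penalty grid
#'
#' Geometric sequences per component from the data-driven
#' \eqn{\lambda_{max}} (smallest penalty with empty support, computed at the
#' KM-initialized weights) down to `lambda_min_ratio * lambda_max`, crossed
#' into a grid.
#'
#' @param data a [survival_dataset()].
#' @param n_lambda sequence length per component.
#' @param lambda_min_ratio smallest grid value relative to lambda_max.
#' @param penalty a [penalty_config()] supplying the standardization flag.
#' @return data frame with columns `lambda_incidence`, `lambda_latency`.
#' @export
default_lambda_grid <- function(data, n_lambda = 4, lambda_min_ratio = 0.05,
                                penalty = penalty_config()) {
  w0 <- mcm_initialize(data)$weights
  lmax_inc <- lambda_max_logistic(data$expression, w0, penalty)
  lmax_lat <- lambda_max_cox(data$expression, data$times, data$events, w0,
                             penalty)
  gseq <- function(lmax) exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                                 length.out = n_lambda))
  expand.grid(lambda_incidence = gseq(lmax_inc),
              lambda_latency = gseq(lmax_lat))
}

#' Cross-validated penalty selection
#'
#' For every grid point, fits the model on k-1 folds and evaluates the
#' held-out observed-data log-likelihood (the quantity EM maximizes);
#' selects the grid point with the highest mean held-out log-likelihood,
#' breaking ties toward the larger total penalty (parsimony). Held-out
#' events at times between training event times use the carry-forward
#' baseline increment; times beyond the training support fall under the
#' zero-tail constraint with the usual probability floor.
#'
#' @param data a [survival_dataset()].
#' @param lambda_grid data frame with columns `lambda_incidence` and
#'   `lambda_latency`; defaults to [default_lambda_grid()].
#' @param k_folds number of folds (>= 2), stratified on the event indicator.
#' @param seed integer seed controlling the fold assignment.
#' @param penalty a [penalty_config()] template (tolerances, iteration caps).
#' @param cure_threshold passed through to [mcm_fit()].
#' @return list with `best_penalty` (a [penalty_config()]), `cv_table`
#'   (grid plus `mean_heldout_loglik`), and `folds`.
#' @export
mcm_cv <- function(data, lambda_grid = NULL, k_folds = 5, seed = 1,
                   penalty = penalty_config(), cure_threshold = 0.5) {
  if (k_folds < 2) stop_input("k_folds must be >= 2")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(data, penalty = penalty)
  if (nrow(lambda_grid) == 0) stop_input("empty lambda grid")
  folds <- cv_folds(data$events, k_folds, seed)
  if (any(tapply(data$events, folds, sum) == 0))
    stop_input("a fold has zero events; reduce k_folds")

  subset_data <- function(idx) {
    survival_dataset(data$expression[idx, , drop = FALSE],
                     data$times[idx], data$events[idx],
                     sample_ids = data$sample_ids[idx],
                     gene_names = data$gene_names,
                     group = data$group[idx])
  }

  # CV fits use a slightly looser EM control and pathwise warm starts along
  # decreasing total penalty: grid points are compared, not reported, and
  # the ranking is insensitive to the acceleration
  cv_cfg <- penalty
  cv_cfg$tolerance <- max(penalty$tolerance, 1e-3)
  cv_cfg$max_iterations <- min(penalty$max_iterations, 30L)
  path <- order(-(lambda_grid$lambda_incidence + lambda_grid$lambda_latency))

  heldout <- matrix(NA_real_, nrow(lambda_grid), k_folds)
  for (fold in seq_len(k_folds)) {
    train <- subset_data(folds != fold)
    test <- subset_data(folds == fold)
    warm <- NULL
    for (g in path) {
      cfg <- cv_cfg
      cfg$lambda_incidence <- lambda_grid$lambda_incidence[g]
      cfg$lambda_latency <- lambda_grid$lambda_latency[g]
      fit <- suppressWarnings(mcm_fit(train, cfg, cure_threshold, init = warm))
      warm <- fit$parameters
      heldout[g, fold] <- observed_loglik(fit$parameters, test)
    }
  }
  cv_table <- cbind(lambda_grid,
                    mean_heldout_loglik = rowMeans(heldout))
  best_ll <- max(cv_table$mean_heldout_loglik)
  cand <- which(cv_table$mean_heldout_loglik >= best_ll - 1e-9 * abs(best_ll) - 1e-12)
  lam_sum <- cv_table$lambda_incidence[cand] + cv_table$lambda_latency[cand]
  pick <- cand[which.max(lam_sum)]
  best <- penalty
  best$lambda_incidence <- cv_table$lambda_incidence[pick]
  best$lambda_latency <- cv_table$lambda_latency[pick]
  list(best_penalty = best, cv_table = cv_table, folds = folds)
}

#' Selected gene tables
#'
#' Nonzero coefficients of each component, sorted by absolute coefficient,
#' analogous to publishing the cure-associated and latency-associated gene
#' lists of a fitted model.
#'
#' @param fit an [mcm_fit()] object.
#' @return list of two data frames `cure` and `latency` with columns
#'   `gene`, `coefficient`, `component`.
#' @export
selected_genes <- function(fit) {
  tab <- function(coefs, component) {
    nz <- which(coefs != 0)
    out <- data.frame(gene = fit$gene_names[nz],
                      coefficient = unname(coefs[nz]),
                      component = rep(component, length(nz)),
                      stringsAsFactors = FALSE)
    out[order(-abs(out$coefficient)), , drop = FALSE]
  }
  list(cure = tab(fit$parameters$incidence_coefficients, "incidence"),
       latency = tab(fit$parameters$latency_coefficients, "latency"))
}

#' Serialize a fitted model to JSON
#'
#' @param fit an [mcm_fit()] object.
#' @param path output file.
#' @export
write_mcm <- function(fit, path) {
  obj <- list(
    package = "curemix",
    version = as.character(utils::packageVersion("curemix")),
    incidence_intercept = fit$parameters$incidence_intercept,
    incidence_coefficients = as.numeric(fit$parameters$incidence_coefficients),
    latency_coefficients = as.numeric(fit$parameters$latency_coefficients),
    gene_names = fit$gene_names,
    baseline_event_times = fit$parameters$baseline$event_times,
    baseline_increments = fit$parameters$baseline$increments,
    training_risk_score_cutoff = fit$training_risk_score_cutoff,
    cure_threshold = fit$cure_threshold,
    penalty = unclass(fit$penalty),
    converged = fit$converged)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted model written by [write_mcm()]
#'
#' @param path JSON file.
#' @return an `mcm_fit` object (without the training trace).
#' @export
read_mcm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline <- baseline_hazard(obj$baseline_event_times, obj$baseline_increments)
  params <- mcm_parameters(obj$incidence_intercept,
                           setNames(obj$incidence_coefficients, obj$gene_names),
                           setNames(obj$latency_coefficients, obj$gene_names),
                           baseline)
  pen <- do.call(penalty_config, obj$penalty[c("lambda_incidence",
                                               "lambda_latency", "standardize",
                                               "max_iterations", "tolerance",
                                               "active_set")])
  structure(list(parameters = params, penalty = pen, trace = NULL,
                 converged = obj$converged, ascent_ok = NA,
                 training_risk_score_cutoff = obj$training_risk_score_cutoff,
                 cure_threshold = obj$cure_threshold,
                 gene_names = obj$gene_names),
            class = "mcm_fit")
}
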