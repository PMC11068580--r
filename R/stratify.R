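#' Predict cure status and relapse-risk groups for new samples
#'
#' Applies a fitted mixture cure model unchanged to new expression data:
#' susceptibility probability from the incidence component, cured vs
#' susceptible by the fitted `cure_threshold`, risk score as the latency
#' linear predictor \eqn{z^\top \hat\beta}, and high vs low risk by
#' comparison with the training median cutoff (scores exactly at the
#' cutoff go to "low"; predicted-cured samples get "not_applicable").
#'
#' @param object an [mcm_fit()] object.
#' @param expression matrix of new samples x genes; must contain every gene
#'   the model was trained on (extra columns are ignored, order-free).
#' @param horizon time at which the population survival is reported
#'   (default 5, i.e. 5 years under the year convention).
#' @param ... unused.
#' @return data frame with columns `sample_id`, `susceptibility_probability`,
#'   `cure_label`, `risk_score`, `risk_group`,
#'   `population_survival_at_horizon`.
#' @export
predict.mcm_fit <- function(object, expression, horizon = 5, ...) {
  expression <- as.matrix(expression)
  if (any(!is.finite(expression)))
    stop_input("non-finite values in expression")
  if (is.null(colnames(expression)))
    stop_input("expression must carry gene names as column names")
  missing <- setdiff(object$gene_names, colnames(expression))
  if (length(missing) > 0)
    stop_input("expression is missing model genes: ",
               paste(missing, collapse = ", "))
  Z <- expression[, object$gene_names, drop = FALSE]
  params <- object$parameters
  pi_hat <- susceptibility_probability(params, Z)
  risk <- linear_predictor(Z, params$latency_coefficients)
  su <- susceptible_survival_matrix(params, Z, rep(horizon, nrow(Z)))
  spop <- (1 - pi_hat) + pi_hat * su
  cured <- pi_hat < object$cure_threshold
  risk_group <- ifelse(cured, "not_applicable",
                       ifelse(risk > object$training_risk_score_cutoff,
                              "high", "low"))
  data.frame(sample_id = rownames(expression) %||% paste0("sample_", seq_len(nrow(Z))),
             susceptibility_probability = unname(pi_hat),
             cure_label = ifelse(cured, "cured", "susceptible"),
             risk_score = unname(risk),
             risk_group = risk_group,
             population_survival_at_horizon = unname(spop),
             stringsAsFactors = FALSE)
}

#' Stratify samples with observed follow-up by their posterior cure status
#'
#' For samples whose outcomes were observed (typically the training cohort),
#' cure status is best assessed by the posterior probability of
#' susceptibility given the follow-up data — the E-step weight at the
#' fitted parameters — rather than by expression alone: a patient with an
#' observed relapse is susceptible with certainty, and a patient censored
#' beyond the last event time is cured with certainty under the zero-tail
#' constraint. With this rule the predicted-cured group can contain no
#' events, so its Kaplan-Meier curve stays at 1 throughout follow-up. Use
#' [predict.mcm_fit()] for samples without outcome data.
#'
#' @param fit an [mcm_fit()] object.
#' @param data a [survival_dataset()] whose genes match the fit.
#' @param horizon time at which population survival is reported.
#' @return data frame with the same columns as [predict.mcm_fit()], with
#'   `susceptibility_probability` holding the posterior weight.
#' @export
stratify_training <- function(fit, data, horizon = 5) {
  stopifnot(inherits(data, "survival_dataset"))
  missing <- setdiff(fit$gene_names, data$gene_names)
  if (length(missing) > 0)
    stop_input("dataset is missing model genes: ",
               paste(missing, collapse = ", "))
  aligned <- survival_dataset(
    data$expression[, fit$gene_names, drop = FALSE],
    data$times, data$events, sample_ids = data$sample_ids,
    gene_names = fit$gene_names, group = data$group)
  params <- fit$parameters
  w <- e_step(params, aligned)
  risk <- linear_predictor(aligned$expression, params$latency_coefficients)
  su <- susceptible_survival_matrix(params, aligned$expression,
                                    rep(horizon, length(w)))
  pi_hat <- susceptibility_probability(params, aligned$expression)
  cured <- w < fit$cure_threshold
  data.frame(sample_id = aligned$sample_ids,
             susceptibility_probability = unname(w),
             cure_label = ifelse(cured, "cured", "susceptible"),
             risk_score = unname(risk),
             risk_group = ifelse(cured, "not_applicable",
                                 ifelse(risk > fit$training_risk_score_cutoff,
                                        "high", "low")),
             population_survival_at_horizon =
               unname((1 - pi_hat) + pi_hat * su),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param label group label attached to the curve.
#' @return object of class `km_curve`: data frame-like list with `times`,
#'   `survival`, `at_risk`, `n_events`, `group_label`.
#' @export
km_estimate <- function(times, events, label = "all") {
  if (length(times) == 0) stop_input("empty input")
  if (any(times <= 0)) stop_input("times must be strictly positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_events = fit$n.event,
                 group_label = label),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("KM curve [", x$group_label, "]: ", length(x$times), " time points, ",
      sum(x$n_events), " events, final survival ",
      signif(x$survival[length(x$survival)], 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$times, survival = x$survival, at_risk = x$at_risk,
             n_events = x$n_events, group_label = x$group_label,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves by group
#'
#' One product-limit curve per label level (e.g., predicted cure status, or
#' an externally supplied genetic-risk classification crossed with the
#' predicted status). A log-rank test across the levels is attached when
#' there are at least two non-empty levels.
#'
#' @param data a [survival_dataset()].
#' @param labels one categorical label per sample.
#' @param min_group_size levels smaller than this are flagged via the
#'   `small_groups` attribute (default 1 = never).
#' @return named list of `km_curve` objects; attributes `logrank_p` and
#'   `small_groups`.
#' @export
km_by_group <- function(data, labels, min_group_size = 1) {
  if (length(labels) != length(data$times))
    stop_input("labels must align with samples")
  labels <- as.character(labels)
  lvls <- unique(labels)
  if (length(lvls) == 0 || all(is.na(lvls))) stop_input("no groups to estimate")
  curves <- lapply(lvls, function(lvl) {
    idx <- which(labels == lvl)
    km_estimate(data$times[idx], data$events[idx], label = lvl)
  })
  names(curves) <- lvls
  sizes <- vapply(lvls, function(lvl) sum(labels == lvl), integer(1))
  attr(curves, "small_groups") <- lvls[sizes < min_group_size]
  if (length(lvls) >= 2) {
    sd <- survival::survdiff(survival::Surv(data$times, data$events) ~ labels)
    attr(curves, "logrank_p") <-
      stats::pchisq(sd$chisq, length(lvls) - 1, lower.tail = FALSE)
  }
  curves
}

#' Write KM curves to per-group CSV files
#'
#' @param curves result of [km_by_group()] (or a single `km_curve`).
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_km <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(curves, "km_curve")) curves <- list(curves)
  paths <- vapply(curves, function(cv) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cv$group_label)
    path <- file.path(dir, paste0("km_", safe, ".csv"))
    write.csv(as.data.frame(cv), path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
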