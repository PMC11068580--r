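#' Harrell's concordance statistic
#'
#' Fraction of comparable pairs ordered correctly by the risk score. A pair
#' (i, j) is comparable when i has an event and either `t_i < t_j`, or
#' `t_i == t_j` with j censored; risk ties count 0.5. Pairs of events at
#' the same time are not comparable.
#'
#' @param risk risk scores (higher = earlier event expected).
#' @param times,events follow-up times and 0/1 event indicators.
#' @return concordance in `[0, 1]`, with attribute `n_comparable_pairs`.
#' @export
c_statistic <- function(risk, times, events) {
  n <- length(risk)
  stopifnot(length(times) == n, length(events) == n)
  ev <- which(events == 1)
  if (length(ev) == 0) stop_input("no comparable pairs: no events")
  comparable <- 0
  concordant <- 0
  for (i in ev) {
    cmp <- (times > times[i]) | (times == times[i] & events == 0)
    if (!any(cmp)) next
    comparable <- comparable + sum(cmp)
    concordant <- concordant + sum((risk[i] > risk[cmp]) + 0.5 * (risk[i] == risk[cmp]))
  }
  if (comparable == 0) stop_input("no comparable pairs in the data")
  structure(concordant / comparable, n_comparable_pairs = comparable)
}

# left-continuous KM estimate of the censoring survival G(t-)
censoring_survival_left <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  function(t) {
    # G(t-) = product over censoring times strictly before t
    vapply(t, function(tt) {
      idx <- fit$time < tt
      if (!any(idx)) 1 else min(fit$surv[idx][sum(idx)], 1)
    }, numeric(1))
  }
}

#' Time-dependent AUC at a fixed horizon
#'
#' Cumulative-case / dynamic-control AUC with inverse-probability-of-
#' censoring weights (Uno-type): cases are samples with an observed event
#' by the horizon (weighted by 1/G(t-)), controls are samples still under
#' observation beyond the horizon (weighted by 1/G(horizon)), with G the
#' Kaplan-Meier estimate of the censoring survival. When no censoring
#' occurs before the horizon all weights are equal and the estimate reduces
#' exactly to the Mann-Whitney AUC of the binary horizon outcome.
#'
#' @param marker predictive marker (higher = higher event risk).
#' @param times,events follow-up times and 0/1 event indicators.
#' @param horizon evaluation time (e.g. 5 for a 5-year AUC).
#' @return AUC in `[0, 1]`.
#' @export
auc_at_time <- function(marker, times, events, horizon) {
  n <- length(marker)
  stopifnot(length(times) == n, length(events) == n)
  cases <- which(times <= horizon & events == 1)
  controls <- which(times > horizon)
  if (length(cases) == 0) stop_input("no cases by the horizon; AUC undefined")
  if (length(controls) == 0) stop_input("no controls beyond the horizon; AUC undefined")
  Gfun <- censoring_survival_left(times, events)
  g_cases <- Gfun(times[cases])
  g_ctrl <- Gfun(horizon + .Machine$double.eps * abs(horizon))
  if (any(g_cases <= 0) || g_ctrl <= 0)
    stop_input("censoring survival reaches 0 before the horizon; weights undefined")
  wc <- 1 / g_cases
  wj <- rep(1 / g_ctrl, length(controls))
  mi <- marker[cases]; mj <- marker[controls]
  cmpmat <- outer(mi, mj, function(a, b) (a > b) + 0.5 * (a == b))
  sum((wc %o% wj) * cmpmat) / (sum(wc) * sum(wj))
}

#' Discrimination report for a fitted mixture cure model
#'
#' Computes Harrell's C-statistic and the time-dependent AUC at the given
#' horizon on a dataset, using by default the combined marker
#' `1 - population_survival_at_horizon`, which blends the incidence and
#' latency components; the latency risk score or the susceptibility
#' probability may be used instead.
#'
#' @param fit an [mcm_fit()] object.
#' @param data a [survival_dataset()].
#' @param horizon evaluation horizon (default 5).
#' @param marker one of `"population_risk"`, `"risk_score"`,
#'   `"susceptibility"`.
#' @param susceptible_only restrict the metrics to predicted-susceptible
#'   samples (default `FALSE`: all samples enter).
#' @return list with `c_statistic`, `auc_at_horizon`, `horizon`,
#'   `n_comparable_pairs`, `marker_definition`.
#' @export
evaluate_fit <- function(fit, data, horizon = 5,
                         marker = c("population_risk", "risk_score",
                                    "susceptibility"),
                         susceptible_only = FALSE) {
  marker <- match.arg(marker)
  pred <- predict(fit, data$expression, horizon = horizon)
  m <- switch(marker,
              population_risk = 1 - pred$population_survival_at_horizon,
              risk_score = pred$risk_score,
              susceptibility = pred$susceptibility_probability)
  keep <- if (susceptible_only) pred$cure_label == "susceptible" else
    rep(TRUE, length(m))
  if (!any(keep)) stop_input("no samples left after restriction")
  m <- m[keep]
  data <- list(times = data$times[keep], events = data$events[keep])
  cs <- c_statistic(m, data$times, data$events)
  list(c_statistic = as.numeric(cs),
       auc_at_horizon = auc_at_time(m, data$times, data$events, horizon),
       horizon = horizon,
       n_comparable_pairs = attr(cs, "n_comparable_pairs"),
       marker_definition = switch(marker,
         population_risk = "1 - population survival at horizon",
         risk_score = "latency linear predictor",
         susceptibility = "susceptibility probability"))
}
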