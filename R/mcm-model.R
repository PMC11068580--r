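#' Nonparametric baseline cumulative hazard
#'
#' Step-function baseline for the latency (Cox) component, stored as
#' increments at the distinct event times. The implied baseline survival is
#' \eqn{S_0(t) = \exp(-\sum_{t_k \le t} \Delta\Lambda_k)}. Beyond the last
#' event time the conditional susceptible survival is defined to be exactly
#' zero (the zero-tail constraint), which identifies the cure fraction with
#' a nonparametric baseline.
#'
#' @param event_times strictly increasing event times.
#' @param increments nonnegative cumulative-hazard increments, one per event
#'   time.
#' @return object of class `baseline_hazard`.
#' @export
baseline_hazard <- function(event_times, increments) {
  event_times <- as.numeric(event_times)
  increments <- as.numeric(increments)
  if (length(event_times) != length(increments))
    stop_input("event_times and increments must have equal length")
  if (length(event_times) == 0)
    stop_input("baseline requires at least one event time")
  if (is.unsorted(event_times, strictly = TRUE))
    stop_input("event_times must be strictly increasing")
  if (any(!is.finite(increments)) || any(increments < 0))
    stop_input("increments must be finite and nonnegative")
  structure(list(event_times = event_times,
                 increments = increments,
                 last_event_time = event_times[length(event_times)]),
            class = "baseline_hazard")
}

#' Cumulative baseline hazard at given times
#'
#' @param baseline a [baseline_hazard()] object.
#' @param t vector of nonnegative times.
#' @return \eqn{\Lambda_0(t) = \sum_{t_k \le t} \Delta\Lambda_k} for each t.
#' @export
cumulative_hazard <- function(baseline, t) {
  if (any(t < 0)) stop_input("t must be nonnegative")
  csum <- cumsum(baseline$increments)
  idx <- findInterval(t, baseline$event_times)
  ifelse(idx == 0, 0, csum[pmax(idx, 1L)])
}

# increment of the baseline hazard applicable at time t: the increment at
# the largest event time <= t (carry-forward), 0 before the first event.
# In-sample events match an event time exactly; the carry-forward rule only
# matters for held-out likelihood evaluation.
hazard_increment_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$event_times)
  ifelse(idx == 0, 0, baseline$increments[pmax(idx, 1L)])
}

#' Mixture cure model parameters
#'
#' @param incidence_intercept log-odds intercept of the susceptibility
#'   (incidence) component.
#' @param incidence_coefficients log-odds-per-unit-expression coefficients;
#'   nonzero entries are the genes associated with cure status.
#' @param latency_coefficients log-hazard coefficients of the latency
#'   component; nonzero entries are the genes associated with time to
#'   relapse among the susceptible.
#' @param baseline a [baseline_hazard()] object.
#' @return object of class `mcm_parameters`.
#' @export
mcm_parameters <- function(incidence_intercept, incidence_coefficients,
                           latency_coefficients, baseline) {
  if (length(incidence_coefficients) != length(latency_coefficients))
    stop_input("coefficient vectors must have equal length (one entry per gene)")
  if (!all(is.finite(c(incidence_intercept, incidence_coefficients,
                       latency_coefficients))))
    stop_input("parameters must be finite")
  if (!inherits(baseline, "baseline_hazard"))
    stop_input("baseline must be a baseline_hazard object")
  structure(list(incidence_intercept = as.numeric(incidence_intercept),
                 incidence_coefficients = as.numeric(incidence_coefficients),
                 latency_coefficients = as.numeric(latency_coefficients),
                 baseline = baseline),
            class = "mcm_parameters")
}

# linear predictors; Z is n x p (p may be 0)
linear_predictor <- function(Z, coef) {
  if (length(coef) == 0) rep(0, nrow(Z)) else drop(Z %*% coef)
}

susceptibility_probability <- function(params, X) {
  expit(params$incidence_intercept + linear_predictor(X, params$incidence_coefficients))
}

#' Conditional survival of susceptible samples
#'
#' \eqn{S_u(t \mid z) = S_0(t)^{\exp(z^\top \beta)}} with the zero-tail
#' constraint: exactly 0 for any `t` beyond the last baseline event time.
#'
#' @param params an [mcm_parameters()] object.
#' @param z a single expression row (length = number of genes).
#' @param t vector of nonnegative times.
#' @return survival probabilities in `[0, 1]`.
#' @export
susceptible_survival <- function(params, z, t) {
  if (any(t < 0)) stop_input("t must be nonnegative")
  z <- matrix(as.numeric(z), nrow = 1)
  drop(susceptible_survival_matrix(params, z[rep(1, length(t)), , drop = FALSE], t))
}

# vectorized over samples: Z row i paired with times[i]
susceptible_survival_matrix <- function(params, Z, times) {
  eta <- linear_predictor(Z, params$latency_coefficients)
  H <- cumulative_hazard(params$baseline, times)
  s <- exp(-H * exp(eta))
  s[times > params$baseline$last_event_time] <- 0
  s
}

#' Population (marginal) survival under the mixture cure model
#'
#' \eqn{S_{pop}(t) = 1 - \pi + \pi S_u(t \mid z)} where
#' \eqn{\pi = \mathrm{expit}(b_0 + x^\top b)} and the same expression row
#' feeds both components. As `t` passes the last event time the value
#' plateaus at exactly `1 - pi`, the cure probability.
#'
#' @inheritParams susceptible_survival
#' @param x_z expression row used for both incidence and latency components.
#' @export
population_survival <- function(params, x_z, t) {
  x_z <- matrix(as.numeric(x_z), nrow = 1)
  pi_i <- susceptibility_probability(params, x_z)
  su <- susceptible_survival(params, x_z, t)
  (1 - pi_i) + pi_i * su
}

#' E-step: posterior susceptibility weights
#'
#' Events are susceptible with certainty (weight 1). A sample censored at
#' time t has posterior weight
#' \deqn{w = \frac{\pi S_u(t)}{1 - \pi + \pi S_u(t)}.}
#' Censoring beyond the last event time forces weight 0 via the zero-tail
#' constraint; the degenerate denominator (pi = 1 and S_u = 0) is defined
#' as weight 0.
#'
#' @param params an [mcm_parameters()] object.
#' @param data a [survival_dataset()].
#' @return numeric vector of weights in `[0, 1]`, one per sample.
#' @export
e_step <- function(params, data) {
  pi_i <- susceptibility_probability(params, data$expression)
  su <- susceptible_survival_matrix(params, data$expression, data$times)
  num <- pi_i * su
  den <- 1 - pi_i + num
  w <- ifelse(den > 0, num / den, 0)
  w[data$events == 1] <- 1
  pmin(pmax(w, 0), 1)
}

#' Weighted Breslow baseline estimator
#'
#' Cumulative-hazard increment at each distinct event time \eqn{t_k}:
#' \deqn{\Delta\Lambda_k = \frac{d_k}{\sum_{j: t_j \ge t_k} w_j e^{z_j^\top \beta}}}
#' with \eqn{d_k} the number of events at \eqn{t_k} (Breslow handling of
#' ties) and posterior weights \eqn{w_j} entering the risk set only.
#'
#' @param data a [survival_dataset()].
#' @param weights posterior susceptibility weights (events must have 1).
#' @param latency_coefficients current latency coefficient vector.
#' @return a [baseline_hazard()] object.
#' @export
breslow_baseline <- function(data, weights, latency_coefficients) {
  if (sum(data$events) == 0) stop_input("breslow_baseline requires at least one event")
  eta <- linear_predictor(data$expression, latency_coefficients)
  r <- weights * exp(eta)
  ord <- order(data$times)
  t_s <- data$times[ord]; d_s <- data$events[ord]; r_s <- r[ord]
  # risk-set mass at each sorted position: sum of r over t_j >= t_i
  risk <- rev(cumsum(rev(r_s)))
  # collapse ties: first position of each distinct time carries the risk mass
  first <- !duplicated(t_s)
  ut <- t_s[first]
  risk_u <- risk[first]
  d_u <- as.numeric(tapply(d_s, match(t_s, ut), sum))
  keep <- d_u > 0
  if (any(risk_u[keep] <= 0))
    stop_input("zero risk-set mass at event time(s): ",
               paste(signif(ut[keep & risk_u <= 0], 6), collapse = ", "))
  baseline_hazard(ut[keep], d_u[keep] / risk_u[keep])
}

#' Observed-data log-likelihood of the mixture cure model
#'
#' \deqn{\ell = \sum_i \delta_i \log[\pi_i\, \Delta\Lambda(t_i) e^{\eta_i}
#'   S_u(t_i)] + (1 - \delta_i) \log[1 - \pi_i + \pi_i S_u(t_i)]}
#' with the discrete hazard taken from the baseline step function
#' (carry-forward at times between event times) and all probabilities
#' floored at `eps` before taking logs.
#'
#' @inheritParams e_step
#' @param eps probability floor guarding `log(0)` (default 1e-12).
#' @return finite scalar log-likelihood.
#' @export
observed_loglik <- function(params, data, eps = 1e-12) {
  pi_i <- susceptibility_probability(params, data$expression)
  eta <- linear_predictor(data$expression, params$latency_coefficients)
  su <- susceptible_survival_matrix(params, data$expression, data$times)
  ev <- data$events == 1
  ll <- 0
  if (any(ev)) {
    dh <- hazard_increment_at(params$baseline, data$times[ev])
    # an event beyond the baseline support has S_u = 0; the eps floor applies
    dens <- pi_i[ev] * dh * exp(eta[ev]) * su[ev]
    ll <- ll + sum(log(pmax(dens, eps)))
  }
  if (any(!ev)) {
    ll <- ll + sum(log(pmax(1 - pi_i[!ev] + pi_i[!ev] * su[!ev], eps)))
  }
  ll
}

#' Penalized observed-data log-likelihood
#'
#' [observed_loglik()] minus the L1 penalties
#' \eqn{\lambda_{inc}\|b\|_1 + \lambda_{lat}\|\beta\|_1}; the quantity the
#' EM algorithm ascends and the one monitored for convergence.
#'
#' @inheritParams observed_loglik
#' @param lambda_incidence,lambda_latency nonnegative penalty levels.
#' @export
penalized_observed_loglik <- function(params, data, lambda_incidence,
                                      lambda_latency, eps = 1e-12) {
  observed_loglik(params, data, eps) -
    lambda_incidence * sum(abs(params$incidence_coefficients)) -
    lambda_latency * sum(abs(params$latency_coefficients))
}

#' Serialize a baseline hazard to CSV
#'
#' Writes columns `event_time,cumulative_hazard` (cumulative sums of the
#' increments).
#'
#' @param baseline a [baseline_hazard()] object.
#' @param path output file.
#' @export
write_baseline <- function(baseline, path) {
  write.csv(data.frame(event_time = baseline$event_times,
                       cumulative_hazard = cumsum(baseline$increments)),
            path, row.names = FALSE)
  invisible(path)
}
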