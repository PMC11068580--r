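# Shared fixtures built in code: small cohorts and hand-rolled oracles.

small_cohort <- function(n = 80, p = 10, seed = 1, ...) {
  simulate_cohort(generator_config(
    n_samples = n, n_genes = p, n_blocks = max(1, p %/% 2),
    within_block_correlation = 0.2,
    n_true_incidence = max(1, min(2, p %/% 2)),
    n_true_latency = max(1, min(2, p %/% 2)),
    seed = seed, ...))
}

random_survival <- function(n, seed, max_time = 5, event_prob = 0.6) {
  set.seed(seed)
  times <- round(runif(n, 0.05, max_time), 3)
  events <- rbinom(n, 1, event_prob)
  list(times = times, events = events)
}

# independent product-limit oracle: explicit loop over distinct times
km_oracle <- function(times, events) {
  ut <- sort(unique(times))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(times = ut, survival = surv)
}

# independent Nelson-Aalen oracle: explicit loop
nelson_aalen_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  inc <- vapply(ut, function(tk) {
    sum(times == tk & events == 1) / sum(times >= tk)
  }, numeric(1))
  list(event_times = ut, increments = inc)
}

# brute-force Harrell concordance: double loop over ordered pairs
c_statistic_oracle <- function(risk, times, events) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- times[j] > times[i] ||
        (times[j] == times[i] && events[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Mann-Whitney AUC of a binary outcome
mann_whitney_auc <- function(marker, outcome) {
  pos <- marker[outcome == 1]
  neg <- marker[outcome == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# intercept-only fitted model for prediction edge cases
intercept_only_fit <- function(intercept = 0, p = 3, cutoff = 0,
                               cure_threshold = 0.5) {
  genes <- paste0("gene_", seq_len(p))
  params <- mcm_parameters(intercept, setNames(numeric(p), genes),
                           setNames(numeric(p), genes),
                           baseline_hazard(c(1, 2), c(0.2, 0.4)))
  structure(list(parameters = params, penalty = penalty_config(),
                 trace = NULL, converged = TRUE, ascent_ok = TRUE,
                 training_risk_score_cutoff = cutoff,
                 cure_threshold = cure_threshold, gene_names = genes),
            class = "mcm_fit")
}
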