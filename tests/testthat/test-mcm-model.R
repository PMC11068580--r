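make_params <- function(intercept = 0, b = numeric(2), beta = numeric(2),
                        event_times = c(1, 2, 3),
                        increments = c(0.2, 0.3, 0.5)) {
  mcm_parameters(intercept, b, beta, baseline_hazard(event_times, increments))
}

test_that("baseline hazard enforces its invariants", {
  expect_error(baseline_hazard(c(2, 1), c(0.1, 0.1)), "increasing")
  expect_error(baseline_hazard(c(1, 2), c(0.1, -0.1)), "nonnegative")
  expect_error(baseline_hazard(numeric(0), numeric(0)), "at least one")
  b <- baseline_hazard(c(1, 3), c(0.5, 0.25))
  expect_equal(cumulative_hazard(b, c(0, 1, 2, 3, 10)),
               c(0, 0.5, 0.5, 0.75, 0.75))
  expect_error(cumulative_hazard(b, -1), "nonnegative")
})

test_that("susceptible survival follows the PH form with a zero tail", {
  p <- make_params(beta = c(0.5, -0.25))
  z <- c(1, 2)
  expect_equal(susceptible_survival(p, z, 0), 1)
  expect_error(susceptible_survival(p, z, -0.5), "nonnegative")
  # beta = 0 reduces to the baseline survival
  p0 <- make_params(beta = c(0, 0))
  expect_equal(susceptible_survival(p0, z, 2.5), exp(-0.5))
  # PH form
  hr <- exp(sum(z * c(0.5, -0.25)))
  expect_equal(susceptible_survival(p, z, 2.5), exp(-0.5)^hr)
  # zero tail
  expect_identical(susceptible_survival(p, z, 3.0001), 0)
})

test_that("population survival mixes the cure fraction correctly", {
  z <- c(0.3, -0.7)
  # intercept +50: everyone susceptible
  p1 <- make_params(intercept = 50, beta = c(0.2, 0.1))
  expect_equal(population_survival(p1, z, 1.5),
               susceptible_survival(p1, z, 1.5), tolerance = 1e-12)
  # intercept -50: everyone cured
  p0 <- make_params(intercept = -50)
  expect_equal(population_survival(p0, z, 2.9), 1, tolerance = 1e-12)
  # beyond the support the curve plateaus at exactly 1 - pi
  p <- make_params(intercept = 0.4, b = c(0.5, 0.2))
  pi_i <- plogis(0.4 + sum(z * c(0.5, 0.2)))
  expect_equal(population_survival(p, z, 100), 1 - pi_i, tolerance = 1e-14)
})

test_that("population survival is non-increasing in time for random parameters", {
  set.seed(42)
  for (rep in 1:25) {
    et <- sort(runif(5, 0.1, 5))
    p <- mcm_parameters(rnorm(1), rnorm(3), rnorm(3),
                        baseline_hazard(et, rexp(5, 2)))
    z <- rnorm(3)
    tt <- sort(c(0, runif(20, 0, 6)))
    s <- vapply(tt, function(t) population_survival(p, z, t), numeric(1))
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("E-step weights match the posterior formula and its edge cases", {
  # pi = 0.5 (zero covariates, intercept 0) and S_u(t) = 0.5 at t = 1
  params <- mcm_parameters(0, numeric(0), numeric(0),
                           baseline_hazard(1, log(2)))
  data <- survival_dataset(matrix(numeric(0), 2, 0), times = c(1, 1),
                           events = c(1, 0))
  w <- e_step(params, data)
  expect_equal(w[1], 1)           # events are susceptible with certainty
  expect_equal(w[2], 1 / 3)       # 0.25 / 0.75
  # censored beyond the last event time: forced cured
  data2 <- survival_dataset(matrix(numeric(0), 1, 0), times = 2, events = 0)
  expect_equal(e_step(params, data2), 0)
})

test_that("E-step weight increases with susceptible survival (censored case)", {
  set.seed(7)
  for (rep in 1:20) {
    pi_i <- runif(1, 0.05, 0.95)
    su <- sort(runif(10))
    w <- pi_i * su / (1 - pi_i + pi_i * su)
    expect_true(all(diff(w) >= 0))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("Breslow baseline matches hand computation and weight algebra", {
  # one event at t = 1 among 4 at risk, all weights 1, beta = 0 -> 1/4
  d <- survival_dataset(matrix(0, 4, 1), times = c(1, 2, 3, 4),
                        events = c(1, 0, 0, 0))
  b <- breslow_baseline(d, rep(1, 4), 0)
  expect_equal(b$event_times, 1)
  expect_equal(b$increments, 1 / 4)

  # halving all weights doubles the increments (weights enter the
  # denominator only)
  d3 <- survival_dataset(matrix(0, 3, 1), times = c(1, 2, 3),
                         events = c(1, 1, 0))
  w <- c(1, 1, 0.6)
  b1 <- breslow_baseline(d3, w, 0)
  # hand Breslow: t=1: 1/(1+1+0.6); t=2: 1/(1+0.6)
  expect_equal(b1$increments, c(1 / 2.6, 1 / 1.6))
  b2 <- breslow_baseline(d3, w / 2, 0)
  expect_equal(b2$increments, 2 * b1$increments)
})

test_that("unweighted Breslow at beta = 0 equals the Nelson-Aalen oracle", {
  for (s in 1:20) {
    sv <- random_survival(n = 30, seed = s)
    d <- survival_dataset(matrix(0, 30, 1), sv$times, pmax(sv$events, s %% 2),
                          sample_ids = paste0("s", 1:30))
    d$events[1] <- 1  # ensure at least one event
    na <- nelson_aalen_oracle(d$times, d$events)
    br <- breslow_baseline(d, rep(1, 30), 0)
    expect_equal(br$event_times, na$event_times)
    expect_equal(br$increments, na$increments, tolerance = 1e-14)
  }
})

test_that("observed log-likelihood matches term-by-term enumeration", {
  # trivial: no susceptibles, no events -> every term log(1) = 0
  p0 <- mcm_parameters(-50, numeric(0), numeric(0), baseline_hazard(1, 0.5))
  d0 <- survival_dataset(matrix(numeric(0), 3, 0), times = c(0.5, 1, 2),
                         events = c(0, 0, 0))
  expect_equal(observed_loglik(p0, d0), 0, tolerance = 1e-10)

  # 2-sample instance, hand enumeration of the two likelihood terms
  params <- mcm_parameters(0.3, c(0.5), c(-0.4), baseline_hazard(1, 0.6))
  X <- matrix(c(0.8, -1.1), 2, 1, dimnames = list(c("a", "b"), "g1"))
  d <- survival_dataset(X, times = c(1, 0.7), events = c(1, 0))
  pi1 <- plogis(0.3 + 0.5 * 0.8); pi2 <- plogis(0.3 + 0.5 * (-1.1))
  hr1 <- exp(-0.4 * 0.8)
  su1 <- exp(-0.6 * hr1)             # event at t = 1 (includes own jump)
  su2 <- 1                           # censored at 0.7 < first event time
  expected <- log(pi1 * 0.6 * hr1 * su1) + log(1 - pi2 + pi2 * su2)
  expect_equal(observed_loglik(params, d), expected, tolerance = 1e-12)

  # penalized version subtracts the L1 terms
  expect_equal(penalized_observed_loglik(params, d, 2, 3),
               expected - 2 * 0.5 - 3 * 0.4, tolerance = 1e-12)
})

test_that("survival dataset validation catches bad inputs", {
  X <- matrix(rnorm(6), 3, 2)
  expect_error(survival_dataset(X, c(1, 2), c(0, 1, 0)), "times")
  expect_error(survival_dataset(X, c(1, 2, 0), c(0, 1, 0)), "positive")
  expect_error(survival_dataset(X, c(1, 2, 3), c(0, 2, 0)), "0/1")
  expect_error(survival_dataset(X, c(1, 2, 3), c(0, 1, 0),
                                gene_names = c("g", "g")), "duplicate")
})
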