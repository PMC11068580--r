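strict <- penalty_config(tolerance = 1e-9, max_iterations = 200)

logistic_instance <- function(n = 30, p = 3, seed = 1, fractional = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  eta <- 0.3 + drop(X %*% rnorm(p))
  w <- if (fractional) plogis(eta + rnorm(n)) else rbinom(n, 1, plogis(eta))
  list(X = X, w = w)
}

cox_instance <- function(n = 20, p = 2, seed = 1, cens = 0.3) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  times <- rexp(n, exp(drop(Z %*% rep(0.5, p))))
  events <- rbinom(n, 1, 1 - cens)
  events[which.max(times)] <- 1
  list(Z = Z, times = times, events = events)
}

test_that("full shrinkage returns the null logistic model at lambda >= lambda_max", {
  inst <- logistic_instance(seed = 2, fractional = TRUE)
  lmax <- lambda_max_logistic(inst$X, inst$w, strict)
  fit <- fit_weighted_lasso_logistic(inst$X, inst$w, lmax * 1.0001,
                                     config = strict)
  expect_equal(unname(fit$coefficients), rep(0, 3))
  expect_equal(fit$intercept, qlogis(mean(inst$w)), tolerance = 1e-8)
  # just below lambda_max at least one coefficient enters
  fit2 <- fit_weighted_lasso_logistic(inst$X, inst$w, lmax * 0.95,
                                      config = strict)
  expect_gt(sum(fit2$coefficients != 0), 0)
})

test_that("unpenalized weighted logistic matches the glm Newton oracle", {
  for (s in 1:4) {
    inst <- logistic_instance(n = 30, p = 3, seed = s, fractional = TRUE)
    fit <- fit_weighted_lasso_logistic(inst$X, inst$w, 0, config = strict)
    oracle <- suppressWarnings(
      glm(inst$w ~ inst$X, family = quasibinomial()))
    expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
    expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
                 tolerance = 1e-4)
  }
})

test_that("a symmetric fractional response carries no signal", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  fit <- fit_weighted_lasso_logistic(X, rep(0.5, 20), 0.5, config = strict)
  expect_equal(unname(fit$coefficients), rep(0, 3))
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
})

test_that("full shrinkage zeroes the Cox coefficients", {
  inst <- cox_instance(seed = 5)
  w <- rep(1, 20)
  lmax <- lambda_max_cox(inst$Z, inst$times, inst$events, w, strict)
  fit <- fit_weighted_lasso_cox(inst$Z, inst$times, inst$events, w,
                                lmax * 1.0001, config = strict)
  expect_equal(unname(fit$coefficients), rep(0, 2))
})

test_that("unpenalized Cox matches the coxph Newton oracle (Breslow ties)", {
  for (s in 1:4) {
    inst <- cox_instance(n = 20, p = 2, seed = s)
    fit <- fit_weighted_lasso_cox(inst$Z, inst$times, inst$events,
                                  rep(1, 20), 0, config = strict)
    oracle <- suppressWarnings(survival::coxph(
      survival::Surv(inst$times, inst$events) ~ inst$Z, ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 50)))
    expect_equal(unname(fit$coefficients), unname(coef(oracle)),
                 tolerance = 1e-4)
  }
})

test_that("censored weights only enter through risk sets", {
  # with no censoring, zeroing censored weights changes nothing
  inst <- cox_instance(n = 15, p = 2, seed = 6, cens = 0)
  inst$events[] <- 1
  w_all <- rep(1, 15)
  f1 <- fit_weighted_lasso_cox(inst$Z, inst$times, inst$events, w_all, 1,
                               config = strict)
  f2 <- fit_weighted_lasso_cox(inst$Z, inst$times, inst$events,
                               ifelse(inst$events == 1, 1, 0), 1,
                               config = strict)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)

  # with censoring, the two weightings genuinely differ
  inst2 <- cox_instance(n = 30, p = 2, seed = 7, cens = 0.4)
  w0 <- ifelse(inst2$events == 1, 1, 0)
  w1 <- rep(1, 30)
  g1 <- fit_weighted_lasso_cox(inst2$Z, inst2$times, inst2$events, w1, 0.5,
                               config = strict)
  g2 <- fit_weighted_lasso_cox(inst2$Z, inst2$times, inst2$events, w0, 0.5,
                               config = strict)
  expect_gt(max(abs(g1$coefficients - g2$coefficients)), 1e-6)
})

test_that("KKT conditions hold at penalized solutions", {
  for (s in 1:10) {
    inst <- logistic_instance(n = 40, p = 6, seed = s, fractional = TRUE)
    lam <- 0.3 * lambda_max_logistic(inst$X, inst$w, strict)
    fit <- fit_weighted_lasso_logistic(inst$X, inst$w, lam, config = strict)
    expect_lt(kkt_residual_logistic(inst$X, inst$w, fit, lam, strict), 1e-6)

    cx <- cox_instance(n = 40, p = 6, seed = s + 100)
    w <- ifelse(cx$events == 1, 1, runif(40))
    lamc <- 0.3 * lambda_max_cox(cx$Z, cx$times, cx$events, w, strict)
    cfit <- fit_weighted_lasso_cox(cx$Z, cx$times, cx$events, w, lamc,
                                   config = strict)
    expect_lt(kkt_residual_cox(cx$Z, cx$times, cx$events, w, cfit, lamc,
                               strict), 1e-6)
  }
})

test_that("solution paths move continuously in lambda (warm starts)", {
  inst <- logistic_instance(n = 60, p = 8, seed = 9, fractional = TRUE)
  lam <- 0.2 * lambda_max_logistic(inst$X, inst$w, strict)
  f0 <- fit_weighted_lasso_logistic(inst$X, inst$w, lam, config = strict)
  f1 <- fit_weighted_lasso_logistic(inst$X, inst$w, lam * 1.01,
                                    init = f0$coefficients, config = strict)
  f2 <- fit_weighted_lasso_logistic(inst$X, inst$w, lam * 0.99,
                                    init = f0$coefficients, config = strict)
  expect_lt(max(abs(f1$coefficients - f0$coefficients)), 0.05)
  expect_lt(max(abs(f2$coefficients - f0$coefficients)), 0.05)
})

test_that("one-dimensional penalized Cox solution matches brute-force optimization", {
  # soft-thresholding in 1-D against direct optimization of the penalized
  # partial likelihood
  inst <- cox_instance(n = 25, p = 1, seed = 10)
  w <- rep(1, 25)
  cfg <- penalty_config(tolerance = 1e-10, max_iterations = 300,
                        standardize = FALSE)
  for (lam in c(0, 0.5, 2)) {
    fit <- fit_weighted_lasso_cox(inst$Z, inst$times, inst$events, w, lam,
                                  config = cfg)
    obj <- function(b) {
      eta <- inst$Z[, 1] * b
      ll <- 0
      for (i in which(inst$events == 1)) {
        ll <- ll + eta[i] - log(sum(exp(eta[inst$times >= inst$times[i]])))
      }
      ll - lam * abs(b)
    }
    brute <- optimize(obj, c(-5, 5), maximum = TRUE, tol = 1e-10)
    expect_equal(unname(fit$coefficients), brute$maximum, tolerance = 1e-4)
  }
})

test_that("solvers reject invalid inputs", {
  X <- matrix(c(1, NA, 0, 1), 2, 2)
  expect_error(fit_weighted_lasso_logistic(X, c(0.5, 0.5), 1), "non-finite")
  expect_error(fit_weighted_lasso_logistic(matrix(0, 2, 1), c(-0.1, 0.5), 1),
               "\\[0, 1\\]")
  Z <- matrix(rnorm(6), 3, 2)
  expect_error(fit_weighted_lasso_cox(Z, 1:3, c(0, 0, 0), rep(1, 3), 1),
               "at least one event")
  expect_error(fit_weighted_lasso_cox(Z, 1:3, c(1, 0, 0), c(0.5, 1, 1), 1),
               "equal 1 for events")
})

test_that("active-set acceleration does not change solutions", {
  inst <- logistic_instance(n = 50, p = 10, seed = 12, fractional = TRUE)
  lam <- 0.2 * lambda_max_logistic(inst$X, inst$w, strict)
  on_cfg <- strict; off_cfg <- strict
  on_cfg$active_set <- TRUE; off_cfg$active_set <- FALSE
  f_on <- fit_weighted_lasso_logistic(inst$X, inst$w, lam, config = on_cfg)
  f_off <- fit_weighted_lasso_logistic(inst$X, inst$w, lam, config = off_cfg)
  expect_equal(f_on$coefficients, f_off$coefficients, tolerance = 1e-6)

  cx <- cox_instance(n = 50, p = 10, seed = 13)
  lamc <- 0.2 * lambda_max_cox(cx$Z, cx$times, cx$events, rep(1, 50), strict)
  c_on <- fit_weighted_lasso_cox(cx$Z, cx$times, cx$events, rep(1, 50),
                                 lamc, config = on_cfg)
  c_off <- fit_weighted_lasso_cox(cx$Z, cx$times, cx$events, rep(1, 50),
                                  lamc, config = off_cfg)
  expect_equal(c_on$coefficients, c_off$coefficients, tolerance = 1e-6)
})
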