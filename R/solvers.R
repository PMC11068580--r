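#' Penalty and solver configuration
#'
#' @param lambda_incidence,lambda_latency nonnegative L1 penalty levels for
#'   the incidence (logistic) and latency (Cox) components. Penalties apply
#'   to internally standardized coefficients when `standardize = TRUE`.
#' @param standardize standardize covariate columns internally before
#'   penalizing (coefficients are always reported on the original scale).
#' @param max_iterations iteration cap for the EM loop and the solvers'
#'   outer (IRLS / quadratic approximation) loops.
#' @param tolerance convergence threshold on the maximum absolute
#'   coefficient change.
#' @param active_set use active-set cycling inside coordinate descent.
#' @export
penalty_config <- function(lambda_incidence = 0, lambda_latency = 0,
                           standardize = TRUE, max_iterations = 100L,
                           tolerance = 1e-6, active_set = TRUE) {
  if (lambda_incidence < 0 || lambda_latency < 0)
    stop_input("penalty levels must be nonnegative")
  if (tolerance <= 0) stop_input("tolerance must be > 0")
  if (max_iterations < 1) stop_input("max_iterations must be >= 1")
  structure(list(lambda_incidence = lambda_incidence,
                 lambda_latency = lambda_latency,
                 standardize = isTRUE(standardize),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 active_set = isTRUE(active_set)),
            class = "penalty_config")
}

INTERCEPT_CAP <- 15
IRLS_WEIGHT_FLOOR <- 1e-5
ETA_CAP <- 500

#' Column scales used for internal standardization
#'
#' Sample standard deviation per column; zero-variance columns get scale 1
#' (they cannot carry signal and stay at their initial coefficient).
#'
#' @param X numeric matrix.
#' @export
column_scales <- function(X) {
  if (ncol(X) == 0) return(numeric(0))
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s <= 0] <- 1
  s
}

standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- column_scales(X)
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

bernoulli_loglik <- function(response, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(response * log(p) + (1 - response) * log(1 - p))
}

#' L1-penalized logistic regression with fractional response
#'
#' Maximizes \eqn{\sum_i [w_i \log \pi_i + (1 - w_i)\log(1 - \pi_i)] -
#' \lambda \|b\|_1} (intercept unpenalized) where the response \eqn{w_i \in
#' [0,1]} may be fractional, as the E-step posterior weights are. Solved by
#' IRLS with coordinate-wise soft-thresholding; step-halving against the
#' penalized objective guarantees monotone ascent, and IRLS working weights
#' are floored at 1e-5 to avoid divergence at fitted probabilities near 0
#' or 1. The intercept is capped at |15|, which matters only when the
#' latent classes separate perfectly.
#'
#' @param X covariate matrix (n x p; p = 0 allowed).
#' @param response values in `[0, 1]`.
#' @param lambda nonnegative penalty level.
#' @param init optional initial coefficient vector (original scale).
#' @param config a [penalty_config()].
#' @return list with `intercept`, `coefficients` (original scale),
#'   `objective` (penalized log-likelihood attained), `converged`,
#'   `iterations`.
#' @export
fit_weighted_lasso_logistic <- function(X, response, lambda, init = NULL,
                                        config = penalty_config()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_input("non-finite values in X")
  if (any(response < 0 | response > 1)) stop_input("response must lie in [0, 1]")
  n <- nrow(X); p <- ncol(X)
  if (length(response) != n) stop_input("response length mismatch")

  cap <- function(b0) max(min(b0, INTERCEPT_CAP), -INTERCEPT_CAP)
  wbar <- mean(response)
  b0_null <- cap(logit(min(max(wbar, 1e-12), 1 - 1e-12)))
  if (p == 0) {
    pfit <- rep(expit(b0_null), n)
    return(list(intercept = b0_null, coefficients = numeric(0),
                objective = bernoulli_loglik(response, pfit),
                converged = TRUE, iterations = 0L))
  }

  if (config$standardize) {
    std <- standardize_columns(X)
    Xs <- std$X
  } else {
    std <- list(center = rep(0, p), scale = rep(1, p))
    Xs <- X
  }
  bs <- if (is.null(init)) rep(0, p) else as.numeric(init) * std$scale
  b0 <- b0_null

  pen_obj <- function(b0, bs) {
    eta <- pmin(pmax(b0 + drop(Xs %*% bs), -ETA_CAP), ETA_CAP)
    bernoulli_loglik(response, expit(eta)) - lambda * sum(abs(bs))
  }
  obj <- pen_obj(b0, bs)
  cd_tol <- config$tolerance * 0.1
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    eta <- pmin(pmax(b0 + drop(Xs %*% bs), -ETA_CAP), ETA_CAP)
    pr <- expit(eta)
    m <- pmax(pr * (1 - pr), IRLS_WEIGHT_FLOOR)
    yw <- eta + (response - pr) / m
    sol <- cd_wls_lasso(Xs, yw, m, lambda, bs, b0, TRUE, cd_tol, 5000L,
                        config$active_set)
    b0_new <- cap(sol$intercept)
    bs_new <- sol$beta
    obj_new <- pen_obj(b0_new, bs_new)
    halvings <- 0L
    while (obj_new < obj - 1e-12 && halvings < 40L) {
      b0_new <- (b0_new + b0) / 2
      bs_new <- (bs_new + bs) / 2
      obj_new <- pen_obj(b0_new, bs_new)
      halvings <- halvings + 1L
    }
    if (obj_new < obj - 1e-12) {  # cannot improve; keep current iterate
      converged <- TRUE
      break
    }
    delta <- max(abs(c(b0_new - b0, bs_new - bs)))
    b0 <- b0_new; bs <- bs_new; obj <- obj_new
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("weighted lasso logistic did not converge in ",
            config$max_iterations, " iterations", call. = FALSE)
  coefs <- bs / std$scale
  intercept <- cap(b0 - sum(bs * std$center / std$scale))
  list(intercept = intercept, coefficients = coefs, objective = obj,
       converged = converged, iterations = it)
}

# gradient/curvature of the weighted Cox partial log-likelihood wrt the
# per-sample linear predictor eta (Breslow ties; events carry weight 1 in
# the numerator, all samples enter risk sets with weight w).
cox_eta_derivs <- function(times, events, case_weights, eta) {
  r <- case_weights * exp(pmin(eta, ETA_CAP))
  ord <- order(times)
  t_s <- times[ord]; d_s <- events[ord]; r_s <- r[ord]
  risk <- rev(cumsum(rev(r_s)))
  first <- !duplicated(t_s)
  ut <- t_s[first]
  R_u <- risk[first]
  d_u <- as.numeric(tapply(d_s, match(t_s, ut), sum))
  evt <- d_u > 0
  if (any(evt & R_u <= 0))
    stop_input("risk set with zero total weight at event time(s): ",
               paste(signif(ut[evt & R_u <= 0], 6), collapse = ", "))
  a <- ifelse(evt, d_u / R_u, 0)
  b <- ifelse(evt, d_u / R_u^2, 0)
  Acum <- cumsum(a); Bcum <- cumsum(b)
  pos <- findInterval(times, ut)
  A <- ifelse(pos == 0, 0, Acum[pmax(pos, 1L)])
  B <- ifelse(pos == 0, 0, Bcum[pmax(pos, 1L)])
  g <- events - r * A
  h <- r * A - r^2 * B
  idx <- events == 1
  pl <- sum(eta[idx] - log(R_u[pmax(pos, 1L)][idx]))
  list(gradient = g, curvature = h, partial_loglik = pl)
}

#' L1-penalized case-weighted Cox partial likelihood
#'
#' Maximizes the weighted partial log-likelihood
#' \deqn{\sum_i \delta_i \left[z_i^\top\beta -
#'   \log \sum_{j: t_j \ge t_i} w_j e^{z_j^\top\beta}\right] -
#'   \lambda\|\beta\|_1,}
#' with Breslow handling of tied event times. Events must carry weight 1;
#' censored samples contribute through risk sets only, weighted by their
#' posterior susceptibility. Solved by an outer quadratic approximation in
#' the linear predictor and inner coordinate-wise soft-thresholding, with
#' step-halving against the penalized objective.
#'
#' @param Z covariate matrix (n x p; p = 0 allowed).
#' @param times,events follow-up times and 0/1 event indicators.
#' @param case_weights weights in `[0, 1]`, 1 wherever `events == 1`.
#' @param lambda nonnegative penalty level.
#' @param init optional initial coefficients (original scale).
#' @param config a [penalty_config()].
#' @return list with `coefficients` (original scale), `objective`
#'   (penalized partial log-likelihood), `converged`, `iterations`.
#' @export
fit_weighted_lasso_cox <- function(Z, times, events, case_weights, lambda,
                                   init = NULL, config = penalty_config()) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop_input("non-finite values in Z")
  if (sum(events) == 0) stop_input("at least one event is required")
  if (any(case_weights[events == 1] != 1))
    stop_input("case_weights must equal 1 for events")
  if (any(case_weights < 0 | case_weights > 1))
    stop_input("case_weights must lie in [0, 1]")
  p <- ncol(Z)
  if (p == 0)
    return(list(coefficients = numeric(0),
                objective = cox_eta_derivs(times, events, case_weights,
                                           rep(0, nrow(Z)))$partial_loglik,
                converged = TRUE, iterations = 0L))

  if (config$standardize) {
    std <- standardize_columns(Z)
    Zs <- std$X
  } else {
    std <- list(center = rep(0, p), scale = rep(1, p))
    Zs <- Z
  }
  bs <- if (is.null(init)) rep(0, p) else as.numeric(init) * std$scale

  pen_obj <- function(bs) {
    d <- cox_eta_derivs(times, events, case_weights, drop(Zs %*% bs))
    d$partial_loglik - lambda * sum(abs(bs))
  }
  obj <- pen_obj(bs)
  cd_tol <- config$tolerance * 0.1
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    eta <- drop(Zs %*% bs)
    d <- cox_eta_derivs(times, events, case_weights, eta)
    m <- pmax(d$curvature, IRLS_WEIGHT_FLOOR)
    yw <- eta + d$gradient / m
    sol <- cd_wls_lasso(Zs, yw, m, lambda, bs, 0, FALSE, cd_tol, 5000L,
                        config$active_set)
    bs_new <- sol$beta
    obj_new <- pen_obj(bs_new)
    halvings <- 0L
    while (obj_new < obj - 1e-12 && halvings < 40L) {
      bs_new <- (bs_new + bs) / 2
      obj_new <- pen_obj(bs_new)
      halvings <- halvings + 1L
    }
    if (obj_new < obj - 1e-12) {
      converged <- TRUE
      break
    }
    delta <- max(abs(bs_new - bs))
    bs <- bs_new; obj <- obj_new
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("weighted lasso Cox did not converge in ",
            config$max_iterations, " iterations", call. = FALSE)
  list(coefficients = bs / std$scale, objective = obj,
       converged = converged, iterations = it)
}

#' Smallest penalty shrinking all slopes to zero (logistic component)
#'
#' Computed from the gradient of the null (intercept-only) model on the
#' standardized scale: \eqn{\lambda_{max} = \max_j |x_j^\top (w - \bar w)|}.
#'
#' @inheritParams fit_weighted_lasso_logistic
#' @export
lambda_max_logistic <- function(X, response, config = penalty_config()) {
  X <- as.matrix(X)
  if (ncol(X) == 0) return(0)
  Xs <- if (config$standardize) standardize_columns(X)$X else X
  max(abs(drop(crossprod(Xs, response - mean(response)))))
}

#' Smallest penalty shrinking all slopes to zero (Cox component)
#'
#' Maximum absolute coordinate of the weighted partial-likelihood gradient
#' at \eqn{\beta = 0} on the standardized scale.
#'
#' @inheritParams fit_weighted_lasso_cox
#' @export
lambda_max_cox <- function(Z, times, events, case_weights,
                           config = penalty_config()) {
  Z <- as.matrix(Z)
  if (ncol(Z) == 0) return(0)
  Zs <- if (config$standardize) standardize_columns(Z)$X else Z
  g <- cox_eta_derivs(times, events, case_weights, rep(0, nrow(Z)))$gradient
  max(abs(drop(crossprod(Zs, g))))
}

#' KKT residual of a penalized logistic fit
#'
#' Maximum violation of the subgradient optimality conditions on the
#' (standardized) penalty scale: 0 at an exact optimum.
#'
#' @inheritParams fit_weighted_lasso_logistic
#' @param fit result of [fit_weighted_lasso_logistic()].
#' @export
kkt_residual_logistic <- function(X, response, fit, lambda,
                                  config = penalty_config()) {
  X <- as.matrix(X)
  std <- if (config$standardize) standardize_columns(X) else
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  pr <- expit(fit$intercept + linear_predictor(X, fit$coefficients))
  grad0 <- sum(response - pr)
  if (ncol(X) == 0) return(abs(grad0))
  grad <- drop(crossprod(std$X, response - pr))
  bs <- fit$coefficients * std$scale
  viol <- ifelse(bs != 0, abs(grad - lambda * sign(bs)),
                 pmax(abs(grad) - lambda, 0))
  max(abs(grad0), viol)
}

#' KKT residual of a penalized Cox fit
#'
#' @inheritParams fit_weighted_lasso_cox
#' @param fit result of [fit_weighted_lasso_cox()].
#' @export
kkt_residual_cox <- function(Z, times, events, case_weights, fit, lambda,
                             config = penalty_config()) {
  Z <- as.matrix(Z)
  if (ncol(Z) == 0) return(0)
  std <- if (config$standardize) standardize_columns(Z) else
    list(X = Z, center = rep(0, ncol(Z)), scale = rep(1, ncol(Z)))
  eta <- linear_predictor(Z, fit$coefficients)
  g <- cox_eta_derivs(times, events, case_weights, eta)$gradient
  grad <- drop(crossprod(std$X, g))
  bs <- fit$coefficients * std$scale
  viol <- ifelse(bs != 0, abs(grad - lambda * sign(bs)),
                 pmax(abs(grad) - lambda, 0))
  max(viol)
}
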