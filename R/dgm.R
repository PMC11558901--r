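## Selection-model data-generating mechanism ---------------------------------
##
## Complete data are drawn from a joint distribution factorised into a
## sequence of univariate regressions,
##   Z1, Z2, Z3 exogenous ->  W | Z  ->  X | W, Z  ->  Y | X, W, Z
##   -> A1, A2 | Y, X, W, Z  ->  D | A, Y, X, W, Z  ->  MY | D, A, Y, X,
## with logistic models for binary variables and normal models for the
## continuous ones. The outcome missingness model carries the selection-model
## bias parameter delta_sm:
##
##   logit Pr(MY = 1 | D, A, Y, X) = psi0 + psiD D + psiA1 A1 + psiA2 A2
##                                    + psiX X - delta_sm * Y
##
## delta_sm is the difference in the log-odds of *observing* Y between
## records with Y = 1 and Y = 0 (conditional on D, A, X). A large positive
## delta_sm means cases are far more likely to be observed than non-cases,
## the situation in outcome-dependent testing designs.

#' Selection-model data-generating parameters
#'
#' Bundles the coefficient vectors of the sequential (selection-model)
#' data-generating mechanism. All coefficients are on the log-odds scale
#' except the X-model, which is a linear regression with residual variance
#' `xi2`. The bias parameter `delta_sm` is the difference in the log-odds of
#' observing the outcome `Y` between records with `Y = 1` and `Y = 0`,
#' conditional on `D`, `A` and `X`; it enters the missingness model as
#' `- delta_sm * Y` on the log-odds of being missing.
#'
#' @param beta_x Exposure effect on the log-odds scale (coefficient of `X`
#'   in the outcome model).
#' @param beta0 Outcome-model intercept; calibrate with
#'   [calibrate_y_intercept()] to fix the marginal prevalence of `Y`.
#' @param eta Coefficients of the `W | Z` logistic model:
#'   `(intercept, Z1, Z2, Z3)`.
#' @param zeta Coefficients of the `X | W, Z` linear model:
#'   `(intercept, W, Z1, Z2, Z3)`.
#' @param xi2 Residual variance of the `X` model (must be positive).
#' @param beta_rest Outcome-model coefficients other than the intercept and
#'   exposure: `(W, Z1, Z2, Z3)`.
#' @param theta_a1,theta_a2 Coefficients of the auxiliary-variable models
#'   `A | Y, X, W, Z`: `(intercept, Y, X, W, Z1, Z2, Z3)`.
#' @param omega Coefficients of the `D | A, Y, X, W, Z` model:
#'   `(intercept, A1, A2, Y, X, W, Z1, Z2, Z3)`.
#' @param psi Coefficients of the outcome-missingness model other than the
#'   bias parameter: `(intercept, D, A1, A2, X)`.
#' @param delta_sm Bias parameter (log-odds units).
#' @param pz Marginal probabilities of the binary exogenous confounders
#'   `(Z1, Z3)`; `Z2` is standard normal.
#'
#' @return An object of class `sm_dgm_params`.
#' @seealso [sm_params_demo()], [generate_sm_complete()]
#' @export
sm_params <- function(beta_x, beta0, eta, zeta, xi2, beta_rest,
                      theta_a1, theta_a2, omega, psi, delta_sm,
                      pz = c(0.4, 0.3)) {
  stopifnot(
    length(eta) == 4, length(zeta) == 5, length(beta_rest) == 4,
    length(theta_a1) == 7, length(theta_a2) == 7, length(omega) == 9,
    length(psi) == 5, length(pz) == 2
  )
  p <- list(
    beta_x = beta_x, beta0 = beta0,
    eta = unname(eta), zeta = unname(zeta), xi2 = xi2,
    beta_rest = unname(beta_rest),
    theta_a1 = unname(theta_a1), theta_a2 = unname(theta_a2),
    omega = unname(omega), psi = unname(psi),
    delta_sm = delta_sm, pz = unname(pz)
  )
  validate_sm_params(p)
  structure(p, class = "sm_dgm_params")
}

validate_sm_params <- function(p) {
  all_coef <- unlist(p[c("beta_x", "beta0", "eta", "zeta", "beta_rest",
                         "theta_a1", "theta_a2", "omega", "psi", "delta_sm")])
  if (!all(is.finite(all_coef))) {
    stop("all data-generating coefficients must be finite")
  }
  if (!is.finite(p$xi2) || p$xi2 <= 0) stop("xi2 must be positive")
  if (any(p$pz <= 0) || any(p$pz >= 1)) stop("pz must lie in (0, 1)")
  invisible(p)
}

#' Demonstration parameter set for the selection-model generator
#'
#' A self-contained coefficient set emulating a cohort study with a rare
#' binary outcome (marginal prevalence 5%), a continuous standardised
#' exposure, three confounders, two fully observed auxiliary variables
#' strongly predictive of the outcome, one partially observed confounder and
#' one partially observed auxiliary, and a very strong MNAR outcome
#' missingness mechanism (`delta_sm = 7.85`): roughly 85% of outcomes are
#' missing, cases are almost always observed, and being observed is
#' positively related to the exposure. Intercepts of the X and Y models are
#' pre-calibrated so that marginally `X` has mean 0 and standard deviation 1
#' and `Y` has prevalence 0.05 in both the null and non-null exposure
#' scenarios.
#'
#' @param beta_x Exposure effect; the two study scenarios are `log(3)`
#'   (default) and `0`.
#' @param delta_sm Bias parameter of the outcome missingness model.
#' @return An `sm_dgm_params` object.
#' @export
sm_params_demo <- function(beta_x = log(3), delta_sm = 7.85) {
  ## beta0 pre-calibrated (calibrate_y_intercept, n = 4e6) for the two study
  ## scenarios; any other beta_x triggers a fresh calibration.
  beta0 <- if (isTRUE(all.equal(beta_x, log(3)))) {
    -3.9454
  } else if (isTRUE(all.equal(beta_x, 0))) {
    -3.3399
  } else {
    NA_real_
  }
  p <- sm_params(
    beta_x = beta_x,
    beta0 = if (is.na(beta0)) -3 else beta0,
    eta = c(-0.6, 0.3, 0.2, -0.2),
    zeta = c(-0.2179, 0.25, 0.2, 0.3, 0.15),
    xi2 = 0.8732,
    beta_rest = c(0.4, 0.3, 0.25, 0.2),
    theta_a1 = c(-1.3, 1.5, 0.3, 0.2, 0.1, 0.15, 0.1),
    theta_a2 = c(-1.6, 1.8, 0.35, 0.15, 0.12, 0.1, 0.08),
    omega = c(-1.9, 0.5, 0.6, 1.5, 0.3, 0.2, 0.1, 0.1, 0.1),
    psi = c(2.4, -0.4, -0.4, -0.5, -0.3),
    delta_sm = delta_sm,
    pz = c(0.4, 0.3)
  )
  if (is.na(beta0)) {
    p$beta0 <- calibrate_y_intercept(p, target_prevalence = 0.05,
                                     n_calib = 1e6, seed = 20260101)
  }
  p
}

#' Read or write selection-model parameters as YAML
#'
#' Parameter files hold one named block per coefficient vector
#' (`eta`, `zeta`, `xi2`, `beta0`, `beta_x`, `beta_rest`, `theta_a1`,
#' `theta_a2`, `omega`, `psi`, `delta_sm`, `pz`).
#'
#' @param path File path.
#' @return `read_sm_params()` returns an `sm_dgm_params` object;
#'   `write_sm_params()` returns `path` invisibly.
#' @export
read_sm_params <- function(path) {
  y <- yaml::read_yaml(path)
  needed <- c("beta_x", "beta0", "eta", "zeta", "xi2", "beta_rest",
              "theta_a1", "theta_a2", "omega", "psi", "delta_sm")
  missing_blocks <- setdiff(needed, names(y))
  if (length(missing_blocks)) {
    stop("parameter file is missing blocks: ",
         paste(missing_blocks, collapse = ", "))
  }
  sm_params(beta_x = y$beta_x, beta0 = y$beta0, eta = y$eta, zeta = y$zeta,
            xi2 = y$xi2, beta_rest = y$beta_rest, theta_a1 = y$theta_a1,
            theta_a2 = y$theta_a2, omega = y$omega, psi = y$psi,
            delta_sm = y$delta_sm, pz = y$pz %||% c(0.4, 0.3))
}

#' @rdname read_sm_params
#' @param params An `sm_dgm_params` object.
#' @export
write_sm_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Finds the intercept `beta0` such that the marginal prevalence of `Y`
#' under the selection-model generator equals `target_prevalence`.
#' Uses bisection on a single calibration sample with common random numbers
#' (the covariates and the uniforms behind the outcome draws are held fixed
#' while `beta0` moves), so the simulated prevalence is monotone in `beta0`
#' and the search always converges. Deterministic given `seed`.
#'
#' @param params An `sm_dgm_params` object (its `beta0` is ignored).
#' @param target_prevalence Target marginal prevalence, in (0, 1).
#' @param n_calib Calibration sample size (at least 10,000).
#' @param seed Integer seed.
#' @param tol Absolute tolerance on the simulated prevalence.
#' @param bounds Search interval for `beta0`.
#' @return The calibrated intercept (log-odds units).
#' @export
calibrate_y_intercept <- function(params, target_prevalence, n_calib = 1e5,
                                  seed = 1L, tol = 0.002,
                                  bounds = qlogis(target_prevalence) + c(-10, 10)) {
  if (!is.finite(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1) {
    stop("target_prevalence must lie strictly between 0 and 1")
  }
  stopifnot(n_calib >= 1e4)
  validate_sm_params(params)
  set.seed(seed)
  z1 <- draw_bernoulli(rep(params$pz[1], n_calib))
  z2 <- stats::rnorm(n_calib)
  z3 <- draw_bernoulli(rep(params$pz[2], n_calib))
  w <- draw_bernoulli(expit(params$eta[1] + params$eta[2] * z1 +
                              params$eta[3] * z2 + params$eta[4] * z3))
  x <- params$zeta[1] + params$zeta[2] * w + params$zeta[3] * z1 +
    params$zeta[4] * z2 + params$zeta[5] * z3 +
    stats::rnorm(n_calib, sd = sqrt(params$xi2))
  u <- stats::runif(n_calib)
  lp_rest <- params$beta_x * x + params$beta_rest[1] * w +
    params$beta_rest[2] * z1 + params$beta_rest[3] * z2 +
    params$beta_rest[4] * z3
  prev_at <- function(b0) mean(u < expit(b0 + lp_rest))
  lo <- bounds[1]; hi <- bounds[2]
  if (prev_at(lo) > target_prevalence || prev_at(hi) < target_prevalence) {
    stop("calibration failed: bounds [", lo, ", ", hi,
         "] do not bracket the target prevalence")
  }
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    pm <- prev_at(mid)
    if (abs(pm - target_prevalence) <= tol && (hi - lo) < 0.01) break
    if (pm < target_prevalence) lo <- mid else hi <- mid
  }
  mid
}

#' Generate complete data under the selection-model mechanism
#'
#' Draws `n` independent records sequentially:
#' `Z` exogenous, then `W | Z`, `X | W, Z`, `Y | X, W, Z`,
#' `A1, A2 | Y, X, W, Z`, `D | A, Y, X, W, Z` and the outcome-missingness
#' indicator `m_y | D, A, Y, X`. Binary variables use logistic draws,
#' continuous ones normal draws. The missingness indicator is generated
#' jointly with the data (it is part of the mechanism), but no value is
#' blanked here; see [apply_missingness()].
#'
#' @param n Number of records.
#' @param params An `sm_dgm_params` object.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A `data.frame` with columns
#'   `Y, X, Z1, Z2, Z3, W, A1, A2, D, m_y` and attribute `dgm = "sm"`.
#' @export
generate_sm_complete <- function(n, params, seed) {
  stopifnot(n >= 1)
  validate_sm_params(params)
  set.seed(seed)
  z1 <- draw_bernoulli(rep(params$pz[1], n))
  z2 <- stats::rnorm(n)
  z3 <- draw_bernoulli(rep(params$pz[2], n))
  w <- draw_bernoulli(expit(params$eta[1] + params$eta[2] * z1 +
                              params$eta[3] * z2 + params$eta[4] * z3))
  x <- params$zeta[1] + params$zeta[2] * w + params$zeta[3] * z1 +
    params$zeta[4] * z2 + params$zeta[5] * z3 +
    stats::rnorm(n, sd = sqrt(params$xi2))
  y <- draw_bernoulli(expit(params$beta0 + params$beta_x * x +
                              params$beta_rest[1] * w +
                              params$beta_rest[2] * z1 +
                              params$beta_rest[3] * z2 +
                              params$beta_rest[4] * z3))
  lp_a <- function(th) {
    th[1] + th[2] * y + th[3] * x + th[4] * w + th[5] * z1 + th[6] * z2 +
      th[7] * z3
  }
  a1 <- draw_bernoulli(expit(lp_a(params$theta_a1)))
  a2 <- draw_bernoulli(expit(lp_a(params$theta_a2)))
  om <- params$omega
  d <- draw_bernoulli(expit(om[1] + om[2] * a1 + om[3] * a2 + om[4] * y +
                              om[5] * x + om[6] * w + om[7] * z1 +
                              om[8] * z2 + om[9] * z3))
  ps <- params$psi
  m_y <- draw_bernoulli(expit(ps[1] + ps[2] * d + ps[3] * a1 + ps[4] * a2 +
                                ps[5] * x - params$delta_sm * y))
  out <- data.frame(Y = y, X = x, Z1 = z1, Z2 = z2, Z3 = z3, W = w,
                    A1 = a1, A2 = a2, D = d, m_y = m_y)
  attr(out, "dgm") <- "sm"
  out
}

## ---- Covariate missingness ------------------------------------------------

#' Missing-at-random mechanisms for the covariates
#'
#' Logistic models for the missingness indicators of `X`, `W` and `D`, each
#' depending only on the fully observed variables `Z1, Z2, Z3, A1, A2`
#' (so the mechanism is MAR whatever the outcome missingness does). The
#' default coefficients give close to 5% missingness in each variable.
#'
#' @param x,w,d Numeric vectors `(intercept, Z1, Z2, Z3, A1, A2)` of
#'   log-odds coefficients.
#' @return An object of class `mar_mechanism`.
#' @export
mar_mechanism <- function(x, w, d) {
  m <- list(X = unname(x), W = unname(w), D = unname(d))
  if (!all(vapply(m, length, 1L) == 6)) {
    stop("each mechanism needs 6 coefficients: intercept, Z1, Z2, Z3, A1, A2")
  }
  if (!all(is.finite(unlist(m)))) stop("mechanism coefficients must be finite")
  structure(m, class = "mar_mechanism")
}

#' @rdname mar_mechanism
#' @export
mar_mechanism_default <- function() {
  mar_mechanism(
    x = c(-3.20, 0.233, -0.0570, -0.133, 0.363, 0.763),
    w = c(-2.90, 0.0720, -0.232, -0.774, 0.169, 0.417),
    d = c(-2.95, -0.0590, -0.0290, -0.190, 0.130, 0.192)
  )
}

#' Impose the missingness mechanisms on complete data
#'
#' Blanks `Y` wherever the jointly generated indicator `m_y` is 1, then
#' draws the three MAR indicators `m_x, m_w, m_d` independently from their
#' logistic models on `(Z1, Z2, Z3, A1, A2)` and blanks the corresponding
#' entries of `X`, `W`, `D`. Indicators are retained as columns.
#'
#' @param complete A complete dataset from [generate_sm_complete()] or
#'   [generate_pmm_complete()] (must contain `m_y`).
#' @param mech A `mar_mechanism`; default [mar_mechanism_default()].
#' @param seed Integer seed for the MAR indicator draws.
#' @return A `data.frame` of class `observed_dataset` with `NA`s in
#'   `Y, X, W, D` and indicator columns `m_y, m_x, m_w, m_d`.
#' @export
apply_missingness <- function(complete, mech = mar_mechanism_default(), seed) {
  needed <- c("Y", "X", "Z1", "Z2", "Z3", "W", "A1", "A2", "D", "m_y")
  if (!all(needed %in% names(complete))) {
    stop("complete data must contain columns: ",
         paste(setdiff(needed, names(complete)), collapse = ", "))
  }
  set.seed(seed)
  Zmat <- cbind(1, complete$Z1, complete$Z2, complete$Z3,
                complete$A1, complete$A2)
  obs <- complete
  obs$m_x <- draw_bernoulli(expit(drop(Zmat %*% mech$X)))
  obs$m_w <- draw_bernoulli(expit(drop(Zmat %*% mech$W)))
  obs$m_d <- draw_bernoulli(expit(drop(Zmat %*% mech$D)))
  obs$Y[obs$m_y == 1] <- NA_real_
  obs$X[obs$m_x == 1] <- NA_real_
  obs$W[obs$m_w == 1] <- NA_real_
  obs$D[obs$m_d == 1] <- NA_real_
  class(obs) <- c("observed_dataset", "data.frame")
  obs
}
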