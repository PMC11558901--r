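#' mnarpba: probabilistic bias analysis for outcomes missing not at random
#'
#' Implements two probabilistic bias analyses for a binary outcome that is
#' missing not at random (MNAR): a Monte Carlo bias analysis built on NARFCS
#' imputation (a pattern-mixture model with a fixed log-odds offset delta on
#' the outcome's imputation model) and a Bayesian bias analysis based on a
#' sequential selection model fitted by Metropolis-within-Gibbs sampling with
#' data augmentation. The package also provides the reference analyses and a
#' synthetic-data engine needed to validate both methods end to end.
#'
#' @keywords internal
#' @aliases mnarpba-package
"_PACKAGE"

expit <- function(x) stats::plogis(x)

## Deterministic per-task substream seed derived from a root seed.
## Keeps derived seeds positive and below 2^31 so set.seed() accepts them.
substream_seed <- function(seed, id) {
  s <- (as.numeric(seed) %% 2147483647) + 999999937 * (as.numeric(id) %% 65536) +
    7919 * as.numeric(id)
  as.integer(s %% 2147483629 + 1)
}

## Bernoulli draws via explicit uniforms. Using runif() rather than rbinom()
## makes draws at two nearby probability vectors monotone under a common
## seed, which the delta calibration's bisection relies on.
draw_bernoulli <- function(p) {
  as.numeric(stats::runif(length(p)) < p)
}

## ---- Design-matrix GLM fitting -------------------------------------------
## All imputation and Monte Carlo loops work on numeric matrices and call
## glm.fit()/lm.fit() directly; the formula interface is far too slow for
## tens of thousands of model fits.

## Logistic fit on a design matrix (first column must be the intercept).
## Falls back to a ridge-penalised IRLS when the ML fit is degenerate
## (separation, singular design): coefficients stay finite and the loop
## carries on, with a warning.
fit_logistic_matrix <- function(X, y, ridge_fallback = TRUE, ridge = 1e-4,
                                offset = NULL) {
  if (is.null(offset)) offset <- rep(0, length(y))
  fit <- tryCatch(irls_logistic(X, y, offset), error = function(e) NULL)
  degenerate <- is.null(fit) || !fit$converged || anyNA(fit$coef) ||
    any(abs(fit$coef) > 20)
  if (!degenerate) {
    return(list(coef = fit$coef, vcov = fit$vcov, ridged = FALSE))
  }
  if (!ridge_fallback) {
    stop("logistic fit failed (separation or singular design)")
  }
  warning("degenerate logistic fit; using ridge-penalised fallback",
          call. = FALSE)
  ridge_logistic(X, y, ridge, offset = offset)
}

## Plain Newton/IRLS logistic fit on a design matrix. Equivalent to
## glm.fit(family = binomial()) but without its per-iteration R overhead;
## convergence on the deviance to the same 1e-8 relative tolerance.
irls_logistic <- function(X, y, offset = NULL, max_iter = 50L) {
  if (is.null(offset)) offset <- rep(0, length(y))
  ## same initialisation as glm.fit: per-observation mustart, not a
  ## parameter-space start (plain Newton from an intercept-only point
  ## diverges on near-separated fits)
  mu <- (y + 0.5) / 2
  eta <- stats::qlogis(mu)
  beta <- NULL
  conv <- FALSE
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- (eta - offset) + (y - mu) / w
    Xw <- X * w
    ch <- tryCatch(chol(crossprod(X, Xw)), error = function(e) NULL)
    if (is.null(ch)) stop("singular design in logistic fit")
    beta <- drop(backsolve(ch, forwardsolve(t(ch), crossprod(Xw, z))))
    if (!all(is.finite(beta))) break
    eta <- drop(X %*% beta) + offset
    mu <- expit(eta)
    dev <- -2 * sum(y * eta - softplus_util(eta))
    if (abs(dev_old - dev) < 1e-8 * (abs(dev) + 0.1)) {
      conv <- TRUE
      break
    }
    dev_old <- dev
  }
  if (is.null(beta) || !all(is.finite(beta))) stop("logistic fit diverged")
  eta <- drop(X %*% beta) + offset
  mu <- expit(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  V <- chol2inv(chol(crossprod(X, X * w)))
  list(coef = stats::setNames(beta, colnames(X)), vcov = V, converged = conv)
}

softplus_util <- function(x) log1p(exp(pmin(x, 33))) + pmax(x - 33, 0)

## Penalised IRLS: penalty on standardised predictors, never on the intercept.
ridge_logistic <- function(X, y, ridge = 1e-4, max_iter = 50, offset = NULL) {
  if (is.null(offset)) offset <- rep(0, length(y))
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  sds[1] <- 1           # intercept
  sds[sds == 0] <- 1
  pen <- ridge / (sds^2)
  pen[1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta - offset + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + diag(pen, p)
    beta_new <- drop(solve(A, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- expit(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  A <- crossprod(X * sqrt(w)) + diag(pen, p)
  V <- chol2inv(chol(A))
  list(coef = stats::setNames(beta, colnames(X)), vcov = V, ridged = TRUE)
}

## One multivariate normal draw, mean mu, covariance Sigma.
rmvnorm1 <- function(mu, Sigma) {
  p <- length(mu)
  L <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-10, p))
  })
  drop(mu + crossprod(L, stats::rnorm(p)))
}

## Bernoulli-logit log-likelihood given a linear predictor.
loglik_bernoulli <- function(y, eta) {
  sum(y * eta - log1p(exp(pmin(eta, 700))))
}

## Quantile convention used for every interval in the package: linear
## interpolation between order statistics (R's default type 7).
interval_quantiles <- function(x, probs = c(0.5, 0.025, 0.975)) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}
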