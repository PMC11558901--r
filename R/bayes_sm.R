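## Bayesian bias analysis via a sequential selection model. The joint
## distribution of (W, X, Y, A1, A2, D, m_y) given Z is factorised into the
## same univariate regressions as the selection-model generator; the
## outcome-missingness component carries the bias parameter delta_sm with an
## informative (or vague) normal prior, all other coefficients get N(0, 100)
## priors and the residual variance an Inv-Gamma(0.01, 0.01) prior. The
## joint posterior over the parameters and the missing values of Y, X, W, D
## is sampled by Metropolis-within-Gibbs: adaptive random-walk proposals for
## the coefficient blocks (scales tuned to a 20-40% acceptance rate during
## burn-in and frozen afterwards, keeping the post-burn-in chain Markovian),
## a conjugate draw for the residual variance, exact Bernoulli full
## conditionals for missing binary values, and a Metropolis step for the
## missing continuous exposure.

#' Priors for the Bayesian selection model
#'
#' @param delta_mean,delta_variance Normal prior for the bias parameter
#'   `delta_sm` (the difference in the log-odds of observing `Y` between
#'   records with `Y = 1` and `Y = 0`). A zero variance fixes `delta_sm`.
#' @param coef_variance Variance of the mean-zero normal prior on every
#'   other regression coefficient (default 100, vague).
#' @param xi2_shape,xi2_rate Inverse-gamma prior for the residual variance
#'   of the exposure model (default Inv-Gamma(0.01, 0.01)).
#' @return An object of class `sm_priors`.
#' @export
sm_priors <- function(delta_mean = 0, delta_variance = 100,
                      coef_variance = 100, xi2_shape = 0.01, xi2_rate = 0.01) {
  stopifnot(is.finite(delta_mean), is.finite(delta_variance),
            delta_variance >= 0, coef_variance > 0, xi2_shape > 0,
            xi2_rate > 0)
  structure(list(delta_mean = delta_mean, delta_variance = delta_variance,
                 coef_variance = coef_variance, xi2_shape = xi2_shape,
                 xi2_rate = xi2_rate),
            class = "sm_priors")
}

## Component design layouts (response column, predictor columns).
sm_component_layout <- function() {
  list(
    eta   = list(response = "W",  predictors = c("Z1", "Z2", "Z3")),
    zeta  = list(response = "X",  predictors = c("W", "Z1", "Z2", "Z3")),
    beta  = list(response = "Y",  predictors = c("X", "W", "Z1", "Z2", "Z3")),
    theta_a1 = list(response = "A1",
                    predictors = c("Y", "X", "W", "Z1", "Z2", "Z3")),
    theta_a2 = list(response = "A2",
                    predictors = c("Y", "X", "W", "Z1", "Z2", "Z3")),
    omega = list(response = "D",
                 predictors = c("A1", "A2", "Y", "X", "W", "Z1", "Z2", "Z3")),
    psi   = list(response = "m_y", predictors = c("D", "A1", "A2", "X"))
  )
}

softplus <- function(x) log1p(exp(pmin(x, 33))) + pmax(x - 33, 0)

## Linear predictors of every component given current columns and params.
sm_lp <- function(cols, par, component) {
  with(cols, switch(component,
    eta  = par$eta[1] + par$eta[2] * Z1 + par$eta[3] * Z2 + par$eta[4] * Z3,
    zeta = par$zeta[1] + par$zeta[2] * W + par$zeta[3] * Z1 +
      par$zeta[4] * Z2 + par$zeta[5] * Z3,
    beta = par$beta[1] + par$beta[2] * X + par$beta[3] * W +
      par$beta[4] * Z1 + par$beta[5] * Z2 + par$beta[6] * Z3,
    theta_a1 = par$theta_a1[1] + par$theta_a1[2] * Y + par$theta_a1[3] * X +
      par$theta_a1[4] * W + par$theta_a1[5] * Z1 + par$theta_a1[6] * Z2 +
      par$theta_a1[7] * Z3,
    theta_a2 = par$theta_a2[1] + par$theta_a2[2] * Y + par$theta_a2[3] * X +
      par$theta_a2[4] * W + par$theta_a2[5] * Z1 + par$theta_a2[6] * Z2 +
      par$theta_a2[7] * Z3,
    omega = par$omega[1] + par$omega[2] * A1 + par$omega[3] * A2 +
      par$omega[4] * Y + par$omega[5] * X + par$omega[6] * W +
      par$omega[7] * Z1 + par$omega[8] * Z2 + par$omega[9] * Z3,
    psi = par$psi[1] + par$psi[2] * D + par$psi[3] * A1 + par$psi[4] * A2 +
      par$psi[5] * X - par$delta_sm * Y
  ))
}

sm_component_loglik <- function(cols, par, component) {
  lp <- sm_lp(cols, par, component)
  resp <- switch(component, eta = cols$W, zeta = cols$X, beta = cols$Y,
                 theta_a1 = cols$A1, theta_a2 = cols$A2, omega = cols$D,
                 psi = cols$m_y)
  if (component == "zeta") {
    sum(stats::dnorm(resp, lp, sqrt(par$xi2), log = TRUE))
  } else {
    sum(resp * lp - softplus(lp))
  }
}

#' Log joint density of the sequential selection model
#'
#' Sum of the component log-likelihoods (Bernoulli-logit terms for the
#' binary components, normal terms for the exposure model) over a completed
#' dataset, plus the log prior densities of all parameters. Used by the
#' sampler and available directly for checking.
#'
#' @param params Named list with elements `eta` (4), `zeta` (5), `xi2`,
#'   `beta` (6), `theta_a1` (7), `theta_a2` (7), `omega` (9), `psi` (5) and
#'   `delta_sm` — the layout of [sm_component_layout()].
#' @param completed_data A data.frame with complete columns
#'   `Y, X, Z1, Z2, Z3, W, A1, A2, D, m_y`.
#' @param priors An [sm_priors()] object.
#' @return The scalar log joint density (log-likelihood plus log priors).
#' @export
sm_log_joint <- function(params, completed_data, priors) {
  cols <- as.list(completed_data[c("Y", "X", "Z1", "Z2", "Z3", "W", "A1",
                                   "A2", "D", "m_y")])
  if (anyNA(as.data.frame(cols))) stop("completed_data must have no missing values")
  all_par <- unlist(params[c("eta", "zeta", "beta", "theta_a1", "theta_a2",
                             "omega", "psi", "delta_sm", "xi2")])
  if (!all(is.finite(all_par))) stop("non-finite parameter value")
  ll <- sum(vapply(names(sm_component_layout()), function(cmp) {
    sm_component_loglik(cols, params, cmp)
  }, 0))
  coefs <- unlist(params[c("eta", "zeta", "beta", "theta_a1", "theta_a2",
                           "omega", "psi")])
  lp <- sum(stats::dnorm(coefs, 0, sqrt(priors$coef_variance), log = TRUE))
  lp <- lp + stats::dgamma(1 / params$xi2, shape = priors$xi2_shape,
                           rate = priors$xi2_rate, log = TRUE) -
    2 * log(params$xi2)
  if (priors$delta_variance > 0) {
    lp <- lp + stats::dnorm(params$delta_sm, priors$delta_mean,
                            sqrt(priors$delta_variance), log = TRUE)
  }
  ll + lp
}

## ---- sampler ---------------------------------------------------------------

#' Fit the Bayesian selection model by MCMC
#'
#' Metropolis-within-Gibbs sampling of the joint posterior over the
#' selection-model parameters, the bias parameter `delta_sm`, and the
#' missing values of `Y`, `X`, `W` and `D`. Missing binary values are drawn
#' exactly from their Bernoulli full conditionals (the product of every
#' component likelihood term they enter); the missing continuous exposure
#' uses a Metropolis step. Continuous variables are standardised to their
#' observed mean and standard deviation before sampling, so coefficients are
#' reported on the standardised scale (in the package's generator `X` is
#' already standard normal, making the scales essentially identical).
#'
#' @param obs An `observed_dataset`.
#' @param priors An [sm_priors()] object.
#' @param n_iter Total iterations per chain.
#' @param n_burn Burn-in iterations (adaptation happens only here).
#' @param chains Number of chains (2 or more recommended for diagnostics).
#' @param seed Integer root seed; chains use independent substreams.
#' @param standardize Standardise `X` and `Z2` to observed mean 0, SD 1.
#' @return An object of class `sm_mcmc`: list with `chains` (one
#'   iterations-by-parameters matrix per chain, including burn-in),
#'   `n_iter`, `n_burn`, `acceptance` (per chain, per block),
#'   `failed_chains` (indices of chains that broke down numerically, marked
#'   rather than raised), `param_names`, `priors`, `seed`.
#' @export
run_bayes_sm <- function(obs, priors = sm_priors(), n_iter = 5000,
                         n_burn = 1000, chains = 2, seed = 1L,
                         standardize = TRUE) {
  stopifnot(n_iter > n_burn, n_burn >= 1, chains >= 1)
  d <- as.data.frame(obs)
  needed <- c("Y", "X", "Z1", "Z2", "Z3", "W", "A1", "A2", "D", "m_y")
  stopifnot(all(needed %in% names(d)))
  if (standardize) {
    for (v in c("X", "Z2")) {
      mu <- mean(d[[v]], na.rm = TRUE); sdv <- stats::sd(d[[v]], na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) stop("cannot standardise ", v)
      d[[v]] <- (d[[v]] - mu) / sdv
    }
  }
  miss <- lapply(c(Y = "Y", X = "X", W = "W", D = "D"),
                 function(v) which(is.na(d[[v]])))
  chain_results <- vector("list", chains)
  failed <- integer(0)
  for (ch in seq_len(chains)) {
    res <- tryCatch(
      sm_run_one_chain(d, miss, priors, n_iter, n_burn,
                       chain_seed = substream_seed(seed, 7000 + ch)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, ch)
      chain_results[[ch]] <- NULL
      message("run_bayes_sm: chain ", ch, " failed (",
              conditionMessage(res), ") and is marked nonconvergent")
    } else {
      chain_results[[ch]] <- res
    }
  }
  ok <- which(!seq_len(chains) %in% failed)
  if (!length(ok)) {
    return(structure(list(chains = list(), n_iter = n_iter, n_burn = n_burn,
                          acceptance = list(), failed_chains = failed,
                          param_names = character(0), priors = priors,
                          seed = seed, converged = FALSE),
                     class = "sm_mcmc"))
  }
  structure(list(
    chains = lapply(chain_results[ok], `[[`, "trace"),
    n_iter = n_iter, n_burn = n_burn,
    acceptance = lapply(chain_results[ok], `[[`, "acceptance"),
    failed_chains = failed,
    param_names = colnames(chain_results[[ok[1]]]$trace),
    priors = priors, seed = seed, converged = NA
  ), class = "sm_mcmc")
}

sm_run_one_chain <- function(d, miss, priors, n_iter, n_burn, chain_seed) {
  set.seed(chain_seed)
  n <- nrow(d)
  cols <- as.list(d[c("Y", "X", "Z1", "Z2", "Z3", "W", "A1", "A2", "D", "m_y")])
  ## initial fill: draw from the observed values of each variable
  for (v in names(miss)) {
    rows <- miss[[v]]
    if (length(rows)) {
      pool <- cols[[v]][-rows]
      cols[[v]][rows] <- sample(pool, length(rows), replace = TRUE)
    }
  }
  layout <- sm_component_layout()
  fixed_delta <- priors$delta_variance == 0
  ## the bias parameter starts at its prior mean (jittered): the filled-in
  ## outcomes are far too crude to give it a useful likelihood-based start
  delta_init <- priors$delta_mean +
    (!fixed_delta) * stats::rnorm(1, 0, 0.3 * sqrt(min(priors$delta_variance, 4)))
  ## maximum-likelihood starts and proposal shapes on the filled data
  par <- list(xi2 = 1, delta_sm = delta_init)
  prop <- list()
  for (cmp in names(layout)) {
    lay <- layout[[cmp]]
    Xd <- cbind(1, do.call(cbind, cols[lay$predictors]))
    resp <- cols[[lay$response]]
    if (cmp == "zeta") {
      f <- stats::lm.fit(Xd, resp)
      co <- f$coefficients
      sig2 <- sum(f$residuals^2) / (n - ncol(Xd))
      V <- chol2inv(chol(crossprod(Xd))) * sig2
      par$xi2 <- sig2
    } else {
      off <- if (cmp == "psi") -delta_init * cols$Y else NULL
      fl <- suppressWarnings(fit_logistic_matrix(Xd, resp, offset = off))
      co <- fl$coef; V <- fl$vcov
      if (fl$ridged || any(abs(co) > 20) || any(!is.finite(diag(V))) ||
          any(diag(V) > 25)) {
        ## degenerate fit on the crude initial fill: start from a neutral
        ## point with a conservative proposal shape instead of an
        ## astronomical jittered MLE the chain could never walk back from
        co <- c(stats::qlogis(pmin(pmax(mean(resp), 0.001), 0.999)),
                numeric(ncol(Xd) - 1))
        V <- 4 * chol2inv(chol(crossprod(Xd) + diag(1e-6, ncol(Xd))))
      }
    }
    ## overdispersed jittered start
    co <- co + stats::rnorm(length(co), 0, pmin(0.5 * sqrt(pmax(diag(V), 1e-8)), 1))
    par[[cmp]] <- unname(co)
    prop[[cmp]] <- list(L = chol(V + diag(1e-8, ncol(V))),
                        scale = 2.38 / sqrt(ncol(V)))
  }
  x_step <- 0.8 * sqrt(par$xi2)
  delta_step <- if (fixed_delta) 0 else max(0.3, 0.5 * sqrt(min(priors$delta_variance, 9)))

  param_names <- c(
    paste0("eta_", c("0", "Z1", "Z2", "Z3")),
    paste0("zeta_", c("0", "W", "Z1", "Z2", "Z3")), "xi2",
    paste0("beta_", c("0", "X", "W", "Z1", "Z2", "Z3")),
    paste0("theta_a1_", c("0", "Y", "X", "W", "Z1", "Z2", "Z3")),
    paste0("theta_a2_", c("0", "Y", "X", "W", "Z1", "Z2", "Z3")),
    paste0("omega_", c("0", "A1", "A2", "Y", "X", "W", "Z1", "Z2", "Z3")),
    paste0("psi_", c("0", "D", "A1", "A2", "X")), "delta_sm"
  )
  trace <- matrix(NA_real_, n_iter, length(param_names),
                  dimnames = list(NULL, param_names))
  acc <- stats::setNames(numeric(length(layout) + 2),
                         c(names(layout), "delta", "x_aug"))
  tries <- acc
  win_acc <- acc; win_tries <- acc

  logprior_coef <- function(b) sum(stats::dnorm(b, 0, sqrt(priors$coef_variance),
                                                log = TRUE))
  for (it in seq_len(n_iter)) {
    ## --- coefficient blocks (random-walk Metropolis) ---
    for (cmp in names(layout)) {
      if (cmp == "zeta") {
        cur <- par$zeta
        ll_cur <- sm_component_loglik(cols, par, "zeta")
        prps <- prop$zeta
        cand <- drop(cur + prps$scale * crossprod(prps$L, stats::rnorm(5)))
        par_cand <- par; par_cand$zeta <- cand
        ll_cand <- sm_component_loglik(cols, par_cand, "zeta")
        lr <- ll_cand + logprior_coef(cand) - ll_cur - logprior_coef(cur)
      } else {
        cur <- par[[cmp]]
        ll_cur <- sm_component_loglik(cols, par, cmp)
        prps <- prop[[cmp]]
        cand <- drop(cur + prps$scale *
                       crossprod(prps$L, stats::rnorm(length(cur))))
        par_cand <- par; par_cand[[cmp]] <- cand
        ll_cand <- sm_component_loglik(cols, par_cand, cmp)
        lr <- ll_cand + logprior_coef(cand) - ll_cur - logprior_coef(cur)
      }
      tries[cmp] <- tries[cmp] + 1; win_tries[cmp] <- win_tries[cmp] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        par <- par_cand
        acc[cmp] <- acc[cmp] + 1; win_acc[cmp] <- win_acc[cmp] + 1
      }
    }
    ## --- bias parameter: dedicated scalar random-walk update ---
    if (!fixed_delta) {
      ll_cur <- sm_component_loglik(cols, par, "psi")
      cand <- par$delta_sm + delta_step * stats::rnorm(1)
      par_cand <- par; par_cand$delta_sm <- cand
      ll_cand <- sm_component_loglik(cols, par_cand, "psi")
      lr <- ll_cand - ll_cur +
        stats::dnorm(cand, priors$delta_mean, sqrt(priors$delta_variance),
                     log = TRUE) -
        stats::dnorm(par$delta_sm, priors$delta_mean,
                     sqrt(priors$delta_variance), log = TRUE)
      tries["delta"] <- tries["delta"] + 1
      win_tries["delta"] <- win_tries["delta"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        par <- par_cand
        acc["delta"] <- acc["delta"] + 1; win_acc["delta"] <- win_acc["delta"] + 1
      }
    }
    ## --- residual variance: conjugate inverse-gamma draw ---
    lpx <- sm_lp(cols, par, "zeta")
    rss <- sum((cols$X - lpx)^2)
    par$xi2 <- 1 / stats::rgamma(1, shape = priors$xi2_shape + n / 2,
                                 rate = priors$xi2_rate + rss / 2)

    ## --- data augmentation ---
    cols <- sm_augment_binary(cols, par, miss$Y, "Y")
    if (length(miss$X)) {
      res_x <- sm_augment_x(cols, par, miss$X, x_step)
      cols <- res_x$cols
      tries["x_aug"] <- tries["x_aug"] + 1
      win_tries["x_aug"] <- win_tries["x_aug"] + 1
      acc["x_aug"] <- acc["x_aug"] + res_x$acc_rate
      win_acc["x_aug"] <- win_acc["x_aug"] + res_x$acc_rate
    }
    cols <- sm_augment_binary(cols, par, miss$W, "W")
    cols <- sm_augment_binary(cols, par, miss$D, "D")

    ## --- adapt proposal scales during burn-in only ---
    if (it <= n_burn && it %% 50 == 0) {
      for (cmp in names(layout)) {
        rate <- win_acc[cmp] / max(win_tries[cmp], 1)
        prop[[cmp]]$scale <- prop[[cmp]]$scale * exp(1.2 * (rate - 0.28))
      }
      if (win_tries["x_aug"] > 0) {
        rate <- win_acc["x_aug"] / win_tries["x_aug"]
        x_step <- x_step * exp(1.2 * (rate - 0.35))
      }
      if (!fixed_delta && win_tries["delta"] > 0) {
        rate <- win_acc["delta"] / win_tries["delta"]
        delta_step <- delta_step * exp(1.2 * (rate - 0.35))
      }
      win_acc[] <- 0; win_tries[] <- 0
    }
    trace[it, ] <- c(par$eta, par$zeta, par$xi2, par$beta, par$theta_a1,
                     par$theta_a2, par$omega, par$psi, par$delta_sm)
  }
  if (!all(is.finite(trace[n_iter, ]))) stop("chain diverged to non-finite values")
  list(trace = trace, acceptance = acc / pmax(tries, 1))
}

## Bernoulli full-conditional draw for a missing binary variable: the
## conditional log-odds are the variable's own model log-odds plus, for each
## downstream component it enters, the likelihood-ratio contribution of
## flipping it from 0 to 1 with everything else held fixed.
sm_augment_binary <- function(cols, par, rows, var) {
  if (!length(rows)) return(cols)
  contrib <- function(coef_v, lp_full, resp) {
    v <- cols[[var]][rows]
    base <- lp_full[rows] - coef_v * v
    resp[rows] * coef_v - (softplus(base + coef_v) - softplus(base))
  }
  if (var == "Y") {
    lo <- sm_lp(cols, par, "beta")[rows]
    lo <- lo + contrib(par$theta_a1[2], sm_lp(cols, par, "theta_a1"), cols$A1)
    lo <- lo + contrib(par$theta_a2[2], sm_lp(cols, par, "theta_a2"), cols$A2)
    lo <- lo + contrib(par$omega[4], sm_lp(cols, par, "omega"), cols$D)
    lo <- lo + contrib(-par$delta_sm, sm_lp(cols, par, "psi"), cols$m_y)
  } else if (var == "W") {
    lo <- sm_lp(cols, par, "eta")[rows]
    ## linear X-model: normal likelihood ratio for W = 1 vs W = 0
    lpx <- sm_lp(cols, par, "zeta")
    base <- lpx[rows] - par$zeta[2] * cols$W[rows]
    xr <- cols$X[rows]
    lo <- lo + (-(xr - base - par$zeta[2])^2 + (xr - base)^2) / (2 * par$xi2)
    lo <- lo + contrib(par$beta[3], sm_lp(cols, par, "beta"), cols$Y)
    lo <- lo + contrib(par$theta_a1[4], sm_lp(cols, par, "theta_a1"), cols$A1)
    lo <- lo + contrib(par$theta_a2[4], sm_lp(cols, par, "theta_a2"), cols$A2)
    lo <- lo + contrib(par$omega[6], sm_lp(cols, par, "omega"), cols$D)
  } else if (var == "D") {
    lo <- sm_lp(cols, par, "omega")[rows]
    lo <- lo + contrib(par$psi[2], sm_lp(cols, par, "psi"), cols$m_y)
  } else {
    stop("unknown augmented variable ", var)
  }
  cols[[var]][rows] <- draw_bernoulli(expit(lo))
  cols
}

## Metropolis update of the missing continuous exposure values.
sm_augment_x <- function(cols, par, rows, step) {
  logtarget <- function(xv) {
    cl <- cols; cl$X[rows] <- xv
    lp_beta <- sm_lp(cl, par, "beta")[rows]
    lp_a1 <- sm_lp(cl, par, "theta_a1")[rows]
    lp_a2 <- sm_lp(cl, par, "theta_a2")[rows]
    lp_d <- sm_lp(cl, par, "omega")[rows]
    lp_m <- sm_lp(cl, par, "psi")[rows]
    lp_x <- sm_lp(cl, par, "zeta")[rows]
    -(xv - lp_x)^2 / (2 * par$xi2) +
      cl$Y[rows] * lp_beta - softplus(lp_beta) +
      cl$A1[rows] * lp_a1 - softplus(lp_a1) +
      cl$A2[rows] * lp_a2 - softplus(lp_a2) +
      cl$D[rows] * lp_d - softplus(lp_d) +
      cl$m_y[rows] * lp_m - softplus(lp_m)
  }
  x_cur <- cols$X[rows]
  x_new <- x_cur + step * stats::rnorm(length(rows))
  lr <- logtarget(x_new) - logtarget(x_cur)
  accept <- log(stats::runif(length(rows))) < lr
  x_cur[accept] <- x_new[accept]
  cols$X[rows] <- x_cur
  list(cols = cols, acc_rate = mean(accept))
}

## ---- diagnostics and summaries ---------------------------------------------

#' Convergence diagnostics for the selection-model chains
#'
#' Split-R-hat and a (Geyer initial-positive-sequence) effective sample size
#' for the requested parameters, computed on the post-burn-in draws. The
#' default verdict requires R-hat below `rhat_max` and ESS above `ess_min`
#' for every parameter checked. Constant (degenerate) traces give an
#' undefined R-hat and are flagged, not silently passed; with a single chain
#' the diagnostics are computed on its two halves and flagged as limited.
#'
#' @param fit An `sm_mcmc` object with at least one chain.
#' @param parameters Parameter names to check (default the exposure effect
#'   and the bias parameter).
#' @param rhat_max,ess_min Thresholds for the pass verdict.
#' @return A list with `table` (one row per parameter: `rhat`, `ess`,
#'   `pass`), `pass` (overall), and `notes`.
#' @export
check_convergence <- function(fit, parameters = c("beta_X", "delta_sm"),
                              rhat_max = 1.05, ess_min = 200) {
  stopifnot(inherits(fit, "sm_mcmc"))
  if (!length(fit$chains)) {
    return(list(table = NULL, pass = FALSE, notes = "no surviving chains"))
  }
  notes <- character(0)
  if (length(fit$chains) < 2) {
    notes <- c(notes, "single chain: diagnostics based on split halves only")
  }
  post <- lapply(fit$chains, function(m)
    m[(fit$n_burn + 1):fit$n_iter, parameters, drop = FALSE])
  rows <- lapply(parameters, function(p) {
    draws <- lapply(post, function(m) m[, p])
    rh <- split_rhat(draws)
    es <- ess_geyer(draws)
    degenerate <- !is.finite(rh)
    data.frame(parameter = p, rhat = rh, ess = es,
               pass = is.finite(rh) && rh < rhat_max && es > ess_min)
  })
  tab <- do.call(rbind, rows)
  if (any(!is.finite(tab$rhat))) {
    notes <- c(notes, "degenerate (constant) trace: R-hat undefined, flagged as fail")
  }
  list(table = tab, pass = all(tab$pass), notes = notes)
}

## Split-R-hat over a list of equal-length chains.
split_rhat <- function(draws) {
  halves <- unlist(lapply(draws, function(x) {
    h <- floor(length(x) / 2)
    list(x[1:h], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## Effective sample size with Geyer's initial positive sequence truncation,
## averaged autocovariances across chains.
ess_geyer <- function(draws) {
  n <- length(draws[[1]]); m <- length(draws)
  max_lag <- min(n - 1, 500)
  acov <- rep(0, max_lag + 1)
  for (x in draws) {
    xc <- x - mean(x)
    for (l in 0:max_lag) {
      acov[l + 1] <- acov[l + 1] + sum(xc[1:(n - l)] * xc[(1 + l):n]) / n
    }
  }
  acov <- acov / m
  if (acov[1] <= 0) return(NA_real_)
  rho <- acov / acov[1]
  ## sum consecutive pairs while they stay positive
  s <- 0; l <- 1
  while (l + 1 <= max_lag) {
    pair <- rho[l + 1] + rho[l + 2]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    l <- l + 2
  }
  m * n / (1 + 2 * s)
}

#' Summarise the posterior of one parameter
#'
#' Pools the post-burn-in draws of all chains and reports the median and
#' 2.5th/97.5th percentiles under the package's single quantile convention
#' (linear interpolation between order statistics).
#'
#' @param fit An `sm_mcmc` object.
#' @param parameter Parameter name (see `fit$param_names`).
#' @return Named numeric vector `(median, p2.5, p97.5)`.
#' @export
summarize_posterior <- function(fit, parameter) {
  stopifnot(inherits(fit, "sm_mcmc"))
  if (!length(fit$chains)) stop("no surviving chains to summarise")
  if (!parameter %in% fit$param_names) {
    stop("unknown parameter: ", parameter)
  }
  draws <- unlist(lapply(fit$chains, function(m)
    m[(fit$n_burn + 1):fit$n_iter, parameter]))
  if (!length(draws)) stop("empty trace")
  stats::setNames(interval_quantiles(draws), c("median", "p2.5", "p97.5"))
}

#' @export
print.sm_mcmc <- function(x, ...) {
  cat(sprintf("Bayesian selection model: %d chain(s) x %d iterations (%d burn-in)\n",
              length(x$chains), x$n_iter, x$n_burn))
  if (length(x$failed_chains)) {
    cat("  failed chains:", paste(x$failed_chains, collapse = ", "), "\n")
  }
  if (length(x$chains)) {
    bx <- summarize_posterior(x, "beta_X")
    ds <- summarize_posterior(x, "delta_sm")
    cat(sprintf("  beta_X   median %.4f [%.4f, %.4f]\n", bx[1], bx[2], bx[3]))
    cat(sprintf("  delta_sm median %.4f [%.4f, %.4f]\n", ds[1], ds[2], ds[3]))
  }
  invisible(x)
}
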