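## independent brute-force evaluation of the selection-model log joint:
## row-by-row density products, written without reusing package internals
brute_force_log_joint <- function(par, d, priors) {
  ll <- 0
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    lpW <- sum(par$eta * c(1, r$Z1, r$Z2, r$Z3))
    lpX <- sum(par$zeta * c(1, r$W, r$Z1, r$Z2, r$Z3))
    lpY <- sum(par$beta * c(1, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpA1 <- sum(par$theta_a1 * c(1, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpA2 <- sum(par$theta_a2 * c(1, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpD <- sum(par$omega * c(1, r$A1, r$A2, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpM <- sum(par$psi * c(1, r$D, r$A1, r$A2, r$X)) - par$delta_sm * r$Y
    ll <- ll +
      dbinom(r$W, 1, plogis(lpW), log = TRUE) +
      dnorm(r$X, lpX, sqrt(par$xi2), log = TRUE) +
      dbinom(r$Y, 1, plogis(lpY), log = TRUE) +
      dbinom(r$A1, 1, plogis(lpA1), log = TRUE) +
      dbinom(r$A2, 1, plogis(lpA2), log = TRUE) +
      dbinom(r$D, 1, plogis(lpD), log = TRUE) +
      dbinom(r$m_y, 1, plogis(lpM), log = TRUE)
  }
  coefs <- c(par$eta, par$zeta, par$beta, par$theta_a1, par$theta_a2,
             par$omega, par$psi)
  lp <- sum(dnorm(coefs, 0, sqrt(priors$coef_variance), log = TRUE)) +
    dgamma(1 / par$xi2, priors$xi2_shape, rate = priors$xi2_rate, log = TRUE) -
    2 * log(par$xi2) +
    dnorm(par$delta_sm, priors$delta_mean, sqrt(priors$delta_variance),
          log = TRUE)
  ll + lp
}

toy_sm_params <- function(seed = 1) {
  set.seed(seed)
  list(eta = rnorm(4, 0, 0.5), zeta = rnorm(5, 0, 0.5), xi2 = 1.3,
       beta = rnorm(6, 0, 0.5), theta_a1 = rnorm(7, 0, 0.5),
       theta_a2 = rnorm(7, 0, 0.5), omega = rnorm(9, 0, 0.5),
       psi = rnorm(5, 0, 0.5), delta_sm = 2.2)
}

test_that("the log joint equals a brute-force row-by-row evaluation", {
  d <- generate_sm_complete(20, demo_params(), seed = 90)
  par <- toy_sm_params()
  priors <- sm_priors(1, 4)
  expect_equal(sm_log_joint(par, d, priors),
               brute_force_log_joint(par, d, priors), tolerance = 1e-10)

  ## all-zero single row with all-zero coefficients: six Bernoulli-logit
  ## components each contribute log(0.5)
  row0 <- data.frame(Y = 0, X = 0, Z1 = 0, Z2 = 0, Z3 = 0, W = 0, A1 = 0,
                     A2 = 0, D = 0, m_y = 0)
  par0 <- list(eta = rep(0, 4), zeta = rep(0, 5), xi2 = 1, beta = rep(0, 6),
               theta_a1 = rep(0, 7), theta_a2 = rep(0, 7), omega = rep(0, 9),
               psi = rep(0, 5), delta_sm = 0)
  ## isolate the likelihood by differencing out the (data-free) prior part
  ll0 <- sm_log_joint(par0, row0, priors) -
    sm_log_joint(par0, row0[c(), ], priors)
  expect_equal(ll0, 6 * log(0.5) + dnorm(0, 0, 1, log = TRUE),
               tolerance = 1e-10)

  ## i.i.d. additivity: doubling the data doubles the likelihood part
  d2 <- rbind(d, d)
  ll_d <- sm_log_joint(par, d, priors) - sm_log_joint(par, d[c(), ], priors)
  ll_d2 <- sm_log_joint(par, d2, priors) - sm_log_joint(par, d2[c(), ], priors)
  expect_equal(ll_d2, 2 * ll_d, tolerance = 1e-8)

  expect_error(sm_log_joint(modifyList(par, list(delta_sm = NaN)), d, priors),
               "finite")
})

test_that("a zero-variance prior keeps the bias parameter fixed", {
  d <- generate_sm_complete(400, demo_params(), seed = 91)
  obs <- apply_missingness(d, seed = 92)
  fit <- suppressWarnings(
    run_bayes_sm(obs, priors = sm_priors(7.85, 0), n_iter = 200, n_burn = 50,
                 chains = 1, seed = 93))
  tr <- fit$chains[[1]][, "delta_sm"]
  expect_true(all(tr == 7.85))
})

test_that("with complete data the posterior concentrates on the MLE", {
  d <- generate_sm_complete(1500, demo_params(), seed = 94)
  d$m_x <- d$m_w <- d$m_d <- 0
  fit <- suppressWarnings(
    run_bayes_sm(d, priors = sm_priors(0, 100), n_iter = 1500, n_burn = 500,
                 chains = 2, seed = 95))
  expect_length(fit$chains, 2)
  post <- do.call(rbind, lapply(fit$chains, function(m) m[501:1500, ]))
  mle <- fit_substantive(d)
  expect_lt(abs(mean(post[, "beta_X"]) - mle$estimate),
            2 * sd(post[, "beta_X"]))
  ## exposure-model components against their own MLE fits
  fx <- lm(X ~ W + Z1 + Z2 + Z3, data = d)
  expect_lt(abs(mean(post[, "zeta_W"]) - coef(fx)["W"]),
            2 * sd(post[, "zeta_W"]))
  expect_lt(abs(mean(post[, "xi2"]) - summary(fx)$sigma^2),
            3 * sd(post[, "xi2"]))
  ## acceptance rates in the adaptive target range
  accs <- fit$acceptance[[1]][names(fit$acceptance[[1]]) != "x_aug"]
  expect_true(all(accs[accs > 0] > 0.1 & accs[accs > 0] < 0.6))
})

test_that("binary augmentation matches brute-force enumeration", {
  ## three-variable toy check of the Y full conditional: fixed parameters,
  ## one missing Y, compare draw frequency with the enumerated conditional
  par <- toy_sm_params(2)
  cols <- list(Y = 0.0, X = 0.4, Z1 = 1, Z2 = -0.3, Z3 = 0, W = 1,
               A1 = 1, A2 = 0, D = 1, m_y = 1)
  ## enumerate p(Y = y | rest) over y in {0, 1}
  dens <- sapply(c(0, 1), function(y) {
    r <- modifyList(cols, list(Y = y))
    lpY <- sum(par$beta * c(1, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpA1 <- sum(par$theta_a1 * c(1, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpA2 <- sum(par$theta_a2 * c(1, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpD <- sum(par$omega * c(1, r$A1, r$A2, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpM <- sum(par$psi * c(1, r$D, r$A1, r$A2, r$X)) - par$delta_sm * r$Y
    dbinom(r$Y, 1, plogis(lpY)) * dbinom(r$A1, 1, plogis(lpA1)) *
      dbinom(r$A2, 1, plogis(lpA2)) * dbinom(r$D, 1, plogis(lpD)) *
      dbinom(r$m_y, 1, plogis(lpM))
  })
  p1 <- dens[2] / sum(dens)
  vec_cols <- lapply(cols, rep, 400)
  set.seed(96)
  freq <- mean(replicate(50, {
    out <- mnarpba:::sm_augment_binary(vec_cols, par, seq_len(400), "Y")
    mean(out$Y)
  }))
  expect_lt(abs(freq - p1), 3 * sqrt(p1 * (1 - p1) / (400 * 50)))

  ## same for a missing D value
  densD <- sapply(c(0, 1), function(dv) {
    r <- modifyList(cols, list(D = dv))
    lpD <- sum(par$omega * c(1, r$A1, r$A2, r$Y, r$X, r$W, r$Z1, r$Z2, r$Z3))
    lpM <- sum(par$psi * c(1, r$D, r$A1, r$A2, r$X)) - par$delta_sm * r$Y
    dbinom(r$D, 1, plogis(lpD)) * dbinom(r$m_y, 1, plogis(lpM))
  })
  p1D <- densD[2] / sum(densD)
  set.seed(97)
  freqD <- mean(replicate(50, {
    out <- mnarpba:::sm_augment_binary(vec_cols, par, seq_len(400), "D")
    mean(out$D)
  }))
  expect_lt(abs(freqD - p1D), 3 * sqrt(p1D * (1 - p1D) / (400 * 50)))
})

test_that("convergence diagnostics flag degenerate and short runs", {
  const_fit <- structure(list(
    chains = list(matrix(1, 200, 2, dimnames = list(NULL, c("beta_X", "delta_sm"))),
                  matrix(1, 200, 2, dimnames = list(NULL, c("beta_X", "delta_sm")))),
    n_iter = 200, n_burn = 50, param_names = c("beta_X", "delta_sm")),
    class = "sm_mcmc")
  cc <- check_convergence(const_fit)
  expect_false(cc$pass)
  expect_true(any(grepl("degenerate", cc$notes)))

  d <- generate_sm_complete(600, demo_params(), seed = 98)
  obs <- apply_missingness(d, seed = 99)
  short <- suppressWarnings(
    run_bayes_sm(obs, priors = sm_priors(0, 100), n_iter = 60, n_burn = 10,
                 chains = 2, seed = 100))
  expect_false(check_convergence(short)$pass)
})

test_that("well-mixing chains pass diagnostics; R-hat agrees with coda", {
  d <- generate_sm_complete(1200, demo_params(), seed = 101)
  d$m_x <- d$m_w <- d$m_d <- 0
  fit <- suppressWarnings(
    run_bayes_sm(d, priors = sm_priors(7.85, 1), n_iter = 2200, n_burn = 600,
                 chains = 2, seed = 102))
  cc <- check_convergence(fit, parameters = "beta_X", ess_min = 100)
  expect_lt(cc$table$rhat[1], 1.05)
  expect_gt(cc$table$ess[1], 100)

  draws <- lapply(fit$chains, function(m) m[601:2200, "beta_X"])
  rh_coda <- coda::gelman.diag(coda::mcmc.list(lapply(draws, coda::mcmc)),
                               autoburnin = FALSE)$psrf[1]
  expect_lt(abs(mnarpba:::split_rhat(draws) - rh_coda), 0.05)
})

test_that("posterior summaries share the package quantile convention", {
  tr <- matrix(1:100, 100, 2, dimnames = list(NULL, c("beta_X", "delta_sm")))
  fake <- structure(list(chains = list(tr), n_iter = 100, n_burn = 0,
                         param_names = c("beta_X", "delta_sm")),
                    class = "sm_mcmc")
  q <- summarize_posterior(fake, "beta_X")
  expect_equal(unname(q), unname(summarize_mc(as.numeric(1:100))))
  const <- structure(list(chains = list(matrix(2.5, 50, 1,
                            dimnames = list(NULL, "beta_X"))),
                          n_iter = 50, n_burn = 0, param_names = "beta_X"),
                     class = "sm_mcmc")
  expect_equal(unname(summarize_posterior(const, "beta_X")), rep(2.5, 3))
  expect_error(summarize_posterior(fake, "nope"), "unknown parameter")
})
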