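test_that("the substantive fit matches an independent likelihood maximiser", {
  ## toy table large enough for the maximum-likelihood estimate to exist
  d <- generate_sm_complete(150, demo_params(), seed = 110)
  f <- fit_substantive(d)
  ## brute-force oracle: BFGS on a hand-written negative log-likelihood
  X <- cbind(1, d$X, d$Z1, d$Z2, d$Z3, d$W)
  nll <- function(b) {
    lp <- drop(X %*% b)
    -sum(d$Y * lp - log1p(exp(lp)))
  }
  opt <- optim(rep(0, 6), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(f$estimate - opt$par[2]), 1e-3)

  ## fully balanced factorial design: exact null association
  g <- expand.grid(Y = 0:1, X = 0:1, Z1 = 0:1, Z2 = 0:1, Z3 = 0:1, W = 0:1)
  f0 <- fit_substantive(g)
  expect_lt(abs(f0$estimate), 1e-8)
  expect_true(f0$ci_low < 0 && f0$ci_high > 0)

  ## consistency on a large generated sample
  fbig <- fit_substantive(big_sm()[1:3e5, ])
  expect_lt(abs(fbig$estimate - log(3)), 3 * fbig$se)
  expect_error(fit_substantive(within(d, Y[1] <- NA)), "complete")
})

test_that("complete case analysis equals the full fit without missingness and is MCAR-valid", {
  d <- generate_sm_complete(20000, demo_params(), seed = 111)
  d_obs <- d; d_obs$m_x <- d_obs$m_w <- d_obs$m_d <- 0
  full <- fit_substantive(d)
  cca0 <- run_cca(d_obs)
  expect_equal(cca0$estimate, full$estimate, tolerance = 1e-12)
  expect_identical(cca0$n_used, nrow(d))

  ## MCAR mask independent of everything
  set.seed(112)
  mcar <- d
  mcar$Y[runif(nrow(d)) < 0.5] <- NA
  class(mcar) <- c("observed_dataset", "data.frame")
  cca_mcar <- run_cca(mcar)
  expect_lt(abs(cca_mcar$estimate - full$estimate),
            3 * sqrt(cca_mcar$se^2 + full$se^2))
})

test_that("under the MNAR generator CCA underestimates and the population comparison overshoots it", {
  d <- generate_sm_complete(2e5, demo_params(), seed = 113)
  obs <- apply_missingness(d, seed = 114)
  cca <- run_cca(obs)
  expect_lt(cca$estimate + 3 * cca$se, log(3))   # systematic underestimate

  pop <- run_population_comparison(obs)
  expect_gt(pop$fit$estimate, cca$estimate)
  expect_equal(pop$implied_prevalence,
               sum(obs$Y == 1, na.rm = TRUE) / nrow(obs))
  expect_lt(pop$implied_prevalence, mean(d$Y))  # misses the unobserved cases

  ## on data without missing outcomes the population comparison is the full fit
  d2 <- d[1:5000, ]; d2$m_y <- 0
  pop2 <- run_population_comparison(d2)
  expect_equal(pop2$fit$estimate, fit_substantive(d2)$estimate,
               tolerance = 1e-12)
  expect_equal(pop2$implied_prevalence, mean(d2$Y))
})

test_that("MAR multiple imputation is valid under a MAR outcome mechanism", {
  p <- demo_params()
  d <- generate_sm_complete(20000, p, seed = 115)
  ## impose MAR-only missingness of Y driven by fully observed Z and A
  set.seed(116)
  p_mis <- plogis(1.2 + 0.5 * d$Z1 + 0.4 * d$A1 + 0.3 * d$A2)
  obs <- d
  obs$m_y <- as.numeric(runif(nrow(d)) < p_mis)
  obs$Y[obs$m_y == 1] <- NA
  obs$m_x <- obs$m_w <- obs$m_d <- 0
  class(obs) <- c("observed_dataset", "data.frame")
  pooled <- run_mi_mar(obs, M = 10, seed = 117)
  expect_lt(abs(pooled$estimate - log(3)), 3 * pooled$se)
  expect_gt(pooled$between_variance, 0)
})

test_that("auxiliaries amplify MAR-MI bias beyond CCA under the MNAR generator", {
  p <- demo_params()
  bias <- sapply(1:3, function(r) {
    d <- generate_sm_complete(50000, p, seed = 200 + r)
    obs <- apply_missingness(d, seed = 300 + r)
    c(cca = run_cca(obs)$estimate - log(3),
      mi = run_mi_mar(obs, M = 10, seed = 400 + r)$estimate - log(3))
  })
  ## both underestimate; imputing with outcome-predictive auxiliaries under
  ## a wrong MAR assumption pushes the estimate further from the truth
  expect_true(all(bias < 0))
  expect_gt(mean(abs(bias["mi", ])), mean(abs(bias["cca", ])))
})

test_that("MAR MI equals delta-0 NARFCS pooling under matched seeds", {
  obs <- obs_small()
  mi <- run_mi_mar(obs, M = 4, seed = 118)
  imps <- run_fcs(obs, specs = default_imputation_specs(mnar = TRUE),
                  delta = 0, n_burn = 10, K = 4, seed = 118)
  fits <- lapply(imps, fit_substantive)
  pooled <- rubin_pool(vapply(fits, `[[`, 0, "estimate"),
                       vapply(fits, `[[`, 0, "se")^2,
                       n_obs = nrow(obs), n_params = 6)
  expect_equal(mi$estimate, pooled$estimate, tolerance = 1e-12)
  expect_equal(mi$total_variance, pooled$total_variance, tolerance = 1e-12)
})
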