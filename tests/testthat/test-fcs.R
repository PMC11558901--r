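test_that("linear parameter draws follow the exact posterior", {
  set.seed(1)
  n <- 10000
  dat <- data.frame(y = rnorm(n, 3, 1), x1 = rnorm(n))
  spec <- imputation_spec("y", "linear", predictors = "x1")
  set.seed(2)
  draw <- draw_model_params(dat, spec)
  expect_s3_class(draw, "param_draw")
  expect_lt(abs(draw$coefficients[1] - 3), 0.1)
  expect_gt(draw$residual_variance, 0)

  ## sampling-distribution oracle: empirical covariance of repeated draws
  ## matches (X'X)^{-1} * sigma2
  X <- cbind(1, dat$x1)
  s2_hat <- sum(lm.fit(X, dat$y)$residuals^2) / (n - 2)
  target <- chol2inv(chol(crossprod(X))) * s2_hat
  set.seed(3)
  draws <- t(replicate(10000,
                       draw_model_params(dat, spec)$coefficients))
  emp <- cov(draws)
  expect_lt(abs(emp[1, 1] / target[1, 1] - 1), 0.1)
  expect_lt(abs(emp[2, 2] / target[2, 2] - 1), 0.1)
})

test_that("degenerate logistic targets fall back to a ridge draw", {
  set.seed(4)
  dat <- data.frame(y = rep(0, 60), x1 = rnorm(60))
  spec <- imputation_spec("y", "logistic", predictors = "x1")
  expect_warning(draw <- draw_model_params(dat, spec), "ridge")
  expect_true(all(is.finite(draw$coefficients)))
  expect_error(suppressWarnings(
    draw_model_params(dat[1:3, ], spec)), "too few")
})

test_that("the delta offset acts only on rows being imputed, monotonically", {
  set.seed(5)
  n <- 2000
  dat <- data.frame(y = rbinom(n, 1, 0.4), x1 = rnorm(n),
                    m_y = rep(c(0, 1), n / 2))
  spec <- imputation_spec("y", "logistic", predictors = "x1",
                          offset_var = "m_y")
  rows <- which(dat$m_y == 1)
  draw <- structure(list(coefficients = c(`(Intercept)` = 0, x1 = 0.5),
                         residual_variance = NULL, method = "fixed"),
                    class = "param_draw")
  ## saturated negative offset forces all-zero imputations
  col <- impute_variable(dat, spec, draw, delta = -20, rows = rows)
  expect_true(all(col[rows] == 0))
  expect_equal(col[-rows], as.numeric(dat$y[-rows]))

  ## monotonicity of the imputed prevalence in delta (fixed draw)
  set.seed(6); p2 <- mean(impute_variable(dat, spec, draw, delta = 2,
                                          rows = rows)[rows])
  set.seed(6); p0 <- mean(impute_variable(dat, spec, draw, delta = 0,
                                          rows = rows)[rows])
  expect_gt(p2, p0)

  ## delta = 0 reduces to offset-free imputation under a matched RNG state
  spec_mar <- imputation_spec("y", "logistic", predictors = "x1")
  set.seed(7); c1 <- impute_variable(dat, spec, draw, delta = 0, rows = rows)
  set.seed(7); c2 <- impute_variable(dat, spec_mar, draw, delta = 0,
                                     rows = rows)
  expect_identical(c1, c2)
  expect_error(impute_variable(dat, spec_mar, draw, delta = 1, rows = rows),
               "offset")
})

test_that("run_fcs returns identical copies when nothing is missing", {
  d <- generate_sm_complete(500, demo_params(), seed = 51)
  d$m_x <- d$m_w <- d$m_d <- 0
  imps <- run_fcs(d, delta = -5, K = 3, seed = 8)
  expect_length(imps, 3)
  for (im in imps) expect_identical(im$Y, d$Y)
})

test_that("delta = 0 NARFCS reproduces MAR FCS bit-exactly under matched seeds", {
  obs <- obs_small()
  narfcs <- run_fcs(obs, specs = default_imputation_specs(mnar = TRUE),
                    delta = 0, n_burn = 5, K = 2, seed = 9)
  marfcs <- run_fcs(obs, specs = default_imputation_specs(mnar = FALSE),
                    delta = 0, n_burn = 5, K = 2, seed = 9)
  expect_identical(narfcs[[1]], marfcs[[1]])
  expect_identical(narfcs[[2]], marfcs[[2]])
})

test_that("imputation preserves observed values and binary ranges", {
  obs <- obs_small()
  imps <- run_fcs(obs, delta = -6, K = 2, seed = 10)
  for (im in imps) {
    expect_false(anyNA(im[c("Y", "X", "W", "D")]))
    obs_rows <- which(obs$m_y == 0)
    expect_identical(im$Y[obs_rows], obs$Y[obs_rows])
    expect_identical(im$X[obs$m_x == 0], obs$X[obs$m_x == 0])
    expect_true(all(im$Y %in% c(0, 1)))
    expect_true(all(im$W %in% c(0, 1)))
    expect_identical(im$m_y, obs$m_y)
  }
  ## seed reproducibility of whole runs
  expect_identical(run_fcs(obs, delta = -6, K = 2, seed = 10), imps)
})

test_that("visit order changes results only stochastically", {
  obs <- obs_small()
  tr <- truth_sm()
  pool_at <- function(order) {
    imps <- run_fcs(obs, delta = tr$delta_narfcs, K = 8, seed = 11,
                    visit_order = order)
    fits <- lapply(imps, fit_substantive)
    rubin_pool(vapply(fits, `[[`, 0, "estimate"),
               vapply(fits, `[[`, 0, "se")^2, n_obs = nrow(obs), n_params = 6)
  }
  p1 <- pool_at(c("X", "W", "D", "Y"))
  p2 <- pool_at(c("Y", "D", "W", "X"))
  expect_gt(p1$between_variance, 0)  # parameter-draw uncertainty propagates
  expect_gt(p2$between_variance, 0)
  expect_lt(abs(p1$estimate - p2$estimate), 3 * sqrt(p1$total_variance))
})
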