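## Pattern-mixture data-generating mechanism ---------------------------------
##
## The same joint distribution as the selection-model generator, factorised
## the other way round: the fully observed variables and the outcome
## missingness indicator come first, and the outcome is generated last,
## conditional on its own missingness indicator. The coefficient on m_y in
## the Y-model is the pattern-mixture bias parameter delta_narfcs (the
## difference in the log-odds of Y = 1 between records with missing and
## observed Y, conditional on the other predictors). The factorisation
## mirrors the NARFCS bias model. No closed form links the two coefficient
## sets, so the pattern-mixture parameters are obtained by fitting each
## component regression to a large sample generated under the
## selection-model mechanism.

pmm_components <- function() {
  list(
    z1  = list(kind = "bernoulli", predictors = character(0)),
    z2  = list(kind = "linear",   predictors = "Z1"),
    z3  = list(kind = "logistic", predictors = c("Z1", "Z2")),
    a1  = list(kind = "logistic", predictors = c("Z1", "Z2", "Z3")),
    a2  = list(kind = "logistic", predictors = c("Z1", "Z2", "Z3", "A1")),
    m_y = list(kind = "logistic", predictors = c("Z1", "Z2", "Z3", "A1", "A2")),
    w   = list(kind = "logistic",
               predictors = c("Z1", "Z2", "Z3", "A1", "A2", "m_y")),
    x   = list(kind = "linear",
               predictors = c("Z1", "Z2", "Z3", "A1", "A2", "m_y", "W")),
    d   = list(kind = "logistic",
               predictors = c("Z1", "Z2", "Z3", "A1", "A2", "m_y", "W", "X")),
    y   = list(kind = "logistic",
               predictors = c("Z1", "Z2", "Z3", "A1", "A2", "W", "X", "D", "m_y"))
  )
}

pmm_response_column <- c(z1 = "Z1", z2 = "Z2", z3 = "Z3", a1 = "A1",
                         a2 = "A2", m_y = "m_y", w = "W", x = "X", d = "D",
                         y = "Y")

#' Fit the pattern-mixture data-generating model to a large complete sample
#'
#' Fits each univariate regression of the pattern-mixture factorisation
#' (fully observed variables and the outcome-missingness indicator first,
#' then `W`, `X`, `D`, and finally `Y` given `m_y`) by maximum likelihood to
#' a complete dataset, normally one generated under the selection-model
#' mechanism. The fitted coefficient on `m_y` in the `Y`-model is the
#' pattern-mixture bias parameter `delta_narfcs`.
#'
#' @param big A complete dataset from [generate_sm_complete()]. The paper-
#'   faithful procedure uses 50,000,000 rows; a few million already give
#'   stable coefficients and are the practical default at desk scale.
#' @return An object of class `pmm_dgm_params`: per-component coefficient
#'   vectors, residual variances for the linear components, the bias
#'   parameter `delta_narfcs` with its standard error, and the fit sample
#'   size.
#' @export
fit_pmm_params <- function(big) {
  needed <- c("Y", "X", "Z1", "Z2", "Z3", "W", "A1", "A2", "D", "m_y")
  stopifnot(all(needed %in% names(big)))
  comps <- pmm_components()
  n <- nrow(big)
  fits <- list()
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    yv <- big[[pmm_response_column[[nm]]]]
    if (cmp$kind == "bernoulli") {
      fits[[nm]] <- list(kind = "bernoulli", p = mean(yv))
      next
    }
    X <- cbind(`(Intercept)` = rep(1, n))
    for (pv in cmp$predictors) X <- cbind(X, big[[pv]])
    colnames(X) <- c("(Intercept)", cmp$predictors)
    if (cmp$kind == "linear") {
      f <- stats::lm.fit(X, yv)
      sigma2 <- sum(f$residuals^2) / (n - ncol(X))
      fits[[nm]] <- list(kind = "linear",
                         coef = stats::setNames(f$coefficients, colnames(X)),
                         sigma2 = sigma2)
    } else {
      f <- tryCatch(irls_logistic(X, yv), error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        stop("pattern-mixture component fit did not converge: ", nm)
      }
      fits[[nm]] <- list(kind = "logistic",
                         coef = f$coef,
                         se = stats::setNames(sqrt(diag(f$vcov)), colnames(X)))
    }
  }
  structure(
    list(components = fits,
         delta_narfcs = unname(fits$y$coef["m_y"]),
         se_delta_narfcs = unname(fits$y$se["m_y"]),
         eps2 = fits$x$sigma2,
         n_fit = n),
    class = "pmm_dgm_params"
  )
}

#' Generate complete data under the pattern-mixture mechanism
#'
#' Sequential generation in the pattern-mixture order: exogenous and fully
#' observed variables first, then the outcome-missingness indicator, then
#' `W`, `X`, `D`, and finally `Y` conditional on `m_y` through the
#' `delta_narfcs` coefficient. Reproducible given `seed`.
#'
#' @param n Number of records.
#' @param params A `pmm_dgm_params` object from [fit_pmm_params()].
#' @param seed Integer seed.
#' @return A `data.frame` with the same columns as
#'   [generate_sm_complete()] and attribute `dgm = "pmm"`.
#' @export
generate_pmm_complete <- function(n, params, seed) {
  stopifnot(n >= 1, inherits(params, "pmm_dgm_params"))
  if (!is.finite(params$eps2) || params$eps2 <= 0) {
    stop("residual variance of the X component must be positive")
  }
  set.seed(seed)
  comps <- pmm_components()
  cols <- list()
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    fit <- params$components[[nm]]
    if (fit$kind == "bernoulli") {
      val <- draw_bernoulli(rep(fit$p, n))
    } else {
      lp <- rep(fit$coef[1], n)
      for (pv in cmp$predictors) lp <- lp + fit$coef[[pv]] * cols[[pv]]
      val <- if (fit$kind == "linear") {
        lp + stats::rnorm(n, sd = sqrt(fit$sigma2))
      } else {
        draw_bernoulli(expit(lp))
      }
    }
    cols[[pmm_response_column[[nm]]]] <- val
  }
  out <- as.data.frame(cols)[c("Y", "X", "Z1", "Z2", "Z3", "W", "A1", "A2",
                               "D", "m_y")]
  attr(out, "dgm") <- "pmm"
  out
}

#' Derive true target values for performance evaluation
#'
#' Computes the "truth" against which simulation-study estimates are judged.
#' Under the selection-model mechanism, the true exposure effect and
#' selection-model bias parameter are parameters of the generator and are
#' passed through; the pattern-mixture bias parameter `delta_narfcs` is not
#' a parameter of that mechanism, so it is estimated by fitting the NARFCS
#' outcome model (including the covariate missingness indicators) to a large
#' complete sample before any deletion. Under the pattern-mixture mechanism
#' the roles are reversed: `delta_narfcs` is a parameter, and the exposure
#' effect is estimated by fitting the substantive model to a large complete
#' sample before data deletion.
#'
#' @param dgm_kind `"sm"` or `"pmm"`.
#' @param params `sm_dgm_params` or `pmm_dgm_params`, matching `dgm_kind`.
#' @param n_truth Size of the large evaluation sample. Default 5,000,000 at
#'   desk scale (a message notes the Monte Carlo error this carries);
#'   50,000,000 matches the original procedure.
#' @param seed Integer seed.
#' @param mech `mar_mechanism` used to generate the covariate missingness
#'   indicators entering the NARFCS outcome model.
#' @return An object of class `truth_values`: list with `beta_x`,
#'   `delta_narfcs`, `delta_sm`, their provenance (`"parameter"` or
#'   `"large-sample estimate"`), `se_delta_narfcs`, and `n_truth`.
#' @export
derive_truth <- function(dgm_kind = c("sm", "pmm"), params, n_truth = 5e6,
                         seed = 1L, mech = mar_mechanism_default()) {
  dgm_kind <- match.arg(dgm_kind)
  if (n_truth < 5e7) {
    message("derive_truth: using n_truth = ", format(n_truth, big.mark = ","),
            "; estimated truth values carry Monte Carlo error of order 1/sqrt(n)")
  }
  if (dgm_kind == "sm") {
    stopifnot(inherits(params, "sm_dgm_params"))
    big <- generate_sm_complete(n_truth, params, seed = seed)
    masked <- apply_missingness(big, mech = mech,
                                seed = substream_seed(seed, 1L))
    X <- cbind(1, big$X, big$W, big$D, big$A1, big$A2, big$Z1, big$Z2, big$Z3,
               masked$m_y, masked$m_x, masked$m_w, masked$m_d)
    colnames(X) <- c("(Intercept)", "X", "W", "D", "A1", "A2", "Z1", "Z2",
                     "Z3", "m_y", "m_x", "m_w", "m_d")
    f <- fit_logistic_matrix(X, big$Y, ridge_fallback = FALSE)
    structure(list(
      beta_x = params$beta_x,
      delta_narfcs = unname(f$coef["m_y"]),
      delta_sm = params$delta_sm,
      provenance = c(beta_x = "parameter",
                     delta_narfcs = "large-sample estimate",
                     delta_sm = "parameter"),
      se_delta_narfcs = sqrt(V_entry(f$vcov, X, "m_y")),
      n_truth = n_truth
    ), class = "truth_values")
  } else {
    stopifnot(inherits(params, "pmm_dgm_params"))
    big <- generate_pmm_complete(n_truth, params, seed = seed)
    X <- cbind(1, big$X, big$Z1, big$Z2, big$Z3, big$W)
    colnames(X) <- c("(Intercept)", "X", "Z1", "Z2", "Z3", "W")
    f <- fit_logistic_matrix(X, big$Y, ridge_fallback = FALSE)
    Xm <- cbind(1, big$D, big$A1, big$A2, big$X, big$Y)
    colnames(Xm) <- c("(Intercept)", "D", "A1", "A2", "X", "Y")
    fm <- fit_logistic_matrix(Xm, big$m_y, ridge_fallback = FALSE)
    structure(list(
      beta_x = unname(f$coef["X"]),
      delta_narfcs = params$delta_narfcs,
      delta_sm = -unname(fm$coef["Y"]),
      provenance = c(beta_x = "large-sample estimate",
                     delta_narfcs = "parameter",
                     delta_sm = "large-sample estimate"),
      se_delta_narfcs = params$se_delta_narfcs,
      n_truth = n_truth
    ), class = "truth_values")
  }
}

V_entry <- function(V, X, name) {
  i <- match(name, colnames(X))
  V[i, i]
}
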