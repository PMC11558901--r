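#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `K` per-imputation estimates and variances: pooled estimate is
#' the mean; within-imputation variance `W` is the mean of the variances;
#' between-imputation variance `B` is the sample variance of the estimates;
#' total variance `T = W + (1 + 1/K) B`. Degrees of freedom use the
#' Barnard-Rubin small-sample formula with complete-data degrees of freedom
#' `n_obs - n_params` (appropriate when the sample is large but `K` may be
#' small); the classical large-K rule is available via `df_rule`. With
#' `K = 1` the estimate and variance pass through unchanged and the degrees
#' of freedom are infinite — the single-imputation setting in which
#' between-imputation uncertainty must be carried elsewhere (e.g. by a
#' Monte Carlo loop around the imputation).
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard
#'   errors (same length, all positive).
#' @param n_obs Number of observations in the analysis model (used for the
#'   Barnard-Rubin complete-data degrees of freedom).
#' @param n_params Number of parameters of the analysis model.
#' @param df_rule `"barnard-rubin"` (default) or `"rubin"` (1987 rule).
#' @return An object of class `pooled_estimate`: list with `estimate`,
#'   `total_variance`, `within_variance`, `between_variance`, `df`, `K`,
#'   `se`, and a 95% t interval (`ci_low`, `ci_high`).
#' @export
rubin_pool <- function(estimates, variances, n_obs,
                       n_params = 1, df_rule = c("barnard-rubin", "rubin")) {
  df_rule <- match.arg(df_rule)
  K <- length(estimates)
  if (length(variances) != K) stop("estimates and variances differ in length")
  if (K < 1) stop("at least one imputation is required")
  if (any(!is.finite(estimates)) || any(!is.finite(variances)) ||
      any(variances <= 0)) {
    stop("estimates must be finite and variances positive")
  }
  if (K == 1) {
    est <- estimates[1]; Tvar <- variances[1]
    out <- list(estimate = est, total_variance = Tvar,
                within_variance = Tvar, between_variance = 0,
                df = Inf, K = 1L, se = sqrt(Tvar),
                ci_low = est - stats::qnorm(0.975) * sqrt(Tvar),
                ci_high = est + stats::qnorm(0.975) * sqrt(Tvar))
    return(structure(out, class = "pooled_estimate"))
  }
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tvar <- W + (1 + 1 / K) * B
  if (B <= 0) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / K) * B / Tvar
    df_old <- (K - 1) / lambda^2
    if (df_rule == "rubin") {
      df <- df_old
    } else {
      df_com <- max(n_obs - n_params, 1)
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- 1 / (1 / df_old + 1 / df_obs)
    }
  }
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(estimate = qbar, total_variance = Tvar, within_variance = W,
                 between_variance = B, df = df, K = K, se = sqrt(Tvar),
                 ci_low = qbar - tcrit * sqrt(Tvar),
                 ci_high = qbar + tcrit * sqrt(Tvar)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate over %d imputation(s): %.4f (SE %.4f, df %s)\n",
    x$K, x$estimate, x$se, format(round(x$df, 1))))
  cat(sprintf("  95%% CI [%.4f, %.4f]; W = %.5f, B = %.5f, T = %.5f\n",
              x$ci_low, x$ci_high, x$within_variance, x$between_variance,
              x$total_variance))
  invisible(x)
}
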