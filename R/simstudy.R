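## Simulation-study engine: replicate generation, method application, and
## performance summarisation with Monte Carlo uncertainty. Replicates use
## independent seed substreams indexed by replicate id, so any subset can be
## reproduced independently of execution order.

#' Configure a simulation study
#'
#' @param dgm `"sm"` or `"pmm"` data-generating mechanism.
#' @param beta_x True exposure effect scenario (conventionally `log(3)` or
#'   `0`).
#' @param n Observations per simulated dataset.
#' @param n_replicates Number of simulated datasets (at least 2).
#' @param methods Character vector from `"full"`, `"cca"`, `"mi"`,
#'   `"popcomp"`, `"mcnarfcs"`, `"bayes_sm"`.
#' @param seed Root seed.
#' @param params Optional `sm_dgm_params`; default [sm_params_demo()] at the
#'   requested `beta_x` with `delta_sm`.
#' @param delta_sm Bias parameter of the generator (default 7.85, a very
#'   strong MNAR mechanism).
#' @param mech Covariate [mar_mechanism()].
#' @param method_args Per-method settings: `mi = list(M, n_burn)`,
#'   `mcnarfcs = list(prior, S, K, n_burn)`,
#'   `bayes_sm = list(prior, n_sub, n_iter, n_burn, chains)`. `prior` may be
#'   a [bias_prior()] or one of `"vague"`, `"informative"`,
#'   `"very informative"` — the presets N(0,100), N(truth,4), N(truth,1),
#'   resolved against the derived truth. `n_sub` caps the rows given to the
#'   Bayesian analysis (it is far more expensive than the other methods).
#' @param truth Optional precomputed `truth_values`; derived (at `n_truth`)
#'   when absent.
#' @param n_truth Sample size for [derive_truth()] when `truth` is absent.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dgm = c("sm", "pmm"), beta_x = log(3), n = 1e5,
                       n_replicates = 500,
                       methods = c("full", "cca"), seed = 1L,
                       params = NULL, delta_sm = 7.85,
                       mech = mar_mechanism_default(),
                       method_args = list(), truth = NULL, n_truth = 2e6) {
  dgm <- match.arg(dgm)
  stopifnot(n_replicates >= 2)
  known <- c("full", "cca", "mi", "popcomp", "mcnarfcs", "bayes_sm")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  }
  defaults <- list(
    mi = list(M = 50, n_burn = 10),
    mcnarfcs = list(prior = "informative", S = 200, K = 1, n_burn = 10),
    bayes_sm = list(prior = "informative", n_sub = 5000, n_iter = 5000,
                    n_burn = 1000, chains = 2)
  )
  for (m in names(defaults)) {
    method_args[[m]] <- utils::modifyList(defaults[[m]],
                                          method_args[[m]] %||% list())
  }
  if (is.null(params)) params <- sm_params_demo(beta_x, delta_sm = delta_sm)
  structure(list(dgm = dgm, beta_x = beta_x, n = n,
                 n_replicates = n_replicates, methods = methods, seed = seed,
                 params = params, mech = mech, method_args = method_args,
                 truth = truth, n_truth = n_truth),
            class = "sim_config")
}

resolve_prior <- function(spec, truth_value) {
  if (inherits(spec, "bias_prior")) return(spec)
  switch(spec,
         "vague" = bias_prior_vague(),
         "informative" = bias_prior_informative(truth_value),
         "very informative" = bias_prior_very_informative(truth_value),
         stop("unknown prior preset: ", spec))
}

## Generator + truth resolution shared by run_replicate and run_study.
resolve_study_inputs <- function(config) {
  if (config$dgm == "sm") {
    gen_params <- config$params
    truth <- config$truth
    if (is.null(truth)) {
      need_truth <- any(c("mcnarfcs", "bayes_sm") %in% config$methods)
      truth <- if (need_truth) {
        derive_truth("sm", gen_params, n_truth = config$n_truth,
                     seed = substream_seed(config$seed, 55001L),
                     mech = config$mech)
      } else {
        structure(list(beta_x = gen_params$beta_x, delta_narfcs = NA_real_,
                       delta_sm = gen_params$delta_sm,
                       provenance = c(beta_x = "parameter",
                                      delta_narfcs = "not derived",
                                      delta_sm = "parameter"),
                       n_truth = NA_real_),
                  class = "truth_values")
      }
    }
    list(gen = function(n, seed) generate_sm_complete(n, gen_params, seed),
         truth = truth)
  } else {
    big <- generate_sm_complete(config$n_truth, config$params,
                                seed = substream_seed(config$seed, 55002L))
    pmm <- fit_pmm_params(big)
    truth <- config$truth
    if (is.null(truth)) {
      truth <- derive_truth("pmm", pmm, n_truth = config$n_truth,
                            seed = substream_seed(config$seed, 55003L),
                            mech = config$mech)
    }
    list(gen = function(n, seed) generate_pmm_complete(n, pmm, seed),
         truth = truth)
  }
}

#' Run one simulation replicate
#'
#' Generates a complete dataset from the configured mechanism, imposes the
#' missingness, applies every configured method, and returns one row per
#' method. Method failures are recorded in the `converged` column rather
#' than aborting the study. Running the same `rep_id` twice gives identical
#' rows.
#'
#' @param config A [sim_config()].
#' @param rep_id Replicate index (drives the seed substream).
#' @param inputs Optional precomputed [resolve_study_inputs()] result;
#'   `run_study()` passes this to avoid re-deriving the truth per replicate.
#' @return A data.frame with columns
#'   `rep, method, estimate, se, low, high, converged`.
#' @export
run_replicate <- function(config, rep_id, inputs = NULL) {
  if (is.null(inputs)) inputs <- resolve_study_inputs(config)
  seed_rep <- substream_seed(config$seed, rep_id)
  complete <- inputs$gen(config$n, seed_rep)
  obs <- apply_missingness(complete, mech = config$mech,
                           seed = substream_seed(seed_rep, 2L))
  truth <- inputs$truth
  rows <- lapply(config$methods, function(m) {
    out <- data.frame(rep = rep_id, method = m, estimate = NA_real_,
                      se = NA_real_, low = NA_real_, high = NA_real_,
                      converged = FALSE)
    res <- tryCatch({
      if (m == "full") {
        f <- fit_substantive(complete, method = "full")
        c(f$estimate, f$se, f$ci_low, f$ci_high)
      } else if (m == "cca") {
        f <- run_cca(obs)
        c(f$estimate, f$se, f$ci_low, f$ci_high)
      } else if (m == "popcomp") {
        f <- run_population_comparison(obs)$fit
        c(f$estimate, f$se, f$ci_low, f$ci_high)
      } else if (m == "mi") {
        a <- config$method_args$mi
        p <- run_mi_mar(obs, M = a$M, n_burn = a$n_burn,
                        seed = substream_seed(seed_rep, 3L))
        c(p$estimate, p$se, p$ci_low, p$ci_high)
      } else if (m == "mcnarfcs") {
        a <- config$method_args$mcnarfcs
        prior <- resolve_prior(a$prior, truth$delta_narfcs)
        r <- run_mc_pba(obs, prior, S = a$S, K = a$K,
                        seed = substream_seed(seed_rep, 4L),
                        n_burn = a$n_burn)
        c(r$point, NA, r$ci_low, r$ci_high)
      } else if (m == "bayes_sm") {
        a <- config$method_args$bayes_sm
        prior <- resolve_prior(a$prior, truth$delta_sm)
        sub <- as.data.frame(obs)[seq_len(min(a$n_sub, nrow(obs))), ]
        class(sub) <- c("observed_dataset", "data.frame")
        fit <- run_bayes_sm(sub,
                            priors = sm_priors(prior$mean, prior$variance),
                            n_iter = a$n_iter, n_burn = a$n_burn,
                            chains = a$chains,
                            seed = substream_seed(seed_rep, 5L))
        if (!length(fit$chains)) stop("all chains failed")
        q <- summarize_posterior(fit, "beta_X")
        c(q[1], NA, q[2], q[3])
      }
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$estimate <- res[1]; out$se <- res[2]
      out$low <- res[3]; out$high <- res[4]
      out$converged <- TRUE
    }
    out
  })
  do.call(rbind, rows)
}

#' Summarise simulation-study performance
#'
#' Per method: bias (mean estimate minus truth), empirical standard error
#' (SD of the estimates), model-based standard error (root mean squared
#' reported SE; for interval-only methods, mean interval half-width divided
#' by 1.96), and 95% interval coverage in percent, each with its Monte Carlo
#' standard error. Non-converged replicates are excluded per method, with
#' counts reported.
#'
#' @param rows Replicate rows from [run_replicate()] / [run_study()].
#' @param truth A `truth_values` object or the true `beta_x` as a number.
#' @return A data.frame of class `performance_table`, one row per method.
#' @export
compute_performance <- function(rows, truth) {
  beta_true <- if (inherits(truth, "truth_values")) truth$beta_x else truth
  out <- lapply(split(rows, rows$method), function(d) {
    n_total <- nrow(d)
    d <- d[d$converged & is.finite(d$estimate), ]
    R <- nrow(d)
    if (R < 2) stop("need at least 2 converged replicates per method (",
                    d$method[1], ")")
    bias <- mean(d$estimate) - beta_true
    emp_se <- stats::sd(d$estimate)
    se2 <- ifelse(is.finite(d$se), d$se^2, ((d$high - d$low) / (2 * 1.96))^2)
    mod_se <- sqrt(mean(se2))
    cover <- mean(d$low <= beta_true & beta_true <= d$high)
    data.frame(
      method = d$method[1], n_converged = R, n_total = n_total,
      bias = bias, bias_mcse = emp_se / sqrt(R),
      emp_se = emp_se, emp_se_mcse = emp_se / sqrt(2 * (R - 1)),
      mod_se = mod_se, mod_se_mcse = stats::sd(se2) / (2 * mod_se * sqrt(R)),
      coverage = 100 * cover,
      coverage_mcse = 100 * sqrt(cover * (1 - cover) / R)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("performance_table", "data.frame")
  res
}

#' Run a full simulation study
#'
#' Maps [run_replicate()] over `n_replicates` independent substreams and
#' summarises with [compute_performance()].
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `performance`
#'   (a `performance_table`), `results` (the raw per-replicate rows),
#'   `truth`, `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  inputs <- resolve_study_inputs(config)
  rows <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    run_replicate(config, r, inputs = inputs)
  }))
  structure(list(performance = compute_performance(rows, inputs$truth),
                 results = rows, truth = inputs$truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulation study: %s generator, beta_X = %.4f, n = %d, %d replicates\n",
              x$config$dgm, x$truth$beta_x, x$config$n,
              x$config$n_replicates))
  print(x$performance, digits = 4)
  invisible(x)
}
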