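# mnarpba

Probabilistic bias analysis for a binary outcome that is **missing not at
random (MNAR)** — the situation where whether the outcome is recorded depends
on the outcome itself (outcome-dependent testing being the canonical
example), so that complete case analysis and ordinary multiple imputation are
both biased and no analysis of the observed data alone can fix them.

The package is aimed at epidemiologists and biostatisticians who want to
state an explicit, externally informed prior for the outcome–missingness
dependency and propagate it into the exposure-effect estimate. It provides:

* **Monte Carlo NARFCS** (`run_mc_pba()`): a Monte Carlo bias analysis built
  on the not-at-random fully conditional specification imputation model. The
  outcome's imputation model carries a fixed log-odds offset
  `delta * M^Y` — `delta` is the difference in the log-odds of `Y = 1`
  between records with missing and observed outcomes. Each Monte Carlo step
  draws `delta` from its prior `N(mu, sigma^2)`, imputes `K` times with it
  fixed, fits the substantive logistic regression
  `logit Pr(Y=1) = beta_0 + beta_X X + beta_Z Z + beta_W W`,
  pools by Rubin's rules, and adds random sampling error; the resulting
  frequency distribution of bias-adjusted estimates of `beta_X` is
  summarised by its median and 2.5th/97.5th percentiles.
* **A Bayesian selection model** (`run_bayes_sm()`): the joint distribution
  of the data and the outcome-missingness indicator is factorised into
  sequential univariate regressions ending in
  `logit Pr(M^Y=1 | D, A, Y, X) = psi_0 + psi_D D + psi_A A + psi_X X - delta_sm Y`,
  with `delta_sm` (the log-odds difference in *observing* the outcome
  between cases and non-cases) given a normal prior and everything —
  parameters and missing values of `Y, X, W, D` — sampled jointly by
  Metropolis-within-Gibbs with data augmentation. Unlike the Monte Carlo
  analysis, the likelihood can down-weight prior values of `delta_sm`
  incompatible with the data.
* The **reference analyses** (full data, complete case, MAR multiple
  imputation, population-based comparison group), **Rubin's rules** pooling
  with Barnard–Rubin degrees of freedom, a **synthetic-data generator**
  emulating a cohort with a rare outcome (5% prevalence) under a very strong
  MNAR mechanism, delta↔prevalence **calibration** (`calibrate_delta()`),
  and a **simulation-study engine** (`run_study()`) reporting bias,
  empirical and model-based standard errors and 95% coverage, each with
  Monte Carlo standard errors.

## Worked example

```r
library(mnarpba)

params   <- sm_params_demo(beta_x = log(3))            # true beta_X = 1.0986
complete <- generate_sm_complete(20000, params, seed = 1)
obs      <- apply_missingness(complete, seed = 2)      # ~84% of Y missing

fit_substantive(complete)   # what we would estimate with full data
#> full: beta_X = 1.1151 (SE 0.0415), 95% CI [1.0338, 1.1964], n = 20000
#>   odds ratio 3.050 [2.812, 3.308]

run_cca(obs)                # complete case analysis: badly attenuated
#> cca: beta_X = 0.7893 (SE 0.0540), 95% CI [0.6835, 0.8951], n = 2730
#>   odds ratio 2.202 [1.981, 2.448]

truth <- derive_truth("sm", params, n_truth = 1e6, seed = 3)
run_mc_pba(obs, bias_prior_informative(truth$delta_narfcs),
           S = 50, K = 1, seed = 4)
#> Monte Carlo NARFCS bias analysis (S = 50, K = 1, prior informative N(-7.77, 4))
#>   beta_X median 1.0811, 95% interval [0.9859, 1.2047]
```

The full-data fit recovers the generating effect (odds ratio 3). Dropping
the ~84% of records with missing outcomes attenuates the estimate to an odds
ratio of 2.2, because under this mechanism being observed is positively
related to both the outcome and the exposure. The Monte Carlo NARFCS
analysis, given an informative prior centred at the true pattern-mixture
bias parameter (−7.77 log-odds, estimated from a large pre-deletion sample),
recovers the effect; its interval is wider than the full-data interval
because it also carries the prior's uncertainty about the missingness
mechanism.

The Bayesian counterpart runs as

```r
fit <- run_bayes_sm(obs, priors = sm_priors(delta_mean = 7.85, delta_variance = 1),
                    n_iter = 5000, n_burn = 1000, chains = 2, seed = 5)
check_convergence(fit)
summarize_posterior(fit, "beta_X")
```

A thin command-line wrapper with subcommands `simulate`, `impute`, `mcpba`,
`bayes-sm`, `compare`, `simstudy` and `calibrate` is installed under
`inst/cli/mnarpba`.

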