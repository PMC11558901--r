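---
title: "Probabilistic bias analysis for an outcome missing not at random"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic bias analysis for an outcome missing not at random}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cohort study records a binary outcome $Y$ (say, infection), a continuous
exposure $X$, confounders $Z = (Z_1, Z_2, Z_3)$ and $W$, and auxiliary
variables $A = (A_1, A_2)$ and $D$ that are predictive of the outcome and of
whether it is observed. The substantive analysis is the logistic regression

$$\Pr(Y = 1 \mid X, Z, W) = \operatorname{expit}(\beta_0 + \beta_X X +
\beta_Z Z + \beta_W W),$$

and the estimand is the exposure effect $\beta_X$ on the log-odds scale.
Most outcomes are unobserved, and whether $Y$ is observed depends on $Y$
itself (outcome-dependent testing): the data are missing not at random
(MNAR). No analysis of the observed data alone can identify the
outcome–missingness dependency, so standard methods — complete case analysis
(CCA), multiple imputation assuming missing at random (MAR MI) — can be
badly biased, and the analyst must instead quantify how conclusions change
under explicit, externally informed assumptions about that dependency. That
quantification is a *bias analysis*; making the assumption probabilistic (a
prior on the bias parameter rather than a handful of fixed values) yields a
*probabilistic bias analysis*.

`mnarpba` implements two of them end to end, plus the reference analyses
and a synthetic-data engine for validating everything by simulation.

## The two bias models

**Pattern-mixture / NARFCS.** Each partially observed variable gets a
univariate imputation model on everything else, including the missingness
indicators of the other incomplete variables. The outcome model additionally
carries a fixed offset on its own indicator $M^Y$:

$$\operatorname{logit} \Pr(Y = 1 \mid \cdot) = \lambda_0 + \lambda_X X +
\dots + \delta\, M^Y,$$

so $\delta$ is the difference in the log-odds of $Y = 1$ between records
with missing and observed outcomes, conditional on the other predictors.
$\delta$ is not estimable from the data; it is fixed before each run of the
fully-conditional-specification (FCS) algorithm. The *Monte Carlo* bias
analysis wraps this in a loop: at step $s$ draw
$\delta^{(s)} \sim N(\mu, \sigma^2)$ from its prior, impute $K$ times with
$\delta^{(s)}$ fixed, fit the substantive model, pool with Rubin's rules
into $(\tilde\beta_X, \tilde V_X)$, and add random sampling error
$\hat\beta_X^{(s)} \sim N(\tilde\beta_X, \tilde V_X)$. The $S$ values of
$\hat\beta_X$ form a frequency distribution summarised by its median and
2.5th/97.5th percentiles. No draw is ever rejected or reweighted against the
data — the prior is used exactly as stated, which is both the method's
convenience and its weakness when the prior is wrong.

**Selection model, Bayesian.** The joint distribution of
$(W, X, Y, A, D, M^Y)$ given $Z$ is factorised into a sequence of univariate
regressions ending in the missingness model

$$\operatorname{logit} \Pr(M^Y = 1 \mid D, A, Y, X) = \psi_0 + \psi_D D +
\psi_A A + \psi_X X - \delta^{SM} Y,$$

where $\delta^{SM}$ is the difference in the log-odds of *observing* $Y$
between records with $Y = 1$ and $Y = 0$. (We parameterise on the observing
scale throughout: a positive $\delta^{SM}$ means cases are more likely to be
observed, the situation in testing-driven data collection.) All coefficients
get $N(0, 100)$ priors, the residual variance of the exposure model an
Inv-Gamma(0.01, 0.01) prior, and $\delta^{SM}$ its externally informed
$N(\mu^{SM}, \sigma^{SM})$ prior. Bayes' theorem combines prior and
likelihood, so values of $\delta^{SM}$ incompatible with the observed data
are down-weighted — with weak priors the data themselves can rule bias
mechanisms out, which the Monte Carlo approach cannot do.

## Sampler design

The Bayesian fit is a bespoke Metropolis-within-Gibbs sampler
(`run_bayes_sm()`); any valid MCMC targeting this posterior would do, and
the design choices here favour robustness at moderate data sizes:

* Coefficient blocks (one per component regression) use random-walk
  Metropolis proposals shaped by the inverse observed information of a
  maximum-likelihood fit at initialisation, with scalar scales adapted
  during burn-in toward a 20–40% acceptance rate and frozen afterwards, so
  the post-burn-in chain is Markovian.
* $\delta^{SM}$ gets its own scalar random-walk update. It starts at its
  prior mean: the initial fill-in of the missing outcomes is far too crude
  to give it a meaningful likelihood start, and a jittered degenerate MLE
  can place the chain on a flat plateau it never leaves. For the same reason
  any component whose initial fit is degenerate (separation on the filled
  data) starts from a neutral point with a conservative proposal shape.
* The residual variance of the exposure model has a conjugate inverse-gamma
  full conditional and is drawn exactly.
* Missing binary values ($Y$, $W$, $D$) are drawn exactly from their
  Bernoulli full conditionals — the product of every component likelihood
  term they enter; a toy-model test checks these frequencies against brute
  force enumeration. Missing values of the continuous exposure use a
  vectorised Metropolis step (the downstream logistic terms make the exact
  conditional non-standard) with its own adapted step size.
* Continuous variables are standardised to observed mean 0 and SD 1 before
  sampling (the generator already produces standard-normal exposures, so
  reported effects are per SD either way).
* A chain that collapses numerically is *marked* nonconvergent and excluded,
  never raised as an error: a simulation study must survive individual
  failures and report their count.

Convergence is judged by split-$\hat R$ < 1.05 and an effective sample size
above 200 for $\beta_X$ and $\delta^{SM}$ (`check_convergence()`; thresholds
configurable). Constant traces give an undefined $\hat R$ and are flagged
rather than passed.

## The FCS engine

`run_fcs()` follows standard chained-equations practice: initial fill by
sampling each variable's observed values with replacement; visits ordered by
increasing missingness (ties: declared order; the choice is testable —
pooled estimates agree across visit orders within Monte Carlo error);
parameter draws per univariate model from the exact normal–inverse-chi-square
posterior (linear) or the asymptotic normal approximation around the MLE
(logistic), so that imputation-model uncertainty propagates into Rubin's
between-imputation variance; ten burn-in sweeps by default. Predictors with
no variation among the fit rows (say, an indicator that never fires) are
dropped from that fit with a zero coefficient, the usual chained-equations
convention. Separation or a
singular design in a univariate fit falls back to a small ridge penalty
($10^{-4}$ on standardised predictors) with a warning — a rare small-sample
degeneracy must not kill a ten-thousand-step Monte Carlo loop. With
$\delta = 0$ the NARFCS configuration reproduces ordinary MAR FCS bit for
bit under matched seeds; that equality is a regression test.

Pooling uses Rubin's rules with Barnard–Rubin degrees of freedom (samples
here are large while $K$ may be tiny; the 1987 rule is available). With
$K = 1$ — the usual Monte Carlo setting — the estimate and variance pass
through and between-imputation uncertainty is instead carried by the Monte
Carlo loop's sampling-error step.

All intervals in the package (Monte Carlo percentiles, posterior summaries)
use one quantile convention: linear interpolation between order statistics
(R's type 7), stated explicitly because percentile rules differ across
software.

## The synthetic-data generator

`generate_sm_complete()` draws complete data sequentially —
$Z$ exogenous, $W \mid Z$, $X \mid W, Z$, $Y \mid X, W, Z$,
$A \mid Y, X, W, Z$, $D \mid A, Y, X, W, Z$, $M^Y \mid D, A, Y, X$ — with
logistic models for binary variables and normal models for continuous ones.
The shipped demo parameter set (`sm_params_demo()`, also versioned as YAML
under `inst/extdata/`) encodes the study conditions the package is validated
under:

* marginal outcome prevalence 5% in both the null ($\beta_X = 0$) and
  non-null ($\beta_X = \ln 3$) scenarios, with the intercept calibrated by
  bisection on a fixed calibration sample (common random numbers make the
  simulated prevalence monotone in the intercept, so the search always
  converges);
* exposure and the continuous confounder marginally standard normal
  (intercept and residual variance calibrated the same way);
* a very strong MNAR mechanism, $\delta^{SM} = 7.85$: about 85% of outcomes
  missing, cases almost always observed, and observation positively related
  to the exposure — which makes CCA an underestimate and gives the
  population-based comparison group its overshoot;
* auxiliary variables strongly predictive of the outcome, the configuration
  under which MAR MI amplifies rather than removes MNAR bias;
* covariate missingness of about 5% each in $X$, $W$, $D$ from logistic MAR
  models on the fully observed $(Z, A)$ (`mar_mechanism_default()`), giving
  a non-monotone overall pattern.

The pattern-mixture generator is obtained by *fitting* the reverse
factorisation (fully observed variables and $M^Y$ first; the outcome last,
given its own indicator) to a large selection-model sample
(`fit_pmm_params()`): no closed form links the two coefficient sets. The
chosen component order is $Z_1$; $Z_2 \mid Z_1$; $Z_3 \mid Z_1, Z_2$;
$A_1 \mid Z$; $A_2 \mid Z, A_1$; $M^Y \mid Z, A$; $W$; $X$; $D$;
$Y \mid Z, A, W, X, D, M^Y$ — the outcome model mirrors the NARFCS bias
model. "True" values for performance evaluation come from
`derive_truth()`: parameters are passed through where they exist
(e.g. $\beta_X$ under the selection-model generator) and estimated from a
large complete sample where they do not (the pattern-mixture
$\delta$, which is the $M^Y$ coefficient of the NARFCS outcome model fitted
before any deletion). The default evaluation sample is five million rows
(the package's tests and acceptance script use two million); at that size
the estimated $\delta$ carries a standard error of a few hundredths of a
log-odds unit, which the test tolerances reflect.

What the generator deliberately does **not** emulate: real covariate
distributions of any particular cohort (all binary background variables are
exchangeable Bernoulli draws), non-monotone missingness beyond independent
per-variable masks, measurement error, or effect heterogeneity. Passing
tests therefore demonstrate internal validity of the methods under the
declared mechanisms, not robustness to the messiness of real data.

## Reproducibility and numerics

Every top-level operation takes one integer seed; replicates, imputation
chains and Monte Carlo steps use deterministic substreams indexed by their
id, so any replicate can be reproduced alone and results do not depend on
execution order. Binary draws go through explicit uniforms, which couples
runs at different $\delta$ under a common seed — the bisection in
`calibrate_delta()` (mapping an external prevalence onto the conditional
log-odds scale of $\delta$) relies on that monotone coupling, and uses five
imputations per candidate value by default as a noise/compute compromise.
Logistic fitting uses a lean iteratively reweighted least squares routine
with `glm.fit`'s initialisation and stopping rule (the two agree to
near machine precision in tests) because fit overhead dominates the Monte
Carlo loops. Monte Carlo steps that fail are recorded with their reason and
excluded from summaries; more than 10% failures aborts the analysis.

## Scales used in validation

The simulation designs in the package's tests and acceptance script are
deliberate reductions of a full-scale study (a thousand replicates of
$n = 100{,}000$ with $S = 10{,}000$ Monte Carlo steps or 50,000 MCMC
iterations per dataset, which takes CPU-days per method): the reference
CCA/full-data study uses 500 replicates at $n = 100{,}000$; Monte Carlo
NARFCS recovery uses 100 replicates at $n = 10{,}000$ with $S = 15$ and
single imputation; Bayesian-model checks run a few thousand iterations at
$n$ between about 1,500 and 4,000. Tolerances are set from the Monte Carlo
error these sizes imply (e.g. three Monte Carlo standard errors for biases
and coverages), not from the full-scale study's.

## Known limitations

* The Monte Carlo bias analysis is only as good as its prior; with a vague
  prior it inherits the bias of MAR imputation, and only the Bayesian
  analysis can recover information about the bias parameter from the data.
* Imputation models are main-effects GLMs; no interactions, nonlinearities,
  predictive mean matching, or categorical targets beyond binary.
* Single-parameter pooling only; exposure effects are reported on the
  log-odds scale (exponentiate for odds ratios).
* The Bayesian sampler's random-walk updates mix slowly for weakly
  identified bias parameters at small $n$; diagnostics must be consulted,
  and runs flagged nonconvergent should be treated as missing results, as
  the simulation engine does.
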