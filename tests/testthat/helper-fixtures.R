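## Shared fixtures, generated once per test run and cached (the large
## selection-model sample is expensive and several files reuse it).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

demo_params <- function() cached("demo_params", sm_params_demo(log(3)))

## 1e6-row complete sample under the demo selection-model generator
big_sm <- function() {
  cached("big_sm", generate_sm_complete(1e6, demo_params(), seed = 990001))
}

## derived truth (beta_x, delta_narfcs, delta_sm) at n = 1e6
truth_sm <- function() {
  cached("truth_sm", suppressMessages(
    derive_truth("sm", demo_params(), n_truth = 1e6, seed = 990002)))
}

## a moderate observed dataset for imputation-level tests
obs_small <- function() {
  cached("obs_small", {
    d <- generate_sm_complete(8000, demo_params(), seed = 990003)
    apply_missingness(d, seed = 990004)
  })
}

## null-coefficient generator parameters (every slope 0)
null_params <- function(delta_sm = 0, psi0 = 0) {
  sm_params(beta_x = 0, beta0 = 0,
            eta = rep(0, 4), zeta = rep(0, 5), xi2 = 1,
            beta_rest = rep(0, 4), theta_a1 = rep(0, 7),
            theta_a2 = rep(0, 7), omega = rep(0, 9),
            psi = c(psi0, 0, 0, 0, 0), delta_sm = delta_sm,
            pz = c(0.5, 0.5))
}
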