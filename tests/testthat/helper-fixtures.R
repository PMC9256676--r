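# Lazily built, cached fixtures shared across test files. Everything is
# generated in code at test time; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic cohort: 3 participants per age group, 40 trials/condition
small_trials <- function() {
  fixture("small_trials", function() {
    pars <- sample_cohort_params(n_per_group = 3, seed = 101)
    simulate_experiment(pars, design = stimulus_design(n_trials = 40),
                        seed = 102)
  })
}

small_standardized <- function() {
  fixture("small_standardized", function() {
    standardize_attributes(filter_trials(small_trials())$trials)
  })
}

# quick hierarchical fit used by several formula/identity tests
small_fit <- function() {
  fixture("small_fit", function() {
    suppressWarnings(
      fit_stddm(small_standardized(), "M3",
                mcmc = mcmc_config("test", n_burn = 150L, n_keep = 150L),
                seed = 103)
    )
  })
}

# minimal stand-in fit object for functions that only consume posterior draws
fake_fit_from_mu <- function(mu_array, par_names) {
  structure(list(
    model_id = "M3", par_names = par_names,
    draws = list(mu = mu_array),
    cells = tibble::tibble(cell = 1:4,
                           age_group = rep(c("younger", "older"), each = 2),
                           condition = rep(c("aid", "control"), 2))
  ), class = "stddm_fit")
}
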