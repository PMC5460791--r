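# Shared fixtures: small synthetic cohorts and trial tables built in code.

default_params <- function() subject_params(alpha = 2, beta = 14, gamma = 2)

# small complete experiment for fitting tests; memoised per session
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- draw_population(population_params(), 6, seed = 901)
      cache <<- run_experiment(co, exp2_design(), seed = 902)
    }
    cache
  }
})

# one quick hierarchical fit shared by the method tests
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_experiment()
      cache <<- suppressWarnings(fit_effort_model(
        sim$trials, "log_difference",
        mcmc = mcmc_config(n_chains = 2, n_warmup = 200, n_samples = 200),
        seed = 903))
    }
    cache
  }
})

# hand-built trial table with known probabilities
toy_trials <- function() {
  data.frame(
    subject_id = c(1, 1, 2, 2),
    experiment = 2L, session = "none", condition_id = 1L,
    staircase_id = 1L, trial_index = 1:4,
    F_R_N = c(3, 3, 6, 6), F_T_N = c(10, 5, 9, 12),
    direction = "inward", amplitude_mm = 120,
    duration_window_ms = "800-1300", n_ref_repeats = 2L,
    choice = c("reference", "test", "reference", "reference"),
    stringsAsFactors = FALSE
  )
}
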