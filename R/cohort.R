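#' Population-level parameter distributions
#'
#' Means and standard deviations of the normal distributions from which
#' subject-level parameters are drawn. The defaults sit inside the posterior
#' credible intervals reported for real cohorts (population mean of the
#' force exponent near 2, effort offset in the 5-22 range, sensitivity in
#' the 1-4 range) and define the study conditions the simulator emulates.
#'
#' @param mu_alpha,sigma_alpha Mean and SD of the force exponent.
#' @param mu_beta,sigma_beta Mean and SD of the effort offset.
#' @param mu_gamma,sigma_gamma Mean and SD of the effort sensitivity.
#' @return An object of class `population_params`.
#' @export
population_params <- function(mu_alpha = 2.0, sigma_alpha = 0.3,
                              mu_beta = 14, sigma_beta = 5,
                              mu_gamma = 2.5, sigma_gamma = 1) {
  if (any(c(sigma_alpha, sigma_beta, sigma_gamma) <= 0))
    stop("population standard deviations must be > 0")
  structure(list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 mu_gamma = mu_gamma, sigma_gamma = sigma_gamma),
            class = "population_params")
}

# lower truncation point keeping effort positive and log-utilities finite
PARAM_LOWER <- 1e-6

# draw from N(mu, sd) truncated to (PARAM_LOWER, Inf) by inverse-CDF on the
# upper tail, which stays stable even when the truncation removes almost
# all of the mass (possible for extreme population draws)
rtruncnorm_pos <- function(n, mu, sd) {
  p_hi <- stats::pnorm(PARAM_LOWER, mu, sd, lower.tail = FALSE)
  p_hi <- pmax(p_hi, 1e-300)
  x <- stats::qnorm(stats::runif(n) * p_hi, mu, sd, lower.tail = FALSE)
  pmax(x, PARAM_LOWER)
}

#' Draw a synthetic subject cohort
#'
#' Subject parameters (alpha, beta, gamma) are drawn independently from the
#' population normals, truncated to positivity so that effort and the
#' log-based utilities are well defined. When `experiment = 1`, direction
#' cost coefficients are attached for the duration/amplitude simulator
#' (`c_in = 1`, `c_out = 1.15`: outward movements cost ~15% more).
#'
#' @param pop A [population_params()] object.
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Optional integer seed; a fixed seed reproduces the cohort.
#' @param experiment 1 or 2 (default 2, the repeated-movement design).
#' @return A data frame of class `cohort` with one row per subject.
#' @export
draw_population <- function(pop, n_subjects, seed = NULL, experiment = 2L) {
  if (!inherits(pop, "population_params")) stop("'pop' must be population_params")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cohort <- data.frame(
    subject_id = seq_len(n_subjects),
    alpha = rtruncnorm_pos(n_subjects, pop$mu_alpha, pop$sigma_alpha),
    beta  = rtruncnorm_pos(n_subjects, pop$mu_beta, pop$sigma_beta),
    gamma = rtruncnorm_pos(n_subjects, pop$mu_gamma, pop$sigma_gamma)
  )
  if (experiment == 1L) {
    cohort$c_in <- 1.0
    cohort$c_out <- 1.15
  }
  attr(cohort, "population") <- pop
  attr(cohort, "seed") <- seed
  class(cohort) <- c("cohort", class(cohort))
  cohort
}

subject_params_from_row <- function(row) {
  if (!is.null(row$c_in))
    exp1_params(row$alpha, row$beta, row$gamma, row$c_in, row$c_out)
  else
    subject_params(row$alpha, row$beta, row$gamma)
}

#' Simulate one binary choice
#'
#' Bernoulli draw with the probit [choice_probability()]; uses the current
#' RNG stream (seed upstream for reproducibility).
#'
#' @inheritParams choice_probability
#' @return `"reference"` or `"test"`.
#' @export
simulate_choice <- function(F_R, F_T, params, model = UTILITY_MODELS,
                            n_ref_repeats = 2) {
  p <- choice_probability(F_R, F_T, params, model, n_ref_repeats)
  if (stats::runif(1) < p) "reference" else "test"
}

#' Stochastic and deterministic observers for the staircase engine
#'
#' `observer_exp2()` plays the repeated-versus-single comparison with the
#' probit choice rule; `observer_exp1()` plays the duration/amplitude
#' comparison using the generative duration-integrated, direction-scaled
#' effort (test movements run opposite to the reference direction).
#' With `deterministic = TRUE` the observer picks the higher-utility action
#' by sign (ties go to the test action), i.e. the zero-noise limit.
#'
#' @param params A [subject_params()] (exp2) or [exp1_params()] (exp1)
#'   object.
#' @param model One of [UTILITY_MODELS].
#' @param deterministic Pick by sign of the utility difference instead of
#'   sampling.
#' @return A `function(condition, F_T)` suitable for
#'   [run_staircase_session()].
#' @export
observer_exp2 <- function(params, model = "log_difference",
                          deterministic = FALSE) {
  params <- as_subject_params(params)
  model <- match_utility_model(model)
  function(condition, F_T) {
    p <- choice_probability(condition$F_R, F_T, params, model,
                            condition$n_ref_repeats)
    if (deterministic) {
      if (p > 0.5) "reference" else "test"
    } else {
      if (stats::runif(1) < p) "reference" else "test"
    }
  }
}

#' @rdname observer_exp2
#' @export
observer_exp1 <- function(params, model = "log_difference",
                          deterministic = FALSE) {
  model <- match_utility_model(model)
  opposite <- c(inward = "outward", outward = "inward")
  function(condition, F_T) {
    E_ref <- generative_effort_exp1(condition$F_R, condition$ref_duration_ms / 1000,
                                    condition$direction, params)
    E_test <- generative_effort_exp1(F_T, condition$test_duration_ms / 1000,
                                     opposite[[condition$direction]], params)
    z <- (utility(E_ref, model) - utility(E_test, model)) / params$gamma
    if (deterministic) {
      if (z > 0) "reference" else "test"
    } else {
      if (stats::runif(1) < stats::pnorm(z)) "reference" else "test"
    }
  }
}

#' Simulate a full staircase experiment for a cohort
#'
#' Plays every subject of the cohort through all conditions of the design,
#' with the condition staircases randomly interleaved, and collects the
#' standard trial table. Ground-truth generating parameters stay in the
#' separate `cohort` object (returned alongside, never merged into the
#' trial table).
#'
#' @param cohort A [draw_population()] cohort.
#' @param design A design data frame; defaults to [exp2_design()].
#' @param model Utility model generating the choices.
#' @param seed Optional integer seed for choices and interleaving.
#' @param deterministic Use zero-noise observers (sign rule).
#' @return List with `trials` (trial table over all subjects),
#'   `ground_truth` (the cohort), `inversion_means` (per subject x
#'   condition equivalent-force estimates from the staircase inversions)
#'   and `model`.
#' @export
run_experiment <- function(cohort, design = exp2_design(),
                           model = "log_difference", seed = NULL,
                           deterministic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  model <- match_utility_model(model)
  experiment <- design$experiment[1]
  all_trials <- vector("list", nrow(cohort))
  inv_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    params <- subject_params_from_row(row)
    obs <- if (experiment == 1L)
      observer_exp1(params, model, deterministic)
    else
      observer_exp2(params, model, deterministic)
    res <- run_staircase_session(design, obs, subject_id = row$subject_id)
    all_trials[[i]] <- res$trials
    inv_rows[[i]] <- data.frame(
      subject_id = row$subject_id,
      condition_id = design$condition_id,
      F_R = design$F_R,
      direction = design$direction,
      equivalent_force = vapply(res$staircases,
                                equivalent_force_from_inversions, numeric(1))
    )
  }
  list(trials = do.call(rbind, all_trials),
       ground_truth = cohort,
       inversion_means = do.call(rbind, inv_rows),
       model = model)
}
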