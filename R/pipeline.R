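# Config-driven pipeline entry points. These functions back the
# command-line wrapper in inst/scripts/effortdisc-cli.R; each takes a
# configuration list (usually from read_run_config()) and writes its
# artifacts to an output directory.

resolve_design <- function(cfg) {
  experiment <- if (is.null(cfg$experiment)) 2L else as.integer(cfg$experiment)
  if (experiment == 1L)
    exp1_design(if (is.null(cfg$session)) "amplitude" else cfg$session)
  else
    exp2_design()
}

#' Simulate a full synthetic experiment from a configuration
#'
#' Draws a cohort from the configured population, plays every subject
#' through the staircase design and writes the trial table
#' (`trials.csv`), the ground-truth sidecar (`ground_truth.yaml`), the
#' per-condition inversion means (`inversion_means.csv`) and the fully
#' resolved configuration (`config.yaml`) into `out_dir`. The same
#' configuration and seed produce byte-identical trial tables.
#'
#' @param config Named list (or path to a YAML file) with fields
#'   `experiment` (1/2), `session`, `n_subjects`, `model`, `seed`,
#'   `deterministic` and an optional `population` list passed to
#'   [population_params()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return The [run_experiment()] result, invisibly when writing.
#' @export
simulate_experiment_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  pop <- do.call(population_params, as.list(config$population))
  n_subjects <- if (is.null(config$n_subjects)) 16L else as.integer(config$n_subjects)
  seed <- if (is.null(config$seed)) stop("config must set an explicit seed")
          else as.integer(config$seed)
  model <- if (is.null(config$model)) "log_difference" else config$model
  experiment <- if (is.null(config$experiment)) 2L else as.integer(config$experiment)
  design <- resolve_design(config)
  cohort <- draw_population(pop, n_subjects, seed = seed, experiment = experiment)
  res <- run_experiment(cohort, design, model = model, seed = seed + 1L,
                        deterministic = isTRUE(config$deterministic))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(res$trials, file.path(out_dir, "trials.csv"))
    write_ground_truth(cohort, file.path(out_dir, "ground_truth.yaml"))
    utils::write.csv(res$inversion_means,
                     file.path(out_dir, "inversion_means.csv"),
                     row.names = FALSE, quote = FALSE)
    yaml::write_yaml(c(config,
                       list(n_subjects = n_subjects, model = model,
                            experiment = experiment)),
                     file.path(out_dir, "config.yaml"))
    return(invisible(res))
  }
  res
}

#' Fit one or more utility models to a trial table and compare them
#'
#' Fits each requested utility model with [fit_effort_model()], writes the
#' WAIC comparison table (`waic_table.csv`), per-model population posterior
#' summaries (`posterior_<model>.csv`), per-model draw archives
#' (`fit_<model>/`, see [write_fit_archive()]) and the population-level
#' equivalent-force curve of the best model (`pse_curve.csv`).
#'
#' @param trials Trial table or path to a trial-table CSV.
#' @param models Character vector of [UTILITY_MODELS] to fit.
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed (each model uses `seed`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `fits` (named list of `effort_fit`), `comparison`
#'   (WAIC table) and `accuracy` (percent correctly predicted choices per
#'   model).
#' @export
fit_models_config <- function(trials, models = UTILITY_MODELS,
                              mcmc = mcmc_config(preset = "reduced"),
                              seed = 1, out_dir = NULL) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  models <- vapply(models, match_utility_model, character(1))
  fits <- lapply(models, function(m)
    fit_effort_model(trials, model = m, mcmc = mcmc, seed = seed))
  names(fits) <- models
  comparison <- compare_models(fits)
  accuracy <- vapply(fits, function(f) predict_choice_accuracy(trials, f),
                     numeric(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "waic_table.csv"),
                     row.names = FALSE, quote = FALSE)
    for (m in models) {
      s <- posterior_summaries(fits[[m]])
      utils::write.csv(s$population,
                       file.path(out_dir, paste0("posterior_", m, ".csv")),
                       row.names = FALSE, quote = FALSE)
      write_fit_archive(fits[[m]], file.path(out_dir, paste0("fit_", m)))
    }
    best <- comparison$model[1]
    utils::write.csv(posterior_summaries(fits[[best]])$pse_curve,
                     file.path(out_dir, "pse_curve.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(fits = fits, comparison = comparison, accuracy = accuracy)
}
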