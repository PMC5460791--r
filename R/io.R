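# Delimited-text IO for trial tables, ground-truth sidecars and run
# configuration. Dialect pinned: UTF-8, comma separator, "." decimal,
# mandatory header row.

TRIAL_COLUMNS <- c("subject_id", "experiment", "session", "condition_id",
                   "staircase_id", "trial_index", "F_R_N", "F_T_N",
                   "direction", "amplitude_mm", "duration_window_ms",
                   "n_ref_repeats", "choice")

#' Write / read a trial table
#'
#' Trial tables are plain CSV with a fixed column set; writing and reading
#' round-trips losslessly.
#'
#' @param trials A trial-table data frame (see [run_experiment()]).
#' @param path File path.
#' @return `read_trial_table()` returns the validated data frame;
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8",
                            colClasses = c(duration_window_ms = "character"))
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop(sprintf("file '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  bad <- which(!trials$choice %in% c("reference", "test"))
  if (length(bad))
    stop(sprintf("invalid 'choice' value '%s' at data row %d",
                 trials$choice[bad[1]], bad[1]))
  trials
}

#' Import an externally formatted trial table via a column mapping
#'
#' Adapter for deposited choice tables whose column names and choice coding
#' differ from the package schema. `mapping` translates standard column
#' names to the file's column names; unmapped optional columns are filled
#' with defaults. Choice values are recoded through `reference_value`.
#'
#' @param path CSV file to import.
#' @param mapping Named character vector/list: names are standard trial
#'   columns, values the file's column names. `subject_id`, `F_R_N`,
#'   `F_T_N` and `choice` must be mapped (or already standard).
#' @param reference_value Value in the file's choice column that denotes
#'   choosing the reference action (everything else is `"test"`).
#' @param n_ref_repeats Default repetition count if the file has none.
#' @param sep Field separator of the source file.
#' @return A standard trial-table data frame.
#' @export
import_trial_table <- function(path, mapping = NULL, reference_value = "reference",
                               n_ref_repeats = 2, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mapping <- as.list(mapping)
  get_col <- function(std, required = FALSE) {
    src <- if (!is.null(mapping[[std]])) mapping[[std]] else std
    if (src %in% names(raw)) return(raw[[src]])
    if (required)
      stop(sprintf("required column '%s' (mapped to '%s') not found in '%s'",
                   std, src, path))
    NULL
  }
  out <- data.frame(
    subject_id = get_col("subject_id", TRUE),
    F_R_N = as.numeric(get_col("F_R_N", TRUE)),
    F_T_N = as.numeric(get_col("F_T_N", TRUE)),
    stringsAsFactors = FALSE)
  choice_raw <- get_col("choice", TRUE)
  out$choice <- ifelse(choice_raw == reference_value, "reference", "test")
  defaults <- list(experiment = 2L, session = "none", condition_id = NA_integer_,
                   staircase_id = NA_integer_, trial_index = seq_len(nrow(out)),
                   direction = "none", amplitude_mm = NA_real_,
                   duration_window_ms = "", n_ref_repeats = n_ref_repeats)
  for (std in names(defaults)) {
    v <- get_col(std)
    out[[std]] <- if (is.null(v)) defaults[[std]] else v
  }
  out[, TRIAL_COLUMNS]
}

#' Write / read the ground-truth sidecar of a synthetic cohort
#'
#' The generating subject parameters and population settings are stored in
#' a YAML sidecar, separate from the trial table so that fitting code
#' cannot accidentally consume them.
#'
#' @param cohort A [draw_population()] cohort.
#' @param path YAML file path.
#' @return `read_ground_truth()` returns a list with `population` and
#'   `subjects`.
#' @export
write_ground_truth <- function(cohort, path) {
  pop <- attr(cohort, "population")
  yaml::write_yaml(list(
    population = unclass(pop),
    seed = attr(cohort, "seed"),
    subjects = lapply(seq_len(nrow(cohort)), function(i)
      as.list(as.data.frame(cohort)[i, , drop = FALSE]))
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- yaml::read_yaml(path)
  subjects <- do.call(rbind, lapply(raw$subjects, as.data.frame))
  list(population = do.call(population_params, raw$population),
       seed = raw$seed, subjects = subjects)
}

#' Read a run configuration file
#'
#' YAML (or JSON, a YAML subset) configuration with `experiment`,
#' `n_subjects`, `model`, `seed` and optional `population`, `session`,
#' `mcmc` sections; unknown fields are rejected with the offending name.
#'
#' @param path Configuration file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("experiment", "session", "n_subjects", "model", "seed",
               "deterministic", "population", "mcmc", "models", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg
}
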