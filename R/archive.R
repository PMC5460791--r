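# Plain-text fit archives: posterior draws and metadata written as CSV +
# YAML so that summaries can be reproduced without re-sampling.

#' Write / read a fitted model archive
#'
#' Serialises an `effort_fit` to a directory of delimited-text files:
#' `population_draws.csv` (iteration, chain, the six population
#' parameters), `subject_draws.csv` (long format: iteration, chain,
#' subject, alpha, beta, gamma) and `meta.yaml` (model id, subjects,
#' sampler settings, seed, diagnostics, WAIC). Reading reconstructs a fit
#' object suitable for [posterior_summaries()], [coef()], [waic()] and
#' [predict.effort_fit()]; supply the original `trials` to restore the
#' pointwise log-likelihood and prediction methods.
#'
#' @param fit An `effort_fit`.
#' @param dir Archive directory (created if needed).
#' @param trials Optional trial table to re-attach on read.
#' @return `read_fit_archive()` returns an `effort_fit`;
#'   `write_fit_archive()` returns `dir` invisibly.
#' @export
write_fit_archive <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- fit$draws$population
  d <- dim(pd)
  pop_long <- data.frame(
    iteration = rep(seq_len(d[1]), d[2]),
    chain = rep(seq_len(d[2]), each = d[1]),
    matrix(pd, d[1] * d[2], d[3], dimnames = list(NULL, dimnames(pd)[[3]])))
  utils::write.csv(pop_long, file.path(dir, "population_draws.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(fit$draws$subject)) {
    sd_ <- fit$draws$subject
    ds <- dim(sd_)
    sub_long <- data.frame(
      iteration = rep(seq_len(ds[1]), ds[2] * ds[3]),
      chain = rep(rep(seq_len(ds[2]), each = ds[1]), ds[3]),
      subject_id = rep(fit$subjects, each = ds[1] * ds[2]),
      alpha = as.vector(sd_[, , , 1]),
      beta = as.vector(sd_[, , , 2]),
      gamma = as.vector(sd_[, , , 3]))
    utils::write.csv(sub_long, file.path(dir, "subject_draws.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(list(
    model = fit$model,
    subjects = fit$subjects,
    mcmc = unclass(fit$mcmc),
    seed = fit$seed,
    waic = if (!is.null(fit$waic)) fit$waic$waic,
    diagnostics = as.list(fit$diagnostics)
  ), file.path(dir, "meta.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_fit_archive
#' @export
read_fit_archive <- function(dir, trials = NULL) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  pop_long <- utils::read.csv(file.path(dir, "population_draws.csv"))
  n_iter <- max(pop_long$iteration)
  n_chain <- max(pop_long$chain)
  pop_names <- setdiff(names(pop_long), c("iteration", "chain"))
  pop_long <- pop_long[order(pop_long$chain, pop_long$iteration), ]
  pop <- array(as.matrix(pop_long[, pop_names]),
               c(n_iter, n_chain, length(pop_names)),
               dimnames = list(NULL, NULL, pop_names))
  subjects <- meta$subjects
  subj <- NULL
  sub_path <- file.path(dir, "subject_draws.csv")
  if (file.exists(sub_path)) {
    sub_long <- utils::read.csv(sub_path)
    sub_long <- sub_long[order(match(sub_long$subject_id, subjects),
                               sub_long$chain, sub_long$iteration), ]
    n_sub <- length(subjects)
    subj <- array(NA_real_, c(n_iter, n_chain, n_sub, 3L),
                  dimnames = list(NULL, NULL, NULL,
                                  c("alpha", "beta", "gamma")))
    for (j in 1:3)
      subj[, , , j] <- array(sub_long[[c("alpha", "beta", "gamma")[j]]],
                             c(n_iter, n_chain, n_sub))
  }
  fit <- structure(list(
    model = meta$model,
    draws = list(population = pop, subject = subj),
    subjects = subjects,
    trials = trials,
    priors = prior_spec(),
    mcmc = do.call(mcmc_config, meta$mcmc),
    seed = meta$seed,
    diagnostics = as.data.frame(meta$diagnostics)
  ), class = "effort_fit")
  if (!is.null(trials)) {
    fit$data <- prepare_trial_data(trials)
    fit$log_lik <- loglik_matrix(fit)
    fit$waic <- waic(fit)
  }
  fit
}
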