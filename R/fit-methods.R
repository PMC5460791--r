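# WAIC, model comparison and the S3 surface of `effort_fit` objects.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Watanabe-Akaike information criterion
#'
#' Computed on the deviance scale from the pointwise log-likelihood matrix:
#' `WAIC = -2 (lppd - p_waic)` where `lppd` is the log pointwise predictive
#' density (posterior-averaged likelihood per trial) and the effective
#' number of parameters `p_waic` is the summed posterior variance of the
#' per-trial log-likelihood. Differences between models convert to relative
#' likelihoods via [relative_likelihood()].
#'
#' @param x An `effort_fit`, or a pointwise log-likelihood matrix with one
#'   row per posterior draw and one column per trial (at least 2 rows).
#' @param ... Unused.
#' @return An object of class `effortdisc_waic`: list with `waic`, `lppd`,
#'   `p_waic` and `elpd_waic`.
#' @export
waic <- function(x, ...) UseMethod("waic")

#' @rdname waic
#' @export
waic.effort_fit <- function(x, ...) {
  if (is.null(x$log_lik)) x$log_lik <- loglik_matrix(x)
  waic(x$log_lik)
}

#' @rdname waic
#' @export
waic.matrix <- function(x, ...) {
  if (nrow(x) < 2)
    stop("WAIC needs at least 2 posterior draws (pointwise variance undefined)")
  S <- nrow(x)
  lppd <- sum(apply(x, 2, log_sum_exp) - log(S))
  p_waic <- sum(apply(x, 2, stats::var))
  structure(list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
                 elpd_waic = lppd - p_waic),
            class = "effortdisc_waic")
}

#' @export
print.effortdisc_waic <- function(x, ...) {
  cat(sprintf("WAIC %.4g (lppd %.4g, p_waic %.3g)\n", x$waic, x$lppd, x$p_waic))
  invisible(x)
}

as_waic_value <- function(x) {
  if (inherits(x, "effortdisc_waic")) x$waic
  else if (inherits(x, "effort_fit")) waic(x)$waic
  else as.numeric(x)
}

#' Relative likelihood of two models from their WAICs
#'
#' The Akaike-weight-style evidence ratio `exp(-(waic_a - waic_b) / 2)`:
#' how likely model `a` is relative to model `b` to minimise expected
#' out-of-sample deviance. Antisymmetric:
#' `relative_likelihood(a, b) * relative_likelihood(b, a) == 1`.
#'
#' @param waic_a,waic_b WAIC values (numbers, `effortdisc_waic` objects or
#'   fits).
#' @return The evidence ratio of model a versus model b.
#' @export
relative_likelihood <- function(waic_a, waic_b) {
  exp(-(as_waic_value(waic_a) - as_waic_value(waic_b)) / 2)
}

#' Compare several fitted utility models by WAIC
#'
#' @param ... Named `effort_fit` objects (or a single list of them).
#' @return Data frame sorted by WAIC with the relative likelihood of each
#'   model versus the best one.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "effort_fit"))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$model, character(1))
  w <- vapply(fits, as_waic_value, numeric(1))
  ord <- order(w)
  data.frame(model = names(fits)[ord], waic = w[ord],
             delta_waic = w[ord] - min(w),
             rel_likelihood = exp(-(w[ord] - min(w)) / 2),
             row.names = NULL)
}

# posterior medians of the subject-level parameters as a data frame
median_subject_params <- function(fit) {
  fd <- flat_subject_draws(fit)
  data.frame(subject_id = fit$subjects,
             alpha = apply(fd$alpha, 2, stats::median),
             beta = apply(fd$beta, 2, stats::median),
             gamma = apply(fd$gamma, 2, stats::median))
}

#' Choice-prediction accuracy of a fitted model
#'
#' Binary predictions from the fitted equivalent-force curve: the model
#' predicts `"reference"` whenever the test force exceeds the subject's
#' equivalent force at the trial's reference force (posterior-median
#' subject parameters); an exact tie predicts `"test"`.
#'
#' @param trials Trial table sharing subjects with the fit.
#' @param fit An `effort_fit`.
#' @return Percent of trials whose observed choice matches the prediction.
#' @export
predict_choice_accuracy <- function(trials, fit) {
  pars <- median_subject_params(fit)
  idx <- match(trials$subject_id, pars$subject_id)
  if (anyNA(idx)) stop("trials contain subjects absent from the fit")
  FTeq <- (trials$n_ref_repeats * trials$F_R_N^pars$alpha[idx] +
             (trials$n_ref_repeats - 1) * pars$beta[idx])^(1 / pars$alpha[idx])
  predicted <- ifelse(trials$F_T_N > FTeq, "reference", "test")
  100 * mean(predicted == trials$choice)
}

#' Posterior summaries: compound population posteriors and PSE curves
#'
#' The compound posterior of a subject-level parameter is the mixture, over
#' posterior draws of its population mean and SD, of the corresponding
#' (positivity-truncated) normals: the distribution of a new subject's
#' parameter. The equivalent-force (point-of-subjective-equality) curve is
#' evaluated per posterior draw on the force grid; its pointwise median and
#' central 95% band are returned, at the population level (compound draws)
#' and per subject.
#'
#' @param fit An `effort_fit`.
#' @param F_R_grid Reference-force grid in newtons.
#' @param n_ref_repeats Repetition factor of the design (default 2).
#' @return List with `population` (data frame of posterior quantiles for
#'   the six population parameters), `compound` (quantiles of the compound
#'   subject-level posteriors), `pse_curve` (population-level curve with
#'   95% band) and `subject_pse` (per-subject curves with bands).
#' @export
posterior_summaries <- function(fit, F_R_grid = seq(0, 9, by = 0.5),
                                n_ref_repeats = 2) {
  pop <- flat_pop_draws(fit)
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  pop_tab <- data.frame(parameter = colnames(pop),
                        mean = colMeans(pop),
                        t(apply(pop, 2, qs)), row.names = NULL)
  names(pop_tab)[3:5] <- c("q2.5", "median", "q97.5")

  # one compound draw per posterior draw: a new subject from that draw's
  # truncated population normal
  S <- nrow(pop)
  comp <- sapply(c(alpha = 1, beta = 2, gamma = 3), function(j) {
    rtruncnorm_pos(S, pop[, j], pop[, j + 3])
  })
  comp_tab <- data.frame(parameter = c("alpha", "beta", "gamma"),
                         t(apply(comp, 2, qs)), row.names = NULL)
  names(comp_tab)[2:4] <- c("q2.5", "median", "q97.5")

  curve_q <- function(alpha_draws, beta_draws) {
    cm <- vapply(F_R_grid, function(f) {
      qs((n_ref_repeats * f^alpha_draws +
            (n_ref_repeats - 1) * beta_draws)^(1 / alpha_draws))
    }, numeric(3))
    data.frame(F_R = F_R_grid, lower = cm[1, ], median = cm[2, ],
               upper = cm[3, ])
  }
  pse <- curve_q(comp[, 1], comp[, 2])

  subject_pse <- NULL
  if (!is.null(fit$draws$subject)) {
    fd <- flat_subject_draws(fit)
    subject_pse <- lapply(seq_along(fit$subjects), function(i) {
      cbind(subject_id = fit$subjects[i],
            curve_q(fd$alpha[, i], fd$beta[, i]))
    })
    subject_pse <- do.call(rbind, subject_pse)
  }
  list(population = pop_tab, compound = comp_tab, pse_curve = pse,
       subject_pse = subject_pse)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.effort_fit <- function(x, ...) {
  cat("Hierarchical probit effort-discounting fit\n")
  cat(sprintf("  utility model: %s\n", x$model))
  cat(sprintf("  subjects: %d, trials: %d\n",
              length(x$subjects), nrow(x$trials)))
  cat(sprintf("  chains: %d, draws/chain: %d (after %d warmup)\n",
              x$mcmc$n_chains, x$mcmc$n_samples, x$mcmc$n_warmup))
  if (!is.null(x$waic)) cat(sprintf("  WAIC: %.4g\n", x$waic$waic))
  cat(sprintf("  max split R-hat: %.3f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.effort_fit <- function(object, ...) {
  s <- posterior_summaries(object)
  out <- list(model = object$model,
              population = merge(s$population, object$diagnostics,
                                 by = "parameter", sort = FALSE),
              compound = s$compound, waic = object$waic)
  class(out) <- "summary.effort_fit"
  out
}

#' @export
print.summary.effort_fit <- function(x, ...) {
  cat(sprintf("Utility model: %s\n\nPopulation-level posterior:\n", x$model))
  print(x$population, digits = 3)
  cat("\nCompound (new-subject) posteriors:\n")
  print(x$compound, digits = 3)
  if (!is.null(x$waic)) { cat("\n"); print(x$waic) }
  invisible(x)
}

#' @export
coef.effort_fit <- function(object, ...) {
  pop <- flat_pop_draws(object)
  out <- apply(pop, 2, stats::median)
  attr(out, "subjects") <- median_subject_params(object)
  out
}

#' Predict from a fitted effort-discounting model
#'
#' @param object An `effort_fit`.
#' @param newdata Trial table (defaults to the fitted trials) for types
#'   `"prob"` and `"choice"`; for `"equivalent_force"` a data frame with
#'   columns `subject_id` and `F_R_N` (and optionally `n_ref_repeats`).
#' @param type `"prob"` (probability of choosing the reference),
#'   `"choice"` (deterministic prediction from the equivalent-force
#'   boundary) or `"equivalent_force"`.
#' @param ... Unused.
#' @return Numeric or character vector, one element per row of `newdata`.
#' @export
predict.effort_fit <- function(object, newdata = NULL,
                               type = c("prob", "choice", "equivalent_force"),
                               ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$trials
  pars <- median_subject_params(object)
  idx <- match(newdata$subject_id, pars$subject_id)
  if (anyNA(idx)) stop("newdata contains subjects absent from the fit")
  nrep <- if ("n_ref_repeats" %in% names(newdata)) newdata$n_ref_repeats else 2
  if (type == "equivalent_force") {
    return((nrep * newdata$F_R_N^pars$alpha[idx] +
              (nrep - 1) * pars$beta[idx])^(1 / pars$alpha[idx]))
  }
  p <- vapply(seq_len(nrow(newdata)), function(r) {
    choice_probability(newdata$F_R_N[r], newdata$F_T_N[r],
                       subject_params(pars$alpha[idx[r]], pars$beta[idx[r]],
                                      pars$gamma[idx[r]]),
                       object$model, nrep[min(r, length(nrep))])
  }, numeric(1))
  if (type == "prob") p else ifelse(p > 0.5, "reference", "test")
}

#' Simulate posterior-predictive choices
#'
#' Each simulation draws one joint posterior draw of the subject parameters
#' and regenerates the Bernoulli choices of the fitted trial table.
#'
#' @param object An `effort_fit`.
#' @param nsim Number of simulated choice vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of `"reference"`/`"test"`.
#' @export
simulate.effort_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fd <- flat_subject_draws(object)
  S <- nrow(fd$alpha)
  trials <- object$trials
  idx <- match(trials$subject_id, object$subjects)
  out <- replicate(nsim, {
    s <- sample.int(S, 1)
    p <- vapply(seq_len(nrow(trials)), function(r) {
      i <- idx[r]
      choice_probability(trials$F_R_N[r], trials$F_T_N[r],
                         subject_params(fd$alpha[s, i], fd$beta[s, i],
                                        fd$gamma[s, i]),
                         object$model, trials$n_ref_repeats[r])
    }, numeric(1))
    ifelse(stats::runif(nrow(trials)) < p, "reference", "test")
  })
  as.data.frame(out, stringsAsFactors = FALSE,
                col.names = paste0("sim_", seq_len(nsim)))
}

#' Choice-probability residuals per design cell
#'
#' Observed minus fitted probability of choosing the reference action,
#' aggregated over (subject, reference force, test force) cells; the cell
#' weight is its trial count. Mirrors the residual diagnostic that
#' separates the four utility models, which share the equivalent-force
#' curve but differ in psychometric-curve shape.
#'
#' @param object An `effort_fit`.
#' @param ... Unused.
#' @return Data frame with one row per cell: observed and fitted reference
#'   rates, `residual` and `n_trials`.
#' @export
residuals.effort_fit <- function(object, ...) {
  trials <- object$trials
  fitted_p <- predict.effort_fit(object, trials, type = "prob")
  key <- interaction(trials$subject_id, trials$F_R_N, trials$F_T_N, drop = TRUE)
  agg <- data.frame(
    subject_id = tapply(trials$subject_id, key, `[`, 1),
    F_R_N = tapply(trials$F_R_N, key, `[`, 1),
    F_T_N = tapply(trials$F_T_N, key, `[`, 1),
    observed = as.numeric(tapply(trials$choice == "reference", key, mean)),
    fitted = as.numeric(tapply(fitted_p, key, mean)),
    n_trials = as.integer(tapply(fitted_p, key, length)),
    row.names = NULL)
  agg$residual <- agg$observed - agg$fitted
  agg
}

#' Plot the fitted equivalent-force curve
#'
#' Population-level point-of-subjective-equality curve with its 95%
#' credible band, against the identity and doubling reference lines.
#'
#' @param x An `effort_fit`.
#' @param F_R_grid Reference-force grid, N.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.effort_fit <- function(x, F_R_grid = seq(0, 9, by = 0.25), ...) {
  s <- posterior_summaries(x, F_R_grid)
  pse <- s$pse_curve
  graphics::plot(pse$F_R, pse$median, type = "n",
                 xlab = "reference force (N)",
                 ylab = "equivalent test force (N)",
                 ylim = range(0, pse$upper, 2 * max(F_R_grid)), ...)
  graphics::polygon(c(pse$F_R, rev(pse$F_R)), c(pse$lower, rev(pse$upper)),
                    col = grDevices::adjustcolor("firebrick", 0.25),
                    border = NA)
  graphics::lines(pse$F_R, pse$median, col = "firebrick", lwd = 2)
  graphics::abline(0, 1, lty = 3)
  graphics::abline(0, 2, lty = 3)
  invisible(pse)
}
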