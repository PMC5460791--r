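#' Prior specification for the hierarchical probit model
#'
#' Wide priors on the population-level parameters: normal priors on the
#' population means of the force exponent and effort offset, and a common
#' half-Cauchy prior on all positive scale parameters (the population mean
#' of the sensitivity and the three population SDs).
#'
#' @param mu_alpha_mean,mu_alpha_sd Normal prior on the population mean of
#'   the force exponent (default N(1, 10)).
#' @param mu_beta_mean,mu_beta_sd Normal prior on the population mean of
#'   the effort offset (default N(0, 100)).
#' @param scale_cauchy Scale of the half-Cauchy(0, scale) prior shared by
#'   `mu_gamma`, `sigma_alpha`, `sigma_beta`, `sigma_gamma` (default 20).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mu_alpha_mean = 1, mu_alpha_sd = 10,
                       mu_beta_mean = 0, mu_beta_sd = 100,
                       scale_cauchy = 20) {
  structure(list(mu_alpha_mean = mu_alpha_mean, mu_alpha_sd = mu_alpha_sd,
                 mu_beta_mean = mu_beta_mean, mu_beta_sd = mu_beta_sd,
                 scale_cauchy = scale_cauchy),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Default preset matches the reference sampling settings (4 chains of
#' 1000 retained draws after 1000 warmup iterations); the `"reduced"`
#' preset (2 chains x 500 draws after 500 warmup) is intended for
#' simulation studies and continuous testing.
#'
#' @param n_chains,n_warmup,n_samples Chain count, warmup iterations and
#'   retained draws per chain.
#' @param preset `"default"` or `"reduced"`; explicit arguments override
#'   the preset values.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = NULL, n_warmup = NULL, n_samples = NULL,
                        preset = c("default", "reduced")) {
  preset <- match.arg(preset)
  def <- if (preset == "default") c(4L, 1000L, 1000L) else c(2L, 500L, 500L)
  cfg <- list(n_chains = if (is.null(n_chains)) def[1] else as.integer(n_chains),
              n_warmup = if (is.null(n_warmup)) def[2] else as.integer(n_warmup),
              n_samples = if (is.null(n_samples)) def[3] else as.integer(n_samples))
  if (any(unlist(cfg) < 1)) stop("MCMC settings must be positive")
  structure(cfg, class = "mcmc_config")
}

MODEL_CODES <- c(log_difference = 0L, difference = 1L,
                 hyperbolic = 2L, hyperbolic_log = 3L)

# validate/extract the trial-table columns the likelihood needs
prepare_trial_data <- function(trials) {
  required <- c("subject_id", "F_R_N", "F_T_N", "n_ref_repeats", "choice")
  missing <- setdiff(required, names(trials))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(trials) == 0) {
    return(list(n_sub = 0L, subjects = integer(0), ord = integer(0),
                subj_start = integer(0), subj_len = integer(0),
                FR = numeric(0), FT = numeric(0), nrep = integer(0),
                choice = integer(0), subj0 = integer(0)))
  }
  subjects <- sort(unique(trials$subject_id))
  idx <- match(trials$subject_id, subjects)
  ord <- order(idx)
  idx <- idx[ord]
  len <- tabulate(idx, nbins = length(subjects))
  start <- c(0L, cumsum(len)[-length(len)])
  list(n_sub = length(subjects), subjects = subjects, ord = ord,
       subj_start = as.integer(start), subj_len = as.integer(len),
       FR = as.numeric(trials$F_R_N[ord]), FT = as.numeric(trials$F_T_N[ord]),
       nrep = as.integer(trials$n_ref_repeats[ord]),
       choice = as.integer(trials$choice[ord] == "reference"),
       subj0 = as.integer(idx - 1L))
}

# log posterior conditionals for one population mean / SD given the subject
# values x; includes the truncation normalisation of the subject-level
# truncated normals, Z(mu, sigma) = P(X > PARAM_LOWER)
pop_mu_logpost <- function(m, x, s, prior_log) {
  lz <- stats::pnorm((m - PARAM_LOWER) / s, log.p = TRUE)
  -sum((x - m)^2) / (2 * s^2) - length(x) * lz + prior_log(m)
}

pop_sigma_logpost <- function(s, x, m, scale_cauchy) {
  if (s <= 0) return(-Inf)
  lz <- stats::pnorm((m - PARAM_LOWER) / s, log.p = TRUE)
  -length(x) * log(s) - sum((x - m)^2) / (2 * s^2) - length(x) * lz -
    log1p((s / scale_cauchy)^2)
}

#' Fit the hierarchical Bayesian effort-discounting model
#'
#' Fits the probit choice model to a trial table: each binary choice between
#' an `n`-times repeated reference movement (force `F_R_N`) and a single
#' test movement (force `F_T_N`) is Bernoulli with probability
#' `Phi((U(n E_i(F_R)) - U(E_i(F_T))) / gamma_i)`, where subject `i`'s
#' effort is `E_i(F) = F^alpha_i + beta_i` and `U` is the chosen utility
#' transform. Subject parameters are drawn from population normals
#' (truncated to positivity) whose means and SDs get the [prior_spec()]
#' priors.
#'
#' Posterior sampling uses a slice-within-Gibbs scheme: univariate slice
#' updates (stepping out and shrinkage) for every subject parameter against
#' its Bernoulli likelihood plus hierarchical prior, and for the six
#' population parameters against the exact truncated-normal population
#' density and their priors. Slice sampling requires no step-size tuning
#' and is reproducible given `seed`.
#'
#' @param trials Trial table (see [run_experiment()] or
#'   [read_trial_table()]) with columns `subject_id`, `F_R_N`, `F_T_N`,
#'   `n_ref_repeats` and `choice` (`"reference"`/`"test"`).
#' @param model One of [UTILITY_MODELS].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed controlling all chains.
#' @param compute_loglik Keep the pointwise log-likelihood matrix (needed
#'   for WAIC; default `TRUE`).
#' @return An object of class `effort_fit` with posterior draws
#'   (`$draws$population`: iterations x chains x 6; `$draws$subject`:
#'   iterations x chains x subjects x 3), the pointwise log-likelihood
#'   matrix, WAIC, and convergence diagnostics.
#' @seealso [waic()], [predict.effort_fit()], [posterior_summaries()]
#' @export
fit_effort_model <- function(trials, model = UTILITY_MODELS,
                             priors = prior_spec(),
                             mcmc = mcmc_config(), seed = 1,
                             compute_loglik = TRUE) {
  model <- match_utility_model(model)
  mcode <- MODEL_CODES[[model]]
  dat <- prepare_trial_data(trials)
  n_sub <- dat$n_sub
  n_iter <- mcmc$n_warmup + mcmc$n_samples
  pop_names <- c("mu_alpha", "mu_beta", "mu_gamma",
                 "sigma_alpha", "sigma_beta", "sigma_gamma")

  set.seed(seed)
  chain_seeds <- sample.int(2^30, mcmc$n_chains)

  pop_draws <- array(NA_real_,
                     c(mcmc$n_samples, mcmc$n_chains, 6L),
                     dimnames = list(NULL, NULL, pop_names))
  subj_draws <- if (n_sub > 0)
    array(NA_real_, c(mcmc$n_samples, mcmc$n_chains, n_sub, 3L),
          dimnames = list(NULL, NULL, NULL, c("alpha", "beta", "gamma")))
  else NULL

  mu_priors <- list(
    function(m) stats::dnorm(m, priors$mu_alpha_mean, priors$mu_alpha_sd, log = TRUE),
    function(m) stats::dnorm(m, priors$mu_beta_mean, priors$mu_beta_sd, log = TRUE),
    function(m) if (m <= 0) -Inf else -log1p((m / priors$scale_cauchy)^2)
  )
  mu_lower <- c(-Inf, -Inf, PARAM_LOWER)

  t0 <- proc.time()[["elapsed"]]
  for (chain in seq_len(mcmc$n_chains)) {
    set.seed(chain_seeds[chain])
    # overdispersed but likelihood-feasible starting points
    if (n_sub > 0) {
      params <- cbind(alpha = stats::runif(n_sub, 1.0, 3.0),
                      beta = stats::runif(n_sub, 5, 25),
                      gamma = stats::runif(n_sub, 0.5, 4))
      mu <- pmax(colMeans(params), PARAM_LOWER * 2)
      sigma <- pmax(apply(params, 2, stats::sd), 0.25)
      if (any(!is.finite(sigma))) sigma <- c(0.5, 5, 1)
    } else {
      params <- matrix(numeric(0), 0, 3)
      mu <- c(1, 0, 2)
      sigma <- c(1, 10, 1)
    }
    for (iter in seq_len(n_iter)) {
      if (n_sub > 0) {
        params <- cpp_slice_sweep(params, mu, sigma,
                                  dat$subj_start, dat$subj_len,
                                  dat$FR, dat$FT, dat$nrep, dat$choice,
                                  mcode, PARAM_LOWER, pmax(sigma, 0.05))
      }
      for (j in 1:3) {
        x <- if (n_sub > 0) params[, j] else numeric(0)
        w_mu <- max(if (n_sub > 1) stats::sd(x) else 1, 0.5)
        mu[j] <- slice_sample1(mu[j],
                               function(m) pop_mu_logpost(m, x, sigma[j], mu_priors[[j]]),
                               w = w_mu, lower = mu_lower[j])
        sigma[j] <- slice_sample1(sigma[j],
                                  function(s) pop_sigma_logpost(s, x, mu[j], priors$scale_cauchy),
                                  w = w_mu, lower = 1e-6)
      }
      if (iter > mcmc$n_warmup) {
        k <- iter - mcmc$n_warmup
        pop_draws[k, chain, ] <- c(mu, sigma)
        if (n_sub > 0) subj_draws[k, chain, , ] <- params
      }
    }
  }
  runtime <- proc.time()[["elapsed"]] - t0

  diagnostics <- data.frame(
    parameter = pop_names,
    rhat = vapply(1:6, function(p) split_rhat(pop_draws[, , p]), numeric(1)),
    ess = vapply(1:6, function(p) ess_basic(pop_draws[, , p]), numeric(1))
  )
  if (any(is.finite(diagnostics$rhat) & diagnostics$rhat > 1.05))
    warning("some population parameters have split R-hat > 1.05; ",
            "consider longer chains")

  fit <- structure(list(
    model = model,
    draws = list(population = pop_draws, subject = subj_draws),
    subjects = dat$subjects,
    trials = trials,
    data = dat,
    priors = priors,
    mcmc = mcmc,
    seed = seed,
    diagnostics = diagnostics,
    runtime_s = runtime
  ), class = "effort_fit")

  if (compute_loglik && n_sub > 0 && nrow(trials) > 0) {
    fit$log_lik <- loglik_matrix(fit)
    fit$waic <- waic(fit)
  }
  fit
}

# flatten the per-chain subject draws into S x n_sub matrices
flat_subject_draws <- function(fit) {
  sd_ <- fit$draws$subject
  if (is.null(sd_)) stop("fit has no subject-level draws")
  d <- dim(sd_)  # iter, chain, sub, 3
  S <- d[1] * d[2]
  list(alpha = matrix(aperm(sd_[, , , 1, drop = FALSE], c(1, 2, 3, 4)), S, d[3]),
       beta  = matrix(aperm(sd_[, , , 2, drop = FALSE], c(1, 2, 3, 4)), S, d[3]),
       gamma = matrix(aperm(sd_[, , , 3, drop = FALSE], c(1, 2, 3, 4)), S, d[3]))
}

# flatten population draws into an S x 6 matrix
flat_pop_draws <- function(fit) {
  pd <- fit$draws$population
  d <- dim(pd)
  out <- matrix(pd, d[1] * d[2], d[3])
  colnames(out) <- dimnames(pd)[[3]]
  out
}

# pointwise log-likelihood matrix (posterior draws x trials), trial order
# matching the input trial table
loglik_matrix <- function(fit) {
  fd <- flat_subject_draws(fit)
  dat <- fit$data
  ll <- cpp_loglik_matrix(fd$alpha, fd$beta, fd$gamma, dat$subj0,
                          dat$FR, dat$FT, dat$nrep, dat$choice,
                          MODEL_CODES[[fit$model]])
  # undo the by-subject sort so columns align with the input rows
  ll[, order(dat$ord), drop = FALSE]
}

#' Pointwise Bernoulli-probit log-likelihood of a trial table
#'
#' Evaluates, for fixed subject parameters, the log probability mass of
#' each observed choice under the probit model.
#'
#' @param trials Trial table (see [fit_effort_model()]).
#' @param params_by_subject Data frame with columns `subject_id`, `alpha`,
#'   `beta`, `gamma` covering every subject present in `trials`.
#' @param model One of [UTILITY_MODELS].
#' @return Numeric vector, one log-likelihood per trial (in input order);
#'   `-Inf` with a warning where the utility is undefined.
#' @export
log_likelihood <- function(trials, params_by_subject,
                           model = UTILITY_MODELS) {
  model <- match_utility_model(model)
  if (nrow(trials) == 0) return(numeric(0))
  idx <- match(trials$subject_id, params_by_subject$subject_id)
  if (anyNA(idx))
    stop("missing parameters for subject(s): ",
         paste(unique(trials$subject_id[is.na(idx)]), collapse = ", "))
  ll <- cpp_pointwise_loglik(
    as.numeric(params_by_subject$alpha), as.numeric(params_by_subject$beta),
    as.numeric(params_by_subject$gamma), as.integer(idx - 1L),
    as.numeric(trials$F_R_N), as.numeric(trials$F_T_N),
    as.integer(trials$n_ref_repeats),
    as.integer(trials$choice == "reference"), MODEL_CODES[[model]])
  if (any(!is.finite(ll)))
    warning("utility undefined for some trials; returning -Inf there")
  ll
}
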