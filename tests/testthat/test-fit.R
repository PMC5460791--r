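test_that("pointwise log-likelihood matches a naive per-trial oracle", {
  sim <- small_experiment()
  tr <- sim$trials
  co <- sim$ground_truth
  pars <- data.frame(subject_id = co$subject_id, alpha = co$alpha,
                     beta = co$beta, gamma = co$gamma)
  for (m in c("log_difference", "hyperbolic")) {
    ll <- log_likelihood(tr, pars, m)
    oracle <- vapply(seq_len(nrow(tr)), function(i) {
      p <- subject_params(pars$alpha[tr$subject_id[i]],
                          pars$beta[tr$subject_id[i]],
                          pars$gamma[tr$subject_id[i]])
      pr <- choice_probability(tr$F_R_N[i], tr$F_T_N[i], p, m,
                               tr$n_ref_repeats[i])
      log(if (tr$choice[i] == "reference") pr else 1 - pr)
    }, numeric(1))
    expect_equal(ll, oracle, tolerance = 1e-12, info = m)
  }
  expect_true(all(is.finite(log_likelihood(tr, pars, "difference"))))
  expect_length(log_likelihood(tr[0, ], pars), 0)
  # an indifferent trial has mass log(1/2) whatever the choice
  even <- toy_trials()[1, ]
  even$F_T_N <- equivalent_force(even$F_R_N, default_params())
  pars1 <- data.frame(subject_id = 1, alpha = 2, beta = 14, gamma = 2)
  expect_equal(log_likelihood(even, pars1), log(0.5), tolerance = 1e-9)
})

test_that("WAIC matches the naive double-loop computation", {
  set.seed(71)
  S <- 20; n <- 50
  ll <- matrix(log(runif(S * n, 0.2, 0.9)), S, n)
  w <- waic(ll)
  # brute-force oracle
  lppd <- 0; p_waic <- 0
  for (j in 1:n) {
    lppd <- lppd + log(mean(exp(ll[, j])))
    p_waic <- p_waic + var(ll[, j])
  }
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  expect_equal(w$lppd, lppd, tolerance = 1e-10)
  # identical draws: no effective parameters, WAIC is the plain deviance
  ll0 <- matrix(rep(log(c(0.3, 0.6, 0.8)), each = 4), 4, 3)
  w0 <- waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * sum(log(c(0.3, 0.6, 0.8))))
  expect_error(waic(ll0[1, , drop = FALSE]), "2 posterior draws")
})

test_that("relative likelihood converts WAIC differences to evidence ratios", {
  expect_equal(relative_likelihood(100, 100), 1)
  expect_equal(relative_likelihood(4.50e3, 4.43e3), exp(-35))
  a <- relative_likelihood(4.5e3, 4.43e3) * relative_likelihood(4.43e3, 4.5e3)
  expect_equal(a, 1)
})

test_that("a priors-only fit reproduces the prior for the population means", {
  fit <- suppressWarnings(fit_effort_model(
    toy_trials()[0, ], "log_difference",
    mcmc = mcmc_config(n_chains = 2, n_warmup = 200, n_samples = 600),
    seed = 77))
  mu_a <- effortdisc:::flat_pop_draws(fit)[, "mu_alpha"]
  # prior is N(1, 10); the posterior mean must sit near 1 within MC error
  expect_lt(abs(mean(mu_a) - 1), 2)
  expect_gt(sd(mu_a), 5)
})

test_that("the hierarchical fit recovers single-subject parameters from rich data", {
  # dense factorial design (not staircase-concentrated) pins the parameters
  set.seed(81)
  p_true <- subject_params(2, 14, 1.2)
  grid <- expand.grid(F_R_N = c(0, 3, 6, 9), F_T_N = seq(0, 16, 2),
                      rep = 1:6)
  pr <- choice_probability(grid$F_R_N, grid$F_T_N, p_true, "log_difference")
  tr <- data.frame(subject_id = 1, F_R_N = grid$F_R_N, F_T_N = grid$F_T_N,
                   n_ref_repeats = 2,
                   choice = ifelse(runif(nrow(grid)) < pr, "reference", "test"))
  fit <- suppressWarnings(fit_effort_model(
    tr, "log_difference",
    mcmc = mcmc_config(n_chains = 2, n_warmup = 400, n_samples = 400),
    seed = 82))
  fd <- effortdisc:::flat_subject_draws(fit)
  a_med <- median(fd$alpha[, 1]); a_sd <- sd(fd$alpha[, 1])
  expect_lt(abs(a_med - 2), 2 * a_sd + 0.05)
  # PSE curve is recovered even where single parameters trade off
  pse_fit <- median((2 * 6^fd$alpha[, 1] + fd$beta[, 1])^(1 / fd$alpha[, 1]))
  expect_equal(pse_fit, equivalent_force(6, p_true), tolerance = 0.75)
})

test_that("fit object exposes the standard modelling methods", {
  fit <- small_fit()
  expect_s3_class(fit, "effort_fit")
  expect_output(print(fit), "utility model: log_difference")
  s <- summary(fit)
  expect_s3_class(s, "summary.effort_fit")
  expect_true(all(c("mu_alpha", "sigma_gamma") %in% s$population$parameter))
  cf <- coef(fit)
  expect_named(cf, c("mu_alpha", "mu_beta", "mu_gamma",
                     "sigma_alpha", "sigma_beta", "sigma_gamma"))
  expect_equal(nrow(attr(cf, "subjects")), 6)
  # probabilities in (0,1), choices binary, equivalent forces increasing
  pr <- predict(fit, type = "prob")
  expect_true(all(pr > 0 & pr < 1))
  nd <- data.frame(subject_id = 1, F_R_N = c(0, 3, 6, 9))
  eq <- predict(fit, nd, type = "equivalent_force")
  expect_true(all(diff(eq) > 0))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$trials), 2L))
  expect_true(all(unlist(sims) %in% c("reference", "test")))
  res <- residuals(fit)
  expect_true(all(abs(res$residual) <= 1))
  expect_equal(sum(res$n_trials), nrow(fit$trials))
})

test_that("posterior summaries include bands that cover the draw-wise quantiles", {
  fit <- small_fit()
  s <- posterior_summaries(fit, F_R_grid = c(0, 3, 6, 9))
  expect_true(all(s$pse_curve$lower <= s$pse_curve$median &
                    s$pse_curve$median <= s$pse_curve$upper))
  # band oracle: quantiles of draw-wise curves at one grid point
  pd <- effortdisc:::flat_pop_draws(fit)
  set.seed(4)
  alpha_rep <- effortdisc:::rtruncnorm_pos(nrow(pd), pd[, "mu_alpha"],
                                           pd[, "sigma_alpha"])
  beta_rep <- effortdisc:::rtruncnorm_pos(nrow(pd), pd[, "mu_beta"],
                                          pd[, "sigma_beta"])
  curve6 <- (2 * 6^alpha_rep + beta_rep)^(1 / alpha_rep)
  row6 <- s$pse_curve[s$pse_curve$F_R == 6, ]
  expect_equal(row6$median, median(curve6), tolerance = 0.2)
  # compound posterior collapses onto mu when sigma -> 0
  expect_true(all(s$compound$q2.5 < s$compound$q97.5))
  # PSE points from the curve satisfy P = 0.5 under the median parameters
  mp <- effortdisc:::median_subject_params(fit)
  p1 <- subject_params(mp$alpha[1], mp$beta[1], mp$gamma[1])
  expect_equal(choice_probability(6, equivalent_force(6, p1), p1, fit$model),
               0.5, tolerance = 1e-9)
})

test_that("choice-prediction accuracy behaves in the limiting cases", {
  fit <- small_fit()
  tr <- fit$trials
  acc <- predict_choice_accuracy(tr, fit)
  expect_true(acc >= 50 && acc <= 100)
  # permutation invariance
  expect_equal(predict_choice_accuracy(tr[sample(nrow(tr)), ], fit), acc)
  # a zero-noise observer is predicted almost perfectly away from the boundary
  det <- draw_population(population_params(), 2, seed = 91)
  dsim <- run_experiment(det, exp2_design(), seed = 92, deterministic = TRUE)
  dfit <- suppressWarnings(fit_effort_model(
    dsim$trials, "log_difference",
    mcmc = mcmc_config(n_chains = 2, n_warmup = 200, n_samples = 200),
    seed = 93))
  expect_gt(predict_choice_accuracy(dsim$trials, dfit), 85)
})

test_that("the sampler agrees with an exhaustive grid posterior on fixed hyperparameters", {
  # tiny single-subject dataset; oracle: 3-D quadrature over (alpha, beta,
  # gamma) with the same hierarchical density at fixed population values
  set.seed(95)
  p_true <- subject_params(2, 14, 1.5)
  grid <- expand.grid(F_R_N = c(0, 6), F_T_N = c(2, 6, 10, 14), rep = 1:4)
  pr <- choice_probability(grid$F_R_N, grid$F_T_N, p_true, "log_difference")
  tr <- data.frame(subject_id = 1, F_R_N = grid$F_R_N, F_T_N = grid$F_T_N,
                   n_ref_repeats = 2,
                   choice = ifelse(runif(nrow(grid)) < pr, "reference", "test"))
  mu <- c(2, 14, 1.5); sigma <- c(0.3, 5, 1)
  ag <- seq(1.2, 3.2, length.out = 41)
  bg <- seq(2, 30, length.out = 41)
  gg <- seq(0.3, 4.5, length.out = 41)
  lp <- array(0, c(41, 41, 41))
  for (ia in 1:41) for (ib in 1:41) {
    ll <- vapply(gg, function(g) sum(log_likelihood(
      tr, data.frame(subject_id = 1, alpha = ag[ia], beta = bg[ib], gamma = g),
      "log_difference")), numeric(1))
    lp[ia, ib, ] <- ll +
      dnorm(ag[ia], mu[1], sigma[1], log = TRUE) +
      dnorm(bg[ib], mu[2], sigma[2], log = TRUE) +
      dnorm(gg, mu[3], sigma[3], log = TRUE)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  alpha_mean_oracle <- sum(apply(w, 1, sum) * ag)
  # MCMC route: one slice-sweep chain with the population fixed at mu/sigma
  dat <- effortdisc:::prepare_trial_data(tr)
  set.seed(96)
  params <- matrix(c(2, 14, 1.5), 1, 3)
  draws <- numeric(4000)
  for (it in 1:4500) {
    params <- effortdisc:::cpp_slice_sweep(params, mu, sigma,
      dat$subj_start, dat$subj_len, dat$FR, dat$FT, dat$nrep, dat$choice,
      0L, 1e-6, pmax(sigma, 0.05))
    if (it > 500) draws[it - 500] <- params[1, 1]
  }
  expect_equal(mean(draws), alpha_mean_oracle, tolerance = 0.05)
})
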