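# MCMC convergence diagnostics (split R-hat and effective sample size) and
# a univariate slice sampler used for the population-level updates.

#' Split R-hat of one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return R-hat (>= 1; values near 1 indicate convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(draws[seq_len(n), , drop = FALSE],
                  draws[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size of one parameter
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence on the
#' chain-averaged autocorrelations.
#'
#' @param draws Matrix of draws, iterations x chains.
#' @return Estimated number of independent draws.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4L) return(NA_real_)
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) return(n * m)
  max_lag <- min(n - 1L, 200L)
  acov <- sapply(seq_len(m), function(c) {
    x <- draws[, c] - mean(draws[, c])
    stats::acf(x, lag.max = max_lag, plot = FALSE,
               type = "covariance", demean = FALSE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  B_over_n <- if (m > 1) stats::var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while their sum stays positive
  s <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(n * m / (1 + 2 * s), 1)
}

# univariate slice sampler with stepping out and shrinkage (Neal 2003);
# mirrors the C++ version used for subject-level updates
slice_sample1 <- function(x0, logf, w, lower = -Inf, upper = Inf,
                          max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- x0 + (w - u)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- L - w; k <- k - 1L }
  L <- max(L, lower)
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- R + w; k <- k - 1L }
  R <- min(R, upper)
  for (it in 1:200) {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}
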