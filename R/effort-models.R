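#' Utility model identifiers
#'
#' The four competing transforms linking effort to utility. Choices are
#' modelled on utility differences, so each transform induces a different
#' psychometric-curve shape while all share the same equivalent-force curve.
#'
#' @format Character vector of the four admissible model ids:
#'   `"log_difference"` (U = -log E), `"difference"` (U = -E),
#'   `"hyperbolic"` (U = 1/E) and `"hyperbolic_log"` (U = 1/log E).
#' @export
UTILITY_MODELS <- c("log_difference", "difference", "hyperbolic", "hyperbolic_log")

#' @keywords internal
match_utility_model <- function(model) {
  match.arg(model, UTILITY_MODELS)
}

#' Per-subject effort/choice parameters
#'
#' Bundles the three subject-level parameters of the probit choice model:
#' the force exponent `alpha`, the effort offset `beta` (the effort of a
#' movement against no external force) and the effort sensitivity `gamma`
#' (the probit scale dividing utility differences). All three must be
#' strictly positive so that effort is positive and the log-based utilities
#' stay finite at a 0 N force.
#'
#' @param alpha Force exponent (dimensionless), > 0.
#' @param beta Effort offset (effort units), > 0.
#' @param gamma Effort sensitivity / probit scale, > 0.
#' @return An object of class `subject_params`.
#' @examples
#' p <- subject_params(alpha = 2, beta = 14, gamma = 2)
#' effort(3, p)  # 3^2 + 14 = 23
#' @export
subject_params <- function(alpha, beta, gamma) {
  for (nm in c("alpha", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("subject parameters: alpha = %.4g, beta = %.4g, gamma = %.4g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

as_subject_params <- function(p) {
  if (inherits(p, "subject_params")) return(p)
  if (is.list(p) && all(c("alpha", "beta", "gamma") %in% names(p)))
    return(subject_params(p$alpha, p$beta, p$gamma))
  stop("expected a 'subject_params' object or a list with alpha, beta, gamma")
}

#' Subjective effort of a movement against a resistive force
#'
#' Effort is a power law of force with an offset, `E(F) = F^alpha + beta`.
#' The offset encodes that a movement against no force still carries effort.
#' `0^alpha` is taken as 0 (the continuous limit for alpha > 0), so
#' `effort(0, p)` equals `beta`.
#'
#' @param F Resistive force in newtons; vectorised; must be >= 0.
#' @param params A [subject_params()] object (only `alpha`, `beta` are used).
#' @return Effort values, same length as `F`; strictly increasing in `F`.
#' @export
effort <- function(F, params) {
  params <- as_subject_params(params)
  if (any(!is.finite(F)) || any(F < 0))
    stop("force must be finite and >= 0")
  F^params$alpha + params$beta
}

#' Utility of an effort value under one of the four competing models
#'
#' @param E Effort value(s); must be > 0 (and `log(E) != 0` for
#'   `"hyperbolic_log"`).
#' @param model One of [UTILITY_MODELS].
#' @return Utility values; monotonically decreasing in `E` on the valid
#'   domain.
#' @export
utility <- function(E, model = UTILITY_MODELS) {
  model <- match_utility_model(model)
  if (any(!is.finite(E)))
    stop("effort values must be finite")
  if (any(E <= 0))
    stop(sprintf("utility undefined for non-positive effort (E = %g)",
                 E[which(E <= 0)[1L]]))
  switch(model,
    log_difference = -log(E),
    difference     = -E,
    hyperbolic     = 1 / E,
    hyperbolic_log = {
      lE <- log(E)
      if (any(abs(lE) < 1e-12))
        stop(sprintf("hyperbolic_log utility singular at effort E = %g (log E = 0)",
                     E[which(abs(lE) < 1e-12)[1L]]))
      1 / lE
    }
  )
}

#' Probability of choosing the reference action
#'
#' Probit choice model: the probability of preferring the reference action
#' (whose effort is that of its movement times the number of repetitions)
#' over the single test movement is
#' `Phi((U(n * E(F_R)) - U(E(F_T))) / gamma)`,
#' with `Phi` the standard normal CDF. With `n_ref_repeats = 2` this is the
#' repeated-versus-single design; `n_ref_repeats = 1` reduces to a
#' single-versus-single comparison.
#'
#' @param F_R Reference force(s), N.
#' @param F_T Test force(s), N.
#' @param params A [subject_params()] object.
#' @param model One of [UTILITY_MODELS].
#' @param n_ref_repeats Number of reference-movement repetitions (default 2).
#' @return Probability in (0, 1) of choosing the reference action;
#'   strictly increasing in `F_T`.
#' @export
choice_probability <- function(F_R, F_T, params, model = UTILITY_MODELS,
                               n_ref_repeats = 2) {
  params <- as_subject_params(params)
  model <- match_utility_model(model)
  E_R <- n_ref_repeats * effort(F_R, params)
  E_T <- effort(F_T, params)
  stats::pnorm((utility(E_R, model) - utility(E_T, model)) / params$gamma)
}

#' Equivalent force (point of subjective equality)
#'
#' The test force at which a single test movement feels as effortful as the
#' `n`-times repeated reference movement, i.e. the solution of
#' `E(F_Teq) = n * E(F_R)`:
#' `F_Teq = (n * F_R^alpha + (n - 1) * beta)^(1/alpha)`.
#' For `n = 2` this is the classic repeated-movement design; the curve is
#' identical for all four utility models. `n = 1` gives the identity.
#'
#' @inheritParams choice_probability
#' @return Equivalent force(s), N; strictly increasing in `F_R`.
#' @export
equivalent_force <- function(F_R, params, n_ref_repeats = 2) {
  params <- as_subject_params(params)
  if (any(!is.finite(F_R)) || any(F_R < 0))
    stop("force must be finite and >= 0")
  (n_ref_repeats * F_R^params$alpha +
     (n_ref_repeats - 1) * params$beta)^(1 / params$alpha)
}

#' Isoeffort reference curves in the force-duration plane
#'
#' Two reference shapes against which empirical isoeffort curves can be
#' compared. Under a linear effort cost `E(F, d) = alpha * F + beta * d`
#' the curve of test forces equally effortful as a reference movement
#' `(F_R, d_R)` is a straight line; under a pure impulse cost
#' `E(F, d) = F * d` it is the convex inverse function.
#'
#' @param F_R Reference force, N.
#' @param d_R Reference movement duration, s.
#' @param d_T Test movement duration grid, s (> 0).
#' @param alpha,beta Coefficients of the linear cost (linear curve only).
#' @return Test forces on the `d_T` grid.
#' @export
isoeffort_linear <- function(F_R, d_R, d_T, alpha, beta) {
  if (any(d_T <= 0) || d_R <= 0) stop("durations must be > 0")
  (alpha * F_R + beta * d_R) / alpha - (beta / alpha) * d_T
}

#' @rdname isoeffort_linear
#' @export
isoeffort_impulse <- function(F_R, d_R, d_T) {
  if (any(d_T <= 0) || d_R <= 0) stop("durations must be > 0")
  F_R * d_R / d_T
}

#' Generative effort model for duration/amplitude comparisons
#'
#' A duration-integrated, direction-scaled extension of the power-law
#' effort used to simulate observers in the single-versus-single experiment
#' where the two movements differ in duration or amplitude and direction:
#' `E = c_dir * d * (F^alpha + beta)`. This generative extension reflects
#' the finding that effort grows monotonically with movement duration
#' (effort integrated over time) and that outward movements are costlier
#' than inward ones; it is an artifact of the simulator, not a model fitted
#' to choice data.
#'
#' @param F Resistive force, N.
#' @param d Movement duration, s (> 0).
#' @param direction `"inward"` or `"outward"`.
#' @param params An [exp1_params()] object.
#' @return Effort value(s); at `d = 1` and `c_dir = 1` this reduces to
#'   [effort()].
#' @export
generative_effort_exp1 <- function(F, d, direction = c("inward", "outward"),
                                   params) {
  direction <- match.arg(direction)
  if (any(d <= 0)) stop("duration must be > 0")
  c_dir <- if (direction == "inward") params$c_in else params$c_out
  c_dir * d * effort(F, params)
}

#' Subject parameters for the duration/amplitude experiment simulator
#'
#' Extends [subject_params()] with multiplicative direction coefficients;
#' `c_out > c_in` encodes that outward movements (away from the body
#' midline) feel costlier at the same force.
#'
#' @inheritParams subject_params
#' @param c_in,c_out Direction cost coefficients (> 0).
#' @return An object of classes `exp1_params` and `subject_params`.
#' @export
exp1_params <- function(alpha, beta, gamma, c_in = 1.0, c_out = 1.15) {
  p <- subject_params(alpha, beta, gamma)
  if (c_in <= 0 || c_out <= 0) stop("direction coefficients must be > 0")
  p$c_in <- c_in
  p$c_out <- c_out
  class(p) <- c("exp1_params", class(p))
  p
}
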