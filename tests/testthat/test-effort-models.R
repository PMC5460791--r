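test_that("effort is the power law with offset and handles the 0 N limit", {
  p <- default_params()
  expect_equal(effort(0, p), 14)            # 0^alpha = 0, so E(0) = beta
  expect_equal(effort(3, p), 23)
  expect_equal(effort(9, subject_params(1, 1e-6, 1)), 9 + 1e-6)
  grid <- effort(seq(0, 16, 0.5), p)
  expect_true(all(diff(grid) > 0))
  expect_error(effort(-1, p), "force")
  expect_error(subject_params(-2, 14, 2), "alpha")
})

test_that("the four utility transforms match their closed forms and domains", {
  expect_equal(utility(1, "difference"), -1)
  expect_equal(utility(1, "log_difference"), 0)
  expect_equal(utility(23, "hyperbolic"), 1 / 23)
  expect_equal(utility(exp(2), "hyperbolic_log"), 0.5)
  for (m in UTILITY_MODELS) {
    E <- seq(1.5, 60, length.out = 40)
    expect_true(all(diff(utility(E, m)) < 0), info = m)
    expect_error(utility(-1, m))
  }
  expect_error(utility(1, "hyperbolic_log"), "singular")
})

test_that("choice probability follows the probit of the utility difference", {
  p <- subject_params(2, 14, 2)
  # independent oracle: hand-computed utility difference and the normal CDF
  # evaluated by numerical integration
  z <- log((10^2 + 14) / (2 * (3^2 + 14))) / 2
  phi_oracle <- 0.5 + stats::integrate(stats::dnorm, 0, abs(z))$value * sign(z)
  expect_equal(choice_probability(3, 10, p, "log_difference"), phi_oracle,
               tolerance = 1e-8)
  expect_equal(round(choice_probability(3, 10, p, "log_difference"), 3), 0.675)
  # infinite-sensitivity limit: indifference
  p_flat <- subject_params(2, 14, 1e9)
  expect_equal(choice_probability(3, 12, p_flat, "difference"), 0.5,
               tolerance = 1e-6)
})

test_that("choice probability is 0.5 at the equivalent force for all models", {
  set.seed(42)
  for (m in UTILITY_MODELS) {
    for (rep in 1:20) {
      p <- subject_params(runif(1, 0.5, 3), runif(1, 2, 25), runif(1, 0.5, 5))
      F_R <- runif(1, 0, 10)
      FTeq <- equivalent_force(F_R, p)
      expect_equal(choice_probability(F_R, FTeq, p, m), 0.5,
                   tolerance = 1e-9, info = m)
    }
  }
})

test_that("choice probability is monotone in both forces", {
  p <- subject_params(1.8, 10, 1.5)
  FT <- seq(0, 16, 0.5)
  FR <- seq(0, 9, 0.5)
  for (m in UTILITY_MODELS) {
    up <- choice_probability(4, FT, p, m)
    expect_true(all(diff(up) >= 0), info = m)
    keep <- up > 1e-12 & up < 1 - 1e-12  # away from double-precision saturation
    expect_true(all(diff(up[keep]) > 0), info = m)
    dn <- choice_probability(FR, 8, p, m)
    expect_true(all(diff(dn) <= 0), info = m)
    keep <- dn > 1e-12 & dn < 1 - 1e-12
    expect_true(all(diff(dn[keep]) < 0), info = m)
  }
})

test_that("equivalent force solves E(F_Teq) = n E(F_R)", {
  p <- default_params()
  expect_equal(equivalent_force(9, p), sqrt(176))
  expect_equal(equivalent_force(0, subject_params(2, 16, 1)), 4)
  # linear, offset-free effort doubles the force exactly
  lin <- subject_params(1, 1e-6, 1)
  expect_equal(equivalent_force(c(1, 4, 7), lin), 2 * c(1, 4, 7),
               tolerance = 1e-5)
  # n = 1 is the identity
  expect_equal(equivalent_force(c(0, 3, 6, 9), p, n_ref_repeats = 1),
               c(0, 3, 6, 9))
  # defining equation and bisection oracle
  set.seed(7)
  for (rep in 1:25) {
    p <- subject_params(runif(1, 0.5, 3), runif(1, 1, 25), 1)
    F_R <- runif(1, 0, 9)
    FTeq <- equivalent_force(F_R, p)
    expect_equal(effort(FTeq, p), 2 * effort(F_R, p), tolerance = 1e-10)
    root <- uniroot(function(x) effort(x, p) - 2 * effort(F_R, p),
                    c(0, 64), tol = 1e-12)$root
    expect_equal(FTeq, root, tolerance = 1e-8)
  }
  grid <- equivalent_force(seq(0, 9, 0.25), default_params())
  expect_true(all(diff(grid) > 0))
})

test_that("isoeffort reference curves have the straight-line and inverse shapes", {
  expect_equal(isoeffort_impulse(6, 1, 2), 3)
  expect_equal(isoeffort_impulse(6, 1.3, 1.3), 6)
  d_T <- seq(0.4, 2, 0.2)
  expect_equal(isoeffort_linear(7, 1, d_T, alpha = 2, beta = 0),
               rep(7, length(d_T)))
  lin <- isoeffort_linear(7, 1, d_T, alpha = 2, beta = 3)
  expect_equal(diff(lin, differences = 2), rep(0, length(d_T) - 2))  # straight
  imp <- isoeffort_impulse(7, 1, d_T)
  expect_true(all(diff(imp, differences = 2) > 0))  # convex
  expect_error(isoeffort_impulse(6, 1, 0), "duration")
})

test_that("the generative duration/direction effort reduces to the core model", {
  g <- exp1_params(2, 14, 2, c_in = 1, c_out = 1)
  expect_equal(generative_effort_exp1(3, 1, "inward", g), effort(3, g))
  expect_equal(generative_effort_exp1(3, 2, "inward", g),
               2 * generative_effort_exp1(3, 1, "inward", g))
  g2 <- exp1_params(2, 14, 2)
  expect_gt(generative_effort_exp1(5, 1, "outward", g2),
            generative_effort_exp1(5, 1, "inward", g2))
  # equivalence point against a root-finding oracle on the defining equation
  # c d_T E(F_T) = c d_R E(F_R), alpha=2 beta=14, d_R=1.05, d_T=0.4, F_R=5
  root <- uniroot(function(x)
    generative_effort_exp1(x, 0.4, "inward", g) -
      generative_effort_exp1(5, 1.05, "inward", g), c(0, 40), tol = 1e-12)$root
  expect_equal(root, sqrt(1.05 / 0.4 * 39 - 14), tolerance = 1e-8)
  expect_equal(root, 9.40, tolerance = 1e-3)
})
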