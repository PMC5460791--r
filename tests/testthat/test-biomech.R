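test_that("minimum-jerk kinematics match the closed-form profile", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 1e-3)
  expect_equal(tr$x[nrow(tr)] - tr$x[1], 0.16, tolerance = 1e-12)
  expect_equal(max(tr$v), 1.875 * 0.16 / 1.05, tolerance = 1e-4)
  expect_equal(tr$v[1], 0)
  expect_equal(tr$a[1], 0)
  expect_equal(tr$v[nrow(tr)], 0, tolerance = 1e-12)
  # speed profile is time-symmetric
  v <- tr$v
  expect_equal(v, rev(v), tolerance = 1e-9)
})

test_that("virtual mass-spring-friction channel renders the friction force", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 5e-4)
  # no friction: only the inertial reaction of the 100 g virtual mass
  # remains (~ m * a_max ~ 0.08 N), far below any condition force
  f0 <- simulate_resistive_force(tr, haptics_params(friction_level = 0,
                                                    spring_k = 1000))
  expect_lt(max(abs(f0$applied_force)), 0.1)
  # constant-velocity handle, long run: spring force balances friction
  # (a 1 N/mm spring so the steady state is reached within the run)
  t <- seq(0, 20, 5e-4)
  const_v <- data.frame(t = t, x = 0.05 * t, v = 0.05, a = 0)
  attr(const_v, "onset") <- 0; attr(const_v, "offset") <- max(t)
  class(const_v) <- c("trajectory", class(const_v))
  fr <- simulate_resistive_force(const_v,
                                 haptics_params(friction_level = 6,
                                                spring_k = 1000,
                                                taper_on_ms = 0))
  tail_force <- fr$applied_force[fr$t > 15]
  expect_equal(mean(abs(tail_force)), 6, tolerance = 0.05)
})

test_that("the command envelope tapers off linearly after target acquisition", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 5e-4, post = 0.8)
  fr <- simulate_resistive_force(tr, haptics_params(friction_level = 6,
                                                    spring_k = 1000,
                                                    taper_off_ms = 600))
  after <- fr$applied_force[fr$t > 1.05 + 0.6 + 1e-9]
  expect_true(all(abs(after) < 1e-12))
  mid_taper <- abs(fr$applied_force[which.min(abs(fr$t - 1.35))])
  at_offset <- abs(fr$applied_force[which.min(abs(fr$t - 1.05))])
  expect_lt(mid_taper, at_offset)
})

test_that("impulse and work integrals match hand calculations", {
  t <- seq(0, 1.3, 1e-3)
  tr <- data.frame(t = t, x = 0.2 / 1.3 * t, v = 0.2 / 1.3,
                   applied_force = -6)
  expect_equal(impulse(tr), 6 * 1.3, tolerance = 1e-10)   # 7.8 N s
  expect_equal(work(tr), 6 * 0.2, tolerance = 1e-10)      # 1.2 J
  expect_error(impulse(tr, window = c(5, 6)), "empty")
})

test_that("energy consistency: force-velocity work equals the path integral", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 5e-4, pre = 0.1, post = 0.5)
  fr <- simulate_resistive_force(tr, haptics_params(friction_level = 6,
                                                    spring_k = 1000))
  w_fv <- work(fr)
  w_path <- sum(abs(fr$applied_force[-1] * diff(fr$x)))
  expect_equal(w_fv, w_path, tolerance = 1e-3)
})

test_that("impulse scales with force level at fixed duration", {
  sim_one <- function(F) {
    tr <- min_jerk_trajectory(0.16, 1.05, dt = 5e-4, pre = 0.1, post = 0.4)
    impulse(simulate_resistive_force(tr, haptics_params(friction_level = F,
                                                        spring_k = 1000)))
  }
  expect_equal(sim_one(10) / sim_one(6), 10 / 6, tolerance = 0.05)
})

test_that("work separates by amplitude and impulse by duration", {
  run <- function(A_mm, d_ms, F = 6) {
    tr <- min_jerk_trajectory(A_mm / 1000, d_ms / 1000, dt = 5e-4,
                              pre = 0.1, post = 0.4)
    fr <- simulate_resistive_force(tr, haptics_params(friction_level = F,
                                                      spring_k = 1000))
    c(W = work(fr), J = impulse(fr))
  }
  spread <- function(x) diff(range(x)) / mean(x)
  # amplitude varies, duration fixed: work ordered and well separated,
  # impulse comparatively flat
  amp <- sapply(c(120, 160, 200), run, d_ms = 1025)
  expect_true(all(diff(amp["W", ]) > 0))
  expect_gt(spread(amp["W", ]), 0.5)
  expect_lt(spread(amp["J", ]), 0.25)
  # duration varies, amplitude fixed: impulse ordered and separated, work flat
  dur <- sapply(c(400, 1050, 1650), run, A_mm = 160)
  expect_true(all(diff(dur["J", ]) > 0))
  expect_gt(spread(dur["J", ]), 0.5)
  expect_lt(spread(dur["W", ]), 0.25)
})

test_that("static arm inverse dynamics equal the Jacobian-transpose map", {
  arm <- arm_params()
  t <- seq(0, 0.5, 1e-2)
  still <- data.frame(t = t, x = 0, v = 0, a = 0)
  # no external force, no motion: zero torques (no gravity in the plane)
  id0 <- arm_inverse_dynamics(still, arm, external_force = 0)
  expect_equal(max(abs(c(id0$tau1, id0$tau2))), 0, tolerance = 1e-10)
  # constant 6 N hand force: torques = J^T F, checked against a
  # virtual-work finite-difference oracle d(hand position)/d(q) . F
  id6 <- arm_inverse_dynamics(still, arm, external_force = 6)
  q <- c(id6$q1[1], id6$q2[1])
  hand_pos <- function(q) c(arm$l1 * cos(q[1]) + arm$l2 * cos(q[1] + q[2]),
                            arm$l1 * sin(q[1]) + arm$l2 * sin(q[1] + q[2]))
  h <- 1e-7
  tau_oracle <- sapply(1:2, function(j) {
    dq <- numeric(2); dq[j] <- h
    sum((hand_pos(q + dq) - hand_pos(q - dq)) / (2 * h) * c(6, 0))
  })
  expect_equal(c(id6$tau1[1], id6$tau2[1]), tau_oracle, tolerance = 1e-6)
})

test_that("moving arm with no load has zero external torque component", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 2e-3)
  id <- arm_inverse_dynamics(tr, external_force = 0)
  expect_equal(max(abs(c(id$tau1_external, id$tau2_external))), 0)
  expect_gt(max(abs(id$tau1_inertial)), 0)
})

test_that("rotational impulse and work integrate joint torque series", {
  t <- seq(0, 1, 1e-3)
  torq <- data.frame(t = t, tau1 = 1, tau2 = 0, qd1 = 2, qd2 = 0,
                     tau1_inertial = 0, tau2_inertial = 0,
                     tau1_external = 1, tau2_external = 0)
  rw <- rotational_impulse_work(torq)
  expect_equal(rw$impulse, 1, tolerance = 1e-10)   # 1 N m for 1 s
  expect_equal(rw$work, 2, tolerance = 1e-10)      # |tau * omega| dt
  zero <- within(torq, {tau1 <- 0; qd1 <- 0; tau1_external <- 0})
  expect_equal(rotational_impulse_work(zero)$impulse, 0)
})

test_that("load-compensation torques outweigh inertial torques for a loaded reach", {
  tr <- min_jerk_trajectory(0.16, 1.05, dt = 1e-3)
  fr <- simulate_resistive_force(tr, haptics_params(friction_level = 6,
                                                    spring_k = 1000))
  id <- arm_inverse_dynamics(fr)
  ext <- rotational_impulse_work(id, component = "external")
  inert <- rotational_impulse_work(id, component = "inertial")
  expect_gt(ext$impulse / inert$impulse, 1)
})
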