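# Physics layer: minimum-jerk reach kinematics, the virtual
# mass-spring-friction force channel of the haptic manipulator, endpoint
# work/impulse integrals, and a planar two-link arm inverse-dynamics model.

#' Haptic force-generation parameters
#'
#' The manipulator renders a kinetic-friction-like resistive force by
#' letting the subject drag a virtual point mass through a virtual spring;
#' the friction force (of magnitude `friction_level`) acts on the virtual
#' mass, and the spring force is the command sent to the handle. Commands
#' are shaped by a trapezoidal envelope (linear tapers at force onset and
#' offset).
#'
#' @param virtual_mass Virtual point mass, kg (default 0.1).
#' @param spring_k Virtual spring stiffness, N/m (default 1; configurable
#'   because metre-scale spring extensions arise at multi-newton friction
#'   levels with this default).
#' @param friction_level Kinetic friction magnitude, N (the condition's
#'   resistive force level).
#' @param cycle_dt Haptic cycle period, s (default 5e-4, i.e. 2 kHz).
#' @param taper_on_ms,taper_off_ms Envelope taper durations, ms.
#' @param deadband Velocity deadband regularising static friction, m/s.
#' @return An object of class `haptics_params`.
#' @export
haptics_params <- function(virtual_mass = 0.1, spring_k = 1,
                           friction_level = 6, cycle_dt = 5e-4,
                           taper_on_ms = 200, taper_off_ms = 600,
                           deadband = 1e-4) {
  stopifnot(virtual_mass > 0, spring_k > 0, friction_level >= 0,
            cycle_dt > 0, deadband > 0)
  structure(as.list(environment()), class = "haptics_params")
}

#' Minimum-jerk reach trajectory
#'
#' The stereotyped straight reach profile
#' `x(t) = A (10 tau^3 - 15 tau^4 + 6 tau^5)`, `tau = t/T`, with zero
#' velocity and acceleration at both ends and peak speed `15/8 * A/T`.
#' Optional flat padding before onset and after offset embeds the movement
#' in the integration window used for work and impulse.
#'
#' @param amplitude Movement amplitude, m.
#' @param duration Movement duration `T`, s.
#' @param dt Sample period, s (default 5e-4, the haptic cycle).
#' @param pre,post Stationary padding before movement onset / after offset,
#'   s (default 0).
#' @return A data frame of class `trajectory` with columns `t`, `x`, `v`,
#'   `a`; attributes `onset` and `offset` give the movement limits in s.
#' @export
min_jerk_trajectory <- function(amplitude, duration, dt = 5e-4,
                                pre = 0, post = 0) {
  stopifnot(amplitude > 0, duration > 0, dt > 0, pre >= 0, post >= 0)
  t <- seq(-pre, duration + post, by = dt)
  tau <- pmin(pmax(t / duration, 0), 1)
  x <- amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  v <- amplitude / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  a <- amplitude / duration^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
  out <- data.frame(t = t, x = x, v = v, a = a)
  attr(out, "onset") <- 0
  attr(out, "offset") <- duration
  class(out) <- c("trajectory", class(out))
  out
}

#' Simulate the resistive force produced by the virtual mass-spring model
#'
#' Replays a handle trajectory through the haptic force channel: each cycle
#' the virtual mass is advanced by semi-implicit Euler under the spring
#' force (handle to mass) and a kinetic friction of magnitude
#' `friction_level` opposing the mass velocity (with a small velocity
#' deadband as static regime: the mass sticks while the spring force stays
#' below the friction level). The virtual mass starts at the handle
#' position (spring force 0, the movement-start reset). The returned
#' `applied_force` is the spring force acting on the handle, shaped by the
#' linear on/off tapers anchored at movement onset and offset.
#'
#' @param traj A `trajectory` (uniform time grid).
#' @param hp A [haptics_params()].
#' @return The trajectory with columns `applied_force` (signed, N) and
#'   `mass_x` added.
#' @export
simulate_resistive_force <- function(traj, hp = haptics_params()) {
  t <- traj$t; xh <- traj$x
  n <- length(t)
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > 1e-9) stop("trajectory grid must be uniform")
  xm <- numeric(n); vm <- 0
  xm[1] <- xh[1]
  force <- numeric(n)
  for (k in seq_len(n - 1L)) {
    f_spring <- hp$spring_k * (xh[k] - xm[k])  # spring force on the mass
    if (abs(vm) <= hp$deadband && abs(f_spring) <= hp$friction_level) {
      vm <- 0  # static: friction balances the spring, mass sticks
      f_fric <- -f_spring
    } else {
      dir <- if (abs(vm) > hp$deadband) sign(vm) else sign(f_spring)
      f_fric <- -hp$friction_level * dir
    }
    vm <- vm + dt * (f_spring + f_fric) / hp$virtual_mass
    xm[k + 1L] <- xm[k] + dt * vm
    force[k] <- -f_spring  # reaction on the handle
    if (!is.finite(xm[k + 1L]))
      stop("virtual-mass integration diverged; check haptics parameters")
  }
  force[n] <- -hp$spring_k * (xh[n] - xm[n])
  onset <- attr(traj, "onset"); offset <- attr(traj, "offset")
  env <- envelope_taper(t, onset, offset, hp$taper_on_ms / 1000,
                        hp$taper_off_ms / 1000)
  traj$applied_force <- force * env
  traj$mass_x <- xm
  traj
}

# trapezoidal command envelope: ramps up over taper_on before onset is
# complete, stays 1 during the movement, ramps down over taper_off after
# the offset (target acquisition)
envelope_taper <- function(t, onset, offset, taper_on, taper_off) {
  env <- rep(1, length(t))
  if (taper_on > 0) {
    ramp <- (t - (onset - taper_on)) / taper_on
    env <- pmin(env, pmax(ramp, 0))
  } else env[t < onset] <- 1
  if (taper_off > 0) {
    ramp <- 1 - (t - offset) / taper_off
    env <- pmin(env, pmax(ramp, 0))
  }
  env
}

clip_window <- function(traj, window) {
  if (is.null(window)) return(traj)
  keep <- traj$t >= window[1] & traj$t <= window[2]
  if (!any(keep)) stop("empty integration window")
  traj[keep, , drop = FALSE]
}

trapz <- function(t, y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)

#' Impulse and work of a force-loaded trajectory
#'
#' Trapezoidal integrals over the analysis window (conventionally movement
#' onset minus 100 ms to movement offset plus 400 ms): impulse is
#' `J = integral |F| dt` (N s) and work is `W = integral |F v| dt` (J),
#' the magnitude of the work exchanged with the resistive load (which
#' always opposes motion).
#'
#' @param traj A trajectory with an `applied_force` column (see
#'   [simulate_resistive_force()]).
#' @param window `c(t_min, t_max)` in s, or `NULL` for the whole
#'   trajectory.
#' @return Scalar impulse (N s) / work (J).
#' @export
impulse <- function(traj, window = NULL) {
  tr <- clip_window(traj, window)
  trapz(tr$t, abs(tr$applied_force))
}

#' @rdname impulse
#' @export
work <- function(traj, window = NULL) {
  tr <- clip_window(traj, window)
  trapz(tr$t, abs(tr$applied_force * tr$v))
}

#' Planar two-link arm parameters
#'
#' Dempster-style anthropometrics for a shoulder-elbow chain moving in a
#' horizontal plane (gravity ignored, wrist rigid): segment masses as
#' fractions of body mass, centre-of-mass positions and radii of gyration
#' as fractions of segment length. Defaults are standard cadaver-study
#' constants; all overridable.
#'
#' @param body_mass Body mass M, kg.
#' @param l_upper,l_fore Upper-arm and forearm+hand lengths, m.
#' @param mass_frac_upper,mass_frac_fore Segment masses / M.
#' @param com_frac_upper,com_frac_fore Centre of mass position / segment
#'   length, from the proximal joint.
#' @param gyr_frac_upper,gyr_frac_fore Radius of gyration about the segment
#'   centre of mass / segment length.
#' @return An object of class `arm_params` with derived masses, COM
#'   offsets and moments of inertia.
#' @export
arm_params <- function(body_mass = 70, l_upper = 0.30, l_fore = 0.33,
                       mass_frac_upper = 0.028, mass_frac_fore = 0.022,
                       com_frac_upper = 0.436, com_frac_fore = 0.682,
                       gyr_frac_upper = 0.322, gyr_frac_fore = 0.468) {
  m1 <- mass_frac_upper * body_mass
  m2 <- mass_frac_fore * body_mass
  structure(list(
    l1 = l_upper, l2 = l_fore, m1 = m1, m2 = m2,
    r1 = com_frac_upper * l_upper, r2 = com_frac_fore * l_fore,
    I1 = m1 * (gyr_frac_upper * l_upper)^2,
    I2 = m2 * (gyr_frac_fore * l_fore)^2
  ), class = "arm_params")
}

# inverse kinematics: planar 2-link, shoulder at origin, elbow-down branch
arm_ik <- function(px, py, arm) {
  d2 <- px^2 + py^2
  c2 <- (d2 - arm$l1^2 - arm$l2^2) / (2 * arm$l1 * arm$l2)
  if (any(c2 > 1 + 1e-9 | c2 < -1 + 1e-12))
    stop("hand path unreachable for these arm segment lengths")
  c2 <- pmin(pmax(c2, -1), 1)
  q2 <- acos(c2)
  q1 <- atan2(py, px) - atan2(arm$l2 * sin(q2), arm$l1 + arm$l2 * cos(q2))
  cbind(q1 = q1, q2 = q2)
}

arm_jacobian <- function(q1, q2, arm) {
  s1 <- sin(q1); c1 <- cos(q1)
  s12 <- sin(q1 + q2); c12 <- cos(q1 + q2)
  matrix(c(-arm$l1 * s1 - arm$l2 * s12, -arm$l2 * s12,
           arm$l1 * c1 + arm$l2 * c12, arm$l2 * c12),
         2, 2, byrow = TRUE)
}

# central finite differences on a uniform grid
fd_diff <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

#' Inverse dynamics of a planar two-link arm
#'
#' Computes the shoulder and elbow torques a subject must produce to move
#' the hand along a trajectory while an external force acts at the hand,
#' decomposed into an inertial component (`M(q) qdd + C(q, qd)`, gravity
#' absent in the horizontal plane) and an external-force component
#' (`J(q)^T F_subject`, the Jacobian-transpose image of the force the
#' subject exerts on the handle to balance the load).
#'
#' @param traj A trajectory (1-D movement coordinate, uniform grid),
#'   optionally carrying `applied_force` (signed manipulator force along
#'   the movement axis) from [simulate_resistive_force()].
#' @param arm An [arm_params()].
#' @param hand_start Hand position at `x = 0` in shoulder-centred planar
#'   coordinates, m.
#' @param axis Unit vector of the movement axis in the same frame.
#' @param external_force Either `NULL` (use `-applied_force` from `traj`,
#'   i.e. the subject balances the manipulator force) or a numeric vector
#'   of signed force magnitudes along `axis` exerted by the subject, N.
#' @return Data frame with per-sample joint angles, velocities and torque
#'   components: `tau1_inertial`, `tau2_inertial`, `tau1_external`,
#'   `tau2_external`, `tau1`, `tau2` (N m).
#' @export
arm_inverse_dynamics <- function(traj, arm = arm_params(),
                                 hand_start = c(-0.08, 0.40),
                                 axis = c(1, 0), external_force = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  px <- hand_start[1] + traj$x * axis[1]
  py <- hand_start[2] + traj$x * axis[2]
  q <- arm_ik(px, py, arm)
  dt <- traj$t[2] - traj$t[1]
  qd <- apply(q, 2, fd_diff, dt = dt)
  qdd <- apply(qd, 2, fd_diff, dt = dt)

  if (is.null(external_force)) {
    external_force <- if (!is.null(traj$applied_force)) -traj$applied_force
                      else rep(0, nrow(q))
  }
  if (length(external_force) == 1L)
    external_force <- rep(external_force, nrow(q))

  n <- nrow(q)
  out <- matrix(0, n, 4,
                dimnames = list(NULL, c("tau1_inertial", "tau2_inertial",
                                        "tau1_external", "tau2_external")))
  for (k in seq_len(n)) {
    c2 <- cos(q[k, 2]); s2 <- sin(q[k, 2])
    M11 <- arm$I1 + arm$I2 + arm$m1 * arm$r1^2 +
      arm$m2 * (arm$l1^2 + arm$r2^2 + 2 * arm$l1 * arm$r2 * c2)
    M12 <- arm$I2 + arm$m2 * (arm$r2^2 + arm$l1 * arm$r2 * c2)
    M22 <- arm$I2 + arm$m2 * arm$r2^2
    h <- arm$m2 * arm$l1 * arm$r2 * s2
    tau_in <- c(M11 * qdd[k, 1] + M12 * qdd[k, 2] -
                  h * qd[k, 2] * (2 * qd[k, 1] + qd[k, 2]),
                M12 * qdd[k, 1] + M22 * qdd[k, 2] + h * qd[k, 1]^2)
    Fv <- external_force[k] * axis
    tau_ex <- t(arm_jacobian(q[k, 1], q[k, 2], arm)) %*% Fv
    out[k, ] <- c(tau_in, tau_ex)
  }
  res <- data.frame(t = traj$t, q1 = q[, 1], q2 = q[, 2],
                    qd1 = qd[, 1], qd2 = qd[, 2], out)
  res$tau1 <- res$tau1_inertial + res$tau1_external
  res$tau2 <- res$tau2_inertial + res$tau2_external
  res
}

#' Summed joint rotational impulse and work
#'
#' Per-joint trapezoidal integrals of `|tau| dt` (rotational impulse,
#' N m s) and `|tau * omega| dt` (rotational work, J) over the analysis
#' window, summed over the shoulder and elbow.
#'
#' @param torques Output of [arm_inverse_dynamics()] (or any data frame
#'   with `t`, `tau1`, `tau2`, `qd1`, `qd2`).
#' @param window `c(t_min, t_max)` in s, or `NULL` for the full series.
#' @param component `"total"`, `"inertial"` or `"external"`.
#' @return List with `impulse` (N m s) and `work` (J).
#' @export
rotational_impulse_work <- function(torques, window = NULL,
                                    component = c("total", "inertial",
                                                  "external")) {
  component <- match.arg(component)
  tr <- clip_window(torques, window)
  cols <- switch(component,
                 total = c("tau1", "tau2"),
                 inertial = c("tau1_inertial", "tau2_inertial"),
                 external = c("tau1_external", "tau2_external"))
  imp <- trapz(tr$t, abs(tr[[cols[1]]])) + trapz(tr$t, abs(tr[[cols[2]]]))
  wrk <- trapz(tr$t, abs(tr[[cols[1]]] * tr$qd1)) +
    trapz(tr$t, abs(tr[[cols[2]]] * tr$qd2))
  list(impulse = imp, work = wrk)
}
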