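#' Advance the mechanical state by one (or more) integrator substeps
#'
#' Semi-implicit Euler integration of the 9-DOF planar equations of motion
#' `M(q) qddot = tau_gravity + tau_velocity + tau_contact + tau_limits + tau`,
#' with the supplied joint torques held constant. Contact and joint-limit
#' torques are applied internally.
#'
#' @param model a `gait_model` (or config)
#' @param q,qdot 9-vectors of generalized coordinates and velocities
#' @param joint_torques 6-vector of internal joint torques (N*m,
#'   flexion/dorsiflexion positive): hipR, kneeR, ankleR, hipL, kneeL, ankleL
#' @param h substep size in seconds
#' @param n_substeps number of substeps to take
#' @return list with advanced `q` and `qdot`
#' @export
forward_dynamics_step <- function(model, q, qdot, joint_torques = rep(0, 6),
                                  h = 1e-3, n_substeps = 1) {
  model <- as_gait_model(model)
  stopifnot(length(q) == 9, length(qdot) == 9, length(joint_torques) == 6,
            h > 0, all(is.finite(q)), all(is.finite(qdot)),
            all(is.finite(joint_torques)))
  out <- fd_step_cpp(model$ptr, q, qdot, joint_torques, h,
                     as.integer(n_substeps))
  list(q = as.numeric(out$q), qdot = as.numeric(out$qdot))
}

#' Generalized accelerations at a state
#'
#' Solves `M(q) qddot = rhs` once, without integrating. Useful for
#' equilibrium analysis and dynamics verification.
#'
#' @inheritParams forward_dynamics_step
#' @return 9-vector qddot
#' @export
joint_accelerations <- function(model, q, qdot, joint_torques = rep(0, 6)) {
  model <- as_gait_model(model)
  as.numeric(accel_cpp(model$ptr, q, qdot, joint_torques))
}

#' Joint-space mass matrix
#'
#' @inheritParams forward_dynamics_step
#' @return symmetric positive-definite 9 x 9 matrix
#' @export
mass_matrix <- function(model, q) {
  model <- as_gait_model(model)
  mass_matrix_cpp(model$ptr, q)
}

#' Foot-ground contact forces
#'
#' Hunt-Crossley normal force `k * depth^1.5 * (1 + c * depth_rate)` clamped at
#' zero, with tanh-regularized Coulomb friction bounded by `mu * normal`, at
#' the heel and toe point of each foot. Airborne points carry exactly zero.
#'
#' @inheritParams forward_dynamics_step
#' @return list: per-point `normal`, `tangential`, `position` plus per-foot
#'   vertical/horizontal totals
#' @export
compute_contact <- function(model, q, qdot) {
  model <- as_gait_model(model)
  cc <- contact_cpp(model$ptr, q, qdot)
  cc$normal <- as.numeric(cc$normal)
  cc$tangential <- as.numeric(cc$tangential)
  cc
}

#' Total mechanical energy
#'
#' Kinetic plus gravitational potential energy of all seven segments, with the
#' potential datum at ground level (y = 0).
#'
#' @inheritParams forward_dynamics_step
#' @return list with `total`, `kinetic`, `potential` in joules
#' @export
total_mechanical_energy <- function(model, q, qdot) {
  model <- as_gait_model(model)
  energy_cpp(model$ptr, q, qdot)
}

#' Passive (torque-free) simulation
#'
#' Integrates the plant with zero joint torques, recording state and energy.
#' With contact and joint limits disabled in the config this is a conservative
#' multi-pendulum, which is how the integrator's energy behaviour is audited.
#'
#' @inheritParams forward_dynamics_step
#' @param duration simulated time, s
#' @param record_every record every k-th substep
#' @return list of `time`, `energy`, `q`, `qdot` histories
#' @export
passive_simulate <- function(model, q, qdot, duration, h = 1e-4,
                             record_every = 10) {
  model <- as_gait_model(model)
  passive_rollout_cpp(model$ptr, q, qdot, duration, h,
                      as.integer(record_every))
}

#' Find a bilateral static equilibrium pose
#'
#' Numerically finds a left/right-symmetric standing pose in which gravity,
#' compliant contact, and joint-limit torques balance: the squared
#' generalized accelerations at zero velocity are minimized over pelvis
#' height and pitch plus the (shared) hip, knee, and ankle angles. A vertical
#' pre-solve sinks the pelvis until the contact carries the body weight
#' (above ground the residual is flat in height, which would strand a local
#' search).
#'
#' @param model a `gait_model`
#' @param q0 initial guess (9-vector), symmetric
#' @return list with the equilibrium `q`, the residual acceleration norm
#'   (1/s^2 units, should be near machine level), and the optimizer
#'   convergence code
#' @export
find_static_equilibrium <- function(model, q0 = standing_pose(model$config)) {
  model <- as_gait_model(model)
  weight <- sum(model$config$segments$mass) * model$config$gravity
  vert <- function(y) {
    q <- q0; q[2] <- y
    cc <- compute_contact(model, q, rep(0, 9))
    cc$vertical_R + cc$vertical_L - weight
  }
  lo <- q0[2] - 0.08
  if (vert(lo) > 0) {
    q0[2] <- stats::uniroot(vert, c(lo, q0[2]), tol = 1e-12)$root
  }
  # Root-solve the generalized passive force residual over the symmetric
  # coordinates (pelvis_y, pitch, hip, knee, ankle). Forces (not
  # accelerations) avoid both the mass-matrix amplification of the light
  # foot segment and the airborne free-fall plateau (where the vertical
  # residual is the full body weight).
  expand <- function(x) c(q0[1], x[1], x[2], x[3], x[4], x[5],
                          x[3], x[4], x[5])
  obj <- function(x) {
    f <- passive_forces_cpp(model$ptr, expand(x), rep(0, 9))
    sum(f^2)
  }
  x0 <- c(q0[2], q0[3], q0[4], q0[5], q0[6])
  fit <- optim(x0, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 20000,
                              parscale = rep(0.005, 5)))
  for (i in 1:3) {
    fit2 <- optim(fit$par, obj, method = "BFGS",
                  control = list(reltol = 1e-16, maxit = 3000,
                                 parscale = rep(0.005, 5)))
    if (fit2$value < fit$value) fit <- fit2
    fit3 <- optim(fit$par, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-16, maxit = 20000,
                                 parscale = rep(0.001, 5)))
    if (fit3$value < fit$value) fit <- fit3
  }
  q <- expand(fit$par)
  a <- joint_accelerations(model, q, rep(0, 9))
  list(q = q, residual = sqrt(sum(a^2)),
       force_residual = sqrt(fit$value), convergence = fit$convergence)
}
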