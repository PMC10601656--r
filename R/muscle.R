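#' First-order activation dynamics
#'
#' Advances muscle activation toward excitation with
#' `da/dt = (e - a) / tau`, where `tau = tau_act` while the excitation exceeds
#' the activation (activation) and `tau_deact` otherwise (relaxation). The
#' update is the exact exponential solution over `dt` for constant excitation,
#' clamped to `[0, 1]`. Vectorized over muscles.
#'
#' @param a activation(s) in `[0, 1]`
#' @param e excitation(s) in `[0, 1]`
#' @param dt time step, s
#' @param tau_act,tau_deact activation/deactivation time constants, s
#' @return updated activation(s)
#' @export
activation_step <- function(a, e, dt, tau_act = 0.01, tau_deact = 0.04) {
  stopifnot(dt > 0, all(a >= 0 & a <= 1), all(e >= 0 & e <= 1),
            tau_act > 0, tau_deact > 0)
  n <- max(length(a), length(e))
  as.numeric(activation_step_cpp(rep_len(a, n), rep_len(e, n), dt,
                                 tau_act, tau_deact))
}

#' Muscle-tendon unit lengths and velocities
#'
#' With constant signed moment arms `r_j`, the MTU length is linear in the
#' joint angles: `l_mt = ref - sum_j r_j * (q_j - q_ref_j)` with the reference
#' posture at zero joint angles; the MTU velocity is its time derivative.
#' Normalized fiber quantities assume a rigid tendon
#' (`l_fiber = l_mt - l_slack`).
#'
#' @param model a `gait_model`
#' @param q,qdot 9-vectors
#' @return list: `l_mt`, `v_mt` (m, m/s) and normalized `l_norm`, `v_norm`
#' @export
mtu_kinematics <- function(model, q, qdot = rep(0, 9)) {
  model <- as_gait_model(model)
  lapply(mtu_kinematics_cpp(model$ptr, q, qdot), as.numeric)
}

#' Hill-type muscle force with rigid tendon
#'
#' `F = MIF * (a * f_L(l) * f_V(v) + f_PE(l))`, never negative, with
#' normalized fiber length `l = (l_mt - l_slack)/l_opt` and normalized
#' velocity `v = v_mt / (v_max * l_opt)` (shortening negative). A
#' non-positive fiber length yields zero active force and a geometry warning
#' flag.
#'
#' @param a activation in `[0, 1]`
#' @param l_mt,v_mt MTU length (m) and velocity (m/s)
#' @param mif maximum isometric force, N
#' @param lopt optimal fiber length, m
#' @param lslack tendon slack length, m
#' @param vmax max contraction velocity, optimal lengths/s
#' @param curves list of curve constants, defaults as in
#'   [default_model_config()]
#' @return list with `force` (N) and `geometry_warning`
#' @export
muscle_force <- function(a, l_mt, v_mt, mif, lopt, lslack, vmax = 10,
                         curves = default_model_config()$curves) {
  stopifnot(a >= 0, a <= 1)
  muscle_force_one_cpp(a, l_mt, v_mt, mif, lopt, lslack, vmax,
                       curves$fl_width, curves$fv_K, curves$fv_ecc_max,
                       curves$fpe_k, curves$fpe_e0)
}

#' Active force-length curve
#'
#' Gaussian bump centered at optimal fiber length:
#' `exp(-((l - 1)/width)^2)`.
#'
#' @param lnorm normalized fiber length
#' @param width curve width, default 0.45
#' @return force scale factor in `(0, 1]`
#' @export
force_length_curve <- function(lnorm, width = 0.45) {
  vapply(lnorm, fl_curve_cpp, numeric(1), width = width)
}

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric side (zero at maximum shortening
#' velocity, one at isometric) and a slope-matched saturating eccentric
#' branch with plateau `ecc_max`.
#'
#' @param vnorm normalized fiber velocity (shortening negative)
#' @param K Hill curvature constant
#' @param ecc_max eccentric plateau
#' @return force scale factor
#' @export
force_velocity_curve <- function(vnorm, K = 0.25, ecc_max = 1.5) {
  vapply(vnorm, fv_curve_cpp, numeric(1), K = K, ecc_max = ecc_max)
}

#' Passive elastic curve
#'
#' Exponential parallel-elastic force engaging beyond optimal fiber length,
#' reaching one normalized force at strain `e0`.
#'
#' @param lnorm normalized fiber length
#' @param k shape constant
#' @param e0 strain at one normalized force
#' @return passive force in units of MIF
#' @export
passive_force_curve <- function(lnorm, k = 4, e0 = 0.6) {
  vapply(lnorm, fpe_curve_cpp, numeric(1), k = k, e0 = e0)
}

#' Muscle forces for the full 18-unit set
#'
#' @param model a `gait_model`
#' @param activations 18-vector in `[0, 1]`
#' @param q,qdot 9-vectors
#' @return 18-vector of forces, N
#' @export
muscle_forces <- function(model, activations, q, qdot = rep(0, 9)) {
  model <- as_gait_model(model)
  stopifnot(length(activations) == 18,
            all(activations >= 0 & activations <= 1))
  as.numeric(muscle_forces_cpp(model$ptr, activations, q, qdot))
}

#' Joint torques from muscle forces
#'
#' `tau_j = sum_k r_kj * F_k` over the muscles spanning joint j, with the
#' signed constant moment arms of the model (flexion/dorsiflexion positive).
#'
#' @param model a `gait_model`
#' @param forces 18-vector of non-negative muscle forces, N
#' @return 6-vector of internal joint torques, N*m
#' @export
joint_torques_from_muscles <- function(model, forces) {
  model <- as_gait_model(model)
  stopifnot(length(forces) == 18, all(forces >= 0))
  as.numeric(joint_torques_cpp(model$ptr, forces))
}
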