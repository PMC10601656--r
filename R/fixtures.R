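#' Specification of a synthetic episode trace
#'
#' Describes a kinematically plausible but dynamics-free walking trace:
#' alternating square-wave ground reaction forces with a given footstep
#' period and duty cycle, a prescribed pelvis speed and tilt, and constant
#' (or per-muscle) excitations. Synthetic traces exercise the reward,
#' footstep and gait-cycle bookkeeping with analytically known ground truth;
#' they make no claim of dynamic consistency.
#'
#' @param duration trace length, s (at least two footstep periods)
#' @param step_period time between initial contacts of alternating feet, s
#'   (one gait cycle per leg is `2 * step_period`)
#' @param duty_cycle loaded fraction of each leg's gait cycle, in (0, 1)
#' @param pelvis_speed constant speed (m/s) or a per-step vector
#' @param pelvis_tilt constant tilt (rad) or a per-step vector
#' @param excitation constant level in `[0, 1]`, or an 18-vector, or a
#'   steps x 18 matrix
#' @param grf_amplitude loaded-phase vertical GRF, N
#' @param dt control interval, s
#' @return object of class `synthetic_trace_spec`
#' @export
synthetic_trace_spec <- function(duration = 12, step_period = 0.55,
                                 duty_cycle = 0.6, pelvis_speed = 1.3,
                                 pelvis_tilt = 0.05, excitation = 0.1,
                                 grf_amplitude = 800, dt = 0.01) {
  stopifnot(duty_cycle > 0, duty_cycle < 1, duration >= 2 * step_period,
            step_period > 0, dt > 0)
  spec <- list(duration = duration, step_period = step_period,
               duty_cycle = duty_cycle, pelvis_speed = pelvis_speed,
               pelvis_tilt = pelvis_tilt, excitation = excitation,
               grf_amplitude = grf_amplitude, dt = dt)
  class(spec) <- "synthetic_trace_spec"
  spec
}

#' Generate a synthetic episode trace
#'
#' Constructs every field the reward and analysis stages consume: time grid,
#' pelvis state (x from integrated speed, pitch from the tilt profile),
#' square-wave GRFs (right foot loaded on the first half-period, left foot
#' shifted by one step period), and the excitation matrix. Footstep
#' boundaries, toe-off fractions and reward components are analytically known
#' from the spec.
#'
#' @param spec a [synthetic_trace_spec()]
#' @param v_tgt target speed stored in the trace (used by reward
#'   computations), or NULL
#' @param weights [reward_weights()]
#' @return a `gait_trace`
#' @export
make_trace <- function(spec, v_tgt = 1.45, weights = reward_weights()) {
  stopifnot(inherits(spec, "synthetic_trace_spec"))
  dt <- spec$dt
  n <- as.integer(round(spec$duration / dt))
  time <- seq_len(n) * dt
  # Square waves built on integer control-step arithmetic (a float phase
  # would jitter the loaded/unloaded boundary by one sample). The right leg
  # starts 10% of a cycle before its first initial contact, so even the
  # first strike follows an unloaded, debounce-able interval; the left leg
  # is shifted by half a cycle.
  n_cyc <- as.integer(round(2 * spec$step_period / dt))
  n_loaded <- as.integer(round(spec$duty_cycle * n_cyc))
  lead <- as.integer(round(0.1 * n_cyc))
  idx_R <- (seq_len(n) - 1L + n_cyc - lead) %% n_cyc
  idx_L <- (idx_R + n_cyc %/% 2L) %% n_cyc
  grf_R <- ifelse(idx_R < n_loaded, spec$grf_amplitude, 0)
  grf_L <- ifelse(idx_L < n_loaded, spec$grf_amplitude, 0)
  v <- rep_len(spec$pelvis_speed, n)
  tilt <- rep_len(spec$pelvis_tilt, n)
  exc <- spec$excitation
  if (is.matrix(exc)) {
    stopifnot(nrow(exc) == n, ncol(exc) == 18)
  } else if (length(exc) == 18) {
    exc <- matrix(exc, n, 18, byrow = TRUE)
  } else {
    exc <- matrix(rep_len(exc, 1), n, 18)
  }
  q <- matrix(0, n, 9)
  q[, 1] <- cumsum(v * dt)
  q[, 2] <- 0.91
  q[, 3] <- tilt
  qdot <- matrix(0, n, 9)
  qdot[, 1] <- v
  qdot[, 3] <- c(0, diff(tilt)) / dt
  grf <- cbind(grf_R, 0, grf_L, 0)
  tr <- build_trace(time = time, q = q, qdot = qdot, grf = grf,
                    excitations = exc, activations = NULL,
                    terminated_early = FALSE, dt = dt, v_tgt = v_tgt,
                    weights = weights)
  # ground-truth labels, known by construction
  ic_R <- which(idx_R == 0L)
  ic_L <- which(idx_L == 0L)
  tr$truth <- list(
    ic_R = ic_R, ic_L = ic_L,
    toe_off_pct = n_loaded / n_cyc * 100,
    n_cycles_R = max(0L, length(ic_R) - 2L),  # after dropping first + partial
    footstep_rows = sort(c(ic_R, ic_L)),
    step_rows = n_cyc %/% 2L)
  tr
}

#' The hand-computable single-footstep fixture
#'
#' A 50-step footstep at dt = 0.01 s with constant pelvis speed 1.2 m/s,
#' tilt 0.1 rad and all 18 excitations at 0.2. With the default weights and
#' a 1.45 m/s target its components evaluate to r_steps = 0.5,
#' J_vel = 0.125, J_pel = 0.005, J_mul = 0.36 and the weighted reward to
#' -2.96.
#'
#' @return list with the inputs (`v_pel`, `theta_pel`, `excitations`, `dt`,
#'   `v_tgt`) and the expected component values
#' @export
reference_footstep_fixture <- function() {
  list(v_pel = rep(1.2, 50), theta_pel = rep(0.1, 50),
       excitations = matrix(0.2, 50, 18), dt = 0.01, v_tgt = 1.45,
       expected = list(r_steps = 0.5, J_vel = 0.125, J_pel = 0.005,
                       J_mul = 0.36, reward = -2.96))
}
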