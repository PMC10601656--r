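#' Reward weights
#'
#' Weights of the footstep reward: step-duration reward, velocity-deviation
#' cost, pelvis-tilt cost and muscle-effort cost. Defaults (10, 60, 20, 1).
#'
#' @param w_steps,w_vel,w_pel,w_mul non-negative weights
#' @return named list of class `reward_weights`
#' @export
reward_weights <- function(w_steps = 10, w_vel = 60, w_pel = 20, w_mul = 1) {
  w <- list(w_steps = w_steps, w_vel = w_vel, w_pel = w_pel, w_mul = w_mul)
  if (any(unlist(w) < 0)) stop("reward weights must be non-negative")
  class(w) <- "reward_weights"
  w
}

#' The 12 initial-state parameters
#'
#' Forward and rightward speed, pelvis height, trunk lean, and bilateral hip
#' abduction, hip flexion, knee flexion and ankle angles. The planar model
#' ignores the rightward speed and the hip ab/adduction entries (kept so the
#' optimization vector has the documented 12 slots).
#'
#' @param forward_speed m/s
#' @param rightward_speed m/s (ignored by the planar plant)
#' @param pelvis_height m, must exceed 0.6 for a viable start
#' @param trunk_lean rad, anterior positive
#' @param hip_abduction_R,hip_abduction_L rad (ignored by the planar plant)
#' @param hip_flexion_R,hip_flexion_L rad
#' @param knee_flexion_R,knee_flexion_L rad
#' @param ankle_R,ankle_L rad, dorsiflexion positive
#' @return named numeric vector of length 12, class `initial_state`
#' @export
initial_state <- function(forward_speed = 1.3, rightward_speed = 0,
                          pelvis_height = 0.91, trunk_lean = 0.05,
                          hip_abduction_R = 0, hip_abduction_L = 0,
                          hip_flexion_R = 0.2, hip_flexion_L = -0.1,
                          knee_flexion_R = 0.1, knee_flexion_L = 0.15,
                          ankle_R = 0, ankle_L = 0) {
  v <- c(forward_speed = forward_speed, rightward_speed = rightward_speed,
         pelvis_height = pelvis_height, trunk_lean = trunk_lean,
         hip_abduction_R = hip_abduction_R, hip_abduction_L = hip_abduction_L,
         hip_flexion_R = hip_flexion_R, hip_flexion_L = hip_flexion_L,
         knee_flexion_R = knee_flexion_R, knee_flexion_L = knee_flexion_L,
         ankle_R = ankle_R, ankle_L = ankle_L)
  class(v) <- "initial_state"
  v
}

#' @export
print.initial_state <- function(x, ...) {
  cat("<initial_state> 12 parameters\n")
  print(unclass(x))
  invisible(x)
}

init_names <- function() names(initial_state())

# map the 12 initial-state parameters onto (q, qdot)
state_from_init <- function(init) {
  init <- as.numeric(init)
  if (length(init) != 12) stop("initial state must have exactly 12 entries")
  q <- c(0, init[3], init[4], init[7], init[9], init[11],
         init[8], init[10], init[12])
  qdot <- c(init[1], rep(0, 8))
  list(q = q, qdot = qdot)
}

#' Physical bounds of the 12 initial-state parameters
#'
#' @return data.frame with columns `name`, `lo`, `hi`
#' @export
initial_state_bounds <- function() {
  data.frame(
    name = init_names(),
    lo = c(0.5, -0.5, 0.85, -0.3, -0.3, -0.3, -0.5, -0.5, 0, 0, -0.5, -0.5),
    hi = c(2.0, 0.5, 1.05, 0.3, 0.3, 0.3, 0.8, 0.8, 1.0, 1.0, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Create a walking MDP environment
#'
#' Wraps the plant and the episode lifecycle into a reset/step interface. The
#' action is the 18-vector of muscle excitations; each step advances
#' activation dynamics and mechanics by the 0.01 s control interval and
#' accrues the survival reward; completed footsteps (alternating initial
#' contacts) emit the footstep reward. The episode ends when the horizon is
#' reached or the pelvis falls below 0.6 m.
#'
#' The environment is a mutable closure-based object; use `env$reset()`,
#' `env$step(action)`, `env$trace()`. For optimization use the much faster
#' [run_episode()], which runs the same plant and controller fully in
#' compiled code.
#'
#' @param model `gait_model` or config
#' @param horizon episode length, s
#' @param v_tgt target speed (m/s) or `NULL` to drop the velocity cost
#' @param weights a [reward_weights()] object
#' @return environment object (list of closures)
#' @export
gait_env <- function(model, horizon = 10, v_tgt = 1.45,
                     weights = reward_weights()) {
  model <- as_gait_model(model)
  cfg <- model$config
  dt <- cfg$dt
  n_sub <- cfg$n_substeps
  thr <- cfg$contact$threshold
  e <- new.env(parent = emptyenv())
  e$done <- TRUE

  observation <- function() {
    list(q = e$q, qdot = e$qdot, activations = e$act,
         grf_R_vertical = e$grfR, grf_L_vertical = e$grfL,
         f_norm = e$fnorm, l_norm = e$lnorm,
         phases = e$phases, time = e$time)
  }

  readout <- function() {
    tot <- e$grfR + e$grfL
    load <- if (tot > 1e-9) c(e$grfR, e$grfL) / tot else c(0, 0)
    list(f_norm = e$fnorm, l_norm = e$lnorm,
         theta = e$q[3], theta_dot = e$qdot[3],
         knee = c(e$q[5], e$q[8]), knee_dot = c(e$qdot[5], e$qdot[8]),
         ankle = c(e$q[6], e$q[9]), ankle_dot = c(e$qdot[6], e$qdot[9]),
         load = load)
  }

  reset <- function(init = initial_state(),
                    controller_params = default_controller_params()) {
    iv <- as.numeric(init)
    if (length(iv) != 12) stop("initial state must have exactly 12 entries")
    if (iv[3] <= cfg$pelvis_min)
      stop("invalid initial state: pelvis height ", iv[3],
           " m is at or below the termination height ", cfg$pelvis_min, " m")
    s <- state_from_init(iv)
    e$q <- s$q; e$qdot <- s$qdot; e$time <- 0; e$done <- FALSE
    cc <- contact_cpp(model$ptr, e$q, e$qdot)
    e$grfR <- cc$vertical_R; e$grfL <- cc$vertical_L
    e$phases <- init_phases(e$grfR, e$grfL, thr)
    # activations start at the controller's baseline excitations
    e$act <- rep(0, 18)
    sr <- mtu_kinematics_cpp(model$ptr, e$q, e$qdot)
    e$lnorm <- sr$l_norm
    e$fnorm <- as.numeric(muscle_forces_cpp(model$ptr, e$act, e$q, e$qdot)) /
      cfg$muscles$mif
    e$act <- compute_excitations(readout(), e$phases, controller_params)
    e$fnorm <- as.numeric(muscle_forces_cpp(model$ptr, e$act, e$q, e$qdot)) /
      cfg$muscles$mif
    e$rows <- list()
    observation()
  }

  step <- function(action) {
    if (e$done) stop("step() called on a finished episode; call reset() first")
    action <- as.numeric(action)
    stopifnot(length(action) == 18, all(action >= 0 & action <= 1))
    e$phases <- update_phases(e$phases, e$grfR, e$grfL, thr, dt)
    out <- control_step_cpp(model$ptr, e$q, e$qdot, e$act, action, dt,
                            as.integer(n_sub))
    e$q <- out$q; e$qdot <- out$qdot; e$act <- out$act
    e$grfR <- out$grf_R_vertical; e$grfL <- out$grf_L_vertical
    e$fnorm <- out$f_norm; e$lnorm <- out$l_norm
    e$time <- e$time + dt
    e$rows[[length(e$rows) + 1]] <- c(
      e$time, e$q, e$qdot, e$grfR, out$grf_R_horizontal, e$grfL,
      out$grf_L_horizontal, action, e$act)
    fell <- e$q[2] < cfg$pelvis_min
    horizon_hit <- e$time >= horizon - 1e-9
    e$done <- fell || horizon_hit
    list(observation = observation(), reward_increment = dt,
         done = e$done, info = list(fell = fell, time = e$time))
  }

  trace <- function() {
    if (length(e$rows) == 0) stop("no steps taken yet")
    m <- do.call(rbind, e$rows)
    build_trace(time = m[, 1], q = m[, 2:10, drop = FALSE],
                qdot = m[, 11:19, drop = FALSE],
                grf = m[, 20:23, drop = FALSE],
                excitations = m[, 24:41, drop = FALSE],
                activations = m[, 42:59, drop = FALSE],
                terminated_early = e$done && e$time < horizon - 1e-9,
                dt = dt, v_tgt = v_tgt, weights = weights)
  }

  list(reset = reset, step = step, trace = trace,
       model = model, horizon = horizon, v_tgt = v_tgt, weights = weights)
}

# assemble an EpisodeTrace object from raw histories
build_trace <- function(time, q, qdot, grf, excitations, activations,
                        terminated_early, dt, v_tgt = NULL,
                        weights = reward_weights(), diverged = FALSE) {
  tr <- list(time = as.numeric(time), q = as.matrix(q),
             qdot = as.matrix(qdot), grf = as.matrix(grf),
             excitations = as.matrix(excitations),
             activations = if (is.null(activations)) NULL
                           else as.matrix(activations),
             terminated_early = isTRUE(terminated_early),
             diverged = isTRUE(diverged), dt = dt, v_tgt = v_tgt,
             weights = weights)
  colnames(tr$grf) <- c("grf_R_vertical", "grf_R_horizontal",
                        "grf_L_vertical", "grf_L_horizontal")
  class(tr) <- "gait_trace"
  tr
}

#' Run one closed-loop episode in compiled code
#'
#' Rolls out the reflex controller against the plant for up to `horizon`
#' seconds at the 0.01 s control interval (10 integrator substeps each),
#' terminating early when the pelvis drops below 0.6 m. Returns the full
#' episode trace with the reward breakdown attached.
#'
#' @param model `gait_model` or config
#' @param controller_params 37-vector (canonical order) or named
#' @param init an [initial_state()] (12 parameters)
#' @param horizon episode length, s
#' @param v_tgt target speed (m/s) or `NULL` for no velocity cost
#' @param weights [reward_weights()]
#' @return object of class `gait_trace`
#' @export
run_episode <- function(model, controller_params, init = initial_state(),
                        horizon = 10, v_tgt = 1.45,
                        weights = reward_weights()) {
  model <- as_gait_model(model)
  cfg <- model$config
  if (!is.null(names(controller_params)))
    controller_params <- pack_params(controller_params)
  iv <- as.numeric(init)
  if (length(iv) != 12) stop("initial state must have exactly 12 entries")
  if (iv[3] <= cfg$pelvis_min)
    stop("invalid initial state: pelvis height at or below ", cfg$pelvis_min)
  s <- state_from_init(iv)
  raw <- rollout_cpp(model$ptr, as.numeric(controller_params), s$q, s$qdot,
                     horizon, cfg$dt, as.integer(cfg$n_substeps),
                     cfg$pelvis_min)
  if (raw$n_steps == 0) {
    tr <- build_trace(time = numeric(0), q = matrix(0, 0, 9),
                      qdot = matrix(0, 0, 9), grf = matrix(0, 0, 4),
                      excitations = matrix(0, 0, 18),
                      activations = matrix(0, 0, 18),
                      terminated_early = TRUE, dt = cfg$dt, v_tgt = v_tgt,
                      weights = weights, diverged = isTRUE(raw$diverged))
    return(tr)
  }
  tr <- build_trace(time = raw$time, q = raw$q, qdot = raw$qdot,
                    grf = raw$grf, excitations = raw$excitations,
                    activations = raw$activations,
                    terminated_early = isTRUE(raw$terminated_early),
                    dt = cfg$dt, v_tgt = v_tgt, weights = weights,
                    diverged = isTRUE(raw$diverged))
  tr
}

#' @export
print.gait_trace <- function(x, ...) {
  cat("<gait_trace>", length(x$time), "control steps (",
      sprintf("%.2f", if (length(x$time)) max(x$time) else 0), "s )\n")
  cat("  terminated early:", x$terminated_early,
      if (x$diverged) " [diverged]" else "", "\n")
  rw <- episode_reward(x)
  cat(sprintf("  reward: %.4f (alive %.4f, footsteps %.4f over %d steps)\n",
              rw$total, rw$r_alive, rw$r_footsteps, rw$n_footsteps))
  invisible(x)
}

#' Detect completed footsteps in a trace
#'
#' A footstep boundary is an initial contact: the vertical GRF of a foot
#' rising through the contact threshold after at least 50 ms unloaded
#' (debounce), with boundaries alternating between feet (re-contacts of the
#' same foot are ignored). The trailing partial footstep is discarded.
#'
#' @param trace a `gait_trace` (or anything with `grf` matrix and `dt`)
#' @param threshold contact threshold, N
#' @param debounce minimum unloaded time before an initial contact, s
#' @return data.frame with columns `start_step`, `end_step`, `duration`,
#'   `leading_foot` (one row per completed footstep; zero rows if fewer than
#'   two alternating contacts)
#' @export
detect_footsteps <- function(trace, threshold = 20, debounce = 0.05) {
  dt <- trace$dt
  need <- max(1L, as.integer(round(debounce / dt)))
  events_t <- integer(0)
  events_f <- character(0)
  for (foot in c("R", "L")) {
    v <- trace$grf[, paste0("grf_", foot, "_vertical")]
    loaded <- v >= threshold
    n <- length(loaded)
    if (n < need + 1) next
    unloaded_streak <- 0L
    for (i in seq_len(n)) {
      if (loaded[i]) {
        if (unloaded_streak >= need) {
          events_t <- c(events_t, i)
          events_f <- c(events_f, foot)
        }
        unloaded_streak <- 0L
      } else {
        unloaded_streak <- unloaded_streak + 1L
      }
    }
  }
  if (length(events_t) == 0)
    return(data.frame(start_step = integer(0), end_step = integer(0),
                      duration = numeric(0), leading_foot = character(0),
                      stringsAsFactors = FALSE))
  ord <- order(events_t)
  events_t <- events_t[ord]; events_f <- events_f[ord]
  # enforce alternation: keep the first event, then only opposite-foot events
  keep_t <- events_t[1]; keep_f <- events_f[1]
  for (i in seq_along(events_t)[-1]) {
    if (events_f[i] != keep_f[length(keep_f)]) {
      keep_t <- c(keep_t, events_t[i]); keep_f <- c(keep_f, events_f[i])
    }
  }
  if (length(keep_t) < 2)
    return(data.frame(start_step = integer(0), end_step = integer(0),
                      duration = numeric(0), leading_foot = character(0),
                      stringsAsFactors = FALSE))
  data.frame(start_step = keep_t[-length(keep_t)],
             end_step = keep_t[-1],
             duration = (keep_t[-1] - keep_t[-length(keep_t)]) * dt,
             leading_foot = keep_f[-length(keep_f)],
             stringsAsFactors = FALSE)
}

#' Reward of one completed footstep
#'
#' Over the footstep's control steps:
#' `r_steps = sum(dt)`;
#' `J_vel  = |sum((v_pel - v_tgt) dt)|` (deviation of distance travelled);
#' `J_pel  = sum(theta_pel^2 dt)`;
#' `J_mul  = sum_k sum(e_k^2 dt)`;
#' reward `= w_steps r_steps - w_vel J_vel - w_pel J_pel - w_mul J_mul`.
#' With `v_tgt = NULL` the velocity cost is omitted entirely.
#'
#' @param v_pel per-step horizontal pelvis velocity, m/s
#' @param theta_pel per-step pelvis tilt, rad
#' @param excitations steps x 18 matrix of excitations
#' @param dt control interval, s
#' @param v_tgt target speed or NULL
#' @param weights [reward_weights()]
#' @return list with `reward` and components `r_steps`, `J_vel`, `J_pel`,
#'   `J_mul`
#' @export
footstep_reward <- function(v_pel, theta_pel, excitations, dt = 0.01,
                            v_tgt = 1.45, weights = reward_weights()) {
  excitations <- as.matrix(excitations)
  n <- length(v_pel)
  stopifnot(length(theta_pel) == n, nrow(excitations) == n)
  r_steps <- n * dt
  J_vel <- if (is.null(v_tgt)) 0 else abs(sum((v_pel - v_tgt) * dt))
  J_pel <- sum(theta_pel^2 * dt)
  J_mul <- sum(excitations^2 * dt)
  reward <- weights$w_steps * r_steps -
    (if (is.null(v_tgt)) 0 else weights$w_vel * J_vel) -
    weights$w_pel * J_pel - weights$w_mul * J_mul
  list(reward = reward, r_steps = r_steps, J_vel = J_vel, J_pel = J_pel,
       J_mul = J_mul)
}

#' Total episode reward with breakdown
#'
#' Survival reward (`dt` per executed control step) plus the sum of completed
#' footstep rewards.
#'
#' @param trace a `gait_trace`
#' @param weights [reward_weights()]; defaults to those stored in the trace
#' @param v_tgt target speed; defaults to the one stored in the trace. Pass
#'   `v_tgt = NULL` explicitly via `drop_vel = TRUE` to omit the velocity
#'   cost.
#' @param drop_vel if TRUE, the velocity cost is omitted
#' @param threshold,debounce footstep detection settings
#' @return list: `total`, `r_alive`, `r_footsteps`, `n_footsteps`,
#'   `footsteps` (per-footstep component table)
#' @export
episode_reward <- function(trace, weights = NULL, v_tgt = "trace",
                           drop_vel = FALSE, threshold = 20,
                           debounce = 0.05) {
  if (is.null(weights)) weights <- trace$weights
  if (identical(v_tgt, "trace")) v_tgt <- trace$v_tgt
  if (drop_vel) v_tgt <- NULL
  n <- length(trace$time)
  r_alive <- n * trace$dt
  fs <- detect_footsteps(trace, threshold, debounce)
  comp <- NULL
  r_fs <- 0
  if (nrow(fs) > 0) {
    rows <- lapply(seq_len(nrow(fs)), function(i) {
      idx <- fs$start_step[i]:(fs$end_step[i] - 1L)
      r <- footstep_reward(trace$qdot[idx, 1], trace$q[idx, 3],
                           trace$excitations[idx, , drop = FALSE],
                           trace$dt, v_tgt, weights)
      data.frame(start_step = fs$start_step[i], end_step = fs$end_step[i],
                 leading_foot = fs$leading_foot[i], reward = r$reward,
                 r_steps = r$r_steps, J_vel = r$J_vel, J_pel = r$J_pel,
                 J_mul = r$J_mul, stringsAsFactors = FALSE)
    })
    comp <- do.call(rbind, rows)
    r_fs <- sum(comp$reward)
  }
  list(total = r_alive + r_fs, r_alive = r_alive, r_footsteps = r_fs,
       n_footsteps = nrow(fs), footsteps = comp)
}

#' Write / read an episode trace as CSV + JSON sidecar
#'
#' The CSV has one row per control step with columns `time`, `q1..q9`,
#' `qd1..qd9`, the four GRF channels and `e1..e18`; the JSON sidecar carries
#' the reward breakdown, footstep table and termination cause.
#'
#' @param trace a `gait_trace`
#' @param path CSV path; the sidecar is written next to it as `<path>.json`
#' @return `read_trace` returns a `gait_trace` (without activations)
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = trace$time, trace$q, trace$qdot, trace$grf,
                   trace$excitations)
  names(df) <- c("time", paste0("q", 1:9), paste0("qd", 1:9),
                 colnames(trace$grf), paste0("e", 1:18))
  write.csv(df, path, row.names = FALSE)
  rw <- episode_reward(trace)
  side <- list(
    dt = trace$dt, v_tgt = trace$v_tgt,
    weights = unclass(trace$weights),
    terminated_early = trace$terminated_early, diverged = trace$diverged,
    reward = list(total = rw$total, r_alive = rw$r_alive,
                  r_footsteps = rw$r_footsteps,
                  n_footsteps = rw$n_footsteps),
    footsteps = rw$footsteps
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- do.call(reward_weights, as.list(side$weights))
  build_trace(time = df$time, q = as.matrix(df[, paste0("q", 1:9)]),
              qdot = as.matrix(df[, paste0("qd", 1:9)]),
              grf = as.matrix(df[, c("grf_R_vertical", "grf_R_horizontal",
                                     "grf_L_vertical", "grf_L_horizontal")]),
              excitations = as.matrix(df[, paste0("e", 1:18)]),
              activations = NULL,
              terminated_early = isTRUE(side$terminated_early),
              dt = side$dt,
              v_tgt = if (is.null(side$v_tgt)) NULL else side$v_tgt,
              weights = w, diverged = isTRUE(side$diverged))
}
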