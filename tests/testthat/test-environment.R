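test_that("reset poses the skeleton from the 12 initial-state parameters", {
  m <- fresh_model()
  env <- gait_env(m, horizon = 2, v_tgt = 1.3)
  init <- initial_state(hip_flexion_R = 0.3, forward_speed = 1.1,
                        pelvis_height = 0.95, trunk_lean = 0.07)
  obs <- env$reset(init)
  expect_equal(obs$q[4], 0.3)
  expect_equal(obs$q[2], 0.95)
  expect_equal(obs$q[3], 0.07)
  expect_equal(obs$qdot[1], 1.1)
  # the two non-sagittal entries are documented no-ops
  init2 <- init
  init2["rightward_speed"] <- 0.4
  init2["hip_abduction_R"] <- 0.2
  init2["hip_abduction_L"] <- -0.2
  obs2 <- env$reset(init2)
  expect_identical(obs2$q, obs$q)
  expect_identical(obs2$qdot, obs$qdot)
  # reset is deterministic
  obs3 <- env$reset(init)
  expect_identical(obs3$q, obs$q)
  expect_identical(obs3$activations, obs$activations)
})

test_that("an initial pelvis height at or below 0.6 m is rejected", {
  m <- fresh_model()
  env <- gait_env(m)
  expect_error(env$reset(initial_state(pelvis_height = 0.55)),
               "pelvis height")
  expect_error(run_episode(m, default_controller_params(),
                           initial_state(pelvis_height = 0.6)),
               "pelvis")
})

test_that("step accrues survival reward and terminates on the fall height", {
  # contact switched off: the model is forced into free fall from just above
  # the termination height, so the pelvis crosses 0.6 m within one step
  cfg <- default_model_config()
  cfg$contact$enabled <- FALSE
  env <- gait_env(build_model(cfg), horizon = 5, v_tgt = NULL)
  env$reset(initial_state(pelvis_height = 0.6001, forward_speed = 0,
                          hip_flexion_R = 0, hip_flexion_L = 0,
                          knee_flexion_R = 0, knee_flexion_L = 0,
                          trunk_lean = 0))
  st <- env$step(rep(0, 18))
  expect_true(st$done)
  expect_true(st$info$fell)
  rw <- episode_reward(env$trace())
  expect_identical(rw$total, 0.01)
  expect_identical(rw$n_footsteps, 0L)
  # stepping a finished episode is a contract violation
  expect_error(env$step(rep(0, 18)), "finished")
})

test_that("R_alive equals 0.01 per executed control step on any trace", {
  m <- fresh_model()
  tr <- run_episode(m, default_controller_params(), initial_state(),
                    horizon = 2, v_tgt = 1.3)
  rw <- episode_reward(tr)
  expect_equal(rw$r_alive, 0.01 * length(tr$time), tolerance = 1e-12)
  tr2 <- make_trace(synthetic_trace_spec(duration = 6, step_period = 0.5))
  expect_equal(episode_reward(tr2)$r_alive, 0.01 * length(tr2$time),
               tolerance = 1e-12)
})

test_that("zero excitation decays the activations monotonically", {
  m <- fresh_model()
  env <- gait_env(m, horizon = 1, v_tgt = NULL)
  obs <- env$reset()
  prev <- obs$activations
  for (i in 1:20) {
    st <- env$step(rep(0, 18))
    expect_true(all(st$observation$activations <= prev + 1e-12))
    prev <- st$observation$activations
    if (st$done) break
  }
})

test_that("footstep detection matches the constructed waveform oracle", {
  tr <- make_trace(synthetic_trace_spec(duration = 12, step_period = 0.55,
                                        duty_cycle = 0.6))
  fs <- detect_footsteps(tr)
  rows <- tr$truth$footstep_rows
  expect_equal(fs$start_step, rows[-length(rows)])
  expect_equal(fs$end_step, rows[-1])
  expect_true(all(fs$duration == 0.55))
  # boundaries alternate feet
  expect_true(all(fs$leading_foot[-1] != head(fs$leading_foot, -1)))
  # one foot never loaded: no completed footsteps
  tr1 <- make_trace(synthetic_trace_spec(duration = 6, step_period = 0.5))
  tr1$grf[, "grf_L_vertical"] <- 0
  expect_identical(nrow(detect_footsteps(tr1)), 0L)
})

test_that("threshold chatter within the debounce window yields one event", {
  tr <- make_trace(synthetic_trace_spec(duration = 6, step_period = 0.5))
  # inject 2 unloaded samples (20 ms < 50 ms) in the middle of a stance
  ic <- tr$truth$ic_R[2]
  tr$grf[ic + 10:11, "grf_R_vertical"] <- 0
  fs0 <- detect_footsteps(make_trace(synthetic_trace_spec(duration = 6,
                                                          step_period = 0.5)))
  fs <- detect_footsteps(tr)
  expect_identical(nrow(fs), nrow(fs0))
})

test_that("the hand-computable footstep evaluates to -2.96 exactly", {
  fx <- reference_footstep_fixture()
  r <- footstep_reward(fx$v_pel, fx$theta_pel, fx$excitations, fx$dt,
                       fx$v_tgt)
  expect_equal(r$r_steps, 0.5, tolerance = 1e-12)
  expect_equal(r$J_vel, 0.125, tolerance = 1e-12)
  expect_equal(r$J_pel, 0.005, tolerance = 1e-12)
  expect_equal(r$J_mul, 0.36, tolerance = 1e-12)
  expect_equal(r$reward, -2.96, tolerance = 1e-12)
  # exact tracking zeroes the velocity cost; zero excitation zeroes J_mul
  r2 <- footstep_reward(rep(1.45, 50), fx$theta_pel, fx$excitations,
                        fx$dt, 1.45)
  expect_equal(r2$J_vel, 0)
  r3 <- footstep_reward(fx$v_pel, fx$theta_pel, matrix(0, 50, 18), fx$dt,
                        fx$v_tgt)
  expect_equal(r3$J_mul, 0)
})

test_that("episode reward accounting is exact and linear in the weights", {
  tr <- make_trace(synthetic_trace_spec(duration = 10, step_period = 0.5,
                                        pelvis_speed = 1.2,
                                        pelvis_tilt = 0.1,
                                        excitation = 0.2))
  rw <- episode_reward(tr)
  expect_equal(rw$total, rw$r_alive + sum(rw$footsteps$reward),
               tolerance = 1e-12)
  # doubling w_steps doubles only the step component
  w2 <- reward_weights(w_steps = 20)
  rw2 <- episode_reward(tr, weights = w2)
  d <- rw2$total - rw$total
  expect_equal(d, 10 * sum(rw$footsteps$r_steps), tolerance = 1e-10)
  # dropping the velocity target removes the J_vel term entirely
  rw3 <- episode_reward(tr, drop_vel = TRUE)
  expect_equal(rw3$total - rw$total, 60 * sum(rw$footsteps$J_vel),
               tolerance = 1e-10)
})

test_that("reward is weakly decreasing in excitation level and speed error", {
  base <- synthetic_trace_spec(duration = 8, step_period = 0.5,
                               pelvis_speed = 1.45, excitation = 0.1)
  r0 <- episode_reward(make_trace(base))$total
  up <- base; up$excitation <- 0.3
  expect_lte(episode_reward(make_trace(up))$total, r0)
  off <- base; off$pelvis_speed <- 1.0
  expect_lte(episode_reward(make_trace(off))$total, r0)
})

test_that("the interactive environment reproduces the compiled rollout bit-for-bit", {
  m <- fresh_model()
  p <- default_controller_params()
  init <- initial_state()
  tr_cpp <- run_episode(m, p, init, horizon = 2, v_tgt = 1.3)
  env <- gait_env(m, horizon = 2, v_tgt = 1.3)
  obs <- env$reset(init, p)
  ph <- obs$phases
  repeat {
    ph <- update_phases(ph, obs$grf_R_vertical, obs$grf_L_vertical, 20, 0.01)
    tot <- obs$grf_R_vertical + obs$grf_L_vertical
    ro <- list(f_norm = obs$f_norm, l_norm = obs$l_norm,
               theta = obs$q[3], theta_dot = obs$qdot[3],
               knee = c(obs$q[5], obs$q[8]),
               knee_dot = c(obs$qdot[5], obs$qdot[8]),
               ankle = c(obs$q[6], obs$q[9]),
               ankle_dot = c(obs$qdot[6], obs$qdot[9]),
               load = if (tot > 1e-9)
                 c(obs$grf_R_vertical, obs$grf_L_vertical) / tot
               else c(0, 0))
    a <- compute_excitations(ro, ph, p)
    st <- env$step(a)
    obs <- st$observation
    if (st$done) break
  }
  tr_r <- env$trace()
  expect_identical(dim(tr_r$q), dim(tr_cpp$q))
  expect_equal(tr_r$q, tr_cpp$q, tolerance = 0)
  expect_equal(tr_r$excitations, tr_cpp$excitations, tolerance = 0)
  expect_equal(tr_r$grf, tr_cpp$grf, tolerance = 0)
})

test_that("traces round-trip through CSV plus JSON sidecar", {
  m <- fresh_model()
  tr <- run_episode(m, default_controller_params(), initial_state(),
                    horizon = 1, v_tgt = 1.3)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$q, tr$q, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr2$grf, tr$grf, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(episode_reward(tr2)$total, episode_reward(tr)$total,
               tolerance = 1e-10)
  unlink(c(path, paste0(path, ".json")))
})
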