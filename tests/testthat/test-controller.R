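test_that("pack/unpack round-trips the canonical 37-slot layout", {
  expect_length(controller_param_names(), 37)
  set.seed(21)
  x <- runif(37)
  expect_identical(pack_params(unpack_params(x)), x)
  named <- unpack_params(x)
  expect_named(named, controller_param_names())
  expect_length(pack_params(default_controller_params()), 37)
  expect_error(unpack_params(runif(36)), "37")
  expect_error(pack_params(list(kp_trunk = 1)), "missing")
})

test_that("bound projection clamps baselines into [0, 1] range limits", {
  p <- default_controller_params()
  p["c0_SOL"] <- 2.5
  p["G_F_SOL"] <- -1
  pr <- unpack_params(project_params(pack_params(p)))
  expect_lte(pr["c0_SOL"], 0.3)
  expect_gte(pr["G_F_SOL"], 0)
  b <- controller_param_bounds()
  expect_true(all(project_params(rep(99, 37)) <= b$hi))
  expect_true(all(project_params(rep(-99, 37)) >= b$lo))
})

test_that("zero gains with equal baselines give uniform excitations", {
  p <- rep(0, 37)
  p[24:32] <- 0.05  # the nine co-stimulation baselines
  ro <- blank_readout()
  e <- compute_excitations(ro, both_stance(), p)
  expect_identical(e, rep(0.05, 18))
  e2 <- compute_excitations(ro, both_swing(), p)
  expect_identical(e2, rep(0.05, 18))
})

test_that("stance SOL force feedback reproduces the hand-evaluated law", {
  p <- rep(0, 37)
  p[24:32] <- 0.01
  names37 <- controller_param_names()
  p[match("G_F_SOL", names37)] <- 1.2
  ro <- blank_readout()
  ro$f_norm[muscle_index("SOL")] <- 0.5
  e <- compute_excitations(ro, both_stance(), p)
  expect_equal(e[muscle_index("SOL")], 0.01 + 1.2 * 0.5)  # = 0.61
  expect_equal(e[muscle_index("SOL", "L")], 0.01)
})

test_that("excitations are always inside [0.01, 1] under extreme readouts", {
  set.seed(31)
  for (i in 1:30) {
    p <- runif(37, 0, 5)
    ro <- blank_readout()
    ro$f_norm <- runif(18, 0, 10)
    ro$l_norm <- runif(18, 0, 4)
    ro$theta <- runif(1, -2, 2); ro$theta_dot <- runif(1, -10, 10)
    ro$knee <- runif(2, -2, 2); ro$knee_dot <- runif(2, -20, 20)
    ro$ankle <- runif(2, -2, 2); ro$ankle_dot <- runif(2, -20, 20)
    ro$load <- runif(2)
    ph <- list(stance = runif(2) > 0.5, tsince = runif(2))
    e <- compute_excitations(ro, ph, p)
    expect_true(all(e >= 0.01 & e <= 1))
  }
})

test_that("identical inputs give bit-identical excitations", {
  set.seed(41)
  p <- runif(37)
  ro <- blank_readout()
  ro$f_norm <- runif(18)
  ph <- list(stance = c(TRUE, FALSE), tsince = c(0.2, 0.1))
  expect_identical(compute_excitations(ro, ph, p),
                   compute_excitations(ro, ph, p))
})

test_that("mirrored readouts with swapped phases swap the leg excitations", {
  mirror_ro <- function(ro) {
    sw <- c(10:18, 1:9)
    list(f_norm = ro$f_norm[sw], l_norm = ro$l_norm[sw],
         theta = ro$theta, theta_dot = ro$theta_dot,
         knee = rev(ro$knee), knee_dot = rev(ro$knee_dot),
         ankle = rev(ro$ankle), ankle_dot = rev(ro$ankle_dot),
         load = rev(ro$load))
  }
  set.seed(51)
  for (i in 1:20) {
    p <- runif(37, 0, 3)
    ro <- blank_readout()
    ro$f_norm <- runif(18); ro$l_norm <- runif(18, 0.6, 1.4)
    ro$knee <- runif(2, -0.2, 1); ro$knee_dot <- runif(2, -5, 5)
    ro$ankle <- runif(2, -0.5, 0.5); ro$ankle_dot <- runif(2, -5, 5)
    ro$theta <- runif(1, -0.3, 0.5); ro$theta_dot <- runif(1, -2, 2)
    ro$load <- c(0.7, 0.3)
    ph <- list(stance = c(TRUE, FALSE), tsince = c(0.25, 0.15))
    ph_m <- list(stance = rev(ph$stance), tsince = rev(ph$tsince))
    e <- compute_excitations(ro, ph, p)
    e_m <- compute_excitations(mirror_ro(ro), ph_m, p)
    expect_equal(e_m, e[c(10:18, 1:9)], tolerance = 1e-14)
  }
})

test_that("non-finite readout raises an error naming the channel", {
  p <- default_controller_params()
  ro <- blank_readout()
  ro$f_norm[3] <- NaN
  expect_error(compute_excitations(ro, both_stance(), p), "readout")
})

test_that("phase update follows square-wave GRF threshold crossings", {
  # 1 Hz square wave per leg, 50% duty, sampled at 100 Hz
  dt <- 0.01
  t <- seq(dt, 4, by = dt)
  grf_R <- ifelse((t - dt) %% 1 < 0.5, 500, 0)
  grf_L <- ifelse((t - dt + 0.5) %% 1 < 0.5, 500, 0)
  ph <- init_phases(grf_R[1], grf_L[1])
  stance_hist <- matrix(NA, length(t), 2)
  ds_hist <- logical(length(t))
  transitions <- 0
  prev <- ph$stance
  for (i in seq_along(t)) {
    ph <- update_phases(ph, grf_R[i], grf_L[i], 20, dt)
    stance_hist[i, ] <- ph$stance
    ds_hist[i] <- all(ph$stance)
    transitions <- transitions + sum(ph$stance != prev)
    prev <- ph$stance
  }
  expect_equal(mean(stance_hist[, 1]), 0.5, tolerance = 0.01)
  expect_equal(mean(stance_hist[, 2]), 0.5, tolerance = 0.01)
  # one transition per leg per half-period boundary inside the horizon:
  # boundaries at t = 0.51, 1.01, ..., 3.51 for each leg
  expect_equal(transitions, 14)
  # non-overlapping 50% duty waves: never double support
  expect_false(any(ds_hist))
})

test_that("double support is flagged exactly on overlapping samples", {
  dt <- 0.01
  t <- seq(dt, 4, by = dt)
  grf_R <- ifelse((t - dt) %% 1 < 0.6, 500, 0)
  grf_L <- ifelse((t - dt + 0.5) %% 1 < 0.6, 500, 0)
  ph <- init_phases(grf_R[1], grf_L[1])
  ds <- logical(length(t))
  for (i in seq_along(t)) {
    ph <- update_phases(ph, grf_R[i], grf_L[i], 20, dt)
    ds[i] <- all(ph$stance)
  }
  expect_identical(ds, grf_R >= 20 & grf_L >= 20)
})

test_that("an always-airborne leg stays in swing for the whole horizon", {
  ph <- init_phases(0, 400)
  for (i in 1:500) ph <- update_phases(ph, 0, 400, 20, 0.01)
  expect_false(ph$stance[1])
  expect_true(ph$stance[2])
  expect_equal(ph$tsince[1], 5, tolerance = 1e-9)
})

test_that("controller parameters survive a JSON round trip", {
  p <- default_controller_params()
  path <- tempfile(fileext = ".json")
  save_controller_params(p, path)
  p2 <- load_controller_params(path)
  expect_equal(p2, p, tolerance = 1e-15)
  unlink(path)
})
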