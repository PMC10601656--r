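test_that("activation dynamics: fixed point, closed form, monotone decay", {
  # e = a is a fixed point
  expect_identical(activation_step(0.5, 0.5, 0.01), 0.5)
  # rising step matches the exact exponential 1 - exp(-t/tau_act)
  tau_a <- 0.01; tau_d <- 0.04
  a <- 0
  n <- 100; dt <- 1e-3
  for (i in 1:n) a <- activation_step(a, 1, dt, tau_a, tau_d)
  expect_equal(a, 1 - exp(-n * dt / tau_a), tolerance = 1e-6)
  # falling from 1 toward 0: monotone, never below 0
  a <- 1
  prev <- a
  for (i in 1:200) {
    a <- activation_step(a, 0, dt, tau_a, tau_d)
    expect_lte(a, prev)
    expect_gte(a, 0)
    prev <- a
  }
  expect_equal(prev, exp(-200 * dt / tau_d), tolerance = 1e-6)
})

test_that("MTU lengths are linear in joint angles with the signed moment arms", {
  m <- fresh_model()
  q0 <- standing_pose(m$config)
  mk0 <- mtu_kinematics(m, q0)
  expect_equal(mk0$l_mt, m$config$muscles$mtu_ref_length, tolerance = 1e-12)
  # knee flexion lengthens the VAS (extensor, negative moment arm) by |r|*dq
  dq <- 0.3
  q1 <- q0; q1[5] <- q1[5] + dq
  mk1 <- mtu_kinematics(m, q1)
  i_vas <- muscle_index("VAS")
  r_vas <- m$config$muscles$r_knee[i_vas]
  expect_lt(r_vas, 0)
  expect_equal(mk1$l_mt[i_vas] - mk0$l_mt[i_vas], abs(r_vas) * dq,
               tolerance = 1e-12)
  # finite-difference of l_mt along a prescribed q(t) equals v_mt
  set.seed(3)
  qdot <- runif(9, -2, 2)
  eps <- 1e-7
  qa <- q0 + (0.1 - eps) * qdot
  qb <- q0 + (0.1 + eps) * qdot
  la <- mtu_kinematics(m, qa)$l_mt
  lb <- mtu_kinematics(m, qb)$l_mt
  v <- mtu_kinematics(m, q0 + 0.1 * qdot, qdot)$v_mt
  expect_equal((lb - la) / (2 * eps), v, tolerance = 1e-6)
})

test_that("isometric force at optimal length equals MIF exactly", {
  tab <- default_muscle_table()
  for (i in c(1, 5, 8)) {
    f <- muscle_force(a = 1, l_mt = tab$lslack[i] + tab$lopt[i], v_mt = 0,
                      mif = tab$mif[i], lopt = tab$lopt[i],
                      lslack = tab$lslack[i])
    expect_equal(f$force, tab$mif[i], tolerance = 1e-12)
    expect_false(f$geometry_warning)
  }
})

test_that("force-velocity endpoints and eccentric plateau", {
  expect_equal(force_velocity_curve(0), 1)
  expect_equal(force_velocity_curve(-1), 0)
  expect_lt(force_velocity_curve(50), 1.5)
  expect_gt(force_velocity_curve(0.5), 1)
  # shortening at v_max zeroes the active term regardless of activation
  tab <- default_muscle_table()
  i <- 8  # SOL
  f <- muscle_force(a = 0.7, l_mt = tab$lslack[i] + tab$lopt[i],
                    v_mt = -tab$vmax[i] * tab$lopt[i],
                    mif = tab$mif[i], lopt = tab$lopt[i],
                    lslack = tab$lslack[i])
  expect_equal(f$force, 0, tolerance = 1e-12)
})

test_that("force-length curve peaks at optimal length", {
  grid <- seq(0.5, 1.6, by = 0.01)
  fl <- force_length_curve(grid)
  expect_equal(grid[which.max(fl)], 1)
  expect_equal(max(fl), 1)
})

test_that("passive force alone is produced at zero activation", {
  tab <- default_muscle_table()
  i <- 5  # VAS
  lnorm <- 1.3
  f <- muscle_force(a = 0, l_mt = tab$lslack[i] + lnorm * tab$lopt[i],
                    v_mt = 0, mif = tab$mif[i], lopt = tab$lopt[i],
                    lslack = tab$lslack[i])
  expect_equal(f$force, tab$mif[i] * passive_force_curve(lnorm),
               tolerance = 1e-12)
  expect_gt(f$force, 0)
  # below optimal length the passive element is disengaged
  expect_identical(passive_force_curve(0.95), 0)
})

test_that("non-positive fiber length yields zero force and a geometry warning", {
  f <- muscle_force(a = 1, l_mt = 0.2, v_mt = 0, mif = 1000, lopt = 0.1,
                    lslack = 0.25)
  expect_equal(f$force, 0)
  expect_true(f$geometry_warning)
})

test_that("force is non-negative and monotone in activation", {
  m <- fresh_model()
  set.seed(5)
  for (i in 1:20) {
    q <- c(0, runif(1, 0.7, 1.1), runif(7, -0.6, 0.6))
    qdot <- runif(9, -3, 3)
    a1 <- runif(18)
    a2 <- pmin(1, a1 + runif(18, 0, 0.2))
    f1 <- muscle_forces(m, a1, q, qdot)
    f2 <- muscle_forces(m, a2, q, qdot)
    expect_true(all(f1 >= 0))
    expect_true(all(f2 >= f1 - 1e-12))
  }
})

test_that("joint torques match a brute-force loop over muscle-joint pairs", {
  m <- fresh_model()
  expect_identical(joint_torques_from_muscles(m, rep(0, 18)), rep(0, 6))
  # right SOL alone plantarflexes only the right ankle
  f <- rep(0, 18)
  i_sol <- muscle_index("SOL")
  f[i_sol] <- 1234
  tau <- joint_torques_from_muscles(m, f)
  r_sol <- m$config$muscles$r_ankle[i_sol]
  expect_equal(tau, c(0, 0, r_sol * 1234, 0, 0, 0), tolerance = 1e-12)
  expect_lt(tau[3], 0)  # plantarflexion
  # random force vector vs an independent summation oracle
  set.seed(13)
  f <- runif(18, 0, 2000)
  tab <- m$config$muscles
  oracle <- numeric(6)
  for (k in 1:18) {
    j0 <- if (tab$side[k] == "R") 0 else 3
    oracle[j0 + 1] <- oracle[j0 + 1] + tab$r_hip[k] * f[k]
    oracle[j0 + 2] <- oracle[j0 + 2] + tab$r_knee[k] * f[k]
    oracle[j0 + 3] <- oracle[j0 + 3] + tab$r_ankle[k] * f[k]
  }
  expect_equal(joint_torques_from_muscles(m, f), oracle, tolerance = 1e-10)
})

test_that("scaling MIF scales isometric force and joint torque exactly", {
  cfg <- default_model_config()
  for (s in c(0.8, 0.6)) {
    cfg_w <- scale_muscle_mif(cfg, "SOL", s)
    i_sol <- muscle_index("SOL")
    tab <- cfg$muscles
    f0 <- muscle_force(1, tab$lslack[i_sol] + tab$lopt[i_sol], 0,
                       tab$mif[i_sol], tab$lopt[i_sol],
                       tab$lslack[i_sol])$force
    fw <- muscle_force(1, tab$lslack[i_sol] + tab$lopt[i_sol], 0,
                       cfg_w$muscles$mif[i_sol], tab$lopt[i_sol],
                       tab$lslack[i_sol])$force
    expect_equal(fw, s * f0, tolerance = 1e-12)
    # whole-model force vector scales only on the weakened muscle, both sides
    m0 <- build_model(cfg); mw <- build_model(cfg_w)
    q <- standing_pose(cfg)
    a <- rep(0.6, 18)
    F0 <- muscle_forces(m0, a, q)
    Fw <- muscle_forces(mw, a, q)
    sel <- cfg$muscles$name == "SOL"
    expect_equal(Fw[sel], s * F0[sel], tolerance = 1e-12)
    expect_equal(Fw[!sel], F0[!sel], tolerance = 1e-12)
  }
})
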