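test_that("mass matrix matches the finite-difference Jacobian oracle and is SPD", {
  m <- fresh_model()
  set.seed(42)
  for (i in 1:100) {
    q <- c(runif(1, -1, 1), runif(1, 0.5, 1.5), runif(7, -1, 1))
    M <- mass_matrix(m, q)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    if (i <= 10) {
      # full oracle comparison on a subset (the oracle is slow)
      expect_equal(M, oracle_mass_matrix(m$config, q), tolerance = 1e-6)
    }
  }
})

test_that("passive pendulum conserves energy to within 0.1% over 5 s", {
  m <- pendulum_model()
  q0 <- c(0, 2, 0.3, 0.4, 0.3, 0.1, -0.3, 0.2, -0.1)
  pr <- passive_simulate(m, q0, rep(0, 9), 5, h = 1e-4, record_every = 100)
  e0 <- pr$energy[1]
  drift <- max(abs(pr$energy - e0)) / abs(e0)
  expect_lt(drift, 0.001)
})

test_that("free fall with doubled gravity matches the closed form", {
  m <- free_model(gravity = 2 * 9.81)
  q0 <- c(0, 5, rep(0, 7))
  h <- 1e-4
  pr <- passive_simulate(m, q0, rep(0, 9), 0.5, h = h, record_every = 100)
  n <- length(pr$time)
  expected <- 5 - 0.5 * (2 * 9.81) * pr$time^2
  # symplectic Euler carries a half-step velocity offset: O(g h t)
  expect_lt(max(abs(pr$q[, 2] - expected)), 2 * 9.81 * h * pr$time[n])
  expect_equal(pr$q[n, 2], expected[n], tolerance = 1e-3)
})

test_that("static equilibrium pose stays at rest for one second", {
  m <- fresh_model()
  eq <- find_static_equilibrium(m)
  expect_lt(eq$residual, 1e-6)
  pr <- passive_simulate(m, eq$q, rep(0, 9), 1.0, h = 1e-3,
                         record_every = 1000)
  n <- length(pr$time)
  expect_lt(sqrt(sum(pr$qdot[n, ]^2)), 1e-3)
})

test_that("static single-support-style stance balances body weight within 1%", {
  m <- fresh_model()
  eq <- find_static_equilibrium(m)
  cc <- compute_contact(m, eq$q, rep(0, 9))
  weight <- sum(m$config$segments$mass) * m$config$gravity
  expect_equal(cc$vertical_R + cc$vertical_L, weight, tolerance = 0.01)
  # all load on one leg: lift the other foot well off the ground
  q1 <- eq$q
  q1[7] <- 0.6   # left hip flexion
  q1[8] <- 1.2   # left knee flexion
  vert <- function(y) {
    q <- q1; q[2] <- y
    cc <- compute_contact(m, q, rep(0, 9))
    cc$vertical_R + cc$vertical_L - weight
  }
  q1[2] <- uniroot(vert, c(q1[2] - 0.08, q1[2] + 0.05), tol = 1e-12)$root
  cc1 <- compute_contact(m, q1, rep(0, 9))
  expect_equal(cc1$vertical_L, 0)
  expect_equal(cc1$vertical_R, weight, tolerance = 0.01)
})

test_that("airborne feet carry exactly zero contact force", {
  m <- fresh_model()
  q <- c(0, 2, 0.1, 0.3, 0.4, -0.1, -0.2, 0.5, 0.2)
  cc <- compute_contact(m, q, c(1, -2, rep(0.5, 7)))
  expect_identical(cc$normal, rep(0, 4))
  expect_identical(cc$tangential, rep(0, 4))
})

test_that("fast sliding saturates friction at mu times the normal force", {
  m <- fresh_model()
  q <- standing_pose(m$config)
  q[2] <- q[2] - 0.01             # penetrate 1 cm
  qdot <- c(2, 0, rep(0, 7))      # slide forward at 2 m/s >> v_smooth
  cc <- compute_contact(m, q, qdot)
  mu <- m$config$contact$mu
  loaded <- cc$normal > 0
  expect_true(any(loaded))
  ratio <- abs(cc$tangential[loaded]) / cc$normal[loaded]
  expect_equal(ratio, rep(mu, sum(loaded)), tolerance = 1e-10)
  expect_true(all(cc$tangential[loaded] < 0))  # opposes forward sliding
})

test_that("contact normal forces are never negative along a rollout", {
  m <- fresh_model()
  tr <- run_episode(m, default_controller_params(), initial_state(),
                    horizon = 3, v_tgt = 1.3)
  expect_true(all(tr$grf[, c("grf_R_vertical", "grf_L_vertical")] >= 0))
})

test_that("mechanical energy agrees with the per-segment hand summation", {
  m <- fresh_model()
  set.seed(7)
  for (i in 1:5) {
    q <- c(runif(1, -1, 1), runif(1, 0.7, 1.3), runif(7, -0.8, 0.8))
    en <- total_mechanical_energy(m, q, rep(0, 9))
    expect_equal(en$kinetic, 0)
    expect_equal(en$potential, oracle_potential_energy(m$config, q),
                 tolerance = 1e-10)
  }
  # rigid translation at speed v: KE = 1/2 (sum m) v^2 exactly
  v <- 1.7
  en <- total_mechanical_energy(m, standing_pose(m$config),
                                c(v, rep(0, 8)))
  expect_equal(en$kinetic, 0.5 * sum(m$config$segments$mass) * v^2,
               tolerance = 1e-12)
  # energy is non-negative once the datum sits at the lowest configuration
  qlow <- c(0, 0.02, rep(0, 7))  # pelvis nearly at ground
  elow <- total_mechanical_energy(m, qlow, rep(0, 9))$potential
  expect_gte(total_mechanical_energy(m, standing_pose(m$config),
                                     rep(0, 9))$total - elow, 0)
})

test_that("exchanging the legs mirrors the accelerations exactly", {
  m <- fresh_model()
  set.seed(11)
  for (i in 1:20) {
    q <- c(runif(1, -1, 1), runif(1, 0.6, 1.2), runif(7, -0.7, 0.7))
    qdot <- runif(9, -2, 2)
    tau <- runif(6, -50, 50)
    a1 <- joint_accelerations(m, q, qdot, tau)
    a2 <- joint_accelerations(m, swap_legs_q(q), swap_legs_q(qdot),
                              swap_legs_tau(tau))
    expect_equal(a2, swap_legs_q(a1), tolerance = 1e-9)
  }
})

test_that("a diverging state raises a simulation-diverged error", {
  m <- fresh_model()
  q <- standing_pose(m$config)
  expect_error(
    forward_dynamics_step(m, q, rep(1e10, 9), rep(1e8, 6), h = 1,
                          n_substeps = 50),
    "diverged")
})
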