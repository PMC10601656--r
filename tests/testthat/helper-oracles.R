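# Independent R-side oracles for the compiled dynamics. These re-derive the
# kinematics from scratch (plain rotation matrices, numerical Jacobians) and
# never call the package's compiled routines.

rot2 <- function(psi) {
  matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
}

# Segment orientation angles (CCW positive), linear in q.
# q = (x, y, pitch, hipR, kneeR, ankleR, hipL, kneeL, ankleL)
oracle_angle_rows <- function() {
  W <- matrix(0, 7, 9)
  W[1, 3] <- -1
  W[2, c(3, 4)] <- c(-1, 1)
  W[3, c(3, 4, 5)] <- c(-1, 1, -1)
  W[4, c(3, 4, 5, 6)] <- c(-1, 1, -1, 1)
  W[5, c(3, 7)] <- c(-1, 1)
  W[6, c(3, 7, 8)] <- c(-1, 1, -1)
  W[7, c(3, 7, 8, 9)] <- c(-1, 1, -1, 1)
  W
}

# 7 x 2 matrix of segment COM positions (HAT, thighR, shankR, footR, left...)
oracle_com_positions <- function(cfg, q) {
  seg <- cfg$segments
  gl <- function(nm, col) seg[[col]][seg$name == nm]
  hip <- q[1:2]
  W <- oracle_angle_rows()
  psi <- as.numeric(W %*% q)
  out <- matrix(NA_real_, 7, 2)
  out[1, ] <- hip + rot2(psi[1]) %*% c(0, gl("HAT", "com_offset"))
  legs <- list(R = list(b = 2:4, jq = 4:6), L = list(b = 5:7, jq = 7:9))
  for (s in names(legs)) {
    b <- legs[[s]]$b
    tl <- gl(paste0("thigh_", s), "length"); tc <- gl(paste0("thigh_", s), "com_offset")
    sl <- gl(paste0("shank_", s), "length"); sc <- gl(paste0("shank_", s), "com_offset")
    out[b[1], ] <- hip + rot2(psi[b[1]]) %*% c(0, -tc)
    knee <- hip + rot2(psi[b[1]]) %*% c(0, -tl)
    out[b[2], ] <- knee + rot2(psi[b[2]]) %*% c(0, -sc)
    ankle <- knee + rot2(psi[b[2]]) %*% c(0, -sl)
    out[b[3], ] <- ankle + rot2(psi[b[3]]) %*% cfg$foot$com
  }
  out
}

# finite-difference COM Jacobians -> mass matrix by summation over segments
oracle_mass_matrix <- function(cfg, q, eps = 1e-6) {
  seg <- cfg$segments
  W <- oracle_angle_rows()
  M <- matrix(0, 9, 9)
  J <- array(0, c(7, 2, 9))
  for (j in 1:9) {
    qp <- q; qp[j] <- qp[j] + eps
    qm <- q; qm[j] <- qm[j] - eps
    J[, , j] <- (oracle_com_positions(cfg, qp) -
                   oracle_com_positions(cfg, qm)) / (2 * eps)
  }
  for (b in 1:7) {
    Jb <- J[b, , ]
    M <- M + seg$mass[b] * (t(Jb) %*% Jb) +
      seg$inertia[b] * (W[b, ] %o% W[b, ])
  }
  M
}

oracle_potential_energy <- function(cfg, q) {
  p <- oracle_com_positions(cfg, q)
  sum(cfg$segments$mass * cfg$gravity * p[, 2])
}

# leg-exchange permutation of a 9-vector (swap right and left leg coordinates)
swap_legs_q <- function(q) q[c(1, 2, 3, 7, 8, 9, 4, 5, 6)]
swap_legs_tau <- function(tau) tau[c(4, 5, 6, 1, 2, 3)]

# model variants used across tests (built once per test file run)
fresh_model <- function(...) {
  cfg <- default_model_config()
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  build_model(cfg)
}

pendulum_model <- function() {
  cfg <- default_model_config()
  cfg$contact$enabled <- FALSE
  cfg$limits_enabled <- FALSE
  cfg$base_pinned <- TRUE
  build_model(cfg)
}

free_model <- function(gravity = 9.81) {
  cfg <- default_model_config()
  cfg$contact$enabled <- FALSE
  cfg$limits_enabled <- FALSE
  cfg$gravity <- gravity
  build_model(cfg)
}

# a readout filled with zeros, for controller unit tests
blank_readout <- function() {
  list(f_norm = rep(0, 18), l_norm = rep(1, 18), theta = 0, theta_dot = 0,
       knee = c(0, 0), knee_dot = c(0, 0), ankle = c(0, 0),
       ankle_dot = c(0, 0), load = c(0.5, 0.5))
}

both_stance <- function() list(stance = c(TRUE, TRUE), tsince = c(0.3, 0.1))
both_swing <- function() list(stance = c(FALSE, FALSE), tsince = c(0.1, 0.1))

muscle_index <- function(name, side = "R") {
  base <- match(name, c("ILPSO", "GMAX", "HAM", "RF", "VAS", "BFSH", "GAS",
                        "SOL", "TA"))
  base + if (side == "L") 9L else 0L
}
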