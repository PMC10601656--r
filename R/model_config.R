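#' Default planar musculoskeletal model configuration
#'
#' Builds the full parameter set of the walking plant: seven rigid segments
#' (HAT = head-arms-trunk-pelvis, left/right thigh, shank, foot), six internal
#' flexion/extension degrees of freedom (hips, knees, ankles) plus the planar
#' floating base (x, y, pitch), Hunt-Crossley foot-ground contact at a heel and
#' a toe point per foot, soft joint-limit stops, and 18 Hill-type muscle-tendon
#' units with constant moment arms and rigid tendons.
#'
#' Anthropometry defaults approximate a 1.80 m, 75 kg adult with segment masses
#' closing to total body mass (HAT including pelvis carries about 61%). All
#' values are plain list entries and may be overridden before building the
#' model. Units are SI throughout; angles in radians, flexion/dorsiflexion
#' positive, anterior pelvis tilt positive.
#'
#' @param total_mass body mass in kg used only for documentation/BW scaling;
#'   the per-segment masses below are authoritative.
#' @return an object of class `gait_model_config` (a named list).
#' @export
default_model_config <- function(total_mass = 75) {
  segments <- data.frame(
    name = c("HAT", "thigh_R", "shank_R", "foot_R",
             "thigh_L", "shank_L", "foot_L"),
    mass = c(46.0, 9.3, 3.7, 1.25, 9.3, 3.7, 1.25),
    length = c(0.80, 0.41, 0.43, 0.25, 0.41, 0.43, 0.25),
    com_offset = c(0.35, 0.18, 0.19, 0.12, 0.18, 0.19, 0.12),
    inertia = c(2.45, 0.130, 0.057, 0.0065, 0.130, 0.057, 0.0065),
    stringsAsFactors = FALSE
  )
  joints <- data.frame(
    name = c("hip_R", "knee_R", "ankle_R", "hip_L", "knee_L", "ankle_L"),
    lo = rep(c(-30, 0, -60) * pi / 180, 2),
    hi = rep(c(120, 120, 40) * pi / 180, 2),
    stringsAsFactors = FALSE
  )
  cfg <- list(
    segments = segments,
    # foot-local geometry (origin at ankle, x forward, y up), metres
    foot = list(heel = c(-0.06, -0.07), toe = c(0.19, -0.07),
                com = c(0.05, -0.04)),
    gravity = 9.81,
    joints = joints,
    joint_limit_stiffness = 300,  # N*m/rad outside the stop
    joint_limit_damping = 5,      # N*m*s/rad, resisting only
    limits_enabled = TRUE,
    contact = list(k = 8e4, dissipation = 1.0, mu = 0.9, v_smooth = 0.05,
                   threshold = 20, enabled = TRUE),
    base_pinned = FALSE,  # hold pelvis translation fixed (suspension tests)
    muscles = default_muscle_table(),
    activation = list(tau_act = 0.01, tau_deact = 0.04),
    curves = list(fl_width = 0.45, fv_K = 0.25, fv_ecc_max = 1.5,
                  fpe_k = 4, fpe_e0 = 0.6),
    dt = 0.01,         # control interval, s
    n_substeps = 10,   # integrator substeps per control interval (h = 1e-3 s)
    pelvis_min = 0.6,  # termination height, m
    total_mass = total_mass
  )
  class(cfg) <- "gait_model_config"
  cfg
}

#' Default 18-muscle parameter table
#'
#' One row per muscle-tendon unit, bilaterally symmetric: maximum isometric
#' force (MIF, N), optimal fiber length (m), tendon slack length (m), maximum
#' contraction velocity (optimal lengths/s) and signed constant moment arms (m)
#' about the spanned joints (flexion/dorsiflexion positive). HAM, RF and GAS
#' are biarticular; the rest span a single joint.
#'
#' With a rigid tendon all MTU excursion goes into the fiber, so each
#' muscle's operating range is anchored through `standing_lnorm`, the
#' normalized fiber length in the reference standing posture: extensors that
#' stretch in flexion sit on the ascending limb (0.8-0.9), keeping
#' physiological joint excursions within sensible passive-force territory.
#' `mtu_ref_length = lslack + standing_lnorm * lopt`; see
#' [tune_ref_lengths()] to renormalize for other postures.
#'
#' @return data.frame with 18 rows in canonical order (right leg ILPSO, GMAX,
#'   HAM, RF, VAS, BFSH, GAS, SOL, TA, then the left leg).
#' @export
default_muscle_table <- function() {
  base <- data.frame(
    name = c("ILPSO", "GMAX", "HAM", "RF", "VAS", "BFSH", "GAS", "SOL", "TA"),
    mif = c(2000, 1500, 3000, 1200, 6000, 350, 1500, 4000, 800),
    lopt = c(0.11, 0.11, 0.12, 0.10, 0.11, 0.12, 0.06, 0.05, 0.06),
    lslack = c(0.14, 0.13, 0.31, 0.35, 0.23, 0.10, 0.40, 0.26, 0.24),
    vmax = rep(10, 9),
    r_hip = c(0.05, -0.06, -0.06, 0.04, 0, 0, 0, 0, 0),
    r_knee = c(0, 0, 0.03, -0.045, -0.045, 0.03, 0.02, 0, 0),
    r_ankle = c(0, 0, 0, 0, 0, 0, -0.05, -0.05, 0.04),
    standing_lnorm = c(1.00, 0.85, 0.90, 0.80, 0.80, 1.05, 0.90, 0.90, 0.95),
    stringsAsFactors = FALSE
  )
  tab <- rbind(transform(base, side = "R"), transform(base, side = "L"))
  tab$mtu_ref_length <- tab$lslack + tab$standing_lnorm * tab$lopt
  rownames(tab) <- paste(tab$name, tab$side, sep = "_")
  tab
}

#' Renormalize MTU reference lengths for a chosen posture
#'
#' Sets each muscle's `mtu_ref_length` so that, at the supplied posture, the
#' normalized fiber length equals `target` (default 1, i.e. optimal length).
#' With rigid tendons `l_fiber = l_mt - l_slack` and
#' `l_mt = ref - sum_j r_j q_j`, so
#' `ref = l_slack + target * l_opt + sum_j r_j q_j`.
#'
#' @param config a `gait_model_config`
#' @param q 9-vector posture (only the 6 internal joint angles matter)
#' @param target normalized fiber length at the posture, in `[0.7, 1.1]`
#' @return the config with an updated muscle table
#' @export
tune_ref_lengths <- function(config, q = standing_pose(config), target = 1.0) {
  stopifnot(inherits(config, "gait_model_config"),
            target >= 0.7, target <= 1.1)
  tab <- config$muscles
  qj <- q[4:9]
  R <- moment_arm_matrix(tab)
  tab$mtu_ref_length <- tab$lslack + target * tab$lopt + as.numeric(R %*% qj)
  config$muscles <- tab
  config
}

# 18 x 6 signed moment arm matrix; joint order hipR kneeR ankleR hipL kneeL ankleL
moment_arm_matrix <- function(tab) {
  R <- matrix(0, nrow(tab), 6)
  right <- tab$side == "R"
  R[right, 1] <- tab$r_hip[right]
  R[right, 2] <- tab$r_knee[right]
  R[right, 3] <- tab$r_ankle[right]
  R[!right, 4] <- tab$r_hip[!right]
  R[!right, 5] <- tab$r_knee[!right]
  R[!right, 6] <- tab$r_ankle[!right]
  R
}

#' Validate a model configuration
#'
#' Checks the structural invariants: exactly 7 segments with positive masses,
#' lengths and inertias and COM offsets inside the segment; exactly 6 joint
#' limit pairs with `lo < hi`; 18 bilaterally symmetric muscles with positive
#' MIF and optimal length and activation faster than deactivation; contact
#' stiffness positive and friction in (0, 2]; heel posterior to toe.
#'
#' @param config a `gait_model_config`
#' @return the config, invisibly; stops with an informative message otherwise
#' @export
validate_model_config <- function(config) {
  seg <- config$segments
  if (nrow(seg) != 7) stop("expected exactly 7 segments, got ", nrow(seg))
  if (any(seg$mass <= 0)) stop("segment masses must be positive")
  if (any(seg$length <= 0)) stop("segment lengths must be positive")
  if (any(seg$inertia <= 0)) stop("segment inertias must be positive")
  if (any(seg$com_offset < 0 | seg$com_offset > seg$length))
    stop("com_offset must lie within [0, length] for every segment")
  jt <- config$joints
  if (nrow(jt) != 6) stop("expected exactly 6 internal joint limit pairs")
  if (any(jt$lo >= jt$hi)) stop("joint limits need lo < hi")
  mus <- config$muscles
  if (nrow(mus) != 18) stop("expected exactly 18 muscle-tendon units")
  if (any(mus$mif <= 0) || any(mus$lopt <= 0))
    stop("muscle MIF and optimal fiber length must be positive")
  r <- mus[mus$side == "R", c("mif", "lopt", "lslack", "vmax")]
  l <- mus[mus$side == "L", c("mif", "lopt", "lslack", "vmax")]
  if (!isTRUE(all.equal(r, l, check.attributes = FALSE)))
    stop("muscle parameters must be bilaterally symmetric")
  biart <- mus$name %in% c("HAM", "RF", "GAS")
  n_joints <- rowSums(abs(mus[, c("r_hip", "r_knee", "r_ankle")]) > 0)
  if (any(n_joints[biart] != 2) || any(n_joints[!biart] != 1))
    stop("HAM, RF, GAS must span 2 joints; all other muscles exactly 1")
  if (config$activation$tau_act >= config$activation$tau_deact)
    stop("tau_act must be smaller than tau_deact")
  ct <- config$contact
  if (ct$k <= 0) stop("contact stiffness must be positive")
  if (ct$mu <= 0 || ct$mu > 2) stop("friction coefficient must be in (0, 2]")
  if (config$foot$heel[1] >= config$foot$toe[1])
    stop("heel contact point must be posterior to the toe")
  invisible(config)
}

#' Build the compiled model
#'
#' Flattens a validated configuration into the compiled plant used by the
#' dynamics, muscle and rollout routines. The returned object carries both the
#' original configuration and an external pointer to the compiled structure;
#' it is what every simulation function expects.
#'
#' @param config a `gait_model_config`, defaults to [default_model_config()]
#' @return object of class `gait_model`
#' @export
build_model <- function(config = default_model_config()) {
  validate_model_config(config)
  seg <- config$segments
  mus <- config$muscles
  flat <- list(
    mass = seg$mass,
    inertia = seg$inertia,
    hat_com = seg$com_offset[seg$name == "HAT"],
    thigh_len = seg$length[seg$name == "thigh_R"],
    thigh_com = seg$com_offset[seg$name == "thigh_R"],
    shank_len = seg$length[seg$name == "shank_R"],
    shank_com = seg$com_offset[seg$name == "shank_R"],
    foot_com = config$foot$com, heel = config$foot$heel, toe = config$foot$toe,
    gravity = config$gravity,
    joint_lo = config$joints$lo, joint_hi = config$joints$hi,
    limit_k = config$joint_limit_stiffness,
    limit_d = config$joint_limit_damping,
    limits_enabled = isTRUE(config$limits_enabled),
    contact_k = config$contact$k, contact_c = config$contact$dissipation,
    contact_mu = config$contact$mu, contact_vs = config$contact$v_smooth,
    contact_threshold = config$contact$threshold,
    contact_enabled = isTRUE(config$contact$enabled),
    base_pinned = isTRUE(config$base_pinned),
    muscles = list(
      mif = mus$mif, lopt = mus$lopt, lslack = mus$lslack, vmax = mus$vmax,
      lref = mus$mtu_ref_length, moment_arm = moment_arm_matrix(mus),
      tau_act = config$activation$tau_act,
      tau_deact = config$activation$tau_deact,
      fl_width = config$curves$fl_width, fv_K = config$curves$fv_K,
      fv_ecc_max = config$curves$fv_ecc_max,
      fpe_k = config$curves$fpe_k, fpe_e0 = config$curves$fpe_e0
    )
  )
  model <- list(ptr = build_model_cpp(flat), config = config)
  class(model) <- "gait_model"
  model
}

#' @export
print.gait_model <- function(x, ...) {
  cfg <- x$config
  cat("<gait_model> planar biped\n")
  cat("  segments:", nrow(cfg$segments),
      sprintf("(total mass %.1f kg)", sum(cfg$segments$mass)), "\n")
  cat("  DOF: 9 (3 floating base + 6 internal)\n")
  cat("  muscles:", nrow(cfg$muscles), "Hill-type, rigid tendon\n")
  cat("  contact: Hunt-Crossley, k =", cfg$contact$k,
      "mu =", cfg$contact$mu, "\n")
  invisible(x)
}

as_gait_model <- function(model) {
  if (inherits(model, "gait_model")) return(model)
  if (inherits(model, "gait_model_config")) return(build_model(model))
  stop("expected a gait_model or gait_model_config")
}

#' Scale a muscle's maximum isometric force (weakness protocol)
#'
#' Multiplies the named muscle's MIF bilaterally by `scale`, leaving every
#' other model parameter untouched. Scaling MIF scales isometric muscle force
#' and its joint-torque contribution exactly proportionally.
#'
#' @param config a `gait_model_config`
#' @param muscle one of "ILPSO","GMAX","HAM","RF","VAS","BFSH","GAS","SOL","TA"
#' @param scale positive multiplier, e.g. 0.8 or 0.6 for 80%/60% strength
#' @return modified config
#' @export
scale_muscle_mif <- function(config, muscle, scale) {
  stopifnot(inherits(config, "gait_model_config"), scale > 0)
  muscle <- match.arg(muscle, unique(config$muscles$name))
  sel <- config$muscles$name == muscle
  if (!any(sel)) stop("unknown muscle: ", muscle)
  config$muscles$mif[sel] <- config$muscles$mif[sel] * scale
  config
}

#' Standing posture
#'
#' Generalized coordinates of the reference standing pose: pelvis above the
#' ankles at hip height (thigh + shank + ankle height above sole), all
#' internal angles zero. The feet rest on the ground plane (y = 0) with a tiny
#' penetration left for the compliant contact to carry weight.
#'
#' @param config a `gait_model_config`
#' @return 9-vector q
#' @export
standing_pose <- function(config = default_model_config()) {
  seg <- config$segments
  hip_h <- seg$length[seg$name == "thigh_R"] +
    seg$length[seg$name == "shank_R"] - config$foot$heel[2]
  c(0, hip_h, rep(0, 7))
}
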