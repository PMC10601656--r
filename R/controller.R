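#' Canonical names of the 37 reflex-controller parameters
#'
#' The controller is bilaterally shared: one scalar per slot serves both legs.
#' Slots, in order: three target angles (trunk lean, swing knee, swing ankle);
#' stance force-feedback gains for SOL, GAS, VAS, HAM, GMAX; the swing HAM
#' force gain; TA length-feedback gain and offset; SOL-to-TA inhibition gain;
#' swing ILPSO length-feedback gain and offset; swing BFSH velocity gain;
#' stance knee damping gain; knee overextension-guard gain and threshold;
#' trunk PD gains and the HAM/GMAX/ILPSO distribution weights; nine
#' co-stimulation baselines (muscle order ILPSO, GMAX, HAM, RF, VAS, BFSH,
#' GAS, SOL, TA); swing ankle and knee PD gains; and the double-support
#' push-off boost.
#'
#' @return character vector of length 37
#' @export
controller_param_names <- function() {
  c("theta_tgt_trunk", "theta_tgt_knee_swing", "theta_tgt_ankle_swing",
    "G_F_SOL", "G_F_GAS", "G_F_VAS", "G_F_HAM_stance", "G_F_GMAX_stance",
    "G_F_HAM_swing", "G_L_TA", "l_off_TA", "G_SOLTA", "G_L_ILPSO_swing",
    "l_off_ILPSO", "G_V_BFSH_swing", "G_V_knee_stance", "k_overext",
    "phi_knee_off", "kp_trunk", "kd_trunk", "w_HAM", "w_GMAX", "w_ILPSO",
    paste0("c0_", c("ILPSO", "GMAX", "HAM", "RF", "VAS", "BFSH", "GAS",
                    "SOL", "TA")),
    "kp_ankle_swing", "kd_ankle_swing", "kp_knee_swing", "kd_knee_swing",
    "e_DS")
}

#' Physical bounds of the 37 controller parameters
#'
#' Used for bound projection and to map the optimizer's normalized unit box
#' onto physical units. Gains live in `[0, 3]`-ish ranges, length offsets in
#' optimal-length units, target angles inside the joint ranges, baselines in
#' `[0, 0.3]`.
#'
#' @return data.frame with columns `name`, `lo`, `hi`
#' @export
controller_param_bounds <- function() {
  nm <- controller_param_names()
  lo <- setNames(numeric(37), nm)
  hi <- setNames(numeric(37), nm)
  lo["theta_tgt_trunk"] <- -0.2;  hi["theta_tgt_trunk"] <- 0.4
  lo["theta_tgt_knee_swing"] <- 0;  hi["theta_tgt_knee_swing"] <- 1.4
  lo["theta_tgt_ankle_swing"] <- -0.5;  hi["theta_tgt_ankle_swing"] <- 0.5
  gains <- c("G_F_SOL", "G_F_GAS", "G_F_VAS", "G_F_HAM_stance",
             "G_F_GMAX_stance", "G_F_HAM_swing", "G_L_TA", "G_SOLTA",
             "G_L_ILPSO_swing", "G_V_BFSH_swing", "G_V_knee_stance")
  lo[gains] <- 0; hi[gains] <- 3
  lo["l_off_TA"] <- 0.5; hi["l_off_TA"] <- 1.5
  lo["l_off_ILPSO"] <- 0.5; hi["l_off_ILPSO"] <- 1.5
  lo["k_overext"] <- 0; hi["k_overext"] <- 5
  lo["phi_knee_off"] <- 0; hi["phi_knee_off"] <- 0.4
  lo["kp_trunk"] <- 0; hi["kp_trunk"] <- 8
  lo["kd_trunk"] <- 0; hi["kd_trunk"] <- 2
  lo[c("w_HAM", "w_GMAX", "w_ILPSO")] <- 0
  hi[c("w_HAM", "w_GMAX", "w_ILPSO")] <- 1
  lo[grep("^c0_", nm)] <- 0; hi[grep("^c0_", nm)] <- 0.3
  lo[c("kp_ankle_swing", "kp_knee_swing")] <- 0
  hi[c("kp_ankle_swing", "kp_knee_swing")] <- 8
  lo[c("kd_ankle_swing", "kd_knee_swing")] <- 0
  hi[c("kd_ankle_swing", "kd_knee_swing")] <- 1
  lo["e_DS"] <- 0; hi["e_DS"] <- 0.5
  data.frame(name = nm, lo = unname(lo), hi = unname(hi),
             stringsAsFactors = FALSE)
}

#' Pack named controller parameters into the canonical 37-vector
#'
#' @param named named list or named numeric vector covering all 37 parameters
#' @return numeric vector of length 37 in canonical order
#' @export
pack_params <- function(named) {
  nm <- controller_param_names()
  v <- unlist(named)
  missing <- setdiff(nm, names(v))
  if (length(missing) > 0)
    stop("missing controller parameters: ", paste(missing, collapse = ", "))
  out <- as.numeric(v[nm])
  if (length(out) != 37 || any(is.na(out)))
    stop("controller parameter vector must have exactly 37 finite entries")
  out
}

#' Unpack a 37-vector into named controller parameters
#'
#' @param vector numeric vector of length 37 (canonical order)
#' @return named numeric vector
#' @export
unpack_params <- function(vector) {
  if (length(vector) != 37)
    stop("controller parameter vector must have length 37, got ",
         length(vector))
  setNames(as.numeric(vector), controller_param_names())
}

#' Project controller parameters into their physical bounds
#'
#' Componentwise clamp onto the [controller_param_bounds()] box; in
#' particular co-stimulation baselines land in `[0, 0.3]` and all gains are
#' non-negative afterwards.
#'
#' @param params 37-vector
#' @return projected 37-vector
#' @export
project_params <- function(params) {
  b <- controller_param_bounds()
  pmin(pmax(as.numeric(params), b$lo), b$hi)
}

#' A hand-tuned default controller parameter set
#'
#' A plausible mid-range starting point (not an optimized gait): moderate
#' plantarflexor force feedback, small co-stimulation, upright trunk target.
#' Mainly useful as an optimization seed and in examples.
#'
#' @return named 37-vector
#' @export
default_controller_params <- function() {
  p <- setNames(numeric(37), controller_param_names())
  p["theta_tgt_trunk"] <- 0.08
  p["theta_tgt_knee_swing"] <- 1.0
  p["theta_tgt_ankle_swing"] <- 0.1
  p[c("G_F_SOL", "G_F_GAS")] <- c(1.2, 1.0)
  p[c("G_F_VAS", "G_F_HAM_stance", "G_F_GMAX_stance")] <- c(1.0, 0.4, 0.4)
  p["G_F_HAM_swing"] <- 0.3
  p["G_L_TA"] <- 1.1; p["l_off_TA"] <- 0.95; p["G_SOLTA"] <- 0.4
  p["G_L_ILPSO_swing"] <- 0.8; p["l_off_ILPSO"] <- 0.9
  p["G_V_BFSH_swing"] <- 0.3; p["G_V_knee_stance"] <- 0.2
  p["k_overext"] <- 1.5; p["phi_knee_off"] <- 0.15
  p["kp_trunk"] <- 2.0; p["kd_trunk"] <- 0.3
  p[c("w_HAM", "w_GMAX", "w_ILPSO")] <- c(0.4, 0.5, 0.5)
  p[grep("^c0_", names(p))] <- 0.02
  p["kp_ankle_swing"] <- 1.5; p["kd_ankle_swing"] <- 0.1
  p["kp_knee_swing"] <- 1.5; p["kd_knee_swing"] <- 0.1
  p["e_DS"] <- 0.15
  p
}

#' Compute the 18 muscle excitations of the reflex controller
#'
#' Phase-dependent reflex laws per leg. In stance: positive force feedback on
#' SOL, GAS and VAS; a knee overextension guard and extension damping on VAS;
#' TA length feedback with reciprocal inhibition from SOL force; HAM/GMAX
#' force feedback; a trunk-balance PD signal scaled by the leg's load share,
#' distributed to HAM/GMAX when the trunk leans forward of its target and to
#' ILPSO when backward; a push-off boost on the trailing leg in double
#' support. In swing: ILPSO length feedback, HAM force feedback, BFSH
#' knee-extension damping, and PD tracking of the swing knee and ankle target
#' angles through the VAS/BFSH and SOL/TA antagonist pairs. All channels are
#' clamped to `[0.01, 1]`.
#'
#' @param readout sensory readout: list with `f_norm`, `l_norm` (18 each,
#'   delayed), `theta`, `theta_dot` (trunk pitch), `knee`, `knee_dot`,
#'   `ankle`, `ankle_dot` (2 each, right then left), `load` (2, load shares)
#' @param phases list with logical `stance` (right, left) and numeric
#'   `tsince` (time since last transition, s)
#' @param params 37-vector (canonical order) or named vector/list
#' @return 18-vector of excitations in `[0.01, 1]`, canonical muscle order
#' @export
compute_excitations <- function(readout, phases, params) {
  if (!is.null(names(params)) && length(names(params)) == length(params) &&
      all(nzchar(names(params)))) {
    params <- pack_params(params)
  }
  as.numeric(excitations_cpp(readout, phases, as.numeric(params)))
}

#' Update per-leg stance/swing phases from vertical GRF
#'
#' A leg is in stance while its vertical GRF is at or above the contact
#' threshold (default 20 N) and in swing otherwise; `tsince` accumulates time
#' since the last transition, at most one transition per control step. Both
#' legs loaded means double support.
#'
#' @param phases list with `stance` (logical 2) and `tsince` (numeric 2)
#' @param grf_R,grf_L vertical GRF of right/left foot, N
#' @param threshold contact threshold, N
#' @param dt control step, s
#' @return updated phases list
#' @export
update_phases <- function(phases, grf_R, grf_L, threshold = 20, dt = 0.01) {
  update_phases_cpp(phases, grf_R, grf_L, threshold, dt)
}

#' Initial phase bookkeeping from an initial contact state
#'
#' @param grf_R,grf_L initial vertical GRFs, N
#' @param threshold contact threshold, N
#' @return phases list
#' @export
init_phases <- function(grf_R = 0, grf_L = 0, threshold = 20) {
  list(stance = c(grf_R >= threshold, grf_L >= threshold),
       tsince = c(0, 0))
}

#' Save / load controller parameters as JSON
#'
#' The file carries both the named fields and the flat canonical 37-vector;
#' either form is accepted on load (named fields win if both present).
#'
#' @param params named 37-vector (or plain vector in canonical order)
#' @param path file path
#' @return `load_controller_params` returns a named 37-vector
#' @export
save_controller_params <- function(params, path) {
  if (is.null(names(params))) params <- unpack_params(params)
  obj <- list(named = as.list(params), flat = as.numeric(params[controller_param_names()]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_controller_params
#' @export
load_controller_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$named)) return(unpack_params(pack_params(obj$named)))
  unpack_params(as.numeric(obj$flat))
}
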