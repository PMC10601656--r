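// [[Rcpp::depends(RcppArmadillo)]]
#include "controller.h"

using namespace Rcpp;
using namespace ng;

static Model* get_model(SEXP xp) {
  Rcpp::XPtr<Model> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP build_model_cpp(List cfg) {
  Model* M = new Model();
  M->mass = as<arma::vec>(cfg["mass"]);
  M->inertia = as<arma::vec>(cfg["inertia"]);
  M->hat_com = as<double>(cfg["hat_com"]);
  M->thigh_len = as<double>(cfg["thigh_len"]);
  M->thigh_com = as<double>(cfg["thigh_com"]);
  M->shank_len = as<double>(cfg["shank_len"]);
  M->shank_com = as<double>(cfg["shank_com"]);
  arma::vec fc = as<arma::vec>(cfg["foot_com"]);
  arma::vec hl = as<arma::vec>(cfg["heel"]);
  arma::vec to = as<arma::vec>(cfg["toe"]);
  M->foot_com = {fc(0), fc(1)};
  M->heel = {hl(0), hl(1)};
  M->toe = {to(0), to(1)};
  M->gravity = as<double>(cfg["gravity"]);
  M->joint_lo = as<arma::vec>(cfg["joint_lo"]);
  M->joint_hi = as<arma::vec>(cfg["joint_hi"]);
  M->limit_k = as<double>(cfg["limit_k"]);
  M->limit_d = as<double>(cfg["limit_d"]);
  M->limits_enabled = as<bool>(cfg["limits_enabled"]);
  M->c_k = as<double>(cfg["contact_k"]);
  M->c_c = as<double>(cfg["contact_c"]);
  M->c_mu = as<double>(cfg["contact_mu"]);
  M->c_vs = as<double>(cfg["contact_vs"]);
  M->contact_threshold = as<double>(cfg["contact_threshold"]);
  M->contact_enabled = as<bool>(cfg["contact_enabled"]);
  M->base_pinned = as<bool>(cfg["base_pinned"]);
  List mus = cfg["muscles"];
  M->mus.mif = as<arma::vec>(mus["mif"]);
  M->mus.lopt = as<arma::vec>(mus["lopt"]);
  M->mus.lslack = as<arma::vec>(mus["lslack"]);
  M->mus.vmax = as<arma::vec>(mus["vmax"]);
  M->mus.lref = as<arma::vec>(mus["lref"]);
  M->mus.r = as<arma::mat>(mus["moment_arm"]);
  M->mus.tau_act = as<double>(mus["tau_act"]);
  M->mus.tau_deact = as<double>(mus["tau_deact"]);
  M->mus.fl_width = as<double>(mus["fl_width"]);
  M->mus.fv_K = as<double>(mus["fv_K"]);
  M->mus.fv_ecc_max = as<double>(mus["fv_ecc_max"]);
  M->mus.fpe_k = as<double>(mus["fpe_k"]);
  M->mus.fpe_e0 = as<double>(mus["fpe_e0"]);
  M->W = orientation_rows();
  if (M->mass.n_elem != NB || M->mus.mif.n_elem != NMUS ||
      M->mus.r.n_rows != NMUS || M->mus.r.n_cols != NJ) {
    delete M;
    stop("malformed model configuration");
  }
  Rcpp::XPtr<Model> ptr(M, true);
  return ptr;
}

// [[Rcpp::export]]
List fd_step_cpp(SEXP xp, arma::vec q, arma::vec qdot, arma::vec tau6, double h,
                 int n_sub = 1) {
  Model* M = get_model(xp);
  for (int i = 0; i < n_sub; ++i) substep(*M, q, qdot, tau6, h);
  if (!q.is_finite() || !qdot.is_finite()) {
    stop("simulation diverged (non-finite state)");
  }
  return List::create(_["q"] = q, _["qdot"] = qdot);
}

// [[Rcpp::export]]
arma::vec accel_cpp(SEXP xp, arma::vec q, arma::vec qdot, arma::vec tau6) {
  return accel(*get_model(xp), q, qdot, tau6);
}

// [[Rcpp::export]]
arma::mat mass_matrix_cpp(SEXP xp, arma::vec q) {
  Dyn d = assemble(*get_model(xp), q, arma::vec(NQ, arma::fill::zeros));
  return d.Mmat;
}

// [[Rcpp::export]]
List contact_cpp(SEXP xp, arma::vec q, arma::vec qdot) {
  ContactForces cf = compute_contact(*get_model(xp), q, qdot);
  return List::create(
      _["normal"] = cf.normal, _["tangential"] = cf.tangential,
      _["position"] = cf.pos,
      _["vertical_R"] = cf.normal(0) + cf.normal(1),
      _["horizontal_R"] = cf.tangential(0) + cf.tangential(1),
      _["vertical_L"] = cf.normal(2) + cf.normal(3),
      _["horizontal_L"] = cf.tangential(2) + cf.tangential(3));
}

// [[Rcpp::export]]
List energy_cpp(SEXP xp, arma::vec q, arma::vec qdot) {
  double ke, pe;
  double tot = mech_energy(*get_model(xp), q, qdot, &ke, &pe);
  return List::create(_["total"] = tot, _["kinetic"] = ke, _["potential"] = pe);
}

// [[Rcpp::export]]
List passive_rollout_cpp(SEXP xp, arma::vec q, arma::vec qdot, double duration,
                         double h, int record_every = 10) {
  Model* M = get_model(xp);
  int n = (int)std::round(duration / h);
  arma::vec tau6(NJ, arma::fill::zeros);
  int nrec = n / record_every + 1;
  arma::vec tvec(nrec), evec(nrec);
  arma::mat qs(nrec, NQ), qds(nrec, NQ);
  int r = 0;
  tvec(0) = 0.0; evec(0) = mech_energy(*M, q, qdot);
  qs.row(0) = q.t(); qds.row(0) = qdot.t(); r = 1;
  for (int i = 1; i <= n; ++i) {
    substep(*M, q, qdot, tau6, h);
    if (!q.is_finite() || !qdot.is_finite())
      stop("simulation diverged at t = %f", i * h);
    if (i % record_every == 0 && r < nrec) {
      tvec(r) = i * h;
      evec(r) = mech_energy(*M, q, qdot);
      qs.row(r) = q.t(); qds.row(r) = qdot.t();
      ++r;
    }
  }
  return List::create(_["time"] = tvec.head(r), _["energy"] = evec.head(r),
                      _["q"] = qs.rows(0, r - 1), _["qdot"] = qds.rows(0, r - 1));
}

// Generalized passive force vector (gravity + velocity bias + contact +
// joint stops); zero at a static equilibrium.
// [[Rcpp::export]]
arma::vec passive_forces_cpp(SEXP xp, arma::vec q, arma::vec qdot) {
  Dyn d = assemble(*get_model(xp), q, qdot);
  return d.rhs_passive;
}

// Damped passive settling: exponential velocity bleed between substeps so the
// plant relaxes into a static equilibrium of gravity + contact + joint stops.
// [[Rcpp::export]]
List relax_rollout_cpp(SEXP xp, arma::vec q, arma::vec qdot, double duration,
                       double h, double damping) {
  Model* M = get_model(xp);
  int n = (int)std::round(duration / h);
  arma::vec tau6(NJ, arma::fill::zeros);
  double decay = std::exp(-damping * h);
  for (int i = 0; i < n; ++i) {
    substep(*M, q, qdot, tau6, h);
    qdot *= decay;
    if (!q.is_finite() || !qdot.is_finite())
      stop("relaxation diverged at t = %f", i * h);
  }
  return List::create(_["q"] = q, _["qdot"] = qdot);
}

// ---------------- muscles ----------------

// [[Rcpp::export]]
arma::vec activation_step_cpp(arma::vec a, arma::vec e, double dt,
                              double tau_act, double tau_deact) {
  arma::vec out(a.n_elem);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    out(i) = activation_step(a(i), e(i), dt, tau_act, tau_deact);
  return out;
}

// [[Rcpp::export]]
List mtu_kinematics_cpp(SEXP xp, arma::vec q, arma::vec qdot) {
  Model* M = get_model(xp);
  arma::vec lmt, vmt;
  mtu_kinematics(*M, q, qdot, lmt, vmt);
  arma::vec lnorm = (lmt - M->mus.lslack) / M->mus.lopt;
  arma::vec vnorm = vmt / (M->mus.vmax % M->mus.lopt);
  return List::create(_["l_mt"] = lmt, _["v_mt"] = vmt, _["l_norm"] = lnorm,
                      _["v_norm"] = vnorm);
}

// [[Rcpp::export]]
double fl_curve_cpp(double lnorm, double width) {
  MuscleSet ms; ms.fl_width = width;
  return fl_curve(lnorm, ms);
}

// [[Rcpp::export]]
double fv_curve_cpp(double vnorm, double K, double ecc_max) {
  MuscleSet ms; ms.fv_K = K; ms.fv_ecc_max = ecc_max;
  return fv_curve(vnorm, ms);
}

// [[Rcpp::export]]
double fpe_curve_cpp(double lnorm, double k, double e0) {
  MuscleSet ms; ms.fpe_k = k; ms.fpe_e0 = e0;
  return fpe_curve(lnorm, ms);
}

// [[Rcpp::export]]
List muscle_force_one_cpp(double a, double l_mt, double v_mt, double mif,
                          double lopt, double lslack, double vmax,
                          double fl_width, double fv_K, double fv_ecc_max,
                          double fpe_k, double fpe_e0) {
  MuscleSet ms;
  ms.fl_width = fl_width; ms.fv_K = fv_K; ms.fv_ecc_max = fv_ecc_max;
  ms.fpe_k = fpe_k; ms.fpe_e0 = fpe_e0;
  bool warn = false;
  double f = muscle_force_one(a, l_mt, v_mt, mif, lopt, lslack, vmax, ms, &warn);
  return List::create(_["force"] = f, _["geometry_warning"] = warn);
}

// [[Rcpp::export]]
arma::vec muscle_forces_cpp(SEXP xp, arma::vec act, arma::vec q, arma::vec qdot) {
  return muscle_forces(*get_model(xp), act, q, qdot);
}

// [[Rcpp::export]]
arma::vec joint_torques_cpp(SEXP xp, arma::vec forces) {
  return joint_torques_from_muscles(*get_model(xp), forces);
}

// ---------------- controller ----------------

static Readout readout_from_list(const List& ro) {
  Readout r;
  r.fnorm = as<arma::vec>(ro["f_norm"]);
  r.lnorm = as<arma::vec>(ro["l_norm"]);
  r.theta = as<double>(ro["theta"]);
  r.thetad = as<double>(ro["theta_dot"]);
  arma::vec kn = as<arma::vec>(ro["knee"]), knd = as<arma::vec>(ro["knee_dot"]);
  arma::vec an = as<arma::vec>(ro["ankle"]), and_ = as<arma::vec>(ro["ankle_dot"]);
  arma::vec ld = as<arma::vec>(ro["load"]);
  for (int s = 0; s < 2; ++s) {
    r.knee[s] = kn(s); r.kneed[s] = knd(s);
    r.ankle[s] = an(s); r.ankled[s] = and_(s);
    r.load[s] = ld(s);
  }
  if (!r.fnorm.is_finite() || !r.lnorm.is_finite())
    stop("non-finite sensory readout (muscle force/length channel)");
  return r;
}

static LegPhase phase_from_list(const List& ph) {
  LegPhase p;
  LogicalVector st = ph["stance"];
  NumericVector ts = ph["tsince"];
  p.stance[0] = st[0]; p.stance[1] = st[1];
  p.tsince[0] = ts[0]; p.tsince[1] = ts[1];
  return p;
}

// [[Rcpp::export]]
arma::vec excitations_cpp(List readout, List phases, arma::vec params) {
  if (params.n_elem != (arma::uword)NPAR) stop("expected 37 controller parameters");
  Readout r = readout_from_list(readout);
  LegPhase p = phase_from_list(phases);
  return compute_excitations(r, p, params);
}

// [[Rcpp::export]]
List update_phases_cpp(List phases, double grf_R, double grf_L, double threshold,
                       double dt) {
  LegPhase p = phase_from_list(phases);
  update_phases(p, grf_R, grf_L, threshold, dt);
  return List::create(
      _["stance"] = LogicalVector::create(p.stance[0], p.stance[1]),
      _["tsince"] = NumericVector::create(p.tsince[0], p.tsince[1]));
}

// ---------------- episode rollout ----------------

struct SensorState {
  arma::vec fnorm, lnorm;
};

static SensorState sense(const Model& M, const arma::vec& act, const arma::vec& q,
                         const arma::vec& qdot) {
  SensorState s;
  arma::vec lmt, vmt;
  mtu_kinematics(M, q, qdot, lmt, vmt);
  s.lnorm = (lmt - M.mus.lslack) / M.mus.lopt;
  s.fnorm = muscle_forces(M, act, q, qdot) / M.mus.mif;
  return s;
}

static Readout make_readout(const Model& M, const SensorState& delayed,
                            const arma::vec& q, const arma::vec& qdot,
                            double grfR, double grfL) {
  Readout r;
  r.fnorm = delayed.fnorm;
  r.lnorm = delayed.lnorm;
  r.theta = q(2); r.thetad = qdot(2);
  r.knee[0] = q(4); r.kneed[0] = qdot(4);
  r.ankle[0] = q(5); r.ankled[0] = qdot(5);
  r.knee[1] = q(7); r.kneed[1] = qdot(7);
  r.ankle[1] = q(8); r.ankled[1] = qdot(8);
  double tot = grfR + grfL;
  if (tot > 1e-9) { r.load[0] = grfR / tot; r.load[1] = grfL / tot; }
  else { r.load[0] = 0.0; r.load[1] = 0.0; }
  return r;
}

// Advance activations + mechanics over one control interval with excitations
// held constant; semi-implicit Euler substeps.
static bool advance_control_step(const Model& M, arma::vec& q, arma::vec& qdot,
                                 arma::vec& act, const arma::vec& exc, double dt,
                                 int n_sub) {
  double h = dt / n_sub;
  for (int i = 0; i < n_sub; ++i) {
    for (int k = 0; k < NMUS; ++k)
      act(k) = activation_step(act(k), exc(k), h, M.mus.tau_act, M.mus.tau_deact);
    arma::vec F = muscle_forces(M, act, q, qdot);
    arma::vec tau = joint_torques_from_muscles(M, F);
    substep(M, q, qdot, tau, h);
    if (!q.is_finite() || !qdot.is_finite()) return false;
  }
  return true;
}

// [[Rcpp::export]]
List control_step_cpp(SEXP xp, arma::vec q, arma::vec qdot, arma::vec act,
                      arma::vec exc, double dt, int n_sub) {
  Model* M = get_model(xp);
  bool ok = advance_control_step(*M, q, qdot, act, exc, dt, n_sub);
  if (!ok) stop("simulation diverged during control step");
  ContactForces cf = compute_contact(*M, q, qdot);
  SensorState ss = sense(*M, act, q, qdot);
  return List::create(
      _["q"] = q, _["qdot"] = qdot, _["act"] = act,
      _["grf_R_vertical"] = cf.normal(0) + cf.normal(1),
      _["grf_R_horizontal"] = cf.tangential(0) + cf.tangential(1),
      _["grf_L_vertical"] = cf.normal(2) + cf.normal(3),
      _["grf_L_horizontal"] = cf.tangential(2) + cf.tangential(3),
      _["f_norm"] = ss.fnorm, _["l_norm"] = ss.lnorm);
}

// Full closed-loop episode: reflex controller in the loop, 0.01 s control
// interval, termination on horizon or pelvis drop below pelvis_min.
// [[Rcpp::export]]
List rollout_cpp(SEXP xp, arma::vec params, arma::vec q0, arma::vec qdot0,
                 double horizon, double dt = 0.01, int n_sub = 10,
                 double pelvis_min = 0.6) {
  Model* M = get_model(xp);
  if (params.n_elem != (arma::uword)NPAR) stop("expected 37 controller parameters");
  int nmax = (int)std::round(horizon / dt);
  arma::vec q = q0, qdot = qdot0;

  ContactForces cf = compute_contact(*M, q, qdot);
  double grfR = cf.normal(0) + cf.normal(1);
  double grfL = cf.normal(2) + cf.normal(3);
  LegPhase ph;
  ph.stance[0] = grfR >= M->contact_threshold;
  ph.stance[1] = grfL >= M->contact_threshold;
  ph.tsince[0] = ph.tsince[1] = 0.0;

  // activations start at the controller's baseline excitations for the
  // initial readout (muscle force equilibration is implicit: rigid tendon)
  arma::vec act(NMUS, arma::fill::zeros);
  SensorState delayed = sense(*M, act, q, qdot);
  Readout r0 = make_readout(*M, delayed, q, qdot, grfR, grfL);
  act = compute_excitations(r0, ph, params);
  delayed = sense(*M, act, q, qdot);

  arma::vec tvec(nmax);
  arma::mat qs(nmax, NQ), qds(nmax, NQ), grf(nmax, 4), exc(nmax, NMUS),
      actm(nmax, NMUS);
  bool fell = false, diverged = false;
  int n = 0;
  for (int i = 0; i < nmax; ++i) {
    update_phases(ph, grfR, grfL, M->contact_threshold, dt);
    Readout ro = make_readout(*M, delayed, q, qdot, grfR, grfL);
    arma::vec e = compute_excitations(ro, ph, params);
    bool ok = advance_control_step(*M, q, qdot, act, e, dt, n_sub);
    if (!ok) { diverged = true; break; }
    cf = compute_contact(*M, q, qdot);
    grfR = cf.normal(0) + cf.normal(1);
    grfL = cf.normal(2) + cf.normal(3);
    delayed = sense(*M, act, q, qdot);
    tvec(n) = (i + 1) * dt;
    qs.row(n) = q.t(); qds.row(n) = qdot.t();
    grf(n, 0) = grfR; grf(n, 1) = cf.tangential(0) + cf.tangential(1);
    grf(n, 2) = grfL; grf(n, 3) = cf.tangential(2) + cf.tangential(3);
    exc.row(n) = e.t(); actm.row(n) = act.t();
    ++n;
    if (q(1) < pelvis_min) { fell = true; break; }
  }
  if (n == 0) {
    return List::create(_["n_steps"] = 0, _["terminated_early"] = true,
                        _["diverged"] = diverged);
  }
  return List::create(
      _["time"] = tvec.head(n), _["q"] = qs.rows(0, n - 1),
      _["qdot"] = qds.rows(0, n - 1), _["grf"] = grf.rows(0, n - 1),
      _["excitations"] = exc.rows(0, n - 1), _["activations"] = actm.rows(0, n - 1),
      _["n_steps"] = n, _["terminated_early"] = fell || diverged,
      _["diverged"] = diverged);
}
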