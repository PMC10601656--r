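#ifndef NEUROGAIT_MODEL_H
#define NEUROGAIT_MODEL_H

#include <RcppArmadillo.h>

// Planar 7-segment biped. Generalized coordinates (9):
//   q[0] pelvis_x, q[1] pelvis_y  (hip joint centre in the world frame)
//   q[2] pelvis_pitch (anterior tilt positive)
//   q[3] hip_R, q[4] knee_R, q[5] ankle_R   (flexion / dorsiflexion positive)
//   q[6] hip_L, q[7] knee_L, q[8] ankle_L
// Bodies: 0 HAT, 1 thigh_R, 2 shank_R, 3 foot_R, 4 thigh_L, 5 shank_L, 6 foot_L.
// Segment orientations are linear in q (constant coefficient rows W), so the
// angular Jacobians are constant and all velocity bias comes from the
// translational chains.

namespace ng {

constexpr int NQ = 9;
constexpr int NB = 7;
constexpr int NMUS = 18;
constexpr int NJ = 6;     // internal DOF: hipR kneeR ankleR hipL kneeL ankleL
constexpr int NPAR = 37;  // reflex controller parameters

struct MuscleSet {
  arma::vec mif, lopt, lslack, vmax, lref;  // 18 each
  arma::mat r;                              // 18 x 6 signed moment arms [m]
  double tau_act, tau_deact;
  double fl_width;    // gaussian force-length width (0.45)
  double fv_K;        // Hill concentric curvature (0.25)
  double fv_ecc_max;  // eccentric plateau (1.5)
  double fpe_k;       // passive exponential shape (4)
  double fpe_e0;      // passive strain at one normalized force (0.6)
};

struct Model {
  // segment inertial parameters
  arma::vec mass;     // 7
  arma::vec inertia;  // 7 (about COM, out-of-plane)
  double hat_com;     // COM distance above hip along HAT axis
  double thigh_len, thigh_com, shank_len, shank_com;
  arma::vec2 foot_com, heel, toe;  // foot-local (x fwd, y up), origin at ankle
  double gravity;
  // joint limits (soft stops) on the 6 internal DOF
  arma::vec joint_lo, joint_hi;  // 6
  double limit_k, limit_d;
  bool limits_enabled;
  // contact
  double c_k, c_c, c_mu, c_vs;  // Hunt-Crossley k, dissipation, friction, vel smoothing
  double contact_threshold;     // stance detection [N]
  bool contact_enabled;
  bool base_pinned;             // hold pelvis x, y fixed (suspension tests)
  MuscleSet mus;
  // constant angular-Jacobian rows, 7 x 9
  arma::mat W;
};

inline arma::mat orientation_rows() {
  arma::mat W(NB, NQ, arma::fill::zeros);
  // psi_HAT = -pitch
  W(0, 2) = -1;
  // right leg: psi_thigh = -pitch + hip ; psi_shank = psi_thigh - knee ;
  // psi_foot = psi_shank + ankle
  W(1, 2) = -1; W(1, 3) = 1;
  W(2, 2) = -1; W(2, 3) = 1; W(2, 4) = -1;
  W(3, 2) = -1; W(3, 3) = 1; W(3, 4) = -1; W(3, 5) = 1;
  W(4, 2) = -1; W(4, 6) = 1;
  W(5, 2) = -1; W(5, 6) = 1; W(5, 7) = -1;
  W(6, 2) = -1; W(6, 6) = 1; W(6, 7) = -1; W(6, 8) = 1;
  return W;
}

inline arma::vec2 rot(double psi, const arma::vec2& v) {
  double c = std::cos(psi), s = std::sin(psi);
  return {c * v(0) - s * v(1), s * v(0) + c * v(1)};
}
inline arma::vec2 rot90(const arma::vec2& v) { return {-v(1), v(0)}; }

// One rigid point on the kinematic chain: world position, 2x9 Jacobian and the
// velocity-product acceleration (qddot = 0 term). Chains are sums of rotated
// constant local vectors, each tied to one body orientation.
struct PointKin {
  arma::vec2 p;
  arma::mat J;        // 2 x 9
  arma::vec2 abias;   // Jdot * qdot
};

struct ChainTerm { int body; arma::vec2 v; };

inline PointKin point_kin(const Model& M, const arma::vec& q, const arma::vec& qdot,
                          const std::vector<ChainTerm>& terms) {
  PointKin out;
  out.p = {q(0), q(1)};
  out.J.zeros(2, NQ);
  out.J(0, 0) = 1.0; out.J(1, 1) = 1.0;
  out.abias.zeros();
  for (const auto& t : terms) {
    double psi = arma::dot(M.W.row(t.body), q);
    double psid = arma::dot(M.W.row(t.body), qdot);
    arma::vec2 rv = rot(psi, t.v);
    arma::vec2 drv = rot90(rv);  // d(rot(psi,v))/dpsi
    out.p += rv;
    for (int j = 0; j < NQ; ++j) {
      double w = M.W(t.body, j);
      if (w != 0.0) { out.J(0, j) += w * drv(0); out.J(1, j) += w * drv(1); }
    }
    out.abias += -psid * psid * rv;
  }
  return out;
}

// Chains for the seven COMs and the four contact points.
inline std::vector<ChainTerm> chain_com(const Model& M, int body) {
  arma::vec2 up_hat = {0.0, M.hat_com};
  arma::vec2 dn_tc = {0.0, -M.thigh_com}, dn_tl = {0.0, -M.thigh_len};
  arma::vec2 dn_sc = {0.0, -M.shank_com}, dn_sl = {0.0, -M.shank_len};
  switch (body) {
    case 0: return {{0, up_hat}};
    case 1: return {{1, dn_tc}};
    case 2: return {{1, dn_tl}, {2, dn_sc}};
    case 3: return {{1, dn_tl}, {2, dn_sl}, {3, M.foot_com}};
    case 4: return {{4, dn_tc}};
    case 5: return {{4, dn_tl}, {5, dn_sc}};
    default: return {{4, dn_tl}, {5, dn_sl}, {6, M.foot_com}};
  }
}

inline std::vector<ChainTerm> chain_contact(const Model& M, int point) {
  // 0 heel_R, 1 toe_R, 2 heel_L, 3 toe_L
  arma::vec2 dn_tl = {0.0, -M.thigh_len}, dn_sl = {0.0, -M.shank_len};
  switch (point) {
    case 0: return {{1, dn_tl}, {2, dn_sl}, {3, M.heel}};
    case 1: return {{1, dn_tl}, {2, dn_sl}, {3, M.toe}};
    case 2: return {{4, dn_tl}, {5, dn_sl}, {6, M.heel}};
    default: return {{4, dn_tl}, {5, dn_sl}, {6, M.toe}};
  }
}

struct ContactForces {
  // per point: normal (vertical) and tangential (horizontal) force, position
  arma::vec normal;      // 4
  arma::vec tangential;  // 4
  arma::mat pos;         // 4 x 2
  arma::vec gen;         // 9, generalized contact force
};

// Contact forces; optionally accumulates the (negative semidefinite)
// velocity-derivative matrix D = dF/dqdot used for implicit damping in the
// integrator. Only the diagonal per-point velocity derivatives enter, which
// keeps D symmetric.
inline ContactForces compute_contact(const Model& M, const arma::vec& q,
                                     const arma::vec& qdot,
                                     arma::mat* Dacc = nullptr) {
  ContactForces cf;
  cf.normal.zeros(4); cf.tangential.zeros(4); cf.pos.zeros(4, 2);
  cf.gen.zeros(NQ);
  if (!M.contact_enabled) return cf;
  for (int i = 0; i < 4; ++i) {
    PointKin pk = point_kin(M, q, qdot, chain_contact(M, i));
    cf.pos(i, 0) = pk.p(0); cf.pos(i, 1) = pk.p(1);
    double depth = -pk.p(1);
    if (depth <= 0.0) continue;
    arma::vec v = pk.J * qdot;
    double ddot = -v(1);
    double kd15 = M.c_k * std::pow(depth, 1.5);
    double fn = kd15 * (1.0 + M.c_c * ddot);
    if (fn < 0.0) fn = 0.0;
    double sech = 1.0 / std::cosh(v(0) / M.c_vs);
    double ft = -M.c_mu * fn * std::tanh(v(0) / M.c_vs);
    cf.normal(i) = fn;
    cf.tangential(i) = ft;
    arma::vec2 F = {ft, fn};
    cf.gen += pk.J.t() * F;
    if (Dacc) {
      double d_t = -M.c_mu * fn * sech * sech / M.c_vs;  // dFt/dvx <= 0
      double d_n = (fn > 0.0) ? -kd15 * M.c_c : 0.0;     // dFn/dvy <= 0
      arma::mat22 Dp = {{d_t, 0.0}, {0.0, d_n}};
      *Dacc += pk.J.t() * Dp * pk.J;
    }
  }
  return cf;
}

inline arma::vec joint_limit_torques(const Model& M, const arma::vec& q,
                                     const arma::vec& qdot) {
  arma::vec tau(NJ, arma::fill::zeros);
  if (!M.limits_enabled) return tau;
  for (int j = 0; j < NJ; ++j) {
    double x = q(3 + j), xd = qdot(3 + j);
    if (x < M.joint_lo(j)) {
      tau(j) = M.limit_k * (M.joint_lo(j) - x) - M.limit_d * xd;
    } else if (x > M.joint_hi(j)) {
      tau(j) = -M.limit_k * (x - M.joint_hi(j)) - M.limit_d * xd;
    }
  }
  return tau;
}

struct Dyn { arma::mat Mmat; arma::vec rhs_passive; arma::mat Dmat; };

// Assemble M(q), the torque-free right-hand side (gravity + velocity bias +
// contact + joint limits), and the damping Jacobian D = dF/dqdot used by the
// implicit-damping velocity update. Joint torques add on slots 3..8.
inline Dyn assemble(const Model& M, const arma::vec& q, const arma::vec& qdot) {
  Dyn d;
  d.Mmat.zeros(NQ, NQ);
  d.rhs_passive.zeros(NQ);
  d.Dmat.zeros(NQ, NQ);
  for (int b = 0; b < NB; ++b) {
    PointKin pk = point_kin(M, q, qdot, chain_com(M, b));
    d.Mmat += M.mass(b) * (pk.J.t() * pk.J);
    d.Mmat += M.inertia(b) * (M.W.row(b).t() * M.W.row(b));
    arma::vec2 gvec = {0.0, -M.gravity};
    d.rhs_passive += M.mass(b) * (pk.J.t() * (gvec - pk.abias));
  }
  ContactForces cf = compute_contact(M, q, qdot, &d.Dmat);
  d.rhs_passive += cf.gen;
  arma::vec tl = joint_limit_torques(M, q, qdot);
  d.rhs_passive.subvec(3, 8) += tl;
  if (M.limits_enabled) {
    for (int j = 0; j < NJ; ++j) {
      double x = q(3 + j);
      if (x < M.joint_lo(j) || x > M.joint_hi(j))
        d.Dmat(3 + j, 3 + j) -= M.limit_d;
    }
  }
  return d;
}

inline arma::vec accel(const Model& M, const arma::vec& q, const arma::vec& qdot,
                       const arma::vec& tau6) {
  Dyn d = assemble(M, q, qdot);
  arma::vec rhs = d.rhs_passive;
  rhs.subvec(3, 8) += tau6;
  if (M.base_pinned) {
    // pelvis translation constrained: solve the reduced 7-DOF system
    arma::uvec free = arma::regspace<arma::uvec>(2, NQ - 1);
    arma::vec qdd(NQ, arma::fill::zeros);
    qdd(free) = arma::solve(d.Mmat.submat(free, free), rhs(free),
                            arma::solve_opts::likely_sympd);
    return qdd;
  }
  return arma::solve(d.Mmat, rhs, arma::solve_opts::likely_sympd);
}

// Semi-implicit Euler substep with implicit treatment of the contact and
// joint-stop damping: (M - h D) dv = h * rhs, then q += h * (qdot + dv).
// With D = 0 this reduces to plain semi-implicit Euler; -D is PSD so the
// system stays symmetric positive-definite.
inline void substep(const Model& M, arma::vec& q, arma::vec& qdot,
                    const arma::vec& tau6, double h) {
  Dyn d = assemble(M, q, qdot);
  arma::vec rhs = d.rhs_passive;
  rhs.subvec(3, 8) += tau6;
  arma::mat A = d.Mmat - h * d.Dmat;
  if (!A.is_finite() || !rhs.is_finite()) {
    q.fill(arma::datum::nan);  // flag divergence for the caller
    return;
  }
  if (M.base_pinned) {
    arma::uvec free = arma::regspace<arma::uvec>(2, NQ - 1);
    arma::vec dv;
    if (!arma::solve(dv, A.submat(free, free), h * rhs(free),
                     arma::solve_opts::likely_sympd +
                     arma::solve_opts::no_approx)) {
      q.fill(arma::datum::nan);
      return;
    }
    qdot(free) += dv;
    qdot(0) = 0.0; qdot(1) = 0.0;
  } else {
    arma::vec dv;
    if (!arma::solve(dv, A, h * rhs,
                     arma::solve_opts::likely_sympd +
                     arma::solve_opts::no_approx)) {
      q.fill(arma::datum::nan);
      return;
    }
    qdot += dv;
  }
  q += h * qdot;
}

inline double mech_energy(const Model& M, const arma::vec& q, const arma::vec& qdot,
                          double* ke_out = nullptr, double* pe_out = nullptr) {
  double ke = 0.0, pe = 0.0;
  for (int b = 0; b < NB; ++b) {
    PointKin pk = point_kin(M, q, qdot, chain_com(M, b));
    arma::vec v = pk.J * qdot;
    double psid = arma::dot(M.W.row(b), qdot);
    ke += 0.5 * M.mass(b) * arma::dot(v, v) + 0.5 * M.inertia(b) * psid * psid;
    pe += M.mass(b) * M.gravity * pk.p(1);
  }
  if (ke_out) *ke_out = ke;
  if (pe_out) *pe_out = pe;
  return ke + pe;
}

// ---------------- muscles ----------------

inline double fl_curve(double lnorm, const MuscleSet& ms) {
  double x = (lnorm - 1.0) / ms.fl_width;
  return std::exp(-x * x);
}

inline double fv_curve(double vnorm, const MuscleSet& ms) {
  if (vnorm <= -1.0) return 0.0;
  if (vnorm <= 0.0) return (1.0 + vnorm) / (1.0 - vnorm / ms.fv_K);
  // eccentric branch, slope-matched at zero, saturating at fv_ecc_max
  double gain = ms.fv_ecc_max - 1.0;                 // 0.5
  double b = gain * ms.fv_K / (1.0 + ms.fv_K);       // matches concentric slope
  return 1.0 + gain * vnorm / (vnorm + b);
}

inline double fpe_curve(double lnorm, const MuscleSet& ms) {
  if (lnorm <= 1.0) return 0.0;
  return (std::exp(ms.fpe_k * (lnorm - 1.0) / ms.fpe_e0) - 1.0) /
         (std::exp(ms.fpe_k) - 1.0);
}

// rigid tendon: fiber length = l_mt - l_slack
inline double muscle_force_one(double a, double l_mt, double v_mt, double mif,
                               double lopt, double lslack, double vmax,
                               const MuscleSet& ms, bool* geom_warn = nullptr) {
  double lf = l_mt - lslack;
  if (lf <= 0.0) {
    if (geom_warn) *geom_warn = true;
    return 0.0;
  }
  double lnorm = lf / lopt;
  double vnorm = v_mt / (vmax * lopt);
  double f = mif * (a * fl_curve(lnorm, ms) * fv_curve(vnorm, ms) + fpe_curve(lnorm, ms));
  return f > 0.0 ? f : 0.0;
}

// l_mt = lref - sum_j r_kj * q_j (reference posture q = 0), v_mt = -r * qdot
inline void mtu_kinematics(const Model& M, const arma::vec& q, const arma::vec& qdot,
                           arma::vec& lmt, arma::vec& vmt) {
  arma::vec qj = q.subvec(3, 8), qdj = qdot.subvec(3, 8);
  lmt = M.mus.lref - M.mus.r * qj;
  vmt = -(M.mus.r * qdj);
}

inline arma::vec muscle_forces(const Model& M, const arma::vec& act,
                               const arma::vec& q, const arma::vec& qdot) {
  arma::vec lmt, vmt, F(NMUS);
  mtu_kinematics(M, q, qdot, lmt, vmt);
  for (int k = 0; k < NMUS; ++k) {
    F(k) = muscle_force_one(act(k), lmt(k), vmt(k), M.mus.mif(k), M.mus.lopt(k),
                            M.mus.lslack(k), M.mus.vmax(k), M.mus);
  }
  return F;
}

inline arma::vec joint_torques_from_muscles(const Model& M, const arma::vec& F) {
  return M.mus.r.t() * F;  // 6-vector, flexion/dorsiflexion positive
}

// exact first-order activation dynamics over dt with constant excitation
inline double activation_step(double a, double e, double dt, double tau_act,
                              double tau_deact) {
  double tau = (e > a) ? tau_act : tau_deact;
  double out = e + (a - e) * std::exp(-dt / tau);
  if (out < 0.0) out = 0.0;
  if (out > 1.0) out = 1.0;
  return out;
}

}  // namespace ng

#endif
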