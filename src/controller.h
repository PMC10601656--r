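#ifndef NEUROGAIT_CONTROLLER_H
#define NEUROGAIT_CONTROLLER_H

#include "model.h"

// Reflex gait controller: 37 bilaterally shared parameters mapping delayed
// proprioceptive (normalized muscle force/length), trunk and contact-load
// state to 18 muscle excitations through phase-dependent laws.
//
// Muscle order (per side): 0 ILPSO, 1 GMAX, 2 HAM, 3 RF, 4 VAS, 5 BFSH,
// 6 GAS, 7 SOL, 8 TA; right = 0..8, left = 9..17.
//
// Parameter layout (0-based):
//  0 theta_tgt_trunk        1 theta_tgt_knee_swing   2 theta_tgt_ankle_swing
//  3 G_F_SOL  4 G_F_GAS  5 G_F_VAS  6 G_F_HAM_st  7 G_F_GMAX_st
//  8 G_F_HAM_sw  9 G_L_TA  10 l_off_TA  11 G_SOLTA  12 G_L_ILPSO_sw
//  13 l_off_ILPSO  14 G_V_BFSH_sw  15 G_V_knee_st  16 k_overext
//  17 phi_knee_off  18 kp_trunk  19 kd_trunk  20 w_HAM  21 w_GMAX  22 w_ILPSO
//  23..31 c0 baselines (muscle order ILPSO..TA)  32 kp_ankle_sw  33 kd_ankle_sw
//  34 kp_knee_sw  35 kd_knee_sw  36 e_DS

namespace ng {

enum Mus { ILPSO = 0, GMAX, HAM, RF, VAS, BFSH, GAS, SOL, TA };

constexpr double E_MIN = 0.01;
constexpr double E_MAX = 1.0;

struct LegPhase {
  bool stance[2];          // [right, left]
  double tsince[2];        // s since last transition
};

struct Readout {
  arma::vec fnorm;   // 18, delayed F / MIF
  arma::vec lnorm;   // 18, delayed fiber length / l_opt
  double theta, thetad;          // trunk (pelvis) pitch, rate
  double knee[2], kneed[2];      // flexion positive
  double ankle[2], ankled[2];    // dorsiflexion positive
  double load[2];                // leg load share in [0, 1]
};

inline void update_phases(LegPhase& ph, double grfR, double grfL, double thr,
                          double dt) {
  double grf[2] = {grfR, grfL};
  for (int s = 0; s < 2; ++s) {
    bool loaded = grf[s] >= thr;
    if (loaded != ph.stance[s]) {
      ph.stance[s] = loaded;
      ph.tsince[s] = 0.0;
    } else {
      ph.tsince[s] += dt;
    }
  }
}

inline double clamp_e(double e) {
  if (e < E_MIN) return E_MIN;
  if (e > E_MAX) return E_MAX;
  return e;
}

inline arma::vec compute_excitations(const Readout& ro, const LegPhase& ph,
                                     const arma::vec& p) {
  arma::vec e(NMUS);
  bool ds = ph.stance[0] && ph.stance[1];
  // trailing leg in double support = the one loaded for longer
  int trailing = -1;
  if (ds) trailing = (ph.tsince[0] >= ph.tsince[1]) ? 0 : 1;
  for (int s = 0; s < 2; ++s) {
    int off = 9 * s;
    double loc[9];
    for (int m = 0; m < 9; ++m) loc[m] = p(23 + m);  // co-stimulation baselines
    if (ph.stance[s]) {
      loc[SOL] += p(3) * ro.fnorm(off + SOL);
      loc[GAS] += p(4) * ro.fnorm(off + GAS);
      double knee = ro.knee[s], kneed = ro.kneed[s];
      double overext = std::max(0.0, p(17) - knee) * (kneed < 0.0 ? 1.0 : 0.0);
      loc[VAS] += p(5) * ro.fnorm(off + VAS) - p(16) * overext -
                  p(15) * std::max(0.0, -kneed);
      loc[TA] += p(9) * std::max(0.0, ro.lnorm(off + TA) - p(10)) -
                 p(11) * ro.fnorm(off + SOL);
      loc[HAM] += p(6) * ro.fnorm(off + HAM);
      loc[GMAX] += p(7) * ro.fnorm(off + GMAX);
      // trunk balance PD, scaled by the leg's load share
      double u = (p(18) * (ro.theta - p(0)) + p(19) * ro.thetad) * ro.load[s];
      if (u > 0.0) {
        loc[HAM] += p(20) * u;
        loc[GMAX] += p(21) * u;
      } else {
        loc[ILPSO] += p(22) * (-u);
      }
      if (ds && trailing == s) {  // push-off boost on the trailing leg
        loc[SOL] += p(36);
        loc[GAS] += p(36);
        loc[ILPSO] += p(36);
      }
    } else {  // swing
      loc[ILPSO] += p(12) * std::max(0.0, ro.lnorm(off + ILPSO) - p(13));
      loc[HAM] += p(8) * ro.fnorm(off + HAM);
      double knee = ro.knee[s], kneed = ro.kneed[s];
      loc[BFSH] += p(14) * std::max(0.0, -kneed);
      double uk = p(34) * (knee - p(1)) + p(35) * kneed;
      if (uk > 0.0) loc[VAS] += uk; else loc[BFSH] += -uk;
      double ua = p(32) * (ro.ankle[s] - p(2)) + p(33) * ro.ankled[s];
      if (ua > 0.0) loc[SOL] += ua; else loc[TA] += -ua;
    }
    for (int m = 0; m < 9; ++m) e(off + m) = clamp_e(loc[m]);
  }
  return e;
}

}  // namespace ng

#endif
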