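// Core forward dynamics of the 7-link sagittal-plane walker.
//
// Conventions (documented once, used everywhere):
//   world: x forward (walking direction), z up; treadmill surface at z = 0;
//   belt surface velocity = -nu (belt runs backward under the walker).
//   q = (x, z, theta, hR, kR, aR, hL, kL, aL)
//     (x, z)  hip-joint position (both hips coincide on the trunk);
//     theta   trunk pitch, CCW positive, 0 = upright (positive = backward lean);
//     h       hip flexion positive (thigh forward);
//     k       knee flexion positive (shank backward);
//     a       ankle dorsiflexion positive (toe up).
//   Absolute segment angles (CCW from straight down):
//     thigh = theta + h,  shank = theta + h - k,  foot = theta + h - k + a,
//   so a joint torque positive in its own flexion convention enters the
//   generalized force vector as Q[q_j] += tau_j.
//   Muscle order per leg: IL GM VA BFS TA SO RF BFL GC (right leg first).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NQ = 9, NMUS = 9, NPTS = 4;
static const int IL = 0, GM = 1, VA = 2, BFS = 3, TA = 4, SO = 5, RF = 6,
                 BFL = 7, GC = 8;

struct Params {
  // segments: 0 trunk, 1 thigh, 2 shank, 3 foot (legs identical)
  double m_tr, m_th, m_sh, m_ft;
  double I_tr, I_th, I_sh, I_ft;
  double L_th, L_sh;          // thigh, shank lengths
  double c_tr, c_th, c_sh;    // COM offset from proximal joint along segment
  double fcx, fcz;            // foot COM in foot frame (ankle at origin)
  double d_toe, d_heel;       // sole extent forward/backward of the ankle
  double sole_z;              // sole depth below the ankle
  double inner;               // inset of the two inner contact points (0.04 m)
  double g;
  // passive joints
  double visc_hip, visc_knee, visc_ank;
  double k_lim, c_lim;
  double knee_lo, knee_hi, ank_lo, ank_hi;
  // contact
  double kn, cn, kt, ct, mu;
  // muscles
  double Fmax[NMUS], lopt[NMUS], vfac[NMUS], kpe[NMUS];
  double r[NMUS][3];          // moment arms (hip, knee, ankle), signed
  double Tact, fl_w, fv_c, fv_ecc;
  // CPG / synergy
  double omega, Kphi, phiFC, tauFC;
  int resetting;
  double Phi[5], dPhi[5], Lam[5], W[NMUS][5];
  // regulation
  double kap[NMUS], sig[NMUS], lam[NMUS];
  double theta_ref, v_ref, tauReg;
};

static double getd(const List& L, const char* nm) {
  if (!L.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<double>(L[nm]);
}

static Params parseParams(const List& P) {
  Params p;
  List b = P["body"], j = P["joints"], c = P["contact"], mu = P["muscles"],
       ct = P["ctrl"];
  p.m_tr = getd(b, "m_trunk"); p.m_th = getd(b, "m_thigh");
  p.m_sh = getd(b, "m_shank"); p.m_ft = getd(b, "m_foot");
  p.I_tr = getd(b, "I_trunk"); p.I_th = getd(b, "I_thigh");
  p.I_sh = getd(b, "I_shank"); p.I_ft = getd(b, "I_foot");
  p.L_th = getd(b, "L_thigh"); p.L_sh = getd(b, "L_shank");
  p.c_tr = getd(b, "c_trunk"); p.c_th = getd(b, "c_thigh");
  p.c_sh = getd(b, "c_shank");
  p.fcx = getd(b, "foot_com_x"); p.fcz = getd(b, "foot_com_z");
  p.d_toe = getd(b, "d_toe"); p.d_heel = getd(b, "d_heel");
  p.sole_z = getd(b, "sole_z"); p.inner = getd(b, "inner_offset");
  p.g = getd(b, "g");
  if (p.m_tr <= 0 || p.m_th <= 0 || p.m_sh <= 0 || p.m_ft <= 0 ||
      p.I_tr <= 0 || p.I_th <= 0 || p.I_sh <= 0 || p.I_ft <= 0 ||
      p.L_th <= 0 || p.L_sh <= 0)
    stop("segment masses, inertias and lengths must be strictly positive");
  p.visc_hip = getd(j, "visc_hip"); p.visc_knee = getd(j, "visc_knee");
  p.visc_ank = getd(j, "visc_ankle");
  p.k_lim = getd(j, "k_limit"); p.c_lim = getd(j, "c_limit");
  p.knee_lo = getd(j, "knee_lo"); p.knee_hi = getd(j, "knee_hi");
  p.ank_lo = getd(j, "ankle_lo"); p.ank_hi = getd(j, "ankle_hi");
  p.kn = getd(c, "k_normal"); p.cn = getd(c, "c_normal");
  p.kt = getd(c, "k_tangent"); p.ct = getd(c, "c_tangent");
  p.mu = getd(c, "mu_tangent");
  NumericMatrix M = mu["table"]; // 9 x 7: Fmax lopt vfac kpe r_hip r_knee r_ankle
  if (M.nrow() != NMUS || M.ncol() != 7) stop("muscle table must be 9 x 7");
  for (int i = 0; i < NMUS; ++i) {
    p.Fmax[i] = M(i, 0); p.lopt[i] = M(i, 1); p.vfac[i] = M(i, 2);
    p.kpe[i] = M(i, 3);
    p.r[i][0] = M(i, 4); p.r[i][1] = M(i, 5); p.r[i][2] = M(i, 6);
    if (p.Fmax[i] <= 0 || p.lopt[i] <= 0 || p.vfac[i] <= 0)
      stop("muscle Fmax, lopt, vmax factors must be positive");
  }
  p.Tact = getd(mu, "T_act");
  p.fl_w = getd(mu, "fl_width"); p.fv_c = getd(mu, "fv_shape");
  p.fv_ecc = getd(mu, "fv_ecc");
  p.omega = getd(ct, "omega"); p.Kphi = getd(ct, "K_phi");
  p.phiFC = getd(ct, "phi_fc"); p.tauFC = getd(ct, "tau_fc");
  p.resetting = as<int>(ct["resetting"]);
  NumericVector Phi = ct["Phi"], dPhi = ct["dPhi"], Lam = ct["Lambda"];
  for (int i = 0; i < 5; ++i) {
    p.Phi[i] = Phi[i]; p.dPhi[i] = dPhi[i]; p.Lam[i] = Lam[i];
    if (p.dPhi[i] <= 0) stop("pulse durations must be positive");
  }
  NumericMatrix W = ct["W"];
  if (W.nrow() != NMUS || W.ncol() != 5) stop("synergy weights must be 9 x 5");
  for (int i = 0; i < NMUS; ++i)
    for (int k = 0; k < 5; ++k) {
      if (W(i, k) < 0) stop("synergy weights must be non-negative");
      p.W[i][k] = W(i, k);
    }
  NumericVector kap = ct["kappa"], sig = ct["sigma"], lam = ct["lambda"];
  for (int i = 0; i < NMUS; ++i) {
    p.kap[i] = kap[i]; p.sig[i] = sig[i]; p.lam[i] = lam[i];
  }
  p.theta_ref = getd(ct, "theta_ref"); p.v_ref = getd(ct, "v_ref");
  p.tauReg = getd(ct, "tau_reg");
  return p;
}

// ----------------------------------------------------------------- kinematics

struct Kin {
  double p0[2], v0[2];            // hip point
  double knee[2][2], ankle[2][2]; // per leg
  double vknee[2][2], vankle[2][2];
  double a_th[2], a_sh[2], a_ft[2], w_th[2], w_sh[2], w_ft[2];
  double pts[2][NPTS][2], vpts[2][NPTS][2]; // contact points, world frame
  double com[7][2], vcom[7][2];   // 0 trunk, then thighR shankR footR, L...
};

static inline void rot(double a, double vx, double vz, double* ox, double* oz) {
  double c = std::cos(a), s = std::sin(a);
  *ox = c * vx - s * vz;
  *oz = s * vx + c * vz;
}

static void computeKin(const double* q, const double* qd, const Params& p,
                       Kin& K) {
  K.p0[0] = q[0]; K.p0[1] = q[1];
  K.v0[0] = qd[0]; K.v0[1] = qd[1];
  // trunk COM: p0 + c_tr * (-sin th, cos th)
  double th = q[2], wtr = qd[2];
  K.com[0][0] = q[0] - p.c_tr * std::sin(th);
  K.com[0][1] = q[1] + p.c_tr * std::cos(th);
  K.vcom[0][0] = qd[0] - p.c_tr * std::cos(th) * wtr;
  K.vcom[0][1] = qd[1] - p.c_tr * std::sin(th) * wtr;
  double lx[NPTS] = {p.d_toe, p.d_toe - p.inner, -(p.d_heel - p.inner),
                     -p.d_heel};
  for (int leg = 0; leg < 2; ++leg) {
    int jb = 3 + 3 * leg;
    double ath = th + q[jb], ash = ath - q[jb + 1], aft = ash + q[jb + 2];
    double wth = wtr + qd[jb], wsh = wth - qd[jb + 1], wft = wsh + qd[jb + 2];
    K.a_th[leg] = ath; K.a_sh[leg] = ash; K.a_ft[leg] = aft;
    K.w_th[leg] = wth; K.w_sh[leg] = wsh; K.w_ft[leg] = wft;
    double sth = std::sin(ath), cth = std::cos(ath);
    double ssh = std::sin(ash), csh = std::cos(ash);
    // e(a) = (sin a, -cos a); d/dt e = w * (cos a, sin a)
    K.knee[leg][0] = q[0] + p.L_th * sth;
    K.knee[leg][1] = q[1] - p.L_th * cth;
    K.vknee[leg][0] = qd[0] + p.L_th * cth * wth;
    K.vknee[leg][1] = qd[1] + p.L_th * sth * wth;
    K.ankle[leg][0] = K.knee[leg][0] + p.L_sh * ssh;
    K.ankle[leg][1] = K.knee[leg][1] - p.L_sh * csh;
    K.vankle[leg][0] = K.vknee[leg][0] + p.L_sh * csh * wsh;
    K.vankle[leg][1] = K.vknee[leg][1] + p.L_sh * ssh * wsh;
    int ib = 1 + 3 * leg;
    K.com[ib][0] = q[0] + p.c_th * sth;
    K.com[ib][1] = q[1] - p.c_th * cth;
    K.vcom[ib][0] = qd[0] + p.c_th * cth * wth;
    K.vcom[ib][1] = qd[1] + p.c_th * sth * wth;
    K.com[ib + 1][0] = K.knee[leg][0] + p.c_sh * ssh;
    K.com[ib + 1][1] = K.knee[leg][1] - p.c_sh * csh;
    K.vcom[ib + 1][0] = K.vknee[leg][0] + p.c_sh * csh * wsh;
    K.vcom[ib + 1][1] = K.vknee[leg][1] + p.c_sh * ssh * wsh;
    double ox, oz;
    rot(aft, p.fcx, p.fcz, &ox, &oz);
    K.com[ib + 2][0] = K.ankle[leg][0] + ox;
    K.com[ib + 2][1] = K.ankle[leg][1] + oz;
    // d/dt R(a) v = w * S R(a) v, S(x,z) = (-z, x)
    K.vcom[ib + 2][0] = K.vankle[leg][0] - wft * oz;
    K.vcom[ib + 2][1] = K.vankle[leg][1] + wft * ox;
    for (int k = 0; k < NPTS; ++k) {
      rot(aft, lx[k], -p.sole_z, &ox, &oz);
      K.pts[leg][k][0] = K.ankle[leg][0] + ox;
      K.pts[leg][k][1] = K.ankle[leg][1] + oz;
      K.vpts[leg][k][0] = K.vankle[leg][0] - wft * oz;
      K.vpts[leg][k][1] = K.vankle[leg][1] + wft * ox;
    }
  }
}

// ------------------------------------------------------------------- contact

// Unilateral spring-damper: normal force on penetration, clamped >= 0;
// tangential spring anchored at `anchor_x`, the anchor convecting with the
// belt while the point is in contact (handled by the anchor ODE in the RHS).
static void contactForce(double px, double pz, double vx, double vz,
                         double anchor_x, double belt_v, const Params& p,
                         double* fx, double* fz) {
  *fx = 0.0; *fz = 0.0;
  if (pz >= 0.0) return;
  double fn = -p.kn * pz - p.cn * vz;
  if (fn <= 0.0) return;   // no adhesion
  *fz = fn;
  double ft = -p.kt * (px - anchor_x) - p.ct * (vx - belt_v);
  // tangential force bounded by the normal load (regularized friction limit)
  double cap = p.mu * fn;
  if (ft > cap) ft = cap;
  if (ft < -cap) ft = -cap;
  *fx = ft;
}

// ------------------------------------------------------------ passive joints

static void passiveTorques(const double* q, const double* qd, const Params& p,
                           double* tau6) {
  double visc[3] = {p.visc_hip, p.visc_knee, p.visc_ank};
  for (int leg = 0; leg < 2; ++leg)
    for (int j = 0; j < 3; ++j) {
      int idx = 3 + 3 * leg + j;
      double t = -visc[j] * qd[idx];
      if (j > 0) { // knee and ankle limits
        double lo = (j == 1) ? p.knee_lo : p.ank_lo;
        double hi = (j == 1) ? p.knee_hi : p.ank_hi;
        if (q[idx] < lo)
          t += -p.k_lim * (q[idx] - lo) - p.c_lim * qd[idx];
        else if (q[idx] > hi)
          t += -p.k_lim * (q[idx] - hi) - p.c_lim * qd[idx];
      }
      tau6[3 * leg + j] = t;
    }
}

// ------------------------------------------------------------------- muscles

static void muscleGeom(const double* q, const double* qd, const Params& p,
                       double* len, double* vel) {
  for (int leg = 0; leg < 2; ++leg) {
    int jb = 3 + 3 * leg;
    for (int m = 0; m < NMUS; ++m) {
      double dl = 0.0, dv = 0.0;
      for (int j = 0; j < 3; ++j) {
        dl += p.r[m][j] * q[jb + j];
        dv += p.r[m][j] * qd[jb + j];
      }
      len[leg * NMUS + m] = p.lopt[m] - dl;
      vel[leg * NMUS + m] = -dv;   // lengthening positive
    }
  }
}

static double forceLength(double l, double lopt, double w) {
  double x = (l / lopt - 1.0) / w;
  return std::exp(-x * x);
}

// lengthening velocity positive; classic Hill for shortening, bounded
// eccentric plateau for lengthening
static double forceVelocity(double vl, double vmax, double c, double ecc) {
  if (vl < 0.0) {
    if (vl <= -vmax) return 0.0;
    return (1.0 + vl / vmax) / (1.0 - vl / (c * vmax));
  }
  double k = 0.15 * vmax;
  return (ecc * vl + k) / (vl + k);
}

static void muscleForces(const double* act, const double* len,
                         const double* vel, const Params& p, double* F) {
  for (int leg = 0; leg < 2; ++leg)
    for (int m = 0; m < NMUS; ++m) {
      int i = leg * NMUS + m;
      double vmax = p.vfac[m] * p.lopt[m];
      double fa = act[i] * p.Fmax[m] * forceLength(len[i], p.lopt[m], p.fl_w) *
                  forceVelocity(vel[i], vmax, p.fv_c, p.fv_ecc);
      double fp = (len[i] > p.lopt[m]) ? p.kpe[m] * (len[i] - p.lopt[m]) : 0.0;
      double f = fa + fp;
      F[i] = (f > 0.0) ? f : 0.0;
    }
}

static void muscleTorques(const double* F, const Params& p, double* tau6) {
  for (int leg = 0; leg < 2; ++leg)
    for (int j = 0; j < 3; ++j) {
      double t = 0.0;
      for (int m = 0; m < NMUS; ++m) t += p.r[m][j] * F[leg * NMUS + m];
      tau6[3 * leg + j] += t;
    }
}

// ------------------------------------------------------------------ dynamics

// Mass matrix and generalized forces.  Per body, the COM Jacobian has the
// closed planar-chain form: d(com)/d(theta or hip) = S (com - p0),
// d/d(knee) = -S (com - knee), d/d(ankle) = S (com - ankle), with
// S(x, z) = (-z, x); body angular velocity is a fixed +-1 combination of
// rates, so rotational inertia enters M only.
static void buildJ(const Kin& K, const Params& p, int body, double J[2][NQ],
                   double w[NQ]) {
  for (int c = 0; c < NQ; ++c) { J[0][c] = 0; J[1][c] = 0; w[c] = 0; }
  J[0][0] = 1.0; J[1][1] = 1.0;
  const double* com = K.com[body];
  double rx = com[0] - K.p0[0], rz = com[1] - K.p0[1];
  J[0][2] = -rz; J[1][2] = rx; w[2] = 1.0;
  if (body == 0) return;
  int leg = (body <= 3) ? 0 : 1;
  int seg = (body - 1) % 3;   // 0 thigh, 1 shank, 2 foot
  int jb = 3 + 3 * leg;
  J[0][jb] = -rz; J[1][jb] = rx; w[jb] = 1.0;
  if (seg >= 1) {
    double kx = com[0] - K.knee[leg][0], kz = com[1] - K.knee[leg][1];
    J[0][jb + 1] = kz; J[1][jb + 1] = -kx; w[jb + 1] = -1.0;
  }
  if (seg == 2) {
    double ax = com[0] - K.ankle[leg][0], az = com[1] - K.ankle[leg][1];
    J[0][jb + 2] = -az; J[1][jb + 2] = ax; w[jb + 2] = 1.0;
  }
}

static void accelerations(const double* q, const double* qd, const Params& p,
                          const double* tau6, const double ptF[2][NPTS][2],
                          bool gravity, double trunk_torque, double fx_hip,
                          double fz_hip, const Kin& K, double* qdd) {
  arma::mat M(NQ, NQ, arma::fill::zeros);
  arma::vec Q(NQ, arma::fill::zeros);
  double mass[7] = {p.m_tr, p.m_th, p.m_sh, p.m_ft, p.m_th, p.m_sh, p.m_ft};
  double inert[7] = {p.I_tr, p.I_th, p.I_sh, p.I_ft, p.I_th, p.I_sh, p.I_ft};
  double wtr = qd[2];
  for (int b = 0; b < 7; ++b) {
    double J[2][NQ], w[NQ];
    buildJ(K, p, b, J, w);
    // centripetal COM acceleration (qdd = 0): sum over chain elements of
    // -rate^2 * (world offset of that element)
    double a0[2] = {0.0, 0.0};
    if (b == 0) {
      double rx = K.com[0][0] - K.p0[0], rz = K.com[0][1] - K.p0[1];
      a0[0] = -wtr * wtr * rx; a0[1] = -wtr * wtr * rz;
    } else {
      int leg = (b <= 3) ? 0 : 1, seg = (b - 1) % 3;
      double wth = K.w_th[leg], wsh = K.w_sh[leg], wft = K.w_ft[leg];
      if (seg == 0) {
        a0[0] = -wth * wth * (K.com[b][0] - K.p0[0]);
        a0[1] = -wth * wth * (K.com[b][1] - K.p0[1]);
      } else if (seg == 1) {
        a0[0] = -wth * wth * (K.knee[leg][0] - K.p0[0]) -
                wsh * wsh * (K.com[b][0] - K.knee[leg][0]);
        a0[1] = -wth * wth * (K.knee[leg][1] - K.p0[1]) -
                wsh * wsh * (K.com[b][1] - K.knee[leg][1]);
      } else {
        a0[0] = -wth * wth * (K.knee[leg][0] - K.p0[0]) -
                wsh * wsh * (K.ankle[leg][0] - K.knee[leg][0]) -
                wft * wft * (K.com[b][0] - K.ankle[leg][0]);
        a0[1] = -wth * wth * (K.knee[leg][1] - K.p0[1]) -
                wsh * wsh * (K.ankle[leg][1] - K.knee[leg][1]) -
                wft * wft * (K.com[b][1] - K.ankle[leg][1]);
      }
    }
    double fx = -mass[b] * a0[0];
    double fz = -mass[b] * a0[1] - (gravity ? mass[b] * p.g : 0.0);
    for (int ci = 0; ci < NQ; ++ci) {
      double Jx = J[0][ci], Jz = J[1][ci];
      if (Jx == 0.0 && Jz == 0.0 && w[ci] == 0.0) continue;
      Q(ci) += Jx * fx + Jz * fz;
      for (int cj = ci; cj < NQ; ++cj) {
        double v = mass[b] * (Jx * J[0][cj] + Jz * J[1][cj]) +
                   inert[b] * w[ci] * w[cj];
        if (v != 0.0) { M(ci, cj) += v; if (cj != ci) M(cj, ci) += v; }
      }
    }
  }
  // contact forces at sole points
  for (int leg = 0; leg < 2; ++leg) {
    int jb = 3 + 3 * leg;
    for (int k = 0; k < NPTS; ++k) {
      double fx = ptF[leg][k][0], fz = ptF[leg][k][1];
      if (fx == 0.0 && fz == 0.0) continue;
      double px = K.pts[leg][k][0], pz = K.pts[leg][k][1];
      Q(0) += fx; Q(1) += fz;
      double m0 = (px - K.p0[0]) * fz - (pz - K.p0[1]) * fx;
      Q(2) += m0; Q(jb) += m0;
      Q(jb + 1) -= (px - K.knee[leg][0]) * fz - (pz - K.knee[leg][1]) * fx;
      Q(jb + 2) += (px - K.ankle[leg][0]) * fz - (pz - K.ankle[leg][1]) * fx;
    }
  }
  for (int i = 0; i < 6; ++i) Q(3 + i) += tau6[i];
  Q(2) += trunk_torque;
  Q(0) += fx_hip; Q(1) += fz_hip;
  arma::vec sol;
  bool ok = arma::solve(sol, M, Q, arma::solve_opts::likely_sympd);
  if (!ok) stop("singular mass matrix: check segment parameters");
  for (int i = 0; i < NQ; ++i) qdd[i] = sol(i);
}

// ----------------------------------------------------------------- CPG parts

static inline double wrap2pi(double x) {
  double y = x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
  return (y >= 2.0 * M_PI) ? 0.0 : y;
}

static inline double pulse(double phi, int i, const Params& p) {
  double d = wrap2pi(phi - p.Phi[i]);
  return (d > 0.0 && d <= p.dPhi[i]) ? 1.0 : 0.0;
}

static void synergyCommand(double phi, const Params& p, double* u) {
  double pi_[5];
  for (int i = 0; i < 5; ++i) pi_[i] = pulse(phi, i, p);
  for (int m = 0; m < NMUS; ++m) {
    double s = 0.0;
    for (int i = 0; i < 5; ++i) s += p.W[m][i] * p.Lam[i] * pi_[i];
    u[m] = s;
  }
}

// ----------------------------------------------------------------- full RHS

// State vector y (length 46):
//   0..8   q, 9..17 qd, 18..35 activations (R leg then L), 36..37 phases
//   38..45 tangential anchor x positions (R: toe, toe-in, heel-in, heel; L)
static const int NY = 46;

static void rhs(const double* y, const Params& p, const double* ureg18,
                double belt_v, double assist, double* dy,
                double ptF[2][NPTS][2]) {
  const double* q = y;
  const double* qd = y + NQ;
  const double* act = y + 18;
  const double* phi = y + 36;
  const double* anch = y + 38;
  Kin K;
  computeKin(q, qd, p, K);
  double F[2][NPTS][2];
  for (int leg = 0; leg < 2; ++leg)
    for (int k = 0; k < NPTS; ++k) {
      int ai = leg * NPTS + k;
      contactForce(K.pts[leg][k][0], K.pts[leg][k][1], K.vpts[leg][k][0],
                   K.vpts[leg][k][1], anch[ai], belt_v, p, &F[leg][k][0],
                   &F[leg][k][1]);
      // anchor: convect with the belt while penetrating, track the point
      // otherwise (so each touchdown starts with zero tangential stretch)
      dy[38 + ai] = (K.pts[leg][k][1] < 0.0) ? belt_v : K.vpts[leg][k][0];
    }
  if (ptF)
    for (int leg = 0; leg < 2; ++leg)
      for (int k = 0; k < NPTS; ++k) {
        ptF[leg][k][0] = F[leg][k][0];
        ptF[leg][k][1] = F[leg][k][1];
      }
  double tau6[6];
  passiveTorques(q, qd, p, tau6);
  double len[18], vel[18], Fm[18];
  muscleGeom(q, qd, p, len, vel);
  muscleForces(act, len, vel, p, Fm);
  muscleTorques(Fm, p, tau6);
  // bootstrap scaffold (harness): trunk-righting torque plus partial body
  // weight support and a weak horizontal tether at the hip, faded out
  // during the warm-up and absent on the limit cycle
  double tau_tr = 0.0, fx_h = 0.0, fz_h = 0.0;
  if (assist > 0.0) {
    // one-sided safety net: catches the hips only below z_floor so the
    // legs, not the scaffold, carry body weight in normal cycles
    double z_floor = 0.85 * (p.L_th + p.L_sh + p.sole_z);
    tau_tr = assist * (-150.0 * (q[2] - p.theta_ref) - 30.0 * qd[2]);
    if (q[1] < z_floor) {
      double f = 20000.0 * (z_floor - q[1]) - 1500.0 * qd[1];
      if (f > 0.0) fz_h = assist * f;
    }
    fx_h = assist * (-120.0 * qd[0]);
  } else if (assist < 0.0) {
    // rigid hold: stiff two-sided clamp of trunk height and pitch while
    // the legs entrain to belt and rhythm (released instantaneously)
    double z_hold = 0.955 * (p.L_th + p.L_sh + p.sole_z);
    tau_tr = -1500.0 * (q[2] - p.theta_ref) - 150.0 * qd[2];
    fz_h = 60000.0 * (z_hold - q[1]) - 3000.0 * qd[1];
    fx_h = -150.0 * qd[0];
  }
  double qdd[NQ];
  accelerations(q, qd, p, tau6, F, true, tau_tr, fx_h, fz_h, K, qdd);
  for (int i = 0; i < NQ; ++i) { dy[i] = qd[i]; dy[NQ + i] = qdd[i]; }
  // motor commands and activation dynamics
  for (int leg = 0; leg < 2; ++leg) {
    double us[NMUS];
    synergyCommand(phi[leg], p, us);
    for (int m = 0; m < NMUS; ++m) {
      double u = us[m] + ureg18[leg * NMUS + m];
      if (u < 0.0) u = 0.0;
      if (u > 1.0) u = 1.0;
      dy[18 + leg * NMUS + m] = (u - act[leg * NMUS + m]) / p.Tact;
    }
  }
  // oscillator phases (continuous part of the phase dynamics)
  double dphi_r = phi[0] - phi[1], dphi_l = phi[1] - phi[0];
  dy[36] = p.omega - p.Kphi * std::sin(dphi_r - M_PI);
  dy[37] = p.omega - p.Kphi * std::sin(dphi_l - M_PI);
}

static void rk4(double* y, double h, const Params& p, const double* ureg18,
                double belt_v, double assist) {
  double k1[NY], k2[NY], k3[NY], k4[NY], yt[NY];
  rhs(y, p, ureg18, belt_v, assist, k1, nullptr);
  for (int i = 0; i < NY; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs(yt, p, ureg18, belt_v, assist, k2, nullptr);
  for (int i = 0; i < NY; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs(yt, p, ureg18, belt_v, assist, k3, nullptr);
  for (int i = 0; i < NY; ++i) yt[i] = y[i] + h * k3[i];
  rhs(yt, p, ureg18, belt_v, assist, k4, nullptr);
  for (int i = 0; i < NY; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// ------------------------------------------------- granular exported surface

// [[Rcpp::export]]
NumericMatrix pg_fk_points(NumericVector q, NumericVector qd, List P) {
  if (q.size() != NQ || qd.size() != NQ) stop("q and qd must have length 9");
  for (int i = 0; i < NQ; ++i)
    if (!std::isfinite(q[i]) || !std::isfinite(qd[i]))
      stop("non-finite body state");
  Params p = parseParams(P);
  Kin K;
  computeKin(q.begin(), qd.begin(), p, K);
  NumericMatrix out(8, 4);
  for (int leg = 0; leg < 2; ++leg)
    for (int k = 0; k < NPTS; ++k) {
      int r = leg * NPTS + k;
      out(r, 0) = K.pts[leg][k][0]; out(r, 1) = K.pts[leg][k][1];
      out(r, 2) = K.vpts[leg][k][0]; out(r, 3) = K.vpts[leg][k][1];
    }
  colnames(out) = CharacterVector::create("x", "z", "vx", "vz");
  rownames(out) = CharacterVector::create(
      "r_toe", "r_toe_in", "r_heel_in", "r_heel", "l_toe", "l_toe_in",
      "l_heel_in", "l_heel");
  return out;
}

// [[Rcpp::export]]
NumericVector pg_contact_force(NumericVector pos, NumericVector vel,
                               double anchor_x, double belt_v, List P) {
  Params p = parseParams(P);
  double fx, fz;
  contactForce(pos[0], pos[1], vel[0], vel[1], anchor_x, belt_v, p, &fx, &fz);
  return NumericVector::create(_["fx"] = fx, _["fz"] = fz);
}

// [[Rcpp::export]]
NumericVector pg_passive_torques(NumericVector q, NumericVector qd, List P) {
  Params p = parseParams(P);
  double tau6[6];
  passiveTorques(q.begin(), qd.begin(), p, tau6);
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = tau6[i];
  out.names() = CharacterVector::create("hip_r", "knee_r", "ankle_r", "hip_l",
                                        "knee_l", "ankle_l");
  return out;
}

// [[Rcpp::export]]
NumericMatrix pg_mass_matrix(NumericVector q, List P) {
  Params p = parseParams(P);
  double qd0[NQ] = {0};
  Kin K;
  computeKin(q.begin(), qd0, p, K);
  double mass[7] = {p.m_tr, p.m_th, p.m_sh, p.m_ft, p.m_th, p.m_sh, p.m_ft};
  double inert[7] = {p.I_tr, p.I_th, p.I_sh, p.I_ft, p.I_th, p.I_sh, p.I_ft};
  NumericMatrix M(NQ, NQ);
  for (int b = 0; b < 7; ++b) {
    double J[2][NQ], w[NQ];
    buildJ(K, p, b, J, w);
    for (int ci = 0; ci < NQ; ++ci)
      for (int cj = 0; cj < NQ; ++cj)
        M(ci, cj) += mass[b] * (J[0][ci] * J[0][cj] + J[1][ci] * J[1][cj]) +
                     inert[b] * w[ci] * w[cj];
  }
  return M;
}

// [[Rcpp::export]]
NumericVector pg_accelerations(NumericVector q, NumericVector qd,
                               NumericVector tau6, NumericMatrix point_forces,
                               List P, bool gravity = true) {
  Params p = parseParams(P);
  if (point_forces.nrow() != 8 || point_forces.ncol() != 2)
    stop("point_forces must be 8 x 2 (fx, fz)");
  Kin K;
  computeKin(q.begin(), qd.begin(), p, K);
  double F[2][NPTS][2];
  for (int leg = 0; leg < 2; ++leg)
    for (int k = 0; k < NPTS; ++k) {
      F[leg][k][0] = point_forces(leg * NPTS + k, 0);
      F[leg][k][1] = point_forces(leg * NPTS + k, 1);
    }
  double qdd[NQ];
  accelerations(q.begin(), qd.begin(), p, tau6.begin(), F, gravity, 0.0,
                0.0, 0.0, K, qdd);
  NumericVector out(NQ);
  for (int i = 0; i < NQ; ++i) out[i] = qdd[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix pg_muscle_geometry(NumericVector q, NumericVector qd, List P) {
  Params p = parseParams(P);
  double len[18], vel[18];
  muscleGeom(q.begin(), qd.begin(), p, len, vel);
  NumericMatrix out(18, 2);
  for (int i = 0; i < 18; ++i) { out(i, 0) = len[i]; out(i, 1) = vel[i]; }
  colnames(out) = CharacterVector::create("length", "velocity");
  return out;
}

// [[Rcpp::export]]
NumericVector pg_muscle_forces(NumericVector act, NumericVector len,
                               NumericVector vel, List P) {
  Params p = parseParams(P);
  if (act.size() != 18) stop("activations must have length 18");
  double F[18];
  muscleForces(act.begin(), len.begin(), vel.begin(), p, F);
  NumericVector out(18);
  for (int i = 0; i < 18; ++i) out[i] = F[i];
  return out;
}

// [[Rcpp::export]]
NumericVector pg_muscle_torques(NumericVector forces, List P) {
  Params p = parseParams(P);
  double tau6[6] = {0, 0, 0, 0, 0, 0};
  muscleTorques(forces.begin(), p, tau6);
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = tau6[i];
  out.names() = CharacterVector::create("hip_r", "knee_r", "ankle_r", "hip_l",
                                        "knee_l", "ankle_l");
  return out;
}

// [[Rcpp::export]]
NumericVector pg_energy(NumericVector q, NumericVector qd, List P) {
  Params p = parseParams(P);
  Kin K;
  computeKin(q.begin(), qd.begin(), p, K);
  double mass[7] = {p.m_tr, p.m_th, p.m_sh, p.m_ft, p.m_th, p.m_sh, p.m_ft};
  double inert[7] = {p.I_tr, p.I_th, p.I_sh, p.I_ft, p.I_th, p.I_sh, p.I_ft};
  double wtr = qd[2];
  double wb[7] = {wtr, K.w_th[0], K.w_sh[0], K.w_ft[0], K.w_th[1], K.w_sh[1],
                  K.w_ft[1]};
  double ke = 0.0, pe = 0.0;
  for (int b = 0; b < 7; ++b) {
    ke += 0.5 * mass[b] * (K.vcom[b][0] * K.vcom[b][0] +
                           K.vcom[b][1] * K.vcom[b][1]) +
          0.5 * inert[b] * wb[b] * wb[b];
    pe += mass[b] * p.g * K.com[b][1];
  }
  return NumericVector::create(_["kinetic"] = ke, _["potential"] = pe);
}

// [[Rcpp::export]]
NumericVector pg_synergy_cpp(double phi, List P) {
  Params p = parseParams(P);
  double u[NMUS];
  synergyCommand(phi, p, u);
  NumericVector out(NMUS);
  for (int m = 0; m < NMUS; ++m) out[m] = u[m];
  return out;
}

// ------------------------------------------------------------- the main loop

// [[Rcpp::export]]
List pg_run(List P, List state, double duration, double dt, List belt,
            double log_dt, bool store_traj = true) {
  Params p = parseParams(P);
  if (dt <= 0) stop("dt must be positive");
  if (log_dt < dt) log_dt = dt;
  double nu = getd(belt, "nu");
  if (nu <= 0) stop("baseline belt speed must be positive");
  double pert_on = belt.containsElementNamed("pert_on")
                       ? as<double>(belt["pert_on"]) : NA_REAL;
  double pert_mag = belt.containsElementNamed("pert_mag")
                        ? as<double>(belt["pert_mag"]) : 0.1;
  double pert_dur = belt.containsElementNamed("pert_dur")
                        ? as<double>(belt["pert_dur"]) : 0.001;
  double pert_sign = belt.containsElementNamed("pert_sign")
                         ? as<double>(belt["pert_sign"]) : 1.0;
  double ramp_dur = belt.containsElementNamed("ramp_dur")
                        ? as<double>(belt["ramp_dur"]) : 0.0;
  double assist_until = belt.containsElementNamed("assist_until")
                            ? as<double>(belt["assist_until"]) : 0.0;
  int assist_hold = belt.containsElementNamed("assist_hold")
                        ? as<int>(belt["assist_hold"]) : 0;
  bool has_pert = R_finite(pert_on);
  if (has_pert && pert_dur <= 0) stop("perturbation duration must be positive");

  double y[NY];
  NumericVector q0 = state["q"], qd0 = state["qd"], act0 = state["act"],
                phi0 = state["phi"], anch0 = state["anchors"];
  for (int i = 0; i < NQ; ++i) { y[i] = q0[i]; y[NQ + i] = qd0[i]; }
  for (int i = 0; i < 18; ++i) y[18 + i] = act0[i];
  y[36] = phi0[0]; y[37] = phi0[1];
  for (int i = 0; i < 8; ++i) y[38 + i] = anch0[i];
  double t = getd(state, "t");
  LogicalVector ct0 = state["contact"];
  bool legc[2] = {(bool)ct0[0], (bool)ct0[1]};
  NumericVector due0 = state["due"];
  double due[2] = {due0[0], due0[1]};   // NA when no pending reset
  // regulation delay buffer (absolute times; 8 channels: per leg IL GM TA SO)
  std::vector<double> buf_t;
  std::vector<std::array<double, 8>> buf_p;
  {
    NumericVector bt = state["buf_t"];
    NumericMatrix bp = state["buf_p"];
    for (int i = 0; i < bt.size(); ++i) {
      buf_t.push_back(bt[i]);
      std::array<double, 8> row;
      for (int j = 0; j < 8; ++j) row[j] = bp(i, j);
      buf_p.push_back(row);
    }
  }
  const int regmus[4] = {IL, GM, TA, SO};
  double stand_h = p.L_th + p.L_sh + p.sole_z;
  double fall_h = 0.6 * stand_h;
  double t_end = t + duration;
  int n_steps = (int)std::llround(duration / dt);
  int log_every = (int)std::llround(log_dt / dt);
  if (log_every < 1) log_every = 1;

  // trajectory storage
  int ncol = 1 + 9 + 9 + 2 + 2 + 4 + 1 + 18 + 18;
  int max_rows = store_traj ? n_steps / log_every + 2 : 1;
  NumericMatrix traj(max_rows, ncol);
  int nrow = 0;
  std::vector<double> ev_rc, ev_ro, ev_lc, ev_lo, ev_res_r, ev_res_l;

  double prev_minz[2];
  double last_fc[2] = {-1e9, -1e9};
  double refractory = 0.4 * 2.0 * M_PI / p.omega;
  auto assist_gain = [&](double tt) {
    if (assist_until <= 0.0 || tt >= assist_until) return 0.0;
    if (assist_hold) return -1.0;
    double hold = 0.4 * assist_until;
    if (tt <= hold) return 1.0;
    return (assist_until - tt) / (assist_until - hold);
  };
  auto belt_speed = [&](double tt) {
    double v = nu;
    if (ramp_dur > 0.0 && tt < ramp_dur) v = nu * tt / ramp_dur;
    if (has_pert && tt >= pert_on && tt < pert_on + pert_dur)
      v += pert_sign * pert_mag;
    return -v;   // belt surface runs backward
  };
  auto record_p = [&](double tt) {
    // regulation signals emitted now (delayed before acting on muscles)
    double th = y[2], thd = y[NQ + 2], v = y[NQ + 0];
    std::array<double, 8> row;
    for (int leg = 0; leg < 2; ++leg)
      for (int k = 0; k < 4; ++k) {
        int m = regmus[k];
        double pv = 0.0;
        if (legc[leg]) {
          pv = -p.kap[m] * (th - p.theta_ref) - p.sig[m] * thd -
               p.lam[m] * (v - p.v_ref);
        }
        row[leg * 4 + k] = pv;
      }
    buf_t.push_back(tt);
    buf_p.push_back(row);
  };
  auto lookup_ureg = [&](double tt, double* ureg18) {
    for (int i = 0; i < 18; ++i) ureg18[i] = 0.0;
    double tq = tt - p.tauReg;
    if (buf_t.empty() || tq < buf_t.front()) return;
    // linear interpolation on the sample grid
    size_t lo = 0, hi = buf_t.size() - 1;
    if (tq >= buf_t[hi]) lo = hi;
    else {
      while (hi - lo > 1) {
        size_t mid = (lo + hi) / 2;
        if (buf_t[mid] <= tq) lo = mid; else hi = mid;
      }
    }
    for (int leg = 0; leg < 2; ++leg)
      for (int k = 0; k < 4; ++k) {
        double v;
        if (lo == buf_t.size() - 1) v = buf_p[lo][leg * 4 + k];
        else {
          double w = (tq - buf_t[lo]) / (buf_t[lo + 1] - buf_t[lo]);
          v = (1 - w) * buf_p[lo][leg * 4 + k] + w * buf_p[lo + 1][leg * 4 + k];
        }
        ureg18[leg * NMUS + regmus[k]] += v;
      }
  };
  auto log_row = [&](double tt) {
    if (!store_traj || nrow >= max_rows) return;
    Kin K;
    computeKin(y, y + NQ, p, K);
    double F[2][NPTS][2], fsum[2][2] = {{0, 0}, {0, 0}};
    double bv = belt_speed(tt);
    for (int leg = 0; leg < 2; ++leg)
      for (int k = 0; k < NPTS; ++k) {
        contactForce(K.pts[leg][k][0], K.pts[leg][k][1], K.vpts[leg][k][0],
                     K.vpts[leg][k][1], y[38 + leg * NPTS + k], bv, p,
                     &F[leg][k][0], &F[leg][k][1]);
        fsum[leg][0] += F[leg][k][0];
        fsum[leg][1] += F[leg][k][1];
      }
    int c = 0;
    traj(nrow, c++) = tt;
    for (int i = 0; i < NQ; ++i) traj(nrow, c++) = y[i];
    for (int i = 0; i < NQ; ++i) traj(nrow, c++) = y[NQ + i];
    traj(nrow, c++) = wrap2pi(y[36]); traj(nrow, c++) = wrap2pi(y[37]);
    traj(nrow, c++) = legc[0]; traj(nrow, c++) = legc[1];
    traj(nrow, c++) = fsum[0][0]; traj(nrow, c++) = fsum[0][1];
    traj(nrow, c++) = fsum[1][0]; traj(nrow, c++) = fsum[1][1];
    traj(nrow, c++) = -bv;
    for (int i = 0; i < 18; ++i) traj(nrow, c++) = y[18 + i];
    double ureg18[18];
    lookup_ureg(tt, ureg18);
    for (int leg = 0; leg < 2; ++leg) {
      double us[NMUS];
      synergyCommand(wrap2pi(y[36 + leg]), p, us);
      for (int m = 0; m < NMUS; ++m) {
        double u = us[m] + ureg18[leg * NMUS + m];
        if (u < 0) u = 0;
        if (u > 1) u = 1;
        traj(nrow, c++) = u;
      }
    }
    ++nrow;
  };

  {
    Kin K;
    computeKin(y, y + NQ, p, K);
    for (int leg = 0; leg < 2; ++leg) {
      double mz = K.pts[leg][0][1];
      for (int k = 1; k < NPTS; ++k) mz = std::min(mz, K.pts[leg][k][1]);
      prev_minz[leg] = mz;
    }
    if (buf_t.empty()) record_p(t);
    log_row(t);
  }

  std::string status = "ok";
  double fall_time = NA_REAL;
  for (int step = 0; step < n_steps; ++step) {
    double t_target = t + dt;
    double ureg18[18];
    lookup_ureg(t, ureg18);
    // split the step at pending reset times and perturbation edges
    while (t < t_target - 1e-12) {
      double t_next = t_target;
      for (int leg = 0; leg < 2; ++leg)
        if (R_finite(due[leg]) && due[leg] > t && due[leg] < t_next)
          t_next = due[leg];
      if (has_pert) {
        if (pert_on > t && pert_on < t_next) t_next = pert_on;
        double off = pert_on + pert_dur;
        if (off > t && off < t_next) t_next = off;
      }
      double h = t_next - t;
      rk4(y, h, p, ureg18, belt_speed(t + 0.5 * h), assist_gain(t));
      t = t_next;
      for (int leg = 0; leg < 2; ++leg)
        if (R_finite(due[leg]) && t >= due[leg] - 1e-12) {
          if (p.resetting) y[36 + leg] = p.phiFC;
          (leg == 0 ? ev_res_r : ev_res_l).push_back(due[leg]);
          due[leg] = NA_REAL;
        }
    }
    t = t_target;
    // clamp activations, wrap phases
    for (int i = 18; i < 36; ++i) {
      if (y[i] < 0) y[i] = 0;
      if (y[i] > 1) y[i] = 1;
    }
    y[36] = wrap2pi(y[36]); y[37] = wrap2pi(y[37]);
    bool bad = false;
    for (int i = 0; i < NY; ++i)
      if (!std::isfinite(y[i])) bad = true;
    if (bad) { status = "diverged"; break; }
    // foot-contact events (per-leg OR over the 4 points, with hysteresis)
    Kin K;
    computeKin(y, y + NQ, p, K);
    for (int leg = 0; leg < 2; ++leg) {
      double mz = K.pts[leg][0][1];
      for (int k = 1; k < NPTS; ++k) mz = std::min(mz, K.pts[leg][k][1]);
      if (!legc[leg] && mz < -0.002) {
        // 2 mm penetration threshold: a committed landing, not a graze
        double z0 = prev_minz[leg] + 0.002, z1 = mz + 0.002;
        double frac = (z0 > 0.0 && z0 > z1) ? z0 / (z0 - z1) : 1.0;
        double t_ev = t - dt + frac * dt;
        legc[leg] = true;
        if (t_ev - last_fc[leg] >= refractory) {
          last_fc[leg] = t_ev;
          (leg == 0 ? ev_rc : ev_lc).push_back(t_ev);
          if (!R_finite(due[leg])) due[leg] = t_ev + p.tauFC;
        }
      } else if (legc[leg] && mz > 0.0005) {
        legc[leg] = false;
        (leg == 0 ? ev_ro : ev_lo).push_back(t);
      }
      prev_minz[leg] = mz;
    }
    record_p(t);
    // trim the delay buffer
    while (buf_t.size() > 4 && buf_t[1] < t - p.tauReg - 10 * dt) {
      buf_t.erase(buf_t.begin());
      buf_p.erase(buf_p.begin());
    }
    if ((step + 1) % log_every == 0) log_row(t);
    if (y[1] < fall_h) { status = "fall"; fall_time = t; break; }
  }

  // final resume state
  NumericVector qf(NQ), qdf(NQ), actf(18), phif(2), anchf(8), duef(2);
  for (int i = 0; i < NQ; ++i) { qf[i] = y[i]; qdf[i] = y[NQ + i]; }
  for (int i = 0; i < 18; ++i) actf[i] = y[18 + i];
  phif[0] = y[36]; phif[1] = y[37];
  for (int i = 0; i < 8; ++i) anchf[i] = y[38 + i];
  duef[0] = due[0]; duef[1] = due[1];
  int nb = buf_t.size();
  NumericVector bt(nb);
  NumericMatrix bp(nb, 8);
  for (int i = 0; i < nb; ++i) {
    bt[i] = buf_t[i];
    for (int j = 0; j < 8; ++j) bp(i, j) = buf_p[i][j];
  }
  List st = List::create(
      _["t"] = t, _["q"] = qf, _["qd"] = qdf, _["act"] = actf, _["phi"] = phif,
      _["anchors"] = anchf,
      _["contact"] = LogicalVector::create(legc[0], legc[1]), _["due"] = duef,
      _["buf_t"] = bt, _["buf_p"] = bp);
  List events = List::create(
      _["contact_r"] = wrap(ev_rc), _["off_r"] = wrap(ev_ro),
      _["contact_l"] = wrap(ev_lc), _["off_l"] = wrap(ev_lo),
      _["reset_r"] = wrap(ev_res_r), _["reset_l"] = wrap(ev_res_l));
  NumericMatrix tout;
  if (store_traj) {
    tout = traj(Range(0, std::max(nrow - 1, 0)), Range(0, ncol - 1));
    CharacterVector cn(ncol);
    int c = 0;
    cn[c++] = "t";
    const char* qn[9] = {"x", "z", "theta", "hip_r", "knee_r", "ankle_r",
                         "hip_l", "knee_l", "ankle_l"};
    for (int i = 0; i < 9; ++i) cn[c++] = qn[i];
    for (int i = 0; i < 9; ++i) cn[c++] = std::string(qn[i]) + "_d";
    cn[c++] = "phi_r"; cn[c++] = "phi_l";
    cn[c++] = "stance_r"; cn[c++] = "stance_l";
    cn[c++] = "fx_r"; cn[c++] = "fz_r"; cn[c++] = "fx_l"; cn[c++] = "fz_l";
    cn[c++] = "belt_speed";
    const char* mn[9] = {"il", "gm", "va", "bfs", "ta", "so", "rf", "bfl",
                         "gc"};
    for (int leg = 0; leg < 2; ++leg)
      for (int i = 0; i < 9; ++i)
        cn[c++] = std::string("act_") + mn[i] + (leg == 0 ? "_r" : "_l");
    for (int leg = 0; leg < 2; ++leg)
      for (int i = 0; i < 9; ++i)
        cn[c++] = std::string("u_") + mn[i] + (leg == 0 ? "_r" : "_l");
    colnames(tout) = cn;
  }
  return List::create(_["status"] = status, _["t_end"] = t,
                      _["fall_time"] = fall_time, _["state"] = st,
                      _["events"] = events, _["traj"] = tout);
}
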