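// Multibody core: lumped sphere-beam chains, penalty contacts, stiff
// linearly-implicit integration. R types appear only at the API edge.
#include <Rcpp.h>
#include <array>
#include <vector>
#include "core_math.h"

using namespace Rcpp;

// ---------------------------------------------------------------- model ----

struct ChainSpec {
  int n = 0;
  double L0 = 0, EA = 0, GJ = 0, EI = 0, Phi = 0, beta = 0, r_contact = 0;
  std::vector<Vec3> r_rel0;
  std::vector<Mat3> Rrel0;
  std::vector<Mat3> E0;
  std::vector<double> mass;
  std::vector<Vec3> inertia;       // body-frame diagonal (tangent first)
  std::vector<int> clamped;        // 0-based sphere indices
  double K12[12][12] = {{0}};      // element-frame stiffness
  double Kbb[6][6] = {{0}};        // condensed distal-node block
};

struct Prim {
  int type = 0, class_id = 0, guide = -1;
  double p[15] = {0};
};

struct RingSpec {
  bool present = false;
  std::vector<Prim> prims;
  double hole_length = 0;
  std::vector<int> guide_of_nail;
};

struct CanalSpec {
  bool present = false;
  double prox[4] = {0}, dist[4] = {0}, bow[3] = {0};
  Vec3 frac_point, frac_normal;
  Mat3 frame;
  int class_id = 0;
};

struct FragSpec {
  double mass = 0.1;
  Vec3 inertia{1e-4, 1e-4, 1e-4};
  Vec3 k, kr, c, cr;               // bushing stiffness/damping, fracture frame
};

struct Model {
  std::vector<ChainSpec> chains;
  std::vector<double> Kp, ep, Cp, dp, abortp;
  RingSpec ring;
  CanalSpec canal;
  FragSpec frag;
  bool has_frag = false;
  std::vector<std::pair<int, int>> pairs;
  int nn_class = -1;
  int subdiv = 2;
  Vec3 gravity;
  std::vector<std::array<double, 7>> prescribed; // chain,sphere,axis,x0,x1,t0,t1
  std::vector<std::array<double, 5>> point_forces; // chain,sphere,fx,fy,fz
};

struct Stage {
  double t0 = 0, t1 = 1;
  double ring_y0 = 0, travel = 0, m_t0 = 0, m_t1 = 1;
  double load_peak = 0, load_t0 = 0, load_t1 = 1;
  Vec3 load_dir{1, 0, 0};
  bool frag_free = false;
  double drag = 0;
};

struct Control {
  double h0 = 1e-5, hmin = 1e-10, hmax = 5e-3;
  double rtol = 2e-4, atol_v = 1e-5, atol_w = 1e-3;
  double out_dt = 0.01, max_pen_ratio = 10.0;
  bool save_states = false, record = true;
};

struct BodyState {
  Vec3 x, v, w;
  Quat q;
};

struct SimState {
  std::vector<std::vector<BodyState>> chains;
  BodyState frag;
  bool has_frag = false;
};

// ------------------------------------------------------- motion laws -------

static inline double quint01(double tau, double& dvel) {
  if (tau <= 0) { dvel = 0; return 0; }
  if (tau >= 1) { dvel = 0; return 1; }
  double t2 = tau * tau, t3 = t2 * tau;
  dvel = 30 * t2 * t2 - 60 * t3 + 30 * t2;
  return 6 * t3 * t2 - 15 * t2 * t2 + 10 * t3;
}

static inline double ring_pos(const Stage& st, double t, double& vel) {
  double dur = st.m_t1 - st.m_t0;
  if (dur <= 0 || st.travel == 0) { vel = 0; return st.ring_y0; }
  double dv;
  double s = quint01((t - st.m_t0) / dur, dv);
  vel = st.travel * dv / dur;
  return st.ring_y0 + st.travel * s;
}

static inline double load_mag(const Stage& st, double t) {
  double dur = st.load_t1 - st.load_t0;
  if (st.load_peak == 0 || dur <= 0) return 0;
  double dv;
  return st.load_peak * quint01((t - st.load_t0) / dur, dv);
}

// ------------------------------------------------------ contact law --------

static inline double step_smooth_c(double x, double x0, double h0,
                                   double x1, double h1) {
  if (x <= x0) return h0;
  if (x >= x1) return h1;
  double d = (x - x0) / (x1 - x0);
  return h0 + (h1 - h0) * d * d * (3 - 2 * d);
}

// Geometric query result; n is the push-out direction on the sphere.
struct Gap {
  bool hit = false;
  double g = 0;
  Vec3 n, pt;
};

static Gap gap_tube(const Vec3& p, double rs, double cx, double cz,
                    double R) {
  Gap out;
  Vec3 d(p.x - cx, 0, p.z - cz);
  double rho = norm(d);
  double g = rho + rs - R;
  if (g <= 0) return out;
  Vec3 dn = rho > 1e-12 ? d * (1.0 / rho) : Vec3(1, 0, 0);
  out.hit = true; out.g = g; out.n = -dn;
  out.pt = Vec3(cx, p.y, cz) + dn * R;
  return out;
}

// guide-hole wall sector (solid outside radius, bounded in angle and y)
static Gap gap_wall_patch(const Vec3& p, double rs, const Prim& pr,
                          double ring_y) {
  Gap out;
  double cx = pr.p[0], cz = pr.p[2];
  double rh = pr.p[3], len = pr.p[4], a0 = pr.p[5], a1 = pr.p[6];
  double yl = p.y - ring_y;
  Vec3 d(p.x - cx, 0, p.z - cz);
  double rho = std::sqrt(d.x * d.x + d.z * d.z);
  double ang = std::atan2(d.x, d.z);
  if (ang < 0) ang += 2 * M_PI;
  if (ang >= a0 && ang <= a1 && yl >= 0 && yl <= len) {
    double g = rho + rs - rh;
    if (g <= 0) return out;
    Vec3 dn = rho > 1e-12 ? d * (1.0 / rho)
                          : Vec3(std::sin((a0 + a1) / 2), 0,
                                 std::cos((a0 + a1) / 2));
    out.hit = true; out.g = g; out.n = -dn;
    out.pt = Vec3(cx, p.y, cz) + dn * rh;
    return out;
  }
  double angc = std::min(std::max(ang, a0), a1);
  double ylc = std::min(std::max(yl, 0.0), len);
  Vec3 e(cx + rh * std::sin(angc), ring_y + ylc, cz + rh * std::cos(angc));
  Vec3 dv = p - e;
  double dist = norm(dv);
  double g = rs - dist;
  if (g <= 0 || dist < 1e-12) return out;
  out.hit = true; out.g = g; out.n = dv * (1.0 / dist); out.pt = e;
  return out;
}

// solid central cylinder of the conceptual ring (axis = ring axis)
static Gap gap_central(const Vec3& p, double rs, const Prim& pr,
                       double ring_y) {
  Gap out;
  double R = pr.p[3], len = pr.p[4];
  double yl = p.y - ring_y;
  Vec3 d(p.x, 0, p.z);
  double rho = norm(d);
  Vec3 dn = rho > 1e-12 ? d * (1.0 / rho) : Vec3(1, 0, 0);
  if (yl >= 0 && yl <= len) {
    double g = rs + R - rho;
    if (g <= 0) return out;
    out.hit = true; out.g = g; out.n = dn;
    out.pt = dn * R; out.pt.y = p.y;
    return out;
  }
  double ylc = std::min(std::max(yl, 0.0), len);
  Vec3 e = dn * std::min(rho, R); e.y = ring_y + ylc;
  Vec3 dv = p - e;
  double dist = norm(dv);
  double g = rs - dist;
  if (g <= 0 || dist < 1e-12) return out;
  out.hit = true; out.g = g; out.n = dv * (1.0 / dist); out.pt = e;
  return out;
}

// rounded hole-mouth rim (torus around the guide axis)
static Gap gap_rim(const Vec3& p, double rs, const Prim& pr, double ring_y) {
  Gap out;
  double cx = pr.p[0], cz = pr.p[2];
  double cr = pr.p[3], tr = pr.p[4], yl = pr.p[5];
  double yc = ring_y + yl;
  Vec3 d(p.x - cx, 0, p.z - cz);
  double rho = std::sqrt(d.x * d.x + d.z * d.z);
  Vec3 dn = rho > 1e-12 ? d * (1.0 / rho) : Vec3(1, 0, 0);
  Vec3 cpt(cx + cr * dn.x, yc, cz + cr * dn.z);
  Vec3 dv = p - cpt;
  double dist = norm(dv);
  double g = rs + tr - dist;
  if (g <= 0 || dist < 1e-12) return out;
  out.hit = true; out.g = g; out.n = dv * (1.0 / dist);
  out.pt = cpt + out.n * tr;
  return out;
}

static Gap gap_box_core(const Vec3& p, double rs, const Vec3& c,
                        const Mat3& U, const Vec3& half) {
  Gap out;
  Vec3 l = U.tmul(p - c);
  Vec3 cl(std::min(std::max(l.x, -half.x), half.x),
          std::min(std::max(l.y, -half.y), half.y),
          std::min(std::max(l.z, -half.z), half.z));
  Vec3 dv = l - cl;
  double dist = norm(dv);
  if (dist > 1e-12) {
    double g = rs - dist;
    if (g <= 0) return out;
    Vec3 nl = dv * (1.0 / dist);
    out.hit = true; out.g = g; out.n = U * nl; out.pt = c + U * cl;
    return out;
  }
  double dmin = half.x - std::fabs(l.x);
  Vec3 nl(l.x >= 0 ? 1.0 : -1.0, 0, 0);
  double dy = half.y - std::fabs(l.y);
  if (dy < dmin) { dmin = dy; nl = Vec3(0, l.y >= 0 ? 1.0 : -1.0, 0); }
  double dz = half.z - std::fabs(l.z);
  if (dz < dmin) { dmin = dz; nl = Vec3(0, 0, l.z >= 0 ? 1.0 : -1.0); }
  out.hit = true; out.g = rs + dmin; out.n = U * nl; out.pt = p;
  return out;
}

static Gap gap_box(const Vec3& p, double rs, const Prim& pr, double ring_y) {
  Vec3 c(pr.p[0], pr.p[1] + ring_y, pr.p[2]);
  Vec3 half(pr.p[3], pr.p[4], pr.p[5]);
  Mat3 U;
  for (int col = 0; col < 3; ++col)
    for (int row = 0; row < 3; ++row)
      U(row, col) = pr.p[6 + 3 * col + row];
  return gap_box_core(p, rs, c, U, half);
}

static Gap gap_prim(const Vec3& p, double rs, const Prim& pr, double ring_y) {
  switch (pr.type) {
    case 1: return gap_wall_patch(p, rs, pr, ring_y);
    case 2: return gap_central(p, rs, pr, ring_y);
    case 3: return gap_rim(p, rs, pr, ring_y);
    case 4: return gap_box(p, rs, pr, ring_y);
  }
  return Gap();
}

static inline double canal_R(const CanalSpec& cn, int frag, double y) {
  const double* s = frag == 0 ? cn.prox : cn.dist;
  double yc = std::min(std::max(y, s[0]), s[1]);
  double tau = (s[1] > s[0]) ? (yc - s[0]) / (s[1] - s[0]) : 0.0;
  return s[2] + tau * (s[3] - s[2]);
}

static inline double canal_bow_x(const CanalSpec& cn, double y) {
  if (cn.bow[2] == 0) return 0;
  double y0 = cn.bow[0], y1 = cn.bow[1];
  double yc = std::min(std::max(y, y0), y1);
  return cn.bow[2] * std::sin(M_PI * (yc - y0) / (y1 - y0));
}

// sphere vs canal fragment inner wall (fragment reference placement)
static Gap gap_canal_frag(const Vec3& p, double rs, const CanalSpec& cn,
                          int frag) {
  Gap out;
  double side = dot(p - cn.frac_point, cn.frac_normal);
  if ((frag == 0 && side > 0) || (frag == 1 && side <= 0)) return out;
  const double* s = frag == 0 ? cn.prox : cn.dist;
  if (p.y < s[0] - rs || p.y > s[1] + rs) return out;
  return gap_tube(p, rs, canal_bow_x(cn, p.y), 0.0, canal_R(cn, frag, p.y));
}

// ------------------------------------------------------- beam element ------

static void build_K12(ChainSpec& ch) {
  double L = ch.L0;
  double ax = ch.EA / L, to = ch.GJ / L;
  double P = ch.Phi;
  double b1 = 12 * ch.EI / ((1 + P) * L * L * L);
  double b2 = 6 * ch.EI / ((1 + P) * L * L);
  double b3 = (4 + P) * ch.EI / ((1 + P) * L);
  double b4 = (2 - P) * ch.EI / ((1 + P) * L);
  double (&K)[12][12] = ch.K12;
  std::memset(K, 0, sizeof(ch.K12));
  K[0][0] = K[6][6] = ax; K[0][6] = K[6][0] = -ax;
  K[3][3] = K[9][9] = to; K[3][9] = K[9][3] = -to;
  int iy[4] = {1, 5, 7, 11};
  double By[4][4] = {{b1, b2, -b1, b2}, {b2, b3, -b2, b4},
                     {-b1, -b2, b1, -b2}, {b2, b4, -b2, b3}};
  int iz[4] = {2, 4, 8, 10};
  double Bz[4][4] = {{b1, -b2, -b1, -b2}, {-b2, b3, b2, b4},
                     {-b1, b2, b1, b2}, {-b2, b4, b2, b3}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      K[iy[i]][iy[j]] += By[i][j];
      K[iz[i]][iz[j]] += Bz[i][j];
    }
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) ch.Kbb[i][j] = K[6 + i][6 + j];
}

// wrench of segment i on its distal sphere (world frame) and strain energy
static void segment_wrench(const ChainSpec& ch, int i, const BodyState& A_,
                           const BodyState& B_, Vec3& Fb, Vec3& Mb,
                           Mat3& Re_out, double* pe) {
  Mat3 Ra = qrot(A_.q), Rb = qrot(B_.q);
  Vec3 r_ab = B_.x - A_.x;
  Vec3 r_rel = Ra.tmul(r_ab);
  Mat3 Rrel = Ra.t() * Rb;
  Mat3 dR = Rrel * ch.Rrel0[i].t();
  Vec3 th_a = rot_log(dR);
  const Mat3& E0 = ch.E0[i];
  Vec3 d_e = E0.tmul(r_rel - ch.r_rel0[i]);
  Vec3 th_e = E0.tmul(th_a);
  Vec3 vrel = Ra.tmul(B_.v - A_.v - cross(A_.w, r_ab));
  Vec3 wrel = Ra.tmul(B_.w - A_.w);
  Vec3 vd_e = E0.tmul(vrel);
  Vec3 wd_e = E0.tmul(wrel);
  double u6[6] = {d_e.x, d_e.y, d_e.z, th_e.x, th_e.y, th_e.z};
  double ud6[6] = {vd_e.x, vd_e.y, vd_e.z, wd_e.x, wd_e.y, wd_e.z};
  double f6[6];
  for (int r = 0; r < 6; ++r) {
    double s = 0;
    for (int k = 0; k < 6; ++k)
      s += ch.Kbb[r][k] * (u6[k] + ch.beta * ud6[k]);
    f6[r] = -s;
  }
  Re_out = Ra * E0;
  Fb = Re_out * Vec3(f6[0], f6[1], f6[2]);
  Mb = Re_out * Vec3(f6[3], f6[4], f6[5]);
  if (pe) {
    double e = 0;
    for (int r = 0; r < 6; ++r)
      for (int k = 0; k < 6; ++k)
        e += 0.5 * u6[r] * ch.Kbb[r][k] * u6[k];
    *pe += e;
  }
}

// --------------------------------------------------------- containers ------

struct LogAcc {
  std::vector<Vec3> base_reaction;
  std::vector<Vec3> ring_force;
  std::vector<double> ring_fmag;
  std::vector<double> nn_sum;
  std::vector<Vec3> nn_vec;
  std::vector<Vec3> canal_prox, canal_dist;
  double pe_beam = 0, pe_contact = 0, ke = 0;
  double max_pen = 0;
  void init(int nc, int np) {
    base_reaction.assign(nc, Vec3());
    ring_force.assign(nc, Vec3());
    ring_fmag.assign(nc, 0.0);
    nn_sum.assign(np, 0.0);
    nn_vec.assign(np, Vec3());
    canal_prox.assign(nc, Vec3());
    canal_dist.assign(nc, Vec3());
    pe_beam = pe_contact = ke = max_pen = 0;
  }
};

struct Workspace {
  std::vector<BandMatrix> A;
  std::vector<std::vector<double>> rhs;
  std::vector<std::vector<Vec3>> F, Tq, Kv, Kw;
  BandMatrix Af;
  std::vector<double> rhsf;
  Vec3 Ff, Tf, Kvf, Kwf;
  std::vector<double> a_prev;
  double max_pen_eval = 0;
  std::vector<double> pen_class;     // run-max penetration (m) per class
};

enum ContactTag { TAG_RING = 0, TAG_CANAL_PROX = 1, TAG_CANAL_DIST = 2 };

// =================================================== force evaluation ======

static void evaluate(const Model& M, const SimState& S, double t,
                     double ring_y, double ring_v, const Stage& st, double h,
                     Workspace& W, bool build, LogAcc* log) {
  const int nc = (int)M.chains.size();
  double max_pen = 0;

  for (int c = 0; c < nc; ++c) {
    std::fill(W.F[c].begin(), W.F[c].end(), Vec3());
    std::fill(W.Tq[c].begin(), W.Tq[c].end(), Vec3());
    std::fill(W.Kv[c].begin(), W.Kv[c].end(), Vec3());
    std::fill(W.Kw[c].begin(), W.Kw[c].end(), Vec3());
    if (build) {
      W.A[c].zero();
      std::fill(W.rhs[c].begin(), W.rhs[c].end(), 0.0);
    }
  }
  W.Ff = W.Tf = W.Kvf = W.Kwf = Vec3();
  if (build && M.has_frag) {
    W.Af.zero();
    std::fill(W.rhsf.begin(), W.rhsf.end(), 0.0);
  }

  // ---- gravity, drag, gyroscopic terms, mass blocks ----
  for (int c = 0; c < nc; ++c) {
    const ChainSpec& ch = M.chains[c];
    for (int i = 0; i < ch.n; ++i) {
      const BodyState& b = S.chains[c][i];
      Mat3 R = qrot(b.q);
      const Vec3& Ib = ch.inertia[i];
      Vec3 wl = R.tmul(b.w);
      Vec3 Iww = R * Vec3(Ib.x * wl.x, Ib.y * wl.y, Ib.z * wl.z);
      W.F[c][i] += M.gravity * ch.mass[i];
      W.Tq[c][i] -= cross(b.w, Iww);
      if (st.drag > 0) {
        W.F[c][i] -= b.v * (st.drag * ch.mass[i]);
        W.Tq[c][i] -= Iww * st.drag;
      }
      if (build) {
        BandMatrix& A = W.A[c];
        int o = 6 * i;
        double sd = 1.0 + h * st.drag;
        for (int k = 0; k < 3; ++k) A.add(o + k, o + k, ch.mass[i] * sd);
        for (int r = 0; r < 3; ++r)
          for (int s2 = 0; s2 <= r; ++s2) {
            double v = 0;
            for (int k = 0; k < 3; ++k)
              v += R(r, k) * (&Ib.x)[k] * R(s2, k);
            A.add(o + 3 + r, o + 3 + s2, v * sd);
          }
      }
      if (log) log->ke += 0.5 * (ch.mass[i] * dot(b.v, b.v) + dot(b.w, Iww));
    }
  }
  for (const auto& pf : M.point_forces)
    W.F[(int)pf[0]][(int)pf[1]] += Vec3(pf[2], pf[3], pf[4]);

  // ---- beam segments ----
  for (int c = 0; c < nc; ++c) {
    const ChainSpec& ch = M.chains[c];
    for (int i = 0; i < ch.n - 1; ++i) {
      const BodyState& A_ = S.chains[c][i];
      const BodyState& B_ = S.chains[c][i + 1];
      Vec3 Fb, Mb;
      Mat3 Re;
      segment_wrench(ch, i, A_, B_, Fb, Mb, Re,
                     log ? &log->pe_beam : nullptr);
      Vec3 r_ab = B_.x - A_.x;
      W.F[c][i + 1] += Fb;
      W.Tq[c][i + 1] += Mb;
      W.F[c][i] -= Fb;
      W.Tq[c][i] -= Mb + cross(r_ab, Fb);

      if (build) {
        BandMatrix& A = W.A[c];
        double scale = h * ch.beta + h * h;
        int off[4] = {6 * i, 6 * i + 3, 6 * (i + 1), 6 * (i + 1) + 3};
        double v12[12] = {A_.v.x, A_.v.y, A_.v.z, A_.w.x, A_.w.y, A_.w.z,
                          B_.v.x, B_.v.y, B_.v.z, B_.w.x, B_.w.y, B_.w.z};
        double Kv12[12] = {0};
        for (int I = 0; I < 4; ++I)
          for (int J = 0; J < 4; ++J) {
            Mat3 Kb;
            for (int r = 0; r < 3; ++r)
              for (int s2 = 0; s2 < 3; ++s2)
                Kb(r, s2) = ch.K12[3 * I + r][3 * J + s2];
            Mat3 Kw = Re * Kb * Re.t();
            for (int r = 0; r < 3; ++r)
              for (int s2 = 0; s2 < 3; ++s2)
                Kv12[3 * I + r] += Kw(r, s2) * v12[3 * J + s2];
            if (off[I] >= off[J])
              for (int r = 0; r < 3; ++r)
                for (int s2 = 0; s2 < 3; ++s2) {
                  int gi = off[I] + r, gj = off[J] + s2;
                  if (gi >= gj) A.add(gi, gj, scale * Kw(r, s2));
                }
          }
        W.Kv[c][i] += Vec3(Kv12[0], Kv12[1], Kv12[2]);
        W.Kw[c][i] += Vec3(Kv12[3], Kv12[4], Kv12[5]);
        W.Kv[c][i + 1] += Vec3(Kv12[6], Kv12[7], Kv12[8]);
        W.Kw[c][i + 1] += Vec3(Kv12[9], Kv12[10], Kv12[11]);
      }
    }
  }

  // ---- unified sphere/collocation-point contact against a surface ----
  auto contact = [&](int c, int ia, int ib, double wb, const Gap& gp,
                     int cls, const Vec3& v_pt, const Vec3& v_surf, int tag) {
    double K = M.Kp[cls], e = M.ep[cls];
    double g = gp.g;
    double gdot = -dot(v_pt - v_surf, gp.n);
    double stp = step_smooth_c(g, 0, 0, M.dp[cls], M.Cp[cls]);
    double Fn = K * std::pow(g, e) + stp * gdot;
    if (Fn < 0) Fn = 0;
    Vec3 Fv = gp.n * Fn;
    double wa = 1.0 - wb;
    W.F[c][ia] += Fv * wa;
    if (wb > 0) W.F[c][ib] += Fv * wb;
    double pen = g / M.abortp[cls];
    if (pen > max_pen) max_pen = pen;
    if (g > W.pen_class[cls]) W.pen_class[cls] = g;

    double kn = K * e * std::pow(g, e - 1);
    if (build) {
      double s = h * stp + h * h * kn;
      BandMatrix& A = W.A[c];
      const double nv[3] = {gp.n.x, gp.n.y, gp.n.z};
      auto add_block = [&](int oi, int oj, double wgt) {
        for (int r = 0; r < 3; ++r)
          for (int s2 = 0; s2 < 3; ++s2) {
            int gi = 6 * oi + r, gj = 6 * oj + s2;
            if (gi >= gj) A.add(gi, gj, s * wgt * nv[r] * nv[s2]);
          }
      };
      add_block(ia, ia, wa * wa);
      if (wb > 0) {
        add_block(ib, ib, wb * wb);
        add_block(ib, ia, wa * wb);
      }
      double kv = kn * dot(gp.n, v_pt - v_surf);
      W.Kv[c][ia] += gp.n * (kv * wa);
      if (wb > 0) W.Kv[c][ib] += gp.n * (kv * wb);
    }
    if (tag == TAG_CANAL_PROX && M.has_frag && st.frag_free) {
      Vec3 r = gp.pt - S.frag.x;
      W.Ff -= Fv;
      W.Tf -= cross(r, Fv);
      if (build) {
        double s = h * stp + h * h * kn;
        const double nv[3] = {gp.n.x, gp.n.y, gp.n.z};
        for (int r2 = 0; r2 < 3; ++r2)
          for (int s2 = 0; s2 <= r2; ++s2)
            W.Af.add(r2, s2, s * nv[r2] * nv[s2]);
        W.Kvf -= gp.n * (kn * dot(gp.n, v_pt - v_surf));
      }
    }
    if (log) {
      log->pe_contact += K * std::pow(g, e + 1) / (e + 1);
      if (tag == TAG_RING) {
        log->ring_force[c] += Fv;
        log->ring_fmag[c] += Fn;
      } else if (tag == TAG_CANAL_PROX) {
        log->canal_prox[c] += Fv;
      } else if (tag == TAG_CANAL_DIST) {
        log->canal_dist[c] += Fv;
      }
    }
  };

  // ---- nail vs ring primitives and canal walls ----
  double hl = M.ring.present ? M.ring.hole_length : 0;
  for (int c = 0; c < nc; ++c) {
    const ChainSpec& ch = M.chains[c];
    double rs = ch.r_contact;
    int guide = (M.ring.present && c < (int)M.ring.guide_of_nail.size())
                ? M.ring.guide_of_nail[c] : -1;
    int nsub = M.subdiv - 1;
    int npts = ch.n + (ch.n - 1) * nsub;
    for (int ip = 0; ip < npts; ++ip) {
      int ia, ib; double wb;
      if (ip < ch.n) { ia = ib = ip; wb = 0; }
      else {
        int k = ip - ch.n;
        ia = k / nsub; ib = ia + 1;
        wb = (double)(k % nsub + 1) / M.subdiv;
      }
      Vec3 p = S.chains[c][ia].x * (1.0 - wb) + S.chains[c][ib].x * wb;
      Vec3 v_pt = S.chains[c][ia].v * (1.0 - wb) + S.chains[c][ib].v * wb;

      if (guide >= 0 && p.y > ring_y - 2 * rs && p.y < ring_y + hl + 2 * rs) {
        for (const Prim& pr : M.ring.prims) {
          if (pr.guide >= 0 && pr.guide != guide) continue;
          Gap gp = gap_prim(p, rs, pr, ring_y);
          if (gp.hit)
            contact(c, ia, ib, wb, gp, pr.class_id, v_pt,
                    Vec3(0, ring_v, 0), TAG_RING);
        }
      }
      if (M.canal.present) {
        Gap gd = gap_canal_frag(p, rs, M.canal, 1);
        if (gd.hit)
          contact(c, ia, ib, wb, gd, M.canal.class_id, v_pt, Vec3(),
                  TAG_CANAL_DIST);
        if (M.has_frag && st.frag_free) {
          Mat3 Rf = qrot(S.frag.q);
          Vec3 pl = M.canal.frac_point + Rf.tmul(p - S.frag.x);
          Gap g0 = gap_canal_frag(pl, rs, M.canal, 0);
          if (g0.hit) {
            Gap gw = g0;
            gw.n = Rf * g0.n;
            gw.pt = S.frag.x + Rf * (g0.pt - M.canal.frac_point);
            Vec3 v_surf = S.frag.v + cross(S.frag.w, gw.pt - S.frag.x);
            contact(c, ia, ib, wb, gw, M.canal.class_id, v_pt, v_surf,
                    TAG_CANAL_PROX);
          }
        } else {
          Gap g0 = gap_canal_frag(p, rs, M.canal, 0);
          if (g0.hit)
            contact(c, ia, ib, wb, g0, M.canal.class_id, v_pt, Vec3(),
                    TAG_CANAL_PROX);
        }
      }
    }
  }

  // ---- nail-nail contacts (sphere level, adjacent chains) ----
  if (M.nn_class >= 0) {
    int cls = M.nn_class;
    double K = M.Kp[cls], e = M.ep[cls];
    for (size_t pid = 0; pid < M.pairs.size(); ++pid) {
      int ci = M.pairs[pid].first, cj = M.pairs[pid].second;
      double rr = M.chains[ci].r_contact + M.chains[cj].r_contact;
      double rr2 = rr * rr;
      for (int i = 0; i < M.chains[ci].n; ++i) {
        const Vec3& pi = S.chains[ci][i].x;
        for (int j = 0; j < M.chains[cj].n; ++j) {
          Vec3 d = pi - S.chains[cj][j].x;
          double d2 = dot(d, d);
          if (d2 >= rr2) continue;
          double dist = std::sqrt(d2);
          Vec3 n = dist > 1e-12 ? d * (1.0 / dist) : Vec3(1, 0, 0);
          double g = rr - dist;
          const Vec3& vi = S.chains[ci][i].v;
          const Vec3& vj = S.chains[cj][j].v;
          double stp = step_smooth_c(g, 0, 0, M.dp[cls], M.Cp[cls]);
          double gdot = -dot(vi - vj, n);
          double Fn = K * std::pow(g, e) + stp * gdot;
          if (Fn < 0) Fn = 0;
          Vec3 Fv = n * Fn;
          W.F[ci][i] += Fv;
          W.F[cj][j] -= Fv;
          double pen = g / M.abortp[cls];
          if (pen > max_pen) max_pen = pen;
          if (g > W.pen_class[cls]) W.pen_class[cls] = g;
          if (build) {
            double kn = K * e * std::pow(g, e - 1);
            double s = h * stp + h * h * kn;
            const double nv[3] = {n.x, n.y, n.z};
            for (int r = 0; r < 3; ++r)
              for (int s2 = 0; s2 <= r; ++s2) {
                W.A[ci].add(6 * i + r, 6 * i + s2, s * nv[r] * nv[s2]);
                W.A[cj].add(6 * j + r, 6 * j + s2, s * nv[r] * nv[s2]);
              }
            double kv = kn * dot(n, vi - vj);
            W.Kv[ci][i] += n * kv;
            W.Kv[cj][j] -= n * kv;
          }
          if (log) {
            log->pe_contact += K * std::pow(g, e + 1) / (e + 1);
            log->nn_sum[pid] += Fn;
            log->nn_vec[pid] += Fv;
          }
        }
      }
    }
  }

  // ---- proximal fragment: bushing, load, gravity ----
  if (M.has_frag && st.frag_free) {
    const FragSpec& fg = M.frag;
    Mat3 Rf = qrot(S.frag.q);
    Vec3 u = S.frag.x - M.canal.frac_point;
    Vec3 th = rot_log(Rf);
    const Mat3& Fm = M.canal.frame;
    Vec3 uf = Fm.tmul(u), thf = Fm.tmul(th);
    Vec3 vf = Fm.tmul(S.frag.v), wf = Fm.tmul(S.frag.w);
    Vec3 Fb = Fm * Vec3(-(fg.k.x * uf.x + fg.c.x * vf.x),
                        -(fg.k.y * uf.y + fg.c.y * vf.y),
                        -(fg.k.z * uf.z + fg.c.z * vf.z));
    Vec3 Mb = Fm * Vec3(-(fg.kr.x * thf.x + fg.cr.x * wf.x),
                        -(fg.kr.y * thf.y + fg.cr.y * wf.y),
                        -(fg.kr.z * thf.z + fg.cr.z * wf.z));
    W.Ff += Fb + M.gravity * fg.mass + st.load_dir * load_mag(st, t);
    W.Tf += Mb;
    if (st.drag > 0) {
      W.Ff -= S.frag.v * (st.drag * fg.mass);
      W.Tf -= Vec3(fg.inertia.x * S.frag.w.x, fg.inertia.y * S.frag.w.y,
                   fg.inertia.z * S.frag.w.z) * st.drag;
    }
    if (build) {
      double sd = 1.0 + h * st.drag;
      for (int r = 0; r < 3; ++r) W.Af.add(r, r, fg.mass * sd);
      for (int r = 0; r < 3; ++r)
        for (int s2 = 0; s2 <= r; ++s2) {
          double kt = 0, ct = 0, krr = 0, crr = 0, iw = 0;
          for (int k = 0; k < 3; ++k) {
            kt += Fm(r, k) * (&fg.k.x)[k] * Fm(s2, k);
            ct += Fm(r, k) * (&fg.c.x)[k] * Fm(s2, k);
            krr += Fm(r, k) * (&fg.kr.x)[k] * Fm(s2, k);
            crr += Fm(r, k) * (&fg.cr.x)[k] * Fm(s2, k);
            iw += Rf(r, k) * (&fg.inertia.x)[k] * Rf(s2, k);
          }
          W.Af.add(r, s2, h * ct + h * h * kt);
          W.Af.add(3 + r, 3 + s2, h * crr + h * h * krr + iw * sd);
        }
      Vec3 Kvt = Fm * Vec3(fg.k.x * vf.x, fg.k.y * vf.y, fg.k.z * vf.z);
      Vec3 Kvr = Fm * Vec3(fg.kr.x * wf.x, fg.kr.y * wf.y, fg.kr.z * wf.z);
      W.Kvf += Kvt;
      W.Kwf += Kvr;
    }
    if (log) log->ke += 0.5 * fg.mass * dot(S.frag.v, S.frag.v);
  }

  if (log) {
    log->max_pen = max_pen;
    for (int c = 0; c < nc; ++c)
      if (!M.chains[c].clamped.empty())
        log->base_reaction[c] = -W.F[c][M.chains[c].clamped[0]];
  }
  W.max_pen_eval = max_pen;
}

// ======================================================= model parsing =====

static Vec3 as_vec3(SEXP s) {
  NumericVector v(s);
  return Vec3(v[0], v[1], v[2]);
}

static Model parse_model(const List& ml) {
  Model M;
  List nails = ml["nails"];
  for (int c = 0; c < nails.size(); ++c) {
    List nl = nails[c];
    ChainSpec ch;
    ch.n = as<int>(nl["n"]);
    ch.L0 = as<double>(nl["L0"]);
    ch.EA = as<double>(nl["EA"]);
    ch.GJ = as<double>(nl["GJ"]);
    ch.EI = as<double>(nl["EI"]);
    ch.Phi = as<double>(nl["Phi"]);
    ch.beta = as<double>(nl["beta"]);
    ch.r_contact = as<double>(nl["contact_radius"]);
    NumericMatrix rr = nl["r_rel0"], qq = nl["q_rel0"], ee = nl["E0"],
                  ii = nl["inertia"];
    NumericVector mm = nl["mass"];
    for (int i = 0; i < ch.n - 1; ++i) {
      ch.r_rel0.push_back(Vec3(rr(0, i), rr(1, i), rr(2, i)));
      ch.Rrel0.push_back(qrot(Quat(qq(0, i), qq(1, i), qq(2, i), qq(3, i))));
      Mat3 E;
      for (int col = 0; col < 3; ++col)
        for (int row = 0; row < 3; ++row)
          E(row, col) = ee(3 * col + row, i);
      ch.E0.push_back(E);
    }
    for (int i = 0; i < ch.n; ++i) {
      ch.mass.push_back(mm[i]);
      ch.inertia.push_back(Vec3(ii(0, i), ii(1, i), ii(2, i)));
    }
    IntegerVector cl = nl["clamped"];
    for (int k : cl) ch.clamped.push_back(k);
    build_K12(ch);
    M.chains.push_back(std::move(ch));
  }

  NumericMatrix par = ml["params"];
  for (int j = 0; j < par.ncol(); ++j) {
    M.Kp.push_back(par(0, j));
    M.ep.push_back(par(1, j));
    M.Cp.push_back(par(2, j));
    M.dp.push_back(par(3, j));
    M.abortp.push_back(par(4, j));
  }

  if (!Rf_isNull(ml["ring"])) {
    List rl = ml["ring"];
    M.ring.present = true;
    M.ring.hole_length = as<double>(rl["hole_length"]);
    NumericMatrix pm = rl["prim"];
    for (int j = 0; j < pm.ncol(); ++j) {
      Prim pr;
      pr.type = (int)pm(0, j);
      pr.class_id = (int)pm(1, j);
      pr.guide = (int)pm(2, j);
      for (int k = 0; k < 15; ++k) pr.p[k] = pm(3 + k, j);
      M.ring.prims.push_back(pr);
    }
    IntegerVector gn = rl["guide_of_nail"];
    for (int g : gn) M.ring.guide_of_nail.push_back(g);
  }

  if (!Rf_isNull(ml["canal"])) {
    List cl = ml["canal"];
    M.canal.present = true;
    NumericVector pp = cl["prox"], dd = cl["dist"], bb = cl["bow"],
                  fr = cl["frame"];
    for (int k = 0; k < 4; ++k) { M.canal.prox[k] = pp[k]; M.canal.dist[k] = dd[k]; }
    for (int k = 0; k < 3; ++k) M.canal.bow[k] = bb[k];
    M.canal.frac_point = as_vec3(cl["frac_point"]);
    M.canal.frac_normal = as_vec3(cl["frac_normal"]);
    for (int col = 0; col < 3; ++col)
      for (int row = 0; row < 3; ++row)
        M.canal.frame(row, col) = fr[3 * col + row];
    M.canal.class_id = as<int>(cl["class_id"]);
  }

  if (!Rf_isNull(ml["fragment"])) {
    List fl = ml["fragment"];
    M.has_frag = true;
    M.frag.mass = as<double>(fl["mass"]);
    M.frag.inertia = as_vec3(fl["inertia"]);
    M.frag.k = as_vec3(fl["k"]);
    M.frag.kr = as_vec3(fl["kr"]);
    M.frag.c = as_vec3(fl["c"]);
    M.frag.cr = as_vec3(fl["cr"]);
  }

  if (!Rf_isNull(ml["pairs"])) {
    IntegerMatrix pm = ml["pairs"];
    for (int j = 0; j < pm.ncol(); ++j)
      M.pairs.push_back({pm(0, j), pm(1, j)});
  }
  M.nn_class = as<int>(ml["nn_class"]);
  M.subdiv = as<int>(ml["subdiv"]);
  M.gravity = as_vec3(ml["gravity"]);

  if (!Rf_isNull(ml["prescribed"])) {
    NumericMatrix pm = ml["prescribed"];
    for (int j = 0; j < pm.ncol(); ++j) {
      std::array<double, 7> row;
      for (int k = 0; k < 7; ++k) row[k] = pm(k, j);
      M.prescribed.push_back(row);
    }
  }
  if (ml.containsElementNamed("point_forces") &&
      !Rf_isNull(ml["point_forces"])) {
    NumericMatrix pm = ml["point_forces"];
    for (int j = 0; j < pm.ncol(); ++j) {
      std::array<double, 5> row;
      for (int k = 0; k < 5; ++k) row[k] = pm(k, j);
      M.point_forces.push_back(row);
    }
  }
  return M;
}

static Stage parse_stage(const List& sl) {
  Stage st;
  st.t0 = as<double>(sl["t0"]); st.t1 = as<double>(sl["t1"]);
  st.ring_y0 = as<double>(sl["ring_y0"]); st.travel = as<double>(sl["travel"]);
  st.m_t0 = as<double>(sl["m_t0"]); st.m_t1 = as<double>(sl["m_t1"]);
  st.load_peak = as<double>(sl["load_peak"]);
  st.load_t0 = as<double>(sl["load_t0"]);
  st.load_t1 = as<double>(sl["load_t1"]);
  st.load_dir = as_vec3(sl["load_dir"]);
  st.frag_free = as<bool>(sl["frag_free"]);
  st.drag = as<double>(sl["drag"]);
  return st;
}

static Control parse_control(const List& cl) {
  Control ct;
  ct.h0 = as<double>(cl["h0"]); ct.hmin = as<double>(cl["hmin"]);
  ct.hmax = as<double>(cl["hmax"]); ct.rtol = as<double>(cl["rtol"]);
  ct.atol_v = as<double>(cl["atol_v"]); ct.atol_w = as<double>(cl["atol_w"]);
  ct.out_dt = as<double>(cl["out_dt"]);
  ct.max_pen_ratio = as<double>(cl["max_pen_ratio"]);
  ct.save_states = as<bool>(cl["save_states"]);
  ct.record = as<bool>(cl["record"]);
  return ct;
}

static SimState parse_state(const NumericVector& sv, const Model& M) {
  SimState S;
  S.has_frag = M.has_frag;
  size_t idx = 0;
  for (const ChainSpec& ch : M.chains) {
    std::vector<BodyState> bs(ch.n);
    for (int i = 0; i < ch.n; ++i) {
      BodyState& b = bs[i];
      b.x = Vec3(sv[idx], sv[idx + 1], sv[idx + 2]);
      b.q = Quat(sv[idx + 3], sv[idx + 4], sv[idx + 5], sv[idx + 6]);
      b.v = Vec3(sv[idx + 7], sv[idx + 8], sv[idx + 9]);
      b.w = Vec3(sv[idx + 10], sv[idx + 11], sv[idx + 12]);
      idx += 13;
    }
    S.chains.push_back(std::move(bs));
  }
  if (M.has_frag) {
    BodyState& b = S.frag;
    b.x = Vec3(sv[idx], sv[idx + 1], sv[idx + 2]);
    b.q = Quat(sv[idx + 3], sv[idx + 4], sv[idx + 5], sv[idx + 6]);
    b.v = Vec3(sv[idx + 7], sv[idx + 8], sv[idx + 9]);
    b.w = Vec3(sv[idx + 10], sv[idx + 11], sv[idx + 12]);
  }
  return S;
}

static NumericVector pack_state(const SimState& S) {
  size_t n = 0;
  for (const auto& ch : S.chains) n += 13 * ch.size();
  if (S.has_frag) n += 13;
  NumericVector sv(n);
  size_t idx = 0;
  auto put = [&](const BodyState& b) {
    sv[idx] = b.x.x; sv[idx + 1] = b.x.y; sv[idx + 2] = b.x.z;
    sv[idx + 3] = b.q.w; sv[idx + 4] = b.q.x; sv[idx + 5] = b.q.y;
    sv[idx + 6] = b.q.z;
    sv[idx + 7] = b.v.x; sv[idx + 8] = b.v.y; sv[idx + 9] = b.v.z;
    sv[idx + 10] = b.w.x; sv[idx + 11] = b.w.y; sv[idx + 12] = b.w.z;
    idx += 13;
  };
  for (const auto& ch : S.chains)
    for (const BodyState& b : ch) put(b);
  if (S.has_frag) put(S.frag);
  return sv;
}

// ========================================================= integrator ======

// [[Rcpp::export]]
List cpp_simulate(List model, NumericVector state, List stage, List control) {
  Model M = parse_model(model);
  Stage st = parse_stage(stage);
  Control ct = parse_control(control);
  SimState S = parse_state(state, M);

  const int nc = (int)M.chains.size();
  const int np = (int)M.pairs.size();
  const int bw = 11;

  Workspace W;
  W.A.resize(nc);
  W.rhs.resize(nc);
  W.F.resize(nc); W.Tq.resize(nc); W.Kv.resize(nc); W.Kw.resize(nc);
  int ndof_total = 0;
  int nbodies = 0;
  for (int c = 0; c < nc; ++c) {
    int n = M.chains[c].n;
    W.A[c].resize(6 * n, bw);
    W.rhs[c].assign(6 * n, 0.0);
    W.F[c].assign(n, Vec3());
    W.Tq[c].assign(n, Vec3());
    W.Kv[c].assign(n, Vec3());
    W.Kw[c].assign(n, Vec3());
    ndof_total += 6 * n;
    nbodies += n;
  }
  if (M.has_frag) { W.Af.resize(6, 5); W.rhsf.assign(6, 0.0); ndof_total += 6; nbodies += 1; }
  W.a_prev.assign(ndof_total, 0.0);
  W.pen_class.assign(M.Kp.size(), 0.0);
  std::vector<double> a_new(ndof_total, 0.0);

  // constrained DOF bookkeeping per chain
  std::vector<std::vector<int>> clamped_dofs(nc);
  for (int c = 0; c < nc; ++c)
    for (int k : M.chains[c].clamped)
      for (int d = 0; d < 6; ++d) clamped_dofs[c].push_back(6 * k + d);

  // output buffers
  std::vector<double> o_t, o_ring, o_load, o_base, o_ringf, o_ringm,
      o_nns, o_nnv, o_cpx, o_cdx, o_frag, o_en, o_pen, o_states;

  LogAcc acc;
  auto record_sample = [&](double t) {
    if (!ct.record) return;
    double rv;
    double ry = ring_pos(st, t, rv);
    acc.init(nc, np);
    evaluate(M, S, t, ry, rv, st, 0.0, W, false, &acc);
    o_t.push_back(t);
    o_ring.push_back(ry);
    o_load.push_back(load_mag(st, t));
    for (int c = 0; c < nc; ++c) {
      o_base.push_back(acc.base_reaction[c].x);
      o_base.push_back(acc.base_reaction[c].y);
      o_base.push_back(acc.base_reaction[c].z);
      o_ringf.push_back(acc.ring_force[c].x);
      o_ringf.push_back(acc.ring_force[c].y);
      o_ringf.push_back(acc.ring_force[c].z);
      o_ringm.push_back(acc.ring_fmag[c]);
      o_cpx.push_back(acc.canal_prox[c].x);
      o_cpx.push_back(acc.canal_prox[c].y);
      o_cpx.push_back(acc.canal_prox[c].z);
      o_cdx.push_back(acc.canal_dist[c].x);
      o_cdx.push_back(acc.canal_dist[c].y);
      o_cdx.push_back(acc.canal_dist[c].z);
    }
    for (int p = 0; p < np; ++p) {
      o_nns.push_back(acc.nn_sum[p]);
      o_nnv.push_back(norm(acc.nn_vec[p]));
    }
    if (M.has_frag) {
      o_frag.push_back(S.frag.x.x); o_frag.push_back(S.frag.x.y);
      o_frag.push_back(S.frag.x.z);
      o_frag.push_back(S.frag.q.w); o_frag.push_back(S.frag.q.x);
      o_frag.push_back(S.frag.q.y); o_frag.push_back(S.frag.q.z);
    }
    o_en.push_back(acc.ke);
    o_en.push_back(acc.pe_beam);
    o_en.push_back(acc.pe_contact);
    o_pen.push_back(acc.max_pen);
    if (ct.save_states) {
      NumericVector sv = pack_state(S);
      for (double v : sv) o_states.push_back(v);
    }
  };

  double t = st.t0;
  double h = ct.h0;
  int status = 0;
  long n_steps = 0, n_rejects = 0;
  double next_out = st.t0 + ct.out_dt;
  record_sample(st.t0);

  const double teps = 1e-12;
  while (t < st.t1 - teps) {
    if (n_steps + n_rejects > 100000000L) { status = 2; break; }
    double h_try = std::min(h, st.t1 - t);
    if (ct.record) h_try = std::min(h_try, std::max(next_out - t, ct.hmin));

    double rv1;
    double ry1 = ring_pos(st, t + h_try, rv1);
    evaluate(M, S, t, ry1, rv1, st, h_try, W, true, nullptr);
    if (W.max_pen_eval > ct.max_pen_ratio) { status = 1; break; }

    // rhs = h F - h^2 K v
    for (int c = 0; c < nc; ++c) {
      const ChainSpec& ch = M.chains[c];
      for (int i = 0; i < ch.n; ++i) {
        Vec3 rf = W.F[c][i] * h_try - W.Kv[c][i] * (h_try * h_try);
        Vec3 rt = W.Tq[c][i] * h_try - W.Kw[c][i] * (h_try * h_try);
        W.rhs[c][6 * i] = rf.x; W.rhs[c][6 * i + 1] = rf.y;
        W.rhs[c][6 * i + 2] = rf.z;
        W.rhs[c][6 * i + 3] = rt.x; W.rhs[c][6 * i + 4] = rt.y;
        W.rhs[c][6 * i + 5] = rt.z;
      }
      // prescribed translational DOF of this chain
      for (const auto& pr : M.prescribed) {
        if ((int)pr[0] != c) continue;
        int dof = 6 * (int)pr[1] + (int)pr[2];
        double dvq;
        double tau1 = pr[6] > pr[5] ? (t + h_try - pr[5]) / (pr[6] - pr[5]) : 1.0;
        double s1 = quint01(tau1, dvq);
        double xt = pr[3] + (pr[4] - pr[3]) * s1;
        double vt = pr[6] > pr[5] ? (pr[4] - pr[3]) * dvq / (pr[6] - pr[5]) : 0.0;
        (void)xt;
        const BodyState& b = S.chains[c][(int)pr[1]];
        double vcur = (int)pr[2] == 0 ? b.v.x : ((int)pr[2] == 1 ? b.v.y : b.v.z);
        double dv = vt - vcur;
        BandMatrix& A = W.A[c];
        for (int i2 = std::max(0, dof - bw);
             i2 <= std::min(6 * ch.n - 1, dof + bw); ++i2) {
          if (i2 == dof) continue;
          double Aij = i2 > dof ? A.at(i2, dof) : A.at(dof, i2);
          W.rhs[c][i2] -= Aij * dv;
        }
        A.constrain(dof);
        W.rhs[c][dof] = dv;
      }
      for (int dof : clamped_dofs[c]) {
        W.A[c].constrain(dof);
        W.rhs[c][dof] = 0.0;
      }
    }

    bool ok = true;
    for (int c = 0; c < nc && ok; ++c) {
      if (!W.A[c].factor()) { ok = false; break; }
      W.A[c].solve(W.rhs[c]);
    }
    bool frag_solved = false;
    if (ok && M.has_frag && st.frag_free) {
      Vec3 rf = W.Ff * h_try - W.Kvf * (h_try * h_try);
      Vec3 rt = W.Tf * h_try - W.Kwf * (h_try * h_try);
      W.rhsf[0] = rf.x; W.rhsf[1] = rf.y; W.rhsf[2] = rf.z;
      W.rhsf[3] = rt.x; W.rhsf[4] = rt.y; W.rhsf[5] = rt.z;
      if (!W.Af.factor()) ok = false;
      else { W.Af.solve(W.rhsf); frag_solved = true; }
    }
    if (!ok) {
      h = std::max(ct.hmin, h_try * 0.25);
      if (h_try <= ct.hmin * 1.0001) { status = 2; break; }
      ++n_rejects;
      continue;
    }

    // error estimate (implicit-Euler LTE ~ h/2 * |a_n+1 - a_n|)
    double err = 0;
    int gi = 0;
    for (int c = 0; c < nc; ++c) {
      const ChainSpec& ch = M.chains[c];
      for (int i = 0; i < ch.n; ++i)
        for (int d = 0; d < 6; ++d) {
          double dv = W.rhs[c][6 * i + d];
          double a = dv / h_try;
          a_new[gi] = a;
          const BodyState& b = S.chains[c][i];
          double vref = d < 3 ? (&b.v.x)[d] : (&b.w.x)[d - 3];
          double sc = (d < 3 ? ct.atol_v : ct.atol_w) +
                      ct.rtol * std::fabs(vref + dv);
          double e = 0.5 * h_try * std::fabs(a - W.a_prev[gi]) / sc;
          if (e > err) err = e;
          ++gi;
        }
    }
    if (M.has_frag) {
      for (int d = 0; d < 6; ++d) {
        double dv = frag_solved ? W.rhsf[d] : 0.0;
        double a = dv / h_try;
        a_new[gi] = a;
        double vref = d < 3 ? (&S.frag.v.x)[d] : (&S.frag.w.x)[d - 3];
        double sc = (d < 3 ? ct.atol_v : ct.atol_w) +
                    ct.rtol * std::fabs(vref + dv);
        double e = 0.5 * h_try * std::fabs(a - W.a_prev[gi]) / sc;
        if (e > err) err = e;
        ++gi;
      }
    }

    if (err > 1.0 && h_try > ct.hmin * 1.0001) {
      h = std::max(ct.hmin, h_try * std::max(0.2, 0.7 / std::sqrt(err)));
      ++n_rejects;
      continue;
    }

    // accept
    for (int c = 0; c < nc; ++c) {
      const ChainSpec& ch = M.chains[c];
      for (int i = 0; i < ch.n; ++i) {
        BodyState& b = S.chains[c][i];
        b.v += Vec3(W.rhs[c][6 * i], W.rhs[c][6 * i + 1], W.rhs[c][6 * i + 2]);
        b.w += Vec3(W.rhs[c][6 * i + 3], W.rhs[c][6 * i + 4],
                    W.rhs[c][6 * i + 5]);
        b.x += b.v * h_try;
        if (dot(b.w, b.w) > 0) {
          b.q = qmul(quat_exp_half(b.w, h_try), b.q);
          b.q.normalize();
        }
      }
    }
    if (M.has_frag && frag_solved) {
      S.frag.v += Vec3(W.rhsf[0], W.rhsf[1], W.rhsf[2]);
      S.frag.w += Vec3(W.rhsf[3], W.rhsf[4], W.rhsf[5]);
      S.frag.x += S.frag.v * h_try;
      if (dot(S.frag.w, S.frag.w) > 0) {
        S.frag.q = qmul(quat_exp_half(S.frag.w, h_try), S.frag.q);
        S.frag.q.normalize();
      }
    }
    // pin prescribed DOF exactly
    for (const auto& pr : M.prescribed) {
      int c = (int)pr[0], sph = (int)pr[1], ax = (int)pr[2];
      double dvq;
      double tau1 = pr[6] > pr[5] ? (t + h_try - pr[5]) / (pr[6] - pr[5]) : 1.0;
      double s1 = quint01(tau1, dvq);
      double xt = pr[3] + (pr[4] - pr[3]) * s1;
      double vt = pr[6] > pr[5] ? (pr[4] - pr[3]) * dvq / (pr[6] - pr[5]) : 0.0;
      BodyState& b = S.chains[c][sph];
      (&b.x.x)[ax] = xt;
      (&b.v.x)[ax] = vt;
    }
    std::copy(a_new.begin(), a_new.end(), W.a_prev.begin());
    t += h_try;
    ++n_steps;

    if (ct.record && t >= next_out - 1e-9) {
      record_sample(t);
      next_out += ct.out_dt;
    }

    // conservative growth: frequent contact events make optimistic step
    // increases thrash against rejections
    double grow = err > 1e-8 ? 0.7 / std::sqrt(err) : 1.4;
    h = std::min(ct.hmax, h_try * std::min(1.4, std::max(0.3, grow)));
    if ((n_steps & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  if (status != 0 && ct.record) record_sample(t);

  int ns = (int)o_t.size();
  auto mat = [&](std::vector<double>& v, int ncol) {
    NumericMatrix m(ns, std::max(ncol, 0));
    if (ncol > 0)
      for (int i = 0; i < ns; ++i)
        for (int j = 0; j < ncol; ++j) m(i, j) = v[(size_t)i * ncol + j];
    return m;
  };

  return List::create(
      _["t"] = NumericVector(o_t.begin(), o_t.end()),
      _["ring_y"] = NumericVector(o_ring.begin(), o_ring.end()),
      _["load"] = NumericVector(o_load.begin(), o_load.end()),
      _["base_reaction"] = mat(o_base, 3 * nc),
      _["ring_force"] = mat(o_ringf, 3 * nc),
      _["ring_fmag"] = mat(o_ringm, nc),
      _["nn_sum"] = mat(o_nns, np),
      _["nn_vecmag"] = mat(o_nnv, np),
      _["canal_prox"] = mat(o_cpx, 3 * nc),
      _["canal_dist"] = mat(o_cdx, 3 * nc),
      _["frag_pose"] = mat(o_frag, M.has_frag ? 7 : 0),
      _["energy"] = mat(o_en, 3),
      _["max_pen"] = NumericVector(o_pen.begin(), o_pen.end()),
      _["states"] = mat(o_states, ct.save_states ? 13 * nbodies : 0),
      _["status"] = status,
      _["t_end"] = t,
      _["state_final"] = pack_state(S),
      _["n_steps"] = (double)n_steps,
      _["n_rejects"] = (double)n_rejects,
      _["h_final"] = h,
      _["pen_class"] = NumericVector(W.pen_class.begin(),
                                     W.pen_class.end()));
}

// ============================================== residual for settling ======

// [[Rcpp::export]]
List cpp_residual(List model, NumericVector state, double t, List stage) {
  Model M = parse_model(model);
  Stage st = parse_stage(stage);
  SimState S = parse_state(state, M);
  // zero velocities: residual measures static equilibrium of positions
  for (auto& ch : S.chains)
    for (auto& b : ch) { b.v = Vec3(); b.w = Vec3(); }
  S.frag.v = Vec3(); S.frag.w = Vec3();
  Stage st0 = st;
  st0.drag = 0;
  const int nc = (int)M.chains.size();
  Workspace W;
  W.A.resize(nc); W.rhs.resize(nc);
  W.F.resize(nc); W.Tq.resize(nc); W.Kv.resize(nc); W.Kw.resize(nc);
  for (int c = 0; c < nc; ++c) {
    int n = M.chains[c].n;
    W.F[c].assign(n, Vec3());
    W.Tq[c].assign(n, Vec3());
    W.Kv[c].assign(n, Vec3());
    W.Kw[c].assign(n, Vec3());
  }
  W.pen_class.assign(M.Kp.size(), 0.0);
  double rv;
  double ry = ring_pos(st, t, rv);
  LogAcc acc;
  acc.init(nc, (int)M.pairs.size());
  evaluate(M, S, t, ry, 0.0, st0, 0.0, W, false, &acc);
  double fmax = 0, tmax = 0;
  for (int c = 0; c < nc; ++c) {
    std::vector<bool> is_cl(M.chains[c].n, false);
    for (int k : M.chains[c].clamped) is_cl[k] = true;
    for (const auto& pr : M.prescribed)
      if ((int)pr[0] == c) is_cl[(int)pr[1]] = true;
    for (int i = 0; i < M.chains[c].n; ++i) {
      if (is_cl[i]) continue;
      fmax = std::max(fmax, norm(W.F[c][i]));
      tmax = std::max(tmax, norm(W.Tq[c][i]));
    }
  }
  return List::create(_["max_force"] = fmax, _["max_torque"] = tmax,
                      _["max_pen"] = W.max_pen_eval);
}

// ================================================== beam-chain kernel ======

// [[Rcpp::export]]
List cpp_chain_forces(List spec, NumericMatrix pos, NumericMatrix quat,
                      NumericMatrix vel, NumericMatrix angvel) {
  ChainSpec ch;
  ch.n = as<int>(spec["n"]);
  ch.L0 = as<double>(spec["L0"]);
  ch.EA = as<double>(spec["EA"]);
  ch.GJ = as<double>(spec["GJ"]);
  ch.EI = as<double>(spec["EI"]);
  ch.Phi = as<double>(spec["Phi"]);
  ch.beta = as<double>(spec["beta"]);
  NumericMatrix rr = spec["r_rel0"], qq = spec["q_rel0"], ee = spec["E0"];
  for (int i = 0; i < ch.n - 1; ++i) {
    ch.r_rel0.push_back(Vec3(rr(0, i), rr(1, i), rr(2, i)));
    ch.Rrel0.push_back(qrot(Quat(qq(0, i), qq(1, i), qq(2, i), qq(3, i))));
    Mat3 E;
    for (int col = 0; col < 3; ++col)
      for (int row = 0; row < 3; ++row)
        E(row, col) = ee(3 * col + row, i);
    ch.E0.push_back(E);
  }
  build_K12(ch);

  std::vector<BodyState> bs(ch.n);
  for (int i = 0; i < ch.n; ++i) {
    bs[i].x = Vec3(pos(0, i), pos(1, i), pos(2, i));
    bs[i].q = Quat(quat(0, i), quat(1, i), quat(2, i), quat(3, i));
    bs[i].v = Vec3(vel(0, i), vel(1, i), vel(2, i));
    bs[i].w = Vec3(angvel(0, i), angvel(1, i), angvel(2, i));
  }
  NumericMatrix F(ch.n, 3), Mo(ch.n, 3);
  double pe = 0;
  for (int i = 0; i < ch.n - 1; ++i) {
    Vec3 Fb, Mb;
    Mat3 Re;
    segment_wrench(ch, i, bs[i], bs[i + 1], Fb, Mb, Re, &pe);
    Vec3 r_ab = bs[i + 1].x - bs[i].x;
    F(i + 1, 0) += Fb.x; F(i + 1, 1) += Fb.y; F(i + 1, 2) += Fb.z;
    Mo(i + 1, 0) += Mb.x; Mo(i + 1, 1) += Mb.y; Mo(i + 1, 2) += Mb.z;
    F(i, 0) -= Fb.x; F(i, 1) -= Fb.y; F(i, 2) -= Fb.z;
    Vec3 Ma = Mb + cross(r_ab, Fb);
    Mo(i, 0) -= Ma.x; Mo(i, 1) -= Ma.y; Mo(i, 2) -= Ma.z;
  }
  return List::create(_["force"] = F, _["moment"] = Mo,
                      _["strain_energy"] = pe);
}

// ==================================================== exported kernels =====

// [[Rcpp::export]]
NumericVector cpp_step_smooth(NumericVector x, double x0, double h0,
                              double x1, double h1) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = step_smooth_c(x[i], x0, h0, x1, h1);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_impact_force(NumericVector g, NumericVector gdot, double K,
                               double e, double Cmax, double dmax) {
  NumericVector out(g.size());
  for (int i = 0; i < g.size(); ++i) {
    double gi = g[i];
    if (gi <= 0) { out[i] = 0; continue; }
    double F = K * std::pow(gi, e) +
               step_smooth_c(gi, 0, 0, dmax, Cmax) * gdot[i];
    out[i] = F > 0 ? F : 0;
  }
  return out;
}

static List gap_to_list(const Gap& g) {
  if (!g.hit)
    return List::create(_["hit"] = false);
  return List::create(_["hit"] = true, _["g"] = g.g,
                      _["normal"] = NumericVector::create(g.n.x, g.n.y, g.n.z),
                      _["point"] = NumericVector::create(g.pt.x, g.pt.y,
                                                         g.pt.z));
}

// [[Rcpp::export]]
List cpp_gap_sphere_tube(NumericVector center, double rs,
                         NumericVector axis_point, NumericVector axis_dir,
                         double R) {
  // transform into a frame with the tube axis along y
  Vec3 p = as_vec3(center), a0 = as_vec3(axis_point), ad = as_vec3(axis_dir);
  double an = norm(ad);
  ad = ad * (1.0 / an);
  Vec3 rel = p - a0;
  double yl = dot(rel, ad);
  Vec3 radial = rel - ad * yl;
  double rho = norm(radial);
  Gap out;
  double g = rho + rs - R;
  if (g > 0) {
    Vec3 dn = rho > 1e-12 ? radial * (1.0 / rho) : Vec3(1, 0, 0);
    out.hit = true; out.g = g; out.n = -dn;
    out.pt = a0 + ad * yl + dn * R;
  }
  return gap_to_list(out);
}

// [[Rcpp::export]]
List cpp_gap_sphere_sphere(NumericVector c1, double r1, NumericVector c2,
                           double r2) {
  Vec3 p1 = as_vec3(c1), p2 = as_vec3(c2);
  Vec3 d = p1 - p2;
  double dist = norm(d);
  Gap out;
  double g = r1 + r2 - dist;
  if (g > 0) {
    Vec3 n = dist > 1e-12 ? d * (1.0 / dist) : Vec3(1, 0, 0);
    out.hit = true; out.g = g; out.n = n;
    out.pt = p2 + n * r2;
  }
  return gap_to_list(out);
}

// [[Rcpp::export]]
List cpp_gap_sphere_cylinder(NumericVector center, double rs,
                             NumericVector base, NumericVector axis,
                             double radius, double length) {
  // solid finite cylinder: lateral surface, caps and edges
  Vec3 p = as_vec3(center), b0 = as_vec3(base), ad = as_vec3(axis);
  ad = ad * (1.0 / norm(ad));
  Vec3 rel = p - b0;
  double yl = dot(rel, ad);
  Vec3 radial = rel - ad * yl;
  double rho = norm(radial);
  Vec3 dn = rho > 1e-12 ? radial * (1.0 / rho) : Vec3();
  Gap out;
  if (yl >= 0 && yl <= length) {
    if (rho >= radius) {
      double g = rs + radius - rho;
      if (g > 0) {
        out.hit = true; out.g = g; out.n = dn;
        out.pt = b0 + ad * yl + dn * radius;
      }
      return gap_to_list(out);
    }
    // center inside the solid: push out along the nearest feature
    double d_lat = radius - rho;
    double d_cap0 = yl, d_cap1 = length - yl;
    if (rho > 1e-12 && d_lat <= std::min(d_cap0, d_cap1)) {
      out.hit = true; out.g = rs + d_lat; out.n = dn;
      out.pt = b0 + ad * yl + dn * radius;
    } else if (d_cap0 <= d_cap1) {
      out.hit = true; out.g = rs + d_cap0; out.n = -ad; out.pt = b0 + radial;
    } else {
      out.hit = true; out.g = rs + d_cap1; out.n = ad;
      out.pt = b0 + ad * length + radial;
    }
    return gap_to_list(out);
  }
  double ylc = std::min(std::max(yl, 0.0), length);
  double rhoc = std::min(rho, radius);
  Vec3 e = b0 + ad * ylc + (rho > 1e-12 ? dn * rhoc : Vec3());
  Vec3 dv = p - e;
  double dist = norm(dv);
  double g = rs - dist;
  if (g > 0 && dist > 1e-12) {
    out.hit = true; out.g = g; out.n = dv * (1.0 / dist); out.pt = e;
  }
  return gap_to_list(out);
}

// [[Rcpp::export]]
List cpp_gap_sphere_box(NumericVector center, double rs,
                        NumericVector box_center, NumericMatrix axes,
                        NumericVector half) {
  Mat3 U;
  for (int col = 0; col < 3; ++col)
    for (int row = 0; row < 3; ++row) U(row, col) = axes(row, col);
  Gap out = gap_box_core(as_vec3(center), rs, as_vec3(box_center), U,
                         as_vec3(half));
  return gap_to_list(out);
}
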