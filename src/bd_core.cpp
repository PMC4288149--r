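// Compiled core for chromassemble: overdamped Langevin integration of a
// bead-and-patch DNA polymer plus rigid protein cores, exact analytic
// gradients for every potential term, and the Gauss-integral writhe sum.
//
// Unit system: lengths in nm, energies in kBT, time in Brownian times
// (tau_B of a DNA bead). Quaternions are scalar-first (w, x, y, z) and
// encode right-handed rotations of body axes into the lab frame.
#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// xoshiro256++ seeded via splitmix64; deterministic given the integer seed.
struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f; have_spare = true;
    return u * f;
  }
  // zero-mean unit-variance uniform kick: the standard cheap thermostat
  // noise for overdamped Euler-Maruyama (only the first two moments
  // matter at O(dt); successive kicks average to Gaussian)
  inline double kick() {
    return (2.0 * unif() - 1.0) * 1.7320508075688772;
  }
};

// ---------------------------------------------------------- small algebra --
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { return {x, y, z}; }
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm3(V3 a) { return std::sqrt(dot(a, a)); }

struct Q4 { double w, x, y, z; };
static inline Q4 qmul(Q4 a, Q4 b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}
static inline Q4 qconj(Q4 a) { return {a.w, -a.x, -a.y, -a.z}; }
static inline Q4 qnormalize(Q4 a) {
  double n = std::sqrt(a.w * a.w + a.x * a.x + a.y * a.y + a.z * a.z);
  return {a.w / n, a.x / n, a.y / n, a.z / n};
}
// rotate body vector into lab frame
static inline V3 qrot(Q4 q, V3 v) {
  Q4 p = qmul(qmul(q, {0.0, v.x, v.y, v.z}), qconj(q));
  return {p.x, p.y, p.z};
}
static inline Q4 q_from_rotvec(V3 w) {
  double th = norm3(w);
  if (th < 1e-14) return {1.0, 0.5 * w.x, 0.5 * w.y, 0.5 * w.z};
  double s = std::sin(0.5 * th) / th;
  return {std::cos(0.5 * th), s * w.x, s * w.y, s * w.z};
}

// -------------------------------------------------------------- parameters --
struct FF {
  double sigma, bond_k, bond_r0, bend_k, twist_k, align_k;
  double eps_rep, eps_site, eps_nano, softcore_cap;
  double site_cut, site_ang_c, core_diam, path_radius;
  double nano_well_w, slit_k, confine_R, confine_k;
  // derived
  double dd_cut, dd_sig, cc_cut, cc_sig;
  double cd_cut_oct, cd_sig_oct, cd_contact_nano, cd_sig_nano, cd_cut_nano;
};

static FF parse_ff(const List& p) {
  FF f;
  f.sigma        = as<double>(p["sigma_dna"]);
  f.bond_k       = as<double>(p["bond_k"]);
  f.bond_r0      = as<double>(p["bond_r0"]);
  f.bend_k       = as<double>(p["bend_k"]);
  f.twist_k      = as<double>(p["twist_k"]);
  f.align_k      = as<double>(p["align_k"]);
  f.eps_rep      = as<double>(p["eps_rep"]);
  f.eps_site     = as<double>(p["eps_site"]);
  f.eps_nano     = as<double>(p["eps_nano"]);
  f.softcore_cap = as<double>(p["softcore_cap"]);
  f.site_cut     = as<double>(p["site_capture"]);
  f.site_ang_c   = as<double>(p["site_ang_cos"]);
  f.core_diam    = as<double>(p["core_diam"]);
  f.path_radius  = as<double>(p["path_radius"]);
  f.nano_well_w  = as<double>(p["nano_well_w"]);
  f.slit_k       = as<double>(p["slit_k"]);
  f.confine_R    = as<double>(p["confine_R"]);
  f.confine_k    = as<double>(p["confine_k"]);
  const double s6 = std::pow(2.0, 1.0 / 6.0);
  f.dd_sig = f.sigma;            f.dd_cut = s6 * f.dd_sig;
  f.cc_sig = f.core_diam;        f.cc_cut = s6 * f.cc_sig;
  // octamer body: repulsion vanishes exactly at the wrap-path radius so a
  // docked bead feels no residual push
  f.cd_cut_oct = f.path_radius;  f.cd_sig_oct = f.path_radius / s6;
  f.cd_contact_nano = 0.5 * (f.core_diam + f.sigma);
  f.cd_sig_nano = f.cd_contact_nano / s6;
  f.cd_cut_nano = f.cd_contact_nano + f.nano_well_w;
  return f;
}

// WCA (purely repulsive truncated-shifted LJ), returns energy, fills dEdr
static inline double wca(double r, double sig, double cut, double eps,
                         double* dEdr) {
  *dEdr = 0.0;
  if (r >= cut) return 0.0;
  double sr2 = sig * sig / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  *dEdr = -24.0 * eps * (2.0 * sr12 - sr6) / r;
  return 4.0 * eps * (sr12 - sr6) + eps;
}

// ------------------------------------------------------------ force kernel --
struct Flags {
  bool softcore;
  double twist_scale;   // topo-I window scales twist stiffness
  double eps_mult;      // affinity boost
  double slit_gap;      // <= 0 means off; full gap (wall at +-gap/2)
};

struct Sys {
  int n, m, S;
  std::vector<V3> r;        // bead positions
  std::vector<Q4> q;        // bead orientations
  std::vector<int> chain;   // chain id per bead (0-based contiguous runs)
  std::vector<int> circ;    // per chain: 1 if circular
  std::vector<V3> cr;       // core positions
  std::vector<Q4> cq;       // core orientations
  std::vector<int> ckind;   // 0 octamer, 1 nanoparticle
  std::vector<V3> site_loc, site_dir;   // shared local geometry
  std::vector<int> active;  // m x S mask, row-major
};

struct Out {
  std::vector<V3> fb, tb, fc, tc;
  double e_bond, e_bend, e_align, e_twist, e_rep, e_soft, e_site, e_nano, e_slit;
  void reset(int n, int m) {
    fb.assign(n, {0, 0, 0}); tb.assign(n, {0, 0, 0});
    fc.assign(m, {0, 0, 0}); tc.assign(m, {0, 0, 0});
    e_bond = e_bend = e_align = e_twist = e_rep = e_soft = e_site = e_nano =
        e_slit = 0.0;
  }
  double total() const {
    return e_bond + e_bend + e_align + e_twist + e_rep + e_soft + e_site +
           e_nano + e_slit;
  }
};

struct NeighborLists {
  std::vector<std::pair<int, int>> bb, bc, cc;
  std::vector<V3> ref_r, ref_cr;
  double skin = 2.5;
  bool valid = false;

  bool need_rebuild(const Sys& s) const {
    if (!valid) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < s.n; ++i)
      if (dot(s.r[i] - ref_r[i], s.r[i] - ref_r[i]) > lim2) return true;
    for (int i = 0; i < s.m; ++i)
      if (dot(s.cr[i] - ref_cr[i], s.cr[i] - ref_cr[i]) > lim2) return true;
    return false;
  }
  void rebuild(const Sys& s, const FF& f) {
    bb.clear(); bc.clear(); cc.clear();
    double bb_cut = f.dd_cut + skin;
    double bc_cut = std::max(f.cd_cut_nano,
                             f.path_radius + f.site_cut) + skin;
    double cc_cut = f.cc_cut + skin;
    double bb2 = bb_cut * bb_cut, bc2 = bc_cut * bc_cut, cc2 = cc_cut * cc_cut;
    for (int i = 0; i < s.n; ++i)
      for (int j = i + 1; j < s.n; ++j) {
        if (s.chain[i] == s.chain[j]) {
          if (j == i + 1) continue;  // bonded neighbours excluded
        }
        V3 d = s.r[i] - s.r[j];
        if (dot(d, d) < bb2) bb.emplace_back(i, j);
      }
    // circular chains: also exclude first-last bond partners
    // (handled above only for consecutive indices; do it here)
    for (int i = 0; i < s.m; ++i)
      for (int j = 0; j < s.n; ++j) {
        V3 d = s.cr[i] - s.r[j];
        if (dot(d, d) < bc2) bc.emplace_back(i, j);
      }
    for (int i = 0; i < s.m; ++i)
      for (int j = i + 1; j < s.m; ++j) {
        V3 d = s.cr[i] - s.cr[j];
        if (dot(d, d) < cc2) cc.emplace_back(i, j);
      }
    ref_r = s.r; ref_cr = s.cr; valid = true;
  }
};

// chain bookkeeping: list of (first, last, circular) runs
static std::vector<std::array<int, 3>> chain_runs(const Sys& s) {
  std::vector<std::array<int, 3>> runs;
  int start = 0;
  for (int i = 1; i <= s.n; ++i) {
    if (i == s.n || s.chain[i] != s.chain[start]) {
      int cid = s.chain[start];
      int circ = (cid >= 0 && cid < (int)s.circ.size()) ? s.circ[cid] : 0;
      runs.push_back({start, i - 1, circ});
      start = i;
    }
  }
  return runs;
}

// per-step caches of rotated body frames
struct FrameCache {
  std::vector<V3> e1, patch;          // bead tangent axis, patch direction
  std::vector<V3> site_pos, site_dir; // world site arrays, m*S row-major
  void fill(const Sys& s) {
    e1.resize(s.n); patch.resize(s.n);
    for (int i = 0; i < s.n; ++i) {
      e1[i] = qrot(s.q[i], v3(1, 0, 0));
      patch[i] = qrot(s.q[i], v3(0, 1, 0));
    }
    site_pos.resize(s.m * s.S); site_dir.resize(s.m * s.S);
    for (int c = 0; c < s.m; ++c) {
      if (s.ckind[c] == 1) continue;
      for (int k = 0; k < s.S; ++k) {
        site_pos[c * s.S + k] = s.cr[c] + qrot(s.cq[c], s.site_loc[k]);
        site_dir[c * s.S + k] = qrot(s.cq[c], s.site_dir[k]);
      }
    }
  }
};

static void compute_forces(const Sys& s, const FF& f, const Flags& fl,
                           NeighborLists& nl, FrameCache& fc, Out& out) {
  out.reset(s.n, s.m);
  if (nl.need_rebuild(s)) nl.rebuild(s, f);
  fc.fill(s);
  auto runs = chain_runs(s);

  // --- bonded terms, per chain run ---
  for (auto& run : runs) {
    int a = run[0], b = run[1];
    bool circ = run[2] != 0;
    int nb = b - a + 1;
    if (nb < 2) continue;
    int njoint = circ ? nb : nb - 1;
    for (int k = 0; k < njoint; ++k) {
      int i = a + k;
      int j = a + ((k + 1) % nb);
      V3 d = s.r[j] - s.r[i];
      double L = norm3(d);
      V3 bh = (1.0 / L) * d;
      // stretch
      double dl = L - f.bond_r0;
      out.e_bond += 0.5 * f.bond_k * dl * dl;
      V3 fstr = (f.bond_k * dl) * bh;  // force on i along +bh
      out.fb[i] = out.fb[i] + fstr;
      out.fb[j] = out.fb[j] - fstr;
      // patch alignment: E = ka * (2 - f1_i.bh - f1_j.bh)
      V3 e1i = fc.e1[i];
      V3 e1j = fc.e1[j];
      out.e_align += f.align_k * (2.0 - dot(e1i, bh) - dot(e1j, bh));
      out.tb[i] = out.tb[i] + f.align_k * cross(e1i, bh);
      out.tb[j] = out.tb[j] + f.align_k * cross(e1j, bh);
      // d(bh)/dr_j = (I - bh bh^T)/L ; E depends on -ka*(e1i+e1j).bh
      V3 esum = e1i + e1j;
      V3 gperp = (f.align_k / L) * (esum - dot(esum, bh) * bh);
      out.fb[j] = out.fb[j] + gperp;   // force = -dE/dr_j = +ka*(...)
      out.fb[i] = out.fb[i] - gperp;
      // twist: harmonic in the bond-referenced patch dihedral, the same
      // functional the topology module measures. Referencing the dihedral
      // to the bond (not frame-to-frame swing-twist) is what makes the
      // discrete ribbon hold its winding: with positions fixed the total
      // dihedral around a closed chain is bounded, so twist can only be
      // exchanged with writhe (discrete White), not silently relaxed.
      {
        double kt = f.twist_k * fl.twist_scale;
        if (kt > 0.0) {
          V3 u = fc.patch[i], v = fc.patch[j];
          double ub = dot(u, bh), vb = dot(v, bh);
          V3 uxv = cross(u, v);
          double sn = dot(bh, uxv);
          double cs = dot(u, v) - ub * vb;
          double D = sn * sn + cs * cs;
          if (D > 1e-12) {
            // E = kt (1 - cos phi): same stiffness as the harmonic form at
            // small angles, smooth and bounded through phi = pi
            double sqD = std::sqrt(D);
            out.e_twist += kt * (1.0 - cs / sqD);
            double g = -kt * sn / (D * sqD);  // multiplies (c ds - s dc)
            V3 a1 = u - ub * bh;       // projections
            V3 a2 = v - vb * bh;
            // torque on bead i (patch u): ds = w.(u x (v x bh)), dc = w.(u x a2)
            V3 ti = g * (cs * cross(u, cross(v, bh)) - sn * cross(u, a2));
            // torque on bead j (patch v): ds = w.(v x (bh x u)), dc = w.(v x a1)
            V3 tj = g * (cs * cross(v, cross(bh, u)) - sn * cross(v, a1));
            out.tb[i] = out.tb[i] + ti;
            out.tb[j] = out.tb[j] + tj;
            // forces through the bond direction
            V3 gb = cs * uxv - sn * (-1.0 * (vb * u + ub * v));
            V3 gperp2 = gb - dot(gb, bh) * bh;
            V3 fj = (g / L) * gperp2;
            out.fb[j] = out.fb[j] + fj;
            out.fb[i] = out.fb[i] - fj;
          }
        }
      }
    }
    // bending (Kratky-Porod on position tangents)
    int ntrip = circ ? nb : nb - 2;
    for (int k = 0; k < ntrip; ++k) {
      int i0 = a + k;
      int i1 = a + ((k + 1) % nb);
      int i2 = a + ((k + 2) % nb);
      V3 d1 = s.r[i1] - s.r[i0];
      V3 d2 = s.r[i2] - s.r[i1];
      double L1 = norm3(d1), L2 = norm3(d2);
      V3 t1 = (1.0 / L1) * d1, t2 = (1.0 / L2) * d2;
      double c = dot(t1, t2);
      out.e_bend += f.bend_k * (1.0 - c);
      // F = -dE/dr = bend_k * d(cos)/dr
      V3 g0 = (-f.bend_k / L1) * (t2 - c * t1);  // d cos/d r_i0 * bend_k
      V3 g2 = ( f.bend_k / L2) * (t1 - c * t2);  // d cos/d r_i2 * bend_k
      out.fb[i0] = out.fb[i0] + g0;
      out.fb[i2] = out.fb[i2] + g2;
      out.fb[i1] = out.fb[i1] - (g0 + g2);
    }
  }

  // --- bead-bead excluded volume (or soft-core during topo-II windows) ---
  for (auto& pr : nl.bb) {
    int i = pr.first, j = pr.second;
    // exclusion for circular wrap bond
    if (s.chain[i] == s.chain[j]) {
      bool adj = false;
      for (auto& run : runs)
        if (run[2] && i == run[0] && j == run[1]) adj = true;
      if (adj) continue;
    }
    V3 d = s.r[i] - s.r[j];
    double r = norm3(d);
    if (r < 1e-9) continue;
    V3 rh = (1.0 / r) * d;
    if (fl.softcore) {
      // capped cosine repulsion: E(0) = cap, smoothly zero at sigma
      double rc = f.dd_sig;
      if (r < rc) {
        double A = 0.5 * f.softcore_cap;
        out.e_soft += A * (1.0 + std::cos(M_PI * r / rc));
        double dEdr = -A * M_PI / rc * std::sin(M_PI * r / rc);
        V3 fi = (-dEdr) * rh;
        out.fb[i] = out.fb[i] + fi;
        out.fb[j] = out.fb[j] - fi;
      }
    } else {
      double dEdr;
      double e = wca(r, f.dd_sig, f.dd_cut, f.eps_rep, &dEdr);
      if (e != 0.0) {
        out.e_rep += e;
        V3 fi = (-dEdr) * rh;
        out.fb[i] = out.fb[i] + fi;
        out.fb[j] = out.fb[j] - fi;
      }
    }
  }

  // --- core-core ---
  for (auto& pr : nl.cc) {
    int i = pr.first, j = pr.second;
    V3 d = s.cr[i] - s.cr[j];
    double r = norm3(d);
    if (r < 1e-9) continue;
    double dEdr;
    double e = wca(r, f.cc_sig, f.cc_cut, f.eps_rep, &dEdr);
    if (e != 0.0) {
      out.e_rep += e;
      V3 fi = (-dEdr) * ((1.0 / r) * d);
      out.fc[i] = out.fc[i] + fi;
      out.fc[j] = out.fc[j] - fi;
    }
  }

  // --- core-bead: body repulsion, nanoparticle well, octamer sites ---
  for (auto& pr : nl.bc) {
    int ic = pr.first, ib = pr.second;
    V3 d = s.r[ib] - s.cr[ic];
    double r = norm3(d);
    if (r < 1e-9) continue;
    V3 rh = (1.0 / r) * d;
    bool nano = s.ckind[ic] == 1;
    double sig = nano ? f.cd_sig_nano : f.cd_sig_oct;
    double cut = nano ? f.cd_contact_nano : f.cd_cut_oct;
    double dEdr;
    double e = wca(r, sig, cut, f.eps_rep, &dEdr);
    if (e != 0.0) {
      out.e_rep += e;
      V3 fb_ = (-dEdr) * rh;
      out.fb[ib] = out.fb[ib] + fb_;
      out.fc[ic] = out.fc[ic] - fb_;
      // central force through core centre: no torque on core
    }
    if (nano) {
      // isotropic attraction: flat-bottomed at the surface contact (full
      // depth wherever the bead touches the sphere), smooth cosine decay
      // over nano_well_w outward
      double rm = f.cd_contact_nano, w = f.nano_well_w;
      if (f.eps_nano > 0.0 && r < rm + w) {
        if (r <= rm) {
          out.e_nano += -f.eps_nano;
        } else {
          double u = M_PI * (r - rm) / (2.0 * w);
          double cu = std::cos(u);
          out.e_nano += -f.eps_nano * cu * cu;
          double dE = f.eps_nano * 2.0 * cu * std::sin(u) * M_PI / (2.0 * w);
          V3 fb_ = (-dE) * rh;
          out.fb[ib] = out.fb[ib] + fb_;
          out.fc[ic] = out.fc[ic] - fb_;
        }
      }
    } else if (f.eps_site > 0.0 && r < f.path_radius + f.site_cut) {
      // helical path of binding sites with angular modulation on the patch
      double eps = f.eps_site * fl.eps_mult;
      V3 patch = fc.patch[ib];
      for (int sidx = 0; sidx < s.S; ++sidx) {
        if (!s.active[ic * s.S + sidx]) continue;
        V3 sp = fc.site_pos[ic * s.S + sidx];
        V3 dd = s.r[ib] - sp;
        double ds = norm3(dd);
        if (ds >= f.site_cut) continue;
        V3 nst = fc.site_dir[ic * s.S + sidx];
        double cb = dot(patch, nst);
        if (cb <= f.site_ang_c) continue;
        double gg = (cb - f.site_ang_c) / (1.0 - f.site_ang_c);
        double g2 = gg * gg;
        double u = M_PI * ds / (2.0 * f.site_cut);
        double cu = std::cos(u);
        double Sd = cu * cu;
        out.e_site += -eps * Sd * g2;
        // distance gradient
        double dSd = -2.0 * cu * std::sin(u) * M_PI / (2.0 * f.site_cut);
        double dEdd = -eps * g2 * dSd;
        V3 fb_ = v3(0, 0, 0);
        if (ds > 1e-9) fb_ = (-dEdd / ds) * dd;
        out.fb[ib] = out.fb[ib] + fb_;
        out.fc[ic] = out.fc[ic] - fb_;
        out.tc[ic] = out.tc[ic] - cross(sp - s.cr[ic], fb_);
        // angular gradient: E depends on cb = patch . nst
        double dEdc = -eps * Sd * 2.0 * gg / (1.0 - f.site_ang_c);
        V3 tq = (-dEdc) * cross(patch, nst);
        out.tb[ib] = out.tb[ib] + tq;
        out.tc[ic] = out.tc[ic] - tq;
      }
    }
  }

  // --- spherical confinement (emulates the finite box / concentration) ---
  if (f.confine_R > 0.0 && f.confine_k > 0.0) {
    auto wall = [&](V3 p, V3* fv) -> double {
      double r = norm3(p);
      if (r <= f.confine_R || r < 1e-9) return 0.0;
      double ex = r - f.confine_R;
      *fv = *fv + (-f.confine_k * ex / r) * p;
      return 0.5 * f.confine_k * ex * ex;
    };
    for (int i = 0; i < s.n; ++i) out.e_slit += wall(s.r[i], &out.fb[i]);
    for (int i = 0; i < s.m; ++i) out.e_slit += wall(s.cr[i], &out.fc[i]);
  }

  // --- slit (flattening walls at z = +- gap/2) ---
  if (fl.slit_gap > 0.0 && f.slit_k > 0.0) {
    double gz = 0.5 * fl.slit_gap;
    for (int i = 0; i < s.n; ++i) {
      double az = std::fabs(s.r[i].z);
      if (az > gz) {
        double ex = az - gz;
        out.e_slit += 0.5 * f.slit_k * ex * ex;
        out.fb[i].z += -f.slit_k * ex * (s.r[i].z > 0 ? 1.0 : -1.0);
      }
    }
    for (int i = 0; i < s.m; ++i) {
      double az = std::fabs(s.cr[i].z);
      if (az > gz) {
        double ex = az - gz;
        out.e_slit += 0.5 * f.slit_k * ex * ex;
        out.fc[i].z += -f.slit_k * ex * (s.cr[i].z > 0 ? 1.0 : -1.0);
      }
    }
  }
}

// ------------------------------------------------------------ marshalling --
static Sys sys_from_r(const NumericMatrix& pos, const NumericMatrix& quat,
                      const IntegerVector& chain, const IntegerVector& circ,
                      const NumericMatrix& cpos, const NumericMatrix& cquat,
                      const IntegerVector& ckind,
                      const NumericMatrix& site_loc,
                      const NumericMatrix& site_dir,
                      const IntegerMatrix& active) {
  Sys s;
  s.n = pos.nrow(); s.m = cpos.nrow(); s.S = site_loc.nrow();
  s.r.resize(s.n); s.q.resize(s.n); s.chain.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.r[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    s.q[i] = {quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)};
    s.chain[i] = chain[i];
  }
  s.circ.assign(circ.begin(), circ.end());
  s.cr.resize(s.m); s.cq.resize(s.m); s.ckind.resize(s.m);
  for (int i = 0; i < s.m; ++i) {
    s.cr[i] = {cpos(i, 0), cpos(i, 1), cpos(i, 2)};
    s.cq[i] = {cquat(i, 0), cquat(i, 1), cquat(i, 2), cquat(i, 3)};
    s.ckind[i] = ckind[i];
  }
  s.site_loc.resize(s.S); s.site_dir.resize(s.S);
  for (int i = 0; i < s.S; ++i) {
    s.site_loc[i] = {site_loc(i, 0), site_loc(i, 1), site_loc(i, 2)};
    s.site_dir[i] = {site_dir(i, 0), site_dir(i, 1), site_dir(i, 2)};
  }
  s.active.assign(s.m * s.S, 0);
  for (int i = 0; i < s.m; ++i)
    for (int j = 0; j < s.S; ++j) s.active[i * s.S + j] = active(i, j);
  return s;
}

static NumericMatrix mat_from_v3(const std::vector<V3>& v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].x; m(i, 1) = v[i].y; m(i, 2) = v[i].z;
  }
  return m;
}
static NumericMatrix mat_from_q4(const std::vector<Q4>& v) {
  NumericMatrix m(v.size(), 4);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].w; m(i, 1) = v[i].x; m(i, 2) = v[i].y; m(i, 3) = v[i].z;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix quat, IntegerVector chain,
                IntegerVector circ, NumericMatrix cpos, NumericMatrix cquat,
                IntegerVector ckind, NumericMatrix site_loc,
                NumericMatrix site_dir, IntegerMatrix active, List params,
                bool softcore, double twist_scale, double eps_mult,
                double slit_gap) {
  Sys s = sys_from_r(pos, quat, chain, circ, cpos, cquat, ckind, site_loc,
                     site_dir, active);
  FF f = parse_ff(params);
  Flags fl{softcore, twist_scale, eps_mult, slit_gap};
  NeighborLists nl;
  FrameCache fc;
  Out out;
  compute_forces(s, f, fl, nl, fc, out);
  return List::create(
      _["energy"] = out.total(),
      _["terms"] = NumericVector::create(
          _["bond"] = out.e_bond, _["bend"] = out.e_bend,
          _["align"] = out.e_align, _["twist"] = out.e_twist,
          _["rep"] = out.e_rep, _["soft"] = out.e_soft,
          _["site"] = out.e_site, _["nano"] = out.e_nano,
          _["slit"] = out.e_slit),
      _["f_bead"] = mat_from_v3(out.fb), _["t_bead"] = mat_from_v3(out.tb),
      _["f_core"] = mat_from_v3(out.fc), _["t_core"] = mat_from_v3(out.tc));
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix quat, IntegerVector chain,
             IntegerVector circ, NumericMatrix cpos, NumericMatrix cquat,
             IntegerVector ckind, NumericMatrix site_loc,
             NumericMatrix site_dir, IntegerMatrix active, List params,
             bool softcore, double twist_scale, double eps_mult,
             double slit_gap0, double slit_gap1, double dt, int nsteps,
             int stride, double seed, double t0, double temperature,
             double limit_move) {
  Sys s = sys_from_r(pos, quat, chain, circ, cpos, cquat, ckind, site_loc,
                     site_dir, active);
  FF f = parse_ff(params);
  NeighborLists nl;
  FrameCache fc;
  Out out;
  Xoshiro rng(static_cast<uint64_t>(seed));

  // mobilities in reduced units (D of a DNA bead = sigma^2 per tau_B)
  double Dt = f.sigma * f.sigma;            // 6.25 nm^2 / tau_B
  double Dr = 3.0;                          // rad^2 / tau_B
  double rat = f.sigma / f.core_diam;       // Stokes scaling for the core
  double Dtc = Dt * rat;
  double Drc = Dr * rat * rat * rat;
  double kT = temperature;                  // 1 = ambient; 0 = deterministic
  double sq_b_t = std::sqrt(2.0 * Dt * dt * kT);
  double sq_b_r = std::sqrt(2.0 * Dr * dt * kT);
  double sq_c_t = std::sqrt(2.0 * Dtc * dt * kT);
  double sq_c_r = std::sqrt(2.0 * Drc * dt * kT);
  double max_disp = 0.5 * f.sigma;

  int nsnap = nsteps / std::max(stride, 1) + 1;
  List snaps(nsnap);
  NumericVector times(nsnap);
  int isnap = 0;

  auto snapshot = [&](double t) {
    snaps[isnap] = List::create(
        _["pos"] = mat_from_v3(s.r), _["quat"] = mat_from_q4(s.q),
        _["cpos"] = mat_from_v3(s.cr), _["cquat"] = mat_from_q4(s.cq));
    times[isnap] = t;
    ++isnap;
  };
  snapshot(t0);

  for (int step = 1; step <= nsteps; ++step) {
    Flags fl{softcore, twist_scale, eps_mult, 0.0};
    if (slit_gap0 > 0.0) {
      double a = static_cast<double>(step - 1) / std::max(nsteps - 1, 1);
      fl.slit_gap = slit_gap0 + a * (slit_gap1 - slit_gap0);
    }
    compute_forces(s, f, fl, nl, fc, out);
    for (int i = 0; i < s.n; ++i) {
      V3 dx = (Dt * dt) * out.fb[i] +
              v3(sq_b_t * rng.kick(), sq_b_t * rng.kick(), sq_b_t * rng.kick());
      double nd = norm3(dx);
      if (limit_move > 0.0) {
        if (nd > limit_move) dx = (limit_move / nd) * dx;
      } else if (nd > max_disp) {
        stop("unstable step: bead displacement %.3f nm at step %d; reduce dt",
             nd, step);
      }
      s.r[i] = s.r[i] + dx;
      V3 w = (Dr * dt) * out.tb[i] +
             v3(sq_b_r * rng.kick(), sq_b_r * rng.kick(), sq_b_r * rng.kick());
      s.q[i] = qnormalize(qmul(q_from_rotvec(w), s.q[i]));
    }
    for (int i = 0; i < s.m; ++i) {
      V3 dx = (Dtc * dt) * out.fc[i] +
              v3(sq_c_t * rng.kick(), sq_c_t * rng.kick(), sq_c_t * rng.kick());
      double nd = norm3(dx);
      if (limit_move > 0.0) {
        if (nd > limit_move) dx = (limit_move / nd) * dx;
      } else if (nd > max_disp) {
        stop("unstable step: core displacement %.3f nm at step %d; reduce dt",
             nd, step);
      }
      s.cr[i] = s.cr[i] + dx;
      V3 w = (Drc * dt) * out.tc[i] +
             v3(sq_c_r * rng.kick(), sq_c_r * rng.kick(), sq_c_r * rng.kick());
      s.cq[i] = qnormalize(qmul(q_from_rotvec(w), s.cq[i]));
    }
    if (step % std::max(stride, 1) == 0) snapshot(t0 + step * dt);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  // trim if stride did not divide nsteps evenly
  if (isnap < nsnap) {
    snaps = snaps[Range(0, isnap - 1)];
    times = times[Range(0, isnap - 1)];
  }
  return List::create(_["snapshots"] = snaps, _["times"] = times);
}

// -------------------------------------------------------------- site pairs --
// Bead-site contacts for binding analysis: one row per (bead, core, site)
// within the capture radius of an active site, with distance, angular
// factor and energy (in kBT).
// [[Rcpp::export]]
NumericMatrix cpp_site_pairs(NumericMatrix pos, NumericMatrix quat,
                             NumericMatrix cpos, NumericMatrix cquat,
                             IntegerVector ckind, NumericMatrix site_loc,
                             NumericMatrix site_dir, IntegerMatrix active,
                             List params, double eps_mult) {
  FF f = parse_ff(params);
  int n = pos.nrow(), m = cpos.nrow(), S = site_loc.nrow();
  std::vector<double> rows;
  double reach = f.path_radius + f.site_cut + 1.0;
  for (int ic = 0; ic < m; ++ic) {
    if (ckind[ic] == 1) continue;
    Q4 cq = {cquat(ic, 0), cquat(ic, 1), cquat(ic, 2), cquat(ic, 3)};
    V3 cc = {cpos(ic, 0), cpos(ic, 1), cpos(ic, 2)};
    for (int ib = 0; ib < n; ++ib) {
      V3 rb = {pos(ib, 0), pos(ib, 1), pos(ib, 2)};
      V3 dc = rb - cc;
      if (dot(dc, dc) > reach * reach) continue;
      Q4 qb = {quat(ib, 0), quat(ib, 1), quat(ib, 2), quat(ib, 3)};
      V3 patch = qrot(qb, v3(0, 1, 0));
      for (int sidx = 0; sidx < S; ++sidx) {
        if (!active(ic, sidx)) continue;
        V3 sl = {site_loc(sidx, 0), site_loc(sidx, 1), site_loc(sidx, 2)};
        V3 sp = cc + qrot(cq, sl);
        V3 dd = rb - sp;
        double ds = norm3(dd);
        if (ds >= f.site_cut) continue;
        V3 sd = {site_dir(sidx, 0), site_dir(sidx, 1), site_dir(sidx, 2)};
        V3 nst = qrot(cq, sd);
        double cb = dot(patch, nst);
        double gg = cb > f.site_ang_c
                        ? (cb - f.site_ang_c) / (1.0 - f.site_ang_c)
                        : 0.0;
        double u = M_PI * ds / (2.0 * f.site_cut);
        double cu = std::cos(u);
        double e = -f.eps_site * eps_mult * cu * cu * gg * gg;
        rows.insert(rows.end(),
                    {(double)(ib + 1), (double)(ic + 1), (double)(sidx + 1),
                     ds, cb, e});
      }
    }
  }
  int nr = rows.size() / 6;
  NumericMatrix outm(nr, 6);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 6; ++j) outm(i, j) = rows[i * 6 + j];
  colnames(outm) = CharacterVector::create("bead", "core", "site", "dist",
                                           "cos_beta", "energy");
  return outm;
}

// ------------------------------------------------------------------ writhe --
// Signed solid angle of the spherical triangle (a, b, c); robust atan2 form.
static inline double tri_omega(V3 a, V3 b, V3 c) {
  double num = dot(a, cross(b, c));
  double den = 1.0 + dot(a, b) + dot(b, c) + dot(c, a);
  return 2.0 * std::atan2(num, den);
}
// Gauss-integral contribution of segment pair (p1->p2, p3->p4), exact.
static inline double pair_writhe(V3 p1, V3 p2, V3 p3, V3 p4) {
  V3 a = p3 - p1, b = p4 - p1, c = p4 - p2, d = p3 - p2;
  double na = norm3(a), nb_ = norm3(b), nc = norm3(c), nd = norm3(d);
  if (na < 1e-12 || nb_ < 1e-12 || nc < 1e-12 || nd < 1e-12) return 0.0;
  a = (1.0 / na) * a; b = (1.0 / nb_) * b; c = (1.0 / nc) * c;
  d = (1.0 / nd) * d;
  return -(tri_omega(a, b, c) + tri_omega(a, c, d)) / (4.0 * M_PI);
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix verts, bool closed) {
  int nv = verts.nrow();
  if (nv < 3) return 0.0;
  int m = closed ? nv : nv - 1;
  std::vector<V3> A(m), B(m);
  for (int i = 0; i < m; ++i) {
    A[i] = {verts(i, 0), verts(i, 1), verts(i, 2)};
    int j = (i + 1) % nv;
    B[i] = {verts(j, 0), verts(j, 1), verts(j, 2)};
  }
  double tot = 0.0;
  for (int i = 0; i < m - 1; ++i)
    for (int j = i + 1; j < m; ++j) {
      if (j == i + 1) continue;
      if (closed && i == 0 && j == m - 1) continue;
      tot += pair_writhe(A[i], B[i], A[j], B[j]);
    }
  return 2.0 * tot;
}

// Gauss linking number of two closed polylines (exact integral, rounded by
// the caller). Used as an independent cross-check of Tw + Wr.
// [[Rcpp::export]]
double cpp_link(NumericMatrix c1, NumericMatrix c2) {
  int n1 = c1.nrow(), n2 = c2.nrow();
  double tot = 0.0;
  for (int i = 0; i < n1; ++i) {
    V3 p1 = {c1(i, 0), c1(i, 1), c1(i, 2)};
    int i2 = (i + 1) % n1;
    V3 p2 = {c1(i2, 0), c1(i2, 1), c1(i2, 2)};
    for (int j = 0; j < n2; ++j) {
      V3 p3 = {c2(j, 0), c2(j, 1), c2(j, 2)};
      int j2 = (j + 1) % n2;
      V3 p4 = {c2(j2, 0), c2(j2, 1), c2(j2, 2)};
      tot += pair_writhe(p1, p2, p3, p4);
    }
  }
  return tot;
}
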