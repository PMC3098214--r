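// Simulation engine: pairwise forces over gestalt shape hierarchies,
// TEA-approximated Rotne-Prager hydrodynamics, BD/LD propagation,
// periodic/reflecting/open boundaries with constant-density interfaces.
//
// Unit system: nm / ps / kDa / e; all energies and force constants in kT,
// so BD displacements are D * F_kT * dt and kT enters only through the
// Langevin relaxation time tau = m * D / kT and the Coulomb prefactor.
//
// All randomness is drawn from R's RNG in a fixed order (gestalt storage
// order within each step), so a run is bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <sstream>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x = 0, y = 0, z = 0;
  Vec3() {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}

struct Quat {
  double w = 1, x = 0, y = 0, z = 0;
  Quat() {}
  Quat(double w_, double x_, double y_, double z_) : w(w_), x(x_), y(y_), z(z_) {}
};

inline Quat qmul(const Quat& a, const Quat& b) {
  return Quat(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}

inline void qnormalize(Quat& q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

inline Vec3 qrotate(const Quat& q, const Vec3& v) {
  // v' = q v q*
  const double tx = 2 * (q.y * v.z - q.z * v.y);
  const double ty = 2 * (q.z * v.x - q.x * v.z);
  const double tz = 2 * (q.x * v.y - q.y * v.x);
  return Vec3(v.x + q.w * tx + (q.y * tz - q.z * ty),
              v.y + q.w * ty + (q.z * tx - q.x * tz),
              v.z + q.w * tz + (q.x * ty - q.y * tx));
}

inline Quat quat_from_rotvec(const Vec3& w) {
  double th = w.norm();
  if (th < 1e-14) return Quat(1, 0.5 * w.x, 0.5 * w.y, 0.5 * w.z);  // first order
  double s = std::sin(0.5 * th) / th;
  return Quat(std::cos(0.5 * th), s * w.x, s * w.y, s * w.z);
}

// ---------------------------------------------------------------- pair kernels

struct ColourTable {
  int nc = 0;
  std::vector<double> eps, sigma, cutoff, rlin;
  std::vector<int> attr, defined;
  int idx(int a, int b) const { return a * nc + b; }
};

// Lennard-Jones 12-6 reparameterised so the minimum sits at surface
// separation sigma with depth -eps; repulsive-only pairs keep the s^-12
// branch. Linear continuation (constant force) below s = rlin.
// Returns energy; *dU = dU/ds.
inline double vdw_energy(double s, double eps, double sigma, double cutoff,
                         bool attractive, double rlin, double* dU) {
  if (s >= cutoff) { *dU = 0; return 0; }
  auto core = [&](double ss, double* d) -> double {
    double inv = sigma / ss;
    double i6 = inv * inv * inv; i6 *= i6;           // (sigma/s)^6
    if (attractive) {
      *d = -(12.0 * eps / ss) * (i6 * i6 - i6);
      return eps * (i6 * i6 - 2.0 * i6);
    }
    *d = -(12.0 * eps / ss) * i6 * i6;
    return eps * i6 * i6;
  };
  if (s < rlin) {
    double d0; double u0 = core(rlin, &d0);
    *dU = d0;
    return u0 + d0 * (s - rlin);
  }
  return core(s, dU);
}

// Screened Coulomb with burial depths: U = (Ce/eps_r) qi qk exp(-k(r-B)) / r,
// unscreened for the buried stretch B = bi + bk.  Ce in kT*nm.
inline double es_energy(double r, double qq, double B, double kappa,
                        double Ce_over_epsr, double* dU) {
  double u = Ce_over_epsr * qq * std::exp(-kappa * (r - B)) / r;
  *dU = u * (-kappa - 1.0 / r);
  return u;
}

// Rotne-Prager-Yamakawa mobility block (3x3, row-major into out[9]) between
// spheres (ai, Di) and (ak, Dk) separated by dr.  Far field uses the
// unequal-radii RPY form; overlapping centers fall back to the standard
// regularised form with the mean radius (working ansatz; exact for equal
// radii).  c = kT/(6 pi eta) is taken as sqrt(Di ai Dk ak).
inline void rpy_block(const Vec3& dr, double ai, double ak, double Di, double Dk,
                      double* out) {
  double r = dr.norm();
  if (r < 1e-9) stop("rpy_block: coincident hydrodynamic centers");
  double c = std::sqrt(Di * ai * Dk * ak);
  double e[3] = { dr.x / r, dr.y / r, dr.z / r };
  double ciso, cdy;
  if (r >= ai + ak) {
    double a2 = ai * ai + ak * ak;
    double pre = 0.75 * c / r;
    ciso = pre * (1.0 + a2 / (3.0 * r * r));
    cdy  = pre * (1.0 - a2 / (r * r));
  } else {
    double ab = 0.5 * (ai + ak);
    double Db = c / ab;
    ciso = Db * (1.0 - 9.0 * r / (32.0 * ab));
    cdy  = Db * (3.0 * r / (32.0 * ab));
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      out[3 * a + b] = ciso * (a == b ? 1.0 : 0.0) + cdy * e[a] * e[b];
}

// ------------------------------------------------------------------- system

struct Interface {
  int axis = 0, side = 0;       // side 0: plane at 0, inflow +; side 1: at L
  double rho = 0;
  int species = -1;
  // injectable template (single gestalt)
  double Dtr = 0, Drot = 0, mass = NA_REAL;
  std::vector<Vec3> voff; std::vector<double> vrad; std::vector<int> vcol;
  bool has_hydro = false; double hy_a = 0, hy_D = 0;
  double max_rad = 0;
  // bookkeeping
  long n_absorbed = 0, n_injected = 0;
  double nu = 0;                // mean insertions per step
  double pending = 0;           // deferred insertions
};

struct System {
  // mobile gestalts (struct-of-vectors; dead entries stay, alive flags skip)
  std::vector<Vec3> pos, posu, vel;   // wrapped, unwrapped, velocity
  std::vector<Quat> quat;
  std::vector<double> Dtr, Drot, mass;  // mass NA => BD
  std::vector<int> species, protein;
  std::vector<char> alive;

  // shapes, indexed per gestalt
  std::vector<std::vector<int>> vdw_of, ch_of, re_of;
  std::vector<Vec3> vdw_off; std::vector<double> vdw_r; std::vector<int> vdw_col;
  std::vector<Vec3> ch_off; std::vector<double> ch_q, ch_b;
  std::vector<int> re_type; std::vector<double> re_k; std::vector<Vec3> re_x0, re_F0;
  std::vector<int> hy_idx;            // per gestalt: -1 or index into hy_a/hy_D
  std::vector<double> hy_a, hy_D;

  // bonds
  std::vector<int> bond_a, bond_b;
  std::vector<Vec3> bond_oa, bond_ob;
  std::vector<double> bond_k2, bond_k4, bond_L0;

  // fixed walls
  std::vector<Vec3> w_pos; std::vector<double> w_r; std::vector<int> w_col;
  std::vector<Vec3> wc_pos; std::vector<double> wc_q, wc_b;

  // box
  double L[3] = {0, 0, 0};
  int mode[3] = {0, 0, 0};            // 0 none, 1 periodic, 2 reflecting, 3 open

  ColourTable ct;
  std::vector<Interface> ifaces;

  // forces
  std::vector<Vec3> F, T;
  double energy = 0;
  long n_int = 0;

  int n() const { return (int)pos.size(); }

  inline Vec3 minimg(Vec3 d) const {
    if (mode[0] == 1) d.x -= L[0] * std::round(d.x / L[0]);
    if (mode[1] == 1) d.y -= L[1] * std::round(d.y / L[1]);
    if (mode[2] == 1) d.z -= L[2] * std::round(d.z / L[2]);
    return d;
  }
};

void parse_offsets(const NumericMatrix& m, std::vector<Vec3>& out) {
  for (int i = 0; i < m.nrow(); ++i) out.push_back(Vec3(m(i, 0), m(i, 1), m(i, 2)));
}

System build_system(const List& sys) {
  System S;
  NumericMatrix pos = sys["pos"], quat = sys["quat"], vel = sys["vel"];
  NumericVector Dtr = sys["Dtr"], Drot = sys["Drot"], mass = sys["mass"];
  IntegerVector spec = sys["species"], prot = sys["protein"];
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    S.pos.push_back(Vec3(pos(i, 0), pos(i, 1), pos(i, 2)));
    S.posu.push_back(S.pos.back());
    S.vel.push_back(Vec3(vel(i, 0), vel(i, 1), vel(i, 2)));
    S.quat.push_back(Quat(quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3)));
    S.Dtr.push_back(Dtr[i]); S.Drot.push_back(Drot[i]); S.mass.push_back(mass[i]);
    S.species.push_back(spec[i]); S.protein.push_back(prot[i]);
    S.alive.push_back(1);
  }
  S.vdw_of.resize(n); S.ch_of.resize(n); S.re_of.resize(n);
  S.hy_idx.assign(n, -1);

  IntegerVector vg = sys["vdw_g"];
  NumericMatrix voff = sys["vdw_off"];
  NumericVector vr = sys["vdw_r"]; IntegerVector vc = sys["vdw_col"];
  for (int j = 0; j < vg.size(); ++j) {
    S.vdw_of[vg[j]].push_back(j);
    S.vdw_off.push_back(Vec3(voff(j, 0), voff(j, 1), voff(j, 2)));
    S.vdw_r.push_back(vr[j]); S.vdw_col.push_back(vc[j]);
  }
  IntegerVector cg = sys["ch_g"];
  NumericMatrix coff = sys["ch_off"];
  NumericVector cq = sys["ch_q"], cb = sys["ch_b"];
  for (int j = 0; j < cg.size(); ++j) {
    S.ch_of[cg[j]].push_back(j);
    S.ch_off.push_back(Vec3(coff(j, 0), coff(j, 1), coff(j, 2)));
    S.ch_q.push_back(cq[j]); S.ch_b.push_back(cb[j]);
  }
  IntegerVector hg = sys["hy_g"];
  NumericVector ha = sys["hy_a"], hD = sys["hy_D"];
  for (int j = 0; j < hg.size(); ++j) {
    S.hy_idx[hg[j]] = (int)S.hy_a.size();
    S.hy_a.push_back(ha[j]); S.hy_D.push_back(hD[j]);
  }
  IntegerVector rg = sys["re_g"], rt = sys["re_type"];
  NumericVector rk = sys["re_k"];
  NumericMatrix rx0 = sys["re_x0"], rF = sys["re_F"];
  for (int j = 0; j < rg.size(); ++j) {
    S.re_of[rg[j]].push_back(j);
    S.re_type.push_back(rt[j]); S.re_k.push_back(rk[j]);
    S.re_x0.push_back(Vec3(rx0(j, 0), rx0(j, 1), rx0(j, 2)));
    S.re_F0.push_back(Vec3(rF(j, 0), rF(j, 1), rF(j, 2)));
  }
  IntegerVector ba = sys["bond_a"], bb = sys["bond_b"];
  NumericMatrix boa = sys["bond_oa"], bob = sys["bond_ob"];
  NumericVector bk2 = sys["bond_k2"], bk4 = sys["bond_k4"], bL0 = sys["bond_L0"];
  for (int j = 0; j < ba.size(); ++j) {
    S.bond_a.push_back(ba[j]); S.bond_b.push_back(bb[j]);
    S.bond_oa.push_back(Vec3(boa(j, 0), boa(j, 1), boa(j, 2)));
    S.bond_ob.push_back(Vec3(bob(j, 0), bob(j, 1), bob(j, 2)));
    S.bond_k2.push_back(bk2[j]); S.bond_k4.push_back(bk4[j]); S.bond_L0.push_back(bL0[j]);
  }
  NumericMatrix wp = sys["w_pos"];
  NumericVector wr = sys["w_r"]; IntegerVector wc = sys["w_col"];
  for (int j = 0; j < wp.nrow(); ++j) {
    S.w_pos.push_back(Vec3(wp(j, 0), wp(j, 1), wp(j, 2)));
    S.w_r.push_back(wr[j]); S.w_col.push_back(wc[j]);
  }
  NumericMatrix wcp = sys["wc_pos"];
  NumericVector wcq = sys["wc_q"], wcb = sys["wc_b"];
  for (int j = 0; j < wcp.nrow(); ++j) {
    S.wc_pos.push_back(Vec3(wcp(j, 0), wcp(j, 1), wcp(j, 2)));
    S.wc_q.push_back(wcq[j]); S.wc_b.push_back(wcb[j]);
  }
  NumericVector bl = sys["box_L"]; IntegerVector bm = sys["box_mode"];
  for (int a = 0; a < 3; ++a) { S.L[a] = bl[a]; S.mode[a] = bm[a]; }

  List ctl = sys["colours"];
  NumericMatrix ce = ctl["eps"], cs = ctl["sigma"], cc = ctl["cutoff"], cl = ctl["rlin"];
  IntegerMatrix cat_ = ctl["attractive"], cd = ctl["defined"];
  S.ct.nc = ce.nrow();
  S.ct.eps.resize(S.ct.nc * S.ct.nc); S.ct.sigma.resize(S.ct.nc * S.ct.nc);
  S.ct.cutoff.resize(S.ct.nc * S.ct.nc); S.ct.rlin.resize(S.ct.nc * S.ct.nc);
  S.ct.attr.resize(S.ct.nc * S.ct.nc); S.ct.defined.resize(S.ct.nc * S.ct.nc);
  for (int a = 0; a < S.ct.nc; ++a)
    for (int b = 0; b < S.ct.nc; ++b) {
      int k = S.ct.idx(a, b);
      S.ct.eps[k] = ce(a, b); S.ct.sigma[k] = cs(a, b);
      S.ct.cutoff[k] = cc(a, b); S.ct.rlin[k] = cl(a, b);
      S.ct.attr[k] = cat_(a, b); S.ct.defined[k] = cd(a, b);
    }

  List ifl = sys["interfaces"];
  for (int j = 0; j < ifl.size(); ++j) {
    List f = ifl[j];
    Interface I;
    I.axis = as<int>(f["axis"]); I.side = as<int>(f["side"]);
    I.rho = as<double>(f["rho"]); I.species = as<int>(f["species"]);
    List tpl = f["template"];
    I.Dtr = as<double>(tpl["Dtr"]); I.Drot = as<double>(tpl["Drot"]);
    I.mass = as<double>(tpl["mass"]);
    NumericMatrix tvo = tpl["vdw_off"];
    NumericVector tvr = tpl["vdw_r"]; IntegerVector tvc = tpl["vdw_col"];
    for (int m = 0; m < tvo.nrow(); ++m) {
      I.voff.push_back(Vec3(tvo(m, 0), tvo(m, 1), tvo(m, 2)));
      I.vrad.push_back(tvr[m]); I.vcol.push_back(tvc[m]);
      I.max_rad = std::max(I.max_rad, tvr[m]);
    }
    I.has_hydro = as<bool>(tpl["has_hydro"]);
    if (I.has_hydro) { I.hy_a = as<double>(tpl["hy_a"]); I.hy_D = as<double>(tpl["hy_D"]); }
    S.ifaces.push_back(I);
  }
  S.F.assign(n, Vec3()); S.T.assign(n, Vec3());
  return S;
}

struct Config {
  double dt, kT, kappa, eps_r, coulomb;
  long steps; int stride, record, tensor_stride;
  bool hi;
};

Config parse_config(const List& cfg) {
  Config c;
  c.dt = as<double>(cfg["dt"]); c.kT = as<double>(cfg["kT"]);
  c.kappa = as<double>(cfg["kappa"]); c.eps_r = as<double>(cfg["eps_r"]);
  c.coulomb = as<double>(cfg["coulomb"]);
  c.steps = (long)as<double>(cfg["steps"]);
  c.stride = as<int>(cfg["stride"]);
  c.record = as<int>(cfg["record"]);
  c.tensor_stride = as<int>(cfg["tensor_stride"]);
  c.hi = as<bool>(cfg["hi"]);
  return c;
}

// ------------------------------------------------------------ force evaluation

void pair_gestalt_forces(System& S, const Config& C, int i, int k) {
  // vdW sphere pairs
  for (int a : S.vdw_of[i]) {
    Vec3 pa = S.pos[i] + qrotate(S.quat[i], S.vdw_off[a]);
    for (int b : S.vdw_of[k]) {
      Vec3 pb = S.pos[k] + qrotate(S.quat[k], S.vdw_off[b]);
      Vec3 d = S.minimg(pa - pb);
      int ci = S.vdw_col[a], ck = S.vdw_col[b];
      int t = S.ct.idx(ci, ck);
      if (!S.ct.defined[t]) {
        std::ostringstream msg;
        msg << "no interaction parameters for colour pair (" << ci << ", " << ck << ")";
        stop(msg.str());
      }
      double r = d.norm();
      double s = r - S.vdw_r[a] - S.vdw_r[b];
      if (s >= S.ct.cutoff[t]) continue;
      if (r < 1e-12) stop("vdW spheres at coincident centers");
      double dU;
      double u = vdw_energy(s, S.ct.eps[t], S.ct.sigma[t], S.ct.cutoff[t],
                            S.ct.attr[t] != 0, S.ct.rlin[t], &dU);
      S.energy += u;
      Vec3 f = d * (-dU / r);          // force on i
      S.F[i] += f;
      S.T[i] += cross(pa - S.pos[i], f);
      S.F[k] -= f;
      S.T[k] -= cross(pb - S.pos[k], f);
    }
  }
  // charge pairs
  if (!S.ch_of[i].empty() && !S.ch_of[k].empty()) {
    for (int a : S.ch_of[i]) {
      Vec3 pa = S.pos[i] + qrotate(S.quat[i], S.ch_off[a]);
      for (int b : S.ch_of[k]) {
        if (S.ch_q[a] == 0 || S.ch_q[b] == 0) continue;
        Vec3 pb = S.pos[k] + qrotate(S.quat[k], S.ch_off[b]);
        Vec3 d = S.minimg(pa - pb);
        double r = d.norm();
        if (r < 1e-12) stop("point charges at coincident positions");
        double B = S.ch_b[a] + S.ch_b[b];
        if (C.kappa > 0 && r > B + 5.0 / C.kappa) continue;
        double dU;
        double u = es_energy(r, S.ch_q[a] * S.ch_q[b], B, C.kappa,
                             C.coulomb / C.eps_r, &dU);
        S.energy += u;
        Vec3 f = d * (-dU / r);
        S.F[i] += f; S.T[i] += cross(pa - S.pos[i], f);
        S.F[k] -= f; S.T[k] -= cross(pb - S.pos[k], f);
      }
    }
  }
}

void wall_forces(System& S, const Config& C, int i) {
  for (int a : S.vdw_of[i]) {
    Vec3 pa = S.pos[i] + qrotate(S.quat[i], S.vdw_off[a]);
    for (size_t b = 0; b < S.w_pos.size(); ++b) {
      Vec3 d = S.minimg(pa - S.w_pos[b]);
      int t = S.ct.idx(S.vdw_col[a], S.w_col[b]);
      if (!S.ct.defined[t]) stop("no interaction parameters for wall colour pair");
      double r = d.norm();
      double s = r - S.vdw_r[a] - S.w_r[b];
      if (s >= S.ct.cutoff[t]) continue;
      if (r < 1e-12) stop("vdW sphere coincides with obstacle center");
      double dU;
      double u = vdw_energy(s, S.ct.eps[t], S.ct.sigma[t], S.ct.cutoff[t],
                            S.ct.attr[t] != 0, S.ct.rlin[t], &dU);
      S.energy += u;
      Vec3 f = d * (-dU / r);
      S.F[i] += f; S.T[i] += cross(pa - S.pos[i], f);
    }
  }
  if (!S.ch_of[i].empty() && !S.wc_pos.empty()) {
    for (int a : S.ch_of[i]) {
      Vec3 pa = S.pos[i] + qrotate(S.quat[i], S.ch_off[a]);
      for (size_t b = 0; b < S.wc_pos.size(); ++b) {
        Vec3 d = S.minimg(pa - S.wc_pos[b]);
        double r = d.norm();
        if (r < 1e-12) stop("charge coincides with wall charge");
        double B = S.ch_b[a] + S.wc_b[b];
        if (C.kappa > 0 && r > B + 5.0 / C.kappa) continue;
        double dU;
        double u = es_energy(r, S.ch_q[a] * S.wc_q[b], B, C.kappa,
                             C.coulomb / C.eps_r, &dU);
        S.energy += u;
        Vec3 f = d * (-dU / r);
        S.F[i] += f; S.T[i] += cross(pa - S.pos[i], f);
      }
    }
  }
}

void bond_forces_all(System& S) {
  for (size_t j = 0; j < S.bond_a.size(); ++j) {
    int A = S.bond_a[j], B = S.bond_b[j];
    if (!S.alive[A] || !S.alive[B]) continue;
    Vec3 pa = S.pos[A] + qrotate(S.quat[A], S.bond_oa[j]);
    Vec3 pb = S.pos[B] + qrotate(S.quat[B], S.bond_ob[j]);
    Vec3 d = S.minimg(pa - pb);
    double r = d.norm();
    Vec3 u = (r < 1e-12) ? Vec3(1, 0, 0) : d * (1.0 / r);  // documented tie-break
    double dl = r - S.bond_L0[j];
    double fmag = S.bond_k2[j] * dl + S.bond_k4[j] * dl * dl * dl;
    S.energy += 0.5 * S.bond_k2[j] * dl * dl + 0.25 * S.bond_k4[j] * dl * dl * dl * dl;
    Vec3 f = u * (-fmag);             // force on A
    S.F[A] += f; S.T[A] += cross(pa - S.pos[A], f);
    S.F[B] -= f; S.T[B] -= cross(pb - S.pos[B], f);
  }
}

void external_forces_all(System& S) {
  for (int i = 0; i < S.n(); ++i) {
    if (!S.alive[i]) continue;
    for (int j : S.re_of[i]) {
      if (S.re_type[j] == 0) {        // harmonic confinement of the origin
        Vec3 d = S.pos[i] - S.re_x0[j];
        S.F[i] -= d * S.re_k[j];
        S.energy += 0.5 * S.re_k[j] * d.norm2();
      } else {                        // constant force
        S.F[i] += S.re_F0[j];
      }
    }
  }
}

void accumulate_forces(System& S, const Config& C, const std::vector<int>& act) {
  for (int i = 0; i < S.n(); ++i) { S.F[i] = Vec3(); S.T[i] = Vec3(); }
  S.energy = 0; S.n_int = 0;
  int na = (int)act.size();
  for (int u = 0; u < na; ++u)
    for (int v = u + 1; v < na; ++v) {
      pair_gestalt_forces(S, C, act[u], act[v]);
      ++S.n_int;
    }
  for (int u = 0; u < na; ++u) {
    wall_forces(S, C, act[u]);
    S.n_int += (long)S.w_pos.size();
  }
  bond_forces_all(S);
  external_forces_all(S);
}

// ---------------------------------------------------------------- TEA machinery

// One TEA evaluation over the hydrodynamic subset `hyd` (gestalt indices).
// Blocks are built from wrapped positions with minimum-image separations and
// cached when the subset is small enough; coefficients follow the truncated
// expansion: eps = <tr(B_ik)/(3 sqrt(Di Dk))>, a beta^2 + 2 beta - 1 = 0 with
// a = eps ((N-2) - (N-1) eps), and per-coordinate normalisation C so the
// self-covariance of the correlated displacements stays 2 D_ii dt exactly.
struct TEA {
  int nh = 0;
  double eps = 0, beta = 0.5;
  bool fallback = false;
  std::vector<double> C;              // 3*nh
  std::vector<double> blocks;        // cached nh*nh*9 when nh <= cache_limit
  bool cached = false;
  static const int cache_limit = 256;
};

void tea_compute(const System& S, const std::vector<int>& hyd, TEA& t) {
  int nh = (int)hyd.size();
  t.nh = nh;
  t.C.assign(3 * nh, 1.0);
  t.eps = 0; t.beta = 0.5; t.fallback = false;
  if (nh < 2) return;
  t.cached = nh <= TEA::cache_limit;
  if (t.cached) t.blocks.assign((size_t)nh * nh * 9, 0.0);

  double esum = 0;
  std::vector<double> rowsq(3 * nh, 0.0);
  double blk[9];
  for (int u = 0; u < nh; ++u) {
    int gi = hyd[u]; int hi_ = S.hy_idx[gi];
    for (int v = u + 1; v < nh; ++v) {
      int gk = hyd[v]; int hk = S.hy_idx[gk];
      Vec3 d = S.minimg(S.pos[gi] - S.pos[gk]);
      rpy_block(d, S.hy_a[hi_], S.hy_a[hk], S.hy_D[hi_], S.hy_D[hk], blk);
      if (t.cached)
        for (int q = 0; q < 9; ++q) {
          t.blocks[((size_t)u * nh + v) * 9 + q] = blk[q];
          t.blocks[((size_t)v * nh + u) * 9 + 3 * (q % 3) + q / 3] = blk[q];
        }
      esum += (blk[0] + blk[4] + blk[8]) / (3.0 * std::sqrt(S.hy_D[hi_] * S.hy_D[hk]));
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double e2 = blk[3 * a + b] * blk[3 * a + b];
          rowsq[3 * u + a] += e2 / S.hy_D[hk];
          rowsq[3 * v + b] += e2 / S.hy_D[hi_];
        }
    }
  }
  t.eps = esum / (0.5 * nh * (nh - 1));
  double aq = t.eps * ((nh - 2) - (nh - 1) * t.eps);
  if (std::fabs(aq) < 1e-12) {
    t.beta = 0.5;
  } else if (1.0 + aq < 0) {
    t.beta = 1.0; t.fallback = true;   // documented degeneracy
  } else {
    t.beta = (-1.0 + std::sqrt(1.0 + aq)) / aq;
  }
  for (int u = 0; u < nh; ++u) {
    double Dii = S.hy_D[S.hy_idx[hyd[u]]];
    for (int a = 0; a < 3; ++a)
      t.C[3 * u + a] = std::sqrt(Dii / (Dii + t.beta * t.beta * rowsq[3 * u + a]));
  }
}

// Effective deterministic forces F_i^eff = F_i + sum_k (B_ik / D_ii) F_k and
// correlated random displacements R_i = C_i (r_i + beta sum_k (B_ik/D_kk) r_k).
void tea_apply(const System& S, const std::vector<int>& hyd, const TEA& t,
               std::vector<Vec3>& F, std::vector<Vec3>& R) {
  int nh = t.nh;
  if (nh < 2) return;
  std::vector<Vec3> Fe(nh), Re(nh);
  for (int u = 0; u < nh; ++u) { Fe[u] = F[hyd[u]]; Re[u] = R[hyd[u]]; }
  double blk[9];
  const double* bp = blk;
  for (int u = 0; u < nh; ++u) {
    int gi = hyd[u]; int hi_ = S.hy_idx[gi];
    double Dii = S.hy_D[hi_];
    Vec3 fsum, rsum;
    for (int v = 0; v < nh; ++v) {
      if (v == u) continue;
      int gk = hyd[v]; int hk = S.hy_idx[gk];
      if (t.cached) {
        bp = &t.blocks[((size_t)u * nh + v) * 9];
      } else {
        Vec3 d = S.minimg(S.pos[gi] - S.pos[gk]);
        rpy_block(d, S.hy_a[hi_], S.hy_a[hk], S.hy_D[hi_], S.hy_D[hk], blk);
        bp = blk;
      }
      const Vec3& fk = Fe[v];
      fsum += Vec3(bp[0] * fk.x + bp[1] * fk.y + bp[2] * fk.z,
                   bp[3] * fk.x + bp[4] * fk.y + bp[5] * fk.z,
                   bp[6] * fk.x + bp[7] * fk.y + bp[8] * fk.z) * (1.0 / Dii);
      const Vec3& rk = Re[v];
      double Dkk = S.hy_D[hk];
      rsum += Vec3(bp[0] * rk.x + bp[1] * rk.y + bp[2] * rk.z,
                   bp[3] * rk.x + bp[4] * rk.y + bp[5] * rk.z,
                   bp[6] * rk.x + bp[7] * rk.y + bp[8] * rk.z) * (1.0 / Dkk);
    }
    F[gi] = Fe[u] + fsum;
    R[gi] = Vec3(t.C[3 * u + 0] * (Re[u].x + t.beta * rsum.x),
                 t.C[3 * u + 1] * (Re[u].y + t.beta * rsum.y),
                 t.C[3 * u + 2] * (Re[u].z + t.beta * rsum.z));
  }
}

}  // namespace

// ================================================================ exposed API

// [[Rcpp::export]]
List cpp_rpy_block(NumericVector dr, double ai, double ak, double Di, double Dk) {
  double out[9];
  rpy_block(Vec3(dr[0], dr[1], dr[2]), ai, ak, Di, Dk, out);
  NumericMatrix M(3, 3);
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) M(a, b) = out[3 * a + b];
  return List::create(_["block"] = M);
}

// [[Rcpp::export]]
List cpp_pair_vdw(NumericVector dr, double ai, double ak, double eps, double sigma,
                  double cutoff, bool attractive, double rlin) {
  Vec3 d(dr[0], dr[1], dr[2]);
  double r = d.norm();
  if (r < 1e-12) stop("vdW spheres at coincident centers");
  double s = r - ai - ak;
  double dU = 0, u = 0;
  if (s < cutoff) u = vdw_energy(s, eps, sigma, cutoff, attractive, rlin, &dU);
  Vec3 f = d * (s < cutoff ? -dU / r : 0.0);
  return List::create(_["energy"] = u,
                      _["force"] = NumericVector::create(f.x, f.y, f.z));
}

// [[Rcpp::export]]
List cpp_pair_es(NumericVector dr, double qi, double qk, double bi, double bk,
                 double kappa, double eps_r, double coulomb) {
  Vec3 d(dr[0], dr[1], dr[2]);
  double r = d.norm();
  if (r < 1e-12) stop("point charges at coincident positions");
  double dU;
  double u = es_energy(r, qi * qk, bi + bk, kappa, coulomb / eps_r, &dU);
  Vec3 f = d * (-dU / r);
  return List::create(_["energy"] = u,
                      _["force"] = NumericVector::create(f.x, f.y, f.z));
}

// [[Rcpp::export]]
List cpp_forces(List sysR, List cfgR) {
  System S = build_system(sysR);
  Config C = parse_config(cfgR);
  std::vector<int> act;
  for (int i = 0; i < S.n(); ++i) if (S.alive[i]) act.push_back(i);
  accumulate_forces(S, C, act);
  int n = S.n();
  NumericMatrix F(n, 3), T(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = S.F[i].x; F(i, 1) = S.F[i].y; F(i, 2) = S.F[i].z;
    T(i, 0) = S.T[i].x; T(i, 1) = S.T[i].y; T(i, 2) = S.T[i].z;
  }
  return List::create(_["force"] = F, _["torque"] = T,
                      _["energy"] = S.energy, _["n_int"] = (double)S.n_int);
}

// TEA coefficients for a set of hydrodynamic spheres (positions nh x 3).
// [[Rcpp::export]]
List cpp_tea_coefficients(NumericMatrix pos, NumericVector a, NumericVector D) {
  System S;
  int nh = pos.nrow();
  for (int i = 0; i < nh; ++i) {
    S.pos.push_back(Vec3(pos(i, 0), pos(i, 1), pos(i, 2)));
    S.alive.push_back(1);
    S.hy_idx.push_back(i);
    S.hy_a.push_back(a[i]); S.hy_D.push_back(D[i]);
  }
  std::vector<int> hyd(nh);
  for (int i = 0; i < nh; ++i) hyd[i] = i;
  TEA t;
  tea_compute(S, hyd, t);
  return List::create(_["epsilon"] = t.eps, _["beta"] = t.beta,
                      _["C"] = NumericVector(t.C.begin(), t.C.end()),
                      _["fallback"] = t.fallback);
}

// Apply TEA to deterministic forces (columns of F, nh x 3) and raw random
// displacements (raw, nh x 3); returns both transformed sets.
// [[Rcpp::export]]
List cpp_tea_apply(NumericMatrix pos, NumericVector a, NumericVector D,
                   NumericMatrix Fm, NumericMatrix raw) {
  System S;
  int nh = pos.nrow();
  for (int i = 0; i < nh; ++i) {
    S.pos.push_back(Vec3(pos(i, 0), pos(i, 1), pos(i, 2)));
    S.alive.push_back(1);
    S.hy_idx.push_back(i);
    S.hy_a.push_back(a[i]); S.hy_D.push_back(D[i]);
  }
  std::vector<int> hyd(nh);
  for (int i = 0; i < nh; ++i) hyd[i] = i;
  TEA t;
  tea_compute(S, hyd, t);
  std::vector<Vec3> F(nh), R(nh);
  for (int i = 0; i < nh; ++i) {
    F[i] = Vec3(Fm(i, 0), Fm(i, 1), Fm(i, 2));
    R[i] = Vec3(raw(i, 0), raw(i, 1), raw(i, 2));
  }
  tea_apply(S, hyd, t, F, R);
  NumericMatrix Fe(nh, 3), Re(nh, 3);
  for (int i = 0; i < nh; ++i) {
    Fe(i, 0) = F[i].x; Fe(i, 1) = F[i].y; Fe(i, 2) = F[i].z;
    Re(i, 0) = R[i].x; Re(i, 1) = R[i].y; Re(i, 2) = R[i].z;
  }
  return List::create(_["F_eff"] = Fe, _["R_corr"] = Re,
                      _["epsilon"] = t.eps, _["beta"] = t.beta);
}

// ------------------------------------------------------------------- full run

// [[Rcpp::export]]
List cpp_run(List sysR, List cfgR) {
  System S = build_system(sysR);
  Config C = parse_config(cfgR);
  RNGScope rngScope;

  std::vector<int> act;
  for (int i = 0; i < S.n(); ++i) if (S.alive[i]) act.push_back(i);
  bool act_dirty = false;

  // interface injection rates
  for (auto& I : S.ifaces) {
    int a1 = (I.axis + 1) % 3, a2 = (I.axis + 2) % 3;
    double A = S.L[a1] * S.L[a2];
    I.nu = I.rho * A * std::sqrt(I.Dtr * C.dt / M_PI);
  }

  // frame storage
  std::vector<double> fr_frame, fr_time, fr_prot, fr_spec, fr_gest;
  std::vector<double> fr_x, fr_y, fr_z, fr_qw, fr_qx, fr_qy, fr_qz;
  std::vector<double> fr_ex, fr_ey, fr_ez;     // end-to-end (com_ee mode)
  std::vector<double> sr_time, sr_np, sr_energy;
  std::vector<double> ev_time, ev_iface, ev_type;  // 0 absorb, 1 inject

  std::vector<Vec3> R(S.n());
  std::vector<int> hyd;
  TEA tea;
  long inserted = 0, removed = 0; double deferred = 0;
  int frame_no = 0;

  auto record_frame = [&](long step) {
    double tm = step * C.dt;
    if (C.record == 1) {
      for (int i : act) {
        fr_frame.push_back(frame_no); fr_time.push_back(tm);
        fr_prot.push_back(S.protein[i]); fr_spec.push_back(S.species[i]);
        fr_gest.push_back(i);
        fr_x.push_back(S.posu[i].x); fr_y.push_back(S.posu[i].y); fr_z.push_back(S.posu[i].z);
        fr_qw.push_back(S.quat[i].w); fr_qx.push_back(S.quat[i].x);
        fr_qy.push_back(S.quat[i].y); fr_qz.push_back(S.quat[i].z);
      }
    } else if (C.record == 2) {
      // per-protein center of mass + end-to-end vector (first to last gestalt)
      int i = 0, na = (int)act.size();
      while (i < na) {
        int p = S.protein[act[i]];
        Vec3 com; int cnt = 0; int first = act[i], last = act[i];
        int j = i;
        while (j < na && S.protein[act[j]] == p) {
          com += S.posu[act[j]]; ++cnt; last = act[j]; ++j;
        }
        com = com * (1.0 / cnt);
        Vec3 ee = S.posu[last] - S.posu[first];
        fr_frame.push_back(frame_no); fr_time.push_back(tm);
        fr_prot.push_back(p); fr_spec.push_back(S.species[first]);
        fr_gest.push_back(cnt);
        fr_x.push_back(com.x); fr_y.push_back(com.y); fr_z.push_back(com.z);
        fr_ex.push_back(ee.x); fr_ey.push_back(ee.y); fr_ez.push_back(ee.z);
        i = j;
      }
    }
    sr_time.push_back(tm); sr_np.push_back((double)act.size());
    sr_energy.push_back(S.energy);
    ++frame_no;
  };

  record_frame(0);

  for (long step = 0; step < C.steps; ++step) {
    if (act_dirty) {
      act.clear();
      for (int i = 0; i < S.n(); ++i) if (S.alive[i]) act.push_back(i);
      act_dirty = false;
    }

    accumulate_forces(S, C, act);

    // raw random displacements, deterministic draw order
    if ((int)R.size() < S.n()) R.resize(S.n());
    for (int i : act) {
      double sd = std::sqrt(2.0 * S.Dtr[i] * C.dt);
      R[i] = Vec3(norm_rand() * sd, norm_rand() * sd, norm_rand() * sd);
    }

    if (C.hi) {
      hyd.clear();
      for (int i : act) if (S.hy_idx[i] >= 0) hyd.push_back(i);
      if (hyd.size() >= 2) {
        if (step % C.tensor_stride == 0 || (int)hyd.size() != tea.nh)
          tea_compute(S, hyd, tea);
        tea_apply(S, hyd, tea, S.F, R);
      }
    }

    // propagate
    for (int i : act) {
      Vec3 dx;
      if (ISNA(S.mass[i]) || !(S.mass[i] > 0)) {
        dx = S.F[i] * (S.Dtr[i] * C.dt) + R[i];
      } else {
        double tau = S.mass[i] * S.Dtr[i] / C.kT;
        double e = std::exp(-C.dt / tau);
        // F/gamma including the effective random force gamma*R/dt
        Vec3 fg = S.F[i] * S.Dtr[i] + R[i] * (1.0 / C.dt);
        dx = fg * C.dt + (S.vel[i] - fg) * (tau * (1.0 - e));
        S.vel[i] = S.vel[i] * e + fg * (1.0 - e);
      }
      S.pos[i] += dx;
      S.posu[i] += dx;
      if (S.Drot[i] > 0) {
        double sr = std::sqrt(2.0 * S.Drot[i] * C.dt);
        Vec3 w = S.T[i] * (S.Drot[i] * C.dt) +
                 Vec3(norm_rand() * sr, norm_rand() * sr, norm_rand() * sr);
        S.quat[i] = qmul(quat_from_rotvec(w), S.quat[i]);
        qnormalize(S.quat[i]);
      }
      if (!std::isfinite(S.pos[i].x) || !std::isfinite(S.pos[i].y) ||
          !std::isfinite(S.pos[i].z)) {
        std::ostringstream msg;
        msg << "propagation diverged at step " << (step + 1)
            << ", gestalt " << (i + 1);
        stop(msg.str());
      }
    }

    // boundaries
    for (int ax = 0; ax < 3; ++ax) {
      if (S.mode[ax] == 0) continue;
      double Lx = S.L[ax];
      for (int i : act) {
        double* p = ax == 0 ? &S.pos[i].x : (ax == 1 ? &S.pos[i].y : &S.pos[i].z);
        if (S.mode[ax] == 1) {                       // periodic wrap
          *p -= Lx * std::floor(*p / Lx);
        } else if (S.mode[ax] == 2) {                // specular reflection
          double* pu = ax == 0 ? &S.posu[i].x : (ax == 1 ? &S.posu[i].y : &S.posu[i].z);
          double* v = ax == 0 ? &S.vel[i].x : (ax == 1 ? &S.vel[i].y : &S.vel[i].z);
          bool hit = false;
          double q = *p;
          while (q < 0 || q > Lx) {
            if (q < 0) q = -q; else q = 2 * Lx - q;
            hit = true;
          }
          if (hit) { *p = q; *pu = q; *v = -*v; }
        }
      }
    }

    // open interfaces: absorb crossers, then inject
    if (!S.ifaces.empty()) {
      double tm = (step + 1) * C.dt;
      for (int i : act) {
        if (!S.alive[i]) continue;
        for (int ax = 0; ax < 3; ++ax) {
          if (S.mode[ax] != 3) continue;
          double c = ax == 0 ? S.pos[i].x : (ax == 1 ? S.pos[i].y : S.pos[i].z);
          int crossed = c < 0 ? 0 : (c > S.L[ax] ? 1 : -1);
          if (crossed < 0) continue;
          // find matching interface for this species and side
          int match = -1;
          for (size_t f = 0; f < S.ifaces.size(); ++f)
            if (S.ifaces[f].axis == ax && S.ifaces[f].side == crossed &&
                S.ifaces[f].species == S.species[i]) { match = (int)f; break; }
          if (match >= 0) {
            S.alive[i] = 0; act_dirty = true; ++removed;
            S.ifaces[match].n_absorbed++;
            ev_time.push_back(tm); ev_iface.push_back(match + 1); ev_type.push_back(0);
          } else {                                  // non-listed species reflect
            double* p = ax == 0 ? &S.pos[i].x : (ax == 1 ? &S.pos[i].y : &S.pos[i].z);
            double* pu = ax == 0 ? &S.posu[i].x : (ax == 1 ? &S.posu[i].y : &S.posu[i].z);
            double* v = ax == 0 ? &S.vel[i].x : (ax == 1 ? &S.vel[i].y : &S.vel[i].z);
            double q = *p;
            while (q < 0 || q > S.L[ax]) { if (q < 0) q = -q; else q = 2 * S.L[ax] - q; }
            *p = q; *pu = q; *v = -*v;
          }
        }
      }
      for (size_t f = 0; f < S.ifaces.size(); ++f) {
        Interface& I = S.ifaces[f];
        if (I.rho <= 0) continue;
        int n_ins = (int)R::rpois(I.nu);
        n_ins += (int)I.pending; I.pending -= (int)I.pending;
        double sdt = std::sqrt(2.0 * I.Dtr * C.dt);
        int a1 = (I.axis + 1) % 3, a2 = (I.axis + 2) % 3;
        int budget = 128;   // per-step attempt budget: a geometrically
                            // blocked interface must not spin forever
        for (int m = 0; m < n_ins; ++m) {
          if (budget <= 0) { I.pending += n_ins - m; break; }
          bool placed = false;
          Vec3 npos;
          for (int attempt = 0; attempt < 32 && !placed && budget > 0;
               ++attempt, --budget) {
            double ray = sdt * std::sqrt(-2.0 * std::log(unif_rand()));
            double depth = ray * unif_rand();   // one-step crossing-depth profile
            double coord[3];
            coord[I.axis] = I.side == 0 ? depth : S.L[I.axis] - depth;
            coord[a1] = unif_rand() * S.L[a1];
            coord[a2] = unif_rand() * S.L[a2];
            npos = Vec3(coord[0], coord[1], coord[2]);
            placed = true;
            for (size_t b = 0; b < S.w_pos.size() && placed; ++b) {
              Vec3 d = S.minimg(npos - S.w_pos[b]);
              if (d.norm() < S.w_r[b] + I.max_rad) placed = false;
            }
            // also redraw on overlap with mobile particles: dropping a new
            // sphere inside an existing repulsive core would discharge the
            // (linearised) contact force as a violent unphysical kick
            for (size_t u = 0; u < S.pos.size() && placed; ++u) {
              if (!S.alive[u]) continue;
              for (int b : S.vdw_of[u]) {
                Vec3 sp = S.pos[u] + qrotate(S.quat[u], S.vdw_off[b]);
                for (size_t q = 0; q < I.voff.size(); ++q) {
                  Vec3 d = S.minimg((npos + I.voff[q]) - sp);
                  double srf = d.norm() - I.vrad[q] - S.vdw_r[b];
                  int t = S.ct.idx(I.vcol[q], S.vdw_col[b]);
                  double guard = S.ct.defined[t] ? S.ct.rlin[t] : 0.0;
                  if (srf < guard) { placed = false; break; }
                }
                if (!placed) break;
              }
            }
          }
          if (!placed) { I.pending += 1; continue; }
          // append new gestalt
          int gid = S.n();
          S.pos.push_back(npos); S.posu.push_back(npos);
          S.vel.push_back(Vec3()); S.quat.push_back(Quat());
          S.Dtr.push_back(I.Dtr); S.Drot.push_back(I.Drot); S.mass.push_back(I.mass);
          S.species.push_back(I.species);
          S.protein.push_back(gid + 1000000);   // unique instance ids for injected
          S.alive.push_back(1);
          S.vdw_of.push_back(std::vector<int>());
          S.ch_of.push_back(std::vector<int>());
          S.re_of.push_back(std::vector<int>());
          for (size_t q = 0; q < I.voff.size(); ++q) {
            S.vdw_of[gid].push_back((int)S.vdw_off.size());
            S.vdw_off.push_back(I.voff[q]); S.vdw_r.push_back(I.vrad[q]);
            S.vdw_col.push_back(I.vcol[q]);
          }
          if (I.has_hydro) {
            S.hy_idx.push_back((int)S.hy_a.size());
            S.hy_a.push_back(I.hy_a); S.hy_D.push_back(I.hy_D);
          } else S.hy_idx.push_back(-1);
          S.F.push_back(Vec3()); S.T.push_back(Vec3());
          act_dirty = true; ++inserted;
          I.n_injected++;
          ev_time.push_back(tm); ev_iface.push_back(f + 1); ev_type.push_back(1);
        }
      }
      if (act_dirty) {
        act.clear();
        for (int i = 0; i < S.n(); ++i) if (S.alive[i]) act.push_back(i);
        act_dirty = false;
      }
    }

    if ((step + 1) % C.stride == 0) record_frame(step + 1);
    if ((step & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  // final state
  int n = S.n();
  NumericMatrix pos(n, 3), posu(n, 3), quat(n, 4), vel(n, 3);
  IntegerVector spec(n), prot(n); LogicalVector alive(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = S.pos[i].x; pos(i, 1) = S.pos[i].y; pos(i, 2) = S.pos[i].z;
    posu(i, 0) = S.posu[i].x; posu(i, 1) = S.posu[i].y; posu(i, 2) = S.posu[i].z;
    vel(i, 0) = S.vel[i].x; vel(i, 1) = S.vel[i].y; vel(i, 2) = S.vel[i].z;
    quat(i, 0) = S.quat[i].w; quat(i, 1) = S.quat[i].x;
    quat(i, 2) = S.quat[i].y; quat(i, 3) = S.quat[i].z;
    spec[i] = S.species[i]; prot[i] = S.protein[i]; alive[i] = S.alive[i] != 0;
  }
  List frames;
  if (C.record == 2) {
    frames = List::create(
      _["frame"] = fr_frame, _["time_ps"] = fr_time, _["protein"] = fr_prot,
      _["species"] = fr_spec, _["n_gestalts"] = fr_gest,
      _["x"] = fr_x, _["y"] = fr_y, _["z"] = fr_z,
      _["ex"] = fr_ex, _["ey"] = fr_ey, _["ez"] = fr_ez);
  } else {
    frames = List::create(
      _["frame"] = fr_frame, _["time_ps"] = fr_time, _["protein"] = fr_prot,
      _["species"] = fr_spec, _["gestalt"] = fr_gest,
      _["x"] = fr_x, _["y"] = fr_y, _["z"] = fr_z,
      _["qw"] = fr_qw, _["qx"] = fr_qx, _["qy"] = fr_qy, _["qz"] = fr_qz);
  }
  return List::create(
    _["frames"] = frames,
    _["series"] = List::create(_["time_ps"] = sr_time, _["n_p"] = sr_np,
                               _["energy_kT"] = sr_energy),
    _["events"] = List::create(_["time_ps"] = ev_time, _["interface"] = ev_iface,
                               _["type"] = ev_type),
    _["state"] = List::create(_["pos"] = pos, _["pos_unwrapped"] = posu,
                              _["quat"] = quat, _["vel"] = vel,
                              _["species"] = spec, _["protein"] = prot,
                              _["alive"] = alive),
    _["counters"] = List::create(_["inserted"] = (double)inserted,
                                 _["removed"] = (double)removed,
                                 _["n_int"] = (double)S.n_int),
    _["tea"] = List::create(_["epsilon"] = tea.eps, _["beta"] = tea.beta));
}
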