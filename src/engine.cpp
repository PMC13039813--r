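// Overdamped Langevin engine for actin filaments and crosslinkers confined
// in a deformable ellipsoidal droplet.  Single time-stepping implementation
// shared by simulate_droplet() and step_boundary(); R-level module functions
// mirror the individual force terms and are cross-checked in the test suite.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------- utilities

// Thermal-noise generator: xoshiro256++ with Box-Muller pairs.  The state is
// (re)seeded from R's RNG stream at the start of every engine call, so a
// trajectory remains a pure function of (configuration, seed) while the
// half-billion normal draws of a long run avoid R's inversion sampler.
struct NoiseRng {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_r() {
    // splitmix64 expansion of two draws from R's stream
    uint64_t seed = (uint64_t)(unif_rand() * 9007199254740992.0) ^
                    ((uint64_t)(unif_rand() * 9007199254740992.0) << 11);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    have_spare = false;
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double uniform() { return (next() >> 11) * 1.1102230246251565e-16; }
  bool have_spare = false;
  double spare = 0.0;
  double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = uniform(); } while (u1 <= 0.0);
    u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};
static NoiseRng g_noise;

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

// Gauss-Legendre nodes/weights on [-1,1] via Newton on P_n (standard).
static void gauss_legendre(int n, std::vector<double> &x, std::vector<double> &w) {
  x.resize(n); w.resize(n);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1 = 2.0, pp = 0.0;
    while (std::fabs(z - z1) > 1e-15) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z; z = z1 - p1 / pp;
    }
    x[i] = -z; x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp); w[n - 1 - i] = w[i];
  }
}

// Ellipsoid surface area gradient dA/da_i (and area) by quadrature over the
// first octant of the standard parametrization.
static void area_and_grad(const double ax[3], double &area, double grad[3],
                          int n = 20) {
  static std::unordered_map<int, std::pair<std::vector<double>,
                                           std::vector<double>>> cache;
  auto &nodes = cache[n];
  if ((int)nodes.first.size() != n)
    gauss_legendre(n, nodes.first, nodes.second);
  const std::vector<double> &gx = nodes.first, &gw = nodes.second;
  double a = ax[0], b = ax[1], c = ax[2];
  area = 0.0; grad[0] = grad[1] = grad[2] = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = (gx[i] + 1.0) * M_PI / 4.0, wt = gw[i] * M_PI / 4.0;
    double st = std::sin(t), ct = std::cos(t);
    double st2 = st * st, ct2 = ct * ct;
    for (int j = 0; j < n; ++j) {
      double p = (gx[j] + 1.0) * M_PI / 4.0, wp = gw[j] * M_PI / 4.0;
      double sp = std::sin(p), cp = std::cos(p);
      double s2c2 = st2 * cp * cp, s2s2 = st2 * sp * sp;
      double q = b*b*c*c*s2c2 + a*a*c*c*s2s2 + a*a*b*b*ct2;
      double r = std::sqrt(q), W = wt * wp * st;
      area += 8.0 * W * r;
      grad[0] += 8.0 * W * (a * (c*c*s2s2 + b*b*ct2)) / r;
      grad[1] += 8.0 * W * (b * (c*c*s2c2 + a*a*ct2)) / r;
      grad[2] += 8.0 * W * (c * (b*b*s2c2 + a*a*s2s2)) / r;
    }
  }
}

// Closest point on the ellipsoid surface (Lagrange multiplier solve).
// g(l) = sum a_i^2 p_i^2 / (a_i^2 + l)^2 - 1 is decreasing and convex on
// (-min a_i^2, inf), so Newton from any point left of the root converges
// monotonically; a bisection safeguard covers the rare overshoot.
static Vec3 project_ellipsoid(const Vec3 &p, const double ax[3]) {
  double a2[3] = {ax[0]*ax[0], ax[1]*ax[1], ax[2]*ax[2]};
  double pc[3] = {p.x, p.y, p.z};
  double lo = 1e300;
  bool any = false;
  for (int i = 0; i < 3; ++i) if (pc[i] != 0.0) { lo = std::min(lo, a2[i]); any = true; }
  if (!any) { // exact center: shortest axis, smallest index tie-break
    int k = 0;
    for (int i = 1; i < 3; ++i) if (ax[i] < ax[k]) k = i;
    Vec3 s = {0, 0, 0};
    if (k == 0) s.x = ax[0]; else if (k == 1) s.y = ax[1]; else s.z = ax[2];
    return s;
  }
  lo = -lo;
  double lob = lo, hi = 0.0;
  bool have_hi = false;
  double l = 0.0;
  for (int it = 0; it < 100; ++it) {
    double gv = -1.0, dg = 0.0;
    for (int i = 0; i < 3; ++i) if (pc[i] != 0.0) {
      double d = a2[i] + l;
      double q = a2[i] * pc[i] * pc[i] / (d * d);
      gv += q;
      dg += -2.0 * q / d;
    }
    if (std::fabs(gv) < 1e-12) break;
    if (gv > 0.0) { if (l > lob) lob = l; }
    else { if (!have_hi || l < hi) { hi = l; have_hi = true; } }
    double ln = l - gv / dg;
    if (std::isfinite(ln) && ln > lob && (!have_hi || ln < hi))
      l = ln;
    else if (have_hi)
      l = 0.5 * (lob + hi);
    else
      l = 0.5 * (lob + l);
  }
  Vec3 s;
  s.x = (pc[0] != 0.0) ? a2[0] * pc[0] / (a2[0] + l) : 0.0;
  s.y = (pc[1] != 0.0) ? a2[1] * pc[1] / (a2[1] + l) : 0.0;
  s.z = (pc[2] != 0.0) ? a2[2] * pc[2] / (a2[2] + l) : 0.0;
  return s;
}

// One explicit axis update with pressure solved so volume is conserved.
// Gload[i] already holds sum(f_i * x_i/a_i) over boundary point loads; it is
// expressed in normalized surface coordinates so it is constant under
// sub-stepping.  Returns number of sub-steps used.
// advance the axes by one explicit sub-step of length h
static void boundary_substep(double trial[3], const double Gload[3], double h,
                             double sigma, double mu, double V0) {
  const double c43 = 4.0 * M_PI / 3.0;
  double area, dA[3];
  area_and_grad(trial, area, dA);
  double dV[3], G0[3];
  double vol = c43 * trial[0] * trial[1] * trial[2];
  for (int i = 0; i < 3; ++i) {
    dV[i] = vol / trial[i];
    G0[i] = Gload[i] - sigma * dA[i];
  }
  // Newton on P: (4pi/3) prod(a_i + h/mu (G0_i + P dV_i)) = V0
  double P = sigma * (dA[0] + dA[1] + dA[2]) / (dV[0] + dV[1] + dV[2]);
  for (int it = 0; it < 100; ++it) {
    double na[3], prod = c43;
    for (int i = 0; i < 3; ++i) {
      na[i] = trial[i] + h / mu * (G0[i] + P * dV[i]);
      if (na[i] < 1e-6) na[i] = 1e-6;
      prod *= na[i];
    }
    double res = prod - V0;
    if (std::fabs(res) < 1e-10 * V0) {
      for (int i = 0; i < 3; ++i) trial[i] = na[i];
      return;
    }
    double dres = 0.0;
    for (int i = 0; i < 3; ++i) dres += prod / na[i] * h / mu * dV[i];
    P -= res / dres;
  }
  stop("boundary volume solve did not converge in 100 iterations");
}

static int boundary_step_core(double ax[3], const double Gload[3], double dt,
                              double sigma, double mu, double V0) {
  // explicit stability: the tension+pressure restoring rate on a near-sphere
  // is ~ sigma * (8 pi / 3) / mu per axis; sub-divide so rate * h <= 0.5
  double rate = sigma * (8.0 * M_PI / 3.0) / mu;
  int nsub = std::max(1, (int)std::ceil(2.0 * rate * dt));
  for (;;) {
    double trial[3] = {ax[0], ax[1], ax[2]};
    double h = dt / nsub;
    double worst = 0.0;
    for (int s = 0; s < nsub; ++s) {
      double prev[3] = {trial[0], trial[1], trial[2]};
      boundary_substep(trial, Gload, h, sigma, mu, V0);
      for (int i = 0; i < 3; ++i)
        worst = std::max(worst, std::fabs(trial[i] - prev[i]) / prev[i]);
    }
    if (worst <= 0.1 || nsub >= 1024) {
      for (int i = 0; i < 3; ++i) ax[i] = trial[i];
      return nsub;
    }
    nsub *= 2;
  }
}

// [[Rcpp::export]]
List cpp_step_boundary(NumericVector semi_axes, NumericMatrix loads, double dt,
                       double sigma, double mu, double V0) {
  double ax[3] = {semi_axes[0], semi_axes[1], semi_axes[2]};
  double G[3] = {0, 0, 0};
  for (int r = 0; r < loads.nrow(); ++r) {
    double f[3] = {loads(r, 3), loads(r, 4), loads(r, 5)};
    for (int i = 0; i < 3; ++i) G[i] += f[i] * (loads(r, i) / ax[i]);
  }
  int nsub = boundary_step_core(ax, G, dt, sigma, mu, V0);
  return List::create(_["semi_axes"] = NumericVector::create(ax[0], ax[1], ax[2]),
                      _["substeps"] = nsub);
}

// [[Rcpp::export]]
List cpp_ellipsoid_area(NumericVector semi_axes, int n = 48) {
  double ax[3] = {semi_axes[0], semi_axes[1], semi_axes[2]};
  double area, grad[3];
  area_and_grad(ax, area, grad, n);
  return List::create(_["area"] = area,
                      _["grad"] = NumericVector::create(grad[0], grad[1], grad[2]));
}

// ------------------------------------------------------------- system state

struct Fil {
  std::vector<Vec3> v;
  double partial;
  bool capped;
};

struct ALink { int fil; double s; };   // actin link: filament index, abscissa

struct Params {
  double dt, L_seg, k_grow, k_bend, k_cap, k_uncap;
  double k_bind, k_unbind, F0, k_form, k_split, bind_dist, k_link;
  double steric_k, linker_radius, kBT, eta;
  double sigma, mu_eff, V0, conf_k;
  bool rigid;
  int mode; // 0 none, 1 tetramer, 2 monomer
};

// sparse uniform grid keyed on cell indices
struct Grid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> cells;
  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) | ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  }
  void build(const std::vector<Vec3> &pts, double cell_) {
    cell = cell_;
    cells.clear();
    for (size_t i = 0; i < pts.size(); ++i) {
      int ix = (int)std::floor(pts[i].x / cell);
      int iy = (int)std::floor(pts[i].y / cell);
      int iz = (int)std::floor(pts[i].z / cell);
      cells[key(ix, iy, iz)].push_back((int)i);
    }
  }
  template <class F> void query(const Vec3 &p, F fn) const {
    int ix = (int)std::floor(p.x / cell);
    int iy = (int)std::floor(p.y / cell);
    int iz = (int)std::floor(p.z / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int idx : it->second) fn(idx);
        }
  }
};

struct System {
  std::vector<Fil> fils;
  std::vector<Vec3> lpos;
  std::vector<std::vector<ALink>> alinks;  // per linker
  std::vector<std::vector<int>> plinks;    // partner indices (0-based)
  double ax[3];
};

static double fil_length(const Fil &f, double L_seg) {
  return ((double)f.v.size() - 2.0) * L_seg + f.partial;
}

static void fil_point(const Fil &f, double L_seg, double s, Vec3 &pt,
                      int &seg, double &w) {
  int n = (int)f.v.size();
  double total = fil_length(f, L_seg);
  if (s < 0) s = 0;
  if (s > total) s = total;
  seg = (int)std::floor(s / L_seg);
  if (seg > n - 2) seg = n - 2;
  double s0 = seg * L_seg;
  double slen = (seg == n - 2) ? f.partial : L_seg;
  w = (slen > 0) ? (s - s0) / slen : 0.0;
  if (w > 1.0) w = 1.0;
  pt.x = f.v[seg].x + (f.v[seg + 1].x - f.v[seg].x) * w;
  pt.y = f.v[seg].y + (f.v[seg + 1].y - f.v[seg].y) * w;
  pt.z = f.v[seg].z + (f.v[seg + 1].z - f.v[seg].z) * w;
}

// nearest point on segment [a,b] to p; returns squared distance, sets t
static double seg_dist2(const Vec3 &p, const Vec3 &a, const Vec3 &b, double &t) {
  Vec3 d = vsub(b, a), ap = vsub(p, a);
  double dd = vdot(d, d);
  t = dd > 0 ? vdot(ap, d) / dd : 0.0;
  if (t < 0) t = 0; if (t > 1) t = 1;
  Vec3 q = {a.x + t * d.x - p.x, a.y + t * d.y - p.y, a.z + t * d.z - p.z};
  return vdot(q, q);
}

// --------------------------------------------------------------- mechanics

static void add_bending_forces(const Fil &f, const Params &P,
                               std::vector<Vec3> &F) {
  int n = (int)f.v.size();
  if (n < 3) return;
  double kfull = P.k_bend / P.L_seg;
  // the hinge flanking the partial plus-end segment is ramped in
  // quadratically as that segment fills: the hinge's displacement stiffness
  // scales as w / partial^2, so w = (partial/L_seg)^2 keeps it bounded and
  // the explicit integration stable while new vertices appear during growth
  double wtip = (f.partial / P.L_seg) * (f.partial / P.L_seg);
  if (wtip > 1) wtip = 1;
  for (int h = 1; h < n - 1; ++h) {
    double k = (h == n - 2) ? kfull * wtip : kfull;
    if (k == 0) continue;
    Vec3 a = vsub(f.v[h], f.v[h - 1]);
    Vec3 b = vsub(f.v[h + 1], f.v[h]);
    double la = vnorm(a), lb = vnorm(b);
    if (la == 0 || lb == 0) stop("coincident filament vertices");
    double ct = vdot(a, b) / (la * lb);
    double ilab = 1.0 / (la * lb);
    Vec3 dca = {b.x * ilab - ct * a.x / (la * la),
                b.y * ilab - ct * a.y / (la * la),
                b.z * ilab - ct * a.z / (la * la)};
    Vec3 dcb = {a.x * ilab - ct * b.x / (lb * lb),
                a.y * ilab - ct * b.y / (lb * lb),
                a.z * ilab - ct * b.z / (lb * lb)};
    F[h - 1].x -= k * dca.x; F[h - 1].y -= k * dca.y; F[h - 1].z -= k * dca.z;
    F[h].x += k * (dca.x - dcb.x); F[h].y += k * (dca.y - dcb.y);
    F[h].z += k * (dca.z - dcb.z);
    F[h + 1].x += k * dcb.x; F[h + 1].y += k * dcb.y; F[h + 1].z += k * dcb.z;
  }
}

static void shake_project(Fil &f, double L_seg) {
  // Newton iteration on the segment-length constraints: for a chain the
  // constraint Gram matrix is tridiagonal, so each iteration is O(n)
  // (Thomas solve); convergence is quadratic for the small violations a
  // Langevin sub-step produces
  int n = (int)f.v.size();
  int m = n - 1;
  if (m < 1) return;
  static std::vector<Vec3> u;
  static std::vector<double> len, r, diag, off, lam;
  u.resize(m); len.resize(m); r.resize(m); diag.resize(m); off.resize(m);
  lam.resize(m);
  for (int iter = 0; iter < 100; ++iter) {
    double worst = 0.0;
    for (int j = 0; j < m; ++j) {
      Vec3 d = vsub(f.v[j + 1], f.v[j]);
      len[j] = vnorm(d);
      if (len[j] == 0) stop("coincident vertices in constraint projection");
      u[j] = {d.x / len[j], d.y / len[j], d.z / len[j]};
      double tgt = (j == m - 1) ? f.partial : L_seg;
      r[j] = len[j] - tgt;
      if (std::fabs(r[j]) > worst) worst = std::fabs(r[j]);
    }
    if (worst < 1e-7) return;
    // solve (J J^T) lam = -r with (JJ^T)_jj = 2, (JJ^T)_{j,j+1} = -u_j.u_{j+1}
    for (int j = 0; j < m; ++j) {
      diag[j] = 2.0;
      if (j < m - 1) off[j] = -vdot(u[j], u[j + 1]);
      lam[j] = -r[j];
    }
    for (int j = 1; j < m; ++j) {            // Thomas forward sweep
      double w = off[j - 1] / diag[j - 1];
      diag[j] -= w * off[j - 1];
      lam[j] -= w * lam[j - 1];
    }
    lam[m - 1] /= diag[m - 1];
    for (int j = m - 2; j >= 0; --j)
      lam[j] = (lam[j] - off[j] * lam[j + 1]) / diag[j];
    // dx = J^T lam: vertex j gets -u_j lam_j + u_{j-1} lam_{j-1}
    for (int j = 0; j < n; ++j) {
      Vec3 dx = {0, 0, 0};
      if (j < m) {
        dx.x -= u[j].x * lam[j]; dx.y -= u[j].y * lam[j];
        dx.z -= u[j].z * lam[j];
      }
      if (j > 0) {
        dx.x += u[j - 1].x * lam[j - 1]; dx.y += u[j - 1].y * lam[j - 1];
        dx.z += u[j - 1].z * lam[j - 1];
      }
      f.v[j].x += dx.x; f.v[j].y += dx.y; f.v[j].z += dx.z;
    }
  }
  stop("inextensibility projection did not converge");
}

static void grow_fil(Fil &f, const Params &P) {
  if (f.capped || P.k_grow <= 0) return;
  int n = (int)f.v.size();
  Vec3 d = vsub(f.v[n - 1], f.v[n - 2]);
  double nd = vnorm(d);
  if (nd > 0) { d.x /= nd; d.y /= nd; d.z /= nd; } else d = {1, 0, 0};
  double remaining = f.partial + P.k_grow * P.dt;
  Vec3 base = f.v[n - 2];
  f.v.pop_back();
  while (remaining > P.L_seg + 1e-12) {
    base.x += d.x * P.L_seg; base.y += d.y * P.L_seg; base.z += d.z * P.L_seg;
    f.v.push_back(base);
    remaining -= P.L_seg;
  }
  f.v.push_back({base.x + d.x * remaining, base.y + d.y * remaining,
                 base.z + d.z * remaining});
  f.partial = remaining;
}

// ------------------------------------------------------------ main stepper

struct StepWork {
  std::vector<Vec3> vpts;          // all filament vertices flattened
  std::vector<int> vfil, vidx;     // owner filament / vertex index
  Grid grid;                       // over filament vertices
  Grid lgrid;                      // over linker centers (monomer mode)
  std::vector<int> seg_base;       // global segment index offset per filament
  std::vector<int> seg_stamp;      // de-duplication stamps, one per segment
  int epoch = 0;
  struct StericPair { int linker, fil, seg; };
  std::vector<StericPair> steric_pairs;  // cached contacts, one outer step
};

// visit each distinct segment with a vertex in the 27-cell neighbourhood of
// p exactly once (stamp-based de-duplication)
template <class F>
static void for_segments_near(const System &S, StepWork &W, const Vec3 &p,
                              F fn) {
  ++W.epoch;
  W.grid.query(p, [&](int vi) {
    int fi = W.vfil[vi], idx = W.vidx[vi];
    int n = (int)S.fils[fi].v.size();
    for (int s0 = idx - 1; s0 <= idx; ++s0) {
      if (s0 < 0 || s0 > n - 2) continue;
      int key = W.seg_base[fi] + s0;
      if (W.seg_stamp[key] == W.epoch) continue;
      W.seg_stamp[key] = W.epoch;
      fn(fi, s0);
    }
  });
}

static void kinetics_step(System &S, const Params &P, StepWork &W) {
  int nf = (int)S.fils.size(), nl = (int)S.lpos.size();
  if (nl == 0 || P.mode == 0) return;
  int cap = (P.mode == 1) ? 4 : 1;
  double reach = P.bind_dist + 0.5 * P.L_seg;
  (void)reach;
  // unbinding (Bell) for actin links
  for (int i = 0; i < nl; ++i) {
    auto &links = S.alinks[i];
    for (size_t r = 0; r < links.size();) {
      const Fil &f = S.fils[links[r].fil];
      if (links[r].s > fil_length(f, P.L_seg) + 1e-9) { // dangling
        links.erase(links.begin() + r);
        continue;
      }
      Vec3 pt; int seg; double w;
      fil_point(f, P.L_seg, links[r].s, pt, seg, w);
      double tension = P.k_link * vnorm(vsub(pt, S.lpos[i]));
      double koff = P.k_unbind * std::exp(tension / P.F0);
      if (koff > 0 && unif_rand() < 1.0 - std::exp(-koff * P.dt))
        links.erase(links.begin() + r);
      else
        ++r;
    }
  }
  // binding: candidates are nearest segment points within bind_dist
  if (P.k_bind > 0 && nf > 0) {
    std::vector<int> stamp((size_t)0);
    std::vector<std::pair<int,int>> segs;   // (fil, seg index)
    std::vector<double> segt;
    // a linker can only bind if its uniform draw undercuts the binding
    // probability at the (generous) candidate-count bound, so the grid
    // search is skipped for the overwhelming majority of draws at low
    // k_bind; the decision distribution is unchanged for n <= 128
    const double p_bound = 1.0 - std::exp(-P.k_bind * 128.0 * P.dt);
    for (int i = 0; i < nl; ++i) {
      if ((int)S.alinks[i].size() >= cap) continue;
      double u = unif_rand();
      if (u >= p_bound) continue;
      segs.clear(); segt.clear();
      const Vec3 &c = S.lpos[i];
      for_segments_near(S, W, c, [&](int fi, int s0) {
        double t;
        double d2 = seg_dist2(c, S.fils[fi].v[s0], S.fils[fi].v[s0 + 1], t);
        if (d2 <= P.bind_dist * P.bind_dist) {
          segs.push_back({fi, s0});
          segt.push_back(t);
        }
      });
      int ncand = (int)segs.size();
      if (ncand == 0) continue;
      // P(at least one binding event in dt) = 1 - exp(-k_bind * n * dt),
      // exact for any dt; on success one candidate is chosen uniformly
      double rate = P.k_bind * ncand;
      if (u < 1.0 - std::exp(-rate * P.dt)) {
        int pick = (int)std::floor(unif_rand() * ncand);
        if (pick >= ncand) pick = ncand - 1;
        int fi = segs[pick].first, s0 = segs[pick].second;
        double slen = (s0 == (int)S.fils[fi].v.size() - 2)
                        ? S.fils[fi].partial : P.L_seg;
        S.alinks[i].push_back({fi, s0 * P.L_seg + segt[pick] * slen});
      }
    }
  }
  // multimer events (monomer mode)
  if (P.mode == 2) {
    // splitting with Bell law
    if (P.k_split > 0) {
      for (int i = 0; i < nl; ++i) {
        auto &pl = S.plinks[i];
        for (size_t r = 0; r < pl.size();) {
          int j = pl[r];
          if (j < i) { ++r; continue; }    // each bond tested once
          double tension = P.k_link * vnorm(vsub(S.lpos[j], S.lpos[i]));
          double koff = P.k_split * std::exp(tension / P.F0);
          if (unif_rand() < 1.0 - std::exp(-koff * P.dt)) {
            pl.erase(pl.begin() + r);
            auto &plj = S.plinks[j];
            for (size_t q = 0; q < plj.size(); ++q)
              if (plj[q] == i) { plj.erase(plj.begin() + q); break; }
          } else ++r;
        }
      }
    }
    if (P.k_form > 0) {
      W.lgrid.build(S.lpos, std::max(P.bind_dist, 1e-3));
      for (int i = 0; i < nl; ++i) {
        if ((int)S.plinks[i].size() >= 2) continue;
        const Vec3 &c = S.lpos[i];
        std::vector<int> cand;
        W.lgrid.query(c, [&](int j) {
          if (j == i) return;
          Vec3 d = vsub(S.lpos[j], c);
          if (vdot(d, d) <= P.bind_dist * P.bind_dist) cand.push_back(j);
        });
        for (int j : cand) {
          if ((int)S.plinks[i].size() >= 2) break;
          if ((int)S.plinks[j].size() >= 2) continue;
          bool dup = false;
          for (int q : S.plinks[i]) if (q == j) { dup = true; break; }
          if (dup) continue;
          if (j < i) continue;   // examine each unordered pair once
          // reject cycle closure: walk the chain from i
          bool cycle = false;
          {
            int prev = -1, cur = i;
            while (true) {
              int nxt = -1;
              for (int q : S.plinks[cur]) if (q != prev) { nxt = q; break; }
              if (nxt < 0) break;
              if (nxt == j) { cycle = true; break; }
              prev = cur; cur = nxt;
            }
          }
          if (cycle) continue;
          if (unif_rand() < 1.0 - std::exp(-P.k_form * P.dt)) {
            S.plinks[i].push_back(j);
            S.plinks[j].push_back(i);
          }
        }
      }
    }
  }
}

// accumulate all forces; returns boundary generalized load vector
static void compute_forces(const System &S, const Params &P, StepWork &W,
                           std::vector<std::vector<Vec3>> &Ff,
                           std::vector<Vec3> &Fl, double Gload[3]) {
  int nf = (int)S.fils.size(), nl = (int)S.lpos.size();
  Gload[0] = Gload[1] = Gload[2] = 0.0;
  for (int fi = 0; fi < nf; ++fi) {
    Ff[fi].assign(S.fils[fi].v.size(), {0, 0, 0});
    add_bending_forces(S.fils[fi], P, Ff[fi]);
  }
  Fl.assign(nl, {0, 0, 0});
  // link forces
  for (int i = 0; i < nl; ++i) {
    for (const ALink &al : S.alinks[i]) {
      const Fil &f = S.fils[al.fil];
      Vec3 pt; int seg; double w;
      fil_point(f, P.L_seg, al.s, pt, seg, w);
      Vec3 d = vsub(pt, S.lpos[i]);
      Vec3 fr = {P.k_link * d.x, P.k_link * d.y, P.k_link * d.z};
      Fl[i].x += fr.x; Fl[i].y += fr.y; Fl[i].z += fr.z;
      Ff[al.fil][seg].x -= fr.x * (1 - w);
      Ff[al.fil][seg].y -= fr.y * (1 - w);
      Ff[al.fil][seg].z -= fr.z * (1 - w);
      Ff[al.fil][seg + 1].x -= fr.x * w;
      Ff[al.fil][seg + 1].y -= fr.y * w;
      Ff[al.fil][seg + 1].z -= fr.z * w;
    }
    for (int j : S.plinks[i]) {
      if (j <= i) continue;
      Vec3 d = vsub(S.lpos[j], S.lpos[i]);
      Fl[i].x += P.k_link * d.x; Fl[i].y += P.k_link * d.y; Fl[i].z += P.k_link * d.z;
      Fl[j].x -= P.k_link * d.x; Fl[j].y -= P.k_link * d.y; Fl[j].z -= P.k_link * d.z;
    }
  }
  // steric repulsion linker <-> filament over the cached contact pairs
  if (P.steric_k > 0) {
    for (const StepWork::StericPair &sp : W.steric_pairs) {
      const Vec3 &c = S.lpos[sp.linker];
      int fi = sp.fil, s0 = sp.seg;
      double t;
      double d2 = seg_dist2(c, S.fils[fi].v[s0], S.fils[fi].v[s0 + 1], t);
      if (d2 < P.linker_radius * P.linker_radius && d2 > 1e-20) {
        double d = std::sqrt(d2);
        Vec3 q = {c.x - (S.fils[fi].v[s0].x + t * (S.fils[fi].v[s0+1].x - S.fils[fi].v[s0].x)),
                  c.y - (S.fils[fi].v[s0].y + t * (S.fils[fi].v[s0+1].y - S.fils[fi].v[s0].y)),
                  c.z - (S.fils[fi].v[s0].z + t * (S.fils[fi].v[s0+1].z - S.fils[fi].v[s0].z))};
        double mag = P.steric_k * (P.linker_radius - d) / d;
        Vec3 fr = {mag * q.x, mag * q.y, mag * q.z};
        Fl[sp.linker].x += fr.x; Fl[sp.linker].y += fr.y; Fl[sp.linker].z += fr.z;
        Ff[fi][s0].x -= fr.x * (1 - t); Ff[fi][s0].y -= fr.y * (1 - t);
        Ff[fi][s0].z -= fr.z * (1 - t);
        Ff[fi][s0 + 1].x -= fr.x * t; Ff[fi][s0 + 1].y -= fr.y * t;
        Ff[fi][s0 + 1].z -= fr.z * t;
      }
    }
  }
  // confinement (and boundary reaction loads)
  auto confine = [&](const Vec3 &p, Vec3 &F) {
    double s = (p.x / S.ax[0]) * (p.x / S.ax[0]) +
               (p.y / S.ax[1]) * (p.y / S.ax[1]) +
               (p.z / S.ax[2]) * (p.z / S.ax[2]);
    if (s <= 1.0) return;
    Vec3 sp = project_ellipsoid(p, S.ax);
    Vec3 f = {P.conf_k * (sp.x - p.x), P.conf_k * (sp.y - p.y),
              P.conf_k * (sp.z - p.z)};
    F.x += f.x; F.y += f.y; F.z += f.z;
    // reaction -f applied at sp, projected on axes in normalized coords
    Gload[0] += -f.x * (sp.x / S.ax[0]);
    Gload[1] += -f.y * (sp.y / S.ax[1]);
    Gload[2] += -f.z * (sp.z / S.ax[2]);
  };
  for (int fi = 0; fi < nf; ++fi)
    for (size_t k = 0; k < S.fils[fi].v.size(); ++k)
      confine(S.fils[fi].v[k], Ff[fi][k]);
  for (int i = 0; i < nl; ++i) confine(S.lpos[i], Fl[i]);
}

static void build_vertex_grid(const System &S, const Params &P, StepWork &W) {
  W.vpts.clear(); W.vfil.clear(); W.vidx.clear();
  W.seg_base.assign(S.fils.size(), 0);
  int nseg = 0;
  for (size_t fi = 0; fi < S.fils.size(); ++fi) {
    W.seg_base[fi] = nseg;
    nseg += std::max((int)S.fils[fi].v.size() - 1, 0);
    for (size_t k = 0; k < S.fils[fi].v.size(); ++k) {
      W.vpts.push_back(S.fils[fi].v[k]);
      W.vfil.push_back((int)fi);
      W.vidx.push_back((int)k);
    }
  }
  W.seg_stamp.assign(nseg, 0);
  W.epoch = 0;
  double cell = std::max(P.bind_dist, P.linker_radius) + 0.5 * P.L_seg;
  W.grid.build(W.vpts, cell);
}

// cache linker-filament contacts for the current outer step; the margin
// absorbs motion during the mechanics sub-steps
static void build_steric_pairs(const System &S, const Params &P, StepWork &W) {
  W.steric_pairs.clear();
  if (P.steric_k <= 0 || S.lpos.empty() || S.fils.empty()) return;
  double reach = P.linker_radius + 0.05;
  for (int i = 0; i < (int)S.lpos.size(); ++i) {
    const Vec3 &c = S.lpos[i];
    for_segments_near(S, W, c, [&](int fi, int s0) {
      double t;
      double d2 = seg_dist2(c, S.fils[fi].v[s0], S.fils[fi].v[s0 + 1], t);
      if (d2 < reach * reach) W.steric_pairs.push_back({i, fi, s0});
    });
  }
}

static void one_step(System &S, const Params &P, StepWork &W,
                     std::vector<std::vector<Vec3>> &Ff, std::vector<Vec3> &Fl) {
  int nf = (int)S.fils.size(), nl = (int)S.lpos.size();
  // 1. growth
  for (auto &f : S.fils) grow_fil(f, P);
  // 2. capping
  if (P.k_cap > 0 || P.k_uncap > 0) {
    double kmax = std::max(P.k_cap, P.k_uncap);
    int nsub = std::max(1, (int)std::ceil(kmax * P.dt / 0.1));
    double h = P.dt / nsub;
    for (auto &f : S.fils)
      for (int s = 0; s < nsub; ++s) {
        double k = f.capped ? P.k_uncap : P.k_cap;
        if (k > 0 && unif_rand() < 1.0 - std::exp(-k * h)) f.capped = !f.capped;
      }
  }
  // neighbor grid over current vertices (used by kinetics and sterics)
  bool need_grid = nl > 0 && nf > 0 && (P.k_bind > 0 || P.steric_k > 0);
  if (need_grid) build_vertex_grid(S, P, W);
  else { W.steric_pairs.clear(); }
  // 3. kinetics
  kinetics_step(S, P, W);
  if (need_grid) build_steric_pairs(S, P, W);
  // 4-6. mechanics with adaptive sub-stepping: the stiffest force scale
  // depends on how many links share a vertex, so the stability bound
  // mobility * stiffness * h <= 1 is re-evaluated from the current link
  // multiplicity each step
  double mu_v = 1.0 / (6.0 * M_PI * P.eta * (0.5 * P.L_seg));
  double mu_l = 1.0 / (6.0 * M_PI * P.eta * P.linker_radius);
  int nmax_v = 0, nmax_l = 0;
  {
    std::vector<std::vector<int>> vc(nf);
    for (int fi = 0; fi < nf; ++fi) vc[fi].assign(S.fils[fi].v.size(), 0);
    for (int i = 0; i < nl; ++i) {
      int cnt = (int)S.alinks[i].size() + (int)S.plinks[i].size();
      if (cnt > nmax_l) nmax_l = cnt;
      for (const ALink &al : S.alinks[i]) {
        Vec3 pt; int seg; double w;
        fil_point(S.fils[al.fil], P.L_seg, al.s, pt, seg, w);
        if (++vc[al.fil][seg] > nmax_v) nmax_v = vc[al.fil][seg];
        if (++vc[al.fil][seg + 1] > nmax_v) nmax_v = vc[al.fil][seg + 1];
      }
    }
  }
  double lam_v = 16.0 * P.k_bend / (P.L_seg * P.L_seg * P.L_seg) +
                 P.conf_k + P.steric_k + nmax_v * P.k_link;
  double lam_l = P.conf_k + P.steric_k + nmax_l * P.k_link;
  double rate = mu_v * lam_v;
  if (nl > 0) rate = std::max(rate, mu_l * lam_l);
  int nsub = std::max(1, (int)std::ceil(P.dt * rate));
  double h = P.dt / nsub;
  double sd_v = std::sqrt(2.0 * mu_v * P.kBT * h);
  double sd_l = std::sqrt(2.0 * mu_l * P.kBT * h);
  double max_disp2 = P.L_seg * P.L_seg;
  double Gacc[3] = {0, 0, 0};
  for (int sub = 0; sub < nsub; ++sub) {
    double Gload[3];
    compute_forces(S, P, W, Ff, Fl, Gload);
    for (int i = 0; i < 3; ++i) Gacc[i] += Gload[i];
    for (int fi = 0; fi < nf; ++fi) {
      Fil &f = S.fils[fi];
      for (size_t k = 0; k < f.v.size(); ++k) {
        Vec3 &F = Ff[fi][k];
        if (!std::isfinite(F.x) || !std::isfinite(F.y) || !std::isfinite(F.z))
          stop("non-finite force on filament %d vertex %d", fi + 1, (int)k + 1);
        Vec3 dx = {mu_v * F.x * h, mu_v * F.y * h, mu_v * F.z * h};
        if (P.kBT > 0) {
          dx.x += sd_v * g_noise.normal(); dx.y += sd_v * g_noise.normal();
          dx.z += sd_v * g_noise.normal();
        }
        if (vdot(dx, dx) > max_disp2)
          stop("unstable step: filament displacement exceeds L_seg; reduce dt");
        f.v[k].x += dx.x; f.v[k].y += dx.y; f.v[k].z += dx.z;
      }
    }
    for (int i = 0; i < nl; ++i) {
      Vec3 &F = Fl[i];
      if (!std::isfinite(F.x) || !std::isfinite(F.y) || !std::isfinite(F.z))
        stop("non-finite force on linker %d", i + 1);
      Vec3 dx = {mu_l * F.x * h, mu_l * F.y * h, mu_l * F.z * h};
      if (P.kBT > 0) {
        dx.x += sd_l * g_noise.normal(); dx.y += sd_l * g_noise.normal();
        dx.z += sd_l * g_noise.normal();
      }
      S.lpos[i].x += dx.x; S.lpos[i].y += dx.y; S.lpos[i].z += dx.z;
    }
    for (auto &f : S.fils) shake_project(f, P.L_seg);
  }
  // 7. boundary update with the time-averaged reaction load
  if (!P.rigid) {
    for (int i = 0; i < 3; ++i) Gacc[i] /= nsub;
    boundary_step_core(S.ax, Gacc, P.dt, P.sigma, P.mu_eff, P.V0);
  }
}

// ----------------------------------------------------- R interface helpers

static Params params_from_list(const List &cfg) {
  Params P;
  P.dt = cfg["dt"]; P.L_seg = cfg["L_seg"]; P.k_grow = cfg["k_grow"];
  P.k_bend = cfg["k_bend"]; P.k_cap = cfg["k_cap"]; P.k_uncap = cfg["k_uncap"];
  P.k_bind = cfg["k_bind"]; P.k_unbind = cfg["k_unbind"]; P.F0 = cfg["F0"];
  P.k_form = cfg["k_form"]; P.k_split = cfg["k_split"];
  P.bind_dist = cfg["binding_distance"]; P.k_link = cfg["link_stiffness"];
  P.steric_k = cfg["steric_stiffness"]; P.linker_radius = cfg["linker_radius"];
  P.kBT = cfg["k_BT"]; P.eta = cfg["medium_viscosity"];
  P.sigma = cfg["surface_tension"]; P.mu_eff = cfg["effective_viscosity"];
  P.V0 = cfg["reference_volume"]; P.conf_k = cfg["confinement_stiffness"];
  P.rigid = cfg["rigid"]; P.mode = cfg["mode"];
  return P;
}

static System system_from_list(const List &st) {
  System S;
  List fv = st["fil_vertices"];
  NumericVector fp = st["fil_partial"];
  LogicalVector fc = st["fil_capped"];
  for (int i = 0; i < fv.size(); ++i) {
    NumericMatrix m = fv[i];
    Fil f;
    f.v.resize(m.nrow());
    for (int r = 0; r < m.nrow(); ++r) f.v[r] = {m(r, 0), m(r, 1), m(r, 2)};
    f.partial = fp[i];
    f.capped = fc[i];
    S.fils.push_back(std::move(f));
  }
  NumericMatrix lp = st["linker_pos"];
  for (int r = 0; r < lp.nrow(); ++r)
    S.lpos.push_back({lp(r, 0), lp(r, 1), lp(r, 2)});
  S.alinks.assign(S.lpos.size(), {});
  S.plinks.assign(S.lpos.size(), {});
  NumericMatrix al = st["actin_links"];  // cols: linker, filament, abscissa
  for (int r = 0; r < al.nrow(); ++r)
    S.alinks[(int)al(r, 0) - 1].push_back({(int)al(r, 1) - 1, al(r, 2)});
  NumericMatrix plm = st["partner_links"]; // cols: linker_i, linker_j
  for (int r = 0; r < plm.nrow(); ++r) {
    int i = (int)plm(r, 0) - 1, j = (int)plm(r, 1) - 1;
    S.plinks[i].push_back(j);
    S.plinks[j].push_back(i);
  }
  NumericVector ax = st["semi_axes"];
  S.ax[0] = ax[0]; S.ax[1] = ax[1]; S.ax[2] = ax[2];
  return S;
}

static List system_to_list(const System &S) {
  List fv(S.fils.size());
  NumericVector fp(S.fils.size());
  LogicalVector fc(S.fils.size());
  for (size_t i = 0; i < S.fils.size(); ++i) {
    const Fil &f = S.fils[i];
    NumericMatrix m((int)f.v.size(), 3);
    for (size_t r = 0; r < f.v.size(); ++r) {
      m(r, 0) = f.v[r].x; m(r, 1) = f.v[r].y; m(r, 2) = f.v[r].z;
    }
    fv[i] = m; fp[i] = f.partial; fc[i] = f.capped;
  }
  NumericMatrix lp((int)S.lpos.size(), 3);
  for (size_t r = 0; r < S.lpos.size(); ++r) {
    lp(r, 0) = S.lpos[r].x; lp(r, 1) = S.lpos[r].y; lp(r, 2) = S.lpos[r].z;
  }
  int na = 0, np = 0;
  for (auto &v : S.alinks) na += (int)v.size();
  for (auto &v : S.plinks) np += (int)v.size();
  NumericMatrix al(na, 3);
  int r = 0;
  for (size_t i = 0; i < S.alinks.size(); ++i)
    for (auto &x : S.alinks[i]) {
      al(r, 0) = (double)i + 1; al(r, 1) = (double)x.fil + 1; al(r, 2) = x.s; ++r;
    }
  NumericMatrix plm(np / 2, 2);
  r = 0;
  for (size_t i = 0; i < S.plinks.size(); ++i)
    for (int j : S.plinks[i]) if (j > (int)i) {
      plm(r, 0) = (double)i + 1; plm(r, 1) = (double)j + 1; ++r;
    }
  return List::create(_["fil_vertices"] = fv, _["fil_partial"] = fp,
                      _["fil_capped"] = fc, _["linker_pos"] = lp,
                      _["actin_links"] = al, _["partner_links"] = plm,
                      _["semi_axes"] = NumericVector::create(S.ax[0], S.ax[1], S.ax[2]));
}

// [[Rcpp::export]]
List cpp_run_engine(List state, List cfg, int nsteps, int snapshot_every,
                    double t0) {
  Params P = params_from_list(cfg);
  System S = system_from_list(state);
  g_noise.seed_from_r();
  StepWork W;
  std::vector<std::vector<Vec3>> Ff(S.fils.size());
  std::vector<Vec3> Fl;
  List frames;
  std::vector<double> times;
  std::vector<List> snaps;
  snaps.push_back(system_to_list(S));
  times.push_back(t0);
  for (int step = 1; step <= nsteps; ++step) {
    one_step(S, P, W, Ff, Fl);
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snaps.push_back(system_to_list(S));
      times.push_back(t0 + step * P.dt);
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  List out(snaps.size());
  for (size_t i = 0; i < snaps.size(); ++i) out[i] = snaps[i];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["snapshots"] = out,
                      _["final_state"] = system_to_list(S));
}

// Forces on the current configuration (no motion); used to cross-check the
// C++ mechanics against the R-level module functions.
// [[Rcpp::export]]
List cpp_system_forces(List state, List cfg) {
  Params P = params_from_list(cfg);
  System S = system_from_list(state);
  StepWork W;
  build_vertex_grid(S, P, W);
  build_steric_pairs(S, P, W);
  std::vector<std::vector<Vec3>> Ff(S.fils.size());
  std::vector<Vec3> Fl;
  double G[3];
  compute_forces(S, P, W, Ff, Fl, G);
  List ff(S.fils.size());
  for (size_t i = 0; i < S.fils.size(); ++i) {
    NumericMatrix m((int)Ff[i].size(), 3);
    for (size_t r = 0; r < Ff[i].size(); ++r) {
      m(r, 0) = Ff[i][r].x; m(r, 1) = Ff[i][r].y; m(r, 2) = Ff[i][r].z;
    }
    ff[i] = m;
  }
  NumericMatrix fl((int)Fl.size(), 3);
  for (size_t r = 0; r < Fl.size(); ++r) {
    fl(r, 0) = Fl[r].x; fl(r, 1) = Fl[r].y; fl(r, 2) = Fl[r].z;
  }
  return List::create(_["filament_forces"] = ff, _["linker_forces"] = fl,
                      _["boundary_load"] = NumericVector::create(G[0], G[1], G[2]));
}
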