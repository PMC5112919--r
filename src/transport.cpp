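// Monte Carlo transport kernels: ray-capsule geometry, cell placement,
// chord-based microscopic replay through the periodic cell domain, and the
// macroscopic plate-level photon / electron / muon trackers.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;
static const double ME_EV = 510998.95;

// ---------------------------------------------------------------- RNG -----
// xoshiro256++ (deterministic across platforms), seeded via splitmix64.
struct Rng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = TWO_PI * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
  inline int poisson(double lambda) {
    if (lambda <= 0) return 0;
    if (lambda < 30) {
      double L = std::exp(-lambda), p = 1.0; int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    int k = (int)std::lround(lambda + std::sqrt(lambda) * normal());
    return k < 0 ? 0 : k;
  }
};

// --------------------------------------------------------- vec helpers ----
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void norm3(double* a) {
  double n = std::sqrt(dot3(a, a));
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}
static inline void deflect(double* d, double theta, double phi) {
  double u[3], v[3];
  if (std::fabs(d[2]) < 0.99) { u[0] = -d[1]; u[1] = d[0]; u[2] = 0; }
  else { u[0] = 0; u[1] = -d[2]; u[2] = d[1]; }
  norm3(u);
  v[0] = d[1] * u[2] - d[2] * u[1];
  v[1] = d[2] * u[0] - d[0] * u[2];
  v[2] = d[0] * u[1] - d[1] * u[0];
  double st = std::sin(theta), ct = std::cos(theta);
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    d[i] = ct * d[i] + st * (cp * u[i] + sp * v[i]);
  norm3(d);
}

// ------------------------------------------------- ray-capsule chord ------
// Entry/exit ray parameters for a capsule (segment c +/- h*a, radius r).
// Returns t0 > t1 when the ray misses.
static void capsule_ts(const double* p, const double* d, const double* c,
                       const double* a, double r, double h,
                       double& t0, double& t1) {
  t0 = 1.0; t1 = -1.0;
  double m[3] = { p[0] - c[0], p[1] - c[1], p[2] - c[2] };
  double best0 = 1e300, best1 = -1e300;
  bool found = false;
  double md = dot3(m, a), dd = dot3(d, a);
  if (h > 0) {
    double mp[3], dp[3];
    for (int i = 0; i < 3; ++i) { mp[i] = m[i] - md * a[i]; dp[i] = d[i] - dd * a[i]; }
    double A = dot3(dp, dp), B = 2 * dot3(mp, dp), C = dot3(mp, mp) - r * r;
    if (A > 1e-14) {
      double disc = B * B - 4 * A * C;
      if (disc >= 0) {
        double sq = std::sqrt(disc);
        double ts[2] = { (-B - sq) / (2 * A), (-B + sq) / (2 * A) };
        for (int j = 0; j < 2; ++j) {
          double ax = md + ts[j] * dd;
          if (std::fabs(ax) <= h) {
            found = true;
            if (ts[j] < best0) best0 = ts[j];
            if (ts[j] > best1) best1 = ts[j];
          }
        }
      }
    }
  }
  int ncap = (h > 0) ? 2 : 1;
  for (int s = 0; s < ncap; ++s) {
    double sgn = (ncap == 1) ? 0.0 : (s == 0 ? 1.0 : -1.0);
    double cc[3] = { c[0] + sgn * h * a[0], c[1] + sgn * h * a[1], c[2] + sgn * h * a[2] };
    double mm[3] = { p[0] - cc[0], p[1] - cc[1], p[2] - cc[2] };
    double B = 2 * dot3(mm, d), C = dot3(mm, mm) - r * r;
    double disc = B * B - 4 * C;
    if (disc >= 0) {
      double sq = std::sqrt(disc);
      double ts[2] = { (-B - sq) / 2, (-B + sq) / 2 };
      for (int j = 0; j < 2; ++j) {
        if (h > 0) {
          double ax = md + ts[j] * dd;
          if (std::fabs(ax) < h - 1e-12) continue;  // inside cylinder section
        }
        found = true;
        if (ts[j] < best0) best0 = ts[j];
        if (ts[j] > best1) best1 = ts[j];
      }
    }
  }
  if (found) { t0 = best0; t1 = best1; }
}

// [[Rcpp::export]]
NumericVector ray_capsule_cpp(NumericVector origin, NumericVector direction,
                              NumericVector center, NumericVector axis,
                              double radius, double half_length) {
  double t0, t1;
  capsule_ts(origin.begin(), direction.begin(), center.begin(), axis.begin(),
             radius, half_length, t0, t1);
  return NumericVector::create(t0, t1);
}

// shortest distance between segments (c1 +/- h1 a1) and (c2 +/- h2 a2)
static double seg_seg_dist(const double* c1, const double* a1, double h1,
                           const double* c2, const double* a2, double h2) {
  double p1[3], d1[3], p2[3], d2[3];
  for (int i = 0; i < 3; ++i) {
    p1[i] = c1[i] - h1 * a1[i]; d1[i] = 2 * h1 * a1[i];
    p2[i] = c2[i] - h2 * a2[i]; d2[i] = 2 * h2 * a2[i];
  }
  double r[3] = { p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2] };
  double A = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0, t = 0;
  if (A <= 1e-14 && e <= 1e-14) { }
  else if (A <= 1e-14) { t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot3(d1, r);
    if (e <= 1e-14) { s = std::min(1.0, std::max(0.0, -c / A)); }
    else {
      double b = dot3(d1, d2), den = A * e - b * b;
      if (den > 1e-14) s = std::min(1.0, std::max(0.0, (b * f - c * e) / den));
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / A)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / A)); }
    }
  }
  double q[3];
  for (int i = 0; i < 3; ++i)
    q[i] = (p1[i] + s * d1[i]) - (p2[i] + t * d2[i]);
  return std::sqrt(dot3(q, q));
}

// [[Rcpp::export]]
double segment_distance_cpp(NumericVector c1, NumericVector a1, double h1,
                            NumericVector c2, NumericVector a2, double h2) {
  return seg_seg_dist(c1.begin(), a1.begin(), h1, c2.begin(), a2.begin(), h2);
}

// [[Rcpp::export]]
List place_cells_cpp(int n, double edge, double radius, double half_length,
                     bool reject_overlap, double seed) {
  Rng rng((uint64_t)seed * 2654435761ULL + 17ULL);
  NumericMatrix centers(n, 3), axes(n, 3);
  std::vector<double> cx, cy, cz, ax, ay, az;
  long attempts = 0, max_attempts = 2000L * (n + 100L);
  for (int i = 0; i < n; ) {
    if (++attempts > max_attempts)
      stop("cell placement stalled: packing too dense for the non-overlap policy");
    double c[3] = { rng.unif() * edge, rng.unif() * edge, rng.unif() * edge };
    double u = 2 * rng.unif() - 1, phi = TWO_PI * rng.unif();
    double st = std::sqrt(std::max(0.0, 1 - u * u));
    double a[3] = { st * std::cos(phi), st * std::sin(phi), u };
    bool ok = true;
    if (reject_overlap) {
      double reach = 2 * (radius + half_length);
      for (int j = 0; j < i && ok; ++j) {
        double del[3] = { cx[j] - c[0], cy[j] - c[1], cz[j] - c[2] };
        for (int k = 0; k < 3; ++k) {  // minimum image in the periodic box
          if (del[k] > edge / 2) del[k] -= edge;
          if (del[k] < -edge / 2) del[k] += edge;
        }
        if (std::sqrt(dot3(del, del)) > reach) continue;
        double cjim[3] = { c[0] + del[0], c[1] + del[1], c[2] + del[2] };
        double aj[3] = { ax[j], ay[j], az[j] };
        if (seg_seg_dist(c, a, half_length, cjim, aj, half_length) < 2 * radius)
          ok = false;
      }
    }
    if (ok) {
      cx.push_back(c[0]); cy.push_back(c[1]); cz.push_back(c[2]);
      ax.push_back(a[0]); ay.push_back(a[1]); az.push_back(a[2]);
      ++i;
    }
  }
  for (int i = 0; i < n; ++i) {
    centers(i, 0) = cx[i]; centers(i, 1) = cy[i]; centers(i, 2) = cz[i];
    axes(i, 0) = ax[i]; axes(i, 1) = ay[i]; axes(i, 2) = az[i];
  }
  return List::create(_["centers"] = centers, _["axes"] = axes);
}

// ------------------------------------------------- stopping table view ----
struct SpTable {
  double logE0 = 0, dlog = 1;
  int n = 0;
  const double *S = nullptr, *Rfull = nullptr, *Rres = nullptr;  // eV/um, um (water)
  double Emin = 0, Emax = 0;
  bool valid = false;
  inline double clampE(double E) const {
    return std::min(std::max(E, Emin), Emax);
  }
  inline double interp(const double* arr, double E) const {
    double x = (std::log(clampE(E)) - logE0) / dlog;
    int i = (int)x;
    if (i < 0) i = 0;
    if (i >= n - 1) i = n - 2;
    double f = x - i;
    return arr[i] * (1 - f) + arr[i + 1] * f;
  }
  inline double S_at(double E) const { return interp(S, E); }
  inline double Rfull_at(double E) const { return interp(Rfull, E); }
  inline double Rres_at(double E) const { return interp(Rres, E); }
  inline double E_from_R(double r, bool restricted) const {
    const double* R = restricted ? Rres : Rfull;
    if (r <= R[0]) return Emin;
    if (r >= R[n - 1]) return Emax;
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (R[mid] <= r) lo = mid; else hi = mid;
    }
    double f = (r - R[lo]) / (R[hi] - R[lo]);
    return std::exp(logE0 + (lo + f) * dlog);
  }
};

static void load_tables(List tables, std::vector<SpTable>& tb,
                        std::vector<NumericVector>& keep) {
  tb.assign(8, SpTable());
  keep.clear();
  keep.reserve(24);
  for (int code = 1; code <= 7; ++code) {
    if (code > tables.size() || Rf_isNull(tables[code - 1])) continue;
    List t = tables[code - 1];
    NumericVector S = t["S"], Rf_ = t["Rfull"], Rr = t["Rres"];
    keep.push_back(S); keep.push_back(Rf_); keep.push_back(Rr);
  }
  int ki = 0;
  for (int code = 1; code <= 7; ++code) {
    if (code > tables.size() || Rf_isNull(tables[code - 1])) continue;
    List t = tables[code - 1];
    SpTable s;
    s.logE0 = as<double>(t["logE0"]);
    s.dlog = as<double>(t["dlog"]);
    s.n = keep[ki].size();
    s.S = keep[ki].begin();
    s.Rfull = keep[ki + 1].begin();
    s.Rres = keep[ki + 2].begin();
    ki += 3;
    s.Emin = std::exp(s.logE0);
    s.Emax = std::exp(s.logE0 + (s.n - 1) * s.dlog);
    s.valid = true;
    tb[code] = s;
  }
}

static const double MASS_EV[8] = { 0, ME_EV, ME_EV, 105.6583755e6,
                                   105.6583755e6, 938.27208e6, 3727.379e6,
                                   14895.08e6 };
static const double Z2_SP[8] = { 0, 1, 1, 1, 1, 1, 4, 64 };
static const double XI_PER_UM = 8.52291;  // 0.1535356*(Z/A)*100 eV/um, beta=1

static inline double beta2_of(int sp, double E) {
  double g = 1 + E / MASS_EV[sp];
  return 1 - 1 / (g * g);
}
static inline double tmax_of(int sp, double E) {
  if (sp == 1) return E / 2;
  if (sp == 2) return E;
  double m = MASS_EV[sp];
  double g = 1 + E / m;
  double bg2 = g * g - 1;
  return 2 * ME_EV * bg2 / (1 + 2 * g * ME_EV / m + (ME_EV / m) * (ME_EV / m));
}
static inline double delta_rate_um(int sp, double E, double delta_eV) {
  double Tmax = tmax_of(sp, E);
  if (Tmax <= delta_eV) return 0.0;
  return XI_PER_UM * Z2_SP[sp] / beta2_of(sp, E) * (1 / delta_eV - 1 / Tmax);
}
// Highland multiple-scattering width over path s [um] in water, e+/e-
static inline double highland_theta(double E, double s_um) {
  if (s_um <= 0) return 0.0;
  double pc = std::sqrt(E * (E + 2 * ME_EV));       // eV
  double beta_pc = pc * pc / (E + ME_EV);           // eV
  double sx = s_um / 3.608e5;                       // s / X0
  double lg = 1 + 0.038 * std::log(sx);
  if (lg < 0.25) lg = 0.25;
  double th = 13.6e6 / beta_pc * std::sqrt(sx) * lg;
  return std::min(th, 1.0);
}

// Landau-type chord deposit: Moyal component restricted below discrete_min
// plus discrete knock-on transfers above it (mirrors sample_deposit() on
// the R side). discrete_min is the production threshold (100 eV): in-cell
// transfers above it are sampled individually and deposited locally.
static double chord_deposit(Rng& rng, const SpTable& tb, int sp, double E,
                            double weq_um, bool straggling, double discrete_min) {
  if (weq_um <= 0) return 0.0;
  double S = tb.S_at(E);
  if (!straggling) return std::min(S * weq_um, E);
  double b2 = beta2_of(sp, E);
  double xi = XI_PER_UM * Z2_SP[sp] / b2 * weq_um;
  double Tmax = tmax_of(sp, E);
  double Sres = S;
  if (Tmax > discrete_min) {
    double loss = XI_PER_UM * Z2_SP[sp] / b2 * std::log(Tmax / discrete_min);
    Sres = std::max(S - loss, 0.10 * S);
  }
  double moyal = -2.0 * std::log(std::fabs(rng.normal()) + 1e-300);
  double dep = Sres * weq_um + xi * (moyal - 1.2704);
  if (dep < 0) dep = 0;
  if (Tmax > discrete_min) {
    double nu = xi * (1 / discrete_min - 1 / Tmax);
    int k = rng.poisson(nu);
    for (int i = 0; i < k; ++i) {
      double u = rng.unif();
      dep += discrete_min / (1 - u * (1 - discrete_min / Tmax));
    }
  }
  return std::min(dep, E);
}

// ------------------------------------------------------- micro replay -----
struct Particle {
  int sp; double E; double p[3]; double d[3]; double w; int event;
};

// [[Rcpp::export]]
List run_micro_cpp(IntegerVector species, NumericVector E0, NumericMatrix pos,
                   NumericMatrix dir, NumericVector wt,
                   NumericMatrix centers, NumericMatrix axes,
                   double radius, double half_length, double edge,
                   NumericVector well_min, NumericVector well_max,
                   bool kill_outside, List tables, double cutoff_eV,
                   double delta_eV, bool straggling, bool msc, bool deltas_on,
                   double cell_density, double seed) {
  const int nprim = species.size();
  const int ncell = centers.nrow();
  std::vector<SpTable> tb;
  std::vector<NumericVector> keep;
  load_tables(tables, tb, keep);
  Rng rng((uint64_t)seed * 0x9e3779b9ULL + 12345ULL);

  // spatial grid over the periodic box
  const int nb = std::max(4, std::min(25, (int)(edge / 8.0)));
  const double bs = edge / nb;
  struct Entry { int cell; signed char ox, oy, oz; };
  std::vector<std::vector<Entry>> grid((size_t)nb * nb * nb);
  const double reach = radius + half_length;
  for (int ci = 0; ci < ncell; ++ci) {
    double c[3] = { centers(ci, 0), centers(ci, 1), centers(ci, 2) };
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = (int)std::floor((c[k] - reach - 1e-9) / bs);
      hi[k] = (int)std::floor((c[k] + reach + 1e-9) / bs);
    }
    for (int ix = lo[0]; ix <= hi[0]; ++ix)
      for (int iy = lo[1]; iy <= hi[1]; ++iy)
        for (int iz = lo[2]; iz <= hi[2]; ++iz) {
          int wx = ((ix % nb) + nb) % nb, wy = ((iy % nb) + nb) % nb,
              wz = ((iz % nb) + nb) % nb;
          Entry e;
          e.cell = ci;
          e.ox = (signed char)((ix - wx) / nb);
          e.oy = (signed char)((iy - wy) / nb);
          e.oz = (signed char)((iz - wz) / nb);
          grid[((size_t)wx * nb + wy) * nb + wz].push_back(e);
        }
  }

  std::vector<double> h_ev, h_cell, h_tx, h_ty, h_tz, h_dep, h_Ein,
      h_px, h_py, h_pz, h_dx, h_dy, h_dz, h_sp, h_w;
  double E_in = 0, dep_cells = 0, dep_medium = 0, escaped = 0;
  int n_skipped = 0;
  std::vector<Particle> stack;
  const double EPS = 1e-6;

  for (int ip = 0; ip < nprim; ++ip) {
    int sp = species[ip];
    if (sp < 1 || sp > 7 || !tb[sp].valid || !(E0[ip] > 0)) { ++n_skipped; continue; }
    Particle prim;
    prim.sp = sp; prim.E = E0[ip]; prim.w = wt[ip]; prim.event = ip + 1;
    for (int k = 0; k < 3; ++k) { prim.p[k] = pos(ip, k); prim.d[k] = dir(ip, k); }
    norm3(prim.d);
    E_in += prim.E * prim.w;
    stack.clear();
    stack.push_back(prim);

    while (!stack.empty()) {
      Particle q = stack.back();
      stack.pop_back();
      const SpTable& T = tb[q.sp];
      while (true) {
        if (q.E < cutoff_eV) { dep_medium += q.E * q.w; break; }
        if (kill_outside) {
          bool inside = true;
          for (int k = 0; k < 3; ++k)
            if (q.p[k] < well_min[k] || q.p[k] > well_max[k]) { inside = false; break; }
          if (!inside) { escaped += q.E * q.w; break; }
        }
        double lp[3];
        for (int k = 0; k < 3; ++k) {
          double tf = std::floor(q.p[k] / edge);
          lp[k] = q.p[k] - tf * edge;
          if (lp[k] >= edge) lp[k] -= edge;
          if (lp[k] < 0) lp[k] += edge;
        }
        double t_face = 1e300;
        for (int k = 0; k < 3; ++k) {
          if (q.d[k] > 1e-12) t_face = std::min(t_face, (edge - lp[k]) / q.d[k]);
          else if (q.d[k] < -1e-12) t_face = std::min(t_face, -lp[k] / q.d[k]);
        }
        t_face += EPS;
        bool use_res = deltas_on && tmax_of(q.sp, q.E) > delta_eV;
        double r_rem = use_res ? T.Rres_at(q.E) : T.Rfull_at(q.E);
        double s_delta = 1e300;
        if (deltas_on) {
          double rate = delta_rate_um(q.sp, q.E, delta_eV);
          if (rate > 0) s_delta = -std::log(rng.unif()) / rate;
        }
        double Lmax = std::min(std::min(t_face, r_rem), s_delta);

        // nearest cell entry along [0, Lmax] (grid DDA, bins within tile)
        double Ldda = std::min(Lmax, t_face);
        int bi[3]; double tMax[3], tDelta[3]; int stepb[3];
        for (int k = 0; k < 3; ++k) {
          bi[k] = (int)(lp[k] / bs);
          if (bi[k] < 0) bi[k] = 0;
          if (bi[k] >= nb) bi[k] = nb - 1;
          if (q.d[k] > 1e-12) {
            stepb[k] = 1;
            tMax[k] = ((bi[k] + 1) * bs - lp[k]) / q.d[k];
            tDelta[k] = bs / q.d[k];
          } else if (q.d[k] < -1e-12) {
            stepb[k] = -1;
            tMax[k] = (bi[k] * bs - lp[k]) / q.d[k];
            tDelta[k] = -bs / q.d[k];
          } else { stepb[k] = 0; tMax[k] = 1e300; tDelta[k] = 1e300; }
        }
        double best_t0 = 1e300, best_t1 = 0;
        int best_cell = -1;
        double tcur = 0;
        while (true) {
          const std::vector<Entry>& cellv =
              grid[((size_t)bi[0] * nb + bi[1]) * nb + bi[2]];
          for (size_t ie = 0; ie < cellv.size(); ++ie) {
            const Entry& e = cellv[ie];
            // a cell wrapped from raw bin offset o appears translated by
            // -o*edge in the local frame
            double cc[3] = { centers(e.cell, 0) - e.ox * edge,
                             centers(e.cell, 1) - e.oy * edge,
                             centers(e.cell, 2) - e.oz * edge };
            double aa[3] = { axes(e.cell, 0), axes(e.cell, 1), axes(e.cell, 2) };
            double t0, t1;
            capsule_ts(lp, q.d, cc, aa, radius, half_length, t0, t1);
            if (t0 > t1) continue;
            if (t1 <= EPS) continue;
            if (t0 > Ldda) continue;
            if (t0 < best_t0) { best_t0 = t0; best_t1 = t1; best_cell = e.cell; }
          }
          if (best_cell >= 0 && best_t0 < tcur) break;
          int kmin = (tMax[0] < tMax[1]) ? (tMax[0] < tMax[2] ? 0 : 2)
                                         : (tMax[1] < tMax[2] ? 1 : 2);
          tcur = tMax[kmin];
          if (tcur > Ldda) break;
          bi[kmin] += stepb[kmin];
          if (bi[kmin] < 0 || bi[kmin] >= nb) break;
          tMax[kmin] += tDelta[kmin];
        }

        if (best_cell >= 0 && best_t0 <= Lmax) {
          double t0 = std::max(best_t0, 0.0);
          if (t0 > 0) {  // medium flight up to the entry
            double Eold = q.E;
            q.E = T.E_from_R(r_rem - t0, use_res);
            dep_medium += (Eold - q.E) * q.w;
            for (int k = 0; k < 3; ++k) q.p[k] += q.d[k] * t0;
            if (q.E < cutoff_eV) { dep_medium += q.E * q.w; q.E = 0; break; }
          }
          double chord = best_t1 - t0;
          if (chord < 0) chord = 0;
          double weq = chord * cell_density;
          double rin_cell = T.Rfull_at(q.E) / cell_density;
          bool stops = chord >= rin_cell;
          double dep = stops ? q.E
                             : chord_deposit(rng, T, q.sp, q.E, weq,
                                             straggling, cutoff_eV);
          if (dep > 0) {
            double tx = std::floor(q.p[0] / edge), ty = std::floor(q.p[1] / edge),
                   tz = std::floor(q.p[2] / edge);
            h_ev.push_back(q.event); h_cell.push_back(best_cell + 1);
            h_tx.push_back(tx); h_ty.push_back(ty); h_tz.push_back(tz);
            h_dep.push_back(dep); h_Ein.push_back(q.E);
            h_px.push_back(q.p[0] - tx * edge);
            h_py.push_back(q.p[1] - ty * edge);
            h_pz.push_back(q.p[2] - tz * edge);
            h_dx.push_back(q.d[0]); h_dy.push_back(q.d[1]); h_dz.push_back(q.d[2]);
            h_sp.push_back(q.sp); h_w.push_back(q.w);
          }
          dep_cells += dep * q.w;
          q.E -= dep;
          if (stops || q.E < cutoff_eV) { dep_cells += q.E * q.w; break; }
          for (int k = 0; k < 3; ++k) q.p[k] += q.d[k] * (chord + EPS);
          if (msc && (q.sp == 1 || q.sp == 2)) {
            double th0 = highland_theta(q.E, t0 + chord);
            if (th0 > 0) deflect(q.d, std::fabs(rng.normal()) * th0,
                                 TWO_PI * rng.unif());
          }
          continue;
        }

        // no cell before the limiting event
        if (Lmax >= r_rem) {  // track end in the medium
          for (int k = 0; k < 3; ++k) q.p[k] += q.d[k] * r_rem;
          dep_medium += q.E * q.w;
          break;
        }
        double s = Lmax;
        double Eold = q.E;
        q.E = T.E_from_R(r_rem - s, use_res);
        dep_medium += (Eold - q.E) * q.w;
        for (int k = 0; k < 3; ++k) q.p[k] += q.d[k] * s;
        if (deltas_on && s == s_delta) {
          double Tmax = tmax_of(q.sp, q.E);
          if (Tmax > delta_eV) {
            double u = rng.unif();
            double Td = delta_eV / (1 - u * (1 - delta_eV / Tmax));
            if (Td > q.E) Td = q.E;
            q.E -= Td;
            if (Td > cutoff_eV) {
              Particle ddp;
              ddp.sp = 1; ddp.E = Td; ddp.w = q.w; ddp.event = q.event;
              for (int k = 0; k < 3; ++k) { ddp.p[k] = q.p[k]; ddp.d[k] = q.d[k]; }
              double cosd;
              if (q.sp == 1 || q.sp == 2)
                cosd = std::sqrt(Td * (q.E + Td + 2 * ME_EV) /
                                 ((q.E + Td) * (Td + 2 * ME_EV)));
              else
                cosd = std::sqrt(std::min(1.0, Td / Tmax));
              if (cosd > 1) cosd = 1;
              deflect(ddp.d, std::acos(cosd), TWO_PI * rng.unif());
              stack.push_back(ddp);
            } else {
              dep_medium += Td * q.w;
            }
          }
        }
        if (msc && (q.sp == 1 || q.sp == 2) && s > 0.01) {
          double th0 = highland_theta(q.E, s);
          if (th0 > 0) deflect(q.d, std::fabs(rng.normal()) * th0,
                               TWO_PI * rng.unif());
        }
      }
    }
  }

  size_t nh = h_ev.size();
  NumericMatrix hits(nh, 15);
  for (size_t i = 0; i < nh; ++i) {
    hits(i, 0) = h_ev[i]; hits(i, 1) = h_cell[i];
    hits(i, 2) = h_tx[i]; hits(i, 3) = h_ty[i]; hits(i, 4) = h_tz[i];
    hits(i, 5) = h_dep[i]; hits(i, 6) = h_Ein[i];
    hits(i, 7) = h_px[i]; hits(i, 8) = h_py[i]; hits(i, 9) = h_pz[i];
    hits(i, 10) = h_dx[i]; hits(i, 11) = h_dy[i]; hits(i, 12) = h_dz[i];
    hits(i, 13) = h_sp[i]; hits(i, 14) = h_w[i];
  }
  return List::create(
      _["hits"] = hits, _["E_in"] = E_in, _["E_deposited_cells"] = dep_cells,
      _["E_deposited_medium"] = dep_medium, _["E_escaped"] = escaped,
      _["n_skipped"] = n_skipped);
}

// --------------------------------------------------- macroscopic level ----
// Simplified 96-well plate: polypropylene block with a grid of square
// cavities, some filled with broth; the sensitive well is centered at the
// origin. Units: mm.
struct Plate {
  double pitch, inner_half, wall_zlo, wall_zhi, liq_zlo, liq_zhi;
  int ncol, nrow, ix_off, iy_off;
  const int* filled;  // ncol x nrow, column-major [ix*nrow+iy]
  double world[6];    // xlo xhi ylo yhi zlo zhi
  int material(double x, double y, double z) const {
    if (z > wall_zhi || z < wall_zlo) return 0;
    double gx = x + (ix_off + 0.5) * pitch, gy = y + (iy_off + 0.5) * pitch;
    int ix = (int)std::floor(gx / pitch), iy = (int)std::floor(gy / pitch);
    if (ix < 0 || ix >= ncol || iy < 0 || iy >= nrow) return 0;
    double u = x - (ix - ix_off) * pitch, v = y - (iy - iy_off) * pitch;
    if (std::fabs(u) <= inner_half && std::fabs(v) <= inner_half) {
      if (filled[ix * nrow + iy] && z <= liq_zhi && z >= liq_zlo) return 2;
      return 0;
    }
    return 1;
  }
  bool in_sens(const double* p) const {
    return std::fabs(p[0]) <= inner_half && std::fabs(p[1]) <= inner_half &&
           p[2] >= liq_zlo && p[2] <= liq_zhi;
  }
  bool in_world(const double* p) const {
    return p[0] >= world[0] && p[0] <= world[1] && p[1] >= world[2] &&
           p[1] <= world[3] && p[2] >= world[4] && p[2] <= world[5];
  }
};

static Plate plate_from_list(List pl, IntegerVector& filled_keep) {
  Plate P;
  P.pitch = as<double>(pl["pitch"]);
  P.inner_half = as<double>(pl["inner_half"]);
  P.wall_zlo = as<double>(pl["wall_zlo"]); P.wall_zhi = as<double>(pl["wall_zhi"]);
  P.liq_zlo = as<double>(pl["liq_zlo"]); P.liq_zhi = as<double>(pl["liq_zhi"]);
  P.ncol = as<int>(pl["ncol"]); P.nrow = as<int>(pl["nrow"]);
  P.ix_off = as<int>(pl["ix_off"]); P.iy_off = as<int>(pl["iy_off"]);
  filled_keep = pl["filled"];
  P.filled = filled_keep.begin();
  NumericVector w = pl["world"];
  for (int i = 0; i < 6; ++i) P.world[i] = w[i];
  return P;
}

struct MacroRecorder {
  std::vector<double> sp, E, x, y, z, dx, dy, dz, tag;
  void add(int spc, double Ee, const double* p, const double* d, int tg) {
    sp.push_back(spc); E.push_back(Ee);
    x.push_back(p[0]); y.push_back(p[1]); z.push_back(p[2]);
    dx.push_back(d[0]); dy.push_back(d[1]); dz.push_back(d[2]);
    tag.push_back(tg);
  }
  NumericMatrix to_matrix() const {
    size_t n = sp.size();
    NumericMatrix m(n, 9);
    for (size_t i = 0; i < n; ++i) {
      m(i, 0) = sp[i]; m(i, 1) = E[i]; m(i, 2) = x[i]; m(i, 3) = y[i];
      m(i, 4) = z[i]; m(i, 5) = dx[i]; m(i, 6) = dy[i]; m(i, 7) = dz[i];
      m(i, 8) = tag[i];
    }
    return m;
  }
};

// straight-line condensed-history charged-particle tracker at the plate
// level; records the particle per the phase-space rule and tallies dose in
// the sensitive well. mat_scale: water-equivalent density factor per material.
static void track_charged(const Plate& P, const SpTable& T, int spc,
                          double E, double p0[3], double d0[3],
                          bool record_at_creation, MacroRecorder& rec,
                          double& dose_eV, const double* mat_scale,
                          double step_mm, double kill_eV) {
  double p[3] = { p0[0], p0[1], p0[2] };
  double d[3] = { d0[0], d0[1], d0[2] };
  norm3(d);
  bool recorded = false;
  bool was_in = P.in_sens(p);
  if (record_at_creation || was_in) {
    rec.add(spc, E, p, d, was_in ? 1 : 2);
    recorded = true;
  }
  int guard = 0;
  while (++guard < 100000) {
    if (!P.in_world(p)) return;
    bool in_sens = P.in_sens(p);
    if (E < kill_eV) {
      if (in_sens) dose_eV += E;
      return;
    }
    if (in_sens && !recorded) {  // entered the sensitive well
      rec.add(spc, E, p, d, 2);
      recorded = true;
    }
    int mat = P.material(p[0], p[1], p[2]);
    double weq = step_mm * 1000.0 * mat_scale[mat];  // um water-equivalent
    double r = T.Rfull_at(E);
    double Enew;
    if (weq >= r) Enew = 0;
    else Enew = T.E_from_R(r - weq, false);
    if (in_sens) dose_eV += (E - Enew);
    E = Enew;
    for (int k = 0; k < 3; ++k) p[k] += d[k] * step_mm;
  }
}

// [[Rcpp::export]]
List macro_charged_cpp(IntegerVector species, NumericVector E0,
                       NumericMatrix pos, NumericMatrix dir,
                       LogicalVector created_in_well, List plate,
                       List tables, NumericVector mat_scale,
                       double step_mm, double kill_eV) {
  IntegerVector filled_keep;
  Plate P = plate_from_list(plate, filled_keep);
  std::vector<SpTable> tb;
  std::vector<NumericVector> keep;
  load_tables(tables, tb, keep);
  MacroRecorder rec;
  double dose_eV = 0;
  for (int i = 0; i < species.size(); ++i) {
    int spc = species[i];
    if (spc < 1 || spc > 7 || !tb[spc].valid) continue;
    double p[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    double d[3] = { dir(i, 0), dir(i, 1), dir(i, 2) };
    track_charged(P, tb[spc], spc, E0[i], p, d, created_in_well[i], rec,
                  dose_eV, mat_scale.begin(), step_mm, kill_eV);
  }
  return List::create(_["records"] = rec.to_matrix(), _["dose_eV"] = dose_eV);
}

struct MuView {
  double logE0, dlog; int n;
  const double *pe, *co, *pa;
  inline double get(const double* a, double E) const {
    double x = (std::log(E) - logE0) / dlog;
    int i = (int)x;
    if (i < 0) i = 0;
    if (i >= n - 1) i = n - 2;
    double f = x - i;
    return a[i] * (1 - f) + a[i + 1] * f;
  }
};

// [[Rcpp::export]]
List macro_photons_cpp(NumericVector E0, NumericMatrix pos, NumericMatrix dir,
                       List plate, List mu_tables, NumericVector mu_major,
                       double mu_logE0, double mu_dlog, List etables,
                       NumericVector mat_scale, double binding_eV,
                       double step_mm, double kill_eV, double seed) {
  IntegerVector filled_keep;
  Plate P = plate_from_list(plate, filled_keep);
  std::vector<SpTable> tb;
  std::vector<NumericVector> keep;
  load_tables(etables, tb, keep);
  // photon attenuation per material (0 air, 1 poly, 2 broth)
  std::vector<MuView> MU(3);
  std::vector<NumericVector> mukeep;
  for (int m = 0; m < 3; ++m) {
    List t = mu_tables[m];
    NumericVector pe = t["pe"], co = t["co"], pa = t["pa"];
    mukeep.push_back(pe); mukeep.push_back(co); mukeep.push_back(pa);
  }
  for (int m = 0; m < 3; ++m) {
    MU[m].logE0 = mu_logE0; MU[m].dlog = mu_dlog;
    MU[m].n = mukeep[3 * m].size();
    MU[m].pe = mukeep[3 * m].begin();
    MU[m].co = mukeep[3 * m + 1].begin();
    MU[m].pa = mukeep[3 * m + 2].begin();
  }
  int nmaj = mu_major.size();
  Rng rng((uint64_t)seed * 0x51f15eedULL + 7ULL);
  MacroRecorder rec;
  double dose_eV = 0;
  double Emin_grid = std::exp(mu_logE0);
  long n_compton = 0, n_pe = 0, n_pair = 0, n_interacted = 0;

  for (int i = 0; i < E0.size(); ++i) {
    double E = E0[i];
    bool interacted = false;
    double p[3] = { pos(i, 0), pos(i, 1), pos(i, 2) };
    double d[3] = { dir(i, 0), dir(i, 1), dir(i, 2) };
    norm3(d);
    int guard = 0;
    while (++guard < 10000) {
      if (E < std::max(2e3, Emin_grid * 1.01)) {
        if (P.in_sens(p)) dose_eV += E;
        break;
      }
      // majorant lookup
      double x = (std::log(E) - mu_logE0) / mu_dlog;
      int ig = (int)x;
      if (ig < 0) ig = 0;
      if (ig >= nmaj - 1) ig = nmaj - 2;
      double f = x - ig;
      double mumaj = mu_major[ig] * (1 - f) + mu_major[ig + 1] * f;
      double s_cm = -std::log(rng.unif()) / mumaj;
      for (int k = 0; k < 3; ++k) p[k] += d[k] * s_cm * 10.0;  // cm -> mm
      if (!P.in_world(p)) break;
      int mat = P.material(p[0], p[1], p[2]);
      double mpe = MU[mat].get(MU[mat].pe, E), mco = MU[mat].get(MU[mat].co, E),
             mpa = MU[mat].get(MU[mat].pa, E);
      double mtot = mpe + mco + mpa;
      if (rng.unif() * mumaj > mtot) continue;  // null collision
      if (!interacted) { interacted = true; ++n_interacted; }
      double u = rng.unif() * mtot;
      if (u < mco) {
        // Compton: Kahn sampling of the scattered-photon fraction
        ++n_compton;
        double kk = E / ME_EV, eps_min = 1 / (1 + 2 * kk);
        double a1 = -std::log(eps_min), a2 = (1 - eps_min * eps_min) / 2;
        double eps, sin2, t1;
        do {
          if (rng.unif() < a1 / (a1 + a2))
            eps = eps_min * std::exp(a1 * rng.unif());
          else
            eps = std::sqrt(eps_min * eps_min +
                            (1 - eps_min * eps_min) * rng.unif());
          t1 = (1 - eps) / (kk * eps);
          sin2 = t1 * (2 - t1);
        } while (rng.unif() > 1 - eps * sin2 / (1 + eps * eps));
        double cth = 1 - (1 - eps) / (kk * eps);
        double Ee = E * (1 - eps);
        double pe_mom = std::sqrt(Ee * (Ee + 2 * ME_EV));
        double ce = pe_mom > 0 ? (E - E * eps * cth) / pe_mom : 1.0;
        if (ce > 1) ce = 1;
        if (ce < -1) ce = -1;
        double phi = TWO_PI * rng.unif();
        double de[3] = { d[0], d[1], d[2] };
        deflect(de, std::acos(ce), phi);
        if (Ee > kill_eV)
          track_charged(P, tb[1], 1, Ee, p, de, P.in_sens(p), rec, dose_eV,
                        mat_scale.begin(), step_mm, kill_eV);
        else if (P.in_sens(p)) dose_eV += Ee;
        deflect(d, std::acos(cth), phi + TWO_PI / 2);
        E *= eps;
      } else if (u < mco + mpe) {
        ++n_pe;
        double Ee = E - binding_eV;
        if (P.in_sens(p)) dose_eV += std::min(E, binding_eV);
        if (Ee > kill_eV) {
          double de[3] = { d[0], d[1], d[2] };
          track_charged(P, tb[1], 1, Ee, p, de, P.in_sens(p), rec, dose_eV,
                        mat_scale.begin(), step_mm, kill_eV);
        } else if (P.in_sens(p)) dose_eV += std::max(0.0, Ee);
        break;
      } else {
        ++n_pair;
        double Ek = E - 2 * ME_EV;
        if (Ek < 0) Ek = 0;
        if (Ek / 2 > kill_eV) {
          double de[3] = { d[0], d[1], d[2] };
          track_charged(P, tb[1], 1, Ek / 2, p, de, P.in_sens(p), rec, dose_eV,
                        mat_scale.begin(), step_mm, kill_eV);
          double dp[3] = { d[0], d[1], d[2] };
          track_charged(P, tb[2], 2, Ek / 2, p, dp, P.in_sens(p), rec, dose_eV,
                        mat_scale.begin(), step_mm, kill_eV);
        } else if (P.in_sens(p)) dose_eV += Ek;
        // annihilation photons dropped (negligible local deposit)
        break;
      }
    }
  }
  return List::create(_["records"] = rec.to_matrix(), _["dose_eV"] = dose_eV,
                      _["n_compton"] = n_compton, _["n_pe"] = n_pe,
                      _["n_pair"] = n_pair,
                      _["n_primaries_interacted"] = n_interacted);
}
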