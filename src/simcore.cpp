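// Coarse-grained Langevin dynamics of sticker-spacer polymers.
//
// Stickers are point particles of type A or B on linear chains. Bonded
// neighbours interact through a finitely extensible stretchable bond;
// unlike-type stickers attract through a short-range cosine well that
// saturates one-to-one (same-type stickers repel through a WCA core, so a
// second partner cannot reach an occupied sticker); all distances use the
// minimum image in a periodic box. Integration is BAOAB Langevin
// splitting. A private counter-free xoshiro256** RNG keeps trajectories
// bitwise reproducible for a given seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG --
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    have_spare = false; spare = 0.0;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare; double spare;
  double gauss() {  // Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 2.0 * M_PI * v;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// --------------------------------------------------------- potentials --
struct FF { double K, R0, U0, r0, eps, sigma, rc; };

static FF readFF(const List &ff) {
  FF f;
  f.K = as<double>(ff["K"]);     f.R0 = as<double>(ff["R0"]);
  f.U0 = as<double>(ff["U0"]);   f.r0 = as<double>(ff["r0"]);
  f.eps = as<double>(ff["epsilon"]); f.sigma = as<double>(ff["sigma"]);
  f.rc = as<double>(ff["rc"]);
  return f;
}

static inline double u_bond(double r, const FF &f) {
  if (r >= f.R0) return R_PosInf;
  double x = r / f.R0;
  return -0.5 * f.K * f.R0 * f.R0 * std::log(1.0 - x * x);
}
// force scalar F(r) = -dU/dr; vector force on i is F(r)/r * (xi - xj)
static inline double f_bond(double r, const FF &f) {
  double x = r / f.R0;
  return -f.K * r / (1.0 - x * x);
}
static inline double u_attr(double r, const FF &f) {
  if (r >= f.r0) return 0.0;
  return -0.5 * f.U0 * (1.0 + std::cos(M_PI * r / f.r0));
}
static inline double f_attr(double r, const FF &f) {
  if (r >= f.r0) return 0.0;
  return -0.5 * f.U0 * (M_PI / f.r0) * std::sin(M_PI * r / f.r0);
}
static inline double u_rep(double r, const FF &f) {
  if (r > f.rc) return 0.0;
  double s6 = std::pow(f.sigma / r, 6.0);
  return 4.0 * f.eps * (s6 * s6 - s6) + f.eps;
}
static inline double f_rep(double r, const FF &f) {
  if (r > f.rc) return 0.0;
  double s6 = std::pow(f.sigma / r, 6.0);
  return 4.0 * f.eps * (12.0 * s6 * s6 - 6.0 * s6) / r;
}

// [[Rcpp::export]]
NumericVector bond_energy_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = u_bond(r[i], f);
  return out;
}
// [[Rcpp::export]]
NumericVector bond_force_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i)
    out[i] = (r[i] >= f.R0) ? R_NegInf : f_bond(r[i], f);
  return out;
}
// [[Rcpp::export]]
NumericVector attract_energy_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = u_attr(r[i], f);
  return out;
}
// [[Rcpp::export]]
NumericVector attract_force_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = f_attr(r[i], f);
  return out;
}
// [[Rcpp::export]]
NumericVector repulse_energy_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = u_rep(r[i], f);
  return out;
}
// [[Rcpp::export]]
NumericVector repulse_force_cpp(NumericVector r, List ff) {
  FF f = readFF(ff);
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = f_rep(r[i], f);
  return out;
}

// ----------------------------------------------------------- geometry --
static inline double mind(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

struct System {
  int n;
  std::vector<double> x, y, z;      // wrapped positions
  std::vector<int> ix, iy, iz;      // image counts
  std::vector<int> type, mol;       // 1/2, 1-based molecule id
  double Lx, Ly, Lz;
  std::vector<int> bond_i, bond_j;  // chain bonds
  void wrap(int i) {
    if (x[i] < 0 || x[i] >= Lx) { double s = std::floor(x[i] / Lx); x[i] -= s * Lx; ix[i] += (int)s; }
    if (y[i] < 0 || y[i] >= Ly) { double s = std::floor(y[i] / Ly); y[i] -= s * Ly; iy[i] += (int)s; }
    if (z[i] < 0 || z[i] >= Lz) { double s = std::floor(z[i] / Lz); z[i] -= s * Lz; iz[i] += (int)s; }
  }
  inline void dvec(int i, int j, double &dx, double &dy, double &dz, double &r2) const {
    dx = mind(x[i] - x[j], Lx); dy = mind(y[i] - y[j], Ly); dz = mind(z[i] - z[j], Lz);
    r2 = dx * dx + dy * dy + dz * dz;
  }
};

static System makeSystem(const NumericMatrix &pos, const IntegerMatrix &img,
                         const IntegerVector &type, const IntegerVector &mol,
                         const NumericVector &box) {
  System s;
  s.n = pos.nrow();
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2];
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.ix.resize(s.n); s.iy.resize(s.n); s.iz.resize(s.n);
  s.type.resize(s.n); s.mol.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.ix[i] = img(i, 0); s.iy[i] = img(i, 1); s.iz[i] = img(i, 2);
    s.type[i] = type[i]; s.mol[i] = mol[i];
    s.wrap(i);
  }
  for (int i = 0; i + 1 < s.n; ++i)
    if (s.mol[i] == s.mol[i + 1]) { s.bond_i.push_back(i); s.bond_j.push_back(i + 1); }
  return s;
}

// Cell list over the periodic box; falls back to an all-pairs loop when the
// box is too small for 3 cells in every direction.
// linked-cell list (head/next arrays): O(ncells + N) rebuild per step
struct CellList {
  int ncx, ncy, ncz;
  bool brute;
  std::vector<int> head, nxt, cell_of;
  void build(const System &s, double cutoff) {
    ncx = std::max(1, (int)(s.Lx / cutoff));
    ncy = std::max(1, (int)(s.Ly / cutoff));
    ncz = std::max(1, (int)(s.Lz / cutoff));
    brute = (ncx < 3 || ncy < 3 || ncz < 3);
    if (brute) return;
    head.assign((size_t)ncx * ncy * ncz, -1);
    nxt.assign(s.n, -1);
    cell_of.assign(s.n, 0);
    for (int i = 0; i < s.n; ++i) {
      int cx = std::min(ncx - 1, (int)(s.x[i] / s.Lx * ncx));
      int cy = std::min(ncy - 1, (int)(s.y[i] / s.Ly * ncy));
      int cz = std::min(ncz - 1, (int)(s.z[i] / s.Lz * ncz));
      int c = (cx * ncy + cy) * ncz + cz;
      cell_of[i] = c;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  template <class Fun>
  void forPairs(const System &s, double cutoff, Fun fun) const {
    double cut2 = cutoff * cutoff;
    double dx, dy, dz, r2;
    if (brute) {
      for (int i = 0; i < s.n; ++i)
        for (int j = i + 1; j < s.n; ++j) {
          s.dvec(i, j, dx, dy, dz, r2);
          if (r2 < cut2) fun(i, j, dx, dy, dz, std::sqrt(r2));
        }
      return;
    }
    // iterate over particles, scanning the 27 neighbouring cells of each
    // occupied cell; a pair is visited once via (cell,id) ordering
    for (int i = 0; i < s.n; ++i) {
      int c = cell_of[i];
      int cz = c % ncz, cy = (c / ncz) % ncy, cx = c / (ncz * ncy);
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int nx = (cx + ox + ncx) % ncx;
            int ny = (cy + oy + ncy) % ncy;
            int nz = (cz + oz + ncz) % ncz;
            int c1 = (nx * ncy + ny) * ncz + nz;
            if (c1 < c) continue;
            for (int j = head[c1]; j != -1; j = nxt[j]) {
              if (c1 == c && j <= i) continue;
              s.dvec(i, j, dx, dy, dz, r2);
              if (r2 < cut2) fun(i, j, dx, dy, dz, std::sqrt(r2));
            }
          }
    }
  }
};

// nonbonded + bond forces; returns potential energy
static double computeForces(const System &s, const FF &f,
                            std::vector<double> &fx, std::vector<double> &fy,
                            std::vector<double> &fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double cutoff = std::max(f.rc, f.r0);
  CellList cl; cl.build(s, cutoff);
  double pe = 0.0;
  cl.forPairs(s, cutoff, [&](int i, int j, double dx, double dy, double dz, double r) {
    double fs = 0.0;
    if (s.type[i] != s.type[j]) {
      if (r < f.r0) { pe += u_attr(r, f); fs = f_attr(r, f); }
    } else {
      if (r <= f.rc) { pe += u_rep(r, f); fs = f_rep(r, f); }
    }
    if (fs != 0.0 && r > 1e-12) {
      double c = fs / r;
      fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
    }
  });
  for (size_t b = 0; b < s.bond_i.size(); ++b) {
    int i = s.bond_i[b], j = s.bond_j[b];
    double dx, dy, dz, r2;
    s.dvec(i, j, dx, dy, dz, r2);
    double r = std::sqrt(r2);
    if (r >= f.R0)
      stop("bond %d-%d stretched to %.3f nm (>= R0 = %.3f): unstable; reduce dt",
           i + 1, j + 1, r, f.R0);
    pe += u_bond(r, f);
    double c = f_bond(r, f) / std::max(r, 1e-12);
    fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
    fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
  }
  return pe;
}

// [[Rcpp::export]]
double potential_energy_cpp(NumericMatrix pos, IntegerMatrix img,
                            IntegerVector type, IntegerVector mol,
                            NumericVector box, List ff) {
  System s = makeSystem(pos, img, type, mol, box);
  FF f = readFF(ff);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  return computeForces(s, f, fx, fy, fz);
}

// [[Rcpp::export]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerMatrix img,
                         IntegerVector type, IntegerVector mol,
                         NumericVector box, List ff) {
  System s = makeSystem(pos, img, type, mol, box);
  FF f = readFF(ff);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  computeForces(s, f, fx, fy, fz);
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) { out(i,0)=fx[i]; out(i,1)=fy[i]; out(i,2)=fz[i]; }
  return out;
}

// BAOAB Langevin integrator (gamma = 0, kBT = 0 reduces to velocity Verlet)
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix pos, NumericMatrix vel, IntegerMatrix img,
                      IntegerVector type, IntegerVector mol, NumericVector box,
                      List ff, int n_steps, double dt, double kBT, double gamma,
                      double mass, double seed, int record_every,
                      double time0) {
  System s = makeSystem(pos, img, type, mol, box);
  FF f = readFF(ff);
  int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { vx[i]=vel(i,0); vy[i]=vel(i,1); vz[i]=vel(i,2); }
  Xoshiro rng((uint64_t)seed);
  double c1 = (gamma > 0) ? std::exp(-gamma * dt / mass) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt(kBT / mass * (1.0 - c1 * c1))
                          : std::sqrt(kBT / mass * 2.0 * gamma * dt / mass); // 0 if gamma=0
  int nrec = n_steps / record_every;
  NumericVector rtimes(nrec);
  Dimension dim(n, 3, nrec);
  NumericVector rpos(dim);
  IntegerVector rimg(dim);
  NumericVector rpe(nrec), rke(nrec);

  double pe = computeForces(s, f, fx, fy, fz);
  double half = 0.5 * dt / mass;
  int irec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {       // B
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
    }
    for (int i = 0; i < n; ++i) {       // A
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
      s.wrap(i);
    }
    if (gamma > 0) {                    // O
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * rng.gauss();
        vy[i] = c1 * vy[i] + c2 * rng.gauss();
        vz[i] = c1 * vz[i] + c2 * rng.gauss();
      }
    }
    for (int i = 0; i < n; ++i) {       // A
      s.x[i] += 0.5 * dt * vx[i]; s.y[i] += 0.5 * dt * vy[i]; s.z[i] += 0.5 * dt * vz[i];
      s.wrap(i);
    }
    pe = computeForces(s, f, fx, fy, fz);
    for (int i = 0; i < n; ++i) {       // B
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
    }
    if (step % record_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
      if (!std::isfinite(pe) || !std::isfinite(ke))
        stop("energy diverged at step %d: reduce dt", step);
      rtimes[irec] = time0 + step * dt;
      for (int i = 0; i < n; ++i) {
        rpos[irec * 3 * n + 0 * n + i] = s.x[i];
        rpos[irec * 3 * n + 1 * n + i] = s.y[i];
        rpos[irec * 3 * n + 2 * n + i] = s.z[i];
        rimg[irec * 3 * n + 0 * n + i] = s.ix[i];
        rimg[irec * 3 * n + 1 * n + i] = s.iy[i];
        rimg[irec * 3 * n + 2 * n + i] = s.iz[i];
      }
      rpe[irec] = pe; rke[irec] = ke;
      ++irec;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix fpos(n, 3), fvel(n, 3);
  IntegerMatrix fimg(n, 3);
  for (int i = 0; i < n; ++i) {
    fpos(i,0)=s.x[i]; fpos(i,1)=s.y[i]; fpos(i,2)=s.z[i];
    fvel(i,0)=vx[i];  fvel(i,1)=vy[i];  fvel(i,2)=vz[i];
    fimg(i,0)=s.ix[i]; fimg(i,1)=s.iy[i]; fimg(i,2)=s.iz[i];
  }
  return List::create(_["times"] = rtimes, _["pos"] = rpos, _["img"] = rimg,
                      _["pe"] = rpe, _["ke"] = rke,
                      _["final_pos"] = fpos, _["final_vel"] = fvel,
                      _["final_img"] = fimg, _["final_time"] = time0 + n_steps * dt);
}

// Soft steepest-descent relaxation of overlaps (repulsion + bonds only;
// the attraction is left out so freshly placed chains are not glued)
// [[Rcpp::export]]
List minimize_cpp(NumericMatrix pos, IntegerMatrix img, IntegerVector type,
                  IntegerVector mol, NumericVector box, List ff,
                  int n_iter, double max_disp) {
  System s = makeSystem(pos, img, type, mol, box);
  FF f = readFF(ff);
  FF fr = f; fr.U0 = 0.0;           // disable attraction
  int n = s.n;
  std::vector<double> fx(n), fy(n), fz(n);
  for (int it = 0; it < n_iter; ++it) {
    computeForces(s, fr, fx, fy, fz);
    for (int i = 0; i < n; ++i) {
      double fm = std::sqrt(fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i]);
      double sc = (fm > 0) ? std::min(max_disp / fm, 0.02) : 0.0;
      s.x[i] += sc * fx[i]; s.y[i] += sc * fy[i]; s.z[i] += sc * fz[i];
      s.wrap(i);
    }
  }
  NumericMatrix fpos(n, 3);
  IntegerMatrix fimg(n, 3);
  for (int i = 0; i < n; ++i) {
    fpos(i,0)=s.x[i]; fpos(i,1)=s.y[i]; fpos(i,2)=s.z[i];
    fimg(i,0)=s.ix[i]; fimg(i,1)=s.iy[i]; fimg(i,2)=s.iz[i];
  }
  return List::create(_["pos"] = fpos, _["img"] = fimg);
}

// Mean lifetime of the A-B bond of an isolated pair: one A and one B
// sticker in a small periodic box; a bond exists while r < r0.
// [[Rcpp::export]]
List pair_lifetime_cpp(List ff, double boxL, double dt, double kBT,
                       double gamma, double mass, double seed,
                       int n_events, double max_steps) {
  FF f = readFF(ff);
  Xoshiro rng((uint64_t)seed);
  double x[2][3];
  double v[2][3];
  // start bonded: B at a small offset from A
  x[0][0] = boxL/2; x[0][1] = boxL/2; x[0][2] = boxL/2;
  x[1][0] = boxL/2 + 0.3 * f.r0; x[1][1] = boxL/2; x[1][2] = boxL/2;
  for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k)
    v[p][k] = std::sqrt(kBT / mass) * rng.gauss();
  double c1 = std::exp(-gamma * dt / mass);
  double c2 = std::sqrt(kBT / mass * (1.0 - c1 * c1));
  double half = 0.5 * dt / mass;
  std::vector<double> lifetimes;
  bool bonded = true;
  double bond_start = 0.0, t = 0.0;
  double fvec[2][3];
  auto force = [&](void) {
    double dx = mind(x[0][0]-x[1][0], boxL);
    double dy = mind(x[0][1]-x[1][1], boxL);
    double dz = mind(x[0][2]-x[1][2], boxL);
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double fs = (r < f.r0) ? f_attr(r, f) : 0.0;
    double c = (r > 1e-12) ? fs / r : 0.0;
    fvec[0][0] = c*dx; fvec[0][1] = c*dy; fvec[0][2] = c*dz;
    fvec[1][0] = -c*dx; fvec[1][1] = -c*dy; fvec[1][2] = -c*dz;
    return r;
  };
  force();
  double steps = 0;
  while ((int)lifetimes.size() < n_events && steps < max_steps) {
    for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k) v[p][k] += half * fvec[p][k];
    for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k) {
      x[p][k] += 0.5 * dt * v[p][k];
      x[p][k] -= boxL * std::floor(x[p][k] / boxL);
    }
    for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k)
      v[p][k] = c1 * v[p][k] + c2 * rng.gauss();
    for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k) {
      x[p][k] += 0.5 * dt * v[p][k];
      x[p][k] -= boxL * std::floor(x[p][k] / boxL);
    }
    double r = force();
    for (int p = 0; p < 2; ++p) for (int k = 0; k < 3; ++k) v[p][k] += half * fvec[p][k];
    t += dt; steps += 1;
    bool now = (r < f.r0);
    if (now && !bonded) { bonded = true; bond_start = t; }
    else if (!now && bonded) { bonded = false; lifetimes.push_back(t - bond_start); }
    if (((long long)steps) % 100000LL == 0) Rcpp::checkUserInterrupt();
  }
  if (lifetimes.empty())
    stop("no complete bond intervals observed within max_steps");
  return List::create(_["lifetimes"] = wrap(lifetimes),
                      _["total_time"] = t,
                      _["n_events"] = (int)lifetimes.size());
}

// ------------------------------------------------------ trajectory ops --
// sticker pairs within cutoff (optionally only unlike types)
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cpp(NumericMatrix pos, IntegerVector type,
                                IntegerVector mol, NumericVector box,
                                double cutoff, bool unlike_only) {
  IntegerMatrix img(pos.nrow(), 3);
  System s = makeSystem(pos, img, type, mol, box);
  CellList cl; cl.build(s, cutoff);
  std::vector<int> pi, pj;
  cl.forPairs(s, cutoff, [&](int i, int j, double, double, double, double) {
    if (unlike_only && s.type[i] == s.type[j]) return;
    pi.push_back(i + 1); pj.push_back(j + 1);
  });
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k,0) = pi[k]; out(k,1) = pj[k]; }
  return out;
}

// connected components over polymers: stickers connect if on the same
// chain or within cutoff (any type); labels sorted by decreasing size
// [[Rcpp::export]]
IntegerVector cluster_polymers_cpp(NumericMatrix pos, IntegerVector type,
                                   IntegerVector mol, NumericVector box,
                                   double cutoff) {
  IntegerMatrix img(pos.nrow(), 3);
  System s = makeSystem(pos, img, type, mol, box);
  int nmol = 0;
  for (int i = 0; i < s.n; ++i) nmol = std::max(nmol, s.mol[i]);
  std::vector<int> parent(nmol);
  for (int m = 0; m < nmol; ++m) parent[m] = m;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  CellList cl; cl.build(s, cutoff);
  cl.forPairs(s, cutoff, [&](int i, int j, double, double, double, double) {
    int a = find(s.mol[i] - 1), b = find(s.mol[j] - 1);
    if (a != b) parent[a] = b;
  });
  std::vector<int> root(nmol), count(nmol, 0);
  for (int m = 0; m < nmol; ++m) { root[m] = find(m); count[root[m]]++; }
  // rank roots by decreasing cluster size (ties: lower root id first)
  std::vector<int> order;
  for (int m = 0; m < nmol; ++m) if (count[m] > 0) order.push_back(m);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (count[a] != count[b]) return count[a] > count[b];
    return a < b;
  });
  std::vector<int> label(nmol);
  for (size_t k = 0; k < order.size(); ++k) label[order[k]] = (int)k + 1;
  IntegerVector out(nmol);
  for (int m = 0; m < nmol; ++m) out[m] = label[root[m]];
  return out;
}
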