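// Langevin-dynamics engine for pili-driven twitching bacilliforms.
//
// Each twitcher is a stiff chain of four spheres (WCA excluded volume between
// all pairs, FENE bonds, harmonic angle rigidity) in a 2D periodic box,
// integrated with a BAOAB underdamped Langevin scheme (exact OU drag).
// Motility is a rule-based cycle: REST -(p per tau)-> EXTENSION -(10 tau)->
// RETRACTION, where a dummy pilus anchor a distance L0 ahead (within a cone)
// pulls the head with constant force kP until the head arrives (r < LR), the
// pilus snaps (r > LS) or the adhesion is exhausted (t >= tM).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <string>
#include <algorithm>
#include <chrono>
using namespace Rcpp;

static inline double now_s() {
  return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
}

// ---------------------------------------------------------------- RNG ------

// xoshiro256++ seeded through splitmix64; one stream per run.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double unif_open() {  // (0, 1), safe for log()
    for (;;) { double u = unif(); if (u > 0.0) return u; }
  }

  // 128-layer Marsaglia-Tsang ziggurat for the standard normal.
  // Tables are built at construction from the published base constants;
  // the fast-accept test is done on the raw integer mantissa.
  double zx[129], zy[129], zw[128], zbase_w, zR;
  uint64_t zk[128];
  void zig_init() {
    const double R = 3.442619855899;          // base strip x
    const double V = 9.91256303526217e-3;     // common strip area
    zR = R;
    zx[0] = R;
    zy[0] = std::exp(-0.5 * R * R);
    zbase_w = V / zy[0];
    for (int i = 1; i <= 128; ++i) {
      double y = zy[i - 1] + V / zx[i - 1];
      if (y >= 1.0) { zy[i] = 1.0; zx[i] = 0.0; }
      else { zy[i] = y; zx[i] = std::sqrt(-2.0 * std::log(y)); }
    }
    zx[128] = 0.0; zy[128] = 1.0;
    // strip i (1..127): width zx[i-1], sampled as x = v * zw[i] with
    // v the signed 53-bit mantissa; fast accept while |x| < zx[i].
    zw[0] = zbase_w * 0x1.0p-52;
    zk[0] = (uint64_t)(zR / zbase_w * 0x1.0p52);
    for (int i = 1; i < 128; ++i) {
      zw[i] = zx[i - 1] * 0x1.0p-52;
      zk[i] = (uint64_t)(zx[i] / zx[i - 1] * 0x1.0p52);
    }
  }
  inline double norm() {
    for (;;) {
      const uint64_t r = next();
      const int i = (int)(r & 127);
      const int64_t v = (int64_t)r >> 11;    // signed 53-bit
      const uint64_t av = (uint64_t)(v < 0 ? -v : v);
      if (av < zk[i]) return v * zw[i];      // inside the next strip
      if (i == 0) {
        const double x = v * zw[0];
        // exact tail beyond R
        const double sgn = (x < 0.0) ? -1.0 : 1.0;
        double a, b;
        do {
          a = -std::log(unif_open()) / zR;
          b = -std::log(unif_open());
        } while (b + b < a * a);
        return sgn * (zR + a);
      }
      const double x = v * zw[i];
      const double y = zy[i - 1] + unif() * (zy[i] - zy[i - 1]);
      if (y < std::exp(-0.5 * x * x)) return x;
    }
  }
};

// ------------------------------------------------------------- params ------

struct Par {
  double sigma, mass, eps, T, zeta, dt, boxL;
  double rc, R0, kF, kH, Lbody, kP, r0, L0, LR, LS, tM;
  double restp, extdur, cone;
  int spt, N;
};

static Par load_par(const List& P) {
  Par p;
  p.sigma = as<double>(P["sigma"]);
  p.mass = as<double>(P["mass"]);
  p.eps = as<double>(P["epsilon"]);
  p.T = as<double>(P["temperature"]);
  p.zeta = as<double>(P["zeta"]);
  p.dt = as<double>(P["dt"]);
  p.boxL = as<double>(P["box_L"]);
  p.rc = as<double>(P["wca_cutoff"]);
  p.R0 = as<double>(P["fene_R0"]);
  p.kF = as<double>(P["fene_kF"]);
  p.kH = as<double>(P["angle_kH"]);
  p.Lbody = as<double>(P["body_length"]);
  p.kP = as<double>(P["pilus_kP"]);
  p.r0 = as<double>(P["pilus_r0"]);
  p.L0 = as<double>(P["pilus_L0"]);
  p.LR = as<double>(P["arrive_LR"]);
  p.LS = as<double>(P["snap_LS"]);
  p.tM = as<double>(P["exhaust_tM"]);
  p.restp = as<double>(P["rest_exit_prob"]);
  p.extdur = as<double>(P["extension_duration"]);
  p.cone = as<double>(P["cone_half_angle"]);
  p.spt = as<int>(P["steps_per_tau"]);
  p.N = as<int>(P["n_twitchers"]);
  return p;
}

// ------------------------------------------------------ force kernels ------

// WCA: V = 4 eps [(s/r)^12 - (s/r)^6] + eps for r < rc, else 0.
static inline void wca_vf(double r2, double sigma2, double eps,
                          double& V, double& f_over_r) {
  const double s2 = sigma2 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
  V = 4.0 * eps * (s12 - s6) + eps;
  f_over_r = eps * (48.0 * s12 - 24.0 * s6) / r2;  // repulsive, along r_ij
}

// FENE: V = -1/2 kF R0^2 ln(1 - (r/R0)^2); attractive.
static inline double fene_k(double r2, double R02, double kF) {
  return kF / (1.0 - r2 / R02);  // force on i = +k * (r_j - r_i)
}

// signed turning angle atan2(cr, dt). Rods are stiff, so |phi| is small
// almost always: use the atan Taylor series there (|rel err| < 4e-10 for
// |z| <= 0.2, evaluated in Estrin form for latency), fall back to atan2
// for strongly bent triples.
static inline double turn_angle(double cr, double dt) {
  const double acr = std::fabs(cr);
  if (dt > 5.0 * acr) {  // |z| < 0.2
    const double z = cr / dt, t = z * z, t2 = t * t;
    const double c01 = 1.0 + t * (-1.0 / 3);
    const double c23 = 1.0 / 5 + t * (-1.0 / 7);
    const double c45 = 1.0 / 9 + t * (-1.0 / 11);
    return z * (c01 + t2 * (c23 + t2 * c45));
  }
  return std::atan2(cr, dt);
}

// phases
enum { REST = 0, EXT = 1, RETR = 2 };
enum { EV_REST_EXIT = 0, EV_ANCHOR = 1, EV_ARRIVE = 2, EV_SNAP = 3,
       EV_EXHAUST = 4 };

// ------------------------------------------------------------- system ------

struct System {
  Par p;
  int ns;                       // 4 * N spheres
  double halfL, sigma2, R02, rc2;
  std::vector<double> xw, yw, xu, yu, vx, vy, fx, fy;
  std::vector<int> phase;
  std::vector<double> clk, ax, ay;  // phase clock; anchor (wrapped coords)
  // Verlet pair list with baked minimum-image shifts
  double skin, rv2;
  std::vector<int> pairs;       // flat (i, j)
  std::vector<double> pshift;   // flat (sx, sy) per pair
  std::vector<double> disp_acc; // per-sphere |displacement| since rebuild
  std::vector<int> cstart, corder, ccell, cfill;  // cell scratch
  double acc_disp;

  void setup(const Par& pp) {
    p = pp;
    ns = 4 * p.N;
    halfL = 0.5 * p.boxL;
    sigma2 = p.sigma * p.sigma;
    R02 = p.R0 * p.R0;
    rc2 = p.rc * p.rc;
    skin = 0.25 * p.sigma;
    const double rv = p.rc + skin;
    rv2 = rv * rv;
    xw.assign(ns, 0.0); yw.assign(ns, 0.0);
    xu.assign(ns, 0.0); yu.assign(ns, 0.0);
    vx.assign(ns, 0.0); vy.assign(ns, 0.0);
    fx.assign(ns, 0.0); fy.assign(ns, 0.0);
    disp_acc.assign(ns, 0.0);
    phase.assign(p.N, REST);
    clk.assign(p.N, 0.0);
    ax.assign(p.N, 0.0); ay.assign(p.N, 0.0);
    acc_disp = 1e30;  // force initial build
  }

  inline double mi(double d) const {
    if (d > halfL) return d - p.boxL;
    if (d < -halfL) return d + p.boxL;
    return d;
  }
  inline double wrap(double x) const {
    x -= p.boxL * std::floor(x / p.boxL);
    return (x >= p.boxL) ? x - p.boxL : x;  // guard the x/L rounding edge
  }

  void build_pairs() {
    pairs.clear();
    const double rv = p.rc + skin;
    int nc = (int)std::floor(p.boxL / rv);
    pshift.clear();
    if (nc < 4) {  // box too small for cells: brute force candidates
      for (int i = 0; i < ns; ++i)
        for (int j = i + 1; j < ns; ++j) {
          const double rx = xw[i] - xw[j], ry = yw[i] - yw[j];
          const double dx = mi(rx), dy = mi(ry);
          if (dx * dx + dy * dy < rv2) {
            pairs.push_back(i); pairs.push_back(j);
            pshift.push_back(dx - rx); pshift.push_back(dy - ry);
          }
        }
      std::fill(disp_acc.begin(), disp_acc.end(), 0.0);
      acc_disp = 0.0;
      return;
    }
    const double cw = p.boxL / nc;
    // counting sort of spheres into cells for contiguous traversal
    cstart.assign(nc * nc + 1, 0);
    corder.resize(ns);
    ccell.resize(ns);
    for (int i = 0; i < ns; ++i) {
      int cx = (int)(xw[i] / cw), cy = (int)(yw[i] / cw);
      if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1;
      if (cx < 0) cx = 0; if (cy < 0) cy = 0;
      const int c = cx + nc * cy;
      ccell[i] = c;
      ++cstart[c + 1];
    }
    for (int c = 0; c < nc * nc; ++c) cstart[c + 1] += cstart[c];
    {
      std::vector<int>& fill = cfill;
      fill.assign(nc * nc, 0);
      for (int i = 0; i < ns; ++i)
        corder[cstart[ccell[i]] + fill[ccell[i]]++] = i;
    }
    // half stencil: self, E, N, NE, NW
    const int offs[4][2] = {{1, 0}, {0, 1}, {1, 1}, {-1, 1}};
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        const int c = cx + nc * cy;
        const int a0 = cstart[c], a1 = cstart[c + 1];
        // within the cell
        for (int a = a0; a < a1; ++a)
          for (int b = a + 1; b < a1; ++b)
            try_pair(corder[a], corder[b]);
        for (int o = 0; o < 4; ++o) {
          const int ox = (cx + offs[o][0] + nc) % nc;
          const int oy = (cy + offs[o][1] + nc) % nc;
          const int c2 = ox + nc * oy;
          const int b0 = cstart[c2], b1 = cstart[c2 + 1];
          for (int a = a0; a < a1; ++a)
            for (int b = b0; b < b1; ++b)
              try_pair(corder[a], corder[b]);
        }
      }
    std::fill(disp_acc.begin(), disp_acc.end(), 0.0);
    acc_disp = 0.0;
  }

  inline void try_pair(int i, int j) {
    const double rx = xw[i] - xw[j], ry = yw[i] - yw[j];
    const double dx = mi(rx), dy = mi(ry);
    if (dx * dx + dy * dy < rv2) {
      pairs.push_back(i); pairs.push_back(j);
      pshift.push_back(dx - rx); pshift.push_back(dy - ry);
    }
  }

  // forces at current positions, accumulated into zeroed fx/fy; returns
  // false on bond overstretch
  bool forces(std::string& err, long step) {
    // WCA over the candidate pair list (image shifts baked at build time)
    const size_t np = pairs.size();
    for (size_t k = 0; k < np; k += 2) {
      const int i = pairs[k], j = pairs[k + 1];
      const double dx = xw[i] - xw[j] + pshift[k];
      const double dy = yw[i] - yw[j] + pshift[k + 1];
      const double r2 = dx * dx + dy * dy;
      if (r2 < rc2) {
        const double inv_r2 = 1.0 / r2;
        const double s2 = sigma2 * inv_r2, s6 = s2 * s2 * s2;
        const double fr = p.eps * 24.0 * s6 * (2.0 * s6 - 1.0) * inv_r2;
        fx[i] += fr * dx; fy[i] += fr * dy;
        fx[j] -= fr * dx; fy[j] -= fr * dy;
      }
    }
    // bonded terms per twitcher; bodies are contiguous in unwrapped
    // coordinates so no minimum image is needed within a twitcher
    for (int g = 0; g < p.N; ++g) {
      const int b = 4 * g;
      for (int i = b; i < b + 3; ++i) {
        const double dx = xu[i + 1] - xu[i], dy = yu[i + 1] - yu[i];
        const double r2 = dx * dx + dy * dy;
        if (r2 >= R02) {
          err = "FENE bond overstretched (twitcher " + std::to_string(g + 1) +
                ", step " + std::to_string(step) + ", r = " +
                std::to_string(std::sqrt(r2)) + ")";
          return false;
        }
        const double kk = fene_k(r2, R02, p.kF);
        fx[i] += kk * dx; fy[i] += kk * dy;
        fx[i + 1] -= kk * dx; fy[i + 1] -= kk * dy;
      }
      for (int i = b; i < b + 2; ++i) {
        // signed turning angle phi; V = kH phi^2 / 2 (theta0 = pi)
        const double b1x = xu[i + 1] - xu[i], b1y = yu[i + 1] - yu[i];
        const double b2x = xu[i + 2] - xu[i + 1],
                     b2y = yu[i + 2] - yu[i + 1];
        const double cr = b1x * b2y - b1y * b2x, dt_ = b1x * b2x + b1y * b2y;
        const double phi = turn_angle(cr, dt_);
        const double r1s = b1x * b1x + b1y * b1y,
                     r2s = b2x * b2x + b2y * b2y;
        const double a1 = p.kH * phi / r1s, a2 = p.kH * phi / r2s;
        const double fix = a1 * b1y, fiy = -a1 * b1x;
        const double fkx = a2 * b2y, fky = -a2 * b2x;
        fx[i] += fix; fy[i] += fiy;
        fx[i + 2] += fkx; fy[i + 2] += fky;
        fx[i + 1] -= fix + fkx; fy[i + 1] -= fiy + fky;
      }
    }
    // pilus force on retracting heads
    for (int g = 0; g < p.N; ++g) {
      if (phase[g] != RETR) continue;
      const int h = 4 * g + 3;
      const double dx = mi(ax[g] - xw[h]), dy = mi(ay[g] - yw[h]);
      const double r = std::sqrt(dx * dx + dy * dy);
      if (r > p.r0) {
        fx[h] += p.kP * dx / r; fy[h] += p.kP * dy / r;
      }
    }
    return true;
  }

  double potential_energy() const {
    double V = 0.0;
    // all-pairs WCA (brute; used only for sampled-frame diagnostics)
    for (int i = 0; i < ns; ++i)
      for (int j = i + 1; j < ns; ++j) {
        const double dx = mi(xw[i] - xw[j]), dy = mi(yw[i] - yw[j]);
        const double r2 = dx * dx + dy * dy;
        if (r2 < rc2) { double v, fr; wca_vf(r2, sigma2, p.eps, v, fr); V += v; }
      }
    for (int g = 0; g < p.N; ++g) {
      const int b = 4 * g;
      for (int i = b; i < b + 3; ++i) {
        const double dx = mi(xw[i + 1] - xw[i]), dy = mi(yw[i + 1] - yw[i]);
        const double r2 = dx * dx + dy * dy;
        V += -0.5 * p.kF * R02 * std::log(1.0 - r2 / R02);
      }
      for (int i = b; i < b + 2; ++i) {
        const double b1x = mi(xw[i + 1] - xw[i]), b1y = mi(yw[i + 1] - yw[i]);
        const double b2x = mi(xw[i + 2] - xw[i + 1]),
                     b2y = mi(yw[i + 2] - yw[i + 1]);
        const double phi = std::atan2(b1x * b2y - b1y * b2x,
                                      b1x * b2x + b1y * b2y);
        V += 0.5 * p.kH * phi * phi;
      }
    }
    return V;
  }
  double kinetic_energy() const {
    double K = 0.0;
    for (int i = 0; i < ns; ++i) K += vx[i] * vx[i] + vy[i] * vy[i];
    return 0.5 * p.mass * K;
  }
};

// equilibrium bond length of combined WCA + FENE (bracketing bisection)
static double bond_equilibrium(const Par& p) {
  double lo = 0.8 * p.sigma, hi = p.rc;
  for (int it = 0; it < 200; ++it) {
    const double r = 0.5 * (lo + hi), r2 = r * r;
    double V, fr;
    wca_vf(r2, p.sigma * p.sigma, p.eps, V, fr);
    const double fnet = fr * r - fene_k(r2, p.R0 * p.R0, p.kF) * r;
    if (fnet > 0.0) lo = r; else hi = r;
  }
  return 0.5 * (lo + hi);
}

// --------------------------------------------------------------- init ------

static void place_rod(System& S, int g, double cx, double cy,
                      double ex, double ey, double req) {
  for (int o = 0; o < 4; ++o) {
    const int i = 4 * g + o;
    const double off = (o - 1.5) * req;
    S.xu[i] = cx + off * ex; S.yu[i] = cy + off * ey;
    S.xw[i] = S.wrap(S.xu[i]); S.yw[i] = S.wrap(S.yu[i]);
  }
}

static bool init_insertion(System& S, RNG& rng, double req, std::string& err) {
  const double min_d2 = 0.95 * 0.95 * S.sigma2;
  const long max_attempts = 50000;
  for (int g = 0; g < S.p.N; ++g) {
    bool placed = false;
    for (long a = 0; a < max_attempts; ++a) {
      const double cx = rng.unif() * S.p.boxL, cy = rng.unif() * S.p.boxL;
      const double th = rng.unif() * 2.0 * M_PI;
      const double ex = std::cos(th), ey = std::sin(th);
      bool ok = true;
      for (int o = 0; o < 4 && ok; ++o) {
        const double off = (o - 1.5) * req;
        const double px = S.wrap(cx + off * ex), py = S.wrap(cy + off * ey);
        for (int j = 0; j < 4 * g; ++j) {
          const double dx = S.mi(px - S.xw[j]), dy = S.mi(py - S.yw[j]);
          if (dx * dx + dy * dy < min_d2) { ok = false; break; }
        }
      }
      if (ok) { place_rod(S, g, cx, cy, ex, ey, req); placed = true; break; }
    }
    if (!placed) {
      err = "random insertion failed for twitcher " + std::to_string(g + 1) +
            "; use init = \"lattice\" for dense systems";
      return false;
    }
  }
  return true;
}

static bool init_lattice(System& S, RNG& rng, double req, std::string& err) {
  const double L = S.p.boxL;
  const int nx = std::max(1, (int)std::floor(L / (S.p.Lbody + 0.2)));
  const int ny = (int)std::ceil((double)S.p.N / nx);
  const double sy = L / ny, sx = L / nx;
  if (sy < 1.02 * S.p.sigma) {
    err = "lattice placement cannot fit the requested coverage";
    return false;
  }
  for (int g = 0; g < S.p.N; ++g) {
    const int ix = g % nx, iy = g / nx;
    const double cx = (ix + 0.5) * sx, cy = (iy + 0.5) * sy;
    const double dir = (rng.unif() < 0.5) ? 1.0 : -1.0;  // random polarity
    place_rod(S, g, cx, cy, dir, 0.0, req);
  }
  return true;
}

// ---------------------------------------------------------- simulation -----

struct Recorder {
  int F, N, ns;
  bool spheres, energy;
  NumericVector time, com, comw, vel, polar, anch;
  IntegerVector phase, phase0;
  NumericVector sphw, sphu, en;
  int f = 0;
  Recorder(int F_, int N_, int ns_, bool sph, bool ene)
    : F(F_), N(N_), ns(ns_), spheres(sph), energy(ene),
      time(F_), com(Dimension(F_, N_, 2)), comw(Dimension(F_, N_, 2)),
      vel(Dimension(F_, N_, 2)), polar(Dimension(F_, N_, 2)),
      anch(Dimension(F_, N_, 2)), phase(F_ * N_), phase0(F_ * N_),
      sphw(sph ? Dimension(F_, ns_, 2) : Dimension(1, 1, 1)),
      sphu(sph ? Dimension(F_, ns_, 2) : Dimension(1, 1, 1)),
      en(ene ? F_ : 1) {}
  inline void rec(System& S, double t, const std::vector<double>& cx,
                  const std::vector<double>& cy,
                  const std::vector<double>& vxc,
                  const std::vector<double>& vyc,
                  const std::vector<int>& ph0, bool have_vel) {
    time[f] = t;
    for (int n = 0; n < N; ++n) {
      com[f + F * n] = cx[n];
      com[f + F * (n + N)] = cy[n];
      comw[f + F * n] = S.wrap(cx[n]);
      comw[f + F * (n + N)] = S.wrap(cy[n]);
      vel[f + F * n] = have_vel ? vxc[n] : NA_REAL;
      vel[f + F * (n + N)] = have_vel ? vyc[n] : NA_REAL;
      const int hd = 4 * n + 3, tl = 4 * n;
      const double px = S.xu[hd] - S.xu[tl], py = S.yu[hd] - S.yu[tl];
      const double pr = std::sqrt(px * px + py * py);
      polar[f + F * n] = px / pr;
      polar[f + F * (n + N)] = py / pr;
      phase[f + F * n] = S.phase[n];
      phase0[f + F * n] = ph0[n];
      if (S.phase[n] == RETR) {
        anch[f + F * n] = S.ax[n]; anch[f + F * (n + N)] = S.ay[n];
      } else {
        anch[f + F * n] = NA_REAL; anch[f + F * (n + N)] = NA_REAL;
      }
    }
    if (spheres) {
      for (int i = 0; i < ns; ++i) {
        sphw[f + F * i] = S.xw[i]; sphw[f + F * (i + ns)] = S.yw[i];
        sphu[f + F * i] = S.xu[i]; sphu[f + F * (i + ns)] = S.yu[i];
      }
    }
    if (energy) en[f] = S.potential_energy() + S.kinetic_energy();
    ++f;
  }
};

// [[Rcpp::export]]
List sim_run_cpp(List P, int n_tau, double seed, int sample_every,
                 bool keep_spheres, bool record_events, bool record_energy,
                 std::string init_mode, int warmup_tau) {
  const Par p = load_par(P);
  System S; S.setup(p);
  RNG rng((uint64_t)seed); rng.zig_init();

  const double tau = p.dt * p.spt;
  const double req = bond_equilibrium(p);
  std::string err;

  // initial configuration
  const double A_tw = (p.Lbody - p.sigma) * p.sigma +
                      M_PI * 0.25 * p.sigma * p.sigma;
  const double phi = p.N * A_tw / (p.boxL * p.boxL);
  bool lattice = (init_mode == "lattice") ||
                 (init_mode == "auto" && phi > 0.3);
  bool ok = lattice ? init_lattice(S, rng, req, err)
                    : init_insertion(S, rng, req, err);
  if (!ok) stop(err);
  for (int g = 0; g < p.N; ++g) S.clk[g] = rng.unif() * 10.0 * tau;

  // integrator constants (BAOAB; exact Ornstein-Uhlenbeck drag)
  const double cO = std::exp(-p.zeta * p.dt / p.mass);
  const double sdO = std::sqrt(p.T / p.mass * (1.0 - cO * cO));
  const double hb = 0.5 * p.dt / p.mass, ha = 0.5 * p.dt;

  S.build_pairs();
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  if (!S.forces(err, 0)) stop(err);

  // per-twitcher com bookkeeping for per-tau velocities
  std::vector<double> cx(p.N), cy(p.N), pcx(p.N), pcy(p.N),
                      vtx(p.N, 0.0), vty(p.N, 0.0);
  std::vector<int> ph0(p.N);  // phase at start of current tau interval
  auto coms = [&](std::vector<double>& ox, std::vector<double>& oy) {
    for (int g = 0; g < p.N; ++g) {
      const int b = 4 * g;
      ox[g] = 0.25 * (S.xu[b] + S.xu[b + 1] + S.xu[b + 2] + S.xu[b + 3]);
      oy[g] = 0.25 * (S.yu[b] + S.yu[b + 1] + S.yu[b + 2] + S.yu[b + 3]);
    }
  };

  // event log
  std::vector<int> ev_tw, ev_kind;
  std::vector<double> ev_t;
  long counts[5] = {0, 0, 0, 0, 0};
  bool counting = false;

  const long total_rec = (long)n_tau * p.spt;
  const long total_warm = (long)warmup_tau * p.spt;
  const int F = n_tau / sample_every + 1;
  Recorder R(F, p.N, S.ns, keep_spheres, record_energy);

  long step_g = 0;  // global step counter for diagnostics
  double t_sweep = 0, t_pairs = 0, t_force = 0, t_mot = 0;
  auto run_block = [&](long nsteps, bool recording) {
    double t0_offset = 0.0;
    if (recording) {
      coms(pcx, pcy);
      for (int g = 0; g < p.N; ++g) ph0[g] = S.phase[g];
      coms(cx, cy);
      R.rec(S, 0.0, cx, cy, vtx, vty, ph0, false);
    }
    for (long s = 1; s <= nsteps; ++s) {
      ++step_g;
      // fused B-A-O-A sweep; wrapped coordinates are refreshed only at
      // pair-list rebuilds (a single minimum-image fold absorbs the drift)
      const double tt0 = now_s();
      double amax = 0.0;
      const double hac = ha * (1.0 + cO);
      // deterministic half of the sweep (vectorizable, no RNG)
      for (int i = 0; i < S.ns; ++i) {
        const double ux = S.vx[i] + hb * S.fx[i],
                     uy = S.vy[i] + hb * S.fy[i];
        S.fx[i] = 0.0; S.fy[i] = 0.0;
        const double dx = hac * ux, dy = hac * uy;
        S.xu[i] += dx; S.yu[i] += dy;
        S.xw[i] += dx; S.yw[i] += dy;
        S.vx[i] = cO * ux; S.vy[i] = cO * uy;
        S.disp_acc[i] += std::fabs(dx) + std::fabs(dy);
      }
      if (sdO > 0.0) {  // Ornstein-Uhlenbeck noise kicks
        for (int i = 0; i < S.ns; ++i) {
          const double nx = sdO * rng.norm(), ny = sdO * rng.norm();
          S.vx[i] += nx; S.vy[i] += ny;
          const double dx = ha * nx, dy = ha * ny;
          S.xu[i] += dx; S.yu[i] += dy;
          S.xw[i] += dx; S.yw[i] += dy;
          const double a = (S.disp_acc[i] += std::fabs(dx) + std::fabs(dy));
          if (a > amax) amax = a;
        }
      } else {
        for (int i = 0; i < S.ns; ++i)
          if (S.disp_acc[i] > amax) amax = S.disp_acc[i];
      }
      const double tt1 = now_s();
      if (amax > 0.5 * S.skin) {
        for (int i = 0; i < S.ns; ++i) {
          S.xw[i] = S.wrap(S.xu[i]); S.yw[i] = S.wrap(S.yu[i]);
        }
        S.build_pairs();
      }
      const double tt2 = now_s();
      if (!S.forces(err, step_g)) stop(err);
      // B
      for (int i = 0; i < S.ns; ++i) { S.vx[i] += hb * S.fx[i]; S.vy[i] += hb * S.fy[i]; }
      const double tt3 = now_s();
      t_sweep += tt1 - tt0; t_pairs += tt2 - tt1; t_force += tt3 - tt2;

      const double tt4 = now_s();
      const double tnow = t0_offset + s * p.dt;
      // clocks and retraction termination (every integration step,
      // tie-break order: arrive > snap > exhaust)
      for (int g = 0; g < p.N; ++g) {
        S.clk[g] += p.dt;
        if (S.phase[g] != RETR) continue;
        const int h = 4 * g + 3;
        const double dx = S.mi(S.ax[g] - S.xw[h]), dy = S.mi(S.ay[g] - S.yw[h]);
        const double r = std::sqrt(dx * dx + dy * dy);
        int ev = -1;
        if (r < p.LR) ev = EV_ARRIVE;
        else if (r > p.LS) ev = EV_SNAP;
        else if (S.clk[g] >= p.tM - 0.5 * p.dt) ev = EV_EXHAUST;
        if (ev >= 0) {
          S.phase[g] = REST; S.clk[g] = 0.0;
          if (counting) {
            ++counts[ev];
            if (record_events) {
              ev_tw.push_back(g + 1); ev_kind.push_back(ev); ev_t.push_back(tnow);
            }
          }
        }
      }
      // tau boundary: motility draws (ordered by twitcher index) + sampling
      if (s % p.spt == 0) {
        for (int g = 0; g < p.N; ++g) {
          if (S.phase[g] == REST) {
            if (rng.unif() < p.restp) {
              S.phase[g] = EXT; S.clk[g] = 0.0;
              if (counting) {
                ++counts[EV_REST_EXIT];
                if (record_events) {
                  ev_tw.push_back(g + 1); ev_kind.push_back(EV_REST_EXIT);
                  ev_t.push_back(tnow);
                }
              }
            }
          } else if (S.phase[g] == EXT && S.clk[g] >= p.extdur - 0.5 * p.dt) {
            const int hd = 4 * g + 3, tl = 4 * g;
            double px = S.xu[hd] - S.xu[tl], py = S.yu[hd] - S.yu[tl];
            const double pr = std::sqrt(px * px + py * py);
            px /= pr; py /= pr;
            const double al = (2.0 * rng.unif() - 1.0) * p.cone;
            const double ca = std::cos(al), sa = std::sin(al);
            const double exr = ca * px - sa * py, eyr = sa * px + ca * py;
            S.ax[g] = S.wrap(S.xw[hd] + p.L0 * exr);
            S.ay[g] = S.wrap(S.yw[hd] + p.L0 * eyr);
            S.phase[g] = RETR; S.clk[g] = 0.0;
            if (counting) {
              ++counts[EV_ANCHOR];
              if (record_events) {
                ev_tw.push_back(g + 1); ev_kind.push_back(EV_ANCHOR);
                ev_t.push_back(tnow);
              }
            }
          }
        }
        // per-tau com/velocity bookkeeping
        coms(cx, cy);
        for (int g = 0; g < p.N; ++g) {
          vtx[g] = (cx[g] - pcx[g]) / tau; vty[g] = (cy[g] - pcy[g]) / tau;
        }
        if (recording) {
          const long tb = s / p.spt;
          // finiteness guard
          for (int g = 0; g < p.N; ++g)
            if (!std::isfinite(cx[g]) || !std::isfinite(cy[g]))
              stop("non-finite position (twitcher " + std::to_string(g + 1) +
                   ", step " + std::to_string(step_g) + ")");
          if (tb % sample_every == 0)
            R.rec(S, tb * tau, cx, cy, vtx, vty, ph0, true);
        }
        pcx = cx; pcy = cy;
        for (int g = 0; g < p.N; ++g) ph0[g] = S.phase[g];
      }
      t_mot += now_s() - tt4;
    }
  };

  if (total_warm > 0) run_block(total_warm, false);
  counting = true;
  run_block(total_rec, true);

  List events = List::create(_["twitcher"] = wrap(ev_tw),
                             _["kind"] = wrap(ev_kind),
                             _["time"] = wrap(ev_t));
  IntegerVector cnt = IntegerVector::create(
      _["rest_exit"] = (int)counts[0], _["anchor_placed"] = (int)counts[1],
      _["arrive"] = (int)counts[2], _["snap"] = (int)counts[3],
      _["exhaust"] = (int)counts[4]);

  List out = List::create(
      _["time"] = R.time, _["com"] = R.com, _["com_wrapped"] = R.comw,
      _["vel"] = R.vel, _["polar"] = R.polar, _["phase"] = R.phase,
      _["phase_start"] = R.phase0, _["anchor"] = R.anch,
      _["events"] = events, _["event_counts"] = cnt,
      _["bond_eq"] = req, _["frames"] = R.f,
      _["timing"] = NumericVector::create(_["sweep"] = t_sweep,
          _["rebuild"] = t_pairs, _["forces"] = t_force, _["motility"] = t_mot));
  if (keep_spheres) {
    out["spheres_wrapped"] = R.sphw;
    out["spheres_unwrapped"] = R.sphu;
  }
  if (record_energy) out["energy"] = R.en;
  return out;
}

// ------------------------------------------------- exported force API ------

// [[Rcpp::export]]
List wca_ef_cpp(NumericVector r, double sigma, double eps, double rc) {
  const int n = r.size();
  NumericVector V(n), f(n);
  for (int k = 0; k < n; ++k) {
    if (r[k] < rc) {
      double v, fr;
      wca_vf(r[k] * r[k], sigma * sigma, eps, v, fr);
      V[k] = v; f[k] = fr * r[k];
    } else { V[k] = 0.0; f[k] = 0.0; }
  }
  return List::create(_["energy"] = V, _["force"] = f);
}

// [[Rcpp::export]]
List fene_ef_cpp(NumericVector r, double R0, double kF) {
  const int n = r.size();
  NumericVector V(n), f(n);
  const double R02 = R0 * R0;
  for (int k = 0; k < n; ++k) {
    const double r2 = r[k] * r[k];
    V[k] = -0.5 * kF * R02 * std::log(1.0 - r2 / R02);
    f[k] = kF * r[k] / (1.0 - r2 / R02);  // magnitude of restoring force
  }
  return List::create(_["energy"] = V, _["force"] = f);
}

// [[Rcpp::export]]
List angle_ef_cpp(NumericMatrix xi, NumericMatrix xj, NumericMatrix xk,
                  double kH) {
  const int n = xi.nrow();
  NumericVector V(n), theta(n);
  NumericMatrix Fi(n, 2), Fj(n, 2), Fk(n, 2);
  for (int q = 0; q < n; ++q) {
    const double b1x = xj(q, 0) - xi(q, 0), b1y = xj(q, 1) - xi(q, 1);
    const double b2x = xk(q, 0) - xj(q, 0), b2y = xk(q, 1) - xj(q, 1);
    const double r1s = b1x * b1x + b1y * b1y, r2s = b2x * b2x + b2y * b2y;
    if (r1s == 0.0 || r2s == 0.0) stop("degenerate (zero-length) bond vector");
    const double phi = std::atan2(b1x * b2y - b1y * b2x,
                                  b1x * b2x + b1y * b2y);
    V[q] = 0.5 * kH * phi * phi;
    theta[q] = M_PI - std::fabs(phi);
    const double a1 = kH * phi / r1s, a2 = kH * phi / r2s;
    Fi(q, 0) = a1 * b1y; Fi(q, 1) = -a1 * b1x;
    Fk(q, 0) = a2 * b2y; Fk(q, 1) = -a2 * b2x;
    Fj(q, 0) = -Fi(q, 0) - Fk(q, 0); Fj(q, 1) = -Fi(q, 1) - Fk(q, 1);
  }
  return List::create(_["energy"] = V, _["theta"] = theta, _["F_i"] = Fi,
                      _["F_j"] = Fj, _["F_k"] = Fk);
}

// Full force field at given sphere positions (wrapped coordinates).
// method: "cell" uses the cell/Verlet candidate list, "brute" all pairs.
// [[Rcpp::export]]
NumericMatrix total_forces_cpp(NumericMatrix pos, IntegerVector phase,
                               NumericMatrix anchor, List P,
                               std::string method) {
  const Par p = load_par(P);
  System S; S.setup(p);
  if (pos.nrow() != S.ns) stop("position matrix must have 4*N rows");
  for (int i = 0; i < S.ns; ++i) {
    S.xw[i] = pos(i, 0); S.yw[i] = pos(i, 1);
  }
  // unfold each body into contiguous unwrapped coordinates (bonded terms
  // act on those); bodies are far shorter than half the box
  for (int g = 0; g < p.N; ++g) {
    const int b = 4 * g;
    S.xu[b] = S.xw[b]; S.yu[b] = S.yw[b];
    for (int i = b + 1; i < b + 4; ++i) {
      S.xu[i] = S.xu[i - 1] + S.mi(S.xw[i] - S.xw[i - 1]);
      S.yu[i] = S.yu[i - 1] + S.mi(S.yw[i] - S.yw[i - 1]);
    }
    S.phase[g] = phase[g];
    S.ax[g] = anchor(g, 0); S.ay[g] = anchor(g, 1);
  }
  if (method == "brute") {
    S.pairs.clear(); S.pshift.clear();
    for (int i = 0; i < S.ns; ++i)
      for (int j = i + 1; j < S.ns; ++j) {
        const double rx = S.xw[i] - S.xw[j], ry = S.yw[i] - S.yw[j];
        S.pairs.push_back(i); S.pairs.push_back(j);
        S.pshift.push_back(S.mi(rx) - rx); S.pshift.push_back(S.mi(ry) - ry);
      }
  } else {
    S.build_pairs();
  }
  std::string err;
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  if (!S.forces(err, 0)) stop(err);
  NumericMatrix out(S.ns, 2);
  for (int i = 0; i < S.ns; ++i) { out(i, 0) = S.fx[i]; out(i, 1) = S.fy[i]; }
  return out;
}

// [[Rcpp::export]]
List system_energy_cpp(NumericMatrix pos, List P) {
  const Par p = load_par(P);
  System S; S.setup(p);
  if (pos.nrow() != S.ns) stop("position matrix must have 4*N rows");
  for (int i = 0; i < S.ns; ++i) { S.xw[i] = pos(i, 0); S.yw[i] = pos(i, 1); }
  return List::create(_["potential"] = S.potential_energy());
}

// [[Rcpp::export]]
double bond_equilibrium_cpp(List P) {
  return bond_equilibrium(load_par(P));
}

// Free Langevin particle under a constant external force (integrator oracle
// support): same BAOAB scheme and RNG as the full engine.
// [[Rcpp::export]]
List free_particle_cpp(int n_steps, double dt, double mass, double zeta,
                       double temperature, NumericVector force, double seed,
                       int sample_every) {
  RNG rng((uint64_t)seed); rng.zig_init();
  const double cO = std::exp(-zeta * dt / mass);
  const double sdO = std::sqrt(temperature / mass * (1.0 - cO * cO));
  const double hb = 0.5 * dt / mass, ha = 0.5 * dt;
  double x = 0.0, y = 0.0, vx = 0.0, vy = 0.0;
  const double Fx = force[0], Fy = force[1];
  const int F = n_steps / sample_every + 1;
  NumericVector t(F), ox(F), oy(F), ovx(F), ovy(F);
  int f = 0;
  t[f] = 0; ox[f] = x; oy[f] = y; ovx[f] = vx; ovy[f] = vy; ++f;
  for (int s = 1; s <= n_steps; ++s) {
    vx += hb * Fx; vy += hb * Fy;
    x += ha * vx; y += ha * vy;
    if (sdO > 0.0) {
      vx = cO * vx + sdO * rng.norm();
      vy = cO * vy + sdO * rng.norm();
    } else { vx *= cO; vy *= cO; }
    x += ha * vx; y += ha * vy;
    vx += hb * Fx; vy += hb * Fy;
    if (s % sample_every == 0) {
      t[f] = s * dt; ox[f] = x; oy[f] = y; ovx[f] = vx; ovy[f] = vy; ++f;
    }
  }
  return List::create(_["time"] = t, _["x"] = ox, _["y"] = oy,
                      _["vx"] = ovx, _["vy"] = ovy);
}

// Raw draws from the engine's RNG (for distributional checks).
// [[Rcpp::export]]
NumericVector rng_normal_cpp(int n, double seed) {
  RNG rng((uint64_t)seed); rng.zig_init();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.norm();
  return out;
}

// [[Rcpp::export]]
NumericVector rng_unif_cpp(int n, double seed) {
  RNG rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}
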