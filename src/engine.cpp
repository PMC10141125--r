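// Langevin bead-spring integrator for driven pore translocation.
//
// Reduced Lennard-Jones units throughout: lengths in sigma, energies in
// epsilon, masses in m, time in tau = sigma*sqrt(m/epsilon).  The wall is a
// set of frozen beads; only polymer beads are integrated.  Periodic boundaries
// apply in y and z (transverse to the pore axis x); x is open.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

// Deterministic, platform-independent RNG: splitmix64 uniforms feeding a
// Marsaglia-Tsang ziggurat for the Gaussian thermostat noise (the integrator
// draws 3N deviates per step, so the Gaussian sampler is on the hot path).
struct ZigguratTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigguratTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

static const ZigguratTables ZIG;

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < ZIG.kn[iz]) return hz * ZIG.wn[iz];
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * ZIG.wn[iz];
      if (ZIG.fn[iz] + unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

struct Par {
  double dt, gam, kT, m, eps, sig, kb, R0, fext, xp, plen, boxY, boxZ, skin;
  double sig2, rc2, R02;
  bool pbc;
};

Par parse_params(const List& p) {
  Par q;
  q.dt = as<double>(p["dt"]);
  q.gam = as<double>(p["gamma"]);
  q.kT = as<double>(p["kT"]);
  q.m = as<double>(p["mass"]);
  q.eps = as<double>(p["epsilon"]);
  q.sig = as<double>(p["sigma"]);
  q.kb = as<double>(p["k_fene"]);
  q.R0 = as<double>(p["R0"]);
  q.fext = as<double>(p["f_ext"]);
  q.xp = as<double>(p["x_p"]);
  q.plen = as<double>(p["pore_length"]);
  q.boxY = as<double>(p["box_y"]);
  q.boxZ = as<double>(p["box_z"]);
  q.skin = as<double>(p["skin"]);
  q.sig2 = q.sig * q.sig;
  q.rc2 = std::pow(2.0, 1.0 / 3.0) * q.sig2;  // (2^{1/6} sigma)^2
  q.R02 = q.R0 * q.R0;
  q.pbc = (q.boxY > 0.0) && (q.boxZ > 0.0);
  return q;
}

inline void min_image(double& dy, double& dz, const Par& P) {
  if (P.pbc) {
    dy -= P.boxY * std::nearbyint(dy / P.boxY);
    dz -= P.boxZ * std::nearbyint(dz / P.boxZ);
  }
}

inline double wrap0(double y, double L) {
  double w = y - L * std::floor(y / L);
  if (w >= L) w = 0.0;
  return w;
}

// Static cell grid over the (frozen) wall beads.
struct WallGrid {
  bool active = false;
  double xlo = 0.0, xhi = 0.0, hx = 1.0, cy = 1.0, cz = 1.0;
  int ncx = 0, ncy = 0, ncz = 0;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& wx, const std::vector<double>& wy,
             const std::vector<double>& wz, const Par& P, double rlist) {
    int W = (int)wx.size();
    if (W == 0) return;
    active = true;
    double xmin = wx[0], xmax = wx[0];
    for (int i = 1; i < W; ++i) {
      xmin = std::min(xmin, wx[i]);
      xmax = std::max(xmax, wx[i]);
    }
    xlo = xmin - rlist;
    xhi = xmax + rlist;
    hx = rlist;
    ncx = std::max(1, (int)std::floor((xhi - xlo) / hx) + 1);
    ncy = std::max(1, (int)std::floor(P.boxY / rlist));
    ncz = std::max(1, (int)std::floor(P.boxZ / rlist));
    cy = P.boxY / ncy;
    cz = P.boxZ / ncz;
    head.assign((size_t)ncx * ncy * ncz, -1);
    nxt.assign(W, -1);
    for (int w = 0; w < W; ++w) {
      int ix = std::min(ncx - 1, std::max(0, (int)std::floor((wx[w] - xlo) / hx)));
      int iy = (int)std::floor(wrap0(wy[w], P.boxY) / cy) % ncy;
      int iz = (int)std::floor(wrap0(wz[w], P.boxZ) / cz) % ncz;
      size_t c = ((size_t)ix * ncy + iy) * ncz + iz;
      nxt[w] = head[c];
      head[c] = w;
    }
  }
};

struct Engine {
  Par P;
  int N, M, W;
  std::vector<double> px, py, pz, vx, vy, vz, fx, fy, fz;
  std::vector<double> wx, wy, wz;
  std::vector<int> b1, b2;
  WallGrid grid;
  double rlist, rl2;
  // neighbour lists
  std::vector<int> ppi, ppj;              // polymer-polymer pairs
  std::vector<int> wstart, wlist;         // per-bead wall neighbours (CSR)
  std::vector<double> px0, py0, pz0;      // positions at last rebuild
  bool overstretch = false;
  int bad_bond = -1;

  void init(const NumericMatrix& pos, const NumericMatrix& vel,
            const IntegerMatrix& bonds, const NumericMatrix& wall,
            const Par& par) {
    P = par;
    N = pos.nrow();
    M = bonds.nrow();
    W = wall.nrow();
    px.resize(N); py.resize(N); pz.resize(N);
    vx.assign(N, 0.0); vy.assign(N, 0.0); vz.assign(N, 0.0);
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    for (int i = 0; i < N; ++i) {
      px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
      if (vel.nrow() == N) {
        vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
      }
    }
    b1.resize(M); b2.resize(M);
    for (int b = 0; b < M; ++b) {
      b1[b] = bonds(b, 0) - 1;  // 1-based from R
      b2[b] = bonds(b, 1) - 1;
    }
    wx.resize(W); wy.resize(W); wz.resize(W);
    for (int w = 0; w < W; ++w) {
      wx[w] = wall(w, 0); wy[w] = wall(w, 1); wz[w] = wall(w, 2);
    }
    rlist = std::pow(2.0, 1.0 / 6.0) * P.sig + P.skin;
    rl2 = rlist * rlist;
    grid.build(wx, wy, wz, P, rlist);
    build_neigh();
  }

  void build_neigh() {
    ppi.clear();
    ppj.clear();
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        min_image(dy, dz, P);
        if (dx * dx + dy * dy + dz * dz < rl2) {
          ppi.push_back(i);
          ppj.push_back(j);
        }
      }
    }
    wstart.assign(N + 1, 0);
    wlist.clear();
    if (grid.active) {
      for (int i = 0; i < N; ++i) {
        wstart[i] = (int)wlist.size();
        if (px[i] < grid.xlo || px[i] > grid.xhi) continue;
        int ix0 = (int)std::floor((px[i] - grid.xlo) / grid.hx);
        double ywr = wrap0(py[i], P.boxY), zwr = wrap0(pz[i], P.boxZ);
        int iy0 = (int)std::floor(ywr / grid.cy) % grid.ncy;
        int iz0 = (int)std::floor(zwr / grid.cz) % grid.ncz;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = ix0 + dx;
          if (ix < 0 || ix >= grid.ncx) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int iy = (iy0 + dy + grid.ncy) % grid.ncy;
            for (int dz = -1; dz <= 1; ++dz) {
              int iz = (iz0 + dz + grid.ncz) % grid.ncz;
              size_t c = ((size_t)ix * grid.ncy + iy) * grid.ncz + iz;
              for (int w = grid.head[c]; w >= 0; w = grid.nxt[w]) {
                double ddx = px[i] - wx[w], ddy = py[i] - wy[w],
                       ddz = pz[i] - wz[w];
                min_image(ddy, ddz, P);
                if (ddx * ddx + ddy * ddy + ddz * ddz < rl2)
                  wlist.push_back(w);
              }
            }
          }
        }
      }
    } else {
      for (int i = 0; i < N; ++i) wstart[i] = 0;
    }
    wstart[N] = (int)wlist.size();
    // fix CSR starts: wstart[i] currently holds start of bead i, computed
    // sequentially above only when grid active; make it consistent otherwise
    if (!grid.active) wstart.assign(N + 1, 0);
    px0 = px; py0 = py; pz0 = pz;
  }

  bool needs_rebuild() const {
    double lim = 0.25 * P.skin * P.skin;  // (skin/2)^2
    for (int i = 0; i < N; ++i) {
      double dx = px[i] - px0[i], dy = py[i] - py0[i], dz = pz[i] - pz0[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // Conservative forces (FENE + WCA + optional driving force).
  void compute_forces(bool drive) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    overstretch = false;
    // FENE bonds (unwrapped coordinates: bonded beads are always close)
    for (int b = 0; b < M; ++b) {
      int i = b1[b], j = b2[b];
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= P.R02) {
        overstretch = true;
        bad_bond = b;
        return;
      }
      double fmag = -P.kb / (1.0 - r2 / P.R02);  // attractive
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
    // WCA, polymer-polymer (includes bonded pairs: Kremer-Grest convention)
    int npp = (int)ppi.size();
    for (int k = 0; k < npp; ++k) {
      int i = ppi[k], j = ppj[k];
      double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
      min_image(dy, dz, P);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < P.rc2 && r2 > 0.0) {
        double sr2 = P.sig2 / r2;
        double sr6 = sr2 * sr2 * sr2;
        double fpair = 24.0 * P.eps * (2.0 * sr6 * sr6 - sr6) / r2;
        fx[i] += fpair * dx; fy[i] += fpair * dy; fz[i] += fpair * dz;
        fx[j] -= fpair * dx; fy[j] -= fpair * dy; fz[j] -= fpair * dz;
      }
    }
    // WCA, polymer-wall (wall frozen: one-sided)
    for (int i = 0; i < N; ++i) {
      for (int k = wstart[i]; k < wstart[i + 1]; ++k) {
        int w = wlist[k];
        double dx = px[i] - wx[w], dy = py[i] - wy[w], dz = pz[i] - wz[w];
        min_image(dy, dz, P);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < P.rc2 && r2 > 0.0) {
          double sr2 = P.sig2 / r2;
          double sr6 = sr2 * sr2 * sr2;
          double fpair = 24.0 * P.eps * (2.0 * sr6 * sr6 - sr6) / r2;
          fx[i] += fpair * dx; fy[i] += fpair * dy; fz[i] += fpair * dz;
        }
      }
    }
    if (drive) {
      double x1 = P.xp, x2 = P.xp + P.plen;
      for (int i = 0; i < N; ++i)
        if (px[i] >= x1 && px[i] <= x2) fx[i] += P.fext;
    }
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bonds,
                      NumericMatrix wall, List params, int nsteps,
                      int sample_every, int fixed_bead, bool drive,
                      bool stop_on_exit, double t0, double seed) {
  Par P = parse_params(params);
  Engine E;
  E.init(pos, vel, bonds, wall, P);
  Rng rng((uint64_t)seed);
  int N = E.N;
  int fix = fixed_bead - 1;  // -1 if none
  if (fix >= 0) {
    E.vx[fix] = 0.0; E.vy[fix] = 0.0; E.vz[fix] = 0.0;
  }

  int max_frames = nsteps / sample_every + 2;
  std::vector<double> times;
  times.reserve(max_frames);
  std::vector<double> tkin;
  tkin.reserve(max_frames);
  std::vector<double> frames;
  frames.reserve((size_t)max_frames * N * 3);

  double halfdt_m = 0.5 * P.dt / P.m;
  double sfac = (P.gam > 0.0 && P.kT > 0.0)
                    ? std::sqrt(2.0 * P.gam * P.kT / P.dt)
                    : 0.0;
  double exit_x = P.xp + P.plen;

  auto record = [&](double t) {
    times.push_back(t);
    double k2 = 0.0;
    for (int i = 0; i < N; ++i)
      k2 += E.vx[i] * E.vx[i] + E.vy[i] * E.vy[i] + E.vz[i] * E.vz[i];
    tkin.push_back(P.m * k2 / (3.0 * N));
    for (int i = 0; i < N; ++i) {
      frames.push_back(E.px[i]);
      frames.push_back(E.py[i]);
      frames.push_back(E.pz[i]);
    }
  };
  auto all_exited = [&]() {
    for (int i = 0; i < N; ++i)
      if (E.px[i] <= exit_x) return false;
    return true;
  };

  // initial force evaluation (conservative + drive + langevin terms)
  E.compute_forces(drive);
  int status = 0;  // 0 = step cap reached, 1 = completed exit, 2 = overstretch
  long steps_done = 0;
  if (E.overstretch) {
    status = 2;
  } else {
    if (sfac > 0.0 || P.gam > 0.0) {
      for (int i = 0; i < N; ++i) {
        if (i == fix) continue;
        E.fx[i] += -P.gam * E.vx[i] + sfac * rng.norm();
        E.fy[i] += -P.gam * E.vy[i] + sfac * rng.norm();
        E.fz[i] += -P.gam * E.vz[i] + sfac * rng.norm();
      }
    }
    record(t0);
    for (int step = 1; step <= nsteps; ++step) {
      // half kick + drift
      for (int i = 0; i < N; ++i) {
        if (i == fix) continue;
        E.vx[i] += halfdt_m * E.fx[i];
        E.vy[i] += halfdt_m * E.fy[i];
        E.vz[i] += halfdt_m * E.fz[i];
        E.px[i] += P.dt * E.vx[i];
        E.py[i] += P.dt * E.vy[i];
        E.pz[i] += P.dt * E.vz[i];
      }
      if (E.needs_rebuild()) E.build_neigh();
      E.compute_forces(drive);
      if (E.overstretch) {
        status = 2;
        steps_done = step;
        break;
      }
      if (sfac > 0.0 || P.gam > 0.0) {
        for (int i = 0; i < N; ++i) {
          if (i == fix) continue;
          E.fx[i] += -P.gam * E.vx[i] + sfac * rng.norm();
          E.fy[i] += -P.gam * E.vy[i] + sfac * rng.norm();
          E.fz[i] += -P.gam * E.vz[i] + sfac * rng.norm();
        }
      }
      // second half kick
      for (int i = 0; i < N; ++i) {
        if (i == fix) continue;
        E.vx[i] += halfdt_m * E.fx[i];
        E.vy[i] += halfdt_m * E.fy[i];
        E.vz[i] += halfdt_m * E.fz[i];
      }
      steps_done = step;
      if (step % sample_every == 0) {
        record(t0 + step * P.dt);
        if (stop_on_exit && all_exited()) {
          status = 1;
          break;
        }
      }
    }
  }

  NumericMatrix out_pos(N, 3), out_vel(N, 3);
  for (int i = 0; i < N; ++i) {
    out_pos(i, 0) = E.px[i]; out_pos(i, 1) = E.py[i]; out_pos(i, 2) = E.pz[i];
    out_vel(i, 0) = E.vx[i]; out_vel(i, 1) = E.vy[i]; out_vel(i, 2) = E.vz[i];
  }
  return List::create(
      _["times"] = NumericVector(times.begin(), times.end()),
      _["frames"] = NumericVector(frames.begin(), frames.end()),
      _["tkin"] = NumericVector(tkin.begin(), tkin.end()),
      _["status"] = status, _["steps_done"] = (double)steps_done,
      _["bad_bond"] = E.bad_bond + 1, _["positions"] = out_pos,
      _["velocities"] = out_vel);
}

//' @noRd
// [[Rcpp::export(name = ".forces_cpp")]]
NumericMatrix forces_cpp(NumericMatrix pos, IntegerMatrix bonds,
                         NumericMatrix wall, List params, bool drive) {
  Par P = parse_params(params);
  Engine E;
  NumericMatrix novel(0, 3);
  E.init(pos, novel, bonds, wall, P);
  E.compute_forces(drive);
  if (E.overstretch)
    stop("FENE bond %d at or beyond maximum extension R0", E.bad_bond + 1);
  int N = E.N;
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; ++i) {
    f(i, 0) = E.fx[i]; f(i, 1) = E.fy[i]; f(i, 2) = E.fz[i];
  }
  return f;
}

namespace {

inline double clamp1(double x) { return std::max(-1.0, std::min(1.0, x)); }

inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

inline bool unit3(double* a) {
  double n = std::sqrt(dot3(a, a));
  if (n < 1e-12) return false;
  a[0] /= n; a[1] /= n; a[2] /= n;
  return true;
}

// squared minimum distance between segments p1-p2 and p3-p4
double segseg_dist2(const double* p1, const double* p2, const double* p3,
                    const double* p4) {
  double d1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double d2[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
  double r[3] = {p1[0] - p3[0], p1[1] - p3[1], p1[2] - p3[2]};
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0.0, t = 0.0;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {
    // both points
  } else if (a <= EPS) {
    t = std::max(0.0, std::min(1.0, f / e));
  } else {
    double c = dot3(d1, r);
    if (e <= EPS) {
      s = std::max(0.0, std::min(1.0, -c / a));
    } else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      if (denom > EPS)
        s = std::max(0.0, std::min(1.0, (b * f - c * e) / denom));
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::max(0.0, std::min(1.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::max(0.0, std::min(1.0, (b - c) / a));
      }
    }
  }
  double c1[3] = {p1[0] + s * d1[0], p1[1] + s * d1[1], p1[2] + s * d1[2]};
  double c2[3] = {p3[0] + t * d2[0], p3[1] + t * d2[1], p3[2] + t * d2[2]};
  double dd[3] = {c1[0] - c2[0], c1[1] - c2[1], c1[2] - c2[2]};
  return dot3(dd, dd);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".linking_number_cpp")]]
double linking_number_cpp(NumericMatrix a, NumericMatrix b, double tol) {
  int n = a.nrow(), m = b.nrow();
  if (n < 3 || m < 3) stop("closed polylines need at least 3 vertices");
  std::vector<double> A(3 * (n + 1)), B(3 * (m + 1));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) A[3 * i + k] = a(i, k);
  for (int k = 0; k < 3; ++k) A[3 * n + k] = a(0, k);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < 3; ++k) B[3 * j + k] = b(j, k);
  for (int k = 0; k < 3; ++k) B[3 * m + k] = b(0, k);

  double tol2 = tol * tol;
  double sum = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* p1 = &A[3 * i];
    const double* p2 = &A[3 * (i + 1)];
    double r12[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    for (int j = 0; j < m; ++j) {
      const double* p3 = &B[3 * j];
      const double* p4 = &B[3 * (j + 1)];
      if (segseg_dist2(p1, p2, p3, p4) < tol2)
        stop("segments of the two curves intersect (distance below tolerance); topology ill-defined");
      // Klenin-Langowski solid-angle formula for a segment pair
      double r13[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
      double r14[3] = {p4[0] - p1[0], p4[1] - p1[1], p4[2] - p1[2]};
      double r23[3] = {p3[0] - p2[0], p3[1] - p2[1], p3[2] - p2[2]};
      double r24[3] = {p4[0] - p2[0], p4[1] - p2[1], p4[2] - p2[2]};
      double n1[3], n2[3], n3[3], n4[3];
      cross3(r13, r14, n1);
      cross3(r14, r24, n2);
      cross3(r24, r23, n3);
      cross3(r23, r13, n4);
      if (!unit3(n1) || !unit3(n2) || !unit3(n3) || !unit3(n4)) continue;
      double omega = std::asin(clamp1(dot3(n1, n2))) +
                     std::asin(clamp1(dot3(n2, n3))) +
                     std::asin(clamp1(dot3(n3, n4))) +
                     std::asin(clamp1(dot3(n4, n1)));
      double r34[3] = {p4[0] - p3[0], p4[1] - p3[1], p4[2] - p3[2]};
      double cr[3];
      cross3(r34, r12, cr);
      double sgn = dot3(cr, r13);
      sum += (sgn >= 0.0 ? 1.0 : -1.0) * omega;
    }
  }
  return sum / (4.0 * M_PI);
}
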