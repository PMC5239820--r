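// Langevin toy engines for well-tempered (funnel) metadynamics.
//
// Two systems are implemented:
//   * a 2D collective-variable model (z, c) with analytic preset potentials,
//     used to exercise hill deposition and free-energy-surface reconstruction;
//   * a 1D multi-particle "solvent trap" channel (ligand + M solvent
//     particles) with a coordination-number restraint, used to exercise the
//     dry-state protocol and the trapped-solvent hysteresis.
//
// Integrator: BAOAB splitting. Randomness: mt19937_64 + an explicit
// Box-Muller transform so that trajectories are bit-reproducible for a given
// seed independently of the C++ standard library's normal_distribution.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 0.0019872041; // kcal mol^-1 K^-1

namespace {

struct Rng {
  std::mt19937_64 gen;
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : gen(seed), has_spare(false), spare(0.0) {}
  double unif() {
    // 53-bit uniform in [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = 0.0;
    do { u1 = unif(); } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// quartic one-sided walls
inline double wall_hi(double x, double onset, double k, double& f) {
  if (x <= onset) return 0.0;
  double d = x - onset;
  f -= 4.0 * k * d * d * d;
  return k * d * d * d * d;
}
inline double wall_lo(double x, double onset, double k, double& f) {
  if (x >= onset) return 0.0;
  double d = onset - x;
  f += 4.0 * k * d * d * d;
  return k * d * d * d * d;
}

// Analytic preset potentials over (z, c).
// id 0 "double_well": p = (h, z0, w, tilt, kc)
//   U = h ((q^2 - 1)^2) + tilt (z - z0) + kc c^2,  q = (z - z0)/w
// id 1 "binding": p = (eps, zb, wz)
//   U = -eps exp(-(z - zb)^2 / (2 wz^2)) (1 - c)/2
inline void preset_eval(int id, const double* p, double z, double c,
                        double& u, double& fz, double& fc) {
  if (id == 0) {
    double h = p[0], z0 = p[1], w = p[2], tilt = p[3], kc = p[4];
    double q = (z - z0) / w;
    double q2 = q * q;
    u = h * (q2 - 1.0) * (q2 - 1.0) + tilt * (z - z0) + kc * c * c;
    fz = -(4.0 * h * (q2 - 1.0) * q / w + tilt);
    fc = -2.0 * kc * c;
  } else if (id == 1) {
    double eps = p[0], zb = p[1], wz = p[2];
    double g = std::exp(-(z - zb) * (z - zb) / (2.0 * wz * wz));
    double ang = 0.5 * (1.0 - c);
    u = -eps * g * ang;
    fz = -eps * g * ang * (z - zb) / (wz * wz);
    fc = -eps * g * 0.5;
  } else {
    stop("unknown preset id");
  }
}

// Uniform-grid bias store with bilinear interpolation (2D) of the bias
// energy and its gradient; hills are accumulated within a cutoff of
// `cut` standard deviations per dimension (cut = Inf means all nodes).
struct BiasGrid2D {
  double x0, dx, y0, dy;
  int nx, ny;
  std::vector<double> v, gx, gy;
  BiasGrid2D(double x0_, double x1, double dx_, double y0_, double y1, double dy_)
      : x0(x0_), dx(dx_), y0(y0_), dy(dy_) {
    nx = (int)std::floor((x1 - x0) / dx + 0.5) + 1;
    ny = (int)std::floor((y1 - y0) / dy + 0.5) + 1;
    v.assign((size_t)nx * ny, 0.0);
    gx.assign((size_t)nx * ny, 0.0);
    gy.assign((size_t)nx * ny, 0.0);
  }
  inline size_t idx(int i, int j) const { return (size_t)j * nx + i; }
  void add_hill(double cx, double cy, double sx, double sy, double h, double cut) {
    int i0 = 0, i1 = nx - 1, j0 = 0, j1 = ny - 1;
    if (R_finite(cut)) {
      i0 = std::max(0, (int)std::floor((cx - cut * sx - x0) / dx));
      i1 = std::min(nx - 1, (int)std::ceil((cx + cut * sx - x0) / dx));
      j0 = std::max(0, (int)std::floor((cy - cut * sy - y0) / dy));
      j1 = std::min(ny - 1, (int)std::ceil((cy + cut * sy - y0) / dy));
    }
    for (int j = j0; j <= j1; ++j) {
      double yy = y0 + j * dy;
      double ey = std::exp(-0.5 * (yy - cy) * (yy - cy) / (sy * sy));
      for (int i = i0; i <= i1; ++i) {
        double xx = x0 + i * dx;
        double ex = std::exp(-0.5 * (xx - cx) * (xx - cx) / (sx * sx));
        double g = h * ex * ey;
        size_t k = idx(i, j);
        v[k] += g;
        gx[k] += -g * (xx - cx) / (sx * sx);
        gy[k] += -g * (yy - cy) / (sy * sy);
      }
    }
  }
  void interp(double x, double y, double& vv, double& fx, double& fy) const {
    double tx = (x - x0) / dx, ty = (y - y0) / dy;
    int i = (int)std::floor(tx), j = (int)std::floor(ty);
    if (i < 0) { i = 0; tx = 0.0; } else if (i > nx - 2) { i = nx - 2; tx = nx - 1.0; }
    if (j < 0) { j = 0; ty = 0.0; } else if (j > ny - 2) { j = ny - 2; ty = ny - 1.0; }
    double ax = tx - i, ay = ty - j;
    size_t k00 = idx(i, j), k10 = idx(i + 1, j), k01 = idx(i, j + 1), k11 = idx(i + 1, j + 1);
    double w00 = (1 - ax) * (1 - ay), w10 = ax * (1 - ay), w01 = (1 - ax) * ay, w11 = ax * ay;
    vv = w00 * v[k00] + w10 * v[k10] + w01 * v[k01] + w11 * v[k11];
    // gx, gy store dV/dx, dV/dy; the force is minus the gradient
    fx = -(w00 * gx[k00] + w10 * gx[k10] + w01 * gx[k01] + w11 * gx[k11]);
    fy = -(w00 * gy[k00] + w10 * gy[k10] + w01 * gy[k01] + w11 * gy[k11]);
  }
};

struct BiasGrid1D {
  double x0, dx;
  int nx;
  std::vector<double> v, gx;
  BiasGrid1D(double x0_, double x1, double dx_) : x0(x0_), dx(dx_) {
    nx = (int)std::floor((x1 - x0) / dx + 0.5) + 1;
    v.assign(nx, 0.0);
    gx.assign(nx, 0.0);
  }
  void add_hill(double cx, double sx, double h, double cut) {
    int i0 = 0, i1 = nx - 1;
    if (R_finite(cut)) {
      i0 = std::max(0, (int)std::floor((cx - cut * sx - x0) / dx));
      i1 = std::min(nx - 1, (int)std::ceil((cx + cut * sx - x0) / dx));
    }
    for (int i = i0; i <= i1; ++i) {
      double xx = x0 + i * dx;
      double g = h * std::exp(-0.5 * (xx - cx) * (xx - cx) / (sx * sx));
      v[i] += g;
      gx[i] += -g * (xx - cx) / (sx * sx);
    }
  }
  void interp(double x, double& vv, double& fx) const {
    double tx = (x - x0) / dx;
    int i = (int)std::floor(tx);
    if (i < 0) { i = 0; tx = 0.0; } else if (i > nx - 2) { i = nx - 2; tx = nx - 1.0; }
    double ax = tx - i;
    vv = (1 - ax) * v[i] + ax * v[i + 1];
    fx = -((1 - ax) * gx[i] + ax * gx[i + 1]);
  }
};

// switching-function term of the generalized coordination number,
// t(x) = (1 - x^n)/(1 - x^m), with the removable singularity at x = 1
// handled explicitly (limit n/m, slope n(n-m)/(2m)).
inline void sw_term(double r, double r0, int n, int m, double& t, double& dtdr) {
  double x = r / r0;
  if (x < 1e-12) { t = 1.0; dtdr = 0.0; return; }
  if (std::fabs(x - 1.0) < 1e-8) {
    t = (double)n / m;
    dtdr = ((double)n * (n - m)) / (2.0 * m) / r0;
    return;
  }
  double xn = std::pow(x, n), xm = std::pow(x, m);
  double den = 1.0 - xm;
  t = (1.0 - xn) / den;
  double dt = (-(double)n * xn / x * den + (1.0 - xn) * (double)m * xm / x) / (den * den);
  dtdr = dt / r0;
}

} // namespace

// Evaluate a preset potential on vectors of (z, c); single source of truth
// shared with the R-side quadrature oracles.
// [[Rcpp::export]]
NumericVector preset_u(int preset_id, NumericVector pars, NumericVector z, NumericVector c) {
  if (z.size() != c.size()) stop("z and c must have equal length");
  NumericVector out(z.size());
  double u, fz, fc;
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    preset_eval(preset_id, pars.begin(), z[i], c[i], u, fz, fc);
    out[i] = u;
  }
  return out;
}

// Well-tempered metadynamics on the 2D collective-variable toy model.
// The funnel restraint reduces to a flat-bottom pair of quartic walls on z
// (onset z_lo below, z_wall above); c is reflected at +/- c_bound.
// [[Rcpp::export]]
List engine_wtmetad_2d(int preset_id, NumericVector pars,
                       double mass, double friction, double T,
                       double W0, double sigma1, double sigma2,
                       double stride, double gamma,
                       double z_wall, double k_wall, double z_lo, double k_lo,
                       double c_bound,
                       double z_init, double c_init,
                       int nsteps, double dt, int out_stride,
                       double seed, bool deposit, double grid_cut) {
  Rng rng((uint64_t)seed);
  BiasGrid2D bias(-0.4, 2.4, 0.005, -1.1, 1.1, 0.01);

  int stride_steps = std::max(1, (int)std::floor(stride / dt + 0.5));
  double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(KB * T / mass);
  double dT = (R_finite(gamma)) ? (gamma - 1.0) * T : R_PosInf;

  double z = z_init, c = c_init;
  double vz = 0.0, vc = 0.0;
  if (T > 0.0) {
    vz = std::sqrt(KB * T / mass) * rng.norm();
    vc = std::sqrt(KB * T / mass) * rng.norm();
  }

  double u, fz, fc;
  auto force = [&](double zz, double cc, double& uu, double& ffz, double& ffc) {
    preset_eval(preset_id, pars.begin(), zz, cc, uu, ffz, ffc);
    uu += wall_hi(zz, z_wall, k_wall, ffz);
    uu += wall_lo(zz, z_lo, k_lo, ffz);
    if (deposit) {
      double bv, bfx, bfy;
      bias.interp(zz, cc, bv, bfx, bfy);
      uu += bv; ffz += bfx; ffc += bfy;
    }
  };
  force(z, c, u, fz, fc);

  int nout = nsteps / out_stride + 1;
  NumericVector t_out(nout), z_out(nout), c_out(nout), e_out(nout);
  std::vector<double> ht, hz, hc, hh;

  int iout = 0;
  t_out[iout] = 0.0; z_out[iout] = z; c_out[iout] = c;
  e_out[iout] = u + 0.5 * mass * (vz * vz + vc * vc);
  ++iout;

  for (int step = 1; step <= nsteps; ++step) {
    // B
    vz += 0.5 * dt * fz / mass;
    vc += 0.5 * dt * fc / mass;
    // A
    z += 0.5 * dt * vz;
    c += 0.5 * dt * vc;
    // O
    if (friction > 0.0 && T > 0.0) {
      vz = c1 * vz + c2 * rng.norm();
      vc = c1 * vc + c2 * rng.norm();
    } else if (friction > 0.0) {
      vz = c1 * vz; vc = c1 * vc;
    }
    // A
    z += 0.5 * dt * vz;
    c += 0.5 * dt * vc;
    // reflect c at the bounds of the angular variable
    if (c > c_bound)  { c = 2.0 * c_bound - c;  vc = -vc; }
    if (c < -c_bound) { c = -2.0 * c_bound - c; vc = -vc; }
    // B
    force(z, c, u, fz, fc);
    vz += 0.5 * dt * fz / mass;
    vc += 0.5 * dt * fc / mass;

    if (!std::isfinite(z) || !std::isfinite(c) || !std::isfinite(u) || std::fabs(z) > 10.0)
      stop("trajectory diverged at step %d (z = %g, c = %g): reduce dt", step, z, c);

    if (deposit && step % stride_steps == 0) {
      double bv, bfx, bfy;
      bias.interp(z, c, bv, bfx, bfy);
      double h = R_finite(dT) ? W0 * std::exp(-bv / (KB * dT)) : W0;
      bias.add_hill(z, c, sigma1, sigma2, h, grid_cut);
      ht.push_back(step * dt); hz.push_back(z); hc.push_back(c); hh.push_back(h);
      force(z, c, u, fz, fc); // bias changed under our feet
    }

    if (step % out_stride == 0) {
      t_out[iout] = step * dt; z_out[iout] = z; c_out[iout] = c;
      e_out[iout] = u + 0.5 * mass * (vz * vz + vc * vc);
      ++iout;
    }
  }

  return List::create(
      _["times"] = t_out, _["cv1"] = z_out, _["cv2"] = c_out, _["energy"] = e_out,
      _["hill_times"] = NumericVector(ht.begin(), ht.end()),
      _["hill_cv1"] = NumericVector(hz.begin(), hz.end()),
      _["hill_cv2"] = NumericVector(hc.begin(), hc.end()),
      _["hill_heights"] = NumericVector(hh.begin(), hh.end()));
}

// 1D solvent-trap channel: ligand (optional) + M solvent particles.
// Site well at z_site (depth eps_L for the ligand, eps_W for solvent),
// solvent reservoir extends to -L_res behind the site (entered at a
// confinement cost eps_R, which is what makes displacing trapped solvent
// slow), channel ends at L_chan. Pairwise r^-12 repulsion prevents particle crossing. Optional
// coordination-number restraint (dry state) and optional 1D well-tempered
// metadynamics on the ligand coordinate.
// [[Rcpp::export]]
List engine_solvent_trap(double eps_L, double eps_W, double z_site, double w_site,
                         double eps_R, double L_res, double L_chan,
                         double A_rep, double d_rep,
                         double z_virtual, double k_s, double S_0,
                         int n_sw, int m_sw, double r_0,
                         bool restraint_on, bool include_ligand, bool metad_on,
                         double W0, double sigma, double stride, double gamma,
                         double mass, double friction, double T,
                         NumericVector z_init,
                         int nsteps, double dt, int out_stride, double seed,
                         double k_wall) {
  const int N = z_init.size();
  const int i_lig = include_ligand ? 0 : -1;
  const int M = include_ligand ? N - 1 : N;
  if (M < 0) stop("no particles");

  Rng rng((uint64_t)seed);
  BiasGrid1D bias(-L_res - 0.3, L_chan + 0.3, 0.005);
  int stride_steps = std::max(1, (int)std::floor(stride / dt + 0.5));
  double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1)) * std::sqrt(KB * T / mass);
  double dT = (R_finite(gamma)) ? (gamma - 1.0) * T : R_PosInf;
  const double rcut = 2.5 * d_rep;
  const double fmax_pair = 1.0e4; // numerical safeguard on the stiff core

  std::vector<double> z(z_init.begin(), z_init.end()), v(N, 0.0), f(N, 0.0);
  if (T > 0.0)
    for (int i = 0; i < N; ++i) v[i] = std::sqrt(KB * T / mass) * rng.norm();

  double S_now = 0.0, VS_now = 0.0;

  auto forces = [&](double& utot) {
    utot = 0.0;
    std::fill(f.begin(), f.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double eps = (i == i_lig) ? eps_L : eps_W;
      double dz = z[i] - z_site;
      double g = std::exp(-dz * dz / (2.0 * w_site * w_site));
      utot += -eps * g;
      f[i] += -eps * g * dz / (w_site * w_site);
      if (i != i_lig && eps_R != 0.0) {
        // reservoir confinement penalty: smooth step of height eps_R
        // behind the site (z < 0), logistic width 0.05 nm
        double s = 1.0 / (1.0 + std::exp(z[i] / 0.05));
        utot += eps_R * s;
        f[i] += eps_R * s * (1.0 - s) / 0.05;
      }
      double lo = (i == i_lig) ? 0.0 : -L_res;
      utot += wall_lo(z[i], lo, k_wall, f[i]);
      utot += wall_hi(z[i], L_chan, k_wall, f[i]);
    }
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dz = z[i] - z[j];
        double r = std::fabs(dz);
        if (r >= rcut) continue;
        double xr = d_rep / std::max(r, 1e-6);
        double x6 = xr * xr * xr; x6 *= x6;
        double u = A_rep * x6 * x6;
        double fr = 12.0 * u / std::max(r, 1e-6);
        if (fr > fmax_pair) fr = fmax_pair;
        utot += u;
        double s = (dz >= 0.0) ? 1.0 : -1.0;
        f[i] += s * fr;
        f[j] -= s * fr;
      }
    // coordination number of solvent around the virtual site
    double S = 0.0;
    std::vector<double> dSdz(N, 0.0);
    for (int i = 0; i < N; ++i) {
      if (i == i_lig) continue;
      double r = std::fabs(z[i] - z_virtual);
      double t, dtdr;
      sw_term(r, r_0, n_sw, m_sw, t, dtdr);
      S += t;
      dSdz[i] = dtdr * ((z[i] >= z_virtual) ? 1.0 : -1.0);
    }
    S_now = S;
    VS_now = (S >= S_0) ? k_s * std::pow(S - S_0, 4.0) : 0.0;
    if (restraint_on && S >= S_0) {
      utot += VS_now;
      double dVdS = 4.0 * k_s * std::pow(S - S_0, 3.0);
      for (int i = 0; i < N; ++i) {
        if (i == i_lig) continue;
        double fi = -dVdS * dSdz[i];
        if (fi > fmax_pair) fi = fmax_pair;
        if (fi < -fmax_pair) fi = -fmax_pair;
        f[i] += fi;
      }
    }
    if (metad_on && include_ligand) {
      double bv, bf;
      bias.interp(z[i_lig], bv, bf);
      utot += bv;
      f[i_lig] += bf;
    }
  };

  double utot;
  forces(utot);

  int nout = nsteps / out_stride + 1;
  NumericVector t_out(nout), zl_out(nout), S_out(nout), VS_out(nout);
  std::vector<double> ht, hz, hh;

  int iout = 0;
  t_out[0] = 0.0;
  zl_out[0] = include_ligand ? z[i_lig] : NA_REAL;
  S_out[0] = S_now; VS_out[0] = VS_now;
  ++iout;

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) v[i] += 0.5 * dt * f[i] / mass;
    for (int i = 0; i < N; ++i) z[i] += 0.5 * dt * v[i];
    if (friction > 0.0 && T > 0.0)
      for (int i = 0; i < N; ++i) v[i] = c1 * v[i] + c2 * rng.norm();
    else if (friction > 0.0)
      for (int i = 0; i < N; ++i) v[i] = c1 * v[i];
    for (int i = 0; i < N; ++i) z[i] += 0.5 * dt * v[i];
    forces(utot);
    for (int i = 0; i < N; ++i) v[i] += 0.5 * dt * f[i] / mass;

    for (int i = 0; i < N; ++i)
      if (!std::isfinite(z[i]) || std::fabs(z[i]) > 10.0)
        stop("trajectory diverged at step %d (particle %d, z = %g): reduce dt",
             step, i + 1, z[i]);

    if (metad_on && include_ligand && step % stride_steps == 0) {
      double bv, bf;
      bias.interp(z[i_lig], bv, bf);
      double h = R_finite(dT) ? W0 * std::exp(-bv / (KB * dT)) : W0;
      bias.add_hill(z[i_lig], sigma, h, 6.0);
      ht.push_back(step * dt); hz.push_back(z[i_lig]); hh.push_back(h);
      forces(utot);
    }

    if (step % out_stride == 0) {
      t_out[iout] = step * dt;
      zl_out[iout] = include_ligand ? z[i_lig] : NA_REAL;
      S_out[iout] = S_now; VS_out[iout] = VS_now;
      ++iout;
    }
  }

  return List::create(
      _["times"] = t_out, _["cv1"] = zl_out, _["S"] = S_out, _["V_S"] = VS_out,
      _["hill_times"] = NumericVector(ht.begin(), ht.end()),
      _["hill_cv1"] = NumericVector(hz.begin(), hz.end()),
      _["hill_heights"] = NumericVector(hh.begin(), hh.end()));
}

// Accumulate Gaussian hills onto a uniform 2D grid (CV1 x CV2). Used by the
// free-energy-surface reconstruction; hills are added in the order given so
// that incremental and one-shot accumulation agree bit for bit.
// [[Rcpp::export]]
NumericMatrix grid_add_hills(NumericMatrix V, NumericVector g1, NumericVector g2,
                             NumericVector c1, NumericVector c2,
                             NumericVector s1, NumericVector s2,
                             NumericVector h, double cutoff) {
  NumericMatrix out = clone(V);
  const int n1 = g1.size(), n2 = g2.size();
  if (out.nrow() != n1 || out.ncol() != n2) stop("grid dimensions mismatch");
  const double x0 = g1[0], dx = (n1 > 1) ? g1[1] - g1[0] : 1.0;
  const double y0 = g2[0], dy = (n2 > 1) ? g2[1] - g2[0] : 1.0;
  for (R_xlen_t k = 0; k < c1.size(); ++k) {
    int i0 = 0, i1 = n1 - 1, j0 = 0, j1 = n2 - 1;
    if (R_finite(cutoff)) {
      i0 = std::max(0, (int)std::floor((c1[k] - cutoff * s1[k] - x0) / dx));
      i1 = std::min(n1 - 1, (int)std::ceil((c1[k] + cutoff * s1[k] - x0) / dx));
      j0 = std::max(0, (int)std::floor((c2[k] - cutoff * s2[k] - y0) / dy));
      j1 = std::min(n2 - 1, (int)std::ceil((c2[k] + cutoff * s2[k] - y0) / dy));
      if (i0 > i1 || j0 > j1) continue;
    }
    for (int j = j0; j <= j1; ++j) {
      double ey = std::exp(-0.5 * (g2[j] - c2[k]) * (g2[j] - c2[k]) / (s2[k] * s2[k]));
      for (int i = i0; i <= i1; ++i) {
        double ex = std::exp(-0.5 * (g1[i] - c1[k]) * (g1[i] - c1[k]) / (s1[k] * s1[k]));
        out(i, j) += h[k] * ex * ey;
      }
    }
  }
  return out;
}
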