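#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Electron rest mass [MeV] and the helix constant: p [MeV/c] = 0.29979 * B [T] * r [mm].
static const double ME = 0.510999;
static const double PB = 0.29979;

// ---- portable per-particle RNG: splitmix64 stream + Box-Muller ----
// Substreams are keyed by (seed, particle_id) so histories are reproducible
// independently of execution order.
struct Rng {
  uint64_t s;
  bool has_cached;
  double cached;
  explicit Rng(uint64_t seed) : s(seed), has_cached(false), cached(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double unif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    has_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

static uint64_t mix_seed(uint64_t seed, uint64_t id) {
  // splitmix64 finalizer over the pair
  uint64_t z = seed * 0x9E3779B97F4A7C15ULL + id;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Moller-corrected Bethe collision stopping power [MeV/mm].
// I_mev: mean excitation energy [MeV]; za: Z/A; rho: g/cm^3.
static double stopping_power(double T, double rho, double I_mev, double za) {
  double tau = T / ME;
  double g = 1.0 + tau;
  double beta2 = 1.0 - 1.0 / (g * g);
  double F = 1.0 - beta2 +
    (tau * tau / 8.0 - (2.0 * tau + 1.0) * std::log(2.0)) / (g * g);
  double logterm = std::log(tau * tau * (tau + 2.0) / (2.0 * (I_mev / ME) * (I_mev / ME)));
  double s_mass = 0.153536 * za / beta2 * (logterm + F); // MeV cm^2/g
  return s_mass * rho / 10.0;                            // MeV/mm
}

// Highland multiple-scattering width [rad] for a sub-step of `step_mm`.
// The logarithmic correction is evaluated at the cumulative track thickness
// `cum_mm` (Gottschalk's prescription): evaluating it per thin sub-step makes
// the summed variance depend on the step subdivision and vanish for very
// thin steps, i.e. it breaks additivity.
static double highland(double T, double step_mm, double cum_mm,
                       double rho, double x0) {
  double E = T + ME;
  double p = std::sqrt(E * E - ME * ME);
  double beta = p / E;
  double t = step_mm * rho / 10.0 / x0;  // sub-step in radiation lengths
  double tc = cum_mm * rho / 10.0 / x0;  // whole track so far
  double th = 13.6 / (beta * p) * std::sqrt(t) * (1.0 + 0.038 * std::log(tc));
  return th > 0.0 ? th : 0.0;
}

static void normalize3(double* v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  for (int k = 0; k < 3; ++k) v[k] /= n;
}

// Rotate direction d by polar angle theta (uniform azimuth phi) about itself.
static void deflect(double* d, double theta, double phi) {
  double ct = std::cos(theta), st = std::sin(theta);
  // orthonormal basis (u, v) perpendicular to d
  double u[3];
  if (std::fabs(d[0]) < 0.9) { u[0] = 0; u[1] = -d[2]; u[2] = d[1]; }
  else                       { u[0] = -d[1]; u[1] = d[0]; u[2] = 0; }
  normalize3(u);
  double v[3] = { d[1] * u[2] - d[2] * u[1],
                  d[2] * u[0] - d[0] * u[2],
                  d[0] * u[1] - d[1] * u[0] };
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int k = 0; k < 3; ++k)
    d[k] = ct * d[k] + st * (cp * u[k] + sp * v[k]);
  normalize3(d);
}

// Exact helical advance for an electron (charge -e) in uniform field B*bhat:
// the perpendicular momentum component rotates towards bhat x v.
static void helix_step(double* pos, double* dir, double T, double B,
                       const double* bhat, double step) {
  if (B <= 0.0) {
    for (int k = 0; k < 3; ++k) pos[k] += step * dir[k];
    return;
  }
  double E = T + ME;
  double p = std::sqrt(E * E - ME * ME);
  double dpar = dir[0] * bhat[0] + dir[1] * bhat[1] + dir[2] * bhat[2];
  double dperp[3] = { dir[0] - dpar * bhat[0],
                      dir[1] - dpar * bhat[1],
                      dir[2] - dpar * bhat[2] };
  double dp = std::sqrt(dperp[0] * dperp[0] + dperp[1] * dperp[1] + dperp[2] * dperp[2]);
  if (dp < 1e-14) { // motion parallel to B
    for (int k = 0; k < 3; ++k) pos[k] += step * dir[k];
    return;
  }
  double e1[3] = { dperp[0] / dp, dperp[1] / dp, dperp[2] / dp };
  double e2[3] = { bhat[1] * e1[2] - bhat[2] * e1[1],   // bhat x e1
                   bhat[2] * e1[0] - bhat[0] * e1[2],
                   bhat[0] * e1[1] - bhat[1] * e1[0] };
  double phi = PB * B * step / p;        // direction rotation over the arc
  double r = p * dp / (PB * B);          // gyroradius of the perpendicular motion
  double sphi = std::sin(phi), cphi = std::cos(phi);
  for (int k = 0; k < 3; ++k) {
    pos[k] += step * dpar * bhat[k] + r * (sphi * e1[k] + (1.0 - cphi) * e2[k]);
    dir[k] = dpar * bhat[k] + dp * (cphi * e1[k] + sphi * e2[k]);
  }
  normalize3(dir);
}

// [[Rcpp::export(name = ".transport_cpp")]]
List transport_cpp(NumericVector energies,
                   double B,
                   NumericVector b_axis,
                   double sphere_radius,
                   double cutoff,
                   double max_frac_eloss,
                   double max_step,
                   double seed,
                   bool scattering,
                   double density,
                   double excitation_mev,
                   double z_over_a,
                   double radiation_length,
                   Nullable<NumericMatrix> init_pos = R_NilValue,
                   Nullable<NumericMatrix> init_dir = R_NilValue) {
  const int n = energies.size();
  double bhat[3] = { b_axis[0], b_axis[1], b_axis[2] };
  normalize3(bhat);

  bool have_pos = init_pos.isNotNull(), have_dir = init_dir.isNotNull();
  NumericMatrix P0, D0;
  if (have_pos) P0 = NumericMatrix(init_pos);
  if (have_dir) D0 = NumericMatrix(init_dir);

  std::vector<int> hid;
  std::vector<double> hx, hy, hz, hde;
  hid.reserve(1024); hx.reserve(1024);
  NumericVector dep_sum(n), escaped(n), fx(n), fy(n), fz(n);
  LogicalVector esc_flag(n);

  const double R2 = sphere_radius * sphere_radius;
  const long max_steps = 2000000;

  for (int i = 0; i < n; ++i) {
    Rng rng(mix_seed((uint64_t)seed, (uint64_t)(i + 1)));
    double T = energies[i];
    double pos[3] = {0, 0, 0};
    double dir[3];
    if (have_pos) { pos[0] = P0(i, 0); pos[1] = P0(i, 1); pos[2] = P0(i, 2); }
    if (have_dir) {
      dir[0] = D0(i, 0); dir[1] = D0(i, 1); dir[2] = D0(i, 2);
      normalize3(dir);
    } else { // isotropic
      double c = 2.0 * rng.unif() - 1.0;
      double s = std::sqrt(1.0 - c * c);
      double ph = 2.0 * M_PI * rng.unif();
      dir[0] = s * std::cos(ph); dir[1] = s * std::sin(ph); dir[2] = c;
    }
    if (pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2] > R2)
      stop("initial position outside the sphere");

    if (T <= cutoff) { // immediate local absorption at the source
      if (T > 0) {
        hid.push_back(i + 1); hx.push_back(pos[0]); hy.push_back(pos[1]);
        hz.push_back(pos[2]); hde.push_back(T);
        dep_sum[i] = T;
      }
      fx[i] = pos[0]; fy[i] = pos[1]; fz[i] = pos[2];
      continue;
    }

    bool alive = true;
    double path = 0.0; // cumulative tracklength, for the Highland log term
    for (long it = 0; alive && it < max_steps; ++it) {
      double S = stopping_power(T, density, excitation_mev, z_over_a);
      double step = std::min(max_step, max_frac_eloss * T / S);
      path += step;
      double de = S * step;
      bool last = false;
      if (T - de <= cutoff) { de = T; last = true; } // deposit the remainder locally
      helix_step(pos, dir, T, B, bhat, step);
      if (pos[0] * pos[0] + pos[1] * pos[1] + pos[2] * pos[2] > R2) {
        escaped[i] = T;          // energy carried out of the sphere
        esc_flag[i] = true;
        alive = false;
      } else {
        hid.push_back(i + 1); hx.push_back(pos[0]); hy.push_back(pos[1]);
        hz.push_back(pos[2]); hde.push_back(de);
        dep_sum[i] += de;
        T -= de;
        if (last || T <= 0) {
          alive = false;
        } else if (scattering) {
          // Highland width is the plane-projected RMS angle; the space polar
          // angle of two independent Gaussian projections is Rayleigh with
          // scale sigma (E[theta^2] = 2 sigma^2).
          double sg = highland(T, step, path, density, radiation_length);
          if (sg > 0) {
            double theta = sg * std::sqrt(-2.0 * std::log(rng.unif()));
            deflect(dir, theta, 2.0 * M_PI * rng.unif());
          }
        }
      }
    }
    fx[i] = pos[0]; fy[i] = pos[1]; fz[i] = pos[2];
  }

  return List::create(
    _["particle_id"] = IntegerVector(hid.begin(), hid.end()),
    _["x"] = NumericVector(hx.begin(), hx.end()),
    _["y"] = NumericVector(hy.begin(), hy.end()),
    _["z"] = NumericVector(hz.begin(), hz.end()),
    _["energy"] = NumericVector(hde.begin(), hde.end()),
    _["deposited"] = dep_sum,
    _["escaped_energy"] = escaped,
    _["escaped"] = esc_flag,
    _["final_x"] = fx, _["final_y"] = fy, _["final_z"] = fz);
}
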