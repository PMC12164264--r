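#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic Gaussian-mixture landscapes. 1-D terms: G(r) = sum h_k *
// exp(-(r-c_k)^2 / (2 w_k^2)); 2-D terms are separable Gaussians over
// (com, hb). Energies in kcal/mol, lengths in Angstrom, time in ps.

static inline double g1d(const NumericVector& c, const NumericVector& h,
                         const NumericVector& w, double r) {
  double g = 0.0;
  for (int k = 0; k < c.size(); ++k) {
    double z = (r - c[k]) / w[k];
    g += h[k] * std::exp(-0.5 * z * z);
  }
  return g;
}

static inline double dg1d(const NumericVector& c, const NumericVector& h,
                          const NumericVector& w, double r) {
  double g = 0.0;
  for (int k = 0; k < c.size(); ++k) {
    double z = (r - c[k]) / w[k];
    g += -h[k] * z / w[k] * std::exp(-0.5 * z * z);
  }
  return g;
}

// Overdamped (Brownian) dynamics on G(r) + (k/2)(r - r_c(t))^2 with the
// restraint centre moved at constant speed; the accumulated external work
// is dW = k (r_c - r) dr_c, the standard constant-velocity pulling
// convention. speed == 0 gives a stationary restraint (equilibrium
// sampling; work stays exactly 0). Positions are recorded every
// record_stride steps after n_equil equilibration steps. Uses R's RNG.
// [[Rcpp::export]]
List cpp_brownian_pull(NumericVector centers, NumericVector heights,
                       NumericVector widths, double r_start, double speed_A_ps,
                       double spring_k, double temperature, double diffusion,
                       double dt, int n_steps, int n_equil, int record_stride,
                       double kB) {
  const double kT = kB * temperature;
  const double mob = diffusion / kT;          // mobility, A^2 ps^-1 / (kcal/mol)
  const double sig = std::sqrt(2.0 * diffusion * dt);
  const double max_drift = 0.1;               // A per step, stability guard

  double r = r_start;
  // equilibrate in the restrained bound basin (restraint fixed at r_start)
  for (int s = 0; s < n_equil; ++s) {
    double force = -dg1d(centers, heights, widths, r) - spring_k * (r - r_start);
    double drift = mob * force * dt;
    if (std::fabs(drift) > max_drift)
      stop("integration unstable: deterministic drift per step exceeds 0.1 A; reduce dt");
    r += drift + sig * R::norm_rand();
  }

  int n_rec = n_steps / record_stride;
  NumericVector rc_out(n_rec), w_out(n_rec), r_out(n_rec);
  double rc = r_start, work = 0.0;
  for (int s = 0; s < n_steps; ++s) {
    double force = -dg1d(centers, heights, widths, r) - spring_k * (r - rc);
    double drift = mob * force * dt;
    if (std::fabs(drift) > max_drift)
      stop("integration unstable: deterministic drift per step exceeds 0.1 A; reduce dt");
    r += drift + sig * R::norm_rand();
    double drc = speed_A_ps * dt;
    work += spring_k * (rc - r) * drc;        // dW evaluated before moving rc
    rc += drc;
    if ((s + 1) % record_stride == 0) {
      int i = (s + 1) / record_stride - 1;
      rc_out[i] = rc;
      w_out[i] = work;
      r_out[i] = r;
    }
  }
  return List::create(_["coordinate"] = rc_out, _["work"] = w_out,
                      _["position"] = r_out);
}

static inline void grad2d(const NumericVector& ccom, const NumericVector& chb,
                          const NumericVector& h, const NumericVector& wcom,
                          const NumericVector& whb, double com, double hb,
                          double* gx, double* gy) {
  double gcom = 0.0, ghb = 0.0;
  for (int k = 0; k < ccom.size(); ++k) {
    double zx = (com - ccom[k]) / wcom[k];
    double zy = (hb - chb[k]) / whb[k];
    double e = h[k] * std::exp(-0.5 * (zx * zx + zy * zy));
    gcom += -e * zx / wcom[k];
    ghb += -e * zy / whb[k];
  }
  *gx = gcom;
  *gy = ghb;
}

// RAMD-like dissociation on a 2-D (com displacement, H-bond distance)
// landscape: overdamped dynamics plus a constant-magnitude external force
// whose random orientation is re-drawn whenever the displacement over one
// check interval falls below min_displacement. The centroid reflects at
// zero; the H-bond distance reflects at hb_min (van der Waals contact).
// Terminates when com >= stop_distance or at max_steps (truncated flag).
// Uses R's RNG.
// [[Rcpp::export]]
List cpp_ramd_2d(NumericVector centers_com, NumericVector centers_hb,
                 NumericVector heights, NumericVector widths_com,
                 NumericVector widths_hb, double com0, double hb0,
                 double force_magnitude, double check_interval_ps,
                 double min_displacement, double stop_distance, double dt,
                 int max_steps, double temperature, double diffusion,
                 int record_stride, double kB, double hb_min) {
  const double kT = kB * temperature;
  const double mob = diffusion / kT;
  const double sig = std::sqrt(2.0 * diffusion * dt);
  const int check_stride = std::max(1, (int)std::lround(check_interval_ps / dt));

  double com = com0, hb = hb0;
  double theta = 2.0 * M_PI * R::unif_rand();
  double fx = force_magnitude * std::cos(theta);
  double fy = force_magnitude * std::sin(theta);
  double com_chk = com, hb_chk = hb;

  std::vector<double> t_out, com_out, hb_out;
  t_out.reserve(max_steps / record_stride + 2);
  com_out.reserve(max_steps / record_stride + 2);
  hb_out.reserve(max_steps / record_stride + 2);
  t_out.push_back(0.0); com_out.push_back(com); hb_out.push_back(hb);

  bool truncated = true;
  int s = 0;
  for (; s < max_steps; ++s) {
    double gx, gy;
    grad2d(centers_com, centers_hb, heights, widths_com, widths_hb, com, hb,
           &gx, &gy);
    com += mob * (-gx + fx) * dt + sig * R::norm_rand();
    hb += mob * (-gy + fy) * dt + sig * R::norm_rand();
    if (com < 0) com = -com;
    if (hb < hb_min) hb = 2.0 * hb_min - hb;  // vdW contact wall

    if ((s + 1) % check_stride == 0) {
      double dx = com - com_chk, dy = hb - hb_chk;
      if (std::sqrt(dx * dx + dy * dy) < min_displacement) {
        theta = 2.0 * M_PI * R::unif_rand();
        fx = force_magnitude * std::cos(theta);
        fy = force_magnitude * std::sin(theta);
      }
      com_chk = com; hb_chk = hb;
    }
    if ((s + 1) % record_stride == 0) {
      t_out.push_back((s + 1) * dt);
      com_out.push_back(com);
      hb_out.push_back(hb);
    }
    if (com >= stop_distance) { truncated = false; ++s; break; }
  }
  // ensure the terminal point is recorded
  if (t_out.back() < s * dt) {
    t_out.push_back(s * dt); com_out.push_back(com); hb_out.push_back(hb);
  }
  return List::create(_["time"] = wrap(t_out), _["com"] = wrap(com_out),
                      _["hb"] = wrap(hb_out), _["truncated"] = truncated);
}
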