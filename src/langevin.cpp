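#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-dimensional overdamped Langevin dynamics on a gridded potential with
// on-the-fly Gaussian hill deposition (standard, constant-height metadynamics).
//
// The potential is supplied as force values on a uniform grid covering the CV
// domain; linear interpolation between grid nodes. The accumulated bias is the
// exact sum of deposited Gaussians; hills are bucketed by centre so only hills
// within 8 sigma of the current CV are touched (the neglected tail is below
// 1e-14 of a hill height). Reflective walls at the domain edges.
//
// Uses R's RNG so set.seed() in R makes runs reproducible.

static inline double interp_force(const std::vector<double>& F,
                                  double lo, double h, int n, double x) {
  double u = (x - lo) / h;
  int i = (int)u;
  if (i < 0) i = 0;
  if (i > n - 2) i = n - 2;
  double w = u - i;
  return F[i] * (1.0 - w) + F[i + 1] * w;
}

// [[Rcpp::export]]
List langevin_metad_cpp(NumericVector fgrid, double lo, double hi,
                        double x0, double n_steps_d, double dt,
                        double mobility, double kT,
                        double hill_height, double hill_sigma,
                        int deposit_stride, int cv_stride,
                        int integrator) {
  const int ng = fgrid.size();
  const double h = (hi - lo) / (ng - 1);
  std::vector<double> F(fgrid.begin(), fgrid.end());

  const long n_steps = (long)(n_steps_d + 0.5);
  const long n_save = n_steps / cv_stride;
  const long n_hills = hill_height > 0.0 ? n_steps / deposit_stride : 0;

  NumericVector cv_time(n_save), cv(n_save);
  NumericVector hl_time(n_hills), hl_center(n_hills);

  // hill bucketing by centre
  const double bw = hill_sigma > 0 ? hill_sigma : (hi - lo);
  const int nb = (int)((hi - lo) / bw) + 2;
  std::vector< std::vector<double> > bucket(nb);
  const double inv2s2 = hill_sigma > 0 ? 1.0 / (2.0 * hill_sigma * hill_sigma) : 0.0;
  const double invs2  = hill_sigma > 0 ? 1.0 / (hill_sigma * hill_sigma) : 0.0;

  double x = x0;
  const double noise_amp = std::sqrt(2.0 * kT * mobility * dt);
  double xi_prev = norm_rand();
  long isave = 0, ihill = 0;

  for (long s = 1; s <= n_steps; ++s) {
    // potential force + bias force
    double f = interp_force(F, lo, h, ng, x);
    if (ihill > 0) {
      int jc = (int)((x - lo) / bw);
      int j0 = jc - 8; if (j0 < 0) j0 = 0;
      int j1 = jc + 8; if (j1 > nb - 1) j1 = nb - 1;
      double fb = 0.0;
      for (int j = j0; j <= j1; ++j) {
        const std::vector<double>& b = bucket[j];
        for (size_t q = 0; q < b.size(); ++q) {
          double dx = x - b[q];
          fb += dx * std::exp(-dx * dx * inv2s2);
        }
      }
      f += hill_height * invs2 * fb;
    }

    double xi = norm_rand();
    if (integrator == 1) {          // Leimkuhler-Matthews (BAOAB limit)
      x += mobility * f * dt + noise_amp * 0.5 * (xi_prev + xi);
    } else {                        // Euler-Maruyama
      x += mobility * f * dt + noise_amp * xi;
    }
    xi_prev = xi;

    // reflective walls
    while (x < lo || x > hi) {
      if (x < lo) x = 2.0 * lo - x;
      if (x > hi) x = 2.0 * hi - x;
    }
    if (!std::isfinite(x))
      stop("non-finite CV value encountered during integration (x = %f)", x);

    if (hill_height > 0.0 && (s % deposit_stride) == 0 && ihill < n_hills) {
      hl_time[ihill] = s * dt;
      hl_center[ihill] = x;
      int jc = (int)((x - lo) / bw);
      if (jc < 0) jc = 0;
      if (jc > nb - 1) jc = nb - 1;
      bucket[jc].push_back(x);
      ++ihill;
    }
    if ((s % cv_stride) == 0 && isave < n_save) {
      cv_time[isave] = s * dt;
      cv[isave] = x;
      ++isave;
    }
  }

  return List::create(_["time"] = cv_time, _["cv"] = cv,
                      _["hill_time"] = hl_time, _["hill_center"] = hl_center);
}
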