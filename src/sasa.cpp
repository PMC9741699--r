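#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
// Test points on each atom's extended sphere (vdW + probe) from a
// deterministic golden-spiral lattice; a point is accessible if outside every
// neighbour's extended sphere. Per-atom area = exposed fraction * 4*pi*R^2.

// [[Rcpp::export]]
NumericVector shrake_rupley_cpp(NumericMatrix xyz, NumericVector radius_ext,
                                int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double Ri = radius_ext[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double cut = Ri + radius_ext[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double tx = xyz(i, 0) + Ri * px[k];
      double ty = xyz(i, 1) + Ri * py[k];
      double tz = xyz(i, 2) + Ri * pz[k];
      bool free_pt = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        int j = nbr[q];
        double dx = tx - xyz(j, 0);
        double dy = ty - xyz(j, 1);
        double dz = tz - xyz(j, 2);
        double Rj = radius_ext[j];
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * exposed / n_points;
  }
  return area;
}
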