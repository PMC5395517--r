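#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// Fibonacci-lattice test-point set (no randomness, so areas are
// bit-reproducible and rotation invariance holds to quadrature error).

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int n = coords.nrow();
  NumericVector area(n);
  // Fibonacci sphere points
  std::vector<double> ux(n_points), uy(n_points), uz(n_points);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * k;
    ux[k] = r * std::cos(th); uy[k] = r * std::sin(th); uz[k] = z;
  }
  std::vector<double> er(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) { er[i] = radii[i] + probe; rmax = std::max(rmax, er[i]); }

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    nb.clear();
    double cut = er[i] + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xi - coords(j, 0), dy = yi - coords(j, 1), dz = zi - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < cut * cut && d2 < (er[i] + er[j]) * (er[i] + er[j])) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + er[i] * ux[k], py = yi + er[i] * uy[k], pz = zi + er[i] * uz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = px - coords(j, 0), dy = py - coords(j, 1), dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * (double)acc / n_points;
  }
  return area;
}
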