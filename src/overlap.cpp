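#include <Rcpp.h>
using namespace Rcpp;

// Exact double-sum Gaussian overlap between two typed point sets:
//   O = sum_ij delta(type_i, type_j) (pi/(2 gamma))^(3/2) exp(-(gamma/2) d_ij^2)
// No cutoff truncation: patch sizes are small enough for the full sum.

// [[Rcpp::export(name = ".gaussian_overlap_cpp")]]
double gaussian_overlap_cpp(NumericMatrix a, NumericMatrix b,
                            IntegerVector ta, IntegerVector tb,
                            double gamma, bool type_matched) {
  int na = a.nrow(), nb = b.nrow();
  double pref = std::pow(M_PI / (2.0 * gamma), 1.5);
  double g2 = gamma / 2.0;
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    int ti = type_matched ? ta[i] : 0;
    for (int j = 0; j < nb; ++j) {
      if (type_matched && ti != tb[j]) continue;
      double dx = xi - b(j, 0), dy = yi - b(j, 1), dz = zi - b(j, 2);
      acc += std::exp(-g2 * (dx * dx + dy * dy + dz * dz));
    }
  }
  return pref * acc;
}

// PatchScore objective for one rigid transform of patch b:
// returns (3*T_color + T_shape, T_shape, T_color). Self-overlaps are
// precomputed by the caller; transform is x -> R x + t.
// [[Rcpp::export(name = ".patch_objective_cpp")]]
NumericVector patch_objective_cpp(NumericMatrix as, NumericMatrix bs,
                                  NumericMatrix ac, NumericMatrix bc,
                                  IntegerVector ta, IntegerVector tb,
                                  double gamma_shape, double gamma_color,
                                  double o_aa_s, double o_bb_s,
                                  double o_aa_c, double o_bb_c,
                                  bool has_color,
                                  NumericMatrix R, NumericVector t) {
  double prefs = std::pow(M_PI / (2.0 * gamma_shape), 1.5);
  double gs2 = gamma_shape / 2.0;
  int na = as.nrow(), nb = bs.nrow();
  double acc = 0.0;
  for (int j = 0; j < nb; ++j) {
    double x = R(0,0)*bs(j,0) + R(0,1)*bs(j,1) + R(0,2)*bs(j,2) + t[0];
    double y = R(1,0)*bs(j,0) + R(1,1)*bs(j,1) + R(1,2)*bs(j,2) + t[1];
    double z = R(2,0)*bs(j,0) + R(2,1)*bs(j,1) + R(2,2)*bs(j,2) + t[2];
    for (int i = 0; i < na; ++i) {
      double dx = as(i,0) - x, dy = as(i,1) - y, dz = as(i,2) - z;
      acc += std::exp(-gs2 * (dx*dx + dy*dy + dz*dz));
    }
  }
  double o_ab_s = prefs * acc;
  double ts = o_ab_s / (o_aa_s + o_bb_s - o_ab_s);
  ts = std::min(1.0, std::max(0.0, ts));
  double tc = 0.0;
  if (has_color) {
    double prefc = std::pow(M_PI / (2.0 * gamma_color), 1.5);
    double gc2 = gamma_color / 2.0;
    int nac = ac.nrow(), nbc = bc.nrow();
    double accc = 0.0;
    for (int j = 0; j < nbc; ++j) {
      double x = R(0,0)*bc(j,0) + R(0,1)*bc(j,1) + R(0,2)*bc(j,2) + t[0];
      double y = R(1,0)*bc(j,0) + R(1,1)*bc(j,1) + R(1,2)*bc(j,2) + t[1];
      double z = R(2,0)*bc(j,0) + R(2,1)*bc(j,1) + R(2,2)*bc(j,2) + t[2];
      for (int i = 0; i < nac; ++i) {
        if (ta[i] != tb[j]) continue;
        double dx = ac(i,0) - x, dy = ac(i,1) - y, dz = ac(i,2) - z;
        accc += std::exp(-gc2 * (dx*dx + dy*dy + dz*dz));
      }
    }
    double o_ab_c = prefc * accc;
    tc = o_ab_c / (o_aa_c + o_bb_c - o_ab_c);
    tc = std::min(1.0, std::max(0.0, tc));
  }
  return NumericVector::create(3.0 * tc + ts, ts, tc);
}
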