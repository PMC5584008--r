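#include <Rcpp.h>
#include <Rmath.h>
using namespace Rcpp;

// Exhaustive nearest-point search on the arch curve: for each sample
// (xs, ys) returns the grid abscissa minimizing
// (x - xs)^2 + theta^2 (arch(x) - ys)^2 over ngrid equispaced points.
// Reference implementation used to validate the projection's
// grid-plus-refinement search.
// [[Rcpp::export(name = ".arch_brute")]]
NumericVector arch_brute(NumericVector xs, NumericVector ys, double theta,
                         int ngrid) {
  const int n = xs.size();
  std::vector<double> grid(ngrid), ag(ngrid);
  for (int j = 0; j < ngrid; ++j) {
    double x = (double)j / (ngrid - 1);
    grid[j] = x;
    ag[j] = (x <= 0.0 || x >= 1.0) ? 0.0 : ::Rf_dnorm4(::Rf_qnorm5(x, 0, 1, 1, 0), 0, 1, 0);
  }
  NumericVector out(n);
  const double th2 = theta * theta;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf, bx = 0.0;
    for (int j = 0; j < ngrid; ++j) {
      double dx = grid[j] - xs[i];
      double dy = ag[j] - ys[i];
      double d2 = dx * dx + th2 * dy * dy;
      if (d2 < best) { best = d2; bx = grid[j]; }
    }
    out[i] = bx;
  }
  return out;
}
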