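#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum of unit-amplitude isotropic Gaussians exp(-d^2 / (2 sigma^2)) placed at
// atom positions, evaluated on the tensor grid (ax x ay x az). The Gaussian
// is separable, so each atom contributes an outer product of three
// per-axis exponential vectors. Output is in R array order (x fastest).
// [[Rcpp::export]]
NumericVector density_accumulate_cpp(NumericMatrix xyz, NumericVector ax,
                                     NumericVector ay, NumericVector az,
                                     double sigma) {
  const int nx = ax.size(), ny = ay.size(), nz = az.size();
  const int na = xyz.nrow();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> ex(nx), ey(ny), ez(nz);
  for (int a = 0; a < na; ++a) {
    const double x = xyz(a, 0), y = xyz(a, 1), z = xyz(a, 2);
    for (int i = 0; i < nx; ++i) {
      const double d = ax[i] - x;
      ex[i] = std::exp(-d * d * inv2s2);
    }
    for (int j = 0; j < ny; ++j) {
      const double d = ay[j] - y;
      ey[j] = std::exp(-d * d * inv2s2);
    }
    for (int k = 0; k < nz; ++k) {
      const double d = az[k] - z;
      ez[k] = std::exp(-d * d * inv2s2);
    }
    double *p = REAL(out);
    for (int k = 0; k < nz; ++k) {
      const double fz = ez[k];
      if (fz < 1e-300) { continue; }
      for (int j = 0; j < ny; ++j) {
        const double f = fz * ey[j];
        double *row = p + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k);
        for (int i = 0; i < nx; ++i) {
          row[i] += f * ex[i];
        }
      }
    }
  }
  return out;
}
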