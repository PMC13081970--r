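#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Boundary index mapping for out-of-range line positions.
// mode: 0 = reflect (symmetric, edge voxel repeated: c b a | a b c | c b a),
//       1 = nearest, 2 = constant (flagged by -1, caller substitutes cval).
static inline int map_index(int i, int n, int mode) {
  if (i >= 0 && i < n) return i;
  if (mode == 2) return -1;
  if (mode == 1) return i < 0 ? 0 : n - 1;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// Correlate a 3D column-major array with a centered 1D kernel along one axis.
//   out[i] = sum_t kernel[t] * in[i + t - r],  r = (length(kernel) - 1) / 2
// axis: 1, 2 or 3 (R convention). Kernel length must be odd.
// [[Rcpp::export(name = ".conv3d_axis")]]
NumericVector conv3d_axis(const NumericVector& x, const IntegerVector& dim,
                          const NumericVector& kernel, int axis, int mode,
                          double cval) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int r = (klen - 1) / 2;
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");

  const int n = (axis == 1) ? n1 : (axis == 2 ? n2 : n3);
  const R_xlen_t stride = (axis == 1) ? 1 :
    (axis == 2 ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2);

  NumericVector out(no_init(x.size()));
  const double* px = x.begin();
  const double* pk = kernel.begin();
  double* po = out.begin();

  std::vector<double> buf(n + 2 * r);

  // iterate over all lines along `axis`
  const int m1 = (axis == 1) ? n2 : n1;
  const int m2 = (axis == 3) ? n2 : n3;
  const R_xlen_t s1 = (axis == 1) ? (R_xlen_t)n1 : 1;
  const R_xlen_t s2 = (axis == 3) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;

  for (int j2 = 0; j2 < m2; ++j2) {
    for (int j1 = 0; j1 < m1; ++j1) {
      const R_xlen_t base = (R_xlen_t)j1 * s1 + (R_xlen_t)j2 * s2;
      // fill padded line buffer
      for (int i = -r; i < n + r; ++i) {
        int im = map_index(i, n, mode);
        buf[i + r] = (im < 0) ? cval : px[base + (R_xlen_t)im * stride];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double* b = &buf[i];
        for (int t = 0; t < klen; ++t) acc += pk[t] * b[t];
        po[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
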