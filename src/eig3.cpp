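// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Voxel-wise eigendecomposition of a field of symmetric 3x3 tensors.
// S: n x 6 matrix of unique components in order (xx, xy, xz, yy, yz, zz).
// Returns lambda (n x 3, descending: l1 >= l2 >= l3) and v3 (n x 3), the unit
// eigenvector of the smallest eigenvalue, sign-canonicalized so that its
// largest-magnitude component is positive (orientation is axial: v3 == -v3).
// [[Rcpp::export(name = ".eig3_field")]]
List eig3_field(const NumericMatrix& S) {
  const int n = S.nrow();
  if (S.ncol() != 6) stop("S must have 6 columns (xx, xy, xz, yy, yz, zz)");
  NumericMatrix lambda(n, 3), v3(n, 3);

  arma::mat33 A;
  arma::vec3 eval;
  arma::mat33 evec;

  for (int i = 0; i < n; ++i) {
    const double xx = S(i, 0), xy = S(i, 1), xz = S(i, 2);
    const double yy = S(i, 3), yz = S(i, 4), zz = S(i, 5);
    if (!std::isfinite(xx) || !std::isfinite(xy) || !std::isfinite(xz) ||
        !std::isfinite(yy) || !std::isfinite(yz) || !std::isfinite(zz))
      stop("non-finite tensor entry at voxel index %d", i + 1);
    A(0, 0) = xx; A(0, 1) = xy; A(0, 2) = xz;
    A(1, 0) = xy; A(1, 1) = yy; A(1, 2) = yz;
    A(2, 0) = xz; A(2, 1) = yz; A(2, 2) = zz;
    arma::eig_sym(eval, evec, A);  // ascending order
    lambda(i, 0) = eval(2);
    lambda(i, 1) = eval(1);
    lambda(i, 2) = eval(0);
    // eigenvector of the smallest eigenvalue
    double vx = evec(0, 0), vy = evec(1, 0), vz = evec(2, 0);
    double ax = std::fabs(vx), ay = std::fabs(vy), az = std::fabs(vz);
    double lead = (ax >= ay && ax >= az) ? vx : (ay >= az ? vy : vz);
    if (lead < 0) { vx = -vx; vy = -vy; vz = -vz; }
    v3(i, 0) = vx; v3(i, 1) = vy; v3(i, 2) = vz;
  }
  return List::create(_["lambda"] = lambda, _["v3"] = v3);
}
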