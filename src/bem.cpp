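// Solid-angle assembly for the collocation boundary element method.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Signed solid angle subtended by each triangle at each observation point
// (van Oosterom & Strackee 1983).  obs: N x 3; V: nv x 3; F: nt x 3
// (1-based vertex indices).  Positive for a triangle whose outward normal
// (counter-clockwise vertex order) faces away from the observation point.
// [[Rcpp::export]]
arma::mat solid_angles_cpp(const arma::mat& obs, const arma::mat& V,
                           const arma::imat& F) {
  const int N = obs.n_rows, nt = F.n_rows;
  arma::mat W(N, nt);
  for (int t = 0; t < nt; ++t) {
    const arma::rowvec v1 = V.row(F(t, 0) - 1);
    const arma::rowvec v2 = V.row(F(t, 1) - 1);
    const arma::rowvec v3 = V.row(F(t, 2) - 1);
    for (int i = 0; i < N; ++i) {
      const arma::rowvec r1 = v1 - obs.row(i);
      const arma::rowvec r2 = v2 - obs.row(i);
      const arma::rowvec r3 = v3 - obs.row(i);
      const double n1 = arma::norm(r1), n2 = arma::norm(r2), n3 = arma::norm(r3);
      const double num = arma::dot(r1, arma::cross(r2, r3));
      const double den = n1 * n2 * n3 + arma::dot(r1, r2) * n3 +
        arma::dot(r1, r3) * n2 + arma::dot(r2, r3) * n1;
      W(i, t) = 2.0 * std::atan2(num, den);
    }
  }
  return W;
}
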