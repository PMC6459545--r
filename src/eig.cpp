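#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Eigen-decomposition of symmetric 3x3 structure tensors, one per row of
// `tensors` with components ordered (xx, xy, xz, yy, yz, zz). Returns the
// unit eigenvector of the smallest eigenvalue (the local fiber axis for a
// tubular structure) and all eigenvalues in ascending order.
// [[Rcpp::export]]
List cpp_smallest_eigvec3(NumericMatrix tensors) {
  const int n = tensors.nrow();
  NumericMatrix vec(n, 3), val(n, 3);
  arma::mat33 T;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    T(0, 0) = tensors(i, 0); T(0, 1) = tensors(i, 1); T(0, 2) = tensors(i, 2);
    T(1, 0) = tensors(i, 1); T(1, 1) = tensors(i, 3); T(1, 2) = tensors(i, 4);
    T(2, 0) = tensors(i, 2); T(2, 1) = tensors(i, 4); T(2, 2) = tensors(i, 5);
    arma::eig_sym(ev, V, T);
    vec(i, 0) = V(0, 0); vec(i, 1) = V(1, 0); vec(i, 2) = V(2, 0);
    val(i, 0) = ev(0); val(i, 1) = ev(1); val(i, 2) = ev(2);
  }
  return List::create(_["vectors"] = vec, _["values"] = val);
}
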