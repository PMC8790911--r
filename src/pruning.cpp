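// Felsenstein pruning inner loop for reversible genotype models.
// Transition probabilities come from the cached eigendecomposition:
// P(t) = A * diag(exp(values * t)) * Ainv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat pmat(const mat& A, const mat& Ainv, const vec& ev, double t) {
  mat B = Ainv;
  B.each_col() %= exp(ev * t);
  mat P = A * B;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  return P;
}

// edges: k x 2 (child, parent), postorder (children before parents),
// 1-based node ids; tips occupy slices 1..ntip of `tips`.
// [[Rcpp::export(name = ".cpp_loglik_inward")]]
Rcpp::List cpp_loglik_inward(const arma::imat& edges,
                             const arma::vec& elen,
                             const int ntip,
                             const arma::cube& tips,
                             const arma::mat& A,
                             const arma::mat& Ainv,
                             const arma::vec& ev,
                             const arma::vec& pi,
                             const arma::vec& weights) {
  const uword s = tips.n_cols;
  const uword ns = tips.n_rows;
  int ntot = ntip;
  for (uword k = 0; k < edges.n_rows; ++k) {
    ntot = std::max(ntot, std::max(edges(k, 0), edges(k, 1)));
  }
  field<mat> M(ntot + 1);
  mat SC(ntot + 1, s, fill::zeros);
  uvec started(ntot + 1, fill::zeros);
  int root = edges(edges.n_rows - 1, 1);
  for (uword k = 0; k < edges.n_rows; ++k) {
    int ch = edges(k, 0), par = edges(k, 1);
    mat P = pmat(A, Ainv, ev, elen(k));
    mat child = (ch <= ntip) ? mat(tips.slice(ch - 1)) : M(ch);
    rowvec csc = (ch <= ntip) ? rowvec(s, fill::zeros) : rowvec(SC.row(ch));
    // rescale completed child (underflow control)
    rowvec mx = sum(child, 0);
    mx.transform([](double x) { return x <= 0 ? 1.0 : x; });
    child.each_row() /= mx;
    csc += log(mx);
    mat contrib = P * child;
    if (!started(par)) {
      M(par) = contrib;
      SC.row(par) = csc;
      started(par) = 1;
    } else {
      M(par) %= contrib;
      SC.row(par) += csc;
    }
    if (ch > ntip) M(ch).reset();
  }
  rowvec rootl = pi.t() * M(root);
  rowvec sl = log(rootl) + SC.row(root);
  double total = dot(weights, sl.t());
  return Rcpp::List::create(Rcpp::Named("loglik") = total,
                            Rcpp::Named("site_loglik") = sl);
}
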