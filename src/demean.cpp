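// Iterated weighted demeaning (alternating projections) over several
// categorical factors — the inner loop of the within estimator and its
// bootstrap replicates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// m: n x c data; f: n x F 1-based factor codes; w: weights.
// Subtracts weighted group means factor by factor until the largest
// adjustment falls below tol (supremum norm).
// [[Rcpp::export]]
Rcpp::List demean_cpp(arma::mat m, const arma::imat& f, const arma::vec& w,
                      double tol = 1e-10, int max_iter = 2000) {
  const uword n = m.n_rows, C = m.n_cols, F = f.n_cols;
  std::vector<uword> nlev(F);
  for (uword j = 0; j < F; ++j) nlev[j] = (uword) f.col(j).max();
  std::vector<vec> gw(F);
  for (uword j = 0; j < F; ++j) {
    gw[j] = vec(nlev[j], fill::zeros);
    for (uword i = 0; i < n; ++i) gw[j][f(i, j) - 1] += w[i];
    gw[j].transform([](double v) { return v > 0 ? v : 1.0; });
  }
  int sweeps = 0;
  for (sweeps = 0; sweeps < max_iter; ++sweeps) {
    double delta = 0.0;
    for (uword j = 0; j < F; ++j) {
      for (uword c = 0; c < C; ++c) {
        vec gs(nlev[j], fill::zeros);
        for (uword i = 0; i < n; ++i) gs[f(i, j) - 1] += w[i] * m(i, c);
        gs /= gw[j];
        double dmax = abs(gs).max();
        if (dmax > delta) delta = dmax;
        for (uword i = 0; i < n; ++i) m(i, c) -= gs[f(i, j) - 1];
      }
    }
    if (delta < tol) { ++sweeps; break; }
  }
  return Rcpp::List::create(Rcpp::Named("m") = m,
                            Rcpp::Named("sweeps") = sweeps);
}
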