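// Ridge-penalized multinomial logistic fit on an aggregated count table.
// Categorical covariates make the (context x unit) contingency table a
// sufficient statistic, and every context row of the implicit dummy
// design has at most three nonzero entries (intercept, one hour dummy,
// one day dummy), so gradient and Hessian assemble in O(G) per block.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// hour_idx/dow_idx: 1-based level index per context row (level 1 is the
// reference absorbed into the intercept); H/D: level counts; N: G x K
// counts with the reference unit in column 0. Coefficient layout per
// non-reference unit: [intercept, hour levels 2..H, dow levels 2..D].
// Maximizes sum N log P - ridge * ||B||^2 by damped Newton from zero.
// [[Rcpp::export]]
Rcpp::List multinom_newton(const arma::ivec& hour_idx,
                           const arma::ivec& dow_idx,
                           int H, int D, const arma::mat& N,
                           double ridge, int max_iter = 100,
                           double tol = 1e-9) {
  const uword G = N.n_rows, K = N.n_cols;
  const uword m = K - 1;
  const uword p = 1 + (H - 1) + (D - 1);
  const vec n_g = sum(N, 1);
  mat B(p, m, fill::zeros);

  // per-row nonzero column pattern (intercept always, -1 = absent)
  ivec hcol(G), dcol(G);
  for (uword g = 0; g < G; ++g) {
    hcol[g] = hour_idx[g] > 1 ? hour_idx[g] - 1 : -1;
    dcol[g] = dow_idx[g] > 1 ? (H - 1) + dow_idx[g] - 1 : -1;
  }

  auto probs = [&](const mat& Bcur) -> mat {
    mat eta(G, m);
    for (uword k = 0; k < m; ++k) {
      for (uword g = 0; g < G; ++g) {
        double e = Bcur(0, k);
        if (hcol[g] >= 0) e += Bcur(hcol[g], k);
        if (dcol[g] >= 0) e += Bcur(dcol[g], k);
        eta(g, k) = e;
      }
    }
    vec mx = max(join_horiz(zeros<vec>(G), eta), 1);
    mat ex = exp(eta.each_col() - mx);
    vec denom = exp(-mx) + sum(ex, 1);
    mat P(G, K);
    P.col(0) = exp(-mx) / denom;
    for (uword k = 0; k < m; ++k) P.col(k + 1) = ex.col(k) / denom;
    return P;
  };
  auto pll = [&](const mat& Bcur, const mat& P) -> double {
    double ll = accu(N % log(clamp(P, 1e-300, 1.0)));
    return ll - ridge * accu(Bcur % Bcur);
  };
  auto gradient = [&](const mat& Bcur, const mat& P) -> vec {
    vec g2(p * m, fill::zeros);
    for (uword k = 0; k < m; ++k) {
      double* gk = g2.memptr() + k * p;
      for (uword g = 0; g < G; ++g) {
        double r = N(g, k + 1) - n_g[g] * P(g, k + 1);
        gk[0] += r;
        if (hcol[g] >= 0) gk[hcol[g]] += r;
        if (dcol[g] >= 0) gk[dcol[g]] += r;
      }
      for (uword a = 0; a < p; ++a) gk[a] -= 2.0 * ridge * Bcur(a, k);
    }
    return g2;
  };

  mat P = probs(B);
  double f = pll(B, P);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    vec g2 = gradient(B, P);
    if (norm(g2, "inf") < 1e-6) { converged = true; break; }
    mat Hs(p * m, p * m, fill::zeros);
    for (uword k = 0; k < m; ++k) {
      for (uword l = 0; l <= k; ++l) {
        mat blk(p, p, fill::zeros);
        for (uword g = 0; g < G; ++g) {
          double v = (k == l)
            ? n_g[g] * P(g, k + 1) * (1.0 - P(g, k + 1))
            : -(n_g[g] * P(g, k + 1) * P(g, l + 1));
          const int cols[3] = {0, (int)hcol[g], (int)dcol[g]};
          for (int a = 0; a < 3; ++a) {
            if (cols[a] < 0) continue;
            for (int b = 0; b < 3; ++b) {
              if (cols[b] < 0) continue;
              blk(cols[a], cols[b]) -= v;
            }
          }
        }
        if (k == l) blk.diag() -= 2.0 * ridge;
        Hs.submat(k * p, l * p, (k + 1) * p - 1, (l + 1) * p - 1) = blk;
        if (l != k) {
          Hs.submat(l * p, k * p, (l + 1) * p - 1, (k + 1) * p - 1) = blk.t();
        }
      }
    }
    vec step;
    bool ok = solve(step, Hs, -g2,
                    solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      mat Hd = Hs;
      Hd.diag() -= 1e-6;
      if (!solve(step, Hd, -g2)) break;
    }
    // step halving on the penalized objective
    double alpha = 1.0;
    mat Bnew, Pnew;
    double fnew;
    int halves = 0;
    do {
      Bnew = B + alpha * reshape(step, p, m);
      Pnew = probs(Bnew);
      fnew = pll(Bnew, Pnew);
      alpha *= 0.5;
      ++halves;
    } while (fnew < f - 1e-12 && halves < 30);
    if (fnew < f - 1e-12) break;  // no improving step
    double df = fnew - f;
    B = Bnew; P = Pnew; f = fnew;
    if (std::abs(df) < tol * (std::abs(f) + 1.0) &&
        norm(gradient(B, P), "inf") < 1e-5) {
      converged = true;
      break;
    }
  }
  if (!converged) {
    converged = norm(gradient(B, P), "inf") < 1e-5;
  }
  double loglik = accu(N % log(clamp(P, 1e-300, 1.0)));
  return Rcpp::List::create(
    Rcpp::Named("coef") = B,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("penalized") = f,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter);
}
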