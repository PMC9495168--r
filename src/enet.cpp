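#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net on a standardized design.
//
// Minimizes (1/(2n)) * ||y - X b||^2 + lambda * ((1-alpha)/2 * ||b||^2
//                                               + alpha * ||b||_1)
// for a decreasing sequence of lambda values with warm starts. Columns of X
// are assumed centered; `xsq` holds (1/n) * x_j'x_j (1 for unit-variance
// columns, 0 flags a dropped zero-variance column). y is assumed centered.
//
// After each full sweep the solver cycles over the active set only until it
// stabilizes, then re-checks with a full sweep (the usual active-set
// strategy); convergence is a full sweep whose largest coefficient change
// falls below `tol`.
//
// Returns an m x L coefficient matrix (one column per lambda).
// [[Rcpp::export(name = ".enet_cd_path")]]
NumericMatrix enet_cd_path(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& xsq,
                           const NumericVector& lambdas, double alpha,
                           double tol, int max_iter) {
  const int n = X.nrow(), m = X.ncol(), L = lambdas.size();
  NumericMatrix out(m, L);
  std::vector<double> b(m, 0.0), r(y.begin(), y.end());
  std::vector<int> active;
  active.reserve(m);

  auto update_coord = [&](int j) -> double {
    const double* xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    return rho;
  };

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha;
    const double l2 = lam * (1.0 - alpha);
    int iter = 0;
    while (iter < max_iter) {
      // full sweep
      ++iter;
      double max_delta = 0.0;
      for (int j = 0; j < m; ++j) {
        if (xsq[j] <= 0.0) continue;
        double rho = update_coord(j) / n + xsq[j] * b[j];
        double bj = 0.0;
        if (rho > l1)       bj = (rho - l1) / (xsq[j] + l2);
        else if (rho < -l1) bj = (rho + l1) / (xsq[j] + l2);
        const double delta = bj - b[j];
        if (delta != 0.0) {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) r[i] -= delta * xj[i];
          b[j] = bj;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) break;

      // iterate on the active set until it stabilizes
      active.clear();
      for (int j = 0; j < m; ++j) if (b[j] != 0.0) active.push_back(j);
      while (iter < max_iter) {
        ++iter;
        double amax = 0.0;
        for (int j : active) {
          double rho = update_coord(j) / n + xsq[j] * b[j];
          double bj = 0.0;
          if (rho > l1)       bj = (rho - l1) / (xsq[j] + l2);
          else if (rho < -l1) bj = (rho + l1) / (xsq[j] + l2);
          const double delta = bj - b[j];
          if (delta != 0.0) {
            const double* xj = &X(0, j);
            for (int i = 0; i < n; ++i) r[i] -= delta * xj[i];
            b[j] = bj;
            const double ad = std::fabs(delta);
            if (ad > amax) amax = ad;
          }
        }
        if (amax < tol) break;
      }
    }
    for (int j = 0; j < m; ++j) out(j, l) = b[j];
  }
  return out;
}
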