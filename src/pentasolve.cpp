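#include <Rcpp.h>
using namespace Rcpp;

// Solves A x = b for symmetric positive-definite pentadiagonal A given by
// its main diagonal d0 and first/second super-diagonals d1, d2
// (lengths n, n-1, n-2), via banded LDL^T factorization.
// [[Rcpp::export(name = ".penta_solve")]]
NumericVector penta_solve(NumericVector d0, NumericVector d1,
                          NumericVector d2, NumericVector b) {
  int n = d0.size();
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0);
  NumericVector x(n);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
    if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double e = d1[i];
      if (i >= 1) e -= L1[i - 1] * L2[i - 1] * D[i - 1];
      L1[i] = e / D[i];
    }
    if (i + 2 < n) L2[i] = d2[i] / D[i];
  }
  // forward substitution L y = b
  for (int i = 0; i < n; ++i) {
    double yi = b[i];
    if (i >= 1) yi -= L1[i - 1] * x[i - 1];
    if (i >= 2) yi -= L2[i - 2] * x[i - 2];
    x[i] = yi;
  }
  // diagonal and backward substitution L^T x = y / D
  for (int i = n - 1; i >= 0; --i) {
    double xi = x[i] / D[i];
    if (i + 1 < n) xi -= L1[i] * x[i + 1];
    if (i + 2 < n) xi -= L2[i] * x[i + 2];
    x[i] = xi;
  }
  return x;
}
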