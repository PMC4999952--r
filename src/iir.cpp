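#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// b, a are coefficient vectors with a[0] == 1 (normalized by the caller);
// zi has length max(len(a), len(b)) - 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(na, nb);
  int n = x.size();
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const double *bp = bb.data(), *ap = aa.data();
  double *zp = z.data();
  for (int i = 0; i < n; ++i) {
    double xi = xp[i];
    double yi = bp[0] * xi + zp[0];
    for (int j = 0; j < nf - 2; ++j)
      zp[j] = bp[j + 1] * xi + zp[j + 1] - ap[j + 1] * yi;
    zp[nf - 2] = bp[nf - 1] * xi - ap[nf - 1] * yi;
    yp[i] = yi;
  }
  return y;
}
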