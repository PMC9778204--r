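#include <Rcpp.h>
using namespace Rcpp;

// Template-match pair counts for sample entropy.
//
// Counts unordered pairs (i, j), i < j, of m-length templates whose
// Chebyshev distance is strictly below r, and likewise for (m+1)-length
// templates.  Template starts for order m run over 1..Ns-m+1 and for
// order m+1 over 1..Ns-m, mirroring the printed counting convention of
// the generalized-MSE algorithm (self-matches excluded by construction).
// [[Rcpp::export]]
NumericVector sampen_pair_counts(NumericVector y, int m, double r) {
  const int n = y.size();
  const int nm = n - m + 1;   // templates of length m
  const int nm1 = n - m;      // templates of length m + 1
  double cm = 0.0, cm1 = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double ad = std::abs(y[i + k] - y[j + k]);
        if (ad > d) d = ad;
        if (d >= r) break;
      }
      if (d < r) {
        cm += 1.0;
        if (j < nm1) {
          double ad = std::abs(y[i + m] - y[j + m]);
          if (ad < r && d < r) {
            double dmax = d > ad ? d : ad;
            if (dmax < r) cm1 += 1.0;
          }
        }
      }
    }
  }
  return NumericVector::create(cm, cm1);
}
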