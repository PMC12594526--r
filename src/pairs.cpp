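#include <Rcpp.h>
using namespace Rcpp;

// Count ordered pairs (i != j) with distance <= each threshold in r
// (r must be increasing). Returns cumulative counts per threshold.
// [[Rcpp::export(name = ".count_pairs_within")]]
NumericVector count_pairs_within(NumericVector x, NumericVector y,
                                 NumericVector r) {
  const int n = x.size();
  const int nr = r.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = r[k] * r[k];
  std::vector<double> counts(nr, 0.0);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j];
      const double dy = yi - y[j];
      const double d2 = dx * dx + dy * dy;
      // first threshold >= d2 via binary search on the squared grid
      int lo = std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin();
      if (lo < nr) counts[lo] += 2.0;  // both (i,j) and (j,i)
    }
  }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) {
    acc += counts[k];
    out[k] = acc;
  }
  return out;
}
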