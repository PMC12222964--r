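// Batch two-sided Wilcoxon rank-sum tests of many sub-cube samples against
// one reference sample, using the tie-corrected normal approximation with
// continuity correction (matching stats::wilcox.test(exact = FALSE)).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_ranksum_batch(NumericVector refSorted, List tests) {
  int m = tests.size();
  NumericVector out(m);
  int n2 = refSorted.size();
  std::vector<double> buf;
  for (int t = 0; t < m; ++t) {
    NumericVector x = tests[t];
    int n1 = x.size();
    buf.assign(x.begin(), x.end());
    std::sort(buf.begin(), buf.end());
    // W = rank-sum statistic of the test sample minus its minimum, i.e. the
    // Mann-Whitney U of x against ref; ties give half counts.
    double U = 0;
    {
      int lo = 0, hi = 0;
      for (int i = 0; i < n1; ++i) {
        double v = buf[i];
        while (lo < n2 && refSorted[lo] < v) ++lo;
        if (hi < lo) hi = lo;
        while (hi < n2 && refSorted[hi] <= v) ++hi;
        U += lo + 0.5 * (hi - lo);
      }
    }
    // tie correction over the pooled sample
    double tieSum = 0;
    {
      int i = 0, jj = 0;
      int n = n1 + n2;
      while (i < n1 || jj < n2) {
        double v;
        if (jj >= n2 || (i < n1 && buf[i] <= refSorted[jj])) v = buf[i];
        else v = refSorted[jj];
        double cnt = 0;
        while (i < n1 && buf[i] == v) { ++i; ++cnt; }
        while (jj < n2 && refSorted[jj] == v) { ++jj; ++cnt; }
        tieSum += cnt * cnt * cnt - cnt;
      }
      double sigma2 = ((double)n1 * n2 / 12.0) *
        ((n + 1.0) - tieSum / ((double)n * (n - 1.0)));
      double z = U - (double)n1 * n2 / 2.0;
      double corr = (z > 0) ? 0.5 : ((z < 0) ? -0.5 : 0.0);
      if (sigma2 <= 0) { out[t] = 1.0; continue; }
      z = (z - corr) / std::sqrt(sigma2);
      double p = 2.0 * std::min(R::pnorm(z, 0, 1, 1, 0), R::pnorm(z, 0, 1, 0, 0));
      out[t] = std::min(1.0, p);
    }
  }
  return out;
}
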