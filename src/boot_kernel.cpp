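#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// median of a scratch vector (modified in place); mean of the two middle
// order statistics for even counts, matching stats::median
static double med_inplace(std::vector<double> &x) {
  const size_t n = x.size();
  const size_t h = n / 2;
  std::nth_element(x.begin(), x.begin() + h, x.end());
  double m = x[h];
  if (n % 2 == 0) {
    const double lo = *std::max_element(x.begin(), x.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Weighted-bootstrap iteration kernel.
//
// Per iteration: draw n_draw test genes uniformly with replacement and
// n_draw reference genes with replacement proportional to ref_weights
// (inverse-CDF on the cumulative weights); compute
//   median_diff = median(log2 TPM of test draws with TPM > 0)
//               - median(log2 TPM of reference draws with TPM > 0)
//   prop_diff   = (share of test draws with TPM > threshold)
//               - (share of reference draws with TPM > threshold)
// median_diff is NA when one side has no non-zero draw.  Uses R's RNG, so
// results are reproducible under set.seed(); the draw order (n test then
// n reference uniforms per iteration) is mirrored by the pure-R engine.
// [[Rcpp::export(name = ".boot_kernel")]]
List boot_kernel(NumericVector tpm_test, NumericVector tpm_ref,
                 NumericVector ref_weights, int n_draw, int n_iter,
                 double expressed_threshold) {
  const int nt = tpm_test.size();
  const int nr = tpm_ref.size();
  if (nt < 1 || nr < 1) stop("empty pool");
  if (ref_weights.size() != nr) stop("weights/pool length mismatch");

  std::vector<double> cumw(nr);
  double tot = 0.0;
  for (int i = 0; i < nr; ++i) {
    if (ref_weights[i] < 0) stop("negative weight");
    tot += ref_weights[i];
    cumw[i] = tot;
  }
  if (tot <= 0) stop("all reference weights are zero");

  NumericVector med_diff(n_iter), prop_diff(n_iter);
  std::vector<double> lt, lr;
  lt.reserve(n_draw);
  lr.reserve(n_draw);

  for (int b = 0; b < n_iter; ++b) {
    lt.clear();
    lr.clear();
    int expr_t = 0, expr_r = 0;
    for (int j = 0; j < n_draw; ++j) {
      int idx = (int)(unif_rand() * nt);
      if (idx >= nt) idx = nt - 1;
      const double v = tpm_test[idx];
      if (v > expressed_threshold) ++expr_t;
      if (v > 0) lt.push_back(std::log2(v));
    }
    for (int j = 0; j < n_draw; ++j) {
      const double target = unif_rand() * tot;
      int idx = (int)(std::upper_bound(cumw.begin(), cumw.end(), target) -
                      cumw.begin());
      if (idx >= nr) idx = nr - 1;
      const double v = tpm_ref[idx];
      if (v > expressed_threshold) ++expr_r;
      if (v > 0) lr.push_back(std::log2(v));
    }
    med_diff[b] = (lt.empty() || lr.empty())
                      ? NA_REAL
                      : med_inplace(lt) - med_inplace(lr);
    // two divisions, matching mean(t > thr) - mean(r > thr) in R exactly
    prop_diff[b] = (double)expr_t / n_draw - (double)expr_r / n_draw;
  }
  return List::create(_["median_diff"] = med_diff,
                      _["prop_diff"] = prop_diff);
}
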