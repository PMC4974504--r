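#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Multi-tau correlator on binned photon counts.
//
// Level 0 correlates at lag offsets 1..m base bins; every further
// level halves the time resolution (adjacent-bin pairwise sum) and
// correlates at offsets m/2+1 .. m in coarsened bins, producing a
// quasi-logarithmic lag grid without overlap between levels.
// Normalization is the symmetric fluctuation form
//   G(k) = M * S_ab / (S_a * S_b) - 1
// with S_ab = sum_i a_i b_{i+k}, S_a = sum over the direct window,
// S_b over the delayed window, M the number of terms; G -> 0 for
// uncorrelated stationary signals.
//
// Returns lag in base-bin units, G, and the term count per lag.
// [[Rcpp::export]]
List multitau_cpp(IntegerVector a, IntegerVector b, int m, int n_levels) {
  if (a.size() != b.size()) stop("channel arrays differ in length");
  const bool same = (a.begin() == b.begin());
  std::vector<double> va(a.begin(), a.end());
  std::vector<double> vb;
  if (!same) vb.assign(b.begin(), b.end());
  std::vector<double>& ra = va;
  std::vector<double>& rb = same ? va : vb;

  std::vector<double> lags, G, nsamp;
  long n = (long)va.size();
  long scale = 1;

  for (int lev = 0; lev < n_levels; ++lev) {
    const int k_lo = (lev == 0) ? 1 : m / 2 + 1;
    if (n <= m + 1) break;
    for (int k = k_lo; k <= m; ++k) {
      const long M = n - k;
      double sab = 0.0, sa = 0.0, sb = 0.0;
      const double* pa = ra.data();
      const double* pb = rb.data() + k;
      for (long i = 0; i < M; ++i) {
        sab += pa[i] * pb[i];
        sa += pa[i];
        sb += pb[i];
      }
      double g = NA_REAL;
      if (sa > 0 && sb > 0)
        g = sab * (double)M / (sa * sb) - 1.0;
      lags.push_back((double)k * (double)scale);
      G.push_back(g);
      nsamp.push_back((double)M);
    }
    // coarsen by factor 2
    long nh = n / 2;
    for (long i = 0; i < nh; ++i) ra[i] = ra[2 * i] + ra[2 * i + 1];
    ra.resize(nh);
    if (!same) {
      for (long i = 0; i < nh; ++i) rb[i] = rb[2 * i] + rb[2 * i + 1];
      rb.resize(nh);
    }
    n = nh;
    scale *= 2;
  }

  return List::create(Named("lag_bins") = wrap(lags),
                      Named("G") = wrap(G),
                      Named("n_samples") = wrap(nsamp));
}

// Exact binned-intensity correlation at arbitrary integer lags
// (brute-force oracle for the multi-tau scheme).
// [[Rcpp::export]]
List direct_correlate_cpp(IntegerVector a, IntegerVector b,
                          IntegerVector lags_bins) {
  if (a.size() != b.size()) stop("channel arrays differ in length");
  const long n = a.size();
  const int nk = lags_bins.size();
  NumericVector G(nk), nsamp(nk);
  for (int j = 0; j < nk; ++j) {
    const long k = lags_bins[j];
    if (k < 1 || k >= n) { G[j] = NA_REAL; nsamp[j] = 0; continue; }
    const long M = n - k;
    double sab = 0.0, sa = 0.0, sb = 0.0;
    for (long i = 0; i < M; ++i) {
      sab += (double)a[i] * (double)b[i + k];
      sa += a[i];
      sb += b[i + k];
    }
    G[j] = (sa > 0 && sb > 0) ? sab * (double)M / (sa * sb) - 1.0
                              : NA_REAL;
    nsamp[j] = (double)M;
  }
  return List::create(Named("G") = G, Named("n_samples") = nsamp);
}
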