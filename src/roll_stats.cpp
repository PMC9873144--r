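#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window quantile at every sample. Window is centered, [i-h, i+h] in
// sample indices, shrinking at the edges. Quantile uses linear interpolation
// between order statistics (R type 7). Maintains a sorted window so the whole
// pass is O(n * w) with cheap memmoves, fast enough for waveform-rate input.
// [[Rcpp::export]]
NumericVector roll_quantile_cpp(NumericVector x, int halfwin, double p) {
  const int n = x.size();
  if (n == 0) return NumericVector(0);
  if (halfwin < 0) stop("halfwin must be >= 0");
  if (p < 0.0 || p > 1.0) stop("p must lie in [0,1]");
  NumericVector out(n);
  std::vector<double> win;
  win.reserve(2 * halfwin + 2);
  int lo = 0, hi = -1; // current window covers x[lo..hi]
  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - halfwin);
    int nhi = std::min(n - 1, i + halfwin);
    while (hi < nhi) {
      ++hi;
      double v = x[hi];
      win.insert(std::lower_bound(win.begin(), win.end(), v), v);
    }
    while (lo < nlo) {
      double v = x[lo];
      win.erase(std::lower_bound(win.begin(), win.end(), v));
      ++lo;
    }
    const int m = (int)win.size();
    double hidx = p * (m - 1);
    int j = (int)hidx;
    double frac = hidx - j;
    out[i] = (j + 1 < m) ? win[j] + frac * (win[j + 1] - win[j]) : win[j];
  }
  return out;
}

// Centered moving average with shrinking edge windows.
// [[Rcpp::export]]
NumericVector roll_mean_cpp(NumericVector x, int halfwin) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - halfwin);
    int hi = std::min(n - 1, i + halfwin);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}
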