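// Dip-type unimodality statistic: the smallest half-bandwidth d such that a
// distribution function that is convex left of some mode and concave right of
// it fits inside the Kolmogorov band of half-width d around the empirical
// CDF. Computed by bisection over d; each feasibility check builds greatest
// convex minorants of the upper band incrementally (monotone chain) and
// verifies the lower band, and symmetrically for the concave side.
// For equally spaced data the statistic equals the exact lower bound 1/(2n);
// for two equal point masses it equals 1/4.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// Given unique support points ux (increasing) with band [lo, hi] (both
// nondecreasing), return for each prefix [0..m] whether a convex,
// nondecreasing function fits inside the band; feasibility is monotone in m,
// so return the largest feasible m (or -1 if none).
int max_convex_prefix(const std::vector<double> &ux,
                      const std::vector<double> &lo,
                      const std::vector<double> &hi) {
  const int n = (int)ux.size();
  std::vector<int> hull;      // indices of hull vertices (on hi)
  hull.reserve(n);
  for (int m = 0; m < n; ++m) {
    // add point (ux[m], hi[m]) to the lower hull
    while (hull.size() >= 2) {
      int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
      double s1 = (hi[b] - hi[a]) / (ux[b] - ux[a]);
      double s2 = (hi[m] - hi[b]) / (ux[m] - ux[b]);
      if (s2 < s1 - 1e-15) hull.pop_back(); else break;
    }
    hull.push_back(m);
    // the hull changed only on the final segment (a .. m); verify lo there
    if (hull.size() >= 2) {
      int a = hull[hull.size() - 2];
      double s = (hi[m] - hi[a]) / (ux[m] - ux[a]);
      for (int i = a + 1; i < m; ++i) {
        double v = hi[a] + s * (ux[i] - ux[a]);
        if (v < lo[i] - 1e-12) return m - 1;
      }
    }
    if (hi[m] < lo[m] - 1e-12) return m - 1; // empty band at m itself
  }
  return n - 1;
}

bool feasible(const std::vector<double> &ux, const std::vector<double> &lo,
              const std::vector<double> &hi) {
  const int n = (int)ux.size();
  int mL = max_convex_prefix(ux, lo, hi);
  if (mL < 0) return false;
  // concave suffix via mirror transform: x -> -x reversed, band [1-hi, 1-lo]
  std::vector<double> rx(n), rlo(n), rhi(n);
  for (int i = 0; i < n; ++i) {
    rx[i] = -ux[n - 1 - i];
    rlo[i] = 1.0 - hi[n - 1 - i];
    rhi[i] = 1.0 - lo[n - 1 - i];
  }
  int mR = max_convex_prefix(rx, rlo, rhi);
  if (mR < 0) return false;
  int minR = n - 1 - mR; // smallest start index of a feasible concave suffix
  return mL >= minR;
}

} // namespace

// [[Rcpp::export]]
double cpp_dip_statistic(NumericVector xin) {
  std::vector<double> x(xin.begin(), xin.end());
  std::sort(x.begin(), x.end());
  const int n = (int)x.size();
  if (n < 2 || x.front() == x.back()) return 0.0;
  // collapse ties: at each unique x, lower band = max over dups of i/n - d,
  // upper band = min over dups of (i-1)/n + d. Store the extreme rank bounds.
  std::vector<double> ux, lo_rank, hi_rank; // in F units before +-d
  for (int i = 0; i < n;) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    ux.push_back(x[i]);
    lo_rank.push_back((double)j / n);       // max i/n over the tie block
    hi_rank.push_back((double)i / n);       // min (i-1)/n is i/n with 0-based
    i = j;
  }
  const int m = (int)ux.size();
  double dlo = 0.5 / n, dhi = 0.25;
  std::vector<double> lo(m), hi(m);
  auto check = [&](double d) {
    for (int i = 0; i < m; ++i) {
      lo[i] = std::max(0.0, lo_rank[i] - d);
      hi[i] = std::min(1.0, hi_rank[i] + d);
    }
    return feasible(ux, lo, hi);
  };
  if (check(dlo)) return dlo;
  for (int it = 0; it < 40 && dhi - dlo > 1e-10; ++it) {
    double mid = 0.5 * (dlo + dhi);
    if (check(mid)) dhi = mid; else dlo = mid;
  }
  return dhi;
}
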