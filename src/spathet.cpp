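#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Fixed-radius neighbor pairs via grid bucketing. Returns 1-based index
// pairs (i < j) with Euclidean distance <= r (closed ball). Equivalent to
// the all-pairs definition but O(n * local density) for typical tissues.
// [[Rcpp::export]]
List cpp_radius_edges(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  const double r2 = r * r;
  std::unordered_map<long long, std::vector<int> > buckets;
  buckets.reserve(n * 2);
  std::vector<long long> bx(n), by(n);
  for (int i = 0; i < n; ++i) {
    bx[i] = (long long)std::floor(x[i] / r);
    by[i] = (long long)std::floor(y[i] / r);
    buckets[bx[i] * 2000003LL + by[i]].push_back(i);
  }
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = buckets.find((bx[i] + dx) * 2000003LL + (by[i] + dy));
        if (it == buckets.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) { ei.push_back(i + 1); ej.push_back(j + 1); }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej));
}

// Two-group logrank chi-square statistic (1 df). group is 0/1, status is
// 0 = censored / 1 = event. Returns 0 when the variance degenerates.
// [[Rcpp::export]]
double cpp_logrank_chisq(NumericVector time, IntegerVector status, IntegerVector group) {
  const int n = time.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return time[a] < time[b]; });
  double O = 0.0, E = 0.0, V = 0.0;
  int atrisk = n;
  int atrisk1 = 0;
  for (int i = 0; i < n; ++i) if (group[i] == 1) ++atrisk1;
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0, d1 = 0, removed = 0, removed1 = 0;
    const double t = time[ord[i]];
    while (j < n && time[ord[j]] == t) {
      const int idx = ord[j];
      if (status[idx] == 1) { ++d; if (group[idx] == 1) ++d1; }
      ++removed;
      if (group[idx] == 1) ++removed1;
      ++j;
    }
    if (d > 0 && atrisk > 0) {
      const double n1 = (double)atrisk1, nn = (double)atrisk;
      O += d1;
      E += d * n1 / nn;
      if (atrisk > 1)
        V += (double)d * (n1 / nn) * (1.0 - n1 / nn) * ((double)(atrisk - d) / (double)(atrisk - 1));
    }
    atrisk -= removed;
    atrisk1 -= removed1;
    i = j;
  }
  if (V <= 0.0) return 0.0;
  const double diff = O - E;
  return diff * diff / V;
}
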