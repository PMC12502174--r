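#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Two-sample KS statistic over a pooled sorted sample. `grp1` marks group-1
// membership aligned to the sorted order; ties are handled by evaluating
// |F1 - F2| only where the pooled value changes.
static double ks_from_sorted(const std::vector<double>& v,
                             const std::vector<int>& grp1,
                             int n1, int n2) {
  int n = n1 + n2;
  double d = 0.0;
  int c1 = 0, c2 = 0;
  for (int i = 0; i < n; ++i) {
    if (grp1[i]) ++c1; else ++c2;
    if (i == n - 1 || v[i + 1] != v[i]) {
      double diff = std::fabs((double)c1 / n1 - (double)c2 / n2);
      if (diff > d) d = diff;
    }
  }
  return d;
}

// xorshift64* — small self-contained generator so the permutation stream is
// fully determined by the seed passed from R.
static inline uint64_t next_u64(uint64_t& s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double next_unif(uint64_t& s) {
  return (next_u64(s) >> 11) * (1.0 / 9007199254740992.0);  // [0, 1)
}

// [[Rcpp::export(name = ".perm_ks_cpp", rng = false)]]
List perm_ks_cpp(NumericVector x, NumericVector y, int n_perm, int seed) {
  int n1 = x.size(), n2 = y.size(), n = n1 + n2;
  std::vector<std::pair<double, int> > pool(n);
  for (int i = 0; i < n1; ++i) pool[i] = std::make_pair(x[i], 1);
  for (int i = 0; i < n2; ++i) pool[n1 + i] = std::make_pair(y[i], 0);
  std::sort(pool.begin(), pool.end());
  std::vector<double> v(n);
  std::vector<int> grp(n);
  for (int i = 0; i < n; ++i) { v[i] = pool[i].first; grp[i] = pool[i].second; }
  double obs = ks_from_sorted(v, grp, n1, n2);

  uint64_t state = (uint64_t)(uint32_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  for (int k = 0; k < 8; ++k) next_u64(state);

  // permute the group labels over the sorted positions (values are fixed)
  std::vector<int> perm(grp);
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {       // Fisher-Yates
      int j = (int)(next_unif(state) * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double d = ks_from_sorted(v, perm, n1, n2);
    if (d >= obs - 1e-12) ++count;
  }
  double p = (1.0 + count) / (1.0 + n_perm);
  return List::create(Named("statistic") = obs, Named("p_value") = p);
}
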