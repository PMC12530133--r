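#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Characteristic-value search for the maximal information coefficient.
//
// For a fixed q-bin equal-frequency partition of the v-axis, the best
// u-axis partition into l bins (for every l = 2..L simultaneously) is found
// by dynamic programming over m equal-frequency micro-bins of u, maximizing
// sum_parts [ sum_q p_pq log p_pq - p_p log p_p ]  (H(Q) is a constant).
// Entropies use natural logs internally; the ratio I / log(min(l, q)) is
// base-free.
//
// ord_u: 0-based order of the u variable; vbin: 0-based v-bin per data index.

static double part_val(const std::vector<std::vector<int> >& pref,
                       int q, int n, int j, int i) {
  // value of a part covering micro-bins (j, i]
  double val = 0.0;
  int tot = 0;
  for (int b = 0; b < q; ++b) {
    int c = pref[b][i] - pref[b][j];
    tot += c;
    if (c > 0) { double p = (double) c / n; val += p * std::log(p); }
  }
  if (tot > 0) { double p = (double) tot / n; val -= p * std::log(p); }
  return val;
}

// [[Rcpp::export(name = ".mic_axis_dp")]]
NumericVector mic_axis_dp(IntegerVector ord_u, IntegerVector vbin,
                          int q, int L, int clump_factor) {
  int n = ord_u.size();
  int m = std::min(n, clump_factor * L);   // micro-bins (superclumps)
  if (m < L) m = L;

  // assign micro-bin to each u-rank position (equal frequency)
  // prefix counts pref[b][i] = #points in v-bin b among first i micro-bins
  std::vector<std::vector<int> > pref(q, std::vector<int>(m + 1, 0));
  for (int pos = 0; pos < n; ++pos) {
    int mb = (int) ((long long) pos * m / n);   // 0..m-1
    int b = vbin[ord_u[pos]];
    pref[b][mb + 1] += 1;
  }
  for (int b = 0; b < q; ++b)
    for (int i = 1; i <= m; ++i) pref[b][i] += pref[b][i - 1];

  // DP: F[l][i] best value of first i micro-bins split into l parts
  std::vector<std::vector<double> > F(L + 1,
      std::vector<double>(m + 1, -std::numeric_limits<double>::infinity()));
  for (int i = 1; i <= m; ++i) F[1][i] = part_val(pref, q, n, 0, i);
  for (int l = 2; l <= L; ++l) {
    for (int i = l; i <= m; ++i) {
      double best = -std::numeric_limits<double>::infinity();
      for (int j = l - 1; j < i; ++j) {
        double cand = F[l - 1][j] + part_val(pref, q, n, j, i);
        if (cand > best) best = cand;
      }
      F[l][i] = best;
    }
  }

  // H(Q) for the fixed axis
  double hq = 0.0;
  for (int b = 0; b < q; ++b) {
    int c = pref[b][m];
    if (c > 0) { double p = (double) c / n; hq -= p * std::log(p); }
  }

  NumericVector out(L + 1, NA_REAL);   // out[l] = I for l u-bins (nats)
  for (int l = 2; l <= L; ++l) {
    double I = F[l][m] + hq;
    if (I < 0) I = 0;
    out[l] = I;
  }
  return out;
}
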