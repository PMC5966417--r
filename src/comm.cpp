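// All-pairs communication round.
//
// For every unordered agent pair, intersect the two plasticity intervals,
// count the languages inside (binary search over sorted positions) and,
// when at least one is shared, draw one uniformly. One unif_rand() call per
// successful pair, in lexicographic pair order, so trajectories match the
// plain-R reference implementation draw for draw.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// [[Rcpp::export]]
List comm_round_cpp(NumericVector a, NumericVector p,
                    NumericVector ls_sorted, IntegerVector ord) {
  const int n = a.size();
  const double* ls = ls_sorted.begin();
  const double* ls_end = ls_sorted.end();
  const int L = ls_sorted.size();

  // per-agent bounds: bs = first language >= lo, es = first > hi; the
  // intersection of two intervals has bounds max(bs) .. min(es), so the
  // pair loop needs no further searching
  std::vector<int> bs(n), es(n);
  IntegerVector usable(n);
  for (int i = 0; i < n; ++i) {
    double lo = a[i] - p[i], hi = a[i] + p[i];
    bs[i] = std::lower_bound(ls, ls_end, lo) - ls;
    es[i] = std::upper_bound(ls, ls_end, hi) - ls;
    usable[i] = es[i] - bs[i];
  }

  std::vector<int> pi, pj, pl;
  std::vector<double> benefit(n, 0.0);
  // first-touch registry of (language, agent) usage pairs -> SA_x
  std::vector<uint8_t> seen((size_t)L * n, 0);
  std::vector<int64_t> user_keys;
  if (L > 0) {
    const int64_t N64 = n;
    pi.reserve((size_t)n * 16); pj.reserve((size_t)n * 16);
    pl.reserve((size_t)n * 16);
    for (int i = 0; i < n - 1; ++i) {
      const int bi = bs[i], ei = es[i];
      for (int j = i + 1; j < n; ++j) {
        int b = bi > bs[j] ? bi : bs[j];
        int e = ei < es[j] ? ei : es[j];
        int c = e - b;
        if (c <= 0) continue;
        int k = b + (int)(unif_rand() * c);
        if (k >= e) k = e - 1;  // guard the unif_rand() ~ 1 edge
        int lang = ord[k];      // 1-based original index
        pi.push_back(i + 1);
        pj.push_back(j + 1);
        pl.push_back(lang);
        benefit[i] += ls[k];
        benefit[j] += ls[k];
        int64_t lk = (int64_t)(lang - 1) * N64;
        if (!seen[lk + i]) { seen[lk + i] = 1; user_keys.push_back(lk + i); }
        if (!seen[lk + j]) { seen[lk + j] = 1; user_keys.push_back(lk + j); }
      }
    }
  }

  // sorted for a deterministic, implementation-independent ordering
  std::sort(user_keys.begin(), user_keys.end());
  const int nu = user_keys.size();
  IntegerVector u_lang(nu), u_agent(nu);
  for (int k = 0; k < nu; ++k) {
    u_lang[k] = (int)(user_keys[k] / n) + 1;
    u_agent[k] = (int)(user_keys[k] % n) + 1;
  }

  return List::create(
    _["pair_i"] = IntegerVector(pi.begin(), pi.end()),
    _["pair_j"] = IntegerVector(pj.begin(), pj.end()),
    _["pair_lang"] = IntegerVector(pl.begin(), pl.end()),
    _["usable_counts"] = usable,
    _["users_lang"] = u_lang,
    _["users_agent"] = u_agent,
    _["benefit"] = NumericVector(benefit.begin(), benefit.end()));
}
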