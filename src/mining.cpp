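#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Maximal irreducible intervals of a coverage vector at threshold mu.
//
// With S the prefix-sum sequence of (v - mu) (S[0] = 0), a half-open
// interval [i, j) is irreducible iff S[i] = min(S[i..j]) and
// S[j] = max(S[i..j]): the first condition says every prefix of the
// interval has mean >= mu, the second the same for every suffix.
// Irreducibility depends only on the interval's own values.
//
// Greedy scan: a position i with v[i] >= mu can open a region (the
// singleton [i, i+1) is already irreducible).  Admissible ends j must
// lie before the first k > i with S[k] < S[i]; among those, the last
// position attaining the running maximum of S is the maximal extent.
// Two overlapping (or abutting) irreducible intervals merge into a
// larger irreducible interval, so maximal regions are pairwise disjoint
// and the greedy left-to-right emission is exhaustive.
//
// strict = true uses strict comparisons (> mu) throughout; eps absorbs
// floating-point noise in either mode.
// [[Rcpp::export(name = ".mine_maximal")]]
NumericMatrix mine_maximal(NumericVector v, double mu, double eps, bool strict) {
  int n = v.size();
  std::vector<double> S(n + 1);
  S[0] = 0.0;
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + (v[i] - mu);

  std::vector<double> st, en, mv;
  int a = 0;
  while (a < n) {
    bool can_open = strict ? (v[a] > mu + eps) : (v[a] >= mu - eps);
    if (!can_open) { ++a; continue; }
    double base = S[a];
    // m = first index k > a where the prefix condition fails
    int m = n + 1;
    for (int k = a + 1; k <= n; ++k) {
      bool below = strict ? (S[k] <= base + eps) : (S[k] < base - eps);
      if (below) { m = k; break; }
    }
    // maximal end = last admissible argmax of S on (a, m-1]
    int bstar = a + 1;
    double best = S[a + 1];
    for (int k = a + 2; k <= m - 1; ++k) {
      if (strict) {
        if (S[k] > best + eps) { best = S[k]; bstar = k; }
      } else {
        if (S[k] >= best - eps) {
          if (S[k] > best) best = S[k];
          bstar = k;
        }
      }
    }
    st.push_back((double) a);
    en.push_back((double) bstar);
    mv.push_back((S[bstar] - S[a]) / (bstar - a) + mu);
    a = bstar;
  }

  int nr = (int) st.size();
  NumericMatrix out(nr, 3);
  for (int r = 0; r < nr; ++r) {
    out(r, 0) = st[r];
    out(r, 1) = en[r];
    out(r, 2) = mv[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "mean");
  return out;
}
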