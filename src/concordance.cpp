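#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick tree (binary indexed tree) over score ranks.
struct Fenwick {
  std::vector<long long> t; // 1-indexed internal storage
  int n;
  explicit Fenwick(int n_) : t(n_ + 1, 0), n(n_) {}
  void add(int i) { // i is a 0-based rank
    for (++i; i <= n; i += i & -i) t[i]++;
  }
  long long prefix(int i) const { // count of inserted 0-based ranks <= i
    long long s = 0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

// Pair counts for Harrell's C. A pair is usable iff its two follow-up times
// differ and the smaller time carries an event; it is concordant when the
// earlier death has the higher risk score, tied when the scores are equal.
// Sweeps times in decreasing order with a Fenwick tree over score ranks, so
// the cost is O(n log n) rather than O(n^2).
// [[Rcpp::export]]
NumericVector concordance_pair_counts(NumericVector time, IntegerVector event,
                                      NumericVector score) {
  const int n = time.size();
  if (event.size() != n || score.size() != n)
    stop("time, event and score must have equal length");

  std::vector<double> uniq(score.begin(), score.end());
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  const int m = (int)uniq.size();
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i)
    rank[i] = (int)(std::lower_bound(uniq.begin(), uniq.end(), score[i]) -
                    uniq.begin());

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return time[a] > time[b]; });

  Fenwick bit(m);
  long long conc = 0, disc = 0, tied = 0, inserted = 0;
  int i = 0;
  while (i < n) {
    int j = i; // group of tied times, processed together
    while (j < n && time[idx[j]] == time[idx[i]]) ++j;
    for (int k = i; k < j; ++k) {
      int s = idx[k];
      if (event[s] == 1) {
        // all inserted subjects have strictly larger time
        long long le = bit.prefix(rank[s]);
        long long lt = rank[s] > 0 ? bit.prefix(rank[s] - 1) : 0;
        long long eq = le - lt;
        conc += lt;          // longer survivor has lower risk score
        tied += eq;
        disc += inserted - le;
      }
    }
    for (int k = i; k < j; ++k) {
      bit.add(rank[idx[k]]);
      ++inserted;
    }
    i = j;
  }
  return NumericVector::create(
      _["concordant"] = (double)conc, _["discordant"] = (double)disc,
      _["tied"] = (double)tied, _["usable"] = (double)(conc + disc + tied));
}
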