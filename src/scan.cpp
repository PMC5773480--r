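#include <Rcpp.h>
#include <functional>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Quadruplex run-chaining matcher. Convention: leftmost start, greedy runs
// (longest first, so a run of >= 2*min_run+1 may split into two quartet
// runs joined by an all-G loop), lazy loops (shortest first), candidates
// containing N rejected, matches non-overlapping (resume at match end).
// rs/re: 0-based starts / half-open ends of the maximal runs of the run
// character. Failed (position, depth) states are memoised: failure is
// path-independent.
// [[Rcpp::export]]
List scan_chain_cpp(std::string s, IntegerVector rs, IntegerVector re,
                    int min_run, int loop_min, int loop_max) {
  const int n = rs.size();
  std::vector<int> starts, ends;
  std::unordered_set<long long> failed;

  std::function<int(int, int, int)> try_run =
      [&](int pos, int mi, int depth) -> int {
    if (depth == 4) return re[mi];
    const long long key = ((long long)pos << 2) | depth;
    if (failed.count(key)) return -1;
    for (int a = re[mi] - pos; a >= min_run; --a) {   // greedy run
      const int x = pos + a;
      for (int loop = loop_min; loop <= loop_max; ++loop) {  // lazy loop
        const int q = x + loop;
        int lo = std::upper_bound(rs.begin(), rs.end(), q) - rs.begin() - 1;
        if (lo < 0) continue;
        if (q >= re[lo] || re[lo] - q < min_run) continue;
        bool okN = true;
        for (int t = x; t < q; ++t)
          if (s[t] == 'N') { okN = false; break; }
        if (!okN) continue;
        const int hit = try_run(q, lo, depth + 1);
        if (hit >= 0) return hit;
      }
    }
    failed.insert(key);
    return -1;
  };

  int resume = 0, i = 0;
  while (i < n) {
    if (rs[i] < resume) { ++i; continue; }
    const int hit = try_run(rs[i], i, 1);
    if (hit >= 0) {
      starts.push_back(rs[i]);
      ends.push_back(hit);
      resume = hit;
      while (i < n && rs[i] < resume) ++i;
    } else {
      ++i;
    }
  }
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends));
}
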