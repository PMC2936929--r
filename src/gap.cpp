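#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Exhaustive scan of a fragment layout (unit parts) for right-hand sides
// that are per-color achievable and jointly integrally infeasible with
// K = 3. Enumerates every consistent rhs (rows summing to the fragment
// length), prunes colors whose count vector no single 0/1 assignment can
// achieve, and tests joint feasibility by exhaustive 3^n search with early
// exit. Returns the integrally infeasible candidates; the caller decides
// which of them the LP relaxation deems feasible (those witness an
// infinite integrality gap).
// [[Rcpp::export(name = ".gap_scan_cpp")]]
IntegerMatrix gap_scan_cpp(int n, IntegerVector fi, IntegerVector fj,
                           int max_candidates) {
  int Fn = fi.size();
  if (n > 20 || Fn > 12) stop("layout too large for exhaustive scan");
  // achievable per-color count vectors over all 2^n binary assignments,
  // packed 5 bits per fragment
  std::unordered_set<uint64_t> achievable;
  std::vector<int> len(Fn);
  for (int f = 0; f < Fn; ++f) len[f] = fj[f] - fi[f] + 1;
  for (uint32_t mask = 0; mask < (1u << n); ++mask) {
    uint64_t key = 0;
    for (int f = 0; f < Fn; ++f) {
      int c = 0;
      for (int l = fi[f] - 1; l <= fj[f] - 1; ++l) c += (mask >> l) & 1u;
      key |= ((uint64_t) c) << (5 * f);
    }
    achievable.insert(key);
  }
  // odometer over consistent rhs: per fragment (a, b) with c = len - a - b
  std::vector<int> a(Fn, 0), b(Fn, 0);
  std::vector<std::vector<int> > cand;
  std::vector<int> col(n);
  for (;;) {
    uint64_t k1 = 0, k2 = 0, k3 = 0;
    bool ok = true;
    for (int f = 0; f < Fn && ok; ++f) {
      int c = len[f] - a[f] - b[f];
      k1 |= ((uint64_t) a[f]) << (5 * f);
      k2 |= ((uint64_t) b[f]) << (5 * f);
      k3 |= ((uint64_t) c) << (5 * f);
    }
    if (achievable.count(k1) && achievable.count(k2) && achievable.count(k3)) {
      // joint feasibility by exhaustive 3-coloring with early exit
      std::fill(col.begin(), col.end(), 0);
      bool feas = false;
      for (;;) {
        bool good = true;
        for (int f = 0; f < Fn && good; ++f) {
          int ca = 0, cb = 0;
          for (int l = fi[f] - 1; l <= fj[f] - 1; ++l) {
            ca += col[l] == 0; cb += col[l] == 1;
          }
          good = (ca == a[f]) && (cb == b[f]);
        }
        if (good) { feas = true; break; }
        int i = n - 1;
        while (i >= 0 && col[i] == 2) col[i--] = 0;
        if (i < 0) break;
        ++col[i];
      }
      if (!feas) {
        std::vector<int> row(2 * Fn);
        for (int f = 0; f < Fn; ++f) { row[f] = a[f]; row[Fn + f] = b[f]; }
        cand.push_back(row);
        if ((int) cand.size() >= max_candidates) break;
      }
    }
    // advance odometer (b fastest, then a)
    int f = 0;
    for (;;) {
      if (f >= Fn) break;
      if (b[f] < len[f] - a[f]) { ++b[f]; break; }
      b[f] = 0;
      if (a[f] < len[f]) { ++a[f]; break; }
      a[f] = 0; ++f;
    }
    if (f >= Fn) break;
  }
  IntegerMatrix out(cand.size(), 2 * Fn);
  for (size_t r = 0; r < cand.size(); ++r)
    for (int c = 0; c < 2 * Fn; ++c) out(r, c) = cand[r][c];
  return out;
}
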