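#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive minimum-error search over all K^n colorings of the covered
// residues. Fragments are given as inclusive ranges in covered-position
// coordinates (every residue of a fragment is covered by definition, so the
// ranges stay contiguous). Used as the independent oracle for every solver:
// it never touches parts, LPs, flows or multipliers.
// [[Rcpp::export(name = ".bf_enumerate_cpp")]]
List bf_enumerate_cpp(int ncov, int K, IntegerVector fi, IntegerVector fj,
                      IntegerMatrix b, bool keep_all) {
  int Fn = fi.size();
  if (ncov == 0)
    return List::create(_["optimum"] = 0,
                        _["solutions"] = IntegerMatrix(keep_all ? 1 : 0, 0));
  std::vector<int> col(ncov, 1);
  std::vector<std::vector<int> > best_cols;
  long long best = -1;
  R_xlen_t n_total = 1;
  for (int i = 0; i < ncov; ++i) {
    n_total *= K;
    if (n_total > 100000000LL) stop("exhaustive search limited to K^n <= 1e8");
  }
  std::vector<int> cnt(K);
  for (;;) {
    long long err = 0;
    for (int f = 0; f < Fn && (best < 0 || err <= best || keep_all); ++f) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int l = fi[f] - 1; l <= fj[f] - 1; ++l) ++cnt[col[l] - 1];
      for (int k = 0; k < K; ++k) {
        long long d = (long long) b(f, k) - cnt[k];
        err += d < 0 ? -d : d;
      }
    }
    if (best < 0 || err < best) {
      best = err;
      if (keep_all) { best_cols.clear(); best_cols.push_back(col); }
    } else if (keep_all && err == best) {
      best_cols.push_back(col);
    }
    int i = ncov - 1;
    while (i >= 0 && col[i] == K) { col[i] = 1; --i; }
    if (i < 0) break;
    ++col[i];
  }
  IntegerMatrix sols(keep_all ? (int) best_cols.size() : 0, ncov);
  for (int r = 0; r < (int) best_cols.size(); ++r)
    for (int c = 0; c < ncov; ++c) sols(r, c) = best_cols[r][c];
  return List::create(_["optimum"] = (double) best, _["solutions"] = sols);
}
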