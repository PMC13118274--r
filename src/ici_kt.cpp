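#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Mergesort on y (already ordered by x, ties in x broken by y) counting
// strict inversions y[i] > y[j] for i < j.  Counts returned as double:
// exact for any n with n(n-1)/2 < 2^53.
static double merge_count(std::vector<double>& y, std::vector<double>& buf,
                          R_xlen_t lo, R_xlen_t hi) {
  if (hi - lo < 2) return 0.0;
  R_xlen_t mid = lo + (hi - lo) / 2;
  double cnt = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  R_xlen_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {          // strict: ties are not inversions
      cnt += (double)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi)  buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return cnt;
}

// Pair census for Kendall tau-b by sort + mergesort exchange counting.
// x, y must be free of NA (missing already replaced by a sentinel).
// Returns the counts needed for tau-b, tau-max and the tie-corrected
// Mann-Kendall variance:
//   n_tot = n(n-1)/2; con / dis = concordant / discordant pairs;
//   ntie  = pairs tied in both x and y;
//   x_ties / y_ties = tied-group sizes (>= 2) in x and in y.
// [[Rcpp::export(name = ".kendallPairCensus")]]
List kendall_pair_census(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  if (n < 2) stop("need at least two observations");

  std::vector<R_xlen_t> perm(n);
  for (R_xlen_t i = 0; i < n; ++i) perm[i] = i;
  std::sort(perm.begin(), perm.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  // tie runs in x, and joint (x, y) tie runs
  std::vector<double> x_ties, y_ties;
  double xtie = 0, ntie = 0;
  R_xlen_t run = 1, jrun = 1;
  for (R_xlen_t i = 1; i <= n; ++i) {
    bool xeq = (i < n) && x[perm[i]] == x[perm[i - 1]];
    bool jeq = xeq && y[perm[i]] == y[perm[i - 1]];
    if (jeq) { ++jrun; } else { ntie += 0.5 * jrun * (jrun - 1); jrun = 1; }
    if (xeq) { ++run; }
    else {
      if (run > 1) {
        x_ties.push_back((double)run);
        xtie += 0.5 * (double)run * ((double)run - 1);
      }
      run = 1;
    }
  }

  std::vector<double> ys(n), buf(n);
  for (R_xlen_t i = 0; i < n; ++i) ys[i] = y[perm[i]];
  double dis = merge_count(ys, buf, 0, n);

  // mergesort left ys sorted: tie runs in y
  double ytie = 0;
  run = 1;
  for (R_xlen_t i = 1; i <= n; ++i) {
    if (i < n && ys[i] == ys[i - 1]) { ++run; }
    else {
      if (run > 1) {
        y_ties.push_back((double)run);
        ytie += 0.5 * (double)run * ((double)run - 1);
      }
      run = 1;
    }
  }

  double n_tot = 0.5 * (double)n * ((double)n - 1);
  double con = n_tot - xtie - ytie + ntie - dis;

  return List::create(
    _["n"] = (double)n, _["n_tot"] = n_tot,
    _["con"] = con, _["dis"] = dis,
    _["ntie"] = ntie,
    _["x_ties"] = wrap(x_ties), _["y_ties"] = wrap(y_ties));
}
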