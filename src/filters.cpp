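#include <Rcpp.h>
using namespace Rcpp;

// Centred moving median of a 0/1 vector. For odd k the window median is 1
// iff the window sum reaches (k+1)/2. The first and last k/2 positions
// cannot centre a window and keep their original values.
// [[Rcpp::export]]
IntegerVector cpp_moving_median_binary(const IntegerVector& v, int k) {
  int n = v.size();
  int half = k / 2;
  int need = (k + 1) / 2;
  IntegerVector out(n);
  if (n == 0) return out;
  if (n <= 2 * half) {  // no interior: everything is boundary
    for (int i = 0; i < n; ++i) out[i] = v[i];
    return out;
  }
  for (int i = 0; i < half; ++i) {
    out[i] = v[i];
    out[n - 1 - i] = v[n - 1 - i];
  }
  int wsum = 0;
  for (int i = 0; i < k; ++i) wsum += v[i];
  out[half] = wsum >= need ? 1 : 0;
  for (int c = half + 1; c < n - half; ++c) {
    wsum += v[c + half] - v[c - half - 1];
    out[c] = wsum >= need ? 1 : 0;
  }
  return out;
}

// Zero out maximal runs of ones shorter than min_run slots.
// [[Rcpp::export]]
IntegerVector cpp_duration_filter(const IntegerVector& m, int min_run) {
  int n = m.size();
  IntegerVector out = clone(m);
  int i = 0;
  while (i < n) {
    if (out[i] == 1) {
      int j = i;
      while (j < n && out[j] == 1) ++j;
      if (j - i < min_run)
        for (int t = i; t < j; ++t) out[t] = 0;
      i = j;
    } else {
      ++i;
    }
  }
  return out;
}

// Per-pair co-location counts for one day of traces.
// codes: n_res x n_slots integer matrix of place codes, NA = position unknown.
// Returns, for each unordered pair (i < j), the raw co-location count, the
// count after moving-median (k) + minimum-duration (min_run) filtering, and
// the raw count restricted to each [starts[w], ends[w]] window (1-based,
// inclusive).
// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(const IntegerMatrix& codes, int k, int min_run,
                              const IntegerVector& starts,
                              const IntegerVector& ends) {
  int n = codes.nrow();
  int T = codes.ncol();
  int nw = starts.size();
  int npairs = n * (n - 1) / 2;
  NumericMatrix out(npairs, 2 + nw);
  IntegerVector v(T);
  int row = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++row) {
      int raw = 0;
      for (int t = 0; t < T; ++t) {
        int ci = codes(i, t), cj = codes(j, t);
        int eq = (ci != NA_INTEGER && cj != NA_INTEGER && ci == cj) ? 1 : 0;
        v[t] = eq;
        raw += eq;
      }
      out(row, 0) = raw;
      if (raw == 0) {
        out(row, 1) = 0;
      } else {
        IntegerVector f = cpp_duration_filter(cpp_moving_median_binary(v, k), min_run);
        int filt = 0;
        for (int t = 0; t < T; ++t) filt += f[t];
        out(row, 1) = filt;
      }
      for (int w = 0; w < nw; ++w) {
        int cnt = 0;
        int lo = starts[w] - 1, hi = ends[w] - 1;
        for (int t = lo; t <= hi; ++t) cnt += v[t];
        out(row, 2 + w) = cnt;
      }
    }
  }
  return out;
}
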