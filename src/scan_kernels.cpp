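#include <Rcpp.h>
using namespace Rcpp;

// Log-odds score of every window row in W (values 1..4 = A,C,G,T; 0 = N)
// against an L x 4 log-odds matrix. Windows touching an N score -Inf.
// [[Rcpp::export]]
NumericVector cpp_score_windows(const IntegerMatrix& W, const NumericMatrix& lo) {
  const int n = W.nrow(), L = W.ncol();
  if (lo.nrow() != L || lo.ncol() != 4)
    stop("log-odds matrix must be L x 4");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    bool bad = false;
    for (int j = 0; j < L; ++j) {
      const int b = W(i, j);
      if (b == 0) { bad = true; break; }
      s += lo(j, b - 1);
    }
    out[i] = bad ? R_NegInf : s;
  }
  return out;
}

// Number of window rows within maxmis mismatches of a seed word.
// [[Rcpp::export]]
int cpp_mismatch_count(const IntegerMatrix& W, const IntegerVector& seed,
                       int maxmis) {
  const int n = W.nrow(), L = W.ncol();
  if (seed.size() != L) stop("seed length must equal window length");
  int total = 0;
  for (int i = 0; i < n; ++i) {
    int mis = 0;
    for (int j = 0; j < L; ++j) {
      if (W(i, j) != seed[j]) {
        if (++mis > maxmis) break;
      }
    }
    if (mis <= maxmis) ++total;
  }
  return total;
}

// Column-wise base counts (4 x L) of a subset of window rows (1-based idx).
// [[Rcpp::export]]
IntegerMatrix cpp_column_counts(const IntegerMatrix& W, const IntegerVector& idx) {
  const int L = W.ncol(), m = idx.size();
  IntegerMatrix cnt(4, L);
  for (int k = 0; k < m; ++k) {
    const int i = idx[k] - 1;
    for (int j = 0; j < L; ++j) {
      const int b = W(i, j);
      if (b >= 1 && b <= 4) cnt(b - 1, j) += 1;
    }
  }
  return cnt;
}
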