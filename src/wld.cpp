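#include <Rcpp.h>
using namespace Rcpp;

// Weighted Levenshtein distance between integer-coded sequences.
// Codes are 1-based row/column indices into the substitution cost matrix;
// insertions and deletions cost 1, substitution of u by v costs cost(u, v).
static double wld_one(const IntegerVector& a, const IntegerVector& b,
                      const NumericMatrix& cost) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double sub = prev[j - 1] + cost(ai, b[j - 1] - 1);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double wld_cpp(IntegerVector a, IntegerVector b, NumericMatrix cost) {
  return wld_one(a, b, cost);
}

// Full symmetric matrix of weighted Levenshtein distances; each unordered
// pair is computed exactly once.
// [[Rcpp::export]]
NumericMatrix pairwise_wld_cpp(List seqs, NumericMatrix cost) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = wld_one(ss[i], ss[j], cost);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
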