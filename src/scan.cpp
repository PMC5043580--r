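#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood-ratio scores for every window of a coded sequence.
// codes: 0=A,1=C,2=G,3=T,4=other (voids the window).
// ll: width x 4 matrix of log2(p/bg) terms.
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector codes, NumericMatrix ll) {
  const int n = codes.size(), w = ll.nrow();
  if (n < w) return NumericVector(0);
  const int nw = n - w + 1;
  NumericVector out(nw);
  for (int i = 0; i < nw; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int k = 0; k < w; ++k) {
      const int b = codes[i + k];
      if (b > 3) { ok = false; break; }
      s += ll(k, b);
    }
    out[i] = ok ? s : R_NegInf;
  }
  return out;
}

// Count windows scoring >= threshold on both strands. llm is the
// minus-strand matrix (reverse-complemented PWM over complemented background).
// [[Rcpp::export]]
int cpp_count_hits(IntegerVector codes, NumericMatrix ll, NumericMatrix llm,
                   double threshold) {
  const int n = codes.size(), w = ll.nrow();
  if (n < w) return 0;
  const int nw = n - w + 1;
  int count = 0;
  for (int i = 0; i < nw; ++i) {
    double sf = 0.0, sr = 0.0;
    bool ok = true;
    for (int k = 0; k < w; ++k) {
      const int b = codes[i + k];
      if (b > 3) { ok = false; break; }
      sf += ll(k, b);
      sr += llm(k, b);
    }
    if (!ok) continue;
    if (sf >= threshold) ++count;
    if (sr >= threshold) ++count;
  }
  return count;
}
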