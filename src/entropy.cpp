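#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Sample entropy match counts (Richman & Moorman convention).
// Templates of length m and m+1 taken with lag `delay`; both counts use the
// same N - m*delay template set so A/B is a conditional probability.
// Chebyshev distance, self-matches excluded. Returns c(B, A).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r, int delay) {
  int n = x.size();
  int nt = n - m * delay;  // templates whose (m+1)-th element still exists
  if (nt < 2) return NumericVector::create(0.0, 0.0);
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double diff = std::abs(x[i + k * delay] - x[j + k * delay]);
        if (diff > d) d = diff;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double diff = std::abs(x[i + m * delay] - x[j + m * delay]);
      if (diff > d) d = diff;
      if (d <= r) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}

// LZ76 exhaustive parsing of a 0/1 integer vector.
// Classic reproducibility scan (Kaspar-Schuster loop), but the trailing
// phrase is only counted when it ends in an innovation, so a constant
// sequence parses to a single phrase.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1;        // first symbol is always an innovation
  int i = 0;        // start of prefix available for copying
  int k = 1;        // current extension length
  int l = 1;        // start of current phrase
  int k_max = 1;
  bool pending = false;  // an uncounted (reproducible so far) phrase exists
  while (l + k <= n) {
    pending = true;
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {          // innovation: no prefix source reproduces phrase
        ++c;
        l += k_max;
        i = 0;
        k = 1;
        k_max = 1;
        pending = false;
      } else {
        k = 1;
      }
    }
  }
  // trailing characters that stayed reproducible are not a new phrase
  (void)pending;
  return c;
}
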