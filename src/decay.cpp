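#include <Rcpp.h>
using namespace Rcpp;

// Geometric (leaky) accumulation S(t) = a * S(t-1) + x(t), S(0) = 0.
// Equals the explicit weighted sum sum_j a^(t-j) x(j); kept in C++ because
// it sits inside every mood-model likelihood evaluation.
// [[Rcpp::export(name = ".decay_filter")]]
NumericVector decay_filter(NumericVector x, double a) {
  int n = x.size();
  NumericVector out(n);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    s = a * s + x[i];
    out[i] = s;
  }
  return out;
}
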