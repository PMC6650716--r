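#include <Rcpp.h>
using namespace Rcpp;

// Upper tail P(X >= k) of a Poisson-binomial variable X = sum of independent
// Bernoulli(q_t), by exact dynamic-programming convolution of the full
// distribution. The tail is summed directly over its own pmf terms (smallest
// first) rather than via 1 - P(X < k), so small tails keep full relative
// precision.
// [[Rcpp::export]]
double poisbinom_tail(NumericVector q, int k) {
  int T = q.size();
  if (k <= 0) return 1.0;
  if (k > T) return 0.0;
  std::vector<double> f(T + 1, 0.0);
  f[0] = 1.0;
  for (int t = 0; t < T; t++) {
    double qt = q[t];
    for (int j = t + 1; j >= 1; j--)
      f[j] = f[j] * (1.0 - qt) + f[j - 1] * qt;
    f[0] *= (1.0 - qt);
  }
  double tail = 0.0;
  for (int j = T; j >= k; j--) tail += f[j];
  if (tail > 1.0) tail = 1.0;
  return tail;
}
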