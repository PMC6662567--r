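#include <Rcpp.h>
using namespace Rcpp;

// Sample a DNA sequence of length n from an order-3 Markov chain.
// trans: 64 x 4 row-stochastic matrix, rows indexed by the previous three
// bases encoded base-4 (A=0, C=1, G=2, T=3) with the oldest base most
// significant.  u: n uniform(0,1) draws taken from R's RNG so that the
// result is reproducible under set.seed(); the first three bases are drawn
// from the chain's uniform start (u[0..2]).
// [[Rcpp::export]]
std::string markov_sequence(int n, NumericMatrix trans, NumericVector u) {
  if (trans.nrow() != 64 || trans.ncol() != 4)
    stop("transition matrix must be 64 x 4");
  if (u.size() < n) stop("need one uniform draw per base");
  static const char bases[] = {'A', 'C', 'G', 'T'};
  std::string out(n, 'A');
  int state = 0;
  for (int i = 0; i < n; ++i) {
    int b;
    if (i < 3) {
      b = (int)(u[i] * 4.0);
      if (b > 3) b = 3;
    } else {
      double r = u[i];
      double cum = 0.0;
      b = 3;
      for (int j = 0; j < 4; ++j) {
        cum += trans(state, j);
        if (r < cum) { b = j; break; }
      }
    }
    out[i] = bases[b];
    state = ((state * 4) % 64 + b) % 64;
  }
  return out;
}
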