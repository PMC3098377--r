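#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain over the DNA alphabet. `cum_trans` is a 4x4 matrix
// of cumulative transition probabilities (rows = current base A,C,G,T; each
// row ends at 1). `u` supplies one uniform per emitted base (drawn in R so
// set.seed() governs determinism); u[0] picks the initial state from
// `cum_init`. Returns the sequence as a single string.
// [[Rcpp::export]]
std::string markov_seq_cpp(NumericMatrix cum_trans, NumericVector cum_init,
                           NumericVector u) {
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  const int n = u.size();
  std::string out(n, 'A');
  int state = 0;
  for (int j = 0; j < 4; ++j) {
    if (u[0] <= cum_init[j]) { state = j; break; }
  }
  out[0] = alpha[state];
  for (int i = 1; i < n; ++i) {
    const double ui = u[i];
    int next = 3;
    for (int j = 0; j < 4; ++j) {
      if (ui <= cum_trans(state, j)) { next = j; break; }
    }
    out[i] = alpha[next];
    state = next;
  }
  return out;
}
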