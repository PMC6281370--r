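#include <Rcpp.h>
using namespace Rcpp;

// Lag histogram of every jitter surrogate.
//
// sp:  sorted spike times
// lo, hi: 0-based candidate spike ranges per event (spikes lo[e]..hi[e]-1
//         can fall in the window of event e wherever it lands in its cell)
// jit: n_events x S matrix of jittered event times
// Returns a B x S integer matrix of bin counts.
// [[Rcpp::export]]
IntegerMatrix jitter_lag_counts(NumericVector sp, IntegerVector lo,
                                IntegerVector hi, NumericMatrix jit,
                                double half, double bw, int B) {
  const int ne = jit.nrow(), S = jit.ncol();
  IntegerMatrix out(B, S);
  for (int s = 0; s < S; ++s) {
    IntegerMatrix::Column col = out(_, s);
    for (int e = 0; e < ne; ++e) {
      const double pos = jit(e, s);
      const int h = hi[e];
      for (int i = lo[e]; i < h; ++i) {
        const int b = (int)std::floor((sp[i] - pos + half) / bw);
        if (b >= 0 && b < B) ++col[b];
      }
    }
  }
  return out;
}
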