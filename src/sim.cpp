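#include <Rcpp.h>
using namespace Rcpp;

// Per-time-point state counts for a population of cells following the
// licensing/transition rules. States: 1 nonresolved, 2 resolved, 3 compacted.
// One uniform draw is consumed per cell per step (U is n x m, column = cell),
// whether or not the cell is transition-eligible, so the draw layout is
// independent of the parameters (common random numbers).
//
// effect_next: a successful draw at step k takes effect from step k+1
// (the recorded state at k is the pre-draw state); otherwise it takes
// effect at k itself. At most one transition per cell per step.
// [[Rcpp::export]]
IntegerMatrix cpp_state_counts(NumericVector times,
                               NumericVector t1, NumericVector t2,
                               NumericMatrix U,
                               double p1, double p2,
                               bool effect_next) {
  const int n = times.size();
  const int m = t1.size();
  if (U.nrow() != n || U.ncol() != m)
    stop("uniform matrix must be n x m");
  IntegerMatrix counts(n, 3);
  for (int i = 0; i < m; ++i) {
    int state = 1;
    const double a = t1[i], b = t2[i];
    for (int k = 0; k < n; ++k) {
      if (state == 3) {  // absorbing: count the rest and stop
        for (int kk = k; kk < n; ++kk) counts(kk, 2)++;
        break;
      }
      const double u = U(k, i);
      int next = state;
      if (state == 1 && times[k] >= a && u < p1) next = 2;
      else if (state == 2 && times[k] >= b && u < p2) next = 3;
      if (effect_next) {
        counts(k, state - 1)++;
        state = next;
      } else {
        state = next;
        counts(k, state - 1)++;
      }
    }
  }
  return counts;
}
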