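#include <Rcpp.h>
using namespace Rcpp;

// Simulate a k-dimensional VAR(p) with per-sample switching between two
// coefficient sets. A0/A1 are k x (k*p) matrices holding the lag blocks
// [A_1 | A_2 | ... | A_p]; innov is k x n and provides both the innovations
// and the first p initialisation columns. state[t] == 1 selects A1 at time t.
// [[Rcpp::export]]
NumericMatrix var_switch_sim_cpp(NumericMatrix A0, NumericMatrix A1,
                                 NumericMatrix innov, IntegerVector state) {
  const int k = innov.nrow();
  const int n = innov.ncol();
  const int p = A0.ncol() / k;
  NumericMatrix x(k, n);
  for (int t = 0; t < std::min(p, n); ++t)
    for (int i = 0; i < k; ++i) x(i, t) = innov(i, t);
  for (int t = p; t < n; ++t) {
    const NumericMatrix& A = (state[t] == 1) ? A1 : A0;
    for (int i = 0; i < k; ++i) {
      double acc = innov(i, t);
      for (int lag = 1; lag <= p; ++lag) {
        const int off = (lag - 1) * k;
        for (int j = 0; j < k; ++j) acc += A(i, off + j) * x(j, t - lag);
      }
      x(i, t) = acc;
    }
  }
  return x;
}

// Plain VAR(p) simulation (single coefficient set).
// [[Rcpp::export]]
NumericMatrix var_sim_cpp(NumericMatrix A, NumericMatrix innov) {
  IntegerVector state(innov.ncol(), 0);
  return var_switch_sim_cpp(A, A, innov, state);
}
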