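#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-state HMM given per-observation
// log emission likelihoods. logB is T x K. Returns posterior gamma (T x K),
// accumulated transition expectations xi_sum (K x K), gamma at t = 1, and
// the sequence log-likelihood.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix bhat(T, K);
  NumericVector m(T);
  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, logB(t, k));
    m[t] = mx;
    for (int k = 0; k < K; ++k) bhat(t, k) = std::exp(logB(t, k) - mx);
  }
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = std::exp(logpi[k]);

  NumericMatrix ahat(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { ahat(0, k) = pi[k] * bhat(0, k); s += ahat(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) ahat(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += ahat(t - 1, i) * A(i, j);
      a *= bhat(t, j);
      ahat(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < K; ++j) ahat(t, j) /= s;
  }

  NumericMatrix bbeta(T, K);
  for (int k = 0; k < K; ++k) bbeta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += A(i, j) * bhat(t + 1, j) * bbeta(t + 1, j);
      bbeta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = ahat(t, k) * bbeta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += ahat(t, i) * A(i, j) * bhat(t + 1, j) *
                    bbeta(t + 1, j) / c[t + 1];
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + m[t];
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = ll);
}

// Viterbi decoding in log space; returns the 1-based most probable path.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericVector logpi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix back(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = d(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = d(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      d(t, j) = best + logB(t, j);
      back(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (d(T - 1, k) > d(T - 1, arg)) arg = k;
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = back(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
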