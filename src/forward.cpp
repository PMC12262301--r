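#include <Rcpp.h>
using namespace Rcpp;

// Per-trial forward passes for the trial-by-trial learners. Predictor values
// are always computed from the state *before* the current trial's update, so
// they reflect expectancy about the upcoming node at stimulus onset.

// [[Rcpp::export]]
NumericVector recency_predictors_cpp(IntegerVector nodes0, int n_states,
                                     double alpha) {
  int T = nodes0.size();
  NumericVector pred(T);
  std::vector<double> W(n_states, 1.0 / n_states);
  for (int t = 0; t < T; ++t) {
    int s = nodes0[t];
    pred[t] = W[s];
    for (int j = 0; j < n_states; ++j) W[j] *= (1.0 - alpha);
    W[s] += alpha;
  }
  return pred;
}

// [[Rcpp::export]]
NumericVector onestep_predictors_cpp(IntegerVector nodes0, int n_states,
                                     double alpha) {
  int T = nodes0.size();
  NumericVector pred(T, NA_REAL);
  std::vector<double> Tm((size_t)n_states * n_states, 1.0 / n_states);
  for (int t = 1; t < T; ++t) {
    int sp = nodes0[t - 1], s = nodes0[t];
    double *row = &Tm[(size_t)sp * n_states];
    pred[t] = row[s];
    for (int j = 0; j < n_states; ++j) row[j] *= (1.0 - alpha);
    row[s] += alpha;
  }
  return pred;
}

// SR-TD(lambda) with a dutch eligibility trace. Update order per transition
// (s_prev -> s): trace increment, TD error, sweep over all rows weighted by
// eligibility, trace decay by gamma*lambda. M is the one-step-ahead SR; its
// closed-form initial value under a uniform transition matrix has every entry
// equal to 1 / (n * (1 - gamma)).
// [[Rcpp::export]]
List srtd_run_cpp(IntegerVector nodes0, int n_states, double alpha,
                  double gamma, double lambda,
                  Nullable<NumericMatrix> M_init = R_NilValue,
                  bool want_pred = true) {
  int T = nodes0.size();
  NumericVector pred(T, NA_REAL);
  std::vector<double> M((size_t)n_states * n_states);
  if (M_init.isNotNull()) {
    NumericMatrix Mi(M_init);
    for (int i = 0; i < n_states; ++i)
      for (int j = 0; j < n_states; ++j)
        M[(size_t)i * n_states + j] = Mi(i, j);
  } else {
    double v = 1.0 / (n_states * (1.0 - gamma));
    std::fill(M.begin(), M.end(), v);
  }
  std::vector<double> e(n_states, 0.0), delta(n_states);
  for (int t = 1; t < T; ++t) {
    int sp = nodes0[t - 1], s = nodes0[t];
    if (want_pred) {
      double rs = 0.0;
      const double *row = &M[(size_t)sp * n_states];
      for (int j = 0; j < n_states; ++j) rs += row[j];
      pred[t] = row[s] / rs;
    }
    e[sp] = (1.0 - alpha) * e[sp] + 1.0;
    const double *rs_row = &M[(size_t)s * n_states];
    const double *rp_row = &M[(size_t)sp * n_states];
    for (int j = 0; j < n_states; ++j)
      delta[j] = gamma * rs_row[j] - rp_row[j];
    delta[s] += 1.0;
    const double *__restrict dp = delta.data();
    for (int i = 0; i < n_states; ++i) {
      double w = alpha * e[i];
      if (w == 0.0) continue;
      double *__restrict row = &M[(size_t)i * n_states];
      for (int j = 0; j < n_states; ++j) row[j] += w * dp[j];
    }
    double gl = gamma * lambda;
    for (int i = 0; i < n_states; ++i) {
      e[i] *= gl;
      if (e[i] < 1e-14) e[i] = 0.0;
    }
  }
  NumericMatrix Mout(n_states, n_states);
  for (int i = 0; i < n_states; ++i)
    for (int j = 0; j < n_states; ++j)
      Mout(i, j) = M[(size_t)i * n_states + j];
  return List::create(_["pred"] = pred, _["M"] = Mout,
                      _["e"] = NumericVector(e.begin(), e.end()));
}

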