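#include <Rcpp.h>
using namespace Rcpp;

// wrapped Cauchy density with mean 0, concentration 0 <= g < 1
inline double dwcauchy0(double phi, double g) {
  return (1.0 - g * g) / (2.0 * M_PI * (1.0 + g * g - 2.0 * g * std::cos(phi)));
}

// Scaled forward recursion over concatenated sequences.
// P: T x K matrix of per-interval emission likelihoods, already masked
//    (impossible states 0, missing streams contributing factor 1).
// seq_start: length-T indicator, 1 where a new independent sequence begins.
// Returns total log-likelihood; -Inf if some interval has an all-zero row.
// [[Rcpp::export]]
double C_forward(NumericMatrix P, NumericMatrix Gamma, NumericVector delta,
                 IntegerVector seq_start) {
  int T = P.nrow(), K = P.ncol();
  std::vector<double> prev(K), cur(K);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double c = 0.0;
    if (seq_start[t]) {
      for (int j = 0; j < K; ++j) { cur[j] = delta[j] * P(t, j); c += cur[j]; }
    } else {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += prev[i] * Gamma(i, j);
        cur[j] = s * P(t, j);
        c += cur[j];
      }
    }
    if (!(c > 0.0) || !R_finite(c)) return R_NegInf;
    for (int j = 0; j < K; ++j) prev[j] = cur[j] / c;
    ll += std::log(c);
  }
  return ll;
}

// Negative log-likelihood with emissions computed in place (fast path for
// numerical optimisation). States 1..n_move are free movement states; known
// holds 0 (free: any movement state) or a 1-based state index to mask to.
// emits[j] = FALSE marks states with no emission distributions (unknown state).
// Steps of exactly 0 carry the zero-mass weight pi0[j].
// log_step = log(step) and cos_angle = cos(angle) are precomputed once from
// the data so repeated optimiser calls avoid transcendental re-evaluation.
// Returns a large penalty value when the masked likelihood degenerates.
// [[Rcpp::export]]
double C_nll(NumericVector step, NumericVector log_step,
             NumericVector cos_angle, IntegerVector known,
             IntegerVector seq_start, NumericVector mu, NumericVector sigma,
             NumericVector kappa, NumericVector pi0, LogicalVector emits,
             int n_move, NumericMatrix Gamma, NumericVector delta) {
  int T = step.size(), K = Gamma.nrow();
  std::vector<double> shape(K), rate(K), lconst(K), wc_num(K), wc_c1(K),
      wc_c2(K), prev(K), cur(K), p(K);
  for (int j = 0; j < K; ++j) {
    if (emits[j]) {
      shape[j] = (mu[j] * mu[j]) / (sigma[j] * sigma[j]);
      rate[j] = mu[j] / (sigma[j] * sigma[j]);
      // gamma log-density: (shape-1) log l - rate l + shape log rate - lgamma(shape)
      lconst[j] = shape[j] * std::log(rate[j]) - std::lgamma(shape[j]);
      wc_num[j] = (1.0 - kappa[j] * kappa[j]) / (2.0 * M_PI);
      wc_c1[j] = 1.0 + kappa[j] * kappa[j];
      wc_c2[j] = 2.0 * kappa[j];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    bool s_obs = !NumericVector::is_na(step[t]);
    bool a_obs = !NumericVector::is_na(cos_angle[t]);
    for (int j = 0; j < K; ++j) {
      bool allowed = (known[t] == 0) ? (j < n_move) : (j == known[t] - 1);
      if (!allowed) { p[j] = 0.0; continue; }
      double pe = 1.0;
      if (emits[j]) {
        if (s_obs) {
          if (step[t] == 0.0) pe *= pi0[j];
          else pe *= (1.0 - pi0[j]) *
            std::exp((shape[j] - 1.0) * log_step[t] - rate[j] * step[t] +
                     lconst[j]);
        }
        if (a_obs) pe *= wc_num[j] / (wc_c1[j] - wc_c2[j] * cos_angle[t]);
      }
      p[j] = pe;
    }
    double c = 0.0;
    if (seq_start[t]) {
      for (int j = 0; j < K; ++j) { cur[j] = delta[j] * p[j]; c += cur[j]; }
    } else {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += prev[i] * Gamma(i, j);
        cur[j] = s * p[j];
        c += cur[j];
      }
    }
    if (!(c > 0.0) || !R_finite(c)) return 1e10;
    for (int j = 0; j < K; ++j) prev[j] = cur[j] / c;
    ll += std::log(c);
  }
  return -ll;
}
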