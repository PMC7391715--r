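#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double ldnorm(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.5 * z * z - std::log(s) - 0.9189385332046727; // log(1/sqrt(2pi))
}

// Scaled forward-backward pass for a 2-state Gaussian HMM with shared
// emission sigma. Emission densities are computed in log space with a
// per-step shift so that traces with large 1/f excursions cannot
// underflow. Returns the log-likelihood and the sufficient statistics
// for the M-step.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector x, NumericVector mean, double sigma,
                   NumericMatrix P, NumericVector pi0) {
  const int n = x.size();
  std::vector<double> a0(n), a1(n), b0(n), b1(n), csc(n);
  double loglik = 0.0;

  for (int t = 0; t < n; ++t) {
    double l0 = ldnorm(x[t], mean[0], sigma);
    double l1 = ldnorm(x[t], mean[1], sigma);
    double mx = l0 > l1 ? l0 : l1;
    b0[t] = std::exp(l0 - mx);
    b1[t] = std::exp(l1 - mx);
    loglik += mx; // shift re-enters the likelihood here
  }

  // forward
  double f0 = pi0[0] * b0[0], f1 = pi0[1] * b1[0];
  double c = f0 + f1;
  a0[0] = f0 / c; a1[0] = f1 / c; csc[0] = c;
  loglik += std::log(c);
  for (int t = 1; t < n; ++t) {
    f0 = (a0[t - 1] * P(0, 0) + a1[t - 1] * P(1, 0)) * b0[t];
    f1 = (a0[t - 1] * P(0, 1) + a1[t - 1] * P(1, 1)) * b1[t];
    c = f0 + f1;
    a0[t] = f0 / c; a1[t] = f1 / c; csc[t] = c;
    loglik += std::log(c);
  }

  // backward + accumulation of gamma / xi sums
  double g_sum0 = 0, g_sum1 = 0, gx0 = 0, gx1 = 0, gxx0 = 0, gxx1 = 0;
  NumericMatrix trans(2, 2);
  double be0 = 1.0, be1 = 1.0; // beta_t (scaled)
  // t = n-1 contribution
  {
    double g0 = a0[n - 1], g1 = a1[n - 1];
    g_sum0 += g0; g_sum1 += g1;
    gx0 += g0 * x[n - 1]; gx1 += g1 * x[n - 1];
    gxx0 += g0 * x[n - 1] * x[n - 1]; gxx1 += g1 * x[n - 1] * x[n - 1];
  }
  double gamma1_0 = 0, gamma1_1 = 0;
  for (int t = n - 2; t >= 0; --t) {
    double cb0 = b0[t + 1] * be0, cb1 = b1[t + 1] * be1;
    // xi(i,j) = alpha_t(i) P(i,j) b_j(t+1) beta_{t+1}(j) / c_{t+1}
    double inv_c = 1.0 / csc[t + 1];
    trans(0, 0) += a0[t] * P(0, 0) * cb0 * inv_c;
    trans(0, 1) += a0[t] * P(0, 1) * cb1 * inv_c;
    trans(1, 0) += a1[t] * P(1, 0) * cb0 * inv_c;
    trans(1, 1) += a1[t] * P(1, 1) * cb1 * inv_c;
    // beta_t
    double nb0 = (P(0, 0) * cb0 + P(0, 1) * cb1) * inv_c;
    double nb1 = (P(1, 0) * cb0 + P(1, 1) * cb1) * inv_c;
    be0 = nb0; be1 = nb1;
    double g0 = a0[t] * be0, g1 = a1[t] * be1;
    double gs = g0 + g1; g0 /= gs; g1 /= gs; // guard tiny drift
    g_sum0 += g0; g_sum1 += g1;
    gx0 += g0 * x[t]; gx1 += g1 * x[t];
    gxx0 += g0 * x[t] * x[t]; gxx1 += g1 * x[t] * x[t];
    if (t == 0) { gamma1_0 = g0; gamma1_1 = g1; }
  }

  return List::create(
    _["loglik"] = loglik,
    _["gamma_sum"] = NumericVector::create(g_sum0, g_sum1),
    _["gamma_x"] = NumericVector::create(gx0, gx1),
    _["gamma_xx"] = NumericVector::create(gxx0, gxx1),
    _["trans"] = trans,
    _["gamma1"] = NumericVector::create(gamma1_0, gamma1_1));
}

// Most-probable state path (Viterbi) for the same model.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mean,
                              double sigma, NumericMatrix P,
                              NumericVector pi0) {
  const int n = x.size();
  std::vector<unsigned char> bp0(n), bp1(n);
  double lp00 = std::log(P(0, 0)), lp01 = std::log(P(0, 1));
  double lp10 = std::log(P(1, 0)), lp11 = std::log(P(1, 1));
  double d0 = std::log(pi0[0]) + ldnorm(x[0], mean[0], sigma);
  double d1 = std::log(pi0[1]) + ldnorm(x[0], mean[1], sigma);
  for (int t = 1; t < n; ++t) {
    double c00 = d0 + lp00, c10 = d1 + lp10;
    double c01 = d0 + lp01, c11 = d1 + lp11;
    double n0, n1;
    if (c00 >= c10) { n0 = c00; bp0[t] = 0; } else { n0 = c10; bp0[t] = 1; }
    if (c01 >= c11) { n1 = c01; bp1[t] = 0; } else { n1 = c11; bp1[t] = 1; }
    d0 = n0 + ldnorm(x[t], mean[0], sigma);
    d1 = n1 + ldnorm(x[t], mean[1], sigma);
  }
  IntegerVector path(n);
  int s = d1 > d0 ? 1 : 0;
  path[n - 1] = s;
  for (int t = n - 1; t > 0; --t) {
    s = (s == 0) ? bp0[t] : bp1[t];
    path[t - 1] = s;
  }
  return path;
}
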