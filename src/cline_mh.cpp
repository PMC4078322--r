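#include <Rcpp.h>
using namespace Rcpp;

// Sigmoid cline with optional exponential tails, unscaled shape f(x) in [0,1].
// Full parameter vector layout (fixed throughout the package):
//   0 center, 1 width, 2 delta_L, 3 tau_L, 4 delta_R, 5 tau_R, 6 p_min, 7 p_max
static inline double cline_shape(double x, const double *th,
                                 int left_tail, int right_tail) {
  double c = th[0], w = th[1];
  if (left_tail && x < c - th[2]) {
    double dL = th[2], tL = th[3];
    double f0 = 1.0 / (1.0 + std::exp(4.0 * dL / w));
    double slope = (4.0 * tL / w) / (1.0 + std::exp(-4.0 * dL / w));
    return f0 * std::exp(slope * (x - c + dL));
  }
  if (right_tail && x > c + th[4]) {
    double dR = th[4], tR = th[5];
    double f1 = 1.0 / (1.0 + std::exp(-4.0 * dR / w));
    double slope = (4.0 * tR / w) / (1.0 + std::exp(-4.0 * dR / w));
    return 1.0 - (1.0 - f1) * std::exp(-slope * (x - c - dR));
  }
  return 1.0 / (1.0 + std::exp(-4.0 * (x - c) / w));
}

static double loglik_full(const double *th, const NumericVector &x,
                          const NumericVector &k, const NumericVector &n,
                          int left_tail, int right_tail) {
  const double eps = 1e-9;
  if (th[1] <= 0.0 || th[6] > th[7]) return R_NegInf;
  double ll = 0.0;
  for (int i = 0; i < x.size(); ++i) {
    double f = cline_shape(x[i], th, left_tail, right_tail);
    double p = th[6] + (th[7] - th[6]) * f;
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += R::dbinom(k[i], n[i], p, 1);
  }
  return ll;
}

// [[Rcpp::export]]
double cline_loglik_cpp(NumericVector full, NumericVector x, NumericVector k,
                        NumericVector n, int left_tail, int right_tail) {
  return loglik_full(REAL(full), x, k, n, left_tail, right_tail);
}

// Random-walk Metropolis chain for a cline model. Free parameters `theta`
// map linearly into the 8-slot full vector: full = base + map %*% theta,
// which also handles the mirrored-tail models (one free delta feeding both
// slots). Proposals are multivariate normal via an upper-triangular Cholesky
// factor; flat priors on [lower, upper] with rejection outside the box.
// [[Rcpp::export]]
List mh_chain_cpp(NumericVector theta0, NumericMatrix chol_up,
                  NumericVector lower, NumericVector upper,
                  NumericMatrix map, NumericVector base_full,
                  NumericVector x, NumericVector k, NumericVector n,
                  int left_tail, int right_tail, int n_iter) {
  const int p = theta0.size();
  NumericMatrix samples(n_iter, p);
  NumericVector lls(n_iter);
  std::vector<double> cur(theta0.begin(), theta0.end());
  std::vector<double> prop(p), z(p), full(8);

  auto expand = [&](const std::vector<double> &th) {
    for (int s = 0; s < 8; ++s) {
      double v = base_full[s];
      for (int j = 0; j < p; ++j) v += map(s, j) * th[j];
      full[s] = v;
    }
  };

  expand(cur);
  double ll_cur = loglik_full(full.data(), x, k, n, left_tail, right_tail);
  int accepts = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < p; ++j) z[j] = norm_rand();
    bool ok = true;
    for (int j = 0; j < p; ++j) {
      double step = 0.0;
      for (int i = 0; i <= j; ++i) step += z[i] * chol_up(i, j);
      prop[j] = cur[j] + step;
      if (prop[j] < lower[j] || prop[j] > upper[j]) ok = false;
    }
    if (ok) {
      expand(prop);
      double ll_new = loglik_full(full.data(), x, k, n, left_tail, right_tail);
      if (R_finite(ll_new) && std::log(unif_rand()) < ll_new - ll_cur) {
        cur = prop;
        ll_cur = ll_new;
        ++accepts;
      }
    }
    for (int j = 0; j < p; ++j) samples(it, j) = cur[j];
    lls[it] = ll_cur;
  }
  return List::create(_["samples"] = samples, _["ll"] = lls,
                      _["accepts"] = accepts);
}
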