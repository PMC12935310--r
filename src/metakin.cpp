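#include <Rcpp.h>
using namespace Rcpp;

// Forward algorithm over the 4 hidden joint states with per-step log
// emission weights. logE has one row per increment (frames 1..T-1), columns
// in the fixed state ordering (++, +-, -+, --). Returns the log marginal
// likelihood and the normalised filtered probabilities used for backward
// sampling.
// [[Rcpp::export]]
List forward_filter_cpp(const NumericMatrix& logE, const NumericMatrix& P,
                        const NumericVector& pi0) {
  const int n = logE.nrow();
  NumericMatrix alpha(n, 4);
  double loglik = 0.0;
  double a[4];
  for (int t = 0; t < n; ++t) {
    double m = R_NegInf;
    for (int s = 0; s < 4; ++s) m = std::max(m, logE(t, s));
    if (!R_finite(m)) m = 0.0; // all-missing step: emission weight 1
    double c = 0.0;
    for (int s = 0; s < 4; ++s) {
      double pred;
      if (t == 0) {
        pred = pi0[s];
      } else {
        pred = 0.0;
        for (int r = 0; r < 4; ++r) pred += alpha(t - 1, r) * P(r, s);
      }
      a[s] = pred * std::exp(logE(t, s) - m);
      c += a[s];
    }
    if (c <= 0.0 || !R_finite(c)) {
      return List::create(_["loglik"] = R_NegInf, _["alpha"] = alpha);
    }
    for (int s = 0; s < 4; ++s) alpha(t, s) = a[s] / c;
    loglik += std::log(c) + m;
  }
  return List::create(_["loglik"] = loglik, _["alpha"] = alpha);
}

// Joint backward sampling of hidden state paths given the filtered
// probabilities. Returns n_draws x n matrix of 1-based state indices.
// [[Rcpp::export]]
IntegerMatrix backward_sample_cpp(const NumericMatrix& alpha,
                                  const NumericMatrix& P, int n_draws) {
  const int n = alpha.nrow();
  IntegerMatrix paths(n_draws, n);
  NumericVector w(4);
  for (int d = 0; d < n_draws; ++d) {
    double u = R::runif(0.0, 1.0), c = 0.0;
    int s = 3;
    for (int k = 0; k < 4; ++k) { c += alpha(n - 1, k); if (u <= c) { s = k; break; } }
    paths(d, n - 1) = s + 1;
    for (int t = n - 2; t >= 0; --t) {
      double tot = 0.0;
      for (int k = 0; k < 4; ++k) { w[k] = alpha(t, k) * P(k, s); tot += w[k]; }
      u = R::runif(0.0, 1.0) * tot; c = 0.0; int snew = 3;
      for (int k = 0; k < 4; ++k) { c += w[k]; if (u <= c) { snew = k; break; } }
      s = snew;
      paths(d, t) = s + 1;
    }
  }
  return paths;
}

// Dynamic time warping distance between equal-or-unequal length series with
// a Sakoe-Chiba band, symmetric step pattern, squared local cost; returns
// the square root of the accumulated cost.
// [[Rcpp::export]]
double dtw_band_cpp(const NumericVector& x, const NumericVector& y, int band) {
  const int n = x.size(), m = y.size();
  const double inf = R_PosInf;
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double d = x[i - 1] - y[j - 1];
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return std::sqrt(prev[m]);
}
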