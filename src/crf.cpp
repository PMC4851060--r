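// Linear-chain CRF internals: online (filtered) marginal recursion and the
// class-weighted per-position log-likelihood with exact reverse-mode
// gradient.  All recursions run in log space.
//
// Model: unary log-potential u_t(y) supplied as a T x K matrix (computed
// in R as X %*% t(unary_weights)); homogeneous transition log-potentials
// trans(y_prev, y_cur) as a K x K matrix.  The filtered marginal obeys
//   lm_1 = u_1 - lse(u_1)
//   a_t(z) = u_t(z) + lse_y'( trans(y', z) + lm_{t-1}(y') ),
//   lm_t = a_t - lse(a_t),
// which equals log p(y_t | x_{1..t}) for the chain with those potentials.

#include <Rcpp.h>
using namespace Rcpp;

static inline double lse(const std::vector<double>& v) {
  double m = v[0];
  for (size_t k = 1; k < v.size(); ++k) if (v[k] > m) m = v[k];
  double s = 0.0;
  for (size_t k = 0; k < v.size(); ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

// forward pass shared by filtering and the objective; fills lm (T x K) and
// b (T x K, b.row(0) unused) with log-sum terms
static void forward_pass(const NumericMatrix& logU, const NumericMatrix& trans,
                         NumericMatrix& lm, NumericMatrix& b) {
  const int T = logU.nrow(), K = logU.ncol();
  std::vector<double> a(K), tmp(K);
  for (int t = 0; t < T; ++t) {
    for (int z = 0; z < K; ++z) {
      double bz = 0.0;
      if (t > 0) {
        for (int y = 0; y < K; ++y) tmp[y] = trans(y, z) + lm(t - 1, y);
        bz = lse(tmp);
        b(t, z) = bz;
      }
      a[z] = logU(t, z) + bz;
    }
    double Z = lse(a);
    for (int z = 0; z < K; ++z) lm(t, z) = a[z] - Z;
  }
}

// [[Rcpp::export(name = ".crf_filter_cpp")]]
NumericMatrix crf_filter_cpp(NumericMatrix logU, NumericMatrix trans) {
  const int T = logU.nrow(), K = logU.ncol();
  NumericMatrix lm(T, K), b(T, K);
  forward_pass(logU, trans, lm, b);
  return lm;  // log filtered marginals
}

// Weighted per-position log-likelihood sum_t w[y_t] * lm_t(y_t) and its
// gradient wrt logU (returned as delta, T x K; chain rule to unary weights
// is crossprod(delta, X) in R) and wrt trans (K x K).
// [[Rcpp::export(name = ".crf_wll_core_cpp")]]
List crf_wll_core_cpp(NumericMatrix logU, NumericMatrix trans,
                      IntegerVector y, NumericVector w) {
  const int T = logU.nrow(), K = logU.ncol();
  if (y.size() != T) stop("label/feature length mismatch");
  NumericMatrix lm(T, K), b(T, K);
  forward_pass(logU, trans, lm, b);

  double value = 0.0;
  for (int t = 0; t < T; ++t) {
    int yt = y[t] - 1;
    if (yt < 0 || yt >= K) stop("label out of range");
    value += w[yt] * lm(t, yt);
  }

  NumericMatrix delta(T, K), gradT(K, K);
  std::vector<double> G(K, 0.0), Gnew(K);
  for (int t = T - 1; t >= 0; --t) {
    G[y[t] - 1] += w[y[t] - 1];
    double S = 0.0;
    for (int k = 0; k < K; ++k) S += G[k];
    for (int z = 0; z < K; ++z)
      delta(t, z) = G[z] - std::exp(lm(t, z)) * S;
    if (t > 0) {
      std::fill(Gnew.begin(), Gnew.end(), 0.0);
      for (int z = 0; z < K; ++z) {
        double dz = delta(t, z);
        for (int yp = 0; yp < K; ++yp) {
          // softmax responsibility of y_{t-1}=yp for reaching z at t
          double P = std::exp(trans(yp, z) + lm(t - 1, yp) - b(t, z));
          gradT(yp, z) += dz * P;
          Gnew[yp] += dz * P;
        }
      }
      G = Gnew;
    }
  }
  return List::create(_["value"] = value, _["delta"] = delta,
                      _["grad_trans"] = gradT, _["logm"] = lm);
}
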