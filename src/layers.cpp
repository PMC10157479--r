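// Elementwise and pooling helpers for the CNN; these are memory-bound
// operations where R's logical indexing dominates the training profile.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(rng = false)]]
NumericMatrix lrelu_fwd(const NumericMatrix& Y, double slope) {
  NumericMatrix out(Y.nrow(), Y.ncol());
  const double* y = Y.begin();
  double* o = out.begin();
  const R_xlen_t n = Y.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = y[i] < 0 ? slope * y[i] : y[i];
  return out;
}

// gradient through the activation; `act` is the forward *output*, whose
// sign equals the pre-activation sign for slope > 0
// [[Rcpp::export(rng = false)]]
NumericMatrix lrelu_bwd(const NumericMatrix& dout, const NumericMatrix& act,
                        double slope) {
  NumericMatrix dx(dout.nrow(), dout.ncol());
  const double* d = dout.begin();
  const double* a = act.begin();
  double* o = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = a[i] < 0 ? slope * d[i] : d[i];
  return dx;
}

// max-pool kernel 2 stride 2 along the position axis of a C x (L*B)
// channel-major feature map; odd tails pool a single element.
// Returns the pooled map and the flat argmax indices for the backward pass.
// [[Rcpp::export(rng = false)]]
List maxpool2_fwd(const NumericMatrix& X, int L, int B) {
  const int C = X.nrow();
  const int Lout = (L + 1) / 2;
  NumericMatrix Y(C, (R_xlen_t)Lout * B);
  IntegerVector arg((R_xlen_t)C * Lout * B);
  const double* x = X.begin();
  double* y = Y.begin();
  int* a = arg.begin();
  for (int b = 0; b < B; ++b) {
    for (int m = 0; m < Lout; ++m) {
      const R_xlen_t c1 = ((R_xlen_t)b * L + 2 * m) * C;
      const bool has2 = (2 * m + 1) < L;
      const R_xlen_t c2 = has2 ? c1 + C : c1;
      const R_xlen_t o = ((R_xlen_t)b * Lout + m) * C;
      for (int c = 0; c < C; ++c) {
        const double v1 = x[c1 + c];
        const double v2 = x[c2 + c];
        if (has2 && v2 > v1) {
          y[o + c] = v2;
          a[o + c] = (int)(c2 + c);
        } else {
          y[o + c] = v1;
          a[o + c] = (int)(c1 + c);
        }
      }
    }
  }
  return List::create(_["out"] = Y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix maxpool2_bwd(const NumericMatrix& dout,
                           const IntegerVector& arg, int C, int L, int B) {
  NumericMatrix dx(C, (R_xlen_t)L * B);
  double* o = dx.begin();
  const double* d = dout.begin();
  const int* a = arg.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) o[a[i]] += d[i];
  return dx;
}

// fused batch-norm forward over a C x M channel-major map (per-row stats)
// [[Rcpp::export(rng = false)]]
List bn_fwd(const NumericMatrix& Y, const NumericVector& gamma,
            const NumericVector& beta, double eps) {
  const int C = Y.nrow();
  const R_xlen_t M = Y.ncol(), n = Y.size();
  std::vector<double> sum(C, 0.0), sumsq(C, 0.0);
  const double* y = Y.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int c = (int)(i % C);
    sum[c] += y[i];
    sumsq[c] += y[i] * y[i];
  }
  NumericVector mean(C), var(C), inv(C);
  for (int c = 0; c < C; ++c) {
    mean[c] = sum[c] / M;
    var[c] = sumsq[c] / M - mean[c] * mean[c];
    inv[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericMatrix out(C, M), xhat(C, M);
  double* o = out.begin();
  double* xh = xhat.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int c = (int)(i % C);
    xh[i] = (y[i] - mean[c]) * inv[c];
    o[i] = gamma[c] * xh[i] + beta[c];
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv,
                      _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(rng = false)]]
List bn_bwd(const NumericMatrix& dout, const NumericMatrix& xhat,
            const NumericVector& inv, const NumericVector& gamma) {
  const int C = dout.nrow();
  const R_xlen_t M = dout.ncol(), n = dout.size();
  NumericVector dgamma(C), dbeta(C);
  const double* d = dout.begin();
  const double* xh = xhat.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int c = (int)(i % C);
    dgamma[c] += d[i] * xh[i];
    dbeta[c] += d[i];
  }
  NumericMatrix dY(C, M);
  double* o = dY.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int c = (int)(i % C);
    o[i] = inv[c] * gamma[c] * (d[i] - dbeta[c] / M - xh[i] * dgamma[c] / M);
  }
  return List::create(_["dY"] = dY, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
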