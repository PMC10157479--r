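// Batched 1-D convolution ("same" padding, stride 1) used by the CNN
// regressor.  Feature maps are stored channel-major: a C x (L*B) matrix
// whose columns run position-fastest within each sample.  Each kernel
// shift is a single DGEMM over the whole (per-sample zero-padded) batch,
// so the layer runs at BLAS speed without materialising an im2col copy.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

// copy the valid columns of each sample into a padded buffer (pads zeroed)
static void pad_batch(const double* x, double* xp, int nch, int L, int B,
                      int p) {
  const int Lp = L + 2 * p;
  std::memset(xp, 0, sizeof(double) * (size_t)nch * Lp * B);
  for (int b = 0; b < B; ++b)
    std::memcpy(xp + ((size_t)b * Lp + p) * nch, x + (size_t)b * L * nch,
                sizeof(double) * (size_t)nch * L);
}

static void unpad_batch(const double* xp, double* x, int nch, int L, int B,
                        int p) {
  const int Lp = L + 2 * p;
  for (int b = 0; b < B; ++b)
    std::memcpy(x + (size_t)b * L * nch, xp + ((size_t)b * Lp + p) * nch,
                sizeof(double) * (size_t)nch * L);
}

// X: Cin x (L*B); K: array dim (Cin, Cout, W), W odd.  Returns Cout x (L*B).
// [[Rcpp::export(rng = false)]]
NumericMatrix conv1d_forward(const NumericMatrix& X, const NumericVector& K,
                             int cin, int cout, int W, int L, int B) {
  const int p = (W - 1) / 2, Lp = L + 2 * p;
  const int ncp = Lp * B;
  std::vector<double> Xp((size_t)cin * ncp), Yp((size_t)cout * ncp, 0.0);
  pad_batch(X.begin(), Xp.data(), cin, L, B, p);
  const double one = 1.0;
  for (int w = 0; w < W; ++w) {
    const int d = w - p;
    const int c0 = d < 0 ? -d : 0;
    const int c1 = d > 0 ? ncp - 1 - d : ncp - 1;
    const int ncols = c1 - c0 + 1;
    if (ncols <= 0) continue;
    F77_CALL(dgemm)("T", "N", &cout, &ncols, &cin, &one,
                    &K[(size_t)w * cin * cout], &cin,
                    Xp.data() + (size_t)(c0 + d) * cin, &cin, &one,
                    Yp.data() + (size_t)c0 * cout, &cout FCONE FCONE);
  }
  NumericMatrix Y(cout, L * B);
  unpad_batch(Yp.data(), Y.begin(), cout, L, B, p);
  return Y;
}

// Gradients wrt input and kernel.  dY: Cout x (L*B).
// [[Rcpp::export(rng = false)]]
List conv1d_backward(const NumericMatrix& X, const NumericVector& K,
                     const NumericMatrix& dY, int cin, int cout, int W,
                     int L, int B) {
  const int p = (W - 1) / 2, Lp = L + 2 * p;
  const int ncp = Lp * B;
  std::vector<double> Xp((size_t)cin * ncp), dYp((size_t)cout * ncp),
      dXp((size_t)cin * ncp, 0.0);
  pad_batch(X.begin(), Xp.data(), cin, L, B, p);
  pad_batch(dY.begin(), dYp.data(), cout, L, B, p);
  NumericVector dK((size_t)cin * cout * W);
  const double one = 1.0, zero = 0.0;
  for (int w = 0; w < W; ++w) {
    const int d = w - p;
    const int c0 = d < 0 ? -d : 0;
    const int c1 = d > 0 ? ncp - 1 - d : ncp - 1;
    const int ncols = c1 - c0 + 1;
    if (ncols <= 0) continue;
    // dX[:, c+d] += K_w %*% dY[:, c]
    F77_CALL(dgemm)("N", "N", &cin, &ncols, &cout, &one,
                    &K[(size_t)w * cin * cout], &cin,
                    dYp.data() + (size_t)c0 * cout, &cout, &one,
                    dXp.data() + (size_t)(c0 + d) * cin, &cin FCONE FCONE);
    // dK_w = X[:, c+d] %*% t(dY[:, c])
    F77_CALL(dgemm)("N", "T", &cin, &cout, &ncols, &one,
                    Xp.data() + (size_t)(c0 + d) * cin, &cin,
                    dYp.data() + (size_t)c0 * cout, &cout, &zero,
                    &dK[(size_t)w * cin * cout], &cin FCONE FCONE);
  }
  NumericMatrix dX(cin, L * B);
  unpad_batch(dXp.data(), dX.begin(), cin, L, B, p);
  dK.attr("dim") = IntegerVector::create(cin, cout, W);
  return List::create(_["dX"] = dX, _["dK"] = dK);
}
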