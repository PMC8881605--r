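#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Prediction-path forward pass for the six weekly-weather conv branches.
// Processes one (sample, variable) series at a time with small contiguous
// buffers, avoiding the large (N * L) x C intermediates of the R training
// path. Valid padding, ReLU after every conv layer, one trailing average
// pool. Output layout matches the R flatten: column (v-1)*Lf*F + (p-1)*F + f.
//
// conv_w: per-variable list (length 6) of per-layer weight matrices
//         ((k * C_in) x F, rows ordered (tap-1)*C_in + channel);
// conv_b: matching per-variable list of per-layer bias vectors.

// [[Rcpp::export]]
NumericMatrix cpp_cnn_branches(NumericMatrix Wx, int n_weeks,
                               List conv_w, List conv_b,
                               IntegerVector kernel, IntegerVector stride,
                               int pool) {
  const int N = Wx.nrow();
  const int n_var = 6;
  const int n_layers = kernel.size();

  std::vector<int> L(n_layers + 1), C(n_layers + 1);
  L[0] = n_weeks; C[0] = 1;
  {
    List w0 = conv_w[0];
    for (int l = 0; l < n_layers; ++l) {
      L[l + 1] = (L[l] - kernel[l]) / stride[l] + 1;
      C[l + 1] = as<NumericMatrix>(w0[l]).ncol();
      if (L[l + 1] < 1) stop("kernel exceeds input length");
    }
  }
  const int Lf = L[n_layers] / pool;
  const int F = C[n_layers];
  const int K = Lf * F;

  NumericMatrix out(N, n_var * K);
  double* outp = REAL(out);
  const double* wxp = REAL(Wx);

  std::vector<double> cur, nxt, series((size_t)N * n_weeks);

  for (int v = 0; v < n_var; ++v) {
    // flat copies of this variable's weights/biases
    List wv = conv_w[v], bv = conv_b[v];
    std::vector<std::vector<double> > Wf(n_layers), Bf(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      NumericMatrix W = as<NumericMatrix>(wv[l]);
      Wf[l].assign(W.begin(), W.end());            // column-major (kC) x F
      NumericVector B = as<NumericVector>(bv[l]);
      Bf[l].assign(B.begin(), B.end());
    }
    // transpose this variable's N x L block into series-contiguous storage
    for (int p = 0; p < n_weeks; ++p) {
      const double* col = wxp + (size_t)(v * n_weeks + p) * N;
      for (int n = 0; n < N; ++n) series[(size_t)n * n_weeks + p] = col[n];
    }
    for (int n = 0; n < N; ++n) {
      const double* s0 = &series[(size_t)n * n_weeks];
      cur.assign(s0, s0 + n_weeks);
      for (int l = 0; l < n_layers; ++l) {
        const int k = kernel[l], st = stride[l];
        const int Lo = L[l + 1], Ci = C[l], Fo = C[l + 1];
        const int kc = k * Ci;
        const double* W = Wf[l].data();
        const double* B = Bf[l].data();
        nxt.assign((size_t)Lo * Fo, 0.0);
        for (int t = 0; t < Lo; ++t) {
          const double* in = &cur[(size_t)t * st * Ci]; // taps are contiguous
          double* o = &nxt[(size_t)t * Fo];
          for (int f = 0; f < Fo; ++f) {
            const double* wf = W + (size_t)f * kc;
            double acc = B[f];
            for (int r = 0; r < kc; ++r) acc += in[r] * wf[r];
            o[f] = acc > 0.0 ? acc : 0.0;
          }
        }
        cur.swap(nxt);
      }
      // average pool + flattened write (column-major out, stride N)
      for (int p = 0; p < Lf; ++p) {
        for (int f = 0; f < F; ++f) {
          double acc = 0.0;
          for (int j = 0; j < pool; ++j) acc += cur[(size_t)(p * pool + j) * F + f];
          outp[(size_t)(v * K + p * F + f) * N + n] = acc / pool;
        }
      }
    }
  }
  return out;
}
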