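#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Training-path kernels for the conv branches: forward with retained
// activations, and backward producing conv weight/bias gradients plus
// nothing else (the head and static branch live in R / BLAS).
//
// Activation layout per layer: one flat vector over (sample, variable,
// position, channel), channel fastest, i.e. index
// ((n * 6 + v) * L_l + p) * C_l + c.

static void trace_shapes(int n_weeks, List conv_w,
                         IntegerVector kernel, IntegerVector stride,
                         std::vector<int>& L, std::vector<int>& C) {
  const int n_layers = kernel.size();
  L.assign(n_layers + 1, 0); C.assign(n_layers + 1, 0);
  L[0] = n_weeks; C[0] = 1;
  List w0 = conv_w[0];
  for (int l = 0; l < n_layers; ++l) {
    L[l + 1] = (L[l] - kernel[l]) / stride[l] + 1;
    C[l + 1] = as<NumericMatrix>(w0[l]).ncol();
    if (L[l + 1] < 1) stop("kernel exceeds input length");
  }
}

// [[Rcpp::export]]
List cpp_branch_train_fwd(NumericMatrix Wx, int n_weeks,
                          List conv_w, List conv_b,
                          IntegerVector kernel, IntegerVector stride,
                          int pool) {
  const int N = Wx.nrow();
  const int n_var = 6;
  const int n_layers = kernel.size();
  std::vector<int> L, C;
  trace_shapes(n_weeks, conv_w, kernel, stride, L, C);
  const int Lf = L[n_layers] / pool;
  const int F = C[n_layers];
  const int K = Lf * F;

  List acts(n_layers + 1);
  std::vector<double*> actp(n_layers + 1);
  for (int l = 0; l <= n_layers; ++l) {
    NumericVector a((size_t)N * n_var * L[l] * C[l]);
    acts[l] = a;
    actp[l] = REAL(a);
  }
  NumericMatrix flat(N, n_var * K);
  double* flatp = REAL(flat);
  const double* wxp = REAL(Wx);

  for (int v = 0; v < n_var; ++v) {
    List wv = conv_w[v], bv = conv_b[v];
    std::vector<std::vector<double> > Wf(n_layers), Bf(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      NumericMatrix W = as<NumericMatrix>(wv[l]);
      Wf[l].assign(W.begin(), W.end());
      NumericVector B = as<NumericVector>(bv[l]);
      Bf[l].assign(B.begin(), B.end());
    }
    for (int n = 0; n < N; ++n) {
      const size_t sv = (size_t)(n * n_var + v);
      // copy the input series into act0
      double* a0 = actp[0] + sv * n_weeks;
      for (int p = 0; p < n_weeks; ++p) a0[p] = wxp[(size_t)(v * n_weeks + p) * N + n];
      for (int l = 0; l < n_layers; ++l) {
        const int k = kernel[l], st = stride[l];
        const int Lo = L[l + 1], Ci = C[l], Fo = C[l + 1];
        const int kc = k * Ci;
        const double* W = Wf[l].data();
        const double* B = Bf[l].data();
        const double* in0 = actp[l] + sv * ((size_t)L[l] * Ci);
        double* out0 = actp[l + 1] + sv * ((size_t)Lo * Fo);
        for (int t = 0; t < Lo; ++t) {
          const double* in = in0 + (size_t)t * st * Ci;
          double* o = out0 + (size_t)t * Fo;
          for (int f = 0; f < Fo; ++f) {
            const double* wf = W + (size_t)f * kc;
            double acc = B[f];
            for (int r = 0; r < kc; ++r) acc += in[r] * wf[r];
            o[f] = acc > 0.0 ? acc : 0.0;
          }
        }
      }
      const double* last = actp[n_layers] + sv * ((size_t)L[n_layers] * F);
      for (int p = 0; p < Lf; ++p) {
        for (int f = 0; f < F; ++f) {
          double acc = 0.0;
          for (int j = 0; j < pool; ++j) acc += last[(size_t)(p * pool + j) * F + f];
          flatp[(size_t)(v * K + p * F + f) * N + n] = acc / pool;
        }
      }
    }
  }
  return List::create(_["flat"] = flat, _["acts"] = acts);
}

// [[Rcpp::export]]
List cpp_branch_train_bwd(NumericMatrix dFlat, List acts, int n_weeks,
                          List conv_w, IntegerVector kernel,
                          IntegerVector stride, int pool, bool shared) {
  const int N = dFlat.nrow();
  const int n_var = 6;
  const int n_layers = kernel.size();
  std::vector<int> L, C;
  trace_shapes(n_weeks, conv_w, kernel, stride, L, C);
  const int Lf = L[n_layers] / pool;
  const int F = C[n_layers];
  const int K = Lf * F;

  std::vector<const double*> actp(n_layers + 1);
  for (int l = 0; l <= n_layers; ++l) actp[l] = REAL((SEXP)acts[l]);
  const double* dfp = REAL(dFlat);

  const int n_groups = shared ? 1 : n_var;
  // gradient accumulators [group][layer]
  std::vector<std::vector<std::vector<double> > > dW(n_groups), dB(n_groups);
  std::vector<std::vector<std::vector<double> > > Wf(n_var);
  for (int v = 0; v < n_var; ++v) {
    List wv = conv_w[v];
    Wf[v].resize(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      NumericMatrix W = as<NumericMatrix>(wv[l]);
      Wf[v][l].assign(W.begin(), W.end());
    }
  }
  for (int g = 0; g < n_groups; ++g) {
    dW[g].resize(n_layers); dB[g].resize(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      dW[g][l].assign((size_t)kernel[l] * C[l] * C[l + 1], 0.0);
      dB[g][l].assign(C[l + 1], 0.0);
    }
  }

  // per-series gradient buffers
  std::vector<std::vector<double> > dact(n_layers + 1);
  for (int l = 0; l <= n_layers; ++l) dact[l].resize((size_t)L[l] * C[l]);

  for (int v = 0; v < n_var; ++v) {
    const int g = shared ? 0 : v;
    for (int n = 0; n < N; ++n) {
      const size_t sv = (size_t)(n * n_var + v);
      // pool backward: spread dFlat over the pooled window
      std::fill(dact[n_layers].begin(), dact[n_layers].end(), 0.0);
      for (int p = 0; p < Lf; ++p) {
        for (int f = 0; f < F; ++f) {
          const double d = dfp[(size_t)(v * K + p * F + f) * N + n] / pool;
          for (int j = 0; j < pool; ++j) {
            dact[n_layers][(size_t)(p * pool + j) * F + f] += d;
          }
        }
      }
      for (int l = n_layers - 1; l >= 0; --l) {
        const int k = kernel[l], st = stride[l];
        const int Lo = L[l + 1], Ci = C[l], Fo = C[l + 1];
        const int kc = k * Ci;
        const double* out = actp[l + 1] + sv * ((size_t)Lo * Fo);
        const double* in0 = actp[l] + sv * ((size_t)L[l] * Ci);
        const double* W = Wf[v][l].data();
        double* gW = dW[g][l].data();
        double* gB = dB[g][l].data();
        std::fill(dact[l].begin(), dact[l].end(), 0.0);
        for (int t = 0; t < Lo; ++t) {
          const double* in = in0 + (size_t)t * st * Ci;
          double* din = &dact[l][(size_t)t * st * Ci];
          for (int f = 0; f < Fo; ++f) {
            if (out[(size_t)t * Fo + f] <= 0.0) continue; // ReLU gate
            const double dz = dact[l + 1][(size_t)t * Fo + f];
            if (dz == 0.0) continue;
            gB[f] += dz;
            const double* wf = W + (size_t)f * kc;
            double* gw = gW + (size_t)f * kc;
            for (int r = 0; r < kc; ++r) {
              gw[r] += in[r] * dz;
              din[r] += wf[r] * dz;
            }
          }
        }
      }
    }
  }

  // package gradients: matrices (k*Ci) x Fo per group/layer
  List out(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    List gl_w(n_layers), gl_b(n_layers);
    for (int l = 0; l < n_layers; ++l) {
      NumericMatrix m(kernel[l] * C[l], C[l + 1]);
      std::copy(dW[g][l].begin(), dW[g][l].end(), m.begin());
      gl_w[l] = m;
      gl_b[l] = NumericVector(dB[g][l].begin(), dB[g][l].end());
    }
    out[g] = List::create(_["dW"] = gl_w, _["db"] = gl_b);
  }
  return out;
}
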