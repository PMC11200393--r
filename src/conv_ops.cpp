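// Strided 3x3 convolution and transposed-convolution kernels used by the
// convolutional autoencoders, plus the Adam parameter update. All conv
// layers use stride 2 with asymmetric "same" padding (pad 0 at the leading
// edge, 1 at the trailing edge), so a conv halves each spatial side and a
// transposed conv doubles it.
//
// Numerical design: parameters and activations cross the R boundary in
// double precision; the im2col/GEMM arithmetic inside each layer runs in
// single precision (the standard precision for convolutional training),
// which halves memory traffic and BLAS cost at ~1e-7 relative error per
// layer. The Adam update runs fully in double precision.
//
// Layout conventions shared with the R side:
//   activations  : arrays dim (H, W, C, N), column-major
//   conv weights : matrix (9*Cin)  x Cout, row index a + 3*b + 9*c
//   convT weights: matrix Cin x (9*Cout), col index a + 3*b + 9*c
// im2col rows enumerate output positions r = i + j*(H/2); batches are
// stacked into one tall matrix so each layer runs a single GEMM.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::List;

// Gather the 3x3 stride-2 patches of one (H2, W2, C) cube (pointer `xp`)
// into rows [row0, row0 + oh*ow) of the single-precision matrix A.
static void im2col2_into(const double* xp, int H2, int W2, int C,
                         fmat& A, uword row0) {
  const int oh = H2 / 2, ow = W2 / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H2 * W2;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        float* col = A.colptr(a + 3 * b + 9 * c) + row0;
        for (int j = 0; j < ow; ++j) {
          const int xj = 2 * j + b;
          if (xj >= W2) { for (int i = 0; i < oh; ++i) col[i + j * oh] = 0.0f; continue; }
          const double* src = xc + (size_t)xj * H2;
          float* dst = col + (size_t)j * oh;
          const int imax = (2 * (oh - 1) + a < H2) ? oh : oh - 1;
          for (int i = 0; i < imax; ++i) dst[i] = (float)src[2 * i + a];
          if (imax < oh) dst[oh - 1] = 0.0f;
        }
      }
  }
}

// Transpose of im2col2_into: scatter-add rows of A into the double cube.
static void col2im2_add(const fmat& A, uword row0, double* xp,
                        int H2, int W2, int C) {
  const int oh = H2 / 2, ow = W2 / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * H2 * W2;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        const float* col = A.colptr(a + 3 * b + 9 * c) + row0;
        for (int j = 0; j < ow; ++j) {
          const int xj = 2 * j + b;
          if (xj >= W2) continue;
          double* dst = xc + (size_t)xj * H2;
          const float* src = col + (size_t)j * oh;
          const int imax = (2 * (oh - 1) + a < H2) ? oh : oh - 1;
          for (int i = 0; i < imax; ++i) dst[2 * i + a] += src[i];
        }
      }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) Rcpp::stop("expected a 4-d (H, W, C, N) array");
  return d;
}

static fmat to_f(const NumericMatrix& w) {
  fmat Wf(w.nrow(), w.ncol());
  std::transform(w.begin(), w.end(), Wf.begin(),
                 [](double v) { return (float)v; });
  return Wf;
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                       bool relu = false) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H / 2, ow = W / 2, Cout = w.ncol();
  const size_t M = (size_t)oh * ow;
  if (w.nrow() != 9 * C) Rcpp::stop("weight rows must equal 9*Cin");
  fmat Wf = to_f(w);
  fmat A(M * N, 9 * C);
  for (int s = 0; s < N; ++s)
    im2col2_into(&x[0] + (size_t)s * H * W * C, H, W, C, A, M * s);
  fmat Y = A * Wf;
  NumericVector y(R_xlen_t(M) * Cout * N);
  y.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < Cout; ++c) {
      const float* src = Y.colptr(c) + M * s;
      double* dst = &y[0] + ((size_t)s * Cout + c) * M;
      const double bc = b[c];
      if (relu)
        for (size_t i = 0; i < M; ++i) dst[i] = std::max(0.0, src[i] + bc);
      else
        for (size_t i = 0; i < M; ++i) dst[i] = src[i] + bc;
    }
  return y;
}

// Pack dy (optionally masked by act > 0) into a float matrix whose rows
// enumerate positions of the (oh, ow) grid, stacked over the batch.
static void pack_dy(const double* dy, const double* act, int per_sample,
                    size_t M, int Cout, int N, fmat& dY) {
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < Cout; ++c) {
      const double* src = dy + (size_t)s * per_sample + (size_t)c * M;
      float* dst = dY.colptr(c) + M * s;
      if (act) {
        const double* mk = act + (size_t)s * per_sample + (size_t)c * M;
        for (size_t i = 0; i < M; ++i)
          dst[i] = mk[i] > 0.0 ? (float)src[i] : 0.0f;
      } else {
        for (size_t i = 0; i < M; ++i) dst[i] = (float)src[i];
      }
    }
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
              Rcpp::Nullable<NumericVector> act = R_NilValue) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H / 2, ow = W / 2, Cout = w.ncol();
  const size_t M = (size_t)oh * ow;
  fmat Wf = to_f(w);
  fmat A(M * N, 9 * C), dY(M * N, Cout);
  for (int s = 0; s < N; ++s)
    im2col2_into(&x[0] + (size_t)s * H * W * C, H, W, C, A, M * s);
  const double* ap = act.isNotNull() ? &NumericVector(act)[0] : nullptr;
  pack_dy(&dy[0], ap, M * Cout, M, Cout, N, dY);
  fmat dW = A.t() * dY;
  frowvec db = sum(dY, 0);
  fmat dA = dY * Wf.t();
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  for (int s = 0; s < N; ++s)
    col2im2_add(dA, M * s, &dx[0] + (size_t)s * H * W * C, H, W, C);
  return List::create(Rcpp::Named("dx") = dx,
                      Rcpp::Named("dw") = Rcpp::wrap(conv_to<mat>::from(dW)),
                      Rcpp::Named("db") = Rcpp::wrap(conv_to<vec>::from(db.t())));
}

// [[Rcpp::export(name = ".convt_fwd")]]
NumericVector convt_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                        bool relu = false) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (w.nrow() != C) Rcpp::stop("weight rows must equal Cin");
  const int Cout = w.ncol() / 9;
  const int oh = 2 * H, ow = 2 * W;
  const size_t M = (size_t)H * W;
  fmat Wf = to_f(w);
  fmat X(M * N, C);
  pack_dy(&x[0], nullptr, M * C, M, C, N, X);
  fmat B = X * Wf;                                 // (M*N) x (9*Cout)
  NumericVector y(R_xlen_t(oh) * ow * Cout * N);
  y.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  for (int s = 0; s < N; ++s) {
    double* yp = &y[0] + (size_t)s * oh * ow * Cout;
    col2im2_add(B, M * s, yp, oh, ow, Cout);
    for (int c = 0; c < Cout; ++c) {
      double* dst = yp + (size_t)c * oh * ow;
      const double bc = b[c];
      if (relu)
        for (size_t i = 0; i < (size_t)oh * ow; ++i)
          dst[i] = std::max(0.0, dst[i] + bc);
      else
        for (size_t i = 0; i < (size_t)oh * ow; ++i) dst[i] += bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".convt_bwd")]]
List convt_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
               Rcpp::Nullable<NumericVector> act = R_NilValue) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol() / 9;
  const int oh = 2 * H, ow = 2 * W;
  const size_t M = (size_t)H * W;
  fmat Wf = to_f(w);
  fmat X(M * N, C), G(M * N, 9 * Cout);
  vec db(Cout, fill::zeros);
  pack_dy(&x[0], nullptr, M * C, M, C, N, X);
  const double* ap = act.isNotNull() ? &NumericVector(act)[0] : nullptr;
  std::vector<double> dym;                 // masked copy when act is given
  const double* dybase = &dy[0];
  if (ap) {
    dym.resize(dy.size());
    for (R_xlen_t i = 0; i < dy.size(); ++i)
      dym[i] = ap[i] > 0.0 ? dy[i] : 0.0;
    dybase = dym.data();
  }
  for (int s = 0; s < N; ++s) {
    const double* dyp = dybase + (size_t)s * oh * ow * Cout;
    im2col2_into(dyp, oh, ow, Cout, G, M * s);
    for (int c = 0; c < Cout; ++c) {
      const double* p = dyp + (size_t)c * oh * ow;
      double acc = 0.0;
      for (size_t i = 0; i < (size_t)oh * ow; ++i) acc += p[i];
      db[c] += acc;
    }
  }
  fmat dW = X.t() * G;
  fmat dX = G * Wf.t();                            // (M*N) x C
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < C; ++c) {
      const float* src = dX.colptr(c) + M * s;
      double* dst = &dx[0] + ((size_t)s * C + c) * M;
      for (size_t i = 0; i < M; ++i) dst[i] = src[i];
    }
  return List::create(Rcpp::Named("dx") = dx,
                      Rcpp::Named("dw") = Rcpp::wrap(conv_to<mat>::from(dW)),
                      Rcpp::Named("db") = Rcpp::wrap(db));
}

// One Adam step over a whole parameter list, in double precision. `m` and
// `v` are moment buffers owned by the optimiser state (allocated in
// adam_init) and updated in place; updated parameters are returned as fresh
// arrays.
// [[Rcpp::export(name = ".adam_update")]]
List adam_update(List params, List grads, List m, List v, int t,
                 double lr, double beta1, double beta2, double eps) {
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  List out(params.size());
  for (int k = 0; k < params.size(); ++k) {
    NumericVector p = params[k], g = grads[k], mk = m[k], vk = v[k];
    const R_xlen_t n = p.size();
    if (g.size() != n || mk.size() != n || vk.size() != n)
      Rcpp::stop("parameter/gradient size mismatch at slot %d", k + 1);
    NumericVector pn(n);
    pn.attr("dim") = p.attr("dim");
    double* pp = &p[0]; double* gp = &g[0];
    double* mp = &mk[0]; double* vp = &vk[0]; double* op = &pn[0];
    for (R_xlen_t i = 0; i < n; ++i) {
      mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
      vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
      op[i] = pp[i] - lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
    }
    out[k] = pn;
  }
  out.names() = params.names();
  return out;
}

// ---------------------------------------------------------------------------
// Fused whole-network training step for the convolutional autoencoder.
// Runs the full forward and backward pass in single precision with im2col
// buffers shared between the two passes; the slower layer-by-layer R path
// (cae_forward/cae_backward) computes the same quantities and serves as the
// reference implementation in the tests.

static void fim2col(const float* xp, int H2, int W2, int C,
                    fmat& A, uword row0) {
  const int oh = H2 / 2, ow = W2 / 2;
  for (int c = 0; c < C; ++c) {
    const float* xc = xp + (size_t)c * H2 * W2;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        float* col = A.colptr(a + 3 * b + 9 * c) + row0;
        for (int j = 0; j < ow; ++j) {
          const int xj = 2 * j + b;
          if (xj >= W2) { for (int i = 0; i < oh; ++i) col[i + j * oh] = 0.0f; continue; }
          const float* src = xc + (size_t)xj * H2;
          float* dst = col + (size_t)j * oh;
          const int imax = (2 * (oh - 1) + a < H2) ? oh : oh - 1;
          for (int i = 0; i < imax; ++i) dst[i] = src[2 * i + a];
          if (imax < oh) dst[oh - 1] = 0.0f;
        }
      }
  }
}

static void fcol2im_add(const fmat& A, uword row0, float* xp,
                        int H2, int W2, int C) {
  const int oh = H2 / 2, ow = W2 / 2;
  for (int c = 0; c < C; ++c) {
    float* xc = xp + (size_t)c * H2 * W2;
    for (int b = 0; b < 3; ++b)
      for (int a = 0; a < 3; ++a) {
        const float* col = A.colptr(a + 3 * b + 9 * c) + row0;
        for (int j = 0; j < ow; ++j) {
          const int xj = 2 * j + b;
          if (xj >= W2) continue;
          float* dst = xc + (size_t)xj * H2;
          const float* src = col + (size_t)j * oh;
          const int imax = (2 * (oh - 1) + a < H2) ? oh : oh - 1;
          for (int i = 0; i < imax; ++i) dst[2 * i + a] += src[i];
        }
      }
  }
}

// Stage geometry: input side, in/out channels per stage.
static const int ENC_H[5] = {128, 64, 32, 16, 8};
static const int ENC_CI[5] = {1, 16, 32, 64, 128};
static const int ENC_CO[5] = {16, 32, 64, 128, 128};
static const int DEC_H[5] = {4, 8, 16, 32, 64};
static const int DEC_CI[5] = {128, 128, 64, 32, 16};
static const int DEC_CO[5] = {128, 64, 32, 16, 1};

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat f(m.nrow(), m.ncol());
  std::transform(m.begin(), m.end(), f.begin(),
                 [](double v) { return (float)v; });
  return f;
}
static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec f(v.size());
  std::transform(v.begin(), v.end(), f.begin(),
                 [](double v_) { return (float)v_; });
  return f;
}
static SEXP mat_to_r(const fmat& f) {
  NumericMatrix m(f.n_rows, f.n_cols);
  std::transform(f.begin(), f.end(), m.begin(),
                 [](float v) { return (double)v; });
  return m;
}
static SEXP vec_to_r(const fvec& f) {
  NumericVector v(f.size());
  std::transform(f.begin(), f.end(), v.begin(),
                 [](float x) { return (double)x; });
  return v;
}

// Encoder forward over a float batch stored sample-major (H, W, C, N).
// acts[l] receives the rectified activation of stage l; As[l] the im2col
// matrix of its input (kept for the backward pass when keep_cols is true).
static void enc_forward(const std::vector<fmat>& Wf, const std::vector<fvec>& bf,
                        const fvec& x, int N, std::vector<fvec>& acts,
                        std::vector<fmat>& As, bool keep_cols) {
  const float* in = x.memptr();
  for (int l = 0; l < 5; ++l) {
    const int H = ENC_H[l], C = ENC_CI[l], Co = ENC_CO[l];
    const int oh = H / 2;
    const size_t M = (size_t)oh * oh;
    fmat A(M * N, 9 * C);
    for (int s = 0; s < N; ++s)
      fim2col(in + (size_t)s * H * H * C, H, H, C, A, M * s);
    fmat Y = A * Wf[l];
    acts[l].set_size(M * Co * N);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < Co; ++c) {
        const float* src = Y.colptr(c) + M * s;
        float* dst = acts[l].memptr() + ((size_t)s * Co + c) * M;
        const float bc = bf[l][c];
        for (size_t i = 0; i < M; ++i) dst[i] = std::max(0.0f, src[i] + bc);
      }
    if (keep_cols) As[l] = std::move(A);
    in = acts[l].memptr();
  }
}

// [[Rcpp::export(name = ".cae_step")]]
List cae_step(List params, NumericVector x) {
  IntegerVector d = dims4(x);
  const int N = d[3];
  if (d[0] != 128 || d[1] != 128 || d[2] != 1)
    Rcpp::stop("expected 128x128x1 input images");
  // weights, float copies
  std::vector<fmat> eW(5), dW(5);
  std::vector<fvec> eB(5), dB(5);
  for (int l = 0; l < 5; ++l) {
    eW[l] = as_fmat(params[2 * l]);     eB[l] = as_fvec(params[2 * l + 1]);
    dW[l] = as_fmat(params[12 + 2 * l]); dB[l] = as_fvec(params[13 + 2 * l]);
  }
  fmat Dw = as_fmat(params[10]);
  fvec Db = as_fvec(params[11]);

  fvec xf(x.size());
  std::transform(x.begin(), x.end(), xf.begin(),
                 [](double v) { return (float)v; });

  std::vector<fvec> eacts(5);
  std::vector<fmat> eAs(5);
  enc_forward(eW, eB, xf, N, eacts, eAs, true);

  // dense 2048 -> 2048 with ReLU; latent is enc stage 5 flattened
  fmat latent(eacts[4].memptr(), 2048, N, false, true);
  fmat D = Dw * latent;
  D.each_col() += Db;
  D.transform([](float v) { return std::max(0.0f, v); });

  // decoder transposed convolutions
  std::vector<fvec> dacts(6);
  dacts[0] = fvec(D.memptr(), (size_t)2048 * N);   // copy, sample-major
  for (int l = 0; l < 5; ++l) {
    const int H = DEC_H[l], C = DEC_CI[l], Co = DEC_CO[l];
    const int oh = 2 * H;
    const size_t M = (size_t)H * H;
    fmat Xm(M * N, C);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < C; ++c)
        std::copy(dacts[l].memptr() + ((size_t)s * C + c) * M,
                  dacts[l].memptr() + ((size_t)s * C + c + 1) * M,
                  Xm.colptr(c) + M * s);
    fmat B = Xm * dW[l];
    dacts[l + 1] = fvec((size_t)oh * oh * Co * N, fill::zeros);
    for (int s = 0; s < N; ++s) {
      float* yp = dacts[l + 1].memptr() + (size_t)s * oh * oh * Co;
      fcol2im_add(B, M * s, yp, oh, oh, Co);
      for (int c = 0; c < Co; ++c) {
        float* dst = yp + (size_t)c * oh * oh;
        const float bc = dB[l][c];
        if (l < 4)
          for (size_t i = 0; i < (size_t)oh * oh; ++i)
            dst[i] = std::max(0.0f, dst[i] + bc);
        else
          for (size_t i = 0; i < (size_t)oh * oh; ++i)
            dst[i] = 1.0f / (1.0f + std::exp(-(dst[i] + bc)));
      }
    }
  }
  fvec& xhat = dacts[5];

  // mean squared reconstruction error and its gradient
  double loss = 0.0;
  fvec dout(xhat.size());
  const double scale = 2.0 / (double)xhat.size();
  for (size_t i = 0; i < xhat.size(); ++i) {
    const float e = xhat[i] - xf[i];
    loss += (double)e * e;
    dout[i] = (float)(scale * e) * xhat[i] * (1.0f - xhat[i]); // sigmoid
  }
  loss /= (double)xhat.size();

  List grads(22);
  // decoder backward
  fvec da = std::move(dout);
  for (int l = 4; l >= 0; --l) {
    const int H = DEC_H[l], C = DEC_CI[l], Co = DEC_CO[l];
    const int oh = 2 * H;
    const size_t M = (size_t)H * H;
    if (l < 4) {                          // ReLU mask of this stage's output
      const fvec& act = dacts[l + 1];
      for (size_t i = 0; i < da.size(); ++i)
        if (act[i] <= 0.0f) da[i] = 0.0f;
    }
    fmat G(M * N, 9 * Co);
    fvec dbv(Co, fill::zeros);
    for (int s = 0; s < N; ++s) {
      const float* dyp = da.memptr() + (size_t)s * oh * oh * Co;
      fim2col(dyp, oh, oh, Co, G, M * s);
      for (int c = 0; c < Co; ++c) {
        const float* p = dyp + (size_t)c * oh * oh;
        float acc = 0.0f;
        for (size_t i = 0; i < (size_t)oh * oh; ++i) acc += p[i];
        dbv[c] += acc;
      }
    }
    fmat Xm(M * N, C);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < C; ++c)
        std::copy(dacts[l].memptr() + ((size_t)s * C + c) * M,
                  dacts[l].memptr() + ((size_t)s * C + c + 1) * M,
                  Xm.colptr(c) + M * s);
    fmat dWl = Xm.t() * G;
    fmat dXm = G * dW[l].t();
    grads[12 + 2 * l] = mat_to_r(dWl);
    grads[13 + 2 * l] = vec_to_r(dbv);
    fvec dprev((size_t)H * H * C * N);
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < C; ++c)
        std::copy(dXm.colptr(c) + M * s, dXm.colptr(c) + M * (s + 1),
                  dprev.memptr() + ((size_t)s * C + c) * M);
    da = std::move(dprev);
  }

  // dense backward (ReLU mask from D, which aliases dacts[0])
  fmat dd(da.memptr(), 2048, N, false, true);
  {
    const float* dact = dacts[0].memptr();
    float* p = dd.memptr();
    for (size_t i = 0; i < (size_t)2048 * N; ++i)
      if (dact[i] <= 0.0f) p[i] = 0.0f;
  }
  fmat dDw = dd * latent.t();
  fvec dDb = sum(dd, 1);
  grads[10] = mat_to_r(dDw);
  grads[11] = vec_to_r(dDb);
  fmat dlat = Dw.t() * dd;                // 2048 x N
  fvec denc(dlat.memptr(), (size_t)2048 * N);

  // encoder backward
  da = std::move(denc);
  for (int l = 4; l >= 0; --l) {
    const int H = ENC_H[l], C = ENC_CI[l], Co = ENC_CO[l];
    const int oh = H / 2;
    const size_t M = (size_t)oh * oh;
    fmat dY(M * N, Co);
    const fvec& act = eacts[l];
    for (int s = 0; s < N; ++s)
      for (int c = 0; c < Co; ++c) {
        const float* src = da.memptr() + ((size_t)s * Co + c) * M;
        const float* mk = act.memptr() + ((size_t)s * Co + c) * M;
        float* dst = dY.colptr(c) + M * s;
        for (size_t i = 0; i < M; ++i) dst[i] = mk[i] > 0.0f ? src[i] : 0.0f;
      }
    fmat dWl = eAs[l].t() * dY;
    frowvec dbv = sum(dY, 0);
    grads[2 * l] = mat_to_r(dWl);
    grads[2 * l + 1] = vec_to_r(fvec(dbv.t()));
    if (l > 0) {
      fmat dA = dY * eW[l].t();
      fvec dprev((size_t)H * H * C * N, fill::zeros);
      for (int s = 0; s < N; ++s)
        fcol2im_add(dA, M * s, dprev.memptr() + (size_t)s * H * H * C, H, H, C);
      da = std::move(dprev);
    }
  }

  grads.names() = params.names();
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = grads);
}

// Encoder-only forward pass: images to 2048-dim latent columns.
// [[Rcpp::export(name = ".cae_encode")]]
NumericMatrix cae_encode(List params, NumericVector x) {
  IntegerVector d = dims4(x);
  const int N = d[3];
  std::vector<fmat> eW(5);
  std::vector<fvec> eB(5);
  for (int l = 0; l < 5; ++l) {
    eW[l] = as_fmat(params[2 * l]);
    eB[l] = as_fvec(params[2 * l + 1]);
  }
  fvec xf(x.size());
  std::transform(x.begin(), x.end(), xf.begin(),
                 [](double v) { return (float)v; });
  std::vector<fvec> acts(5);
  std::vector<fmat> As(5);
  enc_forward(eW, eB, xf, N, acts, As, false);
  NumericMatrix out(2048, N);
  std::transform(acts[4].begin(), acts[4].end(), out.begin(),
                 [](float v) { return (double)v; });
  return out;
}
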