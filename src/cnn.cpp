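// 3D convolutional engine for SRNet/MRNet.
//
// Layout conventions:
//  * an activation is an arma::mat with channels in rows and one column per
//    (patch, voxel) pair; the column index of voxel v of patch p is p*V + v,
//    with v = x + d1*(y + d2*z) (column-major voxel order, 0-based);
//  * a conv weight is (c_out x KK*c_in) where KK is the kernel volume and the
//    column index of kernel offset o, input channel j is o*c_in + j;
//  * the fully-connected head is (2 x K*c_last): logit row 0 = negative class,
//    row 1 = positive class (the Progressive Index).
//
// All matrix products use hand-rolled kernels (no BLAS) so results are
// bit-identical regardless of BLAS backend or thread count.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::umat;
using arma::uword;

// ---------------------------------------------------------------- kernels --

// C = A * B (A: m x k, B: k x n); C is resized and zeroed.
static void gemm_nn(const mat& A, const mat& B, mat& C) {
  const uword m = A.n_rows, k = A.n_cols, n = B.n_cols;
  C.zeros(m, n);
  for (uword j = 0; j < n; ++j) {
    double* cj = C.colptr(j);
    const double* bj = B.colptr(j);
    for (uword l = 0; l < k; ++l) {
      const double b = bj[l];
      if (b == 0.0) continue;   // zero-padded columns are common
      const double* al = A.colptr(l);
      for (uword i = 0; i < m; ++i) cj[i] += al[i] * b;
    }
  }
}

// C += A * B^T (A: m x N, B: p x N, C: m x p).
static void gemm_nt_acc(const mat& A, const mat& B, mat& C) {
  const uword m = A.n_rows, N = A.n_cols, p = B.n_rows;
  for (uword v = 0; v < N; ++v) {
    const double* av = A.colptr(v);
    const double* bv = B.colptr(v);
    for (uword j = 0; j < p; ++j) {
      const double b = bv[j];
      if (b == 0.0) continue;
      double* cj = C.colptr(j);
      for (uword i = 0; i < m; ++i) cj[i] += av[i] * b;
    }
  }
}

// ---------------------------------------------------------------- geometry --

struct Geom {
  int nlayer;
  int KK;                                   // kernel volume
  std::vector<std::array<int, 3>> dims;     // conv-input dims per layer
  std::vector<int> V;                       // voxels per layer input
  std::vector<std::vector<int>> nbr;        // V[l]*KK source voxel ids, -1 pad
};

static std::vector<int> make_nbr(const std::array<int, 3>& d,
                                 const std::array<int, 3>& kern) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int h1 = kern[0] / 2, h2 = kern[1] / 2, h3 = kern[2] / 2;
  const int KK = kern[0] * kern[1] * kern[2];
  std::vector<int> nbr((size_t)d1 * d2 * d3 * KK);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        const int v = x + d1 * (y + d2 * z);
        int o = 0;
        for (int oz = -h3; oz <= h3; ++oz)
          for (int oy = -h2; oy <= h2; ++oy)
            for (int ox = -h1; ox <= h1; ++ox, ++o) {
              const int xs = x + ox, ys = y + oy, zs = z + oz;
              nbr[(size_t)v * KK + o] =
                  (xs < 0 || ys < 0 || zs < 0 || xs >= d1 || ys >= d2 || zs >= d3)
                      ? -1
                      : xs + d1 * (ys + d2 * zs);
            }
      }
  return nbr;
}

static Geom make_geom(const IntegerVector& dims0, int nlayer,
                      const std::array<int, 3>& kern) {
  Geom g;
  g.nlayer = nlayer;
  g.KK = kern[0] * kern[1] * kern[2];
  std::array<int, 3> d = {dims0[0], dims0[1], dims0[2]};
  for (int l = 0; l < nlayer; ++l) {
    g.dims.push_back(d);
    g.V.push_back(d[0] * d[1] * d[2]);
    g.nbr.push_back(make_nbr(d, kern));
    if (l < nlayer - 1) {
      if (d[0] % 2 || d[1] % 2 || d[2] % 2)
        stop("patch dimensions do not survive the pooling schedule");
      d = {d[0] / 2, d[1] / 2, d[2] / 2};
    }
  }
  return g;
}

// ------------------------------------------------------------- primitives --

static void im2col(const mat& A, mat& Col, const std::vector<int>& nbr,
                   int V, int P, int cin, int KK) {
  Col.set_size((uword)KK * cin, (uword)P * V);
  for (int p = 0; p < P; ++p) {
    const uword base = (uword)p * V;
    for (int v = 0; v < V; ++v) {
      double* cptr = Col.colptr(base + v);
      const size_t nb = (size_t)v * KK;
      for (int o = 0; o < KK; ++o) {
        const int s = nbr[nb + o];
        double* dst = cptr + (size_t)o * cin;
        if (s < 0) {
          std::memset(dst, 0, sizeof(double) * cin);
        } else {
          const double* src = A.colptr(base + s);
          std::memcpy(dst, src, sizeof(double) * cin);
        }
      }
    }
  }
}

static void col2im_acc(mat& dA, const mat& dCol, const std::vector<int>& nbr,
                       int V, int P, int cin, int KK) {
  dA.zeros(cin, (uword)P * V);
  for (int p = 0; p < P; ++p) {
    const uword base = (uword)p * V;
    for (int v = 0; v < V; ++v) {
      const double* cptr = dCol.colptr(base + v);
      const size_t nb = (size_t)v * KK;
      for (int o = 0; o < KK; ++o) {
        const int s = nbr[nb + o];
        if (s < 0) continue;
        double* aptr = dA.colptr(base + s);
        const double* src = cptr + (size_t)o * cin;
        for (int j = 0; j < cin; ++j) aptr[j] += src[j];
      }
    }
  }
}

// 2x2x2 max pool, stride 2; Arg records the source column per (row, out col).
static void maxpool(const mat& A, mat& Out, umat& Arg,
                    const std::array<int, 3>& d, int P) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  const int V = d1 * d2 * d3, Vo = e1 * e2 * e3;
  const uword c = A.n_rows;
  Out.set_size(c, (uword)P * Vo);
  Arg.set_size(c, (uword)P * Vo);
  for (int p = 0; p < P; ++p) {
    for (int z = 0; z < e3; ++z)
      for (int y = 0; y < e2; ++y)
        for (int x = 0; x < e1; ++x) {
          const uword ocol = (uword)p * Vo + (x + e1 * (y + e2 * z));
          double* optr = Out.colptr(ocol);
          uword* gptr = Arg.colptr(ocol);
          bool first = true;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int vi =
                    (2 * x + dx) + d1 * ((2 * y + dy) + d2 * (2 * z + dz));
                const uword icol = (uword)p * V + vi;
                const double* iptr = A.colptr(icol);
                if (first) {
                  for (uword j = 0; j < c; ++j) { optr[j] = iptr[j]; gptr[j] = icol; }
                  first = false;
                } else {
                  for (uword j = 0; j < c; ++j)
                    if (iptr[j] > optr[j]) { optr[j] = iptr[j]; gptr[j] = icol; }
                }
              }
        }
  }
}

struct Cache {
  std::vector<mat> col;   // im2col input per layer
  std::vector<mat> act;   // post-ReLU, pre-pool activation per layer
  std::vector<umat> arg;  // pool argmax per pooled layer
};

// Forward the backbone over P patches; X is (V0 x P). Returns (c_last x P).
static mat forward_backbone(const std::vector<mat>& W, const std::vector<vec>& b,
                            const mat& X, int P, const Geom& g, Cache* cache) {
  mat A(const_cast<double*>(X.memptr()), 1, (uword)P * g.V[0], false, true);
  mat cur;  // owns the running activation after layer 1
  if (cache) {
    cache->col.resize(g.nlayer);
    cache->act.resize(g.nlayer);
    cache->arg.resize(g.nlayer - 1);
  }
  mat colbuf;
  for (int l = 0; l < g.nlayer; ++l) {
    const int cin = (int)W[l].n_cols / g.KK;
    const mat& Ain = (l == 0) ? A : cur;
    im2col(Ain, colbuf, g.nbr[l], g.V[l], P, cin, g.KK);
    mat Z;
    gemm_nn(W[l], colbuf, Z);
    Z.each_col() += b[l];
    // ReLU in place
    double* zp = Z.memptr();
    const size_t nz = Z.n_elem;
    for (size_t i = 0; i < nz; ++i)
      if (zp[i] < 0) zp[i] = 0;
    if (cache) { cache->col[l] = std::move(colbuf); colbuf.reset(); }
    if (l < g.nlayer - 1) {
      mat pooled;
      umat arg;
      maxpool(Z, pooled, arg, g.dims[l], P);
      if (cache) { cache->act[l] = std::move(Z); cache->arg[l] = std::move(arg); }
      cur = std::move(pooled);
    } else {
      if (cache) cache->act[l] = Z;  // keep a copy; Z also feeds the GAP
      cur = std::move(Z);
    }
  }
  // global average pool over the surviving voxels of the last layer
  const int VL = g.V[g.nlayer - 1];
  const uword cL = cur.n_rows;
  mat F(cL, P);
  for (int p = 0; p < P; ++p) {
    vec acc(cL, arma::fill::zeros);
    for (int v = 0; v < VL; ++v) acc += cur.col((uword)p * VL + v);
    F.col(p) = acc / VL;
  }
  return F;
}

// Backward through the backbone; dF is (c_last x P). Accumulates dW/db.
static void backward_backbone(const std::vector<mat>& W, const Geom& g,
                              const Cache& cache, const mat& dF, int P,
                              std::vector<mat>& dW, std::vector<vec>& db) {
  const int L = g.nlayer;
  const int VL = g.V[L - 1];
  const uword cL = dF.n_rows;
  // spread GAP gradient
  mat dAct(cL, (uword)P * VL);
  for (int p = 0; p < P; ++p) {
    const vec gcol = dF.col(p) / VL;
    for (int v = 0; v < VL; ++v) dAct.col((uword)p * VL + v) = gcol;
  }
  for (int l = L - 1; l >= 0; --l) {
    // ReLU mask
    const mat& actl = cache.act[l];
    mat dZ = dAct;
    {
      double* dzp = dZ.memptr();
      const double* ap = actl.memptr();
      const size_t n = dZ.n_elem;
      for (size_t i = 0; i < n; ++i)
        if (ap[i] <= 0) dzp[i] = 0;
    }
    gemm_nt_acc(dZ, cache.col[l], dW[l]);
    db[l] += arma::sum(dZ, 1);
    if (l == 0) break;
    const mat Wt = W[l].t();
    mat dCol;
    gemm_nn(Wt, dZ, dCol);
    const int cin = (int)W[l].n_cols / g.KK;
    mat dPool;
    col2im_acc(dPool, dCol, g.nbr[l], g.V[l], P, cin, g.KK);
    // un-pool to the previous layer's pre-pool activation
    const uword cprev = dPool.n_rows;
    dAct.zeros(cprev, (uword)P * g.V[l - 1]);
    const umat& arg = cache.arg[l - 1];
    for (uword ocol = 0; ocol < dPool.n_cols; ++ocol) {
      const double* dp = dPool.colptr(ocol);
      const uword* gp = arg.colptr(ocol);
      for (uword i = 0; i < cprev; ++i) dAct(i, gp[i]) += dp[i];
    }
  }
}

// Column-wise softmax of a 2 x n logit matrix.
static mat softmax2(const mat& logits) {
  mat p(2, logits.n_cols);
  for (uword j = 0; j < logits.n_cols; ++j) {
    const double a = logits(0, j), b = logits(1, j);
    const double m = a > b ? a : b;
    const double ea = std::exp(a - m), eb = std::exp(b - m);
    const double s = ea + eb;
    p(0, j) = ea / s;
    p(1, j) = eb / s;
  }
  return p;
}

static double mean_ce(const mat& prob, const IntegerVector& y,
                      const std::vector<int>& idx, double clip_eps) {
  double s = 0;
  for (size_t i = 0; i < idx.size(); ++i) {
    double p = prob(1, i);
    if (p < clip_eps) p = clip_eps;
    if (p > 1 - clip_eps) p = 1 - clip_eps;
    s += (y[idx[i]] == 1) ? -std::log(p) : -std::log(1 - p);
  }
  return s / idx.size();
}

static void unpack_params(const List& conv_w, const List& conv_b,
                          std::vector<mat>& W, std::vector<vec>& b) {
  const int L = conv_w.size();
  W.resize(L);
  b.resize(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<mat>(conv_w[l]);
    b[l] = as<vec>(conv_b[l]);
  }
}

// Gather the columns of X belonging to the given subjects (K patches each).
static mat gather_subjects(const mat& X, const std::vector<int>& subj, int K) {
  mat out(X.n_rows, (uword)subj.size() * K);
  for (size_t i = 0; i < subj.size(); ++i)
    for (int k = 0; k < K; ++k)
      out.col(i * K + k) = X.col((uword)subj[i] * K + k);
  return out;
}

// Forward a whole cohort in chunks; returns class probabilities (n x 2) and,
// optionally, the concatenated features (n x K*c_last).
static List forward_all(const std::vector<mat>& W, const std::vector<vec>& b,
                        const mat& fc_w, const vec& fc_b, const mat& X, int K,
                        const Geom& g, bool return_features, int chunk) {
  const int n = X.n_cols / K;
  const uword cL = W.back().n_rows;
  mat prob(n, 2);
  mat feat;
  if (return_features) feat.set_size(n, (uword)K * cL);
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int B = std::min(chunk, n - s0);
    std::vector<int> subj(B);
    for (int i = 0; i < B; ++i) subj[i] = s0 + i;
    mat Xb = gather_subjects(X, subj, K);
    mat F = forward_backbone(W, b, Xb, B * K, g, nullptr);
    mat Fc(F.memptr(), cL * K, B, false, true);
    mat logits;
    gemm_nn(fc_w, Fc, logits);
    logits.each_col() += fc_b;
    mat p = softmax2(logits);
    for (int i = 0; i < B; ++i) {
      prob(s0 + i, 0) = p(0, i);
      prob(s0 + i, 1) = p(1, i);
    }
    if (return_features)
      for (int i = 0; i < B; ++i) feat.row(s0 + i) = Fc.col(i).t();
  }
  return List::create(_["prob"] = prob, _["features"] = feat);
}

// ---------------------------------------------------------------- exports --

// [[Rcpp::export]]
List cpp_cnn_forward(List conv_w, List conv_b, arma::mat fc_w, arma::vec fc_b,
                     const arma::mat& X, IntegerVector dims0, int K,
                     IntegerVector kernel, bool return_features = false,
                     int chunk_subjects = 32) {
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(conv_w, conv_b, W, b);
  std::array<int, 3> kern = {kernel[0], kernel[1], kernel[2]};
  Geom g = make_geom(dims0, (int)W.size(), kern);
  return forward_all(W, b, fc_w, fc_b, X, K, g, return_features, chunk_subjects);
}

// [[Rcpp::export]]
arma::mat cpp_backbone_features(List conv_w, List conv_b, const arma::mat& X,
                                IntegerVector dims0, IntegerVector kernel,
                                int chunk_patches = 64) {
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(conv_w, conv_b, W, b);
  std::array<int, 3> kern = {kernel[0], kernel[1], kernel[2]};
  Geom g = make_geom(dims0, (int)W.size(), kern);
  const int P = X.n_cols;
  const uword cL = W.back().n_rows;
  mat out(P, cL);
  for (int p0 = 0; p0 < P; p0 += chunk_patches) {
    const int B = std::min(chunk_patches, P - p0);
    mat F = forward_backbone(W, b, X.cols(p0, p0 + B - 1), B, g, nullptr);
    out.rows(p0, p0 + B - 1) = F.t();
  }
  return out;
}

// Mean cross-entropy loss and its analytic gradients on a full batch
// (used to verify backpropagation against finite differences).
// [[Rcpp::export]]
List cpp_cnn_loss_grad(List conv_w, List conv_b, arma::mat fc_w, arma::vec fc_b,
                       const arma::mat& X, IntegerVector y, IntegerVector dims0,
                       int K, IntegerVector kernel, double clip_eps) {
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(conv_w, conv_b, W, b);
  std::array<int, 3> kern = {kernel[0], kernel[1], kernel[2]};
  const int L = (int)W.size();
  Geom g = make_geom(dims0, L, kern);
  const int n = X.n_cols / K;
  const uword cL = W.back().n_rows;

  Cache cache;
  mat F = forward_backbone(W, b, X, n * K, g, &cache);
  mat Fc(F.memptr(), cL * K, n, false, true);
  mat logits;
  gemm_nn(fc_w, Fc, logits);
  logits.each_col() += fc_b;
  mat p = softmax2(logits);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  const double loss = mean_ce(p, y, idx, clip_eps);

  mat dlogits = p;
  for (int i = 0; i < n; ++i) dlogits(y[i] == 1 ? 1 : 0, i) -= 1.0;
  dlogits /= n;
  mat dfw(arma::size(fc_w), arma::fill::zeros);
  gemm_nt_acc(dlogits, Fc, dfw);
  vec dfb = arma::sum(dlogits, 1);
  const mat fcwt = fc_w.t();
  mat dFc;
  gemm_nn(fcwt, dlogits, dFc);
  mat dF(dFc.memptr(), cL, (uword)n * K, false, true);
  std::vector<mat> dW(L);
  std::vector<vec> db(L);
  for (int l = 0; l < L; ++l) {
    dW[l].zeros(arma::size(W[l]));
    db[l].zeros(W[l].n_rows);
  }
  backward_backbone(W, g, cache, dF, n * K, dW, db);
  List out_dw(L), out_db(L);
  for (int l = 0; l < L; ++l) {
    out_dw[l] = dW[l];
    out_db[l] = db[l];
  }
  return List::create(_["loss"] = loss, _["d_conv_w"] = out_dw,
                      _["d_conv_b"] = out_db, _["d_fc_w"] = dfw,
                      _["d_fc_b"] = dfb);
}

// Mini-batch Adam training of backbone + FC head with cross-entropy loss.
// X: (V0 x n*K); y: length n in {0,1}; perm: (n_train x epochs) 1-based
// subject indices giving the (seeded, R-generated) shuffling per epoch.
// [[Rcpp::export]]
List cpp_cnn_train(List conv_w, List conv_b, arma::mat fc_w, arma::vec fc_b,
                   const arma::mat& X, IntegerVector y, IntegerVector dims0,
                   int K, IntegerVector kernel, IntegerMatrix perm,
                   int batch_size, double lr, double beta1, double beta2,
                   double adam_eps, double clip_eps, const arma::mat& Xval,
                   IntegerVector yval) {
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(conv_w, conv_b, W, b);
  std::array<int, 3> kern = {kernel[0], kernel[1], kernel[2]};
  const int L = (int)W.size();
  Geom g = make_geom(dims0, L, kern);
  const int n_train = perm.nrow();
  const int epochs = perm.ncol();
  const uword cL = W.back().n_rows;

  // Adam state
  std::vector<mat> mW(L), vW(L), dW(L);
  std::vector<vec> mb(L), vb(L), db(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(arma::size(W[l]));
    vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(W[l].n_rows);
    vb[l].zeros(W[l].n_rows);
  }
  mat mfw(arma::size(fc_w), arma::fill::zeros), vfw(arma::size(fc_w), arma::fill::zeros);
  vec mfb(2, arma::fill::zeros), vfb(2, arma::fill::zeros);
  long tstep = 0;

  auto adam_step = [&](mat& P_, mat& m_, mat& v_, const mat& g_) {
    m_ = beta1 * m_ + (1 - beta1) * g_;
    v_ = beta2 * v_ + (1 - beta2) * (g_ % g_);
    const double bc1 = 1 - std::pow(beta1, (double)tstep);
    const double bc2 = 1 - std::pow(beta2, (double)tstep);
    P_ -= lr * (m_ / bc1) / (arma::sqrt(v_ / bc2) + adam_eps);
  };
  auto adam_step_v = [&](vec& P_, vec& m_, vec& v_, const vec& g_) {
    m_ = beta1 * m_ + (1 - beta1) * g_;
    v_ = beta2 * v_ + (1 - beta2) * (g_ % g_);
    const double bc1 = 1 - std::pow(beta1, (double)tstep);
    const double bc2 = 1 - std::pow(beta2, (double)tstep);
    P_ -= lr * (m_ / bc1) / (arma::sqrt(v_ / bc2) + adam_eps);
  };

  NumericVector train_loss(epochs), val_loss(epochs);
  const bool has_val = Xval.n_cols > 0;

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0;
    for (int s0 = 0; s0 < n_train; s0 += batch_size) {
      const int B = std::min(batch_size, n_train - s0);
      std::vector<int> subj(B), yb(B);
      for (int i = 0; i < B; ++i) {
        subj[i] = perm(s0 + i, e) - 1;
        yb[i] = subj[i];
      }
      mat Xb = gather_subjects(X, subj, K);
      Cache cache;
      mat F = forward_backbone(W, b, Xb, B * K, g, &cache);
      mat Fc(F.memptr(), cL * K, B, false, true);
      mat logits;
      gemm_nn(fc_w, Fc, logits);
      logits.each_col() += fc_b;
      mat p = softmax2(logits);
      eloss += mean_ce(p, y, yb, clip_eps) * B;

      // gradients
      mat dlogits = p;
      for (int i = 0; i < B; ++i) dlogits(y[subj[i]] == 1 ? 1 : 0, i) -= 1.0;
      dlogits /= B;
      mat dfw(arma::size(fc_w), arma::fill::zeros);
      gemm_nt_acc(dlogits, Fc, dfw);
      vec dfb = arma::sum(dlogits, 1);
      const mat fcwt = fc_w.t();
      mat dFc;
      gemm_nn(fcwt, dlogits, dFc);
      mat dF(dFc.memptr(), cL, (uword)B * K, false, true);
      for (int l = 0; l < L; ++l) {
        dW[l].zeros(arma::size(W[l]));
        db[l].zeros(W[l].n_rows);
      }
      backward_backbone(W, g, cache, dF, B * K, dW, db);

      ++tstep;
      for (int l = 0; l < L; ++l) {
        adam_step(W[l], mW[l], vW[l], dW[l]);
        adam_step_v(b[l], mb[l], vb[l], db[l]);
      }
      adam_step(fc_w, mfw, vfw, dfw);
      adam_step_v(fc_b, mfb, vfb, dfb);
    }
    train_loss[e] = eloss / n_train;
    if (has_val) {
      List fv = forward_all(W, b, fc_w, fc_b, Xval, K, g, false, 32);
      mat pv = as<mat>(fv["prob"]);
      double s = 0;
      for (uword i = 0; i < pv.n_rows; ++i) {
        double p1 = pv(i, 1);
        if (p1 < clip_eps) p1 = clip_eps;
        if (p1 > 1 - clip_eps) p1 = 1 - clip_eps;
        s += (yval[i] == 1) ? -std::log(p1) : -std::log(1 - p1);
      }
      val_loss[e] = s / pv.n_rows;
    } else {
      val_loss[e] = NA_REAL;
    }
  }

  List out_w(L), out_b(L);
  for (int l = 0; l < L; ++l) {
    out_w[l] = W[l];
    out_b[l] = b[l];
  }
  return List::create(_["conv_w"] = out_w, _["conv_b"] = out_b,
                      _["fc_w"] = fc_w, _["fc_b"] = fc_b,
                      _["train_loss"] = train_loss, _["val_loss"] = val_loss);
}
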