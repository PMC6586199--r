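// Dual-path 1D convolutional network over base and codon one-hot encodings.
//
// Each path: conv(64 kernels, length 6, ReLU) -> maxpool(3) ->
// batchnorm+dropout -> conv(128, length 3, ReLU) -> maxpool(3) ->
// batchnorm+dropout -> conv(256, length 3, ReLU) -> global average pooling.
// Head: concatenate -> dense (same width as its input, ReLU) -> softmax(3).
// Trained with Adam on softmax cross-entropy.
//
// Implementation notes:
//  * single precision; feature maps are channel-major (C x batch*time) so
//    every hot operation touches contiguous columns of column-major storage.
//  * convolutions 2 and 3 are im2col + GEMM; convolution 1 exploits the
//    one-hot input: fragments are carried as integer column indices, so conv1
//    is a gather-sum of weight columns and its weight gradient a scatter-add.
//    Ambiguous/padding positions (index -1) contribute nothing, exactly like
//    an all-zero one-hot row.
//  * weight layout (as seen from R): conv weights are kernels x (Cin*klen),
//    i.e. nrow = kernel count; dense Wd is width x width, output Wo is
//    3 x width; biases and batchnorm parameters are column vectors.
//  * batchnorm normalises each channel over (batch x time); inference uses
//    exponential running moments (momentum 0.9). Dropout is inverted.
//  * all randomness (init, shuffling, dropout) comes from one std::mt19937
//    seeded explicitly, so results are reproducible from the seed.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

static const float BN_EPS = 1e-3f;
static const float BN_MOMENTUM = 0.9f;

struct PathDims {
  int T0, T1, T2, T3, T4, T5;
};

static PathDims path_dims(int Lmax) {
  PathDims d;
  d.T0 = 2 * Lmax;     // padded one-hot rows
  d.T1 = d.T0 - 5;     // conv1, kernel 6, valid
  d.T2 = d.T1 / 3;     // maxpool 3
  d.T3 = d.T2 - 2;     // conv2, kernel 3
  d.T4 = d.T3 / 3;     // maxpool 3
  d.T5 = d.T4 - 2;     // conv3, kernel 3
  return d;
}

struct PathW {
  fmat W1; fvec b1, g1, be1, rm1, rv1;   // conv1 (64 x Cin*6) + bn1
  fmat W2; fvec b2, g2, be2, rm2, rv2;   // conv2 (128 x 192) + bn2
  fmat W3; fvec b3;                      // conv3 (256 x 384)
  float cnt1 = 0.0f, cnt2 = 0.0f;        // bn update counts (bias correction)
};

struct HeadW {
  fmat Wd, Wo; fvec bd, bo;
};

struct PathCache {
  fmat A1;            // 64 x (B*T1), post-ReLU
  fmat P1; umat I1;   // 64 x (B*T2) pooled + argmax offsets
  fmat X1h; fvec is1; // bn1 x-hat and 1/sd
  fmat M1;            // dropout mask (0 or 1/keep)
  fmat X2;            // im2col 192 x (B*T3)
  fmat A2;            // 128 x (B*T3), post-ReLU
  fmat P2; umat I2;
  fmat X2h; fvec is2;
  fmat M2;
  fmat X3;            // im2col 384 x (B*T5)
  fmat A3;            // 256 x (B*T5), post-ReLU
  fmat G;             // 256 x B global average
};

// ---- R <-> arma ------------------------------------------------------------

static fmat getf(const List& w, const std::string& name) {
  NumericMatrix m = w[name];
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = (float)m(i, j);
  return out;
}

static fvec getv(const List& w, const std::string& name) {
  fmat m = getf(w, name);
  return fvec(m.col(0));
}

static NumericMatrix putf(const fmat& f) {
  NumericMatrix m(f.n_rows, f.n_cols);
  for (arma::uword j = 0; j < f.n_cols; ++j)
    for (arma::uword i = 0; i < f.n_rows; ++i)
      m(i, j) = (double)f(i, j);
  return m;
}

static NumericMatrix putv(const fvec& v) { return putf(fmat(v)); }

static PathW load_path(const List& w, const std::string& p) {
  PathW pw;
  pw.W1 = getf(w, p + "_W1"); pw.b1 = getv(w, p + "_b1");
  pw.g1 = getv(w, p + "_g1"); pw.be1 = getv(w, p + "_be1");
  pw.rm1 = getv(w, p + "_rm1"); pw.rv1 = getv(w, p + "_rv1");
  pw.W2 = getf(w, p + "_W2"); pw.b2 = getv(w, p + "_b2");
  pw.g2 = getv(w, p + "_g2"); pw.be2 = getv(w, p + "_be2");
  pw.rm2 = getv(w, p + "_rm2"); pw.rv2 = getv(w, p + "_rv2");
  pw.W3 = getf(w, p + "_W3"); pw.b3 = getv(w, p + "_b3");
  pw.cnt1 = (float)getf(w, p + "_cnt1")(0, 0);
  pw.cnt2 = (float)getf(w, p + "_cnt2")(0, 0);
  return pw;
}

static void store_path(List& w, const std::string& p, const PathW& pw) {
  w[p + "_W1"] = putf(pw.W1); w[p + "_b1"] = putv(pw.b1);
  w[p + "_g1"] = putv(pw.g1); w[p + "_be1"] = putv(pw.be1);
  w[p + "_rm1"] = putv(pw.rm1); w[p + "_rv1"] = putv(pw.rv1);
  w[p + "_W2"] = putf(pw.W2); w[p + "_b2"] = putv(pw.b2);
  w[p + "_g2"] = putv(pw.g2); w[p + "_be2"] = putv(pw.be2);
  w[p + "_rm2"] = putv(pw.rm2); w[p + "_rv2"] = putv(pw.rv2);
  w[p + "_W3"] = putf(pw.W3); w[p + "_b3"] = putv(pw.b3);
  w[p + "_cnt1"] = putf(fmat(1, 1, arma::fill::value(pw.cnt1)));
  w[p + "_cnt2"] = putf(fmat(1, 1, arma::fill::value(pw.cnt2)));
}

// ---- init ------------------------------------------------------------------

static fmat glorot(int nr, int nc, std::mt19937& rng) {
  float lim = std::sqrt(6.0f / (float)(nr + nc));
  std::uniform_real_distribution<float> u(-lim, lim);
  fmat m(nr, nc);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = u(rng);
  return m;
}

static PathW init_path(int Cin, std::mt19937& rng) {
  PathW p;
  p.W1 = glorot(64, Cin * 6, rng);
  p.b1.zeros(64); p.g1.ones(64); p.be1.zeros(64);
  p.rm1.zeros(64); p.rv1.zeros(64);
  p.W2 = glorot(128, 64 * 3, rng);
  p.b2.zeros(128); p.g2.ones(128); p.be2.zeros(128);
  p.rm2.zeros(128); p.rv2.zeros(128);
  p.W3 = glorot(256, 128 * 3, rng);
  p.b3.zeros(256);
  return p;
}

// ---- layers ----------------------------------------------------------------

// conv1 gather-sum. idx: T0 x n; cols selects batch members.
static void conv1_forward(const IntegerMatrix& idx, const std::vector<int>& cols,
                          const PathW& w, int Cin, const PathDims& d, fmat& A1) {
  const int B = (int)cols.size();
  A1.set_size(64, (arma::uword)B * d.T1);
  for (int b = 0; b < B; ++b) {
    const int j = cols[b];
    for (int t = 0; t < d.T1; ++t) {
      const arma::uword co = (arma::uword)b * d.T1 + t;
      A1.col(co) = w.b1;
      for (int k = 0; k < 6; ++k) {
        const int id = idx(t + k, j);
        if (id >= 0) A1.col(co) += w.W1.col(id + Cin * k);
      }
    }
  }
  A1.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
}

static void conv1_backward(const IntegerMatrix& idx, const std::vector<int>& cols,
                           int Cin, const PathDims& d, const fmat& dA1,
                           fmat& dW1, fvec& db1) {
  const int B = (int)cols.size();
  dW1.zeros(64, (arma::uword)Cin * 6);
  db1 = arma::sum(dA1, 1);
  for (int b = 0; b < B; ++b) {
    const int j = cols[b];
    for (int t = 0; t < d.T1; ++t) {
      const arma::uword co = (arma::uword)b * d.T1 + t;
      for (int k = 0; k < 6; ++k) {
        const int id = idx(t + k, j);
        if (id >= 0) dW1.col(id + Cin * k) += dA1.col(co);
      }
    }
  }
}

// non-overlapping maxpool of length 3 along time, per sample
static void maxpool3(const fmat& X, int B, int Tin, int Tout, fmat& P, umat& I) {
  const int C = (int)X.n_rows;
  P.set_size(C, (arma::uword)B * Tout);
  I.set_size(C, (arma::uword)B * Tout);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Tout; ++t) {
      const arma::uword c0 = (arma::uword)b * Tin + 3 * t;
      const arma::uword co = (arma::uword)b * Tout + t;
      const float* x0 = X.colptr(c0);
      const float* x1 = X.colptr(c0 + 1);
      const float* x2 = X.colptr(c0 + 2);
      float* p = P.colptr(co);
      arma::uword* ix = I.colptr(co);
      for (int c = 0; c < C; ++c) {
        if (x0[c] >= x1[c] && x0[c] >= x2[c]) { p[c] = x0[c]; ix[c] = 0; }
        else if (x1[c] >= x2[c])              { p[c] = x1[c]; ix[c] = 1; }
        else                                  { p[c] = x2[c]; ix[c] = 2; }
      }
    }
}

// scatter gradient to argmax positions, gated by the (post-ReLU) activation
static void maxpool3_backward(const fmat& dP, const umat& I, int B, int Tin,
                              int Tout, const fmat& Apost, fmat& dX) {
  const int C = (int)dP.n_rows;
  dX.zeros(C, (arma::uword)B * Tin);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < Tout; ++t) {
      const arma::uword c0 = (arma::uword)b * Tin + 3 * t;
      const arma::uword co = (arma::uword)b * Tout + t;
      const float* dp = dP.colptr(co);
      const arma::uword* ix = I.colptr(co);
      for (int c = 0; c < C; ++c) {
        const arma::uword cc = c0 + ix[c];
        if (Apost(c, cc) > 0.0f) dX(c, cc) = dp[c];
      }
    }
}

static fmat bn_forward(const fmat& X, fvec& g, fvec& be, fvec& rm, fvec& rv,
                       float& cnt, bool training, fmat& xhat, fvec& invstd) {
  fvec mu, var;
  if (training) {
    mu = arma::mean(X, 1);
    var = arma::mean(arma::square(X.each_col() - mu), 1);
    rm = BN_MOMENTUM * rm + (1.0f - BN_MOMENTUM) * mu;
    rv = BN_MOMENTUM * rv + (1.0f - BN_MOMENTUM) * var;
    cnt += 1.0f;
  } else if (cnt > 0.0f) {
    // bias-corrected exponential moments (EMA started from zero)
    const float corr = 1.0f - std::pow(BN_MOMENTUM, cnt);
    mu = rm / corr;
    var = rv / corr;
  } else {
    mu.zeros(X.n_rows);       // untrained model: identity normalisation
    var.ones(X.n_rows);
  }
  invstd = 1.0f / arma::sqrt(var + BN_EPS);
  xhat = X.each_col() - mu;
  xhat.each_col() %= invstd;
  fmat Y = xhat.each_col() % g;
  Y.each_col() += be;
  return Y;
}

static fmat bn_backward(const fmat& dY, const fmat& xhat, const fvec& invstd,
                        const fvec& gamma, fvec& dgamma, fvec& dbeta) {
  const float N = (float)dY.n_cols;
  dbeta = arma::sum(dY, 1);
  dgamma = arma::sum(dY % xhat, 1);
  fmat dX = N * dY;
  dX.each_col() -= dbeta;
  dX -= xhat.each_col() % dgamma;
  dX.each_col() %= (gamma % invstd) / N;
  return dX;
}

static void dropout_mask(fmat& M, arma::uword nr, arma::uword nc, float rate,
                         std::mt19937& rng) {
  M.set_size(nr, nc);
  const float keep = 1.0f - rate;
  const float scale = 1.0f / keep;
  std::uniform_real_distribution<float> u(0.0f, 1.0f);
  float* p = M.memptr();
  const arma::uword nel = nr * nc;
  for (arma::uword i = 0; i < nel; ++i) p[i] = (u(rng) < keep) ? scale : 0.0f;
}

// im2col, kernel length 3: output column t stacks input columns t, t+1, t+2
static void im2col3(const fmat& Y, int B, int Tin, int Tout, fmat& X) {
  const int C = (int)Y.n_rows;
  X.set_size((arma::uword)3 * C, (arma::uword)B * Tout);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < 3; ++k)
      X.submat((arma::uword)k * C, (arma::uword)b * Tout,
               (arma::uword)(k + 1) * C - 1, (arma::uword)(b + 1) * Tout - 1) =
          Y.cols((arma::uword)b * Tin + k, (arma::uword)b * Tin + k + Tout - 1);
}

static void col2im3(const fmat& dX, int B, int Tin, int Tout, fmat& dY) {
  const int C = (int)dX.n_rows / 3;
  dY.zeros(C, (arma::uword)B * Tin);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < 3; ++k)
      dY.cols((arma::uword)b * Tin + k, (arma::uword)b * Tin + k + Tout - 1) +=
          dX.submat((arma::uword)k * C, (arma::uword)b * Tout,
                    (arma::uword)(k + 1) * C - 1, (arma::uword)(b + 1) * Tout - 1);
}

static void path_forward(const IntegerMatrix& idx, const std::vector<int>& cols,
                         PathW& w, int Cin, const PathDims& d, bool training,
                         float dropout, std::mt19937& rng, PathCache& c) {
  const int B = (int)cols.size();
  conv1_forward(idx, cols, w, Cin, d, c.A1);
  maxpool3(c.A1, B, d.T1, d.T2, c.P1, c.I1);
  fmat Y1 = bn_forward(c.P1, w.g1, w.be1, w.rm1, w.rv1, w.cnt1, training,
                       c.X1h, c.is1);
  if (training && dropout > 0.0f) {
    dropout_mask(c.M1, Y1.n_rows, Y1.n_cols, dropout, rng);
    Y1 %= c.M1;
  }
  im2col3(Y1, B, d.T2, d.T3, c.X2);
  c.A2 = w.W2 * c.X2;
  c.A2.each_col() += w.b2;
  c.A2.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
  maxpool3(c.A2, B, d.T3, d.T4, c.P2, c.I2);
  fmat Y2 = bn_forward(c.P2, w.g2, w.be2, w.rm2, w.rv2, w.cnt2, training,
                       c.X2h, c.is2);
  if (training && dropout > 0.0f) {
    dropout_mask(c.M2, Y2.n_rows, Y2.n_cols, dropout, rng);
    Y2 %= c.M2;
  }
  im2col3(Y2, B, d.T4, d.T5, c.X3);
  c.A3 = w.W3 * c.X3;
  c.A3.each_col() += w.b3;
  c.A3.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
  c.G.set_size(256, B);
  for (int b = 0; b < B; ++b)
    c.G.col(b) = arma::mean(c.A3.cols((arma::uword)b * d.T5,
                                      (arma::uword)(b + 1) * d.T5 - 1), 1);
}

struct PathG {
  fmat W1; fvec b1, g1, be1;
  fmat W2; fvec b2, g2, be2;
  fmat W3; fvec b3;
};

static void path_backward(const IntegerMatrix& idx, const std::vector<int>& cols,
                          PathW& w, int Cin, const PathDims& d, float dropout,
                          const PathCache& c, const fmat& dG, PathG& g) {
  const int B = (int)cols.size();
  // global average pooling + conv3 ReLU
  fmat dA3(256, (arma::uword)B * d.T5);
  const float inv = 1.0f / (float)d.T5;
  for (int b = 0; b < B; ++b)
    dA3.cols((arma::uword)b * d.T5, (arma::uword)(b + 1) * d.T5 - 1).each_col() =
        fvec(dG.col(b) * inv);
  dA3 %= arma::conv_to<fmat>::from(c.A3 > 0.0f);
  g.W3 = dA3 * c.X3.t();
  g.b3 = arma::sum(dA3, 1);
  fmat dX3 = w.W3.t() * dA3;
  fmat dY2;
  col2im3(dX3, B, d.T4, d.T5, dY2);
  if (dropout > 0.0f) dY2 %= c.M2;
  fmat dP2 = bn_backward(dY2, c.X2h, c.is2, w.g2, g.g2, g.be2);
  fmat dA2;
  maxpool3_backward(dP2, c.I2, B, d.T3, d.T4, c.A2, dA2);
  g.W2 = dA2 * c.X2.t();
  g.b2 = arma::sum(dA2, 1);
  fmat dX2 = w.W2.t() * dA2;
  fmat dY1;
  col2im3(dX2, B, d.T2, d.T3, dY1);
  if (dropout > 0.0f) dY1 %= c.M1;
  fmat dP1 = bn_backward(dY1, c.X1h, c.is1, w.g1, g.g1, g.be1);
  fmat dA1;
  maxpool3_backward(dP1, c.I1, B, d.T1, d.T2, c.A1, dA1);
  conv1_backward(idx, cols, Cin, d, dA1, g.W1, g.b1);
}

// ---- Adam ------------------------------------------------------------------

struct Param { fmat* m = nullptr; fvec* v = nullptr; };

static Param P_(fmat& m) { Param p; p.m = &m; return p; }
static Param P_(fvec& v) { Param p; p.v = &v; return p; }

struct Adam {
  std::vector<fmat> mM, vM;
  float lr, b1, b2, eps;
  int t;
  void init(const std::vector<Param>& ps, float lr_) {
    lr = lr_; b1 = 0.9f; b2 = 0.999f; eps = 1e-7f; t = 0;
    mM.clear(); vM.clear();
    for (const auto& p : ps) {
      arma::uword nr = p.m ? p.m->n_rows : p.v->n_rows;
      arma::uword nc = p.m ? p.m->n_cols : 1;
      mM.push_back(fmat(nr, nc, arma::fill::zeros));
      vM.push_back(fmat(nr, nc, arma::fill::zeros));
    }
  }
  void step(std::vector<Param>& ps, std::vector<Param>& gs) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      fmat g = gs[i].m ? *gs[i].m : fmat(*gs[i].v);
      mM[i] = b1 * mM[i] + (1.0f - b1) * g;
      vM[i] = b2 * vM[i] + (1.0f - b2) * arma::square(g);
      fmat upd = lr * (mM[i] / c1) / (arma::sqrt(vM[i] / c2) + eps);
      if (ps[i].m) *ps[i].m -= upd;
      else         *ps[i].v -= fvec(upd.col(0));
    }
  }
};

static void collect_path(PathW& p, std::vector<Param>& out) {
  out.push_back(P_(p.W1)); out.push_back(P_(p.b1));
  out.push_back(P_(p.g1)); out.push_back(P_(p.be1));
  out.push_back(P_(p.W2)); out.push_back(P_(p.b2));
  out.push_back(P_(p.g2)); out.push_back(P_(p.be2));
  out.push_back(P_(p.W3)); out.push_back(P_(p.b3));
}

static void collect_grad(PathG& p, std::vector<Param>& out) {
  out.push_back(P_(p.W1)); out.push_back(P_(p.b1));
  out.push_back(P_(p.g1)); out.push_back(P_(p.be1));
  out.push_back(P_(p.W2)); out.push_back(P_(p.b2));
  out.push_back(P_(p.g2)); out.push_back(P_(p.be2));
  out.push_back(P_(p.W3)); out.push_back(P_(p.b3));
}

// ---- entry points ----------------------------------------------------------

// [[Rcpp::export]]
List cnn_init_cpp(int Lmax, std::string paths, int seed) {
  std::mt19937 rng((unsigned)seed);
  const bool base = paths == "both" || paths == "base";
  const bool codon = paths == "both" || paths == "codon";
  if (!base && !codon) stop("paths must be 'both', 'base' or 'codon'");
  const int width = (base ? 256 : 0) + (codon ? 256 : 0);
  List w;
  if (base)  { PathW p = init_path(4, rng);  store_path(w, "b", p); }
  if (codon) { PathW p = init_path(64, rng); store_path(w, "c", p); }
  w["Wd"] = putf(glorot(width, width, rng));
  w["bd"] = putv(fvec(width, arma::fill::zeros));
  w["Wo"] = putf(glorot(3, width, rng));
  w["bo"] = putv(fvec(3, arma::fill::zeros));
  return w;
}

static fmat softmax_cols(fmat Z) {
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    float mx = Z.col(j).max();
    Z.col(j) = arma::exp(Z.col(j) - mx);
    Z.col(j) /= arma::accu(Z.col(j));
  }
  return Z;
}

// forward pass; returns 3 x B probabilities
static fmat model_forward(const IntegerMatrix& bohIdx, const IntegerMatrix& cohIdx,
                          const std::vector<int>& cols, bool base, bool codon,
                          PathW* pb, PathW* pc, const HeadW& h, const PathDims& d,
                          bool training, float dropout, std::mt19937& rng,
                          PathCache* cb, PathCache* cc, fmat* Hout, fmat* Dout) {
  fmat H;
  if (base && codon) {
    path_forward(bohIdx, cols, *pb, 4, d, training, dropout, rng, *cb);
    path_forward(cohIdx, cols, *pc, 64, d, training, dropout, rng, *cc);
    H = arma::join_cols(cb->G, cc->G);
  } else if (base) {
    path_forward(bohIdx, cols, *pb, 4, d, training, dropout, rng, *cb);
    H = cb->G;
  } else {
    path_forward(cohIdx, cols, *pc, 64, d, training, dropout, rng, *cc);
    H = cc->G;
  }
  fmat D = h.Wd * H;
  D.each_col() += h.bd;
  D.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
  fmat logits = h.Wo * D;
  logits.each_col() += h.bo;
  if (Hout) *Hout = H;
  if (Dout) *Dout = D;
  return softmax_cols(logits);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, IntegerMatrix bohIdx, IntegerMatrix cohIdx,
                   IntegerVector labels, int Lmax, std::string paths,
                   double dropout, int epochs, int batch_size, double lr,
                   int seed) {
  const bool base = paths == "both" || paths == "base";
  const bool codon = paths == "both" || paths == "codon";
  const PathDims d = path_dims(Lmax);
  const int n = labels.size();
  if (bohIdx.ncol() != n || cohIdx.ncol() != n)
    stop("encodings and labels disagree on the number of fragments");
  if (batch_size < 2) stop("batch_size must be >= 2 (batchnorm needs batches)");

  PathW pb, pc;
  if (base) pb = load_path(weights, "b");
  if (codon) pc = load_path(weights, "c");
  HeadW h;
  h.Wd = getf(weights, "Wd"); h.bd = getv(weights, "bd");
  h.Wo = getf(weights, "Wo"); h.bo = getv(weights, "bo");

  std::vector<Param> params;
  if (base) collect_path(pb, params);
  if (codon) collect_path(pc, params);
  params.push_back(P_(h.Wd)); params.push_back(P_(h.bd));
  params.push_back(P_(h.Wo)); params.push_back(P_(h.bo));

  Adam opt;
  opt.init(params, (float)lr);

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector loss_hist(epochs);
  PathCache cb, cc;
  PathG gb, gc;
  HeadW gh;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int s = 0; s < n; s += batch_size) {
      const int B = std::min(batch_size, n - s);
      if (B < 2) continue;  // batchnorm degenerates on a single sample
      std::vector<int> cols(order.begin() + s, order.begin() + s + B);

      fmat H, D;
      fmat P = model_forward(bohIdx, cohIdx, cols, base, codon, &pb, &pc, h, d,
                             true, (float)dropout, rng, &cb, &cc, &H, &D);

      double loss = 0.0;
      fmat dZ = P;
      for (int b = 0; b < B; ++b) {
        const int y = labels[cols[b]];
        loss -= std::log(std::max(P(y, b), 1e-12f));
        dZ(y, b) -= 1.0f;
      }
      loss /= B;
      dZ /= (float)B;
      ep_loss += loss;
      ++n_batches;

      gh.Wo = dZ * D.t();
      gh.bo = arma::sum(dZ, 1);
      fmat dD = h.Wo.t() * dZ;
      dD %= arma::conv_to<fmat>::from(D > 0.0f);
      gh.Wd = dD * H.t();
      gh.bd = arma::sum(dD, 1);
      fmat dH = h.Wd.t() * dD;

      std::vector<Param> grads;
      if (base && codon) {
        path_backward(bohIdx, cols, pb, 4, d, (float)dropout, cb,
                      dH.rows(0, 255), gb);
        path_backward(cohIdx, cols, pc, 64, d, (float)dropout, cc,
                      dH.rows(256, 511), gc);
        collect_grad(gb, grads);
        collect_grad(gc, grads);
      } else if (base) {
        path_backward(bohIdx, cols, pb, 4, d, (float)dropout, cb, dH, gb);
        collect_grad(gb, grads);
      } else {
        path_backward(cohIdx, cols, pc, 64, d, (float)dropout, cc, dH, gc);
        collect_grad(gc, grads);
      }
      grads.push_back(P_(gh.Wd)); grads.push_back(P_(gh.bd));
      grads.push_back(P_(gh.Wo)); grads.push_back(P_(gh.bo));

      opt.step(params, grads);
      Rcpp::checkUserInterrupt();
    }
    loss_hist[ep] = ep_loss / std::max(1, n_batches);
  }

  List out = clone(weights);
  if (base) store_path(out, "b", pb);
  if (codon) store_path(out, "c", pc);
  out["Wd"] = putf(h.Wd); out["bd"] = putv(h.bd);
  out["Wo"] = putf(h.Wo); out["bo"] = putv(h.bo);
  return List::create(_["weights"] = out, _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List weights, IntegerMatrix bohIdx,
                              IntegerMatrix cohIdx, int Lmax, std::string paths,
                              int batch_size) {
  const bool base = paths == "both" || paths == "base";
  const bool codon = paths == "both" || paths == "codon";
  const PathDims d = path_dims(Lmax);
  const int n = bohIdx.ncol();

  PathW pb, pc;
  if (base) pb = load_path(weights, "b");
  if (codon) pc = load_path(weights, "c");
  HeadW h;
  h.Wd = getf(weights, "Wd"); h.bd = getv(weights, "bd");
  h.Wo = getf(weights, "Wo"); h.bo = getv(weights, "bo");

  std::mt19937 rng(0);  // unused: no dropout at inference
  PathCache cb, cc;
  NumericMatrix out(n, 3);
  for (int s = 0; s < n; s += batch_size) {
    const int B = std::min(batch_size, n - s);
    std::vector<int> cols(B);
    for (int b = 0; b < B; ++b) cols[b] = s + b;
    fmat P = model_forward(bohIdx, cohIdx, cols, base, codon, &pb, &pc, h, d,
                           false, 0.0f, rng, &cb, &cc, nullptr, nullptr);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < 3; ++k) out(s + b, k) = (double)P(k, b);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
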