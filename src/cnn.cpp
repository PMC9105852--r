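// Shallow CNN for small square single-channel ROI patches:
//   conv 3x3 (C filters, same padding) + ReLU -> 2x2 maxpool
//   conv 3x3 (C filters, same padding) + ReLU -> 2x2 maxpool
//   flatten (C * (S/4)^2) -> dense(H) + ReLU -> dropout -> dense(K) softmax
// trained with mini-batch ADAM on cross-entropy. All randomness (weight
// init, epoch shuffling, dropout masks) comes from one std::mt19937 stream,
// so results are bit-reproducible for a given seed on a given platform.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// im2col for 3x3 same-padding convolution. A: (S,S,Cin) -> M: (S*S, 9*Cin),
// column k*Cin+ch holds channel ch shifted by offset k (zero outside).
void im2col(const cube& A, mat& M) {
  const int S = A.n_rows;
  const int C = A.n_slices;
  M.zeros();
  for (int k = 0; k < 9; ++k) {
    const int dr = k / 3 - 1, dc = k % 3 - 1;
    const int rlo = std::max(0, -dr), rhi = std::min(S, S - dr);
    const int clo = std::max(0, -dc), chi = std::min(S, S - dc);
    for (int ch = 0; ch < C; ++ch) {
      const double* sm = A.slice_memptr(ch);
      double* col = M.colptr(k * C + ch);
      for (int c = clo; c < chi; ++c) {
        std::memcpy(col + c * S + rlo, sm + (c + dc) * S + (rlo + dr),
                    (rhi - rlo) * sizeof(double));
      }
    }
  }
}

// Adjoint of im2col: scatter-add dM back onto the input grid.
void col2im(const mat& dM, cube& dA) {
  const int S = dA.n_rows;
  const int C = dA.n_slices;
  dA.zeros();
  for (int k = 0; k < 9; ++k) {
    const int dr = k / 3 - 1, dc = k % 3 - 1;
    const int rlo = std::max(0, -dr), rhi = std::min(S, S - dr);
    const int clo = std::max(0, -dc), chi = std::min(S, S - dc);
    for (int ch = 0; ch < C; ++ch) {
      double* sm = dA.slice_memptr(ch);
      const double* col = dM.colptr(k * C + ch);
      for (int c = clo; c < chi; ++c) {
        for (int r = rlo; r < rhi; ++r) {
          sm[(c + dc) * S + (r + dr)] += col[c * S + r];
        }
      }
    }
  }
}

// 2x2 max pooling on (S*S, C) activations; stores the winning row index for
// the backward pass (first maximum wins on ties).
void maxpool(const mat& Z, int S, mat& P, umat& I) {
  const int S2 = S / 2;
  for (uword ch = 0; ch < Z.n_cols; ++ch) {
    const double* z = Z.colptr(ch);
    double* p = P.colptr(ch);
    uword* ix = I.colptr(ch);
    for (int c2 = 0; c2 < S2; ++c2) {
      for (int r2 = 0; r2 < S2; ++r2) {
        const int base = 2 * c2 * S + 2 * r2;
        int best = base;
        double bv = z[base];
        const int cand[3] = {base + 1, base + S, base + S + 1};
        for (int j = 0; j < 3; ++j) {
          if (z[cand[j]] > bv) { bv = z[cand[j]]; best = cand[j]; }
        }
        p[c2 * S2 + r2] = bv;
        ix[c2 * S2 + r2] = best;
      }
    }
  }
}

void unpool(const mat& dP, const umat& I, mat& dZ) {
  dZ.zeros();
  for (uword ch = 0; ch < dP.n_cols; ++ch) {
    const double* dp = dP.colptr(ch);
    const uword* ix = I.colptr(ch);
    double* dz = dZ.colptr(ch);
    for (uword i = 0; i < dP.n_rows; ++i) dz[ix[i]] += dp[i];
  }
}

struct Params {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4;
};

struct Adam {
  mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  vec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  long t = 0;
  explicit Adam(const Params& p) {
    mW1.zeros(size(p.W1)); vW1.zeros(size(p.W1));
    mW2.zeros(size(p.W2)); vW2.zeros(size(p.W2));
    mW3.zeros(size(p.W3)); vW3.zeros(size(p.W3));
    mW4.zeros(size(p.W4)); vW4.zeros(size(p.W4));
    mb1.zeros(size(p.b1)); vb1.zeros(size(p.b1));
    mb2.zeros(size(p.b2)); vb2.zeros(size(p.b2));
    mb3.zeros(size(p.b3)); vb3.zeros(size(p.b3));
    mb4.zeros(size(p.b4)); vb4.zeros(size(p.b4));
  }
  template <typename T>
  void step1(T& w, const T& g, T& m, T& v, double lr) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Params& p, const Params& g, double lr) {
    ++t;
    step1(p.W1, g.W1, mW1, vW1, lr); step1(p.b1, g.b1, mb1, vb1, lr);
    step1(p.W2, g.W2, mW2, vW2, lr); step1(p.b2, g.b2, mb2, vb2, lr);
    step1(p.W3, g.W3, mW3, vW3, lr); step1(p.b3, g.b3, mb3, vb3, lr);
    step1(p.W4, g.W4, mW4, vW4, lr); step1(p.b4, g.b4, mb4, vb4, lr);
  }
};

// Scratch buffers reused across images.
struct Work {
  mat M1, Z1, P1, M2, Z2, P2;
  umat I1, I2;
  cube A1, dA1;
  mat dZ1, dZ2, dP1, dP2, dM2;
  vec f, h, hr, mask, z, p, dz, dh, df;
  Work(int S, int C, int H, int K) {
    const int S2 = S / 2, S4 = S / 4, F = C * S4 * S4;
    M1.set_size(S * S, 9);        Z1.set_size(S * S, C);
    P1.set_size(S2 * S2, C);      I1.set_size(S2 * S2, C);
    A1.set_size(S2, S2, C);
    M2.set_size(S2 * S2, 9 * C);  Z2.set_size(S2 * S2, C);
    P2.set_size(S4 * S4, C);      I2.set_size(S4 * S4, C);
    dA1.set_size(S2, S2, C);
    dZ1.set_size(S * S, C);       dZ2.set_size(S2 * S2, C);
    dP1.set_size(S2 * S2, C);     dP2.set_size(S4 * S4, C);
    dM2.set_size(S2 * S2, 9 * C);
    f.set_size(F); h.set_size(H); hr.set_size(H); mask.set_size(H);
    z.set_size(K); p.set_size(K); dz.set_size(K); dh.set_size(H); df.set_size(F);
  }
};

// Forward pass for image x (S,S). Training mode applies inverted dropout
// with the supplied mask. Returns the softmax probabilities in w.p.
void forward(const cube& X, uword img, const Params& par, Work& w, int S,
             bool train, double keep) {
  const cube x(const_cast<double*>(X.slice_memptr(img)), S, S, 1, false, true);
  im2col(x, w.M1);
  w.Z1 = w.M1 * par.W1;
  w.Z1.each_row() += par.b1.t();
  mat R1 = clamp(w.Z1, 0.0, datum::inf);
  maxpool(R1, S, w.P1, w.I1);
  std::memcpy(w.A1.memptr(), w.P1.memptr(), w.P1.n_elem * sizeof(double));
  im2col(w.A1, w.M2);
  w.Z2 = w.M2 * par.W2;
  w.Z2.each_row() += par.b2.t();
  mat R2 = clamp(w.Z2, 0.0, datum::inf);
  maxpool(R2, S / 2, w.P2, w.I2);
  w.f = vectorise(w.P2);
  w.h = par.W3.t() * w.f + par.b3;
  w.hr = clamp(w.h, 0.0, datum::inf);
  if (train && keep < 1.0) w.hr = (w.hr % w.mask) / keep;
  w.z = par.W4.t() * w.hr + par.b4;
  w.p = exp(w.z - w.z.max());
  w.p /= accu(w.p);
}

// Backward pass; accumulates gradients into g. Assumes forward() just ran.
void backward(const Params& par, Params& g, Work& w, int S, int label,
              bool train, double keep) {
  w.dz = w.p;
  w.dz(label) -= 1.0;
  g.W4 += w.hr * w.dz.t();
  g.b4 += w.dz;
  vec dhr = par.W4 * w.dz;
  if (train && keep < 1.0) dhr = (dhr % w.mask) / keep;
  w.dh = dhr % conv_to<vec>::from(w.h > 0);
  g.W3 += w.f * w.dh.t();
  g.b3 += w.dh;
  w.df = par.W3 * w.dh;
  std::memcpy(w.dP2.memptr(), w.df.memptr(), w.df.n_elem * sizeof(double));
  unpool(w.dP2, w.I2, w.dZ2);
  w.dZ2 %= conv_to<mat>::from(w.Z2 > 0);
  g.W2 += w.M2.t() * w.dZ2;
  g.b2 += sum(w.dZ2, 0).t();
  w.dM2 = w.dZ2 * par.W2.t();
  col2im(w.dM2, w.dA1);
  mat dP1v(w.dA1.memptr(), w.dP1.n_rows, w.dP1.n_cols, false, true);
  unpool(dP1v, w.I1, w.dZ1);
  w.dZ1 %= conv_to<mat>::from(w.Z1 > 0);
  g.W1 += w.M1.t() * w.dZ1;
  g.b1 += sum(w.dZ1, 0).t();
}

void zero_like(Params& g, const Params& p) {
  g.W1.zeros(size(p.W1)); g.W2.zeros(size(p.W2));
  g.W3.zeros(size(p.W3)); g.W4.zeros(size(p.W4));
  g.b1.zeros(size(p.b1)); g.b2.zeros(size(p.b2));
  g.b3.zeros(size(p.b3)); g.b4.zeros(size(p.b4));
}

mat randn_mat(int r, int c, double sd, std::mt19937& gen) {
  std::normal_distribution<double> nd(0.0, sd);
  mat m(r, c);
  for (uword i = 0; i < m.n_elem; ++i) m(i) = nd(gen);
  return m;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::ivec& y,
                         int filters, int hidden, int nclasses,
                         double lr, double dropout, int batch, int epochs,
                         int seed) {
  const int S = X.n_rows;
  const int n = X.n_slices;
  if ((int)X.n_cols != S || S % 4 != 0)
    Rcpp::stop("images must be square with side divisible by 4");
  if ((int)y.n_elem != n) Rcpp::stop("label count does not match image count");
  const int C = filters, H = hidden, K = nclasses;
  const int F = C * (S / 4) * (S / 4);
  const double keep = 1.0 - dropout;

  std::mt19937 gen(seed);
  Params par;
  par.W1 = randn_mat(9, C, std::sqrt(2.0 / 9.0), gen);
  par.W2 = randn_mat(9 * C, C, std::sqrt(2.0 / (9.0 * C)), gen);
  par.W3 = randn_mat(F, H, std::sqrt(2.0 / F), gen);
  par.W4 = randn_mat(H, K, std::sqrt(1.0 / H), gen);
  par.b1.zeros(C); par.b2.zeros(C); par.b3.zeros(H); par.b4.zeros(K);

  Params grad;
  Adam opt(par);
  Work w(S, C, H, K);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const int bs = std::min(batch, n);

  std::vector<double> histLoss(epochs), histAcc(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double lossSum = 0.0;
    int correct = 0;
    for (int start = 0; start < n; start += bs) {
      const int stop = std::min(start + bs, n);
      zero_like(grad, par);
      for (int j = start; j < stop; ++j) {
        const int img = order[j];
        if (keep < 1.0) {
          for (int u = 0; u < H; ++u) w.mask(u) = unif(gen) < keep ? 1.0 : 0.0;
        }
        forward(X, img, par, w, S, true, keep);
        const int lab = y(img);
        lossSum += -std::log(std::max(w.p(lab), 1e-300));
        if (w.p.index_max() == (uword)lab) ++correct;
        backward(par, grad, w, S, lab, true, keep);
      }
      const double inv = 1.0 / (stop - start);
      grad.W1 *= inv; grad.W2 *= inv; grad.W3 *= inv; grad.W4 *= inv;
      grad.b1 *= inv; grad.b2 *= inv; grad.b3 *= inv; grad.b4 *= inv;
      opt.step(par, grad, lr);
    }
    histLoss[ep] = lossSum / n;
    histAcc[ep] = (double)correct / n;
    if (ep % 10 == 9) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = par.W1, Rcpp::Named("b1") = par.b1,
      Rcpp::Named("W2") = par.W2, Rcpp::Named("b2") = par.b2,
      Rcpp::Named("W3") = par.W3, Rcpp::Named("b3") = par.b3,
      Rcpp::Named("W4") = par.W4, Rcpp::Named("b4") = par.b4,
      Rcpp::Named("loss") = histLoss, Rcpp::Named("accuracy") = histAcc);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const Rcpp::List& weights, const arma::cube& X) {
  Params par;
  par.W1 = Rcpp::as<mat>(weights["W1"]); par.b1 = Rcpp::as<vec>(weights["b1"]);
  par.W2 = Rcpp::as<mat>(weights["W2"]); par.b2 = Rcpp::as<vec>(weights["b2"]);
  par.W3 = Rcpp::as<mat>(weights["W3"]); par.b3 = Rcpp::as<vec>(weights["b3"]);
  par.W4 = Rcpp::as<mat>(weights["W4"]); par.b4 = Rcpp::as<vec>(weights["b4"]);
  const int S = X.n_rows;
  const int n = X.n_slices;
  const int C = par.W1.n_cols, H = par.W3.n_cols, K = par.W4.n_cols;
  if ((int)X.n_cols != S || S % 4 != 0)
    Rcpp::stop("images must be square with side divisible by 4");
  if ((int)par.W3.n_rows != C * (S / 4) * (S / 4))
    Rcpp::stop("image size does not match the trained input contract");
  Work w(S, C, H, K);
  mat out(n, K);
  for (int i = 0; i < n; ++i) {
    forward(X, i, par, w, S, false, 1.0);
    out.row(i) = w.p.t();
  }
  return out;
}
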