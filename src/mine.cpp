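// Donsker-Varadhan lower-bound trainer for mutual information estimation.
//
// A single-hidden-layer statistic network T(x, y) is trained by Adam gradient
// ascent on the DV objective
//     E_P[T] - log E_Q[e^T],
// where P is the paired (joint) empirical distribution and Q the product of
// marginals, realised by permuting the y rows within each minibatch.  The
// gradient of the log-partition term uses an exponential moving average of
// E_Q[e^T] in the denominator (the standard bias fix for this estimator);
// the recorded bound itself is the uncorrected batch value.  Training is in
// nats; the R wrapper converts the returned curve to bits.
//
// Determinism: all randomness (init, batch sampling, permutations) comes from
// a private std::mt19937 seeded from R, so repeated calls with the same seed
// produce identical curves and the R session RNG is left untouched.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;

namespace {

// exp via 2^(x log2 e) with a degree-5 polynomial for the fractional part;
// relative error ~1e-7, ample for an activation function, and much cheaper
// than libm exp, which dominates the training loop otherwise.
inline double fast_exp(double x) {
  if (x < -30.0) return 0.0;
  if (x > 30.0) x = 30.0;
  const double t = x * 1.4426950408889634; // log2(e)
  const double fi = std::floor(t);
  const double f = t - fi;
  const double p = 1.0 + f * (0.69314718055994531 +
                       f * (0.24022650695910072 +
                       f * (0.05550410866482158 +
                       f * (0.00961812910762848 +
                       f * 0.00133335581464284))));
  return std::ldexp(p, static_cast<int>(fi));
}

// ELU (alpha = 1), computed in place; d receives the derivative
inline void elu_inplace(mat& Z, mat& dZ) {
  const uword n = Z.n_elem;
  double* z = Z.memptr();
  double* d = dZ.memptr();
  for (uword i = 0; i < n; ++i) {
    if (z[i] < 0.0) {
      const double e = fast_exp(z[i]);
      z[i] = e - 1.0;
      d[i] = e;
    } else {
      d[i] = 1.0;
    }
  }
}

struct Adam {
  mat m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  // ascent step (maximisation)
  void step(mat& w, const mat& g, double lr, double b1t, double b2t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    w += lr * (m / (1.0 - b1t)) / (sqrt(v / (1.0 - b2t)) + eps);
  }
};

} // namespace

// [[Rcpp::export(name = ".mine_train_cpp")]]
Rcpp::NumericVector mine_train_cpp(const arma::mat& X, const arma::mat& Y,
                                   int hidden, double lr, int n_iter,
                                   int batch, double ema_decay,
                                   unsigned int seed) {
  const uword n = X.n_rows;
  const uword dx = X.n_cols, dy = Y.n_cols, d = dx + dy;
  const uword H = hidden;
  if (Y.n_rows != n) Rcpp::stop("x and y must have the same number of rows");
  const uword B = std::min<uword>(batch, n);

  std::mt19937 rng(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_int_distribution<uword> unif(0, n - 1);

  // He-style init for the hidden layer, small output layer
  mat W1(d, H), w2(H, 1);
  const double s1 = std::sqrt(2.0 / double(d));
  const double s2 = std::sqrt(1.0 / double(H));
  for (uword i = 0; i < W1.n_elem; ++i) W1[i] = s1 * norm(rng);
  for (uword i = 0; i < w2.n_elem; ++i) w2[i] = s2 * norm(rng);
  rowvec b1v(H, fill::zeros);
  double b2 = 0.0;

  Adam aW1(d, H), ab1(1, H), aw2(H, 1), ab2(1, 1);

  Rcpp::NumericVector curve(n_iter);
  double ema = -1.0; // initialised from the first batch

  // preallocated buffers (B x H traffic dominates; avoid per-iter allocs)
  mat A(B, d), Am(B, d);
  mat Z(B, H), Zm(B, H), dAct(B, H), dActm(B, H);
  vec tj(B), tm(B), etm(B), gm(B);
  mat gW1(d, H);
  rowvec gb1(H);
  mat gw2(H, 1);
  uvec idx(B), perm(B);

  const double gj = 1.0 / double(B); // dL/dt for every joint sample

  double b1t = 1.0, b2t = 1.0;

  for (int it = 0; it < n_iter; ++it) {
    // minibatch of paired rows; marginal batch permutes y within the batch
    for (uword i = 0; i < B; ++i) idx[i] = unif(rng);
    perm = idx;
    for (uword i = B - 1; i > 0; --i) {
      std::uniform_int_distribution<uword> u(0, i);
      std::swap(perm[i], perm[u(rng)]);
    }
    A.cols(0, dx - 1) = X.rows(idx);
    A.cols(dx, d - 1) = Y.rows(idx);
    Am.cols(0, dx - 1) = A.cols(0, dx - 1);
    Am.cols(dx, d - 1) = Y.rows(perm);

    // forward
    Z = A * W1;
    Z.each_row() += b1v;
    elu_inplace(Z, dAct);
    tj = Z * w2;
    tj += b2;

    Zm = Am * W1;
    Zm.each_row() += b1v;
    elu_inplace(Zm, dActm);
    tm = Zm * w2;
    tm += b2;

    double mean_etm = 0.0;
    for (uword i = 0; i < B; ++i) {
      double t = tm[i];
      if (t > 50.0) t = 50.0;
      etm[i] = std::exp(t);
      mean_etm += etm[i];
    }
    mean_etm /= double(B);
    if (!std::isfinite(mean_etm) || mean_etm <= 0.0) {
      Rcpp::NumericVector bad(n_iter, NA_REAL);
      return bad; // caller marks the replicate failed
    }
    ema = (ema < 0.0) ? mean_etm
                      : ema_decay * ema + (1.0 - ema_decay) * mean_etm;

    double mean_tj = 0.0;
    for (uword i = 0; i < B; ++i) mean_tj += tj[i];
    curve[it] = mean_tj / double(B) - std::log(mean_etm);

    // backward: dL/dtj = 1/B ; dL/dtm = -e^{tm} / (B * ema)
    const double cm = -1.0 / (double(B) * ema);
    for (uword i = 0; i < B; ++i) gm[i] = cm * etm[i];

    // reuse dAct/dActm as the per-unit delta matrices:
    //   dZ(i,h)  = gj    * w2[h] * dAct(i,h)   (joint pass)
    //   dZm(i,h) = gm[i] * w2[h] * dActm(i,h)  (marginal pass)
    // and accumulate gw2/gb1 in the same sweep.
    const double* w2p = w2.memptr();
    for (uword h = 0; h < H; ++h) {
      const double wh = w2p[h];
      double* dz = dAct.colptr(h);
      double* dzm = dActm.colptr(h);
      const double* zc = Z.colptr(h);
      const double* zmc = Zm.colptr(h);
      double s = 0.0, sw = 0.0;
      for (uword i = 0; i < B; ++i) {
        sw += zc[i] * gj + zmc[i] * gm[i];
        const double a = gj * wh * dz[i];
        const double b = gm[i] * wh * dzm[i];
        dz[i] = a;
        dzm[i] = b;
        s += a + b;
      }
      gb1[h] = s;
      gw2(h, 0) = sw;
    }
    gW1 = A.t() * dAct + Am.t() * dActm;
    double gb2 = 0.0; // sum(gj) + sum(gm)
    for (uword i = 0; i < B; ++i) gb2 += gm[i];
    gb2 += 1.0;

    b1t *= 0.9; b2t *= 0.999;
    aW1.step(W1, gW1, lr, b1t, b2t);
    mat b1m(b1v); ab1.step(b1m, conv_to<mat>::from(gb1), lr, b1t, b2t);
    b1v = b1m;
    aw2.step(w2, gw2, lr, b1t, b2t);
    mat b2m(1, 1); b2m[0] = b2;
    mat gb2m(1, 1); gb2m[0] = gb2;
    ab2.step(b2m, gb2m, lr, b1t, b2t);
    b2 = b2m[0];

    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return curve; // nats
}
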