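// Core numerical loops: Euler simulation of rate networks, fused
// loss/gradient kernels (backpropagation through time) for RNN training and
// latent-circuit fitting, and the iterative-closest-point inner loop.
// Activation kinds: 0 = relu, 1 = sigmoid (with slope), 2 = tanh.
//
// Internally all state is kept time-major ((units, trials) per step) so the
// per-step matrix products run on contiguous memory; tensors cross the R
// boundary in the package's (units, time, trials) convention.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat act_apply(const mat& x, int kind, double slope) {
  switch (kind) {
  case 0: return clamp(x, 0.0, datum::inf);
  case 1: return 1.0 / (1.0 + exp(-slope * x));
  default: return tanh(x);
  }
}

// derivative of f evaluated from the pre-activation a
static inline mat act_deriv(const mat& a, int kind, double slope) {
  switch (kind) {
  case 0: return conv_to<mat>::from(a > 0.0);
  case 1: {
    mat s = 1.0 / (1.0 + exp(-slope * a));
    return slope * s % (1.0 - s);
  }
  default: {
    mat th = tanh(a);
    return 1.0 - th % th;
  }
  }
}

// (d, T, K) -> (d, K, T): slice t holds all trials at step t
static cube to_time_major(const cube& X) {
  cube P(X.n_rows, X.n_slices, X.n_cols);
  for (uword k = 0; k < X.n_slices; ++k) {
    const mat& S = X.slice(k);
    for (uword t = 0; t < X.n_cols; ++t) P.slice(t).col(k) = S.col(t);
  }
  return P;
}

static cube from_time_major(const cube& P) {
  cube X(P.n_rows, P.n_slices, P.n_cols);
  for (uword k = 0; k < P.n_cols; ++k) {
    mat& S = X.slice(k);
    for (uword t = 0; t < P.n_slices; ++t) S.col(t) = P.slice(t).col(k);
  }
  return X;
}

struct noise_gen {
  std::mt19937_64 eng;
  std::normal_distribution<double> dist;
  noise_gen(unsigned int seed) : eng(seed), dist(0.0, 1.0) {}
  mat draw(uword r, uword c) {
    mat M(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) M(i, j) = dist(eng);
    return M;
  }
};

// shared forward pass in time-major layout; fills Yp (N,K,T), Ap and Up
static void forward_core(const mat& W_inp, const mat& W_rec, cube& Up,
                         cube& Yp, cube& Ap, const vec& y0, double gamma,
                         int kind, double slope, double sigma_inp,
                         double sigma_rec, bool noise, unsigned int seed) {
  const uword N = W_rec.n_rows, K = Up.n_cols, T = Up.n_slices;
  const double s_in = std::sqrt(2.0 * gamma * sigma_inp * sigma_inp);
  const double s_rec = std::sqrt(2.0 * gamma * sigma_rec * sigma_rec);
  noise_gen rng(seed);
  mat Ycur = repmat(y0, 1, K);
  for (uword t = 0; t < T; ++t) {
    if (noise) Up.slice(t) += s_in * rng.draw(Up.n_rows, K);
    mat At = W_rec * Ycur + W_inp * Up.slice(t);
    if (noise) At += s_rec * rng.draw(N, K);
    Ycur = (1.0 - gamma) * Ycur + gamma * act_apply(At, kind, slope);
    Yp.slice(t) = Ycur;
    Ap.slice(t) = At;
  }
}

// Forward Euler simulation of tau*ydot = -y + f(W_rec y + W_inp u) with
// optional process noise per the discretized update
//   y_t = (1-g) y_{t-1} + g f(W_rec y_{t-1} + W_inp (u_t + s_in z) + s_rec x).
// U has dims (n_in, T, K); returns activity (N, T, K) and outputs
// W_out y (n_out, T, K).
// [[Rcpp::export]]
Rcpp::List cpp_rnn_forward(const arma::mat& W_inp, const arma::mat& W_rec,
                           const arma::mat& W_out, const arma::cube& U,
                           const arma::vec& y0, double gamma, int kind,
                           double slope, double sigma_inp, double sigma_rec,
                           bool noise, unsigned int seed) {
  const uword N = W_rec.n_rows, T = U.n_cols, K = U.n_slices;
  cube Up = to_time_major(U);
  cube Yp(N, K, T), Ap(N, K, T);
  forward_core(W_inp, W_rec, Up, Yp, Ap, y0, gamma, kind, slope,
               sigma_inp, sigma_rec, noise, seed);
  cube Y = from_time_major(Yp);
  cube O(W_out.n_rows, T, K);
  for (uword k = 0; k < K; ++k) O.slice(k) = W_out * Y.slice(k);
  return Rcpp::List::create(Rcpp::Named("activity") = Y,
                            Rcpp::Named("outputs") = O);
}

// Fused training pass: forward simulation (optionally with noise), masked
// mean-squared output error + activity penalty, and gradients with respect
// to all three weight matrices by backpropagation through time. The input
// orthogonality penalty is handled on the R side (it does not involve the
// dynamics). mask is (T, K); targets is (n_out, T, K).
// [[Rcpp::export]]
Rcpp::List cpp_train_grad(const arma::mat& W_inp, const arma::mat& W_rec,
                          const arma::mat& W_out, const arma::cube& U,
                          const arma::cube& targets, const arma::mat& mask,
                          const arma::vec& y0, double gamma, int kind,
                          double slope, double sigma_inp, double sigma_rec,
                          bool noise, unsigned int seed, double lambda_r) {
  const uword N = W_rec.n_rows, T = U.n_cols, K = U.n_slices;
  const uword n_out = W_out.n_rows;
  cube Up = to_time_major(U);
  cube Yp(N, K, T), Ap(N, K, T);
  forward_core(W_inp, W_rec, Up, Yp, Ap, y0, gamma, kind, slope,
               sigma_inp, sigma_rec, noise, seed);
  cube Tp = to_time_major(targets);
  const double cnt_out = n_out * accu(mask);   // plain means over all
  const double len_y = double(N) * T * K;      // masked / tensor elements
  double mse = 0.0, act_pen = 0.0;
  mat G(N, K, fill::zeros);
  mat gWrec(N, N, fill::zeros), gWinp(N, W_inp.n_cols, fill::zeros),
      gWout(n_out, N, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& Yt = Yp.slice(tt);
    mat Err = W_out * Yt - Tp.slice(tt);           // (n_out, K)
    Err.each_row() %= mask.row(tt);                // zero unmasked steps
    mse += accu(square(Err));
    act_pen += accu(square(Yt));
    mat dO = (2.0 / cnt_out) * Err;
    gWout += dO * Yt.t();
    G += W_out.t() * dO + (2.0 * lambda_r / len_y) * Yt;
    mat D = gamma * (act_deriv(Ap.slice(tt), kind, slope) % G);
    mat Yprev = (tt == 0) ? repmat(y0, 1, K) : mat(Yp.slice(tt - 1));
    gWrec += D * Yprev.t();
    gWinp += D * Up.slice(tt).t();
    G = (1.0 - gamma) * G + W_rec.t() * D;
  }
  double loss = mse / cnt_out + lambda_r * act_pen / len_y;
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("mse") = mse / cnt_out,
    Rcpp::Named("gW_inp") = gWinp, Rcpp::Named("gW_rec") = gWrec,
    Rcpp::Named("gW_out") = gWout);
}

// Fused latent-circuit pass: noiseless forward simulation of the small
// circuit, loss terms (masked output error, embedding mismatch
// lambda_emb * mean((Q x - z)^2), weight penalty handled in R), and
// gradients for w_inp, w_rec, w_out and Q. z is (N_PC, T, K).
// [[Rcpp::export]]
Rcpp::List cpp_latent_grad(const arma::mat& w_inp, const arma::mat& w_rec,
                           const arma::mat& w_out, const arma::mat& Q,
                           const arma::cube& z, const arma::cube& U,
                           const arma::cube& targets, const arma::mat& mask,
                           double gamma, int kind, double slope,
                           double lambda_emb) {
  const uword n = w_rec.n_rows, T = U.n_cols, K = U.n_slices;
  const uword n_out = w_out.n_rows;
  cube Up = to_time_major(U);
  cube Xp(n, K, T), Ap(n, K, T);
  vec x0(n, fill::zeros);
  forward_core(w_inp, w_rec, Up, Xp, Ap, x0, gamma, kind, slope, 0, 0,
               false, 0);
  cube Tp = to_time_major(targets);
  cube Zp = to_time_major(z);
  const double cnt_out = n_out * accu(mask);
  const double len_z = double(z.n_rows) * T * K;
  double mse = 0.0, emb_sq = 0.0;
  mat G(n, K, fill::zeros);
  mat gwrec(n, n, fill::zeros), gwinp(n, w_inp.n_cols, fill::zeros),
      gwout(n_out, n, fill::zeros), gQ(Q.n_rows, Q.n_cols, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& Xt = Xp.slice(tt);
    mat Err = w_out * Xt - Tp.slice(tt);
    Err.each_row() %= mask.row(tt);
    mse += accu(square(Err));
    mat dO = (2.0 / cnt_out) * Err;
    gwout += dO * Xt.t();
    mat E = Q * Xt - Zp.slice(tt);                 // (N_PC, K)
    emb_sq += accu(square(E));
    gQ += E * Xt.t();
    G += w_out.t() * dO + (2.0 * lambda_emb / len_z) * (Q.t() * E);
    mat D = gamma * (act_deriv(Ap.slice(tt), kind, slope) % G);
    mat Xprev = (tt == 0) ? mat(n, K, fill::zeros) : mat(Xp.slice(tt - 1));
    gwrec += D * Xprev.t();
    gwinp += D * Up.slice(tt).t();
    G = (1.0 - gamma) * G + w_rec.t() * D;
  }
  gQ *= 2.0 * lambda_emb / len_z;
  return Rcpp::List::create(
    Rcpp::Named("loss") = mse / cnt_out + lambda_emb * emb_sq / len_z,
    Rcpp::Named("mse") = mse / cnt_out,
    Rcpp::Named("emb") = emb_sq / len_z,
    Rcpp::Named("gw_inp") = gwinp, Rcpp::Named("gw_rec") = gwrec,
    Rcpp::Named("gw_out") = gwout, Rcpp::Named("gQ") = gQ);
}

// run one ICP descent from a given orthogonal initialization; returns the
// converged mean squared mismatch
static double icp_descent(const mat& src, const mat& tgt,
                          const ivec& tag_src, const ivec& tag_tgt,
                          bool tagged, mat Arot, int max_iter, double tol) {
  const uword d = src.n_cols, m = tgt.n_rows;
  double prev = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    mat srcA = src * Arot;
    mat matched(m, d);
    for (uword i = 0; i < m; ++i) {
      double dmin = datum::inf;
      uword jmin = 0;
      for (uword j = 0; j < src.n_rows; ++j) {
        if (tagged && tag_src(j) != tag_tgt(i)) continue;
        double dd = accu(square(srcA.row(j) - tgt.row(i)));
        if (dd < dmin) { dmin = dd; jmin = j; }
      }
      matched.row(i) = src.row(jmin);
    }
    mat Uu, Vv;
    vec s;
    svd(Uu, s, Vv, matched.t() * tgt);
    Arot = Uu * Vv.t();
    double score = accu(square(matched * Arot - tgt)) / (m * d);
    if (prev - score < tol * std::max(prev, 1.0)) return score;
    prev = score;
  }
  return prev;
}

// One ICP registration direction: find the orthogonal transform A minimizing
// the mean squared mismatch when every target point is matched to its
// nearest transformed source point (one-to-many matches allowed, optionally
// restricted to equal tags). Initializations combine principal-axis
// alignments (the transforms mapping the source's second-moment eigenbasis
// onto the target's, over all axis-sign combinations, capped at 2^7) with
// n_tries Haar-random orthogonal starts drawn from R's RNG; the minimum
// converged score is returned.
// [[Rcpp::export]]
double cpp_icp_register(const arma::mat& src, const arma::mat& tgt,
                        const arma::ivec& tag_src, const arma::ivec& tag_tgt,
                        int n_tries, int max_iter, double tol) {
  const uword d = src.n_cols;
  const bool tagged = tag_src.n_elem > 0;
  double best = datum::inf;
  // principal-axis initializations
  vec es, et;
  mat Vs, Vt;
  eig_sym(es, Vs, symmatu(src.t() * src));
  eig_sym(et, Vt, symmatu(tgt.t() * tgt));
  const int n_sign = 1 << std::min<uword>(d, 7);
  for (int sgn = 0; sgn < n_sign; ++sgn) {
    vec flips(d, fill::ones);
    for (uword j = 0; j < std::min<uword>(d, 7); ++j)
      if (sgn & (1 << j)) flips(j) = -1.0;
    mat A0 = Vs * diagmat(flips) * Vt.t();
    double sc = icp_descent(src, tgt, tag_src, tag_tgt, tagged, A0,
                            max_iter, tol);
    if (sc < best) best = sc;
  }
  // random restarts
  for (int tr = 0; tr < n_tries; ++tr) {
    mat Gs(d, d);
    for (uword j = 0; j < d; ++j)
      for (uword i = 0; i < d; ++i) Gs(i, j) = R::norm_rand();
    mat Q, R;
    qr(Q, R, Gs);                         // Haar-distributed orthogonal init
    Q = Q * diagmat(sign(R.diag()));
    double sc = icp_descent(src, tgt, tag_src, tag_tgt, tagged, Q,
                            max_iter, tol);
    if (sc < best) best = sc;
  }
  return best;
}
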