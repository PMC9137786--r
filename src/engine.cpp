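// Fused forward/backward training kernels for the two forecaster
// architectures. The R engine (R/nnet_engine.R) defines the reference
// semantics and keeps the activation-hook path used by the quantization
// emulation; these kernels compute the identical arithmetic without R-level
// allocation overhead and are used for training and plain prediction.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline void relu_inplace(mat& x) { x.elem(find(x < 0)).zeros(); }

// im2col for a (M x T x C) cube with kernel width k -> (M*Tout x k*C),
// column index c*k + j (matches the W layout used by the R engine)
static mat im2col(const cube& A, int k) {
  const int M = A.n_rows, T = A.n_cols, C = A.n_slices, Tout = T - k + 1;
  mat out(M * Tout, k * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      out.col(c * k + j) = vectorise(A.slice(c).cols(j, j + Tout - 1));
  return out;
}

static cube col2im(const mat& dcol, int M, int T, int C, int k) {
  const int Tout = T - k + 1;
  cube dA(M, T, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j) {
      const mat m(const_cast<double*>(dcol.colptr(c * k + j)), M, Tout,
                  false, true);
      dA.slice(c).cols(j, j + Tout - 1) += m;
    }
  return dA;
}

// pairwise max pooling over the time axis; ties keep the earlier element
static cube pool_fwd(const cube& A, ucube& mask) {
  const int M = A.n_rows, T = A.n_cols, C = A.n_slices, P = T / 2;
  cube out(M, P, C);
  mask.set_size(M, P, C);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p)
      for (int m = 0; m < M; ++m) {
        const double a = A(m, 2 * p, c), b = A(m, 2 * p + 1, c);
        const bool first = a >= b;
        mask(m, p, c) = first;
        out(m, p, c) = first ? a : b;
      }
  return out;
}

static cube pool_bwd(const cube& d, const ucube& mask, int T) {
  const int M = d.n_rows, P = d.n_cols, C = d.n_slices;
  cube dA(M, T, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < P; ++p)
      for (int m = 0; m < M; ++m) {
        if (mask(m, p, c)) dA(m, 2 * p, c) = d(m, p, c);
        else dA(m, 2 * p + 1, c) = d(m, p, c);
      }
  return dA;
}

struct CnnFwd {
  mat M1, Z1, M2, Z2, Xf, Zd, Ad;
  cube P1, P2;
  ucube mask1, mask2;
  vec pred;
  int T1, T2, P1len, P2len;
};

// X: (N, 3, T) cube; feature rows fold into the batch axis so kernels mix
// only timestamps within one feature row
static void cnn_forward(const mat& W1, const vec& b1, const mat& W2,
                        const vec& b2, const mat& Wd, const vec& bd,
                        const mat& Wo, const vec& bo, const cube& X,
                        CnnFwd& s) {
  const int N = X.n_rows, T = X.n_slices, k = W1.n_rows;
  const int F1 = W1.n_cols, F2 = W2.n_cols, M = N * 3;
  const cube A0(const_cast<double*>(X.memptr()), M, T, 1, false, true);
  s.T1 = T - k + 1;
  s.M1 = im2col(A0, k);
  s.Z1 = s.M1 * W1;
  s.Z1.each_row() += b1.t();
  mat A1 = s.Z1;
  relu_inplace(A1);
  const cube A1c(A1.memptr(), M, s.T1, F1, false, true);
  s.P1 = pool_fwd(A1c, s.mask1);
  s.P1len = s.P1.n_cols;
  s.T2 = s.P1len - k + 1;
  s.M2 = im2col(s.P1, k);
  s.Z2 = s.M2 * W2;
  s.Z2.each_row() += b2.t();
  mat A2 = s.Z2;
  relu_inplace(A2);
  const cube A2c(A2.memptr(), M, s.T2, F2, false, true);
  s.P2 = pool_fwd(A2c, s.mask2);
  s.P2len = s.P2.n_cols;
  s.Xf = mat(s.P2.memptr(), N, 3 * s.P2len * F2);
  s.Zd = s.Xf * Wd;
  s.Zd.each_row() += bd.t();
  s.Ad = s.Zd;
  relu_inplace(s.Ad);
  s.pred = s.Ad * Wo + bo(0);
}

// [[Rcpp::export(".cnn_pred_cpp")]]
arma::vec cnn_pred_cpp(const arma::mat& W1, const arma::vec& b1,
                       const arma::mat& W2, const arma::vec& b2,
                       const arma::mat& Wd, const arma::vec& bd,
                       const arma::mat& Wo, const arma::vec& bo,
                       const arma::cube& X) {
  CnnFwd s;
  cnn_forward(W1, b1, W2, b2, Wd, bd, Wo, bo, X, s);
  return s.pred;
}

// [[Rcpp::export(".cnn_grad_cpp")]]
Rcpp::List cnn_grad_cpp(const arma::mat& W1, const arma::vec& b1,
                        const arma::mat& W2, const arma::vec& b2,
                        const arma::mat& Wd, const arma::vec& bd,
                        const arma::mat& Wo, const arma::vec& bo,
                        const arma::cube& X, const arma::vec& y) {
  CnnFwd s;
  cnn_forward(W1, b1, W2, b2, Wd, bd, Wo, bo, X, s);
  const int N = X.n_rows, k = W1.n_rows;
  const int F1 = W1.n_cols, F2 = W2.n_cols, M = N * 3;
  const vec err = s.pred - y;
  const double loss = dot(err, err) / N;
  const vec dpred = 2.0 * err / N;

  const mat dWo = s.Ad.t() * dpred;
  const double dbo = accu(dpred);
  mat dZd = dpred * Wo.t();
  dZd.elem(find(s.Zd <= 0)).zeros();
  const mat dWd = s.Xf.t() * dZd;
  const vec dbd = sum(dZd, 0).t();
  mat dXf = dZd * Wd.t();
  const cube dP2(dXf.memptr(), M, s.P2len, F2, false, true);
  cube dA2 = pool_bwd(dP2, s.mask2, s.T2);
  mat dZ2(dA2.memptr(), M * s.T2, F2, false, true);
  dZ2.elem(find(s.Z2 <= 0)).zeros();
  const mat dW2 = s.M2.t() * dZ2;
  const vec db2 = sum(dZ2, 0).t();
  const mat dcol2 = dZ2 * W2.t();
  cube dP1 = col2im(dcol2, M, s.P1len, F1, k);
  cube dA1 = pool_bwd(dP1, s.mask1, s.T1);
  mat dZ1(dA1.memptr(), M * s.T1, F1, false, true);
  dZ1.elem(find(s.Z1 <= 0)).zeros();
  const mat dW1 = s.M1.t() * dZ1;
  const vec db1 = sum(dZ1, 0).t();

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
    Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
    Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd,
    Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
}

struct LstmFwd {
  cube I, F, G, O, Cc, Tc;   // gate activations and cell states per step
  cube Hall;                 // hidden states, slice t = h_{t-1}
  mat Zd, Ad, h;
  vec pred;
};

// X: (N, F, T) cube; gate block order: input, forget, candidate, output
static void lstm_forward(const mat& Wx, const mat& Wh, const vec& b,
                         const mat& Wd, const vec& bd, const mat& Wo,
                         const vec& bo, const cube& X, LstmFwd& s,
                         bool keep) {
  const int N = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  if (keep) {
    s.I.set_size(N, H, T); s.F.set_size(N, H, T); s.G.set_size(N, H, T);
    s.O.set_size(N, H, T); s.Cc.set_size(N, H, T); s.Tc.set_size(N, H, T);
    s.Hall.set_size(N, H, T);
  }
  for (int t = 0; t < T; ++t) {
    if (keep) s.Hall.slice(t) = h;
    mat A = X.slice(t) * Wx + h * Wh;
    A.each_row() += b.t();
    const mat i = sigmoid_m(A.cols(0, H - 1));
    const mat f = sigmoid_m(A.cols(H, 2 * H - 1));
    const mat g = tanh(A.cols(2 * H, 3 * H - 1));
    const mat o = sigmoid_m(A.cols(3 * H, 4 * H - 1));
    if (keep) s.Cc.slice(t) = c;       // c_{t-1}
    c = f % c + i % g;
    const mat tc = tanh(c);
    h = o % tc;
    if (keep) {
      s.I.slice(t) = i; s.F.slice(t) = f; s.G.slice(t) = g;
      s.O.slice(t) = o; s.Tc.slice(t) = tc;
    }
  }
  s.h = h;
  s.Zd = h * Wd;
  s.Zd.each_row() += bd.t();
  s.Ad = s.Zd;
  relu_inplace(s.Ad);
  s.pred = s.Ad * Wo + bo(0);
}

// [[Rcpp::export(".lstm_pred_cpp")]]
arma::vec lstm_pred_cpp(const arma::mat& Wx, const arma::mat& Wh,
                        const arma::vec& b, const arma::mat& Wd,
                        const arma::vec& bd, const arma::mat& Wo,
                        const arma::vec& bo, const arma::cube& X) {
  LstmFwd s;
  lstm_forward(Wx, Wh, b, Wd, bd, Wo, bo, X, s, false);
  return s.pred;
}

// [[Rcpp::export(".lstm_grad_cpp")]]
Rcpp::List lstm_grad_cpp(const arma::mat& Wx, const arma::mat& Wh,
                         const arma::vec& b, const arma::mat& Wd,
                         const arma::vec& bd, const arma::mat& Wo,
                         const arma::vec& bo, const arma::cube& X,
                         const arma::vec& y) {
  LstmFwd s;
  lstm_forward(Wx, Wh, b, Wd, bd, Wo, bo, X, s, true);
  const int N = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  const vec err = s.pred - y;
  const double loss = dot(err, err) / N;
  const vec dpred = 2.0 * err / N;

  const mat dWo = s.Ad.t() * dpred;
  const double dbo = accu(dpred);
  mat dZd = dpred * Wo.t();
  dZd.elem(find(s.Zd <= 0)).zeros();
  const mat dWd = s.h.t() * dZd;
  const vec dbd = sum(dZd, 0).t();
  mat dh = dZd * Wd.t();
  mat dc(N, H, fill::zeros);
  mat dWx(Wx.n_rows, 4 * H, fill::zeros);
  mat dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dA(N, 4 * H);
  for (int t = T - 1; t >= 0; --t) {
    const mat& i = s.I.slice(t);
    const mat& f = s.F.slice(t);
    const mat& g = s.G.slice(t);
    const mat& o = s.O.slice(t);
    const mat& tc = s.Tc.slice(t);
    const mat& c_prev = s.Cc.slice(t);
    const mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    dA.cols(0, H - 1) = (dc % g) % i % (1.0 - i);
    dA.cols(H, 2 * H - 1) = (dc % c_prev) % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dWx += X.slice(t).t() * dA;
    dWh += s.Hall.slice(t).t() * dA;
    db += sum(dA, 0).t();
    dh = dA * Wh.t();
    dc = dc % f;
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("Wx") = dWx, Rcpp::Named("Wh") = dWh, Rcpp::Named("b") = db,
    Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd,
    Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
}
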