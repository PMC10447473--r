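// Recurrent amortized posterior approximator.
//
// Architecture: a single LSTM consumes the encoded observation sequence;
// at every prefix length t its hidden state h_t conditions a Gaussian
// posterior head factorized ancestrally as q(eta | h_t) q(theta_t | h_t, eta)
// (diagonal Gaussians in standardized, transformed parameter space).
// The training criterion is the mean over a batch of simulated records of
// -sum_t log q(theta_t, eta | x_{1:t}), whose gradient is computed here by
// backpropagation through time.
//
// Parameter vector layout (column-major, fixed order; dims = n_in, H, H2,
// d, k): Wx(4H x n_in), Wh(4H x H), b(4H), W1(H2 x H), b1(H2),
// Wm_eta(k x H2), bm_eta(k), Ws_eta(k x H2), bs_eta(k),
// W2(H2 x (H2+k)), b2(H2), Wm_th(d x H2), bm_th(d), Ws_th(d x H2),
// bs_th(d). Gate row blocks of the LSTM: input, forget, output, candidate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;
static const double S_CLAMP = 7.0;

struct Params {
  mat Wx, Wh, W1, Wm_e, Ws_e, W2, Wm_t, Ws_t;
  vec b, b1, bm_e, bs_e, b2, bm_t, bs_t;
};

static int par_len(int n_in, int H, int H2, int d, int k) {
  return 4 * H * n_in + 4 * H * H + 4 * H +
         H2 * H + H2 +
         k * H2 + k + k * H2 + k +
         H2 * (H2 + k) + H2 +
         d * H2 + d + d * H2 + d;
}

static Params unpack(const vec& p, int n_in, int H, int H2, int d, int k) {
  Params P;
  int o = 0;
  auto take_mat = [&](int r, int c) {
    mat M(p.memptr() + o, r, c); o += r * c; return M; };
  auto take_vec = [&](int r) {
    vec v(p.memptr() + o, r); o += r; return v; };
  P.Wx = take_mat(4 * H, n_in);
  P.Wh = take_mat(4 * H, H);
  P.b  = take_vec(4 * H);
  P.W1 = take_mat(H2, H);
  P.b1 = take_vec(H2);
  P.Wm_e = take_mat(k, H2);
  P.bm_e = take_vec(k);
  P.Ws_e = take_mat(k, H2);
  P.bs_e = take_vec(k);
  P.W2 = take_mat(H2, H2 + k);
  P.b2 = take_vec(H2);
  P.Wm_t = take_mat(d, H2);
  P.bm_t = take_vec(d);
  P.Ws_t = take_mat(d, H2);
  P.bs_t = take_vec(d);
  return P;
}

// pack gradients in the identical order
struct Grads {
  mat Wx, Wh, W1, Wm_e, Ws_e, W2, Wm_t, Ws_t;
  vec b, b1, bm_e, bs_e, b2, bm_t, bs_t;
  Grads(int n_in, int H, int H2, int d, int k) :
    Wx(4 * H, n_in, fill::zeros), Wh(4 * H, H, fill::zeros),
    W1(H2, H, fill::zeros),
    Wm_e(k, H2, fill::zeros), Ws_e(k, H2, fill::zeros),
    W2(H2, H2 + k, fill::zeros),
    Wm_t(d, H2, fill::zeros), Ws_t(d, H2, fill::zeros),
    b(4 * H, fill::zeros), b1(H2, fill::zeros),
    bm_e(k, fill::zeros), bs_e(k, fill::zeros), b2(H2, fill::zeros),
    bm_t(d, fill::zeros), bs_t(d, fill::zeros) {}
  vec pack() const {
    vec out(Wx.n_elem + Wh.n_elem + b.n_elem + W1.n_elem + b1.n_elem +
            Wm_e.n_elem + bm_e.n_elem + Ws_e.n_elem + bs_e.n_elem +
            W2.n_elem + b2.n_elem + Wm_t.n_elem + bm_t.n_elem +
            Ws_t.n_elem + bs_t.n_elem);
    int o = 0;
    auto put = [&](const mat& M) {
      std::copy(M.memptr(), M.memptr() + M.n_elem, out.memptr() + o);
      o += M.n_elem; };
    auto putv = [&](const vec& v) {
      std::copy(v.memptr(), v.memptr() + v.n_elem, out.memptr() + o);
      o += v.n_elem; };
    put(Wx); put(Wh); putv(b); put(W1); putv(b1);
    put(Wm_e); putv(bm_e); put(Ws_e); putv(bs_e);
    put(W2); putv(b2); put(Wm_t); putv(bm_t); put(Ws_t); putv(bs_t);
    return out;
  }
};

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Loss and gradient of the training criterion on one batch.
// X: (n_in x B x T) encoded observations; TH: (d x B x T) standardized
// theta targets; ETA: (k x B) standardized eta targets; tw: length-T 0/1
// weights over time steps (all ones unless subsampling).
// [[Rcpp::export]]
Rcpp::List cpp_nf_loss_grad(const arma::vec& par,
                            const arma::ivec& dims,
                            const arma::cube& X,
                            const arma::cube& TH,
                            const arma::mat& ETA,
                            const arma::vec& tw,
                            bool want_grad = true) {
  const int n_in = dims[0], H = dims[1], H2 = dims[2], d = dims[3],
            k = dims[4];
  const int B = X.n_cols, T = X.n_slices;
  if ((int)par.n_elem != par_len(n_in, H, H2, d, k))
    Rcpp::stop("parameter vector has wrong length");
  Params P = unpack(par, n_in, H, H2, d, k);

  cube Ic(H, B, T), Fc(H, B, T), Oc(H, B, T), Gc(H, B, T),
       Cc(H, B, T), Hc(H, B, T), Zc(H2, B, T), Z2c(H2, B, T);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  double loss = 0.0;

  for (int t = 0; t < T; ++t) {
    mat G = P.Wx * X.slice(t) + P.Wh * h_prev;
    G.each_col() += P.b;
    mat I = sigm(G.rows(0, H - 1));
    mat F = sigm(G.rows(H, 2 * H - 1));
    mat O = sigm(G.rows(2 * H, 3 * H - 1));
    mat Gg = tanh(G.rows(3 * H, 4 * H - 1));
    mat C = F % c_prev + I % Gg;
    mat Hs = O % tanh(C);
    Ic.slice(t) = I; Fc.slice(t) = F; Oc.slice(t) = O; Gc.slice(t) = Gg;
    Cc.slice(t) = C; Hc.slice(t) = Hs;
    h_prev = Hs; c_prev = C;

    mat Z = tanh(P.W1 * Hs + repmat(P.b1, 1, B));
    Zc.slice(t) = Z;
    mat U;
    if (k > 0) U = join_cols(Z, ETA); else U = Z;
    mat Z2 = tanh(P.W2 * U + repmat(P.b2, 1, B));
    Z2c.slice(t) = Z2;

    if (tw[t] == 0.0) continue;
    if (k > 0) {
      mat Mx = P.Wm_e * Z; Mx.each_col() += P.bm_e;
      mat Sx = P.Ws_e * Z; Sx.each_col() += P.bs_e;
      Sx = clamp(Sx, -S_CLAMP, S_CLAMP);
      mat R = ETA - Mx;
      loss += accu(Sx + 0.5 * square(R) % exp(-2.0 * Sx) +
                   0.5 * LOG2PI) / B;
    }
    mat Mt = P.Wm_t * Z2; Mt.each_col() += P.bm_t;
    mat St = P.Ws_t * Z2; St.each_col() += P.bs_t;
    St = clamp(St, -S_CLAMP, S_CLAMP);
    mat Rt = TH.slice(t) - Mt;
    loss += accu(St + 0.5 * square(Rt) % exp(-2.0 * St) +
                 0.5 * LOG2PI) / B;
  }

  if (!want_grad)
    return Rcpp::List::create(Rcpp::_["loss"] = loss);

  Grads G(n_in, H, H2, d, k);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat dHs = dh_next;
    if (tw[t] != 0.0) {
      const mat& Z = Zc.slice(t);
      const mat& Z2 = Z2c.slice(t);
      mat U;
      if (k > 0) U = join_cols(Z, ETA); else U = Z;
      // theta head (recompute mean/log-sd, cheap GEMMs)
      mat Mt = P.Wm_t * Z2; Mt.each_col() += P.bm_t;
      mat StRaw = P.Ws_t * Z2; StRaw.each_col() += P.bs_t;
      mat St = clamp(StRaw, -S_CLAMP, S_CLAMP);
      mat Rt = Mt - TH.slice(t);
      mat e2 = exp(-2.0 * St);
      mat dMt = Rt % e2 / B;
      mat dSt = (1.0 - square(Rt) % e2) / B;
      dSt.elem(find(abs(StRaw) > S_CLAMP)).zeros();
      G.Wm_t += dMt * Z2.t(); G.bm_t += sum(dMt, 1);
      G.Ws_t += dSt * Z2.t(); G.bs_t += sum(dSt, 1);
      mat dZ2 = P.Wm_t.t() * dMt + P.Ws_t.t() * dSt;
      mat dA2 = dZ2 % (1.0 - square(Z2));
      G.W2 += dA2 * U.t(); G.b2 += sum(dA2, 1);
      mat dU = P.W2.t() * dA2;
      mat dZ = dU.rows(0, H2 - 1);
      if (k > 0) {
        mat Mx = P.Wm_e * Z; Mx.each_col() += P.bm_e;
        mat SxRaw = P.Ws_e * Z; SxRaw.each_col() += P.bs_e;
        mat Sx = clamp(SxRaw, -S_CLAMP, S_CLAMP);
        mat Rx = Mx - ETA;
        mat ex2 = exp(-2.0 * Sx);
        mat dMx = Rx % ex2 / B;
        mat dSx = (1.0 - square(Rx) % ex2) / B;
        dSx.elem(find(abs(SxRaw) > S_CLAMP)).zeros();
        G.Wm_e += dMx * Z.t(); G.bm_e += sum(dMx, 1);
        G.Ws_e += dSx * Z.t(); G.bs_e += sum(dSx, 1);
        dZ += P.Wm_e.t() * dMx + P.Ws_e.t() * dSx;
      }
      mat dA1 = dZ % (1.0 - square(Z));
      G.W1 += dA1 * Hc.slice(t).t(); G.b1 += sum(dA1, 1);
      dHs += P.W1.t() * dA1;
    }
    // LSTM cell backward
    const mat& I = Ic.slice(t); const mat& F = Fc.slice(t);
    const mat& O = Oc.slice(t); const mat& Gg = Gc.slice(t);
    const mat& C = Cc.slice(t);
    mat tanC = tanh(C);
    mat c_prev_t = (t == 0) ? mat(H, B, fill::zeros) : Cc.slice(t - 1);
    mat h_prev_t = (t == 0) ? mat(H, B, fill::zeros) : Hc.slice(t - 1);
    mat dO = dHs % tanC % O % (1.0 - O);
    mat dC = dc_next + dHs % O % (1.0 - square(tanC));
    mat dI = dC % Gg % I % (1.0 - I);
    mat dF = dC % c_prev_t % F % (1.0 - F);
    mat dGg = dC % I % (1.0 - square(Gg));
    mat dGall = join_cols(join_cols(dI, dF), join_cols(dO, dGg));
    G.Wx += dGall * X.slice(t).t();
    G.Wh += dGall * h_prev_t.t();
    G.b  += sum(dGall, 1);
    dh_next = P.Wh.t() * dGall;
    dc_next = dC % F;
  }
  return Rcpp::List::create(Rcpp::_["loss"] = loss,
                            Rcpp::_["grad"] = G.pack());
}

// Forward pass returning all hidden states h_t (H x B x T).
// [[Rcpp::export]]
arma::cube cpp_lstm_hidden(const arma::vec& par,
                           const arma::ivec& dims,
                           const arma::cube& X) {
  const int n_in = dims[0], H = dims[1], H2 = dims[2], d = dims[3],
            k = dims[4];
  const int B = X.n_cols, T = X.n_slices;
  if ((int)par.n_elem != par_len(n_in, H, H2, d, k))
    Rcpp::stop("parameter vector has wrong length");
  Params P = unpack(par, n_in, H, H2, d, k);
  cube Hc(H, B, T);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat G = P.Wx * X.slice(t) + P.Wh * h_prev;
    G.each_col() += P.b;
    mat I = sigm(G.rows(0, H - 1));
    mat F = sigm(G.rows(H, 2 * H - 1));
    mat O = sigm(G.rows(2 * H, 3 * H - 1));
    mat Gg = tanh(G.rows(3 * H, 4 * H - 1));
    c_prev = F % c_prev + I % Gg;
    h_prev = O % tanh(c_prev);
    Hc.slice(t) = h_prev;
  }
  return Hc;
}

// [[Rcpp::export]]
int cpp_nf_par_len(const arma::ivec& dims) {
  return par_len(dims[0], dims[1], dims[2], dims[3], dims[4]);
}
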