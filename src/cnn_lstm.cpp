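// CNN-LSTM sequence classifier: 1-D convolution over one-hot DNA input,
// ReLU, max pooling, a masked LSTM pass over the pooled feature sequence
// (bidirectional when backward-direction weights are present), and a dense
// output head (1 sigmoid unit for binary tasks, K-way softmax for the
// family task). Hand-derived gradients; correctness is guarded by
// finite-difference tests in the package test suite.
//
// Parameter list layout (R side):
//   conv_W : (4*wf) x F   rows ordered j*4 + base (base A,C,G,T)
//   conv_b : F
//   Wx, Wh, b             forward-direction gates [input|forget|cell|output]
//   Wx_b, Wh_b, b_b       backward direction (optional)
//   W_out  : H x K (or 2H x K bidirectional)
//   b_out  : K
// Padded positions (code < 0) are dropped before encoding, so the
// recurrent pass only ever sees real sequence content; an empty sequence
// yields the bias-only output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct LstmWeights {
  arma::mat Wx, Wh;
  arma::vec b;
};

struct Params {
  arma::mat conv_W;
  arma::vec conv_b;
  LstmWeights fwd, bwd;
  bool bidir;
  arma::mat W_out;
  arma::vec b_out;
  int wf, F, H, K;
};

Params unpack(const List& params) {
  Params P;
  P.conv_W = as<arma::mat>(params["conv_W"]);
  P.conv_b = as<arma::vec>(params["conv_b"]);
  P.fwd.Wx = as<arma::mat>(params["Wx"]);
  P.fwd.Wh = as<arma::mat>(params["Wh"]);
  P.fwd.b = as<arma::vec>(params["b"]);
  P.bidir = params.containsElementNamed("Wx_b");
  if (P.bidir) {
    P.bwd.Wx = as<arma::mat>(params["Wx_b"]);
    P.bwd.Wh = as<arma::mat>(params["Wh_b"]);
    P.bwd.b = as<arma::vec>(params["b_b"]);
  }
  P.W_out = as<arma::mat>(params["W_out"]);
  P.b_out = as<arma::vec>(params["b_out"]);
  P.F = P.conv_W.n_cols;
  P.wf = P.conv_W.n_rows / 4;
  P.H = P.fwd.Wh.n_rows;
  P.K = P.W_out.n_cols;
  return P;
}

arma::mat onehot_row(const IntegerMatrix& codes, int row) {
  int L = 0;
  for (int j = 0; j < codes.ncol(); ++j) {
    int c = codes(row, j);
    if (c >= 0 && c <= 3) ++L;
  }
  arma::mat X(L, 4, arma::fill::zeros);
  int t = 0;
  for (int j = 0; j < codes.ncol(); ++j) {
    int c = codes(row, j);
    if (c >= 0 && c <= 3) X(t++, c) = 1.0;
  }
  return X;
}

arma::mat conv_forward(const arma::mat& X, const Params& P) {
  int L = X.n_rows;
  int T = L - P.wf + 1;
  if (T <= 0) return arma::mat(0, P.F);
  arma::mat Z(T, P.F);
  Z.each_row() = P.conv_b.t();
  for (int j = 0; j < P.wf; ++j) {
    Z += X.rows(j, j + T - 1) * P.conv_W.rows(4 * j, 4 * j + 3);
  }
  return Z;
}

void pool_forward(const arma::mat& A, int pool, arma::mat& Pm,
                  arma::umat& amax) {
  int T = A.n_rows, F = A.n_cols;
  int Tp = (T + pool - 1) / pool;
  Pm.set_size(Tp, F);
  amax.set_size(Tp, F);
  for (int tp = 0; tp < Tp; ++tp) {
    int lo = tp * pool, hi = std::min(T, lo + pool) - 1;
    for (int f = 0; f < F; ++f) {
      double best = A(lo, f);
      int arg = lo;
      for (int t = lo + 1; t <= hi; ++t) {
        if (A(t, f) > best) { best = A(t, f); arg = t; }
      }
      Pm(tp, f) = best;
      amax(tp, f) = arg;
    }
  }
}

struct LstmCache {
  arma::cube gates;   // B x 4H x Tmax (post-activation)
  arma::cube h_all;   // B x H x (Tmax + 1)
  arma::cube c_all;   // B x H x (Tmax + 1)
};

// Batched masked LSTM over pooled sequences of varying length; rows past a
// sequence's length hold their state.
arma::mat lstm_forward(const std::vector<arma::mat>& P_list,
                       const LstmWeights& W, int H, int F,
                       const std::vector<int>& Tp, int Tmax,
                       LstmCache* cache) {
  int B = P_list.size();
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  if (cache) {
    cache->gates.zeros(B, 4 * H, std::max(Tmax, 1));
    cache->h_all.zeros(B, H, std::max(Tmax, 1) + 1);
    cache->c_all.zeros(B, H, std::max(Tmax, 1) + 1);
  }
  for (int t = 0; t < Tmax; ++t) {
    arma::mat Xt(B, F, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      if (t < Tp[b]) Xt.row(b) = P_list[b].row(t);
    }
    arma::mat G = Xt * W.Wx + h * W.Wh;
    G.each_row() += W.b.t();
    arma::mat gi = 1.0 / (1.0 + arma::exp(-G.cols(0, H - 1)));
    arma::mat gf = 1.0 / (1.0 + arma::exp(-G.cols(H, 2 * H - 1)));
    arma::mat gg = arma::tanh(G.cols(2 * H, 3 * H - 1));
    arma::mat go = 1.0 / (1.0 + arma::exp(-G.cols(3 * H, 4 * H - 1)));
    arma::mat c_new = gf % c + gi % gg;
    arma::mat h_new = go % arma::tanh(c_new);
    for (int b = 0; b < B; ++b) {
      if (t >= Tp[b]) {
        c_new.row(b) = c.row(b);
        h_new.row(b) = h.row(b);
      }
    }
    if (cache) {
      cache->h_all.slice(t) = h;
      cache->c_all.slice(t) = c;
      arma::mat Gact(B, 4 * H);
      Gact.cols(0, H - 1) = gi;
      Gact.cols(H, 2 * H - 1) = gf;
      Gact.cols(2 * H, 3 * H - 1) = gg;
      Gact.cols(3 * H, 4 * H - 1) = go;
      cache->gates.slice(t) = Gact;
    }
    c = c_new;
    h = h_new;
  }
  if (cache) {
    cache->h_all.slice(Tmax) = h;
    cache->c_all.slice(Tmax) = c;
  }
  return h;
}

// Backpropagation through the masked LSTM; adds parameter gradients into
// dW and per-step input gradients into dP_list.
void lstm_backward(const std::vector<arma::mat>& P_list,
                   const LstmWeights& W, int H, int F,
                   const std::vector<int>& Tp, int Tmax,
                   const LstmCache& cache, arma::mat dh,
                   arma::mat& dWx, arma::mat& dWh, arma::vec& db,
                   std::vector<arma::mat>& dP_list) {
  int B = P_list.size();
  arma::mat dc(B, H, arma::fill::zeros);
  for (int t = Tmax - 1; t >= 0; --t) {
    const arma::mat& Gact = cache.gates.slice(t);
    arma::mat gi = Gact.cols(0, H - 1);
    arma::mat gf = Gact.cols(H, 2 * H - 1);
    arma::mat gg = Gact.cols(2 * H, 3 * H - 1);
    arma::mat go = Gact.cols(3 * H, 4 * H - 1);
    arma::mat c_prev = cache.c_all.slice(t);
    arma::mat c_new = cache.c_all.slice(t + 1);
    arma::mat h_prev = cache.h_all.slice(t);
    arma::mat tanh_c = arma::tanh(c_new);

    arma::vec active(B);
    for (int b = 0; b < B; ++b) active[b] = (t < Tp[b]) ? 1.0 : 0.0;
    arma::mat dh_act = dh, dc_act = dc;
    dh_act.each_col() %= active;
    dc_act.each_col() %= active;

    arma::mat d_o = dh_act % tanh_c;
    arma::mat dct = dc_act + dh_act % go % (1.0 - tanh_c % tanh_c);
    arma::mat d_i = dct % gg;
    arma::mat d_f = dct % c_prev;
    arma::mat d_g = dct % gi;
    arma::mat dc_prev = dct % gf;

    arma::mat dG(B, 4 * H);
    dG.cols(0, H - 1) = d_i % gi % (1.0 - gi);
    dG.cols(H, 2 * H - 1) = d_f % gf % (1.0 - gf);
    dG.cols(2 * H, 3 * H - 1) = d_g % (1.0 - gg % gg);
    dG.cols(3 * H, 4 * H - 1) = d_o % go % (1.0 - go);

    arma::mat Xt(B, F, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      if (t < Tp[b]) Xt.row(b) = P_list[b].row(t);
    }
    dWx += Xt.t() * dG;
    dWh += h_prev.t() * dG;
    db += arma::sum(dG, 0).t();

    arma::mat dXt = dG * W.Wx.t();
    for (int b = 0; b < B; ++b) {
      if (t < Tp[b]) dP_list[b].row(t) += dXt.row(b);
    }
    arma::mat pass = 1.0 - arma::repmat(active, 1, H);
    dh = dG * W.Wh.t() + dh % pass;
    dc = dc_prev + dc % pass;
  }
}

std::vector<arma::mat> reverse_rows(const std::vector<arma::mat>& P_list) {
  std::vector<arma::mat> out(P_list.size());
  for (size_t b = 0; b < P_list.size(); ++b) {
    out[b] = arma::flipud(P_list[b]);
  }
  return out;
}

// Shared convolution + pooling stage.
struct Encoded {
  std::vector<arma::mat> X_list, Z_list, P_list;
  std::vector<arma::umat> amax_list;
  std::vector<int> Tp;
  int Tmax = 0;
};

Encoded encode_batch(const IntegerMatrix& codes, const Params& P, int pool) {
  int B = codes.nrow();
  Encoded E;
  E.X_list.resize(B);
  E.Z_list.resize(B);
  E.P_list.resize(B);
  E.amax_list.resize(B);
  E.Tp.resize(B);
  for (int b = 0; b < B; ++b) {
    arma::mat X = onehot_row(codes, b);
    arma::mat Zpre = conv_forward(X, P);
    arma::mat Z = Zpre;
    Z.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::mat Pm;
    arma::umat amax;
    if (Z.n_rows > 0) pool_forward(Z, pool, Pm, amax);
    E.X_list[b] = X;
    E.Z_list[b] = Zpre;
    E.P_list[b] = Pm;
    E.amax_list[b] = amax;
    E.Tp[b] = Pm.n_rows;
    E.Tmax = std::max(E.Tmax, E.Tp[b]);
  }
  return E;
}

arma::mat head_forward(const Encoded& E, const Params& P,
                       LstmCache* cf, LstmCache* cb,
                       std::vector<arma::mat>* P_rev_out) {
  int B = E.P_list.size();
  arma::mat h = lstm_forward(E.P_list, P.fwd, P.H, P.F, E.Tp, E.Tmax, cf);
  arma::mat hcat = h;
  if (P.bidir) {
    std::vector<arma::mat> P_rev = reverse_rows(E.P_list);
    arma::mat hb = lstm_forward(P_rev, P.bwd, P.H, P.F, E.Tp, E.Tmax, cb);
    hcat = arma::join_rows(h, hb);
    if (P_rev_out) *P_rev_out = P_rev;
  }
  arma::mat logits = hcat * P.W_out;
  logits.each_row() += P.b_out.t();
  (void)B;
  return logits;
}

}  // namespace

// Forward pass returning logits (B x K).
// [[Rcpp::export]]
arma::mat nn_logits_cpp(IntegerMatrix codes, List params, int pool) {
  Params P = unpack(params);
  Encoded E = encode_batch(codes, P, pool);
  return head_forward(E, P, nullptr, nullptr, nullptr);
}

// Loss and parameter gradients for one batch.
// task 0: binary cross entropy on a single sigmoid unit (y in {0,1}).
// task 1: weighted categorical cross entropy over K softmax classes.
// [[Rcpp::export]]
List nn_batch_grad_cpp(IntegerMatrix codes, List params, int pool,
                       NumericVector y, NumericVector w, int task,
                       bool compute_grads) {
  Params P = unpack(params);
  int B = codes.nrow(), H = P.H, F = P.F;
  Encoded E = encode_batch(codes, P, pool);

  LstmCache cache_f, cache_b;
  std::vector<arma::mat> P_rev;
  arma::mat logits = head_forward(E, P, &cache_f, &cache_b, &P_rev);
  arma::mat hcat(B, P.bidir ? 2 * H : H);
  hcat.cols(0, H - 1) = cache_f.h_all.slice(E.Tmax);
  if (P.bidir) hcat.cols(H, 2 * H - 1) = cache_b.h_all.slice(E.Tmax);

  double loss = 0.0;
  arma::mat dlogits(B, P.K, arma::fill::zeros);
  double wsum = 0.0;
  for (int b = 0; b < B; ++b) wsum += w[b];
  if (wsum <= 0) wsum = 1.0;
  if (task == 0) {
    for (int b = 0; b < B; ++b) {
      double z = logits(b, 0);
      double l = std::max(z, 0.0) - z * y[b] + std::log1p(std::exp(-std::fabs(z)));
      loss += w[b] * l;
      double p = 1.0 / (1.0 + std::exp(-z));
      dlogits(b, 0) = w[b] * (p - y[b]) / wsum;
    }
    loss /= wsum;
  } else {
    for (int b = 0; b < B; ++b) {
      arma::rowvec z = logits.row(b);
      double m = z.max();
      arma::rowvec e = arma::exp(z - m);
      double s = arma::accu(e);
      arma::rowvec p = e / s;
      int cls = (int)y[b];
      loss += -w[b] * (z[cls] - m - std::log(s));
      dlogits.row(b) = w[b] * p / wsum;
      dlogits(b, cls) -= w[b] / wsum;
    }
    loss /= wsum;
  }

  List out = List::create(_["loss"] = loss, _["logits"] = logits);
  if (!compute_grads) return out;

  arma::mat dW_out = hcat.t() * dlogits;
  arma::vec db_out = arma::sum(dlogits, 0).t();
  arma::mat dhcat = dlogits * P.W_out.t();

  arma::mat dWx(arma::size(P.fwd.Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(P.fwd.Wh), arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  std::vector<arma::mat> dP_list(B);
  for (int b = 0; b < B; ++b) dP_list[b].zeros(E.Tp[b], F);

  lstm_backward(E.P_list, P.fwd, H, F, E.Tp, E.Tmax, cache_f,
                dhcat.cols(0, H - 1), dWx, dWh, db, dP_list);

  arma::mat dWx_b, dWh_b;
  arma::vec db_b;
  if (P.bidir) {
    dWx_b.zeros(arma::size(P.bwd.Wx));
    dWh_b.zeros(arma::size(P.bwd.Wh));
    db_b.zeros(4 * H);
    std::vector<arma::mat> dP_rev(B);
    for (int b = 0; b < B; ++b) dP_rev[b].zeros(E.Tp[b], F);
    lstm_backward(P_rev, P.bwd, H, F, E.Tp, E.Tmax, cache_b,
                  dhcat.cols(H, 2 * H - 1), dWx_b, dWh_b, db_b, dP_rev);
    for (int b = 0; b < B; ++b) dP_list[b] += arma::flipud(dP_rev[b]);
  }

  arma::mat dconv_W(arma::size(P.conv_W), arma::fill::zeros);
  arma::vec dconv_b(P.F, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    int T = E.Z_list[b].n_rows;
    if (T == 0) continue;
    arma::mat dA(T, F, arma::fill::zeros);
    const arma::umat& amax = E.amax_list[b];
    for (int tp = 0; tp < E.Tp[b]; ++tp) {
      for (int f = 0; f < F; ++f) {
        dA(amax(tp, f), f) += dP_list[b](tp, f);
      }
    }
    arma::mat relu_mask = arma::conv_to<arma::mat>::from(E.Z_list[b] > 0);
    arma::mat dZ = dA % relu_mask;
    dconv_b += arma::sum(dZ, 0).t();
    const arma::mat& X = E.X_list[b];
    for (int j = 0; j < P.wf; ++j) {
      dconv_W.rows(4 * j, 4 * j + 3) += X.rows(j, j + T - 1).t() * dZ;
    }
  }

  List grads = List::create(
      _["conv_W"] = dconv_W, _["conv_b"] = dconv_b, _["Wx"] = dWx,
      _["Wh"] = dWh, _["b"] = db, _["W_out"] = dW_out, _["b_out"] = db_out);
  if (P.bidir) {
    grads["Wx_b"] = dWx_b;
    grads["Wh_b"] = dWh_b;
    grads["b_b"] = db_b;
  }
  out["grads"] = grads;
  return out;
}

// Forward pass on a dense (possibly fractional) one-hot matrix plus the
// gradient of one output logit with respect to the input. Used by the
// integrated-gradients attribution path.
// [[Rcpp::export]]
List nn_input_grad_cpp(arma::mat X, List params, int pool, int class_idx) {
  Params P = unpack(params);
  int F = P.F, H = P.H;
  arma::mat Zpre = conv_forward(X, P);
  arma::mat Z = Zpre;
  Z.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::mat Pm;
  arma::umat amax;
  if (Z.n_rows > 0) pool_forward(Z, pool, Pm, amax);
  std::vector<arma::mat> P_list{Pm};
  std::vector<int> Tp{(int)Pm.n_rows};
  LstmCache cache_f, cache_b;
  std::vector<arma::mat> P_rev;
  arma::mat h = lstm_forward(P_list, P.fwd, H, F, Tp, Tp[0], &cache_f);
  arma::mat hcat = h;
  if (P.bidir) {
    P_rev = reverse_rows(P_list);
    arma::mat hb = lstm_forward(P_rev, P.bwd, H, F, Tp, Tp[0], &cache_b);
    hcat = arma::join_rows(h, hb);
  }
  arma::mat logits = hcat * P.W_out;
  logits.each_row() += P.b_out.t();

  arma::mat dlogits(1, P.K, arma::fill::zeros);
  dlogits(0, class_idx) = 1.0;
  arma::mat dhcat = dlogits * P.W_out.t();

  arma::mat dWx(arma::size(P.fwd.Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(P.fwd.Wh), arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  std::vector<arma::mat> dP_list{arma::mat(Tp[0], F, arma::fill::zeros)};
  lstm_backward(P_list, P.fwd, H, F, Tp, Tp[0], cache_f,
                dhcat.cols(0, H - 1), dWx, dWh, db, dP_list);
  if (P.bidir) {
    arma::mat dWx_b(arma::size(P.bwd.Wx), arma::fill::zeros);
    arma::mat dWh_b(arma::size(P.bwd.Wh), arma::fill::zeros);
    arma::vec db_b(4 * H, arma::fill::zeros);
    std::vector<arma::mat> dP_rev{arma::mat(Tp[0], F, arma::fill::zeros)};
    lstm_backward(P_rev, P.bwd, H, F, Tp, Tp[0], cache_b,
                  dhcat.cols(H, 2 * H - 1), dWx_b, dWh_b, db_b, dP_rev);
    dP_list[0] += arma::flipud(dP_rev[0]);
  }

  arma::mat dX(arma::size(X), arma::fill::zeros);
  int T = Zpre.n_rows;
  if (T > 0) {
    arma::mat dA(T, F, arma::fill::zeros);
    for (int tp = 0; tp < Tp[0]; ++tp) {
      for (int f = 0; f < F; ++f) dA(amax(tp, f), f) += dP_list[0](tp, f);
    }
    arma::mat relu_mask = arma::conv_to<arma::mat>::from(Zpre > 0);
    arma::mat dZ = dA % relu_mask;
    for (int j = 0; j < P.wf; ++j) {
      dX.rows(j, j + T - 1) += dZ * P.conv_W.rows(4 * j, 4 * j + 3).t();
    }
  }
  return List::create(_["logits"] = logits, _["dX"] = dX);
}
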