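// Batched forward/backward passes for the GRU and LSTM sequence classifiers.
//
// Cell conventions (kept exactly as in the screening model):
//   GRU:  z = sig(bz + Uz x + Wz h_prev)
//         r = sig(br + Ur x + Wr h_prev)
//         hc = tanh(bh + Uh x + Wh (r % h_prev))
//         h = z % h_prev + (1 - z) % hc          <- z gates the PREVIOUS state
//   LSTM: g,f,o = sig(b + U x + W h_prev)
//         sc = act(bc + Uc x + Wc h_prev)         <- act = sigmoid by default
//         s = f % s_prev + g % sc                    (tanh variant optional)
//         h = tanh(s) % o
// Loss: mean softmax cross-entropy + lambda * sum of squared weight
// matrices (U, W and the head V; biases excluded).
//
// For throughput on one core, input projections (U x + b) for all timesteps
// are computed as one matrix product per layer, the per-gate recurrent
// matrices are stacked so each timestep costs one or two products, and the
// weight-gradient accumulations over time collapse into single large
// products after the backward sweep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::span;

static inline mat sig(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// a = U x + W h + b (b broadcast across columns)
static inline mat affine(const mat& U, const mat& x, const mat& W,
                         const mat& h, const vec& b) {
  mat a = U * x + W * h;
  a.each_col() += b;
  return a;
}

// [[Rcpp::export]]
arma::mat gru_step_cpp(const arma::mat& x, const arma::mat& h_prev, List p) {
  mat Uz = p["Uz"], Ur = p["Ur"], Uh = p["Uh"];
  mat Wz = p["Wz"], Wr = p["Wr"], Wh = p["Wh"];
  vec bz = p["bz"], br = p["br"], bh = p["bh"];
  mat z = sig(affine(Uz, x, Wz, h_prev, bz));
  mat r = sig(affine(Ur, x, Wr, h_prev, br));
  mat hc = arma::tanh(affine(Uh, x, Wh, mat(r % h_prev), bh));
  return z % h_prev + (1.0 - z) % hc;
}

// [[Rcpp::export]]
List lstm_step_cpp(const arma::mat& x, const arma::mat& h_prev,
                   const arma::mat& s_prev, List p, bool cand_tanh) {
  mat Ug = p["Ug"], Uf = p["Uf"], Uo = p["Uo"], Uc = p["Uc"];
  mat Wg = p["Wg"], Wf = p["Wf"], Wo = p["Wo"], Wc = p["Wc"];
  vec bg = p["bg"], bf = p["bf"], bo = p["bo"], bc = p["bc"];
  mat g = sig(affine(Ug, x, Wg, h_prev, bg));
  mat f = sig(affine(Uf, x, Wf, h_prev, bf));
  mat o = sig(affine(Uo, x, Wo, h_prev, bo));
  mat a = affine(Uc, x, Wc, h_prev, bc);
  mat sc = cand_tanh ? mat(arma::tanh(a)) : sig(a);
  mat s = f % s_prev + g % sc;
  mat h = arma::tanh(s) % o;
  return List::create(_["h"] = h, _["s"] = s);
}

static mat softmax_cols(const mat& logits) {
  mat z = logits.each_row() - arma::max(logits, 0);
  mat e = arma::exp(z);
  return e.each_row() / arma::sum(e, 0);
}

// Stacked per-layer parameters.
struct GruP {
  mat Uall;   // [Uz; Ur; Uh]  (3H x I)
  mat Wzr;    // [Wz; Wr]      (2H x H)
  mat Wh;     //               (H x H)
  vec ball;   // [bz; br; bh]
  int H;
};
struct LstmP {
  mat Uall;   // [Ug; Uf; Uo; Uc] (4H x I)
  mat Wall;   // [Wg; Wf; Wo; Wc] (4H x H)
  vec ball;
  int H;
};

static GruP pack_gru(List p) {
  GruP q;
  mat Uz = p["Uz"], Ur = p["Ur"], Uh = p["Uh"];
  mat Wz = p["Wz"], Wr = p["Wr"], Wh = p["Wh"];
  vec bz = p["bz"], br = p["br"], bh = p["bh"];
  q.H = Wz.n_rows;
  q.Uall = arma::join_cols(Uz, Ur, Uh);
  q.Wzr = arma::join_cols(Wz, Wr);
  q.Wh = Wh;
  q.ball = arma::join_cols(bz, br, bh);
  return q;
}
static LstmP pack_lstm(List p) {
  LstmP q;
  mat Ug = p["Ug"], Uf = p["Uf"], Uo = p["Uo"], Uc = p["Uc"];
  mat Wg = p["Wg"], Wf = p["Wf"], Wo = p["Wo"], Wc = p["Wc"];
  vec bg = p["bg"], bf = p["bf"], bo = p["bo"], bc = p["bc"];
  q.H = Wg.n_rows;
  q.Uall = arma::join_cols(arma::join_cols(Ug, Uf), arma::join_cols(Uo, Uc));
  q.Wall = arma::join_cols(arma::join_cols(Wg, Wf), arma::join_cols(Wo, Wc));
  q.ball = arma::join_cols(arma::join_cols(bg, bf), arma::join_cols(bo, bc));
  return q;
}

// [[Rcpp::export]]
List rnn_batch_cpp(const arma::mat& Xb, const arma::ivec& y, List layers,
                   const arma::mat& V, const arma::vec& cvec,
                   std::string type, int in_dim, double lambda,
                   bool cand_tanh, bool want_grads) {
  const int B = Xb.n_rows, L = Xb.n_cols;
  if (L % in_dim != 0) stop("frame length %d not divisible by in_dim %d", L, in_dim);
  const int T = L / in_dim;
  const int n_layers = layers.size();
  const bool is_gru = (type == "gru");
  const int N = B * T;

  // time-major input matrix: column t*B + b holds x_t for case b
  mat X(in_dim, N);
  for (int t = 0; t < T; ++t)
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < in_dim; ++k)
        X(k, t * B + b) = Xb(b, t * in_dim + k);

  std::vector<GruP> gp; std::vector<LstmP> lp;
  for (int l = 0; l < n_layers; ++l) {
    if (is_gru) gp.push_back(pack_gru(layers[l]));
    else lp.push_back(pack_lstm(layers[l]));
  }

  // caches per layer (kept only when gradients are wanted)
  std::vector<mat> Hs(n_layers);            // hidden sequences (H x N)
  std::vector<mat> Gates(n_layers);         // gate activations (3H or 4H x N)
  std::vector<mat> Ss(n_layers);            // LSTM cell states (H x N)

  mat cur = X;                              // input to current layer (I x N)
  std::vector<mat> layer_inputs(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    if (want_grads) layer_inputs[l] = cur;
    const int H = is_gru ? gp[l].H : lp[l].H;
    mat Hseq(H, N);
    if (is_gru) {
      const GruP& q = gp[l];
      mat P = q.Uall * cur;                 // 3H x N
      P.each_col() += q.ball;
      if (want_grads) Gates[l].set_size(3 * H, N);
      mat h(H, B, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        span cs(t * B, t * B + B - 1);
        mat azr = P(span(0, 2 * H - 1), cs) + q.Wzr * h;
        mat z = sig(azr.rows(0, H - 1));
        mat r = sig(azr.rows(H, 2 * H - 1));
        mat rh = r % h;
        mat hc = arma::tanh(P(span(2 * H, 3 * H - 1), cs) + q.Wh * rh);
        mat hn = z % h + (1.0 - z) % hc;
        if (want_grads) {
          Gates[l](span(0, H - 1), cs) = z;
          Gates[l](span(H, 2 * H - 1), cs) = r;
          Gates[l](span(2 * H, 3 * H - 1), cs) = hc;
        }
        Hseq.cols(t * B, t * B + B - 1) = hn;
        h = hn;
      }
    } else {
      const LstmP& q = lp[l];
      mat P = q.Uall * cur;                 // 4H x N
      P.each_col() += q.ball;
      if (want_grads) { Gates[l].set_size(4 * H, N); Ss[l].set_size(H, N); }
      mat h(H, B, arma::fill::zeros), s(H, B, arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        span cs(t * B, t * B + B - 1);
        mat a = P.cols(cs) + q.Wall * h;    // 4H x B
        mat g = sig(a.rows(0, H - 1));
        mat f = sig(a.rows(H, 2 * H - 1));
        mat o = sig(a.rows(2 * H, 3 * H - 1));
        mat ac = a.rows(3 * H, 4 * H - 1);
        mat sc = cand_tanh ? mat(arma::tanh(ac)) : sig(ac);
        mat sn = f % s + g % sc;
        mat hn = arma::tanh(sn) % o;
        if (want_grads) {
          Gates[l](span(0, H - 1), cs) = g;
          Gates[l](span(H, 2 * H - 1), cs) = f;
          Gates[l](span(2 * H, 3 * H - 1), cs) = o;
          Gates[l](span(3 * H, 4 * H - 1), cs) = sc;
          Ss[l].cols(t * B, t * B + B - 1) = sn;
        }
        Hseq.cols(t * B, t * B + B - 1) = hn;
        h = hn; s = sn;
      }
    }
    if (want_grads) Hs[l] = Hseq;
    cur = Hseq;
  }

  mat hT = cur.cols((T - 1) * B, N - 1);       // H x B
  mat logits = V * hT;
  logits.each_col() += cvec;
  mat probs = softmax_cols(logits);

  double ce = 0.0;
  for (int b = 0; b < B; ++b)
    ce -= std::log(std::max(probs(y[b] - 1, b), 1e-300));
  ce /= B;
  double l2 = 0.0;
  if (lambda > 0) {
    for (int l = 0; l < n_layers; ++l) {
      if (is_gru) l2 += arma::accu(gp[l].Uall % gp[l].Uall) +
                        arma::accu(gp[l].Wzr % gp[l].Wzr) +
                        arma::accu(gp[l].Wh % gp[l].Wh);
      else l2 += arma::accu(lp[l].Uall % lp[l].Uall) +
                 arma::accu(lp[l].Wall % lp[l].Wall);
    }
    l2 += arma::accu(V % V);
  }
  List out = List::create(_["loss"] = ce + lambda * l2, _["probs"] = probs.t());
  if (!want_grads) return out;

  // ----- backward -----
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) dlogits(y[b] - 1, b) -= 1.0;
  dlogits /= B;
  mat dV = dlogits * hT.t() + 2.0 * lambda * V;
  vec dc = arma::sum(dlogits, 1);
  mat dhT = V.t() * dlogits;
  mat dUpper;                                  // dL/d(input seq) of layer above

  List gl(n_layers);
  for (int l = n_layers - 1; l >= 0; --l) {
    const mat& In = layer_inputs[l];
    const int H = is_gru ? gp[l].H : lp[l].H;
    mat dh(H, B, arma::fill::zeros);
    if (l == n_layers - 1) dh = dhT;

    if (is_gru) {
      const GruP& q = gp[l];
      mat dA(3 * H, N);                        // [daz; dar; dac] per step
      mat RH(H, N);                            // r % h_prev per step (for dWh)
      for (int t = T - 1; t >= 0; --t) {
        span cs(t * B, t * B + B - 1);
        if (l < n_layers - 1) dh += dUpper.cols(cs);
        mat h_prev = (t == 0) ? mat(H, B, arma::fill::zeros)
                              : mat(Hs[l].cols((t - 1) * B, t * B - 1));
        mat z = Gates[l](span(0, H - 1), cs);
        mat r = Gates[l](span(H, 2 * H - 1), cs);
        mat hc = Gates[l](span(2 * H, 3 * H - 1), cs);
        mat daz = (dh % (h_prev - hc)) % z % (1.0 - z);
        mat dac = (dh % (1.0 - z)) % (1.0 - hc % hc);
        mat WhT_dac = q.Wh.t() * dac;
        mat dar = (WhT_dac % h_prev) % r % (1.0 - r);
        mat dazr = arma::join_cols(daz, dar);
        dA(span(0, 2 * H - 1), cs) = dazr;
        dA(span(2 * H, 3 * H - 1), cs) = dac;
        RH.cols(cs) = r % h_prev;
        dh = dh % z + q.Wzr.t() * dazr + WhT_dac % r;
      }
      // weight gradients as single products over all timesteps
      mat Hprev(H, N, arma::fill::zeros);
      if (T > 1) Hprev.cols(B, N - 1) = Hs[l].cols(0, N - B - 1);
      mat dUall = dA * In.t();                 // 3H x I
      mat dWzr = dA.rows(0, 2 * H - 1) * Hprev.t();
      mat dWh = dA.rows(2 * H, 3 * H - 1) * RH.t();
      vec db = arma::sum(dA, 1);
      List p = layers[l];
      mat Uz = p["Uz"], Ur = p["Ur"], Uh = p["Uh"];
      mat Wz = p["Wz"], Wr = p["Wr"];
      gl[l] = List::create(
        _["Uz"] = mat(dUall.rows(0, H - 1)) + 2.0 * lambda * Uz,
        _["Ur"] = mat(dUall.rows(H, 2 * H - 1)) + 2.0 * lambda * Ur,
        _["Uh"] = mat(dUall.rows(2 * H, 3 * H - 1)) + 2.0 * lambda * Uh,
        _["Wz"] = mat(dWzr.rows(0, H - 1)) + 2.0 * lambda * Wz,
        _["Wr"] = mat(dWzr.rows(H, 2 * H - 1)) + 2.0 * lambda * Wr,
        _["Wh"] = dWh + 2.0 * lambda * q.Wh,
        _["bz"] = vec(db.subvec(0, H - 1)),
        _["br"] = vec(db.subvec(H, 2 * H - 1)),
        _["bh"] = vec(db.subvec(2 * H, 3 * H - 1)));
      if (l > 0) dUpper = q.Uall.t() * dA;     // I x N
    } else {
      const LstmP& q = lp[l];
      mat dA(4 * H, N);
      mat ds(H, B, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        span cs(t * B, t * B + B - 1);
        if (l < n_layers - 1) dh += dUpper.cols(cs);
        mat h_prev = (t == 0) ? mat(H, B, arma::fill::zeros)
                              : mat(Hs[l].cols((t - 1) * B, t * B - 1));
        mat s_prev = (t == 0) ? mat(H, B, arma::fill::zeros)
                              : mat(Ss[l].cols((t - 1) * B, t * B - 1));
        mat g = Gates[l](span(0, H - 1), cs);
        mat f = Gates[l](span(H, 2 * H - 1), cs);
        mat o = Gates[l](span(2 * H, 3 * H - 1), cs);
        mat sc = Gates[l](span(3 * H, 4 * H - 1), cs);
        mat s = Ss[l].cols(t * B, t * B + B - 1);
        mat ts = arma::tanh(s);
        mat dao = (dh % ts) % o % (1.0 - o);
        ds += dh % o % (1.0 - ts % ts);
        mat daf = (ds % s_prev) % f % (1.0 - f);
        mat dag = (ds % sc) % g % (1.0 - g);
        mat dsc = ds % g;
        mat dac = cand_tanh ? mat(dsc % (1.0 - sc % sc))
                            : mat(dsc % sc % (1.0 - sc));
        mat da = arma::join_cols(arma::join_cols(dag, daf),
                                 arma::join_cols(dao, dac));
        dA.cols(cs) = da;
        dh = q.Wall.t() * da;
        ds = ds % f;
      }
      mat Hprev(H, N, arma::fill::zeros);
      if (T > 1) Hprev.cols(B, N - 1) = Hs[l].cols(0, N - B - 1);
      mat dUall = dA * In.t();
      mat dWall = dA * Hprev.t();
      vec db = arma::sum(dA, 1);
      List p = layers[l];
      mat Ug = p["Ug"], Uf = p["Uf"], Uo = p["Uo"], Uc = p["Uc"];
      mat Wg = p["Wg"], Wf = p["Wf"], Wo = p["Wo"], Wc = p["Wc"];
      gl[l] = List::create(
        _["Ug"] = mat(dUall.rows(0, H - 1)) + 2.0 * lambda * Ug,
        _["Uf"] = mat(dUall.rows(H, 2 * H - 1)) + 2.0 * lambda * Uf,
        _["Uo"] = mat(dUall.rows(2 * H, 3 * H - 1)) + 2.0 * lambda * Uo,
        _["Uc"] = mat(dUall.rows(3 * H, 4 * H - 1)) + 2.0 * lambda * Uc,
        _["Wg"] = mat(dWall.rows(0, H - 1)) + 2.0 * lambda * Wg,
        _["Wf"] = mat(dWall.rows(H, 2 * H - 1)) + 2.0 * lambda * Wf,
        _["Wo"] = mat(dWall.rows(2 * H, 3 * H - 1)) + 2.0 * lambda * Wo,
        _["Wc"] = mat(dWall.rows(3 * H, 4 * H - 1)) + 2.0 * lambda * Wc,
        _["bg"] = vec(db.subvec(0, H - 1)),
        _["bf"] = vec(db.subvec(H, 2 * H - 1)),
        _["bo"] = vec(db.subvec(2 * H, 3 * H - 1)),
        _["bc"] = vec(db.subvec(3 * H, 4 * H - 1)));
      if (l > 0) dUpper = q.Uall.t() * dA;
    }
  }

  out["grad_layers"] = gl;
  out["grad_V"] = dV;
  out["grad_c"] = dc;
  return out;
}
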