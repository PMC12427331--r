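// Encoder-only Transformer core: forward and analytic backward passes for
// the masked-token (MLM) and [CLS]-regression heads.  Post-norm layer
// ordering (MHSA + residual + LayerNorm, then FFN + residual + LayerNorm),
// learned absolute position embeddings, GELU activation (tanh form, whose
// derivative reuses the cached tanh and needs no further transcendentals).
// Attention is computed in key-major (transposed) layout so softmax and its
// backward run down contiguous columns.  The whole pass is templated on the
// working precision: single precision for training throughput, double
// precision for finite-difference gradient verification.  The optimiser and
// training loop live in R; this file computes losses, predictions,
// attention maps and gradients.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

template <typename eT> struct TF {

typedef arma::Mat<eT> mt;
typedef arma::Col<eT> ct;

static constexpr eT NEG_INF = (eT)-1e30;

struct Layer {
  mt Wq, Wk, Wv, Wo, W1, W2;
  ct bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

struct Model {
  int L, H, d, ffn, V, P;
  double dropout;
  mt tok_emb, pos_emb;
  ct emb_g, emb_b;
  std::vector<Layer> layers;
  mt mlm_W; ct mlm_b;
  mt cls_W1; ct cls_b1, cls_w2, cls_ln_g, cls_ln_b; eT cls_b2;
};

static mt getm(const List& p, const std::string& nm) {
  return arma::conv_to<mt>::from(as<arma::mat>(p[nm]));
}
static ct getv(const List& p, const std::string& nm) {
  return arma::conv_to<ct>::from(as<arma::vec>(p[nm]));
}

static Model load_model(const List& p, const List& config) {
  Model m;
  m.L = as<int>(config["n_layers"]);
  m.H = as<int>(config["n_heads"]);
  m.d = as<int>(config["d_model"]);
  m.ffn = as<int>(config["ffn_size"]);
  m.dropout = as<double>(config["dropout"]);
  m.tok_emb = getm(p, "tok_emb");
  m.pos_emb = getm(p, "pos_emb");
  m.V = m.tok_emb.n_rows;
  m.P = m.pos_emb.n_rows;
  m.emb_g = getv(p, "emb_ln_g");
  m.emb_b = getv(p, "emb_ln_b");
  char buf[64];
  for (int l = 0; l < m.L; ++l) {
    Layer lay;
    #define GETM(field) { snprintf(buf, 64, "l%d_%s", l + 1, #field); lay.field = getm(p, buf); }
    #define GETV(field) { snprintf(buf, 64, "l%d_%s", l + 1, #field); lay.field = getv(p, buf); }
    GETM(Wq) GETM(Wk) GETM(Wv) GETM(Wo) GETM(W1) GETM(W2)
    GETV(bq) GETV(bk) GETV(bv) GETV(bo) GETV(b1) GETV(b2)
    GETV(ln1_g) GETV(ln1_b) GETV(ln2_g) GETV(ln2_b)
    #undef GETM
    #undef GETV
    m.layers.push_back(lay);
  }
  m.mlm_W = getm(p, "mlm_W");
  m.mlm_b = getv(p, "mlm_b");
  m.cls_W1 = getm(p, "cls_W1");
  m.cls_b1 = getv(p, "cls_b1");
  m.cls_w2 = getv(p, "cls_w2");
  m.cls_ln_g = getv(p, "cls_ln_g");
  m.cls_ln_b = getv(p, "cls_ln_b");
  m.cls_b2 = (eT)as<double>(p["cls_b2"]);
  return m;
}

struct LayerGrad {
  mt Wq, Wk, Wv, Wo, W1, W2;
  ct bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

struct Grads {
  mt tok_emb, pos_emb;
  ct emb_g, emb_b;
  std::vector<LayerGrad> layers;
  mt mlm_W; ct mlm_b;
  mt cls_W1; ct cls_b1, cls_w2, cls_ln_g, cls_ln_b; eT cls_b2;
};

static Grads zero_grads(const Model& m) {
  Grads g;
  g.tok_emb.zeros(m.V, m.d);
  g.pos_emb.zeros(m.P, m.d);
  g.emb_g.zeros(m.d); g.emb_b.zeros(m.d);
  for (int l = 0; l < m.L; ++l) {
    LayerGrad lg;
    lg.Wq.zeros(m.d, m.d); lg.Wk.zeros(m.d, m.d);
    lg.Wv.zeros(m.d, m.d); lg.Wo.zeros(m.d, m.d);
    lg.W1.zeros(m.d, m.ffn); lg.W2.zeros(m.ffn, m.d);
    lg.bq.zeros(m.d); lg.bk.zeros(m.d); lg.bv.zeros(m.d); lg.bo.zeros(m.d);
    lg.b1.zeros(m.ffn); lg.b2.zeros(m.d);
    lg.ln1_g.zeros(m.d); lg.ln1_b.zeros(m.d);
    lg.ln2_g.zeros(m.d); lg.ln2_b.zeros(m.d);
    g.layers.push_back(lg);
  }
  g.mlm_W.zeros(m.d, m.V); g.mlm_b.zeros(m.V);
  g.cls_W1.zeros(m.d, m.d); g.cls_b1.zeros(m.d);
  g.cls_w2.zeros(m.d);
  g.cls_ln_g.zeros(m.d); g.cls_ln_b.zeros(m.d);
  g.cls_b2 = (eT)0;
  return g;
}

static SEXP outm(const mt& x) {
  return wrap(arma::conv_to<arma::mat>::from(x));
}
static SEXP outv(const ct& x) {
  return wrap(arma::conv_to<arma::vec>::from(x));
}

static List grads_to_list(const Model& m, const Grads& g) {
  List out;
  out["tok_emb"] = outm(g.tok_emb); out["pos_emb"] = outm(g.pos_emb);
  out["emb_ln_g"] = outv(g.emb_g); out["emb_ln_b"] = outv(g.emb_b);
  char buf[64];
  for (int l = 0; l < m.L; ++l) {
    #define PUTM(field) { snprintf(buf, 64, "l%d_%s", l + 1, #field); out[buf] = outm(g.layers[l].field); }
    #define PUTV(field) { snprintf(buf, 64, "l%d_%s", l + 1, #field); out[buf] = outv(g.layers[l].field); }
    PUTM(Wq) PUTM(Wk) PUTM(Wv) PUTM(Wo) PUTM(W1) PUTM(W2)
    PUTV(bq) PUTV(bk) PUTV(bv) PUTV(bo) PUTV(b1) PUTV(b2)
    PUTV(ln1_g) PUTV(ln1_b) PUTV(ln2_g) PUTV(ln2_b)
    #undef PUTM
    #undef PUTV
  }
  out["mlm_W"] = outm(g.mlm_W); out["mlm_b"] = outv(g.mlm_b);
  out["cls_W1"] = outm(g.cls_W1); out["cls_b1"] = outv(g.cls_b1);
  out["cls_w2"] = outv(g.cls_w2);
  out["cls_ln_g"] = outv(g.cls_ln_g); out["cls_ln_b"] = outv(g.cls_ln_b);
  out["cls_b2"] = (double)g.cls_b2;
  return out;
}

// ---- primitive ops --------------------------------------------------------

static mt ln_forward(const mt& X, const ct& g, const ct& b,
                     mt& xhat, ct& invstd) {
  ct mu = arma::mean(X, 1);
  mt Xc = X.each_col() - mu;
  ct v = arma::mean(arma::square(Xc), 1);
  invstd = (eT)1 / arma::sqrt(v + (eT)LN_EPS);
  xhat = Xc.each_col() % invstd;
  mt Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static mt ln_backward(const mt& dY, const mt& xhat, const ct& invstd,
                      const ct& g, ct& dg, ct& db) {
  dg += arma::sum(dY % xhat, 0).t();
  db += arma::sum(dY, 0).t();
  mt dxhat = dY.each_row() % g.t();
  ct m1 = arma::mean(dxhat, 1);
  ct m2 = arma::mean(dxhat % xhat, 1);
  mt dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= invstd;
  return dX;
}

// GELU, tanh formulation; T caches tanh(c*(x + a x^3)).
static void gelu_forward(mt& X, mt& T) {
  const eT C = (eT)0.7978845608028654, A = (eT)0.044715;
  T.set_size(X.n_rows, X.n_cols);
  eT* x = X.memptr(); eT* t = T.memptr();
  arma::uword n = X.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    eT xi = x[i];
    eT ti = std::tanh(C * (xi + A * xi * xi * xi));
    t[i] = ti;
    x[i] = (eT)0.5 * xi * ((eT)1 + ti);
  }
}

static void gelu_backward(mt& dG, const mt& X, const mt& T) {
  const eT C = (eT)0.7978845608028654, A = (eT)0.044715;
  eT* d = dG.memptr();
  const eT* x = X.memptr(); const eT* t = T.memptr();
  arma::uword n = dG.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    eT xi = x[i], ti = t[i];
    eT inner = C * ((eT)1 + (eT)3 * A * xi * xi);
    d[i] *= (eT)0.5 * ((eT)1 + ti) + (eT)0.5 * xi * ((eT)1 - ti * ti) * inner;
  }
}

// column-wise softmax in place (columns are attention rows in the
// transposed layout)
static void softmax_cols(mt& M) {
  arma::uword T = M.n_rows;
  for (arma::uword q = 0; q < M.n_cols; ++q) {
    eT* c = M.colptr(q);
    eT mx = c[0];
    for (arma::uword k = 1; k < T; ++k) if (c[k] > mx) mx = c[k];
    eT s = 0;
    for (arma::uword k = 0; k < T; ++k) { c[k] = std::exp(c[k] - mx); s += c[k]; }
    eT inv = (eT)1 / s;
    for (arma::uword k = 0; k < T; ++k) c[k] *= inv;
  }
}

static mt make_dropout_mask(int r, int c, double p, std::mt19937_64& rng) {
  mt M(r, c);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  eT s = (eT)(1.0 / (1.0 - p));
  eT* x = M.memptr();
  for (arma::uword i = 0; i < M.n_elem; ++i) x[i] = (U(rng) < p) ? (eT)0 : s;
  return M;
}

// ---- encoder forward/backward --------------------------------------------

struct LayerCache {
  mt Xin, Q, K, V, O, X1, Fh, Tanh;
  mt xhat1, xhat2;
  ct invstd1, invstd2;
  mt m1, m2;                          // dropout masks (empty when inactive)
  std::vector<arma::Cube<eT>> Pt;     // per batch element: T x T x H,
                                      // Pt(k, q) = attention(query q -> key k)
};

struct EncCache {
  int B, T;
  mt xhat_e; ct invstd_e; mt m_e;
  std::vector<LayerCache> layers;
  IntegerMatrix ids;
};

static mt encoder_forward(const Model& m, const IntegerMatrix& ids,
                          const NumericMatrix& attn, bool train,
                          std::mt19937_64& rng, EncCache& cache,
                          bool need_cache) {
  int B = ids.nrow(), T = ids.ncol();
  cache.B = B; cache.T = T; cache.ids = ids;
  bool drop = train && m.dropout > 0.0;
  int dh = m.d / m.H;
  eT scale = (eT)(1.0 / std::sqrt((double)dh));

  mt X(B * T, m.d);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      int id = ids(b, t);
      if (id < 0 || id >= m.V) stop("token id out of range");
      if (t >= m.P) stop("sequence longer than max_positions");
      X.row(b * T + t) = m.tok_emb.row(id) + m.pos_emb.row(t);
    }
  {
    mt xh; ct is;
    X = ln_forward(X, m.emb_g, m.emb_b, xh, is);
    if (need_cache) { cache.xhat_e = std::move(xh); cache.invstd_e = std::move(is); }
  }
  if (drop) {
    cache.m_e = make_dropout_mask(B * T, m.d, m.dropout, rng);
    X %= cache.m_e;
  }

  cache.layers.resize(m.L);
  mt Sbuf(T, T);
  for (int l = 0; l < m.L; ++l) {
    const Layer& ly = m.layers[l];
    LayerCache& lc = cache.layers[l];
    if (need_cache) lc.Xin = X;
    mt Q = X * ly.Wq; Q.each_row() += ly.bq.t();
    mt K = X * ly.Wk; K.each_row() += ly.bk.t();
    mt V = X * ly.Wv; V.each_row() += ly.bv.t();
    mt O(B * T, m.d);
    if (need_cache) lc.Pt.assign(B, arma::Cube<eT>());
    for (int b = 0; b < B; ++b) {
      ct neg(T);
      for (int t = 0; t < T; ++t) neg(t) = (attn(b, t) > 0.5) ? (eT)0 : NEG_INF;
      int r0 = b * T, r1 = b * T + T - 1;
      if (need_cache) lc.Pt[b].set_size(T, T, m.H);
      for (int h = 0; h < m.H; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        if (need_cache) {
          mt S(lc.Pt[b].slice_memptr(h), T, T, false, true);
          S = K.submat(r0, c0, r1, c1) * Q.submat(r0, c0, r1, c1).t() * scale;
          S.each_col() += neg;
          softmax_cols(S);
          O.submat(r0, c0, r1, c1) = S.t() * V.submat(r0, c0, r1, c1);
        } else {
          Sbuf = K.submat(r0, c0, r1, c1) * Q.submat(r0, c0, r1, c1).t() * scale;
          Sbuf.each_col() += neg;
          softmax_cols(Sbuf);
          O.submat(r0, c0, r1, c1) = Sbuf.t() * V.submat(r0, c0, r1, c1);
        }
      }
    }
    if (need_cache) {
      lc.Q = std::move(Q); lc.K = std::move(K); lc.V = std::move(V);
      lc.O = O;
    }
    mt AO = O * ly.Wo; AO.each_row() += ly.bo.t();
    if (drop) { lc.m1 = make_dropout_mask(B * T, m.d, m.dropout, rng); AO %= lc.m1; }
    AO += X;
    {
      mt xh; ct is;
      X = ln_forward(AO, ly.ln1_g, ly.ln1_b, xh, is);
      if (need_cache) { lc.xhat1 = std::move(xh); lc.invstd1 = std::move(is); }
    }
    if (need_cache) lc.X1 = X;
    mt F = X * ly.W1; F.each_row() += ly.b1.t();
    if (need_cache) lc.Fh = F;
    mt Tn;
    gelu_forward(F, Tn);          // F becomes the activation
    if (need_cache) lc.Tanh = std::move(Tn);
    mt F2 = F * ly.W2; F2.each_row() += ly.b2.t();
    if (drop) { lc.m2 = make_dropout_mask(B * T, m.d, m.dropout, rng); F2 %= lc.m2; }
    F2 += X;
    {
      mt xh; ct is;
      X = ln_forward(F2, ly.ln2_g, ly.ln2_b, xh, is);
      if (need_cache) { lc.xhat2 = std::move(xh); lc.invstd2 = std::move(is); }
    }
  }
  return X;
}

static void encoder_backward(const Model& m, const EncCache& cache,
                             mt dX, Grads& g) {
  int B = cache.B, T = cache.T;
  int dh = m.d / m.H;
  eT scale = (eT)(1.0 / std::sqrt((double)dh));
  mt dPt(T, T), dSt(T, T);
  for (int l = m.L - 1; l >= 0; --l) {
    const Layer& ly = m.layers[l];
    const LayerCache& lc = cache.layers[l];
    LayerGrad& lg = g.layers[l];
    // LN2
    mt dR2 = ln_backward(dX, lc.xhat2, lc.invstd2, ly.ln2_g,
                         lg.ln2_g, lg.ln2_b);
    mt dX1 = dR2;                       // residual branch
    mt dF2 = std::move(dR2);
    if (lc.m2.n_elem) dF2 %= lc.m2;
    // recompute the GELU activation from cached pre-activation + tanh
    mt G = lc.Fh;
    {
      eT* gp = G.memptr(); const eT* tp = lc.Tanh.memptr();
      for (arma::uword i = 0; i < G.n_elem; ++i)
        gp[i] = (eT)0.5 * gp[i] * ((eT)1 + tp[i]);
    }
    lg.W2 += G.t() * dF2;
    lg.b2 += arma::sum(dF2, 0).t();
    mt dG = dF2 * ly.W2.t();
    gelu_backward(dG, lc.Fh, lc.Tanh);   // dG becomes dFh
    lg.W1 += lc.X1.t() * dG;
    lg.b1 += arma::sum(dG, 0).t();
    dX1 += dG * ly.W1.t();
    // LN1
    mt dR1 = ln_backward(dX1, lc.xhat1, lc.invstd1, ly.ln1_g,
                         lg.ln1_g, lg.ln1_b);
    mt dXin = dR1;                      // residual branch
    mt dAO = std::move(dR1);
    if (lc.m1.n_elem) dAO %= lc.m1;
    lg.Wo += lc.O.t() * dAO;
    lg.bo += arma::sum(dAO, 0).t();
    mt dO = dAO * ly.Wo.t();
    mt dQ(B * T, m.d), dK(B * T, m.d), dV(B * T, m.d);
    for (int b = 0; b < B; ++b) {
      int r0 = b * T, r1 = b * T + T - 1;
      for (int h = 0; h < m.H; ++h) {
        int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mt Pt(const_cast<eT*>(lc.Pt[b].slice_memptr(h)), T, T,
                    false, true);
        mt dOb = dO.submat(r0, c0, r1, c1);
        // dPt(k,q) = <V_k, dO_q>
        dPt = lc.V.submat(r0, c0, r1, c1) * dOb.t();
        dV.submat(r0, c0, r1, c1) = Pt * dOb;
        // softmax backward down contiguous columns
        for (int q = 0; q < T; ++q) {
          const eT* pc = Pt.colptr(q);
          eT* dpc = dPt.colptr(q);
          eT* dsc = dSt.colptr(q);
          eT rs = 0;
          for (int k = 0; k < T; ++k) rs += dpc[k] * pc[k];
          for (int k = 0; k < T; ++k) dsc[k] = pc[k] * (dpc[k] - rs);
        }
        dQ.submat(r0, c0, r1, c1) = dSt.t() * lc.K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) = dSt * lc.Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    lg.Wq += lc.Xin.t() * dQ; lg.bq += arma::sum(dQ, 0).t();
    lg.Wk += lc.Xin.t() * dK; lg.bk += arma::sum(dK, 0).t();
    lg.Wv += lc.Xin.t() * dV; lg.bv += arma::sum(dV, 0).t();
    dXin += dQ * ly.Wq.t() + dK * ly.Wk.t() + dV * ly.Wv.t();
    dX = std::move(dXin);
  }
  if (cache.m_e.n_elem) dX %= cache.m_e;
  dX = ln_backward(dX, cache.xhat_e, cache.invstd_e, m.emb_g,
                   g.emb_g, g.emb_b);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      g.tok_emb.row(cache.ids(b, t)) += dX.row(b * T + t);
      g.pos_emb.row(t) += dX.row(b * T + t);
    }
}

// ---- tasks ----------------------------------------------------------------

static List run_encode(List params, IntegerMatrix ids, NumericMatrix attn,
                       List config, bool retain_attention) {
  Model m = load_model(params, config);
  std::mt19937_64 rng(0);
  EncCache cache;
  mt X = encoder_forward(m, ids, attn, false, rng, cache, retain_attention);
  List out;
  out["hidden"] = outm(X);
  out["B"] = cache.B; out["T"] = cache.T;
  if (retain_attention) {
    int B = cache.B, T = cache.T;
    List layers(m.L);
    for (int l = 0; l < m.L; ++l) {
      NumericVector a((R_xlen_t)T * T * m.H * B);
      a.attr("dim") = IntegerVector::create(T, T, m.H, B);
      R_xlen_t off = 0;
      for (int b = 0; b < B; ++b)
        for (int h = 0; h < m.H; ++h) {
          // export query-major: a[q, k, h, b] sums to 1 over k
          mt P = mt(const_cast<eT*>(cache.layers[l].Pt[b].slice_memptr(h)),
                    T, T, false, true).t();
          std::copy(P.begin(), P.end(), a.begin() + off);
          off += (R_xlen_t)T * T;
        }
      layers[l] = a;
    }
    out["attention"] = layers;
  }
  return out;
}

static List run_mlm(List params, IntegerMatrix ids, NumericMatrix attn,
                    IntegerMatrix labels, List config, bool train,
                    int seed, bool want_grads) {
  Model m = load_model(params, config);
  std::mt19937_64 rng((unsigned long long)seed);
  EncCache cache;
  mt X = encoder_forward(m, ids, attn, train, rng, cache, want_grads);
  int B = ids.nrow(), T = ids.ncol();
  std::vector<int> rows; std::vector<int> labs;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      if (labels(b, t) >= 0) {
        rows.push_back(b * T + t);
        labs.push_back(labels(b, t));
      }
  int M = rows.size();
  if (M == 0) stop("no labeled positions in batch");
  mt Hs(M, m.d);
  for (int i = 0; i < M; ++i) Hs.row(i) = X.row(rows[i]);
  mt logits = Hs * m.mlm_W;
  logits.each_row() += m.mlm_b.t();
  ct mx = arma::max(logits, 1);
  mt Z = logits.each_col() - mx;
  mt E = arma::exp(Z);
  ct sm = arma::sum(E, 1);
  double loss = 0.0;
  for (int i = 0; i < M; ++i)
    loss += -((double)Z(i, labs[i]) - std::log((double)sm(i)));
  loss /= M;
  List out; out["loss"] = loss; out["n_labeled"] = M;
  if (want_grads) {
    mt Pr = E.each_col() / sm;
    for (int i = 0; i < M; ++i) Pr(i, labs[i]) -= (eT)1;
    Pr /= (eT)M;
    Grads g = zero_grads(m);
    g.mlm_W = Hs.t() * Pr;
    g.mlm_b = arma::sum(Pr, 0).t();
    mt dHs = Pr * m.mlm_W.t();
    mt dX(B * T, m.d, arma::fill::zeros);
    for (int i = 0; i < M; ++i) dX.row(rows[i]) += dHs.row(i);
    encoder_backward(m, cache, dX, g);
    out["grads"] = grads_to_list(m, g);
  }
  return out;
}

static List run_reg(List params, IntegerMatrix ids, NumericMatrix attn,
                    NumericVector y, List config, bool train,
                    int seed, bool want_grads) {
  Model m = load_model(params, config);
  std::mt19937_64 rng((unsigned long long)seed);
  EncCache cache;
  mt X = encoder_forward(m, ids, attn, train, rng, cache, want_grads);
  int B = ids.nrow(), T = ids.ncol();
  mt Hc(B, m.d);
  for (int b = 0; b < B; ++b) Hc.row(b) = X.row(b * T);
  // LayerNorm ahead of the pooler standardises the [CLS] features, so the
  // tanh head starts in its linear regime whatever the encoder's training
  // history (a freshly initialised head on an MLM-trained encoder would
  // otherwise saturate)
  mt xhat_c; ct invstd_c;
  mt Hn = ln_forward(Hc, m.cls_ln_g, m.cls_ln_b, xhat_c, invstd_c);
  mt pre = Hn * m.cls_W1; pre.each_row() += m.cls_b1.t();
  mt Hh = arma::tanh(pre);
  ct yhat = Hh * m.cls_w2 + m.cls_b2;
  double loss = NA_REAL;
  if (y.size() == B) {
    loss = 0.0;
    for (int b = 0; b < B; ++b) loss += std::pow((double)yhat(b) - y[b], 2);
    loss /= B;
  }
  List out;
  out["loss"] = loss;
  NumericVector preds(B);
  for (int b = 0; b < B; ++b) preds[b] = (double)yhat(b);
  out["preds"] = preds;
  if (want_grads) {
    if (y.size() != B) stop("gradients need labels of length B");
    ct dyhat(B);
    for (int b = 0; b < B; ++b) dyhat(b) = (eT)(2.0 * ((double)yhat(b) - y[b]) / B);
    Grads g = zero_grads(m);
    g.cls_w2 = Hh.t() * dyhat;
    g.cls_b2 = arma::accu(dyhat);
    mt dHh = dyhat * m.cls_w2.t();
    mt dpre = dHh % ((eT)1 - arma::square(Hh));
    g.cls_W1 = Hn.t() * dpre;
    g.cls_b1 = arma::sum(dpre, 0).t();
    mt dHn = dpre * m.cls_W1.t();
    mt dHc = ln_backward(dHn, xhat_c, invstd_c, m.cls_ln_g,
                         g.cls_ln_g, g.cls_ln_b);
    mt dX(B * T, m.d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) dX.row(b * T) = dHc.row(b);
    encoder_backward(m, cache, dX, g);
    out["grads"] = grads_to_list(m, g);
  }
  return out;
}

}; // struct TF

// ---- entry points ---------------------------------------------------------

// [[Rcpp::export]]
List cpp_tf_encode(List params, IntegerMatrix ids, NumericMatrix attn,
                   List config, bool retain_attention = false,
                   bool single = true) {
  return single ? TF<float>::run_encode(params, ids, attn, config,
                                        retain_attention)
                : TF<double>::run_encode(params, ids, attn, config,
                                         retain_attention);
}

// [[Rcpp::export]]
List cpp_tf_mlm(List params, IntegerMatrix ids, NumericMatrix attn,
                IntegerMatrix labels, List config, bool train = true,
                int seed = 1, bool want_grads = true, bool single = true) {
  return single ? TF<float>::run_mlm(params, ids, attn, labels, config,
                                     train, seed, want_grads)
                : TF<double>::run_mlm(params, ids, attn, labels, config,
                                      train, seed, want_grads);
}

// [[Rcpp::export]]
List cpp_tf_reg(List params, IntegerMatrix ids, NumericMatrix attn,
                NumericVector y, List config, bool train = true,
                int seed = 1, bool want_grads = true, bool single = true) {
  return single ? TF<float>::run_reg(params, ids, attn, y, config, train,
                                     seed, want_grads)
                : TF<double>::run_reg(params, ids, attn, y, config, train,
                                      seed, want_grads);
}
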