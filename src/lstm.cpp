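// Recurrent fingerprint-to-concentration model: stacked LSTM over the
// wavelength sequence, mean pooling over steps, linear readout, softmax.
// Trained with AdamW on a Huber loss between predicted and true fractions.
// Single precision throughout: the minibatch loop dominates runtime and the
// gradients involved are well inside float range.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using arma::fmat;
using arma::frowvec;
using arma::fcube;
using arma::uword;

static inline fmat sigmoidf(const fmat& z) { return 1.0f / (1.0f + arma::exp(-z)); }

struct Layer {
  fmat Wx;      // D x 4H, gate order [i f g o]
  fmat Wh;      // H x 4H
  frowvec b;    // 4H
};

struct Params {
  std::vector<Layer> layers;
  fmat Wo;      // H x N
  frowvec bo;   // N
};

struct Adam {
  std::vector<Layer> m1, v1;   // per-layer first/second moments
  fmat mWo, vWo;
  frowvec mbo, vbo;
  long step = 0;
};

// cached forward activations for one layer over all steps
struct Cache {
  fcube I, F, G, O, C, TC, H;  // each B x Hd x K
};

static Params init_params(int D, int Hd, int L, int N, std::mt19937& rng) {
  Params p;
  float k = 1.0f / std::sqrt(static_cast<float>(Hd));
  std::uniform_real_distribution<float> u(-k, k);
  for (int l = 0; l < L; ++l) {
    int d = (l == 0) ? D : Hd;
    Layer ly;
    ly.Wx.set_size(d, 4 * Hd);
    ly.Wh.set_size(Hd, 4 * Hd);
    ly.b.set_size(4 * Hd);
    for (auto& v : ly.Wx) v = u(rng);
    for (auto& v : ly.Wh) v = u(rng);
    for (auto& v : ly.b) v = u(rng);
    // positive forget-gate bias helps early gradient flow
    ly.b.subvec(Hd, 2 * Hd - 1) += 1.0f;
    p.layers.push_back(std::move(ly));
  }
  p.Wo.set_size(Hd, N);
  p.bo.set_size(N);
  for (auto& v : p.Wo) v = u(rng);
  for (auto& v : p.bo) v = u(rng);
  return p;
}

// forward pass over a batch; fills caches when keep = true; returns softmax
// probabilities (B x N) and the pooled hidden state via hbar_out
static fmat forward(const Params& p, const fmat& X, const arma::fvec& wl,
                    int feat, std::vector<Cache>* caches, fmat& hbar_out) {
  const uword B = X.n_rows, K = X.n_cols;
  const int Hd = p.layers[0].Wh.n_rows;
  const int L = p.layers.size();
  fmat below;  // input to current layer at step t
  fmat hbar(B, Hd, arma::fill::zeros);

  // layer inputs for layer 0 are built per step from X and wl
  std::vector<fmat> hseq(K);  // output sequence of the current layer
  for (int l = 0; l < L; ++l) {
    const Layer& ly = p.layers[l];
    fmat h(B, Hd, arma::fill::zeros), c(B, Hd, arma::fill::zeros);
    Cache* cc = nullptr;
    if (caches) {
      Cache& ca = (*caches)[l];
      ca.I.set_size(B, Hd, K); ca.F.set_size(B, Hd, K); ca.G.set_size(B, Hd, K);
      ca.O.set_size(B, Hd, K); ca.C.set_size(B, Hd, K); ca.TC.set_size(B, Hd, K);
      ca.H.set_size(B, Hd, K);
      cc = &ca;
    }
    for (uword t = 0; t < K; ++t) {
      fmat xt;
      if (l == 0) {
        xt.set_size(B, feat);
        xt.col(0) = X.col(t);
        if (feat == 2) xt.col(1).fill(wl(t));
      } else {
        xt = hseq[t];
      }
      fmat Z = xt * ly.Wx + h * ly.Wh;
      Z.each_row() += ly.b;
      fmat I = sigmoidf(Z.cols(0, Hd - 1));
      fmat F = sigmoidf(Z.cols(Hd, 2 * Hd - 1));
      fmat G = arma::tanh(Z.cols(2 * Hd, 3 * Hd - 1));
      fmat O = sigmoidf(Z.cols(3 * Hd, 4 * Hd - 1));
      c = F % c + I % G;
      fmat tc = arma::tanh(c);
      h = O % tc;
      if (cc) {
        cc->I.slice(t) = I; cc->F.slice(t) = F; cc->G.slice(t) = G;
        cc->O.slice(t) = O; cc->C.slice(t) = c; cc->TC.slice(t) = tc;
        cc->H.slice(t) = h;
      }
      hseq[t] = h;
    }
  }
  hbar.zeros(B, Hd);
  for (uword t = 0; t < K; ++t) hbar += hseq[t];
  hbar /= static_cast<float>(K);
  hbar_out = hbar;

  fmat logits = hbar * p.Wo;
  logits.each_row() += p.bo;
  logits.each_col() -= arma::max(logits, 1);
  fmat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);
  return P;
}

// Huber loss (transition delta) between probabilities and targets, mean over
// all elements; grad returned on the probability scale
static float huber_loss(const fmat& P, const fmat& Y, float delta, fmat& grad) {
  fmat R = P - Y;
  fmat A = arma::abs(R);
  fmat quad = 0.5f * arma::square(R);
  fmat lin = delta * (A - 0.5f * delta);
  fmat lossm = quad;
  arma::uvec big = arma::find(A > delta);
  lossm.elem(big) = lin.elem(big);
  float scale = 1.0f / static_cast<float>(P.n_elem);
  grad = arma::clamp(R, -delta, delta) * scale;
  return arma::accu(lossm) * scale;
}

static void adamw_update(fmat& w, fmat& m, fmat& v, const fmat& g,
                         float lr, float b1, float b2, float eps, float wd,
                         float bc1, float bc2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * arma::square(g);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + eps) + wd * w);
}
static void adamw_update(frowvec& w, frowvec& m, frowvec& v, const frowvec& g,
                         float lr, float b1, float b2, float eps, float wd,
                         float bc1, float bc2) {
  m = b1 * m + (1.0f - b1) * g;
  v = b2 * v + (1.0f - b2) * arma::square(g);
  w -= lr * ((m / bc1) / (arma::sqrt(v / bc2) + eps) + wd * w);
}

// one minibatch forward + backward + AdamW step; returns batch loss
static float train_step(Params& p, Adam& ad, const fmat& X, const arma::fvec& wl,
                        const fmat& Y, int feat, float delta,
                        float lr, float b1, float b2, float eps, float wd) {
  const uword B = X.n_rows, K = X.n_cols;
  const int Hd = p.layers[0].Wh.n_rows;
  const int L = p.layers.size();
  const int N = p.Wo.n_cols;

  std::vector<Cache> caches(L);
  fmat hbar;
  fmat P = forward(p, X, wl, feat, &caches, hbar);
  fmat gP;
  float loss = huber_loss(P, Y, delta, gP);

  // softmax backward: dlogit = P .* (g - rowsum(g .* P))
  arma::fvec dot = arma::sum(gP % P, 1);        // B x 1
  fmat gc = gP;
  gc.each_col() -= dot;
  fmat dlog = P % gc;                           // B x N

  fmat dWo = hbar.t() * dlog;
  frowvec dbo = arma::sum(dlog, 0);
  fmat dhbar = dlog * p.Wo.t();                 // B x Hd

  // gradient on the top-layer output sequence: mean pooling spreads dhbar/K
  fmat dh_pool = dhbar / static_cast<float>(K);

  // backprop through layers, top down; dx of layer l feeds layer l-1
  std::vector<fmat> dWx(L), dWh(L);
  std::vector<frowvec> db(L);
  fcube dX_below;  // B x Hd x K gradient wrt the layer-below output sequence
  for (int l = L - 1; l >= 0; --l) {
    const Layer& ly = p.layers[l];
    const Cache& ca = caches[l];
    int d = ly.Wx.n_rows;
    dWx[l].zeros(d, 4 * Hd);
    dWh[l].zeros(Hd, 4 * Hd);
    db[l].zeros(4 * Hd);
    fmat dh_rec(B, Hd, arma::fill::zeros), dc_rec(B, Hd, arma::fill::zeros);
    fcube dX_cur;
    if (l > 0) dX_cur.set_size(B, Hd, K);
    for (int t = K - 1; t >= 0; --t) {
      fmat dh = dh_rec;
      if (l == L - 1) dh += dh_pool;
      else dh += dX_below.slice(t);
      const fmat& I = ca.I.slice(t); const fmat& F = ca.F.slice(t);
      const fmat& G = ca.G.slice(t); const fmat& O = ca.O.slice(t);
      const fmat& tc = ca.TC.slice(t);
      fmat c_prev = (t == 0) ? fmat(B, Hd, arma::fill::zeros) : ca.C.slice(t - 1);
      fmat dc = dc_rec + dh % O % (1.0f - arma::square(tc));
      fmat dZ(B, 4 * Hd);
      dZ.cols(0, Hd - 1)          = (dc % G) % I % (1.0f - I);
      dZ.cols(Hd, 2 * Hd - 1)     = (dc % c_prev) % F % (1.0f - F);
      dZ.cols(2 * Hd, 3 * Hd - 1) = (dc % I) % (1.0f - arma::square(G));
      dZ.cols(3 * Hd, 4 * Hd - 1) = (dh % tc) % O % (1.0f - O);

      fmat xt;
      if (l == 0) {
        xt.set_size(B, d);
        xt.col(0) = X.col(t);
        if (d == 2) xt.col(1).fill(wl(t));
      } else {
        xt = caches[l - 1].H.slice(t);
      }
      fmat h_prev = (t == 0) ? fmat(B, Hd, arma::fill::zeros) : ca.H.slice(t - 1);
      dWx[l] += xt.t() * dZ;
      dWh[l] += h_prev.t() * dZ;
      db[l] += arma::sum(dZ, 0);
      if (l > 0) dX_cur.slice(t) = dZ * ly.Wx.t();
      dh_rec = dZ * ly.Wh.t();
      dc_rec = dc % F;
    }
    if (l > 0) dX_below = std::move(dX_cur);
  }

  // AdamW
  ad.step += 1;
  float bc1 = 1.0f - std::pow(b1, static_cast<float>(ad.step));
  float bc2 = 1.0f - std::pow(b2, static_cast<float>(ad.step));
  for (int l = 0; l < L; ++l) {
    adamw_update(p.layers[l].Wx, ad.m1[l].Wx, ad.v1[l].Wx, dWx[l], lr, b1, b2, eps, wd, bc1, bc2);
    adamw_update(p.layers[l].Wh, ad.m1[l].Wh, ad.v1[l].Wh, dWh[l], lr, b1, b2, eps, wd, bc1, bc2);
    adamw_update(p.layers[l].b,  ad.m1[l].b,  ad.v1[l].b,  db[l], lr, b1, b2, eps, 0.0f, bc1, bc2);
  }
  adamw_update(p.Wo, ad.mWo, ad.vWo, dWo, lr, b1, b2, eps, wd, bc1, bc2);
  adamw_update(p.bo, ad.mbo, ad.vbo, dbo, lr, b1, b2, eps, 0.0f, bc1, bc2);
  return loss;
}

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List ls;
  for (size_t l = 0; l < p.layers.size(); ++l) {
    ls.push_back(Rcpp::List::create(
        Rcpp::Named("Wx") = arma::conv_to<arma::mat>::from(p.layers[l].Wx),
        Rcpp::Named("Wh") = arma::conv_to<arma::mat>::from(p.layers[l].Wh),
        Rcpp::Named("b") = arma::conv_to<arma::rowvec>::from(p.layers[l].b)));
  }
  return Rcpp::List::create(
      Rcpp::Named("layers") = ls,
      Rcpp::Named("Wo") = arma::conv_to<arma::mat>::from(p.Wo),
      Rcpp::Named("bo") = arma::conv_to<arma::rowvec>::from(p.bo));
}

static Params params_from_list(const Rcpp::List& w) {
  Params p;
  Rcpp::List ls = w["layers"];
  for (int l = 0; l < ls.size(); ++l) {
    Rcpp::List e = ls[l];
    Layer ly;
    ly.Wx = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(e["Wx"]));
    ly.Wh = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(e["Wh"]));
    ly.b = arma::conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(e["b"]));
    p.layers.push_back(std::move(ly));
  }
  p.Wo = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(w["Wo"]));
  p.bo = arma::conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(w["bo"]));
  return p;
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::mat& X, const arma::vec& wl,
                          const arma::mat& Y,
                          int hidden, int layers, int feat,
                          int epochs, int batch, double lr, double weight_decay,
                          double beta1, double beta2, double huber_delta,
                          double train_fraction, int seed,
                          Rcpp::Nullable<Rcpp::List> warm_start = R_NilValue,
                          bool verbose = false) {
  const uword n = X.n_rows;
  const int N = Y.n_cols;
  if (Y.n_rows != n) Rcpp::stop("X and Y row counts differ");
  if (n < 1) Rcpp::stop("empty dataset");
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat Yf = arma::conv_to<fmat>::from(Y);
  arma::fvec wlf = arma::conv_to<arma::fvec>::from(wl);

  std::mt19937 rng(static_cast<unsigned>(seed));
  Params p = warm_start.isNotNull()
                 ? params_from_list(Rcpp::List(warm_start))
                 : init_params(feat, hidden, layers, N, rng);

  Adam ad;
  for (int l = 0; l < layers; ++l) {
    Layer z;
    z.Wx.zeros(p.layers[l].Wx.n_rows, p.layers[l].Wx.n_cols);
    z.Wh.zeros(hidden, 4 * hidden);
    z.b.zeros(4 * hidden);
    ad.m1.push_back(z);
    ad.v1.push_back(z);
  }
  ad.mWo.zeros(hidden, N); ad.vWo.zeros(hidden, N);
  ad.mbo.zeros(N); ad.vbo.zeros(N);

  // train / validation split on a seeded permutation
  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  uword ntr = static_cast<uword>(std::round(train_fraction * n));
  if (ntr < 1) ntr = 1;
  if (ntr > n) ntr = n;
  std::vector<uword> tr(perm.begin(), perm.begin() + ntr);
  std::vector<uword> va(perm.begin() + ntr, perm.end());

  std::vector<double> hist_train, hist_val;
  fmat hb;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double epl = 0.0;
    uword nb = 0;
    for (uword s = 0; s < tr.size(); s += batch) {
      uword e = std::min(s + static_cast<uword>(batch), (uword)tr.size());
      arma::uvec idx(e - s);
      for (uword k = s; k < e; ++k) idx(k - s) = tr[k];
      fmat Xb = Xf.rows(idx);
      fmat Yb = Yf.rows(idx);
      float loss = train_step(p, ad, Xb, wlf, Yb, feat, (float)huber_delta,
                              (float)lr, (float)beta1, (float)beta2, 1e-8f,
                              (float)weight_decay);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
      epl += loss;
      nb += 1;
      if (nb % 64 == 0) Rcpp::checkUserInterrupt();
    }
    hist_train.push_back(epl / std::max<uword>(nb, 1));

    double vl = NA_REAL;
    if (!va.empty()) {
      double acc = 0.0;
      uword nel = 0;
      for (uword s = 0; s < va.size(); s += 4096) {
        uword e = std::min(s + (uword)4096, (uword)va.size());
        arma::uvec idx(e - s);
        for (uword k = s; k < e; ++k) idx(k - s) = va[k];
        fmat Xb = Xf.rows(idx);
        fmat P = forward(p, Xb, wlf, feat, nullptr, hb);
        fmat g;
        acc += huber_loss(P, Yf.rows(idx), (float)huber_delta, g) * P.n_elem;
        nel += P.n_elem;
      }
      vl = acc / nel;
    }
    hist_val.push_back(vl);
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << "/" << epochs
                  << " train " << hist_train.back()
                  << " val " << vl << std::endl;
  }

  Rcpp::List out = params_to_list(p);
  out["history_train"] = hist_train;
  out["history_val"] = hist_val;
  out["n_train"] = (double)tr.size();
  out["n_val"] = (double)va.size();
  return out;
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(const Rcpp::List& weights, const arma::mat& X,
                           const arma::vec& wl, int feat) {
  Params p = params_from_list(weights);
  fmat Xf = arma::conv_to<fmat>::from(X);
  arma::fvec wlf = arma::conv_to<arma::fvec>::from(wl);
  const uword n = Xf.n_rows;
  arma::mat out(n, p.Wo.n_cols);
  fmat hb;
  for (uword s = 0; s < n; s += 4096) {
    uword e = std::min(s + (uword)4096, n);
    fmat P = forward(p, Xf.rows(s, e - 1), wlf, feat, nullptr, hb);
    out.rows(s, e - 1) = arma::conv_to<arma::mat>::from(P);
  }
  return out;
}
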