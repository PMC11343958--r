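// GRU next-step predictor: forward pass, backpropagation through time and
// an AdaBound-optimised training loop. Single recurrent layer + linear
// readout, MSE loss, dropout between the recurrent output and the readout.
// All randomness (init, shuffling, dropout) is driven by one std::mt19937
// seeded from R, so runs are reproducible independently of R's RNG state.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Gru {
  // weights; biases kept as 1-row matrices so the optimiser can treat all
  // parameters uniformly
  mat Wxr, Wxz, Wxh, Whr, Whz, Whh, Wo;
  mat er, ez, eh, bo;
  int d = 0, h = 0, dout = 0;

  void init(int d_, int h_, int dout_, std::mt19937& rng) {
    d = d_; h = h_; dout = dout_;
    auto fill_u = [&rng](mat& M, int fan_in) {
      // uniform in +/- 1/sqrt(fan_in)
      double a = 1.0 / std::sqrt((double)fan_in);
      std::uniform_real_distribution<double> U(-a, a);
      for (uword i = 0; i < M.n_elem; ++i) M(i) = U(rng);
    };
    Wxr.set_size(d, h); Wxz.set_size(d, h); Wxh.set_size(d, h);
    Whr.set_size(h, h); Whz.set_size(h, h); Whh.set_size(h, h);
    Wo.set_size(h, dout);
    fill_u(Wxr, d); fill_u(Wxz, d); fill_u(Wxh, d);
    fill_u(Whr, h); fill_u(Whz, h); fill_u(Whh, h);
    fill_u(Wo, h);
    er.zeros(1, h); ez.set_size(1, h); ez.fill(1.0); eh.zeros(1, h); bo.zeros(1, dout);
  }

  std::vector<mat*> params() {
    return {&Wxr, &Wxz, &Wxh, &Whr, &Whz, &Whh, &Wo, &er, &ez, &eh, &bo};
  }

  // Forward over all time steps; caches gate activations for BPTT.
  // X is n x d x T (slice t = inputs at step t). Hs gets T+1 slices
  // (slice 0 = zero initial state).
  void forward(const cube& X, cube& Hs, cube& Rs, cube& Zs, cube& Hc) const {
    const uword n = X.n_rows, T = X.n_slices;
    Hs.set_size(n, h, T + 1); Hs.slice(0).zeros();
    Rs.set_size(n, h, T); Zs.set_size(n, h, T); Hc.set_size(n, h, T);
    for (uword t = 0; t < T; ++t) {
      const mat& Xt = X.slice(t);
      const mat& Hp = Hs.slice(t);
      mat Ar = Xt * Wxr + Hp * Whr; Ar.each_row() += er.row(0);
      mat R = sigm(Ar);
      mat Az = Xt * Wxz + Hp * Whz; Az.each_row() += ez.row(0);
      mat Z = sigm(Az);
      mat Ah = Xt * Wxh + (R % Hp) * Whh; Ah.each_row() += eh.row(0);
      mat Hct = tanh(Ah);
      Hs.slice(t + 1) = Z % Hp + (1.0 - Z) % Hct;
      Rs.slice(t) = R; Zs.slice(t) = Z; Hc.slice(t) = Hct;
    }
  }

  // Readout from final hidden state (mask = dropout mask, ones in eval mode)
  mat readout(const mat& Hlast) const {
    mat Y = Hlast * Wo;
    Y.each_row() += bo.row(0);
    return Y;
  }
};

struct Grads {
  mat Wxr, Wxz, Wxh, Whr, Whz, Whh, Wo, er, ez, eh, bo;
  void zeros_like(const Gru& g) {
    Wxr.zeros(size(g.Wxr)); Wxz.zeros(size(g.Wxz)); Wxh.zeros(size(g.Wxh));
    Whr.zeros(size(g.Whr)); Whz.zeros(size(g.Whz)); Whh.zeros(size(g.Whh));
    Wo.zeros(size(g.Wo));
    er.zeros(size(g.er)); ez.zeros(size(g.ez)); eh.zeros(size(g.eh));
    bo.zeros(size(g.bo));
  }
  std::vector<mat*> params() {
    return {&Wxr, &Wxz, &Wxh, &Whr, &Whz, &Whh, &Wo, &er, &ez, &eh, &bo};
  }
};

// AdaBound: Adam with element-wise step sizes clipped into a band that
// tightens around final_lr as t grows.
struct AdaBound {
  std::vector<mat> m, v;
  double lr, beta1, beta2, eps, wd, final_lr, gamma;
  long t = 0;

  void init(Gru& g, double lr_, double b1, double b2, double eps_,
            double wd_, double flr, double gamma_) {
    lr = lr_; beta1 = b1; beta2 = b2; eps = eps_; wd = wd_;
    final_lr = flr; gamma = gamma_;
    for (mat* p : g.params()) {
      m.push_back(zeros<mat>(size(*p)));
      v.push_back(zeros<mat>(size(*p)));
    }
  }

  void step(Gru& g, Grads& gr) {
    ++t;
    std::vector<mat*> P = g.params(), G = gr.params();
    const double bc1 = 1.0 - std::pow(beta1, (double)t);
    const double bc2 = 1.0 - std::pow(beta2, (double)t);
    const double lb = final_lr * (1.0 - 1.0 / (gamma * t + 1.0));
    const double ub = final_lr * (1.0 + 1.0 / (gamma * t));
    for (size_t k = 0; k < P.size(); ++k) {
      mat grad = *G[k] + wd * (*P[k]);
      m[k] = beta1 * m[k] + (1.0 - beta1) * grad;
      v[k] = beta2 * v[k] + (1.0 - beta2) * (grad % grad);
      mat mhat = m[k] / bc1;
      mat vhat = v[k] / bc2;
      mat eta = lr / (sqrt(vhat) + eps);
      eta = clamp(eta, lb, ub);
      *P[k] -= eta % mhat;
    }
  }
};

// one batch: forward, MSE loss, full BPTT; returns the loss
double batch_grads(const Gru& g, const cube& Xb, const mat& Yb,
                   const mat& dropmask, Grads& gr) {
  cube Hs, Rs, Zs, Hc;
  g.forward(Xb, Hs, Rs, Zs, Hc);
  const uword T = Xb.n_slices, nb = Xb.n_rows;
  mat Hdrop = Hs.slice(T) % dropmask;
  mat Yhat = g.readout(Hdrop);
  mat resid = Yhat - Yb;
  double loss = accu(resid % resid) / (double)(nb * g.dout);

  mat dY = (2.0 / (double)(nb * g.dout)) * resid;
  gr.zeros_like(g);
  gr.Wo = Hdrop.t() * dY;
  gr.bo = sum(dY, 0);
  mat dH = (dY * g.Wo.t()) % dropmask;
  for (sword t = (sword)T - 1; t >= 0; --t) {
    const mat& Hp = Hs.slice(t);
    const mat& R = Rs.slice(t);
    const mat& Z = Zs.slice(t);
    const mat& Hct = Hc.slice(t);
    const mat& Xt = Xb.slice(t);
    mat dZ = dH % (Hp - Hct);
    mat dHc = dH % (1.0 - Z);
    mat dHp = dH % Z;
    mat dAh = dHc % (1.0 - Hct % Hct);
    gr.Wxh += Xt.t() * dAh;
    gr.Whh += (R % Hp).t() * dAh;
    gr.eh += sum(dAh, 0);
    mat dRH = dAh * g.Whh.t();
    dHp += dRH % R;
    mat dR = dRH % Hp;
    mat dAz = dZ % Z % (1.0 - Z);
    mat dAr = dR % R % (1.0 - R);
    gr.Wxz += Xt.t() * dAz; gr.Whz += Hp.t() * dAz; gr.ez += sum(dAz, 0);
    gr.Wxr += Xt.t() * dAr; gr.Whr += Hp.t() * dAr; gr.er += sum(dAr, 0);
    dHp += dAz * g.Whz.t() + dAr * g.Whr.t();
    dH = dHp;
  }
  return loss;
}

Gru gru_from_list(const Rcpp::List& w) {
  Gru g;
  g.Wxr = Rcpp::as<mat>(w["W_xr"]); g.Wxz = Rcpp::as<mat>(w["W_xz"]);
  g.Wxh = Rcpp::as<mat>(w["W_xh"]); g.Whr = Rcpp::as<mat>(w["W_hr"]);
  g.Whz = Rcpp::as<mat>(w["W_hz"]); g.Whh = Rcpp::as<mat>(w["W_hh"]);
  g.er = Rcpp::as<mat>(w["e_r"]); g.ez = Rcpp::as<mat>(w["e_z"]);
  g.eh = Rcpp::as<mat>(w["e_h"]);
  g.Wo = Rcpp::as<mat>(w["W_out"]); g.bo = Rcpp::as<mat>(w["b_out"]);
  g.d = g.Wxr.n_rows; g.h = g.Wxr.n_cols; g.dout = g.Wo.n_cols;
  return g;
}

Rcpp::List gru_to_list(const Gru& g) {
  return Rcpp::List::create(
    Rcpp::Named("W_xr") = g.Wxr, Rcpp::Named("W_xz") = g.Wxz,
    Rcpp::Named("W_xh") = g.Wxh, Rcpp::Named("W_hr") = g.Whr,
    Rcpp::Named("W_hz") = g.Whz, Rcpp::Named("W_hh") = g.Whh,
    Rcpp::Named("e_r") = g.er, Rcpp::Named("e_z") = g.ez,
    Rcpp::Named("e_h") = g.eh,
    Rcpp::Named("W_out") = g.Wo, Rcpp::Named("b_out") = g.bo);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".gru_train_cpp")]]
Rcpp::List gru_train_cpp(const arma::cube& X, const arma::mat& Y,
                         int hidden, int num_epoch, int batch_size,
                         double lr, double beta1, double beta2,
                         double weight_decay, double dropout,
                         double final_lr, double gamma_bound,
                         double eps, int seed) {
  const uword n = X.n_rows, d = X.n_cols;
  const int dout = Y.n_cols;
  if (Y.n_rows != n) Rcpp::stop("inputs and targets disagree on sample count");
  std::mt19937 rng((unsigned)seed);
  Gru g;
  g.init((int)d, hidden, dout, rng);
  AdaBound opt;
  opt.init(g, lr, beta1, beta2, eps, weight_decay, final_lr, gamma_bound);
  Grads gr;

  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  std::bernoulli_distribution keep(1.0 - dropout);
  const double scale = dropout > 0 ? 1.0 / (1.0 - dropout) : 1.0;

  Rcpp::NumericVector loss_hist(num_epoch);
  for (int ep = 0; ep < num_epoch; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; int nb_count = 0;
    for (uword off = 0; off < n; off += batch_size) {
      const uword nb = std::min<uword>(batch_size, n - off);
      uvec bidx(nb);
      for (uword i = 0; i < nb; ++i) bidx[i] = idx[off + i];
      cube Xb(nb, d, X.n_slices);
      for (uword t = 0; t < X.n_slices; ++t) Xb.slice(t) = X.slice(t).rows(bidx);
      mat Yb = Y.rows(bidx);
      mat dmask(nb, g.h);
      if (dropout > 0) {
        for (uword i = 0; i < dmask.n_elem; ++i)
          dmask(i) = keep(rng) ? scale : 0.0;
      } else dmask.ones();
      double loss = batch_grads(g, Xb, Yb, dmask, gr);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
      opt.step(g, gr);
      ep_loss += loss; ++nb_count;
    }
    loss_hist[ep] = ep_loss / nb_count;
  }

  // eval mode (no dropout): per-output mean squared next-step error on the
  // training windows
  cube Hs, Rs, Zs, Hc;
  g.forward(X, Hs, Rs, Zs, Hc);
  mat resid = g.readout(Hs.slice(X.n_slices)) - Y;
  rowvec sigma2 = mean(resid % resid, 0);

  return Rcpp::List::create(
    Rcpp::Named("weights") = gru_to_list(g),
    Rcpp::Named("sigma2") = Rcpp::NumericVector(sigma2.begin(), sigma2.end()),
    Rcpp::Named("loss_history") = loss_hist);
}

//' @noRd
// [[Rcpp::export(name = ".gru_forward_cpp")]]
Rcpp::List gru_forward_cpp(const Rcpp::List& weights, const arma::cube& X) {
  Gru g = gru_from_list(weights);
  if ((int)X.n_cols != g.d) Rcpp::stop("input dimension does not match weights");
  cube Hs, Rs, Zs, Hc;
  g.forward(X, Hs, Rs, Zs, Hc);
  mat Yhat = g.readout(Hs.slice(X.n_slices));
  return Rcpp::List::create(
    Rcpp::Named("prediction") = Yhat,
    Rcpp::Named("hidden") = (mat)Hs.slice(X.n_slices));
}
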