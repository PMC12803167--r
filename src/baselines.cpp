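// Vanilla RNN and LSTM baselines (hidden 128 by default) trained under the
// identical clipped-surrogate objective; policy and value read the same
// hidden state. Gradients are exact BPTT over the stored rollout segment,
// truncated at episode boundaries.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sigm(const vec& a) { return 1.0 / (1.0 + exp(-a)); }
static inline vec softmax2b(const vec& l) {
  vec e = exp(l - l.max());
  return e / accu(e);
}

// per-step loss derivatives shared by both baselines
static void ppo_step_loss(const vec& logits, int a1, double oldlp, double A,
                          double R, double V, double clip_eps,
                          double ent_coef, double val_coef, int T,
                          vec& dl, double& dV,
                          double& lpi, double& lv, double& lH) {
  vec pi = clamp(softmax2b(logits), 1e-12, 1.0);
  int a = a1 - 1;
  double logp = std::log(pi[a]);
  double ratio = std::exp(logp - oldlp);
  double rc = std::min(std::max(ratio, 1.0 - clip_eps), 1.0 + clip_eps);
  double s1 = ratio * A, s2 = rc * A;
  bool unclipped = (s1 <= s2);
  double H = -accu(pi % log(pi));
  double verr = V - R;
  lpi += -std::min(s1, s2); lv += verr * verr; lH += H;
  vec ea = zeros<vec>(2); ea[a] = 1.0;
  double gsurr = unclipped ? ratio * A : 0.0;
  dl = (-(gsurr) * (ea - pi) + ent_coef * (pi % (log(pi) + H))) / double(T);
  dV = 2.0 * val_coef * verr / double(T);
}

// ---- vanilla RNN: h' = tanh(Wh h + Win o + b) ----

// [[Rcpp::export]]
arma::vec rnn_step_cpp(Rcpp::List params, arma::vec h, arma::vec o) {
  mat Wh = Rcpp::as<mat>(params["Wh"]), Win = Rcpp::as<mat>(params["Win"]);
  vec b = Rcpp::as<vec>(params["b"]);
  return tanh(Wh * h + Win * o + b);
}

// [[Rcpp::export]]
Rcpp::List rnn_ppo_grad_cpp(Rcpp::List params, arma::mat obs,
                            arma::ivec actions, arma::vec old_logp,
                            arma::vec adv, arma::vec ret, arma::ivec reset,
                            arma::vec h0, arma::vec init_h,
                            double clip_eps, double ent_coef,
                            double val_coef) {
  mat Wh = Rcpp::as<mat>(params["Wh"]), Win = Rcpp::as<mat>(params["Win"]);
  vec b = Rcpp::as<vec>(params["b"]);
  mat Wpi = Rcpp::as<mat>(params["Wpi"]), Wv = Rcpp::as<mat>(params["Wv"]);
  const int T = obs.n_rows, Nh = Wh.n_rows;
  mat OBS = obs.t(), H0(Nh, T), H1(Nh, T), DL(2, T);
  vec DV(T);
  double lpi = 0.0, lv = 0.0, lH = 0.0;

  vec h = h0;
  for (int t = 0; t < T; ++t) {
    if (reset[t]) h = init_h;
    H0.col(t) = h;
    h = tanh(Wh * h + Win * OBS.col(t) + b);
    H1.col(t) = h;
    vec logits = Wpi * h;
    double V = as_scalar(Wv * h);
    vec dl; double dV;
    ppo_step_loss(logits, actions[t], old_logp[t], adv[t], ret[t], V,
                  clip_eps, ent_coef, val_coef, T, dl, dV, lpi, lv, lH);
    DL.col(t) = dl; DV[t] = dV;
  }

  mat gWh(size(Wh), fill::zeros), gWin(size(Win), fill::zeros);
  vec gb(Nh, fill::zeros);
  mat gWpi(size(Wpi), fill::zeros), gWv(size(Wv), fill::zeros);
  vec gh(Nh, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec hn = H1.col(t), hp = H0.col(t), o = OBS.col(t);
    gh += Wpi.t() * DL.col(t) + DV[t] * Wv.t();
    gWpi += DL.col(t) * hn.t();
    gWv += DV[t] * hn.t();
    vec dz = gh % (1.0 - hn % hn);
    gWh += dz * hp.t(); gWin += dz * o.t(); gb += dz;
    gh = Wh.t() * dz;
    if (reset[t]) gh.zeros();
  }
  double Td = double(T);
  return Rcpp::List::create(
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wh") = gWh, Rcpp::Named("Win") = gWin,
      Rcpp::Named("b") = gb, Rcpp::Named("Wpi") = gWpi,
      Rcpp::Named("Wv") = gWv),
    Rcpp::Named("loss") = lpi / Td + val_coef * lv / Td - ent_coef * lH / Td,
    Rcpp::Named("policy_loss") = lpi / Td,
    Rcpp::Named("value_loss") = lv / Td,
    Rcpp::Named("entropy") = lH / Td);
}

// ---- LSTM (gate order i, f, g, o stacked in rows of Wi/Whh/b) ----

// [[Rcpp::export]]
Rcpp::List lstm_step_cpp(Rcpp::List params, arma::vec h, arma::vec c,
                         arma::vec o) {
  mat Wi = Rcpp::as<mat>(params["Wi"]), Whh = Rcpp::as<mat>(params["Whh"]);
  vec b = Rcpp::as<vec>(params["b"]);
  int Nh = Whh.n_cols;
  vec zall = Wi * o + Whh * h + b;
  vec ig = sigm(zall.subvec(0, Nh - 1));
  vec fg = sigm(zall.subvec(Nh, 2 * Nh - 1));
  vec gg = tanh(zall.subvec(2 * Nh, 3 * Nh - 1));
  vec og = sigm(zall.subvec(3 * Nh, 4 * Nh - 1));
  vec cn = fg % c + ig % gg;
  vec hn = og % tanh(cn);
  return Rcpp::List::create(Rcpp::Named("h") = hn, Rcpp::Named("c") = cn);
}

// [[Rcpp::export]]
Rcpp::List lstm_ppo_grad_cpp(Rcpp::List params, arma::mat obs,
                             arma::ivec actions, arma::vec old_logp,
                             arma::vec adv, arma::vec ret, arma::ivec reset,
                             arma::vec h0, arma::vec c0, arma::vec init_h,
                             arma::vec init_c, double clip_eps,
                             double ent_coef, double val_coef) {
  mat Wi = Rcpp::as<mat>(params["Wi"]), Whh = Rcpp::as<mat>(params["Whh"]);
  vec b = Rcpp::as<vec>(params["b"]);
  mat Wpi = Rcpp::as<mat>(params["Wpi"]), Wv = Rcpp::as<mat>(params["Wv"]);
  const int T = obs.n_rows, Nh = Whh.n_cols;
  mat OBS = obs.t();
  mat H0(Nh, T), C0(Nh, T), H1(Nh, T), C1(Nh, T);
  mat IG(Nh, T), FG(Nh, T), GG(Nh, T), OG(Nh, T), TC(Nh, T);
  mat DL(2, T); vec DV(T);
  double lpi = 0.0, lv = 0.0, lH = 0.0;

  vec h = h0, c = c0;
  for (int t = 0; t < T; ++t) {
    if (reset[t]) { h = init_h; c = init_c; }
    H0.col(t) = h; C0.col(t) = c;
    vec zall = Wi * OBS.col(t) + Whh * h + b;
    vec ig = sigm(zall.subvec(0, Nh - 1));
    vec fg = sigm(zall.subvec(Nh, 2 * Nh - 1));
    vec gg = tanh(zall.subvec(2 * Nh, 3 * Nh - 1));
    vec og = sigm(zall.subvec(3 * Nh, 4 * Nh - 1));
    c = fg % c + ig % gg;
    vec tc = tanh(c);
    h = og % tc;
    IG.col(t) = ig; FG.col(t) = fg; GG.col(t) = gg; OG.col(t) = og;
    TC.col(t) = tc; H1.col(t) = h; C1.col(t) = c;
    vec logits = Wpi * h;
    double V = as_scalar(Wv * h);
    vec dl; double dV;
    ppo_step_loss(logits, actions[t], old_logp[t], adv[t], ret[t], V,
                  clip_eps, ent_coef, val_coef, T, dl, dV, lpi, lv, lH);
    DL.col(t) = dl; DV[t] = dV;
  }

  mat gWi(size(Wi), fill::zeros), gWhh(size(Whh), fill::zeros);
  vec gb(4 * Nh, fill::zeros);
  mat gWpi(size(Wpi), fill::zeros), gWv(size(Wv), fill::zeros);
  vec gh(Nh, fill::zeros), gc(Nh, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec hn = H1.col(t), hp = H0.col(t), cp = C0.col(t), o = OBS.col(t);
    vec ig = IG.col(t), fg = FG.col(t), gg = GG.col(t), og = OG.col(t);
    vec tc = TC.col(t);
    gh += Wpi.t() * DL.col(t) + DV[t] * Wv.t();
    gWpi += DL.col(t) * hn.t();
    gWv += DV[t] * hn.t();
    vec dog = gh % tc % og % (1.0 - og);
    gc += gh % og % (1.0 - tc % tc);
    vec di = gc % gg % ig % (1.0 - ig);
    vec dgg = gc % ig % (1.0 - gg % gg);
    vec df = gc % cp % fg % (1.0 - fg);
    vec gc_prev = gc % fg;
    vec dz = join_cols(join_cols(di, df), join_cols(dgg, dog));
    gWi += dz * o.t(); gWhh += dz * hp.t(); gb += dz;
    gh = Whh.t() * dz;
    gc = gc_prev;
    if (reset[t]) { gh.zeros(); gc.zeros(); }
  }
  double Td = double(T);
  return Rcpp::List::create(
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wi") = gWi, Rcpp::Named("Whh") = gWhh,
      Rcpp::Named("b") = gb, Rcpp::Named("Wpi") = gWpi,
      Rcpp::Named("Wv") = gWv),
    Rcpp::Named("loss") = lpi / Td + val_coef * lv / Td - ent_coef * lH / Td,
    Rcpp::Named("policy_loss") = lpi / Td,
    Rcpp::Named("value_loss") = lv / Td,
    Rcpp::Named("entropy") = lH / Td);
}
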