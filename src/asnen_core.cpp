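// Tripartite neuron-astrocyte network: forward dynamics and
// backpropagation-through-time for the clipped-surrogate objective.
//
// Conventions (must match the R-level documentation):
//  - w is the row-major flattening of the recurrent matrix W:
//    W(i,j) = w[i*Nx + j]. The outer product x x^T is symmetric, so its
//    row-major and column-major flattenings coincide; C is flattened
//    row-major to align with w.
//  - Update rules (gamma = discretization step, tau = astrocyte timescale):
//      x' = (1-g) x + g * sigmoid(W x + Winx o)
//      w' = (1-g) w + g * [ sigmoid(vec(x x^T)) .* vec(C) + tanh(D z) ]
//      z' = (1-g) z + g*tau * [ tanh(F z) + rowsum(H .* tanh(x x^T))/Nx
//                               + tanh(Winz o) ]
//    The rowsum/Nx pooling requires Nz == Nx (each astrocyte pools the
//    synapses of one row); enforced at the R level.
//  - Policy logits = Wpi x' (2 x 1), value = Wv z' (scalar); both read the
//    post-update state of the step that consumed the observation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// row-major reshape: W(i,j) = w[i*Nx + j]
static inline mat rm_mat(const vec& w, int Nx) {
  return reshape(w, Nx, Nx).st();
}
static inline vec rm_vec(const mat& A) {
  return vectorise(A.st());
}
static inline vec sigmoid(const vec& a) {
  return 1.0 / (1.0 + exp(-a));
}

struct AsnenP {
  mat Winx, Winz, C, D, H, F, Wpi, Wv;
  vec cvec;
  double gamma, tau;
  int Nx, Nz, Nw;
};

static AsnenP unpack_asnen(const Rcpp::List& p) {
  AsnenP q;
  q.Winx = Rcpp::as<mat>(p["Winx"]);
  q.Winz = Rcpp::as<mat>(p["Winz"]);
  q.C    = Rcpp::as<mat>(p["C"]);
  q.D    = Rcpp::as<mat>(p["D"]);
  q.H    = Rcpp::as<mat>(p["H"]);
  q.F    = Rcpp::as<mat>(p["F"]);
  q.Wpi  = Rcpp::as<mat>(p["Wpi"]);
  q.Wv   = Rcpp::as<mat>(p["Wv"]);
  q.gamma = Rcpp::as<double>(p["gamma"]);
  q.tau   = Rcpp::as<double>(p["tau"]);
  q.Nx = q.C.n_rows;
  q.Nz = q.F.n_rows;
  q.Nw = q.Nx * q.Nx;
  q.cvec = rm_vec(q.C);
  return q;
}

// one forward step; outputs overwrite x, w, z
static void asnen_fwd(const AsnenP& P, vec& x, vec& w, vec& z, const vec& o) {
  const double g = P.gamma, tau = P.tau;
  mat W = rm_mat(w, P.Nx);
  vec s = sigmoid(W * x + P.Winx * o);
  mat Pout = x * x.t();                 // outer product of pre-step x
  vec pv = vectorise(Pout);             // symmetric: row-major == col-major
  vec sw = sigmoid(pv);
  vec td = tanh(P.D * z);
  vec tf = tanh(P.F * z);
  mat P2 = tanh(Pout);
  vec gp = sum(P.H % P2, 1) / double(P.Nx);
  vec ti = tanh(P.Winz * o);
  vec xn = (1.0 - g) * x + g * s;
  vec wn = (1.0 - g) * w + g * (sw % P.cvec + td);
  vec zn = (1.0 - g) * z + g * tau * (tf + gp + ti);
  x = xn; w = wn; z = zn;
}

// [[Rcpp::export]]
Rcpp::List asnen_step_cpp(Rcpp::List params, arma::vec x, arma::vec w,
                          arma::vec z, arma::vec o) {
  AsnenP P = unpack_asnen(params);
  asnen_fwd(P, x, w, z, o);
  return Rcpp::List::create(Rcpp::Named("x") = x, Rcpp::Named("w") = w,
                            Rcpp::Named("z") = z);
}

// stable softmax over a 2-vector of logits
static inline vec softmax2(const vec& l) {
  vec s = l - l.max();
  vec e = exp(s);
  return e / accu(e);
}

// Clipped-surrogate loss and full parameter gradients over one stored
// rollout segment. States replay from (x0, w0, z0); reset[t] == 1 means the
// dynamical state is set to (init_x, init_w, init_z) before consuming row t
// (episode boundary), and adjoints are truncated there.
// actions are 1-based indices into the 2-action policy.
// [[Rcpp::export]]
Rcpp::List asnen_ppo_grad_cpp(Rcpp::List params, arma::mat obs,
                              arma::ivec actions, arma::vec old_logp,
                              arma::vec adv, arma::vec ret,
                              arma::ivec reset,
                              arma::vec x0, arma::vec w0, arma::vec z0,
                              arma::vec init_x, arma::vec init_w,
                              arma::vec init_z,
                              double clip_eps, double ent_coef,
                              double val_coef) {
  AsnenP P = unpack_asnen(params);
  const int T = obs.n_rows, Nx = P.Nx, Nz = P.Nz, Nw = P.Nw;
  const double g = P.gamma, tau = P.tau;

  mat X0(Nx, T), Z0m(Nz, T), X1(Nx, T), Z1(Nz, T);
  mat Wpre(Nw, T), S(Nx, T), SW(Nw, T), TD(Nw, T), P2S(Nw, T);
  mat TF(Nz, T), TI(Nz, T), OBS = obs.t();   // 3 x T
  mat DL(2, T);                              // dLoss/dlogits
  vec DV(T);                                 // dLoss/dV
  double loss_pi = 0.0, loss_v = 0.0, ent_sum = 0.0;

  vec x = x0, w = w0, z = z0;
  for (int t = 0; t < T; ++t) {
    if (reset[t]) { x = init_x; w = init_w; z = init_z; }
    X0.col(t) = x; Wpre.col(t) = w; Z0m.col(t) = z;
    vec o = OBS.col(t);
    mat W = rm_mat(w, Nx);
    vec s = sigmoid(W * x + P.Winx * o);
    mat Pout = x * x.t();
    vec pv = vectorise(Pout);
    vec sw = sigmoid(pv);
    vec td = tanh(P.D * z);
    vec tf = tanh(P.F * z);
    mat P2 = tanh(Pout);
    vec gp = sum(P.H % P2, 1) / double(Nx);
    vec ti = tanh(P.Winz * o);
    vec xn = (1.0 - g) * x + g * s;
    vec wn = (1.0 - g) * w + g * (sw % P.cvec + td);
    vec zn = (1.0 - g) * z + g * tau * (tf + gp + ti);
    S.col(t) = s; SW.col(t) = sw; TD.col(t) = td; P2S.col(t) = vectorise(P2);
    TF.col(t) = tf; TI.col(t) = ti;
    X1.col(t) = xn; Z1.col(t) = zn;
    x = xn; w = wn; z = zn;

    // readouts + per-step loss pieces
    vec logits = P.Wpi * xn;
    vec pi = softmax2(logits);
    pi = clamp(pi, 1e-12, 1.0);
    int a = actions[t] - 1;
    double logp = std::log(pi[a]);
    double ratio = std::exp(logp - old_logp[t]);
    double rc = std::min(std::max(ratio, 1.0 - clip_eps), 1.0 + clip_eps);
    double s1 = ratio * adv[t], s2 = rc * adv[t];
    bool unclipped = (s1 <= s2);
    double surr = std::min(s1, s2);
    double H = -accu(pi % log(pi));
    double V = as_scalar(P.Wv * zn);
    double verr = V - ret[t];
    loss_pi += -surr; loss_v += verr * verr; ent_sum += H;

    // d(total mean loss)/dlogits and /dV for this step
    vec ea = zeros<vec>(2); ea[a] = 1.0;
    double gsurr = unclipped ? ratio * adv[t] : 0.0;  // dsurr/dlogp_a
    vec dl = -(gsurr) * (ea - pi) + ent_coef * (pi % (log(pi) + H));
    DL.col(t) = dl / double(T);
    DV[t] = 2.0 * val_coef * verr / double(T);
  }

  // backward
  mat gWinx(size(P.Winx), fill::zeros), gWinz(size(P.Winz), fill::zeros);
  vec gc(Nw, fill::zeros);
  mat gD(size(P.D), fill::zeros), gH(size(P.H), fill::zeros);
  mat gF(size(P.F), fill::zeros), gWpi(size(P.Wpi), fill::zeros);
  mat gWv(size(P.Wv), fill::zeros);
  vec gx(Nx, fill::zeros), gw(Nw, fill::zeros), gz(Nz, fill::zeros);
  rowvec onesNx = ones<rowvec>(Nx);

  for (int t = T - 1; t >= 0; --t) {
    vec xp = X0.col(t), zp = Z0m.col(t), wp = Wpre.col(t);
    vec xn = X1.col(t), zn = Z1.col(t);
    vec o = OBS.col(t);
    // readout contributions (post-state adjoints)
    vec dl = DL.col(t);
    gx += P.Wpi.t() * dl;
    gWpi += dl * xn.t();
    gz += DV[t] * P.Wv.t();
    gWv += DV[t] * zn.t();

    // x-update
    vec s = S.col(t);
    vec dax = g * (gx % s % (1.0 - s));
    mat W = rm_mat(wp, Nx);
    vec gx0 = (1.0 - g) * gx + W.t() * dax;
    vec gw0 = rm_vec(dax * xp.t());
    gWinx += dax * o.t();

    // w-update
    vec sw = SW.col(t), td = TD.col(t);
    gw0 += (1.0 - g) * gw;
    gc += g * (gw % sw);
    vec dp = g * (gw % P.cvec % sw % (1.0 - sw));
    mat Dp = rm_mat(dp, Nx);
    gx0 += (Dp + Dp.t()) * xp;
    vec du = g * (gw % (1.0 - td % td));
    gD += du * zp.t();
    vec gz0 = (1.0 - g) * gz + P.D.t() * du;

    // z-update
    vec tf = TF.col(t), ti = TI.col(t);
    vec df = g * tau * (gz % (1.0 - tf % tf));
    gF += df * zp.t();
    gz0 += P.F.t() * df;
    vec dgp = g * tau * gz / double(Nx);
    mat P2 = reshape(P2S.col(t), Nx, Nx);
    gH += (dgp * onesNx) % P2;
    mat M = (dgp * onesNx) % P.H % (1.0 - P2 % P2);
    gx0 += (M + M.t()) * xp;
    vec di = g * tau * (gz % (1.0 - ti % ti));
    gWinz += di * o.t();

    if (reset[t]) { gx.zeros(); gw.zeros(); gz.zeros(); }
    else { gx = gx0; gw = gw0; gz = gz0; }
  }

  double Td = double(T);
  double loss = loss_pi / Td + val_coef * loss_v / Td - ent_coef * ent_sum / Td;
  return Rcpp::List::create(
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Winx") = gWinx, Rcpp::Named("Winz") = gWinz,
      Rcpp::Named("C") = rm_mat(gc, Nx), Rcpp::Named("D") = gD,
      Rcpp::Named("H") = gH, Rcpp::Named("F") = gF,
      Rcpp::Named("Wpi") = gWpi, Rcpp::Named("Wv") = gWv),
    Rcpp::Named("loss") = loss,
    Rcpp::Named("policy_loss") = loss_pi / Td,
    Rcpp::Named("value_loss") = loss_v / Td,
    Rcpp::Named("entropy") = ent_sum / Td);
}
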