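// Fast path for the message-passing network: batched forward pass and
// analytic backpropagation.  Mirrors the reference R implementation in
// R/gnn_core.R exactly (same architecture, same layer-norm epsilon);
// equivalence of the two paths is asserted in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-6;

struct MLP {
  mat W1, W2, W3;
  vec b1, b2, b3;
  bool ln;
  vec g, o;
};

struct Cache {
  mat x, h1, h2, yhat;
  vec s;
};

struct Grad {
  mat W1, W2, W3;
  vec b1, b2, b3, gg, go;
};

static MLP read_mlp(const Rcpp::List& l) {
  MLP p;
  p.W1 = Rcpp::as<mat>(l["W1"]);
  p.b1 = Rcpp::as<vec>(l["b1"]);
  p.W2 = Rcpp::as<mat>(l["W2"]);
  p.b2 = Rcpp::as<vec>(l["b2"]);
  p.W3 = Rcpp::as<mat>(l["W3"]);
  p.b3 = Rcpp::as<vec>(l["b3"]);
  p.ln = l.containsElementNamed("ln_gain");
  if (p.ln) {
    p.g = Rcpp::as<vec>(l["ln_gain"]);
    p.o = Rcpp::as<vec>(l["ln_offset"]);
  }
  return p;
}

static Grad zero_grad(const MLP& p) {
  Grad g;
  g.W1 = zeros<mat>(p.W1.n_rows, p.W1.n_cols);
  g.W2 = zeros<mat>(p.W2.n_rows, p.W2.n_cols);
  g.W3 = zeros<mat>(p.W3.n_rows, p.W3.n_cols);
  g.b1 = zeros<vec>(p.b1.n_elem);
  g.b2 = zeros<vec>(p.b2.n_elem);
  g.b3 = zeros<vec>(p.b3.n_elem);
  if (p.ln) {
    g.gg = zeros<vec>(p.g.n_elem);
    g.go = zeros<vec>(p.o.n_elem);
  }
  return g;
}

static Rcpp::List grad_to_list(const MLP& p, const Grad& g) {
  if (p.ln) {
    return Rcpp::List::create(
      Rcpp::Named("W1") = g.W1, Rcpp::Named("b1") = g.b1,
      Rcpp::Named("W2") = g.W2, Rcpp::Named("b2") = g.b2,
      Rcpp::Named("W3") = g.W3, Rcpp::Named("b3") = g.b3,
      Rcpp::Named("ln_gain") = g.gg, Rcpp::Named("ln_offset") = g.go);
  }
  return Rcpp::List::create(
    Rcpp::Named("W1") = g.W1, Rcpp::Named("b1") = g.b1,
    Rcpp::Named("W2") = g.W2, Rcpp::Named("b2") = g.b2,
    Rcpp::Named("W3") = g.W3, Rcpp::Named("b3") = g.b3);
}

static mat mlp_fwd(const MLP& p, const mat& x, Cache& c) {
  c.x = x;
  c.h1 = x * p.W1.t();
  c.h1.each_row() += p.b1.t();
  c.h1.transform([](double v) { return v < 0 ? 0.0 : v; });
  c.h2 = c.h1 * p.W2.t();
  c.h2.each_row() += p.b2.t();
  c.h2.transform([](double v) { return v < 0 ? 0.0 : v; });
  mat y = c.h2 * p.W3.t();
  y.each_row() += p.b3.t();
  if (p.ln) {
    vec mu = mean(y, 1);
    mat yc = y.each_col() - mu;
    c.s = sqrt(mean(square(yc), 1) + LN_EPS);
    c.yhat = yc.each_col() / c.s;
    mat out = c.yhat;
    out.each_row() %= p.g.t();
    out.each_row() += p.o.t();
    return out;
  }
  return y;
}

static mat mlp_bwd(const MLP& p, const Cache& c, const mat& dout, Grad& g) {
  mat dy;
  if (p.ln) {
    g.gg += sum(dout % c.yhat, 0).t();
    g.go += sum(dout, 0).t();
    mat dyhat = dout;
    dyhat.each_row() %= p.g.t();
    vec m1 = mean(dyhat, 1);
    vec m2 = mean(dyhat % c.yhat, 1);
    mat t2 = c.yhat;
    t2.each_col() %= m2;
    dy = dyhat;
    dy.each_col() -= m1;
    dy -= t2;
    dy.each_col() /= c.s;
  } else {
    dy = dout;
  }
  g.W3 += dy.t() * c.h2;
  g.b3 += sum(dy, 0).t();
  mat dh2 = dy * p.W3;
  dh2.elem(find(c.h2 <= 0)).zeros();
  g.W2 += dh2.t() * c.h1;
  g.b2 += sum(dh2, 0).t();
  mat dh1 = dh2 * p.W2;
  dh1.elem(find(c.h1 <= 0)).zeros();
  g.W1 += dh1.t() * c.x;
  g.b1 += sum(dh1, 0).t();
  return dh1 * p.W1;
}

// [[Rcpp::export(name = ".gnn_pass_cpp")]]
Rcpp::List gnn_pass_cpp(const arma::mat& node_features,
                        const arma::mat& edge_features,
                        const arma::uvec& senders,   // 0-based
                        const arma::uvec& receivers, // 0-based
                        const arma::mat& target,     // 0x0 when absent
                        bool edge_task, int n_steps, bool agg_mean,
                        const Rcpp::List& mlps,
                        const arma::vec& row_weights,
                        bool compute_grads) {
  MLP enc_e = read_mlp(mlps["edge_encoder"]);
  MLP enc_v = read_mlp(mlps["node_encoder"]);
  MLP core_e = read_mlp(mlps["core_edge"]);
  MLP core_v = read_mlp(mlps["core_node"]);
  MLP dec = read_mlp(mlps["decoder"]);
  const uword nE = edge_features.n_rows;
  const uword nN = node_features.n_rows;
  const uword L = enc_e.W3.n_rows;

  Cache c_enc_e, c_enc_v;
  mat E0 = mlp_fwd(enc_e, edge_features, c_enc_e);
  mat V0 = mlp_fwd(enc_v, node_features, c_enc_v);
  mat e = E0, v = V0;

  vec cnt;
  if (agg_mean) {
    cnt = zeros<vec>(nN);
    for (uword k = 0; k < nE; ++k) cnt(receivers(k)) += 1.0;
    cnt.elem(find(cnt == 0)).ones();
  }

  std::vector<Cache> ce(n_steps), cv(n_steps), cd(n_steps);
  Rcpp::List outs(n_steps);
  std::vector<mat> outs_m(n_steps);
  double loss = NA_REAL;
  bool has_target = target.n_elem > 0;
  vec w;
  if (has_target) {
    w = row_weights / (double(n_steps) * double(target.n_cols));
  }

  for (int t = 0; t < n_steps; ++t) {
    mat ein(nE, 6 * L);
    ein.cols(0, L - 1) = E0;
    ein.cols(L, 2 * L - 1) = e;
    ein.cols(2 * L, 3 * L - 1) = V0.rows(senders);
    ein.cols(3 * L, 4 * L - 1) = v.rows(senders);
    ein.cols(4 * L, 5 * L - 1) = V0.rows(receivers);
    ein.cols(5 * L, 6 * L - 1) = v.rows(receivers);
    mat e_new = mlp_fwd(core_e, ein, ce[t]);
    mat agg = zeros<mat>(nN, L);
    for (uword k = 0; k < nE; ++k) agg.row(receivers(k)) += e_new.row(k);
    if (agg_mean) agg.each_col() /= cnt;
    mat nin(nN, 3 * L);
    nin.cols(0, L - 1) = V0;
    nin.cols(L, 2 * L - 1) = v;
    nin.cols(2 * L, 3 * L - 1) = agg;
    mat v_new = mlp_fwd(core_v, nin, cv[t]);
    mat decoded = mlp_fwd(dec, edge_task ? e_new : v_new, cd[t]);
    outs_m[t] = decoded;
    outs[t] = decoded;
    e = e_new;
    v = v_new;
  }

  if (has_target) {
    loss = 0.0;
    for (int t = 0; t < n_steps; ++t) {
      mat d2 = outs_m[t] - target;
      d2 %= d2;
      d2.each_col() %= w;
      loss += accu(d2);
    }
  }

  if (!compute_grads) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("per_step_outputs") = outs);
  }

  Grad g_enc_e = zero_grad(enc_e), g_enc_v = zero_grad(enc_v);
  Grad g_core_e = zero_grad(core_e), g_core_v = zero_grad(core_v);
  Grad g_dec = zero_grad(dec);
  mat ge = zeros<mat>(nE, L), gv = zeros<mat>(nN, L);
  mat gE0 = zeros<mat>(nE, L), gV0 = zeros<mat>(nN, L);

  for (int t = n_steps - 1; t >= 0; --t) {
    mat dd = outs_m[t] - target;
    dd.each_col() %= w;
    dd *= 2.0;
    mat ddec = mlp_bwd(dec, cd[t], dd, g_dec);
    if (edge_task) ge += ddec; else gv += ddec;
    mat dnin = mlp_bwd(core_v, cv[t], gv, g_core_v);
    gV0 += dnin.cols(0, L - 1);
    mat gv_prev = dnin.cols(L, 2 * L - 1);
    mat dagg = dnin.cols(2 * L, 3 * L - 1);
    if (agg_mean) dagg.each_col() /= cnt;
    for (uword k = 0; k < nE; ++k) ge.row(k) += dagg.row(receivers(k));
    mat dein = mlp_bwd(core_e, ce[t], ge, g_core_e);
    gE0 += dein.cols(0, L - 1);
    mat ge_prev = dein.cols(L, 2 * L - 1);
    for (uword k = 0; k < nE; ++k) {
      gV0.row(senders(k)) += dein.cols(2 * L, 3 * L - 1).row(k);
      gv_prev.row(senders(k)) += dein.cols(3 * L, 4 * L - 1).row(k);
      gV0.row(receivers(k)) += dein.cols(4 * L, 5 * L - 1).row(k);
      gv_prev.row(receivers(k)) += dein.cols(5 * L, 6 * L - 1).row(k);
    }
    ge = ge_prev;
    gv = gv_prev;
  }
  gE0 += ge;
  gV0 += gv;
  mlp_bwd(enc_e, c_enc_e, gE0, g_enc_e);
  mlp_bwd(enc_v, c_enc_v, gV0, g_enc_v);

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("edge_encoder") = grad_to_list(enc_e, g_enc_e),
    Rcpp::Named("node_encoder") = grad_to_list(enc_v, g_enc_v),
    Rcpp::Named("core_edge") = grad_to_list(core_e, g_core_e),
    Rcpp::Named("core_node") = grad_to_list(core_v, g_core_v),
    Rcpp::Named("decoder") = grad_to_list(dec, g_dec));
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("per_step_outputs") = outs,
                            Rcpp::Named("grads") = grads);
}
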