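// Amortized variational inference core: forward evaluation of the ELBO for
// a minibatch of regional datapoints and reverse-mode gradients for every
// trainable quantity (LSTM encoders, output heads, subject/external-input
// lookup matrices, the neural-mass MLP, observation model, noise
// log-variances and the external-input time scale).
//
// All parameters live in one flat vector whose layout is defined by
// Layout below and mirrored in R by vae_param_layout(). Gradients are
// checked against central finite differences in the test suite.
//
// Per-datapoint ELBO (one region of one subject; n = number of regions):
//   L = E_q[log p(y | x)]                                   (reconstruction)
//     + beta * ( E_q[log p(x | theta, u_ext, u)] + H[q(x)]
//                - KL[q(theta_r) || N(0,I)]
//                - (1/n) KL[q(theta_s) || N(0,I)] )
//     + beta * (1/n) * ( E_q[log p(u_ext)] + H[q(u_ext)] )
// with expectations approximated by one reparameterized sample per call,
// Gaussian entropies and the theta KLs in closed form, and the state-prior
// and AR(1) terms evaluated at the sampled trajectories.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Layout {
  int n_s, m_r, m_s, n_t, n_sub, n_l, n_h, d_in, n_i;
  int Wx1, Wh1, bh1, Ho1, bo1;
  int Wx2, Wh2, bh2, Ho2, bo2;
  int M1, V1, M2, V2;
  int W1f, b1f, W2f, b2f;
  int a, b, lso, lss, ltau;
  int total;
  explicit Layout(const IntegerVector& dims) {
    n_s = dims["n_s"]; m_r = dims["m_r"]; m_s = dims["m_s"];
    n_t = dims["n_t"]; n_sub = dims["n_sub"]; n_l = dims["n_l"];
    n_h = dims["n_h"];
    d_in = 2 + n_sub;
    n_i = n_s + m_r + m_s + 2;
    int o = 0;
    Wx1 = o; o += 4 * n_l * d_in;
    Wh1 = o; o += 4 * n_l * n_l;
    bh1 = o; o += 4 * n_l;
    Ho1 = o; o += 2 * n_s * n_l;
    bo1 = o; o += 2 * n_s;
    Wx2 = o; o += 4 * n_l * d_in;
    Wh2 = o; o += 4 * n_l * n_l;
    bh2 = o; o += 4 * n_l;
    Ho2 = o; o += 2 * m_r * n_l;
    bo2 = o; o += 2 * m_r;
    M1 = o; o += m_s * n_sub;
    V1 = o; o += m_s * n_sub;
    M2 = o; o += n_t * n_sub;
    V2 = o; o += n_t * n_sub;
    W1f = o; o += n_h * n_i;
    b1f = o; o += n_h;
    W2f = o; o += n_s * n_h;
    b2f = o; o += n_s;
    a = o; o += n_s;
    b = o; o += 1;
    lso = o; o += 1;
    lss = o; o += n_s;
    ltau = o; o += 1;
    total = o;
  }
};

// [[Rcpp::export]]
int vae_param_count_cpp(const IntegerVector& dims) {
  return Layout(dims).total;
}

// read-only aliasing view into the flat parameter vector (no copy; C++17
// guaranteed elision keeps the aliasing semantics on return)
static arma::mat pview(const arma::vec& p, int off, int r, int c) {
  return arma::mat(const_cast<double*>(p.memptr()) + off, r, c, false, true);
}
static void acc(arma::vec& g, int off, const arma::mat& d) {
  std::size_t n = d.n_elem;
  double* dst = g.memptr() + off;
  const double* src = d.memptr();
  for (std::size_t i = 0; i < n; ++i) dst[i] += src[i];
}

struct LstmCache {
  std::vector<arma::mat> i, f, g, o, c, tc, h;  // each B x n_l per step
};

static void lstm_forward(const std::vector<arma::mat>& X,
                         const arma::mat& Wx, const arma::mat& Wh,
                         const arma::vec& bh, int n_l, LstmCache& cc) {
  const int T = (int) X.size();
  const int B = X[0].n_rows;
  arma::mat h(B, n_l, arma::fill::zeros), c(B, n_l, arma::fill::zeros);
  cc.i.resize(T); cc.f.resize(T); cc.g.resize(T); cc.o.resize(T);
  cc.c.resize(T); cc.tc.resize(T); cc.h.resize(T);
  for (int k = 0; k < T; ++k) {
    arma::mat G = X[k] * Wx.t() + h * Wh.t();
    G.each_row() += bh.t();
    arma::mat gi = 1.0 / (1.0 + arma::exp(-G.cols(0, n_l - 1)));
    arma::mat gf = 1.0 / (1.0 + arma::exp(-G.cols(n_l, 2 * n_l - 1)));
    arma::mat gg = arma::tanh(G.cols(2 * n_l, 3 * n_l - 1));
    arma::mat go = 1.0 / (1.0 + arma::exp(-G.cols(3 * n_l, 4 * n_l - 1)));
    c = gf % c + gi % gg;
    arma::mat tc = arma::tanh(c);
    h = go % tc;
    cc.i[k] = gi; cc.f[k] = gf; cc.g[k] = gg; cc.o[k] = go;
    cc.c[k] = c; cc.tc[k] = tc; cc.h[k] = h;
  }
}

// Backpropagation through time; dh_up[k] is the upstream gradient on h_k
// (empty matrix when a step has no output head).
static void lstm_backward(const std::vector<arma::mat>& X,
                          const arma::mat& Wh, const LstmCache& cc,
                          const std::vector<arma::mat>& dh_up, int n_l,
                          arma::mat& dWx, arma::mat& dWh, arma::vec& dbh) {
  const int T = (int) X.size();
  const int B = X[0].n_rows;
  dWx.zeros(4 * n_l, X[0].n_cols);
  dWh.zeros(4 * n_l, n_l);
  dbh.zeros(4 * n_l);
  arma::mat dh(B, n_l, arma::fill::zeros), dc(B, n_l, arma::fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    if (dh_up[k].n_elem > 0) dh += dh_up[k];
    const arma::mat& gi = cc.i[k]; const arma::mat& gf = cc.f[k];
    const arma::mat& gg = cc.g[k]; const arma::mat& go = cc.o[k];
    const arma::mat& tc = cc.tc[k];
    arma::mat do_ = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    arma::mat di = dc % gg;
    arma::mat dg = dc % gi;
    arma::mat df(B, n_l, arma::fill::zeros);
    if (k > 0) df = dc % cc.c[k - 1];
    arma::mat dc_prev = dc % gf;
    arma::mat dG(B, 4 * n_l);
    dG.cols(0, n_l - 1)           = di % gi % (1.0 - gi);
    dG.cols(n_l, 2 * n_l - 1)     = df % gf % (1.0 - gf);
    dG.cols(2 * n_l, 3 * n_l - 1) = dg % (1.0 - gg % gg);
    dG.cols(3 * n_l, 4 * n_l - 1) = do_ % go % (1.0 - go);
    dWx += dG.t() * X[k];
    if (k > 0) dWh += dG.t() * cc.h[k - 1];
    dbh += arma::sum(dG, 0).t();
    dh = dG * Wh;
    dc = dc_prev;
  }
}

// [[Rcpp::export]]
List vae_loss_grad_cpp(const arma::vec& params, const IntegerVector& dims,
                       const arma::mat& Y,        // n_t x B observations
                       const arma::mat& U,        // n_t x B network inputs
                       const IntegerVector& subj, // B, 0-based
                       double beta, double alpha_f, double alpha_x,
                       int n_regions,
                       const arma::cube& eps_x,   // n_t x B x n_s
                       const arma::mat& eps_r,    // B x m_r
                       const arma::mat& eps_s,    // B x m_s
                       const arma::mat& eps_u,    // n_t x B
                       bool want_grad) {
  const Layout L(dims);
  const int n_t = L.n_t, B = (int) Y.n_cols, n_s = L.n_s, m_r = L.m_r,
            m_s = L.m_s, n_l = L.n_l, n_h = L.n_h;
  if ((int) Y.n_rows != n_t) stop("Y has wrong number of time steps");
  const double LOG2PI = std::log(2.0 * M_PI);
  const double inv_n = 1.0 / (double) n_regions;

  const arma::mat Wx1 = pview(params, L.Wx1, 4 * n_l, L.d_in);
  const arma::mat Wh1 = pview(params, L.Wh1, 4 * n_l, n_l);
  const arma::vec bh1 = pview(params, L.bh1, 4 * n_l, 1);
  const arma::mat Ho1 = pview(params, L.Ho1, 2 * n_s, n_l);
  const arma::vec bo1 = pview(params, L.bo1, 2 * n_s, 1);
  const arma::mat Wx2 = pview(params, L.Wx2, 4 * n_l, L.d_in);
  const arma::mat Wh2 = pview(params, L.Wh2, 4 * n_l, n_l);
  const arma::vec bh2 = pview(params, L.bh2, 4 * n_l, 1);
  const arma::mat Ho2 = pview(params, L.Ho2, 2 * m_r, n_l);
  const arma::vec bo2 = pview(params, L.bo2, 2 * m_r, 1);
  const arma::mat M1 = pview(params, L.M1, m_s, L.n_sub);
  const arma::mat V1 = pview(params, L.V1, m_s, L.n_sub);
  const arma::mat M2 = pview(params, L.M2, n_t, L.n_sub);
  const arma::mat V2 = pview(params, L.V2, n_t, L.n_sub);
  const arma::mat W1f = pview(params, L.W1f, n_h, L.n_i);
  const arma::vec b1f = pview(params, L.b1f, n_h, 1);
  const arma::mat W2f = pview(params, L.W2f, n_s, n_h);
  const arma::vec b2f = pview(params, L.b2f, n_s, 1);
  const arma::vec a = pview(params, L.a, n_s, 1);
  const double bb = params(L.b);
  const double lso = params(L.lso);
  const arma::vec lss = pview(params, L.lss, n_s, 1);
  const double ltau = params(L.ltau);
  const double tau = std::exp(ltau);
  const double alpha = std::exp(-1.0 / tau);
  const double so2 = std::exp(lso);
  const arma::vec ss2 = arma::exp(lss);

  // encoder inputs: [y_k, u_k, one-hot subject]
  std::vector<arma::mat> X(n_t);
  for (int k = 0; k < n_t; ++k) {
    arma::mat xk(B, L.d_in, arma::fill::zeros);
    for (int bq = 0; bq < B; ++bq) {
      xk(bq, 0) = Y(k, bq);
      xk(bq, 1) = U(k, bq);
      xk(bq, 2 + subj[bq]) = 1.0;
    }
    X[k] = xk;
  }

  LstmCache c1, c2;
  lstm_forward(X, Wx1, Wh1, bh1, n_l, c1);
  lstm_forward(X, Wx2, Wh2, bh2, n_l, c2);

  // state posterior per step and reparameterized samples
  std::vector<arma::mat> mu_x(n_t), lv_x(n_t), xs(n_t);  // B x n_s
  for (int k = 0; k < n_t; ++k) {
    arma::mat O = c1.h[k] * Ho1.t();
    O.each_row() += bo1.t();
    mu_x[k] = O.cols(0, n_s - 1);
    lv_x[k] = O.cols(n_s, 2 * n_s - 1);
    arma::mat ek(B, n_s);
    for (int bq = 0; bq < B; ++bq)
      for (int s = 0; s < n_s; ++s) ek(bq, s) = eps_x(k, bq, s);
    xs[k] = mu_x[k] + arma::exp(0.5 * lv_x[k]) % ek;
  }
  arma::mat O2 = c2.h[n_t - 1] * Ho2.t();
  O2.each_row() += bo2.t();
  arma::mat mu_r = O2.cols(0, m_r - 1);
  arma::mat lv_r = O2.cols(m_r, 2 * m_r - 1);
  arma::mat th_r = mu_r + arma::exp(0.5 * lv_r) % eps_r;
  arma::mat mu_s(B, m_s), lv_s(B, m_s), th_s(B, m_s);
  for (int bq = 0; bq < B; ++bq)
    for (int m = 0; m < m_s; ++m) {
      mu_s(bq, m) = M1(m, subj[bq]);
      lv_s(bq, m) = V1(m, subj[bq]);
      th_s(bq, m) = mu_s(bq, m) + std::exp(0.5 * lv_s(bq, m)) * eps_s(bq, m);
    }
  arma::mat mu_u(n_t, B), lv_u(n_t, B), us(n_t, B);
  for (int bq = 0; bq < B; ++bq)
    for (int k = 0; k < n_t; ++k) {
      mu_u(k, bq) = M2(k, subj[bq]);
      lv_u(k, bq) = V2(k, subj[bq]);
      us(k, bq) = mu_u(k, bq) + std::exp(0.5 * lv_u(k, bq)) * eps_u(k, bq);
    }

  // reconstruction
  arma::mat pred(n_t, B);
  for (int k = 0; k < n_t; ++k)
    pred.row(k) = (xs[k] * a).t() + bb;
  double rec = -0.5 * n_t * B * (LOG2PI + lso)
               - 0.5 * arma::accu(arma::square(pred - Y)) / so2;

  // state prior under the f-rollout density, k = 0..n_t-2
  const int Tm1 = n_t - 1;
  std::vector<arma::mat> Z(Tm1), Hrelu(Tm1), resid_x(Tm1);
  double lpx = -0.5 * B * n_s * LOG2PI
               - 0.5 * arma::accu(arma::square(xs[0]));
  for (int k = 0; k < Tm1; ++k) {
    arma::mat z(L.n_i, B);
    z.rows(0, n_s - 1) = xs[k].t();
    if (m_r > 0) z.rows(n_s, n_s + m_r - 1) = th_r.t();
    if (m_s > 0) z.rows(n_s + m_r, n_s + m_r + m_s - 1) = th_s.t();
    z.row(L.n_i - 2) = us.row(k);
    z.row(L.n_i - 1) = U.row(k);
    arma::mat h = W1f * z;
    h.each_col() += b1f;
    arma::mat hr = h;
    hr.transform([](double v) { return v > 0.0 ? v : 0.0; });
    arma::mat f = W2f * hr;
    f.each_col() += b2f;
    Z[k] = z; Hrelu[k] = hr;
    arma::mat resid = xs[k + 1].t() - xs[k].t() - f;  // n_s x B
    resid_x[k] = resid;
    for (int s = 0; s < n_s; ++s)
      lpx += -0.5 * B * (LOG2PI + lss(s))
             - 0.5 * arma::accu(arma::square(resid.row(s))) / ss2(s);
  }

  double Hx = 0.0;
  for (int k = 0; k < n_t; ++k)
    Hx += 0.5 * arma::accu(lv_x[k] + 1.0 + LOG2PI);
  double KLr = 0.5 * arma::accu(arma::square(mu_r) + arma::exp(lv_r)
                                - 1.0 - lv_r);
  double KLs = (m_s > 0)
    ? 0.5 * arma::accu(arma::square(mu_s) + arma::exp(lv_s) - 1.0 - lv_s)
    : 0.0;
  double lpu = -0.5 * B * LOG2PI
               - 0.5 * arma::accu(arma::square(us.row(0)));
  arma::mat eu(n_t, B, arma::fill::zeros);
  for (int k = 1; k < n_t; ++k) {
    eu.row(k) = us.row(k) - alpha * us.row(k - 1);
    lpu += -0.5 * B * LOG2PI - 0.5 * arma::accu(arma::square(eu.row(k)));
  }
  double Hu = 0.5 * arma::accu(lv_u + 1.0 + LOG2PI);

  double reg_x = 0.0;
  for (int k = 0; k < n_t; ++k) reg_x += arma::accu(arma::square(xs[k]));
  reg_x *= alpha_x;
  double reg_f = alpha_f * (arma::accu(arma::square(W1f))
                            + arma::accu(arma::square(b1f))
                            + arma::accu(arma::square(W2f))
                            + arma::accu(arma::square(b2f)));

  double elbo = rec + beta * (lpx + Hx - KLr - inv_n * KLs
                              + inv_n * (lpu + Hu));
  double loss = -elbo + reg_x + reg_f;

  List terms = List::create(
    _["reconstruction"] = rec, _["state_prior"] = lpx,
    _["state_entropy"] = Hx, _["kl_theta_r"] = KLr,
    _["kl_theta_s"] = KLs, _["ext_prior"] = lpu,
    _["ext_entropy"] = Hu, _["reg_x"] = reg_x, _["reg_f"] = reg_f);

  if (!std::isfinite(loss)) {
    CharacterVector nm = terms.names();
    for (int i = 0; i < terms.size(); ++i)
      if (!std::isfinite(as<double>(terms[i])))
        stop("non-finite ELBO term '%s'", std::string(nm[i]).c_str());
    stop("non-finite loss");
  }

  if (!want_grad)
    return List::create(_["loss"] = loss, _["elbo"] = elbo,
                        _["terms"] = terms);

  // ============================ backward ============================
  arma::vec grad(L.total, arma::fill::zeros);
  std::vector<arma::mat> dxs(n_t);
  for (int k = 0; k < n_t; ++k) dxs[k].zeros(B, n_s);
  arma::mat dth_r(B, m_r, arma::fill::zeros);
  arma::mat dth_s(B, m_s, arma::fill::zeros);
  arma::mat dus(n_t, B, arma::fill::zeros);

  // reconstruction: d(-rec)
  {
    arma::mat dpred = (pred - Y) / so2;
    for (int k = 0; k < n_t; ++k)
      dxs[k] += dpred.row(k).t() * a.t();
    arma::vec da(n_s, arma::fill::zeros);
    for (int k = 0; k < n_t; ++k) da += xs[k].t() * dpred.row(k).t();
    acc(grad, L.a, da);
    grad(L.b) += arma::accu(dpred);
    grad(L.lso) += 0.5 * n_t * B
                   - 0.5 * arma::accu(arma::square(pred - Y)) / so2;
  }

  // state prior (weight beta) and the MLP f
  {
    dxs[0] += beta * xs[0];
    arma::mat dW1f(n_h, L.n_i, arma::fill::zeros);
    arma::vec db1f(n_h, arma::fill::zeros);
    arma::mat dW2f(n_s, n_h, arma::fill::zeros);
    arma::vec db2f(n_s, arma::fill::zeros);
    arma::vec dlss(n_s, arma::fill::zeros);
    for (int k = 0; k < Tm1; ++k) {
      arma::mat rt = resid_x[k];
      rt.each_col() /= ss2;
      rt *= beta;                       // d(-beta lpx)/dresid
      dxs[k + 1] += rt.t();
      dxs[k] -= rt.t();
      arma::mat df = -rt;
      dW2f += df * Hrelu[k].t();
      db2f += arma::sum(df, 1);
      arma::mat dH = W2f.t() * df;
      dH.elem(arma::find(Hrelu[k] == 0.0)).zeros();
      dW1f += dH * Z[k].t();
      db1f += arma::sum(dH, 1);
      arma::mat dz = W1f.t() * dH;
      dxs[k] += dz.rows(0, n_s - 1).t();
      if (m_r > 0) dth_r += dz.rows(n_s, n_s + m_r - 1).t();
      if (m_s > 0) dth_s += dz.rows(n_s + m_r, n_s + m_r + m_s - 1).t();
      dus.row(k) += dz.row(L.n_i - 2);
      for (int s = 0; s < n_s; ++s)
        dlss(s) += beta * (0.5 * B
                   - 0.5 * arma::accu(arma::square(resid_x[k].row(s)))
                         / ss2(s));
    }
    acc(grad, L.W1f, dW1f); acc(grad, L.b1f, db1f);
    acc(grad, L.W2f, dW2f); acc(grad, L.b2f, db2f);
    acc(grad, L.lss, dlss);
  }

  // regularizers
  for (int k = 0; k < n_t; ++k) dxs[k] += 2.0 * alpha_x * xs[k];
  acc(grad, L.W1f, 2.0 * alpha_f * W1f);
  acc(grad, L.b1f, 2.0 * alpha_f * b1f);
  acc(grad, L.W2f, 2.0 * alpha_f * W2f);
  acc(grad, L.b2f, 2.0 * alpha_f * b2f);

  // external-input AR prior (weight beta/n)
  {
    for (int k = 0; k < n_t; ++k) {
      arma::rowvec d = (k == 0) ? arma::rowvec(us.row(0)) : arma::rowvec(eu.row(k));
      if (k + 1 < n_t) d -= alpha * eu.row(k + 1);
      dus.row(k) += beta * inv_n * d;
    }
    double dalpha = 0.0;
    for (int k = 1; k < n_t; ++k)
      dalpha += -arma::accu(eu.row(k) % us.row(k - 1));
    grad(L.ltau) += beta * inv_n * dalpha * alpha / tau;  // dalpha/dltau = alpha/tau
  }

  // states: sample chain + entropy -> h1 head -> BPTT
  {
    arma::mat dHo1(2 * n_s, n_l, arma::fill::zeros);
    arma::vec dbo1(2 * n_s, arma::fill::zeros);
    std::vector<arma::mat> dh_up(n_t);
    for (int k = 0; k < n_t; ++k) {
      arma::mat dmu = dxs[k];
      arma::mat dlv = 0.5 * dxs[k] % (xs[k] - mu_x[k]) - 0.5 * beta;
      arma::mat dO(B, 2 * n_s);
      dO.cols(0, n_s - 1) = dmu;
      dO.cols(n_s, 2 * n_s - 1) = dlv;
      dHo1 += dO.t() * c1.h[k];
      dbo1 += arma::sum(dO, 0).t();
      dh_up[k] = dO * Ho1;
    }
    acc(grad, L.Ho1, dHo1); acc(grad, L.bo1, dbo1);
    arma::mat dWx, dWh; arma::vec dbh;
    lstm_backward(X, Wh1, c1, dh_up, n_l, dWx, dWh, dbh);
    acc(grad, L.Wx1, dWx); acc(grad, L.Wh1, dWh); acc(grad, L.bh1, dbh);
  }

  // regional parameters: sample chain + closed-form KL -> h2 head -> BPTT
  {
    arma::mat dmu_r = dth_r + beta * mu_r;
    arma::mat dlv_r = 0.5 * dth_r % (th_r - mu_r)
                      + beta * 0.5 * (arma::exp(lv_r) - 1.0);
    arma::mat dO(B, 2 * m_r);
    dO.cols(0, m_r - 1) = dmu_r;
    dO.cols(m_r, 2 * m_r - 1) = dlv_r;
    acc(grad, L.Ho2, dO.t() * c2.h[n_t - 1]);
    acc(grad, L.bo2, arma::sum(dO, 0).t());
    std::vector<arma::mat> dh_up(n_t);
    dh_up[n_t - 1] = dO * Ho2;
    arma::mat dWx, dWh; arma::vec dbh;
    lstm_backward(X, Wh2, c2, dh_up, n_l, dWx, dWh, dbh);
    acc(grad, L.Wx2, dWx); acc(grad, L.Wh2, dWh); acc(grad, L.bh2, dbh);
  }

  // subject parameters: sample chain + closed-form KL (weight beta/n)
  if (m_s > 0) {
    arma::mat dmu_s = dth_s + beta * inv_n * mu_s;
    arma::mat dlv_s = 0.5 * dth_s % (th_s - mu_s)
                      + beta * inv_n * 0.5 * (arma::exp(lv_s) - 1.0);
    for (int bq = 0; bq < B; ++bq)
      for (int m = 0; m < m_s; ++m) {
        grad(L.M1 + subj[bq] * m_s + m) += dmu_s(bq, m);
        grad(L.V1 + subj[bq] * m_s + m) += dlv_s(bq, m);
      }
  }

  // external input: sample chain + entropy (weight beta/n)
  {
    arma::mat dmu_u = dus;
    arma::mat dlv_u = 0.5 * dus % (us - mu_u) - 0.5 * beta * inv_n;
    for (int bq = 0; bq < B; ++bq)
      for (int k = 0; k < n_t; ++k) {
        grad(L.M2 + subj[bq] * n_t + k) += dmu_u(k, bq);
        grad(L.V2 + subj[bq] * n_t + k) += dlv_u(k, bq);
      }
  }

  return List::create(_["loss"] = loss, _["elbo"] = elbo,
                      _["terms"] = terms, _["grad"] = grad);
}

// Forward-only posterior extraction: returns the posterior means and
// log-variances for states and regional parameters for a batch, plus the
// subject-level lookups.
// [[Rcpp::export]]
List vae_encode_cpp(const arma::vec& params, const IntegerVector& dims,
                    const arma::mat& Y, const arma::mat& U,
                    const IntegerVector& subj) {
  const Layout L(dims);
  const int n_t = L.n_t, B = (int) Y.n_cols, n_s = L.n_s, m_r = L.m_r,
            m_s = L.m_s, n_l = L.n_l;
  const arma::mat Wx1 = pview(params, L.Wx1, 4 * n_l, L.d_in);
  const arma::mat Wh1 = pview(params, L.Wh1, 4 * n_l, n_l);
  const arma::vec bh1 = pview(params, L.bh1, 4 * n_l, 1);
  const arma::mat Ho1 = pview(params, L.Ho1, 2 * n_s, n_l);
  const arma::vec bo1 = pview(params, L.bo1, 2 * n_s, 1);
  const arma::mat Wx2 = pview(params, L.Wx2, 4 * n_l, L.d_in);
  const arma::mat Wh2 = pview(params, L.Wh2, 4 * n_l, n_l);
  const arma::vec bh2 = pview(params, L.bh2, 4 * n_l, 1);
  const arma::mat Ho2 = pview(params, L.Ho2, 2 * m_r, n_l);
  const arma::vec bo2 = pview(params, L.bo2, 2 * m_r, 1);
  const arma::mat M1 = pview(params, L.M1, m_s, L.n_sub);
  const arma::mat V1 = pview(params, L.V1, m_s, L.n_sub);
  const arma::mat M2 = pview(params, L.M2, n_t, L.n_sub);
  const arma::mat V2 = pview(params, L.V2, n_t, L.n_sub);

  std::vector<arma::mat> X(n_t);
  for (int k = 0; k < n_t; ++k) {
    arma::mat xk(B, L.d_in, arma::fill::zeros);
    for (int bq = 0; bq < B; ++bq) {
      xk(bq, 0) = Y(k, bq);
      xk(bq, 1) = U(k, bq);
      xk(bq, 2 + subj[bq]) = 1.0;
    }
    X[k] = xk;
  }
  LstmCache c1, c2;
  lstm_forward(X, Wx1, Wh1, bh1, n_l, c1);
  lstm_forward(X, Wx2, Wh2, bh2, n_l, c2);
  arma::cube mu_x(n_t, B, n_s), lv_x(n_t, B, n_s);
  for (int k = 0; k < n_t; ++k) {
    arma::mat O = c1.h[k] * Ho1.t();
    O.each_row() += bo1.t();
    for (int bq = 0; bq < B; ++bq)
      for (int s = 0; s < n_s; ++s) {
        mu_x(k, bq, s) = O(bq, s);
        lv_x(k, bq, s) = O(bq, n_s + s);
      }
  }
  arma::mat O2 = c2.h[n_t - 1] * Ho2.t();
  O2.each_row() += bo2.t();
  arma::mat mu_s(m_s, B), lv_s(m_s, B);
  arma::mat mu_u(n_t, B), lv_u(n_t, B);
  for (int bq = 0; bq < B; ++bq) {
    if (m_s > 0) { mu_s.col(bq) = M1.col(subj[bq]); lv_s.col(bq) = V1.col(subj[bq]); }
    mu_u.col(bq) = M2.col(subj[bq]);
    lv_u.col(bq) = V2.col(subj[bq]);
  }
  return List::create(
    _["mu_x"] = mu_x, _["logvar_x"] = lv_x,
    _["mu_r"] = O2.cols(0, m_r - 1),
    _["logvar_r"] = O2.cols(m_r, 2 * m_r - 1),
    _["mu_s"] = mu_s, _["logvar_s"] = lv_s,
    _["mu_u"] = mu_u, _["logvar_u"] = lv_u);
}
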