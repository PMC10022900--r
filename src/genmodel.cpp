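// Closed-loop rollout of the learned generative network model.
// Each node j carries an n_s-dimensional state evolved by the shared
// two-layer ReLU vector field f; nodes are coupled through the noise-free
// linear projection g(x) = a.x + b of their states.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// f applied to a batch of inputs: Z is (n_i x B); returns (n_s x B).
static arma::mat mlp_eval(const arma::mat& W1, const arma::vec& b1,
                          const arma::mat& W2, const arma::vec& b2,
                          const arma::mat& Z) {
  arma::mat H = W1 * Z;
  H.each_col() += b1;
  H.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat out = W2 * H;
  out.each_col() += b2;
  return out;
}

// [[Rcpp::export]]
arma::mat mlp_eval_cpp(const arma::mat& W1, const arma::vec& b1,
                       const arma::mat& W2, const arma::vec& b2,
                       const arma::mat& Z) {
  return mlp_eval(W1, b1, W2, b2, Z);
}

// [[Rcpp::export]]
List network_rollout_cpp(const arma::mat& W1, const arma::vec& b1,
                         const arma::mat& W2, const arma::vec& b2,
                         const arma::vec& a_proj, double b_proj,
                         double sigma_o, const arma::vec& sigma_s,
                         const arma::mat& theta_r,  // n x m_r
                         const arma::vec& theta_s,  // m_s
                         const arma::mat& Wnet,     // n x n
                         const arma::vec& u_ext,    // burn_in + n_t
                         int n_t, int burn_in,
                         bool use_network, bool system_noise,
                         bool observation_noise,
                         const arma::mat& x_init) { // n_s x n
  const int n = theta_r.n_rows;
  const int n_s = a_proj.n_elem;
  const int m_r = theta_r.n_cols;
  const int m_s = theta_s.n_elem;
  const int n_i = n_s + m_r + m_s + 2;
  const int total = burn_in + n_t;
  arma::mat X = x_init;                  // n_s x n current state
  arma::mat Y(n_t, n);                   // observations
  arma::cube Xout(n_t, n_s, n);
  arma::mat Z(n_i, n);
  for (int r = 0; r < n; ++r)
    for (int m = 0; m < m_r; ++m) Z(n_s + m, r) = theta_r(r, m);
  for (int r = 0; r < n; ++r)
    for (int m = 0; m < m_s; ++m) Z(n_s + m_r + m, r) = theta_s(m);
  for (int k = 0; k < total; ++k) {
    arma::rowvec g = a_proj.t() * X;     // 1 x n, noise-free projection
    g += b_proj;
    arma::vec u(n, arma::fill::zeros);
    if (use_network) u = Wnet * g.t();
    for (int r = 0; r < n; ++r) {
      for (int s = 0; s < n_s; ++s) Z(s, r) = X(s, r);
      Z(n_i - 2, r) = u_ext(k);
      Z(n_i - 1, r) = u(r);
    }
    arma::mat F = mlp_eval(W1, b1, W2, b2, Z);
    if (system_noise) {
      arma::mat eta(n_s, n);
      for (int s = 0; s < n_s; ++s)
        for (int r = 0; r < n; ++r) eta(s, r) = norm_rand() * sigma_s(s);
      X += F + eta;
    } else {
      X += F;
    }
    if (!X.is_finite())
      stop("non-finite state in network rollout at step %d", k + 1);
    if (k >= burn_in) {
      int t = k - burn_in;
      arma::rowvec yk = a_proj.t() * X;
      yk += b_proj;
      if (observation_noise)
        for (int r = 0; r < n; ++r) yk(r) += norm_rand() * sigma_o;
      Y.row(t) = yk;
      for (int s = 0; s < n_s; ++s)
        for (int r = 0; r < n; ++r) Xout(t, s, r) = X(s, r);
    }
  }
  return List::create(_["y"] = Y, _["x"] = Xout);
}
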