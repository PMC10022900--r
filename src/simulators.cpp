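// Euler-Maruyama integrators for the two stochastic whole-brain simulators.
// Noise convention: additive Gaussian increments sd * sqrt(dt) * N(0,1).
// All random draws come from R's RNG so that set.seed() on the R side
// makes trajectories reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void check_finite(const arma::vec& v, int step) {
  if (!v.is_finite())
    stop("non-finite state at step %d: check noise level and time step", step);
}

// Hopf network: planar oscillator per node, diffusive coupling through both
// variables. States x, y are (n_steps+1) x n matrices including the initial
// condition row.
// [[Rcpp::export]]
List hopf_sim_cpp(const arma::mat& W, const arma::vec& a,
                  const arma::vec& omega, double G, double beta,
                  double dt, int n_steps,
                  const arma::vec& x0, const arma::vec& y0) {
  const int n = W.n_rows;
  arma::mat X(n_steps + 1, n), Y(n_steps + 1, n);
  arma::vec x = x0, y = y0;
  X.row(0) = x.t(); Y.row(0) = y.t();
  const arma::vec rowsum = arma::sum(W, 1);
  const double sq = beta * std::sqrt(dt);
  for (int k = 0; k < n_steps; ++k) {
    arma::vec r2 = arma::square(x) + arma::square(y);
    arma::vec cx = G * (W * x - rowsum % x);
    arma::vec cy = G * (W * y - rowsum % y);
    arma::vec dx = (a - r2) % x - omega % y + cx;
    arma::vec dy = (a - r2) % y + omega % x + cy;
    if (sq > 0.0) {
      arma::vec nx(n), ny(n);
      for (int i = 0; i < n; ++i) { nx(i) = norm_rand(); ny(i) = norm_rand(); }
      x += dt * dx + sq * nx;
      y += dt * dy + sq * ny;
    } else {
      x += dt * dx;
      y += dt * dy;
    }
    if ((k & 255) == 0 || k == n_steps - 1) { check_finite(x, k + 1); check_finite(y, k + 1); }
    X.row(k + 1) = x.t(); Y.row(k + 1) = y.t();
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// Sigmoidal population transfer function with its removable singularity at
// a*x - b = 0 handled by the series limit 1/d + z/2 + d z^2 / 12.
// [[Rcpp::export]]
arma::vec pmfm_transfer_cpp(const arma::vec& x, double aH, double bH, double dH) {
  arma::vec z = aH * x - bH, H(x.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) {
    double dz = dH * z(i);
    if (std::fabs(dz) < 1e-6)
      H(i) = 1.0 / dH + z(i) / 2.0 + dH * z(i) * z(i) / 12.0;
    else
      H(i) = z(i) / (1.0 - std::exp(-dz));
  }
  return H;
}

// Parametric mean-field network: one synaptic gating variable per node.
// Time is in milliseconds (tau_s = 100 ms, dt = 10 ms by protocol).
// [[Rcpp::export]]
List pmfm_sim_cpp(const arma::mat& W, const arma::vec& r,
                  const arma::vec& sigma, double G, double J, double Io,
                  double tau_s, double gamma,
                  double aH, double bH, double dH,
                  double dt, int n_steps, const arma::vec& S0) {
  const int n = W.n_rows;
  arma::mat S(n_steps + 1, n);
  arma::vec s = S0;
  S.row(0) = s.t();
  const double sqdt = std::sqrt(dt);
  int n_out_of_range = 0;
  for (int k = 0; k < n_steps; ++k) {
    arma::vec In = G * (W * s);
    arma::vec x = r % (J * s) + Io + In;
    arma::vec H = pmfm_transfer_cpp(x, aH, bH, dH);
    arma::vec drift = -s / tau_s + (1.0 - s) % (gamma * H);
    if (arma::any(sigma > 0.0)) {
      arma::vec eta(n);
      for (int i = 0; i < n; ++i) eta(i) = norm_rand();
      s += dt * drift + sqdt * (sigma % eta);
    } else {
      s += dt * drift;
    }
    if ((k & 255) == 0 || k == n_steps - 1) check_finite(s, k + 1);
    n_out_of_range += (int) (arma::sum(s < 0.0) + arma::sum(s > 1.0));
    S.row(k + 1) = s.t();
  }
  return List::create(_["S"] = S, _["n_out_of_range"] = n_out_of_range);
}
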