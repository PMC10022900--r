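#' Construct the learned generative model container
#'
#' The generative system is a shared neural mass `f` (two-layer ReLU
#' network), a linear observation model `g(x) = a . x + b` with Gaussian
#' noise `sigma_o`, per-state system noise SDs `sigma_s`, and an AR(1)
#' prior with time scale `tau` for the subject-wide external input. Time
#' is discretized at one sample unit (`dt = 1`): all learned rates are
#' per-sample, the physical sampling interval is metadata.
#'
#' @param mlp a [neural_mass_mlp].
#' @param obs list with `a` (length `n_s`), `b`, `sigma_o`.
#' @param sigma_s positive vector of system-noise SDs (length `n_s`).
#' @param tau AR(1) time scale of the external-input prior, in samples.
#' @return An object of class `generative_model`.
#' @export
generative_model <- function(mlp, obs, sigma_s, tau) {
  stopifnot(inherits(mlp, "neural_mass_mlp"),
            length(obs$a) == mlp$n_s, obs$sigma_o > 0,
            length(sigma_s) == mlp$n_s, all(sigma_s > 0), tau > 0)
  structure(list(mlp = mlp, obs = obs, sigma_s = sigma_s,
                 ext = external_input_prior(tau), dt = 1),
            class = "generative_model")
}

#' Two-layer ReLU neural mass
#'
#' `f(z) = W2 relu(W1 z + b1) + b2`, where `z` is the concatenation of
#' the state (`n_s`), regional parameters (`m_r`), subject parameters
#' (`m_s`), the external input and the network input, so the input size
#' is `n_i = n_s + m_r + m_s + 2`.
#'
#' @param W1 matrix `n_h x n_i`; `b1` length `n_h`; `W2` matrix
#'   `n_s x n_h`; `b2` length `n_s`.
#' @param b1,W2,b2 see `W1`.
#' @param n_s,m_r,m_s state / regional / subject parameter dimensions.
#' @return An object of class `neural_mass_mlp`.
#' @export
neural_mass_mlp <- function(W1, b1, W2, b2, n_s, m_r, m_s) {
  n_i <- n_s + m_r + m_s + 2
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  stopifnot(ncol(W1) == n_i, length(b1) == nrow(W1),
            nrow(W2) == n_s, ncol(W2) == nrow(W1), length(b2) == n_s)
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2,
                 b2 = as.numeric(b2), n_s = n_s, m_r = m_r, m_s = m_s,
                 n_h = nrow(W1), n_i = n_i),
            class = "neural_mass_mlp")
}

#' AR(1) prior for the external input
#'
#' `u_0 ~ N(0, 1)`, `u_{k+1} ~ N(alpha u_k, 1)` with
#' `alpha = exp(-1/tau)`. The innovation SD is fixed to 1 because any
#' scaling can be absorbed by the vector field.
#'
#' @param tau time scale in samples (> 0).
#' @return List of class `external_input_prior` with `tau`, `alpha`,
#'   `sigma = 1`.
#' @export
external_input_prior <- function(tau) {
  stopifnot(tau > 0)
  alpha <- exp(-1 / tau)
  structure(list(tau = tau, alpha = alpha, sigma = 1),
            class = "external_input_prior")
}

#' Network input computed from observations
#'
#' Because the coupling acts through the observed variable, the input to
#' region `j` is `u_j(t) = sum_i w_ji y_i(t)`: a known linear function of
#' the data, independent of any hidden state. This is what decouples the
#' network inference into independent regional problems.
#'
#' @param y observation matrix, time by regions.
#' @param W a [connectome] with matching size.
#' @return Matrix of the same shape as `y`.
#' @export
compute_network_input <- function(y, W) {
  stopifnot(inherits(W, "connectome"))
  y <- as.matrix(y)
  if (ncol(y) != W$n_regions)
    stop("y has ", ncol(y), " regions but the connectome has ",
         W$n_regions)
  y %*% t(W$weights)
}

#' Evaluate the neural mass vector field
#'
#' @param x state vector (length `n_s`).
#' @param theta_r,theta_s parameter vectors (lengths `m_r`, `m_s`).
#' @param u_ext_k,u_k scalar external and network inputs.
#' @param mlp a [neural_mass_mlp].
#' @return `dx/dt`, length `n_s`.
#' @export
eval_f <- function(x, theta_r, theta_s, u_ext_k, u_k, mlp) {
  stopifnot(inherits(mlp, "neural_mass_mlp"))
  z <- c(x, theta_r, theta_s, u_ext_k, u_k)
  if (length(z) != mlp$n_i)
    stop("concatenated input has length ", length(z),
         " but the network expects n_i = ", mlp$n_i)
  as.numeric(mlp_eval_cpp(mlp$W1, mlp$b1, mlp$W2, mlp$b2,
                          matrix(z, ncol = 1)))
}

#' One Euler step of the generative state equation
#'
#' `x_{k+1} = x_k + dt * f(...) + noise`, with the noise vector supplied
#' by the caller so both stochastic sampling and noise-free rollouts use
#' the same path.
#'
#' @param x_k current state.
#' @param theta_r,theta_s,u_ext_k,u_k inputs to the vector field.
#' @param model a [generative_model].
#' @param noise additive noise vector (length `n_s`), e.g.
#'   `rnorm(n_s) * model$sigma_s`.
#' @return The next state.
#' @export
step_state <- function(x_k, theta_r, theta_s, u_ext_k, u_k, model,
                       noise = 0) {
  stopifnot(inherits(model, "generative_model"))
  x_k + model$dt * eval_f(x_k, theta_r, theta_s, u_ext_k, u_k,
                          model$mlp) + noise
}

#' Linear observation of a state
#'
#' @param x_k state vector.
#' @param obs observation model list (`a`, `b`, `sigma_o`).
#' @param noise scalar observation noise (caller-supplied).
#' @return Scalar observation `a . x + b + noise`.
#' @export
observe <- function(x_k, obs, noise = 0) {
  sum(obs$a * x_k) + obs$b + noise
}

#' Sample an external-input series from its AR(1) prior
#'
#' @param prior an [external_input_prior].
#' @param n_t series length.
#' @param seed integer seed.
#' @return Numeric vector of length `n_t`.
#' @export
sample_external_input <- function(prior, n_t, seed) {
  stopifnot(inherits(prior, "external_input_prior"))
  set.seed(seed)
  u <- numeric(n_t)
  u[1] <- rnorm(1, 0, prior$sigma)
  if (n_t > 1)
    for (k in 2:n_t)
      u[k] <- rnorm(1, prior$alpha * u[k - 1], prior$sigma)
  u
}

#' Closed-loop simulation of the learned network model
#'
#' Rolls out the coupled system: at every step the coupling input to node
#' `j` is `sum_i w_ji g(x_i)` using the noise-free projection (the
#' observation noise is assumed small enough to be folded into the
#' coupling). Toggles allow switching off the external input and/or the
#' network coupling, mirroring the "only ext"/"only net" comparisons.
#' The initial state is drawn from its `N(0, I)` prior and a burn-in is
#' discarded.
#'
#' @param model a [generative_model].
#' @param theta_r matrix, regions by `m_r`.
#' @param theta_s vector of subject parameters (length `m_s`).
#' @param W a [connectome].
#' @param n_t number of retained samples.
#' @param seed integer seed.
#' @param u_ext external-input series of length `burn_in + n_t`, or
#'   `NULL` to sample from the AR(1) prior.
#' @param use_external,use_network toggles zeroing the external input or
#'   the connectome.
#' @param system_noise,observation_noise noise toggles (both on for
#'   posterior-predictive generation; off for deterministic rollouts).
#' @param burn_in initial samples discarded (default 50).
#' @return List with `y` (`n_t` by regions, observation noise included)
#'   and the latent trajectory `x` (`n_t` by `n_s` by regions).
#' @export
simulate_network <- function(model, theta_r, theta_s, W, n_t, seed,
                             u_ext = NULL, use_external = TRUE,
                             use_network = TRUE, system_noise = TRUE,
                             observation_noise = TRUE, burn_in = 50) {
  stopifnot(inherits(model, "generative_model"),
            inherits(W, "connectome"))
  theta_r <- as.matrix(theta_r)
  n <- nrow(theta_r)
  stopifnot(n == W$n_regions, ncol(theta_r) == model$mlp$m_r,
            length(theta_s) == model$mlp$m_s)
  set.seed(seed)
  total <- burn_in + n_t
  if (!use_external) {
    u_ext <- numeric(total)
  } else if (is.null(u_ext)) {
    u_ext <- sample_external_input(model$ext, total,
                                   sample.int(.Machine$integer.max, 1))
  }
  stopifnot(length(u_ext) == total)
  x0 <- matrix(rnorm(model$mlp$n_s * n), model$mlp$n_s, n)
  out <- network_rollout_cpp(
    model$mlp$W1, model$mlp$b1, model$mlp$W2, model$mlp$b2,
    model$obs$a, model$obs$b, model$obs$sigma_o, model$sigma_s,
    theta_r, as.numeric(theta_s), W$weights, u_ext,
    n_t, burn_in, use_network, system_noise, observation_noise, x0)
  attr(out$y, "sampling_interval") <- NA_real_
  out
}
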