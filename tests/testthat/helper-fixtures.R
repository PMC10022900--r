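# Shared fixtures built in code. Heavy objects are cached lazily in this
# environment so that only the files that need them pay for them once.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small Hopf cohort for fast unit tests (default protocol durations are
# exercised separately in the acceptance file)
tiny_hopf_cohort <- function() {
  fixture("tiny_hopf", function()
    build_hopf_cohort(n_subjects = 2, seed = 101, n_regions = 6,
                      duration = 65, discard = 25))
}

# reduced-scale study cohort (4 subjects x 20 regions x 180 samples)
reduced_hopf_cohort <- function() {
  fixture("reduced_hopf", function()
    build_hopf_cohort(n_subjects = 4, seed = 11, n_regions = 20))
}

reduced_training_config <- function(m_r = 2) {
  training_config(n_s = 2, m_r = m_r, m_s = 1, n_l = 64, n_h = 64,
                  epochs_phase1 = 300, epochs_phase2 = 150,
                  kl_ramp_epochs = 100, seed = 5)
}

# the reduced-cohort training run shared by the acceptance checks
reduced_trained <- function() {
  fixture("reduced_trained", function()
    train(reduced_hopf_cohort(), reduced_training_config(m_r = 2)))
}

reduced_trained_mr4 <- function() {
  fixture("reduced_trained_mr4", function()
    train(reduced_hopf_cohort(), reduced_training_config(m_r = 4)))
}

hopf_ground_truth <- function(cohort, what) {
  unlist(lapply(cohort$subjects, function(s) s$ground_truth[[what]]))
}

# a hand-set generative model with prescribed MLP weights, for tests that
# need full control over the vector field
toy_generative_model <- function(W1, b1, W2, b2, n_s, m_r, m_s = 0,
                                 a = NULL, b = 0, sigma_o = 0.1,
                                 sigma_s = NULL, tau = 10) {
  mlp <- neural_mass_mlp(W1, b1, W2, b2, n_s, m_r, m_s)
  if (is.null(a)) a <- c(1, rep(0, n_s - 1))
  if (is.null(sigma_s)) sigma_s <- rep(0.1, n_s)
  generative_model(mlp, list(a = a, b = b, sigma_o = sigma_o),
                   sigma_s, tau)
}

# linear field f(x) = -decay * x as a ReLU network: -x = relu(-x) - relu(x)
linear_decay_model <- function(n_s, m_r = 1, m_s = 0, decay = 0.5, ...) {
  n_i <- n_s + m_r + m_s + 2
  W1 <- matrix(0, 2 * n_s, n_i)
  for (s in seq_len(n_s)) {
    W1[2 * s - 1, s] <- -1
    W1[2 * s, s] <- 1
  }
  W2 <- matrix(0, n_s, 2 * n_s)
  for (s in seq_len(n_s)) {
    W2[s, 2 * s - 1] <- decay
    W2[s, 2 * s] <- -decay
  }
  toy_generative_model(W1, numeric(2 * n_s), W2, numeric(n_s),
                       n_s, m_r, m_s, ...)
}

# uncoupled pMFM drift of a single node (time in ms), for root oracles
pmfm_drift <- function(S, r, In = 0, p = pmfm_params()) {
  x <- r * p$J * S + p$I_o + In
  -S / p$tau_s + (1 - S) * p$gamma * pmfm_transfer(x, p)
}

# grid sign-change oracle for roots of a scalar function on [lo, hi]
grid_roots <- function(fn, lo = 0, hi = 1, n = 10000) {
  S <- seq(lo, hi, length.out = n + 1)
  v <- fn(S)
  idx <- which(diff(sign(v)) != 0)
  (S[idx] + S[idx + 1]) / 2
}
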