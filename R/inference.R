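#' Dimension set of the variational model
#'
#' @param n_s state dimension; `m_r`, `m_s` regional/subject parameter
#'   dimensions; `n_t` series length; `n_sub` number of subjects; `n_l`
#'   LSTM width; `n_h` hidden units of the neural-mass MLP.
#' @param m_r,m_s,n_t,n_sub,n_l,n_h see above.
#' @return Named integer vector used by the inference core.
#' @export
vae_dims <- function(n_s, m_r, m_s, n_t, n_sub, n_l = 64, n_h = 64) {
  d <- c(n_s = n_s, m_r = m_r, m_s = m_s, n_t = n_t, n_sub = n_sub,
         n_l = n_l, n_h = n_h)
  storage.mode(d) <- "integer"
  stopifnot(all(d[c("n_s", "m_r", "n_t", "n_sub", "n_l", "n_h")] > 0),
            d["m_s"] >= 0)
  d
}

# Offsets (0-based) and shapes of every trainable block in the flat
# parameter vector; must mirror the Layout struct of the C++ core.
vae_param_layout <- function(dims) {
  n_s <- dims[["n_s"]]; m_r <- dims[["m_r"]]; m_s <- dims[["m_s"]]
  n_t <- dims[["n_t"]]; n_sub <- dims[["n_sub"]]; n_l <- dims[["n_l"]]
  n_h <- dims[["n_h"]]
  d_in <- 2 + n_sub
  n_i <- n_s + m_r + m_s + 2
  blocks <- list(
    Wx1 = c(4 * n_l, d_in), Wh1 = c(4 * n_l, n_l), bh1 = c(4 * n_l, 1),
    Ho1 = c(2 * n_s, n_l), bo1 = c(2 * n_s, 1),
    Wx2 = c(4 * n_l, d_in), Wh2 = c(4 * n_l, n_l), bh2 = c(4 * n_l, 1),
    Ho2 = c(2 * m_r, n_l), bo2 = c(2 * m_r, 1),
    M1 = c(m_s, n_sub), V1 = c(m_s, n_sub),
    M2 = c(n_t, n_sub), V2 = c(n_t, n_sub),
    W1f = c(n_h, n_i), b1f = c(n_h, 1),
    W2f = c(n_s, n_h), b2f = c(n_s, 1),
    a = c(n_s, 1), b = c(1, 1), lso = c(1, 1), lss = c(n_s, 1),
    ltau = c(1, 1))
  off <- 0
  out <- list()
  for (nm in names(blocks)) {
    sh <- blocks[[nm]]
    out[[nm]] <- list(offset = off, nrow = sh[1], ncol = sh[2])
    off <- off + sh[1] * sh[2]
  }
  stopifnot(off == vae_param_count_cpp(dims))
  attr(out, "total") <- off
  out
}

layout_get <- function(params, layout, name) {
  b <- layout[[name]]
  v <- params[b$offset + seq_len(b$nrow * b$ncol)]
  if (b$ncol == 1) return(as.numeric(v))
  matrix(v, b$nrow, b$ncol)
}

layout_set <- function(params, layout, name, value) {
  b <- layout[[name]]
  params[b$offset + seq_len(b$nrow * b$ncol)] <- as.numeric(value)
  params
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(nr, nc) {
  # orthonormal columns/rows from the QR of a Gaussian matrix
  n <- max(nr, nc)
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  Q[seq_len(nr), seq_len(nc), drop = FALSE]
}

# Initialization: recurrent kernels orthogonal with forget-gate bias 1,
# input kernels and heads Glorot-uniform; log sigma_s^2 = -2,
# log sigma_o^2 = 0, a ~ N(0, 0.3), b = 0, lookup matrices ~ N(0, 0.01),
# external-input time scale initialized at 10 samples.
vae_init_params <- function(dims, seed) {
  set.seed(seed)
  layout <- vae_param_layout(dims)
  p <- numeric(attr(layout, "total"))
  n_l <- dims[["n_l"]]
  for (enc in c(1, 2)) {
    wx <- paste0("Wx", enc); wh <- paste0("Wh", enc)
    bh <- paste0("bh", enc)
    p <- layout_set(p, layout, wx,
                    glorot(layout[[wx]]$nrow, layout[[wx]]$ncol))
    W <- do.call(rbind, lapply(1:4, function(i) orthogonal_init(n_l, n_l)))
    p <- layout_set(p, layout, wh, W)
    bias <- numeric(4 * n_l)
    bias[(n_l + 1):(2 * n_l)] <- 1  # forget gate open at start
    p <- layout_set(p, layout, bh, bias)
    ho <- paste0("Ho", enc); bo <- paste0("bo", enc)
    p <- layout_set(p, layout, ho,
                    glorot(layout[[ho]]$nrow, layout[[ho]]$ncol))
  }
  for (nm in c("M1", "V1", "M2", "V2")) {
    b <- layout[[nm]]
    if (b$nrow * b$ncol > 0)
      p <- layout_set(p, layout, nm,
                      matrix(rnorm(b$nrow * b$ncol, 0, 0.01),
                             b$nrow, b$ncol))
  }
  p <- layout_set(p, layout, "W1f",
                  glorot(layout$W1f$nrow, layout$W1f$ncol))
  p <- layout_set(p, layout, "W2f",
                  glorot(layout$W2f$nrow, layout$W2f$ncol))
  p <- layout_set(p, layout, "a", rnorm(dims[["n_s"]], 0, 0.3))
  p <- layout_set(p, layout, "lso", 0)
  p <- layout_set(p, layout, "lss", rep(-2, dims[["n_s"]]))
  p <- layout_set(p, layout, "ltau", log(10))
  p
}

#' Kullback-Leibler divergence of a diagonal Gaussian from N(0, I)
#'
#' Closed form `0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))`.
#'
#' @param mu mean vector.
#' @param sigma2 variance vector (positive).
#' @return Non-negative scalar; zero iff `mu = 0`, `sigma2 = 1`.
#' @export
gaussian_kl <- function(mu, sigma2) {
  stopifnot(length(mu) == length(sigma2), all(sigma2 > 0))
  0.5 * sum(mu^2 + sigma2 - 1 - log(sigma2))
}

#' L2 regularization terms of the training objective
#'
#' `alpha_f * (sum of squared weights and biases of f) +
#'  alpha_x * (sum of squared sampled states)`.
#'
#' @param f_weights list of numeric arrays (the MLP weights and biases).
#' @param states numeric array of sampled states (may be `NULL`).
#' @param alpha_f,alpha_x regularization strengths (defaults 0.01).
#' @return Scalar penalty.
#' @export
regularizers <- function(f_weights, states = NULL, alpha_f = 0.01,
                         alpha_x = 0.01) {
  wf <- sum(vapply(f_weights, function(w) sum(w^2), numeric(1)))
  sx <- if (is.null(states)) 0 else sum(states^2)
  alpha_f * wf + alpha_x * sx
}

#' Annealing coefficient of the prior/posterior ELBO terms
#'
#' Linear ramp from 0 at the first epoch to 1 at epoch `ramp_epochs`,
#' constant afterwards.
#'
#' @param epoch current epoch (1-based).
#' @param ramp_epochs epoch at which the coefficient reaches 1.
#' @return Value in `[0, 1]`.
#' @export
beta_schedule <- function(epoch, ramp_epochs = 500) {
  if (ramp_epochs <= 1) return(1)
  min(1, max(0, (epoch - 1) / (ramp_epochs - 1)))
}

#' Training configuration
#'
#' Defaults follow the synthetic-data schedule: two phases of Adam
#' (learning rates 0.003 then 0.001), batch size 16, KL-annealing ramp
#' over the first 500 epochs, gradient values clipped at +/- 1000,
#' one reparameterized sample per ELBO evaluation, and a held-out split
#' of 20% of the regional time series.
#'
#' @param n_s,m_r,m_s latent dimensions (state, regional, subject).
#' @param n_l,n_h LSTM width and MLP hidden units.
#' @param epochs_phase1,epochs_phase2 epochs per learning-rate phase.
#' @param lr_phase1,lr_phase2 Adam learning rates.
#' @param batch_size minibatch size (datapoints = regional series).
#' @param kl_ramp_epochs length of the linear annealing ramp.
#' @param grad_clip elementwise gradient clip limit.
#' @param alpha_f,alpha_x regularization strengths.
#' @param holdout fraction of regional series kept out of the gradient
#'   (0 disables the split).
#' @param seed master seed (initialization, split, data order, sampling).
#' @param eval_every epochs between held-out evaluations.
#' @return List of class `training_config`.
#' @export
training_config <- function(n_s = 2, m_r = 2, m_s = 1, n_l = 64, n_h = 64,
                            epochs_phase1 = 2000, epochs_phase2 = 1000,
                            lr_phase1 = 0.003, lr_phase2 = 0.001,
                            batch_size = 16, kl_ramp_epochs = 500,
                            grad_clip = 1000, alpha_f = 0.01,
                            alpha_x = 0.01, holdout = 0.2, seed = 1,
                            eval_every = 10) {
  stopifnot(holdout >= 0, holdout < 1, batch_size >= 1)
  structure(as.list(environment()), class = "training_config")
}

# Flatten a cohort into the datapoint arrays consumed by the core:
# one column per regional time series, with its network input and
# 0-based subject index.
cohort_datapoints <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  Ys <- list(); Us <- list(); subj <- integer(0); region <- integer(0)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    u <- compute_network_input(s$y, s$connectome)
    Ys[[i]] <- s$y
    Us[[i]] <- u
    subj <- c(subj, rep(i - 1L, ncol(s$y)))
    region <- c(region, seq_len(ncol(s$y)))
  }
  list(Y = do.call(cbind, Ys), U = do.call(cbind, Us),
       subj = subj, region = region)
}

adam_update <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$step <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the generative network model on a cohort
#'
#' Minimizes the negative dataset ELBO plus L2 regularizers by Adam with
#' the reparameterization trick, KL annealing and gradient clipping. Each
#' datapoint is one regional time series with its precomputed network
#' input and subject identity; a random fraction of datapoints can be
#' held out of the gradient to monitor generalization.
#'
#' @param cohort a `cohort` object.
#' @param config a [training_config].
#' @return A `trained_vae` object: flat parameter vector, dimensions,
#'   per-epoch diagnostics (`train_loss`, `holdout_loss`, `beta`), the
#'   datapoint split, and the config.
#' @export
train <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(config, "training_config"))
  dp <- cohort_datapoints(cohort)
  n_t <- nrow(dp$Y)
  n_sub <- length(cohort$subjects)
  n_regions <- ncol(cohort$subjects[[1]]$y)
  N <- ncol(dp$Y)
  dims <- vae_dims(config$n_s, config$m_r, config$m_s, n_t, n_sub,
                   config$n_l, config$n_h)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  params <- vae_init_params(dims, seeds[1])
  set.seed(seeds[2])
  n_hold <- round(config$holdout * N)
  hold_idx <- if (n_hold > 0) sort(sample.int(N, n_hold)) else integer(0)
  train_idx <- setdiff(seq_len(N), hold_idx)
  set.seed(seeds[3])
  n_epochs <- config$epochs_phase1 + config$epochs_phase2
  adam <- list(m = numeric(length(params)), v = numeric(length(params)),
               t = 0)
  diag_train <- numeric(n_epochs)
  diag_hold <- rep(NA_real_, n_epochs)
  diag_beta <- numeric(n_epochs)
  n_s <- dims[["n_s"]]; m_r <- dims[["m_r"]]; m_s <- dims[["m_s"]]
  draw_eps <- function(B) list(
    x = array(rnorm(n_t * B * n_s), c(n_t, B, n_s)),
    r = matrix(rnorm(B * m_r), B, m_r),
    s = matrix(rnorm(B * m_s), B, m_s),
    u = matrix(rnorm(n_t * B), n_t, B))
  for (epoch in seq_len(n_epochs)) {
    lr <- if (epoch <= config$epochs_phase1) config$lr_phase1
          else config$lr_phase2
    beta <- beta_schedule(epoch, config$kl_ramp_epochs)
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0
    for (bt in batches) {
      B <- length(bt)
      eps <- draw_eps(B)
      res <- vae_loss_grad_cpp(params, dims,
                               dp$Y[, bt, drop = FALSE],
                               dp$U[, bt, drop = FALSE],
                               dp$subj[bt], beta,
                               config$alpha_f * B, config$alpha_x,
                               n_regions, eps$x, eps$r, eps$s, eps$u,
                               TRUE)
      g <- as.numeric(res$grad) / B
      g <- pmin(pmax(g, -config$grad_clip), config$grad_clip)
      adam <- adam_update(adam, g, lr)
      params <- as.numeric(params - adam$step)
      tot <- tot + res$loss
    }
    diag_train[epoch] <- tot / length(ord)
    diag_beta[epoch] <- beta
    if (length(hold_idx) > 0 &&
        (epoch %% config$eval_every == 0 || epoch == n_epochs)) {
      B <- length(hold_idx)
      eps <- draw_eps(B)
      res <- vae_loss_grad_cpp(params, dims,
                               dp$Y[, hold_idx, drop = FALSE],
                               dp$U[, hold_idx, drop = FALSE],
                               dp$subj[hold_idx], beta,
                               config$alpha_f * B, config$alpha_x,
                               n_regions, eps$x, eps$r, eps$s, eps$u,
                               FALSE)
      diag_hold[epoch] <- res$loss / B
    }
    if (!is.finite(diag_train[epoch]))
      stop("training diverged at epoch ", epoch,
           "; last finite training loss: ",
           if (epoch > 1) diag_train[epoch - 1] else NA)
  }
  structure(list(params = params, dims = dims, config = config,
                 split = list(train = train_idx, holdout = hold_idx),
                 datapoints = list(subj = dp$subj, region = dp$region),
                 diagnostics = data.frame(
                   epoch = seq_len(n_epochs), train_loss = diag_train,
                   holdout_loss = diag_hold, beta = diag_beta),
                 sampling_interval = cohort$sampling_interval),
            class = "trained_vae")
}

#' @export
print.trained_vae <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "<trained_vae> n_s=%d m_r=%d m_s=%d, %d subjects, %d samples\n",
    d[["n_s"]], d[["m_r"]], d[["m_s"]], d[["n_sub"]], d[["n_t"]]))
  n <- nrow(x$diagnostics)
  cat(sprintf("  final train loss %.3f (epoch %d)\n",
              x$diagnostics$train_loss[n], n))
  invisible(x)
}

#' Per-datapoint ELBO of the current model
#'
#' Evaluates the single-datapoint evidence lower bound (and its term
#' breakdown) for one regional time series, using one reparameterized
#' sample.
#'
#' @param trained a `trained_vae` (or a list with `params` and `dims`).
#' @param y,u observed series and network-input series (length `n_t`).
#' @param subject 1-based subject index.
#' @param n_regions number of regions `n` entering the 1/n weights.
#' @param beta annealing coefficient in `[0, 1]`.
#' @param seed seed for the reparameterization draws.
#' @return List with `elbo`, `loss` and named `terms`.
#' @export
elbo <- function(trained, y, u, subject, n_regions, beta = 1, seed = 1) {
  dims <- trained$dims
  stopifnot(length(y) == dims[["n_t"]], length(u) == dims[["n_t"]],
            beta >= 0, beta <= 1)
  set.seed(seed)
  n_t <- dims[["n_t"]]
  eps_x <- array(rnorm(n_t * dims[["n_s"]]), c(n_t, 1, dims[["n_s"]]))
  eps_r <- matrix(rnorm(dims[["m_r"]]), 1)
  eps_s <- matrix(rnorm(dims[["m_s"]]), 1, dims[["m_s"]])
  eps_u <- matrix(rnorm(n_t), n_t, 1)
  cfg <- trained$config
  res <- vae_loss_grad_cpp(trained$params, dims, matrix(y, ncol = 1),
                           matrix(u, ncol = 1), as.integer(subject) - 1L,
                           beta,
                           cfg$alpha_f %||% 0.01, cfg$alpha_x %||% 0.01,
                           n_regions, eps_x, eps_r, eps_s, eps_u, FALSE)
  res[c("elbo", "loss", "terms")]
}

#' Approximate posteriors for a set of datapoints
#'
#' Runs the encoders on the given series and returns the Gaussian
#' posterior parameters for the states, regional parameters, subject
#' parameters and external input.
#'
#' @param trained a `trained_vae`.
#' @param y,u matrices `n_t` by B of observations and network inputs.
#' @param subjects 1-based subject index per column.
#' @return List of posterior means and log-variances.
#' @export
encode <- function(trained, y, u, subjects) {
  y <- as.matrix(y); u <- as.matrix(u)
  subjects <- as.integer(subjects)
  stopifnot(ncol(y) == ncol(u), length(subjects) == ncol(y),
            all(subjects >= 1), all(subjects <= trained$dims[["n_sub"]]))
  vae_encode_cpp(trained$params, trained$dims, y, u, subjects - 1L)
}

# Posterior parameters of theta_r for every datapoint of a cohort,
# in cohort datapoint order (subject-major).
encode_cohort <- function(trained, cohort) {
  dp <- cohort_datapoints(cohort)
  enc <- encode(trained, dp$Y, dp$U, dp$subj + 1L)
  list(mu_r = enc$mu_r, logvar_r = enc$logvar_r,
       mu_s = enc$mu_s, logvar_s = enc$logvar_s,
       mu_u = enc$mu_u, logvar_u = enc$logvar_u,
       subj = dp$subj, region = dp$region)
}

#' Posterior samples of the regional parameters
#'
#' @param trained a `trained_vae`.
#' @param cohort the cohort the model was trained on.
#' @param n_draws number of sample sets.
#' @param seed integer seed.
#' @return Array `n_draws` by datapoints by `m_r`, with the posterior
#'   means in attribute `means`.
#' @export
sample_theta_r <- function(trained, cohort, n_draws = 50, seed = 1) {
  enc <- encode_cohort(trained, cohort)
  mu <- enc$mu_r; sdv <- exp(0.5 * enc$logvar_r)
  set.seed(seed)
  N <- nrow(mu); m_r <- ncol(mu)
  out <- array(NA_real_, c(n_draws, N, m_r))
  for (d in seq_len(n_draws))
    out[d, , ] <- mu + sdv * matrix(rnorm(N * m_r), N, m_r)
  attr(out, "means") <- mu
  attr(out, "subj") <- enc$subj
  attr(out, "region") <- enc$region
  out
}

#' Posterior-collapse diagnostic table
#'
#' For each dimension of the regional parameter space, the KL divergence
#' of the approximate posterior from the N(0, 1) prior is computed for
#' every regional datapoint; dimensions are reported sorted by
#' decreasing mean KL. Values near zero flag dimensions whose posterior
#' has collapsed to the prior (unused capacity), which is how the
#' effective dimensionality of the parameter space is read off.
#'
#' @param trained a `trained_vae`.
#' @param cohort the training cohort.
#' @return Data frame with columns `dimension`, `kl_mean`, `kl_sd`,
#'   sorted by decreasing `kl_mean`.
#' @export
posterior_collapse_report <- function(trained, cohort) {
  enc <- encode_cohort(trained, cohort)
  mu <- enc$mu_r; s2 <- exp(enc$logvar_r)
  kl <- 0.5 * (mu^2 + s2 - 1 - log(s2))   # per datapoint x dimension
  ord <- order(colMeans(kl), decreasing = TRUE)
  data.frame(dimension = ord,
             kl_mean = colMeans(kl)[ord],
             kl_sd = apply(kl, 2, sd)[ord])
}

#' Extract the learned generative model
#'
#' Packages the decoder side of a trained system (the neural-mass MLP,
#' observation model, system noise and external-input prior) as a
#' [generative_model] usable for closed-loop simulation and dynamical
#' analysis.
#'
#' @param trained a `trained_vae`.
#' @return A [generative_model].
#' @export
as_generative_model <- function(trained) {
  dims <- trained$dims
  layout <- vae_param_layout(dims)
  p <- trained$params
  mlp <- neural_mass_mlp(layout_get(p, layout, "W1f"),
                         layout_get(p, layout, "b1f"),
                         layout_get(p, layout, "W2f"),
                         layout_get(p, layout, "b2f"),
                         dims[["n_s"]], dims[["m_r"]], dims[["m_s"]])
  obs <- list(a = layout_get(p, layout, "a"),
              b = layout_get(p, layout, "b"),
              sigma_o = sqrt(exp(layout_get(p, layout, "lso"))))
  sigma_s <- sqrt(exp(layout_get(p, layout, "lss")))
  tau <- exp(layout_get(p, layout, "ltau"))
  generative_model(mlp, obs, sigma_s, tau)
}

#' Subject-level posterior summaries
#'
#' @param trained a `trained_vae`.
#' @return List with per-subject means/log-variances of the subject
#'   parameters (`theta_s`) and the external input (`u_ext`).
#' @export
subject_posteriors <- function(trained) {
  layout <- vae_param_layout(trained$dims)
  p <- trained$params
  list(mu_s = layout_get(p, layout, "M1"),
       logvar_s = layout_get(p, layout, "V1"),
       mu_u = layout_get(p, layout, "M2"),
       logvar_u = layout_get(p, layout, "V2"))
}
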