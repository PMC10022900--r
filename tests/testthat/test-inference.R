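test_that("the closed-form Gaussian KL matches hand values and Monte Carlo", {
  expect_equal(gaussian_kl(0, 1), 0)
  expect_equal(gaussian_kl(1, 1), 0.5)
  expect_equal(gaussian_kl(c(0, 1), c(1, 1)), 0.5)
  # non-negativity, zero only at the prior
  expect_gt(gaussian_kl(0.1, 1), 0)
  expect_gt(gaussian_kl(0, 1.5), 0)
  # Monte-Carlo oracle: KL = E_q[log q - log p] at 1e6 samples
  mu <- 0.7; s2 <- 1.8
  set.seed(4)
  z <- rnorm(1e6, mu, sqrt(s2))
  lq <- dnorm(z, mu, sqrt(s2), log = TRUE)
  lp <- dnorm(z, 0, 1, log = TRUE)
  mc <- mean(lq - lp)
  se <- sd(lq - lp) / sqrt(1e6)
  expect_lt(abs(gaussian_kl(mu, s2) - mc), 3 * se)
})

test_that("regularizer arithmetic is exact and linear in its strengths", {
  expect_equal(regularizers(list(matrix(0, 2, 2)), NULL), 0)
  # single weight w = 2 at alpha_f = 0.01 -> 0.04
  expect_equal(regularizers(list(2), NULL, alpha_f = 0.01), 0.04)
  w <- list(matrix(1:4, 2), c(0.5, -0.5))
  x <- matrix(rnorm(6), 2)
  r1 <- regularizers(w, x, alpha_f = 0.01, alpha_x = 0.02)
  r2 <- regularizers(w, x, alpha_f = 0.02, alpha_x = 0.04)
  expect_equal(r2, 2 * r1)
  expect_equal(r1, 0.01 * (sum(unlist(w)^2)) + 0.02 * sum(x^2))
})

test_that("the annealing ramp is linear from the first epoch", {
  expect_equal(beta_schedule(1, 500), 0)
  expect_equal(beta_schedule(500, 500), 1)
  expect_equal(beta_schedule(2000, 500), 1)
  # linear interpolation between (1, 0) and (500, 1)
  expect_equal(beta_schedule(250, 500), 249 / 499)
  expect_equal(beta_schedule(250, 500), 0.5, tolerance = 0.01)
})

test_that("analytic ELBO gradients agree with central finite differences", {
  dims <- brainvae:::vae_dims(n_s = 2, m_r = 2, m_s = 1, n_t = 6,
                              n_sub = 2, n_l = 3, n_h = 4)
  set.seed(12)
  p <- brainvae:::vae_init_params(dims, seed = 3) +
    rnorm(vae_param_count_cpp(dims), 0, 0.05)
  B <- 2; n_t <- 6
  Y <- matrix(rnorm(n_t * B), n_t, B)
  U <- matrix(rnorm(n_t * B), n_t, B)
  subj <- c(0L, 1L)
  eps_x <- array(rnorm(n_t * B * 2), c(n_t, B, 2))
  eps_r <- matrix(rnorm(B * 2), B, 2)
  eps_s <- matrix(rnorm(B), B, 1)
  eps_u <- matrix(rnorm(n_t * B), n_t, B)
  loss_of <- function(pp, grad = FALSE)
    brainvae:::vae_loss_grad_cpp(pp, dims, Y, U, subj, 0.8, 0.013,
                                 0.011, 7, eps_x, eps_r, eps_s, eps_u,
                                 grad)
  g <- loss_of(p, TRUE)$grad
  h <- 1e-6
  idx <- seq(1, length(p), by = 7)  # probe a spread of parameters
  for (i in idx) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    num <- (loss_of(pp)$loss - loss_of(pm)$loss) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("the ELBO reduces to the reconstruction term when annealing is off", {
  co <- tiny_hopf_cohort()
  cfg <- training_config(n_s = 2, m_r = 2, m_s = 1, n_l = 8, n_h = 8,
                         epochs_phase1 = 1, epochs_phase2 = 0,
                         holdout = 0, seed = 2)
  tr <- train(co, cfg)
  dp <- brainvae:::cohort_datapoints(co)
  res0 <- elbo(tr, dp$Y[, 1], dp$U[, 1], subject = 1, n_regions = 6,
               beta = 0, seed = 5)
  expect_equal(res0$elbo, res0$terms$reconstruction)
  # at beta = 1 every term enters with its stated weight
  res1 <- elbo(tr, dp$Y[, 1], dp$U[, 1], subject = 1, n_regions = 6,
               beta = 1, seed = 5)
  with(res1$terms, expect_equal(
    res1$elbo,
    reconstruction + state_prior + state_entropy - kl_theta_r -
      kl_theta_s / 6 + (ext_prior + ext_entropy) / 6))
  # identical seeds give identical stochastic estimates
  res1b <- elbo(tr, dp$Y[, 1], dp$U[, 1], subject = 1, n_regions = 6,
                beta = 1, seed = 5)
  expect_identical(res1$elbo, res1b$elbo)
})

test_that("encoders are deterministic, subject-aware and order-sensitive", {
  co <- tiny_hopf_cohort()
  cfg <- training_config(n_s = 2, m_r = 2, m_s = 1, n_l = 8, n_h = 8,
                         epochs_phase1 = 2, epochs_phase2 = 0,
                         holdout = 0, seed = 3)
  tr <- train(co, cfg)
  dp <- brainvae:::cohort_datapoints(co)
  e1 <- encode(tr, dp$Y[, 1:2], dp$U[, 1:2], dp$subj[1:2] + 1L)
  e2 <- encode(tr, dp$Y[, 1:2], dp$U[, 1:2], dp$subj[1:2] + 1L)
  expect_identical(e1$mu_r, e2$mu_r)
  # subject lookups return the corresponding columns of the matrices
  sp <- subject_posteriors(tr)
  expect_equal(as.numeric(e1$mu_s[, 1]), as.numeric(sp$mu_s[, 1]))
  expect_equal(as.numeric(e1$mu_u[, 1]), as.numeric(sp$mu_u[, 1]))
  # the recurrent encoder is order-sensitive: time-permuted input
  # produces different regional-parameter posteriors
  set.seed(9)
  yp <- dp$Y[sample(nrow(dp$Y)), 1, drop = FALSE]
  ep <- encode(tr, yp, dp$U[, 1, drop = FALSE], 1L)
  expect_gt(max(abs(ep$mu_r - e1$mu_r[1, ])), 1e-8)
})

test_that("a short optimization run reduces the training loss", {
  co <- tiny_hopf_cohort()
  # annealing held at 1 so per-epoch losses are directly comparable
  cfg <- training_config(n_s = 2, m_r = 2, m_s = 1, n_l = 8, n_h = 8,
                         epochs_phase1 = 30, epochs_phase2 = 0,
                         kl_ramp_epochs = 1, holdout = 0.2, seed = 4)
  tr <- train(co, cfg)
  d <- tr$diagnostics
  expect_equal(nrow(d), 30)
  # clear downward trend from the first to the last epochs
  expect_lt(mean(tail(d$train_loss, 5)), mean(head(d$train_loss, 5)))
  expect_equal(d$beta, rep(1, 30))
  # held-out loss evaluated on schedule
  expect_false(is.na(d$holdout_loss[30]))
  # the held-out split leaves 80% of datapoints for training
  expect_length(tr$split$train, round(0.8 * 12))
})

test_that("posterior-collapse reporting follows the closed form and ordering", {
  co <- tiny_hopf_cohort()
  cfg <- training_config(n_s = 2, m_r = 3, m_s = 1, n_l = 8, n_h = 8,
                         epochs_phase1 = 1, epochs_phase2 = 0,
                         holdout = 0, seed = 6)
  tr <- train(co, cfg)
  layout <- brainvae:::vae_param_layout(tr$dims)
  # force the regional-parameter head to emit exactly the prior
  p <- tr$params
  p <- brainvae:::layout_set(p, layout, "Ho2",
                             matrix(0, 2 * 3, tr$dims[["n_l"]]))
  p <- brainvae:::layout_set(p, layout, "bo2", rep(0, 6))
  tr$params <- p
  rep0 <- posterior_collapse_report(tr, co)
  expect_equal(rep0$kl_mean, rep(0, 3))
  # one dimension emitting mu = 1, sigma = 1 has KL exactly 0.5
  bo2 <- rep(0, 6); bo2[2] <- 1
  tr$params <- brainvae:::layout_set(p, layout, "bo2", bo2)
  rep1 <- posterior_collapse_report(tr, co)
  expect_equal(rep1$kl_mean[1], 0.5)
  expect_equal(rep1$dimension[1], 2)
  expect_equal(rep1$kl_sd[1], 0)
  # the report is sorted by decreasing mean KL
  expect_true(all(diff(rep1$kl_mean) <= 0))
})

test_that("training is reproducible from its seed", {
  co <- tiny_hopf_cohort()
  cfg <- training_config(n_s = 1, m_r = 1, m_s = 0, n_l = 4, n_h = 4,
                         epochs_phase1 = 3, epochs_phase2 = 0,
                         holdout = 0, seed = 11)
  t1 <- train(co, cfg)
  t2 <- train(co, cfg)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$diagnostics$train_loss, t2$diagnostics$train_loss)
})
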