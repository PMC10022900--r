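test_that("functional connectivity and its comparisons behave as correlations", {
  set.seed(1)
  y <- matrix(rnorm(600), 200, 3)
  FC <- fc(y)
  expect_equal(diag(FC), rep(1, 3), ignore_attr = TRUE)
  expect_equal(FC, t(FC))
  expect_equal(fc_similarity(FC, FC), 1)
  # perfectly anti-correlated pair
  y2 <- cbind(y[, 1], -y[, 1])
  expect_equal(fc(y2)[1, 2], -1)
  # independent long white-noise channels: mean off-diagonal FC near 0
  yw <- matrix(rnorm(20000), 2000, 10)
  expect_lt(abs(fc_mean(fc(yw))), 0.02)
})

test_that("spectral cosine similarity is scale-invariant and separates tones", {
  t <- seq(0, 99.5, by = 0.5)
  s1 <- sin(2 * pi * 0.1 * t)
  s2 <- sin(2 * pi * 0.8 * t)
  expect_equal(spectral_cosine(s1, s1), 1)
  expect_equal(spectral_cosine(s1, 3.7 * s1), 1)
  # tones with disjoint spectral support are nearly orthogonal
  expect_lt(spectral_cosine(s1, s2), 0.05)
  # mean removal: adding an offset changes nothing
  expect_equal(spectral_cosine(s1 + 5, s1), 1)
})

test_that("variance difference is signed and antisymmetric", {
  set.seed(2)
  a <- rnorm(4000, 0, 1); b <- rnorm(4000, 0, 2)
  expect_equal(variance_difference(a, a), 0)
  expect_equal(variance_difference(a, b), -3, tolerance = 0.2)
  expect_equal(variance_difference(a, b), -variance_difference(b, a))
})

test_that("the 1-D Wasserstein distance equals exhaustive assignment cost", {
  expect_equal(wasserstein_1d(c(0, 0), c(1, 1)), 1)
  expect_equal(wasserstein_1d(c(3, 1, 2), c(3, 1, 2)), 0)
  # brute force over all pairings for equal-size samples up to 5 points
  brute <- function(a, b) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
      out
    }
    min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
  }
  set.seed(3)
  for (n in 2:5) {
    a <- round(rnorm(n), 2); b <- round(rnorm(n), 2)
    expect_equal(wasserstein_1d(a, b), brute(a, b))
  }
  # unequal sizes: replicate each sample to the common refinement
  a <- c(0, 1); b <- c(0, 0.5, 1)
  expect_equal(wasserstein_1d(a, b),
               wasserstein_1d(rep(a, each = 3), rep(b, each = 2)))
  # metric properties on small instances
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
    expect_equal(wasserstein_1d(x, y), wasserstein_1d(y, x))
    expect_gte(wasserstein_1d(x, y), 0)
    expect_lte(wasserstein_1d(x, z),
               wasserstein_1d(x, y) + wasserstein_1d(y, z) + 1e-12)
  }
})

test_that("switch counting is hysteretic and log-scaled", {
  expect_equal(switch_count(rep(2.5, 100)), 0)
  # clean alternating square wave: 2k+1 blocks give 2k switches
  k <- 6
  wave <- rep(rep(c(1, -1), length.out = 2 * k + 1), each = 10)
  expect_equal(switch_count(wave), log(1 + 2 * k))
  # jitter below the hysteresis band leaves the count unchanged
  set.seed(4)
  jit <- wave + runif(length(wave), -0.2, 0.2)
  expect_equal(switch_count(jit), log(1 + 2 * k))
  # noise around a single level never crosses the band
  flat <- rnorm(500, 0, 1)
  expect_equal(switch_count(flat, band_sd = 4), 0)
})

test_that("parameter recovery is exact for stored parameters and null at random", {
  set.seed(5)
  n <- 60
  truth <- rnorm(n)
  theta <- cbind(truth, rnorm(n))
  r <- recover_parameters(theta, NULL, truth)
  expect_equal(r$rho, 1)
  # any monotone nonlinear storage still gives rho = 1 (rank invariance)
  theta_nl <- cbind(exp(truth), rnorm(n))
  expect_equal(recover_parameters(theta_nl, NULL, exp(truth))$rho, 1)
  # samples route: degenerate posterior centred on the means
  smp <- array(0, c(10, n, 2))
  for (d in 1:10) smp[d, , ] <- theta
  rs <- recover_parameters(theta, smp, truth, n_draws = 10)
  expect_equal(rs$rho, rep(1, 10))
  expect_equal(rs$interval, c(1, 1))
  # independent parameters: null distribution centred near zero
  null_rho <- vapply(1:50, function(i) {
    recover_parameters(matrix(rnorm(2 * n), n, 2), NULL, rnorm(n))$rho
  }, numeric(1))
  expect_lt(abs(median(null_rho)), 0.25)
  expect_error(recover_parameters(theta, NULL, rep(1, n)), "constant")
})

test_that("surrogates preserve exactly what they are meant to preserve", {
  co <- tiny_hopf_cohort()
  # reshuffling permutes whole series: the multiset is unchanged
  sh <- make_surrogates(co, "reshuffle", seed = 6)
  pool0 <- do.call(cbind, lapply(co$subjects, function(s) s$y))
  pool1 <- do.call(cbind, lapply(sh$subjects, function(s) s$y))
  expect_equal(pool0[, order(colSums(pool0))],
               pool1[, order(colSums(pool1))])
  expect_false(identical(pool0, pool1))
  # white noise matches the normalized dataset's first two moments
  wn <- make_surrogates(co, "white_noise", seed = 7)
  all_w <- unlist(lapply(wn$subjects, function(s) s$y))
  expect_equal(mean(all_w), 0, tolerance = 0.05)
  expect_equal(var(all_w), 1, tolerance = 0.05)
  expect_equal(dim(wn$subjects[[1]]$y), dim(co$subjects[[1]]$y))
  # re-running the generative simulator with the cohort's own seed
  # reproduces it exactly
  rr <- make_surrogates(co, "model_rerun", seed = co$seed)
  expect_equal(rr$subjects[[1]]$y, co$subjects[[1]]$y,
               ignore_attr = TRUE)
})

test_that("regional features match hand computations on constructions", {
  M <- matrix(c(0, 2, 1,
                2, 0, 4,
                1, 4, 0), 3, 3, byrow = TRUE) / 4
  W <- connectome(M)
  n_t <- 500
  sampling <- 0.72
  t <- (seq_len(n_t) - 1) * sampling
  # region 1: slow tone below 0.1 Hz with k full periods
  k <- 18
  f1 <- k / (n_t * sampling)
  y <- cbind(sin(2 * pi * f1 * t), rnorm(n_t), rnorm(n_t))
  ft <- feature_table(y, W, sampling_interval = sampling)
  # in-strength: row sums of the coupling matrix
  expect_equal(ft$in_strength, rowSums(M))
  # eigenvector centrality: principal eigenvector of the symmetric matrix
  ev <- eigen(M)
  expect_equal(ft$centrality, abs(ev$vectors[, 1]), tolerance = 1e-8)
  # a pure sub-0.1 Hz tone has all its power below 0.1 Hz
  expect_equal(ft$power_below_0.1Hz[1], 1, tolerance = 1e-6)
  # sine with k full periods crosses zero 2k times (endpoints exact)
  expect_equal(ft$zero_crossings[1], 2 * k, tolerance = 1)
  # correlations are well-defined and bounded
  expect_true(all(abs(ft$corr_mean_signal) <= 1))
  expect_true(all(abs(ft$corr_network_input) <= 1))
  expect_equal(nrow(ft), 3)
})

test_that("feature regression recovers exact linear structure and scale invariance", {
  set.seed(8)
  n <- 68; m_r <- 3
  theta <- matrix(rnorm(n * m_r), n, m_r)
  feat <- 2 * theta[, 1] - theta[, 3]
  res <- suppressWarnings(feature_regression(theta, feat))  # exact fit
  expect_equal(res$r2, 1)
  expect_true(res$significant[1])
  expect_true(res$significant[3])
  expect_equal(res$threshold, 0.001 / 45)
  # scale invariance of R^2
  res2 <- suppressWarnings(feature_regression(theta, 100 * feat))
  expect_equal(res2$r2, res$r2)
  # feature independent of theta: R^2 stays near the small-sample bias
  # level m_r / (n - 1)
  r2_null <- vapply(1:30, function(i)
    feature_regression(theta, rnorm(n))$r2, numeric(1))
  expect_lt(abs(mean(r2_null) - m_r / (n - 1)), 0.025)
  expect_error(feature_regression(theta, rep(1, n)), "variance")
  # posterior-sample route averages over draws
  smp <- array(rnorm(5 * n * m_r, sd = 0.01), c(5, n, m_r))
  for (d in 1:5) smp[d, , ] <- smp[d, , ] + theta
  res3 <- feature_regression(smp, feat, n_draws = 5)
  expect_equal(res3$n_draws, 5)
  expect_gt(res3$r2, 0.99)
})

test_that("external feature maps load from two-column TSV", {
  path <- file.path(tempdir(), "feat.tsv")
  writeLines(c("lh_bankssts\t0.52", "lh_caudalacc\t-1.3"), path)
  v <- read_feature_tsv(path)
  expect_equal(unname(v), c(0.52, -1.3))
  expect_identical(names(v), c("lh_bankssts", "lh_caudalacc"))
  writeLines(c("r1\txx"), path)
  expect_error(read_feature_tsv(path))
})
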