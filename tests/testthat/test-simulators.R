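single_node <- connectome(matrix(0, 1, 1) + 0)

test_that("an uncoupled noise-free Hopf node follows the polar-form solution", {
  # supercritical: orbit settles on the circle of radius sqrt(a)
  for (a in c(1, 0.49)) {
    p <- hopf_params(a = a, f = 0.05, G = 0, beta_noise = 0)
    raw <- simulate_hopf(single_node, p, 200, seed = 1, x0 = 0.1, y0 = 0)
    n <- nrow(raw$x)
    radius <- sqrt(raw$x[n, 1]^2 + raw$y[n, 1]^2)
    expect_equal(radius, sqrt(a), tolerance = 0.02)
  }
  # subcritical: decay to the origin
  p <- hopf_params(a = -0.5, f = 0.05, G = 0, beta_noise = 0)
  raw <- simulate_hopf(single_node, p, 200, seed = 1, x0 = 0.5, y0 = 0.5)
  n <- nrow(raw$x)
  expect_lt(max(abs(c(raw$x[n, 1], raw$y[n, 1]))), 1e-3)
})

test_that("strongly coupled identical Hopf oscillators phase-lock", {
  W <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
  p <- hopf_params(a = 1, f = 0.05, G = 2, beta_noise = 0)
  raw <- simulate_hopf(W, p, 400, seed = 3,
                       x0 = c(1, -0.3), y0 = c(0, 0.8))
  keep <- seq(nrow(raw$x) - 5000, nrow(raw$x))
  phase <- atan2(raw$y[keep, ], raw$x[keep, ])
  dphi <- atan2(sin(phase[, 1] - phase[, 2]), cos(phase[, 1] - phase[, 2]))
  expect_lt(sd(dphi), 1e-3)
})

test_that("noise-free Hopf trajectories converge at first order in dt", {
  p1 <- hopf_params(a = 0.5, f = 0.05, G = 0, beta_noise = 0, dt = 0.02)
  p2 <- hopf_params(a = 0.5, f = 0.05, G = 0, beta_noise = 0, dt = 0.01)
  p3 <- hopf_params(a = 0.5, f = 0.05, G = 0, beta_noise = 0, dt = 0.005)
  end_x <- function(p) {
    raw <- simulate_hopf(single_node, p, 10, seed = 1, x0 = 0.3, y0 = 0)
    raw$x[nrow(raw$x), 1]
  }
  # Richardson-style: error(dt) ~ C dt, so successive differences halve
  d12 <- abs(end_x(p1) - end_x(p2))
  d23 <- abs(end_x(p2) - end_x(p3))
  expect_equal(d12 / d23, 2, tolerance = 0.35)
})

test_that("Hopf postprocessing yields the protocol shape and trivial identities", {
  W <- generate_connectome(6, seed = 2)
  p <- hopf_params(a = 0.3, f = 0.05, G = 0.1)
  raw <- simulate_hopf(W, p, 205, seed = 4)
  y <- postprocess_hopf(raw)
  expect_equal(dim(y), c(180, 6))
  expect_equal(attr(y, "sampling_interval"), 1)
  # no discard and native rate: identity on the x channel
  y_id <- postprocess_hopf(raw, discard = 0, target_rate = 1 / p$dt)
  expect_equal(unname(y_id), unname(raw$x[-1, , drop = FALSE]),
               ignore_attr = TRUE)
  expect_error(postprocess_hopf(raw, discard = 300), "discard")
})

test_that("the mean-field transfer function handles its removable singularity", {
  p <- pmfm_params()
  # analytic limit at a_H x = b_H (x = 0.4 nA): H = 1/d_H
  expect_equal(pmfm_transfer(0.4, p), 1 / 0.154, tolerance = 1e-9)
  # continuity across the singular point
  xs <- seq(0.4 - 1e-7, 0.4 + 1e-7, length.out = 11)
  expect_lt(max(abs(diff(pmfm_transfer(xs, p)))), 1e-4)
  # monotone increasing on a wide range
  expect_true(all(diff(pmfm_transfer(seq(0, 1, 0.01), p)) > 0))
})

test_that("a noise-free uncoupled mean-field node settles on a drift root", {
  for (r in c(0.9, 1.4)) {
    p <- pmfm_params(r = r, sigma = 0, G = 0)
    raw <- simulate_pmfm(single_node, p, 120, seed = 5, S0 = 0.5)
    final <- raw$S[nrow(raw$S), 1]
    roots <- grid_roots(function(S) pmfm_drift(S, r = r))
    expect_lt(min(abs(final - roots)), 1e-4)
    # noise-free states stay within the gating interval
    expect_true(all(raw$S >= 0 & raw$S <= 1))
    expect_identical(raw$n_out_of_range, 0L)
  }
})

test_that("mean-field postprocessing yields the protocol shape and window means", {
  W <- generate_connectome(6, seed = 6)
  p <- pmfm_params(r = 1.2, sigma = 0.01, G = 0.2)
  raw <- simulate_pmfm(W, p, 16.4 * 60, seed = 7)
  y <- postprocess_pmfm(raw)
  expect_equal(dim(y), c(1200, 6))
  expect_equal(attr(y, "sampling_interval"), 0.72)
  # window equal to one step: identity after discard
  y_id <- postprocess_pmfm(raw, discard = 120, window = 0.01)
  expect_equal(unname(y_id), unname(raw$S[-seq_len(12001), , drop = FALSE]),
               ignore_attr = TRUE)
  # non-integer window/step ratio is an error, not an interpolation
  expect_error(postprocess_pmfm(raw, window = 0.715), "multiple")
  # linear ramp: window means equal ramp midpoints
  ramp <- raw
  ramp$S <- matrix(seq_len(nrow(raw$S)), ncol = 1)
  ramp$duration <- raw$duration
  y_ramp <- postprocess_pmfm(ramp, discard = 120, window = 0.72)
  first_win <- mean(12002:(12001 + 72))
  expect_equal(y_ramp[1, 1], first_win)
  expect_equal(unname(diff(y_ramp[, 1])), rep(72, nrow(y_ramp) - 1))
})

test_that("the coupling scan returns the FC-maximizing grid value", {
  W <- generate_connectome(6, seed = 8)
  p <- pmfm_params(r = 1.2, sigma = 0.01)
  # a single grid value is returned as-is
  expect_equal(as.numeric(find_optimal_G(W, p, grid = 0.19,
                                         probe_duration = 30,
                                         fc_window = 15, seed = 1)), 0.19)
  # degenerate: no noise, zero variance, FC undefined
  p0 <- pmfm_params(r = 1.2, sigma = 0)
  expect_error(find_optimal_G(W, p0, grid = c(0.18, 0.2),
                              probe_duration = 30, fc_window = 15,
                              seed = 1), "variance")
  # argmax equals a brute-force scan over the same probes
  grid <- seq(0.17, 0.22, length.out = 5)
  g_opt <- find_optimal_G(W, p, grid = grid, probe_duration = 60,
                          fc_window = 30, seed = 9)
  scan <- attr(g_opt, "scan")
  expect_equal(as.numeric(g_opt), scan$G[which.max(scan$mean_fc)])
  expect_equal(nrow(scan), 5)
})

test_that("Hopf cohorts implement the stated study conditions", {
  co <- tiny_hopf_cohort()
  expect_s3_class(co, "cohort")
  expect_length(co$subjects, 2)
  G <- hopf_ground_truth(co, "G")
  expect_equal(G, seq(0, 0.7, length.out = 2))
  f <- hopf_ground_truth(co, "f")
  expect_true(all(f >= 0.03 & f <= 0.07))
  a <- hopf_ground_truth(co, "a")
  expect_true(all(a >= -1 & a <= 1))
  # dataset-wide normalization
  all_y <- unlist(lapply(co$subjects, function(s) s$y))
  expect_equal(mean(all_y), 0, tolerance = 1e-6)
  expect_equal(var(all_y), 1, tolerance = 1e-4)
  # bit-identical regeneration from the same master seed
  co2 <- build_hopf_cohort(n_subjects = 2, seed = 101, n_regions = 6,
                           duration = 65, discard = 25)
  expect_identical(co$subjects[[1]]$y, co2$subjects[[1]]$y)
  expect_identical(co$subjects[[2]]$ground_truth,
                   co2$subjects[[2]]$ground_truth)
})

test_that("mean-field cohorts implement the stated study conditions", {
  co <- fixture("tiny_pmfm", function()
    build_pmfm_cohort(n_subjects = 2, seed = 103, n_regions = 6,
                      duration = 180, discard = 36,
                      G_grid = seq(0.17, 0.22, length.out = 5)))
  G <- vapply(co$subjects, function(s) s$ground_truth$G, numeric(1))
  expect_true(all(G >= 0.17 & G <= 0.22))
  r <- unlist(lapply(co$subjects, function(s) s$ground_truth$r))
  expect_true(all(r >= 1.0 & r <= 1.4))
  sg <- unlist(lapply(co$subjects, function(s) s$ground_truth$sigma))
  expect_true(all(sg >= 0.005 & sg <= 0.02))
  expect_equal(nrow(co$subjects[[1]]$y), (180 - 36) / 0.72)
  all_y <- unlist(lapply(co$subjects, function(s) s$y))
  expect_equal(mean(all_y), 0, tolerance = 1e-6)
  expect_equal(var(all_y), 1, tolerance = 1e-4)
})

test_that("mean-field initial conditions are drawn from the stated interval", {
  W <- generate_connectome(8, seed = 2)
  p <- pmfm_params(r = 1.2, sigma = 0.01, G = 0.2)
  for (s in 1:5) {
    raw <- simulate_pmfm(W, p, 1, seed = s)
    expect_true(all(raw$S[1, ] >= 0.2 & raw$S[1, ] <= 0.8))
  }
})

test_that("a misconfigured integration aborts with the step index", {
  # absurd noise blows the state up; the integrator must say where
  W <- generate_connectome(4, seed = 3)
  p <- hopf_params(a = 1, f = 0.05, beta_noise = 1e6)
  expect_error(simulate_hopf(W, p, 10, seed = 1), "non-finite state at step")
})
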