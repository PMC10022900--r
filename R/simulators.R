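#' Parameters of the Hopf whole-brain simulator
#'
#' Each node is a planar neural mass near a supercritical Hopf bifurcation:
#' for `a < 0` it has a stable fixed point at the origin, for `a > 0` a
#' stable limit cycle of radius `sqrt(a)` and frequency `f` (Hz). Nodes are
#' coupled diffusively through the connectome, scaled by `G`.
#'
#' @param a per-region bifurcation parameter (scalar is recycled).
#' @param f per-region intrinsic frequency in Hz (> 0).
#' @param G global coupling scale (>= 0).
#' @param beta_noise additive noise SD (Euler-Maruyama increments
#'   `beta_noise * sqrt(dt)`).
#' @param dt integration step in seconds.
#' @return A list of class `hopf_params`.
#' @export
hopf_params <- function(a = -0.5, f = 0.05, G = 0, beta_noise = 0.05,
                        dt = 0.02) {
  stopifnot(all(f > 0), dt > 0, G >= 0, beta_noise >= 0)
  structure(list(a = a, f = f, G = G, beta_noise = beta_noise, dt = dt),
            class = "hopf_params")
}

#' Parameters of the parametric mean-field whole-brain simulator
#'
#' One-equation reduction of a spiking network: the synaptic gating
#' variable `S` of each node relaxes with time constant `tau_s` and is
#' driven by the sigmoidal population rate `H` of the total input current.
#' Depending on the recurrent strength `r` and the network input, a node
#' is in a monostable down-state, a bistable, or a monostable up-state
#' regime; state switching is noise-driven. Time is in milliseconds.
#'
#' @param r per-region recurrent connection strength.
#' @param sigma per-region noise SD (in 1/sqrt(ms) units; Euler-Maruyama
#'   increments `sigma * sqrt(dt)`).
#' @param G global coupling scale.
#' @param J synaptic coupling (nA); `I_o` subcortical input (nA).
#' @param I_o excitatory subcortical input (nA).
#' @param tau_s decay time constant (ms); `gamma` rate constant (1/ms).
#' @param gamma kinetic rate constant.
#' @param a_H,b_H,d_H transfer-function constants (nC^-1, Hz, s).
#' @param dt integration step (ms).
#' @return A list of class `pmfm_params`.
#' @export
pmfm_params <- function(r = 1.2, sigma = 1e-3, G = 0, J = 0.2609,
                        I_o = 0.295, tau_s = 100, gamma = 0.641 / 1000,
                        a_H = 270, b_H = 108, d_H = 0.154, dt = 10) {
  stopifnot(tau_s > 0, all(sigma >= 0), dt > 0)
  structure(list(r = r, sigma = sigma, G = G, J = J, I_o = I_o,
                 tau_s = tau_s, gamma = gamma, a_H = a_H, b_H = b_H,
                 d_H = d_H, dt = dt),
            class = "pmfm_params")
}

#' Population transfer function of the mean-field model
#'
#' `H(x) = (a_H x - b_H) / (1 - exp(-d_H (a_H x - b_H)))`, with the
#' removable singularity at `a_H x = b_H` evaluated by its limit `1/d_H`.
#'
#' @param x total input current (nA), vectorized.
#' @param p a [pmfm_params] object supplying the constants.
#' @return Firing rate in Hz.
#' @export
pmfm_transfer <- function(x, p = pmfm_params()) {
  as.numeric(pmfm_transfer_cpp(as.numeric(x), p$a_H, p$b_H, p$d_H))
}

#' Simulate a Hopf whole-brain network
#'
#' Euler-Maruyama integration of the coupled planar oscillators, with
#' diffusive coupling `G * sum_j w_ij (x_j - x_i)` (and likewise for `y`).
#'
#' @param W a [connectome].
#' @param p a [hopf_params] object; `a` and `f` are recycled to the number
#'   of regions.
#' @param duration simulated time in seconds.
#' @param seed integer seed (also draws the initial conditions,
#'   `N(0, 0.3)` per variable, unless `x0`/`y0` are given).
#' @param x0,y0 optional initial conditions.
#' @return A list of class `hopf_raw` with matrices `x`, `y`
#'   (`n_steps + 1` rows including the initial condition) and metadata.
#' @export
simulate_hopf <- function(W, p, duration, seed, x0 = NULL, y0 = NULL) {
  stopifnot(inherits(W, "connectome"), inherits(p, "hopf_params"))
  n <- W$n_regions
  a <- rep_len(p$a, n); f <- rep_len(p$f, n)
  set.seed(seed)
  if (is.null(x0)) x0 <- rnorm(n, 0, 0.3)
  if (is.null(y0)) y0 <- rnorm(n, 0, 0.3)
  n_steps <- round(duration / p$dt)
  raw <- hopf_sim_cpp(W$weights, a, 2 * pi * f, p$G, p$beta_noise,
                      p$dt, n_steps, x0, y0)
  structure(list(x = raw$x, y = raw$y, dt = p$dt, duration = duration,
                 params = p, seed = seed),
            class = "hopf_raw")
}

#' Reduce a raw Hopf trajectory to the observation matrix
#'
#' Keeps the first variable (`x`) of every node, discards the initial
#' transient and decimates to the target sampling rate. With the standard
#' protocol (205 s run, 25 s discard, 1 Hz) every regional series has
#' exactly 180 samples.
#'
#' @param raw a `hopf_raw` object.
#' @param discard initial transient to drop, seconds.
#' @param target_rate output sampling rate in Hz; `1/dt` means no
#'   decimation.
#' @return Numeric matrix, time by regions, with attribute
#'   `sampling_interval` (seconds).
#' @export
postprocess_hopf <- function(raw, discard = 25, target_rate = 1) {
  stopifnot(inherits(raw, "hopf_raw"))
  if (raw$duration <= discard)
    stop("run of ", raw$duration, " s is not longer than the ", discard,
         " s discard window")
  step <- 1 / (target_rate * raw$dt)
  if (abs(step - round(step)) > 1e-8)
    stop("1/target_rate must be a multiple of dt")
  step <- round(step)
  n_drop <- round(discard / raw$dt)
  X <- raw$x[-seq_len(n_drop + 1), , drop = FALSE]  # drop t=0 row + transient
  idx <- seq(step, nrow(X), by = step)
  out <- X[idx, , drop = FALSE]
  attr(out, "sampling_interval") <- 1 / target_rate
  out
}

#' Simulate a parametric mean-field whole-brain network
#'
#' Euler-Maruyama integration of the synaptic gating equations, with
#' network input `I_n = G * sum_j w_ij S_j`. Initial conditions are drawn
#' uniformly on `[0.2, 0.8]` unless supplied. Excursions of `S` outside
#' `[0, 1]` under noise are not clipped; they are counted and reported in
#' the `n_out_of_range` field.
#'
#' @param W a [connectome].
#' @param p a [pmfm_params]; `r` and `sigma` are recycled.
#' @param duration simulated time in seconds (converted to ms internally).
#' @param seed integer seed.
#' @param S0 optional initial gating values.
#' @return A list of class `pmfm_raw` with matrix `S` and metadata.
#' @export
simulate_pmfm <- function(W, p, duration, seed, S0 = NULL) {
  stopifnot(inherits(W, "connectome"), inherits(p, "pmfm_params"))
  n <- W$n_regions
  r <- rep_len(p$r, n); sigma <- rep_len(p$sigma, n)
  set.seed(seed)
  if (is.null(S0)) S0 <- runif(n, 0.2, 0.8)
  n_steps <- round(duration * 1000 / p$dt)
  raw <- pmfm_sim_cpp(W$weights, r, sigma, p$G, p$J, p$I_o, p$tau_s,
                      p$gamma, p$a_H, p$b_H, p$d_H, p$dt, n_steps, S0)
  structure(list(S = raw$S, n_out_of_range = raw$n_out_of_range,
                 dt = p$dt, duration = duration, params = p, seed = seed),
            class = "pmfm_raw")
}

#' Reduce a raw mean-field trajectory to the observation matrix
#'
#' Discards the initial transient and averages over non-overlapping
#' windows. With the standard protocol (16.4 min run, 2 min discard,
#' 0.72 s windows at dt = 10 ms) every regional series has exactly 1200
#' samples.
#'
#' @param raw a `pmfm_raw` object.
#' @param discard transient to drop, seconds.
#' @param window averaging window, seconds; must be an integer multiple of
#'   the integration step.
#' @return Numeric matrix, time by regions, with attribute
#'   `sampling_interval` (seconds).
#' @export
postprocess_pmfm <- function(raw, discard = 120, window = 0.72) {
  stopifnot(inherits(raw, "pmfm_raw"))
  if (raw$duration <= discard)
    stop("run of ", raw$duration, " s is not longer than the ", discard,
         " s discard window")
  steps_per_win <- window * 1000 / raw$dt
  if (abs(steps_per_win - round(steps_per_win)) > 1e-8)
    stop("window (", window, " s) is not an integer multiple of the ",
         "integration step (", raw$dt, " ms); refusing to interpolate")
  steps_per_win <- round(steps_per_win)
  n_drop <- round(discard * 1000 / raw$dt)
  S <- raw$S[-seq_len(n_drop + 1), , drop = FALSE]
  n_win <- nrow(S) %/% steps_per_win
  S <- S[seq_len(n_win * steps_per_win), , drop = FALSE]
  grp <- rep(seq_len(n_win), each = steps_per_win)
  out <- apply(S, 2, function(col) tapply(col, grp, mean))
  out <- matrix(out, nrow = n_win)
  attr(out, "sampling_interval") <- window
  out
}

#' Grid search for the coupling maximizing functional connectivity
#'
#' For each candidate `G`, runs a probe simulation and computes the mean
#' off-diagonal functional connectivity (Pearson correlation) of the final
#' window of the raw gating trajectory; returns the grid argmax.
#'
#' @param W a [connectome].
#' @param p a [pmfm_params] (its `G` is ignored).
#' @param grid candidate couplings; default 31 values on `[0.17, 0.22]`.
#' @param probe_duration probe length in seconds (default 4 min).
#' @param fc_window final stretch used for FC, seconds (default 2 min).
#' @param seed integer seed (one independent probe per grid value).
#' @return The grid value with the highest mean FC, with the full scan in
#'   attribute `scan`.
#' @export
find_optimal_G <- function(W, p, grid = seq(0.17, 0.22, length.out = 31),
                           probe_duration = 240, fc_window = 120, seed = 1) {
  stopifnot(length(grid) >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, length(grid))
  mean_fc <- vapply(seq_along(grid), function(i) {
    pg <- p; pg$G <- grid[i]
    raw <- simulate_pmfm(W, pg, probe_duration, sub_seeds[i])
    n_keep <- round(fc_window * 1000 / p$dt)
    S <- raw$S[(nrow(raw$S) - n_keep + 1):nrow(raw$S), , drop = FALSE]
    v <- apply(S, 2, var)
    if (all(v == 0)) stop("FC undefined: all probe series have zero ",
                          "variance (is sigma = 0?)")
    fc_mean(fc(S))
  }, numeric(1))
  if (all(is.na(mean_fc))) stop("FC scan produced only NaN values")
  out <- grid[which.max(mean_fc)]
  attr(out, "scan") <- data.frame(G = grid, mean_fc = mean_fc)
  out
}

normalize_cohort <- function(subjects) {
  all_vals <- unlist(lapply(subjects, function(s) s$y))
  m <- mean(all_vals); s <- sd(all_vals)
  subjects <- lapply(subjects, function(su) {
    su$y <- (su$y - m) / s
    su
  })
  list(subjects = subjects, center = m, scale = s)
}

#' Build a synthetic Hopf validation cohort
#'
#' The standard conditions: one connectome per subject, coupling `G`
#' spaced linearly between 0 and 0.7 across subjects, per-region
#' frequencies uniform on `[0.03, 0.07]` Hz, bifurcation parameters
#' uniform on `[-1, 1]`, initial conditions `N(0, 0.3)`, 205 s runs with
#' the first 25 s discarded and the `x` variable decimated to 1 Hz
#' (180 samples per region). The assembled observations are normalized to
#' zero mean and unit variance across the whole dataset.
#'
#' @param n_subjects number of subjects (default 8).
#' @param seed master seed; all subject-level seeds derive from it.
#' @param n_regions regions per subject (default 68, must be even).
#' @param duration,discard simulation protocol, seconds.
#' @param beta_noise system noise SD.
#' @param G_max top of the linear coupling ramp.
#' @param density connectome density.
#' @return A `cohort` object: per-subject observations (`y`, time by
#'   regions), connectomes, ground-truth parameters, seeds; plus the
#'   sampling interval and the normalization applied.
#' @export
build_hopf_cohort <- function(n_subjects = 8, seed = 1, n_regions = 68,
                              duration = 205, discard = 25,
                              beta_noise = 0.05, G_max = 0.7,
                              density = 0.7) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_subjects),
                  ncol = 2)
  G_values <- if (n_subjects == 1) 0 else
    seq(0, G_max, length.out = n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    W <- generate_connectome(n_regions, seeds[i, 1], density = density)
    set.seed(seeds[i, 2])
    a <- runif(n_regions, -1, 1)
    f <- runif(n_regions, 0.03, 0.07)
    p <- hopf_params(a = a, f = f, G = G_values[i],
                     beta_noise = beta_noise)
    sim_seed <- sample.int(.Machine$integer.max, 1)
    raw <- simulate_hopf(W, p, duration, sim_seed)
    y <- postprocess_hopf(raw, discard = discard, target_rate = 1)
    list(y = y, connectome = W, seed = sim_seed,
         ground_truth = list(a = a, f = f, G = G_values[i]))
  })
  norm <- normalize_cohort(subjects)
  structure(list(subjects = norm$subjects, model = "hopf",
                 sampling_interval = 1,
                 normalization = list(center = norm$center,
                                      scale = norm$scale),
                 seed = seed,
                 build_args = list(n_subjects = n_subjects,
                                   n_regions = n_regions,
                                   duration = duration, discard = discard,
                                   beta_noise = beta_noise,
                                   G_max = G_max, density = density)),
            class = "cohort")
}

#' Build a synthetic parametric mean-field validation cohort
#'
#' One connectome per subject; per-region recurrent strengths uniform on
#' `[1.0, 1.4]` (spanning the monostable-down and bistable regimes of the
#' uncoupled node) and per-region noise SDs log-uniform on
#' `[0.005, 0.02]` (spanning quiescent to frequently switching nodes); the subject coupling `G` is set to the value in
#' `[0.17, 0.22]` maximizing mean FC in a 4-min probe. Each subject is
#' simulated for 16.4 min, the first 2 min discarded, and the gating
#' trajectories averaged over 0.72 s windows (1200 samples per region);
#' dataset-wide normalization is applied last.
#'
#' @param n_subjects number of subjects (default 8).
#' @param seed master seed.
#' @param n_regions regions per subject (default 68, must be even).
#' @param duration,discard simulation protocol, seconds.
#' @param sigma_range range of the log-uniform regional noise law.
#' @param r_range range of the uniform regional recurrent-strength law.
#' @param G_grid candidate couplings for the per-subject FC scan.
#' @param density connectome density.
#' @return A `cohort` object (see [build_hopf_cohort]).
#' @export
build_pmfm_cohort <- function(n_subjects = 8, seed = 1, n_regions = 68,
                              duration = 16.4 * 60, discard = 120,
                              sigma_range = c(5e-3, 2e-2),
                              r_range = c(1.0, 1.4),
                              G_grid = seq(0.17, 0.22, length.out = 31),
                              density = 0.7) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_subjects),
                  ncol = 3)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    W <- generate_connectome(n_regions, seeds[i, 1], density = density)
    set.seed(seeds[i, 2])
    r <- runif(n_regions, r_range[1], r_range[2])
    sigma <- exp(runif(n_regions, log(sigma_range[1]),
                       log(sigma_range[2])))
    p <- pmfm_params(r = r, sigma = sigma)
    G_opt <- find_optimal_G(W, p, grid = G_grid, seed = seeds[i, 2])
    p$G <- as.numeric(G_opt)
    sim_seed <- sample.int(.Machine$integer.max, 1)
    raw <- simulate_pmfm(W, p, duration, sim_seed)
    y <- postprocess_pmfm(raw, discard = discard, window = 0.72)
    list(y = y, connectome = W, seed = sim_seed,
         n_out_of_range = raw$n_out_of_range,
         ground_truth = list(r = r, sigma = sigma,
                             G = as.numeric(G_opt)))
  })
  norm <- normalize_cohort(subjects)
  structure(list(subjects = norm$subjects, model = "pmfm",
                 sampling_interval = 0.72,
                 normalization = list(center = norm$center,
                                      scale = norm$scale),
                 seed = seed,
                 build_args = list(n_subjects = n_subjects,
                                   n_regions = n_regions,
                                   duration = duration, discard = discard,
                                   sigma_range = sigma_range,
                                   r_range = r_range, G_grid = G_grid,
                                   density = density)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_s <- length(x$subjects)
  d <- dim(x$subjects[[1]]$y)
  cat(sprintf(
    "<cohort> %s model: %d subjects, %d regions, %d samples at %.2f s\n",
    x$model, n_s, d[2], d[1], x$sampling_interval))
  invisible(x)
}
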