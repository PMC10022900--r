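#' Functional connectivity and its comparison
#'
#' `fc` computes the Pearson correlation matrix of a multichannel time
#' series (time by regions). `fc_similarity` compares two FC matrices by
#' the Pearson correlation of their off-diagonal (upper-triangle) entries,
#' and `fc_mean` returns the mean off-diagonal value.
#'
#' @param ts_matrix numeric matrix, time by regions.
#' @param FC_a,FC_b square correlation matrices of equal size.
#' @param FC a square correlation matrix.
#' @return `fc`: a symmetric correlation matrix with unit diagonal;
#'   `fc_similarity`, `fc_mean`: a scalar.
#' @export
fc <- function(ts_matrix) {
  stats::cor(ts_matrix)
}

#' @rdname fc
#' @export
fc_similarity <- function(FC_a, FC_b) {
  stopifnot(all(dim(FC_a) == dim(FC_b)))
  ut <- upper.tri(FC_a)
  stats::cor(FC_a[ut], FC_b[ut])
}

#' @rdname fc
#' @export
fc_mean <- function(FC) {
  mean(FC[row(FC) != col(FC)])
}

#' Cosine similarity of two magnitude spectra
#'
#' Both series are mean-removed; the similarity is the cosine of the angle
#' between their one-sided discrete Fourier magnitude spectra. Invariant
#' under amplitude scaling of either series.
#'
#' @param ts_a,ts_b numeric vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
spectral_cosine <- function(ts_a, ts_b) {
  stopifnot(length(ts_a) == length(ts_b))
  mag <- function(x) {
    x <- x - mean(x)
    m <- Mod(stats::fft(x))
    m[seq_len(floor(length(x) / 2) + 1)]
  }
  a <- mag(ts_a); b <- mag(ts_b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Signed difference of time-series variances
#'
#' @param ts_a,ts_b numeric vectors.
#' @return `var(ts_a) - var(ts_b)`.
#' @export
variance_difference <- function(ts_a, ts_b) {
  var(ts_a) - var(ts_b)
}

#' One-dimensional Wasserstein (earth mover's) distance
#'
#' For equal sample sizes this is the mean absolute difference of the
#' sorted samples (the optimal transport pairing in 1-D); for unequal
#' sizes the integral of the absolute difference of empirical quantile
#' functions is evaluated exactly on the merged probability grid.
#'
#' @param samples_a,samples_b numeric vectors of draws from the two
#'   distributions.
#' @return Non-negative distance.
#' @export
wasserstein_1d <- function(samples_a, samples_b) {
  a <- sort(samples_a); b <- sort(samples_b)
  na <- length(a); nb <- length(b)
  if (na == nb) return(mean(abs(a - b)))
  # merged breakpoints of the two empirical quantile functions
  p <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  w <- diff(c(0, p))
  qa <- a[pmin(na, ceiling(p * na - 1e-12))]
  qb <- b[pmin(nb, ceiling(p * nb - 1e-12))]
  sum(w * abs(qa - qb))
}

#' Log-scaled count of up/down state switches
#'
#' Binarizes the series by hysteresis thresholding around its midpoint
#' (mean) with a dead band of `0.5 * band_sd` SDs on each side, counts the
#' transitions between the up and down state, and returns `log(1 + k)`.
#' The hysteresis band makes the count robust to jitter smaller than the
#' band.
#'
#' @param ts numeric vector.
#' @param band_sd half-width of the dead band in SD units (default 0.5).
#' @return `log(1 + number_of_switches)`; 0 for a constant series.
#' @export
switch_count <- function(ts, band_sd = 0.5) {
  s <- sd(ts)
  if (!is.finite(s) || s == 0) return(log(1))
  mid <- mean(ts)
  hi <- mid + band_sd * s
  lo <- mid - band_sd * s
  state <- 0L  # 0 = undecided yet
  k <- 0L
  for (v in ts) {
    new_state <- if (v > hi) 1L else if (v < lo) -1L else 0L
    if (new_state != 0L) {
      if (state != 0L && new_state != state) k <- k + 1L
      state <- new_state
    }
  }
  log(1 + k)
}

#' Recovery of ground-truth parameters from inferred posteriors
#'
#' Identifies the direction in the inferred regional-parameter space along
#' which a ground-truth parameter is stored, by ordinary least squares
#' from the posterior means to the true values. Then, for each of
#' `n_draws` posterior sample sets, projects the samples on that direction
#' and computes Spearman's rank correlation with the truth, yielding a
#' distribution of recovery scores.
#'
#' @param theta_means matrix (units by parameter dimensions) of posterior
#'   means.
#' @param theta_samples array (draws by units by dimensions) of posterior
#'   samples; if `NULL`, only the point estimate from the means is
#'   returned.
#' @param true_params numeric vector of ground-truth values, one per unit.
#' @param subset optional logical mask restricting the units entering the
#'   correlation (the projection is still fitted on all units).
#' @param n_draws number of posterior sample sets to score.
#' @return A list of class `recovery_result`: projection `weights`,
#'   `rho` (distribution over draws), `rho_mean`, and the 5/95 percentile
#'   interval.
#' @export
recover_parameters <- function(theta_means, theta_samples, true_params,
                               subset = NULL, n_draws = 50) {
  theta_means <- as.matrix(theta_means)
  stopifnot(nrow(theta_means) == length(true_params))
  if (sd(true_params) == 0)
    stop("true parameter is constant: rank correlation undefined")
  fit <- lm(true_params ~ theta_means)
  w <- coef(fit)
  if (anyNA(w)) w[is.na(w)] <- 0
  project <- function(Th) w[1] + as.matrix(Th) %*% w[-1]
  mask <- if (is.null(subset)) rep(TRUE, length(true_params)) else subset
  rho_of <- function(Th)
    suppressWarnings(cor(project(Th)[mask], true_params[mask],
                         method = "spearman"))
  if (is.null(theta_samples)) {
    rho <- rho_of(theta_means)
  } else {
    stopifnot(length(dim(theta_samples)) == 3)
    n_draws <- min(n_draws, dim(theta_samples)[1])
    rho <- vapply(seq_len(n_draws),
                  function(d) rho_of(theta_samples[d, , ]), numeric(1))
  }
  structure(list(weights = w, rho = rho, rho_mean = mean(rho),
                 interval = as.numeric(quantile(rho, c(0.05, 0.95))),
                 subset = mask),
            class = "recovery_result")
}

#' Surrogate cohorts for goodness-of-fit baselines
#'
#' \describe{
#'   \item{model_rerun}{re-simulates the original generative simulator
#'     with a different (or identical) noise seed -- an optimistic
#'     baseline for how much a fresh observation of the true system
#'     differs.}
#'   \item{reshuffle}{randomly permutes whole regional time series across
#'     regions and subjects, preserving their multiset exactly.}
#'   \item{white_noise}{independent `N(0, 1)` series of matching shape
#'     (the dataset-wide mean and variance of a normalized cohort).}
#' }
#'
#' @param cohort a `cohort` object.
#' @param kind surrogate type.
#' @param seed integer seed.
#' @return A `cohort` of the same shape.
#' @export
make_surrogates <- function(cohort,
                            kind = c("model_rerun", "reshuffle",
                                     "white_noise"),
                            seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(cohort, "cohort"))
  if (kind == "model_rerun") {
    builder <- if (cohort$model == "hopf") build_hopf_cohort
               else build_pmfm_cohort
    args <- cohort$build_args %||%
      list(n_subjects = length(cohort$subjects),
           n_regions = ncol(cohort$subjects[[1]]$y))
    args$seed <- seed
    return(do.call(builder, args))
  }
  set.seed(seed)
  out <- cohort
  if (kind == "reshuffle") {
    n_sub <- length(cohort$subjects)
    n_reg <- ncol(cohort$subjects[[1]]$y)
    pool <- do.call(cbind, lapply(cohort$subjects, function(s) s$y))
    perm <- sample.int(ncol(pool))
    for (i in seq_len(n_sub))
      out$subjects[[i]]$y <-
        pool[, perm[((i - 1) * n_reg + 1):(i * n_reg)], drop = FALSE]
  } else {
    for (i in seq_along(cohort$subjects)) {
      d <- dim(cohort$subjects[[i]]$y)
      y <- matrix(rnorm(prod(d)), d[1], d[2])
      attr(y, "sampling_interval") <-
        attr(cohort$subjects[[i]]$y, "sampling_interval")
      out$subjects[[i]]$y <- y
    }
  }
  out
}

#' Per-region features of a subject's data
#'
#' Computes the individual-level regional features used to interpret the
#' inferred parameters: connectome node in-strength and eigenvector
#' centrality; loadings of the first and second principal component of
#' the time series; correlation of each regional series with the mean
#' signal and with its network input; number of zero crossings; and the
#' fraction of spectral power below 0.1 Hz (the series being normalized,
#' total power is constant, so the fraction is the meaningful quantity).
#'
#' @param y numeric matrix, time by regions (zero-mean scale expected for
#'   zero crossings).
#' @param W a [connectome].
#' @param sampling_interval seconds per sample (defaults to the matrix
#'   attribute, else 1).
#' @return A data frame, one row per region, one column per feature.
#' @export
feature_table <- function(y, W, sampling_interval = NULL) {
  stopifnot(inherits(W, "connectome"), ncol(y) == W$n_regions)
  if (is.null(sampling_interval))
    sampling_interval <- attr(y, "sampling_interval") %||% 1
  n <- ncol(y)
  in_strength <- rowSums(W$weights)
  ev <- eigen(W$weights, symmetric = isSymmetric(W$weights))
  centrality <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  pca <- prcomp(y, center = TRUE, scale. = FALSE)
  mean_sig <- rowMeans(y)
  u <- compute_network_input(y, W)
  corr_mean <- vapply(seq_len(n), function(j) cor(y[, j], mean_sig),
                      numeric(1))
  corr_netin <- vapply(seq_len(n), function(j) cor(y[, j], u[, j]),
                       numeric(1))
  zc <- vapply(seq_len(n), function(j) {
    s <- sign(y[, j] - mean(y[, j]))
    s <- s[s != 0]
    sum(diff(s) != 0)
  }, numeric(1))
  lowpow <- vapply(seq_len(n), function(j) {
    x <- y[, j] - mean(y[, j])
    m2 <- Mod(stats::fft(x))^2
    nf <- floor(length(x) / 2)
    freqs <- (1:nf) / (length(x) * sampling_interval)
    p <- m2[2:(nf + 1)]
    sum(p[freqs < 0.1]) / sum(p)
  }, numeric(1))
  data.frame(in_strength = in_strength,
             centrality = centrality,
             pca1 = pca$rotation[, 1],
             pca2 = pca$rotation[, 2],
             corr_mean_signal = corr_mean,
             corr_network_input = corr_netin,
             zero_crossings = zc,
             power_below_0.1Hz = lowpow)
}

#' Posterior-predictive goodness-of-fit of a trained model
#'
#' For each subject, repeatedly samples the regional and subject
#' parameters from their posteriors, generates new time series with the
#' trained model (fresh system and observation noise), and scores the
#' generated data against the originals: per-region spectral cosine
#' similarity, variance difference, 1-D Wasserstein distance and
#' difference of log switch counts, plus subject-level FC similarity and
#' mean FC.
#'
#' @param trained a `trained_vae`.
#' @param cohort the training cohort.
#' @param n_draws posterior draws per subject.
#' @param seed integer seed.
#' @param u_ext_mode external input for generation: a sample from its
#'   subject posterior (default), a fresh draw from the AR(1) prior, or
#'   zero.
#' @param subjects subset of subject indices (default all).
#' @return List with data frames `metrics` (one row per subject, region,
#'   draw) and `fc` (one row per subject, draw).
#' @export
evaluate_cohort_fit <- function(trained, cohort, n_draws = 10, seed = 1,
                                u_ext_mode = c("posterior", "prior",
                                               "zero"),
                                subjects = NULL) {
  u_ext_mode <- match.arg(u_ext_mode)
  stopifnot(inherits(trained, "trained_vae"), inherits(cohort, "cohort"))
  model <- as_generative_model(trained)
  enc <- encode_cohort(trained, cohort)
  sp <- subject_posteriors(trained)
  set.seed(seed)
  n_sub <- length(cohort$subjects)
  if (is.null(subjects)) subjects <- seq_len(n_sub)
  burn_in <- 50
  met <- list(); fcs <- list()
  for (i in subjects) {
    su <- cohort$subjects[[i]]
    n_t <- nrow(su$y); n_reg <- ncol(su$y)
    sel <- which(enc$subj == i - 1)
    mu_r <- enc$mu_r[sel, , drop = FALSE]
    sd_r <- exp(0.5 * enc$logvar_r[sel, , drop = FALSE])
    FC_orig <- fc(su$y)
    for (d in seq_len(n_draws)) {
      th_r <- mu_r + sd_r * matrix(rnorm(length(mu_r)), nrow(mu_r))
      th_s <- if (trained$dims[["m_s"]] > 0)
        sp$mu_s[, i] + exp(0.5 * sp$logvar_s[, i]) *
          rnorm(trained$dims[["m_s"]])
      else numeric(0)
      u_ext <- switch(u_ext_mode,
        posterior = {
          us <- sp$mu_u[, i] + exp(0.5 * sp$logvar_u[, i]) * rnorm(n_t)
          c(rep(us[1], burn_in), us)  # burn-in held at the first value
        },
        prior = NULL,   # simulate_network samples the AR(1) prior
        zero = numeric(burn_in + n_t))
      gen <- simulate_network(model, th_r, th_s, su$connectome, n_t,
                              seed = sample.int(.Machine$integer.max, 1),
                              u_ext = u_ext, burn_in = burn_in)
      for (j in seq_len(n_reg)) {
        met[[length(met) + 1]] <- data.frame(
          subject = i, region = j, draw = d,
          spectral_cosine = spectral_cosine(su$y[, j], gen$y[, j]),
          variance_difference = variance_difference(gen$y[, j],
                                                    su$y[, j]),
          wasserstein = wasserstein_1d(su$y[, j], gen$y[, j]),
          switch_diff = switch_count(gen$y[, j]) -
                        switch_count(su$y[, j]))
      }
      FC_gen <- fc(gen$y)
      fcs[[length(fcs) + 1]] <- data.frame(
        subject = i, draw = d,
        fc_similarity = fc_similarity(FC_orig, FC_gen),
        fc_mean_orig = fc_mean(FC_orig),
        fc_mean_gen = fc_mean(FC_gen))
    }
  }
  list(metrics = do.call(rbind, met), fc = do.call(rbind, fcs))
}

#' Read an external per-region feature map
#'
#' External feature maps (gene-expression components, myelin ratios,
#' cytoarchitectonic densities, ...) are consumed as two-column
#' tab-separated text: region label, value. None are bundled; any
#' per-region vector can be regressed on the inferred parameters with
#' [feature_regression].
#'
#' @param path two-column TSV file (no header).
#' @return Named numeric vector, one value per region.
#' @export
read_feature_tsv <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("region", "value"),
                   colClasses = c("character", "numeric"))
  if (anyNA(tb$value)) stop("non-numeric feature value in ", path)
  stats::setNames(tb$value, tb$region)
}

#' Multivariate regression of a regional feature on inferred parameters
#'
#' Regresses a (normalized) per-region feature on the inferred regional
#' parameters, repeated over posterior sample draws: for each draw an
#' ordinary least squares fit gives R-squared, weights and two-sided
#' t-test p-values; means over draws are reported, with a Bonferroni
#' significance threshold.
#'
#' @param theta_samples array (draws by regions by dimensions) of
#'   posterior samples, or a matrix (regions by dimensions) for a single
#'   draw.
#' @param feature per-region numeric vector.
#' @param n_draws number of draws used (default 100, capped by the array).
#' @param bonferroni_m number of comparisons the 0.001 threshold is
#'   corrected for (default 45, i.e. threshold 2.22e-5).
#' @return List with `r2`, `weights`, `p_values` (means over draws),
#'   `significant` (mean p below the corrected threshold), `threshold`.
#' @export
feature_regression <- function(theta_samples, feature, n_draws = 100,
                               bonferroni_m = 45) {
  if (length(dim(theta_samples)) == 2)
    theta_samples <- array(theta_samples,
                           c(1, nrow(theta_samples), ncol(theta_samples)))
  stopifnot(dim(theta_samples)[2] == length(feature))
  if (sd(feature) == 0) stop("feature has zero variance")
  feat <- as.numeric(scale(feature))
  n_draws <- min(n_draws, dim(theta_samples)[1])
  m_r <- dim(theta_samples)[3]
  r2 <- numeric(n_draws)
  wts <- matrix(NA_real_, n_draws, m_r)
  pvs <- matrix(NA_real_, n_draws, m_r)
  for (d in seq_len(n_draws)) {
    Th <- as.matrix(theta_samples[d, , ])
    fit <- lm(feat ~ Th)
    sm <- summary(fit)
    r2[d] <- sm$r.squared
    cf <- sm$coefficients
    wts[d, ] <- cf[-1, 1]
    pvs[d, ] <- cf[-1, 4]
  }
  threshold <- 0.001 / bonferroni_m
  list(r2 = mean(r2), weights = colMeans(wts),
       p_values = colMeans(pvs),
       significant = colMeans(pvs) < threshold,
       threshold = threshold, n_draws = n_draws)
}
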