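#' Locate fixed points of a vector field
#'
#' Runs damped least-squares (Levenberg-Marquardt) root finding from
#' multiple random initializations sampled uniformly from a box, keeps
#' the converged roots (`max|field| < tol`) and deduplicates them within
#' `10 * tol` in the max-norm.
#'
#' @param field function mapping a state vector to its time derivative.
#' @param dim state dimension.
#' @param n_inits number of random initializations.
#' @param box lower/upper bound of the sampling box per dimension.
#' @param tol residual tolerance for a converged root.
#' @param seed integer seed.
#' @return Matrix of roots (one per row; zero rows if none converged),
#'   with the initializations in attribute `inits`.
#' @export
find_fixed_points <- function(field, dim, n_inits = 60, box = c(-2, 2),
                              tol = 1e-6, seed = 1) {
  set.seed(seed)
  inits <- matrix(runif(n_inits * dim, box[1], box[2]), n_inits, dim)
  roots <- list()
  for (i in seq_len(n_inits)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = inits[i, ], fn = function(x) field(x),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- fit$par
    if (max(abs(field(r))) < tol) roots[[length(roots) + 1]] <- r
  }
  if (length(roots) == 0) {
    out <- matrix(numeric(0), 0, dim)
  } else {
    R <- do.call(rbind, roots)
    keep <- rep(TRUE, nrow(R))
    for (i in seq_len(nrow(R))) {
      if (!keep[i]) next
      if (i < nrow(R))
        for (j in (i + 1):nrow(R))
          if (keep[j] && max(abs(R[i, ] - R[j, ])) < 10 * tol)
            keep[j] <- FALSE
    }
    out <- R[keep, , drop = FALSE]
  }
  attr(out, "inits") <- inits
  out
}

numeric_jacobian <- function(field, x, rel_step = 1e-6) {
  d <- length(x)
  J <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    h <- rel_step * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (field(xp) - field(xm)) / (2 * h)
  }
  J
}

#' Classify a fixed point by its Jacobian eigenvalues
#'
#' The Jacobian is evaluated by central finite differences. A point is
#' stable iff all eigenvalue real parts are negative: a stable node when
#' all eigenvalues are (numerically) real, a stable spiral when a complex
#' pair is present (decaying oscillations). Mixed-sign real parts give a
#' saddle; otherwise the point is unstable.
#'
#' @param field vector-field function.
#' @param root state vector at which `field` vanishes.
#' @param imag_tol threshold on `|Im|` for calling an eigenvalue real.
#' @return List with `eigenvalues` (complex), `stable` and `label`.
#' @export
classify_fixed_point <- function(field, root, imag_tol = 1e-8) {
  J <- numeric_jacobian(field, root)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <-
    if (all(re < 0)) {
      if (all(abs(Im(ev)) < imag_tol)) "stable node" else "stable spiral"
    } else if (any(re < 0) && any(re > 0)) {
      "saddle"
    } else {
      "unstable"
    }
  list(eigenvalues = ev, stable = all(re < 0), label = label)
}

#' Detect unsteady (non-convergent) deterministic dynamics
#'
#' Simulates the noise-free field from each initialization for
#' `horizon_1` seconds; an initialization has converged if every state
#' in the final `check_window` stays within `eps` (L2) of the terminal
#' state. Failing trajectories are extended to `horizon_2` and
#' re-checked; if still failing they are flagged unsteady (periodic or
#' chaotic motion, by construction of the criterion).
#'
#' Horizons are expressed in seconds and converted to integration steps
#' via `sampling_interval` (for sample-unit models the learned step is
#' one sample).
#'
#' @param field vector-field function.
#' @param inits matrix of initial states (one per row).
#' @param horizon_1,horizon_2 first and extended horizons, seconds.
#' @param check_window convergence window, seconds.
#' @param eps L2 vicinity threshold.
#' @param sampling_interval seconds per integration step (default 0.72).
#' @return Logical vector, `TRUE` where the trajectory is unsteady.
#' @export
detect_unsteady <- function(field, inits, horizon_1 = 288,
                            check_window = 72, eps = 1e-3,
                            horizon_2 = 1200,
                            sampling_interval = 0.72) {
  inits <- as.matrix(inits)
  n1 <- ceiling(horizon_1 / sampling_interval)
  n2 <- ceiling(horizon_2 / sampling_interval)
  nw <- ceiling(check_window / sampling_interval)
  roll <- function(x0, n_steps) {
    d <- length(x0)
    out <- matrix(NA_real_, n_steps + 1, d)
    out[1, ] <- x0
    x <- x0
    for (k in seq_len(n_steps)) {
      x <- x + field(x)
      if (any(!is.finite(x))) return(out[seq_len(k), , drop = FALSE])
      out[k + 1, ] <- x
    }
    out
  }
  converged <- function(tr, nw) {
    if (nrow(tr) < nw + 1) return(FALSE)
    final <- tr[nrow(tr), ]
    win <- tr[(nrow(tr) - nw):(nrow(tr)), , drop = FALSE]
    all(sqrt(rowSums((win - matrix(final, nrow(win), length(final),
                                   byrow = TRUE))^2)) < eps)
  }
  vapply(seq_len(nrow(inits)), function(i) {
    tr <- roll(inits[i, ], n1)
    if (converged(tr, nw)) return(FALSE)
    tr <- roll(inits[i, ], n2)
    !converged(tr, nw)
  }, logical(1))
}

# vector field of one uncoupled learned node at fixed inputs
node_field <- function(model, theta_r, theta_s, u = 0, u_ext = 0) {
  force(model); force(theta_r); force(theta_s); force(u); force(u_ext)
  function(x) eval_f(x, theta_r, theta_s, u_ext, u, model$mlp)
}

# joint field of the coupled network (n * n_s dimensions, states stacked
# region-major), coupling through the noise-free projection g(x)
network_field <- function(model, theta_r, theta_s, W, u_ext = 0) {
  theta_r <- as.matrix(theta_r)
  n <- nrow(theta_r)
  n_s <- model$mlp$n_s
  function(xflat) {
    X <- matrix(xflat, n_s, n)
    g <- as.numeric(crossprod(model$obs$a, X)) + model$obs$b
    u <- as.numeric(W$weights %*% g)
    Z <- rbind(X, t(theta_r),
               if (model$mlp$m_s > 0)
                 matrix(theta_s, model$mlp$m_s, n) else NULL,
               rep(u_ext, n), u)
    as.numeric(mlp_eval_cpp(model$mlp$W1, model$mlp$b1, model$mlp$W2,
                            model$mlp$b2, Z))
  }
}

#' Dynamical-regime census of uncoupled nodes
#'
#' For every supplied regional parameter configuration and every
#' combination of network and external input on a grid, locates the
#' fixed points of the single-node field, classifies their stability and
#' probes for unsteady dynamics from the same initializations.
#'
#' @param model a [generative_model].
#' @param theta_r_list matrix (configurations by `m_r`) or list of
#'   parameter vectors.
#' @param theta_s subject parameter vector (default zeros).
#' @param input_grid numeric values taken by both `u` and `u_ext`
#'   (crossed); default `c(-1, 0, 1)`.
#' @param n_inits random initializations per configuration (default 60).
#' @param seed integer seed.
#' @param sampling_interval seconds per sample for the unsteadiness
#'   horizons.
#' @return Data frame, one row per configuration and input combination:
#'   number of fixed points, number stable, multistable and unsteady
#'   flags.
#' @export
node_regime_census <- function(model, theta_r_list,
                               theta_s = numeric(model$mlp$m_s),
                               input_grid = c(-1, 0, 1), n_inits = 60,
                               seed = 1, sampling_interval = 0.72) {
  if (is.list(theta_r_list))
    theta_r_list <- do.call(rbind, theta_r_list)
  theta_r_list <- as.matrix(theta_r_list)
  grid <- expand.grid(u = input_grid, u_ext = input_grid)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             nrow(theta_r_list) * nrow(grid)),
                  nrow(theta_r_list))
  rows <- list()
  for (i in seq_len(nrow(theta_r_list))) {
    for (gidx in seq_len(nrow(grid))) {
      fld <- node_field(model, theta_r_list[i, ], theta_s,
                        u = grid$u[gidx], u_ext = grid$u_ext[gidx])
      fp <- find_fixed_points(fld, model$mlp$n_s, n_inits = n_inits,
                              seed = seeds[i, gidx])
      stable <- if (nrow(fp) == 0) logical(0) else
        vapply(seq_len(nrow(fp)),
               function(r) classify_fixed_point(fld, fp[r, ])$stable,
               logical(1))
      uns <- detect_unsteady(fld, attr(fp, "inits"),
                             sampling_interval = sampling_interval)
      rows[[length(rows) + 1]] <- data.frame(
        config = i, u = grid$u[gidx], u_ext = grid$u_ext[gidx],
        n_fixed = nrow(fp), n_stable = sum(stable),
        multistable = sum(stable) > 1, unsteady = any(uns))
    }
  }
  do.call(rbind, rows)
}

#' Dynamical-regime analysis of the coupled network
#'
#' Treats the coupled system (all regions, coupling through the
#' observation projection) as a single vector field of dimension
#' `n_regions * n_s` and repeats the fixed-point/stability/unsteadiness
#' census for several posterior samples of the regional parameters, with
#' the external input set to zero.
#'
#' @param model a [generative_model].
#' @param theta_r_samples array (samples by regions by `m_r`), a single
#'   matrix (regions by `m_r`), or a list of such matrices.
#' @param theta_s subject parameter vector.
#' @param W a [connectome].
#' @param n_inits random initializations (default 100).
#' @param seed integer seed.
#' @param sampling_interval seconds per sample.
#' @return List of class `regime_report`: per-sample data frame
#'   (`n_fixed`, `n_stable`, `unsteady`), overall `multistable` flag,
#'   and the fixed points of the last sample.
#' @export
network_regime_analysis <- function(model, theta_r_samples,
                                    theta_s = numeric(model$mlp$m_s),
                                    W, n_inits = 100, seed = 1,
                                    sampling_interval = 0.72) {
  if (is.matrix(theta_r_samples))
    theta_r_samples <- list(theta_r_samples)
  if (is.array(theta_r_samples) && length(dim(theta_r_samples)) == 3)
    theta_r_samples <- lapply(seq_len(dim(theta_r_samples)[1]),
                              function(d) theta_r_samples[d, , ])
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(theta_r_samples))
  rows <- list(); last_fp <- NULL
  for (s in seq_along(theta_r_samples)) {
    th <- as.matrix(theta_r_samples[[s]])
    fld <- network_field(model, th, theta_s, W, u_ext = 0)
    dim_full <- nrow(th) * model$mlp$n_s
    fp <- find_fixed_points(fld, dim_full, n_inits = n_inits,
                            seed = seeds[s])
    stable <- if (nrow(fp) == 0) logical(0) else
      vapply(seq_len(nrow(fp)),
             function(r) classify_fixed_point(fld, fp[r, ])$stable,
             logical(1))
    uns <- detect_unsteady(fld, attr(fp, "inits"),
                           sampling_interval = sampling_interval)
    rows[[s]] <- data.frame(sample = s, n_fixed = nrow(fp),
                            n_stable = sum(stable),
                            unsteady = any(uns))
    last_fp <- fp
  }
  tab <- do.call(rbind, rows)
  structure(list(per_sample = tab,
                 multistable = any(tab$n_stable > 1),
                 unsteady = any(tab$unsteady),
                 fixed_points = last_fp),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report>\n")
  print(x$per_sample)
  cat("multistable:", x$multistable, " unsteady:", x$unsteady, "\n")
  invisible(x)
}
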