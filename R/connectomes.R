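#' Structural connectome container
#'
#' A `connectome` is a square non-negative coupling matrix `weights`
#' (max-normalized so that the largest entry equals one), together with the
#' preprocessing variant that produced it and, optionally, the homotopic
#' region pairing used for the homotopic variants.
#'
#' @param weights square numeric matrix of coupling strengths.
#' @param variant one of `"standard"`, `"log"`, `"standard+homotopic"`,
#'   `"log+homotopic"`, `"perturbed"`.
#' @param homotopic_pairing optional two-column integer matrix of region
#'   index pairs (1-based), one row per homotopic pair.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, variant = "standard", homotopic_pairing = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectome weights must be a square matrix")
  if (!is.numeric(weights) || anyNA(weights))
    stop("connectome weights must be numeric and free of NA")
  variant <- match.arg(variant,
    c("standard", "log", "standard+homotopic", "log+homotopic", "perturbed"))
  if (variant != "perturbed" && any(weights < 0))
    stop("negative weights are only allowed in the 'perturbed' variant")
  structure(
    list(weights = unname(weights), n_regions = nrow(weights),
         variant = variant, homotopic_pairing = homotopic_pairing),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d x %d, variant '%s', max weight %.4g\n",
              x$n_regions, x$n_regions, x$variant, max(x$weights)))
  invisible(x)
}

max_normalize <- function(W) {
  m <- max(abs(W))
  if (m == 0) stop("cannot max-normalize an all-zero matrix")
  W / m
}

#' Generate a synthetic structural connectome
#'
#' Stand-in for tractography-derived streamline-count matrices. Edges are
#' selected with probability `density` on the upper triangle, weighted with
#' log-normal draws (heavy-tailed, like streamline counts), symmetrized,
#' zero-diagonal and max-normalized. `n_regions` must be even so that a
#' two-hemisphere block layout defines homotopic pairs: region `i` in the
#' first half pairs with region `i + n_regions/2`.
#'
#' @param n_regions even number of regions.
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @param density fraction of possible edges present, in (0, 1].
#' @param meanlog,sdlog parameters of the log-normal weight law.
#' @return A [connectome], with the homotopic pairing attached.
#' @export
generate_connectome <- function(n_regions, seed, density = 0.7,
                                meanlog = 0, sdlog = 1) {
  if (n_regions %% 2 != 0)
    stop("n_regions must be even: homotopic pairing maps region i to ",
         "i + n_regions/2, which requires two equal hemisphere blocks")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  set.seed(seed)
  n <- n_regions
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  W[on] <- exp(rnorm(length(on), meanlog, sdlog))
  W <- W + t(W)
  W <- max_normalize(W)
  pairing <- cbind(seq_len(n %/% 2), seq_len(n %/% 2) + n %/% 2)
  connectome(W, "standard", homotopic_pairing = pairing)
}

#' Preprocess a structural connectome
#'
#' Applies the preprocessing variants used for whole-brain modeling:
#' \describe{
#'   \item{standard}{identity.}
#'   \item{log}{entrywise `log10(W + 10^q)`, shifted to be non-negative.}
#'   \item{homotopic}{overwrites each homotopic pair entry (both
#'     directions) with the `homotopic_pct` percentile of all `n^2` entries
#'     of the input matrix.}
#' }
#' After every transformation the matrix is re-normalized so that its
#' largest element equals one.
#'
#' @param W a [connectome] (max-normalized).
#' @param variant `"standard"`, `"log"`, `"standard+homotopic"` or
#'   `"log+homotopic"`.
#' @param q exponent of the log-scaling offset, `10^q`; default -3.
#' @param homotopic_pct percentile (0-100) used for homotopic
#'   strengthening; default 97. Computed over all matrix entries,
#'   including the zero diagonal.
#' @return A [connectome] with the requested variant.
#' @export
preprocess_connectome <- function(W, variant = c("standard", "log",
                                                 "standard+homotopic",
                                                 "log+homotopic"),
                                  q = -3, homotopic_pct = 97) {
  variant <- match.arg(variant)
  stopifnot(inherits(W, "connectome"))
  M <- W$weights
  use_log <- variant %in% c("log", "log+homotopic")
  use_hom <- variant %in% c("standard+homotopic", "log+homotopic")
  if (use_log) {
    # log10 of a max-normalized matrix lies in [q, log10(1 + 10^q)];
    # shift by -q so an absent connection maps to 0, keeping the matrix
    # non-negative and order-preserving before renormalization
    M <- log10(M + 10^q) - q
  }
  if (use_hom) {
    if (is.null(W$homotopic_pairing))
      stop("homotopic variant requested but the connectome carries no ",
           "homotopic pairing")
    v <- as.numeric(quantile(W$weights, homotopic_pct / 100, names = FALSE))
    if (use_log) v <- log10(v + 10^q) - q  # percentile taken on the input scale
    p <- W$homotopic_pairing
    M[cbind(p[, 1], p[, 2])] <- v
    M[cbind(p[, 2], p[, 1])] <- v
  }
  M <- max_normalize(M)
  connectome(M, variant, homotopic_pairing = W$homotopic_pairing)
}

#' Randomly perturb a connectome
#'
#' Returns `W + eps * A` with `A` a matrix of independent standard normal
#' entries, then max-normalized. Used to probe the sensitivity of the
#' inference to errors in the assumed structural network; the result may
#' contain negative entries.
#'
#' @param W a [connectome].
#' @param eps perturbation magnitude, >= 0.
#' @param seed integer seed.
#' @return A [connectome] with variant `"perturbed"` (or the input
#'   unchanged when `eps == 0`).
#' @export
perturb_connectome <- function(W, eps, seed) {
  stopifnot(inherits(W, "connectome"), eps >= 0)
  if (eps == 0) return(W)
  set.seed(seed)
  n <- W$n_regions
  A <- matrix(rnorm(n * n), n, n)
  raw <- W$weights + eps * A
  out <- connectome(max_normalize(raw), "perturbed",
                    homotopic_pairing = W$homotopic_pairing)
  out$scale <- max(abs(raw))  # pre-normalization maximum, for provenance
  out
}

#' Read / write a connectome as delimited text
#'
#' The on-disk format is a square tab-separated matrix without header.
#' An optional JSON sidecar `<path>.json` stores the variant and the
#' homotopic pairing.
#'
#' @param path file path of the TSV matrix.
#' @param W a [connectome] (for writing).
#' @return `read_connectome` returns a [connectome]; `write_connectome`
#'   returns `path` invisibly.
#' @export
read_connectome <- function(path) {
  M <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  side <- paste0(path, ".json")
  variant <- "standard"; pairing <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    variant <- meta$variant %||% "standard"
    if (!is.null(meta$homotopic_pairing))
      pairing <- matrix(as.integer(meta$homotopic_pairing), ncol = 2)
  }
  connectome(M, variant, homotopic_pairing = pairing)
}

#' @rdname read_connectome
#' @export
write_connectome <- function(W, path) {
  stopifnot(inherits(W, "connectome"))
  write.table(format(W$weights, digits = 12, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(variant = W$variant)
  if (!is.null(W$homotopic_pairing))
    meta$homotopic_pairing <- as.integer(W$homotopic_pairing)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
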