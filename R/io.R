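#' Read and write regional time-series matrices as TSV
#'
#' On-disk format: rows are time points, columns are regions, with a
#' header row of region labels. Values round-trip losslessly to 12
#' significant digits.
#'
#' @param path file path.
#' @param matrix numeric matrix, time by regions.
#' @param labels region labels (defaults to existing column names or
#'   `R1..Rn`).
#' @return `read_timeseries_tsv` returns the matrix with column labels;
#'   `write_timeseries_tsv` returns `path` invisibly.
#' @export
read_timeseries_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty time-series file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2)
    stop("time-series file has no data rows: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol <- length(header)
  bad <- which(vapply(rows, length, integer(1)) != ncol)
  if (length(bad) > 0)
    stop("ragged row ", bad[1] + 1, " in ", path, ": expected ", ncol,
         " fields")
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals))
    stop("non-numeric cell in ", path)
  out <- matrix(vals, ncol = ncol, byrow = TRUE)
  colnames(out) <- header
  out
}

#' @rdname read_timeseries_tsv
#' @export
write_timeseries_tsv <- function(matrix, path, labels = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(labels))
    labels <- colnames(matrix) %||% paste0("R", seq_len(ncol(matrix)))
  txt <- apply(matrix, 1, function(r)
    paste(format(r, digits = 12, trim = TRUE, scientific = TRUE),
          collapse = "\t"))
  writeLines(c(paste(labels, collapse = "\t"), txt), path)
  invisible(path)
}

#' Write / read a simulated cohort as a directory of TSVs
#'
#' One `subject_XX.tsv` per subject (plus its connectome) and a JSON
#' manifest carrying the model kind, seeds, ground-truth parameters,
#' sampling interval and normalization.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    write_timeseries_tsv(s$y, file.path(dir,
                         sprintf("subject_%02d.tsv", i)))
    write_connectome(s$connectome, file.path(dir,
                     sprintf("connectome_%02d.tsv", i)))
  }
  manifest <- list(
    model = cohort$model,
    n_subjects = length(cohort$subjects),
    sampling_interval = cohort$sampling_interval,
    normalization = cohort$normalization,
    seed = cohort$seed,
    package_version = as.character(utils::packageVersion("brainvae")),
    subjects = lapply(cohort$subjects, function(s)
      list(seed = s$seed, ground_truth = s$ground_truth)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  n <- mf$n_subjects
  subjects <- lapply(seq_len(n), function(i) {
    y <- read_timeseries_tsv(file.path(dir,
                             sprintf("subject_%02d.tsv", i)))
    attr(y, "sampling_interval") <- mf$sampling_interval
    W <- read_connectome(file.path(dir,
                         sprintf("connectome_%02d.tsv", i)))
    gt <- if (is.data.frame(mf$subjects)) as.list(mf$subjects[i, ])
          else mf$subjects[[i]]
    truth <- lapply(gt$ground_truth, function(v) unlist(v, use.names = FALSE))
    list(y = y, connectome = W, seed = unlist(gt$seed),
         ground_truth = truth)
  })
  structure(list(subjects = subjects, model = mf$model,
                 sampling_interval = mf$sampling_interval,
                 normalization = mf$normalization, seed = mf$seed),
            class = "cohort")
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is one JSON archive (schema version 1) holding the
#' flat parameter vector, the dimension set, the training configuration,
#' the datapoint split and the per-epoch diagnostics.
#'
#' @param trained a `trained_vae`.
#' @param path checkpoint path (`.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   a `trained_vae`.
#' @export
save_checkpoint <- function(trained, path) {
  stopifnot(inherits(trained, "trained_vae"))
  obj <- list(schema = 1L,
              package_version =
                as.character(utils::packageVersion("brainvae")),
              params = trained$params,
              dims = as.list(trained$dims),
              config = unclass(trained$config),
              split = trained$split,
              datapoints = trained$datapoints,
              diagnostics = trained$diagnostics,
              sampling_interval = trained$sampling_interval)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != 1)
    stop("unsupported checkpoint schema: ", obj$schema)
  dims <- unlist(obj$dims)
  storage.mode(dims) <- "integer"
  cfg <- obj$config
  class(cfg) <- "training_config"
  structure(list(params = as.numeric(obj$params), dims = dims,
                 config = cfg, split = obj$split,
                 datapoints = obj$datapoints,
                 diagnostics = as.data.frame(obj$diagnostics),
                 sampling_interval = obj$sampling_interval),
            class = "trained_vae")
}

#' Read a run configuration file
#'
#' YAML file mirroring [training_config] plus optional simulator and
#' evaluation blocks; unknown keys are rejected to catch typos. The
#' master seed must be present.
#'
#' @param path YAML file.
#' @return Named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "training", "simulator", "evaluation", "paths")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a master seed")
  tr_known <- names(formals(training_config))
  if (!is.null(cfg$training)) {
    bad <- setdiff(names(cfg$training), tr_known)
    if (length(bad) > 0)
      stop("unknown training keys: ", paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}
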