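## File I/O: response matrices from CSV, fitted results to a directory of
## plain-text tables, and the canonical eta tuning grids.

#' Canonical eta tuning grids
#'
#' `"coarse"` is the simulation-study grid `(0.10, 0.09, ..., 0.01) * N`;
#' `"fine"` is the questionnaire-analysis grid
#' `(0.040, 0.038, ..., 0.002) * N`.
#'
#' @param N Sample size.
#' @param preset `"coarse"` or `"fine"`.
#' @return Numeric vector of penalty weights, descending.
#' @export
eta_grid <- function(N, preset = c("coarse", "fine")) {
  preset <- match.arg(preset)
  switch(preset,
         coarse = seq(0.10, 0.01, by = -0.01) * N,
         fine = seq(0.040, 0.002, by = -0.002) * N)
}

#' Read a binary response matrix from CSV
#'
#' Rows are subjects, columns are items; cells must be 0 or 1.  An optional
#' header row of item labels is kept as column names.
#'
#' @param path CSV file path.
#' @param header Does the file have a header row of item labels?
#' @return N x J integer matrix (item labels as `colnames` when present).
#' @export
read_responses <- function(path, header = NA) {
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), ",")[[1]]
    header <- suppressWarnings(any(is.na(as.numeric(first))))
  }
  df <- utils::read.csv(path, header = header, check.names = FALSE)
  Y <- as.matrix(df)
  bad <- which(is.na(Y) | !(Y %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary or missing entry at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path))
  storage.mode(Y) <- "integer"
  rownames(Y) <- NULL
  Y
}

#' Write a fitted model to a directory of plain-text files
#'
#' Writes `A.tsv` (J x K loadings), `b.tsv`, `sigma.tsv`, `lambda.tsv`, and
#' `run.json` (configuration, convergence diagnostics, seed).  When `fit`
#' carries a tuning path, `path.csv` gets one row per eta (eta, BIC, number
#' of nonzero loadings, converged).  Numbers are written at 15 significant
#' digits so a round-trip reproduces the estimates to full precision.
#'
#' @param fit An `m2pl_fit` (optionally with a `path` field) or an
#'   `m2pl_path`.
#' @param outdir Output directory (created if needed).
#' @param seed Optional master seed to record in `run.json`.
#' @return `outdir`, invisibly.
#' @export
write_fit <- function(fit, outdir, seed = NULL) {
  if (inherits(fit, "m2pl_path")) {
    path <- fit
    fit <- path$fits[[path$selected]]
    fit$path <- path
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, digits = 15, scientific = TRUE, trim = TRUE)
  wtsv <- function(x, file) utils::write.table(
    matrix(fmt(x), nrow = NROW(x)), file.path(outdir, file),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  wtsv(fit$A, "A.tsv")
  wtsv(fit$b, "b.tsv")
  wtsv(fit$Sigma, "sigma.tsv")
  utils::write.table(fit$Lambda, file.path(outdir, "lambda.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(fit$path)) {
    p <- fit$path
    nz <- vapply(p$fits, function(f)
      if (is.null(f)) NA_integer_ else sum(f$Lambda != 0), integer(1))
    conv <- vapply(p$fits, function(f)
      if (is.null(f)) NA else f$converged, logical(1))
    utils::write.csv(
      data.frame(eta = p$etas, bic = p$bic, n_nonzero = nz, converged = conv),
      file.path(outdir, "path.csv"), row.names = FALSE)
  }
  cfg <- fit$config
  jsonlite::write_json(
    list(N = cfg$N, J = cfg$J, K = cfg$K,
         anchors = list(items = as.integer(names(cfg$anchors)),
                        traits = as.integer(cfg$anchors)),
         eta = fit$eta, bic = fit$bic, loglik = fit$loglik,
         variant = fit$variant, sigma_known = fit$sigma_known,
         n_iter = fit$n_iter, converged = fit$converged,
         warnings = fit$warnings, seed = seed,
         package_version = as.character(utils::packageVersion("iemirt"))),
    file.path(outdir, "run.json"), digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

#' Read a loading matrix written by [write_fit()]
#'
#' @param path Path to `A.tsv` (or any TSV written by [write_fit()]).
#' @return Numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)))
}
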