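## Baseline estimators (constrained exploratory IFA, hard-thresholding
## variants) and the evaluation metrics used in recovery studies.

#' Unpenalized constrained exploratory IFA
#'
#' [em_fit()] with `eta = 0` and the covariance estimated: the anchor
#' constraints still resolve the rotation, but without the penalty the
#' truly-zero loadings come back small-but-nonzero.  This is stage 1 of the
#' two-stage method and the starting point of the thresholding baselines.
#'
#' @inheritParams em_fit
#' @return An `m2pl_fit`.
#' @export
constrained_eifa <- function(Y, config, grid, control = em_control()) {
  em_fit(Y, 0, config, grid, variant = "ieml1", control = control)
}

#' Hard-threshold a loading matrix
#'
#' Free loadings with `|a| < c` are truncated to zero.  Anchor rows are left
#' untouched: their off-trait entries are fixed zeros already and their
#' own-trait loading is exempt from truncation.
#'
#' @param A_hat Estimated J x K loading matrix.
#' @param c Non-negative threshold.
#' @param config An [m2pl_config()] (identifies the anchor rows).
#' @return List with `A` (truncated matrix) and `Lambda` (its support).
#' @export
hard_threshold_estimate <- function(A_hat, c, config) {
  if (c < 0) stop("threshold must be non-negative")
  A <- A_hat
  free <- matrix(TRUE, config$J, config$K)
  free[as.integer(names(config$anchors)), ] <- FALSE
  A[free & abs(A) < c] <- 0
  list(A = A, Lambda = loading_structure(A))
}

#' Exploratory IFA with BIC-optimal hard threshold
#'
#' One unpenalized constrained fit, truncated at each candidate threshold;
#' the BIC of each truncated model (likelihood re-evaluated at the truncated
#' parameters) picks the winner.
#'
#' @inheritParams em_fit
#' @param thresholds Candidate cut-offs (default `seq(0.30, 0.70, by = 0.05)`).
#' @param eifa_fit Optionally, a precomputed [constrained_eifa()] result to
#'   threshold (avoids refitting).
#' @return An `m2pl_fit`-like object for the selected threshold, with extra
#'   fields `threshold`, `thresholds`, `bic_by_threshold` and `eifa` (the
#'   untruncated fit).
#' @export
eifa_opt <- function(Y, config, grid, thresholds = seq(0.30, 0.70, by = 0.05),
                     control = em_control(), eifa_fit = NULL) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  fit0 <- if (is.null(eifa_fit)) constrained_eifa(Y, config, grid, control)
          else eifa_fit
  bics <- numeric(length(thresholds))
  trunc <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    tr <- hard_threshold_estimate(fit0$A, thresholds[i], config)
    cand <- fit0
    cand$A <- tr$A
    cand$Lambda <- tr$Lambda
    cand$loglik <- observed_loglik(tr$A, fit0$b, fit0$Sigma, Y, grid)
    bics[i] <- bic_m2pl(cand, Y, grid)
    cand$bic <- bics[i]
    trunc[[i]] <- cand
  }
  best <- which.min(bics)
  out <- trunc[[best]]
  out$threshold <- thresholds[best]
  out$thresholds <- thresholds
  out$bic_by_threshold <- bics
  out$eifa <- fit0
  out
}

metric_universe <- function(config) {
  free_rows <- matrix(TRUE, config$J, config$K)
  free_rows[as.integer(names(config$anchors)), ] <- FALSE
  free_rows
}

#' Correct rate of structure recovery
#'
#' Proportion of agreement between the estimated and true support patterns
#' over the free entries -- all entries of non-anchor rows; anchor rows are
#' excluded entirely, so with K single anchors the denominator is K(J - K).
#'
#' @param Lambda_hat,Lambda_true J x K binary matrices.
#' @param config An [m2pl_config()].
#' @return Proportion in \[0, 1\].
#' @export
correct_rate <- function(Lambda_hat, Lambda_true, config) {
  if (!all(dim(Lambda_hat) == dim(Lambda_true)))
    stop("shape mismatch")
  u <- metric_universe(config)
  mean((Lambda_hat == Lambda_true)[u])
}

#' False negative rate, false positive rate and precision of the support
#'
#' Computed over the same free-entry universe as [correct_rate()], with
#' "positive" meaning a truly nonzero loading.  Ratios with a zero
#' denominator are returned as `NaN` with `undefined` naming them.
#'
#' @inheritParams correct_rate
#' @return List with `FNR`, `FPR`, `precision`, the confusion counts, and
#'   `undefined` (character vector of undefined metrics).
#' @export
confusion_metrics <- function(Lambda_hat, Lambda_true, config) {
  if (!all(dim(Lambda_hat) == dim(Lambda_true)))
    stop("shape mismatch")
  u <- metric_universe(config)
  hat <- Lambda_hat[u] != 0
  tru <- Lambda_true[u] != 0
  TP <- sum(hat & tru); FN <- sum(!hat & tru)
  FP <- sum(hat & !tru); TN <- sum(!hat & !tru)
  rate <- function(num, den) if (den == 0) NaN else num / den
  out <- list(FNR = rate(FN, FN + TP), FPR = rate(FP, FP + TN),
              precision = rate(TP, TP + FP),
              TP = TP, FN = FN, FP = FP, TN = TN)
  out$undefined <- names(which(vapply(out[c("FNR", "FPR", "precision")],
                                      is.nan, logical(1))))
  out
}

#' Per-parameter mean squared error across replications
#'
#' @param estimates List of replication results; each element a list with
#'   `A` (J x K), `b` (length J) and optionally `Sigma` (K x K).
#' @param truth List with the true `A`, `b`, `Sigma`.
#' @return List with entry-wise MSE matrices `A`, `b`, `Sigma` (off-diagonal
#'   entries only; diagonal is fixed at 1 and reported as 0), the number of
#'   replications `S`, and convenience means `mean_A`, `mean_b`,
#'   `mean_Sigma_offdiag`.
#' @export
mse_report <- function(estimates, truth) {
  S <- length(estimates)
  if (S < 1) stop("need at least one replication")
  mse_A <- Reduce(`+`, lapply(estimates, function(e) (e$A - truth$A)^2)) / S
  mse_b <- Reduce(`+`, lapply(estimates, function(e) (e$b - truth$b)^2)) / S
  has_sigma <- !is.null(estimates[[1]]$Sigma) && !is.null(truth$Sigma)
  mse_S <- NULL
  if (has_sigma) {
    mse_S <- Reduce(`+`, lapply(estimates,
                                function(e) (e$Sigma - truth$Sigma)^2)) / S
    diag(mse_S) <- 0
  }
  K <- ncol(truth$A)
  list(A = mse_A, b = mse_b, Sigma = mse_S, S = S,
       mean_A = mean(mse_A), mean_b = mean(mse_b),
       mean_Sigma_offdiag = if (has_sigma && K > 1)
         mean(mse_S[upper.tri(mse_S) | lower.tri(mse_S)]) else NA_real_)
}
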