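## Model configuration, item parameters and the likelihood / penalized
## objective of the multidimensional two-parameter logistic (M2PL) model.
##
## The model: subject i holds a K-dimensional latent trait theta_i ~ N(0, Sigma)
## with unit-diagonal Sigma; the probability of a positive response to item j is
##   P(y_ij = 1 | theta_i) = plogis(a_j' theta_i + b_j),
## with discrimination (loading) vector a_j and difficulty (intercept) b_j.
## Anchor items are constrained to load on a single pre-specified trait, which
## fixes the rotational indeterminacy of the loading matrix A.

#' Default anchor items for a K-trait design
#'
#' Returns the anchor map used throughout the simulation designs: one anchor
#' item per trait, at the item positions conventional for tests with J = 40
#' items (K = 3: items 1, 10, 19; K = 4: items 1, 7, 13, 19; K = 5: items
#' 1, 5, 9, 13, 17).
#'
#' @param K Number of latent traits (3, 4 or 5 for the canned positions;
#'   otherwise, or whenever the canned positions do not fit into J items,
#'   anchors default to items `1:K`).
#' @param J Number of items (default 40, the standard test length).
#' @return Named integer vector mapping item index (name) to trait index
#'   (value).
#' @export
default_anchors <- function(K, J = 40L) {
  items <- switch(as.character(K),
    "3" = c(1L, 10L, 19L),
    "4" = c(1L, 7L, 13L, 19L),
    "5" = c(1L, 5L, 9L, 13L, 17L),
    seq_len(K))
  if (max(items) > J) items <- seq_len(K)
  stats::setNames(seq_len(K), items)
}

#' M2PL model configuration
#'
#' Bundles the problem dimensions and the anchor-item constraints used for
#' identification.  Each anchor item loads on exactly one trait; all its other
#' loadings are fixed at zero throughout estimation.
#'
#' @param N Number of subjects (positive integer).
#' @param J Number of items.
#' @param K Number of latent traits (`K <= J`).
#' @param anchors Named integer vector: names are item indices, values are the
#'   trait each anchored item measures.  More than one anchor per trait is
#'   allowed (as in confirmatory designations for real questionnaires).
#' @return An object of class `m2pl_config`.
#' @export
m2pl_config <- function(N, J, K, anchors = default_anchors(K, J)) {
  N <- as.integer(N); J <- as.integer(J); K <- as.integer(K)
  if (N < 1L || J < 1L || K < 1L) stop("N, J and K must be positive")
  if (K > J) stop("K must not exceed J")
  items <- as.integer(names(anchors))
  if (length(items) == 0L || anyNA(items))
    stop("'anchors' must be a named vector mapping item index to trait index")
  if (any(items < 1L | items > J)) stop("anchor item index out of range")
  if (anyDuplicated(items)) stop("each anchor item may appear only once")
  traits <- as.integer(anchors)
  if (any(traits < 1L | traits > K)) stop("anchor trait index out of range")
  if (!all(seq_len(K) %in% traits))
    stop("every trait needs at least one anchor item")
  structure(
    list(N = N, J = J, K = K,
         anchors = stats::setNames(traits, items)),
    class = "m2pl_config")
}

#' @export
print.m2pl_config <- function(x, ...) {
  cat(sprintf("M2PL configuration: N = %d subjects, J = %d items, K = %d traits\n",
              x$N, x$J, x$K))
  cat("anchor items (item -> trait): ",
      paste(sprintf("%s->%d", names(x$anchors), x$anchors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fixed-zero constraint mask implied by the anchors
#'
#' @param config An [m2pl_config()].
#' @return J x K logical matrix; `TRUE` marks loadings constrained to be
#'   exactly zero for identification.
#' @export
fixed_zero_mask <- function(config) {
  mask <- matrix(FALSE, config$J, config$K)
  items <- as.integer(names(config$anchors))
  for (idx in seq_along(items)) {
    mask[items[idx], ] <- TRUE
    mask[items[idx], config$anchors[idx]] <- FALSE
  }
  mask
}

check_item_params <- function(A, b, config = NULL) {
  if (!is.matrix(A) || !is.numeric(A)) stop("A must be a numeric matrix")
  if (length(b) != nrow(A)) stop("length(b) must equal nrow(A)")
  if (!all(is.finite(A)) || !all(is.finite(b)))
    stop("item parameters must be finite")
  if (!is.null(config)) {
    if (nrow(A) != config$J || ncol(A) != config$K)
      stop("A has the wrong dimensions for this configuration")
    if (any(A[fixed_zero_mask(config)] != 0))
      stop("anchor-constrained loadings must be exactly zero")
  }
  invisible(TRUE)
}

check_latent_cov <- function(Sigma, tol = 1e-8) {
  if (!is.matrix(Sigma) || nrow(Sigma) != ncol(Sigma))
    stop("Sigma must be a square matrix")
  if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("Sigma must be symmetric")
  if (max(abs(diag(Sigma) - 1)) > 1e-10)
    stop("Sigma must have a unit diagonal")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol) stop("Sigma must be positive definite")
  invisible(TRUE)
}

check_response_matrix <- function(Y) {
  if (!is.matrix(Y)) stop("Y must be a matrix")
  if (anyNA(Y)) stop("Y must not contain missing values")
  if (!all(Y %in% c(0, 1))) stop("Y entries must be 0 or 1")
  cm <- colMeans(Y)
  if (any(cm == 0 | cm == 1))
    warning("some items have constant responses (all 0 or all 1)")
  invisible(TRUE)
}

#' M2PL item response probability
#'
#' Probability of a positive response given trait vector `theta`, computed via
#' the overflow-safe logistic branch (`plogis`), so linear predictors up to
#' |x| = 700 neither overflow nor return NaN.
#'
#' @param a Discrimination vector (length K).
#' @param b Difficulty scalar.
#' @param theta Trait vector (length K) or a matrix with K columns (one row
#'   per evaluation point).
#' @return Probability in (0, 1), vectorized over rows of `theta`.
#' @export
response_prob <- function(a, b, theta) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(theta)))
    stop("response_prob: inputs must be finite")
  if (is.matrix(theta)) {
    stats::plogis(drop(theta %*% a) + b)
  } else {
    stats::plogis(sum(a * theta) + b)
  }
}

## log phi(theta | Sigma) at the rows of X, via the Cholesky factor
log_dmvnorm <- function(X, Sigma) {
  K <- ncol(X)
  R <- chol(Sigma)
  Z <- forwardsolve(t(R), t(X))          # K x G
  -0.5 * (K * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(Z^2))
}

## P x G matrix of log P(y_row | theta_g) for distinct response rows Yd
item_loglik_matrix <- function(Yd, A, b, grid) {
  lp <- grid$points %*% t(A) + rep(b, each = grid$G)   # G x J
  logF <- stats::plogis(lp, log.p = TRUE)
  log1mF <- stats::plogis(-lp, log.p = TRUE)
  Yd %*% t(logF) + (1 - Yd) %*% t(log1mF)
}

#' Observed-data log-likelihood on a quadrature grid
#'
#' The marginal log-likelihood of the binary response matrix, with the
#' integral over the latent traits replaced by a sum over the fixed grid.
#' The prior mass placed on the grid points is normalized to one, so the
#' value is the exact log-likelihood of the grid-discretized latent model
#' (and is invariant to the grid for items with zero loadings).
#'
#' @param A J x K loading matrix.
#' @param b Length-J difficulty vector.
#' @param Sigma K x K unit-diagonal latent covariance.
#' @param Y N x J binary response matrix.
#' @param grid A [build_grid()] object.
#' @return Scalar log-likelihood (always <= 0).
#' @export
observed_loglik <- function(A, b, Sigma, Y, grid) {
  if (is.null(grid) || grid$G < 1L) stop("grid must be non-empty")
  check_item_params(A, b)
  check_latent_cov(Sigma)
  gp <- group_patterns(Y)
  L <- item_loglik_matrix(gp$patterns, A, b, grid)     # P x G
  logphi <- log_dmvnorm(grid$points, Sigma)
  logpi <- logphi - logsumexp(logphi)                  # normalized prior mass
  M <- L + rep(logpi, each = nrow(L))
  rowmax <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  ll_rows <- rowmax + log(rowSums(exp(M - rowmax)))
  sum(gp$counts * ll_rows)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' L1-penalized marginal objective
#'
#' `observed_loglik` minus `eta` times the entry-wise L1 norm of the loading
#' matrix.  Every free loading is penalized, including the anchors' own-trait
#' loadings; loadings fixed at zero contribute nothing.
#'
#' @inheritParams observed_loglik
#' @param eta Non-negative penalty weight (on the raw scale of the objective;
#'   tuning grids such as [eta_grid()] already carry the factor N).
#' @return Scalar penalized objective.
#' @export
penalized_objective <- function(A, b, Sigma, Y, grid, eta) {
  if (length(eta) != 1 || !is.finite(eta) || eta < 0)
    stop("eta must be a non-negative scalar")
  observed_loglik(A, b, Sigma, Y, grid) - eta * sum(abs(A))
}

#' Loading structure (support pattern) of a loading matrix
#'
#' @param A J x K loading matrix.
#' @param tol Threshold; entries with `abs(A) > tol` count as nonzero.  The
#'   default 0 is appropriate because coordinate descent produces exact zeros.
#' @return J x K binary matrix.
#' @export
loading_structure <- function(A, tol = 0) {
  if (tol < 0) stop("tol must be non-negative")
  (abs(A) > tol) * 1L
}
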