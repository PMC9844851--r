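## M-step subproblems: the per-item weighted L1-penalized logistic
## regression (solved in C++ by IRLS + coordinate-wise soft-thresholding)
## and the covariance update under the unit-diagonal positive-definite
## constraint (projected gradient ascent on Q~0).

#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - lam, 0)` -- the proximal map of the L1 penalty used
#' inside the coordinate descent.
#'
#' @param x Numeric.
#' @param lam Non-negative threshold.
#' @return Numeric of the same shape as `x`.
#' @export
soft_threshold <- function(x, lam) {
  if (any(lam < 0)) stop("lam must be non-negative")
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Solve one item's weighted L1-penalized logistic subproblem
#'
#' Maximizes the weighted penalized Bernoulli log-likelihood
#' `sum_r w_r [z_r lp_r - log(1 + exp(lp_r))] - eta * sum(|a|)` over the free
#' coordinates of `a` and the (unpenalized) intercept `b`.  Coordinates in
#' `fixed_zero` are pinned at exactly 0; inactive penalized coordinates come
#' back as exact zeros.  If one response class carries no weight and
#' `eta = 0` the intercept is separated; it is then capped at +/- 30 with a
#' warning.
#'
#' @param design m x K matrix of pseudo-observation covariates (grid points).
#' @param z Length-m 0/1 pseudo-responses.
#' @param w Length-m non-negative weights.
#' @param eta Non-negative penalty weight.
#' @param fixed_zero Length-K logical; `TRUE` pins the coordinate at 0.
#' @param init_a,init_b Warm start.
#' @param control List of solver tolerances, see [em_control()].
#' @return List with `a`, `b`, `objective` (achieved Q~_j), `score` (per
#'   coordinate gradient of the unpenalized part, for KKT checks), `score_b`,
#'   `n_outer`, `converged` and `separated`.
#' @export
fit_item_weighted_l1 <- function(design, z, w, eta, fixed_zero = NULL,
                                 init_a = NULL, init_b = 0,
                                 control = em_control()) {
  K <- ncol(design)
  if (is.null(fixed_zero)) fixed_zero <- rep(FALSE, K)
  if (is.null(init_a)) init_a <- rep(0, K)
  if (eta < 0) stop("eta must be non-negative")
  if (any(w < 0)) stop("weights must be non-negative")
  W1 <- sum(w[z == 1]); W0 <- sum(w[z == 0])
  if (W1 + W0 == 0) stop("all pseudo-observation weights are zero")
  if (W1 == 0 || W0 == 0) {
    ## complete separation of the pseudo-data: the intercept MLE diverges;
    ## clip it at the cap and leave the (penalized) loadings at zero
    b_sep <- if (W0 == 0) control$b_cap else -control$b_cap
    a_sep <- rep(0, K)
    p <- stats::plogis(drop(design %*% a_sep) + b_sep)
    warning("one pseudo-response class has zero weight (separation); ",
            "intercept clipped to ", b_sep)
    return(list(a = a_sep, b = b_sep,
                objective = sum(w * (z * log(p) + (1 - z) * log1p(-p))),
                score = drop(crossprod(design, w * (z - p))),
                score_b = sum(w * (z - p)),
                n_outer = 0L, converged = TRUE, separated = TRUE))
  }
  fit <- cd_logit(design, as.numeric(z), as.numeric(w), eta, !fixed_zero,
                  as.numeric(init_a), init_b,
                  control$cd_tol_coord, control$cd_tol_obj,
                  control$cd_max_outer, control$cd_max_inner, control$b_cap)
  separated <- isTRUE(fit$at_cap)
  if (separated)
    warning("intercept reached the separation cap (|b| = ",
            control$b_cap, ")")
  list(a = as.numeric(fit$a), b = fit$b, objective = fit$objective,
       score = as.numeric(fit$score), score_b = fit$score_b,
       n_outer = fit$n_outer, converged = fit$converged,
       separated = separated)
}

## projection onto {symmetric, eigenvalues >= floor, unit diagonal}
project_unit_corr <- function(M, eig_floor = 1e-6, diag_tol = 1e-10,
                              max_it = 200) {
  M <- (M + t(M)) / 2
  for (it in seq_len(max_it)) {
    e <- eigen(M, symmetric = TRUE)
    vals <- pmax(e$values, eig_floor)
    M <- e$vectors %*% (vals * t(e$vectors))
    M <- (M + t(M)) / 2
    d <- diag(M)
    M <- M / sqrt(outer(d, d))
    M <- (M + t(M)) / 2
    if (max(abs(diag(M) - 1)) < diag_tol &&
        min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >
          eig_floor / 2) break
  }
  diag(M) <- 1
  M
}

#' Covariance update of the M-step
#'
#' Maximizes `Q~0(Sigma) = -(N/2){K log 2 pi + log det Sigma +
#' tr(Sigma^{-1} S*)}` over unit-diagonal positive-definite matrices by
#' projected gradient ascent with Armijo backtracking.  The projection
#' symmetrizes, clips eigenvalues at 1e-6 and rescales to a unit diagonal.
#' Ascent is monotone; iteration stops when the projected gradient (the
#' off-diagonal part, per observation) is below `control$sigma_tol`.
#'
#' @param S_star Scatter matrix (symmetric PSD).
#' @param sigma_init Starting unit-diagonal covariance.
#' @param N Number of subjects.
#' @param control See [em_control()].
#' @return Unit-diagonal positive-definite matrix with attributes
#'   `converged`, `iterations` and `pgrad` (final projected-gradient norm).
#'   A warning is raised on non-convergence and the best iterate returned.
#' @export
update_covariance <- function(S_star, sigma_init, N,
                              control = em_control()) {
  S_star <- (S_star + t(S_star)) / 2
  Sigma <- project_unit_corr(sigma_init)
  ## work with g(Sigma) = log det Sigma + tr(Sigma^{-1} S*)  (minimize)
  gval <- function(S) {
    R <- chol(S)
    2 * sum(log(diag(R))) + sum(chol2inv(R) * S_star)
  }
  g <- gval(Sigma)
  K <- ncol(Sigma)
  converged <- FALSE
  pg_norm <- Inf
  it <- 0L
  step <- 1
  for (it in seq_len(control$sigma_max_iter)) {
    Si <- chol2inv(chol(Sigma))
    Gr <- Si - Si %*% S_star %*% Si      # gradient of g
    Gr <- (Gr + t(Gr)) / 2
    PG <- Gr; diag(PG) <- 0              # tangent to the unit-diagonal constraint
    pg_norm <- max(abs(PG))
    if (pg_norm < control$sigma_tol) { converged <- TRUE; break }
    accepted <- FALSE
    s <- step
    for (h in seq_len(60)) {
      ## step along the tangent component only: under the unit-diagonal
      ## rescaling the full gradient is not a descent direction
      cand <- project_unit_corr(Sigma - s * PG)
      gc <- gval(cand)
      if (gc < g - 1e-12) {
        Sigma <- cand; g <- gc; accepted <- TRUE
        step <- min(s * 2, 1e3)          # mild step growth for the next round
        break
      }
      s <- s / 2
    }
    if (!accepted) { converged <- pg_norm < sqrt(control$sigma_tol); break }
  }
  if (!converged && pg_norm >= control$sigma_tol)
    warning("covariance update stopped before reaching stationarity (|pg| = ",
            format(pg_norm), ")")
  attr(Sigma, "converged") <- converged
  attr(Sigma, "iterations") <- it
  attr(Sigma, "pgrad") <- pg_norm
  Sigma
}

#' KKT check for an item subproblem solution
#'
#' Verifies the subgradient optimality conditions of the weighted
#' L1-penalized logistic objective: `|score_k| <= eta + tol` for zero
#' coordinates, `score_k = sign(a_k) * eta` within `tol` for active ones, and
#' `|score_b| <= tol` for the intercept (unless capped).
#'
#' @param fit Result of [fit_item_weighted_l1()].
#' @param eta Penalty weight the fit used.
#' @param fixed_zero Logical mask of pinned coordinates.
#' @param tol Tolerance (default 1e-6).
#' @return `TRUE` invisibly if all conditions hold; otherwise a character
#'   vector describing the violations, with `ok = FALSE` attribute semantics:
#'   use [kkt_ok()] for a logical summary.
#' @export
kkt_violations <- function(fit, eta, fixed_zero = NULL, tol = 1e-6) {
  K <- length(fit$a)
  if (is.null(fixed_zero)) fixed_zero <- rep(FALSE, K)
  out <- character(0)
  for (k in seq_len(K)) {
    if (fixed_zero[k]) next
    s <- fit$score[k]
    if (fit$a[k] == 0) {
      if (abs(s) > eta + tol)
        out <- c(out, sprintf("coord %d: |score| = %.3g > eta = %.3g", k, abs(s), eta))
    } else if (abs(s - sign(fit$a[k]) * eta) > tol) {
      out <- c(out, sprintf("coord %d: score = %.3g != sign(a)*eta = %.3g",
                            k, s, sign(fit$a[k]) * eta))
    }
  }
  if (!fit$separated && abs(fit$score_b) > tol)
    out <- c(out, sprintf("intercept: |score| = %.3g", abs(fit$score_b)))
  if (length(out) == 0) invisible(TRUE) else out
}

#' @rdname kkt_violations
#' @export
kkt_ok <- function(fit, eta, fixed_zero = NULL, tol = 1e-6) {
  isTRUE(kkt_violations(fit, eta, fixed_zero, tol))
}
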