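## EM orchestration: initialization, the IEML1 / naive EML1 loops, BIC,
## the warm-started tuning path and the two-stage baseline driver.

#' Control parameters for the EM algorithm and its inner solvers
#'
#' @param tol_param EM stops when the largest elementwise change in
#'   (A, b, Sigma) falls below this (default 1e-5) ...
#' @param tol_q ... and the relative change of the surrogate is below this
#'   (default 1e-8).
#' @param max_iter Cap on EM iterations (default 500).
#' @param group Group identical response patterns in the E-step (default
#'   `TRUE`; the naive variant always works on the ungrouped N x G data).
#' @param cd_tol_coord,cd_tol_obj,cd_max_outer,cd_max_inner,b_cap Inner
#'   coordinate-descent tolerances; the defaults are tight enough to support
#'   the 1e-13 cross-variant agreement check.
#' @param sigma_tol,sigma_max_iter Stationarity tolerance (on the projected
#'   gradient of the per-observation Q~0) and iteration cap of the
#'   covariance update.
#' @param verbose Print one line per EM iteration.
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol_param = 1e-5, tol_q = 1e-8, max_iter = 500L,
                       group = TRUE,
                       cd_tol_coord = 1e-14, cd_tol_obj = 1e-15,
                       cd_max_outer = 200L, cd_max_inner = 1000L,
                       b_cap = 30,
                       sigma_tol = 1e-8, sigma_max_iter = 500L,
                       verbose = FALSE) {
  structure(list(tol_param = tol_param, tol_q = tol_q,
                 max_iter = as.integer(max_iter), group = group,
                 cd_tol_coord = cd_tol_coord, cd_tol_obj = cd_tol_obj,
                 cd_max_outer = as.integer(cd_max_outer),
                 cd_max_inner = as.integer(cd_max_inner), b_cap = b_cap,
                 sigma_tol = sigma_tol,
                 sigma_max_iter = as.integer(sigma_max_iter),
                 verbose = verbose),
            class = "em_control")
}

#' Default starting values
#'
#' Anchor items start with a loading of 1 on their own trait (an identity
#' block when there is one anchor per trait), every other free loading starts
#' at 1/J, difficulties at 0, and the latent covariance at the identity.
#'
#' @param config An [m2pl_config()].
#' @return List with `A`, `b`, `Sigma`.
#' @export
default_init <- function(config) {
  A <- matrix(1 / config$J, config$J, config$K)
  A[fixed_zero_mask(config)] <- 0
  items <- as.integer(names(config$anchors))
  A[cbind(items, as.integer(config$anchors))] <- 1
  list(A = A, b = rep(0, config$J), Sigma = diag(config$K))
}

#' Fit a penalized M2PL model by EM
#'
#' Alternates the grid E-step with the per-item penalized logistic M-step and
#' (unless the covariance is fixed) the constrained covariance update, until
#' the parameters and the surrogate stabilize.  The `"ieml1"` variant solves
#' each item subproblem on the 2 x G artificial observations; the `"eml1"`
#' variant solves the identical subproblem on the naive N x G augmented data.
#' Both maximize the same surrogate, so their results agree to numerical
#' precision; `"ieml1"` is the one to use.
#'
#' @param Y N x J binary response matrix.
#' @param eta Penalty weight (raw scale; tuning grids carry the factor N).
#' @param config An [m2pl_config()].
#' @param grid An `m2pl_grid`.
#' @param variant `"ieml1"` (artificial-data M-step) or `"eml1"` (naive).
#' @param sigma_fixed Optional known covariance; when given it is never
#'   updated (the two-stage second stage and variant-comparison mode).
#' @param init Optional list `(A, b, Sigma)` of starting values (warm start).
#' @param structure_zeros Optional J x K logical (or 0/1) matrix of loadings
#'   to pin at zero in addition to the anchor constraints -- a confirmatory
#'   fit at a given loading structure.
#' @param control An [em_control()].
#' @return An object of class `m2pl_fit`: `A`, `b`, `Sigma`, `Lambda`,
#'   `eta`, `bic`, `n_iter`, `converged`, `q_trace` / `q_pre_trace` (the
#'   surrogate after and before each M-step; their difference is the
#'   per-iteration EM ascent, always >= ~-1e-9), `ascent_slack` (the most
#'   negative such increment), `loglik`, `item_scores`/`score_b` (for KKT
#'   checks), `warnings`, plus bookkeeping fields.
#' @export
em_fit <- function(Y, eta, config, grid,
                   variant = c("ieml1", "eml1"),
                   sigma_fixed = NULL, init = NULL,
                   structure_zeros = NULL,
                   control = em_control()) {
  variant <- match.arg(variant)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  check_response_matrix(Y)
  if (nrow(Y) != config$N || ncol(Y) != config$J)
    stop("Y does not match the configuration")
  if (eta < 0) stop("eta must be non-negative")
  mask <- fixed_zero_mask(config)
  if (!is.null(structure_zeros)) {
    if (!all(dim(structure_zeros) == dim(mask)))
      stop("structure_zeros must be J x K")
    mask <- mask | (structure_zeros != 0)
  }
  sigma_known <- !is.null(sigma_fixed)
  if (sigma_known) check_latent_cov(sigma_fixed)

  state <- if (is.null(init)) default_init(config) else init
  A <- state$A; b <- state$b
  Sigma <- if (sigma_known) sigma_fixed else state$Sigma
  A[mask] <- 0
  N <- config$N; J <- config$J; K <- config$K; G <- grid$G

  group <- if (variant == "eml1") FALSE else control$group
  if (variant == "eml1") {
    X_naive <- grid$points[rep(seq_len(G), times = N), , drop = FALSE]
  }
  X_art <- rbind(grid$points, grid$points)
  z_art <- c(rep(1, G), rep(0, G))

  q_trace <- q_pre_trace <- numeric(0)
  ascent_slack <- Inf
  warns <- character(0)
  converged <- FALSE
  q_prev <- NA_real_
  item_scores <- matrix(NA_real_, J, K)
  score_b <- rep(NA_real_, J)
  separated <- rep(FALSE, J)

  for (iter in seq_len(control$max_iter)) {
    post <- posterior_table(Y, A, b, Sigma, grid, group = group)
    art <- artificial_weights(Y, post)
    S_star <- scatter_matrix(post, grid)
    q_pre <- q_components(A, b, Sigma, art, S_star, grid, eta)$total

    A_old <- A; b_old <- b; Sigma_old <- Sigma

    if (!sigma_known) {
      Sigma <- withCallingHandlers(
        update_covariance(S_star, Sigma, N, control),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      attributes(Sigma) <- attributes(Sigma)["dim"]
    }

    qj_sum <- 0
    for (j in seq_len(J)) {
      if (variant == "ieml1") {
        wj <- c(art$w[j, "1", ], art$w[j, "0", ])
        Xj <- X_art; zj <- z_art
      } else {
        wj <- as.vector(t(post$weights))
        Xj <- X_naive
        zj <- rep(post$patterns[, j], each = G)
      }
      fit_j <- withCallingHandlers(
        fit_item_weighted_l1(Xj, zj, wj, eta, fixed_zero = mask[j, ],
                             init_a = A[j, ], init_b = b[j],
                             control = control),
        warning = function(w) {
          warns <<- c(warns, paste0("item ", j, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      A[j, ] <- fit_j$a
      b[j] <- fit_j$b
      item_scores[j, ] <- fit_j$score
      score_b[j] <- fit_j$score_b
      separated[j] <- fit_j$separated
      qj_sum <- qj_sum + fit_j$objective
    }

    q_post <- q0_value(Sigma, S_star, N) + qj_sum
    inc <- q_post - q_pre
    ascent_slack <- min(ascent_slack, inc)
    if (inc < -1e-6)
      stop(sprintf("EM surrogate decreased by %.3g at iteration %d", -inc, iter))
    q_trace <- c(q_trace, q_post)
    q_pre_trace <- c(q_pre_trace, q_pre)

    ## Sigma rows/columns of a "dead" trait (no nonzero loadings anywhere)
    ## do not enter the likelihood; exclude them from the convergence test
    ## instead of chasing their grid-truncation drift
    dSigma <- abs(Sigma - Sigma_old)
    dead <- colSums(abs(A)) == 0
    if (any(dead)) {
      dSigma[dead, ] <- 0
      dSigma[, dead] <- 0
    }
    delta <- max(abs(A - A_old), abs(b - b_old), dSigma)
    rel_q <- if (is.na(q_prev)) Inf else
      abs(q_post - q_prev) / (abs(q_prev) + 1)
    if (control$verbose)
      message(sprintf("iter %3d  Q = %.8f  max|dPsi| = %.2e", iter, q_post, delta))
    q_prev <- q_post
    if (delta < control$tol_param && rel_q < control$tol_q) {
      converged <- TRUE
      break
    }
    ## all-zero loadings are an exact stationary point at which the latent
    ## covariance drops out of the likelihood; once A and b have settled
    ## there, iterating Sigma only chases grid-truncation noise
    if (all(A[!mask] == 0) &&
        max(abs(A - A_old), abs(b - b_old)) < control$tol_param) {
      converged <- TRUE
      warns <- c(warns,
                 "all free loadings shrunk to zero; Sigma is not identified at this eta")
      break
    }
  }

  dead <- which(colSums(abs(A)) == 0)
  if (!sigma_known && length(dead))
    warns <- c(warns, paste0("trait(s) ", paste(dead, collapse = ", "),
                             " have no nonzero loadings; their covariance entries are not identified"))

  ## resolve sign indeterminacy: reflect any trait whose (first) anchor
  ## loading came out negative
  items <- as.integer(names(config$anchors))
  for (k in seq_len(K)) {
    anchor_k <- items[match(k, as.integer(config$anchors))]
    if (A[anchor_k, k] < 0) {
      A[, k] <- -A[, k]
      if (K > 1) {
        Sigma[k, -k] <- -Sigma[k, -k]
        Sigma[-k, k] <- -Sigma[-k, k]
      }
    }
  }

  fit <- structure(
    list(A = A, b = b, Sigma = Sigma,
         Lambda = loading_structure(A),
         eta = eta, n_iter = length(q_trace), converged = converged,
         q_trace = q_trace, q_pre_trace = q_pre_trace,
         ascent_slack = ascent_slack,
         item_scores = item_scores, score_b = score_b,
         separated = separated,
         variant = variant, sigma_known = sigma_known,
         config = config, warnings = unique(warns)),
    class = "m2pl_fit")
  fit$loglik <- observed_loglik(A, b, Sigma, Y, grid)
  fit$bic <- bic_m2pl(fit, Y, grid)
  if (!converged)
    fit$warnings <- c(fit$warnings,
                      sprintf("EM stopped at the %d-iteration cap", control$max_iter))
  fit
}

#' @export
print.m2pl_fit <- function(x, ...) {
  cat(sprintf("penalized M2PL fit (%s): N = %d, J = %d, K = %d\n",
              x$variant, x$config$N, x$config$J, x$config$K))
  cat(sprintf("eta = %g, BIC = %.2f, log-lik = %.2f, %d EM iterations%s\n",
              x$eta, x$bic, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("nonzero loadings: %d of %d free entries\n",
              sum(x$Lambda[!fixed_zero_mask(x$config)]),
              sum(!fixed_zero_mask(x$config))))
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Bayesian information criterion of a fitted model
#'
#' `-2 * loglik + d * log(N)` where the degrees of freedom `d` count the
#' nonzero free loadings, plus the J difficulties, plus the K(K-1)/2 free
#' covariance entries when Sigma was estimated.  Both counts are
#' conventions; they can be switched off.
#'
#' @param fit An `m2pl_fit`.
#' @param Y,grid Data and grid on which to (re-)evaluate the likelihood; if
#'   `fit$loglik` is present it is reused.
#' @param count_difficulty Include the J difficulty parameters in d.
#' @param count_sigma Include K(K-1)/2 covariance parameters; defaults to
#'   whether Sigma was estimated.
#' @return Scalar BIC.
#' @export
bic_m2pl <- function(fit, Y, grid, count_difficulty = TRUE,
                     count_sigma = NULL) {
  ll <- if (!is.null(fit$loglik)) fit$loglik else
    observed_loglik(fit$A, fit$b, fit$Sigma, Y, grid)
  cfg <- fit$config
  if (is.null(count_sigma)) count_sigma <- !isTRUE(fit$sigma_known)
  free <- !fixed_zero_mask(cfg)
  d <- sum(fit$Lambda[free] != 0) +
    (if (count_difficulty) cfg$J else 0L) +
    (if (count_sigma) cfg$K * (cfg$K - 1) / 2 else 0L)
  -2 * ll + d * log(cfg$N)
}

#' Fit a tuning path and select eta by BIC
#'
#' Fits are run from the largest to the smallest eta.  By default every eta
#' is fitted from the same default starting values, matching the standard
#' protocol; with `warm_start = TRUE` each fit is seeded by the previous
#' solution (a degenerate all-zero fit never seeds the next one, since the
#' all-zero saddle is stationary at every smaller eta).  The selected fit
#' attains the minimum BIC; exact ties break toward the larger eta (the
#' sparser model).
#'
#' @param Y,config,grid,variant,sigma_fixed,control As in [em_fit()].
#' @param etas Candidate penalty weights, e.g. [eta_grid()].
#' @param warm_start Seed each fit with the previous solution instead of
#'   cold-starting (default `FALSE`: the marginal problem is nonconvex and a
#'   partially collapsed warm start can drag the rest of the path into a
#'   poorer stationary point).
#' @param bic `"refit"` (default) evaluates each candidate's BIC at an
#'   unpenalized confirmatory refit on the selected support, so the
#'   criterion judges the structure rather than the shrinkage; `"shrunk"`
#'   plugs the penalized estimates straight into the likelihood.  The
#'   shrunk version decreases essentially monotonically in eta (small eta
#'   buys back shrinkage bias on every true loading), which drives
#'   selection to the densest candidate; the refit version reproduces the
#'   interior BIC minima this method is known for.
#' @return An object of class `m2pl_path`: `etas` (descending), `fits`,
#'   `bic`, `selected` (index), `errors` (per-eta error messages, if any).
#'   With `bic = "refit"` each fit also carries a `refit` element (the
#'   confirmatory refit) and `bic_shrunk` keeps the plug-in values.
#' @export
fit_path <- function(Y, etas, config, grid, variant = "ieml1",
                     sigma_fixed = NULL, control = em_control(),
                     warm_start = FALSE, bic = c("refit", "shrunk")) {
  bic <- match.arg(bic)
  if (length(etas) == 0) stop("etas must be non-empty")
  etas <- sort(as.numeric(etas), decreasing = TRUE)
  fits <- vector("list", length(etas))
  errors <- rep(NA_character_, length(etas))
  init <- NULL
  for (i in seq_along(etas)) {
    res <- tryCatch(
      em_fit(Y, etas[i], config, grid, variant = variant,
             sigma_fixed = sigma_fixed, init = init, control = control),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      if (bic == "refit") res <- add_refit_bic(res, Y, config, grid,
                                               sigma_fixed, control)
      fits[[i]] <- res
      if (warm_start)
        init <- if (all(res$A[!fixed_zero_mask(config)] == 0)) NULL
                else list(A = res$A, b = res$b, Sigma = res$Sigma)
    }
  }
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$bic,
                 numeric(1))
  if (all(is.na(bics))) stop("every fit along the path failed")
  selected <- which(bics == min(bics, na.rm = TRUE))[1]   # first = largest eta
  structure(list(etas = etas, fits = fits, bic = bics,
                 selected = selected, errors = errors, bic_type = bic),
            class = "m2pl_path")
}

## replace a path fit's BIC by the refit version: unpenalized EM constrained
## to the fit's support, warm-started at the fit (an all-zero fit needs no
## refit -- nothing was shrunk)
add_refit_bic <- function(fit, Y, config, grid, sigma_fixed, control) {
  fit$bic_shrunk <- fit$bic
  if (all(fit$Lambda[!fixed_zero_mask(config)] == 0)) return(fit)
  rf <- em_fit(Y, 0, config, grid, variant = fit$variant,
               sigma_fixed = sigma_fixed,
               init = list(A = fit$A, b = fit$b, Sigma = fit$Sigma),
               structure_zeros = fit$Lambda == 0, control = control)
  fit$refit <- list(A = rf$A, b = rf$b, Sigma = rf$Sigma,
                    loglik = rf$loglik, converged = rf$converged)
  tmp <- fit
  tmp$loglik <- rf$loglik
  fit$bic <- bic_m2pl(tmp, Y, grid)
  fit
}

#' @export
print.m2pl_path <- function(x, ...) {
  cat("BIC tuning path:\n")
  nz <- vapply(x$fits, function(f)
    if (is.null(f)) NA_integer_ else sum(f$Lambda != 0), integer(1))
  tab <- data.frame(eta = x$etas, BIC = x$bic, nonzero = nz)
  tab$selected <- ifelse(seq_along(x$etas) == x$selected, "*", "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Two-stage estimation
#'
#' Stage 1 estimates the latent covariance by an unpenalized constrained
#' exploratory IFA ([constrained_eifa()]); stage 2 runs the penalized BIC
#' path with that covariance held fixed.  Used as the comparison baseline:
#' its covariance estimate inherits all of stage 1's error.
#'
#' @param Y,etas,config,grid,control,bic As in [fit_path()].
#' @return The selected stage-2 `m2pl_fit`, with extra fields `stage1` (the
#'   unpenalized fit whose `Sigma` was substituted) and `path`.
#' @export
two_stage_fit <- function(Y, etas, config, grid, control = em_control(),
                          bic = c("refit", "shrunk")) {
  stage1 <- constrained_eifa(Y, config, grid, control = control)
  path <- fit_path(Y, etas, config, grid, variant = "ieml1",
                   sigma_fixed = stage1$Sigma, control = control,
                   bic = bic)
  fit <- path$fits[[path$selected]]
  fit$stage1 <- stage1
  fit$path <- path
  fit
}
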