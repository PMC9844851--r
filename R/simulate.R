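## Synthetic data generation for parameter-recovery studies, and the weight
## diagnostics that motivate the reduced quadrature grids.
##
## The simulation world: J = 40 items measuring K in {3, 4, 5} correlated
## traits; nonzero loadings drawn i.i.d. U(0.5, 2); difficulties N(0, 1);
## latent covariance with unit diagonal and all off-diagonals 0.1; one
## anchor item per trait at the conventional positions (see
## [default_anchors()]).

#' Simulation design configuration
#'
#' @param N Number of subjects.
#' @param J Number of items (default 40).
#' @param K Number of traits (default 3; designs are tuned for 3-5).
#' @param off_diag Common off-diagonal of the true latent covariance
#'   (default 0.1).
#' @param structure `"block"` for the default block-sparse pattern (see
#'   [loading_pattern()]), or a user-supplied J x K binary matrix whose
#'   anchor rows must load only on their own trait.
#' @param seed Integer seed; every draw from this configuration is
#'   reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N, J = 40L, K = 3L, off_diag = 0.1,
                       structure = "block", seed = 1L) {
  anchors <- default_anchors(K, J)
  if (is.matrix(structure)) {
    if (nrow(structure) != J || ncol(structure) != K)
      stop("structure must be J x K")
    items <- as.integer(names(anchors))
    for (i in seq_along(items)) {
      want <- as.integer(seq_len(K) == anchors[i])
      if (!all(structure[items[i], ] == want))
        stop("structure violates the anchor constraints")
    }
  }
  structure(list(N = as.integer(N), J = as.integer(J), K = as.integer(K),
                 off_diag = off_diag, structure = structure,
                 anchors = anchors, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default block-sparse loading pattern
#'
#' Items are split into K consecutive segments starting at the anchor
#' positions; every item in segment s loads on trait s, and the last two
#' non-anchor items of each segment additionally load on the next trait
#' (cyclically), so the selection problem includes cross-loading items.
#'
#' @param J,K Dimensions.
#' @param anchors Anchor map as in [default_anchors()].
#' @return J x K binary matrix.
#' @export
loading_pattern <- function(J, K, anchors = default_anchors(K)) {
  items <- sort(as.integer(names(anchors)))
  Lambda <- matrix(0L, J, K)
  bounds <- c(items, J + 1L)
  for (s in seq_len(K)) {
    seg <- seq(bounds[s], bounds[s + 1] - 1L)
    Lambda[seg, s] <- 1L
    non_anchor <- setdiff(seg, items)
    cross <- utils::tail(non_anchor, 2L)
    Lambda[cross, (s %% K) + 1L] <- 1L
  }
  for (i in seq_along(items))
    Lambda[items[i], ] <- as.integer(seq_len(K) == anchors[as.character(items[i])])
  Lambda
}

#' Draw a true model from a simulation design
#'
#' @param cfg A [sim_config()].
#' @return A list of class `m2pl_true_model` with `A`, `b`, `Sigma`,
#'   `Lambda`, `anchors`, `config` (the matching [m2pl_config()]) and
#'   `seed`.
#' @export
generate_true_model <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  Lambda <- if (is.matrix(cfg$structure)) (cfg$structure != 0) * 1L
            else loading_pattern(cfg$J, cfg$K, cfg$anchors)
  set.seed(cfg$seed)
  A <- matrix(0, cfg$J, cfg$K)
  nz <- which(Lambda != 0)
  A[nz] <- stats::runif(length(nz), 0.5, 2)
  b <- stats::rnorm(cfg$J)
  Sigma <- matrix(cfg$off_diag, cfg$K, cfg$K)
  diag(Sigma) <- 1
  structure(list(A = A, b = b, Sigma = Sigma, Lambda = Lambda,
                 anchors = cfg$anchors,
                 config = m2pl_config(cfg$N, cfg$J, cfg$K, cfg$anchors),
                 seed = cfg$seed),
            class = "m2pl_true_model")
}

#' Simulate binary responses from a true model
#'
#' Latent traits are drawn from N(0, Sigma); responses are conditionally
#' independent Bernoulli draws with the M2PL probabilities.
#'
#' @param model An `m2pl_true_model` (or any list with `A`, `b`, `Sigma`).
#' @param N Number of subjects.
#' @param seed Integer seed.
#' @return N x J binary matrix.
#' @export
generate_responses <- function(model, N, seed) {
  set.seed(seed)
  K <- ncol(model$A)
  Theta <- matrix(stats::rnorm(N * K), N, K) %*% chol(model$Sigma)
  P <- stats::plogis(Theta %*% t(model$A) + rep(model$b, each = N))
  matrix(stats::rbinom(length(P), 1L, P), nrow(P), ncol(P))
}

#' Serialize / restore a true model as JSON
#'
#' @param model An `m2pl_true_model`.
#' @param path File path.
#' @return `write_true_model` returns `path` invisibly; `read_true_model`
#'   returns the model.
#' @export
write_true_model <- function(model, path) {
  jsonlite::write_json(
    list(A = model$A, b = model$b, Sigma = model$Sigma,
         Lambda = model$Lambda,
         anchors = list(items = as.integer(names(model$anchors)),
                        traits = as.integer(model$anchors)),
         seed = model$seed),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_true_model
#' @export
read_true_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  anchors <- stats::setNames(as.integer(x$anchors$traits),
                             as.integer(x$anchors$items))
  structure(list(A = as.matrix(x$A), b = as.numeric(x$b),
                 Sigma = as.matrix(x$Sigma), Lambda = as.matrix(x$Lambda),
                 anchors = anchors, seed = x$seed),
            class = "m2pl_true_model")
}

#' Weight-concentration diagnostics for the artificial data
#'
#' Sorts the 2 x G artificial weights of one item in descending order and
#' reports how much of the total mass (= N) the largest m carry, plus the
#' smallest axis-aligned box \[-c, c\]^K containing the grid points of the
#' top-m weights -- the empirical basis for replacing Grid11 with the
#' reduced Grid7 / Grid5 sets.
#'
#' @param art An [artificial_weights()] object.
#' @param item Item index.
#' @param grid The grid the weights live on.
#' @param m Number of top weights to summarize (default `2 * G`, i.e. all).
#' @return List with `sorted` (descending weights), `cumulative` (cumulative
#'   fractions of the total, ending at 1), `top_m`, `top_share`, `box_c`
#'   (half-width of the covering box) and `top_points` (grid points of the
#'   top-m weights).
#' @export
weight_diagnostics <- function(art, item, grid, m = NULL) {
  if (item < 1 || item > art$J) stop("invalid item index")
  w <- c(art$r[item, ], art$f - art$r[item, ])   # z = 1 block then z = 0 block
  pts <- rbind(grid$points, grid$points)
  ord <- order(w, decreasing = TRUE)
  sorted <- w[ord]
  total <- sum(sorted)
  cumulative <- cumsum(sorted) / total
  if (is.null(m)) m <- length(w)
  m <- min(m, length(w))
  top_points <- pts[ord[seq_len(m)], , drop = FALSE]
  list(sorted = sorted, cumulative = cumulative,
       top_m = m, top_share = cumulative[m],
       box_c = max(abs(top_points)), top_points = top_points)
}

#' Derive a per-replication seed from a master seed
#'
#' Fixed-offset streams keep replications independent and individually
#' reproducible; the result stays inside the 32-bit integer range.
#'
#' @param master Master seed (integer).
#' @param r Replication number (1, 2, ...).
#' @return Integer seed.
#' @export
replication_seed <- function(master, r) {
  as.integer((as.numeric(master) + 104729 * as.numeric(r)) %% 2147483647L)
}
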