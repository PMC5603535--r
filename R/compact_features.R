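# Compact feature learning: each node's diffusion states across all
# networks of a collection are concatenated and reduced to a low-dimensional
# feature vector by truncated SVD of the elementwise log of the concatenated
# diffusion matrix. The rank-d factor X = U_d * sqrt(Sigma_d) is the node
# feature matrix; by Eckart-Young it minimizes the Frobenius reconstruction
# error of the log-diffusion matrix among rank-d factorizations.

#' Concatenate diffusion states across networks
#'
#' @param states list of n x n diffusion-state matrices over the same node
#'   registry, in collection order.
#' @return n x (k*n) matrix of the horizontally concatenated states.
#' @export
concat_states <- function(states) {
  stopifnot(length(states) > 0)
  n <- nrow(states[[1]])
  for (s in states)
    if (!all(dim(s) == c(n, n)))
      stop("diffusion states differ in shape")
  do.call(cbind, lapply(states, unclass))
}

# deterministic SVD sign convention: the largest-magnitude entry of each
# left singular vector is made positive (ties broken by first index)
.fix_svd_signs <- function(sv) {
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

#' Learn compact features from concatenated diffusion states
#'
#' Computes `L = log(concat + log_offset)` and its rank-`d` truncated SVD
#' `L ~ U_d Sigma_d V_d'`; the feature matrix is `X = U_d Sigma_d^{1/2}`.
#' The log transform turns the multiplicative structure of diffusion
#' probabilities into additive structure, and the offset bounds the log of
#' near-zero diffusion mass. Singular vectors follow a fixed sign convention
#' (largest-magnitude entry positive) so results are reproducible across
#' numerics backends.
#'
#' @param concat nonnegative matrix from [concat_states()].
#' @param d target dimension; must not exceed the numerical rank of `L`.
#' @param log_offset small positive constant added before the log;
#'   default `1/nrow(concat)`.
#' @return n x d feature matrix with attributes `d`, `log_offset`,
#'   `singular_values` and `context` (the matching factor
#'   `V_d Sigma_d^{1/2}`, so `X %*% t(context)` reconstructs `L`).
#' @export
compact_learn <- function(concat, d, log_offset = 1 / nrow(concat)) {
  if (any(concat < 0)) stop("diffusion matrix must be nonnegative")
  if (d < 1) stop("d must be >= 1")
  if (log_offset <= 0) stop("log_offset must be positive")
  L <- log(concat + log_offset)
  sv <- .fix_svd_signs(svd(L))
  rank <- sum(sv$d > max(dim(L)) * .Machine$double.eps * sv$d[1])
  if (d > rank)
    stop("d = ", d, " exceeds the numerical rank of the log-diffusion ",
         "matrix; the achievable maximum is ", rank)
  scale <- sqrt(sv$d[seq_len(d)])
  X <- sv$u[, seq_len(d), drop = FALSE] %*% diag(scale, d)
  rownames(X) <- rownames(concat)
  structure(X, d = d, log_offset = log_offset,
            singular_values = sv$d[seq_len(d)],
            context = sv$v[, seq_len(d), drop = FALSE] %*% diag(scale, d))
}

#' Diffuse a network collection and learn node features
#'
#' Composition of [diffuse_collection()], [concat_states()] and
#' [compact_learn()]. When `d` exceeds what the collection supports
#' (at most n), it is lowered with a warning; the value actually used is
#' recorded in the result's attributes together with all hyperparameters.
#'
#' @param coll ordered named list of square nonnegative matrices over one
#'   node type.
#' @param d requested feature dimension.
#' @param restart_prob,tol,max_iter RWR parameters, see [rwr()].
#' @param log_offset see [compact_learn()]; default `1/n`.
#' @return n x d feature matrix with provenance attributes
#'   (`source_networks`, `restart_prob`, `d`, `log_offset`).
#' @export
learn_features <- function(coll, d, restart_prob = 0.5, tol = 1e-8,
                           max_iter = 1000L, log_offset = NULL) {
  states <- diffuse_collection(coll, restart_prob, tol, max_iter)
  concat <- concat_states(states)
  if (is.null(log_offset)) log_offset <- 1 / nrow(concat)
  d_max <- min(dim(concat))
  if (d > d_max) {
    warning("feature dimension lowered from ", d, " to ", d_max,
            " (collection of ", nrow(concat), " nodes)", call. = FALSE)
    d <- d_max
  }
  # the numerical rank can fall below min(dim); lower d further if needed
  X <- tryCatch(compact_learn(concat, d, log_offset), error = function(e) {
    rank <- as.integer(sub(".*achievable maximum is ", "",
                           conditionMessage(e)))
    if (is.na(rank)) stop(e)
    warning("feature dimension lowered from ", d, " to the numerical rank ",
            rank, call. = FALSE)
    compact_learn(concat, rank, log_offset)
  })
  attr(X, "source_networks") <- names(coll)
  attr(X, "restart_prob") <- restart_prob
  X
}
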