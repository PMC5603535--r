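# Random walk with restart (RWR) on each network of a collection. Row i of
# the resulting diffusion-state matrix S is the stationary distribution of a
# walker that follows edges with probability 1 - restart_prob and teleports
# back to node i with probability restart_prob; it encodes node i's
# topological context in that network.

#' Row-normalize a nonnegative matrix into a transition matrix
#'
#' Rows with positive sum are divided by their sum; all-zero (dangling) rows
#' are replaced by the uniform distribution 1/n so the result is exactly
#' row-stochastic.
#'
#' @param A square nonnegative matrix.
#' @return row-stochastic matrix of the same dimension.
#' @export
row_normalize <- function(A) {
  if (any(A < 0)) stop("matrix has negative entries")
  n <- ncol(A)
  rs <- rowSums(A)
  W <- A / ifelse(rs > 0, rs, 1)
  if (any(rs == 0)) W[rs == 0, ] <- 1 / n
  W
}

#' Random walk with restart
#'
#' Iterates `S <- (1 - p) * S %*% W + p * I` from `S = I` until the largest
#' per-row L1 change drops below `tol`, so row i of the result is the RWR
#' stationary distribution started at node i. At convergence S solves
#' `S = p * solve(I - (1 - p) W)` (the closed form used as an oracle in the
#' test suite).
#'
#' @param W row-stochastic transition matrix (see [row_normalize()]).
#' @param restart_prob restart probability p in (0, 1\]; `p = 1` returns the
#'   identity (pure restart).
#' @param tol convergence tolerance on the per-row L1 change.
#' @param max_iter iteration cap; hitting it raises a convergence warning.
#' @return the diffusion-state matrix S with attributes `iterations`,
#'   `converged` and `restart_prob`. Every row sums to 1.
#' @export
rwr <- function(W, restart_prob = 0.5, tol = 1e-8, max_iter = 1000L) {
  if (!is.numeric(restart_prob) || restart_prob < 0 || restart_prob > 1)
    stop("restart_prob must lie in (0, 1]")
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (max(abs(rowSums(W) - 1)) > 1e-6)
    stop("W is not row-stochastic; apply row_normalize() first")
  p <- restart_prob
  S <- diag(n)
  converged <- FALSE
  it <- 0L
  restart <- p * diag(n)
  while (it < max_iter) {
    it <- it + 1L
    S_new <- (1 - p) * (S %*% W) + restart
    delta <- max(rowSums(abs(S_new - S)))
    S <- S_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("RWR did not converge within ", max_iter,
            " iterations (last per-row L1 change ",
            format(delta, digits = 3), ")", call. = FALSE)
  dimnames(S) <- dimnames(W)
  structure(S, iterations = it, converged = converged,
            restart_prob = p)
}

#' Diffuse every network of a collection
#'
#' Applies [row_normalize()] followed by [rwr()] to each network, preserving
#' collection order. Errors and convergence warnings are tagged with the
#' network's name.
#'
#' @param coll ordered named list of square nonnegative matrices (one side
#'   of [build_collections()]).
#' @inheritParams rwr
#' @return named list of diffusion-state matrices in collection order.
#' @export
diffuse_collection <- function(coll, restart_prob = 0.5, tol = 1e-8,
                               max_iter = 1000L) {
  stopifnot(length(coll) > 0)
  out <- vector("list", length(coll))
  names(out) <- names(coll)
  for (nm in names(coll)) {
    out[[nm]] <- withCallingHandlers(
      rwr(row_normalize(coll[[nm]]), restart_prob, tol, max_iter),
      warning = function(w) {
        warning("network '", nm, "': ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      },
      error = function(e) stop("network '", nm, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}
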