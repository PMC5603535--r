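# Low-rank bilinear projection from drug feature space onto protein feature
# space, fitted against the known interaction matrix P in the style of
# inductive matrix completion: P ~ X Z Y' with Z = F G' of rank k, learned
# by alternating ridge-regularized least squares. Scoring a pair (i, j) is
# the bilinear form x_i' Z y_j, i.e. the proximity of protein j's feature
# vector to the projected feature vector of drug i.

# Solve the Sylvester-type normal equation  (A'A) F (B'B) + lambda F = M
# via eigendecompositions of the two symmetric Gram matrices.
.ridge_bilinear_solve <- function(ea, BtB, M, lambda) {
  eb <- eigen(BtB, symmetric = TRUE)
  denom <- outer(ea$values, eb$values) + lambda
  if (any(denom <= .Machine$double.eps))
    stop("degenerate normal equations (lambda too small for a ",
         "rank-deficient factor); raise reg_lambda", call. = FALSE)
  Mt <- crossprod(ea$vectors, M %*% eb$vectors)
  ea$vectors %*% (Mt / denom) %*% t(eb$vectors)
}

#' Fit the low-rank bilinear projection by alternating least squares
#'
#' Minimizes `||P - X F G' Y'||_F^2 + lambda (||F||_F^2 + ||G||_F^2)` over
#' the rank-`k` factor pair (F, G) of the projection matrix `Z = F G'`.
#' Each alternating substep solves its ridge normal equations exactly (via
#' eigendecomposition of the Gram matrices), so the objective is
#' non-increasing across iterations; this is asserted on the recorded trace.
#' With the default `loss = "full"` every entry of the binary `P`
#' contributes to the squared loss, i.e. unobserved pairs are treated as
#' zeros. `loss = "masked"` restricts the loss to the entries flagged in
#' `mask` and handles the rest by EM-style imputation from the current fit
#' (a majorize-minimize scheme, so the masked objective is also
#' non-increasing).
#'
#' @param X drug feature matrix (n_drug x d_drug), see [learn_features()].
#' @param Y protein feature matrix (n_protein x d_protein).
#' @param P binary known-interaction matrix (n_drug x n_protein).
#' @param k rank of the projection, `k <= min(d_drug, d_protein)`.
#' @param reg_lambda ridge penalty `lambda >= 0`; with `lambda = 0` and
#'   rank-deficient features the solve is refused with guidance to raise it.
#' @param iters maximum number of alternating iterations.
#' @param seed seed for the Gaussian initialization (scaled by
#'   `1/sqrt(k)`).
#' @param tol stop when the relative objective change falls below this.
#' @param loss `"full"` (default) or `"masked"`.
#' @param mask binary matrix of observed entries, required for
#'   `loss = "masked"`.
#' @return object of class `dti_projection`: list with factors `F`, `G`,
#'   `k`, `reg_lambda`, `seed`, `loss`, and `objective_trace` (value at
#'   initialization plus one value per iteration).
#' @export
fit_projection <- function(X, Y, P, k = min(50L, ncol(X), ncol(Y)),
                           reg_lambda = 1, iters = 100L, seed = 0L,
                           tol = 1e-6, loss = c("full", "masked"),
                           mask = NULL) {
  loss <- match.arg(loss)
  X <- unclass(X); Y <- unclass(Y); P <- unclass(P)
  if (nrow(P) != nrow(X) || ncol(P) != nrow(Y))
    stop("P must be n_drug x n_protein matching the feature matrices")
  if (!all(P %in% c(0, 1))) stop("P must be binary {0,1}")
  if (k < 1 || k > min(ncol(X), ncol(Y)))
    stop("k must lie in [1, min(d_drug, d_protein)]")
  if (reg_lambda < 0) stop("reg_lambda must be >= 0")
  if (reg_lambda == 0 && k >= min(ncol(X), ncol(Y)))
    warning("k at the feature dimension with reg_lambda = 0: the solution ",
            "is not unique", call. = FALSE)
  if (loss == "masked") {
    if (is.null(mask)) stop("loss = 'masked' requires a mask matrix")
    stopifnot(all(dim(mask) == dim(P)), all(mask %in% c(0, 1)))
  }

  set.seed(seed)
  Fm <- matrix(stats::rnorm(ncol(X) * k), ncol(X), k) / sqrt(k)
  Gm <- matrix(stats::rnorm(ncol(Y) * k), ncol(Y), k) / sqrt(k)

  XtX <- crossprod(X); YtY <- crossprod(Y)
  ex <- eigen(XtX, symmetric = TRUE)
  ey <- eigen(YtY, symmetric = TRUE)

  objective <- function(Fm, Gm, P_ref) {
    R <- P_ref - X %*% Fm %*% crossprod(Gm, t(Y))
    if (loss == "masked") R <- R * mask
    sum(R^2) + reg_lambda * (sum(Fm^2) + sum(Gm^2))
  }

  P_work <- P
  trace <- objective(Fm, Gm, P)
  for (it in seq_len(iters)) {
    if (loss == "masked") {
      S_hat <- X %*% Fm %*% crossprod(Gm, t(Y))
      P_work <- mask * P + (1 - mask) * S_hat
    }
    XtPY <- crossprod(X, P_work %*% Y)
    # F-substep: columns of the protein side held fixed at B = Y G
    Fm <- .ridge_bilinear_solve(ex, crossprod(Gm, YtY %*% Gm),
                                XtPY %*% Gm, reg_lambda)
    # G-substep: drug side held fixed at A = X F
    Gm <- .ridge_bilinear_solve(ey, crossprod(Fm, XtX %*% Fm),
                                crossprod(XtPY, Fm), reg_lambda)
    obj <- objective(Fm, Gm, P)
    if (!is.finite(obj))
      stop("objective became non-finite; with reg_lambda = 0 the solve ",
           "can degenerate - raise reg_lambda", call. = FALSE)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(prev - obj) < tol * max(prev, .Machine$double.eps)) break
  }
  structure(list(F = Fm, G = Gm, k = k, reg_lambda = reg_lambda,
                 seed = seed, loss = loss, objective_trace = trace),
            class = "dti_projection")
}

#' @export
print.dti_projection <- function(x, ...) {
  tr <- x$objective_trace
  cat(sprintf(paste0("Bilinear projection model: rank %d, lambda %g, ",
                     "%s loss\n  objective %.4g -> %.4g over %d ",
                     "iteration(s)\n"),
              x$k, x$reg_lambda, x$loss, tr[1], tr[length(tr)],
              length(tr) - 1L))
  invisible(x)
}

#' Score all drug-protein pairs
#'
#' Computes the full score matrix `S_hat = X F G' Y'` of the fitted
#' projection; no thresholding is applied.
#'
#' @param X,Y feature matrices used for (or compatible with) the fit.
#' @param model a `dti_projection` from [fit_projection()].
#' @return n_drug x n_protein numeric score matrix (dimnames carried over
#'   from the feature matrices).
#' @export
score_all <- function(X, Y, model) {
  stopifnot(inherits(model, "dti_projection"))
  if (ncol(X) != nrow(model$F) || ncol(Y) != nrow(model$G))
    stop("feature dimensions do not match the fitted factors")
  S <- unclass(X) %*% model$F %*% crossprod(model$G, t(unclass(Y)))
  if (!is.null(rownames(X)) || !is.null(rownames(Y)))
    dimnames(S) <- list(rownames(X), rownames(Y))
  S
}

#' Rank target candidates for one drug
#'
#' Orders the proteins by descending score for the given drug; ties are
#' broken by ascending protein registry index so rankings are deterministic.
#' With `exclude_known`, proteins already interacting with the drug in
#' `train_P` are removed from the candidate list.
#'
#' @param S_hat score matrix from [score_all()].
#' @param drug drug identifier (rowname) or row index.
#' @param exclude_known drop known training interactions of this drug.
#' @param train_P binary training interaction matrix (required when
#'   `exclude_known`).
#' @return data.frame with columns `protein`, `score`, `rank`.
#' @export
rank_targets <- function(S_hat, drug, exclude_known = FALSE,
                         train_P = NULL) {
  if (is.character(drug)) {
    i <- match(drug, rownames(S_hat))
    if (is.na(i)) stop("unknown drug id '", drug, "'")
  } else {
    i <- drug
    if (i < 1 || i > nrow(S_hat)) stop("drug index out of range")
  }
  s <- S_hat[i, ]
  keep <- seq_along(s)
  if (exclude_known) {
    if (is.null(train_P)) stop("exclude_known requires train_P")
    keep <- which(train_P[i, ] == 0)
  }
  ord <- keep[order(-s[keep], keep)]
  prot <- colnames(S_hat)
  if (is.null(prot)) prot <- as.character(seq_len(ncol(S_hat)))
  data.frame(protein = prot[ord], score = unname(s[ord]),
             rank = seq_along(ord))
}
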