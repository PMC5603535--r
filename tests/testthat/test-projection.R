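# helpers reproducing the model pieces independently of the implementation

als_init <- function(d1, d2, k, seed) {
  set.seed(seed)
  list(F = matrix(rnorm(d1 * k), d1, k) / sqrt(k),
       G = matrix(rnorm(d2 * k), d2, k) / sqrt(k))
}

# brute-force ridge solve of one ALS substep via the Kronecker normal
# equations: minimize ||P - X F B'||^2 + lambda ||F||^2 over F
kron_substep <- function(X, B, P, lambda) {
  K <- kronecker(B, X)
  f <- solve(crossprod(K) + lambda * diag(ncol(K)), crossprod(K, c(P)))
  matrix(f, ncol(X), ncol(B))
}

planted_instance <- function(seed = 21, n_d = 20, n_p = 15, d = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n_d * d), n_d, d)
  Y <- matrix(rnorm(n_p * d), n_p, d)
  Zs <- matrix(rnorm(d * 2), d, 2) %*% t(matrix(rnorm(d * 2), d, 2))
  S <- X %*% Zs %*% t(Y)
  P <- (S >= quantile(S, 0.85)) * 1
  list(X = X, Y = Y, P = P)
}

# a planted model whose thresholded interaction matrix is *exactly*
# representable at rank 2: fully expressive (identity) features and a
# rank-2 bilinear score built from two disjoint blocks
exact_planted_instance <- function(n_d = 20, n_p = 15) {
  u1 <- as.numeric(seq_len(n_d) <= 7);  v1 <- as.numeric(seq_len(n_p) <= 5)
  u2 <- as.numeric(seq_len(n_d) > 13);  v2 <- as.numeric(seq_len(n_p) > 10)
  Zs <- 2 * (u1 %o% v1 + u2 %o% v2)
  P <- (Zs >= 1) * 1
  list(X = diag(n_d), Y = diag(n_p), P = P)
}

test_that("each ALS substep solves its ridge normal equations exactly", {
  set.seed(20)
  X <- matrix(rnorm(5 * 3), 5, 3)
  Y <- matrix(rnorm(4 * 3), 4, 3)
  P <- matrix(rbinom(20, 1, 0.3), 5, 4)
  lam <- 0.7
  m <- fit_projection(X, Y, P, k = 2, reg_lambda = lam, iters = 1L,
                      seed = 9)
  init <- als_init(3, 3, 2, seed = 9)
  F1 <- kron_substep(X, Y %*% init$G, P, lam)
  expect_equal(m$F, F1, tolerance = 1e-8)
  G1 <- kron_substep(Y, X %*% F1, t(P), lam)
  expect_equal(m$G, G1, tolerance = 1e-8)
})

test_that("the objective trace never increases", {
  inst <- planted_instance()
  for (seed in c(0, 1, 2)) {
    m <- fit_projection(inst$X, inst$Y, inst$P, k = 2, reg_lambda = 0.1,
                        iters = 50L, seed = seed)
    expect_true(all(diff(m$objective_trace) <= 1e-9))
  }
})

test_that("a planted rank-2 model is driven far below its initial objective", {
  inst <- exact_planted_instance()
  m <- fit_projection(inst$X, inst$Y, inst$P, k = 2, reg_lambda = 1e-6,
                      iters = 200L, seed = 3)
  tr <- m$objective_trace
  expect_lt(tr[length(tr)], 1e-3 * tr[1])
})

test_that("an all-zero interaction matrix yields a vanishing score matrix", {
  set.seed(22)
  X <- matrix(rnorm(12), 6, 2)
  Y <- matrix(rnorm(10), 5, 2)
  m <- fit_projection(X, Y, matrix(0, 6, 5), k = 2, reg_lambda = 1,
                      iters = 20L, seed = 1)
  expect_lt(max(abs(score_all(X, Y, m))), 1e-6)
})

test_that("scores are the exact bilinear form", {
  m <- structure(list(F = diag(3), G = diag(3), k = 3L, reg_lambda = 0,
                      seed = 0L, loss = "full", objective_trace = 0),
                 class = "dti_projection")
  expect_equal(score_all(diag(3), diag(3), m), diag(3))
  set.seed(23)
  X <- matrix(rnorm(18), 6, 3); Y <- matrix(rnorm(15), 5, 3)
  Fm <- matrix(rnorm(6), 3, 2); Gm <- matrix(rnorm(6), 3, 2)
  m2 <- structure(list(F = Fm, G = Gm, k = 2L, reg_lambda = 0, seed = 0L,
                       loss = "full", objective_trace = 0),
                  class = "dti_projection")
  expect_equal(score_all(X, Y, m2), X %*% Fm %*% t(Gm) %*% t(Y),
               tolerance = 1e-10)
  expect_equal(score_all(2 * X, Y, m2), 2 * score_all(X, Y, m2))
})

test_that("target ranking is deterministic with registry-index tie-breaks", {
  S <- matrix(c(0.9, 0.1, 0.9), 1, 3,
              dimnames = list("d1", c("p0", "p1", "p2")))
  r <- rank_targets(S, "d1")
  expect_equal(r$protein, c("p0", "p2", "p1"))
  expect_equal(r$rank, 1:3)
  train <- matrix(c(1, 0, 0), 1, 3)
  r2 <- rank_targets(S, "d1", exclude_known = TRUE, train_P = train)
  expect_false("p0" %in% r2$protein)
  expect_error(rank_targets(S, "nope"), "unknown drug")
})

test_that("stronger regularization shrinks the projection matrix", {
  inst <- planted_instance()
  nrm <- sapply(c(0.1, 10, 1000), function(lam) {
    m <- fit_projection(inst$X, inst$Y, inst$P, k = 2, reg_lambda = lam,
                        iters = 50L, seed = 1)
    sqrt(sum((m$F %*% t(m$G))^2))
  })
  expect_true(all(diff(nrm) < 0))
})

test_that("the fitted scores do not depend on the random initialization", {
  inst <- planted_instance()
  ms <- lapply(c(4, 5), function(seed)
    fit_projection(inst$X, inst$Y, inst$P, k = 2, reg_lambda = 0.1,
                   iters = 500L, seed = seed, tol = 1e-14))
  S1 <- score_all(inst$X, inst$Y, ms[[1]])
  S2 <- score_all(inst$X, inst$Y, ms[[2]])
  expect_lt(max(abs(S1 - S2)), 1e-4)
})

test_that("masked loss decreases its own objective and fits the mask", {
  inst <- planted_instance()
  mask <- matrix(rbinom(length(inst$P), 1, 0.6), nrow(inst$P))
  m <- fit_projection(inst$X, inst$Y, inst$P, k = 2, reg_lambda = 0.1,
                      iters = 50L, seed = 1, loss = "masked", mask = mask)
  expect_true(all(diff(m$objective_trace) <= 1e-9))
})

test_that("degenerate unregularized solves are refused with guidance", {
  X <- cbind(1:4, 1:4)  # rank-deficient features
  Y <- matrix(rnorm(8), 4, 2)
  P <- matrix(rbinom(16, 1, 0.4), 4, 4)
  suppressWarnings(
    expect_error(fit_projection(X, Y, P, k = 2, reg_lambda = 0,
                                iters = 5L, seed = 1),
                 "reg_lambda"))
})

test_that("a planted-model fit recovers most planted partners at rank 1", {
  g <- synth_fixture(0)
  P <- g$network$relations$drug_protein
  m <- fit_projection(g$truth$U, g$truth$V, P, k = 4, reg_lambda = 0.1,
                      iters = 100L, seed = 1)
  S <- score_all(g$truth$U, g$truth$V, m)
  dimnames(S) <- dimnames(P) <- list(g$network$nodes$drug,
                                     g$network$nodes$protein)
  planted <- P
  planted[g$truth$held_out] <- 1  # held-out planted pairs count as planted
  has_target <- which(rowSums(P) > 0)
  hit <- vapply(has_target, function(i) {
    top <- rank_targets(S, i)$protein[1]
    planted[i, top] == 1
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
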