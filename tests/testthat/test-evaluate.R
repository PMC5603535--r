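make_P <- function(n_d, n_p, n_pos, seed = 1) {
  set.seed(seed)
  P <- matrix(0, n_d, n_p)
  P[sample(n_d * n_p, n_pos)] <- 1
  P
}

test_that("ten-fold matched splits have the prescribed shape", {
  P <- make_P(20, 20, 100)
  splits <- make_cv_splits(P, 10, "matched", seed = 4)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_equal(nrow(sp$test_pos), 10)
    expect_equal(nrow(sp$test_neg), 10)
    expect_equal(nrow(sp$train_pos), 90)
    # positives split disjointly; negatives never overlap known positives
    expect_equal(P[sp$test_pos], rep(1, 10))
    expect_equal(P[sp$test_neg], rep(0, 10))
    both <- rbind(sp$train_pos, sp$test_pos)
    expect_equal(nrow(unique(both)), 100)
  }
})

test_that("skewed negative policies size the negative set correctly", {
  P <- make_P(20, 20, 40)
  sp9 <- make_cv_splits(P, 10, "ratio9", seed = 2)
  for (sp in sp9) expect_equal(nrow(sp$test_neg), 9 * nrow(sp$test_pos))
  spall <- make_cv_splits(P, 10, "all", seed = 2)
  for (sp in spall) expect_equal(nrow(sp$test_neg), 400 - 40)
  # infeasible ratio reports the counts
  dense <- make_P(4, 4, 14)
  expect_error(make_cv_splits(dense, 2, "ratio9", seed = 1),
               "needs .* negatives")
})

test_that("splits are reproducible from the seed", {
  P <- make_P(15, 12, 30)
  s1 <- make_cv_splits(P, 5, "matched", seed = 7)
  s2 <- make_cv_splits(P, 5, "matched", seed = 7)
  expect_identical(s1, s2)
  s3 <- make_cv_splits(P, 5, "matched", seed = 8)
  expect_false(identical(s1, s3))
})

test_that("redundancy filtering removes pairs tied to the training set", {
  # 4 drugs x 4 proteins; protein 1 is redundant with protein 2
  P <- matrix(0, 4, 4)
  P[1, 1] <- P[2, 2] <- P[3, 3] <- P[4, 4] <- 1
  split <- structure(list(
    fold_id = 1L,
    train_pos = cbind(c(2L, 3L), c(2L, 3L)),
    test_pos = cbind(c(1L, 4L), c(1L, 4L)),
    test_neg = cbind(c(1L, 2L), c(4L, 1L)),
    neg_policy = "matched", seed = 0L, filter_log = list()),
    class = "eval_split")
  scores <- diag(4)
  scores[1, 2] <- scores[2, 1] <- 0.9  # proteins 1 and 2 homologous
  g <- build_redundancy_graph(scores, 0.4, "protein", "seq_identity")
  out <- apply_redundancy_filter(split, list(g), mode = "protein")
  # test pair (1,1): protein 1 adjacent to train protein 2 -> removed
  expect_equal(out$test_pos, cbind(4L, 4L), ignore_attr = TRUE)
  # negative (2,1) has protein 1 too
  expect_equal(out$test_neg, cbind(1L, 4L), ignore_attr = TRUE)
  expect_equal(out$filter_log[[1]]$removed_pos, 1)
  # an empty redundancy graph changes nothing
  g0 <- build_redundancy_graph(diag(4), 0.5, "protein")
  out0 <- apply_redundancy_filter(split, list(g0), mode = "protein")
  expect_equal(out0$test_pos, split$test_pos)
  expect_equal(out0$test_neg, split$test_neg)
})

test_that("redundancy filtering agrees with an exhaustive pair scan", {
  set.seed(31)
  for (rep in 1:20) {
    n_d <- 8; n_p <- 7
    P <- make_P(n_d, n_p, 12, seed = 100 + rep)
    split <- make_cv_splits(P, 3, "matched", seed = rep)[[1]]
    sd_ <- matrix(runif(n_d^2), n_d); sd_ <- (sd_ + t(sd_)) / 2
    sp_ <- matrix(runif(n_p^2), n_p); sp_ <- (sp_ + t(sp_)) / 2
    gd <- build_redundancy_graph(sd_, 0.8, "drug", "tanimoto")
    gp <- build_redundancy_graph(sp_, 0.8, "protein", "seq_identity")
    out <- apply_redundancy_filter(split, list(gd, gp), mode = "either")
    # oracle: scan every test pair against every train positive
    keep_oracle <- function(pairs) {
      keep <- rep(TRUE, nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        for (j in seq_len(nrow(split$train_pos))) {
          if (gd[pairs[i, 1], split$train_pos[j, 1]] == 1 ||
              gp[pairs[i, 2], split$train_pos[j, 2]] == 1)
            keep[i] <- FALSE
        }
      }
      pairs[keep, , drop = FALSE]
    }
    expect_equal(out$test_pos, keep_oracle(split$test_pos))
    expect_equal(out$test_neg, keep_oracle(split$test_neg))
  }
})

test_that("AUROC matches exhaustive concordant-pair counting", {
  expect_equal(auroc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  pair_count_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(33)
  for (rep in 1:25) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2)  # rounding forces ties
    expect_equal(auroc(s, y), pair_count_auc(s, y))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "one positive and one negative")
})

test_that("AUROC agrees with an established external implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  for (rep in 1:10) {
    y <- c(1, 0, rbinom(30, 1, 0.3))
    s <- rnorm(32)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("AUPR matches the step-sum oracle", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # step-sum oracle by direct enumeration over distinct thresholds
  step_aupr <- function(s, y) {
    th <- sort(unique(s), decreasing = TRUE)
    prev_rec <- 0; area <- 0
    for (t in th) {
      tp <- sum(y == 1 & s >= t); fp <- sum(y == 0 & s >= t)
      rec <- tp / sum(y == 1); prec <- tp / (tp + fp)
      area <- area + (rec - prev_rec) * prec
      prev_rec <- rec
    }
    area
  }
  set.seed(35)
  for (rep in 1:25) {
    y <- c(1, 0, rbinom(30, 1, 0.3))
    s <- round(runif(32), 2)
    expect_equal(aupr(s, y), step_aupr(s, y))
  }
})

test_that("recall at k matches manual enumeration on a small instance", {
  ranked <- list(d1 = c("p1", "p2", "p3", "p4", "p5", "p6"),
                 d2 = c("p6", "p5", "p4", "p3", "p2", "p1"),
                 d3 = c("p2", "p1", "p4", "p3", "p6", "p5"),
                 d4 = c("p3", "p6", "p1", "p2", "p5", "p4"))
  truth <- list(d1 = c("p1", "p3"),  # ranks 1 and 3
                d2 = "p1",           # rank 6
                d3 = "p4",           # rank 3
                d4 = character(0))   # no held-out targets
  r <- recall_at_k(ranked, truth, k = c(1, 2, 3, 5, 6))
  expect_equal(unname(r), c(1, 1, 3, 3, 4) / 4)
  expect_true(all(diff(r) >= 0))
  # truth at rank 3: in at k = 5, out at k = 2
  r2 <- recall_at_k(ranked["d3"], truth["d3"], k = c(2, 5))
  expect_equal(unname(r2), c(0, 1))
  # macro averaging weights drugs, not pairs
  rm <- recall_at_k(ranked, truth, k = 3, macro = TRUE)
  expect_equal(unname(rm), mean(c(1, 0, 1)))
  expect_error(recall_at_k(ranked, truth, k = 0), "k must be")
})

test_that("network perturbation moves exactly the requested edge count", {
  net <- synth_fixture(0)$network
  edges0 <- hetdti:::.non_dti_edges(net)
  n0 <- nrow(edges0)
  del <- perturb_network(net, 0.10, "delete", seed = 5)
  expect_equal(nrow(hetdti:::.non_dti_edges(del)), n0 - round(0.1 * n0))
  add <- perturb_network(net, 0.10, "add", seed = 5)
  expect_equal(nrow(hetdti:::.non_dti_edges(add)), n0 + round(0.1 * n0))
  # additions never duplicate existing edges: all original edges remain
  key <- function(e) paste(e$relation, e$i, e$j)
  expect_true(all(key(edges0) %in% key(hetdti:::.non_dti_edges(add))))
  # the interaction matrix is never touched
  expect_equal(del$relations$drug_protein, net$relations$drug_protein)
  expect_equal(add$relations$drug_protein, net$relations$drug_protein)
  # determinism
  expect_identical(perturb_network(net, 0.1, "mixed", seed = 9),
                   perturb_network(net, 0.1, "mixed", seed = 9))
  expect_error(perturb_network(net, 1.2), "fraction")
})

test_that("degradation removes the requested fraction and 0 is a no-op", {
  net <- synth_fixture(0)$network
  n0 <- nrow(hetdti:::.non_dti_edges(net))
  deg <- degrade_network(net, 0.2, seed = 3)
  expect_equal(nrow(hetdti:::.non_dti_edges(deg)), n0 - round(0.2 * n0))
  expect_identical(degrade_network(net, 0), net)
})

test_that("singleton evaluation selects exactly the single-target drugs", {
  g <- synth_fixture(0)
  net <- g$network
  P <- net$relations$drug_protein
  singles <- sum(rowSums(P) == 1)
  se <- singleton_eval(net, desk_cfg(0), k = c(1, 4, 40))
  expect_equal(se$n_singletons, singles)
  expect_length(se$ranks, singles)
  expect_equal(unname(se$recall_at_k["k40"]), 1)  # every rank <= n_protein
  # planted signal beats the uniform-random baseline at k = 4 of 40
  expect_gt(se$recall_at_k[["k4"]], 4 / 40)
  # a network with no singleton drugs yields an empty report
  net2 <- net
  net2$relations$drug_protein <- matrix(0, nrow(P), ncol(P))
  net2$relations$drug_protein[, 1:2] <- 1  # every drug has two targets
  expect_warning(se2 <- singleton_eval(net2, desk_cfg(0)),
                 "no singleton")
  expect_equal(se2$n_singletons, 0L)
})

test_that("named-pair hold-outs train on everything else", {
  net <- toy_network()
  P <- net$relations$drug_protein
  sp <- holdout_split(P, data.frame(drug = "D2", protein = "P2"))
  expect_equal(sp$test_pos, cbind(2L, 2L), ignore_attr = TRUE)
  expect_equal(nrow(sp$train_pos), sum(P) - 1)
  expect_error(holdout_split(P, data.frame(drug = "DX", protein = "P1")),
               "unknown")
})
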