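# Evaluation protocols for bipartite link prediction: cross-validation with
# matched or skewed negative sampling, redundancy-aware filtering of the
# test set, ranking metrics (AUROC, AUPR, recall@k), singleton-drug
# hold-outs, a generic named-pair hold-out, and the edge-perturbation
# robustness experiment.

# ---- splits ---------------------------------------------------------------

#' Build cross-validation splits over a binary interaction matrix
#'
#' Partitions the known positives of `P` into `n_folds` disjoint test sets;
#' each fold's negatives are drawn uniformly without replacement from the
#' non-interacting pairs, with size set by the policy: `"matched"` samples
#' as many negatives as test positives, `"ratio9"` nine times as many
#' (positives are then 10% of the test set), `"all"` takes every
#' non-interacting pair. Fully reproducible from `seed`.
#'
#' @param P binary drug x protein interaction matrix.
#' @param n_folds number of folds (default 10).
#' @param neg_policy `"matched"`, `"ratio9"` or `"all"`.
#' @param seed integer seed.
#' @return list of `eval_split` objects; each holds the 2-column index
#'   matrices `train_pos`, `test_pos`, `test_neg`, plus `fold_id`,
#'   `neg_policy`, `seed` and an (initially empty) `filter_log`.
#' @export
make_cv_splits <- function(P, n_folds = 10L, neg_policy = c("matched",
                                                            "ratio9",
                                                            "all"),
                           seed = 0L) {
  neg_policy <- match.arg(neg_policy)
  stopifnot(all(P %in% c(0, 1)))
  pos <- which(P == 1, arr.ind = TRUE)
  neg <- which(P == 0, arr.ind = TRUE)
  dimnames(pos) <- dimnames(neg) <- NULL
  if (nrow(pos) < n_folds)
    stop("need at least ", n_folds, " positives, have ", nrow(pos))
  set.seed(seed)
  perm <- sample.int(nrow(pos))
  fold_of <- rep(seq_len(n_folds), length.out = nrow(pos))[order(perm)]
  lapply(seq_len(n_folds), function(f) {
    test_pos <- pos[fold_of == f, , drop = FALSE]
    n_neg <- switch(neg_policy,
                    matched = nrow(test_pos),
                    ratio9 = 9L * nrow(test_pos),
                    all = nrow(neg))
    if (n_neg > nrow(neg))
      stop("negative policy '", neg_policy, "' needs ", n_neg,
           " negatives but only ", nrow(neg), " non-interacting pairs exist")
    test_neg <- neg[sample.int(nrow(neg), n_neg), , drop = FALSE]
    structure(list(fold_id = f,
                   train_pos = pos[fold_of != f, , drop = FALSE],
                   test_pos = test_pos,
                   test_neg = test_neg,
                   neg_policy = neg_policy,
                   seed = seed,
                   filter_log = list()),
              class = "eval_split")
  })
}

#' Remove redundancy-inflated pairs from a test split
#'
#' Drops from the test set (positives and sampled negatives) every pair
#' whose drug -- or protein, or either, depending on `mode` -- is adjacent
#' in a redundancy graph to a drug (protein) occurring in a training
#' positive. This mirrors the protocol of excluding test interactions whose
#' drug is chemically similar (e.g. Tanimoto > 60%) or whose protein is
#' homologous (sequence identity > 40%) to the training data, which would
#' otherwise inflate cross-validation performance.
#'
#' @param split an `eval_split` from [make_cv_splits()].
#' @param graphs list of [build_redundancy_graph()] objects.
#' @param mode `"drug"`, `"protein"` or `"either"`.
#' @return the filtered `eval_split`; removals are appended to
#'   `filter_log`.
#' @export
apply_redundancy_filter <- function(split, graphs,
                                    mode = c("either", "drug", "protein")) {
  mode <- match.arg(mode)
  if (inherits(graphs, "redundancy_graph")) graphs <- list(graphs)
  flag_nodes <- function(type, train_ids) {
    gs <- Filter(function(g) attr(g, "node_type") == type, graphs)
    if (!length(gs) || !length(train_ids)) return(integer(0))
    bad <- logical(nrow(gs[[1]]))
    for (g in gs)
      bad <- bad | rowSums(g[, train_ids, drop = FALSE] != 0) > 0
    which(bad)
  }
  bad_drugs <- flag_nodes("drug", unique(split$train_pos[, 1]))
  bad_prots <- flag_nodes("protein", unique(split$train_pos[, 2]))
  hit <- function(pairs) switch(mode,
    drug = pairs[, 1] %in% bad_drugs,
    protein = pairs[, 2] %in% bad_prots,
    either = pairs[, 1] %in% bad_drugs | pairs[, 2] %in% bad_prots)
  drop_pos <- hit(split$test_pos)
  drop_neg <- hit(split$test_neg)
  split$filter_log <- c(split$filter_log, list(list(
    mode = mode,
    criteria = vapply(graphs, attr, character(1), "criterion"),
    removed_pos = sum(drop_pos), removed_neg = sum(drop_neg))))
  split$test_pos <- split$test_pos[!drop_pos, , drop = FALSE]
  split$test_neg <- split$test_neg[!drop_neg, , drop = FALSE]
  split
}

#' Hold out a named list of drug-protein pairs
#'
#' Generic splitter for externally defined hold-outs (e.g. interactions
#' discovered after the training database snapshot): the named pairs become
#' the test positives and every remaining known interaction trains the
#' model.
#'
#' @param P binary interaction matrix with dimnames.
#' @param pairs data.frame with columns `drug` and `protein` (ids).
#' @return an `eval_split` with `neg_policy = "none"` and empty `test_neg`.
#' @export
holdout_split <- function(P, pairs) {
  di <- match(pairs$drug, rownames(P))
  pi <- match(pairs$protein, colnames(P))
  if (anyNA(di) || anyNA(pi))
    stop("unknown drug or protein id in hold-out pair list")
  test_pos <- cbind(di, pi)
  dimnames(test_pos) <- NULL
  pos <- which(P == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  is_test <- paste(pos[, 1], pos[, 2]) %in% paste(di, pi)
  structure(list(fold_id = 1L, train_pos = pos[!is_test, , drop = FALSE],
                 test_pos = test_pos,
                 test_neg = matrix(integer(0), 0, 2),
                 neg_policy = "none", seed = NA_integer_,
                 filter_log = list()),
            class = "eval_split")
}

# ---- metrics --------------------------------------------------------------

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC; tied scores contribute 1/2, so a
#' constant score vector yields 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC needs at least one positive and one negative")
  r <- rank(scores)  # average ranks implement the tie = 1/2 convention
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function area: thresholds sweep the distinct score values from high
#' to low, and each recall increment contributes the precision attained at
#' that threshold (no interpolation between points). Tied scores enter the
#' ranking as one block.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0)
    stop("AUPR needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  block_end <- which(!duplicated(s, fromLast = TRUE))  # last index per value
  tp <- cum_tp[block_end]; n <- cum_n[block_end]
  prec <- tp / n
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Micro-averaged recall at top-k
#'
#' Fraction of held-out true targets retrieved within each drug's top-k
#' predictions, micro-averaged over all held-out pairs (the default), or
#' macro-averaged per drug.
#'
#' @param ranked named list: for each drug, its candidate proteins in rank
#'   order (ids or indices), with training positives already excluded.
#' @param truth named list of the held-out true targets per drug (same id
#'   space as `ranked`).
#' @param k integer vector of cut-offs.
#' @param macro average per drug instead of per pair.
#' @return named numeric vector, one recall per `k`, non-decreasing in `k`.
#' @export
recall_at_k <- function(ranked, truth, k, macro = FALSE) {
  if (any(k < 1)) stop("k must be >= 1")
  drugs <- names(truth)[lengths(truth) > 0]
  stopifnot(all(drugs %in% names(ranked)))
  out <- vapply(sort(unique(as.integer(k))), function(kk) {
    per_drug <- vapply(drugs, function(d) {
      hits <- sum(truth[[d]] %in% utils::head(ranked[[d]], kk))
      c(hits, length(truth[[d]]))
    }, numeric(2))
    if (macro) mean(per_drug[1, ] / per_drug[2, ])
    else sum(per_drug[1, ]) / sum(per_drug[2, ])
  }, numeric(1))
  stats::setNames(out, paste0("k", sort(unique(as.integer(k)))))
}

# ---- pipeline-level protocols --------------------------------------------

# shared heavy part of the pipeline: features are learned from the side
# networks only, so they are computed once per network and reused across
# folds; only the projection is refit per training matrix.
pipeline_features <- function(net, cfg) {
  coll <- build_collections(net, cfg$networks)
  if (length(coll$drug) == 0 || length(coll$protein) == 0)
    stop("both a drug-side and a protein-side network are required")
  X <- learn_features(coll$drug, cfg$dim_drug, cfg$restart_prob, cfg$tol,
                      cfg$max_iter, cfg$log_offset)
  Y <- learn_features(coll$protein, cfg$dim_protein, cfg$restart_prob,
                      cfg$tol, cfg$max_iter, cfg$log_offset)
  list(X = X, Y = Y)
}

score_split <- function(feats, P, split, cfg) {
  P_train <- P
  P_train[split$test_pos] <- 0
  model <- fit_projection(feats$X, feats$Y, P_train, cfg$k, cfg$lambda,
                          cfg$iters, seed = cfg$seed + split$fold_id,
                          loss = cfg$loss,
                          mask = if (cfg$loss == "masked") P_train * 0 + 1)
  S_hat <- score_all(feats$X, feats$Y, model)
  list(scores = c(S_hat[split$test_pos], S_hat[split$test_neg]),
       labels = rep(c(1, 0), c(nrow(split$test_pos),
                               nrow(split$test_neg))),
       S_hat = S_hat)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Learns features once from the side networks (which do not involve the
#' interaction matrix), then for every fold refits the projection on the
#' training positives and scores the held-out pairs. Metrics can be
#' averaged over several trials with re-sampled folds and negatives.
#'
#' @param net a validated `hetnet`.
#' @param cfg a [pipeline_config()].
#' @param n_folds,neg_policy,trials protocol parameters; defaults from
#'   `cfg`.
#' @param redundancy_graphs optional list of redundancy graphs applied to
#'   every fold via [apply_redundancy_filter()].
#' @param filter_mode see [apply_redundancy_filter()].
#' @return data.frame with one row per trial x fold (`trial`, `fold`,
#'   `auroc`, `aupr`, `n_pos`, `n_neg`) and a `summary` attribute with mean
#'   and SD of both metrics.
#' @export
evaluate_cv <- function(net, cfg = pipeline_config(),
                        n_folds = cfg$folds, neg_policy = cfg$neg_policy,
                        trials = cfg$trials, redundancy_graphs = NULL,
                        filter_mode = "either") {
  feats <- pipeline_features(net, cfg)
  P <- net$relations$drug_protein
  rows <- list()
  for (tr in seq_len(trials)) {
    splits <- make_cv_splits(P, n_folds, neg_policy,
                             seed = cfg$seed + 101L * tr)
    for (split in splits) {
      if (!is.null(redundancy_graphs))
        split <- apply_redundancy_filter(split, redundancy_graphs,
                                         filter_mode)
      if (nrow(split$test_pos) == 0 || nrow(split$test_neg) == 0) next
      sc <- score_split(feats, P, split, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(trial = tr, fold = split$fold_id,
                   auroc = auroc(sc$scores, sc$labels),
                   aupr = aupr(sc$scores, sc$labels),
                   n_pos = nrow(split$test_pos),
                   n_neg = nrow(split$test_neg))
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "summary") <- c(auroc_mean = mean(res$auroc),
                            auroc_sd = stats::sd(res$auroc),
                            aupr_mean = mean(res$aupr),
                            aupr_sd = stats::sd(res$aupr))
  res
}

#' Singleton-drug hold-out evaluation
#'
#' For every drug with exactly one known interacting target, that single
#' interaction is held out, the projection is refit without it, and the
#' rank of the true target among the drug's candidates is recorded. This is
#' the hard repositioning case: the held-out drug has no training targets
#' left at all.
#'
#' @param net a validated `hetnet`.
#' @param cfg a [pipeline_config()].
#' @param k cut-offs for the recall curve (default 1..n_protein).
#' @return list with `n_singletons`, per-drug `ranks` (named integer
#'   vector) and `recall_at_k`; empty report with a warning when the
#'   network has no singleton drugs.
#' @export
singleton_eval <- function(net, cfg = pipeline_config(), k = NULL) {
  P <- net$relations$drug_protein
  singles <- which(rowSums(P) == 1)
  if (length(singles) == 0) {
    warning("network has no singleton drugs", call. = FALSE)
    return(list(n_singletons = 0L, ranks = integer(0),
                recall_at_k = numeric(0)))
  }
  if (is.null(k)) k <- seq_len(ncol(P))
  feats <- pipeline_features(net, cfg)
  ranks <- vapply(singles, function(i) {
    j <- which(P[i, ] == 1)
    split <- structure(list(fold_id = i,
                            test_pos = cbind(i, j),
                            test_neg = matrix(integer(0), 0, 2)),
                       class = "eval_split")
    sc <- score_split(feats, P, split, cfg)
    ord <- order(-sc$S_hat[i, ], seq_len(ncol(P)))
    match(j, ord)
  }, integer(1))
  names(ranks) <- net$nodes$drug[singles]
  recall <- vapply(sort(unique(as.integer(k))),
                   function(kk) mean(ranks <= kk), numeric(1))
  list(n_singletons = length(singles), ranks = ranks,
       recall_at_k = stats::setNames(recall,
                                     paste0("k",
                                            sort(unique(as.integer(k))))))
}

# ---- perturbation ---------------------------------------------------------

# edge census of the non-DTI relations: one row per undirected/bipartite
# edge (relation, i, j); symmetric relations use the upper triangle
.non_dti_edges <- function(net) {
  out <- list()
  for (i in seq_len(nrow(RELATION_DEFS))) {
    nm <- RELATION_DEFS$name[i]
    if (nm == "drug_protein") next
    m <- net$relations[[nm]]
    idx <- which(m != 0, arr.ind = TRUE)
    if (RELATION_DEFS$symmetric[i])
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx))
      out[[nm]] <- data.frame(relation = nm, i = idx[, 1], j = idx[, 2])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.set_edge <- function(net, relation, i, j, value) {
  net$relations[[relation]][i, j] <- value
  if (RELATION_DEFS$symmetric[RELATION_DEFS$name == relation])
    net$relations[[relation]][j, i] <- value
  net
}

#' Perturb the non-DTI edges of a heterogeneous network
#'
#' Applies exactly `round(fraction * n_edges)` perturbation events to the
#' five relations other than drug-protein (whose labels are the prediction
#' target and stay untouched): deletions of existing edges, additions of
#' absent ones, or a seeded mixture. Deletions that would isolate a node
#' are re-sampled (and reported via a message). Used for the robustness
#' protocol: performance is compared before and after perturbing 10% of the
#' network.
#'
#' @param net a validated `hetnet`.
#' @param fraction fraction of non-DTI edges to perturb, in (0, 1).
#' @param mode `"mixed"` (default; each event is an addition or deletion
#'   with equal probability), `"add"` or `"delete"`.
#' @param seed integer seed.
#' @return the perturbed, re-validated `hetnet`.
#' @export
perturb_network <- function(net, fraction = 0.10,
                            mode = c("mixed", "add", "delete"),
                            seed = 0L) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  edges <- .non_dti_edges(net)
  n_events <- round(fraction * nrow(edges))
  kinds <- switch(mode,
                  add = rep("add", n_events),
                  delete = rep("delete", n_events),
                  mixed = sample(c("add", "delete"), n_events,
                                 replace = TRUE))
  n_del <- sum(kinds == "delete")
  # deletions: sample existing edges, re-sampling any that isolates a node
  if (n_del > 0) {
    deg <- node_degrees(net)
    cand <- sample.int(nrow(edges))
    deleted <- 0L; resampled <- 0L; ptr <- 1L
    while (deleted < n_del && ptr <= length(cand)) {
      e <- edges[cand[ptr], ]; ptr <- ptr + 1L
      rt <- RELATION_DEFS$row_type[RELATION_DEFS$name == e$relation]
      ct <- RELATION_DEFS$col_type[RELATION_DEFS$name == e$relation]
      if (deg[[rt]][e$i] <= 1 || deg[[ct]][e$j] <= 1) {
        resampled <- resampled + 1L
        next
      }
      net <- .set_edge(net, e$relation, e$i, e$j, 0)
      deg[[rt]][e$i] <- deg[[rt]][e$i] - 1L
      deg[[ct]][e$j] <- deg[[ct]][e$j] - 1L
      if (rt == ct) {
        deg[[rt]][e$j] <- deg[[rt]][e$j] - 1L
        deg[[ct]][e$i] <- deg[[ct]][e$i] - 1L
      }
      deleted <- deleted + 1L
    }
    if (resampled > 0)
      message(resampled, " deletion(s) re-sampled to avoid isolating a node")
    if (deleted < n_del)
      warning("only ", deleted, " of ", n_del,
              " deletions possible without isolating nodes", call. = FALSE)
  }
  # additions: uniform over absent cells across the non-DTI relations
  n_add <- sum(kinds == "add")
  if (n_add > 0) {
    rel_names <- setdiff(RELATION_DEFS$name, "drug_protein")
    absent <- lapply(rel_names, function(nm) {
      m <- net$relations[[nm]]
      idx <- which(m == 0, arr.ind = TRUE)
      sym <- RELATION_DEFS$symmetric[RELATION_DEFS$name == nm]
      if (sym) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      else idx <- idx[TRUE, , drop = FALSE]
      idx
    })
    names(absent) <- rel_names
    counts <- vapply(absent, nrow, integer(1))
    pick_rel <- sample(rep(rel_names, counts), n_add)
    for (nm in rel_names) {
      k <- sum(pick_rel == nm)
      if (k == 0) next
      sel <- absent[[nm]][sample.int(nrow(absent[[nm]]), k), ,
                          drop = FALSE]
      for (r in seq_len(k))
        net <- .set_edge(net, nm, sel[r, 1], sel[r, 2], 1)
    }
  }
  validate_network(net)
}
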