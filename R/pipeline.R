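# Pipeline configuration and the run-all orchestration: similarity
# assembly -> per-network diffusion -> compact features -> projection fit
# -> pair scoring, with optional cross-validated evaluation, every output
# stamped with the effective configuration and seed.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. The single
#' `seed` is fanned out to the stages by fixed offsets so each stage is
#' independently reproducible. Requested feature dimensions above what a
#' network supports are lowered at run time with a warning.
#'
#' @param restart_prob RWR restart probability (default 0.5).
#' @param tol,max_iter RWR convergence controls.
#' @param log_offset offset inside the feature-learning log; `NULL` means
#'   `1/n` per collection.
#' @param dim_drug,dim_protein feature dimensions for the two node types.
#' @param k,lambda,iters,loss projection-fit controls, see
#'   [fit_projection()].
#' @param folds,neg_policy,trials evaluation protocol defaults.
#' @param networks optional restriction of the diffusible networks (see
#'   [build_collections()]).
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(restart_prob = 0.5, tol = 1e-8,
                            max_iter = 1000L, log_offset = NULL,
                            dim_drug = 100L, dim_protein = 400L,
                            k = 50L, lambda = 1, iters = 100L,
                            loss = c("full", "masked"), folds = 10L,
                            neg_policy = "matched", trials = 1L,
                            networks = NULL, seed = 0L) {
  loss <- match.arg(loss)
  stopifnot(restart_prob > 0, restart_prob <= 1, lambda >= 0, k >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 log_offset = log_offset,
                 dim_drug = as.integer(dim_drug),
                 dim_protein = as.integer(dim_protein),
                 k = as.integer(k), lambda = lambda,
                 iters = as.integer(iters), loss = loss,
                 folds = as.integer(folds), neg_policy = neg_policy,
                 trials = as.integer(trials), networks = networks,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Fit the full pipeline on a network
#'
#' Assembles the network collections, learns drug and protein features, and
#' fits the bilinear projection against the known interaction matrix. The
#' effective rank `k` is capped at the realized feature dimensions.
#'
#' @param net a validated `hetnet`.
#' @param cfg a [pipeline_config()].
#' @return list with feature matrices `X`, `Y`, the fitted `model`, the
#'   full score matrix `S_hat`, and `cfg`.
#' @export
fit_pipeline <- function(net, cfg = pipeline_config()) {
  feats <- pipeline_features(net, cfg)
  k <- min(cfg$k, ncol(feats$X), ncol(feats$Y))
  P <- net$relations$drug_protein
  mask <- if (cfg$loss == "masked") P * 0 + 1
  model <- fit_projection(feats$X, feats$Y, P, k, cfg$lambda, cfg$iters,
                          seed = cfg$seed + 1L, loss = cfg$loss,
                          mask = mask)
  S_hat <- score_all(feats$X, feats$Y, model)
  list(X = feats$X, Y = feats$Y, model = model, S_hat = S_hat, cfg = cfg)
}

#' Export ranked novel predictions
#'
#' Flattens the score matrix into the pairs not present in the training
#' interaction matrix, sorted by descending score (ties by drug then
#' protein registry index).
#'
#' @param fit result of [fit_pipeline()].
#' @param P training interaction matrix (known pairs are excluded).
#' @param top_n keep at most this many predictions (default all).
#' @return data.frame with columns `drug`, `protein`, `score`, `rank`.
#' @export
predictions_table <- function(fit, P, top_n = Inf) {
  S <- fit$S_hat
  idx <- which(P == 0, arr.ind = TRUE)
  ord <- order(-S[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  n <- min(nrow(idx), top_n)
  idx <- idx[seq_len(n), , drop = FALSE]
  data.frame(drug = rownames(S)[idx[, 1]],
             protein = colnames(S)[idx[, 2]],
             score = S[idx], rank = seq_len(n))
}

#' Run the whole pipeline and write its artifacts
#'
#' Executes similarity assembly, diffusion, feature learning, projection
#' fitting and scoring on `net`, and writes to `out_dir`: the feature
#' matrices (`X.tsv`, `Y.tsv`), the projection factors (`F.tsv`, `G.tsv`),
#' ranked novel predictions (`predictions.tsv`), the effective
#' configuration (`config.yaml`) and, when `eval = TRUE`, cross-validated
#' metrics (`metrics.json`). Reruns with the same configuration and seed
#' produce identical outputs.
#'
#' @param net a validated `hetnet` or a directory path for
#'   [read_network()].
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param eval also run [evaluate_cv()] and write `metrics.json`.
#' @param top_n cap on exported predictions (default 1000).
#' @return the [fit_pipeline()] result, invisibly.
#' @export
run_all <- function(net, cfg = pipeline_config(), out_dir, eval = FALSE,
                    top_n = 1000L) {
  if (is.character(net)) net <- read_network(net)
  validate_network(net)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- fit_pipeline(net, cfg)
  write_matrix(`rownames<-`(unclass(fit$X), net$nodes$drug),
               file.path(out_dir, "X.tsv"))
  write_matrix(`rownames<-`(unclass(fit$Y), net$nodes$protein),
               file.path(out_dir, "Y.tsv"))
  write_matrix(fit$model$F, file.path(out_dir, "F.tsv"))
  write_matrix(fit$model$G, file.path(out_dir, "G.tsv"))
  preds <- predictions_table(fit, net$relations$drug_protein, top_n)
  utils::write.table(preds, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  eff <- fit$cfg
  eff$k <- fit$model$k
  eff$dim_drug <- ncol(fit$X); eff$dim_protein <- ncol(fit$Y)
  yaml::write_yaml(unclass(eff), file.path(out_dir, "config.yaml"))
  if (eval) {
    res <- evaluate_cv(net, cfg)
    jsonlite::write_json(
      list(folds = res, summary = as.list(attr(res, "summary"))),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}
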