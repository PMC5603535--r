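# Synthetic heterogeneous networks with planted low-rank drug-target
# structure. Drugs and proteins carry latent factors U, V; the interaction
# matrix is the top quantile of U V' (so interaction counts are exact and
# tests are count-deterministic), and every side network is generated from
# a network-specific *partial view* of the latent factors: one latent
# dimension blanked out (cycling over dimensions across the networks of a
# side) plus additive Gaussian noise. No single side network can therefore
# rank the pairs driven by its missing dimension, but the ensemble covers
# all dimensions - the situation multi-network integration is meant for,
# and the way real evidence layers behave (chemical similarity, shared
# side-effects and interaction partners each capture different
# determinants of binding).

#' Synthetic network configuration
#'
#' Defaults are sized for fast desk-scale runs of the whole pipeline while
#' keeping a recoverable planted signal: 50 drugs, 40 proteins, rank-4
#' latent structure, 5% interaction density, dense side networks (20% edge
#' density, echoing the high mean degree of curated interaction databases)
#' observed through partial views of the latent factors: each side network
#' sees the factors with one latent dimension blanked (cycling over
#' dimensions) and `view_noise_sd = 0.05` additive noise on the
#' unit-variance factors.
#'
#' @param n_drug,n_protein,n_disease,n_side_effect node counts.
#' @param latent_rank rank of the planted bilinear interaction model.
#' @param dti_density fraction of drug-protein pairs made positive (top
#'   quantile of the latent scores).
#' @param dd_density,pp_density edge densities of the drug-drug and
#'   protein-protein interaction networks (top-quantile latent cosine
#'   pairs).
#' @param assoc_density density of the disease / side-effect association
#'   matrices (top quantile of a planted bilinear model between node and
#'   item latent vectors).
#' @param view_noise_sd SD of the Gaussian noise added to each network's
#'   partial latent view before the network is derived from it.
#' @param noise_flip_prob probability of flipping each non-DTI relation
#'   cell (edge noise); the planted interaction matrix itself stays exact.
#' @param n_heldout planted high-score pairs kept out of the interaction
#'   matrix as ground truth for ranking checks.
#' @param seed integer seed (mandatory).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_drug = 50L, n_protein = 40L, n_disease = 30L,
                         n_side_effect = 25L, latent_rank = 4L,
                         dti_density = 0.05, dd_density = 0.20,
                         pp_density = 0.20, assoc_density = 0.15,
                         view_noise_sd = 0.05, noise_flip_prob = 0.01,
                         n_heldout = 20L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_drug = n_drug, n_protein = n_protein,
              n_disease = n_disease, n_side_effect = n_side_effect,
              latent_rank = latent_rank, dti_density = dti_density,
              dd_density = dd_density, pp_density = pp_density,
              assoc_density = assoc_density,
              view_noise_sd = view_noise_sd,
              noise_flip_prob = noise_flip_prob,
              n_heldout = n_heldout, seed = as.integer(seed))
  for (dn in c("dti_density", "dd_density", "pp_density", "assoc_density"))
    if (cfg[[dn]] <= 0 || cfg[[dn]] >= 1)
      stop(dn, " must lie in (0, 1)")
  if (latent_rank > min(n_drug, n_protein))
    stop("latent_rank must not exceed min(n_drug, n_protein)")
  structure(cfg, class = "synth_config")
}

.cosine_sim <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1
  tcrossprod(M / nrm)
}

# symmetric adjacency over the top `density` quantile of latent-cosine pairs
.topk_graph <- function(view, density) {
  n <- nrow(view)
  sim <- .cosine_sim(view)
  ut <- which(upper.tri(sim))
  m <- max(1L, round(density * length(ut)))
  sel <- ut[order(sim[ut], decreasing = TRUE)[seq_len(m)]]
  adj <- matrix(0, n, n)
  adj[sel] <- 1
  pmax(adj, t(adj))
}

# binary association matrix from a planted bilinear model: items get their
# own latent vectors and the top `density` quantile of view %*% t(item)
# scores becomes an association, so Jaccard profile similarities correlate
# with latent proximity
.latent_assoc <- function(view, n_items, density) {
  A <- matrix(stats::rnorm(n_items * ncol(view)), n_items)
  sc <- view %*% t(A)
  k <- max(1L, round(density * length(sc)))
  out <- matrix(0, nrow(sc), ncol(sc))
  out[order(sc, decreasing = TRUE)[seq_len(k)]] <- 1
  out
}

# similarity matrix emulating chemical / sequence similarity: latent cosine
# with negative values clipped to zero (unrelated pairs score ~0, as real
# fingerprint or identity scores do), unit diagonal
.latent_similarity <- function(view) {
  s <- pmax(.cosine_sim(view), 0)
  diag(s) <- 1
  s
}

.flip_edges <- function(m, prob, symmetric) {
  if (prob <= 0) return(m)
  if (symmetric) {
    flip <- matrix(0, nrow(m), ncol(m))
    ut <- upper.tri(m)
    flip[ut] <- stats::runif(sum(ut)) < prob
    flip <- pmax(flip, t(flip))
  } else {
    flip <- matrix(stats::runif(length(m)) < prob, nrow(m))
  }
  out <- abs(m - flip * 1)
  if (symmetric) diag(out) <- 0
  out
}

#' Generate a synthetic heterogeneous network with planted interactions
#'
#' Draws latent factors `U` (drugs) and `V` (proteins) from a standard
#' normal, plants the interaction matrix as the top `dti_density` quantile
#' of `U V'` (exactly `round(density * n_drug * n_protein)` positives), and
#' derives every side network from its own partial view of the factors
#' (one latent dimension blanked, cycling over dimensions within each
#' side, plus additive noise): drug-drug and protein-protein edges connect
#' top latent-cosine pairs, disease and side-effect associations are the
#' top quantile of a planted bilinear model against item latent vectors,
#' and the
#' chemical/sequence similarity matrices are latent cosine similarities
#' clipped to \[0, 1\]. Non-DTI relation cells are then flipped with
#' `noise_flip_prob`. A random `n_heldout` of the planted top-quantile
#' pairs are withheld from the interaction matrix and returned as held-out
#' ground truth for ranking checks (the matrix still contains exactly
#' `round(dti_density * n_drug * n_protein)` positives).
#'
#' @param cfg a [synth_config()].
#' @return list with `network` (a validated `hetnet`), and `truth`: the
#'   latent factors `U`, `V`, the planted positive index pairs `pairs`,
#'   and the `held_out` pair matrix.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nd <- cfg$n_drug; np <- cfg$n_protein; r <- cfg$latent_rank
  U <- matrix(stats::rnorm(nd * r), nd, r)
  V <- matrix(stats::rnorm(np * r), np, r)
  score <- U %*% t(V)
  m <- round(cfg$dti_density * nd * np)
  if (m < 1) stop("dti_density too small: no pairs above the quantile")
  ord <- order(score, decreasing = TRUE)
  h <- min(cfg$n_heldout, nd * np - m)
  planted <- ord[seq_len(m + h)]
  held_idx <- sample(planted, h)
  P <- matrix(0, nd, np)
  P[setdiff(planted, held_idx)] <- 1
  held_out <- cbind(drug = (held_idx - 1L) %% nd + 1L,
                    protein = (held_idx - 1L) %/% nd + 1L)

  # per-side partial views: view i blanks latent dimension ((i-1) mod r)+1
  # and adds Gaussian noise, so each network misses one dimension but the
  # collection covers them all
  make_view <- function(M, i) {
    M[, (i - 1L) %% ncol(M) + 1L] <- 0
    M + cfg$view_noise_sd * matrix(stats::rnorm(length(M)), nrow(M))
  }

  drug_drug <- .topk_graph(make_view(U, 1L), cfg$dd_density)
  drug_chem <- .latent_similarity(make_view(U, 2L))
  drug_disease <- .latent_assoc(make_view(U, 3L), cfg$n_disease,
                                cfg$assoc_density)
  drug_side_effect <- .latent_assoc(make_view(U, 4L), cfg$n_side_effect,
                                    cfg$assoc_density)
  protein_protein <- .topk_graph(make_view(V, 1L), cfg$pp_density)
  protein_seq <- .latent_similarity(make_view(V, 2L))
  protein_disease <- .latent_assoc(make_view(V, 3L), cfg$n_disease,
                                   cfg$assoc_density)

  drug_drug <- .flip_edges(drug_drug, cfg$noise_flip_prob, TRUE)
  protein_protein <- .flip_edges(protein_protein, cfg$noise_flip_prob,
                                 TRUE)
  drug_disease <- .flip_edges(drug_disease, cfg$noise_flip_prob, FALSE)
  drug_side_effect <- .flip_edges(drug_side_effect, cfg$noise_flip_prob,
                                  FALSE)
  protein_disease <- .flip_edges(protein_disease, cfg$noise_flip_prob,
                                 FALSE)

  relations <- list(drug_protein = P, drug_drug = drug_drug,
                    protein_protein = protein_protein,
                    drug_disease = drug_disease,
                    drug_side_effect = drug_side_effect,
                    protein_disease = protein_disease)

  # guarantee degree >= 1: connect stragglers to their nearest latent
  # neighbor (drugs/proteins) or their highest-scoring partner (items)
  ids <- list(drug = sprintf("D%03d", seq_len(nd)),
              protein = sprintf("P%03d", seq_len(np)),
              disease = sprintf("DS%03d", seq_len(cfg$n_disease)),
              side_effect = sprintf("SE%03d", seq_len(cfg$n_side_effect)))
  net_tmp <- hetero_network(ids$drug, ids$protein, ids$disease,
                            ids$side_effect, relations, validate = FALSE)
  deg <- node_degrees(net_tmp)
  sim_d <- .cosine_sim(U); diag(sim_d) <- -Inf
  sim_p <- .cosine_sim(V); diag(sim_p) <- -Inf
  for (i in which(deg$drug == 0)) {
    j <- which.max(sim_d[i, ])
    relations$drug_drug[i, j] <- relations$drug_drug[j, i] <- 1
  }
  for (i in which(deg$protein == 0)) {
    j <- which.max(sim_p[i, ])
    relations$protein_protein[i, j] <-
      relations$protein_protein[j, i] <- 1
  }
  for (j in which(deg$disease == 0))
    relations$drug_disease[which.max(U[, 1]), j] <- 1
  for (j in which(deg$side_effect == 0))
    relations$drug_side_effect[which.max(U[, 1]), j] <- 1

  net <- hetero_network(ids$drug, ids$protein, ids$disease,
                        ids$side_effect, relations,
                        similarities = list(drug_chem = drug_chem,
                                            protein_seq = protein_seq))

  pairs <- which(P == 1, arr.ind = TRUE)
  dimnames(pairs) <- NULL
  colnames(pairs) <- c("drug", "protein")
  list(network = net,
       truth = list(U = U, V = V, pairs = pairs, held_out = held_out,
                    config = cfg))
}

#' Remove a fraction of non-DTI edges
#'
#' Emulates data incompleteness by deleting `missing_frac` of the edges in
#' the five relations other than drug-protein, uniformly at random
#' (deletions that would isolate a node are re-sampled). `missing_frac = 0`
#' returns the network unchanged.
#'
#' @param net a validated `hetnet`.
#' @param missing_frac fraction of non-DTI edges to remove, in \[0, 1).
#' @param seed integer seed.
#' @return the degraded, re-validated `hetnet`.
#' @export
degrade_network <- function(net, missing_frac, seed = 0L) {
  if (missing_frac < 0 || missing_frac >= 1)
    stop("missing_frac must lie in [0, 1)")
  if (missing_frac == 0) return(net)
  perturb_network(net, missing_frac, mode = "delete", seed = seed)
}
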