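# Association-profile similarities and the per-type network collections fed
# to diffusion, plus the redundancy graphs used by the evaluation filters.

#' Jaccard similarity of binary association profiles
#'
#' For a binary association matrix (rows = objects, columns = associated
#' items, e.g. drugs x side-effects), computes the pairwise Jaccard index
#' J(i, j) = |R_i intersect R_j| / |R_i union R_j| over the rows. Pairs with
#' an empty union get similarity 0; the diagonal is set to 1 by convention,
#' including for all-zero rows, so downstream diffusion always has a valid
#' start distribution.
#'
#' @param assoc binary matrix.
#' @return symmetric similarity matrix over the rows of `assoc`, entries in
#'   \[0, 1\], unit diagonal.
#' @export
jaccard_profile_similarity <- function(assoc) {
  if (any(!is.finite(assoc)) || !all(assoc %in% c(0, 1)))
    stop("association matrix must be binary {0,1}")
  inter <- tcrossprod(assoc)
  rs <- rowSums(assoc)
  un <- outer(rs, rs, `+`) - inter
  sim <- ifelse(un > 0, inter / un, 0)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(assoc), rownames(assoc))
  sim
}

DRUG_NETWORKS <- c("drug_drug", "drug_chem", "drug_disease_jaccard",
                   "drug_side_effect_jaccard")
PROTEIN_NETWORKS <- c("protein_protein", "protein_seq",
                      "protein_disease_jaccard")

#' Assemble the diffusible network collections
#'
#' Builds the ordered per-type collections of square nonnegative networks
#' that the diffusion stage walks on. The drug-side collection is
#' `drug_drug` interactions, the `drug_chem` similarity (when present), and
#' Jaccard profile similarities of the drug-disease and drug-side-effect
#' associations; the protein-side collection is `protein_protein`
#' interactions, the `protein_seq` similarity (when present), and the
#' Jaccard similarity of protein-disease associations. The known
#' drug-protein interaction matrix is deliberately not part of either
#' collection: it is the prediction target, used only by the projection
#' stage.
#'
#' @param net a validated `hetnet`.
#' @param networks optional character vector restricting the collections to
#'   the named networks (for single-network ablations); names as above.
#' @return list with elements `drug` and `protein`, each an ordered named
#'   list of square matrices over that type's registry.
#' @export
build_collections <- function(net, networks = NULL) {
  drug <- list(
    drug_drug = net$relations$drug_drug,
    drug_chem = net$similarities$drug_chem,
    drug_disease_jaccard =
      jaccard_profile_similarity(net$relations$drug_disease),
    drug_side_effect_jaccard =
      jaccard_profile_similarity(net$relations$drug_side_effect))
  protein <- list(
    protein_protein = net$relations$protein_protein,
    protein_seq = net$similarities$protein_seq,
    protein_disease_jaccard =
      jaccard_profile_similarity(net$relations$protein_disease))
  drug <- Filter(Negate(is.null), drug)
  protein <- Filter(Negate(is.null), protein)
  if (!is.null(networks)) {
    unknown <- setdiff(networks, c(names(drug), names(protein)))
    if (length(unknown))
      stop("unknown network(s): ", paste(unknown, collapse = ", "))
    drug <- drug[intersect(names(drug), networks)]
    protein <- protein[intersect(names(protein), networks)]
  }
  list(drug = drug, protein = protein)
}

#' Build a redundancy graph from pairwise scores
#'
#' Thresholds a symmetric pairwise score matrix (sequence identity, Tanimoto
#' or Jaccard similarity) into a binary adjacency: i and j are redundant iff
#' their score strictly exceeds `threshold`. The diagonal is excluded, so an
#' identity score matrix yields an empty graph.
#'
#' @param scores symmetric matrix with entries in \[0, 1\].
#' @param threshold fraction in \[0, 1\]; strict `>` defines edges.
#' @param node_type node type the scores refer to (`"drug"` or `"protein"`).
#' @param criterion label recorded for evaluation filter provenance, e.g.
#'   `"seq_identity"` or `"tanimoto"`.
#' @return binary symmetric adjacency matrix with attributes `node_type`,
#'   `criterion` and `threshold`, class `redundancy_graph`.
#' @export
build_redundancy_graph <- function(scores, threshold,
                                   node_type = c("drug", "protein"),
                                   criterion = "similarity") {
  node_type <- match.arg(node_type)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (max(abs(scores - t(scores))) > 1e-8)
    stop("score matrix must be symmetric")
  adj <- (scores > threshold) * 1
  diag(adj) <- 0
  structure(adj, node_type = node_type, criterion = criterion,
            threshold = threshold, class = c("redundancy_graph", "matrix",
                                             "array"))
}
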