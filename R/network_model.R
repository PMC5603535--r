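# Typed in-memory representation of the heterogeneous drug/protein/disease/
# side-effect network plus readers and writers for its on-disk formats.

NODE_TYPES <- c("drug", "protein", "disease", "side_effect")

# Relation schema: rows = source type, columns = destination type. The six
# relations are binary; same-type interaction relations are undirected and
# stored symmetrically.
RELATION_DEFS <- data.frame(
  name     = c("drug_protein", "drug_drug", "protein_protein",
               "drug_disease", "drug_side_effect", "protein_disease"),
  row_type = c("drug", "drug", "protein", "drug", "drug", "protein"),
  col_type = c("protein", "drug", "protein", "disease", "side_effect",
               "disease"),
  symmetric = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

SIMILARITY_DEFS <- data.frame(
  name      = c("drug_chem", "protein_seq"),
  node_type = c("drug", "protein"),
  stringsAsFactors = FALSE
)

#' Construct a heterogeneous network object
#'
#' Bundles the node identifier registries of the four node types with the six
#' binary relation matrices and the (optional) precomputed drug chemical and
#' protein sequence similarity matrices. Row and column order of every matrix
#' is the registry order of the corresponding node type; that order is stable
#' and defines what each matrix index means for the rest of the pipeline.
#'
#' @param drugs,proteins,diseases,side_effects character vectors of unique
#'   node identifiers, in registry order.
#' @param relations named list of binary matrices; must contain
#'   `drug_protein`, `drug_drug`, `protein_protein`, `drug_disease`,
#'   `drug_side_effect` and `protein_disease`, each dimensioned by its node
#'   registries. Same-type relations must be symmetric.
#' @param similarities named list with optional entries `drug_chem` and
#'   `protein_seq`: symmetric similarity matrices with unit diagonal and
#'   entries in \[0, 1\].
#' @param validate validate invariants on construction (default `TRUE`).
#' @return an object of class `hetnet`.
#' @export
hetero_network <- function(drugs, proteins, diseases, side_effects,
                           relations, similarities = list(),
                           validate = TRUE) {
  net <- structure(
    list(
      nodes = list(drug = as.character(drugs),
                   protein = as.character(proteins),
                   disease = as.character(diseases),
                   side_effect = as.character(side_effects)),
      relations = relations,
      similarities = similarities
    ),
    class = "hetnet"
  )
  # attach dimnames so matrices stay interpretable on their own
  for (i in seq_len(nrow(RELATION_DEFS))) {
    nm <- RELATION_DEFS$name[i]
    if (!is.null(net$relations[[nm]])) {
      dimnames(net$relations[[nm]]) <-
        list(net$nodes[[RELATION_DEFS$row_type[i]]],
             net$nodes[[RELATION_DEFS$col_type[i]]])
    }
  }
  for (i in seq_len(nrow(SIMILARITY_DEFS))) {
    nm <- SIMILARITY_DEFS$name[i]
    if (!is.null(net$similarities[[nm]])) {
      ids <- net$nodes[[SIMILARITY_DEFS$node_type[i]]]
      dimnames(net$similarities[[nm]]) <- list(ids, ids)
    }
  }
  if (validate) validate_network(net)
  net
}

#' @export
print.hetnet <- function(x, ...) {
  cat("Heterogeneous drug-target network\n")
  for (ty in NODE_TYPES)
    cat(sprintf("  %-12s %5d nodes\n", ty, length(x$nodes[[ty]])))
  for (nm in RELATION_DEFS$name) {
    m <- x$relations[[nm]]
    sym <- RELATION_DEFS$symmetric[RELATION_DEFS$name == nm]
    ne <- if (sym) sum(m[upper.tri(m)] != 0) else sum(m != 0)
    cat(sprintf("  %-18s %d edges\n", nm, ne))
  }
  if (length(x$similarities))
    cat("  similarities:", paste(names(x$similarities), collapse = ", "),
        "\n")
  invisible(x)
}

#' Validate heterogeneous network invariants
#'
#' Checks registry uniqueness, matrix dimensions against registries, binary
#' 0/1 relation values, symmetry of same-type relations, similarity matrices
#' in \[0, 1\] with unit diagonal, non-empty node types, and that every node
#' carries at least one edge across the six relations.
#'
#' @param net a `hetnet` object.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  for (ty in NODE_TYPES) {
    ids <- net$nodes[[ty]]
    if (length(ids) == 0L)
      stop("node type '", ty, "' is empty")
    if (anyDuplicated(ids))
      stop("duplicate node ids in registry '", ty, "'")
  }
  for (i in seq_len(nrow(RELATION_DEFS))) {
    nm <- RELATION_DEFS$name[i]
    m <- net$relations[[nm]]
    if (is.null(m)) stop("missing relation matrix '", nm, "'")
    nr <- length(net$nodes[[RELATION_DEFS$row_type[i]]])
    nc <- length(net$nodes[[RELATION_DEFS$col_type[i]]])
    if (!all(dim(m) == c(nr, nc)))
      stop(sprintf("relation '%s' is %dx%d but registries imply %dx%d",
                   nm, nrow(m), ncol(m), nr, nc))
    if (any(!is.finite(m)) || !all(m %in% c(0, 1)))
      stop("relation '", nm, "' must be binary {0,1}")
    if (RELATION_DEFS$symmetric[i] && !isTRUE(all.equal(m, t(m),
                                                        check.attributes = FALSE)))
      stop("relation '", nm, "' must be symmetric")
  }
  for (i in seq_len(nrow(SIMILARITY_DEFS))) {
    nm <- SIMILARITY_DEFS$name[i]
    s <- net$similarities[[nm]]
    if (is.null(s)) next
    n <- length(net$nodes[[SIMILARITY_DEFS$node_type[i]]])
    if (!all(dim(s) == c(n, n)))
      stop("similarity '", nm, "' dimension mismatch")
    if (any(!is.finite(s)) || any(s < 0) || any(s > 1))
      stop("similarity '", nm, "' must lie in [0, 1]")
    if (max(abs(s - t(s))) > 1e-12)
      stop("similarity '", nm, "' must be symmetric")
    if (max(abs(diag(s) - 1)) > 1e-12)
      stop("similarity '", nm, "' must have unit diagonal")
  }
  deg <- node_degrees(net)
  for (ty in NODE_TYPES) {
    if (any(deg[[ty]] == 0))
      stop("isolated ", ty, " node(s): ",
           paste(net$nodes[[ty]][deg[[ty]] == 0], collapse = ", "))
  }
  invisible(net)
}

# per-type node degree summed over the six relation matrices
node_degrees <- function(net) {
  deg <- lapply(net$nodes, function(ids) stats::setNames(numeric(length(ids)),
                                                         ids))
  for (i in seq_len(nrow(RELATION_DEFS))) {
    m <- net$relations[[RELATION_DEFS$name[i]]]
    if (is.null(m)) next
    rt <- RELATION_DEFS$row_type[i]; ct <- RELATION_DEFS$col_type[i]
    deg[[rt]] <- deg[[rt]] + rowSums(m != 0)
    if (rt != ct) deg[[ct]] <- deg[[ct]] + colSums(m != 0)
  }
  deg
}

.read_node_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           colClasses = "character")
  if (!"id" %in% names(tab))
    stop("node table ", path, " lacks an 'id' column")
  ids <- tab$id
  if (anyDuplicated(ids))
    stop("duplicate ids in node table ", path)
  ids
}

.read_edge_list <- function(path, row_ids, col_ids, symmetric) {
  n <- length(row_ids); m <- length(col_ids)
  mat <- matrix(0, n, m)
  if (!file.exists(path)) return(mat)
  lines <- readLines(path)
  ridx <- stats::setNames(seq_along(row_ids), row_ids)
  cidx <- stats::setNames(seq_along(col_ids), col_ids)
  clamped <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("malformed edge line ", ln, " in ", path)
    i <- ridx[parts[1]]; j <- cidx[parts[2]]
    if (is.na(i))
      stop("unknown ", "source id '", parts[1], "' at ", basename(path),
           ":", ln)
    if (is.na(j))
      stop("unknown ", "destination id '", parts[2], "' at ",
           basename(path), ":", ln)
    w <- if (length(parts) >= 3L) as.numeric(parts[3]) else 1
    if (!is.finite(w) || w < 0)
      stop("invalid edge weight at ", basename(path), ":", ln)
    if (w > 1) { w <- 1; clamped <- clamped + 1L }
    if (w > 0) mat[i, j] <- 1  # duplicates collapse
  }
  if (clamped > 0L)
    warning(clamped, " edge weight(s) > 1 clamped to 1 in ",
            basename(path), call. = FALSE)
  if (symmetric) mat <- pmax(mat, t(mat))
  mat
}

#' Read a heterogeneous network from a directory
#'
#' Expects one node table per type (`drug.tsv`, `protein.tsv`, `disease.tsv`,
#' `side_effect.tsv`; TSV with an `id` header column) and one edge list per
#' relation (`drug_protein.tsv`, ...; TSV lines `src<TAB>dst[<TAB>weight]`,
#' `#` comments allowed). Optional dense similarity matrices `drug_chem.tsv`
#' and `protein_seq.tsv` are read when present. Same-type relations are
#' symmetrized by `max(A, t(A))`, duplicate edges collapse to one, edge
#' weights above 1 are clamped to 1 with a warning, and nodes with no edge in
#' any relation are dropped with a message reporting the count.
#'
#' @param dir_path directory containing the files above.
#' @return a validated [hetero_network()] object.
#' @export
read_network <- function(dir_path) {
  nodes <- lapply(stats::setNames(NODE_TYPES, NODE_TYPES), function(ty)
    .read_node_table(file.path(dir_path, paste0(ty, ".tsv"))))
  relations <- list()
  for (i in seq_len(nrow(RELATION_DEFS))) {
    nm <- RELATION_DEFS$name[i]
    relations[[nm]] <- .read_edge_list(
      file.path(dir_path, paste0(nm, ".tsv")),
      nodes[[RELATION_DEFS$row_type[i]]],
      nodes[[RELATION_DEFS$col_type[i]]],
      RELATION_DEFS$symmetric[i])
  }
  similarities <- list()
  for (i in seq_len(nrow(SIMILARITY_DEFS))) {
    nm <- SIMILARITY_DEFS$name[i]
    p <- file.path(dir_path, paste0(nm, ".tsv"))
    if (file.exists(p)) {
      s <- read_matrix(p, fmt = "tsv")
      ids <- nodes[[SIMILARITY_DEFS$node_type[i]]]
      if (!all(dim(s) == length(ids)))
        stop("similarity matrix ", basename(p), " is ", nrow(s), "x",
             ncol(s), " but node table has ", length(ids), " ids")
      if (!is.null(rownames(s)) && !identical(rownames(s), ids))
        s <- s[ids, ids, drop = FALSE]  # align to registry order
      similarities[[nm]] <- unname(s)
    }
  }
  net <- hetero_network(nodes$drug, nodes$protein, nodes$disease,
                        nodes$side_effect, relations, similarities,
                        validate = FALSE)
  drop_isolated_nodes(net)
}

# Remove nodes with zero degree across all six relations, mirroring the
# source-data convention of keeping only nodes with at least one edge.
drop_isolated_nodes <- function(net) {
  deg <- node_degrees(net)
  keep <- lapply(deg, function(d) d > 0)
  n_drop <- sum(vapply(keep, function(k) sum(!k), integer(1)))
  if (n_drop > 0L) {
    message("dropping ", n_drop, " isolated node(s)")
    for (i in seq_len(nrow(RELATION_DEFS))) {
      nm <- RELATION_DEFS$name[i]
      net$relations[[nm]] <- net$relations[[nm]][
        keep[[RELATION_DEFS$row_type[i]]],
        keep[[RELATION_DEFS$col_type[i]]], drop = FALSE]
    }
    for (i in seq_len(nrow(SIMILARITY_DEFS))) {
      nm <- SIMILARITY_DEFS$name[i]
      if (!is.null(net$similarities[[nm]])) {
        k <- keep[[SIMILARITY_DEFS$node_type[i]]]
        net$similarities[[nm]] <- net$similarities[[nm]][k, k, drop = FALSE]
      }
    }
    for (ty in NODE_TYPES) net$nodes[[ty]] <- net$nodes[[ty]][keep[[ty]]]
  }
  validate_network(net)
}

#' Write a heterogeneous network to a directory
#'
#' Inverse of [read_network()]: node tables, relation edge lists and dense
#' similarity TSVs, such that `read_network(write_network(net, d))`
#' reproduces `net` exactly for the binary relations and within 1e-12 for
#' the similarities.
#'
#' @param net a validated `hetnet`.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_network <- function(net, dir_path) {
  validate_network(net)
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (ty in NODE_TYPES)
    utils::write.table(data.frame(id = net$nodes[[ty]]),
                       file.path(dir_path, paste0(ty, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(RELATION_DEFS))) {
    nm <- RELATION_DEFS$name[i]
    m <- net$relations[[nm]]
    idx <- which(m != 0, arr.ind = TRUE)
    if (RELATION_DEFS$symmetric[i]) idx <- idx[idx[, 1] < idx[, 2], ,
                                               drop = FALSE]
    df <- data.frame(
      src = net$nodes[[RELATION_DEFS$row_type[i]]][idx[, 1]],
      dst = net$nodes[[RELATION_DEFS$col_type[i]]][idx[, 2]])
    utils::write.table(df, file.path(dir_path, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  for (i in seq_len(nrow(SIMILARITY_DEFS))) {
    nm <- SIMILARITY_DEFS$name[i]
    if (!is.null(net$similarities[[nm]])) {
      s <- net$similarities[[nm]]
      ids <- net$nodes[[SIMILARITY_DEFS$node_type[i]]]
      dimnames(s) <- list(ids, ids)
      write_matrix(s, file.path(dir_path, paste0(nm, ".tsv")), fmt = "tsv")
    }
  }
  invisible(dir_path)
}

#' Write a matrix as TSV or MatrixMarket
#'
#' `tsv` writes a dense table with row ids in the first column (`id` header)
#' and column ids in the header row. `mtx` writes MatrixMarket coordinate
#' format via the Matrix package, with row and column ids in sidecar files
#' `<path>.rows` / `<path>.cols`; integer matrices round-trip bit-identically.
#'
#' @param m numeric matrix (dimnames used as ids when present).
#' @param path output file path.
#' @param fmt `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, fmt = c("tsv", "mtx")) {
  fmt <- match.arg(fmt)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite entry at [", bad[1, 1], ", ", bad[1, 2],
         "]; refusing to write")
  if (fmt == "tsv") {
    rn <- rownames(m); cn <- colnames(m)
    if (is.null(rn)) rn <- paste0("r", seq_len(nrow(m)))
    if (is.null(cn)) cn <- paste0("c", seq_len(ncol(m)))
    df <- data.frame(id = rn, m, check.names = FALSE)
    colnames(df) <- c("id", cn)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    sm <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                  "dMatrix"), "generalMatrix")
    Matrix::writeMM(sm, path)
    if (!is.null(rownames(m))) writeLines(rownames(m), paste0(path, ".rows"))
    if (!is.null(colnames(m))) writeLines(colnames(m), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path file path.
#' @param fmt `"tsv"` or `"mtx"`.
#' @return numeric matrix with dimnames when ids are available.
#' @export
read_matrix <- function(path, fmt = c("tsv", "mtx")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = NA)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1]])
    m
  } else {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"
    rf <- paste0(path, ".rows"); cf <- paste0(path, ".cols")
    if (file.exists(rf)) rownames(m) <- readLines(rf)
    if (file.exists(cf)) colnames(m) <- readLines(cf)
    m
  }
}
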