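#' Node registry
#'
#' An ordered list of node identifiers of one type (drug, protein, disease or
#' side_effect) together with the 0-based position each identifier occupies in
#' the rows/columns of the relation matrices.
#'
#' @param node_type one of `"drug"`, `"protein"`, `"disease"`, `"side_effect"`.
#' @param ids character vector of unique identifiers, in matrix order.
#' @return an object of class `node_registry`.
#' @export
node_registry <- function(node_type, ids) {
  node_type <- match.arg(node_type, c("drug", "protein", "disease", "side_effect"))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) drh_stop("duplicate %s identifiers in registry", node_type)
  if (length(ids) == 0L) drh_stop("empty registry for node type '%s'", node_type)
  structure(
    list(node_type = node_type, ids = ids,
         index = setNames(seq_along(ids) - 1L, ids)),
    class = "node_registry"
  )
}

#' @export
length.node_registry <- function(x) length(x$ids)

#' Typed relation matrix
#'
#' Wraps one sub-network of the heterogeneous graph: a binary
#' interaction/association matrix or a real-valued similarity matrix, with its
#' source and target node types.
#'
#' @param source_type,target_type node types of rows and columns.
#' @param kind `"interaction"`, `"association"` or `"similarity"`.
#' @param values matrix (dense or `Matrix` sparse); binary for
#'   interaction/association, values in `[0, 1]` for similarity.
#' @param name optional relation name used in error messages.
#' @return an object of class `relation_matrix`.
#' @export
relation_matrix <- function(source_type, target_type, kind, values, name = NULL) {
  kind <- match.arg(kind, c("interaction", "association", "similarity"))
  name <- name %||% paste(source_type, target_type, sep = "_")
  values <- methods::as(methods::as(as.matrix(values), "dMatrix"), "CsparseMatrix")
  if (kind %in% c("interaction", "association")) {
    bad <- which(!(values@x %in% c(0, 1)))
    if (length(bad)) {
      ij <- arrayInd(which(as.matrix(values) != 0 & as.matrix(values) != 1)[1], dim(values))
      drh_stop("non-binary entry in %s matrix '%s' at (%d, %d)",
               kind, name, ij[1], ij[2])
    }
    if (source_type == target_type && nrow(values) == ncol(values) &&
        any(Matrix::diag(values) != 0)) {
      drh_stop("self-loops are not allowed in %s matrix '%s'", kind, name)
    }
  } else {
    if (nrow(values) != ncol(values))
      drh_stop("similarity matrix '%s' must be square", name)
    dense <- as.matrix(values)
    if (max(abs(dense - t(dense))) > 1e-8)
      drh_stop("similarity matrix '%s' is not symmetric (tol 1e-8)", name)
    if (max(abs(diag(dense) - 1)) > 1e-8)
      drh_stop("similarity matrix '%s' must have unit diagonal", name)
    if (min(dense) < -1e-12 || max(dense) > 1 + 1e-12)
      drh_stop("similarity matrix '%s' has entries outside [0, 1]", name)
  }
  structure(
    list(source_type = source_type, target_type = target_type,
         kind = kind, name = name, values = values),
    class = "relation_matrix"
  )
}

# canonical relation names used throughout the package
.DRH_RELATIONS <- c("drug_protein", "drug_drug", "drug_disease",
                    "drug_side_effect", "protein_disease", "protein_protein")
.DRH_SIMILARITIES <- c("drug_similarity", "protein_similarity")

#' Heterogeneous drug-protein-disease network
#'
#' Assembles the four node registries and the eight sub-networks (six binary
#' association/interaction networks plus the drug and protein similarity
#' networks) into one validated container.
#'
#' @param registries named list of [node_registry()] objects
#'   (`drug`, `protein`, `disease`, `side_effect`).
#' @param relations named list of [relation_matrix()] objects using the
#'   canonical names `drug_protein`, `drug_drug`, `drug_disease`,
#'   `drug_side_effect`, `protein_disease`, `protein_protein`,
#'   `drug_similarity`, `protein_similarity`.
#' @return an object of class `hetero_network`.
#' @export
hetero_network <- function(registries, relations) {
  need_types <- c("drug", "protein", "disease", "side_effect")
  if (!all(need_types %in% names(registries)))
    drh_stop("registries must cover: %s", paste(need_types, collapse = ", "))
  need_rel <- c(.DRH_RELATIONS, .DRH_SIMILARITIES)
  missing_rel <- setdiff(need_rel, names(relations))
  if (length(missing_rel))
    drh_stop("missing relations: %s", paste(missing_rel, collapse = ", "))
  sizes <- vapply(registries, length, integer(1))
  for (nm in need_rel) {
    rel <- relations[[nm]]
    exp_dim <- c(sizes[[rel$source_type]], sizes[[rel$target_type]])
    if (!all(dim(rel$values) == exp_dim))
      drh_stop("matrix '%s' has shape %d x %d, expected %d x %d",
               nm, nrow(rel$values), ncol(rel$values), exp_dim[1], exp_dim[2])
  }
  structure(list(registries = registries, relations = relations),
            class = "hetero_network")
}

#' Summarize a heterogeneous network
#'
#' @param network a [hetero_network()].
#' @return list with per-type node counts, per-relation edge counts
#'   (similarities excluded), and totals. Symmetric square association
#'   matrices are counted once per undirected pair, matching the source data
#'   convention.
#' @export
network_summary <- function(network) {
  sizes <- vapply(network$registries, length, integer(1))
  edge_counts <- vapply(.DRH_RELATIONS, function(nm) {
    v <- network$relations[[nm]]$values
    n <- Matrix::nnzero(v)
    rel <- network$relations[[nm]]
    if (rel$source_type == rel$target_type) n / 2 else n
  }, numeric(1))
  list(nodes = as.list(sizes), edges = as.list(edge_counts),
       total_nodes = sum(sizes), total_edges = sum(edge_counts))
}

#' Published node and edge counts of the DTINet heterogeneous network
#'
#' The node and (undirected) edge counts of the reference drug-protein-disease
#' network as published for the DTINet dataset: 708 drugs, 1,512 proteins,
#' 5,603 diseases and 4,192 side effects, with six edge types totalling
#' 1,895,445 edges over 12,015 nodes.
#'
#' @return list with `nodes` (per type), `edges` (per relation) and the
#'   published totals `total_nodes`, `total_edges`.
#' @export
dtinet_reference_counts <- function() {
  list(
    nodes = list(drug = 708, protein = 1512, disease = 5603, side_effect = 4192),
    edges = list(drug_drug = 10036, drug_protein = 1923, drug_disease = 199214,
                 drug_side_effect = 80164, protein_protein = 7363,
                 protein_disease = 1596745),
    total_nodes = 12015,
    total_edges = 1895445
  )
}

#' Multi-labeled drug-protein-disease graph
#'
#' Triples (drug, protein, label set) where each label set is a non-empty set
#' of disease identifiers attached to that drug-protein edge.
#'
#' @param drug,protein character vectors of equal length.
#' @param labels list of character vectors (one non-empty set per edge).
#' @param provenance the label rule used (free text, e.g. "intersection").
#' @return object of class `multilabel_dpd`.
#' @export
multilabel_dpd <- function(drug, protein, labels, provenance = "unknown") {
  drug <- as.character(drug); protein <- as.character(protein)
  if (length(drug) != length(protein) || length(drug) != length(labels))
    drh_stop("drug, protein and labels must have equal length")
  if (anyDuplicated(paste(drug, protein, sep = "\r")))
    drh_stop("duplicate (drug, protein) pairs in multi-label graph")
  if (any(vapply(labels, length, integer(1)) == 0L) && length(labels))
    drh_stop("empty label set in multi-label graph")
  labels <- lapply(labels, function(x) sort(unique(as.character(x))))
  structure(list(drug = drug, protein = protein, labels = labels,
                 provenance = provenance),
            class = "multilabel_dpd")
}

#' @export
length.multilabel_dpd <- function(x) length(x$drug)

#' Single-label drug-protein-disease graph
#'
#' @param drug,protein,disease character vectors of equal length; one disease
#'   label per drug-protein edge.
#' @param label_vocabulary ordered distinct labels; defaults to the sorted
#'   distinct diseases present.
#' @return object of class `dpd_graph`: a data.frame with columns
#'   `drug`, `protein`, `disease` and attribute `label_vocabulary`.
#' @export
dpd_graph <- function(drug, protein, disease, label_vocabulary = NULL) {
  df <- data.frame(drug = as.character(drug), protein = as.character(protein),
                   disease = as.character(disease), stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$drug, df$protein, sep = "\r")))
    drh_stop("duplicate (drug, protein) pairs in DPD graph")
  vocab <- label_vocabulary %||% sort(unique(df$disease))
  if (!all(df$disease %in% vocab))
    drh_stop("disease labels outside the label vocabulary")
  attr(df, "label_vocabulary") <- vocab
  class(df) <- c("dpd_graph", "data.frame")
  df
}

#' @export
print.hetero_network <- function(x, ...) {
  s <- network_summary(x)
  cat("hetero_network:", s$total_nodes, "nodes,", s$total_edges, "edges\n")
  cat("  nodes:", paste(sprintf("%s=%g", names(s$nodes), unlist(s$nodes)),
                        collapse = " "), "\n")
  cat("  edges:", paste(sprintf("%s=%g", names(s$edges), unlist(s$edges)),
                        collapse = " "), "\n")
  invisible(x)
}
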