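# DTINet file dialect: one-ID-per-line node lists and dense
# whitespace-separated matrices whose row/column order follows the lists.
.DTINET_MANIFEST <- list(
  nodes = c(drug = "drug.txt", protein = "protein.txt",
            disease = "disease.txt", side_effect = "se.txt"),
  matrices = list(
    drug_protein     = list(file = "mat_drug_protein.txt",
                            source = "drug", target = "protein", kind = "interaction"),
    drug_drug        = list(file = "mat_drug_drug.txt",
                            source = "drug", target = "drug", kind = "interaction"),
    drug_disease     = list(file = "mat_drug_disease.txt",
                            source = "drug", target = "disease", kind = "association"),
    drug_side_effect = list(file = "mat_drug_se.txt",
                            source = "drug", target = "side_effect", kind = "association"),
    protein_disease  = list(file = "mat_protein_disease.txt",
                            source = "protein", target = "disease", kind = "association"),
    protein_protein  = list(file = "mat_protein_protein.txt",
                            source = "protein", target = "protein", kind = "interaction"),
    drug_similarity    = list(file = "Similarity_Matrix_Drugs.txt",
                              source = "drug", target = "drug", kind = "similarity"),
    protein_similarity = list(file = "Similarity_Matrix_Proteins.txt",
                              source = "protein", target = "protein", kind = "similarity")
  )
)

read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

read_dense_matrix <- function(path, nrow_expected, ncol_expected, name) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != nrow_expected * ncol_expected)
    drh_stop("matrix '%s' (%s) has %d values, expected %d x %d",
             name, basename(path), length(vals), nrow_expected, ncol_expected)
  matrix(vals, nrow = nrow_expected, ncol = ncol_expected, byrow = TRUE)
}

#' Load a DTINet-format heterogeneous network
#'
#' Reads the node lists and the eight dense whitespace-separated matrices of
#' the DTINet dialect from a directory, validates shapes and entry ranges, and
#' returns a [hetero_network()]. Row/column order follows the node lists
#' (0-based internal indices).
#'
#' @param dir_path directory containing `drug.txt`, `protein.txt`,
#'   `disease.txt`, `se.txt`, the six `mat_*.txt` association matrices and the
#'   two `Similarity_Matrix_*.txt` files.
#' @return a validated [hetero_network()]. Per-type node counts and
#'   per-relation nonzero counts are logged via `message()`.
#' @export
load_dtinet <- function(dir_path) {
  if (!dir.exists(dir_path)) drh_stop("data directory not found: %s", dir_path)
  man <- .DTINET_MANIFEST
  registries <- list()
  for (tp in names(man$nodes)) {
    f <- file.path(dir_path, man$nodes[[tp]])
    if (!file.exists(f)) drh_stop("missing node list file: %s", f)
    registries[[tp]] <- node_registry(tp, read_id_list(f))
  }
  sizes <- vapply(registries, length, integer(1))
  relations <- list()
  for (nm in names(man$matrices)) {
    m <- man$matrices[[nm]]
    f <- file.path(dir_path, m$file)
    if (!file.exists(f)) drh_stop("missing matrix file: %s", f)
    vals <- read_dense_matrix(f, sizes[[m$source]], sizes[[m$target]], nm)
    relations[[nm]] <- relation_matrix(m$source, m$target, m$kind, vals, name = nm)
  }
  net <- hetero_network(registries, relations)
  s <- network_summary(net)
  drh_msg("loaded network: %g nodes (%s), %g edges (%s)",
          s$total_nodes,
          paste(sprintf("%s=%g", names(s$nodes), unlist(s$nodes)), collapse = ", "),
          s$total_edges,
          paste(sprintf("%s=%g", names(s$edges), unlist(s$edges)), collapse = ", "))
  net
}

#' Write a heterogeneous network in the DTINet file dialect
#'
#' Inverse of [load_dtinet()]: writes node lists and dense whitespace-separated
#' matrices so the full pipeline runs unchanged on generated data.
#'
#' @param network a [hetero_network()].
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_dtinet <- function(network, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  man <- .DTINET_MANIFEST
  for (tp in names(man$nodes)) {
    writeLines(network$registries[[tp]]$ids, file.path(dir_path, man$nodes[[tp]]))
  }
  for (nm in names(man$matrices)) {
    m <- man$matrices[[nm]]
    dense <- as.matrix(network$relations[[nm]]$values)
    lines <- apply(dense, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                               collapse = "\t"))
    writeLines(lines, file.path(dir_path, m$file))
  }
  invisible(dir_path)
}

#' Build the multi-labeled DPD graph
#'
#' For every drug-protein interaction, attaches a set of disease labels: in
#' `"protein"` mode the diseases associated with the protein (the adjacency
#' join on protein names); in `"intersection"` mode (default) the diseases
#' associated with both the drug and the protein. Pairs whose label set is
#' empty are dropped and their count logged.
#'
#' @param network a [hetero_network()].
#' @param label_source `"intersection"` or `"protein"`.
#' @return a [multilabel_dpd()] graph.
#' @export
build_dpd <- function(network, label_source = c("intersection", "protein")) {
  label_source <- match.arg(label_source)
  rel <- network$relations
  need <- c("drug_protein", "protein_disease",
            if (label_source == "intersection") "drug_disease")
  miss <- setdiff(need, names(rel))
  if (length(miss))
    drh_stop("mode '%s' requires relation(s): %s", label_source,
             paste(miss, collapse = ", "))

  dp <- rel$drug_protein$values
  drug_ids <- network$registries$drug$ids
  prot_ids <- network$registries$protein$ids
  dis_ids <- network$registries$disease$ids

  # adjacency lists: disease index sets per protein / per drug
  pd <- methods::as(rel$protein_disease$values, "TsparseMatrix")
  prot_dis <- split(pd@j + 1L, factor(pd@i + 1L, levels = seq_along(prot_ids)))
  if (label_source == "intersection") {
    dd <- methods::as(rel$drug_disease$values, "TsparseMatrix")
    drug_dis <- split(dd@j + 1L, factor(dd@i + 1L, levels = seq_along(drug_ids)))
  }

  dpt <- methods::as(dp, "TsparseMatrix")
  di <- dpt@i + 1L; pj <- dpt@j + 1L
  keep_d <- character(0); keep_p <- character(0); labels <- list()
  dropped <- 0L
  for (e in seq_along(di)) {
    labs <- prot_dis[[pj[e]]]
    if (label_source == "intersection")
      labs <- intersect(labs, drug_dis[[di[e]]])
    if (length(labs)) {
      keep_d <- c(keep_d, drug_ids[di[e]])
      keep_p <- c(keep_p, prot_ids[pj[e]])
      labels[[length(labels) + 1L]] <- dis_ids[labs]
    } else {
      dropped <- dropped + 1L
    }
  }
  drh_msg("build_dpd(%s): %d labeled triples, %d unlabeled pairs dropped",
          label_source, length(labels), dropped)
  g <- multilabel_dpd(keep_d, keep_p, labels, provenance = label_source)
  attr(g, "dropped") <- dropped
  g
}

#' Write / read drug-protein-disease triples as TSV
#'
#' Format: `drug_id\tprotein_id\tdisease_id[;disease_id...]`. Reading a file
#' where every line carries a single disease yields a [dpd_graph()]; any
#' multi-disease line yields a [multilabel_dpd()] (overridable via `as`).
#'
#' @param graph a [multilabel_dpd()] or [dpd_graph()].
#' @param path file path.
#' @return `write_triples`: `path` invisibly; `read_triples`: the graph.
#' @export
write_triples <- function(graph, path) {
  if (inherits(graph, "multilabel_dpd")) {
    lines <- paste(graph$drug, graph$protein,
                   vapply(graph$labels, paste, character(1), collapse = ";"),
                   sep = "\t")
  } else if (inherits(graph, "dpd_graph")) {
    lines <- paste(graph$drug, graph$protein, graph$disease, sep = "\t")
  } else drh_stop("unsupported graph class: %s", paste(class(graph), collapse = "/"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_triples
#' @param as `"auto"` (single-label iff no line has multiple diseases),
#'   `"multilabel"` or `"single"`.
#' @export
read_triples <- function(path, as = c("auto", "multilabel", "single")) {
  as <- match.arg(as)
  if (!file.exists(path)) drh_stop("triple file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3L))
    drh_stop("malformed triple line %d: expected 3 tab-separated fields, got %d",
             which(nf != 3L)[1], nf[nf != 3L][1])
  drug <- vapply(parts, `[[`, character(1), 1L)
  protein <- vapply(parts, `[[`, character(1), 2L)
  labsets <- strsplit(vapply(parts, `[[`, character(1), 3L), ";", fixed = TRUE)
  single <- all(vapply(labsets, length, integer(1)) == 1L)
  if (as == "single" && !single)
    drh_stop("file contains multi-label lines; cannot read as single-label")
  if (as == "multilabel" || (as == "auto" && !single))
    multilabel_dpd(drug, protein, labsets, provenance = "file")
  else
    dpd_graph(drug, protein, unlist(labsets))
}
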