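# Heterogeneous GraphSAGE (HinSAGE) on the bipartite DPD graph.
#
# Node types: drug, protein. Relation types are ordered tuples
# (source type, edge type, target type); here the labeled drug-protein
# interaction gives two relations, named "drug_protein" (a drug aggregating
# its protein neighbors) and "protein_drug" (the reverse).
#
# Layer update (sum form, the canonical variant):
#   h_v^k = sigma( W_self[t_v]' D_p[h_v^{k-1}]
#                  + sum_r W_neigh[r]' mean_{u in sampled N_r(v)} D_p[h_u^{k-1}]
#                  + b_k )
# The "concat" variant gives self and neighbor terms d_k/2 columns each and
# concatenates them.

.DRH_NODE_TYPES <- c("drug", "protein")
.DRH_EDGE_RELATIONS <- c("drug_protein", "protein_drug")

#' Adjacency lists of a single-label DPD graph
#'
#' @param graph a [dpd_graph()].
#' @param drug_ids,protein_ids node universes (default: ids present in the
#'   graph, sorted). Nodes without edges are retained as isolated.
#' @return list with `drug_ids`, `protein_ids`, `d2p` (per-drug integer
#'   protein indices) and `p2d`.
#' @export
dpd_adjacency <- function(graph, drug_ids = NULL, protein_ids = NULL) {
  drug_ids <- drug_ids %||% sort(unique(graph$drug))
  protein_ids <- protein_ids %||% sort(unique(graph$protein))
  di <- match(graph$drug, drug_ids)
  pj <- match(graph$protein, protein_ids)
  if (anyNA(di) || anyNA(pj))
    drh_stop("graph contains nodes outside the supplied id universes")
  d2p <- split(pj, factor(di, levels = seq_along(drug_ids)))
  p2d <- split(di, factor(pj, levels = seq_along(protein_ids)))
  list(drug_ids = drug_ids, protein_ids = protein_ids,
       d2p = unname(d2p), p2d = unname(p2d))
}

#' Sample relation-typed neighbors
#'
#' Draws `k_samples` neighbors of `node` via `relation`. When `k_samples` is
#' at least the node's degree the full neighborhood is returned with equal
#' multiplicity (each neighbor repeated `k_samples / degree` times when that
#' is an integer, once each otherwise), so the mean aggregate over the sample
#' equals the exact neighborhood mean; below the degree, neighbors are drawn
#' uniformly with replacement. An empty neighborhood yields an empty vector
#' (the downstream aggregate is the zero vector). Deterministic given
#' `rng_seed`.
#'
#' @param graph a [dpd_graph()] (or a prebuilt [dpd_adjacency()] list).
#' @param node node identifier.
#' @param relation `"drug_protein"` (drug -> protein neighbors) or
#'   `"protein_drug"`.
#' @param k_samples number of samples (>= 1).
#' @param rng_seed integer seed.
#' @return character vector of neighbor ids (length `k_samples`, or the full
#'   neighborhood multiplicity described above, or length 0).
#' @export
sample_neighbors <- function(graph, node, relation, k_samples, rng_seed = 1L) {
  relation <- match.arg(relation, .DRH_EDGE_RELATIONS)
  adj <- if (is.list(graph) && !is.null(graph$d2p)) graph else dpd_adjacency(graph)
  if (!is_count(k_samples) || k_samples < 1) drh_stop("k_samples must be >= 1")
  if (relation == "drug_protein") {
    i <- match(node, adj$drug_ids)
    if (is.na(i)) drh_stop("unknown drug node '%s'", node)
    nb <- adj$d2p[[i]]; universe <- adj$protein_ids
  } else {
    i <- match(node, adj$protein_ids)
    if (is.na(i)) drh_stop("unknown protein node '%s'", node)
    nb <- adj$p2d[[i]]; universe <- adj$drug_ids
  }
  deg <- length(nb)
  if (deg == 0L) return(character(0))
  idx <- if (k_samples >= deg) {
    if (k_samples %% deg == 0L) rep(nb, each = k_samples %/% deg) else nb
  } else {
    with_seed(rng_seed, sample(nb, k_samples, replace = TRUE))
  }
  universe[idx]
}

#' Mean aggregation of neighbor features
#'
#' Element-wise mean of the (inverted-dropout-masked) neighbor feature
#' vectors; an empty neighbor list aggregates to the zero vector. Dropout is
#' applied only when `train = TRUE` (surviving entries scaled by `1/(1-p)`).
#'
#' @param neighbor_features list of equal-length numeric vectors (or a matrix
#'   with one row per neighbor).
#' @param dropout_p dropout probability in `[0, 1)`.
#' @param dim expected feature dimension, required when the list is empty.
#' @param train apply dropout?
#' @return numeric vector of length `dim`.
#' @export
aggregate_neighbors <- function(neighbor_features, dropout_p = 0, dim = NULL,
                                train = FALSE) {
  if (is.matrix(neighbor_features))
    neighbor_features <- lapply(seq_len(nrow(neighbor_features)),
                                function(i) neighbor_features[i, ])
  if (!length(neighbor_features)) {
    if (is.null(dim)) drh_stop("dim is required for an empty neighbor list")
    return(numeric(dim))
  }
  lens <- vapply(neighbor_features, length, integer(1))
  if (length(unique(lens)) != 1L)
    drh_stop("neighbor feature vectors have mixed dimensions: %s",
             paste(unique(lens), collapse = ", "))
  M <- do.call(rbind, neighbor_features)
  if (train && dropout_p > 0) {
    mask <- matrix(rbinom(length(M), 1L, 1 - dropout_p), nrow(M)) / (1 - dropout_p)
    M <- M * mask
  }
  colMeans(M)
}

.activate <- function(Z, activation) {
  switch(activation,
         relu = pmax(Z, 0),
         identity = Z,
         drh_stop("unknown activation '%s'", activation))
}

.activate_grad <- function(Z, activation) {
  switch(activation,
         relu = (Z > 0) * 1,
         identity = array(1, dim(Z)),
         drh_stop("unknown activation '%s'", activation))
}

.init_weight <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' Construct a HinSAGE layer
#'
#' @param input_dims named numeric vector: input feature dimension per node
#'   type (`drug`, `protein`).
#' @param d_out output dimension.
#' @param activation `"relu"` or `"identity"`.
#' @param combine `"sum"` (full-width self and neighbor matrices, consistent
#'   with the `(T_v + R_e) d_k d_{k-1} + d_k` parameter count) or `"concat"`
#'   (half-width matrices whose outputs are concatenated; `d_out` must be
#'   even).
#' @return a `hinsage_layer` list.
#' @export
hinsage_layer <- function(input_dims, d_out, activation = "relu",
                          combine = c("sum", "concat")) {
  combine <- match.arg(combine)
  if (combine == "concat" && d_out %% 2 != 0)
    drh_stop("concat combine requires an even output dimension")
  w <- if (combine == "concat") d_out %/% 2 else d_out
  W_self <- list(drug = .init_weight(input_dims[["drug"]], w),
                 protein = .init_weight(input_dims[["protein"]], w))
  # neighbor input dim is the dim of the *target* type of the relation
  W_neigh <- list(drug_protein = .init_weight(input_dims[["protein"]], w),
                  protein_drug = .init_weight(input_dims[["drug"]], w))
  structure(list(W_self = W_self, W_neigh = W_neigh, b = numeric(d_out),
                 d_in = input_dims, d_out = d_out, activation = activation,
                 combine = combine),
            class = "hinsage_layer")
}

#' Trainable parameters of an HinSAGE layer stack
#'
#' Closed form `(T_v + R_e) * d_k * d_prev + d_k`: one self weight matrix per
#' node type, one neighbor weight matrix per relation tuple, one shared bias.
#'
#' @param T_v number of node types.
#' @param R_e number of relation types.
#' @param d_k layer output dimension.
#' @param d_prev input dimension (assumed equal across types).
#' @return integer parameter count.
#' @export
parameter_count <- function(T_v, R_e, d_k, d_prev) {
  for (a in c(T_v, R_e, d_k, d_prev))
    if (!is_count(a) || a <= 0) drh_stop("all arguments must be positive integers")
  (T_v + R_e) * d_k * d_prev + d_k
}

#' Enumerate the stored parameters of a layer or model
#' @param x a `hinsage_layer` or `hinsage_model`.
#' @return total number of weight and bias entries.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "hinsage_model"))
    return(sum(vapply(x$layers, count_parameters, numeric(1))))
  sum(vapply(c(x$W_self, x$W_neigh), length, numeric(1))) + length(x$b)
}

#' Construct a HinSAGE model
#'
#' @param input_dims named vector of input feature dims per node type.
#' @param dims output dimension of each layer (the last entry is the node
#'   embedding dimension).
#' @param neighbor_samples per-layer neighbor sample sizes (same length as
#'   `dims`); `Inf` means the full neighborhood.
#' @param dropout_p dropout probability applied in training mode.
#' @param combine layer combine mode, see [hinsage_layer()].
#' @param seed initialization seed.
#' @return a `hinsage_model` list.
#' @export
hinsage_model <- function(input_dims, dims = c(256, 256),
                          neighbor_samples = c(8, 4), dropout_p = 0.1,
                          combine = "sum", seed = 1L) {
  if (length(neighbor_samples) != length(dims))
    drh_stop("neighbor_samples must have one entry per layer")
  if (!(dropout_p >= 0 && dropout_p < 1)) drh_stop("dropout_p must be in [0, 1)")
  layers <- with_seed(seed, {
    ins <- input_dims
    lapply(seq_along(dims), function(k) {
      act <- if (k == length(dims)) "identity" else "relu"
      lay <- hinsage_layer(ins, dims[k], activation = act, combine = combine)
      ins <<- c(drug = dims[k], protein = dims[k])
      lay
    })
  })
  structure(list(layers = layers, neighbor_samples = neighbor_samples,
                 dropout_p = dropout_p, combine = combine,
                 input_dims = input_dims, dims = dims,
                 T_v = 2L, R_e = 2L, seed = seed),
            class = "hinsage_model")
}

#' Forward pass of one HinSAGE layer for a single node
#'
#' @param layer a [hinsage_layer()].
#' @param node_type `"drug"` or `"protein"`.
#' @param h_self input feature vector of the node.
#' @param aggregates named list (by relation) of aggregated neighbor vectors.
#' @param train_mode apply dropout to the self term?
#' @param dropout_p dropout probability (training mode only).
#' @return output vector of length `layer$d_out`.
#' @export
layer_forward <- function(layer, node_type, h_self, aggregates,
                          train_mode = FALSE, dropout_p = 0) {
  if (length(h_self) != layer$d_in[[node_type]])
    drh_stop("h_self has dim %d, expected %d", length(h_self), layer$d_in[[node_type]])
  rels <- if (node_type == "drug") "drug_protein" else "protein_drug"
  miss <- setdiff(names(aggregates), names(layer$W_neigh))
  if (length(miss)) drh_stop("missing relation weight for: %s", paste(miss, collapse = ", "))
  x <- h_self
  if (train_mode && dropout_p > 0)
    x <- x * (rbinom(length(x), 1L, 1 - dropout_p) / (1 - dropout_p))
  self_part <- drop(x %*% layer$W_self[[node_type]])
  nb_part <- 0
  for (r in names(aggregates)) {
    a <- aggregates[[r]]
    if (length(a) != nrow(layer$W_neigh[[r]]))
      drh_stop("aggregate for '%s' has dim %d, expected %d",
               r, length(a), nrow(layer$W_neigh[[r]]))
    nb_part <- nb_part + drop(a %*% layer$W_neigh[[r]])
  }
  if (length(nb_part) == 1L && identical(nb_part, 0))
    nb_part <- numeric(ncol(layer$W_self[[node_type]]))
  z <- if (layer$combine == "concat") c(self_part, nb_part) + layer$b
       else self_part + nb_part + layer$b
  .activate(z, layer$activation)
}

# ---- vectorized full-graph propagation with per-layer neighbor sampling ----

# Row-stochastic sampled mean operator (n_src x n_tgt). k = Inf or k >= degree
# gives the exact mean; otherwise k draws with replacement.
.mean_operator <- function(adj_list, n_src, n_tgt, k) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (v in seq_len(n_src)) {
    nb <- adj_list[[v]]
    deg <- length(nb)
    if (deg == 0L) next
    if (is.infinite(k) || k >= deg) {
      ii <- c(ii, rep.int(v, deg)); jj <- c(jj, nb); xx <- c(xx, rep.int(1 / deg, deg))
    } else {
      s <- sample(nb, k, replace = TRUE)
      tb <- table(s)
      cols <- as.integer(names(tb))
      ii <- c(ii, rep.int(v, length(cols))); jj <- c(jj, cols)
      xx <- c(xx, as.numeric(tb) / k)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_src, n_tgt))
}

.dropout_mask <- function(n, d, p) {
  matrix(rbinom(n * d, 1L, 1 - p), n, d) / (1 - p)
}

# Full forward pass over all nodes. Returns final embeddings and, if
# keep_cache, everything needed for backpropagation.
.hinsage_forward <- function(model, adj, X_d, X_p, train_mode = FALSE,
                             exact = FALSE, seed = 1L, keep_cache = FALSE) {
  n_d <- nrow(X_d); n_p <- nrow(X_p)
  H_d <- unname(as.matrix(X_d)); H_p <- unname(as.matrix(X_p))
  p <- if (train_mode) model$dropout_p else 0
  cache <- list()
  with_seed(seed, {
    for (k in seq_along(model$layers)) {
      lay <- model$layers[[k]]
      ks <- if (exact) Inf else model$neighbor_samples[k]
      A_d <- .mean_operator(adj$d2p, n_d, n_p, ks)   # drug <- protein neighbors
      A_p <- .mean_operator(adj$p2d, n_p, n_d, ks)
      if (p > 0) {
        m_d_self <- .dropout_mask(n_d, ncol(H_d), p)
        m_p_self <- .dropout_mask(n_p, ncol(H_p), p)
        m_p_nb <- .dropout_mask(n_p, ncol(H_p), p)
        m_d_nb <- .dropout_mask(n_d, ncol(H_d), p)
      } else {
        m_d_self <- m_p_self <- m_p_nb <- m_d_nb <- NULL
      }
      Xd_s <- if (is.null(m_d_self)) H_d else H_d * m_d_self
      Xp_s <- if (is.null(m_p_self)) H_p else H_p * m_p_self
      Agg_d <- as.matrix(A_d %*% (if (is.null(m_p_nb)) H_p else H_p * m_p_nb))
      Agg_p <- as.matrix(A_p %*% (if (is.null(m_d_nb)) H_d else H_d * m_d_nb))
      w <- ncol(lay$W_self$drug)
      d_out <- lay$d_out
      if (lay$combine == "concat") {
        Zd <- cbind(Xd_s %*% lay$W_self$drug, Agg_d %*% lay$W_neigh$drug_protein)
        Zp <- cbind(Xp_s %*% lay$W_self$protein, Agg_p %*% lay$W_neigh$protein_drug)
      } else {
        Zd <- Xd_s %*% lay$W_self$drug + Agg_d %*% lay$W_neigh$drug_protein
        Zp <- Xp_s %*% lay$W_self$protein + Agg_p %*% lay$W_neigh$protein_drug
      }
      Zd <- sweep(Zd, 2, lay$b, `+`); Zp <- sweep(Zp, 2, lay$b, `+`)
      if (keep_cache)
        cache[[k]] <- list(H_d = H_d, H_p = H_p, Zd = Zd, Zp = Zp,
                           A_d = A_d, A_p = A_p, Agg_d = Agg_d, Agg_p = Agg_p,
                           m_d_self = m_d_self, m_p_self = m_p_self,
                           m_p_nb = m_p_nb, m_d_nb = m_d_nb)
      H_d <- .activate(Zd, lay$activation)
      H_p <- .activate(Zp, lay$activation)
    }
  })
  list(H_d = H_d, H_p = H_p, cache = cache)
}

# Backward pass matching .hinsage_forward(keep_cache = TRUE).
# dH_d / dH_p: gradients w.r.t. final embeddings. Returns per-layer gradient
# structures mirroring model$layers.
.hinsage_backward <- function(model, fwd, dH_d, dH_p) {
  grads <- vector("list", length(model$layers))
  for (k in rev(seq_along(model$layers))) {
    lay <- model$layers[[k]]
    cc <- fwd$cache[[k]]
    dZd <- dH_d * .activate_grad(cc$Zd, lay$activation)
    dZp <- dH_p * .activate_grad(cc$Zp, lay$activation)
    w <- ncol(lay$W_self$drug)
    if (lay$combine == "concat") {
      dZd_s <- dZd[, seq_len(w), drop = FALSE]
      dZd_n <- dZd[, w + seq_len(w), drop = FALSE]
      dZp_s <- dZp[, seq_len(w), drop = FALSE]
      dZp_n <- dZp[, w + seq_len(w), drop = FALSE]
    } else {
      dZd_s <- dZd_n <- dZd
      dZp_s <- dZp_n <- dZp
    }
    Xd_s <- if (is.null(cc$m_d_self)) cc$H_d else cc$H_d * cc$m_d_self
    Xp_s <- if (is.null(cc$m_p_self)) cc$H_p else cc$H_p * cc$m_p_self
    g <- list(
      W_self = list(drug = crossprod(Xd_s, dZd_s),
                    protein = crossprod(Xp_s, dZp_s)),
      W_neigh = list(drug_protein = crossprod(cc$Agg_d, dZd_n),
                     protein_drug = crossprod(cc$Agg_p, dZp_n)),
      b = colSums(dZd) + colSums(dZp)
    )
    grads[[k]] <- g
    if (k > 1L) {
      dHd_in <- tcrossprod(dZd_s, lay$W_self$drug)
      if (!is.null(cc$m_d_self)) dHd_in <- dHd_in * cc$m_d_self
      dHp_in <- tcrossprod(dZp_s, lay$W_self$protein)
      if (!is.null(cc$m_p_self)) dHp_in <- dHp_in * cc$m_p_self
      dAgg_d <- tcrossprod(dZd_n, lay$W_neigh$drug_protein)
      dAgg_p <- tcrossprod(dZp_n, lay$W_neigh$protein_drug)
      back_p <- as.matrix(Matrix::crossprod(cc$A_d, dAgg_d))
      if (!is.null(cc$m_p_nb)) back_p <- back_p * cc$m_p_nb
      back_d <- as.matrix(Matrix::crossprod(cc$A_p, dAgg_p))
      if (!is.null(cc$m_d_nb)) back_d <- back_d * cc$m_d_nb
      dH_d <- dHd_in + back_d
      dH_p <- dHp_in + back_p
    }
  }
  grads
}

#' Encode nodes with a HinSAGE model
#'
#' Runs the layer stack (sample -> aggregate -> update) over the DPD graph and
#' returns the final embeddings of the requested nodes. Deterministic given
#' `seed` with `train_mode = FALSE`.
#'
#' @param model a [hinsage_model()].
#' @param graph a [dpd_graph()].
#' @param features named list of `node_features` (from [compact_features()] or
#'   [read_features()]); row names must cover the graph's nodes.
#' @param nodes named list with character vectors `drug` and/or `protein`;
#'   default: all nodes of the feature matrices.
#' @param train_mode apply dropout?
#' @param exact use full neighborhoods instead of sampled ones.
#' @param seed RNG seed for sampling and dropout.
#' @return named list of embedding matrices (rows named by node id).
#' @export
encode_nodes <- function(model, graph, features, nodes = NULL,
                         train_mode = FALSE, exact = FALSE, seed = 1L) {
  X_d <- features$drug$matrix; X_p <- features$protein$matrix
  if (is.null(rownames(X_d)) || is.null(rownames(X_p)))
    drh_stop("feature matrices must have node ids as row names")
  bad_d <- setdiff(unique(graph$drug), rownames(X_d))
  bad_p <- setdiff(unique(graph$protein), rownames(X_p))
  if (length(bad_d) || length(bad_p))
    drh_stop("graph nodes missing from features: %s",
             paste(head(c(bad_d, bad_p), 5), collapse = ", "))
  adj <- dpd_adjacency(graph, rownames(X_d), rownames(X_p))
  fwd <- .hinsage_forward(model, adj, X_d, X_p, train_mode = train_mode,
                          exact = exact, seed = seed)
  rownames(fwd$H_d) <- rownames(X_d); rownames(fwd$H_p) <- rownames(X_p)
  nodes <- nodes %||% list(drug = rownames(X_d), protein = rownames(X_p))
  out <- list()
  if (!is.null(nodes$drug)) {
    miss <- setdiff(nodes$drug, rownames(X_d))
    if (length(miss)) drh_stop("unknown drug node(s): %s", paste(head(miss, 5), collapse = ", "))
    out$drug <- fwd$H_d[nodes$drug, , drop = FALSE]
  }
  if (!is.null(nodes$protein)) {
    miss <- setdiff(nodes$protein, rownames(X_p))
    if (length(miss)) drh_stop("unknown protein node(s): %s", paste(head(miss, 5), collapse = ", "))
    out$protein <- fwd$H_p[nodes$protein, , drop = FALSE]
  }
  out
}
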