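#' Combine node embeddings into an edge embedding
#'
#' @param h_drug,h_protein embedding vectors (matrices with matching row
#'   counts are combined row-wise).
#' @param mode `"concat"`, `"hadamard"` or `"average"`; the latter two require
#'   equal dimensions.
#' @return edge embedding vector (or matrix).
#' @export
edge_embed <- function(h_drug, h_protein, mode = c("concat", "hadamard", "average")) {
  mode <- match.arg(mode)
  vec <- !is.matrix(h_drug)
  if (vec) { h_drug <- rbind(h_drug); h_protein <- rbind(h_protein) }
  if (mode != "concat" && ncol(h_drug) != ncol(h_protein))
    drh_stop("mode '%s' requires equal embedding dimensions (%d vs %d)",
             mode, ncol(h_drug), ncol(h_protein))
  out <- switch(mode,
                concat = cbind(h_drug, h_protein),
                hadamard = h_drug * h_protein,
                average = (h_drug + h_protein) / 2)
  if (vec) drop(out) else out
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Initialize the classification head
#'
#' A single dense softmax layer over the edge embedding (the default head); a
#' deeper head is possible by stacking, but one layer is the canonical
#' configuration.
#'
#' @param edge_dim edge embedding dimension.
#' @param classes character vector: the label vocabulary.
#' @param combine_mode edge combination mode, see [edge_embed()].
#' @param seed initialization seed.
#' @return an `edge_head` list with `W`, `b`, `classes`, `combine_mode`.
#' @export
edge_head <- function(edge_dim, classes, combine_mode = "concat", seed = 1L) {
  if (length(classes) < 2L) drh_stop("need at least 2 classes")
  W <- with_seed(seed, .init_weight(edge_dim, length(classes)))
  structure(list(W = W, b = numeric(length(classes)),
                 classes = as.character(classes), combine_mode = combine_mode),
            class = "edge_head")
}

#' Class probabilities for edge embeddings
#'
#' @param edge_vec edge embedding vector or matrix (rows = edges).
#' @param head an [edge_head()].
#' @return probability vector/matrix over the label vocabulary (rows sum to 1).
#' @export
classify_edge <- function(edge_vec, head) {
  vec <- !is.matrix(edge_vec)
  if (vec) edge_vec <- rbind(edge_vec)
  if (ncol(edge_vec) != nrow(head$W))
    drh_stop("edge embedding has dim %d, head expects %d", ncol(edge_vec), nrow(head$W))
  P <- .softmax_rows(sweep(edge_vec %*% head$W, 2, head$b, `+`))
  colnames(P) <- head$classes
  if (vec) drop(P) else P
}

#' Sample non-interacting negative triples
#'
#' Draws `n` triples whose (drug, protein) pair is uniform over the bipartite
#' complement of the positive pairs (rejection sampling) and whose disease is
#' uniform over the label vocabulary. Deterministic given `rng_seed`.
#'
#' @param graph a [dpd_graph()] of positive triples.
#' @param n number of negatives.
#' @param vocabulary disease labels to sample from (default: the graph's
#'   label vocabulary).
#' @param rng_seed integer seed.
#' @param drug_ids,protein_ids node universes (default: nodes of the graph).
#' @return data.frame (drug, protein, disease) with `is_positive = FALSE`.
#' @export
sample_negative_triples <- function(graph, n, vocabulary = NULL, rng_seed = 1L,
                                    drug_ids = NULL, protein_ids = NULL) {
  vocabulary <- vocabulary %||% attr(graph, "label_vocabulary")
  drug_ids <- drug_ids %||% sort(unique(graph$drug))
  protein_ids <- protein_ids %||% sort(unique(graph$protein))
  n_d <- length(drug_ids); n_p <- length(protein_ids)
  pos_key <- unique(paste(match(graph$drug, drug_ids),
                          match(graph$protein, protein_ids)))
  if (length(pos_key) >= n_d * n_p)
    drh_stop("complement is empty: all drug-protein pairs are positive")
  with_seed(rng_seed, {
    di <- integer(0); pj <- integer(0)
    while (length(di) < n) {
      m <- max(2L * (n - length(di)), 16L)
      cd <- sample.int(n_d, m, replace = TRUE)
      cp <- sample.int(n_p, m, replace = TRUE)
      ok <- !(paste(cd, cp) %in% pos_key)
      di <- c(di, cd[ok]); pj <- c(pj, cp[ok])
    }
    di <- di[seq_len(n)]; pj <- pj[seq_len(n)]
    dis <- sample(vocabulary, n, replace = TRUE)
    data.frame(drug = drug_ids[di], protein = protein_ids[pj], disease = dis,
               is_positive = FALSE, stringsAsFactors = FALSE)
  })
}

#' Training configuration
#'
#' Defaults follow the tuned settings: Adam with learning rate 0.001, dropout
#' 0.1, 50 epochs, L2 regularization (coefficient 5e-4), batch size 200, one
#' negative per positive.
#'
#' @param learning_rate Adam step size (> 0; 0 is allowed and performs no
#'   updates, useful as a baseline).
#' @param dropout_p dropout probability.
#' @param l2_coeff L2 penalty coefficient on weight matrices.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size (positive triples per step).
#' @param neg_ratio negatives per positive for AUC evaluation.
#' @param seed master seed for init, batching, sampling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, dropout_p = 0.1,
                         l2_coeff = 5e-4, epochs = 50L, batch_size = 200L,
                         neg_ratio = 1, seed = 1L) {
  if (learning_rate < 0) drh_stop("learning_rate must be >= 0")
  if (epochs < 1) drh_stop("epochs must be >= 1")
  if (neg_ratio <= 0) drh_stop("neg_ratio must be > 0")
  structure(list(learning_rate = learning_rate, dropout_p = dropout_p,
                 l2_coeff = l2_coeff, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), neg_ratio = neg_ratio,
                 optimizer = "adam", seed = as.integer(seed)),
            class = "train_config")
}

# ---- flat parameter list <-> (model, head), and Adam ----

.params_flatten <- function(model, head) {
  out <- list()
  for (k in seq_along(model$layers)) {
    lay <- model$layers[[k]]
    for (tp in names(lay$W_self)) out[[sprintf("L%d.self.%s", k, tp)]] <- lay$W_self[[tp]]
    for (r in names(lay$W_neigh)) out[[sprintf("L%d.neigh.%s", k, r)]] <- lay$W_neigh[[r]]
    out[[sprintf("L%d.b", k)]] <- lay$b
  }
  out[["head.W"]] <- head$W
  out[["head.b"]] <- head$b
  out
}

.params_restore <- function(model, head, flat) {
  for (k in seq_along(model$layers)) {
    for (tp in names(model$layers[[k]]$W_self))
      model$layers[[k]]$W_self[[tp]] <- flat[[sprintf("L%d.self.%s", k, tp)]]
    for (r in names(model$layers[[k]]$W_neigh))
      model$layers[[k]]$W_neigh[[r]] <- flat[[sprintf("L%d.neigh.%s", k, r)]]
    model$layers[[k]]$b <- flat[[sprintf("L%d.b", k)]]
  }
  head$W <- flat[["head.W"]]
  head$b <- flat[["head.b"]]
  list(model = model, head = head)
}

.grads_flatten <- function(layer_grads, gW_head, gb_head) {
  out <- list()
  for (k in seq_along(layer_grads)) {
    g <- layer_grads[[k]]
    for (tp in names(g$W_self)) out[[sprintf("L%d.self.%s", k, tp)]] <- g$W_self[[tp]]
    for (r in names(g$W_neigh)) out[[sprintf("L%d.neigh.%s", k, r)]] <- g$W_neigh[[r]]
    out[[sprintf("L%d.b", k)]] <- g$b
  }
  out[["head.W"]] <- gW_head
  out[["head.b"]] <- gb_head
  out
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# mean cross-entropy of true classes under probabilities P (rows = triples)
.cross_entropy <- function(P, y) {
  -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
}

# inference-mode scores for a set of triples: probability of each triple's
# disease class under the current model + head (exact neighborhoods).
.score_internal <- function(model, head, graph, features, triples, seed = 1L) {
  emb <- encode_nodes(model, graph, features,
                      nodes = list(drug = rownames(features$drug$matrix),
                                   protein = rownames(features$protein$matrix)),
                      train_mode = FALSE, exact = TRUE, seed = seed)
  E <- edge_embed(emb$drug[triples$drug, , drop = FALSE],
                  emb$protein[triples$protein, , drop = FALSE],
                  mode = head$combine_mode)
  P <- classify_edge(E, head)
  y <- match(triples$disease, head$classes)
  if (anyNA(y)) drh_stop("unknown disease label: %s",
                         paste(utils::head(unique(triples$disease[is.na(y)]), 3),
                               collapse = ", "))
  list(P = P, y = y, prob = P[cbind(seq_len(nrow(P)), y)])
}

#' Train the HinSAGE edge classifier
#'
#' Minimizes categorical cross-entropy of the representative disease labels of
#' the positive training triples (plus an L2 penalty on weight matrices) with
#' Adam, recording per-epoch train/validation loss and AUC-ROC, and returns
#' the weights of the best-validation-AUC epoch.
#'
#' The binary AUC is computed from the multi-class head as: score of a triple
#' = predicted probability of its disease class; positives use their true
#' label, negatives their sampled label.
#'
#' @param model a [hinsage_model()].
#' @param head an [edge_head()].
#' @param graph a [dpd_graph()] of positive triples.
#' @param features named list of `node_features`.
#' @param splits list of integer row-index vectors `train`, `val` (and
#'   optionally `test`) partitioning `graph`.
#' @param cfg a [train_config()].
#' @param negatives optional data.frame (drug, protein, disease, split) of
#'   negative triples; sampled internally when `NULL`.
#' @return list with `model`, `head` (best weights), `history` (data.frame
#'   epoch/train_loss/val_loss/train_auc/val_auc), `best_epoch`, `negatives`.
#' @export
train_drhgnn <- function(model, head, graph, features, splits, cfg = train_config(),
                         negatives = NULL) {
  if (length(intersect(splits$train, splits$val)))
    drh_stop("train and validation splits overlap")
  vocab <- head$classes
  if (is.null(negatives)) {
    n_neg <- ceiling(nrow(graph) * cfg$neg_ratio)
    negatives <- sample_negative_triples(graph, n_neg, vocabulary = vocab,
                                         rng_seed = derive_seed(cfg$seed, 11L),
                                         drug_ids = rownames(features$drug$matrix),
                                         protein_ids = rownames(features$protein$matrix))
    # split negatives in proportion to the positive splits
    n_pos <- nrow(graph)
    n_tr <- round(n_neg * length(splits$train) / n_pos)
    n_va <- round(n_neg * length(splits$val) / n_pos)
    n_te <- max(n_neg - n_tr - n_va, 0L)
    labels <- rep(c("train", "val", "test"), times = c(n_tr, n_va, n_te))
    negatives$split <- with_seed(derive_seed(cfg$seed, 12L),
                                 sample(labels))[seq_len(n_neg)]
  }
  adj_graph <- graph
  tr_pos <- graph[splits$train, , drop = FALSE]
  va_pos <- graph[splits$val, , drop = FALSE]
  tr_neg <- negatives[negatives$split == "train", , drop = FALSE]
  va_neg <- negatives[negatives$split == "val", , drop = FALSE]
  y_all <- match(graph$disease, vocab)
  if (anyNA(y_all)) drh_stop("graph contains labels outside the head vocabulary")

  X_d <- features$drug$matrix; X_p <- features$protein$matrix
  adj <- dpd_adjacency(adj_graph, rownames(X_d), rownames(X_p))
  di_all <- match(graph$drug, rownames(X_d))
  pj_all <- match(graph$protein, rownames(X_p))

  flat <- .params_flatten(model, head)
  state <- .adam_init(flat)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), train_auc = numeric(0),
                        val_auc = numeric(0))
  best <- list(auc = -Inf, flat = flat, epoch = 0L)

  eval_epoch <- function(model, head, epoch) {
    sc_tr <- .score_internal(model, head, adj_graph, features, tr_pos)
    sc_va <- .score_internal(model, head, adj_graph, features, va_pos)
    sc_trn <- .score_internal(model, head, adj_graph, features, tr_neg)
    sc_van <- .score_internal(model, head, adj_graph, features, va_neg)
    data.frame(
      epoch = epoch,
      train_loss = .cross_entropy(sc_tr$P, sc_tr$y),
      val_loss = .cross_entropy(sc_va$P, sc_va$y),
      train_auc = auc_roc(c(sc_tr$prob, sc_trn$prob),
                          c(rep(1L, length(sc_tr$prob)), rep(0L, length(sc_trn$prob)))),
      val_auc = auc_roc(c(sc_va$prob, sc_van$prob),
                        c(rep(1L, length(sc_va$prob)), rep(0L, length(sc_van$prob))))
    )
  }

  n_train <- length(splits$train)
  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- with_seed(derive_seed(cfg$seed, 100L + epoch),
                           sample(splits$train))
    batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      bseed <- derive_seed(cfg$seed, 10000L + epoch * 100L + bi)
      cur <- .params_restore(model, head, flat)
      fwd <- .hinsage_forward(cur$model, adj, X_d, X_p,
                              train_mode = TRUE, seed = bseed, keep_cache = TRUE)
      di <- di_all[idx]; pj <- pj_all[idx]; y <- y_all[idx]
      Hd_b <- fwd$H_d[di, , drop = FALSE]
      Hp_b <- fwd$H_p[pj, , drop = FALSE]
      E <- edge_embed(Hd_b, Hp_b, mode = cur$head$combine_mode)
      P <- .softmax_rows(sweep(E %*% cur$head$W, 2, cur$head$b, `+`))
      B <- length(idx)
      dLogit <- P
      dLogit[cbind(seq_len(B), y)] <- dLogit[cbind(seq_len(B), y)] - 1
      dLogit <- dLogit / B
      gW_head <- crossprod(E, dLogit)
      gb_head <- colSums(dLogit)
      dE <- tcrossprod(dLogit, cur$head$W)
      d_emb <- ncol(Hd_b)
      if (cur$head$combine_mode == "concat") {
        dHd_b <- dE[, seq_len(d_emb), drop = FALSE]
        dHp_b <- dE[, d_emb + seq_len(ncol(Hp_b)), drop = FALSE]
      } else if (cur$head$combine_mode == "hadamard") {
        dHd_b <- dE * Hp_b; dHp_b <- dE * Hd_b
      } else {
        dHd_b <- dE / 2; dHp_b <- dE / 2
      }
      dH_d <- matrix(0, nrow(fwd$H_d), ncol(fwd$H_d))
      dH_p <- matrix(0, nrow(fwd$H_p), ncol(fwd$H_p))
      for (b in seq_len(B)) {    # scatter-add (duplicate nodes accumulate)
        dH_d[di[b], ] <- dH_d[di[b], ] + dHd_b[b, ]
        dH_p[pj[b], ] <- dH_p[pj[b], ] + dHp_b[b, ]
      }
      lgrads <- .hinsage_backward(cur$model, fwd, dH_d, dH_p)
      grads <- .grads_flatten(lgrads, gW_head, gb_head)
      if (cfg$l2_coeff > 0) {
        for (nm in names(grads)) {
          if (!grepl("\\.b$", nm))
            grads[[nm]] <- grads[[nm]] + cfg$l2_coeff * flat[[nm]]
        }
      }
      if (cfg$learning_rate > 0) {
        upd <- .adam_step(flat, grads, state, cfg$learning_rate)
        flat <- upd$flat; state <- upd$state
      }
      if (any(!vapply(flat, function(x) all(is.finite(x)), logical(1))))
        drh_stop("training diverged (non-finite weights) at epoch %d", epoch)
    }
    cur <- .params_restore(model, head, flat)
    row <- eval_epoch(cur$model, cur$head, epoch)
    if (!all(is.finite(unlist(row[-1]))))
      drh_stop("training diverged (non-finite loss) at epoch %d", epoch)
    history <- rbind(history, row)
    if (row$val_auc > best$auc) best <- list(auc = row$val_auc, flat = flat, epoch = epoch)
    drh_msg("epoch %d: train_loss %.4f val_loss %.4f train_auc %.3f val_auc %.3f",
            epoch, row$train_loss, row$val_loss, row$train_auc, row$val_auc)
  }
  final <- .params_restore(model, head, best$flat)
  list(model = final$model, head = final$head, history = history,
       best_epoch = best$epoch, negatives = negatives)
}

#' Score drug-protein-disease triples
#'
#' Probability of each triple's disease class for its drug-protein edge, from
#' the trained model and head, using full (unsampled) neighborhoods; fully
#' deterministic.
#'
#' @param model,head trained components as returned by [train_drhgnn()].
#' @param graph the positive [dpd_graph()] defining message-passing edges.
#' @param triples data.frame with columns drug, protein, disease.
#' @param features named list of `node_features`.
#' @return data.frame of `TripleScore`s: drug, protein, disease, probability,
#'   is_positive (pair membership in `graph`).
#' @export
score_triples <- function(model, head, graph, triples, features) {
  sc <- .score_internal(model, head, graph, features, triples)
  pos_key <- paste(graph$drug, graph$protein, sep = "\r")
  data.frame(drug = triples$drug, protein = triples$protein,
             disease = triples$disease, probability = sc$prob,
             is_positive = paste(triples$drug, triples$protein, sep = "\r") %in% pos_key,
             stringsAsFactors = FALSE)
}
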