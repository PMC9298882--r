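#' Repeated shuffle splits
#'
#' Each repeat shuffles the triples with seed `base_seed + i - 1` and cuts at
#' floor boundaries into train/validation/test; the remainder goes to train.
#'
#' @param n_triples number of triples (or a [dpd_graph()]).
#' @param ratios length-3 numeric (train, val, test) summing to 1.
#' @param n_repeats number of repeats.
#' @param base_seed integer seed of the first repeat.
#' @return object of class `split_spec`: list with `ratios`, `n_repeats`,
#'   `seeds` and `assignment` (per repeat, a list of integer index vectors
#'   `train`, `val`, `test` partitioning `1:n`).
#' @export
make_splits <- function(n_triples, ratios = c(0.6, 0.2, 0.2), n_repeats = 5L,
                        base_seed = 1L) {
  if (inherits(n_triples, "data.frame")) n_triples <- nrow(n_triples)
  if (abs(sum(ratios) - 1) > 1e-9) drh_stop("split ratios must sum to 1")
  if (any(ratios <= 0)) drh_stop("split ratios must be positive")
  if (n_triples < 5L) drh_stop("need at least 5 triples to split")
  seeds <- base_seed + seq_len(n_repeats) - 1L
  n_va <- floor(n_triples * ratios[2])
  n_te <- floor(n_triples * ratios[3])
  n_tr <- n_triples - n_va - n_te
  assignment <- lapply(seeds, function(s) {
    perm <- with_seed(s, sample.int(n_triples))
    list(train = sort(perm[seq_len(n_tr)]),
         val = sort(perm[n_tr + seq_len(n_va)]),
         test = sort(perm[n_tr + n_va + seq_len(n_te)]))
  })
  structure(list(ratios = ratios, n_repeats = as.integer(n_repeats),
                 seeds = seeds, assignment = assignment, n = n_triples),
            class = "split_spec")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs where the positive outscores the
#' negative, ties counted 1/2; computed via the rank statistic.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = positive).
#' @return AUC-ROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) drh_stop("scores and labels differ in length")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    drh_stop("auc_roc requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) summation over descending distinct
#' score thresholds: `sum_k (R_k - R_{k-1}) * P_k`. The chance baseline equals
#' the positive prevalence.
#'
#' @inheritParams auc_roc
#' @return AUPR in `(0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) drh_stop("scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L || sum(labels == 0L) == 0L)
    drh_stop("auc_pr requires both classes to be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into one threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  TP <- tp[last]; FP <- fp[last]
  P <- TP / (TP + FP); R <- TP / n_pos
  sum(diff(c(0, R)) * P)
}

#' ROC / precision-recall curve points
#' @inheritParams auc_roc
#' @return data.frame of curve coordinates over descending thresholds.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], tpr = tp / sum(labels == 1L),
             fpr = fp / sum(labels == 0L))
}

#' @rdname roc_points
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  data.frame(threshold = s[last], recall = tp / sum(labels == 1L),
             precision = tp / (tp + fp))
}

#' Repeated train/evaluate protocol
#'
#' The canonical protocol shuffles the positive triples `n_repeats` times into
#' 60/20/20 train/validation/test parts (seeded), trains the HinSAGE edge
#' classifier per repeat, scores the repeat's test positives plus matched
#' negatives, and aggregates AUC-ROC / AUPR as mean and standard deviation.
#' `protocol = "cv5"` instead uses standard 5-fold test partitions with an
#' inner 75/25 train/validation split of each fold's complement.
#'
#' @param graph a [dpd_graph()] of positive triples.
#' @param features named list of `node_features` covering the graph.
#' @param cfg a [train_config()]; negatives are resampled per repeat from the
#'   repeat's seed.
#' @param model_args list of arguments for [hinsage_model()] (`dims`,
#'   `neighbor_samples`, `combine`); input dims and dropout come from the
#'   features and `cfg`.
#' @param ratios train/val/test fractions (shuffle protocol).
#' @param n_repeats number of repeats (folds for `cv5`).
#' @param base_seed seed of the first repeat.
#' @param protocol `"shuffle"` or `"cv5"`.
#' @return object of class `eval_report`: list with `per_repeat` (data.frame
#'   repeat/auc_roc/auc_pr/best_epoch), `mean` and `sd` per metric, and the
#'   config snapshot.
#' @export
run_protocol <- function(graph, features, cfg = train_config(),
                         model_args = list(dims = c(256, 256),
                                           neighbor_samples = c(8, 4)),
                         ratios = c(0.6, 0.2, 0.2), n_repeats = 5L,
                         base_seed = 1L, protocol = c("shuffle", "cv5")) {
  protocol <- match.arg(protocol)
  n <- nrow(graph)
  vocab <- attr(graph, "label_vocabulary")
  if (protocol == "shuffle") {
    spec <- make_splits(n, ratios, n_repeats, base_seed)
    splits_list <- spec$assignment
  } else {
    folds <- with_seed(base_seed, sample(rep_len(seq_len(n_repeats), n)))
    splits_list <- lapply(seq_len(n_repeats), function(i) {
      test <- which(folds == i)
      rest <- which(folds != i)
      n_va <- floor(length(rest) * 0.25)
      perm <- with_seed(base_seed + i, sample(rest))
      list(train = sort(perm[-seq_len(n_va)]), val = sort(perm[seq_len(n_va)]),
           test = sort(test))
    })
  }
  per <- lapply(seq_along(splits_list), function(i) {
    splits <- splits_list[[i]]
    seed_i <- derive_seed(base_seed, 1000L + i)
    cfg_i <- cfg; cfg_i$seed <- seed_i
    input_dims <- c(drug = ncol(features$drug$matrix),
                    protein = ncol(features$protein$matrix))
    model <- do.call(hinsage_model, c(list(input_dims = input_dims,
                                           dropout_p = cfg$dropout_p,
                                           seed = derive_seed(seed_i, 1L)),
                                      model_args))
    d_emb <- model$dims[length(model$dims)]
    head_obj <- edge_head(2L * d_emb, vocab, combine_mode = "concat",
                          seed = derive_seed(seed_i, 2L))
    fit <- train_drhgnn(model, head_obj, graph, features, splits, cfg_i)
    neg_te <- fit$negatives[fit$negatives$split == "test", , drop = FALSE]
    te_pos <- graph[splits$test, , drop = FALSE]
    sc_pos <- .score_internal(fit$model, fit$head, graph, features, te_pos)
    sc_neg <- .score_internal(fit$model, fit$head, graph, features, neg_te)
    scores <- c(sc_pos$prob, sc_neg$prob)
    labels <- c(rep(1L, length(sc_pos$prob)), rep(0L, length(sc_neg$prob)))
    data.frame(rep = i, auc_roc = auc_roc(scores, labels),
               auc_pr = auc_pr(scores, labels), best_epoch = fit$best_epoch)
  })
  per <- do.call(rbind, per)
  report <- list(
    per_repeat = per,
    mean = list(auc_roc = mean(per$auc_roc), auc_pr = mean(per$auc_pr)),
    sd = list(auc_roc = if (nrow(per) > 1) sd(per$auc_roc) else 0,
              auc_pr = if (nrow(per) > 1) sd(per$auc_pr) else 0),
    best = list(auc_roc = max(per$auc_roc), auc_pr = max(per$auc_pr)),
    config = list(train = unclass(cfg), model = model_args, ratios = ratios,
                  n_repeats = n_repeats, base_seed = base_seed,
                  protocol = protocol)
  )
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%d repeats, %s protocol): AUC-ROC %.4f +/- %.4f, AUPR %.4f +/- %.4f\n",
              nrow(x$per_repeat), x$config$protocol,
              x$mean$auc_roc, x$sd$auc_roc, x$mean$auc_pr, x$sd$auc_pr))
  invisible(x)
}

#' Learning-rate / dropout grid
#'
#' One [run_protocol()] evaluation per (learning rate, dropout) cell; returns
#' a long-format table of mean AUC-ROC per cell.
#'
#' @param graph,features,model_args,ratios,n_repeats,base_seed as in
#'   [run_protocol()].
#' @param lr_list,dropout_list grid values.
#' @param epochs epochs per cell.
#' @param cfg base [train_config()] supplying the remaining settings.
#' @return data.frame with columns learning_rate, dropout, auc_roc, auc_pr.
#' @export
hyperparameter_grid <- function(graph, features, lr_list, dropout_list,
                                epochs = 50L, cfg = train_config(),
                                model_args = list(dims = c(256, 256),
                                                  neighbor_samples = c(8, 4)),
                                ratios = c(0.6, 0.2, 0.2), n_repeats = 1L,
                                base_seed = 1L) {
  if (!length(lr_list) || !length(dropout_list)) drh_stop("empty hyperparameter grid")
  rows <- list()
  for (lr in lr_list) for (dp in dropout_list) {
    cfg_i <- cfg
    cfg_i$learning_rate <- lr; cfg_i$dropout_p <- dp; cfg_i$epochs <- as.integer(epochs)
    rep_i <- run_protocol(graph, features, cfg_i, model_args, ratios,
                          n_repeats, base_seed)
    rows[[length(rows) + 1L]] <- data.frame(learning_rate = lr, dropout = dp,
                                            auc_roc = rep_i$mean$auc_roc,
                                            auc_pr = rep_i$mean$auc_pr)
  }
  do.call(rbind, rows)
}
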