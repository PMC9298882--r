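test_that("shuffle splits cut at floor boundaries with the remainder to train", {
  s10 <- make_splits(10, c(0.6, 0.2, 0.2), n_repeats = 2, base_seed = 1)
  sizes <- vapply(s10$assignment[[1]], length, integer(1))
  expect_equal(unname(sizes), c(6L, 2L, 2L))
  s11 <- make_splits(11, c(0.6, 0.2, 0.2), n_repeats = 1, base_seed = 1)
  expect_equal(unname(vapply(s11$assignment[[1]], length, integer(1))),
               c(7L, 2L, 2L))
  # determinism and partition property
  s10b <- make_splits(10, c(0.6, 0.2, 0.2), n_repeats = 2, base_seed = 1)
  expect_identical(s10, s10b)
  for (rep in s10$assignment) {
    all_idx <- sort(c(rep$train, rep$val, rep$test))
    expect_equal(all_idx, 1:10)
  }
  # distinct repeats shuffle differently
  expect_false(identical(s10$assignment[[1]], s10$assignment[[2]]))
  expect_error(make_splits(10, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(make_splits(3), "at least 5")
})

test_that("auc_roc matches hand-enumerated concordance", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  # pairs: (0.9 vs 0.6) +, (0.9 vs 0.1) +, (0.3 vs 0.6) -, (0.3 vs 0.1) + => 3/4
  expect_equal(auc_roc(c(0.9, 0.3, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_roc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_roc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auc_roc equals the exhaustive pairwise oracle and is rank-invariant", {
  pairwise_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    total <- 0
    for (a in pos) for (b in neg)
      total <- total + (a > b) + 0.5 * (a == b)
    total / (length(pos) * length(neg))
  }
  for (seed in 1:20) {
    xy <- drhgnn:::with_seed(seed, {
      n <- sample(10:60, 1)
      list(s = round(runif(n), 2),   # rounding forces ties
           y = rbinom(n, 1, 0.4))
    })
    if (length(unique(xy$y)) < 2) next
    a <- auc_roc(xy$s, xy$y)
    expect_equal(a, pairwise_oracle(xy$s, xy$y), tolerance = 1e-12)
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(auc_roc(exp(3 * xy$s), xy$y), a, tolerance = 1e-12)
    expect_equal(auc_roc(rank(xy$s, ties.method = "average"), xy$y), a,
                 tolerance = 1e-12)
  }
})

test_that("auc_pr handles perfect, single-positive and chance regimes", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_pr(c(0.99, 0.5, 0.4, 0.3, 0.2), c(1, 0, 0, 0, 0)), 1.0)
  # random scores: AP concentrates near the positive prevalence
  xy <- drhgnn:::with_seed(5, list(s = runif(4000), y = rbinom(4000, 1, 0.3)))
  expect_equal(auc_pr(xy$s, xy$y), 0.3, tolerance = 0.05)
  expect_error(auc_pr(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("curve points end at recall 1 and fpr 1", {
  xy <- drhgnn:::with_seed(8, list(s = runif(50), y = rbinom(50, 1, 0.5)))
  rp <- roc_points(xy$s, xy$y)
  pp <- pr_points(xy$s, xy$y)
  expect_equal(rp$tpr[nrow(rp)], 1)
  expect_equal(rp$fpr[nrow(rp)], 1)
  expect_equal(pp$recall[nrow(pp)], 1)
  expect_true(all(pp$precision >= 0 & pp$precision <= 1))
})

test_that("run_protocol aggregates repeats reproducibly", {
  sim <- small_synth(seed = 9L)
  single <- transform_labels(build_dpd(sim$network, "intersection"))
  feats <- compact_features(sim$network, drug_dim = 8, protein_dim = 8)
  cfg <- train_config(learning_rate = 0.01, epochs = 3, seed = 1)
  rep1 <- run_protocol(single, feats, cfg,
                       model_args = list(dims = c(8, 8), neighbor_samples = c(4, 2)),
                       n_repeats = 1, base_seed = 3)
  expect_equal(rep1$mean$auc_roc, rep1$per_repeat$auc_roc[1])
  expect_equal(rep1$sd$auc_roc, 0)
  rep2 <- run_protocol(single, feats, cfg,
                       model_args = list(dims = c(8, 8), neighbor_samples = c(4, 2)),
                       n_repeats = 2, base_seed = 3)
  expect_equal(rep2$mean$auc_roc, mean(rep2$per_repeat$auc_roc))
  expect_equal(rep2$sd$auc_roc, sd(rep2$per_repeat$auc_roc))
  expect_true(all(rep2$per_repeat$auc_roc >= 0 & rep2$per_repeat$auc_roc <= 1))
  # same seeds reproduce the report
  rep2b <- run_protocol(single, feats, cfg,
                        model_args = list(dims = c(8, 8), neighbor_samples = c(4, 2)),
                        n_repeats = 2, base_seed = 3)
  expect_equal(rep2$per_repeat, rep2b$per_repeat)
})

test_that("cv5 folds partition the triples across repeats", {
  sim <- small_synth(seed = 10L)
  single <- transform_labels(build_dpd(sim$network, "intersection"))
  feats <- compact_features(sim$network, drug_dim = 8, protein_dim = 8)
  cfg <- train_config(learning_rate = 0.01, epochs = 2, seed = 1)
  rep5 <- run_protocol(single, feats, cfg,
                       model_args = list(dims = c(8, 8), neighbor_samples = c(4, 2)),
                       n_repeats = 5, base_seed = 2, protocol = "cv5")
  expect_equal(nrow(rep5$per_repeat), 5L)
  expect_equal(rep5$config$protocol, "cv5")
})

test_that("a 1x1 hyperparameter grid equals a direct protocol run", {
  sim <- small_synth(seed = 11L)
  single <- transform_labels(build_dpd(sim$network, "intersection"))
  feats <- compact_features(sim$network, drug_dim = 8, protein_dim = 8)
  cfg <- train_config(seed = 1)
  tab <- hyperparameter_grid(single, feats, lr_list = 0.01, dropout_list = 0.1,
                             epochs = 2, cfg = cfg,
                             model_args = list(dims = c(8, 8),
                                               neighbor_samples = c(4, 2)),
                             n_repeats = 1, base_seed = 4)
  cfg2 <- cfg; cfg2$learning_rate <- 0.01; cfg2$dropout_p <- 0.1
  cfg2$epochs <- 2L
  direct <- run_protocol(single, feats, cfg2,
                         model_args = list(dims = c(8, 8),
                                           neighbor_samples = c(4, 2)),
                         n_repeats = 1, base_seed = 4)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$auc_roc, direct$mean$auc_roc)
  expect_error(hyperparameter_grid(single, feats, numeric(0), 0.1), "empty")
})
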