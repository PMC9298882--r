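test_that("edge embedding modes follow their definitions", {
  expect_equal(edge_embed(c(1, 2), c(3, 4), "concat"), c(1, 2, 3, 4))
  expect_equal(edge_embed(c(1, 2), c(3, 4), "hadamard"), c(3, 8))
  for (seed in 1:3) {
    x <- drhgnn:::with_seed(seed, rnorm(5))
    expect_equal(edge_embed(x, x, "average"), x)
  }
  expect_error(edge_embed(c(1, 2), c(1, 2, 3), "hadamard"), "equal")
})

test_that("classify_edge is a proper softmax", {
  hd <- edge_head(4, c("a", "b", "c"), seed = 1)
  hd$W[] <- 0; hd$b[] <- 0
  expect_equal(unname(classify_edge(c(1, 1, 1, 1), hd)), rep(1 / 3, 3))
  hd$b <- c(log(2), 0, 0)
  expect_equal(unname(classify_edge(c(0, 0, 0, 0), hd)), c(0.5, 0.25, 0.25))
  hd2 <- edge_head(4, c("a", "b", "c"), seed = 2)
  P <- classify_edge(matrix(rnorm(20), 5, 4), hd2)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-8)
  expect_true(all(P >= 0))
})

test_that("negative sampling avoids positive pairs and respects the count", {
  # 2x2 universe with 3 positives leaves a single non-interacting pair
  g <- dpd_graph(c("d1", "d1", "d2"), c("p1", "p2", "p2"), c("x", "y", "x"))
  neg <- sample_negative_triples(g, 1, rng_seed = 4)
  expect_equal(neg$drug, "d2")
  expect_equal(neg$protein, "p1")
  g2 <- dpd_graph(c("d1", "d2"), c("p1", "p2"), c("x", "y"))
  neg2 <- sample_negative_triples(g2, nrow(g2), rng_seed = 1)
  expect_equal(nrow(neg2), nrow(g2))
  key_pos <- paste(g2$drug, g2$protein)
  expect_false(any(paste(neg2$drug, neg2$protein) %in% key_pos))
  # complete bipartite positives leave no complement
  g3 <- dpd_graph(c("d1", "d1", "d2", "d2"), c("p1", "p2", "p1", "p2"),
                  c("x", "x", "y", "y"))
  expect_error(sample_negative_triples(g3, 1), "complement")
})

test_that("negative pair frequencies are uniform over the complement", {
  g <- dpd_graph(c("d1", "d1", "d2"), c("p1", "p2", "p2"), c("x", "y", "x"),
                 label_vocabulary = c("x", "y"))
  neg <- sample_negative_triples(g, 6000, rng_seed = 7,
                                 drug_ids = c("d1", "d2", "d3"),
                                 protein_ids = c("p1", "p2"))
  # complement pairs: (d2,p1), (d3,p1), (d3,p2)
  counts <- table(paste(neg$drug, neg$protein))
  expect_equal(sort(names(counts)), c("d2 p1", "d3 p1", "d3 p2"))
  expected <- 2000; sigma <- sqrt(6000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - expected) < 3 * sigma))
  # disease labels drawn from the supplied vocabulary
  expect_true(all(neg$disease %in% c("x", "y")))
})

# a small learnable setup shared by the training tests
train_fixture <- function(seed = 1L) {
  sim <- small_synth(seed = seed)
  single <- transform_labels(build_dpd(sim$network, "intersection"))
  feats <- compact_features(sim$network, drug_dim = 8, protein_dim = 8)
  splits <- make_splits(nrow(single), n_repeats = 1, base_seed = seed)$assignment[[1]]
  model <- hinsage_model(c(drug = 8, protein = 8), dims = c(8, 8),
                         neighbor_samples = c(4, 2), dropout_p = 0, seed = seed)
  head_obj <- edge_head(16, attr(single, "label_vocabulary"), seed = seed)
  list(single = single, feats = feats, splits = splits, model = model,
       head = head_obj)
}

test_that("lr = 0 leaves weights unchanged and history bookkeeping holds", {
  fx <- train_fixture()
  cfg <- train_config(learning_rate = 0, epochs = 3, dropout_p = 0, seed = 2)
  fit <- train_drhgnn(fx$model, fx$head, fx$single, fx$feats, fx$splits, cfg)
  expect_equal(fit$model$layers[[1]]$W_self$drug,
               fx$model$layers[[1]]$W_self$drug)
  expect_equal(fit$head$W, fx$head$W)
  expect_equal(nrow(fit$history), 3L)
  expect_equal(fit$history$epoch, 1:3)
  # with static weights every epoch reports the same loss, equal to the plain
  # cross-entropy of the initial model (no hidden penalty term in the report)
  sc <- drhgnn:::.score_internal(fx$model, fx$head, fx$single, fx$feats,
                                 fx$single[fx$splits$train, ])
  expect_equal(fit$history$train_loss,
               rep(drhgnn:::.cross_entropy(sc$P, sc$y), 3), tolerance = 1e-10)
})

test_that("training reduces the loss on a learnable problem", {
  fx <- train_fixture(seed = 2L)
  cfg <- train_config(learning_rate = 0.01, epochs = 8, dropout_p = 0,
                      l2_coeff = 0, seed = 3)
  fit <- train_drhgnn(fx$model, fx$head, fx$single, fx$feats, fx$splits, cfg)
  expect_true(all(diff(fit$history$train_loss[1:5]) < 1e-6))
  expect_lt(fit$history$train_loss[8], fit$history$train_loss[1])
  expect_gt(fit$history$val_auc[8], 0.5)
})

test_that("negatives never collide with positives and splits stay balanced", {
  fx <- train_fixture(seed = 3L)
  cfg <- train_config(epochs = 1, neg_ratio = 1, seed = 5)
  fit <- train_drhgnn(fx$model, fx$head, fx$single, fx$feats, fx$splits, cfg)
  neg <- fit$negatives
  expect_equal(nrow(neg), nrow(fx$single))
  key_pos <- paste(fx$single$drug, fx$single$protein)
  expect_false(any(paste(neg$drug, neg$protein) %in% key_pos))
  # neg_ratio 1: test evaluation set is exactly class-balanced
  expect_equal(sum(neg$split == "test"), length(fx$splits$test))
})

test_that("scores are deterministic and match a from-scratch forward pass", {
  fx <- train_fixture(seed = 4L)
  cfg <- train_config(learning_rate = 0.01, epochs = 2, seed = 7)
  fit <- train_drhgnn(fx$model, fx$head, fx$single, fx$feats, fx$splits, cfg)
  triples <- fx$single[fx$splits$test, ]
  s1 <- score_triples(fit$model, fit$head, fx$single, triples, fx$feats)
  s2 <- score_triples(fit$model, fit$head, fx$single, triples, fx$feats)
  expect_identical(s1, s2)
  expect_true(all(s1$is_positive))
  # independent recomputation through exported building blocks
  emb <- encode_nodes(fit$model, fx$single, fx$feats, exact = TRUE)
  for (i in c(1, 3, 5)) {
    e <- edge_embed(emb$drug[triples$drug[i], ], emb$protein[triples$protein[i], ],
                    "concat")
    p <- classify_edge(e, fit$head)[triples$disease[i]]
    expect_equal(unname(p), s1$probability[i], tolerance = 1e-8)
  }
  # an untrained uniform head scores every triple at 1/n_classes
  hd0 <- fit$head; hd0$W[] <- 0; hd0$b[] <- 0
  s0 <- score_triples(fit$model, hd0, fx$single, triples, fx$feats)
  expect_equal(s0$probability,
               rep(1 / length(hd0$classes), nrow(triples)), tolerance = 1e-12)
  expect_error(score_triples(fit$model, fit$head, fx$single,
                             data.frame(drug = triples$drug[1],
                                        protein = triples$protein[1],
                                        disease = "not-a-disease"),
                             fx$feats),
               "unknown disease")
})
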