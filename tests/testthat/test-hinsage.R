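toy_graph <- function() {
  dpd_graph(drug = c("d1", "d1", "d2"), protein = c("p1", "p2", "p2"),
            disease = c("x", "y", "x"))
}

test_that("sample_neighbors covers forced, empty and sampled regimes", {
  g <- dpd_graph(c("d1", "d1", "d1", "d1"), paste0("p", 1:4), rep("x", 4))
  # p1 has exactly one drug neighbor; k=4 forces it repeated 4 times
  expect_equal(sample_neighbors(g, "p1", "protein_drug", 4), rep("d1", 4))
  # drug with no incident edges in the chosen universe
  adj <- dpd_adjacency(g, drug_ids = c("d1", "d9"), protein_ids = paste0("p", 1:4))
  expect_equal(sample_neighbors(adj, "d9", "drug_protein", 3), character(0))
  # k >= degree returns the full neighborhood with equal multiplicity
  s <- sample_neighbors(g, "d1", "drug_protein", 8)
  expect_equal(sort(unique(s)), paste0("p", 1:4))
  expect_true(all(table(s) == 2))
  expect_error(sample_neighbors(g, "zz", "drug_protein", 2), "unknown drug")
  expect_error(sample_neighbors(g, "d1", "drug_protein", 0), "k_samples")
})

test_that("sub-degree sampling is uniform within 3-sigma binomial bounds", {
  g <- dpd_graph(rep("d1", 10), paste0("p", 1:10), rep("x", 10))
  draws <- unlist(lapply(1:2000, function(s)
    sample_neighbors(g, "d1", "drug_protein", 3, rng_seed = s)))
  n <- length(draws)          # 6000 draws, expected 600 per protein
  counts <- table(factor(draws, levels = paste0("p", 1:10)))
  expected <- n / 10
  sigma <- sqrt(n * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < 3 * sigma))
  # determinism given the seed
  expect_equal(sample_neighbors(g, "d1", "drug_protein", 3, rng_seed = 9L),
               sample_neighbors(g, "d1", "drug_protein", 3, rng_seed = 9L))
})

test_that("aggregate_neighbors is a dropout-aware mean with a zero default", {
  expect_equal(aggregate_neighbors(list(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(aggregate_neighbors(list(), dim = 3), c(0, 0, 0))
  expect_error(aggregate_neighbors(list(1:2, 1:3)), "mixed dimensions")
  for (seed in 1:3) {
    vecs <- drhgnn:::with_seed(seed, lapply(1:5, function(i) rnorm(4)))
    expect_equal(aggregate_neighbors(vecs),
                 Reduce(`+`, vecs) / length(vecs), tolerance = 1e-12)
  }
  # inverted dropout preserves the expected value
  v <- list(rep(1, 2000))
  ag <- drhgnn:::with_seed(1, aggregate_neighbors(v, dropout_p = 0.5, train = TRUE))
  expect_equal(mean(ag), 1, tolerance = 0.1)
})

test_that("layer_forward reproduces hand computations", {
  lay <- hinsage_layer(c(drug = 2, protein = 2), 2, activation = "identity")
  lay$W_self$drug <- diag(2); lay$W_neigh$drug_protein <- diag(2)
  lay$b <- c(0, 0)
  out <- layer_forward(lay, "drug", c(1, 0), list(drug_protein = c(0, 2)))
  expect_equal(out, c(1, 2))
  # bias-only path through ReLU
  lay2 <- hinsage_layer(c(drug = 2, protein = 2), 2, activation = "relu")
  lay2$W_self$drug[] <- 0; lay2$W_neigh$drug_protein[] <- 0
  lay2$b <- c(0.5, -0.5)
  expect_equal(layer_forward(lay2, "drug", c(1, 1), list(drug_protein = c(1, 1))),
               c(0.5, 0))
  # random weights equal hand-rolled matrix arithmetic
  lay3 <- drhgnn:::with_seed(3, hinsage_layer(c(drug = 3, protein = 3), 2,
                                              activation = "identity"))
  h <- c(0.3, -1, 2); a <- c(1, 0.5, -0.5)
  manual <- drop(h %*% lay3$W_self$drug) + drop(a %*% lay3$W_neigh$drug_protein) +
    lay3$b
  expect_equal(layer_forward(lay3, "drug", h, list(drug_protein = a)), manual,
               tolerance = 1e-12)
  expect_error(layer_forward(lay3, "drug", h, list(bogus = a)), "missing relation")
})

test_that("parameter formula matches direct evaluation and enumeration", {
  expect_equal(parameter_count(2, 1, 4, 3), 40)
  expect_equal(parameter_count(2, 2, 256, 100), 102656)
  expect_error(parameter_count(0, 1, 2, 2), "positive")
  # enumeration over a grid of layer configurations (T_v = R_e = 2 here)
  grid <- expand.grid(d_k = c(1, 2, 3, 5, 8, 16), d_prev = c(1, 2, 4, 7, 32))
  for (i in seq_len(nrow(grid))) {
    d_k <- grid$d_k[i]; d_prev <- grid$d_prev[i]
    lay <- hinsage_layer(c(drug = d_prev, protein = d_prev), d_k)
    expect_equal(count_parameters(lay), parameter_count(2, 2, d_k, d_prev))
  }
})

test_that("encode_nodes on an isolated node is sigma(W x + b)", {
  g <- toy_graph()
  feats <- toy_features(c("d1", "d2", "d3"), c("p1", "p2"), d = 2, seed = 2)
  model <- hinsage_model(c(drug = 2, protein = 2), dims = 4,
                         neighbor_samples = 4, dropout_p = 0, seed = 5)
  emb <- encode_nodes(model, g, feats, nodes = list(drug = "d3"))
  x <- feats$drug$matrix["d3", ]
  lay <- model$layers[[1]]
  expect_equal(unname(emb$drug["d3", ]),
               unname(drop(x %*% lay$W_self$drug) + lay$b), tolerance = 1e-12)
})

test_that("a one-layer forward on a 2-node graph matches the manual update", {
  g <- dpd_graph("d1", "p1", "x")
  feats <- toy_features("d1", "p1", d = 2, seed = 3)
  model <- hinsage_model(c(drug = 2, protein = 2), dims = 3,
                         neighbor_samples = 2, dropout_p = 0, seed = 7)
  emb <- encode_nodes(model, g, feats)
  lay <- model$layers[[1]]
  xd <- feats$drug$matrix["d1", ]; xp <- feats$protein$matrix["p1", ]
  zd <- drop(xd %*% lay$W_self$drug) + drop(xp %*% lay$W_neigh$drug_protein) + lay$b
  zp <- drop(xp %*% lay$W_self$protein) + drop(xd %*% lay$W_neigh$protein_drug) + lay$b
  expect_equal(unname(emb$drug["d1", ]), unname(zd), tolerance = 1e-12)
  expect_equal(unname(emb$protein["p1", ]), unname(zp), tolerance = 1e-12)
})

test_that("encoding is deterministic and dropout p=0 train equals inference", {
  g <- toy_graph()
  feats <- toy_features(c("d1", "d2"), c("p1", "p2"), d = 3, seed = 4)
  model <- hinsage_model(c(drug = 3, protein = 3), dims = c(4, 4),
                         neighbor_samples = c(3, 2), dropout_p = 0, seed = 1)
  e1 <- encode_nodes(model, g, feats, seed = 42)
  e2 <- encode_nodes(model, g, feats, seed = 42)
  expect_identical(e1, e2)
  e3 <- encode_nodes(model, g, feats, train_mode = TRUE, seed = 42)
  expect_equal(e1, e3, tolerance = 1e-14)
})

test_that("sampled forward with saturating samples matches the dense oracle", {
  for (seed in 1:3) {
    sim <- drhgnn:::with_seed(seed, {
      nd <- sample(4:9, 1); np <- sample(4:9, 1)
      pairs <- expand.grid(d = sprintf("d%d", 1:nd), p = sprintf("p%d", 1:np),
                           stringsAsFactors = FALSE)
      pick <- pairs[runif(nrow(pairs)) < 0.4, ]
      pick[!duplicated(pick), ]
    })
    if (nrow(sim) < 2) next
    g <- dpd_graph(sim$d, sim$p, rep("x", nrow(sim)))
    drug_ids <- sort(unique(sim$d)); prot_ids <- sort(unique(sim$p))
    feats <- toy_features(drug_ids, prot_ids, d = 3, seed = seed)
    maxdeg <- max(c(table(sim$d), table(sim$p)))
    model <- hinsage_model(c(drug = 3, protein = 3), dims = c(5, 4),
                           neighbor_samples = rep(maxdeg, 2), dropout_p = 0,
                           seed = seed)
    emb <- encode_nodes(model, g, feats, seed = 1)
    oracle <- dense_hinsage_oracle(model, g, feats)
    expect_equal(emb$drug, oracle$drug, tolerance = 1e-8)
    expect_equal(emb$protein, oracle$protein, tolerance = 1e-8)
  }
})

test_that("embeddings are equivariant to node relabeling", {
  g <- toy_graph()
  feats <- toy_features(c("d1", "d2"), c("p1", "p2"), d = 3, seed = 9)
  model <- hinsage_model(c(drug = 3, protein = 3), dims = c(4, 4),
                         neighbor_samples = c(10, 10), dropout_p = 0, seed = 2)
  emb <- encode_nodes(model, g, feats, seed = 1)
  # relabel drugs: d1 <-> d2
  relabel <- c(d1 = "D2", d2 = "D1")
  g2 <- dpd_graph(unname(relabel[g$drug]), g$protein, g$disease)
  feats2 <- feats
  rownames(feats2$drug$matrix) <- unname(relabel[rownames(feats$drug$matrix)])
  emb2 <- encode_nodes(model, g2, feats2, seed = 1)
  expect_equal(unname(emb$drug["d1", ]), unname(emb2$drug["D2", ]), tolerance = 1e-10)
  expect_equal(unname(emb$drug["d2", ]), unname(emb2$drug["D1", ]), tolerance = 1e-10)
})

test_that("concat combine halves the per-term width and still runs end-to-end", {
  g <- toy_graph()
  feats <- toy_features(c("d1", "d2"), c("p1", "p2"), d = 3, seed = 5)
  model <- hinsage_model(c(drug = 3, protein = 3), dims = c(6, 4),
                         neighbor_samples = c(5, 5), dropout_p = 0,
                         combine = "concat", seed = 3)
  expect_equal(ncol(model$layers[[1]]$W_self$drug), 3)
  emb <- encode_nodes(model, g, feats, seed = 1)
  expect_equal(ncol(emb$drug), 4)
  expect_error(hinsage_layer(c(drug = 3, protein = 3), 5, combine = "concat"),
               "even")
})

test_that("backpropagation matches finite-difference gradients", {
  g <- toy_graph()
  feats <- toy_features(c("d1", "d2"), c("p1", "p2"), d = 3, seed = 6)
  model <- hinsage_model(c(drug = 3, protein = 3), dims = c(4, 3),
                         neighbor_samples = c(Inf, Inf), dropout_p = 0, seed = 8)
  head_obj <- edge_head(6, c("x", "y"), seed = 9)
  adj <- dpd_adjacency(g, rownames(feats$drug$matrix),
                       rownames(feats$protein$matrix))
  y <- match(g$disease, head_obj$classes)
  di <- match(g$drug, rownames(feats$drug$matrix))
  pj <- match(g$protein, rownames(feats$protein$matrix))

  loss_fn <- function(model, head_obj) {
    fwd <- drhgnn:::.hinsage_forward(model, adj, feats$drug$matrix,
                                     feats$protein$matrix, seed = 1)
    E <- cbind(fwd$H_d[di, , drop = FALSE], fwd$H_p[pj, , drop = FALSE])
    P <- drhgnn:::.softmax_rows(sweep(E %*% head_obj$W, 2, head_obj$b, `+`))
    -mean(log(P[cbind(seq_along(y), y)]))
  }
  # analytic gradients
  fwd <- drhgnn:::.hinsage_forward(model, adj, feats$drug$matrix,
                                   feats$protein$matrix, seed = 1,
                                   keep_cache = TRUE)
  E <- cbind(fwd$H_d[di, , drop = FALSE], fwd$H_p[pj, , drop = FALSE])
  P <- drhgnn:::.softmax_rows(sweep(E %*% head_obj$W, 2, head_obj$b, `+`))
  dL <- P; dL[cbind(seq_along(y), y)] <- dL[cbind(seq_along(y), y)] - 1
  dL <- dL / length(y)
  dE <- tcrossprod(dL, head_obj$W)
  dH_d <- matrix(0, nrow(fwd$H_d), ncol(fwd$H_d))
  dH_p <- matrix(0, nrow(fwd$H_p), ncol(fwd$H_p))
  for (b in seq_along(y)) {
    dH_d[di[b], ] <- dH_d[di[b], ] + dE[b, 1:3]
    dH_p[pj[b], ] <- dH_p[pj[b], ] + dE[b, 4:6]
  }
  grads <- drhgnn:::.hinsage_backward(model, fwd, dH_d, dH_p)
  # finite differences on a handful of entries of layer-1 weights
  h <- 1e-6
  for (probe in list(c("W_self", "drug", 1, 2), c("W_neigh", "protein_drug", 2, 1))) {
    m2 <- model
    M <- m2$layers[[1]][[probe[1]]][[probe[2]]]
    i <- as.integer(probe[3]); j <- as.integer(probe[4])
    M[i, j] <- M[i, j] + h
    m2$layers[[1]][[probe[1]]][[probe[2]]] <- M
    num <- (loss_fn(m2, head_obj) - loss_fn(model, head_obj)) / h
    ana <- grads[[1]][[probe[1]]][[probe[2]]][i, j]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
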