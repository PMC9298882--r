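options(drhgnn.verbose = FALSE)

# small synthetic network for structural tests (fast to generate)
small_synth <- function(seed = 1L, n = 30L) {
  generate_hetnet(synthetic_config(
    n_drugs = n, n_proteins = n, n_diseases = 8L, n_side_effects = 6L,
    latent_rank = 4L,
    edge_density = list(drug_protein = 0.1, drug_drug = 0.1,
                        protein_protein = 0.1, drug_disease = 0.3,
                        protein_disease = 0.3, drug_side_effect = 0.15),
    seed = seed))
}

# random multi-label DPD graph (ids only, no backing network)
random_multilabel <- function(seed, n_edges = 12L, n_dis = 5L) {
  with_seed <- drhgnn:::with_seed
  with_seed(seed, {
    pairs <- expand.grid(d = sprintf("d%d", 1:6), p = sprintf("p%d", 1:6),
                         stringsAsFactors = FALSE)
    pick <- pairs[sample.int(nrow(pairs), n_edges), ]
    labs <- lapply(seq_len(n_edges), function(i)
      sample(sprintf("dis%d", seq_len(n_dis)), sample(1:3, 1)))
    multilabel_dpd(pick$d, pick$p, labs)
  })
}

# tiny feature set: random dense features over given id universes
toy_features <- function(drug_ids, protein_ids, d = 4L, seed = 1L) {
  drhgnn:::with_seed(seed, {
    Xd <- matrix(rnorm(length(drug_ids) * d), ncol = d,
                 dimnames = list(drug_ids, NULL))
    Xp <- matrix(rnorm(length(protein_ids) * d), ncol = d,
                 dimnames = list(protein_ids, NULL))
    list(drug = structure(list(matrix = Xd, dim = d, node_type = "drug"),
                          class = "node_features"),
         protein = structure(list(matrix = Xp, dim = d, node_type = "protein"),
                             class = "node_features"))
  })
}

# Independent dense full-neighborhood HinSAGE oracle: plain loops over nodes,
# no sampling, no shared code with the package's vectorized forward.
dense_hinsage_oracle <- function(model, graph, features) {
  Xd <- features$drug$matrix; Xp <- features$protein$matrix
  drug_ids <- rownames(Xd); prot_ids <- rownames(Xp)
  Hd <- Xd; Hp <- Xp
  for (lay in model$layers) {
    newHd <- matrix(0, nrow(Hd), lay$d_out)
    newHp <- matrix(0, nrow(Hp), lay$d_out)
    for (i in seq_along(drug_ids)) {
      nb <- graph$protein[graph$drug == drug_ids[i]]
      agg <- if (length(nb)) colMeans(Hp[nb, , drop = FALSE]) else numeric(ncol(Hp))
      z <- drop(Hd[i, ] %*% lay$W_self$drug) +
        drop(agg %*% lay$W_neigh$drug_protein) + lay$b
      newHd[i, ] <- if (lay$activation == "relu") pmax(z, 0) else z
    }
    for (j in seq_along(prot_ids)) {
      nb <- graph$drug[graph$protein == prot_ids[j]]
      agg <- if (length(nb)) colMeans(Hd[nb, , drop = FALSE]) else numeric(ncol(Hd))
      z <- drop(Hp[j, ] %*% lay$W_self$protein) +
        drop(agg %*% lay$W_neigh$protein_drug) + lay$b
      newHp[j, ] <- if (lay$activation == "relu") pmax(z, 0) else z
    }
    rownames(newHd) <- drug_ids; rownames(newHp) <- prot_ids
    Hd <- newHd; Hp <- newHp
  }
  list(drug = Hd, protein = Hp)
}

# minimal hand-built hetero network: 2 drugs, 2 proteins, 2 diseases, 1 SE
mini_net <- function(m_dp, m_pd, m_dd_dis = matrix(0, 2, 2)) {
  sim2 <- diag(2)
  hetero_network(
    registries = list(drug = node_registry("drug", c("d1", "d2")),
                      protein = node_registry("protein", c("p1", "p2")),
                      disease = node_registry("disease", c("delta1", "delta2")),
                      side_effect = node_registry("side_effect", "s1")),
    relations = list(
      drug_protein = relation_matrix("drug", "protein", "interaction", m_dp),
      drug_drug = relation_matrix("drug", "drug", "interaction", matrix(0, 2, 2)),
      drug_disease = relation_matrix("drug", "disease", "association", m_dd_dis),
      drug_side_effect = relation_matrix("drug", "side_effect", "association",
                                         matrix(0, 2, 1)),
      protein_disease = relation_matrix("protein", "disease", "association", m_pd),
      protein_protein = relation_matrix("protein", "protein", "interaction",
                                        matrix(0, 2, 2)),
      drug_similarity = relation_matrix("drug", "drug", "similarity", sim2),
      protein_similarity = relation_matrix("protein", "protein", "similarity", sim2)
    ))
}
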