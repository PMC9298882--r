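# Synthetic DTINet-like networks with planted low-rank structure.
#
# Every node carries a latent unit vector; each association sub-network is a
# Bernoulli draw with edge probability a logistic function of latent inner
# products, with the logistic offset calibrated so the expected density hits
# the requested one. Similarity matrices are cosines of the latent vectors
# clipped to [0, 1]. Because the drug-disease and protein-disease networks are
# driven by the same latent space as the drug-protein network, the disease
# label sets attached to DP edges are shared across latent neighborhoods,
# guaranteeing learnable structure.

#' Synthetic network configuration
#'
#' @param n_drugs,n_proteins,n_diseases,n_side_effects node counts (>= 2).
#' @param latent_rank dimension of the planted latent space (>= 1).
#' @param edge_density named list of target densities in (0,1) per relation
#'   (`drug_protein`, `drug_drug`, `protein_protein`, `drug_disease`,
#'   `protein_disease`, `drug_side_effect`).
#' @param label_sharpness logistic slope on latent inner products; larger
#'   values concentrate each node's associations on its latent neighborhood.
#' @param noise_rate probability in `[0, 0.5)` that an edge is rewired
#'   (removed and replaced by a uniformly random non-edge).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 200L, n_proteins = 200L,
                             n_diseases = 20L, n_side_effects = 30L,
                             latent_rank = 8L,
                             edge_density = list(drug_protein = 0.025,
                                                 drug_drug = 0.05,
                                                 protein_protein = 0.05,
                                                 drug_disease = 0.25,
                                                 protein_disease = 0.25,
                                                 drug_side_effect = 0.08),
                             label_sharpness = 8, noise_rate = 0, seed = 0L) {
  counts <- c(n_drugs, n_proteins, n_diseases, n_side_effects)
  if (any(counts < 2)) drh_stop("all node counts must be >= 2")
  if (!is_count(latent_rank) || latent_rank < 1)
    drh_stop("latent_rank must be a positive integer")
  if (any(unlist(edge_density) <= 0 | unlist(edge_density) >= 1))
    drh_stop("edge densities must lie in (0, 1)")
  if (!(noise_rate >= 0 && noise_rate < 0.5))
    drh_stop("noise_rate must be in [0, 0.5)")
  structure(list(n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
                 n_diseases = as.integer(n_diseases),
                 n_side_effects = as.integer(n_side_effects),
                 latent_rank = as.integer(latent_rank),
                 edge_density = edge_density,
                 label_sharpness = label_sharpness,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

# unit row vectors from a spherical Gaussian
.latent_factors <- function(n, r) {
  U <- matrix(rnorm(n * r), n, r)
  U / sqrt(rowSums(U^2))
}

# offset c with mean(sigmoid(beta * S + c)) = density, by bisection
.calibrate_offset <- function(S, beta, density) {
  f <- function(cc) mean(1 / (1 + exp(-(beta * S + cc)))) - density
  lo <- -50; hi <- 50
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Edge probabilities are a logistic function of latent inner products; the
# edge set is the top density-quantile of those probabilities (deterministic
# thresholding), so that with noise_rate = 0 the network is an exact function
# of the latent factors and the only noise dial is noise_rate.
.draw_bipartite <- function(U_a, U_b, beta, density) {
  S <- U_a %*% t(U_b)
  cc <- .calibrate_offset(S, beta, density)
  P <- 1 / (1 + exp(-(beta * S + cc)))
  k <- round(density * length(P))
  thr <- sort(as.vector(P), decreasing = TRUE)[max(k, 1L)]
  M <- matrix(0L, nrow(P), ncol(P))
  M[P >= thr] <- 1L
  M
}

.draw_square <- function(U, beta, density) {
  S <- U %*% t(U)
  ut <- which(upper.tri(S))
  cc <- .calibrate_offset(S[ut], beta, density)
  P <- 1 / (1 + exp(-(beta * S + cc)))
  k <- round(density * length(ut))
  thr <- sort(P[ut], decreasing = TRUE)[max(k, 1L)]
  M <- matrix(0L, nrow(S), ncol(S))
  sel <- ut[P[ut] >= thr]
  M[sel] <- 1L
  M + t(M)
}

# rewire a fraction of edges to uniformly random non-edges
.apply_noise <- function(M, noise_rate, symmetric = FALSE) {
  if (noise_rate <= 0) return(M)
  if (symmetric) {
    idx <- which(upper.tri(M))
  } else {
    idx <- seq_along(M)
  }
  ones <- idx[M[idx] == 1]
  zeros <- idx[M[idx] == 0]
  drop_n <- rbinom(1L, length(ones), noise_rate)
  if (drop_n > 0) {
    dropped <- sample(ones, drop_n)
    added <- sample(zeros, min(drop_n, length(zeros)))
    M[dropped] <- 0L
    M[added] <- 1L
    if (symmetric) {
      M[lower.tri(M)] <- 0L
      M <- M + t(M)
      diag(M) <- 0L
    }
  }
  M
}

#' Generate a synthetic heterogeneous network
#'
#' @param config a [synthetic_config()].
#' @return list with `network` (a [hetero_network()]), `factors` (the planted
#'   latent unit vectors per node type) and `config`.
#' @export
generate_hetnet <- function(config = synthetic_config()) {
  cfg <- config
  dens <- cfg$edge_density
  exp_nnz <- c(dens$drug_protein * cfg$n_drugs * cfg$n_proteins,
               dens$drug_disease * cfg$n_drugs * cfg$n_diseases,
               dens$protein_disease * cfg$n_proteins * cfg$n_diseases)
  if (any(exp_nnz < 1))
    drh_stop("edge densities incompatible with node counts (expected nonzeros < 1)")
  beta <- cfg$label_sharpness
  with_seed(cfg$seed, {
    U <- list(drug = .latent_factors(cfg$n_drugs, cfg$latent_rank),
              protein = .latent_factors(cfg$n_proteins, cfg$latent_rank),
              disease = .latent_factors(cfg$n_diseases, cfg$latent_rank),
              side_effect = .latent_factors(cfg$n_side_effects, cfg$latent_rank))
    mats <- list(
      drug_protein = .draw_bipartite(U$drug, U$protein, beta, dens$drug_protein),
      drug_drug = .draw_square(U$drug, beta, dens$drug_drug),
      drug_disease = .draw_bipartite(U$drug, U$disease, beta, dens$drug_disease),
      drug_side_effect = .draw_bipartite(U$drug, U$side_effect, beta,
                                         dens$drug_side_effect),
      protein_disease = .draw_bipartite(U$protein, U$disease, beta,
                                        dens$protein_disease),
      protein_protein = .draw_square(U$protein, beta, dens$protein_protein)
    )
    mats <- list(
      drug_protein = .apply_noise(mats$drug_protein, cfg$noise_rate),
      drug_drug = .apply_noise(mats$drug_drug, cfg$noise_rate, symmetric = TRUE),
      drug_disease = .apply_noise(mats$drug_disease, cfg$noise_rate),
      drug_side_effect = .apply_noise(mats$drug_side_effect, cfg$noise_rate),
      protein_disease = .apply_noise(mats$protein_disease, cfg$noise_rate),
      protein_protein = .apply_noise(mats$protein_protein, cfg$noise_rate,
                                     symmetric = TRUE)
    )
    sim_d <- pmin(pmax(U$drug %*% t(U$drug), 0), 1); diag(sim_d) <- 1
    sim_p <- pmin(pmax(U$protein %*% t(U$protein), 0), 1); diag(sim_p) <- 1

    ids <- list(drug = sprintf("d%03d", seq_len(cfg$n_drugs)),
                protein = sprintf("p%04d", seq_len(cfg$n_proteins)),
                disease = sprintf("dis%03d", seq_len(cfg$n_diseases)),
                side_effect = sprintf("se%03d", seq_len(cfg$n_side_effects)))
    registries <- lapply(names(ids), function(tp) node_registry(tp, ids[[tp]]))
    names(registries) <- names(ids)
    relations <- list(
      drug_protein = relation_matrix("drug", "protein", "interaction",
                                     mats$drug_protein, "drug_protein"),
      drug_drug = relation_matrix("drug", "drug", "interaction",
                                  mats$drug_drug, "drug_drug"),
      drug_disease = relation_matrix("drug", "disease", "association",
                                     mats$drug_disease, "drug_disease"),
      drug_side_effect = relation_matrix("drug", "side_effect", "association",
                                         mats$drug_side_effect, "drug_side_effect"),
      protein_disease = relation_matrix("protein", "disease", "association",
                                        mats$protein_disease, "protein_disease"),
      protein_protein = relation_matrix("protein", "protein", "interaction",
                                        mats$protein_protein, "protein_protein"),
      drug_similarity = relation_matrix("drug", "drug", "similarity",
                                        sim_d, "drug_similarity"),
      protein_similarity = relation_matrix("protein", "protein", "similarity",
                                           sim_p, "protein_similarity")
    )
    for (tp in names(U)) rownames(U[[tp]]) <- ids[[tp]]
    list(network = hetero_network(registries, relations), factors = U,
         config = cfg)
  })
}

#' Destroy the planted structure of a DPD graph
#'
#' Replaces the positive (drug, protein) pairs by uniformly random distinct
#' pairs over the same node universes and assigns labels uniformly from the
#' vocabulary: a null graph on which no method should beat chance.
#'
#' @param graph a [dpd_graph()].
#' @param seed integer seed.
#' @param drug_ids,protein_ids node universes (default: the graph's nodes).
#' @return a rewired [dpd_graph()] with the same number of triples.
#' @export
rewire_dpd <- function(graph, seed = 0L, drug_ids = NULL, protein_ids = NULL) {
  drug_ids <- drug_ids %||% sort(unique(graph$drug))
  protein_ids <- protein_ids %||% sort(unique(graph$protein))
  vocab <- attr(graph, "label_vocabulary")
  n <- nrow(graph)
  with_seed(seed, {
    key <- character(0)
    di <- integer(0); pj <- integer(0)
    while (length(di) < n) {
      m <- 2L * (n - length(di)) + 16L
      cd <- sample.int(length(drug_ids), m, replace = TRUE)
      cp <- sample.int(length(protein_ids), m, replace = TRUE)
      kk <- paste(cd, cp)
      ok <- !(kk %in% key) & !duplicated(kk)
      di <- c(di, cd[ok]); pj <- c(pj, cp[ok])
      key <- c(key, kk[ok])
    }
    di <- di[seq_len(n)]; pj <- pj[seq_len(n)]
    dpd_graph(drug_ids[di], protein_ids[pj],
              sample(vocab, n, replace = TRUE), label_vocabulary = vocab)
  })
}

#' Tiny hand-checkable fixture
#'
#' A fixed 2-drug / 2-protein / 3-disease / 1-side-effect network with
#' hand-written matrices, its multi-labeled DPD graph under the intersection
#' rule, and the hand-derived single-label result (label frequencies
#' D1 = 1, D2 = 3, D3 = 2, so the frequency-argmin representatives are D1,
#' D3, D3).
#'
#' @return list with `network`, `multilabel` (expected [multilabel_dpd()])
#'   and `expected_single` (expected [dpd_graph()]).
#' @export
tiny_fixture <- function() {
  drugs <- c("d1", "d2"); prots <- c("p1", "p2")
  dis <- c("D1", "D2", "D3"); se <- "s1"
  m_dp <- matrix(c(1, 1,
                   0, 1), 2, 2, byrow = TRUE)
  m_pd <- matrix(c(1, 1, 0,
                   0, 1, 1), 2, 3, byrow = TRUE)
  m_dd_dis <- matrix(c(1, 1, 1,
                       0, 1, 1), 2, 3, byrow = TRUE)
  m_dd <- matrix(0, 2, 2)
  m_pp <- matrix(0, 2, 2)
  m_dse <- matrix(c(1, 0), 2, 1)
  sim2 <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  registries <- list(drug = node_registry("drug", drugs),
                     protein = node_registry("protein", prots),
                     disease = node_registry("disease", dis),
                     side_effect = node_registry("side_effect", se))
  relations <- list(
    drug_protein = relation_matrix("drug", "protein", "interaction", m_dp),
    drug_drug = relation_matrix("drug", "drug", "interaction", m_dd),
    drug_disease = relation_matrix("drug", "disease", "association", m_dd_dis),
    drug_side_effect = relation_matrix("drug", "side_effect", "association", m_dse),
    protein_disease = relation_matrix("protein", "disease", "association", m_pd),
    protein_protein = relation_matrix("protein", "protein", "interaction", m_pp),
    drug_similarity = relation_matrix("drug", "drug", "similarity", sim2),
    protein_similarity = relation_matrix("protein", "protein", "similarity", sim2)
  )
  network <- hetero_network(registries, relations)
  multilabel <- multilabel_dpd(
    drug = c("d1", "d1", "d2"),
    protein = c("p1", "p2", "p2"),
    labels = list(c("D1", "D2"), c("D2", "D3"), c("D2", "D3")),
    provenance = "intersection"
  )
  expected_single <- dpd_graph(
    drug = c("d1", "d1", "d2"),
    protein = c("p1", "p2", "p2"),
    disease = c("D1", "D3", "D3")
  )
  list(network = network, multilabel = multilabel,
       expected_single = expected_single)
}
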