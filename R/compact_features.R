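#' Random walk with restart
#'
#' Computes the diffusion state of every node of a (non-negative, square)
#' network: row i approximates the stationary distribution of a walk that
#' restarts at node i with probability `restart_prob` each step, i.e. the
#' fixed point of `s_i = p e_i + (1 - p) P' s_i` with `P` the row-normalized
#' transition matrix. Isolated nodes are given a self-loop so probability mass
#' is conserved.
#'
#' @param adjacency square non-negative matrix (dense or sparse), or a
#'   [relation_matrix()] with a square `values` slot.
#' @param restart_prob restart probability in (0, 1].
#' @param tol stop when the maximum L1 change of any diffusion state falls
#'   below `tol`.
#' @param max_iter iteration cap.
#' @return object of class `diffusion_state`: list with `values` (n x n dense
#'   matrix, row i = diffusion state of node i) and `restart_prob`.
#' @export
rwr <- function(adjacency, restart_prob = 0.5, tol = 1e-10, max_iter = 1000L) {
  if (inherits(adjacency, "relation_matrix")) adjacency <- adjacency$values
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) drh_stop("rwr requires a square matrix")
  if (any(A < 0)) drh_stop("rwr requires non-negative entries")
  if (!(restart_prob > 0 && restart_prob <= 1))
    drh_stop("restart_prob must be in (0, 1]")
  n <- nrow(A)
  deg <- rowSums(A)
  iso <- deg == 0
  if (any(iso)) { A[cbind(which(iso), which(iso))] <- 1; deg[iso] <- 1 }
  P <- A / deg   # row-stochastic; invariant to uniform scaling of A

  # iterate all states at once: columns of S are the s_i
  p <- restart_prob
  S <- diag(n)
  tP <- t(P)
  for (it in seq_len(max_iter)) {
    S_new <- p * diag(n) + (1 - p) * (tP %*% S)
    delta <- max(colSums(abs(S_new - S)))
    S <- S_new
    if (delta < tol) break
  }
  S <- t(S)                       # rows are diffusion states
  S <- S / rowSums(S)             # renormalize (no-op up to round-off)
  structure(list(values = S, restart_prob = p, iterations = it, delta = delta),
            class = "diffusion_state")
}

# Build the per-sub-network walk matrices touching one node type.
# Square relations are walked directly; bipartite relations are walked on the
# symmetrized bipartite union graph, with the node_type rows of the resulting
# state kept (full column width).
.profile_blocks <- function(network, node_type) {
  rel <- network$relations
  if (node_type == "drug") {
    specs <- list(
      list(rel = "drug_drug", kind = "square"),
      list(rel = "drug_similarity", kind = "square"),
      list(rel = "drug_disease", kind = "bipartite"),
      list(rel = "drug_side_effect", kind = "bipartite"),
      list(rel = "drug_protein", kind = "bipartite")
    )
  } else if (node_type == "protein") {
    specs <- list(
      list(rel = "protein_protein", kind = "square"),
      list(rel = "protein_similarity", kind = "square"),
      list(rel = "protein_disease", kind = "bipartite"),
      list(rel = "drug_protein", kind = "bipartite_transposed")
    )
  } else drh_stop("node_type must be 'drug' or 'protein'")
  specs <- Filter(function(s) s$rel %in% names(rel), specs)
  if (!length(specs)) drh_stop("no relations incident to node type '%s'", node_type)
  specs
}

#' Concatenated diffusion profile for one node type
#'
#' Runs [rwr()] on every sub-network incident to `node_type` (for drugs:
#' drug-drug interactions, drug similarity, drug-disease, drug-side-effect,
#' drug-protein; for proteins: protein-protein interactions, protein
#' similarity, protein-disease, drug-protein transposed) and horizontally
#' concatenates the resulting diffusion-state rows. Bipartite relations are
#' diffused on the symmetrized bipartite union graph and restricted back to
#' the `node_type` rows, so each block keeps full `n + q` column width.
#'
#' @param network a [hetero_network()].
#' @param node_type `"drug"` or `"protein"`.
#' @inheritParams rwr
#' @return dense matrix (n x m); each row block of each sub-network sums to 1.
#' @export
network_diffusion_profile <- function(network, node_type = c("drug", "protein"),
                                      restart_prob = 0.5, tol = 1e-10,
                                      max_iter = 1000L) {
  node_type <- match.arg(node_type)
  specs <- .profile_blocks(network, node_type)
  n <- length(network$registries[[node_type]])
  blocks <- lapply(specs, function(sp) {
    M <- as.matrix(network$relations[[sp$rel]]$values)
    if (sp$kind == "square") {
      rwr(M, restart_prob, tol, max_iter)$values
    } else {
      if (sp$kind == "bipartite_transposed") M <- t(M)
      q <- ncol(M)
      U <- rbind(cbind(matrix(0, n, n), M),
                 cbind(t(M), matrix(0, q, q)))
      rwr(U, restart_prob, tol, max_iter)$values[seq_len(n), , drop = FALSE]
    }
  })
  do.call(cbind, blocks)
}

#' Low-rank embedding of diffusion profiles
#'
#' Diffusion-component-analysis style embedding. The default deterministic
#' solver takes the element-wise log of the (smoothed) profile, centers each
#' column, and keeps the top `dim` components of its SVD, returning
#' `U %*% diag(sqrt(d))`. The optional `"kl"` solver refines a softmax
#' (multinomial-logistic) reconstruction of each diffusion-state block by
#' directly minimizing the mean row-wise KL divergence, initialized from the
#' SVD solution.
#'
#' @param profile dense non-negative matrix (n x m), rows are concatenated
#'   diffusion states.
#' @param dim embedding dimension, `< min(dim(profile))`.
#' @param eps log smoothing constant; default `1/ncol(profile)`.
#' @param solver `"svd"` (default) or `"kl"`.
#' @param node_type stored on the result for bookkeeping.
#' @param kl_iter,kl_lr iterations and step size of the KL refinement.
#' @return object of class `node_features`: list with `matrix` (n x dim),
#'   `dim`, `node_type`, `solver`.
#' @export
dca_embed <- function(profile, dim, eps = NULL, solver = c("svd", "kl"),
                      node_type = "node", kl_iter = 200L, kl_lr = 0.05) {
  solver <- match.arg(solver)
  profile <- as.matrix(profile)
  if (any(profile < 0)) drh_stop("profile must be non-negative")
  if (dim >= min(nrow(profile), ncol(profile)))
    drh_stop("dim (%d) must be smaller than min(profile shape) = %d",
             dim, min(nrow(profile), ncol(profile)))
  eps <- eps %||% (1 / ncol(profile))
  if (eps <= 0) drh_stop("eps must be positive")
  L <- log(profile + eps)
  L <- sweep(L, 2, colMeans(L))
  sv <- svd(L, nu = dim, nv = dim)
  X <- sv$u %*% diag(sqrt(sv$d[seq_len(dim)]), dim)
  kl_value <- NA_real_
  if (solver == "kl") {
    W <- sv$v %*% diag(sqrt(sv$d[seq_len(dim)]), dim)
    fit <- .kl_refine(profile, X, W, iters = kl_iter, lr = kl_lr)
    X <- fit$X
    kl_value <- fit$objective
  }
  if (any(!is.finite(X))) drh_stop("non-finite entries in embedding")
  rownames(X) <- rownames(profile)
  structure(list(matrix = X, dim = dim, node_type = node_type, solver = solver,
                 kl = kl_value),
            class = "node_features")
}

# Gradient refinement of the multinomial-logistic objective
#   min mean_i KL(s_i || softmax(x_i' w_. + c))  over X, W, c.
.kl_refine <- function(S, X, W, iters, lr) {
  n <- nrow(S); m <- ncol(S)
  Srow <- S / pmax(rowSums(S), .Machine$double.eps)
  cvec <- rep(0, m)
  for (t in seq_len(iters)) {
    Z <- X %*% t(W)
    Z <- sweep(Z, 1, apply(Z, 1, max))
    E <- exp(sweep(Z, 2, cvec, `+`))
    Shat <- E / rowSums(E)
    G <- (Shat - Srow) / n      # d(mean KL)/d logits
    gX <- G %*% W
    gW <- t(G) %*% X
    gc <- colSums(G)
    X <- X - lr * gX; W <- W - lr * gW; cvec <- cvec - lr * gc
  }
  Z <- sweep(X %*% t(W), 2, cvec, `+`)
  Z <- Z - apply(Z, 1, max)
  Shat <- exp(Z) / rowSums(exp(Z))
  obj <- mean(rowSums(ifelse(Srow > 0, Srow * log(Srow / pmax(Shat, 1e-300)), 0)))
  list(X = X, W = W, c = cvec, objective = obj)
}

#' Mean row-wise KL divergence of a softmax reconstruction
#'
#' Utility used to compare embedding fits: fits row-softmax logits `X W' + c`
#' are not re-optimized here; the divergence is evaluated for a given
#' embedding by one ridge-free least-squares decoding of the log-profile.
#'
#' @keywords internal
dca_kl_objective <- function(profile, features, eps = NULL) {
  S <- as.matrix(profile)
  S <- S / pmax(rowSums(S), .Machine$double.eps)
  eps <- eps %||% (1 / ncol(S))
  L <- log(S + eps); L <- sweep(L, 2, colMeans(L))
  X <- features$matrix
  W <- t(qr.solve(crossprod(X) + 1e-10 * diag(ncol(X)), t(X) %*% L))
  Z <- X %*% t(W)
  Z <- sweep(Z, 1, apply(Z, 1, max))
  E <- exp(Z); Shat <- E / rowSums(E)
  mean(rowSums(ifelse(S > 0, S * log(S / pmax(Shat, 1e-300)), 0)))
}

#' Compact feature learning for drugs and proteins
#'
#' Convenience wrapper: diffusion profile ([network_diffusion_profile()])
#' followed by [dca_embed()] for each node type.
#'
#' @param network a [hetero_network()].
#' @param drug_dim,protein_dim embedding dimensions.
#' @inheritParams rwr
#' @inheritParams dca_embed
#' @return named list of `node_features` (`drug`, `protein`), rows named by
#'   node identifiers.
#' @export
compact_features <- function(network, drug_dim = 100L, protein_dim = 400L,
                             restart_prob = 0.5, tol = 1e-10, max_iter = 1000L,
                             solver = "svd") {
  out <- list()
  for (tp in c("drug", "protein")) {
    d <- if (tp == "drug") drug_dim else protein_dim
    prof <- network_diffusion_profile(network, tp, restart_prob, tol, max_iter)
    rownames(prof) <- network$registries[[tp]]$ids
    out[[tp]] <- dca_embed(prof, d, solver = solver, node_type = tp)
  }
  out
}

#' Write / read node feature matrices as TSV (node IDs in the first column)
#' @param features named list of `node_features` as from [compact_features()].
#' @param dir_path output directory.
#' @export
write_features <- function(features, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(features)) {
    m <- features[[tp]]$matrix
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(dir_path, paste0(tp, "_features.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}

#' @rdname write_features
#' @export
read_features <- function(dir_path) {
  out <- list()
  for (tp in c("drug", "protein")) {
    f <- file.path(dir_path, paste0(tp, "_features.tsv"))
    if (!file.exists(f)) drh_stop("missing feature file: %s", f)
    df <- read.table(f, sep = "\t", header = TRUE, check.names = FALSE,
                     colClasses = c(id = "character"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    out[[tp]] <- structure(list(matrix = m, dim = ncol(m), node_type = tp,
                                solver = "file"),
                           class = "node_features")
  }
  out
}
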