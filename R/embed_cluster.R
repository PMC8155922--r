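#' Principal component analysis of a metabolite matrix
#'
#' Eigendecomposition of the column-centered covariance via SVD, reporting
#' the first `n_components` (default 30) eigenvalues, orthonormal
#' eigenvectors, voxel scores, and each component's share of the total
#' column variance. The eigenvector sign is fixed so that the
#' largest-magnitude loading of every component is positive.
#'
#' @param X Matrix (voxels x metabolites) or `normalized_matrix`.
#' @param n_components Number of components to keep (reduced with a warning
#'   when fewer are available).
#' @return Object of class `pca_result`: `eigenvalues`, `eigenvectors`
#'   (features x k), `scores` (voxels x k), `explained_share`,
#'   `total_variance`, `center`.
#' @export
mrs_pca <- function(X, n_components = 30) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  k_max <- min(n - 1, p)
  if (n_components > k_max) {
    warning(sprintf("only %d components available; reducing from %d",
                    k_max, n_components), call. = FALSE)
    n_components <- k_max
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, `-`)
  sv <- svd(Xc, nu = 0, nv = k_max)
  eig <- sv$d[seq_len(k_max)]^2 / (n - 1)
  total <- sum(Xc^2) / (n - 1)
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(V) <- colnames(X)
  structure(list(eigenvalues = eig[seq_len(n_components)],
                 eigenvectors = V, scores = scores,
                 explained_share = eig[seq_len(n_components)] / total,
                 total_variance = total, center = ctr),
            class = "pca_result")
}

#' Select non-trivial principal components by parallel analysis
#'
#' Compares the observed eigenvalue spectrum to that of an ensemble of
#' signal-free matrices built by independently permuting each column of `X`
#' (marginals preserved, correlation destroyed). Component i is non-trivial
#' iff its eigenvalue exceeds the `quantile` (default 95th percentile, the
#' usual parallel-analysis convention, which keeps the per-component
#' false-selection rate near 5%) of the i-th randomized eigenvalue; the
#' contiguous leading run of such components is returned.
#'
#' @param X Matrix or `normalized_matrix`.
#' @param n_randomizations Ensemble size (default 20).
#' @param n_components Components examined (default 30, capped by the data).
#' @param quantile Ensemble quantile used as the threshold; 0.5 would compare
#'   against the ensemble mean-rank behaviour, 0.95 is the default.
#' @param seed Integer seed.
#' @return Integer vector of selected component indices (possibly empty),
#'   with the observed and threshold eigenvalues as attributes.
#' @export
select_nontrivial <- function(X, n_randomizations = 20, n_components = 30,
                              quantile = 0.95, seed = 1L) {
  X <- as_feature_matrix(X)
  k <- min(n_components, nrow(X) - 1, ncol(X))
  obs <- suppressWarnings(mrs_pca(X, k)$eigenvalues)
  rnd <- with_seed(seed, {
    acc <- matrix(0, n_randomizations, k)
    for (r in seq_len(n_randomizations)) {
      Xp <- apply(X, 2, sample)
      acc[r, ] <- suppressWarnings(mrs_pca(Xp, k)$eigenvalues)
    }
    acc
  })
  thr <- apply(rnd, 2, stats::quantile, probs = quantile, names = FALSE)
  nontrivial <- obs > thr
  n_sel <- if (all(nontrivial)) k else which.min(nontrivial) - 1L
  sel <- seq_len(n_sel)
  attr(sel, "eigenvalues") <- obs
  attr(sel, "threshold") <- thr
  sel
}

# shared-nearest-neighbor graph: neighbor sets of size k (self included);
# every pair of points sharing at least one neighbor gets an edge weighted
# by the Jaccard overlap of their neighbor sets, pruned below `prune`
snn_graph <- function(scores, k_neighbors = 20, prune = 1 / 15) {
  n <- nrow(scores)
  if (k_neighbors >= n) {
    stop("k_neighbors must be smaller than the number of points",
         call. = FALSE)
  }
  nn <- FNN::get.knn(scores, k = k_neighbors - 1)$nn.index
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                            j = c(seq_len(n), as.vector(nn)),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)  # S[i,j] = |N(i) intersect N(j)|
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  inter <- S@x
  jac <- inter / (2 * k_neighbors - inter)
  keep <- jac >= prune
  list(from = S@i[keep] + 1L, to = S@j[keep] + 1L, weight = jac[keep],
       n = n)
}

#' Shared-nearest-neighbor clustering
#'
#' Builds a k-nearest-neighbor graph (Euclidean), weights each edge by the
#' Jaccard overlap of the two endpoints' neighbor sets (self included),
#' prunes weights below 1/15, and partitions the weighted graph by Louvain
#' community detection (resolution 0.2, favouring macroscopic tissue-scale
#' communities over the fine sub-communities a geometric kNN graph always
#' contains). Cluster ids are relabeled 1..K by decreasing size.
#'
#' @param scores Matrix (voxels x dims), e.g. non-trivial PCA scores.
#' @param k_neighbors Neighborhood size (default 20).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @param resolution Louvain modularity resolution (default 0.2).
#' @param seed Integer seed (Louvain is randomized).
#' @return Object of class `cluster_result`: `labels` (integer per voxel),
#'   `k` (number of clusters), `k_neighbors`, `embedding2d` (NULL until
#'   [embed2d()] fills it).
#' @export
snn_cluster <- function(scores, k_neighbors = 20, prune = 1 / 15,
                        resolution = 0.2, seed = 1L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 3) stop("too few points to cluster", call. = FALSE)
  if (anyDuplicated(scores) == 0) {
    g <- snn_graph(scores, k_neighbors, prune)
  } else {
    # exact duplicates break kNN ties arbitrarily; jitter-free handling:
    # collapse duplicates, cluster the unique points, propagate labels
    key <- apply(scores, 1, paste, collapse = "\r")
    uniq <- !duplicated(key)
    if (sum(uniq) < 3 || sum(uniq) <= k_neighbors) {
      labels <- as.integer(factor(key, levels = unique(key)))
      sizes <- sort(table(labels), decreasing = TRUE)
      relab <- stats::setNames(seq_along(sizes), names(sizes))
      labels <- unname(relab[as.character(labels)])
      return(structure(list(labels = labels, k = max(labels),
                            k_neighbors = k_neighbors, embedding2d = NULL),
                       class = "cluster_result"))
    }
    sub <- snn_cluster(scores[uniq, , drop = FALSE], k_neighbors, prune,
                       resolution, seed)
    labels <- sub$labels[match(key, key[uniq])]
    return(structure(list(labels = labels, k = sub$k,
                          k_neighbors = k_neighbors, embedding2d = NULL),
                     class = "cluster_result"))
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$from, to = g$to, weight = g$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n)))
  comm <- with_seed(seed, igraph::cluster_louvain(ig,
                                                  resolution = resolution))
  memb <- igraph::membership(comm)
  labels <- as.integer(memb[as.character(seq_len(g$n))])
  sizes <- sort(table(labels), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- unname(relab[as.character(labels)])
  structure(list(labels = labels, k = max(labels),
                 k_neighbors = k_neighbors, embedding2d = NULL),
            class = "cluster_result")
}

#' 2D UMAP embedding
#'
#' Uniform Manifold Approximation and Projection of the voxel scores to two
#' dimensions (library-backed via \pkg{uwot}), run single-threaded so the
#' result is deterministic given `seed`.
#'
#' @param scores Matrix (voxels x dims).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (default 15, capped at n - 1).
#' @return Matrix, voxels x 2.
#' @export
embed2d <- function(scores, seed = 1L, n_neighbors = 15) {
  scores <- as.matrix(scores)
  n_neighbors <- min(n_neighbors, nrow(scores) - 1)
  emb <- with_seed(seed, uwot::umap(scores, n_neighbors = n_neighbors,
                                    n_threads = 1, n_sgd_threads = 1))
  colnames(emb) <- c("umap1", "umap2")
  emb
}

#' Marker metabolites per cluster
#'
#' For every (cluster, metabolite) pair, a two-sided Wilcoxon rank-sum test
#' of in-cluster vs all other voxels, Benjamini-Hochberg adjusted across all
#' pairs; a pair is flagged as a marker when adjusted p < alpha and the
#' effect (log2 ratio of means) is positive (enrichment).
#'
#' @param X Matrix (voxels x metabolites) or [metabolite_table()].
#' @param labels Cluster labels per voxel.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param min_size Clusters below this size are skipped with a warning.
#' @return Data frame of class `marker_table`: `cluster`, `metabolite`,
#'   `log2fc`, `p`, `p_adj`, `marker`.
#' @export
marker_metabolites <- function(X, labels, alpha = 0.05, min_size = 3) {
  if (inherits(X, "metabolite_table")) X <- X$values
  X <- as_feature_matrix(X)
  labels <- as.vector(labels)
  stopifnot(length(labels) == nrow(X))
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least 2 clusters", call. = FALSE)
  eps <- 1e-9
  rows <- list()
  for (cc in cl) {
    in_cl <- labels == cc
    if (sum(in_cl) < min_size || sum(!in_cl) < min_size) {
      warning(sprintf("cluster %s too small (< %d voxels); skipped", cc,
                      min_size), call. = FALSE)
      next
    }
    for (j in seq_len(ncol(X))) {
      a <- X[in_cl, j]
      b <- X[!in_cl, j]
      p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cc,
        metabolite = colnames(X)[j] %||% as.character(j),
        log2fc = log2(max(mean(a), eps) / max(mean(b), eps)),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$marker <- out$p_adj < alpha & out$log2fc > 0
  class(out) <- c("marker_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
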