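test_that("pca satisfies rank, reconstruction and variance identities", {
  set.seed(1)
  # rank-1 matrix: the first component carries everything
  X1 <- runif(40) %*% t(runif(6))
  p1 <- suppressWarnings(mrs_pca(X1, 6))
  expect_gt(p1$explained_share[1], 1 - 1e-10)

  X <- matrix(rnorm(30 * 5), 30, 5)
  pr <- suppressWarnings(mrs_pca(X, 5))
  expect_equal(sum(pr$eigenvalues), pr$total_variance, tolerance = 1e-8)
  expect_equal(sum(pr$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-8)
  # orthonormal loadings and exact reconstruction at full rank
  expect_equal(crossprod(pr$eigenvectors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  Xc <- sweep(X, 2, colMeans(X), `-`)
  expect_equal(pr$scores %*% t(pr$eigenvectors), Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign convention
  for (j in 1:5) {
    v <- pr$eigenvectors[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("isotropic data spreads variance evenly across components", {
  set.seed(2)
  X <- matrix(rnorm(4000 * 5), 4000, 5)
  pr <- suppressWarnings(mrs_pca(X, 5))
  expect_true(all(abs(pr$explained_share - 0.2) < 0.04))
})

test_that("parallel analysis recovers planted rank and rejects noise", {
  X <- spike_matrix(seed = 3)
  sel <- select_nontrivial(X, seed = 3)
  expect_identical(as.integer(sel), 1:3)
  set.seed(4)
  Z <- matrix(rnorm(100 * 20), 100, 20)
  expect_lte(length(select_nontrivial(Z, seed = 4)), 1)
  expect_identical(as.integer(select_nontrivial(X, seed = 3)),
                   as.integer(sel))
})

test_that("selection is monotone in the planted signal strength", {
  set.seed(9)
  p <- 20
  V <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  F_ <- matrix(rnorm(100 * 3), 100, 3)
  Z <- matrix(rnorm(100 * p), 100, p)
  n_sel <- vapply(c(0.5, 2, 8, 20, 60), function(theta) {
    length(select_nontrivial(F_ %*% t(V) * sqrt(theta) + Z, seed = 9))
  }, numeric(1))
  expect_true(all(diff(n_sel) >= 0))
  expect_equal(n_sel[5], 3)
})

test_that("the SNN graph matches brute-force Jaccard enumeration", {
  pts <- cbind(c(0, 1, 2.1, 9, 10), c(0, 0.2, -0.1, 5, 5.3))
  k <- 2
  g <- mrsport:::snn_graph(pts, k_neighbors = k, prune = 0)
  # brute force: neighbor set = self + (k-1) nearest, all overlapping pairs
  D <- as.matrix(dist(pts))
  sets <- lapply(1:5, function(i) {
    c(i, setdiff(order(D[i, ]), i)[seq_len(k - 1)])
  })
  for (e in seq_along(g$from)) {
    inter <- length(intersect(sets[[g$from[e]]], sets[[g$to[e]]]))
    expect_equal(g$weight[e], inter / (2 * k - inter))
  }
  # every sharing pair is present
  expected <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    expected <- expected + (length(intersect(sets[[i]], sets[[j]])) > 0)
  }
  expect_equal(length(g$from), expected)
})

test_that("snn clustering recovers well-separated blobs", {
  b <- blob_points(seed = 5, n_per = 50)
  cl <- snn_cluster(b$x, seed = 1)
  expect_equal(cl$k, 3)
  expect_gte(rand_index_adj(cl$labels, b$labels), 0.95)
  # row-permutation invariance: the partition is unchanged
  perm <- sample(nrow(b$x))
  cl2 <- snn_cluster(b$x[perm, ], seed = 1)
  expect_equal(rand_index_adj(cl2$labels, cl$labels[perm]), 1)
})

test_that("degenerate point sets collapse to single clusters", {
  same <- matrix(1, 30, 2)
  cl <- snn_cluster(same, seed = 1)
  expect_equal(cl$k, 1)
  expect_error(snn_cluster(matrix(rnorm(4), 2, 2)), "too few")
})

test_that("umap embedding is deterministic and separates blobs", {
  b <- blob_points(seed = 6, n_per = 40)
  e1 <- embed2d(b$x, seed = 2)
  expect_identical(dim(e1), c(120L, 2L))
  expect_identical(e1, embed2d(b$x, seed = 2))
  D <- as.matrix(dist(e1))
  within <- mean(D[outer(b$labels, b$labels, `==`) & upper.tri(D)])
  between <- mean(D[outer(b$labels, b$labels, `!=`) & upper.tri(D)])
  expect_lt(within, between)
})

test_that("marker enrichment flags planted signals", {
  set.seed(7)
  X <- matrix(rlnorm(100 * 8), 100, 8)
  colnames(X) <- paste0("M", 1:8)
  labels <- rep(1:2, each = 50)
  X[labels == 2, 3] <- X[labels == 2, 3] * 2  # planted 2x enrichment
  mk <- marker_metabolites(X, labels)
  expect_true(all(mk$p_adj >= mk$p))
  expect_true(all(mk$p >= 0 & mk$p <= 1))
  hit <- mk[mk$cluster == 2 & mk$metabolite == "M3", ]
  expect_true(hit$marker)
  expect_gt(hit$log2fc, 0.5)
  expect_error(marker_metabolites(X, rep(1, 100)), "2 clusters")
})

test_that("small-sample marker p-values equal exact rank-sum enumeration", {
  x <- c(1.3, 2.9, 0.4, 2.1, 3.8, 0.9)  # no ties
  labels <- c(1, 1, 1, 2, 2, 2)
  X <- cbind(M1 = x, M2 = rev(x))
  mk <- marker_metabolites(X, labels, min_size = 3)
  # enumerate all 20 rank assignments of 3-vs-3
  exact_p <- function(vals, grp) {
    r <- rank(vals)
    w_obs <- sum(r[grp == 1])
    combos <- combn(6, 3)
    ws <- apply(combos, 2, function(ii) sum(r[ii]))
    mu <- mean(ws)
    mean(abs(ws - mu) >= abs(w_obs - mu))
  }
  for (m in c("M1", "M2")) {
    got <- mk$p[mk$cluster == 1 & mk$metabolite == m]
    expect_equal(got, exact_p(X[, m], labels), tolerance = 1e-12)
  }
})
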