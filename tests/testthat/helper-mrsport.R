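# shared fixtures, all generated in code

# three tight Gaussian blobs, far apart
blob_points <- function(seed = 1, n_per = 100, sd = 0.1,
                        centers = rbind(c(0, 0), c(10, 0), c(0, 10))) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    sweep(matrix(stats::rnorm(2 * n_per, 0, sd), n_per, 2), 2,
          centers[k, ], `+`)
  }))
  list(x = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# planted k equal-strength orthonormal spikes over unit Gaussian noise
spike_matrix <- function(seed = 1, n = 100, p = 20, k = 3, theta = 20) {
  set.seed(seed)
  V <- qr.Q(qr(matrix(stats::rnorm(p * k), p, k)))
  matrix(stats::rnorm(n * k), n, k) %*% t(V) * sqrt(theta) +
    matrix(stats::rnorm(n * p), n, p)
}

# adjusted Rand index (Hubert & Arabie), written out so cluster tests do not
# depend on the clustering code under test
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# tiny three-peak basis with well-separated resonances
three_peak_basis <- function(width = 0.04, lineshape = "lorentzian") {
  pk <- function(cen) {
    m <- matrix(c(cen, width, 1), ncol = 3)
    colnames(m) <- c("center", "width", "amp")
    m
  }
  structure(list(A = pk(1.0), B = pk(2.2), C = pk(3.4)),
            lineshape = lineshape, class = "basis_set")
}

default_ppm <- function(n = 512) seq(0.2, 4.2, length.out = n)
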