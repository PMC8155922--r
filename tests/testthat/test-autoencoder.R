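# independent inference-mode forward pass used as the reference oracle
oracle_forward <- function(model, X, upto = NULL) {
  sig <- function(x) 1 / (1 + exp(-x))
  layers <- c(model$enc, model$dec)
  if (!is.null(upto)) layers <- layers[seq_len(upto)]
  nh <- length(model$spec$encoder_widths)
  A <- X
  for (k in seq_along(layers)) {
    lyr <- layers[[k]]
    Z <- A %*% lyr$W
    for (j in seq_len(ncol(Z))) Z[, j] <- Z[, j] + lyr$b[j]
    if (k <= nh && model$spec$batch_norm) {
      for (j in seq_len(ncol(Z))) {
        Z[, j] <- (Z[, j] - lyr$rmean[j]) / sqrt(lyr$rvar[j] + 1e-5) *
          lyr$gamma[j] + lyr$beta[j]
      }
    }
    A <- sig(Z)
  }
  A
}

test_that("sigmoid matches its closed form and identities", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-3, -1, 2, 10)) expect_equal(sigmoid(x) + sigmoid(-x), 1)
  expect_equal(sigmoid(1), 0.731058578630005, tolerance = 1e-14)
  expect_equal(sigmoid(1000), 1)  # saturates without overflow
})

test_that("initialization builds the mirrored 34-32-16-8-6 architecture", {
  m <- init_autoencoder(seed = 1)
  dims <- function(lyrs) lapply(lyrs, function(l) dim(l$W))
  expect_identical(dims(m$enc),
                   list(c(34L, 32L), c(32L, 16L), c(16L, 8L), c(8L, 6L)))
  expect_identical(dims(m$dec),
                   list(c(6L, 8L), c(8L, 16L), c(16L, 32L), c(32L, 34L)))
  expect_true(all(vapply(c(m$enc, m$dec),
                         function(l) all(l$b == 0), logical(1))))
  m2 <- init_autoencoder(seed = 1)
  expect_identical(m, m2)
  expect_error(layer_spec(bottleneck = 9), "smaller than")
  expect_error(layer_spec(encoder_widths = c(16, 32, 8)),
               "strictly decreasing")
  expect_error(layer_spec(dropout = 1), "\\[0, 1\\)")
})

test_that("encode and reconstruct match an independent forward oracle", {
  set.seed(4)
  m <- init_autoencoder(seed = 4)
  # make running statistics non-trivial so the oracle exercises batch norm
  for (k in 1:3) {
    m$enc[[k]]$rmean <- rnorm(ncol(m$enc[[k]]$W), 0, 0.3)
    m$enc[[k]]$rvar <- runif(ncol(m$enc[[k]]$W), 0.5, 2)
    m$enc[[k]]$gamma <- runif(ncol(m$enc[[k]]$W), 0.5, 1.5)
    m$enc[[k]]$beta <- rnorm(ncol(m$enc[[k]]$W), 0, 0.2)
  }
  X <- matrix(runif(12 * 34), 12, 34)
  expect_lt(max(abs(encode(m, X) - oracle_forward(m, X, upto = 4))), 1e-10)
  rec <- reconstruct(m, X)
  expect_lt(max(abs(rec - oracle_forward(m, X))), 1e-10)
  expect_identical(dim(rec), dim(X))
  expect_true(all(rec > 0 & rec < 1))
  expect_error(encode(m, X[, 1:10]), "columns")
})

test_that("zero parameters map every voxel to 0.5", {
  m <- init_autoencoder(seed = 1)
  for (k in seq_along(m$enc)) m$enc[[k]]$W[] <- 0
  for (k in seq_along(m$dec)) m$dec[[k]]$W[] <- 0
  X <- matrix(runif(5 * 34), 5, 34)
  expect_true(all(abs(encode(m, X) - 0.5) < 1e-12))
  expect_true(all(abs(reconstruct(m, X) - 0.5) < 1e-12))
})

test_that("training descends, is deterministic, and validates input", {
  set.seed(11)
  X <- matrix(runif(60 * 34), 60, 34)
  m <- init_autoencoder(seed = 11)
  tr <- train_autoencoder(m, X, epochs = 40, seed = 11)
  h <- tr$report$loss_history
  expect_equal(nrow(h), 40)
  expect_lte(h$train[40], h$train[1])
  tr2 <- train_autoencoder(m, X, epochs = 40, seed = 11)
  expect_identical(tr$model, tr2$model)

  noop <- train_autoencoder(m, X, epochs = 0, seed = 11)
  expect_identical(noop$model, m)
  expect_error(train_autoencoder(m, X * 2, seed = 1), "normalized")
  expect_error(train_autoencoder(m, X[1:5, ], seed = 1), "at least 10")
})

test_that("a noiseless rank-1 matrix is reconstructed accurately", {
  set.seed(2)
  X <- runif(200) %*% t(runif(34))
  X <- (X - min(X)) / (max(X) - min(X))
  tr <- train_autoencoder(init_autoencoder(seed = 2), X, epochs = 500,
                          seed = 2)
  expect_lt(tail(tr$report$loss_history$heldout, 1), 0.01)
})

test_that("denoising concentrates variance on the leading components", {
  set.seed(5)
  signal <- matrix(runif(200 * 2), 200, 2) %*% matrix(runif(2 * 34), 2, 34)
  X <- signal + matrix(rnorm(200 * 34, 0, 0.15), 200, 34)
  X <- apply(X, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  tr <- train_autoencoder(init_autoencoder(seed = 5), X, epochs = 200,
                          seed = 5)
  den <- denoise(tr$model, X)
  expect_identical(dim(den$values), dim(X))
  expect_true(isTRUE(attr(den, "denoised")))
  share2 <- function(M) sum(mrs_pca(M, 5)$explained_share[1:2])
  expect_gt(share2(den$values), share2(X))
  # denoising is nearly idempotent compared to its own step size
  dd <- denoise(tr$model, den$values)
  expect_lt(norm(dd$values - den$values, "F"),
            norm(den$values - X, "F"))
  expect_warning(denoise(init_autoencoder(seed = 1), X), "untrained")
})

test_that("bottleneck search scans the candidate grid deterministically", {
  set.seed(6)
  signal <- matrix(runif(80 * 2), 80, 2) %*% matrix(runif(2 * 12), 2, 12)
  X <- signal + matrix(rnorm(80 * 12, 0, 0.1), 80, 12)
  X <- apply(X, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  bs <- bottleneck_search(X, sizes = 4:10, epochs = 30, seed = 6)
  expect_identical(bs$benchmark$size, 4:10)
  expect_true(bs$best %in% 4:10)
  expect_true(all(is.finite(bs$benchmark$benchmark)))
  bs2 <- bottleneck_search(X, sizes = 4:10, epochs = 30, seed = 6)
  expect_identical(bs, bs2)
  expect_error(bottleneck_search(X, sizes = c(1, 12), epochs = 5, seed = 1),
               "n_inputs")
})
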