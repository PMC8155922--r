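gauss2 <- function(seed, n = 60, d = 6, sep = 3) {
  set.seed(seed)
  mu1 <- rnorm(d)
  mu2 <- mu1 + sep * rnorm(d) / sqrt(d)
  X <- rbind(sweep(matrix(rnorm(n * d), n, d), 2, mu1, `+`),
             sweep(matrix(rnorm(n * d), n, d), 2, mu2, `+`))
  list(X = X, y = rep(c("a", "b"), each = n), mu1 = mu1, mu2 = mu2)
}

test_that("two-class fit is collinear with the closed-form discriminant", {
  for (s in 1:5) {
    g <- gauss2(s)
    m <- fit_lda(g$X, g$y)
    mu_a <- colMeans(g$X[g$y == "a", ])
    mu_b <- colMeans(g$X[g$y == "b", ])
    ref <- solve(m$Sigma + diag(m$reg, ncol(g$X)), mu_a - mu_b)
    cosine <- abs(sum(m$w[, 1] * ref)) /
      (sqrt(sum(m$w[, 1]^2)) * sqrt(sum(ref^2)))
    expect_gte(cosine, 0.999)
  }
})

test_that("equal class means give zero between-class scatter", {
  set.seed(1)
  X <- matrix(rnorm(40 * 4), 40, 4)
  X2 <- rbind(X, X)  # identical samples in both classes -> identical means
  m <- fit_lda(X2, rep(c("a", "b"), each = 40))
  expect_lt(max(abs(m$Sigma_b)), 1e-20)
  expect_lt(fisher_criterion(m), 1e-12)
})

test_that("the returned direction locally maximizes the Fisher criterion", {
  g <- gauss2(7)
  m <- fit_lda(g$X, g$y)
  s_opt <- fisher_criterion(m)
  set.seed(7)
  for (i in 1:100) {
    w <- rnorm(ncol(g$X))
    expect_gte(s_opt + 1e-10, fisher_criterion(m, w / sqrt(sum(w^2))))
  }
})

test_that("three separated Gaussians are classified near-perfectly", {
  set.seed(3)
  ctr <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(50 * 3), 50, 3), 2, ctr[k, ], `+`)
  }))
  y <- rep(c("p", "q", "r"), each = 50)
  m <- fit_lda(X, y)
  pred <- predict_lda(m, X)
  expect_gte(mean(pred$predicted == y), 0.99)
  # class means score their own class highest
  expect_identical(predict_lda(m, ctr)$predicted, c("p", "q", "r"))
  expect_equal(unname(rowSums(pred$prob)), rep(1, 150), tolerance = 1e-8)
  expect_error(fit_lda(X[c(1, 51, 52), ], y[c(1, 51, 52)]),
               "fewer than 2 samples")
})

test_that("predicted discriminants match a brute-force density oracle", {
  g <- gauss2(9, n = 40)
  m <- fit_lda(g$X, g$y)
  set.seed(10)
  Xnew <- matrix(rnorm(10 * 6), 10, 6)
  got <- predict_lda(m, Xnew)
  Z <- Xnew %*% m$w
  Sinv <- solve(m$proj_cov)
  for (i in 1:10) {
    for (k in 1:2) {
      d <- Z[i, ] - m$proj_means[k, ]
      expect_equal(unname(got$scores[i, k]),
                   as.numeric(-0.5 * t(d) %*% Sinv %*% d),
                   tolerance = 1e-10)
    }
    dens <- exp(got$scores[i, ])
    expect_equal(unname(got$prob[i, ]), unname(dens / sum(dens)),
                 tolerance = 1e-10)
  }
})

test_that("calibration centers, scales, stores and preserves rankings", {
  g <- gauss2(12, n = 30)
  m <- fit_lda(g$X, g$y)
  sc <- predict_lda(m, g$X)
  cal <- calibrate_scores(sc)
  expect_equal(unname(colMeans(cal$scores)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(cal$scores, 2, sd)), c(1, 1), tolerance = 1e-8)
  # reapplying the stored parameters is idempotent on already-new data
  params <- attr(cal, "calibration")
  again <- calibrate_scores(sc, params = params)
  expect_equal(again$scores, cal$scores, tolerance = 1e-12)
  for (k in 1:2) {
    expect_equal(cor(rank(sc$scores[, k]), rank(cal$scores[, k])), 1)
  }
  # calibration never changes within-class argmax ordering
  expect_identical(apply(cal$scores, 2, which.max),
                   apply(sc$scores, 2, which.max))
  degenerate <- sc
  degenerate$scores[, 1] <- 1
  expect_error(calibrate_scores(degenerate), "zero score variance")
  expect_error(calibrate_scores(predict_lda(m, g$X[1:5, ])), "at least 10")
})

test_that("the patient score is the mean voxel score per class", {
  g <- gauss2(14, n = 30)
  m <- fit_lda(g$X, g$y)
  sc <- calibrate_scores(predict_lda(m, g$X))
  s7 <- sport_score(sc, voxels = 1:7)
  expect_equal(unname(unclass(s7)),
               unname(colSums(sc$scores[1:7, ]) / 7), tolerance = 1e-12)
  s1 <- sport_score(sc, voxels = 3)
  expect_equal(unname(unclass(s1)), unname(sc$scores[3, ]))
  # identical score vectors: mean equals the vector
  rep_sc <- sc
  rep_sc$scores <- matrix(rep(c(1.5, -0.5), each = 4), 4, 2,
                          dimnames = list(NULL, colnames(sc$scores)))
  expect_equal(unname(unclass(sport_score(rep_sc))), c(1.5, -0.5))
  expect_s3_class(sport_score(sc, voxels = integer(0)), "no_tumor")
})

test_that("rank-based AUC equals pair counting and handles ties", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(15)
  for (i in 1:20) {
    s <- sample(1:4, 8, replace = TRUE)  # ties guaranteed
    l <- c(0, 1, sample(0:1, 6, replace = TRUE))
    pairs <- expand.grid(p = which(l == 1), n = which(l == 0))
    oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                          ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
    expect_equal(roc_auc(s, l), oracle, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both label")
})

test_that("rank-based AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  s <- rnorm(40)
  l <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("two-layer prediction masks tumor voxels and names a subtype", {
  co <- generate_cohort(phantom_config(seed = 1),
                        c(wt = 2, IDH = 2, LOH = 2), seed = 31)
  X <- do.call(rbind, lapply(co, function(p) p$study$metabolites$values))
  seg <- unlist(lapply(co, function(p) {
    s <- p$study
    unname(s$segmentation[s$metabolites$voxel_ids])
  }))
  sub <- rep(vapply(co, `[[`, character(1), "subtype"), each = 256)
  nm <- minmax_normalize(X)
  region <- region_from_segment(seg)
  l1 <- fit_lda(nm$values, region, cls = class_set("REGION"))
  tum <- seg %in% c("TUMOR", "CONTRAST")
  l2 <- fit_lda(nm$values[tum, ], sub[tum], cls = class_set("SUBTYPE"))
  cal <- attr(calibrate_scores(predict_lda(l2, nm$values[tum, ])),
              "calibration")
  # a wildtype phantom is predicted wt
  pred <- two_layer_predict(l1, l2, nm$values[1:256, ], calibration = cal)
  expect_false(pred$no_tumor)
  expect_identical(pred$predicted, "wt")
  expect_true(all(which(pred$tumor_mask) %in%
                    which(seg[1:256] %in%
                            c("TUMOR", "CONTRAST", "NECROSIS"))))
  # a pure-NAM phantom yields the explicit no-tumor outcome
  nam_cfg <- phantom_config(seed = 77)
  nam_cfg$tissue_geometry <- list(list(label = "NAM", shape = "background"))
  nam <- generate_phantom(nam_cfg)
  Xn <- apply_normalization(nm, nam$study$metabolites$values)
  pred0 <- two_layer_predict(l1, l2, Xn$values, calibration = cal)
  expect_true(pred0$no_tumor)
  expect_true(is.na(pred0$predicted))
})

test_that("score maps land on the study grid", {
  ph <- generate_phantom(phantom_config(grid_rows = 4, grid_cols = 4,
                                        seed = 9))
  n <- 16
  sc <- structure(list(
    scores = matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b"))),
    prob = matrix(0.5, n, 2, dimnames = list(NULL, c("a", "b"))),
    predicted = rep("a", n), classes = c("a", "b"), calibrated = FALSE),
    class = "voxel_scores")
  maps <- render_score_map(sc, ph$study)
  expect_identical(dim(maps$a), c(4L, 4L))
  expect_true(all(maps$a == 0.5))
  # voxel -> pixel mapping round-trips through the grid coordinates
  mt <- ph$study$metabolites
  sc$prob[, "a"] <- seq_len(n)
  maps <- render_score_map(sc, ph$study)
  for (i in seq_len(n)) {
    expect_equal(maps$a[mt$row[i] + 1, mt$col[i] + 1], i)
  }
})
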