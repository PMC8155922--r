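#' Fit a multiclass Fisher linear discriminant model
#'
#' Between-class scatter is the unweighted average of the outer products of
#' the class-mean deviations from the grand mean of class means; within-class
#' scatter is the pooled scatter divided by (n - C). The discriminant
#' directions are the leading C - 1 eigenvectors of
#' (Sigma + reg I)^-1 Sigma_b, column-normalized with the largest-magnitude
#' loading positive. A small ridge `reg = lambda * trace(Sigma) / p` keeps
#' the within-class covariance invertible when small samples make it rank
#' deficient.
#'
#' @param X Feature matrix (samples x features), typically the
#'   autoencoder-denoised normalized metabolite vectors.
#' @param y Class labels per sample.
#' @param cls A [class_set()] fixing the class order (classes absent from
#'   `y` are dropped); `NULL` uses sorted unique labels.
#' @param lambda Relative ridge strength (default 1e-4).
#' @return Object of class `lda_model`: `classes`, `class_set`, `means`
#'   (classes x features), `grand_mean`, `Sigma_b`, `Sigma`, `reg`, `w`
#'   (features x C-1), projected class means `proj_means` and projected
#'   pooled covariance `proj_cov`.
#' @export
fit_lda <- function(X, y, cls = NULL, lambda = 1e-4) {
  X <- as_feature_matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- if (is.null(cls)) sort(unique(y)) else {
    intersect(cls$classes, unique(y))
  }
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(counts)[which(counts < 2)[1]]), call. = FALSE)
  }
  p <- ncol(X)
  C <- length(classes)
  mu_i <- t(vapply(classes, function(cc) colMeans(X[y == cc, , drop = FALSE]),
                   numeric(p)))
  mu <- colMeans(mu_i)
  Sigma_b <- matrix(0, p, p)
  for (i in seq_len(C)) {
    d <- mu_i[i, ] - mu
    Sigma_b <- Sigma_b + tcrossprod(d)
  }
  Sigma_b <- Sigma_b / C
  Sw <- matrix(0, p, p)
  for (i in seq_len(C)) {
    Xi <- sweep(X[y == classes[i], , drop = FALSE], 2, mu_i[i, ], `-`)
    Sw <- Sw + crossprod(Xi)
  }
  Sigma <- Sw / (nrow(X) - C)
  reg <- lambda * sum(diag(Sigma)) / p
  if (reg <= 0) reg <- lambda
  Sreg <- Sigma + diag(reg, p)
  M <- solve(Sreg, Sigma_b)
  ev <- eigen(M)
  ord <- order(Re(ev$values), decreasing = TRUE)
  k <- C - 1
  w <- Re(ev$vectors[, ord[seq_len(k)], drop = FALSE])
  for (j in seq_len(k)) {
    w[, j] <- w[, j] / sqrt(sum(w[, j]^2))
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  rownames(w) <- colnames(X)
  proj_means <- mu_i %*% w
  proj_cov <- crossprod(w, Sreg) %*% w
  structure(list(classes = classes, class_set = cls, means = mu_i,
                 grand_mean = mu, Sigma_b = Sigma_b, Sigma = Sigma,
                 reg = reg, lambda = lambda, w = w,
                 proj_means = proj_means, proj_cov = proj_cov),
            class = "lda_model")
}

#' Fisher criterion of a direction
#'
#' S(w) = (w' Sigma_b w) / (w' Sigma w), the between- over within-class
#' scatter ratio the discriminant directions maximize.
#'
#' @param model An `lda_model`.
#' @param w Direction vector (defaults to the model's first discriminant).
#' @return Scalar criterion value.
#' @export
fisher_criterion <- function(model, w = model$w[, 1]) {
  as.numeric((t(w) %*% model$Sigma_b %*% w) /
               (t(w) %*% (model$Sigma + diag(model$reg, ncol(model$Sigma)))
                %*% w))
}

#' Per-voxel class scores and probabilities
#'
#' Projects the features onto the discriminant directions and evaluates, per
#' class, the Gaussian discriminant with shared (pooled) covariance in the
#' projected space — the homoscedastic model underlying LDA. A softmax over
#' the discriminants yields posterior-like probabilities (equal priors).
#'
#' @param model An `lda_model`.
#' @param X Feature matrix with the model's feature count.
#' @return Object of class `voxel_scores`: `scores` (samples x classes,
#'   uncalibrated log-density discriminants), `prob` (rows sum to 1),
#'   `predicted` (argmax class, ties to the first class in model order),
#'   `calibrated = FALSE`.
#' @export
predict_lda <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != nrow(model$w)) {
    stop(sprintf("X has %d features, model expects %d", ncol(X),
                 nrow(model$w)), call. = FALSE)
  }
  Z <- X %*% model$w
  Sinv <- solve(model$proj_cov)
  disc <- vapply(seq_along(model$classes), function(i) {
    d <- sweep(Z, 2, model$proj_means[i, ], `-`)
    -0.5 * rowSums((d %*% Sinv) * d)
  }, numeric(nrow(Z)))
  disc <- matrix(disc, nrow = nrow(Z),
                 dimnames = list(rownames(X), model$classes))
  m <- apply(disc, 1, max)
  e <- exp(disc - m)
  prob <- e / rowSums(e)
  pred <- model$classes[apply(disc, 1, which.max)]
  structure(list(scores = disc, prob = prob, predicted = pred,
                 classes = model$classes, calibrated = FALSE),
            class = "voxel_scores")
}

#' Calibrate class scores against a reference distribution
#'
#' Fits a Gaussian to each class's score column over a reference voxel set
#' and z-scores (centers and scales) the scores with the fitted parameters.
#' The parameters are stored so the same calibration can be reapplied to new
#' data via the `params` argument; calibration is monotone per class and so
#' never reorders voxels within a class's ranking.
#'
#' @param scores A `voxel_scores` (the reference set when `params` is NULL).
#' @param params Optional stored calibration (`calibration` attribute of an
#'   earlier result) to reapply.
#' @return A `voxel_scores` with calibrated `scores` (`calibrated = TRUE`)
#'   and the calibration parameters in attribute `"calibration"`.
#' @export
calibrate_scores <- function(scores, params = NULL) {
  stopifnot(inherits(scores, "voxel_scores"))
  if (is.null(params)) {
    if (nrow(scores$scores) < 10) {
      stop("reference set must contain at least 10 voxels", call. = FALSE)
    }
    mu <- colMeans(scores$scores)
    sd_ <- apply(scores$scores, 2, stats::sd)
    if (any(sd_ == 0)) {
      stop("zero score variance; cannot calibrate", call. = FALSE)
    }
    params <- list(mean = mu, sd = sd_)
  }
  cal <- sweep(sweep(scores$scores, 2, params$mean, `-`), 2, params$sd, `/`)
  out <- scores
  out$scores <- cal
  out$calibrated <- TRUE
  attr(out, "calibration") <- params
  out
}

#' Patient-level classifier score
#'
#' The classifier score sc_n for class n is the arithmetic mean, over the
#' given voxel set (typically the predicted tumor mask), of the calibrated
#' per-class voxel scores — one value per class; the predicted class is the
#' argmax.
#'
#' @param scores A `voxel_scores` over the voxels of interest.
#' @param voxels Optional index/logical subset of rows; default all.
#' @return Named numeric vector of per-class scores (class `sport_score`),
#'   or an object of class `no_tumor` when the voxel set is empty.
#' @export
sport_score <- function(scores, voxels = NULL) {
  stopifnot(inherits(scores, "voxel_scores"))
  S <- scores$scores
  if (!is.null(voxels)) S <- S[voxels, , drop = FALSE]
  if (nrow(S) == 0) {
    return(structure(list(message = "no tumor voxels"), class = "no_tumor"))
  }
  structure(colMeans(S), class = "sport_score")
}

#' Two-layer region-then-subtype prediction for one study
#'
#' Layer 1 (region model) assigns every voxel a lesion-class probability;
#' voxels whose tumor-class probability exceeds `threshold` form the tumor
#' mask. Layer 2 (subtype model) scores masked voxels only; the patient-level
#' classifier score is the mean calibrated subtype score over the mask and
#' the predicted subtype its argmax (ties broken by class order). An empty
#' mask yields an explicit no-tumor-detected outcome instead of a score.
#'
#' @param layer1 `lda_model` over region classes.
#' @param layer2 `lda_model` over subtype classes.
#' @param X Feature matrix of the study's voxels (same preprocessing +
#'   denoising as in training).
#' @param tumor_class Name of the tumor class in `layer1` (default
#'   `"TUMOR"`).
#' @param threshold Tumor-probability threshold for the mask (default 0.5).
#' @param calibration Stored layer-2 calibration parameters (from the
#'   training reference); `NULL` leaves layer-2 scores uncalibrated.
#' @return Object of class `patient_prediction`: `tumor_mask` (logical per
#'   voxel), `region` (layer-1 `voxel_scores`), `subtype_scores` (layer-2
#'   `voxel_scores` over the mask or NULL), `sport_scores`, `predicted`
#'   (subtype or NA), `no_tumor` flag.
#' @export
two_layer_predict <- function(layer1, layer2, X, tumor_class = "TUMOR",
                              threshold = 0.5, calibration = NULL) {
  X <- as_feature_matrix(X)
  p1 <- predict_lda(layer1, X)
  if (!tumor_class %in% colnames(p1$prob)) {
    stop(sprintf("layer-1 model has no class '%s'", tumor_class),
         call. = FALSE)
  }
  mask <- p1$prob[, tumor_class] > threshold
  if (!any(mask)) {
    return(structure(list(tumor_mask = mask, region = p1,
                          subtype_scores = NULL, sport_scores = NULL,
                          predicted = NA_character_, no_tumor = TRUE),
                     class = "patient_prediction"))
  }
  p2 <- predict_lda(layer2, X[mask, , drop = FALSE])
  if (!is.null(calibration)) p2 <- calibrate_scores(p2, params = calibration)
  sc <- sport_score(p2)
  predicted <- layer2$classes[which.max(sc[layer2$classes])]
  structure(list(tumor_mask = mask, region = p1, subtype_scores = p2,
                 sport_scores = sc, predicted = predicted, no_tumor = FALSE),
            class = "patient_prediction")
}

#' @export
print.patient_prediction <- function(x, ...) {
  if (x$no_tumor) {
    cat("<patient_prediction> no tumor detected\n")
  } else {
    cat(sprintf("<patient_prediction> %d/%d voxels in tumor mask; %s\n",
                sum(x$tumor_mask), length(x$tumor_mask),
                sprintf("predicted subtype %s", x$predicted)))
    print(round(unclass(x$sport_scores), 4))
  }
  invisible(x)
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, ties
#' counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, or coercible to 0/1; 1 = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both label values must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Render per-class voxel scores onto the CSI grid
#'
#' @param scores A `voxel_scores` (or `patient_prediction`, whose layer-1
#'   probabilities are used) whose rows correspond to `study` voxels in
#'   table order (for a `patient_prediction`, masked layer-2 scores are
#'   placed at their voxel positions).
#' @param study The `mrs_study` supplying grid geometry and coordinates.
#' @param what For a `patient_prediction`: `"subtype"` (layer-2 calibrated
#'   scores on the mask) or `"region"` (layer-1 probabilities everywhere).
#' @return Named list of `grid_rows x grid_cols` matrices, one per class;
#'   voxels without a value are NA.
#' @export
render_score_map <- function(scores, study, what = c("subtype", "region")) {
  what <- match.arg(what)
  mt <- study$metabolites
  grid_of <- function(values, rows_sel) {
    M <- matrix(NA_real_, study$grid_rows, study$grid_cols)
    M[cbind(mt$row[rows_sel] + 1, mt$col[rows_sel] + 1)] <- values
    M
  }
  if (inherits(scores, "patient_prediction")) {
    if (what == "region") {
      S <- scores$region$prob
      sel <- seq_len(nrow(S))
    } else {
      if (scores$no_tumor) {
        S <- matrix(numeric(0), 0, 0)
        return(stats::setNames(list(), character()))
      }
      S <- scores$subtype_scores$scores
      sel <- which(scores$tumor_mask)
    }
  } else {
    stopifnot(inherits(scores, "voxel_scores"))
    S <- scores$prob
    sel <- seq_len(nrow(S))
  }
  out <- lapply(seq_len(ncol(S)), function(j) grid_of(S[, j], sel))
  stats::setNames(out, colnames(S))
}

#' Plot a score map with the plasma palette
#'
#' @param map One matrix from [render_score_map()].
#' @param main Plot title.
#' @export
plot_score_map <- function(map, main = "") {
  pal <- grDevices::hcl.colors(64, "Plasma")
  graphics::image(t(map[nrow(map):1, , drop = FALSE]), col = pal,
                  axes = FALSE, main = main, useRaster = TRUE)
  invisible(NULL)
}
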