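#' Logistic sigmoid
#'
#' sigma(x) = 1 / (1 + exp(-x)), applied elementwise; saturates smoothly at
#' 0 and 1 and never overflows.
#'
#' @param x Numeric scalar or array.
#' @return Same shape as `x`, values in (0, 1).
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Autoencoder layer specification
#'
#' The mirrored denoising architecture: three encoder hidden layers with
#' strictly decreasing widths (default 32, 16, 8), each an affine map
#' followed by batch normalization and a sigmoid, then a sigmoid bottleneck
#' (default 6 neurons), then the mirrored decoder (8, 16, 32) and a sigmoid
#' output layer back to the input width. Dropout (default rate 0.1) acts on
#' the hidden-layer activations during training only.
#'
#' @param encoder_widths Strictly decreasing integer vector.
#' @param bottleneck Bottleneck width, `< min(encoder_widths)`.
#' @param dropout Dropout rate in \[0, 1).
#' @param batch_norm Logical: batch-normalize the encoder hidden layers.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(encoder_widths = c(32, 16, 8), bottleneck = 6,
                       dropout = 0.1, batch_norm = TRUE) {
  encoder_widths <- as.integer(encoder_widths)
  bottleneck <- as.integer(bottleneck)
  if (length(encoder_widths) < 1 || any(diff(encoder_widths) >= 0)) {
    stop("encoder_widths must be strictly decreasing", call. = FALSE)
  }
  if (bottleneck >= encoder_widths[length(encoder_widths)]) {
    stop("bottleneck must be smaller than the last encoder width",
         call. = FALSE)
  }
  if (bottleneck < 1) stop("bottleneck must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  structure(list(encoder_widths = encoder_widths, bottleneck = bottleneck,
                 dropout = dropout, batch_norm = isTRUE(batch_norm)),
            class = "layer_spec")
}

glorot_uniform <- function(d_in, d_out) {
  a <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -a, a), d_in, d_out)
}

#' Initialize an untrained autoencoder
#'
#' Weights are drawn from a symmetric scaled-uniform (Glorot) initializer,
#' biases start at zero, batch-norm scale/shift at 1/0; deterministic given
#' `seed`.
#'
#' @param spec A [layer_spec()].
#' @param n_inputs Input width (number of metabolites, default 34).
#' @param seed Integer seed.
#' @return An object of class `autoencoder_model`.
#' @export
init_autoencoder <- function(spec = layer_spec(), n_inputs = 34, seed = 1L) {
  stopifnot(inherits(spec, "layer_spec"))
  if (n_inputs < spec$bottleneck) {
    stop("n_inputs must be >= bottleneck", call. = FALSE)
  }
  widths <- c(n_inputs, spec$encoder_widths, spec$bottleneck)
  with_seed(seed, {
    enc <- list()
    for (i in seq_along(spec$encoder_widths)) {
      lyr <- list(W = glorot_uniform(widths[i], widths[i + 1]),
                  b = numeric(widths[i + 1]))
      if (spec$batch_norm) {
        lyr$gamma <- rep(1, widths[i + 1])
        lyr$beta <- numeric(widths[i + 1])
        lyr$rmean <- numeric(widths[i + 1])
        lyr$rvar <- rep(1, widths[i + 1])
      }
      enc[[i]] <- lyr
    }
    nh <- length(spec$encoder_widths)
    enc[[nh + 1]] <- list(W = glorot_uniform(widths[nh + 1], spec$bottleneck),
                          b = numeric(spec$bottleneck))
    dec_widths <- c(spec$bottleneck, rev(spec$encoder_widths), n_inputs)
    dec <- list()
    for (i in seq_len(length(dec_widths) - 1)) {
      dec[[i]] <- list(W = glorot_uniform(dec_widths[i], dec_widths[i + 1]),
                       b = numeric(dec_widths[i + 1]))
    }
    structure(list(spec = spec, n_inputs = n_inputs, enc = enc, dec = dec,
                   trained = FALSE, seed = as.integer(seed)),
              class = "autoencoder_model")
  })
}

#' @export
print.autoencoder_model <- function(x, ...) {
  widths <- c(x$n_inputs, x$spec$encoder_widths, x$spec$bottleneck,
              rev(x$spec$encoder_widths), x$n_inputs)
  cat(sprintf("<autoencoder_model> %s%s\n", paste(widths, collapse = "-"),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

bn_eps <- 1e-5

# forward pass; training mode uses batch statistics + dropout and returns a
# cache for backprop; inference mode uses running statistics, no dropout
ae_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  nh <- length(spec$encoder_widths)
  cache <- list(A = list(), Z = list(), Zhat = list(), mu = list(),
                var = list(), mask = list(), S = list())
  A <- X
  cache$A[[1]] <- A
  n_aff <- length(model$enc) + length(model$dec)
  for (k in seq_len(n_aff)) {
    in_enc <- k <= length(model$enc)
    lyr <- if (in_enc) model$enc[[k]] else model$dec[[k - length(model$enc)]]
    Z <- A %*% lyr$W + rep(lyr$b, each = nrow(A))
    cache$Z[[k]] <- Z
    is_enc_hidden <- in_enc && k <= nh
    is_dec_hidden <- !in_enc && k < n_aff
    if (is_enc_hidden && spec$batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
      } else {
        mu <- lyr$rmean
        v <- lyr$rvar
      }
      Zhat <- sweep(sweep(Z, 2, mu, `-`), 2, sqrt(v + bn_eps), `/`)
      cache$mu[[k]] <- mu
      cache$var[[k]] <- v
      cache$Zhat[[k]] <- Zhat
      H <- sweep(sweep(Zhat, 2, lyr$gamma, `*`), 2, lyr$beta, `+`)
    } else {
      H <- Z
    }
    S <- sigmoid(H)
    cache$S[[k]] <- S
    A <- S
    if (training && spec$dropout > 0 && (is_enc_hidden || is_dec_hidden)) {
      keep <- 1 - spec$dropout
      mask <- matrix(stats::rbinom(length(A), 1, keep) / keep,
                     nrow(A), ncol(A))
      cache$mask[[k]] <- mask
      A <- A * mask
    }
    cache$A[[k + 1]] <- A
  }
  list(out = A, cache = cache)
}

# gradients of mean-squared reconstruction loss wrt all parameters
ae_backward <- function(model, X, fwd) {
  spec <- model$spec
  nh <- length(spec$encoder_widths)
  n_enc <- length(model$enc)
  n_aff <- n_enc + length(model$dec)
  cache <- fwd$cache
  n <- nrow(X)
  grads <- list(enc = vector("list", n_enc),
                dec = vector("list", length(model$dec)))
  dA <- 2 * (fwd$out - X) / (n * ncol(X))
  for (k in n_aff:1) {
    in_enc <- k <= n_enc
    lyr <- if (in_enc) model$enc[[k]] else model$dec[[k - n_enc]]
    if (length(cache$mask) >= k && !is.null(cache$mask[[k]])) {
      dA <- dA * cache$mask[[k]]
    }
    S <- cache$S[[k]]
    dH <- dA * S * (1 - S)
    g <- list()
    if (in_enc && k <= nh && spec$batch_norm) {
      Zhat <- cache$Zhat[[k]]
      g$gamma <- colSums(dH * Zhat)
      g$beta <- colSums(dH)
      dZhat <- sweep(dH, 2, lyr$gamma, `*`)
      Z <- cache$Z[[k]]
      mu <- cache$mu[[k]]
      v <- cache$var[[k]]
      inv_sd <- 1 / sqrt(v + bn_eps)
      Zc <- sweep(Z, 2, mu, `-`)
      dvar <- colSums(dZhat * Zc) * (-0.5) * inv_sd^3
      dmu <- colSums(sweep(dZhat, 2, -inv_sd, `*`)) +
        dvar * colMeans(-2 * Zc)
      dZ <- sweep(dZhat, 2, inv_sd, `*`) +
        sweep(Zc, 2, 2 * dvar / n, `*`) +
        rep(dmu / n, each = n)
    } else {
      dZ <- dH
    }
    A_prev <- cache$A[[k]]
    g$W <- crossprod(A_prev, dZ)
    g$b <- colSums(dZ)
    if (in_enc) grads$enc[[k]] <- g else grads$dec[[k - n_enc]] <- g
    dA <- tcrossprod(dZ, lyr$W)
  }
  grads
}

adam_init <- function(model) {
  zero_like <- function(lyr, keys) {
    out <- list()
    for (key in keys) {
      if (!is.null(lyr[[key]])) {
        out[[key]] <- list(m = lyr[[key]] * 0, v = lyr[[key]] * 0)
      }
    }
    out
  }
  list(enc = lapply(model$enc, zero_like, keys = c("W", "b", "gamma", "beta")),
       dec = lapply(model$dec, zero_like, keys = c("W", "b")),
       t = 0)
}

adam_step <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(lyr, g, st) {
    for (key in names(st)) {
      st[[key]]$m <- beta1 * st[[key]]$m + (1 - beta1) * g[[key]]
      st[[key]]$v <- beta2 * st[[key]]$v + (1 - beta2) * g[[key]]^2
      mhat <- st[[key]]$m / corr1
      vhat <- st[[key]]$v / corr2
      lyr[[key]] <- lyr[[key]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(lyr = lyr, st = st)
  }
  for (i in seq_along(model$enc)) {
    r <- upd(model$enc[[i]], grads$enc[[i]], state$enc[[i]])
    model$enc[[i]] <- r$lyr
    state$enc[[i]] <- r$st
  }
  for (i in seq_along(model$dec)) {
    r <- upd(model$dec[[i]], grads$dec[[i]], state$dec[[i]])
    model$dec[[i]] <- r$lyr
    state$dec[[i]] <- r$st
  }
  list(model = model, state = state)
}

as_feature_matrix <- function(X) {
  if (inherits(X, "normalized_matrix")) X$values else as.matrix(X)
}

#' Encode voxels to the latent (bottleneck) representation
#'
#' @param model An `autoencoder_model`.
#' @param X Normalized matrix (`normalized_matrix` or plain matrix in
#'   \[0,1\]) with `n_inputs` columns.
#' @return Matrix, voxels x bottleneck, entries in (0, 1).
#' @export
encode <- function(model, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != model$n_inputs) {
    stop(sprintf("X has %d columns, model expects %d", ncol(X),
                 model$n_inputs), call. = FALSE)
  }
  A <- X
  nh <- length(model$spec$encoder_widths)
  for (k in seq_along(model$enc)) {
    lyr <- model$enc[[k]]
    Z <- A %*% lyr$W + rep(lyr$b, each = nrow(A))
    if (k <= nh && model$spec$batch_norm) {
      Zhat <- sweep(sweep(Z, 2, lyr$rmean, `-`), 2,
                    sqrt(lyr$rvar + bn_eps), `/`)
      Z <- sweep(sweep(Zhat, 2, lyr$gamma, `*`), 2, lyr$beta, `+`)
    }
    A <- sigmoid(Z)
  }
  A
}

#' Reconstruct voxels through the full autoencoder
#'
#' decode(encode(X)) in inference mode (running batch-norm statistics, no
#' dropout); entries lie strictly in (0, 1).
#'
#' @inheritParams encode
#' @return Matrix of the same shape as `X`.
#' @export
reconstruct <- function(model, X) {
  Xm <- as_feature_matrix(X)
  if (ncol(Xm) != model$n_inputs) {
    stop(sprintf("X has %d columns, model expects %d", ncol(Xm),
                 model$n_inputs), call. = FALSE)
  }
  out <- ae_forward(model, Xm, training = FALSE)$out
  dimnames(out) <- dimnames(Xm)
  out
}

#' Train the autoencoder by minibatch Adam
#'
#' Minimizes the mean squared reconstruction error (the elementwise mean of
#' the squared-norm loss, which makes thresholds independent of matrix size)
#' on a random training split, with dropout active during training only and
#' batch-norm running statistics accumulated for inference. Bit-for-bit
#' reproducible given `seed` on a single thread.
#'
#' @param model An `autoencoder_model` (typically fresh from
#'   [init_autoencoder()]).
#' @param X Normalized data, values in \[0, 1\], at least 10 rows.
#' @param epochs Training epochs (default 500).
#' @param split Fraction of rows used for training (default 2/3); the rest is
#'   the held-out split whose loss is tracked per epoch.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed controlling split, shuffling and dropout.
#' @return List: `model` (trained), `report` (class `train_report` with
#'   `loss_history` data frame `epoch`/`train`/`heldout`, `epochs`, `seed`).
#' @export
train_autoencoder <- function(model, X, epochs = 500, split = 2 / 3,
                              batch_size = 32, lr = 1e-3, seed = 1L) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 10) stop("need at least 10 rows to train", call. = FALSE)
  if (min(X) < 0 || max(X) > 1) {
    stop("X must be min-max normalized to [0, 1]", call. = FALSE)
  }
  if (epochs == 0) {
    report <- structure(list(loss_history = data.frame(epoch = integer(),
                                                       train = numeric(),
                                                       heldout = numeric()),
                             epochs = 0L, seed = as.integer(seed)),
                        class = "train_report")
    return(list(model = model, report = report))
  }
  bn_momentum <- 0.1
  with_seed(seed, {
    n <- nrow(X)
    idx <- sample.int(n)
    ntr <- max(2, floor(split * n))
    tr <- idx[seq_len(ntr)]
    ho <- idx[-seq_len(ntr)]
    Xtr <- X[tr, , drop = FALSE]
    Xho <- X[ho, , drop = FALSE]
    state <- adam_init(model)
    hist_tr <- numeric(epochs)
    hist_ho <- numeric(epochs)
    nh <- length(model$spec$encoder_widths)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(ntr)
      starts <- seq(1, ntr, by = batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- perm[starts[bi]:min(starts[bi] + batch_size - 1, ntr)]
        if (length(rows) < 2) {  # batch statistics need >= 2 rows
          batch_losses[bi] <- NA_real_
          next
        }
        Xb <- Xtr[rows, , drop = FALSE]
        fwd <- ae_forward(model, Xb, training = TRUE)
        batch_losses[bi] <- mean((Xb - fwd$out)^2)
        if (model$spec$batch_norm) {
          for (k in seq_len(nh)) {
            model$enc[[k]]$rmean <- (1 - bn_momentum) *
              model$enc[[k]]$rmean + bn_momentum * fwd$cache$mu[[k]]
            model$enc[[k]]$rvar <- (1 - bn_momentum) *
              model$enc[[k]]$rvar + bn_momentum * fwd$cache$var[[k]]
          }
        }
        grads <- ae_backward(model, Xb, fwd)
        st <- adam_step(model, grads, state, lr = lr)
        model <- st$model
        state <- st$state
      }
      hist_tr[ep] <- mean(batch_losses, na.rm = TRUE)
      hist_ho[ep] <- if (nrow(Xho) > 0) {
        mean((Xho - ae_forward(model, Xho, training = FALSE)$out)^2)
      } else NA_real_
    }
    model$trained <- TRUE
    report <- structure(list(loss_history = data.frame(epoch = seq_len(epochs),
                                                       train = hist_tr,
                                                       heldout = hist_ho),
                             epochs = as.integer(epochs),
                             seed = as.integer(seed)),
                        class = "train_report")
    list(model = model, report = report)
  })
}

#' Denoise a normalized metabolite matrix
#'
#' Passes every voxel through the trained autoencoder; the reconstruction is
#' the denoised profile. Voxel order is preserved and the result carries a
#' `denoised` provenance flag.
#'
#' @param model A trained `autoencoder_model`.
#' @param X A `normalized_matrix` or matrix in \[0, 1\].
#' @return A `normalized_matrix` with denoised values (attribute
#'   `denoised = TRUE`); normalization statistics are carried over when the
#'   input had them.
#' @export
denoise <- function(model, X) {
  if (!isTRUE(model$trained)) {
    warning("denoising with an untrained model", call. = FALSE)
  }
  vals <- reconstruct(model, X)
  out <- if (inherits(X, "normalized_matrix")) {
    structure(list(values = vals, mins = X$mins, maxs = X$maxs,
                   constant = X$constant), class = "normalized_matrix")
  } else {
    structure(list(values = vals, mins = rep(0, ncol(vals)),
                   maxs = rep(1, ncol(vals)),
                   constant = rep(FALSE, ncol(vals))),
              class = "normalized_matrix")
  }
  attr(out, "denoised") <- TRUE
  out
}

#' Select the bottleneck width by the eigenvalue-share benchmark
#'
#' Trains one autoencoder per candidate bottleneck width and scores each by
#' the share of variance carried by the first two principal components of the
#' denoised matrix (the denoising benchmark); returns the width maximizing
#' the benchmark, ties broken toward the smaller width.
#'
#' @param X Normalized data in \[0, 1\].
#' @param sizes Candidate bottleneck widths (default 4:10).
#' @param spec Base [layer_spec()]; its bottleneck field is replaced per
#'   candidate.
#' @param epochs Training epochs per candidate.
#' @param seed Integer seed (same seed reused per candidate so runs differ
#'   only in the width).
#' @return List: `best` (integer width), `benchmark` (data frame `size`,
#'   `benchmark`).
#' @export
bottleneck_search <- function(X, sizes = 4:10, spec = layer_spec(),
                              epochs = 500, seed = 1L) {
  X <- as_feature_matrix(X)
  if (any(sizes < 1) || any(sizes >= ncol(X))) {
    stop("sizes must lie in [1, n_inputs)", call. = FALSE)
  }
  bench <- vapply(sizes, function(sz) {
    # wider-than-last-hidden candidates drop the trailing encoder layer(s)
    # so the funnel stays strictly decreasing into the bottleneck
    ew <- spec$encoder_widths[spec$encoder_widths > sz]
    if (!length(ew)) ew <- max(2 * sz, sz + 1)
    sp <- layer_spec(encoder_widths = ew, bottleneck = sz,
                     dropout = spec$dropout, batch_norm = spec$batch_norm)
    mod <- init_autoencoder(sp, n_inputs = ncol(X), seed = seed)
    tr <- train_autoencoder(mod, X, epochs = epochs, seed = seed)
    den <- denoise(tr$model, X)
    pr <- mrs_pca(den$values, n_components = min(30, ncol(X), nrow(X) - 1))
    sum(pr$explained_share[1:2])
  }, numeric(1))
  list(best = sizes[which.max(bench)],
       benchmark = data.frame(size = sizes, benchmark = bench))
}
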