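#' Baseline-correct a spectrum
#'
#' Estimates a smooth polynomial baseline by an iteratively reweighted
#' asymmetric least-squares polynomial fit (10 iterations; points above the
#' current fit are down-weighted to 0.01, points below keep weight 1, so
#' peaks — which only rise above the baseline — are progressively ignored)
#' and subtracts it.
#'
#' @param spectrum An [mrs_spectrum()].
#' @param order Polynomial order (>= 0); needs at least `order + 2` points.
#' @param n_iter Number of reweighting iterations.
#' @return The corrected [mrs_spectrum()] (same ppm axis) with the estimated
#'   baseline attached as attribute `"baseline"`.
#' @export
baseline_correct <- function(spectrum, order = 2, n_iter = 10) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  if (order < 0) stop("order must be >= 0", call. = FALSE)
  n <- length(spectrum$ppm)
  if (n < order + 2) {
    stop(sprintf("need at least %d points for order %d", order + 2, order),
         call. = FALSE)
  }
  u <- rescale_unit(spectrum$ppm)
  P <- outer(u, 0:order, `^`)
  y <- spectrum$intensity
  w <- rep(1, n)
  bl <- numeric(n)
  for (it in seq_len(n_iter)) {
    fit <- stats::lm.wfit(P, y, w)
    bl <- as.numeric(P %*% fit$coefficients)
    w <- ifelse(y > bl, 0.01, 1)
  }
  out <- mrs_spectrum(spectrum$ppm, y - bl)
  attr(out, "baseline") <- bl
  out
}

#' Fit metabolite amplitudes by non-negative linear least squares
#'
#' Simplified spectral quantitation: solves min ||y - B a||^2 subject to
#' a >= 0, where the columns of B are the unit-amplitude metabolite templates
#' of the basis evaluated on the spectrum's ppm axis (via
#' [pracma::lsqnonneg()]). This is a frequency-domain linear stand-in for a
#' full time-domain quantitation tool: no lineshape, phase or frequency-shift
#' estimation is performed.
#'
#' @param spectrum An [mrs_spectrum()] (baseline-corrected).
#' @param basis A `basis_set` whose peaks lie within the ppm range.
#' @return Object of class `fit_result`: `amplitudes` (named, >= 0),
#'   `residual_rms` (same units as intensity), `rank_deficient` flag.
#' @export
fit_basis_amplitudes <- function(spectrum, basis) {
  stopifnot(inherits(spectrum, "mrs_spectrum"))
  B <- basis_matrix(basis, spectrum$ppm)
  y <- spectrum$intensity
  rk <- qr(B)$rank
  rank_deficient <- rk < ncol(B)
  if (rank_deficient) {
    warning(sprintf("basis design matrix rank %d < %d metabolites; %s",
                    rk, ncol(B), "amplitudes are not uniquely determined"),
            call. = FALSE)
  }
  if (all(y == 0)) {
    amps <- stats::setNames(numeric(ncol(B)), colnames(B))
    res <- 0
  } else {
    sol <- pracma::lsqnonneg(B, y)
    amps <- stats::setNames(as.numeric(sol$x), colnames(B))
    res <- sqrt(mean((y - as.numeric(B %*% amps))^2))
  }
  structure(list(amplitudes = amps, residual_rms = res,
                 rank_deficient = rank_deficient),
            class = "fit_result")
}

#' Residual-based voxel quality filter
#'
#' A voxel passes iff its fit residual RMS is at most `threshold` times the
#' study median residual RMS; failing voxels are meant to be relabeled
#' EXCLUDED downstream. The rule is relative to the median, hence invariant
#' to a global rescaling of the intensities.
#'
#' @param fits List of `fit_result` (or numeric vector of residual RMS
#'   values), optionally named by voxel id.
#' @param threshold Positive multiple of the median (default 3).
#' @return Named logical vector, `TRUE` = voxel passes.
#' @export
quality_filter <- function(fits, threshold = 3) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  res <- if (is.numeric(fits)) fits else {
    vapply(fits, function(f) f$residual_rms, numeric(1))
  }
  med <- stats::median(res)
  pass <- res <= threshold * med
  if (!any(pass)) {
    stop("all voxels fail the quality filter; study unusable", call. = FALSE)
  }
  pass
}

#' Min-max normalize a metabolite matrix per column
#'
#' Each metabolite column x is mapped to (x - min x) / (max x - min x), the
#' input-layer scaling of the denoising autoencoder. Constant columns map to
#' all zeros and are flagged; the per-column (min, max) are stored so the
#' same transform can be applied to held-out data and inverted.
#'
#' @param x Numeric matrix (voxels x metabolites) or a [metabolite_table()].
#' @return Object of class `normalized_matrix`: `values` in \[0,1\], `mins`,
#'   `maxs`, `constant` (logical per column).
#' @export
minmax_normalize <- function(x) {
  if (inherits(x, "metabolite_table")) x <- x$values
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix must be finite", call. = FALSE)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  constant <- maxs == mins
  rng <- ifelse(constant, 1, maxs - mins)
  vals <- sweep(sweep(x, 2, mins, `-`), 2, rng, `/`)
  vals[, constant] <- 0
  structure(list(values = vals, mins = mins, maxs = maxs,
                 constant = constant),
            class = "normalized_matrix")
}

#' Apply stored normalization parameters to new data
#'
#' Reuses the (min, max) learned on training data — out-of-range values are
#' clipped to \[0, 1\] so downstream sigmoid-ranged models stay in domain.
#'
#' @param params A `normalized_matrix` (its stored statistics are used).
#' @param x New matrix with the same columns.
#' @return A `normalized_matrix` holding the transformed values and the
#'   training statistics.
#' @export
apply_normalization <- function(params, x) {
  stopifnot(inherits(params, "normalized_matrix"))
  if (inherits(x, "metabolite_table")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != length(params$mins)) {
    stop("column count does not match normalization parameters",
         call. = FALSE)
  }
  rng <- ifelse(params$constant, 1, params$maxs - params$mins)
  vals <- sweep(sweep(x, 2, params$mins, `-`), 2, rng, `/`)
  vals[, params$constant] <- 0
  vals[vals < 0] <- 0
  vals[vals > 1] <- 1
  structure(list(values = vals, mins = params$mins, maxs = params$maxs,
                 constant = params$constant),
            class = "normalized_matrix")
}

#' Invert a min-max normalization
#'
#' @param nm A `normalized_matrix`.
#' @param values Optional matrix in \[0,1\] to back-transform (defaults to
#'   `nm$values`).
#' @return Matrix on the original intensity scale.
#' @export
denormalize <- function(nm, values = nm$values) {
  stopifnot(inherits(nm, "normalized_matrix"))
  rng <- ifelse(nm$constant, 0, nm$maxs - nm$mins)
  sweep(sweep(values, 2, rng, `*`), 2, nm$mins, `+`)
}

#' Pointwise mean and variance of a set of spectra
#'
#' Summarizes baseline-corrected raw spectra of a voxel group as the
#' pointwise mean trace and the (population) variance, the form used to
#' render heat-colored sum spectra.
#'
#' @param spectra List of [mrs_spectrum()] sharing one ppm axis.
#' @return Object of class `mean_spectrum`: `ppm`, `mean`, `variance`.
#' @export
mean_spectrum <- function(spectra) {
  if (!length(spectra)) stop("no spectra given", call. = FALSE)
  ppm <- spectra[[1]]$ppm
  for (s in spectra) {
    if (!isTRUE(all.equal(s$ppm, ppm, tolerance = 0))) {
      stop("all spectra must share one ppm axis", call. = FALSE)
    }
  }
  Y <- vapply(spectra, `[[`, numeric(length(ppm)), "intensity")
  Y <- matrix(Y, nrow = length(ppm))
  m <- rowMeans(Y)
  v <- rowMeans(Y^2) - m^2
  v[v < 0] <- 0
  structure(list(ppm = ppm, mean = m, variance = v), class = "mean_spectrum")
}
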