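#' Default spectral basis set
#'
#' One peak-list per metabolite: (center ppm, linewidth ppm, relative
#' amplitude) triplets with a Lorentzian lineshape. Peak positions are loosely
#' modelled on the short-TE in-vivo proton spectrum (NAA 2.01, creatine
#' 3.03/3.91, choline compounds ~3.2, lactate 1.31, myo-inositol 3.56, lipid
#' and macromolecule bands 0.6-2.1 ppm). The basis is a deliberately
#' simplified synthetic stand-in: no J-coupling or relaxation modelling, and
#' crowded regions are spread slightly so that the linear system remains
#' well conditioned.
#'
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return An object of class `basis_set`: named list of peak matrices
#'   (columns `center`, `width`, `amp`) plus a `lineshape` attribute.
#' @export
default_basis <- function(lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "width", "amp")
    m
  }
  peaks <- list(
    NAA    = pk(2.01, 0.04, 1.00, 2.49, 0.05, 0.25),
    NAAG   = pk(2.09, 0.04, 1.00),
    Cr     = pk(3.03, 0.04, 1.00, 3.91, 0.04, 0.70),
    PCr    = pk(3.07, 0.04, 1.00, 3.95, 0.04, 0.70),
    GPC    = pk(3.21, 0.035, 1.00),
    PCh    = pk(3.26, 0.035, 1.00),
    Ins    = pk(3.56, 0.04, 1.00, 4.06, 0.05, 0.30),
    Lac    = pk(1.27, 0.035, 0.55, 1.35, 0.035, 0.55),
    Ala    = pk(1.47, 0.04, 1.00),
    Asp    = pk(2.67, 0.05, 0.60, 2.81, 0.05, 0.60),
    GABA   = pk(1.89, 0.05, 0.50, 2.28, 0.05, 0.50, 3.01, 0.05, 0.30),
    Glc    = pk(3.43, 0.05, 0.70, 3.80, 0.05, 0.50),
    Gln    = pk(2.44, 0.05, 0.70, 3.76, 0.05, 0.40),
    Glu    = pk(2.34, 0.05, 0.70, 3.74, 0.05, 0.40),
    Gly    = pk(3.52, 0.035, 1.00),
    GSH    = pk(2.93, 0.05, 0.70, 3.77, 0.05, 0.30),
    Lip09  = pk(0.89, 0.07, 1.00),
    Lip13a = pk(1.24, 0.07, 1.00),
    Lip13b = pk(1.31, 0.07, 1.00),
    Lip20  = pk(2.05, 0.07, 1.00),
    MM09   = pk(0.93, 0.09, 1.00),
    MM12   = pk(1.21, 0.09, 1.00),
    MM14   = pk(1.40, 0.09, 1.00),
    MM17   = pk(1.67, 0.09, 1.00),
    MM20   = pk(2.08, 0.09, 1.00),
    PE     = pk(3.22, 0.04, 0.60, 3.98, 0.04, 0.60),
    Scyllo = pk(3.35, 0.03, 1.00),
    Tau    = pk(3.25, 0.04, 0.60, 3.42, 0.04, 0.60),
    Cit    = pk(2.60, 0.04, 1.00),
    Cys    = pk(2.98, 0.04, 1.00),
    EtOH   = pk(1.18, 0.04, 0.70, 3.65, 0.04, 0.40),
    Ser    = pk(3.83, 0.04, 0.60, 3.94, 0.04, 0.60),
    Thr    = pk(1.32, 0.04, 0.60, 3.58, 0.04, 0.60),
    Val    = pk(0.98, 0.04, 0.60, 1.03, 0.04, 0.60)
  )
  structure(peaks, lineshape = lineshape, class = "basis_set")
}

#' Build a well-separated synthetic basis
#'
#' Places one peak per metabolite, evenly spaced over the ppm range; columns
#' of the design matrix are then nearly orthogonal, which is the regime where
#' amplitude recovery from a noisy spectrum is well posed. Useful for solver
#' validation; the default in-vivo-like basis of [default_basis()] is more
#' overlapped.
#'
#' @param n Number of metabolites.
#' @param ppm_range Length-2 numeric range.
#' @param width Common linewidth (ppm).
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @return A `basis_set`.
#' @export
separated_basis <- function(n = 34, ppm_range = c(0.2, 4.2), width = 0.03,
                            lineshape = "lorentzian") {
  centers <- seq(ppm_range[1] + 0.1, ppm_range[2] - 0.1, length.out = n)
  peaks <- lapply(centers, function(cen) {
    m <- matrix(c(cen, width, 1), ncol = 3)
    colnames(m) <- c("center", "width", "amp")
    m
  })
  names(peaks) <- sprintf("M%02d", seq_len(n))
  structure(peaks, lineshape = lineshape, class = "basis_set")
}

validate_basis <- function(basis, ppm_axis = NULL) {
  stopifnot(inherits(basis, "basis_set"))
  for (nm in names(basis)) {
    p <- basis[[nm]]
    if (any(p[, "width"] <= 0)) {
      stop(sprintf("basis '%s': linewidths must be > 0", nm), call. = FALSE)
    }
    if (any(p[, "amp"] < 0)) {
      stop(sprintf("basis '%s': amplitudes must be >= 0", nm), call. = FALSE)
    }
    if (!is.null(ppm_axis) &&
        (any(p[, "center"] < min(ppm_axis)) ||
         any(p[, "center"] > max(ppm_axis)))) {
      stop(sprintf("basis '%s': peak center outside ppm axis", nm),
           call. = FALSE)
    }
  }
  invisible(basis)
}

lineshape_eval <- function(ppm, center, width, lineshape) {
  if (lineshape == "lorentzian") {
    hw <- width / 2
    hw^2 / ((ppm - center)^2 + hw^2)
  } else {
    sigma <- width / (2 * sqrt(2 * log(2)))
    exp(-(ppm - center)^2 / (2 * sigma^2))
  }
}

#' Evaluate unit-amplitude metabolite templates on a ppm axis
#'
#' @param basis A `basis_set`.
#' @param ppm_axis Monotone numeric vector.
#' @return Matrix, `length(ppm_axis)` x metabolites; column m is the template
#'   of metabolite m at unit amplitude.
#' @export
basis_matrix <- function(basis, ppm_axis) {
  validate_basis(basis, ppm_axis)
  ls <- attr(basis, "lineshape")
  B <- vapply(basis, function(p) {
    y <- numeric(length(ppm_axis))
    for (i in seq_len(nrow(p))) {
      y <- y + p[i, "amp"] *
        lineshape_eval(ppm_axis, p[i, "center"], p[i, "width"], ls)
    }
    y
  }, numeric(length(ppm_axis)))
  colnames(B) <- names(basis)
  B
}

#' Synthesize one voxel spectrum from a metabolite profile
#'
#' intensity = sum_m profile\[m\] * template_m(ppm) + polynomial baseline +
#' N(0, noise_sd^2) white noise; fully deterministic given `seed`.
#'
#' @param profile Non-negative amplitude vector, one entry per basis
#'   metabolite.
#' @param basis A `basis_set`.
#' @param ppm_axis Monotone numeric vector.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param baseline_coeffs Polynomial coefficients (intercept first) evaluated
#'   on a ppm axis rescaled to \[-1, 1\]; `NULL` for no baseline.
#' @param seed Integer RNG seed (used only if `noise_sd > 0`).
#' @return An [mrs_spectrum()].
#' @export
simulate_spectrum <- function(profile, basis, ppm_axis, noise_sd = 0,
                              baseline_coeffs = NULL, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
  if (length(profile) != length(basis)) {
    stop("profile length must match basis size", call. = FALSE)
  }
  B <- basis_matrix(basis, ppm_axis)
  y <- as.numeric(B %*% profile)
  if (!is.null(baseline_coeffs) && length(baseline_coeffs)) {
    u <- rescale_unit(ppm_axis)
    y <- y + as.numeric(outer(u, seq_along(baseline_coeffs) - 1, `^`) %*%
                          baseline_coeffs)
  }
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  mrs_spectrum(ppm_axis, y)
}

rescale_unit <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default per-tissue mean metabolite profiles
#'
#' Mean amplitudes (arbitrary units) per segmentation label, encoding the
#' canonical in-vivo contrasts: NAM dominated by NAA and creatine; tumor with
#' reduced NAA and elevated choline compounds; necrosis dominated by lactate,
#' lipids and macromolecules; FLAIR-hyperintense (edema) enriched in
#' myo-inositol; ventricle with globally suppressed signal. The `subtype`
#' argument modulates the TUMOR and CONTRAST profiles: IDH-wildtype gliomas
#' gain lactate, lipids and macromolecules; IDH-mutant tumors (with or
#' without 1p/19q codeletion) gain glycerophosphocholine, the codeleted (LOH)
#' subtype additionally glutamine, alanine and glycine.
#'
#' @param subtype `"wt"`, `"IDH"`, `"LOH"` or `"none"`.
#' @param metabolites Metabolite names (34).
#' @return Named list label -> mean 34-vector.
#' @export
default_tissue_profiles <- function(subtype = c("none", "wt", "IDH", "LOH"),
                                    metabolites = default_metabolites()) {
  subtype <- match.arg(subtype)
  base <- stats::setNames(rep(0.3, length(metabolites)), metabolites)
  set_ <- function(p, ...) {
    v <- c(...)
    p[names(v)] <- v
    p
  }
  nam <- set_(base, NAA = 10, NAAG = 1.2, Cr = 8, PCr = 2.5, GPC = 1.5,
              PCh = 1, Ins = 4, Glu = 6, Gln = 2, Tau = 1, Lac = 0.4)
  tumor <- set_(base, NAA = 3, NAAG = 0.5, Cr = 5, PCr = 1.5, GPC = 3.5,
                PCh = 2, Ins = 3, Glu = 3, Gln = 2.5, Gly = 1.5, Lac = 2,
                Ala = 0.8)
  if (subtype == "wt") {
    tumor <- set_(tumor, Lac = 8, Lip09 = 4, Lip13a = 5, Lip13b = 3.5,
                  Lip20 = 2, MM09 = 3, MM12 = 2.5, MM14 = 2, MM17 = 1.5,
                  MM20 = 1.5, GPC = 3)
  } else if (subtype == "IDH") {
    tumor <- set_(tumor, GPC = 8, PCh = 2.5, Lac = 2.5)
  } else if (subtype == "LOH") {
    tumor <- set_(tumor, GPC = 8, PCh = 2.5, Lac = 2.5, Gln = 6, Ala = 3,
                  Gly = 4)
  }
  contrast <- tumor * 1.15
  necrosis <- set_(base, NAA = 0.6, Cr = 1, GPC = 1.5, Lac = 10, Lip09 = 6,
                   Lip13a = 8, Lip13b = 6, Lip20 = 3, MM09 = 5, MM12 = 4,
                   MM14 = 3.5, MM17 = 2.5, MM20 = 2.5)
  flair <- set_(base, NAA = 6, Cr = 6, GPC = 2, PCh = 1.2, Ins = 8, Glu = 4,
                Gln = 3, Lac = 1)
  lesion <- set_(base, NAA = 5, Cr = 5.5, GPC = 2.5, PCh = 1.5, Ins = 5,
                 Glu = 3.5, Lac = 3, Ala = 1.2)
  ventricle <- stats::setNames(rep(0.15, length(metabolites)), metabolites)
  ventricle[c("Lac", "Glc")] <- c(0.8, 0.6)
  list(NAM = nam, LESION = lesion, TUMOR = tumor, CONTRAST = contrast,
       NECROSIS = necrosis, FLAIR = flair, VENTRICLE = ventricle)
}

#' Default lesion geometry for a phantom grid
#'
#' NAM background; a ventricle rectangle off-center; a tumor disc with a
#' contrast-enhancing rim, an optional necrotic core (IDH-wildtype phantoms
#' only, where central necrosis is typical), and a FLAIR-hyperintense annulus
#' around the lesion. Region specs are applied in list order, later specs
#' overwriting earlier ones.
#'
#' @param grid_rows,grid_cols Grid size.
#' @param center Tumor center `c(row, col)` (0-based, fractional allowed).
#' @param radius Tumor disc radius (grid units).
#' @param necrosis Logical: include a necrotic core.
#' @return List of region specs (`label`, `shape`, geometry fields).
#' @export
default_geometry <- function(grid_rows = 16, grid_cols = 16,
                             center = c(10, 10), radius = 3,
                             necrosis = FALSE) {
  g <- list(
    list(label = "NAM", shape = "background"),
    list(label = "VENTRICLE", shape = "rect",
         r0 = round(grid_rows * 0.2), r1 = round(grid_rows * 0.45),
         c0 = round(grid_cols * 0.15), c1 = round(grid_cols * 0.3)),
    list(label = "FLAIR", shape = "disc", center = center,
         radius = radius + 1.8),
    list(label = "TUMOR", shape = "disc", center = center, radius = radius),
    list(label = "CONTRAST", shape = "annulus", center = center,
         r_in = radius * 0.78, r_out = radius)
  )
  if (necrosis) {
    g <- c(g, list(list(label = "NECROSIS", shape = "disc", center = center,
                        radius = radius * 0.3)))
  }
  g
}

#' Phantom configuration
#'
#' Bundles everything [generate_phantom()] needs: grid geometry, ppm axis,
#' tissue geometry and profiles, subtype, per-metabolite coefficient of
#' variation of the voxel-to-voxel log-normal variation, spectral noise,
#' baseline order, and the seed.
#'
#' @param grid_rows,grid_cols Grid size (default 16x16 = 256 voxels).
#' @param ppm_range,n_points Spectral axis (default 0.2-4.2 ppm, 512 points).
#' @param subtype `"none"`, `"wt"`, `"IDH"` or `"LOH"`.
#' @param tissue_geometry Region spec list; default [default_geometry()]
#'   (necrotic core included for wt).
#' @param tissue_profiles Label -> mean profile list; default
#'   [default_tissue_profiles()] for the chosen subtype.
#' @param cv Coefficient of variation of voxel-to-voxel metabolite variation
#'   (log-normal), recycled per metabolite.
#' @param noise_sd Spectral white-noise SD.
#' @param baseline_order Polynomial baseline order for synthesized spectra.
#' @param with_spectra Logical: synthesize raw spectra (slower) or only the
#'   fitted metabolite table.
#' @param basis A `basis_set` for spectrum synthesis.
#' @param metabolites Metabolite names.
#' @param seed Integer seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_rows = 16, grid_cols = 16,
                           ppm_range = c(0.2, 4.2), n_points = 512,
                           subtype = "none",
                           tissue_geometry = NULL, tissue_profiles = NULL,
                           cv = 0.2, noise_sd = 0.05, baseline_order = 2,
                           with_spectra = FALSE, basis = default_basis(),
                           metabolites = default_metabolites(), seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(tissue_geometry)) {
    tissue_geometry <- default_geometry(grid_rows, grid_cols,
                                        necrosis = identical(subtype, "wt"))
  }
  if (is.null(tissue_profiles)) {
    tissue_profiles <- default_tissue_profiles(subtype, metabolites)
  }
  stopifnot(all(vapply(tissue_profiles, length, integer(1)) ==
                  length(metabolites)))
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 ppm_range = ppm_range, n_points = n_points,
                 subtype = subtype, tissue_geometry = tissue_geometry,
                 tissue_profiles = tissue_profiles,
                 cv = rep_len(cv, length(metabolites)),
                 noise_sd = noise_sd, baseline_order = baseline_order,
                 with_spectra = with_spectra, basis = basis,
                 metabolites = metabolites, seed = as.integer(seed)),
            class = "phantom_config")
}

geometry_labels <- function(config) {
  gr <- config$grid_rows
  gc_ <- config$grid_cols
  rows <- rep(0:(gr - 1), each = gc_)
  cols <- rep(0:(gc_ - 1), times = gr)
  lab <- rep(NA_character_, gr * gc_)
  for (spec in config$tissue_geometry) {
    hit <- switch(spec$shape,
      background = rep(TRUE, gr * gc_),
      rect = rows >= spec$r0 & rows <= spec$r1 &
             cols >= spec$c0 & cols <= spec$c1,
      disc = sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2) <=
             spec$radius,
      annulus = {
        d <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
        d > spec$r_in & d <= spec$r_out
      },
      stop(sprintf("unknown shape '%s'", spec$shape), call. = FALSE))
    lab[hit] <- spec$label
  }
  if (anyNA(lab)) {
    stop("tissue geometry does not cover the grid", call. = FALSE)
  }
  data.frame(row = rows, col = cols, label = lab, stringsAsFactors = FALSE)
}

# mean-preserving log-normal: E[X] = m for any cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv <= 0 || m <= 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate one phantom study with ground truth
#'
#' Assigns each grid voxel a segmentation label from the configured tissue
#' geometry, draws its true metabolite profile log-normally around the tissue
#' mean (mean-preserving, with the configured coefficient of variation), and
#' optionally synthesizes a raw spectrum per voxel. Deterministic given the
#' config (which carries the seed).
#'
#' @param config A [phantom_config()].
#' @return List with `study` (an [mrs_study()]) and `truth` (data frame
#'   `voxel_id`, `label` plus the true 34-profile columns).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  geo <- geometry_labels(config)
  n <- nrow(geo)
  mets <- config$metabolites
  with_seed(config$seed, {
    truth_vals <- matrix(0, n, length(mets), dimnames = list(NULL, mets))
    for (i in seq_len(n)) {
      prof <- config$tissue_profiles[[geo$label[i]]]
      truth_vals[i, ] <- vapply(seq_along(mets), function(m) {
        rlnorm_mean_cv(1, prof[m], config$cv[m])
      }, numeric(1))
    }
    voxel_ids <- sprintf("v%03d_%03d", geo$row, geo$col)
    # measured table = truth + small multiplicative measurement jitter
    meas <- truth_vals *
      matrix(exp(stats::rnorm(n * length(mets), 0, config$noise_sd)),
             n, length(mets))
    spectra <- NULL
    if (config$with_spectra) {
      ppm <- seq(config$ppm_range[1], config$ppm_range[2],
                 length.out = config$n_points)
      spectra <- vector("list", n)
      names(spectra) <- voxel_ids
      for (i in seq_len(n)) {
        bl <- if (config$baseline_order >= 0) {
          stats::rnorm(config$baseline_order + 1, 0, 0.5)
        } else NULL
        sd_i <- config$noise_sd * max(1, max(truth_vals[i, ]))
        y <- simulate_spectrum(truth_vals[i, ], config$basis, ppm,
                               noise_sd = 0, baseline_coeffs = bl)
        if (sd_i > 0) {
          y$intensity <- y$intensity + stats::rnorm(length(ppm), 0, sd_i)
        }
        spectra[[i]] <- y
      }
    }
    mt <- metabolite_table(voxel_ids, geo$row, geo$col, meas,
                           metabolite_names = mets)
    seg <- stats::setNames(geo$label, voxel_ids)
    study <- mrs_study(config$grid_rows, config$grid_cols, mt, seg,
                       spectra = spectra,
                       patient_meta = list(subtype = config$subtype))
    truth <- data.frame(voxel_id = voxel_ids, label = geo$label,
                        truth_vals, check.names = FALSE,
                        stringsAsFactors = FALSE)
    list(study = study, truth = truth)
  })
}

#' Write the ground-truth table of a phantom
#'
#' @param truth The `truth` data frame of [generate_phantom()].
#' @param path File path for the TSV (`voxel_id  label  <true profile>`).
#' @export
save_truth <- function(truth, path) {
  out <- truth
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a multi-patient synthetic cohort
#'
#' One phantom per patient with jittered tumor geometry (center and radius
#' varied deterministically from the cohort seed) and the subtype-specific
#' tissue profiles; `patient_meta$subtype` and `patient_meta$patient_id` are
#' set on every study.
#'
#' @param base_config A [phantom_config()] providing everything except the
#'   subtype and per-patient geometry.
#' @param n_per_subtype Named integer vector/list, names in
#'   `c("wt","IDH","LOH","none")`.
#' @param seed Integer cohort seed.
#' @return List of `list(study=, truth=, subtype=)`, one per patient.
#' @export
generate_cohort <- function(base_config = phantom_config(),
                            n_per_subtype = c(wt = 2, IDH = 2, LOH = 2),
                            seed = 1L) {
  subs <- names(n_per_subtype)
  if (is.null(subs) || !all(subs %in% c("wt", "IDH", "LOH", "none"))) {
    stop("n_per_subtype names must be in wt/IDH/LOH/none", call. = FALSE)
  }
  counts <- unlist(n_per_subtype)
  if (sum(counts) < 1) stop("empty cohort request", call. = FALSE)
  subtype_seq <- rep(subs, counts)
  n_pat <- length(subtype_seq)
  jit <- with_seed(seed, list(
    dr = stats::runif(n_pat, -2.5, 2.5),
    dc = stats::runif(n_pat, -2.5, 2.5),
    rad = stats::runif(n_pat, 2.4, 3.6),
    seeds = sample.int(2^31 - 2, n_pat)
  ))
  lapply(seq_len(n_pat), function(i) {
    sub <- subtype_seq[i]
    ctr <- c(base_config$grid_rows / 2 + jit$dr[i] + 2,
             base_config$grid_cols / 2 + jit$dc[i] + 2)
    ctr <- pmin(pmax(ctr, jit$rad[i] + 2.2),
                c(base_config$grid_rows, base_config$grid_cols) -
                  jit$rad[i] - 2.2)
    cfg <- phantom_config(
      grid_rows = base_config$grid_rows, grid_cols = base_config$grid_cols,
      ppm_range = base_config$ppm_range, n_points = base_config$n_points,
      subtype = sub,
      tissue_geometry = default_geometry(base_config$grid_rows,
                                         base_config$grid_cols,
                                         center = ctr, radius = jit$rad[i],
                                         necrosis = identical(sub, "wt")),
      cv = base_config$cv, noise_sd = base_config$noise_sd,
      baseline_order = base_config$baseline_order,
      with_spectra = base_config$with_spectra, basis = base_config$basis,
      metabolites = base_config$metabolites, seed = jit$seeds[i])
    ph <- generate_phantom(cfg)
    ph$study$patient_meta$subtype <- sub
    ph$study$patient_meta$patient_id <- sprintf("P%03d", i)
    list(study = ph$study, truth = ph$truth, subtype = sub)
  })
}
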