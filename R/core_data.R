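#' Segmentation labels for CSI voxels
#'
#' The eight labels a voxel of a chemical-shift-imaging grid can carry after
#' radiological segmentation: normal appearing matter (NAM), non-tumor lesion
#' (ischemia, inflammation), tumor, contrast-enhancing tumor, necrosis,
#' FLAIR-hyperintense region, ventricle system, and EXCLUDED for voxels that
#' failed quality control or could not be assigned.
#'
#' @return Character vector of the eight valid segmentation labels.
#' @export
segment_labels <- function() {
  c("NAM", "LESION", "TUMOR", "CONTRAST", "NECROSIS", "FLAIR", "VENTRICLE",
    "EXCLUDED")
}

#' Default metabolite basis names
#'
#' A standard 34-metabolite short-echo-time basis covering the major singlets,
#' amino acids, lipid and macromolecule (MM) resonances quantified in brain
#' 1H-MRS. Only the length (34) is normative for the pipeline; the names are
#' configurable everywhere a [metabolite_table()] is built.
#'
#' @return Character vector of 34 metabolite names.
#' @export
default_metabolites <- function() {
  c("NAA", "NAAG", "Cr", "PCr", "GPC", "PCh", "Ins", "Lac", "Ala", "Asp",
    "GABA", "Glc", "Gln", "Glu", "Gly", "GSH", "Lip09", "Lip13a", "Lip13b",
    "Lip20", "MM09", "MM12", "MM14", "MM17", "MM20", "PE", "Scyllo", "Tau",
    "Cit", "Cys", "EtOH", "Ser", "Thr", "Val")
}

#' Construct a single-voxel spectrum
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `ppm`, all finite.
#' @return An object of class `mrs_spectrum` (list with `ppm`, `intensity`).
#' @export
mrs_spectrum <- function(ppm, intensity) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length", call. = FALSE)
  }
  d <- diff(ppm)
  if (length(ppm) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(list(ppm = ppm, intensity = intensity), class = "mrs_spectrum")
}

#' Construct a voxels-by-metabolites intensity table
#'
#' Holds the per-voxel fitted metabolite amplitudes of one CSI study together
#' with the voxel grid coordinates (0-based, row-major).
#'
#' @param voxel_ids Character vector of unique voxel identifiers.
#' @param row,col Integer grid coordinates (0-based) per voxel.
#' @param values Numeric matrix, voxels x metabolites, finite.
#' @param metabolite_names Character vector naming the columns; default the
#'   34-name basis of [default_metabolites()].
#' @return An object of class `metabolite_table`.
#' @export
metabolite_table <- function(voxel_ids, row, col, values,
                             metabolite_names = default_metabolites()) {
  voxel_ids <- as.character(voxel_ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyDuplicated(voxel_ids)) stop("duplicated voxel_ids", call. = FALSE)
  if (length(voxel_ids) != nrow(values) ||
      length(row) != nrow(values) || length(col) != nrow(values)) {
    stop("voxel_ids, row, col and values rows must agree", call. = FALSE)
  }
  if (ncol(values) != length(metabolite_names)) {
    stop(sprintf("values has %d columns but %d metabolite names given",
                 ncol(values), length(metabolite_names)), call. = FALSE)
  }
  rownames(values) <- voxel_ids
  colnames(values) <- metabolite_names
  structure(list(voxel_ids = voxel_ids,
                 row = as.integer(row), col = as.integer(col),
                 values = values,
                 metabolite_names = as.character(metabolite_names)),
            class = "metabolite_table")
}

#' Construct a study (one CSI imaging session)
#'
#' @param grid_rows,grid_cols Integers giving the CSI grid geometry.
#' @param metabolites A [metabolite_table()].
#' @param segmentation Named character vector mapping every voxel id in
#'   `metabolites` to a [segment_labels()] value.
#' @param spectra Optional named list of [mrs_spectrum()] per voxel id.
#' @param patient_meta Free-form list; keys `patient_id` and `subtype`
#'   (one of `"wt"`, `"IDH"`, `"LOH"`, `"none"`) are recognized downstream.
#' @return An object of class `mrs_study`.
#' @export
mrs_study <- function(grid_rows, grid_cols, metabolites, segmentation,
                      spectra = NULL, patient_meta = list()) {
  s <- structure(list(grid_rows = as.integer(grid_rows),
                      grid_cols = as.integer(grid_cols),
                      metabolites = metabolites,
                      segmentation = segmentation,
                      spectra = spectra,
                      patient_meta = patient_meta),
                 class = "mrs_study")
  viol <- validate_study(s)
  if (length(viol)) {
    stop(paste(c("invalid study:", viol), collapse = "\n  "), call. = FALSE)
  }
  s
}

#' @export
print.mrs_study <- function(x, ...) {
  cat(sprintf("<mrs_study> %dx%d grid, %d voxels, %d metabolites%s\n",
              x$grid_rows, x$grid_cols, length(x$metabolites$voxel_ids),
              length(x$metabolites$metabolite_names),
              if (is.null(x$spectra)) "" else
                sprintf(", %d spectra", length(x$spectra))))
  tab <- table(factor(x$segmentation, levels = segment_labels()))
  cat("  segmentation:", paste(sprintf("%s=%d", names(tab)[tab > 0],
                                       tab[tab > 0]), collapse = " "), "\n")
  invisible(x)
}

#' Validate a study against the data-model invariants
#'
#' Reports (never throws) the list of invariant violations: non-finite values,
#' duplicated grid coordinates, segmentation not covering every voxel, unknown
#' labels, geometry too small for the voxel count, and mismatched spectra.
#'
#' @param study An `mrs_study` (or a bare list with the same fields).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_study <- function(study) {
  v <- character()
  mt <- study$metabolites
  if (!inherits(mt, "metabolite_table")) {
    return("metabolites is not a metabolite_table")
  }
  if (!all(is.finite(mt$values))) {
    v <- c(v, "metabolite values contain non-finite entries")
  }
  key <- paste(mt$row, mt$col)
  if (anyDuplicated(key)) {
    dup <- mt$voxel_ids[duplicated(key) | duplicated(key, fromLast = TRUE)]
    v <- c(v, sprintf("duplicated (row,col) for voxels: %s",
                      paste(dup, collapse = ", ")))
  }
  if (study$grid_rows * study$grid_cols < length(mt$voxel_ids)) {
    v <- c(v, sprintf("grid %dx%d smaller than %d voxels",
                      study$grid_rows, study$grid_cols, length(mt$voxel_ids)))
  }
  if (any(mt$row < 0) || any(mt$col < 0) ||
      any(mt$row >= study$grid_rows) || any(mt$col >= study$grid_cols)) {
    v <- c(v, "grid coordinates outside [0, grid_rows) x [0, grid_cols)")
  }
  seg <- study$segmentation
  missing_seg <- setdiff(mt$voxel_ids, names(seg))
  if (length(missing_seg)) {
    v <- c(v, sprintf("segmentation missing voxels: %s",
                      paste(missing_seg, collapse = ", ")))
  }
  bad_lab <- setdiff(unique(seg), segment_labels())
  if (length(bad_lab)) {
    v <- c(v, sprintf("unknown segmentation labels: %s",
                      paste(bad_lab, collapse = ", ")))
  }
  if (!is.null(study$spectra)) {
    extra <- setdiff(names(study$spectra), mt$voxel_ids)
    if (length(extra)) {
      v <- c(v, sprintf("spectra for unknown voxels: %s",
                        paste(extra, collapse = ", ")))
    }
    ok <- vapply(study$spectra, inherits, logical(1), what = "mrs_spectrum")
    if (!all(ok)) v <- c(v, "spectra entries must be mrs_spectrum objects")
  }
  v
}

stop_if_invalid <- function(study) {
  viol <- validate_study(study)
  if (length(viol)) {
    stop(paste(c("invalid study:", viol), collapse = "\n  "), call. = FALSE)
  }
  invisible(study)
}

#' Define an ordered class set for the discriminant models
#'
#' @param level `"REGION"` (voxel origin; defaults to NAM, LESION, TUMOR,
#'   METASTASIS) or `"SUBTYPE"` (glioma molecular subtype; always wt, IDH,
#'   LOH).
#' @param classes Optional override of the REGION class list.
#' @return An object of class `class_set` with fields `classes` and `level`.
#' @export
class_set <- function(level = c("REGION", "SUBTYPE"), classes = NULL) {
  level <- match.arg(level)
  if (level == "SUBTYPE") {
    if (!is.null(classes) && !identical(classes, c("wt", "IDH", "LOH"))) {
      stop("SUBTYPE level is fixed to (wt, IDH, LOH)", call. = FALSE)
    }
    classes <- c("wt", "IDH", "LOH")
  } else if (is.null(classes)) {
    classes <- c("NAM", "LESION", "TUMOR", "METASTASIS")
  }
  structure(list(classes = as.character(classes), level = level),
            class = "class_set")
}

fmt_num <- function(x) {
  # 17 significant digits round-trips doubles exactly through decimal text
  sprintf("%.17g", x)
}

#' Write a study to a directory
#'
#' Writes `metabolites.tsv` (`voxel_id row col <metabolite names>`),
#' `segmentation.tsv` (`voxel_id row col label`), `meta.json`, and, when
#' spectra are present, long-format `spectra.tsv` (`voxel_id ppm intensity`).
#' Numeric fields are written with 17 significant digits so that
#' [load_study()] round-trips them exactly.
#'
#' @param study A valid `mrs_study`.
#' @param path Directory to create/write into.
#' @return Invisibly, `path`.
#' @export
save_study <- function(study, path) {
  stop_if_invalid(study)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", path), call. = FALSE)
  }
  mt <- study$metabolites
  vals <- apply(mt$values, 2, fmt_num)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(mt$values))
  met_df <- data.frame(voxel_id = mt$voxel_ids, row = mt$row, col = mt$col,
                       vals, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(met_df) <- c("voxel_id", "row", "col", mt$metabolite_names)
  utils::write.table(met_df, file.path(path, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seg_df <- data.frame(voxel_id = mt$voxel_ids, row = mt$row, col = mt$col,
                       label = unname(study$segmentation[mt$voxel_ids]),
                       stringsAsFactors = FALSE)
  utils::write.table(seg_df, file.path(path, "segmentation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- study$patient_meta
  meta$grid_rows <- study$grid_rows
  meta$grid_cols <- study$grid_cols
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(study$spectra) && length(study$spectra)) {
    ids <- names(study$spectra)
    n_pt <- vapply(study$spectra, function(s) length(s$ppm), integer(1))
    sp_df <- data.frame(
      voxel_id = rep(ids, n_pt),
      ppm = fmt_num(unlist(lapply(study$spectra, `[[`, "ppm"))),
      intensity = fmt_num(unlist(lapply(study$spectra, `[[`, "intensity"))),
      stringsAsFactors = FALSE)
    utils::write.table(sp_df, file.path(path, "spectra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a study from a directory written by [save_study()]
#'
#' @param path Directory containing `metabolites.tsv`, `segmentation.tsv`,
#'   `meta.json` and optionally `spectra.tsv`.
#' @param metabolite_names Expected metabolite names; the file header must
#'   carry exactly these columns (count mismatch is a format error). `NULL`
#'   accepts whatever the header declares.
#' @return A validated `mrs_study`.
#' @export
load_study <- function(path, metabolite_names = default_metabolites()) {
  need <- c("metabolites.tsv", "segmentation.tsv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("missing file '%s' in '%s'", f, path), call. = FALSE)
    }
  }
  met_df <- utils::read.delim(file.path(path, "metabolites.tsv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- colnames(met_df)
  if (length(hdr) < 4 || !identical(hdr[1:3], c("voxel_id", "row", "col"))) {
    stop("metabolites.tsv: header must start with voxel_id, row, col",
         call. = FALSE)
  }
  names_in_file <- hdr[-(1:3)]
  if (!is.null(metabolite_names) &&
      length(names_in_file) != length(metabolite_names)) {
    stop(sprintf("metabolites.tsv: %d metabolite columns, expected %d",
                 length(names_in_file), length(metabolite_names)),
         call. = FALSE)
  }
  vals <- as.matrix(met_df[, -(1:3), drop = FALSE])
  if (!all(is.finite(vals))) {
    stop("metabolites.tsv contains non-finite values", call. = FALSE)
  }
  mt <- metabolite_table(met_df$voxel_id, met_df$row, met_df$col, vals,
                         metabolite_names = names_in_file)
  seg_df <- utils::read.delim(file.path(path, "segmentation.tsv"),
                              stringsAsFactors = FALSE)
  seg <- stats::setNames(seg_df$label, seg_df$voxel_id)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  grid_rows <- meta$grid_rows
  grid_cols <- meta$grid_cols
  meta$grid_rows <- NULL
  meta$grid_cols <- NULL
  spectra <- NULL
  sp_path <- file.path(path, "spectra.tsv")
  if (file.exists(sp_path)) {
    sp_df <- utils::read.delim(sp_path, stringsAsFactors = FALSE)
    spl <- split(sp_df[c("ppm", "intensity")], sp_df$voxel_id)
    spectra <- lapply(spl, function(d) mrs_spectrum(d$ppm, d$intensity))
    spectra <- spectra[intersect(mt$voxel_ids, names(spectra))]
  }
  mrs_study(grid_rows, grid_cols, mt, seg, spectra = spectra,
            patient_meta = as.list(meta))
}
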