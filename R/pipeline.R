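#' Map segmentation labels to region classes
#'
#' The region-level model is trained on four lesion classes; CSI segmentation
#' labels collapse onto them as: NAM and VENTRICLE -> NAM (non-lesional),
#' LESION and FLAIR -> LESION (non-tumor pathology / edema), TUMOR, CONTRAST
#' and NECROSIS -> TUMOR. METASTASIS is carried through when present as a
#' segmentation-level diagnosis in `patient_meta`. EXCLUDED maps to NA.
#'
#' @param labels Character vector of [segment_labels()] values.
#' @return Character vector of region classes (NA for EXCLUDED).
#' @export
region_from_segment <- function(labels) {
  map <- c(NAM = "NAM", VENTRICLE = "NAM", LESION = "LESION",
           FLAIR = "LESION", TUMOR = "TUMOR", CONTRAST = "TUMOR",
           NECROSIS = "TUMOR", METASTASIS = "METASTASIS",
           EXCLUDED = NA_character_)
  unname(map[labels])
}

#' Pipeline configuration
#'
#' @param phantom A [phantom_config()] used when no input directory is
#'   given.
#' @param input_dir Optional directory of studies saved by [save_study()].
#' @param spec A [layer_spec()] for the denoising autoencoder.
#' @param ae_epochs Autoencoder training epochs.
#' @param bottleneck_search Logical: run the bottleneck width search before
#'   training.
#' @param bottleneck_sizes Candidate widths for the search.
#' @param n_components Fixed number of PCA components for clustering
#'   (overrides the parallel-analysis selection); `NULL` (default) selects
#'   adaptively.
#' @param k_neighbors SNN neighborhood size.
#' @param split Training fraction for patient-level splitting (default 2/3).
#' @param split_mode `"patient"` (default; no voxel of a held-out patient is
#'   seen in training) or `"voxel"`.
#' @param quality_threshold Residual QC threshold (x median), used when
#'   spectra are present.
#' @param seed Mandatory integer seed for the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_config(), input_dir = NULL,
                            spec = layer_spec(), ae_epochs = 500,
                            bottleneck_search = FALSE,
                            bottleneck_sizes = 4:10,
                            n_components = NULL, k_neighbors = 20,
                            split = 2 / 3,
                            split_mode = c("patient", "voxel"),
                            quality_threshold = 3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  split_mode <- match.arg(split_mode)
  structure(list(phantom = phantom, input_dir = input_dir, spec = spec,
                 ae_epochs = ae_epochs,
                 bottleneck_search = bottleneck_search,
                 bottleneck_sizes = bottleneck_sizes,
                 n_components = n_components, k_neighbors = k_neighbors,
                 split = split, split_mode = split_mode,
                 quality_threshold = quality_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(stage, msg, log_file = NULL) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(NULL)
}

run_stage <- function(stage, expr, log_file = NULL) {
  log_stage(stage, "start", log_file)
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

write_tsv_fmt <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(out_dir, config, extra = list()) {
  cfg_json <- jsonlite::toJSON(config_digestible(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- file.path(out_dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- c(list(config_hash = unname(tools::md5sum(tmp)),
                     seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("mrsport"))),
                extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# drop function/environment-carrying members so the hash is stable text
config_digestible <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, config_digestible)
    x[!vapply(x, is.null, logical(1))]
  } else if (is.function(x) || is.environment(x)) NULL else x
}

load_or_generate <- function(config) {
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      stop(sprintf("input directory '%s' does not exist and no phantom %s",
                   config$input_dir, "configuration was given"),
           call. = FALSE)
    }
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    if (!length(dirs)) dirs <- config$input_dir
    lapply(dirs, function(d) list(study = load_study(d), truth = NULL))
  } else {
    list(generate_phantom(config$phantom))
  }
}

#' Run the unsupervised characterization arm
#'
#' Generates (or loads) the studies, min-max normalizes the pooled
#' metabolite matrix, trains the denoising autoencoder (optionally after a
#' bottleneck width search), selects non-trivial principal components by
#' parallel analysis (or uses a fixed count), SNN-clusters the component
#' scores, embeds them in 2D with UMAP, and tests marker-metabolite
#' enrichment per cluster. All artifacts (`normalized.tsv`, `denoised.tsv`,
#' `pca_report.tsv`, `clusters.tsv`, `markers.tsv`, per-cluster
#' `mean_spectra.tsv` when raw spectra exist, `manifest.json`) are written to
#' `out_dir` and are byte-identical across runs with the same config + seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory artifacts.
#' @export
run_characterize <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  studies <- run_stage("load", load_or_generate(config), log_file)
  mt_list <- lapply(studies, function(s) s$study$metabolites)
  X <- do.call(rbind, lapply(mt_list, `[[`, "values"))
  voxel_ids <- unlist(lapply(seq_along(mt_list), function(i) {
    paste0("s", i, ":", mt_list[[i]]$voxel_ids)
  }))
  rownames(X) <- voxel_ids
  seg <- unlist(lapply(studies, function(s) unname(
    s$study$segmentation[s$study$metabolites$voxel_ids])))

  qc_pass <- rep(TRUE, nrow(X))
  spectra_all <- unlist(lapply(studies, function(s) s$study$spectra),
                        recursive = FALSE)
  if (length(spectra_all)) {
    qc <- run_stage("quality_filter", {
      fits <- suppressWarnings(lapply(spectra_all, function(sp) {
        fit_basis_amplitudes(baseline_correct(sp), config$phantom$basis)
      }))
      res <- vapply(fits, `[[`, numeric(1), "residual_rms")
      list(res = res, pass = quality_filter(res, config$quality_threshold))
    }, log_file)
    qc_pass[seq_along(qc$pass)] <- qc$pass
    write_tsv_fmt(data.frame(voxel_id = voxel_ids[seq_along(qc$pass)],
                             residual_rms = qc$res, pass = qc$pass),
                  file.path(out_dir, "qc.tsv"))
  }
  X <- X[qc_pass, , drop = FALSE]
  voxel_ids <- voxel_ids[qc_pass]

  norm <- run_stage("normalize", minmax_normalize(X), log_file)
  jsonlite::write_json(
    stats::setNames(lapply(seq_along(norm$mins), function(j) {
      c(norm$mins[j], norm$maxs[j])
    }), colnames(X)),
    file.path(out_dir, "normalization.json"), digits = NA)

  spec <- config$spec
  if (isTRUE(config$bottleneck_search)) {
    bs <- run_stage("bottleneck_search",
                    bottleneck_search(norm$values, config$bottleneck_sizes,
                                      spec = spec, epochs = config$ae_epochs,
                                      seed = config$seed), log_file)
    write_tsv_fmt(bs$benchmark, file.path(out_dir, "bottleneck_search.tsv"))
    ew <- spec$encoder_widths[spec$encoder_widths > bs$best]
    if (!length(ew)) ew <- 2 * bs$best
    spec <- layer_spec(ew, bs$best, spec$dropout, spec$batch_norm)
  }
  trained <- run_stage("autoencoder", {
    mod <- init_autoencoder(spec, n_inputs = ncol(X), seed = config$seed)
    train_autoencoder(mod, norm$values, epochs = config$ae_epochs,
                      seed = config$seed)
  }, log_file)
  den <- denoise(trained$model, norm)
  write_tsv_fmt(cbind(data.frame(voxel_id = voxel_ids),
                      as.data.frame(norm$values)),
                file.path(out_dir, "normalized.tsv"))
  write_tsv_fmt(cbind(data.frame(voxel_id = voxel_ids),
                      as.data.frame(den$values)),
                file.path(out_dir, "denoised.tsv"))
  write_tsv_fmt(trained$report$loss_history,
                file.path(out_dir, "loss_history.tsv"))

  emb <- run_stage("embed_cluster", {
    pr <- mrs_pca(den$values)
    sel <- if (is.null(config$n_components)) {
      select_nontrivial(den$values, seed = config$seed)
    } else seq_len(config$n_components)
    if (length(sel) < 2) sel <- 1:2  # keep at least a plane to embed
    scores <- pr$scores[, sel, drop = FALSE]
    clu <- snn_cluster(scores, k_neighbors = config$k_neighbors,
                       seed = config$seed)
    um <- embed2d(scores, seed = config$seed)
    list(pca = pr, selected = sel, clusters = clu, umap = um)
  }, log_file)
  write_tsv_fmt(data.frame(component = seq_along(emb$pca$eigenvalues),
                           eigenvalue = emb$pca$eigenvalues,
                           explained_share = emb$pca$explained_share,
                           selected = seq_along(emb$pca$eigenvalues) %in%
                             emb$selected),
                file.path(out_dir, "pca_report.tsv"))
  write_tsv_fmt(data.frame(voxel_id = voxel_ids, segment = seg[qc_pass],
                           cluster = emb$clusters$labels,
                           umap1 = emb$umap[, 1], umap2 = emb$umap[, 2]),
                file.path(out_dir, "clusters.tsv"))

  markers <- run_stage("markers", {
    if (emb$clusters$k >= 2) {
      marker_metabolites(X, emb$clusters$labels)
    } else NULL
  }, log_file)
  if (!is.null(markers)) {
    write_tsv_fmt(as.data.frame(markers), file.path(out_dir, "markers.tsv"))
  }

  if (length(spectra_all)) {
    run_stage("mean_spectra", {
      sp_use <- spectra_all[qc_pass[seq_along(spectra_all)]]
      by_cl <- split(seq_along(sp_use), emb$clusters$labels)
      ms <- lapply(by_cl, function(ii) mean_spectrum(sp_use[ii]))
      df <- do.call(rbind, lapply(names(ms), function(cc) {
        data.frame(cluster = cc, ppm = ms[[cc]]$ppm, mean = ms[[cc]]$mean,
                   variance = ms[[cc]]$variance)
      }))
      write_tsv_fmt(df, file.path(out_dir, "mean_spectra.tsv"))
    }, log_file)
  }
  write_manifest(out_dir, config,
                 extra = list(n_voxels = nrow(X),
                              n_clusters = emb$clusters$k))
  invisible(list(normalized = norm, denoised = den, model = trained$model,
                 pca = emb$pca, selected = emb$selected,
                 clusters = emb$clusters, umap = emb$umap,
                 markers = markers))
}

#' Train and evaluate the two-layer prediction model on a cohort
#'
#' Splits the cohort at the patient level (default 2/3 training, 1/3
#' held-out; no voxel of a held-out patient enters training), learns
#' normalization statistics and the denoising autoencoder on training voxels
#' only, fits the layer-1 region LDA on all labeled training voxels and the
#' layer-2 subtype LDA on true tumor voxels of training patients, calibrates
#' the subtype scores on the training tumor reference, and predicts every
#' held-out patient with [two_layer_predict()]. Writes per-patient
#' `prediction_<id>.json`, `evaluation.json` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param cohort List of `list(study=, subtype=)` as from
#'   [generate_cohort()].
#' @param out_dir Output directory.
#' @param single_layer Also evaluate the single-layer variant (subtype model
#'   applied to every voxel with no tumor mask) for comparison.
#' @return Invisibly: models, per-patient predictions, evaluation list.
#' @export
run_predict <- function(config, cohort, out_dir, single_layer = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  n_pat <- length(cohort)
  subtypes <- vapply(cohort, function(p) p$subtype %||%
                       p$study$patient_meta$subtype, character(1))
  split <- run_stage("split", {
    if (config$split_mode != "patient") {
      stop("only patient-level splitting is supported here", call. = FALSE)
    }
    idx <- with_seed(config$seed, sample.int(n_pat))
    ntr <- max(1, floor(config$split * n_pat))
    list(train = sort(idx[seq_len(ntr)]), test = sort(idx[-seq_len(ntr)]))
  }, log_file)
  train_sub <- subtypes[split$train]
  missing_sub <- setdiff(setdiff(unique(subtypes), "none"),
                         unique(train_sub))
  if (length(missing_sub)) {
    stop(sprintf("subtype(s) absent from training split: %s",
                 paste(missing_sub, collapse = ", ")), call. = FALSE)
  }

  stack_features <- function(ids) {
    do.call(rbind, lapply(ids, function(i) {
      cohort[[i]]$study$metabolites$values
    }))
  }
  Xtr_raw <- stack_features(split$train)
  seg_tr <- unlist(lapply(split$train, function(i) {
    s <- cohort[[i]]$study
    unname(s$segmentation[s$metabolites$voxel_ids])
  }))
  pat_tr <- rep(split$train, vapply(split$train, function(i) {
    nrow(cohort[[i]]$study$metabolites$values)
  }, integer(1)))

  norm <- run_stage("normalize", minmax_normalize(Xtr_raw), log_file)
  trained <- run_stage("autoencoder", {
    mod <- init_autoencoder(config$spec, n_inputs = ncol(Xtr_raw),
                            seed = config$seed)
    train_autoencoder(mod, norm$values, epochs = config$ae_epochs,
                      seed = config$seed)
  }, log_file)
  den_tr <- denoise(trained$model, norm)

  region_tr <- region_from_segment(seg_tr)
  keep1 <- !is.na(region_tr)
  layer1 <- run_stage("layer1_lda",
                      fit_lda(den_tr$values[keep1, , drop = FALSE],
                              region_tr[keep1], cls = class_set("REGION")),
                      log_file)
  tumor_tr <- seg_tr %in% c("TUMOR", "CONTRAST") &
    subtypes[pat_tr] %in% c("wt", "IDH", "LOH")
  layer2 <- run_stage("layer2_lda",
                      fit_lda(den_tr$values[tumor_tr, , drop = FALSE],
                              subtypes[pat_tr][tumor_tr],
                              cls = class_set("SUBTYPE")), log_file)
  cal <- calibrate_scores(predict_lda(layer2,
                                      den_tr$values[tumor_tr, ,
                                                    drop = FALSE]))
  cal_params <- attr(cal, "calibration")

  predict_patient <- function(i) {
    s <- cohort[[i]]$study
    Xi <- apply_normalization(norm, s$metabolites$values)
    di <- denoise(trained$model, Xi)
    two_layer_predict(layer1, layer2, di$values,
                      calibration = cal_params)
  }
  preds <- run_stage("predict", lapply(split$test, predict_patient),
                     log_file)
  names(preds) <- vapply(split$test, function(i) {
    cohort[[i]]$study$patient_meta$patient_id %||% sprintf("P%03d", i)
  }, character(1))

  eval_ <- run_stage("evaluate", {
    truth_sub <- subtypes[split$test]
    pred_sub <- vapply(preds, function(p) {
      if (p$no_tumor) NA_character_ else p$predicted
    }, character(1))
    has_tumor <- truth_sub %in% c("wt", "IDH", "LOH")
    acc <- mean(pred_sub[has_tumor] == truth_sub[has_tumor], na.rm = FALSE)
    # voxel-level region accuracy on held-out patients
    vox_acc <- {
      correct <- 0
      total <- 0
      for (k in seq_along(split$test)) {
        i <- split$test[k]
        s <- cohort[[i]]$study
        truth_reg <- region_from_segment(
          unname(s$segmentation[s$metabolites$voxel_ids]))
        pred_reg <- preds[[k]]$region$predicted
        ok <- !is.na(truth_reg)
        correct <- correct + sum(pred_reg[ok] == truth_reg[ok])
        total <- total + sum(ok)
      }
      correct / total
    }
    aucs <- sapply(c("wt", "IDH", "LOH"), function(cc) {
      sc <- vapply(preds, function(p) {
        if (p$no_tumor) -Inf else unname(p$sport_scores[cc])
      }, numeric(1))
      lab <- truth_sub == cc
      if (all(lab) || !any(lab)) NA_real_ else roc_auc(sc, lab)
    })
    cm <- table(truth = truth_sub[has_tumor],
                predicted = factor(pred_sub[has_tumor],
                                   levels = c("wt", "IDH", "LOH")))
    list(patient_accuracy = acc, voxel_region_accuracy = vox_acc,
         auc = as.list(aucs),
         confusion = as.data.frame(cm, stringsAsFactors = FALSE))
  }, log_file)

  for (k in seq_along(preds)) {
    p <- preds[[k]]
    out <- list(patient_id = names(preds)[k],
                true_subtype = subtypes[split$test[k]],
                no_tumor = p$no_tumor,
                tumor_mask = which(p$tumor_mask),
                sport_scores = if (p$no_tumor) NULL else
                  as.list(unclass(p$sport_scores)),
                predicted = if (p$no_tumor) "no tumor detected" else
                  p$predicted)
    jsonlite::write_json(out,
                         file.path(out_dir,
                                   sprintf("prediction_%s.json",
                                           names(preds)[k])),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(eval_[c("patient_accuracy", "voxel_region_accuracy",
                               "auc")],
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_fmt(eval_$confusion, file.path(out_dir, "confusion.tsv"))
  write_manifest(out_dir, config,
                 extra = list(n_train = length(split$train),
                              n_test = length(split$test)))
  result <- list(split = split, normalization = norm,
                 model = trained$model, layer1 = layer1, layer2 = layer2,
                 calibration = cal_params, predictions = preds,
                 evaluation = eval_)
  if (single_layer) {
    result$single_layer <- lapply(split$test, function(i) {
      s <- cohort[[i]]$study
      Xi <- apply_normalization(norm, s$metabolites$values)
      di <- denoise(trained$model, Xi)
      calibrate_scores(predict_lda(layer2, di$values), params = cal_params)
    })
  }
  invisible(result)
}
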