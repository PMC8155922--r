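test_that("simulate_spectrum composes templates, baseline and noise", {
  ppm <- default_ppm(256)
  basis <- three_peak_basis()
  z <- simulate_spectrum(c(0, 0, 0), basis, ppm)
  expect_true(all(z$intensity == 0))
  # single Lorentzian: maximum at the sampled point closest to its center
  one <- simulate_spectrum(c(0, 1, 0), basis, ppm)
  expect_equal(ppm[which.max(one$intensity)], ppm[which.min(abs(ppm - 2.2))])
  # deterministic noise
  a <- simulate_spectrum(c(1, 1, 1), basis, ppm, noise_sd = 0.1, seed = 5)
  b <- simulate_spectrum(c(1, 1, 1), basis, ppm, noise_sd = 0.1, seed = 5)
  expect_identical(a$intensity, b$intensity)
  expect_error(simulate_spectrum(c(1, 1, 1), basis, ppm, noise_sd = -1),
               ">= 0")
})

test_that("generate_phantom produces a 256-voxel labeled study", {
  ph <- generate_phantom(phantom_config(subtype = "wt", seed = 3))
  expect_equal(length(ph$study$metabolites$voxel_ids), 256)
  expect_equal(ncol(ph$study$metabolites$values), 34)
  expect_true(all(ph$study$segmentation %in% segment_labels()))
  expect_setequal(unique(ph$truth$label),
                  c("NAM", "VENTRICLE", "FLAIR", "TUMOR", "CONTRAST",
                    "NECROSIS"))
  # determinism
  ph2 <- generate_phantom(phantom_config(subtype = "wt", seed = 3))
  expect_identical(ph$study$metabolites$values,
                   ph2$study$metabolites$values)
})

test_that("zero CV and zero noise reproduce the tissue profiles exactly", {
  cfg <- phantom_config(cv = 0, noise_sd = 0, seed = 2)
  ph <- generate_phantom(cfg)
  nam <- ph$study$segmentation == "NAM"
  prof <- cfg$tissue_profiles$NAM
  vals <- ph$study$metabolites$values[nam, , drop = FALSE]
  expect_true(all(abs(sweep(vals, 2, prof, `-`)) < 1e-12))
})

test_that("geometry must cover the grid", {
  cfg <- phantom_config(seed = 1)
  cfg$tissue_geometry <- list(list(label = "TUMOR", shape = "disc",
                                   center = c(8, 8), radius = 2))
  expect_error(generate_phantom(cfg), "does not cover")
})

test_that("cohorts have the requested composition and are reproducible", {
  co <- generate_cohort(phantom_config(seed = 1),
                        c(wt = 2, IDH = 2, LOH = 2), seed = 1)
  expect_length(co, 6)
  expect_equal(as.integer(table(vapply(co, `[[`, character(1),
                                       "subtype"))),
               c(2L, 2L, 2L))
  co2 <- generate_cohort(phantom_config(seed = 1), c(wt = 1), seed = 9)
  co3 <- generate_cohort(phantom_config(seed = 1), c(wt = 1), seed = 9)
  expect_identical(co2[[1]]$study$metabolites$values,
                   co3[[1]]$study$metabolites$values)
  expect_error(generate_cohort(phantom_config(seed = 1), c(wt = 0), seed = 1),
               "empty")
  expect_error(generate_cohort(phantom_config(seed = 1), c(bad = 2), seed = 1),
               "wt/IDH/LOH/none")
})

test_that("wildtype tumors carry more lactate than IDH-mutant ones", {
  co <- generate_cohort(phantom_config(seed = 1),
                        c(wt = 10, IDH = 10), seed = 21)
  lac <- function(p) {
    s <- p$study
    tum <- s$segmentation[s$metabolites$voxel_ids] %in%
      c("TUMOR", "CONTRAST")
    mean(s$metabolites$values[tum, "Lac"])
  }
  m <- vapply(co, lac, numeric(1))
  sub <- vapply(co, `[[`, character(1), "subtype")
  expect_gt(mean(m[sub == "wt"]), mean(m[sub == "IDH"]))
})

test_that("default effect sizes support near-perfect wt/IDH separation", {
  co <- generate_cohort(phantom_config(seed = 1),
                        c(wt = 3, IDH = 3), seed = 4)
  X <- do.call(rbind, lapply(co, function(p) {
    s <- p$study
    tum <- s$segmentation[s$metabolites$voxel_ids] %in%
      c("TUMOR", "CONTRAST")
    s$metabolites$values[tum, , drop = FALSE]
  }))
  y <- unlist(lapply(co, function(p) {
    s <- p$study
    tum <- s$segmentation[s$metabolites$voxel_ids] %in%
      c("TUMOR", "CONTRAST")
    rep(p$subtype, sum(tum))
  }))
  m <- fit_lda(X, y)
  acc <- mean(predict_lda(m, X)$predicted == y)
  expect_gte(acc, 0.95)
})

test_that("noiseless spectra invert exactly through the basis fit", {
  cfg <- phantom_config(grid_rows = 3, grid_cols = 3, cv = 0, noise_sd = 0,
                        baseline_order = -1, with_spectra = TRUE,
                        n_points = 512, seed = 5)
  ph <- generate_phantom(cfg)
  ids <- ph$study$metabolites$voxel_ids[c(1, 5)]
  for (id in ids) {
    f <- suppressWarnings(
      fit_basis_amplitudes(ph$study$spectra[[id]], cfg$basis))
    truth <- as.numeric(ph$truth[ph$truth$voxel_id == id,
                                 cfg$metabolites])
    expect_lt(max(abs(f$amplitudes - truth) / pmax(truth, 1e-12)), 1e-6)
  }
})
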