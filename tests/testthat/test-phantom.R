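test_that("phantom_spec validates degenerate configurations", {
  expect_error(phantom_spec(image_size_mri = 16), ">= 32")
  expect_error(phantom_spec(histology_scale = 1), ">= 2")
  expect_error(phantom_spec(noise_sd = -1), ">= 0")
  expect_error(phantom_spec(tumor_radius_frac = 0), "degenerate")
})

test_that("cohorts are bit-for-bit reproducible from the seed", {
  spec <- phantom_spec(image_size_mri = 32, histology_scale = 4, n_slices = 3,
                       seed = 7)
  a <- generate_cohort(spec, polygons = FALSE)
  b <- generate_cohort(spec, polygons = FALSE)
  expect_identical(a[[2]]$mp_slice$channels, b[[2]]$mp_slice$channels)
  expect_identical(a[[3]]$pimo_raster_aligned, b[[3]]$pimo_raster_aligned)
  expect_identical(vapply(a, `[[`, numeric(1), "true_hypoxia_fraction"),
                   vapply(b, `[[`, numeric(1), "true_hypoxia_fraction"))
})

test_that("constant-probability link gives interior hypoxia rate logistic(intercept)", {
  # with zero coefficients the per-pixel probability is constant at
  # plogis(intercept); measured on interior pixels, clear of the Gaussian
  # blur bleed at the tumor boundary, and averaged over slices because the
  # spatially correlated PIMO draw has a long correlation length
  zero <- c(t2star = 0, t2w = 0, slope = 0, ttm = 0, auc = 0)
  for (b0 in c(-0.8, 0.5)) {
    spec <- phantom_spec(n_slices = 6, noise_sd = 0,
                         hypoxia_link_coefficients = zero,
                         hypoxia_intercept = b0, seed = 13)
    coh <- generate_cohort(spec, polygons = FALSE)
    rate <- vapply(coh, function(s) {
      tum_h <- kronecker(s$mp_slice$tumor_mask, matrix(1, 8, 8)) > 0
      interior <- EBImage::erode(tum_h * 1, EBImage::makeBrush(31, "disc")) > 0
      sum(s$pimo_raster_aligned & interior) / sum(interior)
    }, numeric(1))
    expect_equal(mean(rate), plogis(b0), tolerance = 0.05)
  }
})

test_that("an extreme negative intercept produces no hypoxia at all", {
  zero <- c(t2star = 0, t2w = 0, slope = 0, ttm = 0, auc = 0)
  spec <- phantom_spec(image_size_mri = 32, histology_scale = 4, n_slices = 2,
                       hypoxia_link_coefficients = zero,
                       hypoxia_intercept = -50, seed = 14)
  coh <- generate_cohort(spec, polygons = FALSE)
  expect_equal(vapply(coh, `[[`, numeric(1), "true_hypoxia_fraction"), c(0, 0))
})

test_that("raising the intercept never decreases the cohort-mean fraction", {
  zero <- c(t2star = 0, t2w = 0, slope = 0, ttm = 0, auc = 0)
  for (seed in c(3, 4)) {
    means <- vapply(c(-2, -1, 0, 1), function(b0) {
      spec <- phantom_spec(image_size_mri = 32, histology_scale = 4,
                           n_slices = 2, hypoxia_link_coefficients = zero,
                           hypoxia_intercept = b0, seed = seed)
      mean(vapply(generate_cohort(spec, polygons = FALSE), `[[`, numeric(1),
                  "true_hypoxia_fraction"))
    }, numeric(1))
    expect_true(all(diff(means) >= 0))
  }
})

test_that("generated landmarks map exactly under the true affine and are recoverable", {
  spec <- phantom_spec(image_size_mri = 32, histology_scale = 4, n_slices = 2,
                       seed = 15)
  coh <- generate_cohort(spec, polygons = FALSE)
  for (s in coh) {
    expect_equal(apply_affine(spec$affine_true, s$landmarks$h), s$landmarks$m,
                 tolerance = 1e-12)
    fit <- fit_affine(s$landmarks$h, s$landmarks$m)
    expect_lt(fit$rms, 1e-9)
    expect_equal(fit$A, spec$affine_true$A, tolerance = 1e-9)
  }
})

test_that("slice invariants hold: fraction matches the raster, maps match the DCE stack", {
  spec <- phantom_spec(image_size_mri = 32, histology_scale = 4, n_slices = 2,
                       seed = 16)
  coh <- generate_cohort(spec, polygons = TRUE)
  s <- coh[[1]]
  tum_h <- kronecker(s$mp_slice$tumor_mask, matrix(1, 4, 4)) > 0
  expect_equal(s$true_hypoxia_fraction,
               sum(s$pimo_raster_aligned & tum_h) / sum(tum_h))
  expect_true(all(s$pimo_raster_aligned[!tum_h] == FALSE))
  # channels slope/ttm/auc are exactly the parametric maps of the DCE series
  maps <- dce_param_maps(s$dce)
  expect_equal(s$mp_slice$channels[, , "auc"], maps$auc, ignore_attr = TRUE)
  expect_equal(s$mp_slice$channels[, , "ttm"], maps$ttm, ignore_attr = TRUE)
  expect_equal(s$mp_slice$channels[, , "slope"], maps$slope, ignore_attr = TRUE)
  # the polygon encoding reproduces the histology-frame raster exactly
  expect_equal(unname(suppressWarnings(rasterize_mask(s$pimo_polygons))),
               unname(s$pimo_raster))
  # the MRI-grid fraction map is the exact block average of the aligned raster
  expect_equal(s$pimo_fraction_mri,
               resample_to_mri(s$pimo_raster_aligned, affine2d(diag(2)),
                               c(32, 32), 4))
})
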