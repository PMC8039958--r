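test_that("fit_affine recovers exact transforms from noise-free landmarks", {
  h <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  tf0 <- fit_affine(h, h)
  expect_equal(tf0$A, diag(2), tolerance = 1e-12)
  expect_equal(tf0$t, c(0, 0), tolerance = 1e-12)
  expect_lt(tf0$rms, 1e-12)
  # rotation 20 degrees, scale 1.3, shift (5, -3)
  th <- 20 * pi / 180
  A <- 1.3 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tv <- c(5, -3)
  m <- t(A %*% t(h)) + rep(tv, each = 4)
  tf <- fit_affine(h, m)
  expect_equal(tf$A, A, tolerance = 1e-9)
  expect_equal(tf$t, tv, tolerance = 1e-9)
  expect_lt(tf$rms, 1e-9)
})

test_that("degenerate landmark configurations raise errors", {
  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(2, 2))  # collinear + repeat
  m <- bad + 1
  expect_error(fit_affine(bad, m), "collinear|degenerate")
  expect_error(fit_affine(rbind(c(0, 0), c(1, 1)), rbind(c(0, 0), c(1, 1))),
               "at least 3")
})

test_that("affine recovery succeeds on 100 random non-degenerate transforms", {
  set.seed(41)
  h <- rbind(c(3, 4), c(3, 60), c(55, 58), c(50, 7))
  for (rep in 1:100) {
    tf <- random_affine()
    m <- apply_affine(tf, h)
    fit <- fit_affine(h, m)
    expect_lt(fit$rms, 1e-9)
    expect_lt(max(abs(fit$A - tf$A), abs(fit$t - tf$t)), 1e-8)
  }
})

test_that("resample_to_mri reproduces identity and block-average cases", {
  id <- affine2d(diag(2))
  m <- matrix(runif(64) < 0.5, 8, 8)
  expect_equal(resample_to_mri(m, id, c(8, 8), 1), m * 1)
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 1)
  expect_equal(resample_to_mri(chk, id, c(4, 4), 2), matrix(0.5, 4, 4))
})

test_that("resample_to_mri equals the per-pixel mapping oracle and conserves area", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 30) < 0.4, 30, 30)
    tf <- affine2d(matrix(c(cos(0.2), sin(0.2), -sin(0.2), cos(0.2)), 2, 2),
                   runif(2, -3, 3))
    got <- resample_to_mri(m, tf, c(10, 10), 3)
    expect_equal(got, oracle_resample(m, tf, c(10, 10), 3), tolerance = 1e-12)
  }
  # exact area conservation for an in-bounds area-preserving transform
  m2 <- matrix(FALSE, 40, 40); m2[10:25, 12:28] <- TRUE
  tf2 <- affine2d(diag(2), c(2, 1))
  fr <- resample_to_mri(m2, tf2, c(10, 10), 4)
  expect_equal(sum(fr) * 16, sum(m2))
  expect_warning(resample_to_mri(m2, affine2d(diag(2), c(500, 500)), c(10, 10), 4),
                 "off the MRI grid")
})

test_that("dice satisfies its defining properties and worked example", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE   # |A| = 100
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE   # |B| = 100, overlap 50
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  d <- matrix(FALSE, 20, 20); d[15:20, 15:20] <- TRUE
  expect_equal(dice(a, d), 0)
  expect_equal(dice(a, b), dice(b, a))
  set.seed(43)
  for (rep in 1:20) {
    x <- matrix(runif(100) < 0.5, 10, 10); y <- matrix(runif(100) < 0.5, 10, 10)
    dd <- suppressWarnings(dice(x, y))
    expect_gte(dd, 0); expect_lte(dd, 1)
    expect_equal(dd, suppressWarnings(dice(y, x)))
    if (dd == 1) expect_equal(x, y)
  }
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shapes differ")
  expect_warning(z <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
  expect_equal(z, 0)
})

test_that("the QC gate keeps slices at or above the cohort mean or a fixed score", {
  expect_equal(qc_gate(c(0.90, 0.92, 0.94), 1:3), c(2L, 3L))   # mean 0.92
  expect_equal(qc_gate(rep(0.8, 4), 1:4), 1:4)
  expect_equal(qc_gate(c(0.91, 0.93), 1:2, threshold = 0.92), 2L)
  expect_error(qc_gate(numeric(0)), "at least one")
})

test_that("register_slice co-registers a synthetic histology slice end to end", {
  set.seed(44)
  spec <- phantom_spec(image_size_mri = 32, histology_scale = 4, n_slices = 1,
                       seed = 44)
  s <- generate_cohort(spec, polygons = TRUE)[[1]]
  reg <- register_slice(s$pimo_polygons, s$landmarks$h, s$landmarks$m,
                        c(32, 32), 4, tissue_h = s$tissue_raster,
                        mri_mask = s$mp_slice$tumor_mask)
  expect_lt(reg$tf$rms, 1e-9)
  expect_gt(reg$dsc, 0.92)
  # the registered fraction map agrees closely with the aligned ground truth
  expect_gt(cor(as.vector(reg$pimo_fraction), as.vector(s$pimo_fraction_mri)),
            0.95)
})
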