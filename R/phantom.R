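#' Specification of the synthetic paired mpMRI + histology phantom
#'
#' Describes a cohort of synthetic tumor slices that emulate the study design
#' of paired mpMRI and PIMO-stained histology: each slice is a roughly
#' elliptical tumor with a well-perfused rim (high AUC, steep slope, short
#' TTM) and zero or more poorly perfused interior cores. Per-pixel hypoxia
#' probability is the logistic of a linear combination of the five MR
#' channels (T2* map, T2W, slope, TTM, AUC), each standardized by fixed
#' generator reference statistics, so the MR-to-hypoxia link is known exactly
#' and downstream parameter recovery is meaningful. The PIMO raster is drawn
#' at histology resolution from the smoothed probability field through a
#' spatially correlated uniform field, which keeps the marginal positive rate
#' equal to the local probability while producing contiguous habitats.
#'
#' @param image_size_mri pixels per side of the (square) MRI grid; `>= 32`.
#' @param histology_scale integer histology-to-MRI upsampling factor; `>= 2`.
#' @param n_slices number of slices in the cohort.
#' @param tumor_radius_frac tumor radius as a fraction of the image side.
#' @param rim_width_frac width of the well-perfused rim as a fraction of the
#'   tumor radius.
#' @param hypoxia_link_coefficients named numeric vector of 5 link weights in
#'   channel order `t2star, t2w, slope, ttm, auc` (applied to standardized
#'   channels).
#' @param hypoxia_intercept intercept of the logistic link.
#' @param noise_sd non-negative noise level: standard deviation of the
#'   additive DCE signal noise (baseline signal is 1); T2* and T2W receive
#'   proportional noise (see the package vignette).
#' @param affine_true an [affine2d()] applied to histology-frame data; the
#'   generated landmarks map exactly under it.
#' @param smooth_sigma Gaussian smoothing sigma (histology pixels) of the
#'   probability field and of the correlated noise used for the PIMO draw.
#' @param slices_per_subject slices grouped under one subject id.
#' @param seed integer RNG seed; cohorts are bit-for-bit reproducible given
#'   the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size_mri = 64L,
                         histology_scale = 8L,
                         n_slices = 8L,
                         tumor_radius_frac = 0.32,
                         rim_width_frac = 0.35,
                         hypoxia_link_coefficients = c(t2star = -1.0, t2w = 0.0,
                                                       slope = -1.5, ttm = 1.5,
                                                       auc = -1.5),
                         hypoxia_intercept = -0.8,
                         noise_sd = 0.02,
                         affine_true = affine2d(
                           matrix(c(cos(0.1), sin(0.1), -sin(0.1), cos(0.1)), 2, 2) * 1.04,
                           c(5, -3)),
                         smooth_sigma = 6,
                         slices_per_subject = 3L,
                         seed = 1L) {
  if (image_size_mri < 32) stop("image_size_mri must be >= 32")
  if (histology_scale < 2) stop("histology_scale must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tumor_radius_frac <= 0) stop("degenerate phantom: tumor radius must be positive")
  if (n_slices < 1) stop("n_slices must be >= 1")
  stopifnot(inherits(affine_true, "affine2d"))
  if (length(hypoxia_link_coefficients) != 5L)
    stop("hypoxia_link_coefficients must have 5 elements (one per MR channel)")
  structure(list(image_size_mri = as.integer(image_size_mri),
                 histology_scale = as.integer(histology_scale),
                 n_slices = as.integer(n_slices),
                 tumor_radius_frac = tumor_radius_frac,
                 rim_width_frac = rim_width_frac,
                 hypoxia_link_coefficients = hypoxia_link_coefficients,
                 hypoxia_intercept = hypoxia_intercept,
                 noise_sd = noise_sd,
                 affine_true = affine_true,
                 smooth_sigma = smooth_sigma,
                 slices_per_subject = as.integer(slices_per_subject),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

.gblur <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

# smooth unit-variance random field on an nr x nc grid
.smooth_field <- function(nr, nc, sigma) {
  f <- .gblur(matrix(rnorm(nr * nc), nr, nc), sigma)
  f / sd(f)
}

#' Channel order used throughout the package
#' @export
mp_channels <- c("t2star", "t2w", "slope", "ttm", "auc")

# DCE acquisition grid emulating ~70 s temporal resolution, 22 repetitions,
# contrast injected after the first repetition
.dce_times <- function() 70 * (0:21)

# Noise-free DCE curve for perfusion level p in [0, 1]: gamma-variate uptake
# whose amplitude rises and whose onset delay and time-to-peak shrink with
# better perfusion.
.dce_curve <- function(p, times) {
  t0 <- 70 + 250 * (1 - p)                 # onset: after first repetition
  tp <- t0 + 150 + 450 * (1 - p)           # time of peak
  amp <- 0.3 + 1.7 * p
  u <- (times - t0) / (tp - t0)
  gv <- ifelse(u > 0, u^2 * exp(2 * (1 - u)), 0)
  1 + amp * gv
}

# Reference (noise-free) channel statistics of the generator, evaluated on a
# uniform grid of perfusion levels; used to standardize channels in the link.
.channel_refs <- function() {
  times <- .dce_times()
  ps <- seq(0, 1, by = 0.01)
  curves <- t(vapply(ps, .dce_curve, numeric(length(times)), times = times))
  auc <- rowSums(curves)
  imax <- max.col(curves, ties.method = "first")
  ttm <- times[imax] - times[1]
  slope <- (curves[cbind(seq_along(ps), imax)] - curves[, 1]) / pmax(ttm, 1)
  t2star <- 20 + 14 * ps
  t2w <- 60 + 8 * 0                        # centered smooth field, see generator
  m <- cbind(t2star = t2star, t2w = rep(60, length(ps)), slope = slope,
             ttm = ttm, auc = auc)
  list(mean = colMeans(m),
       sd = pmax(apply(m, 2, sd), c(1e-6, 8, 1e-6, 1e-6, 1e-6)))
}

.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Generate one slice pair; assumes the RNG state is already seeded.
.generate_slice <- function(spec, slice_id, subject_id, refs, polygons) {
  L <- spec$image_size_mri
  s <- spec$histology_scale
  R <- spec$tumor_radius_frac * L
  times <- .dce_times()

  # tumor geometry: rotated ellipse
  ctr <- L / 2 + runif(2, -2, 2)
  ax <- R * runif(2, 0.85, 1.15)
  th <- runif(1, 0, pi)
  gr <- row(matrix(0, L, L)) - 1 - ctr[1]
  gc <- col(matrix(0, L, L)) - 1 - ctr[2]
  u <- (gr * cos(th) + gc * sin(th)) / ax[1]
  v <- (-gr * sin(th) + gc * cos(th)) / ax[2]
  rho <- sqrt(u^2 + v^2)
  tumor <- rho <= 1

  # poorly perfused cores: 0-3 Gaussian depressions inside the tumor
  k <- sample(0:3, 1, prob = c(0.10, 0.25, 0.35, 0.30))
  D <- matrix(0, L, L)
  if (k > 0) {
    for (i in seq_len(k)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      cc <- ctr + rad * mean(ax) * c(cos(ang), sin(ang))
      w <- runif(1, 0.25, 0.55) * R
      amp <- runif(1, 0.70, 1)
      d2 <- (row(D) - 1 - cc[1])^2 + (col(D) - 1 - cc[2])^2
      D <- D + amp * exp(-d2 / (2 * w^2))
    }
    D <- pmin(D, 1)
  }
  rim <- .smoothstep((rho - (1 - spec$rim_width_frac)) / spec$rim_width_frac)
  P <- (1 - D)
  P <- P + (1 - P) * rim
  P <- pmin(pmax(P, 0.05), 1)

  # DCE signal stack + parametric maps
  sig <- array(0, dim = c(L, L, length(times)))
  base_curves <- vapply(as.vector(P), .dce_curve, numeric(length(times)),
                        times = times)               # T x (L*L)
  sig[] <- t(base_curves)
  if (spec$noise_sd > 0)
    sig <- sig + array(rnorm(length(sig), sd = spec$noise_sd), dim = dim(sig))
  dce <- dce_series(sig, times, baseline_index = 1L)
  maps <- dce_param_maps(dce)

  # relaxometry / structural channels
  t2star <- 20 + 14 * P + 1.5 * .smooth_field(L, L, 2) +
    (if (spec$noise_sd > 0) matrix(rnorm(L * L, sd = 10 * spec$noise_sd), L, L) else 0)
  t2w <- 60 + 8 * .smooth_field(L, L, 3) +
    (if (spec$noise_sd > 0) matrix(rnorm(L * L, sd = 20 * spec$noise_sd), L, L) else 0)

  channels <- array(0, dim = c(L, L, 5), dimnames = list(NULL, NULL, mp_channels))
  channels[, , "t2star"] <- t2star
  channels[, , "t2w"] <- t2w
  channels[, , "slope"] <- maps$slope
  channels[, , "ttm"] <- maps$ttm
  channels[, , "auc"] <- maps$auc

  # hypoxia probability: logistic link on standardized channels
  beta <- spec$hypoxia_link_coefficients
  lin <- matrix(spec$hypoxia_intercept, L, L)
  for (i in seq_along(mp_channels)) {
    z <- (channels[, , mp_channels[i]] - refs$mean[mp_channels[i]]) /
      refs$sd[mp_channels[i]]
    lin <- lin + beta[i] * z
  }
  prob <- plogis(lin)
  prob[!tumor] <- 0

  # histology-resolution PIMO draw (MRI-aligned frame)
  Hh <- L * s
  tumor_h <- kronecker(tumor, matrix(TRUE, s, s))
  prob_h <- .gblur(kronecker(prob, matrix(1, s, s)), spec$smooth_sigma)
  prob_h <- pmin(pmax(prob_h, 0), 1)
  un <- .gblur(matrix(rnorm(Hh * Hh), Hh, Hh), spec$smooth_sigma)
  U <- matrix((rank(un) - 0.5) / length(un), Hh, Hh)
  raster_aligned <- (U < prob_h) & tumor_h
  true_fraction <- sum(raster_aligned) / sum(tumor_h)

  # histology frame: inverse-warp the aligned raster through affine_true
  tf <- spec$affine_true
  idx_h <- cbind(as.vector(row(raster_aligned)) - 1,
                 as.vector(col(raster_aligned)) - 1)
  mapped <- apply_affine(tf, idx_h)
  mr <- round(mapped[, 1]) + 1
  mc <- round(mapped[, 2]) + 1
  ok <- mr >= 1 & mr <= Hh & mc >= 1 & mc <= Hh
  raster_hist <- matrix(FALSE, Hh, Hh)
  tissue_hist <- matrix(FALSE, Hh, Hh)
  raster_hist[ok] <- raster_aligned[cbind(mr[ok], mc[ok])]
  tissue_hist[ok] <- tumor_h[cbind(mr[ok], mc[ok])]

  # landmarks: four corners of a box around the tumor, exact under affine_true
  box <- 0.30 * Hh
  lm_h <- rbind(c(box, box), c(box, Hh - box), c(Hh - box, Hh - box), c(Hh - box, box))
  lm_m <- apply_affine(tf, lm_h)

  pimo_fraction_mri <- resample_to_mri(raster_aligned, affine2d(diag(2)),
                                       c(L, L), s)

  structure(list(
    mp_slice = list(channels = channels, tumor_mask = tumor,
                    slice_id = slice_id, subject_id = subject_id),
    dce = dce,
    perfusion = P,
    hypoxia_prob = prob,
    pimo_raster = raster_hist,
    tissue_raster = tissue_hist,
    pimo_raster_aligned = raster_aligned,
    pimo_fraction_mri = pimo_fraction_mri,
    pimo_mask_mri = pimo_fraction_mri >= 0.5,
    pimo_polygons = if (polygons) polygonize(raster_hist) else NULL,
    landmarks = list(h = lm_h, m = lm_m),
    true_hypoxia_fraction = true_fraction,
    slice_id = slice_id, subject_id = subject_id
  ), class = "slice_pair")
}

#' Generate a cohort of synthetic slice pairs
#'
#' Draws `spec$n_slices` paired mpMRI + histology slices. Each slice carries
#' the five-channel MR stack, the raw DCE series, the histology-frame PIMO
#' raster (warped by `affine_true`) with its polygon encoding and exact
#' landmark pairs, the MRI-aligned raster and its block-averaged fraction map
#' on the MRI grid, and the true hypoxia fraction (positive share of the
#' aligned raster inside the tumor).
#'
#' @param spec a [phantom_spec()].
#' @param polygons logical: also polygonize each histology raster (exact but
#'   costly at large histology sizes; disable for large training cohorts
#'   where the polygon encoding is not needed).
#' @return list of `slice_pair` objects (class `habitat_cohort`).
#' @export
generate_cohort <- function(spec, polygons = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  refs <- .channel_refs()
  cohort <- lapply(seq_len(spec$n_slices), function(i) {
    .generate_slice(spec, slice_id = i,
                    subject_id = ((i - 1L) %/% spec$slices_per_subject) + 1L,
                    refs = refs, polygons = polygons)
  })
  attr(cohort, "spec") <- spec
  class(cohort) <- "habitat_cohort"
  cohort
}
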