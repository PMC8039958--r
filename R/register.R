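#' 2D affine transform
#'
#' Six-parameter planar transform `y = A x + t` mapping histology-frame
#' `(row, col)` coordinates to MRI-frame coordinates (both 0-based, at
#' histology resolution).
#'
#' @param A numeric 2x2 linear part; `|det(A)|` must exceed 1e-12.
#' @param t numeric length-2 translation.
#' @param rms optional residual RMS from a landmark fit.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(A, t = c(0, 0), rms = NA_real_) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) <= 1e-12) stop("affine linear part is singular")
  structure(list(A = A, t = as.numeric(t), rms = rms), class = "affine2d")
}

#' Apply an affine transform to points
#'
#' @param tf an [affine2d()].
#' @param pts numeric `n x 2` matrix of `(row, col)` coordinates.
#' @return transformed `n x 2` matrix.
#' @export
apply_affine <- function(tf, pts) {
  stopifnot(inherits(tf, "affine2d"))
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(tf$A), 2, tf$t, `+`)
}

#' Fit a 2D affine transform from paired landmarks
#'
#' Least-squares estimate of the 6-parameter affine minimizing
#' `sum ||A h_i + t - m_i||^2` over the landmark pairs. With the standard
#' four manually placed landmarks the system is over-determined (8 equations,
#' 6 unknowns); the residual RMS (per landmark) is returned with the fit.
#'
#' @param landmarks_h numeric `n x 2` matrix of histology-frame `(row, col)`
#'   points, `n >= 3`, not collinear.
#' @param landmarks_m numeric `n x 2` matrix of corresponding MRI-frame points.
#' @return an [affine2d()] with its `rms` field set.
#' @export
fit_affine <- function(landmarks_h, landmarks_m) {
  h <- matrix(as.numeric(landmarks_h), ncol = 2)
  m <- matrix(as.numeric(landmarks_m), ncol = 2)
  if (nrow(h) < 3L || nrow(h) != nrow(m))
    stop("need at least 3 paired landmarks")
  X <- cbind(h, 1)
  if (qr(X)$rank < 3L)
    stop("degenerate landmarks: source points are collinear or coincident")
  beta <- qr.solve(X, m)                   # 3 x 2
  A <- t(beta[1:2, , drop = FALSE])
  tvec <- beta[3, ]
  res <- X %*% beta - m
  rms <- sqrt(mean(rowSums(res^2)))
  affine2d(A, tvec, rms = rms)
}

#' Resample a histology-resolution mask onto the MRI grid
#'
#' Maps every positive histology-frame pixel through the affine transform
#' into the MRI frame (at histology resolution) and accumulates, per MRI
#' pixel, the fraction of its `scale x scale` footprint that is covered by
#' positive pixels. The result is a continuous PIMO-positive fraction map in
#' `[0, 1]` on the MRI grid - the substrate for CNN patch labels.
#'
#' @param mask_h logical matrix at histology resolution (histology frame).
#' @param tf an [affine2d()] mapping histology to MRI-frame coordinates at
#'   histology resolution; use `affine2d(diag(2))` for already aligned masks.
#' @param mri_shape integer `c(rows, cols)` of the MRI grid.
#' @param scale integer `>= 1`: histology pixels per MRI pixel side.
#' @return numeric matrix `mri_shape` with values in `[0, 1]`.
#' @export
resample_to_mri <- function(mask_h, tf, mri_shape, scale) {
  stopifnot(inherits(tf, "affine2d"), scale >= 1)
  scale <- as.integer(scale)
  out <- matrix(0, mri_shape[1], mri_shape[2])
  idx <- which(mask_h > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  mapped <- apply_affine(tf, idx - 1)      # 0-based centers
  # MRI pixel m covers histology-frame coords [m*scale - 0.5, (m+1)*scale - 0.5)
  mr <- floor((mapped[, 1] + 0.5) / scale)
  mc <- floor((mapped[, 2] + 0.5) / scale)
  keep <- mr >= 0 & mr < mri_shape[1] & mc >= 0 & mc < mri_shape[2]
  if (!any(keep)) {
    warning("transform maps all positive pixels off the MRI grid", call. = FALSE)
    return(out)
  }
  lin <- mr[keep] + 1 + mc[keep] * mri_shape[1]
  counts <- tabulate(lin, nbins = mri_shape[1] * mri_shape[2])
  out[] <- counts / scale^2
  out
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; equals 1 only for identical nonempty
#' masks. Two empty masks give 0 with a warning (undefined overlap).
#'
#' @param mask_a,mask_b logical matrices of identical shape.
#' @return numeric scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- mask_a > 0; b <- mask_b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks are empty; Dice undefined, returning 0", call. = FALSE)
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Quality-control gate on registration similarity
#'
#' Keeps slices whose Dice similarity between the MRI mask and the
#' transformed histology mask reaches the cohort threshold. The default
#' threshold is the cohort mean DSC, the rule used to admit slices into model
#' construction; an explicit numeric threshold (e.g. 0.92) can be given.
#'
#' @param dsc numeric vector of Dice scores.
#' @param slice_ids identifiers parallel to `dsc` (default `seq_along(dsc)`).
#' @param threshold `"mean"` or a numeric cutoff.
#' @return the slice ids passing the gate (`dsc >= threshold`).
#' @export
qc_gate <- function(dsc, slice_ids = seq_along(dsc), threshold = "mean") {
  if (length(dsc) < 1L) stop("at least one Dice pair is required")
  thr <- if (identical(threshold, "mean")) mean(dsc) else as.numeric(threshold)
  slice_ids[dsc >= thr]
}

#' Register one histology slice onto the MRI grid
#'
#' Convenience wrapper over the co-registration stages: rasterize the polygon
#' mask, fit the landmark affine, resample to the MRI grid, and (optionally)
#' score tissue-outline overlap with Dice for QC.
#'
#' @param polygons a [polygon_mask()] of PIMO-positive regions.
#' @param landmarks_h,landmarks_m paired landmark matrices (see [fit_affine()]).
#' @param mri_shape integer `c(rows, cols)`.
#' @param scale histology pixels per MRI pixel side.
#' @param tissue_h optional histology-frame tissue mask; when given together
#'   with `mri_mask`, the two outlines are compared with [dice()].
#' @param mri_mask optional MRI-frame tumor mask for QC.
#' @return list with `tf`, `pimo_fraction` (MRI-grid fraction map), and `dsc`
#'   (NA when QC inputs are absent).
#' @export
register_slice <- function(polygons, landmarks_h, landmarks_m, mri_shape,
                           scale, tissue_h = NULL, mri_mask = NULL) {
  raster <- rasterize_mask(polygons)
  tf <- fit_affine(landmarks_h, landmarks_m)
  fr <- resample_to_mri(raster, tf, mri_shape, scale)
  dsc <- NA_real_
  if (!is.null(tissue_h) && !is.null(mri_mask)) {
    tis <- resample_to_mri(tissue_h, tf, mri_shape, scale)
    dsc <- dice(tis >= 0.5, mri_mask)
  }
  list(tf = tf, pimo_fraction = fr, dsc = dsc)
}
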