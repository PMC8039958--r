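#' Grayscale stain-intensity image
#'
#' Histology staining converted to an 8-bit stain-intensity scale: 0 means no
#' staining (white) and 255 maximum staining (black). An optional tissue mask
#' separates tissue from slide background; thresholding and positive-fraction
#' statistics are restricted to tissue pixels.
#'
#' @param gray integer matrix with values in `[0, 255]`.
#' @param tissue_mask logical matrix of the same shape (default: all pixels).
#' @return An object of class `stain_image`.
#' @export
stain_image <- function(gray, tissue_mask = NULL) {
  gray <- round(gray)
  if (any(gray < 0 | gray > 255, na.rm = TRUE))
    stop("stain intensities must lie in [0, 255]")
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(gray), ncol(gray))
  tissue_mask <- tissue_mask & !is.na(gray)
  if (!all(dim(tissue_mask) == dim(gray)))
    stop("tissue_mask shape must match the image")
  if (!any(tissue_mask)) stop("tissue mask is empty")
  structure(list(gray = gray, tissue_mask = tissue_mask), class = "stain_image")
}

#' Otsu threshold of a stain image
#'
#' Returns the 8-bit level maximizing the between-class variance of the
#' 256-bin histogram of tissue pixels. Pixels at or above the returned level
#' are the "positive" (stained) class under [binarize_stain()]'s convention.
#' Ties are broken toward the lowest level.
#'
#' @param img a [stain_image()].
#' @return integer threshold in `[1, 255]`.
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "stain_image"))
  g <- img$gray[img$tissue_mask]
  if (length(unique(g)) < 2L)
    stop("degenerate input: tissue has a single gray level; Otsu threshold is undefined")
  h <- tabulate(g + 1L, nbins = 256L)          # counts for levels 0..255
  n <- sum(h)
  lev <- 0:255
  csum <- cumsum(h)                            # pixels with level < t for t = 1..256
  cmean <- cumsum(h * lev)
  mu <- cmean[256] / n
  # candidate thresholds t = 1..255: class0 = {g < t}, class1 = {g >= t}
  n0 <- csum[1:255]
  n1 <- n - n0
  m0sum <- cmean[1:255]
  valid <- n0 > 0 & n1 > 0
  sb <- rep(-Inf, 255)
  m0 <- m0sum[valid] / n0[valid]
  m1 <- (cmean[256] - m0sum[valid]) / n1[valid]
  sb[valid] <- (n0[valid] / n) * (n1[valid] / n) * (m0 - m1)^2
  which.max(sb)                                # lowest maximizer; equals t
}

#' Binarize a stain image into a PIMO-positive mask
#'
#' Tissue pixels with stain intensity greater than or equal to the threshold
#' are positive (darker stain = more PIMO adduct). The positive fraction is
#' computed over tissue area.
#'
#' @param img a [stain_image()].
#' @param threshold integer in `[0, 255]` (a per-slice Otsu threshold or a
#'   cohort-wide global threshold, e.g. 92 for PDX or 86 for RIF-1 slides).
#' @return An object of class `pimo_mask` with fields `positive`,
#'   `threshold_used` and `positive_fraction`.
#' @export
binarize_stain <- function(img, threshold) {
  stopifnot(inherits(img, "stain_image"))
  threshold <- as.integer(threshold)
  if (threshold < 0L || threshold > 255L) stop("threshold must lie in [0, 255]")
  pos <- img$tissue_mask & !is.na(img$gray) & img$gray >= threshold
  structure(list(positive = pos,
                 threshold_used = threshold,
                 positive_fraction = sum(pos) / sum(img$tissue_mask)),
            class = "pimo_mask")
}

#' Average PIMO-positive fraction across the slices of one tumor
#'
#' @param masks list of [binarize_stain()] results (or a numeric vector of
#'   per-slice positive fractions).
#' @return the unweighted mean positive fraction.
#' @export
per_tumor_summary <- function(masks) {
  if (length(masks) == 0L) stop("at least one slice mask is required")
  fr <- if (is.numeric(masks)) masks else
    vapply(masks, function(m) m$positive_fraction, numeric(1))
  mean(fr)
}

#' Read a grayscale stain image from TIFF or PNG
#'
#' The file is expected to already encode stain intensity (0 = white / no
#' staining, 255 = black / maximum staining); values stored on `[0, 1]` are
#' rescaled to `[0, 255]`.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param tissue_mask optional logical matrix.
#' @return a [stain_image()].
#' @export
read_stain_image <- function(path, tissue_mask = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (max(img, na.rm = TRUE) <= 1) img <- img * 255
  stain_image(round(img), tissue_mask)
}
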