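#' Split slices into training, validation and test cohorts
#'
#' Random slice-level (not pixel-level) partition at the stated ratios,
#' reproducible by seed. Counts follow `n_val = round(r_val * n)`,
#' `n_test = round(r_test * n)`, with the training set taking the remainder.
#' When `subjects` is supplied the partition is done at the subject level
#' with the same rounding, and every slice follows its subject, so no
#' subject straddles two cohorts.
#'
#' @param slice_ids vector of slice identifiers.
#' @param ratios numeric length-3 `(train, val, test)` summing to 1;
#'   default `c(0.6, 0.1, 0.3)`.
#' @param seed integer seed for the permutation.
#' @param subjects optional vector of subject ids parallel to `slice_ids`.
#' @return list with elements `train`, `val`, `test` (slice id vectors).
#' @export
split_slices <- function(slice_ids, ratios = c(0.6, 0.1, 0.3), seed = 1L,
                         subjects = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  n_all <- length(slice_ids)
  if (n_all < 3L) stop("need at least 3 slices to split")
  units <- if (is.null(subjects)) slice_ids else unique(subjects)
  n <- length(units)
  n_val <- round(ratios[2] * n)
  n_test <- round(ratios[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L)
    stop("a partition is empty after rounding; use more slices")
  set.seed(seed)
  perm <- sample(units)
  grp <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  if (is.null(subjects)) return(grp)
  lapply(grp, function(u) slice_ids[subjects %in% u])
}

# raw (not standardized) patch extraction; internal
.extract_raw <- function(slice, pimo_fraction, window, label_cut,
                         max_patches = NULL) {
  ms <- if (inherits(slice, "slice_pair")) slice$mp_slice else slice
  ch <- ms$channels
  H <- dim(ch)[1]; W <- dim(ch)[2]
  if (window %% 2L != 1L) stop("window must be odd")
  if (window > H || window > W) stop("window larger than the image")
  if (!any(ms$tumor_mask)) stop("tumor mask is empty")
  if (!all(dim(pimo_fraction) == c(H, W)))
    stop("pimo_fraction must be aligned to the slice grid")
  centers <- which(ms$tumor_mask, arr.ind = TRUE)
  if (!is.null(max_patches) && nrow(centers) > max_patches)
    centers <- centers[sort(sample.int(nrow(centers), max_patches)), , drop = FALSE]
  patches <- gather_patches(ch, centers[, 1], centers[, 2], as.integer(window))
  pf <- array(pimo_fraction, dim = c(H, W, 1))
  wins <- gather_patches(pf, centers[, 1], centers[, 2], as.integer(window))
  labmean <- colMeans(matrix(wins, window * window, nrow(centers)))
  list(patches = patches,
       labels = as.integer(labmean >= label_cut),
       window_mean = labmean,
       coords = data.frame(slice_id = ms$slice_id,
                           row = centers[, 1], col = centers[, 2]))
}

.apply_stats <- function(patches, stats) {
  for (c in seq_along(stats$mean))
    patches[, , c, ] <- (patches[, , c, ] - stats$mean[c]) / stats$sd[c]
  patches
}

.patch_stats <- function(patches) {
  nc <- dim(patches)[3]
  m <- s <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- patches[, , c, ]
    m[c] <- mean(v)
    s[c] <- max(sd(v), 1e-8)
  }
  if (nc == length(mp_channels)) names(m) <- names(s) <- mp_channels
  list(mean = m, sd = s)
}

#' Extract labeled multiparametric patches from one slice
#'
#' For every pixel inside the tumor mask, a `window x window` sliding window
#' centered on the pixel cuts a five-channel patch from the MR stack
#' (reflection padding at image edges). The patch label is 1 when the mean of
#' the PIMO-positive fraction map over the window reaches `label_cut`.
#' Channels are z-scored: with the training-set statistics when `stats` is
#' given, otherwise with statistics computed from this slice's patches (which
#' are then stored in the result).
#'
#' @param slice a `slice_pair` or an `mp_slice` list (`channels`,
#'   `tumor_mask`, `slice_id`).
#' @param pimo_fraction numeric matrix on the slice grid, values in `[0, 1]`.
#' @param window odd window size in pixels (default 15).
#' @param label_cut threshold on the window-mean PIMO fraction (default 0.5).
#' @param stats optional list `(mean, sd)` per channel from the training set.
#' @param max_patches optional cap on the number of patches (random
#'   subsample of tumor pixels; seed the RNG for reproducibility).
#' @return An object of class `patch_dataset`: `patches`
#'   `(window, window, 5, N)`, `labels` (0/1), `coords`, `channel_stats`.
#' @export
extract_patches <- function(slice, pimo_fraction, window = 15L,
                            label_cut = 0.5, stats = NULL,
                            max_patches = NULL) {
  raw <- .extract_raw(slice, pimo_fraction, as.integer(window), label_cut,
                      max_patches)
  if (is.null(stats)) stats <- .patch_stats(raw$patches)
  structure(list(patches = .apply_stats(raw$patches, stats),
                 labels = raw$labels,
                 window_mean = raw$window_mean,
                 coords = raw$coords,
                 channel_stats = stats,
                 window = as.integer(window),
                 label_cut = label_cut),
            class = "patch_dataset")
}

#' Build a patch dataset over several slices
#'
#' Extracts patches from every requested slice of a cohort, pools them, and
#' z-scores each channel with statistics computed over all pooled patches
#' (or with externally supplied training statistics, as required for
#' validation/test data).
#'
#' @param cohort a `habitat_cohort` (list of `slice_pair`s).
#' @param ids slice ids to include.
#' @param stats optional training-set channel statistics.
#' @param max_patches_per_slice optional per-slice cap (random subsample).
#' @inheritParams extract_patches
#' @return a `patch_dataset`.
#' @export
build_patch_dataset <- function(cohort, ids, window = 15L, label_cut = 0.5,
                                stats = NULL, max_patches_per_slice = NULL) {
  sl <- Filter(function(s) s$slice_id %in% ids, cohort)
  if (length(sl) == 0L) stop("no slices match `ids`")
  raws <- lapply(sl, function(s)
    .extract_raw(s, s$pimo_fraction_mri, as.integer(window), label_cut,
                 max_patches_per_slice))
  ns <- vapply(raws, function(r) dim(r$patches)[4], integer(1))
  d <- dim(raws[[1]]$patches)
  patches <- array(0, dim = c(d[1], d[2], d[3], sum(ns)))
  at <- 0L
  for (r in raws) {
    n <- dim(r$patches)[4]
    patches[, , , at + seq_len(n)] <- r$patches
    at <- at + n
  }
  labels <- unlist(lapply(raws, `[[`, "labels"), use.names = FALSE)
  wm <- unlist(lapply(raws, `[[`, "window_mean"), use.names = FALSE)
  coords <- do.call(rbind, lapply(raws, `[[`, "coords"))
  if (is.null(stats)) stats <- .patch_stats(patches)
  structure(list(patches = .apply_stats(patches, stats),
                 labels = labels, window_mean = wm, coords = coords,
                 channel_stats = stats, window = as.integer(window),
                 label_cut = label_cut),
            class = "patch_dataset")
}
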