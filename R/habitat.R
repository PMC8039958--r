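#' Predict a per-pixel hypoxia probability map for one slice
#'
#' Extracts the 15x15 five-channel patch around every tumor pixel, z-scores
#' it with the training channel statistics stored in the model, and runs the
#' classifier. The prediction uses the MR channels only - no PIMO input of
#' any kind - and the habitat is reconstructed from the per-pixel
#' probabilities via each patch's center coordinates.
#'
#' @param model a trained [train_hypoxia_cnn()] model.
#' @param slice a `slice_pair` or `mp_slice` list; channel order must match
#'   the model (checked against channel names when available).
#' @param cutoff probability cutoff used to binarize the habitat; defaults
#'   to the model's stored cutoff (see [select_cutoff()]).
#' @return An object of class `hypoxia_map`: `probability` (0 outside the
#'   tumor), `habitat`, `cutoff`, `hypoxia_fraction`, `slice_id`.
#' @export
predict_map <- function(model, slice, cutoff = NULL) {
  stopifnot(inherits(model, "hypoxia_cnn"))
  ms <- if (inherits(slice, "slice_pair")) slice$mp_slice else slice
  if (!any(ms$tumor_mask)) stop("tumor mask is empty")
  cn <- dimnames(ms$channels)[[3]]
  if (!is.null(cn) && !identical(cn, model$channel_names))
    stop("channel order mismatch: expected ",
         paste(model$channel_names, collapse = ", "))
  if (is.null(cutoff)) cutoff <- model$cutoff
  H <- dim(ms$channels)[1]; W <- dim(ms$channels)[2]
  ds <- extract_patches(ms, matrix(0, H, W), window = model$window,
                        label_cut = model$label_cut,
                        stats = model$channel_stats)
  prob_vec <- .predict_prob(model, ds$patches)
  probability <- matrix(0, H, W)
  probability[cbind(ds$coords$row, ds$coords$col)] <- prob_vec
  habitat <- if (is.na(cutoff)) NULL else (probability >= cutoff) & ms$tumor_mask
  structure(list(probability = probability,
                 habitat = habitat,
                 cutoff = cutoff,
                 hypoxia_fraction = if (is.null(habitat)) NA_real_ else
                   sum(habitat) / sum(ms$tumor_mask),
                 tumor_mask = ms$tumor_mask,
                 slice_id = ms$slice_id),
            class = "hypoxia_map")
}

# Dice of (probability >= cutoff) within the tumor against a binary PIMO mask
.dsc_at <- function(map, pimo, cutoff) {
  pred <- (map$probability >= cutoff) & map$tumor_mask
  suppressWarnings(dice(pred, pimo & map$tumor_mask))
}

#' Select the probability cutoff maximizing Dice on training samples
#'
#' For each training sample, scans a regular probability grid for the cutoff
#' giving the largest Dice similarity between the binarized probability map
#' and the binary PIMO mask (ties resolved toward the lowest cutoff), then
#' returns the average of the per-sample optima - the deployed binarization
#' cutoff of the predicted hypoxia probability.
#'
#' @param maps list of [predict_map()] results for training slices.
#' @param pimo_masks parallel list of binary PIMO masks on the MRI grid.
#' @param grid candidate cutoffs (default `seq(0.01, 1, 0.01)`).
#' @return the mean optimal cutoff (numeric scalar).
#' @export
select_cutoff <- function(maps, pimo_masks, grid = seq(0.01, 1, by = 0.01)) {
  if (length(maps) == 0L || length(maps) != length(pimo_masks))
    stop("`maps` and `pimo_masks` must be nonempty and parallel")
  optima <- vapply(seq_along(maps), function(i) {
    dscs <- vapply(grid, function(cc) .dsc_at(maps[[i]], pimo_masks[[i]], cc),
                   numeric(1))
    grid[which.max(dscs)]
  }, numeric(1))
  mean(optima)
}

#' Per-slice hypoxia fractions at a cutoff
#'
#' @param maps list of [predict_map()] results.
#' @param cutoff probability cutoff.
#' @return numeric vector of predicted hypoxia fractions.
#' @export
predicted_fractions <- function(maps, cutoff) {
  vapply(maps, function(m) {
    hab <- (m$probability >= cutoff) & m$tumor_mask
    sum(hab) / sum(m$tumor_mask)
  }, numeric(1))
}
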