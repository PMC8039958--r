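#' Run the full hypoxia-mapping pipeline on a synthetic cohort
#'
#' Slice-level 60/10/30 split, patch extraction with window-mean labels,
#' CNN training under the published schedule, Dice-optimal probability
#' cutoff selection on the training slices, blind prediction of per-pixel
#' hypoxia probability on every slice, and per-cohort Pearson correlation of
#' true versus predicted per-slice hypoxia fraction.
#'
#' @param cohort a [generate_cohort()] result.
#' @param cfg a [train_config()].
#' @param ratios slice-level split ratios `(train, val, test)`.
#' @param split_seed seed for the slice split.
#' @param window sliding-window size (pixels).
#' @param label_cut binarization threshold on the window-mean PIMO fraction.
#' @param max_patches_per_slice optional per-slice cap on training patches.
#' @param map_cohorts cohorts for which probability maps and fraction pairs
#'   are produced (training slices are always mapped, as the cutoff is
#'   selected on them).
#' @return list with `model`, `cutoff`, `split`, `pairs` (per-slice fraction
#'   table), and `correlations` (per-cohort Pearson summary; cohorts with
#'   fewer than 3 mapped slices are omitted).
#' @export
run_hypoxia_pipeline <- function(cohort, cfg = train_config(),
                                 ratios = c(0.6, 0.1, 0.3), split_seed = 1L,
                                 window = 15L, label_cut = 0.5,
                                 max_patches_per_slice = NULL,
                                 map_cohorts = c("train", "val", "test")) {
  ids <- vapply(cohort, `[[`, integer(1), "slice_id")
  split <- split_slices(ids, ratios = ratios, seed = split_seed)

  train_ds <- build_patch_dataset(cohort, split$train, window = window,
                                  label_cut = label_cut,
                                  max_patches_per_slice = max_patches_per_slice)
  val_ds <- build_patch_dataset(cohort, split$val, window = window,
                                label_cut = label_cut,
                                stats = train_ds$channel_stats,
                                max_patches_per_slice = max_patches_per_slice)
  model <- train_hypoxia_cnn(train_ds, val_ds, cfg)

  cohort_of <- function(id) {
    if (id %in% split$train) "train" else if (id %in% split$val) "val" else "test"
  }
  want <- vapply(ids, function(id) cohort_of(id) %in% map_cohorts, logical(1))
  maps <- vector("list", length(cohort))
  for (i in seq_along(cohort))
    if (want[i] || ids[i] %in% split$train)
      maps[[i]] <- predict_map(model, cohort[[i]])

  # Dice-optimal probability cutoff on the training slices
  itrain <- which(ids %in% split$train)
  model$cutoff <- select_cutoff(maps[itrain],
                                lapply(cohort[itrain], `[[`, "pimo_mask_mri"))

  keep <- which(want)
  pairs <- data.frame(
    slice_id = ids[keep],
    cohort = vapply(ids[keep], cohort_of, character(1)),
    true_fraction = vapply(cohort[keep], `[[`, numeric(1),
                           "true_hypoxia_fraction"),
    predicted_fraction = predicted_fractions(maps[keep], model$cutoff))
  big <- names(which(table(pairs$cohort) >= 3))
  list(model = model, cutoff = model$cutoff, split = split, pairs = pairs,
       maps = maps,
       correlations = pearson_by_cohort(pairs[pairs$cohort %in% big, ]))
}
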