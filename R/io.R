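# On-disk interchange: NIfTI images, the polygon-mask JSON schema shared by
# the generator and the co-registration stage, and landmark/truth CSVs.

#' Read a DCE series from NIfTI plus a JSON sidecar
#'
#' The image holds the dynamic stack (rows, cols, time; a singleton third
#' dimension is dropped). The sidecar carries acquisition timing:
#' `{"times": [...seconds...], "baseline_index": <1-based int>}` - timing is
#' always taken from the sidecar, never assumed.
#'
#' @param image_path NIfTI file with the signal stack.
#' @param sidecar_path JSON file with `times` and `baseline_index`.
#' @return a [dce_series()].
#' @export
read_dce_series <- function(image_path, sidecar_path) {
  img <- RNifti::readNifti(image_path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[3] == 1L) a <- a[, , 1, ]
  if (length(dim(a)) != 3L) stop("expected a (rows, cols, time) stack")
  side <- jsonlite::fromJSON(sidecar_path)
  dce_series(a, side$times, side$baseline_index)
}

#' Write DCE parametric maps as NIfTI
#'
#' @param maps a [dce_param_maps()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_param_maps <- function(maps, dir, prefix = "dce") {
  stopifnot(inherits(maps, "param_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("auc", "slope", "ttm"), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(maps[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write / read the polygon-mask JSON schema
#'
#' Schema: an object with `canvas_shape` (rows, cols) and `polygons`, a list
#' of polygons in drawing order, each a list of `[row, col]` vertices
#' (0-based pixel coordinates); polygon order carries the positive/hole
#' nesting semantics.
#'
#' @param poly a [polygon_mask()].
#' @param path output JSON path.
#' @return `write_polygon_json` returns the path invisibly;
#'   `read_polygon_json` returns a [polygon_mask()].
#' @export
write_polygon_json <- function(poly, path) {
  stopifnot(inherits(poly, "polygon_mask"))
  obj <- list(canvas_shape = poly$canvas_shape,
              polygons = lapply(poly$polygons, function(p) unname(as.matrix(p))))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_polygon_json
#' @export
read_polygon_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  polys <- obj$polygons
  if (is.null(polys) || length(polys) == 0) polys <- list()
  # jsonlite collapses same-shaped polygons into one 3D array
  if (is.array(polys) && length(dim(polys)) == 3L)
    polys <- lapply(seq_len(dim(polys)[1]), function(i) polys[i, , ])
  if (is.matrix(polys)) polys <- list(polys)
  polygon_mask(polys, obj$canvas_shape)
}

#' Write landmark pairs as CSV
#'
#' Columns: `slice_id, h_row, h_col, m_row, m_col` (0-based coordinates).
#'
#' @param landmarks list with `h` and `m` 4x2 matrices (see `slice_pair`).
#' @param slice_id identifier recorded in each row.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_landmarks_csv <- function(landmarks, slice_id, path) {
  df <- data.frame(slice_id = slice_id,
                   h_row = landmarks$h[, 1], h_col = landmarks$h[, 2],
                   m_row = landmarks$m[, 1], m_col = landmarks$m[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @param id slice id to extract (default: first in the file).
#' @export
read_landmarks_csv <- function(path, id = NULL) {
  df <- read.csv(path)
  if (!is.null(id)) df <- df[df$slice_id == id, ]
  list(h = cbind(df$h_row, df$h_col), m = cbind(df$m_row, df$m_col))
}

#' Export a synthetic cohort to disk
#'
#' Writes, per slice, the five MR channels and tumor mask as NIfTI, the PIMO
#' polygon mask as JSON (when present), landmarks as CSV, and a cohort-level
#' truth table `truth.csv` (slice_id, subject_id, true_hypoxia_fraction).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return the truth table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    id <- s$slice_id
    RNifti::writeNifti(s$mp_slice$channels,
                       file.path(dir, sprintf("slice%03d_channels.nii.gz", id)))
    RNifti::writeNifti(s$mp_slice$tumor_mask * 1,
                       file.path(dir, sprintf("slice%03d_tumor.nii.gz", id)))
    if (!is.null(s$pimo_polygons))
      write_polygon_json(s$pimo_polygons,
                         file.path(dir, sprintf("slice%03d_pimo.json", id)))
    write_landmarks_csv(s$landmarks, id,
                        file.path(dir, sprintf("slice%03d_landmarks.csv", id)))
  }
  truth <- data.frame(
    slice_id = vapply(cohort, `[[`, integer(1), "slice_id"),
    subject_id = vapply(cohort, `[[`, integer(1), "subject_id"),
    true_hypoxia_fraction = vapply(cohort, `[[`, numeric(1),
                                   "true_hypoxia_fraction"))
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
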