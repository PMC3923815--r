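#' Reference-region intensity normalization
#'
#' Divides every voxel by the mean intensity over the reference region
#' (cerebellum in the intended application, a region relatively spared in
#' Alzheimer's disease), removing per-subject global-uptake variability.
#' After normalization the mean intensity over the reference mask is 1.
#'
#' @param volume 3D numeric array.
#' @param reference_mask Logical array of the same shape, non-empty.
#' @return Normalized 3D array of the same shape.
#' @examples
#' v <- array(2, dim = c(4, 4, 4))
#' m <- array(FALSE, dim = c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
#' w <- intensity_normalize(v, m)
#' mean(w[m])  # 1
#' @export
intensity_normalize <- function(volume, reference_mask) {
  if (!identical(dim(volume), dim(reference_mask)))
    stop("reference mask does not align with volume")
  reference_mask <- array(as.logical(reference_mask), dim = dim(volume))
  if (!any(reference_mask)) stop("empty reference mask")
  m <- mean(volume[reference_mask])
  if (!is.finite(m) || m <= 0)
    stop("non-positive mean reference intensity (corrupt input?)")
  volume / m
}

# Voxel coordinates selected by a mask, in the fixed lexicographic order
# (first axis slowest). This ordering is the contract between feature
# matrices and fitted reduction bases.
mask_coordinates <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), ,
                   drop = FALSE]
  colnames(coords) <- c("i", "j", "k")
  coords
}

#' Flatten a cohort into the subjects-by-voxels feature matrix
#'
#' Optionally applies [intensity_normalize()] per subject, then extracts the
#' brain-mask voxels of each volume into one row per subject. Voxels are
#' ordered lexicographically by coordinate (first axis slowest), so loadings
#' are reproducible across runs.
#'
#' @param cohort A `cohort`.
#' @param normalize Apply reference normalization first (default `TRUE`).
#'   If `FALSE` a message flags that the caller is responsible.
#' @return Object of class `feature_matrix`: `values` (subjects x voxels),
#'   `subject_ids`, `voxel_index` (matrix of 3D coordinates), `shape`.
#' @export
vectorize_cohort <- function(cohort, normalize = TRUE) {
  validate_cohort(cohort)
  if (!any(cohort$brain_mask)) stop("brain mask selects no voxels")
  coords <- mask_coordinates(cohort$brain_mask)
  vols <- cohort$volumes
  if (normalize) {
    vols <- lapply(vols, intensity_normalize, cohort$reference_mask)
  } else {
    message("vectorize_cohort: volumes taken as-is; ",
            "caller is responsible for intensity normalization")
  }
  values <- t(vapply(vols, function(v) v[coords], numeric(nrow(coords))))
  rownames(values) <- cohort$ids
  structure(list(values = values, subject_ids = cohort$ids,
                 voxel_index = coords, shape = dim(cohort$brain_mask)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d voxels (volume %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Rebuild a volume from one feature-matrix row
#'
#' Inverse of the flattening in [vectorize_cohort()] on masked voxels;
#' voxels outside the mask are filled with `fill`.
#'
#' @param fm A `feature_matrix`.
#' @param row Row index or subject id.
#' @param fill Value outside the mask (default 0).
#' @return 3D array of shape `fm$shape`.
#' @export
matrix_to_volume <- function(fm, row, fill = 0) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.character(row)) row <- match(row, fm$subject_ids)
  v <- array(fill, dim = fm$shape)
  v[fm$voxel_index] <- fm$values[row, ]
  v
}

#' Export a feature matrix as a plain-text matrix plus JSON sidecar
#'
#' @param fm A `feature_matrix`.
#' @param path Base path; writes `<path>.csv` (values, no headers) and
#'   `<path>.json` (subject ids, voxel coordinates, shape).
#' @return Invisibly, the two paths written.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.table(fm$values, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(subject_ids = fm$subject_ids,
                            voxel_index = unname(fm$voxel_index),
                            shape = fm$shape),
                       js, auto_unbox = FALSE)
  invisible(c(csv, js))
}
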