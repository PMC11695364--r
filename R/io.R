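# NIfTI volumes with a JSON offset sidecar, CSV feature tables.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write an image volume (with optional offset sidecar)
#'
#' Volumes go to NIfTI-1; when a schedule is supplied its offsets and
#' reference index are stored in a JSON sidecar next to the image
#' (`foo.nii.gz` -> `foo.json`).
#'
#' @param volume 2D matrix or 3D array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param schedule Optional [offset_schedule()] stored as sidecar metadata.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, schedule = NULL) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  if (!is.null(schedule)) {
    jsonlite::write_json(
      list(offsets_ppm = schedule$offsets_ppm,
           reference_index = schedule$reference_index),
      sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' Read an image volume (with optional offset sidecar)
#'
#' Reads a NIfTI volume; if an offset sidecar is present the reconstructed
#' [offset_schedule()] is attached as the `"schedule"` attribute and checked
#' against the stack depth (mismatch is a hard error).
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return Array of voxel data, possibly with a `"schedule"` attribute.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("failed to read NIfTI volume '", path,
                                           "': ", conditionMessage(e)))
  arr <- array(as.numeric(img), dim = dim(img))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    ref <- meta$reference_index
    sched <- offset_schedule(meta$offsets_ppm,
                             if (is.null(ref) || is.na(ref)) NA_integer_ else ref)
    depth <- if (length(dim(arr)) >= 3L) dim(arr)[3] else 1L
    n_ok <- c(length(sched$offsets_ppm), length(spectral_offsets(sched)))
    if (!depth %in% n_ok) {
      stop(sprintf("sidecar offsets (%d) do not match stack depth (%d)",
                   length(sched$offsets_ppm), depth))
    }
    attr(arr, "schedule") <- sched
  }
  arr
}

#' @rdname write_volume
#' @param map Metric map (matrix) to write.
#' @export
write_metric_map <- function(map, path) {
  write_volume(map, path)
}

#' Read an ROI mask from NIfTI
#'
#' Nonzero voxels become the ROI. The mask must fit the bounds of
#' `image_dim` when given.
#'
#' @param path NIfTI path.
#' @param label ROI label.
#' @param image_dim Optional expected `(nx, ny)` dimensions.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, label = "roi", image_dim = NULL) {
  arr <- read_volume(path)
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  if (!is.null(image_dim) && !identical(dim(arr)[1:2], as.integer(image_dim))) {
    stop("mask dimensions do not match the image bounds")
  }
  roi_mask(label, matrix(arr != 0, nrow(arr), ncol(arr)))
}

#' Write / read a feature table as CSV
#'
#' Plain RFC-4180 CSV; column order and group labels survive a round trip.
#'
#' @param table A data.frame of per-subject histogram features.
#' @param path CSV path.
#' @return `write_feature_table` the path invisibly; `read_feature_table`
#'   the data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
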