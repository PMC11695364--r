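#' Z-spectrum volume
#'
#' Per-voxel normalized saturation values `Z = Ssat/S0` over the spectral
#' (non-reference) offsets, with a voxel mask, an optional per-voxel B0 map,
#' and per-voxel quality flags. Values are checked against a sanity band
#' (default `[-0.2, 1.5]`): out-of-band voxels are flagged, never clamped.
#'
#' @param values 3D array `(nx, ny, n_offsets)` of Z values.
#' @param schedule The acquisition [offset_schedule()]; its spectral offsets
#'   must match the third dimension of `values`.
#' @param mask Logical matrix `(nx, ny)`; defaults to all voxels.
#' @param b0_map_ppm Optional numeric matrix of per-voxel B0 shifts (ppm).
#' @param flags Optional logical matrix of voxels flagged by upstream steps.
#' @param sanity_band Length-2 numeric band used for flagging.
#' @return An object of class `zspec_volume`.
#' @export
zspec_volume <- function(values, schedule, mask = NULL, b0_map_ppm = NULL,
                         flags = NULL, sanity_band = c(-0.2, 1.5)) {
  stopifnot(inherits(schedule, "offset_schedule"))
  if (length(dim(values)) != 3L) stop("values must be a 3D array (x, y, offset)")
  offs <- spectral_offsets(schedule)
  if (dim(values)[3] != length(offs)) {
    stop(sprintf("values depth (%d) does not match spectral offsets (%d)",
                 dim(values)[3], length(offs)))
  }
  nx <- dim(values)[1]; ny <- dim(values)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  if (!identical(dim(mask), c(nx, ny))) stop("mask dimensions do not match values")
  if (is.null(flags)) flags <- matrix(FALSE, nx, ny)
  if (!is.null(b0_map_ppm) && !identical(dim(b0_map_ppm), c(nx, ny))) {
    stop("b0_map_ppm dimensions do not match values")
  }
  # finiteness and sanity band inside the mask
  vmat <- matrix(values, nx * ny, dim(values)[3])
  inmask <- as.vector(mask)
  bad <- rep(FALSE, nx * ny)
  bad[inmask] <- !apply(vmat[inmask, , drop = FALSE], 1L, function(v) {
    all(is.finite(v)) && all(v >= sanity_band[1] & v <= sanity_band[2])
  })
  flags <- flags | matrix(bad, nx, ny)
  structure(
    list(values = values, schedule = schedule, offsets = offs, mask = mask,
         b0_map_ppm = b0_map_ppm, flags = flags, sanity_band = sanity_band),
    class = "zspec_volume"
  )
}

#' @export
print.zspec_volume <- function(x, ...) {
  cat(sprintf(
    "<zspec_volume> %d x %d voxels, %d offsets, %d in mask, %d flagged, B0 %s\n",
    dim(x$values)[1], dim(x$values)[2], length(x$offsets), sum(x$mask),
    sum(x$flags & x$mask), if (is.null(x$b0_map_ppm)) "absent" else "present"))
  invisible(x)
}

#' Normalize a saturated stack to a Z-spectrum volume
#'
#' Computes `Z(dw) = Ssat(dw) / S0` voxelwise. S0 is either a separately
#' acquired image (`s0_image`) or, when `s0_image = NULL`, the reference
#' frame designated in the schedule (extracted from the stack and excluded
#' from the spectral values). Voxels with non-positive S0 inside the mask
#' are excluded from the mask; their count is reported via a warning and the
#' `n_s0_excluded` attribute.
#'
#' @param saturated_stack 3D array `(nx, ny, frames)`. Depth must equal the
#'   full schedule length (embedded reference) or the number of spectral
#'   offsets (separate S0).
#' @param s0_image Optional matrix of S0 values.
#' @param schedule The acquisition [offset_schedule()].
#' @param mask Optional logical matrix or [roi_mask()].
#' @return A [zspec_volume()].
#' @export
normalize_to_zspectrum <- function(saturated_stack, s0_image = NULL,
                                   schedule, mask = NULL) {
  stopifnot(inherits(schedule, "offset_schedule"))
  if (length(dim(saturated_stack)) != 3L) {
    stop("saturated_stack must be a 3D array (x, y, frame)")
  }
  if (inherits(mask, "roi_mask")) mask <- mask$voxels
  n_all <- length(schedule$offsets_ppm)
  n_spec <- length(spectral_offsets(schedule))
  depth <- dim(saturated_stack)[3]
  if (is.null(s0_image)) {
    if (is.na(schedule$reference_index)) {
      stop("schedule has no reference frame and no s0_image was supplied")
    }
    if (depth != n_all) {
      stop(sprintf("stack depth (%d) must equal schedule length (%d) when the reference frame is embedded",
                   depth, n_all))
    }
    s0_image <- saturated_stack[, , schedule$reference_index]
    saturated_stack <- saturated_stack[, , -schedule$reference_index, drop = FALSE]
  } else {
    if (depth != n_spec) {
      stop(sprintf("stack depth (%d) must equal the number of spectral offsets (%d) when S0 is separate",
                   depth, n_spec))
    }
  }
  nx <- dim(saturated_stack)[1]; ny <- dim(saturated_stack)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  bad_s0 <- mask & !(is.finite(s0_image) & s0_image > 0)
  n_bad <- sum(bad_s0)
  if (n_bad > 0) {
    warning(sprintf("%d voxel(s) with non-positive S0 excluded from mask", n_bad))
    mask <- mask & !bad_s0
  }
  z <- sweep(saturated_stack, c(1, 2), s0_image, "/")
  z[!is.finite(z)] <- NA_real_
  out <- zspec_volume(z, schedule, mask = mask)
  attr(out, "n_s0_excluded") <- n_bad
  out
}

#' ROI mask
#'
#' @param label Text label (e.g. `"tumor"`).
#' @param voxels Logical matrix with at least one `TRUE` voxel.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, voxels) {
  voxels <- voxels > 0
  if (!any(voxels)) stop("ROI mask is empty")
  structure(list(label = as.character(label), voxels = voxels),
            class = "roi_mask")
}
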