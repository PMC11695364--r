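#' MTR asymmetry map
#'
#' Voxelwise `MTRasym(x) = (Z(-x) - Z(+x)) / M0`. On normalized spectra
#' `M0 = 1`. With `ppm = 3.5` this is the conventional MTR at 3.5 ppm
#' (amide weighted, positive when the +3.5 ppm side is deeper); with
#' `ppm = 3.0` it is the amine-weighted, pH-sensitive contrast. Z values at
#' `+/-ppm` are taken from schedule points when present and cubic-spline
#' interpolated otherwise.
#'
#' @param zspec A B0-corrected [zspec_volume()].
#' @param ppm Asymmetry offset in ppm (must lie within the sampled range).
#' @param m0 Normalization constant.
#' @return Matrix map (`NA` outside the mask).
#' @export
mtr_asym <- function(zspec, ppm = 3.5, m0 = 1) {
  stopifnot(inherits(zspec, "zspec_volume"), ppm > 0)
  offs <- zspec$offsets
  if (ppm > max(offs) || -ppm < min(offs)) {
    stop(sprintf("+/-%g ppm lies outside the sampled offset range", ppm))
  }
  nx <- dim(zspec$values)[1]; ny <- dim(zspec$values)[2]
  vmat <- matrix(zspec$values, nx * ny)
  idx <- match_offsets(c(-ppm, ppm), offs)
  out <- matrix(NA_real_, nx, ny)
  sel <- which(zspec$mask)
  if (!anyNA(idx)) {
    out[sel] <- (vmat[sel, idx[1]] - vmat[sel, idx[2]]) / m0
  } else {
    ord <- order(offs)
    xs <- offs[ord]
    for (i in sel) {
      f <- stats::splinefun(xs, vmat[i, ord], method = "fmm")
      out[i] <- (f(-ppm) - f(ppm)) / m0
    }
  }
  out
}

#' pH-weighted contrast map
#'
#' The amine-proton MTR asymmetry at 3.0 ppm, used as a pH-weighted
#' contrast: faster amine exchange at lower pH modulates the +3.0 ppm side
#' of the spectrum. Reported pH-weighted values are small signed numbers in
#' Z units; converting them to nominal pH requires a user-supplied sigmoid
#' calibration ([ph_from_asym()]).
#'
#' @inheritParams mtr_asym
#' @return Matrix map of MTRasym at 3.0 ppm.
#' @export
ph_weighted_map <- function(zspec, m0 = 1) {
  mtr_asym(zspec, ppm = 3.0, m0 = m0)
}

#' Sigmoid calibration between pH and MTRasym at 3.0 ppm
#'
#' `MTRasym@3.0ppm(pH) = alpha + (beta - alpha) / (1 + 10^e)`, with
#' exponent `e = delta_slope * (kappa * pH)` (`exponent_form = "product"`,
#' the expression as printed in the source literature) or
#' `e = delta_slope * (kappa - pH)` (`"difference"`, the common logistic
#' reading with midpoint `kappa`). Both readings are strictly monotone in pH
#' and are supported throughout; no calibration constants are asserted by
#' this package.
#'
#' @param alpha Lower asymptote.
#' @param beta Upper asymptote (`beta > alpha`).
#' @param delta_slope Slope parameter (nonzero).
#' @param kappa Scale (product form) or midpoint (difference form).
#' @return An object of class `ph_calibration`.
#' @export
ph_calibration <- function(alpha, beta, delta_slope, kappa) {
  stopifnot(is.finite(alpha), is.finite(beta), beta > alpha,
            is.finite(delta_slope), delta_slope != 0, is.finite(kappa))
  structure(list(alpha = alpha, beta = beta, delta_slope = delta_slope,
                 kappa = kappa), class = "ph_calibration")
}

#' @rdname ph_calibration
#' @param ph pH values.
#' @param cal A `ph_calibration`.
#' @param exponent_form `"product"` or `"difference"` (see above).
#' @return `ph_sigmoid`: MTRasym values; `ph_from_asym`: nominal pH.
#' @export
ph_sigmoid <- function(ph, cal, exponent_form = c("product", "difference")) {
  stopifnot(inherits(cal, "ph_calibration"))
  exponent_form <- match.arg(exponent_form)
  e <- switch(exponent_form,
              product = cal$delta_slope * (cal$kappa * ph),
              difference = cal$delta_slope * (cal$kappa - ph))
  cal$alpha + (cal$beta - cal$alpha) / (1 + 10^e)
}

#' @rdname ph_calibration
#' @param asym MTRasym values strictly between `alpha` and `beta`.
#' @export
ph_from_asym <- function(asym, cal,
                         exponent_form = c("product", "difference")) {
  stopifnot(inherits(cal, "ph_calibration"))
  exponent_form <- match.arg(exponent_form)
  ok <- is.finite(asym) & asym > cal$alpha & asym < cal$beta
  if (any(!ok & is.finite(asym))) {
    warning(sprintf("%d value(s) outside (alpha, beta): out of calibration, returned NA",
                    sum(!ok & is.finite(asym))))
  }
  e <- rep(NA_real_, length(asym))
  e[ok] <- log10((cal$beta - cal$alpha) / (asym[ok] - cal$alpha) - 1)
  out <- switch(exponent_form,
                product = e / (cal$delta_slope * cal$kappa),
                difference = cal$kappa - e / cal$delta_slope)
  attr(out, "out_of_calibration") <- !ok & is.finite(asym)
  out
}

#' ROI histogram features of a metric map
#'
#' Mean, median and the 10th/25th/75th/90th percentiles of a metric over
#' the ROI voxels. Percentiles use linear interpolation between order
#' statistics (R quantile type 7), stated explicitly for reproducibility.
#' Flagged voxels (e.g. non-converged fits) should be passed via `exclude`
#' and are dropped before summarizing.
#'
#' @param metric_map Numeric matrix.
#' @param roi A [roi_mask()] or logical matrix.
#' @param metric Name recorded in the output row.
#' @param min_voxels Minimum usable ROI size (error below this).
#' @param exclude Optional logical matrix of voxels to drop.
#' @return One-row data.frame: `metric`, `mean`, `median`, `p10`, `p25`,
#'   `p75`, `p90`, `n_voxels`.
#' @export
extract_histogram_features <- function(metric_map, roi, metric = "value",
                                       min_voxels = 10, exclude = NULL) {
  vox <- if (inherits(roi, "roi_mask")) roi$voxels else roi
  stopifnot(identical(dim(vox), dim(metric_map)))
  if (!is.null(exclude)) vox <- vox & !exclude
  vals <- metric_map[vox]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_voxels) {
    stop(sprintf("ROI has %d usable voxels, fewer than the minimum %d",
                 length(vals), min_voxels))
  }
  q <- stats::quantile(vals, c(0.10, 0.25, 0.75, 0.90), type = 7,
                       names = FALSE)
  data.frame(metric = metric, mean = mean(vals), median = stats::median(vals),
             p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
             n_voxels = length(vals), stringsAsFactors = FALSE)
}

#' Histogram feature table for a set of metric maps
#'
#' Convenience wrapper running [extract_histogram_features()] on each map
#' in a named list (typically the five pool amplitude maps plus MTR 3.5 and
#' the pH-weighted map) for one subject and ROI.
#'
#' @param maps Named list of metric matrices.
#' @param roi A [roi_mask()] or logical matrix.
#' @param subject_id Subject identifier column value.
#' @param exclude Optional logical matrix of flagged voxels.
#' @param min_voxels Minimum usable ROI size per metric.
#' @return Long data.frame with one row per metric.
#' @export
compute_feature_table <- function(maps, roi, subject_id = "S1",
                                  exclude = NULL, min_voxels = 10) {
  rows <- lapply(names(maps), function(nm) {
    extract_histogram_features(maps[[nm]], roi, metric = nm,
                               min_voxels = min_voxels, exclude = exclude)
  })
  cbind(data.frame(subject = subject_id, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
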