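#' Saturation offset schedule
#'
#' An offset schedule is the ordered list of saturation frequency offsets (in
#' ppm from water) at which the saturated images were acquired, together with
#' the index of the normalization reference frame (the effectively
#' unsaturated acquisition used as S0). Set `reference_index = NA` when S0 is
#' acquired as a separate scan rather than as a frame of the stack.
#'
#' @param offsets_ppm Numeric vector of finite frequency offsets in ppm, in
#'   acquisition order.
#' @param reference_index Integer index of the normalization frame within
#'   `offsets_ppm`, or `NA` if S0 is acquired separately.
#' @return An object of class `offset_schedule`.
#' @seealso [build_default_offset_schedule()]
#' @export
offset_schedule <- function(offsets_ppm, reference_index = NA_integer_) {
  offsets_ppm <- as.numeric(offsets_ppm)
  if (length(offsets_ppm) < 2L) {
    stop("an offset schedule needs at least two offsets")
  }
  if (!all(is.finite(offsets_ppm))) {
    stop("all offsets must be finite")
  }
  if (!is.na(reference_index)) {
    reference_index <- as.integer(reference_index)
    if (length(reference_index) != 1L ||
        reference_index < 1L || reference_index > length(offsets_ppm)) {
      stop("reference_index must be a single index into offsets_ppm")
    }
  }
  structure(
    list(offsets_ppm = offsets_ppm, reference_index = reference_index),
    class = "offset_schedule"
  )
}

#' Default 64-offset acquisition schedule
#'
#' Builds the 64-entry saturation schedule used by the 2D single-shot TSE
#' CEST protocol this package targets: 0 first, then symmetric +/- pairs at
#' 0.25 ppm spacing out to 5 ppm, 0.5 ppm spacing out to 7.5 ppm, then
#' +/-10, +/-15, +/-20, +/-25, +/-30, +/-100, and finally an unpaired +300
#' ppm frame. At +300 ppm direct saturation is negligible, so that frame is
#' designated the S0 normalization reference (standard CEST practice; pass a
#' separately acquired S0 to [normalize_to_zspectrum()] to override).
#'
#' @return An `offset_schedule` of length 64 with the +300 ppm frame marked
#'   as the reference.
#' @examples
#' sched <- build_default_offset_schedule()
#' length(sched$offsets_ppm)  # 64
#' @export
build_default_offset_schedule <- function() {
  pair <- function(x) as.vector(rbind(x, -x))
  offs <- c(
    0,
    pair(seq(0.25, 5, by = 0.25)),
    pair(seq(5.5, 7.5, by = 0.5)),
    pair(c(10, 15, 20, 25, 30, 100)),
    300
  )
  offset_schedule(offs, reference_index = length(offs))
}

#' Spectral (non-reference) offsets of a schedule
#'
#' @param schedule An `offset_schedule`.
#' @return Numeric vector of offsets with the normalization frame removed.
#' @export
spectral_offsets <- function(schedule) {
  stopifnot(inherits(schedule, "offset_schedule"))
  if (is.na(schedule$reference_index)) return(schedule$offsets_ppm)
  schedule$offsets_ppm[-schedule$reference_index]
}

#' Background-only offset subsets
#'
#' The two-pool background fit is restricted to offsets assumed to carry only
#' direct-water-saturation and semisolid-MT signal: the MT wings at +/-10,
#' +/-15, +/-20, +/-25, +/-30, +/-100 ppm and the water band at 0, +/-0.25,
#' +/-0.5, +/-0.75, +/-1 ppm. All other offsets are disregarded by that fit.
#'
#' @param type `"all"`, `"water"`, or `"mt"`.
#' @return Numeric vector of offsets in ppm.
#' @export
background_offsets <- function(type = c("all", "water", "mt")) {
  type <- match.arg(type)
  water <- c(0, 0.25, -0.25, 0.5, -0.5, 0.75, -0.75, 1, -1)
  mt <- as.vector(rbind(c(10, 15, 20, 25, 30, 100),
                        -c(10, 15, 20, 25, 30, 100)))
  switch(type, water = water, mt = mt, all = c(water, mt))
}

#' @export
print.offset_schedule <- function(x, ...) {
  ref <- if (is.na(x$reference_index)) "separate S0" else {
    sprintf("frame %d (%+g ppm)", x$reference_index,
            x$offsets_ppm[x$reference_index])
  }
  cat(sprintf("<offset_schedule> %d offsets, %g to %g ppm, reference: %s\n",
              length(x$offsets_ppm), min(x$offsets_ppm),
              max(x$offsets_ppm), ref))
  invisible(x)
}

#' Acquisition parameters
#'
#' Container for the saturation parameters that matter to quantification.
#' All values must be strictly positive.
#'
#' @param saturation_power_uT RF saturation amplitude in microtesla.
#' @param saturation_duration_ms Total saturation duration in milliseconds.
#' @param pulse_duration_s Duration of the (quasi-continuous) saturation
#'   pulse in seconds; sets the water-line plateau bandwidth.
#' @param larmor_freq_mhz Proton Larmor frequency in MHz (127.74 at 3 T),
#'   used to express the plateau bandwidth in ppm.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(saturation_power_uT = 0.9,
                               saturation_duration_ms = 3000,
                               pulse_duration_s = 3,
                               larmor_freq_mhz = 127.74) {
  vals <- c(saturation_power_uT, saturation_duration_ms,
            pulse_duration_s, larmor_freq_mhz)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition parameters must be strictly positive")
  }
  structure(
    list(saturation_power_uT = saturation_power_uT,
         saturation_duration_ms = saturation_duration_ms,
         pulse_duration_s = pulse_duration_s,
         larmor_freq_mhz = larmor_freq_mhz),
    class = "acquisition_params"
  )
}

#' Plateau bandwidth of the water line
#'
#' The adjusted water Lorentzian carries a flat top whose width estimates the
#' Fourier bandwidth of the saturation pulse, (1 / t_pulse) Hz, expressed in
#' ppm by dividing by the Larmor frequency. For the 3 s quasi-continuous
#' saturation used here this is ~0.003 ppm, i.e. negligible, which is why the
#' fitting default is `plateau_bw = 0` (a standard Lorentzian).
#'
#' @param params An [acquisition_params()] object.
#' @return Bandwidth in ppm.
#' @export
plateau_bandwidth <- function(params) {
  stopifnot(inherits(params, "acquisition_params"))
  (1 / params$pulse_duration_s) / params$larmor_freq_mhz
}
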