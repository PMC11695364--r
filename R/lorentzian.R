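#' Lorentzian line parameters
#'
#' A single saturation pool is modelled as a Lorentzian line in the
#' Z-spectrum, parameterized by its amplitude `A` (in Z units, the depth of
#' the dip at the peak), full-width-at-half-maximum `fwhm` (ppm), and center
#' position `center` (ppm from water). The water line may additionally carry
#' a flat plateau of width `plateau_bw` (ppm) accounting for the saturation
#' pulse bandwidth; all other pools use `plateau_bw = 0`.
#'
#' @param amplitude Peak amplitude, `A >= 0`.
#' @param fwhm Full width at half maximum in ppm, `> 0`.
#' @param center Peak position in ppm.
#' @param plateau_bw Plateau width in ppm, `>= 0` (0 gives the standard
#'   Lorentzian).
#' @return An object of class `lorentzian_line`.
#' @export
lorentzian_line <- function(amplitude, fwhm, center, plateau_bw = 0) {
  amplitude <- unname(amplitude); fwhm <- unname(fwhm)
  center <- unname(center); plateau_bw <- unname(plateau_bw)
  if (!is.finite(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be > 0")
  if (!is.finite(center)) stop("center must be finite")
  if (!is.finite(plateau_bw) || plateau_bw < 0) stop("plateau_bw must be >= 0")
  structure(
    list(amplitude = amplitude, fwhm = fwhm, center = center,
         plateau_bw = plateau_bw),
    class = "lorentzian_line"
  )
}

# bare-metal Lorentzian, vectorized over dw
.lor <- function(dw, A, G, d) {
  q <- G^2 / 4
  A * q / (q + (dw - d)^2)
}

#' Evaluate a standard Lorentzian line
#'
#' `L(dw) = A (G^2/4) / (G^2/4 + (dw - d)^2)`: equals `A` at the peak and
#' `A/2` at `d +/- G/2`.
#'
#' @param delta_ppm Offsets in ppm (vectorized).
#' @param line A [lorentzian_line()] (its `plateau_bw` is ignored here).
#' @return Numeric vector of line values.
#' @export
eval_standard_line <- function(delta_ppm, line) {
  stopifnot(inherits(line, "lorentzian_line"))
  .lor(delta_ppm, line$amplitude, line$fwhm, line$center)
}

#' Evaluate the plateau-adjusted water line
#'
#' The water line generalizes the Lorentzian with a flat top of width
#' `plateau_bw`:
#' `L(dw) = A (G^2/4) / (G^2/4 + (x H(x) + y H(-y))^2)` with
#' `x = dw - d - BW/2`, `y = dw - d + BW/2` and `H` the Heaviside step.
#' Inside the plateau (`|dw - d| <= BW/2`) both step terms vanish and the
#' value is exactly `A`; with `BW = 0` it reduces pointwise to
#' [eval_standard_line()].
#'
#' @inheritParams eval_standard_line
#' @return Numeric vector of line values.
#' @export
eval_water_line <- function(delta_ppm, line) {
  stopifnot(inherits(line, "lorentzian_line"))
  A <- line$amplitude; G <- line$fwhm; d <- line$center; bw <- line$plateau_bw
  x <- delta_ppm - d - bw / 2
  y <- delta_ppm - d + bw / 2
  t <- x * (x > 0) + y * (y < 0)
  q <- G^2 / 4
  A * q / (q + t^2)
}

#' Evaluate a five-pool parameter set as a Z-spectrum
#'
#' Forward model of the Z-spectrum: a constant baseline minus the water,
#' semisolid-MT, amide, amine, and NOE lines, each evaluated at
#' `delta_ppm - b0_shift_ppm` so that a static-field offset shifts the whole
#' spectrum. Missing (`NULL`) pools contribute nothing; with only the water
#' and MT pools this is exactly the two-pool background model.
#'
#' @param pools A named list with numeric element `c` (baseline constant)
#'   and [lorentzian_line()] elements among `water`, `mt`, `amide`, `amine`,
#'   `noe` (any may be `NULL`).
#' @param offsets_ppm Offsets at which to evaluate, in ppm.
#' @param b0_shift_ppm Static-field offset in ppm.
#' @return Numeric vector: the noise-free Z-spectrum.
#' @export
simulate_zspectrum <- function(pools, offsets_ppm, b0_shift_ppm = 0) {
  stopifnot(is.list(pools), is.numeric(pools$c))
  dw <- offsets_ppm - b0_shift_ppm
  z <- rep(pools$c, length(dw))
  for (nm in c("water", "mt", "amide", "amine", "noe")) {
    ln <- pools[[nm]]
    if (is.null(ln)) next
    z <- z - if (nm == "water") eval_water_line(dw, ln) else
      eval_standard_line(dw, ln)
  }
  z
}
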