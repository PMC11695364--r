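#' Subpixel rigid (translation) registration of an image stack
#'
#' Estimates the in-plane translation of every frame relative to a reference
#' frame by Fourier cross-correlation, refined to subpixel precision with a
#' locally upsampled discrete Fourier transform (matrix-multiply DFT over a
#' +/-1.5 px neighbourhood of the integer peak), then resamples each frame
#' onto the reference grid via the Fourier shift theorem. Single-slice 2D
#' translation only: that is the dominant motion mode for single-slice
#' acquisitions.
#'
#' Degenerate frames (near-constant, or with a normalized peak correlation
#' below `min_correlation`, e.g. pure noise) are left untouched with a zero
#' shift and a warning.
#'
#' @param stack 3D array `(nx, ny, frames)`, at least 2 frames.
#' @param reference_frame_index Frame used as the registration target.
#' @param upsample Subpixel refinement factor (default 100: 0.01 px grid).
#' @param min_correlation Normalized cross-correlation below which a frame
#'   is declared degenerate.
#' @return List with `stack` (corrected array) and `shifts`
#'   (`frames x 2` matrix of estimated per-frame displacements in px).
#' @export
register_subpixel <- function(stack, reference_frame_index = 1,
                              upsample = 100, min_correlation = 0.3) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]; nf <- dim(stack)[3]
  ref <- stack[, , reference_frame_index]
  ref0 <- ref - mean(ref)
  if (stats::sd(ref) < .Machine$double.eps^0.5) {
    warning("reference frame is constant; no registration performed")
    return(list(stack = stack, shifts = matrix(0, nf, 2)))
  }
  Fr <- stats::fft(ref0)
  kx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)[1:nx]
  ky <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1)[1:ny]
  shifts <- matrix(0, nf, 2)
  out <- stack
  for (f in seq_len(nf)) {
    if (f == reference_frame_index) next
    frame <- stack[, , f]
    if (stats::sd(frame) < .Machine$double.eps^0.5) {
      warning(sprintf("frame %d is constant; shift set to (0, 0)", f))
      next
    }
    Ff <- stats::fft(frame - mean(frame))
    R <- Conj(Fr) * Ff
    cc <- Re(stats::fft(R, inverse = TRUE)) / (nx * ny)
    pk <- which.max(cc)
    pi_ <- (pk - 1) %% nx
    pj_ <- (pk - 1) %/% nx
    s1 <- if (pi_ > nx / 2) pi_ - nx else pi_
    s2 <- if (pj_ > ny / 2) pj_ - ny else pj_
    ncc <- max(cc) / sqrt(sum(ref0^2) * sum((frame - mean(frame))^2))
    if (ncc < min_correlation) {
      warning(sprintf("frame %d: peak correlation %.2f below %.2f; shift set to (0, 0)",
                      f, ncc, min_correlation))
      next
    }
    # upsampled DFT refinement: cc(u) = sum_k R_k exp(2*pi*i(k1 u1/nx + k2 u2/ny))
    grid1 <- s1 + seq(-1.5, 1.5, by = 1 / upsample)
    grid2 <- s2 + seq(-1.5, 1.5, by = 1 / upsample)
    E1 <- exp(2i * pi * outer(grid1, kx) / nx)   # |grid1| x nx
    E2 <- exp(2i * pi * outer(ky, grid2) / ny)   # ny x |grid2|
    ccu <- Re(E1 %*% R %*% E2) / (nx * ny)
    pk2 <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
    sh <- c(grid1[pk2[1]], grid2[pk2[2]])
    shifts[f, ] <- sh
    out[, , f] <- fourier_shift(frame, -sh[1], -sh[2])
  }
  list(stack = out, shifts = shifts)
}

#' Multilinear SVD (truncated HOSVD) denoising
#'
#' Treats the saturated stack as a 3-mode tensor (x, y, offset), computes
#' the singular vectors of each mode unfolding, and reconstructs from a
#' truncated core. By default (`method = "noise_floor"`) each mode's rank
#' keeps the singular values above an optimal hard threshold estimated from
#' the median singular value (Gavish-Donoho rule with unknown noise level);
#' this adapts the truncation to the noise floor rather than to an energy
#' quota, which matters here because the leading component carries almost
#' all raw energy while the CEST features of interest live far below it.
#' `method = "energy"` instead keeps the smallest ranks retaining at least
#' `energy` of each mode's squared singular-value mass. Explicit `ranks`
#' override both.
#'
#' @param stack 3D array `(nx, ny, offsets)`.
#' @param ranks Optional integer vector of length 3; each must not exceed
#'   the corresponding mode size.
#' @param method Automatic rank rule, `"noise_floor"` or `"energy"`.
#' @param energy Retained energy fraction for `method = "energy"`.
#' @return Denoised array with attribute `"ranks"`.
#' @export
denoise_mlsvd <- function(stack, ranks = NULL,
                          method = c("noise_floor", "energy"),
                          energy = 0.999) {
  stopifnot(length(dim(stack)) == 3L)
  method <- match.arg(method)
  dims <- dim(stack)
  unfold <- function(x, mode) {
    perm <- c(mode, setdiff(1:3, mode))
    matrix(aperm(x, perm), dims[mode])
  }
  if (!is.null(ranks)) {
    stopifnot(length(ranks) == 3L)
    if (any(ranks > dims) || any(ranks < 1)) {
      stop("ranks must lie between 1 and the corresponding mode size")
    }
  }
  U <- vector("list", 3)
  r <- integer(3)
  for (m in 1:3) {
    um <- unfold(stack, m)
    s <- svd(um, nu = dims[m], nv = 0)
    if (!is.null(ranks)) {
      r[m] <- ranks[m]
    } else if (method == "energy") {
      e <- cumsum(s$d^2) / sum(s$d^2)
      r[m] <- which(e >= energy)[1]
    } else {
      beta <- min(nrow(um), ncol(um)) / max(nrow(um), ncol(um))
      omega <- 0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
      thr <- omega * stats::median(s$d)
      r[m] <- max(sum(s$d > thr), 1L)
    }
    U[[m]] <- s$u[, seq_len(r[m]), drop = FALSE]
  }
  # successive mode-wise projections onto the retained subspaces
  x <- stack
  for (m in 1:3) {
    perm <- c(m, setdiff(1:3, m))
    xm <- matrix(aperm(x, perm), dims[m])
    xm <- U[[m]] %*% (t(U[[m]]) %*% xm)
    x <- aperm(array(xm, dims[perm]), order(perm))
  }
  attr(x, "ranks") <- r
  x
}

#' B0 map container
#'
#' @param shift_ppm Matrix of per-voxel static-field shifts in ppm.
#' @param method `"two_pool_fit"` or `"spline_minimum"`.
#' @param flags Logical matrix of voxels whose estimate is unreliable
#'   (non-convergent, out of bound, or ambiguous minimum).
#' @return An object of class `b0_map`.
#' @export
b0_map <- function(shift_ppm, method = c("two_pool_fit", "spline_minimum"),
                   flags = NULL) {
  method <- match.arg(method)
  if (is.null(flags)) flags <- matrix(FALSE, nrow(shift_ppm), ncol(shift_ppm))
  structure(list(shift_ppm = shift_ppm, method = method, flags = flags),
            class = "b0_map")
}

#' Estimate B0 from the two-pool background fit
#'
#' Fits the two-pool (water + semisolid MT) background model to each voxel's
#' raw Z-spectrum, restricted to the background-only offsets, and takes the
#' fitted water-line center as the voxel's static-field offset (the water
#' pool's off-resonance is a surrogate B0 map). Non-convergent voxels fall
#' back to 0 ppm and are flagged; estimates beyond `max_shift` are flagged.
#'
#' @param zspec A [zspec_volume()] (uncorrected).
#' @param options Fit configuration from [fit_options()].
#' @param max_shift Flagging bound on `|B0|` in ppm.
#' @return A [b0_map()] with `method = "two_pool_fit"`.
#' @export
estimate_b0_two_pool <- function(zspec, options = fit_options(),
                                 max_shift = 1) {
  stopifnot(inherits(zspec, "zspec_volume"))
  nx <- dim(zspec$values)[1]; ny <- dim(zspec$values)[2]
  shift <- matrix(NA_real_, nx, ny)
  flags <- matrix(FALSE, nx, ny)
  idx <- which(zspec$mask)
  vmat <- matrix(zspec$values, nx * ny)
  for (i in idx) {
    est <- tryCatch({
      bg <- fit_background(vmat[i, ], zspec$offsets, options)
      if (!bg$converged) stop("not converged")
      bg$water$center
    }, error = function(e) NA_real_)
    if (is.na(est)) {
      shift[i] <- 0
      flags[i] <- TRUE
    } else {
      shift[i] <- est
      if (abs(est) > max_shift) flags[i] <- TRUE
    }
  }
  b0_map(shift, "two_pool_fit", flags)
}

#' Estimate B0 as the spline-interpolated spectral minimum
#'
#' Interpolates each voxel's Z-spectrum with a cubic spline near water and
#' takes the argmin over a dense grid (default 0.001 ppm) as the voxel's
#' static-field offset. Requires offsets covering `search_ppm`. With several
#' equally deep minima the one nearest 0 ppm is taken and the voxel flagged.
#'
#' @param zspec A [zspec_volume()] (uncorrected).
#' @param search_ppm Search interval for the minimum (ppm).
#' @param grid_step Dense-grid resolution in ppm.
#' @param window_ppm Offsets within this window feed the spline.
#' @return A [b0_map()] with `method = "spline_minimum"`.
#' @export
estimate_b0_spline_minimum <- function(zspec, search_ppm = c(-1, 1),
                                       grid_step = 0.001, window_ppm = 2.5) {
  stopifnot(inherits(zspec, "zspec_volume"))
  offs <- zspec$offsets
  sel <- which(abs(offs) <= window_ppm)
  xs <- offs[sel]
  if (min(xs) > search_ppm[1] || max(xs) < search_ppm[2] ||
      max(diff(sort(xs))) > 0.5) {
    stop("offsets do not cover the search window densely enough")
  }
  ord <- order(xs)
  grid <- seq(search_ppm[1], search_ppm[2], by = grid_step)
  nx <- dim(zspec$values)[1]; ny <- dim(zspec$values)[2]
  shift <- matrix(NA_real_, nx, ny)
  flags <- matrix(FALSE, nx, ny)
  vmat <- matrix(zspec$values, nx * ny)[, sel, drop = FALSE]
  for (i in which(zspec$mask)) {
    z <- vmat[i, ord]
    if (any(!is.finite(z))) { flags[i] <- TRUE; shift[i] <- 0; next }
    f <- stats::splinefun(xs[ord], z, method = "fmm")
    vals <- f(grid)
    mins <- which(vals <= min(vals) + 1e-12)
    if (length(mins) > 1L && diff(range(grid[mins])) > 2 * grid_step) {
      flags[i] <- TRUE
      mins <- mins[which.min(abs(grid[mins]))]
    }
    shift[i] <- grid[mins[1]]
  }
  b0_map(shift, "spline_minimum", flags)
}

#' Shift Z-spectra to compensate B0 inhomogeneity
#'
#' Re-samples each voxel's spectrum at `offset + shift` with a cubic spline,
#' recentring the water minimum at 0 ppm. Voxels whose `|shift|` exceeds
#' `max_shift` (or is non-finite) are flagged; queries beyond the sampled
#' range use spline extrapolation and their total count is recorded in the
#' `"n_extrapolated"` attribute.
#'
#' @param zspec A [zspec_volume()].
#' @param b0map A [b0_map()] (or plain matrix of shifts in ppm).
#' @param max_shift Largest credible `|B0|` in ppm.
#' @return A corrected [zspec_volume()] with `b0_map_ppm` set.
#' @export
apply_b0_correction <- function(zspec, b0map, max_shift = 1) {
  stopifnot(inherits(zspec, "zspec_volume"))
  shift <- if (inherits(b0map, "b0_map")) b0map$shift_ppm else b0map
  pre_flags <- if (inherits(b0map, "b0_map")) b0map$flags else
    matrix(FALSE, nrow(shift), ncol(shift))
  offs <- zspec$offsets
  ord <- order(offs)
  xs <- offs[ord]
  nx <- dim(zspec$values)[1]; ny <- dim(zspec$values)[2]
  vmat <- matrix(zspec$values, nx * ny)
  out <- vmat
  flags <- zspec$flags | pre_flags
  n_extrap <- 0L
  for (i in which(zspec$mask)) {
    b <- shift[i]
    if (!is.finite(b)) { flags[i] <- TRUE; next }
    if (abs(b) > max_shift) flags[i] <- TRUE
    if (b == 0) next
    z <- vmat[i, ord]
    if (any(!is.finite(z))) { flags[i] <- TRUE; next }
    f <- stats::splinefun(xs, z, method = "fmm")
    q <- offs + b
    n_extrap <- n_extrap + sum(q < xs[1] | q > xs[length(xs)])
    out[i, ] <- f(q)
  }
  res <- zspec_volume(array(out, dim(zspec$values)), zspec$schedule,
                      mask = zspec$mask, b0_map_ppm = shift, flags = flags,
                      sanity_band = zspec$sanity_band)
  attr(res, "n_extrapolated") <- n_extrap
  # keep the unresampled spectra so later fits can avoid interpolation error
  attr(res, "raw_values") <- zspec$values
  res
}
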