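test_that("subpixel registration recovers an injected fractional shift", {
  img <- test_image()
  stack <- array(0, c(dim(img), 3))
  stack[, , 1] <- img
  stack[, , 2] <- cestfit:::fourier_shift(img, 0.6, -1.2)
  stack[, , 3] <- img
  reg <- register_subpixel(stack, reference_frame_index = 1)
  expect_equal(reg$shifts[2, ], c(0.6, -1.2), tolerance = 0.1)
  expect_equal(reg$shifts[3, ], c(0, 0), tolerance = 0.05)
  # corrected frame is restored onto the reference grid
  expect_lt(max(abs(reg$stack[, , 2] - img)), 0.02 * max(img))
})

test_that("registration flags degenerate frames instead of failing", {
  img <- test_image()
  stack <- array(0, c(dim(img), 3))
  stack[, , 1] <- img
  stack[, , 2] <- 5  # constant frame
  set.seed(1)
  stack[, , 3] <- matrix(stats::rnorm(length(img)), nrow(img))  # pure noise
  w <- capture_warnings(reg <- register_subpixel(stack))
  expect_match(w, "constant|correlation", all = TRUE)
  expect_length(w, 2L)
  expect_equal(reg$shifts[2, ], c(0, 0))
  expect_equal(reg$shifts[3, ], c(0, 0))
})

test_that("MLSVD at full rank is the identity and never hurts clean data", {
  set.seed(4)
  x <- array(stats::rnorm(10 * 9 * 8), c(10, 9, 8))
  full <- denoise_mlsvd(x, ranks = c(10, 9, 8))
  expect_equal(full, x, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(denoise_mlsvd(x, ranks = c(11, 9, 8)), "mode size")
})

test_that("MLSVD denoises a noisy low-rank tensor below the noise energy", {
  set.seed(5)
  a <- stats::rnorm(12); b <- stats::rnorm(14); cc <- stats::rnorm(10)
  clean <- outer(outer(a, b), cc)        # exact rank (1,1,1)
  noise <- array(stats::rnorm(length(clean), 0, 0.05), dim(clean))
  den <- denoise_mlsvd(clean + noise)
  expect_lt(sum((den - clean)^2), sum(noise^2))
  # and beats doing nothing by a wide margin
  expect_lt(sum((den - clean)^2), 0.5 * sum(noise^2))
})

test_that("denoised-then-fit beats fit-without-denoising at noise 0.02", {
  cfg <- phantom_config(grid_shape = c(16, 16), noise_sd = 0.02,
                        b0_coefficients = rep(0, 6), seed = 31)
  ph <- generate_phantom(cfg)
  fit_amide_rmse <- function(stack) {
    z <- suppressWarnings(normalize_to_zspectrum(stack, NULL, ph$schedule,
                                                 ph$masks$brain))
    zc <- apply_b0_correction(z, estimate_b0_two_pool(z))
    mm <- fit_voxelwise_pipeline(zc)
    sqrt(mean((mm$maps$amide - ph$truth$amide)[ph$masks$brain]^2,
              na.rm = TRUE))
  }
  raw_rmse <- fit_amide_rmse(ph$saturated_stack)
  den_rmse <- fit_amide_rmse(denoise_mlsvd(ph$saturated_stack))
  expect_lte(den_rmse, raw_rmse)
})

test_that("two-pool B0 estimate recovers injected shifts", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- tumor_pools()
  shifts <- c(0, 0.3, -0.45)
  zmat <- t(sapply(shifts, function(s)
    simulate_zspectrum(pools, offs, b0_shift_ppm = s)))
  z <- spectra_volume(zmat)
  b0 <- estimate_b0_two_pool(z)
  expect_equal(as.vector(b0$shift_ppm), shifts, tolerance = 0.01)
  expect_false(any(b0$flags))
})

test_that("spline-minimum B0 matches injections and the two-pool method", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- tumor_pools()
  shifts <- seq(-0.5, 0.5, by = 0.125)
  zmat <- t(sapply(shifts, function(s)
    simulate_zspectrum(pools, offs, b0_shift_ppm = s)))
  z <- spectra_volume(zmat)
  bspl <- estimate_b0_spline_minimum(z)
  expect_equal(as.vector(bspl$shift_ppm), shifts, tolerance = 0.01)
  # symmetric unshifted spectrum sits at 0
  expect_equal(bspl$shift_ppm[shifts == 0], 0, tolerance = 2e-3)
  btp <- estimate_b0_two_pool(z)
  expect_lt(max(abs(bspl$shift_ppm - btp$shift_ppm)), 0.05)
})

test_that("B0 correction round-trips and a zero map is the identity", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- tumor_pools()
  z0 <- simulate_zspectrum(pools, offs)
  d <- 0.35
  zsh <- simulate_zspectrum(pools, offs, b0_shift_ppm = d)
  z <- spectra_volume(rbind(zsh, z0))
  corr <- apply_b0_correction(z, matrix(c(d, 0), 2, 1))
  sel <- abs(offs) <= 5
  expect_equal(corr$values[1, 1, sel], z0[sel], tolerance = 1e-3)
  expect_identical(corr$values[2, 1, ], z0)
  # excessive shifts are flagged
  corr2 <- apply_b0_correction(z, matrix(c(1.5, 0), 2, 1))
  expect_true(corr2$flags[1, 1])
  expect_false(corr2$flags[2, 1])
})

test_that("correcting for the estimated field removes most of the amide-recovery penalty", {
  # paired recovery with vs without correction. The fit's free line centers
  # (+/-0.4 ppm windows) absorb smaller constant shifts on their own, so the
  # field is set just beyond the window, where only the explicit correction
  # can re-center the resonances.
  cfg <- phantom_config(grid_shape = c(14, 14), noise_sd = 0,
                        b0_coefficients = c(0.6, 0, 0, 0, 0, 0),
                        amplitude_jitter = 0, seed = 41)
  ph <- generate_phantom(cfg)
  z <- normalize_to_zspectrum(ph$saturated_stack, NULL, ph$schedule,
                              ph$masks$tumor)
  err_of <- function(zv) {
    mm <- fit_voxelwise_pipeline(zv)
    mean(abs(mm$maps$amide - ph$truth$amide)[ph$masks$tumor], na.rm = TRUE)
  }
  uncorrected <- err_of(z)
  corrected <- err_of(apply_b0_correction(z, estimate_b0_two_pool(z)))
  expect_lt(corrected, 0.2 * uncorrected)
})
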