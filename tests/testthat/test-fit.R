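test_that("background fit recovers a noise-free two-pool spectrum", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- list(c = 1.02, water = lorentzian_line(0.82, 2.4, 0.1),
                mt = lorentzian_line(0.17, 45, -1.2))
  z <- simulate_zspectrum(pools, offs)
  bg <- fit_background(z, offs)
  expect_true(bg$converged)
  expect_identical(bg$n_points, 21L)
  expect_equal(bg$c, 1.02, tolerance = 1e-4)
  expect_equal(bg$water$amplitude, 0.82, tolerance = 1e-4)
  expect_equal(bg$water$fwhm, 2.4, tolerance = 1e-4)
  expect_equal(bg$water$center, 0.1, tolerance = 1e-4)
  expect_equal(bg$mt$amplitude, 0.17, tolerance = 1e-4)
  expect_equal(bg$mt$center, -1.2, tolerance = 1e-4)
})

test_that("background fit uses only the background offsets", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- list(c = 1, water = lorentzian_line(0.8, 2.2, 0),
                mt = lorentzian_line(0.15, 40, -1))
  z <- simulate_zspectrum(pools, offs)
  bg0 <- fit_background(z, offs)
  # corrupting every non-background offset must leave the fit untouched
  zcor <- z
  bgset <- background_offsets("all")
  nonbg <- !vapply(offs, function(o) any(abs(o - bgset) < 1e-9), logical(1))
  zcor[nonbg] <- 99
  bg1 <- fit_background(zcor, offs)
  expect_identical(bg1$par, bg0$par)
})

test_that("background fit degenerates sensibly and errors on short input", {
  offs <- spectral_offsets(build_default_offset_schedule())
  flat <- rep(1, length(offs))
  bg <- fit_background(flat, offs)
  expect_equal(bg$c, 1, tolerance = 0.05)
  expect_lt(bg$water$amplitude, 0.05)
  expect_lt(bg$mt$amplitude, 0.05)
  expect_lt(bg$residual_rms, 0.01)
  expect_error(fit_background(rep(1, 5), c(0, 0.25, -0.25, 10, -10)),
               "fewer than 8")
})

test_that("solver objective is non-increasing across iterations", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- tumor_pools()
  z <- simulate_zspectrum(pools, offs)
  bg <- fit_background(z, offs)
  expect_true(all(diff(bg$rss_trace) <= 1e-12))
  cf <- fit_cest_pools(compute_mtr_ld(z, offs, bg))
  expect_true(all(diff(cf$rss_trace) <= 1e-12))
})

test_that("Lorentzian-difference spectrum isolates the CEST peaks", {
  offs <- spectral_offsets(build_default_offset_schedule())
  bgpools <- list(c = 1, water = lorentzian_line(0.8, 2.2, 0),
                  mt = lorentzian_line(0.15, 40, -1))
  zbg <- simulate_zspectrum(bgpools, offs)
  bg <- fit_background(zbg, offs)
  # Z equal to the background model: difference is identically ~0
  mld0 <- compute_mtr_ld(zbg, offs, bg)
  expect_lt(max(abs(mld0$values)), 1e-6)
  # add an amide dip of depth 0.05: the difference peaks at ~0.05 at +3.5
  full <- bgpools
  full$amide <- lorentzian_line(0.05, 1.1, 3.5)
  zfull <- simulate_zspectrum(full, offs)
  mld <- compute_mtr_ld(zfull, offs, fit_background(zfull, offs))
  i35 <- match_near(3.5, offs)
  expect_lt(abs(mld$values[i35] - 0.05), 0.003)
  expect_equal(which.max(mld$values), i35)
  # background offsets lie on the reference: difference ~0 at +/-100 ppm
  i100 <- c(match_near(100, offs), match_near(-100, offs))
  expect_lt(max(abs(mld$values[i100])), 5e-3)
})

test_that("three-pool fit recovers noise-free lines, including overlap", {
  offs <- spectral_offsets(build_default_offset_schedule())
  make_mld <- function(a1, g1, a2, g2, a3, g3) {
    eval_standard_line(offs, lorentzian_line(a1, g1, 3.5)) +
      eval_standard_line(offs, lorentzian_line(a2, g2, 2.0)) +
      eval_standard_line(offs, lorentzian_line(a3, g3, -3.5))
  }
  cf <- fit_cest_pools(make_mld(0.05, 1.1, 0.02, 1.8, 0.06, 2.5),
                       offsets_ppm = offs)
  expect_true(cf$converged)
  expect_equal(cf$amide$amplitude, 0.05, tolerance = 1e-4)
  expect_equal(cf$amine$amplitude, 0.02, tolerance = 1e-4)
  expect_equal(cf$noe$amplitude, 0.06, tolerance = 1e-4)
  expect_equal(cf$c, 0, tolerance = 1e-5)
  # zero spectrum: everything collapses to zero
  cf0 <- fit_cest_pools(rep(0, length(offs)), offsets_ppm = offs)
  expect_lt(cf0$amide$amplitude, 1e-6)
  expect_lt(abs(cf0$c), 1e-8)
  # heavily overlapping amide/amine (both width 1.5): within 5% of truth
  cfo <- fit_cest_pools(make_mld(0.05, 1.5, 0.03, 1.5, 0.05, 2.5),
                        offsets_ppm = offs)
  expect_equal(cfo$amide$amplitude, 0.05, tolerance = 0.05 * 0.05)
  expect_equal(cfo$amine$amplitude, 0.03, tolerance = 0.05 * 0.03)
})

test_that("voxelwise pipeline recovers a noiseless phantom to < 1e-3 absolute", {
  ph <- quiet_phantom(grid = c(14, 14), seed = 61)
  z <- normalize_to_zspectrum(ph$saturated_stack, NULL, ph$schedule,
                              ph$masks$brain)
  zc <- apply_b0_correction(z, estimate_b0_two_pool(z))
  mm <- fit_voxelwise_pipeline(zc)
  expect_equal(mm$convergence_fraction, 1)
  for (p in c("ds", "mt", "amide", "amine", "noe")) {
    err <- abs(mm$maps[[p]] - ph$truth[[p]])[ph$masks$brain]
    expect_lt(max(err), 1e-3)
  }
  # bookkeeping: fitted voxels = mask minus failures
  expect_identical(sum(!is.na(mm$maps$ds)), sum(mm$mask) - mm$n_failed)
})

test_that("staged-only and refined estimates agree on well-separated pools", {
  # the joint refinement corrects CEST tail bias; for DS (large, well
  # determined) the two routes must already agree closely
  ph <- quiet_phantom(grid = c(12, 12), seed = 71, jitter = 0)
  z <- normalize_to_zspectrum(ph$saturated_stack, NULL, ph$schedule,
                              ph$masks$tumor)
  zc <- apply_b0_correction(z, estimate_b0_two_pool(z))
  staged <- fit_voxelwise_pipeline(zc, fit_options(refine = FALSE))
  refined <- fit_voxelwise_pipeline(zc)
  i <- ph$masks$tumor
  expect_equal(staged$maps$ds[i], refined$maps$ds[i], tolerance = 0.02)
  # and the refinement must not be worse for any pool
  for (p in c("ds", "mt", "amide", "amine", "noe")) {
    e_staged <- mean(abs(staged$maps[[p]] - ph$truth[[p]])[i])
    e_ref <- mean(abs(refined$maps[[p]] - ph$truth[[p]])[i])
    expect_lte(e_ref, e_staged + 1e-6)
  }
})
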