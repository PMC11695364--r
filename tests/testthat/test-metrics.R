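test_that("MTR asymmetry is zero on symmetric spectra and does the arithmetic", {
  offs <- spectral_offsets(build_default_offset_schedule())
  sym <- simulate_zspectrum(list(c = 1, water = lorentzian_line(0.8, 2, 0)),
                            offs)
  z <- spectra_volume(rbind(sym))
  expect_equal(as.vector(mtr_asym(z, 3.5))[1], 0, tolerance = 1e-12)
  # direct arithmetic: Z(-3.5)=0.70, Z(+3.5)=0.65 -> 0.05
  zm <- sym
  zm[match_near(-3.5, offs)] <- 0.70
  zm[match_near(3.5, offs)] <- 0.65
  z2 <- spectra_volume(rbind(zm))
  expect_equal(as.vector(mtr_asym(z2, 3.5))[1], 0.05)
  expect_error(mtr_asym(z2, 400), "outside")
})

test_that("asymmetry signs follow the defining formula (Z(-x) - Z(+x))", {
  offs <- spectral_offsets(build_default_offset_schedule())
  base <- list(c = 1, water = lorentzian_line(0.8, 2.2, 0),
               mt = lorentzian_line(0.15, 40, -1))
  amide_only <- base; amide_only$amide <- lorentzian_line(0.05, 1.1, 3.5)
  noe_only <- base; noe_only$noe <- lorentzian_line(0.06, 2.5, -3.5)
  za <- spectra_volume(rbind(simulate_zspectrum(amide_only, offs)))
  zn <- spectra_volume(rbind(simulate_zspectrum(noe_only, offs)))
  # an amide dip deepens Z(+3.5), so Z(-3.5) - Z(+3.5) > 0; NOE mirrors it.
  # (the MT line at -1 ppm also contributes negative asymmetry, which the
  # amide term must dominate at +3.5)
  expect_gt(mtr_asym(za, 3.5)[1, 1], 0)
  expect_lt(mtr_asym(zn, 3.5)[1, 1], 0)
})

test_that("asymmetry is antisymmetric under spectral mirroring", {
  offs <- spectral_offsets(build_default_offset_schedule())
  pools <- tumor_pools()
  zf <- simulate_zspectrum(pools, offs)
  # mirror: evaluate the same spectrum at -offsets
  zm <- simulate_zspectrum(pools, -offs)
  a_f <- mtr_asym(spectra_volume(rbind(zf)), 3.5)[1, 1]
  a_m <- mtr_asym(spectra_volume(rbind(zm)), 3.5)[1, 1]
  expect_equal(a_f, -a_m, tolerance = 1e-12)
})

test_that("pH-weighted contrast grows with the amine pool", {
  offs <- spectral_offsets(build_default_offset_schedule())
  amps <- seq(0.005, 0.05, length.out = 6)
  vals <- sapply(amps, function(a) {
    pools <- tumor_pools(amine = a)
    ph_weighted_map(spectra_volume(rbind(simulate_zspectrum(pools, offs))))[1, 1]
  })
  expect_true(all(diff(vals) > 0))
})

test_that("pH sigmoid is monotone and inverts exactly in both readings", {
  # kappa differs by reading: it is a midpoint pH for the difference form
  # but a scale factor for the printed product form (where kappa * pH must
  # keep the base-10 exponent in a representable range)
  cals <- list(
    product = ph_calibration(alpha = -0.05, beta = 0.08,
                             delta_slope = 1.6, kappa = -0.12),
    difference = ph_calibration(alpha = -0.05, beta = 0.08,
                                delta_slope = 1.6, kappa = 6.8))
  for (form in names(cals)) {
    cal <- cals[[form]]
    ph <- seq(5.5, 8, length.out = 41)
    asym <- ph_sigmoid(ph, cal, form)
    expect_true(all(diff(asym) > 0) || all(diff(asym) < 0))
    back <- ph_from_asym(asym, cal, form)
    expect_equal(as.vector(back), ph, tolerance = 1e-10)
  }
  cal <- cals$difference
  # midpoint maps to the half-way asymmetry: exponent 0
  mid_ph_diff <- cal$kappa
  expect_equal(ph_sigmoid(mid_ph_diff, cal, "difference"),
               (cal$alpha + cal$beta) / 2)
  # boundary values are out of calibration
  expect_warning(out <- ph_from_asym(cal$alpha, cal), "out of calibration")
  expect_true(is.na(out[1]))
  expect_error(ph_calibration(0.1, 0.05, 1, 6), "beta")
})

test_that("histogram features match the closed-form percentile oracle", {
  m <- matrix(1:100, 10, 10)
  roi <- roi_mask("all", matrix(TRUE, 10, 10))
  f <- extract_histogram_features(m, roi, metric = "test")
  expect_equal(f$p10, 10.9)
  expect_equal(f$p25, 25.75)
  expect_equal(f$median, 50.5)
  expect_equal(f$p75, 75.25)
  expect_equal(f$p90, 90.1)
  expect_equal(f$mean, 50.5)
  expect_identical(f$n_voxels, 100L)
  # constant map: every feature equals the constant
  fc <- extract_histogram_features(matrix(7, 5, 5), matrix(TRUE, 5, 5))
  expect_true(all(fc[c("mean", "median", "p10", "p25", "p75", "p90")] == 7))
  # voxel-order invariance
  set.seed(9)
  v <- stats::rnorm(100)
  f1 <- extract_histogram_features(matrix(v, 10), matrix(TRUE, 10, 10))
  f2 <- extract_histogram_features(matrix(sample(v), 10), matrix(TRUE, 10, 10))
  expect_equal(f1[-1], f2[-1])
})

test_that("histogram percentile ordering holds on random maps", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(stats::rcauchy(64), 8, 8)  # heavy tails on purpose
    f <- extract_histogram_features(m, matrix(TRUE, 8, 8))
    expect_true(f$p10 <= f$p25 && f$p25 <= f$median &&
                  f$median <= f$p75 && f$p75 <= f$p90)
  }
})

test_that("histogram extraction enforces the minimum ROI size and exclusions", {
  m <- matrix(1, 4, 4)
  roi <- matrix(FALSE, 4, 4); roi[1:2, 1] <- TRUE
  expect_error(extract_histogram_features(m, roi), "fewer than")
  roi_ok <- matrix(TRUE, 4, 4)
  excl <- matrix(FALSE, 4, 4); excl[, 1] <- TRUE
  f <- extract_histogram_features(m, roi_ok, exclude = excl)
  expect_identical(f$n_voxels, 12L)
})
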