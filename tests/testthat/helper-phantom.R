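# shared fixtures, all generated in code

# small noise-free phantom with a flat B0 field
quiet_phantom <- function(grid = c(16, 16), noise = 0, b0 = rep(0, 6),
                          jitter = 0.1, seed = 101, ...) {
  generate_phantom(phantom_config(grid_shape = grid, noise_sd = noise,
                                  b0_coefficients = b0,
                                  amplitude_jitter = jitter, seed = seed,
                                  ...))
}

# canonical tumor-like pool set for single-spectrum tests
tumor_pools <- function(amide = 0.05, amine = 0.02, noe = 0.06,
                        ds = 0.78, mt = 0.15) {
  list(c = 1,
       water = lorentzian_line(ds, 2.2, 0),
       mt = lorentzian_line(mt, 40, -1),
       amide = if (amide > 0) lorentzian_line(amide, 1.1, 3.5),
       amine = if (amine > 0) lorentzian_line(amine, 1.8, 2.0),
       noe = if (noe > 0) lorentzian_line(noe, 2.5, -3.5))
}

# wrap a set of single-voxel spectra (rows) into a zspec_volume
spectra_volume <- function(zmat, schedule = build_default_offset_schedule()) {
  arr <- array(NA_real_, c(nrow(zmat), 1, ncol(zmat)))
  for (i in seq_len(nrow(zmat))) arr[i, 1, ] <- zmat[i, ]
  zspec_volume(arr, schedule)
}

match_near <- function(x, offs) which(abs(offs - x) < 1e-9)[1]

# smooth test image with structure at several scales, for registration
test_image <- function(nx = 48, ny = 48, seed = 3) {
  u <- matrix(rep(seq(-1, 1, length.out = nx), ny), nx, ny)
  v <- matrix(rep(seq(-1, 1, length.out = ny), each = nx), nx, ny)
  exp(-((u + 0.2)^2 + (v - 0.1)^2) / 0.08) +
    0.6 * exp(-((u - 0.4)^2 + (v + 0.3)^2) / 0.02) +
    0.3 * cos(4 * pi * u) * sin(3 * pi * v) * exp(-(u^2 + v^2))
}
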