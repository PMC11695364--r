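# internal helpers shared across modules

# run code with a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# translate a 2D image by (dx, dy) pixels via the Fourier shift theorem;
# periodic boundary, exact for band-limited content and any fractional shift
fourier_shift <- function(img, dx, dy) {
  nx <- nrow(img); ny <- ncol(img)
  kx <- c(0:floor(nx / 2), -(ceiling(nx / 2) - 1):-1)[1:nx] / nx
  ky <- c(0:floor(ny / 2), -(ceiling(ny / 2) - 1):-1)[1:ny] / ny
  # Nyquist bin must stay real for even sizes
  if (nx %% 2 == 0) kx[nx / 2 + 1] <- 0
  if (ny %% 2 == 0) ky[ny / 2 + 1] <- 0
  phase <- exp(-2i * pi * (outer(kx * dx, ky * dy, "+")))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nx * ny)
}

# match requested offsets against a schedule's offsets within tolerance;
# returns indices into `offsets` (NA where absent)
match_offsets <- function(wanted, offsets, tol = 1e-6) {
  vapply(wanted, function(w) {
    i <- which(abs(offsets - w) < tol)
    if (length(i) == 0L) NA_integer_ else i[1]
  }, integer(1))
}
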