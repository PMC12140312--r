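test_that("angular-spectrum propagation is unitary and invertible", {
  x <- seeded_matrix(64, seed = 3, complex = TRUE)
  fld <- complex_field(x, pixel_pitch_um = 1, wavelength_um = 0.532)
  expect_identical(angular_spectrum_propagate(fld, 0)$values, fld$values)

  fwd <- angular_spectrum_propagate(fld, 200)
  back <- angular_spectrum_propagate(fwd, -200)
  expect_lt(max(Mod(back$values - x)), 1e-10)
  # energy conservation (whole grid propagates at this pitch/wavelength)
  expect_lt(abs(sum(Mod(fwd$values)^2) - sum(Mod(x)^2)) / sum(Mod(x)^2),
            1e-10)
  expect_error(angular_spectrum_propagate(fld, NaN), "finite")
})

test_that("evanescent components are removed, propagating ones preserved", {
  # coarse sampling: part of the frequency grid is evanescent
  x <- seeded_matrix(32, seed = 5, complex = TRUE)
  fld <- complex_field(x, pixel_pitch_um = 0.4, wavelength_um = 1.0)
  out <- angular_spectrum_propagate(fld, 50)
  fg <- make_frequency_grid(c(32, 32), 0.4)
  evan <- 1 - (fld$wavelength_um * fg$fx)^2 - (fld$wavelength_um * fg$fy)^2 <= 0
  spec_out <- cfft2(out$values)
  expect_lt(max(Mod(spec_out[evan])), 1e-12)
  spec_in <- cfft2(x)
  expect_lt(max(abs(Mod(spec_out[!evan]) - Mod(spec_in[!evan]))), 1e-10)
})

test_that("Gaussian beam spreads by the analytic width law within 2%", {
  n <- 256; pitch <- 0.5; lambda <- 0.532; w0 <- 10; z <- 200
  yy <- (seq_len(n) - (n / 2 + 1)) * pitch
  r2 <- outer(yy^2, yy^2, `+`)
  fld <- complex_field(exp(-r2 / w0^2) + 0i, pitch, lambda)
  out <- angular_spectrum_propagate(fld, z)
  I <- Mod(out$values)^2
  # FWHM of the central row -> waist w(z); I ~ exp(-2 r^2 / w^2).
  # Sub-pixel: linearly interpolate the half-maximum crossings.
  row <- I[n / 2 + 1, ]
  half <- max(row) / 2
  above <- which(row >= half)
  lo <- min(above); hi <- max(above)
  frac_lo <- (row[lo - 1] - half) / (row[lo - 1] - row[lo])
  frac_hi <- (row[hi + 1] - half) / (row[hi + 1] - row[hi])
  fwhm <- ((hi + 1 - frac_hi) - (lo - 1 + frac_lo)) * pitch
  w_meas <- fwhm / sqrt(2 * log(2))
  w_true <- w0 * sqrt(1 + (z * lambda / (pi * w0^2))^2)
  expect_lt(abs(w_meas - w_true) / w_true, 0.02)
})

test_that("FPM forward matches physics limits and the DFT oracle", {
  sys <- tiny_fpm_system(hi = 64, n_side = 3)
  P <- fpm_ideal_pupil(sys)
  # delta at DC (uniform object), on-axis LED -> uniform unit intensity
  Xu <- cfft2(matrix(1 + 0i, 64, 64))
  onax <- which.min(rowSums(sys$led_kvectors^2))
  Iu <- fpm_forward(Xu, P, sys, onax)
  expect_lt(max(abs(Iu - 1)), 1e-12)

  # pure tilt beyond the pupil cutoff is rejected by the aperture
  q_px <- ceiling(P$cutoff_radius_px + max(abs(sys$shifts_px)) + 2)
  tilt <- exp(2i * pi * q_px * (seq_len(64) - 1) / 64)
  Xt <- cfft2(matrix(tilt, 64, 64, byrow = TRUE))
  for (n in seq_len(sys$n_leds))
    expect_lt(sum(fpm_forward(Xt, P, sys, n)), 1e-12 * sum(Mod(Xt)^2))

  # seeded random object vs literal direct-summation DFT (9 LEDs)
  X <- cfft2(seeded_matrix(64, seed = 11, complex = TRUE))
  for (n in c(2, 5)) {
    I_fast <- fpm_forward(X, P, sys, n)
    I_oracle <- fpm_dft_oracle(X, P, sys, n)
    expect_lt(max(abs(I_fast - I_oracle)) / max(I_oracle), 1e-9)
  }
})

test_that("FPM with ideal pupil on-axis is a low-pass plus downsample", {
  sys <- tiny_fpm_system(hi = 64, n_side = 3)
  P <- fpm_ideal_pupil(sys)
  # band-limited object whose spectrum fits strictly inside the pupil
  lo <- sys$low_pixels
  ctr <- c(64, 64) %/% 2 + 1
  X <- matrix(0 + 0i, 64, 64)
  r <- P$cutoff_radius_px - 2
  for (dy in -3:3) for (dx in -3:3)
    if (dy^2 + dx^2 <= r^2 && dy^2 + dx^2 <= 9)
      X[ctr[1] + dy, ctr[2] + dx] <- seeded_matrix(8, seed = dy * 10 + dx + 50,
                                                   complex = TRUE)[1, 1]
  onax <- which.min(rowSums(sys$led_kvectors^2))
  I <- fpm_forward(X, P, sys, onax)
  # downsampled object intensity: object field on the low-res grid
  obj <- cifft2(X)
  s <- sqrt(prod(sys$low_pixels) / prod(sys$object_pixels))
  Xc <- X[(ctr[1] - lo[1] / 2):(ctr[1] + lo[1] / 2 - 1),
          (ctr[2] - lo[2] / 2):(ctr[2] + lo[2] / 2 - 1)]
  expected <- Mod(cifft2(Xc) * s)^2
  expect_lt(max(abs(I - expected)) / max(expected), 1e-9)
})

test_that("pupil masking never increases spectral energy", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  P <- fpm_ideal_pupil(sys)
  for (seed in 1:5) {
    patch <- seeded_matrix(16, seed = seed, complex = TRUE)
    expect_lte(sum(Mod(patch * P$values)^2), sum(Mod(patch)^2))
  }
})

test_that("spectrum shifts that escape the grid are rejected", {
  kv <- rbind(c(0, 0), c(0.35, 0))     # second LED shifts far outside
  expect_error(fpm_system(c(32, 32), 0.1, 0.532, 1, kv, 2), "crop margin")
  # a tampered shift table is still caught at forward time
  sys <- fpm_system(c(32, 32), 0.1, 0.532, 1, rbind(c(0, 0), c(0.1, 0)), 2)
  sys$shifts_px[2, ] <- c(30, 0)
  P <- fpm_ideal_pupil(sys)
  X <- cfft2(matrix(1 + 0i, 32, 32))
  expect_error(fpm_forward(X, P, sys, 2), "crop window")
})

test_that("coded-ptychography forward degenerates and composes correctly", {
  obj <- phantom_cell_blobs(c(32, 32), 6, c(0.5, 1), c(0, 1), seed = 7)
  pat1 <- complex_field(matrix(1 + 0i, 32, 32), 1, 0.532)
  shifts <- rbind(c(0, 0), c(3, -2))
  sys0 <- lensless_system(0, 0, pat1, shifts)
  fld <- complex_field(obj, 1, 0.532)
  # d1 = d2 = 0, unit pattern, zero shift: output is |object|^2
  expect_lt(max(abs(coded_ptych_forward(fld, sys0, 1) - Mod(obj)^2)), 1e-12)

  # shift equivariance when the pattern is uniform
  sysd <- lensless_system(500, 1000, pat1, shifts)
  I0 <- coded_ptych_forward(fld, sysd, 1)
  I1 <- coded_ptych_forward(fld, sysd, 2)
  expect_lt(max(abs(I1 - fdpr:::.circshift(I0, 3, -2))), 1e-10)

  # seeded random object/pattern vs explicit stage composition
  set.seed(9)
  pat <- complex_field(exp(1i * pi * matrix(runif(32 * 32) < 0.5, 32)), 1, 0.532)
  sys2 <- lensless_system(500, 1000, pat, shifts)
  I <- coded_ptych_forward(fld, sys2, 2)
  stage <- angular_spectrum_propagate(
    complex_field(fdpr:::.circshift(obj, 3, -2), 1, 0.532), 500)
  stage$values <- stage$values * pat$values
  I_oracle <- Mod(angular_spectrum_propagate(stage, 1000)$values)^2
  expect_lt(max(abs(I - I_oracle)), 1e-10)

  expect_error(lensless_system(0, 0, pat1, rbind(c(0, 0), c(20, 0))),
               "half the pattern")
})

test_that("inline holograms conserve energy and show Fresnel fringes", {
  # pure phase object at zero distance is invisible
  obj <- phantom_phase_disk(c(64, 64), 8, 0.5)
  fld <- complex_field(obj, 1, 0.532)
  expect_lt(max(abs(inline_holo_forward(fld, 0) - 1)), 1e-12)

  holo <- inline_holo_forward(fld, 300)
  expect_lt(abs(sum(holo) - sum(Mod(obj)^2)) / sum(Mod(obj)^2), 1e-10)

  # values match the explicit two-stage oracle exactly
  oracle <- Mod(angular_spectrum_propagate(fld, 300)$values)^2
  expect_identical(holo, oracle)
  # fringes: the hologram deviates from unity away from the disk
  expect_gt(max(abs(holo - 1)), 0.05)
})

test_that("LED wave-vectors follow the planar-array geometry", {
  kv <- led_grid_kvectors(3, 2000, 50000, 0.5)
  expect_equal(nrow(kv), 9)
  expect_equal(unname(kv[1, ]), c(0, 0))           # on-axis LED first
  # corner LED: sin(theta) = r / sqrt(r^2 + h^2), split into components
  r <- 2000 * sqrt(2); h <- 50000
  expect_equal(unname(sqrt(sum(kv[9, ]^2))), r / sqrt(r^2 + h^2) / 0.5,
               tolerance = 1e-12)
})
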