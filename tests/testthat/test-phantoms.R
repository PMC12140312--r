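test_that("USAF target renders binary bars at the chart geometry", {
  els <- data.frame(group = 7, element = c(1, 3))
  tgt <- make_usaf_target(c(256, 256), 1, els, background = 1,
                          foreground = 0)
  expect_true(all(tgt$amplitude %in% c(0, 1)))
  # bar width = round(width_um / pitch)
  expect_equal(tgt$geometry$width_px,
               round(vapply(seq_len(2), function(i)
                 usaf_linewidth(7, els$element[i])$width_um, 0) / 1))
  # (g = 7, e = 1) at 1 um pitch: 3.91 um line width -> 4 px bars
  expect_equal(tgt$geometry$width_px[1], 4)
  expect_equal(tgt$geometry$width_um[1], 500 / 2^7, tolerance = 1e-12)
  # unresolvable widths are rejected
  expect_error(make_usaf_target(c(256, 256), 1,
                                data.frame(group = 9, element = 3)),
               "below 2 px")
})

test_that("Zernike pupil screens satisfy their construction contract", {
  # all-zero coefficients: flat phase
  z0 <- make_zernike_pupil_phase(c(32, 32), 12, orders = 15,
                                 coefficients = rep(0, 15))
  expect_equal(max(abs(z0)), 0)

  # exact peak-to-valley rescaling on the disk
  for (seed in c(1, 21)) {
    z <- make_zernike_pupil_phase(c(32, 32), 12, orders = 15, seed = seed,
                                  target_pv_rad = 4 * pi)
    disk <- fdpr:::.radius_grid_px(c(32, 32)) <= 12
    expect_equal(max(z[disk]) - min(z[disk]), 4 * pi, tolerance = 1e-9)
    expect_equal(max(abs(z[!disk])), 0)
  }

  # discrete orthogonality of the first 15 modes on a 256^2 disk
  dims <- c(256, 256); cutoff <- 120
  disk <- fdpr:::.radius_grid_px(dims) <= cutoff
  basis <- lapply(1:15, function(j) {
    cf <- rep(0, 15); cf[j] <- 1
    make_zernike_pupil_phase(dims, cutoff, orders = 15,
                             coefficients = cf)[disk]
  })
  G <- crossprod(do.call(cbind, basis))
  offdiag <- abs(G - diag(diag(G)))
  expect_lt(max(offdiag / sqrt(outer(diag(G), diag(G)))), 0.02)

  expect_error(make_zernike_pupil_phase(c(32, 32), -1), "disk")
})

test_that("FPM simulation honors symmetry, counts and the vignette model", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  flat <- simulate_fpm_dataset(matrix(1, 32, 32), matrix(0, 32, 32), sys,
                               degrade = degradation_none())
  expect_length(flat$observation$frames, sys$n_leds)
  expect_true(all(vapply(flat$observation$frames, min, 0) >= 0))
  # flat object, ideal pupil: all brightfield frames identical
  illum_na <- 0.532 * sqrt(rowSums(sys$led_kvectors^2))
  bf <- which(illum_na < sys$objective_na * 0.9)
  if (length(bf) > 1)
    for (i in bf[-1])
      expect_equal(flat$observation$frames[[i]],
                   flat$observation$frames[[bf[1]]], tolerance = 1e-12)

  # half-plane vignette: strong left/right asymmetry on an oblique frame
  deg <- degradation_spec("half_plane", vignette_strength = 1,
                          poisson_photons = Inf, gaussian_sigma = 0)
  sim <- simulate_fpm_dataset(matrix(1, 32, 32), matrix(0, 32, 32), sys,
                              degrade = deg)
  # frame with +kx illumination: right half of its mask is dark
  ix <- which(sys$led_kvectors[, 1] > 0 &
                abs(sys$led_kvectors[, 2]) < 1e-9)[1]
  mask <- sim$truth$masks[[ix]]
  m <- ncol(mask)
  left <- mean(mask[, 1:(m %/% 2 - 1)])
  right <- mean(mask[, (m %/% 2 + 2):m])
  expect_gt(max(left, right) / max(min(left, right), 1e-12), 5)

  expect_error(
    simulate_fpm_dataset(matrix(1, 32, 32), matrix(0, 32, 32), sys,
                         degrade = degradation_spec(poisson_photons = -5)),
    "poisson")
})

test_that("inline hologram simulation conserves energy before noise", {
  obj <- matrix(1 + 0i, 64, 64)
  sim <- simulate_inline_hologram(obj, 300, 1, 0.532, degradation_none())
  expect_lt(max(abs(sim$observation$frames[[1]] - 1)), 1e-12)

  disk <- phantom_phase_disk(c(128, 128), 8, 0.5)
  sim2 <- simulate_inline_hologram(disk, 300, 1, 0.532, degradation_none())
  holo <- sim2$observation$frames[[1]]
  expect_lt(abs(sum(holo) - sum(Mod(disk)^2)) / sum(Mod(disk)^2), 1e-10)

  # first diffraction ring near the Fresnel-zone radius sqrt(lambda z)
  prof <- holo[65, 65:128] - 1
  r_first <- which.max(abs(prof[9:60])) + 8 - 1     # px beyond the disk edge
  fresnel <- sqrt(0.532 * 300)
  measured <- r_first
  expect_lt(abs(measured - fresnel) / fresnel, 0.35)
})

test_that("coded-ptychography simulation meets its pattern contract", {
  obj <- phantom_cell_blobs(c(256, 256), 10, c(0.5, 1), c(0, 0.5), seed = 3)
  sim <- simulate_coded_dataset(complex_field(obj, 1, 0.532),
                                n_shifts = 4, degrade = degradation_none(),
                                seed = 7)
  phase <- Arg(sim$truth$pattern)
  expect_true(all(abs(phase) < 1e-12 | abs(phase - pi) < 1e-12))
  frac <- mean(abs(phase - pi) < 1e-12)
  expect_lt(abs(frac - 0.5), 0.02)

  # a zero-shift frame equals the direct forward of the unshifted object
  iz <- which(rowSums(abs(sim$sys$scan_shifts_px)) == 0)
  if (length(iz))
    expect_equal(sim$observation$frames[[iz[1]]],
                 coded_ptych_forward(complex_field(obj, 1, 0.532),
                                     sim$sys, iz[1]))
  expect_error(simulate_coded_dataset(complex_field(obj, 1, 0.532),
                                      n_shifts = 1), "n_shifts")
})

test_that("simulators regenerate bit-exactly from their truth records", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  deg <- degradation_spec("half_plane", background_order = 2,
                          background_amplitude = 0.3,
                          poisson_photons = 1e4, gaussian_sigma = 0.01,
                          seed = 77)
  s1 <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                             pupil_phase = NULL, degrade = deg)
  s2 <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                             pupil_phase = NULL, degrade = s1$truth$degrade)
  expect_identical(s1$observation$frames, s2$observation$frames)

  c1 <- simulate_coded_dataset(phantom_phase_disk(c(32, 32), 6, 0.5),
                               n_shifts = 4, seed = 5,
                               degrade = degradation_spec(seed = 3))
  c2 <- simulate_coded_dataset(phantom_phase_disk(c(32, 32), 6, 0.5),
                               n_shifts = 4, seed = 5,
                               degrade = degradation_spec(seed = 3))
  expect_identical(c1$observation$frames, c2$observation$frames)
})

test_that("phantom generators respect their declared ranges", {
  w <- phantom_wheel_phase(c(64, 64), spokes = 6, phase_rad = 1.2)
  expect_true(all(Mod(Mod(w) - 1) < 1e-12))       # pure phase
  expect_setequal(round(unique(as.vector(Arg(w))), 6), c(0, 1.2))

  b <- phantom_cell_blobs(c(64, 64), 8, c(0.4, 0.9), c(0, 0.7), seed = 2)
  expect_true(all(Mod(b) >= 0.4 - 1e-9 & Mod(b) <= 0.9 + 1e-9))
  expect_true(all(Arg(b) >= -1e-9 & Arg(b) <= 0.7 + 1e-9))
  expect_identical(b, phantom_cell_blobs(c(64, 64), 8, c(0.4, 0.9),
                                         c(0, 0.7), seed = 2))
})
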