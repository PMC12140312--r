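# Synthetic phantoms and dataset generators emulating the experimental
# conditions: LED-array FPM stacks with pupil aberrations and vignetting,
# coded-ptychography scan series, single-shot inline holograms, each with
# mixed Poisson-Gaussian noise and a ground-truth record sufficient to
# regenerate the frames bit-exactly.

# ---- simple phantoms -------------------------------------------------------

#' Phase-disk phantom
#'
#' Unit-amplitude field with a uniform phase step on a centered disk.
#'
#' @param dims grid dimensions (even).
#' @param radius_px disk radius in pixels.
#' @param phase_rad phase step height (rad).
#' @return complex matrix.
#' @export
phantom_phase_disk <- function(dims, radius_px, phase_rad = 0.5) {
  .assert_even_dims(dims, "phantom")
  r <- .radius_grid_px(dims)
  exp(1i * phase_rad * (r <= radius_px))
}

#' Wheel-like pure-phase phantom
#'
#' Alternating angular spokes inside a rim: the spoke-wheel test object used
#' to probe twin-image suppression in inline holography.
#'
#' @param dims grid dimensions (even).
#' @param spokes number of spoke pairs.
#' @param phase_rad spoke phase height (rad).
#' @param radius_frac wheel radius as a fraction of the half-extent.
#' @return complex matrix (unit amplitude).
#' @export
phantom_wheel_phase <- function(dims, spokes = 8L, phase_rad = 1,
                                radius_frac = 0.8) {
  .assert_even_dims(dims, "phantom")
  cy <- dims[1L] / 2 + 1L; cx <- dims[2L] / 2 + 1L
  yy <- matrix(seq_len(dims[1L]) - cy, dims[1L], dims[2L])
  xx <- matrix(seq_len(dims[2L]) - cx, dims[1L], dims[2L], byrow = TRUE)
  r <- sqrt(yy^2 + xx^2)
  th <- atan2(yy, xx)
  rim <- radius_frac * min(dims) / 2
  hub <- 0.15 * rim
  wedge <- (sin(spokes * th) > 0) & r <= rim & r >= hub
  exp(1i * phase_rad * wedge)
}

#' Random cell-like blob phantom
#'
#' Seeded sum of Gaussian blobs mapped into the requested amplitude and
#' phase ranges; a stand-in for unstained cell samples.
#'
#' @param dims grid dimensions (even).
#' @param n_blobs number of blobs.
#' @param amplitude_range length-2 range of amplitudes.
#' @param phase_range length-2 range of phases (rad).
#' @param seed RNG seed.
#' @return complex matrix.
#' @export
phantom_cell_blobs <- function(dims, n_blobs = 12L,
                               amplitude_range = c(0.6, 1),
                               phase_range = c(0, 1), seed = 1L) {
  .assert_even_dims(dims, "phantom")
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  acc <- matrix(0, dims[1L], dims[2L])
  yy <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  xx <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  for (b in seq_len(n_blobs)) {
    cy <- stats::runif(1, 0.15, 0.85) * dims[1L]
    cx <- stats::runif(1, 0.15, 0.85) * dims[2L]
    sg <- stats::runif(1, 0.03, 0.1) * min(dims)
    acc <- acc + exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sg^2))
  }
  acc <- acc / max(acc)
  amp <- amplitude_range[1L] + diff(amplitude_range) * acc
  ph <- phase_range[1L] + diff(phase_range) * acc
  amp * exp(1i * ph)
}

# ---- USAF-1951 target ------------------------------------------------------

#' Render a USAF-1951 style resolution target
#'
#' Lays out three-bar elements (a vertical-bar and a horizontal-bar block
#' per element) on an amplitude grid at the requested pixel pitch. Bar
#' widths follow the chart formula (see [usaf_linewidth()]); each element's
#' pixel geometry is returned in a table.
#'
#' @param dims grid dimensions (even).
#' @param pitch_um pixel pitch of the grid (um).
#' @param elements data.frame with columns `group` and `element`.
#' @param background,foreground amplitude values outside/inside the bars.
#' @return list with `amplitude` (matrix with values in
#'   `{background, foreground}`) and `geometry` (data.frame: group, element,
#'   width_um, width_px, row0, col0, row1, col1).
#' @export
make_usaf_target <- function(dims, pitch_um, elements,
                             background = 1, foreground = 0) {
  .assert_even_dims(dims, "target")
  amp <- matrix(background, dims[1L], dims[2L])
  geo <- NULL
  row_cursor <- max(4L, dims[1L] %/% 16L)
  for (i in seq_len(nrow(elements))) {
    g <- elements$group[i]; e <- elements$element[i]
    w_um <- usaf_linewidth(g, e)$width_um
    w <- round(w_um / pitch_um)
    if (w < 2)
      stop(sprintf("group %d element %d: bar width %.3g um is below 2 px at %.3g um pitch",
                   g, e, w_um, pitch_um), call. = FALSE)
    len <- 5L * w
    need_rows <- max(len, 5L * w) + w
    col0 <- max(4L, dims[2L] %/% 16L)
    if (row_cursor + need_rows > dims[1L] ||
        col0 + len + 2L * w + 5L * w > dims[2L])
      stop(sprintf("group %d element %d does not fit on a %dx%d grid",
                   g, e, dims[1L], dims[2L]), call. = FALSE)
    # vertical bars: 3 bars of width w, length 5w, separated by w
    for (b in 0:2) {
      c0 <- col0 + b * 2L * w
      amp[row_cursor:(row_cursor + len - 1L), c0:(c0 + w - 1L)] <- foreground
    }
    # horizontal bars to the right
    hcol <- col0 + len + 2L * w
    for (b in 0:2) {
      r0 <- row_cursor + b * 2L * w
      amp[r0:(r0 + w - 1L), hcol:(hcol + len - 1L)] <- foreground
    }
    geo <- rbind(geo, data.frame(group = g, element = e, width_um = w_um,
                                 width_px = w, row0 = row_cursor, col0 = col0,
                                 row1 = row_cursor + need_rows - 1L,
                                 col1 = hcol + len - 1L))
    row_cursor <- row_cursor + need_rows + w
  }
  list(amplitude = amp, geometry = geo)
}

# ---- Zernike pupil phase ---------------------------------------------------

# OSA/ANSI single index -> (n, m)
.zernike_nm <- function(j) {
  n <- ceiling((-3 + sqrt(9 + 8 * j)) / 2)
  m <- 2 * j - n * (n + 2)
  c(n = n, m = m)
}

# one normalized Zernike polynomial on rho <= 1
.zernike_eval <- function(n, m, rho, theta) {
  am <- abs(m)
  R <- matrix(0, nrow(rho), ncol(rho))
  for (k in 0:((n - am) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) *
         factorial((n - am) / 2 - k)) * rho^(n - 2 * k)
  }
  norm <- sqrt((2 * (n + 1)) / (1 + (m == 0)))
  z <- if (m >= 0) R * cos(am * theta) else R * sin(am * theta)
  norm * z
}

#' Zernike pupil phase screen
#'
#' Builds a pupil phase from the first `orders` Zernike polynomials in
#' OSA/ANSI indexing (piston excluded: indices 1..orders). Coefficients are
#' either supplied or drawn uniformly from [-1, 1] under the seed, then the
#' whole screen is rescaled so that its peak-to-valley over the NA disk
#' equals `target_pv_rad` exactly (a constant screen is left untouched).
#'
#' @param dims pupil grid dimensions (even).
#' @param cutoff_radius_px NA-disk radius in pixels.
#' @param orders number of Zernike modes (default 15).
#' @param coefficients optional numeric vector of length `orders`.
#' @param seed RNG seed used when coefficients are drawn.
#' @param target_pv_rad requested peak-to-valley (rad); `NULL` skips the
#'   rescaling.
#' @return matrix of phases (rad), zero outside the disk; attributes
#'   `"coefficients"` and `"cutoff_radius_px"` record the construction.
#' @export
make_zernike_pupil_phase <- function(dims, cutoff_radius_px, orders = 15L,
                                     coefficients = NULL, seed = 1L,
                                     target_pv_rad = NULL) {
  .assert_even_dims(dims, "pupil")
  if (orders < 1L) stop("orders must be >= 1", call. = FALSE)
  if (!is.null(target_pv_rad) && target_pv_rad < 0)
    stop("target_pv_rad must be >= 0", call. = FALSE)
  r <- .radius_grid_px(dims)
  disk <- r <= cutoff_radius_px
  if (!any(disk)) stop("no pixels inside the NA disk", call. = FALSE)
  cy <- dims[1L] / 2 + 1L; cx <- dims[2L] / 2 + 1L
  yy <- matrix(seq_len(dims[1L]) - cy, dims[1L], dims[2L])
  xx <- matrix(seq_len(dims[2L]) - cx, dims[1L], dims[2L], byrow = TRUE)
  rho <- r / cutoff_radius_px
  theta <- atan2(yy, xx)
  if (is.null(coefficients)) {
    old <- .seed_swap(seed)
    coefficients <- stats::runif(orders, -1, 1)
    .seed_restore(old)
  }
  if (length(coefficients) != orders)
    stop("coefficients must have length orders", call. = FALSE)
  phase <- matrix(0, dims[1L], dims[2L])
  for (j in seq_len(orders)) {
    if (coefficients[j] == 0) next
    nm <- .zernike_nm(j)
    phase <- phase + coefficients[j] *
      .zernike_eval(nm["n"], nm["m"], rho, theta)
  }
  phase[!disk] <- 0
  pv <- max(phase[disk]) - min(phase[disk])
  if (!is.null(target_pv_rad) && pv > 0) {
    phase <- phase * (target_pv_rad / pv)
    coefficients <- coefficients * (target_pv_rad / pv)
  }
  structure(phase, coefficients = coefficients,
            cutoff_radius_px = cutoff_radius_px)
}

# ---- degradations ----------------------------------------------------------

#' Degradation specification for the simulators
#'
#' Applied in fixed order: vignette mask, polynomial background, Poisson
#' shot noise, additive Gaussian read noise (then a clamp at zero so frames
#' remain valid intensities).
#'
#' @param vignette `"none"`, `"half_plane"` (oblique frames lose a
#'   half-plane of light, the half-bright/half-dark pattern), or
#'   `"shifted_aperture"` (circular window whose center displaces linearly
#'   with illumination angle).
#' @param vignette_strength attenuation of the vignetted region in [0, 1]
#'   (1 = fully dark).
#' @param background_order polynomial order of a smooth multiplicative
#'   background (0 disables).
#' @param background_amplitude peak relative amplitude of the background.
#' @param poisson_photons full-scale photon count for shot noise
#'   (`NULL` or `Inf` disables; must be > 0).
#' @param gaussian_sigma additive Gaussian sigma, relative to full scale
#'   (0 disables).
#' @param seed RNG seed for all noise draws.
#' @return object of class `degradation_spec`.
#' @export
degradation_spec <- function(vignette = c("none", "half_plane",
                                          "shifted_aperture"),
                             vignette_strength = 1,
                             background_order = 0L, background_amplitude = 0,
                             poisson_photons = 1e4, gaussian_sigma = 0.01,
                             seed = 1L) {
  vignette <- match.arg(vignette)
  if (vignette_strength < 0 || background_amplitude < 0 || gaussian_sigma < 0)
    stop("degradation strengths must be >= 0", call. = FALSE)
  if (!is.null(poisson_photons) && is.finite(poisson_photons) &&
      poisson_photons <= 0)
    stop("poisson_photons must be > 0", call. = FALSE)
  structure(list(vignette = vignette, vignette_strength = vignette_strength,
                 background_order = as.integer(background_order),
                 background_amplitude = background_amplitude,
                 poisson_photons = poisson_photons,
                 gaussian_sigma = gaussian_sigma, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Clean degradation (no corruption at all)
#' @return a [degradation_spec()] with every mechanism disabled.
#' @export
degradation_none <- function() {
  degradation_spec("none", background_amplitude = 0,
                   poisson_photons = Inf, gaussian_sigma = 0)
}

# vignette mask for one frame; sin_theta = lambda * (kx, ky)
.vignette_mask <- function(dims, degrade, sin_theta) {
  if (degrade$vignette == "none" || sqrt(sum(sin_theta^2)) < 1e-6)
    return(matrix(1, dims[1L], dims[2L]))
  cy <- dims[1L] / 2 + 1L; cx <- dims[2L] / 2 + 1L
  yy <- matrix(seq_len(dims[1L]) - cy, dims[1L], dims[2L])
  xx <- matrix(seq_len(dims[2L]) - cx, dims[1L], dims[2L], byrow = TRUE)
  if (degrade$vignette == "half_plane") {
    side <- xx * sin_theta[1L] + yy * sin_theta[2L]
    mask <- matrix(1, dims[1L], dims[2L])
    mask[side > 0] <- 1 - degrade$vignette_strength
    return(mask)
  }
  # shifted_aperture: circular window displaced along the illumination
  disp <- degrade$vignette_strength * min(dims) * sin_theta
  radius <- 0.75 * min(dims) / 2
  inside <- (xx + disp[1L])^2 + (yy + disp[2L])^2 <= radius^2
  mask <- matrix(1 - degrade$vignette_strength, dims[1L], dims[2L])
  mask[inside] <- 1
  mask
}

# smooth multiplicative polynomial background (deterministic given degrade)
.poly_background <- function(dims, degrade, frame_index) {
  if (degrade$background_order < 1L || degrade$background_amplitude == 0)
    return(matrix(1, dims[1L], dims[2L]))
  u <- matrix(seq_len(dims[1L]) / dims[1L] - 0.5, dims[1L], dims[2L])
  v <- matrix(seq_len(dims[2L]) / dims[2L] - 0.5, dims[1L], dims[2L],
              byrow = TRUE)
  old <- .seed_swap(degrade$seed + 7919L * frame_index)
  cf <- stats::runif((degrade$background_order + 1L)^2, -1, 1)
  .seed_restore(old)
  bg <- matrix(0, dims[1L], dims[2L])
  k <- 1L
  for (p in 0:degrade$background_order)
    for (q in 0:degrade$background_order) {
      bg <- bg + cf[k] * u^p * v^q
      k <- k + 1L
    }
  bg <- bg - min(bg)
  if (max(bg) > 0) bg <- bg / max(bg)
  1 + degrade$background_amplitude * (bg - 0.5)
}

# apply the full degradation pipeline to a list of frames
.apply_degradation <- function(frames, degrade, sin_thetas = NULL) {
  dims <- dim(frames[[1L]])
  n <- length(frames)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    st <- if (is.null(sin_thetas)) c(0, 0) else sin_thetas[i, ]
    masks[[i]] <- .vignette_mask(dims, degrade, st)
    frames[[i]] <- frames[[i]] * masks[[i]] *
      .poly_background(dims, degrade, i)
  }
  full_scale <- max(vapply(frames, max, 0), 1e-12)
  old <- .seed_swap(degrade$seed)
  on.exit(.seed_restore(old))
  for (i in seq_len(n)) {
    f <- frames[[i]]
    if (!is.null(degrade$poisson_photons) && is.finite(degrade$poisson_photons)) {
      lam <- f / full_scale * degrade$poisson_photons
      f <- matrix(stats::rpois(length(lam), lam), dims[1L], dims[2L]) /
        degrade$poisson_photons * full_scale
    }
    if (degrade$gaussian_sigma > 0)
      f <- f + stats::rnorm(length(f), 0,
                            degrade$gaussian_sigma * full_scale)
    frames[[i]] <- pmax(f, 0)
  }
  list(frames = frames, masks = masks, full_scale = full_scale)
}

# ---- dataset simulators ----------------------------------------------------

#' Simulate an FPM acquisition
#'
#' Renders every LED frame through the (optionally aberrated) pupil with
#' [fpm_forward()], then applies the degradation pipeline. The returned
#' truth record (object, pupil, masks, spec echoes) regenerates the frames
#' bit-exactly under the same seed.
#'
#' @param object_amplitude,object_phase real matrices on the high-res grid.
#' @param sys an [fpm_system()].
#' @param pupil_phase optional aberration phase screen on the low-res grid
#'   (e.g. from [make_zernike_pupil_phase()]).
#' @param degrade a [degradation_spec()].
#' @return list with `observation` (an [observation_set()]) and `truth`
#'   (list: object, object_spectrum, pupil, pupil_phase, masks, degrade).
#' @export
simulate_fpm_dataset <- function(object_amplitude, object_phase, sys,
                                 pupil_phase = NULL,
                                 degrade = degradation_none()) {
  if (!all(dim(object_amplitude) == sys$object_pixels) ||
      !all(dim(object_phase) == sys$object_pixels))
    stop("object grids must match sys$object_pixels", call. = FALSE)
  obj <- object_amplitude * exp(1i * object_phase)
  X <- cfft2(obj)
  pupil <- fpm_ideal_pupil(sys)
  if (!is.null(pupil_phase))
    pupil$values <- pupil$values * exp(1i * pupil_phase)
  frames <- lapply(seq_len(sys$n_leds), function(n)
    fpm_forward(X, pupil, sys, n))
  sin_thetas <- sys$led_kvectors * sys$wavelength_um
  deg <- .apply_degradation(frames, degrade, sin_thetas)
  illum <- lapply(seq_len(sys$n_leds), function(n)
    list(kx = sys$led_kvectors[n, 1L], ky = sys$led_kvectors[n, 2L]))
  obs <- observation_set(deg$frames, illum = illum,
                         meta = list(wavelength_um = sys$wavelength_um,
                                     pixel_pitch_um = sys$camera_pitch_um,
                                     objective_na = sys$objective_na))
  list(observation = obs,
       truth = list(object = obj, object_spectrum = X, pupil = pupil,
                    pupil_phase = pupil_phase, masks = deg$masks,
                    full_scale = deg$full_scale, degrade = degrade, sys = sys))
}

#' Simulate a single-shot inline hologram
#'
#' @param object complex matrix or [complex_field()] exit wave.
#' @param distance_um sample-to-sensor distance (um).
#' @param pixel_pitch_um,wavelength_um grid geometry (um), used when
#'   `object` is a bare matrix.
#' @param degrade a [degradation_spec()].
#' @return list with `observation` (single-frame [observation_set()]) and
#'   `truth`.
#' @export
simulate_inline_hologram <- function(object, distance_um,
                                     pixel_pitch_um = 1, wavelength_um = 0.532,
                                     degrade = degradation_none()) {
  fld <- if (inherits(object, "complex_field")) object
         else complex_field(object, pixel_pitch_um, wavelength_um, "object")
  holo <- inline_holo_forward(fld, distance_um)
  deg <- .apply_degradation(list(holo), degrade)
  obs <- observation_set(deg$frames,
                         illum = list(list(distance_um = distance_um)),
                         meta = list(wavelength_um = fld$wavelength_um,
                                     pixel_pitch_um = fld$pixel_pitch_um))
  list(observation = obs,
       truth = list(object = fld$values, distance_um = distance_um,
                    clean = holo, degrade = degrade))
}

#' Simulate a coded-ptychography scan series
#'
#' Draws a seeded random binary-phase coded pattern (phases in {0, pi},
#' half the pixels flipped), scans the object over a jittered raster of
#' integer shifts, and renders each frame with [coded_ptych_forward()].
#'
#' @param object complex matrix or [complex_field()].
#' @param sample_to_mask_um,mask_to_sensor_um propagation distances (um).
#' @param n_shifts number of scan positions (>= 2).
#' @param pixel_pitch_um,wavelength_um grid geometry (um).
#' @param degrade a [degradation_spec()].
#' @param seed RNG seed for the pattern and scan jitter.
#' @return list with `observation`, `sys` (the [lensless_system()]) and
#'   `truth`.
#' @export
simulate_coded_dataset <- function(object, sample_to_mask_um = 500,
                                   mask_to_sensor_um = 1000, n_shifts = 9L,
                                   pixel_pitch_um = 1, wavelength_um = 0.532,
                                   degrade = degradation_none(), seed = 1L) {
  if (n_shifts < 2L) stop("n_shifts must be >= 2", call. = FALSE)
  fld <- if (inherits(object, "complex_field")) object
         else complex_field(object, pixel_pitch_um, wavelength_um, "object")
  dims <- dim(fld$values)
  old <- .seed_swap(seed)
  pat_phase <- matrix(pi * (stats::runif(prod(dims)) < 0.5),
                      dims[1L], dims[2L])
  # jittered raster of integer shifts
  side <- ceiling(sqrt(n_shifts))
  stride <- max(2L, floor(min(dims) / (3L * side)))
  base <- expand.grid(dy = seq_len(side), dx = seq_len(side))[seq_len(n_shifts), ]
  jitter <- matrix(sample(-1:1, 2L * n_shifts, replace = TRUE), n_shifts, 2L)
  shifts <- cbind((base$dy - (side + 1) / 2) * stride,
                  (base$dx - (side + 1) / 2) * stride) + jitter
  shifts <- round(shifts)
  .seed_restore(old)
  pattern <- complex_field(exp(1i * pat_phase), fld$pixel_pitch_um,
                           fld$wavelength_um, "object")
  sys <- lensless_system(sample_to_mask_um, mask_to_sensor_um, pattern, shifts)
  frames <- lapply(seq_len(n_shifts), function(n)
    coded_ptych_forward(fld, sys, n))
  deg <- .apply_degradation(frames, degrade)
  illum <- lapply(seq_len(n_shifts), function(n) list(shift = shifts[n, ]))
  obs <- observation_set(deg$frames, illum = illum,
                         meta = list(wavelength_um = fld$wavelength_um,
                                     pixel_pitch_um = fld$pixel_pitch_um))
  list(observation = obs, sys = sys,
       truth = list(object = fld$values, pattern = pattern$values,
                    shifts = shifts, degrade = degrade, seed = seed))
}
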