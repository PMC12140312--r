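# Forward models A_n for the three modalities, each factorized into
# elementary linear stages with exact adjoints. Intensity taking |.|^2 is
# applied outside the linear chain by the callers.

# ---- angular spectrum ------------------------------------------------------

# band-limited angular-spectrum transfer function on a DC-centered grid
.asp_transfer <- function(dims, pixel_pitch_um, wavelength_um, distance_um) {
  fg <- make_frequency_grid(dims, pixel_pitch_um)
  arg <- 1 - (wavelength_um * fg$fx)^2 - (wavelength_um * fg$fy)^2
  prop <- arg > 0                         # propagating (non-evanescent) band
  H <- matrix(0 + 0i, dims[1L], dims[2L])
  H[prop] <- exp(2i * pi * (distance_um / wavelength_um) * sqrt(arg[prop]))
  H
}

#' Free-space propagation by the angular-spectrum method
#'
#' Applies the exact non-paraxial transfer function
#' `exp(i 2 pi z / lambda * sqrt(1 - (lambda f)^2))` in the Fourier domain,
#' zeroing evanescent components (`(lambda f)^2 > 1`). Energy in the
#' propagating band is conserved exactly; propagation by `-z` undoes
#' propagation by `+z`.
#'
#' @param field a [complex_field()].
#' @param distance_um signed propagation distance in micrometres.
#' @return a [complex_field()] at the new plane.
#' @export
angular_spectrum_propagate <- function(field, distance_um) {
  if (!is.finite(distance_um)) stop("distance must be finite", call. = FALSE)
  if (distance_um == 0) return(field)
  ch <- angular_spectrum_chain(dim(field$values), field$pixel_pitch_um,
                               field$wavelength_um, distance_um)
  out <- field
  out$values <- chain_apply(ch, field$values)
  out
}

#' Angular-spectrum propagation as an operator chain
#'
#' @param dims grid dimensions.
#' @param pixel_pitch_um,wavelength_um sampling and wavelength (um).
#' @param distance_um propagation distance (um).
#' @return an [operator_chain()] (fourier -> transfer mask -> inverse fourier).
#' @export
angular_spectrum_chain <- function(dims, pixel_pitch_um, wavelength_um,
                                   distance_um) {
  H <- .asp_transfer(dims, pixel_pitch_um, wavelength_um, distance_um)
  operator_chain(
    chain_op("fourier", cfft2, cifft2),
    chain_op("elementwise_mask",
             function(x) x * H,
             function(x) x * Conj(H),
             params = list(distance_um = distance_um)),
    chain_op("inverse_fourier", cifft2, cfft2)
  )
}

# ---- FPM system ------------------------------------------------------------

#' Fourier ptychographic microscopy system description
#'
#' @param object_pixels high-resolution object grid dimensions (even).
#' @param objective_na numerical aperture of the objective.
#' @param wavelength_um central illumination wavelength (um).
#' @param object_pitch_um object-plane sampling of the high-resolution grid
#'   (um); the camera (low-resolution) pitch is
#'   `object_pitch_um * downsample_factor`.
#' @param led_kvectors N x 2 matrix of per-LED illumination spatial
#'   frequencies `(kx, ky)` in 1/um (`sin(theta)/lambda` convention, no
#'   2 pi), e.g. from [led_grid_kvectors()].
#' @param downsample_factor integer ratio of high-res to low-res grid size.
#' @return object of class `fpm_system`, including the derived low-res
#'   dimensions, frequency step and per-frame integer spectrum shifts.
#' @export
fpm_system <- function(object_pixels, objective_na, wavelength_um,
                       object_pitch_um, led_kvectors, downsample_factor = 2L) {
  .assert_even_dims(object_pixels, "object")
  downsample_factor <- as.integer(downsample_factor)
  if (downsample_factor < 1L) stop("downsample_factor must be >= 1", call. = FALSE)
  if (any(object_pixels %% downsample_factor != 0))
    stop("object_pixels must be divisible by downsample_factor", call. = FALSE)
  low <- object_pixels %/% downsample_factor
  .assert_even_dims(low, "low-res")
  led_kvectors <- as.matrix(led_kvectors)
  if (ncol(led_kvectors) != 2L) stop("led_kvectors must be N x 2", call. = FALSE)
  df <- 1 / (object_pixels[1L] * object_pitch_um)   # frequency step, 1/um
  illum_na <- wavelength_um * sqrt(rowSums(led_kvectors^2))
  if (objective_na + max(illum_na) > 1)
    stop("synthetic NA (objective + max illumination) exceeds 1", call. = FALSE)
  # integer-pixel quantization of the spectrum shift (sub-pixel opt-in is
  # out of scope of the base model)
  shifts_px <- round(led_kvectors / df)
  margin <- (object_pixels - low) %/% 2L
  bad <- abs(shifts_px[, 1L]) > margin[2L] | abs(shifts_px[, 2L]) > margin[1L]
  if (any(bad))
    stop(sprintf(paste0("LED(s) %s: spectrum shift exceeds the crop margin ",
                        "(%d px); reduce illumination NA or enlarge the ",
                        "object grid"),
                 paste(which(bad), collapse = ", "), margin[1L]),
         call. = FALSE)
  structure(list(object_pixels = object_pixels, objective_na = objective_na,
                 wavelength_um = wavelength_um,
                 object_pitch_um = object_pitch_um,
                 camera_pitch_um = object_pitch_um * downsample_factor,
                 led_kvectors = led_kvectors,
                 downsample_factor = downsample_factor,
                 low_pixels = low, freq_step_per_um = df,
                 shifts_px = shifts_px,
                 n_leds = nrow(led_kvectors),
                 synthetic_na = objective_na + max(illum_na)),
            class = "fpm_system")
}

#' @export
print.fpm_system <- function(x, ...) {
  cat(sprintf("<fpm_system> object %dx%d -> frames %dx%d, NA %.3g (synthetic %.3g), %d LEDs\n",
              x$object_pixels[1L], x$object_pixels[2L],
              x$low_pixels[1L], x$low_pixels[2L],
              x$objective_na, x$synthetic_na, x$n_leds))
  invisible(x)
}

#' Ideal pupil for an FPM system
#' @param sys an [fpm_system()].
#' @return a [pupil_function()] on the low-resolution frequency grid.
#' @export
fpm_ideal_pupil <- function(sys) {
  pupil_function(NULL, na = sys$objective_na,
                 wavelength_um = sys$wavelength_um,
                 freq_step_per_um = sys$freq_step_per_um,
                 dims = sys$low_pixels)
}

#' LED-array illumination wave-vectors
#'
#' Spatial frequencies (1/um, `sin(theta)/lambda` convention) for a planar
#' LED array centered under the sample at the given height.
#'
#' @param n_side LEDs per side of the square grid (odd gives a central,
#'   on-axis LED).
#' @param spacing_um LED pitch (um).
#' @param height_um array-to-sample distance (um).
#' @param wavelength_um wavelength (um).
#' @return `n_side^2 x 2` matrix of `(kx, ky)`, ordered by distance from the
#'   optical axis (brightfield LEDs first).
#' @export
led_grid_kvectors <- function(n_side, spacing_um, height_um, wavelength_um) {
  half <- (n_side - 1) / 2
  pos <- (seq_len(n_side) - 1 - half) * spacing_um
  g <- expand.grid(x = pos, y = pos)
  rad <- sqrt(g$x^2 + g$y^2 + height_um^2)
  k <- cbind(kx = g$x / (wavelength_um * rad), ky = g$y / (wavelength_um * rad))
  k[order(g$x^2 + g$y^2), , drop = FALSE]
}

# crop window (rows, cols) of the shifted low-res patch inside the high-res
# spectrum; errors if the shift pushes the window outside
.fpm_crop_index <- function(sys, frame_index) {
  hi <- sys$object_pixels; lo <- sys$low_pixels
  sh <- sys$shifts_px[frame_index, ]     # (kx, ky) -> (col, row) shift
  ctr <- hi %/% 2L + 1L                  # DC pixel of high-res spectrum
  r0 <- ctr[1L] + sh[2L] - lo[1L] %/% 2L
  c0 <- ctr[2L] + sh[1L] - lo[2L] %/% 2L
  if (r0 < 1L || c0 < 1L || r0 + lo[1L] - 1L > hi[1L] || c0 + lo[2L] - 1L > hi[2L])
    stop(sprintf(paste0("LED %d: spectrum shift (%d, %d) px pushes the crop ",
                        "window outside the %dx%d spectrum"),
                 frame_index, sh[1L], sh[2L], hi[1L], hi[2L]), call. = FALSE)
  list(rows = r0:(r0 + lo[1L] - 1L), cols = c0:(c0 + lo[2L] - 1L))
}

#' FPM forward model as an operator chain
#'
#' The linear part of the n-th FPM observation: shift the object spectrum by
#' the LED wave-vector (realized as an off-center crop), apply the pupil
#' mask, inverse-Fourier transform to the low-resolution image plane, and
#' scale so that a unit object with an ideal pupil yields unit mean
#' intensity. Intensity taking is outside the chain.
#'
#' @param sys an [fpm_system()].
#' @param pupil a [pupil_function()] on the low-res grid.
#' @param frame_index which LED (1-based).
#' @return an [operator_chain()] mapping the high-res object spectrum to the
#'   low-res detector field.
#' @export
fpm_chain <- function(sys, pupil, frame_index) {
  idx <- .fpm_crop_index(sys, frame_index)
  hi <- sys$object_pixels; lo <- sys$low_pixels
  P <- pupil$values
  # orthonormal FFT bookkeeping: a unit object has spectrum value
  # sqrt(prod(hi)) at DC; after crop and orthonormal inverse FFT on the
  # low-res grid the field is sqrt(prod(hi)/prod(lo)) -- normalize by the
  # reciprocal so unit objects give unit intensity.
  s <- sqrt(prod(lo) / prod(hi))
  operator_chain(
    chain_op("fourier_shift_crop",
             function(x) x[idx$rows, idx$cols, drop = FALSE],
             function(x) {
               out <- matrix(0 + 0i, hi[1L], hi[2L])
               out[idx$rows, idx$cols] <- x
               out
             },
             params = list(frame_index = frame_index)),
    chain_op("pupil_mask",
             function(x) x * P,
             function(x) x * Conj(P)),
    chain_op("inverse_fourier",
             function(x) cifft2(x) * s,
             function(x) cfft2(x) * s)
  )
}

#' Predicted low-resolution FPM intensity frame
#'
#' `|inverse-Fourier{ pupil * crop(spectrum shifted by k_n) }|^2` on the
#' low-resolution grid.
#'
#' @param object_spectrum complex matrix (or [complex_field()]) -- the
#'   high-resolution object spectrum, DC-centered.
#' @param pupil a [pupil_function()].
#' @param sys an [fpm_system()].
#' @param frame_index which LED (1-based).
#' @return non-negative numeric matrix of low-res intensities.
#' @export
fpm_forward <- function(object_spectrum, pupil, sys, frame_index) {
  X <- if (inherits(object_spectrum, "complex_field")) object_spectrum$values
       else object_spectrum
  if (!all(dim(X) == sys$object_pixels))
    stop("object spectrum does not match sys$object_pixels", call. = FALSE)
  f <- chain_apply(fpm_chain(sys, pupil, frame_index), X)
  Mod(f)^2
}

# ---- lensless coded system -------------------------------------------------

#' Lensless coded-ptychography system description
#'
#' A fixed coded pattern sits between the (laterally scanned) sample and the
#' sensor. The scan is modeled as integer-pixel circular shifts of the
#' object on a grid matching the pattern; shifts must stay below half the
#' grid extent.
#'
#' @param sample_to_mask_um,mask_to_sensor_um propagation distances (um),
#'   both >= 0.
#' @param coded_pattern a [complex_field()] holding the pattern transmission.
#' @param scan_shifts_px integer N x 2 matrix of per-frame `(dy, dx)` shifts.
#' @return object of class `lensless_system`.
#' @export
lensless_system <- function(sample_to_mask_um, mask_to_sensor_um,
                            coded_pattern, scan_shifts_px) {
  if (sample_to_mask_um < 0 || mask_to_sensor_um < 0)
    stop("propagation distances must be >= 0", call. = FALSE)
  scan_shifts_px <- as.matrix(scan_shifts_px)
  if (ncol(scan_shifts_px) != 2L) stop("scan_shifts_px must be N x 2", call. = FALSE)
  d <- dim(coded_pattern$values)
  if (any(abs(scan_shifts_px) >= matrix(d %/% 2L, nrow(scan_shifts_px), 2L,
                                        byrow = TRUE)))
    stop("scan shifts must be smaller than half the pattern extent", call. = FALSE)
  structure(list(sample_to_mask_um = sample_to_mask_um,
                 mask_to_sensor_um = mask_to_sensor_um,
                 coded_pattern = coded_pattern,
                 scan_shifts_px = scan_shifts_px,
                 n_frames = nrow(scan_shifts_px)),
            class = "lensless_system")
}

# integer circular shift of a matrix by (dy, dx)
.circshift <- function(x, dy, dx) {
  n <- nrow(x); m <- ncol(x)
  dy <- ((dy %% n) + n) %% n
  dx <- ((dx %% m) + m) %% m
  if (dy) x <- x[c((n - dy + 1L):n, 1L:(n - dy)), , drop = FALSE]
  if (dx) x <- x[, c((m - dx + 1L):m, 1L:(m - dx)), drop = FALSE]
  x
}

#' Predicted coded-ptychography intensity frame
#'
#' `|propagate( propagate(shift(object), d1) * pattern, d2 )|^2`, both
#' propagations by the angular-spectrum method.
#'
#' @param object a [complex_field()] (same grid as the coded pattern).
#' @param sys a [lensless_system()].
#' @param frame_index which scan position (1-based).
#' @return non-negative numeric matrix of detector intensities.
#' @export
coded_ptych_forward <- function(object, sys, frame_index) {
  Mod(.coded_forward_field(object$values, sys$coded_pattern$values, sys,
                           object$pixel_pitch_um, object$wavelength_um,
                           frame_index))^2
}

.coded_forward_field <- function(obj_values, pattern_values, sys,
                                 pitch, lambda, frame_index) {
  sh <- sys$scan_shifts_px[frame_index, ]
  x <- .circshift(obj_values, sh[1L], sh[2L])
  if (sys$sample_to_mask_um > 0) {
    H1 <- .asp_transfer(dim(x), pitch, lambda, sys$sample_to_mask_um)
    x <- cifft2(cfft2(x) * H1)
  }
  x <- x * pattern_values
  if (sys$mask_to_sensor_um > 0) {
    H2 <- .asp_transfer(dim(x), pitch, lambda, sys$mask_to_sensor_um)
    x <- cifft2(cfft2(x) * H2)
  }
  x
}

# ---- inline holography -----------------------------------------------------

#' Predicted inline-hologram intensity
#'
#' Intensity of the object field propagated to the detector plane:
#' `|angular_spectrum_propagate(object, distance)|^2`.
#'
#' @param object a [complex_field()].
#' @param distance_um object-to-sensor distance (um).
#' @return non-negative numeric matrix.
#' @export
inline_holo_forward <- function(object, distance_um) {
  Mod(angular_spectrum_propagate(object, distance_um)$values)^2
}
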