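# Image-quality and resolution metrics used to evaluate reconstructions.

#' Blind noise-level estimate
#'
#' Immerkaer-style residual estimator: the frame is convolved with the
#' Laplacian-difference mask `M = [[1,-2,1],[-2,4,-2],[1,-2,1]]`, which
#' annihilates locally affine structure, and the absolute response is
#' averaged as `sqrt(pi/2) / (6 (W-2)(H-2)) * sum |frame * M|`. For i.i.d.
#' Gaussian noise of standard deviation sigma the estimate converges to
#' sigma; it is exactly scale-equivariant.
#'
#' @param frame real matrix, at least 3 x 3.
#' @return estimated noise standard deviation (>= 0).
#' @export
noise_level <- function(frame) {
  n <- nrow(frame); m <- ncol(frame)
  if (n < 3L || m < 3L) stop("frame must be at least 3x3", call. = FALSE)
  r <- frame[1:(n - 2), 1:(m - 2)] - 2 * frame[1:(n - 2), 2:(m - 1)] + frame[1:(n - 2), 3:m] -
    2 * frame[2:(n - 1), 1:(m - 2)] + 4 * frame[2:(n - 1), 2:(m - 1)] - 2 * frame[2:(n - 1), 3:m] +
    frame[3:n, 1:(m - 2)] - 2 * frame[3:n, 2:(m - 1)] + frame[3:n, 3:m]
  sqrt(pi / 2) / (6 * (n - 2) * (m - 2)) * sum(abs(r))
}

#' RMS image contrast
#'
#' Standard deviation divided by mean. Requires a positive mean.
#'
#' @param frame real matrix.
#' @return contrast (>= 0).
#' @export
image_contrast <- function(frame) {
  mu <- mean(frame)
  if (mu <= 0) stop("frame mean must be positive", call. = FALSE)
  stats::sd(as.vector(frame)) / mu
}

#' Peak signal-to-noise ratio
#'
#' `-10 log10(MSE / peak^2)` in dB; identical frames return `Inf`.
#'
#' @param frame,reference same-shape real matrices.
#' @param peak peak signal value; default `max(|reference|)`.
#' @return PSNR in dB.
#' @export
psnr <- function(frame, reference, peak = max(abs(reference))) {
  if (!all(dim(frame) == dim(reference)))
    stop("shape mismatch", call. = FALSE)
  mse <- mean((frame - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# separable Gaussian filter with replicate ("nearest") padding
.gauss_filter <- function(x, sigma = 1.5, radius = 5L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  pad_r <- c(rep(1L, radius), 1:n, rep(n, radius))
  xp <- x[pad_r, , drop = FALSE]
  y <- matrix(0, n, m)
  for (j in seq_along(k)) y <- y + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
  pad_c <- c(rep(1L, radius), 1:m, rep(m, radius))
  yp <- y[, pad_c, drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_along(k)) out <- out + k[j] * yp[, j:(j + m - 1L), drop = FALSE]
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM with the standard settings: 11 x 11 Gaussian window
#' (sigma = 1.5), stability constants `k1 = 0.01`, `k2 = 0.03`, population
#' (filter-weighted) covariances, and the border of half a window width
#' excluded from the mean.
#'
#' @param frame,reference same-shape real matrices.
#' @param data_range dynamic range of the data; default
#'   `max(reference) - min(reference)`.
#' @return mean SSIM in `[-1, 1]` (1 for identical frames).
#' @export
ssim <- function(frame, reference,
                 data_range = max(reference) - min(reference)) {
  if (!all(dim(frame) == dim(reference)))
    stop("shape mismatch", call. = FALSE)
  if (identical(frame, reference)) return(1)
  sigma <- 1.5; radius <- 5L
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- .gauss_filter(frame, sigma, radius)
  my <- .gauss_filter(reference, sigma, radius)
  vx <- .gauss_filter(frame^2, sigma, radius) - mx^2
  vy <- .gauss_filter(reference^2, sigma, radius) - my^2
  cxy <- .gauss_filter(frame * reference, sigma, radius) - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  n <- nrow(s); m <- ncol(s)
  if (n > 2L * radius && m > 2L * radius)
    s <- s[(radius + 1L):(n - radius), (radius + 1L):(m - radius)]
  mean(s)
}

#' USAF-1951 element line width and spatial frequency
#'
#' `frequency = 2^(group + (element - 1)/6)` line pairs per mm;
#' `width_um = 500 / frequency`.
#'
#' @param group chart group number (integer, may be negative).
#' @param element element within the group, 1 to 6.
#' @return list with `width_um` and `freq_lp_mm`.
#' @export
usaf_linewidth <- function(group, element) {
  if (element < 1 || element > 6) stop("element must be in 1..6", call. = FALSE)
  freq <- 2^(group + (element - 1) / 6)
  list(width_um = 500 / freq, freq_lp_mm = freq)
}

#' Abbe (coherent synthetic-aperture) resolution limit
#'
#' `wavelength / (2 NA)` in micrometres.
#'
#' @param wavelength_um wavelength (um, > 0).
#' @param na numerical aperture (0 < na <= 1.5).
#' @param digits rounding for display (default 3 decimals).
#' @return resolution in micrometres.
#' @export
abbe_resolution <- function(wavelength_um, na, digits = 3) {
  if (wavelength_um <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (na <= 0 || na > 1.5) stop("na must be in (0, 1.5]", call. = FALSE)
  round(wavelength_um / (2 * na), digits)
}

#' Pupil-phase RMS error up to the blind-recovery gauges
#'
#' Compares a recovered pupil with a reference after removing the gauges a
#' blind joint object-and-pupil fit cannot determine: a piston and a tip/
#' tilt (a linear pupil phase trades exactly against an object translation,
#' and may wrap many times across the disk, so the tilt is found by a
#' coarse-to-fine phasor-concentration search rather than least squares on
#' wrapped phases), and optionally the conjugate-twin solution (for a
#' symmetric illumination set, conjugate-flipping both object and pupil
#' reproduces every frame exactly). The residual is amplitude-weighted.
#'
#' @param recovered,reference complex pupil matrices of equal size.
#' @param mask logical matrix selecting the NA disk (default: pixels where
#'   `|reference| > 0`).
#' @param allow_twin also score against the conjugate-flipped reference and
#'   return the smaller error (default TRUE).
#' @param max_tilt search range for the tilt, rad/pixel (default 4).
#' @return RMS phase error in radians.
#' @export
pupil_phase_rms <- function(recovered, reference, mask = NULL,
                            allow_twin = TRUE, max_tilt = 4) {
  if (is.null(mask)) mask <- Mod(reference) > 0
  one <- function(ref) {
    d <- dim(mask)
    yy <- row(mask) - (d[1L] / 2 + 1L)
    xx <- col(mask) - (d[2L] / 2 + 1L)
    w <- (Mod(recovered) * Mod(ref))[mask]
    if (sum(w) <= 0) return(Inf)
    thd <- Arg(recovered * Conj(ref))[mask]
    x <- xx[mask]; y <- yy[mask]
    conc <- function(a, b) Mod(sum(w * exp(1i * (thd - a * x - b * y))))
    best <- c(0, 0); bestv <- -1
    for (a in seq(-max_tilt, max_tilt, by = 0.05))
      for (b in seq(-max_tilt, max_tilt, by = 0.05)) {
        v <- conc(a, b)
        if (v > bestv) { bestv <- v; best <- c(a, b) }
      }
    for (a in seq(best[1L] - 0.06, best[1L] + 0.06, by = 0.004))
      for (b in seq(best[2L] - 0.06, best[2L] + 0.06, by = 0.004)) {
        v <- conc(a, b)
        if (v > bestv) { bestv <- v; best <- c(a, b) }
      }
    r <- Arg(exp(1i * (thd - best[1L] * x - best[2L] * y)))
    r <- Arg(exp(1i * (r - Arg(sum(w * exp(1i * r))))))
    sqrt(sum(w * r^2) / sum(w))
  }
  err <- one(reference)
  if (allow_twin) {
    flipidx <- function(n) {
      ctr <- n / 2 + 1
      vapply(1:n, function(i) { j <- 2 * ctr - i; if (j > n) j - n else j }, 0)
    }
    twin <- Conj(reference[flipidx(nrow(reference)),
                           flipidx(ncol(reference))])
    err <- min(err, one(twin))
  }
  err
}

#' Bundle the quality metrics of a reconstruction
#'
#' @param frame real matrix under evaluation.
#' @param reference optional ground-truth matrix (enables PSNR and SSIM).
#' @return object of class `quality_report` with fields `noise_level`,
#'   `contrast`, and when a reference is given `psnr_db`, `ssim`.
#' @export
quality_report <- function(frame, reference = NULL) {
  rep <- list(noise_level = noise_level(frame),
              contrast = image_contrast(frame))
  if (!is.null(reference)) {
    rep$psnr_db <- psnr(frame, reference)
    rep$ssim <- ssim(frame, reference)
  }
  structure(rep, class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> noise %.4g, contrast %.4g", x$noise_level,
              x$contrast))
  if (!is.null(x$psnr_db)) cat(sprintf(", PSNR %.2f dB, SSIM %.4f",
                                       x$psnr_db, x$ssim))
  cat("\n")
  invisible(x)
}
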