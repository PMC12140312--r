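# Classical pixel-domain baselines: Gerchberg-Saxton for inline holography,
# ePIE for coded ptychography, EPRY and momentum-accelerated PIE for FPM.

#' Baseline algorithm configuration
#'
#' @param algorithm `"gs"`, `"epie"`, `"epry"` or `"mpie"`.
#' @param iterations sweep count.
#' @param step_object,step_pupil update step sizes in (0, 2].
#' @param momentum heavy-ball coefficient in [0, 1) (mpie only).
#' @param seed RNG seed (frame-order shuffling in the PIE family).
#' @return object of class `baseline_config`.
#' @export
baseline_config <- function(algorithm = c("epry", "gs", "epie", "mpie"),
                            iterations = 50L, step_object = 1,
                            step_pupil = 1, momentum = 0, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (step_object <= 0 || step_object > 2 || step_pupil <= 0 || step_pupil > 2)
    stop("step sizes must be in (0, 2]", call. = FALSE)
  if (momentum < 0 || momentum >= 1)
    stop("momentum must be in [0, 1)", call. = FALSE)
  structure(list(algorithm = algorithm, iterations = as.integer(iterations),
                 step_object = step_object, step_pupil = step_pupil,
                 momentum = momentum, seed = as.integer(seed)),
            class = "baseline_config")
}

#' Gerchberg-Saxton reconstruction of an inline hologram
#'
#' Alternating projections: back-propagate the detector field to the sample
#' plane, apply the object-plane constraints there, forward-propagate, and
#' replace the detector amplitude by `sqrt(hologram)` while keeping the
#' phase. Deterministic. The detector-domain error
#' `sum((|psi| - sqrt(I))^2)` is recorded each iteration.
#'
#' @param hologram non-negative intensity matrix.
#' @param distance_um sample-to-sensor distance (um).
#' @param pixel_pitch_um,wavelength_um grid geometry (um).
#' @param config a [baseline_config()] (only `iterations` is used).
#' @param constraints list of [constraint_spec()] applied (in order,
#'   replacement-style) at the object plane each iteration; default clamps
#'   the amplitude to at most 1, the usual transmissive-sample constraint.
#' @return list with `object` ([complex_field()] at the sample plane),
#'   `error_trace`, and `detector_field`.
#' @export
gs_inline <- function(hologram, distance_um, pixel_pitch_um, wavelength_um,
                      config = baseline_config("gs", iterations = 100L),
                      constraints = list(
                        constraint_spec("amplitude_threshold", mode = "replace",
                                        params = list(lo = 0, hi = 1)))) {
  if (any(hologram < 0)) stop("hologram must be non-negative", call. = FALSE)
  amp <- sqrt(hologram)
  dims <- dim(hologram)
  Hf <- .asp_transfer(dims, pixel_pitch_um, wavelength_um, distance_um)
  det <- amp + 0i
  err <- numeric(config$iterations)
  obj <- NULL
  for (it in seq_len(config$iterations)) {
    obj <- cifft2(cfft2(det) * Conj(Hf))          # back-propagate
    for (spec in constraints) {
      f <- .resolve_constraint(spec)
      obj <- f(obj) + 0i
    }
    psi <- cifft2(cfft2(obj) * Hf)                # forward
    err[it] <- sum((Mod(psi) - amp)^2)
    det <- amp * ifelse(Mod(psi) > 0, psi / Mod(psi), 1 + 0i)
  }
  list(object = complex_field(obj, pixel_pitch_um, wavelength_um, "object"),
       error_trace = err, detector_field = det)
}

# shared PIE sweep engine for EPRY / mPIE (momentum 0 = plain EPRY)
.fpm_pie <- function(observation, sys, config, pupil_init = NULL,
                     momentum = 0, freeze_pupil = FALSE,
                     object_init = NULL) {
  old_seed <- .seed_swap(config$seed)
  on.exit(.seed_restore(old_seed))
  hi <- sys$object_pixels; lo <- sys$low_pixels
  s <- sqrt(prod(lo) / prod(hi))
  pupil <- if (is.null(pupil_init)) fpm_ideal_pupil(sys) else pupil_init
  P <- if (inherits(pupil, "pupil_function")) pupil$values else pupil + 0i
  support <- pupil_support(fpm_ideal_pupil(sys), dilate = 1.1)
  illum_na <- sys$wavelength_um * sqrt(rowSums(sys$led_kvectors^2))
  if (min(illum_na) > sys$objective_na)
    stop("no brightfield frame: LED coverage must include DC", call. = FALSE)
  # init object spectrum from the most on-axis frame (or as supplied)
  if (is.null(object_init)) {
    bf <- which.min(rowSums(sys$led_kvectors^2))
    amp0 <- sqrt(pmax(observation$frames[[bf]], 0))
    X <- matrix(0 + 0i, hi[1L], hi[2L])
    Xlo <- cfft2(amp0 + 0i) / s
    r0 <- hi[1L] %/% 2L - lo[1L] %/% 2L + 1L
    c0 <- hi[2L] %/% 2L - lo[2L] %/% 2L + 1L
    X[r0:(r0 + lo[1L] - 1L), c0:(c0 + lo[2L] - 1L)] <- Xlo
  } else X <- object_init + 0i
  idx <- lapply(seq_len(sys$n_leds), function(n) .fpm_crop_index(sys, n))
  vX <- matrix(0 + 0i, hi[1L], hi[2L])
  vP <- matrix(0 + 0i, lo[1L], lo[2L])
  loss <- numeric(config$iterations)
  order_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  for (sw in seq_len(config$iterations)) {
    X_prev <- X; P_prev <- P
    set.seed(order_seed + sw)
    ord <- sample.int(sys$n_leds)
    sweep_loss <- 0
    for (n in ord) {
      rows <- idx[[n]]$rows; cols <- idx[[n]]$cols
      patch <- X[rows, cols, drop = FALSE]
      phi <- patch * P
      psi <- cifft2(phi) * s
      I_obs <- observation$frames[[n]]
      sweep_loss <- sweep_loss + sum((Mod(psi)^2 - I_obs)^2)
      psi2 <- sqrt(pmax(I_obs, 0)) * ifelse(Mod(psi) > 0, psi / Mod(psi), 1 + 0i)
      dphi <- cfft2(psi2) / s - phi
      X[rows, cols] <- patch +
        config$step_object * Conj(P) / max(Mod(P)^2) * dphi
      if (!freeze_pupil) {
        P <- P + config$step_pupil * Conj(patch) / max(Mod(patch)^2) * dphi
        P[!support] <- 0
      }
    }
    loss[sw] <- sweep_loss
    if (momentum > 0) {
      vX <- momentum * vX + (X - X_prev)
      vP <- momentum * vP + (P - P_prev)
      X <- X_prev + vX
      P <- P_prev + vP
    }
  }
  list(object_spectrum = X, pupil = P, loss_trace = loss,
       object = cifft2(X))
}

#' FPM reconstruction by embedded pupil recovery (EPRY)
#'
#' Sequential alternating-projection sweeps over the LED frames with the
#' standard ePIE-style conjugate-weighted updates applied to both the
#' object-spectrum patch and the pupil; pupil updates are confined to the
#' NA disk dilated by 10 percent.
#'
#' @param observation an [observation_set()].
#' @param sys an [fpm_system()].
#' @param config a [baseline_config()].
#' @param pupil_init optional starting pupil.
#' @return list with `object_spectrum`, `object` (spatial complex matrix),
#'   `pupil`, `loss_trace` (pixel-domain squared intensity error per sweep).
#' @export
epry_fpm <- function(observation, sys,
                     config = baseline_config("epry"), pupil_init = NULL) {
  .fpm_pie(observation, sys, config, pupil_init, momentum = 0)
}

#' FPM reconstruction by PIE with momentum (mPIE)
#'
#' [epry_fpm()] sweeps augmented with heavy-ball momentum on the object
#' spectrum and pupil; `config$momentum = 0` reduces bitwise to EPRY.
#'
#' @inheritParams epry_fpm
#' @return as [epry_fpm()].
#' @export
mpie_fpm <- function(observation, sys,
                     config = baseline_config("mpie", momentum = 0.7),
                     pupil_init = NULL) {
  .fpm_pie(observation, sys, config, pupil_init, momentum = config$momentum)
}

#' Coded-ptychography reconstruction by ePIE
#'
#' Joint object and coded-pattern recovery: per frame, the detector
#' amplitude is replaced by the measurement, the residual is back-propagated
#' to the mask plane, and object and pattern receive the standard
#' conjugate-weighted ePIE updates (normalized by the max squared modulus).
#'
#' @param observation an [observation_set()].
#' @param sys a [lensless_system()].
#' @param config a [baseline_config()].
#' @param pattern_init optional starting pattern (complex matrix); default
#'   all ones.
#' @param freeze_pattern keep the pattern fixed at its initialization.
#' @return list with `object`, `coded_pattern` (complex matrices) and
#'   `loss_trace`.
#' @export
epie_coded <- function(observation, sys,
                       config = baseline_config("epie", iterations = 100L),
                       pattern_init = NULL, freeze_pattern = FALSE) {
  shifts <- sys$scan_shifts_px
  if (nrow(unique(shifts)) < 2L)
    stop("at least 2 distinct scan shifts required (non-identifiable)",
         call. = FALSE)
  old_seed <- .seed_swap(config$seed)
  on.exit(.seed_restore(old_seed))
  lambda <- observation$meta$wavelength_um
  pitch <- observation$meta$pixel_pitch_um
  dims <- dim(sys$coded_pattern$values)
  H1 <- if (sys$sample_to_mask_um > 0)
    .asp_transfer(dims, pitch, lambda, sys$sample_to_mask_um)
  H2 <- if (sys$mask_to_sensor_um > 0)
    .asp_transfer(dims, pitch, lambda, sys$mask_to_sensor_um)
  prop <- function(x, H) if (is.null(H)) x else cifft2(cfft2(x) * H)
  iprop <- function(x, H) if (is.null(H)) x else cifft2(cfft2(x) * Conj(H))
  obj <- matrix(1 + 0i, dims[1L], dims[2L])
  pat <- if (is.null(pattern_init)) matrix(1 + 0i, dims[1L], dims[2L])
         else pattern_init + 0i
  loss <- numeric(config$iterations)
  order_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
  for (sw in seq_len(config$iterations)) {
    set.seed(order_seed + sw)
    ord <- sample.int(sys$n_frames)
    sweep_loss <- 0
    for (n in ord) {
      sh <- shifts[n, ]
      os <- .circshift(obj, sh[1L], sh[2L])
      w1 <- prop(os, H1)
      ex <- w1 * pat
      det <- prop(ex, H2)
      I_obs <- observation$frames[[n]]
      sweep_loss <- sweep_loss + sum((Mod(det)^2 - I_obs)^2)
      det2 <- sqrt(pmax(I_obs, 0)) *
        ifelse(Mod(det) > 0, det / Mod(det), 1 + 0i)
      dex <- iprop(det2 - det, H2)
      w1_new <- w1 + config$step_object * Conj(pat) / max(Mod(pat)^2) * dex
      if (!freeze_pattern)
        pat <- pat + config$step_pupil * Conj(w1) / max(Mod(w1)^2) * dex
      os_new <- iprop(w1_new, H1)
      obj <- .circshift(os_new, -sh[1L], -sh[2L])
    }
    loss[sw] <- sweep_loss
  }
  list(object = obj, coded_pattern = pat, loss_trace = loss)
}
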