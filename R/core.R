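#' @keywords internal
"_PACKAGE"

# ---- FFT conventions -------------------------------------------------------
# All spectra are DC-centered (fftshift layout) and all transforms are
# orthonormal, so the adjoint of a transform stage equals its inverse.
# Grids must have even dimensions: for even n, fftshift and ifftshift
# coincide (a half-period circular roll).

#' Center/uncenter a DC-centered grid
#'
#' Circularly rolls a matrix by half its extent along both axes, moving the
#' DC (zero-frequency) sample between corner and center position. For even
#' dimensions (the only ones this package accepts) the two operations
#' coincide and are involutions.
#'
#' @param x a matrix.
#' @return the rolled matrix.
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c((d[1L] / 2 + 1L):d[1L], 1L:(d[1L] / 2))
  j <- c((d[2L] / 2 + 1L):d[2L], 1L:(d[2L] / 2))
  x[i, j, drop = FALSE]
}

#' Orthonormal centered 2-D Fourier transforms
#'
#' `cfft2` maps a DC-centered spatial grid to a DC-centered spectrum;
#' `cifft2` is its inverse (and, being unitary, also its adjoint).
#' Orthonormal scaling (`1/sqrt(N)`) is used in both directions so that
#' total energy `sum(|x|^2)` is preserved exactly.
#'
#' @param x complex (or numeric) matrix with even dimensions.
#' @return complex matrix of the same dimensions.
#' @export
cfft2 <- function(x) {
  fftshift2(stats::fft(fftshift2(x))) / sqrt(length(x))
}

#' @rdname cfft2
#' @export
cifft2 <- function(x) {
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

.assert_even_dims <- function(dims, what = "grid") {
  if (length(dims) != 2L || any(dims < 2L) || any(dims %% 2L != 0L))
    stop(sprintf("%s dimensions must be even and >= 2, got [%s]",
                 what, paste(dims, collapse = ", ")), call. = FALSE)
  invisible(dims)
}

# ---- ComplexField ----------------------------------------------------------

#' Sampled complex optical field
#'
#' The unknown wavefront of a phase-retrieval problem: a 2-D complex
#' amplitude on a regular grid, together with the physical sampling interval
#' and wavelength needed by the propagators.
#'
#' @param values complex matrix (even dimensions) of field amplitudes.
#' @param pixel_pitch_um sampling interval in the plane of the field, in
#'   micrometres. Must be positive.
#' @param wavelength_um illumination wavelength in micrometres.
#' @param plane one of `"object"`, `"spectrum"`, `"detector"` -- a label for
#'   which conjugate plane the samples live in.
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_pitch_um, wavelength_um,
                          plane = c("object", "spectrum", "detector")) {
  plane <- match.arg(plane)
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  .assert_even_dims(dim(values), "field")
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite", call. = FALSE)
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("pixel_pitch_um must be > 0", call. = FALSE)
  if (!is.numeric(wavelength_um) || wavelength_um <= 0)
    stop("wavelength_um must be > 0", call. = FALSE)
  structure(list(values = as.matrix(values) + 0i,
                 pixel_pitch_um = pixel_pitch_um,
                 wavelength_um = wavelength_um,
                 plane = plane),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<complex_field> %dx%d, pitch %.4g um, lambda %.4g um, plane '%s'\n",
              d[1L], d[2L], x$pixel_pitch_um, x$wavelength_um, x$plane))
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(Mod(x$values)), max(Mod(x$values))))
  invisible(x)
}

# ---- PupilFunction ---------------------------------------------------------

#' Complex pupil function of an imaging system
#'
#' The aperture transmission in the Fourier plane. The ideal pupil is the
#' indicator of the NA-cutoff disk; aberrations live in its phase. The
#' amplitude is clamped (default 1.5) because a jointly fitted, unbounded
#' pupil amplitude is degenerate with the object amplitude.
#'
#' @param values complex matrix over spatial frequency (DC-centered), or
#'   `NULL` to build the ideal disk pupil.
#' @param na numerical aperture (dimensionless, in (0, 1.5]).
#' @param wavelength_um wavelength in micrometres.
#' @param freq_step_per_um spatial-frequency sample spacing (1/um) of the
#'   pupil grid (i.e. `1/(n * pitch)` of the conjugate image grid).
#' @param dims grid dimensions, required when `values` is `NULL`.
#' @param max_amplitude clamp on `|values|`; default 1.5.
#' @return an object of class `pupil_function` with fields `values`, `na`,
#'   `wavelength_um`, `cutoff_radius_px`, `freq_step_per_um`.
#' @export
pupil_function <- function(values = NULL, na, wavelength_um, freq_step_per_um,
                           dims = NULL, max_amplitude = 1.5) {
  if (na <= 0 || na > 1.5) stop("na must be in (0, 1.5]", call. = FALSE)
  cutoff <- (na / wavelength_um) / freq_step_per_um  # px
  if (is.null(values)) {
    if (is.null(dims)) stop("dims required when values is NULL", call. = FALSE)
    .assert_even_dims(dims, "pupil")
    r <- .radius_grid_px(dims)
    values <- matrix(as.numeric(r <= cutoff), dims[1L], dims[2L]) + 0i
  } else {
    .assert_even_dims(dim(values), "pupil")
    a <- Mod(values)
    over <- a > max_amplitude
    if (any(over)) values[over] <- values[over] * (max_amplitude / a[over])
  }
  structure(list(values = values + 0i, na = na,
                 wavelength_um = wavelength_um,
                 cutoff_radius_px = cutoff,
                 freq_step_per_um = freq_step_per_um,
                 max_amplitude = max_amplitude),
            class = "pupil_function")
}

# radial pixel distance from the DC-centered origin
.radius_grid_px <- function(dims) {
  cy <- dims[1L] / 2 + 1L
  cx <- dims[2L] / 2 + 1L
  yy <- (seq_len(dims[1L]) - cy)
  xx <- (seq_len(dims[2L]) - cx)
  sqrt(outer(yy^2, xx^2, `+`))
}

#' Logical mask of the pupil NA disk
#' @param pupil a [pupil_function()].
#' @param dilate multiplicative dilation of the cutoff radius (default 1).
#' @return logical matrix, TRUE inside the (dilated) cutoff disk.
#' @export
pupil_support <- function(pupil, dilate = 1) {
  .radius_grid_px(dim(pupil$values)) <= pupil$cutoff_radius_px * dilate
}

# ---- ObservationSet --------------------------------------------------------

#' A stack of intensity observations with acquisition metadata
#'
#' @param frames list of non-negative numeric matrices (one per exposure).
#' @param illum per-frame illumination descriptor: a list with, per frame,
#'   either `kx`/`ky` (LED spatial frequency, 1/um), `shift` (integer
#'   `c(dy, dx)` scan shift in pixels), or `distance_um`.
#' @param meta named list: `wavelength_um`, `pixel_pitch_um`, and optionally
#'   `magnification`, `objective_na`.
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(frames, illum = NULL, meta = list()) {
  if (!is.list(frames)) frames <- list(frames)
  obs <- structure(list(frames = frames, illum = illum, meta = meta),
                   class = "observation_set")
  issues <- validate_observation_set(obs)
  if (length(issues))
    stop("invalid observation set:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  obs
}

#' Validate an observation set
#'
#' Reports (rather than throws) every invariant violation: negative
#' intensities, frame-shape mismatches, missing metadata.
#'
#' @param obs a list shaped like an [observation_set()].
#' @return character vector of issue descriptions; empty if valid.
#' @export
validate_observation_set <- function(obs) {
  issues <- character()
  fr <- obs$frames
  if (length(fr) < 1L) issues <- c(issues, "no frames: N must be >= 1")
  shapes <- vapply(fr, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) > 1L)
    issues <- c(issues, sprintf("shape mismatch across frames: %s",
                                paste(unique(shapes), collapse = " vs ")))
  for (i in seq_along(fr)) {
    f <- fr[[i]]
    if (!is.matrix(f)) { issues <- c(issues, sprintf("frame %d is not a matrix", i)); next }
    if (any(!is.finite(f))) issues <- c(issues, sprintf("frame %d has non-finite values", i))
    else if (any(f < 0)) issues <- c(issues, sprintf("frame %d has negative intensity", i))
  }
  for (key in c("wavelength_um", "pixel_pitch_um"))
    if (is.null(obs$meta[[key]]))
      issues <- c(issues, sprintf("missing metadata: %s", key))
  if (!is.null(obs$illum) && length(obs$illum) != length(fr))
    issues <- c(issues, "illumination descriptors do not match frame count")
  issues
}

#' @export
print.observation_set <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1L]]) else c(0L, 0L)
  cat(sprintf("<observation_set> %d frame(s) of %dx%d, lambda %.4g um, pitch %.4g um\n",
              length(x$frames), d[1L], d[2L],
              x$meta$wavelength_um %||% NA_real_,
              x$meta$pixel_pitch_um %||% NA_real_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- frequency grid --------------------------------------------------------

#' DC-centered spatial-frequency coordinate grids
#'
#' Frequencies in 1/um for a grid of the given shape and pixel pitch, with
#' DC at the center pixel `(n/2 + 1, m/2 + 1)` and step `1/(dim * pitch)`
#' per axis.
#'
#' @param shape integer vector `c(rows, cols)`, both even.
#' @param pixel_pitch_um sampling interval in micrometres.
#' @return list with matrices `fy`, `fx` (1/um) and steps `dfy`, `dfx`.
#' @export
make_frequency_grid <- function(shape, pixel_pitch_um) {
  .assert_even_dims(shape, "frequency grid")
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be > 0", call. = FALSE)
  n <- shape[1L]; m <- shape[2L]
  dfy <- 1 / (n * pixel_pitch_um)
  dfx <- 1 / (m * pixel_pitch_um)
  fy <- ((seq_len(n) - (n / 2 + 1L))) * dfy
  fx <- ((seq_len(m) - (m / 2 + 1L))) * dfx
  list(fy = matrix(fy, n, m), fx = matrix(fx, n, m, byrow = TRUE),
       dfy = dfy, dfx = dfx)
}

# ---- OperatorChain ---------------------------------------------------------

#' Factorized linear operator chain
#'
#' A forward model's linear part as an ordered composition of elementary
#' linear stages, each carrying its own adjoint. `chain_apply` applies
#' stages first-to-last; `chain_adjoint` applies the adjoints in reverse,
#' so the pair satisfies the dot-product identity
#' `<A u, v> == <u, A^H v>`.
#'
#' @param ... stages created by [chain_op()].
#' @return an object of class `operator_chain`.
#' @export
operator_chain <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && is.list(ops[[1L]]) && is.null(ops[[1L]]$kind))
    ops <- ops[[1L]]
  for (op in ops)
    if (!inherits(op, "chain_op")) stop("all stages must be chain_op", call. = FALSE)
  structure(list(ops = ops), class = "operator_chain")
}

#' Elementary linear stage of an operator chain
#'
#' @param kind label (e.g. `"pupil_mask"`, `"inverse_fourier"`).
#' @param forward,adjoint functions mapping a complex matrix to a complex
#'   matrix; `adjoint` must be the true Hermitian adjoint of `forward`.
#' @param params named list of stage parameters (kept for serialization).
#' @return an object of class `chain_op`.
#' @export
chain_op <- function(kind, forward, adjoint, params = list()) {
  structure(list(kind = kind, forward = forward, adjoint = adjoint,
                 params = params),
            class = "chain_op")
}

#' @rdname operator_chain
#' @param chain an `operator_chain`.
#' @param x complex matrix input.
#' @export
chain_apply <- function(chain, x) {
  for (op in chain$ops) x <- op$forward(x)
  x
}

#' @rdname operator_chain
#' @export
chain_adjoint <- function(chain, x) {
  for (op in rev(chain$ops)) x <- op$adjoint(x)
  x
}

#' Hermitian inner product of two complex grids
#' @keywords internal
cdot <- function(a, b) sum(Conj(a) * b)

#' Dot-product (adjoint) test for an operator chain
#'
#' Draws seeded random complex inputs of the stated shapes and checks
#' `<A u, v> == <u, A^H v>` to a relative tolerance.
#'
#' @param chain an [operator_chain()].
#' @param in_dim,out_dim input and output grid dimensions.
#' @param n_trials number of random pairs.
#' @param seed RNG seed.
#' @return maximum relative error observed (invisible TRUE attribute not set).
#' @export
adjoint_test <- function(chain, in_dim, out_dim, n_trials = 10, seed = 1) {
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  worst <- 0
  for (t in seq_len(n_trials)) {
    u <- matrix(stats::rnorm(prod(in_dim)) + 1i * stats::rnorm(prod(in_dim)),
                in_dim[1L], in_dim[2L])
    v <- matrix(stats::rnorm(prod(out_dim)) + 1i * stats::rnorm(prod(out_dim)),
                out_dim[1L], out_dim[2L])
    lhs <- cdot(chain_apply(chain, u), v)
    rhs <- cdot(u, chain_adjoint(chain, v))
    worst <- max(worst, Mod(lhs - rhs) / max(Mod(lhs), Mod(rhs), 1e-300))
  }
  worst
}

# Localized RNG handling: stash and restore .Random.seed so package
# internals never perturb the caller's RNG stream.
.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---- specs -----------------------------------------------------------------

#' Feature-extractor specification
#'
#' Defines the feature map Theta and the intensity scaling S whose
#' composition turns raw intensity frames into the feature tensors the loss
#' compares.
#'
#' @param kind `"gradient"` (forward-difference edge channels),
#'   `"wavelet"` (multi-level biorthogonal detail bands) or `"identity"`.
#' @param wavelet_name currently only `"bior2.2"`.
#' @param levels decomposition depth for the wavelet extractor (default 5).
#' @param scaling intensity scaling applied before feature extraction:
#'   `"sqrt"` (amplitude-like, variance-stabilizing for shot noise;
#'   default), `"identity"`, or `"log1p"`.
#' @param scaling_epsilon small positive offset inside the sqrt.
#' @param gradient_scheme `"forward"` (default) or `"central"` differences.
#' @param include_approx include the coarse approximation band of the
#'   wavelet pyramid in the loss (default TRUE).
#' @return an object of class `feature_extractor_spec`.
#' @export
feature_extractor_spec <- function(kind = c("gradient", "wavelet", "identity"),
                                   wavelet_name = "bior2.2",
                                   levels = 5L,
                                   scaling = c("sqrt", "identity", "log1p"),
                                   scaling_epsilon = 1e-9,
                                   gradient_scheme = c("forward", "central"),
                                   include_approx = TRUE) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  gradient_scheme <- match.arg(gradient_scheme)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  if (scaling_epsilon < 0) stop("scaling_epsilon must be >= 0", call. = FALSE)
  if (!identical(wavelet_name, "bior2.2"))
    stop("only the bior2.2 wavelet is implemented", call. = FALSE)
  structure(list(kind = kind, wavelet_name = wavelet_name,
                 levels = as.integer(levels), scaling = scaling,
                 scaling_epsilon = scaling_epsilon,
                 gradient_scheme = gradient_scheme,
                 include_approx = include_approx),
            class = "feature_extractor_spec")
}

#' Loss (feature-distance) specification
#'
#' @param distance `"l2"`, `"l1"`, or `"charbonnier"` (smooth l1,
#'   `sqrt(r^2 + eps^2) - eps`). Exact `l1` is valid for evaluating a loss
#'   but is rejected by the gradient engine; request `charbonnier` there.
#' @param charbonnier_epsilon smoothing width of the charbonnier distance.
#' @param per_level_weights optional numeric weights applied per feature
#'   tensor (recycled); defaults to 1.
#' @return an object of class `loss_spec`.
#' @export
loss_spec <- function(distance = c("charbonnier", "l2", "l1"),
                      charbonnier_epsilon = 1e-3,
                      per_level_weights = NULL) {
  distance <- match.arg(distance)
  if (charbonnier_epsilon <= 0) stop("charbonnier_epsilon must be > 0", call. = FALSE)
  if (!is.null(per_level_weights) && any(per_level_weights < 0))
    stop("per_level_weights must be >= 0", call. = FALSE)
  structure(list(distance = distance,
                 charbonnier_epsilon = charbonnier_epsilon,
                 per_level_weights = per_level_weights),
            class = "loss_spec")
}

#' Plug-and-play constraint specification
#'
#' One entry of the solver's constraint block: a refinement operator C
#' applied to a target parameter group, contributing the penalty
#' `weight * ||u - C(u)||_p^2` to the loss (penalty mode), or replacing
#' the iterate by C(u) every `every` iterations (replacement mode).
#'
#' @param constraint a function `f(matrix) -> matrix`, or the name of a
#'   built-in (`"amplitude_threshold"`, `"tv"`, `"guided_filter"`,
#'   `"support"`).
#' @param weight penalty weight (alpha for the object, beta_k for operator
#'   parameters); must be >= 0. Ignored in replacement mode.
#' @param target which parameter group C refines: `"object"`, `"pupil"`,
#'   `"probe"` or `"coded_pattern"`.
#' @param component which component of the complex iterate C acts on:
#'   `"complex"`, `"amplitude"` or `"phase"`.
#' @param params named list passed to a built-in constraint.
#' @param norm_order p of the penalty norm (kept for generality; the
#'   implemented penalty gradient is the squared-l2 form, p = 2).
#' @param mode `"penalty"` (gradient contribution `2 w (u - C(u))`) or
#'   `"replace"` (hard projection every `every` iterations).
#' @param every replacement cadence in iterations (replacement mode).
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(constraint, weight = 1, target = "object",
                            component = c("complex", "amplitude", "phase"),
                            params = list(), norm_order = 2,
                            mode = c("penalty", "replace"), every = 1L) {
  component <- match.arg(component)
  mode <- match.arg(mode)
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (!target %in% c("object", "pupil", "probe", "coded_pattern"))
    stop("unknown constraint target: ", target, call. = FALSE)
  structure(list(constraint = constraint, weight = weight, target = target,
                 component = component, params = params,
                 norm_order = norm_order, mode = mode,
                 every = as.integer(every)),
            class = "constraint_spec")
}

#' Solver configuration
#'
#' @param optimizer `"adam"`, `"yogi"` or `"sgd_momentum"`.
#' @param learning_rates named numeric: step size per parameter group
#'   (`object`, `pupil`, `coded_pattern`); unnamed scalar applies to all.
#' @param iterations number of gradient steps (>= 0).
#' @param seed integer seed controlling all solver randomness.
#' @param stop_tol relative loss-change tolerance for early stopping
#'   (0 disables).
#' @param log_every cadence of loss logging (0 silences).
#' @param beta1,beta2,epsilon optimizer moment hyperparameters.
#' @param momentum momentum coefficient for `sgd_momentum`.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(optimizer = c("adam", "yogi", "sgd_momentum"),
                          learning_rates = c(object = 0.01, pupil = 0.001,
                                             coded_pattern = 0.01),
                          iterations = 500L, seed = 1L, stop_tol = 0,
                          log_every = 0L, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-8, momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  if (any(learning_rates <= 0)) stop("learning_rates must be > 0", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rates = learning_rates,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 stop_tol = stop_tol, log_every = as.integer(log_every),
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 momentum = momentum),
            class = "solver_config")
}
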