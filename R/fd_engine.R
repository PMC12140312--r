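# The feature-domain solver: loss, Wirtinger gradients, optimizers, and the
# iteration loop with the plug-and-play constraint block.

# ---- distance functions ----------------------------------------------------

# value and derivative of the distance D applied to a residual tensor
.distance_value <- function(r, loss) {
  switch(loss$distance,
         l2 = sum(r^2),
         l1 = sum(abs(r)),
         charbonnier = {
           e <- loss$charbonnier_epsilon
           sum(sqrt(r^2 + e^2) - e)
         })
}

.distance_deriv <- function(r, loss) {
  switch(loss$distance,
         l2 = 2 * r,
         l1 = stop("exact l1 is non-differentiable at 0; use charbonnier",
                   call. = FALSE),
         charbonnier = r / sqrt(r^2 + loss$charbonnier_epsilon^2))
}

# combine pyramid weights with optional per-level loss weights
.tensor_weights <- function(pyr, loss) {
  w <- pyr$weights
  if (!is.null(loss$per_level_weights))
    w <- w * rep_len(loss$per_level_weights, length(w))
  w
}

#' Feature-domain data-fidelity loss
#'
#' `sum_n sum_tensors w * D(Theta(S(obs_n)), Theta(S(pred_n)))`: both the
#' observed and the model-predicted intensity stacks pass through the same
#' intensity scaling and feature extractor, and the per-tensor distances are
#' accumulated. Non-negative; zero iff all feature tensors coincide (up to
#' the charbonnier smoothing offset).
#'
#' @param predicted_frames,observed_frames lists of same-shape non-negative
#'   matrices.
#' @param extractor a [feature_extractor_spec()].
#' @param loss a [loss_spec()].
#' @return scalar loss.
#' @export
feature_loss <- function(predicted_frames, observed_frames,
                         extractor = feature_extractor_spec(),
                         loss = loss_spec()) {
  if (!is.list(predicted_frames)) predicted_frames <- list(predicted_frames)
  if (!is.list(observed_frames)) observed_frames <- list(observed_frames)
  if (length(predicted_frames) != length(observed_frames))
    stop("frame stacks differ in length", call. = FALSE)
  total <- 0
  for (n in seq_along(predicted_frames)) {
    if (!all(dim(predicted_frames[[n]]) == dim(observed_frames[[n]])))
      stop("frame shape mismatch at index ", n, call. = FALSE)
    fp <- extract_features(predicted_frames[[n]], extractor)
    fo <- extract_features(observed_frames[[n]], extractor)
    w <- .tensor_weights(fp, loss)
    for (k in seq_along(fp$tensors))
      total <- total + w[k] *
        .distance_value(fp$tensors[[k]] - fo$tensors[[k]], loss)
  }
  total
}

# ---- model interface -------------------------------------------------------
# A fdpr_model bundles the differentiable forward map of one modality:
#   $params      named list of complex matrices (initial values)
#   $learn       names of the learnable groups
#   $forward(params, n)        complex detector field of frame n
#   $backward(params, n, wbar) named list of dL/d(conj p) contributions given
#                              wbar = dL/d(conj psi_n) at the detector
#   $n_frames, $kind, plus modality bookkeeping

#' FPM forward model for the solver
#'
#' Parameter groups: `object` (the high-resolution object spectrum,
#' DC-centered) and, when `learn_pupil`, `pupil` (complex pupil values on
#' the low-resolution grid).
#'
#' @param sys an [fpm_system()].
#' @param pupil_init optional [pupil_function()] or complex matrix starting
#'   pupil; default the ideal disk.
#' @param learn_pupil jointly fit the pupil (default TRUE).
#' @param init_spectrum optional starting object spectrum; default is built
#'   from the observation by [fd_default_init()].
#' @return object of class `fdpr_model`.
#' @export
fdpr_model_fpm <- function(sys, pupil_init = NULL, learn_pupil = TRUE,
                           init_spectrum = NULL) {
  pupil <- if (is.null(pupil_init)) fpm_ideal_pupil(sys) else pupil_init
  P0 <- if (inherits(pupil, "pupil_function")) pupil$values else pupil + 0i
  support <- pupil_support(fpm_ideal_pupil(sys), dilate = 1.1)
  idx <- lapply(seq_len(sys$n_leds), function(n) .fpm_crop_index(sys, n))
  s <- sqrt(prod(sys$low_pixels) / prod(sys$object_pixels))
  forward <- function(params, n) {
    patch <- params$object[idx[[n]]$rows, idx[[n]]$cols, drop = FALSE]
    cifft2(patch * params$pupil) * s
  }
  backward <- function(params, n, wbar) {
    u <- cfft2(wbar) * s
    patch <- params$object[idx[[n]]$rows, idx[[n]]$cols, drop = FALSE]
    gX <- matrix(0 + 0i, sys$object_pixels[1L], sys$object_pixels[2L])
    gX[idx[[n]]$rows, idx[[n]]$cols] <- u * Conj(params$pupil)
    out <- list(object = gX)
    if (learn_pupil) out$pupil <- u * Conj(patch)
    out
  }
  structure(list(kind = "fpm", sys = sys,
                 params = list(object = NULL, pupil = P0),
                 init_spectrum = init_spectrum,
                 learn = c("object", if (learn_pupil) "pupil"),
                 pupil_support = support,
                 forward = forward, backward = backward,
                 n_frames = sys$n_leds),
            class = "fdpr_model")
}

#' Inline-holography forward model for the solver
#'
#' Single parameter group `object`: the complex exit wave at the sample
#' plane, propagated to the detector by the angular-spectrum method.
#'
#' @param distance_um sample-to-sensor distance (um).
#' @param dims,pixel_pitch_um,wavelength_um detector grid geometry.
#' @return object of class `fdpr_model`.
#' @export
fdpr_model_holography <- function(distance_um, dims, pixel_pitch_um,
                                  wavelength_um) {
  H <- .asp_transfer(dims, pixel_pitch_um, wavelength_um, distance_um)
  forward <- function(params, n) cifft2(cfft2(params$object) * H)
  backward <- function(params, n, wbar)
    list(object = cifft2(cfft2(wbar) * Conj(H)))
  structure(list(kind = "holography", distance_um = distance_um,
                 dims = dims, pixel_pitch_um = pixel_pitch_um,
                 wavelength_um = wavelength_um,
                 params = list(object = NULL),
                 learn = "object",
                 forward = forward, backward = backward,
                 n_frames = 1L),
            class = "fdpr_model")
}

#' Coded-ptychography forward model for the solver
#'
#' Parameter groups `object` and, when `learn_pattern`, `coded_pattern`.
#'
#' @param sys a [lensless_system()].
#' @param pixel_pitch_um,wavelength_um grid geometry (um).
#' @param learn_pattern jointly fit the coded pattern (default TRUE).
#' @return object of class `fdpr_model`.
#' @export
fdpr_model_coded <- function(sys, pixel_pitch_um, wavelength_um,
                             learn_pattern = TRUE) {
  dims <- dim(sys$coded_pattern$values)
  H1 <- if (sys$sample_to_mask_um > 0)
    .asp_transfer(dims, pixel_pitch_um, wavelength_um, sys$sample_to_mask_um)
  H2 <- if (sys$mask_to_sensor_um > 0)
    .asp_transfer(dims, pixel_pitch_um, wavelength_um, sys$mask_to_sensor_um)
  prop <- function(x, H) if (is.null(H)) x else cifft2(cfft2(x) * H)
  iprop <- function(x, H) if (is.null(H)) x else cifft2(cfft2(x) * Conj(H))
  forward <- function(params, n) {
    sh <- sys$scan_shifts_px[n, ]
    w1 <- prop(.circshift(params$object, sh[1L], sh[2L]), H1)
    prop(w1 * params$coded_pattern, H2)
  }
  backward <- function(params, n, wbar) {
    sh <- sys$scan_shifts_px[n, ]
    w1 <- prop(.circshift(params$object, sh[1L], sh[2L]), H1)
    u2 <- iprop(wbar, H2)
    gobj <- .circshift(iprop(u2 * Conj(params$coded_pattern), H1),
                       -sh[1L], -sh[2L])
    out <- list(object = gobj)
    if (learn_pattern) out$coded_pattern <- u2 * Conj(w1)
    out
  }
  structure(list(kind = "coded", sys = sys,
                 pixel_pitch_um = pixel_pitch_um,
                 wavelength_um = wavelength_um,
                 params = list(object = NULL,
                               coded_pattern = sys$coded_pattern$values),
                 learn = c("object", if (learn_pattern) "coded_pattern"),
                 forward = forward, backward = backward,
                 n_frames = sys$n_frames),
            class = "fdpr_model")
}

#' Default parameter initialization from the observation
#'
#' FPM: object spectrum from the Fourier-upsampled square root of the mean
#' brightfield frame with zero phase; pupil from the ideal disk.
#' Holography: square root of the hologram back-propagated to the sample
#' plane. Coded ptychography: unit object, pattern as configured.
#'
#' @param model a `fdpr_model`.
#' @param observation an [observation_set()].
#' @return the model with `params` filled in.
#' @export
fd_default_init <- function(model, observation) {
  p <- model$params
  if (model$kind == "fpm") {
    if (is.null(p$object)) {
      if (!is.null(model$init_spectrum)) p$object <- model$init_spectrum + 0i
      else {
        sys <- model$sys
        bf <- which.min(rowSums(sys$led_kvectors^2))
        amp <- sqrt(pmax(observation$frames[[bf]], 0))
        hi <- sys$object_pixels; lo <- sys$low_pixels
        Xlo <- cfft2(amp + 0i) * sqrt(prod(hi) / prod(lo))
        X <- matrix(0 + 0i, hi[1L], hi[2L])
        r0 <- hi[1L] %/% 2L - lo[1L] %/% 2L + 1L
        c0 <- hi[2L] %/% 2L - lo[2L] %/% 2L + 1L
        X[r0:(r0 + lo[1L] - 1L), c0:(c0 + lo[2L] - 1L)] <- Xlo
        p$object <- X
      }
    }
  } else if (model$kind == "holography") {
    if (is.null(p$object)) {
      amp <- sqrt(pmax(observation$frames[[1L]], 0))
      fld <- complex_field(amp + 0i, model$pixel_pitch_um,
                           model$wavelength_um, plane = "detector")
      p$object <- angular_spectrum_propagate(fld, -model$distance_um)$values
    }
  } else if (model$kind == "coded") {
    if (is.null(p$object))
      p$object <- matrix(1 + 0i, nrow(p$coded_pattern), ncol(p$coded_pattern))
  }
  model$params <- p
  model
}

# ---- Wirtinger gradient ----------------------------------------------------

#' Wirtinger gradient of the feature-domain loss
#'
#' Back-propagates the feature-domain residual through the intensity
#' scaling, the squared modulus and the linear forward chain, returning for
#' each learnable parameter group the direction `g = 2 dL/d(conj p)`, which
#' satisfies `L(p - t g) = L(p) - t ||g||^2 + o(t)` for real step `t`.
#'
#' @param params named list of complex parameter matrices.
#' @param observation an [observation_set()].
#' @param model a `fdpr_model`.
#' @param extractor a [feature_extractor_spec()].
#' @param loss a [loss_spec()] (`l1` must be smoothed: use charbonnier).
#' @param obs_features optional precomputed list of observed-frame pyramids.
#' @param frames optional integer subset of frames to accumulate.
#' @param frame_weights optional per-frame loss weights (length
#'   `model$n_frames`); dim darkfield frames otherwise contribute little and
#'   leave the pupil rim under-determined.
#' @return list with `loss` (scalar) and `grads` (named list of complex
#'   matrices over `model$learn`).
#' @export
wirtinger_gradient <- function(params, observation, model,
                               extractor = feature_extractor_spec(),
                               loss = loss_spec(),
                               obs_features = NULL, frames = NULL,
                               frame_weights = NULL) {
  if (identical(loss$distance, "l1"))
    stop("exact l1 is non-differentiable at 0; use charbonnier", call. = FALSE)
  if (is.null(frames)) frames <- seq_len(model$n_frames)
  if (is.null(obs_features))
    obs_features <- lapply(observation$frames[frames], extract_features,
                           spec = extractor)
  grads <- stats::setNames(vector("list", length(model$learn)), model$learn)
  total <- 0
  for (j in seq_along(frames)) {
    n <- frames[j]
    psi <- model$forward(params, n)
    I <- Re(psi * Conj(psi))
    fp <- extract_features(I, extractor)
    fo <- obs_features[[j]]
    w <- .tensor_weights(fp, loss)
    if (!is.null(frame_weights)) w <- w * frame_weights[n]
    gt <- vector("list", length(fp$tensors))
    for (k in seq_along(fp$tensors)) {
      r <- fp$tensors[[k]] - fo$tensors[[k]]
      total <- total + w[k] * .distance_value(r, loss)
      gt[[k]] <- w[k] * .distance_deriv(r, loss)
    }
    gI <- .features_adjoint(gt, extractor, dim(I)) *
      .scale_intensity_deriv(I, extractor)
    wbar <- gI * psi                      # dL/d(conj psi): I = psi conj(psi)
    contrib <- model$backward(params, n, wbar)
    for (nm in model$learn) {
      if (is.null(contrib[[nm]])) next
      grads[[nm]] <- if (is.null(grads[[nm]])) contrib[[nm]]
                     else grads[[nm]] + contrib[[nm]]
    }
  }
  for (nm in model$learn) {
    if (is.null(grads[[nm]]))
      grads[[nm]] <- matrix(0 + 0i, nrow(params[[nm]]), ncol(params[[nm]]))
    grads[[nm]] <- 2 * grads[[nm]]        # g = 2 dL/d(conj p)
  }
  list(loss = total, grads = grads)
}

# ---- optimizers ------------------------------------------------------------

#' Fresh optimizer state for one parameter group
#'
#' @param optimizer `"adam"`, `"yogi"` or `"sgd_momentum"`.
#' @param dims parameter dimensions.
#' @param beta1,beta2,epsilon,momentum hyperparameters.
#' @return object of class `opt_state`.
#' @export
opt_state <- function(optimizer, dims, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, momentum = 0.9) {
  structure(list(optimizer = optimizer,
                 m = matrix(0 + 0i, dims[1L], dims[2L]),
                 v = matrix(0, dims[1L], dims[2L]),
                 t = 0L, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 momentum = momentum),
            class = "opt_state")
}

#' One optimizer update
#'
#' Adam: exponential first/second moments with bias correction. YOGI: the
#' Adam first moment, but the second moment updated additively by
#' `v <- v - (1 - beta2) * sign(v - |g|^2) * |g|^2`, which forgets stale
#' curvature more slowly and damps the oscillations of non-convex phase
#' retrieval. Complex parameters track the first moment on the complex
#' gradient and the second moment on its squared modulus.
#'
#' @param state an [opt_state()].
#' @param params complex (or real) parameter matrix.
#' @param grads gradient matrix, same shape.
#' @param lr learning rate (> 0).
#' @return list with updated `params` and `state`.
#' @export
optimizer_step <- function(state, params, grads, lr) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (any(!is.finite(Re(grads))) || any(!is.finite(Im(grads))))
    stop("non-finite gradient passed to optimizer_step", call. = FALSE)
  state$t <- state$t + 1L
  if (state$optimizer == "sgd_momentum") {
    state$m <- state$momentum * state$m + grads
    params <- params - lr * state$m
    return(list(params = params, state = state))
  }
  g2 <- Re(grads * Conj(grads))
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grads
  if (state$optimizer == "adam") {
    state$v <- state$beta2 * state$v + (1 - state$beta2) * g2
  } else {                                # yogi
    state$v <- state$v - (1 - state$beta2) * sign(state$v - g2) * g2
  }
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  params <- params - lr * mhat / (sqrt(vhat) + state$epsilon)
  list(params = params, state = state)
}

# ---- eHIO constraint block -------------------------------------------------

#' Apply the plug-and-play constraint block
#'
#' For each penalty-mode constraint, evaluates `u_tilde = C(u)` with C
#' treated as fixed (no gradient through C) and contributes
#' `2 * weight * (u - u_tilde)` to the target's gradient, plus the penalty
#' value `weight * ||u - u_tilde||^2`. Replacement-mode constraints project
#' the iterate, `u <- C(u)`, at their cadence. Constraints are evaluated in
#' list order.
#'
#' @param params named list of complex parameter matrices.
#' @param constraints list of [constraint_spec()].
#' @param iter current iteration (for replacement cadence; default 1).
#' @return list with `grads` (named contributions), `params` (possibly
#'   refined), and `penalty` (scalar).
#' @export
apply_ehio_block <- function(params, constraints, iter = 1L) {
  grads <- list()
  penalty <- 0
  for (spec in constraints) {
    tgt <- spec$target
    if (tgt == "probe") tgt <- "coded_pattern"
    if (is.null(params[[tgt]]))
      stop("constraint target not among parameters: ", spec$target,
           call. = FALSE)
    f <- .resolve_constraint(spec)
    if (identical(spec$mode, "replace")) {
      if (iter %% max(spec$every, 1L) == 0L)
        params[[tgt]] <- f(params[[tgt]]) + 0i
      next
    }
    if (spec$weight == 0) next
    u <- params[[tgt]]
    ut <- f(u) + 0i
    d <- u - ut
    penalty <- penalty + spec$weight * sum(Re(d * Conj(d)))
    g <- 2 * spec$weight * d
    grads[[tgt]] <- if (is.null(grads[[tgt]])) g else grads[[tgt]] + g
  }
  list(grads = grads, params = params, penalty = penalty)
}

# ---- solver ----------------------------------------------------------------

#' Fit a wavefront by feature-domain phase retrieval
#'
#' The single solver entry point: runs `config$iterations` steps of
#' Wirtinger gradient descent on the feature-domain loss, with the
#' constraint block applied each iteration and per-group Adam/YOGI/SGD
#' updates. Deterministic given `config$seed`. Returns the best-loss
#' iterate (the loss oscillates before convergence under adaptive
#' optimizers, so the last iterate need not be the best).
#'
#' @param observation an [observation_set()].
#' @param model a `fdpr_model` ([fdpr_model_fpm()],
#'   [fdpr_model_holography()], [fdpr_model_coded()]).
#' @param extractor a [feature_extractor_spec()].
#' @param loss a [loss_spec()].
#' @param constraints list of [constraint_spec()].
#' @param config a [solver_config()].
#' @param init optional named list of starting parameter values overriding
#'   the defaults from [fd_default_init()].
#' @param batch_leds optional integer: process seeded random mini-batches of
#'   this many frames per step instead of the full sum.
#' @param frame_weights optional per-frame loss weights, or `"normalize"`
#'   to weight each frame by the reciprocal of its mean observed intensity
#'   (equalizes bright- and darkfield contributions).
#' @return an object of class `fdpr_fit`; see [coef.fdpr_fit()],
#'   [fitted.fdpr_fit()], [plot.fdpr_fit()].
#' @export
fd_solve <- function(observation, model,
                     extractor = feature_extractor_spec(),
                     loss = loss_spec(),
                     constraints = list(),
                     config = solver_config(),
                     init = NULL, batch_leds = NULL, frame_weights = NULL) {
  stopifnot(inherits(model, "fdpr_model"))
  if (length(validate_observation_set(observation)))
    stop("invalid observation set", call. = FALSE)
  if (model$n_frames != length(observation$frames))
    stop("model frame count does not match observation", call. = FALSE)
  model <- fd_default_init(model, observation)
  params <- model$params
  if (!is.null(init)) for (nm in names(init)) params[[nm]] <- init[[nm]] + 0i
  for (nm in model$learn)
    if (is.null(params[[nm]])) stop("missing initialization for ", nm, call. = FALSE)

  old_seed <- .seed_swap(config$seed)
  on.exit(.seed_restore(old_seed))

  if (identical(frame_weights, "normalize"))
    frame_weights <- 1 / pmax(vapply(observation$frames, mean, 0), 1e-12)
  obs_features <- lapply(observation$frames, extract_features, spec = extractor)
  lr <- config$learning_rates
  if (is.null(names(lr))) lr <- stats::setNames(rep(lr[1L], length(model$learn)),
                                                model$learn)
  states <- lapply(model$learn, function(nm)
    opt_state(config$optimizer, dim(params[[nm]]), config$beta1, config$beta2,
              config$epsilon, config$momentum))
  names(states) <- model$learn

  trace <- numeric(0)
  # best-loss return is meaningful for penalty-form runs; with hard
  # replacement constraints the projected final iterate is the estimate
  # (tracking the raw loss would always point back at the start)
  use_best <- !any(vapply(constraints, function(s)
    identical(s$mode, "replace"), TRUE))
  best <- list(loss = Inf, params = params, iter = 0L)
  init_loss <- NA_real_
  for (it in seq_len(config$iterations)) {
    frames <- NULL
    obs_sub <- obs_features
    if (!is.null(batch_leds) && batch_leds < model$n_frames) {
      frames <- sample.int(model$n_frames, batch_leds)
      obs_sub <- obs_features[frames]
    }
    wg <- wirtinger_gradient(params, observation, model, extractor, loss,
                             obs_features = obs_sub, frames = frames,
                             frame_weights = frame_weights)
    eh <- apply_ehio_block(params, constraints, iter = it)
    params <- eh$params
    total <- wg$loss + eh$penalty
    trace <- c(trace, total)
    if (it == 1L) init_loss <- total
    # the divergence guard references the largest early loss: an
    # initialization that already reproduces the data (loss 0) must not
    # make every later iterate look divergent
    if (it <= 5L) div_ref <- max(if (exists("div_ref")) div_ref else 0, total)
    if (use_best && is.finite(total) && total < best$loss)
      best <- list(loss = total, params = params, iter = it)
    if (!is.finite(total) || (it > 5L && total > 1e6 * max(div_ref, 1e-300)))
      stop(sprintf("divergence at iteration %d: loss %.4g (initial %.4g)",
                   it, total, init_loss), call. = FALSE)
    for (nm in model$learn) {
      g <- wg$grads[[nm]]
      if (!is.null(eh$grads[[nm]])) g <- g + eh$grads[[nm]]
      lrg <- if (!is.na(lr[nm])) lr[[nm]] else lr[[1L]]
      st <- optimizer_step(states[[nm]], params[[nm]], g, lrg)
      params[[nm]] <- st$params
      states[[nm]] <- st$state
    }
    if (config$log_every > 0L && it %% config$log_every == 0L)
      message(sprintf("iter %5d  loss %.6g", it, total))
    if (config$stop_tol > 0 && it > 1L) {
      prev <- trace[it - 1L]
      if (abs(prev - total) <= config$stop_tol * max(abs(prev), 1e-300)) break
    }
  }
  # evaluate the final iterate too, so 'best' covers the whole trajectory
  if (config$iterations > 0L) {
    wg <- wirtinger_gradient(params, observation, model, extractor, loss,
                             obs_features = obs_features,
                             frame_weights = frame_weights)
    fin <- wg$loss + apply_ehio_block(params, constraints,
                                      iter = config$iterations + 1L)$penalty
    if (!use_best || (is.finite(fin) && fin < best$loss))
      best <- list(loss = fin, params = params, iter = length(trace))
  }

  structure(list(params = best$params, loss = best$loss,
                 best_iter = best$iter, loss_trace = trace,
                 model = model, extractor = extractor, loss_spec = loss,
                 constraints = constraints, config = config,
                 seed = config$seed,
                 observation_meta = observation$meta,
                 observation = observation),
            class = "fdpr_fit")
}

#' Recovered object field of a fit
#'
#' For FPM the object parameter is a spectrum; this helper returns the
#' spatial complex object for any modality.
#'
#' @param fit an `fdpr_fit`.
#' @return complex matrix (spatial domain).
#' @export
recovered_object <- function(fit) {
  if (fit$model$kind == "fpm") cifft2(fit$params$object)
  else fit$params$object
}

#' Blind joint object-and-pupil FPM recovery
#'
#' The package's recipe for recovering large unknown pupil aberrations
#' without priors: a feature-domain fit with first-order gradient features,
#' sqrt intensity scaling and the charbonnier distance, jointly optimizing
#' the object spectrum and the complex pupil from the ideal-disk starting
#' point. The pupil learning rate is higher than the general default
#' because the aberration phase must traverse several radians. The
#' recovered pupil carries the usual blind gauges (global phase, a possibly
#' multi-wrap tip/tilt against an object translation, and the conjugate
#' twin for symmetric LED sets); compare against references with
#' [pupil_phase_rms()], which removes them.
#'
#' @param observation an [observation_set()] of FPM frames.
#' @param sys the [fpm_system()] that produced them.
#' @param iterations gradient-descent budget (default 400).
#' @param seed solver seed.
#' @param learning_rates per-group Adam rates.
#' @return an `fdpr_fit`.
#' @export
fd_blind_fpm <- function(observation, sys, iterations = 400L, seed = 1L,
                         learning_rates = c(object = 0.02, pupil = 0.05)) {
  fd_solve(observation, fdpr_model_fpm(sys, learn_pupil = TRUE),
           feature_extractor_spec("gradient"), loss_spec("charbonnier"),
           config = solver_config("adam", learning_rates,
                                  iterations = iterations, seed = seed))
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.fdpr_fit <- function(x, ...) {
  cat(sprintf("<fdpr_fit> %s, %d frame(s), %s features, %s distance\n",
              x$model$kind, x$model$n_frames, x$extractor$kind,
              x$loss_spec$distance))
  cat(sprintf("  %d iteration(s); best loss %.6g at iteration %d\n",
              length(x$loss_trace), x$loss, x$best_iter))
  invisible(x)
}

#' @export
summary.fdpr_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Feature-domain phase retrieval fit (%s)\n", x$model$kind))
  cat(sprintf("  frames:      %d\n", x$model$n_frames))
  cat(sprintf("  features:    %s (scaling %s)\n", x$extractor$kind,
              x$extractor$scaling))
  cat(sprintf("  distance:    %s\n", x$loss_spec$distance))
  cat(sprintf("  optimizer:   %s, seed %d\n", x$config$optimizer, x$seed))
  cat(sprintf("  iterations:  %d run, best at %d\n", length(x$loss_trace),
              x$best_iter))
  cat(sprintf("  loss:        initial %.6g -> best %.6g\n",
              x$loss_trace[1L], x$loss))
  for (nm in names(x$params))
    cat(sprintf("  param %-14s %s\n", nm,
                paste(dim(x$params[[nm]]), collapse = "x")))
  if (length(x$constraints))
    cat(sprintf("  constraints: %d (%s)\n", length(x$constraints),
                paste(vapply(x$constraints, function(s)
                  if (is.character(s$constraint)) s$constraint else "custom",
                  ""), collapse = ", ")))
  invisible(x)
}

#' Extract recovered parameters
#' @param object an `fdpr_fit`.
#' @param ... unused.
#' @return named list of recovered complex parameter matrices.
#' @export
coef.fdpr_fit <- function(object, ...) object$params

#' Model-predicted intensity frames at the recovered parameters
#' @param object an `fdpr_fit`.
#' @param ... unused.
#' @return list of non-negative matrices, one per frame.
#' @export
fitted.fdpr_fit <- function(object, ...) {
  lapply(seq_len(object$model$n_frames), function(n) {
    psi <- object$model$forward(object$params, n)
    Re(psi * Conj(psi))
  })
}

#' Intensity residuals (observed minus fitted)
#' @param object an `fdpr_fit`.
#' @param ... unused.
#' @return list of matrices.
#' @export
residuals.fdpr_fit <- function(object, ...) {
  f <- fitted(object)
  lapply(seq_along(f), function(n) object$observation$frames[[n]] - f[[n]])
}

#' Plot the loss trace of a fit
#' @param x an `fdpr_fit`.
#' @param log_y log-scale the loss axis (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fdpr_fit <- function(x, log_y = TRUE, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "iteration", ylab = "loss",
                 log = if (log_y && all(x$loss_trace > 0)) "y" else "",
                 main = sprintf("FD-PR loss (%s)", x$model$kind), ...)
  graphics::abline(v = x$best_iter, lty = 3)
  invisible(x)
}
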