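test_that("feature loss hits its closed forms and the brute-force oracle", {
  idspec <- feature_extractor_spec("identity", scaling = "identity")
  f <- abs(seeded_matrix(16, seed = 3))
  expect_equal(feature_loss(list(f), list(f), idspec, loss_spec("l2")), 0)
  expect_equal(feature_loss(list(f), list(f), idspec,
                            loss_spec("l1")), 0)

  # obs = 0, pred = 1 on a 2x2 frame, l2: sum of squares = 4
  expect_equal(feature_loss(list(matrix(1, 2, 2)), list(matrix(0, 2, 2)),
                            idspec, loss_spec("l2")), 4)

  # seeded stack, gradient features, charbonnier vs direct summation
  gspec <- feature_extractor_spec("gradient", scaling = "sqrt",
                                  scaling_epsilon = 1e-9)
  lsp <- loss_spec("charbonnier", charbonnier_epsilon = 1e-3)
  obs <- lapply(1:3, function(i) abs(seeded_matrix(32, seed = 20 + i)))
  pred <- lapply(1:3, function(i) abs(seeded_matrix(32, seed = 30 + i)))
  direct <- 0
  for (i in 1:3) {
    po <- gradient_features(sqrt(obs[[i]] + 1e-9))
    pp <- gradient_features(sqrt(pred[[i]] + 1e-9))
    for (k in 1:2) {
      r <- pp$tensors[[k]] - po$tensors[[k]]
      direct <- direct + sum(sqrt(r^2 + 1e-6) - 1e-3)
    }
  }
  expect_equal(feature_loss(pred, obs, gspec, lsp), direct,
               tolerance = 1e-12)
  expect_error(feature_loss(list(matrix(1, 2, 2)), list(matrix(1, 4, 4))),
               "shape")
})

test_that("Wirtinger gradient vanishes at a noiseless global minimum", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  model <- fd_default_init(fdpr_model_fpm(sys), sim$observation)
  truth <- list(object = sim$truth$object_spectrum,
                pupil = sim$truth$pupil$values)
  wg <- wirtinger_gradient(truth, sim$observation, model,
                           feature_extractor_spec("gradient"),
                           loss_spec("l2"))
  expect_lt(sqrt(sum(Mod(wg$grads$object)^2)), 1e-8)
  expect_lt(sqrt(sum(Mod(wg$grads$pupil)^2)), 1e-8)
})

test_that("single-pixel identity model recovers the analytic gradient", {
  # A = identity, D = l2, identity features and scaling:
  # L = sum((|x|^2 - I)^2), gradient g = 4 (|x|^2 - I) x
  dims <- c(2, 2)
  I_obs <- matrix(c(0.5, 1, 2, 0.1), 2, 2)
  model <- structure(list(
    kind = "custom", n_frames = 1L,
    params = list(object = NULL), learn = "object",
    forward = function(params, n) params$object,
    backward = function(params, n, wbar) list(object = wbar)),
    class = "fdpr_model")
  x <- matrix(c(1 + 1i, 0.3 - 2i, -1 + 0.5i, 2 + 0i), 2, 2)
  obs <- observation_set(list(I_obs), meta = list(wavelength_um = 1,
                                                  pixel_pitch_um = 1))
  wg <- wirtinger_gradient(list(object = x), obs, model,
                           feature_extractor_spec("identity",
                                                  scaling = "identity"),
                           loss_spec("l2"))
  expect_equal(wg$loss, sum((Mod(x)^2 - I_obs)^2))
  expect_equal(wg$grads$object, 4 * (Mod(x)^2 - I_obs) * x,
               tolerance = 1e-12)
})

test_that("Wirtinger gradients match central finite differences", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  model <- fd_default_init(fdpr_model_fpm(sys), sim$observation)
  params <- model$params
  params$object <- params$object * (1 + 0.1 * seeded_matrix(32, seed = 40,
                                                            complex = TRUE))
  ex <- feature_extractor_spec("gradient")
  lo <- loss_spec("charbonnier")
  wg <- wirtinger_gradient(params, sim$observation, model, ex, lo)
  set.seed(55)
  coords <- sample(length(params$object), 10)
  worst <- 0
  for (ii in coords) for (d in c(1, 1i)) {
    h <- 1e-5 * max(1, Mod(params$object[ii]))
    pp <- params; pm <- params
    pp$object[ii] <- pp$object[ii] + d * h
    pm$object[ii] <- pm$object[ii] - d * h
    num <- (wirtinger_gradient(pp, sim$observation, model, ex, lo)$loss -
            wirtinger_gradient(pm, sim$observation, model, ex, lo)$loss) /
      (2 * h)
    ana <- if (d == 1) Re(wg$grads$object[ii]) else Im(wg$grads$object[ii])
    worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
  }
  # pupil coordinates too
  for (ii in sample(length(params$pupil), 10)) for (d in c(1, 1i)) {
    h <- 1e-6
    pp <- params; pm <- params
    pp$pupil[ii] <- pp$pupil[ii] + d * h
    pm$pupil[ii] <- pm$pupil[ii] - d * h
    num <- (wirtinger_gradient(pp, sim$observation, model, ex, lo)$loss -
            wirtinger_gradient(pm, sim$observation, model, ex, lo)$loss) /
      (2 * h)
    ana <- if (d == 1) Re(wg$grads$pupil[ii]) else Im(wg$grads$pupil[ii])
    worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-8))
  }
  expect_lt(worst, 1e-4)
  expect_error(wirtinger_gradient(params, sim$observation, model, ex,
                                  loss_spec("l1")), "charbonnier")
})

test_that("optimizer steps follow the Adam/YOGI recursions", {
  st <- opt_state("adam", c(1, 1))
  out <- optimizer_step(st, matrix(1 + 0i), matrix(0 + 0i), 0.1)
  expect_equal(out$params, matrix(1 + 0i))      # zero gradient: no motion

  # bias-corrected first step has magnitude ~ lr
  st <- opt_state("adam", c(1, 1))
  out <- optimizer_step(st, matrix(0 + 0i), matrix(3 + 0i), 0.1)
  expect_equal(Mod(out$params[1, 1]), 0.1, tolerance = 1e-6)

  # scripted YOGI recursion vs hand-rolled reference
  g_seq <- c(0.5, -1.2, 0.8, 0.05, -0.3)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- 0.05
  p_ref <- 2; m <- 0; v <- 0
  for (t in seq_along(g_seq)) {
    g <- g_seq[t]
    m <- b1 * m + (1 - b1) * g
    v <- v - (1 - b2) * sign(v - g^2) * g^2
    mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
    p_ref <- p_ref - lr * mhat / (sqrt(vhat) + eps)
  }
  st <- opt_state("yogi", c(1, 1), beta1 = b1, beta2 = b2, epsilon = eps)
  p <- matrix(2 + 0i)
  for (t in seq_along(g_seq)) {
    out <- optimizer_step(st, p, matrix(g_seq[t] + 0i), lr)
    p <- out$params; st <- out$state
  }
  expect_equal(Re(p[1, 1]), p_ref, tolerance = 1e-12)
  expect_error(optimizer_step(st, p, matrix(NaN + 0i), lr), "non-finite")
})

test_that("the constraint block contributes the penalty gradient", {
  x <- matrix(1 + 0i, 16, 16)
  params <- list(object = x)
  # weight 0: no contribution, params untouched
  eh <- apply_ehio_block(params, list(constraint_spec("tv", weight = 0)))
  expect_length(eh$grads, 0)
  expect_identical(eh$params, params)
  expect_equal(eh$penalty, 0)

  # identity constraint: zero contribution regardless of weight
  eh <- apply_ehio_block(params, list(constraint_spec(function(u) u,
                                                      weight = 5)))
  expect_equal(max(Mod(eh$grads$object)), 0)
  expect_equal(eh$penalty, 0)

  # hard support mask: gradient 2 alpha x outside, 0 inside
  disk <- fdpr:::.radius_grid_px(c(16, 16)) <= 5
  alpha <- 0.7
  eh <- apply_ehio_block(params, list(
    constraint_spec("support", weight = alpha,
                    params = list(mask = disk))))
  expect_equal(eh$grads$object[!disk], 2 * alpha * x[!disk])
  expect_equal(max(Mod(eh$grads$object[disk])), 0)
  expect_equal(eh$penalty, alpha * sum(!disk))

  expect_error(apply_ehio_block(params, list(
    constraint_spec("tv", target = "pupil"))), "target")

  # replacement mode projects at its cadence
  eh <- apply_ehio_block(params, list(
    constraint_spec("support", mode = "replace",
                    params = list(mask = disk))), iter = 3)
  expect_equal(max(Mod(eh$params$object[!disk])), 0)
})

test_that("solve returns the initialization untouched for zero iterations", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  fit <- fd_solve(sim$observation, fdpr_model_fpm(sys),
                  config = solver_config(iterations = 0))
  expect_length(fit$loss_trace, 0)
  init <- fd_default_init(fdpr_model_fpm(sys), sim$observation)
  expect_identical(fit$params$object, init$params$object)
})

test_that("identical seeds give bitwise-identical loss traces", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  cfg <- solver_config("adam", c(object = 0.01, pupil = 0.002),
                       iterations = 25, seed = 13)
  f1 <- fd_solve(sim$observation, fdpr_model_fpm(sys),
                 feature_extractor_spec("gradient"), loss_spec("charbonnier"),
                 config = cfg, batch_leds = 5)
  f2 <- fd_solve(sim$observation, fdpr_model_fpm(sys),
                 feature_extractor_spec("gradient"), loss_spec("charbonnier"),
                 config = cfg, batch_leds = 5)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$params$object, f2$params$object)
})

test_that("plain gradient descent is non-increasing on noiseless data", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  fit <- fd_solve(sim$observation, fdpr_model_fpm(sys, learn_pupil = FALSE),
                  feature_extractor_spec("gradient"),
                  loss_spec("charbonnier"),
                  config = solver_config("sgd_momentum", c(object = 1e-4),
                                         iterations = 50, seed = 1,
                                         momentum = 0))
  expect_true(all(diff(fit$loss_trace) <= 1e-8 * fit$loss_trace[1]))
})

test_that("feature-domain loss beats pixel loss under vignetting", {
  # the headline mechanism: gradient features vs raw pixels (identity) on
  # half-plane vignetted FPM frames
  sys <- tiny_fpm_system(hi = 64, n_side = 5)
  obj <- tiny_fpm_object(64)
  deg <- degradation_spec("half_plane", vignette_strength = 1,
                          poisson_photons = Inf, gaussian_sigma = 0.01,
                          seed = 11)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys, degrade = deg)
  cfg <- solver_config("adam", c(object = 0.02), iterations = 200, seed = 7)
  fit_feat <- fd_solve(sim$observation, fdpr_model_fpm(sys, learn_pupil = FALSE),
                       feature_extractor_spec("gradient"),
                       loss_spec("charbonnier"), config = cfg)
  fit_pix <- fd_solve(sim$observation, fdpr_model_fpm(sys, learn_pupil = FALSE),
                      feature_extractor_spec("identity"),
                      loss_spec("charbonnier"), config = cfg)
  ta <- norm_amplitude(sim$truth$object)
  p_feat <- psnr(norm_amplitude(recovered_object(fit_feat)), ta)
  p_pix <- psnr(norm_amplitude(recovered_object(fit_pix)), ta)
  expect_gt(p_feat, p_pix)
})

test_that("fit methods expose coefficients, fits, residuals and the trace", {
  sys <- tiny_fpm_system(hi = 32, n_side = 3, pitch = 1)
  obj <- tiny_fpm_object(32)
  sim <- simulate_fpm_dataset(obj$amplitude, obj$phase, sys,
                              degrade = degradation_none())
  fit <- fd_solve(sim$observation, fdpr_model_fpm(sys),
                  feature_extractor_spec("gradient"),
                  loss_spec("charbonnier"),
                  config = solver_config(iterations = 10, seed = 2))
  expect_named(coef(fit), c("object", "pupil"))
  fits <- fitted(fit)
  expect_length(fits, sys$n_leds)
  res <- residuals(fit)
  expect_equal(res[[1]], sim$observation$frames[[1]] - fits[[1]])
  expect_length(fit$loss_trace, 10)
  expect_output(print(fit), "fdpr_fit")
  expect_output(summary(fit), "optimizer")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
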