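# Feature extractors Theta and intensity scalings S. All extractors here
# are linear maps with exact adjoints, which the gradient engine needs to
# back-propagate a feature-domain residual to an intensity-domain gradient.

#' Intensity scaling S
#'
#' Monotone pixel-wise scalings applied to non-negative intensity frames
#' before feature extraction. `sqrt` (default, `sqrt(I + eps)`) maps
#' intensity to an amplitude-like quantity and approximately stabilizes the
#' variance of shot noise; `log1p` compresses dynamic range; `identity`
#' leaves the frame untouched.
#'
#' @param frame non-negative numeric matrix.
#' @param spec a [feature_extractor_spec()] (only `scaling` and
#'   `scaling_epsilon` are used).
#' @return scaled matrix, same shape.
#' @export
scale_intensity <- function(frame, spec = feature_extractor_spec()) {
  if (any(frame < 0)) stop("intensity frame must be non-negative", call. = FALSE)
  switch(spec$scaling,
         sqrt = sqrt(frame + spec$scaling_epsilon),
         log1p = log1p(frame),
         identity = frame)
}

# derivative of S w.r.t. the intensity, evaluated pixel-wise
.scale_intensity_deriv <- function(frame, spec) {
  switch(spec$scaling,
         sqrt = 0.5 / sqrt(frame + spec$scaling_epsilon),
         log1p = 1 / (1 + frame),
         identity = array(1, dim = dim(frame)))
}

# ---- feature pyramid -------------------------------------------------------

#' Bundle of feature tensors
#'
#' Ordered list of 2-D real grids (gradient channels or wavelet sub-bands)
#' with labels and per-tensor loss weights.
#'
#' @param tensors list of numeric matrices.
#' @param level_ids character labels, one per tensor.
#' @param weights non-negative per-tensor weights (default 1).
#' @return object of class `feature_pyramid`.
#' @export
feature_pyramid <- function(tensors, level_ids = NULL, weights = NULL) {
  if (!length(tensors)) stop("pyramid must contain at least one tensor", call. = FALSE)
  if (is.null(level_ids)) level_ids <- paste0("tensor", seq_along(tensors))
  if (is.null(weights)) weights <- rep(1, length(tensors))
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  for (t in tensors)
    if (any(!is.finite(t))) stop("feature tensors must be finite", call. = FALSE)
  structure(list(tensors = tensors, level_ids = level_ids, weights = weights),
            class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat(sprintf("<feature_pyramid> %d tensor(s): %s\n", length(x$tensors),
              paste(x$level_ids, collapse = ", ")))
  invisible(x)
}

# ---- gradient features -----------------------------------------------------

#' First-order gradient features
#'
#' Horizontal and vertical difference channels of an image; the edge
#' features used to guide blind aberration recovery. The forward scheme
#' uses forward differences with replicate boundary (last row/column
#' difference is zero), keeping the operator linear with the simple
#' negative-divergence adjoint. A central-difference scheme is selectable
#' via the spec.
#'
#' @param frame numeric matrix.
#' @param spec a [feature_extractor_spec()]; only `gradient_scheme` is used.
#' @return a [feature_pyramid()] with channels `dh` (along columns) and
#'   `dv` (along rows).
#' @export
gradient_features <- function(frame, spec = feature_extractor_spec()) {
  if (any(!is.finite(frame))) stop("frame must be finite", call. = FALSE)
  n <- nrow(frame); m <- ncol(frame)
  if (identical(spec$gradient_scheme, "central")) {
    dh <- (frame[, c(2:m, m)] - frame[, c(1, 1:(m - 1))]) / 2
    dv <- (frame[c(2:n, n), ] - frame[c(1, 1:(n - 1)), ]) / 2
  } else {
    dh <- cbind(frame[, 2:m, drop = FALSE] - frame[, 1:(m - 1), drop = FALSE],
                rep(0, n))
    dv <- rbind(frame[2:n, , drop = FALSE] - frame[1:(n - 1), , drop = FALSE],
                rep(0, m))
  }
  feature_pyramid(list(dh = dh, dv = dv), level_ids = c("dh", "dv"))
}

# adjoint of gradient_features: maps two channels back to image domain
# (negative divergence with boundary terms matching the forward scheme)
.gradient_features_adjoint <- function(gh, gv, spec) {
  n <- nrow(gh); m <- ncol(gh)
  if (identical(spec$gradient_scheme, "central")) {
    out <- matrix(0, n, m)
    # dh[, j] = (f[, j+1] - f[, j-1])/2 with clamped indices
    for (j in seq_len(m)) {
      jr <- min(j + 1L, m); jl <- max(j - 1L, 1L)
      out[, jr] <- out[, jr] + gh[, j] / 2
      out[, jl] <- out[, jl] - gh[, j] / 2
    }
    for (i in seq_len(n)) {
      ir <- min(i + 1L, n); il <- max(i - 1L, 1L)
      out[ir, ] <- out[ir, ] + gv[i, ] / 2
      out[il, ] <- out[il, ] - gv[i, ] / 2
    }
    return(out)
  }
  out <- matrix(0, n, m)
  # dh[, j] = f[, j+1] - f[, j] for j < m
  out[, 2:m] <- out[, 2:m] + gh[, 1:(m - 1)]
  out[, 1:(m - 1)] <- out[, 1:(m - 1)] - gh[, 1:(m - 1)]
  out[2:n, ] <- out[2:n, ] + gv[1:(n - 1), ]
  out[1:(n - 1), ] <- out[1:(n - 1), ] - gv[1:(n - 1), ]
  out
}

# ---- bior2.2 wavelet (CDF 5/3) via lifting ---------------------------------
# Analysis filters (whole-point symmetric extension):
#   lowpass  h = sqrt(2) * (-1/8, 1/4, 3/4, 1/4, -1/8)   centered on even samples
#   highpass g = (1/sqrt(2)) * (-1/2, 1, -1/2)           centered on odd samples
# The lifting factorization (predict then update) makes the inverse exact by
# construction and keeps the adjoint a short composition of scatter-adds.

.SQRT2 <- sqrt(2)

# forward 1-D analysis on each column of a matrix; returns list(a, d)
.lift_fwd_cols <- function(x) {
  n <- nrow(x)
  if (n %% 2L != 0L) stop("signal length must be even", call. = FALSE)
  e <- x[seq(1L, n, by = 2L), , drop = FALSE]   # x[2i]
  o <- x[seq(2L, n, by = 2L), , drop = FALSE]   # x[2i+1]
  m <- n %/% 2L
  e_next <- e[c(2:m, m), , drop = FALSE]        # e[i+1], whole-point mirror at end
  d <- o - 0.5 * (e + e_next)
  d_prev <- d[c(1L, 1:(m - 1)), , drop = FALSE] # d[i-1], mirror at start
  a <- e + 0.25 * (d_prev + d)
  list(a = a * .SQRT2, d = d / .SQRT2)
}

# exact inverse of .lift_fwd_cols
.lift_inv_cols <- function(a, d) {
  a <- a / .SQRT2
  d <- d * .SQRT2
  m <- nrow(a)
  d_prev <- d[c(1L, 1:(m - 1)), , drop = FALSE]
  e <- a - 0.25 * (d_prev + d)
  e_next <- e[c(2:m, m), , drop = FALSE]
  o <- d + 0.5 * (e + e_next)
  x <- matrix(0, 2L * m, ncol(a))
  x[seq(1L, 2L * m, by = 2L), ] <- e
  x[seq(2L, 2L * m, by = 2L), ] <- o
  x
}

# adjoint of .lift_fwd_cols: given gradients (ga, gd) w.r.t. outputs,
# return gradient w.r.t. the input signal columns
.lift_adj_cols <- function(ga, gd) {
  ga <- ga * .SQRT2
  gd <- gd / .SQRT2
  m <- nrow(ga)
  # update step a[i] = e[i] + 0.25 (d[i-1] + d[i]), d[-1] := d[0]
  ge <- ga
  gd2 <- gd + 0.25 * ga
  gd2[1:(m - 1), ] <- gd2[1:(m - 1), , drop = FALSE] +
    0.25 * ga[2:m, , drop = FALSE]
  gd2[1L, ] <- gd2[1L, ] + 0.25 * ga[1L, ]          # d[0] also serves as d[-1]
  # predict step d[i] = o[i] - 0.5 (e[i] + e[i+1]), e[m] := e[m-1]
  go <- gd2
  ge <- ge - 0.5 * gd2
  ge[2:m, ] <- ge[2:m, , drop = FALSE] - 0.5 * gd2[1:(m - 1), , drop = FALSE]
  ge[m, ] <- ge[m, ] - 0.5 * gd2[m, ]               # e[m-1] also serves as e[m]
  x <- matrix(0, 2L * m, ncol(ga))
  x[seq(1L, 2L * m, by = 2L), ] <- ge
  x[seq(2L, 2L * m, by = 2L), ] <- go
  x
}

# one separable 2-D analysis level: rows then columns
.dwt2_level <- function(x) {
  cw <- .lift_fwd_cols(t(x))                 # along rows
  L <- t(cw$a); H <- t(cw$d)
  cl <- .lift_fwd_cols(L)
  ch <- .lift_fwd_cols(H)
  list(ll = cl$a, lh = ch$a, hl = cl$d, hh = ch$d)
  # lh: horizontal detail (row highpass), hl: vertical detail
}

.idwt2_level <- function(ll, lh, hl, hh) {
  L <- .lift_inv_cols(ll, hl)
  H <- .lift_inv_cols(lh, hh)
  t(.lift_inv_cols(t(L), t(H)))
}

.dwt2_level_adj <- function(gll, glh, ghl, ghh) {
  gL <- .lift_adj_cols(gll, ghl)
  gH <- .lift_adj_cols(glh, ghh)
  t(.lift_adj_cols(t(gL), t(gH)))
}

#' Multi-level bior2.2 wavelet features
#'
#' Separable 2-D discrete wavelet transform with the biorthogonal 2.2
#' (CDF 5/3) filter pair, implemented by lifting with whole-point symmetric
#' boundary extension, so the inverse is exact to machine precision and the
#' transform is non-expansive (each level halves both dimensions). Sub-bands
#' are ordered coarse to fine: the approximation band first (included in the
#' pyramid when `spec$include_approx`), then per level the horizontal,
#' vertical and diagonal detail bands.
#'
#' @param frame numeric matrix; dimensions must be divisible by
#'   `2^spec$levels`.
#' @param spec a [feature_extractor_spec()] with `kind = "wavelet"`.
#' @return a [feature_pyramid()]; attribute `"approx"` always carries the
#'   final approximation band so [wavelet_reconstruct()] can invert.
#' @export
wavelet_features <- function(frame, spec = feature_extractor_spec(kind = "wavelet")) {
  lv <- spec$levels
  d <- dim(frame)
  if (lv > floor(log2(min(d))))
    stop("levels exceed log2 of the smallest dimension", call. = FALSE)
  if (any(d %% 2^lv != 0))
    stop("frame dimensions must be divisible by 2^levels", call. = FALSE)
  tensors <- list(); ids <- character()
  cur <- frame
  details <- vector("list", lv)
  for (l in seq_len(lv)) {
    b <- .dwt2_level(cur)
    details[[l]] <- b
    cur <- b$ll
  }
  # coarse-to-fine ordering
  if (isTRUE(spec$include_approx)) {
    tensors <- c(tensors, list(cur)); ids <- c(ids, sprintf("a%d", lv))
  }
  for (l in rev(seq_len(lv))) {
    b <- details[[l]]
    tensors <- c(tensors, list(b$lh, b$hl, b$hh))
    ids <- c(ids, sprintf(c("h%d", "v%d", "d%d"), l))
  }
  pyr <- feature_pyramid(tensors, level_ids = ids)
  attr(pyr, "approx") <- cur
  attr(pyr, "levels") <- lv
  attr(pyr, "dims") <- d
  pyr
}

#' Exact inverse of [wavelet_features()]
#'
#' @param pyr a pyramid produced by [wavelet_features()] (must carry its
#'   `"approx"` attribute when the approximation band was excluded).
#' @return the reconstructed matrix.
#' @export
wavelet_reconstruct <- function(pyr) {
  lv <- attr(pyr, "levels")
  ids <- pyr$level_ids
  offset <- if (sprintf("a%d", lv) %in% ids) 1L else 0L
  cur <- if (offset) pyr$tensors[[1L]] else attr(pyr, "approx")
  k <- offset + 1L
  for (l in rev(seq_len(lv))) {
    cur <- .idwt2_level(cur, pyr$tensors[[k]], pyr$tensors[[k + 1L]],
                        pyr$tensors[[k + 2L]])
    k <- k + 3L
  }
  cur
}

# adjoint of the (linear) wavelet analysis: pyramid gradients -> frame grad.
# Mirrors the tensor ordering of wavelet_features; gradients for excluded
# approximation bands enter as zero.
.wavelet_features_adjoint <- function(gtensors, spec, dims) {
  lv <- spec$levels
  sub <- dims / 2^lv
  k <- 1L
  if (isTRUE(spec$include_approx)) {
    gll <- gtensors[[1L]]
    k <- 2L
  } else gll <- matrix(0, sub[1L], sub[2L])
  for (l in rev(seq_len(lv))) {
    gll <- .dwt2_level_adj(gll, gtensors[[k]], gtensors[[k + 1L]],
                           gtensors[[k + 2L]])
    k <- k + 3L
  }
  gll
}

# ---- dispatcher ------------------------------------------------------------

#' Extract scaled features from an intensity frame
#'
#' The composition Theta(S(frame)) that both sides of the feature-domain
#' loss pass through: intensity scaling first, then the extractor named by
#' `spec$kind`.
#'
#' @param frame non-negative numeric matrix.
#' @param spec a [feature_extractor_spec()].
#' @return a [feature_pyramid()].
#' @export
extract_features <- function(frame, spec = feature_extractor_spec()) {
  s <- scale_intensity(frame, spec)
  switch(spec$kind,
         identity = feature_pyramid(list(identity = s), level_ids = "identity"),
         gradient = gradient_features(s, spec),
         wavelet = wavelet_features(s, spec),
         stop("unknown feature kind: ", spec$kind, call. = FALSE))
}

# adjoint of the extractor (Theta only, not S) for the gradient engine
.features_adjoint <- function(gtensors, spec, dims) {
  switch(spec$kind,
         identity = gtensors[[1L]],
         gradient = .gradient_features_adjoint(gtensors[[1L]], gtensors[[2L]], spec),
         wavelet = .wavelet_features_adjoint(gtensors, spec, dims))
}
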