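# The library of refinement operators C pluggable into the solver's
# constraint block.

#' Amplitude thresholding constraint
#'
#' Clips the amplitude of a complex field to `[lo, hi]` while preserving the
#' phase exactly. Idempotent.
#'
#' @param x complex matrix or [complex_field()].
#' @param lo,hi amplitude bounds, `0 <= lo <= hi` (hi may be `Inf`).
#' @return same type as `x`.
#' @export
amplitude_threshold <- function(x, lo = 0, hi = Inf) {
  if (lo > hi) stop("lo must be <= hi", call. = FALSE)
  v <- if (inherits(x, "complex_field")) x$values else x
  a <- Mod(v)
  clipped <- pmin(pmax(a, lo), hi)
  scale <- ifelse(a > 0, clipped / a, 0)
  out <- v * scale
  # zero-amplitude pixels with a positive lower bound become real `lo`
  if (lo > 0) out[a == 0] <- lo + 0i
  if (inherits(x, "complex_field")) { x$values <- out; x } else out
}

#' Total-variation (ROF) denoising
#'
#' Approximately solves `argmin_u 0.5 ||u - frame||^2 + weight * TV(u)`
#' (isotropic TV) by Chambolle's dual projection iterations.
#'
#' @param frame real matrix.
#' @param weight TV weight (>= 0; 0 returns the input).
#' @param iterations dual iterations (default 20).
#' @param tau dual step size (default 0.248 < 1/4 for convergence).
#' @return denoised matrix.
#' @export
tv_denoise <- function(frame, weight, iterations = 20L, tau = 0.248) {
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (weight == 0 || iterations == 0L) return(frame)
  n <- nrow(frame); m <- ncol(frame)
  py <- matrix(0, n, m); px <- matrix(0, n, m)
  divergence <- function(py, px) {
    d <- matrix(0, n, m)
    d[1:(n - 1), ] <- d[1:(n - 1), ] + py[1:(n - 1), ]
    d[2:n, ] <- d[2:n, ] - py[1:(n - 1), ]
    d[, 1:(m - 1)] <- d[, 1:(m - 1)] + px[, 1:(m - 1)]
    d[, 2:m] <- d[, 2:m] - px[, 1:(m - 1)]
    d
  }
  for (it in seq_len(iterations)) {
    # Chambolle fixed point: p <- (p + tau grad(div p - f/w)) /
    #                             (1 + tau |grad(div p - f/w)|)
    v <- divergence(py, px) - frame / weight
    gy <- matrix(0, n, m); gx <- matrix(0, n, m)
    gy[1:(n - 1), ] <- v[2:n, ] - v[1:(n - 1), ]
    gx[, 1:(m - 1)] <- v[, 2:m] - v[, 1:(m - 1)]
    den <- 1 + tau * sqrt(gy^2 + gx^2)
    py <- (py + tau * gy) / den
    px <- (px + tau * gx) / den
  }
  frame - weight * divergence(py, px)
}

# moving-average box filter with edge-truncated windows (each output pixel
# averages the part of the (2r+1)^2 window inside the frame)
.box_filter <- function(x, r) {
  n <- nrow(x); m <- ncol(x)
  cs <- apply(x, 2L, cumsum)
  up <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r - 1L
  colsum <- cs[up, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1L), m), cs[lo[lo >= 1L], , drop = FALSE])
  cs2 <- t(apply(colsum, 1L, cumsum))
  upc <- pmin(seq_len(m) + r, m)
  loc <- seq_len(m) - r - 1L
  out <- cs2[, upc, drop = FALSE] -
    cbind(matrix(0, n, sum(loc < 1L)), cs2[, loc[loc >= 1L], drop = FALSE])
  cnt_r <- pmin(seq_len(n) + r, n) - pmax(seq_len(n) - r, 1L) + 1L
  cnt_c <- pmin(seq_len(m) + r, m) - pmax(seq_len(m) - r, 1L) + 1L
  out / outer(cnt_r, cnt_c)
}

#' Guided-filter parameters
#' @param radius_px window half-size (>= 1).
#' @param eps regularization, in squared-intensity units (> 0).
#' @param guide `"self"` or an external guide matrix.
#' @return object of class `guided_filter_params`.
#' @export
guided_filter_params <- function(radius_px = 8L, eps = 0.04, guide = "self") {
  if (radius_px < 1L) stop("radius_px must be >= 1", call. = FALSE)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  structure(list(radius_px = as.integer(radius_px), eps = eps, guide = guide),
            class = "guided_filter_params")
}

#' Edge-preserving guided filter
#'
#' The classic local linear model: in each `(2r+1)^2` box window,
#' `a = cov(g, f) / (var(g) + eps)`, `b = mean(f) - a * mean(g)`; the output
#' averages the per-window coefficients, `mean(a) * g + mean(b)`. With
#' `guide = "self"` it is an edge-preserving denoiser -- the operator used
#' here to erase the twin image of inline holographic reconstructions.
#'
#' @param frame real matrix to filter.
#' @param params a [guided_filter_params()].
#' @return filtered matrix.
#' @export
guided_filter <- function(frame, params = guided_filter_params()) {
  r <- params$radius_px
  if (r >= min(dim(frame)) / 2)
    stop("radius must be < min(dim)/2", call. = FALSE)
  g <- if (identical(params$guide, "self")) frame else params$guide
  mg <- .box_filter(g, r)
  mf <- .box_filter(frame, r)
  mgf <- .box_filter(g * frame, r)
  mgg <- .box_filter(g * g, r)
  a <- (mgf - mg * mf) / (mgg - mg^2 + params$eps)
  b <- mf - a * mg
  .box_filter(a, r) * g + .box_filter(b, r)
}

#' Hessian (second-order curvature) penalty and its gradient
#'
#' Penalty `weight * sum(f_xx^2 + 2 f_xy^2 + f_yy^2)` with second-difference
#' stencils on interior pixels, the discrete squared Frobenius norm of the
#' Hessian. Returns the penalty value and its gradient (the discrete
#' biharmonic form, obtained by applying each stencil's adjoint). Affine
#' frames have zero penalty and gradient. Complex input is penalized on real
#' and imaginary parts independently.
#'
#' @param frame real or complex matrix.
#' @param weight penalty weight (>= 0).
#' @return list with `penalty` (scalar) and `gradient` (matrix like `frame`).
#' @export
hessian_penalty_gradient <- function(frame, weight) {
  if (weight < 0) stop("weight must be >= 0", call. = FALSE)
  if (is.complex(frame)) {
    re <- hessian_penalty_gradient(Re(frame), weight)
    im <- hessian_penalty_gradient(Im(frame), weight)
    return(list(penalty = re$penalty + im$penalty,
                gradient = re$gradient + 1i * im$gradient))
  }
  n <- nrow(frame); m <- ncol(frame)
  if (weight == 0 || n < 3L || m < 3L)
    return(list(penalty = 0, gradient = matrix(0, n, m)))
  fyy <- frame[1:(n - 2), ] - 2 * frame[2:(n - 1), ] + frame[3:n, ]
  fxx <- frame[, 1:(m - 2)] - 2 * frame[, 2:(m - 1)] + frame[, 3:m]
  fxy <- frame[2:n, 2:m] - frame[2:n, 1:(m - 1)] -
         frame[1:(n - 1), 2:m] + frame[1:(n - 1), 1:(m - 1)]
  penalty <- weight * (sum(fxx^2) + 2 * sum(fxy^2) + sum(fyy^2))
  g <- matrix(0, n, m)
  # adjoint scatter of d/df [sum fyy^2] = 2 fyy through stencil (1,-2,1)
  g[1:(n - 2), ] <- g[1:(n - 2), ] + 2 * fyy
  g[2:(n - 1), ] <- g[2:(n - 1), ] - 4 * fyy
  g[3:n, ] <- g[3:n, ] + 2 * fyy
  g[, 1:(m - 2)] <- g[, 1:(m - 2)] + 2 * fxx
  g[, 2:(m - 1)] <- g[, 2:(m - 1)] - 4 * fxx
  g[, 3:m] <- g[, 3:m] + 2 * fxx
  g[2:n, 2:m] <- g[2:n, 2:m] + 4 * fxy
  g[2:n, 1:(m - 1)] <- g[2:n, 1:(m - 1)] - 4 * fxy
  g[1:(n - 1), 2:m] <- g[1:(n - 1), 2:m] - 4 * fxy
  g[1:(n - 1), 1:(m - 1)] <- g[1:(n - 1), 1:(m - 1)] + 4 * fxy
  list(penalty = penalty, gradient = weight * g)
}

# resolve a constraint_spec into a function complex-matrix -> complex-matrix
.resolve_constraint <- function(spec) {
  f <- spec$constraint
  if (is.character(f)) {
    f <- switch(f,
      amplitude_threshold = function(x)
        amplitude_threshold(x, lo = spec$params$lo %||% 0,
                            hi = spec$params$hi %||% Inf),
      tv = function(x) tv_denoise(x, weight = spec$params$weight %||% 0.1,
                                  iterations = spec$params$iterations %||% 20L),
      guided_filter = function(x)
        guided_filter(x, do.call(guided_filter_params,
                                 spec$params[names(spec$params) %in%
                                             c("radius_px", "eps", "guide")])),
      support = function(x) x * (spec$params$mask %||%
                                   stop("support constraint needs params$mask")),
      stop("unknown built-in constraint: ", f, call. = FALSE))
  }
  base <- f
  switch(spec$component,
         complex = base,
         amplitude = function(x) {
           a <- base(Mod(x))
           ph <- ifelse(Mod(x) > 0, x / Mod(x), 1 + 0i)
           a * ph
         },
         phase = function(x) Mod(x) * exp(1i * base(Arg(x))))
}
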