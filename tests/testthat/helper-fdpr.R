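# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; no binary fixtures.

seeded_matrix <- function(n, m = n, seed = 1, complex = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  x <- matrix(stats::rnorm(n * m), n, m)
  if (complex) x <- x + 1i * matrix(stats::rnorm(n * m), n, m)
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  x
}

# small FPM test system: n_side x n_side LED grid over a hi x hi object
tiny_fpm_system <- function(hi = 64, n_side = 5, na = 0.1, pitch = 0.5) {
  kv <- led_grid_kvectors(n_side, 1800, 50000, 0.532)
  fpm_system(c(hi, hi), na, 0.532, pitch, kv, 2L)
}

# smooth complex test object on the high-res grid
tiny_fpm_object <- function(hi = 64, seed_amp = 2, seed_ph = 3) {
  amp <- 0.5 + 0.5 * Mod(phantom_cell_blobs(c(hi, hi), 15, c(0, 1), c(0, 0),
                                            seed = seed_amp))
  ph <- Arg(phantom_cell_blobs(c(hi, hi), 12, c(1, 1), c(0, 1),
                               seed = seed_ph))
  list(amplitude = amp, phase = ph)
}

# amplitude normalized to unit mean (removes the scale/global-phase
# ambiguity before PSNR comparisons)
norm_amplitude <- function(x) {
  a <- Mod(x)
  a / mean(a)
}

# --- independent oracles ----------------------------------------------------

# brute-force direct-summation DFT oracle for one FPM frame
fpm_dft_oracle <- function(X, pupil, sys, n) {
  lo <- sys$low_pixels; hi <- sys$object_pixels
  sh <- sys$shifts_px[n, ]
  ctr_hi <- hi %/% 2L + 1L; ctr_lo <- lo %/% 2L + 1L
  s <- sqrt(prod(lo) / prod(hi))
  out <- matrix(0 + 0i, lo[1L], lo[2L])
  for (r in 1:lo[1L]) for (c in 1:lo[2L]) {
    acc <- 0 + 0i
    for (ky in 1:lo[1L]) for (kx in 1:lo[2L]) {
      Xv <- X[ctr_hi[1L] + sh[2L] + (ky - ctr_lo[1L]),
              ctr_hi[2L] + sh[1L] + (kx - ctr_lo[2L])]
      acc <- acc + pupil$values[ky, kx] * Xv *
        exp(2i * pi * ((ky - ctr_lo[1L]) * (r - ctr_lo[1L]) / lo[1L] +
                       (kx - ctr_lo[2L]) * (c - ctr_lo[2L]) / lo[2L]))
    }
    out[r, c] <- acc / sqrt(prod(lo)) * s
  }
  Mod(out)^2
}

# direct filter-bank convolution DWT oracle (whole-point symmetric
# extension), independent of the package's lifting implementation
dwt1_conv_oracle <- function(x) {
  n <- length(x); m <- n / 2
  h <- sqrt(2) * c(-1 / 8, 1 / 4, 3 / 4, 1 / 4, -1 / 8)  # offsets -2..2
  g <- (1 / sqrt(2)) * c(-1 / 2, 1, -1 / 2)              # offsets -1..1
  ext <- function(i) { while (i < 0 || i >= n) { if (i < 0) i <- -i
                                                 if (i >= n) i <- 2 * (n - 1) - i }
                       x[i + 1] }
  a <- numeric(m); d <- numeric(m)
  for (i in 0:(m - 1)) {
    a[i + 1] <- sum(h * vapply((2 * i - 2):(2 * i + 2), ext, 0))
    d[i + 1] <- sum(g * vapply((2 * i):(2 * i + 2), ext, 0))
  }
  list(a = a, d = d)
}

dwt2_conv_oracle <- function(x) {
  rowpass <- apply(x, 1, dwt1_conv_oracle)   # over rows
  L <- t(vapply(rowpass, `[[`, numeric(ncol(x) / 2), "a"))
  H <- t(vapply(rowpass, `[[`, numeric(ncol(x) / 2), "d"))
  colL <- apply(L, 2, dwt1_conv_oracle)
  colH <- apply(H, 2, dwt1_conv_oracle)
  get_band <- function(cols, band, nr) vapply(cols, `[[`, numeric(nr), band)
  nr <- nrow(x) / 2
  list(ll = get_band(colL, "a", nr), hl = get_band(colL, "d", nr),
       lh = get_band(colH, "a", nr), hh = get_band(colH, "d", nr))
}

# literal double-loop guided-filter oracle (edge-truncated box windows)
guided_filter_oracle <- function(f, r, eps) {
  n <- nrow(f); m <- ncol(f)
  a <- matrix(0, n, m); b <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    ri <- max(1, i - r):min(n, i + r); rj <- max(1, j - r):min(m, j + r)
    w <- f[ri, rj]
    mg <- mean(w); vg <- mean(w^2) - mg^2
    a[i, j] <- vg / (vg + eps)
    b[i, j] <- mg - a[i, j] * mg
  }
  am <- matrix(0, n, m); bm <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    ri <- max(1, i - r):min(n, i + r); rj <- max(1, j - r):min(m, j + r)
    am[i, j] <- mean(a[ri, rj]); bm[i, j] <- mean(b[ri, rj])
  }
  am * f + bm
}

# independent ROF oracle: projected-gradient ascent on the dual problem
# with explicit unit-ball projection
tv_dual_projgrad_oracle <- function(f, w, iters = 20000, tau = 0.1) {
  n <- nrow(f); m <- ncol(f)
  py <- matrix(0, n, m); px <- matrix(0, n, m)
  divp <- function(py, px) {
    d <- matrix(0, n, m)
    d[1:(n - 1), ] <- d[1:(n - 1), ] + py[1:(n - 1), ]
    d[2:n, ] <- d[2:n, ] - py[1:(n - 1), ]
    d[, 1:(m - 1)] <- d[, 1:(m - 1)] + px[, 1:(m - 1)]
    d[, 2:m] <- d[, 2:m] - px[, 1:(m - 1)]
    d
  }
  for (it in 1:iters) {
    v <- divp(py, px) - f / w
    gy <- matrix(0, n, m); gx <- matrix(0, n, m)
    gy[1:(n - 1), ] <- v[2:n, ] - v[1:(n - 1), ]
    gx[, 1:(m - 1)] <- v[, 2:m] - v[, 1:(m - 1)]
    py <- py + tau * gy; px <- px + tau * gx
    mag <- pmax(1, sqrt(py^2 + px^2))
    py <- py / mag; px <- px / mag
  }
  f - w * divp(py, px)
}
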