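# Internal helpers shared across modules.

# Validate a [0,1] H x W x 3 array.
check_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort(sprintf("`%s` must be an H x W x 3 array.", arg))
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    abort(sprintf("`%s` must have all channel values in [0, 1].", arg))
  invisible(img)
}

check_gray <- function(img, arg = "img") {
  if (!is.matrix(img))
    abort(sprintf("`%s` must be an H x W numeric matrix.", arg))
  if (anyNA(img) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    abort(sprintf("`%s` must have values in [0, 1].", arg))
  invisible(img)
}

# Coerce a mask to a 0/1 integer matrix.
as_mask <- function(mask, arg = "mask") {
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    abort(sprintf("`%s` must be a binary (0/1 or logical) matrix.", arg))
  storage.mode(mask) <- "integer"
  mask
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shift a matrix by (dy, dx) with replicate (nearest-edge) padding.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(seq_len(h) - dy, 1L, h)
  ci <- clamp(seq_len(w) - dx, 1L, w)
  m[ri, ci, drop = FALSE]
}

# Central-difference spatial gradient, replicate boundary.
grad_xy <- function(m) {
  gx <- (shift_mat(m, 0L, -1L) - shift_mat(m, 0L, 1L)) / 2
  gy <- (shift_mat(m, -1L, 0L) - shift_mat(m, 1L, 0L)) / 2
  list(gx = gx, gy = gy)
}

# 5-point Laplacian, replicate boundary (Neumann).
laplacian <- function(m) {
  shift_mat(m, 1L, 0L) + shift_mat(m, -1L, 0L) +
    shift_mat(m, 0L, 1L) + shift_mat(m, 0L, -1L) - 4 * m
}

# 1-D Gaussian kernel with support +-ceil(3*sigma); sigma = 0 -> identity.
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Reflect-padded index sequence for length n with margin r.
reflect_idx <- function(n, r) {
  idx <- (1 - r):(n + r)
  idx[idx < 1] <- 2 - idx[idx < 1]
  idx[idx > n] <- 2 * n - idx[idx > n]
  idx
}

# Separable convolution of a matrix with a 1-D kernel along both axes,
# reflect padding.
sep_conv2 <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # rows (vertical pass)
  mp <- m[reflect_idx(h, r), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + h - 1L), , drop = FALSE]
  # cols (horizontal pass)
  mp <- out[, reflect_idx(w, r), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * mp[, i:(i + w - 1L), drop = FALSE]
  out
}

gaussian_blur <- function(m, sigma) sep_conv2(m, gauss_kernel1d(sigma))

# Circular 1-D Gaussian smoothing (for closed-curve coordinates).
smooth_circular <- function(x, sigma) {
  k <- gauss_kernel1d(sigma)
  if (length(k) == 1L) return(x)
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (n < 2L) return(x)
  idx <- ((-r):(n - 1L + r)) %% n + 1L
  xp <- x[idx]
  out <- numeric(n)
  for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + n - 1L)]
  out
}

# Signed shoelace area in image coordinates (y down).  Negative for curves
# traversed counter-clockwise as seen on screen.
shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Run code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
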