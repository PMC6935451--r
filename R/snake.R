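# Snake evolution and contour rasterization.

# Bilinear interpolation of matrix m at 0-based (x, y), clamped to bounds.
bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  dx <- x - x0; dy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  m[cbind(i, j)] * (1 - dx) * (1 - dy) +
    m[cbind(i, j + 1)] * dx * (1 - dy) +
    m[cbind(i + 1, j)] * (1 - dx) * dy +
    m[cbind(i + 1, j + 1)] * dx * dy
}

# Resample a closed polygon to n points at uniform arc length.
resample_closed <- function(pts, n = nrow(pts)) {
  p <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 1e-12) return(pts[rep(1L, n), , drop = FALSE])
  si <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, p[, 1], xout = si)$y
  y <- stats::approx(s, p[, 2], xout = si)$y
  cbind(x = x, y = y)
}

# Circulant pentadiagonal internal-force matrix for a closed snake.
snake_internal_matrix <- function(n, alpha, beta) {
  r <- numeric(n)
  r[1] <- 2 * alpha + 6 * beta
  r[2] <- -(alpha + 4 * beta); r[n] <- r[2]
  r[3] <- beta; r[n - 1] <- r[3]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, ] <- r[((seq_len(n) - i) %% n) + 1L]
  A
}

#' Evolve a snake contour under a GVF field
#'
#' Standard semi-implicit active-contour iteration for a closed snake:
#' `v_{t+1} = (I + gamma A)^{-1} (v_t + gamma kappa F(v_t))`,
#' where `A` is the circulant pentadiagonal internal-force matrix built
#' from the elasticity `alpha` and rigidity `beta`, and `F` is the GVF
#' field sampled at the vertices by bilinear interpolation (normalized to
#' unit vectors by default, so `kappa` sets the external step in pixels
#' regardless of image contrast).  Vertices are resampled to uniform
#' spacing every `params$resample_every` iterations and the evolution
#' stops after `params$iterations` steps or as soon as the mean vertex
#' displacement drops below `params$converge_tol` pixels.
#'
#' @param init A `snake_contour` (or n x 2 matrix, n >= 16) of initial
#'   vertices, closed.
#' @param field A [gvf_field()] covering the image.
#' @param params A [gvf_params()].
#' @param shape Image shape `c(H, W)`; defaults to the field's shape.
#' @param normalize_field Normalize the external force to unit vectors
#'   (recommended, the usual GVF-snake practice).
#' @return A `snake_contour` with attributes `iterations` (steps run) and
#'   `converged`.
#' @export
evolve_snake <- function(init, field, params = gvf_params(), shape = NULL,
                         normalize_field = TRUE) {
  pts <- unclass(init)
  if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) < 16L)
    abort("`init` must be a closed contour with at least 16 vertices.")
  stopifnot(inherits(field, "gvf_field"))
  if (is.null(shape)) shape <- dim(field$u)
  u <- field$u; v <- field$v
  if (normalize_field) {
    mag <- sqrt(u^2 + v^2)
    mag[mag < 1e-12] <- 1
    u <- u / mag; v <- v / mag
  }
  n <- nrow(pts)
  A <- snake_internal_matrix(n, params$alpha, params$beta)
  lhs <- diag(n) + params$gamma * A
  lhs_inv <- solve(lhs)

  converged <- FALSE
  it <- 0L
  snapshot <- pts
  for (it in seq_len(params$iterations)) {
    fx <- bilinear(u, pts[, 1], pts[, 2])
    fy <- bilinear(v, pts[, 1], pts[, 2])
    newx <- lhs_inv %*% (pts[, 1] + params$gamma * params$kappa * fx)
    newy <- lhs_inv %*% (pts[, 2] + params$gamma * params$kappa * fy)
    newx <- clamp(newx, 0, shape[2] - 1)
    newy <- clamp(newy, 0, shape[1] - 1)
    disp <- mean(sqrt((newx - pts[, 1])^2 + (newy - pts[, 2])^2))
    pts <- cbind(x = as.numeric(newx), y = as.numeric(newy))
    if (abs(shoelace_area(pts)) < 5)
      abort("Snake collapsed to less than 5 px^2; bad initialization.")
    if (params$converge_tol > 0 && disp < params$converge_tol) {
      converged <- TRUE
      break
    }
    if (params$resample_every > 0L && it %% params$resample_every == 0L) {
      # At equilibrium, vertices still oscillate across the edge ridge
      # (amplitude set by kappa) and slide tangentially along the curve,
      # so per-vertex displacement never reaches zero.  Measure instead
      # how far the *curve* moved over the window: mean distance of the
      # current vertices to the previous snapshot polyline.
      drift <- mean(dist_to_polyline(pts, snapshot)) / params$resample_every
      if (params$converge_tol > 0 && drift < params$converge_tol) {
        converged <- TRUE
        break
      }
      pts <- resample_closed(pts, n)
      snapshot <- pts
    }
  }
  structure(pts, class = c("snake_contour", "matrix", "array"),
            iterations = it, converged = converged)
}

#' Rasterize a closed contour into a binary mask
#'
#' Even-odd (crossing-number) polygon fill over pixel centers at integer
#' coordinates; pixels whose center lies exactly on a polygon edge are
#' included.  Self-intersecting polygons are filled even-odd with a
#' warning.
#'
#' @param snake A `snake_contour` or n x 2 matrix of (x, y) vertices
#'   (0-based pixel coordinates), taken as a closed polygon.
#' @param shape Image shape `c(H, W)`.
#' @return Integer 0/1 matrix of shape `c(H, W)`.
#' @export
contour_to_mask <- function(snake, shape) {
  pts <- unclass(snake)
  if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) < 3L)
    abort("`snake` must be a closed polygon with >= 3 vertices.")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (self_intersects(pts))
    warn("Self-intersecting contour; applying even-odd fill.")
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  crossings <- matrix(0L, h, w)
  on_edge <- matrix(FALSE, h, w)
  cols0 <- 0:(w - 1)
  eps <- 1e-9
  for (e in seq_len(n)) {
    ya <- y1[e]; yb <- y2[e]; xa <- x1[e]; xb <- x2[e]
    # horizontal-ray crossing count (half-open in y to handle vertices)
    ylo <- min(ya, yb); yhi <- max(ya, yb)
    rlo <- max(0, ceiling(ylo - eps)); rhi <- min(h - 1, floor(yhi))
    if (rlo > rhi) rows <- integer() else {
      rows <- seq.int(rlo, rhi)
      rows <- rows[rows >= ylo - eps & rows < yhi - eps]
    }
    for (r in rows) {
      xi <- xa + (r - ya) * (xb - xa) / (yb - ya)
      hit <- cols0 < xi - eps
      crossings[r + 1L, hit] <- crossings[r + 1L, hit] + 1L
    }
    # boundary pixels: centers within eps of the segment
    rb1 <- max(0, floor(min(ya, yb) - eps)); rb2 <- min(h - 1, ceiling(max(ya, yb) + eps))
    cb1 <- max(0, floor(min(xa, xb) - eps)); cb2 <- min(w - 1, ceiling(max(xa, xb) + eps))
    rb <- if (rb1 > rb2) integer() else seq.int(rb1, rb2)
    cb <- if (cb1 > cb2) integer() else seq.int(cb1, cb2)
    if (length(rb) && length(cb)) {
      px <- rep(cb, times = length(rb)); py <- rep(rb, each = length(cb))
      vx <- xb - xa; vy <- yb - ya
      len2 <- vx^2 + vy^2
      t <- if (len2 < eps) rep(0, length(px)) else
        clamp(((px - xa) * vx + (py - ya) * vy) / len2, 0, 1)
      d2 <- (px - (xa + t * vx))^2 + (py - (ya + t * vy))^2
      on <- d2 <= eps
      if (any(on)) on_edge[cbind(py[on] + 1L, px[on] + 1L)] <- TRUE
    }
  }
  ((crossings %% 2L == 1L) | on_edge) + 0L
}

# Distance from each point (rows of pts) to the closed polyline poly.
dist_to_polyline <- function(pts, poly) {
  m <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  vx <- bx - ax; vy <- by - ay
  len2 <- pmax(vx^2 + vy^2, 1e-12)
  best <- rep(Inf, nrow(pts))
  for (e in seq_len(m)) {
    t <- clamp(((pts[, 1] - ax[e]) * vx[e] + (pts[, 2] - ay[e]) * vy[e]) / len2[e], 0, 1)
    d2 <- (pts[, 1] - (ax[e] + t * vx[e]))^2 + (pts[, 2] - (ay[e] + t * vy[e]))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# O(n^2) segment-pair crossing test (shared endpoints excluded).
self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])
    d2 <- cross(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js])
    d3 <- cross(x1[js], y1[js], x2[js], y2[js], rep(x1[i], length(js)), rep(y1[i], length(js)))
    d4 <- cross(x1[js], y1[js], x2[js], y2[js], rep(x2[i], length(js)), rep(y2[i], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}
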