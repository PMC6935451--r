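#' Curvature profile of a closed boundary curve
#'
#' Computes the signed curvature function along a boundary curve,
#' `k = (x'' y' - x' y'') / (x'^2 + y'^2)^(3/2)`,
#' i.e. the rate of change of the tangent angle with respect to arc
#' length.  Coordinates are first smoothed with a circular 1-D Gaussian
#' (`smooth_sigma` in points) because raw pixel-chain derivatives are
#' noise-dominated; derivatives are circular central finite differences.
#'
#' Sign convention: with image coordinates (x right, y down) a convex
#' curve traversed counter-clockwise *as seen on screen* has positive
#' curvature (a circle of radius r gives `k = +1/r`).  Reversing the
#' traversal flips the sign pointwise.  Concave indentations of a
#' counter-clockwise curve - such as the breast/torso junction corners on
#' the left body margin - therefore show up as negative curvature spikes.
#'
#' @param curve A `boundary_curve` (see [extract_margins()]) or an n x 2
#'   matrix of ordered closed-curve points.
#' @param smooth_sigma Gaussian coordinate smoothing, in points.
#' @return Object of class `curvature_profile`: list with `k` (1/px), `s`
#'   (cumulative arc length, px), `theta` (tangent angle, radians),
#'   `tangent` and `normal` (n x 2 unit vectors), and the smoothed
#'   `points`.
#' @export
curve_curvature <- function(curve, smooth_sigma = 3) {
  pts <- if (inherits(curve, "boundary_curve")) curve$points else curve
  if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) < 5L)
    abort("`curve` must have at least 5 points.")
  x <- smooth_circular(pts[, 1], smooth_sigma)
  y <- smooth_circular(pts[, 2], smooth_sigma)
  n <- length(x)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  xd <- (x[ip] - x[im]) / 2
  yd <- (y[ip] - y[im]) / 2
  xdd <- x[ip] - 2 * x + x[im]
  ydd <- y[ip] - 2 * y + y[im]
  denom <- (xd^2 + yd^2)^1.5
  k <- ifelse(denom > 1e-12, (xdd * yd - xd * ydd) / denom, 0)
  seg <- sqrt((x - x[im])^2 + (y - y[im])^2)
  s <- cumsum(c(0, seg[-1]))
  theta <- atan2(yd, xd)
  sp <- sqrt(xd^2 + yd^2)
  sp[sp < 1e-12] <- 1
  tangent <- cbind(xd, yd) / sp
  normal <- cbind(-tangent[, 2], tangent[, 1])
  structure(list(k = k, s = s, theta = theta,
                 tangent = tangent, normal = normal,
                 points = cbind(x = x, y = y)),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> %d points, k in [%.4f, %.4f] /px\n",
              length(x$k), min(x$k), max(x$k)))
  invisible(x)
}

#' Tidy a curvature profile
#'
#' @param x A `curvature_profile`.
#' @param ... Unused.
#' @return Tibble with columns `index`, `x`, `y`, `s`, `k`, `theta`.
#' @export
tidy.curvature_profile <- function(x, ...) {
  out <- tibble(index = seq_along(x$k))
  out$x <- x$points[, "x"]; out$y <- x$points[, "y"]
  out$s <- x$s; out$k <- x$k; out$theta <- x$theta
  out
}

# Indices of circular local maxima of v exceeding threshold both in
# height and in topographic prominence; peaks closer than min_dist are
# merged (keep the larger).  The prominence requirement rules out a
# constant profile (e.g. a circle's curvature, however large), while the
# height requirement rules out noise bumps on flat stretches that sit
# next to deep valleys.
local_maxima_circ <- function(v, threshold, min_dist = 5L) {
  n <- length(v)
  if (n < 3L) return(integer())
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  cand <- which(v > threshold & v >= v[ip] & v >= v[im] &
                  (v > v[ip] | v > v[im]))
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    walk <- function(step) {
      lo <- v[i]; j <- i
      for (s in seq_len(n - 1L)) {
        j <- ((j - 1L + step) %% n) + 1L
        if (v[j] > v[i]) break
        lo <- min(lo, v[j])
      }
      lo
    }
    v[i] - max(walk(1L), walk(-1L))
  }, numeric(1))
  cand <- cand[prom > threshold]
  if (length(cand) <= 1L) return(cand)
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in ord) {
    d <- abs(kept - i)
    d <- pmin(d, n - d)  # circular distance
    if (all(d >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Find the curvature peaks that delimit a breast
#'
#' On the right margin the delimiting salient points are positive
#' curvature maxima; on the left margin they are negative minima (see the
#' orientation convention in [extract_margins()]).  Peaks are returned in
#' arc-length order.  An empty result signals the caller to fall back to
#' the two points of extreme curvature of the correct sign.
#'
#' @param profile A `curvature_profile`.
#' @param side `"left"` or `"right"`.
#' @param min_prominence Minimum |k| (1/px) a peak must exceed.
#' @param min_dist Minimum index separation between reported peaks.
#' @return Integer vector of point indices (possibly empty).
#' @export
find_curvature_peaks <- function(profile, side = c("right", "left"),
                                 min_prominence = 0.005, min_dist = 10L) {
  side <- match.arg(side)
  stopifnot(inherits(profile, "curvature_profile"))
  if (length(profile$k) == 0L) abort("Empty curvature profile.")
  v <- if (side == "right") profile$k else -profile$k
  local_maxima_circ(v, min_prominence, min_dist)
}

# ---- direct least-squares ellipse fit (constrained conic) ----

# Fits a x^2 + b xy + c y^2 + d x + e y + f = 0 with 4ac - b^2 > 0,
# using the numerically stable partitioned formulation of the direct
# least-squares ellipse fit. Returns the conic coefficients or NULL if no
# elliptical solution exists.
fit_conic_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T)) return(NULL)
  M <- S1 + S2 %*% T
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M2), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) return(NULL)
  a1 <- V[, ok[1]]
  coefs <- c(a1, T %*% a1)  # a b c d e f in shifted frame
  # shift back: substitute x -> x - mx, y -> y - my
  a <- coefs[1]; b <- coefs[2]; cc <- coefs[3]
  d <- coefs[4]; e <- coefs[5]; f <- coefs[6]
  d2 <- d - 2 * a * mx - b * my
  e2 <- e - 2 * cc * my - b * mx
  f2 <- f + a * mx^2 + b * mx * my + cc * my^2 - d * mx - e * my
  c(a, b, cc, d2, e2, f2)
}

# Geometric parameters (center, semi-axes, rotation) from conic coefficients.
conic_to_ellipse <- function(co) {
  a <- co[1]; b <- co[2]; cc <- co[3]; d <- co[4]; e <- co[5]; f <- co[6]
  den <- b^2 - 4 * a * cc
  if (den >= -1e-15) return(NULL)
  x0 <- (2 * cc * d - b * e) / den
  y0 <- (2 * a * e - b * d) / den
  F0 <- a * x0^2 + b * x0 * y0 + cc * y0^2 + d * x0 + e * y0 + f
  M <- matrix(c(a, b / 2, b / 2, cc), 2)
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values
  ax2 <- -F0 / lam
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(NULL)
  semi <- sqrt(ax2)
  # order: semi-axis a along the eigenvector of lam[which] ...
  # eigen returns decreasing values; -F0/lam increasing -> semi increasing
  rot <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  list(center = c(x0, y0), axes = c(semi[1], semi[2]),
       vectors = ev$vectors, rotation = rot)
}

new_ellipse_init <- function(center, axes, rotation, side) {
  structure(list(center = center, axes = axes, rotation = rotation,
                 side = side), class = "ellipse_init")
}

#' @export
print.ellipse_init <- function(x, ...) {
  cat(sprintf(
    "<ellipse_init> side: %s, center (%.1f, %.1f), semi-axes (%.1f, %.1f), rot %.2f rad\n",
    x$side, x$center[1], x$center[2], x$axes[1], x$axes[2], x$rotation))
  invisible(x)
}

# Sum of squared algebraic residuals of a conic on points, normalized.
conic_residual <- function(co, x, y) {
  v <- co[1] * x^2 + co[2] * x * y + co[3] * y^2 +
    co[4] * x + co[5] * y + co[6]
  mean(v^2) / sum(co[1:3]^2)
}

#' Fit the initial breast ellipse from delimiting curvature peaks
#'
#' Given at least two delimiting peak indices on a margin curve, fits a
#' direct least-squares ellipse to the margin points lying between the
#' delimiting peaks (inclusive).  Of the two candidate arcs between the
#' outermost peaks, the one that an ellipse explains best (smallest
#' normalized conic residual) is taken as the breast arc; fitting fails if
#' that arc subtends less than `min_arc_frac` of the whole curve or if the
#' best conic is degenerate (e.g. collinear points).
#'
#' @param peaks Integer indices into the curve points (from
#'   [find_curvature_peaks()]); if more than two, the two with largest
#'   absolute curvature delimit the arc.
#' @param curve A `boundary_curve` or n x 2 point matrix.
#' @param side `"left"` or `"right"`.
#' @param profile Optional precomputed [curve_curvature()] profile (used
#'   to rank peaks when more than two are supplied).
#' @param min_arc_frac Minimum fraction of the curve the breast arc must
#'   subtend.
#' @return An `ellipse_init` (center, semi-axes, rotation, side).
#' @export
fit_initial_ellipse <- function(peaks, curve, side = c("right", "left"),
                                profile = NULL, min_arc_frac = 0.25) {
  side <- match.arg(side)
  pts <- if (inherits(curve, "boundary_curve")) curve$points else curve
  n <- nrow(pts)
  peaks <- sort(unique(as.integer(peaks)))
  if (length(peaks) < 2L)
    abort(sprintf("Initialization failure (%s): need >= 2 delimiting peaks.",
                  side))

  # Every peak pair delimits two candidate arcs; the breast arc is the
  # candidate an ellipse explains best among those long enough to be a
  # breast (>= min_arc_frac of the margin).  Trying all pairs makes the
  # choice robust to duplicate peaks on the same junction corner.
  best <- NULL
  any_fit <- FALSE
  pairs <- utils::combn(peaks, 2L, simplify = FALSE)
  for (pr in pairs) {
    p1 <- pr[1]; p2 <- pr[2]
    for (arc in list(p1:p2, c(p2:n, 1:p1))) {
      if (length(arc) < max(6L, ceiling(min_arc_frac * n))) next
      ax <- pts[arc, 1]; ay <- pts[arc, 2]
      co <- fit_conic_ellipse(ax, ay)
      if (is.null(co)) next
      geom <- conic_to_ellipse(co)
      if (is.null(geom)) next
      any_fit <- TRUE
      res <- conic_residual(co, ax, ay)
      if (is.null(best) || res < best$res)
        best <- list(res = res, geom = geom, frac = length(arc) / n)
    }
  }
  if (is.null(best)) {
    reason <- if (any_fit) "breast arc subtends too little of the margin"
      else "degenerate conic, no ellipse fits the arc"
    abort(sprintf("Initialization failure (%s): %s.", side, reason))
  }
  g <- best$geom
  new_ellipse_init(g$center, g$axes, g$rotation, side)
}

#' Contract an initial ellipse into a snake contour
#'
#' Samples the fitted ellipse at `n_vertices` equally spaced parameter
#' values with both semi-axes scaled by `factor` (default 0.95, a uniform
#' radial contraction so the snake starts just inside the breast
#' boundary), clipping vertices to the image bounds when a shape is given.
#'
#' @param ellipse An `ellipse_init`.
#' @param factor Scale factor in (0, 1].
#' @param n_vertices Number of contour vertices (>= 16).
#' @param shape Optional `c(H, W)` image shape used to clip vertices.
#' @return A `snake_contour`: closed n x 2 matrix of (x, y) vertices.
#' @export
contract_to_snake <- function(ellipse, factor = 0.95, n_vertices = 200L,
                              shape = NULL) {
  stopifnot(inherits(ellipse, "ellipse_init"))
  if (length(factor) != 1L || factor <= 0 || factor > 1)
    abort("`factor` must lie in (0, 1].")
  if (n_vertices < 16L) abort("`n_vertices` must be >= 16.")
  t <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  a <- ellipse$axes[1] * factor
  b <- ellipse$axes[2] * factor
  rot <- ellipse$rotation
  u <- a * cos(t); v <- b * sin(t)
  x <- ellipse$center[1] + cos(rot) * u - sin(rot) * v
  y <- ellipse$center[2] + sin(rot) * u + cos(rot) * v
  pts <- cbind(x = x, y = y)
  if (!is.null(shape)) {
    pts[, 1] <- clamp(pts[, 1], 0, shape[2] - 1)
    pts[, 2] <- clamp(pts[, 2], 0, shape[1] - 1)
  }
  structure(pts, class = c("snake_contour", class(pts)))
}
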