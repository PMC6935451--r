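#' Gradient Vector Flow snake parameters
#'
#' Container for the snake and GVF parameters.  Defaults follow the
#' standard active-contour settings for this application: elasticity
#' `alpha = 0.20`, rigidity `beta = 0.20`, step size `gamma = 1.00`,
#' external-force scale `kappa = 0.1`, external-energy weights
#' `w_line = 0.01`, `w_edge = 0.40`, `w_term = 0.01`, and 5000 evolution
#' iterations (with optional early stop on vertex displacement).  The GVF
#' field regularization `gvf_mu = 0.2` and `gvf_iterations = 200` are the
#' conventional Xu-Prince values.
#'
#' @param alpha Elasticity (tension) weight, >= 0.
#' @param beta Rigidity weight, >= 0.
#' @param gamma Time-step size, > 0.
#' @param kappa Scale of the external (GVF) force.
#' @param w_line Weight of the intensity term of the edge map.
#' @param w_edge Weight of the squared-gradient edge term.
#' @param w_term Weight of the level-line curvature (termination) term.
#' @param iterations Maximum snake iterations.
#' @param gvf_mu GVF field regularization.
#' @param gvf_iterations GVF diffusion iterations.
#' @param edge_sigma Gaussian sigma (pixels) of the edge map.
#' @param converge_tol Mean vertex displacement (px) below which evolution
#'   stops early; set to 0 to always run `iterations` steps.
#' @param resample_every Resample vertices to uniform spacing every this
#'   many iterations.
#' @return A list of class `gvf_params`.
#' @export
gvf_params <- function(alpha = 0.20, beta = 0.20, gamma = 1.00,
                       kappa = 0.1, w_line = 0.01, w_edge = 0.40,
                       w_term = 0.01, iterations = 5000L,
                       gvf_mu = 0.2, gvf_iterations = 200L,
                       edge_sigma = 3, converge_tol = 0.01,
                       resample_every = 50L) {
  p <- list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
            w_line = w_line, w_edge = w_edge, w_term = w_term,
            iterations = as.integer(iterations), gvf_mu = gvf_mu,
            gvf_iterations = as.integer(gvf_iterations),
            edge_sigma = edge_sigma, converge_tol = converge_tol,
            resample_every = as.integer(resample_every))
  with(p, {
    if (any(c(alpha, beta, kappa, w_line, w_edge, w_term) < 0))
      abort("All weights must be >= 0.")
    if (gamma <= 0) abort("`gamma` must be > 0.")
    if (iterations < 1L) abort("`iterations` must be >= 1.")
    if (gvf_mu <= 0) abort("`gvf_mu` must be > 0.")
  })
  class(p) <- "gvf_params"
  p
}

#' Edge map for the GVF snake
#'
#' Combines the three external-energy terms of the classic snake on the
#' Gaussian-smoothed gray image `I_s = G_sigma * I`:
#' `f = w_line * I_s + w_edge * |grad I_s|^2 + w_term * E_term`,
#' where `E_term` is the curvature of the level lines of `I_s`
#' (the termination energy).  `f` is shifted by its minimum so that
#' `f >= 0` everywhere (a pure shift, preserving linearity in the
#' weights); its spatial gradient is returned alongside.
#'
#' The intensity term attracts the contour toward bright (warm) regions,
#' appropriate because breasts are warmer than their surround; its small
#' default weight makes the choice of sign nearly immaterial.
#'
#' The three weights follow the convention of 8-bit active-contour
#' implementations, where `w_line` multiplies gray *levels* and `w_edge`
#' squared gray-level gradients; the `[0, 1]` image is therefore expressed
#' on the 0-255 scale (`intensity_scale`) inside the energy so that the
#' default weights balance the terms as intended (the edge term dominating
#' at genuine boundaries).  The termination term is scale-invariant.
#'
#' @param gray H x W grayscale matrix in `[0, 1]`.
#' @param sigma Gaussian smoothing sigma in pixels (> 0).
#' @param params A [gvf_params()] providing the three weights.
#' @param intensity_scale Gray-level units per unit intensity (default
#'   255, the 8-bit convention the weights assume).
#' @return List of class `edge_map` with `f` (H x W, >= 0), `fx`, `fy`.
#' @export
edge_map <- function(gray, sigma = NULL, params = gvf_params(),
                     intensity_scale = 255) {
  check_gray(gray)
  if (is.null(sigma)) sigma <- params$edge_sigma
  if (sigma <= 0) abort("`sigma` must be > 0.")
  is_ <- gaussian_blur(gray * intensity_scale, sigma)
  g <- grad_xy(is_)
  e_edge <- g$gx^2 + g$gy^2
  # second derivatives for the termination (level-line curvature) term
  gxx <- grad_xy(g$gx); gyy <- grad_xy(g$gy)
  ixx <- gxx$gx; ixy <- gxx$gy; iyy <- gyy$gy
  denom <- (g$gx^2 + g$gy^2)^1.5 + 1e-10
  e_term <- (iyy * g$gx^2 - 2 * ixy * g$gx * g$gy + ixx * g$gy^2) / denom
  f <- params$w_line * is_ + params$w_edge * e_edge + params$w_term * e_term
  f <- f - min(f)
  gf <- grad_xy(f)
  structure(list(f = f, fx = gf$gx, fy = gf$gy), class = "edge_map")
}

#' Gradient Vector Flow field
#'
#' Iterative minimizer of the GVF functional
#' `integral mu (|grad u|^2 + |grad v|^2) + |grad f|^2 |(u,v) - grad f|^2`
#' by explicit diffusion `u <- u + dt (mu lap(u) - b (u - fx))` with
#' `b = fx^2 + fy^2`, initialized at `(fx, fy)`.  The explicit scheme is
#' stable for `dt <= 1 / (4 mu + max(b))`; the default uses exactly that
#' bound and a larger user-supplied `dt` is rejected.  Iterating longer
#' only decreases the functional (see [gvf_energy()]).
#'
#' As in the original GVF formulation, the edge map is rescaled to unit
#' peak before diffusion (`f/max(f)`, when `max(f) > 0`); `mu` is thereby
#' defined relative to a `[0, 1]` edge map rather than to the arbitrary
#' physical scale of `f`, and the returned field approximates the gradient
#' of the *normalized* edge map at strong edges.  [gvf_energy()] applies
#' the same normalization.
#'
#' @param em An [edge_map()].
#' @param mu Regularization weight (> 0).
#' @param n_iter Number of diffusion iterations (>= 1).
#' @param dt Optional explicit time step.
#' @return List of class `gvf_field` with components `u`, `v` (H x W).
#' @export
gvf_field <- function(em, mu = 0.2, n_iter = 200L, dt = NULL) {
  stopifnot(inherits(em, "edge_map"))
  if (mu <= 0) abort("`mu` must be > 0.")
  if (n_iter < 1L) abort("`n_iter` must be >= 1.")
  em <- normalize_edge_map(em)
  b <- em$fx^2 + em$fy^2
  bound <- 1 / (4 * mu + max(b))
  if (is.null(dt)) dt <- bound
  if (dt > bound + 1e-12)
    abort(sprintf(
      "Time step dt = %g violates the stability bound 1/(4 mu + max|grad f|^2) = %g.",
      dt, bound))
  u <- em$fx; v <- em$fy
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu * laplacian(u) - b * (u - em$fx))
    v <- v + dt * (mu * laplacian(v) - b * (v - em$fy))
  }
  structure(list(u = u, v = v), class = "gvf_field")
}

# Rescale an edge map to unit peak (no-op on a flat map).
normalize_edge_map <- function(em) {
  mx <- max(em$f)
  if (mx > 0) {
    em$f <- em$f / mx; em$fx <- em$fx / mx; em$fy <- em$fy / mx
  }
  em
}

#' GVF energy functional
#'
#' Evaluates the discrete Gradient Vector Flow functional
#' `sum mu (|grad u|^2 + |grad v|^2) + b ((u - fx)^2 + (v - fy)^2)`
#' (forward-difference gradients), the quantity [gvf_field()] decreases at
#' every iteration.  The edge map is rescaled to unit peak exactly as in
#' [gvf_field()].
#'
#' @param field A [gvf_field()] (or list with `u`, `v`).
#' @param em The [edge_map()] the field was computed from.
#' @param mu Regularization weight used.
#' @return Scalar energy.
#' @export
gvf_energy <- function(field, em, mu = 0.2) {
  em <- normalize_edge_map(em)
  u <- field$u; v <- field$v
  fwdx <- function(m) cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE]) - m
  fwdy <- function(m) rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE]) - m
  b <- em$fx^2 + em$fy^2
  sum(mu * (fwdx(u)^2 + fwdy(u)^2 + fwdx(v)^2 + fwdy(v)^2) +
        b * ((u - em$fx)^2 + (v - em$fy)^2))
}
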