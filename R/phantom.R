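#' Specify a synthetic thermogram phantom
#'
#' Describes a frontal-view phantom: a cool surround, a warm torso block,
#' and one roughly elliptical, warmer breast per image half whose lower arc
#' protrudes below the torso so that the binarized body silhouette carries
#' the breast boundary (as the curvature-based initialization requires).
#' Abnormal phantoms add a localized Gaussian hot spot inside one breast,
#' producing the intensity and colour asymmetry used as the abnormality
#' cue.
#'
#' All temperatures are on the normalized `[0, 1]` scale rendered by
#' [pseudo_color()].  Defaults are chosen so that, after grayscale
#' conversion, surround/torso/breast are separated both by the
#' binarization threshold 0.25 and by usable edge contrast.
#'
#' @param width,height Image size in pixels.
#' @param left_center,right_center Breast ellipse centers `(x, y)` in
#'   0-based pixel coordinates; each breast must lie in its own image half.
#' @param left_axes,right_axes Semi-axes `(a, b)` in pixels.
#' @param left_rot,right_rot Ellipse rotations in radians.
#' @param surround_temp Temperature of the cool background surround.
#' @param background_temp Temperature of the torso block (the "warm
#'   background" the breasts sit on).
#' @param breast_elev Breast temperature elevation above the torso level.
#' @param torso `(xmin, xmax, ymin, ymax)` of the torso block, pixels.
#' @param noise_sd Standard deviation of the additive Gaussian temperature
#'   noise (0 disables noise).
#' @param hotspot Logical; add a hot spot (abnormal case)?
#' @param hotspot_side `"left"` or `"right"`.
#' @param hotspot_offset Offset `(dx, dy)` of the hot-spot center from the
#'   affected breast's center, pixels.
#' @param hotspot_radius Gaussian radius parameter of the bump, pixels.
#' @param hotspot_elev Peak temperature elevation of the bump.
#' @param edge_softness Width (pixels) of the smooth sigmoidal breast edge.
#' @param seed Integer seed used when rendering noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 160, height = 120,
                         left_center = c(0.30, 0.55) * c(width, height),
                         left_axes = c(0.13 * width, 0.25 * height),
                         left_rot = 0,
                         right_center = c(0.70, 0.55) * c(width, height),
                         right_axes = c(0.13 * width, 0.25 * height),
                         right_rot = 0,
                         surround_temp = 0.05,
                         background_temp = 0.26,
                         breast_elev = 0.18,
                         torso = c(0.10 * width, 0.90 * width,
                                   0.05 * height, 0.55 * height),
                         noise_sd = 0.01,
                         hotspot = FALSE,
                         hotspot_side = "left",
                         hotspot_offset = c(0, 2),
                         hotspot_radius = 0.05 * width,
                         hotspot_elev = 0.30,
                         edge_softness = 1.2,
                         seed = 0L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               left_center = left_center, left_axes = left_axes,
               left_rot = left_rot,
               right_center = right_center, right_axes = right_axes,
               right_rot = right_rot,
               surround_temp = surround_temp,
               background_temp = background_temp,
               breast_elev = breast_elev, torso = torso,
               noise_sd = noise_sd,
               hotspot = isTRUE(hotspot), hotspot_side = hotspot_side,
               hotspot_offset = hotspot_offset,
               hotspot_radius = hotspot_radius, hotspot_elev = hotspot_elev,
               edge_softness = edge_softness, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  w <- spec$width; h <- spec$height
  if (spec$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  half <- w / 2
  for (side in c("left", "right")) {
    ctr <- spec[[paste0(side, "_center")]]
    ax <- spec[[paste0(side, "_axes")]]
    if (any(ax <= 0)) abort("Breast semi-axes must be positive.")
    rot <- spec[[paste0(side, "_rot")]]
    ext_x <- sqrt((ax[1] * cos(rot))^2 + (ax[2] * sin(rot))^2)
    ext_y <- sqrt((ax[1] * sin(rot))^2 + (ax[2] * cos(rot))^2)
    if (ctr[1] - ext_x < 0 || ctr[1] + ext_x > w - 1 ||
        ctr[2] - ext_y < 0 || ctr[2] + ext_y > h - 1)
      abort(sprintf("The %s breast does not fit inside the image.", side))
    in_left_half <- ctr[1] + ext_x < half
    in_right_half <- ctr[1] - ext_x > half
    if ((side == "left" && !in_left_half) ||
        (side == "right" && !in_right_half))
      abort(sprintf("The %s breast must lie entirely in its image half.", side))
  }
  if (!spec$hotspot_side %in% c("left", "right"))
    abort("`hotspot_side` must be \"left\" or \"right\".")
  if (spec$hotspot) {
    ctr <- spec[[paste0(spec$hotspot_side, "_center")]] + spec$hotspot_offset
    ax <- spec[[paste0(spec$hotspot_side, "_axes")]]
    bc <- spec[[paste0(spec$hotspot_side, "_center")]]
    rot <- spec[[paste0(spec$hotspot_side, "_rot")]]
    d <- ellipse_level(ctr[1], ctr[2], bc, ax, rot)
    if (d > 1) abort("Hot spot center must lie inside its breast ellipse.")
  }
  invisible(spec)
}

# Normalized squared ellipse level: <= 1 inside.
ellipse_level <- function(x, y, center, axes, rot) {
  dx <- x - center[1]; dy <- y - center[2]
  u <- cos(rot) * dx + sin(rot) * dy
  v <- -sin(rot) * dx + cos(rot) * dy
  (u / axes[1])^2 + (v / axes[2])^2
}

rasterize_ellipse <- function(h, w, center, axes, rot) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  m <- (ellipse_level(xs, ys, center, axes, rot) <= 1) + 0L
  m
}

#' Render a phantom sample
#'
#' Builds the scalar temperature field (surround + torso + smooth-edged
#' breast ellipses + optional hot-spot bump + seeded Gaussian noise,
#' clipped to `[0, 1]`), renders it through [pseudo_color()], and
#' rasterizes the ground-truth breast masks exactly from the spec
#' ellipses.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `image`
#'   (H x W x 3 RGB array), `temperature` (noise-free field), `left_mask`,
#'   `right_mask` (0/1 matrices), `label` (`"normal"` or `"abnormal"`),
#'   and `spec`.
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(width = 80, height = 60, noise_sd = 0))
#' ph$label
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  # non-overlap check on the exact masks
  lm <- rasterize_ellipse(h, w, spec$left_center, spec$left_axes, spec$left_rot)
  rm_ <- rasterize_ellipse(h, w, spec$right_center, spec$right_axes,
                           spec$right_rot)
  if (any(lm & rm_)) abort("Breast ellipses overlap.")

  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)

  field <- matrix(spec$surround_temp, h, w)
  tt <- spec$torso
  torso <- xs >= tt[1] & xs <= tt[2] & ys >= tt[3] & ys <= tt[4]
  field[torso] <- spec$background_temp

  breast_temp <- spec$background_temp + spec$breast_elev
  for (side in c("left", "right")) {
    ctr <- spec[[paste0(side, "_center")]]
    ax <- spec[[paste0(side, "_axes")]]
    rot <- spec[[paste0(side, "_rot")]]
    lev <- sqrt(ellipse_level(xs, ys, ctr, ax, rot))
    # signed distance approximation from the unit level set, in pixels
    sd_px <- (lev - 1) * min(ax)
    wgt <- 1 / (1 + exp(sd_px / spec$edge_softness))
    field <- field * (1 - wgt) + breast_temp * wgt
  }

  if (spec$hotspot) {
    ctr <- spec[[paste0(spec$hotspot_side, "_center")]] + spec$hotspot_offset
    d2 <- (xs - ctr[1])^2 + (ys - ctr[2])^2
    field <- field + spec$hotspot_elev * exp(-d2 / (2 * (spec$hotspot_radius / 2)^2))
  }

  noiseless <- clamp(field, 0, 1)
  if (spec$noise_sd > 0) {
    field <- field + with_seed(spec$seed, rnorm(h * w, 0, spec$noise_sd))
  }
  field <- clamp(field, 0, 1)

  out <- list(image = pseudo_color(field),
              temperature = noiseless,
              left_mask = lm, right_mask = rm_,
              label = if (spec$hotspot) "abnormal" else "normal",
              spec = spec)
  class(out) <- "phantom_sample"
  out
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, label: %s, seed: %d\n",
              x$spec$width, x$spec$height, x$label, x$spec$seed))
  invisible(x)
}

#' Generate a seeded synthetic phantom dataset
#'
#' Draws `n_normal + n_abnormal` phantom specs with seeded jitter of breast
#' geometry and temperature levels, renders each, and returns a manifest
#' tibble with the rendered samples as a list-column.  Reproducible for a
#' fixed seed; all randomness flows from the single `seed` argument.
#'
#' @param n_normal,n_abnormal Numbers of normal / abnormal samples.
#' @param jitter Named list of jitter half-ranges applied uniformly:
#'   `center` (px), `axes` (relative), `elev` (temperature),
#'   `hotspot_elev` (temperature).
#' @param seed Integer master seed.
#' @param width,height Image size of every sample.
#' @param noise_sd Temperature noise standard deviation for every sample.
#' @param hotspot_elev Mean hot-spot elevation for abnormal samples.
#' @return A tibble with columns `id`, `label`, `seed` and list-columns
#'   `sample` ([render_phantom()] output) and `spec`.
#' @export
#' @examples
#' ds <- make_dataset(2, 2, seed = 1, width = 80, height = 60)
#' ds$label
make_dataset <- function(n_normal, n_abnormal,
                         jitter = list(center = 2, axes = 0.08,
                                       elev = 0.02, hotspot_elev = 0.04),
                         seed = 0L, width = 160, height = 120,
                         noise_sd = 0.01, hotspot_elev = 0.30) {
  stopifnot(n_normal >= 0, n_abnormal >= 0)
  n <- n_normal + n_abnormal
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  if (n == 0L) {
    return(tibble(id = character(), label = character(),
                  seed = integer(), sample = list(), spec = list()))
  }
  jit <- function(nm, default) if (!is.null(jitter[[nm]])) jitter[[nm]] else default
  jc <- jit("center", 2); ja <- jit("axes", 0.08)
  je <- jit("elev", 0.02); jh <- jit("hotspot_elev", 0.04)

  base <- phantom_spec(width = width, height = height, noise_sd = noise_sd)
  draws <- with_seed(seed, lapply(seq_len(n), function(i) {
    list(dc = runif(4, -jc, jc), da = runif(4, -ja, ja),
         de = runif(1, -je, je), dh = runif(1, -jh, jh),
         side = sample(c("left", "right"), 1),
         sub_seed = sample.int(.Machine$integer.max, 1))
  }))

  samples <- vector("list", n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    sp <- tryCatch(
      phantom_spec(
        width = width, height = height,
        left_center = base$left_center + d$dc[1:2],
        left_axes = base$left_axes * (1 + d$da[1:2]),
        right_center = base$right_center + d$dc[3:4],
        right_axes = base$right_axes * (1 + d$da[3:4]),
        breast_elev = base$breast_elev + d$de,
        noise_sd = noise_sd,
        hotspot = labels[i] == "abnormal",
        hotspot_side = d$side,
        hotspot_elev = hotspot_elev + d$dh,
        seed = d$sub_seed),
      error = function(e) abort(paste0(
        "Infeasible jitter ranges: ", conditionMessage(e))))
    samples[[i]] <- render_phantom(sp)
    specs[[i]] <- sp
  }
  tibble(id = sprintf("phantom_%03d", seq_len(n)),
         label = labels,
         seed = vapply(specs, function(s) s$seed, integer(1)),
         sample = samples, spec = specs)
}
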