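#' Load an RGB image from disk
#'
#' Reads a JPEG or PNG file and returns an H x W x 3 array with channel
#' values rescaled to `[0, 1]` (8-bit value 128 becomes 128/255).
#' Single-channel inputs are replicated to three channels; any alpha
#' channel is dropped.
#'
#' @param path Path to a JPEG or PNG file.
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    abort(sprintf("Cannot read image: file not found: %s", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) abort(sprintf(
                    "Cannot read image %s: %s", path, conditionMessage(e))))
  a <- EBImage::imageData(img)   # width x height (x channels)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a <- aperm(a, c(2, 1, 3))      # -> rows = y, cols = x
  nc <- dim(a)[3]
  if (nc == 1L) a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  else if (nc >= 3L) a <- a[, , 1:3, drop = FALSE]
  else abort(sprintf("Cannot read image %s: unsupported channel count %d",
                     path, nc))
  clamp(a, 0, 1)
}

#' Convert an RGB image to grayscale
#'
#' Standard luminance weighting `0.2989 R + 0.5870 G + 0.1140 B`, the
#' conventional choice, monotone in every channel.
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @return H x W grayscale matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  check_rgb(img)
  d <- dim(img)
  ch <- function(i) matrix(img[, , i], d[1], d[2])
  out <- 0.2989 * ch(1) + 0.5870 * ch(2) + 0.1140 * ch(3)
  clamp(out, 0, 1)
}

#' Gaussian denoising
#'
#' Smooths a grayscale image with a normalized `kernel x kernel` Gaussian
#' (default 3 x 3), sigma = kernel/6 rounded to the nearest 0.5 (0.5 for
#' the default), using reflect padding so image borders are not darkened.
#'
#' @param img H x W grayscale matrix in `[0, 1]`.
#' @param kernel Odd positive kernel size; `kernel = 1` is the identity.
#' @return Smoothed matrix, same shape, values within the input range.
#' @export
denoise <- function(img, kernel = 3L) {
  check_gray(img)
  if (length(kernel) != 1L || kernel < 1 || kernel %% 2 == 0)
    abort("`kernel` must be an odd positive integer.")
  if (kernel == 1L) return(img)
  sigma <- round(kernel / 6 * 2) / 2
  r <- (kernel - 1L) %/% 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  sep_conv2(img, k)
}

#' Binarize a grayscale image
#'
#' A pixel is foreground iff its intensity is strictly greater than
#' `threshold` (default 0.25).
#'
#' @param img H x W grayscale matrix in `[0, 1]`.
#' @param threshold Threshold in the open interval (0, 1).
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(img, threshold = 0.25) {
  check_gray(img)
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    abort("`threshold` must lie strictly between 0 and 1.")
  (img > threshold) + 0L
}

# Trace the outer boundary of the largest component of a mask.
# Returns an n x 2 matrix of 0-based (x, y) pixel coordinates, ordered,
# 8-connected, no duplicated consecutive points, not closed-duplicated.
trace_boundary <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labd <- EBImage::imageData(lab)      # transposed frame: width x height
  sizes <- table(labd[labd > 0])
  if (length(sizes) == 0L) abort("Empty scene: mask has no foreground.")
  keep <- as.integer(names(sizes)[which.max(sizes)])
  oc <- EBImage::ocontour(EBImage::Image((labd == keep) + 0))
  # ocontour works on the transposed frame: col 1 = x, col 2 = y, 0-based
  pts <- oc[[1]]
  dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
  pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  pts
}

new_boundary_curve <- function(points, side, orientation) {
  structure(list(points = points, side = side, orientation = orientation),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve> side: %s, %d points, %s on screen\n",
              x$side, nrow(x$points), x$orientation))
  invisible(x)
}

# Orient a closed point sequence to the requested on-screen sense
# (y-down coordinates: shoelace area < 0 <=> counter-clockwise on screen).
orient_points <- function(pts, orientation = c("ccw", "cw")) {
  orientation <- match.arg(orientation)
  a <- shoelace_area(pts)
  flip <- (orientation == "ccw" && a > 0) || (orientation == "cw" && a < 0)
  if (flip) pts <- pts[nrow(pts):1, , drop = FALSE]
  pts
}

#' Extract the left and right body margins from a binarized thermogram
#'
#' Labels the foreground of the binarized silhouette and returns one
#' closed, 8-connected boundary curve per image half.  A single dominant
#' component spanning both halves is split at the vertical midline; two
#' components (one per half) are traced separately.  Curve side labels are
#' assigned from the curve centroid's image half.
#'
#' Orientation convention (this fixes curvature peak signs downstream):
#' the left-half curve is traversed counter-clockwise on screen and the
#' right-half curve clockwise, so the concave breast/torso junction
#' corners appear as negative curvature minima on the left margin and
#' positive maxima on the right margin, matching [find_curvature_peaks()].
#'
#' @param mask 0/1 matrix from [binarize()].
#' @param gray Optional grayscale image (same shape); retained for
#'   edge-backend variants, unused by the default boundary tracer.
#' @return A list with elements `left` and `right`, each a
#'   `boundary_curve` (fields `points` [n x 2, 0-based x,y], `side`,
#'   `orientation`).
#' @export
extract_margins <- function(mask, gray = NULL) {
  mask <- as_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (sum(mask) == 0L) abort("Empty scene: mask has no foreground.")

  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))
  sizes <- table(labm[labm > 0])
  min_size <- max(20, 0.001 * h * w)
  usable <- as.integer(names(sizes)[sizes >= min_size])
  if (length(usable) == 0L) abort("Empty scene: no usable foreground component.")
  if (length(usable) > 2L)
    abort(sprintf("Ambiguous scene: %d usable foreground components.",
                  length(usable)))

  xmid <- (w - 1) / 2
  halves <- list()
  if (length(usable) == 1L) {
    comp <- (labm == usable) + 0L
    xs <- col(comp)[comp == 1L] - 1
    if (min(xs) >= xmid || max(xs) <= xmid)
      abort("Ambiguous scene: single component does not span both halves.")
    left_half <- comp; left_half[, (floor(xmid) + 2L):w] <- 0L
    right_half <- comp; right_half[, 1:(floor(xmid) + 1L)] <- 0L
    halves <- list(left = left_half, right = right_half)
  } else {
    for (u in usable) {
      comp <- (labm == u) + 0L
      cx <- mean(col(comp)[comp == 1L] - 1)
      side <- if (cx <= xmid) "left" else "right"
      if (!is.null(halves[[side]]))
        abort("Ambiguous scene: two components in the same image half.")
      halves[[side]] <- comp
    }
    if (is.null(halves$left) || is.null(halves$right))
      abort("Ambiguous scene: need one component per image half.")
  }

  out <- list()
  for (side in c("left", "right")) {
    pts <- trace_boundary(halves[[side]])
    if (nrow(pts) < 3L)
      abort(sprintf("Degenerate %s margin: fewer than 3 boundary points.", side))
    ori <- if (side == "left") "ccw" else "cw"
    pts <- orient_points(pts, ori)
    out[[side]] <- new_boundary_curve(pts, side, ori)
  }
  out
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output PNG path (foreground stored as 255).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path, type = "png")
  invisible(path)
}
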