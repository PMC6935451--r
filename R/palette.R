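#' Map a temperature field to pseudo-colour RGB
#'
#' Applies the fixed piecewise-linear blue-to-red thermal palette used by
#' the phantom generator: temperature 0 maps to pure blue (0, 0, 1),
#' 0.5 to pure green (0, 1, 0) and 1 to pure red (1, 0, 0), with linear
#' interpolation within each segment.  The mapping is strictly monotone in
#' hue position and invertible (see [temperature_from_rgb()]), so tests can
#' reason about temperature directly from rendered colours.
#'
#' @param field Numeric matrix (H x W) of temperatures in `[0, 1]`.
#' @return An H x W x 3 RGB array with channel values in `[0, 1]`.
#' @seealso [temperature_from_rgb()] for the inverse lookup.
#' @export
#' @examples
#' pseudo_color(matrix(c(0, 0.5, 1), 1))
pseudo_color <- function(field) {
  if (!is.matrix(field)) field <- as.matrix(field)
  if (anyNA(field) || min(field) < 0 || max(field) > 1)
    abort("`field` values must lie in [0, 1].")
  lo <- field <= 0.5
  r <- ifelse(lo, 0, 2 * field - 1)
  g <- ifelse(lo, 2 * field, 2 - 2 * field)
  b <- ifelse(lo, 1 - 2 * field, 0)
  out <- array(0, c(nrow(field), ncol(field), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Recover the temperature field from a pseudo-coloured image
#'
#' Inverse of [pseudo_color()].  Exact for palette colours; for slightly
#' perturbed colours (e.g. 8-bit quantization) the recovered temperature is
#' within `1/255` of the original.
#'
#' @param img H x W x 3 RGB array produced by [pseudo_color()].
#' @return Numeric H x W matrix of temperatures in `[0, 1]`.
#' @export
temperature_from_rgb <- function(img) {
  check_rgb(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  # Lower segment (b >= r): g = 2t, b = 1 - 2t  =>  t = (g + 1 - b) / 4.
  # Upper segment (r >  b): r = 2t - 1, g = 2 - 2t  =>  t = (r - g + 3) / 4.
  t <- ifelse(b >= r, (g + 1 - b) / 4, (r - g + 3) / 4)
  clamp(t, 0, 1)
}
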