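#' Segment the left and right breast in a thermogram
#'
#' Full segmentation pipeline: grayscale conversion, Gaussian denoising,
#' binarization of the body silhouette, extraction of the left/right
#' margins, curvature-peak detection of the delimiting salient points,
#' least-squares elliptical initialization, morphological contraction and
#' GVF snake evolution, and rasterization of the converged contours into
#' per-breast masks.
#'
#' If no curvature peak exceeds the prominence on a margin the pipeline
#' falls back to the two points of extreme curvature of the correct sign
#' on that margin.
#'
#' @param img H x W x 3 RGB array in `[0, 1]` (see [load_image()]), or a
#'   `phantom_sample`.
#' @param params A [gvf_params()].
#' @param threshold Binarization threshold (default 0.25).
#' @param smooth_sigma Curvature coordinate smoothing (points).
#' @param min_prominence Curvature peak prominence (1/px).
#' @param contraction Ellipse contraction factor for the initial snake
#'   (0.90 starts the snake strictly inside the thresholded silhouette,
#'   whose boundary sits slightly outside the luminal edge).
#' @param n_vertices Snake vertex count.
#' @return Object of class `thermo_segmentation`: list with `gray`,
#'   `mask` (binarized silhouette), `margins`, `profiles`, `peaks`,
#'   `ellipses`, `initial` and `snakes` (per-side contours), `left_mask`,
#'   `right_mask` (final per-breast masks) and `params`.
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(noise_sd = 0))
#' seg <- segment_breasts(ph)
#' zsi(seg$left_mask, ph$left_mask)
segment_breasts <- function(img, params = gvf_params(), threshold = 0.25,
                            smooth_sigma = 3, min_prominence = 0.005,
                            contraction = 0.90, n_vertices = 200L) {
  if (inherits(img, "phantom_sample")) img <- img$image
  check_rgb(img)
  gray <- denoise(to_gray(img))
  mask <- binarize(gray, threshold)
  margins <- extract_margins(mask, gray)

  em <- edge_map(gray, params$edge_sigma, params)
  field <- gvf_field(em, params$gvf_mu, params$gvf_iterations)

  shape <- dim(gray)
  out <- list(gray = gray, mask = mask, margins = margins,
              profiles = list(), peaks = list(), ellipses = list(),
              initial = list(), snakes = list(), params = params)
  for (side in c("left", "right")) {
    prof <- curve_curvature(margins[[side]], smooth_sigma)
    pk <- find_curvature_peaks(prof, side, min_prominence)
    if (length(pk) < 2L) {
      # fallback: the two extreme-curvature points of the correct sign,
      # forced apart by at least a tenth of the margin so both delimiters
      # cannot land on the same corner
      v <- if (side == "right") prof$k else -prof$k
      nv <- length(v)
      p1 <- which.max(v)
      d <- abs(seq_len(nv) - p1)
      ok <- pmin(d, nv - d) >= max(10L, nv %/% 10L)
      p2 <- which(ok)[which.max(v[ok])]
      pk <- sort(c(p1, p2))
    }
    ell <- fit_initial_ellipse(pk, margins[[side]], side, prof)
    init <- contract_to_snake(ell, contraction, n_vertices, shape)
    snake <- evolve_snake(init, field, params, shape)
    out$profiles[[side]] <- prof
    out$peaks[[side]] <- pk
    out$ellipses[[side]] <- ell
    out$initial[[side]] <- init
    out$snakes[[side]] <- snake
    out[[paste0(side, "_mask")]] <- contour_to_mask(snake, shape)
  }
  class(out) <- "thermo_segmentation"
  out
}

#' @export
print.thermo_segmentation <- function(x, ...) {
  cat(sprintf(
    "<thermo_segmentation> %dx%d image; snake iterations L=%d%s R=%d%s\n",
    nrow(x$gray), ncol(x$gray),
    attr(x$snakes$left, "iterations"),
    if (attr(x$snakes$left, "converged")) "*" else "",
    attr(x$snakes$right, "iterations"),
    if (attr(x$snakes$right, "converged")) "*" else ""))
  cat(sprintf("  left mask: %d px, right mask: %d px  (* = converged)\n",
              sum(x$left_mask), sum(x$right_mask)))
  invisible(x)
}

#' Build the masked RGB input for image-based classification
#'
#' Pixels outside the union of the two breast masks are zeroed, producing
#' the "segmented image" consumed by the convolutional classifier.
#'
#' @param img H x W x 3 RGB array.
#' @param left_mask,right_mask 0/1 breast masks.
#' @return H x W x 3 array.
#' @export
segmented_input <- function(img, left_mask, right_mask) {
  check_rgb(img)
  m <- (as_mask(left_mask) | as_mask(right_mask)) + 0
  img * array(rep(m, 3L), dim(img))
}
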