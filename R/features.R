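#' Roundness and compactness of a region
#'
#' `roundness(A, P) = 4 * pi * A / P^2`, which equals 1 exactly for a
#' perfect circle (`A = pi r^2`, `P = 2 pi r`) and is smaller for any
#' other simple shape.  `compactness(A, P) = A / P^2` (the dimensionless
#' form; the dimensional variant `A / P` is available via
#' `squared = FALSE` but is not part of the standard feature vector).
#'
#' @param A Region area (pixels^2), > 0.
#' @param P Region perimeter (pixels), > 0.
#' @param squared Use the `A / P^2` form (default) rather than `A / P`.
#' @return Numeric scalar (vectorized over `A`, `P`).
#' @export
#' @examples
#' r <- 17.3
#' roundness(pi * r^2, 2 * pi * r)  # exactly 1
roundness <- function(A, P) {
  stopifnot(all(A > 0), all(P > 0))
  4 * pi * A / P^2
}

#' @rdname roundness
#' @export
compactness <- function(A, P, squared = TRUE) {
  stopifnot(all(A > 0), all(P > 0))
  if (squared) A / P^2 else A / P
}

# Douglas-Peucker polyline simplification (open polyline, iterative).
dp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i1 <- rg[1]; i2 <- rg[2]
    if (i2 - i1 < 2L) next
    a <- pts[i1, ]; b <- pts[i2, ]
    v <- b - a
    len <- sqrt(sum(v^2))
    seg <- (i1 + 1L):(i2 - 1L)
    d <- if (len < 1e-12) {
      sqrt((pts[seg, 1] - a[1])^2 + (pts[seg, 2] - a[2])^2)
    } else {
      abs(v[1] * (pts[seg, 2] - a[2]) - v[2] * (pts[seg, 1] - a[1])) / len
    }
    im <- which.max(d)
    if (d[im] > tol) {
      isplit <- seg[im]
      keep[isplit] <- TRUE
      stack <- c(stack, list(c(i1, isplit)), list(c(isplit, i2)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Perimeter of the traced pixel-centre boundary: Douglas-Peucker
# simplified polygon length plus the half-pixel outward offset correction
# (+2*pi*0.5, exact for convex outlines).  The simplification removes the
# digitization staircase so smooth boundaries measure close to their true
# length while polygonal corners are preserved.
perimeter_from_boundary <- function(pts, tol = 1.0) {
  n <- nrow(pts)
  if (n < 3L) return(2 * n + pi)
  # split the closed curve at the point farthest from point 1 so the two
  # open halves can each be simplified with fixed endpoints
  d1 <- (pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2
  cut <- which.max(d1)
  if (cut <= 2L || cut >= n - 1L) cut <- n %/% 2L
  h1 <- dp_simplify(pts[1:cut, , drop = FALSE], tol)
  h2 <- dp_simplify(pts[c(cut:n, 1L), , drop = FALSE], tol)
  plen <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  plen(h1) + plen(h2) + pi
}

#' Shape descriptors of a segmented region
#'
#' Area `A` (foreground pixel count), perimeter `P` (length of the traced
#' boundary polygon, staircase-simplified, with the half-pixel outward
#' offset correction), roundness `R = 4 pi A / P^2` and compactness
#' `C = A / P^2`.
#'
#' @param mask 0/1 matrix with a single connected foreground region.
#' @return One-row tibble with columns `A`, `P`, `R`, `C`.
#' @export
shape_features <- function(mask) {
  mask <- as_mask(mask)
  A <- sum(mask)
  if (A == 0L) abort("Empty region: mask has no foreground.")
  pts <- trace_boundary(mask)
  P <- perimeter_from_boundary(pts)
  tibble(A = A, P = P, R = roundness(A, P), C = compactness(A, P))
}

#' First-order texture statistics of a channel within a region
#'
#' Mean, median, population variance, standard deviation and Shannon
#' entropy (base 2, from the normalized 256-bin histogram over `[0, 1]`,
#' with `0 log 0 := 0`) of the in-mask pixel values of one colour
#' channel.  These depend only on individual pixel values, not on their
#' spatial arrangement.
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @param mask 0/1 region mask.
#' @param channel 1-3 or `"R"`, `"G"`, `"B"`.
#' @param bins Histogram bin count for the entropy.
#' @param entropy_base Logarithm base (2 = bits).
#' @return One-row tibble with `mu`, `median`, `var`, `sd`, `entropy`.
#' @export
first_order <- function(img, mask, channel, bins = 256L, entropy_base = 2) {
  check_rgb(img)
  mask <- as_mask(mask)
  ch <- channel_index(channel)
  vals <- img[, , ch][mask == 1L]
  if (length(vals) == 0L) abort("Empty region: mask has no foreground.")
  p <- tabulate(pmin(floor(vals * bins), bins - 1) + 1L, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  tibble(mu = mean(vals),
         median = median(vals),
         var = mean((vals - mean(vals))^2),
         sd = sqrt(mean((vals - mean(vals))^2)),
         entropy = -sum(p * log(p, base = entropy_base)))
}

channel_index <- function(channel) {
  if (is.character(channel))
    channel <- match(toupper(channel), c("R", "G", "B"))
  if (is.na(channel) || !channel %in% 1:3)
    abort("`channel` must be 1-3 or one of \"R\", \"G\", \"B\".")
  as.integer(channel)
}

#' Gray-level co-occurrence matrix of a channel within a region
#'
#' Quantizes the channel uniformly to `levels` bins over `[0, 1]`, counts
#' ordered pixel pairs at the given offset(s) with both members inside the
#' mask, symmetrizes (adds the transposed counts) and normalizes to sum 1.
#' Multiple offsets are averaged.  Defaults follow the Haralick
#' convention: 8 levels, offset `(1, 0)`; the four standard offsets
#' `{(1,0),(0,1),(1,1),(1,-1)}` can be requested.
#'
#' @param img H x W x 3 RGB array.
#' @param mask 0/1 region mask.
#' @param channel 1-3 or `"R"`, `"G"`, `"B"`.
#' @param levels Quantization levels (>= 2).
#' @param offsets Either a single `c(dx, dy)` pair, a list of such pairs,
#'   or `"all4"` for the four standard directions.
#' @return Object of class `glcm`: list with the normalized matrix `c`,
#'   `levels`, `offsets`, and the marginal means / standard deviations
#'   `mu_i`, `mu_j`, `sd_i`, `sd_j`.
#' @export
glcm <- function(img, mask, channel, levels = 8L, offsets = c(1, 0)) {
  check_rgb(img)
  mask <- as_mask(mask)
  if (levels < 2L) abort("`levels` must be >= 2.")
  if (identical(offsets, "all4"))
    offsets <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  if (!is.list(offsets)) offsets <- list(offsets)
  ch <- channel_index(channel)
  q <- matrix(pmin(floor(img[, , ch] * levels), levels - 1L),
              nrow(mask), ncol(mask))
  h <- nrow(mask); w <- ncol(mask)
  acc <- matrix(0, levels, levels)
  total <- 0
  for (off in offsets) {
    dx <- off[1]; dy <- off[2]
    r1 <- max(1L, 1L - dy):min(h, h - dy)
    c1 <- max(1L, 1L - dx):min(w, w - dx)
    if (!length(r1) || !length(c1)) next
    m1 <- mask[r1, c1, drop = FALSE] == 1L
    m2 <- mask[r1 + dy, c1 + dx, drop = FALSE] == 1L
    ok <- m1 & m2
    if (!any(ok)) next
    i <- q[r1, c1, drop = FALSE][ok]
    j <- q[r1 + dy, c1 + dx, drop = FALSE][ok]
    cm <- matrix(tabulate(i * levels + j + 1L, nbins = levels^2),
                 levels, levels, byrow = TRUE)
    acc <- acc + cm + t(cm)   # symmetrize
    total <- total + 2 * sum(cm)
  }
  if (total == 0) abort("Degenerate GLCM: no valid in-mask pixel pair at the offset.")
  cmat <- acc / total
  i_idx <- seq_len(levels)
  mu_i <- sum(i_idx * rowSums(cmat)); mu_j <- sum(i_idx * colSums(cmat))
  sd_i <- sqrt(sum((i_idx - mu_i)^2 * rowSums(cmat)))
  sd_j <- sqrt(sum((i_idx - mu_j)^2 * colSums(cmat)))
  structure(list(c = cmat, levels = levels, offsets = offsets,
                 mu_i = mu_i, mu_j = mu_j, sd_i = sd_i, sd_j = sd_j),
            class = "glcm")
}

#' Second-order (co-occurrence) texture descriptors
#'
#' The four Haralick-style statistics of a normalized GLCM `c(i, j)`:
#' contrast `CM = sum |i-j|^2 c(i,j)`, correlation
#' `r = sum (i - mu_i)(j - mu_j) c(i,j) / (sd_i sd_j)` (defined as 0 when
#' either marginal deviation is 0), energy `e = sum c(i,j)^2`, and local
#' homogeneity `HL = sum c(i,j) / (1 + |i-j|)`.
#'
#' @param g A [glcm()].
#' @return One-row tibble with `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
second_order <- function(g) {
  stopifnot(inherits(g, "glcm"))
  L <- g$levels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  cm <- sum((i - j)^2 * g$c)
  e <- sum(g$c^2)
  hl <- sum(g$c / (1 + abs(i - j)))
  r <- if (g$sd_i < 1e-12 || g$sd_j < 1e-12) 0 else
    sum((i - g$mu_i) * (j - g$mu_j) * g$c) / (g$sd_i * g$sd_j)
  tibble(contrast = cm, correlation = r, energy = e, homogeneity = hl)
}

#' Left-right relation (asymmetry) features
#'
#' For each paired base feature value `(Vl, Vr)` computes the three
#' bilateral asymmetry measures: Euclidean distance
#' `ED = sqrt((Vr - Vl)^2)`, Bhattacharyya-style distance
#' `BD = sqrt(|Vr * Vl|)` (the absolute value keeps BD real for
#' sign-indefinite features such as correlation), and absolute difference
#' `D = |Vr - Vl|`.  For scalars ED and D coincide algebraically; both are
#' emitted to honour the standard 3-distances-per-pair layout.
#'
#' @param Vl,Vr Numeric vectors of equal length (left / right values).
#' @return Tibble with columns `feature` (names or index), `ED`, `BD`,
#'   `D`.
#' @export
relation_features <- function(Vl, Vr) {
  if (length(Vl) != length(Vr))
    abort("Pairing error: `Vl` and `Vr` must have the same length.")
  nm <- names(Vl)
  if (is.null(nm)) nm <- as.character(seq_along(Vl))
  Vl <- unname(Vl); Vr <- unname(Vr)
  tibble(feature = nm,
         ED = sqrt((Vr - Vl)^2),
         BD = sqrt(abs(Vr * Vl)),
         D = abs(Vr - Vl))
}

# Base per-side feature vector (31 values): 4 shape + 15 first-order +
# 12 second-order, in documented order.
side_feature_vector <- function(img, mask, levels, offsets) {
  sh <- shape_features(mask)
  out <- c(A = sh$A, P = sh$P, R = sh$R, C = sh$C)
  for (ch in c("R", "G", "B")) {
    fo <- first_order(img, mask, ch)
    v <- c(fo$mu, fo$median, fo$var, fo$sd, fo$entropy)
    names(v) <- paste0(c("mu", "median", "var", "sd", "entropy"), "_", ch)
    out <- c(out, v)
  }
  for (ch in c("R", "G", "B")) {
    so <- second_order(glcm(img, mask, ch, levels, offsets))
    v <- c(so$contrast, so$correlation, so$energy, so$homogeneity)
    names(v) <- paste0(c("contrast", "correlation", "energy", "homogeneity"),
                       "_", ch)
    out <- c(out, v)
  }
  out
}

#' Extract the 155-dimension feature vector of a thermogram
#'
#' Computes, for each breast region, 4 shape descriptors, 5 first-order
#' statistics per colour channel (15) and 4 co-occurrence statistics per
#' channel (12) - 31 per side, 62 bilateral values - plus the 3 relation
#' (asymmetry) distances for each of the 31 base pairs (93), for a total
#' of 8 + 30 + 24 + 93 = 155 named features.
#'
#' Column order: shape block (`A`, `P`, `R`, `C`, each `_left` then
#' `_right`), first-order block (stat x channel, `_left`/`_right`),
#' second-order block likewise, then the relation block
#' (`rel_ED_*`, `rel_BD_*`, `rel_D_*` for each base feature in side
#' order).
#'
#' @param img H x W x 3 RGB array, or a `phantom_sample` (whose truth
#'   masks are then the default regions), or a `thermo_segmentation`.
#' @param left_mask,right_mask 0/1 breast masks (required when `img` is a
#'   plain array).
#' @param levels,offsets GLCM quantization and offset settings, see
#'   [glcm()].
#' @param id Optional image identifier column.
#' @param label Optional class label column (`"normal"`/`"abnormal"`).
#' @return A one-row tibble: `id` and `label` (if given) plus 155 numeric
#'   feature columns.
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(noise_sd = 0))
#' fv <- extract_features(ph)
#' ncol(fv) - 2L  # 155 feature columns
extract_features <- function(img, left_mask = NULL, right_mask = NULL,
                             levels = 8L, offsets = c(1, 0),
                             id = NULL, label = NULL) {
  if (inherits(img, "phantom_sample")) {
    if (is.null(left_mask)) left_mask <- img$left_mask
    if (is.null(right_mask)) right_mask <- img$right_mask
    if (is.null(label)) label <- img$label
    img <- img$image
  } else if (inherits(img, "thermo_segmentation")) {
    abort("Pass the RGB image plus the segmentation masks separately.")
  }
  if (is.null(left_mask) || is.null(right_mask))
    abort("Assembly error: missing block `left_mask`/`right_mask`.")
  check_rgb(img)
  vl <- side_feature_vector(img, left_mask, levels, offsets)
  vr <- side_feature_vector(img, right_mask, levels, offsets)
  rel <- relation_features(vl, vr)

  sided <- setNames(
    as.numeric(rbind(vl, vr)),
    as.vector(rbind(paste0(names(vl), "_left"), paste0(names(vr), "_right"))))
  relv <- setNames(
    as.numeric(t(as.matrix(rel[, c("ED", "BD", "D")]))),
    as.vector(vapply(rel$feature,
                     function(f) paste0("rel_", c("ED", "BD", "D"), "_", f),
                     character(3))))
  row <- as_tibble(as.list(c(sided, relv)))
  if (!is.null(label)) row <- dplyr::bind_cols(tibble(label = label), row)
  if (!is.null(id)) row <- dplyr::bind_cols(tibble(id = id), row)
  row
}

#' Feature names of the 155-dimension vector
#'
#' @param levels Unused; present for forward compatibility.
#' @return Character vector of length 155 in extraction order.
#' @export
feature_names <- function(levels = 8L) {
  base <- c("A", "P", "R", "C",
            paste0(rep(c("mu", "median", "var", "sd", "entropy"), 3), "_",
                   rep(c("R", "G", "B"), each = 5)),
            paste0(rep(c("contrast", "correlation", "energy", "homogeneity"), 3),
                   "_", rep(c("R", "G", "B"), each = 4)))
  c(as.vector(rbind(paste0(base, "_left"), paste0(base, "_right"))),
    as.vector(vapply(base, function(f) paste0("rel_", c("ED", "BD", "D"), "_", f),
                     character(3))))
}

#' Extract features for a whole phantom dataset
#'
#' Maps [extract_features()] over the samples of a [make_dataset()]
#' manifest, using either the ground-truth masks (`masks = "truth"`) or
#' running the full segmentation pipeline first (`masks = "segmented"`).
#'
#' @param dataset Tibble from [make_dataset()].
#' @param masks `"truth"` or `"segmented"`.
#' @param params [gvf_params()] used when `masks = "segmented"`.
#' @param ... Passed to [extract_features()].
#' @return Tibble with one row per sample: `id`, `label`, 155 features.
#' @export
dataset_features <- function(dataset, masks = c("truth", "segmented"),
                             params = gvf_params(), ...) {
  masks <- match.arg(masks)
  rows <- purrr::pmap(list(dataset$sample, dataset$id, dataset$label),
                      function(s, id, lab) {
    if (masks == "truth") {
      extract_features(s$image, s$left_mask, s$right_mask,
                       id = id, label = lab, ...)
    } else {
      seg <- segment_breasts(s$image, params)
      extract_features(s$image, seg$left_mask, seg$right_mask,
                       id = id, label = lab, ...)
    }
  })
  dplyr::bind_rows(rows)
}
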