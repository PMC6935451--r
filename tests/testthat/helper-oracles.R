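# Fixture builders and independent oracles used across the suite.

# Digitized filled disk mask (0-based center coordinates).
make_disk <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) + 0L
}

# Digitized filled (axis-aligned) ellipse mask.
make_ellipse_mask <- function(h, w, cx, cy, a, b) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  (((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1) + 0L
}

# Closed curve sampling of an axis-aligned ellipse, counter-clockwise on
# screen (y down): x = cx + a cos t, y = cy - b sin t.
sample_ellipse_curve <- function(cx, cy, a, b, n) {
  t <- 2 * pi * (0:(n - 1)) / n
  cbind(x = cx + a * cos(t), y = cy - b * sin(t))
}

# Independent GVF oracle: direct sparse solve of the Euler-Lagrange
# equations mu * L u - b (u - fx) = 0 with the same Neumann (replicate)
# Laplacian the iteration uses.  Requires Matrix.
gvf_direct_solve <- function(em, mu) {
  em <- thermoseg:::normalize_edge_map(em)
  h <- nrow(em$f); w <- ncol(em$f)
  n <- h * w
  idx <- function(r, c) (c - 1L) * h + r
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  deg <- matrix(0L, h, w)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- pmin(pmax(row(em$f) + d[1], 1L), h)
    c2 <- pmin(pmax(col(em$f) + d[2], 1L), w)
    inside <- !(r2 == row(em$f) & c2 == col(em$f))
    ii <- c(ii, idx(row(em$f)[inside], col(em$f)[inside]))
    jj <- c(jj, idx(r2[inside], c2[inside]))
    xx <- c(xx, rep(mu, sum(inside)))
    deg <- deg + inside
  }
  b <- em$fx^2 + em$fy^2
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n)) +
    Matrix::Diagonal(n, x = -(mu * as.vector(deg) + as.vector(b)))
  u <- as.vector(Matrix::solve(A, -as.vector(b * em$fx)))
  v <- as.vector(Matrix::solve(A, -as.vector(b * em$fy)))
  list(u = matrix(u, h, w), v = matrix(v, h, w))
}

# Brute-force even-odd point-in-polygon (ray casting) at one point.
point_in_polygon <- function(px, py, pts) {
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  crossing <- 0L
  on_edge <- FALSE
  for (e in seq_len(n)) {
    vx <- x2[e] - x1[e]; vy <- y2[e] - y1[e]
    len2 <- vx^2 + vy^2
    t <- if (len2 < 1e-18) 0 else
      min(max(((px - x1[e]) * vx + (py - y1[e]) * vy) / len2, 0), 1)
    if ((px - (x1[e] + t * vx))^2 + (py - (y1[e] + t * vy))^2 <= 1e-18)
      on_edge <- TRUE
    ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
    if (py >= ylo - 1e-9 && py < yhi - 1e-9 && yhi > ylo) {
      xi <- x1[e] + (py - y1[e]) * vx / vy
      if (px < xi - 1e-9) crossing <- crossing + 1L
    }
  }
  on_edge || (crossing %% 2L == 1L)
}

# Exhaustive GLCM pair-count oracle (symmetrized, normalized).
glcm_bruteforce <- function(q, mask, levels, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    r2 <- r + dy; c2 <- c + dx
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
        mask[r, c] == 1L && mask[r2, c2] == 1L) {
      i <- q[r, c] + 1L; j <- q[r2, c2] + 1L
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

# Build a glcm object from a raw normalized matrix (for formula checks).
glcm_from_matrix <- function(cmat) {
  L <- nrow(cmat)
  i <- seq_len(L)
  mu_i <- sum(i * rowSums(cmat)); mu_j <- sum(i * colSums(cmat))
  structure(list(c = cmat, levels = L, offsets = list(c(1, 0)),
                 mu_i = mu_i, mu_j = mu_j,
                 sd_i = sqrt(sum((i - mu_i)^2 * rowSums(cmat))),
                 sd_j = sqrt(sum((i - mu_j)^2 * colSums(cmat)))),
            class = "glcm")
}

# Small standard phantom used by several suites.
test_phantom <- function(seed = 1, hotspot = FALSE, noise_sd = 0.01) {
  render_phantom(phantom_spec(seed = seed, hotspot = hotspot,
                              noise_sd = noise_sd))
}

# Segmented-image tibble for the CNN from a make_dataset() manifest.
cnn_image_data <- function(ds, mask_fun) {
  tibble::tibble(
    label = ds$label,
    image = purrr::map(seq_len(nrow(ds)), function(i) mask_fun(ds$sample[[i]])))
}
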