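# Small configurable convolutional network for segmented-image
# classification: one valid convolution layer (leaky ReLU), one
# subsampling pooling layer (max by default, average selectable; pool = 0
# pools globally), an optional hidden fully-connected layer and a sigmoid
# output unit, trained full-batch with Adam on the binary cross-entropy.
# Written in plain R; the architecture is config-driven (filters, kernel,
# pool, hidden, input side) and makes no claim of reproducing any
# particular trained network.

#' Resize an RGB image to a square side
#'
#' Bilinear resize (via EBImage) used to standardize segmented images
#' before feeding the convolutional classifier.
#'
#' @param img H x W x 3 array in `[0, 1]`.
#' @param side Output side length in pixels.
#' @return side x side x 3 array.
#' @export
resize_rgb <- function(img, side) {
  check_rgb(img)
  im <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(im, w = side, h = side)
  clamp(aperm(EBImage::imageData(out), c(2, 1, 3)), 0, 1)
}

# Patches matrix (n_loc x k*k*3) of a side x side x 3 image, valid
# convolution, column-major location order.
im2col_rgb <- function(img, k) {
  s <- dim(img)[1]
  g <- s - k + 1L
  cols <- vector("list", k * k * 3L)
  idx <- 1L
  for (ch in 1:3) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    cols[[idx]] <- as.vector(img[(1L + dy):(g + dy), (1L + dx):(g + dx), ch])
    idx <- idx + 1L
  }
  do.call(cbind, cols)
}

# Average-pooling block assignment for a g x g grid with pool p
# (complete blocks only).  Returns list(ids = per-location block id or NA,
# Q = block count, counts = per-block sizes).
pool_map <- function(g, p) {
  if (p <= 0L || p >= g) p <- g   # global pooling
  nb <- g %/% p
  if (nb < 1L) abort("Pooling removes the whole feature map; reduce `pool`.")
  rid <- rep(seq_len(g), times = g)   # row index per location (col-major)
  cid <- rep(seq_len(g), each = g)
  br <- (rid - 1L) %/% p + 1L; bc <- (cid - 1L) %/% p + 1L
  ids <- ifelse(br <= nb & bc <= nb, (bc - 1L) * nb + br, NA_integer_)
  list(ids = ids, Q = nb * nb, counts = tabulate(ids, nb * nb))
}

cnn_init <- function(hp, n_in) {
  F <- hp$filters; k <- hp$kernel
  g <- hp$side - k + 1L
  pm <- pool_map(g, hp$pool)
  nf1 <- k * k * 3L
  nq <- pm$Q * F
  nh <- if (hp$hidden > 0L) hp$hidden else nq
  w <- list(W1 = matrix(rnorm(nf1 * F, 0, sqrt(2 / nf1)), nf1, F),
            b1 = numeric(F), pm = pm)
  if (hp$hidden > 0L) {
    w$W2 <- matrix(rnorm(nq * hp$hidden, 0, sqrt(2 / nq)), nq, hp$hidden)
    w$b2 <- numeric(hp$hidden)
    w$W3 <- matrix(rnorm(hp$hidden, 0, sqrt(2 / hp$hidden)), hp$hidden, 1)
    w$b3 <- 0
  } else {
    w$W3 <- matrix(rnorm(nq, 0, sqrt(2 / nq)), nq, 1)
    w$b3 <- 0
  }
  w
}

leaky <- 0.1  # leaky-ReLU slope: keeps gradient alive in weak-signal filters

cnn_forward <- function(w, P, pool_type = "max") {
  Z1 <- sweep(P %*% w$W1, 2, w$b1, "+")
  A1 <- pmax(Z1, 0) + leaky * pmin(Z1, 0)
  ok <- which(!is.na(w$pm$ids))
  ids <- w$pm$ids[ok]
  if (pool_type == "max") {
    # per-block, per-filter max with argmax locations for backprop
    nF <- ncol(A1)
    pooled <- matrix(-Inf, w$pm$Q, nF)
    amax <- matrix(0L, w$pm$Q, nF)
    for (f in seq_len(nF)) {
      o <- order(ids, A1[ok, f])
      last <- o[cumsum(w$pm$counts)]   # index (within ok-order) of block max
      pooled[, f] <- A1[ok, f][last]
      amax[, f] <- ok[last]
    }
  } else {
    pooled <- rowsum(A1[ok, , drop = FALSE], ids) / w$pm$counts
    amax <- NULL
  }
  q <- as.vector(pooled)
  if (!is.null(w$W2)) {
    z2 <- as.vector(crossprod(w$W2, q)) + w$b2
    a2 <- pmax(z2, 0) + leaky * pmin(z2, 0)
  } else {
    z2 <- NULL
    a2 <- q
  }
  z3 <- sum(w$W3 * a2) + w$b3
  list(Z1 = Z1, A1 = A1, q = q, z2 = z2, a2 = a2, amax = amax,
       p = 1 / (1 + exp(-z3)))
}

# Full-batch Adam on the binary cross-entropy.
cnn_train <- function(patches, y, hp, seed) {
  with_seed(seed, {
    w <- cnn_init(hp, ncol(patches[[1]]))
    wn <- intersect(c("W1", "b1", "W2", "b2", "W3", "b3"), names(w))
    m1 <- lapply(w[wn], function(x) x * 0)
    m2 <- m1
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- length(patches)
    for (ep in seq_len(hp$epochs)) {
      gr <- lapply(w[wn], function(x) x * 0)
      for (i in seq_len(n)) {
        P <- patches[[i]]
        fw <- cnn_forward(w, P, hp$pool_type)
        dz3 <- fw$p - y[i]
        gr$W3 <- gr$W3 + fw$a2 * dz3
        gr$b3 <- gr$b3 + dz3
        if (!is.null(w$W2)) {
          dz2 <- as.vector(w$W3) * dz3 * ifelse(fw$z2 > 0, 1, leaky)
          gr$W2 <- gr$W2 + outer(fw$q, dz2)
          gr$b2 <- gr$b2 + dz2
          dq <- as.vector(w$W2 %*% dz2)
        } else {
          dq <- as.vector(w$W3) * dz3
        }
        dpool <- matrix(dq, w$pm$Q, hp$filters)
        dA1 <- matrix(0, nrow(P), hp$filters)
        if (identical(hp$pool_type, "avg")) {
          ok <- !is.na(w$pm$ids)
          dA1[ok, ] <- dpool[w$pm$ids[ok], , drop = FALSE] /
            w$pm$counts[w$pm$ids[ok]]
        } else {
          for (f in seq_len(hp$filters))
            dA1[fw$amax[, f], f] <- dA1[fw$amax[, f], f] + dpool[, f]
        }
        dZ1 <- dA1 * ifelse(fw$Z1 > 0, 1, leaky)
        gr$W1 <- gr$W1 + crossprod(P, dZ1)
        gr$b1 <- gr$b1 + colSums(dZ1)
      }
      for (nm in names(gr)) {
        g <- gr[[nm]] / n
        m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
        m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g^2
        mh <- m1[[nm]] / (1 - b1^ep)
        vh <- m2[[nm]] / (1 - b2^ep)
        w[[nm]] <- w[[nm]] - hp$lr * mh / (sqrt(vh) + eps)
      }
    }
    w
  })
}

train_predict_cnn <- function(spec, train, test) {
  hp <- spec$hyper
  if (!"image" %in% names(train))
    abort("CNN training needs an `image` list-column of RGB arrays.")
  prep <- function(d) lapply(d$image, function(im)
    im2col_rgb(resize_rgb(im, hp$side) - 0.5, hp$kernel))
  ptr <- prep(train)
  y <- as.numeric(as.character(train$label) == "normal")
  w <- cnn_train(ptr, y, hp, spec$seed)
  if (nrow(test) == 0L)
    return(structure(factor(character(), levels = label_levels),
                     scores = numeric()))
  pte <- prep(test)
  scores <- vapply(pte, function(P) cnn_forward(w, P, hp$pool_type)$p, numeric(1))
  structure(factor(ifelse(scores >= 0.5, "normal", "abnormal"),
                   levels = label_levels),
            scores = scores)
}
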