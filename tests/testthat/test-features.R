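test_that("shape descriptors match analytic oracles", {
  # perfect circle, analytic area/perimeter: R exactly 1
  r <- 12.7
  expect_equal(roundness(pi * r^2, 2 * pi * r), 1)
  expect_equal(compactness(pi * r^2, 2 * pi * r), 1 / (4 * pi))
  expect_equal(compactness(10, 5, squared = FALSE), 2)

  # 10x10 filled square: area by pixel count
  sq <- matrix(0L, 20, 20); sq[5:14, 5:14] <- 1L
  expect_equal(shape_features(sq)$A, 100)

  # 20x5 rectangle: R = 4*pi*100/50^2 within 5% with the traced perimeter
  rect <- matrix(0L, 30, 40); rect[10:14, 10:29] <- 1L
  sf <- shape_features(rect)
  expect_lt(abs(sf$R - 4 * pi * 100 / 50^2), 0.05 * 4 * pi * 100 / 50^2)
  expect_equal(sf$C, sf$R / (4 * pi), tolerance = 1e-12)

  expect_error(shape_features(matrix(0L, 5, 5)), "Empty region")
})

test_that("digitized circles approach roundness 1 as radius grows", {
  rs <- c(20, 50, 100)
  R <- vapply(rs, function(r) {
    side <- 2 * r + 21
    shape_features(make_disk(side, side, r + 10, r + 10, r))$R
  }, numeric(1))
  expect_true(all(diff(abs(R - 1)) < 0))   # monotone approach
  expect_gt(R[3], 0.98)
})

test_that("first-order statistics match hand-computed moments", {
  mk <- function(vals) {
    n <- length(vals)
    img <- array(0, c(1, n, 3))
    img[1, , 1] <- vals; img[1, , 2] <- vals; img[1, , 3] <- vals
    list(img = img, mask = matrix(1L, 1, n))
  }
  f <- mk(rep(0.3, 10))
  fo <- first_order(f$img, f$mask, "R")
  expect_equal(fo$mu, 0.3)
  expect_equal(fo$var, 0); expect_equal(fo$sd, 0); expect_equal(fo$entropy, 0)

  f <- mk(rep(c(0, 1), 8))
  fo <- first_order(f$img, f$mask, "G")
  expect_equal(fo$mu, 0.5)
  expect_equal(fo$entropy, 1)            # 1 bit, two equiprobable values

  f <- mk(c(0.1, 0.2, 0.3, 0.4))
  fo <- first_order(f$img, f$mask, "B")
  expect_equal(fo$mu, 0.25)
  expect_equal(fo$var, 0.0125)           # population variance
  expect_equal(fo$sd, sqrt(0.0125))
  expect_equal(fo$median, 0.25)

  expect_error(first_order(f$img, matrix(0L, 1, 4), "R"), "Empty region")
})

test_that("entropy responds to histogram shape, not channel identity", {
  vals <- c(rep(0.2, 8), rep(0.7, 8))
  img <- array(rep(vals, 3), c(1, 16, 3))
  m <- matrix(1L, 1, 16)
  s <- vapply(c("R", "G", "B"),
              function(ch) first_order(img, m, ch)$entropy, numeric(1))
  expect_equal(unname(s), rep(s[[1]], 3))
  # flattening the histogram increases entropy
  flat <- array(rep(seq(0.05, 0.95, length.out = 16), 3), c(1, 16, 3))
  expect_gt(first_order(flat, m, "R")$entropy, s[[1]])
})

test_that("glcm matches exhaustive pair counting", {
  # constant region: a single entry equal to 1
  img <- array(0.55, c(6, 6, 3))
  g <- glcm(img, matrix(1L, 6, 6), "R", levels = 8)
  expect_equal(sum(g$c), 1)
  expect_equal(sum(g$c > 0), 1)
  expect_equal(max(g$c), 1)

  # perfect vertical stripes alternating bins 0/1, offset (1,0)
  stripes <- array(0, c(6, 6, 3))
  stripes[, seq(2, 6, 2), ] <- 0.9    # bins 0 / 7 at 8 levels... use 2 levels
  g <- glcm(stripes, matrix(1L, 6, 6), "R", levels = 2, offsets = c(1, 0))
  expect_equal(g$c[1, 2], 0.5)
  expect_equal(g$c[2, 1], 0.5)
  expect_equal(g$c[1, 1] + g$c[2, 2], 0)

  # 4x4 toy block, 4 levels: exhaustive enumeration oracle
  vals <- matrix(c(0, 1, 2, 3,
                   1, 1, 2, 2,
                   0, 0, 3, 3,
                   2, 1, 0, 3) / 4 + 0.01, 4, 4, byrow = TRUE)
  img <- array(rep(vals, 3), c(4, 4, 3))
  mask <- matrix(1L, 4, 4); mask[1, 4] <- 0L
  q <- matrix(pmin(floor(img[, , 1] * 4), 3), 4, 4)
  for (off in list(c(1, 0), c(0, 1), c(1, 1))) {
    g <- glcm(img, mask, "R", levels = 4, offsets = off)
    expect_equal(g$c, glcm_bruteforce(q, mask, 4, off[1], off[2]),
                 tolerance = 1e-12)
  }

  # symmetry and normalization invariants on a phantom region
  ph <- test_phantom(seed = 4, hotspot = TRUE)
  g <- glcm(ph$image, ph$left_mask, "G", levels = 8, offsets = "all4")
  expect_equal(sum(g$c), 1, tolerance = 1e-9)
  expect_equal(g$c, t(g$c), tolerance = 1e-12)
  expect_true(all(g$c >= 0))

  expect_error(glcm(img, matrix(0L, 4, 4), "R"), "Degenerate GLCM|no valid")
  single <- matrix(0L, 4, 4); single[2, 2] <- 1L
  expect_error(glcm(img, single, "R", offsets = c(1, 0)), "Degenerate GLCM")
})

test_that("second-order statistics evaluate the standard formulas", {
  # constant region -> single diagonal entry
  cm <- matrix(0, 4, 4); cm[2, 2] <- 1
  so <- second_order(glcm_from_matrix(cm))
  expect_equal(so$contrast, 0)
  expect_equal(so$energy, 1)
  expect_equal(so$homogeneity, 1)
  expect_equal(so$correlation, 0)       # degenerate marginals -> 0 by contract

  # uniform diagonal: CM = 0, e = 1/L, r = 1
  L <- 4
  so <- second_order(glcm_from_matrix(diag(L) / L))
  expect_equal(so$contrast, 0)
  expect_equal(so$energy, 1 / L)
  expect_equal(so$correlation, 1)

  # hand-evaluated 2x2 quarter matrix
  so <- second_order(glcm_from_matrix(matrix(0.25, 2, 2)))
  expect_equal(so$contrast, 0.5)
  expect_equal(so$energy, 0.25)
  expect_equal(so$homogeneity, 0.75)
  expect_equal(so$correlation, 0)

  # energy/homogeneity are 1 only for constant regions; contrast = 0 iff
  # all mass is diagonal
  off_diag <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  so <- second_order(glcm_from_matrix(off_diag))
  expect_lt(so$energy, 1); expect_lt(so$homogeneity, 1)
  expect_gt(so$contrast, 0)
})

test_that("relation features follow the three distance formulas", {
  r <- relation_features(c(a = 1, b = 2), c(a = 1, b = 2))
  expect_equal(r$ED, c(0, 0))
  expect_equal(r$D, c(0, 0))

  r <- relation_features(1, 3)
  expect_equal(r$ED, 2); expect_equal(r$D, 2)
  expect_equal(r$BD, sqrt(3))

  expect_equal(relation_features(0, 0)$BD, 0)
  # sign-indefinite inputs stay real through |Vr * Vl|
  expect_equal(relation_features(-0.5, 0.5)$BD, 0.5)
  expect_error(relation_features(1:3, 1:2), "Pairing error")
})

test_that("the assembled vector has the documented 155-feature layout", {
  ph <- test_phantom(seed = 8, hotspot = TRUE)
  fv <- extract_features(ph, id = "p1")
  feats <- setdiff(names(fv), c("id", "label"))
  expect_length(feats, 155)
  expect_equal(feats, feature_names())

  # block counts: 8 shape + 30 first-order + 24 second-order + 93 relation
  shape_n <- sum(grepl("^(A|P|R|C)_(left|right)$", feats))
  fo_n <- sum(grepl("^(mu|median|var|sd|entropy)_[RGB]_(left|right)$", feats))
  so_n <- sum(grepl("^(contrast|correlation|energy|homogeneity)_[RGB]_(left|right)$",
                    feats))
  rel_n <- sum(grepl("^rel_", feats))
  expect_equal(c(shape_n, fo_n, so_n, rel_n), c(8, 30, 24, 93))
  expect_equal(shape_n + fo_n + so_n + rel_n, 155)
  expect_equal(3 * (4 + 15 + 12), 93)

  expect_error(extract_features(ph$image), "missing block")
})

test_that("identical sides zero all asymmetry features", {
  # mirror-symmetric scene: same mask geometry and values on both halves
  img <- array(0.2, c(40, 80, 3))
  lm <- make_disk(40, 80, 20, 20, 9)
  rm_ <- make_disk(40, 80, 60, 20, 9)
  img[, , 1][lm == 1L | rm_ == 1L] <- 0.6
  img[, , 2][lm == 1L | rm_ == 1L] <- 0.35
  fv <- extract_features(img, lm, rm_)
  rel_ed <- as.numeric(fv[grepl("^rel_ED_", names(fv))])
  rel_d <- as.numeric(fv[grepl("^rel_D_", names(fv))])
  expect_equal(max(abs(rel_ed)), 0, tolerance = 1e-9)
  expect_equal(max(abs(rel_d)), 0, tolerance = 1e-9)
  expect_equal(fv$A_left, fv$A_right)
  expect_equal(fv$P_left, fv$P_right, tolerance = 1e-9)
})

test_that("features are invariant to joint image/mask translation", {
  ph <- test_phantom(seed = 9)
  img <- ph$image; lm <- ph$left_mask; rm_ <- ph$right_mask
  f0 <- extract_features(img, lm, rm_)
  sh <- function(m, dy, dx) {
    out <- m * 0
    h <- nrow(m); w <- ncol(m)
    out[(1 + dy):h, (1 + dx):w] <- m[1:(h - dy), 1:(w - dx)]
    out
  }
  img2 <- array(0, dim(img))
  for (ch in 1:3) img2[, , ch] <- sh(img[, , ch], 3, 2)
  f1 <- extract_features(img2, sh(lm, 3, 2), sh(rm_, 3, 2))
  expect_equal(as.numeric(f1), as.numeric(f0), tolerance = 1e-9)
})
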