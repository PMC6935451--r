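test_that("edge_map behaves on flat and step images", {
  p <- gvf_params()
  const <- matrix(0.4, 20, 20)
  em <- edge_map(const, 2, p)
  expect_equal(max(em$f) - min(em$f), 0)      # constant f, no gradients

  # vertical step at column 10 (0-based x = 9.5): E_edge max within 1 px
  step <- cbind(matrix(0.2, 24, 10), matrix(0.8, 24, 14))
  em <- edge_map(step, 2, gvf_params(w_line = 0, w_term = 0))
  peak_col <- which.max(em$f[12, ])
  expect_lte(abs(peak_col - 10.5), 1.5)

  # linearity: doubling w_edge (others 0) doubles f pointwise
  em1 <- edge_map(step, 2, gvf_params(w_line = 0, w_edge = 0.4, w_term = 0))
  em2 <- edge_map(step, 2, gvf_params(w_line = 0, w_edge = 0.8, w_term = 0))
  expect_equal(em2$f, 2 * em1$f, tolerance = 1e-12)

  expect_error(edge_map(const, -1), "sigma")
})

test_that("gvf_field is zero on flat maps and enforces its stability bound", {
  const <- matrix(0.7, 16, 16)
  em <- edge_map(const, 2)
  fld <- gvf_field(em, 0.2, 50)
  expect_equal(max(abs(fld$u)), 0)
  expect_equal(max(abs(fld$v)), 0)

  ph <- test_phantom(seed = 1, noise_sd = 0)
  em <- edge_map(denoise(to_gray(ph$image)), 3)
  expect_error(gvf_field(em, 0.2, 10, dt = 100), "stability bound")
})

test_that("gvf iteration monotonically decreases the functional", {
  set.seed(7)
  for (rep in 1:3) {
    em <- structure(list(f = matrix(runif(256), 16, 16)), class = "edge_map")
    g <- thermoseg:::grad_xy(em$f)
    em$fx <- g$gx; em$fy <- g$gy
    energies <- vapply(c(1, 2, 5, 10, 25, 50, 100), function(n)
      gvf_energy(gvf_field(em, 0.2, n), em, 0.2), numeric(1))
    expect_true(all(diff(energies) <= 1e-9))
  }
})

test_that("gvf iteration agrees with the direct linear-system minimizer", {
  skip_if_not_installed("Matrix")
  # step-edge toy on a 32 x 32 grid
  gray <- cbind(matrix(0.2, 32, 14), matrix(0.9, 32, 18))
  em <- edge_map(gray, 1.5, gvf_params(w_line = 0, w_term = 0))
  direct <- gvf_direct_solve(em, mu = 0.2)
  iter <- gvf_field(em, 0.2, 5000)
  emn <- thermoseg:::normalize_edge_map(em)
  strong <- (emn$fx^2 + emn$fy^2) > 0.25 * max(emn$fx^2 + emn$fy^2)
  expect_gt(sum(strong), 10)
  # converged iteration matches the direct minimizer at strong edges
  expect_lt(max(abs(iter$u[strong] - direct$u[strong])), 0.02 * max(abs(emn$fx)))
  # in the data-dominated limit (mu small against |grad f|^2) the field
  # reduces to grad f at the edge, within 5%
  lim <- gvf_field(em, 0.002, 20000)
  expect_lt(max(abs(lim$u[strong] - emn$fx[strong])), 0.05 * max(abs(emn$fx)))
})

test_that("snake statics: no force means no motion, tension shrinks", {
  zero_field <- structure(list(u = matrix(0, 60, 60), v = matrix(0, 60, 60)),
                          class = "gvf_field")
  init <- contract_to_snake(
    thermoseg:::new_ellipse_init(c(30, 30), c(15, 10), 0, "left"), 1, 64)

  out <- evolve_snake(init, zero_field,
                      gvf_params(alpha = 0, beta = 0, iterations = 25,
                                 converge_tol = 0, resample_every = 0))
  expect_equal(unclass(out)[, 1:2], unclass(init)[, 1:2], tolerance = 1e-12)

  # alpha > 0: elastic contraction shrinks the area monotonically
  p <- gvf_params(alpha = 0.2, beta = 0, iterations = 10, converge_tol = 0,
                  resample_every = 0)
  areas <- numeric(5)
  sn <- init
  for (i in 1:5) {
    sn <- evolve_snake(sn, zero_field, p)
    areas[i] <- abs(thermoseg:::shoelace_area(unclass(sn)))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("snake collapse under pure tension raises an error", {
  zero_field <- structure(list(u = matrix(0, 40, 40), v = matrix(0, 40, 40)),
                          class = "gvf_field")
  init <- contract_to_snake(
    thermoseg:::new_ellipse_init(c(20, 20), c(6, 6), 0, "left"), 1, 32)
  expect_error(
    evolve_snake(init, zero_field,
                 gvf_params(alpha = 1, beta = 0, iterations = 5000,
                            converge_tol = 0)),
    "collapsed")
})

test_that("snake recovers a synthetic ellipse from nearby initializations", {
  h <- 100; w <- 120
  truth <- make_ellipse_mask(h, w, 60, 50, 40, 25)
  field01 <- matrix(0.1, h, w); field01[truth == 1L] <- 0.6
  gray <- to_gray(pseudo_color(field01))
  p <- gvf_params()
  em <- edge_map(gray, p$edge_sigma, p)
  fld <- gvf_field(em, p$gvf_mu, p$gvf_iterations)
  for (scale in c(0.8, 0.9, 1.0, 1.1)) {
    init <- contract_to_snake(
      thermoseg:::new_ellipse_init(c(60, 50), c(40, 25) * scale, 0, "x"),
      1.0, 200, c(h, w))
    sn <- evolve_snake(init, fld, p)
    z <- zsi(contour_to_mask(sn, c(h, w)), truth)
    expect_gt(z, if (scale == 0.9) 0.95 else 0.9)
  }
})

test_that("contour_to_mask matches the brute-force even-odd oracle", {
  # inclusive square: corners (10,10)..(20,20) -> 11 x 11 = 121 pixels
  sq <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
  m <- contour_to_mask(sq, c(30, 30))
  expect_equal(sum(m), 121)

  # full agreement with the per-pixel ray-casting oracle
  set.seed(5)
  poly <- sample_ellipse_curve(14, 11, 9.3, 6.7, 40)
  m <- contour_to_mask(poly, c(24, 30))
  oracle <- matrix(0L, 24, 30)
  for (yy in 0:23) for (xx in 0:29)
    oracle[yy + 1, xx + 1] <- point_in_polygon(xx, yy, poly) + 0L
  expect_equal(m, oracle)

  # triangle fully outside the image
  tri <- cbind(c(100, 120, 110), c(100, 100, 120))
  expect_equal(sum(contour_to_mask(tri, c(30, 30))), 0)

  # circle r = 30: area within 2% of pi r^2
  circ <- sample_ellipse_curve(40, 40, 30, 30, 360)
  expect_lt(abs(sum(contour_to_mask(circ, c(80, 80))) - pi * 900) / (pi * 900),
            0.02)

  # bow-tie raises the self-intersection warning
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_warning(contour_to_mask(bow, c(12, 12)), "Self-intersecting")
})

test_that("segmentation is deterministic for fixed inputs", {
  ph <- test_phantom(seed = 6)
  s1 <- segment_breasts(ph)
  s2 <- segment_breasts(ph)
  expect_identical(s1$left_mask, s2$left_mask)
  expect_identical(unclass(s1$snakes$right), unclass(s2$snakes$right))
})
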