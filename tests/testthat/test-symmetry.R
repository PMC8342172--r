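test_that("edge centroid matches point masses and closed forms", {
  m <- matrix(0, 12, 12)
  m[6, 4] <- 0.7                      # (x, y) = (3, 5)
  expect_equal(edge_centroid(m), c(x = 3, y = 5))
  m2 <- matrix(0, 12, 12)
  m2[1, 1] <- 0.3; m2[1, 11] <- 0.3   # (0,0) and (10,0)
  expect_equal(edge_centroid(m2), c(x = 5, y = 0))
  u <- matrix(1, 9, 13)
  expect_equal(edge_centroid(u), c(x = 6, y = 4))  # ((w-1)/2, (h-1)/2)
  expect_error(edge_centroid(matrix(0, 5, 5)), "mass")
})

test_that("edge centroid is translation equivariant", {
  set.seed(12)
  base <- matrix(0, 40, 40)
  base[10:20, 8:18] <- runif(121)
  c0 <- edge_centroid(base)
  for (sh in list(c(3, 5), c(7, 2))) {
    shifted <- matrix(0, 40, 40)
    shifted[10:20 + sh[2], 8:18 + sh[1]] <- base[10:20, 8:18]
    expect_equal(edge_centroid(shifted), c0 + c(x = sh[1], y = sh[2]),
                 tolerance = 1e-12)
  }
})

test_that("Harris response separates flat regions, edges and corners", {
  expect_lt(max(abs(harris_response(matrix(0.5, 32, 32)))), 1e-12)
  # bright square: maximal response near a true corner
  img <- matrix(0, 64, 64)
  img[9:41, 9:41] <- 1                # corners at (8,8), (40,8), (8,40), (40,40)
  r <- harris_response(img)
  idx <- which(r == max(r), arr.ind = TRUE)[1, ]
  px <- idx[2] - 1; py <- idx[1] - 1
  corners <- rbind(c(8, 8), c(40, 8), c(8, 40), c(40, 40))
  expect_lte(min(sqrt((corners[, 1] - px)^2 + (corners[, 2] - py)^2)), 2)
  # a straight vertical step is an edge, not a corner
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  rs <- harris_response(step)
  expect_true(all(rs[10:54, 30:34] <= 1e-12))
})

test_that("tip detection averages surviving candidates", {
  resp <- matrix(0, 128, 128)
  p <- harris_params(search_halfwidth = 40)
  resp[91, 41] <- 1                   # (x, y) = (40, 90)
  expect_equal(detect_tip(resp, resp, p), c(x = 40, y = 90))
  resp[93, 45] <- 1                   # add (44, 92)
  expect_equal(detect_tip(resp, resp, p), c(x = 42, y = 91))
  expect_error(detect_tip(resp, matrix(0, 128, 128), p), "candidate")
})

test_that("axis construction follows the two-point line formulas", {
  ax <- axis_from_points(c(0, 0), c(0, 10), c(11, 11))
  expect_equal(c(ax$A, ax$B, ax$C), c(-10, 0, 0))
  ax2 <- axis_from_points(c(0, 0), c(10, 10), c(11, 11))
  expect_equal(ax2$midpoint, c(x = 5, y = 5))
  # both defining points satisfy the line equation
  for (a in list(ax, ax2)) {
    expect_lt(abs(a$A * a$centroid[1] + a$B * a$centroid[2] + a$C), 1e-6)
    expect_lt(abs(a$A * a$tip[1] + a$B * a$tip[2] + a$C), 1e-6)
  }
  expect_error(axis_from_points(c(1, 1), c(1, 1), c(11, 11)), "coincide")
  expect_error(axis_from_coefficients(0, 0, 1, c(11, 11)), "zero")
})

test_that("reflection matrix is an involutive isometry fixing the axis", {
  shape <- c(64, 64)
  axes <- list(
    axis_from_coefficients(1, 0, -20.5, shape),   # vertical x = 20.5
    axis_from_coefficients(0, 1, -12, shape),     # horizontal y = 12
    axis_from_points(c(5, 3), c(50, 60), shape))  # oblique
  for (ax in axes) {
    m <- reflection_matrix(ax)
    expect_equal(m$M %*% m$M, diag(3), tolerance = 1e-9)
    # axis points are fixed
    t <- seq(0, 1, by = 0.25)
    pts <- cbind(ax$centroid[1] + t * (ax$tip[1] - ax$centroid[1]),
                 ax$centroid[2] + t * (ax$tip[2] - ax$centroid[2]))
    expect_equal(reflect_point(m, pts), pts, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # isometry: pairwise distances preserved
    set.seed(5)
    q <- matrix(runif(10, 0, 63), 5, 2)
    qr <- reflect_point(m, q)
    expect_equal(as.numeric(dist(q)), as.numeric(dist(qr)),
                 tolerance = 1e-9)
  }
  # vertical axis closed form: (x, y) -> (2c - x, y)
  m <- reflection_matrix(axis_from_coefficients(1, 0, -20, c(64, 64)))
  expect_equal(reflect_point(m, c(5, 9)), c(x = 35, y = 9), tolerance = 1e-12)
  mh <- reflection_matrix(axis_from_coefficients(0, 1, -10, c(64, 64)))
  expect_equal(reflect_point(mh, c(5, 3)), c(x = 5, y = 17), tolerance = 1e-12)
})

test_that("field reflection is exact for symmetric fields and involutive", {
  fx <- sym_fixture()
  r1 <- reflect_field(fx$phi, fx$m)
  expect_lt(max(abs(r1 - fx$phi)), 1e-3)
  # oblique axis: double reflection returns the original
  ax <- axis_from_points(c(20, 0), c(45, 63), c(64, 64))
  m <- reflection_matrix(ax)
  set.seed(8)
  f <- gaussian_smooth(matrix(runif(64 * 64), 64, 64), 2)
  f2 <- reflect_field(reflect_field(f, m), m)
  interior <- f2[16:48, 16:48] - f[16:48, 16:48]
  # bilinear resampling error scales with the field curvature
  expect_lt(max(abs(interior)), 1e-2)
  # impulse mass moves to the mirrored pixel (axis x = 30, integer mirror)
  mv <- reflection_matrix(axis_from_coefficients(1, 0, -30, c(64, 64)))
  imp <- matrix(0, 64, 64); imp[21, 41] <- 1      # (x, y) = (40, 20)
  ref <- reflect_field(imp, mv)
  expect_equal(ref[21, 21], 1)                     # recovered at (20, 20)
  expect_equal(sum(ref), 1)
})

test_that("symmetry energy is zero for symmetric fields and grows with asymmetry", {
  fx <- notched_fixture()
  n <- prod(fx$shape)
  e_sym <- sct_energy(fx$phi, fx$g, fx$m)
  e_notch <- sct_energy(fx$phi_notched, fx$g, fx$m)
  expect_lt(e_sym, 1e-6 * n)
  expect_gt(e_notch, e_sym + 1)
  # eta scaling
  expect_equal(sct_energy(fx$phi_notched, fx$g, fx$m, eta = 3), 3 * e_notch)
  expect_identical(sct_energy(fx$phi_notched, fx$g, fx$m, eta = 0), 0)
})

test_that("mirror-correlation refinement recovers the axis despite one-sided attenuation", {
  ph <- generate_phantom(phantom_spec(seed = 5, axis_angle = 2,
                                      weak_side_attenuation = 0.2))
  ax <- detect_axis(ph$image, ph$edges)
  expect_lt(axis_angle_error(ax, ph$axis), 1)
  # without refinement the centroid displacement tilts the axis badly
  ax0 <- detect_axis(ph$image, ph$edges, refine = FALSE)
  expect_gt(axis_angle_error(ax0, ph$axis), 5)
})

test_that("tip detection lands near the apex across random phantoms", {
  suite <- phantom_suite("clean", 20, seed = 3)
  hits <- sum(vapply(suite, function(ph) {
    ax <- detect_axis(ph$image, ph$edges)
    tip_error(ax, ph) < 3
  }, logical(1)))
  expect_gte(hits, 18)
})
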