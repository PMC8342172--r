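test_that("circular SDF initialization has the right values and unit gradient", {
  phi <- init_circular_sdf(c(128, 128), c(63.5, 63.5), 20)
  expect_equal(phi[64, 64], sqrt(0.5) - 20)
  gr <- coord_grids(c(128, 128))
  rr <- sqrt((gr$x - 63.5)^2 + (gr$y - 63.5)^2)
  expect_lt(max(abs(phi - (rr - 20))), 1e-12)
  g <- field_gradient(phi)
  s <- sqrt(g$x^2 + g$y^2)
  interior <- rr >= 5 & gr$x > 0 & gr$x < 127 & gr$y > 0 & gr$y < 127
  expect_lt(max(abs(s[interior] - 1)), 0.01)
  expect_error(init_circular_sdf(c(64, 64), c(100, 10), 5), "outside")
  expect_error(init_circular_sdf(c(64, 64), c(10, 10), -1), "positive")
})

test_that("mask extraction counts pixels and honours the component filter", {
  phi <- init_circular_sdf(c(128, 128), c(63.5, 63.5), 20)
  mask <- extract_mask(phi)
  expect_equal(sum(mask), pi * 400, tolerance = 0.05)
  expect_equal(sum(extract_mask(phi + 100)), 0)
  # two blobs: largest-component filter keeps the big one
  phi2 <- pmin(phi, init_circular_sdf(c(128, 128), c(10, 10), 4))
  full <- extract_mask(phi2)
  largest <- extract_mask(phi2, largest_component = TRUE)
  expect_gt(sum(full), sum(largest))
  expect_true(all(largest[phi <= 0]))
  expect_false(any(largest[1:12, 1:12]))
})

test_that("DRLSE right-hand side respects the Dirac band and the double well", {
  phi <- init_circular_sdf(c(96, 96), c(47.5, 47.5), 18)
  g1 <- matrix(1, 96, 96)
  p0 <- evolution_params(lambda = 0, alpha = 0, mode = "drlse")
  # exact SDF: |grad| = 1 sits at the well minimum, so the regularization
  # vanishes away from the cone apex at the centre
  rhs <- drlse_rhs(phi, g1, p0)
  gr <- coord_grids(c(96, 96))
  rr <- sqrt((gr$x - 47.5)^2 + (gr$y - 47.5)^2)
  sel <- rr > 5 & gr$x %in% 5:91 & gr$y %in% 5:91
  expect_lt(max(abs(rhs[sel])), 0.01)
  # length and area contributions vanish where |phi| > epsilon
  p <- evolution_params(mode = "drlse")
  far <- abs(phi) > p$epsilon
  rhs_full <- drlse_rhs(phi, g1, p)
  expect_equal(rhs_full[far], rhs[far] * (p$mu / p0$mu), tolerance = 1e-12)
})

test_that("a negative area weight expands the interface", {
  phi <- init_circular_sdf(c(96, 96), c(47.5, 47.5), 15)
  g1 <- matrix(1, 96, 96)
  p <- evolution_params(alpha = -2, mode = "drlse")
  area0 <- sum(phi <= 0)
  for (i in 1:30) phi <- phi + p$dt * drlse_rhs(phi, g1, p)
  expect_gt(sum(phi <= 0), area0)
})

test_that("symmetry flow vanishes for symmetric states and descends the energy", {
  fx <- notched_fixture()
  sampler <- reflect_sampler(fx$m, fx$shape)
  p <- evolution_params()
  expect_lt(max(abs(sct_rhs(fx$phi, fx$g, sampler, p))), 1e-3)
  p0 <- evolution_params(eta = 0)
  expect_equal(sct_rhs(fx$phi_notched, fx$g, sampler, p0),
               matrix(0, 64, 64))
  # explicit-Euler step decreases the symmetry energy on the notched state
  e0 <- sct_energy(fx$phi_notched, fx$g, sampler = sampler)
  phi1 <- fx$phi_notched + 0.1 * sct_rhs(fx$phi_notched, fx$g, sampler, p)
  e1 <- sct_energy(phi1, fx$g, sampler = sampler)
  expect_lt(e1, e0)
})

test_that("sct mode with eta 0 reproduces drlse bit for bit and runs deterministically", {
  dk <- disk_phantom()
  g <- stop_function(dk$edges)
  phi <- init_circular_sdf(dim(g), c(63.5, 63.5), 25)
  p_sct <- evolution_params(mode = "sct", eta = 0, max_iters = 40)
  p_dr <- evolution_params(mode = "drlse", max_iters = 40)
  f1 <- levelset_evolve(phi, g, p_sct, dk$axis)
  f2 <- levelset_evolve(phi, g, p_dr)
  expect_identical(f1$phi, f2$phi)
  f3 <- levelset_evolve(phi, g, p_dr)
  expect_identical(f2$phi, f3$phi)
})

test_that("the evolution trace records strictly increasing checkpoints and energies", {
  dk <- disk_phantom()
  g <- stop_function(dk$edges)
  phi <- init_circular_sdf(dim(g), c(63.5, 63.5), 28)
  p <- evolution_params(mode = "drlse", max_iters = 60, checkpoint_every = 10)
  fit <- levelset_evolve(phi, g, p)
  expect_s3_class(fit$trace, "tbl_df")
  expect_true(all(diff(fit$trace$iteration) > 0))
  expect_equal(fit$trace$iteration[1], 0)
  expect_named(fit_summary(fit),
               c("mode", "iterations", "stop_reason", "mask_area",
                 "e_reg", "e_len", "e_area", "e_sct", "e_total"))
  expect_identical(fit_trace(fit), fit$trace)
})

test_that("distance regularization keeps a unit-slope wedge at the interface", {
  # After the front settles, the swept region keeps a plateau just below
  # -epsilon (the double well preserves flat regions) while the profile
  # through the zero level stays close to slope 1.
  dk <- disk_phantom()
  g <- stop_function(dk$edges)
  phi <- init_circular_sdf(dim(g), c(63.5, 63.5), 30.5)
  p <- evolution_params(mode = "drlse", max_iters = 600, change_tol = 0)
  fit <- levelset_evolve(phi, g, p)
  gr <- coord_grids(dim(g))
  rr <- sqrt((gr$x - 63.5)^2 + (gr$y - 63.5)^2)
  swept <- rr > 31.5 & rr < 34
  expect_true(all(fit$phi[swept] > -2 * p$epsilon))
  expect_true(median(fit$phi[swept]) < -p$epsilon)
  gp <- field_gradient(fit$phi)
  s <- sqrt(gp$x^2 + gp$y^2)
  expect_equal(mean(s[abs(fit$phi) < 1]), 1, tolerance = 0.35)
})

test_that("divergent evolutions are reported with the failing iteration", {
  g <- matrix(1, 32, 32)
  phi <- init_circular_sdf(c(32, 32), c(15.5, 15.5), 8)
  p <- evolution_params(mu = 0.2, dt = 1, alpha = -2, mode = "drlse",
                        max_iters = 500)
  phi[10, 10] <- 1e300   # poisoned state blows up under differencing
  expect_error(suppressWarnings(levelset_evolve(phi, g, p)),
               "diverged at iteration")
})

test_that("axis refresh keeps running and returns a valid axis", {
  dk <- disk_phantom()
  g <- stop_function(dk$edges)
  phi <- init_circular_sdf(dim(g), c(63.5, 63.5), 28)
  p <- evolution_params(mode = "sct", max_iters = 50, axis_refresh_every = 20)
  fit <- levelset_evolve(phi, g, p, dk$axis)
  expect_s3_class(fit$axis, "symmetry_axis")
  expect_equal(fit$iterations, 50)
})
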