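test_that("speed law and the constant-coefficient formula evaluate correctly", {
  p <- speed_params(2, c0 = 1)
  expect_equal(p$p, 0.5)
  expect_equal(speed_law(1, p), 1)
  expect_equal(speed_law(2, p), sqrt(2))
  expect_equal(speed_law(0.5, p), 1 / sqrt(2))
  expect_error(speed_law(-1, p), "positive")
  expect_equal(general_speed(1, 1, 1, 2, 1), 1)
  expect_equal(general_speed(1, 1, 4, 2, 1), 2)
  ## m = 1: capacity does not enter
  expect_equal(general_speed(2, 3, 0.1, 1, 1), general_speed(2, 3, 10, 1, 1))
  expect_error(general_speed(-1, 1, 1, 2, 1), "positive")
})

test_that("front ODE reproduces the separable closed form on the ramp", {
  p <- speed_params(2, c0 = 1)
  ## k = x + 2: x(t) = (sqrt(x0 + 2) + t/2)^2 - 2
  tr <- front_ode_1d(0, function(x) x + 2, p, t_end = 2, dt = 0.01)
  expect_equal(tr$positions[length(tr$positions)], 1 + 2 * sqrt(2),
               tolerance = 1e-6)
  ## constant speed is exact
  tr1 <- front_ode_1d(0, function(x) 1, p, t_end = 2, dt = 0.02)
  expect_equal(max(abs(tr1$positions - tr1$times)), 0, tolerance = 1e-8)
  ## left-moving into k = 0.5 at slope -1/sqrt(2)
  trL <- front_ode_1d(0, function(x) 0.5, p, t_end = 2, dt = 0.02,
                      direction = "left")
  expect_equal(trL$positions[length(trL$positions)], -2 / sqrt(2),
               tolerance = 1e-8)
  expect_error(front_ode_1d(0, function(x) 1, p, t_end = 2, dt = 0.1), "dt")
  ## trajectory truncates and flags when the front leaves a field's domain
  k <- constant_k(grid_1d(c(-1, 1), 64), 4)
  expect_warning(trx <- front_ode_1d(0, k, p, t_end = 2, dt = 0.02),
                 "truncated")
  expect_true(trx$truncated)
  expect_lt(max(trx$times), 2)
})

test_that("uniformly expanding circles grow at the predicted radius rate", {
  p <- speed_params(2, c0 = 1)
  g <- grid_2d(c(-4, 4), c(-4, 4), 128)
  r <- sqrt(outer(g$x^2, g$y^2, "+"))
  out <- levelset_evolve_2d(levelset_init(g, 1 - r), constant_k(g, 1), p,
                            t_end = 1)
  rad <- sqrt(sum(out$snapshots[[1]]$phi > 0) * g$h[1] * g$h[2] / pi)
  expect_equal(rad, 2, tolerance = 0.02)
  ## K = 4 doubles the rate: radius 0.5 -> 2.5 over t = 1
  out4 <- levelset_evolve_2d(levelset_init(g, 0.5 - r), constant_k(g, 4), p,
                             t_end = 1)
  rad4 <- sqrt(sum(out4$snapshots[[1]]$phi > 0) * g$h[1] * g$h[2] / pi)
  expect_equal(rad4, 2.5, tolerance = 0.02)
  ## outward monotonicity: phi nondecreasing up to reinitialization tolerance
  out2 <- levelset_evolve_2d(levelset_init(g, 1 - r), constant_k(g, 1), p,
                             t_end = 1, snapshot_times = c(0.5, 1))
  expect_gte(min(out2$snapshots[[2]]$phi - out2$snapshots[[1]]$phi), -5e-3)
})

test_that("footpoint and local speed evaluation agree on the front position", {
  p <- speed_params(2, c0 = 1)
  g <- grid_2d(c(-5, 5), c(-5, 5), 128)
  r <- sqrt(outer(g$x^2, g$y^2, "+"))
  k <- k_polar_2d(g)
  oL <- levelset_evolve_2d(levelset_init(g, 1 - r), k, p, t_end = 1,
                           mode = "local")
  oF <- levelset_evolve_2d(levelset_init(g, 1 - r), k, p, t_end = 1,
                           mode = "footpoint")
  H <- hausdorff_distance(levelset_front(oL$snapshots[[1]]),
                          levelset_front(oF$snapshots[[1]]))
  expect_lt(H, 4 * max(g$h))
})

test_that("reinitialization is a fixed point on planar signed distance", {
  g <- grid_2d(c(-2, 2), c(-2, 2), 64)
  phi <- matrix(rep(0.3 - g$x, times = g$ny), g$nx, g$ny)
  out <- reinitialize(levelset_init(g, phi))
  near <- abs(phi) < 5 * g$h[1]
  expect_lt(max(abs(out$phi - phi)[near]), 1e-3 * g$h[1])
})

test_that("reinitialization recovers distance and sign for a circle", {
  g <- grid_2d(c(-4, 4), c(-4, 4), 128)
  r <- sqrt(outer(g$x^2, g$y^2, "+"))
  ## input: a distorted (scaled) level-set function with the same zero set
  out <- reinitialize(levelset_init(g, 1.3 * (1.5 - r)))
  ic <- which.min(abs(g$x))
  expect_equal(out$phi[ic, ic], 1.5, tolerance = 2 * g$h[1] / 1.5)
  expect_identical(out$phi > 0, (1.5 - r) > 0)
  ## gradient magnitude near the front is close to 1
  gr <- pmfront:::grad_central(out$phi, g)
  gm <- sqrt(gr$gx^2 + gr$gy^2)
  near <- abs(out$phi) < 5 * g$h[1]
  expect_true(all(gm[near] >= 0.95 & gm[near] <= 1.05))
  expect_error(reinitialize(levelset_init(g, r + 1)), "sign")
})

test_that("level-set flow stops and flags when the front nears the boundary", {
  p <- speed_params(2, c0 = 1)
  g <- grid_2d(c(-2, 2), c(-2, 2), 64)
  r <- sqrt(outer(g$x^2, g$y^2, "+"))
  expect_warning(
    out <- levelset_evolve_2d(levelset_init(g, 1 - r), constant_k(g, 1), p,
                              t_end = 2),
    "boundary")
  expect_true(out$stopped_at_boundary)
})

test_that("1-d front ODE agrees with the 2-d level set for a y-independent field", {
  p <- speed_params(2, c0 = 1)
  kf <- function(x) 1 + 0.1 * x
  g <- grid_2d(c(-3, 4), c(-2, 2), 140, 80)
  k <- pmfront:::new_kfield(g, matrix(rep(kf(g$x), g$ny), g$nx, g$ny), "C2")
  phi0 <- matrix(rep(0 - g$x, times = g$ny), g$nx, g$ny)
  out <- levelset_evolve_2d(levelset_init(g, phi0), k, p, t_end = 1.5,
                            allow_boundary_contact = TRUE)
  fr <- levelset_front(out$snapshots[[1]])
  tr <- front_ode_1d(0, kf, p, t_end = 1.5, dt = 0.01)
  expect_lt(abs(mean(fr[, 1]) - tr$positions[length(tr$positions)]),
            2 * g$h[1])
})

test_that("cut-off distance is the identity inside, clamped outside, C1 at the seams", {
  d0 <- 1
  expect_equal(cutoff_distance(0.5, d0), 0.5)
  expect_equal(cutoff_distance(3, d0), 2)
  expect_equal(cutoff_distance(-3, d0), -2)
  expect_equal(cutoff_distance(0, d0), 0)
  ## derivative continuity at |s| = d0 and 2 d0
  fd <- function(s) (cutoff_distance(s + 1e-6, d0) -
                       cutoff_distance(s - 1e-6, d0)) / 2e-6
  expect_equal(fd(1 - 1e-5), fd(1 + 1e-5), tolerance = 1e-8)
  expect_equal(fd(2 - 1e-5), fd(2 + 1e-5) + 0, tolerance = 1e-6)
  expect_lt(abs(fd(2 + 1e-5)), 1e-8)
  ## monotone on a fine grid
  s <- seq(-3, 3, by = 1e-3)
  expect_true(all(diff(cutoff_distance(s, d0)) >= 0))
  expect_error(cutoff_distance(1, -1), "positive")
})
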