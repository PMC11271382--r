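test_that("front location is translation-exact and signals absent fronts", {
  g <- grid_1d(c(-4, 8), 600)
  ## steep right-moving layer (support edge 1.3): u crosses 1/2 at the
  ## analytically known offset x* - s * 2 ln 2 inside the layer
  s <- 0.1
  u <- exact_wave_m2(-(g$x - 1.3) / s)
  x1 <- front_position_1d(u, g)
  expect_equal(as.numeric(x1), 1.3 - s * 2 * log(2), tolerance = g$h)
  u2 <- exact_wave_m2(-(g$x - 1.8) / s)
  x2 <- front_position_1d(u2, g)
  expect_equal(as.numeric(x2) - as.numeric(x1), 0.5, tolerance = 1e-6)
  x0 <- front_position_1d(rep(0, g$nx), g)
  expect_true(is.na(x0))
  expect_identical(attr(x0, "status"), "absent")
  ## multiple crossings: outermost returned, flagged
  u3 <- 0.8 * as.numeric(g$x < 0 | (g$x > 2 & g$x < 3))
  x3 <- front_position_1d(u3, g)
  expect_equal(as.numeric(x3), 3, tolerance = g$h)
  expect_true(isTRUE(attr(x3, "multiple")))
})

test_that("least-squares speed recovers exact and noisy slopes", {
  t <- seq(0, 5, by = 0.1)
  f <- estimate_speed(t, 0.7 * t)
  expect_equal(f$slope, 0.7)
  expect_equal(estimate_speed(t, rep(2, length(t)))$slope, 0)
  set.seed(42)
  tn <- seq(0, 5, length.out = 100)
  pos <- 0.7 * tn + rnorm(100, sd = 0.01)
  fit <- estimate_speed(tn, pos)
  ## within 3 standard errors of the true slope
  se <- 0.01 / (stats::sd(tn[tn >= 2.5]) * sqrt(sum(tn >= 2.5)))
  expect_lt(abs(fit$slope - 0.7), 3 * se)
  expect_error(estimate_speed(c(1, 2), c(1, 2)), "5 samples")
})

test_that("2-d contour extraction matches analytic radii and components", {
  g <- grid_2d(c(-3, 3), c(-3, 3), 96)
  r <- sqrt(outer(g$x^2, g$y^2, "+"))
  u <- pmin(pmax(1.2 - r, 0), 1)           # u = 0.5 on the circle r = 0.7
  ctr <- interface_from_field_2d(u, g)
  rad <- sqrt(ctr[, "x"]^2 + ctr[, "y"]^2)
  expect_lt(max(abs(rad - 0.7)), max(g$h))
  e <- interface_from_field_2d(matrix(0, g$nx, g$ny), g)
  expect_equal(nrow(e), 0)
  expect_identical(attr(e, "status"), "empty")
  ## two disjoint bumps give two components
  u2 <- pmax(1 - ((outer(g$x, rep(1, g$ny)) - 1.5)^2 +
                    outer(rep(1, g$nx), g$y)^2) / 0.5, 0) +
    pmax(1 - ((outer(g$x, rep(1, g$ny)) + 1.5)^2 +
                outer(rep(1, g$nx), g$y)^2) / 0.5, 0)
  ctr2 <- interface_from_field_2d(u2, g)
  expect_equal(length(unique(ctr2[, "comp"])), 2)
})

test_that("Hausdorff distance satisfies its defining examples", {
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  A <- cbind(cos(th), sin(th))
  B <- cbind(2 * cos(th), 2 * sin(th))
  expect_equal(hausdorff_distance(A, A), 0)
  expect_equal(hausdorff_distance(A, B), 1, tolerance = 1e-3)
  expect_equal(hausdorff_distance(matrix(c(1, 2), 1), matrix(c(1, 2), 1)), 0)
  expect_error(hausdorff_distance(A[0, ], B), "nonempty")
})

test_that("generation envelopes pass trivially for uniform states", {
  g <- grid_1d(c(-2, 2), 64)
  k <- constant_k(g, 1)
  eps <- 0.1
  t_eps <- eps * abs(log(eps))
  u0_full <- u0_step_1d(g, level = 1)
  u0_full$values[] <- 1
  u0_full$support_mask[] <- TRUE
  run1 <- synthetic_run(g, k, eps, 2, t_eps, 1)
  rep1 <- generation_check(run1, u0_full)
  expect_true(rep1$generation_ok)
  expect_equal(rep1$M_star, 0.5)   # passes at the smallest searched factor
  ## all-zero field with empty-support datum: exterior condition passes
  u0_zero <- u0_full
  u0_zero$values[] <- 0
  u0_zero$values[32] <- 1e-9       # minimal support so distances are defined
  u0_zero$support_mask <- u0_zero$values > 0
  run0 <- synthetic_run(g, k, eps, 2, t_eps, 0)
  expect_true(generation_check(run0, u0_zero)$generation_ok)
})

test_that("generation envelopes hold on the ramp landscape with a modest factor", {
  fx <- fix_generation()
  rep <- generation_check(fx$run, fx$u0, eta_g = 0.1)
  expect_true(rep$generation_ok)
  expect_lte(rep$M_star, 20)
  expect_true(rep$sup_bound_ok)
})

test_that("propagation envelopes hold for the homogeneous problem and scale with eps", {
  hp <- fix_homog_prop()
  reps <- lapply(hp, function(x) propagation_check(x$run, x$limit))
  for (r in reps) expect_true(r$propagation_ok)
  ## smallest eps case: the envelope factor stays modest
  expect_lte(reps[[3]]$M_star, 20)
  ## band margin M * eps halves from eps = 0.2 to 0.1 within 30%
  band <- vapply(seq_along(hp), function(i) reps[[i]]$M_star * hp[[i]]$eps,
                 numeric(1))
  expect_lt(abs(band[1] / band[2] - 2), 0.6)
})

test_that("propagation check rejects mismatched limit coverage", {
  hp <- fix_homog_prop()
  short <- front_ode_1d(0, function(x) 1, speed_params(2, 1), 1, dt = 0.01)
  expect_error(propagation_check(hp[[1]]$run, short), "cover")
})
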