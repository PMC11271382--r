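test_that("logistic reaction step is exact on equilibria and the closed form", {
  k <- constant_k(grid_1d(c(0, 1), 64), 2)
  expect_identical(reaction_step_exact(rep(0, 64), k, 0.3, 0.1), rep(0, 64))
  expect_equal(reaction_step_exact(k$values, k, 0.3, 0.1), k$values)
  ## U = k/2 after dt/eps = ln 3 reaches 3k/4
  expect_equal(reaction_step_exact(rep(1, 64), k, log(3), 1), rep(1.5, 64))
  ## values above k decay toward k
  expect_lt(reaction_step_exact(2.2, 2, 1, 0.5), 2.2)
  expect_gt(reaction_step_exact(2.2, 2, 1, 0.5), 2)
})

test_that("diffusion step conserves mass, fixes constants, and rejects bad steps", {
  g <- grid_1d(c(-10, 10), 400)
  U <- pmax(1 - g$x^2, 0)
  dt <- pmfront:::cfl_dt(U, 1, 2, g, 0.9)
  expect_equal(sum(diffusion_step_explicit(U, dt, 1, 2, g)), sum(U))
  expect_equal(diffusion_step_explicit(rep(0.7, 400), dt, 1, 2, g),
               rep(0.7, 400))
  err <- tryCatch(diffusion_step_explicit(U, 10 * dt, 1, 2, g),
                  error = function(e) conditionMessage(e))
  expect_match(err, "CFL violation")
  expect_match(err, "admissible")
  ## 2-d mass conservation
  g2 <- grid_2d(c(-3, 3), c(-3, 3), 48)
  U2 <- pmax(1 - outer(g2$x^2, g2$y^2, "+"), 0)
  dt2 <- pmfront:::cfl_dt(U2, 1, 2, g2, 0.9)
  expect_equal(sum(diffusion_step_explicit(U2, dt2, 1, 2, g2)), sum(U2))
})

test_that("compact supports spread at the self-similar porous-medium rate", {
  ## reaction-off spreading of a bump: support radius ~ t^(1/(m+1)), m = 2
  g <- grid_1d(c(-20, 20), 800)
  U <- pmax(1 - g$x^2, 0)
  t <- 0
  targets <- 10^seq(0.5, 2, length.out = 24)
  radii <- numeric(0); tims <- numeric(0)
  while (t < 100) {
    dt <- min(pmfront:::cfl_dt(U, 1, 2, g, 0.9), targets[1] - t)
    U <- diffusion_step_explicit(U, dt, 1, 2, g)
    t <- t + dt
    if (abs(t - targets[1]) < 1e-12) {
      radii <- c(radii, max(abs(g$x[U > 1e-12])))
      tims <- c(tims, t)
      targets <- targets[-1]
    }
  }
  slope <- unname(stats::lm.fit(cbind(1, log(tims)), log(radii))$coefficients[2])
  expect_lt(abs(slope - 1 / 3), 1 / 3 * 0.10)
})

test_that("zero initial data stays zero and exact zeros are preserved outside", {
  g <- grid_1d(c(-4, 8), 600)
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  u0$values[] <- 0
  u0$support_mask[] <- FALSE
  run <- evolve(pde_init(u0, k, 0.1, 2), solver_config(0.5))
  expect_true(all(run$snapshots[[1]]$u == 0))
  ## with the step datum, cells far ahead of the front hold exact zeros
  run2 <- evolve(pde_init(u0_step_1d(g), k, 0.1, 2), solver_config(0.2))
  expect_true(all(run2$snapshots[[1]]$u[g$x > 4] == 0))
})

test_that("sup-bound eta follows the printed formula and its eps^2 scaling", {
  expect_identical(sup_bound_eta(constant_k(grid_1d(c(0, 1), 64), 2), 2, 0.1), 0)
  k <- k_ramp_1d()
  ## on the ramp (cusp excluded): |Lap k^2| = 2, max ratio at k = 0.5 -> 8 eps^2
  expect_warning(eta1 <- sup_bound_eta(k, 2, 0.1), "cusp")
  expect_equal(eta1, 8 * 0.1^2, tolerance = 0.05)
  eta2 <- suppressWarnings(sup_bound_eta(k, 2, 0.05))
  expect_equal(eta1 / 0.1^2, eta2 / 0.05^2)
})

test_that("on a C^2 landscape the sup excess obeys the bound at second order", {
  ## the eta_eps estimate assumes a twice-differentiable capacity and small
  ## eps; on the smooth bump landscape the measured overshoot stays below
  ## the bound and its eps^2-normalized size stabilizes as eps decreases
  ex <- fix_bump_excess()
  for (e in ex) expect_lte(e$excess, e$eta + 1e-2)
  r <- vapply(ex, function(e) e$excess / e$eps^2, numeric(1))
  expect_lt(max(r) / min(r), 2)
  ## and the excess is a genuine positive overshoot, not rounding
  expect_true(all(vapply(ex, `[[`, numeric(1), "excess") > 1e-4))
})

test_that("numerically ordered initial data stay ordered (comparison principle)", {
  g <- grid_1d(c(-4, 8), 600)
  k <- k_ramp_1d(g)
  u0b <- u0_step_1d(g)
  u0a <- u0b
  u0a$values <- 0.3 * u0b$values
  dtfix <- 0.5 * pmfront:::cfl_dt(k$values, 0.2, 2, g)
  ra <- evolve(pde_init(u0a, k, 0.2, 2), solver_config(0.5, dt = dtfix))
  rb <- evolve(pde_init(u0b, k, 0.2, 2), solver_config(0.5, dt = dtfix))
  expect_lte(max(ra$snapshots[[1]]$u - rb$snapshots[[1]]$u), 1e-8)
})

test_that("transition-layer width shrinks proportionally to eps", {
  hp <- fix_homog_prop()
  w <- vapply(hp, function(x)
    layer_width_1d(x$run$snapshots[[1]]$u, x$grid), numeric(1))
  ## eps = 0.2 vs 0.1: widths in ratio 2 within 30%
  expect_lt(abs(w[1] / w[2] - 2), 0.6)
  ## eps = 0.1 vs 0.05 as well
  expect_lt(abs(w[2] / w[3] - 2), 0.6)
})

test_that("solver config validates its fields", {
  expect_error(solver_config(1, cfl_safety = 0.95), "cfl_safety")
  expect_error(solver_config(-1), "t_end")
  cfg <- solver_config(2, snapshot_times = c(0.5, 1))
  expect_equal(cfg$snapshot_times, c(0.5, 1, 2))
})

test_that("pde_init enforces the density and grid contracts", {
  g <- grid_1d(c(-4, 8), 600)
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  bad <- u0; bad$values[1] <- 1.2
  expect_error(pde_init(bad, k, 0.1, 2), "0 <= u0 <= 1")
  g2 <- grid_1d(c(-4, 8), 640)
  expect_error(pde_init(u0_step_1d(g2), k, 0.1, 2), "share a grid")
  expect_error(pde_init(u0, k, -0.1, 2), "eps")
})
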