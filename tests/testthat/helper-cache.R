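## shared fixtures: expensive deterministic runs are computed once per test
## session and reused across files (testthat loads helpers before all tests)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## the m = 2 minimal wave at the default resolution
fix_wave_m2 <- function() cached("wave_m2", wave_profile(2, zmax = 40, n = 4000))

## homogeneous speed-law runs, K in {0.5, 1, 2, 4}, m = 2, eps = 0.05
fix_speed_runs <- function() cached("speed_runs", {
  c0 <- as.numeric(minimal_wave_speed(2, tol = 1e-6))
  lapply(c(0.5, 1, 2, 4), function(K)
    homogeneous_speed_run(K, m = 2, eps = 0.05, c0 = c0))
})

## heterogeneous 1-d propagation runs (ramp landscape, t = 4)
fix_propagation <- function() cached("propagation", preset_propagation_1d())

## eps-refinement table on the ramp landscape
fix_convergence <- function() cached("convergence", preset_convergence_1d())

## 2-d band comparison runs at eps = 0.2 and 0.1 (128^2, t_end = 3)
fix_band <- function() {
  cached("band", lapply(c(0.2, 0.1), function(eps)
    preset_cavity_2d(eps = eps, n = 128, xlim = c(-9, 9), t_end = 3,
                     snapshot_times = 1:3)))
}

## homogeneous propagation runs for envelope checks, eps in {0.2, 0.1, 0.05}
fix_homog_prop <- function() cached("homog_prop", {
  lapply(c(0.2, 0.1, 0.05), function(eps) {
    g <- grid_1d(c(-3, 6), 900)
    k <- constant_k(g, 1)
    u0 <- u0_step_1d(g)
    run <- evolve(pde_init(u0, k, eps, 2),
                  solver_config(2, snapshot_times = 2))
    limit <- front_ode_1d(0, k, speed_params(2, 1), 2, dt = 0.01)
    list(eps = eps, grid = g, run = run, limit = limit)
  })
})

## ramp-landscape generation run at eps = 0.1 with a snapshot at t_eps
fix_generation <- function() cached("generation", {
  g <- grid_1d(c(-4, 8), 1200)
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  t_eps <- 0.1 * abs(log(0.1))
  run <- evolve(pde_init(u0, k, 0.1, 2),
                solver_config(t_eps, snapshot_times = t_eps))
  list(grid = g, k = k, u0 = u0, run = run)
})

## smooth-bump landscape runs at eps in {0.2, 0.1, 0.05} for the
## second-order sup-excess rate (C^2 hypotheses hold, eps in the
## asymptotic regime of the generation estimate)
fix_bump_excess <- function() cached("bump_excess", {
  g <- grid_1d(c(-4, 8), 1200)
  k <- k_bump_1d(g)
  u0 <- u0_step_1d(g)
  lapply(c(0.2, 0.1, 0.05), function(eps) {
    run <- evolve(pde_init(u0, k, eps, 2), solver_config(2))
    list(eps = eps, k = k, excess = run$max_u - 1,
         eta = sup_bound_eta(k, 2, eps))
  })
})

## a small synthetic pm_run with prescribed uniform u (for trivial envelope cases)
synthetic_run <- function(grid, k, eps, m, t, u_value) {
  u <- if (grid$dims == 1L) rep(u_value, grid$nx) else
    matrix(u_value, grid$nx, grid$ny)
  structure(list(grid = grid, k = k, eps = eps, m = m, times = t,
                 snapshots = list(list(t = t, U = u * k$values, u = u)),
                 max_u = max(u), n_steps = 0L),
            class = "pm_run")
}
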