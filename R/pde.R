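#' Singularly perturbed porous-medium KPP solver
#'
#' Solves `U_t = eps * Lap(U^m) + (1/eps) U (1 - U/k(x))` with zero-flux
#' boundaries and reports the relative density `u = U/k`.  The equation is
#' advanced by Strang splitting: an exactly integrated logistic reaction half
#' step on each side of an explicit finite-volume step for the degenerate
#' diffusion of `w = U^m` (3-point stencil in 1-d, 5-point in 2-d, zero flux
#' by mirrored ghost cells).  Solving in `U` keeps all spatial heterogeneity
#' inside the exactly solvable reaction; the `u`-form of the equation is the
#' same discrete update divided by `k`.
#'
#' The explicit diffusion step is stable and order preserving under the CFL
#' bound `dt <= h^2 / (2 dims eps m max(U)^(m-1))`; [evolve()] recomputes the
#' admissible step each iteration.  Equilibria `U = 0` and `U = k` are fixed
#' points of the reaction flow to machine precision, and exact zeros are
#' preserved by the degenerate diffusion, so compact supports spread only
#' through genuine flux.
#'
#' @name pde_solver
NULL

#' Initialize a PDE state
#'
#' @param u0 a `pm_u0` initial relative density.
#' @param k a `pm_kfield` on the same grid.
#' @param eps scale-separation parameter (`eps > 0`).
#' @param m diffusion exponent.
#' @return object of class `pm_state`: list with `grid`, `U` (capacity
#'   units), `k`, `t`, `eps`, `m`.
#' @export
pde_init <- function(u0, k, eps, m) {
  stopifnot(inherits(u0, "pm_u0"), inherits(k, "pm_kfield"))
  if (!identical(u0$grid$dims, k$grid$dims) ||
      !isTRUE(all.equal(u0$grid$x, k$grid$x)))
    stop("u0 and k must share a grid")
  if (eps <= 0) stop("eps must be positive")
  check_exponent(m)
  if (any(u0$values < 0) || any(u0$values > 1))
    stop("initial relative density must satisfy 0 <= u0 <= 1")
  structure(list(grid = k$grid, U = u0$values * k$values, k = k, t = 0,
                 eps = eps, m = m),
            class = "pm_state")
}

#' Exact logistic reaction step
#'
#' Advances `U_t = (1/eps) U (1 - U/k)` exactly over `dt`, cellwise:
#' `U <- k U / (U + (k - U) exp(-dt/eps))`.  Equilibria 0 and k are exact
#' fixed points; values slightly above k decay toward k.
#'
#' @param U density array (capacity units), `U >= 0`.
#' @param k `pm_kfield` (or a bare array of capacities).
#' @param dt time step.
#' @param eps scale parameter.
#' @return updated density array.
#' @export
reaction_step_exact <- function(U, k, dt, eps) {
  if (dt <= 0) stop("dt must be positive")
  kv <- if (inherits(k, "pm_kfield")) k$values else k
  e <- exp(-dt / eps)
  kv * U / (U + (kv - U) * e)
}

## admissible explicit step for the degenerate diffusion
cfl_dt <- function(U, eps, m, grid, cfl_safety = 1) {
  mx <- max(U)
  if (mx <= 0) return(Inf)
  cfl_safety * min(grid$h)^2 / (2 * grid$dims * eps * m * mx^(m - 1))
}

#' Explicit degenerate-diffusion step
#'
#' One forward-Euler step `U <- U + dt * eps * Lap_h(U^m)` with zero-flux
#' (mirrored-ghost) boundaries.  Rejects steps that violate the CFL bound.
#'
#' @inheritParams reaction_step_exact
#' @param m diffusion exponent.
#' @param grid the `pm_grid`.
#' @return updated density array.
#' @export
diffusion_step_explicit <- function(U, dt, eps, m, grid) {
  dt_max <- cfl_dt(U, eps, m, grid)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("CFL violation: dt = %.3e exceeds admissible %.3e", dt, dt_max))
  U + dt * eps * lap_neumann(U^m, grid)
}

#' Solver configuration
#'
#' @param t_end final time.
#' @param snapshot_times times at which to store snapshots (always includes
#'   `t_end`); the adaptive step is shortened to land on them exactly.
#' @param cfl_safety fraction of the admissible explicit step to use
#'   (`<= 0.9`).
#' @param dt optional fixed step (still checked against the CFL bound each
#'   iteration); used e.g. for exact comparison-principle experiments where
#'   two runs must share a step sequence.
#' @param tol_bound numerical slack `delta_num` allowed on the sup bound
#'   `u <= 1 + eta_eps + delta_num` before a warning is raised.
#' @return list of class `pm_solver_config`.
#' @export
solver_config <- function(t_end, snapshot_times = NULL, cfl_safety = 0.8,
                          dt = NULL, tol_bound = 1e-2) {
  stopifnot(t_end > 0)
  if (cfl_safety > 0.9 || cfl_safety <= 0) stop("cfl_safety must be in (0, 0.9]")
  st <- sort(unique(c(snapshot_times, t_end)))
  st <- st[st >= 0 & st <= t_end + 1e-12]
  structure(list(t_end = t_end, snapshot_times = st, cfl_safety = cfl_safety,
                 dt = dt, tol_bound = tol_bound),
            class = "pm_solver_config")
}

#' Evolve a PDE state
#'
#' Strang splitting (reaction half step, diffusion step, reaction half step)
#' with an adaptive explicit step.  Snapshots store both `U` and `u = U/k`.
#' Aborts with step diagnostics if the solution turns negative or
#' non-finite.
#'
#' @param state a `pm_state` from [pde_init()].
#' @param config a [solver_config()].
#' @return object of class `pm_run`: list with `grid`, `k`, `eps`, `m`,
#'   `times`, `snapshots` (each a list `t`, `U`, `u`), `max_u` (running
#'   maximum of `u` over the whole run), `n_steps`.
#' @export
evolve <- function(state, config) {
  stopifnot(inherits(state, "pm_state"), inherits(config, "pm_solver_config"))
  grid <- state$grid
  kv <- state$k$values
  eps <- state$eps
  m <- state$m
  U <- state$U
  t <- state$t
  snaps <- list()
  snap_times <- config$snapshot_times
  max_u <- max(U / kv)
  n_steps <- 0L
  if (any(abs(snap_times - t) < 1e-12)) {
    snaps[[length(snaps) + 1L]] <- list(t = t, U = U, u = U / kv)
    snap_times <- snap_times[abs(snap_times - t) >= 1e-12]
  }
  while (t < config$t_end - 1e-12) {
    dt <- cfl_dt(U, eps, m, grid, config$cfl_safety)
    if (!is.null(config$dt)) {
      if (config$dt > cfl_dt(U, eps, m, grid) * (1 + 1e-12))
        stop(sprintf("fixed dt = %.3e violates the CFL bound %.3e at t = %.4f",
                     config$dt, cfl_dt(U, eps, m, grid), t))
      dt <- config$dt
    }
    if (!is.finite(dt)) dt <- config$t_end - t    # U identically zero
    next_stop <- snap_times[snap_times > t + 1e-12][1]
    if (is.na(next_stop)) next_stop <- config$t_end
    dt <- min(dt, next_stop - t)
    U <- reaction_step_exact(U, kv, dt / 2, eps)
    U <- diffusion_step_explicit(U, dt, eps, m, grid)
    U <- reaction_step_exact(U, kv, dt / 2, eps)
    t <- t + dt
    n_steps <- n_steps + 1L
    if (anyNA(U) || any(!is.finite(U)) || any(U < 0))
      stop(sprintf("solver failure at t = %.5f (step %d, dt = %.3e): %s",
                   t, n_steps, dt,
                   if (any(U < 0, na.rm = TRUE)) "negative density"
                   else "non-finite density"))
    max_u <- max(max_u, max(U / kv))
    if (any(abs(snap_times - t) < 1e-9)) {
      snaps[[length(snaps) + 1L]] <- list(t = t, U = U, u = U / kv)
      snap_times <- snap_times[abs(snap_times - t) >= 1e-9]
    }
  }
  structure(list(grid = grid, k = state$k, eps = eps, m = m,
                 times = vapply(snaps, `[[`, numeric(1), "t"),
                 snapshots = snaps, max_u = max_u, n_steps = n_steps),
            class = "pm_run")
}

#' @export
print.pm_run <- function(x, ...) {
  cat(sprintf(
    "<pm_run %d-d: eps = %g, m = %g, %d snapshots to t = %g, %d steps, max u = %.4f>\n",
    x$grid$dims, x$eps, x$m, length(x$snapshots),
    max(x$times), x$n_steps, x$max_u))
  invisible(x)
}

#' Sup-bound excess eta_eps
#'
#' The solution of the perturbed problem can exceed 1 by at most
#' `eta_eps = eps^2 * max(|Lap(k^m)| / k) * 2^(m-1)`, a second-order
#' quantity in eps.  The discrete Laplacian is evaluated on interior cells
#' with cusp cells (flagged by [validate_k()]) excluded with a warning,
#' since a genuine cusp has no bounded Laplacian.
#'
#' @param k a `pm_kfield`.
#' @param m diffusion exponent.
#' @param eps scale parameter.
#' @return the bound (scalar).
#' @export
sup_bound_eta <- function(k, m, eps) {
  stopifnot(inherits(k, "pm_kfield"))
  rep_k <- validate_k(k)
  lap_km <- lap_neumann(k$values^m, k$grid)
  ok <- interior_mask(k$grid) & !rep_k$cusp_cells
  if (rep_k$n_flagged > 0)
    warning(sprintf("%d cusp cell(s) excluded from the Laplacian maximum",
                    rep_k$n_flagged), call. = FALSE)
  eps^2 * max(abs(lap_km[ok]) / k$values[ok]) * 2^(m - 1)
}
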