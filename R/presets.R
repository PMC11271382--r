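#' Reproducible experiment presets
#'
#' Preset pipelines tying the modules together: the 1-d interface-generation
#' and interface-propagation experiments on the piecewise-harmonic ramp
#' landscape, the homogeneous speed-law measurement, the 2-d
#' cavity-formation experiment on the polar landscape with its level-set
#' comparison, and an eps-refinement convergence table.  All presets are
#' fully deterministic (no random numbers), write an optional manifest
#' sufficient to reproduce them, and accept overrides for grid, domain and
#' times; the defaults state the package's standard study conditions.
#'
#' @name presets
NULL

#' Interface generation in 1-d (ramp landscape)
#'
#' Solves the perturbed problem on the ramp landscape from the printed step
#' datum with `eps = 0.1`, `m = 2`, storing `u` at `t = 0, 0.2, 0.4, 0.6`:
#' the transition layer forms at the support edge and the plateau rises to 1.
#'
#' @param eps scale parameter.
#' @param m diffusion exponent.
#' @param h grid spacing.
#' @param xlim 1-d domain.
#' @param snapshot_times snapshot times.
#' @param cfl_safety explicit-step safety factor.
#' @param out_dir optional output directory (CSV profiles, PNG overlay,
#'   JSON manifest).
#' @return list with `run` (`pm_run`), `k`, `u0`, `eta_eps`, `manifest`.
#' @export
preset_generation_1d <- function(eps = 0.1, m = 2, h = 0.01,
                                 xlim = c(-4, 8),
                                 snapshot_times = c(0, 0.2, 0.4, 0.6),
                                 cfl_safety = 0.8, out_dir = NULL) {
  g <- grid_1d(xlim, round(diff(xlim) / h))
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  st <- pde_init(u0, k, eps, m)
  run <- evolve(st, solver_config(max(snapshot_times),
                                  snapshot_times = snapshot_times,
                                  cfl_safety = cfl_safety))
  eta <- suppressWarnings(sup_bound_eta(k, m, eps))
  cfg <- list(preset = "generation_1d", eps = eps, m = m, h = h, xlim = xlim,
              snapshot_times = snapshot_times, cfl_safety = cfl_safety)
  man <- make_manifest(cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_csv(run, file.path(out_dir, "generation_1d.csv"))
    write_manifest(man, file.path(out_dir, "generation_1d_manifest.json"))
    plot_run_1d(run, file.path(out_dir, "generation_1d.png"))
  }
  list(run = run, k = k, u0 = u0, eta_eps = eta, manifest = man)
}

#' Interface propagation in 1-d (ramp landscape)
#'
#' Solves the perturbed problem to `t = 4` for several eps on the ramp
#' landscape and overlays the sharp-interface limit: the right-moving front
#' of the limit ODE `dx/dt = c0 k(x)^p` started at the initial interface
#' `x = 0` (on the ramp the ODE integrates in closed form to
#' `x(t) = (sqrt(x0 + 2) + t/2)^2 - 2` for `m = 2`).  The printed initial
#' datum fills the domain to the left, so only the right-moving interface
#' exists.  The domain extends to `x = 13` so the `t = 4` front
#' (`~ 4 + 4 sqrt(2)`) stays inside.
#'
#' @param eps_values eps values to run.
#' @param t_end final time.
#' @param m,h,xlim,cfl_safety,out_dir see [preset_generation_1d()].
#' @param snapshot_times times stored per run.
#' @return list with `runs` (one `pm_run` per eps), `limit` (`pm_traj`),
#'   `front_positions` (data frame: eps, PDE front at `t_end`, limit front,
#'   gap), `params`, `manifest`.
#' @export
preset_propagation_1d <- function(eps_values = c(0.5, 0.3, 0.1), t_end = 4,
                                  m = 2, h = 0.015, xlim = c(-4, 13),
                                  snapshot_times = c(2, 3, 4),
                                  cfl_safety = 0.8, out_dir = NULL) {
  g <- grid_1d(xlim, round(diff(xlim) / h))
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  params <- speed_params(m)
  limit <- front_ode_1d(0, k, params, t_end, dt = t_end / 800)
  runs <- lapply(eps_values, function(eps) {
    evolve(pde_init(u0, k, eps, m),
           solver_config(t_end, snapshot_times = snapshot_times,
                         cfl_safety = cfl_safety))
  })
  names(runs) <- paste0("eps_", eps_values)
  x_lim_end <- limit$positions[length(limit$positions)]
  fp <- do.call(rbind, lapply(seq_along(eps_values), function(i) {
    ui <- runs[[i]]$snapshots[[which.min(abs(runs[[i]]$times - t_end))]]$u
    xf <- as.numeric(front_position_1d(ui, g))
    data.frame(eps = eps_values[i], pde_front = xf, limit_front = x_lim_end,
               gap = abs(xf - x_lim_end))
  }))
  cfg <- list(preset = "propagation_1d", eps = eps_values, t_end = t_end,
              m = m, h = h, xlim = xlim, snapshot_times = snapshot_times,
              cfl_safety = cfl_safety)
  man <- make_manifest(cfg, c0 = params$c0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fp, file.path(out_dir, "propagation_fronts.csv"),
                     row.names = FALSE)
    write_manifest(man, file.path(out_dir, "propagation_manifest.json"))
    plot_propagation_1d(runs, g, x_lim_end,
                        file.path(out_dir, "propagation_1d.png"))
  }
  list(runs = runs, limit = limit, front_positions = fp, params = params,
       grid = g, k = k, manifest = man)
}

#' Homogeneous front-speed measurement
#'
#' Runs the perturbed problem with constant capacity `K` from a step datum
#' and fits the front speed over the second half of the run; the limit law
#' predicts `c0 K^p`.  The domain is sized from the predicted speed so the
#' front never reaches the boundary.
#'
#' @param K capacity level.
#' @param m,eps,h,cfl_safety solver parameters.
#' @param t_end run length.
#' @param c0 minimal speed (computed if omitted).
#' @return list with `fit` (`pm_speedfit`), `predicted`, `run`.
#' @export
homogeneous_speed_run <- function(K, m = 2, eps = 0.05, h = 0.02,
                                  t_end = 3, cfl_safety = 0.85, c0 = NULL) {
  params <- speed_params(m, c0)
  c_pred <- speed_law(K, params)
  xmax <- 2 + 1.25 * c_pred * t_end + 20 * eps
  g <- grid_1d(c(-3, xmax), round((xmax + 3) / h))
  k <- constant_k(g, K)
  u0 <- u0_step_1d(g)
  snap <- seq(t_end / 2, t_end, length.out = 26)
  run <- evolve(pde_init(u0, k, eps, m),
                solver_config(t_end, snapshot_times = snap,
                              cfl_safety = cfl_safety))
  pos <- vapply(run$snapshots, function(s)
    as.numeric(front_position_1d(s$u, g)), numeric(1))
  fit <- estimate_speed(run$times, pos, window = range(run$times))
  list(fit = fit, predicted = c_pred, run = run)
}

#' 2-d cavity experiment with level-set comparison
#'
#' Solves the perturbed problem on the polar landscape from an elliptical
#' plateau and, in parallel, flows the ellipse boundary by the limit law
#' with the level-set method.  Returns the Hausdorff distance between the
#' PDE half-level contour and the level-set front at each snapshot, and the
#' convex-hull area ratio of the front (values above 1 indicate the cavity:
#' the slow pocket of the landscape makes the invaded region nonconvex).
#' The default initial colony is a tall, thin ellipse whose long flat side
#' faces the slow sector of the landscape; flanking front points outrun the
#' central one there, which is the geometry that develops the cavity within
#' the simulated horizon.
#'
#' @param eps,m solver parameters.
#' @param n grid cells per axis.
#' @param xlim domain (used for both axes).
#' @param t_end final time.
#' @param snapshot_times comparison times.
#' @param semi_axes,edge_width initial ellipse geometry.
#' @param mode level-set speed evaluation mode.
#' @param pde run the PDE too (set `FALSE` for a level-set-only flow).
#' @param cfl_safety,out_dir see [preset_generation_1d()].
#' @return list with `run` (`pm_run` or NULL), `lsrun` (`pm_lsrun`),
#'   `hausdorff` (data frame time/distance, when `pde`), `hull_ratio`
#'   (per snapshot), `params`, `grid`, `k`, `manifest`.
#' @export
preset_cavity_2d <- function(eps = 0.1, m = 2, n = 128, xlim = c(-9, 9),
                             t_end = 3, snapshot_times = 1:3,
                             semi_axes = c(1.0, 3.5), edge_width = 0.3,
                             mode = "local", pde = TRUE, cfl_safety = 0.8,
                             out_dir = NULL) {
  g <- grid_2d(xlim, xlim, n, n)
  k <- k_polar_2d(g)
  u0 <- u0_ellipse_2d(g, c(0, 0), semi_axes, edge_width)
  params <- speed_params(m)
  ls0 <- levelset_init(g, u0$signed_distance)
  lsrun <- levelset_evolve_2d(ls0, k, params, t_end,
                              snapshot_times = snapshot_times, mode = mode)
  run <- NULL
  hdf <- NULL
  if (pde) {
    run <- evolve(pde_init(u0, k, eps, m),
                  solver_config(t_end, snapshot_times = snapshot_times,
                                cfl_safety = cfl_safety))
    hdf <- do.call(rbind, lapply(seq_along(lsrun$times), function(i) {
      t <- lsrun$times[i]
      j <- which.min(abs(run$times - t))
      ctr <- interface_from_field_2d(run$snapshots[[j]]$u, g)
      if (nrow(ctr) == 0) return(NULL)
      data.frame(time = t,
                 hausdorff = hausdorff_distance(
                   ctr, levelset_front(lsrun$snapshots[[i]])))
    }))
  }
  hull <- vapply(lsrun$snapshots, function(s)
    hull_area_ratio(levelset_front(s)), numeric(1))
  cfg <- list(preset = "cavity_2d", eps = eps, m = m, n = n, xlim = xlim,
              t_end = t_end, snapshot_times = snapshot_times,
              semi_axes = semi_axes, edge_width = edge_width, mode = mode)
  man <- make_manifest(cfg, c0 = params$c0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(hdf))
      utils::write.csv(hdf, file.path(out_dir, "cavity_hausdorff.csv"),
                       row.names = FALSE)
    for (i in seq_along(lsrun$snapshots))
      utils::write.csv(as.data.frame(levelset_front(lsrun$snapshots[[i]])),
                       file.path(out_dir, sprintf("front_t%g.csv",
                                                  lsrun$times[i])),
                       row.names = FALSE)
    write_manifest(man, file.path(out_dir, "cavity_manifest.json"))
    if (pde) plot_cavity_2d(run, lsrun, g, file.path(out_dir, "cavity_2d.png"))
  }
  list(run = run, lsrun = lsrun, hausdorff = hdf,
       hull_ratio = stats::setNames(hull, lsrun$times), params = params,
       grid = g, k = k, u0 = u0, manifest = man)
}

## ratio of convex-hull area to polygon area of a front point set (>= 1;
## meaningfully above 1 only for a nonconvex front)
hull_area_ratio <- function(pts) {
  comp <- if ("comp" %in% colnames(pts)) pts[, "comp"] else rep(1, nrow(pts))
  main <- as.integer(names(which.max(table(comp))))
  P <- pts[comp == main, 1:2, drop = FALSE]
  hull <- P[grDevices::chull(P), , drop = FALSE]
  polygon_area(hull) / polygon_area(P)
}

polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  n <- nrow(P)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' eps-refinement convergence table (1-d)
#'
#' For each eps, runs the ramp-landscape experiment to `t_end` and records
#' the transition-layer width, the front-position error against the limit
#' ODE, the sup-bound excess `max(u) - 1`, and the smallest propagation
#' factor `M_P`.  The theory predicts width and front error of order eps and
#' excess of order eps^2.
#'
#' @param eps_values eps values (at least 3).
#' @param t_end measurement time.
#' @param m,h,xlim,cfl_safety solver parameters.
#' @return data frame with one row per eps.
#' @export
preset_convergence_1d <- function(eps_values = c(0.4, 0.2, 0.1), t_end = 2,
                                  m = 2, h = 0.01, xlim = c(-4, 8),
                                  cfl_safety = 0.8) {
  if (length(eps_values) < 3) stop("need at least 3 eps values")
  g <- grid_1d(xlim, round(diff(xlim) / h))
  k <- k_ramp_1d(g)
  u0 <- u0_step_1d(g)
  params <- speed_params(m)
  limit <- front_ode_1d(0, k, params, t_end, dt = t_end / 800)
  x_lim_end <- limit$positions[length(limit$positions)]
  do.call(rbind, lapply(eps_values, function(eps) {
    run <- evolve(pde_init(u0, k, eps, m),
                  solver_config(t_end, snapshot_times = t_end,
                                cfl_safety = cfl_safety))
    u <- run$snapshots[[length(run$snapshots)]]$u
    xf <- as.numeric(front_position_1d(u, g))
    pc <- propagation_check(run, limit)
    data.frame(eps = eps,
               layer_width = layer_width_1d(u, g),
               front_error = abs(xf - x_lim_end),
               sup_excess = run$max_u - 1,
               M_P = pc$M_star)
  }))
}

make_manifest <- function(config, ...) {
  extra <- list(...)
  cfgjson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfgjson, tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  c(list(package = "pmfront",
         version = as.character(utils::packageVersion("pmfront")),
         config = config, config_md5 = h),
    extra)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
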