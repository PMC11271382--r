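#' Plain-text export and configuration
#'
#' Snapshots, fields and fronts are serialized as CSV (wide profiles in 1-d,
#' long tables in 2-d), run metadata as JSON, and preset configuration is
#' read from YAML.  These formats keep every artifact human-readable and
#' diffable.
#'
#' @name io
NULL

#' Write a 1-d run as CSV
#'
#' Columns: `x`, then one `u_t<time>` column per snapshot.
#'
#' @param run a 1-d `pm_run`.
#' @param file output path.
#' @export
write_run_csv <- function(run, file) {
  stopifnot(inherits(run, "pm_run"), run$grid$dims == 1L)
  df <- data.frame(x = run$grid$x)
  for (s in run$snapshots) df[[sprintf("u_t%g", s$t)]] <- s$u
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a 2-d snapshot as long-format CSV
#'
#' Columns `x`, `y`, `u`.
#'
#' @param run a 2-d `pm_run`.
#' @param time snapshot time (nearest stored).
#' @param file output path.
#' @export
write_snapshot_csv <- function(run, time, file) {
  stopifnot(inherits(run, "pm_run"), run$grid$dims == 2L)
  i <- which.min(abs(run$times - time))
  g <- run$grid
  df <- data.frame(x = rep(g$x, times = g$ny), y = rep(g$y, each = g$nx),
                   u = c(run$snapshots[[i]]$u))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a field (carrying capacity or initial density) as CSV
#'
#' 1-d: columns `x`, `value`; 2-d: long format `x`, `y`, `value`.
#'
#' @param field a `pm_kfield` or `pm_u0`.
#' @param file output path.
#' @export
write_field_csv <- function(field, file) {
  g <- field$grid
  df <- if (g$dims == 1L) {
    data.frame(x = g$x, value = field$values)
  } else {
    data.frame(x = rep(g$x, times = g$ny), y = rep(g$y, each = g$nx),
               value = c(field$values))
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a wave profile as CSV (columns z, U)
#'
#' @param profile a `pm_wave`.
#' @param file output path.
#' @export
write_wave_csv <- function(profile, file) {
  stopifnot(inherits(profile, "pm_wave"))
  utils::write.csv(data.frame(z = profile$z, U = profile$U), file,
                   row.names = FALSE)
  invisible(file)
}

#' Read a preset configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; missing keys keep the
#' preset defaults.
#'
#' @param path YAML file.
#' @param allowed character vector of permitted keys (default: common preset
#'   arguments).
#' @return named list of overrides.
#' @export
read_config <- function(path,
                        allowed = c("preset", "eps", "eps_values", "m", "h",
                                    "n", "xlim", "t_end", "snapshot_times",
                                    "cfl_safety", "semi_axes", "edge_width",
                                    "mode", "out_dir")) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}

## ---- figure helpers (base graphics, written only when out_dir is set) ----

plot_run_1d <- function(run, file) {
  grDevices::png(file, width = 900, height = 560)
  on.exit(grDevices::dev.off())
  g <- run$grid
  cols <- grDevices::hcl.colors(length(run$snapshots), "Dark 3")
  graphics::plot(NULL, xlim = g$xlim, ylim = c(0, 1.15), xlab = "x",
                 ylab = "u", main = sprintf("u(x, t), eps = %g", run$eps))
  for (i in seq_along(run$snapshots))
    graphics::lines(g$x, run$snapshots[[i]]$u, col = cols[i], lwd = 2)
  graphics::legend("topright", legend = sprintf("t = %g", run$times),
                   col = cols, lwd = 2, bty = "n")
  invisible(file)
}

plot_propagation_1d <- function(runs, grid, x_limit, file) {
  grDevices::png(file, width = 900, height = 560)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(length(runs), "Dark 3")
  graphics::plot(NULL, xlim = grid$xlim, ylim = c(0, 1.15), xlab = "x",
                 ylab = "u", main = "u(x, t_end) vs sharp-interface limit")
  for (i in seq_along(runs)) {
    s <- runs[[i]]$snapshots[[length(runs[[i]]$snapshots)]]
    graphics::lines(grid$x, s$u, col = cols[i], lwd = 2)
  }
  graphics::segments(grid$xlim[1], 1, x_limit, 1, col = "purple", lwd = 2)
  graphics::segments(x_limit, 1, x_limit, 0, col = "purple", lwd = 2)
  graphics::segments(x_limit, 0, grid$xlim[2], 0, col = "purple", lwd = 2)
  graphics::legend("topright",
                   legend = c(names(runs), "limit step"),
                   col = c(cols, "purple"), lwd = 2, bty = "n")
  invisible(file)
}

plot_cavity_2d <- function(run, lsrun, grid, file) {
  grDevices::png(file, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  n <- length(lsrun$snapshots)
  graphics::par(mfrow = c(ceiling(n / 2), 2), mar = c(2, 2, 2, 1))
  for (i in seq_len(n)) {
    t <- lsrun$times[i]
    j <- which.min(abs(run$times - t))
    graphics::image(grid$x, grid$y, run$snapshots[[j]]$u,
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                    main = sprintf("t = %g", t), xlab = "", ylab = "")
    fr <- levelset_front(lsrun$snapshots[[i]])
    for (cc in unique(fr[, "comp"])) {
      P <- fr[fr[, "comp"] == cc, , drop = FALSE]
      graphics::lines(P[, 1], P[, 2], col = "purple", lwd = 2)
    }
  }
  invisible(file)
}
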