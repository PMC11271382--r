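#' Front extraction, speeds, and interface-theorem checks
#'
#' Tools that connect the perturbed PDE solutions with the sharp-interface
#' limit: locating the transition layer at a fixed level (default 1/2 — any
#' fixed level in (0,1) converges to the interface, 1/2 is symmetric),
#' least-squares front speeds, marching-squares contours, Hausdorff
#' distances, and quantitative checks of the generation and propagation
#' envelopes.  "Equals zero" statements of the limit theory are tested as
#' `u <= 1e-10`: the degenerate diffusion preserves exact zeros, so the
#' tolerance only absorbs rounding.
#'
#' @name diagnostics
NULL

#' Locate the 1-d transition layer
#'
#' Linearly interpolated crossing of `u` through `level`.  With several
#' crossings the outermost one in the scan direction is returned with
#' attribute `multiple = TRUE`; with none, `NA` with attribute
#' `status = "absent"`.
#'
#' @param u density profile (vector on the grid).
#' @param grid a 1-d `pm_grid`.
#' @param level threshold in (0, 1), default 1/2.
#' @param direction scan direction: `"right"` takes the rightmost crossing.
#' @return crossing coordinate (possibly `NA`).
#' @export
front_position_1d <- function(u, grid, level = 0.5,
                              direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(grid$dims == 1L, length(u) == grid$nx, level > 0, level < 1)
  s <- u - level
  up <- s >= 0
  cross <- which(up[-length(up)] != up[-1])
  if (length(cross) == 0)
    return(structure(NA_real_, status = "absent"))
  i <- if (direction == "right") cross[length(cross)] else cross[1]
  x <- grid$x[i] + grid$h * s[i] / (s[i] - s[i + 1])
  if (length(cross) > 1) attr(x, "multiple") <- TRUE
  x
}

#' Least-squares front speed
#'
#' Slope of position against time over a fit window (default: the last half
#' of the series, skipping the interface-generation phase).
#'
#' @param times,positions numeric vectors, or a `pm_traj` as first argument.
#' @param window length-2 time interval to fit in.
#' @return list of class `pm_speedfit` with `slope`, `intercept`, `window`,
#'   `residual_rms`, `n`.
#' @export
estimate_speed <- function(times, positions = NULL, window = NULL) {
  if (inherits(times, "pm_traj")) {
    positions <- times$positions
    times <- times$times
  }
  stopifnot(length(times) == length(positions))
  if (is.null(window)) window <- c((min(times) + max(times)) / 2, max(times))
  sel <- times >= window[1] & times <= window[2] & is.finite(positions)
  if (sum(sel) < 5) stop("fit window must contain at least 5 samples")
  fit <- stats::lm.fit(cbind(1, times[sel]), positions[sel])
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 window = window,
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 n = sum(sel)),
            class = "pm_speedfit")
}

#' Extract a 2-d level contour as a point set
#'
#' Marching-squares contour of `{u = level}`.
#'
#' @param u density matrix.
#' @param grid a 2-d `pm_grid`.
#' @param level contour level in (0, 1).
#' @return matrix with columns `x`, `y`, `comp` (connected component id);
#'   zero rows with attribute `status = "empty"` when the level is not
#'   attained.
#' @export
interface_from_field_2d <- function(u, grid, level = 0.5) {
  stopifnot(grid$dims == 2L, level > 0, level < 1)
  cl <- grDevices::contourLines(grid$x, grid$y, u, levels = level)
  if (length(cl) == 0)
    return(structure(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "comp"))),
                     status = "empty"))
  do.call(rbind, lapply(seq_along(cl), function(i)
    cbind(x = cl[[i]]$x, y = cl[[i]]$y, comp = i)))
}

#' Symmetric Hausdorff distance between point sets
#'
#' @param A,B matrices of points (rows), using the first two columns.
#' @return the Hausdorff distance.
#' @export
hausdorff_distance <- function(A, B) {
  A <- as.matrix(A)[, 1:2, drop = FALSE]
  B <- as.matrix(B)[, 1:2, drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) stop("point sets must be nonempty")
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

## distance from every cell to the support of an initial density
dist_to_support <- function(u0) {
  g <- u0$grid
  m <- u0$support_mask
  if (!any(m)) stop("empty support")
  if (g$dims == 1L) {
    xs <- g$x[m]
    lo <- min(xs); hi <- max(xs)
    pmax(pmax(lo - g$x, g$x - hi), 0)
  } else {
    ## boundary cells of the support: in-support with an out-of-support neighbor
    nx <- g$nx; ny <- g$ny
    nb <- m[c(1, seq_len(nx - 1)), ] & m[c(seq_len(nx)[-1], nx), ] &
      m[, c(1, seq_len(ny - 1))] & m[, c(seq_len(ny)[-1], ny)]
    bnd <- m & !nb
    bx <- rep(g$x, times = ny)[bnd]
    by <- rep(g$y, each = nx)[bnd]
    px <- rep(g$x, times = ny)
    py <- rep(g$y, each = nx)
    d2 <- rep(Inf, length(px))
    for (i in seq_along(bx)) d2 <- pmin(d2, (px - bx[i])^2 + (py - by[i])^2)
    d <- matrix(sqrt(d2), nx, ny)
    d[m] <- 0
    d
  }
}

#' Check the interface-generation envelopes
#'
#' At the generation time `t_eps = eps |ln eps|` the solution must satisfy,
#' for some finite factor M: (i) the sup bound `u <= 1 + eta_eps + tol`,
#' (ii) `u >= 1 - eta_g` wherever `u0 >= M eps`, and (iii) `u <= 1e-10`
#' wherever `dist(x, supp u0) >= M eps`.  M is an existence constant, so the
#' check searches for the smallest value on a grid for which (ii) and (iii)
#' both hold.
#'
#' @param run a `pm_run` containing a snapshot at (or very near) `t_eps`.
#' @param u0 the initial `pm_u0`.
#' @param eta_g level gap in (0, 1).
#' @param M_grid candidate factors, searched in increasing order.
#' @param tol_bound numerical slack on the sup bound.
#' @param zero_tol tolerance standing in for "equals zero".
#' @return list of class `pm_theorem_report` with `sup_bound_ok`,
#'   `generation_ok`, `M_star` (smallest passing factor, NA if none),
#'   `eta_eps`, `t_eps`, `max_u`.
#' @export
generation_check <- function(run, u0, eta_g = 0.1,
                             M_grid = seq(0.5, 40, by = 0.5),
                             tol_bound = 1e-2, zero_tol = 1e-10) {
  stopifnot(inherits(run, "pm_run"), inherits(u0, "pm_u0"))
  eps <- run$eps
  t_eps <- eps * abs(log(eps))
  i <- which.min(abs(run$times - t_eps))
  if (abs(run$times[i] - t_eps) > 0.05 * t_eps + 1e-9)
    stop(sprintf("run has no snapshot near t_eps = %.4f", t_eps))
  u <- run$snapshots[[i]]$u
  eta_eps <- suppressWarnings(sup_bound_eta(run$k, run$m, eps))
  sup_ok <- run$max_u <= 1 + eta_eps + tol_bound
  dsup <- dist_to_support(u0)
  M_star <- NA_real_
  for (M in sort(M_grid)) {
    interior <- u0$values >= M * eps
    exterior <- dsup >= M * eps
    ok_in <- !any(interior) || all(u[interior] >= 1 - eta_g)
    ok_out <- !any(exterior) || all(u[exterior] <= zero_tol)
    if (ok_in && ok_out) { M_star <- M; break }
  }
  structure(list(sup_bound_ok = sup_ok, generation_ok = !is.na(M_star),
                 M_star = M_star, eta_eps = eta_eps, t_eps = t_eps,
                 max_u = run$max_u),
            class = "pm_theorem_report")
}

## signed distance to the limit interface at time t
## 1-d: right-moving front, invaded region on the left
signed_distance_limit_1d <- function(traj, t, grid) {
  xf <- stats::approx(traj$times, traj$positions, xout = t)$y
  if (traj$direction == "right") xf - grid$x else grid$x - xf
}

#' Check the interface-propagation envelopes
#'
#' At each matched time `t > t_eps`, the solution must satisfy
#' `u >= 1 - eta_p` on `{d >= M eps}` and `u <= 1e-10` on `{d <= -M eps}`,
#' with `d` the signed distance to the limit interface (positive inside).
#' The limit may be a 1-d `pm_traj` (right-moving front) or a 2-d
#' `pm_lsrun` whose reinitialized level-set snapshots serve as `d`.
#'
#' @param run a `pm_run`.
#' @param limit a `pm_traj` or `pm_lsrun` with snapshots at the same times.
#' @param eta_p level gap in (0, 1).
#' @inheritParams generation_check
#' @return list of class `pm_theorem_report` with `propagation_ok`,
#'   `M_star_by_time`, `M_star` (largest over checked times), `times`.
#' @export
propagation_check <- function(run, limit, eta_p = 0.1,
                              M_grid = seq(0.5, 40, by = 0.5),
                              zero_tol = 1e-10) {
  stopifnot(inherits(run, "pm_run"))
  eps <- run$eps
  t_eps <- eps * abs(log(eps))
  check_times <- run$times[run$times > t_eps + 1e-12]
  if (length(check_times) == 0) stop("no run snapshots beyond t_eps")
  M_by_t <- vapply(check_times, function(t) {
    i <- which.min(abs(run$times - t))
    u <- run$snapshots[[i]]$u
    d <- if (inherits(limit, "pm_traj")) {
      if (t > max(limit$times) + 1e-9) stop("limit trajectory does not cover t")
      signed_distance_limit_1d(limit, t, run$grid)
    } else if (inherits(limit, "pm_lsrun")) {
      j <- which(abs(limit$times - t) < 1e-6)
      if (length(j) == 0) stop(sprintf("limit has no snapshot at t = %g", t))
      limit$snapshots[[j[1]]]$phi
    } else stop("limit must be a pm_traj or pm_lsrun")
    for (M in sort(M_grid)) {
      inside <- d >= M * eps
      outside <- d <= -M * eps
      ok_in <- !any(inside) || all(u[inside] >= 1 - eta_p)
      ok_out <- !any(outside) || all(u[outside] <= zero_tol)
      if (ok_in && ok_out) return(M)
    }
    NA_real_
  }, numeric(1))
  structure(list(propagation_ok = !anyNA(M_by_t),
                 M_star_by_time = stats::setNames(M_by_t, check_times),
                 M_star = if (anyNA(M_by_t)) NA_real_ else max(M_by_t),
                 times = check_times),
            class = "pm_theorem_report")
}

#' Transition-layer width
#'
#' Distance between the outermost crossings of `u` through `hi` and `lo` in
#' the scan direction; an O(eps) quantity by the propagation theory.
#'
#' @inheritParams front_position_1d
#' @param lo,hi bracketing levels.
#' @return width (possibly `NA` when either level is not crossed).
#' @export
layer_width_1d <- function(u, grid, lo = 0.05, hi = 0.95,
                           direction = "right") {
  x_lo <- front_position_1d(u, grid, lo, direction)
  x_hi <- front_position_1d(u, grid, hi, direction)
  abs(as.numeric(x_lo) - as.numeric(x_hi))
}
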