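#' Sharp-interface limit dynamics
#'
#' In the singular limit the solution becomes a 0/1 step function whose
#' discontinuity set, the interface Gamma_t, moves in its outward normal
#' direction with speed `V_n = c0 * k(x)^p`, `p = (m - 1)/2`.  This module
#' integrates that law directly: as a scalar ODE for front positions in 1-d
#' and as a level-set flow `phi_t = F |grad phi|` in 2-d, with the package's
#' sign convention `phi > 0` inside the invaded region (matching the signed
#' distance d-tilde of the limit theory).  The level-set function is
#' reinitialized to signed distance at a fixed cadence so that `|grad phi|`
#' stays near 1 close to the front.
#'
#' @name interface_flow
NULL

#' Speed-law parameters
#'
#' Bundles the exponent, the minimal wave speed and the derived capacity
#' exponent `p = (m - 1)/2` (the exact relation of the limit law).
#'
#' @param m diffusion exponent.
#' @param c0 minimal wave speed for `k = 1`; computed via
#'   [minimal_wave_speed()] when omitted.
#' @return list of class `pm_speed_params` with `m`, `c0`, `p`.
#' @export
speed_params <- function(m, c0 = NULL) {
  check_exponent(m)
  if (is.null(c0)) c0 <- as.numeric(minimal_wave_speed(m, tol = 1e-6))
  if (c0 <= 0) stop("c0 must be positive")
  structure(list(m = m, c0 = as.numeric(c0), p = (m - 1) / 2),
            class = "pm_speed_params")
}

#' Normal speed of the limit interface
#'
#' `V_n = c0 * k^p` with `p = (m-1)/2`.
#'
#' @param k_value local carrying capacity (positive; vectorized).
#' @param params a [speed_params()] object.
#' @return normal speed(s).
#' @export
speed_law <- function(k_value, params) {
  stopifnot(inherits(params, "pm_speed_params"))
  if (any(k_value <= 0)) stop("carrying capacity must be positive")
  params$c0 * k_value^params$p
}

#' Constant-coefficient front speed
#'
#' For the constant-coefficient equation `U_t = d Lap(U^m) + r U (1 - U/k)`
#' the minimal front speed is `c = c0 * sqrt(d * r * k^(m-1))`.  At `m = 1`
#' the capacity drops out: heterogeneity in k only affects the speed through
#' the nonlinear diffusion.
#'
#' @param d diffusivity, `r` growth rate, `k` capacity (all positive).
#' @param r,k see `d`.
#' @param m diffusion exponent (formula value; no dynamics are computed).
#' @param c0 proportionality constant (minimal speed of the normalized
#'   problem).
#' @return speed.
#' @export
general_speed <- function(d, r, k, m, c0) {
  if (any(c(d, r, k) <= 0)) stop("d, r, k must be positive")
  c0 * sqrt(d * r * k^(m - 1))
}

#' Integrate the 1-d front ODE
#'
#' `dx/dt = +/- c0 k(x)^p` by the classical 4-stage Runge-Kutta method.
#' `k` may be a function of position or a 1-d `pm_kfield` (interpolated
#' linearly, which preserves monotone data).  If the front exits the field's
#' domain the trajectory is truncated and flagged.
#'
#' @param x0 initial front position.
#' @param k function or `pm_kfield`.
#' @param params a [speed_params()].
#' @param t_end final time.
#' @param dt step (must not exceed `t_end/100`).
#' @param direction `"right"` (+) or `"left"` (-).
#' @return object of class `pm_traj`: list with `times`, `positions`,
#'   `direction`, `truncated`.
#' @export
front_ode_1d <- function(x0, k, params, t_end, dt = t_end / 400,
                         direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "pm_speed_params"), t_end > 0)
  if (dt > t_end / 100) stop("dt must not exceed t_end/100")
  if (inherits(k, "pm_kfield")) {
    stopifnot(k$grid$dims == 1L)
    kfun <- stats::approxfun(k$grid$x, k$values, rule = 2)
    xlim <- k$grid$xlim
  } else if (is.function(k)) {
    kfun <- k
    xlim <- c(-Inf, Inf)
  } else stop("k must be a function or a 1-d pm_kfield")
  sgn <- if (direction == "right") 1 else -1
  f <- function(x) sgn * speed_law(kfun(x), params)
  times <- seq(0, t_end, by = dt)
  if (abs(times[length(times)] - t_end) > 1e-12) times <- c(times, t_end)
  xs <- numeric(length(times))
  xs[1] <- x0
  truncated <- FALSE
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1L] - times[i]
    x <- xs[i]
    k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    xn <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (xn < xlim[1] || xn > xlim[2]) {
      times <- times[seq_len(i)]
      xs <- xs[seq_len(i)]
      truncated <- TRUE
      warning("front exited the domain; trajectory truncated", call. = FALSE)
      break
    }
    xs[i + 1L] <- xn
  }
  structure(list(times = times, positions = xs, direction = direction,
                 truncated = truncated),
            class = "pm_traj")
}

#' Level-set state
#'
#' @param grid a 2-d `pm_grid`.
#' @param phi level-set values (`nx` x `ny`), positive inside the invaded
#'   region; ideally an approximate signed distance.
#' @param reinit_every reinitialization cadence in steps.
#' @return object of class `pm_levelset`.
#' @export
levelset_init <- function(grid, phi, reinit_every = 10L) {
  stopifnot(inherits(grid, "pm_grid"), grid$dims == 2L,
            is.matrix(phi), nrow(phi) == grid$nx, ncol(phi) == grid$ny)
  structure(list(grid = grid, phi = phi, t = 0, reinit_every = as.integer(reinit_every)),
            class = "pm_levelset")
}

#' Reinitialize a level-set function to signed distance
#'
#' Extracts the zero level set by marching squares (bilinear contouring) and
#' replaces `phi` by the exact distance to the resulting polyline, signed by
#' the current sign of `phi`.  The zero crossing of the bilinear interpolant
#' is preserved to within a cell.
#'
#' @param ls a `pm_levelset` whose `phi` changes sign.
#' @return the reinitialized `pm_levelset`.
#' @export
reinitialize <- function(ls) {
  stopifnot(inherits(ls, "pm_levelset"))
  g <- ls$grid
  if (all(ls$phi >= 0) || all(ls$phi <= 0))
    stop("phi does not change sign; no zero level set to reinitialize")
  segs <- zero_segments(ls$phi, g)
  px <- rep(g$x, times = g$ny)
  py <- rep(g$y, each = g$nx)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    d2 <- pmin(d2, .seg_dist2(px, py, segs[i, 1], segs[i, 2],
                              segs[i, 3], segs[i, 4]))
  }
  ls$phi <- matrix(sqrt(d2), g$nx, g$ny) * ifelse(ls$phi >= 0, 1, -1)
  ls
}

## zero-contour of phi as a segment list (x0, y0, x1, y1 per row)
zero_segments <- function(phi, grid) {
  cl <- grDevices::contourLines(grid$x, grid$y, phi, levels = 0)
  if (length(cl) == 0) stop("empty zero level set")
  do.call(rbind, lapply(cl, function(comp) {
    n <- length(comp$x)
    if (n < 2) return(NULL)
    cbind(comp$x[-n], comp$y[-n], comp$x[-1], comp$y[-1])
  }))
}

#' Zero level set as a point set
#'
#' @param ls a `pm_levelset`.
#' @return two-column matrix of contour points (marching-squares vertices).
#' @export
levelset_front <- function(ls) {
  cl <- grDevices::contourLines(ls$grid$x, ls$grid$y, ls$phi, levels = 0)
  if (length(cl) == 0) stop("empty zero level set")
  do.call(rbind, lapply(seq_along(cl), function(i)
    cbind(x = cl[[i]]$x, y = cl[[i]]$y, comp = i)))
}

#' Evolve the 2-d interface by the heterogeneous speed law
#'
#' Advances `phi_t = F |grad phi|` (outward motion, `phi > 0` inside) with
#' first-order Godunov upwinding; since `F = c0 k^p > 0` everywhere the
#' upwind direction is always outward.  The speed field is evaluated either
#' at the cell (`mode = "local"`) or at the closest-front-point footprint
#' `x - phi grad(phi)` (`mode = "footpoint"`, the form the signed-distance
#' PDE of the limit theory takes off the front); the two coincide on the
#' front itself.  `phi` is reinitialized to signed distance every
#' `reinit_every` steps and before every stored snapshot.
#'
#' @param ls initial `pm_levelset` (approximate signed distance).
#' @param k a 2-d `pm_kfield` on the same grid.
#' @param params a [speed_params()].
#' @param t_end final time.
#' @param snapshot_times times to store (always includes `t_end`).
#' @param mode speed evaluation mode, `"local"` or `"footpoint"`.
#' @param cfl time-step fraction of `h / max(F)`.
#' @param allow_boundary_contact keep going when the zero level set comes
#'   within 3 cells of the domain boundary (default stops with a flag, since
#'   the limit law is only meaningful while the interface stays inside).
#' @return object of class `pm_lsrun`: list with `times`, `snapshots` (each
#'   a reinitialized `pm_levelset`), `stopped_at_boundary`, `n_steps`.
#' @export
levelset_evolve_2d <- function(ls, k, params, t_end, snapshot_times = NULL,
                               mode = c("local", "footpoint"), cfl = 0.5,
                               allow_boundary_contact = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(ls, "pm_levelset"), inherits(k, "pm_kfield"),
            inherits(params, "pm_speed_params"), k$grid$dims == 2L)
  g <- ls$grid
  Floc <- speed_law(k$values, params)
  dt0 <- cfl * min(g$h) / max(Floc)
  phi <- ls$phi
  t <- ls$t
  snap_times <- sort(unique(c(snapshot_times, t_end)))
  snap_times <- snap_times[snap_times > t + 1e-12]
  snaps <- list()
  times <- numeric(0)
  stopped <- FALSE
  n_steps <- 0L
  step_in_cycle <- 0L
  nx <- g$nx; ny <- g$ny
  while (t < t_end - 1e-12 && !stopped) {
    dt <- min(dt0, (snap_times[snap_times > t + 1e-12][1] %||% t_end) - t)
    F <- if (mode == "local") Floc else footpoint_speed(phi, k, params)
    ## Godunov upwind on psi = -phi (standard F > 0 outward expansion form)
    psi <- -phi
    Dmx <- (psi - psi[c(1, seq_len(nx - 1)), ]) / g$h[1]
    Dpx <- (psi[c(seq_len(nx)[-1], nx), ] - psi) / g$h[1]
    Dmy <- (psi - psi[, c(1, seq_len(ny - 1))]) / g$h[2]
    Dpy <- (psi[, c(seq_len(ny)[-1], ny)] - psi) / g$h[2]
    gradmag <- sqrt(pmax(Dmx, 0)^2 + pmin(Dpx, 0)^2 +
                    pmax(Dmy, 0)^2 + pmin(Dpy, 0)^2)
    phi <- -(psi - dt * F * gradmag)
    t <- t + dt
    n_steps <- n_steps + 1L
    step_in_cycle <- step_in_cycle + 1L
    at_snap <- any(abs(snap_times - t) < 1e-9)
    if (step_in_cycle >= ls$reinit_every || at_snap) {
      tmp <- levelset_init(g, phi, ls$reinit_every)
      phi <- reinitialize(tmp)$phi
      step_in_cycle <- 0L
    }
    if (!allow_boundary_contact && boundary_contact(phi, 3L)) {
      stopped <- TRUE
      warning(sprintf("zero level set within 3 cells of the boundary at t = %.3f; stopping",
                      t), call. = FALSE)
    }
    if (at_snap || stopped) {
      s <- levelset_init(g, phi, ls$reinit_every)
      s$t <- t
      snaps[[length(snaps) + 1L]] <- s
      times <- c(times, t)
      snap_times <- snap_times[abs(snap_times - t) >= 1e-9]
    }
  }
  structure(list(times = times, snapshots = snaps,
                 stopped_at_boundary = stopped, n_steps = n_steps),
            class = "pm_lsrun")
}

`%||%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a

## does the invaded region (phi > 0) reach the outer `width`-cell frame?
boundary_contact <- function(phi, width) {
  nx <- nrow(phi); ny <- ncol(phi)
  idx <- c(seq_len(width), nx - seq_len(width) + 1L)
  idy <- c(seq_len(width), ny - seq_len(width) + 1L)
  any(phi[idx, ] > 0) || any(phi[, idy] > 0)
}

## speed at the closest front point x - phi grad(phi), bilinear k lookup
footpoint_speed <- function(phi, k, params) {
  g <- k$grid
  gr <- grad_central(phi, g)
  ## normalize so the footpoint uses a unit normal even off signed distance
  nrm <- pmax(sqrt(gr$gx^2 + gr$gy^2), 1e-12)
  fx <- rep(g$x, times = g$ny) - c(phi) * c(gr$gx / nrm)
  fy <- rep(g$y, each = g$nx) - c(phi) * c(gr$gy / nrm)
  fx <- pmin(pmax(fx, g$xlim[1] + g$h[1] / 2), g$xlim[2] - g$h[1] / 2)
  fy <- pmin(pmax(fy, g$ylim[1] + g$h[2] / 2), g$ylim[2] - g$h[2] / 2)
  kv <- bilinear_at(k$values, g, fx, fy)
  matrix(speed_law(kv, params), g$nx, g$ny)
}

## bilinear interpolation of a cell-centered field at arbitrary points
bilinear_at <- function(vals, grid, qx, qy) {
  ix <- pmin(pmax(floor((qx - grid$x[1]) / grid$h[1]) + 1L, 1L), grid$nx - 1L)
  iy <- pmin(pmax(floor((qy - grid$y[1]) / grid$h[2]) + 1L, 1L), grid$ny - 1L)
  tx <- pmin(pmax((qx - grid$x[ix]) / grid$h[1], 0), 1)
  ty <- pmin(pmax((qy - grid$y[iy]) / grid$h[2], 0), 1)
  i00 <- cbind(ix, iy); i10 <- cbind(ix + 1L, iy)
  i01 <- cbind(ix, iy + 1L); i11 <- cbind(ix + 1L, iy + 1L)
  (1 - tx) * (1 - ty) * vals[i00] + tx * (1 - ty) * vals[i10] +
    (1 - tx) * ty * vals[i01] + tx * ty * vals[i11]
}

#' Cut-off distance function
#'
#' A monotone C^2 cut-off: the identity on `[-d0, d0]`, constant `+/- 2 d0`
#' outside `[-2 d0, 2 d0]`, joined by a quintic Hermite blend with matching
#' value, first and second derivative at both band edges.
#'
#' @param s signed distance value(s).
#' @param d0 cut-off scale (positive).
#' @return cut-off value(s).
#' @export
cutoff_distance <- function(s, d0) {
  if (d0 <= 0) stop("d0 must be positive")
  a <- abs(s)
  ## quintic blend g on [0,1]: g(0)=0, g'(0)=1, g''(0)=0, g(1)=1, g'(1)=g''(1)=0
  tt <- pmin(pmax((a - d0) / d0, 0), 1)
  gblend <- tt + 4 * tt^3 - 7 * tt^4 + 3 * tt^5
  out <- ifelse(a <= d0, a, ifelse(a >= 2 * d0, 2 * d0, d0 * (1 + gblend)))
  sign(s) * out
}
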