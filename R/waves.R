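#' Sharp traveling waves of the homogeneous porous-medium KPP equation
#'
#' The homogeneous 1-d equation `v_t = (v^m)_xx + v(1 - v)` admits, for each
#' diffusion exponent `m > 1`, a unique (up to translation) traveling wave of
#' minimal speed `c0(m)` whose support is a half line: the wave vanishes
#' identically behind a sharp front.  In the wave coordinate `z` (front at
#' `z = 0`, wave increasing to 1 as `z -> infinity`) the profile solves
#'
#'   (U^m)_zz - c0 U_z + U(1 - U) = 0,  U(z) = 0 for z <= 0.
#'
#' The minimal speed is located by phase-plane shooting in `(U, P)` with
#' `P = (U^m)_z`: along the unstable manifold of the saddle `(1, 0)` the
#' trajectory is integrated down in `U`; for `c > c0` the flux `P` hits zero
#' at positive `U`, for `c < c0` it reaches `U -> 0` with `P/U` bounded away
#' from `c` (wrong front slope), and `c0` is the boundary between the two
#' regimes, found by bisection.
#'
#' @name waves
NULL

## cache for computed minimal speeds (keyed by m), and for profiles
.pm_cache <- new.env(parent = emptyenv())

check_exponent <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || !is.finite(m))
    stop("m must be a finite numeric scalar")
  if (m <= 1)
    stop("diffusion exponent m must exceed 1 (m = 1 is linear diffusion)")
  if (m < 2)
    warning("m in (1, 2) is outside the m >= 2 regime; proceeding anyway",
            call. = FALSE)
  invisible(m)
}

## One phase-plane shot: integrate dP/dU = c - m U^m (1-U)/P from the saddle
## (1,0) down to u_min with fixed-step RK4 on a log-spaced U grid.
## Returns hit = TRUE when P reaches the floor at U > u_min (c too large).
## With store = TRUE also returns the (U, P) trajectory.
shoot_wave <- function(cc, m, n_steps = 4000L, u_min = 1e-8,
                       p_floor = 1e-12, store = FALSE) {
  s0 <- 1e-6
  Ugrid <- sort(unique(c(
    1 - 10^seq(log10(s0), log10(0.5), length.out = n_steps %/% 4),
    seq(0.5, 0.01, length.out = n_steps %/% 2),
    10^seq(log10(0.01), log10(u_min), length.out = n_steps %/% 4))),
    decreasing = TRUE)
  a <- (-cc + sqrt(cc^2 + 4 * m)) / 2      # unstable-manifold slope at U = 1
  P <- a * s0
  Pout <- if (store) c(P, numeric(length(Ugrid) - 1L)) else NULL
  g <- function(U, P) cc - m * U^m * (1 - U) / P
  for (i in seq_len(length(Ugrid) - 1L)) {
    h <- Ugrid[i + 1L] - Ugrid[i]
    U <- Ugrid[i]
    k1 <- g(U, P)
    k2 <- g(U + h / 2, P + h / 2 * k1)
    k3 <- g(U + h / 2, P + h / 2 * k2)
    k4 <- g(U + h, P + h * k3)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(P) || P <= p_floor)
      return(list(hit = TRUE, U_stop = Ugrid[i + 1L], P_end = P))
    if (store) Pout[i + 1L] <- P
  }
  out <- list(hit = FALSE, U_stop = u_min, P_end = P)
  if (store) { out$U <- Ugrid; out$P <- Pout; out$slope_a <- a }
  out
}

#' Minimal traveling-wave speed c0(m)
#'
#' @param m diffusion exponent (`m >= 2`; values in (1, 2) proceed with a
#'   warning, `m <= 1` is rejected).
#' @param tol bisection tolerance on the speed; the shooting criterion is
#'   certified to change sign across `c0 +/- tol`.
#' @param bracket initial speed bracket for the bisection.
#' @return the minimal speed (scalar), with the certified bracket attached as
#'   attribute `"bracket"`.
#' @examples
#' minimal_wave_speed(2)         # 1 to within the shooting tolerance
#' @export
minimal_wave_speed <- function(m, tol = 1e-4, bracket = c(0.02, 6)) {
  check_exponent(m)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  res <- find_c0(m, tol, n_steps = 4000L, bracket = bracket)
  ## certify the returned bracket at +/- tol
  if (shoot_wave(max(res$c0 - tol, 1e-6), m)$hit ||
      !shoot_wave(res$c0 + tol, m)$hit)
    stop("bracket certification failed near the returned speed")
  structure(res$c0, bracket = c(res$c0 - tol, res$c0 + tol))
}

## bisection for the minimal speed at a fixed shooting discretization;
## lo is certified "no hit" and hi "hit" for that discretization
find_c0 <- function(m, tol, n_steps, bracket = c(0.02, 6)) {
  key <- sprintf("c0_%.12g_%g_%d_%g_%g", m, tol, n_steps,
                 bracket[1], bracket[2])
  if (!is.null(.pm_cache[[key]])) return(.pm_cache[[key]])
  lo <- bracket[1]; hi <- bracket[2]
  if (shoot_wave(lo, m, n_steps)$hit || !shoot_wave(hi, m, n_steps)$hit)
    stop(sprintf(paste("bracket failure: shooting criterion does not change",
                       "sign on [%g, %g]"), lo, hi))
  target <- min(tol, 1e-6) / 4
  while (hi - lo > target) {
    mid <- (lo + hi) / 2
    if (shoot_wave(mid, m, n_steps)$hit) hi <- mid else lo <- mid
  }
  .pm_cache[[key]] <- list(c0 = (lo + hi) / 2, lo = lo, hi = hi)
  .pm_cache[[key]]
}

#' Sharp minimal-speed wave profile
#'
#' Reconstructs the minimal-speed profile on a uniform `z` grid, anchored so
#' that the support edge sits exactly at `z = 0`.  The phase-plane trajectory
#' `P(U)` is converted to `z(U)` by quadrature of `dz/dU = m U^(m-1) / P`,
#' using the sharp-front local behavior `U ~ ((m-1) c0 z / m)^(1/(m-1))` to
#' anchor the lower end, and the saddle linearization for the exponential
#' approach to 1 beyond the last tabulated point.  Values at the requested
#' nodes come from a monotone spline in the variable `U^(m-1)` (linear in `z`
#' at the front, so the interpolation is uniformly accurate).
#'
#' @inheritParams minimal_wave_speed
#' @param zmax extent of the profile (`>= 20`).
#' @param n number of uniform samples on `[0, zmax]` (`>= 100`).
#' @param c0 optionally, a precomputed minimal speed to reuse.
#' @return object of class `pm_wave`: list with `m`, `c` (the minimal speed),
#'   `z`, `U`.
#' @export
wave_profile <- function(m, zmax = 40, n = 4000L, c0 = NULL) {
  check_exponent(m)
  stopifnot(n >= 100, zmax >= 20)
  if (is.null(c0)) {
    res <- find_c0(m, tol = 1e-7, n_steps = 12000L)
    c0 <- res$c0
    c_shoot <- res$lo       # certified connecting side for this discretization
  } else {
    c_shoot <- c0
  }
  tr <- shoot_wave(c_shoot, m, n_steps = 12000L, store = TRUE)
  if (tr$hit) stop("non-convergent shooting at the returned minimal speed")
  o <- order(tr$U)
  Us <- tr$U[o]; Ps <- tr$P[o]
  ## z(U) by cumulative trapezoid, anchored by the front asymptote at Us[1]
  z_tab <- pracma::cumtrapz(Us, m * Us^(m - 1) / Ps)[, 1] +
    (m / ((m - 1) * c0)) * Us[1]^(m - 1)
  ## monotone spline of Y = U^(m-1) against z
  fitY <- stats::splinefun(z_tab, Us^(m - 1), method = "hyman")
  z <- seq(0, zmax, length.out = n)
  U <- numeric(n)
  inrange <- z > z_tab[1] & z <= z_tab[length(z_tab)]
  U[inrange] <- pmin(fitY(z[inrange]), 1)^(1 / (m - 1))
  ## front asymptote below the tabulated range
  lowz <- z > 0 & z <= z_tab[1]
  U[lowz] <- ((m - 1) * c0 * z[lowz] / m)^(1 / (m - 1))
  ## exponential tail beyond the tabulated range: U = 1 - s_c e^{-beta (z - z_c)}
  tail <- z > z_tab[length(z_tab)]
  if (any(tail)) {
    beta <- tr$slope_a / m
    s_c <- 1 - Us[length(Us)]
    U[tail] <- 1 - s_c * exp(-beta * (z[tail] - z_tab[length(z_tab)]))
  }
  structure(list(m = m, c = as.numeric(c0), z = z, U = U), class = "pm_wave")
}

#' @export
print.pm_wave <- function(x, ...) {
  cat(sprintf("<pm_wave m = %g, c0 = %.6f, %d samples on [0, %g]>\n",
              x$m, x$c, length(x$z), max(x$z)))
  invisible(x)
}

#' Closed-form minimal wave for m = 2
#'
#' For `m = 2` the minimal-speed wave has the closed form
#' `U(z) = max(0, 1 - exp(-z/2))` with speed `c0 = 1` (substitution into the
#' wave equation gives an identically zero residual).  Used as an independent
#' oracle for the shooting construction.
#'
#' @param z coordinate(s).
#' @return density value(s).
#' @export
exact_wave_m2 <- function(z) pmax(0, 1 - exp(-z / 2))

#' Two-parameter perturbed-wave family
#'
#' The family `V(z; delta, zeta) = (1 + delta) U((1 + delta)^(1 - m/2) zeta z)`
#' rescales the minimal wave in amplitude and space; it satisfies the
#' perturbed wave equation with speed `c(delta, zeta) = c0 (1+delta)^(m/2) zeta`
#' and is the building block of the sub/supersolutions that sandwich the
#' transition layer.  `V` vanishes for `z <= 0` and approaches `1 + delta`;
#' beyond the sampled range of the profile the asymptote `1 + delta` is used.
#'
#' @param profile a minimal-speed `pm_wave` from [wave_profile()].
#' @param delta amplitude perturbation, `|delta| < 1/2`.
#' @param zeta positive spatial rescaling.
#' @param z coordinate(s).
#' @return density value(s).
#' @export
perturbed_wave <- function(profile, delta, zeta, z) {
  stopifnot(inherits(profile, "pm_wave"))
  check_perturbation(delta, zeta)
  arg <- (1 + delta)^(1 - profile$m / 2) * zeta * z
  out <- numeric(length(z))
  pos <- arg > 0
  if (any(pos)) {
    fit <- wave_interpolant(profile)
    out[pos] <- (1 + delta) * fit(arg[pos])
  }
  out
}

check_perturbation <- function(delta, zeta) {
  if (abs(delta) >= 0.5) stop("|delta| must be below 1/2")
  if (zeta <= 0) stop("zeta must be positive")
  invisible(NULL)
}

## monotone interpolant of a wave profile, asymptote 1 beyond the range
wave_interpolant <- function(profile) {
  Y <- profile$U^(profile$m - 1)
  sf <- stats::splinefun(profile$z, Y, method = "monoH.FC")
  zmax <- max(profile$z)
  mm <- profile$m
  function(z) {
    v <- numeric(length(z))
    inr <- z <= zmax
    v[inr] <- pmin(pmax(sf(z[inr]), 0), 1)^(1 / (mm - 1))
    v[!inr] <- 1
    v
  }
}

#' Speed of a perturbed wave
#'
#' `c(delta, zeta) = c0 (1 + delta)^(m/2) zeta`.
#'
#' @inheritParams perturbed_wave
#' @param m diffusion exponent.
#' @param c0 minimal speed of the unperturbed wave.
#' @return speed (scalar).
#' @export
perturbed_speed <- function(delta, zeta, m, c0) {
  check_perturbation(delta, zeta)
  if (c0 <= 0) stop("c0 must be positive")
  c0 * (1 + delta)^(m / 2) * zeta
}
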