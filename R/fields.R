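#' Carrying-capacity fields and initial densities
#'
#' Constructors for the landscapes used throughout the package: the carrying
#' capacity k(x) (always positive, with verified bounds `c_k <= k <= C_k`)
#' and the initial relative density u0 = U0/k with `0 <= u0 <= 1`.
#'
#' `k_ramp_1d()` is the printed piecewise-harmonic 1-d landscape
#' `k(x) = 0.5` for `x < -1.5` and `k(x) = x + 2` for `x >= -1.5`; it is
#' continuous but only Lipschitz at the cusp `x = -1.5`, which is recorded in
#' `smoothness` and flagged by [validate_k()].
#'
#' `k_polar_2d()` is the polar landscape `k(r, theta) = 2 + 1.5 cos(theta)`
#' for radius `>= 2`, regularized inside the unit-2 disk by a quintic smoothstep
#' radial ramp `s(r/2)` with `s(0) = s'(0) = s''(0) = 0` and
#' `s(1) = 1, s'(1) = s''(1) = 0`, so the assembled field is C^2 and equals
#' the polar formula exactly at radius `>= 2`.  The regularization is one explicit
#' choice among many C^2 completions.
#'
#' @param grid a [grid_1d()] / [grid_2d()] object; `k_ramp_1d()` builds a
#'   default 1-d grid on `[-4, 8]` when called without one.
#' @param n cells for the default grid of `k_ramp_1d()`.
#' @param K positive level for the homogeneous field.
#' @return an object of class `pm_kfield`: list with `grid`, `values`
#'   (vector in 1-d, `nx` x `ny` matrix in 2-d), verified bounds `c_k`,
#'   `C_k`, and `smoothness` (`"C2"` or `"Lipschitz"`).
#' @examples
#' k <- k_ramp_1d()
#' k$c_k                      # 0.5
#' @name kfields
NULL

new_kfield <- function(grid, values, smoothness, cusp_at = numeric(0)) {
  if (any(values <= 0)) stop("carrying capacity must be positive everywhere")
  structure(list(grid = grid, values = values,
                 c_k = min(values), C_k = max(values),
                 smoothness = smoothness, cusp_at = cusp_at),
            class = "pm_kfield")
}

#' @rdname kfields
#' @export
k_ramp_1d <- function(grid = grid_1d(c(-4, 8), n), n = 1200L) {
  stopifnot(inherits(grid, "pm_grid"), grid$dims == 1L)
  x <- grid$x
  new_kfield(grid, ifelse(x < -1.5, 0.5, x + 2), smoothness = "Lipschitz",
             cusp_at = -1.5)
}

## quintic smoothstep: 0 -> 1 on [0, 1] with two vanishing derivatives at both ends
smoothstep5 <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t^3 * (10 - 15 * t + 6 * t^2)
}

#' @rdname kfields
#' @export
k_polar_2d <- function(grid) {
  stopifnot(inherits(grid, "pm_grid"), grid$dims == 2L)
  xy <- expand.grid(x = grid$x, y = grid$y)
  r <- sqrt(xy$x^2 + xy$y^2)
  cth <- ifelse(r > 0, xy$x / pmax(r, .Machine$double.eps), 0)
  vals <- 2 + 1.5 * cth * smoothstep5(r / 2)
  new_kfield(grid, matrix(vals, grid$nx, grid$ny), smoothness = "C2")
}

#' @rdname kfields
#' @param base,amplitude,center,width Gaussian-bump parameters of
#'   `k_bump_1d()`: `k(x) = base + amplitude * exp(-((x - center)/width)^2)`,
#'   a smooth heterogeneous landscape satisfying the C^2 structural bounds
#'   (requires `base > 0` and `base + min(amplitude, 0) > 0`).
#' @export
k_bump_1d <- function(grid, base = 1, amplitude = 0.8, center = 1,
                      width = 1.2) {
  stopifnot(inherits(grid, "pm_grid"), grid$dims == 1L, width > 0)
  vals <- base + amplitude * exp(-((grid$x - center) / width)^2)
  new_kfield(grid, vals, smoothness = "C2")
}

#' @rdname kfields
#' @export
constant_k <- function(grid, K) {
  stopifnot(inherits(grid, "pm_grid"))
  if (!is.numeric(K) || length(K) != 1 || K <= 0) stop("K must be a positive scalar")
  vals <- if (grid$dims == 1L) rep(K, grid$nx) else matrix(K, grid$nx, grid$ny)
  new_kfield(grid, vals, smoothness = "C2")
}

#' @export
print.pm_kfield <- function(x, ...) {
  cat(sprintf("<pm_kfield %d-d: k in [%g, %g], %s>\n",
              x$grid$dims, x$c_k, x$C_k, x$smoothness))
  invisible(x)
}

#' Initial relative densities
#'
#' `u0_step_1d()` is the printed 1-d initial datum `u0 = 0.5` on `{x < 0}`,
#' zero elsewhere.  Its support reaches the left domain boundary (the printed
#' experiment does the same), so the compact-support flag is off and only a
#' right-moving interface exists.
#'
#' `u0_ellipse_2d()` builds a compactly supported plateau over an ellipse:
#' `u0 = clamp(s_E / edge_width, 0, 1)` where `s_E` is the signed distance to
#' the ellipse boundary (positive inside), giving a boundary steepness of
#' about `1/edge_width`.
#'
#' @param grid a [grid_1d()]/[grid_2d()] object.
#' @param level plateau height of the 1-d step (default 0.5).
#' @param center,semi_axes ellipse center and semi-axis lengths (length 2).
#' @param edge_width width of the linear edge ramp; must exceed `2h`.
#' @return object of class `pm_u0`: list with `grid`, `values`,
#'   `support_mask`, `steepness` (max inward boundary slope magnitude) and
#'   `compact_support` flag.
#' @export
u0_step_1d <- function(grid = grid_1d(c(-4, 8), 1200L), level = 0.5) {
  stopifnot(grid$dims == 1L, level > 0, level <= 1)
  vals <- ifelse(grid$x < 0, level, 0)
  structure(list(grid = grid, values = vals, support_mask = vals > 0,
                 steepness = level / grid$h, compact_support = FALSE),
            class = "pm_u0")
}

#' Signed distance to an ellipse boundary
#'
#' Positive inside the ellipse.  Computed as the exact distance to a dense
#' polygonal approximation of the boundary (error quadratic in the chord
#' length), which is accurate far below the grid spacing used here.
#'
#' @inheritParams u0_step_1d
#' @param n_boundary number of boundary sample points.
#' @return matrix of signed distances at cell centers.
#' @export
ellipse_signed_distance <- function(grid, center, semi_axes, n_boundary = 2048L) {
  stopifnot(grid$dims == 2L, length(center) == 2, length(semi_axes) == 2,
            all(semi_axes > 0))
  th <- seq(0, 2 * pi, length.out = n_boundary + 1L)[-1L]
  bx <- center[1] + semi_axes[1] * cos(th)
  by <- center[2] + semi_axes[2] * sin(th)
  px <- rep(grid$x, times = grid$ny)
  py <- rep(grid$y, each = grid$nx)
  d2 <- rep(Inf, length(px))
  ## distance to boundary segments, running minimum over segments
  for (i in seq_len(n_boundary)) {
    j <- if (i == n_boundary) 1L else i + 1L
    d2 <- pmin(d2, .seg_dist2(px, py, bx[i], by[i], bx[j], by[j]))
  }
  inside <- ((px - center[1]) / semi_axes[1])^2 +
    ((py - center[2]) / semi_axes[2])^2 < 1
  matrix(sqrt(d2) * ifelse(inside, 1, -1), grid$nx, grid$ny)
}

## squared distance from points (px, py) to segment (ax,ay)-(bx,by)
.seg_dist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

#' @rdname u0_step_1d
#' @export
u0_ellipse_2d <- function(grid, center = c(0, 0), semi_axes = c(2.5, 1.2),
                          edge_width = 0.3) {
  stopifnot(grid$dims == 2L)
  if (edge_width <= 2 * max(grid$h))
    stop("edge_width must exceed twice the grid spacing")
  ## support (sE > -edge_width is irrelevant; support is sE > 0) must stay
  ## strictly inside the domain
  if (center[1] - semi_axes[1] <= grid$xlim[1] + grid$h[1] ||
      center[1] + semi_axes[1] >= grid$xlim[2] - grid$h[1] ||
      center[2] - semi_axes[2] <= grid$ylim[1] + grid$h[2] ||
      center[2] + semi_axes[2] >= grid$ylim[2] - grid$h[2])
    stop("ellipse support must lie strictly inside the domain")
  sE <- ellipse_signed_distance(grid, center, semi_axes)
  vals <- pmin(pmax(sE / edge_width, 0), 1)
  structure(list(grid = grid, values = vals, support_mask = vals > 0,
                 steepness = 1 / edge_width, compact_support = TRUE,
                 signed_distance = sE),
            class = "pm_u0")
}

#' Check the structural bounds of a carrying-capacity field
#'
#' Measures the discrete analogues of the bounds `c_k <= k` and
#' `k + |grad k| + |lap k| <= C_k`: min/max of k, the maximum centered
#' gradient magnitude and the maximum interior 3/5-point Laplacian magnitude.
#' Cusp cells are flagged from two sources.  Constructors that build a field
#' with a known kink (the 1-d ramp) declare its location, and every cell
#' whose 3-point stencil straddles it (center within `1.2 h`) is flagged:
#' only those stencils mix the two branches, because the field is continuous
#' at the kink itself.  In addition, undeclared outliers are flagged when
#' the second difference exceeds `flag_threshold`: a gradient jump of size J
#' produces a second difference of about J/h, growing without bound under
#' refinement, while a C^2 field's second difference stays near its true
#' Laplacian.
#'
#' @param field a `pm_kfield`.
#' @param flag_threshold absolute Laplacian-magnitude threshold for cusp
#'   flagging; default `0.5 / min(h)`.
#' @return list with `min_k`, `max_k`, `max_grad`, `max_lap` (over unflagged
#'   interior cells), `c_k`, `C_k`, `cusp_cells` (logical array) and
#'   `n_flagged`.
#' @export
validate_k <- function(field, flag_threshold = NULL) {
  stopifnot(inherits(field, "pm_kfield"))
  k <- field$values
  if (any(k <= 0)) stop("carrying capacity must be positive")
  g <- field$grid
  if (is.null(flag_threshold)) flag_threshold <- 0.5 / min(g$h)
  gr <- grad_central(k, g)
  gmag <- if (g$dims == 1L) abs(gr$gx) else sqrt(gr$gx^2 + gr$gy^2)
  lap <- lap_neumann(k, g)
  interior <- interior_mask(g)
  flags <- abs(lap) > flag_threshold & interior
  if (length(field$cusp_at) > 0 && g$dims == 1L) {
    for (xc in field$cusp_at)
      flags <- flags | (abs(g$x - xc) < 1.2 * g$h & interior)
  }
  ok <- interior & !flags
  list(min_k = min(k), max_k = max(k),
       max_grad = max(gmag[interior]),
       max_lap = if (any(ok)) max(abs(lap)[ok]) else NA_real_,
       c_k = min(k),
       C_k = max(k) + max(gmag[interior]) +
         (if (any(ok)) max(abs(lap)[ok]) else 0),
       cusp_cells = flags, n_flagged = sum(flags))
}

## logical mask of strictly interior cells (mirrored ghosts distort one-sided
## second differences at the boundary, so bound checks exclude the rim)
interior_mask <- function(grid) {
  if (grid$dims == 1L) {
    m <- rep(TRUE, grid$nx); m[c(1, grid$nx)] <- FALSE; m
  } else {
    m <- matrix(TRUE, grid$nx, grid$ny)
    m[c(1, grid$nx), ] <- FALSE; m[, c(1, grid$ny)] <- FALSE; m
  }
}
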