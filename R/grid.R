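#' Cell-centered computational grids
#'
#' Uniform, cell-centered grids in one or two space dimensions.  All field
#' values in the package live at cell centers; coordinates are continuous, so
#' there is no 0/1-based indexing ambiguity.
#'
#' @param xlim,ylim numeric length-2 extents of the domain per axis.
#' @param n,nx,ny number of cells per axis (at least 32).
#' @return an object of class `pm_grid` with elements `dims`, `h` (spacing per
#'   axis), `xlim` (and `ylim` in 2-d), `nx` (and `ny`), and cell-center
#'   coordinate vectors `x` (and `y`).
#' @examples
#' g <- grid_1d(c(-4, 8), 240)
#' range(g$x)
#' @export
grid_1d <- function(xlim, n) {
  stopifnot(length(xlim) == 2, xlim[2] > xlim[1])
  if (n < 32) stop("grid must have at least 32 cells per axis")
  h <- diff(xlim) / n
  structure(list(dims = 1L, h = h, xlim = xlim, nx = as.integer(n),
                 x = xlim[1] + (seq_len(n) - 0.5) * h),
            class = "pm_grid")
}

#' @rdname grid_1d
#' @export
grid_2d <- function(xlim, ylim, nx, ny = nx) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[2] > xlim[1], ylim[2] > ylim[1])
  if (nx < 32 || ny < 32) stop("grid must have at least 32 cells per axis")
  hx <- diff(xlim) / nx
  hy <- diff(ylim) / ny
  structure(list(dims = 2L, h = c(hx, hy), xlim = xlim, ylim = ylim,
                 nx = as.integer(nx), ny = as.integer(ny),
                 x = xlim[1] + (seq_len(nx) - 0.5) * hx,
                 y = ylim[1] + (seq_len(ny) - 0.5) * hy),
            class = "pm_grid")
}

#' @export
print.pm_grid <- function(x, ...) {
  if (x$dims == 1L) {
    cat(sprintf("<pm_grid 1-d: %d cells on [%g, %g], h = %g>\n",
                x$nx, x$xlim[1], x$xlim[2], x$h))
  } else {
    cat(sprintf("<pm_grid 2-d: %d x %d cells on [%g, %g] x [%g, %g], h = (%g, %g)>\n",
                x$nx, x$ny, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2],
                x$h[1], x$h[2]))
  }
  invisible(x)
}

## zero-flux (mirrored-ghost) discrete Laplacian of a field w on a pm_grid
lap_neumann <- function(w, grid) {
  if (grid$dims == 1L) {
    n <- grid$nx
    (c(w[1], w[-n]) - 2 * w + c(w[-1], w[n])) / grid$h^2
  } else {
    nx <- grid$nx; ny <- grid$ny
    wx <- (w[c(1, seq_len(nx - 1)), , drop = FALSE] - 2 * w +
             w[c(seq_len(nx)[-1], nx), , drop = FALSE]) / grid$h[1]^2
    wy <- (w[, c(1, seq_len(ny - 1)), drop = FALSE] - 2 * w +
             w[, c(seq_len(ny)[-1], ny), drop = FALSE]) / grid$h[2]^2
    wx + wy
  }
}

## centered-difference gradient magnitude (one-sided at the boundary)
grad_central <- function(w, grid) {
  if (grid$dims == 1L) {
    n <- grid$nx
    gx <- (c(w[-1], w[n]) - c(w[1], w[-n])) / (2 * grid$h)
    gx[1] <- (w[2] - w[1]) / grid$h
    gx[n] <- (w[n] - w[n - 1]) / grid$h
    list(gx = gx)
  } else {
    nx <- grid$nx; ny <- grid$ny
    gx <- (w[c(seq_len(nx)[-1], nx), , drop = FALSE] -
             w[c(1, seq_len(nx - 1)), , drop = FALSE]) / (2 * grid$h[1])
    gx[1, ] <- (w[2, ] - w[1, ]) / grid$h[1]
    gx[nx, ] <- (w[nx, ] - w[nx - 1, ]) / grid$h[1]
    gy <- (w[, c(seq_len(ny)[-1], ny), drop = FALSE] -
             w[, c(1, seq_len(ny - 1)), drop = FALSE]) / (2 * grid$h[2])
    gy[, 1] <- (w[, 2] - w[, 1]) / grid$h[2]
    gy[, ny] <- (w[, ny] - w[, ny - 1]) / grid$h[2]
    list(gx = gx, gy = gy)
  }
}
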