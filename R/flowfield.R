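#' Flow field on a space-time grid
#'
#' Holds per-frame 2D velocity vectors on a uniform spatial grid with a
#' validity mask, plus the interpolating lookup used by the displacement
#' projection estimator. Velocities are in um/s; grid coordinates in um.
#'
#' @param grid_x,grid_y grid node coordinates, um (uniformly spaced).
#' @param times frame mid-times, s.
#' @param vx,vy arrays `(t, y, x)` of velocity components, um/s.
#' @param valid logical array of the same shape; invalid nodes must already
#'   have been filled by interpolation (vectors must be finite everywhere).
#' @return object of class `flow_field`.
#' @export
flow_field <- function(grid_x, grid_y, times, vx, vy, valid = NULL) {
  stop_if(length(dim(vx)) != 3L || !all(dim(vx) == dim(vy)),
          "vx/vy must be (t, y, x) arrays of equal shape")
  stop_if(dim(vx)[1] != length(times) || dim(vx)[2] != length(grid_y) ||
            dim(vx)[3] != length(grid_x), "array shape does not match grid")
  if (length(grid_x) > 2L)
    stop_if(stats::sd(diff(grid_x)) > 1e-9 * abs(mean(diff(grid_x))),
            "grid_x must be uniformly spaced")
  if (length(grid_y) > 2L)
    stop_if(stats::sd(diff(grid_y)) > 1e-9 * abs(mean(diff(grid_y))),
            "grid_y must be uniformly spaced")
  stop_if(any(!is.finite(vx)) || any(!is.finite(vy)),
          "flow vectors must be finite everywhere (fill invalid nodes first)")
  if (is.null(valid)) valid <- array(TRUE, dim = dim(vx))
  structure(list(grid_x = grid_x, grid_y = grid_y, times = times,
                 vx = vx, vy = vy, valid = valid),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  spd <- sqrt(x$vx^2 + x$vy^2)
  cat(sprintf("Flow field: %d x %d nodes, %d frames; |v| mean %.4g um/s (max %.4g); %.1f%% interpolated\n",
              length(x$grid_x), length(x$grid_y), length(x$times),
              mean(spd), max(spd), 100 * mean(!x$valid)))
  invisible(x)
}

#' Uniform flow field
#'
#' Convenience constructor for a spatially and temporally constant flow.
#'
#' @param vx,vy velocity components, um/s.
#' @param xlim,ylim,tlim extents covered, um / s.
#' @param n nodes per axis.
#' @export
flow_field_uniform <- function(vx, vy, xlim = c(0, 60), ylim = c(0, 60),
                               tlim = c(0, 1000), n = 5L) {
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  ts <- seq(tlim[1], tlim[2], length.out = 2L)
  flow_field(gx, gy, ts,
             array(vx, dim = c(2L, n, n)), array(vy, dim = c(2L, n, n)))
}

#' Flow field from a velocity function
#'
#' Evaluates `fun(x, y)` (returning a list/data frame with `vx`, `vy`, um/s)
#' on a grid; the field is constant in time.
#'
#' @param fun vectorised function of `(x, y)`.
#' @param xlim,ylim,tlim extents, um / s.
#' @param spacing grid spacing, um.
#' @export
flow_field_from_function <- function(fun, xlim, ylim, tlim = c(0, 1000),
                                     spacing = 1) {
  gx <- seq(xlim[1], xlim[2], by = spacing)
  gy <- seq(ylim[1], ylim[2], by = spacing)
  g <- expand.grid(y = gy, x = gx)
  v <- fun(g$x, g$y)
  vx <- array(0, dim = c(2L, length(gy), length(gx)))
  vy <- array(0, dim = c(2L, length(gy), length(gx)))
  for (ti in 1:2) {
    vx[ti, , ] <- matrix(v$vx, length(gy), length(gx))
    vy[ti, , ] <- matrix(v$vy, length(gy), length(gx))
  }
  flow_field(gx, gy, seq(tlim[1], tlim[2], length.out = 2L), vx, vy)
}

#' Sample a flow field at arbitrary positions and time
#'
#' Bicubic (Catmull-Rom) interpolation in space, nearest-frame lookup in
#' time. Spatial queries outside the grid hull are clamped to the edge
#' (nearest-grid extrapolation); temporal queries outside the covered range
#' are an error.
#'
#' @param field a [flow_field()].
#' @param x,y query positions, um (vectorised).
#' @param t query time, s (scalar or vector of the same length).
#' @return data frame with columns `vx`, `vy` (um/s) and `speed`.
#' @export
sample_flow <- function(field, x, y, t) {
  stopifnot(inherits(field, "flow_field"))
  nt <- length(field$times)
  rng <- range(field$times)
  stop_if(any(t < rng[1] - 1e-9) || any(t > rng[2] + 1e-9),
          sprintf("time query outside field range [%g, %g] s", rng[1], rng[2]))
  if (length(t) == 1L) t <- rep(t, length(x))
  ti <- vapply(t, function(tt) which.min(abs(field$times - tt)), integer(1))
  vx <- numeric(length(x)); vy <- numeric(length(x))
  for (tt in unique(ti)) {
    idx <- ti == tt
    vx[idx] <- interp_bicubic(field$grid_x, field$grid_y, field$vx[tt, , ],
                              x[idx], y[idx])
    vy[idx] <- interp_bicubic(field$grid_x, field$grid_y, field$vy[tt, , ],
                              x[idx], y[idx])
  }
  data.frame(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

#' Write / read a flow field as tidy CSV
#'
#' Long format: one row per (time, node) with columns `t_s`, `grid_x_um`,
#' `grid_y_um`, `vx_um_s`, `vy_um_s`, `valid`.
#'
#' @param field a `flow_field`.
#' @param path CSV path.
#' @export
write_flow_field <- function(field, path) {
  g <- expand.grid(y = seq_along(field$grid_y), x = seq_along(field$grid_x))
  rows <- do.call(rbind, lapply(seq_along(field$times), function(ti) {
    data.frame(t_s = field$times[ti],
               grid_x_um = field$grid_x[g$x], grid_y_um = field$grid_y[g$y],
               vx_um_s = field$vx[ti, , ][cbind(g$y, g$x)],
               vy_um_s = field$vy[ti, , ][cbind(g$y, g$x)],
               valid = field$valid[ti, , ][cbind(g$y, g$x)])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  df <- utils::read.csv(path)
  gx <- sort(unique(df$grid_x_um)); gy <- sort(unique(df$grid_y_um))
  ts <- sort(unique(df$t_s))
  vx <- array(0, dim = c(length(ts), length(gy), length(gx)))
  vy <- vx; valid <- array(TRUE, dim = dim(vx))
  ix <- match(df$grid_x_um, gx); iy <- match(df$grid_y_um, gy)
  it <- match(df$t_s, ts)
  vx[cbind(it, iy, ix)] <- df$vx_um_s
  vy[cbind(it, iy, ix)] <- df$vy_um_s
  valid[cbind(it, iy, ix)] <- as.logical(df$valid)
  flow_field(gx, gy, ts, vx, vy, valid)
}
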