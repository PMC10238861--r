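#' PIV parameters
#'
#' Settings for the two-pass FFT cross-correlation particle image
#' velocimetry of the cortex channel: interrogation windows of 64 then 32 px
#' (the second pass offset by the first-pass estimate), a high-pass
#' pre-filter, a manual velocity limit, a per-frame standard-deviation
#' outlier filter, and a 2-frame rolling time average.
#'
#' @param pass_windows interrogation window sizes, px, decreasing powers of 2.
#' @param grid_spacing vector spacing of the output grid, px.
#' @param highpass_size high-pass filter size, px (background removal by
#'   subtracting a Gaussian blur of this width); `0` disables.
#' @param velocity_limit manual velocity limit, px/frame; faster vectors are
#'   discarded and interpolated from neighbours.
#' @param sd_filter per-frame outlier threshold in standard deviations.
#' @param time_average rolling-average window, frames.
#' @return object of class `piv_params`.
#' @export
piv_params <- function(pass_windows = c(64L, 32L), grid_spacing = 16L,
                       highpass_size = 10, velocity_limit = 0.3,
                       sd_filter = 5, time_average = 2L) {
  pass_windows <- as.integer(pass_windows)
  stop_if(any(diff(pass_windows) >= 0), "pass_windows must be decreasing")
  stop_if(any(bitwAnd(pass_windows, pass_windows - 1L) != 0L),
          "pass_windows must be powers of two")
  check_scalar(velocity_limit, "velocity_limit", min = 0, strict = TRUE)
  check_scalar(sd_filter, "sd_filter", min = 0, strict = TRUE)
  structure(list(pass_windows = pass_windows,
                 grid_spacing = as.integer(grid_spacing),
                 highpass_size = highpass_size,
                 velocity_limit = velocity_limit, sd_filter = sd_filter,
                 time_average = as.integer(time_average)),
            class = "piv_params")
}

## Cross-correlate two equally sized windows via FFT; returns the
## displacement of b relative to a with 3-point Gaussian subpixel fit per
## axis. Returns NULL for degenerate (flat) windows.
xcorr_peak <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NULL)
  n <- nrow(a)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / (n * n)
  ## remove the correlation pedestal so the 3-point Gaussian fit sees a
  ## clean peak (reduces subpixel bias for broad speckle)
  cc <- cc - stats::median(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ## 3-point Gaussian fit needs positive neighbours; shift to be safe
  wrap <- function(i) ((i - 1L) %% n) + 1L
  sub <- function(dr, dc) cc[wrap(pk[1] + dr), wrap(pk[2] + dc)]
  gfit <- function(cm, c0, cp) {
    ## 3-point Gaussian fit; parabolic fallback when a neighbour is <= 0
    d <- if (cm > 0 && c0 > 0 && cp > 0)
      (log(cm) - log(cp)) / (2 * (log(cm) - 2 * log(c0) + log(cp)))
    else (cm - cp) / (2 * (cm - 2 * c0 + cp))
    if (!is.finite(d) || abs(d) > 1) 0 else d
  }
  dy <- (pk[1] - 1); dx <- (pk[2] - 1)
  if (dy > n / 2) dy <- dy - n
  if (dx > n / 2) dx <- dx - n
  dy <- dy + gfit(sub(-1L, 0L), sub(0L, 0L), sub(1L, 0L))
  dx <- dx + gfit(sub(0L, -1L), sub(0L, 0L), sub(0L, 1L))
  c(dx = unname(dx), dy = unname(dy))
}

## Extract a window of size w centred at (cx, cy) (pixel indices), clamped
## inside the image. Returns NULL if it does not fit.
get_window <- function(img, cx, cy, w) {
  h <- w %/% 2L
  x0 <- round(cx) - h + 1L; y0 <- round(cy) - h + 1L
  x0 <- min(max(x0, 1L), ncol(img) - w + 1L)
  y0 <- min(max(y0, 1L), nrow(img) - w + 1L)
  if (x0 < 1L || y0 < 1L) return(NULL)
  img[y0:(y0 + w - 1L), x0:(x0 + w - 1L)]
}

piv_preprocess <- function(stack, params) {
  arr <- stack$frames
  nf <- dim(arr)[1]
  ## bleach correction: divide by per-frame mean
  for (f in seq_len(nf)) {
    m <- mean(arr[f, , ])
    if (m > 0) arr[f, , ] <- arr[f, , ] / m
  }
  ## rolling time average
  ta <- params$time_average
  if (ta > 1L && nf >= ta) {
    out <- array(0, dim = c(nf - ta + 1L, dim(arr)[2], dim(arr)[3]))
    for (f in seq_len(nf - ta + 1L))
      out[f, , ] <- apply(arr[f:(f + ta - 1L), , , drop = FALSE], c(2, 3), mean)
    arr <- out
  }
  ## high-pass: subtract local low-frequency background
  if (params$highpass_size > 0) {
    k <- gaussian_kernel(params$highpass_size / 2)
    for (f in seq_len(dim(arr)[1]))
      arr[f, , ] <- arr[f, , ] - conv2_fft(arr[f, , ], k)
  }
  arr
}

#' Two-pass FFT cross-correlation PIV
#'
#' Estimates the frame-to-frame displacement field of a textured channel.
#' Frames are bleach-normalised, rolling-averaged and high-pass filtered;
#' each grid node is interrogated with a large first-pass window and a
#' smaller second-pass window offset by the rounded first-pass displacement;
#' the correlation peak is refined to subpixel precision by a 3-point
#' Gaussian fit per axis. Vectors beyond the manual velocity limit, then
#' vectors more than `sd_filter` standard deviations from the per-frame
#' mean, are discarded and replaced by interpolation from valid neighbours.
#'
#' @param stack an [image_stack()] with at least 2 frames.
#' @param params a [piv_params()].
#' @return a [flow_field()] in um/s; attribute `fraction_interpolated` gives
#'   the fraction of vectors replaced by interpolation.
#' @export
piv <- function(stack, params = piv_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "piv_params"))
  d <- dim(stack$frames)
  stop_if(d[1] < 2L, "PIV needs at least 2 frames")
  stop_if(max(params$pass_windows) > min(d[2], d[3]),
          "largest window does not fit in the image")
  arr <- piv_preprocess(stack, params)
  nf <- dim(arr)[1]
  stop_if(nf < 2L, "fewer than 2 frames left after time averaging; lower time_average or supply more frames")
  sp <- params$grid_spacing
  w1 <- params$pass_windows[1]
  w2 <- params$pass_windows[length(params$pass_windows)]
  half <- w1 %/% 2L
  gx_px <- seq(half, d[3] - half, by = sp)
  gy_px <- seq(half, d[2] - half, by = sp)
  stop_if(!length(gx_px) || !length(gy_px), "image too small for the window/grid")
  nt <- nf - 1L
  vx <- array(NA_real_, dim = c(nt, length(gy_px), length(gx_px)))
  vy <- vx
  for (f in seq_len(nt)) {
    a_full <- arr[f, , ]; b_full <- arr[f + 1L, , ]
    for (j in seq_along(gy_px)) for (i in seq_along(gx_px)) {
      cx <- gx_px[i]; cy <- gy_px[j]
      est <- c(0, 0)
      for (w in params$pass_windows) {
        wa <- get_window(a_full, cx, cy, w)
        wb <- get_window(b_full, cx + round(est[1]), cy + round(est[2]), w)
        if (is.null(wa) || is.null(wb)) { est <- c(NA, NA); break }
        pk <- xcorr_peak(wa, wb)
        if (is.null(pk)) { est <- c(NA, NA); break }
        est <- c(round(est[1]) + pk["dx"], round(est[2]) + pk["dy"])
      }
      vx[f, j, i] <- est[1]; vy[f, j, i] <- est[2]
    }
  }
  filt <- piv_filter(vx, vy, params)
  n_bad_frame <- apply(!filt$valid, 1, all)
  stop_if(any(n_bad_frame),
          paste("all vectors invalid in frame(s)",
                paste(which(n_bad_frame), collapse = ", ")))
  ## convert px/frame -> um/s on the stack's physical scale
  scale <- stack$pixel_size / stack$frame_interval
  ox <- stack$origin_um[1]; oy <- stack$origin_um[2]
  field <- flow_field(ox + (gx_px - 0.5) * stack$pixel_size,
                      oy + (gy_px - 0.5) * stack$pixel_size,
                      (seq_len(nt) - 0.5) * stack$frame_interval,
                      filt$vx * scale, filt$vy * scale, filt$valid)
  attr(field, "fraction_interpolated") <- mean(!filt$valid)
  field
}

## Apply velocity limit then SD filter; fill invalid nodes from valid
## neighbours (iterative local mean). Operates in px/frame.
piv_filter <- function(vx, vy, params) {
  valid <- is.finite(vx) & is.finite(vy)
  spd <- sqrt(vx^2 + vy^2)
  valid <- valid & (spd <= params$velocity_limit)
  for (f in seq_len(dim(vx)[1])) {
    vv <- valid[f, , ]
    if (!any(vv)) next
    mx <- mean(vx[f, , ][vv]); sx <- stats::sd(vx[f, , ][vv])
    my <- mean(vy[f, , ][vv]); sy <- stats::sd(vy[f, , ][vv])
    ## SD floor guards against flagging ulp-level scatter in uniform fields
    floor_sd <- 1e-9 * params$velocity_limit
    if (is.finite(sx) && sx > floor_sd) vv <- vv & (abs(vx[f, , ] - mx) <= params$sd_filter * sx)
    if (is.finite(sy) && sy > floor_sd) vv <- vv & (abs(vy[f, , ] - my) <= params$sd_filter * sy)
    valid[f, , ] <- vv
  }
  vx[!valid] <- NA; vy[!valid] <- NA
  for (f in seq_len(dim(vx)[1])) {
    vx[f, , ] <- fill_from_neighbours(vx[f, , ])
    vy[f, , ] <- fill_from_neighbours(vy[f, , ])
  }
  list(vx = vx, vy = vy, valid = valid)
}

## Iteratively replace NAs by the mean of their finite 8-neighbours.
fill_from_neighbours <- function(m) {
  if (!any(is.na(m))) return(m)
  if (all(is.na(m))) return(m)
  for (iter in 1:100) {
    if (!any(is.na(m))) break
    nr <- nrow(m); nc <- ncol(m)
    sums <- matrix(0, nr, nc); cnts <- matrix(0, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      ys <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
      xs <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
      nb <- m[ys, xs, drop = FALSE]
      ok <- is.finite(nb)
      sums[ok] <- sums[ok] + nb[ok]
      cnts <- cnts + ok
    }
    fill <- is.na(m) & cnts > 0
    m[fill] <- sums[fill] / cnts[fill]
  }
  m
}
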