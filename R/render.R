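#' Image stack container
#'
#' A minimal carrier for rendered or loaded time-lapse movies: a 3D array of
#' intensities indexed (frame, row = y, column = x) plus the physical pixel
#' size and frame interval.
#'
#' @param frames 3D numeric array `(t, y, x)`, non-negative.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param channel free-text channel label.
#' @param origin_um optional `(x, y)` of the lower pixel corner in the
#'   trajectory coordinate system, um.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        channel = "unknown", origin_um = c(0, 0)) {
  stop_if(length(dim(frames)) != 3L, "frames must be a 3D (t, y, x) array")
  stop_if(any(dim(frames) == 0L), "image stack has zero extent")
  stop_if(any(!is.finite(frames)), "image intensities must be finite")
  check_scalar(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel,
                 origin_um = origin_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack [%s]: %d frames of %d x %d px (%g um/px, %g s/frame)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

## Canvas geometry: field of view, grown to contain the largest excursion,
## padded by 6 px on every side.
canvas_geometry <- function(traj, config, pad_px = 6L) {
  ps <- config$pixel_size
  x_lo <- min(0, if (nrow(traj)) min(traj$x_um) else 0)
  x_hi <- max(config$long_axis, if (nrow(traj)) max(traj$x_um) else 0)
  y_lo <- min(0, if (nrow(traj)) min(traj$y_um) else 0)
  y_hi <- max(config$short_axis, if (nrow(traj)) max(traj$y_um) else 0)
  nx <- ceiling(round((x_hi - x_lo) / ps, 8)) + 2L * pad_px
  ny <- ceiling(round((y_hi - y_lo) / ps, 8)) + 2L * pad_px
  list(nx = as.integer(nx), ny = as.integer(ny),
       origin = c(x_lo - pad_px * ps, y_lo - pad_px * ps))
}

## Add a Gaussian spot at subpixel position (x_px, y_px) (1-based pixel
## centre coordinates) to an image, over a +-4 sigma window.
add_spot <- function(img, x_px, y_px, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  cx <- round(x_px); cy <- round(y_px)
  xs <- max(1L, cx - r):min(ncol(img), cx + r)
  ys <- max(1L, cy - r):min(nrow(img), cy + r)
  if (!length(xs) || !length(ys)) return(img)
  gx <- exp(-(xs - x_px)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y_px)^2 / (2 * sigma^2))
  img[ys, xs] <- img[ys, xs] + amplitude * outer(gy, gx)
  img
}

#' Render trajectories as a synthetic fluorescence movie
#'
#' Each live particle is drawn as a Gaussian spot of width `psf_sigma` at its
#' subpixel position, on a Gaussian-noise background. The canvas is the field
#' of view extended to the largest particle excursion and padded by 6 px on
#' all sides, so no particle is clipped.
#'
#' @param traj a `trajectory_set`.
#' @param config the [sim_config()] used to generate it (supplies geometry,
#'   PSF and camera parameters).
#' @return an [image_stack()] whose `origin_um` attribute maps pixel to
#'   trajectory coordinates.
#' @export
render_images <- function(traj, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "render"))
  geo <- canvas_geometry(traj, config)
  frames_idx <- if (nrow(traj)) sort(unique(traj$frame)) else 0L
  n_frames <- length(frames_idx)
  arr <- array(0, dim = c(n_frames, geo$ny, geo$nx))
  ps <- config$pixel_size
  for (fi in seq_len(n_frames)) {
    img <- matrix(stats::rnorm(geo$ny * geo$nx, config$background_mean,
                               config$background_noise_sd), geo$ny, geo$nx)
    sub <- traj[traj$frame == frames_idx[fi], , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      ## pixel centre of pixel i sits at origin + (i - 0.5) * ps
      x_px <- (sub$x_um[k] - geo$origin[1]) / ps + 0.5
      y_px <- (sub$y_um[k] - geo$origin[2]) / ps + 0.5
      img <- add_spot(img, x_px, y_px, sub$intensity[k], config$psf_sigma)
    }
    arr[fi, , ] <- img
  }
  image_stack(pmax(arr, 0), ps, config$frame_interval,
              channel = "particles", origin_um = geo$origin)
}

#' Render a flowing cortex-like speckle texture
#'
#' Generates a fixed random speckle pattern (smoothed Gaussian noise, the
#' visual analogue of a labelled actomyosin cortex) and warps it frame to
#' frame with the supplied flow field by backward mapping with bilinear
#' subpixel interpolation, adding fresh camera noise per frame. This provides
#' a ground-truth-flow channel against which the PIV stage can be validated.
#'
#' @param flow a [flow_field()] (or uniform field) giving um/s velocities.
#' @param config a [sim_config()]; geometry, noise and timing are taken from
#'   it.
#' @param n_frames number of frames to render (default from `duration`).
#' @param speckle_sigma correlation length of the speckle, px.
#' @param max_speed_px largest tolerated per-frame displacement, px; faster
#'   flows are untrackable by windowed PIV and rejected.
#' @return an [image_stack()], channel `"cortex"`.
#' @export
render_cortex_texture <- function(flow, config, n_frames = NULL,
                                  speckle_sigma = 1.0, max_speed_px = 8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cortex"))
  ps <- config$pixel_size
  dt <- config$frame_interval
  if (is.null(n_frames)) n_frames <- floor(config$duration / dt) + 1L
  nx <- as.integer(ceiling(config$long_axis / ps))
  ny <- as.integer(ceiling(config$short_axis / ps))
  ## base texture with margin so warping never runs out of support
  margin <- 32L
  base <- conv2_fft(matrix(stats::rnorm((ny + 2 * margin) * (nx + 2 * margin)),
                           ny + 2 * margin, nx + 2 * margin),
                    gaussian_kernel(speckle_sigma))
  base <- (base - min(base)) / (max(base) - min(base)) * config$spot_amplitude

  ## per-pixel velocity in px/frame, sampled once at t = 0 (flows here are
  ## quasi-static over the rendered window)
  xs_um <- (seq_len(nx) - 0.5) * ps
  ys_um <- (seq_len(ny) - 0.5) * ps
  g <- expand.grid(y = ys_um, x = xs_um)
  v <- sample_flow(flow, g$x, g$y, t = 0)
  vx <- matrix(v$vx, ny, nx) * dt / ps
  vy <- matrix(v$vy, ny, nx) * dt / ps
  spd <- sqrt(vx^2 + vy^2)
  stop_if(max(spd) > max_speed_px,
          sprintf("flow too fast to track: %.2f px/frame exceeds limit %g",
                  max(spd), max_speed_px))

  arr <- array(0, dim = c(n_frames, ny, nx))
  px_x <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  px_y <- matrix(rep(seq_len(ny), nx), ny, nx)
  for (f in seq_len(n_frames)) {
    shift <- f - 1L
    ## backward map: texture advected along +v means sampling base at x - v t
    sx <- px_x - vx * shift + margin
    sy <- px_y - vy * shift + margin
    warped <- matrix(interp_bilinear(base, as.vector(sx), as.vector(sy)), ny, nx)
    noise <- matrix(stats::rnorm(ny * nx, config$background_mean,
                                 config$background_noise_sd), ny, nx)
    arr[f, , ] <- pmax(warped + noise, 0)
  }
  image_stack(arr, ps, dt, channel = "cortex", origin_um = c(0, 0))
}

#' Write / read an image stack as multi-page TIFF (+ JSON sidecar)
#'
#' Intensities are stored as 32-bit float TIFF pages; pixel size, frame
#' interval, channel and origin go to a `<path>.json` sidecar.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  ## TIFF pages are stored scaled to [0, 1]; the count scale goes to the
  ## sidecar so intensities survive the round trip exactly
  scale <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(i) stack$frames[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               channel = stack$channel, origin_um = stack$origin_um,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size,frame_interval used when no JSON sidecar is present.
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  ps <- pixel_size %||% meta$pixel_size_um %||% 1
  fi <- frame_interval %||% meta$frame_interval_s %||% 1
  sc <- meta$intensity_scale %||% 1
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * sc
  image_stack(arr, ps, fi, channel = meta$channel %||% "unknown",
              origin_um = meta$origin_um %||% c(0, 0))
}
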