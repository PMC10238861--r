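#' Tracking parameters
#'
#' Parameters of the Crocker-Grier style detection/linking scheme. Defaults
#' follow common practice for near-TIRF single-molecule movies: feature size
#' 7 px, no gap closing (memory 0), minimum separation 2 px, maximum
#' frame-to-frame displacement 4 px, minimum track length 11 frames.
#'
#' @param feature_size odd spot diameter, px (>= 3).
#' @param intensity_threshold minimum bandpassed peak intensity, counts.
#' @param min_separation detections closer than this are merged to the
#'   brighter one, px.
#' @param max_displacement largest allowed frame-to-frame movement, px.
#' @param memory frames a particle may vanish and still be relinked (only 0
#'   is implemented; the parameter is accepted for interface compatibility).
#' @param min_track_length shortest track kept, frames (>= 2).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(feature_size = 7L, intensity_threshold = 0,
                            min_separation = 2, max_displacement = 4,
                            memory = 0L, min_track_length = 11L) {
  feature_size <- as.integer(feature_size)
  stop_if(feature_size < 3L || feature_size %% 2L == 0L,
          "feature_size must be odd and >= 3")
  check_scalar(max_displacement, "max_displacement", min = 0, strict = TRUE)
  stop_if(as.integer(memory) < 0L, "memory must be >= 0")
  stop_if(as.integer(memory) > 0L, "memory > 0 (gap closing) is not implemented")
  stop_if(as.integer(min_track_length) < 2L, "min_track_length must be >= 2")
  structure(list(feature_size = feature_size,
                 intensity_threshold = intensity_threshold,
                 min_separation = min_separation,
                 max_displacement = max_displacement,
                 memory = as.integer(memory),
                 min_track_length = as.integer(min_track_length)),
            class = "tracking_params")
}

## Bandpass: subtract boxcar background at feature scale, smooth at 1 px.
bandpass <- function(frame, feature_size) {
  bg <- conv2_fft(frame, boxcar_kernel(feature_size))
  sm <- conv2_fft(frame, gaussian_kernel(1))
  pmax(sm - bg, 0)
}

#' Detect fluorescent spots in one frame
#'
#' Local maxima of the bandpassed image above `intensity_threshold` are
#' refined to subpixel centres by iterative intensity-weighted centroiding
#' within the feature window; detections closer than `min_separation` are
#' merged, keeping the brighter.
#'
#' @param frame 2D numeric matrix (row = y, column = x), finite-valued.
#' @param params a [tracking_params()].
#' @return data frame with columns `x`, `y` (subpixel px, 1-based pixel
#'   centres) and `intensity` (bandpassed peak mass).
#' @export
detect_spots <- function(frame, params = tracking_params()) {
  stop_if(any(!is.finite(frame)), "frame contains non-finite pixels")
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  if (length(frame) == 0L) return(empty)
  bp <- bandpass(frame, params$feature_size)
  r <- params$feature_size %/% 2L
  mx <- max_filter(bp, r)
  peaks <- which(bp >= mx & bp > params$intensity_threshold, arr.ind = TRUE)
  ## drop peaks too close to the border for centroiding
  keep <- peaks[, 1] > r & peaks[, 1] <= nrow(bp) - r &
    peaks[, 2] > r & peaks[, 2] <= ncol(bp) - r
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0L) return(empty)
  ## circular mask for the centroid window
  off <- expand.grid(dy = -r:r, dx = -r:r)
  mask <- with(off, dy^2 + dx^2 <= r^2)
  res <- lapply(seq_len(nrow(peaks)), function(k) {
    cy <- peaks[k, 1]; cx <- peaks[k, 2]
    x <- as.numeric(cx); y <- as.numeric(cy)
    for (it in 1:10) {
      iy <- round(y); ix <- round(x)
      if (iy - r < 1 || iy + r > nrow(bp) || ix - r < 1 || ix + r > ncol(bp)) break
      wy <- off$dy[mask] + iy; wx <- off$dx[mask] + ix
      wts <- bp[cbind(wy, wx)]
      s <- sum(wts)
      if (s <= 0) break
      nx <- sum(wx * wts) / s; ny <- sum(wy * wts) / s
      shift <- max(abs(nx - x), abs(ny - y))
      x <- nx; y <- ny
      if (shift < 1e-3) break
    }
    iy <- round(y); ix <- round(x)
    wy <- pmin(pmax(off$dy[mask] + iy, 1L), nrow(bp))
    wx <- pmin(pmax(off$dx[mask] + ix, 1L), ncol(bp))
    c(x = x, y = y, intensity = sum(bp[cbind(wy, wx)]))
  })
  det <- as.data.frame(do.call(rbind, res))
  ## merge detections closer than min_separation, keeping the brighter
  det <- det[order(-det$intensity), , drop = FALSE]
  kept <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    if (k == 1L) { kept[k] <- TRUE; next }
    dd <- sqrt((det$x[k] - det$x[kept])^2 + (det$y[k] - det$y[kept])^2)
    kept[k] <- all(dd >= params$min_separation)
  }
  det <- det[kept, , drop = FALSE]
  det <- det[order(det$y, det$x), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment among candidate pairs within
#' `max_displacement`, minimising total squared displacement (exact on small
#' conflict components, greedy otherwise; exact distance ties break towards
#' the lower existing particle id). With `memory = 0`, an unmatched particle
#' terminates; new detections start new tracks. Tracks shorter than
#' `min_track_length` are discarded and positions converted to um.
#'
#' @param detections list of per-frame data frames from [detect_spots()],
#'   ordered by frame; or a single data frame with a `frame` column.
#' @param params a [tracking_params()].
#' @param pixel_size um per px.
#' @param frame_interval seconds per frame.
#' @return a [trajectory_set()] with provenance `"tracked"`.
#' @export
link_tracks <- function(detections, params = tracking_params(),
                        pixel_size = 0.1, frame_interval = 0.1) {
  if (is.data.frame(detections)) {
    frames <- sort(unique(detections$frame))
    detections <- lapply(frames, function(f)
      detections[detections$frame == f, c("x", "y", "intensity"), drop = FALSE])
  } else {
    frames <- seq_along(detections) - 1L
  }
  n_frames <- length(detections)
  next_id <- 1L
  rows <- vector("list", n_frames)
  prev <- NULL # data.frame(id, x, y)
  for (f in seq_len(n_frames)) {
    det <- detections[[f]]
    ids <- integer(nrow(det))
    if (!is.null(prev) && nrow(prev) > 0L && nrow(det) > 0L) {
      ## candidate edges within max_displacement
      d2 <- outer(prev$x, det$x, "-")^2 + outer(prev$y, det$y, "-")^2
      cand <- which(d2 <= params$max_displacement^2, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ## deterministic tie-break: order candidates by cost then prev id
        ord <- order(d2[cand], prev$id[cand[, 1]], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        sel <- assign_min_cost(cand[, 1], cand[, 2], d2[cand])
        ids[cand[sel, 2]] <- prev$id[cand[sel, 1]]
      }
    }
    new <- ids == 0L
    if (any(new)) {
      ids[new] <- next_id + seq_len(sum(new)) - 1L
      next_id <- next_id + sum(new)
    }
    if (nrow(det) > 0L)
      rows[[f]] <- data.frame(particle_id = ids, frame = frames[f],
                              x = det$x, y = det$y, intensity = det$intensity)
    prev <- if (nrow(det) > 0L) data.frame(id = ids, x = det$x, y = det$y)
            else NULL
  }
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || nrow(all_rows) == 0L)
    return(trajectory_set(data.frame(particle_id = integer(0), frame = integer(0),
                                     time_s = numeric(0), x_um = numeric(0),
                                     y_um = numeric(0), intensity = numeric(0)),
                          provenance = "tracked"))
  len <- table(all_rows$particle_id)
  keep <- all_rows$particle_id %in% as.integer(names(len)[len >= params$min_track_length])
  all_rows <- all_rows[keep, , drop = FALSE]
  trajectory_set(data.frame(particle_id = all_rows$particle_id,
                            frame = all_rows$frame,
                            time_s = all_rows$frame * frame_interval,
                            ## pixel centre i maps to (i - 0.5) * pixel_size
                            x_um = (all_rows$x - 0.5) * pixel_size,
                            y_um = (all_rows$y - 0.5) * pixel_size,
                            intensity = all_rows$intensity),
                 provenance = "tracked")
}

#' Detect and link a whole stack
#'
#' Convenience wrapper: [detect_spots()] on every frame, then
#' [link_tracks()]. Positions are reported in the trajectory coordinate
#' system of the stack (its `origin_um` is added).
#'
#' @param stack an [image_stack()].
#' @param params a [tracking_params()].
#' @return a [trajectory_set()].
#' @export
track_stack <- function(stack, params = tracking_params()) {
  stopifnot(inherits(stack, "image_stack"))
  det <- lapply(seq_len(dim(stack$frames)[1]),
                function(f) detect_spots(stack$frames[f, , ], params))
  tr <- link_tracks(det, params, pixel_size = stack$pixel_size,
                    frame_interval = stack$frame_interval)
  tr$x_um <- tr$x_um + stack$origin_um[1]
  tr$y_um <- tr$y_um + stack$origin_um[2]
  tr
}
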