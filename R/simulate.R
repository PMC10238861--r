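#' Simulation configuration for membrane particle dynamics
#'
#' Bundles and validates the parameters of the stochastic membrane-particle
#' simulator: Brownian diffusion (optionally heterogeneous across particles),
#' deterministic advection by a cortical flow, and exponential membrane
#' dissociation at constant particle number (a dissociating particle is
#' replaced by a new one at a random position, mimicking binding from a
#' well-mixed cytoplasm).
#'
#' @param n_particles number of particles present in every frame.
#' @param D mean membrane diffusivity, um^2/s.
#' @param cv_D coefficient of variation of per-particle diffusivity. For
#'   `cv_D > 0` each particle draws its own diffusivity from a log-normal
#'   distribution with mean `D` and CV `cv_D` (log-normal guarantees
#'   positivity); `cv_D = 0` gives all particles the same `D`.
#' @param k_off membrane dissociation rate, 1/s. Particle lifetimes are
#'   exponential with this rate; `k_off = 0` means permanent residence.
#' @param v_parallel,v_perpendicular advection velocity along/across the long
#'   (x) axis of the field of view, um/s.
#' @param frame_interval time between frames, s.
#' @param duration total movie duration, s.
#' @param long_axis,short_axis field-of-view extent, um.
#' @param pixel_size um per pixel for rendering.
#' @param psf_sigma point-spread-function width for rendering, px.
#' @param background_mean,background_noise_sd Gaussian camera background, counts.
#' @param spot_amplitude peak amplitude of a rendered spot, counts.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_particles = 100, D = 0.1, cv_D = 0, k_off = 0,
                       v_parallel = 0, v_perpendicular = 0,
                       frame_interval = 0.1, duration = 100,
                       long_axis = 50, short_axis = 30,
                       pixel_size = 0.1, psf_sigma = 1.3,
                       background_mean = 100, background_noise_sd = 10,
                       spot_amplitude = 200, seed = 1L) {
  check_scalar(n_particles, "n_particles", min = 0)
  check_scalar(D, "D", min = 0)
  check_scalar(cv_D, "cv_D", min = 0)
  check_scalar(k_off, "k_off", min = 0)
  check_scalar(frame_interval, "frame_interval", min = 0, strict = TRUE)
  check_scalar(duration, "duration", min = frame_interval)
  check_scalar(pixel_size, "pixel_size", min = 0, strict = TRUE)
  check_scalar(long_axis, "long_axis", min = 0, strict = TRUE)
  check_scalar(short_axis, "short_axis", min = 0, strict = TRUE)
  check_scalar(psf_sigma, "psf_sigma", min = 0, strict = TRUE)
  cfg <- list(n_particles = as.integer(n_particles), D = D, cv_D = cv_D,
              k_off = k_off, v_parallel = v_parallel,
              v_perpendicular = v_perpendicular,
              frame_interval = frame_interval, duration = duration,
              long_axis = long_axis, short_axis = short_axis,
              pixel_size = pixel_size, psf_sigma = psf_sigma,
              background_mean = background_mean,
              background_noise_sd = background_noise_sd,
              spot_amplitude = spot_amplitude, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Particle simulation config:\n")
  cat(sprintf("  %d particles, D = %g um^2/s (CV %g), k_off = %g /s\n",
              x$n_particles, x$D, x$cv_D, x$k_off))
  cat(sprintf("  v = (%g, %g) um/s, dt = %g s, T = %g s, FOV %g x %g um\n",
              x$v_parallel, x$v_perpendicular, x$frame_interval, x$duration,
              x$long_axis, x$short_axis))
  invisible(x)
}

## Draw per-particle diffusivities: log-normal with mean D and CV cv_D.
draw_diffusivities <- function(n, D, cv_D) {
  if (cv_D == 0 || D == 0) return(rep(D, n))
  sdlog2 <- log(1 + cv_D^2)
  stats::rlnorm(n, meanlog = log(D) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

draw_lifetime <- function(k_off) if (k_off <= 0) Inf else stats::rexp(1L, rate = k_off)

#' Simulate membrane particle trajectories
#'
#' Stochastic simulation of `n_particles` membrane-bound particles observed at
#' discrete frames. Each frame-to-frame step is a Gaussian diffusive
#' displacement (per-particle diffusivity) plus a deterministic advective
#' offset `v * dt`. Particles carry exponential lifetimes (rate `k_off`); on
#' expiry a particle is replaced by a new particle id at a uniform-random
#' position, so occupancy is exactly `n_particles` in every frame. No spatial
#' boundary is enforced; the renderer pads its canvas instead.
#'
#' @param config a [sim_config()].
#' @return a `trajectory_set`: a data frame with columns `particle_id`,
#'   `frame`, `time_s`, `x_um`, `y_um`, `intensity`, with attributes
#'   `provenance = "simulated"` and `ground_truth` (per-particle diffusivity
#'   and lifetime).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_frames <- floor(config$duration / config$frame_interval) + 1L
  dt <- config$frame_interval
  n <- config$n_particles
  if (n == 0L) {
    out <- trajectory_set(data.frame(particle_id = integer(0), frame = integer(0),
                                     time_s = numeric(0), x_um = numeric(0),
                                     y_um = numeric(0), intensity = numeric(0)),
                          provenance = "simulated")
    attr(out, "ground_truth") <- data.frame(particle_id = integer(0),
                                            D = numeric(0), lifetime_s = numeric(0))
    return(out)
  }
  drift_x <- config$v_parallel * dt
  drift_y <- config$v_perpendicular * dt

  next_id <- n + 1L
  id <- seq_len(n)
  x <- stats::runif(n, 0, config$long_axis)
  y <- stats::runif(n, 0, config$short_axis)
  Dp <- draw_diffusivities(n, config$D, config$cv_D)
  life <- vapply(seq_len(n), function(i) draw_lifetime(config$k_off), numeric(1))
  ## intensity: constant per particle around the configured spot amplitude
  amp <- rep(config$spot_amplitude, n)

  gt <- data.frame(particle_id = id, D = Dp, lifetime_s = life)
  res <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t_now <- (f - 1L) * dt
    res[[f]] <- data.frame(particle_id = id, frame = f - 1L, time_s = t_now,
                           x_um = x, y_um = y, intensity = amp)
    if (f == n_frames) break
    ## replacements happen for particles whose lifetime ends within this step
    expired <- (life - t_now) <= dt & is.finite(life)
    keep <- !expired
    sd_step <- sqrt(2 * Dp * dt)
    x[keep] <- x[keep] + stats::rnorm(sum(keep), drift_x, sd_step[keep])
    y[keep] <- y[keep] + stats::rnorm(sum(keep), drift_y, sd_step[keep])
    if (any(expired)) {
      k <- sum(expired)
      id[expired] <- next_id - 1L + seq_len(k)
      next_id <- next_id + k
      x[expired] <- stats::runif(k, 0, config$long_axis)
      y[expired] <- stats::runif(k, 0, config$short_axis)
      Dp[expired] <- draw_diffusivities(k, config$D, config$cv_D)
      newlife <- vapply(seq_len(k), function(i) draw_lifetime(config$k_off), numeric(1))
      life[expired] <- t_now + dt + newlife
      gt <- rbind(gt, data.frame(particle_id = id[expired], D = Dp[expired],
                                 lifetime_s = newlife))
    }
  }
  out <- trajectory_set(do.call(rbind, res), provenance = "simulated")
  attr(out, "ground_truth") <- gt
  out
}

#' Trajectory set constructor
#'
#' Validates a table of per-particle, per-frame positions. Frames within a
#' particle id must be strictly increasing and contiguous runs (a particle id
#' never reappears after its last frame).
#'
#' @param df data frame with columns `particle_id`, `frame`, `time_s`, `x_um`,
#'   `y_um`, `intensity`.
#' @param provenance `"simulated"` or `"tracked"`.
#' @return the data frame with class `trajectory_set`.
#' @export
trajectory_set <- function(df, provenance = c("simulated", "tracked")) {
  provenance <- match.arg(provenance)
  need <- c("particle_id", "frame", "time_s", "x_um", "y_um", "intensity")
  stop_if(!all(need %in% names(df)), "missing trajectory columns: ",
          paste(setdiff(need, names(df)), collapse = ", "))
  stop_if(any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)),
          "trajectory positions must be finite")
  if (nrow(df) > 1L) {
    ord <- order(df$particle_id, df$frame)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    d_same <- diff(df$frame)[diff(df$particle_id) == 0]
    stop_if(any(d_same <= 0), "frames must be strictly increasing within a particle")
  }
  structure(df, class = c("trajectory_set", "data.frame"), provenance = provenance)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set (%s): %d particles, %d rows, frames %d..%d\n",
              attr(x, "provenance"), length(unique(x$particle_id)), nrow(x),
              min(x$frame), max(x$frame)))
  invisible(x)
}

#' Write / read trajectory CSV
#'
#' @param traj a `trajectory_set`.
#' @param path CSV path.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param provenance provenance label to attach on read.
#' @export
read_trajectories <- function(path, provenance = "tracked") {
  trajectory_set(utils::read.csv(path), provenance = provenance)
}
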