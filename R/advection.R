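#' Project particle displacements onto the local flow frame
#'
#' For every in-track step of lag `tau_frames`, the raw displacement vector
#' is rotated into the coordinate frame of the local flow vector sampled at
#' the step's start position and time: `dx` is the component parallel to the
#' flow, `dy` the perpendicular component (left-handed normal, so a pure
#' rotation of flow and displacement together leaves the pair unchanged).
#' The local flow speed `nu` is recorded per step; steps where `nu` falls
#' below `speed_floor` are flagged (`ok = FALSE`) because the parallel
#' direction is ill-defined there.
#'
#' @param traj a [trajectory_set()], positions in um.
#' @param flow a [flow_field()] covering the trajectory extent, um/s.
#' @param tau_frames lag in frames (>= 1).
#' @param speed_floor minimum flow speed for a well-defined direction, um/s.
#' @return data frame of class `displacement_sample` with columns
#'   `particle_id`, `t_start`, `tau`, `dx`, `dy`, `nu`, `ok`.
#' @export
project_displacements <- function(traj, flow, tau_frames = 5L,
                                  speed_floor = 0.01) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(flow, "flow_field"))
  stop_if(tau_frames < 1L, "tau_frames must be >= 1")
  df <- as.data.frame(traj)
  df <- df[order(df$particle_id, df$frame), ]
  ## pair each row with the row tau_frames later in the same track
  idx <- seq_len(nrow(df) - tau_frames)
  if (nrow(df) <= tau_frames) idx <- integer(0)
  i0 <- idx; i1 <- idx + tau_frames
  same <- df$particle_id[i0] == df$particle_id[i1] &
    (df$frame[i1] - df$frame[i0]) == tau_frames
  i0 <- i0[same]; i1 <- i1[same]
  if (!length(i0)) {
    warning("no steps at the requested lag")
    out <- data.frame(particle_id = integer(0), t_start = numeric(0),
                      tau = numeric(0), dx = numeric(0), dy = numeric(0),
                      nu = numeric(0), ok = logical(0))
    class(out) <- c("displacement_sample", "data.frame")
    return(out)
  }
  v <- sample_flow(flow, df$x_um[i0], df$y_um[i0], df$time_s[i0])
  nu <- v$speed
  ux <- ifelse(nu > 0, v$vx / nu, 1)
  uy <- ifelse(nu > 0, v$vy / nu, 0)
  ddx <- df$x_um[i1] - df$x_um[i0]
  ddy <- df$y_um[i1] - df$y_um[i0]
  out <- data.frame(particle_id = df$particle_id[i0],
                    t_start = df$time_s[i0],
                    tau = df$time_s[i1] - df$time_s[i0],
                    dx = ddx * ux + ddy * uy,          # parallel to flow
                    dy = -ddx * uy + ddy * ux,         # perpendicular
                    nu = nu,
                    ok = nu >= speed_floor)
  class(out) <- c("displacement_sample", "data.frame")
  out
}

#' Fit advection velocity and coupling coefficient
#'
#' The pooled parallel and perpendicular displacement distributions are
#' Gaussian; their means give the advection velocities `vx = <dx>/tau` and
#' `vy = <dy>/tau`, and the cortex coupling coefficient is
#' `cc = vx / mean(nu)` with `mean(nu)` the mean local flow speed over the
#' fitted steps. The primary fit is the unbinned maximum-likelihood Gaussian
#' (sample mean/SD); a binned least-squares Gaussian fit of the histogram is
#' run as a cross-check and must agree.
#'
#' @param samples a `displacement_sample` from [project_displacements()];
#'   steps flagged `ok = FALSE` are dropped.
#' @param tau lag in seconds; defaults to the samples' common lag.
#' @param min_samples smallest sample size accepted.
#' @param n_bins histogram bins for the cross-check fit.
#' @return object of class `coupling_fit` with elements `vx`, `vy` (um/s),
#'   `nu_bar`, `cc` (NA when `nu_bar` is 0), `sigma_x`, `sigma_y` (um),
#'   `se_vx`, `se_vy`, `se_cc`, `n_steps`, `tau`, and the binned cross-check
#'   (`binned`).
#' @export
fit_advection <- function(samples, tau = NULL, min_samples = 200L,
                          n_bins = 41L) {
  stopifnot(inherits(samples, "displacement_sample") || is.data.frame(samples))
  s <- samples[samples$ok %||% TRUE, , drop = FALSE]
  stop_if(nrow(s) < min_samples,
          sprintf("only %d usable steps (< %d required)", nrow(s), min_samples))
  if (is.null(tau)) {
    tau <- stats::median(s$tau)
  }
  check_scalar(tau, "tau", min = 0, strict = TRUE)
  mx <- mean(s$dx); my <- mean(s$dy)
  sx <- stats::sd(s$dx); sy <- stats::sd(s$dy)
  n <- nrow(s)
  nu_bar <- mean(s$nu)
  vx <- mx / tau; vy <- my / tau
  se_vx <- sx / sqrt(n) / tau; se_vy <- sy / sqrt(n) / tau
  cc <- if (nu_bar > 0) vx / nu_bar else NA_real_
  se_cc <- if (nu_bar > 0) se_vx / nu_bar else NA_real_
  binned <- list(x = gauss_hist_fit(s$dx, n_bins),
                 y = gauss_hist_fit(s$dy, n_bins))
  structure(list(vx = vx, vy = vy, nu_bar = nu_bar, cc = cc,
                 sigma_x = sx, sigma_y = sy, se_vx = se_vx, se_vy = se_vy,
                 se_cc = se_cc, n_steps = n, tau = tau, binned = binned),
            class = "coupling_fit")
}

## Least-squares Gaussian fit to a histogram of displacements; returns the
## fitted mean/sd (NA on failure). Cross-check for the unbinned estimate.
gauss_hist_fit <- function(d, n_bins = 41L) {
  h <- graphics::hist(d, breaks = n_bins, plot = FALSE)
  xc <- h$mids; yc <- h$counts
  st <- list(a = max(yc), mu = mean(d), sg = stats::sd(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(yc ~ a * exp(-(xc - mu)^2 / (2 * sg^2)), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(mean = NA_real_, sd = NA_real_))
  cf <- stats::coef(fit)
  c(mean = unname(cf["mu"]), sd = abs(unname(cf["sg"])))
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("Coupling fit (displacement projection):\n")
  cat(sprintf("  v_parallel = %.4g +- %.2g um/s, v_perp = %.4g +- %.2g um/s (tau = %g s, n = %d)\n",
              x$vx, x$se_vx, x$vy, x$se_vy, x$tau, x$n_steps))
  if (is.na(x$cc)) cat("  mean flow speed 0 -> coupling coefficient undefined\n")
  else cat(sprintf("  mean flow speed = %.4g um/s -> cc = %.3f +- %.3f\n",
                   x$nu_bar, x$cc, x$se_cc))
  invisible(x)
}

#' @export
summary.coupling_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  Gaussian widths: sigma_x = %.4g, sigma_y = %.4g um\n",
              object$sigma_x, object$sigma_y))
  b <- object$binned
  cat(sprintf("  binned cross-check means: x %.4g, y %.4g um\n",
              b$x["mean"], b$y["mean"]))
  invisible(object)
}

#' @export
coef.coupling_fit <- function(object, ...) {
  c(vx = object$vx, vy = object$vy, cc = object$cc,
    sigma_x = object$sigma_x, sigma_y = object$sigma_y)
}

#' Per-particle diffusivity from step sizes
#'
#' Single-lag steady-state estimate: `D = <d^2> / (4 tau)` from 2D squared
#' displacements, or `D = <dy^2> / (2 tau)` using only the component
#' perpendicular to the local flow (removing the advective contribution;
#' required whenever flow is active).
#'
#' @param traj a [trajectory_set()].
#' @param flow a [flow_field()]; required for `mode = "perpendicular"`.
#' @param tau_frames lag in frames.
#' @param mode `"2d"` or `"perpendicular"`.
#' @return data frame of class `diffusivity_estimate` with `particle_id`,
#'   `D`, `n_steps`; attributes `tau`, `mode`, and `pooled` (the single
#'   estimate pooling all steps).
#' @export
estimate_diffusivity <- function(traj, flow = NULL, tau_frames = 2L,
                                 mode = c("2d", "perpendicular")) {
  mode <- match.arg(mode)
  stop_if(mode == "perpendicular" && is.null(flow),
          "perpendicular mode needs a flow field")
  if (mode == "perpendicular") {
    s <- project_displacements(traj, flow, tau_frames, speed_floor = 0)
    tau <- stats::median(s$tau)
    d2 <- s$dy^2
    denom <- 2 * tau
  } else {
    ## plain frame displacement without a flow frame
    flow0 <- flow_field_uniform(1, 0, xlim = range(traj$x_um) + c(-1, 1),
                                ylim = range(traj$y_um) + c(-1, 1),
                                tlim = range(traj$time_s) + c(-1, 1))
    s <- project_displacements(traj, flow0, tau_frames, speed_floor = 0)
    tau <- stats::median(s$tau)
    d2 <- s$dx^2 + s$dy^2
    denom <- 4 * tau
  }
  agg <- stats::aggregate(d2, by = list(particle_id = s$particle_id), FUN = mean)
  cnt <- stats::aggregate(d2, by = list(particle_id = s$particle_id), FUN = length)
  out <- data.frame(particle_id = agg$particle_id, D = agg$x / denom,
                    n_steps = cnt$x)
  attr(out, "tau") <- tau
  attr(out, "mode") <- mode
  attr(out, "pooled") <- mean(d2) / denom
  class(out) <- c("diffusivity_estimate", "data.frame")
  out
}

#' Coupling fits for particles binned by intensity or diffusivity
#'
#' Particles are assigned to bins by mean intensity or by their single-lag
#' diffusivity estimate, and [fit_advection()] is run per bin.
#'
#' @param traj a [trajectory_set()].
#' @param flow a [flow_field()].
#' @param bin_by `"intensity"` or `"diffusivity"`.
#' @param bin_edges numeric bin edges covering the observed range (sorted
#'   internally).
#' @param tau_frames lag for the advection fit, frames.
#' @param diff_tau_frames lag for the diffusivity used in binning, frames.
#' @param min_samples forwarded to [fit_advection()].
#' @return data frame with one row per bin (`bin`, `lower`, `upper`,
#'   `n_particles`, `n_steps`, `vx`, `vy`, `nu_bar`, `cc`); empty bins carry
#'   NA estimates with a warning. The individual `coupling_fit` objects are
#'   in attribute `fits`.
#' @export
bin_and_fit <- function(traj, flow, bin_by = c("intensity", "diffusivity"),
                        bin_edges, tau_frames = 5L, diff_tau_frames = 2L,
                        min_samples = 200L) {
  bin_by <- match.arg(bin_by)
  bin_edges <- sort(bin_edges)
  if (bin_by == "intensity") {
    per <- stats::aggregate(intensity ~ particle_id, data = as.data.frame(traj),
                            FUN = mean)
    val <- stats::setNames(per$intensity, per$particle_id)
  } else {
    de <- estimate_diffusivity(traj, flow, diff_tau_frames, mode = "perpendicular")
    val <- stats::setNames(de$D, de$particle_id)
  }
  samples <- project_displacements(traj, flow, tau_frames)
  bin_of <- cut(val, breaks = bin_edges, include.lowest = TRUE)
  fits <- vector("list", nlevels(bin_of))
  rows <- lapply(seq_len(nlevels(bin_of)), function(b) {
    ids <- as.integer(names(val)[!is.na(bin_of) & as.integer(bin_of) == b])
    sub <- samples[samples$particle_id %in% ids, , drop = FALSE]
    fit <- tryCatch(fit_advection(sub, min_samples = min_samples),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("bin %d (%s): too few samples, estimate missing",
                      b, levels(bin_of)[b]))
      data.frame(bin = levels(bin_of)[b], lower = bin_edges[b],
                 upper = bin_edges[b + 1], n_particles = length(ids),
                 n_steps = nrow(sub), vx = NA_real_, vy = NA_real_,
                 nu_bar = NA_real_, cc = NA_real_)
    } else {
      fits[[b]] <<- fit
      data.frame(bin = levels(bin_of)[b], lower = bin_edges[b],
                 upper = bin_edges[b + 1], n_particles = length(ids),
                 n_steps = fit$n_steps, vx = fit$vx, vy = fit$vy,
                 nu_bar = fit$nu_bar, cc = fit$cc)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Statistical power for detecting advective drift
#'
#' For each diffusivity, simulates `n_replicates` independent sets of
#' `n_displacements` displacement pairs at lag `tau`: the flow-parallel
#' component carries drift `v * tau`, the perpendicular one does not, both
#' with diffusive spread `sqrt(2 D tau)`. Each replicate compares the two
#' samples with an unpaired two-tailed t-test. Detection at a given D is
#' declared when the majority of replicates is significant at `alpha`.
#'
#' @param D_grid diffusivities to probe, um^2/s.
#' @param v advective drift, um/s (> 0).
#' @param n_displacements displacement pairs per replicate.
#' @param tau lag, s.
#' @param n_replicates independent replicates per D.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return list of class `detection_power` with `table` (per-replicate
#'   p-values), `summary` (per-D fraction significant), and
#'   `max_detectable_D` (largest probed D at which the majority of
#'   replicates is significant).
#' @export
detection_power <- function(D_grid, v = 0.1, n_displacements = 1000L,
                            tau = 0.5, n_replicates = 20L, alpha = 0.05,
                            seed = 1L) {
  check_scalar(v, "v", min = 0)
  set.seed(derive_seed(seed, "power"))
  rows <- list()
  for (D in D_grid) {
    sd_step <- sqrt(2 * D * tau)
    for (r in seq_len(n_replicates)) {
      dx <- stats::rnorm(n_displacements, v * tau, sd_step)
      dy <- stats::rnorm(n_displacements, 0, sd_step)
      p <- if (sd_step == 0) 0 else stats::t.test(dx, dy, var.equal = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(D = D, replicate = r, p_value = p)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- stats::aggregate(p_value ~ D, data = tab,
                           FUN = function(p) mean(p < alpha))
  names(summ)[2] <- "fraction_significant"
  detectable <- summ$D[summ$fraction_significant > 0.5]
  structure(list(table = tab, summary = summ,
                 max_detectable_D = if (length(detectable)) max(detectable) else NA_real_,
                 alpha = alpha, v = v, tau = tau,
                 n_displacements = n_displacements),
            class = "detection_power")
}

#' @export
print.detection_power <- function(x, ...) {
  cat(sprintf("Advection detection power (v = %g um/s, tau = %g s, n = %d/replicate):\n",
              x$v, x$tau, x$n_displacements))
  print(x$summary, row.names = FALSE)
  cat(sprintf("  largest reliably detectable D: %g um^2/s\n", x$max_detectable_D))
  invisible(x)
}
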