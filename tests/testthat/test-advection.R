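test_that("displacements are rotated into the local flow frame", {
  mk_traj <- function() trajectory_set(data.frame(
    particle_id = c(1L, 1L), frame = 0:1, time_s = c(0, 0.1),
    x_um = c(1, 1.05), y_um = c(1, 1.02), intensity = 100), "simulated")
  ## flow along +x: dx is the raw x displacement
  s1 <- project_displacements(mk_traj(), uflow(0.1, 0), 1L)
  expect_equal(s1$dx, 0.05, tolerance = 1e-12)
  expect_equal(s1$dy, 0.02, tolerance = 1e-12)
  ## flow rotated 90 deg (along +y): parallel picks up the y component
  s2 <- project_displacements(mk_traj(), uflow(0, 0.1), 1L)
  expect_equal(s2$dx, 0.02, tolerance = 1e-12)
  expect_equal(s2$dy, -0.05, tolerance = 1e-12)
})

test_that("particles advected at the flow velocity drift only parallel to it", {
  tr <- quick_sim(D = 0.05, v = 0.1, n = 200, duration = 10, seed = 61)
  s <- project_displacements(tr, uflow(0.1, 0), 5L)
  se <- sd(s$dy) / sqrt(nrow(s))
  expect_lt(abs(mean(s$dy)), 3 * se)
  expect_equal(mean(s$dx), 0.1 * 0.5, tolerance = 3 * se / 0.05)
})

test_that("coupling coefficients match their constructed values", {
  ## no drift against a 0.1 um/s flow: the eggshell-bead control, cc ~ 0
  tr0 <- quick_sim(D = 0.05, v = 0, n = 200, duration = 10, seed = 63)
  f0 <- fit_advection(project_displacements(tr0, uflow(0.1, 0), 5L))
  expect_lt(abs(f0$cc), 3 * f0$se_cc + 0.02)
  ## full entrainment: cc ~ 1
  tr1 <- quick_sim(D = 0.05, v = 0.1, n = 200, duration = 10, seed = 65)
  f1 <- fit_advection(project_displacements(tr1, uflow(0.1, 0), 5L))
  expect_equal(f1$cc, 1, tolerance = 0.1)
  ## half-speed drift: cc ~ 0.5
  tr5 <- quick_sim(D = 0.05, v = 0.05, n = 200, duration = 10, seed = 67)
  f5 <- fit_advection(project_displacements(tr5, uflow(0.1, 0), 5L))
  expect_equal(f5$cc, 0.5, tolerance = 0.1)
})

test_that("zero mean flow leaves cc undefined and small samples error", {
  tr <- quick_sim(D = 0.05, n = 50, duration = 2, seed = 69)
  s <- project_displacements(tr, uflow(0, 0), 1L, speed_floor = 0)
  fit <- fit_advection(s, tau = 0.1, min_samples = 100L)
  expect_true(is.na(fit$cc))
  expect_error(fit_advection(s[1:50, ], tau = 0.1), "usable steps")
})

test_that("binned Gaussian fit agrees with the sample-moment estimate", {
  tr <- quick_sim(D = 0.1, v = 0.08, n = 300, duration = 10, seed = 71)
  fit <- fit_advection(project_displacements(tr, uflow(0.1, 0), 5L))
  ## the two estimators target the same mean; agreement within a standard
  ## error of the mean displacement
  tol <- fit$sigma_x / sqrt(fit$n_steps)
  expect_lt(abs(fit$binned$x[["mean"]] - fit$vx * fit$tau), 3 * tol)
})

test_that("cc is invariant under a global rotation of flow and trajectories", {
  tr <- quick_sim(D = 0.05, v = 0.1, n = 150, duration = 10, seed = 73)
  f_orig <- fit_advection(project_displacements(tr, uflow(0.1, 0), 5L))
  th <- 35 * pi / 180
  rot <- as.data.frame(tr)
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um
  tr_rot <- trajectory_set(rot, "simulated")
  fl_rot <- uflow(0.1 * cos(th), 0.1 * sin(th), lim = 150)
  f_rot <- fit_advection(project_displacements(tr_rot, fl_rot, 5L))
  expect_equal(f_rot$cc, f_orig$cc, tolerance = 1e-6)
})

test_that("diffusivity estimates recover the simulated values", {
  ## stationary particle -> D = 0
  still <- trajectory_set(data.frame(particle_id = 1L, frame = 0:10,
                                     time_s = (0:10) * 0.1, x_um = 2, y_um = 3,
                                     intensity = 1), "simulated")
  e0 <- estimate_diffusivity(still, tau_frames = 2L, mode = "2d")
  expect_equal(e0$D, 0)
  ## D = 0.1 pooled within 10%
  tr <- quick_sim(D = 0.1, n = 300, duration = 10, seed = 75)
  e1 <- estimate_diffusivity(tr, tau_frames = 2L, mode = "2d")
  expect_equal(attr(e1, "pooled"), 0.1, tolerance = 0.1)
  ## perpendicular-mode estimate is invariant to the advection velocity
  trv <- quick_sim(D = 0.1, v = 0.2, n = 300, duration = 10, seed = 75)
  e2 <- estimate_diffusivity(trv, uflow(0.2, 0), tau_frames = 2L,
                             mode = "perpendicular")
  expect_equal(attr(e2, "pooled"), 0.1, tolerance = 0.1)
  ## pure advection has zero perpendicular diffusivity
  tra <- quick_sim(D = 0, v = 0.1, n = 50, duration = 5, seed = 77)
  e3 <- estimate_diffusivity(tra, uflow(0.1, 0), tau_frames = 2L,
                             mode = "perpendicular")
  expect_lt(attr(e3, "pooled"), 1e-12)
  expect_error(estimate_diffusivity(tr, mode = "perpendicular"), "flow field")
})

test_that("binning by diffusivity leaves coupling unchanged", {
  ## two sub-populations (slow/fast diffusion), both fully advected
  cfg_slow <- sim_config(n_particles = 120, D = 0.01, v_parallel = 0.1,
                         duration = 10, seed = 81)
  cfg_fast <- sim_config(n_particles = 120, D = 0.1, v_parallel = 0.1,
                         duration = 10, seed = 83)
  slow <- simulate_trajectories(cfg_slow)
  fast <- as.data.frame(simulate_trajectories(cfg_fast))
  fast$particle_id <- fast$particle_id + max(slow$particle_id)
  both <- trajectory_set(rbind(as.data.frame(slow), fast), "simulated")
  res <- bin_and_fit(both, uflow(0.1, 0), bin_by = "diffusivity",
                     bin_edges = c(0, 0.04, 1), tau_frames = 5L)
  expect_equal(nrow(res), 2L)
  expect_gt(min(res$n_particles), 50)
  expect_equal(res$cc[1], 1, tolerance = 0.15)
  expect_equal(res$cc[2], 1, tolerance = 0.15)
})

test_that("binning flags empty bins and is stable under permuted edges", {
  tr <- quick_sim(D = 0.05, v = 0.1, n = 100, duration = 5, seed = 85)
  expect_warning(
    res <- bin_and_fit(tr, uflow(0.1, 0), bin_by = "intensity",
                       bin_edges = c(0, 150, 1e4), tau_frames = 2L),
    "too few")
  expect_true(is.na(res$cc[1]) || is.na(res$cc[2]))
  res2 <- suppressWarnings(
    bin_and_fit(tr, uflow(0.1, 0), bin_by = "intensity",
                bin_edges = c(1e4, 0, 150), tau_frames = 2L))
  expect_equal(res2$cc, res$cc)
})

test_that("drift detection power behaves as expected at the extremes", {
  pw <- detection_power(c(0.001, 2), v = 0.1, n_replicates = 10, seed = 3)
  p_small <- pw$table$p_value[pw$table$D == 0.001]
  expect_true(all(p_small < 1e-6))
  ## near-null calibration: fraction significant about alpha
  pw0 <- detection_power(0.01, v = 0, n_replicates = 200, seed = 5)
  expect_gt(pw0$summary$fraction_significant, 0.005)
  expect_lt(pw0$summary$fraction_significant, 0.12)
})
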