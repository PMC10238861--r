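#' Run the full synthetic/real analysis pipeline
#'
#' Orchestrates the stages in dependency order — simulate -> render ->
#' track -> piv -> advect, and/or pde -> metrics — from a single
#' configuration, writing intermediate files, per-stage JSON reports and a
#' provenance log (resolved config, seeds, package version) to `out_dir`.
#' The global seed is fanned out to one deterministic substream per stage,
#' so identical configs give byte-identical outputs.
#'
#' @param config a named list (see Details) or path to a YAML file.
#' @param out_dir output directory, created if missing.
#' @return invisible list with the in-memory stage results and a `status`
#'   data frame.
#'
#' @details Recognised config blocks: `stages` (character subset of
#'   `"simulate"`, `"render"`, `"track"`, `"piv"`, `"advect"`, `"pde"`),
#'   `seed`, `simulation` (arguments of [sim_config()]), `tracking`
#'   ([tracking_params()]), `piv` ([piv_params()]), `pde` ([pde_params()]),
#'   `advection` (`tau_frames`, `flow` = `"piv"` or `"uniform"`,
#'   `uniform_speed`), and input paths `tracks_csv` / `flow_csv` to start
#'   from pre-computed tables instead of simulation.
#' @export
run_pipeline <- function(config, out_dir = "corflow-run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "render", "track", "piv", "advect")
  seed <- config$seed %||% 1L
  res <- list()
  status <- data.frame(stage = character(0), ok = logical(0),
                       message = character(0))
  note <- function(stage, ok, msg = "") {
    status <<- rbind(status, data.frame(stage = stage, ok = ok, message = msg))
    if (!ok) {
      utils::write.csv(status, file.path(out_dir, "status.csv"), row.names = FALSE)
      stop(sprintf("stage '%s' failed: %s (dependents skipped, partial outputs retained)",
                   stage, msg), call. = FALSE)
    }
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% stages)) return(invisible(NULL))
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) note(stage, FALSE, conditionMessage(out))
    else note(stage, TRUE)
    out
  }

  sim_args <- config$simulation %||% list()
  sim_args$seed <- derive_seed(seed, "simulate")
  cfg <- do.call(sim_config, sim_args)

  res$trajectories <- run_stage("simulate", function() {
    tr <- simulate_trajectories(cfg)
    write_trajectories(tr, file.path(out_dir, "trajectories_truth.csv"))
    tr
  })
  if (!is.null(config$tracks_csv))
    res$trajectories <- read_trajectories(config$tracks_csv)

  res$stack <- run_stage("render", function() {
    st <- render_images(res$trajectories, cfg)
    write_image_stack(st, file.path(out_dir, "particles.tif"))
    st
  })
  res$cortex <- run_stage("piv", function() {
    uv <- config$advection$uniform_speed %||% 0.1
    fl <- if (!is.null(config$flow_csv)) read_flow_field(config$flow_csv)
          else flow_field_uniform(uv, 0,
                                  xlim = c(0, cfg$long_axis),
                                  ylim = c(0, cfg$short_axis),
                                  tlim = c(0, cfg$duration))
    ct <- render_cortex_texture(fl, cfg)
    write_image_stack(ct, file.path(out_dir, "cortex.tif"))
    ct
  })
  res$tracks <- run_stage("track", function() {
    tp <- do.call(tracking_params, config$tracking %||% list())
    tr <- track_stack(res$stack, tp)
    write_trajectories(tr, file.path(out_dir, "tracks.csv"))
    tr
  })
  res$flow <- run_stage("piv", function() {
    pp <- do.call(piv_params, config$piv %||% list())
    fl <- piv(res$cortex, pp)
    write_flow_field(fl, file.path(out_dir, "flow.csv"))
    fl
  })
  res$coupling <- run_stage("advect", function() {
    adv <- config$advection %||% list()
    traj <- res$tracks %||% res$trajectories
    flow <- if (identical(adv$flow %||% "piv", "piv") && !is.null(res$flow)) res$flow
            else flow_field_uniform(adv$uniform_speed %||% 0.1, 0,
                                    xlim = c(-10, cfg$long_axis + 10),
                                    ylim = c(-10, cfg$short_axis + 10),
                                    tlim = c(0, cfg$duration))
    s <- project_displacements(traj, flow, adv$tau_frames %||% 5L)
    fit <- fit_advection(s)
    report <- list(vx = fit$vx, vy = fit$vy, cc = fit$cc, nu_bar = fit$nu_bar,
                   sigma_x = fit$sigma_x, sigma_y = fit$sigma_y,
                   n_steps = fit$n_steps, tau = fit$tau,
                   ci_cc = c(fit$cc - 1.96 * fit$se_cc, fit$cc + 1.96 * fit$se_cc))
    jsonlite::write_json(report, file.path(out_dir, "advection.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(s), file.path(out_dir, "displacements.csv"),
                     row.names = FALSE)
    fit
  })
  res$pde <- run_stage("pde", function() {
    pde_args <- config$pde %||% list()
    pp <- do.call(pde_params, pde_args)
    sol <- solve_pde(pp)
    m <- compute_metrics(sol)
    jsonlite::write_json(list(peak_ASI = m$peak_ASI,
                              peak_depletion = m$peak_depletion,
                              t_half_ASI = m$t_half_ASI,
                              t_half_depletion = m$t_half_depletion),
                         file.path(out_dir, "pde_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(solution = sol, metrics = m)
  })

  prov <- list(package = "corflow",
               version = as.character(utils::packageVersion("corflow")),
               seed = seed, stages = stages, config = config)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(status, file.path(out_dir, "status.csv"), row.names = FALSE)
  res$status <- status
  invisible(res)
}

#' Generate small deterministic test fixtures
#'
#' Writes a fixture dataset plus ground-truth sidecars for the requested
#' stage: `"tracking"` (short rendered stack + truth CSV), `"piv"`
#' (translated speckle pair + displacement truth), `"frap"` (noisy recovery
#' curves at tau = 50/150/400 s), or `"profile"` (straightened membrane
#' image + truth).
#'
#' @param kind fixture family.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return invisible character vector of the files written.
#' @export
make_fixtures <- function(kind = c("tracking", "piv", "frap", "profile"),
                          seed = 1L, dir = "fixtures") {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (kind == "tracking") {
    cfg <- sim_config(n_particles = 12, D = 0.02, duration = 4.9,
                      long_axis = 15, short_axis = 15,
                      spot_amplitude = 300, background_noise_sd = 8,
                      seed = derive_seed(seed, "fix-track"))
    tr <- simulate_trajectories(cfg)
    st <- render_images(tr, cfg)
    f1 <- file.path(dir, "tracking_stack.tif")
    f2 <- file.path(dir, "tracking_truth.csv")
    write_image_stack(st, f1); write_trajectories(tr, f2)
    files <- c(f1, paste0(f1, ".json"), f2)
  } else if (kind == "piv") {
    cfg <- sim_config(long_axis = 16, short_axis = 16, duration = 0.2,
                      frame_interval = 0.1, spot_amplitude = 150,
                      background_mean = 50, background_noise_sd = 2,
                      seed = derive_seed(seed, "fix-piv"))
    shift <- c(0.3, -0.2) # px/frame
    fl <- flow_field_uniform(shift[1] * cfg$pixel_size / cfg$frame_interval,
                             shift[2] * cfg$pixel_size / cfg$frame_interval,
                             xlim = c(0, 16), ylim = c(0, 16), tlim = c(0, 1))
    ct <- render_cortex_texture(fl, cfg, n_frames = 2L)
    f1 <- file.path(dir, "piv_pair.tif")
    write_image_stack(ct, f1)
    f2 <- file.path(dir, "piv_truth.json")
    jsonlite::write_json(list(dx_px = shift[1], dy_px = shift[2]), f2,
                         auto_unbox = TRUE, digits = NA)
    files <- c(f1, paste0(f1, ".json"), f2)
  } else if (kind == "frap") {
    taus <- c(50, 150, 400)
    for (i in seq_along(taus)) {
      cur <- synth_frap_curve(taus[i], noise_sd = 0.02,
                              seed = derive_seed(seed, paste0("fix-frap", i)))
      f <- file.path(dir, sprintf("frap_tau%03d.csv", taus[i]))
      utils::write.csv(cur, f, row.names = FALSE)
      files <- c(files, f)
    }
  } else if (kind == "profile") {
    pos <- seq_len(120)
    membrane <- 100 * (1 - 0.45 * (1 + tanh((pos - 60) / 10)))
    img <- synth_membrane_image(membrane, cytoplasm = 40, noise_sd = 2,
                                seed = derive_seed(seed, "fix-profile"))
    f1 <- file.path(dir, "profile_image.csv")
    utils::write.table(img, f1, sep = ",", row.names = FALSE, col.names = FALSE)
    f2 <- file.path(dir, "profile_truth.csv")
    utils::write.csv(data.frame(position = pos, membrane = membrane,
                                cytoplasm = 40), f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
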