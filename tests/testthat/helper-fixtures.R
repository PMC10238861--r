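## Shared fixture builders: everything is generated in code at test time.

## uniform flow covering a generous box around the default field of view
uflow <- function(vx = 0.1, vy = 0, lim = 100, tmax = 200)
  flow_field_uniform(vx, vy, xlim = c(-lim, lim), ylim = c(-lim, lim),
                     tlim = c(0, tmax))

## quick simulation of advected/diffusing particles
quick_sim <- function(D = 0.1, v = 0, n = 100, duration = 10, seed = 1,
                      k_off = 0, ...) {
  simulate_trajectories(sim_config(n_particles = n, D = D, v_parallel = v,
                                   k_off = k_off, duration = duration,
                                   seed = seed, ...))
}

## rendered cortex pair/stack translated at a known px/frame speed
translated_cortex <- function(shift_px = c(3, -1.5), n_frames = 3, seed = 9,
                              fov = 19.2, speckle_sigma = 1.0) {
  cfg <- sim_config(long_axis = fov, short_axis = fov, frame_interval = 0.1,
                    duration = 1, background_mean = 50,
                    background_noise_sd = 2, spot_amplitude = 150, seed = seed)
  fl <- flow_field_uniform(shift_px[1] * cfg$pixel_size / cfg$frame_interval,
                           shift_px[2] * cfg$pixel_size / cfg$frame_interval,
                           xlim = c(0, fov), ylim = c(0, fov), tlim = c(0, 2))
  list(cfg = cfg,
       stack = render_cortex_texture(fl, cfg, n_frames = n_frames,
                                     speckle_sigma = speckle_sigma))
}
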