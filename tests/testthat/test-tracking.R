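test_that("a blank noise frame yields no detections at a 5 SD threshold", {
  set.seed(1)
  frame <- matrix(rnorm(80 * 80, 100, 5), 80, 80)
  det <- detect_spots(frame, tracking_params(intensity_threshold = 25))
  expect_equal(nrow(det), 0L)
})

test_that("a rendered spot is localized to subpixel accuracy", {
  cfg <- sim_config(n_particles = 1, D = 0, duration = 0.1, long_axis = 12,
                    short_axis = 10, spot_amplitude = 200,
                    background_noise_sd = 2, seed = 41)
  tr <- simulate_trajectories(cfg)
  st <- render_images(tr, cfg)
  det <- detect_spots(st$frames[1, , ], tracking_params(intensity_threshold = 50))
  expect_equal(nrow(det), 1L)
  truth_x <- (tr$x_um[1] - st$origin_um[1]) / cfg$pixel_size + 0.5
  truth_y <- (tr$y_um[1] - st$origin_um[2]) / cfg$pixel_size + 0.5
  expect_lt(abs(det$x - truth_x), 0.2)
  expect_lt(abs(det$y - truth_y), 0.2)
})

test_that("close detections are merged to the brighter spot", {
  img <- matrix(5, 60, 60)
  img <- corflow:::add_spot(img, 30, 30, 200, 1.3)
  img <- corflow:::add_spot(img, 31, 30, 150, 1.3)  # 1 px away, dimmer
  det <- detect_spots(img, tracking_params(intensity_threshold = 20,
                                           min_separation = 2))
  expect_equal(nrow(det), 1L)
  expect_lt(det$x, 30.8)  # merged detection sits near the brighter centre
})

test_that("non-finite frames are rejected and detections decrease with threshold", {
  expect_error(detect_spots(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
  cfg <- sim_config(n_particles = 25, D = 0, duration = 0.1, long_axis = 30,
                    short_axis = 30, spot_amplitude = 150,
                    background_noise_sd = 6, seed = 43)
  st <- render_images(simulate_trajectories(cfg), cfg)
  counts <- vapply(c(10, 40, 80, 160), function(th)
    nrow(detect_spots(st$frames[1, , ], tracking_params(intensity_threshold = th))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a single continuous trajectory links into one full-length track", {
  det <- lapply(0:19, function(f)
    data.frame(x = 10 + 0.5 * f, y = 20 + 0.2 * f, intensity = 100))
  tr <- link_tracks(det, tracking_params(min_track_length = 11),
                    pixel_size = 0.1, frame_interval = 0.1)
  expect_equal(length(unique(tr$particle_id)), 1L)
  expect_equal(nrow(tr), 20L)
  ## px -> um conversion of the first position
  expect_equal(tr$x_um[1], (10 - 0.5) * 0.1)
})

test_that("tracks shorter than min_track_length are discarded", {
  det <- lapply(0:9, function(f) data.frame(x = 10, y = 10, intensity = 50))
  tr <- link_tracks(det, tracking_params(min_track_length = 11))
  expect_equal(nrow(tr), 0L)
  tr2 <- link_tracks(det, tracking_params(min_track_length = 10))
  expect_equal(nrow(tr2), 10L)
})

test_that("well-separated particles are linked without identity switches", {
  ## grid of particles with small diffusive motion, spacing >> displacement
  set.seed(47)
  base <- expand.grid(x = seq(10, 50, by = 10), y = seq(10, 50, by = 10))
  pos <- base
  det <- vector("list", 15L)
  truth <- vector("list", 15L)
  for (f in 1:15) {
    pos$x <- pos$x + rnorm(nrow(pos), 0, 0.5)
    pos$y <- pos$y + rnorm(nrow(pos), 0, 0.5)
    det[[f]] <- data.frame(x = pos$x, y = pos$y, intensity = 100)
    truth[[f]] <- data.frame(id = seq_len(nrow(pos)), frame = f - 1,
                             x = pos$x, y = pos$y)
  }
  tr <- link_tracks(det, tracking_params(max_displacement = 4,
                                         min_track_length = 11),
                    pixel_size = 1, frame_interval = 1)
  expect_equal(length(unique(tr$particle_id)), 25L)
  ## every recovered track must follow exactly one ground-truth particle
  tru <- do.call(rbind, truth)
  for (id in unique(tr$particle_id)) {
    sub <- tr[tr$particle_id == id, ]
    match_ids <- vapply(seq_len(nrow(sub)), function(i) {
      cand <- tru[tru$frame == sub$frame[i], ]
      cand$id[which.min((cand$x - sub$x_um[i])^2 + (cand$y - sub$y_um[i])^2)]
    }, integer(1))
    expect_equal(length(unique(match_ids)), 1L)
  }
})

test_that("no track contains a frame gap when memory is 0", {
  cfg <- sim_config(n_particles = 10, D = 0.05, k_off = 0.3, duration = 4,
                    long_axis = 25, short_axis = 25, spot_amplitude = 300,
                    background_noise_sd = 8, seed = 51)
  st <- render_images(simulate_trajectories(cfg), cfg)
  tr <- track_stack(st, tracking_params(intensity_threshold = 100,
                                        min_track_length = 3))
  gaps <- tapply(tr$frame, tr$particle_id, function(f) any(diff(f) != 1))
  expect_false(any(gaps))
})

test_that("simulate-render-track round trip recovers D and particle count", {
  cfg <- sim_config(n_particles = 16, D = 0.05, duration = 5, long_axis = 40,
                    short_axis = 40, spot_amplitude = 400,
                    background_noise_sd = 8, seed = 53)
  truth <- simulate_trajectories(cfg)
  st <- render_images(truth, cfg)
  tr <- track_stack(st, tracking_params(intensity_threshold = 80,
                                        min_track_length = 11))
  n_per_frame <- table(tr$frame)
  expect_equal(mean(n_per_frame), 16, tolerance = 0.1)
  est <- estimate_diffusivity(tr, tau_frames = 2L, mode = "2d")
  expect_equal(attr(est, "pooled"), 0.05, tolerance = 0.15)
})
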