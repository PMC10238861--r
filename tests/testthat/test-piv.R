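test_that("an identical frame pair gives a near-zero field", {
  fx <- translated_cortex(c(0, 0), n_frames = 3)
  pf <- piv(fx$stack, piv_params(time_average = 1))
  px_per_frame <- fx$cfg$frame_interval / fx$cfg$pixel_size
  expect_lt(max(abs(c(pf$vx, pf$vy))) * px_per_frame, 0.02)
})

test_that("a known rigid translation is recovered within 0.2 px/frame", {
  fx <- translated_cortex(c(3, -1.5), n_frames = 3)
  pf <- piv(fx$stack, piv_params(velocity_limit = 5, time_average = 1))
  to_px <- fx$cfg$frame_interval / fx$cfg$pixel_size
  expect_lt(abs(mean(pf$vx) * to_px - 3), 0.2)
  expect_lt(abs(mean(pf$vy) * to_px - (-1.5)), 0.2)
})

test_that("slow translations within the default velocity limit are accurate", {
  fx <- translated_cortex(c(0.3, 0), n_frames = 4)
  pf <- piv(fx$stack)  # all defaults, incl. 0.3 px/frame limit + 2-frame avg
  to_px <- fx$cfg$frame_interval / fx$cfg$pixel_size
  expect_lt(abs(mean(pf$vx) * to_px - 0.3), 0.05)
  expect_lt(abs(mean(pf$vy) * to_px), 0.05)
})

test_that("translation equivariance holds between two imposed speeds", {
  fx1 <- translated_cortex(c(1, 0), n_frames = 3, seed = 9)
  fx2 <- translated_cortex(c(2.5, 0), n_frames = 3, seed = 9)
  p <- piv_params(velocity_limit = 5, time_average = 1)
  to_px <- fx1$cfg$frame_interval / fx1$cfg$pixel_size
  d <- (mean(piv(fx2$stack, p)$vx) - mean(piv(fx1$stack, p)$vx)) * to_px
  expect_lt(abs(d - 1.5), 0.2)
})

test_that("outlier vectors are replaced by neighbour interpolation, idempotently", {
  vx <- array(0.1, dim = c(1, 6, 6)); vy <- array(0, dim = c(1, 6, 6))
  vx[1, 3, 3] <- 10  # a wild outlier
  p <- piv_params(velocity_limit = 0.3, sd_filter = 5)
  f1 <- corflow:::piv_filter(vx, vy, p)
  expect_false(f1$valid[1, 3, 3])
  expect_equal(f1$vx[1, 3, 3], 0.1, tolerance = 1e-12)
  expect_equal(mean(!f1$valid), 1 / 36)
  ## re-filtering the filtered field changes nothing
  f2 <- corflow:::piv_filter(f1$vx, f1$vy, p)
  expect_equal(f2$vx, f1$vx)
  expect_true(all(f2$valid))
})

test_that("uniform and on-node lookups return exact vectors", {
  fl <- flow_field_uniform(0.1, 0, xlim = c(0, 50), ylim = c(0, 30),
                           tlim = c(0, 100))
  v <- sample_flow(fl, c(3.7, 25), c(4.1, 12), 10)
  expect_equal(v$vx, c(0.1, 0.1))
  expect_equal(v$vy, c(0, 0))
  ## a query exactly on a grid node returns the node's vector
  gx <- seq(0, 60, by = 2); gy <- seq(0, 10, by = 2)
  vx <- array(0, dim = c(1, length(gy), length(gx)))
  for (j in seq_along(gy)) vx[1, j, ] <- flow_velocity(gx)
  fl2 <- flow_field(gx, gy, 0, vx, array(0, dim = dim(vx)))
  v2 <- sample_flow(fl2, 30, 4, 0)
  expect_equal(v2$vx, flow_velocity(30), tolerance = 1e-12)
  ## bicubic interpolation tracks the analytic profile off-node within 2%
  v3 <- sample_flow(fl2, 30.7, 5.1, 0)
  expect_equal(v3$vx, flow_velocity(30.7), tolerance = 0.02)
  ## queries outside the covered time range fail
  expect_error(sample_flow(fl2, 30, 4, 5), "time query")
})

test_that("flow fields survive the CSV round trip", {
  fx <- translated_cortex(c(1, 0.5), n_frames = 3)
  pf <- piv(fx$stack, piv_params(velocity_limit = 5, time_average = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_flow_field(pf, f)
  back <- read_flow_field(f)
  expect_equal(back$vx, pf$vx, tolerance = 1e-9)
  expect_equal(back$grid_x, pf$grid_x)
  expect_equal(back$valid, pf$valid)
})

test_that("degenerate flat-window frames are detected", {
  arr <- array(7, dim = c(2, 80, 80))  # perfectly flat: no texture anywhere
  st <- image_stack(arr, 0.1, 0.1)
  expect_error(piv(st, piv_params(pass_windows = c(64L, 32L),
                                  time_average = 1)),
               "all vectors invalid")
})
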