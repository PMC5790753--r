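test_that("baseline window covers the 50 frames before stimulation", {
  # stim at frame 60 (0-based): window must be frames 10..59
  x <- array(0, dim = c(70, 4, 4))
  x[, , ] <- 1
  x[11:60, 1, 1] <- 7  # exactly the window frames for pixel (0,0)
  x[10, 2, 1] <- 99    # one frame before the window
  bs <- baseline_stats(array_movie(x, stim_frame = 60L))
  expect_equal(bs$mean[1, 1], 7)
  expect_equal(bs$mean[2, 1], 1)  # frame 9 (0-based) is outside the window
  expect_equal(bs$sd[1, 1], 0)
  expect_equal(bs$n_zero_sd, 16L)
  expect_error(baseline_stats(array_movie(x, stim_frame = 60L),
                              n_baseline = 65L), "pre-stimulation")
})

test_that("baseline SD estimates track the true noise SD at 50 frames", {
  mov <- noise_movie(frames = 111L, sd = 2, seed = 4)
  bs <- baseline_stats(mov)
  # chi-distribution bias at n = 50 is ~0.5%; mean estimate within 15%
  expect_lt(abs(mean(bs$sd) - 2) / 2, 0.15)
})

test_that("dI/I is exact on constructed intensities", {
  x <- array(1000, dim = c(80, 3, 3))
  mov <- array_movie(x, stim_frame = 60L)
  dff <- compute_dff(mov)
  expect_true(all(dff$data == 0))
  # a pixel at 1.01 x I0 reads 1%
  x2 <- x; x2[70, 2, 2] <- 1010
  dff2 <- compute_dff(array_movie(x2, stim_frame = 60L))
  expect_equal(dff2$data[70, 2, 2], 1, tolerance = 1e-12)
  # nonpositive baseline is an error naming the pixel count
  x3 <- x; x3[1:60, 1, 1] <- 0
  expect_error(compute_dff(array_movie(x3, stim_frame = 60L)),
               "1 pixel")
})

test_that("an injected dI/I step is recovered against baseline noise", {
  set.seed(12)
  x <- array(1000 + rnorm(100 * 4 * 4, sd = 1), dim = c(100, 4, 4))
  x[81:100, , ] <- x[81:100, , ] + 20  # +2% of 1000
  dff <- compute_dff(array_movie(x, stim_frame = 60L))
  step <- mean(dff$data[81:100, , ])
  expect_equal(step, 2, tolerance = 3 * 0.1 / sqrt(50))  # noise/sqrt(50) scale
})

test_that("SD normalization is exact and invertible", {
  set.seed(13)
  x <- array(1000 + rnorm(90 * 5 * 5), dim = c(90, 5, 5))
  mov <- array_movie(x, stim_frame = 60L)
  bs <- baseline_stats(mov)
  nm <- normalize_to_sd(mov, bs)
  # pixel at exactly its baseline mean reads 0; at mean + 2 SD reads 2
  i <- 3L; j <- 4L
  y <- x
  y[70, i, j] <- bs$mean[i, j]
  y[71, i, j] <- bs$mean[i, j] + 2 * bs$sd[i, j]
  nm2 <- normalize_to_sd(array_movie(y, stim_frame = 60L), bs)
  expect_equal(nm2$data[70, i, j], 0, tolerance = 1e-12)
  expect_equal(nm2$data[71, i, j], 2, tolerance = 1e-12)
  # un-normalize recovers the input stack
  nT <- dim(x)[1]
  mu <- array(rep(bs$mean, each = nT), dim = dim(x))
  sda <- array(rep(bs$sd, each = nT), dim = dim(x))
  expect_equal(nm$data * sda + mu, x, tolerance = 1e-10)
  # baseline-window mean of each pixel is ~0 after normalization
  base_mean <- apply(nm$data[11:60, , ], c(2, 3), mean)
  expect_lt(max(abs(base_mean)), 1e-12)
})

test_that("zero-SD pixels are masked, not propagated as infinities", {
  set.seed(14)
  x <- array(1000 + rnorm(90 * 3 * 3), dim = c(90, 3, 3))
  x[, 2, 2] <- 1000  # constant pixel
  nm <- normalize_to_sd(array_movie(x, stim_frame = 60L))
  expect_equal(nm$n_masked_pixels, 1L)
  expect_true(all(is.na(nm$data[, 2, 2])))
  expect_true(all(is.finite(nm$data[, 1, 1])))
  x0 <- array(5, dim = c(90, 3, 3))
  expect_error(normalize_to_sd(array_movie(x0, stim_frame = 60L)),
               "all pixels")
})

test_that("the truncated Gaussian kernels match explicit arithmetic", {
  # 1-D, size 5, sigma 1: weights exp(-k^2/2) renormalized
  raw <- exp(-c(4, 1, 0, 1, 4) / 2)
  expect_equal(gaussian_kernel_1d(5, 1), raw / sum(raw), tolerance = 1e-15)
  expect_equal(sum(gaussian_kernel_1d(3, 1)), 1, tolerance = 1e-15)
  expect_error(gaussian_kernel_1d(4, 1), "odd")
})

test_that("spatial impulse response equals the tabulated 5x5 kernel", {
  x <- array(0, dim = c(70, 11, 11))
  x[65, 6, 6] <- 1
  nm <- structure(list(data = x, frame_interval_ms = 4.4, stim_frame = 60L,
                       stim_site = NULL, rois = list(), smoothed = FALSE,
                       kernel = NULL, n_masked_pixels = 0L),
                  class = "vsd_norm")
  sm <- smooth_movie(nm, temporal_size = 1L, temporal_sigma = 1)  # spatial only
  w <- exp(-c(4, 1, 0, 1, 4) / 2); w <- w / sum(w)
  k2 <- outer(w, w)  # separable 5x5 kernel, unit sum
  expect_equal(sm$data[65, 4:8, 4:8], k2, tolerance = 1e-10)
  expect_equal(sum(sm$data[65, , ]), 1, tolerance = 1e-12)
  # nothing outside the 5x5 support
  expect_true(all(sm$data[65, c(1:3, 9:11), ] == 0))
})

test_that("temporal impulse spreads to exactly the adjacent frames", {
  x <- array(0, dim = c(70, 3, 3))
  x[65, 2, 2] <- 1
  nm <- structure(list(data = x, frame_interval_ms = 4.4, stim_frame = 60L,
                       stim_site = NULL, rois = list(), smoothed = FALSE,
                       kernel = NULL, n_masked_pixels = 0L),
                  class = "vsd_norm")
  sm <- smooth_movie(nm, spatial_size = 1L)
  nz <- which(sm$data[, 2, 2] != 0)
  expect_identical(nz, 64:66)
})

test_that("smoothing preserves constants, commutes with shifts, never raises the max", {
  x <- array(3.7, dim = c(60, 10, 12))
  nm <- structure(list(data = x, frame_interval_ms = 4.4, stim_frame = 50L,
                       stim_site = NULL, rois = list(), smoothed = FALSE,
                       kernel = NULL, n_masked_pixels = 0L),
                  class = "vsd_norm")
  expect_equal(smooth_movie(nm)$data, x, tolerance = 1e-12)
  set.seed(15)
  y <- array(rnorm(60 * 10 * 12), dim = c(60, 10, 12))
  nm$data <- y
  sy <- smooth_movie(nm)$data
  nm$data <- y + 5
  expect_equal(smooth_movie(nm)$data, sy + 5, tolerance = 1e-10)
  expect_lte(max(sy), max(y))
})

test_that("activation threshold is inclusive at exactly 1 SD", {
  x <- array(0, dim = c(70, 3, 3))
  nm <- structure(list(data = x, frame_interval_ms = 4.4, stim_frame = 60L,
                       stim_site = NULL, rois = list(), smoothed = FALSE,
                       kernel = NULL, n_masked_pixels = 0L),
                  class = "vsd_norm")
  nm$data[65, 1, 1] <- 1.0        # exactly at threshold: active
  nm$data[65, 2, 2] <- 1 - 1e-9   # just below: inactive
  m <- activation_mask(nm)
  expect_true(m$mask[65, 1, 1])
  expect_false(m$mask[65, 2, 2])
  expect_equal(m$per_frame[65], 1L)
  expect_equal(sum(m$per_frame), 1L)
})

test_that("pure-noise activation fraction matches the Gaussian null", {
  mov <- noise_movie(frames = 160L, sd = 1, seed = 16)
  nm <- normalize_to_sd(compute_dff(mov))
  m <- activation_mask(nm)
  post <- m$per_frame[62:160]  # skip stim frame itself
  frac <- mean(post) / (60 * 88)
  # Phi(-1) = 0.1587, slightly inflated by the 50-frame baseline estimate
  expect_equal(frac, pnorm(-1), tolerance = 0.08)
})

test_that("ROI time courses report flat traces and exact noise-free latencies", {
  cfg <- vsd_config(frames = 150, baseline_frames = 60, noise_sd = 0)
  mov <- generate_vsd_movie(cfg, seed = 1)
  # noise-free: normalize against externally supplied unit-SD stats
  h <- dim(mov$data)[2]; w <- dim(mov$data)[3]
  bs <- list(mean = matrix(1000, h, w), sd = matrix(1, h, w),
             n_frames = 50L, n_zero_sd = 0L)
  nm <- normalize_to_sd(mov, bs)
  # constant stack -> flat trace at the constant
  flat <- nm; flat$data[] <- 2.5
  tc0 <- roi_timecourse(flat, c(0L, 5L, 0L, 5L))
  expect_true(all(abs(tc0$trace - 2.5) < 1e-12))
  # configured latencies recovered exactly on the frame grid
  tc_sub <- roi_timecourse(nm, "SUB", exclude_frames = 2L)
  tc_ca1 <- roi_timecourse(nm, "CA1", exclude_frames = 2L)
  expect_equal(tc_sub$latency_ms, round(40.8 / 4.4) * 4.4, tolerance = 1e-9)
  expect_equal(tc_ca1$latency_ms, round(78.2 / 4.4) * 4.4, tolerance = 1e-9)
  expect_gte(tc_sub$peak_frame, nm$stim_frame)
  # latency/frame bookkeeping invariant
  expect_equal(tc_sub$latency_ms,
               (tc_sub$peak_frame - nm$stim_frame) * 4.4, tolerance = 1e-12)
  expect_error(roi_timecourse(nm, c(0L, 5L, 80L, 95L)), "bounds")
  expect_error(roi_timecourse(nm, "nope"), "no ROI")
})

test_that("response summary: ratio construction and activated-pixel accounting", {
  cfg <- vsd_config(frames = 174, baseline_frames = 60)
  mov <- generate_vsd_movie(cfg, seed = 3)
  res <- vsd_quantify(mov)
  expect_lte(res$n_activated, 60 * 88)
  expect_gt(res$n_activated, 0)
  expect_gt(res$ca1_sub_ratio, 0)
  expect_lt(res$latencies_ms[["SUB"]], res$latencies_ms[["CA1"]])
  # identical activity in both ROIs -> ratio exactly 1
  nm <- normalize_to_sd(compute_dff(mov))
  nm$data[] <- 1.3
  r1 <- summarize_response(nm)
  expect_equal(r1$ca1_sub_ratio, 1)
  # halving the CA1 component amplitude halves the ratio (within noise)
  cfg2 <- cfg
  cfg2$components[[2]]$amplitude_sd <- cfg$components[[2]]$amplitude_sd / 2
  res2 <- vsd_quantify(generate_vsd_movie(cfg2, seed = 3))
  expect_equal(res2$ca1_sub_ratio / res$ca1_sub_ratio, 0.5, tolerance = 0.05)
})

test_that("CA1/SUB ratio decreases as stimulation moves from the border", {
  ratios <- vapply(c(46L, 54L, 62L), function(col) {
    cfg <- vsd_config(frames = 174, baseline_frames = 60,
                      stim_site = c(30L, col))
    vsd_quantify(generate_vsd_movie(cfg, seed = 8))$ca1_sub_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("analysis window validation and artifact exclusion", {
  cfg <- vsd_config(frames = 120, baseline_frames = 60)
  mov <- generate_vsd_movie(cfg, seed = 2)
  nm <- normalize_to_sd(compute_dff(mov))
  expect_error(summarize_response(nm, window = c(50L, 100L)), "window")
  expect_error(summarize_response(nm, window = c(60L, 130L)), "window")
  r <- summarize_response(nm, window = c(60L, 120L), artifact_frames = 2L)
  expect_equal(r$window, c(60L, 120L))
  # artifact frames (stim impulse at the site) never enter the peak search
  expect_gte(min(vapply(r$timecourses, `[[`, numeric(1), "peak_frame")), 62)
})
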