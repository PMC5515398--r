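test_that("time_differential matches the double-loop oracle exactly", {
  set.seed(21)
  for (k in c(2, 4)) {
    fr <- lapply(1:8, function(i) matrix(runif(64, 0, 255), 8, 8))
    s <- image_stack(fr, mode = "float")
    td <- time_differential(s, k)
    ref <- oracle_time_differential(fr, k)
    expect_equal(n_frames(td), 8 - k)
    for (i in seq_along(ref))
      expect_identical(matrix(td$frames[, , 1, i], 8, 8), ref[[i]])
  }
})

test_that("time_differential closed forms: ramp, step response, telescoping sum", {
  # linear ramp b(t) = t, k = 4 -> every output pixel 2.5
  ramp <- image_stack(lapply(0:7, function(v) matrix(v, 4, 4)), mode = "float")
  td <- time_differential(ramp, 4)
  expect_true(all(abs(td$frames - 2.5) < 1e-12))

  # step of height A: A, 3A/4, 2A/4, A/4, 0, ...
  A <- 40
  st <- image_stack(lapply(c(0, 0, 0, 0, 0, 0, A, A, A, A, A, A),
                           function(v) matrix(v, 2, 2)), mode = "float")
  td2 <- time_differential(st, 4)
  expect_equal(as.numeric(td2$frames[1, 1, 1, ]),
               c(0, 0, A, 3 * A / 4, 2 * A / 4, A / 4, 0, 0))

  # telescoping: the summed differential equals an explicit weighted sum
  set.seed(3)
  fr <- lapply(1:9, function(i) matrix(runif(16, 0, 10), 4, 4))
  k <- 4
  td3 <- time_differential(image_stack(fr, mode = "float"), k)
  total <- matrix(0, 4, 4)
  for (i in seq_len(n_frames(td3))) total <- total + td3$frames[, , 1, i]
  weights <- rep(0, 9)
  for (t in (k + 1):9) {
    weights[t] <- weights[t] + 1
    weights[(t - k):(t - 1)] <- weights[(t - k):(t - 1)] - 1 / k
  }
  ref <- matrix(0, 4, 4)
  for (t in 1:9) ref <- ref + weights[t] * fr[[t]]
  expect_equal(total, ref, tolerance = 1e-12)

  expect_error(time_differential(ramp, 0), ">= 1")
  expect_error(time_differential(ramp, 8), "smaller")
})

test_that("spacetime_map collapses the short axis and is linear", {
  fr <- matrix(rep(0:5, 4), 6, 4)   # row r has value r
  s <- image_stack(lapply(1:3, function(i) fr), mode = "float")
  km <- spacetime_map(s)
  expect_equal(dim(km$mat), c(6L, 3L))
  expect_equal(km$mat[, 1], as.numeric(0:5))
  expect_equal(km$mat[, 3], as.numeric(0:5))

  set.seed(5)
  fr2 <- lapply(1:4, function(i) matrix(runif(24), 6, 4))
  s1 <- image_stack(fr2, mode = "float")
  s2 <- image_stack(lapply(fr2, function(m) 2.5 * m), mode = "float")
  expect_equal(spacetime_map(s2)$mat, 2.5 * spacetime_map(s1)$mat)

  z <- spacetime_map(image_stack(lapply(1:3, function(i) matrix(0, 4, 4)),
                                 mode = "float"))
  expect_true(all(z$mat == 0))
  expect_error(detect_waves(z), NA)
  expect_equal(nrow(detect_waves(z)), 0L)
})

test_that("detect_waves recovers an analytic diagonal ridge", {
  # ridge: position (um) = 900 - 1500 * t; spacing 10 um, dt 0.05 s
  H <- 100; Tn <- 80
  mat <- matrix(0, H, Tn)
  for (j in seq_len(Tn)) {
    t <- (j - 1) * 0.05
    p <- (900 - 1500 * t) / 10         # ridge centre in bins
    rows <- seq_len(H)
    mat[, j] <- exp(-((rows - 1 - p)^2) / (2 * 3^2))
  }
  km <- structure(list(mat = mat, pos_spacing_um = 10, dt_s = 0.05, t0_s = 0,
                       long_axis = "rows"), class = "spacetime_map")
  ev <- detect_waves(km, min_prominence = 0.3, min_extent = 0.5)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$speed_um_per_s - 1500) / 1500, 0.05)
  expect_equal(ev$direction, "head_ward")
  expect_error(detect_waves(structure(list(mat = matrix(numeric(0), 0, 0)),
                                      class = "spacetime_map")), "empty")
})

test_that("full calcium chain recovers wave count and speed from the larva scene", {
  L <- simulate_crawling_larva(seed = 42)
  km <- spacetime_map(time_differential(
    subtract_background(extract_channel(L$stack, "green")), 4))
  ev <- detect_waves(km)
  expect_equal(nrow(ev), length(L$truth$wave_onsets_s))
  expect_true(all(abs(ev$speed_um_per_s - L$truth$wave_speed_um_per_s) /
                  L$truth$wave_speed_um_per_s < 0.1))
  expect_true(all(ev$direction == "head_ward"))
  # onsets align with truth within a generous margin (differential lags onset)
  expect_true(all(abs(ev$onset_s - L$truth$wave_onsets_s) < 0.5))
})

test_that("background subtraction modes behave as documented", {
  const <- image_stack(lapply(1:5, function(i) matrix(17, 4, 4)))
  expect_true(all(subtract_background(const)$frames == 0))
  expect_error(subtract_background(image_stack(matrix(1, 2, 2))), "2 frames")

  # larva arena baseline is removed: off-body ROI trace goes to ~0
  L <- simulate_crawling_larva(duration_s = 3, seed = 7, noise = FALSE)
  g <- subtract_background(extract_channel(L$stack, "green"))
  edge <- roi_trace(g, roi_rect(0, 0, 6, 6))
  expect_lt(max(edge$values), 1)

  # temporal median leaves artefact-free pixels at value - median
  fr <- lapply(1:9, function(i) matrix(c(50, 80), 2, 1))
  fr[[5]][1, 1] <- 200    # brief artefact on one pixel
  s <- image_stack(fr)
  sb <- subtract_background(s, "temporal_median")
  expect_true(all(sb$frames[2, 1, 1, ] == 0))          # constant pixel -> 0
  expect_equal(as.numeric(sb$frames[1, 1, 1, 5]), 150) # spike survives minus median
})

test_that("roi_trace averages the requested pixels", {
  ones <- image_stack(lapply(1:4, function(i) matrix(1, 5, 5)))
  tr <- roi_trace(ones, roi_disk(2, 2, 1.5))
  expect_true(all(tr$values == 1))
  expect_equal(tr$times_s, frame_times(ones))

  # 1x1 rectangle returns the pixel's own series
  fr <- lapply(1:4, function(i) matrix(i * (1:25), 5, 5))
  s <- image_stack(fr, mode = "float")
  tr2 <- roi_trace(s, roi_rect(2, 1, 3, 2))   # pixel (x=2, y=1) -> [row 2, col 3]
  expect_equal(tr2$values, vapply(1:4, function(i) fr[[i]][2, 3], 1))

  expect_error(roi_trace(ones, roi_rect(10, 10, 12, 12)), "outside")
})

test_that("PSF fits recover the generating width across conditions", {
  # noiseless narrow beads: per-bead sigma within 1%
  cam0 <- camera_config(binning = 1, width = 200, height = 200,
                        pixel_size_um = 1, photon_scale = Inf, read_noise_sd = 0)
  b0 <- simulate_beads(cam0, n_beads = 10, sigma_um = 2, seed = 2)
  e0 <- estimate_psf(b0$stack, sigma_guess_px = 2)
  expect_true(all(abs(e0$beads$sigma_px - 2) / 2 < 0.01))

  # realistic SNR at the instrument's width: median within 5%
  b <- simulate_beads(seed = 1)
  e <- estimate_psf(b$stack, sigma_guess_px = 5)
  expect_lt(abs(e$sigma_um - 5.4) / 5.4, 0.05)
  expect_gte(e$n_beads_used, 15)

  expect_error(estimate_psf(image_stack(matrix(0, 64, 64))), "no spots")
})

test_that("PSF median bias stays below 5% over the tested width range", {
  for (s in c(2, 4, 5.4, 8)) {
    b <- simulate_beads(camera_config(binning = 1, width = 400, height = 400,
                                      pixel_size_um = 1),
                        n_beads = 20, sigma_um = s, seed = 13)
    e <- estimate_psf(b$stack, sigma_guess_px = s)
    expect_lt(abs(e$sigma_px - s) / s, 0.05)
  }
})
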