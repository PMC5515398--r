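test_that("detect_events finds square-wave pulses with the protocol spacing", {
  tr <- square_wave_trace(reps = 5, on_s = 1, off_s = 2, rate = 10)
  ev <- detect_events(tr)$intervals
  expect_equal(nrow(ev), 5L)
  expect_equal(diff(ev$onset_s), rep(3, 4))
  expect_equal(ev$end_s - ev$onset_s, rep(1, 5))

  const <- new_trace(seq(0, 5, 0.1), rep(2, 51))
  expect_equal(nrow(detect_events(const)$intervals), 0L)
})

test_that("events closer than min_gap merge; idempotent on its own reconstruction", {
  t <- seq(0, 2, by = 0.01)
  v <- as.numeric((t >= 0.5 & t < 0.7) | (t >= 0.75 & t < 0.95))  # 50 ms apart
  ev <- detect_events(new_trace(t, v), threshold = 0.5, min_gap_s = 0.1)
  expect_equal(nrow(ev$intervals), 1L)
  expect_equal(ev$intervals$onset_s, 0.5)

  # rebuild a square wave from detected events and re-detect: fixed point
  tr <- square_wave_trace(reps = 3, rate = 20)
  ev1 <- detect_events(tr, threshold = 0.5)$intervals
  v2 <- vapply(tr$times_s, function(tt)
    as.numeric(any(tt >= ev1$onset_s & tt < ev1$end_s)), 1)
  ev2 <- detect_events(new_trace(tr$times_s, v2), threshold = 0.5)$intervals
  expect_equal(ev2, ev1)

  expect_error(detect_events(new_trace(numeric(0), numeric(0))), "empty")
})

test_that("PER pipeline: event count equals protocol repeats, onsets match truth", {
  for (seed in 1:3) {
    prot <- protocol_step("led_ring.red", 255, 1e6, 2e6, 3)
    P <- simulate_per_fly(prot, seed = seed)
    bs <- subtract_background(to_grayscale(P$stack), "frame_median")
    ev <- detect_events(per_trace(bs, P$truth$tip_roi))$intervals
    expect_equal(nrow(ev), 3L)
    dt <- 1 / P$stack$frame_rate_hz
    expect_true(all(abs(ev$onset_s - P$truth$extension_intervals$onset_s) <= 2 * dt))
  }
})

test_that("artefact-only control is flat after frame-median subtraction", {
  prot <- protocol_step("led_ring.red", 255, 1e6, 2e6, 3)
  P0 <- simulate_per_fly(prot, seed = 2, extend = FALSE)
  tr0 <- per_trace(subtract_background(to_grayscale(P0$stack), "frame_median"),
                   P0$truth$tip_roi)
  expect_equal(nrow(detect_events(tr0)$intervals), 0L)
  expect_error(per_trace(P0$stack, P0$truth$tip_roi), "greyscale")
})

test_that("larval length handles straight, bent and translated bodies", {
  rod <- matrix(255, 60, 160); rod[26:34, 31:130] <- 40
  lr <- larval_length_series(image_stack(rod, pixel_size_um = 1000))
  expect_lt(abs(lr$values - 100) / 100, 0.05)
  expect_equal(lr$units, "mm")

  # semicircular arc of radius 40: geodesic gives pi*r, not the chord 2r
  h <- 120; w <- 120
  yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rr <- sqrt((xx - 60)^2 + (yy - 100)^2)
  arc <- matrix(255, h, w); arc[rr >= 35.5 & rr <= 44.5 & yy <= 100] <- 40
  la <- larval_length_series(image_stack(arc, pixel_size_um = 1000))
  expect_lt(abs(la$values - pi * 40) / (pi * 40), 0.05)

  # rigid translation leaves the measurement constant within 2%
  fr <- lapply(0:4, function(k) {
    m <- matrix(255, 60, 200); m[26:34, (31:130) + 3 * k] <- 40; m
  })
  lt <- larval_length_series(image_stack(fr, pixel_size_um = 1000))
  expect_lt(diff(range(lt$values)) / mean(lt$values), 0.02)

  blank <- image_stack(matrix(255, 30, 30))
  expect_error(larval_length_series(blank), "no component")
})

test_that("contraction metrics report fractional shortening and recovery", {
  t <- seq(0, 12, by = 0.1)
  const <- new_trace(t, rep(4, length(t)), "mm")
  cm <- contraction_metrics(const, flash_onset_s = 3)
  expect_equal(cm$contraction, 0)
  expect_equal(cm$recovery, 1)

  # 20% shortening during the flash, full recovery
  len <- ifelse(t >= 3 & t < 4, 3.2, 4)
  cm2 <- contraction_metrics(new_trace(t, len, "mm"), flash_onset_s = 3)
  expect_equal(cm2$contraction, 0.2, tolerance = 0.01)
  expect_equal(cm2$len_pre, 4)
  expect_equal(cm2$len_mid, 3.2)

  expect_error(contraction_metrics(const, flash_onset_s = 11), "out of range")
})

test_that("fin-bout verdicts follow the stimulus-duration threshold", {
  FS <- simulate_tethered_fish(data.frame(onset_s = c(1, 4),
                                          duration_s = c(0.15, 0.6)),
                               seed = 1, noise = FALSE)
  lt <- roi_trace(FS$stack, FS$truth$left_roi)
  rt <- roi_trace(FS$stack, FS$truth$right_roi)
  v <- fin_bout_detect(lt, rt, FS$truth$stimuli[, c("onset_s", "duration_s")])
  expect_equal(v$bout, c(FALSE, TRUE))
  dt <- 1 / FS$stack$frame_rate_hz
  expect_lt(abs(v$latency_s[2] - FS$truth$bout_latency_s), 2 * dt)

  expect_equal(nrow(fin_bout_detect(lt, rt, NULL)), 0L)
  expect_error(fin_bout_detect(lt, rt, data.frame(onset_s = c(1, 1.5),
                                                  duration_s = c(0.6, 0.6))),
               "overlapping")
})

test_that("tracker follows a single blob exactly and keeps identities apart", {
  # deterministic blob moving 2 px/frame
  fr <- lapply(0:9, function(k) {
    m <- matrix(220, 60, 80)
    m[25:31, (10:16) + 2 * k] <- 40
    m
  })
  s <- image_stack(fr, frame_rate_hz = 10)
  trk <- track_centroids(s, max_jump_px = 5)
  expect_equal(length(trk), 1L)
  expect_equal(nrow(trk[[1]]), 10L)
  expect_equal(diff(trk[[1]]$cx), rep(2, 9))
  expect_equal(trk[[1]]$cy, rep(27, 10))

  # jump beyond max_jump_px terminates the track and starts a new one
  fr2 <- lapply(0:5, function(k) {
    m <- matrix(220, 40, 120)
    x <- if (k < 3) 10 else 80
    m[18:22, (x:(x + 4))] <- 40
    m
  })
  trk2 <- track_centroids(image_stack(fr2), max_jump_px = 10)
  expect_equal(length(trk2), 2L)
  expect_equal(vapply(trk2, nrow, 1L), c(3L, 3L))
})

test_that("tracker achieves perfect recall/precision on well-separated flies", {
  A <- simulate_arena_flies(n_flies = 5, duration_s = 3, seed = 2)
  trk <- track_centroids(A$stack, max_jump_px = 12)
  expect_equal(length(trk), 5L)
  nT <- n_frames(A$stack)
  expect_true(all(vapply(trk, nrow, 1L) == nT))  # no fragmentation, full recall
  # each track follows exactly one truth identity (zero switches)
  tt <- A$truth$tracks
  for (tr in trk) {
    m <- merge(tr, tt, by = "frame")
    d <- sqrt((m$cx.x - m$cx.y)^2 + (m$cy.x - m$cy.y)^2)
    nearest <- tapply(d, m$id, mean)
    best <- names(which.min(nearest))
    dbest <- d[m$id == as.integer(best)]
    expect_true(all(dbest < 2))
  }
})
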