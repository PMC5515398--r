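#' Camera configuration for the synthetic-scene generators
#'
#' Models the rig camera's acquisition conventions: a 2592 x 1944 full
#' frame whose spatial binning sets the peak frame rate — x1 at 15 Hz,
#' x2 at 42 Hz (1296 x 972), x4 at 90 Hz — and an effective pixel size of
#' about 1 um at peak zoom (scaled by the binning factor). Scenes may
#' override `width`/`height` to render a small field of view directly at
#' the binned output geometry.
#'
#' The sensor model is: analytic intensity `I` in `[0, 1]` -> Poisson photon
#' shot noise with mean `photon_scale * I` -> conversion to grey levels
#' (255 at `I = 1`) -> additive Gaussian read noise -> 8-bit quantisation
#' (round half-up, clamp). `photon_scale = Inf` disables shot noise.
#'
#' @param binning 1, 2 or 4.
#' @param width,height frame size in pixels; default full frame / binning.
#' @param frame_rate_hz default follows the binning pairing (15/42/90).
#' @param pixel_size_um microns per output pixel; default `1 * binning`.
#' @param photon_scale mean photon count at intensity 1 (default 500,
#'   i.e. photon SNR ~ 20 at typical spot intensities).
#' @param read_noise_sd Gaussian read noise s.d. in grey levels (default 1).
#' @export
camera_config <- function(binning = 2, width = NULL, height = NULL,
                          frame_rate_hz = NULL, pixel_size_um = NULL,
                          photon_scale = 500, read_noise_sd = 1) {
  if (!binning %in% c(1, 2, 4)) stop("binning must be 1, 2 or 4")
  rates <- c(`1` = 15, `2` = 42, `4` = 90)
  stopifnot(photon_scale > 0, read_noise_sd >= 0)
  structure(list(
    full_width = 2592L, full_height = 1944L, binning = binning,
    width = as.integer(width %||% (2592L / binning)),
    height = as.integer(height %||% (1944L / binning)),
    frame_rate_hz = frame_rate_hz %||% unname(rates[as.character(binning)]),
    pixel_size_um = pixel_size_um %||% (1 * binning),
    photon_scale = photon_scale, read_noise_sd = read_noise_sd,
    bit_depth = 8L), class = "camera_config")
}

#' Apply the sensor noise model to an analytic intensity image
#'
#' @param intensity numeric array of analytic intensities in `[0, 1]`.
#' @param cam a [camera_config()].
#' @param seed optional integer; when given the draw is deterministic.
#' @return 8-bit grey values, same shape as `intensity`.
#' @export
simulate_sensor <- function(intensity, cam, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(intensity)
  I <- pmin(pmax(as.numeric(intensity), 0), 1)
  grey <- if (is.finite(cam$photon_scale)) {
    rpois(length(I), cam$photon_scale * I) / cam$photon_scale * 255
  } else 255 * I
  if (cam$read_noise_sd > 0) grey <- grey + rnorm(length(I), 0, cam$read_noise_sd)
  out <- .round8(grey)
  dim(out) <- d
  out
}

.new_truth <- function(kind, ...) structure(c(list(kind = kind), list(...)),
                                            class = "ground_truth")

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %s> fields: %s\n", x$kind,
              paste(setdiff(names(x), "kind"), collapse = ", ")))
  invisible(x)
}

# pixel-integrated isotropic Gaussian spot, peak ~ `peak` for sigma >~ 1 px
.render_spot <- function(h, w, cx, cy, sigma, peak) {
  fx <- sigma * sqrt(2 * pi) *
    (pnorm((0:(w - 1) + 0.5 - cx) / sigma) - pnorm((0:(w - 1) - 0.5 - cx) / sigma))
  fy <- sigma * sqrt(2 * pi) *
    (pnorm((0:(h - 1) + 0.5 - cy) / sigma) - pnorm((0:(h - 1) - 0.5 - cy) / sigma))
  peak * outer(fy, fx)
}

#' Simulate a fluorescent-bead field for PSF estimation
#'
#' Beads are sub-resolution point sources, so each renders as the camera's
#' point-spread function: an integrated 2D isotropic Gaussian of standard
#' deviation `sigma_um`. Placement is rejection-sampled to keep beads at
#' least `6 * sigma` apart and away from the frame edge, then the sensor
#' noise model is applied. The default width is the rig's measured
#' resolution limit (5.4 um at 1 um pixels).
#'
#' @param cam a [camera_config()]; default renders a 256 x 256 field at
#'   1 um pixels.
#' @param n_beads number of beads (default 30).
#' @param sigma_um true PSF standard deviation in microns (default 5.4).
#' @param seed integer seed (placement and noise are deterministic in it).
#' @param n_frames_out number of identically-noised-distribution frames.
#' @param peak analytic peak intensity of a bead (default 0.8).
#' @return `list(stack = <image_stack>, truth = <ground_truth>)`; truth
#'   holds the exact 0-based centres and the true sigma.
#' @export
simulate_beads <- function(cam = camera_config(binning = 1, width = 256, height = 256,
                                               pixel_size_um = 1),
                           n_beads = 30, sigma_um = 5.4, seed = 1,
                           n_frames_out = 1, peak = 0.8) {
  stopifnot(sigma_um > 0, n_beads >= 1)
  set.seed(seed)
  h <- cam$height; w <- cam$width
  sigma_px <- sigma_um / cam$pixel_size_um
  margin <- 3 * sigma_px + 2
  min_sep <- 6 * sigma_px
  if (w - 2 * margin < 1 || h - 2 * margin < 1)
    stop("field too crowded: frame smaller than the bead margin")
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n_beads) {
    tries <- tries + 1L
    if (tries > 2000L * n_beads)
      stop("field too crowded to place ", n_beads,
           " beads at the 6-sigma separation constraint")
    px <- runif(1, margin, w - 1 - margin)
    py <- runif(1, margin, h - 1 - margin)
    if (length(cx) == 0L || all((cx - px)^2 + (cy - py)^2 >= min_sep^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  scene <- matrix(0, h, w)
  for (i in seq_len(n_beads))
    scene <- scene + .render_spot(h, w, cx[i], cy[i], sigma_px, peak)
  frames <- lapply(seq_len(n_frames_out), function(k) simulate_sensor(scene, cam))
  stack <- image_stack(frames, frame_rate_hz = cam$frame_rate_hz,
                       pixel_size_um = cam$pixel_size_um, mode = "uint8")
  truth <- .new_truth("beads", centres = data.frame(cx = cx, cy = cy),
                      sigma_um = sigma_um, sigma_px = sigma_px, peak = peak)
  list(stack = stack, truth = truth)
}

#' Configuration for the crawling-larva calcium scene
#'
#' Emulates a GCaMP-expressing larva crawling under the fluorescence
#' camera: tail-to-head peristaltic waves of muscle calcium travel along
#' the body, one per `wave_period_s`, at `wave_speed_um_per_s`; each
#' completed wave advances the body head-ward by `crawl_step_um`. The wave
#' profile is a raised cosine of half-width
#' `wave_width_frac * body_length_um`.
#'
#' @param body_length_um body length (default 3000 um, a second-instar larva).
#' @param body_width_um body width (default 600 um).
#' @param n_segments nominal segment count (used for segment-ROI helpers).
#' @param wave_period_s interval between successive wave onsets (default 1.5 s).
#' @param wave_speed_um_per_s wave propagation speed (default 3000 um/s,
#'   i.e. one body length per second).
#' @param wave_amplitude green fluorescence gain of an active segment, grey
#'   levels (default 120).
#' @param baseline resting green fluorescence of the body, grey levels
#'   (default 60).
#' @param background arena background, grey levels (default 10).
#' @param crawl_step_um head-ward translation per completed wave (default 200).
#' @param wave_width_frac raised-cosine half-width as a fraction of body
#'   length (default 0.25).
#' @param first_onset_s onset time of the first wave (default 0.25 s).
#' @export
larva_config <- function(body_length_um = 3000, body_width_um = 600,
                         n_segments = 11, wave_period_s = 1.5,
                         wave_speed_um_per_s = 3000, wave_amplitude = 120,
                         baseline = 60, background = 10, crawl_step_um = 200,
                         wave_width_frac = 0.25, first_onset_s = 0.25) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("body_length_um", "body_width_um", "wave_period_s",
                             "wave_speed_um_per_s")]) > 0))
  structure(cfg, class = "larva_config")
}

#' Simulate a crawling GCaMP larva with peristaltic calcium waves
#'
#' Renders an RGB stack in which the green channel carries the calcium
#' signal (body baseline plus travelling raised-cosine wave) and the red
#' and blue channels carry only a dim constant body image. The body's long
#' axis is vertical (rows), head at the top, so the space-time analysis
#' axis is image rows. Truth records the exact wave onsets and speed.
#'
#' @param cam a [camera_config()]; the default renders an 80 x 240 field at
#'   20 um pixels and the 10.5 Hz analysis frame rate (42 Hz temporally
#'   downsampled x4).
#' @param cfg a [larva_config()].
#' @param duration_s recording length (default 8 s, five full waves).
#' @param seed integer seed.
#' @param noise apply the sensor noise model (`FALSE` gives the analytic
#'   render quantised only).
#' @return `list(stack, truth)`; truth holds `wave_onsets_s`,
#'   `wave_speed_um_per_s`, head-row positions per frame and body geometry.
#' @export
simulate_crawling_larva <- function(cam = camera_config(binning = 2, width = 80,
                                                        height = 240,
                                                        frame_rate_hz = 10.5,
                                                        pixel_size_um = 20),
                                    cfg = larva_config(), duration_s = 8,
                                    seed = 1, noise = TRUE) {
  set.seed(seed)
  h <- cam$height; w <- cam$width
  px <- cam$pixel_size_um
  L_px <- cfg$body_length_um / px
  if (L_px > h - 4) stop("larva longer than arena")
  if (cfg$wave_period_s * cam$frame_rate_hz < 4)
    stop("waves not resolvable at this frame rate")
  nT <- floor(duration_s * cam$frame_rate_hz)
  times <- (seq_len(nT) - 1) / cam$frame_rate_hz
  traverse_s <- cfg$body_length_um / cfg$wave_speed_um_per_s
  onsets <- seq(cfg$first_onset_s, duration_s, by = cfg$wave_period_s)
  onsets <- onsets[onsets + traverse_s <= duration_s]
  crawl_px <- cfg$crawl_step_um / px
  n_waves_total <- length(onsets)
  head0 <- h - 1 - L_px - 2          # start near the bottom, crawl upward
  if (head0 - n_waves_total * crawl_px < 2)
    stop("larva crawls out of the arena: reduce crawl_step_um or duration")
  half_w <- cfg$body_width_um / px / 2
  xcols <- abs((0:(w - 1)) - (w - 1) / 2) <= half_w
  wave_half_um <- cfg$wave_width_frac * cfg$body_length_um
  frames <- array(0, c(h, w, 3, nT))
  head_rows <- numeric(nT)
  for (t in seq_len(nT)) {
    tt <- times[t]
    completed <- sum(onsets + traverse_s <= tt)
    head_row <- head0 - completed * crawl_px
    head_rows[t] <- head_row
    ys <- 0:(h - 1)
    s_um <- (ys - head_row) * px          # distance from head along the body
    on_body <- s_um >= 0 & s_um <= cfg$body_length_um
    g <- rep(cfg$background, h)
    rb <- rep(cfg$background, h)
    if (any(on_body)) {
      act <- numeric(sum(on_body))
      s_body <- s_um[on_body]
      for (t_k in onsets) {
        if (tt < t_k || tt > t_k + traverse_s + cfg$wave_period_s) next
        s_w <- cfg$body_length_um - cfg$wave_speed_um_per_s * (tt - t_k)
        dd <- abs(s_body - s_w)
        inb <- dd <= wave_half_um
        act[inb] <- act[inb] + 0.5 * (1 + cos(pi * dd[inb] / wave_half_um))
      }
      g[on_body] <- cfg$background + cfg$baseline + cfg$wave_amplitude * pmin(act, 1)
      rb[on_body] <- cfg$background + 20
    }
    green <- matrix(cfg$background, h, w)
    other <- matrix(cfg$background, h, w)
    green[, xcols] <- matrix(g, h, sum(xcols))
    other[, xcols] <- matrix(rb, h, sum(xcols))
    if (noise) {
      frames[, , 1, t] <- simulate_sensor(other / 255, cam)
      frames[, , 2, t] <- simulate_sensor(green / 255, cam)
      frames[, , 3, t] <- simulate_sensor(other / 255, cam)
    } else {
      frames[, , 1, t] <- .round8(other)
      frames[, , 2, t] <- .round8(green)
      frames[, , 3, t] <- .round8(other)
    }
  }
  stack <- image_stack(frames, frame_rate_hz = cam$frame_rate_hz,
                       pixel_size_um = px, mode = "uint8")
  truth <- .new_truth("larva", wave_onsets_s = onsets,
                      wave_speed_um_per_s = cfg$wave_speed_um_per_s,
                      wave_period_s = cfg$wave_period_s,
                      traverse_s = traverse_s,
                      head_rows_px = head_rows, body_length_px = L_px,
                      config = cfg)
  list(stack = stack, truth = truth)
}

# stimulus on-intervals for one channel from a compiled event log
.channel_intervals <- function(log, channel) {
  ev <- log[log$channel == channel, , drop = FALSE]
  if (nrow(ev) == 0L) return(data.frame(onset_s = numeric(0), end_s = numeric(0)))
  on <- ev$t_us[ev$value > 0] / 1e6
  off <- ev$t_us[ev$value == 0] / 1e6
  data.frame(onset_s = on, end_s = off[seq_along(on)])
}

#' Simulate a tethered fly proboscis-extension (PER) scene
#'
#' A fixed fly viewed from the side; during each red-LED stimulus interval
#' of the protocol the proboscis extends (after `latency_s`) into a known
#' tip region which brightens, and a uniform red illumination artefact is
#' added to the whole frame for the stimulus duration — so
#' background-over-time subtraction is genuinely exercised downstream.
#'
#' @param protocol a list of [protocol_step()]s or a compiled event log
#'   addressing `led_ring.red`.
#' @param cam a [camera_config()]; default 96 x 96 at 42 Hz.
#' @param latency_s extension latency after stimulus onset (default 0.1 s).
#' @param seed integer seed.
#' @param extend render the extension (`FALSE` gives the artefact-only
#'   control scene).
#' @param artefact_grey artefact amplitude in grey levels (default 10).
#' @param tail_s recording continues this long after the last event.
#' @return `list(stack, truth)`; truth holds extension intervals, stimulus
#'   intervals and the tip ROI.
#' @export
simulate_per_fly <- function(protocol,
                             cam = camera_config(binning = 2, width = 96,
                                                 height = 96, frame_rate_hz = 42,
                                                 pixel_size_um = 10),
                             latency_s = 0.1, seed = 1, extend = TRUE,
                             artefact_grey = 10, tail_s = 1) {
  if (!is.data.frame(protocol)) protocol <- compile_protocol(protocol)
  stim <- .channel_intervals(protocol, "led_ring.red")
  if (nrow(stim) == 0L) stop("protocol addresses no red-LED channel")
  set.seed(seed)
  h <- cam$height; w <- cam$width
  duration_s <- max(stim$end_s) + tail_s
  nT <- floor(duration_s * cam$frame_rate_hz)
  times <- (seq_len(nT) - 1) / cam$frame_rate_hz
  yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  body <- ((xx - w * 0.35)^2 / (w * 0.22)^2 + (yy - h * 0.5)^2 / (h * 0.3)^2) <= 1
  tip <- roi_disk(cx = w * 0.78, cy = h * 0.5, r = max(3, w * 0.05), label = "proboscis_tip")
  tipmask <- roi_mask(tip, h, w)
  ext <- data.frame(onset_s = stim$onset_s + latency_s,
                    end_s = stim$end_s + latency_s)
  frames <- array(0, c(h, w, 3, nT))
  base <- matrix(30, h, w); base[body] <- 80
  for (t in seq_len(nT)) {
    tt <- times[t]
    in_stim <- any(tt >= stim$onset_s & tt < stim$end_s)
    in_ext <- extend && any(tt >= ext$onset_s & tt < ext$end_s)
    f <- base
    if (in_ext) f[tipmask] <- 180
    if (in_stim) f <- f + artefact_grey
    g8 <- simulate_sensor(f / 255, cam)
    for (c in 1:3) frames[, , c, t] <- g8
  }
  stack <- image_stack(frames, frame_rate_hz = cam$frame_rate_hz,
                       pixel_size_um = cam$pixel_size_um, mode = "uint8")
  truth <- .new_truth("per", extension_intervals = if (extend) ext else ext[0, ],
                      stim_intervals = stim, tip_roi = tip,
                      latency_s = latency_s, artefact_grey = artefact_grey)
  list(stack = stack, truth = truth)
}

#' Simulate a tethered larval-zebrafish optogenetics scene
#'
#' Two pectoral-fin regions burst (oscillatory brightening for
#' `bout_duration_s` after `bout_latency_s`) in response to every light
#' stimulus whose duration reaches `threshold_s`; shorter stimuli elicit
#' nothing. The default threshold is 0.5 s, the empirical reliability
#' boundary for whole-field blue-light ChR2 activation. The model is
#' ROI-level (brightness, not fin kinematics), matching how such recordings
#' are analysed.
#'
#' @param stimuli data.frame or list of `(onset_s, duration_s)` pairs;
#'   must not overlap.
#' @param cam a [camera_config()]; default 120 x 160 at 42 Hz.
#' @param threshold_s minimal effective stimulus duration (default 0.5 s).
#' @param seed integer seed.
#' @param noise apply sensor noise (`FALSE` = noise-free render).
#' @param bout_latency_s bout onset delay after stimulus onset (default 0.1 s).
#' @param bout_duration_s bout length (default 0.8 s).
#' @param artefact_grey stimulus light artefact amplitude (default 0:
#'   the excitation filter is assumed in place).
#' @param tail_s recording tail after the last stimulus (default 1.5 s).
#' @return `list(stack, truth)`; truth holds per-stimulus verdicts and bout
#'   intervals plus the two fin ROIs.
#' @export
simulate_tethered_fish <- function(stimuli,
                                   cam = camera_config(binning = 2, width = 160,
                                                       height = 120,
                                                       frame_rate_hz = 42,
                                                       pixel_size_um = 10),
                                   threshold_s = 0.5, seed = 1, noise = TRUE,
                                   bout_latency_s = 0.1, bout_duration_s = 0.8,
                                   artefact_grey = 0, tail_s = 1.5) {
  if (is.list(stimuli) && !is.data.frame(stimuli))
    stimuli <- do.call(rbind, lapply(stimuli, function(s)
      data.frame(onset_s = s[[1]], duration_s = s[[2]])))
  if (is.null(stimuli) || nrow(stimuli) == 0L)
    stimuli <- data.frame(onset_s = numeric(0), duration_s = numeric(0))
  if (nrow(stimuli) > 1L) {
    o <- order(stimuli$onset_s)
    stimuli <- stimuli[o, ]
    if (any(stimuli$onset_s[-1] < head(stimuli$onset_s + stimuli$duration_s, -1)))
      stop("overlapping stimuli")
  }
  set.seed(seed)
  h <- cam$height; w <- cam$width
  duration_s <- if (nrow(stimuli)) max(stimuli$onset_s + stimuli$duration_s) + tail_s else 3
  nT <- floor(duration_s * cam$frame_rate_hz)
  times <- (seq_len(nT) - 1) / cam$frame_rate_hz
  left_roi <- roi_disk(w * 0.35, h * 0.40, 6, "left_fin")
  right_roi <- roi_disk(w * 0.35, h * 0.60, 6, "right_fin")
  lmask <- roi_mask(left_roi, h, w); rmask <- roi_mask(right_roi, h, w)
  yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  body <- ((xx - w * 0.5)^2 / (w * 0.35)^2 + (yy - h * 0.5)^2 / (h * 0.12)^2) <= 1
  responded <- stimuli$duration_s >= threshold_s
  bouts <- data.frame(onset_s = stimuli$onset_s + bout_latency_s,
                      end_s = stimuli$onset_s + bout_latency_s + bout_duration_s)
  frames <- array(0, c(h, w, 3, nT))
  base <- matrix(25, h, w); base[body] <- 90
  base[lmask] <- 40; base[rmask] <- 40
  for (t in seq_len(nT)) {
    tt <- times[t]
    f <- base
    active <- which(responded & tt >= bouts$onset_s & tt < bouts$end_s)
    if (length(active)) {
      ph <- tt - bouts$onset_s[active[1]]
      burst <- 60 * (0.6 + 0.4 * abs(sin(2 * pi * 6 * ph)))
      f[lmask] <- 40 + burst
      f[rmask] <- 40 + burst
    }
    if (artefact_grey > 0 &&
        any(tt >= stimuli$onset_s & tt < stimuli$onset_s + stimuli$duration_s))
      f <- f + artefact_grey
    g8 <- if (noise) simulate_sensor(f / 255, cam) else .round8(f)
    for (c in 1:3) frames[, , c, t] <- g8
  }
  stack <- image_stack(frames, frame_rate_hz = cam$frame_rate_hz,
                       pixel_size_um = cam$pixel_size_um, mode = "uint8")
  truth <- .new_truth("fish",
                      stimuli = cbind(stimuli, bout = responded),
                      bout_intervals = bouts[responded, , drop = FALSE],
                      bout_latency_s = bout_latency_s,
                      threshold_s = threshold_s,
                      left_roi = left_roi, right_roi = right_roi)
  list(stack = stack, truth = truth)
}

#' Simulate a multi-fly open arena for centroid tracking
#'
#' Dark elliptical flies on a light background perform reflecting,
#' velocity-persistent random walks with pairwise repulsion below a minimum
#' separation. Truth records per-frame centroids with persistent
#' identities.
#'
#' @param cam a [camera_config()]; default 200 x 200 at 15 Hz.
#' @param n_flies number of flies (default 5).
#' @param duration_s recording length (default 5 s).
#' @param seed integer seed.
#' @param blob_radius_px fly body radius (default 4 px).
#' @param min_sep_px minimum centre separation maintained by the walk
#'   (default 32 px, i.e. four blob diameters).
#' @param speed_px mean step length per frame (default 2 px).
#' @param noise apply sensor noise.
#' @return `list(stack, truth)`; truth `tracks` is a data.frame
#'   `(id, frame, time_s, cx, cy)`.
#' @export
simulate_arena_flies <- function(cam = camera_config(binning = 1, width = 200,
                                                     height = 200,
                                                     frame_rate_hz = 15,
                                                     pixel_size_um = 50),
                                 n_flies = 5, duration_s = 5, seed = 1,
                                 blob_radius_px = 4, min_sep_px = 32,
                                 speed_px = 2, noise = TRUE) {
  set.seed(seed)
  h <- cam$height; w <- cam$width
  margin <- blob_radius_px + 3
  if (n_flies * min_sep_px^2 > 0.5 * (w - 2 * margin) * (h - 2 * margin))
    stop("arena too small for ", n_flies, " flies at the minimum separation")
  px <- numeric(0); py <- numeric(0); tries <- 0L
  while (length(px) < n_flies) {
    tries <- tries + 1L
    if (tries > 5000L * n_flies) stop("arena too small: placement failed")
    cx <- runif(1, margin, w - 1 - margin); cy <- runif(1, margin, h - 1 - margin)
    if (length(px) == 0L || all((px - cx)^2 + (py - cy)^2 >= min_sep_px^2)) {
      px <- c(px, cx); py <- c(py, cy)
    }
  }
  vx <- rnorm(n_flies, 0, speed_px); vy <- rnorm(n_flies, 0, speed_px)
  nT <- floor(duration_s * cam$frame_rate_hz)
  times <- (seq_len(nT) - 1) / cam$frame_rate_hz
  frames <- array(0, c(h, w, 1, nT))
  tracks <- vector("list", nT)
  yy <- matrix(0:(h - 1), h, w); xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  for (t in seq_len(nT)) {
    if (t > 1L) {
      vx <- 0.85 * vx + rnorm(n_flies, 0, 0.6 * speed_px)
      vy <- 0.85 * vy + rnorm(n_flies, 0, 0.6 * speed_px)
      sp <- sqrt(vx^2 + vy^2); cap <- 2.5 * speed_px
      f <- ifelse(sp > cap, cap / sp, 1); vx <- vx * f; vy <- vy * f
      px <- px + vx; py <- py + vy
      # reflect at walls
      lo <- px < margin; px[lo] <- 2 * margin - px[lo]; vx[lo] <- -vx[lo]
      hi <- px > w - 1 - margin; px[hi] <- 2 * (w - 1 - margin) - px[hi]; vx[hi] <- -vx[hi]
      lo <- py < margin; py[lo] <- 2 * margin - py[lo]; vy[lo] <- -vy[lo]
      hi <- py > h - 1 - margin; py[hi] <- 2 * (h - 1 - margin) - py[hi]; vy[hi] <- -vy[hi]
      # pairwise repulsion below the minimum separation
      if (n_flies > 1L) for (i in 1:(n_flies - 1)) for (j in (i + 1):n_flies) {
        dx <- px[j] - px[i]; dy <- py[j] - py[i]
        d <- sqrt(dx^2 + dy^2)
        if (d < min_sep_px && d > 0) {
          push <- (min_sep_px - d) / 2
          ux <- dx / d; uy <- dy / d
          px[i] <- max(margin, min(w - 1 - margin, px[i] - ux * push))
          py[i] <- max(margin, min(h - 1 - margin, py[i] - uy * push))
          px[j] <- max(margin, min(w - 1 - margin, px[j] + ux * push))
          py[j] <- max(margin, min(h - 1 - margin, py[j] + uy * push))
        }
      }
    }
    f <- matrix(220, h, w)
    for (i in seq_len(n_flies)) {
      d2 <- (xx - px[i])^2 / blob_radius_px^2 + (yy - py[i])^2 / (0.7 * blob_radius_px)^2
      f[d2 <= 1] <- 40
    }
    frames[, , 1, t] <- if (noise) simulate_sensor(f / 255, cam) else .round8(f)
    tracks[[t]] <- data.frame(id = seq_len(n_flies), frame = t,
                              time_s = times[t], cx = px, cy = py)
  }
  stack <- image_stack(frames, frame_rate_hz = cam$frame_rate_hz,
                       pixel_size_um = cam$pixel_size_um, mode = "uint8")
  truth <- .new_truth("arena", tracks = do.call(rbind, tracks),
                      n_flies = n_flies, blob_radius_px = blob_radius_px,
                      min_sep_px = min_sep_px)
  list(stack = stack, truth = truth)
}
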