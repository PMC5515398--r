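#' Subtract an estimated background from a stack
#'
#' Three estimators: `"static_min_projection"` (per-pixel minimum over
#' time — a moving bright object on a static arena),
#' `"temporal_median"` (per-pixel median over time — removes structure
#' present most of the time), and `"frame_median"` (the spatial median of
#' each frame, i.e. the background level tracked over time — this removes
#' a uniform common-mode stimulus-light artefact exactly, which is the
#' standard treatment for PER recordings). The result is clipped at zero;
#' the background estimate is kept on the returned stack as `$background`.
#'
#' @param stack an `image_stack` with at least 2 frames.
#' @param mode `"static_min_projection"` (default), `"temporal_median"` or
#'   `"frame_median"`.
#' @export
subtract_background <- function(stack,
                                mode = c("static_min_projection", "temporal_median",
                                         "frame_median")) {
  mode <- match.arg(mode)
  d <- dim(stack$frames)
  if (d[4] < 2L) stop("background estimation needs at least 2 frames")
  if (mode == "frame_median") {
    bg <- apply(stack$frames, 4, median)
    out <- sweep(stack$frames, 4, bg, `-`)
  } else {
    bg <- apply(stack$frames, c(1, 2, 3),
                if (mode == "static_min_projection") min else median)
    out <- sweep(stack$frames, c(1, 2, 3), bg, `-`)
  }
  out[out < 0] <- 0
  res <- image_stack(out, frame_rate_hz = stack$frame_rate_hz,
                     pixel_size_um = stack$pixel_size_um, t0_s = stack$t0_s,
                     channel_names = stack$channel_names, mode = stack$mode)
  res$background <- bg
  res
}

#' Mean-intensity trace over a region of interest
#'
#' Per-frame mean of the pixels inside the ROI (channels averaged for RGB
#' stacks); times come from the stack metadata.
#'
#' @param stack an `image_stack`.
#' @param roi a [roi_rect()] or [roi_disk()].
#' @return a `trace` in arbitrary fluorescence units.
#' @export
roi_trace <- function(stack, roi) {
  d <- dim(stack$frames)
  m <- roi_mask(roi, d[1], d[2])
  vals <- vapply(seq_len(d[4]), function(t) {
    acc <- 0
    for (c in seq_len(d[3])) acc <- acc + mean(stack$frames[, , c, t][m])
    acc / d[3]
  }, numeric(1))
  new_trace(frame_times(stack), vals, units = "a.u.")
}

#' Running-average time-differential stack
#'
#' Each output frame is the current frame minus the mean of the `k`
#' preceding frames; the first `k` frames are dropped, values are signed
#' floats, the frame rate is preserved and the start time advances by
#' `k / frame_rate_hz`. This high-passes slow structure and highlights
#' rising activity such as a travelling calcium wave.
#'
#' @param stack a single-channel `image_stack` with more than `k` frames.
#' @param k running-average window (default 4 frames).
#' @export
time_differential <- function(stack, k = 4) {
  d <- dim(stack$frames)
  if (d[3] != 1L) stop("time_differential requires a single-channel stack")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k >= d[4]) stop("k must be smaller than the frame count")
  nT <- d[4] - k
  out <- array(0, c(d[1], d[2], 1L, nT))
  for (i in seq_len(nT)) {
    t <- k + i
    acc <- matrix(0, d[1], d[2])
    for (j in (t - k):(t - 1)) acc <- acc + stack$frames[, , 1L, j]
    out[, , 1L, i] <- stack$frames[, , 1L, t] - acc / k
  }
  image_stack(out, frame_rate_hz = stack$frame_rate_hz,
              pixel_size_um = stack$pixel_size_um,
              t0_s = stack$t0_s + k / stack$frame_rate_hz, mode = "float")
}

#' Collapse a stack to a space-time (kymograph) map
#'
#' Averages each frame across the short body axis, yielding a
#' positions x time matrix: travelling waves appear as diagonal ridges.
#' The caller is responsible for orienting the long body axis along the
#' chosen image axis (no automatic registration is attempted).
#'
#' @param stack a single-channel `image_stack`.
#' @param long_axis `"rows"` (position = image rows, default) or
#'   `"columns"`.
#' @return a `spacetime_map` with position spacing in microns and time
#'   spacing in seconds.
#' @export
spacetime_map <- function(stack, long_axis = c("rows", "columns")) {
  long_axis <- match.arg(long_axis)
  d <- dim(stack$frames)
  if (d[3] != 1L) stop("spacetime_map requires a single-channel stack")
  mat <- vapply(seq_len(d[4]), function(t) {
    f <- matrix(stack$frames[, , 1L, t], d[1], d[2])
    if (long_axis == "rows") rowMeans(f) else colMeans(f)
  }, numeric(if (long_axis == "rows") d[1] else d[2]))
  mat <- matrix(mat, nrow = if (long_axis == "rows") d[1] else d[2])
  structure(list(mat = mat, pos_spacing_um = stack$pixel_size_um,
                 dt_s = 1 / stack$frame_rate_hz, t0_s = stack$t0_s,
                 long_axis = long_axis), class = "spacetime_map")
}

#' @export
print.spacetime_map <- function(x, ...) {
  cat(sprintf("<spacetime_map> %d positions x %d frames, %g um/bin, %g s/frame\n",
              nrow(x$mat), ncol(x$mat), x$pos_spacing_um, x$dt_s))
  invisible(x)
}

#' @export
plot.spacetime_map <- function(x, ...) {
  image(x$t0_s + (seq_len(ncol(x$mat)) - 1) * x$dt_s,
        (seq_len(nrow(x$mat)) - 1) * x$pos_spacing_um,
        t(x$mat), xlab = "time (s)", ylab = "position (um)",
        col = grDevices::hcl.colors(64, "Inferno"), ...)
}

#' Write a space-time map to CSV (rows = positions, columns = frames)
#' @param map a `spacetime_map`.
#' @param path output path.
#' @export
write_spacetime_csv <- function(map, path) {
  utils::write.table(map$mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# 4-connected component labelling of a logical matrix (small inputs)
.label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      r <- (q - 1L) %% h + 1L; c <- (q - 1L) %/% h + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L),
                     c(r - 1L, c - 1L), c(r - 1L, c + 1L),
                     c(r + 1L, c - 1L), c(r + 1L, c + 1L))) {
        if (d[1] >= 1L && d[1] <= h && d[2] >= 1L && d[2] <= w) {
          q2 <- (d[2] - 1L) * h + d[1]
          if (mask[q2] && lab[q2] == 0L) { lab[q2] <- cur; queue <- c(queue, q2) }
        }
      }
    }
  }
  lab
}

#' Detect travelling waves in a space-time map
#'
#' Thresholds the positive part of the (typically time-differentiated)
#' map at `min_prominence` of its maximum, labels connected ridge
#' components, keeps those spanning at least `min_extent` of the position
#' axis, and fits each ridge's intensity-weighted per-frame centroid with
#' a least-squares line. The slope, converted by the axis spacings, is the
#' wave speed.
#'
#' @param map a `spacetime_map`.
#' @param min_prominence threshold as a fraction of the map maximum
#'   (default 0.3; rejects noise ridges).
#' @param min_extent minimum spanned fraction of the position axis
#'   (default 0.5; rejects partial ridges).
#' @return data.frame of wave events: `onset_s`, `end_s`,
#'   `speed_um_per_s`, `direction` (`"head_ward"` = toward position 0),
#'   `peak`.
#' @export
detect_waves <- function(map, min_prominence = 0.3, min_extent = 0.5) {
  if (length(map$mat) == 0L) stop("empty map")
  mx <- max(map$mat)
  empty <- data.frame(onset_s = numeric(0), end_s = numeric(0),
                      speed_um_per_s = numeric(0), direction = character(0),
                      peak = numeric(0))
  if (mx <= 0) return(empty)
  thr <- min_prominence * mx
  mask <- map$mat >= thr
  lab <- .label_components(mask)
  events <- empty
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    rows <- row(map$mat)[sel]
    if ((max(rows) - min(rows) + 1) / nrow(map$mat) < min_extent) next
    cols <- sort(unique(col(map$mat)[sel]))
    cent_t <- numeric(length(cols)); cent_p <- numeric(length(cols))
    for (i in seq_along(cols)) {
      cc <- cols[i]
      rr <- which(sel[, cc])
      wgt <- map$mat[rr, cc]
      cent_t[i] <- map$t0_s + (cc - 1) * map$dt_s
      cent_p[i] <- sum((rr - 1) * wgt) / sum(wgt) * map$pos_spacing_um
    }
    if (length(cols) < 2L) next
    slope <- coef(stats::lm(cent_p ~ cent_t))[2]
    events <- rbind(events, data.frame(
      onset_s = min(cent_t), end_s = max(cent_t),
      speed_um_per_s = abs(slope),
      direction = if (slope < 0) "head_ward" else "tail_ward",
      peak = max(map$mat[sel])))
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  events
}

# residual function for the pixel-integrated Gaussian spot fit
.spot_resid <- function(par, z, xs, ys) {
  amp <- par[1]; cx <- par[2]; cy <- par[3]; s <- abs(par[4]); off <- par[5]
  fx <- s * sqrt(2 * pi) * (pnorm((xs + 0.5 - cx) / s) - pnorm((xs - 0.5 - cx) / s))
  fy <- s * sqrt(2 * pi) * (pnorm((ys + 0.5 - cy) / s) - pnorm((ys - 0.5 - cy) / s))
  as.numeric(z - (off + amp * outer(fy, fx)))
}

#' Estimate the point-spread function width from a bead image
#'
#' Detects candidate spots as local maxima exceeding the image background
#' by `nsd` noise standard deviations, rejects spots with saturated pixels
#' or neighbours closer than `6 * sigma_guess_px`, fits each with a
#' pixel-integrated 2D isotropic Gaussian (amplitude, centre, sigma,
#' offset) by Levenberg-Marquardt least squares, and summarises the PSF
#' width as the median per-bead sigma (robust to occasional
#' mis-detections) converted to microns.
#'
#' @param stack a single-channel `image_stack` of a bead field (frames are
#'   averaged before detection).
#' @param sigma_guess_px starting sigma and scale for the separation /
#'   window rules (default 5 px).
#' @param nsd detection threshold in noise s.d. above the background
#'   median (default 5).
#' @return a `psf_estimate`: `sigma_um`, `sigma_px`, per-bead fit table
#'   (`$beads`), `n_beads_used`.
#' @export
estimate_psf <- function(stack, sigma_guess_px = 5, nsd = 5) {
  d <- dim(stack$frames)
  if (d[3] != 1L) stop("estimate_psf requires a single-channel stack")
  img <- matrix(0, d[1], d[2])
  for (t in seq_len(d[4])) img <- img + matrix(stack$frames[, , 1L, t], d[1], d[2])
  img <- img / d[4]
  bg <- median(img)
  noise <- mad(img)
  if (noise == 0) noise <- max(sd(img) / 10, 0.5)
  thr <- bg + nsd * noise
  h <- d[1]; w <- d[2]
  # local maxima above threshold, over a sigma-scaled neighbourhood
  rad <- max(2L, round(sigma_guess_px))
  cand <- which(img > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - rad):min(h, r + rad); cs <- max(1, c - rad):min(w, c + rad)
    keep[i] <- img[r, c] == max(img[rs, cs])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no spots detected")
  # collapse noise-split maxima within 3 sigma (keep the brightest)
  ord <- order(img[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  merge2 <- (3 * sigma_guess_px)^2
  merged <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(merged) == 0L ||
        all((merged[, 1] - cand[i, 1])^2 + (merged[, 2] - cand[i, 2])^2 > merge2))
      merged <- rbind(merged, cand[i, ])
  }
  sep2 <- (6 * sigma_guess_px)^2
  n <- nrow(merged)
  crowded <- rep(FALSE, n)
  if (n > 1L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if ((merged[i, 1] - merged[j, 1])^2 + (merged[i, 2] - merged[j, 2])^2 < sep2)
      crowded[c(i, j)] <- TRUE
  }
  merged <- merged[!crowded, , drop = FALSE]
  if (nrow(merged) == 0L) stop("all fits rejected: spots too crowded")
  r_win <- ceiling(4 * sigma_guess_px)
  beads <- NULL
  for (i in seq_len(nrow(merged))) {
    r <- unname(merged[i, 1]); c <- unname(merged[i, 2])
    if (r - r_win < 1 || r + r_win > h || c - r_win < 1 || c + r_win > w) next
    z <- img[(r - r_win):(r + r_win), (c - r_win):(c + r_win)]
    if (max(z) >= 255) next   # saturated
    xs <- (c - r_win):(c + r_win) - 1   # 0-based pixel coords
    ys <- (r - r_win):(r + r_win) - 1
    start <- c(amp = max(z) - bg, cx = c - 1, cy = r - 1,
               sigma = sigma_guess_px, off = bg)
    fit <- tryCatch(minpack.lm::nls.lm(par = start, fn = .spot_resid,
                                       z = z, xs = xs, ys = ys,
                                       control = minpack.lm::nls.lm.control(maxiter = 200)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    p <- fit$par
    s <- abs(p[["sigma"]])
    if (s < 0.3 || s > 3 * sigma_guess_px) next
    if (abs(p[["cx"]] - (c - 1)) > r_win || abs(p[["cy"]] - (r - 1)) > r_win) next
    beads <- rbind(beads, data.frame(cx = p[["cx"]], cy = p[["cy"]],
                                     sigma_px = s, amplitude = p[["amp"]],
                                     offset = p[["off"]],
                                     rss = sum(fit$fvec^2)))
  }
  if (is.null(beads) || nrow(beads) == 0L) stop("all fits rejected")
  structure(list(sigma_px = median(beads$sigma_px),
                 sigma_um = median(beads$sigma_px) * stack$pixel_size_um,
                 beads = beads, n_beads_used = nrow(beads)),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf("<psf_estimate> sigma = %.3g um (%.3g px), %d beads used\n",
              x$sigma_um, x$sigma_px, x$n_beads_used))
  invisible(x)
}
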