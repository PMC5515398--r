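#' Proboscis-position trace from a PER recording
#'
#' The PER readout is the mean brightness within a region of interest at
#' the tip of the fully extended proboscis. The recommended pipeline is
#' [to_grayscale()] then [subtract_background()] with
#' `mode = "temporal_median"` (removing the stimulus light artefact) before
#' calling this; the function itself requires a greyscale stack.
#'
#' @param stack a single-channel `image_stack`.
#' @param tip_roi ROI at the tip of the extended proboscis.
#' @return a `trace`.
#' @export
per_trace <- function(stack, tip_roi) {
  if (dim(stack$frames)[3] != 1L)
    stop("per_trace requires a greyscale stack; apply to_grayscale() first")
  roi_trace(stack, tip_roi)
}

#' Detect supra-threshold events in a trace
#'
#' Baseline is the trace median. The default threshold is
#' `baseline + k * sigma` with a MAD-derived sigma (robust to the events
#' themselves); an absolute threshold can be given instead. Maximal runs
#' above threshold become events; runs separated by less than `min_gap_s`
#' are merged, and events shorter than `min_duration_s` are dropped. An
#' event's end is the time of the first sample after the run (so a single
#' supra-threshold sample has one frame interval of duration).
#'
#' @param trace a `trace`.
#' @param threshold absolute threshold; `NULL` (default) uses
#'   `baseline + k * sigma`.
#' @param k sigma multiplier for the default threshold (default 3).
#' @param min_duration_s minimum event duration (default 0.1 s).
#' @param min_gap_s events closer than this are merged (default 0.1 s).
#' @return an `event_list` with `$intervals` (`onset_s`, `end_s`), the
#'   threshold and baseline used.
#' @export
detect_events <- function(trace, threshold = NULL, k = 3,
                          min_duration_s = 0.1, min_gap_s = 0.1) {
  v <- trace$values
  if (length(v) == 0L) stop("empty trace")
  baseline <- median(v)
  if (is.null(threshold)) threshold <- baseline + k * mad(v)
  dt <- if (length(trace$times_s) > 1) median(diff(trace$times_s)) else 1
  above <- v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  iv <- data.frame(onset_s = trace$times_s[starts[on]],
                   end_s = trace$times_s[ends[on]] + dt)
  # merge runs separated by less than min_gap_s
  if (nrow(iv) > 1L) {
    keep <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      last <- keep[[length(keep)]]
      if (iv$onset_s[i] - last$end_s < min_gap_s) {
        keep[[length(keep)]]$end_s <- iv$end_s[i]
      } else keep[[length(keep) + 1L]] <- iv[i, ]
    }
    iv <- do.call(rbind, keep)
  }
  iv <- iv[iv$end_s - iv$onset_s >= min_duration_s, , drop = FALSE]
  rownames(iv) <- NULL
  structure(list(intervals = iv, threshold = threshold, baseline = baseline),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d event(s), threshold %.4g (baseline %.4g)\n",
              nrow(x$intervals), x$threshold, x$baseline))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

# zero-padded shift of a matrix by (dr, dc)
.shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen morphological thinning of a logical matrix -> 1-px skeleton
.thin <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- .shift_mat(m, 1, 0);  p3 <- .shift_mat(m, 1, -1)
      p4 <- .shift_mat(m, 0, -1); p5 <- .shift_mat(m, -1, -1)
      p6 <- .shift_mat(m, -1, 0); p7 <- .shift_mat(m, -1, 1)
      p8 <- .shift_mat(m, 0, 1);  p9 <- .shift_mat(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- m == 1L & B >= 2L & B <= 6L & A == 1L
      if (step == 1L) cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      else            cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# geodesic diameter (px) of an 8-connected skeleton, plus its end vertices
.skeleton_diameter <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0L) return(NULL)
  if (n == 1L) return(list(length_px = 0, ends = rbind(pts[1, ], pts[1, ])))
  key <- paste(pts[, 1], pts[, 2])
  idx <- seq_len(n); names(idx) <- key
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nk <- paste(pts[, 1] + d[1], pts[, 2] + d[2])
    hit <- nk %in% key
    if (any(hit)) {
      from <- c(from, idx[hit])
      to <- c(to, idx[nk[hit]])
      wt <- c(wt, rep(sqrt(sum(d^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- wt
  d1 <- igraph::distances(g, v = 1)
  d1[!is.finite(d1)] <- -1
  v1 <- which.max(d1)
  d2 <- igraph::distances(g, v = v1)
  d2[!is.finite(d2)] <- -1
  v2 <- which.max(d2)
  # measure along a subsampled polyline of the path: the raw 8-connected
  # geodesic zigzags on curves and overestimates arc length by several %
  vp <- as.integer(igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1]])
  pp <- pts[vp, , drop = FALSE]
  stride <- 5L
  idx2 <- unique(c(seq(1L, nrow(pp), by = stride), nrow(pp)))
  seg <- diff(pp[idx2, 1])^2 + diff(pp[idx2, 2])^2
  list(length_px = sum(sqrt(seg)), ends = rbind(pts[v1, ], pts[v2, ]))
}

# radius of the mask at a pixel: distance to the nearest background pixel
.local_radius <- function(mask, r, c) {
  h <- nrow(mask); w <- ncol(mask)
  for (rad in 1:max(h, w)) {
    rs <- max(1, r - rad):min(h, r + rad)
    cs <- max(1, c - rad):min(w, c + rad)
    sub <- mask[rs, cs]
    if (any(!sub)) {
      bgp <- which(!sub, arr.ind = TRUE)
      return(min(sqrt((bgp[, 1] + rs[1] - 1 - r)^2 + (bgp[, 2] + cs[1] - 1 - c)^2)))
    }
  }
  0
}

#' Larval body length per frame
#'
#' Automates the head-to-tail body-axis length measurement: each frame is
#' Otsu-thresholded, the largest connected component kept, skeletonised
#' (Zhang-Suen thinning) and measured as the longest geodesic path through
#' the 8-connected skeleton — so a bent body is measured along its arc,
#' not its chord. The local body radius at both path ends is added back
#' (thinning erodes about half a body width from each end). Lengths are
#' reported in millimetres via the stack's pixel size.
#'
#' @param stack an `image_stack` (RGB converted to greyscale internally).
#' @param intensity_polarity `"dark_on_light"` (default; animal darker
#'   than background) or `"light_on_dark"`.
#' @param min_area_px components smaller than this are ignored (default 20).
#' @return a `trace` in mm.
#' @export
larval_length_series <- function(stack,
                                 intensity_polarity = c("dark_on_light", "light_on_dark"),
                                 min_area_px = 20) {
  intensity_polarity <- match.arg(intensity_polarity)
  if (dim(stack$frames)[3] == 3L) stack <- to_grayscale(stack)
  d <- dim(stack$frames)
  lens <- numeric(d[4])
  for (t in seq_len(d[4])) {
    img <- matrix(stack$frames[, , 1L, t], d[1], d[2])
    if (intensity_polarity == "dark_on_light") img <- 255 - img
    thr <- 255 * EBImage::otsu(EBImage::Image(img / 255))
    mask <- img > thr
    lab <- .label_components(mask)
    if (max(lab) == 0L) stop("no component found in frame ", t)
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    if (sizes[big] < min_area_px) stop("no component found in frame ", t)
    mask <- lab == big
    skel <- .thin(mask)
    di <- .skeleton_diameter(skel)
    if (is.null(di)) stop("no component found in frame ", t)
    len_px <- di$length_px +
      .local_radius(mask, di$ends[1, 1], di$ends[1, 2]) +
      .local_radius(mask, di$ends[2, 1], di$ends[2, 2])
    lens[t] <- len_px * stack$pixel_size_um / 1000
  }
  new_trace(frame_times(stack), lens, units = "mm")
}

#' Length-based contraction metrics around a light flash
#'
#' Samples a body-length trace at three offsets relative to the flash
#' onset — t = -1 s (pre), +0.5 s (mid-flash) and +5 s (recovery), the
#' standard timepoints for optogenetic larval contraction assays — by
#' nearest sample, and reports the fractional contraction
#' `1 - len(0.5)/len(-1)` and recovery `len(5)/len(-1)`.
#'
#' @param lengths a `trace` of body lengths (any units).
#' @param flash_onset_s flash onset time (flash spans
#'   `flash_onset_s` .. `flash_onset_s + flash_dur_s`).
#' @param flash_dur_s flash duration (default 1 s).
#' @return list with `len_pre`, `len_mid`, `len_post`, `contraction`,
#'   `recovery` and the sample times actually used.
#' @export
contraction_metrics <- function(lengths, flash_onset_s, flash_dur_s = 1) {
  offsets <- c(-1, 0.5, 5)
  targets <- flash_onset_s + offsets
  dt <- if (length(lengths$times_s) > 1) median(diff(lengths$times_s)) else Inf
  vals <- numeric(3); used <- numeric(3)
  for (i in 1:3) {
    j <- which.min(abs(lengths$times_s - targets[i]))
    if (abs(lengths$times_s[j] - targets[i]) > max(dt, 1e-9))
      stop("offsets out of range: trace does not span t = ",
           offsets[i], " s relative to the flash")
    vals[i] <- lengths$values[j]; used[i] <- lengths$times_s[j]
  }
  list(len_pre = vals[1], len_mid = vals[2], len_post = vals[3],
       contraction = 1 - vals[2] / vals[1], recovery = vals[3] / vals[1],
       sample_times_s = used, flash_onset_s = flash_onset_s,
       flash_dur_s = flash_dur_s)
}

#' Per-stimulus fin-bout verdicts from two fin traces
#'
#' Runs [detect_events()] on each pectoral-fin brightness trace and scores
#' each stimulus: a bout is attributed when either fin shows an event
#' onset within `window_s` after the stimulus onset; the latency is the
#' earliest such onset minus the stimulus onset.
#'
#' @param left,right `trace`s of the two fin ROIs.
#' @param stimuli data.frame with `onset_s` and `duration_s`.
#' @param window_s response attribution window (default 1 s).
#' @param ... passed to [detect_events()].
#' @return data.frame `(onset_s, duration_s, bout, latency_s)`.
#' @export
fin_bout_detect <- function(left, right, stimuli, window_s = 1, ...) {
  if (is.null(stimuli) || nrow(stimuli) == 0L)
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      bout = logical(0), latency_s = numeric(0)))
  o <- order(stimuli$onset_s)
  stimuli <- stimuli[o, ]
  if (nrow(stimuli) > 1L &&
      any(diff(stimuli$onset_s) < window_s))
    stop("overlapping response windows: stimulus onsets closer than window_s")
  ev <- rbind(detect_events(left, ...)$intervals,
              detect_events(right, ...)$intervals)
  res <- stimuli[, c("onset_s", "duration_s")]
  res$bout <- FALSE; res$latency_s <- NA_real_
  for (i in seq_len(nrow(res))) {
    hits <- ev$onset_s[ev$onset_s > res$onset_s[i] &
                       ev$onset_s <= res$onset_s[i] + window_s]
    if (length(hits)) {
      res$bout[i] <- TRUE
      res$latency_s[i] <- min(hits) - res$onset_s[i]
    }
  }
  rownames(res) <- NULL
  res
}

#' Minimal multi-animal centroid tracker
#'
#' Per frame: threshold (Otsu), label connected components, keep those of
#' at least `min_area_px`, take centroids; link detections to open tracks
#' by greedy global-nearest-neighbour under `max_jump_px`. Unmatched
#' detections open new tracks; unmatched tracks are closed (a jump larger
#' than `max_jump_px` therefore terminates a track and starts a new one).
#'
#' @param stack an `image_stack` (greyscale or RGB).
#' @param polarity `"dark_on_light"` (default) or `"light_on_dark"`.
#' @param max_jump_px maximum per-frame displacement (default 10).
#' @param min_area_px minimum blob area (default 5).
#' @return list of tracks, each a data.frame `(frame, time_s, cx, cy)` in
#'   0-based pixel coordinates.
#' @export
track_centroids <- function(stack, polarity = c("dark_on_light", "light_on_dark"),
                            max_jump_px = 10, min_area_px = 5) {
  polarity <- match.arg(polarity)
  if (dim(stack$frames)[3] == 3L) stack <- to_grayscale(stack)
  d <- dim(stack$frames)
  times <- frame_times(stack)
  tracks <- list()      # closed + open; each df(frame, time_s, cx, cy)
  open <- integer(0)    # indices into tracks that are currently open
  for (t in seq_len(d[4])) {
    img <- matrix(stack$frames[, , 1L, t], d[1], d[2])
    if (polarity == "dark_on_light") img <- 255 - img
    thr <- 255 * EBImage::otsu(EBImage::Image(img / 255))
    mask <- img > thr
    lab <- .label_components(mask)
    dets <- NULL
    if (max(lab) > 0L) {
      for (l in seq_len(max(lab))) {
        pix <- which(lab == l, arr.ind = TRUE)
        if (nrow(pix) < min_area_px) next
        dets <- rbind(dets, data.frame(cx = mean(pix[, 2]) - 1,
                                       cy = mean(pix[, 1]) - 1))
      }
    }
    nd <- if (is.null(dets)) 0L else nrow(dets)
    matched_det <- rep(FALSE, nd)
    matched_tr <- rep(FALSE, length(open))
    if (nd > 0L && length(open) > 0L) {
      heads <- do.call(rbind, lapply(tracks[open], function(tr) tr[nrow(tr), c("cx", "cy")]))
      D <- outer(seq_len(length(open)), seq_len(nd), Vectorize(function(i, j)
        sqrt((heads$cx[i] - dets$cx[j])^2 + (heads$cy[i] - dets$cy[j])^2)))
      repeat {
        D2 <- D
        D2[matched_tr, ] <- Inf; D2[, matched_det] <- Inf
        if (all(!is.finite(D2)) || min(D2) > max_jump_px) break
        ij <- which(D2 == min(D2), arr.ind = TRUE)[1, ]
        i <- ij[1]; j <- ij[2]
        matched_tr[i] <- TRUE; matched_det[j] <- TRUE
        ti <- open[i]
        tracks[[ti]] <- rbind(tracks[[ti]],
                              data.frame(frame = t, time_s = times[t],
                                         cx = dets$cx[j], cy = dets$cy[j]))
      }
    }
    still_open <- open[matched_tr]
    if (nd > 0L) for (j in which(!matched_det)) {
      tracks[[length(tracks) + 1L]] <- data.frame(frame = t, time_s = times[t],
                                                  cx = dets$cx[j], cy = dets$cy[j])
      still_open <- c(still_open, length(tracks))
    }
    open <- still_open
  }
  tracks
}
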