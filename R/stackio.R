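#' @importFrom stats median mad rnorm rpois runif pnorm sd coef setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# round-half-up to integer grey levels (the 8-bit convention used throughout);
# preserves dim (pmax/pmin take attributes from their first, scalar, argument)
.round8 <- function(x) {
  d <- dim(x)
  out <- pmin(255, pmax(0, floor(x + 0.5)))
  dim(out) <- d
  out
}

#' Construct an image stack
#'
#' The universal container for acquired or simulated video: a T-frame stack of
#' 8-bit (or float) images with frame rate, pixel size and acquisition start
#' time. Pixel coordinates are 0-based, row-major, origin at the top-left;
#' rectangles are half-open. Frames are stored internally as an
#' `H x W x C x T` numeric array (C = 1 for greyscale, 3 for RGB).
#'
#' @param frames a matrix (one grey frame), an `H x W x C` array (one frame),
#'   an `H x W x C x T` array, or a list of per-frame matrices/arrays.
#' @param frame_rate_hz frames per second (> 0). Default 42 (the x2-binned
#'   video rate of the camera being emulated).
#' @param pixel_size_um microns per pixel (> 0); default 1 (full zoom).
#' @param t0_s acquisition start time in seconds.
#' @param channel_names labels for C = 3 stacks; default red, green, blue.
#' @param mode `"uint8"` (values must be integers in 0..255) or `"float"`.
#'   Guessed from the data when `NULL`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_rate_hz = 42, pixel_size_um = 1,
                        t0_s = 0, channel_names = NULL, mode = NULL) {
  if (is.list(frames)) {
    if (length(frames) == 0L) stop("stack must contain at least one frame")
    shp <- lapply(frames, function(f) dim(f) %||% length(f))
    if (length(unique(lapply(shp, as.integer))) != 1L)
      stop("inconsistent frame shapes")
    frames <- lapply(frames, function(f) {
      if (is.matrix(f)) array(f, c(dim(f), 1L)) else f
    })
    d <- dim(frames[[1]])
    if (length(d) != 3L) stop("each frame must be H x W or H x W x C")
    arr <- array(0, c(d, length(frames)))
    for (t in seq_along(frames)) arr[, , , t] <- frames[[t]]
    frames <- arr
  } else if (is.matrix(frames)) {
    frames <- array(frames, c(dim(frames), 1L, 1L))
  } else if (length(dim(frames)) == 3L) {
    frames <- array(frames, c(dim(frames), 1L))
  }
  d <- dim(frames)
  if (length(d) != 4L) stop("frames must reduce to an H x W x C x T array")
  if (!d[3] %in% c(1L, 3L)) stop("channel count must be 1 or 3")
  if (any(d < 1L)) stop("empty stack dimensions")
  stopifnot(frame_rate_hz > 0, pixel_size_um > 0)
  if (is.null(mode)) {
    v <- frames[!is.na(frames)]
    mode <- if (length(v) && all(v >= 0 & v <= 255 & v == floor(v))) "uint8" else "float"
  }
  mode <- match.arg(mode, c("uint8", "float"))
  if (mode == "uint8" && (any(frames < 0) || any(frames > 255)))
    stop("uint8 stack values must lie in [0, 255]")
  if (d[3] == 3L && is.null(channel_names)) channel_names <- c("red", "green", "blue")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, t0_s = t0_s,
                 channel_names = channel_names, mode = mode),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s), %d x %d px, %d channel(s), %s\n",
              d[4], d[1], d[2], d[3], x$mode))
  cat(sprintf("  %.3g Hz, %.3g um/px, t0 = %.3g s\n",
              x$frame_rate_hz, x$pixel_size_um, x$t0_s))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `image_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[4]

#' Frame timestamps of a stack
#'
#' Timestamps are implied: `t0_s + k / frame_rate_hz` for frame index k.
#' @param stack an `image_stack`.
#' @return numeric vector of length T, strictly increasing.
#' @export
frame_times <- function(stack)
  stack$t0_s + (seq_len(n_frames(stack)) - 1) / stack$frame_rate_hz

#' Extract one frame as a matrix or H x W x C array
#' @param stack an `image_stack`.
#' @param t 1-based frame index.
#' @export
get_frame <- function(stack, t) {
  d <- dim(stack$frames)
  f <- stack$frames[, , , t, drop = FALSE]
  if (d[3] == 1L) matrix(f, d[1], d[2]) else array(f, d[1:3])
}

.sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")

#' Read an image stack from a multi-page TIFF (plus sidecar metadata)
#'
#' Reads an 8-bit greyscale or RGB multi-page TIFF. Acquisition metadata
#' (`frame_rate_hz`, `pixel_size_um`, `t0_s`, `channel_names`) is taken from a
#' sidecar JSON file named `<stem>.json` next to the TIFF when present;
#' otherwise the documented defaults apply (42 Hz, 1 um/px, t0 = 0).
#' AVI containers are imported by shelling out to `ffmpeg` when that tool is
#' on the PATH.
#'
#' @param path path to a `.tif`/`.tiff` (or `.avi`) file.
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.avi$", path, ignore.case = TRUE)) return(.read_avi(path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable container: ", conditionMessage(e)))
  if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("unreadable container: zero frames")
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) stop("inconsistent frame shapes across pages")
  pages <- lapply(pages, function(p) .round8(p * 255))
  meta <- list()
  sp <- .sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  image_stack(pages,
              frame_rate_hz = meta$frame_rate_hz %||% 42,
              pixel_size_um = meta$pixel_size_um %||% 1,
              t0_s          = meta$t0_s %||% 0,
              channel_names = meta$channel_names,
              mode = "uint8")
}

.read_avi <- function(path) {
  if (Sys.which("ffmpeg") == "")
    stop("AVI import requires ffmpeg on the PATH; convert to TIFF instead")
  td <- tempfile("avi_frames_"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  status <- system2("ffmpeg", c("-v", "error", "-i", shQuote(path),
                                file.path(td, "f_%06d.tif")))
  if (status != 0L) stop("unreadable container: ffmpeg failed on ", path)
  fs <- sort(list.files(td, full.names = TRUE))
  if (length(fs) == 0L) stop("unreadable container: zero frames")
  frames <- lapply(fs, function(f) .round8(tiff::readTIFF(f) * 255))
  image_stack(frames, mode = "uint8")
}

#' Write an image stack to a multi-page TIFF plus sidecar JSON
#'
#' 8-bit stacks are written losslessly (uncompressed 8-bit pages); the
#' round trip through [read_stack()] is bit-identical. Float stacks are
#' rescaled into the unit interval before writing, with the affine scale
#' recorded in the sidecar (`float_offset`, `float_scale`), because TIFF
#' float sample formats are not portably supported by the writer.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path; the sidecar is written to `<stem>.json`.
#' @export
write_stack <- function(stack, path) {
  if (!dir.exists(dirname(path))) stop("unwritable path: no such directory ", dirname(path))
  d <- dim(stack$frames)
  meta <- list(frame_rate_hz = stack$frame_rate_hz,
               pixel_size_um = stack$pixel_size_um,
               t0_s = stack$t0_s)
  if (!is.null(stack$channel_names)) meta$channel_names <- stack$channel_names
  fr <- stack$frames
  if (stack$mode == "float") {
    lo <- min(fr); hi <- max(fr); sc <- if (hi > lo) hi - lo else 1
    meta$float_offset <- lo; meta$float_scale <- sc
    fr <- (fr - lo) / sc
  } else fr <- fr / 255
  pages <- lapply(seq_len(d[4]), function(t) {
    if (d[3] == 1L) matrix(fr[, , 1L, t], d[1], d[2]) else array(fr[, , , t], d[1:3])
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                                 compression = "none"),
                 error = function(e) stop("unwritable path: ", conditionMessage(e)))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Spatially bin a stack by block averaging
#'
#' Emulates the camera's on-sensor binning: each `factor x factor` tile is
#' replaced by its mean (rounded half-up for 8-bit stacks). The pixel size
#' grows by `factor`; a 2592 x 1944 frame binned x2 becomes 1296 x 972.
#'
#' @param stack an `image_stack`.
#' @param factor 1, 2 or 4; frame height and width must be divisible by it.
#' @export
bin_spatial <- function(stack, factor) {
  if (!factor %in% c(1L, 2L, 4L)) stop("unsupported binning factor: ", factor)
  if (factor == 1L) return(stack)
  d <- dim(stack$frames)
  if (d[1] %% factor || d[2] %% factor)
    stop("frame dimensions not divisible by binning factor")
  h <- d[1] %/% factor; w <- d[2] %/% factor
  out <- array(0, c(h, w, d[3], d[4]))
  for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
    m <- matrix(stack$frames[, , c, t], d[1], d[2])
    a <- array(m, c(factor, h, factor, w))
    out[, , c, t] <- colMeans(aperm(a, c(1L, 3L, 2L, 4L)), dims = 2L)
  }
  if (stack$mode == "uint8") out <- .round8(out)
  image_stack(out, frame_rate_hz = stack$frame_rate_hz,
              pixel_size_um = stack$pixel_size_um * factor,
              t0_s = stack$t0_s, channel_names = stack$channel_names,
              mode = stack$mode)
}

#' Temporally downsample a stack
#'
#' Block-averages `factor` consecutive frames (default behaviour; improves
#' SNR) or decimates (keeps every `factor`-th frame) when `method =
#' "decimate"`. The frame rate is divided by `factor`; a trailing partial
#' block is dropped.
#'
#' @param stack an `image_stack`.
#' @param factor integer >= 1, at most T.
#' @param method `"average"` (default) or `"decimate"`.
#' @export
downsample_time <- function(stack, factor, method = c("average", "decimate")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  T <- n_frames(stack)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor > T) stop("factor exceeds frame count")
  if (factor == 1L) return(stack)
  nb <- T %/% factor
  d <- dim(stack$frames)
  out <- array(0, c(d[1:3], nb))
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * factor + 1L):(b * factor)
    if (method == "decimate") {
      out[, , , b] <- stack$frames[, , , idx[1L], drop = FALSE]
    } else {
      acc <- array(0, d[1:3])
      for (t in idx) acc <- acc + array(stack$frames[, , , t, drop = FALSE], d[1:3])
      out[, , , b] <- acc / factor
    }
  }
  if (stack$mode == "uint8") out <- .round8(out)
  image_stack(out, frame_rate_hz = stack$frame_rate_hz / factor,
              pixel_size_um = stack$pixel_size_um, t0_s = stack$t0_s,
              channel_names = stack$channel_names, mode = stack$mode)
}

#' Extract a single colour channel
#'
#' @param stack an RGB `image_stack` (C = 3).
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return a single-channel stack; other metadata preserved.
#' @export
extract_channel <- function(stack, channel) {
  d <- dim(stack$frames)
  if (d[3] != 3L) stop("channel extraction requires an RGB stack")
  names <- stack$channel_names %||% c("red", "green", "blue")
  ci <- match(channel, names)
  if (is.na(ci)) stop("unknown channel: ", channel)
  image_stack(stack$frames[, , ci, , drop = FALSE],
              frame_rate_hz = stack$frame_rate_hz,
              pixel_size_um = stack$pixel_size_um, t0_s = stack$t0_s,
              mode = stack$mode)
}

#' Convert an RGB stack to 8-bit greyscale
#'
#' By default the unweighted per-pixel mean of R, G and B, rounded half-up
#' (the convention used by the analysis pipelines here); pass
#' `weights = c(0.299, 0.587, 0.114)` for luminance weighting. Greyscale
#' input is returned unchanged.
#'
#' @param stack an `image_stack`.
#' @param weights optional length-3 channel weights (normalised internally).
#' @export
to_grayscale <- function(stack, weights = NULL) {
  d <- dim(stack$frames)
  if (d[3] == 1L) return(stack)
  w <- if (is.null(weights)) rep(1 / 3, 3) else weights / sum(weights)
  out <- w[1] * stack$frames[, , 1L, , drop = FALSE] +
         w[2] * stack$frames[, , 2L, , drop = FALSE] +
         w[3] * stack$frames[, , 3L, , drop = FALSE]
  if (stack$mode == "uint8") out <- .round8(out)
  image_stack(out, frame_rate_hz = stack$frame_rate_hz,
              pixel_size_um = stack$pixel_size_um, t0_s = stack$t0_s,
              mode = stack$mode)
}

#' Create a fresh timestamped output path under the rig's output layout
#'
#' Acquisition outputs live under `<root>/FlyPi_output/<kind>/<timestamp>`,
#' one directory per run, mirroring the rig software's convention of never
#' overwriting data. The directory is created (so a returned path can never
#' be returned again) and a numeric suffix disambiguates calls within the
#' same second.
#'
#' @param root base directory (must exist).
#' @param kind one of `"time_lapse"`, `"video"`, `"snapshots"`,
#'   `"temperature_logging"`.
#' @param clock a zero-argument function returning the current time
#'   (POSIXct); injectable for testing.
#' @return the created directory path.
#' @export
make_output_path <- function(root, kind, clock = Sys.time) {
  kinds <- c("time_lapse", "video", "snapshots", "temperature_logging")
  if (!kind %in% kinds)
    stop("unknown output kind: ", kind, " (expected one of ",
         paste(kinds, collapse = ", "), ")")
  base <- file.path(root, "FlyPi_output", kind)
  dir.create(base, recursive = TRUE, showWarnings = FALSE)
  stamp <- format(clock(), "%Y-%m-%dT%H-%M-%S")
  path <- file.path(base, stamp)
  n <- 0L
  while (file.exists(path)) {
    n <- n + 1L
    path <- file.path(base, sprintf("%s_%03d", stamp, n))
  }
  dir.create(path)
  path
}
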