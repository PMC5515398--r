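#' Rectangular region of interest
#'
#' Half-open rectangle `[x0, x1) x [y0, y1)` in 0-based pixel coordinates
#' (x = column, y = row, origin top-left).
#'
#' @param x0,y0 inclusive top-left corner.
#' @param x1,y1 exclusive bottom-right corner; must exceed `x0`,`y0`.
#' @param label optional text label.
#' @export
roi_rect <- function(x0, y0, x1, y1, label = "") {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0)
  structure(list(shape = "rect", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 label = label), class = "roi")
}

#' Disk region of interest
#'
#' @param cx,cy centre in 0-based pixel coordinates.
#' @param r radius in pixels (> 0). A pixel belongs to the disk when its
#'   centre lies within `r` of `(cx, cy)`.
#' @param label optional text label.
#' @export
roi_disk <- function(cx, cy, r, label = "") {
  stopifnot(r > 0)
  structure(list(shape = "disk", cx = cx, cy = cy, r = r, label = label),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  if (x$shape == "rect")
    cat(sprintf("<roi rect [%g,%g)x[%g,%g) '%s'>\n", x$x0, x$x1, x$y0, x$y1, x$label))
  else
    cat(sprintf("<roi disk (%g,%g) r=%g '%s'>\n", x$cx, x$cy, x$r, x$label))
  invisible(x)
}

# logical H x W mask for an ROI; errors if the ROI misses the image entirely
roi_mask <- function(roi, h, w) {
  m <- matrix(FALSE, h, w)
  if (roi$shape == "rect") {
    ylo <- max(0, floor(roi$y0)); yhi <- min(h - 1, ceiling(roi$y1) - 1)
    xlo <- max(0, floor(roi$x0)); xhi <- min(w - 1, ceiling(roi$x1) - 1)
    ys <- if (ylo <= yhi) ylo:yhi else integer(0)
    xs <- if (xlo <= xhi) xlo:xhi else integer(0)
    ys <- ys[ys >= roi$y0 & ys < roi$y1]
    xs <- xs[xs >= roi$x0 & xs < roi$x1]
    if (length(ys) && length(xs)) m[ys + 1, xs + 1] <- TRUE
  } else {
    yy <- matrix(0:(h - 1), h, w)
    xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
    m <- (xx - roi$cx)^2 + (yy - roi$cy)^2 <= roi$r^2
  }
  if (!any(m)) stop("ROI lies outside the image bounds")
  m
}

#' Construct a time-series trace
#'
#' @param times_s strictly increasing times in seconds.
#' @param values same-length numeric values.
#' @param units unit label (e.g. `"a.u."`, `"mm"`, `"degC"`).
#' @export
new_trace <- function(times_s, values, units = "a.u.") {
  stopifnot(length(times_s) == length(values))
  if (length(times_s) > 1 && any(diff(times_s) <= 0))
    stop("trace times must be strictly increasing")
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 units = units), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples [%s], t = %.3g..%.3g s\n",
              length(x$values), x$units,
              if (length(x$times_s)) min(x$times_s) else NA,
              if (length(x$times_s)) max(x$times_s) else NA))
  invisible(x)
}

#' @export
plot.trace <- function(x, ...) {
  plot(x$times_s, x$values, type = "l", xlab = "time (s)", ylab = x$units, ...)
}

#' Write a trace to CSV (`time_s`, `value`; units recorded in the header)
#' @param trace a `trace`.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", trace$units), con)
  write.csv(data.frame(time_s = trace$times_s, value = trace$values),
            con, row.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#' @param path CSV path.
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  units <- if (grepl("^# units:", hdr)) sub("^# units: *", "", hdr) else "a.u."
  df <- read.csv(path, comment.char = "#")
  new_trace(df$time_s, df$value, units)
}
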