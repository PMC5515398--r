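.valid_channel <- function(ch)
  ch %in% c("led_ring.red", "led_ring.green", "led_ring.blue", "led_matrix",
            "peltier.setpoint") || grepl("^gpp\\.[0-9]+$", ch)

#' One step of a stimulus protocol
#'
#' A step drives one output channel with `repeats` cycles of
#' `value` for `on_duration_us` then 0 for `off_duration_us`. Durations are
#' integer microseconds (kept exact: stored as doubles, which represent
#' integers exactly far beyond any protocol length; R's native integer
#' type would overflow within minutes of microseconds).
#'
#' @param channel `led_ring.red|green|blue`, `led_matrix`,
#'   `peltier.setpoint` or `gpp.<n>`.
#' @param value intensity 0-255, or setpoint degC for `peltier.setpoint`.
#' @param on_duration_us,off_duration_us cycle durations in microseconds;
#'   non-negative, not both zero.
#' @param repeats cycle count, >= 1.
#' @export
protocol_step <- function(channel, value, on_duration_us, off_duration_us = 0,
                          repeats = 1) {
  if (!.valid_channel(channel)) stop("unknown channel: ", channel)
  on_duration_us <- as.numeric(on_duration_us)
  off_duration_us <- as.numeric(off_duration_us)
  if (on_duration_us < 0 || off_duration_us < 0 ||
      on_duration_us != floor(on_duration_us) ||
      off_duration_us != floor(off_duration_us))
    stop("durations must be non-negative integer microseconds")
  if (on_duration_us + off_duration_us == 0) stop("durations must not both be zero")
  if (repeats < 1 || repeats != floor(repeats)) stop("repeats must be a positive integer")
  structure(list(channel = channel, value = value,
                 on_duration_us = on_duration_us,
                 off_duration_us = off_duration_us, repeats = repeats),
            class = "protocol_step")
}

#' Compile a protocol into a microsecond-stamped event log
#'
#' Steps execute sequentially. Each repeat emits `(t, channel, value)` at
#' cycle start and `(t + on, channel, 0)` at the on-to-off edge, all in
#' exact integer-microsecond arithmetic (no accumulation drift: timestamps
#' are computed, not incremented). The total span is
#' `sum(repeats * (on + off))`.
#'
#' @param steps a list of [protocol_step()]s (a single step is accepted).
#' @return event log: data.frame `(t_us, channel, value)` with
#'   non-decreasing integer timestamps.
#' @export
compile_protocol <- function(steps) {
  if (inherits(steps, "protocol_step")) steps <- list(steps)
  if (length(steps) == 0L)
    return(data.frame(t_us = numeric(0), channel = character(0),
                      value = numeric(0)))
  logs <- vector("list", length(steps))
  base <- 0
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (!inherits(s, "protocol_step"))
      s <- do.call(protocol_step, s)   # revalidates plain lists
    cycle <- s$on_duration_us + s$off_duration_us
    starts <- base + (seq_len(s$repeats) - 1) * cycle
    logs[[i]] <- data.frame(
      t_us = as.numeric(rbind(starts, starts + s$on_duration_us)),
      channel = s$channel,
      value = as.numeric(rbind(rep(s$value, s$repeats), rep(0, s$repeats))))
    base <- base + s$repeats * cycle
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}

#' Execute an event log against registered channel handlers
#'
#' Dispatches events in timestamp order on a virtual clock: each handler
#' is called as `handler(t_us, value)` with the exact compiled timestamp —
#' execution is deterministic and independent of wall time. The executed
#' log equals the compiled log.
#'
#' @param log an event log from [compile_protocol()].
#' @param handlers named list of `function(t_us, value)` keyed by channel.
#' @return the executed log, invisibly.
#' @export
run_protocol <- function(log, handlers) {
  if (nrow(log) == 0L) return(invisible(log))
  missing <- setdiff(unique(log$channel), names(handlers))
  if (length(missing))
    stop("event addressed to unregistered channel: ",
         paste(missing, collapse = ", "))
  ord <- order(log$t_us)
  for (i in ord) handlers[[log$channel[i]]](log$t_us[i], log$value[i])
  invisible(log[ord, ])
}

#' Format a structured rig command as a serial line
#'
#' The ASCII wire dialect (a documented stand-in, not a clone of any
#' firmware's grammar): `RING <r> <g> <b>`, `PELT SET <degC x 10>`
#' (fixed-point integer, avoiding float parsing on the wire),
#' `SERVO <id> <pos>`, `LOG ON|OFF`.
#'
#' @param cmd a list with `$verb` (`ring`, `pelt_set`, `servo`, `log`) and
#'   its arguments (`r,g,b`; `setpoint_C`; `id,pos`; `on`).
#' @return a single newline-terminated character string.
#' @export
format_command <- function(cmd) {
  line <- switch(cmd$verb,
    ring = {
      v <- c(cmd$r, cmd$g, cmd$b)
      if (any(v < 0 | v > 255 | v != floor(v))) stop("RING values must be 0..255")
      sprintf("RING %d %d %d", cmd$r, cmd$g, cmd$b)
    },
    pelt_set = sprintf("PELT SET %d", as.integer(round(cmd$setpoint_C * 10))),
    servo = sprintf("SERVO %d %d", as.integer(cmd$id), as.integer(cmd$pos)),
    log = sprintf("LOG %s", if (isTRUE(cmd$on)) "ON" else "OFF"),
    stop("unknown verb: ", cmd$verb))
  paste0(line, "\n")
}

#' Parse a serial line into a structured rig command
#'
#' Inverse of [format_command()]; `parse_command(format_command(x))`
#' reproduces `x`. Malformed lines raise an error naming the offending
#' token.
#'
#' @param line a (possibly newline-terminated) ASCII command line.
#' @export
parse_command <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(toks) == 0L || toks[1] == "") stop("empty command line")
  int_tok <- function(t) {
    if (!grepl("^-?[0-9]+$", t)) stop("malformed token: '", t, "'")
    as.integer(t)
  }
  switch(toks[1],
    RING = {
      if (length(toks) != 4L) stop("RING expects 3 arguments")
      v <- vapply(toks[2:4], int_tok, integer(1))
      if (any(v < 0 | v > 255)) stop("malformed token: RING value out of 0..255")
      list(verb = "ring", r = v[[1]], g = v[[2]], b = v[[3]])
    },
    PELT = {
      if (length(toks) != 3L || toks[2] != "SET")
        stop("malformed token: expected 'PELT SET <value>'")
      list(verb = "pelt_set", setpoint_C = int_tok(toks[3]) / 10)
    },
    SERVO = {
      if (length(toks) != 3L) stop("SERVO expects 2 arguments")
      list(verb = "servo", id = int_tok(toks[2]), pos = int_tok(toks[3]))
    },
    LOG = {
      if (length(toks) != 2L || !toks[2] %in% c("ON", "OFF"))
        stop("malformed token: LOG expects ON or OFF")
      list(verb = "log", on = toks[2] == "ON")
    },
    stop("unknown verb: '", toks[1], "'"))
}

#' LED-ring preset states
#'
#' The ring has 12 RGB pixels. Presets cover the standard experimental
#' uses: full-field blue (ChR2), red (Chrimson/ReaChR), green, dim red
#' (behavioural illumination the flies barely see; red = 20), white and
#' off.
#'
#' @param name one of `all_blue_full`, `all_red_full`, `all_green_full`,
#'   `dim_red`, `white`, `off`.
#' @return a 12 x 3 integer matrix (columns r, g, b) of class
#'   `led_ring_state`.
#' @export
ring_preset <- function(name) {
  rgb <- switch(name,
    all_blue_full = c(0, 0, 255),
    all_red_full = c(255, 0, 0),
    all_green_full = c(0, 255, 0),
    dim_red = c(20, 0, 0),
    white = c(255, 255, 255),
    off = c(0, 0, 0),
    stop("unknown preset: ", name))
  structure(matrix(rep(rgb, each = 12), 12, 3,
                   dimnames = list(NULL, c("r", "g", "b"))),
            class = c("led_ring_state", "matrix", "array"))
}

#' Read a protocol from a YAML or JSON file
#'
#' The file holds a list of steps, each with fields `channel`, `value`,
#' `on_duration_us`, `off_duration_us`, `repeats`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list of [protocol_step()]s.
#' @export
read_protocol <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(s) do.call(protocol_step, s))
}
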