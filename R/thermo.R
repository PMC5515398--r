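#' Lumped thermal parameters of the virtual Peltier rig
#'
#' A two-node model: the Peltier surface (where the animal sits and the
#' thermistor is clamped) and the heat sink + fan beneath it. The Peltier
#' pumps heat between the nodes at up to `Q_max` watts (cooling derated by
#' `eta_asym`, since thermoelectric cooling is less efficient than
#' heating); each node also leaks to ambient through its conductance. The
#' default constants are calibrated so the simulated rig reproduces the
#' published loop performance at 19 degC ambient: about +-20 degC
#' attainable range, about 1 degC/s ramps, and sub-degree hold stability.
#'
#' @param C_surf,C_sink heat capacities (J/degC).
#' @param k_surf_sink surface-to-sink conductance (W/degC).
#' @param k_surf_amb surface-to-ambient leak (W/degC).
#' @param k_sink_amb_fan sink-to-ambient conductance with the fan running
#'   (W/degC).
#' @param Q_max peak Peltier heat pumping (W).
#' @param eta_asym cooling derating factor in (0, 1].
#' @param ambient_C ambient temperature (degC).
#' @export
thermo_params <- function(C_surf = 20, C_sink = 200, k_surf_sink = 0.8,
                          k_surf_amb = 0.15, k_sink_amb_fan = 5,
                          Q_max = 30, eta_asym = 0.7, ambient_C = 19) {
  p <- as.list(environment())
  stopifnot(C_surf > 0, C_sink > 0, k_surf_sink > 0, k_surf_amb > 0,
            k_sink_amb_fan > 0, Q_max > 0, eta_asym > 0, eta_asym <= 1)
  structure(p, class = "thermo_params")
}

# largest explicit-Euler step for which both nodes are stable
.euler_bound <- function(p)
  min(p$C_surf / (p$k_surf_sink + p$k_surf_amb),
      p$C_sink / (p$k_surf_sink + p$k_sink_amb_fan))

#' One explicit-Euler step of the two-node thermal plant
#'
#' Heat pumped by the Peltier enters the surface node and leaves the sink
#' node (antisymmetric flows), as does the conducted surface-sink flow;
#' both nodes leak to ambient. Drive `u` in `[-1, 1]` scales the pumping,
#' with cooling derated by `eta_asym`.
#'
#' @param state numeric `c(T_surf, T_sink)` in degC.
#' @param u drive in `[-1, 1]`.
#' @param params a [thermo_params()].
#' @param dt step in seconds; must not exceed the documented stability
#'   bound `min(C/sum(k))` per node.
#' @return updated `c(T_surf, T_sink)`, with attribute `flows` carrying
#'   the per-step heat flows (W) for conservation checks.
#' @export
plant_step <- function(state, u, params, dt) {
  if (dt > .euler_bound(params))
    stop(sprintf("dt = %g exceeds the Euler stability bound %.3g s",
                 dt, .euler_bound(params)))
  u <- max(-1, min(1, u))
  Q <- if (u >= 0) u * params$Q_max else u * params$eta_asym * params$Q_max
  Ts <- state[1]; Tk <- state[2]; a <- params$ambient_C
  q_cond <- params$k_surf_sink * (Ts - Tk)    # surface -> sink conduction
  dTs <- (Q - q_cond - params$k_surf_amb * (Ts - a)) / params$C_surf
  dTk <- (-Q + q_cond - params$k_sink_amb_fan * (Tk - a)) / params$C_sink
  out <- c(Ts + dt * dTs, Tk + dt * dTk)
  attr(out, "flows") <- c(pump = Q, cond_surf = -q_cond, cond_sink = q_cond)
  out
}

#' Beta-model thermistor with ADC quantisation
#'
#' Models a 10 kOhm NTC thermistor read through a resistive divider and an
#' n-bit ADC: `R(T) = r25 * exp(beta * (1/T_K - 1/298.15))`, divider
#' voltage `R_div / (R_div + R)`, quantised to an integer ADC code, then
#' inverted back to degC. Gaussian sensor noise (in degC) is added before
#' quantisation. Vectorised over `T_true_C`.
#'
#' @param T_true_C true temperature(s), degC; must lie in `[-40, 120]`.
#' @param adc_bits ADC resolution (default 10, i.e. codes 0..1023).
#' @param beta_K beta constant (default 3950 K).
#' @param r25_ohm resistance at 25 degC (default 10 kOhm).
#' @param divider_ohm divider resistor (default 10 kOhm).
#' @param noise_sd_C sensor noise s.d. in degC (default 0.1).
#' @param seed optional seed for the noise draw.
#' @return measured temperature(s) in degC.
#' @export
thermistor_model <- function(T_true_C, adc_bits = 10, beta_K = 3950,
                             r25_ohm = 10000, divider_ohm = 10000,
                             noise_sd_C = 0.1, seed = NULL) {
  if (any(T_true_C < -40 | T_true_C > 120))
    stop("temperature outside the thermistor validity range [-40, 120] degC")
  if (!is.null(seed)) set.seed(seed)
  Tn <- T_true_C + if (noise_sd_C > 0) rnorm(length(T_true_C), 0, noise_sd_C) else 0
  TK <- Tn + 273.15
  R <- r25_ohm * exp(beta_K * (1 / TK - 1 / 298.15))
  v <- divider_ohm / (divider_ohm + R)
  codes_max <- 2^adc_bits - 1
  code <- pmin(codes_max - 1, pmax(1, round(v * codes_max)))
  v2 <- code / codes_max
  R2 <- divider_ohm * (1 / v2 - 1)
  1 / (1 / 298.15 + log(R2 / r25_ohm) / beta_K) - 273.15
}

#' Feedback-controller configuration
#'
#' Bang-bang with a hysteresis band (default; robust and tuning-free) or a
#' clamped PI law for comparison.
#'
#' @param mode `"bang_bang"` or `"pi"`.
#' @param hysteresis_C bang-bang half-band (default 0.25 degC).
#' @param Kp,Ki PI gains (per degC and per degC.s).
#' @param i_limit anti-windup clamp on the integral term (drive units).
#' @param update_s controller update period (default 0.1 s).
#' @export
controller_config <- function(mode = c("bang_bang", "pi"), hysteresis_C = 0.25,
                              Kp = 0.5, Ki = 0.05, i_limit = 1, update_s = 0.1) {
  mode <- match.arg(mode)
  stopifnot(hysteresis_C > 0, update_s > 0)
  structure(list(mode = mode, hysteresis_C = hysteresis_C, Kp = Kp, Ki = Ki,
                 i_limit = i_limit, update_s = update_s),
            class = "controller_config")
}

#' One controller update
#'
#' Bang-bang: full heat below `setpoint - hysteresis`, full cool above
#' `setpoint + hysteresis`, previous drive retained inside the band.
#' PI: `clamp(Kp * e + Ki * integral(e))` with integral clamping.
#'
#' @param cfg a [controller_config()].
#' @param setpoint_C,measured_C temperatures in degC.
#' @param ctrl_state list carried between calls (`u`, `integral`); pass
#'   `NULL` initially.
#' @return `list(u = drive, state = updated ctrl_state)`.
#' @export
controller_update <- function(cfg, setpoint_C, measured_C, ctrl_state = NULL) {
  if (is.null(ctrl_state)) ctrl_state <- list(u = 0, integral = 0)
  if (cfg$mode == "bang_bang") {
    u <- if (measured_C < setpoint_C - cfg$hysteresis_C) 1
         else if (measured_C > setpoint_C + cfg$hysteresis_C) -1
         else ctrl_state$u
  } else {
    e <- setpoint_C - measured_C
    ctrl_state$integral <- max(-cfg$i_limit,
                               min(cfg$i_limit,
                                   ctrl_state$integral + e * cfg$Ki * cfg$update_s))
    u <- max(-1, min(1, cfg$Kp * e + ctrl_state$integral))
  }
  ctrl_state$u <- u
  list(u = u, state = ctrl_state)
}

#' Run the closed temperature-control loop
#'
#' Integrates the plant with a fine explicit-Euler step, reads the
#' thermistor and updates the controller every `cfg$update_s`, and logs
#' setpoint, reading and drive at `log_hz` (2 Hz by default, matching the
#' rig's serial temperature log). Deterministic given `seed`.
#'
#' @param params a [thermo_params()].
#' @param cfg a [controller_config()].
#' @param setpoint_schedule data.frame `(start_s, setpoint_C)` (or a list
#'   of such pairs); the first entry must start at 0.
#' @param duration_s total simulated time.
#' @param log_hz logging rate (default 2).
#' @param dt integration step (default 0.01 s).
#' @param noise_sd_C thermistor noise passed to [thermistor_model()].
#' @param seed integer seed.
#' @return a `thermo_log`: data.frame `(time_s, setpoint_C, reading_C,
#'   drive)` at uniform `1/log_hz` spacing.
#' @export
run_loop <- function(params, cfg = controller_config(), setpoint_schedule,
                     duration_s, log_hz = 2, dt = 0.01, noise_sd_C = 0.1,
                     seed = 1) {
  if (is.list(setpoint_schedule) && !is.data.frame(setpoint_schedule))
    setpoint_schedule <- do.call(rbind, lapply(setpoint_schedule, function(s)
      data.frame(start_s = s[[1]], setpoint_C = s[[2]])))
  if (is.null(setpoint_schedule) || nrow(setpoint_schedule) == 0L)
    stop("empty setpoint schedule")
  sch <- setpoint_schedule[order(setpoint_schedule$start_s), ]
  if (sch$start_s[1] > 0) stop("schedule must cover t = 0")
  set.seed(seed)
  nsteps <- ceiling(duration_s / dt)
  state <- c(params$ambient_C, params$ambient_C)
  cs <- NULL
  u <- 0
  reading <- params$ambient_C
  ctrl_every <- max(1L, round(cfg$update_s / dt))
  log_every <- max(1L, round(1 / (log_hz * dt)))
  nlog <- floor(nsteps / log_every)
  log_t <- numeric(nlog); log_sp <- numeric(nlog)
  log_rd <- numeric(nlog); log_u <- numeric(nlog)
  li <- 0L
  for (i in seq_len(nsteps)) {
    t <- (i - 1) * dt
    sp <- sch$setpoint_C[findInterval(t, sch$start_s)]
    if ((i - 1L) %% ctrl_every == 0L) {
      reading <- thermistor_model(state[1], noise_sd_C = noise_sd_C)
      upd <- controller_update(cfg, sp, reading, cs)
      u <- upd$u; cs <- upd$state
    }
    state <- plant_step(state, u, params, dt)
    if (i %% log_every == 0L) {
      li <- li + 1L
      log_t[li] <- t + dt; log_sp[li] <- sp; log_rd[li] <- reading; log_u[li] <- u
    }
  }
  structure(data.frame(time_s = log_t[1:li], setpoint_C = log_sp[1:li],
                       reading_C = log_rd[1:li], drive = log_u[1:li]),
            class = c("thermo_log", "data.frame"))
}

#' Write a thermo log as CSV under the rig output layout
#' @param log a `thermo_log`.
#' @param root output root; the file goes under
#'   `FlyPi_output/temperature_logging/`.
#' @param clock time source for the run directory name.
#' @return the CSV path.
#' @export
write_thermo_log <- function(log, root, clock = Sys.time) {
  dir <- make_output_path(root, "temperature_logging", clock)
  path <- file.path(dir, "thermo_log.csv")
  write.csv(as.data.frame(log), path, row.names = FALSE)
  path
}

#' Loop-performance statistics from a thermo log
#'
#' Splits the log into held epochs at setpoint changes and reports, per
#' transition: the 10-90% ramp rate (`0.8 * |step| / (t90 - t10)`, step =
#' new setpoint minus the temperature at the switch), the hold standard
#' deviation over samples after settling (first entry into the
#' `setpoint +- hysteresis` band plus `settle_extra_s`), the overshoot
#' beyond the setpoint in the step direction, and the epoch min/max.
#'
#' @param log a `thermo_log`.
#' @param hysteresis_C settling band half-width (default 0.25 degC, the
#'   default controller band).
#' @param settle_extra_s extra settling margin after the first band entry
#'   (default 10 s).
#' @return list with `epochs` (per-epoch data.frame), `mean_ramp_C_per_s`,
#'   `max_hold_sd_C`, `min_C`, `max_C`.
#' @export
loop_stats <- function(log, hysteresis_C = 0.25, settle_extra_s = 10) {
  sp <- log$setpoint_C
  changes <- c(1L, which(diff(sp) != 0) + 1L)
  bounds <- c(changes, nrow(log) + 1L)
  rows <- NULL
  for (e in seq_along(changes)) {
    i0 <- bounds[e]; i1 <- bounds[e + 1] - 1L
    seg <- log[i0:i1, ]
    target <- seg$setpoint_C[1]
    start_T <- if (i0 == 1L) seg$reading_C[1] else log$reading_C[i0 - 1L]
    step <- target - start_T
    ramp <- NA_real_
    if (abs(step) > 0.5) {
      l10 <- start_T + 0.1 * step; l90 <- start_T + 0.9 * step
      t10 <- seg$time_s[which(if (step > 0) seg$reading_C >= l10 else seg$reading_C <= l10)[1]]
      t90 <- seg$time_s[which(if (step > 0) seg$reading_C >= l90 else seg$reading_C <= l90)[1]]
      if (!is.na(t10) && !is.na(t90) && t90 > t10)
        ramp <- 0.8 * abs(step) / (t90 - t10)
    }
    inband <- which(abs(seg$reading_C - target) <= hysteresis_C)
    hold_sd <- NA_real_; settled_from <- NA_real_
    if (length(inband)) {
      settled_from <- seg$time_s[inband[1]] + settle_extra_s
      hold <- seg$reading_C[seg$time_s >= settled_from]
      if (length(hold) >= 2) hold_sd <- sd(hold)
    }
    if (is.na(hold_sd) && is.na(ramp) && abs(step) > 0.5)
      warning("epoch ", e, " too short to settle")
    over <- if (step > 0) max(seg$reading_C) - target
            else if (step < 0) target - min(seg$reading_C) else NA_real_
    rows <- rbind(rows, data.frame(
      start_s = seg$time_s[1], setpoint_C = target, step_C = step,
      ramp_C_per_s = ramp, settled_from_s = settled_from,
      hold_sd_C = hold_sd, overshoot_C = max(0, over),
      min_C = min(seg$reading_C), max_C = max(seg$reading_C)))
  }
  list(epochs = rows,
       mean_ramp_C_per_s = mean(rows$ramp_C_per_s, na.rm = TRUE),
       max_hold_sd_C = if (all(is.na(rows$hold_sd_C))) NA_real_
                       else max(rows$hold_sd_C, na.rm = TRUE),
       min_C = min(rows$min_C), max_C = max(rows$max_C))
}

#' Steady-state temperature offsets at full drive
#'
#' Integrates the open-loop plant at `u = +1` and `u = -1` from ambient
#' until `|dT_surf/dt|` falls below `tol` and reports the attained
#' surface-temperature offsets from ambient.
#'
#' @param params a [thermo_params()].
#' @param dt integration step (default 0.05 s).
#' @param tol convergence tolerance on `|dT/dt|` (default 0.001 degC/s).
#' @param max_s integration cap (default 3600 s).
#' @return list with `heat_offset_C` (positive), `cool_offset_C`
#'   (negative) and `min_abs_offset_C`.
#' @export
steady_state_offsets <- function(params, dt = 0.05, tol = 0.001, max_s = 3600) {
  run <- function(u) {
    state <- c(params$ambient_C, params$ambient_C)
    prev <- state[1]
    for (i in seq_len(ceiling(max_s / dt))) {
      state <- plant_step(state, u, params, dt)
      if (i > 10 && abs(state[1] - prev) / dt < tol) break
      prev <- state[1]
    }
    state[1] - params$ambient_C
  }
  heat <- run(1); cool <- run(-1)
  list(heat_offset_C = heat, cool_offset_C = cool,
       min_abs_offset_C = min(abs(heat), abs(cool)))
}
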