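# Independent oracles used across test files.

# naive double-loop running-average time differential (reference semantics)
oracle_time_differential <- function(frames_list, k) {
  T <- length(frames_list)
  out <- vector("list", T - k)
  for (t in (k + 1):T) {
    acc <- frames_list[[t - k]] * 0
    for (j in (t - k):(t - 1)) acc <- acc + frames_list[[j]]
    out[[t - k]] <- frames_list[[t]] - acc / k
  }
  out
}

# analytic pixel-integrated Gaussian bead render (duplicates the model from
# first principles: product of per-axis integrals of a unit-peak Gaussian)
oracle_bead_render <- function(h, w, cx, cy, sigma, peak) {
  img <- matrix(0, h, w)
  for (i in seq_along(cx)) {
    fx <- sigma * sqrt(2 * pi) *
      (pnorm((0:(w - 1) + 0.5 - cx[i]) / sigma) -
       pnorm((0:(w - 1) - 0.5 - cx[i]) / sigma))
    fy <- sigma * sqrt(2 * pi) *
      (pnorm((0:(h - 1) + 0.5 - cy[i]) / sigma) -
       pnorm((0:(h - 1) - 0.5 - cy[i]) / sigma))
    img <- img + peak[i] * outer(fy, fx)
  }
  img
}

# square-wave trace: `reps` pulses of `on_s` at level `hi`, separated by
# `off_s` at level `lo`, sampled at `rate` Hz starting at the first onset
square_wave_trace <- function(reps = 5, on_s = 1, off_s = 2, rate = 10,
                              hi = 1, lo = 0, lead_s = 1) {
  total <- lead_s + reps * (on_s + off_s)
  t <- seq(0, total - 1 / rate, by = 1 / rate)
  v <- rep(lo, length(t))
  for (r in seq_len(reps)) {
    t0 <- lead_s + (r - 1) * (on_s + off_s)
    v[t >= t0 & t < t0 + on_s] <- hi
  }
  new_trace(t, v)
}

# default four-epoch 15/35 degC switching schedule used by the thermal tests
fig_schedule <- function() data.frame(start_s = c(0, 300, 600, 900),
                                      setpoint_C = c(15, 35, 15, 35))
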