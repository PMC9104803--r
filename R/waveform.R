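# Biphasic pulse-train scheduling and boost-converter voltage dynamics.
#
# All schedule timing is carried in integer microseconds; doubles represent
# integers exactly far beyond the ranges used here, so timing assertions are
# exact (no float drift across hours of simulated stimulation).

#' Stimulation parameters for one channel
#'
#' Bundles the per-channel stimulus settings of an FES channel: modulation
#' frequency, per-phase pulse duration, and the boost duty cycle that sets the
#' stimulus amplitude.
#'
#' @param channel_id Small positive integer identifying the channel.
#' @param frequency_hz Modulation frequency in Hz. Must be positive and such
#'   that the period is a whole number of microseconds (e.g. 50, 25, 100 Hz);
#'   schedules are represented on a 1 microsecond grid so that timing
#'   invariants hold exactly.
#' @param pulse_duration_us Duration of each phase in microseconds (a biphasic
#'   cycle contains one positive and one negative phase of this width). Must
#'   be a positive whole number of microseconds and satisfy
#'   `2 * pulse_duration_us < period`.
#' @param amplitude_duty_pct Boost duty cycle in percent, in \[0, 100\].
#'
#' @return An object of class `stim_params`.
#' @examples
#' stim_params(1, frequency_hz = 50, pulse_duration_us = 200,
#'             amplitude_duty_pct = 5)
#' @export
stim_params <- function(channel_id, frequency_hz, pulse_duration_us,
                        amplitude_duty_pct) {
  p <- structure(
    list(channel_id = as.integer(channel_id),
         frequency_hz = as.numeric(frequency_hz),
         pulse_duration_us = as.numeric(pulse_duration_us),
         amplitude_duty_pct = as.numeric(amplitude_duty_pct)),
    class = "stim_params")
  validate_stim_params(p)
  p
}

validate_stim_params <- function(p) {
  problems <- character(0)
  if (!is.finite(p$frequency_hz) || p$frequency_hz <= 0)
    problems <- c(problems, "frequency_hz must be > 0")
  if (!is.finite(p$pulse_duration_us) || p$pulse_duration_us <= 0)
    problems <- c(problems, "pulse_duration_us must be > 0")
  if (p$pulse_duration_us != round(p$pulse_duration_us))
    problems <- c(problems, "pulse_duration_us must be a whole number of microseconds")
  period_us <- 1e6 / p$frequency_hz
  if (abs(period_us - round(period_us)) > 1e-6)
    problems <- c(problems,
                  "frequency_hz must yield a whole-microsecond period (e.g. 50, 25, 100 Hz)")
  if (length(problems) == 0 && 2 * p$pulse_duration_us >= round(period_us))
    problems <- c(problems, sprintf(
      "timing violation: 2 * pulse_duration (%g us) must be < period (%g us)",
      2 * p$pulse_duration_us, round(period_us)))
  if (!is.finite(p$amplitude_duty_pct) ||
      p$amplitude_duty_pct < 0 || p$amplitude_duty_pct > 100)
    problems <- c(problems, "amplitude_duty_pct must lie in [0, 100]")
  if (length(problems) > 0)
    stop("invalid stimulation parameters: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(p)
}

#' Build a biphasic pulse schedule
#'
#' Lays out charge-balanced biphasic cycles on a 1 microsecond grid: each cycle
#' is one positive phase immediately followed by one negative phase of equal
#' width, then a pause filling the remainder of the period (at 50 Hz with
#' 200 us phases: 0.2 + 0.2 + 19.6 = 20 ms). The first phase of every cycle is
#' positive by convention. Cycles that would be truncated mid-phase at the
#' duration boundary are dropped entirely, so every emitted cycle is complete.
#'
#' @param params A [stim_params()] object.
#' @param duration_s Requested schedule length in seconds (>= 0).
#'
#' @return An object of class `pulse_schedule`: a list with `channel_id`,
#'   `events` (data.frame with `start_s`, `end_s`, `polarity` in \{+1, -1\},
#'   plus exact `start_us`, `end_us` columns), `total_duration_s`, and the
#'   generating parameters.
#' @examples
#' sched <- make_schedule(stim_params(1, 50, 200, 5), duration_s = 0.1)
#' nrow(sched$events) / 2  # complete biphasic cycles
#' @export
make_schedule <- function(params, duration_s) {
  validate_stim_params(params)
  stopifnot(is.numeric(duration_s), length(duration_s) == 1, duration_s >= 0)
  period_us <- round(1e6 / params$frequency_hz)
  phase_us <- params$pulse_duration_us
  duration_us <- floor(duration_s * 1e6)

  # cycle k fits iff its second phase ends inside the requested duration
  n_cycles <- 0
  if (duration_us >= 2 * phase_us)
    n_cycles <- floor((duration_us - 2 * phase_us) / period_us) + 1

  if (n_cycles == 0) {
    events <- data.frame(start_us = numeric(0), end_us = numeric(0),
                         polarity = numeric(0))
  } else {
    starts <- (seq_len(n_cycles) - 1) * period_us
    events <- data.frame(
      start_us = as.vector(rbind(starts, starts + phase_us)),
      end_us   = as.vector(rbind(starts + phase_us, starts + 2 * phase_us)),
      polarity = rep(c(1, -1), times = n_cycles))
  }
  events$start_s <- events$start_us * 1e-6
  events$end_s <- events$end_us * 1e-6

  structure(list(channel_id = params$channel_id,
                 events = events,
                 total_duration_s = duration_s,
                 params = params),
            class = "pulse_schedule")
}

#' Measure timing statistics of a pulse schedule
#'
#' Recovers period, frequency and phase width from the event list itself (not
#' from the generating parameters) and flags any cycle whose spacing or phase
#' width deviates from the first cycle's -- the software analogue of checking
#' an oscilloscope trace for a stable 20 ms period and 200 us phases.
#'
#' @param schedule A [make_schedule()] result with at least 2 cycles.
#' @return An object of class `waveform_stats`: list with `frequency_hz`,
#'   `period_ms`, `phase_width_us`, `n_cycles`, and `deviant_cycles` (indices
#'   of cycles whose spacing or width differs from nominal; empty when the
#'   schedule is clean).
#' @export
schedule_stats <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  ev <- schedule$events
  pos <- ev[ev$polarity > 0, , drop = FALSE]
  if (nrow(pos) < 2)
    stop("insufficient data: at least 2 cycles are required to measure a period",
         call. = FALSE)
  spacings_us <- diff(pos$start_us)
  widths_us <- ev$end_us - ev$start_us
  period_us <- spacings_us[1]
  phase_us <- widths_us[1]
  bad_spacing <- which(spacings_us != period_us)
  bad_width <- unique(ceiling(which(widths_us != phase_us) / 2))
  structure(list(frequency_hz = 1e6 / period_us,
                 period_ms = period_us / 1000,
                 phase_width_us = phase_us,
                 n_cycles = nrow(pos),
                 deviant_cycles = sort(unique(c(bad_spacing + 1, bad_width)))),
            class = "waveform_stats")
}

#' Boost-converter state
#'
#' @param voltage_v Output voltage in volts; initialized at the 7 V input rail.
#' @param duty_pct Current duty command in percent.
#' @return An object of class `boost_state`.
#' @export
boost_state <- function(voltage_v = 7, duty_pct = 0) {
  stopifnot(voltage_v >= 0)
  structure(list(voltage_v = voltage_v, duty_pct = duty_pct),
            class = "boost_state")
}

#' Advance the boost-converter voltage by one time step
#'
#' First-order relaxation toward the ideal continuous-conduction boost target
#' `V_in / (1 - duty/100)`, clamped at `v_max`; `duty = 100` maps directly to
#' `v_max`. Charging is faster than discharging (`tau_up < tau_down`), the
#' capacitor-bank asymmetry observed on the real converter. The exact
#' exponential discretization is used, so the step is accurate for any `dt`.
#'
#' @param state A [boost_state()].
#' @param duty_pct Duty command in percent; values outside \[0, 100\] are
#'   clamped with a warning.
#' @param dt Time step in seconds (> 0).
#' @param v_in Input rail voltage (default 7 V).
#' @param v_max Output ceiling (default 100 V).
#' @param tau_up,tau_down Rise / fall time constants in seconds
#'   (defaults 10 ms and 50 ms; `tau_up < tau_down`).
#' @return The updated `boost_state`.
#' @export
boost_step <- function(state, duty_pct, dt, v_in = 7, v_max = 100,
                       tau_up = 0.010, tau_down = 0.050) {
  stopifnot(inherits(state, "boost_state"), dt > 0)
  if (duty_pct < 0 || duty_pct > 100) {
    warning("duty_pct clamped to [0, 100]", call. = FALSE)
    duty_pct <- min(max(duty_pct, 0), 100)
  }
  target <- if (duty_pct >= 100) v_max else min(v_in / (1 - duty_pct / 100), v_max)
  tau <- if (target >= state$voltage_v) tau_up else tau_down
  v <- target + (state$voltage_v - target) * exp(-dt / tau)
  boost_state(voltage_v = min(max(v, 0), v_max), duty_pct = duty_pct)
}

#' Render a schedule as a sampled voltage trace
#'
#' Software stand-in for an oscilloscope: +V during positive phases, -V during
#' negative phases, 0 in the pauses. Sampling below two samples per phase is
#' rejected as undersampling (200 us phases need at least 10 kHz).
#'
#' @param schedule A [make_schedule()] result.
#' @param voltage_v Amplitude in volts applied to each phase.
#' @param sample_rate_hz Sampling rate of the trace.
#' @return A list with `time_s` and `voltage_v` numeric vectors covering
#'   `[0, total_duration_s)`.
#' @export
render_waveform <- function(schedule, voltage_v, sample_rate_hz) {
  stopifnot(inherits(schedule, "pulse_schedule"), voltage_v >= 0)
  ev <- schedule$events
  if (nrow(ev) > 0) {
    phase_s <- (ev$end_us[1] - ev$start_us[1]) * 1e-6
    if (sample_rate_hz * phase_s < 2)
      stop(sprintf(
        "undersampled: %g Hz gives fewer than 2 samples per %g us phase",
        sample_rate_hz, phase_s * 1e6), call. = FALSE)
  }
  n <- floor(schedule$total_duration_s * sample_rate_hz)
  t_us <- (seq_len(n) - 1) / sample_rate_hz * 1e6
  v <- numeric(n)
  if (nrow(ev) > 0 && n > 0) {
    idx <- findInterval(t_us, ev$start_us)  # half-open [start, end)
    inside <- idx > 0
    inside[inside] <- t_us[inside] < ev$end_us[idx[inside]]
    v[inside] <- voltage_v * ev$polarity[idx[inside]]
  }
  list(time_s = t_us * 1e-6, voltage_v = v)
}

#' Write / read a pulse schedule as CSV
#'
#' Columns: `channel`, `start_s`, `end_s`, `polarity`. Times are written in
#' microsecond-exact decimal seconds.
#'
#' @param schedule A `pulse_schedule`.
#' @param path File path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns a `pulse_schedule` (without generating parameters).
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  ev <- schedule$events
  utils::write.csv(
    data.frame(channel = rep(schedule$channel_id, nrow(ev)),
               start_s = sprintf("%.6f", ev$start_s),
               end_s = sprintf("%.6f", ev$end_s),
               polarity = ev$polarity),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("channel", "start_s", "end_s", "polarity") %in% names(d)))
  events <- data.frame(start_us = round(d$start_s * 1e6),
                       end_us = round(d$end_s * 1e6),
                       polarity = d$polarity)
  events$start_s <- events$start_us * 1e-6
  events$end_s <- events$end_us * 1e-6
  total <- if (nrow(events) > 0) max(events$end_s) else 0
  structure(list(channel_id = if (nrow(d) > 0) d$channel[1] else NA_integer_,
                 events = events, total_duration_s = total, params = NULL),
            class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  n <- sum(x$events$polarity > 0)
  cat(sprintf("<pulse_schedule> channel %s: %d biphasic cycle(s) over %g s\n",
              x$channel_id, n, x$total_duration_s))
  invisible(x)
}

#' @export
print.waveform_stats <- function(x, ...) {
  cat(sprintf(
    "<waveform_stats> %g Hz, period %g ms, phase %g us, %d cycles%s\n",
    x$frequency_hz, x$period_ms, x$phase_width_us, x$n_cycles,
    if (length(x$deviant_cycles)) sprintf(" (%d deviant!)",
                                          length(x$deviant_cycles)) else ""))
  invisible(x)
}
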