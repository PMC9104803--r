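# Discrete PID with conditional-integration anti-windup and hard output
# saturation: u = Kp*e + Ki*integral(e) + Kd*de/dt, clamped to [u_min, u_max].
# One instance per controlled degree of freedom.

#' PID gains and output limits
#'
#' Control-action units are signed boost duty-cycle percent: positive output
#' requests agonist stimulation, negative output antagonist stimulation, and
#' the limits bound how hard either muscle may be driven.
#'
#' @param kp Proportional gain, duty%% per degree (>= 0).
#' @param ki Integral gain, duty%% per degree-second (>= 0).
#' @param kd Derivative gain, duty%%-second per degree (>= 0; the reference
#'   controllers are PI, `kd = 0`).
#' @param u_min,u_max Signed output limits in duty%%, `u_min < u_max`.
#' @param derivative_tau Optional first-order derivative-filter time constant
#'   in seconds; 0 (the default) applies the derivative to the raw error,
#'   matching a firmware with no derivative filter.
#' @return An object of class `pid_gains`.
#' @examples
#' # reference sagittal (dorsiflexion / plantar flexion) controller
#' pid_gains(kp = 8.2, ki = 3.8, kd = 0, u_min = -14, u_max = 10)
#' @export
pid_gains <- function(kp, ki, kd = 0, u_min = -Inf, u_max = Inf,
                      derivative_tau = 0) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, u_min < u_max, derivative_tau >= 0)
  structure(list(kp = kp, ki = ki, kd = kd, u_min = u_min, u_max = u_max,
                 derivative_tau = derivative_tau),
            class = "pid_gains")
}

#' Fresh PID state
#'
#' Integrator, previous error (0 after reset, so the first derivative step is
#' taken against 0), last emitted output and saturation flag.
#'
#' @return An object of class `pid_state`, all memory zeroed.
#' @export
pid_state <- function() {
  structure(list(integral = 0, prev_error = 0, last_output = 0,
                 saturated = FALSE, deriv_filtered = 0),
            class = "pid_state")
}

#' Reset a PID state
#'
#' Zeroes the integrator, previous error, output memory and saturation flag.
#' Idempotent.
#'
#' @param state A `pid_state` (ignored except for class checking; kept in the
#'   signature so call sites read naturally).
#' @return A fresh [pid_state()].
#' @export
pid_reset <- function(state) {
  stopifnot(inherits(state, "pid_state"))
  pid_state()
}

#' One PID update
#'
#' Backward-Euler discretization: the integral candidate `I + e*dt` enters the
#' same step's output, so for constant error `e`, `kd = 0` and no saturation
#' the output after `n` steps is exactly `kp*e + ki*e*n*dt`.
#'
#' Anti-windup is conditional integration with the standard clamping
#' predicate: the integral update is discarded whenever the unsaturated output
#' exceeds a limit *and* the error pushes further into that limit
#' (`u' > u_max` with `e > 0`, or `u' < u_min` with `e < 0`). Integration
#' resumes as soon as the error reverses or the output re-enters the interior,
#' so the integrator never winds up while the actuator is pinned.
#'
#' @param gains A [pid_gains()] object.
#' @param state A [pid_state()].
#' @param error Setpoint minus measurement, degrees.
#' @param dt Time step in seconds (> 0).
#' @param anti_windup Set `FALSE` for a naive always-integrating PID (used as
#'   the comparison arm in windup-recovery tests).
#' @return A list with `action` (list of `u`, clamped to the limits, and
#'   `saturated` flag) and `state` (the updated `pid_state`).
#' @export
pid_step <- function(gains, state, error, dt, anti_windup = TRUE) {
  stopifnot(inherits(gains, "pid_gains"), inherits(state, "pid_state"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be > 0", call. = FALSE)
  stopifnot(is.finite(error))

  deriv_raw <- (error - state$prev_error) / dt
  if (gains$derivative_tau > 0) {
    beta <- dt / (gains$derivative_tau + dt)
    deriv <- state$deriv_filtered + beta * (deriv_raw - state$deriv_filtered)
  } else {
    deriv <- deriv_raw
  }

  i_cand <- state$integral + error * dt
  u_cand <- gains$kp * error + gains$ki * i_cand + gains$kd * deriv

  windup <- anti_windup &&
    ((u_cand > gains$u_max && error > 0) || (u_cand < gains$u_min && error < 0))
  if (windup) {
    integral <- state$integral  # frozen
    u_unsat <- gains$kp * error + gains$ki * integral + gains$kd * deriv
  } else {
    integral <- i_cand
    u_unsat <- u_cand
  }

  u <- min(max(u_unsat, gains$u_min), gains$u_max)
  saturated <- u != u_unsat

  new_state <- structure(
    list(integral = integral, prev_error = error, last_output = u,
         saturated = saturated, deriv_filtered = deriv),
    class = "pid_state")
  list(action = list(u = u, saturated = saturated), state = new_state)
}
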