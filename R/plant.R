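# Synthetic ankle plant: two uncoupled rotational degrees of freedom driven by
# stimulation duty cycles through a deadzone/saturation recruitment map with
# first-order activation lag, plus an IMU emulator strapped to the foot.
#
# Per degree of freedom: J*theta'' = tau_act + K*(rest - theta) - B*omega + d,
# semi-implicit Euler at a 1 ms internal step, hard stops with velocity
# zeroing. Angles are degrees at the interface, radians inside the integrator.

#' Reference ankle-plant parameter set
#'
#' Deterministic reference fixture: the documented synthetic ankle under which
#' the shipped PI controllers reach the protocol ranges of motion. Values are
#' desk-scale but physiologically plausible for a foot about the ankle:
#' sagittal inertia 0.02 kg m^2, frontal 0.015 kg m^2; passive stiffness
#' 2 N m/rad returning the joint to neutral; damping chosen overdamped
#' (slowest mechanical pole about 0.3-0.4 s). Each channel produces up to
#' 2 N m at full recruitment; the recruitment map has a 3%% motor threshold
#' and saturates at 14%% duty, so the controller output limits (max magnitude
#' 14) span the full recruitment range. Activation lag 80 ms emulates calcium
#' dynamics. Hard stops at +/-30 deg (sagittal) and +/-25 deg (frontal)
#' bracket the protocol targets. Measurement noise defaults: accelerometer
#' sigma 0.02 g, gyro sigma 0.5 deg/s; disturbance torque off by default (set
#' `disturbance_sigma_nm` to emulate subject reactions to stimulation).
#'
#' Channel mapping (matches the default electrode placement): 1 = dorsiflexion
#' agonist, 2 = plantar flexion, 3 = inversion agonist, 4 = eversion.
#'
#' @param noise_free If `TRUE`, zero all noise and disturbance sigmas
#'   (convenient for oracles and decoupling tests).
#' @return An object of class `ankle_plant_params`.
#' @export
default_plant <- function(noise_free = FALSE) {
  p <- structure(list(
    dofs = list(
      sagittal = list(J = 0.02, B = 0.8, K = 2.0, rest_deg = 0,
                      limits_deg = c(-30, 30)),
      frontal = list(J = 0.015, B = 0.6, K = 2.0, rest_deg = 0,
                     limits_deg = c(-25, 25))),
    channels = list(
      `1` = list(dof = "sagittal", sign = +1, max_torque_nm = 2.0,
                 duty_threshold_pct = 3, duty_saturation_pct = 14,
                 activation_tau_s = 0.08),
      `2` = list(dof = "sagittal", sign = -1, max_torque_nm = 2.0,
                 duty_threshold_pct = 3, duty_saturation_pct = 14,
                 activation_tau_s = 0.08),
      `3` = list(dof = "frontal", sign = +1, max_torque_nm = 2.0,
                 duty_threshold_pct = 3, duty_saturation_pct = 14,
                 activation_tau_s = 0.08),
      `4` = list(dof = "frontal", sign = -1, max_torque_nm = 2.0,
                 duty_threshold_pct = 3, duty_saturation_pct = 14,
                 activation_tau_s = 0.08)),
    noise = list(accel_sigma_g = 0.02, gyro_sigma_dps = 0.5,
                 disturbance_sigma_nm = 0)),
    class = "ankle_plant_params")
  if (noise_free)
    p$noise <- list(accel_sigma_g = 0, gyro_sigma_dps = 0,
                    disturbance_sigma_nm = 0)
  validate_plant_params(p)
  p
}

validate_plant_params <- function(p) {
  stopifnot(inherits(p, "ankle_plant_params"))
  for (nm in names(p$dofs)) {
    d <- p$dofs[[nm]]
    if (!(d$J > 0 && d$B > 0 && d$K > 0))
      stop(sprintf("plant dof '%s': J, B, K must all be > 0", nm), call. = FALSE)
    if (!(d$limits_deg[1] < d$rest_deg && d$rest_deg < d$limits_deg[2]))
      stop(sprintf("plant dof '%s': angle limits must bracket rest_deg", nm),
           call. = FALSE)
  }
  for (nm in names(p$channels)) {
    ch <- p$channels[[nm]]
    if (!(ch$duty_threshold_pct >= 0 &&
          ch$duty_threshold_pct < ch$duty_saturation_pct &&
          ch$duty_saturation_pct <= 100))
      stop(sprintf("channel %s: need 0 <= threshold < saturation <= 100", nm),
           call. = FALSE)
    if (!(ch$activation_tau_s > 0 && ch$max_torque_nm >= 0))
      stop(sprintf("channel %s: bad activation_tau_s or max_torque_nm", nm),
           call. = FALSE)
    if (!ch$dof %in% names(p$dofs))
      stop(sprintf("channel %s: unknown dof '%s'", nm, ch$dof), call. = FALSE)
  }
  invisible(p)
}

#' Initial plant state
#'
#' @param params An `ankle_plant_params` object.
#' @return An object of class `ankle_plant_state`: per-dof angle (deg) and
#'   angular velocity (deg/s) at rest, per-channel activation 0.
#' @export
plant_state <- function(params = default_plant()) {
  validate_plant_params(params)
  angles <- vapply(params$dofs, function(d) d$rest_deg, numeric(1))
  structure(list(
    angle_deg = angles,
    velocity_dps = stats::setNames(numeric(length(params$dofs)),
                                   names(params$dofs)),
    activation = stats::setNames(numeric(length(params$channels)),
                                 names(params$channels))),
    class = "ankle_plant_state")
}

#' Static recruitment map: duty cycle to activation target
#'
#' Models the motor threshold (deadzone) and recruitment saturation of
#' electrically stimulated muscle: 0 below the threshold duty, 1 at or above
#' the saturation duty, linear ramp in between.
#'
#' @param duty_pct Duty cycle in \[0, 100\] (vectorized).
#' @param channel One channel entry of an `ankle_plant_params` (a list with
#'   `duty_threshold_pct` and `duty_saturation_pct`).
#' @return Activation target(s) in \[0, 1\].
#' @examples
#' ch <- default_plant()$channels[["1"]]
#' recruitment(c(0, 3, 8.5, 14, 50), ch)  # 0, 0, 0.5, 1, 1
#' @export
recruitment <- function(duty_pct, channel) {
  stopifnot(all(duty_pct >= 0), all(duty_pct <= 100))
  lo <- channel$duty_threshold_pct
  hi <- channel$duty_saturation_pct
  pmin(pmax((duty_pct - lo) / (hi - lo), 0), 1)
}

#' Advance the plant by one control interval
#'
#' Subdivides `dt` into internal semi-implicit Euler substeps of at most 1 ms
#' (stability without an adaptive solver). Per substep: channel activations
#' relax toward their recruitment targets with their activation time
#' constants; net joint torque is the signed sum of activation x max torque
#' over the dof's channels, plus passive stiffness toward rest, minus viscous
#' damping, plus an optional Gaussian disturbance torque; velocities update
#' before positions; angles are clipped at the hard stops with the outward
#' velocity zeroed.
#'
#' Randomness (the disturbance) is drawn from R's global RNG: seed the
#' session, not the plant.
#'
#' @param params An `ankle_plant_params`.
#' @param state An `ankle_plant_state`.
#' @param command A named duty vector (percent, names = channel ids), e.g. a
#'   [route_action()] / [merge_commands()] result. Missing channels are held
#'   at zero duty.
#' @param dt Control interval in seconds; must satisfy `0 < dt <= 0.01`.
#' @return The updated `ankle_plant_state`.
#' @export
plant_step <- function(params, state, command, dt) {
  stopifnot(inherits(params, "ankle_plant_params"),
            inherits(state, "ankle_plant_state"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0 || dt > 0.01)
    stop("unstable dt: plant_step requires 0 < dt <= 0.01 s", call. = FALSE)
  duties <- stats::setNames(numeric(length(params$channels)),
                            names(params$channels))
  if (length(command) > 0) {
    cmd <- unclass(command)
    stopifnot(!is.null(names(cmd)), all(names(cmd) %in% names(duties)),
              all(cmd >= 0), all(cmd <= 100))
    duties[names(cmd)] <- cmd
  }

  n_sub <- max(1L, ceiling(dt / 0.001))
  h <- dt / n_sub
  deg2rad <- pi / 180

  act <- state$activation
  theta <- state$angle_deg * deg2rad
  omega <- state$velocity_dps * deg2rad
  dist_sigma <- params$noise$disturbance_sigma_nm

  # per-channel precomputation
  ch_names <- names(params$channels)
  targets <- vapply(ch_names, function(nm)
    recruitment(duties[[nm]], params$channels[[nm]]), numeric(1))
  relax <- vapply(ch_names, function(nm)
    1 - exp(-h / params$channels[[nm]]$activation_tau_s), numeric(1))
  tq_sign <- vapply(ch_names, function(nm)
    params$channels[[nm]]$sign * params$channels[[nm]]$max_torque_nm,
    numeric(1))
  ch_dof <- vapply(ch_names, function(nm) params$channels[[nm]]$dof,
                   character(1))

  dof_names <- names(params$dofs)
  J <- vapply(params$dofs, `[[`, numeric(1), "J")
  B <- vapply(params$dofs, `[[`, numeric(1), "B")
  K <- vapply(params$dofs, `[[`, numeric(1), "K")
  rest <- vapply(params$dofs, `[[`, numeric(1), "rest_deg") * deg2rad
  lo <- vapply(params$dofs, function(d) d$limits_deg[1], numeric(1)) * deg2rad
  hi <- vapply(params$dofs, function(d) d$limits_deg[2], numeric(1)) * deg2rad

  for (s in seq_len(n_sub)) {
    act <- act + relax * (targets - act)
    tau_act <- vapply(dof_names, function(dn)
      sum((act * tq_sign)[ch_dof == dn]), numeric(1))
    dist <- if (dist_sigma > 0)
      stats::rnorm(length(dof_names), 0, dist_sigma) else 0
    torque <- tau_act + K * (rest - theta) - B * omega + dist
    omega <- omega + h * torque / J
    theta <- theta + h * omega
    at_hi <- theta > hi
    at_lo <- theta < lo
    theta[at_hi] <- hi[at_hi]
    theta[at_lo] <- lo[at_lo]
    omega[at_hi & omega > 0] <- 0
    omega[at_lo & omega < 0] <- 0
  }

  structure(list(angle_deg = theta / deg2rad,
                 velocity_dps = omega / deg2rad,
                 activation = pmin(pmax(act, 0), 1)),
            class = "ankle_plant_state")
}

#' Emulate one IMU sample from the plant state
#'
#' The accelerometer reads the gravity direction in the sensor frame; the
#' synthetic mount is constructed so that `atan2(ax, az)` recovers the
#' sagittal angle and `atan2(ay, az)` the frontal angle exactly in the
#' noise-free case (the two tilt read-outs stay decoupled). The gyroscope
#' reads the true angular velocities (x = sagittal rate, y = frontal rate).
#' Gaussian noise with the configured sigmas is added per axis from R's
#' global RNG.
#'
#' @param state An `ankle_plant_state`.
#' @param params An `ankle_plant_params` (for the noise sigmas).
#' @param timestamp_s Sample time stamp in seconds.
#' @return An [imu_sample()].
#' @export
synth_imu <- function(state, params, timestamp_s) {
  stopifnot(inherits(state, "ankle_plant_state"),
            inherits(params, "ankle_plant_params"))
  deg2rad <- pi / 180
  ts <- tan(state$angle_deg[["sagittal"]] * deg2rad)
  tf <- tan(state$angle_deg[["frontal"]] * deg2rad)
  az <- 1 / sqrt(1 + ts^2 + tf^2)
  accel <- c(az * ts, az * tf, az)
  gyro <- c(state$velocity_dps[["sagittal"]], state$velocity_dps[["frontal"]], 0)
  ns <- params$noise
  if (ns$accel_sigma_g > 0) accel <- accel + stats::rnorm(3, 0, ns$accel_sigma_g)
  if (ns$gyro_sigma_dps > 0) gyro <- gyro + stats::rnorm(3, 0, ns$gyro_sigma_dps)
  imu_sample(timestamp_s, accel, gyro)
}

#' Total mechanical energy of the plant
#'
#' Kinetic plus passive elastic energy, in joules. Useful for passivity
#' checks: with zero input and zero noise it is non-increasing.
#'
#' @param params An `ankle_plant_params`.
#' @param state An `ankle_plant_state`.
#' @return Energy in joules.
#' @export
plant_energy <- function(params, state) {
  deg2rad <- pi / 180
  e <- 0
  for (nm in names(params$dofs)) {
    d <- params$dofs[[nm]]
    th <- (state$angle_deg[[nm]] - d$rest_deg) * deg2rad
    om <- state$velocity_dps[[nm]] * deg2rad
    e <- e + 0.5 * d$J * om^2 + 0.5 * d$K * th^2
  }
  e
}
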