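# Joint-angle estimation from inertial data via a complementary filter.
#
# Sign convention (fixed across the package): sagittal angle positive for
# dorsiflexion, negative for plantar flexion; frontal angle positive for
# inversion, negative for eversion.

#' A single IMU sample
#'
#' @param timestamp_s Sample time in seconds.
#' @param accel Length-3 accelerometer reading in units of g (x, y, z).
#' @param gyro Length-3 gyroscope reading in degrees/second (x, y, z).
#'   Magnetometer/barometer channels of 10-DoF IMUs are simply not represented:
#'   only accelerometer and gyroscope feed the angle estimate.
#' @return An object of class `imu_sample`.
#' @export
imu_sample <- function(timestamp_s, accel, gyro) {
  stopifnot(length(accel) == 3, length(gyro) == 3,
            is.finite(timestamp_s), all(is.finite(accel)), all(is.finite(gyro)))
  structure(list(timestamp_s = timestamp_s,
                 accel = as.numeric(accel), gyro = as.numeric(gyro)),
            class = "imu_sample")
}

#' Joint angles of the ankle
#'
#' @param sagittal_deg Sagittal-plane angle in degrees (dorsiflexion positive,
#'   plantar flexion negative).
#' @param frontal_deg Frontal-plane angle in degrees (inversion positive,
#'   eversion negative).
#' @return An object of class `joint_angles`.
#' @export
joint_angles <- function(sagittal_deg, frontal_deg) {
  stopifnot(is.finite(sagittal_deg), is.finite(frontal_deg))
  structure(list(sagittal_deg = wrap_deg(sagittal_deg),
                 frontal_deg = wrap_deg(frontal_deg)),
            class = "joint_angles")
}

# wrap to [-180, 180); no unwrapping is needed at anatomical ranges
wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Gravity-referenced tilt from a single accelerometer reading
#'
#' Static inclination: `sagittal = atan2(a_x, a_z)` and
#' `frontal = atan2(a_y, a_z)`, in degrees. Invariant to uniform scaling of
#' the accelerometer vector, so miscalibrated gain does not bias the tilt.
#'
#' @param sample An [imu_sample()].
#' @return A [joint_angles()] object.
#' @examples
#' accel_inclination(imu_sample(0, c(0.5, 0, sqrt(3) / 2), c(0, 0, 0)))
#' @export
accel_inclination <- function(sample) {
  stopifnot(inherits(sample, "imu_sample"))
  a <- sample$accel
  if (sqrt(sum(a^2)) == 0)
    stop("undefined tilt: accelerometer magnitude is zero", call. = FALSE)
  joint_angles(sagittal_deg = atan2(a[1], a[3]) * 180 / pi,
               frontal_deg = atan2(a[2], a[3]) * 180 / pi)
}

#' Complementary-filter state
#'
#' @param angles Current [joint_angles()] estimate.
#' @param alpha Blend coefficient in \[0, 1\]: weight of the gyro-integrated
#'   (high-frequency) path; `1 - alpha` weights the accelerometer tilt
#'   (low-frequency) path. Default 0.98, intended for a 100 Hz update rate
#'   (equivalent low-pass time constant about 0.5 s).
#' @param last_timestamp_s Time of the last absorbed sample.
#' @return An object of class `filter_state`.
#' @export
filter_state <- function(angles = joint_angles(0, 0), alpha = 0.98,
                         last_timestamp_s = -Inf) {
  stopifnot(inherits(angles, "joint_angles"), alpha >= 0, alpha <= 1)
  structure(list(angles = angles, alpha = alpha,
                 last_timestamp_s = last_timestamp_s),
            class = "filter_state")
}

#' Absorb one IMU sample into the complementary filter
#'
#' Per axis: `angle <- alpha * (angle + gyro_rate * dt) +
#' (1 - alpha) * accel_tilt`. The sagittal axis integrates gyro x, the frontal
#' axis gyro y. `alpha = 0` reproduces the accelerometer tilt exactly;
#' `alpha = 1` is pure gyro integration.
#'
#' @param state A [filter_state()].
#' @param sample An [imu_sample()] with a timestamp strictly after the state's.
#' @return The updated `filter_state`.
#' @export
comp_filter_update <- function(state, sample) {
  stopifnot(inherits(state, "filter_state"), inherits(sample, "imu_sample"))
  if (sample$timestamp_s <= state$last_timestamp_s)
    stop("non-monotone timestamp: sample must be later than the filter state",
         call. = FALSE)
  dt <- sample$timestamp_s - state$last_timestamp_s
  tilt <- accel_inclination(sample)
  a <- state$alpha
  sag <- a * (state$angles$sagittal_deg + sample$gyro[1] * dt) +
    (1 - a) * tilt$sagittal_deg
  fro <- a * (state$angles$frontal_deg + sample$gyro[2] * dt) +
    (1 - a) * tilt$frontal_deg
  filter_state(angles = joint_angles(sag, fro), alpha = a,
               last_timestamp_s = sample$timestamp_s)
}

#' Estimate a joint-angle trajectory from an IMU stream
#'
#' Batch fold of [comp_filter_update()], initialized from the accelerometer
#' inclination of the first sample (so a static stream is a fixed point from
#' the very first output).
#'
#' @param samples A data.frame in the IMU CSV schema (`timestamp_s`, `ax_g`,
#'   `ay_g`, `az_g`, `gx_dps`, `gy_dps`, `gz_dps`) or a list of
#'   [imu_sample()] objects; at least one sample.
#' @param alpha Complementary-filter coefficient in \[0, 1\].
#' @return A data.frame with `timestamp_s`, `sagittal_deg`, `frontal_deg`,
#'   one row per sample.
#' @export
estimate_trajectory <- function(samples, alpha = 0.98) {
  if (is.data.frame(samples)) samples <- imu_stream_to_samples(samples)
  if (length(samples) == 0)
    stop("empty IMU stream: at least one sample is required", call. = FALSE)
  n <- length(samples)
  sag <- numeric(n); fro <- numeric(n); ts <- numeric(n)
  st <- filter_state(angles = accel_inclination(samples[[1]]), alpha = alpha,
                     last_timestamp_s = samples[[1]]$timestamp_s)
  ts[1] <- samples[[1]]$timestamp_s
  sag[1] <- st$angles$sagittal_deg
  fro[1] <- st$angles$frontal_deg
  if (n > 1) for (i in 2:n) {
    st <- comp_filter_update(st, samples[[i]])
    ts[i] <- samples[[i]]$timestamp_s
    sag[i] <- st$angles$sagittal_deg
    fro[i] <- st$angles$frontal_deg
  }
  data.frame(timestamp_s = ts, sagittal_deg = sag, frontal_deg = fro)
}

imu_stream_to_samples <- function(d) {
  need <- c("timestamp_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  stopifnot(all(need %in% names(d)))
  if (nrow(d) > 1 && any(diff(d$timestamp_s) <= 0))
    stop("IMU stream timestamps must be strictly increasing", call. = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    imu_sample(d$timestamp_s[i],
               c(d$ax_g[i], d$ay_g[i], d$az_g[i]),
               c(d$gx_dps[i], d$gy_dps[i], d$gz_dps[i])))
}

#' Write / read an IMU stream as CSV
#'
#' Schema: `timestamp_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps` (units in
#' the column names on purpose).
#'
#' @param stream A data.frame in the IMU schema.
#' @param path File path.
#' @export
write_imu_csv <- function(stream, path) {
  need <- c("timestamp_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  stopifnot(all(need %in% names(stream)))
  utils::write.csv(stream[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("timestamp_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  stopifnot(all(need %in% names(d)))
  d[, need]
}
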