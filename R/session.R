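# Closed-loop session: reference generation, the per-tick pipeline
# (sense -> fuse -> PID x2 -> route -> plant), step-response tuning support
# and tracking metrics.

#' Sequential ankle-protocol setpoint profile
#'
#' The proof-of-concept protocol: hold neutral, then inversion (+20 deg
#' frontal), eversion (-5 deg frontal, held for a shorter time), return to
#' neutral, then dorsiflexion (+20 deg sagittal) and plantar flexion (-20 deg
#' sagittal), ending at neutral. Targets are the protocol ranges of motion
#' (20 deg dorsiflexion/plantar flexion/inversion, 5 deg eversion); segment
#' durations are configuration, not physiology.
#'
#' @param neutral_s Initial / interleaved neutral hold, seconds (default 10).
#' @param hold_s Hold per movement segment, seconds (default 10).
#' @param eversion_hold_s Shorter eversion hold, seconds (default 5).
#' @param final_neutral_s Closing neutral hold, seconds (default 5).
#' @return A `setpoint_profile`: data.frame with `label`, `start_s`, `end_s`,
#'   `sagittal_ref_deg`, `frontal_ref_deg`; segments contiguous, starting at
#'   neutral (0, 0).
#' @export
protocol_setpoints <- function(neutral_s = 10, hold_s = 10,
                               eversion_hold_s = 5, final_neutral_s = 5) {
  stopifnot(neutral_s > 0, hold_s > 0, eversion_hold_s > 0, final_neutral_s > 0)
  seg <- data.frame(
    label = c("neutral", "inversion", "eversion", "neutral",
              "dorsiflexion", "plantar_flexion", "neutral"),
    duration_s = c(neutral_s, hold_s, eversion_hold_s, neutral_s,
                   hold_s, hold_s, final_neutral_s),
    sagittal_ref_deg = c(0, 0, 0, 0, 20, -20, 0),
    frontal_ref_deg = c(0, 20, -5, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  seg$end_s <- cumsum(seg$duration_s)
  seg$start_s <- seg$end_s - seg$duration_s
  structure(seg[, c("label", "start_s", "end_s",
                    "sagittal_ref_deg", "frontal_ref_deg")],
            class = c("setpoint_profile", "data.frame"))
}

validate_profile <- function(profile) {
  problems <- character(0)
  need <- c("start_s", "end_s", "sagittal_ref_deg", "frontal_ref_deg")
  if (!is.data.frame(profile) || !all(need %in% names(profile))) {
    return("profile must be a data.frame with start_s, end_s, sagittal_ref_deg, frontal_ref_deg")
  }
  if (nrow(profile) == 0) problems <- c(problems, "profile has no segments")
  else {
    if (any(profile$end_s <= profile$start_s))
      problems <- c(problems, "profile segments must have end_s > start_s")
    if (nrow(profile) > 1 &&
        any(abs(profile$start_s[-1] - profile$end_s[-nrow(profile)]) > 1e-9))
      problems <- c(problems, "profile segments must be contiguous")
    if (profile$sagittal_ref_deg[1] != 0 || profile$frontal_ref_deg[1] != 0)
      problems <- c(problems, "profile must start at neutral (0, 0)")
  }
  problems
}

#' Look up the reference angles at a time point
#'
#' @param profile A `setpoint_profile`.
#' @param t_s Time in seconds (vectorized). Times past the last segment hold
#'   its references.
#' @return data.frame with `sagittal_ref_deg`, `frontal_ref_deg`.
#' @export
setpoint_at <- function(profile, t_s) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0,
            all(c("start_s", "end_s", "sagittal_ref_deg",
                  "frontal_ref_deg") %in% names(profile)))
  idx <- findInterval(t_s, profile$start_s)
  idx[idx < 1] <- 1
  data.frame(sagittal_ref_deg = profile$sagittal_ref_deg[idx],
             frontal_ref_deg = profile$frontal_ref_deg[idx])
}

#' Default closed-loop session configuration
#'
#' Ships the reference tuning: sagittal PI (kp 8.2, ki 3.8, kd 0, limits
#' \[-14, 10\]) and frontal PI (kp 8.1, ki 3.2, kd 0, limits \[-12, 14\]);
#' stimulation at 50 Hz, 200 us phases, 5%% baseline duty on all four
#' channels; 100 Hz control/IMU rate; complementary-filter alpha 0.98;
#' channel pairs 1/2 (sagittal) and 3/4 (frontal); the sequential ankle
#' protocol as the setpoint profile; duty safety ceiling 100%%.
#'
#' @param seed RNG seed recorded in the config (all session randomness flows
#'   from it).
#' @return A `session_config` object.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    imu_rate_hz = 100,
    alpha = 0.98,
    seed = as.integer(seed),
    duty_ceiling_pct = 100,
    stimulation = lapply(1:4, function(ch)
      list(channel_id = ch, frequency_hz = 50, pulse_duration_us = 200,
           amplitude_duty_pct = 5)),
    pid_sagittal = list(kp = 8.2, ki = 3.8, kd = 0, u_min = -14, u_max = 10),
    pid_frontal = list(kp = 8.1, ki = 3.2, kd = 0, u_min = -12, u_max = 14),
    pairs = list(sagittal = list(agonist = 1, antagonist = 2),
                 frontal = list(agonist = 3, antagonist = 4)),
    profile = protocol_setpoints()),
    class = "session_config")
}

#' Validate a session configuration
#'
#' Collects *all* violations rather than stopping at the first, so a config
#' file can be fixed in one pass.
#'
#' @param config A `session_config` (or plain list with the same fields).
#' @param require_neutral_start Enforce that the profile starts at neutral
#'   (relaxed for step-response profiles, which step at `t = 0`).
#' @return Invisibly, the config; raises one aggregated error listing every
#'   violation otherwise.
#' @export
validate_session_config <- function(config, require_neutral_start = TRUE) {
  problems <- character(0)
  need <- c("imu_rate_hz", "alpha", "seed", "duty_ceiling_pct", "stimulation",
            "pid_sagittal", "pid_frontal", "pairs", "profile")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0)
    problems <- c(problems, paste0("missing field(s): ",
                                   paste(missing, collapse = ", ")))
  unknown <- setdiff(names(config), need)
  if (length(unknown) > 0)
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if ("imu_rate_hz" %in% names(config) &&
      (!num_ok(config$imu_rate_hz) || config$imu_rate_hz <= 0))
    problems <- c(problems, "imu_rate_hz must be a positive number")
  if ("alpha" %in% names(config) &&
      (!num_ok(config$alpha) || config$alpha < 0 || config$alpha > 1))
    problems <- c(problems, "alpha must lie in [0, 1]")
  if ("duty_ceiling_pct" %in% names(config) &&
      (!num_ok(config$duty_ceiling_pct) || config$duty_ceiling_pct <= 0))
    problems <- c(problems, "duty_ceiling_pct must be > 0")
  for (nm in c("pid_sagittal", "pid_frontal")) {
    if (!nm %in% names(config)) next
    g <- config[[nm]]
    gf <- c("kp", "ki", "kd", "u_min", "u_max")
    if (!all(gf %in% names(g))) {
      problems <- c(problems, sprintf("%s must have fields %s", nm,
                                      paste(gf, collapse = ", ")))
      next
    }
    if (any(vapply(g[c("kp", "ki", "kd")], function(x) x < 0, logical(1))))
      problems <- c(problems, sprintf("%s: gains must be >= 0", nm))
    if (!(g$u_min < g$u_max))
      problems <- c(problems, sprintf("%s: u_min must be < u_max", nm))
  }
  if ("stimulation" %in% names(config)) {
    for (s in config$stimulation) {
      ok <- tryCatch({
        stim_params(s$channel_id, s$frequency_hz, s$pulse_duration_us,
                    s$amplitude_duty_pct)
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) problems <- c(problems, ok)
    }
  }
  if ("pairs" %in% names(config)) {
    pr <- config$pairs
    if (!all(c("sagittal", "frontal") %in% names(pr))) {
      problems <- c(problems, "pairs must define sagittal and frontal")
    } else {
      chans <- unlist(lapply(pr, function(p) c(p$agonist, p$antagonist)))
      if (length(chans) != 4 || anyDuplicated(chans))
        problems <- c(problems,
                      "pairs must assign 4 distinct channels (each channel in exactly one pair)")
    }
  }
  if ("profile" %in% names(config)) {
    pp <- validate_profile(config$profile)
    if (!require_neutral_start)
      pp <- setdiff(pp, "profile must start at neutral (0, 0)")
    problems <- c(problems, pp)
  }
  if (length(problems) > 0)
    stop("invalid session config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

config_gains <- function(g) {
  pid_gains(kp = g$kp, ki = g$ki, kd = g$kd, u_min = g$u_min, u_max = g$u_max)
}

#' Run a closed-loop stimulation session
#'
#' Per control tick (tick rate = IMU rate): emulate an IMU sample from the
#' current plant state, update the complementary filter, compute the per-dof
#' error against the setpoint profile (error = setpoint - *estimated* angle:
#' the controller only sees the sensor path, as on the real device; the true
#' plant angle is logged for evaluation only), run the two PID controllers,
#' route each signed action to its agonist/antagonist pair, and advance the
#' plant. Fully deterministic given the config seed.
#'
#' A configurable per-channel duty ceiling (`duty_ceiling_pct`) aborts the
#' session if any commanded duty exceeds it -- the software analogue of the
#' pain-threshold stop rule of a human session.
#'
#' @param config A [default_config()]-style `session_config`.
#' @param plant_params An `ankle_plant_params` (default [default_plant()]).
#' @return A `session_log`: list with `header` (config, seed, plant params)
#'   and `records`, a data.frame with one row per tick: time, reference /
#'   estimated / true angles per dof, control actions and saturation flags,
#'   and per-channel duties.
#' @export
run_session <- function(config = default_config(),
                        plant_params = default_plant()) {
  validate_session_config(config)
  run_loop(config, plant_params)
}

# simulation loop; callers have validated config (modulo the neutral-start
# rule, which step profiles relax)
run_loop <- function(config, plant_params) {
  validate_plant_params(plant_params)
  set.seed(config$seed)

  rate <- config$imu_rate_hz
  dt <- 1 / rate
  if (dt > 0.01)
    stop("imu_rate_hz below 100 Hz would need a plant step > 10 ms; ",
         "use a rate >= 100 Hz", call. = FALSE)
  duration <- max(config$profile$end_s)
  n <- floor(duration * rate)

  gains_s <- config_gains(config$pid_sagittal)
  gains_f <- config_gains(config$pid_frontal)
  pair_s <- channel_pair(config$pairs$sagittal$agonist,
                         config$pairs$sagittal$antagonist, "sagittal")
  pair_f <- channel_pair(config$pairs$frontal$agonist,
                         config$pairs$frontal$antagonist, "frontal")

  st_plant <- plant_state(plant_params)
  st_pid_s <- pid_state()
  st_pid_f <- pid_state()
  st_filt <- NULL

  ch_ids <- as.character(c(pair_s$agonist_channel, pair_s$antagonist_channel,
                           pair_f$agonist_channel, pair_f$antagonist_channel))
  rec <- list(
    t_s = numeric(n),
    ref_sagittal_deg = numeric(n), ref_frontal_deg = numeric(n),
    est_sagittal_deg = numeric(n), est_frontal_deg = numeric(n),
    true_sagittal_deg = numeric(n), true_frontal_deg = numeric(n),
    u_sagittal = numeric(n), u_frontal = numeric(n),
    sat_sagittal = logical(n), sat_frontal = logical(n))
  duty_mat <- matrix(0, n, 4, dimnames = list(NULL, paste0("duty_ch", ch_ids)))

  refs <- setpoint_at(config$profile, (seq_len(n) - 1) * dt)

  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    smp <- synth_imu(st_plant, plant_params, t)
    if (is.null(st_filt)) {
      st_filt <- filter_state(angles = accel_inclination(smp),
                              alpha = config$alpha, last_timestamp_s = t)
    } else {
      st_filt <- comp_filter_update(st_filt, smp)
    }
    est <- st_filt$angles

    err_s <- refs$sagittal_ref_deg[i] - est$sagittal_deg
    err_f <- refs$frontal_ref_deg[i] - est$frontal_deg
    out_s <- pid_step(gains_s, st_pid_s, err_s, dt)
    out_f <- pid_step(gains_f, st_pid_f, err_f, dt)
    st_pid_s <- out_s$state
    st_pid_f <- out_f$state

    cmd <- merge_commands(route_action(out_s$action, pair_s),
                          route_action(out_f$action, pair_f))
    if (any(cmd > config$duty_ceiling_pct))
      stop(sprintf(
        "safety stop: commanded duty %.2f%% exceeds ceiling %.2f%% at t = %.2f s",
        max(cmd), config$duty_ceiling_pct, t), call. = FALSE)

    st_plant <- plant_step(plant_params, st_plant, cmd, dt)

    rec$t_s[i] <- t
    rec$ref_sagittal_deg[i] <- refs$sagittal_ref_deg[i]
    rec$ref_frontal_deg[i] <- refs$frontal_ref_deg[i]
    rec$est_sagittal_deg[i] <- est$sagittal_deg
    rec$est_frontal_deg[i] <- est$frontal_deg
    rec$true_sagittal_deg[i] <- st_plant$angle_deg[["sagittal"]]
    rec$true_frontal_deg[i] <- st_plant$angle_deg[["frontal"]]
    rec$u_sagittal[i] <- out_s$action$u
    rec$u_frontal[i] <- out_f$action$u
    rec$sat_sagittal[i] <- out_s$action$saturated
    rec$sat_frontal[i] <- out_f$action$saturated
    duty_mat[i, ] <- cmd[ch_ids]
  }

  records <- cbind(as.data.frame(rec), as.data.frame(duty_mat))
  structure(list(header = list(config = config, seed = config$seed,
                               plant_params = plant_params),
                 records = records),
            class = "session_log")
}

#' Step-response metrics for controller tuning
#'
#' Applies a single setpoint step from neutral on one degree of freedom,
#' simulates to settling, and summarizes the true-angle response: rise time
#' (10%% to 90%% of the step), overshoot beyond the target, settling time
#' (last exit from a band of max(2%% of the step, 0.5 deg) around the
#' target), and signed steady-state error (target minus the mean over the
#' final 10%% of the run).
#'
#' @param config A `session_config`; its profile is replaced by the step.
#' @param plant_params An `ankle_plant_params`.
#' @param dof `"sagittal"` or `"frontal"`.
#' @param step_deg Step magnitude in degrees; must lie within the plant's
#'   hard stops for that dof.
#' @param duration_s Simulation length (default 8 s).
#' @return A `step_metrics` list: `rise_time_s`, `overshoot_deg`,
#'   `steady_state_error_deg`, `settling_time_s`.
#' @export
step_response <- function(config = default_config(),
                          plant_params = default_plant(noise_free = TRUE),
                          dof = c("sagittal", "frontal"), step_deg,
                          duration_s = 8) {
  dof <- match.arg(dof)
  lims <- plant_params$dofs[[dof]]$limits_deg
  if (step_deg < lims[1] || step_deg > lims[2])
    stop(sprintf("step %g deg outside the plant's %s limits [%g, %g]",
                 step_deg, dof, lims[1], lims[2]), call. = FALSE)
  config$profile <- structure(
    data.frame(label = "step", start_s = 0, end_s = duration_s,
               sagittal_ref_deg = if (dof == "sagittal") step_deg else 0,
               frontal_ref_deg = if (dof == "frontal") step_deg else 0),
    class = c("setpoint_profile", "data.frame"))
  validate_session_config(config, require_neutral_start = FALSE)
  log <- run_loop(config, plant_params)
  y <- if (dof == "sagittal") log$records$true_sagittal_deg else
    log$records$true_frontal_deg
  t <- log$records$t_s
  if (step_deg == 0)
    return(structure(list(rise_time_s = 0, overshoot_deg = 0,
                          steady_state_error_deg = 0, settling_time_s = 0),
                     class = "step_metrics"))
  s <- sign(step_deg)
  yn <- y * s  # work in the step direction
  tgt <- abs(step_deg)
  t10 <- t[which(yn >= 0.1 * tgt)[1]]
  t90 <- t[which(yn >= 0.9 * tgt)[1]]
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
  overshoot <- max(0, max(yn) - tgt)
  tail_idx <- t >= 0.9 * duration_s
  ss_err <- step_deg - mean(y[tail_idx])
  band <- max(0.02 * tgt, 0.5)
  outside <- which(abs(yn - tgt) > band)
  settling <- if (length(outside) == 0) 0 else {
    last_out <- max(outside)
    if (last_out == length(t)) NA_real_ else t[last_out + 1]
  }
  structure(list(rise_time_s = rise, overshoot_deg = overshoot,
                 steady_state_error_deg = ss_err, settling_time_s = settling),
            class = "step_metrics")
}

#' Per-segment tracking summary of a session log
#'
#' For every segment of the profile the session was run with: the peak
#' achieved angle in the direction of the reference (signed; for neutral
#' segments the largest absolute excursion), the mean absolute tracking error
#' after a settling window, and the fraction of ticks with a saturated
#' control action, per degree of freedom.
#'
#' @param log A [run_session()] result.
#' @param settle_s Settling window skipped at the start of each segment
#'   before errors are averaged (default 2 s, clipped to half the segment).
#' @return A data.frame, one row per profile segment.
#' @export
tracking_metrics <- function(log, settle_s = 2) {
  stopifnot(inherits(log, "session_log"))
  prof <- log$header$config$profile
  r <- log$records
  out <- lapply(seq_len(nrow(prof)), function(k) {
    seg <- prof[k, ]
    in_seg <- r$t_s >= seg$start_s & r$t_s < seg$end_s
    if (!any(in_seg)) return(NULL)
    w <- min(settle_s, (seg$end_s - seg$start_s) / 2)
    settled <- in_seg & r$t_s >= seg$start_s + w
    peak_dir <- function(y, ref) {
      if (ref > 0) max(y) else if (ref < 0) min(y) else y[which.max(abs(y))]
    }
    data.frame(
      label = if ("label" %in% names(seg)) seg$label else as.character(k),
      start_s = seg$start_s, end_s = seg$end_s,
      sagittal_ref_deg = seg$sagittal_ref_deg,
      frontal_ref_deg = seg$frontal_ref_deg,
      peak_sagittal_deg = peak_dir(r$true_sagittal_deg[in_seg],
                                   seg$sagittal_ref_deg),
      peak_frontal_deg = peak_dir(r$true_frontal_deg[in_seg],
                                  seg$frontal_ref_deg),
      mae_sagittal_deg = mean(abs(seg$sagittal_ref_deg -
                                    r$true_sagittal_deg[settled])),
      mae_frontal_deg = mean(abs(seg$frontal_ref_deg -
                                   r$true_frontal_deg[settled])),
      frac_saturated_sagittal = mean(r$sat_sagittal[in_seg]),
      frac_saturated_frontal = mean(r$sat_frontal[in_seg]))
  })
  do.call(rbind, out)
}

#' Export a session log's records as CSV
#'
#' @param log A `session_log`.
#' @param path File path.
#' @export
write_session_csv <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  utils::write.csv(log$records, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d ticks over %.1f s (seed %d)\n",
              nrow(x$records), max(x$records$t_s), x$header$seed))
  invisible(x)
}

#' @export
print.step_metrics <- function(x, ...) {
  cat(sprintf(paste0("<step_metrics> rise %.3f s, overshoot %.2f deg, ",
                     "ss error %.3f deg, settling %.3f s\n"),
              x$rise_time_s, x$overshoot_deg, x$steady_state_error_deg,
              x$settling_time_s))
  invisible(x)
}
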