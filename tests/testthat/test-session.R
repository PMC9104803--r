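test_that("protocol profile follows the sequential movement order", {
  prof <- protocol_setpoints()
  expect_equal(prof$label,
               c("neutral", "inversion", "eversion", "neutral",
                 "dorsiflexion", "plantar_flexion", "neutral"))
  expect_equal(prof$start_s[1], 0)
  expect_equal(prof$sagittal_ref_deg[1], 0)
  expect_equal(prof$frontal_ref_deg[1], 0)
  # contiguous segments
  expect_equal(prof$start_s[-1], prof$end_s[-nrow(prof)])
  # eversion held for a shorter time than the other movements
  ev <- prof[prof$label == "eversion", ]
  expect_lt(ev$end_s - ev$start_s,
            prof$end_s[2] - prof$start_s[2])
  # reference look-ups
  expect_equal(setpoint_at(prof, 2)$sagittal_ref_deg, 0)
  expect_equal(setpoint_at(prof, 40)$sagittal_ref_deg, 20)   # dorsiflexion
  expect_equal(setpoint_at(prof, 22)$frontal_ref_deg, -5)    # eversion
  expect_equal(setpoint_at(prof, 12)$frontal_ref_deg, 20)    # inversion
})

test_that("config validation aggregates all violations", {
  cfg <- default_config()
  cfg$alpha <- 2
  cfg$pid_sagittal$u_min <- 11  # >= u_max
  cfg$bogus <- 1
  err <- tryCatch(validate_session_config(cfg), error = conditionMessage)
  expect_match(err, "alpha")
  expect_match(err, "pid_sagittal: u_min must be < u_max")
  expect_match(err, "unknown field")
})

test_that("zero gains leave the plant at rest", {
  cfg <- default_config()
  cfg$pid_sagittal[c("kp", "ki", "kd")] <- list(0, 0, 0)
  cfg$pid_frontal[c("kp", "ki", "kd")] <- list(0, 0, 0)
  cfg$profile <- protocol_setpoints(neutral_s = 2, hold_s = 2,
                                    eversion_hold_s = 1, final_neutral_s = 1)
  log <- run_session(cfg, quiet_plant())
  expect_true(all(log$records[, grepl("^duty_", names(log$records))] == 0))
  expect_true(all(abs(log$records$true_sagittal_deg) < 1))
  expect_true(all(abs(log$records$true_frontal_deg) < 1))
})

test_that("logged control actions always respect their limits", {
  cfg <- default_config(seed = 4)
  cfg$profile <- protocol_setpoints(neutral_s = 2, hold_s = 3,
                                    eversion_hold_s = 2, final_neutral_s = 1)
  log <- run_session(cfg, default_plant())  # noisy plant
  r <- log$records
  expect_true(all(r$u_sagittal >= -14 & r$u_sagittal <= 10))
  expect_true(all(r$u_frontal >= -12 & r$u_frontal <= 14))
  # selector mutual exclusion per pair at every tick
  expect_true(all(r$duty_ch1 * r$duty_ch2 == 0))
  expect_true(all(r$duty_ch3 * r$duty_ch4 == 0))
})

test_that("controller independence: frontal setpoints leave sagittal untouched", {
  base <- default_config()
  base$profile <- protocol_setpoints(neutral_s = 2, hold_s = 3,
                                     eversion_hold_s = 2, final_neutral_s = 1)
  moved <- base
  # frontal-only profile change
  moved$profile$frontal_ref_deg <- c(0, 10, -3, 0, 5, 5, 0)
  log_a <- run_session(base, quiet_plant())
  log_b <- run_session(moved, quiet_plant())
  expect_identical(log_a$records$true_sagittal_deg,
                   log_b$records$true_sagittal_deg)
  expect_identical(log_a$records$u_sagittal, log_b$records$u_sagittal)
  # and the frontal trajectory did actually change
  expect_false(identical(log_a$records$true_frontal_deg,
                         log_b$records$true_frontal_deg))
})

test_that("identical config and seed reproduce the log bit-for-bit", {
  cfg <- default_config(seed = 9)
  cfg$profile <- protocol_setpoints(neutral_s = 1, hold_s = 2,
                                    eversion_hold_s = 1, final_neutral_s = 1)
  expect_identical(run_session(cfg, default_plant())$records,
                   run_session(cfg, default_plant())$records)
})

test_that("safety ceiling aborts the session", {
  cfg <- default_config()
  cfg$duty_ceiling_pct <- 5
  expect_error(run_session(cfg, quiet_plant()), "safety stop")
})

test_that("step response metrics behave like a tuned PI", {
  expect_identical(step_response(step_deg = 0)$rise_time_s, 0)

  # reference PI on the reference plant: 10 deg step, offset eliminated
  m <- step_response(default_config(), quiet_plant(), "sagittal", 10)
  expect_lt(abs(m$steady_state_error_deg), 0.5)
  expect_gt(m$rise_time_s, 0)

  # P-only sweep: steady-state error strictly decreases with kp
  ss_err <- vapply(c(1, 2, 4), function(kp) {
    cfg <- default_config()
    cfg$pid_sagittal[c("kp", "ki", "kd")] <- list(kp, 0, 0)
    abs(step_response(cfg, quiet_plant(), "sagittal", 10,
                      duration_s = 6)$steady_state_error_deg)
  }, numeric(1))
  expect_true(all(diff(ss_err) < 0))

  # steps outside the hard stops are rejected
  expect_error(step_response(default_config(), quiet_plant(), "sagittal", 45),
               "outside")
})

test_that("tracking metrics summarize a perfect log with zero error", {
  cfg <- default_config()
  cfg$profile <- protocol_setpoints(neutral_s = 2, hold_s = 2,
                                    eversion_hold_s = 1, final_neutral_s = 1)
  log <- run_session(cfg, quiet_plant())
  # overwrite with a perfect synthetic log: angles identical to references
  log$records$true_sagittal_deg <- log$records$ref_sagittal_deg
  log$records$true_frontal_deg <- log$records$ref_frontal_deg
  m <- tracking_metrics(log)
  expect_equal(m$mae_sagittal_deg, rep(0, nrow(m)))
  expect_equal(m$mae_frontal_deg, rep(0, nrow(m)))
  expect_equal(m$peak_sagittal_deg[m$label == "dorsiflexion"], 20)
  expect_equal(m$peak_frontal_deg[m$label == "eversion"], -5)
})
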