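# Shared helpers for the suite.

# deterministic noise-free reference plant
quiet_plant <- function() default_plant(noise_free = TRUE)

# fold pid_step over an error stream, returning the output sequence
pid_run <- function(gains, errors, dt, anti_windup = TRUE) {
  st <- pid_state()
  u <- numeric(length(errors))
  sat <- logical(length(errors))
  for (i in seq_along(errors)) {
    out <- pid_step(gains, st, errors[i], dt, anti_windup = anti_windup)
    st <- out$state
    u[i] <- out$action$u
    sat[i] <- out$action$saturated
  }
  list(u = u, saturated = sat, state = st)
}

# plant-generated IMU stream under a constant channel command
plant_imu_stream <- function(params, command, n_ticks, dt = 0.01) {
  st <- plant_state(params)
  samples <- vector("list", n_ticks)
  truth <- matrix(NA_real_, n_ticks, 2,
                  dimnames = list(NULL, c("sagittal", "frontal")))
  for (i in seq_len(n_ticks)) {
    samples[[i]] <- synth_imu(st, params, (i - 1) * dt)
    truth[i, ] <- st$angle_deg[c("sagittal", "frontal")]
    st <- plant_step(params, st, command, dt)
  }
  list(samples = samples, truth = truth, final = st)
}
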