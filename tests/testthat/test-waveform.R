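test_that("make_schedule lays out exact biphasic cycles", {
  # 50 Hz / 200 us / 0.1 s: 5 cycles, +phase [20k, 20k+0.2] ms,
  # -phase [20k+0.2, 20k+0.4] ms, 19.6 ms gap
  s <- make_schedule(stim_params(1, 50, 200, 5), 0.1)
  ev <- s$events
  expect_equal(nrow(ev), 10)
  k <- 0:4
  pos <- ev[ev$polarity > 0, ]
  neg <- ev[ev$polarity < 0, ]
  expect_equal(pos$start_us, k * 20000)
  expect_equal(pos$end_us, k * 20000 + 200)
  expect_equal(neg$start_us, k * 20000 + 200)
  expect_equal(neg$end_us, k * 20000 + 400)
  # gap to next cycle = 19.6 ms exactly
  expect_equal(pos$start_us[-1] - neg$end_us[-5], rep(19600, 4))
  expect_equal(ev$polarity[1], 1)  # first phase positive

  # derived case: 25 Hz / 100 us / 0.2 s -> period 40 ms, gap 39.8 ms, 5 cycles
  s2 <- make_schedule(stim_params(1, 25, 100, 0), 0.2)
  st2 <- schedule_stats(s2)
  expect_equal(st2$period_ms, 40)
  expect_equal(st2$n_cycles, 5)
  gap_us <- s2$events$start_us[3] - s2$events$end_us[2]
  expect_equal(gap_us, 39800)

  # zero-length request -> empty events
  expect_equal(nrow(make_schedule(stim_params(1, 50, 200, 5), 0)$events), 0)
})

test_that("invalid stimulation parameters are rejected", {
  expect_error(stim_params(1, 50, 10001, 5), "timing violation")
  expect_error(stim_params(1, -50, 200, 5), "frequency_hz")
  expect_error(stim_params(1, 50, 200, 101), "amplitude_duty_pct")
  expect_error(stim_params(1, 33, 200, 5), "whole-microsecond")
})

test_that("schedule_stats measures timing and needs >= 2 cycles", {
  s <- make_schedule(stim_params(2, 50, 200, 5), 0.2)
  st <- schedule_stats(s)
  expect_equal(st$frequency_hz, 50)
  expect_equal(st$period_ms, 20)
  expect_equal(st$phase_width_us, 200)
  expect_length(st$deviant_cycles, 0)

  single <- make_schedule(stim_params(1, 50, 200, 5), 0.02)
  expect_error(schedule_stats(single), "insufficient data")
})

test_that("stats round-trip recovers parameters exactly (property)", {
  grid <- expand.grid(freq = c(10, 20, 25, 40, 50, 100),
                      phase = c(50, 100, 200, 400))
  for (i in seq_len(nrow(grid))) {
    p <- stim_params(1, grid$freq[i], grid$phase[i], 50)
    st <- schedule_stats(make_schedule(p, 0.5))
    expect_identical(st$frequency_hz, grid$freq[i])
    expect_identical(st$phase_width_us, grid$phase[i])
    expect_length(st$deviant_cycles, 0)
  }
})

test_that("timing closure and charge balance hold over 5 minutes", {
  s <- make_schedule(stim_params(1, 50, 200, 5), 300)
  ev <- s$events
  pos <- ev[ev$polarity > 0, ]
  neg <- ev[ev$polarity < 0, ]
  expect_equal(nrow(pos), 15000)
  # every cycle: equal phase widths (charge balance), exact 20 ms spacing
  expect_true(all(pos$end_us - pos$start_us == 200))
  expect_true(all(neg$end_us - neg$start_us == 200))
  expect_true(all(diff(pos$start_us) == 20000))
  # phase + phase + gap = period for every cycle
  gaps <- pos$start_us[-1] - neg$end_us[-nrow(neg)]
  expect_true(all(200 + 200 + gaps == 20000))
  st <- schedule_stats(s)
  expect_identical(st$frequency_hz, 50)
  expect_length(st$deviant_cycles, 0)
})

test_that("boost converter relaxes to the ideal boost target, clamped", {
  # duty 0: stays at the 7 V rail
  b <- boost_step(boost_state(), 0, 0.01)
  expect_equal(b$voltage_v, 7)
  # duty 30 -> 7 / 0.7 = 10 V steady state (fixed-point iteration oracle)
  b <- boost_state()
  for (i in 1:3000) b <- boost_step(b, 30, 0.001)
  expect_equal(b$voltage_v, 10, tolerance = 1e-6)
  # duty 100 -> clamped at 100 V
  b <- boost_state()
  for (i in 1:3000) b <- boost_step(b, 100, 0.001)
  expect_equal(b$voltage_v, 100, tolerance = 1e-6)
  # monotone steady state in duty, never above 100 V
  ss <- vapply(seq(0, 100, by = 10), function(d) {
    b <- boost_state()
    for (i in 1:3000) b <- boost_step(b, d, 0.001)
    b$voltage_v
  }, numeric(1))
  expect_true(all(diff(ss) >= -1e-9))
  expect_true(all(ss <= 100 + 1e-9))
  # out-of-range duty is clamped with a warning
  expect_warning(boost_step(boost_state(), 150, 0.01), "clamped")
})

test_that("boost hysteresis: rises faster than it falls", {
  frac_time <- function(from, target_duty, frac_target) {
    b <- boost_state(voltage_v = from)
    t <- 0
    target <- if (target_duty >= 100) 100 else min(7 / (1 - target_duty / 100), 100)
    goal <- from + frac_target * (target - from)
    rising <- target > from
    repeat {
      b <- boost_step(b, target_duty, 0.001)
      t <- t + 0.001
      if ((rising && b$voltage_v >= goal) || (!rising && b$voltage_v <= goal))
        return(t)
      if (t > 5) stop("no convergence")
    }
  }
  t_up <- frac_time(7, 80, 0.9)     # 7 V -> 90% of the way to 35 V
  b <- boost_state(7)
  for (i in 1:5000) b <- boost_step(b, 80, 0.001)
  v_hi <- b$voltage_v
  # fall back by the same fraction
  t_down <- local({
    bb <- boost_state(v_hi)
    goal <- v_hi - 0.9 * (v_hi - 7)
    t <- 0
    repeat {
      bb <- boost_step(bb, 0, 0.001)
      t <- t + 0.001
      if (bb$voltage_v <= goal) return(t)
      if (t > 5) stop("no convergence")
    }
  })
  expect_lt(t_up, t_down)
})

test_that("render_waveform samples phases exactly and balances charge", {
  s <- make_schedule(stim_params(1, 50, 200, 5), 0.04)  # 2 cycles
  tr <- render_waveform(s, voltage_v = 50, sample_rate_hz = 1e5)
  # 20 samples at +V then 20 at -V per cycle at 100 kHz
  expect_equal(tr$voltage_v[1:20], rep(50, 20))
  expect_equal(tr$voltage_v[21:40], rep(-50, 20))
  expect_true(all(tr$voltage_v[41:2000] == 0))
  # mean over any full cycle is exactly zero
  expect_identical(sum(tr$voltage_v[1:2000]), 0)
  expect_identical(sum(tr$voltage_v[2001:4000]), 0)
  # undersampling rejected (200 us phases need >= 10 kHz)
  expect_error(render_waveform(s, 50, 5e3), "undersampled")
  # empty schedule -> all-zero trace
  tr0 <- render_waveform(make_schedule(stim_params(1, 50, 200, 5), 0), 50, 1e5)
  expect_length(tr0$voltage_v, 0)
})

test_that("schedule CSV round trip preserves events", {
  s <- make_schedule(stim_params(3, 50, 200, 5), 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, f)
  s2 <- read_schedule_csv(f)
  expect_equal(s2$channel_id, 3)
  expect_equal(s2$events$start_us, s$events$start_us)
  expect_equal(s2$events$end_us, s$events$end_us)
  expect_equal(s2$events$polarity, s$events$polarity)
})
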