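# fesloop

Hardware-free simulator and control library for a four-channel closed-loop
functional electrical stimulation (FES) system.

FES evokes muscle contraction with charge-balanced current pulses; a
closed-loop FES device measures a joint angle with an inertial sensor and
modulates the stimulus amplitude so the joint tracks a reference. `fesloop`
implements that whole loop in software, for control engineers and
rehabilitation researchers who want to exercise and test the *logic* of such
a device — waveform timing, controller saturation and anti-windup behavior,
sensor fusion, safety constraints — without hardware or human subjects:

* **waveform** — biphasic pulse-train scheduling on an exact 1 µs grid
  (at 50 Hz / 200 µs phases: 0.2 + 0.2 + 19.6 = 20 ms per cycle) and a
  boost-converter model (7 V rail, `V = V_in/(1−D)` clamped at 100 V,
  charge-faster-than-discharge lag);
* **pid** — discrete PID per degree of freedom,
  `u = Kp·e + Ki·∫e dt + Kd·de/dt`, backward Euler, hard output saturation
  and conditional-integration anti-windup (the integrator freezes while the
  output is pinned and the error pushes outward);
* **selector** — routes a signed control action to the agonist (u > 0) or
  antagonist (u < 0) stimulation channel, never both;
* **orientation** — complementary filter
  `θ ← α(θ + ω·dt) + (1−α)·atan2-tilt`, default α = 0.98 at 100 Hz;
* **plant** — synthetic two degree-of-freedom ankle:
  `J·θ̈ = τ_act + K(rest−θ) − B·θ̇ + d` per axis, driven through a
  motor-threshold deadzone / linear recruitment / saturation map with
  activation lag, hard stops, sensor noise, emitted as IMU samples;
* **session** — the closed loop (sense → fuse → PID ×2 → route → plant),
  the sequential ankle protocol (inversion +20°, eversion −5°, dorsiflexion
  +20°, plantar flexion −20°), step-response tuning metrics and per-segment
  tracking summaries;
* **cli_io** — JSON config files with aggregate validation, run manifests,
  fixtures, and a CLI (`open-loop`, `closed-loop`, `tune`, `protocol`,
  `fixtures`).

## Worked example

```r
library(fesloop)

# 1. a stimulation schedule, measured like an oscilloscope would
sched <- make_schedule(stim_params(1, frequency_hz = 50,
                                   pulse_duration_us = 200,
                                   amplitude_duty_pct = 5), duration_s = 0.1)
schedule_stats(sched)
#> <waveform_stats> 50 Hz, period 20 ms, phase 200 us, 5 cycles

# 2. controller pinned by a large error: output clamps at the lower limit
g <- pid_gains(kp = 8.2, ki = 3.8, kd = 0, u_min = -14, u_max = 10)
st <- pid_state()
for (i in 1:100) { out <- pid_step(g, st, error = -50, dt = 0.01); st <- out$state }
out$action$u          # -14  (held there; integrator frozen at 0)
st$integral           # 0

# 3. the full closed-loop protocol on the reference plant
log <- run_session(default_config(seed = 1), default_plant(noise_free = TRUE))
m <- tracking_metrics(log)
m[m$label != "neutral", c("label", "peak_sagittal_deg", "peak_frontal_deg")]
#>             label peak_sagittal_deg peak_frontal_deg
#> 2       inversion           0.00000        23.476419
#> 3        eversion           0.00000        -9.768461
#> 5    dorsiflexion          20.97247         3.477577
#> 6 plantar_flexion         -22.85186         3.478816
range(log$records$u_sagittal)  # -14 10   (never outside the limits)
range(log$records$u_frontal)   # -12 14
```

The peaks show every protocol movement reaching its target range of motion
(≥ 20° dorsiflexion, plantar flexion and inversion; ≥ 5° eversion) while the
control actions stay inside their configured limits — saturating at them,
by design, whenever the reference outruns what the actuators can do.

The ~3.5° frontal excursions during the sagittal segments are deadzone
chattering of the frontal regulator around its zero reference, not coupling:
with the noise-free plant, changing only the frontal setpoints leaves the
sagittal trajectory *bit-identical* (see `test-acceptance.R`).

## CLI

```sh
Rscript -e 'fesloop::fesloop_main()' open-loop --frequency 50 --pulse-duration 200 --duty 5 --duration 2 --out out/
Rscript -e 'fesloop::fesloop_main()' closed-loop --seed 1 --out out/
Rscript -e 'fesloop::fesloop_main()' protocol --out out/
```

Every run writes a manifest (tool version, config digest, seed, outputs).
See `vignettes/fesloop-methods.Rmd` for the models, parameter rationale and
limitations.
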