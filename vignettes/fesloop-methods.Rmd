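---
title: "fesloop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fesloop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesloop)
```

# What fesloop simulates

Functional electrical stimulation (FES) devices evoke muscle contraction by
delivering charge-balanced current pulses over surface electrodes. A
closed-loop FES controller measures a joint angle with an inertial sensor,
compares it to a reference, and modulates the stimulus amplitude so that the
joint tracks the reference. `fesloop` reproduces the *logic* of such a
four-channel device entirely in software: the pulse-train scheduler, the
boost-converter amplitude stage, two PID controllers with anti-windup, the
agonist/antagonist muscle selector, the complementary-filter angle estimator,
and — in place of the human ankle — a synthetic two degree-of-freedom plant.
Everything electrical below the waveform level (transistors, diodes, electrode
impedance) and everything network-bound (MQTT, Wi-Fi discovery) is out of
scope.

# The stimulation waveform

A channel is configured by a frequency $f$, a per-phase pulse duration $w$,
and an amplitude duty cycle. Each period $1/f$ contains one biphasic cycle: a
positive phase of width $w$, a negative phase of equal width (charge
balance), and a pause of $1/f - 2w$. At the reference setting of 50 Hz and
200 µs this gives the 0.2 + 0.2 + 19.6 = 20 ms pattern the scheduler must
hold indefinitely.

Schedules are laid out on an exact 1 µs integer grid. This is why
`stim_params()` requires the period to be a whole number of microseconds:
cycle starts are then exact integers and the timing invariants (equal phase
widths, constant period, gap = period − 2w) can be asserted with `==` over
hours of simulated stimulation, not within a float tolerance. The first phase
of a cycle is positive by convention; the convention is arbitrary and only
needs to be fixed. Cycles that would be cut mid-phase at the requested
duration are dropped whole, so every emitted cycle satisfies every invariant.

# The boost stage

The amplitude path is a DC–DC boost converter fed from a 7 V rail with a
±100 V ceiling. No circuit equations are available for the real stage, so
`boost_step()` uses the ideal continuous-conduction law
$V_t = \min(V_{in}/(1-D), V_{max})$ with a first-order lag toward $V_t$,
discretized exactly ($V \leftarrow V_t + (V - V_t)e^{-\Delta t/\tau}$). The
lag is asymmetric — $\tau_{up} = 10$ ms, $\tau_{down} = 50$ ms — because the
output capacitor charges through the switch but discharges only through the
load: the converter rises faster than it falls, and the hysteresis property
test pins exactly that ordering rather than the particular constants.

# PID with conditional integration

Each degree of freedom has its own controller,
$u(t) = K_p e(t) + K_i \int_0^t e\,dt + K_d \,de/dt$, emitting a *signed*
boost duty in percent. Discretization is backward Euler: the integral
candidate $I + e\,\Delta t$ enters the same step's output, so for constant
error the discrete output matches the closed form
$K_p e + K_i e\,n\,\Delta t$ exactly at every step — this is the oracle the
test suite holds the implementation to at $10^4$ steps.

The output is hard-clamped to $[u_{min}, u_{max}]$. Anti-windup is
conditional integration with the standard clamping predicate: the integral
update is discarded iff the unsaturated output exceeds a limit *and* the
error drives further into it. The firmware being emulated names the scheme
but not the predicate; the clamping form is the textbook default and the
property we actually rely on — recovery from saturation never slower than an
always-integrating PID — is tested over random error profiles rather than
assumed. The derivative acts on the raw error (no derivative filter) to
match the emulated firmware; an optional first-order filter exists
(`derivative_tau`) but is off by default, and the shipped controllers are PI
anyway ($K_d = 0$: an unfiltered derivative amplifies sensor noise into the
stimulus, which on a human subject means discomfort).

The shipped gain sets are the reference tuning for ankle control: sagittal
$K_p = 8.2$, $K_i = 3.8$, limits $[-14, 10]$; frontal $K_p = 8.1$,
$K_i = 3.2$, limits $[-12, 14]$. The limit magnitudes
are duty-cycle percent and double as safety constraints: when the reference
is pushed past what the joint tolerates, the controller is *supposed* to pin
at the limit rather than reach the reference.

# Muscle selector

A positive control action stimulates the agonist channel (increases the
angle), a negative one the antagonist; magnitude passes through unchanged
and the two channels of a pair are never driven simultaneously. Deliberately,
no deadzone pre-compensation is applied here: the motor threshold is a plant
nonlinearity the controller has to fight (it shows up as chattering around a
zero reference), not something the routing layer offsets.

# Complementary filter

Joint angles are estimated per axis by
$\hat\theta \leftarrow \alpha(\hat\theta + \omega\,\Delta t) +
(1-\alpha)\,\theta_{acc}$, where $\omega$ is the gyro rate and
$\theta_{acc} = \mathrm{atan2}(a_x, a_z)$ (sagittal) or
$\mathrm{atan2}(a_y, a_z)$ (frontal) is the gravity-referenced tilt. The
blend coefficient defaults to $\alpha = 0.98$ at 100 Hz — an equivalent
low-pass time constant of about half a second, a standard choice for limb
tracking; the coefficient of the original wearable firmware is not published,
so $\alpha$ is a configuration field and both limits are exact by
construction ($\alpha = 0$: pure accelerometer; $\alpha = 1$: pure gyro
integration). Angles wrap to $[-180°, 180°)$; anatomical ranges never
approach the seam. Sign convention throughout: dorsiflexion and inversion
positive.

# The synthetic ankle plant

The plant is the simplest model that exhibits every nonlinearity attributed
to the real system: per degree of freedom a linear rotational second-order
element
$J\ddot\theta = \tau_{act} + K(\theta_{rest}-\theta) - B\dot\theta + d$,
driven through a static recruitment map (zero below the motor-threshold
duty, linear ramp, saturation at full recruitment) and a first-order
activation lag; plus hard stops with velocity zeroing, Gaussian sensor
noise, and an optional Gaussian disturbance torque standing in for the
subject's reactions. The two degrees of freedom are uncoupled, matching the
design assumption of the controller.

Reference parameters (`default_plant()`), chosen once as desk-scale but
plausible for a foot about the ankle axis, and calibrated to the *stated*
operating conditions rather than to any test outcome:

| parameter | sagittal | frontal | why |
|---|---|---|---|
| inertia $J$ (kg·m²) | 0.02 | 0.015 | foot-sized segment |
| damping $B$ (N·m·s/rad) | 0.8 | 0.6 | overdamped (slow pole ≈ 0.3–0.4 s) |
| stiffness $K$ (N·m/rad) | 2.0 | 2.0 | passive return to neutral |
| hard stops (deg) | ±30 | ±25 | bracket the protocol targets |
| max torque/channel (N·m) | 2.0 | 2.0 | full recruitment reaches ≈ 36° more than stops allow in one direction |
| duty threshold / saturation (%) | 3 / 14 | 3 / 14 | recruitment spans the controller limit magnitudes (max 14) |
| activation lag (s) | 0.08 | 0.08 | calcium-dynamics scale |
| accel / gyro noise | 0.02 g / 0.5 °/s | — | consumer-IMU grade |

The 3–14 % recruitment window is the one deliberate calibration: the
controllers' output limits have magnitude at most 14, so the commanded duty
range spans exactly the deadzone-to-full-recruitment interval, and a pinned
controller corresponds to full recruitment — the same proportionality the
real tuning established between PWM limits and tolerated stimulus.

Integration is semi-implicit Euler at an internal 1 ms substep (stable for
these time constants without an adaptive-solver dependency), decimated to
the 100 Hz control rate; `plant_step()` rejects `dt > 10 ms`. The IMU
emulator constructs the gravity vector so that the two tilt read-outs stay
exactly decoupled ($a_x/a_z = \tan\theta_s$, $a_y/a_z = \tan\theta_f$),
which makes the noise-free controller-independence property exact rather
than approximate — a deliberate idealization.

**What a green test does not establish.** The plant is linear between
deadzone and saturation, time-invariant, and decoupled by construction; real
muscle fatigues, co-contracts, is spastic or flaccid depending on the
subject, and real mounting misaligns the sensor axes. Closed-loop results on
this plant demonstrate that the *control logic* is correct and safe
(limits respected, anti-windup effective, movements reached), not that the
tuning transfers to any human ankle.

# The closed-loop session

`run_session()` executes, per tick at the IMU rate (default 100 Hz): emulate
an IMU sample, update the filter, form `error = setpoint − estimated angle`
(the controller sees only the sensor path; the true angle is logged for
evaluation only), run both PIDs, route the actions, step the plant. All
randomness flows from the single config seed, so a log is bit-reproducible.
A configurable duty ceiling aborts the session if exceeded — the software
analogue of a pain-threshold stop rule.

The protocol profile holds neutral, then inversion +20°, eversion −5° (held
for a shorter time, as in the original protocol, where eversion was hard to
evoke comfortably), neutral, dorsiflexion +20°, plantar flexion −20°,
neutral. Segment durations are configuration (defaults 10 s, eversion 5 s,
closing neutral 5 s): the source protocol prints target angles, not a
timeline.

# Numerical and interface choices

* Timing in integer microseconds; angles in degrees at every interface,
  radians only inside the integrator.
* Config files are flat JSON with units embedded in field names
  (`pulse_duration_us`), validated in aggregate so one load reports every
  violation. JSON was chosen over YAML to stay within base-level
  dependencies (`jsonlite` only).
* Config digests are MD5 over a canonical serialization with recursively
  sorted keys, hence invariant under field reordering.
* Step-response metrics use a settling band of max(2 % of the step, 0.5°);
  the 0.5° floor prevents deadzone chattering from making small steps
  "never settle".
* First derivative step after a reset is taken against a previous error of
  0 (documented, tested).

# Known limitations

* The recruitment map is static; no fatigue, no spasticity, no
  subject-dependent threshold drift.
* The boost model is first-order; switching ripple and load-dependent sag
  are not represented, and the boost stage is not in the closed loop (the
  plant consumes duty directly, as the controller's output units are duty).
* The complementary filter is the single-coefficient form; no quaternion,
  Kalman or magnetometer path.
* Human-subject traces are not reproducible point-for-point; the simulation
  targets (peak angles per protocol segment, limits respected) plus the
  property suites are the substitute, and `tracking_metrics()` reports
  exactly what those targets measure.
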