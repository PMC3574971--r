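---
title: "An oscillatory model of working-memory control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An oscillatory model of working-memory control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmsync)
```

## The model

`wmsync` simulates a star-shaped network of Wilson-Cowan neural units as a
mechanism for the real-time control of working memory. The idea separates
*activation* from *phase*: every active Memory Unit oscillates, but only the
subset phase-locked to a central executive is "being processed"; active
units that oscillate out of phase hold their content on standby without
interfering. A theta-band Central Unit broadcasts a synchronizing drive to
all Memory Units; the Memory Units weakly de-synchronize one another. Task
output is produced by a coincidence detector that only fires when a
position-related and a motion-related unit peak together, i.e. when they are
phase-locked.

### Unit dynamics

Each unit is an excitatory/inhibitory population pair $(E, I)$ with a
rectified Naka-Rushton gain
$$S(x) = \frac{c_1 x^2}{c_2^2 + x^2}\ (x > 0),\qquad S(x) = 0\ (x \le 0),$$
and first-order relaxation dynamics

$$\frac{dE}{dt} = a_1\left(-E + S(b_1 E - I + K)\right),\qquad
  \frac{dI}{dt} = a_2\left(-I + S(b_2 E)\right),$$

with $a_1 = 0.26$, $a_2 = 0.13$ per ms, $b_1 = 1.6$, $b_2 = 1.5$,
$c_1 = 100$ (maximum rate), $c_2 = 30$ (semi-saturation). External current
$K$ enters only the excitatory equation. As a function of a constant drive
$K_0$ the unit has a quiescent fixed point for $K_0 < 2$, a stable limit
cycle for $2 < K_0 < 25$, and a saturated fixed point beyond 25;
`find_bifurcation_boundaries()` recovers these transitions numerically
(2.125 and 25.375 on a 0.25-spaced grid, classifying post-transient
peak-to-trough amplitude against $\varepsilon = 1$, i.e. 1% of $c_1$, after
discarding a 2 s transient).

### Network coupling

A Memory Unit $i$ receives
$$K_i(t) = K_0^{(i)}(t) + w_1 E_c(t) - w_2 \sum_{j \ne i} E_j(t),$$
where $E_c$ is the Central Unit's excitatory rate: a synchronizing
common drive with strength $w_1$ and a pairwise de-synchronizing influence
with strength $w_2$. The Central Unit receives only its executive go/no-go
current ($K_c = 5$ active, 0 quiet) and no feedback from the Memory Units.
Base currents are binary: $K_0 = 20$ for an activated (stimulus-latched)
unit, 0 for a quiet one.

### The Central Unit's time scale

A single rate pair $(a_1, a_2)$ cannot put the Central Unit ($K_c = 5$) in
the theta band and the Memory Units ($K_0 = 20$) in the alpha band: with the
values above a unit oscillates at ~18.5 Hz at $K = 5$ and ~15.2 Hz at
$K = 20$ — the unit's frequency *decreases* with drive — and with both
populations near 15-18 Hz no cross-frequency capture occurs at all (memory
phases drift freely relative to the Central Unit for any tested coupling).
Because rescaling $a_1$ and $a_2$ by a common factor is a pure rescaling of
time — it moves the unit's frequency but leaves its bifurcation structure in
$K$ untouched — the model gives the Central Unit rates scaled by
`central_scale` (default 0.324), placing it at 6.0 Hz at $K_c = 5$, the
canonical theta frequency for executive control. This is the reading we
adopt of the rate constants being "adjusted" to the theta-alpha range: the
time scale is a per-role property, the $(b, c)$ nonlinearity is shared.

Two things follow from this arrangement rather than being imposed:

* the theta drive *entrains* driven Memory Units from their uncoupled
  15.2 Hz down into the alpha band (11.9 Hz at $w_1 = 0.15$), locking them
  1:2 to the Central Unit (n:m phase-locking value ≈ 0.93 in steady state);
* all Memory Units receiving the drive share one forcing signal, so units
  captured by it become mutually phase-locked — partial synchronization.

### Integration

The full network is integrated with classical fixed-step RK4 at
`dt = 0.01` ms (compiled core), with every coupling current re-evaluated at
each RK4 sub-stage from the sub-stage states. Trajectories are stored
down-sampled (every 1 ms by default, 0.5 ms in task runs), which fully
resolves 6-20 Hz rhythms. Halving `dt` leaves lock patterns and outcome
labels unchanged, and a 1 s run of the three-unit network matches an
adaptive high-accuracy reference solver (`deSolve::lsoda` at
`rtol = 1e-10`) to better than $10^{-3}$ in sup-norm — both are part of the
test suite.

## Task scenarios

Scenarios are event scripts compiled onto piecewise-constant drive
schedules:

* **move-a-dot** (`build_move_a_dot()`): three Memory Units (position,
  motion, output), $w_1 = 0.15 \gg w_2 = 0.005$. Dot at 1 s, arrow at 2 s;
  the motion unit's activation sends the go signal ($K_c = 5$, next
  integration step). The position/motion pair locks ~0.2-0.3 s after go;
  their summed rate crosses the coincidence threshold 160 and a current
  ramps (0.1/ms, ceiling 20) into the output unit. At 3 s the Central Unit
  and both input units are suppressed.
* **multi-task** (`build_multi_task()`): four units; an extra dot at 0.5 s
  must be *stored* while the move-a-dot sub-task runs with competitive
  coupling $w_1 = 0.2$, $w_2 = 0.02$. The stored unit ends anti-phase
  (folded error ≈ 0.5 cycles) to the locked pair and later to the output
  unit.
* **error correction** (`build_error_correction()`): three active units
  (two position, one motion; latched at 1, 1.5, 2 s — times chosen to
  mirror the other scenarios, as the original timeline is not stated), with
  shutdown of the Central Unit at 3 s ($K_c = 0$) and reactivation at 4 s.

A "brief" stimulus latches $K_0 = 20$ persistently until an explicit
suppression event; suppression sets the base current to zero and the unit
decays to rest. The coincidence detector reads the instantaneous sum
$E_{pos} + E_{mot}$ (no smoothing), latches on first crossing, and keeps
ramping regardless of later sub-threshold sums; the delivered current
persists after 3 s, which is what keeps the output unit oscillating to the
end of the run.

### Trial-to-trial randomness

The quiescent state is a stable fixed point with a ~4 ms relaxation time, so
perturbations of the initial state are forgotten long before the first
stimulus: a quiet unit's oscillation phase is determined by *when it is
latched*. Runs are therefore randomized by seeded stimulus-onset jitter
(uniform on [0, 80 ms] — about 1.2 alpha cycles — per sensory latch, the go
signal moving with the latch that emits it), reflecting trial-to-trial
variability in stimulus timing. The spec-level alternative of perturbing
only the initial state produces bitwise-identical task dynamics for every
seed and was rejected for that reason; the [0, 0.1] state perturbation is
still applied.

### Outcome classification

Over the final 0.5 s of a run each Memory Unit is labelled:
`quiet` (peak-to-trough amplitude < 1), `active_synchronized` (oscillating
and mean folded phase error < 0.01 cycles against some other active unit),
or `active_desynchronized` (oscillating, locked to no one). Anti-phase is
read as folded error within 0.1 cycles of 0.5.

## Phase analysis choices

The waveforms are strongly non-sinusoidal relaxation spikes, so phase is
defined from interpolated peak times rather than an analytic-signal
transform: local maxima above half the trace's range, refined by quadratic
interpolation, at least 20 ms apart; phase advances one cycle per inter-peak
interval and is linearly interpolated in between (`extract_phase()`). The
relative phase error of a pair is the absolute phase difference folded to
[0, 0.5] cycles. A pair counts as locked when the error stays below 0.01
cycles (the lock criterion) for a 0.3 s hold window — about three alpha
cycles — which stops transient coincidences of drifting phases from
counting as locks (`sync_time()`). Dominant frequency is the reciprocal mean
inter-peak interval; n:m cross-frequency locking is
$|\langle e^{2\pi i (n\varphi_{fast} - m\varphi_{slow})}\rangle|$ with
default ratio (1, 2). A zero-crossing-based phase definition gives the same
lock/no-lock classifications in the scenarios tested; peak-based phase is
used throughout because it matches how magnified trace plots are read.

## What the simulations reproduce, and what they do not

The package's tests and acceptance script recompute, from scratch:

* the bifurcation boundaries of the uncoupled unit (near 2 and 25);
* full synchronization of four Memory Units under pure synchronizing
  coupling ($w_1 = 0.1$, $w_2 = 0$), from staggered activation times;
* move-a-dot: the position/motion pair locks within 1 s of the go signal
  (median lock latency ~0.25 s) with steady-state folded error ~$10^{-6}$
  alpha cycles, the output unit activates, and the three-state outcome
  labels are correct across seeds;
* multi-task: the stored unit remains active and ends anti-phase to the
  output unit;
* theta-alpha 1:2 cross-frequency locking of driven units (PLV ≈ 0.93
  settled), with Central ≈ 6 Hz (theta) strictly below Memory ≈ 11.9 Hz
  (alpha) in the operating network.

Four behaviours of the published account do **not** emerge from these
equations, and the corresponding checks are deliberately left failing
rather than being tuned around:

* **Even splay under pure de-synchronization.** With $w_1 = 0$,
  $w_2 = 0.02$ the four units do not spread evenly (gaps ≈ 0.25); they
  always collapse into two in-phase clusters in anti-phase (gaps 0, 0.5, 0,
  0.5), from any initial phases. For these pulse-like waveforms the
  negative pairwise coupling is attractive at short phase distances and
  repulsive only near anti-phase.
* **Random rebinding and ~2 s re-lock after an executive reset.** Because
  pairs cluster, the locked pair survives the 1 s shutdown as an in-phase
  pair (its error grows only ~$e^{3}$ from ~$10^{-5}$), so reactivation
  re-captures the same binding within ~0.1 s in most seeds. When a split
  does occur, re-locking takes ~1.9 s — the time scale the published
  account reports — but such splits are rare, so the *mean* re-lock time is
  ~0.1 s, not ~2 s.
* **Strict output gating.** During the capture transient after the go
  signal, peak alignments of not-yet-resolved pairs can cross the 160
  threshold, so the detector can fire even in runs whose final lock is a
  different pair (and, without any go signal, in a majority of seeds whose
  latch phases happen to align — two identical uncoupled units keep a
  constant relative phase, so an initial alignment persists). Gating by
  synchrony is robust only against *anti-phase* pairs, whose summed rate
  stays well below threshold; that half of the claim holds and is tested.
* **Which position unit binds** to the motion unit under competitive
  coupling ($w_1 = 0.2$, $w_2 = 0.02$) depends on the phases at the go
  signal: roughly half the seeds bind the task-relevant pair. This is the
  same phase sensitivity the error-correction scenario itself relies on, so
  a median-over-seeds demand on one specific pair is at odds with the
  model's own dynamics.

### What the generator does and does not emulate

The scenario scripts *are* the study conditions: binary sensory currents,
persistent latching, a single executive broadcast, identical unit
parameters within each role, no noise, no synaptic plasticity, no learned
input-output mapping. Passing tests therefore speak to the dynamics of this
idealized network, not to biological variability: there is no heterogeneity
across units, no background activity, and stimulus jitter is the only
stochastic element. Problem sizes follow the scenarios (3-4 Memory Units,
4-8 s runs at `dt = 0.01` ms; the bifurcation scan uses 121 five-second
single-unit runs), and every reported quantity is the median or mean over
at least 10 seeded runs.

## Numerical notes and limitations

* Tolerances: lock criterion 0.01 cycles, hold 0.3 s, amplitude threshold
  $\varepsilon = 1$, anti-phase tolerance 0.1 cycles, 2 s transient discard
  for scans. All are arguments, with these defaults.
* The go signal is applied one integration step after the motion latch;
  event times compile into piecewise-constant schedules, so events are
  honoured to within one step.
* `classify_outcome()` needs at least three oscillation peaks in its
  window; units that die mid-window are classified by amplitude as quiet.
* The integrator refuses non-finite states and names the offending unit and
  time; the saturating gain keeps all trajectories in $[0, c_1]$ for every
  parameter set used here.
* Re-lock statistics exclude seeds in which no position-motion pair ever
  re-locks within the run (a wrong position-position binding can persist);
  the acceptance script reports the number of seeds actually averaged.
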