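---
title: "Signal-to-command methods of the hands-free wheelchair interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal-to-command methods of the hands-free wheelchair interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmikit)
```

## The problem

People who cannot use a joystick — because of limited hand or arm function —
can still steer a powered wheelchair through deliberate face and head
gestures. `hmikit` implements two such hands-free interfaces end to end,
without hardware:

* a **face–machine interface**: three piezoelectric sensors (PZ1 at the left
  temple, PZ2 at the right temple, PZ3 at the cheek) sampled at 1000 Hz pick
  up eye winks, both-eye blinks and tongue pushes;
* a **head–machine interface**: a head-mounted accelerometer sampled at
  200 Hz measures x/z tilt excursions for left/right/forward/back head tilts.

Both map gestures to a five-state command vocabulary — `TURN_LEFT`,
`TURN_RIGHT`, `FORWARD`, `BACKWARD` and the default `IDLE` — at a fixed
2-second command cadence. The package adds a seeded synthetic-signal
generator that stands in for human participants, the evaluation metrics used
to score command classification, and a minimal 2D kinematic wheelchair
simulator for route-following experiments.

## Preprocessing

Raw piezo channels pass, in order, through a 3 Hz high-pass (baseline drift
and motion artifacts), an 80 Hz low-pass (high-frequency noise) and a 50 Hz
notch (mains interference). The filter family and order are a design choice
of this package: 4th-order Butterworth for the high/low/band-pass stages and
a 2nd-order constrained biquad with Q = 30 for the notch, all applied as
**causal single-pass** IIR filters — a real-time system cannot look ahead, so
zero-phase two-pass filtering is ruled out. `design_filter()` exposes the
coefficients and `filter_gain()` the exact frequency response, which the test
suite uses as its oracle for pass-band fidelity and stop-band attenuation.

The accelerometer stream has a nominal 0.1–20 Hz band-pass
(`filter_accel()`). This is deliberately **off by default** in the command
pipeline (`pipeline_config(accel_filter = FALSE)`): a sustained head tilt is
a quasi-static (sub-0.1 Hz) plateau, which the band-pass removes — the
amplitude-threshold classifier below and the band-pass are mutually
inconsistent. Rather than silently pick one behaviour, both are implemented
behind the flag and the unfiltered path is the working default.

## The face–machine interface

The only feature is the windowed maximum amplitude (`window_max()`). In a
quick calibration the user performs each sensor's target action five times;
the per-sensor baseline is the mean of the five repetition-window maxima,

$$BP_n = \mathrm{mean}(PP_{n1},\dots,PP_{n5}),$$

and thresholds sit 25 % below the baselines:

$$TP_n = BP_n - 0.25\,BP_n, \qquad
  TP_{1,2} = (BP_1 + BP_2) - 0.25\,(BP_1 + BP_2),$$

where $TP_{1,2}$ guards the both-eye blink (both temple sensors together).
At run time each 1 s window gives per-sensor maxima $DP_n$ and rectified
excesses

$$EP_n = \max(DP_n - TP_n,\, 0), \qquad
  EP_{1,2} = \max\bigl((DP_1 + DP_2) - TP_{1,2},\, 0\bigr).$$

If all four excesses are zero the epoch is `IDLE`; otherwise the argmax over
$(EP_1, EP_2, EP_3, EP_{1,2})$ selects `TURN_LEFT`, `TURN_RIGHT`, `FORWARD`
or `BACKWARD`.

Three design points were genuinely open:

* **The combined live statistic.** The blink threshold $TP_{1,2}$ is defined
  additively, but its live counterpart is not defined anywhere; we take
  $DP_{1,2} = DP_1 + DP_2$, the only construction consistent with the
  threshold. A blink near calibration amplitude then automatically dominates
  the single-sensor excesses ($EP_{1,2} \approx 0.25(BP_1+BP_2)$ exceeds each
  $EP_n \approx 0.25 BP_n$), so no extra suppression rule is needed.
* **Ties** in the argmax break towards the lowest index — deterministic and
  matching the enumeration order of the decision rules.
* **Calibrate on what you classify.** Thresholds are fractions of measured
  amplitudes, so calibration windows must be preprocessed exactly like live
  windows; `fit_session()` runs the calibration repetitions through the same
  filter chain the pipeline applies. (A causal 4th-order chain attenuates a
  short damped burst by roughly 30 %; calibrating on raw windows while
  classifying filtered ones would push every live maximum below threshold.)

The whole chain is scale-equivariant: multiplying calibration and live data
by any $c > 0$ leaves every decision unchanged, which is why the piezo
amplitude units can stay dimensionless.

## The head–machine interface

Calibration tilts (three repetitions per direction, 1 s windows at 200
samples) give the axis extremes — $X_{max}$ from left tilts, $X_{min}$ from
right tilts, $Z_{max}$ from forward, $Z_{min}$ from back — and thresholds 80 %
of the half-range inward from each extreme:

$$T_{x-} = X_{min} + 0.8\,\tfrac{X_{max}-X_{min}}{2}, \qquad
  T_{x+} = X_{max} - 0.8\,\tfrac{X_{max}-X_{min}}{2},$$

and analogously for z, so $T_{x-} < T_{x+}$ for every non-degenerate
calibration and each axis is partitioned into low / idle / high bands. The
decision chain evaluates strictly in order — $A_x < T_{x-}$, else
$A_x > T_{x+}$, else $A_z < T_{z-}$, else $A_z > T_{z+}$, else `IDLE` — so
simultaneous excursions resolve to the x-axis command.

Two open points:

* **Branch labelling.** The published account attaches $X_{max}$ to the
  left-tilt data yet labels the *low*-x branch "turn left", and the
  action-mapping table gives left tilt the positive x axis; these cannot all
  hold at once. We resolve it by self-consistency: at calibration time a
  `label_map` assigns each branch the command of the action whose data
  produced that extreme, so replaying a calibration tilt always returns its
  own command, whatever the sensor polarity. If the mounting polarity is
  inverted (left tilts drive x negative), the auto map detects this and
  swaps the attribution instead of failing. The literal printed rule remains
  available via `fit_head_hmi(..., label_map = "printed")`.
* **Window statistic.** The live scalars $A_x, A_z$ are summarised from the
  1 s decision window by its mean (default; robust against spikes and noise)
  or its last sample (`window_stat = "last_sample"`).

The classifier is offset-equivariant on each axis: shifting calibration and
live data by a common constant changes nothing, so a static mounting offset
is harmless as long as it is present during calibration.

## The command pipeline

One command is emitted every `command_period` = 2 s from the final
`window` = 1 s of each epoch — the analysis window adjacent to the decision
instant minimises latency; which second of the 2 s period is analysed is not
otherwise constrained. Filtering is applied causally to the whole stream
once (identical to sample-by-sample online filtering), so epoch $k$ depends
only on samples up to its decision instant; `run_pipeline()` emits
$\lfloor \mathrm{duration} / \mathrm{period} \rfloor$ epochs and discards a
trailing partial epoch. Gestures that straddle the window boundary can be
missed; this mirrors the physical system and is intentionally not "fixed".

## The synthetic generator

`generate_piezo()` / `generate_accel()` realise scripted action sequences
([`action_script()`], [`command_script()`]) as traces:

* face gestures are damped 20 Hz sinusoid bursts (0.3 s), normalised so the
  burst peak equals `piezo_amp` exactly, on the gesture's target sensor(s);
  20 Hz is deliberately inside the piezo pass-band;
* head tilts are raised-cosine ramps (0.3 s) to a plateau of
  $\pm\sin(\textit{tilt\_angle})\cdot 1\,g$ held for 1 s — deliberately
  below the 0.1 Hz band-pass edge, which is what exposes the filtering
  caveat above;
* rest level is 0 g on both axes (tilt deltas only), so thresholds need no
  orientation offset;
* Gaussian noise floors are added throughout, and everything is reproducible
  from `subject_model(seed = ...)`.

Default subject parameters are chosen as plausible for the instrumentation
rather than fitted to any data: unit burst amplitude (the chain is
scale-invariant), a 2 % noise floor for clean laboratory conditions, 30°
tilts (a comfortable deliberate head tilt, plateau 0.5 g), and equal blink
amplitude factor 1. The generator emulates timing, morphology and noise; it
does **not** emulate inter-participant variability in gesture ability,
muscle fatigue, motion artifacts or cross-talk between sensors — so a
synthetic success rate is an upper bound on what a human study measures, and
passing synthetic tests demonstrates the correctness of the decision chain,
not field performance.

`generate_session()` packages the calibration protocol (five repetitions per
face sensor, three per tilt direction) together with a scripted test trace,
mirroring how a participant session is run.

## Evaluation conventions

`confusion_from_logs()` tallies issued against emitted commands into a
4 × 5 matrix whose fifth column collects `IDLE` outcomes. The metric
denominators were recovered by recomputing the bundled reference grids from
their own count matrices:

* **success** = TP / all trials issued (idle outcomes count as failures);
* **sensitivity** = TP / non-idle outcomes of the command's row (so
  sensitivity ≥ success always);
* **precision** = TP / column total of the emitted command;
* **accuracy** = one-vs-rest $(TP+TN)/(TP+TN+FP+FN)$ over all non-idle
  decisions.

These conventions reproduce every self-consistent cell of the bundled
reference grids (`ref_confusion_face()`, `ref_metrics_face()`, …) at
1-decimal rounding. The grids also contain internal inconsistencies that no
convention reproduces — the face turn-left precision/accuracy cells, a mean
row in the face grid that duplicates the head grid's, and a head grid whose
metric rows are permuted relative to its count rows (as multisets per metric
the recomputation agrees exactly). `reference_discrepancies()` flags such
cells against a recomputation instead of matching them; zero denominators
yield `NA` ("undefined"), never 0. `summary_stats()` uses the population
(n-denominator) SD, the convention validated against the per-participant
accuracy grid; note the route-time grids print sample-SD values, so only
their means are treated as recomputable.

## The wheelchair simulator

The route harness is a minimal discrete kinematic stand-in for a full
wheelchair simulator: per 2 s epoch, `FORWARD`/`BACKWARD` translate by
`speed * epoch` metres along the heading, turns rotate in place by
`turn_rate`, `IDLE` does nothing, and checkpoints (A–E) are captured in
order within a radius. The fixture routes are a straight 20 m corridor and
an L-shaped 35 m course with time limits of 360 s and 720 s, matching the
caps used in the bundled route-time grids. Completion time is
epochs × epoch length; it is non-decreasing in the number of idle or
counter-productive epochs. Published route timings are human-performance
data and are treated as summary-statistics inputs (`ref_route_times()`),
never as simulator outputs.

## Numerical choices and degenerate inputs

* Trace CSV round-trips are kept lossless to 9 significant digits; readers
  validate header, monotone uniform timestamps (1 % jitter bound) and the
  nominal rate (1 % band).
* Calibration rejects: wrong repetition counts, baselines at or below zero,
  degenerate tilt ranges (min ≥ max after polarity resolution).
* Filters are linear and deterministic; the designed DC gain of the
  high-pass is exactly zero and its step transient decays below 1 % of a
  DC = 5 input within 1 s.
* Argmax ties and simultaneous axis excursions break deterministically (low
  index; x before z).

## Problem sizes in the test suite

The suite exercises the full chain at the protocol's native sizes: 12-command
sessions (24 s traces) for exactness checks, and 200-epoch sessions (400 s
traces) for the noise-degradation comparisons, at noise floors of 5–60 % of
the burst amplitude; property checks loop over 20–100 seeded random
instances per operation. These sizes were chosen to make every stochastic
comparison stable under its fixed seed.

## Known limitations

* Thresholds are static after calibration; drift, fatigue and electrode
  movement are out of scope (as in the modelled system, which recalibrates
  per session).
* The face interface relies on raw argmax with no refractory period: a
  gesture spanning two decision windows can emit twice.
* The simulator has no obstacle physics or collision response; time-limit
  comparisons against human data are qualitative.
* No machine-learned classifier is included; the point of the toolkit is the
  transparent threshold pipeline.
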