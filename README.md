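# hmikit

Signal-to-command toolkit for two hands-free assistive human–machine
interfaces (HMIs) for powered-wheelchair control:

* a **face–machine interface** — three piezoelectric sensors (PZ1 left
  temple, PZ2 right temple, PZ3 cheek) sampled at 1000 Hz detect left/right
  eye winks, both-eye blinks and tongue pushes;
* a **head–machine interface** — two-axis (x, z) acceleration sampled at
  200 Hz detects left/right/forward/back head tilts.

Both interfaces emit one of five commands (`TURN_LEFT`, `TURN_RIGHT`,
`FORWARD`, `BACKWARD`, `IDLE`) every 2 seconds. The package implements the
whole chain without hardware: causal IIR preprocessing, threshold
calibration, windowed maximum-amplitude features, the streaming command
pipeline, a seeded synthetic-signal generator standing in for human
participants, per-command confusion-matrix metrics, and a minimal 2D
kinematic wheelchair route simulator.

## The method in brief

**Face.** Calibration performs each action five times; the per-sensor
baseline is the mean of the five window maxima, *BPₙ* = mean(PPₙ₁…PPₙ₅),
with thresholds 25 % below: *TPₙ* = 0.75 · *BPₙ* and
*TP₁,₂* = 0.75 · (*BP₁* + *BP₂*) for the two-sensor blink channel. Each 1 s
live window yields maxima *DPₙ* and rectified excesses
*EPₙ* = max(*DPₙ* − *TPₙ*, 0), *EP₁,₂* = max(*DP₁* + *DP₂* − *TP₁,₂*, 0);
all-zero excesses mean `IDLE`, otherwise argmax(*EP₁*, *EP₂*, *EP₃*,
*EP₁,₂*) selects the command.

**Head.** Calibration tilts (three repetitions per direction) give axis
extremes *Xmax*, *Xmin*, *Zmax*, *Zmin*; thresholds sit 80 % of the
half-range inward, e.g. *Tx₋* = *Xmin* + 0.8 (*Xmax* − *Xmin*)/2. The live
window mean *Ax*, *Az* is tested in strict order
(*Ax* < *Tx₋*, *Ax* > *Tx₊*, *Az* < *Tz₋*, *Az* > *Tz₊*, else `IDLE`), with
branch labels resolved at calibration time so each tilt is detected on the
side its own calibration data occupies.

See the methods vignette (`vignettes/hmikit-methods.Rmd`) for the design
decisions, the evaluation-metric conventions and known limitations.

## Worked example

Simulate a participant session for the standard 12-command evaluation
sequence, calibrate, classify and score it:

```r
library(hmikit)

subj   <- subject_model(piezo_noise_sd = 0.05, seed = 42L)
script <- command_script(evaluation_sequence(), "face")
ses    <- generate_session(script, subj, "face")

fit <- fit_session(ses, "face")
fit
#> Face-machine interface calibration
#>   baselines  BP : 0.70754, 0.70574, 0.72347
#>   thresholds TP : 0.53066, 0.52931, 0.5426  (75% of baseline)
#>   blink  TP12   : 1.06

ep <- run_pipeline(ses$trace, fit, pipeline_config("face"))
ep$command
#>  [1] "TURN_LEFT"  "FORWARD"    "TURN_RIGHT" "BACKWARD"   "FORWARD"
#>  [6] "TURN_RIGHT" "TURN_LEFT"  "BACKWARD"   "FORWARD"    "TURN_LEFT"
#> [11] "BACKWARD"   "TURN_RIGHT"

class_metrics(confusion_from_logs(evaluation_sequence(), ep$command))
#>            success precision sensitivity accuracy
#> TURN_LEFT      100       100         100      100
#> TURN_RIGHT     100       100         100      100
#> FORWARD        100       100         100      100
#> BACKWARD       100       100         100      100
#> Mean           100       100         100      100
```

The baselines (~0.71) are the filtered burst peaks: the causal filter chain
attenuates the unit-amplitude synthetic bursts, and thresholds land at 75 %
of what the classifier actually sees — which is why calibration and live
processing must share the same preprocessing. At a 5 % noise floor all 12
commands classify correctly; success degrades as the noise floor grows
toward the burst amplitude.

Drive the straight 20 m fixture route with the resulting stream:

```r
run_route(route_1(), rep("FORWARD", 30), sim_params())[1:3]
#> $completed
#> [1] TRUE
#> $time
#> [1] 40
#> $last_checkpoint
#> [1] "E"
```

40 s = 20 m at 0.5 m/s, one command per 2 s epoch.

A command-line front end over the same functions is installed at
`inst/scripts/hmi` with subcommands `simulate`, `calibrate`, `classify`,
`evaluate` (with `--strict-ref` discrepancy flagging) and `route`; every run
writes a JSON manifest sufficient to reproduce it.

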