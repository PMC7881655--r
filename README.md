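# myotrainr

Machine-learning myoelectric prosthesis control, and the serious-game
training instruments built around it, as a tested R package — fully
exercisable on synthetic surface EMG, with no hardware in the loop.

## The problem

Multi-articulated hand prostheses can be driven *simultaneously and
proportionally* from surface EMG: instead of the clinical two-electrode
direct-control scheme with explicit mode switching, a learned model maps
eight-channel EMG patterns to continuous movement commands. Making that work
is as much a *user-training* problem as a machine-learning one — users must
produce EMG patterns that are **separable** between movements and
**consistent** within a movement. This package implements the full control
pipeline, the recording and testing protocols used to train and assess users,
two headless serious-game engines used as training instruments, and the
pattern-quality metrics used to monitor progress.

## The pipeline

1. **Features.** Eight-channel EMG is windowed into overlapping 128 ms
   windows with a 50 ms step (20 Hz command rate, < 200 ms delay). Per
   channel the four Hudgins time-domain features are computed — mean absolute
   value (MAV), zero crossings (ZC), waveform length (WL) and slope-sign
   changes (SSC) — giving a 32-vector that is z-normalized with statistics
   frozen at training time.
2. **Regressor.** A feed-forward network `32 → 50 → 25 → K` (tanh, tanh,
   linear) maps each feature vector to K ≤ 7 nonnegative movement strengths
   (fine pinch, lateral pinch, wrist rotation CW/CCW, wrist
   flexion/extension, hand open), trained with minibatches of 64 windows,
   an MSE loss, Adam, and early stopping on a random 10% validation split.
   Targets follow the trapezoidal reference trace (fractions of MVC), so a
   strength *is* a force estimate.
3. **Commands.** The 7 strengths collapse to 4 signed DoF values in
   [−100, 100] (`pinch`, `rotation`, `flex_ext`, `open`); when pinch and open
   are both nonzero the smaller-magnitude one is discarded; a 4-tap moving
   average smooths the stream.
4. **Protocols.** Trapezoid recording procedure (30/60/90% MVC, 5 s
   plateaus, three postures, MVC baselines), training on the most recent
   five procedures, and the Motion Test (hold the prompted movement in a
   ±15/20/30 percentage-point force band for 2 s within 6 s; three trials
   per movement).
5. **Games.** *MyoBox*: the per-electrode RMS values steer a ball through a
   linear channel-contrast direction mapping; platforms narrow as levels
   pass. *Prosthesis Gripper*: tracking, grip activation (command ±25 with
   all other DoFs within ±24, 10 s limit), aperture control (hard cap 1.7×
   object width, sparks above 1.5×, forced close at the cap, fragile
   objects), and a 1000-point release award.
6. **Metrics.** Within-class Distance (WD, consistency — lower is better)
   and Inter-class Distance to the Nearest / All Neighbours (IDNN/IDAN,
   separability — higher is better), computed on class centroids in the
   normalized feature space, plus the spider-plot RMS profile used for
   coaching.
7. **Synthetic EMG.** A seedable generator (movement-specific channel
   patterns × trapezoid envelope × 20–450 Hz band-limited Gaussian carrier
   + baseline noise) with separability (`overlap`) and consistency (`noise`)
   dials — the test bed for everything above.

## Worked example

```r
library(myotrainr)

params <- generator_params(seed = 7)                  # orthogonal patterns
session <- generate_session(params, c("hand_open", "fine_pinch"),
                            n_procedures = 2)
recs <- unlist(lapply(session, `[[`, "recordings"), recursive = FALSE)
model <- fit_movement_regressor(recs, c("hand_open", "fine_pinch"),
                                train_config(seed = 1, max_epochs = 100))
model
#> <emg_regressor> 32-50-25-2 | outputs: hand_open, fine_pinch | best epoch 100 (val MSE 0.001939)

motion_test(model, motion_test_source(params, seed = 500))
#>     movement level success time_s
#> 1  hand_open   0.3    TRUE   2.25
#> 2  hand_open   0.6    TRUE   2.35
#> 3  hand_open   0.9    TRUE   2.40
#> 4 fine_pinch   0.3    TRUE   2.30
#> 5 fine_pinch   0.6    TRUE   2.40
#> 6 fine_pinch   0.9    TRUE   2.35
```

Every trial succeeds shortly after the 2 s minimum hold: the regressor tracks
both *which* movement is performed and *how hard*, at all three force levels.
Streaming control (`run_stream()`) then emits one smoothed command every
50 ms with a 178 ms algorithmic delay, and `session_metrics()` reports
WD/IDNN/IDAN per procedure.

A command-line front end wraps the same functions:

```sh
inst/cli/myoctl generate --seed 7 --out session/ --procedures 3
inst/cli/myoctl train --data session/manifest.json --out model.json --seed 1
inst/cli/myoctl stream --model model.json --input session/proc01_04_hand_open.csv --out commands.csv
```

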