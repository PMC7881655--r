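---
title: "Methods: the control pipeline, training instruments and their design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the control pipeline, training instruments and their design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrainr)
```

# Overview

`myotrainr` implements a proportional, simultaneous myoelectric control
system — features, regressor, command mapping — together with the protocol
and game instruments used to train users of such a system, and the metrics
used to monitor the quality of their EMG patterns. Everything runs headless
and deterministically on synthetic EMG; this vignette records the model
choices, the tunable parameters, and the places where the design was
genuinely open and a decision had to be made.

# Signal model and features

Eight channels of surface EMG are processed in overlapping windows of
**128 ms** with a **50 ms** step, so a streaming loop emits one command every
50 ms (20 Hz) with an algorithmic delay of window span plus one step =
**178 ms**. The sampling rate is not dictated by the method; the package
default is **fs = 1000 Hz**, which is standard for surface EMG and makes both
durations integral sample counts (128 and 50 samples). Any rate for which the
durations convert to whole samples is accepted; anything else is an error
naming the rate, rather than a silent rounding.

Per channel and window we compute the four Hudgins time-domain features:

* **MAV** — mean absolute value, the amplitude proxy;
* **ZC** — zero crossings: consecutive samples of strictly opposite sign
  whose gap is at least `zc_threshold`;
* **WL** — waveform length, the summed absolute first difference;
* **SSC** — slope-sign changes: interior samples where the slope changes
  sign, counted when the larger neighbouring difference is at least
  `ssc_threshold`.

Both deadband thresholds default to **0**: the analog front ends used with
this class of system pre-condition the signal, and the synthetic generator
produces zero-mean carriers for which deadbands are unnecessary. They are
exposed for noisy inputs. The 32-vector is ordered `(MAV, ZC, WL, SSC)` ×
channels 1–8; this ordering is part of the serialization contract and never
changes.

Features are z-normalized with mean and **population** (1/n) standard
deviation. The population form makes a two-point fit normalize its own
training pair to exactly ±1, which is also the behaviour assumed by the
worked examples in the test suite. Standard deviations are floored at
**ε = 1e−8** so silent channels cannot produce division blow-ups; a floored
dimension maps to 0. Normalization statistics are **frozen at fit time** and
stored inside the model: whether they should instead be refitted at every
training event is not decidable from the method description, and freezing is
the conservative choice for a deployed control loop (the inference-time
feature distribution is whatever it is; the model should not silently move
its own input scale).

# Regressor

The regressor is a fully connected network **32 → 50 → 25 → K** with tanh
hidden activations and a linear output layer, K being the number of currently
trained movements (up to 7). Training uses minibatches of **64** windows, a
mean-squared-error loss, **Adam** (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), and early
stopping on a randomly chosen **10%** validation split. The remaining
hyperparameters are not part of the method's published recipe and are
package defaults, exposed in `train_config()`: learning rate **1e−3**,
patience **10** epochs, cap **500** epochs, Glorot-uniform initialization. A
seed is mandatory; given the seed, training is bitwise reproducible (the
split, the shuffles and the init all come from one private RNG stream that
does not disturb the caller's RNG state).

**Target construction** is a design decision: the method trains against the
biofeedback the user sees, so each window's target vector carries the
trapezoid reference value (a fraction of MVC) at the window's last sample on
the prompted movement's output and 0 on all other outputs; rest windows are
all-zero. This gives the outputs a physical scale — a strength of 0.6 means
"60% of MVC on that movement" — which is what makes the Motion Test's force
criterion evaluable directly from the regressor output. Nonnegativity of the
strengths is enforced by rectifying negative raw outputs to zero at
prediction time; the mechanism is unspecified in the method description and
output rectification is the simplest one that preserves the trained
regression surface elsewhere.

# Command mapping

Opposing movements fold into signed DoFs: `pinch = scale·(fine − lateral)`,
`rotation = scale·(CW − CCW)`, `flex_ext = scale·(flexion − extension)`,
`open = scale·open`, each clamped to [−100, 100] (open to [0, 100]). The sign
conventions (fine, CW and flexion positive) are package conventions chosen
for consistency with the grip colour coding (blue/fine = positive,
red/lateral = negative) and documented here; the method fixes only that
opposing movements take opposite signs. `scale` defaults to **100**, i.e. a
full-MVC strength maps to a full-scale command.

The pinch/open mutual exclusion discards the element with the smaller
absolute value. The tie case is not specified; the package discards **open**
on an exact tie, on the grounds that grip training is the harder and more
valuable behaviour — this is arbitrary and flagged as such.

The post-filter averages the last **4** regression outputs. The buffer is
zero-filled at start, so a step input produces the attenuated ramp 25, 50,
75, 100 rather than a delayed step; this trades a brief initial
underestimate for zero added latency.

Whether "hand open" shares the grip DoF or stands alone is ambiguous in the
method text; the package keeps open as the fourth element with the printed
mutual-exclusion rule, which preserves both readings' observable behaviour
(at most one of pinch/open is ever nonzero).

# Protocols

The recording procedure per movement: an MVC baseline, then one trapezoid
trial at each of 30%, 60% and 90% MVC — ramp up, **5 s** plateau, ramp down.
Ramp duration is unstated; the default is **1 s** per side (a comfortable
rate-of-force-development for graded contractions), configurable. The
on-screen force estimate is the mean over channels of window MAV divided by
MVC-plateau MAV, clipped to [0, 1.2]; the estimator is not named in the
method description and the MAV ratio is the natural choice given the feature
set.

Training always uses the **most recent five** procedures (all, when fewer
exist), and the selection is checked for coverage of the three postures
(hanging, armrest, reaching) with a warning on violation — the selection is
still returned, since the protocol rule is about how data are collected, not
a hard precondition of training.

The **Motion Test** prompts each trained movement at each level (three trials
per movement). A trial succeeds when the regressor's argmax equals the prompt
*and* the prompted strength is within the level's margin (±15, ±20, ±30
percentage points of MVC at 30/60/90%) for **2 s** within a **6 s** window.
"For two seconds" is read as *cumulative* in-criterion time — brief
misclassifications should not zero a user's progress in what is primarily a
training instrument — with a consecutive-dwell variant behind
`mode = "consecutive"`. The 6 s window starts at prompt onset (first sample
of the trial stream). The force value is read from the regressor output
itself rather than a separate MAV-ratio estimate: the outputs are trained on
MVC-fraction targets, so they *are* the system's force estimate, and this is
the quantity the user actually controls through the interface.

# Game engines

Both engines are pure state machines — no RNG, no wall clock — so identical
inputs replay identical episodes, and episode logs are replayable artifacts.

**MyoBox** maps the eight per-electrode RMS values linearly to an avatar
direction (vertical: electrodes 2–4 against 6–8; horizontal: 1, 2, 8 against
4–6) and is deliberately played from raw RMS, not the regressor: it shapes
muscle patterns before any model exists. Arena geometry, ball gain, platform
sizes and per-box points are not part of the method; they are named config
constants (`myobox_config()`) logged with every episode. Platform width
decreases by a fixed decrement per level down to a configured minimum.

**Prosthesis Gripper** is played from the regressor's command vector and
implements the printed rules exactly: grip activation at a pinch command of
magnitude **≥ 25** with the colour-matching sign while all other DoFs stay
within **±24**; a **10 s** activation limit; aperture hard-capped at **1.7×**
object width; sparks strictly above **1.5×**; reaching the cap triggers a
forced close ("fully opened" is read as reaching the cap — the cap is the
only "fully" the engine has); a successful release awards **1000** points.
Tracking-task distances, point rates, the aperture slew rate and the
fragile-object closing-speed limit are config constants
(`gripper_config()`). The object queue is deterministic (colours alternate,
widths cycle 60/100/140, every third object fragile) to keep episodes
replayable.

# Pattern metrics

The separability/consistency formulas are defined here on class centroids in
the normalized feature space, the distance being Euclidean by default:

* **WD** — per class, the mean distance of its vectors to the class
  centroid; averaged over classes. Lower = more consistent.
* **IDNN / IDAN** — per class centroid, the distance to the nearest / the
  mean distance to all other centroids; averaged over classes. Higher = more
  separable, and IDNN ≤ IDAN always.

The original metric definitions live in an appendix and a reference that are
not part of the available method text, so these centroid-based Euclidean
forms are this package's documented definitions — deliberately simple,
translation-invariant, and satisfying the stated orderings — with the
distance pluggable (`distance = "mahalanobis"` uses the ridge-regularized
pooled within-class covariance) so a different definition can be slotted in.
Session-level values are means over the session's recording procedures.

# Synthetic EMG generator

Each channel of a generated trial is
`pattern_weight(movement, channel) × trapezoid(level) × carrier + noise`,
where the carrier is Gaussian noise band-passed to **20–450 Hz** (the usual
surface-EMG band; Butterworth order 2 via zero-phase filtering) and
normalized to unit RMS, so a plateau's RMS is approximately
`weight × level`. Defaults: orthogonal patterns (movement *i* excites only
channel *i*), baseline noise SD **0.02** (≈ −34 dB against a full-MVC
plateau, i.e. a clean lab recording), amplitude jitter **5%** per trial
(typical trial-to-trial variability of repeated graded contractions), ramp
**1 s**, rest padding **0.5 s** around the trapezoid. The `overlap` dial
blends all movement patterns toward their common mean (0 = orthogonal, 1 =
identical) and is the generator's separability control.

What the generator emulates: movement-specific channel topographies,
proportional amplitude modulation, trial-to-trial amplitude variability,
baseline noise, and the session structure (rest + per-movement MVC + three
graded levels, postures cycling hanging → armrest → reaching). What it does
**not** emulate: motor-unit physiology, electrode shift, fatigue,
contraction-dependent spectral change, crosstalk between adjacent muscles,
or amputation-specific EMG changes. Passing tests therefore demonstrate that
the pipeline's machinery is correct and well-calibrated on signals matching
its assumptions — not that any accuracy figure transfers to human EMG.

# Numerical choices and problem sizes

* Window counts follow `floor((N − W)/S) + 1`; a too-short recording yields
  an empty window list plus a warning, not an error, so batch pipelines can
  skip degenerate trials.
* Normalizer ε floor 1e−8; constant feature dimensions warn and map to 0.
* Early stopping keeps the best-validation weights (never a later, worse
  epoch); ties favour the earlier epoch.
* The conflict rule and the activation predicate use exact comparisons at
  their printed boundaries (≥ 25, ≤ 24, > 1.5×, ≥ 1.7×); boundary behaviour
  is pinned by tests.
* The test suite and examples train on two-movement sessions of two
  procedures (≈ 2 800 windows, ≤ 100 epochs, a few seconds of CPU) — sizes
  chosen so the full pipeline, including a complete Motion Test, exercises
  in well under a minute while leaving the regressor's accuracy ceiling
  (≥ 99% plateau argmax on held-out orthogonal data) reachable.

# Known limitations

* The regressor is the fixed 32-50-25-K architecture; no classifier
  variants, recurrent models or online adaptation.
* Game engines are headless rule engines: no rendering, audio or input
  devices, and point values other than the printed release award are
  package constants.
* Metrics implement this package's centroid definitions, not the original
  appendix formulas (unavailable); comparisons across implementations should
  compare definitions first.
* The synthetic generator's realism limits are listed above; claims about
  human-subject performance are out of scope entirely.
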