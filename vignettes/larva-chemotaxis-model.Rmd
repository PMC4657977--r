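---
title: "An agent-based model of larval chemotaxis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of larval chemotaxis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvataxis)
```

## The model

`larvataxis` simulates a *Drosophila* larva as a two-segment agent — a head
section and a body section of equal length with one articulation between
them — crawling on a planar odour landscape. The larva has two behavioural
modes. During **runs** the head tip advances at a constant speed
$v_{forward}$ along the head orientation while the body section is pulled
behind it (trailer kinematics: the joint advances, the tail follows, and the
body angle $\alpha$ gradually realigns with the head). During **head casts**
the body is stationary and the head section sweeps from side to side at
$240^\circ$/s, reversing immediately at the $\pm 120^\circ$ range limit.

The only sensory input is the odour concentration $C$ at the head tip,
reduced to the normalised rate of change

$$\phi = \frac{1}{C}\frac{dC}{dt},$$

positive when moving up-gradient. Behavioural transitions are stochastic;
on each step of length $dt$ a transition with rate $r$ fires with
probability $\min(1, r\,dt)$. Each rate is the sum of a base rate and the
dot product of a linear kernel with the recent history of $\phi$:

* **run termination** (klinokinesis): base $0.148\,\mathrm{s^{-1}}$, kernel
  sloping from $+2$ at a 20 s lag to $-2$ at lag zero. Sustained or
  worsening decline in $\phi$ raises the probability of stopping a run and
  starting to cast.
* **cast termination** (klinotaxis): base $2\,\mathrm{s^{-1}}$, a steep
  kernel over the last 0.5 s with weight 150 on the most recent sample. A
  sharp rise in $\phi$ — the head sweeping into higher concentration —
  triggers the return to running, so the new heading tends to point
  up-gradient.
* **weathervaning**: during runs the head continuously makes small casts of
  $\pm 20^\circ$ at $60^\circ$/s. Casting pauses at a base rate of
  $2\,\mathrm{s^{-1}}$, modulated by a differenced-mean kernel
  ($30 \times$ (mean $\phi$ over the last 1 s $-$ mean over the last
  10 s)), and resumes at a constant $1\,\mathrm{s^{-1}}$. While paused the
  head orientation is held fixed in the world, so body realignment curves
  the path towards the side the head points — preferentially the
  up-gradient side.

Behavioural refinements: casts may only terminate during the *outward*
phase of a sweep and only beyond a minimum amplitude of $37^\circ$; at each
centreline crossing the sweep direction reverses with probability 0.5
(producing repeated casts to one side); a run cannot end within 1 s of
starting; the first cast after a run goes to the side the head currently
points (which weathervaning biases up-gradient); head contact with a wall
deflects the head section $15^\circ$ inward during runs and reverses the
sweep during casts, so larvae follow walls until a cast turns them away.

All three rates are computed on every step from the same perceptual
history, whatever the current mode; they only take effect in the mode they
control.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `dt` | 0.1 | s | simulation step; kernel magnitudes are tied to it |
| `v_forward` | 1 | mm/s | forward crawling speed |
| `t_min_run` | 1 | s | run refractory period |
| `theta_max_head_cast` | 120 | deg | head cast range |
| `theta_min_head_cast` | 37 | deg | minimum cast amplitude for termination |
| `cast_speed` | 240 | deg/s | head cast sweep speed |
| `theta_max_weathervane_cast` | 20 | deg | weathervane cast range |
| `weathervane_cast_speed` | 60 | deg/s | weathervane sweep speed |
| `r_run_termination_base` | 0.148 | 1/s | spontaneous run termination |
| `r_cast_termination_base` | 2 | 1/s | spontaneous cast termination |
| `r_weathervane_cast_termination_base` | 2 | 1/s | weathervane pause rate |
| `r_weathervane_cast_resume` | 1 | 1/s | weathervane resume rate |
| `L_head`, `L_body` | 2, 2 | mm | segment lengths (equal segments at larval scale; not fixed by the behavioural data, configurable) |
| `wall_deflection` | 15 | deg | head deflection per contact step ("a small turn", unquantified; configurable) |

`configure_mechanisms()` removes or rescales the *modulation* of each
mechanism by zeroing or multiplying its kernel; the base-rate transitions
themselves always remain (a basal run-termination rate is required for
casting to occur at all, and vice versa).

## Numerical choices

* **Perception discretisation.** $\phi$ uses a backward difference
  normalised by the *current* concentration, with a floor of $10^{-12}$ on
  the denominator so zero-concentration regions produce finite values. Any
  alternative single-sample normalisation (previous or midpoint
  concentration) differs only at $O(dt)$. Because $\phi$ is normalised,
  landscapes are scaled to peak concentration 1 by convention; note that in
  regions where $C$ falls below the floor the normalisation saturates and
  the perceptual signal is effectively lost.
* **Kernel sampling.** Kernels are sampled at lags $0, dt, \dots, T-dt$
  (so a $T = 20$ s kernel has 200 weights, and the tabulated *end value* is
  exactly the weight on the most recent sample). The rate sums are literal
  dot products with no extra $dt$ factor, which ties the tabulated kernel
  magnitudes to $dt = 0.1$ s; the parameter validator warns if `dt` is
  changed. On this grid the default run-termination kernel sums to $-2$:
  a *sustained* negative $\phi$ (running steadily down-gradient) raises the
  termination rate, and a worsening trend raises it further. An
  endpoint-inclusive grid would make the kernel sum exactly zero and
  silence the response to constant relative gradients (ideal exponential
  slopes), which is not the behaviour the mechanism describes.
* **Rates and probabilities.** Computed rates are clamped at 0 before
  conversion, and probabilities are capped at 1.
* **Within-step order.** Run mode: advance and realign, then the
  weathervane sub-machine, then the termination draw. Cast mode: rotate,
  reverse at the range limit, draw the centreline reversal, then the
  termination draw (so termination is tested at the post-rotation angle).
  These orderings are conventions; the model is not sensitive to them at
  $dt = 0.1$ s.
* **Weathervane bookkeeping.** Immediately after a turn the head-body angle
  usually exceeds the $20^\circ$ weathervane range; weathervane casting is
  then *suspended* (head orientation fixed in the world) until realignment
  brings it inside the range, after which casting resumes with a random
  initial direction. This preserves the turn's chosen heading.
* **Randomness.** Each larva owns an independent counter-based RNG stream
  (xoshiro256++ seeded from the master seed and the larva index), so
  batches are bit-reproducible and independent of execution order.
  Start poses are drawn from per-attempt derived seeds, so a discarded
  larva never shifts the draws of later ones.

## Odour landscapes and arenas

Analytic fields (uniform, Gaussian, linear, exponential, step) are
evaluated by the same compiled code used inside the simulation loop, so
analysis-side concentrations agree exactly with what the larva perceived.
Gridded fields use bilinear interpolation inside the grid hull and constant
extrapolation outside (a head may transiently overhang a wall).
Multiplicative noise divides the arena into square cells (default 0.08 mm)
and multiplies each cell by an independent $\mathcal N(1, \sigma^2)$ draw
clamped at zero, frozen per seed.

The measured odour landscapes on which the original behavioural
observations were made are not reproducible from published material, so all
canned experiments use analytic surrogates. The choices, made once:

* **Point-source assay** (65 × 100 mm rectangle): Gaussian with
  $\sigma = 10$ mm. The measured droplet landscape could not be quantified
  at the arena edges, implying a decay of roughly three orders of magnitude
  across the half-arena; $\sigma = 10$ mm reproduces that dynamic range.
  With a much flatter surrogate (e.g. $\sigma = 20$ mm) the relative
  gradient $d/\sigma^2$ near the source is several-fold weaker and the
  emergent first-cast bias largely disappears.
* **Choice assay** (45 mm dish): Gaussian with $\sigma = 30$ mm centred
  5 mm from the left wall, with the standard 1 cm centre exclusion band on
  the preference index.
* **Slope assays** (110 × 65 mm rectangle): exponential with a 30 mm length
  constant, a steep linear ramp spanning 0 to 1, and a shallow linear ramp
  spanning 0.497 to 0.503. Model performance here is *non-monotone* in
  signal strength: very strong signals over-trigger terminations and lower
  path straightness, moderate signals saturate it, and only genuinely weak
  signals degrade guidance. The three surrogates are therefore chosen to
  span clearly separated guidance regimes — near-direct ascent in the
  exponential slope, clearly tortuous paths under default kernels in the
  shallow slope, with a 6-fold kernel scaling markedly improving the
  latter — matching the qualitative pattern reported for the measured
  slope landscapes.

## Event detection and statistics

The metrics module works from recorded trajectories (time, head, centroid
and tail positions, angles), never from the engine's internal state, the
way tracked video data are analysed. Note the recorded behavioural mode is
part of the trajectory record; only `first_cast_stats()` uses it (below).

* **Turns**: maximal periods with $|d\alpha/dt| > 12^\circ$/s, smoothed
  with a 0.3 s moving average; periods shorter than 1 s are discarded. The
  net angle change is measured one sample beyond each end of the
  above-threshold interval, recovering the full ramp amplitude. Smoothing
  and hysteresis windows are expressed in seconds so detection behaves
  consistently across recording strides.
* **Head casts**: maximal excursions of $|\theta| > 37^\circ$, with
  one-sample hysteresis against discretisation chatter.
* **Bearing** $\beta$: the signed angle from the body axis to the local
  up-gradient direction (central finite difference with a 0.1 mm step),
  positive when the gradient lies to the larva's left. An event is
  classified *to-high* when its direction of motion points to the
  up-gradient side at the event start — a turn that overshoots past
  alignment still counts as to-high.
* **Cast-to-turn association**: a cast belongs to a turn if it starts
  within 5 s of the turn's initiation or after the previous turn's end,
  whichever interval is shorter.
* **Indices**: straightness (beeline / path length), preference index
  (side counts excluding the centre band, which still counts towards the
  total; groups of 20 by default), chemotaxis index (fraction of samples
  inside a region of interest).

Two measurement caveats, both visible in the test suite: the 1 s
turn-discard rule removes episodes that terminate right at the
$37^\circ$ minimum (their realignment is brief), so kinematics-only turn
counts run ~6–9% below the internal episode count in a uniform field, and
considerably further below it in steep gradients where the cast-termination
bias concentrates terminations at small angles. For the same reason the
*first-cast* direction statistic computed through full event detection is
diluted: the quickly-terminated (mostly up-gradient) first casts are
exactly the ones whose turns get discarded. `first_cast_stats()` therefore
measures the statistic directly: the sweep direction of the recorded head
angle immediately after each run-to-cast mode change, against the bearing
at run termination.

## The synthetic-data generator

`synth_trajectory()` builds trajectories with *planted* events — body-angle
ramps of known rate and amplitude, triangular head sweeps of known peak —
integrated into consistent head/centroid/tail kinematics. It is the
ground-truth oracle for the event detectors. It emulates the sampled
geometry of tracked data but not its noise: no tracking jitter, no posture
wobble, no frame drops. Passing the planted-event tests therefore shows the
detectors implement their definitions exactly; it does not show robustness
to video-tracking artefacts (the hysteresis and smoothing options exist for
that, but are validated only against discretisation chatter).

`generate_fixture()` writes deterministic landscape grids and trajectory
CSVs for tests and external tooling.

## Scale of the shipped analyses

The test suite and the acceptance script rerun the reference assays at
sizes chosen to keep a full run on one core in well under a minute while
leaving the estimators' sampling error far inside the tolerances asserted:
run-duration calibration over ≥2,000 completed runs, choice assays at the
full 400 larvae, ablation at 200 larvae × 120 s, slope assays at the
original cohort sizes (20/14/11 arrivals). The engine simulates roughly
10⁶ steps per second, so the full original scale (500 larvae × 300 s per
condition) remains desk-scale.

## Known limitations

* Perception is a perfect normalised differentiator: no sensory threshold,
  saturation, adaptation or receptor dynamics. Far from a source the model
  is unrealistically sensitive to minute relative differences (until the
  numerical floor is reached).
* Locomotion is abstracted: no peristaltic cycle, a single articulation
  point, rigid segments; the centroid is identified with the segment
  joint.
* The weathervane mechanism's marginal contribution on top of the two
  termination biases is small; at the shipped assay sizes the full model's
  advantage over the run+cast-only variant is not statistically detectable,
  although weathervaning alone demonstrably improves clustering over the
  no-bias model and biases run curvature up-gradient.
* Larva–larva interactions, time-varying plumes and 3-D effects are out of
  scope.

## A minimal session

```{r example, eval = FALSE}
params <- larva_params()
field  <- odour_field_gaussian(peak = c(0, 0), sigma = 10)
arena  <- arena_rectangle(100, 65)

traj <- simulate_larva(params, field, arena, duration = 300, seed = 1,
                       init = list(position = c(-20, 0), orientation = 0))
plot(traj)

turns <- detect_turns(traj)
casts <- assign_casts_to_turns(detect_head_casts(traj), turns)
straightness_index(traj)

assay <- run_experiment("pi_scan", seed = 1, n = 100, duration = 300,
                        scalings = c(1, 0))
assay$pooled
```
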