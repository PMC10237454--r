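---
title: "Measuring TUG subtask speeds from a single camera: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TUG subtask speeds from a single camera: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugcam)
```

# The measurement model

A Timed Up and Go trial is filmed from the side, perpendicular to a 3 m
walkway, with a static background frame available. The subject's position is
summarised per frame by the *silhouette centroid*: background subtraction
(absolute grayscale difference, strict threshold τ = 50) yields a binary
foreground mask, a 5×5 binary median filter removes isolated noise, and the
centroid is the unweighted mean of the foreground pixel coordinates — the
centre of mass of a uniform lamina.

Two marker pairs calibrate the plane: the walkway pair (3 m apart) fixes the
horizontal metre-per-pixel scale and the world origin at the chair end; the
floor/chair pair (0.5 m apart) fixes the vertical scale and the floor row.
The mapping is linear per axis (pin-hole, fronto-parallel assumption):

$$x = (u - u_0)\, s_x \cdot d, \qquad y = (v_0 - v)\, s_y,$$

with $s_x, s_y$ the scales, $u_0$ the chair-side marker column, $v_0$ the
floor row, and $d = \pm 1$ the walk direction in pixel space. Using absolute
pixel separations for the scales makes camera left/right orientation
irrelevant; this is a deliberate, sign-free reading of the two-point
calibration.

Instantaneous speeds are signed finite differences over a fixed 1/15 s
window — 4 frames at the 60 Hz video rate, 8 frames at the 120 Hz reference
rate — so both systems average motion over the same physical time span. No
additional smoothing is applied to the video track; the windowed secant is
the only low-pass element, matching the minimal conventional pipeline.

# Subtask boundary rules

The nine subtasks are delimited by sync events (trial start = seat-off
trigger, trial stop = seat-on trigger) and seven internal boundaries. The
source method defines the subtasks but not how their boundaries are
detected, so the rules here are this package's own, all exposed as
`seg_params()`:

* **Standing height** is the median height over the middle third (in time)
  of the outbound walk — robust to the vertical gait bob and to the rise
  itself. Sit-to-stand (V1) ends at the first frame within
  `stand_epsilon_m` (default 0.05 m) of standing height; stand-to-sit (V9)
  starts at the last such frame. The 0.05 m default is small relative to a
  typical 0.25–0.30 m seated-to-standing centroid rise but large relative
  to gait bob (±0.015 m) and pixel quantization (≈ 6–12 mm at the tested
  resolutions).
* **Metre crossings** (1 m and 2 m marks) are sign changes of
  $x - \text{mark}$ between consecutive frames, assigned to the later
  frame, searched forward before the peak excursion and backward after it.
* **The turn** (V5) spans the frames with $x > x_{peak} -$
  `turn_margin_m` (default 0.20 m). A margin rule is needed because the
  centroid never reaches the 3 m toe mark; 0.20 m keeps the interval well
  clear of the 2 m crossing while covering the deceleration, pivot and
  re-acceleration.

V1 and V9 average |vertical speed|; V2–V8 average |horizontal speed| — the
turn included, taken at face value as a horizontal-plane speed even though
real turning is mostly rotational. Mean-of-instantaneous-speeds is used
rather than net displacement over duration: for monotone segments the two
coincide up to windowing, and each subtask mean rests on roughly 20–90
samples at 60 Hz.

# The reference (motion-capture) path

Four pelvis markers (left/right ASIS and PSIS) sampled at 120 Hz are
filtered with a 4th-order low-pass Butterworth at 6 Hz — the conventional
choice for gait marker data — and averaged per frame into a pelvis centre
of mass. Filtering is zero-phase (forward–backward with odd reflection
padding and steady-state initial conditions) so filtered events stay aligned
in time with the raw signal; the doubled effective order this implies is
accepted and documented rather than compensated. Since no DSP package is
available in the target environment, the bilinear-transform design and
filtfilt are implemented in-package and tested against analytic gain values.
The 120 Hz reference and 60 Hz video are never resampled onto each other:
systems are compared only at the subtask-mean level.

# The synthetic world

`simulate_trajectory()` scripts a centre-of-mass path from interpretable
parameters: smoothstep chair transfers (1.2 s up, 1.3 s down), cosine-ramped
walking (0.35 s ramps, cruise 1.10 m/s out and 1.05 m/s back by default), a
dwell at the 2.85 m peak excursion (0.8 s), a ±0.015 m vertical gait bob at
1.8 Hz, and a 0.08 m forward bias of the seated centroid reproducing the
thigh-induced offset of real silhouettes. Defaults were chosen once to match
comfortable-pace older-adult trials (cruise speed near 1.1 m/s, total trial
around 9–10 s) and are not revisited by tests.

The renderer draws a torso rectangle plus head disc whose *analytic* area
centroid coincides with the scripted path, so rasterization (pixel-centre
inclusion) is the only video measurement error by construction — about half
a pixel, ≈ 3 mm at the 640×360 acceptance resolution. The marker simulator
places the four pelvis markers at symmetric offsets (±0.10 m
anteroposterior, ±0.12 m lateral) around the same path, so their mean
recovers it exactly; Gaussian noise (2 mm SD) and per-frame salt-and-pepper
pixel noise are drawn from counter-based sub-seeds of one trial seed, making
every artefact reproducible independently of evaluation order.

Recorded ground-truth boundaries apply the same geometric rules to the
*analytic* path, i.e. they are what an ideal tracker would report; recorded
true speeds are time averages of the analytic |velocity| over each phase.
A green end-to-end test therefore establishes that silhouette extraction,
calibration, differentiation and segmentation jointly recover a known
smooth path through a real renderer — it does **not** establish robustness
to perspective error, lens distortion, shadows, flapping clothing, limb
articulation or occlusion, none of which the generator emulates. The turn
is modelled as a dwell (speed reaching zero), which yields turn speeds
around 0.26 m/s — lower than the ≈ 0.4 m/s of real pivoting adults, whose
centroid keeps moving; this is a stated-world simplification, not a target.

# Agreement statistics

Concurrent validity uses the sample Pearson r with the conventional bands
(< 0.50 low, 0.50–0.69 moderate, 0.70–0.89 high, ≥ 0.90 very high; the
published cut-points leave 0.90 itself unassigned and it is banded "very
high" here). Test–retest reliability uses ICC(3,2): two-way mixed effects,
average of k = 2 measurements. The *consistency* definition
$(MS_S - MS_E)/MS_S$ is the default — the label "3,k" conventionally denotes
consistency, and a systematic session offset arguably should not destroy
reliability — with the *absolute agreement* variant selectable
(`type = "agreement"`, McGraw–Wong CI with Satterthwaite degrees of
freedom). Confidence intervals and p-values come from the classical
F-distribution construction; p-values are reported at full precision, with
no display flooring. Bland–Altman limits are the mean difference ± 1.96
sample (n−1) standard deviations, with strict outside counts.

# Numerical and degenerate-input choices

* Pixel coordinates are 0-based (u = column, v = row); image rows grow
  downward, world height upward.
* Frames where the silhouette is empty are flagged invalid, filled by
  linear interpolation in world space between the nearest valid frames;
  unbracketed leading/trailing invalid frames are dropped. Fewer than two
  valid frames is an error, not a guess.
* Thresholding is strict (|difference| exactly equal to τ is background),
  fixing the printed threshold rule's ambiguous orientation in favour of
  "moving object = foreground".
* The median filter is applied to the thresholded binary mask (majority
  vote, edge-replicated borders); the alternative order — filtering the
  grayscale difference — is a recognised ambiguity and this order is fixed
  by tests.
* A subject already standing at the sync start (or still standing at the
  stop) yields the minimal two-frame transfer interval with a message
  rather than an error.
* Ties and exact-threshold hits in boundary detection go to the later
  frame, consistently with the crossing rule.

# Known limitations

* Planar calibration only: no lens model, no perspective correction; valid
  when the subject stays near the calibrated sagittal plane.
* The whole-mask centroid (component selection off by default) is sensitive
  to large non-subject foreground objects; `keep_largest = TRUE` is the
  escape hatch.
* Boundary rules are this package's inventions; published subtask
  definitions are under-specified, so cross-study comparability of V4/V5/V6
  in particular depends on the turn-margin convention.
* The published per-participant supplementary tables of the validating
  study ship only as PDFs and are not redistributed here, so the package
  reproduces the *structure* of that validation (synthetic 20-subject
  concurrent-validity runs), not its printed r/ICC columns.
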