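# tugcam

Markerless measurement of Timed Up and Go (TUG) subtask speeds from a single
sagittal video, with the motion-capture reference computation and the
agreement statistics used to validate such a system.

## The problem

The TUG test — stand up from a chair, walk 3 m, turn, walk back, sit down —
is a standard mobility and fall-risk screen for older adults, but a stopwatch
only yields the total time. Splitting the trial into its nine subtasks and
measuring the speed of each (V1 sit-to-stand, V2–V4 the three outbound 1-m
walk segments, V5 the turn, V6–V8 the three return segments, V9
stand-to-sit, all in m/s) tells a clinician *where* a slow performance comes
from: the chair, the gait, or the turn. `tugcam` implements a complete
single-camera pipeline for this measurement, aimed at movement scientists
who want a transparent, dependency-light reference implementation they can
validate end to end.

## The method

For each video frame the moving body is segmented against a static
background frame by thresholded absolute differencing,

&nbsp;&nbsp;&nbsp;&nbsp;foreground(x, y) = |Fg(x, y) − Bg(x, y)| > τ,&nbsp;&nbsp;τ = 50,

denoised with a 5×5 binary median filter, and summarised by the silhouette
centroid (the unweighted mean of the foreground pixel coordinates). Four
scene markers — two 3 m apart along the walkway, two 0.5 m apart vertically
at the chair — give the planar metre-per-pixel scales, mapping the pixel
centroid to world coordinates x (metres along the walkway from the chair)
and y (height above the floor). Signed instantaneous speeds are finite
differences over a 1/15 s window (4 frames at 60 Hz):
v\[i\] = (x\[i+w\] − x\[i\]) / (w/fps). Geometric rules split the trial at the
standing-height threshold, the 1 m and 2 m mark crossings and the
peak-excursion margin around the turn; each subtask speed is the mean
|v| over its frames (vertical speed for V1/V9, horizontal otherwise).

The reference path mirrors a laboratory motion-capture system: pelvis
marker trajectories (R/L ASIS, R/L PSIS at 120 Hz) are low-pass filtered
with a zero-phase 4th-order Butterworth at 6 Hz, averaged into a pelvis
centre of mass, and segmented with the same machinery. Agreement between
systems or sessions is quantified with Pearson r (with interpretation
bands), the two-way mixed-effects intraclass correlation ICC(3,2) with its
F-based 95% CI, and Bland–Altman limits of agreement (mean difference ±
1.96 SD).

A synthetic trial generator renders silhouette video plus matched marker
tracks from a scripted centre-of-mass path with exact ground truth, so every
stage of the pipeline is testable without any recording.

## Worked example

```r
library(tugcam)

cfg <- trial_config(sp_noise_rate = 0, seed = 1)  # scripted 60 Hz trial
gt  <- simulate_trajectory(cfg)                   # ground-truth path
res <- tug_analyze(render_video(gt), sync = gt$sync)
res$speeds
#> TUG subtask mean speeds (m/s):
#>  label start_frame end_frame duration_s n_samples mean_speed_ms
#>     V1          30        83     0.8833        53        0.2704
#>     V2          83       168     1.4167        85        0.7477
#>     V3         168       222     0.9000        54        1.0974
#>     V4         222       258     0.6000        36        1.1002
#>     V5         258       349     1.5167        91        0.2586
#>     V6         349       386     0.6167        37        1.0502
#>     V7         386       443     0.9500        57        1.0502
#>     V8         443       530     1.4500        87        0.6632
#>     V9         530       587     0.9500        57        0.2382
```

Each row is one subtask: the half-open frame interval it occupies, its
duration, the number of instantaneous speed samples and the mean speed. The
scripted trial cruises at 1.10 m/s outbound and 1.05 m/s back, which the
pipeline recovers exactly in the interior segments (V3, V4, V6, V7); V2 and
V8 are lower because they include gait acceleration near the chair, and the
chair transfers and turn are slower still — the same pattern seen in real
recordings of older adults. All estimates land within 5% of the generator's
ground truth (`gt$true_speeds`).

Agreement statistics on a paired per-subject table:

```r
tab <- simulate_paired(0.9, n = 20, seed = 1)
pearson_validity(tab)
#> Pearson r = 0.918 (very high), p = 1.2e-08, n = 20
icc_3_2(tab)
#> ICC(3,2) [consistency] = 0.956 (95% CI 0.889-0.983, excellent), p = 2.84e-09, n = 20
bland_altman(tab)
#> Bland-Altman: mean diff -0.0050, LOA [-0.0775, 0.0674], 0/20 outside (0.0%)
```

## Command line

An executable dispatcher ships in `inst/exec/tugcam`:

```sh
tugcam simulate --seed 1 --out trial/          # frames + mocap.csv + truth
tugcam analyze --frames trial/ --out trial/analysis
tugcam mocap --markers-csv trial/mocap.csv --sync trial/sync.json
tugcam validate --table-a video.csv --table-b mocap.csv --out validity.json
tugcam reliability --session1 s1.csv --session2 s2.csv
```

## Package layout

- `R/calibration.R` — marker set, pixel→metre model
- `R/foreground.R` — grayscale, background subtraction, median filter, centroid
- `R/kinematics.R` — world track, interpolation, windowed speeds
- `R/segmentation.R` — nine-subtask boundary rules and mean speeds
- `R/mocap.R` — Butterworth/filtfilt, pelvis COM, reference subtask speeds
- `R/agreement.R` — Pearson, ICC(3,2), Bland–Altman
- `R/synthetic.R` — scripted trials, silhouette renderer, marker simulator
- `R/cli.R`, `R/io.R` — commands, PNG/CSV/JSON round-trips

See `vignettes/tugcam-methods.Rmd` for the modelling choices, parameter
meanings and known limitations.
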