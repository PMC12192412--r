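# iristrack

Iris-centre tracking for visible-light eye videos recorded with consumer
cameras (stationary video-oculography), with the validation metrics used
to score trackers against manual annotation, and a seeded synthetic
eye-video generator that stands in for recordings when none can be
shared. Intended for researchers prototyping low-cost, smartphone-grade
eye tracking — e.g. as a front end for oculomotor screening — who need a
tested, reproducible baseline rather than a deep-learning stack.

## The two trackers

In visible light the whole iris reads as a dark disc on the lighter
sclera. Both trackers share a per-frame front end: grayscale conversion
(BT.601 luma), grayscale erosion + dilation (an opening on brightness
that removes specular glints), and a Circular Hough Transform (CHT) in
which Sobel edge pixels vote along their gradient toward the darker side
for centres `(c_x, c_y)` at every radius `r ∈ [15, 50]` px.

* **CHT_ACM** runs on every frame: a morphological active contour
  (region-based snake) narrows the crop to the eye, the crop is binarised
  at Otsu's threshold, CHT candidates are scored by the fraction of
  binarised-white pixels inside the circle, and a circle is accepted as
  the iris only if that fraction is below 60%.
* **CHT_TM** runs CHT_ACM on the first frame only and cuts an iris
  template (square patch + inscribed circular mask). Later frames are
  localised by masked zero-mean normalised cross-correlation at every
  placement; among near-maximal placements the one whose circular region
  is darkest becomes the iris centre. Frames whose best similarity falls
  below 0.5 (blinks, lost track) are flagged invalid.

Trajectories are scored per axis against ground truth over co-valid
frames: MAE, MPE (`mean(|a−m|/(a+ε))·100`), RMSE, and Pearson *r* with
`t = r·√((n−2)/(1−r²))` and a two-tailed Student-t p-value on `n−2`
degrees of freedom.

## Worked example

Simulate a 5-second circular-pursuit video (30 fps, sampled every 10
frames), track it with CHT_TM, and score it against the generator's
ground truth:

```r
library(iristrack)

scene <- scene_config(iris_tone = "brown", seed = 42)
task  <- task_spec("circular", duration_s = 5)
sim   <- simulate_eye_video(scene, task, sampling_interval = 10)

traj <- track_video_cht_tm(sim$frames)
head(tibble::as_tibble(traj), 4)
#> # A tibble: 4 × 7
#>   frame_index time_s     x     y valid similarity method
#>         <int>  <dbl> <dbl> <dbl> <lgl>      <dbl> <chr>
#> 1           0  0      155.  79.6 TRUE      NA     CHT_ACM
#> 2          10  0.333  152   94   TRUE       0.769 CHT_TM
#> 3          20  0.667  143  106   TRUE       0.632 CHT_TM
#> 4          30  1      131  113   TRUE       0.592 CHT_TM

evaluate_trajectory(traj, sim$truth)
#> <iris_eval> 12 co-valid frames (3 excluded)
#>   x: MAE 0.483 px  MPE 0.427%  RMSE 0.576 px  r 0.9999 (p 1.04e-20)
#>   y: MAE 0.472 px  MPE 0.603%  RMSE 0.534 px  r 0.9999 (p 9.92e-21)
```

Frame 0 is the CHT_ACM detection that seeds the template; the tracker
then follows the iris around the circle to half-pixel mean error, and the
three frames whose lid-aperture draw closed too far over the iris were
flagged invalid and excluded from pairing, not silently dropped.
`tidy()`/`glance()` return the same numbers as tibbles,
`autoplot(traj, truth = sim$truth)` plots both axes over time, and
`compare_groups()` lays several evaluations out as a long comparison
table with best-performer flags. `run_end_to_end()` chains
simulate → track (both methods) → evaluate into one output directory with
a JSON manifest; `run_benchmark()` times both trackers on 10/40/100/400
frames — CHT_TM runs ~3x faster per frame here, since it replaces the
per-frame snake + Hough chain with one correlation sweep.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "iristrack.R", package = "iristrack"))')" \
    simulate --task circular --duration 5 --tone brown --seed 42 --out sim_out
```

with `track`, `evaluate`, `benchmark` and `end-to-end` subcommands.

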