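# zapgaze

Microsaccade analysis for continuous visual search ("zapping") tasks.

In a zapping paradigm a small face target (3° of visual angle) appears on a
large display; the moment gaze dwells inside a 3×3° window around it, the
display updates (~18 ms) and the next face appears — observers target several
faces per second, continuously. `zapgaze` is an analysis pipeline for the
high-rate gaze recordings such experiments produce, for researchers in
oculomotor control and active vision:

* **Event detection** — the noise-adaptive velocity-threshold algorithm:
  5-sample smoothed velocities
  `v[n] = (p[n+2] + p[n+1] − p[n−1] − p[n−2]) / (6Δt)`, an elliptic threshold
  at `λ = 5` multiples of the median-based noise SD
  `σ = sqrt(med(v²) − med(v)²)` per axis, a minimum duration of 10 samples
  (8 ms at 1250 Hz), and classification of every event with magnitude < 1° as
  a microsaccade. Saccades and microsaccades share the main sequence
  `V_peak = V_max(1 − e^{−A/C})`, recovered by a log–log fit.
* **Peri-event trial metrics** — alignment of events on trial onset or on the
  first saccade's onset/offset; rate histograms, 0/1/2+ microsaccade count
  distributions, per-subject rates in the (−200, 800) ms interval,
  eccentricity-binned occurrence profiles, and the angular congruence between
  each saccade and the microsaccade that follows it.
* **Landmark mapping** — least-squares similarity (Procrustes, reflection
  forbidden) from each trial's 7 facial landmarks to a template face;
  endpoint-frequency maps smoothed with the 13-cell disk kernel inside a
  5×5-pixel window (~0.077°), and fitted 2D Gaussians of raw endpoints.
* **Run statistics** — maximal runs of consecutive correct or
  microsaccade-free trials (sub-runs are not counted).
* **A synthetic gaze simulator** — generates continuous recordings with
  ground-truth event logs emulating the task (blocks of 500 trials, 4
  counterbalanced conditions, main-sequence kinematics, post-saccadic
  microsaccades at 1–25 ms latency, landmark-anchored endpoint scatter), so
  the whole pipeline is testable end-to-end.

## Worked example

Simulate a two-block session of the 4°-step variant of the task, detect
events, and run the core analyses:

```r
library(zapgaze)

cfg <- sim_config(n_blocks = 2, trials_per_block = 200,
                  placement_scheme = "step4deg", rng_seed = 42)
s <- simulate_session(cfg)
#> <zg_session> 400 trials in 2 block(s), 118677 samples, 532 ground-truth events
#>   463 saccades, 69 microsaccades (ground truth)

ev <- detect_saccades(s$recording)
#> <zg_events> 532 events: 463 saccades, 69 microsaccades
#>   magnitude 0.42-7.25 deg, peak velocity 63-460 deg/s
main_sequence(ev)
#> <zg_main_sequence> log10(Vp) = 2.024 + 0.754 log10(A), r = 0.997, n = 532

evaluate_detection(s$truth, ev)[c("recall", "precision")]
#> recall 1.000, precision 1.000 (median onset error 0.51 ms)

ev$subject <- 1L
fs <- first_saccade_after_onset(s$trials, ev)
mean(fs$correct)           # 0.845: first saccade landed in the 3x3 window
microsaccade_count_distribution(s$trials[fs$correct, ], ev, c(0, 100),
                                "first_saccade_offset", fs[fs$correct, ])
#>   category      pct
#> 1        0 83.13609
#> 2        1 16.86391
#> 3       2+  0.00000

dc <- direction_congruence(fs, ev, s$trials)
#> 81% of post-saccadic microsaccades incongruent (>45 deg; n = 57)

fl <- trial_flags(s$trials, ev, "microsaccade_free", first_sacc = fs)
maximal_runs(fl, by = s$trials$block, criterion = "microsaccade_free")
#> <zg_run_table> criterion 'microsaccade_free': 400 trials, longest run 22
```

Reading the output: every injected event was recovered by the detector with
sub-millisecond onset accuracy; 84.5% of first saccades landed on the face;
among correct trials, 16.9% carried exactly one microsaccade in the 100 ms
after the landing saccade (the generator injects them in 20% of trials —
detection and correctness filtering account for the rest); 81% of those
microsaccades pointed more than 45° away from their saccade; and the longest
stretch of trials without any microsaccade in the (−200, 800) ms interval was
22 trials.

`run_pipeline(cfg, out_dir, n_subjects = 2)` executes all stages from one
configuration and writes figure-analog CSV tables (rates, counts, heatmap
matrices, run tables) plus a QC JSON. A thin command-line wrapper with
`simulate` / `detect` / `runs` / `all` subcommands is installed at
`inst/scripts/zapgaze.R`.

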