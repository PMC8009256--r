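---
title: "Methods: simulating and analyzing microsaccades in continuous visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing microsaccades in continuous visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the pipeline

In a continuous visual search ("zapping") paradigm, a small face (3 degrees
tall) is pasted somewhere on a large display; the moment the observer's gaze
dwells inside a 3x3-degree window around the face, the display is updated
(median latency ~18 ms) and the next face appears.  Observers "zap" several
faces per second, and the scientific question is how microsaccades - ballistic
movements below 1 degree - behave under this regime: when they occur relative
to trial onsets and targeting saccades, where they land on the face, and how
often long stretches of trials pass without any.

`zapgaze` implements the full analysis chain for such experiments:

1. **Detection** (`detect_saccades()`): velocity-threshold segmentation of a
   1250 Hz monocular gaze recording into saccades and microsaccades.
2. **Trial metrics** (`align_events()` and friends): peri-event alignment on
   trial onset or on the first saccade after it, rate histograms, count
   distributions, per-subject rates, eccentricity profiles, and the direction
   relation between saccades and following microsaccades.
3. **Landmark mapping** (`procrustes_fit()`, `endpoint_heatmap()`): endpoint
   frequency maps on a 7-landmark template face.
4. **Run statistics** (`maximal_runs()`): maximal runs of correct and of
   microsaccade-free trials.
5. **Simulation** (`simulate_session()`): a generative model of the task that
   produces gaze traces with ground-truth event logs, so that every stage
   above is testable without recorded data.

All positions are degrees of visual angle (origin at screen center, x
rightward, y upward); all times are milliseconds.

## Event detection

Sample velocities come from the standard 5-sample difference filter

$$v_n = \frac{p_{n+2} + p_{n+1} - p_{n-1} - p_{n-2}}{6\,\Delta t},$$

which simultaneously differentiates and smooths over a 5-sample window.  The
two samples at each segment edge carry velocity 0 and are excluded from both
threshold estimation and events.

The detection threshold per axis is $\eta = \lambda\,\sigma$ with the
median-based noise estimate
$\sigma = \sqrt{\operatorname{med}(v^2) - \operatorname{med}(v)^2}$, robust
against the saccadic tail of the velocity distribution.  The default
$\lambda = 5$.  An event is a maximal run of samples outside the elliptic
threshold $(v_x/\eta_x)^2 + (v_y/\eta_y)^2 > 1$ lasting at least 10 samples
(8 ms at 1250 Hz).  Sub-threshold gaps of at most `merge_gap_samples`
(default 2) between supra-threshold runs are bridged before the duration
test, so that a single movement momentarily dipping below threshold is not
split; the merge is configurable and reported.  Thresholds are estimated per
continuous recording segment (block), not per trial - trials last only a few
hundred milliseconds, far too short for stable medians.

Event magnitude follows the toolbox convention: the component-wise
max-minus-min extent over the event's raw samples,
$\sqrt{(\Delta x_{\text{range}})^2 + (\Delta y_{\text{range}})^2}$;
onset-to-offset displacement is available as an alternative
(`detection_params(magnitude = "displacement")`).  Peak velocity is the
largest sample speed in the event (earliest sample wins ties); the polar
angle comes from the onset-to-offset displacement, mapped to [0, 360).
Every event with magnitude below 1 degree is a microsaccade.  Saccades and
microsaccades share the main sequence; `main_sequence()` fits
$\log_{10} v_{\text{peak}}$ on $\log_{10} A$ by least squares.

Degenerate inputs are refused explicitly: fewer than 5 samples per segment,
fewer than 10 interior velocity samples, or a zero noise floor (constant
velocity) all raise errors rather than returning thresholds of 0.

## The simulator

`sim_config()` encodes the study conditions: 1250 Hz sampling, a 31 x 22
degree screen, 8 blocks of 500 trials in 4 conditions (scene / plain
background crossed with upright / inverted faces, block order counterbalanced
over the 24 orderings), a 3-degree face with a 3x3-degree advance window, a
2-sample (1.6 ms) dwell criterion, and a median 18 ms screen update.  Two
placement schemes are provided: targets uniform over the screen
(`full_screen`) or at exactly 4 degrees from the previous target at polar
angles restricted to the sectors 0-45, 135-235, 315-360 degrees
(`step4deg`).

Parameters the source experiments do not quantify are set to
literature-typical values and are all configurable:

* **Fixation noise**: white Gaussian position noise, sd 0.02 degrees per
  sample; optional random-walk drift (off by default).
* **Saccade latency**: Gamma with mean 150 ms, sd 30 ms after target onset.
* **Endpoint scatter**: saccade endpoints are drawn around an intended
  landmark (sampled from an orientation-dependent mixture over the 7
  landmarks; eyes/forehead-weighted when upright, nose/mouth-weighted when
  inverted) with isotropic sd 0.68 degrees.  That value was calibrated in
  closed form (mixture-weighted normal orthant probabilities) so that ~84%
  of landing saccades fall inside the 3x3 window, echoing the on-target rate
  such tasks produce.  Trials whose first saccade misses trigger a
  corrective saccade to an in-window point.

### Saccade waveforms

Velocity profiles belong to the family $v(t) = V_p \sin^k(\pi t / D)$, whose
$k = 2$ member is the raised cosine.  Peak velocity obeys the main sequence
$V_p = V_{\max}(1 - e^{-A/C})$ (defaults $V_{\max} = 750$ deg/s, $C = 8$
degrees) and duration the rule $D = 2.2A + 21$ ms.  These two rules plus the
displacement constraint $\int_0^D v = A$ over-determine a fixed-shape
profile, so the exponent $k$ is solved per saccade from
$A / (V_p D) = \int_0^1 \sin^k(\pi s)\,ds$; with the default constants $k$
stays within about [1.9, 2.9], i.e. near the raised cosine.  The sampled
waveform is rescaled so the displacement equals the amplitude to machine
precision.

Ground-truth logs record each injected movement's onset and offset at the
20 deg/s speed crossings of its noise-free profile - a standard operational
saccade-onset criterion, commensurate with threshold detection (a smooth
profile has no meaningful "first moving sample", and a convention far below
the detector's operating point would measure the bookkeeping gap between two
definitions rather than detector accuracy).

### Post-saccadic microsaccades

With probability `p_post_saccadic_microsaccade` (default 0.2), the saccade
that lands in the window is followed by a microsaccade at a latency uniform
in 1-25 ms after the movement ends.  Its direction class is sampled first:
with probability `p_direction_incongruent` (default 0.84) the polar angle
differs from the preceding saccade's by more than 45 degrees.  A 10-degree
guard band is left around the 45-degree boundary (incongruent draws lie in
(50, 180], congruent in [0, 40)) so that measurement noise cannot flip the
class; the class probability is therefore recovered exactly by the pipeline.
The endpoint is then drawn from the same orientation-weighted landmark
mixture as saccade endpoints, by rejection, conditioned on the sampled class
and on a step of 0.6-0.95 degrees - so post-saccadic microsaccades share the
saccades' landing distribution, as observed in this paradigm.

The 0.6-degree amplitude floor is a detectability calculation, not a claim
about physiology: with 0.02-degree noise at 1250 Hz the velocity filter's
noise is ~8.3 deg/s per axis, the median-based threshold sits near 28 deg/s
at $\lambda = 5$, and movements below ~0.55 degrees spend fewer than the
required 10 samples above it.  Real microsaccade amplitude distributions
extend well below this floor; any threshold detector (including the one the
real studies used) is blind there, and the simulator only emits what the
study's own detection settings could see.  This is a stated limitation:
recovery statistics on simulated data say nothing about events below the
detection floor.

### Trial-advance timing

The next trial starts at
`landing offset + gaze_feed_delay + dwell + screen update`.  The
`gaze_feed_delay` (default 8 ms) models the online gaze feed's transmission
and filtering lag: the trial-advance logic sees a delayed version of the eye,
so the display change trails the saccade's end by ~27 ms in total.  This
reproduces the paradigm's signature timing - post-saccadic microsaccades
fall in the last tens of milliseconds *before* the next trial onset, and
almost never between a trial's onset and its first saccade.  (The nominal
constants alone - entry-to-update 18 ms with latencies up to 25 ms - would
instead spill a large fraction of microsaccades past the next onset, which
is not what such experiments report; the feed lag closes that gap and is the
package's explicit modeling choice.)

### What the simulator does not emulate

No blinks, no pupil dynamics, no head movement, no binocular disparity, no
1/f noise structure (the noise is white), no images (the "scene" condition
is a label only), and no microsaccades below the detection floor.  Passing
recovery tests therefore demonstrate the correctness of the pipeline's
logic under the stated generative model - not detector performance on real
tracker noise.

## Trial metrics

`first_saccade_after_onset()` resolves, per trial, the earliest saccade
with onset at or after the trial onset and before the next trial's onset
(within the same subject and block), and flags it correct when its endpoint
lies inside the 3x3-degree window (closed boundary).  Trials without a
resolvable saccade are excluded from anchored analyses and counted in the QC
report; for the run criterion "correct" they count as incorrect.

`align_events()` expresses saccade starts, saccade ends, and microsaccade
starts relative to one of three anchors (trial onset, first-saccade onset,
first-saccade offset).  `rate_histogram()` bins a raster at 4 ms (5 samples)
by default - configurable, since figure binning is a display choice - and
reports per bin the percentage of trials with at least one event time in the
bin.  `microsaccade_count_distribution()` reports the percentage of trials
with 0, 1, or 2+ microsaccade onsets in a window (the percentages sum to
100 by construction).  The saccade-microsaccade association window after the
first saccade's offset defaults to 100 ms.

`subject_rates()` computes, per subject, total event onsets inside the
(-200, 800) ms interval around trial onsets divided by (trials x 1 s), and a
two-sided t-based 95% confidence interval across subjects.  At the task's
natural pacing (~4 trials/s) consecutive intervals overlap, so one
microsaccade counts toward several trials; this windowed definition is why
per-interval rates exceed per-trial incidence.

`eccentricity_profile()` partitions trials by eccentricity at onset
(2-degree bins from 4 to 20 degrees by default; bin edges are a choice, the
figures being emulated list eccentricities without edges) and computes a
rate histogram per bin, reporting empty bins rather than dropping them.
`direction_congruence()` classifies saccade-microsaccade pairs by the
minimal angular difference (in [0, 180]) between their polar angles, at the
45-degree boundary.

## Landmark mapping

Each trial's 7 landmarks (hair top, forehead top, left and right eye, nose
tip, mouth center, chin bottom) are fitted to the template by the
least-squares similarity transform - translation, rotation, isotropic scale,
reflection forbidden - computed in closed form in 2D.  Reflection is
forbidden because a face must not mirror; consequently inverted-condition
trials are fitted to the vertically flipped template, and cross-orientation
comparisons use the shared *feature frame*
(`map_session_endpoints(feature_frame = TRUE)` flips inverted-trial points
back), the same convention used to display inverted-face maps.  Degenerate
landmark sets (coincident or collinear) are rejected.

Inclusion filters mirror the paradigm's analysis rules: saccades are mapped
only if their endpoint lies in the 3x3 window; microsaccades only if both
start and end do.  Points exactly on the window edge are included.

Endpoint maps bin mapped points on a pixel grid at 22/1440 ~= 0.0153
degrees per pixel, so the 5x5-pixel smoothing kernel subtends ~0.076
degrees.  The kernel is the discrete disk inside a 5x5 window - the 13 cells
within Euclidean radius 2 - with uniform weight 1/13; under zero padding the
map's mass equals the binned point count minus the mass smoothed across the
grid edge, which is reported.  `fit_endpoint_gaussian()` provides the
maximum-likelihood normalized 2D Gaussian of the raw endpoints - the map
rendering used in this literature - and its center serves as the robust
definition of a map's peak (the raw argmax pixel of a sparse smoothed map is
sampling noise).  `compare_landing_distributions()` reports the cosine
similarity of unit-mass maps (1 for identical shapes, exactly 0 for disjoint
support) and half the L1 distance.

## Run statistics

`maximal_runs()` counts only maximal runs of consecutive criterion-true
trials: a run of length 3 contributes nothing to lengths 1 or 2.  Runs are
computed within blocks by default (`by =` grouping) - a recalibration pause
breaks a run - since whether runs may span same-condition blocks is a
reporting choice; the grouping is configurable.  The table satisfies the
partition identity (sum of length x count plus criterion-false trials equals
total trials) for every input.

## Numerical choices and problem sizes

* Correctness and window-inclusion boundaries are closed, with a 1e-9
  tolerance against floating-point edge effects.
* Ties in peak velocity resolve to the earliest sample; `which.min`/`rle`
  conventions make all segmentations deterministic.
* The waveform exponent solver brackets $k$ in [1e-4, 400] and refuses
  main-sequence configurations implying mean/peak velocity ratios outside
  (0.02, 0.98).
* Test and validation problem sizes are chosen to keep statistical power
  high at interactive runtimes: 1,000 trials for detector recovery, 2,000
  trials for parameter recovery (binomial 99% intervals), 10,000 random
  instances for the brute-force oracle equivalences, and 1e5 samples for
  threshold-scaling checks.

## Known limitations

* The detector has no blink/artifact handling beyond the velocity criterion
  and no drift/tremor decomposition.
* The simulator's noise model is white; real trackers show colored noise and
  slow drift, which inflate median-based thresholds differently.
* Microsaccade amplitudes are emitted only in the detectable 0.6-0.95 degree
  band (see above).
* `Procrustes` fitting assumes the 7 landmarks are complete and ordered;
  there is no automatic landmark detection.
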