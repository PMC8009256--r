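#' Simulation configuration
#'
#' Builds the configuration for the synthetic gaze-trace simulator.  Defaults
#' reproduce the continuous face-search task: a monocular 1250 Hz recording on
#' a 31 x 22 degree screen, blocks of 500 trials in 4 conditions (scene or
#' plain background, upright or inverted faces), 3-degree faces with a 3x3
#' degree advance window, a 2-sample (1.6 ms) dwell criterion, and a median
#' 18 ms screen update after the eye reaches the target.
#'
#' Two target placement schemes are supported: `"full_screen"` draws each
#' target uniformly over the screen with the whole 3x3 window on-screen, and
#' `"step4deg"` places each target at `step_eccentricity` (4 degrees) from the
#' previous one at a polar angle drawn uniformly over `allowed_polar_sectors`.
#'
#' Post-saccadic microsaccades are injected with probability
#' `p_post_saccadic_microsaccade` after the saccade that lands inside the
#' target window, at a latency uniform in `microsaccade_latency_range` after
#' the saccade ends.  Their direction differs from the preceding saccade's
#' polar angle by more than 45 degrees with probability
#' `p_direction_incongruent`.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param screen_px Screen resolution in pixels, `c(width, height)`.
#' @param screen_deg Screen extent in degrees, `c(width, height)`.
#' @param face_height Face height in degrees.
#' @param target_window Side of the square advance window, degrees.
#' @param dwell_samples Samples gaze must stay in-window to advance the trial.
#' @param screen_update_latency Median display update latency, ms.
#' @param screen_update_jitter_sd SD of display update latency jitter, ms.
#' @param gaze_feed_delay Online gaze-feed lag (tracker transmission plus
#'   online filtering) entering the trial-advance clock, ms.
#' @param n_blocks Number of blocks per session.
#' @param trials_per_block Trials per block.
#' @param block_gap_ms Unrecorded recalibration pause between blocks, ms.
#' @param placement_scheme `"full_screen"` or `"step4deg"`.
#' @param step_eccentricity Step size of the `"step4deg"` scheme, degrees.
#' @param allowed_polar_sectors Matrix (or list) of `[lo, hi)` polar-angle
#'   sectors in degrees for the `"step4deg"` scheme.
#' @param p_post_saccadic_microsaccade Probability of a post-saccadic
#'   microsaccade after the landing saccade.
#' @param microsaccade_latency_range Latency range after saccade offset, ms.
#' @param micro_amplitude_range Range of microsaccade amplitudes, degrees;
#'   drawn as `min + diff * Beta(2, 2)`.  Must stay below 1 degree.
#' @param p_direction_incongruent Probability that a post-saccadic
#'   microsaccade's polar angle differs from the preceding saccade's by more
#'   than 45 degrees.
#' @param fixation_noise_sd Per-sample white position noise SD, degrees.
#' @param drift_sd Per-sample random-walk drift SD, degrees (0 disables).
#' @param main_sequence_vmax Asymptotic peak velocity of the main sequence,
#'   deg/s.
#' @param main_sequence_c Amplitude constant of the main sequence, degrees.
#' @param saccade_latency_mean,saccade_latency_sd Gamma-distributed saccade
#'   latency after trial onset, ms.
#' @param endpoint_sd SD of saccade endpoint scatter around the intended
#'   landmark, degrees.  The default 0.68 puts ~84\% of landing saccades
#'   inside the 3x3 window.
#' @param rng_seed Integer seed; the simulator is fully reproducible given it.
#'
#' @return An object of class `zg_sim_config` (a named list).
#' @seealso [simulate_session()], [detection_params()]
#' @export
#' @examples
#' cfg <- sim_config(n_blocks = 1, trials_per_block = 20)
#' cfg$sampling_rate
sim_config <- function(sampling_rate = 1250,
                       screen_px = c(2560, 1440),
                       screen_deg = c(31, 22),
                       face_height = 3,
                       target_window = 3,
                       dwell_samples = 2,
                       screen_update_latency = 18,
                       screen_update_jitter_sd = 1,
                       gaze_feed_delay = 8,
                       n_blocks = 8,
                       trials_per_block = 500,
                       block_gap_ms = 120000,
                       placement_scheme = c("full_screen", "step4deg"),
                       step_eccentricity = 4,
                       allowed_polar_sectors = rbind(c(0, 45),
                                                     c(135, 235),
                                                     c(315, 360)),
                       p_post_saccadic_microsaccade = 0.2,
                       microsaccade_latency_range = c(1, 25),
                       micro_amplitude_range = c(0.6, 0.95),
                       p_direction_incongruent = 0.84,
                       fixation_noise_sd = 0.02,
                       drift_sd = 0,
                       main_sequence_vmax = 750,
                       main_sequence_c = 8,
                       saccade_latency_mean = 150,
                       saccade_latency_sd = 30,
                       endpoint_sd = 0.68,
                       rng_seed = 1L) {
  placement_scheme <- match.arg(placement_scheme)
  if (is.list(allowed_polar_sectors)) {
    allowed_polar_sectors <- do.call(rbind, allowed_polar_sectors)
  }
  allowed_polar_sectors <- matrix(as.numeric(allowed_polar_sectors), ncol = 2)
  cfg <- list(
    sampling_rate = sampling_rate,
    screen_px = screen_px,
    screen_deg = screen_deg,
    face_height = face_height,
    target_window = target_window,
    dwell_samples = dwell_samples,
    screen_update_latency = screen_update_latency,
    screen_update_jitter_sd = screen_update_jitter_sd,
    gaze_feed_delay = gaze_feed_delay,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    block_gap_ms = block_gap_ms,
    placement_scheme = placement_scheme,
    step_eccentricity = step_eccentricity,
    allowed_polar_sectors = allowed_polar_sectors,
    p_post_saccadic_microsaccade = p_post_saccadic_microsaccade,
    microsaccade_latency_range = as.numeric(microsaccade_latency_range),
    micro_amplitude_range = as.numeric(micro_amplitude_range),
    p_direction_incongruent = p_direction_incongruent,
    fixation_noise_sd = fixation_noise_sd,
    drift_sd = drift_sd,
    main_sequence_vmax = main_sequence_vmax,
    main_sequence_c = main_sequence_c,
    saccade_latency_mean = saccade_latency_mean,
    saccade_latency_sd = saccade_latency_sd,
    endpoint_sd = endpoint_sd,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "zg_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$sampling_rate > 0,
    cfg$trials_per_block > 0,
    cfg$n_blocks > 0,
    cfg$p_post_saccadic_microsaccade >= 0,
    cfg$p_post_saccadic_microsaccade <= 1,
    cfg$p_direction_incongruent >= 0, cfg$p_direction_incongruent <= 1,
    cfg$step_eccentricity > 0,
    cfg$fixation_noise_sd >= 0,
    cfg$target_window > 0,
    cfg$main_sequence_vmax > 0, cfg$main_sequence_c > 0,
    length(cfg$screen_deg) == 2, all(cfg$screen_deg > 0),
    diff(cfg$microsaccade_latency_range) >= 0,
    all(cfg$micro_amplitude_range > 0),
    all(cfg$micro_amplitude_range < 1)
  )
  sec <- cfg$allowed_polar_sectors
  if (any(sec < 0) || any(sec > 360) || any(sec[, 2] < sec[, 1])) {
    stop("allowed_polar_sectors must be [lo, hi] ranges within [0, 360]")
  }
  ## the step scheme must be able to keep targets (plus window) on-screen
  if (cfg$placement_scheme == "step4deg") {
    half <- cfg$target_window / 2
    if (any(cfg$screen_deg / 2 - half <= cfg$step_eccentricity / 2)) {
      stop("configuration error: step4deg scheme cannot keep targets on-screen",
           " (screen too small for step_eccentricity)")
    }
  }
  invisible(cfg)
}

#' @export
print.zg_sim_config <- function(x, ...) {
  cat("<zg_sim_config>\n")
  cat(sprintf("  %d block(s) x %d trials, scheme '%s', %g Hz\n",
              x$n_blocks, x$trials_per_block, x$placement_scheme,
              x$sampling_rate))
  cat(sprintf("  p(microsaccade) = %.2f, p(incongruent) = %.2f, seed = %d\n",
              x$p_post_saccadic_microsaccade, x$p_direction_incongruent,
              x$rng_seed))
  invisible(x)
}

#' Event-detection parameters
#'
#' Parameters of the velocity-threshold detector.  The defaults are the
#' standard toolbox settings for 1250 Hz recordings: an elliptic threshold at
#' `lambda = 5` multiples of a median-based noise SD per velocity axis, a
#' minimum event duration of 10 samples (8 ms at 1250 Hz), and classification
#' of every detected event with amplitude below 1 degree as a microsaccade.
#'
#' @param lambda Threshold multiplier applied to the median-based noise SD.
#' @param min_duration_samples Minimum number of supra-threshold samples.
#' @param microsaccade_max_amplitude Saccade/microsaccade split, degrees.
#' @param merge_gap_samples Sub-threshold gaps of at most this many samples
#'   between supra-threshold runs are merged before the duration test.
#' @param magnitude Definition of event magnitude: `"extent"` (component-wise
#'   max minus min over the event, the toolbox convention) or
#'   `"displacement"` (onset-to-offset distance).
#'
#' @return An object of class `zg_detection_params`.
#' @export
#' @examples
#' detection_params()
detection_params <- function(lambda = 5,
                             min_duration_samples = 10,
                             microsaccade_max_amplitude = 1,
                             merge_gap_samples = 2,
                             magnitude = c("extent", "displacement")) {
  magnitude <- match.arg(magnitude)
  stopifnot(lambda > 0, min_duration_samples >= 1,
            microsaccade_max_amplitude > 0, merge_gap_samples >= 0)
  structure(list(lambda = lambda,
                 min_duration_samples = as.integer(min_duration_samples),
                 microsaccade_max_amplitude = microsaccade_max_amplitude,
                 merge_gap_samples = as.integer(merge_gap_samples),
                 magnitude = magnitude),
            class = "zg_detection_params")
}

#' @export
print.zg_detection_params <- function(x, ...) {
  cat(sprintf(
    "<zg_detection_params> lambda = %g, min duration = %d samples,\n",
    x$lambda, x$min_duration_samples))
  cat(sprintf("  microsaccade split at %g deg, merge gap %d samples, %s magnitude\n",
              x$microsaccade_max_amplitude, x$merge_gap_samples, x$magnitude))
  invisible(x)
}
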