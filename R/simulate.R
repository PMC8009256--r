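#' Simulate one recording session of the continuous search task
#'
#' Generates a continuous monocular gaze recording, a trial log, and a
#' ground-truth event log for one simulated subject performing the continuous
#' face-search task: each trial presents a 3-degree face; the subject saccades
#' to it after a Gamma-distributed latency; if the landing point misses the
#' 3x3 degree window a corrective saccade follows; with probability
#' `p_post_saccadic_microsaccade` a small corrective microsaccade is launched
#' 1-25 ms after the landing saccade; and the next trial appears after the
#' online gaze feed confirms window entry plus the dwell and screen-update
#' latencies.
#'
#' Blocks are recorded as separate contiguous segments (the recalibration
#' pause between blocks is not recorded), with the block's condition assigned
#' from the subject's counterbalanced ordering of the 4 conditions.
#'
#' @param config A [sim_config()] object.
#' @param subject Subject index; selects the counterbalance ordering and is
#'   recorded in the outputs.
#' @return An object of class `zg_session`: a list with
#'   * `recording`: data frame `t_ms`, `x_deg`, `y_deg`, `block`
#'     (class `zg_gaze`, attribute `sampling_rate`),
#'   * `trials`: one row per trial (onset, target center, 7 landmark
#'     coordinate pairs, condition, orientation, eccentricity at onset),
#'   * `truth`: ground-truth event log (onset/offset at the 20 deg/s speed
#'     crossings of the injected waveform, start/end positions, amplitude,
#'     model peak velocity, polar angle, class by the 1-degree rule, role),
#'   * `config`.
#' @seealso [simulate_cohort()], [detect_saccades()]
#' @export
#' @examples
#' s <- simulate_session(sim_config(n_blocks = 1, trials_per_block = 5))
#' nrow(s$trials)
simulate_session <- function(config = sim_config(), subject = 1L) {
  validate_sim_config(config)
  set.seed(config$rng_seed)
  dt <- 1000 / config$sampling_rate
  half <- config$target_window / 2
  lat_shape <- (config$saccade_latency_mean / config$saccade_latency_sd)^2
  lat_scale <- config$saccade_latency_sd^2 / config$saccade_latency_mean
  ord <- condition_orderings()[((subject - 1L) %% 24L) + 1L, ]
  block_cond <- zg_conditions()[rep(ord, length.out = config$n_blocks), ]

  rec_list <- vector("list", config$n_blocks)
  trial_rows <- vector("list", config$n_blocks)
  event_rows <- list()
  t0 <- 0
  trial_id <- 0L

  for (b in seq_len(config$n_blocks)) {
    orientation <- block_cond$orientation[b]
    condition <- block_cond$condition[b]
    w_mix <- zg_landmark_weights(orientation)
    xs <- list(); ys <- list()
    cursor <- 0L                      # samples appended so far in this block
    time_at <- function(cur) t0 + cur * dt   # time of the next sample
    cur_pos <- c(0, 0)
    prev_center <- c(0, 0)
    scheduled_onset <- t0 + 250      # lead-in fixation before the first trial
    btrials <- vector("list", config$trials_per_block)
    bevents <- list()

    for (i in seq_len(config$trials_per_block)) {
      trial_id <- trial_id + 1L
      onset_ms <- max(scheduled_onset, time_at(cursor))
      target <- sample_target_position(prev_center, config = config)
      lms <- zg_trial_landmarks(target, orientation, config$face_height)
      ecc <- sqrt(sum((cur_pos - target)^2))
      latency <- rgamma(1, shape = lat_shape, scale = lat_scale)

      ## fixation until the first saccade launches
      n_fix <- max(0L, as.integer(round((onset_ms + latency - time_at(cursor)) / dt)))
      if (n_fix > 0) {
        xs[[length(xs) + 1L]] <- rep(cur_pos[1], n_fix)
        ys[[length(ys) + 1L]] <- rep(cur_pos[2], n_fix)
        cursor <- cursor + n_fix
      }

      ## targeting saccade, plus correctives until the window is reached
      in_window <- FALSE
      n_corrective <- 0L
      landing <- NULL
      first <- TRUE
      while (!in_window) {
        if (first) {
          ## saccades are not launched at sub-degree targets (foveal dead
          ## zone); re-draw the scatter if the implied movement is tiny
          for (tries in seq_len(100)) {
            label <- sample(zg_landmark_names, 1, prob = w_mix)
            endpoint <- lms[label, ] + rnorm(2, 0, config$endpoint_sd)
            if (sqrt(sum((endpoint - cur_pos)^2)) >= 1.05) break
          }
          role <- "targeting"
        } else {
          label <- NA_character_
          ## corrective saccades land in-window with amplitude >= 1 degree,
          ## so that the injection probability alone governs microsaccades
          tries <- 0L
          repeat {
            endpoint <- target + rnorm(2, 0, 0.4)
            tries <- tries + 1L
            if (all(abs(endpoint - target) <= half) &&
                (sqrt(sum((endpoint - cur_pos)^2)) >= 1.05 || tries > 200L))
              break
          }
          role <- "corrective"
          n_corrective <- n_corrective + 1L
          gap <- rgamma(1, shape = lat_shape, scale = lat_scale)
          n_gap <- max(1L, as.integer(round(gap / dt)))
          xs[[length(xs) + 1L]] <- rep(cur_pos[1], n_gap)
          ys[[length(ys) + 1L]] <- rep(cur_pos[2], n_gap)
          cursor <- cursor + n_gap
        }
        amp <- sqrt(sum((endpoint - cur_pos)^2))
        dir <- (atan2(endpoint[2] - cur_pos[2], endpoint[1] - cur_pos[1]) *
                  180 / pi) %% 360
        wave <- synthesize_saccade(amp, dir, config)
        start_ms <- time_at(cursor)
        xs[[length(xs) + 1L]] <- cur_pos[1] + wave[, 1]
        ys[[length(ys) + 1L]] <- cur_pos[2] + wave[, 2]
        cursor <- cursor + nrow(wave)
        cr <- attr(wave, "crossing_ms")
        ev <- list(trial_id = trial_id, block = b,
                   class = if (amp < 1) "microsaccade" else "saccade",
                   role = role,
                   onset_ms = start_ms + cr[1], offset_ms = start_ms + cr[2],
                   x_start = cur_pos[1], y_start = cur_pos[2],
                   x_end = endpoint[1], y_end = endpoint[2],
                   amplitude = amp,
                   peak_velocity = attr(wave, "peak_velocity"),
                   polar_angle = dir, landmark = label,
                   congruent = NA)
        bevents[[length(bevents) + 1L]] <- ev
        cur_pos <- endpoint
        landing <- list(dir = dir, end_ms = start_ms + attr(wave, "duration_ms"))
        in_window <- all(abs(endpoint - target) <= half)
        first <- FALSE
        if (n_corrective > 6L) stop("simulator failed to reach target window")
      }

      ## post-saccadic microsaccade after the landing saccade
      micro <- draw_post_saccadic_microsaccade(cur_pos, landing$dir, config,
                                               landmarks = lms,
                                               weights = w_mix)
      if (!is.null(micro)) {
        n_gap <- max(0L, as.integer(round((landing$end_ms + micro$latency_ms -
                                             time_at(cursor)) / dt)))
        if (n_gap > 0) {
          xs[[length(xs) + 1L]] <- rep(cur_pos[1], n_gap)
          ys[[length(ys) + 1L]] <- rep(cur_pos[2], n_gap)
          cursor <- cursor + n_gap
        }
        wave <- synthesize_saccade(micro$amplitude, micro$direction, config)
        start_ms <- time_at(cursor)
        xs[[length(xs) + 1L]] <- cur_pos[1] + wave[, 1]
        ys[[length(ys) + 1L]] <- cur_pos[2] + wave[, 2]
        cursor <- cursor + nrow(wave)
        cr <- attr(wave, "crossing_ms")
        bevents[[length(bevents) + 1L]] <- list(
          trial_id = trial_id, block = b, class = "microsaccade",
          role = "post_saccadic",
          onset_ms = start_ms + cr[1], offset_ms = start_ms + cr[2],
          x_start = cur_pos[1], y_start = cur_pos[2],
          x_end = micro$endpoint[1], y_end = micro$endpoint[2],
          amplitude = micro$amplitude,
          peak_velocity = attr(wave, "peak_velocity"),
          polar_angle = micro$direction, landmark = NA_character_,
          congruent = micro$congruent)
        cur_pos <- micro$endpoint
      }

      ## the online feed confirms entry, then dwell + screen update
      update <- max(0, rnorm(1, config$screen_update_latency,
                             config$screen_update_jitter_sd))
      scheduled_onset <- landing$end_ms + config$gaze_feed_delay +
        config$dwell_samples * dt + update
      prev_center <- target

      btrials[[i]] <- c(list(trial_id = trial_id, subject = subject, block = b,
                             trial_in_block = i, onset_ms = onset_ms,
                             target_x = target[1], target_y = target[2],
                             condition = condition, orientation = orientation,
                             ecc_deg = ecc, n_corrective = n_corrective),
                        as.list(structure(as.vector(t(lms)),
                                          names = paste0(rep(zg_landmark_names,
                                                             each = 2),
                                                         c("_x", "_y")))))
    }

    ## trailing fixation, then assemble the block's samples with noise
    n_tail <- as.integer(round(200 / dt))
    xs[[length(xs) + 1L]] <- rep(cur_pos[1], n_tail)
    ys[[length(ys) + 1L]] <- rep(cur_pos[2], n_tail)
    cursor <- cursor + n_tail
    x <- unlist(xs, use.names = FALSE)
    y <- unlist(ys, use.names = FALSE)
    n <- length(x)
    if (config$fixation_noise_sd > 0) {
      x <- x + rnorm(n, 0, config$fixation_noise_sd)
      y <- y + rnorm(n, 0, config$fixation_noise_sd)
    }
    if (config$drift_sd > 0) {
      x <- x + cumsum(rnorm(n, 0, config$drift_sd))
      y <- y + cumsum(rnorm(n, 0, config$drift_sd))
    }
    rec_list[[b]] <- data.frame(t_ms = t0 + (seq_len(n) - 1) * dt,
                                x_deg = x, y_deg = y, block = b)
    trial_rows[[b]] <- do.call(rbind, lapply(btrials, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    event_rows[[b]] <- do.call(rbind, lapply(bevents, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    t0 <- t0 + n * dt + config$block_gap_ms
  }

  recording <- do.call(rbind, rec_list)
  attr(recording, "sampling_rate") <- config$sampling_rate
  class(recording) <- c("zg_gaze", "data.frame")
  truth <- do.call(rbind, event_rows)
  truth <- truth[order(truth$onset_ms), , drop = FALSE]
  rownames(truth) <- NULL
  truth$subject <- subject
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  structure(list(recording = recording, trials = trials, truth = truth,
                 config = config),
            class = "zg_session")
}

#' @export
print.zg_session <- function(x, ...) {
  cat(sprintf("<zg_session> %d trials in %d block(s), %d samples, %d ground-truth events\n",
              nrow(x$trials), x$config$n_blocks, nrow(x$recording),
              nrow(x$truth)))
  cat(sprintf("  %d saccades, %d microsaccades (ground truth)\n",
              sum(x$truth$class == "saccade"),
              sum(x$truth$class == "microsaccade")))
  invisible(x)
}

#' Draw a post-saccadic microsaccade
#'
#' With probability `p_post_saccadic_microsaccade`, draws the parameters of a
#' small corrective microsaccade launched after a saccade that landed inside
#' the target window: a latency uniform over `microsaccade_latency_range`
#' after the saccade's end, an amplitude inside `micro_amplitude_range`
#' (below 1 degree), and a direction whose polar angle differs from the
#' preceding saccade's by more than 45 degrees with probability
#' `p_direction_incongruent` (a 10-degree guard band is left around the
#' 45-degree class boundary so that measurement noise cannot flip the
#' class).
#'
#' When the trial's `landmarks` are supplied, the endpoint is drawn from the
#' same orientation-weighted landmark mixture as saccade endpoints,
#' conditioned (by rejection) on the sampled congruence class and on a step
#' inside the amplitude range - so post-saccadic microsaccades share the
#' saccades' landing distribution while the congruence probability stays
#' exact.  Without landmarks (or when rejection fails), the endpoint is the
#' landing point plus a step in the sampled direction.
#'
#' @param saccade_end Landing position of the preceding saccade, `c(x, y)`
#'   degrees (inside the target window).
#' @param saccade_angle Polar angle of the preceding saccade, degrees.
#' @param config A [sim_config()] object.
#' @param landmarks Optional 7 x 2 matrix of the trial's landmarks.
#' @param weights Optional mixture weights over the landmarks.
#' @return `NULL` (no microsaccade emitted) or a list with `latency_ms`,
#'   `amplitude`, `direction`, `endpoint`, `congruent` (`TRUE` when the
#'   angular difference to the saccade is at most 45 degrees).
#' @export
draw_post_saccadic_microsaccade <- function(saccade_end, saccade_angle,
                                            config, landmarks = NULL,
                                            weights = NULL) {
  if (runif(1) >= config$p_post_saccadic_microsaccade) return(NULL)
  lat <- runif(1, config$microsaccade_latency_range[1],
               config$microsaccade_latency_range[2])
  incongruent <- runif(1) < config$p_direction_incongruent
  amin <- config$micro_amplitude_range[1]
  amax <- config$micro_amplitude_range[2]
  if (!is.null(landmarks)) {
    if (is.null(weights)) weights <- rep(1 / nrow(landmarks), nrow(landmarks))
    for (i in seq_len(200)) {
      lab <- sample.int(nrow(landmarks), 1, prob = weights)
      cand <- landmarks[lab, ] + rnorm(2, 0, config$endpoint_sd)
      d <- sqrt(sum((cand - saccade_end)^2))
      if (d < amin || d > amax) next
      ang <- (atan2(cand[2] - saccade_end[2], cand[1] - saccade_end[1]) *
                180 / pi) %% 360
      dd <- angular_difference(ang, saccade_angle)
      ## guarded class sectors: incongruent (50, 180], congruent [0, 40)
      if ((incongruent && dd > 50) || (!incongruent && dd < 40)) {
        return(list(latency_ms = lat, amplitude = d, direction = ang,
                    endpoint = unname(cand), congruent = dd <= 45))
      }
    }
  }
  ## fallback: step from the landing point in a class-consistent direction
  u <- if (incongruent) runif(1, 50, 180) else runif(1, 0, 40)
  dir_m <- (saccade_angle + sample(c(-1, 1), 1) * u) %% 360
  a <- amin + (amax - amin) * rbeta(1, 2, 2)
  list(latency_ms = lat, amplitude = a, direction = dir_m,
       endpoint = saccade_end + a * c(cos(dir_m * pi / 180),
                                      sin(dir_m * pi / 180)),
       congruent = u <= 45)
}

#' Simulate a cohort of subjects
#'
#' Runs [simulate_session()] once per subject with per-subject seeds
#' (`rng_seed + subject - 1`) and per-subject counterbalance orderings, and
#' returns combined trial and ground-truth tables with a `subject` column.
#'
#' @param n_subjects Number of subjects.
#' @param config A [sim_config()] object.
#' @param keep_recordings Keep each session's raw recording (memory-heavy for
#'   large cohorts).
#' @return An object of class `zg_cohort`: list with `sessions` (when kept),
#'   `trials`, `truth`, `config`, `n_subjects`.
#' @export
simulate_cohort <- function(n_subjects, config = sim_config(),
                            keep_recordings = TRUE) {
  stopifnot(n_subjects >= 1)
  sessions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$rng_seed <- config$rng_seed + s - 1L
    sessions[[s]] <- simulate_session(cfg, subject = s)
  }
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  truth <- do.call(rbind, lapply(sessions, `[[`, "truth"))
  ## make trial ids unique across subjects
  offs <- cumsum(c(0, head(vapply(sessions, function(z) nrow(z$trials), 0L), -1)))
  trials$trial_id <- trials$trial_id + rep(offs, vapply(sessions, function(z)
    nrow(z$trials), 0L))
  truth$trial_id <- truth$trial_id + rep(offs, vapply(sessions, function(z)
    nrow(z$truth), 0L))
  if (!keep_recordings) sessions <- NULL
  structure(list(sessions = sessions, trials = trials, truth = truth,
                 config = config, n_subjects = n_subjects),
            class = "zg_cohort")
}
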