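## Pipeline orchestration and file I/O.
##
## CSV schemas (all angles in degrees, all times in ms):
##   gaze:   t_ms, x_deg, y_deg, block
##   trials: trial_id, subject, block, onset_ms, target_x, target_y,
##           condition, orientation, ecc_deg, 7 landmark coordinate pairs
##   events: one row per event with onset/offset, kinematics, class

#' Read / write pipeline tables
#'
#' Thin CSV readers/writers for the pipeline's tables with schema checks.
#'
#' @param path File path.
#' @param x Table to write.
#' @param sampling_rate Sampling rate recorded with a gaze table.
#' @return `read_gaze_csv` returns a `zg_gaze` data frame; the other readers
#'   return plain data frames; writers return the path invisibly.
#' @name zapgaze-io
NULL

#' @rdname zapgaze-io
#' @export
read_gaze_csv <- function(path, sampling_rate = NULL) {
  d <- read.csv(path, comment.char = "#")
  need <- c("t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(d))) {
    stop("malformed gaze CSV '", path, "': needs columns ",
         paste(need, collapse = ", "))
  }
  if (!"block" %in% names(d)) d$block <- 1L
  if (is.null(sampling_rate)) {
    dts <- diff(d$t_ms[d$block == d$block[1]])
    sampling_rate <- 1000 / median(dts)
  }
  attr(d, "sampling_rate") <- sampling_rate
  class(d) <- c("zg_gaze", "data.frame")
  d
}

#' @rdname zapgaze-io
#' @export
write_gaze_csv <- function(x, path) {
  write.csv(as.data.frame(x)[c("t_ms", "x_deg", "y_deg",
                               intersect("block", names(x)))],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname zapgaze-io
#' @export
read_trials_csv <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("trial_id", "onset_ms", "target_x", "target_y")
  if (!all(need %in% names(d))) {
    stop("malformed trial CSV '", path, "': needs columns ",
         paste(need, collapse = ", "))
  }
  if (!"block" %in% names(d)) d$block <- 1L
  d
}

#' @rdname zapgaze-io
#' @export
read_events_csv <- function(path) {
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("onset_ms", "offset_ms", "class")
  if (!all(need %in% names(d))) {
    stop("malformed event CSV '", path, "': needs columns ",
         paste(need, collapse = ", "))
  }
  d
}

#' @rdname zapgaze-io
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' Any subset of [sim_config()] fields may appear in the file; the rest take
#' their defaults.
#'
#' @param path YAML file path.
#' @param config A `zg_sim_config`.
#' @return `read_sim_config` returns a `zg_sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  vals <- unclass(config)
  vals$allowed_polar_sectors <- apply(config$allowed_polar_sectors, 1,
                                      as.numeric, simplify = FALSE)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> detect -> align/analyze -> map -> runs from a
#' single configuration and writes a figure-analog report: event tables,
#' peri-event rate histograms aligned on trial onset and on the first
#' saccade's onset and offset, microsaccade count distributions, per-subject
#' rates, an eccentricity profile, endpoint heatmap matrices (upright and
#' inverted, saccades and microsaccades), maximal-run tables, and a QC JSON
#' (unresolved trials, detector thresholds, Procrustes residuals, heatmap
#' boundary mass).  Outputs are deterministic given the configuration seed.
#'
#' @param config A [sim_config()] object (or path to a YAML file).
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of simulated subjects.
#' @param params [detection_params()] for the detector stage.
#' @param use_ground_truth Bypass detection and pipe the simulator's
#'   ground-truth events through the analyses (validation mode).
#' @param write_gaze Write the raw gaze CSV (large).
#' @return Invisibly, a list with the in-memory results (`trials`, `events`,
#'   `metrics`, `maps`, `runs`, `qc`) and `out_dir`.
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(n_blocks = 2, trials_per_block = 100)
#' res <- run_pipeline(cfg, out_dir = tempfile("zg"), n_subjects = 2)
#' names(res$metrics)
#' }
run_pipeline <- function(config = sim_config(), out_dir = "zapgaze_report",
                         n_subjects = 2, params = detection_params(),
                         use_ground_truth = FALSE, write_gaze = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_cohort(n_subjects, config)
  trials <- cohort$trials

  if (use_ground_truth) {
    events <- cohort$truth
    thresholds <- NULL
  } else {
    evs <- vector("list", n_subjects)
    thresholds <- list()
    for (s in seq_len(n_subjects)) {
      ev <- detect_saccades(cohort$sessions[[s]]$recording, params)
      thresholds[[s]] <- attr(ev, "thresholds")
      ev$subject <- s
      evs[[s]] <- as.data.frame(ev)
    }
    events <- do.call(rbind, evs)
    events <- assign_events_to_trials(trials, events)
  }

  first_sacc <- first_saccade_after_onset(trials, events,
                                          config$target_window)

  metrics <- list()
  for (anchor in c("trial_onset", "first_saccade_onset",
                   "first_saccade_offset")) {
    r <- align_events(trials, events, anchor, c(-100, 100), first_sacc)
    metrics[[paste0("rates_", anchor)]] <- rate_histogram(r, 4)
  }
  metrics$counts_pre_onset <- microsaccade_count_distribution(
    trials, events, c(-100, 0), "trial_onset")
  metrics$counts_post_onset <- microsaccade_count_distribution(
    trials, events, c(0, 100), "trial_onset")
  metrics$counts_post_offset <- microsaccade_count_distribution(
    trials, events, c(0, 100), "first_saccade_offset", first_sacc)
  metrics$subject_rates_microsaccade <-
    subject_rates(trials, events, kind = "microsaccade")
  metrics$subject_rates_saccade <-
    subject_rates(trials, events, kind = "saccade")
  metrics$direction <- direction_congruence(first_sacc, events, trials)
  ecc_hi <- min(20, ceiling(max(trials$ecc_deg)))
  metrics$eccentricity <- if (ecc_hi > 5) {
    eccentricity_profile(trials, events, seq(4, max(6, ecc_hi), 2))
  } else NULL

  ev_map <- if ("trial_id" %in% names(events)) events else
    assign_events_to_trials(trials, events)
  maps <- map_session_endpoints(trials, ev_map, config$face_height,
                                config$target_window)
  heatmaps <- list()
  for (ori in c("upright", "inverted")) {
    for (cls in c("saccades", "microsaccades")) {
      pts <- maps[[cls]][maps[[cls]]$orientation == ori, c("x", "y")]
      heatmaps[[paste(ori, cls, sep = "_")]] <-
        endpoint_heatmap(as.matrix(pts))
    }
  }

  runs <- list()
  for (crit in c("correct", "microsaccade_free")) {
    fl <- trial_flags(trials, events, crit, first_sacc = first_sacc)
    runs[[crit]] <- maximal_runs(
      fl, by = paste(trials$subject, trials$block), criterion = crit)
  }

  qc <- list(
    n_trials = nrow(trials),
    n_events = nrow(events),
    n_saccades = sum(events$class == "saccade"),
    n_microsaccades = sum(events$class == "microsaccade"),
    n_unresolved_trials = sum(!first_sacc$resolved),
    fraction_correct = mean(first_sacc$correct),
    targeting_rate_hz = targeting_rate(trials[trials$subject == 1, ]),
    detector_thresholds = thresholds,
    procrustes_residual_rms = mean(maps$residuals$residual_rms),
    heatmap_boundary_loss = vapply(heatmaps, `[[`, 0, "boundary_loss"),
    config = list(sampling_rate = config$sampling_rate,
                  lambda = params$lambda,
                  min_duration_samples = params$min_duration_samples,
                  seed = config$rng_seed)
  )

  ## write the report
  write_table_csv(trials, file.path(out_dir, "trials.csv"))
  write_table_csv(events, file.path(out_dir, "events.csv"))
  write_table_csv(first_sacc, file.path(out_dir, "first_saccades.csv"))
  for (nm in grep("^rates_", names(metrics), value = TRUE)) {
    write_table_csv(metrics[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  for (nm in grep("^counts_", names(metrics), value = TRUE)) {
    write_table_csv(metrics[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  write_table_csv(metrics$subject_rates_microsaccade$per_subject,
                  file.path(out_dir, "subject_rates_microsaccade.csv"))
  for (nm in names(heatmaps)) {
    write_table_csv(as.data.frame(heatmaps[[nm]]$density),
                    file.path(out_dir, paste0("heatmap_", nm, ".csv")))
  }
  for (crit in names(runs)) {
    write_table_csv(as.data.frame(runs[[crit]]),
                    file.path(out_dir, paste0("runs_", crit, ".csv")))
  }
  if (write_gaze && !is.null(cohort$sessions)) {
    write_gaze_csv(cohort$sessions[[1]]$recording,
                   file.path(out_dir, "gaze_subject1.csv"))
  }
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)

  invisible(list(trials = trials, events = events, truth = cohort$truth,
                 first_sacc = first_sacc, metrics = metrics, maps = maps,
                 heatmaps = heatmaps, runs = runs, qc = qc,
                 out_dir = out_dir))
}
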