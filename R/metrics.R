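## Peri-event trial metrics: anchor resolution, rasters, rate histograms,
## count distributions, rates, eccentricity profiles, direction congruence.
##
## All functions accept either detected events (zg_events) or the simulator's
## ground-truth log - both carry onset_ms/offset_ms/class/polar_angle and
## endpoint columns, so detection can be bypassed for validation.

zg_subject_of <- function(d) {
  if ("subject" %in% names(d)) d$subject else rep(1L, nrow(d))
}

## minimal angular difference in [0, 180]
angular_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' First saccade after trial onset
#'
#' Resolves, per trial, the first event of class `"saccade"` whose onset lies
#' at or after the trial onset and before the next trial's onset (within the
#' same subject and block), together with a correctness flag: whether its
#' endpoint lies inside the 3x3-degree window centered on the target
#' (closed boundary).
#'
#' @param trials Trial log (from [simulate_session()] or a trial CSV):
#'   columns `trial_id`, `onset_ms`, `target_x`, `target_y`, `block`,
#'   optional `subject`.
#' @param events Event table (detected or ground truth), columns `onset_ms`,
#'   `offset_ms`, `class`, `polar_angle`, `x_end`, `y_end`, optional
#'   `subject`.
#' @param target_window Window side in degrees.
#' @return Data frame, one row per trial: `trial_id`, `resolved`,
#'   `sacc_onset_ms`, `sacc_offset_ms`, `sacc_angle`, `x_end`, `y_end`,
#'   `correct` (`FALSE` when unresolved).
#' @export
first_saccade_after_onset <- function(trials, events, target_window = 3) {
  half <- target_window / 2
  n <- nrow(trials)
  out <- data.frame(trial_id = trials$trial_id, resolved = FALSE,
                    sacc_onset_ms = NA_real_, sacc_offset_ms = NA_real_,
                    sacc_angle = NA_real_, x_end = NA_real_, y_end = NA_real_,
                    correct = FALSE)
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  for (s in unique(tsub)) {
    trs <- which(tsub == s)
    sac <- events[esub == s & events$class == "saccade", , drop = FALSE]
    if (nrow(sac) == 0) next
    sac <- sac[order(sac$onset_ms), , drop = FALSE]
    for (b in unique(trials$block[trs])) {
      tb <- trs[trials$block[trs] == b]
      tb <- tb[order(trials$onset_ms[tb])]
      onsets <- trials$onset_ms[tb]
      nexts <- c(onsets[-1], Inf)
      ## first saccade with onset in [onset, next onset)
      pos <- findInterval(onsets, sac$onset_ms, left.open = TRUE) + 1L
      ok <- pos <= nrow(sac) & sac$onset_ms[pos] < nexts
      ## findInterval(left.open) puts onset-coincident saccades at pos
      hit <- tb[ok]
      p <- pos[ok]
      out$resolved[hit] <- TRUE
      out$sacc_onset_ms[hit] <- sac$onset_ms[p]
      out$sacc_offset_ms[hit] <- sac$offset_ms[p]
      out$sacc_angle[hit] <- sac$polar_angle[p]
      out$x_end[hit] <- sac$x_end[p]
      out$y_end[hit] <- sac$y_end[p]
      eps <- 1e-9
      out$correct[hit] <-
        abs(sac$x_end[p] - trials$target_x[hit]) <= half + eps &
        abs(sac$y_end[p] - trials$target_y[hit]) <= half + eps
    }
  }
  out
}

#' Align events to a per-trial anchor
#'
#' Expresses event times relative to a per-trial anchor - the trial onset,
#' or the onset/offset of the first saccade after trial onset - and keeps
#' those falling inside the window.  Three event kinds are aligned:
#' saccade starts, saccade ends, and microsaccade starts.  Trials whose
#' anchor cannot be resolved are excluded and counted.
#'
#' @param trials Trial log.
#' @param events Event table (detected or ground truth).
#' @param anchor `"trial_onset"`, `"first_saccade_onset"`, or
#'   `"first_saccade_offset"`.
#' @param window `c(start_ms, end_ms)` relative to the anchor.
#' @param first_sacc Optional precomputed [first_saccade_after_onset()]
#'   result (recomputed when needed).
#' @return Object of class `zg_raster`: list with `times` (data frame
#'   `trial_id`, `rel_ms`, `kind`), `anchor`, `window`, `n_trials`,
#'   `n_unresolved`, `trial_ids` (the anchored trials).
#' @export
align_events <- function(trials, events,
                         anchor = c("trial_onset", "first_saccade_onset",
                                    "first_saccade_offset"),
                         window = c(-100, 100), first_sacc = NULL) {
  anchor <- match.arg(anchor)
  if (nrow(trials) == 0) stop("empty trial set")
  stopifnot(length(window) == 2, window[2] > window[1])
  if (anchor == "trial_onset") {
    anchors <- trials$onset_ms
    keep <- rep(TRUE, nrow(trials))
  } else {
    if (is.null(first_sacc)) first_sacc <- first_saccade_after_onset(trials, events)
    anchors <- if (anchor == "first_saccade_onset") first_sacc$sacc_onset_ms
               else first_sacc$sacc_offset_ms
    keep <- first_sacc$resolved
  }
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  kinds <- list(saccade_start = list(cls = "saccade", col = "onset_ms"),
                saccade_end = list(cls = "saccade", col = "offset_ms"),
                microsaccade_start = list(cls = "microsaccade", col = "onset_ms"))
  rows <- list()
  for (s in unique(tsub)) {
    trs <- which(tsub == s & keep)
    if (!length(trs)) next
    es <- events[esub == s, , drop = FALSE]
    for (kn in names(kinds)) {
      tt <- sort(es[[kinds[[kn]]$col]][es$class == kinds[[kn]]$cls])
      if (!length(tt)) next
      lo <- findInterval(anchors[trs] + window[1], tt, left.open = TRUE) + 1L
      hi <- findInterval(anchors[trs] + window[2], tt)
      for (j in seq_along(trs)) {
        if (hi[j] >= lo[j]) {
          rel <- tt[lo[j]:hi[j]] - anchors[trs[j]]
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = trials$trial_id[trs[j]], rel_ms = rel, kind = kn)
        }
      }
    }
  }
  times <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = integer(0), rel_ms = numeric(0), kind = character(0))
  structure(list(times = times, anchor = anchor, window = window,
                 n_trials = sum(keep), n_unresolved = sum(!keep),
                 trial_ids = trials$trial_id[keep]),
            class = "zg_raster")
}

#' @export
print.zg_raster <- function(x, ...) {
  cat(sprintf("<zg_raster> anchor %s, window [%g, %g] ms, %d trials (%d unresolved)\n",
              x$anchor, x$window[1], x$window[2], x$n_trials, x$n_unresolved))
  print(table(x$times$kind))
  invisible(x)
}

#' Per-bin occurrence probability
#'
#' Bins an aligned raster and reports, per bin and event kind, the percentage
#' of trials with at least one event time in the bin.
#'
#' @param raster A `zg_raster` from [align_events()].
#' @param bin_width_ms Bin width; must divide the window within rounding.
#' @return Data frame: `bin_start`, `bin_mid`, and one percentage column per
#'   event kind (`saccade_start`, `saccade_end`, `microsaccade_start`),
#'   values in `[0, 100]`.
#' @export
rate_histogram <- function(raster, bin_width_ms = 4) {
  if (bin_width_ms <= 0) stop("bin width must be positive")
  w <- raster$window
  nb <- (w[2] - w[1]) / bin_width_ms
  if (abs(nb - round(nb)) > 1e-6) {
    stop("bin width must divide the window")
  }
  nb <- as.integer(round(nb))
  out <- data.frame(bin_start = w[1] + (0:(nb - 1)) * bin_width_ms)
  out$bin_mid <- out$bin_start + bin_width_ms / 2
  nt <- max(1L, raster$n_trials)
  for (kn in c("saccade_start", "saccade_end", "microsaccade_start")) {
    d <- raster$times[raster$times$kind == kn, , drop = FALSE]
    pct <- numeric(nb)
    if (nrow(d)) {
      bin <- pmin(nb, floor((d$rel_ms - w[1]) / bin_width_ms) + 1L)
      hit <- unique(data.frame(trial = d$trial_id, bin = bin))
      tb <- table(factor(hit$bin, levels = seq_len(nb)))
      pct <- 100 * as.numeric(tb) / nt
    }
    out[[kn]] <- pct
  }
  out
}

#' Distribution of per-trial microsaccade counts
#'
#' Counts microsaccade onsets per trial inside a window around an anchor and
#' reports the percentage of trials with 0, 1, or 2+ microsaccades.
#'
#' @inheritParams align_events
#' @param window `c(start_ms, end_ms)` relative to the anchor.
#' @return Object of class `zg_count_dist`: data frame with `category`
#'   (`"0"`, `"1"`, `"2+"`) and `pct` (sums to 100); attributes `window`,
#'   `anchor`, `n_trials`.
#' @export
microsaccade_count_distribution <- function(trials, events,
                                            window = c(0, 100),
                                            anchor = "trial_onset",
                                            first_sacc = NULL) {
  r <- align_events(trials, events, anchor, window, first_sacc)
  mic <- r$times[r$times$kind == "microsaccade_start", , drop = FALSE]
  counts <- table(factor(mic$trial_id, levels = r$trial_ids))
  n <- max(1L, r$n_trials)
  pct <- c("0" = 100 * sum(counts == 0) / n,
           "1" = 100 * sum(counts == 1) / n,
           "2+" = 100 * sum(counts >= 2) / n)
  structure(data.frame(category = names(pct), pct = as.numeric(pct)),
            window = window, anchor = r$anchor, n_trials = r$n_trials,
            class = c("zg_count_dist", "data.frame"))
}

#' Per-subject event rates around trials
#'
#' Computes each subject's event rate within a fixed interval around trial
#' onset - total event onsets falling in the interval across trials, divided
#' by the number of trials times the interval length - plus the across-subject
#' mean and a two-sided t-based 95% confidence interval.
#'
#' Note that at the task's natural pacing consecutive trials' intervals
#' overlap, so a single event can be counted toward several trials; this is
#' inherent to the windowed definition.
#'
#' @param trials Trial log with a `subject` column (single subject assumed
#'   otherwise).
#' @param events Event table.
#' @param interval `c(start_ms, end_ms)` around trial onset.
#' @param kind `"microsaccade"` or `"saccade"`.
#' @param conf Confidence level.
#' @return List: `per_subject` (data frame `subject`, `rate_hz`), `mean`,
#'   `ci` (`c(lo, hi)`, `NA` with one subject), `ci_defined`.
#' @export
subject_rates <- function(trials, events, interval = c(-200, 800),
                          kind = "microsaccade", conf = 0.95) {
  width_s <- diff(interval) / 1000
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  subjects <- sort(unique(tsub))
  rates <- vapply(subjects, function(s) {
    trs <- which(tsub == s)
    tt <- sort(events$onset_ms[esub == s & events$class == kind])
    if (!length(tt)) return(0)
    lo <- findInterval(trials$onset_ms[trs] + interval[1], tt, left.open = TRUE)
    hi <- findInterval(trials$onset_ms[trs] + interval[2], tt)
    sum(hi - lo) / (length(trs) * width_s)
  }, numeric(1))
  m <- mean(rates)
  if (length(rates) >= 2 && sd(rates) > 0) {
    se <- sd(rates) / sqrt(length(rates))
    q <- qt(1 - (1 - conf) / 2, length(rates) - 1)
    ci <- c(m - q * se, m + q * se); defined <- TRUE
  } else if (length(rates) >= 2) {
    ci <- c(m, m); defined <- TRUE
  } else {
    ci <- c(NA_real_, NA_real_); defined <- FALSE
  }
  list(per_subject = data.frame(subject = subjects, rate_hz = rates),
       mean = m, ci = ci, ci_defined = defined)
}

#' Targeting rate
#'
#' Completed trials per second of active block time (block span from first
#' trial onset to last trial onset), averaged over blocks.
#'
#' @param trials Trial log for a single subject.
#' @return Faces targeted per second (numeric).
#' @export
targeting_rate <- function(trials) {
  rates <- vapply(split(trials$onset_ms, trials$block), function(o) {
    if (length(o) < 2) return(NA_real_)
    (length(o) - 1) / (diff(range(o)) / 1000)
  }, numeric(1))
  mean(rates, na.rm = TRUE)
}

#' Occurrence probabilities by target eccentricity
#'
#' Partitions trials into eccentricity-at-onset bins and computes a
#' [rate_histogram()] per bin for saccade starts, saccade ends, and
#' microsaccade starts, aligned on trial onset.
#'
#' @param trials Trial log with `ecc_deg`.
#' @param events Event table.
#' @param ecc_breaks Bin edges in degrees.
#' @param window Alignment window around trial onset, ms.
#' @param bin_width_ms Time bin width.
#' @return Object of class `zg_ecc_profile`: list with one matrix per kind
#'   (rows = eccentricity bins, columns = time bins; `NA` rows for empty
#'   bins), `n_per_bin`, `ecc_breaks`, `bin_starts`.
#' @export
eccentricity_profile <- function(trials, events, ecc_breaks = seq(4, 20, 2),
                                 window = c(-100, 300), bin_width_ms = 4) {
  nb <- length(ecc_breaks) - 1
  bin <- cut(trials$ecc_deg, ecc_breaks, include.lowest = TRUE)
  kinds <- c("saccade_start", "saccade_end", "microsaccade_start")
  ntime <- as.integer(round(diff(window) / bin_width_ms))
  mats <- lapply(kinds, function(k) matrix(NA_real_, nb, ntime))
  names(mats) <- kinds
  n_per_bin <- integer(nb)
  bin_starts <- NULL
  for (i in seq_len(nb)) {
    trs <- trials[which(as.integer(bin) == i), , drop = FALSE]
    n_per_bin[i] <- nrow(trs)
    if (nrow(trs) == 0) next
    r <- align_events(trs, events, "trial_onset", window)
    h <- rate_histogram(r, bin_width_ms)
    bin_starts <- h$bin_start
    for (k in kinds) mats[[k]][i, ] <- h[[k]]
  }
  structure(c(mats, list(n_per_bin = n_per_bin, ecc_breaks = ecc_breaks,
                         bin_starts = bin_starts, window = window)),
            class = "zg_ecc_profile")
}

#' Microsaccades preceding the first saccade
#'
#' Flags, per trial, whether any microsaccade onset falls strictly between
#' the trial onset and the onset of the first saccade after it.  In the
#' continuous search task these are nearly absent - microsaccades follow
#' saccade offsets rather than precede targeting saccades.
#'
#' @inheritParams first_saccade_after_onset
#' @param first_sacc Optional precomputed anchor resolution.
#' @return Data frame `trial_id`, `ecc_deg` (when available), `pre_micro`
#'   (logical; `NA` for unresolved trials).
#' @export
pre_saccadic_microsaccades <- function(trials, events, first_sacc = NULL) {
  if (is.null(first_sacc)) first_sacc <- first_saccade_after_onset(trials, events)
  tsub <- zg_subject_of(trials); esub <- zg_subject_of(events)
  out <- data.frame(trial_id = trials$trial_id,
                    ecc_deg = if ("ecc_deg" %in% names(trials))
                      trials$ecc_deg else NA_real_,
                    pre_micro = NA)
  for (s in unique(tsub)) {
    trs <- which(tsub == s & first_sacc$resolved)
    tt <- sort(events$onset_ms[esub == s & events$class == "microsaccade"])
    if (!length(trs)) next
    if (!length(tt)) { out$pre_micro[trs] <- FALSE; next }
    lo <- findInterval(trials$onset_ms[trs], tt)                  # t <= onset
    hi <- findInterval(first_sacc$sacc_onset_ms[trs], tt, left.open = TRUE)
    out$pre_micro[trs] <- hi > lo
  }
  out
}

#' Direction congruence of post-saccadic microsaccades
#'
#' Pairs each resolved first saccade with the microsaccades starting within
#' an association window after its offset and classifies each pair by the
#' minimal angular difference between the two polar angles: congruent
#' (at most 45 degrees) or incongruent (more than 45 degrees).
#'
#' @param first_sacc Result of [first_saccade_after_onset()].
#' @param events Event table with `polar_angle`.
#' @param trials Trial log (for subject grouping); optional when both tables
#'   are single-subject.
#' @param window_ms Association window after saccade offset.
#' @return List: `fraction_incongruent`, `fraction_congruent` (sum to 1),
#'   `n_pairs`, `defined` (`FALSE` when no pairs), `pairs` data frame
#'   (`trial_id`, `angle_diff`).
#' @export
direction_congruence <- function(first_sacc, events, trials = NULL,
                                 window_ms = 100) {
  esub <- zg_subject_of(events)
  tsub <- if (!is.null(trials)) zg_subject_of(trials) else
    rep(1L, nrow(first_sacc))
  pairs <- list()
  for (s in unique(tsub)) {
    trs <- which(tsub == s & first_sacc$resolved)
    mic <- events[esub == s & events$class == "microsaccade", , drop = FALSE]
    if (!length(trs) || !nrow(mic)) next
    mic <- mic[order(mic$onset_ms), , drop = FALSE]
    off <- first_sacc$sacc_offset_ms[trs]
    lo <- findInterval(off, mic$onset_ms) + 1L        # strictly after offset
    hi <- findInterval(off + window_ms, mic$onset_ms)
    for (j in seq_along(trs)) {
      if (hi[j] >= lo[j]) {
        dd <- angular_difference(first_sacc$sacc_angle[trs[j]],
                                 mic$polar_angle[lo[j]:hi[j]])
        pairs[[length(pairs) + 1L]] <- data.frame(
          trial_id = first_sacc$trial_id[trs[j]], angle_diff = dd)
      }
    }
  }
  if (!length(pairs)) {
    return(list(fraction_incongruent = NA_real_, fraction_congruent = NA_real_,
                n_pairs = 0L, defined = FALSE,
                pairs = data.frame(trial_id = integer(0),
                                   angle_diff = numeric(0))))
  }
  p <- do.call(rbind, pairs)
  inc <- mean(p$angle_diff > 45)
  list(fraction_incongruent = inc, fraction_congruent = 1 - inc,
       n_pairs = nrow(p), defined = TRUE, pairs = p)
}
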