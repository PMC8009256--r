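#' Compute smoothed sample velocities
#'
#' Estimates per-sample velocity with the standard 5-sample difference filter
#' `v[n] = (p[n+2] + p[n+1] - p[n-1] - p[n-2]) / (6 * dt)`, which both
#' differentiates and smooths over a 5-sample window.  The two samples at
#' each edge carry velocity 0 and are flagged so that threshold estimation
#' can exclude them.
#'
#' @param rec A gaze recording: data frame with columns `t_ms`, `x_deg`,
#'   `y_deg` (and optionally `block`), uniformly sampled; or a `zg_gaze`
#'   object from [simulate_session()].  Velocities are computed per `block`
#'   segment when the column is present.
#' @param sampling_rate Sampling rate in Hz; taken from the recording's
#'   attribute when present.
#' @return A data frame with columns `vx`, `vy` (deg/s) and logical
#'   `interior` (`FALSE` for the edge samples), one row per sample, with the
#'   sampling rate attached as an attribute.
#' @export
#' @examples
#' rec <- data.frame(t_ms = (0:99) * 0.8, x_deg = (0:99) * 0.01, y_deg = 0)
#' v <- compute_velocity(rec, sampling_rate = 1250)
#' mean(v$vx[v$interior])  # 12.5 deg/s for this linear ramp
compute_velocity <- function(rec, sampling_rate = attr(rec, "sampling_rate")) {
  if (is.null(sampling_rate)) stop("sampling_rate is required")
  blocks <- if ("block" %in% names(rec)) rec$block else rep(1L, nrow(rec))
  out_v <- matrix(0, nrow(rec), 2)
  interior <- logical(nrow(rec))
  dt <- 1 / sampling_rate   # seconds
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    n <- length(idx)
    if (n < 5) stop("each recording segment needs at least 5 samples")
    for (j in 1:2) {
      p <- rec[[c("x_deg", "y_deg")[j]]][idx]
      core <- (p[5:n] + p[4:(n - 1)] - p[2:(n - 3)] - p[1:(n - 4)]) / (6 * dt)
      out_v[idx[3:(n - 2)], j] <- core
    }
    interior[idx[3:(n - 2)]] <- TRUE
  }
  out <- data.frame(vx = out_v[, 1], vy = out_v[, 2], interior = interior)
  attr(out, "sampling_rate") <- sampling_rate
  out
}

#' Median-based velocity threshold
#'
#' Estimates the detection threshold per velocity axis as `lambda` multiples
#' of the median-based standard deviation
#' `sigma = sqrt(median(v^2) - median(v)^2)`, which is robust to the saccadic
#' outliers in the velocity distribution.
#'
#' @param vel Velocity trace from [compute_velocity()] (edge samples are
#'   excluded), or any data frame with `vx`, `vy`.
#' @param lambda Threshold multiplier.
#' @return Named numeric `c(eta_x, eta_y)` in deg/s.
#' @export
estimate_threshold <- function(vel, lambda = 5) {
  stopifnot(lambda > 0)
  keep <- if ("interior" %in% names(vel)) vel$interior else TRUE
  vx <- vel$vx[keep]; vy <- vel$vy[keep]
  if (length(vx) < 10) stop("need at least 10 interior velocity samples")
  eta <- vapply(list(vx, vy), function(v) {
    sigma2 <- median(v^2) - median(v)^2
    if (sigma2 <= 0) {
      stop("degenerate velocity noise (sigma = 0); the recording has no ",
           "measurable noise floor - add positional noise or set thresholds ",
           "manually")
    }
    lambda * sqrt(sigma2)
  }, numeric(1))
  names(eta) <- c("eta_x", "eta_y")
  eta
}

## maximal supra-threshold runs: gaps of <= merge_gap sub-threshold samples
## between runs are bridged before the minimum-duration test
zg_threshold_runs <- function(supra, min_duration, merge_gap) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) return(matrix(integer(0), ncol = 2))
  ## merge supra runs separated by short sub-threshold gaps
  merged <- list()
  cs <- starts[on[1]]; ce <- ends[on[1]]
  for (k in on[-1]) {
    if (starts[k] - ce - 1L <= merge_gap) {
      ce <- ends[k]
    } else {
      merged[[length(merged) + 1L]] <- c(cs, ce)
      cs <- starts[k]; ce <- ends[k]
    }
  }
  merged[[length(merged) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, merged)
  m[m[, 2] - m[, 1] + 1L >= min_duration, , drop = FALSE]
}

#' Detect supra-threshold velocity events
#'
#' Segments a velocity trace into ballistic events: maximal runs of samples
#' whose velocity lies outside the elliptic threshold
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`, lasting at least
#' `min_duration_samples`.  Runs separated by at most `merge_gap_samples`
#' sub-threshold samples are merged before the duration test.
#'
#' @param vel Velocity trace from [compute_velocity()].
#' @param params A [detection_params()] object.
#' @param eta Thresholds `c(eta_x, eta_y)`; estimated from `vel` with
#'   [estimate_threshold()] when omitted.
#' @return Integer matrix with columns `onset`, `offset` (sample indices into
#'   `vel`), one row per event, time-ordered and non-overlapping.  May have
#'   zero rows.
#' @export
detect_events <- function(vel, params = detection_params(), eta = NULL) {
  if (is.null(eta)) eta <- estimate_threshold(vel, params$lambda)
  supra <- (vel$vx / eta[1])^2 + (vel$vy / eta[2])^2 > 1
  supra[is.na(supra)] <- FALSE
  if ("interior" %in% names(vel)) supra[!vel$interior] <- FALSE
  m <- zg_threshold_runs(supra, params$min_duration_samples,
                         params$merge_gap_samples)
  colnames(m) <- c("onset", "offset")
  m
}

#' Classify events and measure their kinematics
#'
#' Given detected event windows, measures each event on the raw recording:
#' magnitude (component-wise max-minus-min extent by default, or
#' onset-to-offset displacement), peak velocity (earliest sample wins ties),
#' onset-to-offset displacement and polar angle, and the saccade /
#' microsaccade class by the 1-degree amplitude rule.
#'
#' @param events Integer matrix from [detect_events()] (columns `onset`,
#'   `offset`, sample indices).
#' @param rec The gaze recording the velocities were computed from.
#' @param vel The velocity trace from [compute_velocity()].
#' @param params A [detection_params()] object.
#' @return A data frame of class `zg_events` with one row per event:
#'   `onset_sample`, `offset_sample`, `onset_ms`, `offset_ms`, `duration_ms`,
#'   `x_start`, `y_start`, `x_end`, `y_end`, `magnitude`, `peak_velocity`,
#'   `polar_angle` (degrees in `[0, 360)`), `class`, `block`.
#' @export
classify_and_measure <- function(events, rec, vel,
                                 params = detection_params()) {
  sr <- attr(vel, "sampling_rate")
  dt_ms <- 1000 / sr
  n <- nrow(events)
  out <- data.frame(
    onset_sample = integer(n), offset_sample = integer(n),
    onset_ms = numeric(n), offset_ms = numeric(n), duration_ms = numeric(n),
    x_start = numeric(n), y_start = numeric(n),
    x_end = numeric(n), y_end = numeric(n),
    magnitude = numeric(n), peak_velocity = numeric(n),
    polar_angle = numeric(n), class = character(n),
    block = if ("block" %in% names(rec)) integer(n) else 1L
  )
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  for (i in seq_len(n)) {
    a <- events[i, 1]; b <- events[i, 2]
    xs <- rec$x_deg[a:b]; ys <- rec$y_deg[a:b]
    mag <- if (params$magnitude == "extent") {
      sqrt(diff(range(xs))^2 + diff(range(ys))^2)
    } else {
      sqrt((xs[length(xs)] - xs[1])^2 + (ys[length(ys)] - ys[1])^2)
    }
    dx <- xs[length(xs)] - xs[1]; dy <- ys[length(ys)] - ys[1]
    out$onset_sample[i] <- a; out$offset_sample[i] <- b
    out$onset_ms[i] <- rec$t_ms[a]; out$offset_ms[i] <- rec$t_ms[b]
    out$duration_ms[i] <- (b - a + 1) * dt_ms
    out$x_start[i] <- xs[1]; out$y_start[i] <- ys[1]
    out$x_end[i] <- xs[length(xs)]; out$y_end[i] <- ys[length(ys)]
    out$magnitude[i] <- mag
    out$peak_velocity[i] <- max(speed[a:b])
    out$polar_angle[i] <- (atan2(dy, dx) * 180 / pi) %% 360
    out$class[i] <- if (mag < params$microsaccade_max_amplitude)
      "microsaccade" else "saccade"
    if ("block" %in% names(rec)) out$block[i] <- rec$block[a]
  }
  class(out) <- c("zg_events", "data.frame")
  out
}

#' Detect and classify saccades and microsaccades in a recording
#'
#' The full detection pipeline: per recording segment (block), compute
#' 5-sample smoothed velocities, estimate the median-based elliptic threshold
#' at `lambda` multiples of the noise SD, segment supra-threshold events with
#' the minimum-duration criterion, and measure/classify each event
#' (microsaccade below 1 degree).  Thresholds are estimated per block -
#' trials are too short for stable medians.
#'
#' @param rec Gaze recording (data frame `t_ms`, `x_deg`, `y_deg`, optional
#'   `block`; `zg_gaze` objects carry their sampling rate).
#' @param params A [detection_params()] object.
#' @param sampling_rate Hz, when `rec` carries no attribute.
#' @return A `zg_events` data frame (see [classify_and_measure()]) with the
#'   per-block thresholds in `attr(, "thresholds")`.
#' @export
#' @examples
#' s <- simulate_session(sim_config(n_blocks = 1, trials_per_block = 8))
#' ev <- detect_saccades(s$recording)
#' table(ev$class)
detect_saccades <- function(rec, params = detection_params(),
                            sampling_rate = attr(rec, "sampling_rate")) {
  vel <- compute_velocity(rec, sampling_rate)
  blocks <- if ("block" %in% names(rec)) rec$block else rep(1L, nrow(rec))
  pieces <- list()
  thresholds <- list()
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    vb <- vel[idx, , drop = FALSE]
    attr(vb, "sampling_rate") <- sampling_rate
    eta <- estimate_threshold(vb, params$lambda)
    ev <- detect_events(vb, params, eta)
    ev[] <- ev + idx[1] - 1L   # back to full-recording indices
    pieces[[length(pieces) + 1L]] <- ev
    thresholds[[as.character(b)]] <- eta
  }
  events <- do.call(rbind, pieces)
  out <- classify_and_measure(events, rec, vel, params)
  attr(out, "thresholds") <- thresholds
  attr(out, "params") <- params
  out
}

#' @export
print.zg_events <- function(x, ...) {
  cat(sprintf("<zg_events> %d events: %d saccades, %d microsaccades\n",
              nrow(x), sum(x$class == "saccade"),
              sum(x$class == "microsaccade")))
  if (nrow(x)) {
    cat(sprintf("  magnitude %.2f-%.2f deg, peak velocity %.0f-%.0f deg/s\n",
                min(x$magnitude), max(x$magnitude),
                min(x$peak_velocity), max(x$peak_velocity)))
  }
  invisible(x)
}

#' Main-sequence fit
#'
#' Least-squares fit of `log10(peak velocity)` on `log10(magnitude)` over
#' detected events - the lawful amplitude/peak-velocity relation shared by
#' saccades and microsaccades.
#'
#' @param events A `zg_events` (or ground-truth) data frame with `magnitude`
#'   (or `amplitude`) and `peak_velocity` columns.
#' @return Object of class `zg_main_sequence`: list with `slope`,
#'   `intercept`, `r` (correlation of the logs), `n`, `n_excluded`
#'   (non-positive magnitudes, dropped with a warning), and the raw `pairs`.
#' @export
main_sequence <- function(events) {
  mag <- if ("magnitude" %in% names(events)) events$magnitude else
    events$amplitude
  vp <- events$peak_velocity
  bad <- !(mag > 0) | !(vp > 0) | !is.finite(mag) | !is.finite(vp)
  if (any(bad)) {
    warning(sum(bad), " event(s) with non-positive magnitude or velocity excluded")
  }
  mag <- mag[!bad]; vp <- vp[!bad]
  if (length(mag) < 2) stop("main_sequence needs at least 2 usable events")
  fit <- lm(log10(vp) ~ log10(mag))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(log10(mag), log10(vp)),
                 n = length(mag), n_excluded = sum(bad),
                 pairs = data.frame(magnitude = mag, peak_velocity = vp)),
            class = "zg_main_sequence")
}

#' @export
print.zg_main_sequence <- function(x, ...) {
  cat(sprintf(
    "<zg_main_sequence> log10(Vp) = %.3f + %.3f log10(A), r = %.3f, n = %d\n",
    x$intercept, x$slope, x$r, x$n))
  invisible(x)
}

#' @export
plot.zg_main_sequence <- function(x, ...) {
  p <- x$pairs
  cls <- ifelse(p$magnitude < 1, "microsaccade", "saccade")
  plot(p$magnitude, p$peak_velocity, log = "xy",
       col = ifelse(cls == "microsaccade", "red", "blue"), pch = 16,
       cex = 0.4, xlab = "magnitude (deg)", ylab = "peak velocity (deg/s)",
       main = "Main sequence", ...)
  abline(x$intercept, x$slope, untf = FALSE)
  legend("topleft", legend = c("microsaccade", "saccade"), bty = "n",
         col = c("red", "blue"), pch = 16)
  invisible(x)
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected events to ground-truth events by
#' onset proximity (within `tol_ms`), used to score detector recall,
#' precision, and onset error against the simulator's log.
#'
#' @param truth Ground-truth event log (from [simulate_session()]), columns
#'   `onset_ms`, `class`, `amplitude`.
#' @param events Detected `zg_events`.
#' @param tol_ms Maximum |onset difference| for a match.
#' @return List with `matches` (data frame: truth row, event row, onset error
#'   in ms), `recall`, `precision`, and per-class recall
#'   (`recall_saccade`, `recall_microsaccade`), plus
#'   `median_abs_onset_error_ms`.
#' @export
evaluate_detection <- function(truth, events, tol_ms = 12) {
  nt <- nrow(truth); ne <- nrow(events)
  used <- logical(ne)
  ti <- integer(0); ei <- integer(0); err <- numeric(0)
  ev_on <- events$onset_ms
  for (i in order(truth$onset_ms)) {
    d <- abs(ev_on - truth$onset_ms[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms) {
      used[j] <- TRUE
      ti <- c(ti, i); ei <- c(ei, j); err <- c(err, ev_on[j] - truth$onset_ms[i])
    }
  }
  is_sacc <- truth$class == "saccade"
  is_micro <- truth$class == "microsaccade"
  list(matches = data.frame(truth_row = ti, event_row = ei, onset_error_ms = err),
       recall = length(ti) / max(1L, nt),
       precision = sum(used) / max(1L, ne),
       recall_saccade = sum(ti %in% which(is_sacc)) / max(1L, sum(is_sacc)),
       recall_microsaccade = sum(ti %in% which(is_micro)) /
         max(1L, sum(is_micro)),
       median_abs_onset_error_ms = if (length(err)) median(abs(err)) else NA_real_)
}
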