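## Independent brute-force oracles used across tests.  These deliberately use
## explicit loops and naive logic, not the package's vectorized code paths.

## maximal runs of TRUE by explicit scan
brute_runs <- function(flags) {
  lens <- integer(0)
  cur <- 0L
  for (f in flags) {
    if (isTRUE(f)) {
      cur <- cur + 1L
    } else if (cur > 0L) {
      lens <- c(lens, cur)
      cur <- 0L
    }
  }
  if (cur > 0L) lens <- c(lens, cur)
  if (!length(lens)) {
    return(data.frame(length = integer(0), count = integer(0)))
  }
  tb <- table(lens)
  data.frame(length = as.integer(names(tb)), count = as.integer(tb))
}

## event segmentation by explicit scan over a boolean supra-threshold
## sequence: bridge sub-threshold gaps <= merge_gap, then apply the
## minimum-duration test
brute_detect <- function(supra, min_duration, merge_gap) {
  n <- length(supra)
  events <- list()
  i <- 1L
  while (i <= n) {
    if (supra[i]) {
      start <- i
      end <- i
      j <- i + 1L
      gap <- 0L
      while (j <= n) {
        if (supra[j]) {
          end <- j
          gap <- 0L
        } else {
          gap <- gap + 1L
          if (gap > merge_gap) break
        }
        j <- j + 1L
      }
      if (end - start + 1L >= min_duration) {
        events[[length(events) + 1L]] <- c(start, end)
      }
      i <- end + gap + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(events)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, events)
}

## central-difference speed oracle for a sampled trajectory (deg/s)
brute_peak_speed <- function(xy, dt_s) {
  n <- nrow(xy)
  vx <- (xy[3:n, 1] - xy[1:(n - 2), 1]) / (2 * dt_s)
  vy <- (xy[3:n, 2] - xy[1:(n - 2), 2]) / (2 * dt_s)
  max(sqrt(vx^2 + vy^2))
}

## naive per-trial microsaccade count in a window around an anchor
brute_count_dist <- function(onsets, anchors, window) {
  counts <- integer(length(anchors))
  for (i in seq_along(anchors)) {
    for (t in onsets) {
      r <- t - anchors[i]
      if (r >= window[1] && r <= window[2]) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

## a quick small-session config for tests
small_cfg <- function(..., seed = 7L) {
  sim_config(n_blocks = 1, trials_per_block = 30, rng_seed = seed, ...)
}

## velocity trace wrapper for hand-built vx/vy vectors
as_vel <- function(vx, vy, sampling_rate = 1250, interior = NULL) {
  d <- data.frame(vx = vx, vy = vy)
  if (!is.null(interior)) d$interior <- interior
  attr(d, "sampling_rate") <- sampling_rate
  d
}
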