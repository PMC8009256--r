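## hand-built micro-fixtures: two trials, a saccade each, one microsaccade
mk_fixture <- function() {
  trials <- data.frame(trial_id = 1:2, block = 1L, onset_ms = c(1000, 2000),
                       target_x = c(5, -3), target_y = c(2, 1),
                       ecc_deg = c(6, 4))
  events <- data.frame(
    class = c("saccade", "microsaccade", "saccade"),
    onset_ms = c(1150, 1201, 2160),
    offset_ms = c(1180, 1215, 2190),
    polar_angle = c(0, 30, 200),
    x_start = c(0, 5.2, 5.2), y_start = c(0, 2.1, 2.1),
    x_end = c(5.2, 5.5, -1.4), y_end = c(2.1, 2.2, 1.0))
  list(trials = trials, events = events)
}

test_that("first-saccade resolution applies the 3x3-degree correctness window", {
  f <- mk_fixture()
  fs <- first_saccade_after_onset(f$trials, f$events)
  expect_true(all(fs$resolved))
  ## trial 1 endpoint 0.2 deg off-center: correct
  expect_true(fs$correct[1])
  ## trial 2 endpoint at +1.6 deg in x from center: incorrect
  expect_false(fs$correct[2])
  expect_equal(fs$sacc_onset_ms, c(1150, 2160))
  ## a trial with no saccade is unresolved
  fs2 <- first_saccade_after_onset(f$trials,
                                   f$events[f$events$class != "saccade", ])
  expect_false(any(fs2$resolved))
  expect_false(any(fs2$correct))
})

test_that("alignment stores relative times and is translation invariant", {
  f <- mk_fixture()
  r <- align_events(f$trials, f$events, "first_saccade_offset", c(-50, 50))
  mic <- r$times[r$times$kind == "microsaccade_start", ]
  expect_equal(mic$rel_ms, 21)   # 1201 - 1180
  ## shifting every clock by +500 ms changes nothing
  f2 <- f
  f2$trials$onset_ms <- f2$trials$onset_ms + 500
  f2$events$onset_ms <- f2$events$onset_ms + 500
  f2$events$offset_ms <- f2$events$offset_ms + 500
  r2 <- align_events(f2$trials, f2$events, "first_saccade_offset", c(-50, 50))
  expect_equal(r$times, r2$times)
  expect_error(align_events(f$trials[0, ], f$events), "empty")
})

test_that("rate histogram puts a shared event time in one full bin", {
  trials <- data.frame(trial_id = 1:5, block = 1L,
                       onset_ms = seq(0, 4e4, 1e4),
                       target_x = 0, target_y = 0)
  events <- data.frame(class = "microsaccade",
                       onset_ms = trials$onset_ms + 10,
                       offset_ms = trials$onset_ms + 18, polar_angle = 0,
                       x_start = 0, y_start = 0, x_end = 0, y_end = 0)
  r <- align_events(trials, events, "trial_onset", c(0, 100))
  h <- rate_histogram(r, 4)
  expect_equal(h$microsaccade_start[h$bin_start == 8], 100)
  expect_equal(sum(h$microsaccade_start), 100)
  expect_true(all(h$saccade_start == 0))
  ## no events at all: all bins zero
  h0 <- rate_histogram(align_events(trials, events[0, ], "trial_onset",
                                    c(0, 100)), 4)
  expect_true(all(h0$microsaccade_start == 0))
  expect_error(rate_histogram(r, -1), "positive")
  expect_error(rate_histogram(r, 7), "divide")
})

test_that("count distribution reports thirds for 0/1/2 microsaccades", {
  trials <- data.frame(trial_id = 1:3, block = 1L,
                       onset_ms = c(0, 1e4, 2e4), target_x = 0, target_y = 0)
  events <- data.frame(class = "microsaccade",
                       onset_ms = c(1e4 + 20, 2e4 + 10, 2e4 + 60),
                       offset_ms = c(1e4 + 30, 2e4 + 20, 2e4 + 70),
                       polar_angle = 0, x_start = 0, y_start = 0,
                       x_end = 0, y_end = 0)
  cd <- microsaccade_count_distribution(trials, events, c(0, 100))
  expect_equal(cd$pct, c(100, 100, 100) / 3, tolerance = 1e-9)
  expect_equal(sum(cd$pct), 100, tolerance = 1e-9)
  ## matches the naive double loop
  counts <- brute_count_dist(events$onset_ms, trials$onset_ms, c(0, 100))
  expect_equal(cd$pct,
               100 * c(mean(counts == 0), mean(counts == 1),
                       mean(counts >= 2)))
})

test_that("zero injection yields an all-zero count distribution", {
  cfg <- sim_config(n_blocks = 1, trials_per_block = 30,
                    placement_scheme = "step4deg",
                    p_post_saccadic_microsaccade = 0, rng_seed = 3)
  s <- simulate_session(cfg)
  cd <- microsaccade_count_distribution(s$trials, s$truth, c(0, 100),
                                        "first_saccade_offset")
  expect_equal(cd$pct, c(100, 0, 0))
})

test_that("subject rates count onsets per trial-second with t-based intervals", {
  trials <- data.frame(trial_id = 1:6, subject = rep(1:2, each = 3),
                       block = 1L, onset_ms = rep(c(0, 5e3, 1e4), 2),
                       target_x = 0, target_y = 0)
  ## every trial of both subjects has exactly one microsaccade at +100 ms
  events <- data.frame(subject = rep(1:2, each = 3), class = "microsaccade",
                       onset_ms = rep(c(100, 5100, 10100), 2),
                       offset_ms = rep(c(120, 5120, 10120), 2),
                       polar_angle = 0, x_start = 0, y_start = 0,
                       x_end = 0, y_end = 0)
  sr <- subject_rates(trials, events, interval = c(-200, 800))
  expect_equal(sr$per_subject$rate_hz, c(1, 1))
  expect_equal(sr$mean, 1)
  expect_equal(sr$ci, c(1, 1))   # zero spread
  ## no events: zero rates
  sr0 <- subject_rates(trials, events[0, ], interval = c(-200, 800))
  expect_equal(sr0$per_subject$rate_hz, c(0, 0))
  ## single subject: no interval defined
  sr1 <- subject_rates(trials[trials$subject == 1, ],
                       events[events$subject == 1, ])
  expect_false(sr1$ci_defined)
})

test_that("slow-paced generator recovers the injection probability as a rate", {
  ## non-overlapping (-200, 800) windows: rate equals p per trial-second
  cfg <- sim_config(n_blocks = 1, trials_per_block = 150,
                    placement_scheme = "step4deg",
                    p_post_saccadic_microsaccade = 0.2,
                    screen_update_latency = 1100, rng_seed = 77)
  s <- simulate_session(cfg)
  s$trials$subject <- 1L
  s$truth$subject <- 1L
  sr <- subject_rates(s$trials, s$truth)
  k <- sum(s$truth$role == "post_saccadic")
  ci <- qbinom(c(0.005, 0.995), nrow(s$trials), 0.2) / nrow(s$trials)
  expect_gte(sr$per_subject$rate_hz, ci[1])
  expect_lte(sr$per_subject$rate_hz, ci[2])
  expect_equal(sr$per_subject$rate_hz, k / nrow(s$trials))
})

test_that("eccentricity profile keeps empty bins and ignores trial order", {
  f <- mk_fixture()
  trials <- f$trials
  trials$ecc_deg <- c(4.5, 4.7)   # both in the first bin
  ep <- eccentricity_profile(trials, f$events, seq(4, 10, 2),
                             window = c(-100, 100), bin_width_ms = 4)
  expect_equal(ep$n_per_bin, c(2L, 0L, 0L))
  expect_true(all(is.na(ep$saccade_start[2, ])))
  expect_false(anyNA(ep$saccade_start[1, ]))
  ep2 <- eccentricity_profile(trials[2:1, ], f$events, seq(4, 10, 2),
                              window = c(-100, 100), bin_width_ms = 4)
  expect_equal(ep$microsaccade_start, ep2$microsaccade_start)
})

test_that("direction congruence classifies wrapped angles and handles no pairs", {
  fs <- data.frame(trial_id = 1:2, resolved = TRUE,
                   sacc_onset_ms = c(0, 100), sacc_offset_ms = c(30, 130),
                   sacc_angle = c(0, 10), x_end = 0, y_end = 0,
                   correct = TRUE)
  events <- data.frame(class = "microsaccade", onset_ms = c(40, 140),
                       offset_ms = c(50, 150), polar_angle = c(30, 350),
                       x_start = 0, y_start = 0, x_end = 0, y_end = 0)
  dc <- direction_congruence(fs, events)
  ## 0 vs 30 -> 30 deg; 10 vs 350 -> 20 deg (wraparound): both congruent
  expect_equal(dc$fraction_congruent, 1)
  expect_equal(dc$fraction_incongruent, 0)
  expect_equal(dc$n_pairs, 2)
  expect_equal(dc$fraction_congruent + dc$fraction_incongruent, 1)
  dc0 <- direction_congruence(fs, events[0, ])
  expect_false(dc0$defined)
})

test_that("metrics agree with naive loops on a small ground-truth session", {
  s <- simulate_session(sim_config(n_blocks = 1, trials_per_block = 60,
                                   placement_scheme = "step4deg",
                                   rng_seed = 13))
  ## count distribution around trial onset, brute double loop
  onsets <- s$truth$onset_ms[s$truth$class == "microsaccade"]
  counts <- brute_count_dist(onsets, s$trials$onset_ms, c(-100, 0))
  cd <- microsaccade_count_distribution(s$trials, s$truth, c(-100, 0))
  expect_equal(cd$pct, 100 * c(mean(counts == 0), mean(counts == 1),
                               mean(counts >= 2)), tolerance = 1e-9)
  ## microsaccade-free flags, brute loop
  fl <- trial_flags(s$trials, s$truth, "microsaccade_free")
  brute_fl <- brute_count_dist(onsets, s$trials$onset_ms, c(-200, 800)) == 0
  expect_equal(as.logical(fl), brute_fl)
})
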