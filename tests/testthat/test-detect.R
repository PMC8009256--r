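test_that("the 5-sample velocity estimator is exact on constants and ramps", {
  rec <- data.frame(t_ms = (0:49) * 0.8, x_deg = 1.5, y_deg = -2)
  v <- compute_velocity(rec, sampling_rate = 1250)
  expect_true(all(v$vx == 0) && all(v$vy == 0))
  ## linear ramp x(t) = k t: interior velocity is exactly k
  k <- 3.7  # deg/s
  rec <- data.frame(t_ms = (0:49) * 0.8, x_deg = k * (0:49) * 0.8 / 1000,
                    y_deg = 0)
  v <- compute_velocity(rec, sampling_rate = 1250)
  expect_equal(v$vx[v$interior], rep(k, sum(v$interior)), tolerance = 1e-9)
  ## edges carry velocity zero and are flagged
  expect_equal(which(!v$interior), c(1, 2, 49, 50))
  expect_true(all(v$vx[!v$interior] == 0))
  expect_error(compute_velocity(rec[1:4, ], sampling_rate = 1250),
               "at least 5 samples")
})

test_that("smoothed peak velocity of a synthetic saccade matches a central-difference oracle", {
  cfg <- sim_config()
  w <- synthesize_saccade(10, 15, cfg)
  rec <- data.frame(t_ms = (seq_len(nrow(w) + 40) - 1) * 0.8,
                    x_deg = c(rep(0, 20), w[, 1], rep(w[nrow(w), 1], 20)),
                    y_deg = c(rep(0, 20), w[, 2], rep(w[nrow(w), 2], 20)))
  v <- compute_velocity(rec, sampling_rate = 1250)
  vp <- max(sqrt(v$vx^2 + v$vy^2))
  oracle <- brute_peak_speed(cbind(rec$x_deg, rec$y_deg), 1 / 1250)
  expect_equal(vp, oracle, tolerance = 0.02)
})

test_that("threshold estimator reproduces the literal median-based formula", {
  ## literal multiset {-1, 0, 1} repeated: median(v^2) = 1, median(v) = 0,
  ## so sigma = 1 and eta = lambda exactly
  v <- as_vel(rep(c(-1, 0, 1), 30), rep(c(-1, 0, 1), 30))
  expect_equal(unname(estimate_threshold(v, lambda = 5)), c(5, 5))
  ## homogeneity: scaling the samples scales eta exactly
  v2 <- as_vel(2 * rep(c(-1, 0, 1), 30), 2 * rep(c(-1, 0, 1), 30))
  expect_equal(estimate_threshold(v2, 5), 2 * estimate_threshold(v, 5))
  ## degenerate noise errors out with advice
  expect_error(estimate_threshold(as_vel(rep(1, 50), rep(1, 50))),
               "degenerate")
})

test_that("threshold matches the Gaussian median-chi-square expectation", {
  set.seed(19)
  s <- 6
  v <- as_vel(rnorm(1e5, 0, s), rnorm(1e5, 0, s))
  eta <- estimate_threshold(v, lambda = 5)
  expected <- s * sqrt(qchisq(0.5, df = 1))
  expect_equal(unname(eta[1]) / 5, expected, tolerance = 0.05)
  expect_equal(unname(eta[2]) / 5, expected, tolerance = 0.05)
})

test_that("threshold scales with the noise level", {
  set.seed(29)
  for (k in c(0.5, 3)) {
    e1 <- estimate_threshold(as_vel(rnorm(1e5), rnorm(1e5)), 5)
    e2 <- estimate_threshold(as_vel(rnorm(1e5, 0, k), rnorm(1e5, 0, k)), 5)
    expect_equal(unname(e2 / e1), c(k, k), tolerance = 0.03)
  }
})

test_that("event segmentation finds injected excursions and merges split runs", {
  params <- detection_params()
  ## sub-threshold noise only: empty result
  v <- as_vel(rep(0.1, 200), rep(0, 200))
  expect_equal(nrow(detect_events(v, params, eta = c(1, 1))), 0)
  ## one 20-sample excursion
  vx <- rep(0, 200); vx[101:120] <- 5
  ev <- detect_events(as_vel(vx, rep(0, 200)), params, eta = c(1, 1))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev[1, "onset"] - 101), 2)
  expect_lte(abs(ev[1, "offset"] - 120), 2)
  ## two excursions separated by one sub-threshold sample are merged
  vx <- rep(0, 100); vx[11:20] <- 5; vx[22:31] <- 5
  ev <- detect_events(as_vel(vx, rep(0, 100)),
                      detection_params(merge_gap_samples = 2), eta = c(1, 1))
  expect_equal(nrow(ev), 1)
  expect_equal(unname(ev[1, ]), c(11, 31))
  ## without merging the duration test removes both 10-sample halves? no:
  ## each run is exactly 10 samples, so both survive unmerged
  ev0 <- detect_events(as_vel(vx, rep(0, 100)),
                       detection_params(merge_gap_samples = 0), eta = c(1, 1))
  expect_equal(nrow(ev0), 2)
})

test_that("event segmentation matches the brute-force scan on random sequences", {
  set.seed(37)
  params_list <- list(detection_params(min_duration_samples = 3,
                                       merge_gap_samples = 2),
                      detection_params(min_duration_samples = 5,
                                       merge_gap_samples = 0),
                      detection_params(min_duration_samples = 10,
                                       merge_gap_samples = 2))
  for (rep_i in 1:300) {
    n <- sample(20:120, 1)
    supra <- runif(n) < 0.35
    vx <- ifelse(supra, 5, 0.1)
    p <- params_list[[sample(3, 1)]]
    ours <- detect_events(as_vel(vx, rep(0, n)), p, eta = c(1, 1))
    oracle <- brute_detect(supra, p$min_duration_samples, p$merge_gap_samples)
    expect_equal(unname(ours), unname(oracle))
  }
})

test_that("classification applies the 1-degree split and 3-4-5 geometry", {
  ## build a recording whose event spans a known extent
  rec <- data.frame(t_ms = (0:39) * 0.8,
                    x_deg = c(rep(0, 10), seq(0, 0.5, length.out = 10),
                              rep(0.5, 20)),
                    y_deg = 0)
  vel <- compute_velocity(rec, 1250)
  ev <- classify_and_measure(cbind(onset = 11L, offset = 20L), rec, vel)
  expect_equal(ev$magnitude, 0.5, tolerance = 1e-9)
  expect_equal(ev$class, "microsaccade")
  rec2 <- data.frame(t_ms = (0:39) * 0.8,
                     x_deg = c(rep(0, 10), seq(0, 3, length.out = 10),
                               rep(3, 20)),
                     y_deg = c(rep(0, 10), seq(0, 4, length.out = 10),
                               rep(4, 20)))
  ev2 <- classify_and_measure(cbind(onset = 11L, offset = 20L), rec2,
                              compute_velocity(rec2, 1250))
  expect_equal(ev2$magnitude, 5, tolerance = 1e-9)
  expect_equal(ev2$class, "saccade")
  expect_equal(ev2$polar_angle, (atan2(4, 3) * 180 / pi) %% 360)
  expect_equal(ev2$duration_ms, 10 * 0.8)
})

test_that("detection is invariant to position offsets", {
  s <- simulate_session(small_cfg(seed = 61))
  ev1 <- detect_saccades(s$recording)
  rec2 <- s$recording
  rec2$x_deg <- rec2$x_deg + 12.3
  rec2$y_deg <- rec2$y_deg - 4.5
  ev2 <- detect_saccades(rec2)
  expect_equal(ev1$onset_sample, ev2$onset_sample)
  expect_equal(ev1$offset_sample, ev2$offset_sample)
  expect_equal(ev1$magnitude, ev2$magnitude, tolerance = 1e-9)
})

test_that("rotating the trace rotates polar angles and preserves magnitudes", {
  ## noise-free trace with supplied isotropic thresholds
  cfg <- sim_config(fixation_noise_sd = 0)
  w <- synthesize_saccade(3, 20, cfg)
  mk_rec <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    xy <- rbind(matrix(0, 30, 2), w, matrix(rep(w[nrow(w), ], each = 30), 30)) %*% t(R)
    data.frame(t_ms = (seq_len(nrow(xy)) - 1) * 0.8, x_deg = xy[, 1],
               y_deg = xy[, 2])
  }
  params <- detection_params()
  th <- 73 * pi / 180
  measure <- function(rec) {
    vel <- compute_velocity(rec, 1250)
    ev <- detect_events(vel, params, eta = c(25, 25))
    classify_and_measure(ev, rec, vel, params)
  }
  a <- measure(mk_rec(0)); b <- measure(mk_rec(th))
  expect_equal(nrow(a), 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$polar_angle, (a$polar_angle + 73) %% 360, tolerance = 1e-6)
  expect_equal(a$magnitude, b$magnitude, tolerance = 1e-6)
})

test_that("main-sequence fit recovers exact power-law pairs and rejects degenerate input", {
  ev <- data.frame(magnitude = c(0.5, 1, 2, 4, 8),
                   peak_velocity = 100 * c(0.5, 1, 2, 4, 8))
  fit <- main_sequence(ev)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_error(main_sequence(ev[1, ]), "at least 2")
  expect_warning(fit2 <- main_sequence(rbind(ev, data.frame(magnitude = 0,
                                                            peak_velocity = 10))),
                 "excluded")
  expect_equal(fit2$n_excluded, 1)
})

test_that("main sequence holds on a simulated session", {
  s <- simulate_session(sim_config(n_blocks = 1, trials_per_block = 80,
                                   rng_seed = 71))
  ev <- detect_saccades(s$recording)
  fit <- main_sequence(ev)
  expect_gt(fit$r, 0.9)
})
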