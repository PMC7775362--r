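# Wearable feature families against hand computations and brute-force
# oracles.

test_that("constant acceleration yields one motionless interval spanning it", {
  acc <- sensor_channel("acc", "left", 0, 4,
                        cbind(0, 0, rep(1, 4 * 600)))
  iv <- detect_motionless_intervals(acc, 0.02, 30)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 0)
  expect_gte(iv$end, 599)
})

test_that("alternating quiet and loud minutes are segmented at the quiet ones", {
  set.seed(5)
  fs <- 4
  mins <- 10
  per_min <- fs * 60
  sdv <- rep(rep(c(0, 0.5), length.out = mins), each = per_min)
  z <- 1 + rnorm(mins * per_min, 0, sdv)
  acc <- sensor_channel("acc", "left", 0, fs, cbind(0, 0, z))
  iv <- detect_motionless_intervals(acc, 0.1, 30)
  # quiet minutes are 0-1, 2-3, ... -> 5 intervals of ~60 s each
  expect_equal(nrow(iv), 5)
  expect_true(all(abs((iv$end - iv$start) - 60) <= 2))
  expect_true(all(abs(iv$start %% 120) <= 1))
})

test_that("a zero SD threshold yields no motionless intervals", {
  acc <- sensor_channel("acc", "left", 0, 4, cbind(0, 0, rep(1, 4 * 120)))
  expect_equal(nrow(detect_motionless_intervals(acc, 0, 30)), 0)
  empty <- sensor_channel("acc", "left", 0, 4, matrix(numeric(), ncol = 3))
  expect_equal(nrow(detect_motionless_intervals(empty)), 0)
})

test_that("SCR detection: flat signals, planted bumps, and threshold monotonicity", {
  expect_equal(nrow(detect_scrs(flat_eda())), 0)
  e <- simulate_eda(600, fs = 4, noise_sd = 0, drift_amp_uS = 0,
                    tonic_uS = 0.5, asymmetry = 0,
                    events = data.frame(onset_s = 100, amplitude_uS = 0.3))
  ev <- detect_scrs(e$left, amp_threshold_uS = 0.05)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude_uS - 0.3) / 0.3, 0.1)
  expect_lte(ev$rise_s, 4)
  # raising the threshold never increases the event count
  set.seed(6)
  noisy <- simulate_eda(3600, fs = 4, scr_per_h = 25, noise_sd = 0.01)$left
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4),
                   function(th) nrow(detect_scrs(noisy,
                                                 amp_threshold_uS = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SCR events outside the motionless mask are discarded", {
  e <- simulate_eda(600, fs = 4, noise_sd = 0, drift_amp_uS = 0,
                    tonic_uS = 0.5, asymmetry = 0,
                    events = data.frame(onset_s = c(100, 400),
                                        amplitude_uS = 0.3))
  mask <- tibble::tibble(start = 50, end = 200)
  ev <- detect_scrs(e$left, mask)
  expect_equal(nrow(ev), 1)
  expect_true(ev$onset >= 50 && ev$onset < 200)
})

test_that("bilateral EDA summary is antisymmetric under wrist swap", {
  set.seed(7)
  e <- simulate_eda(1200, fs = 4, scr_per_h = 30, noise_sd = 0.005,
                    asymmetry = 0.2)
  s <- eda_summary(e$left, e$right)
  s_swapped <- eda_summary(e$right, e$left)
  expect_equal(s_swapped$scl_diff, -s$scl_diff)
  expect_equal(s_swapped$scr_count_diff, -s$scr_count_diff)
  # identical channels: all diffs exactly zero
  s0 <- eda_summary(e$left, e$left)
  expect_equal(s0$scl_diff, 0)
  expect_equal(s0$scr_count_diff, 0)
})

test_that("scripted SCL difference is the signed right-minus-left value", {
  l <- flat_eda(0.4)
  r <- flat_eda(0.6)
  r$wrist <- "right"
  s <- eda_summary(l, r)
  expect_equal(s$scl_diff, 0.2)
  expect_equal(s$scl_mean_left, 0.4)
  expect_equal(s$scl_mean_right, 0.6)
})

test_that("IBI cleaning applies the range and 20% successive-change rules", {
  clean <- tibble::tibble(offset_s = cumsum(rep(0.8, 10)),
                          duration_s = rep(0.8, 10))
  out <- clean_ibi(clean)
  expect_equal(out$nn$duration_s, clean$duration_s)
  expect_equal(out$coverage, 1)
  # a 3 s artifact among 0.8 s beats is removed
  d <- c(rep(0.8, 5), 3, rep(0.8, 5))
  art <- tibble::tibble(offset_s = cumsum(d), duration_s = d)
  out2 <- clean_ibi(art)
  expect_equal(nrow(out2$nn), 10)
  expect_true(all(out2$nn$duration_s == 0.8))
  # alternating 0.6/0.9 (50% jumps): every other beat removed
  d3 <- rep(c(0.6, 0.9), 6)
  alt <- tibble::tibble(offset_s = cumsum(d3), duration_s = d3)
  out3 <- clean_ibi(alt)
  expect_equal(out3$nn$duration_s, rep(0.6, 6))
  expect_equal(out3$coverage, 0.5)
})

test_that("time-domain HRV matches hand computations", {
  nn <- c(800, 810, 790, 805)
  td <- hrv_time_domain(nn)
  expect_equal(td$rmssd_ms, sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-12)
  expect_equal(td$sdnn_ms, sd(nn), tolerance = 1e-12)
  expect_equal(round(td$rmssd_ms, 3), 15.546)
  expect_equal(round(td$sdnn_ms, 3), 8.539)
  const <- hrv_time_domain(rep(800, 50))
  expect_equal(const$sdnn_ms, 0)
  expect_equal(const$rmssd_ms, 0)
  expect_true(is.na(hrv_time_domain(c(800))$sdnn_ms))
})

test_that("time-domain HRV equals the brute-force oracle on random series", {
  set.seed(8)
  for (k in 1:200) {
    nn <- rnorm(sample(2:60, 1), 800, 40)
    td <- hrv_time_domain(nn)
    expect_equal(td$rmssd_ms, oracle_rmssd(nn), tolerance = 1e-9)
    expect_equal(td$sdnn_ms, oracle_sdnn(nn), tolerance = 1e-9)
  }
})

test_that("frequency-domain HRV separates LF and HF modulations", {
  t <- cumsum(rep(0.8, 500))
  lf_mod <- hrv_frequency_domain(t, 800 + 50 * sin(2 * pi * 0.1 * t))
  expect_gt(lf_mod$lf_power / lf_mod$hf_power, 10)
  hf_mod <- hrv_frequency_domain(t, 800 + 50 * sin(2 * pi * 0.25 * t))
  expect_gt(hf_mod$hf_power / hf_mod$lf_power, 10)
  const <- hrv_frequency_domain(t, rep(800, 500))
  expect_lt(const$lf_power, 1e-6 * lf_mod$lf_power)
  expect_lt(const$hf_power, 1e-6 * hf_mod$hf_power)
  # too-short windows are missing, not zero
  short <- hrv_frequency_domain(t[1:20], 800 + rnorm(20))
  expect_true(is.na(short$lf_power))
})

test_that("activity count is homogeneous of degree one in the signal", {
  set.seed(9)
  z <- 1 + rnorm(4 * 300, 0, 0.05)
  acc1 <- sensor_channel("acc", "left", 0, 4, cbind(0, 0, z))
  acc2 <- sensor_channel("acc", "left", 0, 4, cbind(0, 0, 2 * z))
  expect_equal(activity_count(acc2), 2 * activity_count(acc1),
               tolerance = 1e-9)
  empty <- sensor_channel("acc", "left", 0, 4, matrix(numeric(), ncol = 3))
  expect_true(is.na(activity_count(empty)))
})

test_that("a planted 8-hour sleep block is recovered within half an hour", {
  set.seed(10)
  segs <- list()
  for (d in 0:1) {
    day0 <- d * 86400
    segs <- c(segs,
      list(simulate_acc(3 * 3600, fs = 2, start_time = day0,
                        sleep_intervals = list(c(0, 3 * 3600)))),
      list(simulate_acc(19 * 3600, fs = 2, start_time = day0 + 5 * 3600,
                        sleep_intervals = list(c(0, 2.5 * 3600),
                                               c(18.5 * 3600, 19 * 3600)))))
  }
  slp <- detect_sleep_period(segs, 2 * 86400)
  expect_lt(abs(slp$est_sleep_duration_h - 8), 0.5)
  # continuous high activity: missing with a reason, not zero
  awake <- list(simulate_acc(48 * 3600, fs = 2, start_time = 0))
  none <- detect_sleep_period(awake, 48 * 3600)
  expect_true(is.na(none$est_sleep_duration_h))
  expect_match(none$reason, "block")
  # insufficient coverage: missing with a coverage reason
  thin <- list(simulate_acc(3600, fs = 2, start_time = 0))
  low <- detect_sleep_period(thin, 48 * 3600)
  expect_match(low$reason, "coverage")
})
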