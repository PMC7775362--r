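# Synthetic cohort generator: determinism, calibration, planted couplings.

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 1), "n_participants",
               class = "moodsense_config_error")
  expect_error(cohort_config(visit_offsets_days = c(0, 7, 7)),
               "visit_offsets_days", class = "moodsense_config_error")
  expect_error(cohort_config(noise_sd = list(eda = -1)), "noise_sd",
               class = "moodsense_config_error")
  expect_error(cohort_config(missingness = list(failure_prob = 1.5)),
               "failure_prob", class = "moodsense_config_error")
})

test_that("identical config and seed give identical cohorts", {
  cc <- cohort_config(n_participants = 2, n_days = 2,
                      visit_offsets_days = c(0, 1, 2), seed = 11,
                      rates = list(eda = 1, acc = 2, temp = 0.5))
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$visits, b$visits)
  expect_identical(a$events, b$events)
  expect_identical(a$locations, b$locations)
  expect_identical(a$streams, b$streams)
  # and a different seed changes the streams
  cc2 <- cohort_config(n_participants = 2, n_days = 2,
                       visit_offsets_days = c(0, 1, 2), seed = 12,
                       rates = list(eda = 1, acc = 2, temp = 0.5))
  d <- generate_cohort(cc2)
  expect_false(identical(a$events, d$events))
})

test_that("visit scores stay on the 0-52 scale and trajectories have full length", {
  tr <- simulate_trajectories(cohort_config(n_participants = 25, seed = 5))
  expect_true(all(tr$visits$hdrs17 >= 0 & tr$visits$hdrs17 <= 52))
  lens <- table(tr$trajectories$participant_id)
  expect_true(all(lens == 64)) # n_days + 1 daily values
  expect_true(all(tr$visits$hdrs_residual ==
                    tr$visits$hdrs17 -
                    rep(tr$visits$hdrs17[tr$visits$visit_index == "screen"],
                        each = 6)))
})

test_that("default calibration hits the within-user SD and decline bands", {
  # mean within-participant visit-score SD in [2.7, 4.7] and mean relative
  # decline from the baseline visit to the last in [5%, 25%], averaged over
  # cohorts (pooling 50 x 20 participants via 10 cohorts of 20 here, with
  # fixed seeds for determinism)
  stats <- vapply(1:10, function(s) {
    v <- simulate_trajectories(cohort_config(n_participants = 20,
                                             seed = 400 + s))$visits
    sds <- tapply(v$hdrs17, v$participant_id, sd)
    dec <- vapply(split(v, v$participant_id), function(vv) {
      b <- vv$hdrs17[vv$visit_index == "v2"]
      l <- vv$hdrs17[vv$visit_index == "v6"]
      (b - l) / max(b, 1)
    }, numeric(1))
    c(mean(sds), mean(dec))
  }, numeric(2))
  expect_gt(mean(stats[1, ]), 2.7)
  expect_lt(mean(stats[1, ]), 4.7)
  expect_gt(mean(stats[2, ]), 0.05)
  expect_lt(mean(stats[2, ]), 0.25)
})

test_that("timestamps are strictly increasing and failure days are empty", {
  cc <- cohort_config(n_participants = 3, n_days = 6,
                      visit_offsets_days = c(0, 2, 4, 6), seed = 21,
                      rates = list(eda = 1, acc = 2, temp = 0.5),
                      missingness = list(failure_prob = 0.3))
  coh <- generate_cohort(cc)
  for (pid in coh$participants) {
    ev <- coh$events[coh$events$participant_id == pid, ]
    expect_true(!is.unsorted(ev$timestamp))
    loc <- coh$locations[coh$locations$participant_id == pid, ]
    expect_true(all(diff(loc$timestamp) > 0))
  }
  fd <- coh$manifest$failure_days
  expect_gt(nrow(fd), 0) # 30% failure rate over 21 participant-days
  for (k in seq_len(nrow(fd))) {
    d0 <- coh$manifest$study_start + fd$day[k] * 86400
    ev <- coh$events[coh$events$participant_id == fd$participant_id[k], ]
    expect_equal(sum(ev$timestamp >= d0 & ev$timestamp < d0 + 86400), 0)
    gt <- coh$ground_truth
    expect_false(any(gt$participant_id == fd$participant_id[k] &
                       gt$day == fd$day[k]))
  }
})

test_that("zero couplings leave daily features uncorrelated with severity", {
  # pooled over five 20-participant cohorts so the 0.15 bound sits several
  # standard errors above pure sampling noise
  pooled <- purrr::map(1:5, function(s) {
    cc <- cohort_config(
      n_participants = 20, seed = 30 + s,
      effect_sizes = list(phone_engagement = 0, mobility = 0, scr_rate = 0,
                          rmssd = 0))
    sim <- simulate_visit_features(cc)
    tg <- residualize(sim$visits)
    al <- dplyr::inner_join(
      sim$features,
      tg[, c("participant_id", "visit_index", "hdrs_residual")],
      by = c("participant_id", "visit_index"))
    al$participant_id <- paste0(s, al$participant_id)
    al
  }) |> purrr::list_rbind()
  informative <- simulate_visit_features(
    cohort_config(n_participants = 2, seed = 1))$informative
  for (f in informative) {
    expect_lt(abs(cor(pooled[[f]], pooled$hdrs_residual)), 0.15)
  }
})

test_that("positive SCR coupling raises SCR rates on high-severity days", {
  # sign test across participants: per-participant mean planted SCR rate on
  # above-median-severity days exceeds that on below-median days
  cc <- cohort_config(n_participants = 20, n_days = 20,
                      visit_offsets_days = c(0, 10, 20), seed = 41,
                      rates = list(eda = 0.2, acc = 0.2, temp = 0.2),
                      effect_sizes = list(scr_rate = 2),
                      missingness = list(failure_prob = 0))
  coh <- generate_cohort(cc)
  gt <- coh$ground_truth
  wins <- vapply(split(gt, gt$participant_id), function(g) {
    hi <- g$severity > median(g$severity)
    if (!any(hi) || all(hi)) return(NA)
    mean(g$scr_per_h[hi]) > mean(g$scr_per_h[!hi])
  }, logical(1))
  wins <- wins[!is.na(wins)]
  bt <- binom.test(sum(wins), length(wins), 0.5, alternative = "greater")
  expect_lt(bt$p.value, 0.05)
})

test_that("EDA simulator honours scripted events, asymmetry and tonic drift", {
  # zero SCR rate + zero noise reproduces the tonic drift exactly
  set.seed(1)
  e <- simulate_eda(600, fs = 4, scr_per_h = 0, noise_sd = 0,
                    asymmetry = 0, tonic_uS = 1.2, drift_amp_uS = 0.1)
  expect_equal(length(e$left$values), 2400)
  expect_identical(e$left$values, e$right$values)
  expect_true(all(abs(e$left$values - 1.2) <= 0.1 + 1e-12))
  expect_equal(nrow(e$events), 0)
  # planted events are recovered by the downstream detector
  e2 <- simulate_eda(1200, fs = 4, noise_sd = 0, drift_amp_uS = 0,
                     tonic_uS = 0.5, asymmetry = 0,
                     events = data.frame(onset_s = c(100, 400, 800),
                                         amplitude_uS = 0.3))
  ev <- detect_scrs(e2$left, amp_threshold_uS = 0.05)
  expect_equal(nrow(ev), 3)
  expect_true(all(abs(ev$amplitude_uS - 0.3) <= 0.03))
})

test_that("IBI simulator plants a recoverable RMSSD", {
  set.seed(2)
  a <- simulate_ibi(3600, rmssd_ms = 40, dropout_frac = 0)
  b <- simulate_ibi(3600, rmssd_ms = 20, dropout_frac = 0)
  ra <- oracle_rmssd(a$channel$values$duration_s * 1000)
  rb <- oracle_rmssd(b$channel$values$duration_s * 1000)
  expect_lt(abs(ra / rb - 2), 0.3) # ratio ~ 2 within 15% on each estimate
  # zero variability: constant series
  z <- simulate_ibi(600, rmssd_ms = 0, dropout_frac = 0)
  expect_equal(sd(z$channel$values$duration_s), 0)
})

test_that("phone simulator puts all fixes at home when excursions are off", {
  set.seed(3)
  ph <- simulate_phone_day(0, excursions = 0, home_lat = 42.36,
                           home_lon = -71.09, gps_noise_deg = 0)
  expect_true(all(ph$locations$lat == 42.36))
  expect_true(all(ph$locations$lon == -71.09))
  g <- downsample_location(ph$locations[, c("timestamp", "lat", "lon")])
  m <- mobility_semantics(g, home = c(lat = 42.36, lon = -71.09))
  expect_equal(m$time_at_home_frac, 1)
  expect_equal(m$total_distance_km, 0)
})
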