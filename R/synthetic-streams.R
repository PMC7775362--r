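# Raw-stream simulators for one participant-day. These write the same
# dialects the readers consume, so a simulated cohort round-trips through the
# real pipeline. Waveform shapes are deliberately simple (tonic drift +
# phasic bumps, white-noise IBI, home-anchored trips): realistic enough to
# exercise every extractor, with planted ground truth returned alongside.

# Skin-conductance response kernel: fast rise to the peak, exponential decay.
scr_kernel <- function(fs, rise_s = 1.5, decay_s = 4, total_s = 15) {
  t <- seq(0, total_s, by = 1 / fs)
  up <- pmin(t / rise_s, 1)^2
  down <- ifelse(t <= rise_s, 1, exp(-(t - rise_s) / decay_s))
  up * down
}

#' Simulate one day of bilateral electrodermal activity
#'
#' Produces left- and right-wrist EDA at `fs` Hz: a slow tonic drift shared
#' by both wrists, a shared Poisson stream of skin-conductance responses
#' (fast-rise / exponential-decay bumps), a configurable relative asymmetry
#' applied to the right wrist, and white sensor noise. Values are clamped to
#' be non-negative.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param start_time UTC epoch seconds of the first sample.
#' @param scr_per_h expected SCR event rate per hour.
#' @param scr_amp_uS mean SCR amplitude (microsiemens); individual event
#'   amplitudes are lognormal around this.
#' @param tonic_uS tonic skin-conductance level.
#' @param asymmetry relative right-minus-left offset (0.1 = right 10% above
#'   left); applied to tonic and phasic components alike.
#' @param noise_sd white-noise SD in microsiemens.
#' @param drift_amp_uS amplitude of the slow sinusoidal tonic drift.
#' @param events optional scripted event table (`onset_s`, `amplitude_uS`)
#'   overriding the Poisson stream; amplitudes are per-event peak heights.
#' @return list with `left` and `right` [sensor_channel()]s and `events`,
#'   the planted event list (onset_s, amplitude_uS) used as a ground-truth
#'   oracle downstream.
#' @export
simulate_eda <- function(duration_s, fs = 4, start_time = 0,
                         scr_per_h = 6, scr_amp_uS = 0.3, tonic_uS = 1.5,
                         asymmetry = 0.15, noise_sd = 0.02,
                         drift_amp_uS = 0.15, events = NULL) {
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs - 1 / fs
  tonic <- tonic_uS + drift_amp_uS * sin(2 * pi * t / max(duration_s, 1) +
                                           runif(1, 0, 2 * pi))
  if (is.null(events)) {
    k <- rpois(1, scr_per_h * duration_s / 3600)
    events <- tibble(
      onset_s = sort(runif(k, 0, max(duration_s - 20, 1))),
      amplitude_uS = stats::rlnorm(k, log(scr_amp_uS), 0.3))
  } else {
    events <- as_tibble(events)
  }
  phasic <- numeric(n)
  if (nrow(events) > 0) {
    kern <- scr_kernel(fs)
    for (j in seq_len(nrow(events))) {
      i0 <- floor(events$onset_s[j] * fs) + 1
      idx <- i0:min(n, i0 + length(kern) - 1)
      if (length(idx) > 0 && idx[1] <= n) {
        phasic[idx] <- phasic[idx] +
          events$amplitude_uS[j] * kern[seq_along(idx)]
      }
    }
  }
  base <- tonic + phasic
  left <- pmax(base + rnorm(n, 0, noise_sd), 0)
  right <- pmax(base * (1 + asymmetry) + rnorm(n, 0, noise_sd), 0)
  list(
    left = sensor_channel("eda", "left", start_time, fs, left),
    right = sensor_channel("eda", "right", start_time, fs, right),
    events = events
  )
}

#' Simulate one day of inter-beat intervals
#'
#' White-noise IBI model: beat durations are `mean_ibi_s` plus independent
#' Gaussian jitter whose SD is `rmssd_ms / sqrt(2)` so the planted
#' root-mean-square of successive differences equals `rmssd_ms` in
#' expectation. Optical-sensor loss is mimicked by deleting random gaps.
#'
#' @param duration_s recording span in seconds.
#' @param mean_ibi_s mean beat-to-beat interval (0.6-1.0 s physiological).
#' @param rmssd_ms planted RMSSD in milliseconds.
#' @param start_time UTC epoch seconds.
#' @param dropout_frac fraction of the recording removed as contiguous gaps.
#' @return list with `channel` (an `ibi` [sensor_channel()], offsets are the
#'   beat end times) and `true_rmssd_ms`.
#' @export
simulate_ibi <- function(duration_s, mean_ibi_s = 0.8, rmssd_ms = 35,
                         start_time = 0, dropout_frac = 0.05) {
  jitter_sd <- rmssd_ms / 1000 / sqrt(2)
  n_max <- ceiling(duration_s / max(mean_ibi_s - 4 * jitter_sd, 0.3)) + 8
  dur <- pmax(mean_ibi_s + rnorm(n_max, 0, jitter_sd), 0.3)
  off <- cumsum(dur)
  keep <- off <= duration_s
  dur <- dur[keep]; off <- off[keep]
  if (dropout_frac > 0 && length(off) > 10) {
    n_gaps <- max(1, rpois(1, 3))
    gap_len <- dropout_frac * duration_s / n_gaps
    for (g in seq_len(n_gaps)) {
      g0 <- runif(1, 0, duration_s - gap_len)
      drop <- off > g0 & off < g0 + gap_len
      dur <- dur[!drop]; off <- off[!drop]
    }
  }
  list(channel = sensor_channel("ibi", "left", start_time, NA,
                                tibble(offset_s = off, duration_s = dur)),
       true_rmssd_ms = rmssd_ms)
}

#' Simulate one day of 3-axis wrist acceleration
#'
#' Gravity on z plus activity-dependent jitter: a planted low-activity sleep
#' block (jitter SD `sleep_noise_g`) and wake-time movement bursts
#' (`wake_noise_g`), giving the actigraphy scorer a recoverable sleep period.
#'
#' @param duration_s,fs,start_time recording span, rate (Hz), start epoch.
#' @param sleep_intervals list of `c(start_s, end_s)` offsets (relative to
#'   `start_time`) that are asleep.
#' @param wake_noise_g,sleep_noise_g jitter SD per axis while awake/asleep.
#' @return an `acc` [sensor_channel()].
#' @export
simulate_acc <- function(duration_s, fs = 32, start_time = 0,
                         sleep_intervals = list(),
                         wake_noise_g = 0.08, sleep_noise_g = 0.004) {
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs - 1 / fs
  sdv <- rep(wake_noise_g, n)
  for (iv in sleep_intervals) {
    sdv[t >= iv[1] & t < iv[2]] <- sleep_noise_g
  }
  vals <- cbind(rnorm(n, 0, sdv), rnorm(n, 0, sdv), 1 + rnorm(n, 0, sdv))
  sensor_channel("acc", "left", start_time, fs, vals)
}

#' Simulate one day of phone events and location fixes
#'
#' Screen sessions (paired ON/OFF), direction-tagged calls with durations,
#' SMS events, and app launches by anonymized category token, plus a
#' home-anchored GPS trace with `excursions` round trips to points
#' `excursion_km` away. Fixes are irregularly sampled (30 s to 10 min) to
#' exercise the 5-min downsampler.
#'
#' @param day_start UTC epoch seconds of local midnight.
#' @param screen_min total expected screen-on minutes.
#' @param excursions expected number of round trips away from home.
#' @param home_lat,home_lon home coordinate (decimal degrees).
#' @param excursion_km typical trip radius in km.
#' @param calls_per_day,sms_per_day,apps_per_day expected event counts.
#' @param gps_noise_deg GPS jitter SD in degrees (~1e-4 is ~10 m).
#' @return list with `events` (tibble: timestamp, event_type, duration_s,
#'   category), `locations` (tibble: timestamp, lat, lon) and ground truth
#'   `truth` (screen_min, n_sessions, excursions).
#' @export
simulate_phone_day <- function(day_start, screen_min = 180, excursions = 2,
                               home_lat = 42.36, home_lon = -71.09,
                               excursion_km = 2, calls_per_day = 3,
                               sms_per_day = 8, apps_per_day = 20,
                               gps_noise_deg = 5e-5) {
  wake0 <- day_start + 8 * 3600
  wake1 <- day_start + 23 * 3600

  # screen sessions: Poisson count, exponential durations scaled to target
  n_sess <- max(1, rpois(1, 10))
  raw <- stats::rexp(n_sess)
  durs <- raw / sum(raw) * screen_min * 60
  starts <- sort(runif(n_sess, wake0, wake1 - 60))
  # enforce non-overlap by trimming each session at the next start
  ends <- pmin(starts + durs, c(starts[-1], wake1))
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  scr <- tibble(
    timestamp = c(starts, ends),
    event_type = rep(c("SCREEN_ON", "SCREEN_OFF"), each = length(starts)),
    duration_s = NA_real_, category = NA_character_)

  n_call <- rpois(1, calls_per_day)
  calls <- tibble(
    timestamp = runif(n_call, wake0, wake1),
    event_type = sample(c("CALL_IN", "CALL_OUT"), n_call, replace = TRUE),
    duration_s = stats::rexp(n_call, 1 / 120), category = NA_character_)
  n_sms <- rpois(1, sms_per_day)
  sms <- tibble(
    timestamp = runif(n_sms, wake0, wake1),
    event_type = sample(c("SMS_IN", "SMS_OUT"), n_sms, replace = TRUE),
    duration_s = NA_real_, category = NA_character_)
  n_app <- rpois(1, apps_per_day)
  apps <- tibble(
    timestamp = runif(n_app, wake0, wake1),
    event_type = "APP_START", duration_s = NA_real_,
    category = sample(sprintf("cat%02d", 1:8), n_app, replace = TRUE))

  events <- bind_rows(scr, calls, sms, apps) |> arrange(.data$timestamp)

  # location: irregular fixes; home unless inside an excursion
  fix_gaps <- runif(500, 30, 600)
  fix_t <- day_start + cumsum(fix_gaps)
  fix_t <- fix_t[fix_t < day_start + SECONDS_PER_DAY]
  lat <- rep(home_lat, length(fix_t))
  lon <- rep(home_lon, length(fix_t))
  n_exc <- rpois(1, excursions)
  exc_done <- 0
  if (n_exc > 0) {
    for (e in seq_len(n_exc)) {
      t0 <- runif(1, wake0, wake1 - 2 * 3600)
      travel <- 15 * 60
      dwell <- runif(1, 3600, 2 * 3600)
      ang <- runif(1, 0, 2 * pi)
      r_km <- excursion_km * stats::rlnorm(1, 0, 0.25)
      dlat <- r_km / 111.19 * cos(ang)
      dlon <- r_km / (111.19 * cos(home_lat * pi / 180)) * sin(ang)
      ph <- (fix_t - t0) / travel
      out <- ph > 0 & ph < 1
      there <- fix_t >= t0 + travel & fix_t < t0 + travel + dwell
      back_ph <- (fix_t - (t0 + travel + dwell)) / travel
      back <- back_ph > 0 & back_ph < 1
      lat[out] <- home_lat + dlat * ph[out]
      lon[out] <- home_lon + dlon * ph[out]
      lat[there] <- home_lat + dlat
      lon[there] <- home_lon + dlon
      lat[back] <- home_lat + dlat * (1 - back_ph[back])
      lon[back] <- home_lon + dlon * (1 - back_ph[back])
      if (any(there)) exc_done <- exc_done + 1
    }
  }
  locations <- tibble(
    timestamp = fix_t,
    lat = lat + rnorm(length(fix_t), 0, gps_noise_deg),
    lon = lon + rnorm(length(fix_t), 0, gps_noise_deg))

  list(events = events, locations = locations,
       truth = list(screen_min = sum(ends - starts) / 60,
                    n_sessions = length(starts), excursions = exc_done))
}
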