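# Wearable-derived feature families. All detectors return explicit missing
# values (never silent zeros) when coverage is insufficient.

# Per-epoch SD of the acceleration magnitude. Returns one row per epoch that
# contains at least 2 samples.
epoch_magnitude_sd <- function(acc, epoch_s = 1) {
  stopifnot(acc$modality == "acc")
  n <- n_samples(acc)
  if (n == 0) {
    return(tibble(epoch_start = numeric(), sd = numeric(), n = integer()))
  }
  t <- channel_times(acc)
  mag <- sqrt(rowSums(acc$values^2))
  ep <- floor((t - acc$start_time) / epoch_s)
  s1 <- rowsum(mag, ep)
  s2 <- rowsum(mag^2, ep)
  cnt <- as.integer(rowsum(rep(1, n), ep)[, 1])
  keep <- cnt >= 2
  sds <- sqrt(pmax((s2[, 1] - s1[, 1]^2 / cnt) / (cnt - 1), 0))
  tibble(epoch_start = acc$start_time +
           as.numeric(rownames(s1)) * epoch_s,
         sd = sds, n = cnt)[keep, ]
}

#' Detect motionless intervals from wrist acceleration
#'
#' Scores 1-second epochs by the SD of the acceleration magnitude; epochs
#' strictly below `sd_threshold_g` merge into half-open intervals, and
#' intervals shorter than `min_duration_s` are dropped. EDA features are
#' computed only inside these intervals, because motion artifacts mimic
#' skin-conductance responses.
#'
#' @param acc a 3-axis `acc` [sensor_channel()].
#' @param sd_threshold_g magnitude-SD threshold in g (default 0.02).
#' @param min_duration_s minimum interval length in seconds (default 30).
#' @return tibble of non-overlapping sorted intervals (`start`, `end`), UTC
#'   epoch seconds, half-open. Empty channel gives an empty set.
#' @export
detect_motionless_intervals <- function(acc, sd_threshold_g = 0.02,
                                        min_duration_s = 30) {
  ep <- epoch_magnitude_sd(acc, 1)
  if (nrow(ep) == 0) return(tibble(start = numeric(), end = numeric()))
  quiet <- ep$sd < sd_threshold_g
  # group consecutive quiet epochs (consecutive == 1 s apart)
  runs <- split(ep$epoch_start[quiet],
                cumsum(c(TRUE, diff(ep$epoch_start[quiet]) > 1)))
  out <- purrr::map(runs, function(r) {
    tibble(start = r[1], end = r[length(r)] + 1)
  }) |> purrr::list_rbind()
  if (nrow(out) == 0) return(tibble(start = numeric(), end = numeric()))
  out |> filter(.data$end - .data$start >= min_duration_s)
}

in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(t)))
  }
  idx <- findInterval(t, intervals$start)
  idx > 0 & t < intervals$end[pmax(idx, 1)]
}

#' Detect skin-conductance responses (trough-to-peak)
#'
#' Low-pass filters the EDA signal (first-order Butterworth at `lp_hz`),
#' locates trough-to-peak upswings, and keeps events with amplitude at least
#' `amp_threshold_uS` and rise time at most `max_rise_s`, restricted to
#' motionless intervals when a mask is given.
#'
#' @param eda an `eda` [sensor_channel()].
#' @param mask optional motionless interval set from
#'   [detect_motionless_intervals()]; `NULL` means the whole recording.
#' @param amp_threshold_uS minimum trough-to-peak amplitude (default 0.05).
#' @param max_rise_s maximum rise time in seconds (default 4).
#' @param lp_hz low-pass cutoff (default 1 Hz; skipped when the sampling
#'   rate cannot support it).
#' @return tibble of events sorted by onset: `onset`, `peak_time`,
#'   `amplitude_uS`, `rise_s`.
#' @export
detect_scrs <- function(eda, mask = NULL, amp_threshold_uS = 0.05,
                        max_rise_s = 4, lp_hz = 1) {
  stopifnot(eda$modality == "eda")
  empty <- tibble(onset = numeric(), peak_time = numeric(),
                  amplitude_uS = numeric(), rise_s = numeric())
  n <- n_samples(eda)
  if (n < 5) return(empty)
  fs <- eda$sample_rate
  x <- eda$values
  if (!is.na(lp_hz) && fs > 2 * lp_hz) {
    # reflect-pad before filtering so edge transients cannot fabricate
    # trough-to-peak upswings at the recording boundaries
    pad <- min(n - 1, ceiling(4 * fs))
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    bf <- signal::butter(1, 2 * lp_hz / fs, type = "low")
    x <- as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
  }
  # maximal rising runs of the filtered signal: each run's first sample is
  # the trough, its last the peak; runs separated by a single-sample dip or
  # plateau are merged (noise ripple), longer separators end the event
  dx <- diff(x)
  r <- rle(as.integer(sign(dx) == 1))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rise_runs <- which(r$values == 1)
  if (length(rise_runs) == 0) return(empty)
  runs <- tibble(a = starts[rise_runs], b = ends[rise_runs])
  if (nrow(runs) > 1) {
    gap <- runs$a[-1] - runs$b[-nrow(runs)] - 1
    grp <- cumsum(c(0, as.integer(gap > max(1, round(0.25 * fs))))) + 1
    runs <- runs |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(a = min(.data$a), b = max(.data$b), .groups = "drop")
  }
  troughs <- runs$a      # dx[a] is the first rising step: trough sample
  pk <- runs$b + 1       # last rising step ends at sample b + 1
  t <- channel_times(eda)
  amp <- x[pk] - x[troughs]
  rise <- (pk - troughs) / fs
  keep <- amp >= amp_threshold_uS & rise <= max_rise_s
  if (!is.null(mask)) keep <- keep & in_intervals(t[troughs], mask)
  tibble(onset = t[troughs][keep], peak_time = t[pk][keep],
         amplitude_uS = amp[keep], rise_s = rise[keep]) |>
    arrange(.data$onset)
}

#' Bilateral EDA summary for one window
#'
#' Computes skin-conductance level and response statistics per wrist inside
#' the motionless mask, and the signed right-minus-left asymmetry features.
#' Windows whose masked coverage falls below `min_masked_frac` of the window
#' yield missing values.
#'
#' @param eda_left,eda_right `eda` [sensor_channel()]s sliced to the window.
#' @param mask motionless intervals tibble; `NULL` uses the whole window.
#' @param window `c(t0, t1)` UTC epoch bounds; defaults to the union span.
#' @param amp_threshold_uS,max_rise_s SCR detector parameters.
#' @param min_masked_frac minimum masked fraction of the window (default
#'   0.05) below which features are missing.
#' @return one-row tibble: `scl_mean_left/right`, `scr_count_left/right`,
#'   `scr_amp_mean_left/right`, `scl_diff`, `scr_count_diff` (right minus
#'   left).
#' @export
eda_summary <- function(eda_left, eda_right, mask = NULL, window = NULL,
                        amp_threshold_uS = 0.05, max_rise_s = 4,
                        min_masked_frac = 0.05) {
  na_row <- tibble(scl_mean_left = NA_real_, scl_mean_right = NA_real_,
                   scr_count_left = NA_real_, scr_count_right = NA_real_,
                   scr_amp_mean_left = NA_real_, scr_amp_mean_right = NA_real_,
                   scl_diff = NA_real_, scr_count_diff = NA_real_)
  if (n_samples(eda_left) == 0 || n_samples(eda_right) == 0) return(na_row)
  if (is.null(window)) {
    window <- c(min(eda_left$start_time, eda_right$start_time),
                max(channel_end_time(eda_left), channel_end_time(eda_right)))
  }
  if (is.null(mask)) mask <- tibble(start = window[1], end = window[2])
  masked_s <- sum(pmax(0, pmin(mask$end, window[2]) -
                         pmax(mask$start, window[1])))
  if (!isTRUE(masked_s >= min_masked_frac * (window[2] - window[1]))) {
    return(na_row)
  }
  one <- function(ch) {
    t <- channel_times(ch)
    inm <- in_intervals(t, mask)
    ev <- detect_scrs(ch, mask, amp_threshold_uS, max_rise_s)
    list(scl = if (any(inm)) mean(ch$values[inm]) else NA_real_,
         count = as.numeric(nrow(ev)),
         amp = if (nrow(ev) > 0) mean(ev$amplitude_uS) else NA_real_)
  }
  l <- one(eda_left); r <- one(eda_right)
  tibble(scl_mean_left = l$scl, scl_mean_right = r$scl,
         scr_count_left = l$count, scr_count_right = r$count,
         scr_amp_mean_left = l$amp, scr_amp_mean_right = r$amp,
         scl_diff = r$scl - l$scl,
         scr_count_diff = r$count - l$count)
}

#' Clean inter-beat intervals to normal-to-normal intervals
#'
#' Drops beats outside the physiological range of 0.3 to 2.0 seconds and
#' beats differing from the previously retained beat by more than
#' `max_rel_change` (default 20%), a standard artifact rule for optical
#' inter-beat data.
#'
#' @param ibi an `ibi` [sensor_channel()] or a tibble with `offset_s`,
#'   `duration_s`.
#' @param range_s allowed beat-duration range in seconds.
#' @param max_rel_change maximum relative change versus the previous
#'   retained beat.
#' @return list with `nn` (tibble `offset_s`, `duration_s` of retained
#'   beats) and `coverage`, the retained fraction of input beats.
#' @export
clean_ibi <- function(ibi, range_s = c(0.3, 2.0), max_rel_change = 0.2) {
  vals <- if (inherits(ibi, "sensor_channel")) ibi$values else as.data.frame(ibi)
  n <- nrow(vals)
  if (n == 0) {
    return(list(nn = tibble(offset_s = numeric(), duration_s = numeric()),
                coverage = NA_real_))
  }
  d <- vals$duration_s
  keep <- logical(n)
  prev <- NA_real_
  for (k in seq_len(n)) {
    if (d[k] < range_s[1] || d[k] > range_s[2]) next
    if (!is.na(prev) && abs(d[k] - prev) / prev > max_rel_change) next
    keep[k] <- TRUE
    prev <- d[k]
  }
  list(nn = vals[keep, c("offset_s", "duration_s")],
       coverage = mean(keep))
}

#' Time-domain heart-rate variability
#'
#' `rmssd` is the root mean square of successive differences between
#' normal-to-normal beats; `sdnn` their sample standard deviation (n - 1
#' denominator). Both in milliseconds.
#'
#' @param nn_ms numeric vector of NN intervals in milliseconds.
#' @return one-row tibble (`sdnn_ms`, `rmssd_ms`); missing when fewer than
#'   2 intervals are available.
#' @export
hrv_time_domain <- function(nn_ms) {
  nn_ms <- nn_ms[is.finite(nn_ms)]
  if (length(nn_ms) < 2) {
    return(tibble(sdnn_ms = NA_real_, rmssd_ms = NA_real_))
  }
  tibble(sdnn_ms = sd(nn_ms),
         rmssd_ms = sqrt(mean(diff(nn_ms)^2)))
}

# Generalized (Lomb-Scargle) periodogram for unevenly sampled series.
# Classical normalization with the time-offset tau; y is centred first.
lomb_periodogram <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

#' Frequency-domain heart-rate variability
#'
#' Band powers of the NN series in the low-frequency (0.04-0.15 Hz) and
#' high-frequency (0.15-0.40 Hz) bands, from a Lomb-Scargle periodogram
#' estimated directly on the unevenly sampled beats (no interpolation, which
#' would bias gappy optical data).
#'
#' @param nn_times_s beat times in seconds (uneven).
#' @param nn_ms NN interval values in milliseconds.
#' @param min_span_s minimum window span (default 300 s of beats).
#' @param min_beats minimum number of beats (default 30).
#' @return one-row tibble (`lf_power`, `hf_power`) in ms^2-per-Hz integrated
#'   band units; missing when the window is too short.
#' @export
hrv_frequency_domain <- function(nn_times_s, nn_ms, min_span_s = 300,
                                 min_beats = 30) {
  ok <- is.finite(nn_times_s) & is.finite(nn_ms)
  t <- nn_times_s[ok]; y <- nn_ms[ok]
  if (length(t) < min_beats || diff(range(t)) < min_span_s) {
    return(tibble(lf_power = NA_real_, hf_power = NA_real_))
  }
  if (sd(y) == 0) return(tibble(lf_power = 0, hf_power = 0))
  one_band <- function(t, y) {
    if (length(t) < min_beats || sd(y) == 0) return(NULL)
    freqs <- seq(0.005, 0.5, by = 0.0025)
    p <- lomb_periodogram(t, y, freqs)
    df <- freqs[2] - freqs[1]
    c(lf = sum(p[freqs >= 0.04 & freqs < 0.15]) * df,
      hf = sum(p[freqs >= 0.15 & freqs < 0.40]) * df)
  }
  span <- range(t)
  if (diff(span) <= 900) {
    b <- one_band(t, y)
  } else {
    # long windows: average band powers over up to 6 evenly spaced 5-min
    # sub-segments (the standard short-term HRV epoch)
    n_seg <- min(6, floor(diff(span) / 300))
    starts <- seq(span[1], span[2] - 300, length.out = n_seg)
    per <- purrr::compact(purrr::map(starts, function(s0) {
      sel <- t >= s0 & t < s0 + 300
      if (sum(sel) < min_beats) return(NULL)
      one_band(t[sel], y[sel])
    }))
    b <- if (length(per)) colMeans(do.call(rbind, per)) else NULL
  }
  if (is.null(b)) {
    return(tibble(lf_power = NA_real_, hf_power = NA_real_))
  }
  tibble(lf_power = unname(b["lf"]), hf_power = unname(b["hf"]))
}

#' Accelerometer activity count for a window
#'
#' Sum of per-1-second magnitude SDs: a unitless movement intensity that is
#' homogeneous of degree one in the signal amplitude.
#'
#' @param acc an `acc` [sensor_channel()] (already sliced to the window).
#' @return scalar activity count; `NA` for an empty channel.
#' @export
activity_count <- function(acc) {
  ep <- epoch_magnitude_sd(acc, 1)
  if (nrow(ep) == 0) return(NA_real_)
  sum(ep$sd)
}

#' Actigraphy sleep estimation over a trailing horizon
#'
#' Scores minute epochs over the `horizon_h` hours before `at_time` using a
#' weighted moving window over activity counts (mean magnitude-SD per
#' minute, smoothed with a centred kernel); a minute is asleep when its
#' smoothed count is below `threshold_g`. Missing minutes (no accelerometer
#' coverage, e.g. the daily charging gap) may bridge a sleep block but never
#' start or end one. The longest block overlapping the 9 p.m. to 11 a.m.
#' night window is the sleep period.
#'
#' @param acc_segments list of `acc` [sensor_channel()] segments.
#' @param at_time UTC epoch seconds; the horizon is `[at_time - horizon_h *
#'   3600, at_time)`.
#' @param horizon_h trailing horizon in hours (default 48).
#' @param threshold_g sleep threshold on smoothed per-minute counts.
#' @param min_coverage minimum covered fraction of the horizon (default
#'   0.5); below it all sleep features are missing.
#' @param tz_offset_hours participant-local clock offset for the night
#'   window.
#' @return one-row tibble: `sleep_onset`, `sleep_offset` (epoch seconds),
#'   `est_sleep_duration_h`; all `NA` (with a `reason` column) when coverage
#'   is insufficient or no sleep block is found.
#' @export
detect_sleep_period <- function(acc_segments, at_time, horizon_h = 48,
                                threshold_g = 0.02, min_coverage = 0.5,
                                tz_offset_hours = 0) {
  h0 <- at_time - horizon_h * 3600
  segs <- slice_segments(acc_segments, h0, at_time)
  miss <- function(reason) tibble(sleep_onset = NA_real_,
                                  sleep_offset = NA_real_,
                                  est_sleep_duration_h = NA_real_,
                                  reason = reason)
  cov <- segments_coverage_s(segs, h0, at_time) / (horizon_h * 3600)
  if (cov < min_coverage) return(miss("insufficient accelerometer coverage"))

  n_min <- as.integer(horizon_h * 60)
  counts <- rep(NA_real_, n_min)
  for (ch in segs) {
    ep <- epoch_magnitude_sd(ch, 60)
    idx <- floor((ep$epoch_start - h0) / 60) + 1
    ok <- idx >= 1 & idx <= n_min
    counts[idx[ok]] <- ep$sd[ok]
  }
  kern <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  obs <- !is.na(counts)
  smoothed <- as.numeric(stats::filter(ifelse(obs, counts, 0), kern,
                                       sides = 2)) /
    pmax(as.numeric(stats::filter(as.numeric(obs), kern, sides = 2)), 1e-9)
  asleep <- obs & !is.na(smoothed) & smoothed < threshold_g
  sleepish <- asleep | !obs

  r <- rle(sleepish)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bs <- starts[r$values]; be <- ends[r$values]
  # trim bridging missing minutes at block edges; a block must start and
  # end with scored sleep
  for (k in seq_along(bs)) {
    while (bs[k] <= be[k] && !asleep[bs[k]]) bs[k] <- bs[k] + 1
    while (be[k] >= bs[k] && !asleep[be[k]]) be[k] <- be[k] - 1
  }
  keep_b <- be >= bs
  blocks <- tibble(start = bs[keep_b], end = be[keep_b])
  if (nrow(blocks) == 0) return(miss("no low-activity block"))

  # night windows: 21:00 local to 11:00 local next day, for each night
  local0 <- h0 + tz_offset_hours * 3600
  day_anchor <- local0 - local0 %% SECONDS_PER_DAY - tz_offset_hours * 3600
  nights <- purrr::map(0:(ceiling(horizon_h / 24) + 1), function(k) {
    c(day_anchor + k * SECONDS_PER_DAY - 3 * 3600,     # 21:00 previous day
      day_anchor + k * SECONDS_PER_DAY + 11 * 3600)     # 11:00
  })
  blocks <- blocks |>
    mutate(t0 = h0 + (.data$start - 1) * 60, t1 = h0 + .data$end * 60,
           night = purrr::map2_lgl(.data$t0, .data$t1, function(a, b) {
             any(vapply(nights, function(nv) {
               min(b, nv[2]) - max(a, nv[1]) > 0
             }, logical(1)))
           })) |>
    filter(.data$night)
  if (nrow(blocks) == 0) return(miss("no sleep block in the night window"))
  best <- blocks |> slice_max(.data$t1 - .data$t0, n = 1, with_ties = FALSE)
  tibble(sleep_onset = best$t0, sleep_offset = best$t1,
         est_sleep_duration_h = (best$t1 - best$t0) / 3600,
         reason = NA_character_)
}
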