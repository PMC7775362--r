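#' Generate a full synthetic cohort of raw streams
#'
#' Builds a multi-participant cohort emulating a 9-week passive-monitoring
#' study: latent daily severity trajectories, clinician visit scores, and for
#' every non-failed participant-day raw bilateral EDA, 3-axis acceleration,
#' inter-beat intervals and skin temperature (with a daily charging/upload
#' gap from 03:00 to 03:00 + `charging_gap_hours` local time), plus phone
#' event logs and GPS traces over the whole day. Planted ground truth (daily
#' severity, SCR event lists, target RMSSD, scripted screen totals and
#' excursion counts) is returned for recovery testing.
#'
#' Output is deterministic given `config$seed`: every participant-day stream
#' draws from its own derived substream.
#'
#' @param config a [cohort_config()]. Note that full wearable rates (EDA 4
#'   Hz, ACC 32 Hz) over 63 days and 31 participants produce billions of
#'   samples; for cohort-scale runs lower `rates` and/or `n_days` via the
#'   config, or use [simulate_visit_features()] for model-level studies.
#' @return an object of class `synthetic_cohort`: list with `config`,
#'   `participants`, `trajectories`, `visits`, `streams` (per participant:
#'   lists of [sensor_channel()] segments per modality/wrist), `events`,
#'   `locations`, `ground_truth` (per participant-day planted values) and
#'   `manifest` (seed, timezone, failure days).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  traj <- simulate_trajectories(config)
  ids <- participant_ids(config$n_participants)
  slopes <- coupling_slopes(config)
  ch <- config$channels
  ns <- config$noise_sd
  gap0 <- 3 * 3600
  gap1 <- gap0 + config$missingness$charging_gap_hours * 3600
  study_start <- 1700000000 # fixed epoch anchor (UTC midnight offset applied)
  study_start <- study_start - study_start %% SECONDS_PER_DAY -
    config$tz_offset_hours * 3600

  sev_tbl <- traj$trajectories
  streams <- list()
  all_events <- list()
  all_locs <- list()
  gt <- list()
  failures <- list()

  for (i in seq_along(ids)) {
    pid <- ids[i]
    sev <- sev_tbl$severity[sev_tbl$participant_id == pid]
    dev <- sev - sev[1]
    home_lat <- ch$home_lat + with_seed(
      derive_seed(config$seed, "home", i), rnorm(1, 0, 0.05))
    home_lon <- ch$home_lon + with_seed(
      derive_seed(config$seed, "home2", i), rnorm(1, 0, 0.05))

    failed <- with_seed(
      derive_seed(config$seed, "failure", i),
      which(runif(config$n_days + 1) < config$missingness$failure_prob) - 1)
    failures[[i]] <- tibble(participant_id = pid, day = failed)

    p_streams <- list(eda_left = list(), eda_right = list(), acc = list(),
                      ibi_left = list(), ibi_right = list(),
                      temp_left = list(), temp_right = list())
    p_events <- list(); p_locs <- list(); p_gt <- list()

    for (d in 0:config$n_days) {
      day0 <- study_start + d * SECONDS_PER_DAY
      dv <- dev[d + 1] # severity deviation governing that day's behaviour
      if (d %in% failed) next

      day_gt <- with_seed(derive_seed(config$seed, "daytruth", i, d), list(
        screen_min = max(10, ch$screen_min + slopes$screen_min * dv +
                           rnorm(1, 0, ns$daily_phone)),
        scr_per_h = max(0, ch$scr_per_h + slopes$scr_per_h * dv +
                          rnorm(1, 0, ns$daily_scr)),
        rmssd_ms = max(5, ch$rmssd_ms + slopes$rmssd_ms * dv +
                         rnorm(1, 0, ns$daily_rmssd)),
        excursions = max(0, ch$excursions + slopes$excursions * dv +
                           rnorm(1, 0, ns$daily_mobility))
      ))

      # wearable segments: [00:00, gap0) and [gap1, 24:00) local
      segs <- list(c(0, gap0), c(gap1, SECONDS_PER_DAY))
      scr_events_n <- 0
      for (s in seq_along(segs)) {
        seg <- segs[[s]]
        seg_len <- seg[2] - seg[1]
        if (seg_len <= 0) next
        t0 <- day0 + seg[1]
        out <- with_seed(derive_seed(config$seed, "eda", i, d, s), {
          simulate_eda(seg_len, fs = config$rates$eda, start_time = t0,
                       scr_per_h = day_gt$scr_per_h,
                       tonic_uS = ch$eda_tonic_uS, asymmetry = ch$asymmetry,
                       noise_sd = ns$eda)
        })
        scr_events_n <- scr_events_n + nrow(out$events)
        p_streams$eda_left <- c(p_streams$eda_left, list(out$left))
        p_streams$eda_right <- c(p_streams$eda_right, list(out$right))

        # sleep 23:30-07:30 local, expressed in segment-relative offsets
        sleep_abs <- list(c(0, 7.5 * 3600), c(23.5 * 3600, SECONDS_PER_DAY))
        sleep_rel <- purrr::keep(purrr::map(sleep_abs, function(iv) {
          c(max(iv[1], seg[1]), min(iv[2], seg[2])) - seg[1]
        }), function(iv) iv[2] > iv[1])
        acc <- with_seed(derive_seed(config$seed, "acc", i, d, s), {
          simulate_acc(seg_len, fs = config$rates$acc, start_time = t0,
                       sleep_intervals = sleep_rel)
        })
        p_streams$acc <- c(p_streams$acc, list(acc))

        for (w in c("left", "right")) {
          ib <- with_seed(derive_seed(config$seed, "ibi", i, d, s, w), {
            simulate_ibi(seg_len, mean_ibi_s = ch$mean_ibi_s,
                         rmssd_ms = day_gt$rmssd_ms, start_time = t0)
          })
          ib$channel$wrist <- w
          p_streams[[paste0("ibi_", w)]] <-
            c(p_streams[[paste0("ibi_", w)]], list(ib$channel))
          tm <- with_seed(derive_seed(config$seed, "temp", i, d, s, w), {
            nt <- round(seg_len * config$rates$temp)
            sensor_channel("temp", w, t0, config$rates$temp,
                           33 + rnorm(nt, 0, ns$temp))
          })
          p_streams[[paste0("temp_", w)]] <-
            c(p_streams[[paste0("temp_", w)]], list(tm))
        }
      }

      ph <- with_seed(derive_seed(config$seed, "phone", i, d), {
        simulate_phone_day(day0, screen_min = day_gt$screen_min,
                           excursions = day_gt$excursions,
                           home_lat = home_lat, home_lon = home_lon,
                           calls_per_day = ch$calls_per_day,
                           sms_per_day = ch$sms_per_day,
                           apps_per_day = ch$apps_per_day)
      })
      p_events[[length(p_events) + 1]] <-
        ph$events |> mutate(participant_id = pid, .before = 1)
      p_locs[[length(p_locs) + 1]] <-
        ph$locations |> mutate(participant_id = pid, .before = 1)
      p_gt[[length(p_gt) + 1]] <- tibble(
        participant_id = pid, day = d, severity = sev[d + 1],
        severity_dev = dv,
        screen_min = ph$truth$screen_min,
        scr_events = scr_events_n,
        scr_per_h = day_gt$scr_per_h,
        rmssd_ms = day_gt$rmssd_ms,
        excursions = ph$truth$excursions)
    }

    streams[[pid]] <- p_streams
    all_events[[i]] <- purrr::list_rbind(p_events)
    all_locs[[i]] <- purrr::list_rbind(p_locs)
    gt[[i]] <- purrr::list_rbind(p_gt)
  }

  visits <- traj$visits |>
    mutate(date = study_start + .data$day_offset * SECONDS_PER_DAY)

  events_tbl <- purrr::list_rbind(all_events)
  if (nrow(events_tbl) == 0) {
    events_tbl <- tibble(participant_id = character(),
                         timestamp = numeric(), event_type = character(),
                         duration_s = numeric(), category = character())
  }
  locs_tbl <- purrr::list_rbind(all_locs)
  if (nrow(locs_tbl) == 0) {
    locs_tbl <- tibble(participant_id = character(), timestamp = numeric(),
                       lat = numeric(), lon = numeric())
  }
  gt_tbl <- purrr::list_rbind(gt)
  if (nrow(gt_tbl) == 0) {
    gt_tbl <- tibble(participant_id = character(), day = numeric(),
                     severity = numeric(), severity_dev = numeric(),
                     screen_min = numeric(), scr_events = numeric(),
                     scr_per_h = numeric(), rmssd_ms = numeric(),
                     excursions = numeric())
  }

  structure(
    list(config = config, participants = ids,
         trajectories = traj$trajectories, visits = visits,
         streams = streams,
         events = events_tbl,
         locations = locs_tbl,
         ground_truth = gt_tbl,
         manifest = list(seed = config$seed,
                         study_start = study_start,
                         tz_offset_hours = config$tz_offset_hours,
                         failure_days = purrr::list_rbind(failures))),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d participants, %d days, %d visits each, seed %d>\n",
    length(x$participants), x$config$n_days,
    length(x$config$visit_offsets_days), x$config$seed))
  invisible(x)
}

#' Simulate a visit-level feature matrix directly
#'
#' Fast path for model-level studies: draws the same latent severity
#' trajectories and channel couplings as [generate_cohort()], but emits
#' per-(participant, visit) daily feature values directly instead of raw
#' waveforms, skipping stream synthesis and extraction. Columns follow the
#' pipeline's naming and manifest scheme (modality-tagged, window-labelled),
#' so the result drops into [fit_severity_model()], [evaluate_cohort()] and
#' [boruta()] unchanged. Severity-coupled columns: daily screen total
#' (mobile), left/right SCR counts and RMSSD (wearable), total distance and
#' time at home (mobile). Uncoupled behavioural columns and `n_noise` pure
#' noise columns are appended so selection has chaff to reject.
#'
#' @param config a [cohort_config()].
#' @param n_noise number of pure-noise features (split between modalities).
#' @return list with `features` (tibble keyed by participant_id,
#'   visit_index; feature columns carry a `manifest` attribute), `visits`,
#'   `manifest`, and `informative`, the planted informative column names.
#' @export
simulate_visit_features <- function(config = cohort_config(), n_noise = 20) {
  stopifnot(inherits(config, "cohort_config"))
  traj <- simulate_trajectories(config)
  slopes <- coupling_slopes(config)
  ch <- config$channels
  ns <- config$noise_sd

  sev <- traj$trajectories
  sev0 <- sev |>
    filter(.data$day == 0) |>
    select("participant_id", sev_screen = "severity")
  rows <- traj$visits |>
    filter(.data$visit_index != "screen") |>
    left_join(sev, by = c("participant_id", "day_offset" = "day")) |>
    left_join(sev0, by = "participant_id") |>
    mutate(severity_dev = .data$severity - .data$sev_screen)

  n <- nrow(rows)
  with_seed(derive_seed(config$seed, "visitfeat"), {
    dv <- rows$severity_dev
    wear_h <- 24 - config$missingness$charging_gap_hours
    feats <- tibble(
      screen_total_min_w00_24 =
        pmax(10, ch$screen_min + slopes$screen_min * dv +
               rnorm(n, 0, ns$daily_phone)),
      scr_count_left_w00_24 =
        pmax(0, (ch$scr_per_h + slopes$scr_per_h * dv) * wear_h +
               rnorm(n, 0, ns$daily_scr * wear_h / 2)),
      scr_count_right_w00_24 =
        pmax(0, (ch$scr_per_h + slopes$scr_per_h * dv) * wear_h +
               rnorm(n, 0, ns$daily_scr * wear_h / 2)),
      hrv_rmssd_left_w00_24 =
        pmax(5, ch$rmssd_ms + slopes$rmssd_ms * dv + rnorm(n, 0, ns$daily_rmssd)),
      hrv_rmssd_right_w00_24 =
        pmax(5, ch$rmssd_ms + slopes$rmssd_ms * dv + rnorm(n, 0, ns$daily_rmssd)),
      total_distance_km_w00_24 =
        pmax(0, (ch$excursions + slopes$excursions * dv) * 4 +
               rnorm(n, 0, ns$daily_mobility * 4)),
      time_at_home_frac_w00_24 =
        clip(1 - (ch$excursions + slopes$excursions * dv) * 0.08 +
               rnorm(n, 0, 0.04), 0, 1),
      # uncoupled behavioural chaff
      n_calls_out_w00_24 = rpois(n, ch$calls_per_day / 2),
      n_sms_in_w00_24 = rpois(n, ch$sms_per_day / 2),
      n_app_launches_w00_24 = rpois(n, ch$apps_per_day),
      eda_scl_mean_left_w00_24 = ch$eda_tonic_uS + rnorm(n, 0, 0.2),
      temp_mean_left_w00_24 = 33 + rnorm(n, 0, ns$temp)
    )
    informative <- names(feats)[1:7]
    mobile_cols <- c("screen_total_min_w00_24", "total_distance_km_w00_24",
                     "time_at_home_frac_w00_24", "n_calls_out_w00_24",
                     "n_sms_in_w00_24", "n_app_launches_w00_24")
    for (j in seq_len(n_noise)) {
      nm <- sprintf("noise_%s_%02d_w00_24",
                    ifelse(j %% 2 == 0, "mobile", "wearable"), j)
      feats[[nm]] <- rnorm(n)
      if (j %% 2 == 0) mobile_cols <- c(mobile_cols, nm)
    }
    manifest <- tibble(
      feature = names(feats),
      modality = ifelse(names(feats) %in% mobile_cols, "mobile", "wearable"),
      window = "00-24")
    features <- bind_cols(
      rows |> select("participant_id", "visit_index"), feats)
    attr(features, "manifest") <- manifest
    class(features) <- c("moodsense_features", class(features))
    list(features = features, visits = traj$visits, manifest = manifest,
         informative = informative)
  })
}
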