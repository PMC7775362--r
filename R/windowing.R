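# Assemble the per-(participant, visit-day) feature matrix over clock-time
# windows and align it to the HDRS visit schedule.

#' Default clock-window set
#'
#' Four 6-hour windows, the 8 a.m. to 6 p.m. waking window, and the daily
#' aggregate.
#'
#' @return tibble (`label`, `start_h`, `end_h`).
#' @export
default_windows <- function() {
  tibble(label = c("w00_06", "w06_12", "w12_18", "w18_24", "w08_18",
                   "w00_24"),
         start_h = c(0, 6, 12, 18, 8, 0),
         end_h = c(6, 12, 18, 24, 18, 24))
}

eda_window_summary <- function(left_segs, right_segs, mask, window, ...) {
  ls <- slice_segments(left_segs, window[1], window[2])
  rs <- slice_segments(right_segs, window[1], window[2])
  if (length(ls) == 0 || length(rs) == 0) {
    return(eda_summary(sensor_channel("eda", "left", window[1], 4, numeric()),
                       sensor_channel("eda", "right", window[1], 4, numeric()),
                       mask, window, ...))
  }
  per <- purrr::map2(ls, rs[seq_along(ls)], function(l, r) {
    s <- eda_summary(l, r, mask, c(l$start_time, channel_end_time(l)), ...)
    s$n <- n_samples(l)
    s
  }) |> purrr::list_rbind()
  ok <- !is.na(per$scl_mean_left)
  if (!any(ok)) return(per[1, 1:8])
  w <- per$n[ok] / sum(per$n[ok])
  amp_w_l <- ifelse(per$scr_count_left[ok] > 0, per$scr_count_left[ok], 0)
  amp_w_r <- ifelse(per$scr_count_right[ok] > 0, per$scr_count_right[ok], 0)
  wmean <- function(x, wt) {
    keep <- is.finite(x) & wt > 0
    if (!any(keep)) return(NA_real_)
    sum(x[keep] * wt[keep]) / sum(wt[keep])
  }
  scl_l <- sum(per$scl_mean_left[ok] * w)
  scl_r <- sum(per$scl_mean_right[ok] * w)
  cnt_l <- sum(per$scr_count_left[ok])
  cnt_r <- sum(per$scr_count_right[ok])
  tibble(scl_mean_left = scl_l, scl_mean_right = scl_r,
         scr_count_left = cnt_l, scr_count_right = cnt_r,
         scr_amp_mean_left = wmean(per$scr_amp_mean_left[ok], amp_w_l),
         scr_amp_mean_right = wmean(per$scr_amp_mean_right[ok], amp_w_r),
         scl_diff = scl_r - scl_l, scr_count_diff = cnt_r - cnt_l)
}

#' Build the windowed feature matrix for a cohort
#'
#' Evaluates every wearable and mobile feature family per clock window for
#' each non-screening visit day (features from the same midnight-to-midnight
#' day as the HDRS administration; sleep uses the trailing 48-hour horizon).
#' Windows whose sensor coverage falls below `min_coverage` yield missing
#' values; remaining missing values are imputed later, at modeling time,
#' from training-set column medians. Normalized EDA columns (per-participant
#' z-scores across the participant's study period) are appended with a
#' `_znorm` suffix.
#'
#' @param cohort a [generate_cohort()] result, or any list with the same
#'   `streams`, `events`, `locations`, `visits`, `manifest` shape.
#' @param windows window set tibble (see [default_windows()]).
#' @param min_coverage minimum covered fraction of a window (default 0.5).
#' @param all_days emit every study day instead of only visit days
#'   (exploratory use; targets exist only at visits).
#' @param physio_params list overriding detector defaults: `sd_threshold_g`,
#'   `min_still_s`, `amp_threshold_uS`, `max_rise_s`.
#' @param mobile_params list overriding mobility defaults: `max_gap_s`,
#'   `home_radius_m`, `move_threshold_m`.
#' @return a `moodsense_features` tibble keyed by (`participant_id`,
#'   `visit_index`) with a `manifest` attribute tagging each column with its
#'   modality and window.
#' @export
build_feature_matrix <- function(cohort, windows = default_windows(),
                                 min_coverage = 0.5, all_days = FALSE,
                                 physio_params = list(),
                                 mobile_params = list()) {
  pp <- utils::modifyList(
    list(sd_threshold_g = 0.02, min_still_s = 30, amp_threshold_uS = 0.05,
         max_rise_s = 4), physio_params)
  mp <- utils::modifyList(
    list(max_gap_s = 6 * 3600, home_radius_m = 200, move_threshold_m = 100),
    mobile_params)
  tz <- cohort$manifest$tz_offset_hours %||% 0
  study_start <- cohort$manifest$study_start

  day_rows <- cohort$visits |>
    filter(.data$visit_index != "screen") |>
    select("participant_id", "visit_index", "day_offset")
  if (all_days) {
    day_rows <- tidyr::expand_grid(
      participant_id = unique(cohort$visits$participant_id),
      day_offset = seq_len(max(cohort$visits$day_offset))) |>
      mutate(visit_index = paste0("d", .data$day_offset))
  }

  per_participant <- split(day_rows, day_rows$participant_id)
  rows <- purrr::imap(per_participant, function(prows, pid) {
    st <- cohort$streams[[pid]]
    ev <- cohort$events |> filter(.data$participant_id == pid)
    loc <- cohort$locations |> filter(.data$participant_id == pid)
    grid_all <- downsample_location(
      loc |> select("timestamp", "lat", "lon"), max_gap_s = mp$max_gap_s)
    home <- infer_home(grid_all, tz)
    sessions <- sessionize_screen(ev)

    purrr::pmap(prows, function(participant_id, visit_index, day_offset) {
      day0 <- study_start + day_offset * SECONDS_PER_DAY
      feats <- list(participant_id = pid, visit_index = visit_index)
      day_mask <- purrr::map(
        slice_segments(st$acc %||% list(), day0, day0 + SECONDS_PER_DAY),
        detect_motionless_intervals,
        sd_threshold_g = pp$sd_threshold_g,
        min_duration_s = pp$min_still_s) |>
        purrr::list_rbind()
      phone_present <- nrow(ev |>
                              filter(.data$timestamp >= day0,
                                     .data$timestamp < day0 + SECONDS_PER_DAY)) > 0 ||
        any(loc$timestamp >= day0 & loc$timestamp < day0 + SECONDS_PER_DAY)

      for (wi in seq_len(nrow(windows))) {
        wlab <- windows$label[wi]
        w0 <- day0 + windows$start_h[wi] * 3600
        w1 <- day0 + windows$end_h[wi] * 3600
        wlen <- w1 - w0

        # ---- wearable ----
        eda_l <- slice_segments(st$eda_left %||% list(), w0, w1)
        wear_cov <- segments_coverage_s(eda_l, w0, w1) / wlen
        if (wear_cov >= min_coverage) {
          es <- eda_window_summary(st$eda_left, st$eda_right,
                                   day_mask, c(w0, w1),
                                   amp_threshold_uS = pp$amp_threshold_uS,
                                   max_rise_s = pp$max_rise_s)
          for (nm in names(es)) {
            feats[[paste0("eda_", nm, "_", wlab)]] <- es[[nm]]
          }
          for (w in c("left", "right")) {
            tsegs <- slice_segments(st[[paste0("temp_", w)]] %||% list(),
                                    w0, w1)
            tv <- unlist(purrr::map(tsegs, "values"))
            feats[[paste0("temp_mean_", w, "_", wlab)]] <-
              if (length(tv)) mean(tv) else NA_real_
            isegs <- slice_segments(st[[paste0("ibi_", w)]] %||% list(),
                                    w0, w1)
            nn_t <- numeric(); nn_d <- numeric()
            for (seg in isegs) {
              cl <- clean_ibi(seg)
              nn_t <- c(nn_t, seg$start_time + cl$nn$offset_s - w0)
              nn_d <- c(nn_d, cl$nn$duration_s)
            }
            td <- hrv_time_domain(nn_d * 1000)
            fd <- hrv_frequency_domain(nn_t, nn_d * 1000)
            feats[[paste0("hrv_sdnn_", w, "_", wlab)]] <- td$sdnn_ms
            feats[[paste0("hrv_rmssd_", w, "_", wlab)]] <- td$rmssd_ms
            feats[[paste0("hrv_lf_", w, "_", wlab)]] <- fd$lf_power
            feats[[paste0("hrv_hf_", w, "_", wlab)]] <- fd$hf_power
          }
          acc_segs <- slice_segments(st$acc %||% list(), w0, w1)
          ac <- sum(purrr::map_dbl(acc_segs, activity_count), na.rm = TRUE)
          feats[[paste0("activity_count_", wlab)]] <-
            if (length(acc_segs)) ac else NA_real_
        } else {
          for (nm in c("scl_mean_left", "scl_mean_right", "scr_count_left",
                       "scr_count_right", "scr_amp_mean_left",
                       "scr_amp_mean_right", "scl_diff", "scr_count_diff")) {
            feats[[paste0("eda_", nm, "_", wlab)]] <- NA_real_
          }
          for (w in c("left", "right")) {
            feats[[paste0("temp_mean_", w, "_", wlab)]] <- NA_real_
            feats[[paste0("hrv_sdnn_", w, "_", wlab)]] <- NA_real_
            feats[[paste0("hrv_rmssd_", w, "_", wlab)]] <- NA_real_
            feats[[paste0("hrv_lf_", w, "_", wlab)]] <- NA_real_
            feats[[paste0("hrv_hf_", w, "_", wlab)]] <- NA_real_
          }
          feats[[paste0("activity_count_", wlab)]] <- NA_real_
        }

        # ---- mobile ----
        if (phone_present) {
          ss <- screen_window_stats(sessions, c(w0, w1))
          cs <- summarize_comms(ev, c(w0, w1))
          as_ <- summarize_apps(ev, c(w0, w1))
          gwin <- grid_all |>
            filter(.data$slot_start >= w0, .data$slot_start < w1)
          obs_frac <- if (nrow(gwin)) mean(gwin$observed) else 0
          ms <- if (obs_frac >= min_coverage) {
            mobility_semantics(gwin, home, mp$home_radius_m,
                               mp$move_threshold_m, tz_offset_hours = tz)
          } else {
            mobility_semantics(gwin[0, ], home)
          }
          for (nm in names(ss)) feats[[paste0(nm, "_", wlab)]] <- ss[[nm]]
          for (nm in names(cs)) feats[[paste0(nm, "_", wlab)]] <- cs[[nm]]
          for (nm in names(as_)) feats[[paste0(nm, "_", wlab)]] <- as_[[nm]]
          for (nm in names(ms)) {
            feats[[paste0("mob_", nm, "_", wlab)]] <- ms[[nm]]
          }
        } else {
          mobile_names <- c(
            "screen_total_s", "screen_mean_s", "screen_median_s",
            "screen_sd_s", "screen_count", "n_calls_in", "n_calls_out",
            "call_dur_mean_in_s", "call_dur_mean_out_s",
            "call_dur_total_in_s", "call_dur_total_out_s", "n_sms_in",
            "n_sms_out", "n_app_launches", "n_distinct_categories")
          for (nm in mobile_names) feats[[paste0(nm, "_", wlab)]] <- NA_real_
          for (nm in c("time_at_home_frac", "transition_time_s",
                       "total_distance_km", "wstat_lat_sd", "wstat_lon_sd",
                       "lat_mean", "lat_median", "lat_sd", "lon_mean",
                       "lon_median", "lon_sd")) {
            feats[[paste0("mob_", nm, "_", wlab)]] <- NA_real_
          }
        }
      }

      # daily sleep over the trailing 48 h
      slp <- detect_sleep_period(st$acc %||% list(),
                                 day0 + SECONDS_PER_DAY,
                                 tz_offset_hours = tz)
      feats[["sleep_duration_h_w00_24"]] <- slp$est_sleep_duration_h
      as_tibble(feats)
    }) |> purrr::list_rbind()
  })
  mat <- purrr::list_rbind(rows)

  # normalized EDA: per-participant z-scores across the study period
  eda_cols <- grep("^eda_", names(mat), value = TRUE)
  for (cc in eda_cols) {
    zn <- paste0(cc, "_znorm")
    mat <- mat |>
      group_by(.data$participant_id) |>
      mutate(!!zn := {
        v <- .data[[cc]]
        s <- sd(v, na.rm = TRUE)
        if (is.na(s) || s == 0) v * NA_real_ else
          (v - mean(v, na.rm = TRUE)) / s
      }) |>
      ungroup()
  }

  manifest <- feature_manifest(setdiff(names(mat),
                                       c("participant_id", "visit_index")))
  attr(mat, "manifest") <- manifest
  class(mat) <- c("moodsense_features", class(mat))
  mat
}

# Derive the manifest (modality, window) from structured column names.
feature_manifest <- function(cols) {
  wearable_prefix <- c("eda_", "temp_", "hrv_", "activity_", "sleep_")
  tibble(feature = cols,
         modality = ifelse(
           purrr::map_lgl(cols, function(x) {
             any(startsWith(x, wearable_prefix))
           }), "wearable", "mobile"),
         window = stringr::str_extract(cols, "w\\d{2}_\\d{2}") %|%
           "w00_24")
}

`%|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Subset a feature matrix by modality
#'
#' @param matrix a `moodsense_features` tibble.
#' @param modality `"wearable"`, `"mobile"` or `"all"`.
#' @return the column subset, manifest updated, row keys unchanged.
#' @export
subset_by_modality <- function(matrix, modality = c("all", "wearable",
                                                    "mobile")) {
  modality <- match.arg(modality)
  manifest <- attr(matrix, "manifest")
  if (modality == "all") return(matrix)
  keep <- manifest$feature[manifest$modality == modality]
  keys <- intersect(c("participant_id", "visit_index", "visit_date"),
                    names(matrix))
  out <- matrix |> select(all_of(c(keys, keep)))
  attr(out, "manifest") <- manifest |> filter(.data$feature %in% keep)
  class(out) <- c("moodsense_features",
                  setdiff(class(out), "moodsense_features"))
  out
}
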