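# Smartphone-derived feature families: screen engagement, communication,
# app usage, and location/mobility semantics.

#' Sessionize screen on/off events
#'
#' Pairs each `SCREEN_ON` with the next `SCREEN_OFF`. An unmatched ON at the
#' end of the stream closes at `stream_end` (or the last event time); an OFF
#' without a preceding ON is ignored.
#'
#' @param events event tibble (see [read_event_log()]).
#' @param stream_end optional UTC epoch closing time for a trailing
#'   unmatched ON.
#' @return tibble of sessions: `start`, `end`, `duration_s`.
#' @export
sessionize_screen <- function(events, stream_end = NULL) {
  scr <- events |>
    filter(.data$event_type %in% c("SCREEN_ON", "SCREEN_OFF")) |>
    arrange(.data$timestamp)
  out <- list()
  open <- NA_real_
  for (k in seq_len(nrow(scr))) {
    if (scr$event_type[k] == "SCREEN_ON") {
      if (!is.na(open)) {
        # ON while already open: close the dangling session at the new ON
        out[[length(out) + 1]] <- c(open, scr$timestamp[k])
      }
      open <- scr$timestamp[k]
    } else if (!is.na(open)) {
      out[[length(out) + 1]] <- c(open, scr$timestamp[k])
      open <- NA_real_
    } # OFF without ON: ignored
  }
  if (!is.na(open)) {
    endt <- stream_end %||% if (nrow(scr) > 0) max(scr$timestamp) else open
    if (endt > open) out[[length(out) + 1]] <- c(open, endt)
  }
  if (length(out) == 0) {
    return(tibble(start = numeric(), end = numeric(),
                  duration_s = numeric()))
  }
  m <- do.call(rbind, out)
  tibble(start = m[, 1], end = m[, 2], duration_s = m[, 2] - m[, 1]) |>
    filter(.data$duration_s > 0)
}

#' Per-window screen-engagement statistics
#'
#' Sessions are split at the window boundaries, so a session crossing
#' midnight credits each side with its own share.
#'
#' @param sessions tibble from [sessionize_screen()].
#' @param window `c(t0, t1)` UTC epoch bounds.
#' @return one-row tibble: `screen_total_s`, `screen_mean_s`,
#'   `screen_median_s`, `screen_sd_s`, `screen_count`. A window with no
#'   sessions reports zero totals and counts (phone present but unused).
#' @export
screen_window_stats <- function(sessions, window) {
  s <- pmax(sessions$start, window[1])
  e <- pmin(sessions$end, window[2])
  d <- (e - s)[e > s]
  if (length(d) == 0) {
    return(tibble(screen_total_s = 0, screen_mean_s = 0,
                  screen_median_s = 0, screen_sd_s = 0, screen_count = 0))
  }
  tibble(screen_total_s = sum(d), screen_mean_s = mean(d),
         screen_median_s = median(d),
         screen_sd_s = if (length(d) > 1) sd(d) else 0,
         screen_count = length(d))
}

#' Per-window communication statistics
#'
#' Direction-stratified call and SMS counts plus call-duration statistics.
#'
#' @param events event tibble.
#' @param window `c(t0, t1)` UTC epoch bounds.
#' @return one-row tibble: `n_calls_in`, `n_calls_out`,
#'   `call_dur_mean_in_s`, `call_dur_mean_out_s`, `call_dur_total_in_s`,
#'   `call_dur_total_out_s`, `n_sms_in`, `n_sms_out`. Empty log gives zeros
#'   (zero-duration means reported as 0).
#' @export
summarize_comms <- function(events, window = c(-Inf, Inf)) {
  ev <- events |>
    filter(.data$timestamp >= window[1], .data$timestamp < window[2])
  cnt <- function(type) sum(ev$event_type == type)
  durs <- function(type) {
    d <- ev$duration_s[ev$event_type == type]
    d[is.finite(d)]
  }
  din <- durs("CALL_IN"); dout <- durs("CALL_OUT")
  tibble(
    n_calls_in = cnt("CALL_IN"), n_calls_out = cnt("CALL_OUT"),
    call_dur_mean_in_s = if (length(din)) mean(din) else 0,
    call_dur_mean_out_s = if (length(dout)) mean(dout) else 0,
    call_dur_total_in_s = sum(din), call_dur_total_out_s = sum(dout),
    n_sms_in = cnt("SMS_IN"), n_sms_out = cnt("SMS_OUT"))
}

#' Per-window app-usage statistics
#'
#' Counts launches and distinct anonymized category tokens; the tokens
#' themselves are never echoed into feature names or values.
#'
#' @param events event tibble.
#' @param window `c(t0, t1)` UTC epoch bounds.
#' @return one-row tibble: `n_app_launches`, `n_distinct_categories`.
#' @export
summarize_apps <- function(events, window = c(-Inf, Inf)) {
  ev <- events |>
    filter(.data$event_type == "APP_START",
           .data$timestamp >= window[1], .data$timestamp < window[2])
  tibble(n_app_launches = nrow(ev),
         n_distinct_categories = dplyr::n_distinct(ev$category[!is.na(ev$category)]))
}

#' Downsample a location trace to a regular 5-minute grid
#'
#' One fix per 5-minute slot (the slot's last observation). Interior gaps up
#' to `max_gap_s` are filled by linear interpolation of latitude and
#' longitude; longer gaps stay missing. The observed/imputed flag is kept
#' for downstream coverage accounting.
#'
#' @param trace tibble (timestamp, lat, lon), sorted.
#' @param slot_s grid resolution in seconds (default 300).
#' @param max_gap_s maximum gap bridged by interpolation (default 6 h).
#' @param span optional `c(t0, t1)` grid span; defaults to the trace span.
#' @return tibble: `slot_start`, `lat`, `lon`, `observed` (logical; `NA`
#'   coordinates where a gap exceeded `max_gap_s`).
#' @export
downsample_location <- function(trace, slot_s = 300, max_gap_s = 6 * 3600,
                                span = NULL) {
  if (nrow(trace) == 0) {
    return(tibble(slot_start = numeric(), lat = numeric(), lon = numeric(),
                  observed = logical()))
  }
  if (is.null(span)) {
    span <- c(floor(min(trace$timestamp) / slot_s) * slot_s,
              floor(max(trace$timestamp) / slot_s) * slot_s + slot_s)
  }
  slots <- seq(span[1], span[2] - slot_s, by = slot_s)
  obs <- trace |>
    mutate(slot_start = floor(.data$timestamp / slot_s) * slot_s) |>
    group_by(.data$slot_start) |>
    slice_tail(n = 1) |>
    ungroup() |>
    select("slot_start", "lat", "lon")
  grid <- tibble(slot_start = slots) |>
    left_join(obs, by = "slot_start") |>
    mutate(observed = !is.na(.data$lat))
  max_gap_slots <- floor(max_gap_s / slot_s)
  grid$lat <- zoo::na.approx(grid$lat, x = grid$slot_start, na.rm = FALSE,
                             maxgap = max_gap_slots)
  grid$lon <- zoo::na.approx(grid$lon, x = grid$slot_start, na.rm = FALSE,
                             maxgap = max_gap_slots)
  grid
}

#' Infer the home location from overnight fixes
#'
#' The densest ~100 m grid cell among fixes between local midnight and 6
#' a.m.; the home coordinate is the median fix within that cell. Falls back
#' to all fixes when no overnight fixes exist.
#'
#' @param grid downsampled grid from [downsample_location()].
#' @param tz_offset_hours participant-local clock offset.
#' @param cell_deg grid cell size in degrees (default 0.001, roughly 100 m).
#' @return named numeric `c(lat, lon)`, or `NULL` when the grid is empty.
#' @export
infer_home <- function(grid, tz_offset_hours = 0, cell_deg = 0.001) {
  g <- grid |> filter(!is.na(.data$lat))
  if (nrow(g) == 0) return(NULL)
  hr <- ((g$slot_start + tz_offset_hours * 3600) %% SECONDS_PER_DAY) / 3600
  night <- g[hr < 6, ]
  if (nrow(night) == 0) night <- g
  cell <- paste(round(night$lat / cell_deg), round(night$lon / cell_deg))
  top <- names(sort(table(cell), decreasing = TRUE))[1]
  inside <- night[cell == top, ]
  c(lat = median(inside$lat), lon = median(inside$lon))
}

#' Semantic mobility summary for one window
#'
#' From the regular 5-minute grid: fraction of observed slots within
#' `home_radius_m` of home (imputed slots count toward coordinate statistics
#' but not toward time at home, to avoid imputation-induced home inflation),
#' transition time (slots whose displacement from the previous slot exceeds
#' `move_threshold_m`, times the slot length), total haversine distance
#' travelled, dwell-time weighted latitude/longitude SDs over stationary
#' bouts, and plain location statistics.
#'
#' @param grid tibble from [downsample_location()], restricted to the
#'   window.
#' @param home `c(lat, lon)`; inferred via [infer_home()] when `NULL`.
#' @param home_radius_m at-home radius in metres (default 200).
#' @param move_threshold_m stationary/moving displacement threshold
#'   (default 100).
#' @param slot_s slot length in seconds (default 300).
#' @param tz_offset_hours passed to [infer_home()].
#' @return one-row tibble: `time_at_home_frac`, `transition_time_s`,
#'   `total_distance_km`, `wstat_lat_sd`, `wstat_lon_sd`, `lat_mean`,
#'   `lat_median`, `lat_sd`, `lon_mean`, `lon_median`, `lon_sd`. All-missing
#'   windows give all-`NA`.
#' @export
mobility_semantics <- function(grid, home = NULL, home_radius_m = 200,
                               move_threshold_m = 100, slot_s = 300,
                               tz_offset_hours = 0) {
  na_row <- tibble(time_at_home_frac = NA_real_, transition_time_s = NA_real_,
                   total_distance_km = NA_real_, wstat_lat_sd = NA_real_,
                   wstat_lon_sd = NA_real_, lat_mean = NA_real_,
                   lat_median = NA_real_, lat_sd = NA_real_,
                   lon_mean = NA_real_, lon_median = NA_real_,
                   lon_sd = NA_real_)
  g <- grid |> filter(!is.na(.data$lat))
  if (nrow(g) == 0) return(na_row)
  if (is.null(home)) home <- infer_home(grid, tz_offset_hours)

  d_home <- haversine_m(g$lat, g$lon, home["lat"], home["lon"])
  obs <- g |> filter(.data$observed)
  at_home <- if (nrow(obs) > 0) {
    mean(haversine_m(obs$lat, obs$lon, home["lat"], home["lon"]) <=
           home_radius_m)
  } else NA_real_

  n <- nrow(g)
  step_m <- if (n > 1) {
    haversine_m(g$lat[-n], g$lon[-n], g$lat[-1], g$lon[-1])
  } else numeric(0)
  # a step across a grid hole (non-adjacent slots) is not a displacement
  adjacent <- if (n > 1) diff(g$slot_start) == slot_s else logical(0)
  moving <- c(FALSE, step_m > move_threshold_m & adjacent)
  total_km <- sum(step_m[adjacent]) / 1000

  stat_run <- cumsum(moving)
  stat <- g[!moving, , drop = FALSE]
  runs <- stat |>
    mutate(run = stat_run[!moving]) |>
    group_by(.data$run) |>
    summarise(lat = mean(.data$lat), lon = mean(.data$lon),
              dwell_s = dplyr::n() * slot_s, .groups = "drop")

  tibble(
    time_at_home_frac = at_home,
    transition_time_s = sum(moving) * slot_s,
    total_distance_km = total_km,
    wstat_lat_sd = weighted_sd(runs$lat, runs$dwell_s),
    wstat_lon_sd = weighted_sd(runs$lon, runs$dwell_s),
    lat_mean = mean(g$lat), lat_median = median(g$lat),
    lat_sd = if (n > 1) sd(g$lat) else 0,
    lon_mean = mean(g$lon), lon_median = median(g$lon),
    lon_sd = if (n > 1) sd(g$lon) else 0)
}
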