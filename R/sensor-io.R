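# Raw-format readers and writers. The wearable dialect is the E4-style CSV
# export: row 1 = epoch start time, row 2 = sample rate in Hz, then samples
# (ACC: three integer columns in units of 1/64 g). IBI files have no rate
# row: row 1 is the start time, then offset,duration pairs in seconds.

#' Read a wrist-sensor CSV export
#'
#' Parses the two-row-header wearable CSV dialect: the first row is the UTC
#' epoch start time, the second the sampling rate in Hz (absent for IBI
#' files, whose subsequent rows are offset,duration pairs), followed by the
#' samples. Raw ACC integers are scaled by 1/64 to g. Timestamps are
#' reconstructed exactly as `start + i / rate` with no cumulative drift.
#'
#' @param path CSV file path.
#' @param modality one of `"eda"`, `"acc"`, `"temp"`, `"hr"`, `"ibi"`.
#' @param wrist `"left"` or `"right"`.
#' @return a [sensor_channel()].
#' @export
read_e4_channel <- function(path, modality, wrist) {
  modality <- match.arg(modality, c("eda", "acc", "temp", "hr", "ibi"))
  lines <- readLines(path)
  if (length(lines) == 0) {
    abort(paste0("malformed header in ", path, ": empty file (row 1)"),
          class = "moodsense_parse_error")
  }
  start <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))
  if (is.na(start)) {
    abort(paste0("malformed header in ", path,
                 ": row 1 is not an epoch start time"),
          class = "moodsense_parse_error")
  }
  if (modality == "ibi") {
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) == 0) {
      return(sensor_channel("ibi", wrist, start, NA,
                            tibble(offset_s = numeric(), duration_s = numeric())))
    }
    mat <- do.call(rbind, strsplit(body, ","))
    off <- suppressWarnings(as.numeric(mat[, 1]))
    dur <- suppressWarnings(as.numeric(mat[, 2]))
    bad <- which(is.na(off) | is.na(dur) | dur <= 0)
    if (length(bad) > 0) {
      abort(sprintf("invalid IBI sample at %s row %d", path, bad[1] + 1),
            class = "moodsense_parse_error")
    }
    if (is.unsorted(off)) {
      abort(sprintf("non-monotone IBI offsets at %s row %d",
                    path, which(diff(off) < 0)[1] + 2),
            class = "moodsense_parse_error")
    }
    return(sensor_channel("ibi", wrist, start, NA,
                          tibble(offset_s = off, duration_s = dur)))
  }
  if (length(lines) < 2) {
    abort(paste0("malformed header in ", path, ": missing rate (row 2)"),
          class = "moodsense_parse_error")
  }
  rate <- suppressWarnings(as.numeric(strsplit(lines[2], ",")[[1]][1]))
  if (is.na(rate) || rate <= 0) {
    abort(paste0("malformed header in ", path,
                 ": nonpositive or missing sample rate (row 2)"),
          class = "moodsense_parse_error")
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (modality == "acc") {
    if (length(body) == 0) {
      vals <- matrix(numeric(), ncol = 3)
    } else {
      mat <- do.call(rbind, strsplit(body, ","))
      if (ncol(mat) != 3) {
        abort(paste0("ACC rows must have 3 columns in ", path),
              class = "moodsense_parse_error")
      }
      vals <- matrix(suppressWarnings(as.numeric(mat)), ncol = 3) / 64
    }
  } else {
    vals <- suppressWarnings(as.numeric(body))
  }
  if (anyNA(vals)) {
    abort(sprintf("non-numeric sample at %s row %d", path,
                  which(is.na(if (is.matrix(vals)) vals[, 1] else vals))[1] + 2),
          class = "moodsense_parse_error")
  }
  sensor_channel(modality, wrist, start, rate, vals)
}

#' Write a wrist-sensor channel in the CSV export dialect
#'
#' @param ch a [sensor_channel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_e4_channel <- function(ch, path) {
  stopifnot(inherits(ch, "sensor_channel"))
  if (ch$modality == "ibi") {
    lines <- c(format(ch$start_time, scientific = FALSE),
               sprintf("%.9g,%.9g", ch$values$offset_s, ch$values$duration_s))
  } else if (ch$modality == "acc") {
    raw <- round(ch$values * 64)
    lines <- c(format(ch$start_time, scientific = FALSE),
               format(ch$sample_rate, scientific = FALSE),
               sprintf("%d,%d,%d", raw[, 1], raw[, 2], raw[, 3]))
  } else {
    lines <- c(format(ch$start_time, scientific = FALSE),
               format(ch$sample_rate, scientific = FALSE),
               sprintf("%.9g", ch$values))
  }
  writeLines(lines, path)
  invisible(path)
}

EVENT_TYPES <- c("SCREEN_ON", "SCREEN_OFF", "CALL_IN", "CALL_OUT",
                 "SMS_IN", "SMS_OUT", "APP_START")

parse_timestamps <- function(x, path) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  # fall back to ISO-8601
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(t)) {
    abort(sprintf("unparseable timestamp at %s row %d", path,
                  which(is.na(t))[1] + 1),
          class = "moodsense_parse_error")
  }
  as.numeric(t)
}

#' Read a smartphone event log
#'
#' Headered CSV with columns `timestamp` (epoch seconds or ISO-8601 UTC,
#' auto-detected), `event_type` (screen, call, SMS and app-launch events),
#' `duration_s` (calls only) and `category` (anonymized app-category token).
#' No app names or message/call content are ever present: the privacy
#' contract of passive sensing.
#'
#' @param path CSV path.
#' @return tibble with typed records, timestamps non-decreasing.
#' @export
read_event_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("timestamp", "event_type")
  if (!all(need %in% names(df))) {
    abort(paste0("event log ", path, " must have columns: ",
                 paste(need, collapse = ", ")),
          class = "moodsense_parse_error")
  }
  ts <- parse_timestamps(df$timestamp, path)
  bad <- which(!(df$event_type %in% EVENT_TYPES))
  if (length(bad) > 0) {
    abort(sprintf("unknown event_type '%s' at %s row %d",
                  df$event_type[bad[1]], path, bad[1] + 1),
          class = "moodsense_parse_error")
  }
  if (is.unsorted(ts)) {
    abort(sprintf("decreasing timestamps at %s row %d", path,
                  which(diff(ts) < 0)[1] + 2),
          class = "moodsense_parse_error")
  }
  dur <- if ("duration_s" %in% names(df)) {
    suppressWarnings(as.numeric(df$duration_s))
  } else rep(NA_real_, nrow(df))
  if (any(dur < 0, na.rm = TRUE)) {
    abort(sprintf("negative duration at %s row %d", path,
                  which(dur < 0)[1] + 1),
          class = "moodsense_parse_error")
  }
  tibble(timestamp = ts, event_type = df$event_type, duration_s = dur,
         category = if ("category" %in% names(df)) df$category else
           NA_character_)
}

#' Write a smartphone event log
#' @param events tibble as returned by [read_event_log()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  readr::write_csv(events |>
                     select("timestamp", "event_type", "duration_s",
                            "category"),
                   path, progress = FALSE)
  invisible(path)
}

#' Read a GPS location trace
#'
#' Headered CSV with `timestamp` (epoch or ISO-8601), `lat`, `lon` in
#' decimal degrees. Rows violating coordinate bounds or strict time ordering
#' are rejected with their line number.
#'
#' @param path CSV path.
#' @return tibble (timestamp, lat, lon).
#' @export
read_location_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("timestamp", "lat", "lon")
  if (!all(need %in% names(df))) {
    abort(paste0("location trace ", path, " must have columns: ",
                 paste(need, collapse = ", ")),
          class = "moodsense_parse_error")
  }
  ts <- parse_timestamps(df$timestamp, path)
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  bad <- which(is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180)
  if (length(bad) > 0) {
    abort(sprintf("invalid coordinate at %s row %d", path, bad[1] + 1),
          class = "moodsense_parse_error")
  }
  if (any(diff(ts) <= 0)) {
    abort(sprintf("non-increasing timestamps at %s row %d", path,
                  which(diff(ts) <= 0)[1] + 2),
          class = "moodsense_parse_error")
  }
  tibble(timestamp = ts, lat = lat, lon = lon)
}

#' Write a GPS location trace
#' @param trace tibble (timestamp, lat, lon).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_location_trace <- function(trace, path) {
  readr::write_csv(trace |> select("timestamp", "lat", "lon"), path,
                   progress = FALSE)
  invisible(path)
}

#' Write a feature matrix with its manifest sidecar
#'
#' One wide CSV row per (participant, visit), columns ordered by the
#' manifest; the manifest (feature name, modality tag, window label) goes to
#' a JSON sidecar at `<path>.manifest.json`. Missing cells survive the
#' roundtrip as missing.
#'
#' @param matrix a feature tibble with a `manifest` attribute, as built by
#'   [build_feature_matrix()] or [simulate_visit_features()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  manifest <- attr(matrix, "manifest")
  if (is.null(manifest)) abort("feature matrix has no manifest attribute")
  if (anyDuplicated(manifest$feature)) {
    abort("duplicate feature names in manifest",
          class = "moodsense_schema_error")
  }
  keys <- intersect(c("participant_id", "visit_index", "visit_date"),
                    names(matrix))
  ordered <- matrix |> select(all_of(c(keys, manifest$feature)))
  readr::write_csv(as_tibble(ordered), path, na = "NA", progress = FALSE)
  jsonlite::write_json(
    list(features = manifest, hash = manifest_hash(manifest)),
    paste0(path, ".manifest.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path (manifest sidecar expected alongside).
#' @return feature tibble with the `manifest` attribute restored.
#' @export
read_feature_matrix <- function(path) {
  manifest_raw <- jsonlite::read_json(paste0(path, ".manifest.json"),
                                      simplifyVector = TRUE)
  manifest <- as_tibble(manifest_raw$features)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = "NA")
  for (k in intersect(c("participant_id", "visit_index"), names(df))) {
    df[[k]] <- as.character(df[[k]])
  }
  attr(df, "manifest") <- manifest
  class(df) <- c("moodsense_features",
                 setdiff(class(df), "moodsense_features"))
  df
}
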