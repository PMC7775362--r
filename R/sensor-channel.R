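#' Uniformly sampled biosensor stream
#'
#' Lightweight container for one wrist-sensor stream: electrodermal activity
#' (`eda`, microsiemens), 3-axis acceleration (`acc`, g), skin temperature
#' (`temp`, degrees C), heart rate (`hr`, bpm), or inter-beat intervals
#' (`ibi`). All modalities except `ibi` are uniformly sampled and store a
#' start time (UTC epoch seconds) plus a sample rate in Hz, so the i-th
#' sample's timestamp is exactly `start_time + (i - 1) / sample_rate`. IBI
#' streams are event series: a two-column table of (offset from start in
#' seconds, beat-to-beat duration in seconds).
#'
#' @param modality one of `"eda"`, `"acc"`, `"temp"`, `"hr"`, `"ibi"`.
#' @param wrist `"left"` or `"right"`.
#' @param start_time UTC epoch seconds of the first sample.
#' @param sample_rate sampling rate in Hz; `NA` for `ibi`.
#' @param values numeric vector; an n-by-3 matrix for `acc`; a data frame
#'   with columns `offset_s`, `duration_s` for `ibi`.
#' @param units measurement units string.
#' @return an object of class `sensor_channel`.
#' @export
sensor_channel <- function(modality, wrist, start_time, sample_rate, values,
                           units = default_units(modality)) {
  modality <- match.arg(modality, c("eda", "acc", "temp", "hr", "ibi"))
  wrist <- match.arg(wrist, c("left", "right"))
  if (modality == "ibi") {
    if (!is.data.frame(values) ||
        !all(c("offset_s", "duration_s") %in% names(values))) {
      abort("ibi values must have columns offset_s, duration_s",
            class = "moodsense_channel_error")
    }
    if (any(values$duration_s <= 0)) {
      abort("ibi durations must be positive", class = "moodsense_channel_error")
    }
    if (is.unsorted(values$offset_s)) {
      abort("ibi offsets must be non-decreasing",
            class = "moodsense_channel_error")
    }
    sample_rate <- NA_real_
    values <- as.data.frame(values, stringsAsFactors = FALSE)
  } else {
    if (!is.na(sample_rate) && sample_rate <= 0) {
      abort("sample_rate must be positive", class = "moodsense_channel_error")
    }
    if (modality == "acc") {
      values <- as.matrix(values)
      if (ncol(values) != 3) {
        abort("acc values must have 3 columns",
              class = "moodsense_channel_error")
      }
    } else {
      values <- as.numeric(values)
    }
  }
  structure(
    list(modality = modality, wrist = wrist,
         start_time = as.numeric(start_time),
         sample_rate = as.numeric(sample_rate),
         values = values, units = units),
    class = "sensor_channel"
  )
}

default_units <- function(modality) {
  switch(modality, eda = "uS", acc = "g", temp = "degC", hr = "bpm",
         ibi = "s")
}

n_samples <- function(ch) {
  if (ch$modality == "ibi") nrow(ch$values)
  else if (ch$modality == "acc") nrow(ch$values)
  else length(ch$values)
}

#' Sample timestamps of a channel
#'
#' @param ch a [sensor_channel()].
#' @return numeric vector of UTC epoch seconds, one per sample (for IBI
#'   streams, the beat offsets added to the start time).
#' @export
channel_times <- function(ch) {
  stopifnot(inherits(ch, "sensor_channel"))
  if (ch$modality == "ibi") ch$start_time + ch$values$offset_s
  else ch$start_time + seq_len(n_samples(ch)) / ch$sample_rate -
    1 / ch$sample_rate
}

channel_end_time <- function(ch) {
  n <- n_samples(ch)
  if (n == 0) return(ch$start_time)
  if (ch$modality == "ibi") ch$start_time + max(ch$values$offset_s)
  else ch$start_time + n / ch$sample_rate
}

# Slice a uniform channel to [t0, t1). O(1): index arithmetic only.
slice_channel <- function(ch, t0, t1) {
  if (ch$modality == "ibi") {
    t <- ch$start_time + ch$values$offset_s
    keep <- t >= t0 & t < t1
    vals <- ch$values[keep, , drop = FALSE]
    vals$offset_s <- vals$offset_s - (t0 - ch$start_time)
    return(sensor_channel("ibi", ch$wrist, t0, NA, vals, ch$units))
  }
  n <- n_samples(ch)
  # 1e-9 guards against float noise when window edges land on sample times
  i0 <- max(1L, as.integer(ceiling((t0 - ch$start_time) * ch$sample_rate - 1e-9)) + 1L)
  i1 <- min(n, as.integer(ceiling((t1 - ch$start_time) * ch$sample_rate - 1e-9)))
  if (i0 > i1 || n == 0) {
    vals <- if (ch$modality == "acc") ch$values[0, , drop = FALSE] else
      ch$values[0]
    return(sensor_channel(ch$modality, ch$wrist, t0, ch$sample_rate, vals,
                          ch$units))
  }
  vals <- if (ch$modality == "acc") ch$values[i0:i1, , drop = FALSE] else
    ch$values[i0:i1]
  sensor_channel(ch$modality, ch$wrist,
                 ch$start_time + (i0 - 1) / ch$sample_rate,
                 ch$sample_rate, vals, ch$units)
}

# Slice every segment of a list of channels to [t0, t1), dropping empties.
slice_segments <- function(segments, t0, t1) {
  out <- lapply(segments, slice_channel, t0 = t0, t1 = t1)
  out[vapply(out, n_samples, integer(1)) > 0]
}

# Seconds of [t0, t1) covered by the segments (uniform channels).
segments_coverage_s <- function(segments, t0, t1) {
  if (length(segments) == 0) return(0)
  sum(vapply(segments, function(ch) {
    a <- max(t0, ch$start_time)
    b <- min(t1, channel_end_time(ch))
    max(0, b - a)
  }, numeric(1)))
}

#' @export
print.sensor_channel <- function(x, ...) {
  cat(sprintf("<sensor_channel %s/%s: %d samples @ %s Hz, start %.0f, %s>\n",
              x$modality, x$wrist, n_samples(x),
              ifelse(is.na(x$sample_rate), "event", format(x$sample_rate)),
              x$start_time, x$units))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.sensor_channel <- function(x, ...) {
  t <- channel_times(x)
  if (x$modality == "acc") {
    tibble(time = t, x = x$values[, 1], y = x$values[, 2], z = x$values[, 3])
  } else if (x$modality == "ibi") {
    tibble(time = t, duration_s = x$values$duration_s)
  } else {
    tibble(time = t, value = x$values)
  }
}
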