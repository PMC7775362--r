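# Independent brute-force oracles and scripted-stream builders used across
# the suite. Oracles are written from the defining formulas, independent of
# the implementation paths they check.

oracle_rmssd <- function(nn_ms) {
  d <- nn_ms[-1] - nn_ms[-length(nn_ms)]
  sqrt(sum(d^2) / length(d))
}

oracle_sdnn <- function(nn_ms) {
  m <- sum(nn_ms) / length(nn_ms)
  sqrt(sum((nn_ms - m)^2) / (length(nn_ms) - 1))
}

# closed-form haversine, R = 6371 km, in metres
oracle_haversine_m <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

# brute-force screen sessionization: explicit scan over ordered events
oracle_sessions <- function(ts, types) {
  out <- list()
  open <- NA
  for (k in seq_along(ts)) {
    if (types[k] == "SCREEN_ON") {
      if (!is.na(open)) out[[length(out) + 1]] <- c(open, ts[k])
      open <- ts[k]
    } else if (types[k] == "SCREEN_OFF" && !is.na(open)) {
      out[[length(out) + 1]] <- c(open, ts[k])
      open <- NA
    }
  }
  if (length(out) == 0) return(matrix(numeric(), ncol = 2))
  do.call(rbind, out)
}

scripted_event_log <- function(ts, types, duration_s = NA_real_,
                               category = NA_character_) {
  tibble::tibble(timestamp = ts, event_type = types,
                 duration_s = duration_s, category = category)
}

# small raw cohort used by several integration tests (built once per run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_participants = 2, n_days = 4,
        visit_offsets_days = c(0, 1, 2, 3, 4),
        seed = 402, rates = list(eda = 0.5, acc = 2, temp = 0.25),
        missingness = list(failure_prob = 0)))
    }
    cache
  }
})

flat_eda <- function(value = 0.5, fs = 4, n = 1200, start = 0) {
  sensor_channel("eda", "left", start, fs, rep(value, n))
}
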