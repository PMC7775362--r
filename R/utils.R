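# Internal helpers shared across modules.

SECONDS_PER_DAY <- 86400L
HDRS_MAX <- 52

# Deterministic 32-bit seed stream: fan a user seed out to per-stage /
# per-participant substreams so stages are individually reproducible.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(parts)) h <- (h * 31 + cc) %% 2147483629
  as.integer(h + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Order-insensitive content hash for feature manifests (schema safety between
# fit and predict). Plain polynomial rolling hash; collision-resistant enough
# for schema mismatch detection, no crypto intent.
manifest_hash <- function(manifest) {
  keys <- sort(paste(manifest$feature, manifest$modality, manifest$window,
                     sep = "|"))
  h <- 0
  for (k in keys) {
    for (cc in utf8ToInt(k)) h <- (h * 131 + cc) %% 2147483629
  }
  sprintf("%08x", h)
}

# Haversine great-circle distance in metres (R = 6371 km).
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

fail_field <- function(field, msg) {
  abort(paste0("invalid configuration: `", field, "` ", msg),
        class = "moodsense_config_error")
}

# Dwell-time weighted standard deviation (population-style, weights
# normalised to one).
weighted_sd <- function(x, w) {
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) == 0) return(NA_real_)
  if (length(x) == 1) return(0)
  wm <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - wm)^2) / sum(w))
}
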