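#' Configuration for the synthetic cohort generator
#'
#' Describes the study design being emulated: a ~9-week observational cohort
#' of participants with major depressive disorder, each wearing a wrist
#' biosensor on both wrists and carrying a study smartphone, with clinician
#' HDRS-17 assessments at a screening visit, a baseline visit one week later,
#' and biweekly follow-ups. Defaults reproduce that design: 31 completers, 63
#' days of streams, visits at day offsets 0/7/21/35/49/63, a 2-hour daily
#' charging/upload gap (so at most 22 h of wearable data per day), and latent
#' severity trajectories calibrated so the mean within-participant SD of
#' visit scores is about 3.7 HDRS points and severity declines about 15% from
#' the study start to the last visit.
#'
#' `effect_sizes` are signed multipliers linking the latent daily severity
#' (as a deviation from the participant's screening-day severity) to the
#' behavioural and physiological channels. At multiplier 1 the canonical
#' slopes are: +12 min of daily screen time per HDRS point
#' (`phone_engagement`; the sign is configurable because the direction
#' reported in the literature is ambiguous), -0.15 daily excursions per point
#' (`mobility`), +0.4 skin-conductance responses per hour per point
#' (`scr_rate`), and -1.2 ms RMSSD per point (`rmssd`).
#'
#' @param n_participants number of participants (>= 2).
#' @param n_days study length in days.
#' @param visit_offsets_days strictly increasing visit day offsets; the first
#'   is the screening visit.
#' @param seed integer master seed; every stream derives a substream from it.
#' @param effect_sizes named list of signed coupling multipliers:
#'   `phone_engagement`, `mobility`, `scr_rate`, `rmssd`.
#' @param noise_sd named list of non-negative noise scales: `eda` (sensor
#'   white noise, microsiemens), `temp` (degrees C), `daily_phone` (min/day),
#'   `daily_scr` (events/h), `daily_rmssd` (ms), `daily_mobility`
#'   (excursions/day).
#' @param missingness list with `charging_gap_hours` (daily wearable gap,
#'   default 2) and `failure_prob` (per participant-day probability that a
#'   technical failure wipes the whole day, default 0.05).
#' @param rates list of sampling rates in Hz: `eda` (default 4), `acc`
#'   (default 32), `temp` (default 4). Lower rates are useful for fast
#'   small-scale runs; the defaults match the wearable device.
#' @param trajectory list of latent-trajectory parameters: `baseline_mean`,
#'   `baseline_sd` (HDRS-17 at screening), `decline_frac` (mean relative
#'   decline over the study), `decline_rel_sd` (between-participant
#'   heterogeneity of the decline), `ar_phi`, `ar_sd` (AR(1) day-to-day
#'   autocorrelation and stationary SD), `rater_sd` (SD of integer-rounded
#'   rater noise on visit scores).
#' @param channels list of channel baselines: `screen_min` (daily screen
#'   minutes), `scr_per_h` (SCR events per hour), `rmssd_ms`, `excursions`
#'   (daily trips away from home), `home_lat`, `home_lon`, `eda_tonic_uS`,
#'   `asymmetry` (relative right-minus-left EDA offset), `mean_ibi_s`,
#'   `calls_per_day`, `sms_per_day`, `apps_per_day`.
#' @param tz_offset_hours fixed participant-local timezone offset applied
#'   when clock-time windows are resolved.
#' @return a validated `cohort_config` object (a named list).
#' @export
cohort_config <- function(n_participants = 31,
                          n_days = 63,
                          visit_offsets_days = c(0, 7, 21, 35, 49, 63),
                          seed = 1L,
                          effect_sizes = list(),
                          noise_sd = list(),
                          missingness = list(),
                          rates = list(),
                          trajectory = list(),
                          channels = list(),
                          tz_offset_hours = 0) {
  effect_sizes <- utils::modifyList(
    list(phone_engagement = 1, mobility = -1, scr_rate = 1, rmssd = -1),
    effect_sizes)
  noise_sd <- utils::modifyList(
    list(eda = 0.02, temp = 0.05, daily_phone = 25, daily_scr = 1.5,
         daily_rmssd = 4, daily_mobility = 0.4),
    noise_sd)
  missingness <- utils::modifyList(
    list(charging_gap_hours = 2, failure_prob = 0.05), missingness)
  rates <- utils::modifyList(list(eda = 4, acc = 32, temp = 4), rates)
  trajectory <- utils::modifyList(
    list(baseline_mean = 16, baseline_sd = 4, decline_frac = 0.2,
         decline_rel_sd = 0.3, ar_phi = 0.8, ar_sd = 2.8, rater_sd = 1.5),
    trajectory)
  channels <- utils::modifyList(
    list(screen_min = 180, scr_per_h = 6, rmssd_ms = 35, excursions = 2,
         home_lat = 42.36, home_lon = -71.09, eda_tonic_uS = 1.5,
         asymmetry = 0.15, mean_ibi_s = 0.8, calls_per_day = 3,
         sms_per_day = 8, apps_per_day = 20),
    channels)

  if (!is_count(n_participants) || n_participants < 2) {
    fail_field("n_participants", "must be an integer >= 2")
  }
  if (!is_count(n_days) || n_days < 1) {
    fail_field("n_days", "must be a positive integer")
  }
  if (!is.numeric(visit_offsets_days) || length(visit_offsets_days) < 2 ||
      any(diff(visit_offsets_days) <= 0) ||
      any(visit_offsets_days < 0) || any(visit_offsets_days > n_days)) {
    fail_field("visit_offsets_days",
               "must be strictly increasing, within [0, n_days]")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    fail_field("seed", "must be a single integer")
  }
  for (nm in names(noise_sd)) {
    if (!is.numeric(noise_sd[[nm]]) || noise_sd[[nm]] < 0) {
      fail_field(paste0("noise_sd$", nm), "must be >= 0")
    }
  }
  if (missingness$failure_prob < 0 || missingness$failure_prob > 1) {
    fail_field("missingness$failure_prob", "must be in [0, 1]")
  }
  if (missingness$charging_gap_hours < 0 ||
      missingness$charging_gap_hours > 24) {
    fail_field("missingness$charging_gap_hours", "must be in [0, 24]")
  }
  for (nm in names(rates)) {
    if (!is.numeric(rates[[nm]]) || rates[[nm]] <= 0) {
      fail_field(paste0("rates$", nm), "must be > 0")
    }
  }
  for (nm in c("phone_engagement", "mobility", "scr_rate", "rmssd")) {
    if (!is.numeric(effect_sizes[[nm]])) {
      fail_field(paste0("effect_sizes$", nm), "must be numeric")
    }
  }

  structure(
    list(n_participants = as.integer(n_participants),
         n_days = as.integer(n_days),
         visit_offsets_days = as.integer(visit_offsets_days),
         seed = as.integer(seed),
         effect_sizes = effect_sizes, noise_sd = noise_sd,
         missingness = missingness, rates = rates,
         trajectory = trajectory, channels = channels,
         tz_offset_hours = tz_offset_hours),
    class = "cohort_config"
  )
}

# Canonical per-HDRS-point slopes scaled by the signed effect multipliers.
coupling_slopes <- function(config) {
  es <- config$effect_sizes
  list(screen_min = 12 * es$phone_engagement,
       excursions = 0.15 * es$mobility,
       scr_per_h = 0.4 * es$scr_rate,
       rmssd_ms = 1.2 * es$rmssd)
}
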