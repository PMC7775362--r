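#' Simulate latent severity trajectories and visit scores
#'
#' Each participant gets a daily latent HDRS-17-scale severity: a linear
#' improvement trend (participant-specific total decline, on average
#' `decline_frac` of the screening level) plus stationary AR(1) day-to-day
#' fluctuation. Clinician visit scores are the latent severity at the visit
#' day plus integer-rounded Gaussian rater noise, clipped to the 0-52 scale.
#'
#' @param config a [cohort_config()].
#' @return list with `trajectories` (tibble: participant_id, day, severity)
#'   and `visits` (tibble: participant_id, visit_index, day_offset, hdrs17,
#'   hdrs_residual); residuals are visit minus screening score.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tr <- config$trajectory
  ids <- participant_ids(config$n_participants)
  n_days <- config$n_days

  per <- purrr::map(seq_along(ids), function(i) {
    with_seed(derive_seed(config$seed, "trajectory", i), {
      baseline <- clip(rnorm(1, tr$baseline_mean, tr$baseline_sd), 5, 40)
      decline <- baseline * tr$decline_frac *
        (1 + rnorm(1, 0, tr$decline_rel_sd))
      innov_sd <- tr$ar_sd * sqrt(1 - tr$ar_phi^2)
      a <- numeric(n_days + 1)
      a[1] <- rnorm(1, 0, tr$ar_sd)
      for (d in seq_len(n_days)) {
        a[d + 1] <- tr$ar_phi * a[d] + rnorm(1, 0, innov_sd)
      }
      sev <- clip(baseline - decline * (0:n_days) / n_days + a, 0, HDRS_MAX)
      rater <- rnorm(length(config$visit_offsets_days), 0, tr$rater_sd)
      scores <- as.integer(clip(round(
        sev[config$visit_offsets_days + 1] + rater), 0, HDRS_MAX))
      list(traj = tibble(participant_id = ids[i], day = 0:n_days,
                         severity = sev),
           visits = tibble(
             participant_id = ids[i],
             visit_index = visit_labels(length(scores)),
             day_offset = config$visit_offsets_days,
             hdrs17 = scores,
             hdrs_residual = scores - scores[1]))
    })
  })

  list(trajectories = purrr::list_rbind(purrr::map(per, "traj")),
       visits = purrr::list_rbind(purrr::map(per, "visits")))
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

visit_labels <- function(n) c("screen", paste0("v", seq_len(n - 1) + 1))
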