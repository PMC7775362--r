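# Deployment-scenario evaluation: user-split and time-split hold-outs,
# MAE/RMSE/Pearson-r metrics, naive baselines, model comparison, adherence.

#' Participant-level hold-out plans (user-split scenario)
#'
#' Randomly holds out `ceiling(frac_test * n)` participants per repeat; all
#' rows of a participant travel together, so performance reflects
#' generalization to unseen patients.
#'
#' @param participants character vector of participant ids.
#' @param frac_test held-out fraction (default 0.2).
#' @param seed integer seed; repeats use derived substreams.
#' @param n_repeats number of repeated splits (default 5).
#' @return tibble: `repeat_idx`, `participant_id`, `role` (train/test).
#' @export
make_user_split <- function(participants, frac_test = 0.2, seed = 1L,
                            n_repeats = 5) {
  participants <- unique(participants)
  n_test <- ceiling(frac_test * length(participants))
  purrr::map(seq_len(n_repeats), function(r) {
    test <- with_seed(derive_seed(seed, "user_split", r),
                      sample(participants, n_test))
    tibble(repeat_idx = r, participant_id = participants,
           role = ifelse(participants %in% test, "test", "train"))
  }) |> purrr::list_rbind()
}

#' Temporal hold-out plan (time-split scenario)
#'
#' Per participant: the screening visit (residual anchor) and the first
#' three follow-up scores form the training side; the last two scheduled
#' visits form the test side. Participants missing both test visits
#' contribute no test rows.
#'
#' @param visits visit tibble with `participant_id`, `visit_index`
#'   (`"screen"`, `"v2"`, ... in schedule order).
#' @return tibble: `participant_id`, `visit_index`, `role`; screening rows
#'   are tagged `train` (they anchor residualization and the baselines).
#' @export
make_time_split <- function(visits) {
  sched <- c("screen", "v2", "v3", "v4", "v5", "v6")
  out <- visits |>
    select("participant_id", "visit_index") |>
    mutate(role = ifelse(.data$visit_index %in% c("v5", "v6"), "test",
                         "train"))
  bad <- setdiff(unique(out$visit_index), sched)
  if (length(bad) > 0) {
    abort(paste0("time split expects the 6-visit schedule; unknown visits: ",
                 paste(bad, collapse = ", ")),
          class = "moodsense_data_error")
  }
  no_test <- out |>
    group_by(.data$participant_id) |>
    summarise(n_test = sum(.data$role == "test"), .groups = "drop") |>
    filter(.data$n_test == 0)
  if (nrow(no_test) > 0) {
    inform(paste0("participants with no test visits: ",
                  paste(no_test$participant_id, collapse = ", ")))
  }
  out
}

#' Hold-out regression metrics
#'
#' MAE, RMSE, Pearson r with a Fisher-z 95% confidence interval, and the
#' normalized MAE (100 * MAE / 52, the HDRS-17 range).
#'
#' @param estimates,observations equal-length numeric vectors.
#' @return one-row tibble: `n`, `mae`, `rmse`, `pearson_r`, `r_lo`, `r_hi`,
#'   `normalized_mae`. `r` is missing (with all-`NA` CI) for zero-variance
#'   inputs or fewer than 2 pairs.
#' @export
regression_metrics <- function(estimates, observations) {
  stopifnot(length(estimates) == length(observations))
  ok <- is.finite(estimates) & is.finite(observations)
  e <- estimates[ok]; o <- observations[ok]
  n <- length(e)
  if (n == 0) {
    return(tibble(n = 0L, mae = NA_real_, rmse = NA_real_,
                  pearson_r = NA_real_, r_lo = NA_real_, r_hi = NA_real_,
                  normalized_mae = NA_real_))
  }
  mae <- mean(abs(e - o))
  rmse <- sqrt(mean((e - o)^2))
  if (n < 2 || sd(e) == 0 || sd(o) == 0) {
    r <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    r <- cor(e, o)
    if (n > 3 && abs(r) < 1) {
      z <- atanh(r); se <- 1 / sqrt(n - 3)
      lo <- tanh(z - qnorm(0.975) * se)
      hi <- tanh(z + qnorm(0.975) * se)
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
  }
  tibble(n = n, mae = mae, rmse = rmse, pearson_r = r, r_lo = lo,
         r_hi = hi, normalized_mae = 100 * mae / HDRS_MAX)
}

#' Naive baseline estimates for a test set
#'
#' Three reference predictors on the absolute HDRS scale: the median of the
#' training scores applied to every test row (`group_median`), each
#' participant's screening score (`individual_screen`, i.e. residual
#' estimate 0), and each participant's median over visits v2-v4
#' (`individual_median`) - the last is definable only in the time-split
#' scenario and is reported as unavailable (`NA`) under user-split.
#'
#' @param train_visits visit tibble (with `hdrs17`) of the training rows
#'   (non-screen visits).
#' @param test_visits visit tibble of the test rows; needs `participant_id`,
#'   `visit_index`, `hdrs_screen`.
#' @param scenario `"user_split"` or `"time_split"`.
#' @return `test_visits` with baseline estimate columns on the absolute
#'   scale: `group_median`, `individual_screen`, `individual_median`.
#' @export
baseline_estimates <- function(train_visits, test_visits,
                               scenario = c("user_split", "time_split")) {
  scenario <- match.arg(scenario)
  gm <- median(train_visits$hdrs17)
  out <- test_visits |>
    mutate(group_median = gm,
           individual_screen = .data$hdrs_screen)
  if (scenario == "time_split") {
    im <- train_visits |>
      filter(.data$visit_index %in% c("v2", "v3", "v4")) |>
      group_by(.data$participant_id) |>
      summarise(individual_median = median(.data$hdrs17), .groups = "drop")
    out <- out |> left_join(im, by = "participant_id")
  } else {
    out$individual_median <- NA_real_
  }
  out
}

#' Compare models by one-way ANOVA over repeats
#'
#' @param mae_table tibble with `model` and `mae` (one row per model x
#'   repeat/fold).
#' @return one-row tibble: `f_stat`, `df1`, `df2`, `p_value`.
#' @export
compare_models <- function(mae_table) {
  stopifnot(all(c("model", "mae") %in% names(mae_table)))
  fit <- aov(mae ~ model, data = mae_table |>
               mutate(model = factor(.data$model)))
  s <- summary(fit)[[1]]
  tibble(f_stat = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
         p_value = s$`Pr(>F)`[1])
}

#' Wear-time adherence
#'
#' Percentage of the achievable daily wear time, where charging and upload
#' take 2 hours out of every day so at most `max_hours = 22` hours of data
#' are possible. Reported rounded to integer percent, for all days and
#' excluding flagged technical-failure days.
#'
#' @param hours_per_day numeric vector of daily uploaded hours.
#' @param max_hours achievable daily maximum (default 22).
#' @param technical_failure optional logical vector flagging days lost to
#'   technical problems.
#' @return one-row tibble: `percent_all`, `percent_excluding_technical`.
#' @export
adherence <- function(hours_per_day, max_hours = 22,
                      technical_failure = NULL) {
  pct <- function(h) {
    if (length(h) == 0) return(NA_real_)
    round(100 * mean(h) / max_hours)
  }
  keep <- if (is.null(technical_failure)) {
    rep(TRUE, length(hours_per_day))
  } else !technical_failure
  tibble(percent_all = pct(hours_per_day),
         percent_excluding_technical = pct(hours_per_day[keep]))
}

fit_and_score <- function(train_mat, test_mat, train_targets, test_targets,
                          config) {
  model <- fit_severity_model(train_mat, train_targets$hdrs_residual,
                              config)
  pred <- predict(model, test_mat)
  est <- pred$residual_est
  regression_metrics(est, test_targets$hdrs_residual)
}

#' Evaluate a cohort under both deployment scenarios
#'
#' Runs the full protocol on a feature matrix aligned to its visits: for
#' each modality subset (all features, mobile only, wearable only) fits the
#' ensemble on the training side of each split and scores the hold-out on
#' the residualized scale, alongside the three naive baselines. The
#' user-split scenario repeats `n_repeats` random participant hold-outs;
#' the time-split scenario has one deterministic split scored per test
#' visit fold (v5, v6) so dispersion and model comparison are defined.
#'
#' @param features a `moodsense_features` tibble.
#' @param visits visit tibble (with screening rows).
#' @param scenarios subset of `c("user_split", "time_split")`.
#' @param modalities subset of `c("all", "mobile", "wearable")`.
#' @param seed integer seed.
#' @param n_repeats user-split repeats (default 5).
#' @param model_cfg base [model_config()]; its seed/grouping is overridden
#'   per scenario (grouped CV folds under user-split, plain under
#'   time-split).
#' @return a `moodsense_report`: tibble of per-scenario, per-model,
#'   per-repeat metrics plus aggregated summary and ANOVA comparison in
#'   attributes.
#' @export
evaluate_cohort <- function(features, visits,
                            scenarios = c("user_split", "time_split"),
                            modalities = c("all", "mobile", "wearable"),
                            seed = 1L, n_repeats = 5,
                            model_cfg = model_config()) {
  targets <- residualize(visits)
  keyed <- features |>
    inner_join(targets, by = c("participant_id", "visit_index"))
  stopifnot(nrow(keyed) > 0)
  feat_cols <- setdiff(names(features),
                       c("participant_id", "visit_index", "visit_date"))
  manifest <- attr(features, "manifest")

  get_mat <- function(rows, modality) {
    m <- keyed[rows, c("participant_id", "visit_index", feat_cols)]
    attr(m, "manifest") <- manifest
    class(m) <- c("moodsense_features",
                  setdiff(class(m), "moodsense_features"))
    subset_by_modality(m, modality)
  }

  results <- list()
  for (scenario in scenarios) {
    if (scenario == "user_split") {
      plans <- make_user_split(unique(keyed$participant_id), 0.2, seed,
                               n_repeats)
      folds <- split(plans, plans$repeat_idx)
    } else {
      plan <- make_time_split(visits |>
                                select("participant_id", "visit_index"))
      folds <- list(`1` = plan |> mutate(repeat_idx = 1))
    }
    for (f in folds) {
      ridx <- f$repeat_idx[1]
      if (scenario == "user_split") {
        te <- keyed$participant_id %in%
          f$participant_id[f$role == "test"]
      } else {
        key <- paste(keyed$participant_id, keyed$visit_index)
        te <- key %in% paste(f$participant_id, f$visit_index)[f$role == "test"]
      }
      if (!any(te) || !any(!te)) next
      cfg <- model_cfg
      cfg$seed <- derive_seed(seed, scenario, ridx)
      cfg$grouped_cv <- scenario == "user_split"
      for (modality in modalities) {
        tr_mat <- get_mat(which(!te), modality)
        te_mat <- get_mat(which(te), modality)
        met <- fit_and_score(tr_mat, te_mat, keyed[!te, ], keyed[te, ],
                             cfg)
        results[[length(results) + 1]] <- met |>
          mutate(scenario = scenario, model = modality, repeat_idx = ridx,
                 .before = 1)
      }
      # baselines on the residual scale
      bl <- baseline_estimates(
        keyed[!te, c("participant_id", "visit_index", "hdrs17")],
        keyed[te, c("participant_id", "visit_index", "hdrs17",
                    "hdrs_screen", "hdrs_residual")],
        scenario)
      for (b in c("group_median", "individual_screen",
                  "individual_median")) {
        est_resid <- bl[[b]] - bl$hdrs_screen
        met <- regression_metrics(est_resid, bl$hdrs_residual)
        results[[length(results) + 1]] <- met |>
          mutate(scenario = scenario, model = paste0("baseline_", b),
                 repeat_idx = ridx, .before = 1)
      }
    }
  }
  report <- purrr::list_rbind(results)
  structure(report, class = c("moodsense_report", class(report)))
}

#' Summarise an evaluation report (mean and SD over repeats)
#'
#' @param report a `moodsense_report` from [evaluate_cohort()].
#' @return tibble: scenario, model, mae (mean), mae_sd, rmse, rmse_sd,
#'   pearson_r, r_lo, r_hi, normalized_mae.
#' @export
summarize_report <- function(report) {
  report |>
    as_tibble() |>
    group_by(.data$scenario, .data$model) |>
    summarise(mae_sd = sd(.data$mae), mae = mean(.data$mae),
              rmse_sd = sd(.data$rmse), rmse = mean(.data$rmse),
              pearson_r = mean(.data$pearson_r, na.rm = TRUE),
              r_lo = mean(.data$r_lo, na.rm = TRUE),
              r_hi = mean(.data$r_hi, na.rm = TRUE),
              normalized_mae = round(100 * mean(.data$mae) / HDRS_MAX, 1),
              .groups = "drop") |>
    select("scenario", "model", "mae", "mae_sd", "rmse", "rmse_sd",
           "pearson_r", "r_lo", "r_hi", "normalized_mae")
}
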