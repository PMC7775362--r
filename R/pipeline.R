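# Configuration and end-to-end orchestration. The package's function
# surface (read_run_config + run_pipeline) is the entry point; every stage
# writes its outputs plus a JSON run manifest so reruns are reproducible
# and auditable.

default_run_config <- function() {
  list(
    seed = 1L,
    pipeline = list(level = "features", out_dir = "moodsense_out"),
    cohort = list(n_participants = 31, n_days = 63,
                  visit_offsets_days = c(0, 7, 21, 35, 49, 63)),
    features = list(
      physio = list(sd_threshold_g = 0.02, min_still_s = 30,
                    amp_threshold_uS = 0.05, max_rise_s = 4),
      mobile = list(max_gap_s = 21600, home_radius_m = 200,
                    move_threshold_m = 100),
      min_coverage = 0.5),
    model = list(n_linear = 15, n_nonlinear = 10, n_folds = 10,
                 num_trees = 500),
    evaluation = list(scenarios = c("user_split", "time_split"),
                      modalities = c("all", "mobile", "wearable"),
                      n_repeats = 5),
    boruta = list(enabled = TRUE, max_iter = 50, alpha = 0.05,
                  num_trees = 500)
  )
}

check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(ref)) {
      abort(paste0("unknown configuration key: ", full),
            class = "moodsense_config_error")
    }
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
        is.list(cfg[[nm]])) {
      check_known_keys(cfg[[nm]], ref[[nm]], full)
    }
  }
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (schema safety); known keys override the
#' defaults of [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "moodsense_config_error")
    }
    user <- yaml::read_yaml(path)
    check_known_keys(user, cfg)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(cfg) {
  manifest_hash(tibble(
    feature = jsonlite::toJSON(cfg, auto_unbox = TRUE),
    modality = "", window = ""))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort (at the visit-feature level by default, or from raw
#' streams when `pipeline.level` is `"raw"`), evaluates the ensemble under
#' the configured scenarios and modality subsets against the naive
#' baselines, optionally runs Boruta selection, and writes a report CSV +
#' JSON and a run manifest into `out_dir`.
#'
#' @param config a configuration list from [read_run_config()], or a path
#'   to a YAML file.
#' @param out_dir output directory (overrides `pipeline.out_dir`).
#' @return invisibly, a list with `report`, `summary`, `selection` (or
#'   `NULL`) and the written file paths.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  check_known_keys(config, default_run_config())
  out_dir <- out_dir %||% config$pipeline$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cc <- cohort_config(
    n_participants = config$cohort$n_participants,
    n_days = config$cohort$n_days,
    visit_offsets_days = config$cohort$visit_offsets_days,
    seed = config$seed)

  if (identical(config$pipeline$level, "raw")) {
    cohort <- generate_cohort(cc)
    features <- build_feature_matrix(
      cohort, min_coverage = config$features$min_coverage,
      physio_params = config$features$physio,
      mobile_params = config$features$mobile)
    visits <- cohort$visits
  } else {
    sim <- simulate_visit_features(cc)
    features <- sim$features
    visits <- sim$visits
  }

  mcfg <- model_config(seed = config$seed,
                       n_linear = config$model$n_linear,
                       n_nonlinear = config$model$n_nonlinear,
                       n_folds = config$model$n_folds,
                       num_trees = config$model$num_trees)
  report <- evaluate_cohort(
    features, visits,
    scenarios = config$evaluation$scenarios,
    modalities = config$evaluation$modalities,
    seed = config$seed, n_repeats = config$evaluation$n_repeats,
    model_cfg = mcfg)
  summary_tbl <- summarize_report(report)

  selection <- NULL
  if (isTRUE(config$boruta$enabled)) {
    targets <- residualize(visits) |>
      inner_join(features |> select("participant_id", "visit_index"),
                 by = c("participant_id", "visit_index"))
    aligned <- features |>
      inner_join(targets |> select("participant_id", "visit_index",
                                   "hdrs_residual"),
                 by = c("participant_id", "visit_index"))
    fm <- aligned |> select(-"hdrs_residual")
    # median-impute for selection (Boruta needs a complete matrix)
    for (cc2 in feature_columns(fm)) {
      v <- fm[[cc2]]
      if (anyNA(v)) fm[[cc2]][is.na(v)] <- median(v, na.rm = TRUE)
      if (anyNA(fm[[cc2]])) fm[[cc2]] <- 0
    }
    bres <- boruta(fm, aligned$hdrs_residual,
                   max_iter = config$boruta$max_iter,
                   alpha = config$boruta$alpha, seed = config$seed,
                   num_trees = config$boruta$num_trees)
    selection <- summarize_selection(bres, attr(features, "manifest"))
    readr::write_csv(selection$ranking,
                     file.path(out_dir, "feature_ranking.csv"),
                     progress = FALSE)
  }

  report_csv <- file.path(out_dir, "evaluation_report.csv")
  readr::write_csv(summary_tbl, report_csv, progress = FALSE)
  jsonlite::write_json(summary_tbl, file.path(out_dir,
                                              "evaluation_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("moodsense")),
    seed = config$seed,
    config_hash = config_hash(config),
    outputs = c("evaluation_report.csv", "evaluation_report.json",
                if (!is.null(selection)) "feature_ranking.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(report = report, summary = summary_tbl,
                 selection = selection,
                 files = file.path(out_dir, manifest$outputs)))
}
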