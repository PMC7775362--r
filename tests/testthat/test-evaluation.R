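# Deployment-scenario evaluation: splits, metrics, baselines, model
# comparison, adherence.

test_that("user split holds out ceiling(0.2 n) participants, disjointly", {
  ids <- sprintf("P%02d", 1:31)
  plans <- make_user_split(ids, 0.2, seed = 7, n_repeats = 5)
  expect_equal(length(unique(plans$repeat_idx)), 5)
  for (r in 1:5) {
    p <- plans[plans$repeat_idx == r, ]
    expect_equal(sum(p$role == "test"), 7) # ceiling(0.2 * 31)
    expect_equal(sum(p$role == "train"), 24)
    expect_length(intersect(p$participant_id[p$role == "test"],
                            p$participant_id[p$role == "train"]), 0)
  }
  expect_identical(make_user_split(ids, 0.2, seed = 7, n_repeats = 5),
                   plans)
  expect_false(identical(
    plans$role, make_user_split(ids, 0.2, seed = 8, n_repeats = 5)$role))
})

test_that("time split trains on screen + v2-v4 and tests on v5-v6", {
  v <- tidyr::expand_grid(participant_id = c("A", "B"),
                          visit_index = c("screen", "v2", "v3", "v4", "v5",
                                          "v6"))
  plan <- make_time_split(v)
  expect_setequal(plan$visit_index[plan$role == "test"], c("v5", "v6"))
  expect_equal(sum(plan$role == "test"), 4)
  # per participant, every test visit is scheduled later than every train one
  sched <- c(screen = 1, v2 = 2, v3 = 3, v4 = 4, v5 = 5, v6 = 6)
  for (p in c("A", "B")) {
    pp <- plan[plan$participant_id == p, ]
    expect_gt(min(sched[pp$visit_index[pp$role == "test"]]),
              max(sched[pp$visit_index[pp$role == "train"]]))
  }
  # a participant with only four visits contributes no test rows
  v4only <- v[!(v$participant_id == "B" & v$visit_index %in% c("v5", "v6")), ]
  expect_message(plan2 <- make_time_split(v4only), "no test visits")
  expect_equal(sum(plan2$role == "test" & plan2$participant_id == "B"), 0)
})

test_that("metrics match hand computations and degenerate cleanly", {
  m <- regression_metrics(c(10, 12), c(11, 15))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, sqrt(5))
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3))$mae, 0)
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3))$pearson_r, 1)
  # normalized MAE uses the 0-52 HDRS-17 range
  expect_equal(round(regression_metrics(rep(3.88, 4) + c(0, 0, 0, 0),
                                        rep(0, 4))$normalized_mae, 1), 7.5)
  z <- regression_metrics(rep(1, 5), rnorm(5))
  expect_true(is.na(z$pearson_r))
  expect_equal(z$n, 5)
})

test_that("Fisher CI contains r and narrows with n", {
  set.seed(13)
  x <- rnorm(500); y <- 0.5 * x + rnorm(500)
  wide <- regression_metrics(x[1:30], y[1:30])
  narrow <- regression_metrics(x, y)
  for (m in list(wide, narrow)) {
    expect_gt(m$pearson_r, m$r_lo)
    expect_lt(m$pearson_r, m$r_hi)
  }
  expect_lt(narrow$r_hi - narrow$r_lo, wide$r_hi - wide$r_lo)
})

test_that("MAE never exceeds RMSE", {
  set.seed(14)
  for (k in 1:50) {
    e <- rnorm(20); o <- rnorm(20)
    m <- regression_metrics(e, o)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("baselines follow their closed forms, with NA where undefined", {
  train <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B", "B"),
    visit_index = c("v2", "v3", "v4", "v2", "v3", "v4"),
    hdrs17 = c(18, 20, 24, 10, 12, 14))
  test <- tibble::tibble(
    participant_id = c("A", "B"), visit_index = "v5",
    hdrs17 = c(21, 9), hdrs_screen = c(22, 11), hdrs_residual = c(-1, -2))
  ts <- baseline_estimates(train, test, "time_split")
  expect_equal(ts$group_median, c(16, 16)) # median of {18,20,24,10,12,14}
  expect_equal(ts$individual_screen, c(22, 11))
  expect_equal(ts$individual_median, c(20, 12))
  us <- baseline_estimates(train, test, "user_split")
  expect_true(all(is.na(us$individual_median)))
  # the screening baseline predicts residual zero by construction
  expect_equal(us$individual_screen - us$hdrs_screen, c(0, 0))
})

test_that("model comparison reports ANOVA df = (2, 12) for 3 models x 5 repeats", {
  set.seed(15)
  tab <- tidyr::expand_grid(model = c("all", "mobile", "wearable"),
                            repeat_idx = 1:5) |>
    dplyr::mutate(mae = rnorm(15, 4, 0.3) +
                    ifelse(.data$model == "mobile", -0.5, 0))
  cm <- compare_models(tab)
  expect_equal(cm$df1, 2)
  expect_equal(cm$df2, 12)
  # identical columns give F ~ 0
  flat <- tab |> dplyr::mutate(mae = rep(c(4, 4.2, 4.1, 3.9, 4.05), 3))
  expect_lt(compare_models(flat)$f_stat, 1e-12)
})

test_that("label permutation keeps null ANOVA p-values roughly uniform", {
  set.seed(16)
  ps <- replicate(200, {
    tab <- tidyr::expand_grid(model = c("a", "b", "c"), repeat_idx = 1:5) |>
      dplyr::mutate(mae = rnorm(15))
    compare_models(tab)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("adherence arithmetic matches the 22-hour daily maximum", {
  expect_equal(adherence(17)$percent_all, 77)
  expect_equal(adherence(15.5)$percent_all, 70)
  expect_equal(adherence(22)$percent_all, 100)
  a <- adherence(c(20, 20, 2, 20), technical_failure = c(FALSE, FALSE, TRUE,
                                                         FALSE))
  expect_equal(a$percent_all, round(100 * 15.5 / 22))
  expect_equal(a$percent_excluding_technical, round(100 * 20 / 22))
})

test_that("evaluation report has sane structure on a small cohort", {
  sim <- simulate_visit_features(cohort_config(n_participants = 12,
                                               seed = 61))
  rep <- evaluate_cohort(sim$features, sim$visits,
                         scenarios = "user_split", modalities = "all",
                         seed = 61, n_repeats = 2,
                         model_cfg = model_config(
                           n_folds = 4,
                           xgb_grid = list(nrounds = 50, max_depth = 2),
                           num_trees = 200))
  s <- summarize_report(rep)
  ok <- !is.na(s$mae)
  expect_true(any(ok))
  expect_true(all(s$mae[ok] <= s$rmse[ok] + 1e-12))
  expect_setequal(unique(s$model),
                  c("all", "baseline_group_median",
                    "baseline_individual_screen",
                    "baseline_individual_median"))
  expect_equal(s$normalized_mae[ok], round(100 * s$mae[ok] / 52, 1))
})

test_that("baselines hold their own on coupling-free cohorts", {
  cc <- cohort_config(
    n_participants = 16, seed = 62,
    effect_sizes = list(phone_engagement = 0, mobility = 0, scr_rate = 0,
                        rmssd = 0))
  sim <- simulate_visit_features(cc)
  rep <- evaluate_cohort(sim$features, sim$visits,
                         scenarios = "user_split", modalities = "all",
                         seed = 62, n_repeats = 3,
                         model_cfg = model_config(
                           n_folds = 4,
                           xgb_grid = list(nrounds = 50, max_depth = 2),
                           num_trees = 200))
  s <- summarize_report(rep)
  model_mae <- s$mae[s$model == "all"]
  gm <- s$mae[s$model == "baseline_group_median"]
  # without couplings the model cannot do meaningfully better than the
  # group-median guess
  expect_gt(model_mae, gm - 0.5)
})
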