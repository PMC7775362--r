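# Residualization and the reduction + boosting/forest ensemble.

test_that("residualization subtracts the screening score", {
  v <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B"),
    visit_index = c("screen", "v2", "v3", "screen", "v2"),
    hdrs17 = c(22, 18, 25, 10, 12))
  r <- residualize(v)
  expect_equal(nrow(r), 3)
  expect_equal(r$hdrs_residual, c(-4, 3, 2))
  # adding a constant to one participant's scores leaves residuals unchanged
  v2 <- v
  v2$hdrs17[v2$participant_id == "A"] <- v2$hdrs17[v2$participant_id == "A"] + 5
  expect_equal(residualize(v2)$hdrs_residual, r$hdrs_residual)
  # missing or duplicated screening rows are structural errors
  expect_error(residualize(v[v$visit_index != "screen", ]),
               class = "moodsense_data_error")
  expect_error(residualize(rbind(v, v[1, ])),
               class = "moodsense_data_error")
})

test_that("the reducer outputs 25 transformed features when supported", {
  sim <- simulate_visit_features(cohort_config(n_participants = 30,
                                               seed = 51), n_noise = 30)
  tg <- residualize(sim$visits)
  al <- dplyr::inner_join(
    sim$features, tg[, c("participant_id", "visit_index", "hdrs_residual")],
    by = c("participant_id", "visit_index"))
  fm <- al |> dplyr::select(-"hdrs_residual")
  m <- fit_severity_model(fm, al$hdrs_residual,
                          model_config(seed = 1, n_folds = 5))
  expect_equal(m$reducer$k1 + m$reducer$k2, 25)
  expect_equal(glance(m)$n_transformed, 25)
})

test_that("fitting is deterministic given the seed", {
  sim <- simulate_visit_features(cohort_config(n_participants = 15,
                                               seed = 52))
  tg <- residualize(sim$visits)
  al <- dplyr::inner_join(
    sim$features, tg[, c("participant_id", "visit_index", "hdrs_residual")],
    by = c("participant_id", "visit_index"))
  fm <- al |> dplyr::select(-"hdrs_residual")
  cfg <- model_config(seed = 9, n_folds = 5,
                      xgb_grid = list(nrounds = 50, max_depth = 2),
                      num_trees = 200)
  m1 <- fit_severity_model(fm, al$hdrs_residual, cfg)
  m2 <- fit_severity_model(fm, al$hdrs_residual, cfg)
  expect_equal(predict(m1, fm)$residual_est, predict(m2, fm)$residual_est,
               tolerance = 1e-12)
})

test_that("constant targets give near-zero predictions", {
  sim <- simulate_visit_features(cohort_config(n_participants = 12,
                                               seed = 53))
  fm <- sim$features
  m <- fit_severity_model(fm, rep(0, nrow(fm)),
                          model_config(seed = 2, n_folds = 4,
                                       xgb_grid = list(nrounds = 50,
                                                       max_depth = 2),
                                       num_trees = 200))
  p <- predict(m, fm)
  expect_true(all(abs(p$residual_est) < 0.5))
})

test_that("column order does not change predictions; schema mismatch refuses", {
  sim <- simulate_visit_features(cohort_config(n_participants = 12,
                                               seed = 54))
  tg <- residualize(sim$visits)
  al <- dplyr::inner_join(
    sim$features, tg[, c("participant_id", "visit_index", "hdrs_residual")],
    by = c("participant_id", "visit_index"))
  fm <- al |> dplyr::select(-"hdrs_residual")
  m <- fit_severity_model(fm, al$hdrs_residual,
                          model_config(seed = 3, n_folds = 4,
                                       xgb_grid = list(nrounds = 50,
                                                       max_depth = 2),
                                       num_trees = 200))
  shuffled <- fm[, c(1, 2, sample(3:ncol(fm)))]
  attr(shuffled, "manifest") <- attr(fm, "manifest")
  expect_equal(predict(m, shuffled)$residual_est,
               predict(m, fm)$residual_est, tolerance = 1e-12)
  # a foreign manifest is refused
  other <- attr(fm, "manifest")
  other$feature[1] <- "something_else"
  bad <- fm
  attr(bad, "manifest") <- other
  expect_error(predict(m, bad), class = "moodsense_schema_error")
})

test_that("absolute estimates add the screening score and clip to 0-52", {
  sim <- simulate_visit_features(cohort_config(n_participants = 12,
                                               seed = 55))
  tg <- residualize(sim$visits)
  al <- dplyr::inner_join(
    sim$features, tg[, c("participant_id", "visit_index", "hdrs_residual",
                         "hdrs_screen")],
    by = c("participant_id", "visit_index"))
  fm <- al |> dplyr::select(-"hdrs_residual", -"hdrs_screen")
  m <- fit_severity_model(fm, al$hdrs_residual,
                          model_config(seed = 4, n_folds = 4,
                                       xgb_grid = list(nrounds = 50,
                                                       max_depth = 2),
                                       num_trees = 200))
  screening <- tg |> dplyr::distinct(.data$participant_id, .data$hdrs_screen)
  p <- predict(m, fm, screening = screening)
  expect_true(all(p$hdrs_est >= 0 & p$hdrs_est <= 52))
  joined <- dplyr::left_join(p, screening, by = "participant_id")
  unclipped <- joined$residual_est + joined$hdrs_screen
  inside <- unclipped >= 0 & unclipped <= 52
  expect_equal(joined$hdrs_est[inside], unclipped[inside])
  # clipping engages for an extreme synthetic screening score
  extreme <- screening
  extreme$hdrs_screen <- 52
  p2 <- predict(m, fm, screening = extreme)
  expect_true(all(p2$hdrs_est <= 52))
})

test_that("training artifacts ignore held-out rows (no leakage)", {
  sim <- simulate_visit_features(cohort_config(n_participants = 16,
                                               seed = 56))
  tg <- residualize(sim$visits)
  al <- dplyr::inner_join(
    sim$features, tg[, c("participant_id", "visit_index", "hdrs_residual")],
    by = c("participant_id", "visit_index"))
  fm <- al |> dplyr::select(-"hdrs_residual")
  train_ids <- unique(fm$participant_id)[1:12]
  tr <- fm[fm$participant_id %in% train_ids, ]
  attr(tr, "manifest") <- attr(fm, "manifest")
  y_tr <- al$hdrs_residual[fm$participant_id %in% train_ids]
  cfg <- model_config(seed = 5, n_folds = 4,
                      xgb_grid = list(nrounds = 50, max_depth = 2),
                      num_trees = 200)
  m1 <- fit_severity_model(tr, y_tr, cfg)
  # perturbing rows outside the training set must not change the fit
  fm2 <- fm
  out <- !fm2$participant_id %in% train_ids
  for (cc in setdiff(names(fm2), c("participant_id", "visit_index"))) {
    fm2[[cc]][out] <- fm2[[cc]][out] * 10 + 100
  }
  tr2 <- fm2[fm2$participant_id %in% train_ids, ]
  attr(tr2, "manifest") <- attr(fm, "manifest")
  m2 <- fit_severity_model(tr2, y_tr, cfg)
  expect_identical(m1$reducer$medians, m2$reducer$medians)
  expect_equal(predict(m1, tr)$residual_est, predict(m2, tr)$residual_est,
               tolerance = 1e-12)
})

test_that("strong planted couplings are recovered on held-out participants", {
  cc <- cohort_config(
    n_participants = 30, seed = 57,
    effect_sizes = list(phone_engagement = 3, mobility = -3, scr_rate = 3,
                        rmssd = -3))
  sim <- simulate_visit_features(cc)
  rep <- evaluate_cohort(sim$features, sim$visits, scenarios = "user_split",
                         modalities = "all", seed = 57, n_repeats = 2)
  s <- summarize_report(rep)
  expect_gte(s$pearson_r[s$model == "all"], 0.6)
})
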