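# Residualized HDRS-17 estimation: median imputation, linear + nonlinear
# dimensionality reduction to 25 transformed features, and an average
# ensemble of gradient-boosted trees and a random forest, tuned by 10-fold
# cross-validation.

#' Residualize visit scores against the screening visit
#'
#' Personalizes the regression target: each non-screening visit's HDRS-17
#' becomes its difference from that participant's screening score, absorbing
#' the heterogeneous baseline presentation.
#'
#' @param visits tibble with `participant_id`, `visit_index` (`"screen"`,
#'   `"v2"`, ...), `hdrs17`.
#' @return tibble of targets (one per non-screening visit):
#'   `participant_id`, `visit_index`, `hdrs17`, `hdrs_screen`,
#'   `hdrs_residual`.
#' @export
residualize <- function(visits) {
  screen <- visits |>
    filter(.data$visit_index == "screen") |>
    select("participant_id", hdrs_screen = "hdrs17")
  if (anyDuplicated(screen$participant_id)) {
    abort("each participant must have exactly one screening visit",
          class = "moodsense_data_error")
  }
  missing <- setdiff(unique(visits$participant_id), screen$participant_id)
  if (length(missing) > 0) {
    abort(paste0("participants without a screening visit: ",
                 paste(missing, collapse = ", ")),
          class = "moodsense_data_error")
  }
  visits |>
    filter(.data$visit_index != "screen") |>
    left_join(screen, by = "participant_id") |>
    mutate(hdrs_residual = .data$hdrs17 - .data$hdrs_screen) |>
    select(any_of(c("participant_id", "visit_index", "hdrs17",
                    "hdrs_screen", "hdrs_residual")))
}

#' Model configuration
#'
#' @param seed integer seed controlling every stochastic fit component.
#' @param n_linear,n_nonlinear output dimensions of the linear
#'   (variance-maximizing projection) and nonlinear (RBF kernel projection)
#'   reducer stages; 15 + 10 = 25 transformed features by default. Both are
#'   capped at what the training sample supports.
#' @param n_folds cross-validation folds for tuning (default 10; reduced
#'   with a warning when there are fewer rows).
#' @param grouped_cv group CV folds by participant (no participant in both
#'   fold sides); used for user-split runs.
#' @param xgb_grid named list of gradient-boosting candidate values
#'   (`nrounds`, `max_depth`); the combination minimizing CV MAE is kept.
#' @param num_trees random-forest size.
#' @return a `model_config` list.
#' @export
model_config <- function(seed = 1L, n_linear = 15, n_nonlinear = 10,
                         n_folds = 10, grouped_cv = TRUE,
                         xgb_grid = list(nrounds = c(75, 200),
                                         max_depth = c(2, 3)),
                         num_trees = 500) {
  structure(list(seed = as.integer(seed), n_linear = n_linear,
                 n_nonlinear = n_nonlinear, n_folds = n_folds,
                 grouped_cv = grouped_cv, xgb_grid = xgb_grid,
                 num_trees = num_trees),
            class = "model_config")
}

feature_columns <- function(matrix) {
  setdiff(names(matrix), c("participant_id", "visit_index", "visit_date"))
}

# Fit the reducer on training data only: median-impute, drop degenerate
# columns, scale, then linear PCA components + RBF kernel PCA components.
fit_reducer <- function(x, n_linear, n_nonlinear) {
  medians <- apply(x, 2, median, na.rm = TRUE)
  all_na <- !is.finite(medians)
  if (any(all_na)) {
    warn(paste0("dropping all-missing columns: ",
                paste(names(medians)[all_na], collapse = ", ")))
  }
  keep <- names(medians)[!all_na]
  x <- x[, keep, drop = FALSE]
  medians <- medians[keep]
  for (j in seq_along(keep)) {
    x[is.na(x[, j]), j] <- medians[j]
  }
  sds <- apply(x, 2, sd)
  keep2 <- sds > 0
  x2 <- x[, keep2, drop = FALSE]
  n <- nrow(x2); p <- ncol(x2)
  k1 <- max(1, min(n_linear, n - 2, p))
  k2 <- max(0, min(n_nonlinear, n - 2, p))
  pca <- prcomp(x2, center = TRUE, scale. = TRUE, rank. = k1)
  xs <- scale(x2, center = pca$center, scale = pca$scale)
  # deterministic RBF bandwidth: inverse median squared pairwise distance
  # over an evenly spaced row subsample (no RNG use here by design)
  idx <- unique(round(seq(1, n, length.out = min(n, 200))))
  d2 <- as.numeric(stats::dist(xs[idx, , drop = FALSE]))^2
  sigma <- 1 / max(median(d2), 1e-8)
  kp <- if (k2 > 0) {
    tryCatch(kernlab::kpca(xs, kernel = "rbfdot",
                           kpar = list(sigma = sigma), features = k2),
             error = function(e) NULL)
  }
  list(medians = medians, keep = keep, keep2 = keep2, pca = pca, kpca = kp,
       sigma = sigma, k1 = k1, k2 = k2)
}

apply_reducer <- function(red, x) {
  x <- x[, red$keep, drop = FALSE]
  for (j in seq_along(red$keep)) {
    x[is.na(x[, j]), j] <- red$medians[j]
  }
  x2 <- x[, red$keep2, drop = FALSE]
  xs <- scale(x2, center = red$pca$center, scale = red$pca$scale)
  z <- xs %*% red$pca$rotation
  if (!is.null(red$kpca)) {
    z <- cbind(z, predict(red$kpca, xs))
  }
  colnames(z) <- paste0("Z", seq_len(ncol(z)))
  z
}

make_folds <- function(n, groups, n_folds, grouped, seed) {
  with_seed(seed, {
    if (grouped) {
      g <- unique(groups)
      k <- min(n_folds, length(g))
      if (k < n_folds) {
        warn(sprintf("reducing folds to %d (only %d groups)", k, length(g)))
      }
      gf <- sample(rep_len(seq_len(k), length(g)))
      gf[match(groups, g)]
    } else {
      k <- min(n_folds, n)
      if (k < n_folds) warn(sprintf("reducing folds to %d rows", k))
      sample(rep_len(seq_len(k), n))
    }
  })
}

fit_xgb <- function(z, y, nrounds, max_depth, seed) {
  xgboost::xgboost(x = z, y = y, objective = "reg:squarederror",
                   nrounds = nrounds, max_depth = max_depth,
                   learning_rate = 0.1, nthreads = 1, seed = seed)
}

#' Fit the residualized-severity ensemble
#'
#' Pipeline fitted on training rows only (imputation medians, reducer and
#' regressors never see test rows): the reducer maps the feature matrix to
#' 25 transformed features, a gradient-boosted tree model is tuned by
#' cross-validated MAE over `config$xgb_grid`, a random forest is fitted
#' alongside, and predictions are the arithmetic mean of the two (0.5/0.5
#' average ensemble). Deterministic given `config$seed`.
#'
#' @param matrix a `moodsense_features` tibble (rows aligned with
#'   `targets`).
#' @param targets numeric vector of residualized HDRS-17 targets.
#' @param config a [model_config()].
#' @return a `moodsense_model` bundle: reducer, both regressors, training
#'   medians, CV table and the training manifest hash.
#' @export
fit_severity_model <- function(matrix, targets, config = model_config()) {
  stopifnot(length(targets) == nrow(matrix))
  manifest <- attr(matrix, "manifest")
  cols <- feature_columns(matrix)
  x <- as.matrix(as.data.frame(matrix[, cols]))
  storage.mode(x) <- "double"
  groups <- if ("participant_id" %in% names(matrix)) {
    matrix$participant_id
  } else as.character(seq_len(nrow(x)))

  folds <- make_folds(nrow(x), groups, config$n_folds, config$grouped_cv,
                      derive_seed(config$seed, "folds"))
  grid <- expand.grid(nrounds = config$xgb_grid$nrounds,
                      max_depth = config$xgb_grid$max_depth)
  cv_mae <- array(NA_real_, dim = c(nrow(grid), max(folds)))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    if (sum(tr) < 3 || sum(!tr) == 0) next
    red_f <- fit_reducer(x[tr, , drop = FALSE], config$n_linear,
                         config$n_nonlinear)
    z_tr <- apply_reducer(red_f, x[tr, , drop = FALSE])
    z_te <- apply_reducer(red_f, x[!tr, , drop = FALSE])
    for (gidx in seq_len(nrow(grid))) {
      m <- fit_xgb(z_tr, targets[tr], grid$nrounds[gidx],
                   grid$max_depth[gidx],
                   derive_seed(config$seed, "cv", f, gidx))
      pred <- predict(m, z_te)
      cv_mae[gidx, f] <- mean(abs(pred - targets[!tr]))
    }
  }
  grid$mae <- rowMeans(cv_mae, na.rm = TRUE)
  best <- which.min(grid$mae)

  red <- fit_reducer(x, config$n_linear, config$n_nonlinear)
  z <- apply_reducer(red, x)
  xgb <- fit_xgb(z, targets, grid$nrounds[best], grid$max_depth[best],
                 derive_seed(config$seed, "xgb"))
  rf <- with_seed(derive_seed(config$seed, "rf"), {
    ranger::ranger(
      x = as.data.frame(z), y = targets, num.trees = config$num_trees,
      seed = derive_seed(config$seed, "rf"), num.threads = 1)
  })

  structure(
    list(reducer = red, xgb = xgb, rf = rf, config = config,
         columns = cols, cv = as_tibble(grid),
         best_params = grid[best, c("nrounds", "max_depth")],
         manifest_hash = if (!is.null(manifest)) manifest_hash(manifest)),
    class = "moodsense_model")
}

#' Predict residualized and absolute HDRS-17
#'
#' Columns are aligned by name (order-free); prediction refuses a matrix
#' whose manifest hash differs from the training manifest (schema safety).
#' The absolute estimate adds each participant's screening score to the
#' residual estimate and clips to the 0-52 scale.
#'
#' @param object a `moodsense_model`.
#' @param matrix feature tibble to predict on.
#' @param screening optional tibble (`participant_id`, `hdrs_screen`) to
#'   reconstruct absolute scores.
#' @param ... unused.
#' @return tibble with row keys, `residual_est` and (when screening scores
#'   are given) `hdrs_est`.
#' @export
predict.moodsense_model <- function(object, matrix, screening = NULL, ...) {
  manifest <- attr(matrix, "manifest")
  if (!is.null(object$manifest_hash) && !is.null(manifest) &&
      !identical(manifest_hash(manifest), object$manifest_hash)) {
    abort("feature manifest does not match the training manifest",
          class = "moodsense_schema_error")
  }
  missing_cols <- setdiff(object$columns, names(matrix))
  if (length(missing_cols) > 0) {
    abort(paste0("prediction matrix lacks training columns: ",
                 paste(head(missing_cols, 5), collapse = ", ")),
          class = "moodsense_schema_error")
  }
  x <- as.matrix(as.data.frame(matrix[, object$columns]))
  storage.mode(x) <- "double"
  z <- apply_reducer(object$reducer, x)
  pred <- (predict(object$xgb, z) +
             predict(object$rf, as.data.frame(z),
                     num.threads = 1)$predictions) / 2
  out <- tibble(residual_est = as.numeric(pred))
  if ("participant_id" %in% names(matrix)) {
    out <- bind_cols(matrix |>
                       select(any_of(c("participant_id", "visit_index"))),
                     out)
  }
  if (!is.null(screening)) {
    out <- out |>
      left_join(screening, by = "participant_id") |>
      mutate(hdrs_est = clip(.data$residual_est + .data$hdrs_screen, 0,
                             HDRS_MAX)) |>
      select(-"hdrs_screen")
  }
  out
}

#' @export
print.moodsense_model <- function(x, ...) {
  cat(sprintf(
    "<moodsense_model: %d features -> %d transformed; xgb(nrounds=%d, depth=%d) + rf(%d trees); CV MAE %.3f>\n",
    length(x$columns), x$reducer$k1 + x$reducer$k2,
    x$best_params$nrounds, x$best_params$max_depth, x$config$num_trees,
    min(x$cv$mae)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.moodsense_model <- function(x, ...) {
  x$cv |>
    mutate(component = "xgb_cv") |>
    select("component", "nrounds", "max_depth", "mae")
}

#' @exportS3Method generics::glance
glance.moodsense_model <- function(x, ...) {
  tibble(n_features = length(x$columns),
         n_transformed = x$reducer$k1 + x$reducer$k2,
         cv_mae = min(x$cv$mae),
         nrounds = x$best_params$nrounds,
         max_depth = x$best_params$max_depth,
         num_trees = x$config$num_trees)
}
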