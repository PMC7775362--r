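# All-relevant feature selection: shadow-feature wrapper around random
# forest importance with binomial hit tests (Bonferroni-corrected), in the
# spirit of the original Boruta algorithm. Decisions are final once made:
# confirmed features stay confirmed, rejected features leave the model.

#' Boruta all-relevant feature selection
#'
#' Each iteration appends a shuffled shadow copy of every still-active
#' column, fits a random forest, and scores a "hit" for real features whose
#' importance exceeds the maximum shadow importance. Two-sided binomial
#' tests (p = 0.5) on the accumulated hit counts, Bonferroni-corrected
#' across the currently undecided features, promote features significantly
#' above chance to `confirmed` and drop features significantly below to
#' `rejected`; survivors at `max_iter` stay `tentative` (no rough-fix pass).
#' Deterministic given `seed`.
#'
#' @param matrix feature tibble or numeric matrix (complete/imputed).
#' @param targets numeric response vector.
#' @param max_iter maximum number of shadow iterations (default 100).
#' @param alpha two-sided significance level before correction (default
#'   0.05).
#' @param seed integer seed.
#' @param num_trees random-forest size per iteration (default 500).
#' @param importance ranger importance measure: `"permutation"` (scaled
#'   permutation importance, the default: it is far better calibrated for
#'   the shadow duel than impurity at these sample sizes) or `"impurity"`
#'   (mean decrease in impurity).
#' @param subsample_frac fraction of rows drawn (without replacement) per
#'   iteration; resampling decorrelates chance in-sample associations
#'   between iterations.
#' @param min_iter first iteration at which decisions are attempted
#'   (default 5).
#' @return a `moodsense_boruta` object: tibble of per-feature `status`,
#'   `hits`, `n_iter`, `median_importance`, plus the importance history in
#'   an attribute.
#' @export
boruta <- function(matrix, targets, max_iter = 100, alpha = 0.05,
                   seed = 1L, num_trees = 500,
                   importance = c("permutation", "impurity"),
                   subsample_frac = 0.85, min_iter = 5) {
  importance <- match.arg(importance)
  x <- as.data.frame(matrix[, feature_columns(as_tibble(matrix))])
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  if (nrow(x) < 10) {
    abort("boruta needs at least 10 rows", class = "moodsense_data_error")
  }
  if (anyNA(x)) {
    abort("boruta needs a complete (imputed) matrix",
          class = "moodsense_data_error")
  }
  feats <- names(x)
  if (sd(targets) == 0) {
    warn("constant target: all features rejected")
    return(new_boruta(tibble(feature = feats, status = "rejected",
                             hits = 0L, n_iter = 0L,
                             median_importance = NA_real_),
                      list()))
  }
  status <- setNames(rep("undecided", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  n_iter <- setNames(rep(0L, length(feats)), feats)
  history <- list()

  for (it in seq_len(max_iter)) {
    active <- feats[status != "rejected"]
    if (!any(status == "undecided")) break
    # each iteration works on a row subsample (without replacement):
    # chance in-sample correlations of noise features then vary between
    # iterations (they are resample-dependent), while genuinely relevant
    # features stay important in every resample. Without this the duel
    # outcomes are nearly deterministic on a fixed sample and the binomial
    # hit model overstates the evidence for lucky noise columns.
    rows <- with_seed(derive_seed(seed, "boot", it),
                      sample.int(nrow(x),
                                 ceiling(subsample_frac * nrow(x))))
    xa <- x[rows, active, drop = FALSE]
    yb <- targets[rows]
    # shadows are shuffled copies of the active columns, topped up to at
    # least 10 so the max-shadow reference never collapses as features are
    # rejected (a lone survivor would otherwise win half its duels by
    # symmetry and drift to confirmation)
    shadow <- with_seed(derive_seed(seed, "shadow", it), {
      src <- xa
      k <- 0
      while (ncol(src) < 10) {
        k <- k + 1
        src <- cbind(src, xa[, (k - 1) %% ncol(xa) + 1, drop = FALSE])
      }
      as.data.frame(lapply(src, sample))
    })
    names(shadow) <- paste0(".shadow_", seq_len(ncol(shadow)))
    dat <- cbind(xa, shadow)
    rf <- ranger::ranger(
      x = dat, y = yb, num.trees = num_trees,
      importance = importance,
      scale.permutation.importance = importance == "permutation",
      num.threads = 1,
      seed = derive_seed(seed, "rf", it))
    imp <- rf$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow_")])
    real_imp <- imp[active]
    hit <- real_imp > shadow_max
    hits[active] <- hits[active] + as.integer(hit)
    n_iter[active] <- n_iter[active] + 1L
    history[[it]] <- tibble(iteration = it, feature = active,
                            importance = unname(real_imp),
                            shadow_max = shadow_max)

    if (it >= min_iter) {
      und <- feats[status == "undecided"]
      m <- length(feats) # Bonferroni across all attributes
      for (f in und) {
        p_up <- pbinom(hits[f] - 1, n_iter[f], 0.5, lower.tail = FALSE)
        p_down <- pbinom(hits[f], n_iter[f], 0.5)
        if (p_up * m < alpha) status[f] <- "confirmed"
        else if (p_down * m < alpha) status[f] <- "rejected"
      }
    }
  }
  status[status == "undecided"] <- "tentative"
  hist_tbl <- purrr::list_rbind(history)
  med_imp <- hist_tbl |>
    group_by(.data$feature) |>
    summarise(median_importance = median(.data$importance),
              .groups = "drop")
  res <- tibble(feature = feats, status = unname(status[feats]),
                hits = unname(hits[feats]),
                n_iter = unname(n_iter[feats])) |>
    left_join(med_imp, by = "feature")
  new_boruta(res, hist_tbl)
}

new_boruta <- function(res, history) {
  structure(res, history = history,
            class = c("moodsense_boruta", class(res)))
}

#' @export
print.moodsense_boruta <- function(x, ...) {
  tab <- table(factor(x$status,
                      levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf("<boruta: %d confirmed, %d tentative, %d rejected (of %d)>\n",
              tab["confirmed"], tab["tentative"], tab["rejected"], nrow(x)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.moodsense_boruta <- function(x, ...) {
  as_tibble(x) |> arrange(desc(.data$median_importance))
}

#' Modality breakdown and ranked table of confirmed features
#'
#' Ranks confirmed features by median importance and reports the integer
#' percentage of confirmed features per modality tag.
#'
#' @param result a `moodsense_boruta`.
#' @param manifest manifest tibble (`feature`, `modality`, `window`).
#' @return list with `ranking` (rank, feature, window, modality,
#'   median_importance) and `modality_pct` (modality, n, percent).
#' @export
summarize_selection <- function(result, manifest) {
  conf <- as_tibble(result) |>
    filter(.data$status == "confirmed") |>
    left_join(manifest, by = "feature") |>
    arrange(desc(.data$median_importance)) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "feature", "window", "modality", "median_importance")
  pct <- conf |>
    count(.data$modality, name = "n") |>
    mutate(percent = round(100 * .data$n / sum(.data$n)))
  list(ranking = conf, modality_pct = pct)
}
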