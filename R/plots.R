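# ggplot2 displays for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.moodsense_report <- function(object, metric = "mae", ...) {
  s <- summarize_report(object)
  sd_col <- paste0(metric, "_sd")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$model, y = .data[[metric]],
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[metric]] - .data[[sd_col]],
                   ymax = .data[[metric]] + .data[[sd_col]]),
      position = ggplot2::position_dodge(0.9), width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = toupper(metric),
                  title = "Hold-out error by model and scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.moodsense_boruta <- function(object, top_n = 25, ...) {
  hist <- attr(object, "history")
  keep <- as_tibble(object) |>
    arrange(desc(.data$median_importance)) |>
    slice_head(n = top_n)
  ggplot2::ggplot(
    hist |> filter(.data$feature %in% keep$feature) |>
      left_join(keep |> select("feature", "status"), by = "feature"),
    ggplot2::aes(x = stats::reorder(.data$feature, .data$importance,
                                    FUN = median),
                 y = .data$importance, fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Random-forest importance",
                  title = "Feature importance vs shadow maximum") +
    ggplot2::theme_minimal()
}

#' Plot latent severity trajectories with visit scores
#'
#' @param cohort a [generate_cohort()] result (or the list returned by
#'   [simulate_trajectories()]).
#' @param participants optional subset of participant ids.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(cohort, participants = NULL) {
  traj <- cohort$trajectories
  visits <- cohort$visits
  if (!is.null(participants)) {
    traj <- traj |> filter(.data$participant_id %in% participants)
    visits <- visits |> filter(.data$participant_id %in% participants)
  }
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$day, y = .data$severity)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = visits,
                        ggplot2::aes(x = .data$day_offset, y = .data$hdrs17),
                        colour = "firebrick", size = 1.6) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "Study day", y = "HDRS-17",
                  title = "Latent severity and clinician visit scores") +
    ggplot2::theme_minimal()
}
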