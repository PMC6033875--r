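#' Plot condition-level sensitivity by modality and expectation
#'
#' Group means with standard-error bars for d' (or mean RT) in the
#' audiovisual vs best-unisensory conditions, split by expectation — the
#' standard display of the modality x expectation interplay.
#'
#' @param scores A [score_conditions()] table.
#' @param best_map Optional [select_best_modalities()] output.
#' @param measure `"dprime"` or `"rt"`.
#' @return A ggplot object.
#' @export
plot_condition_scores <- function(scores, best_map = NULL,
                                  measure = c("dprime", "rt")) {
  measure <- match.arg(measure)
  cells <- condition_cells(scores, best_map, measure)
  summ <- cells |>
    dplyr::group_by(.data$modality, .data$te_state) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$modality, y = .data$mean,
                                     fill = .data$te_state)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7, name = NULL) +
    ggplot2::labs(x = NULL,
                  y = if (measure == "dprime") "d'" else "mean RT (ms)") +
    ggplot2::theme_minimal()
}

#' Plot multisensory facilitation against unisensory imbalance
#'
#' Scatter of per-cell MSF against the unisensory performance difference
#' with a least-squares trend line; points above zero indicate facilitation
#' (AV better than the best unisensory condition), and a negative trend
#' shows facilitation shrinking as one modality dominates.
#'
#' @param msf A [build_msf_records()] table.
#' @param measure `"dprime"` or `"rt"`.
#' @return A ggplot object.
#' @export
plot_msf <- function(msf, measure = c("dprime", "rt")) {
  measure <- match.arg(measure)
  xcol <- if (measure == "dprime") "unidiff_d" else "unidiff_rt"
  ycol <- if (measure == "dprime") "msf_d" else "msf_rt"
  ggplot2::ggplot(msf, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(shape = 4, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linetype = "dotted") +
    ggplot2::labs(
      x = if (measure == "dprime") "unisensory d' difference (max - min)"
          else "unisensory RT difference (ms)",
      y = if (measure == "dprime") "MSF (d' AV - best[A,V])"
          else "MSF (RT best[A,V] - AV, ms)") +
    ggplot2::theme_minimal()
}

#' Plot the history-cell means
#'
#' Mean d' (with SE bars) by modality and target-position match, averaged
#' over the modality-match factor — the display of the phasic
#' expectation-matching effect.
#'
#' @param cells Output of [history_dprime_cells()].
#' @return A ggplot object.
#' @export
plot_history_cells <- function(cells) {
  summ <- cells |>
    dplyr::group_by(.data$subject_id, .data$modality, .data$tp_match) |>
    dplyr::summarise(dprime = mean(.data$dprime), .groups = "drop") |>
    dplyr::group_by(.data$modality, .data$tp_match) |>
    dplyr::summarise(mean = mean(.data$dprime),
                     se = stats::sd(.data$dprime) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$modality, y = .data$mean,
                                     fill = .data$tp_match)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7,
                             name = "n-1 TP") +
    ggplot2::labs(x = NULL, y = "d'") +
    ggplot2::theme_minimal()
}

#' @describeIn rank_models Cross-validated RMSE by rank, highlighting the
#'   named (reported) models.
#' @param object A `temsf_modelsel` object.
#' @export
autoplot.temsf_modelsel <- function(object, ...) {
  named <- object$named
  ggplot2::ggplot(object$models,
                  ggplot2::aes(x = .data$rank, y = .data$rmse)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = named, colour = "red") +
    ggplot2::geom_text(data = named,
                       ggplot2::aes(label = .data$model),
                       vjust = -0.8, size = 3, colour = "red") +
    ggplot2::labs(x = "model rank (1 = best)",
                  y = "leave-one-out RMSE",
                  title = paste("all-subsets model comparison,",
                                object$measure)) +
    ggplot2::theme_minimal()
}
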