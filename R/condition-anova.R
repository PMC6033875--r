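#' Condition-level ANOVA cell table
#'
#' Reduces a [score_conditions()] table to the 2 (modality: best\[A,V\] vs
#' AV) x 2 (expectation) within-subject cells used by the main ANOVA, with
#' the best unisensory modality chosen per subject and per measure by the
#' two-step max-criterion rule.
#'
#' @param scores A [score_conditions()] table.
#' @param best_map Output of [select_best_modalities()]; computed if `NULL`.
#' @param measure `"dprime"` or `"rt"`.
#' @return A tibble with one row per subject x modality (`"bestAV"`,
#'   `"AV"`) x expectation cell, column `value` holding the dv.
#' @export
condition_cells <- function(scores, best_map = NULL,
                            measure = c("dprime", "rt")) {
  measure <- match.arg(measure)
  # subjects missing any modality x expectation cell (e.g. a cell whose few
  # trials had a single target direction) cannot enter the balanced design
  complete <- scores |>
    dplyr::filter(.data$modality %in% c("A", "V", "AV"),
                  .data$te_state %in% c("expected", "unexpected")) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::n_distinct(paste(.data$modality,
                                          .data$te_state)) == 6L) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(scores$subject_id), unique(complete$subject_id))
  if (length(dropped) > 0)
    message("condition ANOVA drops ", length(dropped),
            " subject(s) with incomplete cells: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (is.null(best_map)) best_map <- select_best_modalities(complete)
  col <- if (measure == "dprime") "dprime" else "mean_rt_ms"
  best_col <- if (measure == "dprime") "best_modality_d" else "best_modality_rt"
  complete |>
    dplyr::inner_join(best_map[, c("subject_id", best_col)],
                      by = "subject_id") |>
    dplyr::filter(.data$modality == "AV" |
                    .data$modality == .data[[best_col]]) |>
    dplyr::transmute(
      .data$subject_id, .data$spatial_uncertainty, .data$target_uncertainty,
      modality = dplyr::if_else(.data$modality == "AV", "AV", "bestAV"),
      te_state = .data$te_state,
      value = .data[[col]]
    )
}

#' Main mixed ANOVA: modality x expectation with uncertainty factors
#'
#' Fits the 2 (modality: best\[A,V\], AV) x 2 (expectation) within x
#' 2 (spatial uncertainty) x 2 (target uncertainty) between design on d'
#' or mean RT.
#'
#' @param scores A [score_conditions()] table.
#' @param best_map Optional [select_best_modalities()] output.
#' @param measure `"dprime"` or `"rt"`.
#' @param between Between-subject factors (set to `character()` when all
#'   subjects share one experiment).
#' @param allow_unbalanced Passed to [mixed_anova()].
#' @return A `temsf_anova` object.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(design_config(n_subjects_per_experiment = 4),
#'                           master_seed = 1)
#' trials <- apply_filters(annotate_previous_trial(cohort$trials))
#' scores <- score_conditions(trials)
#' tidy(condition_anova(scores, measure = "dprime"))
#' }
#' @export
condition_anova <- function(scores, best_map = NULL,
                            measure = c("dprime", "rt"),
                            between = c("spatial_uncertainty",
                                        "target_uncertainty"),
                            allow_unbalanced = FALSE) {
  cells <- condition_cells(scores, best_map, measure)
  mixed_anova(cells, dv = "value",
              within = c("modality", "te_state"),
              between = between,
              subject = "subject_id",
              allow_unbalanced = allow_unbalanced)
}
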