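#' Classify trials by their n-1 relation
#'
#' Adds the history factors used in the sequential analysis:
#' `modality_match` (previous trial's target modality equals the current
#' one; AV at n-1 only matches a current AV trial) and `tp_match` (previous
#' target position, early/late, equals the current one — within a block
#' this is equivalent to a match in expectation status). Trials whose n-1
#' fields are missing (first of a block) or whose previous answer was not
#' correct are marked `history_included = FALSE`, with the reason recorded
#' in `history_excluded_reason` — conditioning on a correct n-1 answer
#' avoids post-error influences.
#'
#' @param trials Trial tibble already passed through
#'   [annotate_previous_trial()].
#' @return The tibble with `modality_match`, `tp_match`,
#'   `history_included`, `history_excluded_reason` columns.
#' @export
classify_history <- function(trials) {
  need <- c("prev_target_modality", "prev_target_position", "prev_correct")
  if (!all(need %in% names(trials)))
    stop("run annotate_previous_trial() first (missing n-1 columns)",
         call. = FALSE)
  trials |>
    dplyr::mutate(
      history_excluded_reason = dplyr::case_when(
        is.na(.data$prev_target_modality) ~ "first_in_block",
        is.na(.data$prev_correct) | !.data$prev_correct ~ "prev_not_correct",
        TRUE ~ NA_character_
      ),
      history_included = is.na(.data$history_excluded_reason),
      modality_match = dplyr::if_else(
        .data$history_included,
        dplyr::if_else(.data$prev_target_modality == .data$target_modality,
                       "match", "mismatch"),
        NA_character_),
      tp_match = dplyr::if_else(
        .data$history_included,
        dplyr::if_else(.data$prev_target_position == .data$target_position,
                       "match", "mismatch"),
        NA_character_)
    )
}

#' n-1 conditioned d' cells
#'
#' Restricts current trials to the audiovisual condition and each subject's
#' best unisensory modality (d' measure), then computes 2AFC d' per
#' subject x modality (AV vs best\[A,V\]) x modality-match x TP-match cell,
#' using only trials whose n-1 answer was correct. The resulting 2x2x2
#' within-subject structure (with the experiments' two uncertainty factors
#' between subjects) feeds [mixed_anova()].
#'
#' @param trials Filtered trial tibble that has been annotated and
#'   classified (see [annotate_previous_trial()], [classify_history()];
#'   classification happens automatically if absent).
#' @param best_map Tibble with `subject_id` and `best_modality_d` (from
#'   [select_best_modalities()]).
#' @param correction Extreme-rate correction for [dprime_2afc()].
#' @param min_trials Cells with fewer trials are flagged `low_n`.
#' @param complete_only Drop subjects missing any of the eight cells (with
#'   a message); required before the history ANOVA.
#' @return A tibble of history cells: `subject_id`, `modality`
#'   (`"AV"`/`"bestAV"`), `modality_match`, `tp_match`, `dprime`,
#'   `n_trials`, uncertainty labels.
#' @export
history_dprime_cells <- function(trials, best_map,
                                 correction = "loglinear",
                                 min_trials = 4L,
                                 complete_only = TRUE) {
  if (!"modality_match" %in% names(trials))
    trials <- classify_history(trials)
  if (!all(c("subject_id", "best_modality_d") %in% names(best_map)))
    stop("best_map needs subject_id and best_modality_d", call. = FALSE)
  dat <- trials |>
    dplyr::filter(.data$history_included) |>
    dplyr::inner_join(best_map[, c("subject_id", "best_modality_d")],
                      by = "subject_id") |>
    dplyr::filter(.data$target_modality == "AV" |
                    .data$target_modality == .data$best_modality_d) |>
    dplyr::mutate(modality = dplyr::if_else(.data$target_modality == "AV",
                                            "AV", "bestAV"))
  cells <- dat |>
    dplyr::group_by(.data$subject_id, .data$spatial_uncertainty,
                    .data$target_uncertainty, .data$modality,
                    .data$modality_match, .data$tp_match) |>
    dplyr::summarise(
      n_higher_targets = sum(.data$target_direction == "higher"),
      n_lower_targets = sum(.data$target_direction == "lower"),
      n_hits = sum(.data$response == "higher" &
                     .data$target_direction == "higher"),
      n_fa = sum(.data$response == "higher" &
                   .data$target_direction == "lower"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_higher_targets > 0, .data$n_lower_targets > 0) |>
    dplyr::mutate(
      dprime = dprime_2afc(.data$n_hits, .data$n_higher_targets,
                           .data$n_fa, .data$n_lower_targets,
                           correction = correction),
      n_trials = .data$n_higher_targets + .data$n_lower_targets,
      low_n = .data$n_trials < min_trials
    )
  if (complete_only) {
    full <- cells |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::filter(dplyr::n() == 8L) |>
      dplyr::ungroup()
    dropped <- setdiff(unique(cells$subject_id), unique(full$subject_id))
    if (length(dropped) > 0)
      message("history analysis drops ", length(dropped),
              " subject(s) with empty cells: ",
              paste(utils::head(dropped, 5), collapse = ", "))
    cells <- full
  }
  cells
}

#' Mixed ANOVA over the n-1 history cells
#'
#' Convenience wrapper: fits the 2 (modality: AV vs best\[A,V\]) x
#' 2 (modality match) x 2 (TP match) within x 2 (spatial uncertainty) x
#' 2 (target uncertainty) between design on the history d' cells.
#'
#' @param cells Output of [history_dprime_cells()] (complete subjects).
#' @param between Between-subject factors to include (defaults to both
#'   uncertainty factors; set to `character()` for single-experiment data).
#' @param allow_unbalanced Passed to [mixed_anova()].
#' @return A `temsf_anova` object.
#' @export
history_anova <- function(cells,
                          between = c("spatial_uncertainty",
                                      "target_uncertainty"),
                          allow_unbalanced = FALSE) {
  mixed_anova(cells, dv = "dprime",
              within = c("modality", "modality_match", "tp_match"),
              between = between,
              subject = "subject_id",
              allow_unbalanced = allow_unbalanced)
}
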