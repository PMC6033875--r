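#' 2AFC sensitivity index d'
#'
#' Computes the two-alternative forced-choice sensitivity
#' \deqn{d' = (\Phi^{-1}(H) - \Phi^{-1}(F)) / \sqrt{2}}
#' where H is the rate of "higher" responses to higher targets and F the
#' rate of "higher" responses to lower targets. Extreme rates are handled by
#' the chosen correction before the quantile transform:
#' `"loglinear"` (default) adds 0.5 to each count and 1 to each denominator;
#' `"clamp"` replaces rates of 0 and 1 by `1/(2N)` and `1 - 1/(2N)`;
#' `"none"` applies no correction (infinite d' possible).
#'
#' @param n_hits Number of "higher" responses among higher targets.
#' @param n_higher Number of higher targets.
#' @param n_fa Number of "higher" responses among lower targets.
#' @param n_lower Number of lower targets.
#' @param correction `"loglinear"`, `"clamp"` or `"none"`.
#' @return d' (vectorised over the count arguments).
#' @examples
#' dprime_2afc(16, 20, 4, 20, correction = "none")   # ~1.190
#' dprime_2afc(10, 10, 0, 10)                        # loglinear-corrected
#' @export
dprime_2afc <- function(n_hits, n_higher, n_fa, n_lower,
                        correction = c("loglinear", "clamp", "none")) {
  correction <- match.arg(correction)
  if (any(n_higher <= 0) || any(n_lower <= 0))
    stop("n_higher and n_lower must be positive", call. = FALSE)
  if (any(n_hits < 0) || any(n_fa < 0) || any(n_hits > n_higher) ||
      any(n_fa > n_lower))
    stop("counts must satisfy 0 <= hits <= n_higher, 0 <= fa <= n_lower",
         call. = FALSE)
  H <- switch(correction,
    loglinear = (n_hits + 0.5) / (n_higher + 1),
    clamp = pmin(pmax(n_hits / n_higher, 1 / (2 * n_higher)),
                 1 - 1 / (2 * n_higher)),
    none = n_hits / n_higher)
  F_ <- switch(correction,
    loglinear = (n_fa + 0.5) / (n_lower + 1),
    clamp = pmin(pmax(n_fa / n_lower, 1 / (2 * n_lower)),
                 1 - 1 / (2 * n_lower)),
    none = n_fa / n_lower)
  (stats::qnorm(H) - stats::qnorm(F_)) / sqrt(2)
}

# Temporal-expectation state of a trial: a target is expected when its
# position is the probable one for its block type.
te_state_of <- function(block_type, target_position) {
  ifelse((block_type == "expect_early" & target_position == "early") |
           (block_type == "expect_late" & target_position == "late"),
         "expected", "unexpected")
}

#' Score subject x modality x expectation cells
#'
#' Aggregates a filtered trial table into per-cell performance: hit and
#' false-alarm counts and rates, 2AFC d' (via [dprime_2afc()]) and mean RT.
#' The expectation state is derived from the block type: early targets in
#' expect-early blocks (and late targets in expect-late blocks) are
#' "expected"; with the default early-targets-only filter only early targets
#' contribute.
#'
#' @param trials Filtered trial tibble (see [apply_filters()]).
#' @param correction Extreme-rate correction for [dprime_2afc()].
#' @param min_trials Cells with fewer analysed trials are flagged
#'   (`low_n = TRUE`), not dropped.
#' @return A tibble with one row per non-empty subject x modality x
#'   expectation cell.
#' @export
score_conditions <- function(trials, correction = "loglinear",
                             min_trials = 4L) {
  trials |>
    dplyr::mutate(te_state = te_state_of(.data$block_type,
                                         .data$target_position)) |>
    dplyr::group_by(.data$subject_id, .data$experiment_id,
                    .data$spatial_uncertainty, .data$target_uncertainty,
                    .data$target_modality, .data$te_state) |>
    dplyr::summarise(
      n_higher_targets = sum(.data$target_direction == "higher"),
      n_lower_targets = sum(.data$target_direction == "lower"),
      n_hits = sum(.data$response == "higher" &
                     .data$target_direction == "higher"),
      n_fa = sum(.data$response == "higher" &
                   .data$target_direction == "lower"),
      mean_rt_ms = mean(.data$rt_ms),
      .groups = "drop"
    ) |>
    # a d' needs both target types; single-direction cells are unusable
    dplyr::filter(.data$n_higher_targets > 0, .data$n_lower_targets > 0) |>
    dplyr::mutate(
      hit_rate = (.data$n_hits + 0.5) / (.data$n_higher_targets + 1),
      fa_rate = (.data$n_fa + 0.5) / (.data$n_lower_targets + 1),
      dprime = dprime_2afc(.data$n_hits, .data$n_higher_targets,
                           .data$n_fa, .data$n_lower_targets,
                           correction = correction),
      n_trials = .data$n_higher_targets + .data$n_lower_targets,
      low_n = .data$n_trials < min_trials
    ) |>
    dplyr::rename(modality = "target_modality")
}

#' Best unisensory modality for one subject
#'
#' Two-step max-criterion selection between the auditory and visual
#' conditions: step 1 picks the modality that is better (higher d', or lower
#' RT) in *both* expectation cells; when dominance is split, step 2 picks
#' the better unweighted mean of the two cells. An exact tie after step 2 is
#' broken deterministically (more analysed trials, then A) and flagged.
#'
#' @param scores [score_conditions()] rows for a single subject (must
#'   contain A and V in both expectation states).
#' @param measure `"dprime"` (maximise) or `"rt"` (minimise mean RT).
#' @return A one-row tibble: `best_modality`, `resolved_by`
#'   (`"dominance"`/`"average"`), `tie` flag.
#' @examples
#' sc <- tibble::tibble(
#'   subject_id = "s1",
#'   modality = c("A", "A", "V", "V"),
#'   te_state = c("expected", "unexpected", "expected", "unexpected"),
#'   dprime = c(1.5, 0.9, 1.2, 1.1), mean_rt_ms = 1500, n_trials = 40)
#' select_best_unisensory(sc, "dprime")   # A via average (1.20 vs 1.15)
#' @export
select_best_unisensory <- function(scores, measure = c("dprime", "rt")) {
  measure <- match.arg(measure)
  col <- if (measure == "dprime") "dprime" else "mean_rt_ms"
  better <- if (measure == "dprime") `>` else `<`
  uni <- scores[scores$modality %in% c("A", "V"), ]
  if (nrow(uni) != 4 || length(unique(uni$subject_id)) != 1)
    stop("need exactly the four A/V x expected/unexpected cells of one subject",
         call. = FALSE)
  g <- function(mod, te) uni[[col]][uni$modality == mod & uni$te_state == te]
  a <- c(g("A", "expected"), g("A", "unexpected"))
  v <- c(g("V", "expected"), g("V", "unexpected"))
  if (all(better(a, v)))
    return(tibble::tibble(best_modality = "A", resolved_by = "dominance",
                          tie = FALSE))
  if (all(better(v, a)))
    return(tibble::tibble(best_modality = "V", resolved_by = "dominance",
                          tie = FALSE))
  ma <- mean(a); mv <- mean(v)
  if (ma != mv) {
    best <- if (better(ma, mv)) "A" else "V"
    return(tibble::tibble(best_modality = best, resolved_by = "average",
                          tie = FALSE))
  }
  # exact tie: larger analysed-trial count wins, then A
  na <- sum(uni$n_trials[uni$modality == "A"])
  nv <- sum(uni$n_trials[uni$modality == "V"])
  best <- if (nv > na) "V" else "A"
  tibble::tibble(best_modality = best, resolved_by = "average", tie = TRUE)
}

#' Modality-preference label
#'
#' `"auditory"` when the best unisensory modality is A for both performance
#' measures, `"visual"` when V for both, otherwise `"mixed"`.
#'
#' @param best_d,best_rt Best modality by d' and by RT (`"A"`/`"V"`).
#' @return Character label (vectorised).
#' @export
preference_label <- function(best_d, best_rt) {
  dplyr::case_when(
    best_d == "A" & best_rt == "A" ~ "auditory",
    best_d == "V" & best_rt == "V" ~ "visual",
    TRUE ~ "mixed"
  )
}

#' Best-modality selections for every subject
#'
#' Runs [select_best_unisensory()] per subject for both measures and labels
#' the preference.
#'
#' @param scores A [score_conditions()] table.
#' @return One row per subject: `best_modality_d`, `best_modality_rt`,
#'   `preference_label`, resolution paths and tie flags.
#' @export
select_best_modalities <- function(scores) {
  scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      df$subject_id <- key$subject_id
      d <- select_best_unisensory(df, "dprime")
      r <- select_best_unisensory(df, "rt")
      tibble::tibble(
        best_modality_d = d$best_modality, resolved_by_d = d$resolved_by,
        tie_d = d$tie,
        best_modality_rt = r$best_modality, resolved_by_rt = r$resolved_by,
        tie_rt = r$tie
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(preference_label = preference_label(.data$best_modality_d,
                                                      .data$best_modality_rt))
}

#' Multisensory-facilitation records per subject x expectation cell
#'
#' For each subject and expectation state, computes the max-criterion
#' facilitation outcomes with the sign convention that positive always means
#' facilitation: `msf_d = d'(AV) - d'(best[A,V])` and
#' `msf_rt = RT(best[A,V]) - RT(AV)`, where best\[A,V\] is the subject-level
#' best unisensory modality for the matching measure. The unisensory
#' imbalance predictors use the per-cell spread,
#' `unidiff = max[A,V] - min[A,V]` (d', and analogously RT), which is
#' non-negative by construction. Calibrated per-modality target frequencies
#' are normalised by their grand mean across all subjects.
#'
#' @param scores A [score_conditions()] table.
#' @param frequencies Tibble with `subject_id`, `freq_a`, `freq_v` (the
#'   cohort ground-truth sidecar provides these).
#' @return One row per subject x expectation state (`2 x n_subjects` rows
#'   when complete); subjects missing any required cell are dropped with a
#'   message.
#' @examples
#' cohort <- simulate_cohort(design_config(n_subjects_per_experiment = 2),
#'                           master_seed = 1)
#' trials <- apply_filters(annotate_previous_trial(cohort$trials))
#' msf <- build_msf_records(score_conditions(trials), cohort$observers)
#' @export
build_msf_records <- function(scores, frequencies) {
  scores <- scores[scores$modality %in% c("A", "V", "AV") &
                     scores$te_state %in% c("expected", "unexpected"), ]
  complete <- scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(dplyr::n_distinct(paste(.data$modality, .data$te_state)) == 6L) |>
    dplyr::ungroup()
  dropped <- setdiff(unique(scores$subject_id), unique(complete$subject_id))
  if (length(dropped) > 0)
    message("dropping ", length(dropped),
            " subject(s) with incomplete cells: ",
            paste(utils::head(dropped, 5), collapse = ", "))

  best <- select_best_modalities(complete)
  wide <- complete |>
    dplyr::select("subject_id", "spatial_uncertainty", "target_uncertainty",
                  "modality", "te_state", "dprime", "mean_rt_ms") |>
    tidyr::pivot_wider(names_from = "modality",
                       values_from = c("dprime", "mean_rt_ms"))

  freq <- frequencies |>
    dplyr::transmute(
      .data$subject_id,
      freq_a_norm = .data$freq_a / mean(.data$freq_a),
      freq_v_norm = .data$freq_v / mean(.data$freq_v)
    )

  wide |>
    dplyr::left_join(best, by = "subject_id") |>
    dplyr::left_join(freq, by = "subject_id") |>
    dplyr::mutate(
      best_uni_d = ifelse(.data$best_modality_d == "A",
                          .data$dprime_A, .data$dprime_V),
      best_uni_rt = ifelse(.data$best_modality_rt == "A",
                           .data$mean_rt_ms_A, .data$mean_rt_ms_V),
      msf_d = .data$dprime_AV - .data$best_uni_d,
      msf_rt = .data$best_uni_rt - .data$mean_rt_ms_AV,
      unidiff_d = pmax(.data$dprime_A, .data$dprime_V) -
        pmin(.data$dprime_A, .data$dprime_V),
      unidiff_rt = pmax(.data$mean_rt_ms_A, .data$mean_rt_ms_V) -
        pmin(.data$mean_rt_ms_A, .data$mean_rt_ms_V)
    ) |>
    dplyr::select("subject_id", "te_state", "spatial_uncertainty",
                  "target_uncertainty", "best_modality_d", "best_modality_rt",
                  "preference_label", "msf_d", "msf_rt", "unidiff_d",
                  "unidiff_rt", "freq_a_norm", "freq_v_norm")
}
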