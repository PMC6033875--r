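test_that("n-1 classification follows the match definitions", {
  rows <- dplyr::bind_rows(
    mk_trial(trial_index = 1L, target_modality = "V", response = "higher"),
    mk_trial(trial_index = 2L, target_modality = "V"),                 # V<-V
    mk_trial(trial_index = 3L, target_modality = "AV",
             target_position = "early"),                               # AV<-V
    mk_trial(trial_index = 4L, target_modality = "A",
             target_position = "late", response = "lower"),            # wrong
    mk_trial(trial_index = 5L, target_modality = "AV")                 # post-error
  )
  cl <- classify_history(annotate_previous_trial(rows))
  expect_false(cl$history_included[1])
  expect_equal(cl$history_excluded_reason[1], "first_in_block")
  expect_equal(cl$modality_match[2], "match")
  expect_equal(cl$tp_match[2], "match")
  expect_equal(cl$modality_match[3], "mismatch")
  # trial 5 follows an incorrect answer
  expect_false(cl$history_included[5])
  expect_equal(cl$history_excluded_reason[5], "prev_not_correct")
  # AV at n-1 counts as mismatch for a current unisensory trial
  rows2 <- dplyr::bind_rows(
    mk_trial(trial_index = 1L, target_modality = "AV"),
    mk_trial(trial_index = 2L, target_modality = "A",
             target_position = "late")
  )
  cl2 <- classify_history(annotate_previous_trial(rows2))
  expect_equal(cl2$modality_match[2], "mismatch")
  expect_equal(cl2$tp_match[2], "mismatch")
  expect_error(classify_history(rows), "annotate_previous_trial")
})

test_that("history cells match a hand tally on a crafted block", {
  # 12 trials, one subject, single block; directions balanced so every cell
  # has both target types. All responses correct ("higher"/"lower" as the
  # direction), so no post-error exclusions; first trial drops out.
  spec <- tibble::tribble(
    ~i, ~mod,  ~pos,
    1L, "AV",  "early",
    2L, "AV",  "early",   # mod match, tp match
    3L, "A",   "early",   # mod mismatch (AV before A), tp match
    4L, "A",   "late",    # mod match, tp mismatch
    5L, "AV",  "late",    # mod mismatch, tp match
    6L, "AV",  "early",   # mod match, tp mismatch
    7L, "A",   "early",   # mod mismatch, tp match
    8L, "A",   "early",   # mod match, tp match
    9L, "AV",  "late",    # mod mismatch, tp mismatch
    10L, "AV", "late",    # mod match, tp match
    11L, "A",  "late",    # mod mismatch, tp match
    12L, "A",  "late"     # mod match, tp match
  )
  # two blocks with the identical trial pattern but mirrored target
  # directions, so every populated cell contains both target types
  dirs <- rep(c("higher", "lower"), 6)
  rows <- dplyr::bind_rows(
    purrr::pmap(spec, function(i, mod, pos)
      mk_trial(trial_index = i, target_modality = mod, target_position = pos,
               target_direction = dirs[i], response = dirs[i])),
    purrr::pmap(spec, function(i, mod, pos)
      mk_trial(trial_index = 12L + i, block_index = 2L,
               target_modality = mod, target_position = pos,
               target_direction = dirs[13 - i], response = dirs[13 - i]))
  )
  ann <- classify_history(annotate_previous_trial(rows))
  best <- tibble::tibble(subject_id = "s1", best_modality_d = "A")
  cells <- history_dprime_cells(ann, best, complete_only = FALSE,
                                min_trials = 1)
  tally <- function(m, mm, tp)
    sum(ann$history_included &
          (ifelse(ann$target_modality == "AV", "AV", "bestAV")) == m &
          ann$modality_match == mm & ann$tp_match == tp, na.rm = TRUE)
  for (i in seq_len(nrow(cells))) {
    expect_equal(cells$n_trials[i],
                 tally(cells$modality[i], cells$modality_match[i],
                       cells$tp_match[i]))
  }
  # partition property: analysed trials land in exactly one cell
  expect_equal(sum(cells$n_trials), sum(ann$history_included))
})

test_that("history exclusion accounting sums correctly on simulated data", {
  cohort <- small_cohort()
  ann <- classify_history(
    apply_filters(annotate_previous_trial(cohort$trials)))
  n_excluded <- sum(!ann$history_included)
  reasons <- table(ann$history_excluded_reason)
  expect_equal(sum(reasons), n_excluded)
  expect_setequal(names(reasons), c("first_in_block", "prev_not_correct"))
  # included trials restricted to AV/best partition into the cells
  best <- select_best_modalities(score_conditions(
    apply_filters(annotate_previous_trial(cohort$trials))))
  cells <- suppressMessages(
    history_dprime_cells(ann, best, complete_only = FALSE, min_trials = 1))
  analysed <- ann |>
    dplyr::inner_join(best[, c("subject_id", "best_modality_d")],
                      by = "subject_id") |>
    dplyr::filter(history_included,
                  target_modality == "AV" |
                    target_modality == best_modality_d)
  # cells only drop trials whose cell lacks one of the two target types
  expect_lte(sum(cells$n_trials), nrow(analysed))
  expect_gt(sum(cells$n_trials), 0.9 * nrow(analysed))
})

test_that("a sequential AV gain shows up as a TP-match advantage for AV", {
  cfg <- design_config(n_subjects_per_experiment = 4, n_main_blocks = 4,
                       trials_per_block = 96,
                       trials_per_modality_per_block = 32)
  sampler <- function(n, seed, ...) {
    set.seed(seed)
    purrr::map(seq_len(n), function(i)
      observer_params(te_gain = 0, msi_gain_base = 0,
                      msi_gain_uncertainty = 0, msi_pref_slope = 0,
                      uncertainty_penalty_uni = 0, seq_tp_gain_av = 0.5,
                      lapse_rate = 0,
                      seed = sample.int(.Machine$integer.max, 1)))
  }
  cohort <- simulate_cohort(cfg, master_seed = 77,
                            observer_sampler = sampler,
                            include_practice = FALSE, calibrate = FALSE)
  ann <- classify_history(
    apply_filters(annotate_previous_trial(cohort$trials)))
  best <- tibble::tibble(subject_id = unique(ann$subject_id),
                         best_modality_d = "A")
  cells <- suppressMessages(
    history_dprime_cells(ann, best, complete_only = FALSE, min_trials = 1))
  agg <- cells |>
    dplyr::group_by(modality, tp_match) |>
    dplyr::summarise(dprime = mean(dprime), .groups = "drop")
  g <- function(m, t) agg$dprime[agg$modality == m & agg$tp_match == t]
  av_gain <- g("AV", "match") - g("AV", "mismatch")
  uni_gain <- g("bestAV", "match") - g("bestAV", "mismatch")
  expect_gt(av_gain, 0)
  expect_gt(av_gain, uni_gain)
})
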