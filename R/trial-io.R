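TRIAL_SCHEMA_VERSION <- "temsf-trials-v1"

trial_required_cols <- c(
  "subject_id", "experiment_id", "spatial_uncertainty", "target_uncertainty",
  "block_index", "block_type", "trial_index", "sequence_modality",
  "target_modality", "target_position", "target_onset_ms",
  "target_direction", "response", "rt_ms", "correct"
)

#' Trial filter specification
#'
#' Encodes the analysis inclusion rules: responses inside a closed RT window
#' after target onset (default 150-3000 ms), early targets only by default
#' (late targets are always temporally expected and are not analysed for
#' expectation effects), main experimental blocks only, and a response
#' present. Rows failing several rules are tallied once under the first
#' failing rule in the precedence window > position > block > response.
#'
#' @param rt_window_ms Closed interval `[lo, hi]` in ms.
#' @param positions_included Subset of `c("early", "late")`.
#' @param require_response Drop trials without a response.
#' @param blocks_included Block types retained; defaults to the main blocks.
#' @param correct_only Restrict to correct trials (off by default; affects
#'   RT summaries only, documented switch).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(rt_window_ms = c(150, 3000),
                        positions_included = "early",
                        require_response = TRUE,
                        blocks_included = c("expect_early", "expect_late"),
                        correct_only = FALSE) {
  if (length(rt_window_ms) != 2 || rt_window_ms[1] >= rt_window_ms[2])
    stop("rt_window_ms must be an interval with lower < upper", call. = FALSE)
  if (length(positions_included) == 0)
    stop("positions_included must be nonempty", call. = FALSE)
  structure(list(rt_window_ms = rt_window_ms,
                 positions_included = positions_included,
                 require_response = require_response,
                 blocks_included = blocks_included,
                 correct_only = correct_only),
            class = "filter_spec")
}

#' Write a trial table to delimited text
#'
#' Tab-separated, UTF-8, header row, with a schema-version comment line.
#'
#' @param trials Trial tibble (see [simulate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  writeLines(paste0("# ", TRIAL_SCHEMA_VERSION), path, useBytes = TRUE)
  readr::write_tsv(trials, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads a delimited trial table (TSV by default), checks the schema, and
#' collects malformed rows (e.g. unparsable RTs) into a row-numbered report
#' attached as attribute `"row_report"`. Reading fails if required columns
#' are missing or if more than `max_bad_fraction` of rows are malformed.
#'
#' @param path File path.
#' @param max_bad_fraction Abort if more than this fraction of rows is
#'   malformed.
#' @return A typed tibble of trials.
#' @export
read_trials <- function(path, max_bad_fraction = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(
    path, comment = "#", progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      experiment_id = readr::col_integer(),
      block_index = readr::col_integer(),
      trial_index = readr::col_integer(),
      target_onset_ms = readr::col_double(),
      rt_ms = readr::col_double(),
      correct = readr::col_logical(),
      .default = readr::col_character()
    ))
  missing <- setdiff(trial_required_cols, names(tab))
  if (length(missing) > 0)
    stop("trial table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    if (nrow(probs) > max_bad_fraction * max(nrow(tab), 1L))
      stop("too many malformed rows (", nrow(probs), "); see readr::problems()",
           call. = FALSE)
    warning(nrow(probs), " malformed cell(s); row report attached",
            call. = FALSE)
  }
  if (nrow(tab) == 0) warning("trial table has zero rows", call. = FALSE)
  attr(tab, "row_report") <- tibble::as_tibble(probs)
  tab
}

#' Apply analysis filters to a trial table
#'
#' Retains rows passing every rule in the [filter_spec()] and returns the
#' exclusion tally as attribute `"exclusions"`; a row failing multiple rules
#' counts once, under the precedence window > position > block > response.
#' The RT window is closed: `rt_ms` in `[lo, hi]` is retained.
#'
#' @param trials Trial tibble, ideally already passed through
#'   [annotate_previous_trial()] (annotation must precede filtering so the
#'   n-1 trial can be of any type).
#' @param spec A [filter_spec()].
#' @return The filtered tibble, with attribute `"exclusions"` (a tibble of
#'   reason/n) summing to `rows_in - rows_out`.
#' @examples
#' cohort <- simulate_cohort(design_config(n_subjects_per_experiment = 1),
#'                           master_seed = 1)
#' kept <- apply_filters(cohort$trials, filter_spec())
#' attr(kept, "exclusions")
#' @export
apply_filters <- function(trials, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  rt_ok <- !is.na(trials$rt_ms) &
    trials$rt_ms >= spec$rt_window_ms[1] &
    trials$rt_ms <= spec$rt_window_ms[2]
  pos_ok <- trials$target_position %in% spec$positions_included
  block_ok <- trials$block_type %in% spec$blocks_included
  resp_ok <- !spec$require_response |
    (!is.na(trials$response) & trials$response != "none")
  corr_ok <- !spec$correct_only | (!is.na(trials$correct) & trials$correct)

  reason <- dplyr::case_when(
    !rt_ok ~ "rt_window",
    !pos_ok ~ "target_position",
    !block_ok ~ "block",
    !resp_ok ~ "response",
    !corr_ok ~ "incorrect",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  tally <- dplyr::count(tibble::tibble(reason = reason[!keep]),
                        .data$reason, name = "n")
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusions") <- tally
  attr(out, "filter_spec") <- spec
  out
}

#' Annotate each trial with its predecessor (n-1)
#'
#' Adds `prev_target_modality`, `prev_target_position` and `prev_correct`,
#' computed within subject in session order. n-1 relations do not cross
#' block boundaries (blocks are separated by breaks and a change of
#' expectation context), so the first trial of every block has missing n-1
#' fields. Annotation is computed on the unfiltered table so that filtering
#' never changes which trial counts as "previous".
#'
#' @param trials Trial tibble with strictly increasing `trial_index` within
#'   subject.
#' @return The tibble with three extra columns.
#' @export
annotate_previous_trial <- function(trials) {
  dup <- trials |>
    dplyr::count(.data$subject_id, .data$trial_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop("duplicate trial_index within subject: ",
         paste(utils::head(unique(dup$subject_id), 3), collapse = ", "),
         call. = FALSE)
  trials |>
    dplyr::arrange(.data$subject_id, .data$trial_index) |>
    dplyr::group_by(.data$subject_id, .data$block_index) |>
    dplyr::mutate(
      prev_target_modality = dplyr::lag(.data$target_modality),
      prev_target_position = dplyr::lag(.data$target_position),
      prev_correct = dplyr::lag(.data$correct)
    ) |>
    dplyr::ungroup()
}
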