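#' Target onset time within a stimulus sequence
#'
#' Events are `stim_ms` on-time followed by a `gap_ms` silent gap, so the
#' k-th event starts `(k - 1) * (stim_ms + gap_ms)` ms after sequence onset.
#' With the defaults, position 3 starts at 400 ms and position 9 at 1600 ms.
#'
#' @param position_index 1-based event index (vectorised).
#' @param config A [design_config()].
#' @return Onset time(s) in ms.
#' @export
target_onset_ms <- function(position_index, config = design_config()) {
  validate_design_config(config)
  position_index <- as.integer(position_index)
  if (any(position_index < 1L | position_index > config$sequence_length))
    stop("position_index must lie in [1, ", config$sequence_length, "]",
         call. = FALSE)
  (position_index - 1L) * (config$stim_ms + config$gap_ms)
}

block_type_order <- function(n_main_blocks, subject_index) {
  first <- if (subject_index %% 2L == 1L) c("expect_early", "expect_late")
           else c("expect_late", "expect_early")
  rep(first, length.out = n_main_blocks)
}

# Balanced higher/lower directions for one block x modality cell, shuffled.
balanced_directions <- function(n) {
  base <- rep(c("higher", "lower"), length.out = n)
  sample(base)
}

#' Build the trial layout of one session
#'
#' Lays out the main experiment for one subject: `n_main_blocks` alternating
#' expect-early / expect-late blocks (starting type set by subject-index
#' parity), each with `trials_per_modality_per_block` trials per target
#' modality in random order, target positions drawn independently per trial
#' with the block-type early probability, and target directions balanced
#' 50/50 within block x modality. No responses are filled in.
#'
#' @param config A [design_config()].
#' @param experiment_id Experiment number (must appear in the factor map).
#' @param subject_id Subject label for the output table.
#' @param rng_seed Seed for the layout randomisation.
#' @param subject_index Integer used for starting-block counterbalancing;
#'   defaults to 1 (expect-early first).
#' @return A tibble of trial skeletons, one row per main trial.
#' @examples
#' layout <- build_session_layout(design_config(), 1, "S001", rng_seed = 1)
#' nrow(layout)  # 1008
#' @export
build_session_layout <- function(config, experiment_id, subject_id,
                                 rng_seed = 1L, subject_index = 1L) {
  validate_design_config(config)
  fm <- config$experiment_factor_map
  row <- fm[fm$experiment_id == experiment_id, ]
  if (nrow(row) != 1L)
    stop("experiment_id ", experiment_id, " not in experiment_factor_map",
         call. = FALSE)
  set.seed(as.integer(rng_seed))
  types <- block_type_order(config$n_main_blocks, as.integer(subject_index))
  m <- config$trials_per_modality_per_block

  blocks <- purrr::map(seq_len(config$n_main_blocks), function(b) {
    modality <- sample(rep(c("A", "V", "AV"), each = m))
    direction <- character(length(modality))
    for (mod in c("A", "V", "AV"))
      direction[modality == mod] <- balanced_directions(m)
    p_early <- if (types[b] == "expect_early") config$p_early_expectearly
               else config$p_early_expectlate
    early <- stats::runif(length(modality)) < p_early
    tibble::tibble(
      block_index = b,
      block_type = types[b],
      target_modality = modality,
      target_position = ifelse(early, "early", "late"),
      target_direction = direction
    )
  })
  out <- dplyr::bind_rows(blocks)
  pos_idx <- ifelse(out$target_position == "early",
                    config$early_position, config$late_position)
  tibble::tibble(
    subject_id = subject_id,
    experiment_id = as.integer(experiment_id),
    spatial_uncertainty = row$spatial_uncertainty,
    target_uncertainty = row$target_uncertainty,
    block_index = out$block_index,
    block_type = out$block_type,
    trial_index = seq_len(nrow(out)),
    sequence_modality = if (row$target_uncertainty == "high") "AV"
                        else out$target_modality,
    target_modality = out$target_modality,
    target_position = out$target_position,
    target_onset_ms = target_onset_ms(pos_idx, config),
    target_direction = out$target_direction
  )
}

#' Condition-specific internal sensitivity
#'
#' Composes an observer's internal sensitivity (evidence-distribution
#' separation) for one trial type. The composition is additive with a floor
#' at zero:
#'
#' \deqn{\delta = base(mod) + te\_gain \cdot 1[expected]
#'   - uncertainty\_penalty\_uni \cdot n_{high} \cdot 1[mod \ne AV]
#'   + 1[mod = AV]\,(msi\_gain\_base + msi\_gain\_uncertainty \cdot n_{high}
#'   + msi\_pref\_slope \cdot |\delta_A - \delta_V|
#'   + seq\_tp\_gain\_av \cdot 1[prev\_tp\_match])}
#'
#' where `base(A) = delta_A`, `base(V) = delta_V`,
#' `base(AV) = (delta_A + delta_V)/2` and `n_high` counts the
#' high-uncertainty factors (spatial, target). With all gains zero and
#' balanced deltas every cell has the same sensitivity.
#'
#' All condition arguments are vectorised.
#'
#' @param obs An [observer_params()].
#' @param target_modality `"A"`, `"V"` or `"AV"`.
#' @param te_state `"expected"` or `"unexpected"`.
#' @param spatial_uncertainty,target_uncertainty `"low"` or `"high"`.
#' @param prev_tp_match Logical: previous trial's target position matches.
#' @return Numeric sensitivity, floored at 0.
#' @export
condition_sensitivity <- function(obs, target_modality, te_state,
                                  spatial_uncertainty, target_uncertainty,
                                  prev_tp_match = FALSE) {
  validate_observer_params(obs)
  check_levels <- function(x, lev, nm) {
    if (!all(x %in% lev))
      stop(nm, " must be one of ", paste(lev, collapse = ", "), call. = FALSE)
  }
  check_levels(target_modality, c("A", "V", "AV"), "target_modality")
  check_levels(te_state, c("expected", "unexpected"), "te_state")
  check_levels(spatial_uncertainty, c("low", "high"), "spatial_uncertainty")
  check_levels(target_uncertainty, c("low", "high"), "target_uncertainty")

  base <- dplyr::case_when(
    target_modality == "A" ~ obs$delta_A,
    target_modality == "V" ~ obs$delta_V,
    TRUE ~ (obs$delta_A + obs$delta_V) / 2
  )
  n_high <- (spatial_uncertainty == "high") + (target_uncertainty == "high")
  is_av <- as.numeric(target_modality == "AV")
  delta <- base +
    obs$te_gain * (te_state == "expected") -
    obs$uncertainty_penalty_uni * n_high * (1 - is_av) +
    is_av * (obs$msi_gain_base +
             obs$msi_gain_uncertainty * n_high +
             obs$msi_pref_slope * abs(obs$delta_A - obs$delta_V) +
             obs$seq_tp_gain_av * as.numeric(prev_tp_match))
  pmax(delta, 0)
}

#' Simulate 2AFC responses and response times
#'
#' Equal-variance Gaussian evidence model: on each trial the observer draws
#' evidence `e ~ Normal(s * delta / 2, 1)` with `s = +1` for a "higher"
#' target and `-1` for "lower", and responds "higher" iff `e > criterion`.
#' With probability `lapse_rate` the response is replaced by a fair coin
#' flip, and with probability `miss_rate` by no response. The implied
#' yes/no sensitivity equals `delta`, so the 2AFC estimator
#' `(z(H) - z(F)) / sqrt(2)` converges to `delta / sqrt(2)`. RTs are
#' shifted-lognormal with additive mean reductions for expected and AV
#' targets, floored at 150 ms.
#'
#' @param obs An [observer_params()].
#' @param delta Sensitivity per trial (vectorised).
#' @param target_direction `"higher"` / `"lower"` per trial.
#' @param expected,av Logical per trial: temporally expected; audiovisual.
#' @return A tibble with columns `response` and `rt_ms`.
#' @export
simulate_response <- function(obs, delta, target_direction,
                              expected = FALSE, av = FALSE) {
  validate_observer_params(obs)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  n <- length(delta)
  s <- ifelse(target_direction == "higher", 1, -1)
  e <- stats::rnorm(n, mean = s * delta / 2, sd = 1)
  response <- ifelse(e > obs$criterion, "higher", "lower")
  lapse <- stats::runif(n) < obs$lapse_rate
  if (any(lapse))
    response[lapse] <- sample(c("higher", "lower"), sum(lapse), replace = TRUE)
  rt <- obs$rt_shift_ms + stats::rlnorm(n, obs$rt_mu, obs$rt_sigma) -
    obs$rt_te_effect_ms * as.numeric(expected) -
    obs$rt_av_effect_ms * as.numeric(av)
  rt <- pmax(rt, 150)
  if (obs$miss_rate > 0) {
    miss <- stats::runif(n) < obs$miss_rate
    response[miss] <- "none"
    rt[miss] <- NA_real_
  }
  tibble::tibble(response = response, rt_ms = rt)
}

#' Calibrate per-modality difficulty to 75% accuracy
#'
#' Emulates the threshold-determination stage: for each unisensory modality,
#' a Robbins-Monro staircase over `threshold_block_trials / 2` simulated
#' trials adjusts the sensitivity-equivalent stimulus setting until observed
#' accuracy tracks 75%. Calibration uses equal numbers of early and late
#' targets and no temporal-expectation manipulation, so only the observer's
#' criterion and lapse rate shape the mapping from setting to accuracy.
#'
#' @param obs An [observer_params()].
#' @param config A [design_config()].
#' @param target_accuracy Accuracy level to calibrate to.
#' @param delta_start Starting value of the staircase; defaults to the
#'   closed-form unbiased solution `2 * qnorm(target_accuracy)`.
#' @param delta_max Upper bound; exceeding it aborts with a calibration error.
#' @param max_attempts A staircase whose internal validation batch lands
#'   grossly off target (accuracy more than 0.22 from the target level) is
#'   re-run, as an experimenter would re-run a failed threshold block; after
#'   this many attempts a calibration error is raised.
#' @return A tibble with one row per modality (`modality`, `delta_cal`,
#'   `n_trials`).
#' @examples
#' set.seed(1)
#' calibrate_threshold(observer_params(lapse_rate = 0), design_config())
#' @export
calibrate_threshold <- function(obs, config = design_config(),
                                target_accuracy = 0.75,
                                delta_start = 2 * stats::qnorm(target_accuracy),
                                delta_max = 8,
                                max_attempts = 3L) {
  validate_observer_params(obs)
  validate_design_config(config)
  n_per_mod <- config$threshold_block_trials %/% 2L
  run_staircase <- function(mod) {
    delta <- delta_start
    presented <- numeric(n_per_mod)
    correct <- logical(n_per_mod)
    s_dir <- rep(c(1, -1), length.out = n_per_mod)   # higher / lower targets
    noise <- stats::rnorm(n_per_mod)
    lapse_u <- stats::runif(n_per_mod)
    lapse_coin <- stats::runif(n_per_mod) < 0.5
    for (t in seq_len(n_per_mod)) {
      # same decision model as simulate_response, without the RT machinery
      presented[t] <- delta
      resp_higher <- (noise[t] + s_dir[t] * delta / 2) > obs$criterion
      if (lapse_u[t] < obs$lapse_rate) resp_higher <- lapse_coin[t]
      correct[t] <- resp_higher == (s_dir[t] > 0)
      step <- 1.2 / t^0.45
      delta <- max(delta + step * (target_accuracy - as.numeric(correct[t])), 0)
      if (delta > delta_max)
        stop("calibration failed to converge for modality ", mod,
             " (setting exceeded ", delta_max, "); trace head: ",
             paste(round(utils::head(presented, 5), 3), collapse = ", "),
             call. = FALSE)
    }
    # Readout combines two standard estimators of the 75% point: the
    # post-burn-in staircase average (last 60% of the track, Polyak style)
    # and a one-parameter probit maximum-likelihood fit to the full
    # staircase history. Their small finite-run biases have opposite sign,
    # so the average tracks the target closely.
    track <- c(presented[-1], delta)
    tail_n <- max(1L, n_per_mod - floor(0.4 * n_per_mod))
    d_tail <- mean(track[(n_per_mod - tail_n + 1L):n_per_mod])
    nll <- function(a) {
      p <- stats::pnorm(presented / 2 + a)
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      -sum(ifelse(correct, log(p), log(1 - p)))
    }
    a_hat <- stats::optimize(nll, c(-4, 4))$minimum
    d_ml <- max(0, 2 * (stats::qnorm(target_accuracy) - a_hat))
    d_cal <- (d_tail + d_ml) / 2
    # internal validation batch: a grossly off-target setting (e.g. an
    # observer whose bias puts 75% out of reach of the staircase) aborts
    n_val <- 400L
    s_val <- rep(c(1, -1), length.out = n_val)
    resp_val <- (stats::rnorm(n_val) + s_val * d_cal / 2) > obs$criterion
    lapse_val <- stats::runif(n_val) < obs$lapse_rate
    resp_val[lapse_val] <- stats::runif(sum(lapse_val)) < 0.5
    acc_val <- mean(resp_val == (s_val > 0))
    list(d_cal = d_cal, acc_val = acc_val)
  }
  purrr::map_dfr(c("A", "V"), function(mod) {
    for (attempt in seq_len(max_attempts)) {
      res <- run_staircase(mod)
      if (abs(res$acc_val - target_accuracy) <= 0.22)
        return(tibble::tibble(modality = mod, delta_cal = res$d_cal,
                              n_trials = n_per_mod))
    }
    stop("calibration failed to converge for modality ", mod,
         sprintf(": validation accuracy %.2f vs target %.2f at setting %.2f",
                 res$acc_val, target_accuracy, res$d_cal),
         " after ", max_attempts, " attempts", call. = FALSE)
  })
}

# Simulate responses for a laid-out block of trials belonging to one
# observer, given the effective per-modality baselines.
simulate_trials_for_subject <- function(layout, obs, config) {
  prev_pos <- dplyr::lag(layout$target_position)
  new_block <- layout$block_index != dplyr::lag(layout$block_index,
                                               default = -1L)
  prev_tp_match <- !new_block & prev_pos == layout$target_position
  prev_tp_match[is.na(prev_tp_match)] <- FALSE

  te_state <- ifelse(
    (layout$block_type == "expect_early" & layout$target_position == "early") |
      (layout$block_type == "expect_late" & layout$target_position == "late"),
    "expected", "unexpected")
  # no TE manipulation during practice stages
  te_state[layout$block_type %in% c("training", "threshold")] <- "unexpected"

  delta <- condition_sensitivity(
    obs, layout$target_modality, te_state,
    layout$spatial_uncertainty, layout$target_uncertainty, prev_tp_match)
  resp <- simulate_response(
    obs, delta, layout$target_direction,
    expected = te_state == "expected",
    av = layout$target_modality == "AV")
  layout$response <- resp$response
  layout$rt_ms <- round(resp$rt_ms)
  layout$correct <- ifelse(layout$response == "none", NA,
                           layout$response == layout$target_direction)
  layout
}

practice_layout <- function(config, experiment_id, subject_id) {
  fm <- config$experiment_factor_map
  row <- fm[fm$experiment_id == experiment_id, ]
  mk <- function(n, type, block_index) {
    modality <- sample(rep(c("A", "V"), length.out = n))
    pos <- sample(rep(c("early", "late"), length.out = n))
    tibble::tibble(
      subject_id = subject_id,
      experiment_id = as.integer(experiment_id),
      spatial_uncertainty = row$spatial_uncertainty,
      target_uncertainty = row$target_uncertainty,
      block_index = block_index,
      block_type = type,
      trial_index = NA_integer_,
      sequence_modality = modality,
      target_modality = modality,
      target_position = pos,
      target_onset_ms = target_onset_ms(
        ifelse(pos == "early", config$early_position, config$late_position),
        config),
      target_direction = sample(rep(c("higher", "lower"), length.out = n))
    )
  }
  half <- config$threshold_block_trials %/% 2L
  dplyr::bind_rows(
    mk(config$training_trials, "training", -2L),
    mk(half, "threshold", -1L),
    mk(config$threshold_block_trials - half, "threshold", 0L)
  )
}

#' Simulate a full multi-experiment cohort
#'
#' Generates trial-level data for `n_experiments x n_subjects_per_experiment`
#' synthetic observers. Each subject gets a per-subject seed derived from
#' `master_seed`, a simulated 75%-accuracy calibration stage fixing the
#' per-modality baseline difficulty, optional flagged practice trials, and a
#' full main session laid out by [build_session_layout()] and answered via
#' [simulate_response()]. The subject's signed modality preference is
#' applied on top of the calibrated baselines (half added to A, half
#' subtracted from V), emulating post-calibration attentional imbalance.
#'
#' @param config A [design_config()].
#' @param master_seed Integer master seed; the whole cohort is a
#'   deterministic function of `(config, master_seed, sampler arguments)`.
#' @param observer_sampler Function `(n, seed, ...)` returning a list of
#'   [observer_params()]; defaults to [sample_observers()].
#' @param include_practice Keep training/threshold trials (flagged by
#'   `block_type`) in the output.
#' @param calibrate Run the simulated calibration stage. If `FALSE`, the
#'   observers' nominal baselines are used directly and the frequency
#'   covariates equal those baselines.
#' @param ... Passed on to `observer_sampler`.
#' @return A list of class `"temsf_cohort"` with elements `trials` (tidy
#'   trial table) and `observers` (ground-truth parameter sidecar, one row
#'   per subject, including calibrated values `freq_a` / `freq_v`).
#' @examples
#' cohort <- simulate_cohort(design_config(n_subjects_per_experiment = 1),
#'                           master_seed = 1, include_practice = FALSE)
#' dplyr::count(cohort$trials, block_type)
#' @export
simulate_cohort <- function(config = design_config(),
                            master_seed = 1L,
                            observer_sampler = sample_observers,
                            include_practice = TRUE,
                            calibrate = TRUE,
                            ...) {
  validate_design_config(config)
  n_subj <- config$n_experiments * config$n_subjects_per_experiment
  set.seed(as.integer(master_seed))
  subject_seeds <- sample.int(.Machine$integer.max, n_subj)
  observers <- observer_sampler(n_subj,
                                seed = sample.int(.Machine$integer.max, 1),
                                ...)

  idx <- tibble::tibble(
    subject_index = seq_len(n_subj),
    experiment_id = rep(seq_len(config$n_experiments),
                        each = config$n_subjects_per_experiment),
    subject_id = sprintf("S%03d", seq_len(n_subj))
  )

  per_subject <- purrr::pmap(idx, function(subject_index, experiment_id,
                                           subject_id) {
    obs <- observers[[subject_index]]
    set.seed(subject_seeds[subject_index])
    if (calibrate) {
      cal <- calibrate_threshold(obs, config)
      freq_a <- cal$delta_cal[cal$modality == "A"]
      freq_v <- cal$delta_cal[cal$modality == "V"]
    } else {
      freq_a <- obs$delta_A - obs$pref_imbalance / 2
      freq_v <- obs$delta_V + obs$pref_imbalance / 2
    }
    eff <- obs
    eff$delta_A <- freq_a + obs$pref_imbalance / 2
    eff$delta_V <- freq_v - obs$pref_imbalance / 2

    main <- build_session_layout(config, experiment_id, subject_id,
                                 rng_seed = sample.int(.Machine$integer.max, 1),
                                 subject_index = subject_index)
    layout <- if (include_practice)
      dplyr::bind_rows(practice_layout(config, experiment_id, subject_id), main)
    else main
    layout$trial_index <- seq_len(nrow(layout))
    trials <- simulate_trials_for_subject(layout, eff, config)

    truth <- tibble::tibble(
      subject_id = subject_id,
      experiment_id = as.integer(experiment_id),
      freq_a = freq_a, freq_v = freq_v,
      delta_A_eff = eff$delta_A, delta_V_eff = eff$delta_V,
      pref_imbalance = obs$pref_imbalance,
      te_gain = obs$te_gain,
      msi_gain_base = obs$msi_gain_base,
      msi_gain_uncertainty = obs$msi_gain_uncertainty,
      msi_pref_slope = obs$msi_pref_slope,
      uncertainty_penalty_uni = obs$uncertainty_penalty_uni,
      seq_tp_gain_av = obs$seq_tp_gain_av,
      criterion = obs$criterion,
      lapse_rate = obs$lapse_rate
    )
    list(trials = trials, truth = truth)
  })

  out <- list(
    trials = dplyr::bind_rows(purrr::map(per_subject, "trials")),
    observers = dplyr::bind_rows(purrr::map(per_subject, "truth")),
    config = config,
    master_seed = as.integer(master_seed)
  )
  class(out) <- "temsf_cohort"
  out
}

#' @export
print.temsf_cohort <- function(x, ...) {
  cat("<temsf_cohort>\n")
  cat(sprintf("  %d subjects, %d trials (%d main)\n",
              dplyr::n_distinct(x$trials$subject_id), nrow(x$trials),
              sum(x$trials$block_type %in% c("expect_early", "expect_late"))))
  cat(sprintf("  master_seed = %d\n", x$master_seed))
  invisible(x)
}
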