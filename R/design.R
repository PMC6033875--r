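#' Experimental design configuration
#'
#' Builds the design layout constants for the four-experiment
#' target-in-sequence paradigm: each trial is a sequence of 11 brief stimuli
#' (100 ms on, 100 ms gap) containing exactly one target, presented early
#' (position 3, 400 ms after sequence onset) or late (position 9, 1600 ms).
#' Temporal expectation is manipulated block-wise: "expect early" blocks
#' contain 86% early targets, "expect late" blocks 43%. Experiments cross
#' spatial uncertainty (speakers vs headphones) with target uncertainty
#' (unisensory vs always-audiovisual sequences).
#'
#' @param n_experiments Number of experiments (between-subject factor cells).
#' @param n_subjects_per_experiment Participants per experiment.
#' @param n_main_blocks Main blocks per session (half expect-early, half
#'   expect-late).
#' @param trials_per_block Trials in each main block.
#' @param trials_per_modality_per_block Trials per target modality (A, V, AV)
#'   in each main block; must be `trials_per_block / 3`.
#' @param sequence_length Number of stimulus events per sequence.
#' @param stim_ms,gap_ms Stimulus duration and inter-stimulus gap, ms.
#' @param early_position,late_position 1-based sequence indices of the early
#'   and late target positions.
#' @param p_early_expectearly,p_early_expectlate Probability that a trial's
#'   target is early, in expect-early and expect-late blocks respectively.
#' @param threshold_block_trials Total trials in the threshold-determination
#'   stage (used to calibrate per-modality difficulty to 75% accuracy).
#' @param training_trials Trials in the training block (generated, excluded
#'   from analysis).
#' @param response_deadline_ms Response window after sequence offset, ms.
#' @param iti_ms_range Length-2 numeric, inter-trial-interval range in ms
#'   (metadata only).
#' @param experiment_factor_map Data frame mapping `experiment_id` to
#'   `spatial_uncertainty` and `target_uncertainty` levels (`"low"`/`"high"`).
#'   The default crosses the two factors over experiments 1-4.
#'
#' @return An object of class `"design_config"` (a named list).
#' @examples
#' cfg <- design_config()
#' cfg$trials_per_block            # 168
#' target_onset_ms(3, cfg)         # 400
#' @export
design_config <- function(n_experiments = 4L,
                          n_subjects_per_experiment = 30L,
                          n_main_blocks = 6L,
                          trials_per_block = 168L,
                          trials_per_modality_per_block = 56L,
                          sequence_length = 11L,
                          stim_ms = 100,
                          gap_ms = 100,
                          early_position = 3L,
                          late_position = 9L,
                          p_early_expectearly = 0.86,
                          p_early_expectlate = 0.43,
                          threshold_block_trials = 144L,
                          training_trials = 24L,
                          response_deadline_ms = 1500,
                          iti_ms_range = c(200, 400),
                          experiment_factor_map = NULL) {
  if (is.null(experiment_factor_map)) {
    experiment_factor_map <- tibble::tibble(
      experiment_id = seq_len(n_experiments),
      spatial_uncertainty = c("low", "high", "low", "high")[seq_len(n_experiments)],
      target_uncertainty  = c("low", "low", "high", "high")[seq_len(n_experiments)]
    )
  }
  cfg <- list(
    n_experiments = as.integer(n_experiments),
    n_subjects_per_experiment = as.integer(n_subjects_per_experiment),
    n_main_blocks = as.integer(n_main_blocks),
    trials_per_block = as.integer(trials_per_block),
    trials_per_modality_per_block = as.integer(trials_per_modality_per_block),
    sequence_length = as.integer(sequence_length),
    stim_ms = stim_ms,
    gap_ms = gap_ms,
    early_position = as.integer(early_position),
    late_position = as.integer(late_position),
    p_early_expectearly = p_early_expectearly,
    p_early_expectlate = p_early_expectlate,
    threshold_block_trials = as.integer(threshold_block_trials),
    training_trials = as.integer(training_trials),
    response_deadline_ms = response_deadline_ms,
    iti_ms_range = iti_ms_range,
    experiment_factor_map = experiment_factor_map
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  fail <- function(msg) stop("invalid design_config: ", msg, call. = FALSE)
  if (cfg$trials_per_block != 3L * cfg$trials_per_modality_per_block)
    fail("trials_per_block must equal 3 * trials_per_modality_per_block")
  for (p in c("p_early_expectearly", "p_early_expectlate"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) fail(paste(p, "must lie in (0, 1)"))
  if (!(cfg$early_position < cfg$late_position &&
        cfg$late_position <= cfg$sequence_length))
    fail("need early_position < late_position <= sequence_length")
  if (cfg$n_main_blocks %% 2L != 0L)
    fail("n_main_blocks must be even (half expect-early, half expect-late)")
  fm <- cfg$experiment_factor_map
  if (!all(c("experiment_id", "spatial_uncertainty", "target_uncertainty") %in%
           names(fm)))
    fail("experiment_factor_map must have experiment_id, spatial_uncertainty, target_uncertainty")
  if (anyDuplicated(fm$experiment_id))
    fail("experiment_factor_map has duplicated experiment ids")
  if (!setequal(fm$experiment_id, seq_len(cfg$n_experiments)))
    fail("experiment_factor_map must cover every experiment id exactly once")
  if (!all(fm$spatial_uncertainty %in% c("low", "high")) ||
      !all(fm$target_uncertainty %in% c("low", "high")))
    fail("uncertainty levels must be 'low' or 'high'")
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  %d experiments x %d subjects; %d main blocks x %d trials (%d per modality)\n",
              x$n_experiments, x$n_subjects_per_experiment, x$n_main_blocks,
              x$trials_per_block, x$trials_per_modality_per_block))
  cat(sprintf("  sequence: %d events (%g ms + %g ms gap); targets at %d (%g ms) / %d (%g ms)\n",
              x$sequence_length, x$stim_ms, x$gap_ms,
              x$early_position, target_onset_ms(x$early_position, x),
              x$late_position, target_onset_ms(x$late_position, x)))
  cat(sprintf("  P(early): expect-early %.2f, expect-late %.2f\n",
              x$p_early_expectearly, x$p_early_expectlate))
  invisible(x)
}

#' Synthetic observer parameters
#'
#' Defines a generative signal-detection observer for the 2AFC
#' frequency-discrimination task. Internal sensitivity (the separation, in
#' evidence units, between the "higher" and "lower" evidence distributions)
#' is composed additively per condition from a per-modality baseline plus
#' gains for temporal expectation, audiovisual stimulation, uncertainty, and
#' trial history; see [condition_sensitivity()]. Responses arise from an
#' equal-variance Gaussian evidence model with criterion `criterion` and a
#' lapse process; response times follow a shifted lognormal with additive
#' mean reductions for expected and audiovisual targets.
#'
#' With every gain set to zero and `delta_A == delta_V`, all condition
#' sensitivities are equal: the null observer used for type-I-error checks.
#'
#' @param delta_A,delta_V Baseline sensitivity for auditory and visual
#'   targets (evidence-distribution separation).
#' @param pref_imbalance Signed modality preference: added in half to
#'   `delta_A` and subtracted in half from `delta_V`.
#' @param te_gain Additive sensitivity boost for temporally expected targets.
#' @param msi_gain_base Additive audiovisual (AV) sensitivity gain.
#' @param msi_gain_uncertainty Extra AV gain per high-uncertainty factor
#'   (spatial, target).
#' @param msi_pref_slope Coupling (typically negative) of the AV gain to the
#'   absolute unisensory imbalance `|delta_A - delta_V|`.
#' @param uncertainty_penalty_uni Sensitivity reduction applied to unisensory
#'   targets per high-uncertainty factor.
#' @param seq_tp_gain_av AV sensitivity boost when the previous trial's
#'   target position matches the current one.
#' @param criterion Response criterion c ("higher" responses require evidence
#'   above it).
#' @param rt_shift_ms,rt_mu,rt_sigma Shifted-lognormal RT parameters (ms,
#'   log-ms, log-sd).
#' @param rt_te_effect_ms,rt_av_effect_ms Mean-RT reductions for expected and
#'   AV targets, ms.
#' @param lapse_rate Probability that a response is replaced by a fair coin
#'   flip; must lie in `[0, 0.2]`.
#' @param miss_rate Probability of an omitted response (`"none"`).
#' @param seed Per-observer RNG seed.
#'
#' @return An object of class `"observer_params"` (a named list).
#' @examples
#' obs <- observer_params(te_gain = 0.3)
#' condition_sensitivity(obs, "AV", "expected", "low", "low")
#' @export
observer_params <- function(delta_A = 1.349,
                            delta_V = 1.349,
                            pref_imbalance = 0,
                            te_gain = 0.26,
                            msi_gain_base = 0.17,
                            msi_gain_uncertainty = 0.15,
                            msi_pref_slope = -0.5,
                            uncertainty_penalty_uni = 0.25,
                            seq_tp_gain_av = 0.3,
                            criterion = 0,
                            rt_shift_ms = 600,
                            rt_mu = log(1000),
                            rt_sigma = 0.4,
                            rt_te_effect_ms = 111,
                            rt_av_effect_ms = 59,
                            lapse_rate = 0.02,
                            miss_rate = 0,
                            seed = 1L) {
  obs <- list(
    delta_A = delta_A + pref_imbalance / 2,
    delta_V = delta_V - pref_imbalance / 2,
    pref_imbalance = pref_imbalance,
    te_gain = te_gain,
    msi_gain_base = msi_gain_base,
    msi_gain_uncertainty = msi_gain_uncertainty,
    msi_pref_slope = msi_pref_slope,
    uncertainty_penalty_uni = uncertainty_penalty_uni,
    seq_tp_gain_av = seq_tp_gain_av,
    criterion = criterion,
    rt_shift_ms = rt_shift_ms,
    rt_mu = rt_mu,
    rt_sigma = rt_sigma,
    rt_te_effect_ms = rt_te_effect_ms,
    rt_av_effect_ms = rt_av_effect_ms,
    lapse_rate = lapse_rate,
    miss_rate = miss_rate,
    seed = as.integer(seed)
  )
  class(obs) <- "observer_params"
  validate_observer_params(obs)
  obs
}

validate_observer_params <- function(obs) {
  stopifnot(inherits(obs, "observer_params"))
  fail <- function(msg) stop("invalid observer_params: ", msg, call. = FALSE)
  if (!is.finite(obs$rt_sigma) || obs$rt_sigma <= 0) fail("rt_sigma must be > 0")
  if (obs$lapse_rate < 0 || obs$lapse_rate > 0.2)
    fail("lapse_rate must lie in [0, 0.2]")
  if (obs$miss_rate < 0 || obs$miss_rate > 1) fail("miss_rate must lie in [0, 1]")
  gains <- c(obs$delta_A, obs$delta_V, obs$te_gain, obs$msi_gain_base,
             obs$msi_gain_uncertainty, obs$msi_pref_slope,
             obs$uncertainty_penalty_uni, obs$seq_tp_gain_av, obs$criterion)
  if (!all(is.finite(gains))) fail("all sensitivities/gains must be finite")
  invisible(obs)
}

#' Draw a population of synthetic observers
#'
#' Samples per-subject [observer_params()] around the defaults, emulating a
#' cohort in which the sizes and signs of the population-level effects match
#' the generative assumptions documented in the methods vignette: a positive
#' temporal-expectation gain, a positive audiovisual gain that grows with
#' stimulus uncertainty and shrinks with unisensory imbalance, a unisensory
#' penalty under uncertainty, and a positive AV gain after a target-position
#' match at n-1.
#'
#' @param n Number of observers to draw.
#' @param seed RNG seed for the population draw.
#' @param te_gain_mean,te_gain_sd Population mean/sd of the TE gain.
#' @param msi_gain_mean,msi_gain_sd Population mean/sd of the baseline AV gain.
#' @param pref_sd Population sd of the signed modality preference.
#' @param seq_tp_gain_mean Population mean of the n-1 TP-match AV gain.
#' @param null_observer If `TRUE`, all gains, penalties and preferences are
#'   zero (type-I-error calibration cohorts).
#' @return A list of `observer_params`, length `n`.
#' @export
sample_observers <- function(n,
                             seed = 1L,
                             te_gain_mean = 0.26, te_gain_sd = 0.15,
                             msi_gain_mean = 0.17, msi_gain_sd = 0.1,
                             pref_sd = 0.35,
                             seq_tp_gain_mean = 0.3,
                             null_observer = FALSE) {
  set.seed(as.integer(seed))
  purrr::map(seq_len(n), function(i) {
    if (null_observer) {
      observer_params(
        pref_imbalance = 0, te_gain = 0, msi_gain_base = 0,
        msi_gain_uncertainty = 0, msi_pref_slope = 0,
        uncertainty_penalty_uni = 0, seq_tp_gain_av = 0,
        criterion = stats::rnorm(1, 0, 0.15),
        lapse_rate = 0.02,
        seed = sample.int(.Machine$integer.max, 1)
      )
    } else {
      observer_params(
        pref_imbalance = stats::rnorm(1, 0, pref_sd),
        te_gain = stats::rnorm(1, te_gain_mean, te_gain_sd),
        msi_gain_base = stats::rnorm(1, msi_gain_mean, msi_gain_sd),
        msi_gain_uncertainty = stats::rnorm(1, 0.15, 0.05),
        msi_pref_slope = -0.5,
        uncertainty_penalty_uni = stats::rnorm(1, 0.25, 0.05),
        seq_tp_gain_av = stats::rnorm(1, seq_tp_gain_mean, 0.1),
        criterion = stats::rnorm(1, 0, 0.15),
        rt_mu = stats::rnorm(1, log(1000), 0.1),
        lapse_rate = 0.02,
        seed = sample.int(.Machine$integer.max, 1)
      )
    }
  })
}
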