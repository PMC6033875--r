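# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# small 8-subject cohort (2 per experiment), 4 reduced blocks
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- design_config(n_subjects_per_experiment = 2, n_main_blocks = 4,
                         trials_per_block = 48,
                         trials_per_modality_per_block = 16)
    .fixture_env$small <- simulate_cohort(cfg, master_seed = 401,
                                          include_practice = FALSE)
  }
  .fixture_env$small
}

# handcrafted trial rows with full schema
mk_trial <- function(subject_id = "s1", block_index = 1L,
                     block_type = "expect_early", trial_index = 1L,
                     target_modality = "A", target_position = "early",
                     target_direction = "higher", response = "higher",
                     rt_ms = 1000, experiment_id = 1L,
                     spatial_uncertainty = "low",
                     target_uncertainty = "low") {
  tibble::tibble(
    subject_id = subject_id, experiment_id = experiment_id,
    spatial_uncertainty = spatial_uncertainty,
    target_uncertainty = target_uncertainty,
    block_index = block_index, block_type = block_type,
    trial_index = trial_index,
    sequence_modality = target_modality,
    target_modality = target_modality,
    target_position = target_position,
    target_onset_ms = ifelse(target_position == "early", 400, 1600),
    target_direction = target_direction,
    response = response, rt_ms = rt_ms,
    correct = ifelse(response == "none", NA, response == target_direction)
  )
}

# one-subject condition-score table from explicit cell values
mk_scores <- function(subject_id = "s1",
                      d_a = c(1.1, 0.9), d_v = c(1.0, 1.2),
                      d_av = c(1.4, 1.3),
                      rt_a = c(1400, 1500), rt_v = c(1450, 1480),
                      rt_av = c(1380, 1400),
                      n_trials = 40,
                      spatial_uncertainty = "low",
                      target_uncertainty = "low") {
  tibble::tibble(
    subject_id = subject_id,
    experiment_id = 1L,
    spatial_uncertainty = spatial_uncertainty,
    target_uncertainty = target_uncertainty,
    modality = rep(c("A", "V", "AV"), each = 2),
    te_state = rep(c("expected", "unexpected"), 3),
    dprime = c(d_a, d_v, d_av),
    mean_rt_ms = c(rt_a, rt_v, rt_av),
    n_trials = n_trials
  )
}

# random predictor frame in the shape build_predictor_matrix() emits
mk_pm <- function(n = 40, seed = 1, y = NULL) {
  set.seed(seed)
  pref <- sample(c("a", "v", "m"), n, replace = TRUE)
  pm <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    te_state = rep(c("expected", "unexpected"), length.out = n),
    y = 0,
    SpU = sample(0:1, n, replace = TRUE),
    TaU = sample(0:1, n, replace = TRUE),
    TE = as.integer(rep(c("expected", "unexpected"),
                        length.out = n) == "unexpected"),
    FreqA = rnorm(n, 1, 0.1),
    FreqV = rnorm(n, 1, 0.1),
    PrefA = as.integer(pref == "a"),
    PrefV = as.integer(pref == "v"),
    UniDiff = runif(n, 0, 1)
  )
  pm$y <- if (is.null(y)) rnorm(n) else y
  attr(pm, "measure") <- "dprime"
  pm
}

# naive leave-one-out: refit every fold with lm()
naive_loocv_rmse <- function(pm, mask) {
  preds <- c("SpU", "TaU", "TE", "FreqA", "FreqV", "PrefA", "PrefV",
             "UniDiff")[as.logical(mask)]
  dat <- as.data.frame(pm[, c("y", preds)])
  pred <- vapply(seq_len(nrow(dat)), function(i) {
    fit <- stats::lm(y ~ ., data = dat[-i, , drop = FALSE])
    unname(stats::predict(fit, newdata = dat[i, , drop = FALSE]))
  }, 1)
  sqrt(mean((pred - dat$y)^2))
}
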