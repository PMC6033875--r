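test_that("design configuration invariants are enforced with named errors", {
  expect_error(design_config(trials_per_block = 100),
               "trials_per_block")
  expect_error(design_config(p_early_expectearly = 1.2), "p_early_expectearly")
  expect_error(design_config(early_position = 10, late_position = 9),
               "early_position")
  expect_error(
    design_config(experiment_factor_map = tibble::tibble(
      experiment_id = c(1, 1, 2, 3),
      spatial_uncertainty = "low", target_uncertainty = "low")),
    "duplicated")
})

test_that("target onset times follow the event grid", {
  cfg <- design_config()
  expect_equal(target_onset_ms(3, cfg), 400)
  expect_equal(target_onset_ms(9, cfg), 1600)
  expect_equal(target_onset_ms(1, cfg), 0)
  expect_error(target_onset_ms(12, cfg), "position_index")
  expect_error(target_onset_ms(0, cfg), "position_index")
})

test_that("session layout has the specified block and modality structure", {
  cfg <- design_config()
  lay <- build_session_layout(cfg, 1, "S001", rng_seed = 5)
  expect_equal(nrow(lay), 1008)
  counts <- dplyr::count(lay, block_index, target_modality)
  expect_true(all(counts$n == 56))
  # balanced directions within block x modality
  dirs <- dplyr::count(lay, block_index, target_modality, target_direction)
  expect_true(all(dirs$n == 28))
  # strict alternation, starting type by subject parity
  types <- dplyr::distinct(lay, block_index, block_type)$block_type
  expect_equal(types, rep(c("expect_early", "expect_late"), 3))
  lay2 <- build_session_layout(cfg, 1, "S002", rng_seed = 5,
                               subject_index = 2L)
  types2 <- dplyr::distinct(lay2, block_index, block_type)$block_type
  expect_equal(types2, rep(c("expect_late", "expect_early"), 3))
})

test_that("session layout arithmetic scales to toy configurations", {
  cfg <- design_config(n_main_blocks = 2, trials_per_block = 6,
                       trials_per_modality_per_block = 2)
  lay <- build_session_layout(cfg, 2, "s", rng_seed = 1)
  expect_equal(nrow(lay), 12)
  expect_true(all(dplyr::count(lay, target_modality)$n == 4))
  expect_error(build_session_layout(cfg, 99, "s"), "experiment_factor_map")
})

test_that("empirical target-position proportions match the block probabilities", {
  cfg <- design_config(n_main_blocks = 40, trials_per_block = 600,
                       trials_per_modality_per_block = 200)
  lay <- build_session_layout(cfg, 1, "s", rng_seed = 7)
  for (bt in c("expect_early", "expect_late")) {
    sub <- lay[lay$block_type == bt, ]
    p <- if (bt == "expect_early") cfg$p_early_expectearly
         else cfg$p_early_expectlate
    n <- nrow(sub)
    expect_gt(n, 10000)
    phat <- mean(sub$target_position == "early")
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("condition sensitivity composes additively from the observer gains", {
  null_obs <- observer_params(te_gain = 0, msi_gain_base = 0,
                              msi_gain_uncertainty = 0, msi_pref_slope = 0,
                              uncertainty_penalty_uni = 0, seq_tp_gain_av = 0,
                              delta_A = 1, delta_V = 1)
  grid <- tidyr::expand_grid(mod = c("A", "V", "AV"),
                             te = c("expected", "unexpected"),
                             sp = c("low", "high"), ta = c("low", "high"),
                             tp = c(TRUE, FALSE))
  d <- condition_sensitivity(null_obs, grid$mod, grid$te, grid$sp, grid$ta,
                             grid$tp)
  expect_equal(d, rep(1, nrow(grid)))

  obs <- observer_params(te_gain = 0.3)
  expect_equal(
    condition_sensitivity(obs, "AV", "expected", "low", "low") -
      condition_sensitivity(obs, "AV", "unexpected", "low", "low"),
    0.3)

  # preference-coupled AV gain: slope x imbalance
  bal <- observer_params(msi_pref_slope = -0.5, pref_imbalance = 0,
                         te_gain = 0)
  imb <- observer_params(msi_pref_slope = -0.5, pref_imbalance = 0.4,
                         te_gain = 0)
  av_bal <- condition_sensitivity(bal, "AV", "unexpected", "low", "low")
  av_imb <- condition_sensitivity(imb, "AV", "unexpected", "low", "low")
  # baselines average out the imbalance, so the whole difference is the
  # slope term: -0.5 * |0.4| = -0.2
  expect_equal(av_imb - av_bal, -0.2)

  # floored at zero
  low <- observer_params(delta_A = 0.1, delta_V = 0.1,
                         uncertainty_penalty_uni = 1)
  expect_equal(
    condition_sensitivity(low, "A", "unexpected", "high", "high"), 0)
  expect_error(condition_sensitivity(obs, "X", "expected", "low", "low"),
               "target_modality")
})

test_that("response model yields the closed-form accuracy", {
  obs <- observer_params(criterion = 0, lapse_rate = 0)
  set.seed(21)
  dirs <- rep(c("higher", "lower"), 5000)

  r0 <- simulate_response(obs, rep(0, 10000), dirs)
  acc0 <- mean(r0$response == dirs)
  expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 10000))

  d75 <- 2 * qnorm(0.75)
  r1 <- simulate_response(obs, rep(d75, 10000), dirs)
  acc1 <- mean(r1$response == dirs)
  expect_lt(abs(acc1 - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))

  expect_true(all(r1$rt_ms >= 150))

  biased <- observer_params(criterion = 50, lapse_rate = 0)
  rb <- simulate_response(biased, rep(1, 200), rep("higher", 200))
  expect_true(all(rb$response == "lower"))
})

test_that("analysis-side 2AFC d-prime recovers the generative sensitivity", {
  obs <- observer_params(criterion = 0, lapse_rate = 0)
  delta <- 1.6
  set.seed(33)
  dirs <- rep(c("higher", "lower"), 5000)
  r <- simulate_response(obs, rep(delta, 10000), dirs)
  hi <- dirs == "higher"
  d_hat <- dprime_2afc(sum(r$response[hi] == "higher"), sum(hi),
                       sum(r$response[!hi] == "higher"), sum(!hi))
  expect_lt(abs(d_hat - delta / sqrt(2)), 0.05)
})

test_that("threshold calibration tracks 75% accuracy and flags degenerate bias", {
  obs <- observer_params(criterion = 0, lapse_rate = 0)
  set.seed(5)
  cal <- calibrate_threshold(obs, design_config())
  expect_equal(cal$modality, c("A", "V"))
  expect_equal(cal$n_trials, c(72, 72))
  # a single 72-trial staircase is noisy; the mean over repeated runs must
  # sit close to the closed-form unbiased threshold 2*qnorm(0.75)
  set.seed(6)
  dirs <- rep(c("higher", "lower"), 1000)
  accs <- replicate(12, {
    cal_i <- calibrate_threshold(obs, design_config())
    mean(vapply(cal_i$delta_cal, function(d) {
      r <- simulate_response(obs, rep(d, 2000), dirs)
      mean(r$response == dirs)
    }, 1))
  })
  expect_lt(abs(mean(accs) - 0.75), 0.03)
  expect_lt(abs(mean(replicate(12, {
    mean(calibrate_threshold(obs, design_config())$delta_cal)
  })) - 2 * qnorm(0.75)), 0.25)

  extreme <- observer_params(criterion = 8, lapse_rate = 0)
  set.seed(7)
  expect_error(calibrate_threshold(extreme, design_config()),
               "calibration failed")
})

test_that("cohort generation is deterministic and carries ground truth", {
  cfg <- design_config(n_subjects_per_experiment = 1, n_main_blocks = 2,
                       trials_per_block = 24,
                       trials_per_modality_per_block = 8)
  a <- simulate_cohort(cfg, master_seed = 9)
  b <- simulate_cohort(cfg, master_seed = 9)
  expect_identical(a$trials, b$trials)
  expect_identical(a$observers, b$observers)
  c2 <- simulate_cohort(cfg, master_seed = 10)
  expect_false(identical(a$trials$response, c2$trials$response))

  expect_equal(dplyr::n_distinct(a$trials$subject_id), 4)
  main <- a$trials[a$trials$block_type %in% c("expect_early", "expect_late"), ]
  expect_equal(nrow(main), 4 * 2 * 24)
  expect_setequal(a$observers$subject_id, unique(a$trials$subject_id))
  # practice trials present and flagged
  expect_true(all(c("training", "threshold") %in% a$trials$block_type))
  # correctness flag consistent with response vs direction
  got <- main$correct
  expect_equal(got, main$response == main$target_direction)
})
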