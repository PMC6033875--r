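test_that("2AFC d-prime matches the quantile-function oracle", {
  # symmetric rates: zero sensitivity
  expect_equal(dprime_2afc(10, 20, 10, 20, correction = "none"), 0)
  # raw rates 0.8 / 0.2 without correction
  expect_equal(dprime_2afc(16, 20, 4, 20, correction = "none"),
               (qnorm(0.8) - qnorm(0.2)) / sqrt(2), tolerance = 1e-12)
  # perfect cell with log-linear correction
  expect_equal(dprime_2afc(10, 10, 0, 10, correction = "loglinear"),
               (qnorm(10.5 / 11) - qnorm(0.5 / 11)) / sqrt(2),
               tolerance = 1e-12)
  # clamp correction bounds rates away from 0/1
  expect_equal(dprime_2afc(10, 10, 0, 10, correction = "clamp"),
               (qnorm(1 - 1 / 20) - qnorm(1 / 20)) / sqrt(2),
               tolerance = 1e-12)
  expect_error(dprime_2afc(1, 0, 1, 10), "positive")
  expect_error(dprime_2afc(11, 10, 0, 10), "counts")
})

test_that("d-prime is antisymmetric and monotone in hits", {
  set.seed(2)
  for (i in 1:25) {
    nh <- sample(5:40, 1); nl <- sample(5:40, 1)
    h <- sample(0:nh, 1); f <- sample(0:nl, 1)
    d <- dprime_2afc(h, nh, f, nl)
    # swapping the roles of higher/lower targets negates d'
    expect_equal(dprime_2afc(f, nl, h, nh), -d, tolerance = 1e-12)
  }
  nh <- 30; nl <- 30; f <- 7
  ds <- vapply(0:nh, function(h) dprime_2afc(h, nh, f, nl), 1)
  expect_true(all(diff(ds) > 0))
})

test_that("condition scoring composes counts and d-prime correctly", {
  # handcrafted 8-trial cell: 3/4 hits, 1/4 false alarms
  rows <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    dir <- if (i <= 4) "higher" else "lower"
    resp <- if (i <= 3 || i == 5) "higher" else "lower"
    mk_trial(trial_index = i, target_direction = dir, response = resp)
  }))
  sc <- score_conditions(rows)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$n_hits, 3)
  expect_equal(sc$n_fa, 1)
  expect_equal(sc$te_state, "expected")
  expect_equal(sc$dprime, dprime_2afc(3, 4, 1, 4))
  expect_true(sc$low_n == FALSE)

  # expectation state derives from block type x position
  late_rows <- dplyr::bind_rows(purrr::map(1:4, function(i)
    mk_trial(trial_index = i, block_type = "expect_late",
             target_direction = c("higher", "lower")[1 + i %% 2])))
  sc2 <- score_conditions(late_rows)
  expect_equal(sc2$te_state, "unexpected")
})

test_that("two-step best-modality selection follows dominance then averages", {
  # split dominance, A wins on average: (1.5, 0.9) vs (1.2, 1.1)
  sc <- mk_scores(d_a = c(1.5, 0.9), d_v = c(1.2, 1.1))
  sel <- select_best_unisensory(sc, "dprime")
  expect_equal(sel$best_modality, "A")
  expect_equal(sel$resolved_by, "average")

  # dominance in both cells
  sc2 <- mk_scores(d_a = c(1.5, 1.2), d_v = c(1.0, 0.9))
  sel2 <- select_best_unisensory(sc2, "dprime")
  expect_equal(sel2$best_modality, "A")
  expect_equal(sel2$resolved_by, "dominance")

  # RT is minimised: A (1400, 1500) vs V (1300, 1700) -> means 1450 vs 1500
  sc3 <- mk_scores(rt_a = c(1400, 1500), rt_v = c(1300, 1700))
  sel3 <- select_best_unisensory(sc3, "rt")
  expect_equal(sel3$best_modality, "A")
  expect_equal(sel3$resolved_by, "average")

  # exact tie: deterministic tie-break to A, flagged
  sc4 <- mk_scores(d_a = c(1.2, 1.0), d_v = c(1.0, 1.2))
  sel4 <- select_best_unisensory(sc4, "dprime")
  expect_equal(sel4$best_modality, "A")
  expect_true(sel4$tie)
})

test_that("two-step selection matches a brute-force oracle over a value grid", {
  oracle <- function(a, v) {
    if (all(a > v)) return("A")
    if (all(v > a)) return("V")
    if (mean(a) > mean(v)) "A" else if (mean(v) > mean(a)) "V" else "A"
  }
  vals <- c(0.8, 1.0, 1.2)
  grid <- expand.grid(ae = vals, au = vals, ve = vals, vu = vals)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sc <- mk_scores(d_a = c(g$ae, g$au), d_v = c(g$ve, g$vu))
    sel <- select_best_unisensory(sc, "dprime")
    expect_equal(sel$best_modality, oracle(c(g$ae, g$au), c(g$ve, g$vu)))
  }
})

test_that("preference labels combine the two measures", {
  expect_equal(preference_label("A", "A"), "auditory")
  expect_equal(preference_label("V", "V"), "visual")
  expect_equal(preference_label("A", "V"), "mixed")
  expect_equal(preference_label(c("A", "V"), c("A", "A")),
               c("auditory", "mixed"))
})

test_that("MSF records implement the facilitation sign conventions", {
  # subject 1: best_d = V (split, means 1.0 vs 1.1), best_rt = A (split,
  # means 1450 vs 1465) -> mixed preference
  sc <- dplyr::bind_rows(
    mk_scores("s1"),
    mk_scores("s2", d_a = c(1.5, 1.2), d_v = c(1.0, 0.9),
              rt_a = c(1300, 1350), rt_v = c(1500, 1520))
  )
  freq <- tibble::tibble(subject_id = c("s1", "s2"),
                         freq_a = c(1.2, 1.4), freq_v = c(1.0, 1.2))
  msf <- build_msf_records(sc, freq)
  expect_equal(nrow(msf), 4)

  s1 <- msf[msf$subject_id == "s1", ]
  expect_equal(s1$preference_label, rep("mixed", 2))
  e1 <- s1[s1$te_state == "expected", ]
  # msf_d: AV 1.4 minus best-modality (V) expected cell 1.0
  expect_equal(e1$msf_d, 0.4)
  # msf_rt: best-RT modality (A) expected 1400 minus AV 1380
  expect_equal(e1$msf_rt, 20)
  expect_equal(e1$unidiff_d, 0.1)
  u1 <- s1[s1$te_state == "unexpected", ]
  expect_equal(u1$msf_d, 1.3 - 1.2)
  expect_equal(u1$msf_rt, 1500 - 1400)
  expect_equal(u1$unidiff_d, 0.3, tolerance = 1e-12)

  # unidiff is never negative
  expect_true(all(msf$unidiff_d >= 0))
  expect_true(all(msf$unidiff_rt >= 0))
  # frequency covariates normalised by their grand means
  expect_equal(msf$freq_a_norm[msf$subject_id == "s1"][1], 1.2 / 1.3)
  expect_equal(msf$freq_v_norm[msf$subject_id == "s2"][1], 1.2 / 1.1)

  # subjects with incomplete cells are dropped with a message
  sc_inc <- dplyr::bind_rows(sc, mk_scores("s3")[1:4, ])
  freq3 <- dplyr::bind_rows(freq, tibble::tibble(
    subject_id = "s3", freq_a = 1, freq_v = 1))
  expect_message(msf2 <- build_msf_records(sc_inc, freq3), "incomplete")
  expect_false("s3" %in% msf2$subject_id)
})

test_that("cohorts with an expectation gain show the d-prime benefit", {
  cohort <- small_cohort()
  trials <- apply_filters(annotate_previous_trial(cohort$trials))
  sc <- score_conditions(trials)
  agg <- tapply(sc$dprime, sc$te_state, mean)
  expect_gt(agg["expected"], agg["unexpected"])
})
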