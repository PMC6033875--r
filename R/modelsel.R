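msf_predictor_cols <- c("SpU", "TaU", "TE", "FreqA", "FreqV",
                        "PrefA", "PrefV", "UniDiff")

#' Build the predictor matrix for MSF modelling
#'
#' One row per subject x expectation cell, with the outcome (`msf_d` or
#' `msf_rt`) and the eight predictors in fixed, documented order:
#' `SpU` (1 = high spatial uncertainty), `TaU` (1 = high target
#' uncertainty), `TE` (1 = temporally unexpected), `FreqA` / `FreqV`
#' (normalised calibrated target frequencies), `PrefA` / `PrefV` (indicator
#' coding of the three-level modality-preference label; both 0 for mixed),
#' and `UniDiff` (measure-matched unisensory difference, max - min). The
#' two-indicator preference coding is what yields exactly eight predictors
#' and hence 255 candidate subsets.
#'
#' @param msf A [build_msf_records()] table with no missing values.
#' @param measure `"dprime"` or `"rt"`; selects the outcome and the
#'   measure-matched `UniDiff`.
#' @return A tibble with columns `subject_id`, `te_state`, `y` and the eight
#'   predictors; attribute `"measure"` records the choice.
#' @export
build_predictor_matrix <- function(msf, measure = c("dprime", "rt")) {
  measure <- match.arg(measure)
  need <- c("subject_id", "te_state", "spatial_uncertainty",
            "target_uncertainty", "preference_label", "msf_d", "msf_rt",
            "unidiff_d", "unidiff_rt", "freq_a_norm", "freq_v_norm")
  missing_cols <- setdiff(need, names(msf))
  if (length(missing_cols) > 0)
    stop("msf table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyNA(msf[, need])) {
    bad <- unique(msf$subject_id[!stats::complete.cases(msf[, need])])
    stop("missing predictor values for subject(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = msf$subject_id,
    te_state = msf$te_state,
    y = if (measure == "dprime") msf$msf_d else msf$msf_rt,
    SpU = as.integer(msf$spatial_uncertainty == "high"),
    TaU = as.integer(msf$target_uncertainty == "high"),
    TE = as.integer(msf$te_state == "unexpected"),
    FreqA = msf$freq_a_norm,
    FreqV = msf$freq_v_norm,
    PrefA = as.integer(msf$preference_label == "auditory"),
    PrefV = as.integer(msf$preference_label == "visual"),
    UniDiff = if (measure == "dprime") msf$unidiff_d else msf$unidiff_rt
  )
  attr(out, "measure") <- measure
  out
}

#' Enumerate all non-empty predictor subsets
#'
#' Canonical order: subsets are indexed 1 to `2^n - 1`; predictor `j` is in
#' subset `i` iff bit `j` of `i` is set. With eight predictors this yields
#' the 255 candidate models.
#'
#' @param n_predictors Number of predictors (>= 1).
#' @return A logical matrix, one row per subset.
#' @export
enumerate_subsets <- function(n_predictors) {
  n_predictors <- as.integer(n_predictors)
  if (is.na(n_predictors) || n_predictors < 1)
    stop("n_predictors must be >= 1", call. = FALSE)
  ids <- seq_len(2^n_predictors - 1)
  masks <- vapply(seq_len(n_predictors),
                  function(j) bitwAnd(ids, bitwShiftL(1L, j - 1L)) > 0,
                  logical(length(ids)))
  matrix(masks, nrow = length(ids), ncol = n_predictors,
         dimnames = list(NULL, NULL))
}

# design matrix (with intercept) for a mask over the predictor columns
pm_design <- function(pm, mask) {
  preds <- msf_predictor_cols[mask]
  X <- cbind(`(Intercept)` = 1, as.matrix(pm[, preds, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Leave-one-out cross-validated RMSE of one predictor subset
#'
#' Ordinary least squares with intercept; each observation is predicted by
#' the model fit to the remaining N-1 rows. Held-out residuals are obtained
#' through the exact hat-matrix identity `e_i / (1 - h_ii)`, which equals
#' refitting every fold (verified against a naive per-fold refit in the test
#' suite).
#'
#' @param pm A [build_predictor_matrix()] tibble.
#' @param mask Logical vector over the eight predictors (or a subset-row
#'   from [enumerate_subsets()]).
#' @return A list: `rmse`, `predictions` (held-out), `mask`.
#' @export
loocv_model <- function(pm, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask must include at least one predictor",
                       call. = FALSE)
  X <- pm_design(pm, mask)
  y <- pm$y
  if (nrow(X) <= ncol(X) + 1)
    stop("too few rows (", nrow(X), ") for ", ncol(X) - 1, " predictors",
         call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient design for mask [",
         paste(msf_predictor_cols[mask], collapse = ", "), "]",
         call. = FALSE)
  res <- qr.resid(qr_x, y)
  h <- rowSums(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10))
    stop("leverage ~1 in a fold for mask [",
         paste(msf_predictor_cols[mask], collapse = ", "),
         "]: a training fold is rank-deficient", call. = FALSE)
  press <- res / (1 - h)
  list(rmse = sqrt(mean(press^2)), predictions = y - press, mask = mask)
}

named_model_masks <- function() {
  mk <- function(preds) msf_predictor_cols %in% preds
  list(
    physical = mk(c("SpU", "TaU", "TE", "FreqA", "FreqV")),
    individual = mk(c("PrefA", "PrefV")),
    uni_perf = mk("UniDiff"),
    full = rep(TRUE, length(msf_predictor_cols))
  )
}

#' Rank all 255 candidate models by cross-validated error
#'
#' Runs [loocv_model()] for every non-empty predictor subset, ranks models
#' by ascending RMSE (ties broken by smaller subset, then canonical order),
#' and computes Spearman correlations between held-out predictions and
#' observations (average-rank ties; p by the t approximation). Bonferroni
#' correction is applied over the family of reported correlations (the
#' best, physical, individual, unisensory-performance and full models;
#' `family_m = 5` by default).
#'
#' @param pm A [build_predictor_matrix()] tibble.
#' @param family_m Bonferroni family size for the reported correlations.
#' @param on_singular What to do when a subset's design is rank-deficient
#'   (e.g. a preference indicator that is constant in a small cohort):
#'   `"error"` (default) propagates the fold error with the mask,
#'   `"drop"` assigns the model infinite RMSE so it ranks last, flagged by
#'   `singular = TRUE`.
#' @return An object of class `"temsf_modelsel"`: `tidy()` gives the full
#'   255-row model table, `glance()` the best model's summary; element
#'   `named` holds the five reported models.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(design_config(n_subjects_per_experiment = 4),
#'                           master_seed = 1)
#' trials <- apply_filters(annotate_previous_trial(cohort$trials))
#' msf <- build_msf_records(score_conditions(trials), cohort$observers)
#' sel <- rank_models(build_predictor_matrix(msf, "dprime"))
#' glance(sel)
#' }
#' @export
rank_models <- function(pm, family_m = 5L,
                        on_singular = c("error", "drop")) {
  on_singular <- match.arg(on_singular)
  masks <- enumerate_subsets(length(msf_predictor_cols))
  n <- nrow(pm)
  fits <- purrr::map(seq_len(nrow(masks)), function(i) {
    if (on_singular == "error") return(loocv_model(pm, masks[i, ]))
    tryCatch(loocv_model(pm, masks[i, ]),
             error = function(e) list(rmse = Inf,
                                      predictions = rep(NA_real_, n),
                                      mask = masks[i, ], singular = TRUE))
  })
  singular <- vapply(fits, function(f) isTRUE(f$singular), TRUE)
  rho <- vapply(fits, function(f)
    if (anyNA(f$predictions)) NA_real_
    else stats::cor(f$predictions, pm$y, method = "spearman"), 1)
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  models <- tibble::tibble(
    model_id = seq_len(nrow(masks)),
    predictors = vapply(seq_len(nrow(masks)), function(i)
      paste(msf_predictor_cols[masks[i, ]], collapse = "+"), ""),
    k = rowSums(masks),
    rmse = vapply(fits, function(f) f$rmse, 1),
    rho = rho,
    p_raw = p_raw,
    p_bonf = pmin(1, family_m * p_raw),
    singular = singular
  )
  models$rank <- rank_with_ties(models$rmse, models$k, models$model_id)

  named_masks <- named_model_masks()
  mask_id <- function(mask) sum(bitwShiftL(1L, which(mask) - 1L))
  named <- dplyr::bind_rows(
    models[models$rank == 1, ] |> dplyr::mutate(model = "best"),
    purrr::imap_dfr(named_masks, function(mask, nm)
      models[models$model_id == mask_id(mask), ] |>
        dplyr::mutate(model = nm))
  ) |>
    dplyr::select("model", dplyr::everything())

  out <- list(models = models[order(models$rank), ], named = named,
              masks = masks, pm = pm, family_m = family_m,
              measure = attr(pm, "measure"))
  class(out) <- "temsf_modelsel"
  out
}

# deterministic ranking: rmse ascending, ties by fewer predictors, then
# canonical subset order
rank_with_ties <- function(rmse, k, id) {
  ord <- order(rmse, k, id)
  rk <- integer(length(rmse))
  rk[ord] <- seq_along(ord)
  rk
}

#' @export
print.temsf_modelsel <- function(x, ...) {
  cat("<temsf_modelsel>", nrow(x$models), "models,", nrow(x$pm),
      "data points (measure:", x$measure, ")\n")
  print(as.data.frame(utils::head(x$models, 5)), digits = 4)
  cat("named models:\n")
  print(as.data.frame(x$named[, c("model", "rank", "rmse", "rho", "p_bonf")]),
        digits = 4)
  invisible(x)
}

#' @rdname rank_models
#' @param x A `temsf_modelsel` object.
#' @param ... Unused.
#' @export
tidy.temsf_modelsel <- function(x, ...) x$models

#' @rdname rank_models
#' @export
glance.temsf_modelsel <- function(x, ...) {
  best <- x$models[x$models$rank == 1, ]
  tibble::tibble(
    measure = x$measure,
    n = nrow(x$pm),
    n_models = nrow(x$models),
    best_predictors = best$predictors,
    best_rmse = best$rmse,
    best_rho = best$rho,
    best_p_bonf = best$p_bonf
  )
}

#' Coefficients and per-predictor PRE of a selected model
#'
#' Full-data OLS fit of one predictor subset, with the Proportionate
#' Reduction of Error of each included predictor:
#' `PRE = (SSE_without - SSE_with) / SSE_without`, where the reduced model
#' drops that single predictor while keeping the intercept and all others.
#'
#' @param pm A [build_predictor_matrix()] tibble.
#' @param mask Logical vector over the eight predictors, e.g. the best
#'   model's subset from [rank_models()].
#' @param kappa_threshold Condition-number threshold above which a
#'   collinearity warning (with variance inflation factors) is emitted.
#' @return A tibble, one row per term (intercept first): `beta`, `se`, `t`,
#'   `p`, `pre` (`NA` for the intercept).
#' @export
fit_best_model <- function(pm, mask, kappa_threshold = 100) {
  mask <- as.logical(mask)
  X <- pm_design(pm, mask)
  y <- pm$y
  if (kappa(X, exact = TRUE) > kappa_threshold) {
    vif <- tryCatch({
      Xp <- X[, -1, drop = FALSE]
      vapply(seq_len(ncol(Xp)), function(j) {
        r2 <- summary(stats::lm(Xp[, j] ~ Xp[, -j, drop = FALSE]))$r.squared
        1 / (1 - r2)
      }, 1)
    }, error = function(e) NULL)
    warning("ill-conditioned design (kappa > ", kappa_threshold, "); VIF: ",
            paste(round(vif, 1), collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  sse <- sum(fit$residuals^2)
  dof <- nrow(X) - ncol(X)
  sigma2 <- sse / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(xtx_inv) * sigma2)
  t_stat <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(t_stat), dof)
  pre <- c(NA_real_, vapply(which(mask), function(j) {
    sub <- mask
    sub[j] <- FALSE
    X0 <- pm_design(pm, sub)
    sse0 <- sum(stats::lm.fit(X0, y)$residuals^2)
    (sse0 - sse) / sse0
  }, 1))
  tibble::tibble(
    term = colnames(X),
    beta = unname(fit$coefficients),
    se = unname(se),
    t = unname(t_stat),
    p = unname(p),
    pre = pre
  )
}
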