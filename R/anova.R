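#' Balanced mixed repeated-measures ANOVA
#'
#' Full sum-of-squares decomposition for a balanced design with crossed
#' within-subject factors and crossed between-subject factors (subjects
#' nested in the between-cells). Every main effect and interaction is
#' reported with its F ratio against the matching subject-level error
#' stratum, plus two effect sizes: generalized eta squared
#' `ges = SS_effect / (SS_effect + sum of all subject-level error SS)` and
#' partial eta squared `eta2 = SS_effect / (SS_effect + SS_error_of_effect)`.
#'
#' Implementation note: sums of squares are computed directly from marginal
#' cell totals by Moebius inclusion-exclusion, which for balanced designs is
#' exact and auditable; with a single within factor and no between factors
#' the F statistic reduces to the paired-t squared. Sphericity is moot for
#' two-level within factors.
#'
#' @param data Long tibble, one row per subject x within-cell.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns.
#' @param between Character vector of between-subject factor columns (may be
#'   empty).
#' @param subject Name of the subject identifier column.
#' @param allow_unbalanced Permit unequal between-group sizes, analysed by
#'   unweighted means (harmonic-mean cell size) and flagged approximate.
#' @return An object of class `"temsf_anova"`; `tidy()` returns the effect
#'   table, `glance()` the design summary.
#' @examples
#' d <- tidyr::expand_grid(subject = factor(1:6), w = c("a", "b"))
#' d$y <- rnorm(12) + (d$w == "b") * 0.5
#' fit <- mixed_anova(d, "y", within = "w", subject = "subject")
#' tidy(fit)
#' @export
mixed_anova <- function(data, dv, within, between = character(),
                        subject = "subject_id", allow_unbalanced = FALSE) {
  cols <- c(dv, within, between, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- data[, cols]
  names(df) <- c(".y", within, between, ".subj")
  df$.subj <- as.character(df$.subj)
  if (nrow(df) == 0) stop("no observations to analyse", call. = FALSE)
  if (anyNA(df$.y)) stop("dv contains missing values", call. = FALSE)

  w_levels <- lapply(within, function(f) sort(unique(df[[f]])))
  names(w_levels) <- within
  n_wcells <- prod(vapply(w_levels, length, 1L))

  # completeness: every subject exactly one row per within-cell
  cell_counts <- df |>
    dplyr::count(.data$.subj, dplyr::across(dplyr::all_of(within)))
  per_subj <- dplyr::count(cell_counts, .data$.subj)
  if (any(cell_counts$n != 1L) || any(per_subj$n != n_wcells))
    stop("design incomplete: every subject needs exactly one observation ",
         "per within-cell", call. = FALSE)

  # subjects nested in between cells
  subj_tab <- df |>
    dplyr::distinct(.data$.subj, dplyr::across(dplyr::all_of(between)))
  if (anyDuplicated(subj_tab$.subj) > 0)
    stop("a subject appears in more than one between-group", call. = FALSE)
  n_subj <- nrow(subj_tab)
  if (length(between) > 0) {
    gsize <- subj_tab |> dplyr::count(dplyr::across(dplyr::all_of(between)))
    n_groups <- nrow(gsize)
    balanced <- length(unique(gsize$n)) == 1
    if (!balanced && !allow_unbalanced)
      stop("unequal between-group sizes; set allow_unbalanced = TRUE for an ",
           "unweighted-means analysis", call. = FALSE)
  } else {
    n_groups <- 1L
    balanced <- TRUE
  }

  b_levels <- lapply(between, function(f) sort(unique(df[[f]])))
  names(b_levels) <- between

  # harmonic-mean group size drives the unweighted-means approximation
  n_h <- if (!balanced) 1 / mean(1 / gsize$n) else NA_real_

  # R(S): sum over cells of S of total^2 / cellsize (balanced designs);
  # S is a character vector of factor columns, ".subj" allowed. Error
  # strata always use raw totals (raw = TRUE); under unweighted means the
  # fixed-effect marginals use cell means at the effective cell size.
  N <- nrow(df)
  R_of <- function(S, raw = FALSE) {
    if (length(S) == 0) {
      if (balanced || raw) return(sum(df$.y)^2 / N)
      S <- character(0)
    }
    if (length(S) == 0 && !balanced && !raw)
      return(mean(df$.y)^2 * n_h * n_groups * n_wcells)
    agg <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(S))) |>
      dplyr::summarise(.tot = sum(.data$.y), .n = dplyr::n(),
                       .groups = "drop")
    if (!balanced && !raw && !".subj" %in% S) {
      eff_cell <- n_h * n_groups * n_wcells / nrow(agg)
      return(sum((agg$.tot / agg$.n)^2) * eff_cell)
    }
    sum(agg$.tot^2 / agg$.n)
  }

  subsets <- function(x) {
    out <- list(character(0))
    for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
    out
  }
  ss_term <- function(term) {
    ss <- 0
    for (S in subsets(term))
      ss <- ss + (-1)^(length(term) - length(S)) * R_of(S)
    max(ss, 0)
  }
  df_term <- function(term) {
    lev <- c(w_levels, b_levels)
    prod(vapply(term, function(f) length(lev[[f]]) - 1L, 1L))
  }

  # error strata: Err(V) for each subset V of the within factors
  w_subsets <- subsets(within)
  err <- purrr::map(w_subsets, function(V) {
    ss <- 0
    for (Vp in subsets(V)) {
      sgn <- (-1)^(length(V) - length(Vp))
      ss <- ss + sgn * (R_of(c(Vp, ".subj"), raw = TRUE) -
                          R_of(c(Vp, between), raw = TRUE))
    }
    list(within = V,
         ss = max(ss, 0),
         df = df_term(V) * (n_subj - n_groups))
  })
  stratum_key <- function(V)
    if (length(V) == 0) ".between" else paste(sort(V), collapse = ":")
  names(err) <- vapply(w_subsets, stratum_key, "")
  total_err_ss <- sum(vapply(err, function(e) e$ss, 1))

  # effect terms: between subsets (nonempty) and within x between products
  terms <- list()
  for (B in subsets(between)) {
    for (V in w_subsets) {
      if (length(B) == 0 && length(V) == 0) next
      terms <- c(terms, list(list(w = V, b = B)))
    }
  }
  rows <- purrr::map_dfr(terms, function(tm) {
    term <- c(tm$w, tm$b)
    ss <- ss_term(term)
    stratum <- err[[stratum_key(tm$w)]]
    dfn <- df_term(term)
    Fv <- if (ss <= 0) 0 else (ss / dfn) / (stratum$ss / stratum$df)
    tibble::tibble(
      effect = paste(term, collapse = ":"),
      SS_effect = ss,
      SS_error = stratum$ss,
      df_num = dfn,
      df_den = stratum$df,
      F = Fv,
      p = stats::pf(Fv, dfn, stratum$df, lower.tail = FALSE),
      ges = if (ss <= 0) 0 else ss / (ss + total_err_ss),
      eta2 = if (ss <= 0) 0 else ss / (ss + stratum$ss)
    )
  })

  out <- list(
    table = rows,
    strata = tibble::tibble(
      stratum = names(err),
      SS = vapply(err, function(e) e$ss, 1),
      df = vapply(err, function(e) e$df, 1)
    ),
    dv = dv, within = within, between = between,
    n_subjects = n_subj, n_groups = n_groups,
    balanced = balanced,
    eta2_type = "partial",
    note = if (!balanced) "unweighted-means (harmonic n) approximation"
           else NA_character_
  )
  class(out) <- "temsf_anova"
  out
}

#' @export
print.temsf_anova <- function(x, ...) {
  cat("<temsf_anova> dv =", x$dv, "\n")
  cat("  within:", paste(x$within, collapse = ", "),
      if (length(x$between)) paste("| between:",
                                   paste(x$between, collapse = ", ")), "\n")
  cat(sprintf("  %d subjects in %d group(s)%s\n", x$n_subjects, x$n_groups,
              if (!x$balanced) " [unweighted means]" else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname mixed_anova
#' @param x A `temsf_anova` object.
#' @param ... Unused.
#' @export
tidy.temsf_anova <- function(x, ...) x$table

#' @rdname mixed_anova
#' @export
glance.temsf_anova <- function(x, ...) {
  tibble::tibble(
    dv = x$dv,
    n_subjects = x$n_subjects,
    n_groups = x$n_groups,
    n_effects = nrow(x$table),
    balanced = x$balanced
  )
}

#' Bonferroni-corrected paired comparison
#'
#' Paired t test with Cohen's d for repeated measures
#' (`d = mean(diff) / sd(diff)`) and Bonferroni correction over a family of
#' `m` comparisons. A Jeffreys-Zellner-Siow Bayes factor in favour of the
#' null is attached for non-significant raw p-values (an approximation to
#' standard defaults; see [bf_h0_paired()]).
#'
#' @param x,y Paired numeric vectors (equal length >= 2).
#' @param m Family size for the Bonferroni correction.
#' @param label Contrast name carried into the output.
#' @param bf_threshold Attach `bf_h0` when `p_raw` exceeds this.
#' @return One-row tibble: `contrast`, `t`, `df`, `p_raw`, `p_bonf`,
#'   `cohens_d`, `bf_h0`.
#' @export
posthoc_paired <- function(x, y, m = 1L, label = "contrast",
                           bf_threshold = 0.05) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of equal length >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))   # identical vectors: a well-defined null result
      return(tibble::tibble(contrast = label, t = 0, df = length(x) - 1,
                            p_raw = 1, p_bonf = 1, cohens_d = 0,
                            bf_h0 = bf_h0_paired(0, length(x))))
    stop("degenerate contrast: difference has zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  p_raw <- tt$p.value
  t_stat <- unname(tt$statistic)
  bf <- if (p_raw > bf_threshold) bf_h0_paired(t_stat, length(x)) else NA_real_
  tibble::tibble(
    contrast = label,
    t = t_stat,
    df = unname(tt$parameter),
    p_raw = p_raw,
    p_bonf = min(1, m * p_raw),
    cohens_d = mean(d) / stats::sd(d),
    bf_h0 = bf
  )
}

#' JZS Bayes factor in favour of the null for a paired t statistic
#'
#' One-sample (paired) Jeffreys-Zellner-Siow Bayes factor with a Cauchy
#' prior of scale `r` on the standardised effect size, computed by
#' one-dimensional numerical integration over the mixing variance. Returned
#' as evidence for H0 (`BF_H0 = 1 / BF_10`). This is an approximation to
#' common software defaults and is not guaranteed to match their printed
#' values to all digits.
#'
#' @param t Observed paired t statistic.
#' @param n Number of pairs (>= 2).
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param rel.tol Relative tolerance of the quadrature.
#' @return `BF_H0` as a single number.
#' @examples
#' bf_h0_paired(0, 80)    # > 1: data favour the null
#' @export
bf_h0_paired <- function(t, n, r = sqrt(2) / 2, rel.tol = 1e-10) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  nu <- n - 1
  null_dens <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    a <- 1 + n * g * r^2
    a^(-1 / 2) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel.tol,
                     subdivisions = 500L),
    error = function(e) stop("JZS integration failed: ", conditionMessage(e),
                             " (t = ", t, ", n = ", n, ")", call. = FALSE))
  null_dens / alt$value
}
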