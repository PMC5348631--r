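#' Fit the discounting model for every subject and condition
#'
#' Runs [fit_mle()] separately on each subject's control, familiar and
#' unfamiliar trials, plus a pooled `tag` fit on the concatenated familiar
#' and unfamiliar trials (a single likelihood over all tagged trials, not
#' an average of two fits).  Subjects whose fit fails to converge are
#' retained and flagged.
#'
#' @param choices Trial tibble with columns `subject_id`, `condition`,
#'   `delay_days`, `amount_eur`, `choice`.
#' @param ref Immediate reference amount in euros (default 20).
#' @param ... Further arguments passed to [fit_mle()] (bounds, grid, clip).
#' @return Tibble with one row per subject x condition
#'   (`control`, `familiar`, `unfamiliar`, `tag`): `k`, `beta`, `sqrt_k`,
#'   `nll`, `n_trials`, `converged`, `boundary`.
#' @export
fit_all_subjects <- function(choices, ref = 20, ...) {
  if (!"subject_id" %in% names(choices)) {
    stop("`choices` needs a `subject_id` column", call. = FALSE)
  }
  check_choice_trials(choices)
  fit_row <- function(trials, cond) {
    trials$condition <- NULL  # pooled fits mix labels by design
    f <- withCallingHandlers(
      fit_mle(trials, ref = ref, keep_data = FALSE, ...),
      warning = function(w) invokeRestart("muffleWarning")
    )
    tibble::tibble(condition = cond, k = f$k, beta = f$beta,
                   sqrt_k = f$sqrt_k, nll = f$nll, n_trials = f$n_trials,
                   converged = f$converged, boundary = f$boundary)
  }
  choices |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      per_cond <- purrr::map_dfr(tag_conditions(), function(cond) {
        fit_row(df[df$condition == cond, ], cond)
      })
      pooled <- fit_row(df[df$condition %in% c("familiar", "unfamiliar"), ],
                        "tag")
      dplyr::bind_rows(per_cond, pooled)
    }) |>
    dplyr::ungroup()
}

#' Median/IQR summary table of fitted parameters
#'
#' The cohort-level descriptive table: medians and inter-quartile ranges of
#' the single-subject `k` and `beta` estimates (and, when an `rt_ms` source
#' is supplied, of median RTs) for the control, pooled tag, familiar and
#' unfamiliar conditions.
#'
#' @param fits Output of [fit_all_subjects()].
#' @param choices Optional trial tibble with `rt_ms` to add RT summaries
#'   (the pooled-tag row uses familiar+unfamiliar trials).
#' @return Tibble with one row per condition: `condition`, `k_median`,
#'   `k_iqr`, `beta_median`, `beta_iqr` (and `rt_median`, `rt_iqr`).
#' @export
discount_summary_table <- function(fits, choices = NULL) {
  conds <- c("control", "tag", "familiar", "unfamiliar")
  out <- fits |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      k_median = stats::median(.data$k),
      k_iqr = stats::IQR(.data$k),
      beta_median = stats::median(.data$beta),
      beta_iqr = stats::IQR(.data$beta),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$condition, conds))
  if (!is.null(choices) && "rt_ms" %in% names(choices)) {
    rt_for <- function(cond) {
      rows <- if (cond == "tag") {
        choices[choices$condition %in% c("familiar", "unfamiliar"), ]
      } else choices[choices$condition == cond, ]
      per_subj <- tapply(rows$rt_ms, rows$subject_id,
                         stats::median, na.rm = TRUE)
      c(stats::median(per_subj), stats::IQR(per_subj))
    }
    rt <- vapply(out$condition, rt_for, numeric(2))
    out$rt_median <- rt[1, ]
    out$rt_iqr <- rt[2, ]
  }
  out
}

#' Per-subject episodic-tag effect
#'
#' The change in (square-root-transformed) discounting attributable to the
#' episodic tag: `delta = sqrt_k(tag pooled) - sqrt_k(control)`.  Negative
#' values mean the subject discounted less when choices carried an episodic
#' tag.
#'
#' @param fits Output of [fit_all_subjects()] (needs `control` and `tag`
#'   rows per subject).
#' @return Tibble: `subject_id`, `sqrt_k_control`, `sqrt_k_tag`,
#'   `delta_sqrt_k`.
#' @export
tag_effect <- function(fits) {
  wide <- fits |>
    dplyr::filter(.data$condition %in% c("control", "tag")) |>
    dplyr::select("subject_id", "condition", "sqrt_k") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "sqrt_k",
                       names_prefix = "sqrt_k_")
  dplyr::mutate(wide, delta_sqrt_k = .data$sqrt_k_tag - .data$sqrt_k_control)
}

# Greenhouse-Geisser epsilon from the subjects x conditions matrix.
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  p <- ncol(S)
  dbar <- mean(diag(S))
  gbar <- mean(S)
  num <- (p * (dbar - gbar))^2
  den <- (p - 1) * (sum(S^2) - 2 * p * sum(rowMeans(S)^2) + p^2 * gbar^2)
  num / den
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F-test of a condition effect on a per-subject measure
#' (here, `sqrt(k)` across the three discounting conditions), computed from
#' the standard within-subject error stratum
#' (`aov(value ~ condition + Error(subject))`): condition df = p - 1, error
#' df = (p - 1)(n - 1).  An optional Greenhouse-Geisser correction rescales
#' both dfs by the sphericity epsilon before the p-value is evaluated.
#'
#' @param data Long tibble with one row per subject x condition.
#' @param value,condition,subject Column names (unquoted) of the measure,
#'   the within-subject factor and the subject identifier.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return One-row tibble: `term`, `statistic` (F), `df1`, `df2`,
#'   `p.value`, `epsilon`, `method`.
#' @examples
#' d <- tidyr::expand_grid(subject = letters[1:6],
#'                         condition = tag_conditions())
#' d$y <- stats::rnorm(nrow(d))
#' rm_anova(d, y, condition, subject)
#' @export
rm_anova <- function(data, value, condition, subject,
                     correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  df <- tibble::tibble(
    value = dplyr::pull(data, {{ value }}),
    condition = factor(dplyr::pull(data, {{ condition }})),
    subject = factor(dplyr::pull(data, {{ subject }}))
  )
  if (any(is.na(df$value))) stop("missing cells in the design", call. = FALSE)
  tab <- table(df$subject, df$condition)
  if (any(tab != 1)) {
    stop("design must be complete: one observation per subject x condition",
         call. = FALSE)
  }
  if (nlevels(df$subject) < 3) stop("need at least 3 subjects", call. = FALSE)

  fit <- stats::aov(value ~ condition + Error(subject), data = df)
  stratum <- summary(fit)[["Error: Within"]][[1]]
  df1 <- stratum["condition", "Df"]
  df2 <- stratum["Residuals", "Df"]
  ms_cond <- stratum["condition", "Mean Sq"]
  ms_err <- stratum["Residuals", "Mean Sq"]
  # guard against floating-point dust when all cells agree within a subject
  tol <- 1e-10 * (stats::var(df$value) + 1e-300)
  f_stat <- if (ms_err <= tol) {
    if (ms_cond <= tol) 0 else Inf
  } else ms_cond / ms_err

  eps <- 1
  if (correction == "greenhouse-geisser") {
    wide <- tidyr::pivot_wider(df, names_from = "condition",
                               values_from = "value")
    eps <- gg_epsilon(as.matrix(wide[, -1]))
  }
  tibble::tibble(
    term = "condition",
    statistic = f_stat,
    df1 = df1 * eps,
    df2 = df2 * eps,
    p.value = stats::pf(f_stat, df1 * eps, df2 * eps, lower.tail = FALSE),
    epsilon = eps,
    method = paste0("repeated-measures ANOVA",
                    if (correction != "none") " (Greenhouse-Geisser)")
  )
}

#' Paired t-test
#'
#' Standard paired t on the differences `a - b` (df = n - 1), as used for
#' comparing emotional-closeness ratings or detail counts between the two
#' episodic conditions.  Degenerate zero-variance differences are handled
#' explicitly: identical vectors give `t = 0, p = 1`; a constant nonzero
#' difference gives `t = +/-Inf, p = 0`.
#'
#' @param a,b Equal-length paired numeric vectors, `n >= 2`.
#' @return One-row tibble: `estimate` (mean difference), `statistic` (t),
#'   `df`, `p.value`, `method`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
    t_stat <- if (abs(mean(d)) <= 1e-12) 0 else sign(mean(d)) * Inf
    return(tibble::tibble(
      estimate = mean(d), statistic = t_stat, df = n - 1,
      p.value = if (is.finite(t_stat)) 1 else 0,
      method = "paired t-test (zero-variance differences)"
    ))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value,
    method = "paired t-test"
  )
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Correlates the residuals of `x` and `y` after linearly removing the
#' covariates (with intercept) from both — the partial correlation used to
#' relate the singleton attentional-control score to the per-subject tag
#' effect while holding gender fixed.  Significance uses
#' `df = n - 2 - n_covariates`.
#'
#' Constant covariate columns are absorbed by the intercept and dropped (so
#' an all-ones covariate reproduces the plain Pearson correlation exactly);
#' any remaining rank deficiency is an error, as is zero residual variance
#' (e.g. a covariate identical to `x`).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric vector, matrix or data frame of
#'   covariates (factors/characters are expanded to indicators).
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df`,
#'   `p.value`, `n`, `n_covariates`.
#' @export
covariate_adjusted_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    names(cov_df) <- paste0("cov", seq_along(cov_df))
    cov_mat <- stats::model.matrix(~ ., data = cov_df)[, -1, drop = FALSE]
    if (nrow(cov_mat) != n) {
      stop("covariates must have the same number of rows as `x`",
           call. = FALSE)
    }
    keep <- apply(cov_mat, 2, function(col) stats::sd(col) > 0)
    cov_mat <- cov_mat[, keep, drop = FALSE]
    if (ncol(cov_mat) == 0) cov_mat <- NULL
  }
  design <- cbind(intercept = rep(1, n), cov_mat)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("covariates are rank deficient", call. = FALSE)
  }
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300)) {
    stop("zero residual variance after covariate adjustment; ",
         "correlation is undefined", call. = FALSE)
  }
  n_cov <- ncol(design) - 1
  df <- n - 2 - n_cov
  if (df < 1) stop("not enough observations for the requested adjustment",
                   call. = FALSE)
  r <- stats::cor(rx, ry)
  t_stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    estimate = r,
    statistic = t_stat,
    df = df,
    p.value = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
    n = n,
    n_covariates = n_cov
  )
}

#' Cohort-level analysis report
#'
#' Runs the full group pipeline on fitted subject summaries: the
#' repeated-measures condition ANOVA on `sqrt(k)`, the tag effect, and the
#' gender-adjusted correlations of the singleton score with the control
#' discount rate and with the tag effect.
#'
#' @param fits Output of [fit_all_subjects()].
#' @param scores Per-subject tibble with `subject_id`, `singleton_score`,
#'   and `gender` (plus optional covariate columns).
#' @param correction Sphericity correction for the ANOVA (see [rm_anova()]).
#' @return List of class `"tag_analysis"` with elements `anova`,
#'   `tag_effect`, `cor_control`, `cor_tag_effect`, `summary_table`.
#' @export
analyze_cohort <- function(fits, scores,
                           correction = c("none", "greenhouse-geisser")) {
  per_cond <- dplyr::filter(fits, .data$condition %in% tag_conditions())
  anova <- rm_anova(per_cond, sqrt_k, condition, subject_id,
                    correction = correction)
  eff <- tag_effect(fits)
  merged <- dplyr::inner_join(eff, scores, by = "subject_id")
  gender_ind <- as.integer(factor(merged$gender))
  out <- list(
    anova = anova,
    tag_effect = eff,
    cor_control = covariate_adjusted_correlation(
      merged$singleton_score, merged$sqrt_k_control, gender_ind
    ),
    cor_tag_effect = covariate_adjusted_correlation(
      merged$singleton_score, merged$delta_sqrt_k, gender_ind
    ),
    summary_table = discount_summary_table(fits)
  )
  class(out) <- "tag_analysis"
  out
}

#' @export
print.tag_analysis <- function(x, ...) {
  cat("Condition RM-ANOVA: F(", round(x$anova$df1, 2), ", ",
      round(x$anova$df2, 2), ") = ", round(x$anova$statistic, 3),
      ", p = ", signif(x$anova$p.value, 3), "\n", sep = "")
  cat("Singleton score vs tag effect (gender-adjusted): r = ",
      round(x$cor_tag_effect$estimate, 3),
      ", p = ", signif(x$cor_tag_effect$p.value, 3), "\n", sep = "")
  invisible(x)
}
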