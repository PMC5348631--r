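make_null_cohort_fits <- function(n_subjects = 6, seed = 101) {
  coh <- simulate_cohort(
    cohort_spec(n_subjects = n_subjects, tag_effect_mean = 0,
                tag_effect_sd = 0, seed = seed)
  )
  suppressWarnings(fit_all_subjects(coh$choices))
}

test_that("fit_all_subjects returns per-condition and pooled-tag rows", {
  fits <- make_null_cohort_fits(4)
  expect_equal(nrow(fits), 4 * 4)
  expect_setequal(unique(fits$condition),
                  c("control", "familiar", "unfamiliar", "tag"))
  expect_equal(fits$sqrt_k, sqrt(fits$k))
  # pooled tag fit equals a direct fit on the concatenated tag trials
  coh <- simulate_cohort(cohort_spec(n_subjects = 4, tag_effect_mean = 0,
                                     tag_effect_sd = 0, seed = 101))
  s1 <- coh$choices[coh$choices$subject_id == "S001" &
                      coh$choices$condition != "control", ]
  s1$condition <- NULL
  direct <- suppressWarnings(fit_mle(s1, keep_data = FALSE))
  pooled <- fits[fits$subject_id == "S001" & fits$condition == "tag", ]
  expect_equal(pooled$k, direct$k, tolerance = 1e-6)
  expect_equal(pooled$nll, direct$nll, tolerance = 1e-6)
  # a null cohort has a near-zero median tag effect
  eff <- tag_effect(fits)
  expect_lt(abs(median(eff$delta_sqrt_k)), 0.08)
})

test_that("the summary table mirrors the four-condition layout", {
  fits <- make_null_cohort_fits(4)
  tab <- discount_summary_table(fits)
  expect_equal(tab$condition, c("control", "tag", "familiar", "unfamiliar"))
  expect_true(all(tab$k_median > 0 & tab$beta_median > 0))
})

test_that("rm_anova matches a hand sums-of-squares oracle", {
  # 4 subjects x 3 conditions, values chosen for hand computation
  m <- matrix(c(1, 2, 3,
                2, 4, 3,
                3, 3, 6,
                2, 3, 4), nrow = 4, byrow = TRUE)
  d <- tibble::tibble(
    subject = rep(paste0("s", 1:4), each = 3),
    condition = rep(c("a", "b", "c"), 4),
    y = as.vector(t(m))
  )
  # independent oracle: explicit within-subject sums of squares
  grand <- mean(m)
  ss_cond <- 4 * sum((colMeans(m) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_oracle <- (ss_cond / 2) / (ss_err / 6)
  res <- rm_anova(d, y, condition, subject)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p.value, pf(f_oracle, 2, 6, lower.tail = FALSE))
})

test_that("rm_anova degrees of freedom and invariances", {
  withr::with_seed(55, {
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:22),
                            condition = tag_conditions())
    d$y <- rnorm(nrow(d), 0.3, 0.1)
  })
  res <- rm_anova(d, y, condition, subject)
  expect_equal(c(res$df1, res$df2), c(2, 42))  # n = 22 subjects
  # invariant to adding a per-subject constant
  d2 <- dplyr::group_by(d, subject) |>
    dplyr::mutate(y = y + match(subject[1], sort(unique(d$subject)))) |>
    dplyr::ungroup()
  expect_equal(rm_anova(d2, y, condition, subject)$statistic,
               res$statistic, tolerance = 1e-10)
  # all conditions identical per subject: F = 0
  d3 <- dplyr::group_by(d, subject) |>
    dplyr::mutate(y = y[1]) |> dplyr::ungroup()
  expect_equal(rm_anova(d3, y, condition, subject)$statistic, 0)
  # incomplete designs error
  expect_error(rm_anova(d[-1, ], y, condition, subject), "complete")
  # Greenhouse-Geisser epsilon stays in [1/(p-1), 1] and shrinks the dfs
  gg <- rm_anova(d, y, condition, subject, correction = "greenhouse-geisser")
  expect_true(gg$epsilon >= 0.5 && gg$epsilon <= 1)
  expect_equal(gg$statistic, res$statistic)
  expect_lte(gg$df1, res$df1)
})

test_that("paired_t matches direct formula and handles degenerate input", {
  a <- c(5.1, 6.3, 4.8, 7.0, 5.9)
  b <- c(4.0, 5.1, 5.2, 6.1, 4.4)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(a, b)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 2 * pt(abs(t_oracle), 4, lower.tail = FALSE))
  # n = 22 gives df = 21
  expect_equal(paired_t(rnorm(22), rnorm(22))$df, 21)
  # a == b: t = 0; constant nonzero difference: infinite t
  expect_equal(paired_t(a, a)$statistic, 0)
  expect_equal(paired_t(a, a)$p.value, 1)
  expect_equal(paired_t(a + 2, a)$statistic, Inf)
  expect_equal(paired_t(a + 2, a)$p.value, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("covariate-adjusted correlation reduces to known cases", {
  withr::with_seed(77, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30); g <- rbinom(30, 1, 0.5)
  })
  # no covariates: plain Pearson r with df = n - 2
  plain <- covariate_adjusted_correlation(x, y)
  expect_equal(plain$estimate, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$df, 28)
  expect_equal(plain$p.value, cor.test(x, y)$p.value, tolerance = 1e-10)
  # an all-ones covariate is absorbed by the intercept
  ones <- covariate_adjusted_correlation(x, y, rep(1, 30))
  expect_equal(ones$estimate, plain$estimate)
  expect_equal(ones$df, plain$df)
  # perfectly linear variables give r = 1
  expect_equal(covariate_adjusted_correlation(x, 2 * x + 3)$estimate, 1)
  # df loses one per covariate
  adj <- covariate_adjusted_correlation(x, y, g)
  expect_equal(adj$df, 27)
  # oracle: residualise by explicit lm and correlate
  rx <- residuals(lm(x ~ g)); ry <- residuals(lm(y ~ g))
  expect_equal(adj$estimate, cor(rx, ry), tolerance = 1e-12)
  # degenerate cases
  expect_error(covariate_adjusted_correlation(x, y, x), "residual variance")
  expect_error(covariate_adjusted_correlation(x, y, cbind(g, g)),
               "rank deficient")
})

test_that("analyze_cohort wires fits, scores and covariates together", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 5, seed = 300))
  fits <- suppressWarnings(fit_all_subjects(coh$choices))
  scores <- score_attention(coh$attention)
  scores <- dplyr::inner_join(
    scores, coh$subjects[, c("subject_id", "gender")], by = "subject_id"
  )
  res <- analyze_cohort(fits, scores)
  expect_s3_class(res, "tag_analysis")
  expect_equal(c(res$anova$df1, res$anova$df2), c(2, 8))
  expect_true(abs(res$cor_tag_effect$estimate) <= 1)
  expect_equal(nrow(res$tag_effect), 5)
})

test_that("power rises with the tag-effect size", {
  # with a clear mean effect the RM-ANOVA rejects far above the null rate
  reject_rate <- function(delta_mean, seeds) {
    mean(vapply(seeds, function(s) {
      coh <- simulate_cohort(
        cohort_spec(n_subjects = 23, tag_effect_mean = delta_mean,
                    tag_effect_sd = 0, cond_noise_sd = 0.05, seed = s),
        include = character(0)
      )
      d <- tidyr::pivot_longer(
        coh$subjects[, c("subject_id", "sqrt_k_control_true",
                         "sqrt_k_familiar_true", "sqrt_k_unfamiliar_true")],
        -subject_id, names_to = "condition", values_to = "sk"
      )
      rm_anova(d, sk, condition, subject_id)$p.value < 0.05
    }, TRUE))
  }
  expect_gt(reject_rate(-0.08, 1:40), reject_rate(0, 1:40) + 0.3)
})
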