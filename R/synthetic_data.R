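#' Specification of a synthetic cohort
#'
#' Collects every parameter of the synthetic-cohort generator.  Defaults
#' emulate an older-adult sample: 22 subjects, control-condition
#' `sqrt(k)` centred on 0.2915 (the square root of a typical median discount
#' rate of 0.085 per day), no mean episodic-tag effect, and a strong
#' negative correlation (`rho = -0.67`) between the singleton
#' attentional-control score and the per-subject tag effect on `sqrt(k)`.
#'
#' The tag effect `delta_i` (in `sqrt(k)` units; negative values mean less
#' discounting when the delayed option carries an episodic tag) is drawn
#' jointly with the subject's true singleton score as a bivariate normal
#' with correlation `rho`.  Both tag conditions share the subject's
#' `delta_i`; an additional small iid per-condition deviation
#' (`cond_noise_sd`) represents session-level variability of the discount
#' rate.
#'
#' @param n_subjects Number of subjects (>= 2); default 22.
#' @param sqrt_k_mean,sqrt_k_sd Mean and SD of control-condition `sqrt(k)`.
#' @param tag_effect_mean,tag_effect_sd Mean and between-subject SD of the
#'   tag effect `delta` in `sqrt(k)` units.
#' @param cond_noise_sd SD of the iid per-condition deviation of `sqrt(k)`.
#' @param rho Correlation between the singleton score and `delta`; in
#'   `[-1, 1]`.
#' @param beta_meanlog,beta_sdlog Lognormal parameters of the decision
#'   temperature `beta` (euros).
#' @param p_female Probability that a subject is female.
#' @param singleton_mean,singleton_sd Mean and SD (ms) of the true singleton
#'   score (flexible-condition distractor cost minus strategic-condition
#'   cost; higher = poorer flexible control).
#' @param base_rt_ms Mean visual-search RT without distractor (ms).
#' @param strategic_cost_ms Distractor cost in the strategic condition
#'   (condition 1), ability-independent (ms).
#' @param rt_noise_sd Trial-level Gaussian RT noise SD (ms).
#' @param error_rate Probability that a search trial is an error or miss.
#' @param singleton_target_rate Fraction of flexible-condition trials on
#'   which the singleton is the target (default 0.08).
#' @param interview_rates Named list of per-event Poisson rates for the
#'   detail categories, one numeric vector per familiarity
#'   (`familiar`, `unfamiliar`), each named
#'   `time, place, perceptual, emotion_thought, event, external`.
#' @param rater_noise_sd SD of the Gaussian perturbation added per category
#'   cell to produce the second rater's counts (controls inter-rater
#'   agreement).
#' @param memory_mean,memory_sd Mean and SD of the verbal-learning memory
#'   score (sum of recalled words).
#' @param seed Master seed; every downstream draw derives from it.
#' @return A validated list of class `"cohort_spec"`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 22,
                        sqrt_k_mean = sqrt(0.085),
                        sqrt_k_sd = 0.15,
                        tag_effect_mean = 0,
                        tag_effect_sd = 0.10,
                        cond_noise_sd = 0.02,
                        rho = -0.67,
                        beta_meanlog = log(2.5),
                        beta_sdlog = 0.8,
                        p_female = 0.64,
                        singleton_mean = 71.34,
                        singleton_sd = 89.29,
                        base_rt_ms = 900,
                        strategic_cost_ms = 30,
                        rt_noise_sd = 150,
                        error_rate = 0.0452,
                        singleton_target_rate = 0.08,
                        interview_rates = default_interview_rates(),
                        rater_noise_sd = 1.1,
                        memory_mean = 47.5,
                        memory_sd = 10.34,
                        seed = 1L) {
  spec <- as.list(environment())
  stopifnot(
    spec$n_subjects >= 2,
    spec$sqrt_k_sd > 0, spec$tag_effect_sd >= 0, spec$cond_noise_sd >= 0,
    abs(spec$rho) <= 1,
    spec$p_female >= 0, spec$p_female <= 1,
    spec$error_rate >= 0, spec$error_rate <= 1,
    spec$singleton_target_rate >= 0, spec$singleton_target_rate <= 1,
    spec$rt_noise_sd >= 0, spec$rater_noise_sd >= 0
  )
  cats <- detail_categories(include_external = TRUE)
  for (fam in c("familiar", "unfamiliar")) {
    r <- spec$interview_rates[[fam]]
    if (is.null(r) || !all(cats %in% names(r)) || any(r < 0)) {
      stop("`interview_rates$", fam, "` must be non-negative rates named ",
           paste(cats, collapse = ", "), call. = FALSE)
    }
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat(sprintf("  sqrt(k) ~ N(%.3f, %.3f); tag effect N(%.3f, %.3f); rho = %.2f\n",
              x$sqrt_k_mean, x$sqrt_k_sd, x$tag_effect_mean, x$tag_effect_sd,
              x$rho))
  invisible(x)
}

#' Interview detail categories
#'
#' The five internal (episodic) categories — time, place, perceptual,
#' emotion/thought and event details — plus the pooled external
#' (non-episodic) score.
#'
#' @param include_external Append `"external"`? Default `TRUE`.
#' @return Character vector of category labels.
#' @export
detail_categories <- function(include_external = TRUE) {
  c("time", "place", "perceptual", "emotion_thought", "event",
    if (include_external) "external")
}

#' Default per-event Poisson rates for interview details
#'
#' Rates per imagined event, by partner familiarity.  The four substantive
#' internal subcategories carry essentially all internal details (their sums
#' are 6.55 and 5.87 per event); the `time` category contributes nothing by
#' default.
#'
#' @return Named list with elements `familiar` and `unfamiliar`.
#' @export
default_interview_rates <- function() {
  list(
    familiar = c(time = 0, place = 1.32, perceptual = 1.55,
                 emotion_thought = 1.45, event = 2.23, external = 0.86),
    unfamiliar = c(time = 0, place = 1.14, perceptual = 0.82,
                   emotion_thought = 1.82, event = 2.09, external = 0.68)
  )
}

# Derive independent child seeds from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate choices for a planned schedule
#'
#' Gives every planned trial a Bernoulli choice with delayed-choice
#' probability from [choice_probability()] at the trial's hyperbolic
#' subjective value, plus a lognormal response time.
#'
#' @param schedule Tibble of planned trials (from [build_session()] or
#'   [build_block()]): needs `delay_days` and `amount_eur`.
#' @param k,beta True generative parameters.
#' @param seed Integer seed; the choice vector is a pure function of the
#'   inputs.
#' @param ref Immediate reference amount in euros (default 20).
#' @param rt_meanlog,rt_sdlog Lognormal RT parameters (log-ms scale).
#' @return The schedule with `choice` (`"delayed"`/`"immediate"`) and
#'   `rt_ms` columns appended.
#' @export
simulate_choices <- function(schedule, k, beta, seed, ref = 20,
                             rt_meanlog = log(850), rt_sdlog = 0.35) {
  check_choice_trials(schedule, require_choice = FALSE)
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  if (beta <= 0) stop("`beta` must be strictly positive", call. = FALSE)
  n <- nrow(schedule)
  sv <- subjective_value(schedule$amount_eur, schedule$delay_days, k)
  p <- choice_probability(sv, ref, beta)
  withr::with_seed(seed, {
    delayed <- stats::runif(n) < p
    rt <- stats::rlnorm(n, rt_meanlog, rt_sdlog)
  })
  dplyr::mutate(
    tibble::as_tibble(schedule),
    choice = ifelse(delayed, "delayed", "immediate"),
    rt_ms = rt
  )
}

#' Simulate one subject's visual-search (singleton) session
#'
#' Generates the two-condition attentional-control task: four blocks of 48
#' trials per condition.  In the strategic condition (1) a colour-singleton
#' distractor appears on half the trials and costs `strategic_cost_ms`; in
#' the flexible condition (2) the same distractor costs
#' `strategic_cost_ms + singleton_true`, and on a small fraction of trials
#' the singleton is itself the target (those trials carry no distractor and
#' are excluded from cost computations).  Trial RTs get Gaussian noise;
#' errors/misses occur at `error_rate`; responses beyond the 3000-ms window
#' are recorded as missing.
#'
#' @param singleton_true The subject's true singleton score in ms (flexible
#'   minus strategic distractor cost).
#' @param spec A [cohort_spec()] supplying task parameters.
#' @param seed Integer seed.
#' @return Tibble with columns `condition` (1/2), `trial`,
#'   `distractor_present`, `singleton_target`, `rt_ms`, `correct`.
#' @export
simulate_singleton_trials <- function(singleton_true, spec = cohort_spec(),
                                      seed = 1L) {
  n_per_cond <- 4L * 48L
  withr::with_seed(seed, {
    per_condition <- function(cond) {
      singleton_target <- if (cond == 2L) {
        stats::runif(n_per_cond) < spec$singleton_target_rate
      } else rep(FALSE, n_per_cond)
      # distractor on half of the ordinary trials, balanced then shuffled
      distractor <- rep_len(c(TRUE, FALSE), n_per_cond)[sample.int(n_per_cond)]
      distractor[singleton_target] <- FALSE
      cost <- spec$strategic_cost_ms + if (cond == 2L) singleton_true else 0
      rt <- spec$base_rt_ms + cost * distractor +
        stats::rnorm(n_per_cond, 0, spec$rt_noise_sd)
      correct <- stats::runif(n_per_cond) >= spec$error_rate
      missing <- rt > 3000
      tibble::tibble(
        condition = cond,
        trial = seq_len(n_per_cond),
        distractor_present = distractor,
        singleton_target = singleton_target,
        rt_ms = ifelse(missing, NA_real_, rt),
        correct = ifelse(missing, NA, correct)
      )
    }
    dplyr::bind_rows(per_condition(1L), per_condition(2L))
  })
}

#' Simulate the paired-rater interview tallies for one subject
#'
#' Four imagined events (two familiar, two unfamiliar partners).  Rater 1's
#' count per detail category is Poisson with the familiarity-specific rate;
#' rater 2's count is rater 1's plus a rounded Gaussian perturbation
#' (truncated at zero), whose SD controls inter-rater agreement.
#'
#' @param spec A [cohort_spec()] supplying `interview_rates` and
#'   `rater_noise_sd`.
#' @param seed Integer seed.
#' @return Tibble with columns `event_id`, `familiarity`, `rater` (1/2),
#'   `category`, `count`.
#' @export
simulate_interview <- function(spec = cohort_spec(), seed = 1L) {
  cats <- detail_categories(include_external = TRUE)
  events <- tibble::tibble(
    event_id = c("F1", "F2", "U1", "U2"),
    familiarity = c("familiar", "familiar", "unfamiliar", "unfamiliar")
  )
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(events)), function(i) {
      rates <- spec$interview_rates[[events$familiarity[i]]][cats]
      r1 <- stats::rpois(length(cats), rates)
      r2 <- pmax(0, round(r1 + stats::rnorm(length(cats), 0, spec$rater_noise_sd)))
      tibble::tibble(
        event_id = events$event_id[i],
        familiarity = events$familiarity[i],
        rater = rep(c(1L, 2L), each = length(cats)),
        category = rep(cats, 2),
        count = as.integer(c(r1, r2))
      )
    })
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject generative truths and, on request, all three data
#' streams the analysis consumes: intertemporal choices on an adaptive
#' schedule built from the subject's own control-condition discount rate,
#' the visual-search singleton task, and the paired-rater interview tallies.
#'
#' Per-condition true `sqrt(k)` values are
#' `control_i + delta_i * is_tag + eps_ic`, with `(delta_i, singleton_i)`
#' bivariate normal at correlation `rho` and `eps_ic` iid
#' `N(0, cond_noise_sd)`; values are truncated into the fitting bounds.
#' Choices in each condition are generated with that condition's true
#' `(k, beta)` on the shared schedule.
#'
#' @param spec A [cohort_spec()].
#' @param include Character subset of `c("choices", "attention",
#'   "interview")` selecting which trial-level tables to generate; the
#'   subject-level truths are always produced.  Use `include = character(0)`
#'   for fast cohort-level simulation studies.
#' @return An object of class `"cohort"`: a list with elements `spec`,
#'   `subjects` (one row per subject: gender, memory score, true singleton
#'   score, true `sqrt(k)`/`k`/`beta` per condition, tag effect `delta`),
#'   and — when requested — `choices`, `attention`, `interview` tibbles.
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 3, seed = 42))
#' coh$subjects
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            include = c("choices", "attention", "interview")) {
  stopifnot(inherits(spec, "cohort_spec"))
  bad <- setdiff(include, c("choices", "attention", "interview"))
  if (length(bad) > 0) {
    stop("unknown `include` entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- spec$n_subjects
  bounds <- discount_bounds()
  sk_lo <- sqrt(bounds$k[1]); sk_hi <- sqrt(bounds$k[2])

  seeds <- derive_seeds(spec$seed, 2L + 3L * n)
  subject_seeds <- matrix(seeds[-(1:2)], nrow = n)  # cols: choices, attention, interview

  truths <- withr::with_seed(seeds[1], {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    delta <- spec$tag_effect_mean + spec$tag_effect_sd * z1
    singleton <- spec$singleton_mean +
      spec$singleton_sd * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
    sk_ctrl <- stats::rnorm(n, spec$sqrt_k_mean, spec$sqrt_k_sd)
    eps <- matrix(stats::rnorm(3 * n, 0, spec$cond_noise_sd), nrow = n)
    clamp <- function(x) pmin(pmax(x, sk_lo), sk_hi)
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      gender = ifelse(stats::runif(n) < spec$p_female, "female", "male"),
      memory_score = stats::rnorm(n, spec$memory_mean, spec$memory_sd),
      singleton_true = singleton,
      delta_sqrt_k_true = delta,
      sqrt_k_control_true = clamp(sk_ctrl + eps[, 1]),
      sqrt_k_familiar_true = clamp(sk_ctrl + delta + eps[, 2]),
      sqrt_k_unfamiliar_true = clamp(sk_ctrl + delta + eps[, 3]),
      beta_control_true = stats::rlnorm(n, spec$beta_meanlog, spec$beta_sdlog),
      beta_familiar_true = stats::rlnorm(n, spec$beta_meanlog, spec$beta_sdlog),
      beta_unfamiliar_true = stats::rlnorm(n, spec$beta_meanlog, spec$beta_sdlog)
    )
  })

  out <- list(spec = spec, subjects = truths)
  class(out) <- "cohort"

  if ("choices" %in% include) {
    out$choices <- purrr::map_dfr(seq_len(n), function(i) {
      s <- truths[i, ]
      k_pretest <- s$sqrt_k_control_true^2
      sched <- build_session(k_pretest, seed = subject_seeds[i, 1])
      cond_seeds <- derive_seeds(subject_seeds[i, 1], 3)
      sim <- purrr::map_dfr(seq_along(tag_conditions()), function(ci) {
        cond <- tag_conditions()[ci]
        rows <- dplyr::filter(sched, .data$condition == cond)
        simulate_choices(
          rows,
          k = s[[paste0("sqrt_k_", cond, "_true")]]^2,
          beta = s[[paste0("beta_", cond, "_true")]],
          seed = cond_seeds[ci]
        )
      })
      dplyr::mutate(
        dplyr::arrange(sim, .data$block_index, .data$trial_index),
        subject_id = s$subject_id, .before = 1
      )
    })
  }
  if ("attention" %in% include) {
    out$attention <- purrr::map_dfr(seq_len(n), function(i) {
      dplyr::mutate(
        simulate_singleton_trials(truths$singleton_true[i], spec,
                                  seed = subject_seeds[i, 2]),
        subject_id = truths$subject_id[i], .before = 1
      )
    })
  }
  if ("interview" %in% include) {
    out$interview <- purrr::map_dfr(seq_len(n), function(i) {
      dplyr::mutate(
        simulate_interview(spec, seed = subject_seeds[i, 3]),
        subject_id = truths$subject_id[i], .before = 1
      )
    })
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects\n")
  for (nm in c("choices", "attention", "interview")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
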