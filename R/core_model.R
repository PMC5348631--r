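#' Hyperbolic subjective value of a delayed reward
#'
#' Computes the subjective (present) value of a delayed monetary amount under
#' Mazur's hyperbolic discount function, `SV = A / (1 + k * D)`, where `A` is
#' the delayed amount in euros, `D` the delay in days and `k` the discount
#' rate per day.  Higher `k` means steeper devaluation with delay (more
#' impatience).
#'
#' @param amount Delayed amount in euros; strictly positive. Vectorised.
#' @param delay Delay in days; non-negative. Vectorised.
#' @param k Discount rate per day; non-negative. Vectorised.
#' @return Numeric vector of subjective values in euros. `SV == amount` at
#'   `delay == 0`, and `SV` is strictly decreasing in both `k` and `delay`
#'   when `k > 0`.
#' @examples
#' subjective_value(40, 10, 0.1)   # kD = 1 halves the amount -> 20
#' subjective_value(71, 30, 0.085) # the control-condition median rate -> 20
#' @seealso [indifference_amount()] for the algebraic inverse at a fixed
#'   immediate reference.
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount <= 0)) stop("`amount` must be strictly positive", call. = FALSE)
  if (any(delay < 0)) stop("`delay` must be non-negative", call. = FALSE)
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  amount / (1 + k * delay)
}

#' Softmax probability of choosing the delayed option
#'
#' Logistic (softmax over two options) choice rule on the subjective-value
#' difference: `P(delayed) = 1 / (1 + exp(-(sv_delayed - sv_immediate) / beta))`.
#'
#' `beta` is parameterised as a *temperature* in euros: larger `beta` means a
#' noisier, more random chooser (P is pulled toward 0.5 for any fixed value
#' difference), and `beta -> 0` approaches a deterministic maximiser.  If you
#' prefer the inverse-temperature convention `P = logistic(tau * dSV)`, the
#' two are related by `tau = 1 / beta`; absolute noise-parameter values are
#' not comparable across the two conventions.
#'
#' @param sv_delayed Subjective value of the delayed option (euros).
#' @param sv_immediate Subjective value of the immediate option (euros).
#' @param beta Decision-noise temperature in euros; strictly positive.
#' @return Probability of choosing the delayed option, in (0, 1); exactly 0.5
#'   when the two values are equal.
#' @examples
#' choice_probability(20, 20, 2)      # indifference -> 0.5
#' choice_probability(22, 20, 2)      # logistic(1) = 0.731...
#' @export
choice_probability <- function(sv_delayed, sv_immediate, beta) {
  if (any(beta <= 0)) stop("`beta` must be strictly positive", call. = FALSE)
  stats::plogis((sv_delayed - sv_immediate) / beta)
}

#' Square-root transform of the discount rate
#'
#' Discount rates are strongly right-skewed across subjects; group statistics
#' are therefore run on `sqrt(k)` rather than `k`.
#'
#' @param k Discount rate(s) per day; non-negative.
#' @return `sqrt(k)`; monotone, with 0 mapping to 0.
#' @export
transform_k <- function(k) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  sqrt(k)
}

#' Indifference amount for a given delay
#'
#' The delayed amount whose subjective value equals a fixed immediate
#' reference: `A* = ref * (1 + k * delay)`, the exact algebraic inverse of
#' [subjective_value()].
#'
#' @param k Discount rate per day; non-negative.
#' @param delay Delay in days; non-negative.
#' @param ref Immediate reference amount in euros (default 20).
#' @return Amount in euros at which the chooser is indifferent between the
#'   delayed and the immediate reward.
#' @examples
#' indifference_amount(0.085, 30)  # 20 * (1 + 2.55) = 71
#' @export
indifference_amount <- function(k, delay, ref = 20) {
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  if (any(delay < 0)) stop("`delay` must be non-negative", call. = FALSE)
  if (any(ref <= 0)) stop("`ref` must be strictly positive", call. = FALSE)
  ref * (1 + k * delay)
}

#' Default box constraints for the discounting fit
#'
#' Generous bounds around plausible adult values (group medians are near
#' k = 0.08 per day and beta = 2-3 euros): `k` in `[1e-6, 2]` per day and
#' `beta` in `[1e-3, 1e3]` euros.
#'
#' @return Named list with elements `k` and `beta`, each `c(lower, upper)`.
#' @export
discount_bounds <- function() {
  list(k = c(1e-6, 2), beta = c(1e-3, 1e3))
}

# Validate a trial table and return it with canonical columns.
check_choice_trials <- function(trials, require_choice = TRUE) {
  needed <- c("delay_days", "amount_eur", if (require_choice) "choice")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) stop("trial table is empty", call. = FALSE)
  if ("condition" %in% names(trials)) {
    bad <- setdiff(unique(as.character(trials$condition)), tag_conditions())
    if (length(bad) > 0) {
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (require_choice) {
    bad <- setdiff(unique(as.character(trials$choice)), c("delayed", "immediate"))
    if (length(bad) > 0) {
      stop("`choice` must be 'delayed' or 'immediate', got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  trials
}

#' The three experimental condition labels
#'
#' Delayed options are presented either with an episodic tag (a meeting with
#' a `familiar` or an `unfamiliar` person to be imagined) or without imagery
#' (`control`).
#'
#' @return Character vector `c("control", "familiar", "unfamiliar")`.
#' @export
tag_conditions <- function() c("control", "familiar", "unfamiliar")

#' Negative log-likelihood of a choice set under the discounting model
#'
#' Combines the hyperbolic discount function with softmax action selection:
#' each trial contributes `-log P(observed choice)` where the delayed-choice
#' probability comes from [choice_probability()] at the trial's subjective
#' value.  Probabilities are clipped to `[clip, 1 - clip]` before the log so
#' the objective stays finite at extreme parameter values; the number of
#' clipped trials is reported via the `"n_clipped"` attribute.
#'
#' Fits are per condition: mixing condition labels within one call is an
#' error.
#'
#' @param trials Data frame with columns `delay_days`, `amount_eur`, `choice`
#'   (`"delayed"`/`"immediate"`), and optionally `condition` (must then be a
#'   single label).
#' @param k,beta Candidate parameter values.
#' @param ref Immediate reference amount in euros (default 20).
#' @param clip Probability floor/ceiling margin (default 1e-9).
#' @return The negative log-likelihood (non-negative scalar), with attribute
#'   `n_clipped`.
#' @export
choice_nll <- function(trials, k, beta, ref = 20, clip = 1e-9) {
  trials <- check_choice_trials(trials)
  if ("condition" %in% names(trials) &&
      length(unique(as.character(trials$condition))) > 1) {
    stop("`choice_nll` expects trials from a single condition; got ",
         paste(unique(trials$condition), collapse = ", "), call. = FALSE)
  }
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  if (beta <= 0) stop("`beta` must be strictly positive", call. = FALSE)
  sv <- subjective_value(trials$amount_eur, trials$delay_days, k)
  p_delayed <- choice_probability(sv, ref, beta)
  p_obs <- ifelse(trials$choice == "delayed", p_delayed, 1 - p_delayed)
  clipped <- p_obs < clip | p_obs > 1 - clip
  p_obs <- pmin(pmax(p_obs, clip), 1 - clip)
  out <- -sum(log(p_obs))
  attr(out, "n_clipped") <- sum(clipped)
  out
}

# nll and analytic gradient in log-parameter space, for the optimiser.
# theta = c(log k, log beta).
nll_objective <- function(theta, amount, delay, y, ref, clip) {
  k <- exp(theta[1]); beta <- exp(theta[2])
  dsv <- amount / (1 + k * delay) - ref
  p <- stats::plogis(dsv / beta)
  p_obs <- ifelse(y, p, 1 - p)
  -sum(log(pmin(pmax(p_obs, clip), 1 - clip)))
}

nll_gradient <- function(theta, amount, delay, y, ref, clip) {
  k <- exp(theta[1]); beta <- exp(theta[2])
  dsv <- amount / (1 + k * delay) - ref
  x <- dsv / beta
  p <- stats::plogis(x)
  resid <- p - y                       # d nll / d x per trial
  dx_dlogk <- -amount * delay * k / (1 + k * delay)^2 / beta
  c(sum(resid * dx_dlogk), sum(resid * (-x)))
}

#' Fit the hyperbolic-softmax model to one condition's choices
#'
#' Maximum-likelihood estimation of the discount rate `k` and the decision
#' temperature `beta` by minimising [choice_nll()].  The optimiser is a
#' multi-start bounded quasi-Newton (L-BFGS-B on log-scale parameters with an
#' analytic gradient), started from every node of an `n_grid[1] x n_grid[2]`
#' log-spaced grid spanning the bounds; the best converged start wins.
#'
#' Degenerate choice vectors (every trial the same option) cannot identify
#' the parameters: the fit then returns the relevant `k` bound (lower bound
#' for an all-delayed chooser, upper for all-immediate) with
#' `converged = FALSE` and a warning rather than an error, mirroring how such
#' subjects would otherwise silently pin the optimiser to its box.
#'
#' @param trials Data frame of one condition's trials; see [choice_nll()].
#'   At least 12 trials with both options represented are recommended; fewer
#'   trials still fit but are flagged via `boundary`/`converged`.
#' @param ref Immediate reference amount in euros (default 20).
#' @param bounds List with elements `k` and `beta`, each `c(lower, upper)`;
#'   default [discount_bounds()].
#' @param n_grid Integer vector of length 2: grid starts per parameter
#'   (default `c(8, 8)`).
#' @param clip Probability clipping margin passed to the likelihood.
#' @param keep_data Keep the trial table inside the returned object (used by
#'   [autoplot.discount_fit()]); default `TRUE`.
#' @return An object of class `"discount_fit"`: a list with elements `k`,
#'   `beta`, `sqrt_k`, `nll`, `n_trials`, `n_delayed`, `n_clipped`,
#'   `converged`, `condition`, `ref`, `bounds`.  [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods are provided.
#' @examples
#' sched <- build_session(k = 0.1, seed = 7)
#' trials <- simulate_choices(sched, k = 0.1, beta = 2, seed = 8)
#' fit <- fit_mle(dplyr::filter(trials, condition == "control"))
#' generics::tidy(fit)
#' @export
fit_mle <- function(trials, ref = 20, bounds = discount_bounds(),
                    n_grid = c(8, 8), clip = 1e-9, keep_data = TRUE) {
  trials <- check_choice_trials(trials)
  if ("condition" %in% names(trials) &&
      length(unique(as.character(trials$condition))) > 1) {
    stop("`fit_mle` fits one condition at a time; got ",
         paste(unique(trials$condition), collapse = ", "), call. = FALSE)
  }
  y <- trials$choice == "delayed"
  n <- length(y)
  n_delayed <- sum(y)
  condition <- if ("condition" %in% names(trials)) {
    as.character(trials$condition[1])
  } else NA_character_

  res <- list(
    k = NA_real_, beta = NA_real_, sqrt_k = NA_real_, nll = NA_real_,
    n_trials = n, n_delayed = n_delayed, n_clipped = 0L,
    converged = FALSE, boundary = FALSE, condition = condition,
    ref = ref, bounds = bounds,
    data = if (keep_data) tibble::as_tibble(trials) else NULL
  )
  class(res) <- "discount_fit"

  if (n_delayed == 0L || n_delayed == n) {
    # One-sided choosers: the likelihood is maximised on the k boundary.
    res$k <- if (n_delayed == n) bounds$k[1] else bounds$k[2]
    res$beta <- bounds$beta[1]
    res$sqrt_k <- sqrt(res$k)
    nll <- choice_nll(trials, res$k, res$beta, ref = ref, clip = clip)
    res$nll <- as.numeric(nll)
    res$n_clipped <- attr(nll, "n_clipped")
    res$boundary <- TRUE
    warning("all choices are '", if (n_delayed == n) "delayed" else "immediate",
            "'; returning boundary estimate with converged = FALSE",
            call. = FALSE)
    return(res)
  }

  starts <- expand.grid(
    logk = seq(log(bounds$k[1]), log(bounds$k[2]), length.out = n_grid[1]),
    logb = seq(log(bounds$beta[1]), log(bounds$beta[2]), length.out = n_grid[2])
  )
  lower <- c(log(bounds$k[1]), log(bounds$beta[1]))
  upper <- c(log(bounds$k[2]), log(bounds$beta[2]))
  amount <- trials$amount_eur
  delay <- trials$delay_days

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- try(stats::optim(
      par = c(starts$logk[i], starts$logb[i]),
      fn = nll_objective, gr = nll_gradient,
      amount = amount, delay = delay, y = y, ref = ref, clip = clip,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(factr = 1e7, maxit = 200)
    ), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimisation failed from every start", call. = FALSE)

  res$k <- exp(best$par[1])
  res$beta <- exp(best$par[2])
  res$sqrt_k <- sqrt(res$k)
  nll <- choice_nll(trials, res$k, res$beta, ref = ref, clip = clip)
  res$nll <- as.numeric(nll)
  res$n_clipped <- attr(nll, "n_clipped")
  res$converged <- best$convergence == 0 && n >= 12
  res$boundary <- n < 12
  res
}

#' @export
print.discount_fit <- function(x, ...) {
  cat("Hyperbolic-softmax discounting fit",
      if (!is.na(x$condition)) paste0(" (", x$condition, ")"), "\n", sep = "")
  cat(sprintf("  k = %.4f per day   sqrt(k) = %.4f   beta = %.3f EUR\n",
              x$k, x$sqrt_k, x$beta))
  cat(sprintf("  nll = %.3f over %d trials (%d delayed), converged: %s\n",
              x$nll, x$n_trials, x$n_delayed, x$converged))
  if (x$n_clipped > 0) {
    cat(sprintf("  %d trial probabilities clipped at the likelihood floor\n",
                x$n_clipped))
  }
  invisible(x)
}

#' Tidy a discounting fit
#'
#' @param x A `"discount_fit"` object from [fit_mle()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k`, `beta`, `sqrt_k`) and
#'   columns `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.discount_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "beta", "sqrt_k"),
    estimate = c(x$k, x$beta, x$sqrt_k)
  )
}

#' One-row summary of a discounting fit
#'
#' @param x A `"discount_fit"` object from [fit_mle()].
#' @param ... Unused.
#' @return A one-row tibble: `nll`, `AIC`, `n_trials`, `n_delayed`,
#'   `n_clipped`, `converged`, `boundary`.
#' @exportS3Method generics::glance
glance.discount_fit <- function(x, ...) {
  tibble::tibble(
    nll = x$nll,
    AIC = 2 * x$nll + 2 * 2,
    n_trials = x$n_trials,
    n_delayed = x$n_delayed,
    n_clipped = x$n_clipped,
    converged = x$converged,
    boundary = x$boundary
  )
}
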