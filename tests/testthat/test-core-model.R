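test_that("subjective value follows the hyperbola and its invariants", {
  expect_equal(subjective_value(40, 0, 0.5), 40)       # zero delay is identity
  expect_equal(subjective_value(40, 10, 0.1), 20)      # kD = 1 halves the amount
  expect_equal(subjective_value(71, 30, 0.085), 20)    # 71 / (1 + 2.55)

  # monotone decreasing in delay and in k; equality only at k = 0 or D = 0
  delays <- c(0, 1, 7, 30, 180)
  sv <- subjective_value(50, delays, 0.085)
  expect_true(all(diff(sv) < 0))
  ks <- c(0, 0.01, 0.1, 1)
  expect_true(all(diff(subjective_value(50, 30, ks)) < 0))
  expect_equal(subjective_value(50, 30, 0), 50)

  expect_error(subjective_value(-5, 10, 0.1), "positive")
  expect_error(subjective_value(50, 10, -0.1), "non-negative")
})

test_that("softmax choice probability is a symmetric logistic in the value gap", {
  expect_equal(choice_probability(20, 20, 5), 0.5)
  # gap of exactly +beta is logistic(1)
  expect_equal(choice_probability(22, 20, 2), 0.7310585786300049, tolerance = 1e-12)
  # noiseless limit takes the larger value
  expect_equal(choice_probability(30, 20, 1e-8), 1)
  # larger beta pulls toward 0.5
  p <- choice_probability(25, 20, c(0.5, 2, 10, 100))
  expect_true(all(diff(p) < 0) && all(p > 0.5))
  # complementarity for all inputs
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- runif(1, 1, 80); b <- runif(1, 1, 80); beta <- runif(1, 0.01, 50)
      expect_equal(choice_probability(a, b, beta) + choice_probability(b, a, beta), 1)
    }
  })
  expect_error(choice_probability(20, 20, 0), "positive")
})

test_that("transform_k is the square root and inverts squaring", {
  expect_identical(transform_k(0), 0)
  expect_identical(transform_k(1), 1)
  expect_equal(transform_k(0.085), 0.2915476, tolerance = 1e-6)
  x <- seq(0, 3, by = 0.1)
  expect_equal(transform_k(x^2), x)
  expect_error(transform_k(-1), "non-negative")
})

test_that("indifference amount inverts subjective value", {
  expect_equal(indifference_amount(0, 30), 20)
  expect_equal(indifference_amount(0.085, 30), 71)
  withr::with_seed(7, {
    for (i in 1:25) {
      k <- runif(1, 0, 0.5); d <- sample(0:190, 1)
      a_star <- indifference_amount(k, d)
      expect_equal(subjective_value(a_star, d, k), 20)
    }
  })
})

test_that("negative log-likelihood matches direct summation", {
  # two trials at P(observed) = 0.5 give 2 * ln 2
  even <- tibble::tibble(delay_days = c(0L, 0L), amount_eur = c(20, 20),
                         choice = c("delayed", "immediate"))
  expect_equal(as.numeric(choice_nll(even, k = 0.1, beta = 2)), 2 * log(2))

  # fixed 10-trial fixture vs an independent hand summation
  fix <- make_sim_trials(0.08, 2, n = 10, seed = 99)
  expect_equal(as.numeric(choice_nll(fix, 0.05, 1.5)),
               nll_by_hand(fix, 0.05, 1.5), tolerance = 1e-8)
  expect_gt(as.numeric(choice_nll(fix, 0.05, 1.5)), 0)

  expect_error(choice_nll(fix[0, ], 0.1, 1), "empty")
  mixed <- dplyr::mutate(fix, condition = rep(c("control", "familiar"), 5))
  expect_error(choice_nll(mixed, 0.1, 1), "single condition")
})

test_that("likelihood clipping keeps the objective finite and is counted", {
  fix <- make_sim_trials(0.08, 2, n = 40, seed = 5)
  # absurd parameters drive some probabilities to the floor
  nll <- choice_nll(fix, k = 2, beta = 1e-3)
  expect_true(is.finite(nll))
  expect_gt(attr(nll, "n_clipped"), 0)
})

test_that("fit_mle beats a grid-search oracle on random fixtures", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      k_true <- exp(runif(1, log(0.005), log(0.3)))
      beta_true <- exp(runif(1, log(0.5), log(8)))
      fix <- make_sim_trials(k_true, beta_true, n = 72,
                             seed = sample.int(1e6, 1))
      fit <- suppressWarnings(fit_mle(fix))
      # independent 60x60 grid, inline arithmetic
      kg <- exp(seq(log(1e-6), log(2), length.out = 60))
      bg <- exp(seq(log(1e-3), log(1e3), length.out = 60))
      y <- fix$choice == "delayed"
      grid_min <- Inf
      for (kk in kg) {
        sv <- fix$amount_eur / (1 + kk * fix$delay_days)
        for (bb in bg) {
          p <- 1 / (1 + exp(-(sv - 20) / bb))
          pobs <- pmin(pmax(ifelse(y, p, 1 - p), 1e-9), 1 - 1e-9)
          grid_min <- min(grid_min, -sum(log(pobs)))
        }
      }
      expect_lte(fit$nll, grid_min + 1e-8)
    }
  })
})

test_that("fit_mle recovers parameters from model-generated choices", {
  sched <- build_session(0.08, seed = 21)
  trials <- simulate_choices(sched[, c("delay_days", "amount_eur")],
                             k = 0.08, beta = 1, seed = 22)
  fit <- fit_mle(trials)
  expect_true(fit$converged)
  expect_equal(fit$k, 0.08, tolerance = 0.35)
  expect_equal(fit$beta, 1, tolerance = 0.5)
})

test_that("near-deterministic choosers bracket k between indifference constraints", {
  # beta -> 0: every choice follows the sign of SV - 20 exactly, so the
  # fitted k must separate accepted from rejected offers
  sched <- build_session(0.1, seed = 77)
  trials <- dplyr::mutate(
    sched[, c("delay_days", "amount_eur")],
    sv = amount_eur / (1 + 0.1 * delay_days),
    choice = ifelse(sv > 20, "delayed", "immediate")
  )
  fit <- suppressWarnings(fit_mle(trials[, c("delay_days", "amount_eur", "choice")]))
  # implied per-trial threshold rates: k* = (A/20 - 1)/D; an offer is
  # accepted exactly when k* exceeds the chooser's k
  k_star <- (trials$amount_eur / 20 - 1) / trials$delay_days
  lo <- max(k_star[trials$choice == "immediate"])  # rejected -> k > k*
  hi <- min(k_star[trials$choice == "delayed"])    # accepted -> k < k*
  expect_lte(lo, hi)  # deterministic data admit a separating interval
  expect_gte(fit$k, lo - 1e-3)
  expect_lte(fit$k, hi + 1e-3)
})

test_that("duplicating every trial doubles the nll and keeps the estimate", {
  fix <- make_sim_trials(0.06, 2, n = 36, seed = 13)
  fit1 <- fit_mle(fix)
  fit2 <- fit_mle(dplyr::bind_rows(fix, fix))
  expect_equal(fit2$k, fit1$k, tolerance = 1e-4)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-4)
  expect_equal(fit2$nll, 2 * fit1$nll, tolerance = 1e-6)
})

test_that("one-sided choice vectors return bounded estimates with a warning", {
  fix <- make_sim_trials(0.08, 2, n = 20, seed = 3)
  all_delayed <- dplyr::mutate(fix, choice = "delayed")
  expect_warning(f1 <- fit_mle(all_delayed), "delayed")
  expect_false(f1$converged)
  expect_equal(f1$k, discount_bounds()$k[1])
  all_imm <- dplyr::mutate(fix, choice = "immediate")
  expect_warning(f2 <- fit_mle(all_imm), "immediate")
  expect_false(f2$converged)
  expect_equal(f2$k, discount_bounds()$k[2])
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_mle(make_sim_trials(0.08, 2, n = 36, seed = 8))
  td <- generics::tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("k", "beta", "sqrt_k"))
  expect_equal(td$estimate[td$term == "sqrt_k"], sqrt(fit$k))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$AIC, 2 * fit$nll + 4)
})
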