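# Shared fixture builders. All randomness is seeded at the call site.

# A plain random trial set, independent of the adaptive schedule builder,
# with choices generated from the hyperbolic-softmax model.
make_sim_trials <- function(k, beta, n = 72, seed = 1, ref = 20) {
  withr::with_seed(seed, {
    delays <- sample(unlist(default_delay_sets()), n, replace = TRUE)
    amounts <- round(stats::runif(n, 20.5, 79.5) * 2) / 2
    sv <- amounts / (1 + k * delays)
    p <- stats::plogis((sv - ref) / beta)
    tibble::tibble(
      delay_days = as.integer(delays),
      amount_eur = amounts,
      choice = ifelse(stats::runif(n) < p, "delayed", "immediate")
    )
  })
}

# Deterministic attention-trial table with hand-set RTs.
make_attention_fixture <- function() {
  tibble::tibble(
    condition = rep(c(1L, 2L), each = 8),
    trial = rep(1:8, 2),
    distractor_present = rep(c(TRUE, TRUE, FALSE, FALSE), 4),
    singleton_target = FALSE,
    rt_ms = c(600, 620, 500, 520, 640, 660, 480, 500,
              700, 720, 520, 540, 760, 780, 560, 580),
    correct = TRUE
  )
}

# Minimal long-format interview table for one subject.
make_interview_fixture <- function(counts1, counts2, category = "event") {
  n <- length(counts1)
  tibble::tibble(
    subject_id = "S1",
    event_id = paste0("E", rep(seq_len(n), 2)),
    familiarity = "familiar",
    rater = rep(c(1L, 2L), each = n),
    category = category,
    count = as.integer(c(counts1, counts2))
  )
}

# Inline negative log-likelihood, written independently of choice_nll():
# direct arithmetic summation over trials.
nll_by_hand <- function(trials, k, beta, ref = 20) {
  s <- 0
  for (i in seq_len(nrow(trials))) {
    sv <- trials$amount_eur[i] / (1 + k * trials$delay_days[i])
    p <- 1 / (1 + exp(-(sv - ref) / beta))
    if (trials$choice[i] != "delayed") p <- 1 - p
    s <- s - log(p)
  }
  s
}
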