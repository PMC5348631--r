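#' Default delay pairs for the discounting session
#'
#' Each of the six delay positions draws its delay (in days) from a pair of
#' neighbouring values, so nominal delays vary slightly across trials while
#' spanning roughly two days to six months.
#'
#' @return A list of six integer pairs:
#'   `[1,2], [6,7], [13,15], [28,32], [85,95], [170,190]`.
#' @export
default_delay_sets <- function() {
  list(c(1L, 2L), c(6L, 7L), c(13L, 15L), c(28L, 32L),
       c(85L, 95L), c(170L, 190L))
}

check_delay_sets <- function(delay_sets) {
  ok <- is.list(delay_sets) && length(delay_sets) == 6 &&
    all(vapply(delay_sets, function(p) length(p) == 2 && p[1] < p[2], TRUE))
  if (!ok) stop("`delay_sets` must be six strictly increasing pairs", call. = FALSE)
  delay_sets
}

# Snap to the 0.5-EUR grid, clamp into [lo, hi], and resolve collisions so
# the six rungs stay distinct.
snap_ladder <- function(amounts, lo, hi) {
  v <- sort(pmin(pmax(round(amounts * 2) / 2, lo), hi))
  for (i in seq_along(v)[-1]) v[i] <- max(v[i], v[i - 1] + 0.5)
  if (v[length(v)] > hi) {
    v[length(v)] <- hi
    for (i in rev(seq_along(v))[-1]) v[i] <- min(v[i], v[i + 1] - 0.5)
  }
  v
}

#' Six delayed amounts bracketing the indifference point
#'
#' Builds the amount ladder for one delay: symmetric offsets of +/-10%,
#' +/-25% and +/-45% around [indifference_amount()], so three rungs lie
#' strictly below and three strictly above the point at which the chooser
#' values the delayed and the immediate reward equally.  Amounts are rounded
#' to 0.5 EUR and clamped into `[20.5, 79.5]`; collisions created by
#' clamping are nudged apart on the 0.5-EUR grid (symmetry about the
#' indifference point therefore holds before clamping, not necessarily
#' after).
#'
#' @param k Pretest discount rate per day.
#' @param delay Delay in days.
#' @param ref Immediate reference amount in euros (default 20).
#' @param offsets Fractional offsets of the three rung pairs (default
#'   `c(0.10, 0.25, 0.45)`).
#' @param range Allowed amount range in euros (default `c(20.5, 79.5)`).
#' @return Sorted numeric vector of six distinct amounts in euros.
#' @examples
#' build_amount_ladder(0.085, 30)  # centred on 71, top rungs clamped at 79.5
#' @export
build_amount_ladder <- function(k, delay, ref = 20,
                                offsets = c(0.10, 0.25, 0.45),
                                range = c(20.5, 79.5)) {
  if (length(offsets) != 3 || any(offsets <= 0) || any(offsets >= 1)) {
    stop("`offsets` must be three fractions in (0, 1)", call. = FALSE)
  }
  centre <- indifference_amount(k, delay, ref)
  raw <- centre * c(1 - rev(offsets), 1 + offsets)
  snap_ladder(raw, range[1], range[2])
}

#' Build one 36-trial block
#'
#' Crosses the six delay positions with their six-amount ladders: each delay
#' pair contributes six trials, one per ladder rung, and every trial samples
#' its concrete delay uniformly from the pair (the ladder is computed at the
#' sampled delay).  Trial order is shuffled.  The episodic partner slot
#' (which of the two named persons — or placeholder strings in the control
#' condition — accompanies the trial) alternates deterministically before
#' the shuffle.
#'
#' @param k Pretest discount rate per day.
#' @param condition One of [tag_conditions()].
#' @param seed Integer seed; the block is a pure function of its arguments.
#' @param delay_sets Six delay pairs; default [default_delay_sets()].
#' @inheritParams build_amount_ladder
#' @return Tibble of 36 rows: `trial_index`, `condition`, `partner_slot`,
#'   `delay_days`, `amount_eur`.
#' @export
build_block <- function(k, condition, seed, delay_sets = default_delay_sets(),
                        ref = 20, offsets = c(0.10, 0.25, 0.45),
                        range = c(20.5, 79.5)) {
  condition <- as.character(condition)
  if (!condition %in% tag_conditions()) {
    stop("`condition` must be one of ", paste(tag_conditions(), collapse = ", "),
         call. = FALSE)
  }
  check_delay_sets(delay_sets)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(delay_sets, function(pair) {
      delays <- as.integer(sample(pair, 6, replace = TRUE))
      amounts <- purrr::map2_dbl(
        delays, seq_len(6),
        function(d, r) build_amount_ladder(k, d, ref, offsets, range)[r]
      )
      tibble::tibble(delay_days = delays, amount_eur = amounts)
    })
    rows <- rows[sample.int(nrow(rows)), ]
    tibble::tibble(
      trial_index = seq_len(nrow(rows)),
      condition = condition,
      partner_slot = rep_len(c(1L, 2L), nrow(rows)),
      delay_days = rows$delay_days,
      amount_eur = rows$amount_eur
    )
  })
}

#' Build a participant-specific six-block session
#'
#' Constructs the full adaptive trial schedule from a pretest discount rate:
#' six blocks of 36 trials (216 trials), two consecutive blocks per
#' condition, with the order of the three conditions randomised (pattern
#' AABBCC over a random permutation of control/familiar/unfamiliar).  Every
#' block crosses the six delay pairs with per-delay amount ladders centred
#' on the participant's indifference points, the construction that makes a
#' chooser with the same discount rate pick the delayed option on about half
#' the trials.
#'
#' @param k Pretest discount rate per day.
#' @param seed Integer seed; the schedule is a pure function of `(k, seed)`
#'   and the design arguments.
#' @inheritParams build_block
#' @return Tibble of 216 rows (`block_index`, `trial_index`, `condition`,
#'   `partner_slot`, `delay_days`, `amount_eur`) with attributes `k`, `seed`,
#'   `ref`, `offsets`, `condition_order`.
#' @examples
#' sched <- build_session(k = 0.085, seed = 1)
#' dplyr::count(sched, block_index, condition)
#' @export
build_session <- function(k, seed, delay_sets = default_delay_sets(),
                          ref = 20, offsets = c(0.10, 0.25, 0.45),
                          range = c(20.5, 79.5)) {
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  plan <- withr::with_seed(seed, {
    list(order = sample(tag_conditions()),
         block_seeds = sample.int(.Machine$integer.max - 1L, 6))
  })
  cond_by_block <- rep(plan$order, each = 2)
  blocks <- purrr::map_dfr(seq_len(6), function(b) {
    dplyr::mutate(
      build_block(k, cond_by_block[b], plan$block_seeds[b],
                  delay_sets = delay_sets, ref = ref,
                  offsets = offsets, range = range),
      block_index = b, .before = 1
    )
  })
  attr(blocks, "k") <- k
  attr(blocks, "seed") <- seed
  attr(blocks, "ref") <- ref
  attr(blocks, "offsets") <- offsets
  attr(blocks, "condition_order") <- plan$order
  blocks
}
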