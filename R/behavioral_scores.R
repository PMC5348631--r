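check_attention_records <- function(records) {
  needed <- c("condition", "distractor_present", "rt_ms", "correct")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("attention table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"singleton_target" %in% names(records)) {
    records$singleton_target <- FALSE
  }
  records
}

#' Filter valid visual-search trials
#'
#' Removes error trials, missing responses, and responses slower than the
#' 3000-ms window.  The exclusion tally is attached as attribute
#' `"exclusions"` (and available via [singleton_exclusions()]).
#'
#' @param records Attention-trial tibble with columns `condition`,
#'   `distractor_present`, `singleton_target`, `rt_ms`, `correct` (plus any
#'   identifier columns, which are preserved).
#' @param rt_max Response window in ms (default 3000).
#' @return Tibble of valid trials; attribute `"exclusions"` holds a one-row
#'   tibble with `n_total`, `n_excluded`, `pct_excluded`.
#' @export
filter_singleton_trials <- function(records, rt_max = 3000) {
  records <- check_attention_records(records)
  valid <- !is.na(records$rt_ms) & records$rt_ms <= rt_max &
    !is.na(records$correct) & records$correct
  out <- tibble::as_tibble(records[valid, ])
  attr(out, "exclusions") <- tibble::tibble(
    n_total = nrow(records),
    n_excluded = sum(!valid),
    pct_excluded = 100 * sum(!valid) / nrow(records)
  )
  out
}

#' Exclusion report for a search-trial table
#'
#' @param records Raw attention-trial tibble (or the output of
#'   [filter_singleton_trials()], whose cached report is reused).
#' @param rt_max Response window in ms (default 3000).
#' @return One-row tibble with `n_total`, `n_excluded`, `pct_excluded`.
#' @export
singleton_exclusions <- function(records, rt_max = 3000) {
  cached <- attr(records, "exclusions")
  if (!is.null(cached)) return(cached)
  attr(filter_singleton_trials(records, rt_max), "exclusions")
}

#' Distractor cost of one search condition
#'
#' Mean RT on distractor-present trials minus mean RT on distractor-absent
#' trials, over valid trials of the given condition.  Singleton-target
#' trials (where the colour singleton is the target, not a distractor) are
#' excluded.
#'
#' @param records Attention-trial tibble; invalid trials are dropped via
#'   [filter_singleton_trials()].
#' @param condition Which condition (1 = strategic, 2 = flexible).
#' @param center Summary function for the RT means (default `mean`; pass
#'   `median` for a robust variant).
#' @return The RT cost in ms.
#' @export
distraction_cost <- function(records, condition, center = mean) {
  valid <- filter_singleton_trials(check_attention_records(records))
  rows <- valid[valid$condition == condition & !valid$singleton_target, ]
  rt_present <- rows$rt_ms[rows$distractor_present]
  rt_absent <- rows$rt_ms[!rows$distractor_present]
  if (length(rt_present) == 0) {
    stop("no valid distractor-present trials in condition ", condition,
         call. = FALSE)
  }
  if (length(rt_absent) == 0) {
    stop("no valid distractor-absent trials in condition ", condition,
         call. = FALSE)
  }
  center(rt_present) - center(rt_absent)
}

#' Singleton score: flexible minus strategic distractor cost
#'
#' The index of flexible attentional control: the distractor cost in the
#' flexible condition (2) minus the cost in the strategic condition (1).
#' Higher scores mean the subject was slowed more by the singleton exactly
#' when colour could not be strategically ignored — i.e. poorer flexible
#' control.
#'
#' @inheritParams distraction_cost
#' @return The singleton score in ms.
#' @export
singleton_score <- function(records, center = mean) {
  distraction_cost(records, 2, center) - distraction_cost(records, 1, center)
}

#' Per-subject attention scores
#'
#' Tidy wrapper: computes the strategic and flexible distractor costs, the
#' singleton score, and the exclusion percentage for every subject in a
#' multi-subject attention table.
#'
#' @param records Attention-trial tibble with a `subject_id` column.
#' @param center Summary function for RT means (default `mean`).
#' @return Tibble with one row per subject: `subject_id`, `cost_strategic`,
#'   `cost_flexible`, `singleton_score`, `pct_excluded`.
#' @export
score_attention <- function(records, center = mean) {
  if (!"subject_id" %in% names(records)) {
    stop("`records` needs a `subject_id` column", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        cost_strategic = distraction_cost(df, 1, center),
        cost_flexible = distraction_cost(df, 2, center),
        singleton_score = singleton_score(df, center),
        pct_excluded = singleton_exclusions(df)$pct_excluded
      )
    }) |>
    dplyr::ungroup()
}

#' Summarise interview detail counts
#'
#' Aggregates the long rater-by-category tally table into per-familiarity
#' means and SDs of each detail category, of the internal total (sum of the
#' five episodic categories) and of the external score.  The unit of
#' observation is one imagined event (subject x event), after averaging or
#' selecting raters.
#'
#' @param details Long tibble with columns `event_id`, `familiarity`,
#'   `rater`, `category`, `count` (plus optional `subject_id`).
#' @param rater `"mean"` (default) to average the two raters, or `1`/`2` to
#'   use a single rater's counts.
#' @return Tibble with columns `familiarity`, `category` (the five internal
#'   categories, `"internal"`, `"external"`), `mean`, `sd`, `n_events`.
#' @export
tally_details <- function(details, rater = "mean") {
  needed <- c("event_id", "familiarity", "rater", "category", "count")
  missing <- setdiff(needed, names(details))
  if (length(missing) > 0) {
    stop("interview table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(details$category), detail_categories())
  if (length(bad) > 0) {
    stop("unknown detail category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(details$count < 0)) stop("counts must be non-negative", call. = FALSE)

  if (identical(rater, "mean")) {
    per_cell <- details |>
      dplyr::group_by(dplyr::across(dplyr::any_of(
        c("subject_id", "event_id", "familiarity", "category")
      ))) |>
      dplyr::summarise(count = mean(.data$count), .groups = "drop")
  } else {
    rater_int <- as.integer(rater)
    per_cell <- details |>
      dplyr::filter(.data$rater == .env$rater_int) |>
      dplyr::select(dplyr::any_of(
        c("subject_id", "event_id", "familiarity", "category", "count")
      ))
  }
  internal_cats <- detail_categories(include_external = FALSE)
  per_event <- per_cell |>
    dplyr::mutate(count = as.numeric(.data$count)) |>
    tidyr::pivot_wider(names_from = "category", values_from = "count",
                       values_fill = 0)
  for (cat in c(internal_cats, "external")) {
    if (!cat %in% names(per_event)) per_event[[cat]] <- 0
  }
  per_event <- dplyr::mutate(
    per_event,
    internal = rowSums(dplyr::pick(dplyr::all_of(internal_cats)))
  )
  long <- per_event |>
    tidyr::pivot_longer(dplyr::any_of(c(internal_cats, "internal", "external")),
                        names_to = "category", values_to = "count")
  long |>
    dplyr::group_by(.data$familiarity, .data$category) |>
    dplyr::summarise(
      mean = mean(.data$count),
      sd = stats::sd(.data$count),
      n_events = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$familiarity,
                   match(.data$category,
                         c("internal", internal_cats, "external")))
}

#' Cronbach's alpha for two raters
#'
#' Inter-rater reliability of detail counts, treating the two raters as the
#' "items" of a two-item scale over paired observations:
#' `alpha = (m / (m - 1)) * (1 - sum(var_i) / var_total)` with `m = 2` and
#' `var_total` the variance of the raters' sum.  Equals 1 exactly when the
#' raters differ by a constant; can be negative (or far below 0) under
#' disagreement.
#'
#' @param rater1,rater2 Equal-length numeric vectors of paired scores
#'   (e.g. per-event internal detail totals), `n >= 2`.
#' @return Alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) {
    stop("rater score vectors must have equal length", call. = FALSE)
  }
  if (length(rater1) < 2) stop("need at least 2 paired items", call. = FALSE)
  total_var <- stats::var(rater1 + rater2)
  if (total_var == 0) {
    stop("total score variance is zero; alpha is undefined", call. = FALSE)
  }
  2 * (1 - (stats::var(rater1) + stats::var(rater2)) / total_var)
}

#' Per-event rater totals for reliability analysis
#'
#' Reshapes the long interview table into paired per-event totals for the
#' two raters, for internal or external details, across all subjects and
#' events — the item unit on which [cronbach_alpha()] is computed.
#'
#' @param details Long interview tibble (see [tally_details()]).
#' @param which `"internal"` (sum of the five episodic categories, default)
#'   or `"external"`.
#' @return Tibble with one row per event: identifier columns plus `rater1`
#'   and `rater2` totals.
#' @export
rater_totals <- function(details, which = c("internal", "external")) {
  which <- match.arg(which)
  cats <- if (which == "internal") {
    detail_categories(include_external = FALSE)
  } else "external"
  details |>
    dplyr::filter(.data$category %in% cats) |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("subject_id", "event_id", "familiarity", "rater")
    ))) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "rater", values_from = "total",
                       names_prefix = "rater")
}

#' Inter-rater reliability of the interview coding
#'
#' @param details Long interview tibble (see [tally_details()]).
#' @return Tibble with rows `internal` and `external`: `score`, `alpha`,
#'   `n_items`.
#' @export
interview_reliability <- function(details) {
  purrr::map_dfr(c("internal", "external"), function(w) {
    tot <- rater_totals(details, w)
    tibble::tibble(
      score = w,
      alpha = cronbach_alpha(tot$rater1, tot$rater2),
      n_items = nrow(tot)
    )
  })
}
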