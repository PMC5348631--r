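choice_cols <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    delay_days = readr::col_integer(),
    amount_eur = readr::col_double(),
    choice = readr::col_character(),
    rt_ms = readr::col_double()
  )
}

#' Read / write trial-level choice tables
#'
#' One row per intertemporal decision: `subject_id`, `condition`
#' (control/familiar/unfamiliar), `delay_days` (integer), `amount_eur`,
#' `choice` (delayed/immediate), `rt_ms` (may be empty).  UTF-8, `.` decimal
#' separator, header required.
#'
#' @param path File path.
#' @return `read_choices()` returns a validated tibble.
#' @export
read_choices <- function(path) {
  x <- readr::read_csv(path, col_types = choice_cols())
  check_choice_trials(x)
}

#' @rdname read_choices
#' @param x Choice tibble to write.
#' @export
write_choices <- function(x, path) {
  check_choice_trials(x)
  readr::write_csv(
    x[, c("subject_id", "condition", "delay_days", "amount_eur",
          "choice", "rt_ms")],
    path, na = ""
  )
  invisible(path)
}

#' Read / write attention (visual-search) trial tables
#'
#' Columns: `subject_id`, `condition` (1 strategic / 2 flexible),
#' `distractor_present`, `singleton_target`, `rt_ms` (empty = missing
#' response), `correct`.
#'
#' @param path File path.
#' @return `read_attention()` returns a validated tibble.
#' @export
read_attention <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_integer(),
    distractor_present = readr::col_logical(),
    singleton_target = readr::col_logical(),
    rt_ms = readr::col_double(),
    correct = readr::col_logical()
  ))
  check_attention_records(x)
}

#' @rdname read_attention
#' @param x Attention tibble to write.
#' @export
write_attention <- function(x, path) {
  check_attention_records(x)
  readr::write_csv(
    x[, c("subject_id", "condition", "distractor_present",
          "singleton_target", "rt_ms", "correct")],
    path, na = ""
  )
  invisible(path)
}

#' Read / write interview detail-count tables
#'
#' Long format: `subject_id`, `event_id`, `familiarity`
#' (familiar/unfamiliar), `rater` (1/2), `category`, `count`.
#'
#' @param path File path.
#' @return `read_interview()` returns a validated tibble.
#' @export
read_interview <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    event_id = readr::col_character(),
    familiarity = readr::col_character(),
    rater = readr::col_integer(),
    category = readr::col_character(),
    count = readr::col_integer()
  ))
  bad <- setdiff(unique(x$category), detail_categories())
  if (length(bad) > 0) {
    stop("unknown detail category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_interview
#' @param x Interview tibble to write.
#' @export
write_interview <- function(x, path) {
  readr::write_csv(
    x[, c("subject_id", "event_id", "familiarity", "rater",
          "category", "count")],
    path, na = ""
  )
  invisible(path)
}

#' Write / read a trial schedule with its design manifest
#'
#' The schedule CSV carries `block_index`, `trial_index`, `condition`,
#' `partner_slot`, `delay_days`, `amount_eur`; a JSON sidecar
#' (`<path>.json`) records the pretest `k`, the seed, the immediate
#' reference and the ladder offsets so the schedule can be rebuilt
#' byte-identically.
#'
#' @param schedule Output of [build_session()].
#' @param path CSV file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the schedule tibble with manifest fields re-attached as
#'   attributes.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(
    schedule[, c("block_index", "trial_index", "condition", "partner_slot",
                 "delay_days", "amount_eur")],
    path, na = ""
  )
  manifest <- list(
    k = attr(schedule, "k"),
    seed = attr(schedule, "seed"),
    ref = attr(schedule, "ref"),
    offsets = attr(schedule, "offsets"),
    condition_order = attr(schedule, "condition_order")
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    block_index = readr::col_integer(),
    trial_index = readr::col_integer(),
    condition = readr::col_character(),
    partner_slot = readr::col_integer(),
    delay_days = readr::col_integer(),
    amount_eur = readr::col_double()
  ))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    manifest <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (nm in names(manifest)) attr(x, nm) <- manifest[[nm]]
  }
  x
}
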