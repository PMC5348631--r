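#' Load and validate a run configuration
#'
#' A single YAML or JSON file drives every pipeline stage.  Recognised
#' fields: `seed` (integer, required), `out_dir` (required), `design`
#' (optional list: `k`, `ref`, `offsets`), `cohort` (optional list of
#' [cohort_spec()] arguments), `fit` (optional list: `ref`), `anova`
#' (optional list: `correction`).  Unknown top-level fields are rejected so
#' typos fail fast.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or an
#'   already-parsed list.
#' @return Validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(config)
}

config_error <- function(...) {
  stop(structure(
    class = c("tagdisc_config_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

validate_run_config <- function(config) {
  if (!is.list(config)) config_error("config must be a list/mapping")
  allowed <- c("seed", "out_dir", "design", "cohort", "fit", "anova")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    config_error("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      config$seed != round(config$seed)) {
    config_error("`seed` must be an integer")
  }
  if (is.null(config$out_dir) || !is.character(config$out_dir)) {
    config_error("`out_dir` must be a path")
  }
  if (!is.null(config$design)) {
    k <- config$design$k
    if (is.null(k) || !is.numeric(k) || k < 0) {
      config_error("`design$k` must be a non-negative number")
    }
  }
  if (!is.null(config$cohort)) {
    spec <- try(do.call(cohort_spec,
                        c(config$cohort, list(seed = config$seed))),
                silent = TRUE)
    if (inherits(spec, "try-error")) {
      config_error("invalid `cohort` block: ",
                   attr(spec, "condition")$message)
    }
  }
  structure(config, class = c("run_config", "list"))
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

#' Pipeline stage: build a trial schedule
#'
#' Wraps [build_session()]: builds the participant-specific schedule from
#' `design$k` and writes `schedule.csv` (+ JSON manifest) into `out_dir`.
#'
#' @param config A config list/path accepted by [read_run_config()].
#' @return The schedule tibble, invisibly; files are written to `out_dir`.
#' @export
run_design <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$design)) config_error("config has no `design` block")
  out <- ensure_out_dir(config)
  sched <- build_session(
    k = config$design$k,
    seed = config$seed,
    ref = config$design$ref %||% 20,
    offsets = config$design$offsets %||% c(0.10, 0.25, 0.45)
  )
  write_schedule(sched, file.path(out, "schedule.csv"))
  invisible(sched)
}

#' Pipeline stage: simulate a synthetic cohort
#'
#' Wraps [simulate_cohort()]: generates the cohort named by the `cohort`
#' config block and writes `choices.csv`, `attention.csv`, `interview.csv`,
#' `subjects.csv` and a `manifest.json` (spec + seed) into `out_dir`.
#'
#' @inheritParams run_design
#' @return The `"cohort"` object, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  out <- ensure_out_dir(config)
  spec <- do.call(cohort_spec,
                  c(config$cohort, list(seed = config$seed)))
  cohort <- simulate_cohort(spec)
  write_choices(cohort$choices[, c("subject_id", "condition", "delay_days",
                                   "amount_eur", "choice", "rt_ms")],
                file.path(out, "choices.csv"))
  write_attention(cohort$attention, file.path(out, "attention.csv"))
  write_interview(cohort$interview, file.path(out, "interview.csv"))
  readr::write_csv(cohort$subjects, file.path(out, "subjects.csv"), na = "")
  jsonlite::write_json(unclass(spec), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Pipeline stage: fit the discounting model per subject and condition
#'
#' Wraps [fit_all_subjects()] over `choices.csv` in `out_dir` and writes
#' `fits.csv` plus the median/IQR `summary_table.csv`.
#'
#' @inheritParams run_design
#' @return The fits tibble, invisibly.
#' @export
run_fit <- function(config) {
  config <- read_run_config(config)
  out <- ensure_out_dir(config)
  path <- file.path(out, "choices.csv")
  if (!file.exists(path)) {
    stop("missing input file: ", path, " (run the simulate stage first)",
         call. = FALSE)
  }
  choices <- read_choices(path)
  fits <- fit_all_subjects(choices, ref = config$fit$ref %||% 20)
  readr::write_csv(fits, file.path(out, "fits.csv"), na = "")
  readr::write_csv(discount_summary_table(fits, choices),
                   file.path(out, "summary_table.csv"), na = "")
  invisible(fits)
}

#' Pipeline stage: behavioural scores
#'
#' Computes per-subject singleton scores from `attention.csv` and the
#' interview detail summaries and inter-rater reliability from
#' `interview.csv`; writes `scores.csv`, `detail_summary.csv`,
#' `reliability.csv`.
#'
#' @inheritParams run_design
#' @return The per-subject scores tibble, invisibly.
#' @export
run_score <- function(config) {
  config <- read_run_config(config)
  out <- ensure_out_dir(config)
  for (f in c("attention.csv", "interview.csv")) {
    if (!file.exists(file.path(out, f))) {
      stop("missing input file: ", file.path(out, f), call. = FALSE)
    }
  }
  scores <- score_attention(read_attention(file.path(out, "attention.csv")))
  interview <- read_interview(file.path(out, "interview.csv"))
  readr::write_csv(scores, file.path(out, "scores.csv"), na = "")
  readr::write_csv(tally_details(interview),
                   file.path(out, "detail_summary.csv"), na = "")
  readr::write_csv(interview_reliability(interview),
                   file.path(out, "reliability.csv"), na = "")
  invisible(scores)
}

#' Pipeline stage: group-level analysis
#'
#' Joins the fitted parameters, singleton scores and subject covariates and
#' runs [analyze_cohort()]; writes `report.json` with the ANOVA, the
#' correlations and the summary table.
#'
#' @inheritParams run_design
#' @return The `"tag_analysis"` object, invisibly.
#' @export
run_analyze <- function(config) {
  config <- read_run_config(config)
  out <- ensure_out_dir(config)
  for (f in c("fits.csv", "scores.csv", "subjects.csv")) {
    if (!file.exists(file.path(out, f))) {
      stop("missing input file: ", file.path(out, f), call. = FALSE)
    }
  }
  fits <- readr::read_csv(file.path(out, "fits.csv"),
                          col_types = readr::cols())
  scores <- readr::read_csv(file.path(out, "scores.csv"),
                            col_types = readr::cols())
  subjects <- readr::read_csv(file.path(out, "subjects.csv"),
                              col_types = readr::cols())
  scores <- dplyr::inner_join(
    scores, subjects[, c("subject_id", "gender")], by = "subject_id"
  )
  analysis <- analyze_cohort(fits, scores,
                             correction = config$anova$correction %||% "none")
  report <- list(
    anova = as.list(analysis$anova),
    cor_control = as.list(analysis$cor_control),
    cor_tag_effect = as.list(analysis$cor_tag_effect),
    summary_table = analysis$summary_table,
    seed = config$seed
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(analysis)
}

#' Run the full pipeline
#'
#' `simulate -> fit -> score -> analyze` on one config; equivalent to
#' calling the four stages in order.
#'
#' @inheritParams run_design
#' @return The `"tag_analysis"` object, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  run_simulate(config)
  run_fit(config)
  run_score(config)
  run_analyze(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
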