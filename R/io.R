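session_schema_cols <- c("subject_id", "genotype", "sex", "session_id",
                         "trial_index", "block_index", "high_side", "choice",
                         "rewarded", "iti_s", "nolick_s")

#' Write a session log to CSV
#'
#' Writes the canonical session-log schema: one row per trial, columns
#' `subject_id, genotype, sex, session_id, trial_index, block_index,
#' high_side, choice, rewarded, iti_s, nolick_s`. UTF-8, comma-separated,
#' `.` decimal, LF line endings; missing numeric values are written empty.
#'
#' @param trials Trial tibble (a session, or the `trials` element of a
#'   cohort); extra columns are dropped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path) {
  missing_cols <- setdiff(session_schema_cols, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- trials[, session_schema_cols]
  readr::write_csv(out, path, na = "", eol = "\n")
  invisible(path)
}

schema_error <- function(row, msg) {
  # +1 for the header: report the physical line in the file
  stop(sprintf("session log schema error at line %d: %s", row + 1L, msg),
       call. = FALSE)
}

check_enum <- function(x, allowed, col) {
  bad <- which(!x %in% allowed)
  if (length(bad) > 0) {
    schema_error(bad[1], sprintf("invalid %s '%s' (allowed: %s)",
                                 col, x[bad[1]], paste(allowed, collapse = ", ")))
  }
}

parse_num <- function(x, col, allow_na = TRUE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  if (length(bad) > 0) {
    schema_error(bad[1], sprintf("non-numeric %s '%s'", col, x[bad[1]]))
  }
  if (!allow_na) {
    miss <- which(is.na(v))
    if (length(miss) > 0) schema_error(miss[1], sprintf("missing %s", col))
  }
  v
}

#' Read a session log CSV
#'
#' Parses and validates the canonical session-log schema, reporting the
#' offending line number for malformed rows (unknown columns, invalid
#' enums, non-numeric values, non-monotone trial indices). An empty file
#' with a valid header yields an empty tibble.
#'
#' @param path Path to a session-log CSV.
#' @return A trial tibble with typed columns.
#' @export
read_sessions <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  unknown <- setdiff(names(raw), session_schema_cols)
  if (length(unknown) > 0) {
    stop("unknown session log column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(session_schema_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing session log column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      subject_id = character(0), genotype = character(0), sex = character(0),
      session_id = character(0), trial_index = integer(0),
      block_index = integer(0), high_side = character(0),
      choice = character(0), rewarded = logical(0),
      iti_s = numeric(0), nolick_s = numeric(0)
    ))
  }
  check_enum(raw$genotype, c("WT", "HET"), "genotype")
  check_enum(raw$sex, c("M", "F"), "sex")
  check_enum(raw$high_side, c("left", "right"), "high_side")
  check_enum(raw$choice, c("left", "right", "none"), "choice")
  check_enum(raw$rewarded, c("TRUE", "FALSE", "true", "false"), "rewarded")

  trials <- tibble::tibble(
    subject_id = raw$subject_id,
    genotype = raw$genotype,
    sex = raw$sex,
    session_id = raw$session_id,
    trial_index = as.integer(parse_num(raw$trial_index, "trial_index",
                                       allow_na = FALSE)),
    block_index = as.integer(parse_num(raw$block_index, "block_index",
                                       allow_na = FALSE)),
    high_side = raw$high_side,
    choice = raw$choice,
    rewarded = toupper(raw$rewarded) == "TRUE",
    iti_s = parse_num(raw$iti_s, "iti_s"),
    nolick_s = parse_num(raw$nolick_s, "nolick_s")
  )
  bad_iti <- which(trials$iti_s < 0)
  if (length(bad_iti) > 0) schema_error(bad_iti[1], "negative iti_s")
  bad_rew <- which(trials$rewarded & trials$choice == "none")
  if (length(bad_rew) > 0) {
    schema_error(bad_rew[1], "rewarded trial with choice 'none'")
  }
  # trial_index must increase by 1 within each session
  ord <- trials |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::mutate(.step = .data$trial_index - dplyr::lag(.data$trial_index)) |>
    dplyr::ungroup()
  bad_step <- which(!is.na(ord$.step) & ord$.step != 1)
  if (length(bad_step) > 0) {
    schema_error(ord$.row[bad_step[1]], "non-monotone trial_index")
  }
  trials
}

#' Write / read the subject metadata table
#'
#' @param subjects Tibble with `subject_id`, `genotype`, `sex`, `seizure`.
#' @param path File path.
#' @return `path` (write) or the subjects tibble (read).
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path, na = "", eol = "\n")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    genotype = readr::col_character(),
    sex = readr::col_character(),
    seizure = readr::col_logical()
  ), progress = FALSE)
}

#' Write a cohort to a directory
#'
#' Writes `sessions.csv` (session-log schema) and `subjects.csv`.
#'
#' @param cohort A `forage_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sessions(cohort$trials, file.path(dir, "sessions.csv"))
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}

#' Read a cohort spec from YAML
#'
#' Fields mirror [cohort_spec()]; `agent_spec` is a mapping with `type` and
#' `params`, `latency` a mapping with the [latency_model()] fields, and
#' `curriculum` a sequence of preset names.
#'
#' @param path Path to a YAML file.
#' @return A `forage_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$curriculum)) raw$curriculum <- unlist(raw$curriculum)
  if (!is.null(raw$latency)) raw$latency <- do.call(latency_model, raw$latency)
  do.call(cohort_spec, raw)
}
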