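#' Read a longitudinal cohort table from CSV
#'
#' Reads a flat CSV with one row per subject x age x eye measurement:
#' retinal layer thicknesses (in image pixels) and novel-object-recognition
#' exploration times (in seconds). The expected columns are `subject_id`,
#' `age_months`, `eye` (`left`, `right` or `averaged`), `nfl_gcl_ipl`, `inl`,
#' `onl`, `tr`, `t_novel`, `t_familiar`, `t_total`. Numbers must use the dot
#' decimal separator.
#'
#' @param path Path to a CSV file with a header row.
#' @param schedule Ordered vector of expected visit ages in months; attached
#'   to the returned table as the `"schedule"` attribute.
#' @param validate If `TRUE` (default), run [validate_cohort()] and abort when
#'   any error-level finding is present.
#' @return A tibble with the columns above, one row per record, row order
#'   preserved, with attribute `"schedule"`.
#' @seealso [validate_cohort()], [write_cohort()]
#' @export
read_cohort <- function(path, schedule = c(4, 6, 9), validate = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "retinocog_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      eye = readr::col_character(),
      .default = readr::col_double()
    ),
    locale = readr::locale(decimal_mark = "."),
    progress = FALSE,
    show_col_types = FALSE
  )
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("cohort CSV is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "retinocog_schema_error"
    )
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    first <- probs[1, ]
    abort(
      sprintf(
        "could not parse cohort CSV: %d problem(s); first at line %d, column %d (expected %s, got '%s')",
        nrow(probs), first$row + 1L, first$col, first$expected, first$actual
      ),
      class = "retinocog_parse_error"
    )
  }
  cohort <- as_tibble(raw[, cohort_columns])
  dup <- duplicated(cohort[, c("subject_id", "age_months", "eye")])
  if (any(dup)) {
    d <- cohort[which(dup)[1], ]
    abort(
      sprintf(
        "duplicate (subject_id, age_months, eye) record: (%s, %s, %s)",
        d$subject_id, format(d$age_months), d$eye
      ),
      class = "retinocog_uniqueness_error"
    )
  }
  attr(cohort, "schedule") <- sort(as.numeric(schedule))
  if (validate) {
    findings <- validate_cohort(cohort)
    errs <- findings[findings$severity == "error", ]
    if (nrow(errs) > 0) {
      abort(
        paste0(
          "cohort fails validation with ", nrow(errs), " error(s); first: ",
          errs$message[1]
        ),
        class = "retinocog_validation_error"
      )
    }
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: full double precision is preserved so a
#' write-then-read round trip reproduces every numeric field exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[, cohort_columns], path, progress = FALSE)
  invisible(path)
}

cohort_schedule <- function(cohort, schedule = NULL) {
  s <- schedule %||% attr(cohort, "schedule") %||% c(4, 6, 9)
  sort(as.numeric(s))
}

new_finding <- function(severity, rule, subject_id, age_months, message) {
  tibble(
    severity = severity, rule = rule,
    subject_id = as.character(subject_id),
    age_months = as.numeric(age_months),
    message = message
  )
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a longitudinal cohort and returns the
#' findings as data rather than raising conditions, so callers can decide
#' what is fatal. Error-level findings are violations of hard invariants:
#' negative thicknesses, total retina thinner than the inner nuclear layer,
#' exploration components exceeding the total exploration time, non-positive
#' total time, ages outside the visit schedule, duplicated
#' (subject, age, eye) rows, and behavioural times that differ between the two
#' eyes of the same (subject, age) — behaviour is measured per animal, not per
#' eye. Warning-level findings flag subjects missing a scheduled visit or an
#' eye at a visit; downstream eye averaging falls back to the available eye.
#'
#' The function is pure: it never modifies the cohort, and re-running it on
#' the same input returns the same findings.
#'
#' @param cohort A cohort tibble as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param schedule Expected visit ages; defaults to the cohort's `"schedule"`
#'   attribute, then to `c(4, 6, 9)`.
#' @return A tibble of findings with columns `severity` (`"error"` or
#'   `"warning"`), `rule`, `subject_id`, `age_months` and `message`. Zero rows
#'   iff every invariant holds and no visit/eye is missing.
#' @export
validate_cohort <- function(cohort, schedule = NULL) {
  schedule <- cohort_schedule(cohort, schedule)
  findings <- list()
  add <- function(f) findings[[length(findings) + 1L]] <<- f

  for (col in c(layer_columns, "t_novel", "t_familiar")) {
    bad <- which(cohort[[col]] < 0 | !is.finite(cohort[[col]]))
    for (i in bad) {
      add(new_finding(
        "error", "nonnegative",
        cohort$subject_id[i], cohort$age_months[i],
        sprintf("%s must be finite and >= 0 (got %s)", col, format(cohort[[col]][i]))
      ))
    }
  }
  bad <- which(!is.finite(cohort$t_total) | cohort$t_total <= 0)
  for (i in bad) {
    add(new_finding(
      "error", "positive_total_time",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("t_total must be finite and > 0 (got %s)", format(cohort$t_total[i]))
    ))
  }
  bad <- which(cohort$tr < cohort$inl)
  for (i in bad) {
    add(new_finding(
      "error", "tr_contains_inl",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("tr (%s) < inl (%s): total retina must contain the INL",
              format(cohort$tr[i]), format(cohort$inl[i]))
    ))
  }
  # small tolerance: times are typically transcribed at limited precision
  slack <- 1e-8
  bad <- which(cohort$t_novel + cohort$t_familiar > cohort$t_total * (1 + slack) + slack)
  for (i in bad) {
    add(new_finding(
      "error", "exploration_components",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("t_novel + t_familiar (%s) exceeds t_total (%s)",
              format(cohort$t_novel[i] + cohort$t_familiar[i]),
              format(cohort$t_total[i]))
    ))
  }
  bad <- which(!(cohort$age_months %in% schedule))
  for (i in bad) {
    add(new_finding(
      "error", "age_in_schedule",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("age %s months is not in the visit schedule (%s)",
              format(cohort$age_months[i]), paste(schedule, collapse = ", "))
    ))
  }
  bad <- which(!(cohort$eye %in% c("left", "right", "averaged")))
  for (i in bad) {
    add(new_finding(
      "error", "eye_label",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("eye must be left/right/averaged (got '%s')", cohort$eye[i])
    ))
  }
  dup <- duplicated(cohort[, c("subject_id", "age_months", "eye")])
  for (i in which(dup)) {
    add(new_finding(
      "error", "unique_record",
      cohort$subject_id[i], cohort$age_months[i],
      sprintf("duplicate record for (%s, %s, %s)",
              cohort$subject_id[i], format(cohort$age_months[i]), cohort$eye[i])
    ))
  }

  visits <- dplyr::group_by(cohort, .data$subject_id, .data$age_months)
  visits <- dplyr::summarise(
    visits,
    n_eyes = dplyr::n(),
    any_averaged = any(.data$eye == "averaged"),
    behav_consistent = dplyr::n_distinct(.data$t_novel) == 1 &&
      dplyr::n_distinct(.data$t_familiar) == 1 &&
      dplyr::n_distinct(.data$t_total) == 1,
    .groups = "drop"
  )
  for (i in which(!visits$behav_consistent)) {
    add(new_finding(
      "error", "behaviour_per_animal",
      visits$subject_id[i], visits$age_months[i],
      "behavioural times differ between eyes of the same (subject, age)"
    ))
  }
  for (i in which(visits$n_eyes == 1 & !visits$any_averaged)) {
    add(new_finding(
      "warning", "missing_eye",
      visits$subject_id[i], visits$age_months[i],
      "only one eye measured at this visit; averaging will use it alone"
    ))
  }
  per_subject <- split(visits$age_months, visits$subject_id)
  for (sid in names(per_subject)) {
    absent <- setdiff(schedule, per_subject[[sid]])
    for (a in absent) {
      add(new_finding(
        "warning", "missing_visit", sid, a,
        sprintf("subject %s has no record at scheduled age %s months", sid, format(a))
      ))
    }
  }

  if (length(findings) == 0) {
    return(new_finding(character(), character(), character(), numeric(), character()))
  }
  dplyr::bind_rows(findings)
}
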