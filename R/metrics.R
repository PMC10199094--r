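#' Novel-object-recognition discrimination index
#'
#' The discrimination index (DI) is the difference between the time spent
#' exploring the novel object and the time spent with the familiar object,
#' divided by the total exploration time: `(t_novel - t_familiar) / t_total`.
#' It is dimensionless, bounded in `[-1, 1]`, scale-invariant (multiplying all
#' three times by a positive constant leaves it unchanged), and higher values
#' indicate better recognition memory.
#'
#' @param t_novel,t_familiar,t_total Exploration times in seconds; vectors are
#'   recycled by the usual rules. `t_total` must be positive and
#'   `t_novel + t_familiar` must not exceed it.
#' @return Numeric vector of discrimination indices in `[-1, 1]`.
#' @examples
#' discrimination_index(15, 5, 20)   # 0.5
#' discrimination_index(10, 10, 20)  # 0
#' @export
discrimination_index <- function(t_novel, t_familiar, t_total) {
  if (any(!is.finite(t_total)) || any(t_total <= 0)) {
    abort("t_total must be finite and > 0", class = "retinocog_domain_error")
  }
  if (any(t_novel < 0) || any(t_familiar < 0)) {
    abort("exploration times must be >= 0", class = "retinocog_domain_error")
  }
  if (any(t_novel + t_familiar > t_total * (1 + 1e-8) + 1e-8)) {
    abort("t_novel + t_familiar exceeds t_total", class = "retinocog_domain_error")
  }
  (t_novel - t_familiar) / t_total
}

#' Append a discrimination-index column to a cohort table
#'
#' @param cohort A cohort tibble.
#' @return The cohort with an extra `di` column.
#' @export
add_discrimination_index <- function(cohort) {
  dplyr::mutate(
    cohort,
    di = discrimination_index(.data$t_novel, .data$t_familiar, .data$t_total)
  )
}

#' Paired left-right eye difference check
#'
#' Before averaging the two eyes, checks per retinal layer whether thickness
#' differs systematically between the left and right eye, using a paired
#' two-sided t-test on (subject, age) pairs where both eyes were measured.
#' Averaging eyes is only justified when no lateral difference is detectable.
#' A degenerate all-zero difference vector is reported as `statistic = 0`,
#' `p_value = 1` (no difference detectable, not an error).
#'
#' @param cohort A cohort tibble with `left`/`right` eye rows.
#' @return A tibble with one row per layer: `layer`, `n_pairs`, `mean_diff`
#'   (left minus right, pixels), `statistic`, `p_value`.
#' @export
eye_difference_test <- function(cohort) {
  wide <- tidyr::pivot_wider(
    cohort[cohort$eye %in% c("left", "right"),
           c("subject_id", "age_months", "eye", layer_columns)],
    names_from = "eye",
    values_from = dplyr::all_of(layer_columns)
  )
  purrr::map_dfr(layer_columns, function(layer) {
    lcol <- paste0(layer, "_left")
    rcol <- paste0(layer, "_right")
    if (!all(c(lcol, rcol) %in% names(wide))) {
      return(tibble(layer = layer, n_pairs = 0L, mean_diff = NA_real_,
                    statistic = NA_real_, p_value = NA_real_))
    }
    d <- wide[[lcol]] - wide[[rcol]]
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 2 || sd(d) == 0) {
      p <- if (n > 0 && all(d == 0)) 1 else NA_real_
      return(tibble(layer = layer, n_pairs = n,
                    mean_diff = if (n > 0) mean(d) else NA_real_,
                    statistic = if (!is.na(p)) 0 else NA_real_, p_value = p))
    }
    tt <- t.test(d, mu = 0)
    tibble(layer = layer, n_pairs = n, mean_diff = mean(d),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  })
}

#' Average the two eyes of each subject-age visit
#'
#' Collapses left/right rows to a single `eye = "averaged"` row per
#' (subject, age): each layer thickness becomes the arithmetic mean of the
#' available eyes, and the behavioural times (identical across eyes by
#' construction) are passed through. A visit with a single measured eye uses
#' that eye alone, with a warning.
#'
#' @param cohort A cohort tibble.
#' @return A cohort tibble with one `averaged` row per (subject, age), sorted
#'   by subject then age; the `"schedule"` attribute is preserved.
#' @export
average_eyes <- function(cohort) {
  if (nrow(cohort) == 0) {
    abort("cannot average an empty cohort", class = "retinocog_domain_error")
  }
  one_eyed <- dplyr::count(cohort, .data$subject_id, .data$age_months)
  if (any(one_eyed$n < 2)) {
    warn(sprintf(
      "%d visit(s) have a single measured eye; using the available eye",
      sum(one_eyed$n < 2)
    ))
  }
  out <- dplyr::group_by(cohort, .data$subject_id, .data$age_months)
  out <- dplyr::summarise(
    out,
    eye = "averaged",
    dplyr::across(dplyr::all_of(layer_columns), mean),
    t_novel = .data$t_novel[1],
    t_familiar = .data$t_familiar[1],
    t_total = .data$t_total[1],
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$age_months)
  out <- out[, cohort_columns]
  attr(out, "schedule") <- attr(cohort, "schedule")
  out
}

#' Rolling monthly change between two visits
#'
#' `(value_to - value_from) / (age_to - age_from)`: the average change per
#' month over the interval. Applied to discrimination indices it has units of
#' DI per month; applied to layer thicknesses, pixels per month.
#'
#' @param value_from,value_to Values at the earlier and later visit.
#' @param age_from,age_to Ages in months; `age_to` must exceed `age_from`.
#' @return Numeric change per month.
#' @export
monthly_change <- function(value_from, value_to, age_from, age_to) {
  if (any(age_to <= age_from)) {
    abort("age_to must be strictly greater than age_from",
          class = "retinocog_domain_error")
  }
  (value_to - value_from) / (age_to - age_from)
}

#' Build the per-interval change table
#'
#' Transforms an eye-averaged cohort into one record per subject per adjacent
#' pair of scheduled visits (4 to 6 and 6 to 9 months by default), holding the
#' rolling monthly change in the discrimination index (`d_di`) and in each
#' retinal layer (`d_nfl_gcl_ipl`, `d_inl`, `d_onl`, `d_tr`). Subjects missing
#' a visit contribute only the intervals they complete; non-adjacent visit
#' pairs are never differenced.
#'
#' @param cohort A cohort tibble; if it still carries left/right eye rows it
#'   is passed through [average_eyes()] first.
#' @param schedule Visit schedule in months (default taken from the cohort
#'   attribute, then `c(4, 6, 9)`).
#' @return A tibble with columns `subject_id`, `age_from`, `age_to`, `d_di`,
#'   `d_nfl_gcl_ipl`, `d_inl`, `d_onl`, `d_tr`.
#' @export
build_change_table <- function(cohort, schedule = NULL) {
  schedule <- cohort_schedule(cohort, schedule)
  empty <- tibble(
    subject_id = character(), age_from = numeric(), age_to = numeric(),
    d_di = numeric(), d_nfl_gcl_ipl = numeric(), d_inl = numeric(),
    d_onl = numeric(), d_tr = numeric()
  )
  if (nrow(cohort) == 0) return(empty)
  if (any(cohort$eye != "averaged")) cohort <- average_eyes(cohort)
  cohort <- add_discrimination_index(cohort)

  pairs <- tibble(age_from = schedule[-length(schedule)], age_to = schedule[-1])
  rows <- purrr::pmap_dfr(pairs, function(age_from, age_to) {
    a <- cohort[cohort$age_months == age_from, ]
    b <- cohort[cohort$age_months == age_to, ]
    j <- dplyr::inner_join(a, b, by = "subject_id", suffix = c("_from", "_to"))
    if (nrow(j) == 0) return(empty)
    span <- age_to - age_from
    tibble(
      subject_id = j$subject_id,
      age_from = age_from, age_to = age_to,
      d_di = (j$di_to - j$di_from) / span,
      d_nfl_gcl_ipl = (j$nfl_gcl_ipl_to - j$nfl_gcl_ipl_from) / span,
      d_inl = (j$inl_to - j$inl_from) / span,
      d_onl = (j$onl_to - j$onl_from) / span,
      d_tr = (j$tr_to - j$tr_from) / span
    )
  })
  dplyr::arrange(rows, .data$subject_id, .data$age_from)
}
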