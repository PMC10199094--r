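#' Run the full diagnostic-test pipeline
#'
#' Executes, in order: cohort validation; the paired left-right eye
#' difference check and eye averaging; discrimination indices; per-layer
#' whole-value regressions of thickness on DI; group comparisons of layer
#' thickness between positive- and negative-DI visits (normality-gated test
#' dispatch); the per-interval change table; multiple regression of the DI
#' monthly change on the candidate layer monthly changes (with VIFs, the
#' ANOVA partition and the parameter correlation matrix); selection of the
#' biomarker layer as the predictor with the smallest coefficient p-value;
#' the simple layer-change-on-DI-change regression; DSM-V threshold
#' derivation at `k` SDs; classification; the 2x2 contingency table; and
#' Fisher's exact test plus the full diagnostic metric battery.
#'
#' Total retinal thickness is never offered as a predictor: it is a compound
#' of the individual layers, already well modelled by the NFL-GCL-IPL
#' composite, and including it would only inject collinearity.
#'
#' @param cohort A cohort tibble ([read_cohort()], [simulate_cohort()],
#'   [reference_cohort()]).
#' @param schedule Visit schedule in months (default: cohort attribute).
#' @param alpha Significance level for test dispatch and layer selection.
#' @param k Number of SDs below the mean for the CI threshold.
#' @param predictor_layers Candidate biomarker layers, a subset of
#'   `c("nfl_gcl_ipl", "inl", "onl")`.
#' @param thresholds Optional fixed `c(ci, biomarker)` threshold pair (DI per
#'   month, pixels per month); when supplied, classification uses these
#'   instead of the data-derived thresholds (the derived ones are still
#'   reported).
#' @param out_dir Optional directory; when given, the stage artifacts are
#'   written there (`cohort.csv`, `changes.csv`, `regression_tables.json`,
#'   `thresholds.json`, `contingency.json`, `diagnostics.json`).
#' @return A `pipeline_result` list with elements `validation`,
#'   `eye_difference`, `cohort_averaged`, `whole_value_fits`,
#'   `group_comparisons`, `changes`, `multiple_fit`, `selected_layer`,
#'   `simple_fit`, `thresholds`, `classified`, `contingency`, `report`.
#' @export
run_pipeline <- function(cohort,
                         schedule = NULL,
                         alpha = 0.05,
                         k = 1,
                         predictor_layers = c("nfl_gcl_ipl", "inl", "onl"),
                         thresholds = NULL,
                         out_dir = NULL) {
  predictor_layers <- match.arg(predictor_layers,
                                c("nfl_gcl_ipl", "inl", "onl"),
                                several.ok = TRUE)
  schedule <- cohort_schedule(cohort, schedule)
  attr(cohort, "schedule") <- schedule

  validation <- validate_cohort(cohort)
  errs <- validation[validation$severity == "error", ]
  if (nrow(errs) > 0) {
    abort(paste0("pipeline aborted at validation: ", errs$message[1]),
          class = "retinocog_validation_error")
  }

  has_eyes <- any(cohort$eye %in% c("left", "right"))
  eye_difference <- if (has_eyes) eye_difference_test(cohort) else NULL
  averaged <- if (has_eyes) average_eyes(cohort) else cohort
  averaged <- add_discrimination_index(averaged)

  # whole-value trendlines: layer thickness against DI at matched visits
  whole_value_fits <- purrr::map(
    setNames(layer_columns, layer_columns),
    function(layer) fit_simple_regression(averaged, !!rlang::sym("di"),
                                          !!rlang::sym(layer))
  )

  # thickness grouped by DI sign, normality-gated dispatch
  grouped <- dplyr::mutate(
    averaged,
    di_sign = factor(ifelse(.data$di >= 0, "positive", "negative"),
                     levels = c("positive", "negative"))
  )
  group_comparisons <- purrr::map(
    setNames(layer_columns, layer_columns),
    function(layer) {
      counts <- table(grouped$di_sign)
      if (length(counts) < 2 || any(counts < 3)) return(NULL)
      compare_groups(grouped, !!rlang::sym(layer), !!rlang::sym("di_sign"),
                     alpha = alpha)
    }
  )

  changes <- build_change_table(averaged, schedule)
  if (nrow(changes) < 3) {
    abort("pipeline aborted at change table: fewer than 3 interval records",
          class = "retinocog_domain_error")
  }

  # Table-1 orientation: DI change is the response, layer changes predictors
  pred_cols <- paste0("d_", predictor_layers)
  if (length(pred_cols) > 1) {
    multiple_fit <- fit_multiple_regression(changes, !!rlang::sym("d_di"),
                                            pred_cols)
    ps <- multiple_fit$beta_ps[pred_cols]
    selected_layer <- predictor_layers[which.min(ps)]
    if (min(ps) >= alpha) {
      warn(sprintf(
        "no layer coefficient is significant at alpha = %g; selecting '%s' (smallest p = %.4g)",
        alpha, selected_layer, min(ps)
      ))
    }
  } else {
    multiple_fit <- NULL
    selected_layer <- predictor_layers
  }

  simple_fit <- fit_simple_regression(
    changes, !!rlang::sym("d_di"), !!rlang::sym(paste0("d_", selected_layer))
  )

  spec <- derive_thresholds(changes, layer = selected_layer, k = k,
                            fit = simple_fit)
  if (!is.null(thresholds)) {
    if (length(thresholds) != 2 || any(!is.finite(thresholds))) {
      abort("thresholds must be two finite numbers (ci, biomarker)",
            class = "retinocog_domain_error")
    }
    spec$ci_threshold <- thresholds[1]
    spec$biomarker_threshold <- thresholds[2]
  }

  classified <- classify_changes(changes, spec)
  contingency <- build_contingency(classified)
  report <- diagnostic_report(contingency)

  result <- structure(
    list(
      validation = validation,
      eye_difference = eye_difference,
      cohort_averaged = averaged,
      whole_value_fits = whole_value_fits,
      group_comparisons = group_comparisons,
      changes = changes,
      multiple_fit = multiple_fit,
      selected_layer = selected_layer,
      simple_fit = simple_fit,
      thresholds = spec,
      classified = classified,
      contingency = contingency,
      report = report
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Diagnostic pipeline result (%d subjects, %d interval records)\n",
              dplyr::n_distinct(x$changes$subject_id), nrow(x$changes)))
  cat(sprintf("Selected biomarker layer: %s\n\n", toupper(x$selected_layer)))
  print(x$thresholds)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort_averaged[, cohort_columns],
               file.path(out_dir, "cohort.csv"))
  readr::write_csv(result$changes, file.path(out_dir, "changes.csv"),
                   progress = FALSE)
  readr::write_csv(result$classified, file.path(out_dir, "classified.csv"),
                   progress = FALSE)

  reg <- list(
    whole_value = purrr::map(result$whole_value_fits, function(f) {
      list(slope = f$slope, intercept = f$intercept, r2 = f$r2,
           slope_p = f$slope_p, n = f$n)
    }),
    change_on_di = list(
      layer = result$selected_layer,
      slope = result$simple_fit$slope,
      intercept = result$simple_fit$intercept,
      r2 = result$simple_fit$r2,
      slope_p = result$simple_fit$slope_p,
      n = result$simple_fit$n
    )
  )
  if (!is.null(result$multiple_fit)) {
    mf <- result$multiple_fit
    reg$multiple <- list(
      betas = as.list(mf$betas), beta_ps = as.list(mf$beta_ps),
      vif = as.list(mf$vif), r2_other = as.list(mf$r2_other),
      multiple_r = mf$multiple_r, r2 = mf$r2, adj_r2 = mf$adj_r2,
      anova = mf$anova,
      param_corr = unclass(round(mf$param_corr, 4))
    )
  }
  jsonlite::write_json(reg, file.path(out_dir, "regression_tables.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(as.list(tidy(result$thresholds)),
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(tp = result$contingency$tp, fn = result$contingency$fn,
         fp = result$contingency$fp, tn = result$contingency$tn),
    file.path(out_dir, "contingency.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  report_to_json(result$report, file.path(out_dir, "diagnostics.json"))
  invisible(out_dir)
}
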