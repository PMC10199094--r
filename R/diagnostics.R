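#' Build the 2x2 contingency table of classified change records
#'
#' Cross-tabulates condition against test result under the test-of-health
#' polarity: the condition-positive state is *no cognitive impairment*, so a
#' true positive is a record that is `no_CI` and tests `positive`
#' (predicted healthy), and a true negative is `CI` and `negative`.
#'
#' @param classified A data frame with factor columns `ncd_status`
#'   (`no_CI`/`CI`) and `test_result` (`positive`/`negative`), as produced by
#'   [classify_changes()].
#' @return A `contingency_2x2` object with integer counts `tp` (no_CI &
#'   positive), `fn` (no_CI & negative), `fp` (CI & positive), `tn` (CI &
#'   negative). Supports `as.matrix()` and [tidy()].
#' @export
build_contingency <- function(classified) {
  if (nrow(classified) == 0) {
    abort("cannot build a contingency table from zero records",
          class = "retinocog_domain_error")
  }
  if (!all(c("ncd_status", "test_result") %in% names(classified))) {
    abort("classified records need 'ncd_status' and 'test_result' columns",
          class = "retinocog_domain_error")
  }
  s <- classified$ncd_status
  r <- classified$test_result
  new_contingency(
    tp = sum(s == "no_CI" & r == "positive"),
    fn = sum(s == "no_CI" & r == "negative"),
    fp = sum(s == "CI" & r == "positive"),
    tn = sum(s == "CI" & r == "negative")
  )
}

#' Construct a contingency table from counts
#'
#' @param tp,fn,fp,tn Nonnegative integer cell counts; `tp` = condition
#'   positive (no CI) & test positive, `fn` = no CI & negative, `fp` = CI &
#'   positive, `tn` = CI & negative.
#' @return A `contingency_2x2` object.
#' @export
new_contingency <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be nonnegative integers",
          class = "retinocog_domain_error")
  }
  if (sum(cells) == 0) {
    abort("contingency table must contain at least one record",
          class = "retinocog_domain_error")
  }
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "contingency_2x2")
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(
    c(x$tp, x$fn, x$fp, x$tn),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      condition = c("no_CI", "CI"),
      test = c("positive", "negative")
    )
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 contingency table (condition = no_CI; test-of-health polarity)\n")
  print(as.matrix(x))
  invisible(x)
}

#' @rdname build_contingency
#' @param x A `contingency_2x2` (for the method).
#' @param ... Unused.
#' @method tidy contingency_2x2
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble(
    condition = c("no_CI", "no_CI", "CI", "CI"),
    test = c("positive", "negative", "positive", "negative"),
    cell = c("tp", "fn", "fp", "tn"),
    count = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Conditions on both margins of the 2x2 table and enumerates every table
#' compatible with them; the two-sided p-value is the sum of hypergeometric
#' point probabilities of all tables at most as probable as the observed one
#' (the "method of small p-values"). A relative guard of `1 + 1e-7` absorbs
#' floating-point ties when comparing point probabilities. Degenerate margins
#' that admit a single table give p = 1.
#'
#' @param table A `contingency_2x2`, a 2x2 matrix, or a length-4 count vector
#'   `(tp, fn, fp, tn)`.
#' @return The two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(new_contingency(18, 3, 0, 3))  # 0.0099
#' @export
fisher_exact_two_sided <- function(table) {
  m <- contingency_cells(table)
  a <- m[1]; b <- m[2]; c_ <- m[3]; d <- m[4]
  row1 <- a + b
  col1 <- a + c_
  n <- a + b + c_ + d
  lo <- max(0, col1 - (n - row1))
  hi <- min(row1, col1)
  support <- lo:hi
  probs <- dhyper(support, row1, n - row1, col1)
  p_obs <- dhyper(a, row1, n - row1, col1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

contingency_cells <- function(table) {
  if (inherits(table, "contingency_2x2")) {
    return(c(table$tp, table$fn, table$fp, table$tn))
  }
  if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    return(c(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  }
  if (is.numeric(table) && length(table) == 4) {
    return(as.numeric(table))
  }
  abort("expected a contingency_2x2, a 2x2 matrix, or 4 counts",
        class = "retinocog_domain_error")
}

safe_ratio <- function(num, den) {
  # Inf for x/0 with x > 0 (as printed in diagnostic summaries); NaN for 0/0
  # and for anything built on an already-undefined quantity
  if (is.nan(num) || is.nan(den)) {
    NaN
  } else if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
}

#' Basic diagnostic test parameters
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, diagnostic odds ratio `(tp*tn)/(fp*fn)`, positive
#' likelihood ratio `sensitivity/(1-specificity)`, relative risk (proportion
#' condition-positive among test-positives over that among test-negatives,
#' `[tp/(tp+fp)] / [fn/(fn+tn)]`), and the condition-negative (CI)
#' prevalence `(fp+tn)/total`. Remember the polarity: condition-positive is
#' *no CI*, so sensitivity is the probability that a healthy record tests
#' positive. A zero denominator under a nonzero numerator yields `Inf`
#' (reported as "Infinity"); `0/0` yields `NaN` and is flagged.
#'
#' @param table A `contingency_2x2` (or matrix / 4 counts).
#' @return A tibble with columns `metric`, `value`.
#' @export
basic_diagnostics <- function(table) {
  m <- contingency_cells(table)
  tp <- m[1]; fn <- m[2]; fp <- m[3]; tn <- m[4]
  total <- tp + fn + fp + tn
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "rr", "dor",
               "lr_positive", "prevalence_ci"),
    value = c(
      sens,
      spec,
      safe_ratio(tp, tp + fp),
      safe_ratio(tn, tn + fn),
      safe_ratio(safe_ratio(tp, tp + fp), safe_ratio(fn, fn + tn)),
      safe_ratio(tp * tn, fp * fn),
      safe_ratio(sens, 1 - spec),
      safe_ratio(fp + tn, total)
    )
  )
}

#' Evaluative diagnostic test parameters
#'
#' Prevalence-independent summaries built on the basic block: Youden's
#' `J = sensitivity + specificity - 1` and its reciprocal the number needed
#' to diagnose (NND); the number needed to misdiagnose
#' `NNM = total/(fp + fn)`; the predictive summary index
#' `PSI = PPV + NPV - 1` and its reciprocal the number needed to predict
#' (NNP). NND/NNP are undefined (flagged `NaN`) when J or PSI is not
#' positive — a test no better than chance; NNM is `Inf` for a test that
#' never misclassifies.
#'
#' @param basic The tibble from [basic_diagnostics()].
#' @param table The same contingency table.
#' @return A tibble with columns `metric`, `value` for `youden_j`, `nnd`,
#'   `nnm`, `psi`, `nnp`.
#' @export
evaluative_diagnostics <- function(basic, table) {
  m <- contingency_cells(table)
  tp <- m[1]; fn <- m[2]; fp <- m[3]; tn <- m[4]
  val <- function(name) basic$value[basic$metric == name]
  j <- val("sensitivity") + val("specificity") - 1
  psi <- val("ppv") + val("npv") - 1
  tibble(
    metric = c("youden_j", "nnd", "nnm", "psi", "nnp"),
    value = c(
      j,
      if (is.finite(j) && j > 0) 1 / j else NaN,
      safe_ratio(tp + fn + fp + tn, fp + fn),
      psi,
      if (is.finite(psi) && psi > 0) 1 / psi else NaN
    )
  )
}

#' Full diagnostic test report
#'
#' Combines the contingency table, the two-sided Fisher's exact test, and
#' the basic and evaluative metric blocks into one object.
#'
#' @param table A `contingency_2x2`.
#' @return A `diagnostic_report` with elements `table`, `fisher_p`, `basic`,
#'   `evaluative`, and `metrics` (named numeric vector of everything).
#'   Supports [tidy()], [glance()] and JSON serialization via
#'   [report_to_json()].
#' @export
diagnostic_report <- function(table) {
  if (!inherits(table, "contingency_2x2")) {
    m <- contingency_cells(table)
    table <- new_contingency(m[1], m[2], m[3], m[4])
  }
  basic <- basic_diagnostics(table)
  evaluative <- evaluative_diagnostics(basic, table)
  fisher_p <- fisher_exact_two_sided(table)
  metrics <- setNames(
    c(fisher_p, basic$value, evaluative$value),
    c("fisher_p", basic$metric, evaluative$metric)
  )
  structure(
    list(table = table, fisher_p = fisher_p, basic = basic,
         evaluative = evaluative, metrics = metrics),
    class = "diagnostic_report"
  )
}

format_metric <- function(x) {
  if (is.nan(x)) "undefined" else if (is.infinite(x)) "Infinity" else sprintf("%.4f", x)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  print(x$table)
  cat(sprintf("\nFisher's exact test (two-sided): p = %.4f\n", x$fisher_p))
  cat("\nBasic diagnostic test parameters\n")
  for (i in seq_len(nrow(x$basic))) {
    cat(sprintf("  %-14s %s\n", x$basic$metric[i], format_metric(x$basic$value[i])))
  }
  cat("Evaluative parameters\n")
  for (i in seq_len(nrow(x$evaluative))) {
    cat(sprintf("  %-14s %s\n", x$evaluative$metric[i],
                format_metric(x$evaluative$value[i])))
  }
  invisible(x)
}

#' @rdname diagnostic_report
#' @param x A `diagnostic_report` (for the methods).
#' @param ... Unused.
#' @method tidy diagnostic_report
#' @export
tidy.diagnostic_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "fisher_p", value = x$fisher_p, block = "test"),
    dplyr::mutate(x$basic, block = "basic"),
    dplyr::mutate(x$evaluative, block = "evaluative")
  )
}

#' @rdname diagnostic_report
#' @method glance diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  as_tibble(as.list(x$metrics))
}

#' Serialize a diagnostic report to JSON
#'
#' Infinite metrics are serialized as the string `"Infinity"` and undefined
#' (`NaN`) metrics as `"undefined"`, so the report is loss-free in plain
#' JSON.
#'
#' @param report A `diagnostic_report`.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_to_json <- function(report, path = NULL) {
  enc <- function(x) {
    if (is.nan(x)) "undefined" else if (is.infinite(x)) "Infinity" else x
  }
  payload <- list(
    contingency = list(tp = report$table$tp, fn = report$table$fn,
                       fp = report$table$fp, tn = report$table$tn),
    metrics = lapply(as.list(report$metrics), enc)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
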