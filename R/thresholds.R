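#' Derive the cognitive-impairment threshold from DI monthly changes
#'
#' Following the DSM-V convention that mild neurocognitive disorder begins
#' one standard deviation below the population mean of a cognitive test
#' score (and major NCD two below), the cognitive-impairment (CI) threshold
#' is set at `mu - k * sigma` of the per-interval monthly changes in
#' discrimination index, where `mu` is their sample mean and `sigma` their
#' sample standard deviation (n - 1 denominator). `k = 1` captures mild and
#' major NCD combined; `k = 2` would isolate major NCD.
#'
#' @param di_changes Numeric vector of DI changes per month (one per subject
#'   per completed interval), length >= 2.
#' @param k Number of standard deviations below the mean (default 1).
#' @return A `threshold_spec` object with `mu`, `sigma`, `k` and
#'   `ci_threshold = mu - k * sigma` (DI per month); the biomarker fields are
#'   filled in by [derive_biomarker_threshold()] /
#'   [derive_thresholds()]. Values are kept at full precision; round only for
#'   display.
#' @examples
#' spec <- derive_ci_threshold(c(-0.2, 0.1, -0.1, 0.05))
#' spec$ci_threshold
#' @export
derive_ci_threshold <- function(di_changes, k = 1) {
  di_changes <- di_changes[is.finite(di_changes)]
  if (length(di_changes) < 2) {
    abort("need at least 2 DI changes to estimate mean and SD",
          class = "retinocog_domain_error")
  }
  if (!is.finite(k) || k <= 0) {
    abort("k must be a positive number", class = "retinocog_domain_error")
  }
  mu <- mean(di_changes)
  sigma <- sd(di_changes)
  structure(
    list(
      mu = mu, sigma = sigma, k = k,
      ci_threshold = mu - k * sigma,
      slope = NA_real_, intercept = NA_real_,
      biomarker_threshold = NA_real_,
      layer = NA_character_, n = length(di_changes)
    ),
    class = "threshold_spec"
  )
}

#' Interpolate the biomarker threshold from a regression line
#'
#' Evaluates the fitted layer-change-on-DI-change regression line at the CI
#' threshold: `biomarker_threshold = slope * ci_threshold + intercept`
#' (forward substitution of x into the y-on-x line, not inversion of an
#' x-on-y calibration line). A change record whose monthly layer-thickness
#' change falls below this value is flagged by the diagnostic test.
#'
#' @param fit A [fit_simple_regression()] fit with x = DI change per month
#'   and y = layer-thickness change in pixels per month, or any list with
#'   finite `slope` and `intercept`.
#' @param ci_threshold CI threshold in DI per month.
#' @return Threshold in pixels per month.
#' @examples
#' fit <- list(slope = 3.046, intercept = -0.5284)
#' derive_biomarker_threshold(fit, -0.2222)  # -1.205
#' @export
derive_biomarker_threshold <- function(fit, ci_threshold) {
  if (!is.finite(fit$slope) || !is.finite(fit$intercept)) {
    abort("fit must have finite slope and intercept",
          class = "retinocog_domain_error")
  }
  if (!is.finite(ci_threshold)) {
    abort("ci_threshold must be finite", class = "retinocog_domain_error")
  }
  fit$slope * ci_threshold + fit$intercept
}

#' Derive both thresholds from a change table
#'
#' Convenience wrapper: [derive_ci_threshold()] on the `d_di` column, then
#' [derive_biomarker_threshold()] on the supplied (or freshly fitted)
#' layer-change-on-DI-change regression line.
#'
#' @param changes A change table from [build_change_table()].
#' @param layer Which layer's monthly change carries the biomarker (default
#'   `"inl"`).
#' @param k Number of SDs below the mean for the CI threshold.
#' @param fit Optional pre-computed [fit_simple_regression()] of the layer
#'   change on the DI change; fitted from `changes` when `NULL`.
#' @return A complete `threshold_spec`: `mu`, `sigma`, `k`, `ci_threshold`,
#'   `slope`, `intercept`, `biomarker_threshold`, `layer`.
#' @export
derive_thresholds <- function(changes, layer = "inl", k = 1, fit = NULL) {
  dcol <- paste0("d_", layer)
  if (!dcol %in% names(changes)) {
    abort(sprintf("change table has no column '%s'", dcol),
          class = "retinocog_domain_error")
  }
  spec <- derive_ci_threshold(changes$d_di, k = k)
  if (is.null(fit)) {
    fit <- fit_simple_regression(changes, !!rlang::sym("d_di"), !!rlang::sym(dcol))
  }
  spec$slope <- fit$slope
  spec$intercept <- fit$intercept
  spec$biomarker_threshold <- derive_biomarker_threshold(fit, spec$ci_threshold)
  spec$layer <- layer
  spec
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "Threshold specification (k = %g):\n  DI change: mu = %.4f, sigma = %.4f -> CI threshold %.4f DI/month\n",
    x$k, x$mu, x$sigma, x$ci_threshold
  ))
  if (is.finite(x$biomarker_threshold)) {
    cat(sprintf(
      "  %s line: y = %.4f x + %.4f -> biomarker threshold %.4f px/month\n",
      toupper(x$layer %||% "layer"), x$slope, x$intercept, x$biomarker_threshold
    ))
  }
  cat("  Records at a threshold classify to the healthy/positive side.\n")
  invisible(x)
}

#' @rdname derive_thresholds
#' @param x A `threshold_spec` (for the method).
#' @param ... Unused.
#' @method tidy threshold_spec
#' @export
tidy.threshold_spec <- function(x, ...) {
  tibble(
    mu = x$mu, sigma = x$sigma, k = x$k, ci_threshold = x$ci_threshold,
    slope = x$slope, intercept = x$intercept,
    biomarker_threshold = x$biomarker_threshold,
    layer = x$layer, n = x$n
  )
}

#' Classify change records against the thresholds
#'
#' Applies both threshold rules to each per-interval record: a record is
#' labelled `CI` when its monthly DI change falls strictly below the CI
#' threshold, and `no_CI` otherwise; its diagnostic test result is
#' `positive` (predicted healthy — the test has test-of-health polarity)
#' when the monthly layer-thickness change is at or above the biomarker
#' threshold, `negative` below it. Records exactly at a threshold land on
#' the healthy/positive side: the rule is defined by "above" and "below",
#' and ties take the benign reading consistently.
#'
#' @param changes A change table from [build_change_table()].
#' @param spec A complete `threshold_spec` from [derive_thresholds()] (or
#'   built by hand with fixed thresholds).
#' @return `changes` with two extra factor columns: `ncd_status`
#'   (`no_CI`/`CI`) and `test_result` (`positive`/`negative`).
#' @export
classify_changes <- function(changes, spec) {
  dcol <- paste0("d_", spec$layer %||% "inl")
  d_layer <- changes[[dcol]]
  if (!all(is.finite(changes$d_di)) || !all(is.finite(d_layer))) {
    abort("change table contains non-finite d_di or layer change values",
          class = "retinocog_domain_error")
  }
  if (!is.finite(spec$ci_threshold) || !is.finite(spec$biomarker_threshold)) {
    abort("threshold spec is incomplete", class = "retinocog_domain_error")
  }
  dplyr::mutate(
    changes,
    ncd_status = factor(
      ifelse(.data$d_di < spec$ci_threshold, "CI", "no_CI"),
      levels = c("no_CI", "CI")
    ),
    test_result = factor(
      ifelse(d_layer >= spec$biomarker_threshold, "positive", "negative"),
      levels = c("positive", "negative")
    )
  )
}
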