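#' Simple linear regression of one column on another
#'
#' Ordinary least squares of `y` on `x` with an intercept, reporting the
#' slope, intercept, coefficient of determination, and a two-sided t-test of
#' the null hypothesis that the gradient is zero (`t = slope / se` on `n - 2`
#' degrees of freedom). This is the workhorse for trendlines of layer
#' thickness against discrimination index and for the change-on-change line
#' used to interpolate the biomarker threshold.
#'
#' @param data A data frame.
#' @param x,y Bare column names of the predictor and response.
#' @return A `simple_fit` object with elements `slope`, `intercept`, `r2`,
#'   `slope_se`, `slope_p`, `n`, `x`, `y` (column names) and the underlying
#'   `lm` fit. Supports [tidy()], [glance()], [predict()] and [autoplot()].
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit_simple_regression(d, x, y)$slope  # 2
#' @export
fit_simple_regression <- function(data, x, y) {
  xn <- as_name(enquo(x))
  yn <- as_name(enquo(y))
  xv <- data[[xn]]
  yv <- data[[yn]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  n <- length(xv)
  if (n < 3) {
    abort("simple regression requires at least 3 complete observations",
          class = "retinocog_domain_error")
  }
  if (sd(xv) == 0) {
    abort(sprintf("predictor '%s' is constant; slope is undefined", xn),
          class = "retinocog_singularity_error")
  }
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  # constant response: the flat line fits perfectly, but r2 is 0/0 in the
  # usual formula; report the degenerate fit explicitly
  constant_y <- var(yv) == 0
  structure(
    list(
      slope = if (constant_y) 0 else unname(coef(fit)[2]),
      intercept = if (constant_y) yv[1] else unname(coef(fit)[1]),
      r2 = if (constant_y) 0 else sm$r.squared,
      slope_se = if (constant_y) 0 else sm$coefficients[2, 2],
      slope_p = if (constant_y) NA_real_ else sm$coefficients[2, 4],
      n = n,
      x = xn, y = yn,
      lm = fit,
      data = tibble(!!xn := xv, !!yn := yv)
    ),
    class = "simple_fit"
  )
}

#' @export
print.simple_fit <- function(x, ...) {
  cat(sprintf(
    "Simple linear regression: %s = %.4f * %s + %.4f\n  r^2 = %.4f, slope p = %.4g, n = %d\n",
    x$y, x$slope, x$x, x$intercept, x$r2, x$slope_p, x$n
  ))
  invisible(x)
}

#' @export
predict.simple_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(predict(object$lm)))
  object$slope * newdata + object$intercept
}

#' @rdname fit_simple_regression
#' @param x A `simple_fit` object (for the methods).
#' @param ... Unused.
#' @method tidy simple_fit
#' @export
tidy.simple_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(
    term = c("(Intercept)", x$x),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @rdname fit_simple_regression
#' @method glance simple_fit
#' @export
glance.simple_fit <- function(x, ...) {
  sm <- summary(x$lm)
  tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    statistic = unname(sm$fstatistic[1]),
    p.value = x$slope_p,
    nobs = x$n
  )
}

#' Variance inflation factor from a collinearity r-squared
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of determination
#' from regressing predictor `j` on the remaining predictors. A VIF of 1
#' means no collinearity; values above ~5-10 are conventionally worrying.
#'
#' @param r2_other Numeric vector of r-squared values in `[0, 1)`.
#' @return VIF values, each `>= 1`.
#' @examples
#' variance_inflation(0.1839)  # 1.225
#' @export
variance_inflation <- function(r2_other) {
  if (any(!is.finite(r2_other)) || any(r2_other < 0)) {
    abort("r2_other must be finite and >= 0", class = "retinocog_domain_error")
  }
  if (any(r2_other >= 1)) {
    abort("r2_other >= 1: predictor is perfectly collinear with the others",
          class = "retinocog_singularity_error")
  }
  1 / (1 - r2_other)
}

#' Multiple linear regression with collinearity diagnostics
#'
#' OLS with an intercept of a response on several predictors, reporting per
#' coefficient two-sided t-tests, per-predictor variance inflation factors
#' and their underlying `r2_other`, a partial (Type III) per-predictor F
#' partition alongside the omnibus regression ANOVA, and the parameter
#' correlation matrix derived from the coefficient covariance. For OLS the
#' partial F of a single predictor equals the square of its coefficient
#' t-statistic, so its p-value matches the coefficient p-value.
#'
#' @param data A data frame.
#' @param response Bare column name of the response.
#' @param predictors Character vector of predictor column names.
#' @return A `multiple_fit` object with elements `betas`, `beta_ses`,
#'   `beta_ps`, `vif`, `r2_other`, `anova` (tibble with rows Regression, one
#'   per predictor, Residual, Total), `multiple_r`, `r2`, `adj_r2`,
#'   `param_corr`, `n`, `p`, and the underlying `lm`. Supports [tidy()] and
#'   [glance()].
#' @export
fit_multiple_regression <- function(data, response, predictors) {
  yn <- as_name(enquo(response))
  predictors <- as.character(predictors)
  cols <- c(yn, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("column(s) not in data: ", paste(missing, collapse = ", ")),
          class = "retinocog_domain_error")
  }
  d <- data[cols]
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1) {
    abort(sprintf("need n > p + 1 observations (n = %d, p = %d)", n, p),
          class = "retinocog_domain_error")
  }
  X <- as.matrix(cbind(`(Intercept)` = 1, d[predictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
                 paste(bad, collapse = ", ")),
          class = "retinocog_singularity_error")
  }
  fml <- stats::reformulate(predictors, response = yn)
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients

  r2_other <- vapply(predictors, function(pj) {
    if (p == 1) return(0)
    aux <- lm(stats::reformulate(setdiff(predictors, pj), response = pj), data = d)
    summary(aux)$r.squared
  }, numeric(1))
  vif <- variance_inflation(r2_other)

  yv <- d[[yn]]
  ss_total <- sum((yv - mean(yv))^2)
  ss_resid <- sum(stats::residuals(fit)^2)
  ss_reg <- ss_total - ss_resid
  df_resid <- n - p - 1
  ms_resid <- ss_resid / df_resid
  f_omni <- (ss_reg / p) / ms_resid
  # partial (Type III) per-predictor rows: F = t^2 on (1, df_resid)
  t_pred <- ct[predictors, 3]
  anova_tbl <- dplyr::bind_rows(
    tibble(term = "Regression", ss = ss_reg, df = p, ms = ss_reg / p,
           f = f_omni, p_value = pf(f_omni, p, df_resid, lower.tail = FALSE)),
    tibble(term = predictors,
           ss = t_pred^2 * ms_resid, df = 1, ms = t_pred^2 * ms_resid,
           f = t_pred^2,
           p_value = pf(t_pred^2, 1, df_resid, lower.tail = FALSE)),
    tibble(term = "Residual", ss = ss_resid, df = df_resid, ms = ms_resid,
           f = NA_real_, p_value = NA_real_),
    tibble(term = "Total", ss = ss_total, df = n - 1, ms = NA_real_,
           f = NA_real_, p_value = NA_real_)
  )

  structure(
    list(
      betas = setNames(unname(ct[, 1]), rownames(ct)),
      beta_ses = setNames(unname(ct[, 2]), rownames(ct)),
      beta_ps = setNames(unname(ct[, 4]), rownames(ct)),
      vif = vif,
      r2_other = r2_other,
      anova = anova_tbl,
      multiple_r = sqrt(sm$r.squared),
      r2 = sm$r.squared,
      adj_r2 = sm$adj.r.squared,
      param_corr = cov2cor(vcov(fit)),
      n = n, p = p,
      response = yn, predictors = predictors,
      lm = fit
    ),
    class = "multiple_fit"
  )
}

#' @export
print.multiple_fit <- function(x, ...) {
  cat(sprintf(
    "Multiple linear regression: %s ~ %s\n  multiple R = %.4f, r^2 = %.4f, adjusted r^2 = %.4f, n = %d\n",
    x$response, paste(x$predictors, collapse = " + "),
    x$multiple_r, x$r2, x$adj_r2, x$n
  ))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_multiple_regression
#' @param x A `multiple_fit` object (for the methods).
#' @param ... Unused.
#' @method tidy multiple_fit
#' @export
tidy.multiple_fit <- function(x, ...) {
  terms <- names(x$betas)
  sm <- summary(x$lm)$coefficients
  tibble(
    term = terms,
    estimate = unname(x$betas),
    std.error = unname(x$beta_ses),
    statistic = unname(sm[, 3]),
    p.value = unname(x$beta_ps),
    vif = c(NA_real_, unname(x$vif)),
    r2_other = c(NA_real_, unname(x$r2_other))
  )
}

#' @rdname fit_multiple_regression
#' @method glance multiple_fit
#' @export
glance.multiple_fit <- function(x, ...) {
  omni <- x$anova[x$anova$term == "Regression", ]
  tibble(
    multiple.r = x$multiple_r,
    r.squared = x$r2,
    adj.r.squared = x$adj_r2,
    statistic = omni$f,
    p.value = omni$p_value,
    df = omni$df,
    nobs = x$n
  )
}

#' Adjusted r-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: the sample r-squared penalised for
#' the number of fitted predictors.
#'
#' @param r2 Coefficient of determination.
#' @param n Number of observations.
#' @param p Number of predictors (excluding the intercept).
#' @return Adjusted r-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Compare two groups with normality-gated test dispatch
#'
#' Implements the dispatch rule used throughout the pipeline: the pooled
#' group-centred residuals are put through the four-test normality battery
#' ([normality_battery()]) and the two groups through an F-test for equal
#' variances; only when *all four* normality tests and the variance test are
#' non-significant at `alpha` is an unpaired two-tailed pooled-variance
#' t-test used, otherwise a two-tailed Mann-Whitney U test (exact when the
#' combined sample size is at most 20 and there are no ties, normal
#' approximation with continuity and tie correction otherwise).
#'
#' Two elementwise-identical groups have zero-variance residuals, on which no
#' normality test is defined; that degenerate case is reported directly as
#' `statistic = 0`, `p = 1` (no difference detectable).
#'
#' @param data A data frame.
#' @param value Bare column name of the measurement.
#' @param group Bare column name of the two-level grouping variable.
#' @param alpha Significance level used for the normality and variance gates.
#' @return A `group_comparison` object: `test_used` (`"t_test"` or
#'   `"mann_whitney"`), `statistic`, `p`, `normality` (battery tibble),
#'   `variance_test_p`, group summary tibble. Supports [tidy()] and
#'   [glance()].
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  vn <- as_name(enquo(value))
  gn <- as_name(enquo(group))
  v <- data[[vn]]
  g <- data[[gn]]
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]
  g <- as.factor(as.character(g[keep]))
  lev <- levels(g)
  if (length(lev) != 2) {
    abort(sprintf("'%s' must have exactly 2 levels (got %d)", gn, length(lev)),
          class = "retinocog_domain_error")
  }
  a <- v[g == lev[1]]
  b <- v[g == lev[2]]
  if (length(a) < 3 || length(b) < 3) {
    abort("each group needs at least 3 observations",
          class = "retinocog_domain_error")
  }
  groups_tbl <- tibble(
    group = lev,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sd = c(sd(a), sd(b))
  )
  resid <- c(a - mean(a), b - mean(b))

  if (sd(resid) == 0) {
    # identical-within-group degenerate case: no spread, no test possible
    same <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(
      test_used = "t_test", statistic = if (same) 0 else Inf,
      p = if (same) 1 else 0,
      normality = NULL, variance_test_p = NA_real_,
      groups = groups_tbl, levels = lev, alpha = alpha, degenerate = TRUE
    )
    return(structure(res, class = "group_comparison"))
  }

  battery <- normality_battery(resid, alpha = alpha)
  vt <- var.test(a, b)
  parametric <- attr(battery, "normal") && vt$p.value > alpha
  if (parametric) {
    ht <- t.test(a, b, var.equal = TRUE)
    used <- "t_test"
  } else {
    exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    used <- "mann_whitney"
  }
  structure(
    list(
      test_used = used,
      statistic = unname(ht$statistic),
      p = ht$p.value,
      normality = battery,
      variance_test_p = vt$p.value,
      groups = groups_tbl, levels = lev, alpha = alpha, degenerate = FALSE
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Group comparison (%s vs %s): %s, statistic = %.4g, p = %.4g\n",
    x$levels[1], x$levels[2],
    if (x$test_used == "t_test") "unpaired two-tailed t-test" else "Mann-Whitney U",
    x$statistic, x$p
  ))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object (for the methods).
#' @param ... Unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(
    test_used = x$test_used,
    statistic = x$statistic,
    p.value = x$p,
    variance_test_p = x$variance_test_p,
    normal = if (is.null(x$normality)) NA else attr(x$normality, "normal")
  )
}

#' @rdname compare_groups
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) tidy(x)
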