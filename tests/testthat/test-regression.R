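test_that("simple regression recovers an exact line and handles degeneracies", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  f <- fit_simple_regression(d, x, y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(sum(stats::residuals(f$lm)^2), 0, tolerance = 1e-20)

  dc <- tibble::tibble(x = 1:10, y = rep(3, 10))
  fc <- fit_simple_regression(dc, x, y)
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 0)

  expect_error(fit_simple_regression(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               class = "retinocog_singularity_error")
  expect_error(fit_simple_regression(tibble::tibble(x = 1:2, y = 1:2), x, y),
               class = "retinocog_domain_error")
})

test_that("simple regression matches the normal-equations oracle", {
  set.seed(101)
  for (i in 1:10) {
    d <- tibble::tibble(x = rnorm(10), y = rnorm(10, sd = 2))
    f <- fit_simple_regression(d, x, y)
    o <- ols_oracle(matrix(d$x), d$y)
    expect_equal(f$intercept, o$beta[1], tolerance = 1e-10)
    expect_equal(f$slope, o$beta[2], tolerance = 1e-10)
    expect_equal(f$slope_se, o$se[2], tolerance = 1e-10)
    expect_equal(f$slope_p, o$p[2], tolerance = 1e-10)
    expect_equal(f$r2, cor(d$x, d$y)^2, tolerance = 1e-10)
  }
})

test_that("multiple regression matches the oracle and conserves sums of squares", {
  set.seed(202)
  for (i in 1:8) {
    X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- rnorm(12)
    f <- fit_multiple_regression(d, y, c("a", "b", "c"))
    o <- ols_oracle(X, d$y)
    expect_equal(unname(f$betas), unname(o$beta), tolerance = 1e-9)
    expect_equal(unname(f$beta_ses), unname(o$se), tolerance = 1e-9)
    expect_equal(unname(f$beta_ps), unname(o$p), tolerance = 1e-9)

    an <- f$anova
    ss_total <- an$ss[an$term == "Total"]
    expect_equal(an$ss[an$term == "Regression"] + an$ss[an$term == "Residual"],
                 ss_total, tolerance = 1e-9 * ss_total)
    expect_equal(cov2cor(o$covb), unclass(f$param_corr), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(diag(f$param_corr), rep(1, 4), ignore_attr = TRUE)
  }
})

test_that("VIF identities and cross-check against car", {
  expect_equal(variance_inflation(0), 1)
  expect_equal(round(variance_inflation(0.1839), 3), 1.225)
  expect_equal(round(variance_inflation(0.1565), 3), 1.186)
  expect_error(variance_inflation(1), class = "retinocog_singularity_error")

  set.seed(33)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), 20, 3,
                                              dimnames = list(NULL, c("a", "b", "c")))))
  d$b <- d$b + 0.7 * d$a      # induce collinearity
  d$y <- rnorm(20)
  f <- fit_multiple_regression(d, y, c("a", "b", "c"))
  expect_equal(unname(f$vif * (1 - f$r2_other)), rep(1, 3), tolerance = 1e-12)
  if (requireNamespace("car", quietly = TRUE)) {
    ref <- car::vif(f$lm)
    expect_equal(unname(f$vif), unname(ref), tolerance = 1e-8)
  }

  # exactly orthogonal centered predictors have VIF 1
  dorth <- tibble::tibble(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1),
                          y = c(0.3, 1.2, -0.5, 0.8))
  # need n > p + 1: replicate the design
  dorth <- dplyr::bind_rows(dorth, dplyr::mutate(dorth, y = y + 0.1))
  fo <- fit_multiple_regression(dorth, y, c("a", "b"))
  expect_equal(unname(fo$vif), c(1, 1), tolerance = 1e-12)
})

test_that("single-predictor multiple regression reproduces the simple fit", {
  set.seed(44)
  d <- tibble::tibble(x = rnorm(15), y = rnorm(15))
  fs <- fit_simple_regression(d, x, y)
  fm <- fit_multiple_regression(d, y, "x")
  expect_equal(unname(fm$betas["x"]), fs$slope, tolerance = 1e-10)
  expect_equal(unname(fm$betas["(Intercept)"]), fs$intercept, tolerance = 1e-10)
  expect_equal(unname(fm$beta_ps["x"]), fs$slope_p, tolerance = 1e-10)
  expect_equal(unname(fm$vif), 1)
})

test_that("rank-deficient designs fail naming the offending column", {
  d <- tibble::tibble(a = rnorm(10), y = rnorm(10))
  d$b <- 2 * d$a
  expect_error(fit_multiple_regression(d, y, c("a", "b")),
               "b", class = "retinocog_singularity_error")
})

test_that("the fitted line passes through the centroid", {
  set.seed(55)
  d <- tibble::tibble(x = rnorm(20, 3), y = rnorm(20, -1))
  f <- fit_simple_regression(d, x, y)
  expect_equal(predict(f, mean(d$x)), mean(d$y), tolerance = 1e-12)
})

test_that("adjusted r-squared and multiple R reproduce reported summaries", {
  expect_equal(round(adjusted_r2(0.3301, n = 24, p = 3), 4), 0.2296)
  expect_equal(round(sqrt(0.3301), 4), 0.5745)
})

test_that("group comparison dispatches on the normality battery", {
  set.seed(7)
  d_norm <- tibble::tibble(
    value = c(rnorm(50), rnorm(50, 0.2)),
    grp = rep(c("a", "b"), each = 50)
  )
  g <- compare_groups(d_norm, value, grp)
  expect_equal(g$test_used, "t_test")
  expect_true(attr(g$normality, "normal"))
  # dispatch target agrees with the reference routine
  ref <- t.test(value ~ grp, data = d_norm, var.equal = TRUE)
  expect_equal(g$p, ref$p.value, tolerance = 1e-12)

  set.seed(8)
  d_skew <- tibble::tibble(
    value = c(rexp(50), rnorm(50, 1)),
    grp = rep(c("a", "b"), each = 50)
  )
  g2 <- compare_groups(d_skew, value, grp)
  expect_equal(g2$test_used, "mann_whitney")
  ref2 <- suppressWarnings(wilcox.test(value ~ grp, data = d_skew, correct = TRUE))
  expect_equal(g2$p, ref2$p.value, tolerance = 1e-12)
})

test_that("identical groups compare with p = 1", {
  v <- c(1.2, 3.4, 2.2, 5.0, 0.7, 1.9)
  d <- tibble::tibble(value = c(v, v), grp = rep(c("a", "b"), each = 6))
  g <- compare_groups(d, value, grp)
  expect_equal(g$p, 1)
  expect_equal(g$statistic, 0)

  expect_error(
    compare_groups(tibble::tibble(value = c(1, 2, 1, 2, 3),
                                  grp = c("a", "a", "b", "b", "b")),
                   value, grp),
    class = "retinocog_domain_error"
  )
})
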