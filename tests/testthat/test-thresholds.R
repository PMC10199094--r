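test_that("CI threshold is mean minus k SDs of the DI monthly changes", {
  x <- di_changes_exact()   # exact mean -0.0579, SD 0.1643
  spec <- derive_ci_threshold(x, k = 1)
  expect_equal(round(spec$mu, 4), -0.0579)
  expect_equal(round(spec$sigma, 4), 0.1643)
  expect_equal(round(spec$ci_threshold, 4), -0.2222)

  spec2 <- derive_ci_threshold(c(-2, -1, 0, 1, 2), k = 2)
  expect_equal(spec2$ci_threshold, 0 - 2 * sd(c(-2, -1, 0, 1, 2)))

  spec3 <- derive_ci_threshold(rep(0.1, 5))
  expect_equal(spec3$ci_threshold, 0.1)   # sigma = 0 degenerate

  expect_error(derive_ci_threshold(0.1), class = "retinocog_domain_error")
  expect_error(derive_ci_threshold(c(1, 2), k = 0), class = "retinocog_domain_error")
})

test_that("biomarker threshold is forward substitution into the fitted line", {
  fit <- list(slope = 3.046, intercept = -0.5284)
  expect_equal(round(derive_biomarker_threshold(fit, -0.2222), 3), -1.205)
  expect_equal(derive_biomarker_threshold(list(slope = 1, intercept = 0), 0.37), 0.37)
  expect_equal(derive_biomarker_threshold(list(slope = 0, intercept = -2), 99), -2)
  expect_error(derive_biomarker_threshold(list(slope = NA, intercept = 1), 0),
               class = "retinocog_domain_error")
})

test_that("biomarker threshold is affine in the line's vertical scale", {
  set.seed(9)
  for (i in 1:10) {
    fit <- list(slope = rnorm(1), intercept = rnorm(1))
    alpha <- runif(1, 0.1, 5)
    x <- rnorm(1)
    scaled <- list(slope = alpha * fit$slope, intercept = alpha * fit$intercept)
    expect_equal(derive_biomarker_threshold(scaled, x),
                 alpha * derive_biomarker_threshold(fit, x), tolerance = 1e-12)
  }
})

test_that("classification applies both rules with healthy-side ties", {
  spec <- list(ci_threshold = -0.2222, biomarker_threshold = -1.205,
               layer = "inl")
  ch <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    age_from = 4, age_to = 6,
    d_di = c(-0.30, -0.2222, 0.10, -0.50),
    d_inl = c(-0.50, -2.00, -2.0, -1.205)
  )
  cl <- classify_changes(ch, spec)
  expect_equal(as.character(cl$ncd_status), c("CI", "no_CI", "no_CI", "CI"))
  expect_equal(as.character(cl$test_result),
               c("positive", "negative", "negative", "positive"))

  bad <- ch; bad$d_di[1] <- NA
  expect_error(classify_changes(bad, spec), class = "retinocog_domain_error")
})

test_that("raising k only moves records from CI to no_CI", {
  set.seed(17)
  d_di <- rnorm(40, -0.05, 0.2)
  ch <- tibble::tibble(subject_id = as.character(1:40), age_from = 4,
                       age_to = 6, d_di = d_di, d_inl = rnorm(40, -1, 1))
  prev_ci <- rep(TRUE, 40)
  for (k in c(0.5, 1, 1.5, 2, 3)) {
    spec <- derive_ci_threshold(d_di, k = k)
    spec$biomarker_threshold <- -1; spec$layer <- "inl"
    cl <- classify_changes(ch, spec)
    now_ci <- cl$ncd_status == "CI"
    expect_true(all(now_ci <= prev_ci))   # monotone shrinkage
    prev_ci <- now_ci
  }
  # vacuous limit: threshold below the minimum leaves nobody impaired
  spec <- derive_ci_threshold(d_di, k = 1)
  spec$ci_threshold <- min(d_di) - 1e-9
  spec$biomarker_threshold <- -1; spec$layer <- "inl"
  expect_equal(sum(classify_changes(ch, spec)$ncd_status == "CI"), 0)
})

test_that("derive_thresholds chains the DI and biomarker rules", {
  ch <- build_change_table(reference_cohort())
  spec <- derive_thresholds(ch, layer = "inl", k = 1)
  expect_equal(round(spec$ci_threshold, 4), -0.2222)
  expect_equal(round(spec$biomarker_threshold, 3), -1.205)
  expect_equal(spec$layer, "inl")
  td <- tidy(spec)
  expect_equal(td$slope, spec$slope)
  expect_equal(td$n, 24L)
})
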