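test_that("contingency construction counts cells under test-of-health polarity", {
  cl <- tibble::tibble(
    ncd_status = factor(c(rep("no_CI", 5), rep("CI", 2)),
                        levels = c("no_CI", "CI")),
    test_result = factor(c("positive", "positive", "negative", "positive",
                           "negative", "negative", "positive"),
                         levels = c("positive", "negative"))
  )
  tab <- build_contingency(cl)
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(3L, 2L, 1L, 1L))

  all_pos <- tibble::tibble(
    ncd_status = factor(rep("no_CI", 6), levels = c("no_CI", "CI")),
    test_result = factor(rep("positive", 6), levels = c("positive", "negative"))
  )
  tab2 <- build_contingency(all_pos)
  expect_equal(c(tab2$tp, tab2$fn, tab2$fp, tab2$tn), c(6L, 0L, 0L, 0L))

  expect_error(build_contingency(cl[0, ]), class = "retinocog_domain_error")
  expect_error(new_contingency(0, 0, 0, 0), class = "retinocog_domain_error")
  expect_error(new_contingency(1.5, 0, 0, 1), class = "retinocog_domain_error")
})

test_that("two-sided Fisher test reproduces known tables", {
  expect_equal(round(fisher_exact_two_sided(new_contingency(18, 3, 0, 3)), 4),
               0.0099)
  expect_equal(fisher_exact_two_sided(new_contingency(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact_two_sided(new_contingency(1, 0, 0, 1)), 1)
  # degenerate margins admit a single table
  expect_equal(fisher_exact_two_sided(new_contingency(4, 0, 2, 0)), 1)
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(62)
  for (i in 1:60) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    m <- matrix(cells, 2, 2)
    mine <- fisher_exact_two_sided(m)
    ref <- stats::fisher.test(m)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant under simultaneous row-column transposition", {
  set.seed(63)
  for (i in 1:30) {
    m <- matrix(as.integer(rmultinom(1, sample(5:25, 1), rep(0.25, 4))), 2, 2)
    expect_equal(fisher_exact_two_sided(m), fisher_exact_two_sided(t(m)),
                 tolerance = 1e-12)
  }
})

test_that("two-sided p dominates the one-sided tail p", {
  set.seed(64)
  for (i in 1:30) {
    m <- matrix(as.integer(rmultinom(1, sample(5:25, 1), rep(0.25, 4))), 2, 2)
    a <- m[1, 1]; row1 <- sum(m[1, ]); col1 <- sum(m[, 1]); n <- sum(m)
    lower <- stats::phyper(a, col1, n - col1, row1)
    upper <- stats::phyper(a - 1, col1, n - col1, row1, lower.tail = FALSE)
    one_sided <- min(lower, upper)
    expect_gte(fisher_exact_two_sided(m) + 1e-12, one_sided)
  }
})

test_that("hypergeometric point probabilities over the support sum to one", {
  set.seed(65)
  for (i in 1:20) {
    row1 <- sample(1:15, 1); row2 <- sample(1:15, 1); col1 <- sample(1:(row1 + row2), 1)
    lo <- max(0, col1 - row2); hi <- min(row1, col1)
    expect_equal(sum(dhyper(lo:hi, row1, row2, col1)), 1, tolerance = 1e-12)
  }
})

test_that("basic diagnostics reproduce the reference table's metric battery", {
  tab <- new_contingency(18, 3, 0, 3)
  b <- basic_diagnostics(tab)
  val <- function(m) b$value[b$metric == m]
  expect_equal(round(val("sensitivity"), 4), 0.8571)
  expect_equal(round(val("specificity"), 4), 1.0000)
  expect_equal(round(val("ppv"), 4), 1.0000)
  expect_equal(round(val("npv"), 4), 0.5000)
  expect_equal(round(val("rr"), 4), 2.0000)
  expect_identical(val("dor"), Inf)
  expect_identical(val("lr_positive"), Inf)
  expect_equal(round(val("prevalence_ci"), 4), 0.125)

  e <- evaluative_diagnostics(b, tab)
  ev <- function(m) e$value[e$metric == m]
  expect_equal(round(ev("youden_j"), 4), 0.8571)
  expect_equal(round(ev("nnd"), 4), 1.1667)
  expect_equal(round(ev("nnm"), 4), 8.0000)
  expect_equal(round(ev("psi"), 4), 0.5000)
  expect_equal(round(ev("nnp"), 4), 2.0000)
})

test_that("perfect and uninformative tables hit their boundary values", {
  perfect <- diagnostic_report(new_contingency(10, 0, 0, 10))
  m <- perfect$metrics
  expect_equal(unname(m[c("sensitivity", "specificity", "ppv", "npv")]),
               rep(1, 4))
  expect_equal(unname(m["youden_j"]), 1)
  expect_equal(unname(m["nnd"]), 1)
  expect_identical(unname(m["nnm"]), Inf)

  flat <- diagnostic_report(new_contingency(5, 5, 5, 5))
  fm <- flat$metrics
  expect_equal(unname(fm["sensitivity"]), 0.5)
  expect_equal(unname(fm["specificity"]), 0.5)
  expect_equal(unname(fm["dor"]), 1)
  expect_equal(unname(fm["youden_j"]), 0)
  expect_true(is.nan(unname(fm["nnd"])))   # flagged: no better than chance
})

test_that("diagnostic identities hold on random tables", {
  set.seed(66)
  for (i in 1:30) {
    cells <- as.integer(rmultinom(1, sample(8:40, 1), rep(0.25, 4))) + 1L
    tab <- new_contingency(cells[1], cells[2], cells[3], cells[4])
    b <- basic_diagnostics(tab)
    val <- function(m) b$value[b$metric == m]
    sens <- val("sensitivity"); spec <- val("specificity")
    # DOR factorization
    expect_equal(val("dor"),
                 (sens / (1 - sens)) * (spec / (1 - spec)), tolerance = 1e-10)
    # counts round-trip through the rates
    expect_equal(sens * (tab$tp + tab$fn), tab$tp, tolerance = 1e-10)
    e <- evaluative_diagnostics(b, tab)
    expect_equal(e$value[e$metric == "youden_j"], sens + spec - 1,
                 tolerance = 1e-12)
  }
})

test_that("reports serialize with Infinity as a string", {
  rep_ <- diagnostic_report(new_contingency(18, 3, 0, 3))
  json <- report_to_json(rep_)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$contingency$tp, 18)
  expect_identical(parsed$metrics$dor, "Infinity")
  expect_equal(parsed$metrics$sensitivity, 18 / 21, tolerance = 1e-12)
})
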