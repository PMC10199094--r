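test_that("discrimination index arithmetic and domain errors", {
  expect_equal(discrimination_index(15, 5, 20), 0.5)
  expect_equal(discrimination_index(10, 10, 20), 0)
  expect_equal(discrimination_index(0, 20, 20), -1)
  expect_error(discrimination_index(1, 1, 0), class = "retinocog_domain_error")
  expect_error(discrimination_index(15, 10, 20), class = "retinocog_domain_error")
})

test_that("discrimination index is scale invariant", {
  set.seed(11)
  for (i in 1:25) {
    tt <- runif(1, 10, 100)
    tn <- runif(1, 0, tt / 2)
    tf <- runif(1, 0, tt / 2)
    cc <- runif(1, 0.01, 50)
    expect_equal(discrimination_index(cc * tn, cc * tf, cc * tt),
                 discrimination_index(tn, tf, tt), tolerance = 1e-12)
  }
})

test_that("eye averaging is the arithmetic mean of available eyes", {
  coh <- tiny_cohort()
  avg <- average_eyes(coh)
  expect_equal(nrow(avg), 6)
  expect_true(all(avg$eye == "averaged"))
  m1_4 <- coh[coh$subject_id == "m1" & coh$age_months == 4, ]
  expect_equal(avg$inl[avg$subject_id == "m1" & avg$age_months == 4],
               mean(m1_4$inl))

  one_eye <- coh[!(coh$subject_id == "m2" & coh$age_months == 9 &
                     coh$eye == "right"), ]
  expect_warning(avg2 <- average_eyes(one_eye), "single measured eye")
  left_val <- one_eye$inl[one_eye$subject_id == "m2" &
                            one_eye$age_months == 9]
  expect_equal(avg2$inl[avg2$subject_id == "m2" & avg2$age_months == 9],
               left_val)
})

test_that("eye-difference check reports p = 1 when eyes are identical", {
  coh <- tiny_cohort()
  # remove the deliberate +/-0.5 offset
  for (col in c("nfl_gcl_ipl", "inl", "onl", "tr")) {
    off <- ifelse(coh$eye == "left", 0.5, -0.5)
    coh[[col]] <- coh[[col]] - off
  }
  ed <- eye_difference_test(coh)
  expect_equal(ed$p_value, rep(1, 4))
  expect_equal(ed$statistic, rep(0, 4))
})

test_that("rolling monthly change divides by the months elapsed", {
  expect_equal(monthly_change(0.3, 0.0, 6, 9), -0.1)
  expect_equal(monthly_change(40, 37, 4, 6), -1.5)
  expect_equal(monthly_change(5, 5, 4, 6), 0)
  expect_error(monthly_change(1, 2, 6, 6), class = "retinocog_domain_error")
  expect_error(monthly_change(1, 2, 9, 6), class = "retinocog_domain_error")
})

test_that("change table has one record per subject per adjacent interval", {
  coh <- simulate_cohort(cohort_config(n_mice = 12, seed = 5))
  ch <- build_change_table(coh)
  expect_equal(nrow(ch), 24)
  expect_setequal(unique(paste(ch$age_from, ch$age_to)), c("4 6", "6 9"))

  # a subject present at 4 and 9 months only completes no adjacent interval
  gap <- coh[!(coh$subject_id == "m01" & coh$age_months == 6), ]
  ch2 <- build_change_table(gap)
  expect_equal(sum(ch2$subject_id == "m01"), 0)
  expect_equal(nrow(ch2), 22)

  empty <- coh[0, ]
  expect_equal(nrow(build_change_table(empty)), 0)
})

test_that("changes telescope: sum of change x span equals last minus first", {
  coh <- simulate_cohort(cohort_config(n_mice = 8, seed = 21))
  avg <- add_discrimination_index(average_eyes(coh))
  ch <- build_change_table(coh)
  spans <- ch$age_to - ch$age_from
  for (sid in unique(ch$subject_id)) {
    rows <- ch$subject_id == sid
    first <- avg[avg$subject_id == sid & avg$age_months == 4, ]
    last <- avg[avg$subject_id == sid & avg$age_months == 9, ]
    expect_equal(sum(ch$d_di[rows] * spans[rows]), last$di - first$di,
                 tolerance = 1e-12)
    expect_equal(sum(ch$d_inl[rows] * spans[rows]), last$inl - first$inl,
                 tolerance = 1e-12)
    expect_equal(sum(ch$d_tr[rows] * spans[rows]), last$tr - first$tr,
                 tolerance = 1e-12)
  }
})
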