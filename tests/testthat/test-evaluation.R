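test_that("burden rows partition the percentage scale", {
  expect_equal(as.character(burden_row(c(95, 90, 66.7, 23.3, 3.3, 0))),
               c(">=90", ">=90", "50-89", "10-49", "1-9", "0"))
  expect_error(burden_row(-2), class = "szburden_error_input")
})

test_that("the reference cohort expands to the printed marginals", {
  ref <- reference_cohort()
  tab <- confusion_table(ref$outcomes)
  expect_equal(tab$total, 353)
  expect_equal(unname(tab$col_totals), c(9, 8, 87, 249))
  expect_equal(unname(tab$row_totals), c(33, 39, 79, 23, 179))
  expect_equal(unname(tab$counts[">=90", ]), c(9, 0, 21, 3))
  expect_equal(unname(tab$counts["0", ]), c(0, 2, 20, 157))
})

test_that("confusion table handles edge cases and rejects duplicates", {
  empty <- confusion_table(tibble::tibble(record_id = character(),
                                          category = character(),
                                          max_burden = numeric()))
  expect_equal(empty$total, 0)
  one <- confusion_table(tibble::tibble(record_id = "a", category = "SE",
                                        max_burden = 95))
  expect_equal(unname(one$counts[">=90", "SE"]), 1)
  expect_equal(sum(one$counts), 1)
  dup <- tibble::tibble(record_id = c("a", "a"), category = c("SE", "SZ"),
                        max_burden = c(95, 0))
  expect_error(confusion_table(dup), class = "szburden_error_input")
})

test_that("exact binomial intervals hit their bounds and the beta oracle", {
  expect_equal(binomial_ci(10, 10)$upper, 100)
  expect_equal(binomial_ci(0, 25)$lower, 0)
  ci <- binomial_ci(320, 344)
  expect_equal(ci$lower, 89.797, tolerance = 1e-4)
  expect_equal(ci$upper, 95.479, tolerance = 1e-4)
  # independent oracle: stats::binom.test Clopper-Pearson interval
  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(5:400, 1)
      k <- sample(0:n, 1)
      got <- binomial_ci(k, n)
      want <- 100 * binom.test(k, n)$conf.int
      expect_equal(c(got$lower, got$upper), as.numeric(want),
                   tolerance = 1e-10)
    }
  })
  expect_error(binomial_ci(5, 0), class = "szburden_error_input")
  expect_error(binomial_ci(6, 5), class = "szburden_error_input")
})

test_that("patient metrics reproduce the published accuracy figures", {
  ref <- reference_cohort()
  out <- ref$outcomes

  m90 <- patient_metrics(out, 90, "has_sz_ge_270s")
  expect_equal(m90$sensitivity, 100)          # 9/9 SE records
  expect_equal(m90$detected, 9)
  expect_equal(round(m90$specificity, 1), 93.0)  # 320/344
  expect_equal(m90$false_flags, 24)

  m50 <- patient_metrics(out, 50, "has_sz_ge_150s")
  expect_equal(m50$sensitivity, 100)          # 12/12
  expect_equal(m50$n_positive, 12)
  expect_equal(round(m50$specificity, 1), 82.4)  # 281/341

  m10 <- patient_metrics(out, 10, "has_seizure")
  expect_equal(m10$n_positive, 17)
  expect_equal(m10$detected, 15)
  expect_equal(round(m10$sensitivity, 1), 88.2)  # 15/17
  expect_equal(round(m10$specificity, 1), 59.5)  # 200/336

  # undefined without positives or negatives
  all_pos <- tibble::tibble(record_id = c("a", "b"), max_burden = c(95, 95),
                            p = c(TRUE, TRUE))
  expect_error(patient_metrics(all_pos, 90, "p"),
               class = "szburden_error_undefined_metric")
})

test_that("metrics from the confusion table equal brute-force iteration", {
  withr::with_seed(55, {
    out <- tibble::tibble(
      record_id = sprintf("r%02d", 1:40),
      category = sample(c("SE", "SZ", "HEP", "NL/SL"), 40, replace = TRUE),
      max_burden = sample(c(0, 3.3, 23.3, 66.7, 96.7), 40, replace = TRUE)
    )
    out$has_seizure <- out$category %in% c("SE", "SZ")
    if (sum(out$has_seizure) %in% c(0, 40)) skip("degenerate draw")
    m <- patient_metrics(out, 10, "has_seizure")
    # brute force over records
    det <- 0; fp <- 0
    for (i in 1:40) {
      if (out$max_burden[i] >= 10 && out$has_seizure[i]) det <- det + 1
      if (out$max_burden[i] >= 10 && !out$has_seizure[i]) fp <- fp + 1
    }
    expect_equal(m$detected, det)
    expect_equal(m$false_flags, fp)
    expect_equal(m$sensitivity, 100 * det / sum(out$has_seizure))
  })
})

test_that("negative predictive value counts seizure-free zero-burden records", {
  ref <- reference_cohort()
  npv <- negative_predictive_value(ref$outcomes)
  expect_equal(npv$n_zero_burden, 179)
  expect_equal(npv$true_negative, 177)
  expect_equal(round(npv$npv), 99)

  clean <- tibble::tibble(max_burden = c(0, 0, 50), has_seizure = c(FALSE, FALSE, TRUE))
  expect_equal(negative_predictive_value(clean)$npv, 100)
  bad <- tibble::tibble(max_burden = 0, has_seizure = TRUE)
  expect_equal(negative_predictive_value(bad)$npv, 0)
  none <- tibble::tibble(max_burden = 50, has_seizure = TRUE)
  expect_error(negative_predictive_value(none),
               class = "szburden_error_undefined_metric")
})

test_that("false-detection rate divides events by hours", {
  expect_equal(round(fdr_per_hour(383, 1052), 2), 0.36)
  expect_equal(round(fdr_per_hour(62, 1052), 2), 0.06)
  expect_equal(fdr_per_hour(0, 10), 0)
  expect_error(fdr_per_hour(5, 0), class = "szburden_error_input")
})

test_that("the full report assembles patient, event and record metrics", {
  ref <- reference_cohort()
  rep <- metrics_report(ref$outcomes, ref$event_counts, ref$hours,
                        ref$overall_fp)
  expect_s3_class(rep, "szburden_metrics")
  expect_equal(round(rep$event$sensitivity[rep$event$threshold == 90], 1),
               92.3)  # 12/13
  expect_equal(rep$event$sensitivity[rep$event$threshold == 50], 100)
  expect_equal(round(rep$event$sensitivity[rep$event$threshold == 10], 1),
               80.0)  # 28/35
  expect_equal(round(rep$event$fdr_per_hour, 2), c(0.06, 0.13, 0.31))
  expect_equal(round(rep$overall_fdr, 2), 0.36)

  td <- tidy(rep)
  expect_true(all(c("level", "threshold", "metric", "estimate") %in% names(td)))
  expect_true(any(td$metric == "npv"))
  gl <- glance(rep)
  expect_equal(gl$n_records, 353)
  expect_equal(gl$se_alert_sensitivity, 100)

  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$confusion$total, 353)
})
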