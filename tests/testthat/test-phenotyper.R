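# Hand-built fixtures (helper-fixtures.R) exercise each selection criterion
# independently of the generator.

test_that("the hand-built fixture yields one exclusion per criterion", {
  fx <- hand_fixture()
  cohort <- select_cohort(fx$data, fx$extractions)
  expect_equal(unname(cohort$exclusion_counts),
               c(1L, 1L, 1L, 1L))
  expect_setequal(cohort$included_ids, c("A", "F"))
  expect_equal(cohort$same_day_excluded, "F")
  expect_equal(cohort$analysis_ids, "A")
  att <- attrition_summary(cohort, 6)
  expect_equal(att$n_analysis, 1)
  expect_equal(sum(unlist(att$excluded)) + att$n_included, att$n_input)
})

test_that("two distinct dementia-code dates are not enough", {
  fx <- hand_fixture()
  cohort <- select_cohort(fx$data, fx$extractions)
  expect_false("B" %in% cohort$included_ids)
  expect_equal(unname(cohort$exclusion_counts["dementia_diagnosis"]), 1L)
})

test_that("diagnosis date is the earlier of code and note evidence", {
  dxr <- data.frame(patient_id = "X",
                    date = c("2016-03-01", "2016-06-01", "2016-09-01"),
                    code = "F03.90", stringsAsFactors = FALSE)
  ext <- ext_row("X", "2016-05-15", "DX", "dementia")
  expect_equal(first_diagnosis_date(dxr, ext), as.Date("2016-03-01"))
  # note evidence only
  no_codes <- dxr[0, ]
  expect_equal(first_diagnosis_date(no_codes, ext), as.Date("2016-05-15"))
  # equal dates
  ext2 <- ext_row("X", "2016-03-01", "DX", "dementia")
  expect_equal(first_diagnosis_date(dxr, ext2), as.Date("2016-03-01"))
  expect_error(first_diagnosis_date(no_codes, ext[0, ]), "no qualifying")
})

test_that("ICD prefix matching is dot-insensitive", {
  dxr <- data.frame(patient_id = "X", date = c("2016-01-01", "2016-02-01"),
                    code = c("294.10", "G30.9"), stringsAsFactors = FALSE)
  crit <- cohort_criteria()
  expect_length(memotrace:::dementia_code_dates(dxr, crit), 2)
  dxr2 <- data.frame(patient_id = "X", date = "2016-01-01", code = "I10",
                     stringsAsFactors = FALSE)
  expect_length(memotrace:::dementia_code_dates(dxr2, crit), 0)
})

test_that("first complaint date requires a mapped memory-loss concept", {
  ext <- rbind(ext_row("X", "2015-07-01", "SX", "memory_loss"),
               ext_row("X", "2015-04-01", "SX", "forgetfulness"))
  expect_equal(first_complaint_date(ext), as.Date("2015-04-01"))
  unmapped <- ext_row("X", "2015-04-01", "SX", "UNMAPPED")
  expect_error(first_complaint_date(unmapped), "no note with")
})

test_that("duplicate patient ids are rejected", {
  fx <- hand_fixture()
  fx$data$patients <- rbind(fx$data$patients, fx$data$patients[1, ])
  expect_error(select_cohort(fx$data, fx$extractions), "duplicate")
})

test_that("the recovered cohort equals the generator's planted membership", {
  ds <- synth_small()
  ext <- normalize_extractions(ds$notes)
  cohort <- select_cohort(ds, ext)
  gt <- ds$ground_truth
  expect_setequal(cohort$included_ids, gt$patient_id[gt$in_cohort])
  expect_setequal(cohort$analysis_ids,
                  gt$patient_id[gt$in_cohort & !gt$same_day])
  expect_setequal(cohort$same_day_excluded,
                  gt$patient_id[gt$in_cohort & gt$same_day])
  # each planted archetype is excluded at its criterion
  expect_gte(cohort$exclusion_counts[["dementia_diagnosis"]], 1)
  expect_gte(cohort$exclusion_counts[["annual_visits"]], 1)
  expect_gte(cohort$exclusion_counts[["visit_before_diagnosis"]], 1)
  expect_gte(cohort$exclusion_counts[["memory_symptom"]], 1)
  # planted index dates are recovered exactly
  m <- merge(cohort$index_dates, gt, by = "patient_id")
  expect_true(all(m$first_complaint_date.x == m$first_complaint_date.y))
  expect_true(all(m$first_dx_date.x == m$first_dx_date.y))
  # analysis patients always have an interval of at least one day
  rec <- build_trajectories(cohort, ds, ext)
  expect_true(all(rec$interval_days >= 1))
})
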