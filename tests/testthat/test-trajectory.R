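make_records <- function(n, seed = 1, or_complaint = 1, shifts = FALSE) {
  # minimal self-contained trajectory records for model tests
  set.seed(seed)
  loc <- c("primary_care", "geriatrics", "neurology", "other")
  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    first_complaint_date = as.Date("2014-01-01"),
    interval_days = 1L,
    n_complaints = pmin(18, 1 + rnbinom(n, size = 1.5, mu = 3)),
    complaint_location = sample(loc, n, TRUE),
    dx_location = sample(loc, n, TRUE),
    age_group = sample(c("<65", "65-74", "75-84", "85+"), n, TRUE),
    insurance = sample(c("commercial", "medicare", "medicaid"), n, TRUE),
    caregiver_group = sample(c("husband", "wife", "daughter",
                               "other_adult_children", "other_family_support"),
                             n, TRUE),
    stringsAsFactors = FALSE)
  shift <- if (shifts) ifelse(df$complaint_location == "geriatrics", -141, 0) else 0
  df$interval_days <- as.integer(round(pmax(
    1, 600 + shift + rnorm(n, 0, 150))))
  df$first_dx_date <- df$first_complaint_date + df$interval_days
  eta <- -1.5 + log(or_complaint) * df$n_complaints
  df$prior_med <- runif(n) < plogis(eta)
  class(df) <- c("trajectory_records", "data.frame")
  df
}

test_that("trajectory features obey their date and boundary rules", {
  ds <- synth_small()
  ext <- normalize_extractions(ds$notes)
  cohort <- select_cohort(ds, ext)
  rec <- build_trajectories(cohort, ds, ext)
  gt <- ds$ground_truth
  m <- merge(rec, gt, by = "patient_id")
  expect_equal(m$interval_days.x,
               as.integer(as.Date(m$first_dx_date.y) -
                            as.Date(m$first_complaint_date.y)))
  expect_true(all(m$interval_days.x >= 1))
  expect_equal(m$n_complaints.x, m$n_complaints.y)
  expect_equal(m$prior_med.x, m$prior_med.y)
  expect_equal(m$complaint_location.x, m$complaint_location.y)
  expect_equal(m$dx_location.x, m$dx_location.y)
  expect_equal(m$age_group.x, m$age_group.y)
  has_cg <- m$caregiver_relation != "missing"
  expect_equal(m$caregiver_group.x[has_cg], m$caregiver_group.y[has_cg])
  expect_true(all(is.na(m$caregiver_group.x[!has_cg])))
})

test_that("a medication order on the diagnosis date does not count as prior", {
  ds <- synth_small()
  ext <- normalize_extractions(ds$notes)
  cohort <- select_cohort(ds, ext)
  # move one treated patient's order onto the diagnosis date
  rec0 <- build_trajectories(cohort, ds, ext)
  treated <- rec0$patient_id[rec0$prior_med][1]
  expect_false(is.na(treated))
  dxd <- rec0$first_dx_date[rec0$patient_id == treated]
  ds2 <- ds
  sel <- ds2$medications$patient_id == treated
  ds2$medications$date[sel] <- as.character(dxd)
  ext2 <- ext[!(ext$patient_id == treated & ext$label == "RX"), ]
  rec2 <- build_trajectories(cohort, ds2, ext2)
  expect_false(rec2$prior_med[rec2$patient_id == treated])
})

test_that("interval arithmetic matches the worked example", {
  d <- as.Date("2015-12-09") - as.Date("2015-01-01")
  expect_equal(as.integer(d), 342)
})

test_that("distribution summaries use Tukey hinges and exact extremes", {
  rec <- data.frame(interval_days = c(1, 342, 1458), n_complaints = c(1, 3, 18))
  class(rec) <- c("trajectory_records", "data.frame")
  s <- describe_intervals(rec)
  expect_equal(unname(s$interval_days[c("min", "median", "max")]),
               c(1, 342, 1458))
  expect_equal(unname(s$n_complaints[["median"]]), 3)
  one <- rec[2, , drop = FALSE]
  s1 <- describe_intervals(one)
  expect_true(all(s1$interval_days == 342))
  # order invariance
  shuffled <- rec[c(3, 1, 2), ]
  expect_equal(describe_intervals(shuffled), s)
  expect_error(describe_intervals(rec[0, ]), "no records")
})

test_that("null data give interval-model coverage at the nominal rate", {
  rec <- make_records(4000, seed = 21)
  res <- fit_interval_model(rec)$table
  est <- res[!res$reference, ]
  covered <- est$ci_low <= 0 & est$ci_high >= 0
  expect_gte(mean(covered), 0.85)
  # reference rows carry no estimate
  refs <- res[res$reference, ]
  expect_true(all(is.na(refs$estimate)))
  expect_setequal(refs$level, c("85+", "commercial", "primary_care", "husband"))
})

test_that("a planted geriatrics-complaint effect is recovered within 15 days", {
  rec <- make_records(20000, seed = 22, shifts = TRUE)
  res <- fit_interval_model(rec)$table
  g <- res[res$factor == "complaint_location" & res$level == "geriatrics", ]
  expect_lt(abs(g$estimate - (-141)), 15)
  expect_true(g$ci_low <= g$estimate & g$estimate <= g$ci_high)
})

test_that("the medication model recovers a planted per-complaint odds ratio", {
  rec <- make_records(8000, seed = 23, or_complaint = 1.148)
  res <- fit_medication_model(rec)$table
  nc <- res[res$factor == "n_complaints", ]
  expect_true(nc$ci_low <= 1.148 && 1.148 <= nc$ci_high)
  expect_lt(abs(nc$estimate - 1.148), 0.06)
  # null outcome: odds-ratio CIs cover 1
  rec0 <- make_records(4000, seed = 24, or_complaint = 1)
  res0 <- fit_medication_model(rec0)$table
  est0 <- res0[!res0$reference, ]
  expect_gte(mean(est0$ci_low <= 1 & est0$ci_high >= 1), 0.85)
})

test_that("degenerate outcomes raise a separation error", {
  rec <- make_records(100, seed = 25)
  rec$prior_med <- TRUE
  expect_error(fit_medication_model(rec), "outcome classes")
})

test_that("too few records are rejected by the interval model", {
  rec <- make_records(20, seed = 26)
  expect_error(fit_interval_model(rec), "at least 30")
})

test_that("the analysis report files are written and consistent", {
  rec <- make_records(500, seed = 27)
  dir <- withr::local_tempdir()
  write_trajectory_report(rec, dir)
  expect_true(file.exists(file.path(dir, "trajectories.csv")))
  desc <- jsonlite::read_json(file.path(dir, "descriptives.json"))
  expect_equal(desc$interval_days$median,
               unname(describe_intervals(rec)$interval_days[["median"]]))
  models <- jsonlite::read_json(file.path(dir, "association_models.json"))
  expect_named(models, c("interval_model", "medication_model"))
})
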