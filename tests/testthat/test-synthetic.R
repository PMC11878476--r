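test_that("generation is byte-identical under a fixed seed and differs across seeds", {
  cfg <- generator_config(n_patients = 25, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_ehr(cfg), d1)
  write_dataset(generate_ehr(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
  d3 <- withr::local_tempdir()
  write_dataset(generate_ehr(generator_config(n_patients = 25, seed = 78)), d3)
  h3 <- unname(tools::md5sum(file.path(d3, "ground_truth.json")))
  expect_false(identical(h3, unname(tools::md5sum(file.path(d1, "ground_truth.json")))))
})

test_that("invalid marginals are rejected before generation", {
  expect_error(generator_config(sex_probs = c(female = -0.1, male = 1.1)),
               "negative probability")
})

test_that("gold annotations slice the note text exactly", {
  for (n in notes_small()) {
    e <- n$entities
    if (nrow(e) == 0) next
    expect_identical(substring(n$text, e$start + 1, e$end), e$surface)
  }
})

test_that("structured tables are mutually consistent", {
  ds <- synth_small()
  # every note has a visit on its date
  key_v <- paste(ds$visits$patient_id, ds$visits$date)
  for (n in ds$notes)
    expect_true(paste(n$patient_id, as.character(n$note_date)) %in% key_v)
  # all ids resolve to the patient table
  expect_true(all(ds$visits$patient_id %in% ds$patients$patient_id))
  expect_true(all(ds$diagnoses$patient_id %in% ds$patients$patient_id))
  expect_true(all(ds$medications$patient_id %in% ds$patients$patient_id))
  # cohort members have at least three distinct dementia-code dates
  gt <- ds$ground_truth
  crit <- cohort_criteria()
  for (pid in gt$patient_id[gt$in_cohort]) {
    dxr <- ds$diagnoses[ds$diagnoses$patient_id == pid, ]
    expect_gte(length(memotrace:::dementia_code_dates(dxr, crit)), 3)
  }
})

test_that("the five exclusion archetypes are always present", {
  ds <- synth_small()
  gt <- ds$ground_truth
  ids <- c("EXCL_CODES", "EXCL_GAPYEAR", "EXCL_NOVISIT", "EXCL_NOSX",
           "EXCL_SAMEDAY")
  expect_true(all(ids %in% gt$patient_id))
  expect_false(any(gt$in_cohort[gt$patient_id %in% ids[1:4]]))
  expect_true(gt$in_cohort[gt$patient_id == "EXCL_SAMEDAY"])
  expect_true(gt$same_day[gt$patient_id == "EXCL_SAMEDAY"])
})

test_that("noise knobs force abbreviation and brand-name surfaces", {
  run_seeded <- function(code) memotrace:::run_with_seed(99, code)
  pools <- run_seeded(memotrace:::synth_pools())
  s <- run_seeded(memotrace:::draw_caregiver_surface(pools, "daughter", 1))
  expect_true(s %in% c("dtr", "dghtr"))
  expect_equal(normalize_caregiver(s), "daughter")
  s0 <- run_seeded(memotrace:::draw_caregiver_surface(pools, "daughter", 0))
  expect_equal(s0, "daughter")
  b <- run_seeded(memotrace:::draw_drug_surface(pools, "donepezil", 1))
  expect_equal(b, "Aricept")
  expect_equal(normalize_medication(b), "donepezil")
  g <- run_seeded(memotrace:::draw_drug_surface(pools, "donepezil", 0))
  expect_equal(g, "donepezil")
})

test_that("distractor-only notes carry no gold entities", {
  pools <- memotrace:::synth_pools()
  rn <- memotrace:::run_with_seed(1, memotrace:::render_distractor_note(pools))
  expect_equal(nrow(rn$entities), 0)
  expect_gt(nchar(rn$text), 0)
})

test_that("tabular extraction equals rendered-note extraction up to surfaces", {
  ds <- synth_small()
  rendered <- normalize_extractions(ds$notes)
  a <- rendered[rendered$label %in% c("SX", "CAREGIVER_RELATION", "RX", "DX"),
                c("doc_id", "label", "canonical")]
  b <- ds$extractions[, c("doc_id", "label", "canonical")]
  a <- a[order(a$doc_id, a$label, a$canonical), ]
  b <- b[order(b$doc_id, b$label, b$canonical), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("department marginals match their configured probabilities", {
  cfg <- generator_config(n_patients = 5000, seed = 101,
                          include_archetypes = FALSE)
  ds <- generate_ehr(cfg, render_notes = FALSE)
  gt <- ds$ground_truth
  share_ger <- mean(gt$complaint_location == "geriatrics")
  expect_lt(abs(share_ger - 0.53), 0.03)
  share_dxg <- mean(gt$dx_location == "geriatrics")
  expect_lt(abs(share_dxg - 0.602), 0.03)
  # complaint counts (analysis patients): planted median 3, range within 1..18
  expect_equal(median(gt$n_complaints[!gt$same_day]), 3)
  expect_gte(min(gt$n_complaints), 1)
  expect_lte(max(gt$n_complaints), 18)
})
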