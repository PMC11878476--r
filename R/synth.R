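# Synthetic EHR generator: structured tables plus clinical notes with gold
# standoff annotations, with planted, configurable ground truth. Defaults
# reproduce the study-scale marginals of a single-site outpatient dementia
# cohort: demographic and care-location mixes, a 20.4% same-day
# complaint/diagnosis rate, a log-normal complaint-to-diagnosis interval
# with marginal median 342 days shifted additively by care location and
# caregiver group, a truncated negative-binomial complaint count with median
# 3 on 1..18, and a logistic pre-diagnosis medication model with odds 1.148
# per additional complaint. Intercept-like parameters (the reference-level
# interval median and the medication intercept) are calibrated numerically
# at configuration time so the planted marginals hold exactly.

#' Generator configuration
#'
#' All probabilities, planted effects and noise knobs of the synthetic EHR.
#' Categorical probability vectors must sum to 1 (they are renormalized from
#' published rounded proportions). The seed fully determines the output.
#'
#' @param n_patients Number of cohort-candidate patients (the always-present
#'   excluded archetypes are appended on top when
#'   `include_archetypes = TRUE`).
#' @param seed RNG seed.
#' @param age_probs,sex_probs,race_probs,insurance_probs Demographic
#'   marginals.
#' @param complaint_loc_probs,dx_loc_probs Department marginals for the first
#'   complaint and the diagnosis.
#' @param caregiver_probs Marginal over canonical caregiver relations
#'   including `missing`.
#' @param same_day_rate Fraction of cohort patients whose first complaint and
#'   diagnosis share a date (retained in the cohort, excluded from
#'   analysis).
#' @param interval_median Target marginal median of the complaint-to-
#'   diagnosis interval in days (analysis patients).
#' @param interval_sigma Log-normal sigma of the interval noise.
#' @param interval_max Upper clamp on intervals, days.
#' @param complaint_loc_shift,dx_loc_shift,caregiver_shift Additive day
#'   shifts per level (reference levels primary care / husband at 0).
#' @param nb_size,nb_mu Negative-binomial parameters of the complaint count
#'   before truncation to `1..complaint_max`.
#' @param complaint_max Maximum complaint count.
#' @param med_or_per_complaint Planted odds ratio of pre-diagnosis medication
#'   per additional complaint. Other medication-model effects are planted at
#'   zero (null).
#' @param med_rate Target marginal pre-diagnosis medication rate.
#' @param abbreviation_rate,brand_rate,distractor_rate,satellite_rate,test_rate
#'   Note-surface noise knobs.
#' @param date_start,date_end Window for first-complaint dates.
#' @param include_archetypes Append the five planted exclusion archetypes
#'   (one per selection criterion plus a same-day patient).
#' @return A `generator_config` with calibrated internals
#'   (`interval_base_median`, `med_intercept`).
#' @export
generator_config <- function(
    n_patients = 500,
    seed = 1,
    age_probs = c("<65" = 0.055, "65-74" = 0.108, "75-84" = 0.294, "85+" = 0.542),
    sex_probs = c(female = 0.656, male = 0.344),
    race_probs = c(white = 0.876, african_american = 0.057, other = 0.067),
    insurance_probs = c(commercial = 0.262, medicare = 0.609,
                        medicaid = 0.124, none = 0.003),
    complaint_loc_probs = c(geriatrics = 0.53, primary_care = 0.318,
                            neurology = 0.067, other = 0.085),
    dx_loc_probs = c(geriatrics = 0.602, primary_care = 0.281,
                     neurology = 0.105, other = 0.012),
    caregiver_probs = c(missing = 0.499, husband = 0.0448, wife = 0.0671,
                        daughter = 0.2324, son = 0.0603, son_in_law = 0.0086,
                        daughter_in_law = 0.0086, grandson = 0.0043,
                        granddaughter = 0.0043, nephew = 0.0141,
                        niece = 0.0141, cousin = 0.0141, brother = 0.0142,
                        sister = 0.0141),
    same_day_rate = 149 / 730,
    interval_median = 342,
    interval_sigma = 0.8,
    interval_max = 1460,
    complaint_loc_shift = c(primary_care = 0, geriatrics = -141,
                            neurology = -158, other = 81),
    dx_loc_shift = c(primary_care = 0, geriatrics = -152.9,
                     neurology = -82.2, other = 42),
    caregiver_shift = c(husband = 0, wife = -249.6, daughter = -176.8,
                        other_adult_children = -127.4,
                        other_family_support = -257.5, missing = 0),
    nb_size = 1.5, nb_mu = 3.5, complaint_max = 18,
    med_or_per_complaint = 1.148, med_rate = 0.251,
    abbreviation_rate = 0.3, brand_rate = 0.5, distractor_rate = 0.5,
    satellite_rate = 0.5, test_rate = 0.1,
    date_start = "2011-01-01", date_end = "2014-12-31",
    include_archetypes = TRUE) {
  norm1 <- function(p) {
    if (any(p < 0)) stop("negative probability")
    p / sum(p)
  }
  cfg <- list(
    n_patients = n_patients, seed = seed,
    age_probs = norm1(age_probs), sex_probs = norm1(sex_probs),
    race_probs = norm1(race_probs), insurance_probs = norm1(insurance_probs),
    complaint_loc_probs = norm1(complaint_loc_probs),
    dx_loc_probs = norm1(dx_loc_probs),
    caregiver_probs = norm1(caregiver_probs),
    same_day_rate = same_day_rate,
    interval_median = interval_median, interval_sigma = interval_sigma,
    interval_max = interval_max,
    complaint_loc_shift = complaint_loc_shift, dx_loc_shift = dx_loc_shift,
    caregiver_shift = caregiver_shift,
    nb_size = nb_size, nb_mu = nb_mu, complaint_max = complaint_max,
    med_or_per_complaint = med_or_per_complaint, med_rate = med_rate,
    noise = list(abbreviation_rate = abbreviation_rate, brand_rate = brand_rate,
                 distractor_rate = distractor_rate,
                 satellite_rate = satellite_rate, test_rate = test_rate),
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    include_archetypes = include_archetypes)
  cfg$interval_base_median <- calibrate_interval_base(cfg)
  cfg$med_intercept <- calibrate_med_intercept(cfg)
  structure(cfg, class = "generator_config")
}

caregiver_to_group <- function(relation) {
  ifelse(relation == "missing", "missing",
         unname(caregiver_group_map[relation]))
}

# total additive interval shift for given locations and caregiver group
interval_shift <- function(cfg, comploc, dxloc, cg_group) {
  cfg$complaint_loc_shift[comploc] + cfg$dx_loc_shift[dxloc] +
    cfg$caregiver_shift[cg_group]
}

# Reference-level log-normal median m0 such that the marginal median of
# max(1, shift + LogNormal(log m0, sigma)) over the covariate mixture equals
# the configured interval median. The lower clamp does not move mass across
# the target, so the mixture CDF is exact.
calibrate_interval_base <- function(cfg) {
  target <- cfg$interval_median
  cells <- expand.grid(cl = names(cfg$complaint_loc_probs),
                       dl = names(cfg$dx_loc_probs),
                       cg = names(cfg$caregiver_probs),
                       stringsAsFactors = FALSE)
  w <- cfg$complaint_loc_probs[cells$cl] * cfg$dx_loc_probs[cells$dl] *
    cfg$caregiver_probs[cells$cg]
  sh <- as.numeric(interval_shift(cfg, cells$cl, cells$dl,
                                  caregiver_to_group(cells$cg)))
  if (any(sh >= target)) stop("a positive shift exceeds the target median")
  f <- function(log_m0) {
    sum(w * pnorm((log(target - sh) - log_m0) / cfg$interval_sigma)) - 0.5
  }
  exp(uniroot(f, c(log(10), log(50000)))$root)
}

# Medication intercept b0 with E[plogis(b0 + log(OR) * N)] = med_rate over
# the truncated negative-binomial complaint count N.
calibrate_med_intercept <- function(cfg) {
  k <- seq_len(cfg$complaint_max)
  pk <- dnbinom(k, size = cfg$nb_size, mu = cfg$nb_mu)
  pk <- pk / sum(pk)
  beta <- log(cfg$med_or_per_complaint)
  f <- function(b0) sum(pk * plogis(b0 + beta * k)) - cfg$med_rate
  uniroot(f, c(-12, 5))$root
}

rcat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

draw_truncated_nb <- function(n, cfg) {
  k <- seq_len(cfg$complaint_max)
  pk <- dnbinom(k, size = cfg$nb_size, mu = cfg$nb_mu)
  k[sample.int(length(k), n, replace = TRUE, prob = pk)]
}

age_range_for_group <- c("<65" = "55:64", "65-74" = "65:74",
                         "75-84" = "75:84", "85+" = "85:97")

draw_age <- function(groups) {
  vapply(groups, function(g) {
    r <- as.integer(strsplit(age_range_for_group[g], ":")[[1]])
    sample(seq(r[1], r[2]), 1)
  }, integer(1))
}

#' Generate a synthetic EHR dataset
#'
#' Draws patient-level ground truth (demographics, locations, caregiver,
#' same-day status, interval, complaint count, medication flag), then derives
#' mutually consistent structured tables and — optionally — rendered clinical
#' notes with gold standoff annotations. Gold relations are obtained by
#' nearest-in-sentence linking over the gold entities.
#'
#' @param config A [generator_config()].
#' @param render_notes Render note text and gold annotations (`TRUE`) or emit
#'   only structured tables and the gold extraction table (`FALSE`, faster
#'   for large cohorts).
#' @param link_gold Compute gold relations for rendered notes.
#' @return Object of class `synthetic_ehr`: list with `patients`, `visits`,
#'   `diagnoses`, `medications` (data frames), `notes` (list of
#'   `annotated_note` or `NULL`), `extractions` (gold extraction table),
#'   `ground_truth` (per-patient planted values) and `config`.
#' @export
generate_ehr <- function(config = generator_config(), render_notes = TRUE,
                         link_gold = TRUE) {
  run_with_seed(config$seed, generate_ehr_impl(config, render_notes, link_gold))
}

generate_ehr_impl <- function(cfg, render_notes, link_gold) {
  n <- cfg$n_patients
  pid <- sprintf("P%05d", seq_len(n))

  age_group <- rcat(n, cfg$age_probs)
  sex <- rcat(n, cfg$sex_probs)
  race <- rcat(n, cfg$race_probs)
  insurance <- rcat(n, cfg$insurance_probs)
  comploc <- rcat(n, cfg$complaint_loc_probs)
  dxloc <- rcat(n, cfg$dx_loc_probs)
  caregiver <- rcat(n, cfg$caregiver_probs)
  cg_group <- caregiver_to_group(caregiver)
  same_day <- runif(n) < cfg$same_day_rate

  shift <- as.numeric(interval_shift(cfg, comploc, dxloc, cg_group))
  noise <- rlnorm(n, log(cfg$interval_base_median), cfg$interval_sigma)
  interval <- pmax(1, pmin(cfg$interval_max, round(shift + noise)))
  interval[same_day] <- 0L

  n_complaints <- draw_truncated_nb(n, cfg)
  n_complaints <- pmin(n_complaints, pmax(interval, 1L))

  eta <- cfg$med_intercept + log(cfg$med_or_per_complaint) * n_complaints
  prior_med <- runif(n) < plogis(eta)
  prior_med[same_day] <- FALSE

  c0 <- cfg$date_start +
    floor(runif(n) * (as.numeric(cfg$date_end - cfg$date_start) + 1))
  dx_date <- c0 + interval
  age <- draw_age(age_group)
  birth_year <- as.integer(format(dx_date, "%Y")) - age

  truth <- data.frame(
    patient_id = pid, in_cohort = TRUE, same_day = same_day,
    first_complaint_date = c0, first_dx_date = dx_date,
    interval_days = as.integer(interval), n_complaints = n_complaints,
    prior_med = prior_med, complaint_location = comploc, dx_location = dxloc,
    caregiver_relation = caregiver, caregiver_group = cg_group,
    age_group = age_group, insurance = insurance, sex = sex, race = race,
    stringsAsFactors = FALSE)

  pools <- synth_pools()
  per <- vector("list", n)
  for (i in seq_len(n)) {
    per[[i]] <- build_patient(cfg, pools, truth[i, ], render_notes, link_gold)
  }
  if (cfg$include_archetypes) {
    arch <- build_archetypes(cfg, pools, render_notes, link_gold)
    per <- c(per, arch$per)
    truth <- rbind(truth, arch$truth)
  }

  patients <- data.frame(
    patient_id = truth$patient_id,
    birth_year = c(birth_year, if (cfg$include_archetypes)
      rep(1940L, nrow(truth) - n) else integer()),
    sex = truth$sex, race = truth$race, insurance = truth$insurance,
    stringsAsFactors = FALSE)

  bindcat <- function(field) do.call(rbind, lapply(per, `[[`, field))
  ds <- list(
    patients = patients,
    visits = bindcat("visits"),
    diagnoses = bindcat("diagnoses"),
    medications = bindcat("medications"),
    notes = if (render_notes) do.call(c, lapply(per, `[[`, "notes")) else NULL,
    extractions = bindcat("extractions"),
    ground_truth = truth,
    config = cfg)
  rownames(ds$ground_truth) <- NULL
  class(ds) <- "synthetic_ehr"
  ds
}

#' @export
print.synthetic_ehr <- function(x, ...) {
  cat("<synthetic_ehr> ", nrow(x$patients), " patients, ",
      nrow(x$visits), " visits, ",
      if (is.null(x$notes)) "no rendered notes" else
        paste0(length(x$notes), " notes"), "\n", sep = "")
  invisible(x)
}

# Build all rows for one patient from its ground-truth record.
build_patient <- function(cfg, pools, tr, render_notes, link_gold,
                          overrides = list()) {
  pid <- tr$patient_id
  c0 <- as.Date(tr$first_complaint_date)
  dxd <- as.Date(tr$first_dx_date)
  nC <- tr$n_complaints
  # distinct complaint note dates: c0 plus nC-1 draws from (c0, dxd)
  extra <- if (nC > 1) sort(sample(seq_len(as.numeric(dxd - c0) - 1), nC - 1))
           else integer()
  complaint_dates <- c(c0, c0 + extra)

  sx_surfaces <- pools$sx[sample.int(length(pools$sx), nC, replace = TRUE)]
  cg_surface <- if (tr$caregiver_relation != "missing")
    draw_caregiver_surface(pools, tr$caregiver_relation,
                           cfg$noise$abbreviation_rate) else NULL
  drug_generic <- if (tr$prior_med) pick(pools$drug_generic) else NULL
  drug_surface <- if (tr$prior_med)
    draw_drug_surface(pools, drug_generic, cfg$noise$brand_rate) else NULL
  rx_note_idx <- if (tr$prior_med) sample.int(nC, 1) else 0L
  dx_surface <- pick(pools$dx)

  doc_ids <- sprintf("%s_N%02d", pid, seq_len(nC + 1))
  note_dates <- c(complaint_dates, dxd)
  note_depts <- c(rep(tr$complaint_location, nC), tr$dx_location)

  notes <- NULL
  ext_rows <- list()
  if (render_notes) notes <- vector("list", nC + 1)
  for (j in seq_len(nC)) {
    plan <- list(list(label = "SX", surface = sx_surfaces[j]))
    if (j == 1 && !is.null(cg_surface))
      plan <- c(plan, list(list(label = "CAREGIVER_RELATION", surface = cg_surface)))
    if (j == rx_note_idx)
      plan <- c(plan, list(list(label = "RX", surface = drug_surface)))
    ext_rows[[j]] <- plan_to_extractions(doc_ids[j], pid, note_dates[j],
                                         note_depts[j], plan)
    if (render_notes) {
      rn <- render_complaint_note(
        pools, cfg$noise, sx_surfaces[j],
        caregiver_surface = if (j == 1) cg_surface else NULL,
        drug_surface = if (j == rx_note_idx) drug_surface else NULL)
      notes[[j]] <- finish_note(rn, doc_ids[j], pid, note_dates[j],
                                note_depts[j], link_gold)
    }
  }
  ext_rows[[nC + 1]] <- plan_to_extractions(
    doc_ids[nC + 1], pid, dxd, tr$dx_location,
    list(list(label = "DX", surface = dx_surface)))
  if (render_notes) {
    rn <- render_dx_note(pools, cfg$noise, dx_surface)
    notes[[nC + 1]] <- finish_note(rn, doc_ids[nC + 1], pid, dxd,
                                   tr$dx_location, link_gold)
  }

  # visits: one per note plus fillers so every calendar year from the first
  # visit through the diagnosis year has a visit
  vdates <- note_dates
  vdepts <- note_depts
  if (!is.null(overrides$extra_visits)) {
    vdates <- c(overrides$extra_visits, vdates)
    vdepts <- c(rep("primary_care", length(overrides$extra_visits)), vdepts)
  }
  # same-day patients still have pre-diagnosis contact (just no complaint
  # note before the diagnosis day), so they keep an earlier routine visit
  if (tr$same_day && !isTRUE(overrides$no_prior_visit)) {
    vdates <- c(dxd - 400, vdates)
    vdepts <- c("primary_care", vdepts)
  }
  yrs <- seq(min(as.integer(format(vdates, "%Y"))),
             as.integer(format(dxd, "%Y")))
  missing_yrs <- if (isTRUE(overrides$skip_filler_visits)) integer() else
    setdiff(yrs, as.integer(format(vdates, "%Y")))
  if (length(missing_yrs)) {
    vdates <- c(vdates, as.Date(paste0(missing_yrs, "-06-15")))
    vdepts <- c(vdepts, rep("primary_care", length(missing_yrs)))
  }
  ord <- order(vdates)
  visits <- data.frame(patient_id = pid, date = as.character(vdates[ord]),
                       department = vdepts[ord], stringsAsFactors = FALSE)

  n_code_dates <- if (!is.null(overrides$n_code_dates)) overrides$n_code_dates else 3L
  code_pool <- c("G30.9", "F03.90", "F01.51", "G31.83", "294.10")
  code_dates <- dxd + c(0, 21, 45)[seq_len(n_code_dates)]
  diagnoses <- data.frame(patient_id = pid, date = as.character(code_dates),
                          code = code_pool[sample.int(length(code_pool),
                                                      n_code_dates, replace = TRUE)],
                          stringsAsFactors = FALSE)

  meds <- data.frame(patient_id = character(), date = character(),
                     drug = character(), stringsAsFactors = FALSE)
  if (tr$prior_med) {
    meds <- rbind(meds, data.frame(patient_id = pid,
                                   date = as.character(complaint_dates[rx_note_idx]),
                                   drug = drug_surface, stringsAsFactors = FALSE))
  }
  if (runif(1) < 0.3) {  # non-cognition distractor order
    meds <- rbind(meds, data.frame(patient_id = pid, date = as.character(c0),
                                   drug = pick(c("lisinopril", "metformin",
                                                 "atorvastatin")),
                                   stringsAsFactors = FALSE))
  }

  list(visits = visits, diagnoses = diagnoses, medications = meds,
       notes = notes,
       extractions = do.call(rbind, ext_rows))
}

plan_to_extractions <- function(doc_id, pid, date, dept, plan) {
  lex <- lexicon_cache()
  do.call(rbind, lapply(seq_along(plan), function(k) {
    p <- plan[[k]]
    canonical <- switch(p$label,
      SX = normalize_symptom(p$surface, lex),
      CAREGIVER_RELATION = normalize_caregiver(p$surface, lex),
      RX = normalize_medication(p$surface, lex),
      fold_surface(p$surface))
    data.frame(doc_id = doc_id, patient_id = pid, note_date = as.character(date),
               department = dept, entity_id = paste0("T", k), label = p$label,
               surface = p$surface, canonical = canonical,
               stringsAsFactors = FALSE)
  }))
}

# memoised lexicons (generation touches them per note)
lexicon_env <- new.env(parent = emptyenv())
lexicon_cache <- function() {
  if (is.null(lexicon_env$lex)) lexicon_env$lex <- load_lexicons()
  lexicon_env$lex
}

finish_note <- function(rendered, doc_id, pid, date, dept, link_gold) {
  note <- annotated_note(doc_id, rendered$text, rendered$entities,
                         empty_relations(), patient_id = pid,
                         note_date = date, department = dept)
  if (link_gold && nrow(note$entities) > 1) {
    note$relations <- link_relations(note)
  }
  note
}

# The five always-present excluded archetypes: one violates each selection
# criterion; the fifth is a guaranteed same-day patient.
build_archetypes <- function(cfg, pools, render_notes, link_gold) {
  base <- function(id, interval, n_complaints = 2, caregiver = "missing",
                   same_day = FALSE, in_cohort = FALSE) {
    data.frame(patient_id = id, in_cohort = in_cohort, same_day = same_day,
               first_complaint_date = as.Date("2012-03-01"),
               first_dx_date = as.Date("2012-03-01") + interval,
               interval_days = as.integer(interval),
               n_complaints = n_complaints, prior_med = FALSE,
               complaint_location = "primary_care", dx_location = "geriatrics",
               caregiver_relation = caregiver,
               caregiver_group = caregiver_to_group(caregiver),
               age_group = "85+", insurance = "medicare", sex = "female",
               race = "white", stringsAsFactors = FALSE)
  }
  per <- list(); truth <- list()
  add <- function(tr, overrides = list()) {
    p <- build_patient(cfg, pools, tr, render_notes, link_gold, overrides)
    per[[length(per) + 1]] <<- p
    truth[[length(truth) + 1]] <<- tr
  }
  # criterion 1: only two distinct dementia-code dates
  add(base("EXCL_CODES", 200), list(n_code_dates = 2L))
  # criterion 2: a calendar year without any visit (interval of 900 days
  # spans three calendar years; with a single complaint note and no filler
  # visits the middle year is empty)
  add(base("EXCL_GAPYEAR", 900, n_complaints = 1),
      list(skip_filler_visits = TRUE))
  # criterion 3: no visit before the diagnosis date (same-day-only contact)
  add(base("EXCL_NOVISIT", 0, n_complaints = 1, same_day = TRUE),
      list(no_prior_visit = TRUE))
  # criterion 4: no documented memory-loss symptom
  tr4 <- base("EXCL_NOSX", 300, n_complaints = 0)
  p4 <- build_no_sx_patient(cfg, pools, tr4, render_notes, link_gold)
  per[[length(per) + 1]] <- p4
  truth[[length(truth) + 1]] <- tr4
  # same-day patient: meets all criteria, excluded from analysis only
  add(base("EXCL_SAMEDAY", 0, n_complaints = 1, same_day = TRUE,
           in_cohort = TRUE))
  list(per = per, truth = do.call(rbind, truth))
}

# Archetype without any SX note: distractor notes plus the diagnosis note.
build_no_sx_patient <- function(cfg, pools, tr, render_notes, link_gold) {
  pid <- tr$patient_id
  c0 <- as.Date(tr$first_complaint_date)
  dxd <- as.Date(tr$first_dx_date)
  dx_surface <- pick(pools$dx)
  doc_ids <- sprintf("%s_N%02d", pid, 1:2)
  notes <- NULL
  if (render_notes) {
    rn1 <- render_distractor_note(pools)
    rn2 <- render_dx_note(pools, cfg$noise, dx_surface)
    notes <- list(finish_note(rn1, doc_ids[1], pid, c0, "primary_care", link_gold),
                  finish_note(rn2, doc_ids[2], pid, dxd, tr$dx_location, link_gold))
  }
  ext <- plan_to_extractions(doc_ids[2], pid, dxd, tr$dx_location,
                             list(list(label = "DX", surface = dx_surface)))
  vdates <- c(c0, dxd)
  visits <- data.frame(patient_id = pid, date = as.character(vdates),
                       department = c("primary_care", tr$dx_location),
                       stringsAsFactors = FALSE)
  diagnoses <- data.frame(patient_id = pid,
                          date = as.character(dxd + c(0, 21, 45)),
                          code = c("G30.9", "F03.90", "G30.9"),
                          stringsAsFactors = FALSE)
  list(visits = visits, diagnoses = diagnoses,
       medications = data.frame(patient_id = character(), date = character(),
                                drug = character(), stringsAsFactors = FALSE),
       notes = notes, extractions = ext)
}

#' Write a synthetic dataset to a directory
#'
#' Layout: `patients.csv`, `visits.csv`, `diagnoses.csv`, `medications.csv`,
#' `notes_meta.csv`, `notes/<doc>.txt`, `gold/<doc>.ann`,
#' `ground_truth.json`.
#'
#' @param ds A `synthetic_ehr` (with rendered notes).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "visits", "diagnoses", "medications"))
    write.csv(ds[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  if (!is.null(ds$notes)) {
    dir.create(file.path(dir, "notes"), showWarnings = FALSE)
    dir.create(file.path(dir, "gold"), showWarnings = FALSE)
    meta <- data.frame(
      doc_id = vapply(ds$notes, function(n) n$doc_id, character(1)),
      patient_id = vapply(ds$notes, function(n) as.character(n$patient_id), character(1)),
      note_date = vapply(ds$notes, function(n) as.character(n$note_date), character(1)),
      department = vapply(ds$notes, function(n) as.character(n$department), character(1)),
      stringsAsFactors = FALSE)
    for (n in ds$notes) {
      so <- write_standoff(n)
      writeLines(so$text, file.path(dir, "notes", paste0(n$doc_id, ".txt")), sep = "")
      writeLines(so$ann, file.path(dir, "gold", paste0(n$doc_id, ".ann")), sep = "")
    }
    write.csv(meta, file.path(dir, "notes_meta.csv"), row.names = FALSE)
  }
  gt <- ds$ground_truth
  gt$first_complaint_date <- as.character(gt$first_complaint_date)
  gt$first_dx_date <- as.character(gt$first_dx_date)
  jsonlite::write_json(
    list(schema_version = "1.0",
         planted = list(interval_median = ds$config$interval_median,
                        interval_base_median = ds$config$interval_base_median,
                        med_or_per_complaint = ds$config$med_or_per_complaint,
                        med_intercept = ds$config$med_intercept,
                        seed = ds$config$seed),
         patients = gt),
    file.path(dir, "ground_truth.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a corpus of annotated notes for tagger development
#'
#' Convenience wrapper: generates patients (without exclusion archetypes)
#' until at least `n_notes` rendered notes exist and returns the first
#' `n_notes`.
#'
#' @param n_notes Number of notes.
#' @param config A [generator_config()] (its `n_patients` is overridden).
#' @param seed Seed override.
#' @return List of `annotated_note` with gold entities and relations.
#' @export
generate_annotated_notes <- function(n_notes, config = generator_config(),
                                     seed = config$seed) {
  config$n_patients <- ceiling(n_notes / 2)
  config$seed <- seed
  config$include_archetypes <- FALSE
  ds <- generate_ehr(config, render_notes = TRUE)
  stopifnot(length(ds$notes) >= n_notes)
  ds$notes[seq_len(n_notes)]
}
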