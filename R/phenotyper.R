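# Cohort phenotyping from combined coded and note-derived evidence.
# A patient enters the dementia cohort when they (1) received a dementia
# diagnosis (>= `min_code_dates` distinct dementia ICD code dates plus
# dementia documentation in a note), (2) had at least one outpatient visit in
# every calendar year of observation, (3) had at least one visit before the
# diagnosis date, and (4) had a documented, normalizable memory-loss symptom.
# Patients whose first complaint and first diagnosis fall on the same day are
# retained in the included set but excluded from analysis.

#' Default dementia ICD code prefixes
#'
#' The shipped list (inst/extdata/dementia_icd_codes.csv) is a standard
#' ICD-9/ICD-10 dementia phenotyping set (F00-F03, F05.1, G30, G31.0,
#' G31.83; 290, 294.1, 331.0) assembled for this package; site-specific
#' phenotyping lists can be substituted via `cohort_criteria()`.
#'
#' @return Character vector of code prefixes.
#' @export
default_dementia_codes <- function() {
  df <- read.csv(system.file("extdata", "dementia_icd_codes.csv",
                             package = "memotrace"), stringsAsFactors = FALSE)
  df$code
}

#' Cohort selection criteria
#'
#' @param dementia_codes ICD code prefixes counting as dementia; a recorded
#'   code matches if it equals a prefix or extends it at a subcategory
#'   boundary (e.g. "G30.9" matches "G30").
#' @param min_code_dates Minimum number of distinct dates carrying a dementia
#'   code (distinct dates, not code copies, to avoid duplicate-coding
#'   artifacts).
#' @param require_annual_visits Require >= 1 visit in every calendar year
#'   from first visit through the diagnosis year.
#' @param require_visit_before_dx Require >= 1 visit strictly before the
#'   diagnosis date.
#' @param require_memory_symptom Require >= 1 note with an SX entity whose
#'   normalized concept is a memory-loss concept.
#' @param require_dx_note Require dementia documentation (a DX entity) in the
#'   notes.
#' @return A `cohort_criteria` list.
#' @export
cohort_criteria <- function(dementia_codes = default_dementia_codes(),
                            min_code_dates = 3,
                            require_annual_visits = TRUE,
                            require_visit_before_dx = TRUE,
                            require_memory_symptom = TRUE,
                            require_dx_note = TRUE) {
  stopifnot(min_code_dates >= 1)
  structure(list(dementia_codes = dementia_codes,
                 min_code_dates = min_code_dates,
                 require_annual_visits = require_annual_visits,
                 require_visit_before_dx = require_visit_before_dx,
                 require_memory_symptom = require_memory_symptom,
                 require_dx_note = require_dx_note),
            class = "cohort_criteria")
}

is_dementia_code <- function(code, prefixes) {
  # dot-insensitive prefix match: "G30.9" matches "G30", "294.10" matches "294.1"
  code <- gsub(".", "", toupper(trimws(code)), fixed = TRUE)
  prefixes <- gsub(".", "", toupper(prefixes), fixed = TRUE)
  out <- rep(FALSE, length(code))
  for (p in prefixes) out <- out | startsWith(code, p)
  out
}

# distinct dates on which the patient carries a dementia code
dementia_code_dates <- function(dx_rows, criteria) {
  hit <- is_dementia_code(dx_rows$code, criteria$dementia_codes)
  sort(unique(as.Date(dx_rows$date[hit])))
}

#' First dementia diagnosis date for one patient
#'
#' The earlier of the first structured dementia-code date and the first note
#' date carrying a DX entity; diagnosis and medication evidence is drawn
#' from both structured and unstructured data.
#'
#' @param dx_rows Diagnosis rows for the patient (`date`, `code`).
#' @param patient_extractions Extraction-table rows for the patient.
#' @param criteria A [cohort_criteria()].
#' @return A `Date`.
#' @export
first_diagnosis_date <- function(dx_rows, patient_extractions, criteria = cohort_criteria()) {
  code_dates <- dementia_code_dates(dx_rows, criteria)
  note_dates <- as.Date(patient_extractions$note_date[patient_extractions$label == "DX"])
  cand <- c(code_dates[1], sort(note_dates)[1])
  cand <- cand[!is.na(cand)]
  if (!length(cand)) stop("no qualifying dementia diagnosis evidence")
  min(cand)
}

#' First memory-loss complaint date for one patient
#'
#' Earliest note date among notes containing an SX entity whose normalized
#' concept is a memory-loss concept.
#'
#' @param patient_extractions Extraction-table rows for the patient
#'   (from [normalize_extractions()]).
#' @return A `Date`.
#' @export
first_complaint_date <- function(patient_extractions) {
  hit <- patient_extractions$label == "SX" &
    patient_extractions$canonical %in% memory_loss_concepts()
  if (!any(hit)) stop("no note with a normalized memory-loss symptom")
  min(as.Date(patient_extractions$note_date[hit]))
}

#' Select the study cohort
#'
#' Applies the four inclusion criteria in order, attributing each exclusion
#' to the first failing criterion, then flags included patients whose first
#' complaint and first diagnosis share a date; those are removed from the
#' analysis set.
#'
#' @param data An EHR bundle: list with data frames `patients`
#'   (`patient_id, birth_year, sex, race, insurance`), `visits`
#'   (`patient_id, date, department`), `diagnoses`
#'   (`patient_id, date, code`), `medications`
#'   (`patient_id, date, drug`).
#' @param extractions Extraction table from [normalize_extractions()].
#' @param criteria A [cohort_criteria()].
#' @return Object of class `cohort_result`: `included_ids`,
#'   `exclusion_counts` (named integer vector per criterion),
#'   `same_day_excluded`, `analysis_ids`, and `index_dates` (data frame
#'   `patient_id, first_complaint_date, first_dx_date`).
#' @export
select_cohort <- function(data, extractions, criteria = cohort_criteria()) {
  pts <- data$patients$patient_id
  if (anyDuplicated(pts)) stop("duplicate patient ids")
  vis_by <- split(data$visits, data$visits$patient_id)
  dxs_by <- split(data$diagnoses, data$diagnoses$patient_id)
  ext_by <- split(extractions, extractions$patient_id)

  excl <- c(dementia_diagnosis = 0L, annual_visits = 0L,
            visit_before_diagnosis = 0L, memory_symptom = 0L)
  n_pts <- length(pts)
  inc_flag <- logical(n_pts)
  sd_flag <- logical(n_pts)
  cdates <- rep(as.Date(NA), n_pts)
  ddates <- rep(as.Date(NA), n_pts)
  pi <- 0L

  for (pid in pts) {
    pi <- pi + 1L
    vis <- vis_by[[pid]]
    dxr <- dxs_by[[pid]]
    ext <- ext_by[[pid]]
    if (is.null(ext)) ext <- extractions[0, , drop = FALSE]
    if (is.null(dxr)) dxr <- data$diagnoses[0, , drop = FALSE]
    if (is.null(vis) || nrow(vis) == 0) {
      excl["dementia_diagnosis"] <- excl["dementia_diagnosis"] + 1L
      next
    }
    # criterion 1: dementia diagnosis (codes on >= min distinct dates + note documentation)
    code_dates <- dementia_code_dates(dxr, criteria)
    has_dx_note <- any(ext$label == "DX")
    if (length(code_dates) < criteria$min_code_dates ||
        (criteria$require_dx_note && !has_dx_note)) {
      excl["dementia_diagnosis"] <- excl["dementia_diagnosis"] + 1L
      next
    }
    dx_date <- first_diagnosis_date(dxr, ext, criteria)
    vdates <- as.Date(vis$date)
    # criterion 2: at least one visit per calendar year of observation
    if (criteria$require_annual_visits) {
      yrs <- seq(min(as.integer(format(vdates, "%Y"))),
                 as.integer(format(dx_date, "%Y")))
      if (!all(yrs %in% as.integer(format(vdates, "%Y")))) {
        excl["annual_visits"] <- excl["annual_visits"] + 1L
        next
      }
    }
    # criterion 3: at least one visit before the diagnosis date
    if (criteria$require_visit_before_dx && !any(vdates < dx_date)) {
      excl["visit_before_diagnosis"] <- excl["visit_before_diagnosis"] + 1L
      next
    }
    # criterion 4: documented, normalizable memory-loss symptom
    has_sx <- any(ext$label == "SX" & ext$canonical %in% memory_loss_concepts())
    if (criteria$require_memory_symptom && !has_sx) {
      excl["memory_symptom"] <- excl["memory_symptom"] + 1L
      next
    }
    c_date <- first_complaint_date(ext)
    inc_flag[pi] <- TRUE
    cdates[pi] <- c_date
    ddates[pi] <- dx_date
    if (c_date == dx_date) sd_flag[pi] <- TRUE
  }
  index_dates <- data.frame(patient_id = pts[inc_flag],
                            first_complaint_date = cdates[inc_flag],
                            first_dx_date = ddates[inc_flag],
                            stringsAsFactors = FALSE)
  structure(list(included_ids = pts[inc_flag],
                 exclusion_counts = excl,
                 same_day_excluded = pts[inc_flag & sd_flag],
                 analysis_ids = pts[inc_flag & !sd_flag],
                 index_dates = index_dates),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", length(x$included_ids), " included (",
      length(x$same_day_excluded), " same-day excluded, ",
      length(x$analysis_ids), " analysis); exclusions: ",
      paste(names(x$exclusion_counts), x$exclusion_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attrition summary of a cohort selection
#'
#' @param cohort A `cohort_result`.
#' @param n_input Number of candidate patients entering selection.
#' @return List mirroring a selection-workflow diagram: per-criterion
#'   exclusion counts, included, same-day excluded and analysis counts.
#' @export
attrition_summary <- function(cohort, n_input) {
  list(n_input = n_input,
       excluded = as.list(cohort$exclusion_counts),
       n_included = length(cohort$included_ids),
       n_same_day_excluded = length(cohort$same_day_excluded),
       n_analysis = length(cohort$analysis_ids))
}
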