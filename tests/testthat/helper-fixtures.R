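# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small rendered synthetic dataset reused across test files.
synth_small <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_ehr(generator_config(n_patients = 120, seed = 11))
  .fixture_env$ds
}

notes_small <- function() synth_small()$notes

# The two-entity worked example used throughout the standoff tests.
fixture_note <- function() {
  text <- "Pt c/o memory loss x 2 years."
  ann <- paste("T1\tSX 7 18\tmemory loss",
               "T2\tDURATION 21 28\t2 years",
               "R1\tHAS_DURATION_INFO Arg1:T1 Arg2:T2", sep = "\n")
  parse_standoff(text, ann)
}

# Brute-force CRF path enumeration (independent oracle for Viterbi / logZ).
brute_force_paths <- function(E, A) {
  T <- nrow(E); L <- ncol(E)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(L)), T)))
  scores <- apply(paths, 1, function(p) {
    s <- A[L + 1, p[1]] + E[1, p[1]]
    if (T > 1) for (t in 2:T) s <- s + A[p[t - 1], p[t]] + E[t, p[t]]
    s + A[p[T], L + 2]
  })
  list(paths = paths, scores = scores,
       max = max(scores),
       argmax = paths[which.max(scores), ],
       logZ = {
         m <- max(scores)
         m + log(sum(exp(scores - m)))
       })
}

# One extraction-table row, as produced by normalize_extractions().
ext_row <- function(pid, date, label, canonical, dept = "geriatrics",
                    doc = paste0(pid, "_", date)) {
  data.frame(doc_id = doc, patient_id = pid, note_date = date,
             department = dept, entity_id = "T1", label = label,
             surface = canonical, canonical = canonical,
             stringsAsFactors = FALSE)
}

# Hand-built cohort fixture: one clean patient (A), one failure per selection
# criterion (B: two code dates; C: missing-year visit gap; D: no visit before
# diagnosis; E: no memory symptom) and one same-day patient (F).
hand_fixture <- function() {
  pats <- data.frame(
    patient_id = c("A", "B", "C", "D", "E", "F"),
    birth_year = 1935L, sex = "female", race = "white",
    insurance = "medicare", stringsAsFactors = FALSE)
  v <- function(pid, dates, dept = "geriatrics")
    data.frame(patient_id = pid, date = dates, department = dept,
               stringsAsFactors = FALSE)
  visits <- rbind(
    v("A", c("2015-01-01", "2015-12-09")),
    v("B", c("2015-01-01", "2015-12-09")),
    v("C", c("2013-06-01", "2015-12-09")),          # no 2014 visit
    v("D", "2015-12-09"),                            # nothing before dx
    v("E", c("2015-01-01", "2015-12-09")),
    v("F", c("2015-06-01", "2015-12-09")))
  d <- function(pid, dates, code = "G30.9")
    data.frame(patient_id = pid, date = dates, code = code,
               stringsAsFactors = FALSE)
  diagnoses <- rbind(
    d("A", c("2015-12-09", "2016-01-09", "2016-02-09")),
    d("B", c("2015-12-09", "2016-01-09")),           # only 2 distinct dates
    d("C", c("2015-12-09", "2016-01-09", "2016-02-09")),
    d("D", c("2015-12-09", "2016-01-09", "2016-02-09")),
    d("E", c("2015-12-09", "2016-01-09", "2016-02-09")),
    d("F", c("2015-12-09", "2016-01-09", "2016-02-09")))
  meds <- data.frame(patient_id = character(), date = character(),
                     drug = character(), stringsAsFactors = FALSE)
  ext <- rbind(
    ext_row("A", "2015-01-01", "SX", "memory_loss"),
    ext_row("A", "2015-12-09", "DX", "dementia"),
    ext_row("B", "2015-01-01", "SX", "memory_loss"),
    ext_row("B", "2015-12-09", "DX", "dementia"),
    ext_row("C", "2013-06-01", "SX", "memory_loss"),
    ext_row("C", "2015-12-09", "DX", "dementia"),
    ext_row("D", "2015-12-09", "SX", "memory_loss"),
    ext_row("D", "2015-12-09", "DX", "dementia"),
    ext_row("E", "2015-12-09", "DX", "dementia"),    # never a symptom
    ext_row("F", "2015-12-09", "SX", "memory_loss"), # same-day as diagnosis
    ext_row("F", "2015-12-09", "DX", "dementia"))
  list(data = list(patients = pats, visits = visits, diagnoses = diagnoses,
                   medications = meds),
       extractions = ext)
}

# Flatten entities of a note list for scoring.
flatten_entities <- function(notes) {
  out <- do.call(rbind, lapply(notes, function(n) {
    e <- n$entities
    if (nrow(e) == 0) return(NULL)
    cbind(doc_id = n$doc_id, e[, c("label", "start", "end")])
  }))
  if (is.null(out))
    out <- data.frame(doc_id = character(), label = character(),
                      start = integer(), end = integer())
  out
}
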