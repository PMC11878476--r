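# Concept normalization: heterogeneous surface forms -> canonical values.
# Clinical notes mix synonyms ("forgetfulness", "poor memory"), abbreviations
# ("dtr" for daughter) and brand/generic drug names ("Aricept"/"donepezil");
# lexicons ship as editable CSV resources so sites can extend them.

UNMAPPED <- "UNMAPPED"

fold_surface <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("_", " ", x, fixed = TRUE)  # canonical values re-enter unchanged
  gsub("\\s+", " ", x)
}

#' Load the shipped concept lexicons
#'
#' Reads the CSV lexicons (columns `surface, canonical, category`) bundled
#' with the package, or from a directory of the same layout.
#'
#' @param dir Directory containing `symptom_lexicon.csv`,
#'   `caregiver_lexicon.csv`, `drug_lexicon.csv` and
#'   `cognitive_test_lexicon.csv`; defaults to the package resources.
#' @return Object of class `concept_lexicon` with maps `symptom`,
#'   `caregiver`, `drug`, `cognitive_test` (named character vectors,
#'   names = folded surfaces).
#' @export
load_lexicons <- function(dir = system.file("extdata", package = "memotrace")) {
  read_map <- function(file) {
    df <- read.csv(file.path(dir, file), stringsAsFactors = FALSE)
    setNames(df$canonical, fold_surface(df$surface))
  }
  structure(list(symptom = read_map("symptom_lexicon.csv"),
                 caregiver = read_map("caregiver_lexicon.csv"),
                 drug = read_map("drug_lexicon.csv"),
                 cognitive_test = read_map("cognitive_test_lexicon.csv")),
            class = "concept_lexicon")
}

lookup <- function(map, surface) {
  out <- unname(map[fold_surface(surface)])
  out[is.na(out)] <- UNMAPPED
  out
}

#' Normalize a memory-loss symptom surface form
#'
#' Case- and whitespace-insensitive lookup into the symptom lexicon; the
#' canonical concepts are memory_loss, forgetfulness,
#' short_term_memory_deficit, confusion and cognitive_impairment. Unmapped
#' surfaces return `"UNMAPPED"` (never an error) so they can be logged for
#' lexicon growth.
#'
#' @param surface Character vector of surface forms.
#' @param lexicons A `concept_lexicon`.
#' @return Character vector of canonical concepts or `"UNMAPPED"`.
#' @export
normalize_symptom <- function(surface, lexicons = load_lexicons()) {
  lookup(lexicons$symptom, surface)
}

#' Normalize a caregiver-relation surface form
#'
#' Maps abbreviations and variants (e.g. "dtr") to one of the 13 canonical
#' family relations (husband, wife, daughter, son, son_in_law,
#' daughter_in_law, grandson, granddaughter, nephew, niece, cousin, brother,
#' sister). Non-family supporters are out of scope and return `"UNMAPPED"`.
#'
#' @inheritParams normalize_symptom
#' @return Character vector of canonical relations or `"UNMAPPED"`.
#' @export
normalize_caregiver <- function(surface, lexicons = load_lexicons()) {
  lookup(lexicons$caregiver, surface)
}

#' Normalize a medication surface form to its generic name
#'
#' Brand and generic variants map to one of donepezil, memantine,
#' rivastigmine, galantamine (the cognition-enhancing medications).
#'
#' @inheritParams normalize_symptom
#' @return Character vector of generic names or `"UNMAPPED"`.
#' @export
normalize_medication <- function(surface, lexicons = load_lexicons()) {
  lookup(lexicons$drug, surface)
}

caregiver_group_map <- c(
  husband = "husband", wife = "wife", daughter = "daughter",
  son = "other_adult_children", son_in_law = "other_adult_children",
  daughter_in_law = "other_adult_children", grandson = "other_adult_children",
  granddaughter = "other_adult_children",
  nephew = "other_family_support", niece = "other_family_support",
  cousin = "other_family_support", brother = "other_family_support",
  sister = "other_family_support")

#' Group a canonical caregiver relation for association analysis
#'
#' husband and wife and daughter keep their own groups; son, son-in-law,
#' daughter-in-law, grandson and granddaughter form "other_adult_children";
#' nephew, niece, cousin, brother and sister form "other_family_support".
#' The five groups partition the 13 canonical relations. Raw relations are
#' kept for descriptive tables; the grouping applies only to regression
#' factors.
#'
#' @param relation Character vector of canonical relations.
#' @return Character vector of caregiver groups.
#' @export
group_caregiver <- function(relation) {
  out <- unname(caregiver_group_map[relation])
  if (anyNA(out))
    stop("cannot group non-canonical caregiver relation(s): ",
         paste(unique(relation[is.na(out)]), collapse = ", "))
  out
}

#' Normalize extracted entities into an extraction table
#'
#' Flattens entities from a list of annotated notes and adds the canonical
#' concept per entity according to its label: SX via the symptom lexicon,
#' CAREGIVER_RELATION via the caregiver lexicon, RX via the drug lexicon,
#' COG_TEST_RESULT via the test-name lexicon; other labels keep their folded
#' surface.
#'
#' @param notes List of `annotated_note`.
#' @param lexicons A `concept_lexicon`.
#' @return Data frame `doc_id, patient_id, note_date, department, entity_id,
#'   label, surface, canonical`.
#' @export
normalize_extractions <- function(notes, lexicons = load_lexicons()) {
  rows <- lapply(notes, function(n) {
    e <- n$entities
    if (nrow(e) == 0) return(NULL)
    canonical <- fold_surface(e$surface)
    canonical[e$label == "SX"] <- normalize_symptom(e$surface[e$label == "SX"], lexicons)
    canonical[e$label == "CAREGIVER_RELATION"] <-
      normalize_caregiver(e$surface[e$label == "CAREGIVER_RELATION"], lexicons)
    canonical[e$label == "RX"] <- normalize_medication(e$surface[e$label == "RX"], lexicons)
    canonical[e$label == "COG_TEST_RESULT"] <-
      lookup(lexicons$cognitive_test, e$surface[e$label == "COG_TEST_RESULT"])
    data.frame(doc_id = n$doc_id, patient_id = as.character(n$patient_id),
               note_date = as.character(n$note_date),
               department = as.character(n$department),
               entity_id = e$id, label = e$label, surface = e$surface,
               canonical = canonical, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), patient_id = character(),
                      note_date = character(), department = character(),
                      entity_id = character(), label = character(),
                      surface = character(), canonical = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Canonical memory-loss symptom concepts
#' @return Character vector.
#' @export
memory_loss_concepts <- function() {
  c("memory_loss", "forgetfulness", "short_term_memory_deficit",
    "confusion", "cognitive_impairment")
}
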