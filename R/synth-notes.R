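# Template-based clinical note rendering with exact gold offsets.
# A note is assembled from "pieces": plain text segments and labelled entity
# segments. Offsets accumulate as pieces are concatenated, so every gold
# annotation slices the note text exactly by construction. Surface forms are
# drawn from the shipped normalizer lexicons (including abbreviations and
# brand names at configured rates), and satellites are placed next to their
# triggers inside one sentence so that nearest-in-sentence rule linking
# recovers the gold relations.

seg <- function(text) list(text = text, label = NA_character_)
ent <- function(text, label) list(text = text, label = label)

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

# Assemble pieces into (text, entities); pieces is a flat list.
assemble_note <- function(pieces) {
  texts <- vapply(pieces, `[[`, "", "text")
  labels <- vapply(pieces, `[[`, "", "label")
  ends <- cumsum(nchar(texts))
  starts <- ends - nchar(texts)
  keep <- !is.na(labels)
  ents <- if (any(keep)) {
    data.frame(id = paste0("T", seq_len(sum(keep))), label = labels[keep],
               start = as.integer(starts[keep]), end = as.integer(ends[keep]),
               surface = texts[keep], stringsAsFactors = FALSE)
  } else empty_entities()
  list(text = paste(texts, collapse = ""), entities = ents)
}

# Surface pools (lowercase lexicon keys; capitalisation handled at render
# time and undone by the case-folding normalizer).
synth_pools <- function() {
  lex <- load_lexicons()
  list(
    sx = names(lex$symptom),
    caregiver = split(names(lex$caregiver), unname(lex$caregiver)),
    drug_brand = names(lex$drug)[names(lex$drug) %in%
                                   c("aricept", "namenda", "exelon", "razadyne")],
    drug_generic = c("donepezil", "memantine", "rivastigmine", "galantamine"),
    test = c("MMSE", "MoCA", "SLUMS", "Mini-Cog"),
    dx = c("dementia", "Alzheimer disease", "Alzheimer's dementia",
           "vascular dementia", "major neurocognitive disorder",
           "dementia with Lewy bodies"),
    duration = c("2 years", "18 months", "6 months", "a year",
                 "several months", "3 weeks"),
    temporal = c("today", "this week", "at today's visit"),
    status = c("getting worse", "worsening", "progressively worse",
               "worse over the past year"),
    other_sx = c("word-finding difficulty", "getting lost while driving",
                 "agitation", "apathy", "sleep disturbance"),
    distractor = c("BP 128/76, HR 72.", "Knee pain stable on current regimen.",
                   "Discussed diet and exercise.",
                   "Medication list reviewed and reconciled.",
                   "Labs reviewed, no acute findings.",
                   "Follow up in 3 months.")
  )
}

pick <- function(pool) pool[sample.int(length(pool), 1)]

# A complaint sentence: optional caregiver, an SX mention, optional satellites.
complaint_sentence <- function(pools, sx_surface, caregiver_surface = NULL,
                               with_duration = FALSE, with_status = FALSE) {
  pieces <- list()
  style <- sample.int(3, 1)
  if (!is.null(caregiver_surface)) {
    lead <- pick(c("%s reports ", "Accompanied by %s, who reports ",
                   "Per %s, patient has "))
    cg <- if (startsWith(lead, "%s")) cap_first(caregiver_surface) else caregiver_surface
    parts <- strsplit(lead, "%s", fixed = TRUE)[[1]]
    if (startsWith(lead, "%s")) {
      pieces <- c(pieces, list(ent(cg, "CAREGIVER_RELATION"), seg(parts[2])))
    } else {
      pieces <- c(pieces, list(seg(parts[1]), ent(cg, "CAREGIVER_RELATION"),
                               seg(parts[2])))
    }
    pieces <- c(pieces, list(ent(sx_surface, "SX")))
  } else if (style == 1) {
    pieces <- list(seg("Patient reports "), ent(sx_surface, "SX"))
  } else if (style == 2) {
    pieces <- list(seg("Pt c/o "), ent(sx_surface, "SX"))
  } else {
    pieces <- list(ent(cap_first(sx_surface), "SX"), seg(" noted on review"))
  }
  if (with_duration) {
    joiner <- pick(c(" for ", " x ", " over the past "))
    dur <- if (joiner == " over the past ") pick(c("year", "6 months", "few weeks"))
           else pick(pools$duration)
    pieces <- c(pieces, list(seg(joiner), ent(dur, "DURATION")))
  }
  if (with_status) {
    pieces <- c(pieces, list(seg(", "), ent(pick(pools$status), "STATUS_CHANGE_WORSE")))
  }
  c(pieces, list(seg(". ")))
}

other_symptom_sentence <- function(pools) {
  list(seg("Also with "), ent(pick(pools$other_sx), "OTHER_SYMPTOM"), seg(". "))
}

test_sentence <- function(pools) {
  list(ent(pick(pools$test), "COG_TEST_RESULT"),
       seg(sprintf(" score %d/30. ", sample(15:26, 1))))
}

rx_sentence <- function(pools, drug_surface, sx_surface = NULL) {
  if (is.null(sx_surface)) {
    list(seg("Started on "), ent(drug_surface, "RX"), seg(". "))
  } else {
    list(seg("Started "), ent(drug_surface, "RX"), seg(" for "),
         ent(sx_surface, "SX"), seg(". "))
  }
}

dx_sentence <- function(pools, dx_surface) {
  style <- sample.int(3, 1)
  if (style == 1) {
    list(seg("Assessment: "), ent(dx_surface, "DX"), seg(". "))
  } else if (style == 2) {
    list(seg("Diagnosis of "), ent(dx_surface, "DX"), seg(" made "),
         ent(pick(pools$temporal), "TEMPORAL"), seg(". "))
  } else {
    list(seg("Impression is consistent with "), ent(dx_surface, "DX"), seg(". "))
  }
}

distractor_sentence <- function(pools) list(seg(paste0(pick(pools$distractor), " ")))

# Render one complaint note. `noise` carries the configured rates.
render_complaint_note <- function(pools, noise, sx_surface, caregiver_surface,
                                  drug_surface = NULL) {
  pieces <- list()
  if (runif(1) < noise$distractor_rate) pieces <- c(pieces, distractor_sentence(pools))
  pieces <- c(pieces, complaint_sentence(
    pools, sx_surface, caregiver_surface,
    with_duration = runif(1) < noise$satellite_rate,
    with_status = runif(1) < noise$satellite_rate / 2))
  if (runif(1) < noise$satellite_rate / 2)
    pieces <- c(pieces, other_symptom_sentence(pools))
  if (runif(1) < noise$test_rate) pieces <- c(pieces, test_sentence(pools))
  if (!is.null(drug_surface)) pieces <- c(pieces, rx_sentence(pools, drug_surface))
  if (runif(1) < noise$distractor_rate) pieces <- c(pieces, distractor_sentence(pools))
  assemble_note(pieces)
}

render_dx_note <- function(pools, noise, dx_surface) {
  pieces <- list()
  if (runif(1) < noise$distractor_rate) pieces <- c(pieces, distractor_sentence(pools))
  pieces <- c(pieces, dx_sentence(pools, dx_surface))
  if (runif(1) < noise$distractor_rate) pieces <- c(pieces, distractor_sentence(pools))
  assemble_note(pieces)
}

render_distractor_note <- function(pools) {
  assemble_note(c(distractor_sentence(pools), distractor_sentence(pools)))
}

# Draw a caregiver surface for a canonical relation (abbreviations at the
# configured rate when one exists).
draw_caregiver_surface <- function(pools, relation, abbreviation_rate) {
  surfaces <- pools$caregiver[[relation]]
  abbrevs <- surfaces[nchar(surfaces) <= 4 | grepl("-", surfaces)]
  abbrevs <- setdiff(abbrevs, relation)
  if (length(abbrevs) && runif(1) < abbreviation_rate) return(pick(abbrevs))
  full <- gsub("_", "-", relation)
  if (full %in% surfaces) full else pick(surfaces)
}

draw_drug_surface <- function(pools, generic, brand_rate) {
  lex <- c(aricept = "donepezil", namenda = "memantine",
           exelon = "rivastigmine", razadyne = "galantamine")
  if (runif(1) < brand_rate) {
    cap_first(names(lex)[lex == generic][1])
  } else generic
}
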