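# Annotated-note data model and standoff (BRAT-dialect) persistence.
# Offsets are 0-based half-open [start, end) over Unicode code points.

#' Construct an annotated note
#'
#' The unit of NLP work: note text plus typed entity spans, typed relations
#' and per-note metadata. Entities are a data frame with columns
#' `id, label, start, end, surface`; relations a data frame with columns
#' `id, label, head, tail` (head/tail are entity ids).
#'
#' @param doc_id Document identifier.
#' @param text Note text (single string).
#' @param entities Entity data frame (zero rows allowed).
#' @param relations Relation data frame (zero rows allowed).
#' @param patient_id Patient identifier (optional).
#' @param note_date Note date, ISO-8601 string or `Date` (optional).
#' @param department Location code, e.g. "geriatrics" (optional).
#' @param schema Ontology schema used for validation.
#' @return Object of class `annotated_note`.
#' @export
annotated_note <- function(doc_id, text, entities = empty_entities(),
                           relations = empty_relations(), patient_id = NA,
                           note_date = NA, department = NA,
                           schema = ontology_schema()) {
  note <- structure(
    list(doc_id = doc_id, patient_id = patient_id,
         note_date = if (is.na(note_date[1])) as.Date(NA) else as.Date(note_date),
         department = department, text = text,
         entities = entities, relations = relations),
    class = "annotated_note")
  validate_note(note, schema)
  note
}

#' @export
print.annotated_note <- function(x, ...) {
  cat("<annotated_note> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$entities), " entities, ", nrow(x$relations), " relations\n",
      sep = "")
  invisible(x)
}

#' @rdname annotated_note
#' @export
empty_entities <- function() {
  data.frame(id = character(), label = character(), start = integer(),
             end = integer(), surface = character(), stringsAsFactors = FALSE)
}

#' @rdname annotated_note
#' @export
empty_relations <- function() {
  data.frame(id = character(), label = character(), head = character(),
             tail = character(), stringsAsFactors = FALSE)
}

#' Validate annotated-note invariants
#'
#' Checks offset bounds, surface/offset agreement, id uniqueness and relation
#' schema compatibility; stops with an informative error on the first
#' violation.
#'
#' @param note An `annotated_note`.
#' @param schema Ontology schema.
#' @return `note`, invisibly.
#' @export
validate_note <- function(note, schema = ontology_schema()) {
  ents <- note$entities
  n <- nchar(note$text)
  if (nrow(ents) > 0) {
    if (anyDuplicated(ents$id))
      stop("duplicate entity ids in ", note$doc_id)
    bad <- !(ents$label %in% schema$entity_labels)
    if (any(bad))
      stop("unknown entity label(s): ", paste(unique(ents$label[bad]), collapse = ", "))
    if (any(ents$start < 0) || any(ents$end <= ents$start) || any(ents$end > n))
      stop("entity span out of bounds in ", note$doc_id)
    slice <- substring(note$text, ents$start + 1L, ents$end)
    if (any(slice != ents$surface)) {
      i <- which(slice != ents$surface)[1]
      stop("surface/offset mismatch for entity ", ents$id[i], " in ", note$doc_id,
           ": expected '", slice[i], "', got '", ents$surface[i], "'")
    }
  }
  rels <- note$relations
  if (nrow(rels) > 0) {
    if (anyDuplicated(rels$id))
      stop("duplicate relation ids in ", note$doc_id)
    bad <- !(rels$label %in% schema$relation_labels)
    if (any(bad))
      stop("unknown relation label(s): ", paste(unique(rels$label[bad]), collapse = ", "))
    if (any(rels$head == rels$tail))
      stop("relation with identical head and tail in ", note$doc_id)
    miss <- !(rels$head %in% ents$id) | !(rels$tail %in% ents$id)
    if (any(miss))
      stop("relation argument does not resolve to an entity in ", note$doc_id)
    lab <- function(id) ents$label[match(id, ents$id)]
    for (i in seq_len(nrow(rels))) {
      if (!is_compatible(schema, rels$label[i], lab(rels$head[i]), lab(rels$tail[i])))
        stop("relation ", rels$id[i], " (", rels$label[i], ": ",
             lab(rels$head[i]), " -> ", lab(rels$tail[i]),
             ") violates the schema compatibility map in ", note$doc_id)
    }
  }
  invisible(note)
}

#' Parse standoff annotation into an annotated note
#'
#' Reads the BRAT dialect used for persistence: entity lines
#' `T<k>\tLABEL <start> <end>\t<surface>` and relation lines
#' `R<k>\tLABEL Arg1:T<i> Arg2:T<j>`. Offsets are 0-based half-open.
#'
#' @param text Note text.
#' @param ann Annotation file content as a single string (possibly empty).
#' @param doc_id Document id to record.
#' @param schema Ontology schema.
#' @param ... Passed to [annotated_note()] (metadata fields).
#' @return An `annotated_note` whose invariants all hold.
#' @export
parse_standoff <- function(text, ann, doc_id = "doc", schema = ontology_schema(), ...) {
  lines <- if (nzchar(ann)) strsplit(ann, "\n", fixed = TRUE)[[1]] else character()
  lines <- lines[nzchar(lines)]
  ents <- list(); rels <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (startsWith(ln, "T")) {
      if (length(fields) != 3)
        stop("malformed entity line ", k, ": expected 3 tab-separated fields")
      hdr <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(hdr) != 3 || is.na(suppressWarnings(as.integer(hdr[2]))) ||
          is.na(suppressWarnings(as.integer(hdr[3]))))
        stop("malformed entity line ", k, ": bad label/offset block")
      ents[[length(ents) + 1]] <- data.frame(
        id = fields[1], label = hdr[1],
        start = as.integer(hdr[2]), end = as.integer(hdr[3]),
        surface = fields[3], stringsAsFactors = FALSE)
    } else if (startsWith(ln, "R")) {
      if (length(fields) != 2)
        stop("malformed relation line ", k, ": expected 2 tab-separated fields")
      hdr <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      if (length(hdr) != 3 || !startsWith(hdr[2], "Arg1:") || !startsWith(hdr[3], "Arg2:"))
        stop("malformed relation line ", k, ": expected 'LABEL Arg1:Ti Arg2:Tj'")
      rels[[length(rels) + 1]] <- data.frame(
        id = fields[1], label = hdr[1],
        head = sub("^Arg1:", "", hdr[2]), tail = sub("^Arg2:", "", hdr[3]),
        stringsAsFactors = FALSE)
    } else {
      stop("malformed line ", k, ": unknown annotation type '",
           substr(ln, 1, 1), "'")
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  annotated_note(doc_id, text, entities, relations, schema = schema, ...)
}

#' Serialize an annotated note to standoff form
#'
#' Inverse of [parse_standoff()]: `parse_standoff(text, ann)` on the result
#' reproduces the note exactly.
#'
#' @param note An `annotated_note`.
#' @return List with elements `text` and `ann` (single strings).
#' @export
write_standoff <- function(note) {
  validate_note(note)
  e <- note$entities
  r <- note$relations
  lines <- character()
  if (nrow(e) > 0)
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", e$id, e$label, e$start, e$end, e$surface))
  if (nrow(r) > 0)
    lines <- c(lines, sprintf("%s\t%s Arg1:%s Arg2:%s", r$id, r$label, r$head, r$tail))
  list(text = note$text, ann = paste(lines, collapse = "\n"))
}

#' Read a directory of standoff documents
#'
#' Expects `<doc_id>.txt` / `<doc_id>.ann` pairs plus an optional
#' `notes_meta.csv` (columns doc_id, patient_id, note_date, department).
#'
#' @param dir Directory path (`.txt` files and `notes_meta.csv`).
#' @param ann_dir Directory holding the `.ann` files (defaults to `dir`; a
#'   dataset may keep gold annotations in a sibling `gold/` directory).
#' @param schema Ontology schema.
#' @return List of `annotated_note`.
#' @export
read_standoff_dir <- function(dir, ann_dir = dir, schema = ontology_schema()) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  meta_path <- file.path(dir, "notes_meta.csv")
  if (!file.exists(meta_path))
    meta_path <- file.path(dirname(dir), "notes_meta.csv")
  meta <- if (file.exists(meta_path)) read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  lapply(txts, function(tp) {
    doc_id <- sub("\\.txt$", "", basename(tp))
    ap <- file.path(ann_dir, paste0(doc_id, ".ann"))
    text <- readChar(tp, file.size(tp), useBytes = FALSE)
    ann <- if (file.exists(ap) && file.size(ap) > 0)
      readChar(ap, file.size(ap), useBytes = FALSE) else ""
    args <- list(text = text, ann = ann, doc_id = doc_id, schema = schema)
    if (!is.null(meta) && doc_id %in% meta$doc_id) {
      m <- meta[meta$doc_id == doc_id, ][1, ]
      args <- c(args, list(patient_id = m$patient_id, note_date = m$note_date,
                           department = m$department))
    }
    do.call(parse_standoff, args)
  })
}

#' Write a list of annotated notes to a standoff directory
#'
#' @param notes List of `annotated_note`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_standoff_dir <- function(notes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(
    doc_id = vapply(notes, function(n) as.character(n$doc_id), character(1)),
    patient_id = vapply(notes, function(n) as.character(n$patient_id), character(1)),
    note_date = vapply(notes, function(n) as.character(n$note_date), character(1)),
    department = vapply(notes, function(n) as.character(n$department), character(1)),
    stringsAsFactors = FALSE)
  for (n in notes) {
    so <- write_standoff(n)
    writeLines(so$text, file.path(dir, paste0(n$doc_id, ".txt")), sep = "")
    writeLines(so$ann, file.path(dir, paste0(n$doc_id, ".ann")), sep = "")
  }
  write.csv(meta, file.path(dir, "notes_meta.csv"), row.names = FALSE)
  invisible(dir)
}
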