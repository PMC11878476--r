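# Ontology of prodromal dementia symptoms: 9 entity types, 9 relation types,
# and the head/tail compatibility map that constrains relation instances.

#' Entity labels of the prodromal dementia symptom ontology
#'
#' The nine entity types: memory loss symptom (SX), dementia diagnosis (DX),
#' temporal expression (TEMPORAL), symptom duration (DURATION), worsening
#' status change (STATUS_CHANGE_WORSE), other symptoms (OTHER_SYMPTOM),
#' cognitive test result (COG_TEST_RESULT), caregiver relation
#' (CAREGIVER_RELATION) and cognition-enhancing medication (RX).
#'
#' @return Character vector of the nine entity label codes.
#' @export
entity_labels <- function() {
  c("SX", "DX", "TEMPORAL", "DURATION", "STATUS_CHANGE_WORSE",
    "OTHER_SYMPTOM", "COG_TEST_RESULT", "CAREGIVER_RELATION", "RX")
}

#' Relation labels of the prodromal dementia symptom ontology
#'
#' @return Character vector of the nine relation label codes.
#' @export
relation_labels <- function() {
  c("HAS_COMPLAINT_DATE", "HAS_DIAGNOSIS_DATE", "HAS_OTHER_SYMPTOM_INFO",
    "HAS_STATUS_CHANGE_INFO", "HAS_DURATION_INFO", "HAS_TEST_INFO",
    "HAS_CAREGIVER_INFO", "HAS_TREATMENT_INFO", "HAS_EFFECTS")
}

default_compatibility <- function() {
  list(
    HAS_COMPLAINT_DATE     = list(c("SX", "TEMPORAL")),
    HAS_DIAGNOSIS_DATE     = list(c("DX", "TEMPORAL")),
    HAS_OTHER_SYMPTOM_INFO = list(c("SX", "OTHER_SYMPTOM")),
    HAS_STATUS_CHANGE_INFO = list(c("SX", "STATUS_CHANGE_WORSE")),
    HAS_DURATION_INFO      = list(c("SX", "DURATION")),
    HAS_TEST_INFO          = list(c("SX", "COG_TEST_RESULT")),
    HAS_CAREGIVER_INFO     = list(c("SX", "CAREGIVER_RELATION")),
    HAS_TREATMENT_INFO     = list(c("SX", "RX")),
    HAS_EFFECTS            = list(c("RX", "SX"), c("RX", "STATUS_CHANGE_WORSE"))
  )
}

#' Construct the ontology schema
#'
#' Bundles entity labels, relation labels and the relation compatibility map
#' (which head/tail entity label pairs each relation may connect). The
#' default map directs every relation from its trigger (SX, DX or RX) to the
#' satellite entity it qualifies; it can be overridden from a YAML file via
#' [load_schema()].
#'
#' @param entities Character vector of entity labels.
#' @param relations Character vector of relation labels.
#' @param compatibility Named list: relation label -> list of c(head, tail)
#'   entity-label pairs.
#' @return An object of class `ontology_schema`.
#' @export
ontology_schema <- function(entities = entity_labels(),
                            relations = relation_labels(),
                            compatibility = default_compatibility()) {
  stopifnot(length(entities) >= 1, length(relations) >= 1)
  if (!setequal(names(compatibility), relations))
    stop("compatibility map must have exactly one entry per relation label")
  for (rl in relations) {
    pairs <- compatibility[[rl]]
    if (length(pairs) < 1)
      stop("relation ", rl, " has no compatible head/tail pair")
    for (p in pairs) {
      if (length(p) != 2 || !all(p %in% entities))
        stop("relation ", rl, " has a pair outside the entity label set")
    }
  }
  structure(list(entity_labels = entities, relation_labels = relations,
                 compatibility = compatibility),
            class = "ontology_schema")
}

#' @export
print.ontology_schema <- function(x, ...) {
  cat("<ontology_schema> ", length(x$entity_labels), " entities, ",
      length(x$relation_labels), " relations\n", sep = "")
  invisible(x)
}

#' Check a (relation, head label, tail label) triple against the schema
#'
#' @param schema An `ontology_schema`.
#' @param relation Relation label.
#' @param head_label,tail_label Entity labels of head and tail.
#' @return TRUE if compatible.
#' @export
is_compatible <- function(schema, relation, head_label, tail_label) {
  pairs <- schema$compatibility[[relation]]
  if (is.null(pairs)) return(FALSE)
  any(vapply(pairs, function(p) p[1] == head_label && p[2] == tail_label,
             logical(1)))
}

#' Write an ontology schema to YAML
#'
#' @param schema An `ontology_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_schema <- function(schema, path) {
  obj <- list(
    entities = schema$entity_labels,
    relations = schema$relation_labels,
    compatibility = lapply(schema$compatibility, function(pairs)
      lapply(pairs, function(p) list(head = p[1], tail = p[2])))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an ontology schema from YAML
#'
#' @param path YAML file as written by [save_schema()].
#' @return An `ontology_schema`.
#' @export
load_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  comp <- lapply(obj$compatibility, function(pairs)
    lapply(pairs, function(p) c(p$head, p$tail)))
  ontology_schema(unlist(obj$entities), unlist(obj$relations), comp)
}
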