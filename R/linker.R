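# Rule-based relation linking: each satellite entity (temporal, duration,
# status change, other symptom, test result, caregiver, medication) attaches
# to the nearest compatible trigger entity in the same sentence.

#' Linker configuration
#'
#' @param max_token_distance Maximum distance in tokens between satellite and
#'   head.
#' @param same_sentence Require head and satellite in the same sentence.
#' @return A `linker_config` list.
#' @export
linker_config <- function(max_token_distance = 20, same_sentence = TRUE) {
  stopifnot(max_token_distance > 0)
  structure(list(max_token_distance = max_token_distance,
                 same_sentence = same_sentence),
            class = "linker_config")
}

# relation label implied by a (head label, tail label) pair under the schema
implied_relation <- function(schema, head_label, tail_label) {
  for (rl in schema$relation_labels) {
    if (is_compatible(schema, rl, head_label, tail_label)) return(rl)
  }
  NA_character_
}

#' Link satellite entities to trigger entities
#'
#' For each satellite entity, finds the nearest compatible head entity
#' (distance in tokens, ties broken toward the leftmost head; equidistant
#' SX preferred over DX for temporal satellites) within the same sentence and
#' within `max_token_distance`, and emits the schema-implied relation. Each
#' satellite receives at most one head; unlinkable satellites are skipped.
#'
#' @param note An `annotated_note` with entities (relations ignored).
#' @param schema Ontology schema.
#' @param config A [linker_config()].
#' @return Relation data frame (`id, label, head, tail`).
#' @export
link_relations <- function(note, schema = ontology_schema(),
                           config = linker_config()) {
  ents <- note$entities
  if (nrow(ents) < 2) return(empty_relations())
  ents <- ents[order(ents$start), , drop = FALSE]
  toks <- tokenize(note$text)
  sents <- split_sentences(note$text)
  tok_index <- function(start) {
    i <- findInterval(start, toks$start)
    max(i, 1L)
  }
  sent_index <- function(start) {
    i <- findInterval(start, sents$start)
    max(i, 1L)
  }
  ents$tok <- vapply(ents$start, tok_index, integer(1))
  ents$sent <- vapply(ents$start, sent_index, integer(1))

  trigger_labels <- c("SX", "DX", "RX")
  satellite_labels <- c("TEMPORAL", "DURATION", "STATUS_CHANGE_WORSE",
                        "OTHER_SYMPTOM", "COG_TEST_RESULT",
                        "CAREGIVER_RELATION", "RX")
  rels <- list()
  k <- 0
  for (i in seq_len(nrow(ents))) {
    sat <- ents[i, ]
    if (!(sat$label %in% satellite_labels)) next
    # candidate heads compatible with this satellite as tail
    cand <- ents[ents$id != sat$id & ents$label %in% trigger_labels, , drop = FALSE]
    if (sat$label == "RX")  # RX is a satellite only of SX (treatment link)
      cand <- cand[cand$label == "SX", , drop = FALSE]
    ok <- vapply(seq_len(nrow(cand)), function(j)
      !is.na(implied_relation(schema, cand$label[j], sat$label)), logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (config$same_sentence)
      cand <- cand[cand$sent == sat$sent, , drop = FALSE]
    if (nrow(cand) == 0) next
    dist <- abs(cand$tok - sat$tok)
    cand <- cand[dist <= config$max_token_distance, , drop = FALSE]
    dist <- dist[dist <= config$max_token_distance]
    if (nrow(cand) == 0) next
    best <- min(dist)
    tied <- which(dist == best)
    if (length(tied) > 1) {
      # prefer SX over DX at equal distance, then leftmost
      pref <- tied[cand$label[tied] == "SX"]
      tied <- if (length(pref)) pref else tied
      tied <- tied[order(cand$tok[tied])]
    }
    head <- cand[tied[1], ]
    k <- k + 1
    rels[[k]] <- data.frame(
      id = paste0("R", k),
      label = implied_relation(schema, head$label, sat$label),
      head = head$id, tail = sat$id, stringsAsFactors = FALSE)
  }
  if (!length(rels)) return(empty_relations())
  do.call(rbind, rels)
}

#' Score predicted relations against gold
#'
#' Wrapper over [match_relations()] and [metrics()] mirroring the entity
#' scoring surface.
#'
#' @param gold_notes,pred_notes Lists of `annotated_note`.
#' @return A `metric_report` over relation labels.
#' @export
evaluate_relations <- function(gold_notes, pred_notes) {
  metrics(match_relations(gold_notes, pred_notes))
}
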