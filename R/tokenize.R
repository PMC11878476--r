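# Offset-faithful rule-based tokenisation, sentence splitting and
# BIO conversion. Offsets are 0-based half-open code-point positions.

#' Tokenize text preserving character offsets
#'
#' Splits on whitespace and detaches punctuation: a token is either a maximal
#' run of alphanumerics (apostrophes and underscores allowed inside) or a
#' single punctuation character.
#'
#' @param text Input string.
#' @return Data frame with columns `token`, `start`, `end` (0-based
#'   half-open), one row per token, in text order.
#' @export
tokenize <- function(text) {
  if (!nzchar(text))
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  m <- gregexpr("[[:alnum:]_']+|[^[:alnum:]_'[:space:]]", text)[[1]]
  if (m[1] == -1)
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  data.frame(token = substring(text, starts + 1L, starts + lens),
             start = starts, end = starts + lens, stringsAsFactors = FALSE)
}

clinical_abbrev <- c("Dr", "Mr", "Mrs", "Ms", "Pt", "pt", "vs", "St", "approx",
                     "hx", "e.g", "i.e")

#' Split text into sentences
#'
#' Rule-based: a sentence ends at `.`, `!` or `?` followed by whitespace and
#' an upper-case letter or digit, unless the preceding word is a known
#' clinical abbreviation.
#'
#' @param text Input string.
#' @return Data frame with columns `start`, `end` (0-based half-open spans).
#' @export
split_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0)
    return(data.frame(start = integer(), end = integer()))
  m <- gregexpr("[.!?](?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  bounds <- integer()
  if (m[1] != -1) {
    for (pos in as.integer(m)) {
      prev <- sub(".*?([[:alnum:].]+)$", "\\1", substr(text, max(1, pos - 12), pos - 1))
      if (prev %in% clinical_abbrev) next
      bounds <- c(bounds, pos)  # 1-based position of the terminator
    }
  }
  starts <- c(0L, bounds)  # terminator pos (1-based) == 0-based offset after it
  ends <- c(bounds, n)
  keep <- starts < ends
  out <- data.frame(start = starts[keep], end = ends[keep])
  # trim leading whitespace from each sentence
  for (i in seq_len(nrow(out))) {
    while (out$start[i] < out$end[i] &&
           grepl("^\\s$", substr(text, out$start[i] + 1, out$start[i] + 1)))
      out$start[i] <- out$start[i] + 1L
  }
  out
}

#' Convert an annotated note to tokens with BIO tags
#'
#' Each token receives `O` or `B-LABEL`/`I-LABEL`. Entities whose boundaries
#' fall inside a token are expanded to token boundaries. Overlapping entities
#' are resolved by keeping the longer span (ties: the earlier one) with a
#' warning, since a linear-chain tagger requires non-overlapping spans.
#'
#' @param note An `annotated_note`.
#' @return List with `tokens` (data frame from [tokenize()]) and `tags`
#'   (character vector, one per token).
#' @export
to_bio <- function(note) {
  toks <- tokenize(note$text)
  tags <- rep("O", nrow(toks))
  ents <- note$entities
  if (nrow(ents) > 0) {
    ents <- ents[order(-(ents$end - ents$start), ents$start), , drop = FALSE]
    taken <- rep(FALSE, nrow(toks))
    dropped <- character()
    ents <- ents[order(ents$start), , drop = FALSE]
    # resolve overlaps: longer span wins
    keep <- rep(TRUE, nrow(ents))
    lens <- ents$end - ents$start
    for (i in seq_len(nrow(ents))) {
      if (!keep[i]) next
      for (j in seq_len(nrow(ents))) {
        if (i == j || !keep[j]) next
        if (ents$start[i] < ents$end[j] && ents$start[j] < ents$end[i]) {
          loser <- if (lens[i] >= lens[j]) j else i
          keep[loser] <- FALSE
          dropped <- c(dropped, ents$id[loser])
        }
      }
    }
    if (length(dropped))
      warning("dropped overlapping entities: ", paste(dropped, collapse = ", "))
    ents <- ents[keep, , drop = FALSE]
    for (i in seq_len(nrow(ents))) {
      hit <- which(toks$end > ents$start[i] & toks$start < ents$end[i])
      hit <- hit[!taken[hit]]
      if (!length(hit)) next
      taken[hit] <- TRUE
      tags[hit[1]] <- paste0("B-", ents$label[i])
      if (length(hit) > 1)
        tags[hit[-1]] <- paste0("I-", ents$label[i])
    }
  }
  list(tokens = toks, tags = tags)
}

#' Project BIO tags back to entity spans
#'
#' Contiguous `B-L (I-L)*` runs become entities with character offsets taken
#' from the underlying tokens. Ill-formed `I-` tags (after `O` or a different
#' label) open a new entity, so any tag sequence yields valid spans.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param tags Character vector of BIO tags.
#' @param text The note text (for surfaces).
#' @return Entity data frame (`id, label, start, end, surface`).
#' @export
bio_to_entities <- function(tokens, tags, text) {
  stopifnot(nrow(tokens) == length(tags))
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    data.frame(id = NA_character_, label = cur$label, start = cur$start,
               end = cur$end, surface = substring(text, cur$start + 1, cur$end),
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      out <- c(out, list(flush(cur))); cur <- NULL
    } else {
      lab <- sub("^[BI]-", "", tg)
      if (startsWith(tg, "B-") || is.null(cur) || cur$label != lab) {
        out <- c(out, list(flush(cur)))
        cur <- list(label = lab, start = tokens$start[i], end = tokens$end[i])
      } else {
        cur$end <- tokens$end[i]
      }
    }
  }
  out <- c(out, list(flush(cur)))
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_entities())
  ents <- do.call(rbind, out)
  ents$id <- paste0("T", seq_len(nrow(ents)))
  ents
}
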