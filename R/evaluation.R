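# Span-level scoring of entity and relation extraction:
# precision = TP/(TP+FP), recall = TP/(TP+FN),
# F1 = 2*P*R/(P+R), all defined as 0 when their denominator is 0.

#' Match predicted entities against gold entities
#'
#' Greedy 1:1 matching taken left-to-right over predictions: a prediction is
#' a true positive iff its label matches and (exact mode) its span equals a
#' yet-unmatched gold span, or (overlap mode) intersects one.
#'
#' @param gold,pred Entity data frames (`label, start, end`, optionally
#'   `doc_id` for multi-document scoring).
#' @param mode `"exact"` or `"overlap"`.
#' @return Object of class `confusion_counts`: per-label and micro tp/fp/fn.
#' @export
match_entities <- function(gold, pred, mode = c("exact", "overlap")) {
  mode <- match.arg(mode)
  if (is.null(gold$doc_id)) gold$doc_id <- "d"
  if (is.null(pred$doc_id)) pred$doc_id <- "d"
  key <- paste(gold$doc_id, gold$label, gold$start, gold$end)
  if (anyDuplicated(key)) stop("invalid gold: duplicate identical spans")
  labels <- sort(unique(c(gold$label, pred$label)))
  counts <- data.frame(label = labels, tp = 0L, fp = 0L, fn = 0L,
                       stringsAsFactors = FALSE)
  gold$matched <- FALSE
  ord <- order(pred$doc_id, pred$start, pred$end)
  pred <- pred[ord, , drop = FALSE]
  for (i in seq_len(nrow(pred))) {
    cand <- which(!gold$matched & gold$doc_id == pred$doc_id[i] &
                    gold$label == pred$label[i] &
                    (if (mode == "exact")
                       gold$start == pred$start[i] & gold$end == pred$end[i]
                     else
                       gold$start < pred$end[i] & pred$start[i] < gold$end))
    row <- match(pred$label[i], counts$label)
    if (length(cand)) {
      gold$matched[cand[1]] <- TRUE
      counts$tp[row] <- counts$tp[row] + 1L
    } else {
      counts$fp[row] <- counts$fp[row] + 1L
    }
  }
  fn <- table(factor(gold$label[!gold$matched], levels = labels))
  counts$fn <- as.integer(fn)
  structure(counts, class = c("confusion_counts", "data.frame"))
}

#' Match predicted relations against gold relations
#'
#' A predicted relation is a true positive iff its label and the labels and
#' spans of both arguments match a gold relation exactly.
#'
#' @param gold_notes,pred_notes Lists of `annotated_note` over the same
#'   documents (matched by `doc_id`).
#' @return A `confusion_counts` over relation labels.
#' @export
match_relations <- function(gold_notes, pred_notes) {
  flat <- function(notes) {
    rows <- lapply(notes, function(n) {
      r <- n$relations
      if (nrow(r) == 0) return(NULL)
      e <- n$entities
      hi <- match(r$head, e$id); ti <- match(r$tail, e$id)
      data.frame(doc_id = n$doc_id, label = r$label,
                 start = paste(e$label[hi], e$start[hi], e$end[hi]),
                 end = paste(e$label[ti], e$start[ti], e$end[ti]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(doc_id = character(), label = character(),
                        start = character(), end = character())
    out
  }
  g <- flat(gold_notes); p <- flat(pred_notes)
  gd <- vapply(gold_notes, function(n) n$doc_id, character(1))
  pd <- vapply(pred_notes, function(n) n$doc_id, character(1))
  if (!setequal(gd, pd)) stop("gold and predicted notes cover different documents")
  g <- g[!duplicated(g), , drop = FALSE]  # identical duplicate relations collapse
  match_entities(g, p, mode = "exact")
}

#' Compute precision, recall and F1 from confusion counts
#'
#' @param counts A `confusion_counts` object.
#' @return Object of class `metric_report`: data frame with one row per
#'   label plus a `micro` row (summed counts).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  df <- as.data.frame(counts)
  micro <- data.frame(label = "micro", tp = sum(df$tp), fp = sum(df$fp),
                      fn = sum(df$fn), stringsAsFactors = FALSE)
  df <- rbind(df, micro)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  df$precision <- safe_div(df$tp, df$tp + df$fp)
  df$recall <- safe_div(df$tp, df$tp + df$fn)
  df$f1 <- safe_div(2 * df$precision * df$recall, df$precision + df$recall)
  structure(df, class = c("metric_report", "data.frame"))
}

#' Micro F1 from a metric report
#' @param report A `metric_report`.
#' @return Numeric scalar.
#' @export
micro_f1 <- function(report) report$f1[report$label == "micro"]
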