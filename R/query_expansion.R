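# Query expansion: bigram phrase detection, skip-gram embeddings, nearest-
# neighbour term expansion and rule-based note retrieval.

#' Default seed lexicon of memory-loss terms
#'
#' The seed terms used to retrieve candidate notes; multi-word terms are
#' written with spaces (they are matched across whitespace and merged into
#' underscore bigrams for embedding training).
#'
#' @return Character vector of lowercase seed terms.
#' @export
default_seed_terms <- function() {
  c("memory loss", "confusion", "cognition impairment", "trouble remembering",
    "not recalling", "forgetting", "blackout")
}

#' Detect and merge collocation bigrams
#'
#' Scores adjacent token pairs with the discounted pointwise score
#' `score(a, b) = (count(ab) - delta) * |V| / (count(a) * count(b))` and
#' merges pairs with `count(ab) >= min_count` and score above `threshold`
#' into single `a_b` tokens.
#'
#' @param corpus List of character vectors (tokenized sentences, lowercase).
#' @param min_count Minimum bigram count to consider.
#' @param threshold Score threshold for merging.
#' @param delta Discount subtracted from the bigram count.
#' @return List with `corpus` (merged token sequences) and `phrases`
#'   (data frame `phrase, score, count`).
#' @export
detect_bigrams <- function(corpus, min_count = 5, threshold = 10, delta = 5) {
  if (!length(corpus)) stop("corpus is empty")
  stopifnot(min_count >= 1)
  toks <- unlist(corpus, use.names = FALSE)
  uni <- table(toks)
  vsize <- length(uni)
  pairs <- unlist(lapply(corpus, function(s) {
    if (length(s) < 2) return(character())
    paste(s[-length(s)], s[-1], sep = "\x01")
  }), use.names = FALSE)
  bi <- table(pairs)
  bi <- bi[bi >= min_count]
  phrases <- data.frame(phrase = character(), score = numeric(),
                        count = integer(), stringsAsFactors = FALSE)
  if (length(bi)) {
    parts <- strsplit(names(bi), "\x01", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1)
    b <- vapply(parts, `[`, "", 2)
    score <- (as.numeric(bi) - delta) * vsize /
      (as.numeric(uni[a]) * as.numeric(uni[b]))
    keep <- is.finite(score) & score > threshold
    phrases <- data.frame(phrase = paste(a[keep], b[keep], sep = "_"),
                          score = score[keep], count = as.integer(bi[keep]),
                          stringsAsFactors = FALSE)
  }
  merged_set <- gsub("_", "\x01", phrases$phrase, fixed = TRUE)
  out <- lapply(corpus, function(s) {
    if (length(s) < 2 || !length(merged_set)) return(s)
    res <- character(0)
    i <- 1
    while (i <= length(s)) {
      if (i < length(s) && paste(s[i], s[i + 1], sep = "\x01") %in% merged_set) {
        res <- c(res, paste(s[i], s[i + 1], sep = "_"))
        i <- i + 2
      } else {
        res <- c(res, s[i])
        i <- i + 1
      }
    }
    res
  })
  list(corpus = out, phrases = phrases)
}

#' Train skip-gram embeddings with negative sampling
#'
#' Single-threaded and deterministic given the seed. Tokens with count below
#' `min_count` are dropped from the vocabulary (and from the training
#' sentences) before training.
#'
#' @param corpus List of character vectors (post bigram merge).
#' @param dim Embedding dimension.
#' @param window Maximum context window (dynamically shrunk per position).
#' @param negative Number of negative samples per positive pair.
#' @param epochs Training epochs.
#' @param min_count Vocabulary count threshold.
#' @param alpha Initial learning rate (linearly decayed).
#' @param seed RNG seed.
#' @return Object of class `embedding_model`: `vocabulary` (character),
#'   `vectors` (|V| x dim matrix, rownames = vocabulary), `config`.
#' @export
train_embeddings <- function(corpus, dim = 50, window = 5, negative = 5,
                             epochs = 5, min_count = 2, alpha = 0.05,
                             seed = 13) {
  if (!length(corpus)) stop("corpus is empty")
  if (dim <= 0) stop("embedding dimension must be positive")
  counts <- table(unlist(corpus, use.names = FALSE))
  counts <- counts[counts >= min_count]
  if (!length(counts)) stop("no token reaches min_count")
  vocab <- names(counts)
  sent_ids <- lapply(corpus, function(s) {
    ix <- match(s, vocab)
    as.integer(ix[!is.na(ix)] - 1L)
  })
  sent_ids <- sent_ids[vapply(sent_ids, length, integer(1)) > 0]
  vecs <- cpp_sgns_train(sent_ids, as.numeric(counts), dim, window, negative,
                         epochs, alpha, seed)
  rownames(vecs) <- vocab
  structure(list(vocabulary = vocab, vectors = vecs,
                 config = list(dim = dim, window = window, negative = negative,
                               epochs = epochs, min_count = min_count,
                               alpha = alpha, seed = seed)),
            class = "embedding_model")
}

#' Cosine similarity between two vocabulary terms
#' @param model An `embedding_model`.
#' @param a,b Terms.
#' @return Numeric in [-1, 1].
#' @export
cosine_similarity <- function(model, a, b) {
  va <- model$vectors[a, ]; vb <- model$vectors[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Expand seed terms by embedding similarity
#'
#' For each seed present in the vocabulary, ranks all other terms by cosine
#' similarity and keeps the top `k` with similarity at least `min_sim`.
#' Candidates are deduplicated (keeping the highest-similarity seed) and
#' sorted by similarity, seeds themselves excluded. Intended as
#' human-in-the-loop support: review the candidates, then add accepted terms
#' to the query lexicon.
#'
#' @param model An `embedding_model`.
#' @param seeds Character vector; multi-word seeds are underscore-joined to
#'   match the bigram-merged vocabulary.
#' @param k Candidates per seed (>= 1).
#' @param min_sim Minimum cosine similarity.
#' @return Data frame `term, similarity, nearest_seed`, sorted by
#'   similarity descending.
#' @export
expand_terms <- function(model, seeds, k = 20, min_sim = 0.5) {
  if (k < 1) stop("k must be >= 1")
  seeds <- gsub(" ", "_", tolower(seeds))
  V <- model$vectors
  norms <- sqrt(rowSums(V^2))
  out <- list()
  for (s in seeds) {
    if (!(s %in% model$vocabulary)) {
      warning("seed term absent from vocabulary, skipped: ", s)
      next
    }
    sims <- as.numeric(V %*% V[s, ]) / (norms * norms[s])
    names(sims) <- model$vocabulary
    sims <- sims[setdiff(names(sims), seeds)]
    sims <- sort(sims, decreasing = TRUE)
    sims <- head(sims[sims >= min_sim], k)
    if (length(sims))
      out[[s]] <- data.frame(term = names(sims), similarity = as.numeric(sims),
                             nearest_seed = s, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(term = character(), similarity = numeric(),
                      nearest_seed = character(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, out)
  cand <- cand[order(-cand$similarity), , drop = FALSE]
  cand <- cand[!duplicated(cand$term), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Match query terms in note text
#'
#' Case-insensitive, word-boundary-anchored matching; multi-word terms match
#' across single whitespace runs. A note is retrieved iff at least one span
#' matches.
#'
#' @param text Note text.
#' @param lexicon Character vector of terms (spaces or underscores between
#'   words).
#' @return Data frame `term, start, end` of matched spans (0-based
#'   half-open), possibly empty.
#' @export
match_query <- function(text, lexicon) {
  if (!length(lexicon)) stop("lexicon is empty")
  out <- list()
  for (term in unique(tolower(lexicon))) {
    words <- strsplit(gsub("_", " ", term), "\\s+")[[1]]
    pat <- paste0("\\b", paste(paste0("\\Q", words, "\\E"), collapse = "\\s+"),
                  "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1) next
    out[[term]] <- data.frame(term = term, start = as.integer(m) - 1L,
                              end = as.integer(m) + attr(m, "match.length") - 1L,
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(term = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Retrieve notes matching a query lexicon
#'
#' @param notes List of `annotated_note` (or any objects with `$text`).
#' @param lexicon Character vector of query terms.
#' @return Logical vector: whether each note was retrieved.
#' @export
retrieve_notes <- function(notes, lexicon) {
  vapply(notes, function(n) nrow(match_query(n$text, lexicon)) > 0, logical(1))
}
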