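# BiLSTM-CRF named-entity tagger over BIO tags for the nine ontology entity
# types. The numerical core (LSTM forward/backward, CRF likelihood and
# Viterbi) lives in src/tagger.cpp; this file owns vocabularies, the BIO tag
# inventory, the Adam training loop with early stopping, the
# annotate-retrain-until-F1 loop, and span projection.

#' Tagger configuration
#'
#' @param dim_word Word embedding dimension.
#' @param dim_char Character embedding dimension (0 disables the per-word
#'   character BiLSTM).
#' @param dim_char_hidden Character BiLSTM hidden units per direction.
#' @param hidden Token BiLSTM hidden units per direction.
#' @param dropout Inverted-dropout rate on the token input vectors.
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stop patience on validation micro-F1 (epochs).
#' @param min_epochs Epochs to run before early stopping may trigger.
#' @param batch_size Sequences per gradient step.
#' @param seed RNG seed controlling initialisation, the train/validation
#'   split, shuffling and dropout.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(dim_word = 64, dim_char = 16, dim_char_hidden = 16,
                          hidden = 100, dropout = 0.5, learning_rate = 3e-3,
                          epochs = 30, patience = 5, min_epochs = 10,
                          batch_size = 8, seed = 1) {
  stopifnot(dim_word > 0, dim_char >= 0, hidden > 0, epochs >= 1,
            batch_size >= 1, dropout >= 0, dropout < 1)
  structure(list(dim_word = dim_word, dim_char = dim_char,
                 dim_char_hidden = dim_char_hidden, hidden = hidden,
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = epochs, patience = patience,
                 min_epochs = min_epochs, batch_size = batch_size,
                 seed = seed),
            class = "tagger_config")
}

# BIO tag inventory: "O" first, then B-/I- per entity label.
bio_tagset <- function(labels = entity_labels()) {
  c("O", as.vector(rbind(paste0("B-", labels), paste0("I-", labels))))
}

# (L+2) x (L+2) 0/1 matrix marking structurally forbidden transitions:
# I-X may only follow B-X or I-X; START may not enter I-X.
bio_transition_mask <- function(tagset) {
  L <- length(tagset)
  M <- matrix(0, L + 2, L + 2)
  from <- c(tagset, "START", "STOP")
  to <- from
  for (j in seq_len(L)) {
    if (!startsWith(tagset[j], "I-")) next
    lab <- sub("^I-", "", tagset[j])
    ok_from <- c(paste0("B-", lab), paste0("I-", lab))
    M[which(!(from %in% ok_from)), j] <- 1
  }
  M[, L + 1] <- 1            # nothing enters START
  M[L + 2, ] <- 1            # nothing leaves STOP
  M[L + 1, L + 2] <- 1       # empty path forbidden
  M
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Lowercased word vocabulary with UNK at position 1; char vocabulary likewise.
build_vocab <- function(bio_seqs) {
  words <- unlist(lapply(bio_seqs, function(s) tolower(s$tokens$token)),
                  use.names = FALSE)
  vocab <- c("<unk>", sort(unique(words)))
  chars <- sort(unique(unlist(strsplit(words, ""), use.names = FALSE)))
  list(words = vocab, chars = c("<unk>", chars))
}

# Encode one tokenized+tagged sequence as 0-based id vectors for the C++ core.
encode_sequence <- function(tokens, tags, vocab, tagset, use_char) {
  low <- tolower(tokens$token)
  wid <- match(low, vocab$words)
  wid[is.na(wid)] <- 1L
  caps <- as.numeric(grepl("^[A-Z]", tokens$token))
  seq <- list(words = wid - 1L, caps = caps)
  if (use_char) {
    seq$chars <- lapply(low, function(w) {
      ci <- match(strsplit(w, "")[[1]], vocab$chars)
      ci[is.na(ci)] <- 1L
      ci - 1L
    })
  }
  if (!is.null(tags)) {
    tid <- match(tags, tagset)
    if (anyNA(tid)) stop("tag outside schema: ", paste(unique(tags[is.na(tid)]), collapse = ", "))
    seq$tags <- tid
  }
  seq
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = st)
}

#' Train/validation sizes for a random corpus split
#'
#' @param n Corpus size.
#' @param split Training fraction (e.g. 815 notes at 0.8 give 652 training
#'   and 163 validation notes).
#' @return Named integer vector `c(train =, validation =)`.
#' @export
train_val_sizes <- function(n, split = 0.8) {
  stopifnot(n >= 2, split > 0, split < 1)
  n_train <- as.integer(round(n * split))
  c(train = n_train, validation = as.integer(n) - n_train)
}

#' Train the BiLSTM-CRF tagger
#'
#' Minimises the CRF negative log-likelihood by minibatch Adam, recording the
#' validation micro-F1 (exact-span entity match) after every epoch and
#' keeping the best-scoring parameters (early stop after `patience` epochs
#' without improvement). Deterministic given `config$seed` and
#' single-threaded execution.
#'
#' @param corpus List of `annotated_note` with gold entities.
#' @param config A [tagger_config()].
#' @param split Training fraction for the random train/validation split
#'   (e.g. 0.8 on 815 notes yields 652 training and 163 validation notes).
#' @param quiet Suppress per-epoch messages.
#' @return Object of class `trained_tagger`.
#' @export
train_tagger <- function(corpus, config = tagger_config(), split = 0.8,
                         quiet = TRUE) {
  stopifnot(length(corpus) >= 10, split > 0, split < 1)
  n_train <- train_val_sizes(length(corpus), split)[["train"]]
  perm <- run_with_seed(config$seed, sample.int(length(corpus)))
  train_notes <- corpus[perm[seq_len(n_train)]]
  val_notes <- corpus[perm[-seq_len(n_train)]]
  fit_tagger(train_notes, val_notes, config, quiet = quiet)
}

# Shared fitting routine over an explicit train/validation split.
fit_tagger <- function(train_notes, val_notes, config, quiet = TRUE) {
  tagset <- bio_tagset()
  mask <- bio_transition_mask(tagset)
  train_bio <- lapply(train_notes, to_bio)
  train_bio <- train_bio[vapply(train_bio, function(s) nrow(s$tokens) > 0, logical(1))]
  vocab <- build_vocab(train_bio)
  use_char <- config$dim_char > 0
  dims <- list(n_words = length(vocab$words), dim_word = config$dim_word,
               n_chars = if (use_char) length(vocab$chars) else 0L,
               dim_char = config$dim_char,
               dim_char_hidden = config$dim_char_hidden,
               hidden = config$hidden, n_tags = length(tagset))
  seqs <- lapply(train_bio, function(s)
    encode_sequence(s$tokens, s$tags, vocab, tagset, use_char))
  theta <- cpp_tagger_init(dims, config$seed)
  st <- adam_state(length(theta))
  history <- data.frame(epoch = integer(), loss = numeric(), val_f1 = numeric())
  best <- list(f1 = -Inf, theta = theta, epoch = 0)
  model <- NULL
  rebuild <- function(th) {
    structure(list(theta = th, dims = dims, vocab = vocab, tagset = tagset,
                   mask = mask, config = config, history = history),
              class = "trained_tagger")
  }
  drop_seed <- config$seed
  for (epoch in seq_len(config$epochs)) {
    ord <- run_with_seed(config$seed + 7919L * epoch, sample.int(length(seqs)))
    total_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      drop_seed <- (drop_seed * 69069 + 1) %% 2147483647
      lg <- cpp_tagger_loss_grad(theta, dims, seqs[b], mask, config$dropout,
                                 as.integer(drop_seed))
      total_loss <- total_loss + lg$loss
      up <- adam_step(theta, lg$grad / length(b), st, config$learning_rate)
      theta <- up$theta
      st <- up$state
    }
    model <- rebuild(theta)
    vf1 <- if (length(val_notes)) tagger_validation_f1(model, val_notes) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = total_loss / length(seqs),
                                         val_f1 = vf1))
    if (!quiet)
      message(sprintf("epoch %d: loss %.4f, val F1 %.4f", epoch,
                      total_loss / length(seqs), vf1))
    score <- if (is.na(vf1)) -history$loss[epoch] else vf1
    if (score > best$f1 + 1e-9) best <- list(f1 = score, theta = theta, epoch = epoch)
    min_ep <- if (is.null(config$min_epochs)) 0 else config$min_epochs
    if (epoch >= min_ep && epoch - best$epoch >= config$patience) break
    if (!is.na(vf1) && vf1 >= 1) break
  }
  out <- rebuild(best$theta)
  out$history <- history
  out$val_f1 <- if (length(val_notes)) tagger_validation_f1(out, val_notes) else NA_real_
  out$n_train <- length(train_notes)
  out$n_val <- length(val_notes)
  out
}

#' @export
print.trained_tagger <- function(x, ...) {
  cat("<trained_tagger> |V|=", length(x$vocab$words), ", ",
      length(x$tagset), " tags, val F1 = ",
      if (is.na(x$val_f1)) "NA" else sprintf("%.3f", x$val_f1), "\n", sep = "")
  invisible(x)
}

# Exact-span micro-F1 of the tagger on a list of gold notes.
tagger_validation_f1 <- function(model, notes) {
  gold <- do.call(rbind, lapply(notes, function(n) {
    e <- n$entities
    if (nrow(e) == 0) return(NULL)
    cbind(doc_id = n$doc_id, e[, c("label", "start", "end")])
  }))
  pred <- do.call(rbind, lapply(notes, function(n) {
    e <- predict_entities(model, n$text)
    if (nrow(e) == 0) return(NULL)
    cbind(doc_id = n$doc_id, e[, c("label", "start", "end")])
  }))
  if (is.null(gold)) gold <- data.frame(doc_id = character(), label = character(),
                                        start = integer(), end = integer())
  if (is.null(pred)) pred <- data.frame(doc_id = character(), label = character(),
                                        start = integer(), end = integer())
  micro_f1(metrics(match_entities(gold, pred, mode = "exact")))
}

#' Iterative training until a validation F1 threshold is reached
#'
#' Mirrors the annotate-retrain loop used to develop clinical taggers: after
#' each batch of annotated notes is added to the pool, the model is retrained
#' from scratch and evaluated on a held-out split of the pool; the loop stops
#' once validation micro-F1 exceeds `f1_threshold` or the batches are
#' exhausted (in which case the best model is returned with a warning).
#'
#' @param corpus_batches List of lists of `annotated_note`.
#' @param config A [tagger_config()].
#' @param f1_threshold Stop once validation micro-F1 exceeds this value.
#' @param split Train fraction within the accumulated pool.
#' @param quiet Suppress progress messages.
#' @return A `trained_tagger` with elements `loop_history` (per-batch
#'   validation F1) and `reached_threshold`.
#' @export
train_until <- function(corpus_batches, config = tagger_config(),
                        f1_threshold = 0.8, split = 0.8, quiet = TRUE) {
  stopifnot(length(corpus_batches) >= 1)
  pool <- list()
  loop <- data.frame(batch = integer(), n_notes = integer(), val_f1 = numeric())
  best <- NULL
  for (i in seq_along(corpus_batches)) {
    pool <- c(pool, corpus_batches[[i]])
    model <- train_tagger(pool, config, split = split, quiet = quiet)
    loop <- rbind(loop, data.frame(batch = i, n_notes = length(pool),
                                   val_f1 = model$val_f1))
    if (is.null(best) || model$val_f1 > best$val_f1) best <- model
    if (!quiet)
      message(sprintf("batch %d (%d notes): val F1 %.4f", i, length(pool),
                      model$val_f1))
    if (model$val_f1 > f1_threshold) {
      model$loop_history <- loop
      model$reached_threshold <- TRUE
      return(model)
    }
  }
  warning("F1 threshold ", f1_threshold, " not reached; returning best model")
  best$loop_history <- loop
  best$reached_threshold <- FALSE
  best
}

#' Predict entities in note text
#'
#' Tokenizes, scores with the BiLSTM, decodes BIO tags with the
#' BIO-constrained Viterbi and projects contiguous B/I runs back to character
#' spans.
#'
#' @param model A `trained_tagger`.
#' @param text Note text.
#' @return Entity data frame (`id, label, start, end, surface`).
#' @export
predict_entities <- function(model, text) {
  toks <- tokenize(text)
  if (nrow(toks) == 0) return(empty_entities())
  seq <- encode_sequence(toks, NULL, model$vocab, model$tagset,
                         model$dims$dim_char > 0)
  path <- cpp_tagger_decode(model$theta, model$dims, seq, model$mask)
  bio_to_entities(toks, model$tagset[path], text)
}

#' Annotate a list of notes with predicted entities (and linked relations)
#'
#' @param model A `trained_tagger`.
#' @param notes List of `annotated_note` (entities ignored).
#' @param schema Ontology schema for relation linking; `NULL` skips linking.
#' @param linker A [linker_config()].
#' @return List of `annotated_note` with predicted entities/relations.
#' @export
annotate_notes <- function(model, notes, schema = ontology_schema(),
                           linker = linker_config()) {
  lapply(notes, function(n) {
    ents <- predict_entities(model, n$text)
    out <- annotated_note(n$doc_id, n$text, ents, empty_relations(),
                          patient_id = n$patient_id, note_date = n$note_date,
                          department = n$department, schema = schema)
    if (!is.null(schema)) {
      out$relations <- link_relations(out, schema, linker)
      validate_note(out, schema)
    }
    out
  })
}

#' Save / load a trained tagger
#'
#' The artifact bundles parameters, vocabularies, tag set, BIO mask, config
#' and training history; predictions are identical after reload.
#'
#' @param model A `trained_tagger`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_tagger <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_tagger"))
  model
}
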