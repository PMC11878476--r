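# The tagger's numerical core is exercised three ways: a finite-difference
# gradient check of the hand-derived backpropagation, capacity/convergence
# checks on tiny corpora, and structural properties of decoding.

tiny_dims <- list(n_words = 6, dim_word = 5, n_chars = 8, dim_char = 3,
                  dim_char_hidden = 4, hidden = 6, n_tags = 5)
tiny_mask <- memotrace:::bio_transition_mask(c("O", "B-A", "I-A", "B-B", "I-B"))
tiny_seqs <- list(
  list(words = c(0L, 2L, 3L, 1L), caps = c(1, 0, 0, 0),
       chars = list(c(0L, 1L), c(2L, 3L, 4L), 5L, c(6L, 7L)),
       tags = c(1L, 2L, 3L, 4L)),
  list(words = c(4L, 5L), caps = c(0, 1),
       chars = list(c(1L, 2L), 3L), tags = c(2L, 3L)))

test_that("analytic gradients match finite differences", {
  theta <- memotrace:::cpp_tagger_init(tiny_dims, 42)
  lg <- memotrace:::cpp_tagger_loss_grad(theta, tiny_dims, tiny_seqs, tiny_mask, 0, 1)
  expect_true(is.finite(lg$loss))
  eps <- 1e-6
  set.seed(7)
  idx <- sort(sample(length(theta), 150))
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (memotrace:::cpp_tagger_loss(tp, tiny_dims, tiny_seqs, tiny_mask) -
       memotrace:::cpp_tagger_loss(tm, tiny_dims, tiny_seqs, tiny_mask)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - lg$grad[idx]) / pmax(1e-4, abs(num) + abs(lg$grad[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("training loss decreases and a tiny corpus is memorized", {
  notes <- notes_small()[1:12]
  cfg <- tagger_config(dim_word = 24, dim_char = 8, dim_char_hidden = 8,
                       hidden = 24, dropout = 0, epochs = 60, patience = 60,
                       batch_size = 2, seed = 3)
  m <- memotrace:::fit_tagger(notes, notes, cfg)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  expect_equal(m$val_f1, 1)  # training-set F1 reaches 1 (capacity check)
  # memorized note predicts its gold entities exactly
  n <- notes[[1]]
  pred <- predict_entities(m, n$text)
  expect_equal(pred[order(pred$start), c("label", "start", "end")],
               n$entities[order(n$entities$start), c("label", "start", "end")],
               ignore_attr = TRUE)
})

test_that("prediction is empty on empty text", {
  notes <- notes_small()[1:12]
  cfg <- tagger_config(dim_word = 16, dim_char = 0, hidden = 12, epochs = 2,
                       dropout = 0, seed = 1)
  m <- memotrace:::fit_tagger(notes, list(), cfg)
  expect_equal(nrow(predict_entities(m, "")), 0)
})

test_that("training is deterministic under a fixed seed", {
  notes <- notes_small()[1:15]
  cfg <- tagger_config(dim_word = 16, dim_char = 8, dim_char_hidden = 4,
                       hidden = 12, epochs = 3, patience = 3, seed = 11)
  m1 <- train_tagger(notes, cfg, split = 0.8)
  m2 <- train_tagger(notes, cfg, split = 0.8)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$history, m2$history)
})

test_that("decoded sequences never contain an illegal BIO transition", {
  notes <- notes_small()[1:20]
  cfg <- tagger_config(dim_word = 16, dim_char = 0, hidden = 12, epochs = 1,
                       dropout = 0.5, seed = 2)
  m <- memotrace:::fit_tagger(notes, list(), cfg)  # barely trained on purpose
  for (n in notes_small()[21:50]) {
    toks <- tokenize(n$text)
    seq <- memotrace:::encode_sequence(toks, NULL, m$vocab, m$tagset, FALSE)
    path <- memotrace:::cpp_tagger_decode(m$theta, m$dims, seq, m$mask)
    tags <- m$tagset[path]
    prev <- "O"
    for (tg in tags) {
      if (startsWith(tg, "I-"))
        expect_true(prev %in% paste0(c("B-", "I-"), sub("^I-", "", tg)))
      prev <- tg
    }
  }
})

test_that("predictions are identical after serialization round trip", {
  notes <- notes_small()[1:12]
  cfg <- tagger_config(dim_word = 16, dim_char = 8, dim_char_hidden = 4,
                       hidden = 12, epochs = 3, patience = 3, seed = 5)
  m <- memotrace:::fit_tagger(notes, list(), cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_tagger(m, path)
  m2 <- load_tagger(path)
  for (n in notes_small()[13:20])
    expect_identical(predict_entities(m2, n$text), predict_entities(m, n$text))
})

test_that("a corpus split of 815 notes at 80 percent gives 652 and 163", {
  expect_equal(train_val_sizes(815, 0.8), c(train = 652L, validation = 163L))
})

test_that("tags outside the schema are rejected before training", {
  expect_error(
    memotrace:::encode_sequence(tokenize("memory loss"), c("B-NOPE", "O"),
                                list(words = c("<unk>", "memory", "loss"),
                                     chars = "<unk>"),
                                memotrace:::bio_tagset(), FALSE),
    "tag outside schema")
})

test_that("the iterative loop stops by threshold and is seed-deterministic", {
  notes <- notes_small()[1:120]
  batches <- split(notes, ceiling(seq_along(notes) / 60))
  cfg <- tagger_config(seed = 4)
  # threshold 0: stops after the first batch regardless of quality
  m0 <- train_until(batches, cfg, f1_threshold = 0)
  expect_equal(nrow(m0$loop_history), 1)
  expect_true(m0$reached_threshold)
  m0b <- train_until(batches, cfg, f1_threshold = 0)
  expect_identical(m0$loop_history, m0b$loop_history)
  expect_identical(m0$theta, m0b$theta)
  # unreachable threshold: exhausts batches, warns, returns best model
  expect_warning(mx <- train_until(batches[1], cfg, f1_threshold = 1.5),
                 "not reached")
  expect_false(mx$reached_threshold)
})
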